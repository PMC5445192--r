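# Interleaved LCP array: the per-document LCP arrays interleaved in global
# suffix-array order. Inside a pattern's interval, values below the pattern
# length mark exactly the leftmost occurrence of each distinct document, so
# the array supports document listing (RMQ recursion over the run heads) and
# document counting (skewed wavelet tree over the run heads plus run lengths
# grouped by value).

#' Build the interleaved LCP array
#'
#' For each document, computes its own LCP array (Kasai scan over the
#' document plus terminator) and writes its entries, in order, at the global
#' suffix-array positions belonging to that document.
#'
#' @param collection a \code{repindex_collection}.
#' @param index the \code{repindex_sa} built over it.
#' @return integer vector \code{ILCP[1..n]}.
#' @examples
#' col <- new_collection(c("TATA", "LATA", "AAAA"))
#' build_ilcp(col, build_index(col))
#' # 0 0 0 0 0 0 1 2 3 1 1 0 0 0 2
#' @export
build_ilcp <- function(collection, index) {
  DA <- index$DA
  ilcp <- integer(collection$n)
  for (j in seq_len(collection$d)) {
    Sj <- c(str_to_codes(collection$texts[j]), SENTINEL)
    sa_j <- sa_prefix_doubling(Sj)
    lcp_j <- lcp_kasai(Sj, sa_j)
    ilcp[which(DA == j)] <- lcp_j
  }
  ilcp
}

#' Run-length encode the interleaved LCP array
#'
#' Produces the run-head values \code{VILCP} in a skewed wavelet tree, the
#' run-start bitvector \code{L} (one 1 per run), and the value-grouped length
#' bitvector \code{L'}: run lengths, grouped by value in increasing value
#' order (runs of equal value kept in left-to-right order), each run written
#' as a 1 followed by length-1 zeros, so that select over \code{L'} yields
#' partial sums of lengths per wavelet-tree leaf.
#'
#' @param ilcp integer vector from \code{\link{build_ilcp}}.
#' @return object of class \code{repindex_ilcp} with fields \code{rho},
#'   \code{VILCP}, \code{L}, \code{Lprime}, \code{wt}, \code{lambda},
#'   \code{run_start}, \code{run_end}, and the per-value group offsets.
#' @export
encode_runs <- function(ilcp) {
  stopifnot(length(ilcp) >= 1L)
  runs <- rle(ilcp)
  rho <- length(runs$values)
  n <- length(ilcp)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  Lbits <- logical(n)
  Lbits[run_start] <- TRUE
  # group runs by value (stable: equal values keep left-to-right order)
  grp <- order(runs$values)
  glen <- runs$lengths[grp]
  Lp_bits <- logical(n)
  Lp_bits[cumsum(glen) - glen + 1L] <- TRUE
  lambda <- max(ilcp)
  # run_offset[v + 1] = number of runs whose value is < v
  run_offset <- cumsum(c(0L, tabulate(runs$values + 1L, nbins = lambda + 1L)))
  structure(list(
    rho = rho, n = n, lambda = lambda,
    VILCP = runs$values,
    L = bitvector(Lbits, "sparse"),
    Lprime = bitvector(Lp_bits, "sparse"),
    wt = wavelet_tree(runs$values, "skewed"),
    vilcp_rmq = rmq_build(runs$values),
    run_start = run_start, run_end = run_end,
    run_offset = run_offset
  ), class = "repindex_ilcp")
}

#' Decode a run-length encoded ILCP structure
#'
#' Expands \code{(VILCP, L)} back to the flat array; inverse of
#' \code{\link{encode_runs}}.
#' @param structure a \code{repindex_ilcp}.
#' @return integer vector of length \code{n}.
#' @export
decode_runs <- function(structure) {
  rep(structure$VILCP, structure$run_end - structure$run_start + 1L)
}

#' Document listing via the run-length encoded ILCP array
#'
#' Maps the suffix-array interval to its run interval, then runs the
#' leftmost-minimum RMQ recursion over the run heads (left branch before
#' right): every minimal run below the pattern length is expanded (select on
#' \code{L}, clipped to \code{[l..r]}) and its documents reported and marked;
#' a run whose first document is already marked stops its branch, since its
#' value is at least the pattern length.
#'
#' @param structure a \code{repindex_ilcp}.
#' @param index the underlying \code{repindex_sa}.
#' @param l,r suffix-array interval of a pattern, as returned by
#'   \code{\link{search_pattern}}. For intervals that do not come from a
#'   pattern search the result is unspecified.
#' @param m the pattern length.
#' @return integer vector of document identifiers in discovery order.
#' @export
ilcp_list <- function(structure, index, l, r, m) {
  if (l > r) return(integer(0))
  DA <- index$DA
  lp <- bv_rank(structure$L, 1L, l)
  rp <- bv_rank(structure$L, 1L, r)
  V <- logical(index$collection$d)
  res <- integer(0)
  st <- structure$vilcp_rmq
  vals <- structure$VILCP
  rs <- structure$run_start
  re <- structure$run_end
  recurse <- function(a, b) {
    if (a > b) return(invisible())
    k <- rmq(st, a, b)
    if (vals[k] >= m) return(invisible())
    i <- max(l, rs[k])
    j <- min(r, re[k])
    if (V[DA[i]]) return(invisible())
    for (kk in i:j) {
      doc <- DA[kk]
      if (!V[doc]) {
        V[doc] <<- TRUE
        res[length(res) + 1L] <<- doc
      }
    }
    recurse(a, k - 1L)
    recurse(k + 1L, b)
    invisible()
  }
  recurse(lp, rp)
  res
}

#' Document counting via the run-length encoded ILCP array
#'
#' Counts positions of \code{ILCP[l..r]} holding values below the pattern
#' length without listing documents: descends the skewed wavelet tree of the
#' run heads only into value ranges intersecting \code{[0..m-1]}, sums the
#' spanned run lengths per reached leaf via select on the value-grouped
#' length bitvector \code{L'}, and corrects the first and last run of the
#' interval for partial overlap with \code{[l..r]}.
#'
#' @inheritParams ilcp_list
#' @return integer document count \code{df}.
#' @export
ilcp_count <- function(structure, index, l, r, m) {
  if (l > r) return(0L)
  if (l == r) return(1L)  # a single suffix always lies in exactly one document
  lp <- bv_rank(structure$L, 1L, l)
  rp <- bv_rank(structure$L, 1L, r)
  below <- wt_count_below(structure$wt, lp, rp, m)$hits
  if (nrow(below) == 0L) return(0L)
  # select positions of L' (run starts in the grouped layout), with sentinel
  ones <- structure$Lprime$ones
  startpos <- c(ones, structure$n + 1L)
  total <- 0L
  for (h in seq_len(nrow(below))) {
    v <- below$value[h]
    off <- structure$run_offset[v + 1L]
    a <- off + below$lo[h]
    b <- off + below$hi[h]
    total <- total + (startpos[b + 1L] - startpos[a])
  }
  # the first and last run of [lp..rp] may overlap the interval only partly
  vl <- wt_access(structure$wt, lp)
  if (vl < m) total <- total - (l - structure$run_start[lp])
  vr <- if (rp == lp) vl else wt_access(structure$wt, rp)
  if (vr < m) total <- total - (structure$run_end[rp] - r)
  as.integer(total)
}
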