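# Sadakane-style document counting. For every internal node v of the
# binarized suffix tree with children u, w, the redundancy h(v) = |D_u n D_w|
# satisfies count(v) = count(u) + count(w) - h(v); listing the h values in
# inorder gives an array H with count(l, r) = (r+1-l) - sum(H[l..r-1]),
# answered in constant time from the unary-encoded bitvector H'. Because
# only original (non-binarized) nodes are ever queried, the h-mass of the
# binarization chain of a node is reassigned to the node's own inorder
# position, which makes H' far more compressible.

#' Build the counting array H of a collection
#'
#' Binarizes each multi-way suffix tree node by combining its children
#' right-to-left into a chain, computes the redundancies h over the actual
#' document sets, and reassigns each chain's mass to the original node's
#' inorder position (the suffix-array index where its first child's interval
#' ends). Also derives the values needed by the compressed encodings: the
#' pruning filter F (nodes with more than one distinct document), the
#' pruned-tree H, and per-cell values for the sparse and 1-filters.
#'
#' @param index a \code{repindex_sa}.
#' @param st optional precomputed \code{\link{suffix_tree}}.
#' @return object of class \code{repindex_h} with fields \code{H} (integer,
#'   length n-1), \code{Hp} (pruned-tree values, aligned to \code{F}),
#'   \code{F} (logical: binarized node at this inorder position spans more
#'   than one document), and \code{n}.
#' @export
build_h <- function(index, st = NULL) {
  if (is.null(st)) st <- suffix_tree(index)
  DA <- index$DA
  n <- index$collection$n
  H <- integer(n - 1L)
  Hp <- integer(n - 1L)
  Fbits <- logical(n - 1L)
  for (v in seq_len(st$n_nodes)) {
    if (st$leaf[v]) next
    ch <- st$children[[v]]
    k <- length(ch)
    Dc <- lapply(ch, function(c) unique(DA[st$l[c]:st$r[c]]))
    # suffix unions right-to-left: U[[j]] = docs of children j..k
    U <- vector("list", k)
    U[[k]] <- Dc[[k]]
    if (k > 1L) for (j in (k - 1L):1L) U[[j]] <- union(Dc[[j]], U[[j + 1L]])
    e <- st$r[ch]            # child interval ends; positions e[1..k-1]
    hvals <- vapply(seq_len(k - 1L),
                    function(j) length(intersect(Dc[[j]], U[[j + 1L]])),
                    integer(1L))
    H[e[1L]] <- sum(hvals)
    cnt1 <- length(U[[1L]])  # |D_v|
    Fbits[e[1L]] <- cnt1 > 1L
    if (k > 2L) {
      chain_cnt <- lengths(U)[2L:(k - 1L)]
      Fbits[e[2L:(k - 1L)]] <- chain_cnt > 1L
      # pruned tree keeps chain nodes spanning >1 document
      Hp[e[1L]] <- hvals[1L] + sum(hvals[-1L][chain_cnt > 1L])
    } else {
      Hp[e[1L]] <- hvals[1L]
    }
  }
  structure(list(H = H, Hp = Hp, F = Fbits, n = n), class = "repindex_h")
}

# unary encoding: cell value x -> a 1-bit followed by x 0-bits
unary_bits <- function(values) {
  if (length(values) == 0L) return(logical(0))
  total <- length(values) + sum(values)
  bits <- logical(total)
  bits[cumsum(c(1L, values[-length(values)] + 1L))] <- TRUE
  bits
}

#' Encode the counting array with an encoding and optional filters
#'
#' @param h a \code{repindex_h} from \code{\link{build_h}}.
#' @param encoding bitvector representation of H': \code{"plain"} or
#'   \code{"sparse"}. Query results are identical; only the storage differs.
#' @param filters character subset of \code{c("F", "F_S", "F_1")}.
#'   \code{"F"} prunes single-document subtrees (and cannot be combined with
#'   the others); \code{"F_S"} keeps H' cells only where H > 0; \code{"F_1"}
#'   drops the 0-runs of cells with H = 1 and corrects the query by the
#'   number of marked cells; together, \code{F_S} marks cells with H > 1.
#' @return object of class \code{repindex_count}.
#' @export
encode_h <- function(h, encoding = c("plain", "sparse"), filters = character(0)) {
  encoding <- match.arg(encoding)
  if (length(filters)) {
    bad <- setdiff(filters, c("F", "F_S", "F_1"))
    if (length(bad)) stop("unknown filter(s): ", paste(bad, collapse = ", "))
    if ("F" %in% filters && length(filters) > 1L)
      stop("filter F cannot be combined with F_S / F_1")
  }
  n <- h$n
  obj <- list(encoding = encoding, filters = filters, n = n)
  if ("F" %in% filters) {
    obj$Fbv <- bitvector(h$F, "sparse")
    obj$Hprime <- bitvector(unary_bits(h$Hp[h$F]), encoding)
    obj$cells <- sum(h$F)
  } else {
    fs <- "F_S" %in% filters
    f1 <- "F_1" %in% filters
    if (f1) obj$F1bv <- bitvector(h$H == 1L, "sparse")
    vals <- h$H
    if (f1) vals[vals == 1L] <- 0L
    if (fs) {
      keep <- if (f1) h$H > 1L else h$H > 0L
      obj$FSbv <- bitvector(keep, "sparse")
      vals <- vals[keep]
      obj$cells <- sum(keep)
    } else {
      obj$cells <- n - 1L
    }
    obj$Hprime <- bitvector(unary_bits(vals), encoding)
  }
  structure(obj, class = "repindex_count")
}

# sum of the encoded cell values a..b (1-based cells of this H'), via select
hprime_sum <- function(cs, a, b) {
  if (a > b) return(0L)
  sa <- bv_select(cs$Hprime, 1L, a)
  sb <- if (b == cs$cells) cs$Hprime$length + 1L
        else bv_select(cs$Hprime, 1L, b + 1L)
  as.integer((sb - sa) - (b + 1L - a))
}

#' Count distinct documents in a locus interval
#'
#' Evaluates the closed-form select expression over the unary bitvector H'
#' (with the corrections the active filters require). The interval must be
#' the suffix-array interval of a suffix tree node (the locus of some
#' pattern); behavior on other intervals is undefined.
#'
#' @param cs a \code{repindex_count}.
#' @param l,r closed locus interval; \code{l == r} returns 1 immediately.
#' @return integer \code{df}.
#' @export
sada_count <- function(cs, l, r) {
  if (l > r) stop("empty interval")
  if (l == r) return(1L)
  if (l < 1L || r > cs$n) stop("interval out of range")
  occ <- r + 1L - l
  if ("F" %in% cs$filters) {
    a <- bv_rank(cs$Fbv, 1L, l - 1L) + 1L
    b <- bv_rank(cs$Fbv, 1L, r - 1L)
    if (b < a) return(1L)  # locus inside a pruned (single-document) subtree
    return((b - a + 2L) - hprime_sum(cs, a, b))
  }
  corr <- if ("F_1" %in% cs$filters)
    bv_rank(cs$F1bv, 1L, r - 1L) - bv_rank(cs$F1bv, 1L, l - 1L) else 0L
  if ("F_S" %in% cs$filters) {
    a <- bv_rank(cs$FSbv, 1L, l - 1L) + 1L
    b <- bv_rank(cs$FSbv, 1L, r - 1L)
    return(occ - hprime_sum(cs, a, b) - corr)
  }
  occ - hprime_sum(cs, l, r - 1L) - corr
}

#' Runs of 1s in the plain unary counting bitvector
#'
#' The number of maximal runs of 1-bits in H' (no filters), the quantity
#' whose sublinear growth makes the structure compressible on repetitive and
#' on random collections alike.
#' @param h a \code{repindex_h}.
#' @return integer run count.
#' @export
hprime_runs <- function(h) {
  bits <- unary_bits(h$H)
  rn <- rle(bits)
  sum(rn$values)
}
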