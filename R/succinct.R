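# Rank/select bitvectors, range-minimum structures, and the skewed wavelet
# tree used by the ILCP counting structure. The contracts are the classical
# rank/select/rmq semantics; space layout is not optimized (a plain bitvector
# keeps a cumulative-rank vector, a sparse one keeps the sorted 1-positions).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a rank/select bitvector
#'
#' @param bits logical (or 0/1) vector.
#' @param encoding \code{"plain"} stores the bits plus cumulative ranks;
#'   \code{"sparse"} stores only the sorted positions of the 1s.
#' @return object of class \code{repindex_bitvector}.
#' @export
bitvector <- function(bits, encoding = c("plain", "sparse")) {
  encoding <- match.arg(encoding)
  bits <- as.logical(bits)
  if (anyNA(bits)) stop("bits must be 0/1 without NAs")
  obj <- list(length = length(bits), encoding = encoding)
  if (encoding == "plain") {
    obj$bits <- bits
    obj$csum <- cumsum(bits)
  } else {
    obj$ones <- which(bits)
  }
  structure(obj, class = "repindex_bitvector")
}

#' Rank over a bitvector
#'
#' Counts occurrences of bit \code{c} in positions \code{1..i}; \code{i = 0}
#' yields 0 by convention.
#' @param bv a \code{repindex_bitvector}.
#' @param c bit value, 0 or 1.
#' @param i position(s), \code{0 <= i <= length}.
#' @return integer count(s).
#' @export
bv_rank <- function(bv, c, i) {
  if (any(i < 0L | i > bv$length)) stop("rank position out of range")
  r1 <- if (bv$encoding == "plain") {
    ifelse(i == 0L, 0L, bv$csum[pmax(i, 1L)])
  } else {
    findInterval(i, bv$ones)
  }
  if (c == 1L) as.integer(r1) else as.integer(i - r1)
}

#' Select over a bitvector
#'
#' Position of the \code{j}th occurrence of bit \code{c}.
#' @inheritParams bv_rank
#' @param j occurrence index, \code{1 <= j <= rank_c(length)}.
#' @export
bv_select <- function(bv, c, j) {
  ones <- if (bv$encoding == "plain") which(bv$bits) else bv$ones
  pos <- if (c == 1L) ones else which(!bv_bits(bv))
  if (any(j < 1L | j > length(pos))) stop("select index exceeds bit count")
  pos[j]
}

#' Materialize the bits of a bitvector
#' @param bv a \code{repindex_bitvector}.
#' @return logical vector.
#' @export
bv_bits <- function(bv) {
  if (bv$encoding == "plain") return(bv$bits)
  out <- logical(bv$length)
  out[bv$ones] <- TRUE
  out
}

#' Range-minimum structure with leftmost tie-breaking
#'
#' Sparse-table RMQ over an integer array. Queries return the position of the
#' leftmost minimum in a closed range, the tie-break required by the listing
#' recursions.
#' @param values integer vector.
#' @return object of class \code{repindex_rmq}.
#' @export
rmq_build <- function(values) {
  n <- length(values)
  if (n == 0L) stop("cannot build RMQ over an empty array")
  K <- max(1L, floor(log2(n)) + 1L)
  idx <- matrix(NA_integer_, nrow = K, ncol = n)
  idx[1L, ] <- seq_len(n)
  if (K > 1L) for (k in 2L:K) {
    half <- 2L^(k - 2L)
    span <- 2L^(k - 1L)
    m <- n - span + 1L
    if (m < 1L) break
    a <- idx[k - 1L, seq_len(m)]
    b <- idx[k - 1L, seq_len(m) + half]
    # strict < keeps the leftmost minimiser
    idx[k, seq_len(m)] <- ifelse(values[b] < values[a], b, a)
  }
  structure(list(values = values, idx = idx, n = n), class = "repindex_rmq")
}

#' Leftmost range-minimum query
#'
#' @param st a \code{repindex_rmq}.
#' @param i,j closed query range, \code{1 <= i <= j <= n}.
#' @return position \code{k} of the leftmost minimum of \code{values[i..j]}.
#' @export
rmq <- function(st, i, j) {
  if (i > j) stop("inverted or empty RMQ range")
  if (i < 1L || j > st$n) stop("RMQ range out of bounds")
  if (i == j) return(i)
  k <- floor(log2(j - i + 1L))
  a <- st$idx[k + 1L, i]
  b <- st$idx[k + 1L, j - 2L^k + 1L]
  if (st$values[b] < st$values[a]) b else a
}

# ---------------------------------------------------------------------------
# Wavelet trees
#
# Leaf i (1-based, holding value i-1) of the skewed shape sits at depth
# 1 + 2*floor(log2(i)): leaf 1 hangs off the root, leaves 2-3 live in a
# balanced group two levels down the right spine, leaves 4-7 in the next
# group, and so on. Descending for values [0..m-1] therefore touches at most
# 4m-2 nodes, regardless of the full alphabet size.
# ---------------------------------------------------------------------------

# Builder. vals = sorted distinct values this node is responsible for.
# mode = "balanced" halves the leaf set; "spine" (skewed) splits off the
# current leaf group (size `group`) into a balanced left subtree and recurses
# on the spine with a doubled group.
wt_build_node <- function(seq, vals, mode, group = 1L) {
  if (length(vals) == 1L)
    return(list(leaf = TRUE, value = vals[1L], size = length(seq)))
  nl <- if (mode == "spine") min(group, length(vals) - 1L)
        else ceiling(length(vals) / 2L)
  left_vals <- vals[seq_len(nl)]
  right_vals <- vals[-seq_len(nl)]
  bits <- seq > left_vals[nl]
  left <- wt_build_node(seq[!bits], left_vals, "balanced")
  right <- wt_build_node(seq[bits], right_vals, mode, group * 2L)
  list(leaf = FALSE, bv = bitvector(bits),
       min_val = vals[1L], left_max = left_vals[nl], max_val = vals[length(vals)],
       left = left, right = right)
}

#' Build a wavelet tree over a non-negative integer sequence
#'
#' The alphabet is \code{0..max(seq)}; every value in that range gets a leaf,
#' so leaf index arithmetic is direct (leaf \code{i} holds value \code{i-1}).
#'
#' @param seq non-negative integer vector.
#' @param shape \code{"skewed"} places the i-th leftmost leaf at depth
#'   \code{1 + 2*floor(log2(i))}, keeping traversals for small values cheap
#'   even when the maximum value is large; \code{"balanced"} is the usual
#'   halving shape.
#' @return object of class \code{repindex_wt}.
#' @export
wavelet_tree <- function(seq, shape = c("skewed", "balanced")) {
  shape <- match.arg(shape)
  seq <- as.integer(seq)
  if (length(seq) == 0L) stop("empty sequence")
  if (any(seq < 0L)) stop("wavelet tree requires non-negative values")
  sigma <- max(seq) + 1L
  vals <- 0L:(sigma - 1L)
  root <- wt_build_node(seq, vals,
                        if (shape == "skewed") "spine" else "balanced")
  structure(list(root = root, n = length(seq), sigma = sigma, shape = shape),
            class = "repindex_wt")
}

#' Access a wavelet tree position
#' @param wt a \code{repindex_wt}.
#' @param i position in the underlying sequence.
#' @return the stored value.
#' @export
wt_access <- function(wt, i) {
  if (i < 1L || i > wt$n) stop("position out of range")
  node <- wt$root
  while (!node$leaf) {
    r1 <- bv_rank(node$bv, 1L, i)
    r1prev <- bv_rank(node$bv, 1L, i - 1L)
    if (r1 > r1prev) {            # bit is 1 -> right
      i <- r1
      node <- node$right
    } else {
      i <- i - r1
      node <- node$left
    }
  }
  node$value
}

#' Occurrence intervals of all values below a bound in a range
#'
#' Descends the wavelet tree over \code{seq[l..r]}, pruning every subtree
#' whose value range is disjoint from \code{[0..m-1]} and every empty
#' interval. For each reached leaf it reports the leaf value, the global
#' occurrence ranks \code{lo..hi} of that value covered by \code{[l..r]}
#' (i.e. the \code{lo}-th to \code{hi}-th occurrences of the value in the
#' whole sequence), and the count \code{hi - lo + 1}.
#'
#' @param wt a \code{repindex_wt}.
#' @param l,r closed range over the underlying sequence.
#' @param m upper bound; only values \code{< m} are reported. \code{m} larger
#'   than the alphabet yields all distinct values in the range.
#' @return list with \code{hits}: data.frame(value, lo, hi, count), ordered
#'   by value, and \code{visited}: number of tree nodes touched.
#' @export
wt_count_below <- function(wt, l, r, m) {
  if (l > r) stop("empty range")
  if (l < 1L || r > wt$n) stop("range outside sequence")
  if (m < 1L) stop("m must be >= 1")
  hits <- vector("list", 16L)
  nh <- 0L
  visited <- 0L
  walk <- function(node, a, b) {
    # a = mapped l-1, b = mapped r within this node's subsequence
    visited <<- visited + 1L
    if (node$leaf) {
      nh <<- nh + 1L
      hits[[nh]] <<- c(node$value, a + 1L, b)
      return(invisible())
    }
    if (node$min_val < m) {
      a0 <- a - bv_rank(node$bv, 1L, a)
      b0 <- b - bv_rank(node$bv, 1L, b)
      if (b0 > a0) walk(node$left, a0, b0)
    }
    if (node$left_max + 1L < m) {
      a1 <- bv_rank(node$bv, 1L, a)
      b1 <- bv_rank(node$bv, 1L, b)
      if (b1 > a1) walk(node$right, a1, b1)
    }
    invisible()
  }
  walk(wt$root, l - 1L, r)
  hits <- hits[seq_len(nh)]
  df <- if (nh) {
    mat <- do.call(rbind, hits)
    data.frame(value = mat[, 1L], lo = mat[, 2L], hi = mat[, 3L],
               count = mat[, 3L] - mat[, 2L] + 1L)
  } else {
    data.frame(value = integer(0), lo = integer(0), hi = integer(0),
               count = integer(0))
  }
  df <- df[order(df$value), , drop = FALSE]
  rownames(df) <- NULL
  list(hits = df, visited = visited)
}
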