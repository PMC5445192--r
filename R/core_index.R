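# Suffix-array backend filling the CSA role: construction, pattern search to
# a lexicographic interval [l..r], direct suffix lookup, the document array,
# and the brute-force / classical listing oracles every other engine is
# verified against.

# Prefix-doubling suffix array over integer symbol codes (sentinel = 0 sorts
# first because codes are compared numerically).
sa_prefix_doubling <- function(T) {
  n <- length(T)
  if (n == 1L) return(1L)
  rk <- match(T, sort(unique(T)))
  k <- 1L
  repeat {
    rk2 <- c(rk[-seq_len(min(k, n))], integer(min(k, n)))
    o <- order(rk, rk2)
    a <- rk[o]
    b <- rk2[o]
    newr <- integer(n)
    newr[o] <- cumsum(c(1L, (a[-1L] != a[-n]) | (b[-1L] != b[-n])))
    rk <- newr
    if (rk[o[n]] == n) break
    k <- k * 2L
  }
  order(rk)
}

# Kasai's algorithm; lcp[1] = 0, lcp[i] = lcp of suffixes SA[i-1], SA[i].
lcp_kasai <- function(T, SA) {
  n <- length(T)
  rank <- integer(n)
  rank[SA] <- seq_len(n)
  lcp <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    r <- rank[i]
    if (r > 1L) {
      j <- SA[r - 1L]
      while (i + h <= n && j + h <= n && T[i + h] == T[j + h]) h <- h + 1L
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Build a suffix-array index over a collection
#'
#' Sorts all suffixes of the concatenation (sentinels included, the sentinel
#' smallest) and materializes the document array
#' \code{DA[i] = rank1(B, SA[i])}.
#'
#' @param collection a \code{repindex_collection}.
#' @return object of class \code{repindex_sa} with fields \code{SA},
#'   \code{DA}, \code{LCP} (global LCP array) and the collection.
#' @examples
#' idx <- build_index(new_collection(c("TATA", "LATA", "AAAA")))
#' idx$SA[1]  # 15: the final sentinel is the smallest suffix
#' @export
build_index <- function(collection) {
  stopifnot(inherits(collection, "repindex_collection"))
  SA <- sa_prefix_doubling(collection$T)
  structure(list(SA = SA,
                 DA = collection$doc_of[SA],
                 LCP = lcp_kasai(collection$T, SA),
                 collection = collection),
            class = "repindex_sa")
}

# -1 / 0 / +1: compare suffix T[s..] against pattern P over |P| symbols;
# 0 means the suffix is prefixed by P.
suffix_cmp <- function(T, s, P) {
  n <- length(T)
  m <- length(P)
  len <- min(m, n - s + 1L)
  a <- T[s:(s + len - 1L)]
  b <- P[seq_len(len)]
  d <- which(a != b)
  if (length(d)) {
    i <- d[1L]
    return(if (a[i] < b[i]) -1L else 1L)
  }
  if (len < m) -1L else 0L
}

#' Search a pattern, returning its suffix-array interval
#'
#' Binary searches the sorted suffixes for the range \code{[l..r]} of
#' suffixes prefixed by \code{P}.
#'
#' @param index a \code{repindex_sa}.
#' @param pattern character scalar (sentinel-free, non-empty).
#' @return integer \code{c(l, r)} with \code{l <= r}, or \code{NULL} when the
#'   pattern does not occur.
#' @examples
#' idx <- build_index(new_collection(c("TATA", "LATA", "AAAA")))
#' search_pattern(idx, "TA")  # c(13, 15)
#' @export
search_pattern <- function(index, pattern) {
  P <- if (is.character(pattern)) str_to_codes(pattern) else as.integer(pattern)
  if (length(P) == 0L) stop("pattern must be non-empty")
  if (any(P == SENTINEL)) stop("pattern must not contain the sentinel byte")
  T <- index$collection$T
  SA <- index$SA
  n <- length(SA)
  # lower bound: first i with suffix >= P (cmp >= 0)
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (suffix_cmp(T, SA[mid], P) < 0L) lo <- mid + 1L else hi <- mid
  }
  l <- lo
  # upper bound: last i with suffix prefixed by or < P (cmp <= 0)
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (suffix_cmp(T, SA[mid], P) <= 0L) lo <- mid + 1L else hi <- mid
  }
  r <- lo - 1L
  if (l > r) NULL else c(l, r)
}

#' Look up a suffix-array cell
#' @param index a \code{repindex_sa}.
#' @param i position(s) in \code{1..n}.
#' @return \code{SA[i]}.
#' @export
sa_lookup <- function(index, i) {
  if (any(i < 1L | i > length(index$SA))) stop("index out of range [1..n]")
  index$SA[i]
}

#' Document-array view
#'
#' Returns both the materialized document array and an access function
#' computing entries on the fly from \code{SA} and the boundary ranks, so the
#' two routes can be cross-checked.
#' @param index a \code{repindex_sa}.
#' @return list with \code{DA} (integer vector) and \code{at(i)}.
#' @export
document_array <- function(index) {
  col <- index$collection
  list(DA = index$DA,
       at = function(i) col$doc_of[sa_lookup(index, i)])
}

#' Brute-force document listing over an interval
#'
#' Sorts the distinct document identifiers in \code{DA[l..r]}; the reference
#' answer every listing engine must reproduce.
#' @param index a \code{repindex_sa}.
#' @param l,r closed suffix-array interval; an empty interval (\code{l > r})
#'   yields an empty result.
#' @return sorted integer vector of document identifiers.
#' @export
brute_list <- function(index, l, r) {
  if (l > r) return(integer(0))
  sort(unique(index$DA[l:r]))
}

#' Brute-force top-k over an interval
#'
#' Counts occurrences per document in \code{DA[l..r]} and returns the k most
#' frequent, ties broken by increasing document identifier.
#' @inheritParams brute_list
#' @param k number of documents requested.
#' @return data.frame(doc, tf) with at most \code{k} rows, tf-descending.
#' @export
brute_topk <- function(index, l, r, k) {
  if (k < 1L) stop("k must be >= 1")
  if (l > r) return(data.frame(doc = integer(0), tf = integer(0)))
  tf <- table(index$DA[l:r])
  doc <- as.integer(names(tf))
  tf <- as.integer(tf)
  o <- order(-tf, doc)
  sel <- o[seq_len(min(k, length(o)))]
  data.frame(doc = doc[sel], tf = tf[sel])
}

#' Classical document listing via the C array and range-minimum recursion
#'
#' Builds Muthukrishnan's array \code{C[i]} (previous occurrence of
#' \code{DA[i]}, 0 if none) on demand and lists each distinct document once
#' by RMQ recursion: report positions with \code{C[k] < l}, recursing left
#' before right and stopping when the range minimum is \code{>= l}. Kept as
#' an independently-derived oracle for the compressed engines.
#'
#' @inheritParams brute_list
#' @return integer vector of document identifiers in discovery order.
#' @export
muthu_list <- function(index, l, r) {
  if (l > r) return(integer(0))
  mu <- index$muthu %||% build_muthu(index)
  C <- mu$C
  st <- mu$rmq
  res <- integer(0)
  recurse <- function(a, b) {
    if (a > b) return(invisible())
    k <- rmq(st, a, b)
    if (C[k] >= l) return(invisible())
    res[length(res) + 1L] <<- index$DA[k]
    recurse(a, k - 1L)
    recurse(k + 1L, b)
    invisible()
  }
  recurse(l, r)
  res
}

build_muthu <- function(index) {
  DA <- index$DA
  n <- length(DA)
  C <- integer(n)
  last <- integer(index$collection$d)
  for (i in seq_len(n)) {
    C[i] <- last[DA[i]]
    last[DA[i]] <- i
  }
  list(C = C, rmq = rmq_build(C))
}

#' Precompute the classical listing structures on an index
#'
#' Attaches Muthukrishnan's \code{C} array and its RMQ to the index so
#' repeated \code{\link{muthu_list}} calls do not rebuild them.
#' @param index a \code{repindex_sa}.
#' @return the index with a \code{muthu} field.
#' @export
with_muthu <- function(index) {
  if (is.null(index$muthu)) index$muthu <- build_muthu(index)
  index
}

# ---------------------------------------------------------------------------
# Explicit suffix tree (LCP-interval tree with singleton leaves), used by the
# PDL sampling and the Sadakane counting construction. Desk-scale: O(n) words
# plus recursion over the interval structure.
# ---------------------------------------------------------------------------

#' Build the explicit suffix tree of an index
#'
#' Nodes are LCP intervals of the global suffix array; every suffix is a
#' singleton leaf child of its deepest enclosing interval. Children are in
#' left-to-right (lexicographic) order.
#'
#' @param index a \code{repindex_sa}.
#' @return list with parallel vectors \code{l}, \code{r}, \code{parent},
#'   \code{leaf} and list-column \code{children}; node 1 is the root.
#' @export
suffix_tree <- function(index) {
  LCP <- index$LCP
  n <- length(LCP)
  cap <- 2L * n
  l <- integer(cap); r <- integer(cap); parent <- integer(cap)
  leaf <- logical(cap)
  children <- vector("list", cap)
  cnt <- 0L
  new_node <- function(a, b, p, is_leaf) {
    cnt <<- cnt + 1L
    l[cnt] <<- a; r[cnt] <<- b; parent[cnt] <<- p; leaf[cnt] <<- is_leaf
    cnt
  }
  build <- function(a, b, p) {
    if (a == b) return(new_node(a, b, p, TRUE))
    id <- new_node(a, b, p, FALSE)
    q <- min(LCP[(a + 1L):b])
    splits <- a + which(LCP[(a + 1L):b] == q)
    starts <- c(a, splits)
    ends <- c(splits - 1L, b)
    kids <- integer(length(starts))
    for (ci in seq_along(starts))
      kids[ci] <- build(starts[ci], ends[ci], id)
    children[[id]] <<- kids
    id
  }
  root <- build(1L, n, 0L)
  keep <- seq_len(cnt)
  list(l = l[keep], r = r[keep], parent = parent[keep], leaf = leaf[keep],
       children = children[keep], root = root, n_nodes = cnt)
}
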