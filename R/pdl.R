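# Precomputed document lists: answers to listing/top-k queries are stored at
# a sampled set of suffix tree nodes and grammar-compressed. Block size b
# bounds the intervals solved by brute force; storing factor beta bounds the
# merge overhead when an answer is rebuilt as a union of stored descendant
# sets.

# ---------------------------------------------------------------------------
# Re-Pair style set compressor. Works on a list of integer sequences over
# terminals 1..d; repeatedly replaces the most frequent adjacent pair
# (non-overlapping occurrences, ties to the lexicographically smallest pair)
# with a fresh nonterminal, then flattens rule right-hand sides to terminals
# so every stored rule expands in one step and has length >= 2.
# ---------------------------------------------------------------------------

repair_pairs <- function(seqs) {
  # count non-overlapping adjacent pairs across all sequences
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seqs) {
    len <- length(v)
    if (len < 2L) next
    i <- 1L
    while (i < len) {
      key <- paste(v[i], v[i + 1L])
      n <- get0(key, envir = counts, ifnotfound = 0L)
      assign(key, n + 1L, envir = counts)
      # greedy non-overlap: a counted pair consumes both symbols only when
      # the same pair continues (e.g. runs like a a a)
      if (i + 2L <= len && v[i] == v[i + 1L] && v[i + 1L] == v[i + 2L])
        i <- i + 2L
      else i <- i + 1L
    }
  }
  counts
}

repair_best_pair <- function(counts) {
  keys <- ls(counts)
  if (length(keys) == 0L) return(NULL)
  vals <- vapply(keys, function(k) get(k, envir = counts), integer(1L))
  best <- max(vals)
  if (best < 2L) return(NULL)
  cand <- keys[vals == best]
  mat <- do.call(rbind, lapply(strsplit(cand, " ", fixed = TRUE), as.integer))
  o <- order(mat[, 1L], mat[, 2L])[1L]
  list(pair = mat[o, ], count = best)
}

repair_replace <- function(v, a, b, sym) {
  len <- length(v)
  if (len < 2L) return(v)
  out <- integer(len)
  oi <- 0L
  i <- 1L
  while (i <= len) {
    if (i < len && v[i] == a && v[i + 1L] == b) {
      oi <- oi + 1L
      out[oi] <- sym
      i <- i + 2L
    } else {
      oi <- oi + 1L
      out[oi] <- v[i]
      i <- i + 1L
    }
  }
  out[seq_len(oi)]
}

#' Grammar-compress a family of document sets
#'
#' Re-Pair style compression over the concatenated set encodings: frequent
#' adjacent pairs are replaced by nonterminal symbols until no pair repeats;
#' rules are then flattened so right-hand sides contain only terminals (and
#' thus have length at least 2), letting any set decompress in time linear
#' in its decoded size.
#'
#' @param sets list of integer vectors over document identifiers
#'   \code{1..d}. Order within each vector is preserved (sort the sets first
#'   when only set equality matters, so shared subsets align).
#' @param d the number of documents (terminal alphabet size).
#' @return object of class \code{repindex_sets}: \code{A} (reduced-set
#'   symbol array), \code{B_A} (bitvector marking first cell of each set),
#'   \code{G} (terminal-only rule right-hand sides), \code{B_G} (bitvector
#'   marking first cell of each rule), \code{d}, \code{n_rules}.
#' @export
compress_sets <- function(sets, d) {
  seqs <- lapply(sets, as.integer)
  rules <- list()
  next_sym <- d
  repeat {
    best <- repair_best_pair(repair_pairs(seqs))
    if (is.null(best)) break
    next_sym <- next_sym + 1L
    rules[[next_sym - d]] <- best$pair
    seqs <- lapply(seqs, repair_replace,
                   a = best$pair[1L], b = best$pair[2L], sym = next_sym)
  }
  # flatten rules to terminal-only right-hand sides
  flat <- vector("list", length(rules))
  expand_sym <- function(s) {
    if (s <= d) return(s)
    fr <- flat[[s - d]]
    if (!is.null(fr)) return(fr)
    pair <- rules[[s - d]]
    fr <- c(expand_sym(pair[1L]), expand_sym(pair[2L]))
    flat[[s - d]] <<- fr
    fr
  }
  for (ri in seq_along(rules)) expand_sym(d + ri)
  A <- unlist(seqs, use.names = FALSE)
  alen <- lengths(seqs)
  BA <- logical(length(A))
  BA[cumsum(alen) - alen + 1L] <- TRUE
  G <- unlist(flat, use.names = FALSE)
  glen <- lengths(flat)
  BG <- logical(length(G))
  if (length(G)) BG[cumsum(glen) - glen + 1L] <- TRUE
  structure(list(A = A, B_A = bitvector(BA, "sparse"),
                 G = if (length(G)) G else integer(0),
                 B_G = bitvector(BG, "sparse"),
                 d = d, n_rules = length(rules),
                 set_start = cumsum(alen) - alen + 1L,
                 set_end = cumsum(alen),
                 rule_start = if (length(G)) cumsum(glen) - glen + 1L else integer(0),
                 rule_end = if (length(G)) cumsum(glen) else integer(0)),
            class = "repindex_sets")
}

#' Decompress one stored set
#'
#' Expands the i-th reduced set: terminals are emitted as-is, nonterminals
#' are replaced by their (terminal-only) rule expansion.
#' @param cs a \code{repindex_sets}.
#' @param i set index.
#' @return integer vector of document identifiers, in stored order.
#' @export
decompress_set <- function(cs, i) {
  syms <- cs$A[cs$set_start[i]:cs$set_end[i]]
  if (all(syms <= cs$d)) return(syms)
  out <- vector("list", length(syms))
  for (k in seq_along(syms)) {
    s <- syms[k]
    out[[k]] <- if (s <= cs$d) s
                else cs$G[cs$rule_start[s - cs$d]:cs$rule_end[s - cs$d]]
  }
  unlist(out, use.names = FALSE)
}

# RLE + differential encoding of a non-increasing frequency sequence.
encode_freqs <- function(tf) {
  runs <- rle(tf)
  heads <- runs$values
  list(first = heads[1L],
       drops = if (length(heads) > 1L) -diff(heads) else integer(0),
       lens = runs$lengths)
}

decode_freqs <- function(enc) {
  heads <- cumsum(c(enc$first, -enc$drops))
  rep(heads, enc$lens)
}

# ---------------------------------------------------------------------------
# Sampled suffix tree construction
# ---------------------------------------------------------------------------

#' Build a precomputed-document-list index
#'
#' Samples suffix tree nodes under the three-rule contract: a node either
#' stores its document set, or covers at most \code{b} suffixes (solved by
#' brute force over the suffix array), or is reconstructible as a union of
#' stored descendant sets of total size at most \code{beta} times its own
#' set. Leaves of the sampled tree are the maximal nodes with interval
#' length at most \code{b}; ancestors are kept, then pruned bottom-up
#' whenever their children's stored sets are small enough to merge.
#'
#' @param index a \code{repindex_sa}.
#' @param b block size (>= 1).
#' @param beta storing factor (>= 1, \code{Inf} allowed), or \code{NULL} to
#'   store the lists of all suffix tree nodes above the leaf blocks (the
#'   configuration used for incremental top-k).
#' @param mode \code{"list"} stores canonically sorted sets; \code{"topk"}
#'   stores sets sorted by decreasing term frequency (ties by increasing
#'   document id), optionally with run-length encoded frequencies.
#' @param store_freqs store the term frequencies alongside topk lists
#'   (required when \code{beta} is set; without them the index can still
#'   rank stored prefixes but recounts reported frequencies from the suffix
#'   array).
#' @param st optional precomputed \code{\link{suffix_tree}} of the index.
#' @return object of class \code{repindex_pdl}.
#' @export
build_pdl <- function(index, b = 256L, beta = NULL,
                      mode = c("list", "topk"), store_freqs = TRUE,
                      st = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(b) || b < 1L) stop("block size b must be >= 1")
  if (!is.null(beta) && beta < 1) stop("storing factor beta must be >= 1")
  if (mode == "topk" && !is.null(beta) && !store_freqs)
    stop("beta-mode top-k requires stored frequencies")
  if (is.null(st)) st <- suffix_tree(index)
  DA <- index$DA
  n <- index$collection$n
  d <- index$collection$d

  size <- st$r - st$l + 1L
  # sampled-tree leaves: maximal nodes with interval <= b
  leaves <- integer(0)
  cand <- integer(0)     # internal candidates (interval > b)
  stack <- st$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (size[v] <= b) {
      leaves[length(leaves) + 1L] <- v
    } else {
      cand[length(cand) + 1L] <- v
      # push children right-to-left so left-to-right order pops first
      stack <- c(stack, rev(st$children[[v]]))
    }
  }
  leaves <- leaves[order(st$l[leaves])]
  Lcnt <- length(leaves)

  doc_set <- function(v) sort(unique(DA[st$l[v]:st$r[v]]))
  Dsize <- integer(st$n_nodes)
  for (v in c(leaves, cand)) Dsize[v] <- length(doc_set(v))

  # prune candidates bottom-up (rule 3); with beta NULL keep all
  depth <- integer(st$n_nodes)
  for (v in seq_len(st$n_nodes))       # nodes are created parent-first
    if (st$parent[v] > 0L) depth[v] <- depth[st$parent[v]] + 1L
  kept <- rep(TRUE, st$n_nodes)        # meaningful for cand only
  # current sampled-children map: start from suffix-tree structure
  samp_parent <- integer(st$n_nodes)   # nearest retained sampled ancestor
  for (v in c(cand[order(depth[cand])], leaves)) {
    p <- st$parent[v]
    while (p > 0L && !(p %in% cand && kept[p])) p <- st$parent[p]
    samp_parent[v] <- p
  }
  audit <- NULL
  if (!is.null(beta)) {
    audit <- data.frame(node = integer(0), pruned = logical(0),
                        child_total = integer(0), dsize = integer(0))
    for (v in cand[order(-depth[cand])]) {
      ch <- c(leaves[samp_parent[leaves] == v],
              cand[kept[cand] & samp_parent[cand] == v & cand != v])
      total <- sum(Dsize[ch])
      prune <- total <= beta * Dsize[v]
      audit <- rbind(audit, data.frame(node = v, pruned = prune,
                                       child_total = total,
                                       dsize = Dsize[v]))
      if (prune) {
        kept[v] <- FALSE
        samp_parent[ch] <- samp_parent[v]
      }
    }
  }
  internal <- cand[kept[cand]]
  internal <- internal[order(st$l[internal], -size[internal])]
  Icnt <- length(internal)

  # final numbering: leaves 1..L, internal L+1..L+I
  num <- integer(st$n_nodes)
  num[leaves] <- seq_len(Lcnt)
  num[internal] <- Lcnt + seq_len(Icnt)
  # recompute sampled parent against the final retained set
  final_parent <- integer(Lcnt + Icnt)   # 0 = root of sampled forest
  for (v in c(leaves, internal)) {
    p <- st$parent[v]
    while (p > 0L && num[p] == 0L) p <- st$parent[p]
    final_parent[num[v]] <- if (p > 0L) num[p] else 0L
  }
  node_l <- c(st$l[leaves], st$l[internal])
  node_r <- c(st$r[leaves], st$r[internal])
  # leaf span of each internal node
  leaf_starts <- st$l[leaves]
  first_leaf <- findInterval(node_l, leaf_starts)
  last_leaf <- findInterval(node_r, leaf_starts)
  # first-child marks: node whose first leaf equals its parent's first leaf
  BF <- logical(Lcnt + Icnt)
  for (i in seq_len(Lcnt + Icnt)) {
    p <- final_parent[i]
    if (p > 0L && first_leaf[i] == first_leaf[p]) BF[i] <- TRUE
  }
  Fv <- integer(Icnt)
  if (Icnt > 0L) {
    fc_rank <- cumsum(BF)
    for (i in seq_len(Lcnt + Icnt)) if (BF[i])
      Fv[fc_rank[i]] <- final_parent[i] - Lcnt
  }
  Nv <- if (Icnt > 0L) last_leaf[Lcnt + seq_len(Icnt)] + 1L else integer(0)

  BL <- logical(n)
  BL[leaf_starts] <- TRUE

  # document sets (and frequencies) for every sampled node
  sets <- vector("list", Lcnt + Icnt)
  freq_enc <- if (mode == "topk" && store_freqs) vector("list", Lcnt + Icnt)
              else NULL
  for (i in seq_len(Lcnt + Icnt)) {
    ival <- node_l[i]:node_r[i]
    if (mode == "list") {
      sets[[i]] <- sort(unique(DA[ival]))
    } else {
      tfs <- table(DA[ival])
      doc <- as.integer(names(tfs))
      tf <- as.integer(tfs)
      o <- order(-tf, doc)
      sets[[i]] <- doc[o]
      if (!is.null(freq_enc)) freq_enc[[i]] <- encode_freqs(tf[o])
    }
  }
  cs <- compress_sets(sets, d)

  exact <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(Lcnt + Icnt))
    assign(paste(node_l[i], node_r[i]), i, envir = exact)

  structure(list(
    params = list(b = as.integer(b), beta = beta, mode = mode,
                  store_freqs = store_freqs),
    n = n, d = d, L = Lcnt, I = Icnt,
    B_L = bitvector(BL, "sparse"),
    B_F = bitvector(BF), F = Fv, N = Nv,
    leaf_start = leaf_starts,
    leaf_end = c(leaf_starts[-1L] - 1L, n),
    node_l = node_l, node_r = node_r,
    first_leaf = first_leaf, last_leaf = last_leaf,
    cs = cs, freq_enc = freq_enc,
    exact = exact, audit = audit,
    index = index
  ), class = "repindex_pdl")
}

#' @export
print.repindex_pdl <- function(x, ...) {
  cat(sprintf(
    "PDL index: %d leaves, %d internal nodes (b = %d, beta = %s, mode = %s)\n",
    x$L, x$I, x$params$b,
    if (is.null(x$params$beta)) "none" else format(x$params$beta),
    x$params$mode))
  cat(sprintf("  compressed sets: |A| = %d, %d rules, |G| = %d\n",
              length(x$cs$A), x$cs$n_rules, length(x$cs$G)))
  invisible(x)
}

# walk the sampled tree over full leaf blocks ln..rn, emitting the numbers of
# the maximal stored nodes covering them: climb first-child links while the
# parent's subtree stays inside the range, then jump past the emitted node.
pdl_walk <- function(pdl, ln, rn) {
  out <- integer(0)
  i <- ln
  BF <- bv_bits(pdl$B_F)
  fc_rank <- cumsum(BF)
  while (i <= rn) {
    node <- i
    repeat {
      if (BF[node]) {
        pint <- pdl$F[fc_rank[node]]
        if (pdl$N[pint] - 1L <= rn) {
          node <- pdl$L + pint
          next
        }
      }
      break
    }
    out[length(out) + 1L] <- node
    i <- if (node > pdl$L) pdl$N[node - pdl$L] else i + 1L
  }
  out
}

# split [l..r] into (left brute range, full leaf blocks ln..rn, right brute
# range); any of the three may be empty (NULL / ln > rn)
pdl_split <- function(pdl, l, r) {
  ln <- bv_rank(pdl$B_L, 1L, l)       # leaf containing l
  left <- NULL
  if (pdl$leaf_start[ln] < l) {
    left <- c(l, min(r, pdl$leaf_end[ln]))
    ln <- ln + 1L
  }
  rnleaf <- bv_rank(pdl$B_L, 1L, r)   # leaf containing r
  right <- NULL
  rn <- rnleaf
  if (r < pdl$leaf_end[rnleaf]) {
    rn <- rnleaf - 1L
    if (rnleaf >= ln) right <- c(max(l, pdl$leaf_start[rnleaf]), r)
  }
  if (!is.null(left) && left[2L] >= r) { rn <- ln - 1L; right <- NULL }
  list(left = left, ln = ln, rn = rn, right = right)
}

#' Document listing from precomputed lists
#'
#' Resolves full leaf blocks through the sampled tree (decompressing the
#' stored set of each maximal covering node) and the partial blocks at the
#' interval edges by brute force over the suffix array.
#'
#' @param pdl a \code{repindex_pdl}.
#' @param l,r closed suffix-array interval.
#' @return sorted integer vector of distinct document identifiers.
#' @export
pdl_list <- function(pdl, l, r) {
  if (l > r) return(integer(0))
  sp <- pdl_split(pdl, l, r)
  res <- integer(0)
  if (!is.null(sp$left)) res <- c(res, pdl$index$DA[sp$left[1L]:sp$left[2L]])
  if (sp$ln <= sp$rn)
    for (nd in pdl_walk(pdl, sp$ln, sp$rn))
      res <- c(res, decompress_set(pdl$cs, nd))
  if (!is.null(sp$right)) res <- c(res, pdl$index$DA[sp$right[1L]:sp$right[2L]])
  sort(unique(res))
}

# decoded (doc, tf) pairs of a stored topk-mode node
pdl_node_list <- function(pdl, nd) {
  doc <- decompress_set(pdl$cs, nd)
  tf <- if (!is.null(pdl$freq_enc)) decode_freqs(pdl$freq_enc[[nd]])
        else NA_integer_
  data.frame(doc = doc, tf = tf)
}

#' Top-k retrieval from precomputed lists
#'
#' When the query interval is a stored node, the answer is the prefix of its
#' frequency-sorted list. Otherwise the interval is resolved as in
#' \code{\link{pdl_list}} and the decompressed (document, frequency) lists
#' are brute-force merged, summing frequencies over the disjoint covering
#' ranges.
#'
#' @param pdl a \code{repindex_pdl} built with \code{mode = "topk"}.
#' @param l,r closed suffix-array interval (the locus interval of a pattern).
#' @param k number of documents requested (>= 1); fewer are returned when
#'   fewer documents match.
#' @return data.frame(doc, tf), tf-descending, ties by increasing doc.
#' @export
pdl_topk <- function(pdl, l, r, k) {
  if (k < 1L) stop("k must be >= 1")
  if (pdl$params$mode != "topk") stop("index was not built in topk mode")
  if (l > r) return(data.frame(doc = integer(0), tf = integer(0)))
  nd <- get0(paste(l, r), envir = pdl$exact)
  if (!is.null(nd)) {
    lst <- pdl_node_list(pdl, nd)
    out <- lst[seq_len(min(k, nrow(lst))), , drop = FALSE]
    if (anyNA(out$tf)) {
      # frequencies were not stored: recount the reported documents
      da <- pdl$index$DA[l:r]
      out$tf <- vapply(out$doc, function(dc) sum(da == dc), integer(1L))
    }
    rownames(out) <- NULL
    return(out)
  }
  sp <- pdl_split(pdl, l, r)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(doc, tf) {
    for (ii in seq_along(doc)) {
      key <- as.character(doc[ii])
      assign(key, get0(key, envir = counts, ifnotfound = 0L) + tf[ii],
             envir = counts)
    }
  }
  brute_part <- function(a, b) {
    tt <- table(pdl$index$DA[a:b])
    bump(as.integer(names(tt)), as.integer(tt))
  }
  if (!is.null(sp$left)) brute_part(sp$left[1L], sp$left[2L])
  if (sp$ln <= sp$rn) {
    if (is.null(pdl$freq_enc))
      stop("merging requires stored frequencies; rebuild with store_freqs = TRUE")
    for (ndw in pdl_walk(pdl, sp$ln, sp$rn)) {
      lst <- pdl_node_list(pdl, ndw)
      bump(lst$doc, lst$tf)
    }
  }
  if (!is.null(sp$right)) brute_part(sp$right[1L], sp$right[2L])
  doc <- as.integer(ls(counts))
  tf <- vapply(as.character(doc), function(key) get(key, envir = counts),
               numeric(1L))
  o <- order(-tf, doc)
  sel <- o[seq_len(min(k, length(o)))]
  data.frame(doc = doc[sel], tf = as.integer(tf[sel]))
}

#' Incremental top-k iterator
#'
#' Abstracts a pattern's document list as a sequence in non-increasing
#' term-frequency order (ties by increasing document id) that can be
#' consumed in batches, as needed by ranked multi-term queries. Stored nodes
#' stream their precomputed list; other intervals fall back to a brute-force
#' list built from the suffix array.
#'
#' @inheritParams pdl_topk
#' @return list of closures: \code{next_batch(count)} returns up to
#'   \code{count} more data.frame(doc, tf) rows; \code{peek_tf()} returns the
#'   tf of the next unextracted document (0 when exhausted);
#'   \code{exhausted()}; \code{all_docs()} returns the full matching
#'   document set (decompressed completely).
#' @export
pdl_topk_iter <- function(pdl, l, r) {
  if (pdl$params$mode != "topk") stop("index was not built in topk mode")
  lst <- if (l > r) data.frame(doc = integer(0), tf = integer(0))
         else {
           nd <- get0(paste(l, r), envir = pdl$exact)
           if (!is.null(nd) && !is.null(pdl$freq_enc)) pdl_node_list(pdl, nd)
           else brute_topk(pdl$index, l, r, k = max(1L, pdl$d))
         }
  pos <- 0L
  list(
    next_batch = function(count) {
      if (pos >= nrow(lst)) return(lst[0L, , drop = FALSE])
      take <- seq.int(pos + 1L, min(pos + count, nrow(lst)))
      pos <<- pos + length(take)
      out <- lst[take, , drop = FALSE]
      rownames(out) <- NULL
      out
    },
    peek_tf = function() if (pos >= nrow(lst)) 0L else lst$tf[pos + 1L],
    exhausted = function() pos >= nrow(lst),
    all_docs = function() lst$doc
  )
}
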