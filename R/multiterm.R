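# Ranked multi-term queries under tf-idf. Each term's document list is
# consumed through the incremental top-k iterator (frequency-descending, so
# it behaves like an inverted list sorted by impact), document frequencies
# come from a counting structure, and a doubling loop maintains lower/upper
# score bounds until the top-k set is settled.

#' tf-idf weight of one term in one document
#'
#' The default scheme: \code{f(tf) = tf} and
#' \code{g(df) = log2(d / max(df, 1))}.
#' @param tf term frequency (occurrences of the pattern in the document).
#' @param df document frequency of the pattern.
#' @param d total number of documents in the collection.
#' @return numeric weight \code{tf * log2(d / max(df, 1))}.
#' @examples
#' tfidf_weight(3, 1, 3)  # 3 * log2(3) = 4.7549
#' @export
tfidf_weight <- function(tf, df, d) {
  stopifnot(all(tf >= 0), all(df >= 0), d >= 1)
  tf * log2(d / pmax(df, 1))
}

#' Exhaustive ranked multi-term scorer
#'
#' Scores every document by scanning the full suffix-array interval of each
#' term; the reference answer for \code{\link{ranked_query}}.
#' @param index a \code{repindex_sa}.
#' @param terms character vector of patterns.
#' @param mode \code{"or"} (document matches some term) or \code{"and"}
#'   (document matches every term).
#' @param k number of documents requested.
#' @return data.frame(doc, score), score-descending, ties by increasing doc.
#' @export
brute_ranked_query <- function(index, terms, mode = c("or", "and"), k) {
  mode <- match.arg(mode)
  d <- index$collection$d
  tf <- matrix(0L, nrow = d, ncol = length(terms))
  for (i in seq_along(terms)) {
    iv <- search_pattern(index, terms[i])
    if (is.null(iv)) next
    tt <- tabulate(index$DA[iv[1L]:iv[2L]], nbins = d)
    tf[, i] <- tt
  }
  df <- colSums(tf > 0L)
  w <- sweep(tf, 2L, log2(d / pmax(df, 1)), `*`)
  score <- rowSums(w)
  match_ok <- if (mode == "and") rowSums(tf > 0L) == length(terms)
              else rowSums(tf > 0L) > 0L
  doc <- which(match_ok)
  o <- order(-score[doc], doc)
  sel <- doc[o][seq_len(min(k, length(doc)))]
  data.frame(doc = sel, score = score[sel])
}

#' Ranked multi-term query over the compressed indexes
#'
#' Resolves each term to its suffix-array interval, takes its document
#' frequency from the counting structure, and streams its
#' frequency-descending document list through \code{\link{pdl_topk_iter}}.
#' A loop with batch sizes 2k, 4k, 8k, ... extracts more documents per term,
#' maintains a score lower bound (unseen terms contribute 0) and upper bound
#' (unseen terms contribute the tf of their next unextracted document) for
#' every candidate, and stops as soon as no remaining candidate can enter
#' the top-k: in conjunctive mode candidates are additionally filtered
#' against the fully decompressed term lists. The returned identifier set is
#' always the exact top-k; reported scores are exact unless a disjunctive
#' query stops early.
#'
#' @param index a \code{repindex_sa}.
#' @param pdl a \code{repindex_pdl} built with \code{mode = "topk"}.
#' @param counts a \code{repindex_count} for document frequencies.
#' @param terms character vector of patterns (m >= 1).
#' @param mode \code{"or"} (ranked disjunctive) or \code{"and"} (ranked
#'   conjunctive). A term absent from the collection contributes nothing;
#'   in conjunctive mode it empties the result.
#' @param k number of documents requested (>= 1).
#' @param early_stop set \code{FALSE} to run every list to exhaustion, which
#'   makes all reported scores exact.
#' @return data.frame(doc, score), score-descending, ties by increasing doc.
#' @export
ranked_query <- function(index, pdl, counts, terms, mode = c("or", "and"),
                         k, early_stop = TRUE) {
  mode <- match.arg(mode)
  if (length(terms) < 1L) stop("at least one query term required")
  if (k < 1L) stop("k must be >= 1")
  d <- index$collection$d
  m <- length(terms)
  empty <- data.frame(doc = integer(0), score = numeric(0))

  ivs <- lapply(terms, function(q) search_pattern(index, q))
  absent <- vapply(ivs, is.null, logical(1L))
  if (mode == "and" && any(absent)) return(empty)
  active <- which(!absent)
  if (length(active) == 0L) return(empty)

  g <- numeric(m)
  iters <- vector("list", m)
  tfmap <- vector("list", m)
  members <- vector("list", m)   # full matching sets, built lazily (AND)
  for (i in active) {
    dfi <- sada_count(counts, ivs[[i]][1L], ivs[[i]][2L])
    g[i] <- log2(d / max(dfi, 1))
    iters[[i]] <- pdl_topk_iter(pdl, ivs[[i]][1L], ivs[[i]][2L])
    tfmap[[i]] <- integer(0)     # named by doc id
  }
  if (mode == "and")
    for (i in active) members[[i]] <- iters[[i]]$all_docs()

  seen <- integer(0)
  kp <- 2L * k
  repeat {
    for (i in active) {
      batch <- iters[[i]]$next_batch(kp)
      if (nrow(batch)) {
        v <- tfmap[[i]]
        v[as.character(batch$doc)] <- batch$tf
        tfmap[[i]] <- v
        seen <- union(seen, batch$doc)
      }
    }
    cand <- seen
    if (mode == "and" && length(cand))
      for (i in active)
        cand <- cand[cand %in% members[[i]]]
    exhausted <- all(vapply(active, function(i) iters[[i]]$exhausted(),
                            logical(1L)))
    if (length(cand)) {
      key <- as.character(cand)
      lb <- numeric(length(cand))
      ub <- numeric(length(cand))
      for (i in active) {
        tfi <- unname(tfmap[[i]][key])
        lb <- lb + ifelse(is.na(tfi), 0, tfi) * g[i]
        ub <- ub + ifelse(is.na(tfi), iters[[i]]$peek_tf(), tfi) * g[i]
      }
      o <- order(-lb, cand)
      top <- o[seq_len(min(k, length(o)))]
      rest <- setdiff(seq_along(cand), top)
      lb_min <- min(lb[top])
      ub_unseen <- sum(vapply(active, function(i) iters[[i]]$peek_tf(),
                              numeric(1L)) * g[active])
      settled <- (length(rest) == 0L || all(ub[rest] < lb_min)) &&
        ub_unseen < lb_min
      if (mode == "and" && settled) {
        # top-k docs must be fully known across all terms
        fully <- vapply(cand[top], function(dc) {
          all(vapply(active, function(i)
            !is.na(tfmap[[i]][as.character(dc)]), logical(1L)))
        }, logical(1L))
        settled <- all(fully)
      }
      if (exhausted || (early_stop && settled && length(top) == k)) {
        sel <- cand[top]
        return(data.frame(doc = sel, score = lb[top]))
      }
    } else if (exhausted) {
      return(empty)
    }
    kp <- kp * 2L
  }
}
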