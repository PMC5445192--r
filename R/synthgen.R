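# Generators of synthetic repetitive collections: a base sequence is
# duplicated and perturbed by entropy-preserving point mutations (the
# replacement symbol is drawn from the empirical symbol distribution of the
# source sequence, and may equal the original). Families mirror the usual
# repetitiveness scenarios: plain duplication, sequence databases with
# per-base-document variant groups, and versioned collections where a
# group's variants are either separate documents or concatenated into one.

#' Apply random point mutations to a sequence
#'
#' Each position is independently mutated with probability \code{p}; the
#' replacement is drawn from \code{base_dist} (by default the empirical
#' symbol frequencies of \code{s} itself, which preserves the zero-order
#' composition) and may coincide with the original symbol.
#'
#' @param s character scalar.
#' @param p per-symbol mutation probability in [0, 1].
#' @param base_dist optional named numeric vector of symbol weights; names
#'   are single characters.
#' @return mutated character scalar of the same length. Deterministic under
#'   a fixed RNG seed.
#' @export
mutate_seq <- function(s, p, base_dist = NULL) {
  stopifnot(nchar(s) >= 1L, p >= 0, p <= 1)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (is.null(base_dist)) {
    tab <- table(ch)
    base_dist <- as.numeric(tab)
    names(base_dist) <- names(tab)
  }
  hit <- which(stats::runif(length(ch)) < p)
  if (length(hit))
    ch[hit] <- sample(names(base_dist), length(hit), replace = TRUE,
                      prob = base_dist)
  paste(ch, collapse = "")
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic repetitive collection
#'
#' Families:
#' \describe{
#'   \item{fig5}{one random base of length \code{base_len}, duplicated
#'     \code{d} times, each copy mutated at rate \code{p}.}
#'   \item{dna}{\code{d_base} base documents derived from a common prefix by
#'     mutation at rate \code{10 * p}, then \code{variants} copies of each
#'     base mutated at rate \code{p}; every variant is a document.}
#'   \item{version}{like \code{dna} but the bases are independent random
#'     sequences; every variant is a separate document.}
#'   \item{concat}{same generation as \code{version}, but all variants of
#'     one base are concatenated into a single document, so \code{d = d_base}.}
#' }
#'
#' @param family one of \code{"fig5"}, \code{"dna"}, \code{"concat"},
#'   \code{"version"}.
#' @param base_len length of the base sequence(s).
#' @param d number of copies (fig5 only).
#' @param d_base number of base documents (dna/concat/version).
#' @param variants number of variants per base document.
#' @param p per-symbol mutation probability.
#' @param alphabet symbols of the random source sequence.
#' @param source optional character scalar used (prefix-truncated to
#'   \code{base_len}) instead of a random source sequence.
#' @return a \code{repindex_collection}. Deterministic under a fixed seed.
#' @export
generate_collection <- function(family = c("fig5", "dna", "concat", "version"),
                                base_len = 1000L, d = 8L,
                                d_base = 10L, variants = 10L, p = 0.01,
                                alphabet = c("A", "C", "G", "T"),
                                source = NULL) {
  family <- match.arg(family)
  stopifnot(base_len >= 1L, p >= 0, p <= 1)
  src <- if (!is.null(source)) substr(source, 1L, base_len)
         else random_seq(base_len, alphabet)
  tab <- table(strsplit(src, "", fixed = TRUE)[[1L]])
  dist <- as.numeric(tab); names(dist) <- names(tab)
  if (family == "fig5") {
    stopifnot(d >= 1L)
    return(new_collection(vapply(seq_len(d),
                                 function(i) mutate_seq(src, p, dist),
                                 character(1L))))
  }
  stopifnot(d_base >= 1L, variants >= 1L)
  bases <- if (family == "dna") {
    vapply(seq_len(d_base),
           function(i) mutate_seq(src, min(1, 10 * p), dist), character(1L))
  } else {
    vapply(seq_len(d_base), function(i) random_seq(base_len, alphabet),
           character(1L))
  }
  groups <- lapply(bases, function(bs)
    vapply(seq_len(variants), function(i) mutate_seq(bs, p, dist),
           character(1L)))
  if (family == "concat") {
    new_collection(vapply(groups, paste, character(1L), collapse = ""))
  } else {
    new_collection(unlist(groups, use.names = FALSE))
  }
}

#' Extract ranked query patterns from a collection
#'
#' Samples random substrings of a fixed length uniformly over valid
#' positions, removes duplicates, computes the ranking statistic exactly for
#' each distinct candidate (\code{occ} from the search interval length,
#' \code{df} from a counting engine or, absent one, the brute listing), and
#' keeps the top \code{n_keep}.
#'
#' @param collection a \code{repindex_collection}.
#' @param length pattern length (>= 1).
#' @param n_sample number of random substring draws.
#' @param n_keep patterns to keep after ranking.
#' @param ranking \code{"occ_over_df"} (patterns that pile up inside few
#'   documents) or \code{"term_frequency"} (most frequent patterns).
#' @param index optional prebuilt \code{repindex_sa} over the collection.
#' @param counts optional \code{repindex_count} used for \code{df}.
#' @return data.frame(pattern, occ, df, stat), stat-descending; empty (with
#'   a warning) when no valid substrings exist.
#' @export
extract_patterns <- function(collection, length = 7L, n_sample = 1e5L,
                             n_keep = 1000L,
                             ranking = c("occ_over_df", "term_frequency"),
                             index = NULL, counts = NULL) {
  ranking <- match.arg(ranking)
  plen <- as.integer(length)
  stopifnot(plen >= 1L)
  ok_docs <- which(nchar(collection$texts) >= plen)
  if (length(ok_docs) == 0L) {
    warning("no document long enough for the requested pattern length")
    return(data.frame(pattern = character(0), occ = integer(0),
                      df = integer(0), stat = numeric(0)))
  }
  # sample positions uniformly over all valid (doc, offset) pairs
  navail <- nchar(collection$texts[ok_docs]) - plen + 1L
  cum <- cumsum(navail)
  pick <- sample.int(cum[length(cum)], n_sample, replace = TRUE)
  di <- findInterval(pick - 1L, cum) + 1L
  off <- pick - c(0L, cum)[di]
  pats <- unique(substr(collection$texts[ok_docs][di], off, off + plen - 1L))
  if (is.null(index)) index <- build_index(collection)
  occ <- integer(length(pats))
  df <- integer(length(pats))
  for (i in seq_along(pats)) {
    iv <- search_pattern(index, pats[i])
    occ[i] <- iv[2L] - iv[1L] + 1L
    df[i] <- if (!is.null(counts)) sada_count(counts, iv[1L], iv[2L])
             else length(brute_list(index, iv[1L], iv[2L]))
  }
  stat <- if (ranking == "occ_over_df") occ / df else occ
  o <- order(-stat, pats)
  sel <- o[seq_len(min(n_keep, length(o)))]
  out <- data.frame(pattern = pats[sel], occ = occ[sel], df = df[sel],
                    stat = stat[sel])
  rownames(out) <- NULL
  out
}
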