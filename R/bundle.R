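# Index bundles: one container holding the collection, the suffix-array
# backend, and whichever query engines were built, with save/load that
# round-trips query-identically, plus the benchmark driver that times
# queries from precomputed lexicographic ranges.

BUNDLE_FORMAT <- 1L

#' Build an index bundle over a collection
#'
#' @param collection a \code{repindex_collection}.
#' @param engines subset of \code{c("ilcp", "pdl", "sada")}; the suffix-array
#'   backend and brute oracles are always available.
#' @param b,beta PDL block size and storing factor (\code{beta = NULL}
#'   stores all nodes above the leaf blocks).
#' @param pdl_mode \code{"list"} or \code{"topk"} (top-k and multi-term
#'   queries need \code{"topk"}).
#' @param store_freqs store term frequencies in topk-mode PDL lists.
#' @param encoding,filters Sadakane H' encoding and filter set.
#' @return object of class \code{repindex_bundle}.
#' @export
build_bundle <- function(collection, engines = c("ilcp", "pdl", "sada"),
                         b = 256L, beta = NULL,
                         pdl_mode = "topk", store_freqs = TRUE,
                         encoding = "sparse", filters = character(0)) {
  engines <- match.arg(engines, c("ilcp", "pdl", "sada"), several.ok = TRUE)
  index <- build_index(collection)
  st <- if (any(c("pdl", "sada") %in% engines)) suffix_tree(index) else NULL
  bundle <- list(format = BUNDLE_FORMAT, engines = engines, index = index,
                 params = list(b = b, beta = beta, pdl_mode = pdl_mode,
                               encoding = encoding, filters = filters))
  if ("ilcp" %in% engines)
    bundle$ilcp <- encode_runs(build_ilcp(collection, index))
  if ("pdl" %in% engines)
    bundle$pdl <- build_pdl(index, b = b, beta = beta, mode = pdl_mode,
                            store_freqs = store_freqs, st = st)
  if ("sada" %in% engines)
    bundle$sada <- encode_h(build_h(index, st), encoding, filters)
  structure(bundle, class = "repindex_bundle")
}

#' @export
print.repindex_bundle <- function(x, ...) {
  cat(sprintf("repindex bundle (format %d): n = %d, d = %d; engines: %s\n",
              x$format, x$index$collection$n, x$index$collection$d,
              paste(x$engines, collapse = ", ")))
  invisible(x)
}

#' Save / load an index bundle
#'
#' The container round-trips bit-exactly (same serialized stream) and
#' query-identically.
#' @param bundle a \code{repindex_bundle}.
#' @param path file path.
#' @return \code{load_bundle} returns the bundle; \code{save_bundle} its
#'   path, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "repindex_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "repindex_bundle"))
    stop("not a repindex bundle: ", path)
  if (bundle$format > BUNDLE_FORMAT)
    stop("bundle format ", bundle$format, " is newer than this package")
  bundle
}

#' Run a single-term query against a bundle engine
#'
#' @param bundle a \code{repindex_bundle}.
#' @param pattern the query pattern.
#' @param engine \code{"ilcp"}, \code{"pdl"}, \code{"sada"}, \code{"brute"}
#'   or \code{"muthu"}.
#' @param mode \code{"list"}, \code{"count"} or \code{"topk"}.
#' @param k top-k size when \code{mode = "topk"}.
#' @return document ids (list), a count, or a data.frame(doc, tf).
#' @export
bundle_query <- function(bundle, pattern,
                         engine = c("ilcp", "pdl", "sada", "brute", "muthu"),
                         mode = c("list", "count", "topk"), k = 10L) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  need <- switch(engine, ilcp = "ilcp", pdl = "pdl", sada = "sada", NULL)
  if (!is.null(need) && is.null(bundle[[need]]))
    stop("engine '", engine, "' was not built in this bundle; rebuild with it")
  iv <- search_pattern(bundle$index, pattern)
  m <- nchar(pattern)
  if (is.null(iv)) {
    return(switch(mode, list = integer(0), count = 0L,
                  topk = data.frame(doc = integer(0), tf = integer(0))))
  }
  switch(mode,
    list = switch(engine,
      ilcp = sort(ilcp_list(bundle$ilcp, bundle$index, iv[1L], iv[2L], m)),
      pdl = pdl_list(bundle$pdl, iv[1L], iv[2L]),
      brute = brute_list(bundle$index, iv[1L], iv[2L]),
      muthu = sort(muthu_list(bundle$index, iv[1L], iv[2L])),
      stop("engine '", engine, "' does not answer listing queries")),
    count = switch(engine,
      ilcp = ilcp_count(bundle$ilcp, bundle$index, iv[1L], iv[2L], m),
      sada = sada_count(bundle$sada, iv[1L], iv[2L]),
      brute = length(brute_list(bundle$index, iv[1L], iv[2L])),
      stop("engine '", engine, "' does not answer counting queries")),
    topk = switch(engine,
      pdl = pdl_topk(bundle$pdl, iv[1L], iv[2L], k),
      brute = brute_topk(bundle$index, iv[1L], iv[2L], k),
      stop("engine '", engine, "' does not answer top-k queries")))
}

#' Benchmark engines over a pattern set
#'
#' Mirrors the usual protocol: all lexicographic ranges are resolved first,
#' then each engine is timed over the precomputed ranges. Timings are
#' informational only.
#'
#' @param bundle a \code{repindex_bundle}.
#' @param patterns character vector of query patterns.
#' @param engines engines to run (subset of those built).
#' @param k top-k size used for topk-capable engines.
#' @return data.frame with one row per (pattern, engine): occ, df, result
#'   size and elapsed wall time in seconds.
#' @export
bench_bundle <- function(bundle, patterns,
                         engines = intersect(bundle$engines,
                                             c("ilcp", "pdl", "sada")),
                         k = 10L) {
  if (length(patterns) == 0L)
    return(data.frame(pattern = character(0), engine = character(0),
                      occ = integer(0), df = integer(0),
                      size = integer(0), seconds = numeric(0)))
  ivs <- lapply(patterns, function(p) search_pattern(bundle$index, p))
  rows <- list()
  for (e in engines) {
    mode <- if (e == "sada") "count" else "list"
    for (i in seq_along(patterns)) {
      iv <- ivs[[i]]
      occ <- if (is.null(iv)) 0L else iv[2L] - iv[1L] + 1L
      t0 <- proc.time()[["elapsed"]]
      res <- if (is.null(iv)) integer(0)
             else bundle_query(bundle, patterns[i], engine = e, mode = mode,
                               k = k)
      el <- proc.time()[["elapsed"]] - t0
      df <- if (is.null(iv)) 0L
            else if (mode == "count") as.integer(res)
            else length(brute_list(bundle$index, iv[1L], iv[2L]))
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = patterns[i], engine = e, occ = occ, df = df,
        size = if (mode == "count") 1L else length(res), seconds = el)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
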