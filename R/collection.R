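# Sentinel byte appended to every document. One shared terminator suffices
# because suffixes are compared over the whole concatenation, and 0x00 cannot
# occur in R character data, so inputs never collide with it.
SENTINEL <- 0L

#' Convert a character scalar to integer byte codes
#'
#' Documents are handled internally as integer vectors of byte values
#' (1..255); the sentinel is code 0 and is reserved.
#' @param x character scalar.
#' @return integer vector of byte codes.
#' @keywords internal
str_to_codes <- function(x) {
  as.integer(charToRaw(x))
}

codes_to_str <- function(codes) {
  rawToChar(as.raw(codes[codes != SENTINEL]))
}

#' Build a document collection from character vectors
#'
#' Concatenates the documents in order, appending one sentinel (a reserved
#' byte smaller than every other symbol) to each, and records the boundary
#' structure needed to map text positions to document identifiers.
#'
#' @param texts character vector, one element per document, in order.
#'   Documents are numbered 1..d in input order.
#' @param names optional display names (e.g. FASTA headers); defaults to
#'   \code{doc1..docd}.
#' @return An object of class \code{repindex_collection} with fields
#'   \code{texts}, \code{names}, \code{T} (integer codes of the concatenation,
#'   sentinel = 0), \code{n}, \code{d}, \code{B} (logical boundary bitvector
#'   with a 1 at the first symbol of each document) and \code{doc_of}
#'   (precomputed position-to-document map).
#' @examples
#' col <- new_collection(c("TATA", "LATA", "AAAA"))
#' col$n  # 15
#' @export
new_collection <- function(texts, names = NULL) {
  texts <- unname(texts)
  if (length(texts) < 1L) stop("collection must contain at least one document")
  if (any(!nzchar(texts))) stop("empty document at position ",
                                which(!nzchar(texts))[1L])
  codes <- lapply(texts, str_to_codes)
  if (any(vapply(codes, function(v) any(v == SENTINEL), logical(1L))))
    stop("input documents must not contain the reserved sentinel byte 0x00")
  d <- length(texts)
  lens <- lengths(codes) + 1L
  T <- unlist(lapply(codes, function(v) c(v, SENTINEL)), use.names = FALSE)
  n <- length(T)
  stopifnot(n == sum(lens))
  starts <- cumsum(c(1L, lens[-d]))
  B <- logical(n)
  B[starts] <- TRUE
  if (is.null(names)) names <- paste0("doc", seq_len(d))
  structure(list(texts = texts, names = names, T = T, n = n, d = d,
                 B = B, doc_of = cumsum(B)),
            class = "repindex_collection")
}

#' Load a document collection from files
#'
#' @param source one or more file paths. In \code{plain} mode each file is one
#'   document unless \code{sep} is given, in which case each file is split
#'   into records on the separator. In \code{fasta} mode each FASTA record is
#'   one document and record order defines document identifiers.
#' @param format \code{"plain"} or \code{"fasta"}.
#' @param sep optional record separator for plain mode (a regular expression
#'   passed to \code{strsplit}); \code{NULL} means one document per file.
#' @return a \code{repindex_collection}.
#' @export
load_collection <- function(source, format = c("plain", "fasta"), sep = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(source)
    if (length(seqs) == 0L) stop("no FASTA records in input")
    return(new_collection(as.character(seqs), names = names(seqs)))
  }
  texts <- character(0)
  for (f in source) {
    bytes <- readBin(f, "raw", file.size(f))
    if (any(bytes == as.raw(0L)))
      stop("input file ", f, " contains the reserved sentinel byte 0x00")
    raw <- rawToChar(bytes)
    # tolerate a single trailing newline from text editors
    raw <- sub("\n$", "", raw)
    if (is.null(sep)) {
      texts <- c(texts, raw)
    } else {
      texts <- c(texts, strsplit(raw, sep)[[1L]])
    }
  }
  new_collection(texts)
}

#' Write a collection to disk
#'
#' @param collection a \code{repindex_collection}.
#' @param path output file path.
#' @param format \code{"fasta"} writes one record per document (headers are
#'   the stored display names); \code{"plain"} writes documents separated by
#'   newlines.
#' @export
write_collection <- function(collection, path, format = c("fasta", "plain")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::BStringSet(collection$texts)
    names(x) <- collection$names
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(collection$texts, path)
  }
  invisible(path)
}

#' Map a text position to its document identifier
#'
#' The document holding position \code{p} of the concatenation is the rank of
#' 1-bits in the boundary bitvector up to \code{p}.
#'
#' @param collection a \code{repindex_collection}.
#' @param p 1-based position(s) in the concatenation, \code{1 <= p <= n}.
#' @return integer document identifier(s) in \code{1..d}.
#' @export
doc_of_position <- function(collection, p) {
  if (any(p < 1L | p > collection$n)) stop("position out of range [1..n]")
  collection$doc_of[p]
}

#' @export
print.repindex_collection <- function(x, ...) {
  cat(sprintf("Document collection: d = %d documents, n = %d symbols\n",
              x$d, x$n))
  show <- utils::head(seq_len(x$d), 5L)
  for (j in show)
    cat(sprintf("  [%d] %s (%d symbols)\n", j, x$names[j], nchar(x$texts[j])))
  if (x$d > 5L) cat(sprintf("  ... and %d more\n", x$d - 5L))
  invisible(x)
}
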