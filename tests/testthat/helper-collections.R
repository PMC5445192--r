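# Shared fixtures: the three-document worked example and seeded random
# collections over binary / DNA / letter alphabets.

example_collection <- function() new_collection(c("TATA", "LATA", "AAAA"))

ALPHABETS <- list(bin = c("A", "B"), dna = c("A", "C", "G", "T"),
                  let = LETTERS)

rand_collection <- function(seed, d_range = 3:8, len_range = 5:25,
                            alphabet = ALPHABETS$dna) {
  set.seed(seed)
  d <- sample(d_range, 1L)
  texts <- vapply(seq_len(d), function(i)
    paste(sample(alphabet, sample(len_range, 1L), replace = TRUE),
          collapse = ""), character(1L))
  new_collection(texts)
}

# all distinct substrings of the collection's documents up to max_len
all_patterns <- function(collection, max_len) {
  unique(unlist(lapply(seq_len(max_len), function(L)
    unlist(lapply(collection$texts, function(tx) {
      nc <- nchar(tx)
      if (nc >= L) substring(tx, 1:(nc - L + 1L), L:nc) else character(0)
    })))))
}

# naive suffix sort: order suffix strings directly (byte-wise, sentinel as
# the smallest symbol), independent of the prefix-doubling construction
naive_sa <- function(T) {
  n <- length(T)
  sufs <- lapply(seq_len(n), function(i) T[i:n])
  o <- seq_len(n)
  o[order(vapply(sufs, function(s)
    paste(sprintf("%03d", s), collapse = ""), character(1L)))]
}

all_sada_encodings <- function(h) list(
  plain = encode_h(h, "plain"),
  sparse = encode_h(h, "sparse"),
  F = encode_h(h, "plain", "F"),
  FS = encode_h(h, "sparse", "F_S"),
  F1 = encode_h(h, "plain", "F_1"),
  FS_F1 = encode_h(h, "sparse", c("F_S", "F_1")))
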