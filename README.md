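# repindex

Compressed document-retrieval indexes for repetitive string collections.

Many of today's fastest-growing string collections are *repetitive*: most
documents closely resemble many others. Genome databases holding every
strain of an organism, versioned document archives, and protein families
all share this shape, and exploiting it can shrink index structures by
orders of magnitude. `repindex` implements document retrieval for such
collections — the queries inverted indexes answer for natural language, but
for collections where there are no words to tokenize:

* **document listing** — given a pattern `P`, report every distinct
  document containing `P` once;
* **top-k retrieval** — report the `k` documents where `P` occurs most
  often (term frequency `tf`);
* **document counting** — report only `df`, the number of documents
  containing `P`;
* **ranked multi-term search** — conjunctive/disjunctive queries scored by
  `w(D,Q) = Σᵢ tf(D,qᵢ) · log₂(d / max(df(qᵢ), 1))`.

In pan-genomics these queries identify which strains contain a read's
substring and how specific that substring is; in string mining `df/d` is
the support of a pattern.

All engines sit on a suffix-array backend over the concatenation
`T = S₁$S₂$…S_d$` with the document array
`DA[i] = rank₁(B, SA[i])`. Three engine families are provided:

* **ILCP** — the per-document LCP arrays interleaved in global suffix-array
  order. Inside a pattern's interval, entries below `|P|` mark exactly the
  leftmost occurrence of each matching document, and on repetitive
  collections the array collapses into few runs. Listing uses an RMQ
  recursion over the run heads; counting descends a skewed wavelet tree in
  `O(|P|)` nodes (`build_ilcp`, `encode_runs`, `ilcp_list`, `ilcp_count`).
* **PDL** — precomputed document lists at a sampled suffix tree (block size
  `b`, storing factor `β`), Re-Pair grammar-compressed; top-k lists stored
  frequency-sorted with run-length encoded counts, supporting incremental
  extraction (`build_pdl`, `pdl_list`, `pdl_topk`, `pdl_topk_iter`).
* **Sadakane counting** — per-node redundancies `h(v) = |D_u ∩ D_w|` of the
  binarized suffix tree, unary-encoded so that
  `count(ℓ,r) = 2(r−ℓ) − (select₁(H′,r) − select₁(H′,ℓ)) + 1`, with
  sparse/filtered encodings (`build_h`, `encode_h`, `sada_count`).

Brute-force oracles (`brute_list`, `brute_topk`, `muthu_list`,
`brute_ranked_query`) and synthetic repetitive-collection generators
(`generate_collection`, `mutate_seq`, `extract_patterns`) make every engine
verifiable end to end.

## Worked example

The three documents `TATA`, `LATA`, `AAAA` concatenate to
`T = "TATA$LATA$AAAA$"`:

```r
library(repindex)
col <- new_collection(c("TATA", "LATA", "AAAA"))
idx <- build_index(col)
idx$SA
#>  [1] 15 10  5 14  9  4 13 12 11  7  2  6  8  3  1
idx$DA
#>  [1] 3 2 1 3 2 1 3 3 3 2 1 2 2 1 1

ilcp <- build_ilcp(col, idx)
ilcp
#>  [1] 0 0 0 0 0 0 1 2 3 1 1 0 0 0 2
enc <- encode_runs(ilcp)
enc$rho      # 7 runs
enc$VILCP
#> [1] 0 1 2 3 1 0 2
```

Searching `"TA"` yields suffix-array interval `[13..15]`; the documents
containing it are 2 and 1 (the positions of `ILCP[13..15] = <0,0,2>` below
the pattern length), and every engine agrees:

```r
iv <- search_pattern(idx, "TA")      # c(13, 15)
ilcp_list(enc, idx, iv[1], iv[2], 2) # 2 1
ilcp_count(enc, idx, iv[1], iv[2], 2)# 2
sada_count(encode_h(build_h(idx)), iv[1], iv[2])  # 2

pdl <- build_pdl(idx, b = 1, beta = NULL, mode = "topk")
pdl_topk(pdl, iv[1], iv[2], k = 1)
#>   doc tf
#> 1   1  2
```

Document 1 (`TATA`) holds `TA` twice, so it tops the single-term ranking.
A two-term disjunctive query ranks document 3 first: `AA` occurs 3 times in
`AAAA` and nowhere else, so its weight `3·log₂(3/1) ≈ 4.75` beats document
1's `2·log₂(3/2) ≈ 1.17`:

```r
counts <- encode_h(build_h(idx))
ranked_query(idx, pdl, counts, c("TA", "AA"), mode = "or", k = 3)
#>   doc     score
#> 1   3 4.7548875
#> 2   1 1.1699250
#> 3   2 0.5849625
```

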