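---
title: "Compressed document retrieval on repetitive collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed document retrieval on repetitive collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repindex)
```

## The problem

Given a collection of $d$ documents $S_1, \dots, S_d$ — genome assemblies of
strains of one organism, protein families, versioned text — and a pattern
$P$, three queries recur in string mining and sequence-database search:

* **document listing**: report each distinct document containing $P$ once;
* **top-$k$ retrieval**: report the $k$ documents with the most occurrences
  of $P$ (highest term frequency $\mathsf{tf}$);
* **document counting**: report only $\mathsf{df}$, the number of documents
  containing $P$.

All engines in this package operate on the concatenation
$T = S_1\$S_2\$\cdots S_d\$$, its suffix array $\mathsf{SA}$, and the
document array $\mathsf{DA}[i] = \mathrm{rank}_1(B, \mathsf{SA}[i])$, where
$B$ marks the first symbol of each document. A pattern resolves by binary
search to a lexicographic interval $[\ell..r]$; everything else is a
computation over $\mathsf{DA}[\ell..r]$. The package targets *repetitive*
collections — most documents nearly equal to others — where the auxiliary
structures compress by orders of magnitude; all structures remain correct on
arbitrary collections.

The sentinel is the reserved byte `0x00`, lexicographically smallest, one
per document; inputs containing it are rejected. All public interfaces are
1-based with closed intervals.

## Interleaved LCP

The interleaved LCP array places each document's own LCP array at the global
suffix-array positions of that document:
$\mathsf{ILCP}[i] = \mathsf{LCP}_{S_j}[\mathrm{rank}_j(\mathsf{DA}, i)]$
for $j = \mathsf{DA}[i]$. Because a shared smallest sentinel makes the
relative order of same-document suffixes identical locally and globally,
the per-document arrays embed unchanged. Two properties drive the engines:

1. Inside a pattern interval $[\ell..r]$, the entries with
   $\mathsf{ILCP}[k] < |P|$ sit exactly at the leftmost occurrence of each
   distinct document in $\mathsf{DA}[\ell..r]$ — so listing documents is
   finding values below $m = |P|$.
2. On collections built by lightly editing $d$ copies of a base document of
   length $r_{doc}$, the array consists of $\rho \lesssim r_{doc} +
   O(s \log(r_{doc}+s))$ runs of equal values after $s$ edits, independent
   of $d$.

`encode_runs()` therefore stores only run heads `VILCP` (in a skewed
wavelet tree), a run-boundary bitvector `L`, and a second bitvector `L'`
holding the run lengths grouped by value. Listing
(`ilcp_list`) runs the classical leftmost-minimum RMQ recursion over the
run heads, expanding each qualifying run and marking reported documents;
recursion stops where the first document of a run is already marked, which
by the leftmost-occurrence property implies the run's value is at least
$m$. Counting (`ilcp_count`) descends the skewed wavelet tree only into
value ranges intersecting $[0..m-1]$, sums spanned run lengths with select
on `L'`, and corrects the two boundary runs for partial overlap with
$[\ell..r]$: an overlapping run contributes
$\min(\text{run end}, r) - \max(\text{run start}, \ell) + 1$ positions,
interior runs their full length.

The *skewed* wavelet tree places its $i$-th leftmost leaf (value $i-1$) at
depth $1 + 2\lfloor\log_2 i\rfloor$: the root's left child is leaf 1, then a
right spine hangs balanced groups of $2, 4, 8, \dots$ leaves. A traversal
restricted to values $< m$ touches at most $4m - 2$ nodes regardless of the
maximum LCP value, so counting costs $O(m)$ tree nodes. Leaf $i$ holding
value $i-1$ (every value in $0..\lambda$ gets a leaf) keeps the leaf-index
arithmetic for the grouped lengths direct; the group order in `L'` is
increasing value, runs of equal value in text order — the grouping itself is
required, the inter-group order is our choice for that arithmetic.

## Precomputed document lists

PDL trades construction-time work for query speed: given a block size $b$
and storing factor $\beta \ge 1$, a sampled suffix tree is built in which
every suffix tree node either (1) stores its distinct-document set $D_v$,
(2) spans at most $b$ suffixes (answered by brute force over the suffix
array), or (3) is recoverable as a union of stored descendant sets of total
size at most $\beta\,|D_v|$. Sampled leaves are the maximal nodes with
interval length $\le b$ (their intervals partition $[1..n]$); their
ancestors are pruned bottom-up whenever rule (3) holds, i.e. storing the
node saves less than a factor $\beta$ of merge work. `beta = NULL` keeps
every node above the leaf blocks (the configuration used for incremental
top-k); `beta = Inf` prunes all internal nodes.

The stored sets are grammar-compressed with a Re-Pair-style compressor
(`compress_sets`): the most frequent adjacent symbol pair — non-overlapping
occurrences, ties to the lexicographically smallest pair, so builds are
deterministic — is replaced by a fresh nonterminal until no pair repeats,
and rules are then flattened to terminal-only right-hand sides of length
$\ge 2$, so a set of size $s$ decompresses in $O(s)$. In listing mode sets
are canonically sorted before compression so shared subsets align; in top-k
mode the order is term-frequency-descending (ties by increasing document
id) and compression preserves it. Frequencies are run-length encoded with
differentially encoded run heads.

Queries split $[\ell..r]$ into a partial leaf block on each edge (brute
force over at most $b-1$ cells each) and a span of full blocks resolved
through the sampled tree. The tree walk stored as `B_F`/`F`/`N` (first-child
marks, first-child-to-parent pointers, next-leaf-after-subtree pointers)
climbs from the first uncovered leaf along first-child links while the
parent's subtree still fits in the span, emits that maximal node's set, and
jumps past it; this reading of the structure's function roles is our
interpretation and is exercised against the brute oracle across the full
$b \times \beta$ grid in the tests. Top-k on a stored node reads the list
prefix; on anything else the decompressed lists of the covering nodes are
brute-force merged (frequencies summed over the disjoint cover) — heuristic
early termination for merges is deliberately not implemented, as plain
merging is the robust choice. The sampled tree is built from an explicit
suffix tree in $O(n)$ words, a documented construction-memory limitation;
desk-scale collections are the target.

## Sadakane-style counting

For each internal node $v$ of the binarized suffix tree with children
$u, w$, the redundancy $h(v) = |D_u \cap D_w|$ satisfies
$\mathsf{count}(v) = \mathsf{count}(u) + \mathsf{count}(w) - h(v)$, which
telescopes to $\mathsf{count}(\ell, r) = (r+1-\ell) - \sum_{i=\ell}^{r-1}
H[i]$ with $H$ the inorder listing of $h$. Encoded in unary
($H[i] \mapsto 1\,0^{H[i]}$), the sum becomes a select difference and
counting is $O(1)$ at the locus of $P$. Binarization combines children
right-to-left into a chain; since only original nodes are queried, the
chain's $h$-mass is reassigned to the original node's inorder cell. The
inorder rank of a binary internal node is the suffix-array index where its
left subtree ends, so the whole chain's mass lands at the end of the first
child's interval — no explicit inorder traversal is needed, and the choice
of binarization order is behaviorally irrelevant (the tests check the
count identity for every suffix tree node).

Compressed variants: a plain or sparse bitvector for $H'$; filter `F`
(prune single-document subtrees; a locus falling inside a pruned subtree
has $\mathsf{count} = 1$ by construction and is short-circuited); sparse
filter `F_S` (cells with $H > 0$); 1-filter `F_1` (cells with $H = 1$
contribute via a rank correction instead of unary zeros); and `F_S` with
`F_1` (then `F_S` marks $H > 1$). `F` changes the tree shape, so it cannot
be combined with the cell filters and the combination is rejected. The
query maps a cell range through the filters as
$[\mathrm{rank}_1(F, \ell-1)+1 .. \mathrm{rank}_1(F, r-1)]$ — the
consistent closed-interval reading of rank mapping. On random or
repetitive collections alike, the number of runs of 1s in $H'$ is expected
$O((\sigma/2+1)\, r_{doc} \sqrt{d})$ — sublinear in collection size — which
is what makes the structure compressible; the tests verify the bound with
a factor-2 slack and the sublinear trend at fixed total size.

## Ranked multi-term queries

`ranked_query` scores documents with
$w(D, Q) = \sum_i \mathsf{tf}(D, q_i)\cdot\log_2(d/\max(\mathsf{df}(q_i),1))$.
Document frequencies come from the counting structure (not from
decompressing lists); each term's frequency-descending list is consumed
through the incremental iterator in batches $2k, 4k, 8k, \dots$. Candidate
lower bounds use 0 for unseen terms; upper bounds use the tf of the term's
next unextracted document (0 once a list is exhausted, so bounds are
monotone). Conjunctive candidates are filtered against fully decompressed
term lists. The loop stops when no other candidate's upper bound reaches
the current top-$k$'s lower bounds — strict inequalities, so score ties
force continuation until ranks are provable — or when every list is
exhausted, which also resolves conjunctive queries with no fully matching
document (an otherwise unspecified corner: we return the possibly empty
matching set). The returned identifier set is always exact; scores can be
partial only when a disjunctive query stops early, and `early_stop = FALSE`
makes them exact. Ties across equal scores break by increasing document
id, extending the single-term rule.

## Synthetic collections

`generate_collection` reproduces the standard repetitiveness scenarios:
`fig5` duplicates one random base $d$ times with independent per-symbol
point mutations at rate $p$; `dna` derives $d_{base}$ base documents from a
common prefix at rate $10p$ and then variants at rate $p$; `version` keeps
every variant a separate document while `concat` concatenates a base's
variants into one document. Mutations are entropy-preserving: the
replacement symbol is drawn from the empirical symbol distribution of the
source (and may equal the original), so the zero-order composition is
maintained — the tests check this within $5\sigma$ multinomial bounds.
Mutations are substitutions only; the run-count bound is additionally
exercised with direct substitution edits applied to the concatenation.
`extract_patterns` samples substrings uniformly, deduplicates, computes
$occ$ (interval length) and $\mathsf{df}$ (counting engine) exactly, and
keeps the top patterns by $occ/\mathsf{df}$ — patterns that occur often in
few documents, the regime where compressed listing beats brute force.

Defaults: random bases are uniform DNA ($\sigma = 4$) unless a source
sequence is supplied; `base_len = 1000` matches the usual prefix length for
the `dna` family, with desk-scale `d_base = 10`, `variants = 10`,
`p = 0.01` as a middle mutation rate. Non-ACGT symbols never arise in the
bundled generator because the source is generated, not read from an
external corpus; a supplied `source` string is used byte-wise as given.

## What the tests do and do not show

Every engine is verified against independent brute-force oracles
(`brute_list`, `brute_topk`, an exhaustive multi-term scorer, naive suffix
sorting, per-document LCP by direct prefix comparison) on: the worked
three-document example, bit-exactly; 100+ seeded random collections with
$d \le 20$, document lengths $\le 100$ and alphabets of size 2, 4 and 26,
over *all* distinct patterns of length $\le 4$, across the full PDL
$b \in \{1,2,4,16\} \times \beta \in \{1,2,16,\infty\}$ grid and all
counting encodings; and the stochastic run-count properties at
$(r_{doc}, d) = (256, 32)$ with up to 64 edits and random-DNA collections
with $d \in \{4, 16, 64\}$ over 20 seeds. The slack constant 4 in the
edit-bound test and the factor 2 on the expected-case run bound absorb the
constants hidden in the asymptotic statements and were fixed before the
property runs, not tuned to them.

Synthetic generators emulate duplication-with-point-mutations; real
repetitive data differs in ways the tests do not cover: structural
variation (insertions, deletions, rearrangements rather than
substitutions), skewed document length distributions, and natural-language
token statistics. Passing tests therefore certify algorithmic correctness
and the predicted compressibility trends on the generated families, not
performance or space on any particular real corpus. Space accounting is
reported (structure sizes in the objects), never asserted; no bits-per-
symbol or throughput figures are reproduced, as those are hardware- and
corpus-dependent.

Problem sizes in the test-suite were chosen so the whole verification runs
in minutes on one CPU: oracle equivalence uses documents of 5–25 symbols
and 3–8 documents per collection (the oracles are quadratic or worse, and
the pattern loop is exhaustive), while the stochastic properties use the
stated $(256, 32)$ and $(256, d)$ shapes directly.

## Numerical and degenerate-input choices

* Empty patterns and empty documents are rejected; empty intervals return
  empty results (listing) or are errors (RMQ).
* `search_pattern` returns `NULL` for absent patterns; engines treat the
  corresponding term as `df = 0`.
* RMQ ties always resolve to the leftmost minimum — a correctness
  requirement of the listing recursions, not a convention.
* Top-k ties break by increasing document id everywhere, including inside
  stored PDL lists, so stored prefixes and brute recounts agree exactly.
* `l == r` counting short-circuits to 1 without consulting $H'$.
* The counting structures answer locus intervals (every pattern interval is
  one); behavior on arbitrary non-locus intervals is documented as
  undefined rather than guessed.
* Index serialization (`save_bundle`/`load_bundle`) uses R's serialization
  with a format version tag; round-trips are query-identical.
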