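---
title: "Quantifying chemical divergence between peptide families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemical divergence between peptide families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pepsim)
```

## The problem

Phage-display selections against a target protein return panels of short
peptides. When two selection arms (for example, a chemically cyclized
library and a linear library selected against streptavidin) return binders
with different consensus motifs, the natural question is *how chemically
different are these families, really?* Sequence identity alone understates
the answer: two peptides can share few residues yet present similar
chemistry, or share a scaffold yet diverge at every functional position.

pepsim answers the question three complementary ways, all operating on
plain one-letter sequences:

1. **Whole-sequence chemical similarity.** Each peptide is converted to a
   molecule, fingerprinted with a MinHashed atom-pair fingerprint, and
   pairs are scored by estimated Jaccard similarity (1 identical, 0
   dissimilar).
2. **Positional chemical similarity.** Equal-length peptides are compared
   residue by residue: at each of the twelve positions of a CX10C 12-mer
   the two free amino acids are fingerprinted and scored, decomposing the
   whole-sequence divergence along the scaffold.
3. **TF-IDF cosine similarity.** The sequences are treated as text:
   residue-occurrence vectors weighted by inverse document frequency and
   compared by cosine. This is deliberately chemistry-blind and serves as
   the lexical counterpoint to the fingerprint methods.

Families are then compared by per-peptide mean similarity against the
other family (cross) and against its own family (within), always excluding
self-comparisons.

## From sequence to molecule

`assemble_peptide()` builds a linear peptide: internal residue fragments
(free amino acid minus one water, with open backbone attachment points)
concatenated N-to-C, a free amine at the N-terminus and a free carboxylic
acid at the C-terminus. Choices a user should know:

* **Neutral protonation, no zwitterions.** Formulas are then deterministic
  functions of the sequence.
* **Cysteines are free thiols.** No disulfides and no cyclization linker
  are represented; the analysis compares the peptides' sequence chemistry,
  not their conjugates.
* **Stereochemistry.** Assembled SMILES carry L-alpha stereocentres, but
  the fingerprint strips stereo descriptors by default
  (`fp_params(include_stereo = )`): environment canonicalization is then
  stable under re-serialization, and positional and whole-sequence scores
  cannot disagree on account of stereo perception.

Parsing, canonicalization and formula bookkeeping go through OpenBabel
(via ChemmineR/ChemmineOB). Every assembled molecule satisfies the
conservation identity *formula = sum of free residue formulas − (L−1)
H₂O*, which the test-suite checks exhaustively over all 400 dipeptides and
seeded random 12-mers.

```{r}
formula_string(molecular_formula(assemble_peptide("CGGSGGC")))
```

## The fingerprint

For a molecule with heavy-atom graph `G`, for every unordered pair of
connected atoms `(i, j)` and every radius `k` in `1..max_radius`, we emit
the shingle

```
env_k(i) | d(i,j) | env_k(j)
```

where `d` is the topological distance in bonds and `env_k` is a canonical
serialization of the atom's neighborhood within `k` bonds: a depth-limited
tree unfolding whose sibling branches are sorted lexicographically. Atom
labels carry element, formal charge, aromaticity (lowercase element,
aromatic ring bonds written `:`) and implicit hydrogen count; the two
environments in a shingle are ordered lexicographically so the pair is
unordered. Environments are prefixed with their radius (`r1:`, `r2:`) so
that the radii contribute distinct tokens even when a small molecule
saturates below `max_radius`. The molecule is represented by the *set* of
its shingles — no multiplicities.

Defaults are `max_radius = 2` and `signature_length = 1024`, the published
atom-pair-fingerprint defaults; both are configurable and the estimator
quality test runs at 2048.

**MinHash.** Component `i` of a signature is the minimum over shingles of
a salted 64-bit string hash:

```
base(s)    = FNV-1a 64-bit over the UTF-8 bytes of s
salt(k, i) = splitmix64(k * 0x9E3779B97F4A7C15 + i)    # seed k, permutation i
h_i(s)     = splitmix64(base(s) XOR salt(k, i)) >> 11  # top 53 bits
```

Keeping the top 53 bits makes every component exactly representable as an
R double while preserving ordering, so signatures are byte-identical
across platforms, sessions and machines given the same seed. The fraction
of equal components between two signatures is the classic unbiased
estimate of the Jaccard similarity of the shingle sets; `exact_jaccard()`
is the brute-force oracle (`|A∩B| / |A∪B|`) used throughout the tests and
available to users via `exact = TRUE` for small panels. With 2048
permutations, the binomial standard error at J = 0.5 is about 0.011, so
the tested tolerance of 0.05 per pair is a comfortable 4–5 sigma.

## Positional similarity

At each aligned position the *free amino acid* molecules of the two
residues are fingerprinted and compared. The free-molecule representation
(rather than a backbone-capped residue) reflects how a per-residue
sequence-to-SMILES conversion naturally operates, and makes the positional
dictionary a fixed 20-molecule vocabulary, which pepsim caches per
parameter set. Positions with identical residues short-circuit to exactly
1 — identical molecules have identical shingle sets, and the short-circuit
keeps that exactness independent of signature length.

## TF-IDF convention

Tokens are the 20 single-residue letters. Term counts are weighted by the
smoothed inverse document frequency

```
idf(t) = ln((1 + N) / (1 + df(t))) + 1
```

over the panel supplied to one comparison run (both families jointly, as
they are compared jointly), then Euclidean-normalized; similarity is the
dot product. This is the documented default convention of the standard
text-vectorizer implementations, stated here because other idf variants
change the numbers. The self-similarity diagonal is set to exactly 1 (the
cosine of a vector with itself).

## Motif and logo analytics

`scan_motif()` reports all (overlapping) 1-based offsets of a pattern over
residue letters and the wildcard `X`; HPQ and HPM — the canonical linear
streptavidin-binding motifs — are scanned separately and reported jointly
(`motif_hpq()`). `matches_consensus()` anchors the cyclic-binder consensus
CPXNXXXPXXXC (fixed C1, P2, N4, P8, C12) at position 1 of a 12-mer.

Logo analytics follow the standard information-theoretic convention:
`IC(p) = log2(20) − H(p)` bits, bounded by `[0, log2 20 ≈ 4.32]`. The
small-sample correction `19 / (2 ln(2) n)` is exposed as a flag but off by
default — at the panel sizes this package targets (9–12 sequences) the
correction is visible, and the default favors the uncorrected analytic
anchors (conserved column = `log2 20`, uniform column = 0). The consensus
rule emits a residue where its frequency reaches a threshold, default 0.9;
thresholds at or below 0.5 are rejected because the winner could tie.

## The synthetic panel generator

Real selection outputs live in supplementary tables of the originating
study; the generator reproduces their *structural* features so the whole
pipeline is testable from code alone:

* **Scaffold.** All families are CX10C 12-mers — terminal cysteines, ten
  randomized internal positions, matching the library design ("X = any
  natural amino acid"; cysteine is therefore included in the default
  alphabet, with an `exclude_cys` flag because real selections can
  disfavor extra thiols).
* **str_like** fixes C1, P2, N4, P8, C12 and draws the seven remaining
  positions uniformly — the consensus family, nine members in the
  emulated study design.
* **hpq_like** writes HPQ or HPM (fair seeded coin) at a uniform internal
  offset in 2..9, never overwriting the terminal cysteines — the linear
  binder family, twelve members in the emulated design.
* **random** draws all ten internal positions uniformly — the null panel;
  its consensus-match rate is the analytic (1/20)³ = 1.25e-4.

What the generator does **not** emulate: residue-composition bias of real
selections, positional covariance, enrichment dynamics, or sequencing
error. A passing pipeline on synthetic panels therefore demonstrates the
*methods* behave as specified (conserved positions score exactly 1,
cross-family similarity sits below within-family similarity), not that any
particular real family separates by any particular margin.

Generation uses an isolated RNG (`withr::with_seed`), so identical specs
and seeds give byte-identical panels — and identical FASTA files — without
disturbing the caller's RNG stream.

## Numerical and degenerate-input choices

* Self-pairs and atom pairs in different connected components are never
  shingled; a molecule with fewer than two heavy atoms yields an empty
  shingle set with a warning, and MinHashing an empty set is an error
  (no signature is defined), as is the Jaccard of two empty sets.
* Signatures built with different parameters refuse comparison rather
  than returning a misleading number.
* Within-group means over singleton groups are reported as `NA`
  (undefined), never 0.
* Matrix diagonals are exactly 1 for the whole-sequence and cosine
  methods; cosine entries are clamped to [0, 1] against floating-point
  drift.
* Malformed SMILES are rejected with a character offset where the light
  syntactic scan can name one (unbalanced brackets), and with a clear
  parse error otherwise.

## Validation scale

The test suite validates the estimator against the exact-Jaccard oracle on
50 seeded random 12-mer pairs at signature length 2048 (tolerance 0.05 per
pair, mean bias within 0.01), checks formula conservation on all 400
dipeptides plus 50 seeded 12-mers, compares motif scanning against an
exhaustive sliding-window oracle on 1000 seeded cases, and reproduces the
qualitative family separation (cross < within-str) on ten seeded
9-vs-12-peptide panel pairs at the default 1024 permutations. These sizes
were chosen to exercise every code path at the study's own panel scale
while keeping a full run of the suite in minutes on a laptop.

## A worked run

```{r, eval = FALSE}
str9  <- generate_panel("str_like", 9, seed = 101)
hpq12 <- generate_panel("hpq_like", 12, seed = 202)

cfg <- run_config(str9, hpq12, label_a = "str", label_b = "hpq",
                  params = fp_params(seed = 7), out_dir = "report")
res <- run_comparison(cfg)

glance(res$comparisons$full_map4)
autoplot(res$matrices$full_map4)

pfm <- build_pfm(str9)
consensus_string(pfm)
autoplot(pfm)
```

## Known limitations

* Whole-sequence fingerprints of peptides share the peptide backbone, so
  absolute similarity values are higher than an intuition trained on
  sequence identity expects; the informative quantity is the *contrast*
  between cross- and within-family means.
* Only the 20 natural amino acids are supported; sequences containing
  B, J, O, U, X or Z are rejected rather than guessed at.
* Cyclization chemistry (disulfides, bifunctional linkers) is out of
  scope: the analysis is of the displayed sequences as linear molecules.
* The environment serialization is a tree unfolding, not a full subgraph
  canonical code; symmetry-equivalent atoms always agree, and the
  representation is deterministic, but exotic regular graphs that differ
  only beyond the unfolding depth could in principle share environments.
  At radius 2 on peptide graphs this has no practical effect.
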