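# pepsim

Chemical similarity analysis of phage-display peptide panels.

When two selection campaigns return different families of binders — say a
cyclized library yielding 12-mers with a CPXNX₃PX₃C consensus and a linear
library yielding classic HPQ/HPM-motif streptavidin binders — pepsim
quantifies how chemically divergent the families are, starting from nothing
but the one-letter sequences.

## What it computes

Every peptide is assembled into a linear molecule (free amine N-terminus,
free acid C-terminus, free thiols, neutral protonation) and represented by
its **MinHashed atom-pair fingerprint**: for every pair of heavy atoms
*(i, j)* and radius *k* ∈ {1, 2}, a shingle

```
env_k(i) | d(i,j) | env_k(j)
```

combining the canonical circular-environment strings of the two atoms with
their bond-count distance *d*. The shingle set is summarized by a seeded
MinHash signature (default 1024 permutations), and a pair of peptides is
scored by the estimated Jaccard similarity *Ĵ* = (fraction of equal
components), i.e. 1 − Jaccard distance: 1 for identical, 0 for highly
dissimilar. A brute-force exact Jaccard (|A∩B|/|A∪B|) is built in as the
oracle and as an `exact = TRUE` option.

Three comparison methods share this machinery:

| method | what is compared |
|---|---|
| `full_map4` | whole-sequence molecules, fingerprint Jaccard |
| `positional_mean` | the two free amino acids at each aligned position |
| `tfidf_cosine` | residue text, smoothed-idf-weighted cosine (idf(t) = ln((1+N)/(1+df(t))) + 1, L2-normalized) |

Family contrasts use per-peptide means against the other family and against
the own family, always **excluding self-comparisons**. Motif scanning
(HPQ/HPM, the cyclic consensus), position-frequency matrices, information
content in bits and threshold consensus strings cover the logo side of the
analysis, and a seeded generator produces CX10C panels (`str_like`,
`hpq_like`, `random`) with the structure of real selection outputs.

## Worked example

```r
library(pepsim)

p <- fp_params(seed = 7)              # radius 2, 1024 permutations

# the bundled negative-control peptide vs a near neighbour
full_similarity("CGGSGGC", "CGSGGSGC", p)
#> [1] 0.3710938

# two synthetic families at the study's panel sizes
str9  <- generate_panel("str_like", 9,  seed = 101)   # CPXNXXXPXXXC family
hpq12 <- generate_panel("hpq_like", 12, seed = 202)   # embedded HPQ/HPM

mat <- pairwise_matrix(rbind(str9, hpq12), "full_map4", params = p)
cmp <- cross_family_averages(mat, str9$id, hpq12$id)
glance(cmp)
#> # A tibble: 2 × 4
#>   group     n mean_cross mean_within
#> 1 A         9      0.175       0.264
#> 2 B        12      0.175       0.226
```

The cross-family mean (0.175) sits below both within-family means — the
two families occupy distinguishable chemical space. The positional
decomposition shows where: scaffold positions agree exactly, internal
positions diverge.

```r
positional_similarity(str9$sequence[1], hpq12$sequence[1], p)
#>    position residue_a residue_b similarity
#>  1        1         C         C    1.00000
#>  2        2         P         S    0.04004
#>  ...
#> 12       12         C         C    1.00000
```

Values are exactly 1 where residues are identical (here the scaffold
cysteines) and near 0 for chemically unrelated residues. The logo side:

```r
consensus_string(build_pfm(str9))
#> [1] "CPXNXXXPXXXC"
```

A thin CLI wraps the same functions
(`exec/pepsim generate|similarity|positional|cosine|motif|logo|compare`),
and `run_comparison()` writes a reproducible report bundle (TSV matrices,
per-position profiles, JSON per-peptide averages, manifest) that is
byte-identical across reruns with the same config and seed.

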