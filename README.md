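# paralogdiv

Molecular-evolution toolkit for asking what happened to a pair of gene
duplicates after they split. Given a codon-aligned trio — the two paralogs
plus an outgroup ortholog — the package polarises every change onto one of
the two post-duplication lineages and characterises the asymmetry between
them. It was built around the analysis of the duplicated *FLC*
(FLOWERING LOCUS C) floral repressors of *Boechera stricta*, where one
copy retains the ancestral vernalization-responsive role while the other
accumulates amino-acid changes concentrated near its protein-interaction
(K-box) domain, but every stage is generic.

The stages, each exposed as a documented function:

* **Ancestral reconstruction** (`reconstruct_ancestor`): outgroup parsimony
  per codon column. A column where one paralog differs from the agreeing
  outgroup/other-paralog pair is a substitution on that paralog's branch;
  columns where the paralogs agree against the outgroup (pre-duplication
  changes) and columns with three distinct states (unpolarisable) are
  excluded and reported. A run of gap codons in one paralog is a single
  in-frame indel event.
* **Nei–Gojobori divergence** (`count_sites`, `count_differences`,
  `lineage_divergence`): fractional synonymous/nonsynonymous site counts
  (averaged between ancestor and descendant), pathway-averaged difference
  counts (pathways through stop codons excluded), Jukes–Cantor correction
  *d* = −(3/4)·ln(1 − (4/3)*p*), and ω = dN/dS per lineage. A
  truncate-at-4-decimals mode reproduces the arithmetic of divergence
  tables printed at fixed precision.
* **Tajima's relative rate test** (`tajima_rrt`, `rrt_from_events`):
  χ²₁ = (m₁ − m₂)²/(m₁ + m₂) on lineage-specific change counts, for all
  changes, amino-acid-changing events (nonsynonymous points + indels) or
  synonymous changes.
* **Grantham classification** (`grantham_distance`,
  `classify_substitutions`): physicochemical distance of each amino-acid
  replacement from the 1974 composition/polarity/volume matrix (shipped as
  plain text), radical at ≥ 56 units by default.
* **Domain clustering test** (`domain_cluster_test`, `hypergeom_tail`):
  resampling test of whether substitutions concentrate inside a domain —
  each trial draws *n* distinct residues uniformly from the protein and
  counts in-domain hits; the empirical tail P(count ≥ observed) is
  reported next to the exact hypergeometric tail.
* **Expression analysis** (`relative_expression`, `timepoint_means`,
  `stage_correlation`, `expression_correlations`): qPCR ΔCt relative
  expression 2^(Ct_ref − Ct_gene), per-stage means ± SEM, and Spearman
  rank correlations across stage means with exact permutation p-values at
  small n (plus the large-sample t approximation).
* **Simulators** (`simulate_trio`, `simulate_qpcr`): generate FASTA trios
  with planted, exactly recoverable substitution truth and Ct tables with
  planted expression profiles, so every stage is testable end to end.

`paralog_divergence()` runs reconstruction, divergence and rate tests in
one call and returns a classed object with `print`, `summary`, `coef` and
`as.data.frame` methods; `run_full_analysis()` drives everything from file
inputs and writes a TSV/JSON report bundle with a run manifest.

## Worked example

```r
library(paralogdiv)

sim <- simulate_trio(seed = 7)   # default: 3 vs 9 point changes + one
fit <- paralog_divergence(sim$alignment)  # three-codon deletion, 196 codons
fit
```

```
Post-duplication divergence of paralogs vs outgroup

ancestral assignment (outgroup parsimony)
  paralog1=paralog1 paralog2=paralog2 outgroup=outgroup
  196 codon columns: invariant=176 lineage1=3 lineage2=9 shared=5 ambiguous=0 indel1=0 indel2=3 unalignable=0
  lineage 1: 3 events (1 syn, 2 nonsyn, 0 indel)
  lineage 2: 10 events (1 syn, 8 nonsyn, 1 indel)

Nei-Gojobori divergence per lineage (correction: jukes_cantor)
         lineage S_differences  S_sites     dS N_differences  N_sites     dN
paralog1       1             1 140.3333 0.0072             2 447.6667 0.0045
paralog2       2             1 137.8333 0.0073             8 441.1667 0.0184
          omega indel_events
paralog1 0.6258            0
paralog2 2.5179            1

Tajima relative rate tests
  all            (m1=3, m2=10): X2 = 3.769, P = 0.052
  nonsynonymous  (m1=2, m2=9): X2 = 4.455, P = 0.035
  synonymous     (m1=1, m2=1): X2 = 0.000, P = 1.000
```

Lineage 2 carries ten changes to lineage 1's three; rates do not differ
significantly over all changes (P = 0.052) but do when only
amino-acid-changing events are compared (χ²₁ = 4.455), and lineage 2's
ω ≈ 2.5 against lineage 1's ω ≈ 0.63 — the planted neofunctionalization
signature, recovered exactly. Clustering of the nine lineage-2
amino-acid-changing events in a K-box-like domain:

```r
dom <- domain_annotation("K-box", 83, 170, 196)
domain_cluster_test(L = 196, n = 9, domain = dom, k_obs = 8,
                    n_trials = 1000, seed = 42)
```

```
domain clustering resampling test
domain 'K-box': residues 83-170 of 196 (88 residues)
  8 of 9 substitutions observed in domain (protein L = 196)
  1000 trials (without replacement, seed 42): 7 trials with >= 8 in domain
  empirical P = 0.007, exact tail P = 0.007695
```

Eight of nine substitutions inside an 88-residue window is far beyond the
uniform expectation (~4): the empirical tail (7/1000 trials) agrees with
the exact hypergeometric tail.

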