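---
title: "Methods: post-duplication divergence of paralogs against an outgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-duplication divergence of paralogs against an outgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiv)
```

# The question and the model

After a gene duplication, the two copies evolve on separate branches. With
an outgroup ortholog that diverged before the duplication, every
difference between the copies can in principle be assigned to one branch
or the other, and the two branches compared: counts of changes, rates of
synonymous versus nonsynonymous change, the physicochemical severity of
the replacements, and where on the protein they land. Asymmetry across
these axes — one copy quiet, the other accumulating radical, spatially
clustered amino-acid changes with dN/dS above one — is the classic
signature of neofunctionalization. This package implements that whole
chain of inference on a codon-aligned trio, plus the expression-side
companion analysis (ΔCt relative expression and cross-gene stage
correlations) used to ask whether the copies still behave alike.

# Ancestral assignment by outgroup parsimony

The unit of comparison is the aligned codon column. With three observed
states (paralog 1, paralog 2, outgroup), parsimony on the rooted
three-taxon tree gives an unambiguous ancestral state whenever at least
two states agree:

| pattern | classification | ancestor |
|---|---|---|
| all equal | invariant | the common codon |
| paralog 2 = outgroup ≠ paralog 1 | substitution on lineage 1 | outgroup codon |
| paralog 1 = outgroup ≠ paralog 2 | substitution on lineage 2 | outgroup codon |
| paralogs equal ≠ outgroup | change predating the duplication ("shared") | the paralogs' codon |
| all three differ | ambiguous | undetermined (`NNN`) |

Assumptions: the duplication postdates the split from the outgroup, and
per-column multiple hits across the trio are rare enough that parsimony
and likelihood reconstructions coincide at unambiguous columns — the
regime of closely related duplicates this package targets, where a
196-codon alignment carries tens of changes, not hundreds. Ambiguous
columns are *excluded and reported*, never guessed: at the divergence
levels of interest they are rare, and guessing would silently move counts
between lineages. Likelihood-based reconstruction (as done by codon-model
software) is deliberately out of scope; at these divergences it differs
from parsimony only at columns this package flags as ambiguous anyway.

Indels: a run of consecutive gap codons in exactly one paralog is one
indel event on that lineage regardless of span (a single mutational event,
as for a three-codon in-frame deletion). Columns where the outgroup is
gapped cannot be polarised and are classified `unalignable`. Terminal
stop codons are stripped before analysis, so all counting operates on
sense codons. Residue coordinates are 1-based on the ungapped outgroup
translation, the stable reference all three sequences share.

# Nei–Gojobori counting and the truncation reproduction mode

Site counts: each codon position contributes the fraction of its three
single-nucleotide changes that are synonymous; mutations creating a stop
codon count as nonsynonymous (so S + N = 3 exactly per codon; a
stop-excluding variant is available behind `stop_mutations`). For a
lineage, sites are averaged between ancestor and descendant — the
standard pairwise convention, which is why the two lineages report
slightly different site totals even over the same alignment.

Difference counts: codons differing at one position are classified by
translation; at two or three positions, the synonymous/nonsynonymous step
counts are averaged over every minimal mutational pathway (all orderings
of the differing positions), excluding pathways that pass through a stop
codon. If every pathway is blocked the average falls back to including
them and flags the result — preferable to dropping the codon, which would
understate divergence. The implementation enumerates pathways explicitly
(at most six), and the test suite checks it against an independently
written enumerator on all 61 × 61 sense-codon pairs.

Divergence: *p* = differences/sites per class, optionally Jukes–Cantor
corrected, *d* = −(3/4)·ln(1 − (4/3)*p*), which is monotone and
undefined at *p* ≥ 3/4 (an error, not a silent NA). ω = dN/dS, reported
as missing when dS = 0 rather than infinite.

**Truncation mode.** Counting-method tables are conventionally printed at
four decimals, and the printed ω is formed from the printed dS and dN.
With `rounding = "truncate", decimals = 4`, dS and dN are floored at the
fourth decimal *before* the ratio. This is the only arithmetic consistent
with every cell of the reference divergence table the mode was validated
against (e.g. dN = 0.018217 prints as 0.0182, and 0.0182/0.0074 = 2.4595
while the unrounded ratio is 2.438); it is a reproduction convention, not
a statistical recommendation, and the default is `rounding = "none"`.

# Rate tests

Tajima's relative rate test needs only the lineage-unique change counts:
χ² = (m₁ − m₂)²/(m₁ + m₂) on 1 df, upper tail. Three change classes are
exposed. The `all` class counts point events plus indel events; the
`nonsynonymous` class counts nonsynonymous point events *plus* indel
events, because an in-frame deletion removes amino acids and is an
amino-acid-changing event on that branch — with one syn + eight nonsyn +
one deletion on one lineage and one syn + two nonsyn on the other, this
reading gives (m₁, m₂) = (2, 9) and χ² = 4.455, the only accounting
consistent with treating the ten-versus-three totals as (3, 10) in the
`all` class. `include_indels = FALSE` gives the point-events-only
variant. The p-value is the exact chi-square tail: for χ² = 4.455 that
is 0.0348, which some software displays rounded as 0.036; the exact tail
is reported.

# Grantham classification

The 1974 composition/polarity/volume distance matrix is shipped as a
plain-text table (range 5 for Leu–Ile to 215 for Cys–Trp) and loaded on
first use; structural invariants (symmetry, zero diagonal, range) are
asserted at load and in the tests. A replacement is *radical* at distance
≥ threshold, default 56 Grantham units — a conventional cutoff under
which most common substitutions are conservative. The boundary is
included on the radical side so that "distance below 56" exactly
complements it. Indels have no Grantham distance and are skipped with a
notice.

# The domain clustering test

Null hypothesis: amino-acid-changing events land independently and
uniformly over the protein's L residues. Each trial draws *n* positions
**without replacement** (observed substitutions occupy distinct
residues, so the natural null keeps draws distinct; a with-replacement
binomial variant is available via `sampling` since verbal descriptions
of such procedures often leave this open) and counts hits inside the
domain window. The empirical p is the fraction of trials with count ≥
the observed count — ties count as extreme. Under
without-replacement sampling the trial count is exactly
Hypergeometric(L, domain length, n), so the exact tail
(`hypergeom_tail`, computed by R's log-space hypergeometric machinery)
is reported beside the empirical one; with 1,000 trials the Monte-Carlo
standard error near p ≈ 0.007 is ±0.003, which is why both numbers are
always shown. The RNG is seeded per call and the caller's RNG state is
restored, so results are bit-identical under a fixed seed.

Domain bounds are required input: for MIKC-type MADS proteins such as
FLC the K-box window is commonly drawn around residues 83–170 of the
196-residue protein, which is the simulator's default domain, but any
annotation can be supplied.

# Expression analysis

Relative expression is 2^(Ct_ref − Ct_gene): one cycle = factor two,
exactly. Per-stage means and SEMs tolerate lost samples (reduced n,
flagged; an empty cell is NA with a warning). Correlations between genes
are computed **across the ordered time-point means** (n = 6 in the
motivating design), not across individual replicates — stage profiles,
not sample noise, are what the question is about, and at n = 6 a Spearman
ρ of −0.94 (Σd² = 68) is attainable exactly. With n ≤ 8 the permutation
p-value is exact (all n! rank assignments enumerated; 720 at n = 6);
one-sided tails and a two-sided value (twice the smaller tail, capped at
1) are reported, alongside the large-sample t approximation
t = ρ√((n−2)/(1−ρ²)) that statistical packages typically print — at
n = 6 the two can differ by a factor of three (0.017 exact vs 0.005
approximate at ρ = −0.943), so both are always available and neither is
silently substituted for the other.

# What the simulators emulate — and what they do not

`simulate_trio` plants *exact* truth rather than evolving sequences under
a continuous-time codon model: the downstream analyses consume counts,
classes and positions, so a recoverable truth table is worth more than
model realism. The defaults are the motivating study regime: 196 codons;
three point changes (one synonymous) on lineage 1; nine point changes
(one synonymous) plus one contiguous three-codon deletion on lineage 2;
nonsynonymous lineage-2 changes placed inside the K-box-like domain
(residues 83–170) with probability 8/9, so eight of nine in-domain is the
expected configuration; five outgroup-branch changes. Ancestor codons are
drawn uniformly over the 61 sense codons (a configurable-usage mode is a
documented extension point, not implemented). All planted events occupy
distinct codons, and outgroup changes avoid event codons, so outgroup
parsimony recovers the truth *exactly* — the tests assert recovery across
100 seeds.

Deliberately not emulated: multiple hits at one codon, ambiguous columns,
selection, codon-usage bias, rate variation, alignment error. Passing
tests therefore certify the counting, polarisation and testing machinery,
not robustness to reconstruction ambiguity in deeply diverged real data —
on real input, the `ambiguous`/`shared`/`unalignable` tallies in the
fitted object are the health check to read first.

`simulate_qpcr` writes Ct_gene = Ct_ref − log2(expression) + Gaussian
noise per measurement (default σ = 0.3 cycles, a typical technical
replicate spread; reference baseline Ct 20), sharing the reference
measurement within a sample so the ΔCt transform inverts the planted
profile exactly at σ = 0.

# Numerical and design choices

* Chi-square, hypergeometric, binomial and t tails come from R's `stats`
  distributions; tests cross-check the df = 1 chi-square tail against its
  closed form 2(1 − Φ(√x)) to 1e-10.
* Pathway averaging is exact enumeration, never sampling; rank-tie
  handling is average ranks (`stats::cor`, `rank`).
* Exact-permutation comparisons use a 1e-12 tolerance on ρ when counting
  tail permutations, so floating-point ties land on the inclusive side.
* Sites/differences invariants are enforced to 1e-9 in tests
  (S + N = 3 × codons; Sd + Nd = nucleotide difference count when no
  pathway is stop-blocked).
* Seeds are mandatory wherever randomness exists (`simulate_*`,
  `domain_cluster_test`), are recorded in every result object and report,
  and never touch the caller's RNG stream.
* Problem sizes in the shipped tests were chosen to exercise each
  property at full strength while staying desk-scale: all 3,721 codon
  pairs for the pathway oracle, 1,000 random sequences for the site
  invariant, 100 seeds for planted-truth recovery, 10,000 trials per
  grid point for the Monte-Carlo/exact agreement, all 720 permutations
  at n = 6.

# Known limitations

* Parsimony polarisation degrades as outgroup distance grows; ambiguous
  and shared columns are reported, not resolved. No likelihood-based
  branch models or branch-site selection tests are provided.
* The Nei–Gojobori estimator ignores transition/transversion bias and
  codon-usage structure; its Jukes–Cantor correction saturates at
  p = 3/4.
* The clustering test treats the domain window as fixed a priori; it is
  not a scan statistic and carries no correction for choosing the window
  after seeing the substitutions.
* Expression correlations at n = 6 stages have low power, and the exact
  and approximate p-values legitimately disagree at extreme ρ; both are
  reported so the choice is explicit.
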