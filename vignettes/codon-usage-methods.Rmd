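---
title: "Methods: codon usage bias analysis and the synthetic CDS generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis and the synthetic CDS generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

This vignette documents the statistical model behind `codonbias`, the
conventions and numerical choices that a reimplementation would need to
reproduce its numbers exactly, the design of the synthetic data
generator, and the limitations of the methods themselves.

## The analysis in one paragraph

Synonymous codon usage varies among genes of a transcriptome under the
joint influence of directional mutation pressure (which acts on all
positions, but is read most cleanly at largely-neutral third positions),
natural selection for translational efficiency (which acts mainly on
synonymous choice in highly expressed genes), and drift. The pipeline
quantifies where a CDS set sits between these forces: per-gene
composition and GC3s; RSCU as the basic usage summary; ENc against its
composition-only expectation; the neutrality regression of GC12 on GC3;
PR2 bias at fourfold sites; a correspondence analysis of RSCU profiles
whose first axis summarizes the dominant usage trend; and finally a
high-vs-low-expression contrast that nominates optimal codons.

## Conventions that pin the numbers down

**Family structure.** Leucine, serine and arginine are treated as single
six-fold families, isoleucine as the only three-fold family, and the
three stop codons as an optional `Ter` family of degeneracy 3 that is
reported in pooled tables but excluded from every per-gene index. ATG
and TGG carry no synonymous information: RSCU 1 by definition, excluded
from GC3s, CAI and the correspondence analysis (leaving the 59
informative codons).

**QC filter.** A CDS passes if its length is a multiple of three, it
contains only A/C/G/T, starts with ATG, ends with TAA/TAG/TGA, has no
internal stop, and has at least `min_aa` (default 100) non-stop codons.
Ambiguous sequences are rejected outright rather than codon-masked,
because every downstream index assumes unambiguous codons. "At least
100" is a parameter: both readings of a "longer than 100 amino acids"
cutoff are reachable. Each rejected sequence is reported with the first
failing check in a fixed order (`not_multiple_of_3`, `ambiguous_base`,
`no_start`, `no_stop`, `internal_stop`, `too_short`), so reports are
deterministic.

**ENc.** The package uses Wright's estimator. Per family with total
count $n > 1$, the homozygosity is $F = (n\sum \hat p^2 - 1)/(n-1)$;
class means $\bar F_k$ over the families of degeneracy $k \in
\{2,3,4,6\}$ give $\mathrm{ENc} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar
F_4 + 3/\bar F_6$, capped into $[20, 61]$. Families with $n \le 1$ or
$F = 0$ are uninformative and excluded. A missing three-fold class
(isoleucine absent) is imputed as $(\bar F_2 + \bar F_4)/2$; any other
wholly missing class contributes nothing (its numerator is rescaled to
the zero families observed). These conventions matter only for short
genes but are needed for the estimator to be total.

**GC3s and PR2 scope.** GC3s is the G+C fraction at third positions of
the 59 informative codons. The PR2 third-position counts default to the
eight fourfold-degenerate quartets (CTN, GTN, TCN, CCN, ACN, GCN, CGN,
GGN — Sueoka's convention, under which third-position choice is exactly
synonymous); an `all_synonymous` scope is also computed. PR2 quadrants
are numbered counter-clockwise from (0.5, 0.5); points exactly on a
boundary go to the lowest consistent quadrant index and are counted
separately, so quadrant totals are reproducible.

**CAI.** Relative adaptiveness $w(c) = n_c / \max_{\text{family}} n$
from pooled reference counts; zero-count codons are floored at 0.5
occurrences first, so no $w$ is 0 and a single unused codon cannot
annihilate a gene's geometric mean; a family absent from the reference
gets uninformative $w = 1$ with a warning. CAI is computed as
$\exp(\overline{\log w})$ over a gene's informative codons. The default
reference is the pooled counts of the 5% of genes with lowest ENc — the
standard stand-in for "highly expressed genes" when no expression
measurement exists — and can be overridden with any reference counts or
weight table.

**Correspondence analysis.** The input is the gene × 59-codon RSCU
matrix; families absent from a gene are imputed with the family-uniform
value 1, which is direction-neutral and keeps row profiles well defined.
Rows are normalized to profiles before decomposition, so every gene
carries equal mass and a gene's coordinates are invariant to any
positive rescaling of its row; for genuine RSCU rows (which then all sum
to 59) this coincides with standard CA of the raw matrix. The
standardized residuals $(P - rc^\top)/\sqrt{rc^\top}$ are decomposed by
SVD; axis inertia is the squared singular value, and total inertia
equals the chi-square statistic of the profile table over its grand
total. Axis 1 is oriented so that its correlation with GC3 is positive;
remaining axes (and axis 1 when GC3 is not supplied) put their
largest-magnitude gene coordinate on the positive side.

**Optimal codons.** Genes are ranked by CAI (ties broken by id) and the
top and bottom `fraction` (default 5%, at least one gene each, half-up
rounding) form the high and low pools. Counts are pooled *before* RSCU:
the per-pool RSCU is `k · n_c / Σ n` on summed counts, not an average of
per-gene RSCU values, which is what reproduces published pooled tables
exactly. Each codon of a multi-codon family is tested in a 2×2 Pearson
chi-square — (this codon vs rest of family) × (high vs low) — without
continuity correction (pool counts are large, and this construction
reproduces the published 28-codon worked example); a codon is flagged
optimal when $p < 0.01$ *and* its relative usage is higher in the high
pool. The relative-usage condition is deliberately not `RSCU > 1`: a
codon can be under-represented overall yet still significantly enriched
in highly expressed genes. Stop codons are tested but never flagged;
ATG/TGG are excluded.

**Rounding and report stability.** Published usage tables print two
decimals with halves rounded up; `round_half_up()` reproduces that
(base R rounds half to even), and all pipeline TSVs are sorted on fixed
keys so reruns are byte-identical.

## The synthetic CDS generator

The study-scale dataset this package targets (2,626 CDSs from a rhubarb
transcriptome) is not publicly deposited, so the generator produces CDS
sets with the same statistical structure, plus the ground truth needed
to test recovery:

* **Scale.** Default 500 genes of 100–500 non-stop codons
  (right-skewed Beta length distribution), a size at which every
  diagnostic is well determined while the whole pipeline runs in
  seconds.
* **Composition.** Per-gene GC3 targets are drawn as
  $0.21 + 0.68\,\mathrm{Beta}(0.8, 1.32)$: mean ≈ 0.47 (slightly AT
  rich, matching a mean GC near 46%) with tails that reach both ends of
  the 21–89% range seen in real AT-leaning transcriptomes. The GC12
  target is $0.46 + 0.17\,(\theta - \bar\theta) + \mathcal N(0,
  0.02)$, so the ground-truth neutrality slope is the `gc12_slope`
  parameter (default 0.17, a typical shallow plant-transcriptome
  slope).
* **Codon choice.** Within each family, codon $c$ has weight
  $\exp(b\,[c = \text{preferred}]) \cdot \tau^{[c \text{ ends G/C}]}
  (1-\tau)^{[c \text{ ends A/T}]}$ — a tilted multinomial that any
  oracle can reproduce exactly. The third-base tilt $\tau$ and the
  amino-acid sampling weights are calibrated per gene by root-finding so
  that the *expected* GC3 and GC12 equal their targets (a small
  fixed-point iteration; without it, fixed-third-base families such as
  Met/Trp would bias realized GC3 upward by several points).
* **Expression coupling.** Latent expression $e \sim U(0,1)$; the
  per-gene bias is $b = b_0\,(\kappa e + (1-\kappa)/2)$ with coupling
  $\kappa \in [0,1]$. At $\kappa = 1$ bias follows expression rank
  exactly; at $\kappa = 0$ all genes share the same intermediate bias,
  giving a clean null in which no gene-level usage differences exist.
  Default $b_0 = 2$ (an $e^2 \approx 7$-fold preference at full
  expression) produces ENc values down to the mid-20s in the most
  biased genes.
* **Preferred codons.** By default one A/T-ending codon per multi-codon
  family, sampled from the seed. This mirrors the systems being
  emulated — in AT-rich plant transcriptomes nearly all observed
  optimal codons end in A/U — and means the planted signal is aligned
  with, not opposed by, the composition gradient. Arbitrary planted
  sets (including G/C-ending ones) can be supplied; recovery of
  G/C-ending planted codons against an AT-leaning background is harder,
  precisely because of the composition confounding discussed below.
* **Determinism.** Every gene is generated from its own substream
  derived from `(seed, gene_index)`, so single genes can be regenerated
  without the rest and datasets are byte-identical across runs.

What the generator does *not* emulate: realistic amino-acid composition
(amino acids are sampled near-uniformly, tilted only to hit GC12
targets), length–bias correlations, isochore structure, or assembly and
annotation artifacts. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the *statistics*, not
robustness to upstream data pathology.

## Known limitations of the procedure itself

* **CAI-partition circularity.** The optimal-codon procedure partitions
  genes by CAI computed from the same counts it then tests. Under a
  true null this is anti-conservative: the top-CAI pool is, by
  construction, enriched for genes whose usage leans toward the
  reference weights, so the chi-square rejects above its nominal rate
  even when no gene-level differences exist. The package's null
  calibration therefore contrasts pools drawn by the generator's latent
  expression (independent of the counts under the null), which isolates
  the test's own calibration; results of CAI-partitioned runs on data
  without external expression measurements should be read with this
  selection effect in mind.
* **ENc-reference CAI.** Using lowest-ENc genes as the CAI reference
  conflates strong bias with high expression; in data with extreme
  composition heterogeneity the reference can be dominated by
  composition-extreme rather than highly expressed genes. An external
  reference set is preferable whenever one exists.
* **Neutrality slope attenuation.** The regression uses realized GC3,
  which carries multinomial sampling noise; the slope is attenuated by
  roughly $\mathrm{Var}(\theta)/(\mathrm{Var}(\theta) +
  \mathrm{Var}(\text{noise}))$. At 100+ codons per gene this is a
  ~2–3% effect, well inside the estimate's standard error at a few
  hundred genes.
* **Stop-codon RSCU.** The `Ter` family is reported for completeness of
  pooled tables, but with one stop per gene its "usage" reflects stop
  identity, not synonymous choice, and it is never eligible for the
  optimal flag.

## Degenerate inputs

Genes whose body is all ATG/TGG have undefined GC3s (`NA`); genes with
an empty PR2 axis are excluded from the PR2 plot and logged; families
with zero total in either pool are skipped by the chi-square with a
message; a gene too short to have any family with $n > 1$ has `NA` ENc;
constant parameters propagate `NA` through the correlation matrix with
a warning rather than an error.
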