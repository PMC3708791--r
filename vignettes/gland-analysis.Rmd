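---
title: "Methods: stink-gland transcriptome subtraction and defensive-chemistry quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stink-gland transcriptome subtraction and defensive-chemistry quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandtools)
```

`glandtools` implements the quantitative pipeline of a stink-gland
functional-genomics study: screening gland-specific genes from a
six-library mRNA-seq experiment, quantifying the defensive volatiles
the glands secrete, scoring RNAi knock-down phenotypes, and estimating
phenol-oxidase activity. This vignette documents the models, their
assumptions, the tunable parameters, and the design choices made where
the procedure left room.

## Transcriptome subtraction

### Model and assumptions

The experiment compares six libraries: an anterior-abdomen control
(`s1_ctl`), prothoracic glands from the *tar* mutant (`s2_tthr`), and
wild-type male/female prothoracic (`s3_mthr`, `s4_fthr`) and abdominal
(`s5_mabd`, `s6_fabd`) glands. The design rests on one empirical
premise: the six libraries have nearly equal total read counts
(relative totals within ~6% of the control), so raw read numbers are
comparable across samples without normalisation and represent actual
expression levels. `glandtools` therefore performs **no** library-size
normalisation and **no** dispersion modelling — there are no
replicates; this is a screening procedure, not differential-expression
inference.

Per-gene coverage is `reads × read_length / transcript_length`
(`coverage_depth()`, read length 38 bases by default), and genes with
coverage strictly above 50 — roughly twice the genome-wide depth — in
all four wild-type gland libraries (or in the control) are "abundant"
(`abundant_genes()`).

The screen itself (`classify_subtraction_groups()`) assigns each gene
to at most one of ten subtraction groups. Each group is a conjunction
of pairwise inequalities `log2((r_high + c)/(r_low + c)) >= cutoff`
over specific sample pairs: G1 all four wild-type gland samples over
the control; G2/G3 thoracic over abdominal (and control) and vice
versa; G4/G5 male over female samples and vice versa; G6–G9 the four
single-sample contrasts (s3 over s4, s5 over s6, and their reverses,
each also over the control); and G10 the *tar*-mutant contrast, where
the **absolute** log2 fold change of s2 against both s3 and s4 must
reach the cutoff (the mutant gland may be up- *or* down-regulated).

### Parameters

* `cutoff` (log2 units, default 6 = 64-fold): deliberately far above
  microarray-style 2-fold cutoffs; the screen wants genes worth
  cloning, not an exhaustive DE list.
* `pseudocount` (reads, default 1): the source procedure is silent on
  zero counts; a count pseudocount keeps fold changes finite and is
  the smallest value that does not distort counts in the hundreds.
* `min_reads` (reads, default 64): an auxiliary floor on the *high*
  side of every inequality. Without it, a gene with 63 reads against
  zero (log2 64/1 = 6 with pseudocount 1) would enter a group on what
  is plausibly noise. 64 is the fold-change cutoff expressed as a
  count and can be disabled (`min_reads = 0`).

### Numerical and design choices

* **Precedence.** The groups are stated to be non-overlapping but no
  resolution order is given. Assignment is first-match in ascending
  group order (G1 before G2 before … G10), matching the narrative
  order of the groups; ties are thereby resolved deterministically. A
  diagnostic column reports *all* groups whose conditions held.
* **Raw reads, not coverage**, enter the fold changes, consistent with
  the equal-totals premise above.
* **G5 omits the control comparison** — the female-specific contrast is
  worded only against the male samples — while its mirror G4 includes
  it; the asymmetry is preserved deliberately.

## Synthetic expression libraries

`simulate_expression_library()` plants a configurable number of genes
per group (defaults: 62, 23, 40, 0, 4, 0, 299, 0, 39, 44 — the
observed screening outcome) on top of exchangeable background genes
(default 1000). Planted genes carry
`baseline_reads × planted_fc × margin` expected reads in the samples
that define their group and baseline reads elsewhere; G10 genes
alternate between up-regulation (high s2 only) and down-regulation
(high everywhere but s2, so no wild-type contrast fires first).

Counts are drawn negative-binomially with variance
`mu + dispersion * mu^2`. The defaults state the simulated world:

* `baseline_reads = 50`: background expression around the abundance
  threshold, where most genes sit.
* `planted_fc = 64`, `margin = 2`: the planted signal clears the
  64-fold cutoff with a 2× safety factor, so recovery is robust to
  count noise.
* `dispersion = 0.001` (near-Poisson): each library is a *single
  technical sequencing run* of RNA pooled from hundreds of beetles, so
  between-sample variation of an exchangeable gene is technical
  sampling noise, which is close to Poisson. A biological-replicate
  dispersion (0.01–0.1) would model a different experiment than the
  one emulated.

What the generator does **not** emulate: mapping artefacts, transcript
ends and multi-mapping, library-size differences (all samples share one
size scalar, per the equal-totals premise), correlated expression
between genes, and the male accessory-gland contamination believed to
inflate the real G7. A green recovery test therefore establishes that
the classifier implements the stated inequalities and precedence, not
that the original gene lists would be reproduced from raw reads.

## GC-MS volatile quantification

Ten gland volatiles are registered (`compound_registry()`) with
molecular weights and Kovats retention indices; a compound observed at
two elution positions has two index aliases. Matching
(`match_peak()`) is nearest-alias within a tolerance (default ±5 index
units, chosen below the smallest inter-compound index gap in the
registry); exact ties are left unmatched rather than guessed.

Calibration (`fit_calibration()`) is ordinary least squares of area on
amount over a five-point standard series, with a free intercept —
forcing the origin is *not* assumed — and back-calculation
(`quantify_mass()`) clips negative masses to zero. Compounds without
an authentic standard are quantified as **equivalents** through a
surrogate's curve: ethyl-benzoquinone through the ethyl-hydroquinone
standard, heptadecadiene through heptadecene. Because hydroquinones
are the biosynthetic precursors of the benzoquinones, each pair is
summed (`MBQ_sum = MBQ + MHQ`, `EBQ_sum = EBQ + EHQ`) and treated as
the secreted quinone.

Molar conversion uses the **benzoquinone** molecular weights for the
summed quinones (122.04 and 136.05 g/mol) rather than a mass-weighted
mixture; this convention reproduces the reference nmol totals from the
reference µg means to within ±0.05 nmol (verified in the acceptance
tests). Alkene totals use 210.24 / 236.25 / 238.27 g/mol.

Group comparisons use the two-sided Mann–Whitney–Wilcoxon rank-sum
test; sex comparisons use Welch's *t*-test (the unequal-variance form —
only "t-test" is stated, and assuming equal variances would be the
stronger assumption). The rank-sum test computes its exact null for
combined n ≤ 12 by counting subsets of the doubled midranks with a
dynamic programme (ties exact, no sampling); beyond that it uses the
normal approximation with tie-corrected variance and no continuity
correction. The two-sided p is `2·min(P(W ≤ w), P(W ≥ w))` capped at
1, so identical groups give exactly 1.

## Phenotype-strength classification

Knock-down effects are expressed per beetle, gland and component as
`(kd − control_mean)/control_mean` and condensed into six classes:

| class | rule (any component, either gland) |
|---|---|
| 1 | ≤ 5% of control left in **every** beetle |
| 2 | reduced 75–95% or increased > 75% in **every** beetle |
| 3 | class-1/2 evidence in ≥ 1 beetle but not all |
| 4 | changed 25–75% in the majority of beetles |
| 5 | every change < 25% |
| 6 | uncloned / untested |

Open boundary questions were resolved as: boundaries are inclusive
toward the stronger class (a reduction of exactly 75% is class 2, of
exactly 95% class 1); "occasionally" (class 3) means at least
`min_penetrance` beetles (default 1) but not all; the class-4
"majority" is ≥ 50% of beetles showing the moderate change in the same
component. Evidence from the thoracic or the abdominal gland counts
equally. Under these rules the classes are exhaustive and mutually
exclusive for tested genes, and deepening every reduction can only
move a gene toward a stronger class (tested as a property).

The cohort generator plants, per intended class, changes inside the
open interior of each band (e.g. 77–93% reductions for class 2) so that
recovery is exact by construction; class 6 has no data and cannot be
simulated.

## Phenol-oxidase kinetics and inhibition zones

A plate is read at 490 nm every 2 min for 90 min (46 timepoints).
Blank wells measure substrate self-darkening; their mean is subtracted
pointwise (`blank_correct()`). PO activity is the **Vmax of the linear
phase**: since "linear phase" is not defined operationally, `po_vmax()`
takes the maximal least-squares slope over all contiguous windows of
`window_points` readings (default 10, i.e. 20 min — long enough to
average reading noise, short enough to fit between a lag and a plateau
in a 90-min run), clipped at zero and reported with the window
location. On a noiseless lag/linear/plateau trace any window inside
the linear phase attains exactly the true slope, so the estimator is
consistent by construction; it is also invariant to constant offsets.
Group summaries are on the square-root scale (the reporting scale of
the assay), with Welch *t*-tests against wild-type and significance
stars at 0.001/0.01/0.05. Inhibition-zone areas (cm²) are compared
knock-down vs same-sex wild-type with the shared rank-sum test.

The kinetic generator emulates only the piecewise-linear signal shape
plus Gaussian reading noise — not substrate depletion curvature or
temperature drift — so green tests establish correct slope recovery,
not mechanistic realism.

## Known limitations

* The subtraction screen reproduces the stated group conditions; the
  full auxiliary conditions of the original supplementary procedure
  (per-group read floors, possible coverage-based variants) are not
  printed anywhere and may differ in detail from the `min_reads` floor
  chosen here.
* No magnitude ground truth exists for PO activity or inhibition
  zones; only ordering and significance structure are reproducible.
* The rank-sum exact limit (combined n = 12) is a cost cutoff, not a
  statistical one; above it the tie-corrected normal approximation is
  standard but approximate.
* Real GC-MS peak integration, spectral identification and retention
  drift are out of scope: the pipeline starts at integrated areas.
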