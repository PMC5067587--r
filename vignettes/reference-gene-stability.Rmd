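---
title: "Reference-gene stability analysis: models, parameters and design choices"
author: "refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative RT-PCR reports a target gene's abundance relative to one or
more reference ("housekeeping") genes. In a complex, developing tissue —
the motivating case is the postnatal mouse mammary gland, whose cell-type
composition changes drastically from pre-puberty through puberty,
pregnancy, lactation and involution — the classical references (*Actb*,
*Gapdh*, *18S*, ...) are themselves regulated, and normalizing against
them can obscure or invert genuine developmental trends. `refstab`
implements the full workflow for doing better:

1. **mine** candidate reference genes from public expression matrices by
   selecting genes whose log2 fold change stays inside a narrow window
   across several physiologically divergent comparisons;
2. **score** candidates on qPCR data with four stability algorithms
   (GeNorm, comparative DeltaCt, BestKeeper, NormFinder);
3. **aggregate** the four rankings into a consensus by the geometric mean
   of per-algorithm positions;
4. **quantify** target genes by the efficiency-corrected comparative
   delta-Ct method against a multi-gene normalization factor, with an
   F-test-then-t-test comparison between stages.

A seeded simulator generates Ct tables and expression matrices with
planted ground truth, so every stage of the pipeline is testable without
any external download.

## The measurement model

A Ct value is the PCR cycle at which a reaction's fluorescence crosses a
threshold; one cycle corresponds to a factor *E* in template abundance,
where *E* ∈ (1, 2] is the primer pair's amplification efficiency (2 =
perfect doubling). All modelling is therefore additive on the Ct (log)
scale. The simulator draws

$$Ct_{g,s,r} = B_g + L_s + T_{g,k(s)} + \delta_{g,s} + \varepsilon_{g,s,r}$$

with gene baseline $B_g$, per-sample loading offset
$L_s \sim N(0, \sigma_L^2)$ (pipetting and RNA-input differences, common
to all genes — the quantity normalization is meant to remove),
fixed stage effects $T_{g,k}$ (zero for a true reference gene),
gene-specific biological instability
$\delta_{g,s} \sim N(0, \sigma_g^2)$, and technical-replicate noise
$\varepsilon \sim N(0, \sigma_{tech}^2)$. Defaults mirror a typical
five-stage developmental design: stages P14/P28/P35/P42/P56 with n = 3
biological samples each, technical triplicates, $\sigma_L = 0.5$ cycles,
$\sigma_{tech} = 0.25$ cycles. All draws come from a seeded
Mersenne-Twister stream (inversion method for normals), so a config plus
seed reproduces bit-identical data on any platform.

Technical triplicates are collapsed with the **median** by default —
robust to a single aberrant well — with the mean available as an option.
Relative quantities are obtained per gene as
$q_{gs} = E_g^{\,Ct^{\min}_g - Ct_{gs}}$, which pins each gene's
most-abundant sample at 1.

## The four stability algorithms

**GeNorm.** For genes $j,k$ let
$V_{jk} = \mathrm{sd}_s\!\left(\log_2 q_{js}/q_{ks}\right)$ (sample SD,
n − 1). The stability of gene $j$ is
$M_j = \mathrm{mean}_{k\neq j} V_{jk}$: a gene that tracks the common
loading has constant ratios with every other stable gene and a small
$M$. Ranking proceeds by stepwise exclusion of the highest-$M$ gene,
recomputing $M$ after each removal, until two genes remain. The pairwise
variation $V_{n,n+1}$ — the SD over samples of
$\log_2(NF_n/NF_{n+1})$, where $NF_n$ is the geometric mean of the $n$
best genes' quantities — indicates how many references are enough.

**Comparative DeltaCt.** The same construction applied directly to Ct
differences: $\mathrm{score}_g = \mathrm{mean}_{h\neq g}\,
\mathrm{sd}_s(Ct_g - Ct_h)$. When every efficiency is 2 this is
*algebraically identical* to the GeNorm M-value, since
$\log_2 q_{js}/q_{ks} = (Ct_{ks}-Ct_{js}) + \text{const}$. That identity
is used as a cross-check between the two independently coded paths (they
agree to < 1e−9 on random matrices).

**BestKeeper.** Descriptive statistics on raw Ct: per-gene SD (the
ranking score; a mean-absolute-deviation variant is available via
`use_mad = TRUE`), CV% relative to the arithmetic mean Ct, and the
Pearson correlation of each gene with the *BestKeeper index*, the
per-sample geometric mean Ct over all candidates. Because it scores raw
Ct rather than ratios, BestKeeper is **not** invariant to per-sample
loading — a documented behavioural difference, verified by test: adding
a per-sample offset vector changes BestKeeper SDs while leaving GeNorm,
DeltaCt and NormFinder scores untouched. A zero-variance gene has an
undefined correlation, reported `NA`, and is still ranked by SD.

**NormFinder.** A variance-decomposition view of log2 quantities
$z_{gs}$. Sample-centering $r_{gs} = z_{gs} - \bar z_{\cdot s}$ removes
the common loading component. Without groups the score is
$\mathrm{sd}_s(r_{gs})$. With groups, for each group $k$ the within-gene
variance $v_{gk}$ is bias-corrected by the gene-average of its group
($\hat s^2_{gk} = \max(0,\, v_{gk} - \bar v_k / G)$, $G$ = gene count)
and combined with the intergroup deviation $d_{gk}$ (group mean of $r$,
centered across groups):
$$\mathrm{score}_g = \mathrm{mean}_k\left(|d_{gk}| +
\sqrt{\hat s^2_{gk}/n_k}\right).$$
The original NormFinder publication additionally shrinks the intergroup
differences with a Bayesian factor; this package deliberately uses the
deterministic estimator above. It keeps the intragroup/intergroup
decomposition — a gene with a planted group shift is flagged, and its
reported $d_{gk}$ recover the shift up to the centering factor
$(1 - 1/G)$ — while remaining reproducible without distributional
machinery. Its validation surface is recovery of planted truth on
synthetic data, not numeric identity with the original spreadsheet.

**Aggregation.** Each algorithm contributes integer positions 1..G; the
consensus score is the geometric mean of a gene's positions and the
overall order sorts it ascending (ties: arithmetic mean, then gene
name). The geometric mean is used rather than the arithmetic so that a
single discordant algorithm cannot drag a consistently top-ranked gene
far down. Encoding the four published rankings of the 16-gene mammary
panel reproduces the published consensus order exactly, with the three
novel candidates (*Prdx1*, *Phf7*, *Ctbp1*) in the top three places:

```{r table1}
t1 <- list(
  deltact = c("Prdx1","Ctbp1","Phf7","Tbp","Hprt","Rpl13a","Sugp2","Gapdh",
              "Clock","18S","Usp7","Taf11","Sdha","Actb","Hmbs","Arpc3"),
  bestkeeper = c("Prdx1","Ctbp1","Rpl13a","Phf7","Tbp","Hprt","Sugp2",
                 "Gapdh","Taf11","Usp7","Clock","18S","Sdha","Actb","Hmbs",
                 "Arpc3"),
  normfinder = c("Phf7","Tbp","Prdx1","Ctbp1","Hprt","Rpl13a","Clock",
                 "Sugp2","Gapdh","18S","Usp7","Taf11","Sdha","Actb","Hmbs",
                 "Arpc3"),
  genorm = c("Phf7","Prdx1","Ctbp1","Hprt","Rpl13a","Gapdh","Sugp2","Usp7",
             "Taf11","Clock","Tbp","18S","Sdha","Actb","Hmbs","Arpc3"))
aggregate_rankings(t1, names(t1))
```

## Candidate mining from expression matrices

`log_fold_change()` computes, per gene, the difference of group means of
log2 values — identical to the two-group linear-model coefficient that
GEO2R-style front-ends report. No moderated statistics are implemented:
moderation changes p-values, not the coefficient, and only the logFC
window matters for selection. `stable_gene_filter()` keeps genes with
logFC strictly inside (−0.1, 0.1) by default. The bounds are open
because the defining inequality is written strictly; boundary genes are
measure-zero in continuous data, and the window is configurable.
`intersect_stable_sets()` returns the genes stable in *every*
comparison plus all exclusive Venn region counts; `rank_by_expression()`
orders a candidate set by average expression so a panel can be checked
for spanning low through high abundance.

For real array data, `collapse_probes()` offers two probe-to-gene rules
(keep the brightest probe, or average); published gene counts from such
mining depend on the collapsing rule the original analysis used, which
is typically unstated, so exact count reproduction is not a goal. A
minimal series-matrix reader (`read_series_matrix()`) parses the data
block of GEO series-matrix files; full SOFT parsing is out of scope.

## Target quantification

`normalization_factor()` is the per-sample geometric mean of the
reference genes' relative quantities; dividing a target's quantity by it
removes any per-sample scaling — multiplying all genes' quantities in a
sample by a constant leaves the normalized values unchanged (verified to
1e−9). The calibrator is a *group* whose mean is rescaled to 1 (a bar
chart with the first stage at 1), because group bars are what such
experiments report; rescaling by the single lowest sample is available
via `rescale = "min_sample"`.

Stage comparisons follow the classical two-step recipe: a two-sided
F-test for variance equality chooses between the pooled (Student) and
Welch t-test, with the variance-test alpha defaulting to 0.05 (a
convention, not a published threshold). P-values are reported unadjusted
by default — matching how such pairwise stage comparisons are usually
reported — with Holm adjustment behind a flag.

Amplification efficiencies come from dilution series:
`efficiency_from_dilution_series()` fits Ct against log10 relative input
and returns $E = 10^{-1/\mathrm{slope}}$; a perfect 10-fold series
spaced 3.3219 cycles apart yields exactly $E = 2$. A non-negative slope
flags a failed assay rather than returning a nonsensical efficiency.

## What the simulator does and does not emulate

The generator reproduces the *structure* of a developmental qPCR study:
loading offsets, gene-specific instability, stage effects (including a
monotone "Wnt4-like" trend planted at −0.5 cycles per stage, i.e. true
fold changes 1, √2, 2, 2√2, 4 at E = 2), technical triplicates, and
microarray-like matrices with a planted stable core. It does **not**
emulate amplification-curve shapes, primer-dimer artefacts, probe
effects, inter-run batch drift, or correlated co-regulation between
candidate genes; an optional flag adds extra noise above Ct 32 to mimic
low-abundance targets, but is off by default. Passing recovery tests on
these simulations therefore demonstrates that the algorithms are
implemented correctly and are identifiable under their own model
assumptions — not that any particular biological panel is stable.

Default problem sizes in the test-suite simulations were chosen to
mirror the motivating study design while keeping the suite quick: 15
samples in 5 stages for stability recovery, 5 arrays per condition and a
37-gene planted core for mining recovery, 100 seeded replicates per
property.

## Numerical choices and degenerate inputs

* **Tie-breaks** are lexicographic by gene name everywhere a score ties,
  so all rankings are deterministic. In GeNorm's stepwise exclusion the
  lexicographically greatest of the tied-worst genes is removed first,
  which makes an all-constant matrix rank alphabetically.
* **GeNorm final pair:** the last two genes have identical M by
  construction; they are ordered by their mean M across all rounds in
  which both survived. This uses only already-computed quantities and is
  deterministic.
* **Missing data:** stability algorithms require a complete gene ×
  sample grid. Cells with no surviving replicate become `NA` with a
  warning at collapse time, and conversion to relative quantities fails
  loudly, listing the offending (gene, sample) pairs — none of the four
  algorithms defines imputation, so none is invented.
* **Validity windows:** Ct must lie in (0, 45] (a 40–45-cycle run with
  headroom; configurable), efficiencies in (1, 2.2].
* **Gene names** are opaque, compared case-sensitively; internal
  whitespace is stripped at parse boundaries so typeset variants of the
  same symbol ("Phf 7") unify.

## Known limitations

* The stability scores are reimplementations from their defining
  formulas, not bit-identical ports of qBase+, the RefFinder site, or
  the original BestKeeper/NormFinder spreadsheets; rankings agree in
  validated scenarios but individual score values can differ in tools
  that apply additional smoothing.
* With few candidate genes (≈5), NormFinder's sample-centering injects a
  common noise floor into every residual, limiting its ability to
  separate nearly equally stable genes; and BestKeeper's raw-Ct SD
  conflates loading variation with gene instability, so its ranking is
  only informative when loading is small or has been controlled. Both
  behaviours are intrinsic to the algorithms and are characterised in
  the test suite.
* No confidence intervals on stability values, no inter-run calibration,
  no absolute quantification.
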