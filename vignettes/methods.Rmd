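---
title: "Methods: functional scoring and ACMG/AMP classification of knockin assay data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional scoring and ACMG/AMP classification of knockin assay data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprselect)
```

## The measurement model

A competitive knockin assay introduces, in one culture, two
homology-directed-repair products at the endogenous locus: the variant of
interest and a synonymous internal-control edit (WT′). Amplicon sequencing
at day 2 (baseline) and day 12 (after selection — untreated, PARP
inhibitor, cisplatin or mitomycin C) yields per-sample allele tables. Reads
are classified by exact full-amplicon match into `variant` and `wtprime`
classes; rows matching neither edited amplicon are `frameshift` when their
net indel length is not a multiple of 3, otherwise `other` (this includes
unedited reference reads and substitution-only mismatches). Exact matching
is deliberate: fuzzy alignment belongs to the upstream amplicon aligner
whose table we consume, and exactness keeps the classifier testable
bit-for-bit. An alternative convention would count partial-HDR alleles
(variant edit present, auxiliary silent edits absent) as variant reads; we
require the full expected amplicon and note that relaxing this would only
rescale both numerator classes.

The functional score in arm $c$ is the day-2-normalized ratio

$$ S_c = 100 \times \frac{(V/W)_{12,c}}{(V/W)_{2}} \; [\%] $$

computed **per replicate** and then averaged (mean ± sample SD, $n-1$
denominator; the convention for the assay's SD is not fixed anywhere, and
sample SD is the conservative choice). Normalizing before averaging — not
pooling counts — matches the assay's stated order of operations. The day-2
score is identically 100 for every replicate. A zero WT′ count raises an
error (the sample is flagged, never silently dropped); a `pseudocount`
mode exists but is off by default since the assay defines no smoothing.
Samples under 7,500 total reads fail QC and are excluded; if a replicate's
day-2 baseline fails, that replicate is excluded for the variant.

Frameshift alleles knock the gene out and are under strong negative
selection; the same ratio machinery applied with the frameshift class as
numerator gives a run-level QC gate: an arm is flagged `depleted` when its
mean normalized frameshift/WT′ ratio falls below $100 - k\,\mathrm{sd}$
(default $k = 2$; a whole-run failure of this flag indicates the selection
did not operate).

## Thresholds, calibration and OddsPath

Variants are categorized per arm by the replicate **mean** (the quantity
plotted against threshold lines): deleterious at $\le 25\%$, intermediate
in $(25, 50]$, neutral above $50\%$. The defaults are the assay's
established constants; `roc_curve()` additionally reports the Youden-J
optimal single cutoff for transparency, because no unique "two-threshold
ROC" procedure exists — the intermediate zone is configuration, not
inference.

Calibration uses classified control variants only (risk-allele /
conflicting-classification variants are excluded by role). Each control's
scalar score is its **minimum** replicate-mean ratio across the four day-12
arms — its worst-case behavior — because the pathogenic functional code is
triggered by deleteriousness in *any* arm. Sensitivity is the fraction of
pathogenic controls with an abnormal readout (score $\le 25$), specificity
the fraction of benign controls scoring above the neutral threshold;
binomial CIs use the Wilson score interval, whose $k=n$ lower bound has the
closed form $n/(n+z^2)$ — for 14/14 and 9/9 at 95% this gives 78.5% and
70.1%. (The Wilson and Brown-hybrid constructions coincide at these $k=n$
boundary cases.)

Functional evidence strength follows the OddsPath framework. With $P_1$
the pathogenic proportion among all controls and $P_2$ the pathogenic
proportion within a readout class,

$$ \mathrm{OddsPath} = \frac{P_2 (1 - P_1)}{(1 - P_2) P_1}. $$

A perfect assay makes a readout class pure ($P_2 \in \{0, 1\}$) and the
odds degenerate; the framework's correction adds **one hypothetical
opposite-truth control to the pure class** before computing $P_2$. This
choice uniquely reproduces all three published anchor values: 14 + 9
perfect controls give OddsPath 9 (pathogenic) and $1/14 \approx 0.071$
(benign), and a balanced perfect set of $n + n$ controls gives OddsPath
$n$ — hence 19 + 19 as the requirement for full-strength PS3/BS3.
Strength cutpoints: pathogenic $\ge 350$ very strong, $\ge 18.7$ strong,
$\ge 4.3$ moderate, $\ge 2.1$ supporting; benign on the reciprocal scale
($\le 0.00285$, $0.053$, $0.23$, $0.48$). OddsPath 9 / 0.071 therefore
supports PS3/BS3 at **moderate** strength.

## Evidence codes and classification

Per variant, the engine assembles:

* **PS3/BS3** — deleterious in any arm → PS3 at the calibrated strength;
  otherwise intermediate in any arm → PS3 at indeterminate strength
  (0 points, so hypomorphs are not pushed toward benign); all arms neutral
  → BS3 at the calibrated strength. A variant with no QC-passing arm is
  not assessable.
* **Population** (exactly one): BA1 for filter allele frequency
  $> 10^{-3}$ (stand-alone benign); BS1 strong for FAF in
  $(10^{-4}, 10^{-3}]$; BS1 supporting in $(2\times10^{-5}, 10^{-4}]$;
  PM2 indeterminate for minor allele frequency in $(0, 2\times10^{-5}]$;
  PM2 supporting when absent in controls (also the fallback with no
  frequency data).
* **Computational**: PP3 supporting when SpliceAI $\ge 0.2$ and/or
  BayesDel $\ge 0.30$; BP4 supporting when SpliceAI $\le 0.1$ and BayesDel
  $\le 0.18$; nothing in the gap zone or when a score is missing.
* **Asserted splicing codes** (external evidence passed through): PS1
  (splicing) and PVS1 (RNA) with explicit strengths. PVS1 suppresses both
  PS1 and PP3 for the same variant to avoid double-counting the splicing
  defect.

Codes are combined twice. The **point system** scores supporting/moderate/
strong/very-strong as 1/2/4/8 (benign negated, indeterminate 0) and maps
the total to: benign $\le -7$; likely benign $-6..-2$; uncertain $-1..5$;
likely pathogenic $6..9$; pathogenic $\ge 10$; BA1 short-circuits to
benign. The **qualitative system** implements the original 2015 combining
rules; since those rules predate moderate-strength benign codes, a
moderate benign code counts as two supporting benign codes — the
convention that lets an OddsPath-calibrated BS3-moderate drive a
likely-benign call. The final class is the shared class when the two
systems agree, otherwise the variant stays uncertain and is flagged
discordant (classifications should be claimed only when both systems
support them). An exhaustive scan over every bundle the engine can emit
(both systems, all role-consistent code/strength combinations) verifies
that no bundle is ever pathogenic-side in one system and benign-side in
the other.

Codes the upstream evidence cannot supply for rare variants (PP1/BS4,
PP4/BP5, PS4, PM3/BS2) are intentionally not implemented.

## The synthetic-data generator

The generator exists so every stage is testable without sequencing data.
It parameterizes selection **directly by the target normalized ratio** per
arm — the number of cell generations between day 2 and day 12 is unknown,
and a per-generation fitness model would only re-derive the same measurand
through an extra nuisance parameter. Per sample it draws one multinomial
of `n_reads` reads over (variant, WT′, frameshift, other). Day-2 class
probabilities are the HDR incorporation fractions; defaults (0.10, 0.10,
0.20, 0.60) are free parameters chosen once as realistic knockin/indel
rates — the assay does not report them. In each day-12 arm the variant
fraction is scaled by `true_ratio/100` and perturbed by multiplicative
log-normal noise with mean 1 and coefficient of variation `replicate_cv`
(default 0.1; one parameter suffices to reproduce a mean ± SD replicate
structure), the WT′ fraction is held at its day-2 value (WT′ is the
neutral reference by design), and the frameshift fraction is multiplied by
`frameshift_day12_retention` (default 0.2, i.e. strong negative
selection). Fractions leaving the simplex signal a mis-specified profile
and raise an error.

Panel defaults are the study conditions: 9 benign controls (true ratios
70–110% in every arm), 14 pathogenic controls (0–15%), and query variants
drawn from neutral/intermediate/deleterious strata with weights 45:2:7 —
the observed composition of the assayed VUS panel. Deleterious query
variants still receive BayesDel $\le 0.18$, emulating the documented
discordance between metapredictors and functional effect in this domain.
Simulation is seeded throughout (per-variant seeds derived from the run
seed, kept under $2^{31}$), so identical configurations are byte-identical.

What the generator does **not** emulate: sequencing error, PCR duplicates
and jackpots, partial-HDR and complex alleles, inter-replicate editing
variability beyond the one log-normal term, and arm-specific overdispersion.
Passing tests therefore demonstrate correctness of the analysis under the
assumed count model, not robustness to those real-data artifacts.

## Numerical choices and problem sizes

Ratios are computed in double precision with no smoothing; day-2
normalization is exact by construction. The ROC uses cutoff enumeration
over observed scores (ties handled as diagonal segments, so the trapezoid
AUC equals the Mann–Whitney statistic). Wilson intervals are clamped to
$[0,1]$. The test suite exercises convergence at $10^6$ reads (tolerance
1% on replicate means), parameter recovery on 200 variants at 10,000 reads
× 3 replicates (≥ 95% recovery of deleterious ≤ 20% and neutral ≥ 80%
strata), a 10,000-draw Monte-Carlo oracle for the 20%-ratio sampling
distribution, and the exhaustive (~500-bundle) concordance scan; these
sizes keep the default suite under half a minute while leaving the checks
statistically sharp.

## Bundled stand-in panel

`inst/extdata/synthetic_pbd_panel.tsv` is a **synthetic** table — no
measured data — whose 54 rows mirror a real PALB2-binding-domain VUS
panel: per-arm replicate-mean ratios encoding the published functional
categories (four splice-region variants deleterious, with the
closest-to-donor one carrying an asserted PVS1-RNA strong code and the
three synonymous ones PS1 moderate plus PP3-eligible SpliceAI; three
Trp-site missense variants deleterious with BP4-concordant scores; two
hypomorphs intermediate; 45 neutral with mixed PM2/BS1 population bands).
Classifying it reproduces the 49/54 outcome (45 likely benign, 4 likely
pathogenic, 5 uncertain) and documents *why* the uncertain ones fail:
moderate-strength PS3 plus a contradicting BP4 cannot reach 6 points. The
real per-variant annotations live in the assay's supplementary material
and are not redistributed here.

## Known limitations

* Calibration assumes the control set is representative across protein
  domains; domain-specific recalibration is not implemented.
* The two-threshold scheme is configuration; only the single Youden cutoff
  is derived from data.
* OddsPath is computed from the binary readout only (no continuous
  score-to-odds curve).
* The qualitative/point concordance guarantee covers the nine implemented
  codes at their emitted strengths, not arbitrary external code bundles.
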