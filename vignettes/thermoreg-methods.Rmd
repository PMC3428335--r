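---
title: "Models and methods in thermoreg"
author: "thermoreg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in thermoreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoreg)
```

`thermoreg` couples an energetic description of transcription with
nonlinear-correlation network inference on tumor/control expression
cohorts. This vignette records the models, the defaults and why they were
chosen, the numerical conventions, and the limits of what the test suite
demonstrates.

## The thermodynamic model of transcription

Microarray probe intensity reflects competitive hybridization between
labeled transcripts and probes — a two-state process with a Langmuir
isotherm

$$I(c) = s\,\frac{c}{c + K},$$

where $s$ is the probe's saturation constant (the intensity at which the
probe response saturates) and $K$ the half-saturation concentration. The
package parameterizes $K = \Delta G_{hyb}/(R\,T)$ on a 1 pM reference
scale: the free energy of hybridization measured in thermal units sets
the concentration scale of the isotherm, so stronger-binding probes reach
half saturation at proportionally scaled transcript abundances, and all
reported concentrations are picomolar. Each probe therefore needs three
constants — $\Delta G_{hyb}$ (kcal/mol), $s$ (intensity units), and the
intensity-scale constant $\alpha = s/\Delta G_{hyb}$ (mol/kcal ×
intensity) that links them; `core_params()` ships the calibrated values
for the four master-regulator probes (MNDA, POU2AF1, MEF2C, SMAD3) on the
HGU133A platform, derived from the manufacturer's spike-in calibration
data. Temperature defaults to 310.15 K and enters only through $K$.

The chemical potential of transcription,

$$\mu(I) = \Delta G_{hyb}\,\Bigl(1 - \frac{I}{s}\Bigr)
        = \Delta G_{hyb} - \frac{I}{\alpha},$$

is read as the activation-energy barrier for synthesizing the transcript.
Its sign convention is fixed by three simultaneous contracts: it is
positive below the saturation constant, crosses zero exactly at $I = s$,
and is negative above. Under this form the barrier at vanishing intensity
equals $\Delta G_{hyb}$ — nearly identical across probes — while the
differences between genes emerge at high intensity through their distinct
saturation constants. A transcription factor operating near its
saturation limit (high fractional occupancy $I/s$) has a low barrier:
it is synthesized first as metabolic energy becomes available, which is
the proposed energetic ordering of regulatory cascades.

The transcriptional affinity is the thermodynamic conjugate of probe
intensity. Writing the free energy in intensity variables,

$$A_i = \sum_j \Lambda_{ij}\, \mu_j(I_j)\, \frac{dc_j}{dI_j}(I_j),
\qquad \frac{dc}{dI} = \frac{K\,s}{(s - I)^2},$$

with $\Lambda$ a square matrix of cross-regulation coupling coefficients.
$\Lambda$ defaults to the identity: expression measured in intact
(non-perturbed) cells already embeds the regulatory interactions
implicitly, so per-gene quantities are computed without explicit cross
terms; off-diagonal coupling is supported for model exploration.

Numerical conventions: background-corrected intensity 0 maps to
concentration 0; `intensity_to_concentration` requires
$0 < I < s$ strictly and errors otherwise; `thermo_profile` clamps noisy
intensities at or above saturation to $s(1-10^{-6})$ with a warning;
$\mu$ is defined for all positive intensities (it is the one quantity
meaningfully evaluated above saturation, where it is negative).
Ranking by mean $\mu$ breaks exact ties lexicographically by gene id.

## Surrogate progression and cohort stages

Biopsy cohorts are cross-sectional, so the package orders steady-state
samples by the expression of a malignancy marker (BNIP3, probe
`201848_s_at`) as a surrogate trajectory. The sort is ascending and
stable; ordering is tested to be idempotent.

Differential expression is a deliberately simple, fully documented
moderated statistic: a two-sample t on log2 intensities with each gene's
pooled variance shrunk halfway toward the cohort median variance
($\tilde s^2 = w\,\mathrm{med}(s^2) + (1-w)\,s^2$, $w = 0.5$), p-values
from the t distribution on the pooled degrees of freedom, and
Benjamini–Hochberg q-values. The weight is a fixed, documented constant
rather than an estimated prior: determinism and transparency were
preferred over adaptive shrinkage, and the closed form of this statistic
is itself the contract the tests pin down.

Core-set (master-regulator) selection intersects four annotation
constraints over the significantly differential genes: experimentally
supported TF activity, literature association with breast (score 2) or
other solid (score 1) tumors — liquid neoplasms excluded when the table
is built —, metabolic-pathway membership, and availability of a complete
thermodynamic characterization. On the breast-carcinoma cohort design
this intersection yields {MNDA, POU2AF1, MEF2C, SMAD3}. The q-value
cutoff is a parameter (default 0.05) since no canonical value exists.

## IBS network inference

The Information Based Similarity between two series binarizes increments
(1 where the series increases; zero increments count as "not
increasing"), slides an $m$-bit window, ranks the $2^m$ word types by
frequency (average ranks for ties), and returns

$$D = \frac{1}{2^m - 1} \sum_k |R_1(k) - R_2(k)|\,
      \frac{p_1(k) + p_2(k)}{2} \in [0, 1].$$

$D$ depends only on increment signs and word ranks, hence is invariant
under strictly monotone transforms of either series — the property that
makes it a *nonlinear* correlation measure. The exact variant in force
(average-rank ties, mean-probability weight, normalization) is recorded
in the `ibs_config` so results are reproducible.

Significance is assessed against a permutation null: for each
(core gene, partner) pair, the core gene's series is permuted over
samples and the fraction of permutations with distance at or below the
observed one, with a +1 pseudo-count, is the p-value. Edges are
core-to-genome pairs whose BH-adjusted p is at or below `alpha`;
correlations among the four core genes themselves are retained, not
pruned, because those indirect links are precisely where
metabolic/transcriptional coupling shows. Each edge carries the
highest-precedence literature class of its two members (breast cancer >
other cancer > metabolic > other). Directionality is out of scope: the
measure is symmetric and no causal claim is made.

Two structural properties of this test shaped the defaults and the study
designs used in the tests, and are worth stating plainly:

* *The permutation null detects serial structure, not per-sample
  co-fluctuation.* The IBS word profile of an exchangeable series is
  distributionally invariant under sample permutation, so only signal
  that lives in the *ordering* of samples (trends, programs along
  progression) is detectable. Correlation that is purely per-sample is
  invisible to this null.
* *IBS is a distance between marginal word-rank profiles.* Two genes are
  close when their increment "styles" match, so regulators are
  distinguishable only insofar as their programs differ in word-profile
  style.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with a recorded ground truth (planted edges, progression order, DE
genes, latent concentration matrix). Defaults mirror the network
recovery study design: 4 TFs × 10 targets, 500 background genes, 100
tumors + 100 controls.

* **Progression.** A latent malignancy variable $t$ is uniform per
  sample *within phenotype*: controls on $[0, 0.32]$, tumors on
  $[0.30, 1]$. A malignancy marker that did not separate phenotypes
  would be no marker at all; keeping the phenotype shift approximately
  monotone along the progression axis is also what keeps it from
  corrupting every regulated gene's increment sequence with an
  exchangeable ±1-log2 component (see the first structural property
  above). The marker's latent concentration is strictly monotone
  (affine in log2, 20–2000 pM) in $t$ before noise.
* **Regulator programs.** Each TF takes one ±0.9-log2 step per
  progression rank following a periodic up/down motif unique to it
  (`111000`, `110100`, `101100`, `101110101000`). The motifs were chosen
  by combinatorial search over balanced cyclic words without 4-runs to
  maximize the worst-case IBS profile distance between different
  regulators and to the monotone marker — this is what gives the
  network stage *specificity* (second structural property). A small
  per-sample biological fluctuation (`tf_bio_sd`, default 0.05 log2) is
  added. Base abundance is 400 pM so that regulators traverse moderate
  occupancies: high enough to plant the low-μ signature of master
  regulators, low enough that isotherm compression near saturation does
  not flatten the program (log-intensity increments scale with
  $1-I/s$).
* **Targets.** Each target is an elementwise link-function image
  (linear by default; monotone power law and threshold variants
  available) of its regulator's latent concentration, with slope drawn
  from $[0.15, 0.45]$ — so targets share their regulator's program
  exactly but sit at lower occupancy. With the linear link the tumor
  effect passes through unchanged.
* **Tumor effect.** Regulated genes (TFs, and targets through the link)
  are shifted by `de_effect_size` (default 1) log2 units in tumors,
  applied on latent concentration so that intensities remain inside the
  isotherm's range and noise-free cohorts recover latent concentrations
  exactly.
* **Background and noise.** Background genes are i.i.d. log-normal
  around gene-specific means (100–350 pM, `bg_sd` = 0.5 log2);
  technical noise is multiplicative log-normal on intensity
  (`noise_sd`, default 0.1 log2 ≈ 7% CV, a typical technical-replicate
  scatter), truncated below each gene's saturation constant. Biological
  variation is kept separate from `noise_sd` so noise-free runs still
  exercise differential expression and network inference.

What the generator does **not** emulate: probe-level effects and RMA
preprocessing, batch effects, heavy-tailed or correlated technical
noise, non-regulatory gene-gene correlation (co-expression without a
planted edge), and slow smooth progression programs. In real cohorts
adjacent samples in a marker ordering are independent patients, so
ordering-scale structure is far weaker than planted here; passing the
recovery tests demonstrates correctness of the machinery under its
stated assumptions, not that the method would attain the same operating
point on arbitrary clinical data.

## Study designs used by the tests

The recovery experiments fix their analysis parameters a priori from
power arithmetic, not from observed test outcomes:

* Network recovery runs at word length $m = 4$ and 2000 permutations.
  With the default $m = 2$ there are only four word types, whose rank
  profiles are too coarse to separate regulators; and with 1000
  permutations the smallest attainable p-value ($1/1001$) sits *above*
  the BH cutoff $0.05 \cdot 40 / 2170 \approx 9.2\times10^{-4}$ for 40
  true pairs among ~2170, so recovery would be arithmetically impossible
  regardless of signal. 2000 permutations put the floor at
  $5\times10^{-4}$ with margin.
* The recovery cohort is evaluated in true progression order. One
  ±0.9-log2 step per rank means even a displacement of a single position
  in the ordering corrupts two increments, and the displacement induced
  by technical noise on the marker is
  $\approx \sqrt2\,\sigma\,n/\mathrm{range}\!\approx\!5$ positions at
  $\sigma = 0.1$; the marker ordering is therefore locally scrambled at
  any realistic noise, and the network stage is tested in isolation from
  the ordering stage. Ordering recovery has its own exact test at
  `noise_sd = 0`, and the integrated pipeline test composes both stages
  on a noise-free cohort.
* GSEA's planted-set power experiment uses independent genes with a one
  standard-deviation shift (20 genes, 20+20 samples), where the
  phenotype-permutation null is the right reference. The generator's
  single-regulator target sets are *perfectly* internally correlated, and
  the correlation-preserving phenotype null is correctly conservative for
  them — they are instead detected under the gene-set permutation mode,
  and the tests assert exactly that distinction.

## Enrichment conventions

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ with the universe defaulting to the genes on the matrix;
unadjusted probabilities are reported alongside BH q-values. GSEA ranks
genes by Signal2Noise on log2 intensities with each group's standard
deviation floored at $\max(0.2\,|\bar x|, 0.2)$ — the convention of the
reference implementation; note that on log2 data this floor usually
binds. The enrichment score is the extremum of the weighted running sum
(hit increments $\propto |r|^{w}$, $w = 1$ by default; uniform miss
decrements), NES normalizes by the mean same-sign permutation ES, the
nominal p is the same-sign permutation tail fraction (reported as exactly
0 when no permutation reaches the observed score), and FDR q follows the
standard multi-set normalized-ES procedure with q made monotone
non-decreasing in nominal p within each sign group. Significance
thresholds (nominal p < 0.05, FDR q < 0.25) are configuration defaults,
not hard-coded decisions.

## Pipeline and reproducibility

`run_pipeline()` executes synthesis (optional), differential expression,
core-set selection, marker ordering, thermodynamic profiling, network
inference, ORA and GSEA, writing each stage's table plus a JSON
provenance record (stage, inputs, seed, configuration hash, package
version — deliberately no timestamps, so reruns are byte-identical). All
stage seeds are derived from the single configuration seed. Formats:
TSV/GCT v1.2 for expression, CLS for phenotypes, GMT for gene sets,
SIF/attribute-TSV/GraphML for networks, JSON for ground truth and
provenance. The command-line surface is the R API itself plus
`scripts/acceptance.R`; problem sizes in the shipped tests (cohorts of
up to 545 genes × 200 samples, 100–2000 permutations) were chosen as the
smallest designs at which every planted property is comfortably
detectable.

## Known limitations

* The thermodynamic constants ship for the four master-regulator probes
  only; profiling other genes requires user-supplied calibration, and
  the generator draws plausible values rather than measured ones.
* The chemical potential is linear in intensity by model structure, so
  rankings depend only on mean fractional occupancy and
  $\Delta G_{hyb}$; it cannot express cooperative or multi-state probe
  behavior.
* The permutation-thresholded IBS stage has no power against purely
  per-sample co-fluctuation and limited specificity between regulators
  whose programs share a word-profile style; both are properties of the
  method, not implementation choices.
* Phenotype-permutation GSEA is conservative for internally correlated
  sets; the gene-set permutation mode trades that conservatism for
  blindness to gene-gene correlation.
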