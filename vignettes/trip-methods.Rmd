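---
title: "Models and methods behind the trip pipeline"
author: "trip package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the trip pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trip)
```

# The experiment being modeled

Time-resolved interactome profiling (TRIP) follows the de novo interactome
of a single secretory client protein — the bait — through its maturation.
Cells are pulse-labeled with a clickable methionine surrogate for one hour,
then chased; samples harvested at 0, 0.5, 1, 1.5, 2 and 3 h are enriched in
two stages (epitope-tag immunoprecipitation, then biotin–streptavidin
capture of the pulse-labeled cohort) and quantified together in a TMTpro
multiplex. Each (condition, replicate) contributes eight channels: six
chase timepoints, one *background* channel from cells never pulse-labeled
(minus-Hpg), and one *booster/carrier* channel — the immunoprecipitate
without the second enrichment — whose high peptide load drives
identification depth for the faint chase channels. Two such units fill a
16-plex.

The package implements the downstream statistics only: it starts from a
protein-by-channel intensity table and a channel design, and never touches
spectra.

# Interactor calling

Interactors are proteins enriched in the booster channels over the
background channels. The stage mirrors the established differential
enrichment workflow for affinity-purification TMT data:

1. **log2 transform** (optional pseudocount, default 0).
2. **Per-channel median alignment.** Each channel's observed median is
   brought to the grand median. This removes loading and labeling offsets,
   including the deliberate bulk offset of the booster channel, because the
   large majority of quantified proteins are background binders. We use
   median alignment rather than a variance-stabilizing fit because it is
   deterministic, dependency-free and auditable at protein level; the
   choice matters little after log transformation of protein-level TMT
   intensities.
3. **Left-censored imputation.** TMT missingness at protein level is
   dominated by intensities below the detection limit (missing not at
   random), so missing cells in channel $c$ are drawn from
   $\mathcal N(\mu_c - 1.8\,\sigma_c,\ (0.3\,\sigma_c)^2)$, the
   proteomics-community down-shift convention, with $\mu_c,\sigma_c$ the
   observed channel moments. Shift, width and the seed are configuration
   values; the draw is deterministic given the seed.
4. **Moderated test.** For each protein, $\log_2\!FC$ is the booster-mean
   minus background-mean (replicates pooled across conditions). The pooled
   variance $s^2$ on $df = n_1+n_2-2$ degrees of freedom is shrunk toward
   an empirical-Bayes prior,
   $\tilde s^2 = (d_0 s_0^2 + df\, s^2)/(d_0 + df)$, and
   $t = \log_2\!FC / (\tilde s\sqrt{1/n_1+1/n_2})$ is referred to a
   $t_{d_0+df}$ distribution (standard normal when $d_0=\infty$). The prior
   $(s_0^2, d_0)$ is fit by moment matching on $\log s^2$, inverting the
   trigamma function by Newton iteration. With $d_0=0$ the statistic is
   exactly the ordinary pooled two-sample t; with $d_0=\infty$ all proteins
   share $s_0^2$. If the moment solution finds no excess dispersion the
   prior is degenerate ($d_0=\infty$, $s_0^2$ = mean variance); the same
   fallback covers noise-free synthetic data whose sample variances are all
   zero.
5. **Calling.** BH-adjusted p-values (`stats::p.adjust`) and a fold-change
   cutoff of $2\sigma$, where $\sigma$ is the normal-consistent MAD
   ($1.4826\cdot\mathrm{MAD}$) of all tested log2 fold changes. The MAD is
   used because the fold-change distribution carries a true-interactor
   right tail that would inflate a plain SD; the SD variant remains a
   configuration option. Enrichment is one-sided: depletion is reported but
   never flagged, since the biology of the comparison is enrichment over a
   no-label background. Both thresholds and the realized $\sigma$ are
   recorded in run metadata.

Proteins observed in fewer than two channels per group are flagged and not
tested. Proteins quantified in the booster but absent from the background
are imputed like any others rather than auto-called, avoiding
presence/absence artifacts.

# Temporal profiles

Chase-channel intensities are divided by the bait's intensity in the same
channel. This cancels per-channel gains exactly and accounts for the decay
of the labeled bait cohort to secretion and degradation, so ratios read as
engagement per unit bait. Replicates whose bait is unquantified in any
chase/background channel, or whose bait CV across chase channels exceeds a
threshold (default 0.5), are excluded from all downstream averaging — the
operational form of dropping replicates with inconsistent bait recovery.

Per replicate, enrichment is $\log_2(\text{chase}_t/\text{background})$
against the replicate's own background channel (a condition-average
reference is available as an option; replicate-matched is the default
because it keeps replicates statistically independent). Missing or
non-positive values propagate as missing, never as infinities.

Scaling follows the averaging-first convention: replicate means per
timepoint, negatives clamped to zero (enrichment below background), then
division by the maximum positive value in the protein's *scaling group* so
the maximum maps to exactly 1. The default group is the protein across
*all* conditions jointly, so that a mutant whose peak engagement is half
the wild-type's peaks at 0.5, not 1 — the convention that makes
cross-construct heatmaps comparable on one color scale; per-condition
scaling is a configuration option. SEM of the replicate means is divided
by the same factor so ribbon widths stay on the scaled axis. A profile
with no positive mean is all-zero with an absent scale factor; a timepoint
missing in every replicate stays missing rather than being zero-filled.

Pathway aggregates are the median and first/third quartiles of member
scaled values per (pathway, condition, timepoint); quartiles use the
linear-interpolation (type 7) convention, recorded in metadata because
several conventions exist. Per-profile features are the peak time
(earliest timepoint attaining the maximum), onset time (first timepoint at
scaled ≥ 0.5), and trapezoidal area under the scaled profile.

# Clustering

Scaled profiles (or the concatenation of a condition pair, for combined
series) are clustered by Lloyd's k-means on Euclidean distance —
appropriate here because scaling has already removed amplitude, making
correlation distance largely redundant (it remains an option). The
implementation runs `stats::kmeans(algorithm = "Lloyd")` from centers
sampled among the distinct profiles, 20 restarts by default, keeping the
lowest within-cluster sum of squares; a restart whose initial centers
collapse a cluster is redrawn. Results are deterministic given the seed.
Cluster labels are canonicalized by centroid peak time (cluster 1 peaks
earliest) so labels are comparable across conditions and runs.

Because no principled k is dictated by the experiment, `choose_k` scans
k = 2..8 and selects the maximum mean silhouette width, returning the full
diagnostic table so the user can override; a best silhouette below 0.3 is
reported as weak structure. Cross-condition membership shifts are
summarized by `cluster_flow` as a contingency table over shared proteins
(the Sankey table); marginals conserve the shared-protein count exactly.

# Screen analysis

96-well siRNA screens with lysate and media luminescence readouts carry
four control types per plate: non-targeting siRNA, a fluorescent
transfection control (siGLO), a vehicle control, and a lethal TOX control.
Each plate is divided by the median of its *test* wells — controls are
excluded from the median so the near-zero TOX wells cannot drag it — which
makes normalization exactly invariant to per-plate gain and idempotent.
Per (gene, construct, readout), normalized values are averaged over
replicate plates; the stratum center is the median of per-gene means and
$\sigma$ their normal-consistent MAD (plain SD optional); hits are genes
with $|(\bar x - \text{center})/\sigma| \ge 3$, directions by sign. The
center is the median rather than exactly 1 so residual plate drift does
not bias calls.

A calibration subtlety worth knowing: with $\sigma$ *estimated* from the
same 167 gene means it standardizes, the expected number of $3\sigma$
exceedances is about 1.4 times the known-$\sigma$ Gaussian value
$167\cdot 2\Phi(-3)\approx 0.45$ per stratum — MAD estimation noise
(relative SE ≈ 9% at n = 167) combines with the convexity of the normal
tail, before any noise skew. Simulated null screens in this package
therefore average ~0.6–0.8 hits per stratum, not 0.45; this is a property
of the estimator, not an implementation defect, and it is visible in the
package's own acceptance report (`screen_null_mean_hits`).

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every statistical guarantee above is verified.

* **Bait kinetics.** The labeled cohort decays as
  $B(t) = e^{-(k_s+k_d)t}$ with first-order secretion and degradation
  partitioned proportionally to the rates. The wild-type-like default sets
  $k_s = -\ln(0.3)/4 \approx 0.30\,h^{-1}$, $k_d = 0.01\,h^{-1}$, i.e.
  ~69% secreted by 4 h; the mutant-like default ($k_s = 0.004$,
  $k_d = 0.042\,h^{-1}$) is nearly secretion-dead (~2% of wild type) with
  ~15% degraded over 4 h — the regime of a retained, slowly degraded
  misfolded client.
* **Engagement.** Interactor engagement is the simplest form that
  produces the observed early/intermediate/late/constitutive peak classes:
  a two-exponential wave
  $E(t) = A\,(e^{-k_{off}t}-e^{-k_{on}t})/\max$, peaking at
  $\ln(k_{on}/k_{off})/(k_{on}-k_{off})$ with amplitude $A$, or a constant
  for the flat class. This is a test harness, not a mechanistic chaperone
  cycle. Default classes peak near 0.3, 1.1 and 2.6 h; amplitudes span
  0.4–1.
* **Channels.** Chase intensity for interactor $i$ is
  $\text{floor}\cdot(1 + 30\,B(t)E_i(t))$; the background channel sits at
  the floor; the booster carries every interactor at an amplitude-weighted
  offset with the whole channel scaled 10×. All rows, bait included, are
  multiplied by a per-channel lognormal gain (SD 0.1) — the quantity bait
  normalization must cancel — and per-cell lognormal noise (SD 0.25 on the
  natural log, a realistic protein-level TMT CV). The bait row itself is
  constant before gains, which is what makes the noise-free mean
  enrichment exactly $\log_2(1 + 30\,B(t)E(t))$, the closed form the
  round-trip tests assert.
* **Censoring.** Intensities below the global 20% quantile are set
  missing — the detection-limit (MNAR) mechanism that motivates the
  left-shifted imputation. Because the booster channel is 10× brighter
  than the background channel, censoring is asymmetric between the two
  groups; imputation then pushes background values down, which inflates
  weak positive fold changes. This is a real property of booster-based
  designs, it is why the 2σ fold-change cutoff exists, and it sets the
  small false-call tail visible in the worked example.
* **Determinism.** One RNG stream per dataset: channel gains first, then
  the noise matrix protein by protein, so enlarging the roster appends
  draws without reshuffling earlier proteins. Same seed, byte-identical
  output.

The screen generator mirrors the screen design: 167 genes over two
96-well plates per replicate (86 test wells plus 4/2/2/2 control wells),
two replicate experiments for two constructs and three for the third,
per-plate lognormal gain (SD 0.3), per-well lognormal noise (SD 0.1), TOX
wells at 1% of signal, and planted multiplicative effects for designated
(gene, construct, readout) triples.

## What the simulations do and do not show

The generator reproduces the statistical structure the pipeline's
guarantees depend on — channel roles, replicate design, multiplicative
noise, intensity-dependent missingness, bait decay — but not everything in
real data: no reporter-ion ratio compression (an optional attenuation
factor exists but is unvalidated), no peptide-level variation or protein
inference, no cross-plex batch effects beyond channel gains, no
cell-to-cell stochasticity, and no correlated co-complex structure among
interactors. Passing tests therefore demonstrate correctness of the
statistics under a faithful abstraction of the design, not performance on
any particular real dataset.

# Numerical conventions and edge cases

* Missing tokens accepted on input: empty, `NA`, `NaN`, `N/A`
  (case-insensitive); any other non-numeric cell is an error with row and
  column coordinates. Missingness is explicit, never zero-coded.
* The chase grid is declared (default 0, 0.5, 1, 1.5, 2, 3 h), not
  inferred; off-grid timepoints fail fast to prevent silent misjoins.
* Numeric table output uses 17 significant digits, so write→read round
  trips are exact at double precision; determinism tests compare file
  bytes, not parsed values.
* Peak ties break to the earliest timepoint. Quartiles are type 7. The
  k-means assignment tie-break (equidistant centroids) is the lowest
  cluster index, inherited from `stats::kmeans`.
* "Peak-time recovery within one grid step" in the test suite means
  adjacent grid *index* — the grid is non-uniform (the last step is 1 h) —
  and is evaluated for classes that have a planted peak; a flat
  interactor's argmax under noise is not a recoverable quantity.
* In noise-free data the bait is "called" as its own interactor (any
  nonzero fold change at zero variance is infinitely significant);
  round-trip comparisons exclude the bait row.
* The test suite runs the simulator at 100–500 background proteins and
  20–50 seeds per property; these sizes make the suite complete in well
  under a minute while keeping binomial slack on every calibration bound.

# Known limitations

* The booster/background censoring asymmetry described above biases weak
  fold changes upward at high censoring rates; the robust 2σ cutoff
  controls but does not eliminate it.
* Bait normalization requires the bait quantified in every chase and
  background channel of a replicate; such replicates are excluded rather
  than imputed, which is conservative.
* The moderated test pools replicates across conditions for the
  booster-vs-background contrast; per-plex or per-condition calling would
  need a multi-contrast linear model, which is out of scope.
* No kinetic model is fit to profiles (on/off rates are simulator inputs,
  not estimands), and no spatial/B-score polish is applied to screen
  plates beyond median normalization.
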