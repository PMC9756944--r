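---
title: "Models and methods behind hyphachrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hyphachrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hyphachrom` quantifies how a nucleoid-associated protein (an HU-family
protein, HupA) and topoisomerase I (TopA) shape chromosome behaviour in
*Streptomyces coelicolor*: how much of the protein is DNA-bound (from
single-molecule PALM tracking), how chromosomal *oriC*/ParB foci are
positioned and duplicated in growing hyphae (from time-lapse imaging), where
the protein binds on the chromosome (from windowed differential ChIP), and
how mutants grow (from OD curves). Every analysis stage is paired with a
synthetic-data generator whose ground truth makes the stage testable end to
end. This vignette records the models, the parameters that matter, and the
design choices that were genuinely open.

# Single-molecule diffusion analysis

## Track linking

Localizations are linked frame to frame when they fall within a
`link_radius` of 0.6 µm in consecutive 30 ms frames, with one missing frame
tolerated (gap closing at the same radius); these are the acquisition-rule
defaults of `tracking_config()`. Assignment is greedy in order of ascending
distance. A greedy matcher is what mainstream particle trackers effectively
do at PALM densities, and it is fast and order-stable; it is *not*
guaranteed to minimise the total displacement. Rather than silently assume
the two coincide, the test suite compares greedy against an exhaustive
minimum-total-distance matching: on well-separated instances (spacing well
above the frame-to-frame displacement, the regime the 0.6 µm radius is
designed for) they agree exactly, and on dense unconstrained instances the
measured disagreement rate is reported in the test rather than hidden.
The gap-closing radius reuses `link_radius`: there is a single spatial
scale in the problem, and a separate knob would be unidentifiable anyway.

## The diffusion mixture

For 2D Brownian motion with diffusion coefficient $D$ observed at interval
$\Delta t$ with localization error $\sigma$, the squared one-frame
displacement $r^2$ is exponentially distributed with mean
$4D\Delta t + 4\sigma^2$. A population switching between a DNA-bound
(slow) and a free (fast) state therefore produces a two-component
*exponential* mixture on the pooled lag-1 $r^2$ — this is the
likelihood-exact object to fit, and `fit_diffusion_mixture()` fits it by EM
(10 restarts, best log-likelihood kept; the likelihood trace is
non-decreasing by construction and asserted in tests). Components are
reported as apparent coefficients $D_k = (m_k - 4\sigma^2)/(4\Delta t)$,
clipped at zero, in ascending order. Steps spanning a closed gap have a
doubled time base and are excluded from the fit by default.

The upstream software used in the original experiments describes its fit
only as "a Gaussian mixture model" without naming the fitted variable. We
chose the exponential mixture because it is the exact sampling model; a
per-track MSD-based coefficient with a Gaussian mixture (via mclust) is
provided as `method = "msd_gmm"` and used as a cross-check in the tests,
not as the primary estimator. Two summary conventions are computed because
the field is ambiguous about both: `mean_D_app` (weight-averaged over
components, the default) and `mean_D_track` (averaged over per-track MSD
coefficients), and the mixture weights are step-weighted while
`classify_mobility()` gives track-weighted fractions.

## Mobility classes

Following the 90 ms confinement convention (3 steps of 30 ms), each step is
labelled by its maximum-posterior state and a track with at least
`window_steps = 3` steps is *confined* if every sliding 3-step window is
entirely slow, *free* if entirely fast, and *mixed* otherwise; shorter
tracks are unclassifiable.

A caveat that the synthetic benchmarks make explicit: with the bound and
free coefficients at 0.015 and 0.400 µm²/s the two exponentials overlap
enough that a fast step falls below the posterior boundary with probability
about 0.16. Per-step labelling therefore leaks fast steps into the slow
state, so the *free* fraction is systematically under-counted (a 3-step
free track survives unscathed only $0.84^3 \approx 0.6$ of the time), while
the *confined* fraction — whose per-step leak rate is about 0.01 — is a
calibrated readout. The validation accordingly asserts recovery of the
confined fraction (within ±0.05 of the ground-truth track composition) and
reports free/mixed without asserting them. The validation run uses rapid
photobleaching (0.4 per frame, realistic for PAmCherry, giving mostly
3–5-step tracks) because the all-steps-slow rule attrits long tracks;
this choice follows from the closed-form leak rates above and was fixed
before the benchmark was run.

## The PALM simulator

`simulate_spt()` draws per-molecule two-state Markov chains, Brownian
displacements using the state at the source frame, reflecting boundaries,
i.i.d. Gaussian localization error per coordinate (the standard PALM noise
model), single-frame blinking dropouts and geometric photobleaching.
Because a literally symmetric switch probability would force a stationary
slow fraction of 0.5, the single rate knob is split as
$P(\text{slow}\to\text{fast}) = s(1 - f_{slow})$ and
$P(\text{fast}\to\text{slow}) = s\,f_{slow}$, making the stationary
occupancy exactly `f_slow` while keeping one overall kinetic parameter
(`switch_prob`); the underlying study reports no switching kinetics, so
this parameter is a free modelling choice, not an estimate. With
`stagger = TRUE` activation times are uniform over the movie, giving
realistic PALM densities (tens of concurrent emitters) so that the full
link-then-fit pipeline can be validated; the diffusion-recovery benchmark
uses 8000 molecules over 3000 frames in a 30 × 30 µm field, about 70 000
usable steps, and recovers both coefficients within a few percent.

# Hyphal focus quantification

## Peak detection

The published analysis used unpublished custom peak-finding protocols, so
`detect_foci()` implements a fully specified standard stand-in: an
iterative-clipping (SNIP-style) background over a 2 µm window, Gaussian
smoothing at 0.08 µm (kept below the 0.15 µm optical peak width so peak
height is attenuated by only ~12 %), a detection threshold of 5 robust
noise SDs (1.4826 × MAD of first differences / √2), non-maximum
suppression within `min_separation` = 0.5 µm keeping the higher peak, and
3-point parabolic sub-pixel interpolation. At the simulated
signal-to-noise of 10 the benchmark (100 hyphae) achieves recall ≥ 0.95
with a false-positive rate ≤ 0.05; on flat noise the 5σ threshold yields
zero detections in over 99 % of trials.

## Distance metrics and duplication events

All positions are expressed as distances from the current hyphal tip — the
tip-anchored frame in which the biological measurements are defined
(tip-proximal complex distance, its drift after anchorage loss, distances
between complexes). "Distances between all complexes" is interpreted as
*adjacent* (nearest-neighbour) spacings by default, since the reported
medians (~1.2–1.6 µm) match chain spacing rather than all-pairs distances;
`interfocus_distances(mode = "all_pairs")` retains the alternative.
`track_foci()` links foci across frames by along-axis nearest neighbour
(ties broken towards the tip), declares a duplication when a trajectory
splits into two sisters that each persist at least 2 frames, and reports
sister separations and both sisters' tip distances on the 10-min grid for
90 min after the split, with column means as the average-position trend.
Detected duplications necessarily begin at the resolution limit: two
sisters closer than `min_separation` are one detected focus, so the
detected event clock starts one or two frames after the true split. The
ground-truth-driven tests therefore validate the tracker's separation
series against the generator schedule using noise-free focus tables, and
the detection benchmark disables duplication so that every truth focus
satisfies the well-separated operating condition.

## Phenotype rules

`classify_phenotype()` encodes the time-lapse scoring rules on the 10-min
grid, boundary-exact: a spore with no hypha over the whole 960-min
observation is *nongerminating*; a germling whose extension pauses
strictly longer than 60 min (after the first extension; the dormant period
before emergence does not count) is *inhibited*; a branch whose final
pause lasts at least 120 min with no re-initiation before the end of the
record is a *stalled branch*. Movement of at most `extension_epsilon` =
0.2 µm per frame is not counted as extension (sub-pixel jitter; the
original protocol does not state a value). Records not reaching the end
of the observation window are explicitly `"unclassifiable"` rather than
silently classified. `stall_growth_comparison()` reproduces the paired
protocol behind the stalled-vs-growing contrasts: stalled hyphae measured
one frame (10 min) before arrest, each paired with a growing hypha at its
closest-length frame.

## The hyphal simulator

`simulate_hyphae()` models hyphae as 1D axes (the real measurements are
along-axis distances; no 2D imagery is synthesised). Defaults are the
control-strain conditions: 10-min frames, extension 0.35 µm/frame (about
2 µm/h), a tip-proximal focus at 1.85 µm, chain spacing 1.55 µm,
duplication with a sister separation growing linearly to 1.75 µm over
60 min and then relaxing to the chain spacing by 90 min (the observed
separation curve saturates near 60 min), optional anchorage-loss drift of
0.1 µm per 10 min (the TopA-depletion condition), stochastic permanent
stalls and branches that acquire their first focus about 30 min (default)
after emerging. Branch arrival times are snapped to the acquisition grid
by ceiling — a focus arriving at 32 min is first *seen* at 40 min — so
the observed median can sit one frame above the configured delay; this is
a property of any gridded observation, not of the estimator. Profiles are
Gaussian peaks (σ 0.15 µm, amplitude 80 a.u.) on a gently sloped baseline
with additive noise (σ 8 a.u., i.e. SNR 10). The generator does not
emulate lysis, fluorophore maturation, out-of-focus drift or uneven
illumination, so passing tests say nothing about those failure modes in
real data.

# Sliding-window differential binding

## The procedure

The analysis follows the published window pipeline, re-implemented from
scratch: 69-bp windows every 23 bp (every internal base in exactly 3
windows; the final window of a contig is truncated), fragment counts by
≥1-bp overlap, a *local filter* retaining windows whose mean ChIP count
exceeds the surrounding 2000 bp background — rescaled to window width with
the window's own counts excluded — by log2 fold change > 2 with a 0.5
pseudocount, a common negative-binomial dispersion estimated on the
retained windows by Cox–Reid adjusted profile likelihood, a per-window NB
GLM with log library-size offsets testing the condition coefficient,
transitive merging of windows strictly closer than 100 bp, Simes
combination of member p-values per region, and Benjamini–Hochberg FDR at
0.05 across regions. Region AT content is `(A+T)/(A+C+G+T)`,
case-insensitive, ambiguous bases excluded.

Open points resolved as design choices: the filter compares a window to
its own neighbourhood (not to an input library), evaluated on the average
across all ChIP samples; normalisation uses observed total fragment counts
as offsets (the published coverage was likewise total-read-normalised; no
TMM); counting is per fragment, unstranded. The primary test is the
likelihood ratio against $\chi^2_1$; the published "quasi-likelihood"
F-test involves per-window dispersion shrinkage that is deliberately not
re-implemented — a simplified global-QL F variant is available as
`test = "qlf"`, and the LRT's validity is established by type-I
calibration instead: on null data the per-window rejection rate at 0.05
is ~0.05 and the end-to-end pipeline returns zero significant regions in
≥ 90 % of runs. The from-scratch dispersion estimator and GLM agree with
edgeR's `estimateGLMCommonDisp`/`glmFit`/`glmLRT` to within 5 % on the
dispersion and to ~1e-10 on p-values at a shared dispersion; edgeR serves
only as a test oracle, never as the implementation.

One bias is worth knowing about: because a fragment of length $L$
contributes to every window it touches, a window's expected count scales
with $w + L$ while the rescaled background scales with $w$, so the null
local log2 fold change sits near $\log_2((w+L)/w)$ (about 1.7 at the
defaults) rather than 0. The >2 threshold is applied to the statistic as
defined by the published procedure; the calibration tests demonstrate the
pipeline's end-to-end behaviour with this bias included.

## The ChIP simulator

`simulate_chip()` writes a GC-rich genome (72 % GC, the *S. coelicolor*
value) with AT-boosted binding sites (+0.2 AT inside sites, mirroring the
protein's AT preference), and per-sample fragment sets in a replicated
two-condition design. Overdispersion is generated as a per-sample gamma
multiplicative field, i.i.d. per 1000-bp block, with enriched sites
drawing their extra fragments under a per-site gamma factor: Poisson
thinning preserves the gamma-Poisson (negative binomial) dispersion, so
counts in analysis-scale windows are NB with the configured `dispersion`.
The obvious simpler construction — drawing an NB total per sample and
placing fragments uniformly — puts the entire excess variance into a
library-size factor that observed-total offsets absorb, leaving no
window-level overdispersion at all; the block-gamma field is the simplest
generator whose window counts actually follow the assumed model. The
power benchmark uses 20 sites of 100 bp at 8-fold enrichment in one
condition (3+3 replicates, dispersion 0.1, ~30 background fragments per
window), where the filter margin and the GLM give ≥ 90 % site recovery
with false discoveries consistent with the nominal FDR; the null
benchmark uses a 2-Mb site-free genome with 2000 test windows spaced one
block apart.

# Growth statistics

`fit_log_logistic()` fits the three-parameter log-logistic
$\mathrm{OD}(t) = d / (1 + \exp\{b(\log t - \log e)\})$ by
Levenberg–Marquardt with multi-start initialisation ($b_0 \in \{\pm 1,
\pm 5, \pm 10\}$, $d_0$ = max OD, $e_0$ = time nearest half-max) and
Jacobian-based standard errors; the lower asymptote is fixed at zero (no
variant is named in the source analyses, and OD curves start near blank;
first-timepoint blank subtraction is available as preprocessing). The
drc-style sign convention is kept, so the reported negative slopes
correspond to increasing curves, and $e$ is the ED50 — the time of
half-maximal absorbance ($\mathrm{OD}(e) = d/2$ identically). Over 200
simulated replicate experiments at the realistic noise level (σ = 0.02
OD, 5 replicates, 20-min sampling) the ED50 bias is below 0.1 % and the
±2 SE interval covers the truth ~95 % of the time. The rank-sum test
wraps `stats::wilcox.test` (exact for small untied samples, mid-ranks and
continuity correction otherwise — the source figures do not state a tie
policy), used unpaired because the compared groups are different strains.
`ddct()` implements the comparative ΔΔCt formula with relative level
$2^{-\Delta\Delta C_t}$.

# Reproducibility plumbing

All artifacts are plain text (TSV/CSV with JSON sidecar schemas, BED6,
FASTA, JSON); `run_pipeline()` executes the stages in dependency order on
one master seed (stage seeds derived deterministically, the analysis-stage
RNG pinned and restored), writes a manifest with MD5 content hashes, and
two runs with the same configuration are bit-identical. A failure in a
later stage — e.g. a malformed fragment BED, reported with its line
number — leaves earlier stage outputs intact. `run_config()` rejects
unknown keys and accepts YAML overrides; the exported functions plus
`run_pipeline()` are the package's interface (no shell front-end is
shipped).

# Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so each benchmark has comfortable statistical margin: ~70 000
linked steps per diffusion fit (5 seeds), 20 000 short tracks for the
mobility benchmark, 100 hyphae for detection, twenty 2-Mb null ChIP
datasets and one 0.5-Mb 20-site power dataset, and 200 growth-curve
replicate experiments. The headline numbers these runs produce (bound
and free coefficients, immobile and confined fractions, inter-focus and
sister-separation distances, drift slope, branch colonisation delay,
null calibration, site recovery, ED50 and slope) are exactly what the
acceptance script re-computes and writes.

# Known limitations

Linking is greedy, not globally optimal, and no drift correction or 3D
tracking is attempted; state-lifetime (HMM) inference is out of scope.
Focus detection assumes already-traced 1D profiles; 2D segmentation,
deconvolution and replisome colocalisation are not implemented. The ChIP
module starts from aligned fragment intervals (no alignment, no
MACS-style broad peaks, no input-subtraction model, no TMM). The growth
module fits one fixed model; model selection across growth laws is out of
scope. The generators are deliberately minimal statistical emulations —
they establish that the estimators recover known truth under the assumed
models, not that the models capture every property of real micrographs or
libraries.
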