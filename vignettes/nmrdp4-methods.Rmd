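---
title: "Automated NMR processing and DP4 stereochemistry assignment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated NMR processing and DP4 stereochemistry assignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdp4)
```

## The problem

Relative stereochemistry of a small molecule can be assigned by comparing
DFT-calculated (GIAO) chemical shifts of every candidate diastereomer with
an experimental 1D NMR spectrum. The DP4 statistic turns the comparison
into a Bayesian probability: given per-atom shift-prediction errors
$e_{ij}$ for candidate $i$, a prediction-error density $p(\cdot)$ and a
flat prior over candidates (one of them is assumed correct),

$$
P(\text{candidate } i \mid \text{data}) =
  \frac{\prod_j p(e_{ij})}{\sum_k \prod_j p(e_{kj})} .
$$

The practical bottleneck is everything before that formula: raw
time-domain data must be transformed, phased, baseline-corrected, peak
picked and integrated, and the calculated shifts must be matched to the
experimental peaks without human intervention. `nmrdp4` implements this
workflow end to end for 1D ^1^H and ^13^C spectra, together with a
synthetic-data generator that makes every stage testable against known
ground truth.

## Processing model

**Transform.** Raw FIDs (Bruker-style directories or JCAMP-DX) are
exponentially apodized (defaults 0.3 Hz for ^1^H, 1.0 Hz for ^13^C - a
conventional resolution/sensitivity compromise; both configurable),
zero-filled to twice the next power of two, and Fourier transformed with
the conventional half-weighting of the first time-domain point. The ppm
axis is stored in descending order (the display convention); first-order
phase is defined as linear in the fractional position across that
displayed axis, zero at the first (high-ppm) point - conventions differ
between packages, so this one is fixed and documented here.

**Noise and signal classification.** The noise standard deviation is a
robust estimate over noise-classified points of the real part after a
running-median detrend (window 129 points); the detrend makes the
estimate insensitive to baseline drift. Signal regions are contiguous
runs where the absolute real part exceeds 4 noise standard deviations,
merged across gaps of 0.02 ppm (^1^H) / 0.2 ppm (^13^C). The real part is
used rather than the complex magnitude because dispersion wings in the
imaginary channel decay only as the inverse offset and would lift a
magnitude trace above any usefully low threshold over much of the
spectrum.

**Phasing.** The corrector is staged. Stage 1 classifies the magnitude
trace into per-multiplet regions (threshold runs merged across 25 Hz so
whole multiplets stay together) and estimates one scalar phase per
region from the second moment of its linearly detrended complex trace:
for a symmetric multiplet in a symmetric window,
$\sum_k z_k^2 = e^{2i\varphi}\,(\text{positive real})$, so
$\varphi = \tfrac12\arg\sum z^2$ up to $\pi$, resolved by the sign of the
rotated real sum. Stage 2 regresses the region phases on fractional
frequency position (weights = region peak heights, residuals beyond 3
median absolute deviations rejected), giving $(\varphi_0, \varphi_1)$;
the two stages are iterated three times. Stage 3 refines globally by
variable projection: line positions and widths are read off the spectrum
(subpixel maxima, half-width estimates, then inverse-quadratic refits of
the real part), real line amplitudes are solved by linear least squares
against the exact discrete lineshape (the DTFT of a sampled damped
sinusoid), and $(\varphi_0, \varphi_1)$ minimize the projected residual
by Nelder-Mead. A final polish minimizes the derivative-entropy (ACME)
objective - the entropy of the normalized absolute first derivative of
the real part plus a quadratic penalty on negative intensity - inside a
0.5-degree trust region, and is accepted only if the entropy does not
increase. The model-based refinement is used for accuracy because the
entropy surface alone is nearly flat along the trade-off direction
between $\varphi_0$ and $\varphi_1$ when signals occupy only part of the
sweep; the entropy stage is retained as a safeguarded final criterion.

**Baseline.** A smoothing spline through the points outside
(drift-robustly classified) signal regions is subtracted from the real
part. Knot flexibility defaults to 2.5 degrees of freedom per thousand
noise points.

**^1^H peak picking and deconvolution.** Candidate peaks are local maxima
of the Savitzky-Golay-smoothed real part that coincide with
second-derivative minima; they are kept if the height exceeds 3 noise
standard deviations and the second derivative is below minus one robust
standard deviation of the second-derivative trace (both multiples
configurable and deliberately low - spurious picks are removed later).
Peaks closer than 18 Hz (the largest scalar coupling expected between
protons, applied field-aware in Hz) are grouped into multiplets. Each
group is deconvolved with one generalized Lorentzian per peak - a
Lorentzian-Gaussian mixture sharing one full width at half maximum, with
the mixing free in $[0,1]$ - by Levenberg-Marquardt least squares,
iterating (with a component added at the largest residual) until the
model integral matches the region integral within 1%.

**Noise pruning by BIC.** Each fitted component is removed in turn and
the reduced model refitted; if the removal lowers the Bayesian
Information Criterion (Gaussian residual likelihood, 4 parameters per
component) by more than 10, the component is deleted. The criterion is
evaluated over a window of at least 512 points around the region: on a
window barely wider than the multiplet the parameter penalty
$4\log n$ is too small to reject a component that fits the largest local
noise excursion, so the window size - not the threshold - is what makes
the test sharp. Survivors are regrouped into the final multiplets.

**Solvent removal and referencing.** Candidate multiplets within
0.5 ppm of the expected residual-solvent position are scored by the
cosine similarity of their line-amplitude pattern to the expected
multiplet (1:2:3:2:1 quintets for methanol/DMSO, singlets for chloroform
and benzene), a line-count penalty, and a Gaussian distance term
(sd 0.2 ppm). The best-scoring multiplet is removed and the spectrum is
referenced so that it sits exactly at the solvent's reference shift.

**Integral normalization.** The total proton count $n$ is searched from
(protons $-$ labile protons) to twice the proton count of the candidate
structure; for each $n$ the model integrals are rescaled to sum to $n$
and scored by integer-likeness - the geometric mean of per-multiplet
terms $\max(1 - 2\,|x - \mathrm{round}(x)|, 0.01)$ - and the
best-scoring $n$ (ties to the smaller) fixes the constant. Multiplets
rounding to zero protons are dropped; labile protons are identified from
the structure file as hydrogens bonded to O, N or S.

**^13^C peak picking.** A greedy loop picks the maximum of the residual
(spectrum minus current model, lightly smoothed by a 3-point average so
single-point excursions do not dominate), fits a simple Lorentzian there
and adds it to the model, stopping when the residual maximum falls below
3 noise standard deviations; every 10 picks all parameters are refitted
jointly. Components whose fitted amplitude falls below the stop
threshold, or whose width is far below the resolution-limited width of
the strong peaks, are discarded afterwards - a pointwise 3-sigma stop
necessarily admits the occasional ~4-sigma correlated-noise excursion,
and such survivors are exactly what the amplitude weighting is designed
to down-weight.

**Amplitude weighting.** Peak amplitudes typically fall into groups -
noise, one-carbon signals, and degenerate signals. The density of peak
log-amplitudes is estimated with a Gaussian kernel (Sheather-Jones
bandwidth; the normal-reference rule oversmooths adjacent groups) and
group boundaries are placed at the density valleys (zero slope, positive
curvature). For each group the weight is the carbon count divided by the
number of peaks with amplitude above the group's lower boundary, then
all weights are normalized so the most intense group has weight one. On
the canonical 17-peak example (ten peaks near amplitude 1, five near 5,
two near 10, nine carbons) this yields weights $1$, $2/7$ and $2/17$.
The text description of the boundary rule in terms of second-derivative
minima is ambiguous - the minima of the second derivative of a
multimodal density coincide with its modes and would split each cluster
in half - so this package uses the reading that reproduces the published
worked grouping: boundaries at the valleys.

## Assignment model

The probability matrix $M_{ij}$ is the error-model density of
(scaled shift $i$ $-$ peak $j$); for ^13^C each element is multiplied by
the peak's amplitude weight $A_j$ and by a multiple-assignment penalty
$(1/(1+t_j))^{k_j}$, where $t_j$ counts how often peak $j$ has been
assigned already and $k_j$ is its amplitude-group rank (1 = most
intense). This closed form satisfies the published constraints (equal to
one at $t=0$, strictly decreasing in $t$, decreasing faster for less
intense groups); it is isolated in one function, as is the bias below,
so either can be swapped if a different functional form is preferred.
The most probable assignment maximizes $\prod M$, i.e. minimizes
$\sum -\log M$, solved by a Jonker-Volgenant shortest-augmenting-path
implementation of the Hungarian method (no installed R package provides
one); peak columns are replicated up to
$\lceil n_\text{shifts}/n_\text{peaks} \rceil + 1$ times with the
penalty applied per replication, so peaks may absorb several carbons.

Scaling is staged: literature ("external") factors first (shipped as
identity by default and user-overridable), then an internal linear
regression of calculated on assigned experimental shifts, applied and
re-derived once more after reassignment - the first regression can be
biased by systematic stage-1 misassignments, and the second pass makes
the procedure a fixed point on error-free linear data (a further pass
changes nothing). Regression guards: at least 3 pairs, one
outlier-rejection sweep at 3 median absolute deviations, and slopes
outside $[0.8, 1.2]$ fall back to the identity.

After the second ^13^C pass, each shift's bias is the summed amplitude
weight of unassigned peaks within 10 ppm of its assigned peak divided by
the assigned peak's weight; shifts with bias above one are reassigned in
bias order to the largest-amplitude unassigned peak in their window.
This rescues shifts stranded on nearby noise peaks when a more distant
intense signal peak went unassigned.

^1^H assignment uses no weights, penalties or bias: the integrals say
explicitly how many protons each multiplet can take. Methyl trios
(carbons with exactly three attached hydrogens in the structure file)
are assigned first - the trio's mean shift against multiplets with at
least three protons of remaining capacity, consuming capacity in units
of three - then the remaining non-labile protons are matched with each
multiplet's column replicated once per remaining proton of capacity.

**Error models and DP4.** The default per-nucleus error models are
single Gaussians with sd 2.3 ppm (^13^C) and 0.19 ppm (^1^H) -
conventional DP4 literature values; fitted Gaussian mixtures (any number
of components) slot into the same interface via `fit_error_model()`,
which delegates the EM fit to mclust and supports leave-one-group-out
refits for cross-validation. DP4 probabilities are computed in log space
(epsilon-floored at $10^{-300}$), with ^1^H and ^13^C log-likelihoods
added under the usual independence assumption.

## What the synthetic generator emulates

`simulate_fid()` builds FIDs as sums of damped complex sinusoids - one
line per multiplet component with binomial intensities (s/d/t/q/quintet
patterns), line integrals proportional to proton counts - and injects
zero/first-order phase error, polynomial baseline, a residual-solvent
multiplet and complex Gaussian noise in the frequency domain before
inverting to the time domain; `fourier_transform()` on the written
fixture reproduces the corrupted spectrum exactly. Candidate shift
tables come from `simulate_candidates()`: the true candidate is a linear
transform of the true shifts plus error-model draws, decoys are
additionally perturbed per atom.

What the generator deliberately does **not** emulate: strong coupling
(second-order multiplets, roofing), relaxation-driven lineshape
asymmetry, ^13^C satellites, solvent-dependent shift changes, and
spectra of mixtures. Passing recovery tests on these fixtures therefore
demonstrates the correctness of the processing and assignment machinery
under first-order conditions, not robustness to every distortion of real
spectra.

Default study conditions used by the validation metrics (all in
`R/metrics.R`): random ^1^H spectra carry 3-15 multiplets (4-10 for the
phasing study, whose identifiability degrades when only two or three
multiplets cluster in a narrow part of the sweep), minimum line
signal-to-noise 8-28, widths 1.2-2.0 Hz at 400 MHz, 8192 acquired
points over 4000 Hz; ^13^C spectra carry 10-40 carbons with about 10%
degenerate pairs, signal-to-noise 5-100 at 100.6 MHz, 16384 points over
20000 Hz. The mixture-recovery study draws 10000 errors from a
well-separated 3-Gaussian model (means $-5, 0, 5$ ppm) - component
means of heavily overlapping mixtures are not identifiable to 0.1 ppm at
this sample size, which is a property of the likelihood, not of the
fitter. End-to-end recovery processes each bundled fixture once and
draws fresh candidate sets (3 decoys, perturbation 5 error-model sds)
per replicate.

## Numerical choices and degenerate inputs

* Optimizer budgets: Levenberg-Marquardt fits cap at 40-60 iterations;
  Nelder-Mead phase refinement at 600 evaluations per round, four
  rounds. All fits are deterministic; every stochastic step takes an
  explicit seed.
* Ties in the Hungarian solver resolve by column order (ascending ppm
  within replications); equal-cost matchings are therefore stable across
  runs.
* Zero-probability rows (a shift impossibly far from every peak) are
  floored at $10^{-300}$ and flagged with a warning rather than dropped.
* A spectrum with no classified signal passes through phasing untouched
  with zero phase; single-multiplet integral normalization is degenerate
  and takes the smallest candidate total with a warning; internal
  scaling with fewer than three pairs is skipped with a warning.
* EM components collapsing to zero variance are floored at
  $10^{-3}$ ppm.

## Known limitations

* The phase corrector's first-order accuracy is limited by the frequency
  span of the signals; spectra whose peaks cluster in a narrow band can
  carry several degrees of first-order error even at high
  signal-to-noise (the per-line phase information has no leverage on the
  slope).
* The greedy ^13^C picker retains occasional ~4-sigma correlated-noise
  excursions by design; downstream weighting and the bias stage, not the
  picker, are responsible for making them harmless.
* J-coupling extraction, multiplicity analysis, 2D spectra and mixtures
  of compounds are out of scope; DP4+ (which adds an unscaled-shift
  term) and t-distributed error models are not implemented, though the
  error-model interface leaves room for them.

## A worked miniature

```{r example, eval = FALSE}
lib <- fixture_library()
sim <- simulate_fid(lib$h_clean_6)
sp  <- fourier_transform(sim$fid)
out <- process_proton(sp, total_protons = sum(lib$h_clean_6$multiplets$protons),
                      solvent = NULL)
multiplet_table(out$multiplets)
```

The full pipeline, including candidate assignment and the DP4 table, is
orchestrated by `run_pipeline()` on a validated `run_config()`; the
command-line front end in `inst/cli/nmrdp4.R` is a thin wrapper over the
same functions.
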