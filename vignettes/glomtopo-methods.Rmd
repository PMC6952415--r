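---
title: "From glomerular movies to tunotopic and chemotopic maps: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From glomerular movies to tunotopic and chemotopic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomtopo)
```

# The analysis in one paragraph

Odorant receptors converge onto glomeruli on the surface of the olfactory
bulb, so a functional imaging movie of the bulb under odour stimulation is
a mixture of spatially overlapping glomerular signals, a broad unspecific
component, and noise. `glomtopo` implements the full chain from such
movies to maps of functional organisation: preprocessing into a
frames-by-pixels measurement matrix, separation of glomeruli by
regularized non-negative matrix factorization (rNMF), extraction and
quality-filtering of per-odorant response spectra, structure–activity
models of a glomerulus's molecular receptive range (MRR) in
physico-chemical descriptor spaces, and two kinds of spatial statistics:
*tunotopy* (are glomeruli with correlated response spectra neighbours?)
and *chemotopy* (are glomeruli whose receptive ranges are close in
descriptor space neighbours?). A synthetic-data generator with planted
ground truth replaces animal experiments, so every stage is testable at
desk scale.

# Preprocessing

Intrinsic optical signal (IOS) recordings are binned 8×8 in space and 12
frames in time, converted to the relative reflectance decrease
$\Delta R/R = -(R - R_0)/R$ with $R_0$ the per-pixel mean over the first
2 s (strictly before odorant arrival at 2.5 s), bandpass filtered with a
difference of Gaussians ($\sigma_{low} = 10$ px, $\sigma_{high} = 1$ px)
and downsampled by 2. A 12-s, 5-Hz, 1024×1344 px recording therefore
becomes 5 frames of 64×84 px at 5/12 ≈ 0.42 Hz with a 19.4 µm pixel
pitch. Synapto-pHluorin (SpH) recordings instead use $F - F_0$, a mean
blank-recording time course subtracted per pixel (bleaching correction —
refused, not skipped, when no blanks exist), a 1.5-px Gaussian lowpass,
and factor-2 downsampling (128×128 → 64×64).

Design notes:

* **Stage order.** Binning precedes $\Delta R/R$ (the acquisition
  protocol's order); a `delta_r_first` flag allows the swapped order for
  sensitivity checks. Binning and $\Delta R/R$ commute only approximately,
  but at realistic signal scales the difference is far below noise.
* **Borders.** All Gaussian filters use reflective padding, so footprints
  near the crop boundary are not attenuated by zero-padding artefacts.
* **Bandpass behaviour.** A spatially constant frame maps exactly to
  zero. The closed-form peak response of a 2-D Gaussian blob of width $s$
  is $s^2/(s^2+1) - s^2/(s^2+100)$: a $\sigma = 30$ px blob is attenuated
  about 7.7-fold relative to a $\sigma = 2$ px blob (87%), which is what
  the tests freeze.
* **Response windows in seconds.** Responses are window means of the
  activation course, with frames selected by their *centre time*: IOS
  4.8–9.6 s (exactly post-binning frames 3–4 at 0.42 Hz) and SpH
  6.6–10.3 s. Selecting by seconds rather than frame index resolves an
  internal inconsistency between the SpH frame rate and recording length;
  at 0.94 Hz the window selects frames 7–10.

# Regularized NMF segmentation

The measurement matrix $Y \in \mathbb{R}^{F \times P}$ (frames × pixels)
is factorized into $K$ components, each a non-negative footprint $x_k$
("pixel participation") and an activation course $a_k$, by minimizing

$$\lVert Y - A X \rVert_F^2
  \;+\; \alpha_{sm} \sum_k \lVert a_k \rVert^2 \,\lVert \nabla x_k \rVert^2
  \;+\; \alpha_{sp} \sum_{j<k} \max\!\big(0, \cos(x_j, x_k)\big),$$

with $\nabla$ the first-difference spatial gradient on the pixel grid and
$\cos$ the cosine similarity between footprints. Defaults follow the
imaging protocol: $K = 150$, $\alpha_{sm} = 2$ for IOS; $K = 20$,
$\alpha_{sm} = 5$ for SpH (`default_configs()`); $\alpha_{sp}$ is tuned
by `tune_sparseness()` so that the maximal pairwise footprint correlation
is just below 0.5.

Design choices that were genuinely open:

* **Scale-invariant smoothness.** Any factorization is invariant under
  $(a_k/c,\; c\,x_k)$, so a penalty on $\lVert \nabla x_k \rVert^2$ alone
  can be evaded by shrinking footprints and growing activations.
  Weighting by the activation energy $\lVert a_k \rVert^2$ makes the
  penalty a function of the component's contribution at data scale and
  closes that loophole; without it, footprint recovery under noise
  collapses (matched correlations drop from ≈0.97 to ≈0.3 in our
  simulations).
* **Optimizer.** Alternating block updates: an exact (ridge)
  least-squares solve for the activations when they are unconstrained,
  projected-gradient steps with spectral-norm step sizes and backtracking
  otherwise. Every accepted step decreases the objective, so the recorded
  convergence log is monotone non-increasing *by construction* — a
  property multiplicative NMF updates do not guarantee once smoothness
  and overlap penalties are added. Convergence is declared at a relative
  objective change below `tol` (default 1e-6) within `max_iter` (default
  500); hitting the cap raises a warning, never a silent return.
* **Initialization.** Default is greedy peak-picking: Gaussian-blob seeds
  at successive maxima of a robust per-pixel activation map (mean of the
  top 20% of frames), each peak suppressed before the next pick — the
  strategy functional-imaging segmentation pipelines use. A non-negative
  double-SVD initialization is available (`init = "nndsvd"`), but on
  noisy movies the SVD mixes small footprints into noise-dominated
  singular vectors and local refinement cannot unmix them. Both
  initializations are deterministic given the seed (a small seeded jitter
  breaks exact ties).
* **Sign conventions.** Footprints are always non-negative and returned
  at unit maximum with the scale carried by the activation course.
  Activations are non-negative by default; `nonneg_activations = FALSE`
  (used when capturing odour-evoked inhibition) permits signed courses.

# Response spectra

Per component, odorant and trial, the response is the window mean of the
activation course. Components are kept only if the Pearson correlation
between the response spectra of odour-set repetitions exceeds 0.6 (mean
over pairs when more than two repetitions exist). The reference
glomerulus is labelled automatically as the component whose footprint
places more than half of its mass inside the marker mask — a surrogate
for the manual assignment against the GFP image. Responses of the
reference glomerulus are normalized to its reference-ligand (methyl
propionate) response in the same measurement; measurements whose
reference response does not exceed 0.2‰ (on the fractional $\Delta R/R$
scale, i.e. `min_ref = 2e-4`) are excluded rather than zero-filled, and
the final odour response is the median over the remaining animals.
Welch's two-sided t-test (a robust default; the variant was unspecified)
compares each odorant's replicates against the carrier-gas control, with
the degenerate all-constant case returning $p = 1$.

# Descriptor spaces

EVA vibrational descriptors place a Gaussian kernel of unit height and
standard deviation $\sigma$ on each vibrational frequency and sample the
summed profile at $q = 0, \sigma, \dots, 4000 - \sigma$ cm⁻¹ — an
inclusive-start, exclusive-end grid of $4000/\sigma$ values. The endpoint
convention is chosen so that EVA₅ has 800 columns and the combined
conventional-plus-EVA₅ space has exactly 1600 + 800 = 2400 descriptors,
matching the protocol's combined-space dimension; "width" is read as the
Gaussian standard deviation. Conventional (eDragon-style) descriptor
tables are *consumed* from CSV, never computed — the original service is
external — and the synthetic generator mimics their block structure.
All descriptors are z-normalized column-wise against a reference library
before model fitting; zero-variance reference columns are dropped with a
warning.

# Receptive-range models

Activation models $\hat a = f(x)$ are fitted by multivariate support
vector regression with a Gaussian kernel (explicitly pinned defaults:
cost 1, $\varepsilon$ 0.1, kernel scale $1/(p \cdot \mathrm{var}(X))$ —
"library defaults" are not inherited silently, so results survive library
upgrades), or by univariate linear, isotonic, and unimodal-isotonic
regression. The unimodal fit enumerates all mode positions, fitting
increasing before and decreasing after the candidate mode by
pool-adjacent-violators; the enumeration is exhaustive and therefore
exact. Goodness of fit is $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$;
predictive power $q^2$ refits the model on 50 bootstrap resamples of the
odorant panel and pools squared out-of-bag errors against squared
deviations from a single global mean. Resamples with an empty out-of-bag
set are redrawn and counted. Descriptor-space benchmarks share one
resample sequence across spaces, so comparisons are paired. An SVR whose
training responses all fall inside the $\varepsilon$-tube has no support
vectors; it is treated as the mean predictor instead of an error.
Odour-space embeddings use classical (Torgerson) metric scaling, which is
deterministic and exact on Euclidean-embeddable distances.

# Tunotopy and chemotopy

Spectrum similarity uses the correlation distance
$d_r = 1 - r(s_j, s_k) \in [0, 2]$; chemical similarity uses the cosine
distance between *barycentres of activation*, the activation-weighted
mean descriptor vectors relative to the odorant-panel mean (a glomerulus
equally active on all odorants sits at the origin). Glomeruli are
clustered by UPGMA (average linkage); flat clusters come from an explicit
height threshold — the original manual "distinct gap" judgement is
deliberately not replicated — and clusters spanning fewer than three
animals are discarded. Cluster prototypes are means of unit-norm member
spectra, and clusters are flagged as reference-like when their prototype
correlates with the reference prototype above 0.2.

The spatial statistics are built on a *normalized Mann–Whitney U*: the
fraction of (intra, extra) pairs in which the intra-group distance is
larger, ties half-weighted, so values below 0.5 mean the intra (or
"near") group is closer. Spatial distance is measured to the *nearest*
reference-glomerulus instance (a centre-of-gravity mode exists but is off
by default, since averaging instances distorts distances when several
instances exist). p-values come from the rank-sum test, and every test
carries a shuffle control (default 10,000 permutations of the distances
over glomeruli) whose mean normalized U sits at 0.5 under
exchangeability. The near/far chemotopy sweep repeats the comparison of
chemical distances at a ladder of spatial thresholds, marking thresholds
that empty a group as undefined. The supercluster axis analysis reports,
per animal, the angle between the centre-of-mass axis of two cluster
labels and a configurable anatomical reference direction (image
orientation is acquisition-dependent), plus the percentile of the
centre distance under label shuffles.

# The synthetic generator

`gen_ensemble()` plants, per animal, glomeruli with truncated 2-D
Gaussian footprints (truncation at 3 standard deviations; sd ≈ 1–2 px at
the preprocessed scale, i.e. footprint radii of 3–6 px ≈ 60–120 µm,
matching real glomerular sizes at 19.4 µm/px), 2-D positions, and tuning
centres in a latent chemical space (dimension 3 by default — small
enough for planted-structure recovery, configurable). Identities are
shared across animals: same identity, same tuning centre (up to an
optional jitter), and identity 1 is the planted reference ("MOR18-2-like")
glomerulus present in every animal.

`chemotopy_strength` interpolates between unordered and chemotopic maps:
a fraction of tuning variance lies in a 2-D plane carried onto positions
by a *similarity* transform (similarities preserve distance ranks, so at
strength 1 with zero noise the rank correlation between spatial and
tuning distances is exactly 1); the residual latent dimensions shrink as
$\sqrt{1 - \text{strength}}$. At strength 0 positions come from a
jittered lattice with an enforced separation that `overlap_level`
relaxes: 0 yields provably disjoint truncated footprints.

`gen_response_amplitudes()` applies a Gaussian receptive field
(amplitude = scale · exp(−d²/2w²), clipped at 0 after optional noise);
`gen_movie()` renders baseline (1000 camera units), a 2-frame linear
onset ramp into a plateau, exponential bleaching, i.i.d. pixel noise,
and a single spatially smooth (σ ≥ 20 px) global component with its own
time course — placed there precisely so the difference-of-Gaussians
bandpass demonstrably removes it. IOS movies encode activation as a
reflectance *decrease*, SpH as a fluorescence increase. The peak
fractional signal change is 1% per unit amplitude, putting planted
responses in the per-mille range of real recordings.

What the generator does **not** emulate: optics (no point-spread
function beyond the footprint shape), haemodynamics, movement artefacts,
correlated (shot/vignetting) noise, or molecular structures — vibrational
line spectra are drawn uniformly, standing in for quantum-chemical
output. Passing tests therefore demonstrate correctness of the analysis
under the stated statistical model, not robustness to every artefact of
real data. Animal-scale headline statistics depend on deposited
experimental data and an external descriptor service and are
consequently not reproduced here.

# Problem sizes and numerical choices

The test and acceptance runs use desk-scale problems chosen to exercise
every code path with comfortable margins: one full-scale 1024×1344×60
IOS recording for the geometry check; movies with up to 15 glomeruli on
the 64×84 grid, 24 odorants × 3 trials for factorization recovery at a
peak-signal-to-noise ratio of 5 (recovery demands each component's
signal energy clear the random-matrix noise edge, which sets the odorant
and trial counts); 100-seed calibrations for the spatial statistics and
the paired descriptor-space benchmark at n = 200 odorants, B = 50
bootstraps. Ties in UPGMA are broken deterministically; the normalized-U
orientation (values < 0.5 ⇔ intra group closer), reflective filter
borders, the EVA grid endpoint, and the p = 1 policy for degenerate
t-tests are all fixed and tested explicitly. Every random procedure
takes an explicit seed and is bit-reproducible given it.

# Known limitations

* The rNMF objective is this package's explicit, documented stand-in for
  an unpublished regularizer; it reproduces the described *behaviour*
  (smooth, spatially distinct but possibly overlapping components), not
  any particular legacy implementation bit-for-bit.
* Isotonic model kinds are univariate by design; multivariate monotone
  models are out of scope.
* `mds_embed()` performs classical metric scaling; it does not iterate a
  stress criterion for non-Euclidean inputs.
* The automatic reference labelling is a threshold on footprint/mask
  overlap; with pathological masks (e.g. covering most of the field) it
  will happily label many components, as a manual annotator would not.
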