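---
title: "Partner-based wavelength selection for NIR calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner-based wavelength selection for NIR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Near-infrared (NIR) transmission spectra of biological fluids carry overtone
and combination bands of C–H, N–H and O–H vibrations. A multivariate
calibration predicts an analyte concentration $y$ (here thought of as a serum
protein fraction, in g/L) from the absorbance vector $x \in \mathbb{R}^N$
measured on a grid of $N$ wavelengths. On a full scanning range (e.g.
780–2498 nm at a 2 nm step, $N = 860$) most channels are redundant or
noise-dominated — near strong water absorption the detector is close to
saturation — and full-spectrum models waste latent factors describing
interference and noise. Wavelength selection is therefore a standard step
before fitting the final model.

`nirsel` implements three selectors that share one objective, the
leave-one-out cross-validated root-mean-square error

$$\mathrm{SECV} = \sqrt{\frac{1}{n}\sum_{i=1}^{n}
  (\tilde{y}_i - y_i)^2},$$

where $\tilde{y}_i$ is predicted by a model fitted without sample $i$, and the
companion correlation $R_{P,CV}$ between measured and cross-validated
predicted values.

## PLS engine and the LOOCV protocol

All "-PLS" methods use PLS1 computed by NIPALS on column-centred, unscaled
data (no autoscaling: absorbance channels share a physical unit, and
variance-scaling noise channels would amplify them). With $F$ factors the
model is an affine map $\hat{y} = \bar{y} + (x - \bar{x})^\top b_F$.
Numerical choices:

* component extraction stops early when the X-residual Frobenius norm falls
  below $10^{-12}$; further factors contribute nothing, so requesting more
  factors than the data support is safe on degenerate folds;
* the factor count is chosen by minimum LOOCV SECV over a grid (default
  $F \in \{1,\dots,20\}$; the MC-UVE path uses $\{1,\dots,30\}$), with ties
  broken toward the smaller $F$ — parsimony makes the choice deterministic;
* infeasible entries ($F > \min(n-2, N)$ under LOOCV) are skipped, because
  search grids routinely pair one-channel windows with 20-factor grids.

The PLS/LOOCV path is verified against two independent oracles: at maximal
factor count on full-rank tall matrices PLS must reproduce ordinary least
squares (normal-equations oracle), and the LOOCV wrapper must reproduce
per-fold refits enumerated by hand.

## Optimal partner wavelength combination (OPWC)

Every unordered pair $(\lambda_i, \lambda_k)$ is scored by the LOOCV SECV of
the binary linear regression $y \approx b_0 + b_1 x_{\lambda_i} + b_2
x_{\lambda_k}$ (intercept included — the standard bivariate calibration
form). The *best partner* of $\lambda_i$ is
$f(\lambda_i) = \arg\min_{k \neq i} \mathrm{SECV}(\lambda_i, \lambda_k)$.
Iterating the image of the full grid under this **fixed** mapping,
$\Delta \supseteq f(\Delta) \supseteq f^{(2)}(\Delta) \supseteq \dots$,
shrinks the set monotonically; since the grid is finite the counts must
stabilise, and the stable set — on which $f$ restricts to a bijection — is
the selected combination. It is exactly the set of $f$-periodic wavelengths,
which the test suite checks against a brute-force follow-the-arrows oracle.
Because the score matrix is symmetric, when all finite scores are distinct
every cycle of the stable set has length two: mutual best-partner pairs.

Implementation decisions:

* **Fixed mapping.** Partners are computed once on the full grid and
  iterations only take images. The alternative reading — recomputing
  partners within each shrinking subset — is a different algorithm whose
  termination argument no longer follows from nestedness; it is deliberately
  not implemented.
* **Convergence test.** Set equality rather than count equality; under
  nestedness the two are equivalent, and set equality is strictly safer.
* **Closed-form LOOCV.** Pair scores use the hat-matrix identity
  $e_{(i)} = e_i / (1 - h_i)$ instead of $n$ refits per pair; this is what
  makes the $\binom{860}{2} = 369{,}370$-pair scan a desk-scale computation
  (about a second here). The identity is validated against naive refitting
  on random instances at $10^{-8}$.
* **Sentinels, not exceptions.** A non-identifiable pair (collinear or
  constant channels, leverage at 1) scores $+\infty$ so a dead channel
  cannot abort a full-grid scan; ties in the argmin break toward the
  smallest wavelength for cross-platform determinism.
* Per-iteration PLS evaluation of the shrinking subsets is a diagnostic
  (`trace_pls`), not part of the selection; it uses the same factor grid at
  every iteration.

## Comparison methods

**MW-PLS** exhaustively evaluates windows of $N$ consecutive wavelengths
starting at $I$, for every factor count $F$, and reports the minimum-SECV
triple. Ties break toward smaller $N$, then $I$, then $F$ (not dictated by
the method; chosen for parsimony and determinism). An optional `stride`
subsamples window starts for runtime control; the full-spectrum window is
part of the canonical search space, so the search result can never be worse
than the full-spectrum baseline when the widest window is included.

**MC-UVE-PLS** appends artificial noise variables (default: as many as real
channels, uniform noise at $10^{-10}$ of the mean absorbance), fits PLS
models on many random calibration subsets, and computes each variable's
stability = mean/SD of its regression coefficient across runs. Real channels
whose $|$stability$|$ does not exceed the noise channels' maximum are
eliminated. The literature under-specifies several knobs; the package
declares these defaults rather than inferring intent: calibration fraction
0.8 per sampling (without replacement), cutoff at the noise maximum
(configurable quantile), the in-run factor count fixed beforehand at the
full-data LOOCV optimum, 500 samplings, and 50 independent reruns of which
the minimum-SECV rerun is reported.

## The synthetic-data generator

The reference dataset behind the package's motivating application — 230
clinical serum spectra — is not publicly deposited, so the package ships a
generator whose *serum preset* emulates its shape: a 780–2498 nm grid at
2 nm (860 points), 230 samples, analyte reference values from a normal
distribution with mean 27.477 and SD 3.953 g/L truncated to
[18.70, 41.60] g/L (the clinical panel statistics; truncation makes the
realised sample SD slightly smaller, ≈3.6).

Spectra follow Beer–Lambert mixing: each component has a pure-component
absorptivity built from Gaussian bands (adequate for exercising selectors;
real bands are Voigt-like), a sample's spectrum is the
concentration-weighted sum plus a per-sample linear baseline and additive,
per-channel Gaussian noise whose SD is inflated 100× inside 1950–2050 and
2350–2450 nm — the water-absorption/detector-limited regions where real
serum scans are visibly noise-dominated. The matrix is deliberately
multi-component, because serum is: besides the analyte (bands inside
1500–1850 and 2100–2350 nm) it contains an albumin-like protein, a residual
protein fraction, a lipid fraction, glucose, and a dominant, nearly constant
water background. All organic constituents absorb in the same overtone
regions — that overlap is what makes the selection problem non-trivial. The
ground-truth *informative mask* marks grid points where analyte absorptivity
exceeds 5% of its peak (a declared convention for recovery tests).

What a green recovery test establishes — and what it does not: on this
world, selection (OPWC, MW-PLS) beats the full-spectrum baseline and OPWC's
picks concentrate on analyte-informative channels. The generator does not
model scattering, instrument drift, replicate structure, or correlated
noise, and its smooth Gaussian bands make neighbouring channels more
interchangeable than in real spectra; one visible consequence is that the
best-partner map collapses to far fewer wavelengths (≈6 of 860) than
reported on real serum (28 of 860), and synthetic OPWC trails MW-PLS by more
than the near-parity seen on real data. Conclusions about relative method
ranking on real spectra should not be drawn from the preset.

## Known limitations

* The pairwise scan is $O(N^2 n)$; very fine grids (tens of thousands of
  channels) would need blocking or parallelism (per-pair results are pure,
  so order-independent parallelism is possible).
* Replicate averaging is provided, but no outlier screening is implemented,
  and the package applies no spectral pretreatment (derivatives, SNV, MSC)
  by design — raw absorbance enters all models.
* MC-UVE's cutoff rule is the package's declared convention; other
  conventions (quantile cutoffs) are exposed via `cutoff_quantile`.

## A worked example

```{r, eval = FALSE}
library(nirsel)
sim <- simulate_dataset(serum_preset(seed = 42))
d <- sim$data

scores <- pairwise_scores(d)          # 369,370 BLR LOOCV scores
opwc  <- run_opwc(d, 1:20, scores = scores)
base  <- run_pls_baseline(d, 1:20)
mw    <- search_mwpls(d, N_set = c(10, 25, 50, 75, 100, 150, 200),
                      F_set = 1:15, stride = 10)
opwc$trace$counts   # e.g. 860 44 16 8 7 6 6 — the projection shrinkage
```
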