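---
title: "Iterative gene-weight boosting for single-cell manifold reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative gene-weight boosting for single-cell manifold reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq dissociates cells and discards their spatial (or
temporal) context. Reconstruction algorithms try to recover a latent
one- or two-dimensional manifold — a crypt-to-villus axis, a lobule
zonation axis, a developmental trajectory — from expression alone. They
work well when fed only the genes that vary smoothly along that manifold,
but in practice the input contains genes tied to *other* processes and
plain noise, and nobody hands you the informative subset.

`reconboost` wraps any such reconstruction method in a multiplicative
weights update (MWU) loop that learns a probability distribution over genes
concentrated on the manifold-informative subset, improving the baseline's
reconstruction as it goes, with no prior marker knowledge.

## The algorithm

Let \(X \in \mathbb{R}^{n \times N}\) be the standardized genes-by-cells
matrix, and \(p_t \in \Pi_n\) a distribution over genes. Each round:

1. fit the baseline on the reweighted matrix \(\mathrm{diag}(n\,p_t)\,X\)
   (weights are applied relative to uniform, so round 0 sees the
   standardized data itself — a pure rescaling of the conventional
   \(\mathrm{diag}(p)X\) that keeps the autoencoder's operating range
   independent of \(n\));
2. compute the per-gene reconstruction error
   \(m_t[g] = \frac{1}{N}\sum_j (X_w[g,j] - Y[g,j])^2\), so the round loss
   is the weighted MSE \(\langle m_t, p_t\rangle\);
3. update \(p_{t+1}[g] \propto p_t[g]\, e^{-\eta\, m_t[g]/\max_g m_t[g]}\) —
   the closed-form minimizer of the linearized loss plus a relative-entropy
   proximity term \(\eta\, m_t^\top q + D(q, p_t)\);
4. project \(p_{t+1}\) onto the capped simplex
   \(\Pi_n^{c}\), \(c = 1/(\varepsilon |S|)\), so no gene's weight exceeds
   the cap — mass cannot collapse onto a handful of genes.

After \(T\) rounds (default 10), genes with
\(p_T[g] > (1-\delta)/n\), \(\delta = 0.2\), are labelled
manifold-informative: they kept at least (nearly) their initial uniform
share while uninformative genes decayed.

Two baselines ship with the package: a shallow tanh autoencoder
(`fit_autoencoder()`, trained in compiled code) and a simplified entropic
Gromov–Wasserstein embedder onto a 1-D grid of locations
(`fit_ot_spatial()`), which stands in for published optimal-transport
tissue-reconstruction tools; `adapter_external()` plugs in any external
routine that returns either a reconstruction or an h×N location
distribution. For location-distribution baselines the loss can be switched
to `spatial_variance_loss()`: an interpolation, controlled by
\(\lambda \in [0,1]\), between the average within-location expression
variance and the variance of the increments of the location-mean profile
(a smoothness penalty).

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `eta` | MWU step size (dimensionless; gradients are max-normalized first) | 1 | unnormalized per-gene MSE scales with data variance; normalizing makes `eta` transferable |
| `epsilon`, `s_size` | cap \(1/(\varepsilon|S|)\) on any gene's weight | 0.5, \(n/2\) | \(|S|\) is unknowable a priori on real data; \(n/2\) is the neutral assumption, and the resulting cap \(4/n\) at \(|S|=n/2\) still allows 4-fold enrichment |
| `max_rounds` | weight-update rounds | 10 | the benchmarks below converge in about 10 rounds |
| `delta` | classification slack in the \((1-\delta)/n\) threshold | 0.2 | absorbs round-to-round jitter of weights near uniform |
| `code_dim` | autoencoder bottleneck | 1 | set to the latent manifold dimension being reconstructed |
| `max_width`, `epochs` | AE capacity / training budget | 64, 70 | shallow-regime values; widths 64–128 and 70–100 epochs behave equivalently here |
| `gradient_scale` | error measured on the reweighted (`"reweighted"`) or original (`"original"`) scale | reweighted | see below |
| `entropic_reg` | OT stand-in entropy | 5e-3 | with max-1-scaled distance matrices, 5e-2 blurs the coupling to uniform and loses the ordering |

**Gradient scale.** Measuring \(m_t\) on the matrix the baseline actually
saw (the reweighted one) makes the update self-stabilizing: a gene at
weight \(p\) contributes error \(\propto (np)^2 r\) for intrinsic relative
error \(r\), so weights equilibrate near \(p_i \propto 1/\sqrt{r_i}\)
rather than collapsing winner-take-all. On noiseless data the alternative
`"original"` scale lets small differences in reconstructability compound
multiplicatively across rounds and starve true-positive genes below the
classification threshold; both are exposed, `"reweighted"` is the default.

**Termination.** Besides the hard `max_rounds` stop, two optional criteria
exist: stop when the per-round loss improvement falls below
`loss_improvement_tol` (0 disables it — with a stochastic baseline the loss
jitters, and a literal zero threshold would stop on any uptick), and stop
when the concentration \(D(p_t, u_n)\) *exceeds* `entropy_tol` (the
ground-truth reference \(\chi_S\) is unavailable outside simulation, so
concentration relative to uniform is the observable surrogate; disabled by
default).

## The synthetic benchmark generator

`make_benchmark()` emulates dissociated single-cell data with known ground
truth. Latent cell locations are drawn i.i.d. from one of four manifolds —
\(\mathrm{Unif}([0,1])\), \(\mathrm{Unif}([0,1])^2\), \(N(0,1)\),
\(N(0,I_2)\) — with \(2\times 10^4\) cells at full scale. Each gene is a
random polynomial of its manifold's coordinates with total degree at most
3, z-scored per gene; two 50-gene blocks on different manifolds are
stacked and shuffled so each cell carries genes from two independent
processes (mixtures `D1`–`D4`, differing in location distribution, program
degree, and manifold dimension). Noise at scale \(\beta\) mixes in
per-gene-standardized Gaussian noise as
\(X_\beta = \sqrt{1-\beta}\,X + \sqrt{\beta}\,\bar N\), then re-z-scores,
so every gene keeps mean 0 and variance exactly 1 at every \(\beta\); the
square-root weights are forced by requiring unit variance of the mixture
of two independent unit-variance components (linear weights cannot satisfy
it).

Two generator choices were genuinely open and are worth recording:

* **Polynomial basis.** Coefficients are i.i.d. \(N(0,1)\) over a basis
  *orthonormalized against the latent distribution* (normalized Hermite
  polynomials for Gaussian manifolds, shifted Legendre for uniform ones,
  tensor products in 2-D; constant excluded). Raw monomials would make
  degree a dishonest complexity scale for Gaussian latents:
  \(\mathrm{cov}(c, c^3) = 3\), so a raw degree-3 block is strongly
  inter-correlated — effectively *lower*-rank and easier for a
  one-dimensional code than a degree-2 block, inverting what "different
  degree" is meant to probe in `D2`/`D4`. Orthonormal features make a
  degree-\(d\) block load on exactly \(d\) (or, in 2-D, the corresponding
  number of) uncorrelated directions.
* **Gene counts.** 50 genes per block by default; the mixtures' behaviour
  is insensitive to this in the 20–100 range and 100 total genes keeps the
  benchmark protocol tractable on one CPU.

What the simulator does *not* emulate: count noise (negative binomial,
dropout), batch effects, library-size variation, or non-polynomial
response shapes. Passing benchmarks here demonstrates the reweighting
mechanism under controlled identifiability, not robustness to scRNA-seq
technical artefacts.

## Numerical choices

* Natural logarithms throughout (relative entropy, MWU exponent).
* The capped-simplex projection iterates cap-and-rescale to a fixed point:
  a single pass can push a previously feasible gene over the cap. The
  fixed point equals the exact KL projection (checked in the tests against
  an independent KKT/bisection characterization, \(q_i = \min(c,
  \lambda p_i)\)).
* `mwu_step` subtracts \(\min_g m[g]\) before exponentiating (cancels in
  the normalization; avoids underflow), floors weights at `1e-300`, and
  never zeroes small weights, so genes can recover in later rounds.
* Ties in `classify_genes` resolve to "not informative" (strict `>`).
* Gene rows are z-scored with the population (divide by \(N\)) variance.
* The entropic Gromov–Wasserstein solver starts from a seeded 5% jitter of
  the product coupling: the product coupling is a symmetric stationary
  point of the projected-gradient iteration (exactly stationary for
  \(h = 2\) locations), and the jitter breaks the left–right flip symmetry
  of the grid. Outputs are therefore reproducible given a seed but
  flip-equivalent across seeds. The cell k-NN graph is augmented with the
  Euclidean minimum spanning tree so geodesics are always finite.
* Baselines are refit from scratch each round with a round-derived seed;
  with a fixed master seed a run is bit-reproducible.

## Problem sizes in the reported checks

The package's own acceptance checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run the benchmark protocol at 50 genes per block,
2000 cells, 10 rounds, 5 replicate seeds per condition — the full study
design at reduced cell count, chosen so the complete suite runs on a
single CPU in minutes. At this scale the median TPR on noisy `D1` and the
mean TPR across `D1`/`D2` at \(\beta \in \{0, 0.25\}\) sit at or near 1.0,
and the truth-relative entropy \(D(\chi_S, p_t)\) and the loss both fall
from round 0 to round 10 on `D3`.

## Known limitations

* On `D1` (two 2-D manifolds with equal-complexity programs) the direction
  of concentration is genuinely marginal at 2000 cells: which block the
  1-D-code autoencoder favours can flip between seeds. The cap keeps the
  true block above the classification threshold either way (TPR stays
  high; the per-seed AUC is bimodal), but per-seed FPR need not decrease
  on this recipe at desk scale.
* On noiseless mixtures the within-block spread of reconstructability can
  concentrate weight on part of the true block (occasional TPR dips on
  `D2` at \(\beta = 0\)); moderate noise equalizes per-gene errors and
  removes the effect.
* A single run extracts one manifold. Extracting several means re-running
  on the residual gene set; the package does not orchestrate that.
* The mixed sinusoidal/zonation generative families of real liver data are
  used as label vocabulary in `label_zonated()` diagnostics only and are
  never fitted or simulated.
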