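# reconboost

Iterative gene-weight boosting for single-cell manifold reconstruction.

Single-cell RNA-seq loses the spatial or temporal context of cells.
Reconstruction algorithms (autoencoders, optimal-transport embedders)
recover a latent cell manifold from expression — but only reliably when
their input is restricted to the genes that vary smoothly along that
manifold, a subset that is usually unknown and entangled with genes
driven by other processes and by noise. `reconboost` turns any such
reconstruction method into a subroutine of a multiplicative weights
update (MWU) loop that *learns* the informative gene set while improving
the reconstruction, with no prior marker knowledge.

## The algorithm

With a standardized genes-by-cells matrix `X` (n genes, N cells) and gene
weights `p_t` (a distribution over genes, starting uniform), each round:

1. fit the baseline on the reweighted matrix `diag(n p_t) X`;
2. measure the per-gene reconstruction error
   `m_t[g] = (1/N) Σ_j (X_w[g,j] − Y[g,j])²`, so the round loss is the
   weighted MSE `⟨m_t, p_t⟩`;
3. multiplicative update `p_{t+1}[g] ∝ p_t[g] exp(−η m_t[g] / max m_t)`,
   the closed-form minimizer of `η m_tᵀ q + D(q, p_t)` over the simplex
   (`D` = relative entropy, natural log);
4. project onto the capped simplex `Π_n^c`, `c = 1/(ε|S|)`, so no single
   gene can absorb the mass.

After ~10 rounds, genes with `p_T[g] > (1−δ)/n` (δ = 0.2) are labelled
manifold-informative. Two baselines are built in — a shallow tanh
autoencoder (compiled training loop) and a simplified entropic
Gromov–Wasserstein spatial embedder — plus an adapter for any external
reconstruction routine. Evaluation utilities cover truth-relative entropy
traces `D(χ_S, p_t)`, AUC, TPR/FPR, per-block mutual information between
encoding and expression, mean-profile Pearson correlation, and
linear-fit zonation labelling (R² > 0.1, |slope| > 0.001).

A synthetic-data module generates the benchmark mixtures used throughout:
latent manifolds `Unif([0,1])^d` / `N(0, I_d)` (d = 1, 2), genes as random
degree-≤3 polynomials of location (orthonormal polynomial basis, i.i.d.
normal coefficients), z-scored, stacked into two-block mixtures D1–D4 and
corrupted by variance-preserving Gaussian noise at scale β.

## Worked example

Mixture D3 (50 genes on `Unif([0,1])²`, 50 genes on `Unif([0,1])`, both
degree-3 programs, 2000 cells, noise scale 0.25); 10 rounds with the
autoencoder baseline:

```r
library(reconboost)

d <- make_benchmark("D3", n_genes_per_block = 50, N = 2000,
                    beta = 0.25, seed = 7)
traj <- run_reweighting(d$X, baseline = "ae",
                        config = reweight_config(max_rounds = 10, seed = 7))
glance(traj)
#> # A tibble: 1 × 6
#>   n_genes rounds loss_first loss_last entropy_to_uniform_last n_informative
#>     <int>  <int>      <dbl>     <dbl>                   <dbl>         <int>
#> 1     100     10      0.624     0.444                  0.0618            50

evaluate_trajectory(traj, truth_mask(d))
#> <evaluation_report>
#>   D(chi_S, p_t): 0.6931 (round 0) -> 0.395 (round 10)
#>   AUC = 1.000, TPR = 1.000, FPR = 0.000 (delta = 0.2)
```

Reading this: the weighted reconstruction loss fell from 0.624 to 0.444
over 10 rounds; the divergence between the ground-truth gene distribution
`χ_S` and the learned weights dropped from `ln 2 ≈ 0.693` (uniform start)
to 0.395; ranking genes by final weight separates the two blocks
perfectly (AUC 1.0), and thresholding at `(1−0.2)/n` recovers exactly the
50 genes tied to the 1-D manifold (TPR 1.0, FPR 0.0). `tidy(traj)` gives
the per-round weight/gradient table, `autoplot(traj)` the weight paths.

A command-line interface mirrors this flow
(`inst/scripts/reconboost simulate | run | evaluate`), reading/writing
Matrix Market or delimited matrices with gene/cell sidecar TSVs and JSON
run manifests.

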