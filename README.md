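# rprpca

Disentangles multi-trial / multi-perturbation spatio-temporal biological
data into a **common low-rank response** and a **sparse aberrant
response**, with a random-projection preprocessing step that makes the
separation identifiable on the sparse, eccentric matrices biology
actually produces.

## Who this is for

Anyone stacking repeated spatio-temporal recordings as rows of a matrix
and asking "what do all these trials share, and where does each one
deviate?":

* trial-aligned neural population activity (trials × neurons × time),
  where the shared part is the movement-locked signature and deviations
  are task-irrelevant activity;
* gene- or protein-expression time courses under panels of drug
  perturbations or across cell lines, where the shared part is the
  common network response and deviations are perturbation- or
  mutation-specific aberrations.

## The method

Trials are stacked species-major: row *i* of
`X ∈ R^{q×n·N_T}` is trial *i*'s `n`-species × `N_T`-time-point recording,
with each species' full time course in a contiguous column block.
Principal Component Pursuit separates

```
min ‖L‖* + λ‖S‖₁   s.t.   X = L + S
```

(`‖·‖*` = nuclear norm, sum of singular values; `λ` defaults to
`1/√max(q, n·N_T)`).  Because sparse or eccentric inputs break PCP's
identifiability assumptions, the package first mixes the species
dimension with a random matrix `Ψ` through the Kronecker operator
`R = Ψᵀ ⊗ I_{N_T}`:

```
Y = XR  →  PCP  →  (L_Y, S_Y)  →  L̄ = L_Y R⁻¹,  S̄ = S_Y R⁻¹
```

Time order is never touched; with `m = n` and nonsingular `Ψ` the
pipeline (RP-RPCA) is exactly invertible.  Downstream tools score
sliding-window correlation against templates extracted from `L`
(onset detection with ROC evaluation) and cluster trials with the
disentangled distance
`d(i,j) = (1−γ)(1−corr(Lᵢ,Lⱼ)) + γ(1−corr(Sᵢ,Sⱼ))`.

## Worked example

The benchmark everything else hangs off: a sparse rank-6 50 × 20 matrix,
5% sparse corruption, invertible Gaussian mixing, PCP at the
20%-discounted λ.

```r
library(rprpca)
X  <- gen_sparse_lowrank(seed = 1)              # 50 x 20, sparse, rank 6
cc <- add_sparse_corruption(X, seed = 1)        # 5% entries, norm-matched
P  <- make_projection(n = 2, N_T = 10, seed = 1)
d  <- rp_rpca(cc$corrupted, P, lam = 0.8 * default_lambda(50, 2, 10))
d
#> PCP decomposition: 50 x 20, lambda = 0.1131
#>   rank(L) = 6, nnz(S) = 836 (83.6%)
#>   493 iterations, residual 9.64e-08, converged: TRUE
#>   random-projection pipeline, back-projected: TRUE
numerical_rank(d$L)                             # 6 -- the generating rank
sqrt(sum(d$S^2)) / sqrt(sum(cc$corruption^2))   # 1.09 -- S̄ tracks the
                                                # injected corruption
```

The recovered rank equals the generating rank and the back-projected
sparse component's norm is within 10% of the injected corruption's.  The
same instance *without* projection misidentifies badly
(`pcp_decompose(cc$corrupted, lam = ...)` collapses `L` to rank 0 with a
corruption-norm ratio of 1.44): that gap is the point of the projection
step.

A one-call pipeline with on-disk artifacts and a manifest:

```r
run_pipeline(list(seed = 1, outdir = "run1",
                  stages = c("simulate", "decompose"),
                  decompose = list(lambda_scale = 0.8)))
```

A thin CLI over the same functions lives in `inst/cli/rprpca.R`
(`Rscript rprpca.R simulate|decompose|rp-decompose|detect|roc|cluster ...`).

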