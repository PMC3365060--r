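# discosca

Common and distinctive components for linked omics data blocks.

Integrative experiments often measure several sets of variables on the same
entities — two organisms' genes over aligned cell-cycle time points, or the
same *E. coli* cultures profiled by GC-MS and LC-MS.  The blocks share one
mode (the samples/time points) and the scientific question is which
underlying processes are **common** to all blocks and which are
**distinctive** for a single block.  `discosca` answers it with two related
tools:

* **DISCO-SCA** — simultaneous component analysis (a rank-*R* truncated SVD
  of the row-wise concatenation, constrained to one shared factor
  *P* with *Pᵀ P = I*), followed by orthogonal rotation of the solution to a
  partially specified target: the rotation matrix *B* minimizes
  ‖ *W* ∘ (*T B*) ‖²_F over orthogonal *B*, where the binary mask *W* marks
  the block-factor entries a distinctive component should vanish on.  When
  the composition of common/distinctive components is unknown, all
  (R+1)(R+2)/2 candidate targets are fitted and the one with the smallest
  maximal componentwise deviation is retained.
* **GSVD** — the generalized singular value decomposition
  *X₁ = U₁ S₁ Vᵀ*, *X₂ = U₂ S₂ Vᵀ* with *S₁² + S₂² = I*, in its full
  ("naive") form and in the least-squares **adapted** form (GSVD of the
  rank-*R* truncated SVD of the concatenation).  The cosine weight *c_q²*
  classifies component *q* as common (≈ 0.5) or distinctive (≈ 0 or 1).

A synthetic-data module generates linked blocks from the model
*X_k = U_k S_k Vᵀ + E_k* with known ground truth, and a metrics module
scores recovery by Tucker congruence with permutation/reflection matching.
The methods vignette (`vignettes/disco-sca-methods.Rmd`) documents the
models, the numerical choices and the generator's assumptions.

## Worked example

Generate a pair with one X1-distinctive, one X2-distinctive and two common
components (20% noise), then let the model selection find that structure:

```r
library(discosca)

spec <- simulation_spec(dims = c(60L, 40L, 20L),
                        imposed_vaf = cbind(X1 = c(0.40, 0.00, 0.25, 0.15),
                                            X2 = c(0.00, 0.45, 0.20, 0.15)),
                        noise_fraction = 0.2, seed = 7)
sim <- simulate_blocks(spec)

sca_scree(sim$blocks, 6)    # choose R: sharp drop after component 4
#>          X1    X2 concatenated
#> C1    0.239 0.282        0.261
#> C2    0.070 0.381        0.230
#> C3    0.377 0.023        0.195
#> C4    0.156 0.171        0.164
#> C5    0.015 0.024        0.020
#> C6    0.014 0.017        0.016
#> Total 0.872 0.897        0.885

fit <- disco_sca(sim$blocks, R = 4, seed = 1)
summary(fit)
#> DISCO-SCA, R = 4 , target d1=1,d2=1,common=2
#>
#>           status    X1    X2 deviation
#> C1 distinctive_1 0.395 0.010    0.0096
#> C2 distinctive_2 0.007 0.452    0.0071
#> C3        common 0.286 0.220    0.0655
#> C4        common 0.155 0.175    0.0202
#>
#> Total VAF per block: 0.842 0.856
#> Max deviation: 0.06554
```

The scree table shows four components clearly separated from noise in both
blocks.  The selected target `d1=1,d2=1,common=2` matches the generating
structure: component C1 accounts for 39.5% of X1's variation and
essentially none of X2's (its deviation, 0.0096, is the share it leaks
into the block it should be absent from), C2 is the mirror image, and the
two common components account for similar shares in both blocks (their
deviations are the between-block VAF differences).  Rotation never changes
the total fit — 84.2% / 85.6% per block, the same as the unrotated SCA.
Compare the GSVD classification on the same data:

```r
round(gsvd(sim$blocks)$c[1:4]^2, 2)   # block-1 weight per component
#> [1] 0.01 0.98 0.47 0.42
```

A command-line front end wrapping these functions is installed at
`system.file("cli", "discosca.R", package = "discosca")` with subcommands
`preprocess`, `scree`, `gsvd`, `adapted-gsvd`, `disco`, `select-target`,
`simulate`, `study` and `evaluate`.

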