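---
title: "Common and distinctive components for linked data blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common and distinctive components for linked data blocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discosca)
```

## The problem

Many integrative studies measure several sets of variables on the same
entities: expression of two organisms' genes over aligned time points, or
the same fermentation samples profiled on two mass-spectrometry platforms.
Stacking the blocks and running a single PCA mixes two kinds of structure:
processes *common* to all blocks and processes *distinctive* for one block.
This package separates them with two related tools: the generalized
singular value decomposition (GSVD) of two linked blocks, and simultaneous
component analysis followed by rotation to a partially specified target
(DISCO-SCA).

Throughout, blocks $X_1$ ($I_1 \times J$) and $X_2$ ($I_2 \times J$) share
their *column* mode ($J$ samples/time points); rows are block-specific
variables.  Input files whose shared mode is the rows must be transposed on
import (the CLI has a `--transpose` switch); the package never guesses the
orientation.

## GSVD

The GSVD decomposes both blocks over one shared structure,

$$X_1 = U_1 S_1 V^T, \qquad X_2 = U_2 S_2 V^T,$$

with $U_1^T U_1 = U_2^T U_2 = I$, diagonal $S_1 = \mathrm{diag}(c)$,
$S_2 = \mathrm{diag}(s)$ with $c_q^2 + s_q^2 = 1$, and $V$ of full column
rank $Q = \mathrm{rank}([X_1^T X_2^T]^T)$.  The weight $c_q^2$ acts as the
proportion of component $q$'s variation falling in block 1: values near
$1/2$ mark a common process, near $1$ (resp. $0$) a process distinctive for
block 1 (resp. block 2).  `classify_components()` operationalises "near"
with configurable bands, by default common $= [0.4, 0.6]$ and distinctive
margins of $0.05$ at both ends; the in-between range is reported as
`undetermined` rather than forced into a class.

Estimation follows the thin-SVD / CS-decomposition route: SVD
$X_c = P \Sigma W^T$ truncated at rank $Q$, SVD of the top $I_1$ rows of
$P$ giving $U_1$, $C$ and $Z$, then $U_2$ and $S_2$ by column-wise
orthonormalization of $P_2 Z$ and $V = W \Sigma Z$.  Numerical rank is the
number of singular values above
$\varepsilon\,\sigma_{\max}\max(I_1 + I_2, J)$ with $\varepsilon$ the
machine precision; the threshold is exposed (`rank_tol`) because data
produced by pipelines that truncate precision can sit near the default
cut.

Two non-uniqueness issues need explicit handling:

* **Equal cosines.**  When several components share (numerically) the same
  $c_q$, only their joint subspace is identified.  Within each group of
  cosines equal to $10^{-8}$ we canonicalize so that the group's $V$
  columns are orthogonal with descending norm; when the underlying scales
  differ this restores the generating structure, and when they do not the
  choice is as arbitrary as any other.  Affected components carry
  `stable = FALSE`, as do components whose sine (or cosine) vanishes, since
  the corresponding block basis vector is then arbitrary and is filled in
  by orthonormal completion.
* **Signs.**  Every component is oriented so that the largest-magnitude
  entry of its $v_q$ is positive (the same convention is used for SCA and
  after rotation).

The full GSVD is not a least-squares approximation: truncating it to the
$R$ components with the largest concatenated variation accounted for (VAF)
can fit far worse than a rank-$R$ SVD, and this worsens as common
variation grows.  The *adapted* GSVD (`adapted_gsvd()`) therefore first
replaces $X_c$ by its rank-$R$ truncated SVD and decomposes that; its
per-block total VAF then equals the rank-$R$ SCA totals exactly, which the
test suite asserts to $10^{-9}$.

VAF bookkeeping uses the rank-1 terms: the concatenated VAF of component
$q$ is $\lVert v_q\rVert^2 / \lVert X_c\rVert_F^2$ and the block-$k$ VAF is
$s_{kq}^2 \lVert v_q\rVert^2 / \lVert X_k\rVert_F^2$.  We compute these
explicit ratios rather than reading $s_{kq}^2$ itself as a proportion,
since the latter reading presumes unit-SS block scaling.  Because $V$ is
not column-orthogonal, per-component values of the full GSVD need not sum
to the VAF of a joint approximation; the totals over all $Q$ components do
reach 1.

## SCA and the DISCO rotation

The rank-$R$ simultaneous component model constrains all blocks to one
shared factor,

$$X_k \approx T_k P^T,$$

and its least-squares solution is the truncated SVD of $X_c$.  Of the two
orientation conventions (orthonormality on the shared factor or on the
concatenated block factor) the package uses exactly one internally:
$P^T P = I$ with the scale carried by the block factor.  With this choice
the SS of component $r$ inside block $k$ is just the squared norm of the
corresponding factor column — cross terms vanish — so per-block
per-component VAF is additive, which is what the deviation measure below
needs.  `sca_scree()` tabulates per-block VAF by component for choosing
$R$; the elbow judgement is left to the user (no automatic detector is
provided, as no reliable rule exists for multiblock data).  A tie between
the $R$-th and $(R{+}1)$-th singular values is flagged
(`boundary_tie`) because the retained subspace is then not unique.

Any orthogonal $B$ gives an equally good solution $(T B, P B)$.  DISCO
spends this freedom on interpretability: a *target* assigns each component
a status (common, or distinctive for one block), and the binary mask $W$
marks the block-factor entries that should vanish — the rows of blocks a
component should be absent from.  The rotation minimizes

$$f(B) = \lVert W \circ (T B) \rVert_F^2, \qquad B^T B = I.$$

Since $\lVert T B \rVert_F$ is rotation-invariant, minimizing $f$ is
maximizing the unmasked energy; we iterate a majorization step: at $B_0$
set $Z = (1 - W) \circ (T B_0)$ and solve the orthogonal Procrustes
problem $\min_B \lVert T B - Z\rVert_F^2$, whose solution is the polar
factor $U V^T$ of the SVD of $T^T Z$ (using the full factors of the SVD
keeps $B$ orthogonal even when $T^T Z$ is rank-deficient).  Because
$f(B) \le \lVert T B - Z \rVert_F^2$ with equality at $B_0$, the objective
is nonincreasing — asserted at every iteration in the tests.  Convergence
is declared at a relative decrease below `tol` ($10^{-10}$ by default)
with a cap of `max_iter = 1000`; the criterion is non-convex, so the
identity start is supplemented by `n_restarts = 10` random orthogonal
starts from a seeded stream and the best local optimum is kept.  (The
published description of this rotation problem is silent on
initialization; restarts are our choice, and in practice the identity
start almost always wins because the SCA solution is already close to a
target-consistent orientation.)

Components sharing a status produce identical mask columns, so the
criterion cannot tell them apart.  After convergence each same-status
group is re-rotated so its first component explains maximal variation in
the block factor and each next one the maximum of the remainder — an SVD
of the group's factor columns — which resolves the indeterminacy whenever
the group's scales differ.

### Deviation and target selection

How well a rotated solution attains its target is measured per component:
for a distinctive component, the proportion of VAF in the block where it
should be absent (normalized by that block's own SS — the natural reading
of "variation accounted for *in* that block"); for a common component, the
absolute difference of its VAF proportions between the blocks.  The
solution's summary is the *maximum* componentwise deviation, so a solution
is only as good as its worst component.  With $K > 2$ blocks (supported by
the data structures, though target enumeration is implemented for
$K = 2$), the distinctive deviation generalizes to the maximum over absent
blocks and the common one to the maximum pairwise difference; this
generalization goes beyond the published $K = 2$ definitions and is
documented as such.

When the composition is unknown, `select_target()` tries all
$(R+1)(R+2)/2$ candidate compositions ($d_1$ distinctive for block 1,
$d_2$ for block 2, the rest common; 21 candidates at $R = 5$) and retains
the minimum-max-deviation solution.  Ties within $10^{-9}$ go to fewer
distinctive components, then to lexicographically smaller $(d_1, d_2)$ — a
parsimony preference: a common component is the weaker claim, and
deterministic tie-breaking keeps runs reproducible.

## The synthetic generator

`simulate_blocks()` draws data from the model the methods assume:

$$X_k = U_k S_k V^T + E_k,$$

with $U_1, U_2, V$ uniformly random orthonormal bases,
$s_{kr}^2$ proportional to the imposed per-component weight of component
$r$ in block $k$, and isotropic Gaussian noise scaled so that
$SS(E_k) = \tfrac{f}{1-f}\,SS(U_k S_k V^T)$, i.e. noise accounts for a
fraction $f$ of each block's variation in expectation (cross terms make
the realized fraction stochastic; it is reported per block).  A component
is common when both block weights are positive and distinctive when
exactly one is.

The defaults are the package's study conditions: $X_1$ of size
$144 \times 28$, $X_2$ of size $44 \times 28$, $R = 6$, $f = 0.20$, and
the three imposed-VAF profiles returned by `study_conditions()` — all
distinctive (three per block), a mix (two per block plus two common), and
all common.  The imposed columns are treated as relative signal weights
rather than exact proportions, because their printed sums (0.79–0.82) do
not combine exactly with a 20% noise share; with weights summing to
$\approx 0.8$ and $f = 0.2$ the expected per-component VAF equals the
imposed value to within the profiles' own rounding.

Two deliberate simplifications:

* **Random rather than empirical bases.**  The reference study derived its
  orthonormal bases from empirical mass-spectrometry data; we draw them
  uniformly at random.  Under isotropic noise, VAF and congruence
  statistics are invariant to the choice of orthonormal bases, so the
  comparison remains meaningful — but the generator consequently does not
  emulate heavy-tailed loadings, correlated noise, or block-specific
  variance structure of real platforms, and passing recovery tests say
  nothing about robustness to those.
* **Realizable compositions.**  Under this model a composition whose
  common components coexist with distinctive components in only *one*
  block cannot be realized with exactly zero deviation: the common VAF
  proportions must sum to 1 in the block without distinctive signal but to
  less in the other.  Exact-recovery properties are therefore asserted
  over the realizable compositions (both $d$'s zero or both positive, and
  every block carrying some signal); the remaining compositions are still
  valid *targets* for fitting.

The study driver `run_simulation_study()` reproduces the two standard
summaries: per-component per-block VAF of a representative pair (with
estimated components matched to the generated ones), and mean Tucker
congruences over replications (replication $i$ uses seed
$\mathrm{base} + i$).  With the default conditions it shows the expected
pattern: DISCO-SCA and the adapted GSVD approximate the data equally well
in every condition, while the naive GSVD's fit and recovery collapse as
common variation grows.  Note that the single-pair VAF totals of the naive
GSVD in the all-common condition are highly variable across seeds (block-1
totals roughly 0.26–0.44 under the default conditions); single-pair
comparisons of that quantity should not be over-read.

## Recovery scoring

Tucker's congruence $\phi(a, b) = a^T b / (\lVert a\rVert\,\lVert
b\rVert)$ compares component vectors up to scale.  `match_components()`
aligns estimates with truth over permutations and reflections by
maximizing mean $|\phi|$ — exhaustively (hence exactly) up to 8 estimate
columns, greedily beyond; all built-in studies use $R = 6$, inside the
exact range.  `recovery_report()` scores $V$, $U_1$, $U_2$ separately
(matched independently per structure) and excludes from $U_k$ the
components with zero generated signal in block $k$, whose basis vectors
are arbitrary.  Scale invariance means scoring $U_k$ or $U_k S_k$ gives
identical results.

`label_separation()` implements the cluster-quality check used with
annotated loadings: the correlation, over labelled row pairs, between the
cross product of their loading vectors and the same(0)/different(1) label
indicator.  Taken literally this coding should make well-separated tight
clusters correlate *negatively* (close pairs share labels), yet published
uses report positive values of the same magnitude; rather than silently
flipping a sign we return the literal signed value together with its
absolute value.

## Preprocessing

The preprocessing chain mirrors standard practice for these data and is
deliberately minimal: below-detection imputation (missing cells set to
half the smallest detected value of the *block*, modelling one detection
threshold per platform — the choice of block-wide rather than per-row
minimum is ours), square-root transform for skewed peak areas, per-row
mean-centering and scaling to unit SS, and block weighting (divide by
$\sqrt{I_k}$, or scale each block to unit SS) so a large block cannot
dominate the joint fit.  Constant rows are an error, not a silent drop:
removing rows behind the caller's back desynchronizes row identifiers
between runs.  Missing values are accepted on input only where imputation
will run; no `NaN` survives preprocessing.

## Numerical choices, sizes, limitations

* Tolerances: GSVD structural identities hold to $10^{-10}$ and
  reconstructions to $10^{-8}$ relative; SCA agrees with the truncated SVD
  oracle to $10^{-9}$; rotation leaves totals invariant to $10^{-10}$.
  These are asserted in the test suite at those values.
* Test and study sizes are chosen at desk scale: property suites run on
  hundreds of random instances of size $\sim 10 \times 5$, and the
  replication studies use the full $144/44 \times 28$ conditions with 100
  replications, which complete in well under two minutes on one core.
* The GSVD here is strictly two-block; a $K$-block GSVD with distinctive
  structure is not defined by the underlying theory, while SCA and the
  DISCO rotation formally extend to $K > 2$ (enumeration of targets is the
  missing piece).
* Oblique or simple-structure (varimax-type) rotations are out of scope;
  the rotation implemented is exactly the masked orthogonal one.
* `select_target()` cost grows quadratically in $R$ (number of candidates)
  times the rotation cost; at $R \le 8$ this is seconds.
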