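---
title: "Heterogeneous-network drug repurposing: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous-network drug repurposing: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetnetDR)
```

## The problem and the data model

Computational drug repurposing asks which existing drugs might treat
which diseases. The network formulation works from three matrices: a
drug–drug similarity matrix $M_{rr}$ ($n \times n$, chemical or
target-based similarity in $[0,1]$), a disease–disease similarity matrix
$M_{dd}$ ($m \times m$), and a binary association matrix $M_{rd}$
($n \times m$, 1 for a curated drug–disease indication). Viewed as one
weighted graph, drugs and diseases are vertices and the matrix entries
are edge weights. The guiding biological assumption is guilt by
association: similar drugs tend to treat related diseases, so the
unknown part of $M_{rd}$ is predictable from the two similarity
networks plus the known associations.

`HeterogeneousNetwork` is the package's container for this triple. Its
validity method enforces what every downstream method assumes: both
similarity matrices symmetric (tolerance $10^{-8}$; asymmetry at or
below the tolerance is repaired by averaging with the transpose,
anything larger is rejected with the maximum deviation reported, since
no principled repair exists for a genuinely asymmetric input) with unit
diagonal, and $M_{rd}$ exactly binary. Drugs index rows and diseases
index columns everywhere; this is the orientation under which
$M_{rr} M_{rd} M_{dd}$ is conformable, and every derived adjacency
inherits it. Real curated datasets of this kind are extremely sparse —
the published benchmark collections range from about 0.89 to 0.995
sparsity (fraction of pairs with no known association) — and that
sparsity drives most of the design decisions below.

## Adjacency constructions

Three derived representations feed the predictors.

**Hadamard-weighted adjacency** (matrix-factorization methods):
$M_{MF} = M_{rd} \odot (M_{rr} M_{rd} M_{dd})$, normalized to $[0,1]$
by its maximum entry. Known associations are re-weighted by the
similarity flow between their endpoints; zero entries stay exactly
zero, so the support of $M_{MF}$ equals the support of $M_{rd}$. An
all-zero association matrix is legal and short-circuits the
normalization (no division by zero).

**Block adjacency** (matrix completion):
$M_{MC} = \begin{bmatrix} M_{rr} & M_{rd} \\ M_{rd}' & M_{dd}
\end{bmatrix}$, an $(n+m) \times (n+m)$ symmetric matrix whose
off-diagonal blocks carry the unknowns.

**One-sided stacks** (overlap matrix completion): the drug-side network
stacks $M_{rr}$ over the transposed, imputed association matrix
($(n+m) \times n$, columns indexed by drugs) and the disease-side
network concatenates $M_{dd}$ with the other imputed transpose
($m \times (m+n)$, rows indexed by diseases). This is the one
orientation in which each one-sided completion exposes the full
drug–disease block exactly once. Before stacking, k-nearest-neighbour
imputation fills the profile of any drug or disease with no known
association: the profile becomes the similarity-weighted average of its
$k$ most similar neighbours' profiles (neighbours with empty profiles
excluded), rescaled to maximum 1 so that imputed pseudo-associations
never outrank true ones. Weights are similarity-normalized; the
alternative (raw similarity weights) differs only by the rescaling and
was not pursued. $k = 10$ by default, configurable — small enough to
stay local, large enough to smooth a single noisy neighbour. Imputation
is idempotent and never touches an entity that already has an
association.

**GIP kernel.** When disease similarity must be built from a binary
symptom–disease profile matrix, the Gaussian interaction profile kernel
is used: $K(i,j) = \exp(-\gamma \lVert p_i - p_j \rVert^2)$ with
$\gamma = \gamma' \, m / \sum_i \lVert p_i \rVert^2$, i.e. bandwidth
normalized by the mean squared profile norm so the kernel is insensitive
to the overall density of the profile matrix. $\gamma' = 1$ by default,
the common convention.

## Matrix factorization and the permutation variant

**NMF.** $V \approx WH$ with nonnegative factors, rank $r$, fitted by
the Lee–Seung multiplicative updates minimizing
$\lVert V - WH \rVert_F^2$. The input $V$ is $M_{MF}$. A stabilizer
$\varepsilon = 10^{-12}$ in the update denominators avoids $0/0$ on the
many exact zeros; factors are initialized uniform $(0,1]$ scaled by
$\sqrt{\overline{V}/r}$ so the initial product matches the data mean,
and a fixed seed makes runs reproducible. The objective is recorded per
iteration and is non-increasing (a property the test suite asserts with
$10^{-10}$ slack); iteration stops when its relative change falls below
`tol` ($10^{-6}$ default) or at `maxIter` (2000).

**Rank selection.** The rank is chosen from the singular value spectrum
of the input: the cumulative explained variance
$\mathrm{CEV}_k = \sum_{i \le k} \sigma_i^2 / \sum_i \sigma_i^2$ and
the smallest $k$ reaching a 0.90 threshold. The CEV curve is
nondecreasing with terminal value 1, and the selected rank is clamped
to at least 1.

**NMF-PDR.** The permutation variant asks, per pair, whether NMF
assigns that pair more reconstruction mass than random association
structure would. An observed ensemble of $K$ matrices (default 100)
permutes the $M_{MF}$ values among the known-association positions
only — the association pattern is fixed, the similarity weighting is
shuffled; three null ensembles permute whole rows, whole columns, or
both. NMF runs on each matrix (the rank selected once on the unpermuted
$M_{MF}$ and reused, for comparability and speed), giving per pair $K$
observed and $3K$ null predictions. One-sided Wilcoxon rank-sum tests
(observed greater), with tie and continuity correction via the normal
approximation, yield three z-scores per pair; degenerate constant
comparisons give $z = 0$.

The three z-scores are combined by Stouffer's method. A design point
worth spelling out: the three rank-sum statistics share the *same*
observed sample and are therefore positively dependent, with asymptotic
pairwise correlation $\tfrac12$. The naive divisor $\sqrt{3}$ would
give the combined score a null standard deviation of $\sqrt{2}$; the
package divides by $\sqrt{3 + 6 \cdot \tfrac12} = \sqrt{6}$, the
dependence-corrected Stouffer combination, so the combined score is
approximately standard normal under the null (the test suite verifies
mean and sd on exchangeable ensembles). Since the correction is a
monotone rescaling, rankings — and hence AUC/AUPR — are identical under
either divisor; only calibration differs. The statistic is combined
directly rather than via p-value inversion (equivalent under the normal
approximation).

One practical finding, reproducible with the test suite: the
permutation z-scores only separate signal from null when the NMF runs
inside the ensembles are run to convergence. Truncating the inner NMF
(say, tolerance $10^{-4}$, 300 iterations) buries the permutation
signal in optimization noise and the method loses its edge over plain
NMF; at the default tolerance it wins on planted networks in 8–9 of 10
seeds. Ensemble replicates draw independent child seeds from a master
seed, so results are reproducible and order-independent.

## Bounded nuclear-norm completion and OMC

**BNNR.** Matrix completion relaxes rank minimization to nuclear-norm
minimization with a bounded data-fit term:
$$\min_X \; \lVert X \rVert_* + \tfrac{\alpha}{2}
\lVert P_\Omega(X) - P_\Omega(M) \rVert_F^2
\quad \text{s.t.} \quad 0 \le X \le 1,$$
where $\Omega$ marks observed entries and $\alpha$ balances low rank
against data fidelity (the soft fit is what lets the model tolerate
noisy 0s). The solver is the standard ADMM on the splitting $X = W$:
singular value thresholding of $X + Y/\beta$ at $1/\beta$ for the
nuclear-norm block, a closed-form weighted average (weight
$\alpha/(\alpha+\beta)$ on the data over $\Omega$) followed by exact
clipping to $[0,1]$ for the bound-constrained block, then dual ascent.
$\beta$ is the ADMM penalty parameter — the objective itself contains
only $\alpha$; defaults $\alpha = 1$, $\beta = 10$. Convergence is a
relative Frobenius change below $10^{-6}$ or 500 iterations; a residual
rising for 50 consecutive iterations is flagged as divergence. The
solver is deterministic, and increasing $\alpha$ monotonically tightens
the data fit (asserted in the tests at $\alpha \in \{0.1, 1, 10\}$).

For prediction the whole block adjacency is completed with every entry
treated as observed — similarity blocks and both the 1s and the 0s of
the association blocks — so the bounded regression denoises the zeros;
`maskZerosUnknown = TRUE` switches to treating the 0s as missing. The
completed matrix is not re-symmetrized; prediction reads only the
drug–disease block.

**OMC** applies BNNR separately to the two one-sided stacks (after KNN
imputation), extracts each side's completed drug–disease block, and
averages them elementwise. Averaging two completions of the same block
from different similarity contexts is the method's robustness
mechanism.

## Evaluation protocol

**Stratified CV.** All $n \times m$ pairs are partitioned into $k = 10$
folds (default), stratifying the "1" group and the "0" group
independently so per-fold group sizes differ by at most one — on data
this sparse, unstratified folds can lack positives entirely. Per fold,
the test fold's *positives are zeroed out of the association matrix*
and every adjacency is recomputed from the masked network before the
method runs; the harness never caches an adjacency across folds. This
matters: the test suite contains a deliberate corruption experiment
showing that predicting from the unmasked network measurably inflates
AUPR. Predictions for all pairs of the test fold (both groups) are
collected, so each repeat yields one full prediction matrix in which
every pair was scored by a model that never saw it. CV is repeated
$N = 25$ times (default) with fresh folds and fresh method seeds per
repeat; the median over repeats is the headline statistic, with mean
and SD also reported.

**Ranked metrics.** Evaluation is disease-centric: for each disease,
predicted scores are sorted in descending order and the disease's
column of the true association matrix is reordered accordingly (the
ranked matrix $R_{rd}$). Each pair's pooled score is its negated
within-disease rank, so pairs compare across diseases by rank position,
and AUC/AUPR are computed over all pairs pooled. Ties receive average
ranks for the metrics — this keeps AUC exactly equal to the
Mann–Whitney concordance statistic (verified against a brute-force
pairwise count) — while the displayed reordering breaks ties stably by
drug index. AUPR uses step-wise precision–recall integration (the
average-precision convention), with ties in the pooled ranking resolved
by stable order; the alternative trapezoidal rule gives slightly
different absolute values and is not used. Degenerate inputs (no
positives, or no negatives for AUC) raise an error rather than
returning a silent 0. An alternative per-disease-averaged metric mode
was considered and rejected: with columns of wildly different positive
counts, pooling the rank-transformed pairs is the reading under which
one AUC/AUPR per matrix is well defined.

**The balanced-subsample comparator.** Earlier benchmarking studies
evaluated on test sets built per fold from the fold's positives plus an
equal-size random draw of its negatives. `balancedSubsampleEval`
implements that protocol verbatim for comparison. Discarding almost all
negatives removes almost all false-positive opportunities, so AUPR is
inflated dramatically on sparse data; on planted synthetic networks at
sparsity 0.95 the balanced protocol reports AUPR around 0.8 where
full-matrix evaluation of the *same out-of-sample predictions* reports
around 0.2 — the same qualitative gap reported between published
balanced-protocol numbers and full-matrix re-evaluation on the real
benchmark datasets. The package treats full-matrix evaluation as the
honest default and the balanced protocol as a diagnostic.

## The synthetic generator

Real benchmark datasets require downloads and hours of compute, so
every stage of the package is exercised on synthetic networks with
planted, learnable structure. The generator assigns drugs and diseases
to shared latent clusters: cluster centroids are Gaussian points scaled
by `signal` in a `latentDim`-dimensional space; each entity is its
centroid plus Gaussian noise (`noiseSd`); similarities are the Gaussian
kernel $\exp(-\lVert x_i - x_j \rVert^2 / \text{latentDim})$ with unit
diagonal; association propensity is the same kernel on drug–disease
latent pairs plus logistic noise (`logisticSd`), thresholded at the
`targetSparsity` quantile so realized sparsity hits the target up to
ties. This plants exactly the "similar drugs treat related diseases"
structure the methods assume, and the test suite certifies the signal
is learnable by an independent k-nearest-neighbour label-propagation
baseline (AUC > 0.6 across seeds) before any method under test is
evaluated on it.

Defaults (`signal = 3`, `noiseSd = 0.5`, `logisticSd = 0.1`, 4
clusters, latent dimension 8, sparsity 0.95) describe a strong-signal,
moderately noisy regime at the sparsity typical of the curated
datasets. What the generator does *not* emulate: scale-free degree
distributions, block-structured similarity from shared drug targets,
curation biases (well-studied drugs have more recorded indications),
and the severe size imbalance of real collections. Passing tests on
synthetic networks therefore certify correctness and qualitative
behaviour of the machinery, not expected performance on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, sizes
chosen so the full suite completes in minutes on one core while every
statistical check retains power: networks of 25–100 drugs by 18–80
diseases, 5-fold single-repeat CV for cross-method comparisons (10-fold
where the protocol's stability claim is itself under test), permutation
ensembles of $K = 25$ for method comparisons and $K = 100$ for null
calibration, and 3–10 generator seeds per claim. Monte-Carlo limit
checks use 10,000 pairs. The published-dataset summaries are recomputed
exactly from the published drug/disease/association counts, which
define the matrix dimensions regardless of scale.

Remaining numerical conventions, collected: similarity symmetrization
tolerance $10^{-8}$ with averaging repair; NMF stabilizer $10^{-12}$;
BNNR bound enforced by exact clipping (not a penalty); SVT drops
components with zero shrunk singular value; rank-sum z uses the normal
approximation with tie and continuity correction (exact enumeration is
pointless at $K \ge 25$ with heavy ties); all randomness flows from
master seeds through independent child-seed streams.

## Known limitations

The permutation method is expensive — $4K$ NMF fits per prediction —
and its advantage over plain NMF, while consistent, is small at desk
scale. BNNR treats association zeros as observed by default, which is a
modelling assumption (unknown is not the same as negative); the
masking option exists but is not the default because the bounded
regression performs better with it on sparse planted data. The GIP
bandwidth convention and the KNN weighting scheme are field conventions
rather than uniquely determined choices. Metrics are pooled after a
within-disease rank transform; conclusions about per-disease
performance heterogeneity require inspecting columns individually.
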