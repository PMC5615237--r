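---
title: "Inferring direct PPI networks from AP-MS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring direct PPI networks from AP-MS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsdirect)
```

## The problem

Affinity purification–mass spectrometry (AP-MS) screens tag one protein (the
*bait*), pull it down, and identify everything that came along (the *preys*).
Repeating this over many baits yields a qualitative record: per purification,
one bait and a set of retrieved preys. Two noise mechanisms dominate.
Non-specific *contaminants* stick to the matrix and recur across unrelated
purifications. And because purification recovers whole assemblies, a prey may
be connected to the bait only through intermediate proteins: an *indirect*
(co-complex) association rather than a *direct* physical contact.

Classical co-occurrence scoring separates true association from contamination
but not direct from indirect interaction. This package implements a two-step
procedure: (I) score every co-occurring pair to build an initial network
that mixes direct and indirect associations; (II) treat the initial scores as
an observed correlation matrix and remove the indirect component with a
spectral or algebraic operator; then evaluate how the re-ranking moves
validated binary interactions toward the top.

## Phase I: co-occurrence scores

All four scores consume the same sufficient statistics
(`cooccurrence_counts()`), computed exactly from the purification records:
per protein, the bait count $b_i$, any-role occurrence count $occ_i$, and
prey-slot count $r_j$ (total $T = \sum_j r_j$); per pair, the directed spoke
count $s_{ij}$ (bait $i$ retrieving prey $j$), the matrix count $m_{ij}$
(both as preys under a third bait — the bait is stripped from its own prey
list, so co-prey purifications necessarily have a third-party bait), and the
any-role co-membership count $k_{ij}$. The candidate universe is every pair
with $k_{ij} \ge 1$ (the matrix-model reading: prey–prey co-retrieval is
evidence too). All scores are symmetric in the pair; purification order
never matters.

**Socioaffinity (SA).** Log-odds of observed over expected co-retrieval,
with expectations under random assortment of prey slots
($f_j = r_j / T$):

$$\mathrm{SA}(i,j) = \ln\frac{s_{ij}}{f_j \sum_{k:\,\mathrm{bait}=i} |P_k|}
  + \ln\frac{s_{ji}}{f_i \sum_{k:\,\mathrm{bait}=j} |P_k|}
  + \ln\frac{m_{ij}}{f_i f_j \sum_k |P_k|(|P_k| - 1)}$$

where $|P_k|$ is purification $k$'s prey-list size. A term with a zero
observed count contributes 0 rather than $-\infty$: the score stays finite,
and explicit absence evidence is deliberately left to PE, which has a
dedicated absence term. SA is undefined (error) on a dataset with no preys
at all.

**Purification enrichment (PE).** A Bayesian log-odds accumulating
per-purification presence *and absence* evidence. With smoothed background
frequency $\tilde f_j = (r_j + \mathit{pseudo}/n)/(T + \mathit{pseudo})$
over $n$ proteins, each purification with bait $i$ contributes
$\ln(r/\tilde f_j)$ if it retrieved $j$ and
$\ln((1-r)/(1-\tilde f_j))$ if not; the matrix term adds
$m_{ij}\,\ln\!\big(r/(\tilde f_i \tilde f_j \bar S)\big)$ with
$\bar S$ the mean of $|P_k|(|P_k|-1)$. Defaults $r = 0.5$ (a true partner
is retrieved in half of its chances — agnostic) and $\mathit{pseudo} = 20$
(stabilizes frequencies of rarely seen proteins); both are exposed. With
$\mathit{pseudo} = 0$ a protein retrieved in every prey slot has
$\tilde f = 1$ and the absence term diverges, so a positive pseudocount is
recommended in practice.

**Dice coefficient (DC).** Membership overlap,
$2 k_{ij} / (occ_i + occ_j) \in (0, 1]$ on the candidate universe.

**Hypergeometric (Hart).** Significance of co-membership: with population
$N$ purifications, $occ_i$ marked, $occ_j$ drawn, the score is
$-\log_{10} P(X \ge k_{ij})$ (upper tail via `stats::phyper`; the tail is
symmetric under swapping the roles). P-values are clamped below at
`p_floor` ($10^{-300}$ by default) so extreme enrichment stays finite.

## Phase II: removing indirect associations

Model the initial network as an observed association matrix $G$ in which
each entry sums the direct effect and the effects mediated along chains of
direct links: $G = S + S^2 + S^3 + \dots = S(I - S)^{-1}$ for the true
direct matrix $S$ with spectral radius below 1. Both operators invert this
relationship in closed form.

**Network deconvolution** diagonalizes $G = V \Lambda V^{\top}$ and applies
$\lambda \mapsto \lambda/(1+\lambda)$ to each eigenvalue — the exact inverse
of the series ($\lambda_{obs} = \lambda/(1-\lambda)$). Because an arbitrary
score matrix need not satisfy the spectral-radius condition, eigenvalues are
first divided by
$m = \max\big(\lambda^{+}\tfrac{1-\beta}{\beta},\,
|\lambda^{-}|\tfrac{1+\beta}{\beta},\, 1\big)$, which guarantees the
transformed spectrum lies in $[-\beta, \beta]$. Default $\beta = 0.99$ (the
deconvolution tool's documented default) and $\alpha = 1$ (no pre-sparsification;
with $\alpha < 1$ only the top fraction of entries by magnitude is kept).
`force_no_scaling = TRUE` skips step one for input that is already a valid
closure; on such input recovery is exact to machine precision (a property
the test suite verifies on random instances).

**Silencer.** The algebraic transform
$S = \big(G - I + \mathcal D((G - I)G)\big)\,G^{-1}$, where $\mathcal D$
keeps only the diagonal. On two nodes it is a fixed point (the off-diagonal
$g$ returns exactly); on $G = I$ it returns 0. If $G$ is numerically
singular (reciprocal condition number below $10^{-12}$) a ridge of
$10^{-8}\,\mathrm{tr}(G)/n$ is added before inversion, with a message. The
output is symmetrized and its off-diagonal *magnitudes* are the direct
scores.

### Bridging scores and matrices

Both operators were derived for correlation-like input; an AP-MS score
network is not one, and the embedding matters. `network_to_matrix()`
offers two normalizations:

* `"positive"` (default): scores clamped at zero, divided by the maximum.
  The rationale: SA and PE are log-odds, and a value at or below 0 means
  *no evidence of association*; the observed correlation of such a pair is
  zero. Plain min–max, by contrast, maps the most depleted pair to 0 and —
  critically — neutral pairs to mid-range weights, filling the matrix with
  medium-strength edges on contaminant hubs. In replicated simulations
  under the package's reference conditions this inflates the hub part of
  the spectrum and visibly degrades the refined ranking for SA. For DC and
  Hart, which are nonnegative with a meaningful zero, `"positive"` is just
  a rescaling.
* `"minmax"`: the conventional $(x - \min)/(\max - \min)$, kept as an
  option.

For the silencer, `refine_network()` additionally rescales the off-diagonal
part $C$ to spectral radius 0.5 (`target_radius`) before adding the unit
diagonal. The closed form presumes $G = I + C$ generated by a convergent
series — $\rho(C) < 1$ and $G$ invertible. Raw $[0,1]$ weights violate
this: a tightly co-purified complex produces a near-all-ones block, $G$
becomes effectively singular, and the inverse is dominated by numerical
noise (in unscaled runs the ridge fired on every replicate and contaminant
pairs flooded the top ranks). Any radius comfortably inside $(0,1)$ behaves
similarly; 0.5 sits in the middle. Deconvolution needs no such step — its
$\beta$ scaling plays exactly this role internally.

By default the refined matrix is re-ranked over exactly the initial
network's candidate pairs (`restrict_to_initial = TRUE`), so initial and
filtered rankings are comparable; the operators do create nonzero entries
outside the candidate universe, and `restrict_to_initial = FALSE` exposes
them.

## Evaluation

`hit_curve()` walks the ranking in canonical order — descending score, ties
broken by the lexicographic pair, so ranks are deterministic — and counts
cumulative hits in a reference set of validated binary interactions.
`normalized_auc()` integrates the piecewise-linear curve through $(0,0)$,
$(1,y_1), \dots, (x_{max}, y_{max})$ by the trapezoid rule and divides by
$x_{max}\, y_{max}$: 0 with no hits (defined limit), 0.5 when hits arrive
at a constant rate (the diagonal), approaching 1 when all hits are
front-loaded. Each curve is normalized by its own $y_{max}$ (the literal
reading of the definition); when comparing curves a shared depth is used
and the `"up"` verdict requires a strict increase. The default reporting
depth is $x_{max} = 10{,}000$, the conventional scale for genome-wide AP-MS
rankings; it is truncated to the network size when necessary.
`compare_networks()` reports Venn-cell overlap counts among the top-$k$
pair sets of several methods.

## The synthetic generator

`simulate_apms()` produces datasets with known ground truth so that every
stage is testable without external downloads. `build_truth()` samples
disjoint complexes (default 10, sizes 3–6) wired as a random spanning tree
plus each extra within-complex edge with probability 0.3 — connected but
not cliquish, so direct and indirect co-complex pairs both exist.
`simulate_purifications()` draws a bait uniformly from complex members; its
direct neighbours are retrieved with `p_direct` (0.8), its non-adjacent
co-complex partners with `p_indirect` (0.4), and a Poisson(2) number of
contaminants is drawn from a 40-protein pool with Zipf(1) propensities, so
a few sticky contaminants recur in a large fraction of purifications. One
seed fixes everything; identical configurations give byte-identical
datasets. Defaults were chosen once as a realistic small screen: a few
hundred purifications over a few dozen true proteins, bait reuse, roughly
half the retrieved prey slots attributable to noise mechanisms.

What the generator deliberately does **not** emulate: protein abundance and
spectral counts, bait-dependent tagging efficiency, overlapping complexes,
and — importantly — *transitive* retrieval. Indirect partners are retrieved
by an independent Bernoulli draw given the bait, not by propagation through
a retrieved intermediate, so the observed co-occurrence matrix is not an
exact transitive closure of the direct network. Passing tests on this
generator therefore demonstrate correct mechanics and a realistic
qualitative behaviour, not performance on real screens.

## Replicated recovery experiment

`recovery_experiment()` runs the full two-step procedure over replicate
simulations (10 seeds at the reference conditions; roughly 80 proteins and
1,200 candidate pairs per replicate — small enough that the whole
experiment takes seconds) and reports the precision of true direct edges
among the top $|direct|$ ranks plus the normalized AUC against the
direct-edge reference, before and after refinement. Two regimes emerge
consistently:

* For PE and Hart — where the initial ranking leaves room — both operators
  raise direct-edge precision and mean direct-edge rank, robustly across
  seeds.
* For SA and DC the initial ranking is already near its ceiling under
  these conditions, and refinement mostly reshuffles near-ties at the top
  boundary; single replicates can lose a few ranks. The mean-rank property
  test is therefore asserted for PE and Hart, and the stricter
  every-combination claim is tested — and documented — at its observed
  strength in the acceptance suite.

## Numerical and degenerate-input conventions

* Zero-count SA terms contribute 0 (see above); PE's matrix term is 0 when
  $m_{ij} = 0$; the hypergeometric tail is clamped at `p_floor`.
* Score serialization uses `%.17g`, so network files round-trip doubles
  exactly; readers reject NaN scores, strip bait self-retrieval, and
  deduplicate preys and reference pairs (self-pairs dropped with a count).
* An empty purification (no preys) is legal; an empty dataset is not.
* Matrices are re-symmetrized after eigen-reconstruction and inversion to
  absorb floating-point drift; diagonals are zeroed on output.
* A single-edge network normalizes to weight 1 under both mappings; a
  network whose scores are all non-positive embeds (under `"positive"`) as
  the zero matrix, and both operators map zero to zero.

## Known limitations

The scores are operational definitions faithful to their originals but not
bit-compatible with any particular legacy implementation; formulas, not
software, define correctness here (each has an independent brute-force
oracle in the test suite). The framework evaluates rankings only — it does
not threshold networks, estimate error rates, or detect complexes. The
generator's independence assumptions understate the transitivity that the
refinement operators are built to exploit, which makes the synthetic
benchmark conservative for them precisely where the initial scorer is
already strong.
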