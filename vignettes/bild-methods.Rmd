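---
title: "Column log-odds scores from Dirichlet-mixture priors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Column log-odds scores from Dirichlet-mixture priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bild)
```

## The scoring model

A column of a multiple alignment of related sequences is modeled as draws
from an unknown multinomial ρ over the residue alphabet; a prior Θ — a
mixture of M Dirichlet densities with weights $m_k$ and parameter vectors
$\alpha_k$ — expresses what distributions "true" columns tend to have. The
column score compares the marginal likelihood of the observed counts under
this generative model with the i.i.d. background model:

$$S(x) \;=\; \log_2 \sum_k m_k
  \frac{\Gamma(\alpha^*_k)}{\Gamma(\alpha^*_k + n)}
  \prod_j \frac{\Gamma(\alpha_{kj} + c_j)}{\Gamma(\alpha_{kj})}
  \;-\; \sum_j c_j \log_2 p_j ,$$

with $\alpha^*_k = \sum_j \alpha_{kj}$, counts $c_j$ (fractional counts are
allowed and arise from sequence weighting), $n = \sum_j c_j$, and background
$p$. Equivalently, the score is the sum of sequential per-letter log-odds
terms in any observation order: the predictive probability of the next
letter under the current posterior mixture, over its background probability.
This identity — the aggregated closed form equals the chain-rule product for
every permutation — is the central internal consistency check of the
package and is property-tested with random fractional counts.

Three consequences drive everything downstream:

* scores are **permutation-invariant** in the column's letters;
* background-generated columns have **negative expected score**, so a
  maximal-scoring contiguous extent is well defined — no arbitrary width
  parameter is needed;
* the score decomposes into **incremental letter scores**, which are exactly
  the entries of a position-specific score matrix for aligning one more
  sequence to a profile.

All probability arithmetic is in log space through `lgamma()`; Γ is never
evaluated directly, so columns with hundreds of weighted observations are
numerically safe. Posterior updates are exactly invertible (downdating), and
the Gibbs sampler and leave-one-out matrices rely on that exactness rather
than on approximate count subtraction.

## Prior diagnostics

Two scalar summaries calibrate how "deep" a prior is. The implied pairwise
matrix $q_{ab} = E[\rho_a \rho_b]$ has the closed form
$\sum_k m_k \alpha_{ka}(\alpha_{kb} + [a=b]) / (\alpha^*_k(\alpha^*_k+1))$;
its relative entropy H against the product background is the classical
per-pair information of the substitution matrix the prior implies. The mean
multinomial relative entropy H̄ uses the digamma closed form
$(1/\ln 2)\sum_i (\alpha_i/\alpha^*)(\psi(\alpha_i+1)-\psi(\alpha^*+1))
- \sum_i (\alpha_i/\alpha^*)\log_2 p_i$ per component and measures the
per-column information available from a deep alignment. Both are checked
against Monte-Carlo integration over prior-sampled multinomials in the test
suite, and both default their reference distribution to the prior's own
implied background $p_i = \sum_k m_k \alpha_{ki}/\alpha^*_k$; the symmetric
DNA table in the acceptance checks uses the uniform background, which there
coincides with the center. For single-letter columns, the column-column
score reduces exactly to $\log_2 q_{ab}/(p_a p_b)$ with $p$ the implied
background — the scoring background cancels in the difference.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| prior α (per component) | user/file | column-distribution prior; symmetric `alpha_star * center` helper for DNA |
| background *p* | implied by prior | null letter distribution; CLI can use uniform or input composition |
| insertion costs | 9.25 + 0.25·l bits | ⇒ initiation frequency 0.87 %/position, mean length ≈ 6.3 |
| deletion costs | 8.5 + 1.0·l bits | ⇒ initiation 0.28 %/position, mean length 2.0 |
| no-gap penalty ε | −log2(1−f_ins−f_del) ≈ 0.017 bits | cost of *not* opening a gap at a match, keeps bit scores probabilistic |
| report threshold | −25 bits | hits below this are not reported; only positive hits feed the next profile |
| inclusion prior π | 0.5 | prior odds that a sequence carries the pattern; π-term vanishes at 0.5 |
| HMM deletion multiplier c | 2.5 | deletion-extension cost c·\|s̄_j\| through column j |
| HMM insertion threshold T | 1 bit | insertions forbidden between nearby columns with s′ > T |

The cost↔frequency mapping is `extend = −log2 q`,
`open + extend = −log2(f(1−q))` with q the per-position extension
probability; mean gap length is 1/(1−q). The deletion extension coefficient
(1.0 bit) follows from the mean deletion length 2.0 (extension probability
1/2). A symmetric mode (`gap_params(symmetric = TRUE)`) sets deletion costs
equal to insertion costs for benchmark generators that make no
insertion/deletion asymmetry.

## The algorithms

**Gibbs sampler.** Sweeps visit sequences in random order; the visited
sequence's observations are removed exactly, a PSSM is built from the
remaining counts, and a new offset is drawn with probability
$\propto 2^{s(x)/T}$. When exclusion is enabled an "absent" outcome competes
with weight $2^{\mathrm{threshold}/T}$, where the threshold is the
description-length price $\log_2 L_\mathrm{eff} + \log_2((1-\pi)/\pi)$ of
adding the segment. Every fifth sweep the width is re-optimized by exact
best-interval search over all candidate columns the offsets admit (the
effective length convention is $L - W + 1$, the number of start positions).
Design choices made where the procedure was genuinely open, fixed once:
temperature 1 (pure Gibbs) with optional geometric annealing over the final
10 % of sweeps; restarts 10 and sweeps 200 by default, with early stop after
50 unimproved sweeps; width initialized at the midpoint of its bounds;
exclusion sampling disabled for the first quarter of each restart so a
profile can form before sequences are allowed to drop out.

**Program 1.** Each round rebuilds the exact leave-one-out PSSM per sequence
and realigns the *whole* profile to the best segment of the sequence
(semi-global: every column matched or deleted, terminal deletions charged,
sequence flanks free) by an affine-gap dynamic program. All sequences are
realigned each round, including previously excluded ones; only
positive-scoring hits build the next profile, and iteration stops when the
objective — hit scores minus start-position, instance and width description
costs — stops increasing. The returned profile is the one the reported hits
were scored against, so every hit score re-derives exactly from its path.
Multiple instances per sequence use greedy masking; the m-th instance in a
sequence pays $\log_2 L_\mathrm{eff} + \log_2 m$ bits, the increment of a
Poisson(1) prior on the per-sequence instance count (the minimal choice
consistent with a mean of one instance per sequence; the exact form of this
cost was an open design point). Width adjustment proposes adding or removing
one terminal column, realigns, and keeps changes that raise the objective.

**Program 2.** Identical loop, but the aligner is a semi-global Viterbi pass
through a profile HMM rebuilt each round from the current column scores:
deletion extension through column j costs $c\,|\bar s_j|$ (s̄_j, the
background-mean incremental score, is computed against the same background
as the emissions, keeping one bit scale); the deletion existence cost stays
at Program 1's 8.5 bits (the published default for this cost is not
recoverable, so continuity with Program 1 was chosen; it is configurable);
insertion costs stay uniform, but a junction is closed whenever two columns
at distance ≤ 2 both have normalized score s′ above T — implemented as the
literal three-case junction rule. The two aligners are deliberately
independent implementations (vectorized Gotoh-style recurrences vs a scalar
state machine) and are cross-checked against each other and against
exhaustive path enumeration on all small instances.

Deterministic tie-breaking throughout: Match over Delete over Insert, and
the smaller end coordinate among equal-scoring segments; the empty extent is
preferred at score 0, then leftmost, then shortest intervals.

## What the simulator emulates — and what it does not

`generate_ungapped` draws one multinomial per motif column from the prior
(component choice by weight, then normalized gamma variates — exact), plants
one realization per carrier at a uniform offset, and fills the rest with
i.i.d. background. `generate_gapped` adds geometric-length deletions of
motif columns and geometric-length background insertions at internal
junctions; `shuffle_negatives` concatenates, permutes and re-cuts, so
composition is preserved exactly. This matches the generative assumptions of
the scoring model, which is precisely why recovery benchmarks on these data
are informative about the *implementation* and optimistic about *real
sequences*: real proteins have phylogenetic correlation between rows,
composition drift, repeats and low-complexity tracts, none of which the
simulator produces. Passing benchmarks here demonstrates correctness of the
machinery, not field performance.

Benchmark problem sizes were fixed once as desk-scale study conditions:
offset recovery uses 8 sequences × length 100 with a width-12 implant from a
symmetric α* = 0.2 prior, 50 generator/sampler seed pairs, success = offset
within ±1; the gapped benchmark uses 16 × 150 with width 20 and an insertion
rate chosen so that about one sequence in ten carries a ~5-letter insertion,
success = ≥ 95 % of implanted residues recovered in the correct columns
under a single register shift; negative controls run the sampler on 20
composition-preserving shuffles and require non-positive description gain in
at least 95 % of runs.

## Numerical choices and degenerate inputs

Ambiguity codes contribute zero observation weight under the default policy
(consistent with the ω → 0 limit of the fractional-observation factors) and
are errors in strict mode. Mixture weights are renormalized on input with a
warning; recorded parameter sums are verified to 1e-6 and recomputed.
Sequences shorter than the current width are excluded with a warning; a
profile aligned to any sequence always has the all-deletion path available,
so semi-global scores are never −∞. Inclusion priors of exactly 0 or 1 yield
±∞ thresholds, handled as always-exclude / never-exclude; objectives clamp
the prior-odds term to keep bookkeeping finite. Traceback equality tests use
a 1e-6 tolerance, needed because the vectorized insertion recurrence
(a cumulative-maximum formulation of affine opening) accumulates floating
error in a different order than the stepwise recurrence.

## Known limitations

Sequence-weight *estimation* is out of scope (weights are accepted, not
computed), as are MELD-style scores from pairwise matrices, subfamily
clustering, profile-profile gapped alignment (column-column scores are
exposed; the aligner is not built), composition adjustment of priors, and
E-value statistics for gapped scores. The UCSC protein mixture parameter
files are read but not redistributed; diagnostics for those priors require
the user to supply the files. The dynamic programs are pure R, adequate for
motif-scale profiles (tens of columns) and thousands of residues, not for
genome-scale scanning.
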