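---
title: "Inferring TF regulatory logic and collaborations from binding and time-series expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TF regulatory logic and collaborations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tflogic)
```

## The problem

A transcription factor (TF) that binds a gene's promoter may activate or
repress it, and its presence may be *necessary* (losing the TF loses the
expression), *sufficient* (having the TF guarantees the expression), or
both. Many genes are bound by several TFs whose influence is only visible
jointly, and physical binding (e.g. from ChIP experiments) does not by
itself imply regulation. `tflogic` takes a TF–DNA binding network and a
ternarized time-series expression matrix and infers, per regulatory
module,

1. an individual role for each TF — activator/repressor crossed with
   necessary/sufficient (`AN`, `AS`, `RN`, `RS`, the combined `ANS`/`RNS`,
   or `NoDecision`), and
2. minimal significant multi-TF interactions
   `<h_tf1, ..., h_tfk> => h_g`: a joint up/down pattern over k TFs that
   drives the targets in one direction.

Minimality is deliberate and is the opposite of classical frequent-pattern
mining: the scientifically useful output is the *smallest* TF group whose
joint state explains the targets, because that is what a higher-order
knockout experiment would test.

## Data model

Expression changes are ternary: up (`+1`), down (`-1`), no change (`0`).
Real-valued log-ratio input is discretized with a symmetric cutoff
(default 0.35, the conventional change threshold for log-ratio cell-cycle
microarrays); the threshold is inclusive (`>= cutoff` is up) so that
boundary values are handled deterministically. Input values must already
be log-ratios — consecutive time points are never differenced.

A *regulatory module* groups target genes that are bound by exactly the
same TF set and fall in the same co-expression cluster; the module's TFs
are kept in lexicographic order, which fixes the merge order in the miner
and makes the whole pipeline deterministic. Genes without a cluster label
are dropped (with a warning): cluster filtering, e.g. by functional
enrichment, is delegated to the user's label table. When no cluster
labels are supplied, all bound genes form one cluster and modules are
purely TF-set groups; `cluster_targets()` offers k-means under the
(1 − Pearson) distance (profiles are row-standardized, after which
Euclidean k-means is monotone in correlation distance), with `k = 50` as
the conventional default for genome-scale data. Clustering quality is
plumbing, not part of the method's claims.

## Stage 1: individual TF roles

Each atomic role asserts one (TF state, gene state) agreement: AS pairs
TF-up with gene-up, RS TF-up with gene-down, AN TF-down with gene-down,
RN TF-down with gene-up; a no-change state never matches. For a TF `tf_m`
in module `R_k`, the likelihood of a role is its agreement count over all
time points and module genes, normalized by the *same role's* total count
over every (module, TF) pair:

```
Lk(tf_m, R_k, I) = sum_{t, g in R_k} Gamma(I) / sum_{all (R, tf)} sum_{t, g} Gamma(I)
```

The normalization scope matters. On the built-in example
(`toy_example()`: tf1 up for six time points then down; tf2 always up;
tf3 always down; both targets up for five time points then down) the AN
agreement counts are 12 (tf1), 0 (tf2) and 14 (tf3), giving
`Lk(tf1, AN) = 12/26 ≈ 0.461` — the only reading that reproduces that
value is the same-label global denominator, which is what the package
implements.

Posteriors are `Pos = Pri(I) × Lk`, with the prior the assignment
frequency of the role over all (module, TF) pairs divided by
`|R| × |TF|`. The EM iteration starts from a seeded random assignment and
uniform priors; the expectation step recomputes posteriors (likelihoods
are constant and precomputed once); the maximization step maximizes the
module score `S(R_k)` — the summed agreement count of the assigned roles
— which amounts to assigning each pair the role with the maximal
agreement count, ties broken by the fixed order AN < AS < RN < RS, and
then refreshing the priors from the assignment frequencies. We
deliberately let the score maximization, not the posterior ranking, drive
the assignment: an assignment-by-posterior dynamic has multiple
initialization-dependent fixed points (on the toy example a uniform-prior
start would label tf1 `AS`, because the AS normalizer is smaller, not
because the data support sufficiency), whereas the score-maximizing step
has a unique fixed point, converges in two iterations, is independent of
the seed, and labels tf1 `AN` — the label the data actually support (its
down state forces the targets down in 12 of 12 opportunities, while its
up state predicts the targets in only 10 of 12).

Significance is assessed by permutation: the TF's time profile is
permuted `B` times (default 999) with the prior and the global
denominator held fixed, and the p-value is the add-one upper tail of the
null posteriors. A role whose converged prior is zero therefore has
observed posterior 0 and p = 1; a constant TF profile (never changing
state) is invariant under permutation and also gets p = 1, i.e.
`NoDecision` — such a TF carries no usable signal for an individual call
and is exactly the input the multi-TF stage is meant to handle.
Classification: no significant role gives `NoDecision`; when both the
necessary and sufficient role of one direction are significant and their
posteriors differ by less than `eps` (default 0.05) the combined `ANS` or
`RNS` is emitted; otherwise the significant role with the highest
posterior wins. Note that with few modules the priors concentrate on few
roles, which makes `ANS`/`RNS` calls rare on small data — combined calls
need prior mass on both roles, which realistically only happens with many
modules.

## Stage 2: minimal multi-TF interactions

The affinity of a candidate `<h_tf1, ..., h_tfk> => h_g` is

```
AfnScore = P(pattern & h_g) * P(h_g) / P(pattern)
         = P(h_g | pattern) * P(h_g)
```

with `P(x)` the fraction of (time point, gene) pairs at which `x` holds.
The conditional factor rewards patterns that reliably force the target;
the marginal factor discounts directions that are trivially common. The
score is 0–1 and never exceeds `P(h_g)`; a pattern that never occurs
scores 0.

The level-wise search starts from every 1-TF pattern
(TF up/down ⇒ target up/down) that occurs at least once and is not
already a significant stage-1 pattern; the stage-1 significant patterns
seed the significance index instead. Seeding is per *pattern*, not per
TF: a TF whose down state is individually significant can still
contribute its up state to collaborations (on the toy example, tf1-down ⇒
gene-down is individually significant while tf1-up participates in the
reported 3-TF interaction). At level k, two insignificant (k−1)-TF
candidates merge when they predict the same direction and differ in
exactly one TF identity; a merged candidate with *any* significant
subpattern is pruned (one-deletion lookups in a hash index cost O(k), and
a full subset sweep at report time guarantees global minimality); the
survivors are scored and tested, significant ones are reported and
indexed, and the rest seed the next level.

The level-k significance test compares a candidate's score against the
distribution of the affinity scores of **all** `C(m, k) · 2^k · 2`
possible k-TF candidates of the module (a 3-TF module has 40), via a
leave-one-out location-scale t fit (df = n − 2, upper tail). Using the
full enumeration as the null — rather than only the handful of generated
candidates — is what gives the test resolution at the deep levels where
few candidates survive: on the toy example the three surviving 2-TF
candidates score 0.347, 0.174 and 0.347 and are all insignificant
(p ≈ 0.10, 0.36, 0.10), while the single 3-TF candidate stands far above
its 16-candidate level distribution (p ≈ 0.033) and is the only reported
interaction. Degenerate levels (fewer than three null scores, or zero
variance) yield p = 1 rather than a crash or a spurious call. Reported
interactions are annotated `sufficient` when all TF states are up,
`necessary` when all are down, and `mixed` otherwise.

One property of this design should be understood before interpreting
output at scale: p-values are calibrated *per candidate* (the false
positive rate per tested candidate is about `alpha`), not per module.
A module that reaches level 2 tests tens of correlated candidates, so a
pure-noise module will typically still emit one or two spurious
collaborations at the default `alpha = 0.05`; that raw-threshold
reporting is the method's convention, and users wanting module-level
error control should lower `alpha` substantially or post-filter by
affinity score.

## Synthetic benchmark

`simulate_trn()` builds the test substrate: by default 11 TFs and 17
targets (28 nodes) wired by 58 edges, 12 of which (20.7%) are
binding-only decoys that never influence expression — these exist purely
to measure precision — plus two feed-forward loops (TF → TF → gene with
the TF → gene shortcut). Every target carries a planted generating rule
over its regulatory TFs: an atomic role for single-TF rules, a state
pattern ⇒ direction for 2–3-TF rules; the downstream TF of each
feed-forward loop is itself driven by a 1-TF rule from its upstream TF,
so TF → TF edges are recoverable in principle. Root TF rows are i.i.d.
ternary draws with `P(up) = P(down) = 0.4`, `P(nc) = 0.2`; a target takes
its planted direction whenever its rule's pattern holds and otherwise a
no-change-biased free draw (`P(nc) = 0.5`, chosen once as a realistic
"mostly quiescent" baseline). Noise is symmetric: each cell is
independently resampled to one of the two other states with probability
`noise_rate` (10% or 40% in the standard configurations), and the
corruption mask is recorded so tests can condition on clean cells.

What the generator does *not* emulate: temporal autocorrelation (cell
cycles are smooth, these draws are i.i.d.), TF protein activity distinct
from mRNA state, binding-strength heterogeneity, and measurement-level
intensity noise (corruption acts on the ternary states directly). Passing
the synthetic recovery tests therefore demonstrates that the algorithm
inverts its own generative assumptions under state noise — a necessary
check, not evidence about any particular organism's data.

Evaluation is edge-based by default: an edge counts as predicted when it
participates in any reported interaction, and the decoy edges are the
negatives; `prf_metrics()` returns precision/recall/specificity with
flagged `NA` (never `NaN`) for empty denominators, and `roc_auc()` is the
midrank Mann–Whitney statistic for score-ranked predictions.

## Parameters

| key | default | meaning |
|-----|---------|---------|
| `cutoff` | 0.35 | inclusive log-ratio threshold for up/down |
| `alpha` | 0.05 | significance threshold, both stages |
| `eps` | 0.05 | posterior closeness for `ANS`/`RNS` |
| `B` | 999 | permutations per (module, TF) |
| `max_iter`, `tol` | 100, 1e-6 | EM controls |
| `max_k` | unbounded | deepest interaction size to mine |
| `k` | 50 | k-means clusters when clustering is requested |
| `seed` | 1 | master seed; every random draw flows from it |

## Numerical and design choices

* Inclusive ternarization (`>= cutoff`); negation symmetry
  (`ternarize(-x) = negate(ternarize(x))`) is tested.
* All tie-breaks are fixed: label order AN < AS < RN < RS in the EM,
  lexicographic TF order in modules and merges, sorted output tables;
  two runs with the same seed produce byte-identical files.
* Division guards: zero-denominator likelihoods and affinity scores are
  0; degenerate level tests and constant profiles give p = 1; undefined
  metrics are flagged `NA`.
* Time summation runs over all T time points; the worked example is
  consistent with either including or dropping a boundary point, and the
  full range is the simpler rule.
* The test suite validates the miner against a brute-force oracle
  (plain enumeration, naive counting, set-algebra level-wise filtering)
  on dozens of random modules with up to 4 TFs and 50 time points, and
  the end-to-end recovery on 20 replicates per noise rate of the
  full-size benchmark (T = 500); these sizes exercise every code path
  the defaults reach while keeping the default test run quick.

## Limitations

* Ternary states discard magnitude; a weak consistent regulator and a
  strong one are indistinguishable.
* Individual-role priors couple modules; on very small inputs (one or two
  modules) prior mass concentrates and combined `ANS`/`RNS` labels are
  effectively unreachable.
* Per-candidate error control (see above).
* The level-k null enumerates `C(m,k)·2^k·2` candidates per module, which
  is exponential in k; modules with very many bound TFs should be mined
  with a finite `max_k`.
* TF activity is read from its own ternary mRNA profile; post-
  transcriptional regulation breaks that assumption.
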