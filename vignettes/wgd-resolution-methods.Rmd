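---
title: "Modeling the resolution of whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the resolution of whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdresolve)
```

## The problem

After a whole-genome duplication (WGD), every locus exists in two copies, one
per parental subgenome. Over time most duplicate pairs are *fractionated* —
returned to single copy — while some are fixed as permanent duplicates. In
allopolyploids the two subgenomes often lose genes at different rates
(*biased fractionation*, BF). Measuring BF from a single polyploid genome is
circular: within one synteny block it is easy to say which homoeologous
region kept more genes, but nothing ties the "dominant" region of one block
to that of another. `wgdresolve` follows the multi-genome strategy: when
several species share the same WGD, their common ancestry of losses links
blocks together, and the parental origin of each region becomes a latent
variable that can be inferred jointly across genomes with explicit
confidence estimates.

The package covers the full path from raw gene orders to inference:

1. build *pillars* — ancestral loci anchored by an outgroup gene, holding up
   to two homoeologous genes per polyploid genome — by simulated annealing of
   slot assignments and ancestral order (`anneal_pillars()`,
   `merge_pillars()`, `optimize_global_order()`);
2. model duplicate resolution along a phylogeny with a 4-state Markov model
   and couple adjacent pillars with a hidden Markov chain over subgenome
   assignments (`loss_model()`, `sequence_loglik()`);
3. fit nested model families by maximum likelihood and compare them with
   likelihood-ratio tests (`fit_model()`, `lrt()`, `topology_sweep()`);
4. decode per-pillar subgenome assignments and expected per-branch losses
   (`posterior_assignments()`, `expected_loss_counts()`,
   `block_segmentation()`, `fit_blocks()`);
5. test functional association of retained genes with subgenomes through a
   protein-interaction permutation test (`randomization_test()`,
   `confidence_sweep()`).

A simulator (`simulate_pillars()` and friends) generates all of these data
types with known truth and is the backbone of the test suite.

## The loss model

States are `U` (undifferentiated duplicate), `F` (fixed duplicate) and the
single-copy states `S1`, `S2`, one per parental subgenome; `F`, `S1`, `S2`
are absorbing. Rates out of `U` are:

* `U -> S1` at rate 1. The base loss rate alpha is absorbed into the branch
  lengths, which are therefore measured in alpha x time units; this removes
  alpha as a free parameter.
* `U -> S2` at rate `epsilon` (0 <= epsilon <= 1): the fractionation bias.
  Attaching `epsilon` to the flow *into* `S2` makes the expected ratio of
  S2-losses to S1-losses equal `epsilon` on every branch, so the MLE of
  `epsilon` is directly the retention ratio of the more-fractionated
  subgenome relative to the less-fractionated one. `epsilon = 1` is the
  unbiased (degenerate) case.
* `U -> F` at rate `gamma` (gamma >= 0): the relative fixation rate.

Transition probabilities have an elementary closed form (absorbing target
states), which the tests verify against a generic matrix exponential. One
known convention caveat: other implementations may scale the *total* outflow
from `U` to 1 rather than the `U -> S1` rate; this changes only the scale of
reported branch lengths, not likelihood ratios or posterior decodings.

Every pillar starts at the root — the WGD event itself — in state `U` with
probability 1.

## The assignment HMM

Each genome's two homoeologous tracks (`p1`, `p2` slots) map to the two
parental subgenomes in one of two ways, so with `n` genomes a pillar has
`2^n` possible assignment vectors. Observations only say *which slot* kept a
gene; which *subgenome* that slot belongs to is hidden. Along the ancestral
gene order the assignment is strongly autocorrelated — it changes only where
rearrangement shuffled the tracks — so the assignment vector evolves as a
hidden Markov chain over pillars: each genome independently keeps its
assignment with probability `1 - theta` per junction and flips with `theta`.
Where a genome shows a *double synteny break* (both slot chains interrupted),
its flip probability is 0.5: the assignment decorrelates completely.

Two modeling choices deserve note:

* *Per-genome flips.* A single shared switching process for the whole vector
  would make the per-genome "double break => 0.5" rule inexpressible; with
  per-genome independent flips it is exact, and for small `theta` the
  whole-vector stay probability `(1 - theta)^n ~ 1 - n theta` matches the
  shared-process reading anyway.
* *Uniform initial distribution* over the `2^n` vectors: there is no
  positional information before the first pillar.

Emissions are per-pillar phylogenetic likelihoods computed by Felsenstein
pruning; the batch engine (C++) prunes all `2^n` assignments in one pass by
indexing partial likelihoods with the assignment sub-vector of each subtree.
The forward/backward passes use per-position rescaling (not logs) for
numerical stability; the factorised flip kernel is applied as `n` sweeps of
2x2 mixes, `O(n 2^n)` per junction. The state space is capped at `n = 12`
genomes (4096 vectors); larger analyses are rejected with an explanatory
error.

Expected per-branch loss counts use the absorbing-state fact that a loss to
`S1` happened on branch `e` iff the state is `U` at the parent and `S1` at
the child of `e`; an inside-outside pass gives these joint probabilities per
assignment vector, which are then weighted by the HMM posterior. The
simulator records realized per-branch losses, and the test suite checks the
posterior expectations against them — not just internal consistency.

## Model families and fitting

Five nested families: `WGD-n` (gamma = 0, epsilon = 1), `WGD-f` (gamma
free), `WGD-b` (epsilon free), `WGD-bf` (both) and `WGD-btf`, which frees a
separate `epsilon_early` on a designated branch class, by default the
branches incident to the root — the shared interval immediately after the
WGD. This last family asks *when* biased fractionation acted: a yeast-like
history shows strong early bias (`epsilon_early << 1`) and none later
(`epsilon_late ~ 1`), while a plant-like history shows similar bias
throughout.

`fit_model()` maximises the sequence likelihood over branch lengths, the
free global parameters and `theta`, using bound-constrained quasi-Newton
(`L-BFGS-B`) with a tighter polishing restart; convergence is declared when
the polish moves the log-likelihood by less than 1e-4. Bounds are enforced
on the raw parameters so `epsilon` can sit exactly on its boundary 1 — which
matters for the boundary LRT below. Deterministic given `seed`; optional
jittered multi-starts.

`lrt()` reports the plain chi-square tail of `2 (lnL_full - lnL_nested)`.
When the nested model pins `epsilon` at the boundary value 1, the correct
asymptotic null is the mixture `0.5 chi2_0 + 0.5 chi2_1`, so the plain
chi-square p-value is *conservative* (true rejection rate ~2.5% at nominal
5%). We report the plain value to match common practice and document the
conservatism; the calibration test in the suite accordingly checks size
control (rate below the binomial envelope of the nominal level), not
two-sided agreement with 5%. Tiny negative statistics (up to 0.1 lnL units)
are clamped to zero — at a boundary optimum the two fits legitimately tie to
within optimizer tolerance — while larger violations raise an error.

`topology_sweep()` enumerates all rooted topologies (3 taxa: 3; 4 taxa: 15;
capped by default at 5 taxa) via `phangorn::allTrees` and refits each;
`fit_blocks()` re-estimates `epsilon` within each high-confidence subgenome
block, holding everything else at the global MLE, to ask whether the bias is
genome-wide or block-specific.

## The synteny pipeline

The pipeline turns per-genome annotations plus anchor-to-candidate homology
into pillars. Its score is the number of positions where a slot's gene and
the next non-empty same-slot gene are *genomic neighbors* — adjacent within
the analysis-set-restricted order on the same chromosome, never wrapping.
This strict neighbor definition needs no window-size tuning. Breaks are the
complement: a slot whose next gene is not a neighbor; both slots breaking in
one genome is a double break, which feeds the HMM's `theta = 0.5` rule.

Homolog candidates come from a pair filter with the published thresholds
(two shared exact 7-mers, length ratio >= 0.8, identity >= 0.70 in seed
mode; E-value <= 1e-8 in blast mode; optional Ka cutoff, default 0.1,
against homology surviving from older shared polyploidies).

Optimisation is simulated annealing with geometric cooling (`T <- c T`
per sweep) over six move types: swap two pillars, relocate a segment,
reverse a segment, reassign a slot to another unclaimed candidate (or empty
it), swap a pillar's two slots, and — added after observing deep local
optima the listed moves cannot escape — *reverse a segment while swapping
its slots*, i.e. read a double-conserved-synteny block on the opposite
strand. Without the compound move, an inverted block is locally optimal:
fixing it needs a reversal and ~every slot swap simultaneously. A
zero-temperature quench (uphill-only sweeps from the best configuration)
finishes each run. The score is maintained incrementally for single-pillar
moves and revalidated against a full recount at checkpoints and on exit;
the cooling constants are tuned for test-suite-scale instances and are all
overridable.

Merging keeps a genome's gene only when one of its genomic neighbors is
itself an assigned pillar gene, then keeps pillars to which every genome
still contributes; the global ancestral order is re-annealed with
assignments frozen. The high-synteny subset keeps pillars with full
syntenic support in at least one direction (every occupied slot linked
toward its predecessor, or every one toward its successor, per genome).

## The simulator: what it emulates, what it does not

`simulate_pillars()` draws tip states down the tree from `U`, a hidden
assignment chain with per-junction flips and planted double breaks, and slot
observations with gene identifiers that encode the truth;
`simulate_genome_orders()` re-expresses a simulated pillar set as the raw
pipeline inputs (two homoeologous chromosomes per genome in ancestral order,
plus an outgroup chromosome and a passing homology table). Defaults are the
plant-WGD-like stated world used throughout the tests: `gamma = 0.17`,
`epsilon = 0.65`, `theta = 0.005`, double-break rate 0.026 per genome per
junction (the At-alpha-scale figure implied by ~1100 double breaks over
~7200 junctions and six genomes), and a six-genome ladder tree whose shared
root branch (0.55) resolves roughly half of all pairs before the first
speciation.

The generator does *not* emulate: segmental rearrangement within
chromosomes (double breaks are planted as junction events, not caused by
simulated translocations), homology noise (every candidate table it emits
passes the filters), nested older polyploidies, assembly fragmentation, or
convergent loss states. A green test on simulated data therefore
establishes correctness of the inference machinery under the model's own
assumptions — not robustness to violations of them. `simulate_interaction_network()`
similarly plants a known crossing-depletion factor for calibrating the
network test.

## Numerical choices and degenerate inputs

* Gradients are numerical; the finite-difference step is 1e-5 because the
  default 1e-3 cannot resolve `theta` (itself of order 1e-2) and stalls the
  optimiser a few hundredths of a log-unit short of the optimum. For nested
  comparisons, warm-starting the fuller family from the nested MLE (shared
  parameters at the nested optimum, `epsilon` just inside its bound) keeps
  likelihood ratios non-negative by construction.
* Emission rows are rescaled by their maximum; an all-zero row (data
  impossible under the model, e.g. `epsilon = 0` against a conflicting
  observation) yields `-Inf` log-likelihood rather than an error in
  `sequence_loglik()`, and an explicit error in posterior decoding.
* Oracle equivalences (brute-force path enumeration, matrix exponential)
  are asserted at 1e-9 / 1e-10; round-trip IO serialises probabilities at
  15 significant digits.
* Ties in topology ranking break by parameter count, then lexicographic
  newick. The `ratio_S2_S1` loss ratio is `NA` where the `S1` expectation
  is zero.
* Every stochastic entry point (`simulate_*`, `anneal_pillars`,
  `optimize_global_order`, `fit_model`, `randomization_test`) takes an
  explicit seed and is bit-reproducible from it.

## Known limitations

* With a single polyploid genome (`n = 1`) the model runs but BF is only
  weakly identifiable (exactly the circularity the multi-genome design
  exists to break).
* Branch lengths and `gamma` trade off on very short trees; the tests
  recover global parameters, not individual branch lengths.
* The LRT at the `epsilon` boundary is conservative (see above); a mixture
  reference or parametric bootstrap would be sharper but is not what the
  reported values mean here.
* Annealing is stochastic; on large real genomes multiple seeded replicates
  (supported and ranked by score) are the intended usage, as is fitting on
  the best few orders.

## A small worked run

```{r example, eval = FALSE}
cfg <- wgd_sim_config(tree = example_wgd_tree(4), m = 800, seed = 1)
pillars <- simulate_pillars(cfg)
fit <- fit_model(pillars, cfg$model$tree, family = "bf", seed = 1)
fit
post <- posterior_assignments(pillars, fit$model)
head(expected_loss_counts(pillars, fit$model, post))
block_segmentation(post, pillars, confidence = 0.85, min_genomes = 3)
```
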