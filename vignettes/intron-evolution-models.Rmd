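---
title: "Simulating intron evolution with mutation-and-deletion and mutation-and-insertion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intron evolution with mutation-and-deletion and mutation-and-insertion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the models address

Spliceosomal introns vary enormously in length even when they interrupt the
same position of the same gene across related species. Two contrasting
histories can produce that variation: the extant introns may descend from a
*long* ancestral sequence that shrank lineage by lineage (loss-dominated
evolution), or from a *short* ancestor that grew by repeated insertion
(gain-dominated evolution). Because intron sequences align poorly,
phylogenies built from them have weak support and cannot distinguish the two
directly.

`intronsim` approaches the question by forward simulation. Two generative
models evolve nucleotide sequences down a fixed guide tree whose leaves carry
the observed intron lengths:

* **MD (mutation-and-deletion)** starts from a long random ancestor and
  removes blocks of bases until each leaf reaches its target length;
* **MI (mutation-and-insertion)** starts from a short ancestor and inserts
  random blocks until the targets are reached.

Both models interleave the length changes with point substitutions. Sequence
sets produced under each model are then summarized by five attributes and
compared statistically with a reference distribution; the model whose
attribute profile is compatible with the reference is the better explanation
of the observed introns.

## The simulators

### Sequence model

A sequence is a string over `{A,C,G,T}`. Ancestral sequences are generated
i.i.d. uniform and then *capped*: the first two bases are replaced by `GT`
and the last two by `AG`, the canonical splice-site dinucleotides. The caps
are protected from all later mutation and indel events, so every simulated
sequence keeps the structure of an intron along the entire run. (The
original description caps only the starting ancestor and is silent about
later protection; protecting throughout is this package's choice, and it is
flag-controlled in `mutate_bases()`.)

Substitutions follow a two-class scheme: a base is replaced by its
transition partner (A<->G, C<->T) with probability $R/(R+1)$ and by either
transversion partner with probability $1/(2(R+1))$ each. The
transition/transversion ratio defaults to $R = 1.5$, matching the value
observed for the reference introns, and every substitution is recorded in a
ledger so the realized ratio can be audited after a run.

Indels are single contiguous blocks at uniformly chosen internal positions.
Nothing in the source material constrains their position or contiguity; one
block per event at a uniform position is the simplest model consistent with
"a length of bases removed or inserted per event". Event sizes are drawn
uniformly from inclusive integer ranges (`L_I/D` for indels, `M_I/D` for
mutations) because neither process is believed to occur in fixed amounts.

### The guide tree

The guide tree is the rooted display of an unrooted binary tree: with $N$
leaves there are $N-2$ internal nodes (`AS_1` ... `AS_12` for the default
$N=14$), the root `AS_1` showing a basal trifurcation. This is the only
reading that reconciles "12 ancestral sequences for 14 introns" with a
binary tree, and it matches how unrooted maximum-likelihood trees are
usually drawn.

The packaged fixture (`fixture_tree()`) emulates the reference tree's
anatomy without claiming its exact branch lengths (which are not available
in text form): a ladder of backbone ancestors, each carrying one leaf, the
root and the last backbone node carrying two each. For the default 14-leaf
tree the leaf length table anchors the three documented lengths -- 112
(`Rt112`, whale shark, attached to `AS_9`), 376 (`Cm376`, elephant shark,
attached to `AS_2`) and 1975 (`Am1975`, Mexican tetra, attached to the last
ancestor `AS_12`). The placement of `Am1975` on `AS_12` is what makes the
documented validity bounds meaningful: the smallest MD value of `L_AS12`
(2000) must exceed the longest intron, and in MI mode the ancestor of the
shortest intron must stay below 112. The remaining 11 lengths are drawn
uniformly on [150, 1800] -- inside the observed 112-1975 span, with margin
so that the anchored leaves alone determine the binding constraints. Branch
lengths are uniform on [0.05, 0.60], the magnitude range typical of
maximum-likelihood trees of fast-evolving non-coding sequence; both ranges
are arguments if other regimes are wanted.

### Stage planning

Five parameters control a run: `L_AS1` and `L_AS12` (lengths of the first
and last backbone ancestors), `M_1` (substitutions per unit branch length),
and the two event-size ranges. Only the endpoint lengths are documented, so
intermediate ancestors are scheduled by linear interpolation along the
backbone index, followed by a repair pass that clamps interior nodes so that
lengths are monotone along every root-to-leaf path and every ancestor is
strictly longer (MD) or shorter (MI) than each of its leaf children. The
endpoints stay fixed at their parameter values; if an endpoint itself breaks
a constraint (e.g. MD with `L_AS12 = 1900` against a 1975-base leaf) the
plan is reported invalid with the offending ancestor/leaf pairs, rather than
silently adjusted. Note that validity is a property of the *planned node
lengths*, not of the raw parameters: in MI mode `L_AS12 = 140` is legitimate
even though the shortest intron is 112, because the ancestor of that intron
sits earlier on the backbone and the planner keeps it below 112.

Per-branch mutation budgets are `round(M_1 * branch_length)` (half-up).

### Branch evolution

Along each branch the engine alternates a mutation event and an indel event
-- mutation first, reading the documented phrase "mutation and
deletion/insertion alternately" in written order -- drawing each event size
from its range and capping the final draws by the remaining budget, so
every leaf sequence has *exactly* its target length for every seed and the
per-branch ledger totals equal the budget exactly. (Whether the original
implementation capped or redrew final events is unknown; capping is the
choice here because it guarantees exact terminal lengths.) On very short
MI ancestors a mutation event is further capped by the number of internal
positions; the budget is then spent across more cycles.

## The five attributes

Each generated set of 14 sequences is summarized by:

* `L_MSA` -- column count of the multiple sequence alignment;
* `R_K2+I` -- transition/transversion ratio under the Kimura two-parameter
  model, from site counts pooled over all pairs;
* `Dbar` -- mean pairwise K2P distance over pairs with defined distance;
* `SEDbar` -- bootstrap standard error of `Dbar` over alignment columns
  (500 replicates by default);
* `TS_ML` -- the topology score of the set's inferred tree against the
  reference tree.

The K2P formulas are the textbook closed forms on the transition proportion
$P$ and transversion proportion $Q$ computed over both-ungapped sites:
$d = -\tfrac12\ln\big((1-2P-Q)\sqrt{1-2Q}\big)$, split into transition and
transversion components whose ratio estimates $R$. Saturated pairs
($1-2P-Q \le 0$ or $1-2Q \le 0$) are excluded from `Dbar` and counted;
for tree inference their distances are imputed as twice the largest defined
distance. Pooling site counts for `R_K2+I` (rather than averaging per-pair
ratios) is deliberate: per-pair ratios explode when the transversion
distance is near zero. The direction of the resulting deviation from other
software's estimators is unknown. A crude invariant-sites discount is
available behind `invariant_sites = TRUE` (the fraction of constant columns
is removed from each pair's comparable-site count); it is off by default
because the exact "+I" estimator used in the original workflow is
unspecified.

### Alignment

No R multiple-alignment engine is assumed; the builtin aligner is a
deterministic progressive aligner written for this package: 3-mer frequency
distances, average-linkage guide clustering, and profile-profile global
alignment (match +1, mismatch -1, linear gap -2 per site) in compiled code.
Gaps are only inserted, never substituted, so de-gapping any row returns its
input exactly. An adapter (`align_sequences(method = "external")`) shells
out to an external aligner such as `mafft` when one is preferred; it falls
back to the builtin aligner with a warning when the executable is missing.

### Tree inference

The original workflow inferred maximum-likelihood trees; the contribution
being evaluated here is the topology *score*, not the tree search engine.
Tree inference therefore uses neighbor-joining on the K2P distance matrix
(rows sorted by label first, so input order cannot change the result;
negative branch lengths clamped to zero), and the interface accepts any
externally inferred tree should an ML program be available.

### The topology score

`TS_ML` operates on a deterministic *ladderized drawing*: at every internal
node the larger clade is placed on top, ties broken by the lexicographically
smallest descendant leaf label; leaves then occupy rows $0..N-1$ and an
internal node sits at the mean row of its children. Each leaf has a *branch
form* -- inverted-L if it sits more than half a row above its parent node,
L if more than half a row below, straight otherwise -- and a *relative
location*, the leaf in the row directly above (`TOP` for the topmost).
A test tree is scored leaf by leaf against the reference: one point when the
branch forms agree, one when the relative locations agree, giving a maximum
of $2N = 28$ for the default tree; any tree scores $2N$ against itself.
The half-row tolerance makes "straight" well-defined at the basal
trifurcation, where a leaf can sit exactly at its parent's row. Fixing the
ladderization convention is essential: the original score was read off a
particular program's drawing, and any deterministic convention preserves
the score's meaning while making it reproducible.

## Experiments

`l16_design()` builds the standard $L_{16}(4^5)$ orthogonal array over
GF(4), so each level appears four times per column and every ordered level
pair exactly once per column pair; `materialize_tests()` maps it through the
published level table (MD: `L_AS1` 4000-7000, `L_AS12` 2000-2750; MI:
`L_AS1` 10-40, `L_AS12` 110-140; `M_1` 200-800 and the two event-size
ranges shared). The assignment of level combinations to run numbers 1-16 is
internal to this package: no canonical row order exists for this design, so
run ids are not comparable across implementations, only the set of 16 level
combinations is. `run_orthogonal()`
executes the screen with 10 replicates per test by default, per-run seeds
derived deterministically from a master seed and recorded per row; failures
are per-run, recorded in a `status` column.

The reference distribution (`perturb_reference()`) follows the 1-base
perturbation procedure: each replicate gives every reference sequence
exactly one internal substitution, realigns from scratch, and recomputes
the attributes; means and SDs over 10 replicates form the "reference"
columns that model runs are t-tested against. Because the real chordate
intron sequences are not redistributable, `synthetic_reference_set()`
provides a clearly synthetic stand-in (an MD run at the `MD_23` parameter
set); all numbers derived from it characterize the pipeline, not the
published biology.

The statistical layer mirrors a standard SPSS workflow: pooled-variance
independent t tests (Welch behind a flag; which variant the original used
is not stated), main-effects ANOVA with no interactions (the L16 screen at
10 replicates leaves 144 residual df), Duncan's multiple range test built
from studentized-range quantiles at protection level $(1-\alpha)^{p-1}$
with harmonic-mean group size under imbalance, and stars at $P<.1$, $.05$,
$.01$ (strict).

## What the synthetic fixture does and does not show

The fixture tree and synthetic reference set emulate the *shape* of the
study -- leaf count, length range, anchored lengths, branch-length
magnitudes -- but not the real sequences, the real tree's branch lengths, or
the internals of the original alignment/ML software. Consequently the
published reference attribute values (alignment length 2139, ratio 1.53,
mean distance 1.084, SE 0.089) and the published per-test attribute means
are *not* reproduction targets of this package; tests instead hold the
pipeline to exact structural contracts (leaf lengths, budget conservation,
monotone ancestor lengths, score bounds, array balance) and to independent
numerical oracles (closed-form K2P values, brute-force distance averaging,
additive-matrix NJ recovery, $F = t^2$, a brute-force Duncan oracle).

## Numerical and scale choices

* Mutation positions are distinct within one event but may recur across
  events: events count substitutions, not distinct sites.
* Undefined pairwise distances: excluded from `Dbar`, imputed ($2\times$
  max) for NJ, counted in `n_undefined_pairs`.
* Bootstrap: 500 column resamples by default; reported examples and tests
  use 30-120 replicates where only determinism or scaling is at stake.
* Test-suite problem sizes: sampler checks at $10^5$ events; orthogonal
  smoke runs at 2 replicates (32 runs) on the 14-leaf fixture and at 1-2
  replicates on a 6-leaf fixture where only plumbing is exercised. These
  sizes make the suite comfortably reproducible on a laptop while leaving
  the statistical tolerances (binomial 3-SD bands, chi-square at generous
  levels) meaningful.
* All randomness flows through R's RNG; run-level functions take explicit
  seeds and record them in outputs. CSV/JSON outputs carry the seed and
  package version in a header; FASTA files deliberately do not (comment
  lines are nonstandard in FASTA), their seed lives in the adjacent JSON
  manifest.

## Known limitations

* The builtin aligner is a plain progressive scheme -- no iterative
  refinement -- so alignments (and hence `L_MSA`, `Dbar`) are not
  comparable in absolute value with Muscle-based numbers.
* Pooled `R_K2+I` saturates toward small values when many pairs are highly
  diverged; it is reported but carries little signal in that regime.
* NJ is a distance method; on saturated data its topology is noisy, which
  the score absorbs by design (that is the quantity under study).
* Mixed histories (gain *and* loss in one run), rate heterogeneity across
  sites and context-dependent mutation are out of scope.

## A minimal session

```{r, eval = FALSE}
library(intronsim)

tree <- fixture_tree(seed = 1)
params <- named_tests("MD")$params[[7]]   # the MD_23 setting
run <- run_simulation(tree, params, seed = 42)
glance(run)

intron_attributes(run$leaves, tree, seed = 7)

screen <- run_orthogonal("MD", tree, reps = 2, master_seed = 11,
                         bootstrap_reps = 100)
me <- main_effects_anova(screen, "Dbar")
tidy(me)
autoplot(me)
```
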