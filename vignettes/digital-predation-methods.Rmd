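---
title: "Methods: digital evolution of anti-predator behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital evolution of anti-predator behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`digiprey` is an agent-based laboratory for asking how *evolutionary
history* (EH: did a prey population evolve where predators could arise?)
and *standing genetic variation* (SGV: how much genotype diversity does a
population start with?) shape the evolvability of anti-predator behavior.

Digital organisms carry a genome: an ordered sequence of instructions over
a fixed 60-symbol alphabet. Ten symbols are behavioral — movement (`move`),
turning (`turn-left`, `turn-right`), a 45° forward-looking sensor (`look`),
feeding (`eat`), reproduction (`repro`), predation (`attack`) and three
conditionals (`if-prey-seen`, `if-predator-seen`, `if-resource-here`) — and
the remaining 50 are inert no-ops, among which `nop-X` is the designated
"do nothing" replacement symbol. Keeping 50 inert symbols preserves the
mutational target size of the full alphabet (a random substitution is
behavioral only one time in six) without committing to a Turing-complete
virtual CPU, whose register semantics contribute nothing to the questions
the package addresses.

Organisms live on a bounded rectangular grid. Every cell starts with one
resource unit; a consumed cell replenishes 100 updates later. Time advances
in *updates*: each update, every living organism executes 30 instruction
*cycles* in a freshly randomized order. Ordinary instructions cost one
cycle; a successful reproduction costs a full update's budget (30 cycles,
overrunning into the next update if needed); a successful attack costs 10
cycles of handling time; a failed attack costs one cycle. Reproduction
requires 10 consumed resource units and at least 100 updates since the
organism's last rebirth; the offspring's genome passes through the
mutation-on-copy operator and is placed in the faced cell, and the parent
is "reborn" — execution pointer, sensor and resource tally reset, lifetime
trait counters kept (they are what the trait assays measure). Lifespan is
capped at 500 updates / 15,000 executed instructions.

Predation works through the `attack` instruction: it kills the prey in the
faced cell, transfers 10% of the victim's current resource tally to the
attacker, and classifies the attacker as a *realized predator* from its
first execution onward, successful or not — carrying the instruction is not
enough, but a failed strike is still an attack. Attacks are fatal only
while the living prey count exceeds a protection threshold (1,000 at full
scale); because births push the count above the threshold transiently
within an update, predators in capped arenas kill through rapid repeated
attacks, exactly the regime the enforced prey levels of the competition and
assay trials create. The prey cap itself is enforced at the end of each
update by uniform random removal.

### Mutation on copy

Per reproduction: at most one substitution (probability `p_sub`; uniform
position; replacement uniform over the full alphabet, so a silent redraw of
the same symbol is possible) and at most one indel event — insertion and
deletion fire independently (`p_ins`, `p_del`) and if both fire, one is
kept with equal probability. A deletion that would empty the genome is
suppressed. The two phase presets are `phase1_rates()` (0.25 / 0.05 / 0.05)
and `phase2_rates()` (0.001 / 0.005 / 0.005). With the attack instruction
banned, the attack symbol is removed from the substitution and insertion
draw alphabets, so it can never enter a genome that lacks it.

The alternative reading of "one insertion or deletion per reproduction" —
one of *each* — would roughly double the indel rate; under the chosen
reading the Phase 2 preset reproduces the calibration below, which is the
criterion the rates were defined by.

### Why these rates give ~5% divergence

Five hundred generations at `phase2_rates()` accumulate on average
`500 × 0.001 ≈ 0.5` substitutions (each differing from the ancestor with
probability 59/60) and `500 × (1 − 0.995²) ≈ 5` indel events per length-100
genome. Each surviving indel contributes about one gap column to the global
alignment, so expected divergence is close to `(5 + 0.5) / ~102 ≈ 5%`. The
package measures this on *compositionally random* ancestors (uniform over
the alphabet). On a nearly homogeneous genome (e.g. 97% `nop-X`) an
insertion/deletion pair cancels under alignment — the shifted run still
matches — and measured divergence drops to ~3.5%; the calibration is a
statement about typical sequence, not about degenerate compositions.

## The three phases

**Phase 1.** Nine copies of a hand-written ancestor seed the grid centre
and evolve at the high Phase 1 rates, with the attack instruction allowed
(predator EH) or banned (no-predator EH). The ancestor is a blind forager:
`[move, eat] × 3, turn-left, repro`, padded with `nop-X` to length 100. The
periodic turn is deliberate: on a bounded grid a turn-free walker parks
against the wall and starves on a single regenerating cell, which stalls
establishment for hundreds of updates per generation; the turning loop
keeps the ancestor "blind" (no sensors, no conditionals, no attack) while
making it viable at desk scale. The population cap is applied in both EH
treatments at desk scale: predation is too sporadic in short runs to act as
the top-down control it provides at full scale.

**Phase 2.** The base population is *purified* — realized predators and
offspring of predators are excluded, then every remaining attack
instruction is replaced by `nop-X` — and expanded into the three SGV
constructions, all preserving population size exactly and tagging every
founder with a unique lineage id:

* *clone*: one genotype, chosen abundance-weighted (a uniformly sampled
  organism's genotype; genotype-uniform sampling is available via
  `clone_sampling = "genotype"`), duplicated;
* *intermediate*: genotypes resampled with replacement, each draw emitting
  `Uniform{1..55}` identical copies (the final draw truncated to land on
  the seed size exactly); "up to 55" is read as a uniform draw, with the
  fixed-55 alternative available through `max_copies`;
* *high*: a verbatim duplicate of the seed.

Construction diversity is therefore ordered `H(clone) = 0 ≤
H(intermediate) ≤ H(high) = H(seed)`, with the middle inequality holding
in expectation (per-draw fluctuations can approach the seed's diversity).
Each construction then evolves at the low Phase 2 rates against a *static*
predator population — immortal, sterile, non-evolving; on reaching a
lifespan cap a static predator resets in place — so predation pressure is
identical across replicates and no predator–prey coevolution occurs.

**Phase 3.** Mutation rates are zero. Every trial uses the
double-injection protocol: populations are injected uniformly at random,
run for a conditioning period so the resource landscape is partially
consumed, then discarded and re-injected fresh into the conditioned
landscape for the scored trial (the conditioning organisms are discarded;
the consumed landscape is what carries over). Competitions pair each
replicate of each treatment with one random replicate of each of the five
other treatments (5 pairings × 6R replicates = 30R pairings; 900 at
R = 30), each run with and without the novel predator, with the prey level
enforced as both the cap and the protection threshold (2,000 at full
scale). Trait assays run each population alone at an enforced prey level
(1,000 at full scale), accumulating per-prey lifetime proportions of
moves, turns and looks, and the number of attacks directed at the
population.

Predator populations are scripted fixtures: a pursuit loop (`look`,
`if-prey-seen`, `attack`, `move`, `turn-left`, `move`) whose genome
fraction is set by an `aggressiveness` knob. Selecting evolved predator
populations from banks of replicates by their realized visual-sensor usage
would make the fixture depend on unrepeatable details of particular
evolutionary runs; the knob keeps the operative contrast instead — the
novel Phase 3 predator uses about half the visual-sensor activity of the
Phase 2 predator (`aggressiveness = 0.5` vs `1`).

## Metrics and statistics

*Shannon diversity* is computed on exact-sequence genotype tables,
`H = −Σ p log p`, natural log by default (the base is exposed). Genotype
identity is exact sequence equality — no alignment-based clustering.

*Divergence* between a genome and its lineage ancestor is
`100 − percent identity` of a Needleman–Wunsch global alignment (match +1,
mismatch −1, gap −1; ties broken diagonal > up > left, making the traceback
deterministic). Identity's denominator is the alignment length, so gap
columns count as non-matches. The scoring weights are normative for this
package (the original platform's are unpublished); the divergence
calibration above is insensitive to reasonable symmetric choices.

*PerMANOVA* is implemented from its definition: Gower-centred
inner-product matrix `G = −½ C D² C`, sequential (Type I) sums of squares
via nested projection matrices in the order SGV, EH, PT, then first-order
interactions; pseudo-F against the residual; p-values from free random row
permutation with the `(1 + exceedances) / (1 + n_perm)` convention (999
permutations by default, minimum attainable p = 0.001). Euclidean distance
on the two-column competitor-share response is the default (Bray–Curtis is
available). The response is the final-sample shares of the two competitors;
per-lineage columns would be an equivalent parameterisation up to the
shares-sum-to-one constraint. The test suite cross-checks the
implementation against an independent one (`vegan::adonis2`) with a shared
permutation matrix, and against exhaustive enumeration at n = 6. The linear
mixed-effects analysis of trait deltas is out of scope by design: the
package exports the tidy per-replicate table (`write_lmm_input()`) for
external fitting.

Bootstrap summaries (`summarize_deltas()`) use percentile intervals with
2,000 resamples; at n = 30 replicates these run slightly below nominal
coverage, which the test suite measures rather than hides.

## Synthetic populations

`make_seed_population()` emulates the genotype-abundance structure of an
evolved population without running evolution: random genomes with
configurable behavioral densities, expanded under a uniform, geometric or
empirical abundance model. Geometric is the default because evolved
populations are dominated by a few genotypes with a rare tail; the true
abundance shape of full-scale evolved populations is not reported anywhere,
so this is an explicit modelling assumption. Every genotype is guaranteed
one copy, the remainder multinomial. What the generator does *not* emulate:
genealogical correlation between genotypes (they are independent random
sequences), epistasis, and any adaptation of the behavioral composition to
the grid — so tests built on it validate the pipeline's bookkeeping and
statistics, not the evolutionary dynamics themselves, which only the
simulation phases exercise.

## Numerical and design choices

* **Scheduling.** A fresh seeded random permutation of organisms each
  update, whole cycle budget per organism; births and kills take effect
  immediately (a prey killed mid-update does not execute its remaining
  cycles). The original platform's finer-grained scheduler is out of scope;
  the permutation removes positional bias.
* **Geometry.** 0-based coordinates, origin top-left; 8 compass facings at
  45°; the view cone is the set of cells whose bearing lies within ±22.5°
  of the facing (lattice bearings never fall exactly on the boundary) and
  whose Chebyshev distance is at most `view_range` (default 20, exposed in
  configuration; the platform's exact long-range cone rule is unpublished,
  so the sector definition here is normative). Movement off-edge is refused
  but still costs the cycle.
* **Conditionals** skip the next instruction when false, reading the
  sensor state stored by the most recent `look` (prey/predator seen) or the
  current cell (resource); this is the minimal mechanism that lets sensor
  use causally matter to survival.
* **Failed attacks** cost one cycle: the stated 10-cycle handling time is
  conditional on success, and a failed strike plausibly costs no more than
  any other instruction.
* **Eligibility ages** count from the last rebirth, because reproduction
  resets the parent's internal state including its age marker.
* **Determinism.** All randomness flows through R's global RNG; a single
  `set.seed()` before a pipeline reproduces every trajectory, snapshot and
  log byte-for-byte. The event log records demographic events only
  (births, deaths, kills, cap removals, static resets), which is sufficient
  to fingerprint a trajectory without logging every instruction.

## Problem sizes

The full-scale design (251×251 grid, 2,000,000 Phase 1 updates, 200,000
Phase 2 updates, 30 replicates, prey levels 1,000/2,000) is available as
`experiment_profile("paper")` and `default_config("paper")`. The package's
own demonstrations run much smaller: the `desk` profile (60×60, 50,000 /
20,000 updates, 5 replicates, prey levels ÷10) for a workstation-scale
re-run of the design, and the `analysis/` scripts smaller still (grids
24–28, Phase 1 ~15,000 updates, Phase 2 ~3,000 updates, 3 replicates) so
the complete chain — two EH treatments through PerMANOVA — finishes in tens
of minutes of single-threaded R. The test suite uses yet smaller arenas
chosen so each property is decidable in seconds. Headline full-scale
outcomes (which treatment wins 2-million-update competitions) are emergent
properties of long evolution and are not claimed at reduced scale; what the
reduced runs demonstrate is that every rule, metric and statistic of the
design operates and is reproducible.

## Known limitations

* The instruction architecture is deliberately reduced; absolute trait
  values (e.g. look proportions) are not comparable to a full virtual-CPU
  implementation, only their experimental contrasts are.
* Predator fixtures are scripted, not evolved; the aggressiveness knob is a
  stand-in for selection on realized sensor usage among evolved replicates.
* Organism lookup during `look`/`attack` scans the roster linearly — ample
  at desk-scale population sizes, quadratic-ish at full scale.
* `run_phase1` at reduced scale rarely fixes effective predation;
  realized-predator emergence statistics belong to the desk profile and
  larger.
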