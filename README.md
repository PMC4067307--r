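# digiprey

Agent-based digital evolution of anti-predator behavior, at desk scale.

## The problem

Can a population's capacity to evolve defenses against a novel predator be
predicted from its *evolutionary history* (EH — did it evolve where
predators could arise?) and its *standing genetic variation* (SGV — how
much genotype diversity does it start with)? Answering this with living
organisms takes thousands of generations; `digiprey` implements the
question as a digital-evolution experiment for researchers in experimental
evolution and behavioral ecology who want a fully controlled, fully
reproducible model system.

Self-replicating digital organisms carry instruction-sequence genomes over
a 60-symbol alphabet (10 behavioral instructions — movement, turning, a 45°
view-cone sensor, feeding, reproduction, attack, conditionals — plus 50
inert no-ops). They live on a bounded resource grid, execute 30 instruction
cycles per update, reproduce after consuming 10 resource units (offspring
genomes pass through a mutation-on-copy operator: at most one substitution,
at most one indel per reproduction), and can become predators by executing
the `attack` instruction, which kills the prey in the faced cell and
transfers 10% of its resource tally — but only while the prey count exceeds
a protection threshold.

The full three-phase experimental design is implemented:

1. **Phase 1** — open-ended evolution from 9 hand-written ancestors, with
   the attack instruction allowed (*predator* EH) or banned
   (*no-predator* EH), at rates 0.25/0.05/0.05 per reproduction.
2. **Phase 2** — prey purification (predators and latent attack
   instructions removed), SGV construction (*clone* / *intermediate* /
   *high*: 1 genotype, resampled with up-to-55-copy draws, or a verbatim
   duplicate), then evolution against a static (immortal, sterile) predator
   population at rates 0.001/0.005/0.005, calibrated so 500 generations of
   neutral accumulation give ~5% ancestor–descendant divergence.
3. **Phase 3** — mutation-free pairwise competitions (30·R pairings at R
   replicates; 900 at R = 30, each under predator-present and -absent
   treatments) and trait assays, both using a double-injection protocol
   onto a pre-conditioned resource landscape.

Metrics and statistics: Shannon diversity H = −Σ pᵢ ln pᵢ on genotype
tables; divergence = 100 − percent identity of a Needleman–Wunsch global
alignment (match +1, mismatch −1, gap −1); trait-proportion deltas
(post − pre proportions of moves/turns/looks per total instructions); and a
from-definition PerMANOVA (sequential sums of squares on the Gower-centred
distance matrix, pseudo-F, permutation p-values with 999 permutations).

## Worked example

Calibrate the Phase 2 mutation rates against their defining property —
about 5% neutral divergence after 500 generations:

```r
library(digiprey)
set.seed(101)
rates <- phase2_rates()
divs <- vapply(1:500, function(k) {
  anc <- sample.int(60L, 100L, replace = TRUE)      # random length-100 ancestor
  global_align(neutral_lineage(anc, 500L, rates), anc)$divergence
}, numeric(1))
mean(divs)
#> [1] 5.090604
```

Build the standing-variation treatments from a synthetic seed population
and check the designed diversity ordering:

```r
set.seed(72)
seed <- make_seed_population(1000, 200, abundance_model = "uniform")
sapply(c("clone", "intermediate", "high"), function(lev)
  shannon_diversity(genotype_table(make_sgv_population(seed, lev))))
#>        clone intermediate         high
#>     0.000000     3.184079     5.298317
```

`clone` populations start with zero diversity, `high` reproduces the seed's
H (= ln 200 ≈ 5.30 here), and `intermediate` lands in between — the three
starting conditions whose evolutionary consequences the competitions then
measure. A run of the full reduced-scale pipeline lives in `analysis/`
(numbered scripts: calibration, Phase 1, Phase 2, competitions, assays,
PerMANOVA), each writing CSV reports under `results/`.

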