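# cspdyn

Can two closely related species coexist in the same patch when they interfere
with each other's reproduction — misdirected courtship, heterospecific
matings, lost mating opportunities — but exhibit **conspecific sperm
precedence** (CSP), so that a doubly mated female fertilises with conspecific
sperm regardless of mating order? `cspdyn` is an R package for ecologists
studying that question. It combines three strands:

1. **A behaviourally explicit community model.** A female's mating history
   unfolds on a decision-making tree: suitors arrive by (activity-weighted)
   species frequency, virgins accept with probabilities `p`, once-mated
   females with probabilities `q`, and CSP grants full fecundity to any
   female with at least one conspecific mating. For at most two matings the
   probability of securing conspecific sperm has the closed form

   ```
   P_X = (p_XX + p_XY * q_XX * f_Y) * f_X / (f_X * p_XX + f_Y * p_XY)
   ```

   with frequencies `f`. Expected fecundity `E_X = [(1 - c) + c * P_X] * r`
   (niche overlap `c`, egg production `r`) feeds the ODE community dynamics

   ```
   dN_X/dt = [E_X(N_X, N_Y) - v * (N_X + b * N_Y)] * N_X
   ```

   The package finds equilibria, classifies their stability from Jacobian
   eigenvalues, computes invasion fitness `r * (1 - c - b)` — so stable
   exclusion requires `b + c > 1` — locates that boundary by bisection, and
   maps basins of attraction.

2. **Signal-detection analysis of mating trials.** From hit / miss /
   false-alarm / correct-rejection counts of male mating attempts and female
   rejection behaviour: log-linear-corrected rates, sensitivity `d'`, bias
   `beta`, criterion, binary-decision ROC/AUC, and an unpaired DeLong
   comparison of AUCs between species.

3. **A comparative summary** of 24 published species pairs with CSP,
   classified as sympatry, niche partitioning, parapatry or allopatry, plus
   seeded synthetic generators (individual-based decision-tree walks and
   mating-trial sessions) so every stage is testable from code alone.

## Worked example

```r
library(cspdyn)

probs <- example_mating_probs()          # asymmetric ladybird-like acceptance
pars  <- community_params(probs, c = 0.9) # high niche overlap

conspecific_mating_probability(probs, NX = 1, NY = 1, focal = "X")
#> [1] 0.4666667
expected_fecundity(pars, 1, 1)
#>   EX   EY
#> 13.0 20.5

stability_report(25, 0, pars)
#> boundary_X equilibrium at (25, 0): stable
#>   eigenvalues: -5+0i, -25+0i (residual 0)

invasion_fitness(pars, invader = "Y")
#> [1] -5
exclusion_boundary(pars, b = 0.3)
#> [1] 0.7000003
```

Read: at equal densities an X-female has only a 47% chance of securing
conspecific sperm (vs 80% for Y), so her expected fecundity drops to 13 of 25
eggs. With niche overlap 0.9 and competition 0.3 (`b + c = 1.2 > 1`) the
species-X-only state at density 25 is locally stable (both eigenvalues
negative) and a rare invader declines at per-capita rate 5; exclusion stops
being stable below the critical overlap `c* = 1 - b = 0.7`, which the
bisection recovers numerically.

The behavioural side, from the packaged mating-trial counts:

```r
counts <- read_counts(response_counts_file())
cc <- contingency_counts(47, 40, 10, 32)  # male attempts, 2014
sdt_statistics(cc)
#> d' = 0.793, beta = 1.265, criterion = 0.297 (H = 0.540, F = 0.244)
binary_auc(cc)$auc
#> [1] 0.6510673

category_summary(load_pairs())$by_category
#>           sympatry niche_partitioning          parapatry          allopatry
#>                  6                  9                  7                  2
```

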