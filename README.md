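# foodwebspectra

Do ecosystems that *evolved* look like the random matrices classically used
to argue about their stability?  `foodwebspectra` assembles food webs by
sequential invasion under generalised Lotka–Volterra (GLV) dynamics and
examines the eigenvalue spectra of the resulting community matrices, side
by side with a connectivity-matched sparse random-matrix null model.  It is
aimed at theoretical ecologists and complex-systems researchers studying
community stability, assembly and random matrix theory.

## Model

For producers $i$ and consumers $c$ (biomass normalised to the carrying
capacity of a single implicit nutrient source):

$$\dot S_i/S_i = k\big(1 - \textstyle\sum_{j\,\mathrm{prod}} S_j\big) - \alpha_i - \sum_p \eta_{pi} S_p,
\qquad
\dot S_c/S_c = \beta \sum_m \eta_{cm} S_m - \alpha_c - \sum_p \eta_{pc} S_p.$$

Invaders arrive one at a time at biomass $10^{-10}$ with random parameters
($\alpha \sim U(0.05,0.5)$, $\eta \sim U(0.01,1)$, $k = 1$); after each
arrival the web relaxes to a feasible state, with extinctions (biomass
$\le 10^{-12}$) resolved by event-detecting ODE integration.  Three
assembly modes control diet acquisition: **treelike** (one resource per
consumer), **non-omnivorous** (a second resource only at equal trophic
level) and **omnivorous** (any second resource).  The community matrix
$C = \mathrm{diag}(S^*)\,J$ at the analytic fixed point
$S^* = R^{-1}K$ supplies the spectra; the null model draws $N\times N$
matrices with diagonal $-1$ and off-diagonal $\mathcal N(0,1)$ entries
present with probability $p(N) = (N^2+21N-28)/(9N(N-1))$.

## Worked example

```r
library(foodwebspectra)

cfg <- assembly_config(mode = "omnivorous", beta = 0.75,
                       attempts = 2000, seed = 7)
h <- evolve(cfg)
h
#> <evolution_history> omnivorous, beta = 0.75: 2000 attempts, success rate 31.1%, final richness 6

m <- evolution_metrics(h)
round(m$richness_histogram, 3)
#>     1     2     3     4     5     6     7     8     9
#> 0.024 0.060 0.341 0.096 0.342 0.043 0.094 0.002 0.002
```

About 31% of invaders establish at this (short) run length, and the web
spends most attempts at *odd* species richness (3 and 5 here) — a pairing
effect of feasibility in webs fed by a single nutrient.  Pooling the
recorded spectra of webs with at least three species:

```r
ps <- pool_spectra(h, min_richness = 3)
purely_real_fraction(unlist(ps))
#> [1] 0.262
```

so roughly a quarter of the eigenvalues are purely real — the population
of strongly damped, non-oscillatory modes that forms the left peak of the
bi-modal real-part distributions of evolved webs
(`real_part_distribution()` scales each distribution to start at $-1$ for
comparison across richnesses; `ensemble_spectrum()` provides the uni-modal
random null).

The two-species building block is available in closed form and agrees with
the dense solver:

```r
w <- two_species_web(0.1, 0.2, beta = 1, eta = 0.5)
steady_state(w)$populations
#> [1] 0.4 1.0
community_matrix(w)$eigenvalues
#> [1] -0.2+0.244949i -0.2-0.244949i
two_species_eigenvalues(two_species_system(0.1, 0.2, beta_eta = 0.5))
#> [1] -0.2+0.244949i -0.2-0.244949i
```

A thin command-line front end (`inst/cli/foodwebspectra.R`) exposes
`evolve`, `random` and `analyze` subcommands over the same functions and
writes `events.csv`, `eigenvalues.csv`, `metrics.json` and JSON web
snapshots.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from fresh seeded simulations: the per-mode invasion success
rates at β = 0.75 (2×10⁴ attempts each), the minimum community-matrix
eigenvalue real part over 10⁴ random feasible two-species webs, the
purely-real eigenvalue percentage of pooled evolved spectra by species
richness (three modes × β ∈ {0.5, 0.75, 1}), and the percentage of
loop-allowing webs that are treelike.  Results are written as a flat JSON
object; the run takes on the order of ten minutes on one CPU.
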