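---
title: "Modeling inducible, reversible gene drives with revdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inducible, reversible gene drives with revdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revdrive)
```

## The model

`revdrive` models a CRISPR homing gene drive in a randomly mating,
infinite population with non-overlapping generations. Two alleles segregate
at the drive locus: wild type `W` and drive `D`, with frequencies
$q_W = 1 - q_D$. In a `W/D` heterozygote the drive nuclease cleaves the
wild-type allele and is copied across by homology-directed repair with
probability $e_W$, converting the individual to a `D/D` homozygote before
reproduction — the super-Mendelian transmission that lets a drive spread
from rare. No resistance alleles arise: failed conversion (probability
$1 - e_W$) simply leaves a heterozygote.

Selection acts through the relative fitness $f$ of the drive homozygote
(wild type $= 1$); the unconverted heterozygote has fitness $(1-h) + fh$
with dominance $h$ (default $0.5$, codominance). One generation of random
union, drive conversion and selection gives the recursion implemented by
`step_standard()`:

$$
q_D' \;=\;
\frac{f\,(q_D^2 + 2 q_W q_D e_W) \;+\; \bigl((1-h)+fh\bigr)\, q_W q_D (1-e_W)}
     {1 - (1-f)(q_D^2 + 2 q_W q_D e_W) - (h-fh)\, 2 q_W q_D (1-e_W)} ,
$$

whose denominator is the population mean fitness (`mean_fitness()`).

### Three reversal mechanisms

A drive released into the wild may need to be slowed or removed. The
package models an external signal — temperature, a small molecule, an
environmental cue — that reaches a fraction $\alpha$ of the population per
generation from a chosen start generation onward
(`induction_settings()`). Once applied, the signal stays on at the same
level. Three engineered responses are modeled:

1. **Inducible efficiency** (`"inducible_efficiency"`): responding
   individuals switch to a reduced homing efficiency $e_W'$. The recursion
   uses the population-average effective efficiency
   $e_{\mathrm{eff}} = \alpha\, e_W' + (1-\alpha)\, e_W$.
2. **Inducible fitness** (`"inducible_fitness"`): responders switch the
   drive-homozygote fitness to $f'$; the mixture
   $f_{\mathrm{eff}} = \alpha f' + (1-\alpha) f$ replaces $f$ everywhere,
   including inside the heterozygote fitness.
3. **Self-cleaving drive** (`"self_cleaving"`): the drive carries a
   regulated guide-RNA cassette targeting the drive cassette itself.
   Self-cleavage fires at rate $E = (1-\alpha)e_D + \alpha e_D'$, where
   $e_D$ is basal ("leaky") activation and $e_D'$ the induced rate.

### Genotype bookkeeping for the self-cleaving drive

In a heterozygote the self-cleavage reaction (rate $E$) and the homing
reaction (rate $e_W$) fire independently, giving four outcomes; a drive
homozygote adds two more:

| event | probability | resulting genotype |
|---|---|---|
| both drive and target cleaved | $E\,e_W$ | lethal (no intact copy of the locus) |
| only the drive cleaved | $E\,(1-e_W)$ | `W/W` — the wild-type homolog is copied back |
| only the target cleaved | $(1-E)\,e_W$ | `D/D` |
| neither cleaved | $(1-E)(1-e_W)$ | `W/D` |
| homozygote, both alleles excised | $E^2$ | lethal |
| homozygote, at most one excised | $1-E^2$ | `D/D` (repair templated by the intact drive allele) |

`step_self_cleaving()` forms the surviving pools
$DD = q_D^2(1-E^2) + 2q_Wq_D(1-E)e_W$,
$DW = 2q_Wq_D(1-E)(1-e_W)$,
$WW = q_W^2 + 2q_Wq_D E(1-e_W)$ and the lethal mass
$q_D^2E^2 + 2q_Wq_D E e_W$, then takes the fitness-weighted allele count.
This surviving-pool formulation was chosen because it conserves
probability exactly (the four masses always sum to one) and because each
term maps one-to-one onto the event table above; the enumeration oracle
below re-derives it independently. Two modeling choices worth making
explicit: a heterozygote whose drive is excised while the target stays
intact is scored as genetically wild type at full fitness, since
homology-directed repair restores the wild-type sequence; and a drive
homozygote with exactly one excised allele is repaired back to `D/D`
(fitness $f$) rather than penalized, because the intact homolog serves as
the repair template. The fully lethal corner ($q_D = 1$, $E = 1$) has zero
mean fitness; a frequency model cannot represent extinction, so the step
signals a classed `gd_degenerate_error` instead of returning 0/0 (the
guard triggers below $10^{-12}$).

## Parameters and defaults

| parameter | meaning | range | default |
|---|---|---|---|
| `e_W` | drive conversion efficiency per heterozygote | $[0,1]$ | — |
| `f` | drive homozygote fitness relative to wild type | $[0,1]$ | — |
| `h` | dominance of the fitness effect | $[0,1]$ | 0.5 |
| `e_W_induced`, `f_induced` | post-signal values of `e_W`, `f` | $[0,1]$ | baseline |
| `e_D`, `e_D_induced` | basal / induced self-cleavage rate | $[0,1]$ | 0 |
| `alpha` | fraction of individuals responding per generation | $[0,1]$ | — |
| `initial_q_D` | release frequency of the drive allele | $(0,1)$ | 0.001 |
| `fixation_threshold` | strict frequency cutoff declaring fixation | $(0.5,1)$ | 0.99999 |
| `max_generations` | simulation horizon | $\ge 1$ | 1000 |

The defaults are the package's standard study conditions: a 0.1% release
frequency represents a realistic small introduction, codominant fitness
costs are the conventional neutral assumption, and 1,000 generations with
a $>0.99999$ cutoff comfortably brackets the dynamics of every scenario of
interest. `h` is kept free (rather than hard-coded at 0.5) so dominance
edge cases can be exercised.

One convention is deliberately pinned: with the signal starting at
generation $g$, the transition that produces generation $g+1$ is the first
induced one — generations $\ge g$ are exposed. The fixation check is a
strict inequality applied after every update and also at generation 0.

## Running trajectories and sweeps

```{r trajectory}
p <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.1)
cfg <- simulation_config(p, variant = "inducible_efficiency",
                         induction = induction_settings(alpha = 0.9,
                                                        start_generation = 10))
tr <- run_simulation(cfg)
tr
```

The drive climbs for ten generations, then the induced efficiency drop
turns the tide and the wild type returns to fixation. Phase diagrams come
from `grid_sweep()`; `find_threshold()` bisects a single parameter for the
critical value at which the outcome flips:

```{r threshold}
th <- find_threshold("f", c(0.3, 0.7),
                     simulation_config(drive_params(e_W = 1, f = 0.5)))
th$value
```

With a perfect drive ($e_W = 1$) the drive invades only when $f$ exceeds
about $0.5$ — matching the linearised invasion condition below.

## Invasion diagnostics

Linearising a variant's recursion at $q_D \to 0$ gives the per-generation
growth factor of rare drive alleles,
$\lambda = 2 f_{\mathrm{eff}} e_{\mathrm{eff}} +
\bigl((1-h)+f_{\mathrm{eff}}h\bigr)(1-e_{\mathrm{eff}})$
(for the self-cleaving variant, multiplied by $1-E$); $\lambda > 1$
predicts invasion. `invasion_report()` reports $\lambda$ alongside the
classic favorability rule of thumb $f(e_W+1) > 1$ from earlier
individual-based drive models; the two are distinct diagnostics and the
package never conflates them. At $e_W = 1$, $h = 0.5$ both place the
boundary at $f = 0.5$; elsewhere they differ.

A caveat on finite horizons: close to the boundary, $\lambda \approx 1$
and the rare phase can consume more than the 1,000-generation default
horizon, so the *empirical* fixation boundary sits slightly above the
analytic one (at $e_W = 1$ by about $6 \times 10^{-4}$ in $f$). Threshold
comparisons should therefore be read against the bisection bracket plus
this horizon displacement, not as exact recoveries of $\lambda = 1$.

## Validation design

The closed-form steps are cross-checked against two independent routes:

- **Genotype enumeration** (`enumerate_pool()` /
  `oracle_next_frequency()`): explicit probability tree over genotype
  fates, with no shared algebra with the step functions. The test suite
  requires agreement within $10^{-12}$ over 10,000 random parameter draws
  for all four variants.
- **Wright–Fisher sampling** (`wright_fisher_step()`): binomial sampling
  of $2N$ alleles around the oracle's deterministic value; replicate means
  must converge to the deterministic step as $N$ grows
  ($N = 10^3 \dots 10^5$ in the tests).

Additional pinned properties: every step maps $[0,1]$ into itself (the
ratio is clamped against one-ulp floating-point excursions at the
boundaries); each inducible variant collapses bit-exactly onto the
standard recursion when nothing is induced; and a perfect cost-free drive
obeys the closed form $1 - q_n = (1-q_0)^{2^n}$, reaching the fixation
threshold from $q_0 = 0.001$ at generation 14.

The test suite runs its sweeps on coarse grids (up to $11 \times 11$) and
its stochastic checks at a few hundred replicates; these sizes give the
properties full coverage while keeping the default suite fast. The
101-point default of `axis_spec()` is intended for production phase
diagrams.

## Limitations

The model is deterministic and infinite-population: it has no drift, no
stochastic loss of a rare drive, and no notion of population size or
extinction (the all-lethal corner is reported as a degenerate condition,
not as suppression). It excludes resistance alleles (NHEJ products),
sex-specific or multi-locus inheritance, maternal deposition, spatial
structure, and pulsed or time-varying induction schedules — the signal is
a single step change held constant thereafter. Conclusions about real
releases should treat these trajectories as the mean-field skeleton that
finite, structured populations will scatter around.
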