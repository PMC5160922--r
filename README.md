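# metaenv

Inference-based microbial growth strategies in meta-changing nutrient
environments.

Microbes in hosts and other rich habitats face nutrient fluctuations that
mix randomness with structure: not only does the environment switch between
nutrients (say glucose and galactose), the *way* it switches changes over
time, driven by regimes the cells cannot observe — feeding versus fasting,
stable versus noisy stretches. `metaenv` treats adaptation to such
"meta-changing" environments as a problem of probabilistic inference and
provides, end to end:

* **Environment generators** — two- and three-nutrient Markov environments,
  and hidden-regime (switching-state) environments whose regime chain is
  parameterized by p1 = P(periodic → periodic) and p2 = P(constant →
  periodic).
* **A switching-state Bayesian model** with conjugate Dirichlet priors on
  all transition probabilities, collapsed so that inference tracks only
  transition counts; an exact enumeration oracle for the posterior
  predictive P(C_{t+1} | C_0:t); and the flat (no-hidden-state) Markov
  baseline.
* **A real-time particle filter** over hidden regimes with per-particle
  count statistics {s, **S**, **C**}, systematic resampling under an
  effective-sample-size trigger, and a Rao-Blackwellized predictive
  estimate.
* **Growth-policy fitness simulations** — posterior-predictive, plastic,
  random, constant (glucose-only) and bet-hedging policies, exponential
  growth with action lag k = 1 and zero mismatched growth, spline-based
  growth-rate estimation, and bootstrap confidence intervals.
* **Closed-form policy analysis** for two-nutrient Markov environments:
  R(π1) = V11[θ_Glu→Glu + θ_Gal→Glu], R(π2) = V22[(1−θ_Glu→Glu) +
  (1−θ_Gal→Glu)], the four-case adaptive rate R(π3), and the fold-change
  grid R(π3)/R(π1).
* **A molecular transition-counter circuit** — the eight-species mass-action
  network in which each sugar arms the sensor for the other, sensors and
  sugars reversibly form activators, and activators produce slowly degrading
  counter molecules whose plateaus store how many Glu→Gal and Gal→Glu
  switches have occurred.

Everything is tibble-first and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()` visualizations.

## Worked example

Simulate a meta-changing environment that mostly alternates glucose and
galactose but occasionally locks into constant glucose, run online
inference, and compare growth policies:

```r
library(metaenv)

meta <- two_state_glu_gal_spec(p1 = 0.9, p2 = 0.1)
env  <- sample_meta_env(meta, horizon = 200, seed = 42)

pf <- filter_sequence(env, model_spec(), n_particles = 200, seed = 1)
head(as.data.frame(pf), 3)
#>   t     p_Glu     p_Gal      ess
#> 1 1 0.5000000 0.5000000 200.0000
#> 2 2 0.5000000 0.5000000 200.0000
#> 3 3 0.3951389 0.6048611 192.0308

compare_policies(meta,
                 c("posterior_predictive", "plastic", "random", "constant"),
                 n_sims = 20, horizon = 200, seed = 7)
#>                 policy mean_rate     ci_lo     ci_hi n_sims
#> 1 posterior_predictive 0.4456988 0.4386837 0.4525106     20
#> 2              plastic 0.2512009 0.2282938 0.2740169     20
#> 3               random 0.2619736 0.2522341 0.2714690     20
#> 4             constant 0.4239556 0.4123645 0.4353781     20
```

The filter starts uniform (P(Glu) = 0.5) and updates as transitions
accumulate; `ess` is the effective sample size of the particle weights.
In the policy table, rates are e-folds per step: the inference-based
policy (0.446) beats constant glucose-tuning (0.424, which wastes every
galactose step), and both dominate plastic tuning (0.251, which with a
one-step lag chases the nutrient that just disappeared) and random tuning
(0.262).

The transition-counter circuit, driven by alternating 50-unit sugar
pulses (switches at t = 50, 100, 150):

```r
count_switches()
#>   direction final_level increment count
#> 1  GluToGal       0.952     0.479     2
#> 2  GalToGlu       0.476     0.479     1
```

The circuit's memory species record exactly 2 glucose-to-galactose and 1
galactose-to-glucose transitions, with a final level ratio of 2: the
chemistry implements the count statistics that collapsed Bayesian
inference needs.

A command-line front end over the same functions lives at
`inst/cli/metaenv.R` (subcommands `simulate-env`, `filter`,
`compare-policies`, `analytic-grid`, `circuit-sim`).

## Further reading

The methods vignette (`vignettes/metaenv-methods.Rmd`) documents the
generative model, the collapsed inference scheme and particle filter, the
growth and policy conventions, the circuit's rate-constant rationale, and
the package's numerical choices and limitations.
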