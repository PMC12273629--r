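# blastoabc

Compartment models of cell-fate allocation in the preimplantation mouse
embryo, with likelihood-free (ABC) inference.

## The scientific problem

Between the 8-cell morula (E2.5) and the late blastocyst (E4.5), the
mouse embryo allocates cells to three lineages: blastomeres (*B*) sort
into outer **trophectoderm** (*T*) or inner **unspecified ICM** (*C*),
and unspecified ICM cells then specify as **primitive endoderm** (*P*,
PrE) or **epiblast** (*E*, EPI). `blastoabc` models these allocations as
a small ODE system over cell numbers,

```
dB/dt = αB − βB
dT/dt = αT + (1−ρ)βB
dC/dt = αC + ρβB − η(C+E)^m C − ζP^l C
dP/dt = αP + η(C+E)^m C
dE/dt = αE + ζP^l C
```

where all host cells share a net per-capita growth rate α, blastomeres
differentiate at rate β with ICM bias ρ, PrE specification is induced by
FGF4 from unspecified ICM and EPI (rate η(C+E)^m), and EPI specification
is fed back positively by PrE (rate ζP^l). The exponents l, m ∈ {0,1,2}
encode no, linear, or nonlinear feedback.

A chimera extension adds donor embryonic stem cells (Fgf4+/+, *D⁺*, or
Fgf4−/−, *D⁻*) injected at the 8-cell stage: donors grow at their own
net rate α_D, Fgf4+/+ donors join the FGF4 induction term
(η(C+E+D⁺)^m), and donor crowding displaces host cells toward the TE by
shrinking the ICM bias to ρ₀ / (1 + a(D⁺+D⁻)^n). Nested variants
F / GF / FC / GFC switch differential growth (G) and crowding (C) on and
off around the FGF4 term (F).

Because real count data are single snapshots of embryos at unknown
developmental ages, models are fitted **in state space**: a three-term
summary statistic S measures (1) how close each observation lies to the
nearest trajectory point, (2) how well per-lineage maxima match, and
(3) whether blastomeres and unspecified ICM are exhausted by 48 h.
Posteriors come from ABC-MCMC (accept a move when S ≤ ε); competing
variants are compared by rejection-ABC Bayes factors (ratio of
prior-predictive acceptance rates at a common ε, read on the
Kass–Raftery scale). A Gillespie simulator realises the same reaction
network exactly, for checking that the deterministic model is an
adequate mean-field description at realistic (tens to hundreds of
cells) population sizes.

The package is aimed at quantitative developmental biologists who want
to fit, check, and compare this family of models on per-embryo lineage
counts — real or synthetic.

## Worked example

```r
library(blastoabc)

# the default parameterisation: alpha = 0.06/h, beta = 0.3/h, rho = 0.35,
# nonlinear feedbacks l = m = 2
p <- base_params()
tr <- solve_embryo(p)                 # 8-cell morula -> 48 h
round(trajectory_state(tr, 48), 1)
#>       B       T       C       P       E  D_plus D_minus
#>     0.0    92.6     0.2    31.7    18.0     0.0     0.0

asymptotic_te_fraction(base_params(rho = 0.35, zeta = 0, eta = 0))
#> [1] 0.6499996
```

A 48 h solve of the default model turns 8 blastomeres into ~142 cells:
65% trophectoderm, with the ICM fully resolved into 31.7 PrE and 18.0
EPI cells and essentially no blastomeres or unspecified ICM left — the
composition of a late blastocyst. With specification switched off, the
TE share converges to 1 − ρ = 0.65.

Inference on synthetic snapshot data:

```r
data <- generate_dataset(synthetic_spec(base_params(), n_embryos = 60,
                                        sampling = "cross_sectional",
                                        noise = "multinomial", seed = 1))
model  <- base_model_simulator(dt = 0.5)
priors <- default_base_priors()
eps <- calibrate_epsilon(model, data, priors, n_pilot = 1500,
                         quantile = 0.002, seed = 2)$epsilon
post <- abc_mcmc(model, data, priors,
                 abc_config(epsilon = eps, n_iterations = 30000,
                            seed = 3, burn_in = 3000))
round(posterior_median_params(post), 4)
#>  alpha   beta    rho   zeta      l    eta      m
#> 0.0583 0.4714 0.3170 0.0014 2.0000 0.0094 2.0000
```

The posterior median recovers the generating growth rate (0.0583 vs
0.06 /h) and both feedback exponents (l = m = 2, i.e. nonlinear
feedback), while β, ρ, ζ, η are identified more weakly — snapshots with
classification noise constrain their combinations rather than each one
individually.

Published-style model comparison from acceptance bookkeeping:

```r
bayes_factor(posterior_counts(500, 6289, 17300),
             posterior_counts(500, 105027, 17300),
             "PrE feedback", "no feedback")
#> ABC model comparison at epsilon = 1.73e+04
#>   PrE feedback: 500 / 6289 accepted
#>   no feedback: 500 / 105027 accepted
#>   Bayes factor (a/b) = 16.7 - positive evidence
```

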