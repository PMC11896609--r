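# flyAL

Individual fruit flies, even isogenic ones reared together, show stable
idiosyncratic odor preferences, and part of that individuality is already
visible in how their antennal-lobe projection neurons (PNs) encode odors.
`flyAL` is an R package for studying how developmental noise in the
antennal-lobe circuit could produce that physiological individuality. It
provides:

- a **leaky-integrate-and-fire (LIF) network simulator** for the antennal
  lobe, parameterized by a connectome-style synapse-count matrix, with
  class-specific electrophysiology for olfactory receptor neurons (ORNs),
  local neurons (LNs) and PNs, templated action potentials, exponential
  postsynaptic currents, and odorant-response-driven ORN spike input;
- **idiosyncrasy generators** that create simulated individual flies by
  bootstrapping cell populations (ORNs and PNs glomerulus-by-glomerulus,
  LNs as a single pool) or by resampling each glomerulus's PN input-synapse
  density from the volume–synapse power law
  `log S_g = log(a V_g^d) + eps`, `eps ~ N(0, sigma^2)`
  (a = 8.98, d = 0.73, sigma = 0.38);
- **population analyses**: PCA over glomerulus–odor response features, a
  glomerular organization index (GOI) for PCA loadings, linear preference
  models (e.g. `preference = beta0 + beta1 * PC2` with the published
  coefficients −0.058 and −0.081), linear-logistic decoding with twofold
  cross-validation, and within/across-individual response distances;
- **latent-correlation inference**: a simulation-based correction of an
  observed calcium–behavior R² for measurement repeatability. Latent states
  are mixed at `r_latent`, noisy readouts at `r_c = (R²_cc)^(1/4)` and
  `r_b = (R²_bb)^(1/4)`, and the posterior over `R²_latent` is accumulated
  by inverting simulated observed-R² distributions over a grid;
- **synthetic-data generators** for glomerularly organized connectomes,
  DoOR-style bounded odorant-response matrices with missingness, glomerular
  volumes, and paired calcium/behavior datasets with known ground truth —
  so the entire pipeline runs and is tested without any external download.

The core model integrates, for each neuron `i` below threshold,

    C_i dV_i/dt = (V_{i,0} − V_i)/R_i + I_odor,i(t) + Σ_j a_i W_ji I_j(t)

where `W_ji` are signed synapse counts and `a_i` is a hand-tuned,
class-specific sensitivity (0.1 for ORNs, 0.04 for excitatory LNs, 0.02
for inhibitory LNs, 0.4 for PNs). Odor input drives ORNs as an
inhomogeneous Poisson process with rate
`FR = FR_max · D · (f_a + (1 − f_a) e^{−t/t_a})`
(`FR_max` = 400 Hz, `f_a` = 0.75, `t_a` = 110 ms; 10 Hz spontaneously).

## Worked example

```r
library(flyAL)

cf <- canonical_fixture()        # tuned 8-glomerulus synthetic AL
resp <- run_odor_panel(cf$weights, cf$door, cf$protocol, seed = 1)
resp
#> <al_response> 8 glomeruli x 12 odors; mean PN rate 102.8 Hz

validate_al_model(resp)
#> # A tibble: 5 x 4
#>   criterion                    value reference                     pass
#>   <chr>                        <dbl> <chr>                         <lgl>
#> 1 orn_baseline_rate          10.4    5-20                          TRUE
#> 2 pn_evoked_rate             94.5    10-200                        TRUE
#> 3 pn_more_uniform_than_orn   -0.0928 < 0 (PN Gini below ORN Gini)  TRUE
#> 4 pn_more_separated_than_orn  0.0359 > 0 (PN separation above ORN) TRUE
#> 5 sublinear_transfer          0.942  < 1                           TRUE
```

The report says the simulated circuit reproduces the canonical
antennal-lobe computations: ORNs rest near 10 Hz, odor-evoked PN rates sit
in the physiological range, PN rates are distributed more uniformly than
ORN rates, PN odor representations are more separated than ORN ones, and
the ORN-to-PN transfer function is sublinear (gain-compressing).

Simulated individuals and the organization of their variability:

```r
pop <- simulate_al_population(cf$weights, cf$door, cf$protocol,
                              n_flies = 100, mode = "orn",
                              volumes = cf$volumes, seed = 11)
population_goi(pop)
#> # A tibble: 1 x 3
#>     goi     se     n
#>   <dbl>  <dbl> <int>
#> 1 0.812 0.0112   100
```

A GOI of 0.81 means that, under ORN-population bootstrapping, 81% of the
loading energy of the leading PCs of PN responses is organized by
glomerulus — the signature seen in recorded flies — versus about 0.15 under
pure Poisson spike-timing variation.

Latent-correlation inference from a paired dataset:

```r
pd <- generate_paired_dataset(N = 69, r2_latent = 0.5,
                              r2_cc = 0.77, r2_bb = 0.12, seed = 1)
avg <- impute_and_average(pd$calcium)
score <- as.matrix(avg[, -1]) %*% pd$truth$loadings
obs <- as.numeric(cor(score, pd$behavior$measurement_1))^2
obs
#> [1] 0.0427
infer_latent(obs, repeatability_estimate(0.77),
             repeatability_estimate(0.12), N = 69, seed = 1)
#> <latent_inference> median R^2_latent = 0.123 (90% CI 0.002-0.476), N = 69
```

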