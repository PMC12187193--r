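# respscope

Individual-level aerobic performance phenotyping of fish from
intermittent-flow respirometry.

Ectotherm populations are not metabolically uniform: measured repeatedly
across a temperature gradient, some individuals sustain a wide aerobic
scope at every treatment ("high performers") while others collapse
outside a narrow optimum. `respscope` implements the full analysis chain
for classifying such phenotypes: raw chamber-oxygen traces → per-cycle
oxygen-consumption rates → per-individual standard metabolic rate (SMR),
maximum metabolic rate (MMR) and aerobic scope (AS) at each test
temperature → a percentile rank-score that buckets each individual as a
low, intermediate or high aerobic performer. A seeded simulator with
known thermal performance curves stands in for raw laboratory data, so
every stage is testable by parameter recovery.

## The method in brief

Each closed (measurement) phase of an intermittent-flow run yields one
rate via

```
RO2 = ((Vre − M)/W)·(|ΔO2a/Δt|·60) − ((Vre − M)/W)·(|ΔO2b/Δt|·60)·(Vre/(Vre − M))
```

(chamber volume `Vre` in l, fish mass `W` in kg, displacement `M` in l,
animal and fishless-chamber O2 declines in mg·l⁻¹·min⁻¹; slopes by OLS
after excluding the first minute, kept only when R² > 0.9). Per
individual × temperature, SMR is the 0.2 quantile of the 24-h run's
rates, MMR the single highest post-chase recovery rate, and AS = MMR −
SMR. Rates are temperature de-trended with the Boltzmann factor
`e^(−E/kT)` (E = 0.63 eV) before the allometric exponent is fitted by
ln–ln regression of rate on mass, and indices are reported as
`RO2 / M^a`. Each individual then scores 1–4 points per temperature
against fixed per-temperature AS percentile cutoffs (25th/50th/75th of
the species' scope range), the three scores are summed (3–12), and the
total classifies the phenotype: ≤ 5 low, 6–9 intermediate, ≥ 10 high.

## Worked example

Simulate a tiny three-fish cohort (one individual per archetype,
deterministic parameters, realistic sensor noise) and run the whole
chain:

```r
library(respscope)

cfg <- pipeline_config(
  mode = "synthetic", seed = 42,
  n_per_archetype = c(high = 1, intermediate = 1, low = 1),
  randomize = FALSE, alpha = -0.2,
  trace = trace_config(noise_sd_mg_l = 0.005, sample_interval_s = 30)
)
res <- run_pipeline(cfg)
res$indices[, c("individual_id", "treatment_temp_c", "smr", "mmr", "aerobic_scope")]
#> # A tibble: 9 × 5
#>   individual_id treatment_temp_c   smr   mmr aerobic_scope
#>   <chr>                    <dbl> <dbl> <dbl>         <dbl>
#> 1 hig_01                      10 0.687  6.18         5.49
#> 2 hig_01                      16 1.05   6.67         5.62
#> 3 hig_01                      21 1.42   6.38         4.96
#> 4 int_01                      10 0.692  3.76         3.07
#> 5 int_01                      16 1.06   4.85         3.79
#> 6 int_01                      21 1.45   4.16         2.72
#> 7 low_01                      10 0.698  1.74         1.04
#> 8 low_01                      16 1.06   3.36         2.30
#> 9 low_01                      21 1.49   2.21         0.725

res$scorecards
#> # A tibble: 3 × 6
#>   individual_id score_16 score_10 score_high total phenotype
#>   <chr>            <int>    <int>      <int> <int> <chr>
#> 1 hig_01               4        4          3    11 high
#> 2 int_01               4        2          1     7 intermediate
#> 3 low_01               2        1          1     4 low
```

Indices are per-minute mass-corrected rates (the scale of the packaged
cutoffs). The high-performer keeps AS near 5–5.6 at all three
temperatures (scores 4/4/3, total 11 → high), the low performer's scope
collapses away from 16 °C (2/1/1, total 4 → low). SMR rises with
temperature in every fish, as it should under Q10 kinetics.

Real data enter through the same pipeline with `mode = "files"` and a
long-format trace CSV (`individual_id, treatment_temp_c, time_s,
o2_mg_l, phase, chamber_volume_l, fish_mass_kg, displacement_l`); a thin
command-line wrapper lives in `exec/respscope` (subcommands `simulate`,
`pipeline`, `score`, `summarize`).

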