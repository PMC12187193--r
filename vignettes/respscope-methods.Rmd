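---
title: "Methods: from oxygen traces to aerobic performance phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to aerobic performance phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respscope)
```

## The measurement model

Intermittent-flow respirometry alternates closed ("measure") phases, in
which a fish depletes the oxygen of a sealed chamber, with flush phases
that restore saturation. During a closed phase the chamber concentration
falls approximately linearly, and the whole-animal mass-specific oxygen
consumption rate of one cycle is

$$
R_{O_2} \;=\; \frac{V_{re}-M}{W}\left(\frac{\Delta[O_{2a}]}{\Delta t}\times 60\right)
\;-\;\frac{V_{re}-M}{W}\left(\frac{\Delta[O_{2b}]}{\Delta t}\times 60\right)\frac{V_{re}}{V_{re}-M},
$$

with chamber volume $V_{re}$ (l), fish mass $W$ (kg), displacement volume
$M$ (l; tissue density is taken as 1 kg l$^{-1}$, so $M = W$ numerically),
the animal-cycle decline $\Delta[O_{2a}]/\Delta t$ and the
fishless-chamber (microbial) decline $\Delta[O_{2b}]/\Delta t$, both in
mg l$^{-1}$ min$^{-1}$. Slopes are fitted by ordinary least squares on
time in minutes, so the factor 60 converts to mg O$_2$ kg$^{-1}$
h$^{-1}$; both slopes enter as magnitudes of decline so a consuming fish
yields a positive rate. `ro2()` implements this literally; its two linear
coefficients, $((V_{re}-M)/W)\cdot 60$ in the animal slope and
$-(V_{re}/W)\cdot 60$ in the background slope, are asserted as an
invariant in the tests.

Three quality rules precede the rate equation, mirroring standard
practice: the first minute of each closed phase is excluded from the fit
(mixing transient), a cycle is retained only when its fit has
$R^2 > 0.9$ (strict inequality), and cycles with fewer than three
retained samples are marked unusable — a state distinct from failing the
$R^2$ filter. For a zero-variance (flat) cycle, $R^2$ is defined as 0, so
flat traces fail the filter instead of passing it vacuously; this
convention is ours, chosen as the conservative reading.

## From cycle rates to SMR, MMR and aerobic scope

For each individual $\times$ temperature, SMR is the 0.2 quantile of the
24-h run's cycle rates, computed by linear interpolation of order
statistics at rank $h = q(n-1)$ (R's type-7 quantile; the worked value
for rates $1\ldots10$ is 2.8). The phrase "lowest 20 %" admits another
reading — the mean of the lowest fifth — and that estimator is exposed as
`smr_method = "mean_lowest_20"`, but the quantile is the default. MMR is
the single highest cycle rate of the post-chase recovery run. Aerobic
scope is $AS = MMR - SMR$; negative scope (possible at temperatures
outside an individual's performance window) is flagged, never clamped or
dropped, because the scoring stage needs complete triples.

Two corrections sit between raw rates and reported indices:

* **Temperature.** Rates are multiplied by the Boltzmann factor
  $e^{-E/kT}$ with $E = 0.63$ eV (the average activation energy of
  ectotherm metabolism), $k = 8.617333\times10^{-5}$ eV K$^{-1}$ and $T$
  in kelvin. The factor is applied exactly as written: its absolute
  scale is $\sim 10^{-11}$ and only the relative factor across
  temperatures matters, because the corrected values are used solely to
  de-trend temperature before the allometric regression. The
  conventional reference-normalized form
  $e^{(E/k)(1/T - 1/T_{ref})}$ (which actually flattens an
  Arrhenius-shaped series; the literal form steepens it) is exposed as
  `boltzmann_mode = "reference_normalized"`, but the literal form is the
  default because fidelity to the published procedure takes precedence
  over convention.
* **Body mass.** The allometric exponent $a$ is the OLS slope of
  $\ln(\text{rate})$ on $\ln(\text{mass})$, pooled over SMR and MMR
  values at all temperatures (per-kind estimation is available; the
  pooling level is our choice, as is applying the final correction
  $MO_2 = RO_2 / M^a$ to the *raw* rather than temperature-scaled rates —
  reported indices visibly retain their temperature dependence, which
  rules out a persistent Boltzmann factor).

The reported unit scale defaults to per-minute (`unit_scale`), the scale
on which the packaged classification cutoffs are expressed; the rate
equation's native scale (mg O$_2$ kg$^{-1}$ h$^{-1}$) is a switch away,
and cutoffs are always interpreted on the reported scale.

## The rank-scoring classification

Classification uses fixed per-temperature aerobic-scope cutoffs — the
25th/50th/75th percentiles of the scope range available to the species —
packaged as `table1_cutoffs()`:

```{r}
table1_cutoffs()
```

All three rows are exactly evenly spaced, which identifies the cutoffs
as linear interpolation over a (min, max) scope range;
`cutoffs_from_range()` reproduces each row from its implied range (for
example the 16 °C row from (0.9, 4.3)). Empirical per-cohort quantiles
are available through `cutoffs_empirical()` and the choice is recorded
in the `provenance` column. An individual scores 1–4 points per
temperature (lower-inclusive half-open bands: a value exactly on a
cutoff takes the higher score — our tie-break, chosen to keep the score
monotone and total), the three scores are summed (3–12; the 21 °C and
24 °C treatments share one pooled cutoff row and contribute exactly one
high-temperature score), and the total classifies the individual:
$\le 5$ low, 6–9 intermediate, $\ge 10$ high. The integer thresholds are
the rounded 25th/75th percentiles (5.25, 9.75) of the achievable
interval $[3, 12]$. Individuals missing a temperature are flagged and
excluded, never imputed.

## What the simulator emulates

`simulate_trace()` inverts the measurement model: an individual's
instantaneous mass-specific rate sets the chamber decline
$r \cdot W / ((V_{re}-M)\cdot 60)$ plus the microbial background, with
i.i.d. Gaussian sensor noise per sample. Consumption is integrated
analytically within each closed phase, so noiseless constant-rate phases
are exactly linear and oxygen is conserved to machine precision — both
are tested invariants. The protocol constants mirror the study design:
a 29.72-l chamber, 5-min measure / 15-min flush (3/17 at treatments
$\ge 21$ °C), a 24-h SMR run, a ~5-h post-chase recovery run, a 3-h
fishless background run, and treatment temperatures {10, 16, 21} with an
option to assign individuals to 24 °C instead of 21.

An individual's "true" phenotype is a Q10 curve for SMR (default Q10
drawn around 2, anchored at the 16 °C acclimation temperature) and a
Gaussian thermal performance curve for MMR — the simplest forms that
produce unimodal scope curves. The 24-h run modulates SMR with a diel
sinusoid (`circadian_amp`, drawn 0.04–0.12); the recovery run decays
exponentially from MMR toward SMR with time constant `tau_recovery_s`
(drawn 2–3 h, so the ~5-h protocol ends near SMR and the first fitted
cycle — minutes 1–5 — underestimates the programmed MMR by under 2 %).
The chase itself is not simulated (the fish is out of the chamber);
recovery traces begin at chamber re-entry. Flushes reset concentration
to saturation instantaneously, because the processing chain only ever
reads closed phases. Noise is white; real sensor noise is mildly
autocorrelated, and real declines can curve when mixing is imperfect, so
passing recovery tests here demonstrates correctness of the chain, not
robustness to every pathology of field data.

Between-individual heterogeneity comes from three archetypes: high
performers (high MMR peak, broad curve), low performers (low peak,
narrow curve) and intermediates. Archetype parameters are drawn
uniformly from fixed ranges, with the peak aerobic scope drawn directly
(per-minute units at reference mass) so that the 2–3-fold
between-individual variation in the scope trait — an individual's peak
scope across test temperatures — holds by construction; a draw is
accepted only if its true scope triple, scored against the packaged
cutoffs, classifies into the intended archetype. Rejection makes the
truth-level class proportions of a simulated cohort exact, so cohort
recovery tests isolate the measurement chain rather than the sampling
noise of the draw. One structural limitation is worth knowing: a
Gaussian MMR atop a Q10 SMR cannot produce a *flat* scope profile
(the log of `Q10-SMR + const` is convex in temperature while a Gaussian
log-MMR is concave), so archetype scope profiles are humped rather than
flat.

Body masses are uniform on 0.6–2.0 kg (the plausibility band implied by
a 20–70 g:ml fish-to-chamber ratio in a 29.72-l chamber), and
mass-specific rates carry a planted allometric factor
$M^{-0.2}$ (whole-animal scaling $\sim M^{0.8}$). Displacement volume is
mass at density 1 kg l$^{-1}$.

## Verification cohorts and numerical choices

The deterministic verification cohort (`randomize = FALSE`) takes every
parameter at its range midpoint, switches the diel modulation off, and
assigns the fixed mass series 1.2/1.5/1.8 kg in draw order. With equal
archetype sizes in multiples of three, each archetype sees the same
masses, mass is orthogonal to archetype and temperature by balance, and
the pooled ln–ln regression recovers the planted exponent exactly in the
noiseless case — the package's recovery tests show SMR within 0.1 %, MMR
within 2 % (the residual is the within-cycle recovery decay), and scope
rank order preserved at every temperature. The masses sit in the upper
half of the plausible range because at 10 °C a small fish's decline is
shallow enough that realistic sensor noise pushes cycle fits under the
$R^2$ filter wholesale; heavier verification fish keep the noisy-case
(0.01 mg l$^{-1}$) recovery within 10 % without touching the filter.

A three-fish cohort cannot support the pooled allometric regression at
all — archetype and mass are perfectly confounded — so the small fixture
cohorts fix the exponent at its planted value (`alpha = -0.2`), and
estimation is exercised on nine fish and upward. At the study's size
(44 fish) the estimate's spread is about $\pm 0.07$, which the
classification margins absorb.

Problem sizes in the tests and acceptance script are chosen to keep a
full run on one CPU in minutes: traces are sampled at 5-s intervals for
single-trace and 9-fish checks, and at 30 s for the 44-fish
classification-recovery runs (30 s is the coarsest grid that leaves the
3-min high-temperature cycles with enough points after the first-minute
exclusion). Sampling density is not a sensitive parameter for any
reported quantity; it only trades precision of individual slope fits
against run time.

## Degenerate inputs and edge handling

* Unlabelled traces segment by an explicit measure/flush schedule, or
  fail loudly.
* A simulated configuration whose concentration would cross 0 mg l$^{-1}$
  within a closed phase (implausible chamber-to-fish ratio) is rejected
  at generation time.
* Background exceeding the animal signal yields a negative rate,
  emitted with a warning and a flag.
* Cutoffs must satisfy $c_{25} < c_{50} < c_{75}$; degenerate empirical
  cutoffs (tied quantiles) are an error rather than a silent collapse.
* In the trace CSV dialect, time must increase strictly within a run; a
  reset to zero starts a new run, anything else is an error with the
  offending sample index.

## Known limitations

The simulator's white noise and instantaneous flushes idealize real
loggers; the packaged cutoffs apply to one species and one scope range,
and recomputing them from a different cohort changes the classification
(the `provenance` field exists to keep that visible); and the literal
Boltzmann factor is a faithful transcription, not an endorsement — users
standardizing to a reference temperature should switch
`boltzmann_mode`. Linear mixed-model analysis of the resulting indices
is deliberately out of scope: the indices tables are shaped for export
into any general statistics tool.
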