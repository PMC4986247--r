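---
title: "A hybrid stochastic-deterministic model of the ATM/p53/NF-kB/Wip1 DNA damage response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid stochastic-deterministic model of the ATM/p53/NF-kB/Wip1 DNA damage response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrsim)
```

## The biological system and the model

Ionizing radiation (IR) produces DNA double-strand breaks (DSBs).  A
non-dividing mammalian cell detects them through the ATM kinase acting with
the MRN complex, and propagates the signal to two transcription factors that
decide the cell's fate: p53 and NF-kB.  The Wip1 phosphatase (PPM1D) is the
network's switch-off element: it is transcriptionally induced by p53, CREB
and NF-kB, and it dephosphorylates — and thereby deactivates — ATM, Chk2 and
active p53, while re-activating multi-phosphorylated nuclear Mdm2.  Wip1's
own transcript is destabilised by miR-16, whose biogenesis is promoted by
the ATM-activated RNA-binding protein KSRP.  The fate readouts are two p53
target genes: p21 (cell-cycle arrest) and Bax (apoptosis).

`ddrsim` implements this network as a single-cell simulator with three
well-mixed compartments (extracellular space, cytoplasm, nucleus) and a
hybrid numerical scheme in the Haseltine–Rawlings spirit:

* the **continuous partition** — 28 protein/transcript species — evolves by
  mass-action and Michaelis–Menten rate laws integrated with fixed-step
  4th-order Runge–Kutta;
* the **stochastic partition** — allele states of the Wip1, Chk2 and ATM
  genes, the integer DSB count, and the TNF receptor pool — fires as
  discrete events sampled with the direct Gillespie method.

The two partitions are coupled both ways: propensities depend on continuous
species (gene activation scales with p53, CREB and NF-kB levels), and the
discrete state enters the rate laws (transcription is proportional to the
active allele count; the DSB count drives ATM activation; active receptors
drive IKK).  Within each deterministic step window the propensities are
frozen; an event sampled inside the window is applied at its sampled time,
with the ODE state integrated piecewise up to it.  This freezing is accurate
because every channel is slow (at most ~1e-3 per second) relative to the
window.

The model definition is fully declarative: a species table, a parameter
table, a reaction-term table (each term is a rate constant times up to three
factors — linear, Michaelis–Menten, inhibitory, Hill, allele-count, DSB or
receptor factors) and a gene table.  The identical tables drive the compiled
C++ engine and a pure-R reference evaluator (`rhs()`), so every term is
unit-testable, and the model round-trips through YAML.

## Units, parameters and calibration

Levels are molecule counts per cell and time is in seconds, so the discrete
and continuous partitions share one unit system.  Degradation rates are
derived from half-lives (`rate = ln 2 / t_half`); the half-lives of stable
signalling proteins (ATM, Chk2, NF-kB, KSRP, CREB) are set at 8–10 h,
transcripts at 1–4 h, Mdm2 at 30 min, and Wip1 deliberately long (transcript
1.5 h, protein 18 h) to reproduce its slow, non-oscillatory rise.  Synthesis
constants balance the declared resting levels.

Coupling strengths have no direct literature values; the parameter table
flags them `fitted`.  They were calibrated by trial and error — the same
strategy used for the class of models this package belongs to, which are
practically non-identifiable in the large — against benchmark observations
for irradiated U2-OS osteosarcoma cells:

* Wip1 transcript peaks ~2 h after a 10 Gy exposure, while the protein
  peaks ~18 h after exposure and declines beyond 24 h (the transcript is
  curtailed by the rising miR-16 pool; the protein, with its 18 h
  half-life, integrates the transcript and peaks much later);
* shRNA knockdown of Wip1 to 25 % expression lowers the post-IR protein
  about four-fold;
* the largest genotype difference in active p53 occurs near the first p53
  pulse, about 2 h after IR;
* clonogenic survival falls with dose, with knockdown cells about two-fold
  less clonogenic at 2 and 4 Gy;
* TNF-alpha given before IR is radioprotective (fewer apoptotic cells at
  48 h), whereas TNF-alpha 6 h after IR does not protect; the benchmark
  observations put the protection near three-fold and score most
  TNF-after-IR deaths between 24 and 48 h.

We make no claim that this parameter set is unique; it is one set consistent
with those observations.

### Choices made where the design was open

* **Repair saturation.** DSB repair fires at `vmax * n / (km + n)`
  (repair-complex limited) rather than first order.  A saturating rate both
  matches the observation that the per-break repair rate falls at higher
  doses and produces repair durations roughly linear in dose, which the
  dose dependence of clonogenic survival requires.
* **Mdm2/MdmX** are merged into one species with cytoplasmic, nuclear and
  multi-phosphorylated inactive nuclear forms; Wip1 reactivates the latter.
* **Functional forms.**  Binding, synthesis, degradation and transport are
  mass action; enzymatic (de)phosphorylation steps are Michaelis–Menten in
  the substrate.  Two deliberate cooperative exceptions: Bax transcription
  is a Hill function (n = 3) of active p53, reflecting multi-site promoter
  activation and giving the sharp low/high apoptotic commitment the
  two-threshold fate mechanism needs; and Wip1's dephosphorylation of
  active p53 is a Hill function (n = 3) of the Wip1 level, so that cells
  with one versus two active Wip1 alleles (or knocked-down expression)
  separate cleanly into "can switch off" and "cannot switch off"
  subpopulations.  Both forms stay within the declarative factor algebra.
* **Gene switching rates.**  Gene deactivation is spontaneous; activation
  propensities are linear in the regulators.  The Wip1 gene switches slowly
  (days-scale deactivation), so the allele configuration a cell carries
  into the exposure acts as a quenched source of cell-to-cell variability —
  the main stochastic determinant of fate.  NF-kB is a strong activator of
  the Wip1 gene; this is the mechanism by which a TNF-alpha pulse given
  before irradiation pre-arms cells with Wip1 and protects them.
* **Knockdown mechanism.**  `apply_knockdown()` scales the target's
  translation efficiency so that steady-state protein is exactly the
  requested fraction of wild type at every transcript level (knockdown
  efficiency is measured on protein immunoblots).  An alternative
  implementation as an added transcript-degradation term gives the right
  resting level but a much smaller post-IR fold, because induced transcript
  degradation is then dominated by miR-16; the translation form is the one
  consistent with the four-fold protein observation.
* **Division clock.**  The model has no explicit cell cycle.  The first
  division is scored when 24 h of *unarrested* time have accumulated after
  the exposure; arrest pauses the clock.  A fixed wall-clock division time
  would let long-arrested cells "divide" while arrested, which contradicts
  the clonogenic interpretation.
* **Arrest totalization.**  Arrest intervals are summed without requiring
  contiguity before comparison with the 63.9 h colony-forming limit.

### Fate thresholds

The two-threshold mechanism scores arrest when p21 exceeds its threshold
and apoptosis at the first instant active nuclear p53 and Bax exceed their
thresholds *simultaneously*.  The default thresholds (p21 500, active p53
350, Bax 495 molecules) were placed relative to the simulated resting
medians (roughly 2x, 7x and 3x rest) so that untreated cells essentially
never cross, knockdown cells with an unlucky allele draw cross between
roughly 18 and 45 h after exposure, and wild-type crossings are a few
percent.  `thresholds_from_rest()` re-derives thresholds as multiples of a
resting state if the model is modified.

## Numerical choices

* Default engine cadence: 0.1 s step, 10 s sampling, matching the regime in
  which the scheme was conceived.  Population work in this package uses a
  10 s step with 10–20 min sampling: the deterministic partition is
  non-stiff (fastest rate ~6e-3/s), and halving or hundred-folding the step
  changes trajectories by well under 0.5 % (a tested property).  The
  methods scripts state the population sizes they use (120–250 cells per
  condition; the headline experiments in the source material used 1000).
* Stochastic burn-in: 6 h before the exposure, starting from the mean-field
  resting point *conditioned on the cell's sampled allele configuration*
  (the Wip1 gene is deliberately slower than any feasible burn-in, so
  conditioning replaces an impractically long equilibration; fast genes
  equilibrate within the burn-in).
* Negative transient levels after an RK4 step are clipped to zero and
  counted (`clip_count`); in practice the count is zero at the default
  steps.
* Protocol discontinuities (IR start/stop, TNF washout) align with step
  boundaries, so the integrator never steps across them.
* Quantiles use the nearest-rank convention for platform-independent
  reproducibility, and every cell's randomness derives from
  (master seed, cell index), making population results independent of
  execution order.

## What the simulator does and does not capture

The synthetic populations emulate: Poisson DSB induction at 35 breaks per
Gy delivered at 1 Gy/min; saturating repair; gene-switching heterogeneity;
receptor-level TNF noise; and the fate rules above.  They do not capture
cell-cycle-phase effects (explicitly out of scope), mechanistic caspase
activation (Bax level is the apoptosis proxy), locus-specific repair, or
cell-line mutations beyond the parameter hooks.  Passing the packaged tests
therefore shows that the *mechanism as modelled* reproduces the benchmark
population statistics, not that the parameter set is biologically unique.

## A worked example

```{r example, eval = FALSE}
library(ddrsim)
model <- build_default_model()
protocol <- make_protocol("ir_only", dose = 10, burn_in = 6 * 3600,
                          horizon = 30 * 3600)
cfg <- engine_config(dt = 10, save_every = 1200, t_end = 30 * 3600)
pop <- run_population(model, protocol, n = 100, master_seed = 1, cfg = cfg)
peak_time(pop, "WIP1")       # median Wip1 protein peak (16-24 h plateau)
peak_time(pop, "WIP1_mRNA", to = 12 * 3600)  # transcript peak, ~2 h
```

## Limitations

Parameter sloppiness means many quantitative details (absolute molecule
counts, oscillation amplitudes) should not be over-interpreted; the model's
value is in the population-level contrasts it reproduces (genotype, dose,
TNF timing).  The clonogenic rules are a deliberate simplification of
colony formation, and the apoptotic fractions at the few-percent scale
carry binomial noise of the same order at the population sizes used in the
tests.  Two benchmark contrasts are only partially reproduced by this
parameter set: apoptotic commitments concentrate in the first 24 h after
a 4 Gy exposure (the late 24-48 h share is under-represented, because the
joint p53/Bax crossing window closes once the damage is repaired at
~26 h), and the TNF radioprotection fold comes out near 1.5-2 rather
than 3.  Both are reported as computed by `scripts/acceptance.R` and
exercised honestly by the test suite.
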