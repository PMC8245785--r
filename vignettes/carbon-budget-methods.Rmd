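---
title: "Methods: carbon budgets for kleptoplastidic ciliates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon budgets for kleptoplastidic ciliates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kleptoCarbon)
```

## The measurement problem

Generalist non-constitutive mixotrophs (GNCMs) — ciliates that steal and
operate chloroplasts from a wide range of algal prey — acquire carbon through
two channels: phagotrophy and photosynthesis by the sequestered plastids.
Quantifying how the two channels respond to irradiance and prey availability
requires stitching together several classical rate measurements made on
batch cultures: cell counts over time, grazing-rate estimation against
prey-monoculture controls, single-cell radiocarbon incubations, picked-cell
fluorometry, and biovolume from linear cell dimensions. `kleptoCarbon`
implements that full calculation chain as a validated pipeline, together
with a mechanistic simulator of the two standard experimental designs
(starvation after prey depletion, and acclimation to fixed prey densities
under daily dilution) so that every estimator can be verified by parameter
recovery against known ground truth.

## Estimators

**Growth and mortality.** Rates assume exponential change within an
interval: $\mu = (\ln N_1 - \ln N_0)/t$ with $t$ in days. Negative values
are valid mortality rates; a zero count makes the rate undefined and the
record is flagged rather than dropped or zeroed.

**Clearance and ingestion.** The grazing coefficient is estimated against a
prey monoculture control grown over the same interval:
$g = k - \frac{\ln(C_1/C_0)}{t}$, where $k$ is the control's growth rate.
Clearance is $F = g/\bar N$ and ingestion $I = F \bar C$, where $\bar N$ and
$\bar C$ are logarithmic means, $\bar X = (X_1 - X_0)/\ln(X_1/X_0)$ — the
time average of an exponentially changing population. Using the logarithmic
mean of the *grazer* density is the standard refinement of the original
clearance-rate derivation for growing grazer populations. Negative $g$
(prey outgrowing its control) is retained and flagged; under the default
policy the ingestion rate is reported as 0 while the raw $g$ is preserved,
because clamping at the $I$ level matches the ecological interpretation
while keeping evidence of control mismatch auditable. Prey counts of zero
at the end of an interval are replaced by a detection limit (default 0.5
cells mL^-1^, one cell per largest counted volume: the log formulas require
positivity) and flagged `depleted_prey`.

**Inorganic carbon uptake.** The single-cell radiocarbon method: picked
cells are incubated 3 h with NaH^14^CO~3~ in a light and a dark vial, and

$$p = \frac{(D_l^* - D_d^*)/N \; \cdot \; C_m \cdot 10^6}
           {SA_v \cdot V \cdot t}$$

gives pg C cell^-1^ h^-1^, where $D^*$ are vial-total DPM, $N$ the picked
cells, $C_m$ the dissolved inorganic carbon (µg C mL^-1^), $SA_v$ the
medium's specific activity per mL, $V$ the vial volume and $t$ the
incubation time in hours. Daily uptake multiplies by the photoperiod
(default 14 h). Two bookkeeping decisions are made explicit because the
field often leaves them implicit:

* *Specific activity is put on a per-mL basis* ($SA_v$ = subsample DPM /
  subsample volume), and $C_m$ is likewise per mL, so the tracer fraction
  $(D^*/(SA_v V))$ is dimensionless. The method's published descriptions
  give SA "in DPM" without a volume basis; the per-mL contract is a
  recorded convention, not an interpretation claim.
* *Measured DPM are scaled to vial totals* by `vial_volume/counted_volume`
  (2.0/1.9 by default), because a 100 µL subsample is removed for the
  specific-activity measurement before acidification. Setting
  `counted_volume = vial_volume` recovers a no-correction mode.

Dark-above-light differences are kept as negative rates and flagged by
default (`keep_negative`); silent clamping would bias low-irradiance
treatments upward.

**Biovolume and carbon.** Cells are classified spherical or ellipsoidal.
"Ellipsoid" is a prolate spheroid, $(\pi/6) L W^2$, the standard convention
for Lugol-fixed ciliate biometry; for spheres the diameter is the mean of
the two measured axes so the result cannot depend on which axis was
labelled length. Carbon conversions are linear: 0.19 pg C µm^-3^ for the
ciliate, 10 pg C per prey cell, both overridable per treatment. No
fixation-shrinkage correction is applied by default; a multiplicative
volume-correction hook exists (default 1).

**Budget.** $C_I = I \times$ `prey_carbon`; $\mu_{yC} = \mu_y C_y$;
$GGE = \mu_{yC}/C_I$, never clamped above 1 — with photosynthetic
supplementation efficiencies above 1 are real and expected; the partition
of acquired carbon is $100\,P/(P + C_I)$ against $100\,C_I/(P + C_I)$,
using gross ingested carbon in the denominator (the only definition
consistent with a two-input budget). Undefined quantities propagate as
explicit `NA`, never as zeros.

## The simulator

The pipeline's correctness argument is parameter recovery, so the
generator is first-class, tested code. Its deterministic core tracks, per
culture: prey density $C$, ciliate density $N$, per-cell chl-a $Q$ and
per-cell carbon $c$, integrated by forward Euler at `dt = 0.01` d
(dynamics are smooth and slow; a convergence test halves `dt` and requires
trajectory agreement at the 1-2% level):

* prey: $\dot C = \mu_x(E) C - I(C) N$, with light-limited growth
  $\mu_x = \mu_{max}(1 - e^{-E/E_k})$ and Monod ingestion
  $I(C) = I_{max} C/(K + C)$;
* chl pool: $\dot Q = \epsilon\, q_{prey} I(C) - (d_0 + d_1 E)\, Q$ — a
  retention fraction $\epsilon$ (default 0.05) of ingested prey chl is
  sequestered, and the pool decays faster under stronger light;
* photosynthesis: $P = P^B_{max}(1 - e^{-\alpha E/P^B_{max}})
  e^{-\beta E} \cdot Q e^{-k_s Q}$ — saturating P–I response with
  high-light photoinhibition ($\beta$) and chl self-shading ($k_s$);
* carbon balance: $net = a(10\,I(C) + P) - R$; a surplus refills $c$ and,
  at the division threshold, drives division at rate $net/c$; a deficit
  drains $c$ and drives mortality at rate $m_0 \min(1, -net/R)$.

Two functional-form choices deserve comment. First, sequestering only a
retention fraction of ingested chl is required to hold the well-fed chl
pool near the observed ~65 pg cell^-1^: at realistic ingestion
(~10^3^ prey d^-1^, 0.28 pg chl per prey) full retention would predict a
pool an order of magnitude too large at plausible decay rates. Second, the
photoinhibition factor $e^{-\beta E}$ encodes the defining physiological
feature of these organisms — stolen plastids cannot be repaired or
photoprotected by the host — without which the model cannot produce the
observed high-light syndrome (fast chl loss, collapsing uptake, fastest
culture mortality at the highest irradiance *despite* more light). Both
forms are deliberately the simplest ones consistent with those
observations, and both sit behind ordinary parameters so alternative forms
can be substituted.

Default preset (chosen once, as field-realistic values, and not revisited):
$\mu_{max} = 0.7$ d^-1^, $E_k = 30$; $I_{max} = 3500$ d^-1^,
$K = 1.2 \times 10^5$ cells mL^-1^ (a near-linear functional response over
the experimental prey range, clearance ~0.025 mL d^-1^); $q_{prey} = 0.28$
pg, $\epsilon = 0.05$, $d_0 = 0.1$ d^-1^, $d_1 = 0.003$ d^-1^ per µmol
photons m^-2^ s^-1^; $\alpha = 0.3$, $P^B_{max} = 25$ pg C (pg chl)^-1^
d^-1^, $\beta = 0.012$, $k_s = 0.004$; $a = 0.6$, $R = 180$ pg C cell^-1^
d^-1^, $m_0 = 0.7$ d^-1^; division threshold 8000 pg C (≈ 42,000 µm^3^),
starvation floor 2500 pg C. These give well-fed growth ~0.6 d^-1^,
ingestion ~870 prey d^-1^ at bloom prey density, chl half-lives of 5.3 /
3.2 / 1.5 d at 10 / 40 / 120 µmol photons m^-2^ s^-1^, and starvation
survival longest at the intermediate irradiance.

Mortality is carbon-balance-driven with the floor rate $m_0$ (the
alternative, a fixed starvation mortality, is selectable by setting the
balance parameters accordingly); a balance-driven term is what produces
the observed irradiance ordering of survival times, since the deficit
grows at the speed the chl pool decays.

The observation layer adds, per measurement process: Poisson counting over
2 mL wells repeated until ≥ 200 individuals are expected (up to 12 wells;
0.1 mL cytometry draws for prey), lognormal DPM error (CV 5%) on top of a
dark-vial background, lognormal fluorometry error (CV 8%), and normal
error on each linear dimension (CV 5%). With `noise = "none"` every
reading is the exact forward value, so the pipeline must invert it to
float tolerance — the basis of the recovery tests. Dilution-protocol
bookkeeping (pre-/post-dilution phases, triplicate splitting at day 2,
prey monoculture controls) mirrors the experimental designs.

## What the simulations do and do not show

The generator emulates exponential predator–prey dynamics with ingestion
coupling, the daily-dilution and prey-depletion protocols, and the four
measurement processes. It deliberately omits demographic stochasticity
(densities are continuous; all randomness is observational), prey
photoacclimation beyond light-limited growth, diel light:dark structure
(photosynthesis enters as a daily-average rate), and any respiration or
egestion terms beyond the single maintenance parameter. Passing recovery
tests therefore demonstrates that the estimators are correct for the
processes they assume — not that those assumptions hold in any particular
real data set.

One structural limit is worth stating precisely. The clearance estimator's
logarithmic means are exact only when both populations change
exponentially within an interval. Under the acclimation protocol the
grazers, held at 15 cells mL^-1^ by daily dilution, can double within a
cycle at high prey; grazing pressure then grows through the day, the prey
trajectory is no longer log-linear, and the estimator acquires a 2–5%
structural bias at the highest prey density (it is well under 2% at the
two lower densities, and growth and uptake recover to float precision
throughout). This is a property of the classical method under its own
standard protocol, not of the implementation, and it is visible here only
because the simulator provides ground truth that real experiments lack.

## Numerical and interface choices

* Intervals run post-dilution to next pre-dilution under the acclimation
  protocol, so growth needs no dilution correction; starvation designs use
  consecutive sampling days. Control growth is matched per interval, and
  averaged across control cultures where several exist.
* Point measurements (scintillation, fluorometry) attach to the interval
  ending on their sampling day; biovolume averages all dimension rows in
  `(t0, t1]`, and the per-cell carbon entering $\mu_{yC}$ is taken from
  that same window.
* `rates.csv` is written at full double precision (`%.17g`) so write/read
  round trips are bit-identical; all interchange is plain CSV.
* Dimension rows with length < width are swapped with a warning
  (transcription-order slips are far likelier than oblate cells); unpaired
  scintillation vials are hard errors, since silently dropping a dark
  control would bias every uptake value.
* Analysis stages are seed-free by construction; all randomness lives in
  the simulator and is fully determined by `sim_params(seed)`.

The test suite runs the designs at desk scale: the full 3×3 zero-noise
acclimation design once, 100 noisy replicate seeds for the
recovery-dispersion check, and single-treatment runs elsewhere; these
sizes are the package's own verification choices and complete in a few
minutes on one CPU.

## Known limitations

Beyond the simulator scope above: the pipeline reports treatment × day
means ± SD and leaves inferential statistics (mixed models, multiple
comparisons) to downstream tools; there is no functional-response fitting
to the estimated ingestion rates; DIC enters as a measured value, with no
carbonate-system chemistry; and the biovolume-to-carbon factor is linear —
no allometric alternatives are offered.
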