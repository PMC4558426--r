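# thermocode

Dose–response characterization of insect antennal thermoreceptor neurons
from paired temperature traces and sorted spike trains.

Antennal sensilla of ants house cold-sensitive neurons that extract
different parameters of the thermal environment in parallel. `thermocode`
implements the quantitative analysis of two such neuron types for
electrophysiologists working with single-sensillum recordings:

* **TT-neuron** (transient-temperature / thermal-flux detector): phasic
  firing encodes the temperature changing rate `r` (°C/s). The response is
  normalized to the 10-s pre-stimulus baseline (nIF, baseline ≡ 100 %) and
  follows a Weber–Fechner law, fitted as

  `nIF = a + b · ln|r|`

  with quality control (slope p < 0.05, |Pearson r| > 0.3). Derived
  readouts: **differential sensitivity** `b·ln 10` (%/decade), **detection
  threshold** (stimulus where the fit crosses the resting noise band
  `100 ± 2·SD`), and the **resolving power**

  `Δx = (2σ/|b|) · Φ⁻¹(γ)`,  `γ = 0.9`, `Φ⁻¹(0.9) ≈ 1.28`,

  where `σ² = Σε²/(n−1)` is the variance of the nIF about the regression.
  `jnd(r, Δx) = Δx·r` converts it to the just-noticeable stimulus
  difference at intensity `r`.

* **ST-neuron** (steady-temperature detector): sustained mean rate encodes
  absolute temperature inside a narrow working range, modelled as a
  decreasing logistic

  `rate(T) = r_low + (r_high − r_low) / (1 + exp((T − T₀)/w))`

  fitted by Gauss–Newton iteration with step halving. Derived readouts:
  turning-point sensitivity `−(r_high − r_low)/(4w)` (APs/°C), the working
  range (10 % departure from each activity plateau, inverted through the
  fitted curve), a resolving power in °C (same `Δx` rule on a linear
  regression within ±1 °C of `T₀`), and a paired rank test of the two
  plateaus.

A first-class synthetic-data module simulates the stimulation protocol
(ramp → 500-s plateau → return ramp, 4-Hz sampling, 0.01 °C measurement
noise) and both neuron types as inhomogeneous gamma-renewal spike trains
with known ground truth, so every stage of the pipeline is validated by
parameter recovery. See the vignette
(`vignettes/thermoreceptor-analysis.Rmd`) for the methods in full.

## Worked example

Simulate one ST unit with the default ground truth (plateaus 50/29.5
APs/s, T₀ = 30 °C, turning-point slope −6.5 APs/°C) and recover it:

```r
library(thermocode)
rec <- simulateSTCohort(nUnits = 1, seed = 7)[[1]]
analyzeST(rec)
#> STFitResult: plateaus 49.71/29.43 APs/s, T0 30.03 degC, width 0.7752 degC
#>   sensitivity at T0 -6.539 APs/degC, converged TRUE (9 iter, 2076 bins)
#>   working range 29.16-31.41 degC (literal rule)
#>   resolving power 1.38 degC
#>   activity drop between plateaus 39.5%
```

The fitted plateaus, midpoint and sensitivity sit on the generator's
ground truth; the resolving power says this unit distinguishes steady
temperatures ~1.4 °C apart at its most sensitive point; the two activity
levels differ by ~40 %.

A TT unit stimulated with three cooling ramps (−0.03/−0.1/−0.3 °C/s,
generator gain 60 %/decade, response threshold 0.02 °C/s):

```r
recs <- simulateTTCohort(nUnits = 1, seed = 7)[[1]]
analyzeTTUnit(recs)
#> TTFitResult (cooling): n = 40 points
#>   differential sensitivity 66.66 %/decade (slope 28.95 %/ln-unit), intercept 213%
#>   Pearson r 0.688, p 9.5e-07, sigma 14.5% -> QC pass
#>   detection threshold -0.03821 degC/s (fit)
#>   resolving power 1.28
```

The sensitivity recovers the 60 %/decade ground truth within the spread
expected at this design size; the detection threshold sits above the
generative 0.02 °C/s because it measures where the response clears the
~20 % resting noise level (see the vignette for why that offset is a
property of the method).

The tabulated worked-example conversions:

```r
reproduceWorkedExamples()
#>                quantity  value  units
#>         phi_inverse_0.9  1.280
#>    jnd_at_-0.1_rp_0.372 -0.037 degC/s
#>  jnd_at_-0.047_rp_0.372 -0.017 degC/s
#>   jnd_at_0.029_rp_0.275  0.008 degC/s
```

## Command line

A thin CLI over the same functions lives at
`inst/scripts/thermocode-cli.R`:

```sh
Rscript inst/scripts/thermocode-cli.R simulate --out cohort --class ST --units 7 --seed 1
Rscript inst/scripts/thermocode-cli.R analyze  --in cohort --out results --class ST
Rscript inst/scripts/thermocode-cli.R summarize --in results --out results
Rscript inst/scripts/thermocode-cli.R reproduce-worked-examples
```

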