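# usvwhisk

Analysis of the temporal coordination between rat **ultrasonic
vocalizations (USVs)**, **whisking**, **facial touch** and **auditory-cortex
single-unit activity**.

During social facial touch, rats whisk at ~8 Hz and emit 50-kHz-class calls
(trills, complex, flat, ...) at strongly elevated rates. This package
implements the full analysis chain used to quantify that coordination and
the cortical responses that accompany it:

- **Whisking kinematics** — up-sampling of whisker-angle traces to 1 kHz,
  zero-phase fourth-order Butterworth band-pass (1–25 Hz), whisk-cycle
  detection with quality control (cycle length 50–250 ms, amplitude
  ≥ 7.5°), analytic-signal (Hilbert) phase with 0° at maximum protraction
  and 180° at maximum retraction, and Welch-PSD rhythm estimation.
- **Vocal analysis** — spectrogram parameterization, per-category call
  statistics (mean ± SEM, 20th/80th quantiles), microphone-array call-source
  assignment (side score = max of the two same-side channels; assign when
  the score ratio exceeds a margin, default 1.5) with accuracy accounting,
  calling rates per scenario and in/out of touch, call-interval periodicity,
  and trigger-locked relative sound power (geometric mean across triggers).
- **Coordination** — whisking phase at call onsets, the Hodges–Ajne test of
  circular uniformity `p = (n − 2m)·C(n,m)/2^(n−1)` with `m` the minimum
  half-circle count, call-triggered whisking averages, and the
  retraction/protraction split of call phases.
- **Unit classification** — spike-width features (full width and
  second-half width at 25 % of peak, scaled to the widest unit),
  k-means (k = 2) putative RS/FS labeling, and the recording-stability
  exclusion metric (mean |Pearson R| between period midpoint and firing
  rate over 1000 permutations of interaction-matched control periods;
  excluded above 0.4).
- **Response metrics** — PSTHs, matched event-free baselines placed 10 s of
  *clean* time before each event (jumping over all calls and interactions),
  and the response index `RI = (in − out)/(in + out)` for calls, touch
  (suppression) and the 200-ms post-touch off-response, plus the
  sample-size-equalizing bootstrap for in/out-of-touch comparisons.
- **Phase locking** — occupancy-normalized spike-phase histograms, Rayleigh
  vectors, and a count-insensitive circular time-shift shuffle test; a unit
  is locked iff ≥ 10 spikes in tracked time, Rayleigh length > 0.2 and the
  observed length reaches the 95 % quantile of its shuffle distribution.
- **Synthetic sessions** — a generator with known ground truth (jittered
  8 Hz whisking, lognormal 2.86 ± 2.68 s touch episodes, phase-coupled call
  point processes via von Mises thinning, directional microphone
  intensities, and units with call/touch/off-response gains) used for
  calibration and parameter-recovery testing throughout.

## Worked example

```r
library(usvwhisk)

session <- generateSession(synthConfig(durationS = 600, seed = 1))
session
#> SessionRecording 'synthetic-seed1' (600.0 s)
#>   2 whisker trace(s), 304 call(s), 8 touch episode(s), 8 unit(s)
#>   scenarios: subject_alone, social_setting
#>   ground truth attached (synthetic session)

report <- runPipeline(session, analysisConfig(nShuffles = 1000, seed = 1))
co <- report$report$stages$coordination$summary
```

The coordination stage reports, for this session,

```
emitter uniformity: n = 192, m = 43, p = 5.21e-13
retraction/protraction: 147 vs 45 (binomial p = 7.82e-14)
whisking peak: 7.81 Hz (dominant: TRUE)
```

meaning: of the 192 subject calls that fell in quality-controlled whisk
cycles, the emptiest half-circle of onset phases held only 43, far fewer
than the ~96 expected under uniformity, so calling is strongly non-uniform
in whisking phase; calls concentrate in retraction (147 vs 45), and the
whisker trace itself oscillates at 7.8 Hz. The vocal stage on the same
session gives scenario calling rates of 0.12 Hz (subject alone) and 0.89 Hz
(social setting), in-touch vs out-of-touch rates of 1.31 vs 0.87 Hz, and
source assignment of 69 % correct / 2 % wrong / 29 % unassigned against the
generator's ground-truth emitters — all close to the generating parameters
(0.13 / 0.80 / 1.50 Hz and the directional-intensity regime). The units
stage recovers the 6 RS / 2 FS composition from waveform widths alone.

A command-line wrapper is included:

```sh
Rscript inst/scripts/usvwhisk simulate --out sess --seed 1 --duration 600
Rscript inst/scripts/usvwhisk analyze --session sess --out results
Rscript inst/scripts/usvwhisk report --out results
```

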