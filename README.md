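# eegbss

Automatic reduction of ocular and muscular artifacts in multichannel
EEG by determined blind source separation, for researchers building
brain-computer interfaces (BCIs) and anyone who needs artifact-reduced
EEG with a fully inspectable, scriptable pipeline.

Scalp EEG is modelled as a linear instantaneous mixture
`x(n) = A s(n) + d(n)` of `Q = P` unknown neuronal and artifactual
sources. The package fits the demixing matrix `W ≈ A⁻¹` by one of
three estimators, identifies each estimated component from three
features, and reconstructs the recording with the artifactual
components zeroed:

* **Extended infomax ICA** (time domain): whitening followed by
  natural-gradient likelihood ascent with the score
  `φ(ŝ) = −(ŝ + sgn(c₄)·tanh ŝ)`, the sub/super-Gaussian switch driven
  by each source's empirical fourth cumulant `c₄ = M₄ − 3M₂²`.
* **IVA** (frequency domain): per-bin demixing matrices learned
  jointly under a spherical multivariate super-Gaussian prior,
  `φᵢ(ŝ) = ŝᵢ / √(Σᵢ′ |ŝᵢ′|²)`, which keeps source order aligned
  across frequency bins.
* **ILRMA** (frequency domain): per-bin demixing coupled to a low-rank
  nonnegative source-variance model `r_ijq = Σ_k z_qk t_ik v_kj`
  (shared basis pool, soft partitioning), minimising
  `Σ_ij { Σ_q log r_ijq + Σ_q |y_ijq|²/r_ijq − 2 log|det Wᵢ| }`
  by majorization-minimization (source model) and iterative projection
  (demixing). The cost is non-increasing at every iteration, by
  construction and by test.

Both frequency-domain methods use a 50%-overlapped 1-s Hamming-window
STFT whose overlap-add inverse reconstructs covered samples exactly.
Components are identified from a 32×32 scalp topography, a median
Welch PSD (1-50 Hz) and a 1-s autocorrelation — scaled exactly as the
identification stage expects (max |·| = 0.99, zero-lag 0.99) — through
a pluggable classifier; a documented heuristic stand-in labels
eye/muscle/brain. Components labelled `eye` or `muscle` are zeroed
across all bins and frames and the recording is remixed.

A ground-truthed synthetic EEG generator (oscillatory neuronal
sources, SSVEP responses, ~20-per-minute eyeblink trains, muscle
bursts, low-rank broadband test sources, distance-attenuated mixing)
and evaluation tools (permutation-aligned correlation, Amari index,
CCA-based SSVEP frequency identification, packaged per-subject
artifact-epoch counts) make every stage testable without any external
data. See the methods vignette
(`vignettes/artifact-reduction-methods.Rmd`) for the models,
assumptions, parameter rationale and limitations.

## Worked example

A blink-contaminated four-target SSVEP session with known targets;
ILRMA is trained on all epochs, the blink component is found and
removed, and frequency identification from the occipital channels is
compared before and after:

```r
library(eegbss)

ses <- ssvep_blink_session(seed = 1)
ses$epochs
#> <epoch_set> 100 trials x 4 channels x 200 samples @ 100 Hz

res <- reduce_pipeline(ses$epochs, ses$epochs, method = "ilrma",
                       band = c(1, 10), seed = 1)
res$report$labels
#> [1] "brain" "brain" "brain" "eye"
res$report$dropped
#> [1] 4

max(diff(res$report$cost_trace))   # ILRMA cost never increases
#> [1] -15.78077

hits <- function(eps) sapply(1:20, function(e)
  cca_identify(eps$epochs[e, 3:4, ], eps$fs)[[1]] == ses$targets[e])
c(before = accuracy(sum(hits(ses$epochs)), 20),
  after  = accuracy(sum(hits(res$epochs)), 20))
#> before  after
#>     75     80
```

The fourth component — frontal, low-frequency, high-amplitude — is
labelled `eye` and removed; identification accuracy on the 20
evaluated epochs rises from 75% to 80% (larger gains on harder seeds;
the three-session aggregate in the acceptance run goes from 45% to
70%).

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/eegbss.R`:

```sh
Rscript inst/scripts/eegbss.R simulate --out scene --seed 7
Rscript inst/scripts/eegbss.R separate --in scene --out sep --method ilrma --iters 200 --seed 7
Rscript inst/scripts/eegbss.R reduce   --in scene --out red --method ilrma --band 1:10 --seed 7
Rscript inst/scripts/eegbss.R evaluate --truth scene --est red --out report.json
```

Every randomised stage takes an explicit `--seed` recorded in its JSON
run report; identical invocations produce identical artifacts. A YAML
or JSON file passed with `--config` supplies defaults that explicit
flags override.

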