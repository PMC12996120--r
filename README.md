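# phispec

Tools for asking whether a person's resting-state EEG organizes its theta
and alpha rhythms around the golden ratio (φ ≈ 1.618) or around the
harmonic 2:1 ratio — and whether that organization relates to the two
rhythms converging on the 8 Hz band boundary.

The package is aimed at EEG researchers working with eyes-closed
resting-state recordings (EDF, BrainVision, or plain delimited matrices)
who want a tested, fully scriptable implementation of the index, its
processing chain, and the validation battery needed to interpret it.

## The quantities

For each subject, band **spectral centroids** are computed from
Welch power spectra,

    f_band = Σ f·P(f) / Σ P(f),   theta = [4, 8) Hz, alpha = [8, 13) Hz,

alpha over posterior channels (O1 O2 Oz P3 P4 Pz P7 P8) and theta over
either the same group or the frontal group (Fz F3 F4). The **Phi Coupling
Index** compares the centroid ratio R = f_α/f_θ with the two candidate
organizations:

    PCI = ln( (|R − 2| + ε) / (|R − φ| + ε) ),   φ = 1.618034, ε = 0.01.

PCI > 0 means R is closer to φ ("φ-organized"), PCI < 0 closer to
harmonic 2:1, PCI = 0 exactly at the midpoint 1.809017. **Theta–alpha
convergence** is the bounded transform `1/(|f_α − f_θ| + 0.5)`, ranging
from ≈ 0.1 (9 Hz separation) to 2.0 (coincident centroids). The central
estimator `pci_fit()` reports their association; null models, a
reference-constant sweep, an ε-sensitivity ladder, an aperiodic (1/f)
correction and a frontal-theta variant probe whether that association is
more than shared construction. Details and design rationale are in the
methods vignette (`vignettes/phi-coupling-methods.Rmd`).

## Worked example

```r
library(phispec)

# 20 synthetic eyes-closed subjects (11-channel 10-20 layout, 60 s @ 160 Hz)
spec <- synth_spec(n_subjects = 20, seed = 42)
res  <- make_cohort(spec)          # generate -> preprocess -> PSD -> indices
fit  <- pci_fit(res$cohort, n_boot = 2000, seed = 42)
summary(fit)
```

```
Phi-coupling cohort fit
  n subjects          : 20
  mean ratio (SD)     : 1.682 (0.159)
  deviation from phi  : 3.9%   from 2:1 : 16%
  phi-organized (PCI>0): 80.0%
  PCI ~ convergence   : r = 0.295 (p = 0.206), 95% CI [-0.050, 0.625]; rho = 0.468 (p = 0.0376); n = 20
```

Reading it: the generator draws true ratios from Normal(1.677, 0.142), so
about 80% of subjects land closer to φ than to 2:1 — the estimated
fraction and the mean ratio's 3.9%-from-φ / 16%-from-2:1 deviations
recover that calibration through the full filtering/PSD/centroid chain.
The PCI–convergence correlation is weak here because the default
generator plants no coupling between ratio proximity and centroid
separation; constructions that do plant it (see below) produce strong,
sweep-localized associations.

```r
# A null model: independent theta/alpha pairs inside the physiological
# bands (slow-alpha/fast-theta regime), no true coupling
null_band_constrained(6.5, 0.5, 9.6, 0.8, n_subjects = 200,
                      n_draws = 2000, seed = 42)
#> <null_result:band_constrained> 2000 draws: null r = -0.275 (SD 0.087)

# Specificity sweep on a cohort constructed with ratios clustered at phi
phi_sweep(synth_coupled_cohort(300, 1.618034, seed = 42))
#> <sweep_result:proximity> 20 constants; argmax c = 1.618; r at phi = 0.874
```

The same workflow runs from the shell over a directory of recordings:

```sh
Rscript inst/exec/phispec simulate --out recs --n 20 --seed 42
Rscript inst/exec/phispec analyze  --input recs --out cohort.csv
Rscript inst/exec/phispec validate --cohort cohort.csv --out report --seed 42
```

`validate` writes `report.json` (versioned schema) and `report.md` with
the ratio summary, the primary correlation, both null models, the sweep,
the ε table, median-split profiles and, when the columns exist,
per-dataset, subgroup and frontal-theta sections. Real EDF/BrainVision
recordings go through the same `analyze` entry point.

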