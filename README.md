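# mdifkit

Quantification of cerebral glucose metabolism (CMRGlu) from dynamic
[18F]FDG PET **without arterial sampling**.

Dynamic FDG quantification needs the arterial plasma input function
Cp(t). `mdifkit` recovers it from the PET image itself: for an
irreversible two-tissue compartment tracer the input can be written in
closed form as a function of the whole-brain time-activity curve (TAC)
and the four whole-brain rate constants — the **model-derived input
function (MDIF)**:

    Cp(t) = 1/(R·Vb) · [ Cwb(t) + (1−Vb)/(R·Vb) · K1 ·
            ( (k3−α2)/(α2−α1)·e^(−α2 t) − (k3−α1)/(α2−α1)·e^(−α1 t) ) ∗ Cwb(t) ]

with α1,2 = a ∓ √(a²−b), a = ((1−Vb)/(R·Vb)·K1 + k2 + k3)/2,
b = (1−Vb)/(R·Vb)·K1·k3, and R the whole-blood-to-plasma ratio. The
four parameters are estimated by **simultaneous estimation (SIME)**:
several cluster TACs with distinct kinetics are fitted jointly to the
two-tissue model, all driven by the candidate MDIF, with one or two
late venous samples anchoring the scale. Because the whole-brain TAC
has the highest SNR in the image, the MDIF is low-noise, free of
partial-volume effects, and follows any injection protocol shape —
unlike exponential-model image-derived input functions (the classical
SIME comparator, also implemented here).

The package covers the full workflow:

* `kinetics` — forward irreversible 2TCM (`twotcm_forward`), exact
  closed-form input inversion (`mdif_from_wb`), exponential bolus input
  model (`feng_input`), Ki algebra (`ki_of`);
* `sime` — `fit_sime_mdif` (28 parameters at 6 regions) and
  `fit_sime_idif` (31), seeded profiled multi-start Levenberg–Marquardt
  with literature bounds and the distribution-volume constraint;
* `fitting` — standalone weighted NLLS fits (`fit_standalone`,
  `make_weights`), Patlak analysis (`patlak`, t* = 20 min), CMRGlu
  conversion (lumped constant 0.52), error-propagation CV of Ki,
  input-function AUC comparison (`compare_curves`);
* `clustering` — HYPR-style composite-guided denoising
  (`hypr_denoise`), seeded k-medoids TAC clustering (`cluster_tacs`),
  largest-cluster selection (`select_clusters`);
* `simulate` — a fully synthetic, deterministic six-region simulation
  study (`reference_simulation`, `voi_microparameters`) plus
  configurable TAC/4D-phantom generators;
* `io` + CLI — delimited TAC/anchor tables, NIfTI volumes, YAML
  configs, a provenance-rich `run_pipeline`, and an `inst/cli/mdifkit`
  command-line tool (`simulate`, `sime`, `fit`, `patlak`, `compare`,
  `cluster`, `pipeline`).

## Worked example

Estimate the input function on the built-in noiseless simulation and
quantify the six regions with it:

```r
library(mdifkit)

sim  <- reference_simulation()          # AIF, 6 regional TACs, WB TAC, anchors
prob <- sime_problem(sim$wb_tac, sim$region_tacs, sim$anchors,
                     R = sim$R, mode = "mdif")
fit  <- fit_sime_mdif(prob, seed = 1)
fit
#> <sime_result> mode=mdif  28 parameters, 6 regions
#>   cost=1.35618e-23  converged=TRUE (20 iterations)
#>   anchor % difference: 0.00, 0.00

fit$wb_params
#> <micro_params> K1=0.09 mL/g/min  k2=0.117  k3=0.066 1/min  Vb=0.067 mL/g  (Ki=0.03246)

w      <- make_weights(sim$wb_tac$grid, sim$wb_tac)
refits <- lapply(sim$region_tacs, fit_standalone,
                 cp = fit$input_function, weights = w, R = sim$R)
ki <- sapply(refits, function(f) 100 * f$params$Ki)
round(c(mean = mean(ki), sd = sd(ki)), 2)
#> mean   sd
#> 3.26 0.89

compare_curves(fit$input_function, sim$aif)$overall_ratio
#> [1] 1
```

The SIME cost collapses to the anchor floor (~1e-22), the whole-brain
parameters come back at their generating values (K1 = 0.090, k2 =
0.117, k3 = 0.066, Vb = 0.067), the recovered input overlays the true
one (AUC ratio 1.000), and the regional net clearance summary is
3.26 ± 0.89 mL/100 g/min. Converting to metabolism at a plasma glucose
of 5 µmol/mL: `cmrglu_from_ki(3.26, cmrglu_config(plasma_glucose = 5))`
→ 31.3 µmol/100 g/min.

The same flow runs from the shell:

```sh
inst/cli/mdifkit simulate --out simdir/
inst/cli/mdifkit sime --mode mdif --tacs simdir/tacs.csv --wb-label WB \
    --anchors simdir/anchors.csv --R 1 --out result.json
```

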