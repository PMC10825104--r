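---
title: "Model-derived input functions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-derived input functions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdifkit)
```

## The quantification problem

Absolute quantification of cerebral glucose metabolism from dynamic
[18F]FDG PET requires the arterial plasma input function $C_p(t)$ — the
time course of tracer concentration driving every tissue curve.
Measuring it by arterial cannulation is invasive; image-derived
alternatives extracted from the carotid arteries suffer partial-volume
effects and low signal-to-noise ratio (SNR).

`mdifkit` implements a model-driven alternative. FDG kinetics in brain
tissue follow the irreversible two-tissue compartment model (2TCM) with
influx $K_1$ (mL/g/min), efflux $k_2$ (1/min), phosphorylation $k_3$
(1/min) and fractional blood volume $V_b$ (mL/g):

$$C_{PET}(t) = (1-V_b)\,\frac{K_1}{k_f}\left(k_3 + k_2 e^{-k_f t}\right)
  * C_p(t) + V_b\,C_b(t), \qquad k_f = k_2 + k_3,$$

with $C_b = R\,C_p$ for a constant blood-to-plasma ratio $R$. Because
this map from input to tissue is linear and causal, it can be inverted
in closed form. Applied to the whole-brain (WB) TAC — the highest-SNR
curve available in the image — the inversion yields the *model-derived
input function* (MDIF):

$$C_p^{MDIF}(t) = \frac{1}{R V_b}\left[C_{wb}(t) +
  \frac{1-V_b}{R V_b} K_1\left(
  \frac{k_3-\alpha_2}{\alpha_2-\alpha_1}e^{-\alpha_2 t} -
  \frac{k_3-\alpha_1}{\alpha_2-\alpha_1}e^{-\alpha_1 t}\right) *
  C_{wb}(t)\right],$$

with $\alpha_{1,2} = a \mp \sqrt{a^2-b}$,
$a = \tfrac12\!\left(\tfrac{1-V_b}{R V_b}K_1 + k_f\right)$ and
$b = \tfrac{1-V_b}{R V_b}K_1 k_3$. For non-negative rates $a^2 \ge b$
always holds, so the kernel rates are real; the identities
$\alpha_1+\alpha_2 = 2a$ and $\alpha_1\alpha_2 = b$ are tested as
invariants.

The four WB parameters that define the MDIF are unknown; they are found
by *simultaneous estimation* (SIME): several regional TACs with distinct
kinetics are fitted jointly to the 2TCM, all driven by the candidate
MDIF, with one or two late blood samples ("anchors") pinning the scale.
The cost is the plain residual sum of squares over all regional curves
plus the squared anchor mismatches. The comparator estimator
(`fit_sime_idif`) models the input instead as the classical
four-exponential-coefficient bolus form with a delay (7 parameters);
fewer input parameters (4 vs 7) is one of the MDIF's practical
advantages.

## Numerical design

**Convolution on clinical grids.** Frame schedules are strongly
non-uniform (2 s frames at the bolus, 300 s frames late), so discrete or
FFT convolution would introduce spacing-dependent bias. All forward
convolutions evaluate the exponential kernels *exactly* against a
piecewise-linear interpolant of the sampled input (closed-form
per-interval recursion, with series fallbacks for small $\alpha h$ and a
node pinned at $(0, 0)$ — no tracer before injection). Model curves are
evaluated at frame mid-times; against an independent trapezoid
quadrature oracle the forward curves agree to better than 0.01%.

**Evaluating the inversion.** `mdif_from_wb` offers two numerically
equivalent evaluations. The explicit kernel above, integrated against a
piecewise-linear interpolant of $C_{wb}$ (`method = "kernel"`), is
accurate to <0.1% on fine grids but leaves ~1% error across the sparse
late frames of a 60-min clinical schedule, where a piecewise-linear
representation of the curved WB TAC is the limiting approximation. The
default (`method = "deconvolution"`) instead inverts the sampled forward
operator exactly: the forward model maps input samples to tissue samples
through a lower-triangular linear system (diagonal bounded below by
$V_b R > 0$), which is solved by forward substitution. The two methods
agree on fine grids (tested <0.1%), but the operator inverse makes
forward-then-invert exact to machine precision on *any* schedule. That
exactness matters for SIME: it keeps the cost at the generating
parameters at its theoretical floor (zero for noiseless data with exact
anchors), so the estimator is unbiased by discretization. When the
kernel rates coalesce ($a^2$ within $10^{-10}$ of $b$, relatively), the
kernel path substitutes the analytic confluent limit
$-(1+(k_3-a)t)e^{-at}$; the degenerate case is exercised in the tests
with $k_2 = 0$, $\tfrac{1-V_b}{RV_b}K_1 = k_3$.

**Optimization.** Both SIME estimators minimize the joint cost by
bound-constrained Levenberg–Marquardt (`minpack.lm::nls.lm`; `ftol`,
`ptol` $10^{-9}$, at most 1024 iterations per start — the
implementation's iteration cap). Tissue boxes follow literature values:
upper bounds $(0.2, 0.4, 0.2, 0.10)$ for $(K_1, k_2, k_3, V_b)$ in SIME
(standalone fits use $(0.5, 0.5, 0.2, 1)$ with lower bounds 0), lower
bounds 0.01, and the distribution-volume constraint $K_1 < k_2+k_3$ is
enforced smoothly by the reparameterization $K_1 = s\,(k_2+k_3)$,
$s \in [0.01, 0.999]$. One consequence of the reparameterization is
that the $K_1$ box is only implied, not imposed; returned solutions are
checked against it post hoc in the tests.

The joint objective (28 parameters for MDIF-SIME at six regions, 31 for
IDIF-SIME) is strongly multimodal when all parameters are randomized at
once: joint fits from full-box random starts routinely stall in
compensating local minima with the input scaled a few percent and
$K_1$/$V_b$ biased 15–20%. The package therefore randomizes only the
*input-model* parameters (a 4- or 7-dimensional box) and profiles the
tissue parameters out: for every candidate input, each regional TAC is
fitted separately (a cheap, well-behaved 4-parameter problem), placing
the start on the variable-projection manifold. A pool of
Latin-hypercube candidates (plus the box's geometric and arithmetic
midpoints and, for the IDIF, data-driven starts: tail rate and amplitude
from the log-slope through the anchors, first-pass rate from the WB peak
lag, amplitude from the WB peak over candidate blood volumes) is ranked
by its manifold-start cost, and the best `n_starts + 2` candidates get
the full joint fit; the lowest final cost wins. The schedule is seeded
and fully deterministic. On the built-in simulation this recovers all
parameters to ~$10^{-11}$% across seeds.

**Anchors.** Anchor samples are treated as plasma concentrations and
compared directly with the input function, linearly interpolated at the
anchor times between frame mid-times. MDIF-SIME anchors enter the cost
with weight 1; IDIF-SIME anchors carry the customary extra weight of 10.
Anchors are not optional decoration: on noiseless data the anchor-free
objective has an *exact* scaling ridge ($C_p \to c\,C_p$ with
$K_1 \to K_1(1-V_b)/(c-V_b)$, $V_b \to V_b/c$ reproduces every tissue
curve), so without anchors only the input's shape is identified. The
test suite demonstrates the ridge explicitly.

**Delay.** The IDIF delay is boxed to ±10 s around an initial estimate:
the time at which the WB TAC first exceeds 5% of its running 2-minute
maximum, with linear back-interpolation to the crossing
(`estimate_delay`).

**Patlak and CMRGlu.** `patlak` regresses $C(t)/C_p(t)$ on
$\int_0^t C_p/C_p(t)$ for frames with mid-time beyond $t^* = 20$ min
(trapezoid plasma integral from $(0,0)$; at least 3 points required) and
reports the slope $\times 100$ in mL/100 g/min;
CMRGlu $= K_i\,C_{glu}/LC$ with lumped constant 0.52 and plasma glucose
in µmol/mL. Weights for the standalone fits are
$w_i \propto \Delta t_i / C_{wb}(t_i)$, normalized to maximum 1, the
inverse-variance model for reconstructed PET frames. The CV of $K_i$
uses the error-propagation rule over the $(K_1,k_2,k_3)$ covariance
block $\gamma = (J^TJ)^{-1}\,\mathrm{WRSS}/T$ (the $V_b$ column is
excluded, matching the 3-component gradient of $K_i$). A brain density
of 1.05 g/mL is carried in the configuration for tissue mL↔g
conversions (the parameter units here are already per gram, so it is
informational); the density constant is exposed rather than hard-coded
because its printed form in the source literature is ambiguous
("mL/g").

## The built-in simulation study

`reference_simulation()` regenerates the package's validation surface
end to end, with no external data:

* the analytic input is the exponential bolus model with population
  constants $A_1 = 850$ a.u./min, $A_2 = 22$, $A_3 = 21$ a.u.,
  $\lambda = (4, 0.12, 0.01)$ min$^{-1}$, no delay;
* six regional TACs are generated by the forward 2TCM from literature
  parameter sets with deliberately distinct kinetics
  (`voi_microparameters()`), with $C_b = C_p$ ($R = 1$, arbitrary
  units);
* the WB TAC uses the tabulated whole-brain parameter row
  $(0.090, 0.117, 0.066, 0.067)$. Note a quirk of that table: the WB
  $K_1, k_2, k_3$ equal the column means of the six regions (at 3
  decimals), but the WB $V_b = 0.067$ is a canonical whole-brain blood
  volume, not the mean of the regional entries (0.057) — several
  regional $V_b$ cells are placeholders where the source studies did
  not report blood volume;
* anchors are read from the *analytic* input at 28.5 and 53.5 min —
  both frame mid-times of the 50-frame, 60-min clinical schedule
  (`human_frame_grid()`), so exact anchors cost exactly zero at the
  truth;
* everything is deterministic.

```{r simulation, eval = FALSE}
sim <- reference_simulation()
prob <- sime_problem(sim$wb_tac, sim$region_tacs, sim$anchors,
                     R = sim$R, mode = "mdif")
fit <- fit_sime_mdif(prob, seed = 1)
w <- make_weights(sim$wb_tac$grid, sim$wb_tac)
refits <- lapply(sim$region_tacs, fit_standalone,
                 cp = fit$input_function, weights = w, R = sim$R)
```

On this noiseless problem the SIME cost reaches its anchor floor
(~$10^{-22}$), all 28 parameters are recovered to well under 1%, and
the regional $K_i$ from the standalone refits average
3.26 ± 0.89 mL/100 g/min — the tabulated ground truth.

**What the generator emulates, and what it does not.** The synthetic
study reproduces the *model structure* of a human scan: realistic frame
schedule, realistic rate constants, bolus-shaped input, exact anchors.
The optional noise model (`phantom_spec`) draws independent Gaussian
frame noise with variance proportional to value/duration — the standard
first-order description of reconstructed PET frame statistics — and the
voxel phantom lays regions out as compact slabs. Real data differ in
ways the generator does not attempt: correlated reconstruction noise,
motion, partial-volume mixing at region boundaries, plasma-to-blood
ratio dynamics, metabolite handling (FDG needs none) and anchor
measurement error. Passing the simulation tests therefore validates the
algebra, the numerics and the estimator — not robustness to every
clinical artifact.

## Clustering

SIME needs regional TACs with *distinct* kinetics. `cluster_tacs`
groups in-mask voxel TACs by k-medoids under Euclidean distance on the
raw frame values (no normalization), with 10 seeded restarts, at most
500 iterations each, and a per-iteration objective trace (the
assignment and medoid-update steps are both non-increasing, which the
tests assert). Determinism is bitwise for a fixed seed. Empty clusters
arising from duplicate TACs are reseeded with the farthest point.
Cluster *mean* TACs are always computed from the original image; the
HYPR-style composite-guided denoiser
(`hypr_denoise`: frame $\to C \cdot (G \otimes \text{frame}) /
(G \otimes C + \varepsilon)$, with $C$ the duration-weighted composite,
Gaussian $\sigma$ = 3 voxels, $\varepsilon = 10^{-12}$) serves only to
stabilize the partitioning, since its bias is harmless for grouping but
not for quantification. The 3D Gaussian filter is implemented as
separable zero-padded 1D convolutions; because numerator and
denominator share the kernel, the ratio is exact for spatially uniform
frames and approximately flux-preserving on smooth images (tested to
2%). `select_clusters` keeps the largest `n` clusters per tissue class
(size-descending, ties to the lower index). The qualitative "mostly
non-brain cluster" exclusion used with PET-only masks is implemented as
an explicit opt-in flag that drops the earliest-peaking mean TAC — the
vascular signature — and logs the choice.

Problem sizes in the test suite are chosen for tight feedback: the
clustering phantom is a 24×10×6 volume (six 240-voxel slabs, noise
scale 0.05), the dense-grid checks use 0.01-min grids over 60 min, and
the Monte-Carlo noise calibration uses 1000 replicates of a 50-frame
curve; at 1000 replicates the per-frame variance estimate itself
fluctuates by ~4.5% (1σ), so calibration is asserted on the mean ratio.

## Open choices made here

* **Frame integration.** Model curves are evaluated at frame mid-times
  (a config-free convention in this implementation); frame-averaged
  evaluation changes the noiseless results negligibly on this schedule
  and is not offered.
* **Anchor semantics.** Anchors are plasma concentrations compared to
  the plasma input directly; no $R$ conversion is applied to them.
* **Simulation $R = 1$, $C_b = C_p$** — the only self-consistent
  reading of an arbitrary-units simulation with a single theoretical
  input.
* **K1 box under reparameterization** — see above; checked post hoc.
* **Units.** Times are minutes internally; all file interfaces carry
  seconds (PET convention) with explicit column names.

## Limitations

* The closed-form inversion covers the irreversible 2TCM only;
  reversible tracers and metabolite-corrected inputs are out of scope.
* Only the plasma input is recovered; vascular corrections needing the
  whole-blood curve inherit the constant-$R$ assumption.
* The delay estimator assumes a clean early rise of the WB TAC; very
  noisy first-pass data may need a manual delay box.
* The non-brain cluster exclusion is a heuristic stand-in for a
  qualitative judgement and is flagged as such in logs.
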