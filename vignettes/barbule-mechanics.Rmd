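---
title: "Cantilever mechanics of feather barbules: models, numerics and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cantilever mechanics of feather barbules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featherbeam)
```

## The mechanical picture

A flight-feather vane is a cantilever hierarchy: barbs clamp into the rachis,
barbules clamp into barbs, and hooklets on the barbules zip adjacent barbs
together. `featherbeam` models two loading situations on that hierarchy:

* a **transient** one — a combing force at a barbule's tip is released and
  the barbule rings in its first bending mode, which is how shaking and
  preening help re-zip the vane and also how an attached water drop gets
  flung off; and
* a **static** one — the pressure of the air column carried by the bird sags
  each tapered barbule and barb by a small, recoverable amount.

Both use Euler–Bernoulli beam theory: slender beams, small deflections,
plane sections, linear elasticity, no shear deformation or rotary inertia
(Timoshenko corrections are out of scope), no damping and no aerodynamic
coupling.

## Modal analysis of the uniform barbule

For a uniform clamped-free beam of length $l$, modulus $E$, density $\rho$,
section area $A$ and second moment $I_z$, separation of variables
$y(x,t) = Y(x)\sin(pt+\varphi)$ turns the bending-vibration equation into
$Y'''' - k^4 Y = 0$ with $k^4 = \rho A p^2 / (E I_z)$. The clamped-free
boundary conditions (zero displacement and slope at the root, zero moment
and shear at the tip) admit non-trivial solutions only where

$$\cos\beta = -\operatorname{sech}\beta, \qquad \beta = kl,$$

equivalently $\cos\beta\cosh\beta = -1$. The mode shape normalised by its
constant is

$$\frac{Y(\xi l)}{C} = \cosh\beta\xi - \cos\beta\xi -
  \sigma(\beta)\,(\sinh\beta\xi - \sin\beta\xi), \qquad
  \sigma(\beta) = \frac{\sinh\beta - \sin\beta}{\cosh\beta + \cos\beta},$$

and the natural frequencies are $p_n = (\beta_n/l)^2\sqrt{E I_z/(\rho A)}$.
For the first mode $\beta_1 = 1.875104$, $\sigma(\beta_1) = 0.7341$ and the
tip shape value is $Y(l)/C = 2.000$:

```{r}
beta <- solve_eigenvalues(6)
round(beta, 6)
round(sigma_coefficient(beta[1]), 4)
round(mode_shape(beta[1], 1), 3)
```

A tip force $F$ produces the static deflection $F l^3/(3EI_z)$; matching it
to the first-mode tip value 2.000 gives the excitation amplitude
$C = F l^3 / (6 E I_z)$ (`amplitude_from_tip_force()`).

### Numerical choices

* **Root bracketing.** $\operatorname{sech}\beta$ decays exponentially, so
  root $n$ lies within an exponentially shrinking neighbourhood of the
  cosine zero $(2n-1)\pi/2$; we bracket root 1 in $[1, 3]$ and root
  $n \ge 2$ in $(2n-1)\pi/2 \pm 0.5$, guaranteeing exactly one sign change
  per bracket. `uniroot()` refines to interval tolerance $10^{-12}$ and up
  to three Newton steps polish the root to the floating-point floor; the
  residual $|\cos\beta + \operatorname{sech}\beta|$ of every returned root
  is below $10^{-12}$ (measured: near machine epsilon), and the roots are
  stable to the 6th decimal under tolerance changes from $10^{-10}$ to
  $10^{-14}$.
* **Overflow safety.** $\cosh$ and $\sinh$ overflow near $\beta \approx
  710$ in doubles. `characteristic_residual()` uses
  $\operatorname{sech}\beta = 2e^{-\beta}/(1+e^{-2\beta})$;
  `sigma_coefficient()` switches to an $e^{-\beta}$-rescaled ratio for
  $\beta \ge 20$; and `mode_shape()` assembles
  $\cosh a - \sigma\sinh a$ as
  $\tfrac12[(1-\sigma)e^{a} + (1+\sigma)e^{-a}]$ with $1-\sigma$ computed
  in the cancellation-free form
  $(e^{-\beta} + \cos\beta + \sin\beta)/(\cosh\beta+\cos\beta)$, because
  $\sigma$ is exponentially close to 1 for high modes and the naive
  difference loses all significant digits.
* **Conditioning of the determinant form.** The equivalent condition
  $\cos\beta\cosh\beta = -1$ is ill-conditioned for checking: its residual
  at a root grows like $\cosh\beta \cdot \Delta\beta$, so at mode 6
  ($\cosh\beta_6 \approx 1.6\times10^7$) even the correctly rounded double
  root leaves a residual of order $10^{-8}$. The tests therefore assert the
  $10^{-8}$ determinant residual for the first five modes and a
  conditioning-aware bound ($4\varepsilon\beta\cosh\beta$) beyond; the
  well-conditioned $\cos\beta+\operatorname{sech}\beta$ residual is held
  at machine level for all modes.
* The clamped-root value $Y(0) = 0$ is returned exactly (the two stable
  sub-expressions cancel only to $\sim10^{-16}$ on their own).

### What is deliberately not modelled

Modal participation is not ranked: low modes are the ones a broadband comb
release excites most easily, and callers ask for however many modes they
need. Damped or forced response and multi-mode superposition are out of
scope — the response module is first-mode only, as the barbule model
requires.

## First-mode vibration response

With $C$ and $\varphi$ fixed by the excitation, the response is
$y(\xi l, t) = C\,S(\beta_1,\xi)\sin(p_1 t + \varphi)$ and its exact time
derivative $v = p_1 C S \cos(p_1 t + \varphi)$. The tip velocity amplitude
carries the dimensionless constant

$$\beta_1^2 \, S(\beta_1, 1) = 7.03203,$$

giving $v_{\max} = 7.03203\,(C/l^2)\sqrt{E I_z/(\rho A)}$ and, through the
small-angle picture of the beam oscillating rigidly about its root,
$\omega(t) \approx v(l,t)/l$ and $\omega_{\max} = v_{\max}/l$ (implemented
literally, with no arctangent correction). $v_{\max}$ is also the speed
imparted to a water drop attached at the tip — the droplet-shedding speed.
The drop is treated as massless: its inertia is assumed not to perturb the
mode.

The **phase default** is $\varphi = \pi/2$: at $t=0$ the beam then sits at
the static deflection shape with zero velocity, which is exactly the
release-from-rest state after combing. The paper-level model leaves the
phase free, so it is a configuration parameter. How a physical preening
force maps to $F$ (hence $C$) is likewise left to the user; the shipped
default ($1\,\mu$N) is a placeholder of plausible magnitude, and every
reported kinematic quantity is proportional to it.

Maxima over time grids default to 4096 samples per period; the grid maximum
of $|v(l,t)|$ approaches $v_{\max}$ from below as the grid refines, which
the tests use as a convergence check.

## Static deflection of tapered barbules and barbs

The air column of a bird of mass $m$ over wing-plus-body area $A$ presses
$q = mg/A$ on the vane; a beam of width $w$ carries the line load $qw$,
giving shear $Q(x) = qw(l-x)$ and moment $M(x) = \tfrac12 qw(l-x)^2$. The
barbule tapers linearly to zero thickness at the tip with slope $k = t/l$,
so $I(x) = w(t - kx)^3/12$ and the deflection integral

$$\delta(x) = \int_0^x \frac{6q(l-y)^3}{E\,(t - \tfrac{t}{l}y)^3}\,dy$$

has a constant integrand $6ql^3/(Et^3)$ — the $(l-y)^3$ factors cancel —
so the deflection is **linear** in $x$:
$\delta(x) = 6mgl^3x/(EAt^3)$, $\delta_{\max} = 6mgl^4/(EAt^3)$. The same
formula with $l_B, t_B$ covers a barb. This is the model's own
unit-load-style integral, implemented verbatim; `method = "quadrature"`
evaluates it with `integrate()` (relative tolerance $10^{-12}$) as an
independent route, and the tests require agreement with the closed form to
$10^{-8}$ relative over 50 random parameter sets. A point (combing) load on
a uniform section gives $\delta = Pl^3/(3EI_z)$, again with a quadrature
cross-check of the unit-load integrand $P(l-x)^2/(EI_z)$.

Degenerate inputs: at $x = l$ the tapered section vanishes;
`section_inertia()` returns 0 there with a warning rather than an error,
because the deflection closed form stays finite at the tip. The linear
model has no validity bound in the source model, so the pipeline flags
barbules with $\delta_{\max}/l > 0.1$ — that threshold is a package
choice marking where small-deflection theory becomes doubtful, not a
derived quantity.

## The synthetic feather generator

No numeric barb/barbule dimensions are published alongside the model — the
micro-structure is documented by SEM imagery — so the generator emulates the
*hierarchy*, not a measured specimen. Defaults are pigeon-scale values
chosen from the feather-biomechanics literature and are deliberately
labelled placeholders:

| parameter | default | units |
|---|---|---|
| keratin modulus $E$ | $2.5\times10^9$ | Pa |
| keratin density $\rho$ | 1150 | kg/m³ |
| bird mass $m$ | 0.35 | kg |
| wing+body area $A$ | 0.065 | m² |
| barbs per feather | 8–12 | — |
| barbules per barb | 15–25 | — |
| barb length / root thickness | 15–30 mm / 150–350 µm | m |
| barbule length / root thickness | 200–500 µm / 5–15 µm | m |
| width : thickness | 2 | — |

Counts are uniform over their integer ranges; dimensions are log-uniform
(they are scale parameters, and a log-uniform collapses exactly when a
range is degenerate, which the tests exploit). One material is shared per
feather. Each barbule is generated as a tapered beam and also carries the
uniform `beam_section` built from its **root** cross-section
($A = wt$, $I_z = wt^3/12$): the modal model assumes a uniform beam while
the static model is tapered, and root dimensions are the package's stated
convention for feeding the same barbule to both (a slight stiffness
overestimate for the vibration stage).

Generation seeds R's RNG from the config and restores the caller's RNG
state, so a geometry is a pure function of its configuration; the config
and its hash are embedded in every geometry document and report.

What passing tests on synthetic feathers do **not** show: that real
barbules have these dimensions, that keratin is linearly elastic at these
strains, or that the uniform-section modal idealisation matches a real
tapered, curved, hooked barbule. They show that the pipeline computes the
stated models correctly and reproducibly on geometries of realistic
magnitude.

## Pipeline and reproducibility

`run_modes()`, `run_deflect()`, `run_vibrate()`, `run_generate()` and
`run_analyze()` (and the `inst/exec/featherbeam` wrapper) each write their
reports (CSV with comma separator, `.` decimal, header row, no index
column; JSON at full precision), a `config_echo.yaml` sufficient to replay
the run, and a `run.log` with the package version, seed, config hash and
the characteristic-equation residual of every reported eigenvalue.
Identical configurations produce byte-identical geometry and summary files.

```{r}
out <- file.path(tempdir(), "fb-demo")
res <- run_analyze(list(generator = list(seed = 7L)), out_dir = out)
head(res$summary[, c("barb_index", "barbule_index", "length_l",
                     "freq1_hz", "delta_max", "linearity_warning")])
```

Problem sizes used throughout the documentation and tests — feathers of
around 10 barbs × 20 barbules, 50-set quadrature sweeps, 4096-point time
grids — run in seconds and are the package's chosen defaults for
illustrating and validating the models.

## Known limitations

* First-mode-only response; no damping, drag, or drop-detachment
  criterion (adhesion is not modelled, so "shedding speed" means the peak
  speed available to the drop).
* Rectangular cross-sections only, as implied by $I = wt^3/12$.
* Hooklet–groove interlocking mechanics are qualitative in the source
  model and are not implemented.
* The linear-taper static model and uniform-section modal model coexist;
  the root-section convention above is an assumption, flagged per barbule
  when $\delta_{\max}/l$ grows large.
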