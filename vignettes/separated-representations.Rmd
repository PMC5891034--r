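---
title: "Net rigid-body interactions by separated representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net rigid-body interactions by separated representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidsep)
```

## The problem and the model

Two rigid bodies P and Q carry M and N particles at fixed reference
coordinates $\vec p_i^{\,\circ}$, $\vec q_j^{\,\circ}$, each with one scalar
property $\lambda^P_i$, $\lambda^Q_j$ (a charge, a mass, a spring weight).
Any pairwise law of the form

$$f_{ij} = s(\lambda^P_i, \lambda^Q_j)\,\phi(d_{ij})$$

— a separable property prefactor times a pure distance shape — induces a net
interaction $F_{PQ}(\xi) = \sum_{i}\sum_{j} f_{ij}$ that depends on the
relative pose $\xi$ of the two bodies alone once the reference geometry is
fixed. Evaluating $F_{PQ}$ by the double loop costs $O(MN)$ per pose. The
package instead builds a *separated representation*

$$F_{PQ}(\xi) \approx \sum_{k=1}^{r} C_k\, h_k(\xi),$$

where each $h_k$ is a monomial in a handful of *pose primitives* and each
characteristic constant $C_k$ is a sum over all pairs of a geometry-only
coefficient. The $C_k$ are accumulated once ($O(MN)$, preprocessing); every
subsequent pose costs $O(r)$, with $r$ set by the surrogate degree and the
pose family, not by M or N. The package exposes that claim as an assertable
counter: `pose_sweep()` records that the model pass performs zero
pairwise-law evaluations.

The construction has two steps:

1. **Surrogate.** The distance shape is fitted by least squares as a
   polynomial in *squared* distance, $\phi(d) \approx \sum_{k=0}^n a_k
   (d^2)^k$, over the squared-distance range the sweep will visit. Squared
   distance is the key choice: under a rigid motion $d^2 = \lVert R\vec
   q^{\,\circ} + \vec x - \vec p^{\,\circ}\rVert^2$ is itself a polynomial
   in the entries of $R$ and $\vec x$, so each power $(d^2)^k$ expands into
   finitely many pose monomials. A polynomial in $d$ would not close.
2. **Expansion and accumulation.** For each pair, $(d^2)^k$ is expanded in a
   sparse monomial algebra over the family's primitives
   (`translation_x1`: $x_1$; `rotation_x3`: $\sin\theta,\cos\theta$ with the
   rewrite $\cos^2\theta \to 1-\sin^2\theta$; `general_se3`: the nine
   rotation-matrix entries plus $x_1,x_2,x_3$ treated as independent
   symbols). The per-pair coefficients, times the pair's prefactor, are
   summed into the $C_k$.

For vector outputs the same machinery applies componentwise: the surrogate
targets $|\vec f|/d$ instead of the magnitude, so that component $l$ of the
pairwise force is the polynomial sum times $(q_{j,l}(\xi) - p^\circ_{i,l})$,
with $q_{j,l}(\xi)$ itself degree-1 in the primitives; the pairwise moment
about the frame origin is the cross product $\vec q_j(\xi) \times \vec
f_{ij}$, again polynomial. The net force/moment models therefore carry three
components sharing one monomial list.

### Pose conventions

Body P is fixed and the frame is attached to it; the reference pose is the
identity. Rotations are axis–angle about an axis through the frame origin,
right-handed, angles in radians. Units are whatever the particle files use;
the package performs no conversion, so pose sweeps and coordinates must
agree.

## Exactness and error

If the shape is *exactly* a polynomial in $d^2$ of degree $\le n$, the whole
pipeline is exact up to rounding: the separated model equals brute force at
every pose. The test suite drives this with a debug law (`poly_d2`) across
all three families; it is the package's primary correctness oracle, next to
dual brute-force engines (a generic vectorised R path and a compiled Coulomb
kernel) that must agree with each other.

For genuine laws the only approximation error is the regression residual.
Writing $f_{ij} = \text{(separated form)} + \epsilon_{ij}$, the net error is
$E_{\rm net} = \sum_{ij}\epsilon_{ij}$. When the residuals behave like
i.i.d. draws with standard deviation $\sigma_r$, the standard deviation of
$E_{\rm net}$ is $\sqrt{MN}\,\sigma_r$. A looser reading — that the net
error grows *linearly* in the particle counts, $MN\sigma_r$ — holds only as
an upper bound, and the two differ by the factor $\sqrt{MN}$;
`error_propagation_sim()` makes both statements testable by direct Monte
Carlo, and the test suite checks the square-root law at 5% and the linear
expression as a bound. In practice residuals at nearby sample points are
strongly correlated, so the i.i.d. picture is itself an idealisation; the
end-to-end experiments measure the realised error directly instead.

The realised accuracy of a fitted model is summarised by
`average_percent_error()`: the mean over snapshots of
$|F_{\rm approx}-F_{\rm brute}|/|F_{\rm brute}|$ (Euclidean norms for vector
outputs), in percent. Published "average error" figures rarely state whether
they are signed means, absolute means, or RMS; the absolute-mean reading is
the default here and the alternatives are available via the `metric`
argument for sensitivity checks. Snapshots whose reference value is below
$10^{-12}$ times the sweep maximum are excluded from the mean (and counted):
with mixed-sign charges the net energy can cross zero, where relative error
is meaningless.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `degree` | 9 | Surrogate degree $n$ in $d^2$. The worked examples both use 9; translation models then have $\le 2n+1 = 19$ monomials, rotation models $\le 2(n+1)$ of the form $\sin^k\theta$, $\sin^k\theta\cos\theta$. |
| `n_samples` | 2000 | Regression sample size, uniform grid in $d$ (not $d^2$), endpoints included. Uniform-in-$d$ weights the short range, where singular laws vary fastest. |
| `domain` | computed | $[d^2_{\min}, d^2_{\max}]$ from `compute_d2_range()` over the intended sweep, padded 1% per side. The fit is only trusted there; evaluation outside extrapolates with a warning rather than failing, because almost-rigid perturbations legitimately push a few distances slightly past the rigid range. |
| `eps` | $1/(4\pi)$ | Dielectric constant of the Coulomb laws, chosen so the energy is $\lambda\lambda/d$ in dimensionless form. |
| `chunk_size` | 200000 | Pairs per block in the vectorised accumulation; memory control only, results identical. |
| `charge_law` | uniform on [0.5, 1.5] | Single-sign charges keep the net energy bounded away from zero so percent error is well conditioned; mixed-sign (e.g. `normal`) is available. |

## Numerical choices

- **Stable regression.** The Vandermonde system is solved by QR in the
  rescaled variable $t = (d^2 - \text{mid})/\text{half} \in [-1, 1]$ and the
  coefficients are converted to monomials in $d^2$ exactly via the binomial
  theorem. At degree 9 this is comfortably stable; a warning reports the
  estimated digit loss if a much higher degree on a wide domain makes the
  monomial form unreliable.
- **Sparse algebra with pruning.** Pose polynomials are maps from exponent
  tuples to coefficients. After every product, coefficients below $10^{-14}$
  relative to the largest are pruned, preventing rank inflation from
  cancellation dust. Monomial order in a finished model is canonical (total
  degree, then exponents), so identical inputs give byte-identical models
  regardless of the accumulation path.
- **Accumulation precision.** Per-coefficient sums over pairs run through
  R's `colSums`/`sum`, which accumulate in extended (long-double) precision;
  with $MN \approx 10^6$ mixed-sign terms this matches or beats explicit
  compensated summation in double precision.
- **Fast and generic paths.** The one-parameter families use closed-form
  per-pair $d^2$ coefficients and vectorised recurrences (translation: a
  convolution with $(c, b, 1)$; rotation: a two-track recurrence over
  $\sin^m$ and $\sin^m\cos$ with the $\cos^2$ rewrite). The generic path
  loops over pairs with the sparse algebra and covers `general_se3`. The
  test suite requires both to produce identical models.
- **Degenerate inputs.** Coincident cross-pairs make singular laws blow up:
  the brute-force oracle detects them and names the offending pair. Poses
  with non-unit axes, wrong parameter arity, or non-finite values are
  rejected at construction.

## The synthetic experiments

`run_experiment()` reproduces five end-to-end setups on randomly charged
axis-aligned boxes, 500 particles per box and 500 evenly spaced snapshots by
default (both scalable):

- **translation_energy** — Coulomb energy, $x_1 \in [0, 5]$. The box
  dimension parameters give P a $3\times3$ cross-section and Q a $1\times1$
  one; the remaining free lengths (not stated with the published figures)
  are calibrated once, analytically: gap 1 so the closest approach is 1, Q a
  unit cube, and P's thickness $\sqrt{74}-7$ so the farthest corner pair at
  $x_1=5$ gives $d^2 = 82$. The box-hull $d^2$ range is then exactly the
  published $[1, 82]$; the sampled-particle range is slightly interior.
- **rotation_energy** — same two boxes, $\theta \in [-\pi/2, 0]$ about the
  third axis. Where that axis passes is not dimensioned in the source
  figures; the preset puts the frame origin at the centre of Q, so Q spins
  in place. This choice keeps the visited $d^2$ range narrow, which is
  consistent with the published rotation errors being *smaller* than the
  translation ones; an axis far from Q would instead sweep it through a huge
  range and degrade the fit.
- **almost_rigid** — the translation setup, but at every snapshot each
  particle of both bodies is displaced independently and uniformly within a
  cube of edge 0.1–0.5 before the brute-force pass, while the model keeps
  the rigid reference geometry. Error grows with the edge. Note that
  independent per-particle displacements partially average out across
  $MN$ pairs, so the degradation at these sizes is mild; correlated
  (collective) flexibility would hit harder and is not modelled.
- **force / moment** — all box dimensions 1, gap 1 (keeping $d \ge 1$, away
  from the $1/d^3$ blow-up of the force-over-distance surrogate),
  $x_1 \in [0, 2]$, vector outputs. The moment error exceeds the force
  error: moment polynomials multiply the force ones by posed coordinates,
  compounding the surrogate error.

The generator emulates what the published experiments describe: uniform
particle positions in boxes, random charges, a single swept pose parameter.
It does not emulate real molecular structure — no excluded volume, no
correlated charge placement, no solvent screening, no conformational
coupling between bodies — so passing experiments demonstrate the *method's*
fidelity (separated model vs. brute force on the same inputs), not accuracy
on any particular molecular system. For real inputs, use particle CSV/XYZ
files and the same pipeline.

Problem sizes used by the test suite and the acceptance script are the
published ones (500 or 1000 particles per box, 500 snapshots, degree 9);
the structural and exactness checks run at 3–40 particles where brute force
is trivially cheap.

## Known limitations

- The `general_se3` family treats the nine rotation-matrix entries as
  independent primitives; their orthogonality relations are not used to
  compress the basis, so ranks grow quickly with degree. The one-parameter
  families are the practical fast paths.
- No automatic rank truncation or alternating-least-squares compression is
  attempted; the rank is whatever the expansion produces.
- Gradients/Hessians of the separated model, periodic (Ewald) electrostatics
  and cutoff schemes are out of scope.
- Laws whose prefactor does not factor over the two particle properties are
  rejected; that separability is a modelling assumption, not a convenience.
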