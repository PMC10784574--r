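---
title: "Unbalanced regularized optimal mass transport: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbalanced regularized optimal mass transport: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromt)
```

## The problem

Dynamic contrast-enhanced MRI follows an injected tracer through serial
images whose intensity is taken as proportional to tracer density. Classical
dynamic optimal mass transport explains the change between two frames by a
velocity field minimizing kinetic energy under the continuity equation, and
its regularized variant adds a diffusion term, giving an
advection–diffusion constraint. Both require the two frames to carry equal
total mass. Real tracer series violate this badly: total intensity climbs
during wash-in and falls during clearance.

`uromt` removes that restriction by adding a *relative source* $r(t,x)$ to
the constraint: the density may gain mass where $r > 0$ and lose it where
$r < 0$, at a fractional rate per unit time, gated by a binary indicator
$\chi(t,x)$. For one image pair $(\rho_0^{img}, \rho_1^{img})$ the solver
minimizes

$$
\Gamma(v, r) \;=\; \int_0^T\!\!\int_\Omega \rho\,\bigl(\lVert v\rVert^2
  + \alpha\,\chi\,r^2\bigr)\,dx\,dt
  \;+\; \beta \int_\Omega \bigl(\rho(T) - \rho_1^{img}\bigr)^2 dx
$$

subject to
$\partial_t\rho + \nabla\!\cdot\!(\rho v) = \sigma\,\Delta\rho + \chi\rho r$
and $\rho(0) = \rho_0^{img}$. The second cost term is the Fisher–Rao source
penalty; the third replaces the hard terminal constraint by a quadratic
mismatch (free end-point), which avoids over-fitting image noise. The
density is a *state*: it is fully determined by the controls $(v, r)$, so
the optimization runs over the controls alone. As $\alpha \to \infty$ the
source is suppressed and the balanced model is recovered; the package's
tests verify this limit numerically on a synthetic instance.

## Discretization

The domain is a cell-centered $n_1 \times n_2 \times n_3$ grid with
spacings $\Delta x, \Delta y, \Delta z$; the pair interval $[0, T]$ splits
into $m$ substeps of length $\Delta t$. All fields are flattened x-fastest
(R's native array order), the one ordering used everywhere — operators,
file round trips, seeds. Velocities are stored per substep as
$[v_x; v_y; v_z]$ (length $3n$), the source and indicator as length-$n$
vectors.

The discrete cost is

$$
\Gamma_1 = (\Delta t\,\Delta x\Delta y\Delta z)\,
  \textstyle\sum_i \rho_{i+1}^\top (v_{i,x}^2 + v_{i,y}^2 + v_{i,z}^2),
\qquad
\Gamma_2 = (\Delta t\,\Delta x\Delta y\Delta z)\,
  \textstyle\sum_i \rho_{i+1}^\top (r_i^2 \odot \chi_i),
$$
$$
\Gamma_3 = (\Delta x\Delta y\Delta z)\,\lVert \rho_m - \rho_1^{img}\rVert^2,
\qquad
\Gamma = \Gamma_1 + \alpha\,\Gamma_2 + \beta\,\Gamma_3 .
$$

Step-$i$ controls are deliberately paired with the state $\rho_{i+1}$ they
produce (the block-vector convention); the analytic gradient below is the
exact derivative of this pairing, which keeps the gradient check against
finite differences tight rather than approximate.

## Forward dynamics

Each substep applies an operator splitting in three stages:

1. **Source** — $\rho^{src} = (1 + \Delta t\, r_i \odot \chi_i)\odot\rho_i$,
   a diagonal factor $R(r_i)$. The exact ledger
   $\mathrm{sum}(\rho^{src}) - \mathrm{sum}(\rho_i) = \Delta t
   \sum \rho_i r_i \chi_i$ holds to machine precision.
2. **Advection** — $\rho^{adv} = S(v_i)\,\rho^{src}$, a particle-in-cell
   matrix: each cell center is displaced by $\Delta t\,v$, and its mass is
   split over the eight surrounding cell centers with trilinear weights.
   Columns sum to one, so advection conserves mass exactly for any
   velocity.
3. **Diffusion** — backward Euler,
   $(I - \sigma\Delta t\,Q)\,\rho_{i+1} = \rho^{adv}$, with $Q$ the 7-point
   Neumann Laplacian (ghost-point closure; rows sum to zero, symmetric).
   $L = I - \sigma\Delta t\,Q$ is symmetric positive definite; a sparse
   Cholesky factorization is computed once per (grid, $\sigma$, $\Delta t$)
   and reused, with a conjugate-gradient fallback at relative tolerance
   $10^{-10}$. Because $\mathbf{1}^\top Q = 0$, the solve conserves total
   mass, and backward Euler preserves nonnegativity.

Displaced points that leave the box are clamped componentwise to the
cell-center range before the weights are computed, so no mass exits —
consistent with the no-flux boundary condition. The forward construction
does not define what happens at the boundary otherwise; clamping is this
package's declared choice.

## Gradient, Hessian, optimizer

Because $S(v)$ is linear in $v$ (through the per-axis weight factors) and
$R(r)$ is linear in $r$, the states are compositions of the per-step
factors, and the Jacobians $J_v = \partial\rho/\partial v$ and
$J_r = \partial\rho/\partial r$ are lower-triangular block matrices whose
blocks chain the factors $L^{-1} S R$. The package never materializes them:
`jacobian_apply()` runs a forward recursion injecting per step either
$B_j x_{v,j}$ (with $B_j$ the derivative of $S(v_j)w$ in $v_j$ at fixed
post-source mass $w$) or $\Delta t\,S_j(\rho_j \chi_j x_{r,j})$, and
`jacobian_transpose_apply()` runs the reverse recursion, reusing the same
symmetric diffusion factorization. Where the displacement clamp is active
the weight derivative is zero (the clamp freezes that coordinate); exactly
on the boundary the unclamped trilinear derivative is used, a subgradient
choice at a measure-zero set.

The gradient combines the direct elementwise terms
($2 v \odot \rho$ replicated per axis; $2\alpha\, r\chi\odot\rho$) with one
shared adjoint sweep for all Jacobian-transpose terms. The Hessian is the
Gauss–Newton approximation: elementwise curvature from $\Gamma_1$ and
$\Gamma_2$ plus the terminal term
$2\beta(\Delta x\Delta y\Delta z) (J^m)^\top (J^m x)$ coupling $v$ and $r$
through the final-state sensitivity; the second-order term from the
$\Gamma_1$ cross-dependence on the state is dropped, as the Gauss–Newton
scheme prescribes. The handle is symmetric positive semidefinite whenever
the density is nonnegative — verified numerically in the tests.

Each outer iteration solves $Hx = -g$ approximately by preconditioned
conjugate gradients with a Jacobi preconditioner built from the closed-form
elementwise curvature, then backtracks (Armijo) from $t = 1$. Two
stabilizations matter in practice:

* **Feasibility guard.** The source step can only shrink a positive density
  to zero if $1 + \Delta t\,r\chi$ reaches zero; any evaluation with
  $1 + \Delta t\,r\chi < 10^{-8}$ on a positive-density voxel is rejected
  and the line search halves past it. This preserves the density
  interpretation of the state.
* **Inner damping.** In near-empty voxels the Gauss–Newton curvature is
  almost singular, and the undamped inner solve pours enormous control
  updates into them — the guard then forces microscopic steps and the
  search stalls. The inner operator is therefore
  $H + \lambda I$ with $\lambda = \texttt{damping} \cdot \max(\mathrm{diag}\,H)$
  (default damping $10^{-3}$), a Levenberg-style regularization that bounds
  those directions while leaving well-conditioned ones essentially
  untouched.

Defaults (all configurable through `uromt_params()`): 10 Gauss–Newton
iterations per pair, 20 PCG iterations at relative tolerance $10^{-2}$
(loose inner solves are standard for Gauss–Newton), Armijo constant
$10^{-4}$ with at most 12 halvings, relative cost-decrease stop at
$10^{-4}$, zero initial controls (deterministic, reproducible runs). The
reference description of the outer algorithm leaves the inner solver, line
search and stopping rule unspecified; these are the package's own choices.

Multi-frame sequences run loop $k$: frame $k{-}1 \to$ frame $k$, optionally
chaining each loop from the previous loop's final interpolation instead of
the raw frame, which smooths the prolonged dynamics and avoids re-injecting
frame noise.

## Post-processing

*Eulerian*: per-substep speed maps $\lVert v\rVert$ and source maps $r$ at
cell centers, and their plain mean over a frame window
$[N_0, N_1]$ — $\frac{1}{m(N_1-N_0)}\sum_{k,j} s_{k,j}$ and likewise for
$r$. *Lagrangian*: seeds (cell centers above a density threshold,
subsampled per axis) are integrated with one explicit Euler step per
numerical substep, trilinearly interpolating each velocity component and
clamping to the box; this matches the solver's own temporal resolution, and
higher-order integrators would add accuracy the piecewise-constant-in-time
velocity does not support. Each vertex carries the local speed and a Péclet
number

$$
\mathrm{Pe} = \frac{\rho\,\lVert v\rVert}{\sigma\,\lVert\nabla\rho\rVert
  + \varepsilon}, \qquad \varepsilon = 10^{-12},
$$

the ratio of advective to diffusive flux magnitude, with $\rho$ and its
central-difference gradient interpolated from the concurrent interpolated
image. The exact Péclet formula is a declared convention of this package
(the verbal definition — advection rate over diffusion rate — admits
variants); with $\sigma = 0$ the ratio is reported as $+\infty$ wherever
$\rho\lVert v\rVert > 0$. Velocity flux vectors connect each pathline's
start to its end.

## The synthetic benchmark

The generator rebuilds the five-frame "wormhole" phantom: frame $i$ samples

$$
G_i(x,y,z) = \frac{100}{\sqrt{2\pi}}
  \exp\!\Bigl(-\tfrac{(x-0.8i)^2+(y-0.8i)^2+(z-0.8i)^2}{2}\Bigr),
$$

scales the ball of radius 1.5 about the center by $1 + a_i$ with
$a = (0, 0.1, 0.2, 0.1, 0)$ (mass gain to the middle frame, loss after),
and smooths frame $i \ge 1$ with a Gaussian filter of standard deviation
$(i{+}1)\sqrt{0.2}$ voxels — each frame independently from its own
unsmoothed construction, not cumulatively. The smoothing kernel is
truncated at four standard deviations, renormalized, and applied separably
with reflective borders, so it preserves total mass to solver precision.

The blob lives in continuous coordinates; voxel $i$ maps to
$(i - i_0)\,h$ per axis with scale $h = 10/n$ and origin
$i_0 = \lceil 0.36\,n\rceil$. This mapping is a package choice: it places
the five centers (0 to 3.2 per axis) and roughly $3\sigma$ of every blob
inside the box, and at the default $n = 50$ it lands all centers exactly on
grid points so the unsmoothed peak attains the printed amplitude
$100/\sqrt{2\pi}$. At strongly reduced grids the outermost tails are
slightly truncated and the generator warns. Per-pair indicators translate
the radius-1.5 ball linearly across the substeps (center
$0.8(i + j/m)$ per axis); the two-frame variant instead uses an all-ones
indicator.

What the phantom does *not* emulate: MRI noise and bias fields, baseline
signal conversion, anatomy-dependent boundaries, or spatially varying
diffusivity. Tests passing on it demonstrate the solver's mathematical
correctness and its qualitative source/speed patterns, not robustness to
real acquisition artifacts.

## Problem sizes and numerical checks

The test suite works at three scales, chosen so each check exercises what
it must and nothing more: dense-oracle comparisons (forward chain against
explicitly assembled $L^{-1}SR$ products, cost against a materialized
axis-summing operator) on $\sim 4\times4\times3$ grids where dense algebra
is exact and cheap; gradient-versus-finite-difference and adjoint-identity
checks on $5\times5\times4$, $m = 2$ (relative agreement $10^{-4}$ and
$10^{-9}$ respectively); and full solver studies on the $24^3$, $m = 4$
reduction of the sphere phantom, where the five-frame run recovers the
gain-then-loss source pattern inside the indicator region, the
unrestricted two-frame run recovers the departure/arrival sign split, and
the $\alpha$-sweep over $\{10^3, 10^4, 5\cdot10^4\}$ reproduces the
fidelity-versus-source trade-off (NMSE and PCTM nondecreasing, source norm
nonincreasing in $\alpha$). Finite-difference steps for the advection
derivative stay within one linear piece of the piecewise-linear trilinear
weights, since the derivative is one-sided at the (measure-zero) weight
kinks.

Degenerate inputs are handled explicitly: single-cell axes drop out of the
stencil and the trilinear weights; $\sigma = 0$ turns the diffusion solve
into an exact identity; an all-zero indicator reduces the model to balanced
transport (the tests verify the interpolated mass is then constant to
$10^{-10}$).

## Known limitations

* Diffusion is constant and isotropic; spatially varying or tensor
  diffusivity is out of scope.
* Advection is first-order particle-in-cell; sharp fronts blur over many
  substeps, which the free end-point term partly compensates.
* The Gauss–Newton Hessian drops a second-order term, so convergence near
  flat regions relies on the line search; the cost decrease per iteration,
  not a gradient-norm certificate, is the practical stopping signal.
* Control resolution equals the substep count $m$; temporal detail finer
  than $\Delta t$ is invisible to the model.
* The Péclet convention above is one of several in use; comparisons across
  software should check the formula first.
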