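---
title: "Methods: multifunctionality and metastable switching in a reservoir computer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifunctionality and metastable switching in a reservoir computer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rcswitch` studies an echo-state reservoir computer: a random recurrent
network whose internal weights are fixed and only a linear readout is
trained. The driven ("open-loop") system is the ODE

$$\dot r = \gamma\!\left(-r + \tanh(M r + \sigma W_{in} u(t))\right),
\qquad r(0) = 0,$$

with reservoir state $r \in \mathbb{R}^N$, sparse random adjacency matrix
$M$ (each entry independently nonzero with probability $P$, nonzero values
uniform on $[-1,1]$, the whole matrix rescaled to a prescribed spectral
radius $\rho$), and an input matrix $W_{in}$ with exactly one nonzero per
row, so each neuron listens to a single component of the planar drive
$u(t)$. The spectral radius $\rho$ tunes how strongly past states influence
the present one — it is the bifurcation parameter of the whole study.

Training replaces the drive by a readout over quadratic features,
$q(r) = [r;\, r^2]$, giving the autonomous ("closed-loop") system

$$\dot{\hat r} = \gamma\!\left(-\hat r + \tanh(M \hat r +
\sigma W_{in} W_{out}\, q(\hat r))\right),
\qquad \hat u = W_{out}\, q(\hat r).$$

The squared features break the odd symmetry of the tanh flow; without them
every reconstructed attractor coexists with a spurious sign-flipped
"mirror" copy (demonstrated by the package's symmetry tests, which show
exact trajectory negation under a linear-only readout and its absence
under the quadratic one). Because $|\tanh| < 1$, each component satisfies
$\dot{\hat r}_i < 0$ whenever $\hat r_i > 1$, so the box $[-1,1]^N$ is
globally attracting: the closed loop can wander chaotically but can never
diverge. This containment is what forces a new attractor into existence
when the trained orbits destabilize — the origin of the switching
dynamics.

## The seeing-double task

The synthetic-data generator produces the two circular drives
$u(t) = (b_x \cos t + x_{cen},\, b_y \sin t)$: orbit A counter-clockwise
($b_x = b_y = 5$) centered at $(+x_{cen}, 0)$, orbit B its mirror image
through the y-axis, clockwise ($b_x = -5$, $b_y = 5$) centered at
$(-x_{cen}, 0)$. Decreasing $x_{cen}$ moves the circles together: disjoint
for $x_{cen} > 5$, touching at $5$, overlapping below, identical at $0$.
The generator is analytic, so the integrator evaluates it exactly at RK4
half-steps rather than interpolating — this removes an avoidable
$O(\tau^2)$ error source.

What the generator does *not* emulate: measurement noise (the training
signals are noise-free by design), unequal radii or frequencies, and
same-direction rotation pairs. Conclusions drawn from these tests
therefore speak to the clean, perfectly periodic task; robustness to noisy
or asymmetric drives is outside this package's scope.

## Training

Both orbits drive the same open loop from the zero state. States before
$t_{listen}$ are discarded (the listening stage; the echo-state tests
verify that by then the state is independent of the initial condition to
$10^{-6}$), states up to $t_{train}$ form the feature matrix
$X = [X_A, X_B]$, and the readout solves the ridge regression
$W_{out} = Y X^{\top} (X X^{\top} + \beta I)^{-1}$ via a Cholesky
factorization of the Gram matrix (never an explicit inverse; the package
tests agreement with a brute-force `solve()` oracle to $10^{-10}$). The
end-of-training states of the two drives are stored: they are the
canonical initial conditions for testing the closed loop on each orbit.

Parameter defaults, units, and rationale:

| parameter | default | why |
|---|---|---|
| $N$ | 100 | large enough for echo-state behavior at $P = 0.04$, small enough for desk-scale sweeps |
| $P$ | 0.04 | per-element Bernoulli connection probability |
| $\gamma$ | 10 (1/time) | reservoir timescale ~10x faster than the $2\pi$ orbit period |
| $\sigma$ | 0.1 | keeps $\sigma W_{in} u$ in the responsive range of tanh for $|u| \le 13.5$ |
| $\tau$ | 0.01 (time) | fixed RK4 step; order-4 convergence verified on a closed-form benchmark |
| $t_{listen}, t_{train}$ | 50, 550 | ~80 orbit periods of training data, 50,000 regression columns >> $2N$ |
| $\beta$ (ridge) | $10^{-4}$ | conditions the Gram matrix without visible bias |

All are configuration, recorded in every output sidecar. Scaled-down runs
(used for the wide continuation studies; see below) shorten the window to
$t_{listen} = 20$, $t_{train} = 120$, still ~11 periods and 10,000 columns.

## The multifunctionality verdict

The criterion of "indistinguishable" long-term dynamics is operationalized
quantitatively: after discarding the first half of a horizon-500 closed-loop
run (about 80 orbit periods; long enough to expose slow escapes from
unstable orbits), a reconstruction passes if its mean relative radial
deviation from the target circle is below 5% *and* its net rotation
direction (sign of the summed cross products about the center) matches the
orbit. Both passing is `multifunctional`, one is `partial` (typically both
initializations fall onto the same surviving orbit), none is `failed`
(typically the switching regime). The 5% / half-discard choices are this
package's own operationalization of a visual criterion and are labeled as
such in reports.

## Continuation protocol

From a $\rho$ where the closed loop is multifunctional, $\rho$ is lowered
in fixed steps. One base random draw of $(M, W_{in})$ is made per seed and
*rescaled* at every $\rho$ — never redrawn — and the identical input
sequences retrain the readout at each step, so $\rho$ is the only varying
quantity. Each orbit's branch is re-initialized from its own final state
at the previous $\rho$ (the simplest point on or near the attractor,
standard continuation practice), integrated for $t = 200$, the first half
discarded, and the local maxima $x_m$ of the projected x-variable recorded
with an attractor label (orbit A / orbit B / switching / fixed point /
other, decided by a relay-transition count, mean-x sign, and a late-time
displacement test with tolerance $10^{-3} b$ over the last quarter
window). When a branch's reconstruction is lost the carried state simply
follows whatever attractor the flow approaches next, so branches turn into
records of the successor attractors — exactly how the bifurcation panels
of the switching studies are built.

Numerical choices: local maxima use a three-point stencil with plateau
starts counted once; the paper-scale step is 0.001 but the package-default
0.01 keeps a five-$x_{cen}$ study in minutes on one core (the acceptance
study uses 61 grid points x 5 center offsets with the shortened training
window); a random-probe utility (`probe_basins`) draws uniform states in
$[-1,1]^N$ to look for untrained attractors at chosen $\rho$ values.

On the realizations examined during development the protocol reproduces
the qualitative sequence of the original study: stable reconstruction of
both orbits at large $\rho$; loss of one orbit with long transients and
escape times that climb a staircase as $\rho$ approaches restabilization;
a window of metastable switching between the two orbit regions when both
are unstable; and a terminal fixed point at small $\rho$. The specific
bifurcation values are realization-dependent (different seeds shift them),
so the package's tests assert the qualitative structure, never specific
$\rho$ values.

## Switching statistics

Transitions between the metastable states are detected by a two-threshold
non-ideal relay on the projected x-component: the detector changes state
only when the *far* threshold is crossed (defaults $\alpha = -2$,
$\beta = 2$), so excursions into the band never register — the false
alarms a single-threshold detector would emit. Samples exactly at a
threshold do not trigger (a measure-zero, deterministic tie-break).
Residence times are differences of consecutive transition sample times (no
sub-$\tau$ interpolation; the $\le \tau = 0.01$ error is negligible against
minimum residences of a few time units). The open-ended first and last
stays are excluded. Histograms use bins spaced evenly on a log scale
between the data minimum and maximum (default 100), normalized to unit
integral; a weighted log-linear fit over occupied bins recovers a known
exponential rate within 10% in the package's tests. Completed stays can be
tagged with their winding number about the resident orbit's center, which
stratifies the multi-branch residence distributions by loop count.

The orientation question — which metastable state is "high" on the x-axis —
is configurable (`high_state`): the detector's default labeling follows
the relay convention (low state entered below $\alpha$), while every
domain-level caller in the package uses `high_state = "A"` so the labels
match the orbit centers ($+x_{cen}$ for A). Long collections run in chunks
with carried detector state; chunked and single-run transition times are
bit-identical by construction (times are computed from global step
indices).

Escape times are measured from the closed-loop initialization at an
orbit's end-of-training state to the first relay transition out of that
orbit's metastable state; "never escaped within the horizon" is a valid
outcome, reported as `NA`.

## Design decisions that were genuinely open

* The sparsity wording of the source design ("sparsity $P$ or degree
  $N/P$") is internally inconsistent for $N = 100$; the per-element
  Bernoulli($P$) reading is implemented, matching "each element is chosen
  independently".
* Diagonal entries of $M$ are treated like any other entry.
* $\rho = 0$ returns the zero matrix (the limit of the rescaling) so
  sweeps can include the degenerate endpoint; a nilpotent *base* draw with
  a positive target radius is an error instructing the caller to redraw.
* The relay's textual definition is self-contradictory as printed in its
  source; the standard non-ideal relay (cross below $\alpha$ enters the
  low state, cross above $\beta$ the high state) is implemented, which
  reproduces the intended no-false-alarm behavior.
* The readout is retrained in full at every continuation step (listening
  stage included), rather than reusing harvested states across $\rho$.
* Branch re-initialization uses the final integrated state at the previous
  $\rho$; a two-step debounce against long transients is unnecessary under
  this convention because the classifier sees the full tracking window
  after transient discard.

## Known limitations

* All results are per-realization; seeds are recorded everywhere, and
  cross-realization statements in the tests are of the form "at least k of
  n seeds".
* The verdict is radial-error plus rotation; it would accept a
  reconstruction with a matching radius histogram but wrong phase speed
  profile, which the original visual criterion might reject.
* Fixed-step RK4 only; no adaptive or implicit integrators, no
  noise-driven variants.
* The classification of the switching phenomenon (chaotic itinerancy
  versus heteroclinic cycling) is deliberately left open, as in the study
  this package operationalizes.
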