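---
title: "Hard-constrained neural excess Gibbs energy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-constrained neural excess Gibbs energy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gibbsnn` models the scaled molar excess Gibbs energy $g^E/(RT)$ of an
$N$-component liquid mixture as a function of molecular embeddings
$\mathbf e_1,\dots,\mathbf e_N$, temperature $T$ and mole fractions
$\mathbf x$, and derives every other quantity from it by exact
differentiation:

$$\ln\gamma_i
  = \frac{g^E}{RT} + \frac{\partial(g^E/RT)}{\partial x_i}
    - \sum_{j<N} x_j\,\frac{\partial (g^E/RT)}{\partial x_j},
  \qquad
  h^E = -\,\frac{R\,T^2}{s_T}\,\frac{\partial (g^E/RT)}{\partial T^{*}} ,$$

where $T^{*}=(T-\mu_T)/s_T$ is the standard-scaled temperature input.
Because $\ln\gamma_i$ is a derivative of one generating potential, the
Gibbs--Duhem relation $\sum_i x_i\, \mathrm d\ln\gamma_i=0$ and the
pure-component limit $\gamma_i\to1$ hold *by construction*, for trained and
untrained weights alike: the test suite checks them with random weights.

The forward pass is:

1. **Scaling.** Embeddings and temperature are standard-scaled with scalers
   fitted on the training split only (sample standard deviation, floored at
   $10^{-8}$).  $x_N$ is reconstructed from the summation condition.
2. **Embedding refinement.** One Lipschitz-constrained layer with SiLU
   activation maps each scaled embedding to $\boldsymbol\theta_i$.
3. **Similarity and lumping.** $R_{ij} =
   \exp(-\beta\|\boldsymbol\theta_i-\boldsymbol\theta_j\|^2)$ with fixed
   $\beta=100$; the corrected fractions are $\tilde x_i=\sum_j x_j R_{ij}$.
   Components with bitwise-identical embeddings get $R_{ij}=1$ exactly, so
   duplicating a component and splitting its mole fraction reproduces the
   pseudo-binary mixture to machine precision.
4. **Binary projection.** Each pair $(i,j)$ is projected with the symmetric
   (Muggianu-type) map $X_i^{(ij)}=(1+\tilde x_i-\tilde x_j)/2$, which has
   no singular points at infinite dilution.  We evaluate it in the
   half-difference form $0.5 \pm d/2$, which is exactly antisymmetric under
   the pair swap, so the deep-set symmetry below is bitwise.
5. **Deep-set interaction.** Per subsystem, $[\boldsymbol\theta_k,
   X_k^{(ij)}, T^*]$ is passed through a two-layer mixture network for both
   members; the *summed* outputs go through a two-layer property network
   with a scalar linear head, giving $\phi_{ij}$.  The interaction is
   $q_{ij} = \phi_{ij}\,(1-R_{ij})$, which vanishes identically for
   identical components.
6. **Assembly.** $g^E/RT = \sum_{i<j} x_i x_j\, q_{ij}$ — the original
   mole-fraction prefactors with $q$ evaluated at the lumped, projected
   fractions.  Predicting $q$ directly (rather than a subsystem energy
   divided by $X_iX_j$) avoids divisions by zero at infinite dilution.

All layers are 96 wide in the reference configuration (98 inputs for the
mixture network's first layer: refined embedding + projected fraction +
scaled temperature); the scalar head of the property network is forced by
$\phi_{ij}$ being a scalar.  The scaled-down study uses width 32.

## Differentiation strategy

No automatic-differentiation framework is assumed: the package propagates
first- and second-order Taylor jets (value, $\partial/\partial X$,
$\partial^2/\partial X^2$, $\partial/\partial T^*$) analytically through
the layers (`forward.R`), which makes activity coefficients, excess
enthalpies and stability curvatures *exact* derivatives of the implemented
forward pass.  For training, the same jet propagation is recorded on a
small reverse-mode tape (`tape.R`), so losses that depend on derivatives
(activity coefficients, $h^E$, curvature) are differentiated with respect
to the network parameters through the jets — effectively
forward-over-reverse mixed second derivatives.  The SiLU derivative ladder
is implemented in closed form up to fourth order (the backward pass of the
$k$-th derivative needs the $(k{+}1)$-th).  A dedicated test compares the
tape path with the independent plain-numeric path, and every tape primitive
is checked against central finite differences.

## Lipschitz regularization

Each layer stores raw weights, a bias and a learnable constant $c^*$; the
effective weights are $W_\mathrm{raw}/\sigma_{\max}(W_\mathrm{raw})\cdot
\mathrm{softplus}(c^*)$.  $\sigma_{\max}$ is estimated by power iteration
with two warm-started iterations per optimizer step (the estimate enters
the graph as $u^\top W v$ with $u,v$ detached, so gradients flow through
$W$); frozen models use 50 iterations.  $c^*$ is initialized so the scaled
weights equal the raw initialization.  The regularization term is the
product $\prod_l \mathrm{softplus}(c^*_l)$ over all five layers; with
weight zero an L2 penalty on the raw matrices is used instead.  The
activation's Lipschitz constant (≈1.1 for SiLU) is deliberately not
included in the bound; the empirical-bound test absorbs it as
$1.1^{\#\text{activations}}$.

## Training losses

The total loss is the batch-size-normalized weighted sum of five data
losses, the Gibbs stability loss and the Lipschitz term.  All data losses
use smooth-L1 with per-type transition parameters
($\beta_\mathrm{TPXY}=1$, $\beta_\mathrm{ACI}=2$, $\beta_\mathrm{TPX}=1$,
$\beta_\mathrm{LLE}=0.35$, $\beta_\mathrm{HE}=2$), summed over records (the
per-record mean over two activity coefficients for TPXY, hence the
compensating factor $1/2$ on the ACI loss):

* **TPXY** — both $\ln\gamma$ against values derived from $(p, y, x)$ via
  the extended Raoult's law with Antoine vapor pressures.
* **TPX** — $\ln(p/\mathrm{bar})$ of the predicted bubble pressure.
* **ACI** — $\ln\gamma^\infty$ of the solute, evaluated exactly at zero
  solute fraction (the formulas are finite on the simplex boundary).
* **LLE** — the 101-node $\Delta g_\mathrm{mix}/(RT)$ curve is passed
  through the *frozen* surrogate solver; the smooth-L1 on the phase
  compositions is masked by $m_k\in\{0,1\}$, recomputed each forward pass
  from the spinodal criterion (negative curvature somewhere on the grid).
  One-phase-only records contribute only the reported phase's term.
* **HE** — excess enthalpies, compared in kJ/mol (the evaluation metric's
  unit; the reference recipe does not state the loss unit).
* **Gibbs** — $\sum_k \max(0, \min_d S_k)$ with $S_k$ the exact curvature
  of the scaled mixing Gibbs energy on the grid: a hinge that penalizes
  missed miscibility gaps and is exactly zero once a gap is predicted, so
  it is mutually exclusive with the masked LLE term per record.

Training uses AdamW (decoupled decay on the raw weight matrices only) with
a one-cycle cosine schedule (peak $10^{-2}$, warm-up 30%, initial division
25, final division $10^4$).  Model selection minimizes the weighted
validation *data* loss, restricted to epochs at or beyond a configurable
minimum (default 50).  Mixed-type batches arise from seeded proportional
shuffling.

**Loss weights.** The defaults
$(w_\mathrm{TPX}, w_\mathrm{LLE}, w_\mathrm{HE}, w_\mathrm{Gibbs},
w_\mathrm{Lips}) = (1, 5, 0.1, 0.1, 10^{-6})$ stand in for a
hyperparameter grid search that is out of scope here;
`grid_search_weights()` is the harness for re-tuning them on synthetic
data.  On the scaled-down study the ranking of candidate weightings was
dominated by dataset difficulty rather than by the weights themselves, so
the defaults were left untouched.

## Surrogate phase-split solver

Iterative flash solvers are awkward inside a gradient-based training loop,
so binary LLE data are handled by a small surrogate network (101 → 64 → 64
→ 2, ReLU, sigmoid output) that maps a discretized
$\Delta g_\mathrm{mix}/(RT)$ curve to the two phase compositions.
Permutation equivariance — reversing the curve must map $(x',x'')$ to
$(1-x'',1-x')$ — is enforced structurally: the network is evaluated on the
curve and its reversal and the results are cross-paired and averaged,
$x' = (a + 1 - b_r)/2$, $x'' = (b + 1 - a_r)/2$.  This cross-pairing is the
only averaging of the two passes that yields the identity exactly, which is
why it was adopted; the identity holds for untrained weights and is tested
as such.  The surrogate is trained for 200 epochs (Adam, MSE, one-cycle
peak $10^{-2}$) on convex-envelope labels of classical-model curves
(symmetric two-suffix Margules with $A\sim U(2.05,4)$, and asymmetric NRTL
draws), with best-epoch selection on a held-out split; the reference
pipeline instead labels curves from a group-contribution model over
experimental state points, which is out of scope here — the surrogate only
needs representative double-well curves.  Its weights are frozen during
main-model training; gradients reach the main model only through the curve.

## Phase equilibria

$\Delta g_\mathrm{mix}/(RT)$ curves use the $x\ln x\to0$ endpoint
convention (endpoints exactly zero) on a 101-node grid by default (the
grid is a configurable knob; 101 matches the surrogate input).  Phase
splits come from the lower convex hull of the discretized curve
(monotone-chain construction); a hull edge skipping at least two interior
nodes is reported as a miscibility gap.  The two-node threshold suppresses
spurious single-node edges from floating-point ties on convex curves;
physically meaningful gaps at the parameter ranges used here span dozens of
nodes (a symmetric Margules system just past the critical point, $A=2.05$,
already has a gap of width ≈0.27).  An independent exact solver
(`lle_common_tangent`) brackets gaps on a dense grid and polishes the
endpoints with Newton iterations on the isoactivity conditions; the test
suite requires hull and exact solver to agree within one grid step.  LLE is
treated as pressure-independent.  Bubble pressures use the extended
Raoult's law with an ideal vapor phase and the Antoine dialect
$\log_{10}(p^s/\mathrm{bar}) = A - B/(T/\mathrm K + C)$; temperatures
outside a declared validity range warn rather than error.  Binodal
temperature scans report a critical solution temperature as the midpoint of
the bracketing step whenever a gap appears or disappears.

## Synthetic data

Experimental collections of this kind are proprietary, so the package
generates its own study data from classical models with known ground
truth.  Fictitious components carry hash-seeded (SHA-256 of an identifier)
standard-normal embeddings; each binary system's parameters are smooth
functions of its two embeddings through fixed seeded projections,
symmetric in the pair and standardized over the candidate-pair population
— without this link no model could generalize from embeddings to mixture
behavior, which is the premise being emulated.  For two-suffix Margules
systems, $A(T) = a + b/T$ with $b = 400\,s_2$ K and the extremal value of
$A$ over 273–428 K set to $2 + 1.5\tanh((s_1-\text{thr})/0.3)$, anchored
at whichever end of the temperature range maximizes $A$; the threshold is
the empirical quantile of the score $s_1$, and the requested number of
demixing systems is drawn exactly.  Two structural requirements shape this
map.  First, demixing systems must sit clearly above the critical
interaction so their gaps are resolvable on the 101-grid.  Second, the
embedding → parameter surface must be smooth enough for a
Lipschitz-regularized network to represent — a near-step map is
unlearnable by construction.  A smooth squash alone cannot satisfy both
(systems arbitrarily close to the threshold would have arbitrarily narrow
gaps), so the generator additionally excludes a *dead zone* around the
threshold when drawing pairs from the candidate pool: every selected
system is decisively miscible ($A \lesssim 1.3$) or decisively demixing
($A \gtrsim 2.7$), which is also the physically typical situation —
ambient near-critical systems are rare.  NRTL systems apply the same
construction to the critical interaction strength of the symmetric case
(found numerically per nonrandomness parameter), with mild asymmetry and
temperature dependence.

Records mirror the five experimental types.  VLE records are assembled
through the extended Raoult's law with per-component Antoine coefficients
(normal boiling points 300–420 K); LLE endpoints come from the exact
common-tangent solver; 95% of temperatures are uniform on 273–428 K with
5% in adjacent tails.  Default noise levels — sd 0.02 on $\ln\gamma$,
0.005 on LLE mole fractions, 10 J/mol on $h^E$, 0.01 on $\ln p$, 0.005 on
vapor fractions — are plausible experimental magnitudes, configurable, and
deliberately modest; they are placeholders for sensitivity studies, not
calibrated measurement models.  Three quarters of LLE records report only
one phase, matching the typical completeness of experimental LLE
collections.  Curation removes VLE records above 10 bar and LLE records
above 50 bar, and validates ternary infinite-dilution systems against
binary references within ±5 K (systems with endpoint deviations above 0.1
or missing references are dropped; only mixed-solvent points of retained
systems are kept).  Curation is idempotent; a ternary system reporting no
endpoints has nothing to validate and passes through.

What the generator does *not* emulate: correlated instrument error, biased
laboratory-to-laboratory offsets, composition-dependent noise,
association/speciation chemistry, polymers, or electrolytes.  Passing the
scaled-down study therefore demonstrates that the training machinery can
recover smooth embedding-linked ground truth from mixed noisy record types
— not that the model reaches experimental accuracy on real mixtures.

## The scaled-down recovery study

`recovery_experiment()` is the package's end-to-end check: 60 synthetic
binary systems (40% demixing) from a pool of shared components, the
default record counts (35 TPXY, 35 TPX, 4 ACI, 13 LLE, 27 HE per system —
the per-system densities typical of the large experimental collections
this pipeline emulates; ≈6400 records), a surrogate trained on 2000
labeled curves, and a width-32, $D=16$ model trained for 100 epochs at
batch size 128 with selection from epoch 50.  At this study size the
validation split is 10% of the systems, stratified by demixing status: a
5% split would leave three systems, and a selection metric dominated by a
single system.  The experiment
reports the mean per-system MAE of $\ln\gamma$ on freshly drawn noise-free
state points of the training systems, the miscibility-gap detection rate on
the demixing training systems at their LLE record temperatures (counted per
record, aggregated per system by majority), and the relative drop of the
weighted validation data loss from epoch 1.  These problem sizes keep the
full study under ten minutes on one CPU while leaving each system enough
records to constrain its interaction surface.

Single-member training at this scale has visible run-to-run variability:
across master seeds, most runs recover the ground truth to
MAE(ln γ) ≈ 0.02 with full gap detection, but occasional seeds land in a
poorer optimization basin (one in five in our checks).  This is the
variability that ensembling over independent initializations — ten members
in the reference recipe — is designed to average away; the study uses one
member to stay within a desk-scale compute budget, and `n_ensemble` is
exposed for anyone wanting the smoother behavior.

## Numerical choices and conventions

* $R = 8.31446$ J/(mol K); temperatures in K, pressures in bar, $h^E$
  internally in J/mol (kJ/mol in losses and metrics).
* The similarity RBF acts on the embedding network's output exactly as
  emitted (SiLU applied, no further transformation).
* Ensemble predictions average $\ln\gamma$ arithmetically across members;
  since $\ln\gamma$, $g^E/RT$ and $h^E$ are all linear in the generating
  surface and its derivatives, this equals differentiating the mean
  surface.  (Averaging nonlinear derived quantities such as bubble
  pressures would differ; those are computed from the averaged
  $\ln\gamma$.)
* Column minima in the stability loss route their subgradient to the
  first attained minimum; hull construction pops vertices on exact
  collinearity (ties count as non-left turns), so marginally convex curves
  produce no spurious gaps.
* Checkpoints are versioned JSON (~15 significant digits), which
  round-trips predictions far below every tolerance used here; loaders
  reject unknown versions.
* The chemistry toolkit used for SMILES canonicalization is Open Babel;
  the bundled embedding backend is the hash-seeded synthetic one.  A
  transformer-embedding backend (the published 384-dimensional variant)
  is an interface slot: requesting it without the model produces an
  actionable error rather than a download.

## Known limitations

Pressure dependence of the activity coefficients is neglected (VLE data
are curated to ≤10 bar accordingly).  Ions and explicit speciation are not
treated.  Multicomponent phase-split construction (ternary convex
envelopes, three-phase LLLE) is out of scope: the envelope code is binary,
and multicomponent behavior enters only through the Muggianu projection.
The surrogate is trained on positive samples only and cannot signal "no
gap" — that decision always comes from the curvature criterion.  Training
assumes binary systems; the forward pass itself is fully $N$-component.
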