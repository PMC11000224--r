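---
title: "Multicenter n-layer ONIOM and mRRHO thermochemistry in mconiom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicenter n-layer ONIOM and mRRHO thermochemistry in mconiom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mconiom)
```

## The model

Subtractive ONIOM approximates an expensive calculation on a large
"real" system by combining calculations at several levels of theory on
nested fragments. For two layers,

$$E^{\mathrm{ONIOM}} = E^{\mathrm{low}}(\mathrm{real})
  + E^{\mathrm{high}}(\mathrm{model}) - E^{\mathrm{low}}(\mathrm{model}),$$

where the model system is a chemically capped fragment of the real
system. `mconiom` generalizes this to a *dependency tree*: layer 1 is a
single root node holding every atom; each deeper layer holds any number
of mutually disjoint fragments ("centers"), each a strict subset of its
parent. Every node carries a *high* level (its own calculator) and a
*low* level, which is by construction its parent's high level. The
composite property of a node $F_i$ is assembled recursively,

$$F_i = \mathrm{HIGH}_i(\mathrm{model}_i)
  + \sum_{j \in \mathrm{children}(i)}
    \left[ F_j - \mathrm{LOW}_j(\mathrm{model}_j) \right],$$

terminating at leaf nodes, where the property is the high-level model
result alone. Because each child's low level equals its parent's high
level, binding one calculator to every level makes every correction
cancel exactly and the composite collapses to the plain real-system
result. This *telescoping identity* is the single most valuable
invariant in the package: it holds to machine precision for energies,
gradients, and Hessians, and the test suite asserts it over randomized
tree shapes.

Embedding is purely mechanical: layers couple through geometry and the
subtractive expression only. There is no point-charge or electrostatic
coupling, and per-node charge/multiplicity labels are passed through to
calculators untouched.

## Link atoms and the fragment Jacobian

Cutting a covalent bond $a\!-\!b$ (host $a$ inside the fragment,
partner $b$ outside) leaves a dangling valence that is saturated by a
hydrogen cap placed *statically* on the bond vector:

$$\mathbf{r}_{l} = \mathbf{r}_a + k_{ab}\,(\mathbf{r}_b - \mathbf{r}_a),
\qquad
k_{ab} = \frac{R^{\mathrm{cov}}_a + R^{\mathrm{cov}}_H}
              {R^{\mathrm{cov}}_a + R^{\mathrm{cov}}_b}.$$

The factor is the ratio of covalent-radius sums of an $a$–H bond to the
original $a$–$b$ bond, so the cap sits where a hydrogen would bond to
$a$. It depends only on the elements, never on the instantaneous bond
length, so capping introduces no new degrees of freedom. We ship the
single-bond covalent radii of the Pyykkö–Atsumi compilation as an
explicit table; radii enter only through lookups, so users can supply
their own table, and $k_{ab}$ can be overridden per bond in the
partition config. Caps are always hydrogen. When one host atom carries
two caps the construction still works but is geometrically strained, so
it is allowed with a warning rather than forbidden.

Because capped-fragment coordinates are a *linear* map of real-system
coordinates, the map has a constant block-sparse Jacobian
$\mathbf{J}_i = \partial \mathbf{r}'_i / \partial \mathbf{r}$ made of
$3\times 3$ scalar blocks: one identity block for each retained atom,
and the pair $(1-k_{ab})\mathbf{E}$, $k_{ab}\mathbf{E}$ for each cap.
Fragment gradients and Hessians are pulled back into the real basis by

$$\mathbf{g}_i = \mathbf{J}_i^{\mathsf T}\,\mathbf{g}'_i, \qquad
  \mathbf{H}_i = \mathbf{J}_i^{\mathsf T}\,\mathbf{H}'_i\,\mathbf{J}_i,$$

applied blockwise without ever forming the dense matrix. Two structural
facts follow from each model atom's blocks summing to the identity: a
rigid translation of the real system translates every fragment rigidly,
and composite forces from translation/rotation-invariant calculators
carry no net force or torque. Both are asserted numerically in the
tests, alongside a finite-difference check of the full Jacobian
(central differences of the capping map, step $10^{-5}$ Å, agreement to
$10^{-7}$).

The model-system atom ordering is frozen — fragment atoms in ascending
real-system index order, then caps in cut-bond order — because the
Jacobian indexes into it. Atom indices are 1-based everywhere (code,
config files, and messages alike), matching both R convention and the
config ergonomics.

## Calculators

All energy backends implement one contract: geometry in, energy
(Hartree), optional analytic gradient (Hartree/Å) and Hessian
(Hartree/Å²) out. Two built-in toy potentials make the whole machinery
testable offline:

* `harmonic_ff()` — harmonic bonds and angles with analytic gradients.
  Equilibrium lengths default to covalent-radius sums, force constants
  to 0.5 Hartree/Å² (bonds) and 0.05 Hartree/rad² (angles), chosen so
  toy stretching frequencies land in the hundreds-of-cm⁻¹ range of
  real covalent bonds at these reduced masses.
* `dissociative_ff()` — bounded Gaussian bond wells
  $-D\,e^{-(r-r_0)^2/2w^2}$ (default depth $D = 0.15$ Hartree, width
  $w = 0.35$ Å), harmonic angles, and Lennard-Jones interactions
  between pairs beyond 1–3 connectivity. The Gaussian well means bond
  cleavage climbs monotonically to a dissociated plateau with *no
  barrier*, the qualitative signature of Gaussian-bond force fields;
  a dense 1-D scan in the tests confirms there is no intermediate
  maximum. The bond list acts as a reference topology: supplied
  explicitly it is retained while bonds stretch arbitrarily, so
  cleavage and reformation happen on one smooth surface.

Both potentials perceive bonds from geometry (distance below
$1.15\,(R_a + R_b)$, the conventional tolerance, overridable) when no
explicit topology is given. This is what lets a single calculator
evaluate capped fragments of any size, the way a general force field
would. Toy Hessians are central differences of the analytic gradients
(step $5\times 10^{-4}$ Å), accurate to roughly $10^{-8}$ Hartree/Å²
— far below every tolerance used downstream.

`shifted_calculator()` builds affine rescalings $E' = sE + c$ of any
base calculator. These make cheap, *distinguishable* levels of theory
for layered tests: a rescaled level disagrees with its base everywhere,
so cancellations in the composite are exercised nontrivially, while
the algebra of the subtractive scheme ($E = E_{\mathrm{low}}(R) +
(s-1)E_{\mathrm{low}}(M) + c$ for one child) stays checkable in closed
form. `external_adapter()` is a thin subprocess shim (write XYZ, run a
command, parse with a user function) for plugging in real engines; the
suite exercises it only with a mock script.

## Thermochemistry

`normal_modes()` mass-weights a Hessian, projects out rigid-body
motions (translation vectors and Eckart rotation vectors,
orthonormalized by QR, removed by an orthogonal projector), and
diagonalizes. Eigenvalues convert to wavenumbers with negative values
reported as negative (imaginary) frequencies. Linearity is detected
from the inertia tensor (smallest principal moment below $10^{-6}$ of
the largest), switching between 6 and 5 projected modes; a single atom
projects 3.

`mrrho_gibbs()` computes ideal-gas free energies in the modified
rigid-rotor harmonic-oscillator approximation. Translational entropy is
Sackur–Tetrode at 1 atm; rotational entropy is the classical rigid
rotor on the inertia-tensor eigenvalues with symmetry number
$\sigma = 1$ by default (no point-group perception — a documented
limitation). Vibrational entropy uses Grimme's rovibrational
interpolation: each mode contributes

$$S_{\mathrm{vib}}(\nu) = w(\nu)\,S_{\mathrm{HO}}(\nu)
  + \bigl(1 - w(\nu)\bigr)\,S_{\mathrm{fr}}(\nu), \qquad
  w(\nu) = \frac{1}{1 + (\nu_0/\nu)^4},$$

with threshold $\nu_0 = 25\ \mathrm{cm}^{-1}$. The free-rotor branch
uses an effective moment $\mu' = \mu B_{\mathrm{av}}/(\mu +
B_{\mathrm{av}})$ with $B_{\mathrm{av}} = 10^{-44}\ \mathrm{kg\,m^2}$,
which caps the harmonic divergence as $\nu \to 0^+$; the interpolation
exponent and $B_{\mathrm{av}}$ follow the established mRRHO literature
and are config keys, as is $\nu_0$. We apply the smooth weight to *all*
modes — it is within $10^{-3}$ of 1 above 140 cm⁻¹, so this differs
from a hard cutoff only in the transition region; `hard_cutoff = TRUE`
restores the alternative reading (interpolate only below $\nu_0$).

Two consequences are worth knowing. First, $S_{\mathrm{vib}}$ stays
finite for arbitrarily small real frequencies, which is precisely why
the scheme is usable on large floppy systems. Second, because only the
*entropy* is interpolated while ZPE and thermal energies stay harmonic,
the identity $\mathrm{d}G/\mathrm{d}T = -S$ is exact only in the
harmonic regime; with modes inside the interpolation region the
residual is small (order $10^{-3}$ kcal/mol/K on our fixtures) but
nonzero. The tests assert both behaviours rather than pretending the
identity is universal.

Imaginary-mode policy: for a putative minimum, imaginary modes are
excluded with a warning; a structure declared a transition state
(`is_ts = TRUE`) may carry exactly one silently; more than one always
warns; an all-imaginary input is an error.

`oniom_thermo()` chains the engine and the thermochemistry: composite
Hessian → normal modes → mRRHO $G(T)$. This *reconstructed-Hessian*
route is validated against the direct route (finite differences of the
composite gradient) on an optimized disulfide-bridge-like dimer
fixture: the two free energies agree to well under 0.05 kcal/mol, with
the observed gap around $10^{-7}$ kcal/mol because both routes resolve
the same surface to FD accuracy.

`reaction_delta()` and `temperature_scan()` implement the
supramolecular approach: $\Delta X = \sum \mathrm{products} - \sum
\mathrm{reactants}$ over whole-complex single structures, with element
balance enforced (declare small molecules such as H₂ explicitly).
Frequencies are computed once per species and reused across the
temperature grid.

## Synthetic fixtures and what they do (not) show

`make_fixture()` generates all test inputs deterministically from a
seed: a diatomic at its toy equilibrium, a 10-atom chain, a
C–C–S–S–C–C "bridge dimer", and a 40-atom chain carrying three disjoint
S–S bridges with a 3-layer, 3-center partition (1 root + 3 middle + 3
core nodes) — a toy-scale analogue of partitioning a disulfide-rich
protein around its cystine bridges. Geometries are tetrahedral zig-zag
chains at covalent-radius bond lengths with a small (±0.02 Å) seeded
jitter so that nothing is exactly planar or symmetric. Sizes were
chosen as the smallest that still exercise every code path (multiple
centers, multiple layers, caps on both sides of a fragment):
finite-difference Hessians of the 40-atom composite surface complete in
seconds, and nothing in the algebra being tested depends on system
size.

Passing these tests establishes the *machinery* — exact telescoping,
correct Jacobian projection, derivative consistency, thermochemical
closed forms — on smooth analytic surfaces. It says nothing about the
accuracy of any real electronic-structure combination on real
molecules: toy potentials have no electrostatics, no dispersion beyond
a generic LJ term, and no chemistry in their parameters, and the
supramolecular free energies here are single-structure results with no
conformational (landscape) entropy and no solvation.

## Numerical choices

* Units: Å, Hartree, amu, cm⁻¹ internally; user-facing energy reports
  in kcal/mol via 1 Hartree = 627.509474 kcal/mol.
* FD steps: $10^{-5}$ Å (Jacobian checks), $10^{-4}$ Å (gradient
  checks), $5\times 10^{-4}$ Å (Hessians from gradients).
* Composite Hessians are symmetrized after accumulation to suppress FD
  asymmetry noise; `normal_modes()` rejects asymmetry above $10^{-6}$.
* Evaluation caching is keyed by (node, calculator) within one
  composite call — a parent-high/child-low pair on the same fragment
  geometry evaluates once. Geometries are fixed within a call, and no
  cache survives across calls, so caching cannot change any value.
* Accumulation follows the fixed node order of the tree, so results do
  not depend on evaluation order; sibling order and node renaming leave
  the composite invariant (tested).
* The optimizer wraps BFGS (`stats::optim`) with the analytic composite
  gradient and re-checks `max |g|` against the requested tolerance
  (default $10^{-4}$ Hartree/Å), restarting if the inner convergence
  test returned early. Optimizing across a bond-perception boundary is
  the one non-smooth scenario; fixtures keep bonds well inside the
  threshold, and the dissociative potential should be given an explicit
  reference topology whenever bonds are meant to stretch far.

## Known limitations

Mechanical embedding only; no electrostatic or polarized coupling
between layers. No symmetry numbers, no hindered-rotor torsional
corrections beyond the entropy interpolation, no solvation, and no
conformational averaging. PDB input is a coordinates-and-elements
subset, writing is always XYZ. The config format is JSON (YAML
accepted); TOML is not supported.
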