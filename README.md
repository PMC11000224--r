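# mconiom

Multicenter *n*-layer subtractive ONIOM (mechanical embedding) with
mRRHO thermochemistry, in R.

## What problem this solves

Reactions buried inside large (bio)molecules — the textbook case being
disulfide-bond chemistry in a cystine-rich protein — are too big for a
single high-level quantum calculation, yet the chemistry is local.
Subtractive ONIOM handles this by nesting fragments: evaluate the whole
system cheaply, carve out the chemically active region, and correct it
at a better level,

```
E = E_low(real) + E_high(model) − E_low(model)
```

`mconiom` generalizes this to a *dependency tree* with any number of
layers and any number of disjoint "centers" per layer — e.g. one
high-level node per disulfide bridge inside a force-field description
of the whole protein. The package provides, for users who want the
composite machinery with their own energy backends:

* **Partitioning** — tree construction and validation from a simple
  JSON/YAML config; automatic detection of cut bonds; hydrogen link
  atoms placed statically at
  `r_l = r_a + k_ab (r_b − r_a)` with
  `k_ab = (R_a + R_H)/(R_a + R_b)` from covalent radii.
* **Composite assembly** — recursive energies, gradients, and Hessians
  over the tree (`F_i = HIGH_i + Σ_j [F_j − LOW_j]`), with every
  fragment derivative pulled back into the real-system basis through
  its block-sparse Jacobian (`g = Jᵀ g′`, `H = Jᵀ H′ J`).
* **Calculators** — a uniform energy/gradient/Hessian contract, two
  built-in analytic toy potentials (harmonic; dissociative
  Gaussian-bond + LJ, which cleaves bonds without a barrier), affine
  "level" factories, and a subprocess adapter for external engines.
* **Thermochemistry** — normal modes on (composite) Hessians with
  Eckart projection, and modified rigid-rotor harmonic-oscillator
  (mRRHO) Gibbs energies with Grimme's rovibrational entropy
  interpolation below 25 cm⁻¹; supramolecular reaction ΔE/ΔG(T) and
  temperature scans.
* **A CLI** (`inst/cli/mconiom.R`) exposing validate / energy / grad /
  hessian / opt / thermo / scan / fixtures.

## Worked example

Two-layer ONIOM on a generated C–C–S–S–C–C "disulfide bridge dimer",
with the bridge region promoted to a distinguishable higher level:

```r
library(mconiom)

fx   <- make_fixture("bridge_dimer")
tree <- build_tree(fx$system, fx$partition, fx$calculators)
tree
#> <oniom_tree> 6 atoms, 2 nodes, 2 layers
#>   [L1] root: 6 atoms, 0 caps, high=ff low=-
#>   [L2] bridge: 4 atoms, 2 caps, high=sqm low=ff

oniom_composite(tree, fx$calculators, wanted = "gradient")
#> <oniom_result> E = -0.8814768290 Ha (-553.135061 kcal/mol)
#>   |g|max = 6.337e-02 Ha/A
#>   node root         high    -0.74908597  low-corr    +0.00000000
#>   node bridge       high    -0.88166324  low-corr    +0.74927239
```

The per-node breakdown shows the subtractive structure: the bridge
node adds its high-level model energy and removes the same model at the
parent's level; the terms sum to the composite energy. Optimizing on
the composite surface and running thermochemistry on the *assembled*
composite Hessian:

```r
opt <- oniom_optimize(tree, fx$calculators, gtol = 1e-7, maxit = 3000)
oniom_thermo(opt$tree, fx$calculators, T = 298.15)
#> <thermo_result> T = 298.15 K
#>   E(el)      -554.504352 kcal/mol
#>   ZPE           8.773367 kcal/mol
#>   H corr        5.828231 kcal/mol
#>   S            94.993268 cal/mol/K (trans 40.060 rot 27.236 vib 27.697)
#>   G          -568.224997 kcal/mol
```

The twelve vibrational modes span 20–1329 cm⁻¹; the 20 cm⁻¹ torsion
sits in the entropy-interpolation region (w(20 cm⁻¹) ≈ 0.29), which is
exactly where the mRRHO treatment differs from a plain harmonic
oscillator. Binding one calculator to *every* level collapses the
composite to the plain calculation to machine precision — the
telescoping identity that anchors the test suite.

Command-line equivalent:

```sh
Rscript inst/cli/mconiom.R thermo --fixture bridge_dimer --quiet
Rscript inst/cli/mconiom.R energy --geometry sys.xyz \
    --partition part.json --calc ff=dissoc --calc sqm=dissoc:1.15:-0.02
```

## Scope

Mechanical embedding only (no inter-layer electrostatics). The
electronic-structure methods themselves are out of scope: built-in
potentials are analytic toys for exercising the machinery, and real
engines attach through `external_adapter()` or the calculator contract.
See `vignettes/mconiom-methods.Rmd` for the model, parameter choices,
and limitations.
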