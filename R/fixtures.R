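# Deterministic synthetic fixtures: small capped-peptide-like chains and
# disulfide-bridge dimers that exercise every layer of the machinery
# without any external structure files. Geometries are built from
# covalent-radius bond lengths on a tetrahedral zig-zag backbone with a
# small seeded 3D jitter (so nothing is exactly planar or symmetric), and
# each fixture ships a matching toy-calculator set and partition config.

zigzag_chain <- function(elements, jitter = 0.02, seed = 1) {
  n <- length(elements)
  r <- covalent_radius(elements)
  coords <- matrix(0, n, 3)
  # tetrahedral backbone alternating in the xz-plane, jitter in all axes
  half <- (pi - acos(-1 / 3)) / 2
  set.seed(seed)
  noise <- matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  for (i in seq_len(n)[-1]) {
    blen <- r[i - 1] + r[i]
    dirn <- c(cos(half) , 0, sin(half) * (-1)^i)
    coords[i, ] <- coords[i - 1, ] + blen * dirn
  }
  coords + noise
}

#' Generate a deterministic test fixture
#'
#' Each fixture is a small synthetic molecular system with a matching toy
#' calculator set and a partition config ready for [build_tree()]:
#'
#' * `diatomic` — one C2 molecule at its toy-potential equilibrium bond
#'   length (zero-gradient start).
#' * `chain` — a 10-atom carbon zig-zag chain.
#' * `bridge_dimer` — a C-C-S-S-C-C chain, mimicking two alkyl arms
#'   joined by a disulfide bridge, with a 2-layer partition whose inner
#'   node is the C-S-S-C bridge region.
#' * `tri_bridge_peptide` — a 40-atom chain carrying three disjoint S-S
#'   bridges, with a 3-layer 3-center partition: one all-atom root, three
#'   middle-layer fragments wrapping the bridges, and three inner nodes
#'   holding the S-S pairs (1 + 3 + 3 nodes).
#'
#' The same seed always reproduces identical bytes; the seed and
#' generator parameters are recorded in `provenance`.
#'
#' @param kind One of `"diatomic"`, `"chain"`, `"bridge_dimer"`,
#'   `"tri_bridge_peptide"`.
#' @param seed Integer seed for the coordinate jitter.
#' @return A `fixture`: `name`, `system`, `calculators` (named list),
#'   `partition` (config list), `provenance`.
#' @examples
#' fx <- make_fixture("tri_bridge_peptide")
#' length(build_tree(fx$system, fx$partition)$nodes)  # 7
#' @export
make_fixture <- function(kind = c("diatomic", "chain", "bridge_dimer",
                                  "tri_bridge_peptide"),
                         seed = 1L) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })

  base_ff <- dissociative_ff(name = "ff")
  calcs3 <- list(
    ff = base_ff,
    sqm = shifted_calculator(base_ff, scale = 1.15, shift = -0.02,
                             name = "sqm"),
    dft = shifted_calculator(base_ff, scale = 1.32, shift = -0.05,
                             name = "dft")
  )

  if (kind == "diatomic") {
    r0 <- 2 * covalent_radius("C")
    sys <- atomic_system(c("C", "C"),
                         rbind(c(0, 0, 0), c(0, 0, r0)),
                         name = "diatomic")
    calcs <- list(ff = harmonic_ff(list(ka = 0), name = "ff"))
    part <- list(nodes = list(
      list(id = "root", layer = 1, atoms = "1-2", calculator = "ff")))
  } else if (kind == "chain") {
    els <- rep("C", 10)
    sys <- atomic_system(els, zigzag_chain(els, seed = seed),
                         name = "chain")
    calcs <- calcs3[c("ff", "sqm")]
    part <- list(nodes = list(
      list(id = "root", layer = 1, atoms = "1-10", calculator = "ff"),
      list(id = "mid", layer = 2, atoms = "4-7", calculator = "sqm")))
  } else if (kind == "bridge_dimer") {
    els <- c("C", "C", "S", "S", "C", "C")
    sys <- atomic_system(els, zigzag_chain(els, seed = seed),
                         name = "bridge_dimer")
    calcs <- calcs3[c("ff", "sqm")]
    part <- list(nodes = list(
      list(id = "root", layer = 1, atoms = "1-6", calculator = "ff"),
      list(id = "bridge", layer = 2, atoms = "2-5", calculator = "sqm")))
  } else { # tri_bridge_peptide
    els <- rep("C", 40)
    bridges <- list(c(8, 9), c(20, 21), c(32, 33))
    for (b in bridges) els[b] <- "S"
    sys <- atomic_system(els, zigzag_chain(els, seed = seed),
                         name = "tri_bridge_peptide")
    calcs <- calcs3
    part <- list(nodes = list(
      list(id = "root", layer = 1, atoms = "1-40", calculator = "ff"),
      list(id = "mid1", layer = 2, atoms = "5-12", calculator = "sqm"),
      list(id = "mid2", layer = 2, atoms = "17-24", calculator = "sqm"),
      list(id = "mid3", layer = 2, atoms = "29-36", calculator = "sqm"),
      list(id = "core1", layer = 3, atoms = "8-9", calculator = "dft"),
      list(id = "core2", layer = 3, atoms = "20-21", calculator = "dft"),
      list(id = "core3", layer = 3, atoms = "32-33", calculator = "dft")))
  }

  structure(
    list(name = kind, system = sys, calculators = calcs,
         partition = part,
         provenance = list(kind = kind, seed = seed,
                           generator = "mconiom::make_fixture")),
    class = "fixture"
  )
}
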