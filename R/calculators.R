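#' The calculator contract
#'
#' A calculator is any object that maps a geometry (plus formal charge and
#' number of unpaired electrons) to an energy in Hartree, optionally an
#' analytic gradient in Hartree/Angstrom (length `3m`, atom-major), and
#' optionally a `3m x 3m` Hessian in Hartree/Angstrom^2. The built-in toy
#' potentials honour the physical invariances (translation, rotation,
#' gradient/energy consistency) that the composite-assembly machinery
#' relies on; external electronic-structure engines plug in through the
#' same surface via [external_adapter()].
#'
#' @param name Calculator label (appears in breakdowns and logs).
#' @param fn Function `(system, charge, uhf, wanted)` returning a list
#'   with `energy` and, as requested, `gradient` and `hessian`.
#' @param capabilities Character subset of
#'   `c("energy", "gradient", "hessian")`.
#' @param params Parameter list stored for provenance.
#' @return An object of class `oniom_calculator`.
#' @export
new_calculator <- function(name, fn,
                           capabilities = c("energy", "gradient", "hessian"),
                           params = list()) {
  structure(list(name = name, fn = fn, capabilities = capabilities,
                 params = params),
            class = "oniom_calculator")
}

#' @export
print.oniom_calculator <- function(x, ...) {
  cat(sprintf("<oniom_calculator> %s [%s]\n", x$name,
              paste(x$capabilities, collapse = ",")))
  invisible(x)
}

#' Evaluate a calculator on a geometry
#'
#' @param calc An `oniom_calculator`.
#' @param system An `atomic_system` (real system or capped fragment).
#' @param wanted Properties to compute, subset of
#'   `c("energy", "gradient", "hessian")`.
#' @param charge,uhf Formal charge and unpaired-electron count, passed
#'   through to the backend (the toy potentials accept and ignore them).
#' @return A `calc_result`: `energy` (Hartree), optional `gradient`
#'   (Hartree/Angstrom, length `3m`), optional `hessian` (symmetrized),
#'   and `meta` (calculator name + parameters).
#' @export
calc_evaluate <- function(calc, system, wanted = "energy",
                          charge = 0L, uhf = 0L) {
  stopifnot(inherits(calc, "oniom_calculator"))
  missing_cap <- setdiff(wanted, calc$capabilities)
  if (length(missing_cap) > 0) {
    stop("calculator '", calc$name, "' cannot compute: ",
         paste(missing_cap, collapse = ", "), call. = FALSE)
  }
  res <- calc$fn(system, charge, uhf, wanted)
  if ("gradient" %in% wanted &&
      length(res$gradient) != 3L * n_atoms(system)) {
    stop("calculator '", calc$name, "' returned a gradient of wrong length",
         call. = FALSE)
  }
  if ("hessian" %in% wanted && !is.null(res$hessian)) {
    res$hessian <- (res$hessian + t(res$hessian)) / 2
  }
  res$meta <- list(calculator = calc$name, params = calc$params)
  class(res) <- "calc_result"
  res
}

flat_coords <- function(system) as.numeric(t(system$coords))

with_coords <- function(system, x) {
  system$coords <- matrix(x, ncol = 3, byrow = TRUE)
  system
}

#' Finite-difference Hessian from an analytic gradient
#' @noRd
fd_hessian_from_gradient <- function(grad_fn, x0, step = 5e-4) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    H[, i] <- (grad_fn(xp) - grad_fn(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

# --- internal geometry kernels (shared by the toy potentials) -----------

bond_terms_energy_grad <- function(coords, bonds, efun, dfun) {
  # efun(r, row), dfun(r, row): energy and dE/dr for one bond row
  n <- nrow(coords)
  g <- matrix(0, n, 3)
  e <- 0
  for (t in seq_len(nrow(bonds))) {
    i <- bonds$i[t]; j <- bonds$j[t]
    d <- coords[j, ] - coords[i, ]
    r <- sqrt(sum(d^2))
    e <- e + efun(r, bonds[t, ])
    de <- dfun(r, bonds[t, ])
    u <- d / r
    g[i, ] <- g[i, ] - de * u
    g[j, ] <- g[j, ] + de * u
  }
  list(energy = e, grad = g)
}

angle_triples <- function(bonds, n) {
  # all i-j-k with i<k both bonded to centre j
  adj <- vector("list", n)
  for (t in seq_len(nrow(bonds))) {
    adj[[bonds$i[t]]] <- c(adj[[bonds$i[t]]], bonds$j[t])
    adj[[bonds$j[t]]] <- c(adj[[bonds$j[t]]], bonds$i[t])
  }
  out <- list()
  for (j in seq_len(n)) {
    nb <- sort(unique(adj[[j]]))
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) {
      for (b in seq(a + 1, length(nb))) {
        out[[length(out) + 1]] <- c(nb[a], j, nb[b])
      }
    }
  }
  out
}

angle_terms_energy_grad <- function(coords, triples, ka, theta0) {
  n <- nrow(coords)
  g <- matrix(0, n, 3)
  e <- 0
  for (tr in triples) {
    i <- tr[1]; j <- tr[2]; k <- tr[3]
    u <- coords[i, ] - coords[j, ]
    v <- coords[k, ] - coords[j, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    ct <- sum(u * v) / (nu * nv)
    ct <- max(-1, min(1, ct))
    th <- acos(ct)
    st <- sqrt(max(1 - ct^2, 1e-12))
    e <- e + 0.5 * ka * (th - theta0)^2
    pref <- ka * (th - theta0)
    dthi <- (ct * u / nu - v / nv) / (nu * st)
    dthk <- (ct * v / nv - u / nu) / (nv * st)
    g[i, ] <- g[i, ] + pref * dthi
    g[k, ] <- g[k, ] + pref * dthk
    g[j, ] <- g[j, ] - pref * (dthi + dthk)
  }
  list(energy = e, grad = g)
}

perceive_bonds <- function(system, scale = 1.15) {
  tp <- infer_topology(system, scale)
  data.frame(i = tp[, 1], j = tp[, 2])
}

pair_key <- function(ea, eb) {
  paste(pmin(ea, eb), pmax(ea, eb), sep = "-")
}

# --- harmonic toy force field -------------------------------------------

#' Harmonic toy force field
#'
#' Analytic bonded potential
#' `E = sum 1/2 k_b (r - r0)^2 + sum 1/2 k_a (theta - theta0)^2`
#' with analytic gradient and a central-difference Hessian of the
#' gradient. Bonds are taken from an explicit topology in `params$bonds`
#' (columns `i`, `j`, optional `r0`, `k`) when supplied and index-valid
#' for the geometry; otherwise they are perceived from the geometry by
#' the covalent-radius distance rule, with `r0` defaulting to the
#' covalent-radius sum and `k` to `params$kb`. Per-element-pair
#' overrides go in `params$pair_params` (columns `pair` like `"C-S"`,
#' `r0`, `k`); with `params$strict = TRUE` a perceived bond without an
#' override is an error. Angle terms are added for every bonded triple
#' when `params$ka > 0`.
#'
#' @param params List: `kb` (default 0.5 Hartree/A^2), `ka` (default 0.05
#'   Hartree/rad^2, 0 disables angles), `theta0` (default tetrahedral),
#'   `bonds`, `pair_params`, `strict`, `bond_scale`.
#' @param name Calculator label.
#' @return An `oniom_calculator`.
#' @export
harmonic_ff <- function(params = list(), name = "harmonic") {
  p <- utils::modifyList(
    list(kb = 0.5, ka = 0.05, theta0 = acos(-1 / 3), bonds = NULL,
         pair_params = NULL, strict = FALSE, bond_scale = 1.15),
    params)
  fn <- function(system, charge, uhf, wanted) {
    coords <- system$coords
    n <- nrow(coords)
    bonds <- p$bonds
    if (is.null(bonds) || (nrow(bonds) > 0 && max(bonds$i, bonds$j) > n)) {
      bonds <- perceive_bonds(system, p$bond_scale)
    }
    if (nrow(bonds) > 0) {
      if (is.null(bonds$r0) || is.null(bonds$k)) {
        key <- pair_key(system$elements[bonds$i], system$elements[bonds$j])
        r0 <- covalent_radius(system$elements[bonds$i]) +
          covalent_radius(system$elements[bonds$j])
        k <- rep(p$kb, nrow(bonds))
        if (!is.null(p$pair_params)) {
          m <- match(key, p$pair_params$pair)
          hit <- !is.na(m)
          r0[hit] <- p$pair_params$r0[m[hit]]
          k[hit] <- p$pair_params$k[m[hit]]
          if (p$strict && any(!hit)) {
            stop("harmonic_ff: missing pair parameters for ",
                 paste(unique(key[!hit]), collapse = ", "), call. = FALSE)
          }
        } else if (p$strict) {
          stop("harmonic_ff: strict mode requires pair_params",
               call. = FALSE)
        }
        if (is.null(bonds$r0)) bonds$r0 <- r0
        if (is.null(bonds$k)) bonds$k <- k
      }
    }
    energy_grad <- function(x) {
      cc <- matrix(x, ncol = 3, byrow = TRUE)
      e <- 0
      g <- matrix(0, n, 3)
      if (nrow(bonds) > 0) {
        bt <- bond_terms_energy_grad(
          cc, bonds,
          function(r, row) 0.5 * row$k * (r - row$r0)^2,
          function(r, row) row$k * (r - row$r0))
        e <- e + bt$energy; g <- g + bt$grad
      }
      if (p$ka > 0 && nrow(bonds) > 0) {
        at <- angle_terms_energy_grad(cc, angle_triples(bonds, n),
                                      p$ka, p$theta0)
        e <- e + at$energy; g <- g + at$grad
      }
      list(energy = e, grad = as.numeric(t(g)))
    }
    x0 <- flat_coords(system)
    out <- list()
    eg <- energy_grad(x0)
    out$energy <- eg$energy
    if ("gradient" %in% wanted) out$gradient <- eg$grad
    if ("hessian" %in% wanted) {
      out$hessian <- fd_hessian_from_gradient(
        function(x) energy_grad(x)$grad, x0)
    }
    out
  }
  new_calculator(name, fn, params = p)
}

# --- dissociative toy force field ---------------------------------------

#' Dissociative toy force field (Gaussian bonds + LJ)
#'
#' Each listed bond contributes a bounded Gaussian well
#' `E_bond = -D exp(-(r - r0)^2 / (2 w^2))`, which decays to zero at
#' large separation: stretching a bond out of its well climbs
#' monotonically to the dissociated plateau with no barrier in between.
#' Harmonic angle terms act on bonded triples, and a Lennard-Jones term
#' acts between all pairs that are neither bonded nor 1-3 neighbours.
#' The bond list is the potential's reference topology: it is fixed once
#' (explicitly via `params$bonds`, or perceived from the construction-time
#' geometry rule on first use) and retained while bonds stretch, so
#' cleavage and reformation happen on one smooth surface.
#'
#' @param params List: `D` well depth (default 0.15 Hartree), `w` width
#'   (default 0.35 A), `bonds` (data frame `i`, `j`, optional `r0`, `D`,
#'   `w`), `ka`, `theta0` angle terms as in [harmonic_ff()] (default
#'   `ka = 0.03`), `lj_eps` (default 2e-4 Hartree), `lj_rmin_scale`
#'   (LJ minimum at `scale * (R_i + R_j)`, default 1.8), `bond_scale`.
#' @param name Calculator label.
#' @return An `oniom_calculator`.
#' @export
dissociative_ff <- function(params = list(), name = "dissoc") {
  p <- utils::modifyList(
    list(D = 0.15, w = 0.35, bonds = NULL, ka = 0.03,
         theta0 = acos(-1 / 3), lj_eps = 2e-4, lj_rmin_scale = 1.8,
         bond_scale = 1.15),
    params)
  if (p$D <= 0 || p$w <= 0) {
    stop("dissociative_ff: D and w must be positive", call. = FALSE)
  }
  fn <- function(system, charge, uhf, wanted) {
    coords <- system$coords
    n <- nrow(coords)
    bonds <- p$bonds
    if (is.null(bonds) || (nrow(bonds) > 0 && max(bonds$i, bonds$j) > n)) {
      bonds <- perceive_bonds(system, p$bond_scale)
    }
    if (nrow(bonds) > 0) {
      if (is.null(bonds$r0)) {
        bonds$r0 <- covalent_radius(system$elements[bonds$i]) +
          covalent_radius(system$elements[bonds$j])
      }
      if (is.null(bonds$D)) bonds$D <- p$D
      if (is.null(bonds$w)) bonds$w <- p$w
      if (any(bonds$D <= 0) || any(bonds$w <= 0)) {
        stop("dissociative_ff: non-positive per-bond D or w", call. = FALSE)
      }
    }
    triples <- if (nrow(bonds) > 0) angle_triples(bonds, n) else list()
    # pairs excluded from LJ: bonded (1-2) and angle-spanning (1-3)
    excl <- new.env(hash = TRUE)
    pk <- function(i, j) paste(min(i, j), max(i, j))
    for (t in seq_len(nrow(bonds))) assign(pk(bonds$i[t], bonds$j[t]),
                                           TRUE, envir = excl)
    for (tr in triples) assign(pk(tr[1], tr[3]), TRUE, envir = excl)
    lj_pairs <- NULL
    if (n >= 2 && p$lj_eps > 0) {
      all_p <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- !vapply(seq_len(nrow(all_p)), function(t)
        exists(pk(all_p[t, 1], all_p[t, 2]), envir = excl,
               inherits = FALSE), logical(1))
      lj_pairs <- all_p[keep, , drop = FALSE]
    }
    rmin <- NULL
    if (!is.null(lj_pairs) && nrow(lj_pairs) > 0) {
      rmin <- p$lj_rmin_scale *
        (covalent_radius(system$elements[lj_pairs[, 1]]) +
           covalent_radius(system$elements[lj_pairs[, 2]]))
    }
    energy_grad <- function(x) {
      cc <- matrix(x, ncol = 3, byrow = TRUE)
      e <- 0
      g <- matrix(0, n, 3)
      if (nrow(bonds) > 0) {
        bt <- bond_terms_energy_grad(
          cc, bonds,
          function(r, row) -row$D * exp(-(r - row$r0)^2 / (2 * row$w^2)),
          function(r, row) row$D * (r - row$r0) / row$w^2 *
            exp(-(r - row$r0)^2 / (2 * row$w^2)))
        e <- e + bt$energy; g <- g + bt$grad
      }
      if (p$ka > 0 && length(triples) > 0) {
        at <- angle_terms_energy_grad(cc, triples, p$ka, p$theta0)
        e <- e + at$energy; g <- g + at$grad
      }
      if (!is.null(lj_pairs) && nrow(lj_pairs) > 0) {
        d <- cc[lj_pairs[, 2], , drop = FALSE] -
          cc[lj_pairs[, 1], , drop = FALSE]
        r <- sqrt(rowSums(d^2))
        s6 <- (rmin / r)^6
        e <- e + sum(p$lj_eps * (s6^2 - 2 * s6))
        de <- p$lj_eps * 12 * (s6 - s6^2) / r
        u <- d / r
        for (t in seq_len(nrow(lj_pairs))) {
          g[lj_pairs[t, 1], ] <- g[lj_pairs[t, 1], ] - de[t] * u[t, ]
          g[lj_pairs[t, 2], ] <- g[lj_pairs[t, 2], ] + de[t] * u[t, ]
        }
      }
      list(energy = e, grad = as.numeric(t(g)))
    }
    x0 <- flat_coords(system)
    out <- list()
    eg <- energy_grad(x0)
    out$energy <- eg$energy
    if ("gradient" %in% wanted) out$gradient <- eg$grad
    if ("hessian" %in% wanted) {
      out$hessian <- fd_hessian_from_gradient(
        function(x) energy_grad(x)$grad, x0)
    }
    out
  }
  new_calculator(name, fn, params = p)
}

#' Affine-rescaled calculator
#'
#' Wraps a base calculator with `E' = scale * E + shift` (gradients and
#' Hessians scale accordingly). Handy for manufacturing cheap,
#' distinguishable "levels of theory" in layered tests: a rescaled copy
#' disagrees with its base everywhere while sharing its stationary
#' points.
#'
#' @param base An `oniom_calculator`.
#' @param scale Multiplier applied to all properties.
#' @param shift Constant energy offset (Hartree).
#' @param name Calculator label.
#' @return An `oniom_calculator`.
#' @export
shifted_calculator <- function(base, scale = 1, shift = 0,
                               name = paste0(base$name, "_shifted")) {
  stopifnot(inherits(base, "oniom_calculator"))
  fn <- function(system, charge, uhf, wanted) {
    res <- calc_evaluate(base, system, wanted, charge, uhf)
    out <- list(energy = scale * res$energy + shift)
    if (!is.null(res$gradient)) out$gradient <- scale * res$gradient
    if (!is.null(res$hessian)) out$hessian <- scale * res$hessian
    out
  }
  new_calculator(name, fn, capabilities = base$capabilities,
                 params = list(scale = scale, shift = shift,
                               base = base$name))
}

#' External-engine adapter (optional)
#'
#' Thin subprocess shim for real electronic-structure backends: writes
#' the geometry as XYZ, invokes a command, and hands the output to a
#' user-supplied parser. No engine-specific logic ships enabled; the test
#' suite only exercises the shim with a mock engine.
#'
#' @param command Path or name of the engine executable.
#' @param parser Function `(stdout_lines, workdir, system)` returning a
#'   list with `energy` (Hartree) and optionally `gradient`
#'   (Hartree/Angstrom, atom-major).
#' @param args Function `(xyz_path)` returning the argument vector; the
#'   default passes the XYZ path alone.
#' @param capabilities Declared capabilities of the engine.
#' @param name Calculator label.
#' @return An `oniom_calculator`.
#' @export
external_adapter <- function(command, parser,
                             args = function(xyz) xyz,
                             capabilities = c("energy", "gradient"),
                             name = "external") {
  fn <- function(system, charge, uhf, wanted) {
    if (Sys.which(command) == "" && !file.exists(command)) {
      stop("external calculator '", name, "': engine '", command,
           "' not found on PATH (optional dependency)", call. = FALSE)
    }
    wd <- tempfile("mconiom-ext-")
    dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE))
    xyz <- file.path(wd, "input.xyz")
    write_xyz(system, xyz)
    res <- suppressWarnings(
      system2(command, args(xyz), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0L) {
      stop("external calculator '", name, "' failed (exit ", status, "):\n",
           paste(utils::tail(res, 5), collapse = "\n"), call. = FALSE)
    }
    out <- parser(res, wd, system)
    if (is.null(out$energy)) {
      stop("external calculator '", name,
           "': parser produced no energy", call. = FALSE)
    }
    out
  }
  new_calculator(name, fn, capabilities = capabilities,
                 params = list(command = command))
}
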