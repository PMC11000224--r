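# Frequency conversion: eigenvalue lambda in Hartree / (Angstrom^2 amu)
# -> angular frequency^2 in s^-2.
.lambda_to_s2 <- .const$hartree_J / (.const$amu_kg * 1e-20)

inertia_tensor <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(x))) {
    r2 <- sum(x[i, ]^2)
    I <- I + masses[i] * (diag(3) * r2 - outer(x[i, ], x[i, ]))
  }
  I
}

#' Is a geometry linear?
#'
#' Decided from the inertia-tensor eigenvalues: linear when the smallest
#' principal moment is below `tol` times the largest.
#' @noRd
is_linear_geometry <- function(coords, masses, tol = 1e-6) {
  if (nrow(coords) < 3) return(TRUE)
  ev <- eigen(inertia_tensor(coords, masses), symmetric = TRUE,
              only.values = TRUE)$values
  min(ev) < tol * max(ev)
}

#' Harmonic normal-mode analysis
#'
#' Mass-weights a Cartesian Hessian, projects out rigid translations and
#' rotations (Eckart frame), diagonalizes, and converts eigenvalues to
#' wavenumbers. Negative eigenvalues (imaginary frequencies) are
#' reported as negative wavenumbers. Six modes are projected for a
#' nonlinear geometry, five for a linear one (detected from the inertia
#' tensor), three for a single atom.
#'
#' @param hessian Symmetric `3N x 3N` Hessian (Hartree/Angstrom^2).
#' @param masses Atomic masses (amu), length N.
#' @param coords N x 3 coordinates (Angstrom), for the rotational
#'   projector and linearity detection.
#' @param sym_tol Maximum tolerated asymmetry before the input is
#'   rejected (Hartree/Angstrom^2).
#' @return List: `frequencies` (all 3N, cm^-1, ascending), `vibrational`
#'   (the 3N - n_projected physical modes), `modes` (mass-weighted
#'   eigenvectors, columns matching `frequencies`), `n_projected`,
#'   `linear`.
#' @export
normal_modes <- function(hessian, masses, coords, sym_tol = 1e-6) {
  coords <- as.matrix(coords)
  N <- length(masses)
  stopifnot(nrow(coords) == N, all(dim(hessian) == 3 * N))
  asym <- max(abs(hessian - t(hessian)))
  if (asym > sym_tol) {
    stop("Hessian asymmetry ", format(asym, digits = 3),
         " exceeds tolerance", call. = FALSE)
  }
  H <- (hessian + t(hessian)) / 2
  invsqm <- rep(1 / sqrt(masses), each = 3)
  Hmw <- H * outer(invsqm, invsqm)

  # rigid-body vectors in mass-weighted coordinates
  sqm <- rep(sqrt(masses), each = 3)
  com <- colSums(coords * masses) / sum(masses)
  xc <- sweep(coords, 2, com)
  B <- matrix(0, 3 * N, 6)
  for (k in 1:3) {
    v <- numeric(3 * N)
    v[seq(k, 3 * N, by = 3)] <- 1
    B[, k] <- v * sqm
  }
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(N), function(i)
      c(axes[k, 2] * xc[i, 3] - axes[k, 3] * xc[i, 2],
        axes[k, 3] * xc[i, 1] - axes[k, 1] * xc[i, 3],
        axes[k, 1] * xc[i, 2] - axes[k, 2] * xc[i, 1]),
      numeric(3)))
    B[, 3 + k] <- as.numeric(t(rot)) * sqm
  }
  # drop null rigid-body vectors (monoatomic, linear)
  keep <- sqrt(colSums(B^2)) > 1e-8
  B <- B[, keep, drop = FALSE]
  Q <- qr.Q(qr(B))
  # guard against rank deficiency within the kept set (linear molecules)
  rk <- qr(B)$rank
  Q <- Q[, seq_len(rk), drop = FALSE]
  P <- diag(3 * N) - Q %*% t(Q)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  ee <- eigen(Hp, symmetric = TRUE)
  lam <- rev(ee$values)
  vec <- ee$vectors[, rev(seq_len(3 * N)), drop = FALSE]
  freq <- sign(lam) * sqrt(abs(lam) * .lambda_to_s2) /
    (2 * pi * .const$c_cm)
  ord <- order(freq)
  freq <- freq[ord]
  vec <- vec[, ord, drop = FALSE]
  n_proj <- rk
  # the n_proj projected modes are those of smallest |frequency|
  drop_idx <- order(abs(freq))[seq_len(n_proj)]
  vib <- freq[-drop_idx]
  list(frequencies = freq, vibrational = sort(vib), modes = vec,
       n_projected = n_proj,
       linear = is_linear_geometry(coords, masses))
}

#' Head-Gordon style interpolation weight
#'
#' `w(nu) = 1 / (1 + (nu0 / nu)^alpha)`: close to 1 well above the
#' threshold `nu0`, 0.5 at the threshold, and vanishing as `nu -> 0`,
#' where the free-rotor entropy takes over from the diverging
#' harmonic-oscillator expression.
#'
#' @param nu Wavenumber(s), cm^-1.
#' @param nu0 Interpolation threshold (default 25 cm^-1).
#' @param alpha Interpolation exponent (default 4).
#' @return Weight(s) in (0, 1).
#' @export
rovib_weight <- function(nu, nu0 = 25, alpha = 4) {
  1 / (1 + (nu0 / nu)^alpha)
}

# Molar entropies in J/mol/K, energies in J/mol; nu in cm^-1.
s_ho <- function(nu, T) {
  theta <- .const$h * .const$c_cm * nu / .const$kB    # K
  x <- theta / T
  .const$R * (x / expm1(x) - log(-expm1(-x)))
}

s_free_rotor <- function(nu, T, Bav = 1e-44) {
  mu <- .const$h / (8 * pi^2 * .const$c_cm * nu)       # kg m^2
  mup <- mu * Bav / (mu + Bav)
  .const$R * (0.5 + log(sqrt(8 * pi^3 * mup * .const$kB * T /
                               .const$h^2)))
}

s_trans_st <- function(mass_amu, T, p = .const$atm_Pa) {
  m <- mass_amu * .const$amu_kg
  q <- (2 * pi * m * .const$kB * T / .const$h^2)^1.5 * .const$kB * T / p
  .const$R * (log(q) + 1 + 1.5)
}

#' mRRHO thermochemistry of one structure
#'
#' Ideal-gas rigid-rotor harmonic-oscillator free energy with Grimme's
#' rovibrational entropy interpolation: each mode's vibrational entropy
#' is `w * S_HO + (1 - w) * S_fr` with the weight of [rovib_weight()],
#' so harmonic entropies are used essentially unchanged above the
#' threshold while low-frequency modes are damped toward a hindered
#' free-rotor limit instead of diverging. Translational entropy is
#' Sackur-Tetrode at the standard pressure; rotational entropy comes
#' from the classical rigid rotor on the inertia tensor. The zero-point
#' energy and thermal vibrational energy use the harmonic expressions
#' over the real modes.
#'
#' Imaginary frequencies (negative wavenumbers) are excluded from the
#' sums: with a warning for a putative minimum, silently for exactly one
#' when `params$is_ts` marks the input as a transition structure.
#'
#' @param system `atomic_system` the frequencies belong to (masses,
#'   coordinates, rotational constants).
#' @param frequencies Vibrational wavenumbers (cm^-1); negative values
#'   denote imaginary modes.
#' @param T Temperature (K), scalar.
#' @param E_elec Electronic (composite) energy in Hartree, added to G.
#' @param params List of knobs: `nu0` (25 cm^-1), `alpha` (4), `Bav`
#'   (1e-44 kg m^2), `pressure` (Pa, default 1 atm), `sigma` (rotational
#'   symmetry number, default 1), `is_ts` (default FALSE),
#'   `hard_cutoff` (apply the interpolation only below `nu0`; default
#'   FALSE uses the smooth weight everywhere).
#' @return A `thermo_result`: `frequencies`, `zpe`, `U_trans`, `U_rot`,
#'   `U_vib`, `S_trans`, `S_rot`, `S_vib` (kcal/mol and cal/mol/K),
#'   `H_corr`, `G` (kcal/mol, includes `E_elec`), `T`, `n_imaginary`.
#' @export
mrrho_gibbs <- function(system, frequencies, T = 298.15, E_elec = 0,
                        params = list()) {
  p <- utils::modifyList(
    list(nu0 = 25, alpha = 4, Bav = 1e-44, pressure = .const$atm_Pa,
         sigma = 1, is_ts = FALSE, hard_cutoff = FALSE),
    params)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  freqs <- as.numeric(frequencies)
  imag <- freqs < 0
  n_imag <- sum(imag)
  if (n_imag == length(freqs) && length(freqs) > 0) {
    stop("all frequencies imaginary; not a meaningful stationary point",
         call. = FALSE)
  }
  if (n_imag > 0) {
    if (p$is_ts && n_imag == 1) {
      # expected for a transition structure; drop silently
    } else {
      warning(n_imag, " imaginary frequenc",
              if (n_imag == 1) "y" else "ies",
              " excluded from thermochemistry", call. = FALSE)
    }
  }
  nu <- freqs[!imag]
  nu <- nu[nu > 1e-8]
  N <- n_atoms(system)
  mass <- sum(system$masses)
  kcal <- function(J_mol) J_mol / .const$cal_J / 1000
  cal <- function(J_molK) J_molK / .const$cal_J

  # translation
  U_trans <- 1.5 * .const$R * T
  S_trans <- s_trans_st(mass, T, p$pressure)

  # rotation
  if (N == 1) {
    U_rot <- 0; S_rot <- 0
  } else {
    Iev <- eigen(inertia_tensor(system$coords, system$masses),
                 symmetric = TRUE, only.values = TRUE)$values
    Iev_SI <- Iev * .const$amu_kg * 1e-20
    if (is_linear_geometry(system$coords, system$masses)) {
      I1 <- max(Iev_SI)
      U_rot <- .const$R * T
      S_rot <- .const$R *
        (1 + log(8 * pi^2 * I1 * .const$kB * T / (p$sigma * .const$h^2)))
    } else {
      U_rot <- 1.5 * .const$R * T
      qr_ <- sqrt(pi * prod(Iev_SI)) / p$sigma *
        (8 * pi^2 * .const$kB * T / .const$h^2)^1.5
      S_rot <- .const$R * (1.5 + log(qr_))
    }
  }

  # vibration
  if (length(nu) > 0) {
    theta <- .const$h * .const$c_cm * nu / .const$kB
    zpe_J <- 0.5 * .const$R * sum(theta)     # R*theta = NA*h*c*nu
    U_vib <- .const$R * sum(theta / expm1(theta / T))
    w <- rovib_weight(nu, p$nu0, p$alpha)
    if (p$hard_cutoff) w[nu >= p$nu0] <- 1
    S_vib <- sum(w * s_ho(nu, T) + (1 - w) * s_free_rotor(nu, T, p$Bav))
  } else {
    zpe_J <- 0; U_vib <- 0; S_vib <- 0
  }

  S_tot <- S_trans + S_rot + S_vib
  H_corr_J <- U_trans + U_rot + U_vib + .const$R * T   # +pV for ideal gas
  G_kcal <- hartree_to_kcal(E_elec) + kcal(zpe_J) + kcal(H_corr_J) -
    T * kcal(S_tot)

  structure(
    list(frequencies = freqs, zpe = kcal(zpe_J),
         U_trans = kcal(U_trans), U_rot = kcal(U_rot), U_vib = kcal(U_vib),
         S_trans = cal(S_trans), S_rot = cal(S_rot), S_vib = cal(S_vib),
         H_corr = kcal(H_corr_J), E_elec = E_elec,
         G = G_kcal, T = T, n_imaginary = n_imag),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> T = %.2f K\n", x$T))
  cat(sprintf("  E(el)   %14.6f kcal/mol\n", hartree_to_kcal(x$E_elec)))
  cat(sprintf("  ZPE     %14.6f kcal/mol\n", x$zpe))
  cat(sprintf("  H corr  %14.6f kcal/mol\n", x$H_corr))
  cat(sprintf("  S       %14.6f cal/mol/K (trans %.3f rot %.3f vib %.3f)\n",
              x$S_trans + x$S_rot + x$S_vib, x$S_trans, x$S_rot, x$S_vib))
  cat(sprintf("  G       %14.6f kcal/mol\n", x$G))
  if (x$n_imaginary > 0) {
    cat(sprintf("  (%d imaginary mode(s) excluded)\n", x$n_imaginary))
  }
  invisible(x)
}

#' Thermochemistry from a composite ONIOM Hessian
#'
#' One-call pipeline: assemble the composite energy and Hessian over the
#' tree, run [normal_modes()], and evaluate [mrrho_gibbs()] at the
#' requested temperature. This is the reconstructed-Hessian route to
#' free-energy corrections for systems too large for a single high-level
#' Hessian.
#'
#' @param tree An `oniom_tree`.
#' @param calculators Named calculator bindings.
#' @param T Temperature (K).
#' @param params Passed to [mrrho_gibbs()].
#' @return A `thermo_result` with an extra `modes` field.
#' @export
oniom_thermo <- function(tree, calculators, T = 298.15, params = list()) {
  res <- oniom_composite(tree, calculators,
                         wanted = c("energy", "gradient", "hessian"))
  nm <- normal_modes(res$hessian, tree$system$masses, tree$system$coords)
  th <- mrrho_gibbs(tree$system, nm$vibrational, T = T,
                    E_elec = res$energy, params = params)
  th$modes <- nm
  th
}

#' Define a reaction species
#'
#' Bundles what [reaction_delta()] needs per species: the structure, its
#' electronic (or composite) energy, and its vibrational frequencies.
#' Build one from raw pieces, or let it evaluate a calculator / ONIOM
#' tree itself.
#'
#' @param system An `atomic_system`, or an `oniom_tree`.
#' @param calculator Optional calculator (or named calculator list for a
#'   tree) used to compute the energy and Hessian when `energy` /
#'   `frequencies` are not supplied.
#' @param energy Electronic energy (Hartree).
#' @param frequencies Vibrational wavenumbers (cm^-1).
#' @param coef Stoichiometric coefficient (positive integer).
#' @param label Species label for tables.
#' @param thermo_params Per-species [mrrho_gibbs()] params (e.g. sigma).
#' @return An `oniom_species`.
#' @export
reaction_species <- function(system, calculator = NULL, energy = NULL,
                             frequencies = NULL, coef = 1,
                             label = NULL, thermo_params = list()) {
  if (inherits(system, "oniom_tree")) {
    tree <- system
    if (is.null(energy) || is.null(frequencies)) {
      res <- oniom_composite(tree, calculator,
                             wanted = c("energy", "gradient", "hessian"))
      nm <- normal_modes(res$hessian, tree$system$masses,
                         tree$system$coords)
      energy <- energy %||% res$energy
      frequencies <- frequencies %||% nm$vibrational
    }
    system <- tree$system
  } else if (!is.null(calculator) &&
             (is.null(energy) || is.null(frequencies))) {
    want <- c("energy", if (is.null(frequencies)) "hessian")
    res <- calc_evaluate(calculator, system, want)
    energy <- energy %||% res$energy
    if (is.null(frequencies)) {
      nm <- normal_modes(res$hessian, system$masses, system$coords)
      frequencies <- nm$vibrational
    }
  }
  if (is.null(energy)) stop("species needs an energy", call. = FALSE)
  structure(
    list(system = system, energy = energy, frequencies = frequencies,
         coef = coef, label = label %||% system$name,
         thermo_params = thermo_params),
    class = "oniom_species"
  )
}

element_counts <- function(species_list) {
  tab <- list()
  for (sp in species_list) {
    t0 <- table(sp$system$elements)
    for (el in names(t0)) {
      tab[[el]] <- (tab[[el]] %||% 0) + sp$coef * t0[[el]]
    }
  }
  tab
}

#' Supramolecular reaction energetics
#'
#' `Delta X = sum(products) - sum(reactants)` with stoichiometric
#' coefficients, for the electronic energy and, when every species
#' carries frequencies, the mRRHO Gibbs energy at each requested
#' temperature. Species element counts must balance across the arrow
#' (declare small molecules such as H2 explicitly as species).
#'
#' @param reactants,products Lists of [reaction_species()].
#' @param T Temperature(s), K.
#' @param params Shared [mrrho_gibbs()] params merged under each
#'   species' own `thermo_params`.
#' @return A data frame with one row per temperature: `T`, `dE_kcal`,
#'   `dG_kcal` (NA when frequencies are missing).
#' @export
reaction_delta <- function(reactants, products, T = 298.15,
                           params = list()) {
  if (inherits(reactants, "oniom_species")) reactants <- list(reactants)
  if (inherits(products, "oniom_species")) products <- list(products)
  bal_r <- element_counts(reactants)
  bal_p <- element_counts(products)
  els <- union(names(bal_r), names(bal_p))
  for (el in els) {
    if ((bal_r[[el]] %||% 0) != (bal_p[[el]] %||% 0)) {
      stop("stoichiometry error: element ", el, " unbalanced (",
           bal_r[[el]] %||% 0, " reactant vs ", bal_p[[el]] %||% 0,
           " product)", call. = FALSE)
    }
  }
  dE <- sum(vapply(products, function(s) s$coef * s$energy, numeric(1))) -
    sum(vapply(reactants, function(s) s$coef * s$energy, numeric(1)))
  have_freq <- all(vapply(c(reactants, products),
                          function(s) !is.null(s$frequencies), logical(1)))
  rows <- lapply(T, function(Tk) {
    dG <- NA_real_
    if (have_freq) {
      gsum <- function(side, sign) {
        sum(vapply(side, function(s) {
          th <- mrrho_gibbs(s$system, s$frequencies, T = Tk,
                            E_elec = s$energy,
                            params = utils::modifyList(params,
                                                       s$thermo_params))
          sign * s$coef * th$G
        }, numeric(1)))
      }
      dG <- gsum(products, 1) + gsum(reactants, -1)
    }
    data.frame(T = Tk, dE_kcal = hartree_to_kcal(dE), dG_kcal = dG)
  })
  do.call(rbind, rows)
}

#' Reaction free energy over a temperature grid
#'
#' Vectorized [reaction_delta()]: frequencies are computed once per
#' species and only the thermostatistical sums are redone per
#' temperature.
#'
#' @param reactants,products Lists of [reaction_species()].
#' @param T_grid Numeric vector of temperatures (K), non-empty.
#' @param params Shared [mrrho_gibbs()] params.
#' @return Data frame `T`, `dE_kcal`, `dG_kcal`, one row per grid point.
#' @export
temperature_scan <- function(reactants, products, T_grid,
                             params = list()) {
  if (length(T_grid) == 0) stop("empty temperature grid", call. = FALSE)
  reaction_delta(reactants, products, T = sort(as.numeric(T_grid)),
                 params = params)
}
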