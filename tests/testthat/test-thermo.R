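const <- list(h = 6.62607015e-34, kB = 1.380649e-23, c = 2.99792458e10,
              R = 8.314462618, amu = 1.66053906660e-27,
              Eh = 4.3597447222071e-18, NA_ = 6.02214076e23)

test_that("diatomic frequency matches the sqrt(k/mu) closed form", {
  k <- 0.5   # Hartree / A^2
  fx <- make_fixture("diatomic")
  calc <- harmonic_ff(list(ka = 0))
  H <- calc_evaluate(calc, fx$system,
                     c("energy", "gradient", "hessian"))$hessian
  nm <- normal_modes(H, fx$system$masses, fx$system$coords)
  expect_length(nm$vibrational, 1)
  expect_true(nm$linear)
  mu <- prod(fx$system$masses) / sum(fx$system$masses)
  k_SI <- k * const$Eh / 1e-20          # J / m^2
  nu_cf <- sqrt(k_SI / (mu * const$amu)) / (2 * pi * const$c)
  expect_lt(abs(nm$vibrational - nu_cf), 0.01)
})

test_that("rigid-body modes vanish after projection", {
  fx <- make_fixture("bridge_dimer")
  calc <- dissociative_ff()
  H <- calc_evaluate(calc, fx$system,
                     c("energy", "gradient", "hessian"))$hessian
  nm <- normal_modes(H, fx$system$masses, fx$system$coords)
  expect_equal(nm$n_projected, 6)
  removed <- setdiff(seq_along(nm$frequencies),
                     match(nm$vibrational, nm$frequencies))
  expect_lt(max(abs(nm$frequencies[removed])), 1)
  expect_error(normal_modes(H + matrix(1e-3, nrow(H), ncol(H)) *
                              upper.tri(H),
                            fx$system$masses, fx$system$coords),
               "asymmetry")
})

test_that("bent triatomic frequencies match an independent FD pipeline", {
  # water-like toy: O-H bonds + angle term
  rOH <- covalent_radius("O") + covalent_radius("H")
  th0 <- acos(-1 / 3)
  sys <- atomic_system(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          rOH * c(sin(th0 / 2), 0, cos(th0 / 2)),
          rOH * c(-sin(th0 / 2), 0, cos(th0 / 2))),
    name = "waterish")
  calc <- harmonic_ff()
  H <- calc_evaluate(calc, sys, c("energy", "gradient", "hessian"))$hessian
  nm <- normal_modes(H, sys$masses, sys$coords)
  expect_length(nm$vibrational, 3)
  expect_true(all(nm$vibrational > 100))
  # independent route: double central differences of the energy
  efun <- function(x) {
    s <- sys; s$coords <- unflatten(x)
    calc_evaluate(calc, s, "energy")$energy
  }
  x0 <- flatten(sys$coords)
  h <- 1e-3
  n <- length(x0)
  Hfd <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xpp <- x0; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm <- x0; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp <- x0; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm <- x0; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      Hfd[i, j] <- (efun(xpp) - efun(xpm) - efun(xmp) + efun(xmm)) /
        (4 * h * h)
    }
  }
  nm2 <- normal_modes((Hfd + t(Hfd)) / 2, sys$masses, sys$coords)
  expect_equal(nm$vibrational, nm2$vibrational, tolerance = 1e-3)
})

test_that("harmonic-oscillator entropy matches the textbook closed form", {
  nu <- 1000; T <- 298.15
  sys <- atomic_system(c("C", "C"),
                       rbind(c(0, 0, 0), c(0, 0, 1.5)))
  th <- mrrho_gibbs(sys, nu, T = T)
  x <- const$h * const$c * nu / (const$kB * T)
  S_ho <- const$R * (x / (exp(x) - 1) - log(1 - exp(-x))) / 4.184
  # at 1000 cm^-1 the interpolation weight is ~1 (1 - w ~ 4e-7)
  expect_lt(abs(th$S_vib - S_ho), 1e-6)
  # exactly at the threshold the weight is one half by construction
  expect_identical(rovib_weight(25), 0.5)
  w_half_S <- mrrho_gibbs(sys, 25, T = T)$S_vib
  nu0 <- 25
  mu_fr <- const$h / (8 * pi^2 * const$c * nu0)
  mup <- mu_fr * 1e-44 / (mu_fr + 1e-44)
  S_fr <- const$R * (0.5 + log(sqrt(8 * pi^3 * mup * const$kB * T /
                                      const$h^2))) / 4.184
  x0 <- const$h * const$c * nu0 / (const$kB * T)
  S_ho25 <- const$R * (x0 / (exp(x0) - 1) - log(1 - exp(-x0))) / 4.184
  expect_equal(w_half_S, 0.5 * S_ho25 + 0.5 * S_fr, tolerance = 1e-10)
})

test_that("the rovibrational interpolation weight behaves as designed", {
  nus <- 10^seq(log10(0.1), log10(4000), length.out = 200)
  w <- rovib_weight(nus)
  expect_true(all(diff(w) > 0))          # monotone increasing
  expect_lt(w[1], 1e-9)                  # -> 0 as nu -> 0+
  expect_gt(w[length(w)], 1 - 1e-8)      # -> 1 as nu >> nu0
  # vibrational entropy stays finite down to 0.1 cm^-1
  sys <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  S <- vapply(nus, function(nu) mrrho_gibbs(sys, nu)$S_vib, numeric(1))
  expect_true(all(is.finite(S)))
  expect_lt(max(S), 15)  # free-rotor cap, cal/mol/K; bare HO would diverge
})

test_that("monoatomic gas free energy reduces to Sackur-Tetrode", {
  T <- 298.15; m_amu <- 39.948
  sys <- atomic_system("Ar", matrix(0, 1, 3))
  th <- mrrho_gibbs(sys, numeric(0), T = T, E_elec = -1)
  # independent hand-coded oracle
  m <- m_amu * const$amu
  S <- const$R * (log((2 * pi * m * const$kB * T / const$h^2)^1.5 *
                        const$kB * T / 101325) + 2.5)
  G_J <- 2.5 * const$R * T - T * S       # U(3/2 RT) + pV(RT) - TS
  G_kcal <- -1 * 627.509474 + G_J / 4184
  expect_equal(th$G, G_kcal, tolerance = 1e-8)
  expect_equal(th$S_rot, 0)
  expect_equal(th$zpe, 0)
  # internal consistency: G recomposes from its parts
  expect_equal(th$G,
               hartree_to_kcal(th$E_elec) + th$zpe + th$H_corr -
                 th$T * (th$S_trans + th$S_rot + th$S_vib) / 1000,
               tolerance = 1e-8)
})

test_that("imaginary-mode policy distinguishes minima from saddles", {
  sys <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  expect_warning(mrrho_gibbs(sys, c(-40, 300, 800)), "imaginary")
  expect_silent(mrrho_gibbs(sys, c(-40, 300, 800),
                            params = list(is_ts = TRUE)))
  expect_warning(mrrho_gibbs(sys, c(-40, -20, 800),
                             params = list(is_ts = TRUE)), "imaginary")
  expect_error(mrrho_gibbs(sys, c(-40, -20)), "all frequencies imaginary")
  expect_error(mrrho_gibbs(sys, 100, T = -3), "positive")
})

test_that("dG/dT equals -S along the temperature axis", {
  sys <- atomic_system(rep("C", 4),
                       make_fixture("chain")$system$coords[1:4, ])
  slope <- function(freqs) {
    th <- mrrho_gibbs(sys, freqs, T = 298.15)
    dT <- 0.05
    Gp <- mrrho_gibbs(sys, freqs, T = 298.15 + dT)$G
    Gm <- mrrho_gibbs(sys, freqs, T = 298.15 - dT)$G
    c(fd = (Gp - Gm) / (2 * dT),
      S = (th$S_trans + th$S_rot + th$S_vib) / 1000)
  }
  # all modes well above the interpolation threshold: thermodynamic
  # identity holds to FD accuracy
  s1 <- slope(c(150, 400, 800, 1600))
  expect_lt(abs(s1["fd"] + s1["S"]), 1e-4)
  # with modes in the interpolation region the entropy is damped while
  # the enthalpy stays harmonic, so the identity is only approximate --
  # a known property of the interpolated-entropy scheme
  s2 <- slope(c(20, 80, 300))
  expect_lt(abs(s2["fd"] + s2["S"]), 1e-2)
  # G(T) is continuous across the grid
  Gs <- vapply(seq(250, 350, 1), function(Tk)
    mrrho_gibbs(sys, c(20, 80, 300), T = Tk)$G, numeric(1))
  expect_lt(max(abs(diff(Gs, differences = 2))), 1e-3)
})

test_that("reaction deltas follow stoichiometric arithmetic", {
  sysA <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                        name = "A")
  # identity reaction: everything cancels
  spA <- reaction_species(sysA, energy = -2, frequencies = c(100, 900))
  d0 <- reaction_delta(list(spA), list(spA))
  expect_equal(d0$dE_kcal, 0)
  expect_equal(d0$dG_kcal, 0)
  # fabricated energies: 2A -> A2 with E_A = -1, E_A2 = -3 Hartree
  sysA2 <- atomic_system(rep("C", 4),
                         make_fixture("chain")$system$coords[1:4, ],
                         name = "A2")
  spA1 <- reaction_species(sysA, energy = -1, coef = 2)
  spA2 <- reaction_species(sysA2, energy = -3)
  d1 <- reaction_delta(list(spA1), list(spA2))
  expect_equal(d1$dE_kcal, hartree_to_kcal(-1))
  # element balance enforced
  spBad <- reaction_species(atomic_system("S", matrix(0, 1, 3)),
                            energy = 0)
  expect_error(reaction_delta(list(spA1), list(spBad)),
               "stoichiometry error")
})

test_that("toy dimerization energetics recompute outside the reaction API", {
  calc <- dissociative_ff(name = "ff")
  fx <- make_fixture("diatomic")
  mono_t <- build_tree(fx$system, list(nodes = list(
    list(id = "root", layer = 1, atoms = "1-2", calculator = "ff"))))
  o_mono <- oniom_optimize(mono_t, list(ff = calc), gtol = 1e-7,
                           maxit = 2000)
  dimer0 <- atomic_system(rep("C", 4),
                          make_fixture("chain", 2)$system$coords[1:4, ],
                          name = "dimer")
  dim_t <- build_tree(dimer0, list(nodes = list(
    list(id = "root", layer = 1, atoms = "1-4", calculator = "ff"))))
  o_dim <- oniom_optimize(dim_t, list(ff = calc), gtol = 1e-7,
                          maxit = 3000)
  sp_m <- reaction_species(o_mono$tree, list(ff = calc), coef = 2)
  sp_d <- reaction_species(o_dim$tree, list(ff = calc))
  d <- reaction_delta(list(sp_m), list(sp_d), T = 298.15)
  # independent recomputation of dE outside the reaction API
  dE_direct <- calc_evaluate(calc, o_dim$system, "energy")$energy -
    2 * calc_evaluate(calc, o_mono$system, "energy")$energy
  expect_equal(d$dE_kcal, hartree_to_kcal(dE_direct), tolerance = 1e-10)
  # association loses translational entropy: dG grows with T
  scan <- temperature_scan(list(sp_m), list(sp_d), seq(200, 400, 50))
  expect_equal(nrow(scan), 5)
  expect_true(all(diff(scan$dG_kcal) > 0))
  # single-point grid agrees with reaction_delta
  expect_equal(temperature_scan(list(sp_m), list(sp_d), 298.15)$dG_kcal,
               d$dG_kcal)
  expect_error(temperature_scan(list(sp_m), list(sp_d), numeric(0)),
               "empty")
})

test_that("entropy-neutral reactions have temperature-flat dG", {
  sysA <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                        name = "A")
  sysB <- atomic_system(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                        name = "B")
  freqs <- c(80, 400, 1200)
  spA <- reaction_species(sysA, energy = -1.0, frequencies = freqs)
  spB <- reaction_species(sysB, energy = -1.1, frequencies = freqs)
  scan <- temperature_scan(list(spA), list(spB), seq(200, 400, 25))
  expect_lt(max(scan$dG_kcal) - min(scan$dG_kcal), 1e-6)
  expect_equal(scan$dG_kcal[1], hartree_to_kcal(-0.1), tolerance = 1e-6)
})
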