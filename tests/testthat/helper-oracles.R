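# Independent oracles used across the suite. These deliberately avoid the
# package's block-sparse / recursive code paths: projections go through
# dense matrices, Jacobians through finite differences of the capped-
# fragment map, and composite assembly through an explicit signed sum.

flatten <- function(coords) as.numeric(t(coords))
unflatten <- function(x) matrix(x, ncol = 3, byrow = TRUE)

# dense-matrix projection oracle
dense_project_gradient <- function(J, g_model) {
  as.numeric(t(jacobian_matrix(J)) %*% g_model)
}
dense_project_hessian <- function(J, H_model) {
  M <- jacobian_matrix(J)
  t(M) %*% H_model %*% M
}

# finite-difference Jacobian of the real -> capped-fragment coordinate map
fd_jacobian <- function(node, system, step = 1e-5) {
  n <- n_atoms(system)
  model0 <- build_fragment_geometry(node, system)
  m <- n_atoms(model0)
  Jfd <- matrix(0, 3 * m, 3 * n)
  x0 <- flatten(system$coords)
  for (i in seq_len(3 * n)) {
    for (sgn in c(1, -1)) {
      x <- x0
      x[i] <- x[i] + sgn * step
      sys2 <- system
      sys2$coords <- unflatten(x)
      mod <- build_fragment_geometry(node, sys2)
      Jfd[, i] <- Jfd[, i] + sgn * flatten(mod$coords) / (2 * step)
    }
  }
  Jfd
}

# explicit signed-sum expansion of the subtractive scheme: the composite
# equals sum over nodes of high(model) minus, for non-root nodes,
# low(model) at the parent's high level -- each projected densely.
brute_force_composite <- function(tree, calculators, wanted = "energy") {
  e <- 0
  n3 <- 3 * n_atoms(tree$system)
  g <- numeric(n3)
  H <- matrix(0, n3, n3)
  for (id in names(tree$nodes)) {
    nd <- tree$nodes[[id]]
    terms <- list(list(level = nd$high_level, sign = 1))
    if (!is.na(nd$parent)) {
      terms <- c(terms, list(list(
        level = tree$nodes[[nd$parent]]$high_level, sign = -1)))
    }
    for (tm in terms) {
      res <- calc_evaluate(calculators[[tm$level]], nd$model, wanted)
      e <- e + tm$sign * res$energy
      if ("gradient" %in% wanted) {
        g <- g + tm$sign * dense_project_gradient(nd$jacobian, res$gradient)
      }
      if ("hessian" %in% wanted) {
        H <- H + tm$sign * dense_project_hessian(nd$jacobian, res$hessian)
      }
    }
  }
  out <- list(energy = e)
  if ("gradient" %in% wanted) out$gradient <- g
  if ("hessian" %in% wanted) out$hessian <- (H + t(H)) / 2
  out
}

# central-difference gradient of any scalar function of flat coordinates
fd_gradient <- function(efun, x0, step = 1e-4) {
  vapply(seq_along(x0), function(i) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    (efun(xp) - efun(xm)) / (2 * step)
  }, numeric(1))
}

# central-difference Hessian from any gradient function
fd_hessian <- function(gfun, x0, step = 1e-4) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    H[, i] <- (gfun(xp) - gfun(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

# random 2- or 3-layer partition over a linear chain of n atoms:
# disjoint contiguous layer-2 windows, each optionally holding a
# layer-3 core
random_chain_partition <- function(n, n_centers = 2, three_layer = TRUE) {
  cuts <- sort(sample(seq(2, n - 1), 2 * n_centers))
  nodes <- list(list(id = "root", layer = 1,
                     atoms = sprintf("1-%d", n), calculator = "ff"))
  for (c0 in seq_len(n_centers)) {
    a <- cuts[2 * c0 - 1]; b <- cuts[2 * c0]
    nodes[[length(nodes) + 1]] <- list(
      id = sprintf("mid%d", c0), layer = 2,
      atoms = sprintf("%d-%d", a, b), calculator = "sqm")
    if (three_layer && b - a >= 2) {
      nodes[[length(nodes) + 1]] <- list(
        id = sprintf("core%d", c0), layer = 3,
        atoms = sprintf("%d-%d", a + 1, b - 1), calculator = "dft")
    }
  }
  list(nodes = nodes)
}

# three distinguishable smooth calculators sharing one functional form
toy_levels <- function() {
  base <- dissociative_ff(name = "ff")
  list(ff = base,
       sqm = shifted_calculator(base, 1.15, -0.02, name = "sqm"),
       dft = shifted_calculator(base, 1.32, -0.05, name = "dft"))
}

# rigid rotation matrix from an axis-angle triple
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# simple ethane-like geometry: two tetrahedral CH3 groups on a C-C bond
make_ethane <- function() {
  rcc <- 2 * covalent_radius("C")
  rch <- covalent_radius("C") + covalent_radius("H")
  c1 <- c(0, 0, 0); c2 <- c(0, 0, rcc)
  h <- function(center, phi, updown) {
    th <- acos(-1 / 3)
    center + rch * c(sin(th) * cos(phi), sin(th) * sin(phi),
                     updown * cos(th))
  }
  coords <- rbind(c1, c2,
                  h(c1, 0, 1), h(c1, 2 * pi / 3, 1), h(c1, 4 * pi / 3, 1),
                  h(c2, pi / 3, -1), h(c2, pi, -1), h(c2, 5 * pi / 3, -1))
  atomic_system(c("C", "C", rep("H", 6)), coords, name = "ethane")
}
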