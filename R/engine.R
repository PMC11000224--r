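#' Project a fragment gradient into the real-system basis
#'
#' Applies the transpose of the node's real-to-model Jacobian blockwise:
#' a retained fragment atom's force lands on its real atom unchanged,
#' while the force on a hydrogen cap over cut bond (a, b) with factor k
#' is split as `(1-k)` onto the host a and `k` onto the partner b —
#' exactly the chain rule for the static cap position.
#'
#' @param J An `oniom_jacobian`.
#' @param g_model Fragment gradient, length `3 * m_model` (atom-major).
#' @return Real-system gradient, length `3 * n_real`.
#' @export
project_gradient <- function(J, g_model) {
  if (length(g_model) != 3L * J$m_model) {
    stop("gradient length ", length(g_model), " != 3 * ", J$m_model,
         call. = FALSE)
  }
  g_real <- numeric(3L * J$n_real)
  en <- J$entries
  for (t in seq_len(nrow(en))) {
    mi <- 3L * (en$model[t] - 1L) + 1:3
    ri <- 3L * (en$real[t] - 1L) + 1:3
    g_real[ri] <- g_real[ri] + en$coeff[t] * g_model[mi]
  }
  g_real
}

#' Project a fragment Hessian into the real-system basis
#'
#' Computes `J^T H J` over the block-sparse structure; the result is
#' symmetric whenever the input is.
#'
#' @param J An `oniom_jacobian`.
#' @param H_model Fragment Hessian, `3m x 3m`, symmetric.
#' @return Real-system Hessian, `3n x 3n`.
#' @export
project_hessian <- function(J, H_model) {
  m3 <- 3L * J$m_model
  if (!all(dim(H_model) == c(m3, m3))) {
    stop("hessian dimension mismatch: expected ", m3, " x ", m3,
         call. = FALSE)
  }
  en <- J$entries
  nent <- nrow(en)
  H_real <- matrix(0, 3L * J$n_real, 3L * J$n_real)
  for (s in seq_len(nent)) {
    ms <- 3L * (en$model[s] - 1L) + 1:3
    rs <- 3L * (en$real[s] - 1L) + 1:3
    cs <- en$coeff[s]
    for (t in seq_len(nent)) {
      mt <- 3L * (en$model[t] - 1L) + 1:3
      rt <- 3L * (en$real[t] - 1L) + 1:3
      H_real[rs, rt] <- H_real[rs, rt] +
        cs * en$coeff[t] * H_model[ms, mt]
    }
  }
  H_real
}

eval_projected <- function(tree, node, level_name, calculators, wanted,
                           cache, verbose = FALSE) {
  key <- paste(node$id, level_name, sep = "\r")
  hit <- cache[[key]]
  if (!is.null(hit) && all(wanted %in% hit$has)) return(hit)
  calc <- calculators[[level_name]]
  if (is.null(calc)) {
    stop("no calculator bound to level '", level_name, "' (node '",
         node$id, "')", call. = FALSE)
  }
  res <- tryCatch(
    calc_evaluate(calc, node$model, wanted, node$charge, node$uhf),
    error = function(e) {
      stop("calculator '", level_name, "' failed on node '", node$id,
           "': ", conditionMessage(e), call. = FALSE)
    })
  if (verbose) {
    message(sprintf("  eval node=%s level=%s E=%+.10f Ha",
                    node$id, level_name, res$energy))
  }
  out <- list(energy = res$energy, has = wanted)
  if ("gradient" %in% wanted) {
    out$gradient <- project_gradient(node$jacobian, res$gradient)
  }
  if ("hessian" %in% wanted) {
    out$hessian <- project_hessian(node$jacobian, res$hessian)
  }
  cache[[key]] <- out
  out
}

node_property_rec <- function(tree, node_id, calculators, wanted, cache,
                              breakdown, verbose) {
  node <- tree$nodes[[node_id]]
  high <- eval_projected(tree, node, node$high_level, calculators, wanted,
                         cache, verbose)
  acc <- high
  breakdown[[node_id]] <- list(high = high$energy, low_correction = 0)
  for (ch_id in node$children) {
    ch <- tree$nodes[[ch_id]]
    rec <- node_property_rec(tree, ch_id, calculators, wanted, cache,
                             breakdown, verbose)
    breakdown <- rec$breakdown
    low <- eval_projected(tree, ch, node$high_level, calculators, wanted,
                          cache, verbose)
    breakdown[[ch_id]]$low_correction <- -low$energy
    acc$energy <- acc$energy + rec$value$energy - low$energy
    if ("gradient" %in% wanted) {
      acc$gradient <- acc$gradient + rec$value$gradient - low$gradient
    }
    if ("hessian" %in% wanted) {
      acc$hessian <- acc$hessian + rec$value$hessian - low$hessian
    }
  }
  list(value = acc, breakdown = breakdown)
}

#' Recursive property of one ONIOM node
#'
#' Implements the subtractive recursion over the dependency tree: a
#' node's property is its own model evaluated at the node's high level,
#' plus, for each child, the child's recursively assembled property minus
#' the child's model evaluated at this node's (= the child's low) level.
#' Leaf nodes return their high-level model result alone, which
#' terminates the recursion. Every fragment result is projected into the
#' real-system basis through that fragment's Jacobian before it is
#' accumulated. For a two-layer tree with one child this reduces to the
#' classic `E = E_low(real) + E_high(model) - E_low(model)`.
#'
#' @param tree An `oniom_tree`.
#' @param node_id Node to assemble (defaults to the root).
#' @param calculators Named list binding level names to calculators.
#' @param wanted Properties, subset of
#'   `c("energy", "gradient", "hessian")`.
#' @param verbose Log each fragment evaluation via `message()`.
#' @return An `oniom_result` (see [oniom_composite()]).
#' @export
node_property <- function(tree, node_id = tree$root_id, calculators,
                          wanted = "energy", verbose = FALSE) {
  stopifnot(inherits(tree, "oniom_tree"))
  wanted <- union("energy", wanted)
  cache <- new.env(parent = emptyenv())
  rec <- node_property_rec(tree, node_id, calculators, wanted, cache,
                           list(), verbose)
  out <- rec$value
  if (!is.null(out$hessian)) {
    out$hessian <- (out$hessian + t(out$hessian)) / 2
  }
  structure(
    list(energy = out$energy, gradient = out$gradient,
         hessian = out$hessian, per_node_breakdown = rec$breakdown),
    class = "oniom_result"
  )
}

#' Composite ONIOM energy / gradient / Hessian
#'
#' Assembles the full multicenter composite property for the tree's root
#' (the real system): the signed sum, over all nodes, of high-level model
#' evaluations and low-level child corrections, with every fragment
#' derivative pulled back into the real-system basis through its
#' Jacobian. When the same calculator is bound to every level the scheme
#' telescopes exactly to the plain real-system result. Duplicate
#' (fragment, calculator) evaluations within one call are cached; the
#' per-node breakdown records each node's high contribution and low
#' correction, and their sum reproduces the composite energy.
#'
#' @inheritParams node_property
#' @return An `oniom_result`: `energy` (Hartree), optional `gradient`
#'   (length `3n`, Hartree/Angstrom), optional symmetric `hessian`
#'   (`3n x 3n`), and `per_node_breakdown`.
#' @examples
#' fx <- make_fixture("bridge_dimer")
#' tree <- build_tree(fx$system, fx$partition)
#' res <- oniom_composite(tree, fx$calculators, wanted = "gradient")
#' res$energy
#' @export
oniom_composite <- function(tree, calculators, wanted = "energy",
                            verbose = FALSE) {
  missing_lv <- setdiff(
    unique(vapply(tree$nodes, `[[`, character(1), "high_level")),
    names(calculators))
  if (length(missing_lv) > 0) {
    stop("no calculator bound to level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  node_property(tree, tree$root_id, calculators, wanted, verbose)
}

#' @export
print.oniom_result <- function(x, ...) {
  cat(sprintf("<oniom_result> E = %.10f Ha (%.6f kcal/mol)\n",
              x$energy, hartree_to_kcal(x$energy)))
  if (!is.null(x$gradient)) {
    cat(sprintf("  |g|max = %.3e Ha/A\n", max(abs(x$gradient))))
  }
  if (!is.null(x$hessian)) {
    cat(sprintf("  hessian: %d x %d\n", nrow(x$hessian), ncol(x$hessian)))
  }
  for (id in names(x$per_node_breakdown)) {
    b <- x$per_node_breakdown[[id]]
    cat(sprintf("  node %-12s high %+14.8f  low-corr %+14.8f\n",
                id, b$high, b$low_correction))
  }
  invisible(x)
}

#' Serialize a composite result to JSON
#'
#' @param result An `oniom_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
result_to_json <- function(result, path = NULL) {
  obj <- list(
    energy_hartree = result$energy,
    energy_kcal_mol = hartree_to_kcal(result$energy),
    per_node = result$per_node_breakdown
  )
  if (!is.null(result$gradient)) {
    obj$gradient_norm <- sqrt(sum(result$gradient^2))
    obj$gradient_max <- max(abs(result$gradient))
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Minimize the composite energy
#'
#' Quasi-Newton (BFGS) minimization of the composite surface in the
#' real-system coordinates, using the analytic composite gradient.
#' Convergence is declared when the largest gradient component drops
#' below `gtol`; otherwise the last geometry is returned flagged as
#' unconverged.
#'
#' @param tree An `oniom_tree`.
#' @param calculators Named calculator bindings.
#' @param gtol Convergence threshold on `max |g|` (Hartree/Angstrom).
#' @param maxit Total BFGS iteration budget.
#' @return List: `system` (optimized geometry), `tree` (updated),
#'   `result` (final `oniom_result` with gradient), `converged`,
#'   `iterations`.
#' @export
oniom_optimize <- function(tree, calculators, gtol = 1e-4, maxit = 500) {
  x0 <- flat_coords(tree$system)
  fn <- function(x) {
    oniom_composite(tree_set_coords(tree, matrix(x, ncol = 3, byrow = TRUE)),
                    calculators)$energy
  }
  gr <- function(x) {
    oniom_composite(tree_set_coords(tree, matrix(x, ncol = 3, byrow = TRUE)),
                    calculators, wanted = "gradient")$gradient
  }
  iterations <- 0L
  x <- x0
  converged <- max(abs(gr(x))) < gtol
  tries <- 0L
  while (!converged && iterations < maxit && tries < 5L) {
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = maxit - iterations,
                                       reltol = 1e-14))
    x <- opt$par
    iterations <- iterations + opt$counts[["gradient"]]
    converged <- max(abs(gr(x))) < gtol
    tries <- tries + 1L
  }
  tree <- tree_set_coords(tree, matrix(x, ncol = 3, byrow = TRUE))
  res <- oniom_composite(tree, calculators, wanted = "gradient")
  if (!converged) {
    warning("optimization not converged: max|g| = ",
            format(max(abs(res$gradient)), digits = 3), call. = FALSE)
  }
  list(system = tree$system, tree = tree, result = res,
       converged = converged, iterations = iterations)
}
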