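#' Link-atom scale factor from covalent radii
#'
#' For a cut covalent bond a-b with the fragment-side host atom `a` and the
#' severed partner `b`, the hydrogen cap is placed along the bond vector at
#' a fixed fraction of the bond,
#' `k_ab = (R_a + R_H) / (R_a + R_b)`,
#' the ratio of the covalent-radius sums for an a-H bond and the original
#' a-b bond. The factor is static: it carries no dependence on the current
#' bond length, so capping introduces no extra degrees of freedom.
#'
#' @param el_a Element of the host atom (inside the fragment).
#' @param el_b Element of the severed partner (outside the fragment).
#' @param radii Covalent-radius table, element -> Angstrom.
#' @return Dimensionless scale factor `k_ab`.
#' @examples
#' link_scale_factor("C", "C")  # < 1: an H cap sits closer than the C
#' link_scale_factor("C", "H")  # 1: cap coincides with the replaced H
#' @export
link_scale_factor <- function(el_a, el_b, radii = covalent_radii_table()) {
  ra <- covalent_radius(el_a, radii)
  rb <- covalent_radius(el_b, radii)
  rh <- covalent_radius("H", radii)
  (ra + rh) / (ra + rb)
}

#' Place a hydrogen link atom on a cut bond
#'
#' The cap position is the affine point `r_l = r_a + k * (r_b - r_a)`,
#' collinear with the cut bond by construction.
#'
#' @param r_a Position of the host atom (length-3).
#' @param r_b Position of the severed partner (length-3).
#' @param k Dimensionless scale factor (see [link_scale_factor()]).
#' @return Length-3 cap position.
#' @export
place_link_atom <- function(r_a, r_b, k) {
  r_a <- as.numeric(r_a); r_b <- as.numeric(r_b)
  if (sqrt(sum((r_b - r_a)^2)) < 1e-12) {
    stop("coincident host/partner positions for link atom", call. = FALSE)
  }
  r_a + k * (r_b - r_a)
}

#' Infer bond topology from geometry
#'
#' Two atoms are bonded when their distance is below
#' `scale * (R_a + R_b)` with single-bond covalent radii; the conventional
#' tolerance `scale = 1.15` is the default.
#'
#' @param system An `atomic_system`.
#' @param scale Distance tolerance multiplier.
#' @param radii Covalent-radius table.
#' @return 2-column integer matrix of bonded pairs, `i < j`.
#' @export
infer_topology <- function(system, scale = 1.15,
                           radii = covalent_radii_table()) {
  n <- n_atoms(system)
  if (n < 2) return(matrix(integer(0), 0, 2))
  r <- covalent_radius(system$elements, radii)
  d <- as.matrix(stats::dist(system$coords))
  thr <- outer(r, r, "+") * scale
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  unname(cbind(as.integer(hit[, 1]), as.integer(hit[, 2])))
}

#' Bonds cut by a fragment boundary
#'
#' Returns every bonded pair with one end inside the fragment (the host,
#' first column) and the other outside (the partner, second column). Uses
#' the system's stored topology, or infers one from geometry.
#'
#' @param system An `atomic_system`.
#' @param fragment Integer vector of fragment atom indices (1-based).
#' @param topology Optional explicit bond list overriding the system's.
#' @param scale Bond-perception tolerance when topology must be inferred.
#' @return 2-column matrix `(host, partner)`, ordered by host then partner.
#' @export
detect_cut_bonds <- function(system, fragment, topology = NULL,
                             scale = 1.15) {
  if (is.null(topology)) topology <- system$topology
  if (is.null(topology)) topology <- infer_topology(system, scale)
  fragment <- sort(unique(as.integer(fragment)))
  if (nrow(topology) == 0) return(matrix(integer(0), 0, 2))
  in1 <- topology[, 1] %in% fragment
  in2 <- topology[, 2] %in% fragment
  cut <- xor(in1, in2)
  if (!any(cut)) return(matrix(integer(0), 0, 2))
  a <- ifelse(in1[cut], topology[cut, 1], topology[cut, 2])
  b <- ifelse(in1[cut], topology[cut, 2], topology[cut, 1])
  ord <- order(a, b)
  unname(cbind(as.integer(a[ord]), as.integer(b[ord])))
}

#' Build link-atom specs for a fragment
#' @noRd
make_link_specs <- function(system, fragment, topology = NULL,
                            scale = 1.15, overrides = NULL) {
  cuts <- detect_cut_bonds(system, fragment, topology, scale)
  if (nrow(cuts) == 0) return(list())
  hosts <- cuts[, 1]
  if (anyDuplicated(hosts)) {
    warning("atom ", paste(unique(hosts[duplicated(hosts)]), collapse = ","),
            " hosts more than one link atom (geometrically strained)",
            call. = FALSE)
  }
  lapply(seq_len(nrow(cuts)), function(i) {
    a <- cuts[i, 1]; b <- cuts[i, 2]
    k <- NULL
    if (!is.null(overrides)) {
      for (ov in overrides) {
        if ((ov$a == a && ov$b == b) || (ov$a == b && ov$b == a)) k <- ov$k
      }
    }
    if (is.null(k)) {
      k <- link_scale_factor(system$elements[a], system$elements[b])
    }
    if (k <= 0) stop("link scale factor must be positive", call. = FALSE)
    list(host = a, partner = b, k = k, cap = "H")
  })
}

#' Capped model geometry of an ONIOM node
#'
#' Fragment atoms appear first in ascending real-system index order, then
#' one hydrogen cap per cut bond, in the order of the node's link list.
#' This ordering is frozen: the node's Jacobian indexes into it.
#'
#' @param node A node of an [build_tree()] tree (or any list with `atoms`
#'   and `links` fields).
#' @param system The real `atomic_system`.
#' @return An `atomic_system` for the capped fragment.
#' @export
build_fragment_geometry <- function(node, system) {
  idx <- sort(unique(as.integer(node$atoms)))
  els <- system$elements[idx]
  xyz <- system$coords[idx, , drop = FALSE]
  for (lk in node$links) {
    pos <- place_link_atom(system$coords[lk$host, ],
                           system$coords[lk$partner, ], lk$k)
    els <- c(els, lk$cap)
    xyz <- rbind(xyz, pos)
  }
  atomic_system(els, xyz,
                name = paste0(system$name, ":", node$id %||% "fragment"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jacobian of the real-to-model coordinate map
#'
#' The capped-fragment coordinates are a linear function of the
#' real-system coordinates, so the map has a constant, block-sparse
#' Jacobian built from 3x3 scalar blocks: a retained fragment atom mapped
#' from real atom p carries a single identity block at p; a hydrogen cap
#' on cut bond (a, b) with factor k carries `(1-k) I` at a and `k I` at b.
#' Every model atom's blocks sum to the identity, which is what makes
#' rigid translations of the real system translate each fragment rigidly.
#'
#' The transpose of this map pulls fragment gradients and Hessians back
#' into the real-system basis (see [project_gradient()],
#' [project_hessian()]).
#'
#' @param node Tree node with `atoms` and `links` fields.
#' @param system The real `atomic_system`.
#' @return An `oniom_jacobian`: fields `node_id`, `n_real`, `m_model` and
#'   `entries` (data frame `model`, `real`, `coeff`, one row per 3x3
#'   scalar block).
#' @export
build_jacobian <- function(node, system) {
  idx <- sort(unique(as.integer(node$atoms)))
  m_frag <- length(idx)
  n_links <- length(node$links)
  model <- c(seq_len(m_frag), rep(m_frag + seq_len(n_links), each = 2))
  real <- idx
  coeff <- rep(1, m_frag)
  for (lk in node$links) {
    real <- c(real, lk$host, lk$partner)
    coeff <- c(coeff, 1 - lk$k, lk$k)
  }
  structure(
    list(node_id = node$id %||% NA_character_,
         n_real = n_atoms(system),
         m_model = m_frag + n_links,
         entries = data.frame(model = as.integer(model),
                              real = as.integer(real),
                              coeff = as.numeric(coeff))),
    class = "oniom_jacobian"
  )
}

#' Dense matrix form of a Jacobian
#'
#' Expands the block-sparse Jacobian into a plain `3m x 3n` matrix,
#' mainly for inspection and cross-checks; the projection routines work
#' blockwise and never form this.
#'
#' @param J An `oniom_jacobian`.
#' @return Numeric `3*m_model x 3*n_real` matrix.
#' @export
jacobian_matrix <- function(J) {
  M <- matrix(0, 3 * J$m_model, 3 * J$n_real)
  for (i in seq_len(nrow(J$entries))) {
    mi <- J$entries$model[i]; ri <- J$entries$real[i]
    c0 <- J$entries$coeff[i]
    rows <- 3 * (mi - 1) + 1:3
    cols <- 3 * (ri - 1) + 1:3
    M[cbind(rows, cols)] <- M[cbind(rows, cols)] + c0
  }
  M
}

parse_atom_spec <- function(spec) {
  if (is.numeric(spec)) return(sort(unique(as.integer(spec))))
  out <- integer(0)
  for (part in unlist(strsplit(as.character(spec), "[,[:space:]]+"))) {
    if (!nzchar(part)) next
    if (grepl("^[0-9]+-[0-9]+$", part)) {
      ab <- as.integer(strsplit(part, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", part)) {
      out <- c(out, as.integer(part))
    } else {
      stop("cannot parse atom selection '", part, "'", call. = FALSE)
    }
  }
  sort(unique(out))
}

#' Build and validate a multicenter ONIOM dependency tree
#'
#' The partition config lists one entry per node: its `layer` (1 = the
#' root layer holding every atom), its `atoms` (1-based indices, ranges
#' like `"5-14"`, or arrays), and the `calculator` name applied to its
#' capped model at the node's own (high) level. Parents are inferred by
#' containment: each layer-L node's parent is the layer L-1 node whose
#' atom set contains it. Each node's low level is its parent's
#' calculator, which is what makes the subtractive scheme telescope.
#' Cut bonds are detected against the full-system topology (stored,
#' supplied, or perceived from geometry) and capped with hydrogens; each
#' node's capped model geometry and Jacobian are prepared here.
#'
#' @param system The real `atomic_system`.
#' @param config A list (typically from [read_partition_config()]) with a
#'   `nodes` list and optional `links` overrides (`a`, `b`, `k`) and
#'   `bond_scale`.
#' @param calculators Optional named list of calculators; when given,
#'   every referenced calculator name must be present.
#' @return An `oniom_tree`: `nodes` (named list), `root_id`, `system`,
#'   `topology`.
#' @seealso [validate_tree()], [oniom_composite()]
#' @export
build_tree <- function(system, config, calculators = NULL) {
  stopifnot(inherits(system, "atomic_system"))
  if (is.null(config$nodes) || length(config$nodes) == 0) {
    stop("partition config has no nodes", call. = FALSE)
  }
  n <- n_atoms(system)
  scale <- config$bond_scale %||% 1.15
  topology <- system$topology %||% infer_topology(system, scale)
  overrides <- config$links

  nodes <- list()
  for (i in seq_along(config$nodes)) {
    nd <- config$nodes[[i]]
    id <- nd$id %||% sprintf("node%d", i)
    if (id %in% names(nodes)) stop("duplicate node id '", id, "'",
                                   call. = FALSE)
    atoms <- parse_atom_spec(nd$atoms)
    if (length(atoms) == 0) stop("node '", id, "' selects no atoms",
                                 call. = FALSE)
    if (any(atoms < 1L | atoms > n)) {
      stop("node '", id, "': atom index out of range 1..", n, call. = FALSE)
    }
    if (is.null(nd$calculator)) {
      stop("node '", id, "' has no calculator", call. = FALSE)
    }
    if (!is.null(calculators) && !(nd$calculator %in% names(calculators))) {
      stop("node '", id, "': unknown calculator '", nd$calculator, "'",
           call. = FALSE)
    }
    nodes[[id]] <- list(
      id = id, layer = as.integer(nd$layer), atoms = atoms,
      parent = NA_character_, children = character(0),
      high_level = nd$calculator, low_level = NA_character_,
      charge = nd$charge %||% 0L, uhf = nd$uhf %||% 0L,
      links = list()
    )
  }

  layers <- vapply(nodes, `[[`, integer(1), "layer")
  roots <- names(nodes)[layers == 1L]
  if (length(roots) != 1L) {
    stop("exactly one layer-1 root node required, found ", length(roots),
         call. = FALSE)
  }
  root_id <- roots
  if (!setequal(nodes[[root_id]]$atoms, seq_len(n))) {
    stop("root node '", root_id, "' must contain all ", n, " atoms",
         call. = FALSE)
  }

  # parent inference by containment in the previous layer
  for (id in names(nodes)) {
    nd <- nodes[[id]]
    if (id == root_id) next
    cand <- names(nodes)[layers == nd$layer - 1L]
    parent <- cand[vapply(cand, function(p)
      all(nd$atoms %in% nodes[[p]]$atoms), logical(1))]
    if (length(parent) == 0) {
      stop("node '", id, "' (layer ", nd$layer,
           ") is not contained in any layer-", nd$layer - 1L, " node",
           call. = FALSE)
    }
    parent <- parent[1]
    if (length(nd$atoms) >= length(nodes[[parent]]$atoms)) {
      stop("node '", id, "' is not a strict subset of its parent '",
           parent, "'", call. = FALSE)
    }
    nodes[[id]]$parent <- parent
    nodes[[id]]$low_level <- nodes[[parent]]$high_level
    nodes[[parent]]$children <- c(nodes[[parent]]$children, id)
  }

  # sibling disjointness
  for (id in names(nodes)) {
    ch <- nodes[[id]]$children
    if (length(ch) < 2) next
    for (i in seq_len(length(ch) - 1)) {
      for (j in seq(i + 1, length(ch))) {
        ov <- intersect(nodes[[ch[i]]]$atoms, nodes[[ch[j]]]$atoms)
        if (length(ov) > 0) {
          stop("sibling nodes '", ch[i], "' and '", ch[j],
               "' share atom(s) ", paste(utils::head(ov, 5), collapse = ","),
               call. = FALSE)
        }
      }
    }
  }

  # link atoms, capped models, Jacobians
  for (id in names(nodes)) {
    nodes[[id]]$links <- make_link_specs(system, nodes[[id]]$atoms,
                                         topology, scale, overrides)
    nodes[[id]]$model <- build_fragment_geometry(nodes[[id]], system)
    nodes[[id]]$jacobian <- build_jacobian(nodes[[id]], system)
  }

  tree <- structure(
    list(nodes = nodes, root_id = root_id, system = system,
         topology = topology, bond_scale = scale),
    class = "oniom_tree"
  )
  diag <- validate_tree(tree)
  if (length(diag) > 0) {
    stop("invalid ONIOM tree:\n  ", paste(diag, collapse = "\n  "),
         call. = FALSE)
  }
  tree
}

#' @export
print.oniom_tree <- function(x, ...) {
  layers <- vapply(x$nodes, `[[`, integer(1), "layer")
  cat(sprintf("<oniom_tree> %d atoms, %d nodes, %d layers\n",
              n_atoms(x$system), length(x$nodes), max(layers)))
  for (id in names(x$nodes)) {
    nd <- x$nodes[[id]]
    cat(sprintf("  [L%d] %s: %d atoms, %d caps, high=%s low=%s\n",
                nd$layer, id, length(nd$atoms), length(nd$links),
                nd$high_level, if (is.na(nd$low_level)) "-" else nd$low_level))
  }
  invisible(x)
}

#' Validate an ONIOM tree
#'
#' Pure reporting: returns a character vector of violated structural
#' invariants (empty means valid) and never mutates its input. Checked:
#' single all-atom root at layer 1, acyclicity and reachability, strict
#' child-subset containment, sibling disjointness, layer monotonicity,
#' low level equal to the parent's high level, and link-atom sanity.
#'
#' @param tree An `oniom_tree` (possibly hand-built, possibly broken).
#' @return Character vector of diagnostics; `character(0)` if valid.
#' @export
validate_tree <- function(tree) {
  out <- character(0)
  nodes <- tree$nodes
  n <- n_atoms(tree$system)
  root <- tree$root_id
  if (!(root %in% names(nodes))) {
    return("root_id does not name a node")
  }
  if (nodes[[root]]$layer != 1L) {
    out <- c(out, sprintf("root '%s' not at layer 1", root))
  }
  if (!setequal(nodes[[root]]$atoms, seq_len(n))) {
    out <- c(out, sprintf("root '%s' does not contain all atoms", root))
  }
  if (!is.na(nodes[[root]]$parent)) {
    out <- c(out, sprintf("root '%s' has a parent", root))
  }
  # reachability + acyclicity by walking parent links
  for (id in names(nodes)) {
    if (id == root) next
    seen <- character(0)
    cur <- id
    repeat {
      if (cur %in% seen) {
        out <- c(out, sprintf("acyclicity violated at node '%s'", id))
        break
      }
      seen <- c(seen, cur)
      if (cur == root) break
      cur <- if (cur %in% names(nodes)) nodes[[cur]]$parent else NA_character_
      if (is.na(cur)) {
        out <- c(out, sprintf("node '%s' not reachable from root", id))
        break
      }
    }
  }
  for (id in names(nodes)) {
    nd <- nodes[[id]]
    if (id == root) next
    p <- nd$parent
    if (is.na(p) || !(p %in% names(nodes))) next
    pn <- nodes[[p]]
    if (nd$layer != pn$layer + 1L) {
      out <- c(out, sprintf(
        "layer monotonicity violated: '%s' (L%d) child of '%s' (L%d)",
        id, nd$layer, p, pn$layer))
    }
    if (!all(nd$atoms %in% pn$atoms) || length(nd$atoms) >= length(pn$atoms)) {
      out <- c(out, sprintf("node '%s' is not a strict subset of '%s'",
                            id, p))
    }
    if (!identical(nd$low_level, pn$high_level)) {
      out <- c(out, sprintf(
        "node '%s' low level (%s) != parent '%s' high level (%s)",
        id, nd$low_level, p, pn$high_level))
    }
    for (lk in nd$links) {
      if (!(lk$host %in% nd$atoms) || (lk$partner %in% nd$atoms)) {
        out <- c(out, sprintf(
          "node '%s': link atom host/partner on wrong side of boundary", id))
      }
    }
  }
  for (id in names(nodes)) {
    ch <- nodes[[id]]$children
    if (length(ch) < 2) next
    for (i in seq_len(length(ch) - 1)) {
      for (j in seq(i + 1, length(ch))) {
        if (length(intersect(nodes[[ch[i]]]$atoms,
                             nodes[[ch[j]]]$atoms)) > 0) {
          out <- c(out, sprintf("siblings '%s' and '%s' overlap",
                                ch[i], ch[j]))
        }
      }
    }
  }
  out
}

#' Read a partition config file
#'
#' JSON is the primary format; YAML is accepted when the `yaml` package is
#' available. The schema is a `nodes` array (each with `layer`, `atoms`,
#' `calculator`, optional `id`, `charge`, `uhf`), optional `links`
#' overrides (`a`, `b`, `k`, 1-based indices) and optional `bond_scale`.
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` config.
#' @return A config list suitable for [build_tree()].
#' @export
read_partition_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(cfg$nodes)) {
    stop("partition config '", path, "' has no 'nodes' array", call. = FALSE)
  }
  cfg
}

#' Replace the real-system coordinates of a tree
#'
#' Recomputes every node's capped model geometry for new real-system
#' coordinates. The topology, link list and Jacobians are static (the
#' capping factors do not depend on geometry), so only cap positions move.
#'
#' @param tree An `oniom_tree`.
#' @param coords New N x 3 coordinate matrix (Angstrom).
#' @return The updated tree.
#' @export
tree_set_coords <- function(tree, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n_atoms(tree$system), ncol(coords) == 3)
  tree$system$coords <- unname(coords)
  for (id in names(tree$nodes)) {
    tree$nodes[[id]]$model <-
      build_fragment_geometry(tree$nodes[[id]], tree$system)
  }
  tree
}
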