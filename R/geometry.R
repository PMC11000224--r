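#' Construct an atomic system
#'
#' The central molecular container: element symbols, Cartesian coordinates
#' in Angstrom, per-atom masses in amu, and an optional bond topology.
#' This is the "real system" that ONIOM fragments and link-atom Jacobians
#' are defined against.
#'
#' @param elements Character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param masses Optional numeric vector of atomic masses (amu); filled
#'   from the element table when `NULL`.
#' @param topology Optional 2-column integer matrix of bonded atom-index
#'   pairs (1-based).
#' @param name Free-text label carried into file comments.
#' @return An object of class `atomic_system`.
#' @examples
#' atomic_system("He", matrix(0, 1, 3))
#' @export
atomic_system <- function(elements, coords, masses = NULL, topology = NULL,
                          name = "") {
  elements <- normalize_element(elements)
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an N x 3 matrix", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (n < 1L || nrow(coords) != n) {
    stop("need >= 1 atom and one coordinate row per element", call. = FALSE)
  }
  if (is.null(masses)) masses <- atomic_mass(elements)
  if (length(masses) != n) stop("masses length mismatch", call. = FALSE)
  # every element must resolve in both reference tables
  covalent_radius(elements)
  if (!is.null(topology)) {
    topology <- as.matrix(topology)
    if (ncol(topology) != 2) stop("topology must have 2 columns", call. = FALSE)
    storage.mode(topology) <- "integer"
    bad <- topology[, 1] == topology[, 2] |
      topology < 1L | topology > n
    if (any(bad)) {
      stop("topology pairs must reference distinct atoms in 1..", n,
           call. = FALSE)
    }
  }
  structure(
    list(elements = elements, coords = unname(coords),
         masses = as.numeric(masses), topology = topology,
         name = as.character(name)),
    class = "atomic_system"
  )
}

#' Number of atoms in a system
#' @param system An `atomic_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) length(system$elements)

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("<atomic_system> %s: %d atoms (%s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ",")))
  invisible(x)
}

#' Extract a sub-system by atom indices
#' @noRd
subset_system <- function(system, idx, name = system$name) {
  atomic_system(system$elements[idx], system$coords[idx, , drop = FALSE],
                masses = system$masses[idx], name = name)
}

#' Read an XYZ file
#'
#' Standard XYZ dialect: atom count line, comment line, then
#' `element x y z` rows. Coordinates are taken as Angstrom.
#'
#' @param path Path to an XYZ file.
#' @return An `atomic_system`; the comment line becomes its `name`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ parse error at line 1: truncated file",
                              call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("XYZ parse error at line 1: malformed atom count '",
         trimws(lines[1]), "'", call. = FALSE)
  }
  if (length(lines) < n + 2) {
    stop("XYZ parse error: expected ", n + 2, " lines, found ",
         length(lines), call. = FALSE)
  }
  els <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error at line ", ln, ": need 'element x y z'",
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(val)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate",
           call. = FALSE)
    }
    els[i] <- tok[1]
    xyz[i, ] <- val
  }
  atomic_system(els, xyz, name = trimws(lines[2]))
}

#' Write an XYZ file
#'
#' Coordinates are printed with six decimals; the comment line carries the
#' system name and, when given, an energy annotation.
#'
#' @param system An `atomic_system`.
#' @param path Output file path.
#' @param energy Optional energy (Hartree) recorded on the comment line.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(system, path, energy = NULL) {
  stopifnot(inherits(system, "atomic_system"))
  comment <- system$name
  if (!is.null(energy)) {
    comment <- sprintf("%s energy= %.10f", comment, energy)
  }
  rows <- sprintf("%-3s %13.6f %13.6f %13.6f", system$elements,
                  system$coords[, 1], system$coords[, 2], system$coords[, 3])
  out <- c(as.character(n_atoms(system)), comment, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read coordinates from a PDB file (read-only subset)
#'
#' Parses ATOM/HETATM records only: element (column 77-78, falling back to
#' the atom-name field) and orthogonal coordinates. Everything else in the
#' record is ignored; writing is always XYZ.
#'
#' @param path Path to a PDB file.
#' @return An `atomic_system`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("PDB parse error: non-numeric coordinate field", call. = FALSE)
  }
  el <- trimws(substr(rec, 77, 78))
  fallback <- !nzchar(el)
  if (any(fallback)) {
    # atom-name columns 13-16; strip digits, first letters give the element
    nm <- gsub("[0-9'\" ]", "", substr(rec[fallback], 13, 16))
    el[fallback] <- substr(nm, 1, 1)
  }
  atomic_system(el, cbind(x, y, z), name = basename(path))
}
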