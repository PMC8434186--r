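#' Molecule container
#'
#' A light container for a molecular fragment: chemical elements, Cartesian
#' coordinates in Angstrom, optional atom labels (e.g. PDB atom names) and a
#' bond list. Only C, N, O and H are supported, matching the valence basis
#' of the LCAO model (2s, 2p for C/N/O; 1s for H).
#'
#' @param elements character vector of element symbols (C, N, O, H).
#' @param coords numeric matrix (n x 3) of Cartesian coordinates, Angstrom.
#' @param name molecule label.
#' @param labels optional character vector of per-atom names; defaults to
#'   element + index.
#' @param bonds optional integer matrix (m x 2) of 1-based atom index pairs,
#'   each unordered pair stored once.
#' @param meta optional data.frame of per-atom metadata (e.g. PDB residue
#'   and chain fields), carried along untouched.
#'
#' @return An object of class \code{lcao_molecule}.
#' @examples
#' m <- molecule(c("C", "H", "H"),
#'               rbind(c(0, 0, 0), c(1.09, 0, 0), c(-1.09, 0, 0)))
#' chem_formula(m)
#' @export
molecule <- function(elements, coords, name = "molecule", labels = NULL,
                     bonds = NULL, meta = NULL) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (!is.matrix(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(elements))
    stop("coords must be an n x 3 matrix matching elements")
  bad <- setdiff(unique(elements), SUPPORTED_ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: C, N, O, H)")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (is.null(labels))
    labels <- paste0(elements, seq_along(elements))
  bonds <- normalize_bonds(bonds, length(elements))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(name = name, elements = elements, coords = coords,
                 labels = as.character(labels), bonds = bonds, meta = meta),
            class = "lcao_molecule")
}

normalize_bonds <- function(bonds, n) {
  if (is.null(bonds) || NROW(bonds) == 0L)
    return(matrix(integer(0), ncol = 2L))
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2L) stop("bonds must have two columns")
  if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
  if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bonds are not allowed")
  bonds <- t(apply(bonds, 1L, sort))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
}

#' Number of atoms of a molecule
#' @param mol an \code{lcao_molecule}.
#' @return Integer atom count.
#' @export
natoms <- function(mol) length(mol$elements)

#' Molecular formula in C, H, N, O order
#' @param mol an \code{lcao_molecule}.
#' @return A string such as \code{"C5H5N5"}.
#' @export
chem_formula <- function(mol) {
  counts <- table(factor(mol$elements, levels = c("C", "H", "N", "O")))
  paste0(mapply(function(el, k) {
    if (k == 0) "" else if (k == 1) el else paste0(el, k)
  }, names(counts), as.integer(counts)), collapse = "")
}

#' @export
print.lcao_molecule <- function(x, ...) {
  cat(sprintf("Molecule '%s': %d atoms (%s), %d bonds\n",
              x$name, natoms(x), chem_formula(x), nrow(x$bonds)))
  invisible(x)
}

#' Apply a rigid motion to a molecule
#'
#' Rotates by matrix \code{R} about the origin, then translates by \code{t}.
#'
#' @param mol an \code{lcao_molecule}.
#' @param R 3 x 3 rotation matrix (orthogonal, det +1).
#' @param t length-3 translation vector, Angstrom.
#' @return The transformed molecule (bonds and labels preserved).
#' @export
transform_molecule <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  mol$coords <- sweep(mol$coords %*% t(R), 2L, -as.numeric(t))
  mol
}

#' Rotation matrix about a coordinate axis
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param angle_deg rotation angle, degrees (right-hand rule).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("z", "x", "y"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
         y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
         z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
}

#' Watson--Crick pair container
#'
#' Holds the two bases of a base pair. Orbital and atom index spaces are
#' concatenated (atoms of \code{base2} follow those of \code{base1}), so a
#' pair can be treated as one molecule by \code{\link{pair_as_molecule}}.
#'
#' @param base1,base2 \code{lcao_molecule} fragments.
#' @param name pair label (e.g. \code{"G-C"}).
#' @return An object of class \code{lcao_base_pair}.
#' @export
base_pair <- function(base1, base2, name = paste(base1$name, base2$name,
                                                 sep = "-")) {
  stopifnot(inherits(base1, "lcao_molecule"), inherits(base2, "lcao_molecule"))
  if (natoms(base1) < 1L || natoms(base2) < 1L)
    stop("both bases of a pair must be non-empty")
  structure(list(base1 = base1, base2 = base2, name = name),
            class = "lcao_base_pair")
}

#' @export
print.lcao_base_pair <- function(x, ...) {
  cat(sprintf("Base pair '%s': %s (%d atoms) + %s (%d atoms)\n", x$name,
              x$base1$name, natoms(x$base1), x$base2$name, natoms(x$base2)))
  invisible(x)
}

#' Merge the two bases of a pair into one molecule
#'
#' @param pair an \code{lcao_base_pair}.
#' @return An \code{lcao_molecule} whose atoms are base1 followed by base2;
#'   bond indices of base2 are offset accordingly (no inter-base bonds, the
#'   hydrogen-bond contacts are handled by the pair Hamiltonian).
#' @export
pair_as_molecule <- function(pair) {
  b1 <- pair$base1; b2 <- pair$base2
  n1 <- natoms(b1)
  bonds <- rbind(b1$bonds, b2$bonds + n1)
  molecule(c(b1$elements, b2$elements), rbind(b1$coords, b2$coords),
           name = pair$name, labels = c(b1$labels, b2$labels), bonds = bonds)
}

#' Apply a rigid motion to both bases of a pair
#' @inheritParams transform_molecule
#' @param pair an \code{lcao_base_pair}.
#' @return The transformed pair.
#' @export
transform_pair <- function(pair, R = diag(3), t = c(0, 0, 0)) {
  pair$base1 <- transform_molecule(pair$base1, R, t)
  pair$base2 <- transform_molecule(pair$base2, R, t)
  pair
}

#' Stacked-dimer container
#'
#' Two successive base pairs of a double-stranded stack. The label follows
#' the 5'-3' step naming of the leading strand: in step \code{"XY"},
#' \code{pair1} is X with its complement and \code{pair2} is Y with its
#' complement.
#'
#' @param pair1,pair2 \code{lcao_base_pair} objects.
#' @param label step name such as \code{"GG"}.
#' @return An object of class \code{lcao_dimer}.
#' @export
dimer <- function(pair1, pair2, label = paste0(pair1$name, "/", pair2$name)) {
  stopifnot(inherits(pair1, "lcao_base_pair"),
            inherits(pair2, "lcao_base_pair"))
  structure(list(pair1 = pair1, pair2 = pair2, label = label),
            class = "lcao_dimer")
}

#' @export
print.lcao_dimer <- function(x, ...) {
  cat(sprintf("Stacked dimer '%s': %s over %s\n", x$label, x$pair2$name,
              x$pair1$name))
  invisible(x)
}

#' Stack a second base pair over a first with a given rise and twist
#'
#' Builds an ideal step: \code{pair2} is rotated by \code{twist} degrees
#' about the global z axis (the helix axis, through the origin) and then
#' translated by \code{rise} Angstrom along +z; \code{pair1} is left where
#' it is. With both pairs expressed in the standard base-pair reference
#' frame this produces an ideal B-DNA step (3.4 Angstrom, 36 degrees).
#'
#' @param pair1,pair2 \code{lcao_base_pair} objects in the base-pair
#'   reference frame (helix axis along z through the origin).
#' @param rise helical rise, Angstrom.
#' @param twist helical twist, degrees.
#' @param label step label.
#' @return An \code{lcao_dimer}.
#' @export
build_ideal_dimer <- function(pair1, pair2, rise = 3.4, twist = 36,
                              label = paste0(pair1$name, "/", pair2$name)) {
  R <- rotation_about_axis("z", twist)
  dimer(pair1, transform_pair(pair2, R, c(0, 0, rise)), label = label)
}
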