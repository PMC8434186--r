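#' Read a molecular structure file
#'
#' Dispatches to \code{\link{read_xyz}} or \code{\link{read_pdb}} based on
#' \code{format} (or the file extension when \code{format = "auto"}).
#' Coordinates are taken as Angstrom; bonds are left empty and can be
#' perceived afterwards with \code{\link{detect_bonds}}.
#'
#' @param path path to an existing file.
#' @param format \code{"xyz"}, \code{"pdb"} or \code{"auto"}.
#' @param name molecule label; defaults to the file base name (or the XYZ
#'   comment line when present).
#' @return An \code{lcao_molecule}.
#' @export
load_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  switch(format, xyz = read_xyz(path, name = name),
         pdb = read_pdb(path, name = name))
}

#' Read an XYZ file
#'
#' Standard two-header-line XYZ dialect: atom count, comment line, then one
#' \code{element x y z} record per atom (free whitespace).
#'
#' @param path path to the file.
#' @param name molecule label; defaults to the comment line if non-empty,
#'   else the file base name.
#' @return An \code{lcao_molecule} with empty bond list.
#' @export
read_xyz <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: invalid atom count '",
         trimws(lines[1L]), "'")
  if (length(lines) < n + 2L)
    stop("XYZ parse error at line ", length(lines) + 1L,
         ": expected ", n, " atom records")
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    ln <- k + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", ln, ": need 'element x y z'")
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    el[k] <- tok[1L]; xyz[k, ] <- v
  }
  bad <- setdiff(unique(el), SUPPORTED_ELEMENTS)
  if (length(bad))
    stop("unsupported element(s) in ", basename(path), ": ",
         paste(bad, collapse = ", "))
  if (is.null(name)) {
    cmt <- trimws(lines[2L])
    name <- if (nzchar(cmt)) cmt else
      tools::file_path_sans_ext(basename(path))
  }
  molecule(el, xyz, name = name)
}

#' Write an XYZ file
#'
#' @param mol an \code{lcao_molecule}.
#' @param path output path.
#' @param comment comment (second) line; defaults to the molecule name.
#' @param digits coordinate digits after the decimal point.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(mol, path, comment = mol$name, digits = 8) {
  fmt <- sprintf("%%-2s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  lines <- c(as.character(natoms(mol)), comment,
             sprintf(fmt, mol$elements, mol$coords[, 1L], mol$coords[, 2L],
                     mol$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read ATOM/HETATM records from a PDB file
#'
#' Fixed-column parsing of ATOM and HETATM records: atom name from columns
#' 13-16, residue name 18-20, chain 22, residue number 23-26, coordinates
#' 31-54, element from columns 77-78 with fallback to the first alphabetic
#' character of the atom name. Chain/residue fields are preserved in
#' \code{$meta} so bases can be pruned from oligomer snapshots with
#' \code{\link{select_residues}}.
#'
#' @param path path to the file.
#' @param name molecule label; defaults to the file base name.
#' @return An \code{lcao_molecule} with per-atom metadata.
#' @export
read_pdb <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(sel)) stop("PDB parse error: no ATOM/HETATM records in ", path)
  n <- length(sel)
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  aname <- character(n); resn <- character(n); chain <- character(n)
  resi <- integer(n)
  for (k in seq_len(n)) {
    ln <- sel[k]; s <- lines[ln]
    if (nchar(s) < 54L)
      stop("PDB parse error at line ", ln, ": record shorter than 54 columns")
    x <- suppressWarnings(as.numeric(substr(s, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(s, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(s, 47L, 54L)))
    if (any(is.na(c(x, y, z))))
      stop("PDB parse error at line ", ln, ": non-numeric coordinate field")
    aname[k] <- trimws(substr(s, 13L, 16L))
    resn[k] <- trimws(substr(s, 18L, 20L))
    chain[k] <- substr(s, 22L, 22L)
    resi[k] <- suppressWarnings(as.integer(substr(s, 23L, 26L)))
    e <- trimws(substr(s, 77L, 78L))
    if (!nzchar(e)) {
      ch <- strsplit(aname[k], "")[[1L]]
      e <- ch[grepl("[A-Za-z]", ch)][1L]
    }
    e <- paste0(toupper(substr(e, 1L, 1L)),
                tolower(substr(e, 2L, nchar(e))))
    el[k] <- e
    xyz[k, ] <- c(x, y, z)
  }
  bad <- setdiff(unique(el), SUPPORTED_ELEMENTS)
  if (length(bad))
    stop("unsupported element(s) in ", basename(path), ": ",
         paste(bad, collapse = ", "))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  molecule(el, xyz, name = name, labels = aname,
           meta = data.frame(resname = resn, chain = chain, resid = resi,
                             stringsAsFactors = FALSE))
}

#' Extract residues from a PDB-derived molecule
#'
#' @param mol molecule read by \code{\link{read_pdb}}.
#' @param resid residue numbers to keep.
#' @param chain optional chain identifier filter.
#' @return An \code{lcao_molecule} restricted to the selected atoms.
#' @export
select_residues <- function(mol, resid, chain = NULL) {
  if (is.null(mol$meta)) stop("molecule carries no residue metadata")
  keep <- mol$meta$resid %in% resid
  if (!is.null(chain)) keep <- keep & mol$meta$chain %in% chain
  if (!any(keep)) stop("selection matched no atoms")
  molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE],
           name = mol$name, labels = mol$labels[keep],
           meta = mol$meta[keep, , drop = FALSE])
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' \code{scale * (r_cov(i) + r_cov(j))} with covalent radii H 0.31, C 0.76,
#' N 0.71, O 0.66 Angstrom. The result depends only on the distance matrix,
#' so it is invariant under rigid motions.
#'
#' @param mol an \code{lcao_molecule}.
#' @param scale dimensionless tolerance on the radii sum.
#' @return The molecule with its \code{bonds} field filled.
#' @export
detect_bonds <- function(mol, scale = 1.15) {
  n <- natoms(mol)
  if (n == 1L) { mol$bonds <- normalize_bonds(NULL, 1L); return(mol) }
  d <- as.matrix(stats::dist(mol$coords))
  clash <- d < 0.4 & upper.tri(d)
  if (any(clash)) {
    ij <- which(clash, arr.ind = TRUE)[1L, ]
    stop(sprintf("clashing atoms: %s and %s are %.3f A apart (< 0.4 A)",
                 mol$labels[ij[1L]], mol$labels[ij[2L]],
                 d[ij[1L], ij[2L]]))
  }
  rc <- COVALENT_RADII[mol$elements]
  cutoff <- outer(rc, rc, "+") * scale
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- normalize_bonds(unname(hit), n)
  mol
}
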