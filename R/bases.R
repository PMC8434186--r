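# Heavy-atom geometries of the five nucleobases in the standard base-pair
# reference frame (planar, z = 0; strand-I orientation: +y toward the
# sugar, +x toward the major groove). C1' is the glycosidic carbon of the
# sugar; fixtures replace it by a capping hydrogen on the glycosidic
# nitrogen. The complementary (strand II) base of a Watson-Crick pair is
# the standard geometry of the complement reflected through y -> -y,
# z -> -z, which is what makes the hydrogen-bonding faces meet.
.BASE_HEAVY <- list(
  A = list(
    atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3",
              "C4"),
    elem  = c("C", "N", "C", "N", "C", "C", "N", "N", "C", "N", "C"),
    xy = rbind(c(-2.479, 5.346), c(-1.291, 4.498), c(0.024, 4.897),
               c(0.877, 3.902), c(0.071, 2.771), c(0.369, 1.398),
               c(1.611, 0.909), c(-0.668, 0.532), c(-1.912, 1.023),
               c(-2.320, 2.290), c(-1.267, 3.124)),
    glyco = "N9", ring_h = c("C8", "C2"), nh = character(0),
    amino = c(N6 = "C6"), methyl = character(0)),
  G = list(
    atoms = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
              "N3", "C4"),
    elem  = c("C", "N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C"),
    xy = rbind(c(-2.477, 5.399), c(-1.289, 4.551), c(0.023, 4.962),
               c(0.870, 3.969), c(0.071, 2.833), c(0.424, 1.460),
               c(1.554, 0.955), c(-0.700, 0.641), c(-1.999, 1.087),
               c(-2.949, 0.139), c(-2.342, 2.364), c(-1.265, 3.177)),
    glyco = "N9", ring_h = "C8", nh = "N1",
    amino = c(N2 = "C2"), methyl = character(0)),
  C = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    elem  = c("C", "N", "C", "O", "N", "C", "N", "C", "C"),
    xy = rbind(c(-2.477, 5.402), c(-1.285, 4.542), c(-1.472, 3.158),
               c(-2.628, 2.709), c(-0.391, 2.344), c(0.837, 2.868),
               c(1.875, 2.027), c(1.056, 4.275), c(-0.023, 5.068)),
    glyco = "N1", ring_h = c("C5", "C6"), nh = character(0),
    amino = c(N4 = "C4"), methyl = character(0)),
  T = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    elem  = c("C", "N", "C", "O", "N", "C", "O", "C", "C", "C"),
    xy = rbind(c(-2.481, 5.354), c(-1.284, 4.500), c(-1.462, 3.135),
               c(-2.562, 2.608), c(-0.298, 2.407), c(0.994, 2.897),
               c(1.944, 2.119), c(1.106, 4.338), c(2.466, 4.961),
               c(-0.024, 5.057)),
    glyco = "N1", ring_h = "C6", nh = "N3",
    amino = character(0), methyl = c(C7 = "C5")),
  U = list(
    atoms = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    elem  = c("C", "N", "C", "O", "N", "C", "O", "C", "C"),
    xy = rbind(c(-2.481, 5.354), c(-1.284, 4.500), c(-1.462, 3.131),
               c(-2.563, 2.608), c(-0.302, 2.397), c(0.989, 2.884),
               c(1.935, 2.094), c(1.089, 4.311), c(-0.024, 5.053)),
    glyco = "N1", ring_h = c("C5", "C6"), nh = "N3",
    amino = character(0), methyl = character(0))
)

.BASE_FULL_NAMES <- c(A = "adenine", G = "guanine", C = "cytosine",
                      T = "thymine", U = "uracil")

#' Watson--Crick complement of a one-letter base code
#' @format Named character vector (\code{A, T, G, C}).
#' @export
WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

# bond lengths used when placing hydrogens (Angstrom)
.BL_NH <- 1.01
.BL_CH_AROM <- 1.08
.BL_CH_SP3 <- 1.09

.unit <- function(v) v / sqrt(sum(v^2))

#' Build a nucleobase in the standard base-pair reference frame
#'
#' Returns one of the five nucleobases (adenine, guanine, cytosine,
#' thymine, uracil) as a planar molecule in the standard base-pair
#' reference frame: heavy atoms from the standard planar reference
#' geometry, the sugar replaced by a hydrogen cap on the glycosidic
#' nitrogen, and the remaining hydrogens placed geometrically (N-H 1.01 A
#' and aromatic C-H 1.08 A along external bisectors, planar amino groups
#' with 120-degree H-N-H, tetrahedral methyl for thymine). Bonds are
#' perceived with \code{\link{detect_bonds}}.
#'
#' @param base one of \code{"A","G","C","T","U"} (one-letter codes or full
#'   lower-case names are accepted).
#' @param strand \code{1} for the standard (leading-strand) orientation,
#'   \code{2} for the complementary-strand orientation, i.e. the same base
#'   reflected through (y, z) -> (-y, -z) so that it pairs with a strand-1
#'   partner.
#' @return An \code{lcao_molecule} with labels and bonds; all atoms lie in
#'   z = 0 except thymine's two out-of-plane methyl hydrogens.
#' @examples
#' ade <- nucleobase("A")
#' chem_formula(ade)   # "C5H5N5"
#' @export
nucleobase <- function(base, strand = 1L) {
  key <- toupper(substr(base, 1L, 1L))
  if (nchar(base) > 1L) {
    hit <- names(.BASE_FULL_NAMES)[match(tolower(base), .BASE_FULL_NAMES)]
    if (!is.na(hit)) key <- hit
  }
  if (!key %in% names(.BASE_HEAVY))
    stop("unknown base '", base, "' (use A, G, C, T or U)")
  spec <- .BASE_HEAVY[[key]]
  pos <- cbind(spec$xy, 0)
  rownames(pos) <- spec$atoms

  # heavy-atom connectivity, used to find the ring neighbors of each
  # H-bearing atom
  heavy <- detect_bonds(molecule(spec$elem, pos, labels = spec$atoms))
  nbrs <- function(a) {
    i <- match(a, spec$atoms)
    j <- c(heavy$bonds[heavy$bonds[, 1L] == i, 2L],
           heavy$bonds[heavy$bonds[, 2L] == i, 1L])
    spec$atoms[j]
  }
  ext_bisector_h <- function(a, len) {
    nb <- setdiff(nbrs(a), "C1'")
    if (length(nb) != 2L)
      stop("cannot place H on ", a, ": expected two ring neighbors")
    u <- -.unit(.unit(pos[nb[1L], ] - pos[a, ]) +
                .unit(pos[nb[2L], ] - pos[a, ]))
    pos[a, ] + len * u
  }

  lab <- character(0); hxyz <- NULL
  add <- function(label, p) {
    lab <<- c(lab, label); hxyz <<- rbind(hxyz, unname(p))
  }
  # glycosidic cap: H replaces C1' along the N -> C1' direction
  gN <- spec$glyco
  add(paste0("H", substr(gN, 2L, 3L)),
      pos[gN, ] + .BL_NH * .unit(pos["C1'", ] - pos[gN, ]))
  for (a in spec$ring_h) add(sub("^C", "H", a),
                             ext_bisector_h(a, .BL_CH_AROM))
  for (a in spec$nh) add(sub("^N", "H", a), ext_bisector_h(a, .BL_NH))
  # planar amino group: two H at +/-60 degrees from the C -> N extension
  for (nN in names(spec$amino)) {
    u <- .unit(pos[nN, ] - pos[spec$amino[[nN]], ])
    v <- c(-u[2L], u[1L], 0)
    for (s in c(1, -1))
      add(paste0("H", substr(nN, 2L, 3L), if (s > 0) "1" else "2"),
          pos[nN, ] + .BL_NH * (cos(pi / 3) * u + s * sin(pi / 3) * v))
  }
  # tetrahedral methyl: one in-plane H anti to the ring bond, two mirrored
  # out of the base plane
  for (cM in names(spec$methyl)) {
    a <- .unit(pos[cM, ] - pos[spec$methyl[[cM]], ])
    v <- c(-a[2L], a[1L], 0)
    ct <- cos(70.529 * pi / 180); st <- sin(70.529 * pi / 180)
    dirs <- list(ct * a + st * v,
                 ct * a + st * (cos(2 * pi / 3) * v + sin(2 * pi / 3) *
                                c(0, 0, 1)),
                 ct * a + st * (cos(2 * pi / 3) * v - sin(2 * pi / 3) *
                                c(0, 0, 1)))
    for (k in seq_along(dirs))
      add(paste0("H", substr(cM, 2L, 3L), k),
          pos[cM, ] + .BL_CH_SP3 * .unit(dirs[[k]]))
  }

  keep <- setdiff(seq_along(spec$atoms), match("C1'", spec$atoms))
  mol <- molecule(c(spec$elem[keep], rep("H", length(lab))),
                  rbind(pos[keep, , drop = FALSE], hxyz),
                  name = .BASE_FULL_NAMES[[key]],
                  labels = c(spec$atoms[keep], lab))
  mol <- detect_bonds(mol)
  if (strand != 1L) mol <- transform_molecule(mol, diag(c(1, -1, -1)))
  mol
}

#' Build a Watson--Crick base pair in the standard reference frame
#'
#' The leading-strand base sits in its standard strand-1 orientation and
#' its complement in the strand-2 orientation, which brings the two
#' hydrogen-bonding faces together at standard donor-acceptor distances.
#' The pair mid-frame origin is at (0, 0, 0) with the helix axis along z,
#' ready for \code{\link{build_ideal_dimer}}.
#'
#' @param base leading-strand base, one of \code{"A","T","G","C"}.
#' @return An \code{lcao_base_pair} named e.g. \code{"A-T"}.
#' @examples
#' gc <- wc_pair("G")
#' @export
wc_pair <- function(base) {
  key <- toupper(substr(base, 1L, 1L))
  if (!key %in% names(WC_COMPLEMENT))
    stop("no Watson-Crick pair for base '", base, "'")
  base_pair(nucleobase(key, strand = 1L),
            nucleobase(WC_COMPLEMENT[[key]], strand = 2L),
            name = paste(key, WC_COMPLEMENT[[key]], sep = "-"))
}

#' Build an ideal B-DNA dimer for a dinucleotide step
#'
#' Convenience wrapper: \code{ideal_dimer("GG")} stacks the pair of the
#' second letter over the pair of the first with the given rise and twist
#' (3.4 Angstrom and 36 degrees by default). Step names follow the 5'-3'
#' direction of the leading strand.
#'
#' @param step two-letter step such as \code{"GG"}, \code{"TC"}, \code{"AT"}.
#' @param rise helical rise, Angstrom.
#' @param twist helical twist, degrees.
#' @return An \code{lcao_dimer}.
#' @examples
#' gg <- ideal_dimer("GG")
#' @export
ideal_dimer <- function(step, rise = 3.4, twist = 36) {
  step <- toupper(step)
  if (nchar(step) != 2L)
    stop("step must be two letters, e.g. 'GG'")
  b <- strsplit(step, "")[[1L]]
  build_ideal_dimer(wc_pair(b[1L]), wc_pair(b[2L]), rise = rise,
                    twist = twist, label = step)
}

#' List the packaged heterocycle fixture geometries
#'
#' The package ships XYZ geometries for a set of planar heterocycles
#' (purines, pyrimidines, azoles and fused bicyclics) used by the
#' benchmark module; the five nucleobases are generated by
#' \code{\link{nucleobase}} instead.
#'
#' @return Character vector of fixture molecule names.
#' @export
heterocycle_fixtures <- function() {
  files <- list.files(system.file("extdata", "heterocycles",
                                  package = "lcaowire"),
                      pattern = "\\.xyz$")
  sort(sub("\\.xyz$", "", files))
}

#' Load a fixture geometry by name
#'
#' Resolves nucleobase names through \code{\link{nucleobase}} and all other
#' names through the packaged heterocycle XYZ files.
#'
#' @param name molecule name (e.g. \code{"adenine"}, \code{"pyrimidine"},
#'   \code{"9H-purine"}).
#' @return An \code{lcao_molecule} with bonds detected.
#' @export
fixture_molecule <- function(name) {
  if (tolower(name) %in% .BASE_FULL_NAMES ||
      toupper(name) %in% names(.BASE_FULL_NAMES))
    return(nucleobase(name))
  path <- system.file("extdata", "heterocycles", paste0(name, ".xyz"),
                      package = "lcaowire")
  if (!nzchar(path) || !file.exists(path))
    stop("no packaged fixture named '", name, "'")
  detect_bonds(read_xyz(path, name = name))
}
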