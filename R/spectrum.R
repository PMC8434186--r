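#' Diagonalize an LCAO Hamiltonian and fill the electronic levels
#'
#' Solves the real symmetric eigenproblem and fills the valence electrons
#' (C 4, N 5, O 6, H 1 per atom) pairwise from the bottom of the spectrum,
#' which locates the HOMO and LUMO. Within the frontier-orbital reading of
#' the model, \eqn{-E_{HOMO}} approximates the ionization energy and
#' \eqn{E_{LUMO} - E_{HOMO}} the excitation energy.
#'
#' @param ham result of \code{\link{build_hamiltonian}} or
#'   \code{\link{build_pair_hamiltonian}} (alternatively pass a bare
#'   symmetric matrix plus \code{basis} and \code{mol}).
#' @param basis,mol only needed when \code{ham} is a bare matrix.
#' @return An object of class \code{lcao_spectrum}: \code{energies}
#'   (ascending, eV), \code{coefficients} (orthonormal columns, one per
#'   molecular orbital), \code{n_electrons}, \code{homo}/\code{lumo}
#'   (1-based level indices), \code{degenerate_frontier} flag (HOMO or
#'   LUMO within 1e-6 eV of an adjacent level), the \code{basis} and the
#'   underlying molecule.
#' @examples
#' sp <- solve_spectrum(build_hamiltonian(nucleobase("A")))
#' ionization_energy(sp)
#' @export
solve_spectrum <- function(ham, basis = NULL, mol = NULL) {
  if (is.list(ham) && !is.null(ham$H)) {
    basis <- ham$basis; mol <- ham$molecule; H <- ham$H
  } else H <- ham
  if (!isSymmetric(unname(H), tol = 1e-9))
    stop("Hamiltonian must be symmetric")
  ne <- as.integer(sum(VALENCE_ELECTRONS[mol$elements]))
  if (ne %% 2L != 0L)
    stop("odd valence electron count (", ne,
         "): only closed-shell molecules are supported")
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  energies <- eig$values[ord]
  coeff <- eig$vectors[, ord, drop = FALSE]
  # fix the arbitrary eigenvector phase: largest-magnitude coefficient
  # positive
  for (k in seq_len(ncol(coeff))) {
    m <- which.max(abs(coeff[, k]))
    if (coeff[m, k] < 0) coeff[, k] <- -coeff[, k]
  }
  homo <- ne %/% 2L
  lumo <- homo + 1L
  if (homo < 1L || lumo > length(energies))
    stop("electron filling outside the computed spectrum")
  degen <- (homo > 1L && energies[homo] - energies[homo - 1L] < 1e-6) ||
    (energies[lumo] - energies[homo] < 1e-6) ||
    (lumo < length(energies) && energies[lumo + 1L] - energies[lumo] < 1e-6)
  structure(list(energies = energies, coefficients = coeff,
                 n_electrons = ne, homo = homo, lumo = lumo,
                 degenerate_frontier = degen, basis = basis,
                 molecule = mol),
            class = "lcao_spectrum")
}

#' @export
print.lcao_spectrum <- function(x, ...) {
  cat(sprintf(paste0("LCAO spectrum of '%s': %d levels, %d electrons\n",
                     "  HOMO #%d = %.3f eV, LUMO #%d = %.3f eV, ",
                     "gap = %.3f eV\n"),
              x$molecule$name, length(x$energies), x$n_electrons,
              x$homo, x$energies[x$homo], x$lumo, x$energies[x$lumo],
              excitation_energy(x)))
  invisible(x)
}

#' Ionization energy estimate (-E_HOMO)
#' @param spec an \code{lcao_spectrum}.
#' @return Energy in eV.
#' @export
ionization_energy <- function(spec) -spec$energies[spec$homo]

#' Excitation energy estimate (HOMO-LUMO gap)
#' @param spec an \code{lcao_spectrum}.
#' @return Energy in eV.
#' @export
excitation_energy <- function(spec)
  spec$energies[spec$lumo] - spec$energies[spec$homo]

# least-squares plane normal of a set of points (SVD); error on collinear
# input
.plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr))
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("cannot fit a molecular plane: atoms are collinear")
  sv$v[, 3L]
}

#' Classify molecular orbitals as pi, sigma or lone-pair-like
#'
#' For every molecular orbital the pi weight is the summed squared
#' projection of its p coefficients on the local base-plane normal (fitted
#' per base for pairs, over heavy atoms). Orbitals with pi weight above
#' \code{threshold} are labelled \code{"pi"}; the rest \code{"sigma"}.
#' Occupied sigma orbitals whose weight is dominated by N/O s and in-plane
#' p components are additionally flagged lone-pair-like (\code{"n"}).
#' Unoccupied orbitals are decorated with a star (\code{"pi*"},
#' \code{"sigma*"}). Reported weights are retained so users can apply a
#' different threshold.
#'
#' @param spec an \code{lcao_spectrum}.
#' @param fragments optional list of atom index vectors, one per fragment,
#'   each with its own fitted plane; defaults to one fragment (or the two
#'   bases when the spectrum came from a pair Hamiltonian built by
#'   \code{\link{solve_pair}}).
#' @param threshold pi-weight cutoff.
#' @return A data.frame with one row per orbital: \code{level},
#'   \code{energy}, \code{occupied}, \code{pi_weight}, \code{n_weight},
#'   \code{character}.
#' @export
classify_character <- function(spec, fragments = NULL, threshold = 0.5) {
  mol <- spec$molecule
  basis <- spec$basis
  if (is.null(fragments)) {
    fragments <- if (!is.null(spec$fragments)) spec$fragments else
      list(seq_len(natoms(mol)))
  }
  heavy <- mol$elements != "H"
  normals <- matrix(NA_real_, natoms(mol), 3L)
  for (fr in fragments) {
    at <- fr[heavy[fr]]
    if (length(at) < 3L)
      stop("fragment too small to fit a plane")
    nrm <- .plane_normal(mol$coords[at, , drop = FALSE])
    normals[fr, ] <- matrix(nrm, length(fr), 3L, byrow = TRUE)
  }
  p_rows <- which(basis$orbital %in% c("px", "py", "pz"))
  s_rows <- which(basis$orbital == "s")
  nmo <- ncol(spec$coefficients)
  pi_w <- numeric(nmo); n_w <- numeric(nmo)
  for (k in seq_len(nmo)) {
    ck <- spec$coefficients[, k]
    pw <- 0; inplane_no <- 0
    for (a in seq_len(natoms(mol))) {
      rows <- which(basis$atom == a & basis$orbital != "s")
      if (!length(rows)) next
      cp <- ck[rows]
      proj <- sum(cp * normals[a, ])
      pw <- pw + proj^2
      if (mol$elements[a] %in% c("N", "O"))
        inplane_no <- inplane_no + (sum(cp^2) - proj^2)
    }
    s_no <- sum(ck[s_rows[mol$elements[basis$atom[s_rows]] %in%
                            c("N", "O")]]^2)
    pi_w[k] <- pw
    n_w[k] <- inplane_no + s_no
  }
  occupied <- seq_len(nmo) <= spec$homo
  char <- ifelse(pi_w > threshold, "pi", "sigma")
  char[char == "sigma" & occupied & n_w > threshold] <- "n"
  char[!occupied] <- paste0(sub("^n$", "sigma", char[!occupied]), "*")
  data.frame(level = seq_len(nmo), energy = spec$energies,
             occupied = occupied, pi_weight = pi_w, n_weight = n_w,
             character = char, stringsAsFactors = FALSE)
}

#' Solve a Watson--Crick pair and keep fragment bookkeeping
#'
#' Convenience wrapper: builds the pair Hamiltonian, diagonalizes it and
#' records the atom index ranges of the two bases so that
#' \code{\link{classify_character}} fits one plane per base.
#'
#' @param pair an \code{lcao_base_pair}.
#' @param params an \code{\link{lcao_params}} object.
#' @param cross_cutoff see \code{\link{build_pair_hamiltonian}}.
#' @return An \code{lcao_spectrum} with a \code{fragments} field.
#' @export
solve_pair <- function(pair, params = lcao_params(), cross_cutoff = 10.0) {
  spec <- solve_spectrum(build_pair_hamiltonian(pair, params, cross_cutoff))
  n1 <- natoms(pair$base1)
  spec$fragments <- list(seq_len(n1),
                         n1 + seq_len(natoms(pair$base2)))
  spec
}

#' Frontier orbital of a given character
#'
#' Picks the highest occupied (or lowest unoccupied) level whose
#' classified character matches, e.g. the first pi ionization even when a
#' lone-pair level lies above, or the lowest pi* level when a sigma* level
#' intrudes below it.
#'
#' @param spec an \code{lcao_spectrum}.
#' @param what \code{"pi"} or \code{"sigma"}.
#' @param occupied \code{TRUE} for the occupied side.
#' @param chars optional precomputed \code{\link{classify_character}}
#'   table.
#' @return The 1-based level index, or \code{NA} if no such level exists.
#' @export
frontier_level <- function(spec, what = "pi", occupied = TRUE,
                           chars = NULL) {
  if (is.null(chars)) chars <- classify_character(spec)
  want <- if (occupied) what else paste0(what, "*")
  hit <- which(chars$occupied == occupied & chars$character == want)
  if (!length(hit)) return(NA_integer_)
  if (occupied) max(hit) else min(hit)
}

#' Transition dipole and oscillator strength between two orbitals
#'
#' Point-dipole approximation: only same-atom, same-orbital products
#' contribute, so the transition dipole is
#' \eqn{\vec d = -e \sum_{i\nu} c^{L*}_{i\nu} \vec r_\nu c^{H}_{i\nu}} and
#' the oscillator strength \eqn{f = \frac{2}{3} \frac{m_e}{\hbar^2} E d^2}
#' evaluated in atomic units with \eqn{E} the transition energy. Because
#' distinct molecular orbitals are orthogonal, the dipole is independent
#' of the coordinate origin.
#'
#' @param spec an \code{lcao_spectrum}.
#' @param from,to 1-based orbital indices; default HOMO to LUMO.
#' @return A list with \code{f} (dimensionless), \code{dipole}
#'   (e * Angstrom, length-3), \code{energy} (eV).
#' @examples
#' sp <- solve_spectrum(build_hamiltonian(nucleobase("A")))
#' oscillator_strength(sp)$f
#' @export
oscillator_strength <- function(spec, from = spec$homo, to = spec$lumo) {
  if (from == to) stop("zero transition: 'from' and 'to' are the same level")
  cH <- spec$coefficients[, from]
  cL <- spec$coefficients[, to]
  pos <- spec$molecule$coords[spec$basis$atom, , drop = FALSE]
  w <- cL * cH
  dip <- -colSums(pos * w)          # e * Angstrom
  E <- spec$energies[to] - spec$energies[from]
  f <- (2 / 3) * (E / HARTREE_EV) * sum((dip / BOHR_ANG)^2)
  list(f = f, dipole = dip, energy = E)
}
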