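#' Maximum transfer percentage between two sites
#'
#' For a carrier initially localized on one of two coupled sites, the
#' maximum probability of finding it on the other site during coherent
#' evolution is \eqn{p = (2t)^2 / ((2t)^2 + \Delta^2)}, with \eqn{t} the
#' transfer integral and \eqn{\Delta} the on-site energy difference.
#'
#' @param t transfer integral, eV.
#' @param delta on-site (HOMO or LUMO) energy difference, eV.
#' @return p in [0, 1].
#' @examples
#' max_transfer_percentage(0.1, 0)     # 1
#' max_transfer_percentage(0.05, 0.1)  # 0.5
#' @export
max_transfer_percentage <- function(t, delta) {
  if (t == 0 && delta == 0)
    stop("maximum transfer percentage is undefined for t = delta = 0")
  (2 * t)^2 / ((2 * t)^2 + delta^2)
}

# exponential-regime coupling matrix between the orbitals of two molecule
# fragments (all atom pairs within cutoff)
.cross_coupling <- function(mol1, mol2, params, cutoff = 10.0,
                            min_dist = 1.5) {
  b1 <- orbital_basis(mol1); b2 <- orbital_basis(mol2)
  sl1 <- .atom_slices(b1); sl2 <- .atom_slices(b2)
  V <- matrix(0, nrow(b1), nrow(b2))
  for (i in seq_len(natoms(mol1))) {
    for (j in seq_len(natoms(mol2))) {
      dv <- mol2$coords[j, ] - mol1$coords[i, ]
      d2 <- sum(dv^2)
      if (d2 < min_dist^2)
        stop(sprintf(
          "overlapping monomers: cross distance %.2f A < %.2f A",
          sqrt(d2), min_dist))
      if (d2 > cutoff^2) next
      V[sl1[[i]], sl2[[j]]] <-
        slater_koster_block(mol1$coords[i, ], mol2$coords[j, ],
                            mol1$elements[i], mol2$elements[j], params,
                            "exponential")
    }
  }
  V
}

.resolve_level <- function(spec, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  switch(toupper(sel), HOMO = spec$homo, LUMO = spec$lumo,
         stop("orbital selector must be 'HOMO', 'LUMO' or a level index"))
}

#' Inter-monomer transfer integral of a stacked dimer
#'
#' Solves each base pair of the dimer independently, then contracts the
#' selected molecular orbitals with the exponential-regime Slater--Koster
#' couplings between the atoms of the two monomers:
#' \eqn{t = \sum c^{(\lambda)}_{i\nu} V_{i\nu,j\mu} c^{(\lambda')}_{j\mu}}.
#' The sign of \eqn{t} depends on the arbitrary orbital phases (fixed here
#' by the largest-coefficient-positive convention); reports quote
#' \eqn{|t|}.
#'
#' @param dim an \code{lcao_dimer} (monomer 1 is \code{pair1}, the 5' side
#'   of the step).
#' @param params an \code{\link{lcao_params}} object.
#' @param orbital1,orbital2 \code{"HOMO"}, \code{"LUMO"} or explicit level
#'   indices, per monomer.
#' @param cutoff inter-monomer coupling cutoff, Angstrom.
#' @param spectra optional precomputed list of the two monomer spectra (as
#'   from \code{\link{solve_pair}}) to avoid re-diagonalizing.
#' @return An object of class \code{lcao_transfer}: \code{t} (signed, eV),
#'   \code{delta} (E_monomer1 - E_monomer2, eV), \code{p}, \code{orbital}
#'   (the two resolved level indices) and the monomer energies.
#' @examples
#' \donttest{
#' tr <- transfer_integral(ideal_dimer("GG"))
#' abs(tr$t) * 1000  # meV
#' }
#' @export
transfer_integral <- function(dim, params = lcao_params(),
                              orbital1 = "HOMO", orbital2 = orbital1,
                              cutoff = 10.0, spectra = NULL) {
  if (is.null(spectra))
    spectra <- list(solve_pair(dim$pair1, params),
                    solve_pair(dim$pair2, params))
  s1 <- spectra[[1L]]; s2 <- spectra[[2L]]
  k1 <- .resolve_level(s1, orbital1)
  k2 <- .resolve_level(s2, orbital2)
  V <- .cross_coupling(s1$molecule, s2$molecule, params, cutoff)
  t_val <- drop(crossprod(s1$coefficients[, k1], V %*%
                            s2$coefficients[, k2]))
  e1 <- s1$energies[k1]; e2 <- s2$energies[k2]
  delta <- e1 - e2
  p <- if (t_val == 0 && delta == 0) NA_real_ else
    max_transfer_percentage(t_val, delta)
  structure(list(t = t_val, delta = delta, p = p,
                 orbital = c(k1, k2), energies = c(e1, e2),
                 label = dim$label),
            class = "lcao_transfer")
}

#' @export
print.lcao_transfer <- function(x, ...) {
  cat(sprintf(
    "Transfer %s: |t| = %.1f meV, Delta = %.1f meV, p = %.3f\n",
    x$label, abs(x$t) * 1e3, abs(x$delta) * 1e3, x$p))
  invisible(x)
}

#' Hole/electron transfer table for a stacked dimer
#'
#' Reports the frontier transfer channels of a dimer: HOMO-HOMO (holes),
#' LUMO-LUMO (electrons), and additional rows for near-frontier levels
#' within \code{window} of the frontier level or for sigma*-classified
#' unoccupied levels intruding below the first pi* level, as such split
#' channels do occur in stacked purine dimers.
#'
#' @param dim an \code{lcao_dimer}.
#' @param params an \code{\link{lcao_params}} object.
#' @param window energy window (eV) around each frontier level within
#'   which extra near-degenerate channels are also reported.
#' @param cutoff inter-monomer coupling cutoff, Angstrom.
#' @return A data.frame with columns \code{channel}, \code{character}
#'   (from \code{\link{classify_character}}, per monomer),
#'   \code{level1}, \code{level2}, \code{t_mev} (absolute value),
#'   \code{delta_mev} (absolute value), \code{p}.
#' @export
dimer_report <- function(dim, params = lcao_params(), window = 0.05,
                         cutoff = 10.0) {
  s1 <- solve_pair(dim$pair1, params)
  s2 <- solve_pair(dim$pair2, params)
  ch1 <- classify_character(s1)
  ch2 <- classify_character(s2)
  spectra <- list(s1, s2)

  channel_levels <- function(spec, chars, occupied) {
    frontier <- if (occupied) spec$homo else spec$lumo
    cand <- if (occupied) seq_len(spec$homo) else
      seq(spec$lumo, length(spec$energies))
    near <- cand[abs(spec$energies[cand] - spec$energies[frontier]) <=
                   window]
    if (!occupied) {
      # sigma* channels intruding below (or at) the first pi* level
      first_pi <- frontier_level(spec, "pi", occupied = FALSE,
                                 chars = chars)
      if (!is.na(first_pi))
        near <- union(near, cand[cand <= first_pi])
    }
    sort(unique(c(frontier, near)))
  }

  rows <- list()
  for (side in c("hole", "electron")) {
    occ <- side == "hole"
    l1 <- channel_levels(s1, ch1, occ)
    l2 <- channel_levels(s2, ch2, occ)
    for (a in l1) for (b in l2) {
      tr <- transfer_integral(dim, params, orbital1 = a, orbital2 = b,
                              cutoff = cutoff, spectra = spectra)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = side,
        character = paste(ch1$character[a], ch2$character[b], sep = "/"),
        level1 = a, level2 = b,
        t_mev = abs(tr$t) * 1e3, delta_mev = abs(tr$delta) * 1e3,
        p = tr$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "label") <- dim$label
  out
}
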