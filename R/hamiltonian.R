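#' Valence orbital basis of a molecule
#'
#' Enumerates the atom-centered valence basis: 2s, 2px, 2py, 2pz for each
#' C, N, O atom and 1s for each H, grouped by atom in atom order.
#'
#' @param mol an \code{lcao_molecule}.
#' @return A data.frame with columns \code{atom} (1-based index),
#'   \code{element} and \code{orbital} (\code{"s"}, \code{"px"},
#'   \code{"py"}, \code{"pz"}).
#' @export
orbital_basis <- function(mol) {
  per_atom <- lapply(seq_along(mol$elements), function(i) {
    orbs <- if (mol$elements[i] == "H") "s" else c("s", "px", "py", "pz")
    data.frame(atom = i, element = mol$elements[i], orbital = orbs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_atom)
}

# radial coupling strengths V_chi for the four Slater-Koster channels at
# distance d (Angstrom): Harrison 1/d^2 inside a molecule, exponential
# decay for non-covalent contacts
.sk_radial <- function(d, params, regime) {
  chi <- params$chi
  base <- switch(regime,
                 harrison = params$hbar2_over_m / d^2,
                 exponential = params$hbar2_over_m / params$d0^2 *
                   exp(-params$beta * (d - params$d0)),
                 stop("unknown regime '", regime, "'"))
  c(ss = chi[["ss_sigma"]] * base, sp = chi[["sp_sigma"]] * base,
    pps = chi[["pp_sigma"]] * base, ppp = chi[["pp_pi"]] * base)
}

#' Slater--Koster coupling block between two atoms
#'
#' Builds the two-center coupling block between the valence orbitals of
#' atoms i and j from the directional cosines of the vector pointing from
#' i to j: \eqn{V_{ss} = V_{ss\sigma}}, \eqn{V_{sx} = \xi_1 V_{sp\sigma}}
#' (with the opposite sign for \eqn{\langle p_i | H | s_j \rangle}),
#' \eqn{V_{xx} = \xi_1^2 V_{pp\sigma} + (1-\xi_1^2) V_{pp\pi}} and
#' \eqn{V_{xy} = \xi_1 \xi_2 (V_{pp\sigma} - V_{pp\pi})}. The radial parts
#' follow Harrison's \eqn{\chi \hbar^2/(m d^2)} form in the
#' \code{"harrison"} regime and the exponentially decaying form
#' \eqn{\chi \hbar^2/(m d_0^2) e^{-\beta(d-d_0)}} in the
#' \code{"exponential"} regime used for hydrogen-bonded and stacked
#' contacts. Every element involving an H 1s orbital is damped by the
#' factor \code{b} once per H orbital.
#'
#' @param pos_i,pos_j Cartesian positions (Angstrom) of atoms i and j.
#' @param elem_i,elem_j element symbols.
#' @param params an \code{\link{lcao_params}} object.
#' @param regime \code{"harrison"} or \code{"exponential"}.
#' @return The coupling block in eV, \code{n_i x n_j} where H contributes
#'   one orbital and C/N/O four (ordered s, px, py, pz).
#' @examples
#' p <- lcao_params()
#' slater_koster_block(c(0, 0, 0), c(1.35, 0, 0), "H", "H", p)
#' @export
slater_koster_block <- function(pos_i, pos_j, elem_i, elem_j, params,
                                regime = c("harrison", "exponential")) {
  regime <- match.arg(regime)
  dv <- as.numeric(pos_j) - as.numeric(pos_i)
  d <- sqrt(sum(dv^2))
  if (d <= 0.4)
    stop(sprintf("atoms too close for a two-center coupling: d = %.3f A", d))
  u <- dv / d
  v <- .sk_radial(d, params, regime)
  ni <- if (elem_i == "H") 1L else 4L
  nj <- if (elem_j == "H") 1L else 4L
  M <- matrix(0, ni, nj)
  M[1L, 1L] <- v[["ss"]]
  if (nj == 4L) M[1L, 2:4] <- u * v[["sp"]]
  if (ni == 4L) M[2:4, 1L] <- -u * v[["sp"]]
  if (ni == 4L && nj == 4L)
    M[2:4, 2:4] <- outer(u, u) * (v[["pps"]] - v[["ppp"]]) +
      diag(3) * v[["ppp"]]
  damp <- (if (elem_i == "H") params$b else 1) *
    (if (elem_j == "H") params$b else 1)
  M * damp
}

.onsite_block <- function(element, params) {
  if (element == "H") return(params$onsite[["H.1s"]])
  es <- params$onsite[[paste0(element, ".2s")]]
  ep <- params$onsite[[paste0(element, ".2p")]]
  c(es, ep, ep, ep)
}

# orbital index ranges per atom for a basis data.frame
.atom_slices <- function(basis) {
  split(seq_len(nrow(basis)), basis$atom)
}

#' Assemble the all-valence LCAO Hamiltonian of a molecule
#'
#' Diagonal elements are the on-site energies of the parameter set;
#' off-diagonal blocks are Slater--Koster couplings in the Harrison
#' \eqn{1/d^2} regime for bonded atom pairs only (couplings between
#' non-neighboring atoms are zero, and the overlap matrix is taken as the
#' identity).
#'
#' @param mol an \code{lcao_molecule} with bonds detected.
#' @param params an \code{\link{lcao_params}} object.
#' @return A list with \code{H} (real symmetric matrix, eV) and
#'   \code{basis} (see \code{\link{orbital_basis}}).
#' @examples
#' ade <- nucleobase("A")
#' dim(build_hamiltonian(ade)$H)   # 45 x 45
#' @export
build_hamiltonian <- function(mol, params = lcao_params()) {
  if (natoms(mol) > 1L && nrow(mol$bonds) == 0L)
    warning("molecule '", mol$name,
            "' has no bonds; Hamiltonian will be diagonal ",
            "(run detect_bonds first?)")
  basis <- orbital_basis(mol)
  sl <- .atom_slices(basis)
  H <- diag(unlist(lapply(mol$elements, .onsite_block, params = params)))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1L]; j <- mol$bonds[r, 2L]
      blk <- slater_koster_block(mol$coords[i, ], mol$coords[j, ],
                                 mol$elements[i], mol$elements[j], params,
                                 "harrison")
      H[sl[[i]], sl[[j]]] <- blk
      H[sl[[j]], sl[[i]]] <- t(blk)
    }
  }
  list(H = H, basis = basis, molecule = mol)
}

#' Assemble the LCAO Hamiltonian of a Watson--Crick pair
#'
#' Intra-base blocks are exactly those of \code{\link{build_hamiltonian}};
#' every cross-base atom pair within \code{cross_cutoff} is coupled with
#' the exponentially decaying Slater--Koster regime appropriate for
#' non-covalent (hydrogen-bond) contacts.
#'
#' @param pair an \code{lcao_base_pair} whose bases have bonds detected.
#' @param params an \code{\link{lcao_params}} object.
#' @param cross_cutoff distance (Angstrom) beyond which cross-base
#'   couplings are dropped; at the default 10 A the exponential factor is
#'   below 1e-5 of its contact value, so the cutoff is numerically inert.
#' @return A list with \code{H}, \code{basis} (over the concatenated
#'   atoms, base1 first) and \code{molecule} (the merged pair).
#' @examples
#' at <- wc_pair("A")
#' dim(build_pair_hamiltonian(at)$H)   # 87 x 87
#' @export
build_pair_hamiltonian <- function(pair, params = lcao_params(),
                                   cross_cutoff = 10.0) {
  h1 <- build_hamiltonian(pair$base1, params)
  h2 <- build_hamiltonian(pair$base2, params)
  n1 <- nrow(h1$H); n2 <- nrow(h2$H)
  H <- matrix(0, n1 + n2, n1 + n2)
  H[seq_len(n1), seq_len(n1)] <- h1$H
  H[n1 + seq_len(n2), n1 + seq_len(n2)] <- h2$H
  merged <- pair_as_molecule(pair)
  basis <- orbital_basis(merged)
  sl <- .atom_slices(basis)
  na1 <- natoms(pair$base1)
  for (i in seq_len(na1)) {
    for (j in (na1 + 1L):natoms(merged)) {
      dv <- merged$coords[j, ] - merged$coords[i, ]
      if (sum(dv^2) > cross_cutoff^2) next
      blk <- slater_koster_block(merged$coords[i, ], merged$coords[j, ],
                                 merged$elements[i], merged$elements[j],
                                 params, "exponential")
      H[sl[[i]], sl[[j]]] <- blk
      H[sl[[j]], sl[[i]]] <- t(blk)
    }
  }
  list(H = H, basis = basis, molecule = merged)
}
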