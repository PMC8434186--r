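# Physical constants (atomic units expressed in eV / Angstrom / fs)
HBAR2_OVER_M <- 7.6199682    # hbar^2/m_e, eV * Angstrom^2
HARTREE_EV   <- 27.211386    # 1 hartree in eV
BOHR_ANG     <- 0.529177     # 1 bohr in Angstrom
HBAR_EV_FS   <- 0.6582119569 # hbar in eV * fs

#' All-valence LCAO parameter set
#'
#' Bundles the semi-empirical parameters of the all-valence LCAO model:
#' on-site energies of the H 1s and C/N/O 2s, 2p valence orbitals, the
#' dimensionless Harrison-type prefactors \eqn{\chi} of the Slater--Koster
#' two-center couplings, the damping factor \eqn{b} applied once per
#' participating H orbital, and the exponential-regime constants used for
#' non-covalent (hydrogen-bonded or stacked) contacts,
#' \eqn{V_\chi = \chi \hbar^2/(m d_0^2)\, e^{-\beta (d - d_0)}}.
#'
#' @param onsite named numeric vector of on-site energies (eV) with names
#'   \code{H.1s, C.2s, C.2p, N.2s, N.2p, O.2s, O.2p}; all negative.
#' @param chi named numeric vector of dimensionless Slater--Koster
#'   prefactors with names \code{ss_sigma, sp_sigma, pp_sigma, pp_pi}.
#' @param b damping factor applied multiplicatively once per H orbital
#'   taking part in a coupling (so H--H couplings carry \code{b^2}).
#' @param d0 reference covalent bond length (Angstrom).
#' @param beta exponential decay rate (1/Angstrom) of the non-covalent
#'   regime. The default \code{2/d0} reads the decay constant as
#'   \code{2/d0 * (d - d0)} in the exponent; it is kept as a knob because
#'   an absolute rate of 2/Angstrom is an alternative reading (see the
#'   methods vignette for the calibration against stacked-dimer transfer
#'   integrals).
#'
#' @return An object of class \code{lcao_params}.
#' @examples
#' p <- lcao_params()
#' p$onsite[["C.2p"]]
#' @export
lcao_params <- function(onsite = c(H.1s = -13.64,
                                   C.2s = -13.18, C.2p = -6.70,
                                   N.2s = -14.51, N.2p = -9.55,
                                   O.2s = -15.03, O.2p = -11.52),
                        chi = c(ss_sigma = -1.32, sp_sigma = -1.42,
                                pp_sigma = 2.22, pp_pi = -0.73),
                        b = 0.70, d0 = 1.35, beta = 2 / d0) {
  need_on <- c("H.1s", "C.2s", "C.2p", "N.2s", "N.2p", "O.2s", "O.2p")
  need_chi <- c("ss_sigma", "sp_sigma", "pp_sigma", "pp_pi")
  if (!all(need_on %in% names(onsite)))
    stop("onsite must name all of: ", paste(need_on, collapse = ", "))
  if (!all(need_chi %in% names(chi)))
    stop("chi must name all of: ", paste(need_chi, collapse = ", "))
  if (any(!is.finite(onsite)) || any(onsite >= 0))
    stop("all on-site energies must be finite and negative (eV)")
  if (chi[["pp_sigma"]] <= 0)
    stop("chi pp_sigma must be positive")
  if (any(chi[c("ss_sigma", "sp_sigma", "pp_pi")] >= 0))
    stop("chi ss_sigma, sp_sigma and pp_pi must be negative")
  if (!(b > 0 && b <= 1)) stop("b must lie in (0, 1]")
  if (d0 <= 0) stop("d0 must be positive")
  if (beta <= 0) stop("beta must be positive")
  structure(list(onsite = onsite[need_on], chi = chi[need_chi],
                 b = b, d0 = d0, beta = beta,
                 hbar2_over_m = HBAR2_OVER_M),
            class = "lcao_params")
}

#' @export
print.lcao_params <- function(x, ...) {
  cat("All-valence LCAO parameter set\n")
  cat("  on-site (eV):", paste(names(x$onsite), sprintf("%.2f", x$onsite),
                               collapse = "  "), "\n")
  cat("  chi:", paste(names(x$chi), sprintf("%.2f", x$chi), collapse = "  "),
      "\n")
  cat(sprintf("  b = %.2f   d0 = %.2f A   beta = %.4f 1/A\n",
              x$b, x$d0, x$beta))
  invisible(x)
}

#' Read an LCAO parameter file
#'
#' Reads a YAML parameter file whose fields mirror \code{\link{lcao_params}}
#' (\code{onsite}, \code{chi}, \code{b}, \code{d0}, \code{beta}); missing
#' fields fall back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return An \code{lcao_params} object.
#' @export
read_lcao_params <- function(path) {
  y <- yaml::read_yaml(path)
  d <- lcao_params()
  on <- d$onsite; ch <- d$chi
  if (!is.null(y$onsite)) on[names(y$onsite)] <- unlist(y$onsite)
  if (!is.null(y$chi)) ch[names(y$chi)] <- unlist(y$chi)
  lcao_params(onsite = on, chi = ch,
              b = if (is.null(y$b)) d$b else y$b,
              d0 = if (is.null(y$d0)) d$d0 else y$d0,
              beta = if (is.null(y$beta)) d$beta else y$beta)
}

# valence electrons contributed per element
VALENCE_ELECTRONS <- c(C = 4, N = 5, O = 6, H = 1)

# covalent radii (Angstrom) for bond perception
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

SUPPORTED_ELEMENTS <- c("C", "N", "O", "H")
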