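#' Tight-binding wire model of a base-pair stack
#'
#' Nearest-neighbor chain whose sites are base-pair HOMO or LUMO states:
#' on-site energies \eqn{E_\alpha} and hopping integrals
#' \eqn{t_{\alpha,\alpha+1}}.
#'
#' @param onsite numeric vector of on-site energies, eV.
#' @param hops numeric vector of nearest-neighbor transfer integrals, eV;
#'   length \code{length(onsite) - 1}.
#' @return An object of class \code{lcao_wire}.
#' @examples
#' w <- wire_model(c(-8.3, -8.3), hops = 0.116)
#' wire_eigenstates(w)$energies
#' @export
wire_model <- function(onsite, hops = numeric(0)) {
  onsite <- as.numeric(onsite); hops <- as.numeric(hops)
  n <- length(onsite)
  if (n < 1L) stop("a wire needs at least one site")
  if (length(hops) != max(n - 1L, 0L))
    stop("hops must have length ", n - 1L)
  if (any(!is.finite(c(onsite, hops))))
    stop("wire parameters must be finite")
  structure(list(onsite = onsite, hops = hops), class = "lcao_wire")
}

#' @export
print.lcao_wire <- function(x, ...) {
  cat(sprintf("Tight-binding wire: %d sites\n", length(x$onsite)))
  cat("  onsite (eV):", paste(sprintf("%.3f", x$onsite), collapse = " "),
      "\n")
  if (length(x$hops))
    cat("  hops (meV): ",
        paste(sprintf("%.1f", x$hops * 1e3), collapse = " "), "\n")
  invisible(x)
}

.wire_matrix <- function(model) {
  n <- length(model$onsite)
  H <- diag(model$onsite, n, n)
  if (n > 1L) for (a in seq_len(n - 1L)) {
    H[a, a + 1L] <- model$hops[a]
    H[a + 1L, a] <- model$hops[a]
  }
  H
}

#' Eigenstates of a tight-binding wire
#'
#' @param model an \code{\link{wire_model}}.
#' @return A list with \code{energies} (ascending, eV) and
#'   \code{occupations}, an N x N matrix whose column k holds the
#'   per-site occupation probabilities \eqn{|v_{jk}|^2} of eigenstate k
#'   (each column sums to 1).
#' @export
wire_eigenstates <- function(model) {
  H <- .wire_matrix(model)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  list(energies = eig$values[ord],
       occupations = eig$vectors[, ord, drop = FALSE]^2,
       vectors = eig$vectors[, ord, drop = FALSE])
}

#' Coherent carrier dynamics on a wire
#'
#' Propagates the time-dependent site amplitudes of an extra carrier under
#' the wire Hamiltonian, using the spectral form of the propagator:
#' \eqn{A(t) = \sum_k \langle v_k | A(0) \rangle e^{-i E_k t/\hbar} v_k}
#' with \eqn{\hbar = 0.6582} eV fs. The norm is conserved exactly up to
#' round-off.
#'
#' @param model an \code{\link{wire_model}}.
#' @param initial complex (or numeric) amplitude vector, normalized to 1;
#'   or a site index given as \code{site = k}.
#' @param times numeric vector of output times, fs.
#' @param site convenience alternative to \code{initial}: start fully
#'   localized on this site.
#' @return A list with \code{times}, \code{amplitudes} (complex matrix,
#'   one row per time, one column per site) and \code{populations}
#'   (\eqn{|A_\alpha(t)|^2}, same shape).
#' @examples
#' w <- wire_model(c(0, 0), hops = 0.1)
#' out <- propagate(w, site = 1, times = seq(0, 40, by = 0.5))
#' max(out$populations[, 2])   # reaches 1: resonant two-site oscillation
#' @export
propagate <- function(model, initial = NULL, times, site = NULL) {
  n <- length(model$onsite)
  if (is.null(initial)) {
    if (is.null(site)) stop("give either 'initial' amplitudes or 'site'")
    initial <- rep(0, n); initial[site] <- 1
  }
  initial <- as.complex(initial)
  if (length(initial) != n)
    stop("initial amplitudes must have one entry per site")
  nrm <- sum(Mod(initial)^2)
  if (abs(nrm - 1) > 1e-9)
    stop(sprintf("initial state is not normalized: sum |A|^2 = %.6f", nrm))
  eig <- wire_eigenstates(model)
  Vt <- t(eig$vectors)               # rows: eigenstates
  proj <- drop(Vt %*% initial)       # <v_k | A(0)>
  phases <- exp(outer(times, eig$energies,
                      function(tt, ee) -1i * ee * tt / HBAR_EV_FS))
  amp <- (phases * matrix(proj, nrow = length(times), ncol = n,
                          byrow = TRUE)) %*% Vt
  list(times = times, amplitudes = amp, populations = Mod(amp)^2)
}

#' Parameterize a wire model from a stack of base-pair geometries
#'
#' Solves every monomer (base pair) of a stack, takes its HOMO or LUMO
#' energy as the site energy, and computes the transfer integral between
#' each pair of consecutive monomers, yielding the nearest-neighbor wire
#' model of the stack.
#'
#' @param pairs list of \code{lcao_base_pair} objects in stacking order
#'   (consecutive mid-frame distance below 6 Angstrom).
#' @param params an \code{\link{lcao_params}} object.
#' @param orbital \code{"HOMO"} (holes) or \code{"LUMO"} (electrons).
#' @param cutoff inter-monomer coupling cutoff, Angstrom.
#' @return A list with \code{model} (an \code{\link{wire_model}}) and
#'   \code{transfers} (list of \code{lcao_transfer}, one per step).
#' @export
build_wire_from_dimers <- function(pairs, params = lcao_params(),
                                   orbital = c("HOMO", "LUMO"),
                                   cutoff = 10.0) {
  orbital <- match.arg(orbital)
  if (!length(pairs)) stop("empty base-pair sequence")
  centroid <- function(p) colMeans(pair_as_molecule(p)$coords)
  if (length(pairs) > 1L) {
    for (a in seq_len(length(pairs) - 1L)) {
      gap <- sqrt(sum((centroid(pairs[[a + 1L]]) - centroid(pairs[[a]]))^2))
      if (gap >= 6)
        stop(sprintf(
          "monomers %d and %d are not stacked (centroid gap %.1f A)",
          a, a + 1L, gap))
    }
  }
  spectra <- lapply(pairs, solve_pair, params = params)
  level <- vapply(spectra, function(s) .resolve_level(s, orbital), 1L)
  onsite <- mapply(function(s, k) s$energies[k], spectra, level)
  transfers <- list()
  hops <- numeric(0)
  if (length(pairs) > 1L) {
    for (a in seq_len(length(pairs) - 1L)) {
      dm <- dimer(pairs[[a]], pairs[[a + 1L]],
                  label = paste0("step", a))
      tr <- transfer_integral(dm, params, orbital1 = level[a],
                              orbital2 = level[a + 1L], cutoff = cutoff,
                              spectra = list(spectra[[a]],
                                             spectra[[a + 1L]]))
      transfers[[a]] <- tr
      hops[a] <- tr$t
    }
  }
  list(model = wire_model(onsite, hops), transfers = transfers)
}
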