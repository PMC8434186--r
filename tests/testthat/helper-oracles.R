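# shared oracles and generators for the test suite

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent pi-electron (Huckel-type) matrix over the heavy atoms of an
# exactly planar molecule in the xy-plane: diagonal 2p on-site energies,
# off-diagonal chi_pppi * hbar^2/(m d^2) for bonded heavy pairs
huckel_pz_matrix <- function(mol, params = lcao_params()) {
  heavy <- which(mol$elements != "H")
  n <- length(heavy)
  M <- diag(vapply(mol$elements[heavy],
                   function(e) params$onsite[[paste0(e, ".2p")]], 1.0),
            n, n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
    ki <- match(i, heavy); kj <- match(j, heavy)
    if (is.na(ki) || is.na(kj)) next
    d2 <- sum((mol$coords[i, ] - mol$coords[j, ])^2)
    v <- params$chi[["pp_pi"]] * params$hbar2_over_m / d2
    M[ki, kj] <- v; M[kj, ki] <- v
  }
  M
}

# fixed-step classical Runge-Kutta integrator for the wire equations of
# motion i hbar dA/dt = H A, independent of the spectral propagator
rk4_propagate <- function(model, a0, t_end, dt) {
  H <- diag(model$onsite, length(model$onsite))
  n <- length(model$onsite)
  if (n > 1) for (k in seq_len(n - 1)) {
    H[k, k + 1] <- model$hops[k]; H[k + 1, k] <- model$hops[k]
  }
  hbar <- 0.6582119569
  deriv <- function(a) -1i / hbar * (H %*% a)
  a <- as.complex(a0)
  nstep <- round(t_end / dt)
  for (s in seq_len(nstep)) {
    k1 <- deriv(a)
    k2 <- deriv(a + dt / 2 * k1)
    k3 <- deriv(a + dt / 2 * k2)
    k4 <- deriv(a + dt * k3)
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  drop(a)
}

# printed frontier energies (eV) and oscillator strength used by the
# printed-number regression checks
NUCLEOBASE_PRINTED <- data.frame(
  molecule = c("adenine", "guanine", "thymine", "cytosine", "uracil"),
  ionization = c(8.44, 8.36, 9.09, 8.68, 8.89),
  excitation = c(4.20, 4.25, 4.77, 4.54, 4.70),
  stringsAsFactors = FALSE)
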