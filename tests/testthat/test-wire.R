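test_that("wire eigenstates match closed forms", {
  # single site
  w1 <- wire_eigenstates(wire_model(-8.3))
  expect_equal(w1$energies, -8.3)
  expect_equal(drop(w1$occupations), 1)
  # two sites
  E1 <- -8.2; E2 <- -8.5; tt <- 0.08
  w2 <- wire_eigenstates(wire_model(c(E1, E2), tt))
  mean_ <- (E1 + E2) / 2; split <- sqrt(((E1 - E2) / 2)^2 + tt^2)
  expect_equal(w2$energies, c(mean_ - split, mean_ + split),
               tolerance = 1e-12)
  # uniform open chain: E + 2 t cos(k pi / (N + 1))
  for (N in c(5, 17, 50)) {
    wu <- wire_eigenstates(wire_model(rep(-8, N), rep(-0.1, N - 1)))
    ks <- seq_len(N)
    expect_equal(wu$energies,
                 sort(-8 + 2 * (-0.1) * cos(ks * pi / (N + 1))),
                 tolerance = 1e-10)
    expect_equal(colSums(wu$occupations), rep(1, N), tolerance = 1e-12)
  }
})

test_that("propagation conserves norm and energy and reverses in time", {
  set.seed(9)
  model <- wire_model(c(-8.3, -8.45, -8.3, -8.6), runif(3, 0.02, 0.12))
  H <- diag(model$onsite)
  for (k in 1:3) { H[k, k + 1] <- model$hops[k]; H[k + 1, k] <- model$hops[k] }
  times <- seq(0, 200, by = 2)
  out <- propagate(model, site = 2, times = times)
  norms <- rowSums(out$populations)
  expect_lt(max(abs(norms - 1)), 1e-9)
  energies <- vapply(seq_along(times), function(i) {
    a <- out$amplitudes[i, ]
    Re(Conj(a) %*% H %*% a)
  }, 1.0)
  expect_lt(max(abs(energies - energies[1])), 1e-9)
  # time reversal: propagate the final state backwards
  back <- propagate(model, initial = out$amplitudes[length(times), ],
                    times = -200)
  a0 <- rep(0, 4); a0[2] <- 1
  expect_lt(max(Mod(back$amplitudes[1, ] - a0)), 1e-8)
})

test_that("the spectral propagator agrees with an independent integrator", {
  # on-site energies gauge-shifted near zero so the fixed-step oracle is
  # not dominated by the fast global phase
  model <- wire_model(c(0, -0.05, -0.2), c(0.09, 0.04))
  a0 <- c(1, 0, 0)
  spectral <- propagate(model, initial = a0, times = 100)
  rk <- rk4_propagate(model, a0, t_end = 100, dt = 0.01)
  expect_lt(max(Mod(drop(spectral$amplitudes) - rk)), 1e-6)
})

test_that("two-site special cases follow the Rabi closed form", {
  tt <- 0.05
  w <- wire_model(c(-8, -8), tt)
  period <- pi * 0.6582119569 / tt
  times <- seq(0, period, length.out = 801)
  out <- propagate(w, site = 1, times = times)
  # resonant case: complete oscillation with period pi hbar / |t|
  expect_equal(max(out$populations[, 2]), 1, tolerance = 1e-10)
  expect_equal(out$populations[801, 1], 1, tolerance = 1e-10)
  # long-time mean off-site occupation is p / 2
  dd <- 0.07
  w2 <- wire_model(c(-8 + dd / 2, -8 - dd / 2), tt)
  omega <- sqrt((2 * tt)^2 + dd^2) / 2 / 0.6582119569
  tgrid <- seq(0, 400 * pi / omega, length.out = 200001)
  out2 <- propagate(w2, site = 1, times = tgrid)
  expect_equal(mean(out2$populations[, 2]),
               max_transfer_percentage(tt, dd) / 2, tolerance = 1e-4)
  # decoupled sites never exchange population
  w0 <- wire_model(c(-8, -8.2), 0)
  out0 <- propagate(w0, site = 1, times = c(0, 50, 500))
  expect_equal(out0$populations[, 1], rep(1, 3), tolerance = 1e-12)
})

test_that("invalid wire inputs are rejected", {
  expect_error(wire_model(numeric(0)), "at least one site")
  expect_error(wire_model(c(-8, -8), numeric(0)), "length")
  expect_error(propagate(wire_model(c(-8, -8), 0.1),
                         initial = c(1, 1), times = 0),
               "not normalized")
})

test_that("a stack of base pairs parameterizes the expected wire", {
  pairs <- lapply(0:2, function(k)
    transform_pair(wc_pair("G"), rotation_about_axis("z", 36 * k),
                   c(0, 0, 3.4 * k)))
  wm <- build_wire_from_dimers(pairs, orbital = "HOMO")
  expect_length(wm$model$onsite, 3L)
  # identical geometry blocks: equal on-site energies and equal hops
  expect_lt(diff(range(wm$model$onsite)), 1e-9)
  expect_lt(diff(range(abs(wm$model$hops))), 1e-9)
  gg <- transfer_integral(ideal_dimer("GG"))
  expect_equal(abs(wm$model$hops[1]), abs(gg$t), tolerance = 1e-9)
  expect_error(build_wire_from_dimers(list()), "empty")
  apart <- list(wc_pair("G"),
                transform_pair(wc_pair("G"), t = c(0, 0, 12)))
  expect_error(build_wire_from_dimers(apart), "not stacked")
})
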