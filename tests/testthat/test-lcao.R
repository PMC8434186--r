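test_that("two-center couplings reproduce hand-evaluated limits", {
  p <- lcao_params()
  # two H 1s orbitals at the reference covalent distance, Harrison regime:
  # b^2 * chi_sssigma * hbar^2/(m d^2)
  v <- slater_koster_block(c(0, 0, 0), c(1.35, 0, 0), "H", "H", p)
  expect_equal(drop(v), p$b^2 * (-1.32) * 7.6199682 / 1.35^2,
               tolerance = 1e-12)
  # heavy-heavy block along z: pz-pz is pure sigma, px-px pure pi,
  # px-py zero
  blk <- slater_koster_block(c(0, 0, 0), c(0, 0, 1.4), "C", "C", p)
  base <- 7.6199682 / 1.4^2
  expect_equal(blk[4, 4], 2.22 * base, tolerance = 1e-12)
  expect_equal(blk[2, 2], -0.73 * base, tolerance = 1e-12)
  expect_equal(blk[2, 3], 0, tolerance = 1e-15)
  # same pair along x: now px-px is the sigma channel
  blk <- slater_koster_block(c(0, 0, 0), c(1.4, 0, 0), "C", "C", p)
  expect_equal(blk[2, 2], 2.22 * base, tolerance = 1e-12)
  expect_equal(blk[4, 4], -0.73 * base, tolerance = 1e-12)
})

test_that("s-p couplings are antisymmetric so blocks transpose correctly", {
  set.seed(11)
  p <- lcao_params()
  for (k in 1:10) {
    ri <- stats::rnorm(3); rj <- ri + stats::rnorm(3)
    for (pair in list(c("C", "N"), c("H", "O"), c("N", "N"))) {
      bij <- slater_koster_block(ri, rj, pair[1], pair[2], p)
      bji <- slater_koster_block(rj, ri, pair[2], pair[1], p)
      expect_equal(bij, t(bji), tolerance = 1e-12)
    }
  }
})

test_that("couplings too short-ranged raise a geometry error", {
  p <- lcao_params()
  expect_error(slater_koster_block(c(0, 0, 0), c(0.3, 0, 0), "C", "C", p),
               "too close")
})

test_that("Harrison couplings scale exactly as 1/distance^2", {
  p <- lcao_params()
  ri <- c(0.1, -0.4, 0.7); rj <- c(1.2, 0.5, -0.3)
  b1 <- slater_koster_block(ri, rj, "C", "N", p)
  for (lambda in c(1.7, 2.5, 4)) {
    bl <- slater_koster_block(lambda * ri, lambda * rj, "C", "N", p)
    expect_equal(bl, b1 / lambda^2, tolerance = 1e-12)
  }
})

test_that("the molecular Hamiltonian has the stated structure", {
  p <- lcao_params()
  ade <- nucleobase("A")
  h <- build_hamiltonian(ade, p)
  expect_equal(dim(h$H), c(45L, 45L))
  expect_true(isSymmetric(h$H))
  onsite_sum <- sum(vapply(ade$elements, function(e)
    if (e == "H") p$onsite[["H.1s"]] else
      p$onsite[[paste0(e, ".2s")]] + 3 * p$onsite[[paste0(e, ".2p")]], 1.0))
  expect_equal(sum(diag(h$H)), onsite_sum, tolerance = 1e-10)
  # single atom: bare on-site block
  hc <- build_hamiltonian(molecule("C", matrix(0, 1, 3)), p)
  expect_equal(diag(hc$H), c(-13.18, -6.70, -6.70, -6.70))
  # multi-atom molecule without bonds warns
  expect_warning(build_hamiltonian(molecule(c("C", "C"),
                                            rbind(c(0, 0, 0), c(5, 0, 0))),
                                   p),
                 "no bonds")
})

test_that("electron filling locates the frontier orbitals", {
  sp <- solve_spectrum(build_hamiltonian(nucleobase("A")))
  expect_equal(sp$n_electrons, 50L)
  expect_equal(sp$homo, 25L)
  expect_equal(sp$lumo, 26L)
  expect_false(sp$degenerate_frontier)
  # eigenvector matrix is orthogonal
  G <- crossprod(sp$coefficients)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  # completeness: total weight of each basis orbital over all MOs is 1
  expect_lt(max(abs(rowSums(sp$coefficients^2) - 1)), 1e-8)
  # energies ascending
  expect_true(all(diff(sp$energies) >= -1e-12))
})

test_that("a two-orbital toy splits into E +/- |V|", {
  p <- lcao_params()
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                bonds = rbind(c(1, 2)))
  sp <- solve_spectrum(build_hamiltonian(m, p))
  V <- p$b^2 * p$chi[["ss_sigma"]] * p$hbar2_over_m
  E <- p$onsite[["H.1s"]]
  expect_equal(sp$energies, c(E - abs(V), E + abs(V)), tolerance = 1e-10)
})

test_that("odd-electron systems are refused", {
  m <- molecule("N", matrix(0, 1, 3))
  expect_error(solve_spectrum(build_hamiltonian(m)), "odd")
})

test_that("spectra are invariant under rigid motions", {
  set.seed(3)
  ref <- solve_spectrum(build_hamiltonian(nucleobase("G")))
  for (k in 1:10) {
    moved <- detect_bonds(transform_molecule(nucleobase("G"),
                                             random_rotation(),
                                             stats::rnorm(3, sd = 10)))
    sp <- solve_spectrum(build_hamiltonian(moved))
    expect_lt(max(abs(sp$energies - ref$energies)), 1e-8)
  }
})

test_that("the pair Hamiltonian decouples at large separation", {
  at <- wc_pair("A")
  h <- build_pair_hamiltonian(at)
  expect_equal(dim(h$H), c(87L, 87L))
  far <- base_pair(at$base1, transform_molecule(at$base2, t = c(0, -50, 0)))
  spec <- solve_pair(far)
  s1 <- solve_spectrum(build_hamiltonian(at$base1))
  s2 <- solve_spectrum(build_hamiltonian(far$base2))
  expect_equal(spec$energies, sort(c(s1$energies, s2$energies)),
               tolerance = 1e-10)
})

test_that("orbital characters follow the plane-projection definition", {
  sp <- solve_spectrum(build_hamiltonian(nucleobase("U")))
  ch <- classify_character(sp)
  # a planar molecule in the xy-plane has exact pi/sigma separation
  expect_true(all(ch$pi_weight < 1e-12 | ch$pi_weight > 1 - 1e-12))
  expect_equal(ch$character[sp$homo], "pi")
  # pi MOs of an xy-planar molecule live purely on pz
  basis <- sp$basis
  pz <- basis$orbital == "pz"
  for (k in which(ch$pi_weight > 0.5))
    expect_lt(sum(sp$coefficients[!pz, k]^2), 1e-20)
  # lone-pair flag: some occupied sigma level dominated by N/O in-plane
  expect_true(any(ch$character == "n"))
})

test_that("transition dipoles follow the point-dipole contraction", {
  # two-site toy solved in closed form: bonding/antibonding H pair
  p <- lcao_params()
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)),
                bonds = rbind(c(1, 2)))
  sp <- solve_spectrum(build_hamiltonian(m, p))
  os <- oscillator_strength(sp)
  # |d| = |r1 - r2| / 2 in e*Angstrom for (1,1)/sqrt2 -> (1,-1)/sqrt2
  expect_equal(sqrt(sum(os$dipole^2)), 0.5, tolerance = 1e-10)
  f_closed <- (2 / 3) * (os$energy / 27.211386) * (0.5 / 0.529177)^2
  expect_equal(os$f, f_closed, tolerance = 1e-12)
  # orthogonal orbitals with disjoint atomic support give zero dipole
  m3 <- molecule(c("H", "H", "H", "H"),
                 rbind(c(0, 0, 0), c(1, 0, 0),
                       c(10, 0, 0), c(11, 0, 0)),
                 bonds = rbind(c(1, 2), c(3, 4)))
  sp3 <- solve_spectrum(build_hamiltonian(m3, p))
  os3 <- oscillator_strength(sp3, from = 1, to = 4)
  pair_of <- function(k) which(abs(sp3$coefficients[, k]) > 1e-6)
  if (!length(intersect(pair_of(1), pair_of(4))))
    expect_lt(abs(os3$f), 1e-16)
  expect_error(oscillator_strength(sp3, from = 2, to = 2), "zero transition")
})

test_that("parameter validation and YAML round trip work", {
  expect_error(lcao_params(b = 1.4), "b must")
  expect_error(lcao_params(chi = c(ss_sigma = 1.3, sp_sigma = -1.4,
                                   pp_sigma = 2.2, pp_pi = -0.7)),
               "negative")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("beta: 2.0", "b: 0.65", "chi:", "  pp_pi: -0.80"), path)
  p <- read_lcao_params(path)
  expect_equal(p$beta, 2.0)
  expect_equal(p$b, 0.65)
  expect_equal(p$chi[["pp_pi"]], -0.80)
  expect_equal(p$chi[["pp_sigma"]], 2.22)
})
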