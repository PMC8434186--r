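test_that("XYZ files echo through the reader faithfully", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "methylene-like toy",
               "C 0.0 0.0 0.0", "H 1.09 0 0", "H -1.09 0 0"), path)
  m <- load_structure(path)
  expect_equal(natoms(m), 3L)
  expect_equal(chem_formula(m), "CH2")
  expect_equal(unname(m$coords[2, "x"]), 1.09)
  expect_equal(m$name, "methylene-like toy")
})

test_that("XYZ round trip preserves coordinates and element order", {
  set.seed(42)
  m <- molecule(sample(c("C", "N", "O", "H"), 12, replace = TRUE),
                matrix(stats::rnorm(36, sd = 3), 12, 3), name = "blob")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, path)
  m2 <- read_xyz(path)
  expect_identical(m2$elements, m$elements)
  expect_lt(max(abs(m2$coords - m$coords)), 1e-6)
})

test_that("unsupported elements and malformed records are rejected", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "P 0 0 0"), path)
  expect_error(read_xyz(path), "P")
  writeLines(c("2", "", "C 0 0 0", "N 1.4 zero 0"), path)
  expect_error(read_xyz(path), "line 4")
})

test_that("PDB fixed columns parse, with element fallback and residue pruning", {
  pdb_line <- function(serial, name, resn, chain, resi, xyz, elem = "") {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resn, chain, resi, xyz[1], xyz[2], xyz[3], elem)
  }
  ade <- nucleobase("A")
  lines <- c(pdb_line(1, "N9", "DA", "A", 1, ade$coords[2, ], "N"),
             # element column blank: falls back to the atom-name letter
             pdb_line(2, "C8", "DA", "A", 1, ade$coords[3, ]),
             pdb_line(3, "O4'", "DT", "B", 2, c(1, 2, 3), "O"),
             "TER", "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_pdb(path)
  expect_identical(m$elements, c("N", "C", "O"))
  expect_identical(m$labels, c("N9", "C8", "O4'"))
  expect_equal(m$coords[1, ], ade$coords[2, ], tolerance = 1e-3)
  sub <- select_residues(m, 1)
  expect_equal(natoms(sub), 2L)
  expect_identical(unique(sub$meta$resname), "DA")
})

test_that("packaged adenine has the printed formula and purine connectivity", {
  ade <- nucleobase("adenine")
  expect_equal(natoms(ade), 15L)
  expect_equal(chem_formula(ade), "C5H5N5")
  # bond count of a fused 5+6 ring system: atoms + rings - 1
  expect_equal(nrow(ade$bonds), 16L)
})

test_that("bond perception follows covalent radii and flags clashes", {
  ch <- detect_bonds(molecule(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0))))
  expect_equal(nrow(ch$bonds), 1L)
  cc <- detect_bonds(molecule(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0))))
  expect_equal(nrow(cc$bonds), 0L)
  expect_error(detect_bonds(molecule(c("C", "C"),
                                     rbind(c(0, 0, 0), c(0.2, 0, 0)))),
               "clashing")
})

test_that("bond perception is invariant under rigid motions", {
  set.seed(7)
  ade <- nucleobase("A")
  for (k in 1:20) {
    moved <- transform_molecule(ade, random_rotation(), stats::rnorm(3, sd = 8))
    expect_identical(detect_bonds(moved)$bonds, ade$bonds)
  }
})

test_that("ideal stacking is the stated rigid motion", {
  gc <- wc_pair("G")
  # pure translation at zero twist
  d0 <- build_ideal_dimer(gc, wc_pair("G"), rise = 3.4, twist = 0)
  shift <- pair_as_molecule(d0$pair2)$coords - pair_as_molecule(gc)$coords
  expect_lt(max(abs(sweep(shift, 2, c(0, 0, 3.4)))), 1e-12)
  # full turn at zero rise is the identity
  d1 <- build_ideal_dimer(gc, wc_pair("G"), rise = 0, twist = 360)
  expect_lt(max(abs(pair_as_molecule(d1$pair2)$coords -
                      pair_as_molecule(gc)$coords)), 1e-9)
  # the step is rigid: intra-pair distances preserved
  d2 <- build_ideal_dimer(gc, wc_pair("G"), rise = 3.4, twist = 36)
  expect_lt(max(abs(dist(pair_as_molecule(d2$pair2)$coords) -
                      dist(pair_as_molecule(gc)$coords))), 1e-9)
  # inverse motion restores the original coordinates
  undone <- transform_pair(transform_pair(d2$pair2, t = c(0, 0, -3.4)),
                           rotation_about_axis("z", -36))
  expect_lt(max(abs(pair_as_molecule(undone)$coords -
                      pair_as_molecule(gc)$coords)), 1e-9)
})

test_that("base-pair parameters vanish for the undistorted standard pair", {
  for (b in c("A", "T", "G", "C")) {
    pr <- wc_pair(b)
    p <- base_pair_parameters(pr$base1, pr$base2)
    expect_lt(max(abs(unlist(p))), 1e-8)
  }
})

test_that("pure displacements map to single base-pair parameters", {
  pr <- wc_pair("G")
  p <- base_pair_parameters(transform_molecule(pr$base1, t = c(0.5, 0, 0)),
                            pr$base2)
  expect_equal(p$shear, 0.5, tolerance = 1e-9)
  expect_lt(max(abs(unlist(p)[-1])), 1e-8)
  # rotation oracle: base 2 rotated about the shared y axis through its
  # frame origin by +10 degrees gives propeller -10 under our convention
  f2 <- fit_base_frame(pr$base2)
  b2 <- transform_molecule(
    transform_molecule(pr$base2, t = -f2$origin),
    rotation_about_axis("y", 10), f2$origin)
  p <- base_pair_parameters(pr$base1, b2)
  expect_equal(p$propeller, -10, tolerance = 1e-6)
  expect_lt(max(abs(unlist(p)[c("shear", "stretch", "stagger", "buckle",
                                "opening")])), 1e-6)
})

test_that("swapping the bases follows the documented symmetry table", {
  pr <- wc_pair("G")
  f2 <- fit_base_frame(pr$base2)
  b2 <- transform_molecule(
    transform_molecule(pr$base2, t = -f2$origin),
    rotation_about_axis("x", 7) %*% rotation_about_axis("z", 4),
    f2$origin + c(0.3, 0.2, 0.25))
  p12 <- unlist(base_pair_parameters(pr$base1, b2))
  p21 <- unlist(base_pair_parameters(b2, pr$base1))
  flip <- c("shear", "buckle")
  keep <- c("stretch", "stagger", "propeller", "opening")
  expect_equal(p21[flip], -p12[flip], tolerance = 1e-9)
  expect_equal(p21[keep], p12[keep], tolerance = 1e-9)
})

test_that("degenerate frame-defining atoms raise a frame error", {
  line <- molecule(rep(c("N", "C"), 3),
                   cbind(seq(0, 5), 0, 0),
                   labels = c("N1", "C2", "N3", "C4", "C5", "C6"))
  line$labels <- c("N1", "C2", "N3", "C4", "C5", "C6")
  expect_error(fit_base_frame(line, base = "C"), "collinear|degenerate")
})
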