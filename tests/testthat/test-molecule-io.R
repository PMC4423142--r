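test_that("molecule constructor enforces its invariants", {
  expect_error(molecule("m", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        bonds = cbind(1L, 1L, 1L)), "self-bond")
  expect_error(molecule("m", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        bonds = rbind(c(1L, 2L, 1L), c(2L, 1L, 1L))),
               "duplicate bond")
  expect_error(molecule("m", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        bonds = cbind(1L, 3L, 1L)), "out of range")
  expect_error(molecule("m", c("C", "Xx"), rbind(c(0, 0, 0), c(1, 0, 0))),
               "Xx")
  expect_error(molecule("m", "C", matrix(c(0, 0, NA), 1)), "non-finite")
})

test_that("read_sdf parses V2000 records and flags 2D structures", {
  methane <- c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(methane, f)
  mols <- read_sdf(f)
  expect_length(mols, 1L)
  expect_equal(n_atoms(mols[[1]]), 5L)
  expect_equal(nrow(mols[[1]]$bonds), 4L)
  expect_equal(mols[[1]]$elements, c("C", "H", "H", "H", "H"))
  expect_length(mols[[1]]$flags, 0L)

  # empty file -> empty list
  writeLines(character(), f)
  expect_length(read_sdf(f), 0L)

  # bond index 0 -> parse error (V2000 is 1-based)
  bad <- methane
  bad[10] <- "  0  2  1  0"
  writeLines(bad, f)
  expect_error(read_sdf(f), "1-based")

  # malformed counts line names the record
  bad2 <- methane
  bad2[4] <- " xx yy  0  0"
  writeLines(bad2, f)
  expect_error(read_sdf(f), "record 1")

  # all-zero z coordinates -> 2d_only flag
  flat <- c("flat", "", "",
            "  2  1  0  0  0  0  0  0  0  0999 V2000",
            "    0.0000    0.0000    0.0000 C   0  0",
            "    1.5000    0.0000    0.0000 C   0  0",
            "  1  2  1  0", "M  END", "$$$$")
  writeLines(flat, f)
  expect_true("2d_only" %in% read_sdf(f)[[1]]$flags)
})

test_that("SDF write/read round trip preserves the molecule", {
  m <- make_point_cloud_molecule(7, seed = 42)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, f)
  back <- read_sdf(f)[[1]]
  expect_equal(back$elements, m$elements)
  expect_equal(back$coords, m$coords, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(back$bonds[, 1:2], m$bonds[, 1:2], ignore_attr = TRUE)
  # multi-record files round trip record by record
  m2 <- make_point_cloud_molecule(4, seed = 43)
  write_sdf(list(m, m2), f)
  expect_length(read_sdf(f), 2L)
})

test_that("read_xyz parses counts, elements and scientific notation", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "a diatomic", "C 0.0 0.0 0.0", "O 1.128 0.0 0.0"), f)
  m <- read_xyz(f)
  expect_equal(n_atoms(m), 2L)
  expect_equal(nrow(m$bonds), 0L)
  expect_equal(m$elements, c("C", "O"))

  writeLines(c("5", "", "C 0 0 0", "H 1 0 0", "H 0 1 0", "H 0 0 1"), f)
  expect_error(read_xyz(f), "count")

  writeLines(c("2", "sci", "C 0.0e0 0 0", "O 1.128e+00 0.0 0.0"), f)
  expect_equal(geom_distance_matrix(read_xyz(f))[1, 2], 1.128)
})

test_that("perceive_bonds connects pairs within the covalent-radius rule", {
  m <- molecule("tri", c("C", "C", "C"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 0, 0)))
  b <- perceive_bonds(m)
  expect_equal(nrow(b$bonds), 1L)      # only the 1.5 A pair bonds
  expect_equal(unname(b$bonds[1, 1:2]), c(1L, 2L))
  # scale is overridable
  b2 <- perceive_bonds(m, scale = 4)
  expect_gt(nrow(b2$bonds), 1L)
})
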