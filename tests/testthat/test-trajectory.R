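test_that("minimum_image_distance handles wrapping and identity", {
  expect_equal(minimum_image_distance(c(0.1, 0, 0), c(5.9, 0, 0),
                                      c(6, 6, 6)), 0.2)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3),
                                      c(6, 6, 6)), 0)
  # symmetry
  p <- c(0.3, 5.7, 2.2); q <- c(5.5, 0.4, 3.1)
  expect_equal(minimum_image_distance(p, q, c(6, 6, 6)),
               minimum_image_distance(q, p, c(6, 6, 6)))
})

test_that("minimum_image_distance matches the 27-image brute force", {
  set.seed(41)
  for (i in 1:500) {
    box <- runif(3, 2, 9)
    p <- runif(3, 0, box); q <- runif(3, 0, box)
    expect_lt(abs(minimum_image_distance(p, q, box) -
                    oracle_min_image(p, q, box)), 1e-12)
  }
})

test_that("lattice translations leave minimum-image distances unchanged", {
  set.seed(42)
  box <- c(4, 5, 6)
  for (i in 1:50) {
    p <- runif(3, 0, box); q <- runif(3, 0, box)
    shift <- sample(-3:3, 3, replace = TRUE) * box
    expect_equal(minimum_image_distance(p + shift, q + shift, box),
                 minimum_image_distance(p, q, box), tolerance = 1e-12)
    expect_equal(minimum_image_distance(p, q + shift, box),
                 minimum_image_distance(p, q, box), tolerance = 1e-12)
  }
})

make_diatomic <- function(x1, x2, box = c(6, 6, 6)) {
  atoms <- data.frame(
    atom_id = 0:1, name = c("A", "B"), element = "C", mass = c(12, 12),
    residue_label = "MOL", residue_index = 1L, molecule_id = 0L,
    donor = FALSE, polar_h = FALSE, acceptor = FALSE,
    donor_of = NA_integer_, stringsAsFactors = FALSE)
  top <- asd_topology(atoms, data.frame(molecule_id = 0L, kind = "drug"))
  fr <- list(time = 0, box = box,
             positions = rbind(x1, x2, deparse.level = 0))
  list(top = top, fr = fr)
}

test_that("unwrap_molecule rejoins split molecules and is idempotent", {
  s <- make_diatomic(c(5.95, 1, 1), c(0.05, 1, 1))
  out <- unwrap_molecule(s$fr, s$top, 0L)
  expect_equal(out[2, 1], 6.05)
  # already-whole molecule is untouched
  s2 <- make_diatomic(c(2.0, 1, 1), c(2.1, 1, 1))
  expect_equal(unwrap_molecule(s2$fr, s2$top, 0L), s2$fr$positions)
})

test_that("unwrapped rigid bodies recover generator intra distances", {
  tmpl <- build_drug_template()
  true_d <- as.matrix(dist(tmpl$rel_pos))
  sim <- simulate_asd(generator_config(seed = 9, n_drug = 6,
                                       n_frames = 3, n_protein = 0,
                                       drug_D = 1.0))
  tr <- sim$trajectory
  for (m in molecules_of_kind(tr$topology, "drug")) {
    pos <- unwrap_molecule(get_frame(tr, 2), tr$topology, m)
    expect_equal(as.matrix(dist(pos)), true_d, ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("center_of_mass: midpoint, single atom, split water", {
  s <- make_diatomic(c(0, 0, 0) + 1, c(1, 0, 0) + 1)
  expect_equal(center_of_mass(s$fr, s$top, 0L), c(1.5, 1, 1))
  # straddling the boundary: unwrap first, COM near the heavy atom
  atoms <- data.frame(
    atom_id = 0:2, name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    mass = c(16, 1, 1), residue_label = "SOL", residue_index = 1L,
    molecule_id = 0L, donor = c(TRUE, FALSE, FALSE),
    polar_h = c(FALSE, TRUE, TRUE), acceptor = c(TRUE, FALSE, FALSE),
    donor_of = c(NA_integer_, 0L, 0L), stringsAsFactors = FALSE)
  top <- asd_topology(atoms, data.frame(molecule_id = 0L, kind = "water"))
  fr <- list(time = 0, box = c(6, 6, 6),
             positions = rbind(c(0.02, 1, 1), c(5.95, 1.05, 1),
                               c(0.09, 0.95, 1)))
  pos <- unwrap_molecule(fr, top, 0L)
  com <- center_of_mass(fr, top, 0L, positions = pos)
  expect_lt(sqrt(sum((com - pos[1, ])^2)), 0.1)
  # unwhole molecule errors
  expect_error(center_of_mass(fr, top, 0L), "not whole")
})

test_that("extxyz round trip preserves frames, times and positions", {
  sim <- make_two_layer_fixture(3, 2, seed = 5, n_frames = 2)
  f <- withr::local_tempfile(fileext = ".extxyz")
  write_trajectory(sim$trajectory, f, "extxyz")
  tr <- read_trajectory(f, "extxyz", sim$trajectory$topology)
  expect_equal(n_frames(tr), 2)
  expect_equal(tr$times, c(0, 10))
  expect_equal(tr$coords, sim$trajectory$coords, tolerance = 1e-7)
  # second write is byte-identical (round-trip identity mod formatting)
  f2 <- withr::local_tempfile(fileext = ".extxyz")
  write_trajectory(tr, f2, "extxyz")
  expect_identical(readLines(f), readLines(f2))
})

test_that("gro round trip preserves positions to printed precision", {
  sim <- make_two_layer_fixture(2, 2, seed = 6, n_frames = 3)
  f <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(sim$trajectory, f, "gro_series")
  tr <- read_trajectory(f, "gro_series", sim$trajectory$topology)
  expect_equal(tr$coords, sim$trajectory$coords, tolerance = 5.1e-4)
})

test_that("parse errors name the offending frame", {
  sim <- make_two_layer_fixture(2, 0, seed = 6, n_frames = 4)
  f <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(sim$trajectory, f, "gro_series")
  lines <- readLines(f)
  flen <- n_atoms(sim$trajectory$topology) + 3L
  truncated <- lines[seq_len(3 * flen + flen %/% 2)]  # frame 4 cut mid-block
  writeLines(truncated, f)
  expect_error(read_trajectory(f, "gro_series"), "frame 4")
  # malformed title
  writeLines(sub("t=", "x=", lines), f)
  expect_error(read_trajectory(f, "gro_series"), "t=")
})

test_that("topology sidecar round trip is lossless", {
  sim <- simulate_asd(generator_config(seed = 2, n_drug = 3, n_water = 2,
                                       n_frames = 2))
  top <- sim$trajectory$topology
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology(top, f)
  top2 <- read_topology(f)
  expect_equal(top2$atoms, top$atoms)
  expect_equal(top2$molecules, top$molecules)
})

test_that("resolve_window handles last:N, ranges and bad input", {
  tr <- ballistic_trajectory(nf = 20)
  expect_equal(resolve_window(tr, "last:5"), 16:20)
  expect_equal(resolve_window(tr, c(3L, 7L)), 3:7)
  expect_equal(resolve_window(tr, NULL), 1:20)
  expect_error(resolve_window(tr, 0L), "outside")
  expect_error(resolve_window(tr, "last:x"), "last:N")
})
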