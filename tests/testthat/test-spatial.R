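test_that("min_distance_to_protein: direct construction and PBC", {
  fx <- make_two_layer_fixture(1, 0, seed = 9)
  tr <- fx$trajectory
  fr <- get_frame(tr, 1)
  m <- molecules_of_kind(tr$topology, "drug")[1]
  # brute-force over all protein atoms and 27 images
  prot <- which(tr$topology$atoms$molecule_id == 0)
  pos <- unwrap_molecule(fr, tr$topology, m)
  com <- center_of_mass(fr, tr$topology, m, positions = pos)
  brute <- min(vapply(prot, function(i)
    oracle_min_image(com, fr$positions[i, ], fr$box), numeric(1)))
  expect_equal(min_distance_to_protein(fr, tr$topology, m, "com"), brute,
               tolerance = 1e-12)
  brute_atom <- min(apply(pos, 1, function(p)
    min(vapply(prot, function(i)
      oracle_min_image(p, fr$positions[i, ], fr$box), numeric(1)))))
  expect_equal(min_distance_to_protein(fr, tr$topology, m, "atom"),
               brute_atom, tolerance = 1e-12)
})

test_that("atom-mode distance obeys the COM triangle bound", {
  tmpl <- build_drug_template()
  com_rel <- colSums(tmpl$rel_pos * tmpl$masses) / sum(tmpl$masses)
  max_off <- max(sqrt(rowSums(sweep(tmpl$rel_pos, 2, com_rel)^2)))
  for (s in 1:10) {
    fx <- make_two_layer_fixture(3, 3, seed = s, n_frames = 1)
    st <- shell_table(fx$trajectory)
    expect_true(all(st$min_dist_atom <= st$min_dist_com + max_off + 1e-9))
    expect_true(all(st$min_dist_com <= st$min_dist_atom + max_off + 1e-9))
  }
})

test_that("shell table: index arithmetic and contact flag", {
  fx <- make_two_layer_fixture(5, 5, seed = 4)
  st <- shell_table(fx$trajectory)
  expect_equal(st$shell_index, as.integer(floor(st$min_dist_atom / 0.4)))
  expect_equal(st$fds_flag, st$min_dist_atom <= 0.4)
  # each (molecule, frame) sample appears exactly once
  expect_equal(nrow(st), 10 * n_frames(fx$trajectory))
  expect_false(any(duplicated(st[, c("molecule_id", "frame")])))
})

test_that("distance histogram: fractions sum to 1; planted structure", {
  fx <- make_two_layer_fixture(10, 0, seed = 2)
  h <- distance_histogram(fx$trajectory)
  expect_equal(sum(h$fraction), 1)
  expect_equal(sum(h$fraction[h$bin_lo >= 0.45]), 0)
  # empty drug set: empty histogram, no error
  fx0 <- make_two_layer_fixture(0, 0, seed = 2)
  h0 <- distance_histogram(fx0$trajectory)
  expect_equal(nrow(h0), 0L)
})

test_that("second_layer_fraction recovers planted fractions exactly", {
  cases <- list(c(10, 0), c(15, 5), c(10, 10), c(0, 10))
  for (cs in cases) {
    fx <- make_two_layer_fixture(cs[1], cs[2], seed = sum(cs) + 1)
    st <- shell_table(fx$trajectory)
    expect_equal(second_layer_fraction(st), fx$truth$planted_fraction)
  }
})

test_that("second_layer_fraction is monotone under added bulk molecules", {
  base <- make_two_layer_fixture(8, 4, seed = 3)
  more <- make_two_layer_fixture(8, 5, seed = 3)
  f1 <- second_layer_fraction(shell_table(base$trajectory))
  f2 <- second_layer_fraction(shell_table(more$trajectory))
  expect_gte(f2, f1)
})

test_that("rdf: spike for a fixed pair, nonnegativity, r_max guard", {
  atoms <- data.frame(
    atom_id = 0:1, name = "X", element = "C", mass = 12,
    residue_label = "MOL", residue_index = 1:2, molecule_id = 0:1,
    donor = FALSE, polar_h = FALSE, acceptor = FALSE,
    donor_of = NA_integer_, stringsAsFactors = FALSE)
  top <- asd_topology(atoms, data.frame(molecule_id = 0:1, kind = "drug"))
  co <- array(0, c(2, 3, 1))
  co[1, , 1] <- c(1, 1, 1); co[2, , 1] <- c(1.5, 1, 1)
  tr <- asd_trajectory(top, co, 0, c(6, 6, 6))
  g <- rdf(tr, 0L, 1L, r_max = 2, bin_width = 0.05)
  expect_true(all(g$g >= 0))
  peak <- g$r[which.max(g$g)]
  expect_equal(peak, 0.525)  # 0.5 nm falls in bin [0.50, 0.55)
  expect_equal(sum(g$g > 0), 1L)
  expect_error(rdf(tr, 0L, 1L, r_max = 4), "half")
})

test_that("rdf of uniform points is flat at 1", {
  set.seed(5)
  n <- 400; nf <- 30; L <- 5
  atoms <- data.frame(
    atom_id = 0:(n - 1), name = "X", element = "C", mass = 12,
    residue_label = "GAS", residue_index = seq_len(n),
    molecule_id = 0:(n - 1), donor = FALSE, polar_h = FALSE,
    acceptor = FALSE, donor_of = NA_integer_, stringsAsFactors = FALSE)
  top <- asd_topology(atoms,
                      data.frame(molecule_id = 0:(n - 1), kind = "drug"))
  co <- array(runif(n * 3 * nf, 0, L), c(n, 3, nf))
  tr <- asd_trajectory(top, co, seq_len(nf), rep(L, 3))
  g <- rdf(tr, 0:(n - 1), 0:(n - 1), r_max = 2.4, bin_width = 0.05)
  expect_true(all(abs(g$g[g$r > 0.5] - 1) < 0.02))
})
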