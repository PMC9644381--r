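# geometry fixture: one donor-H on molecule 0, one acceptor on molecule 1
two_molecule_frame <- function(D, H, A, box = c(6, 6, 6)) {
  atoms <- data.frame(
    atom_id = 0:2, name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
    mass = c(16, 1, 16), residue_label = c("GLU", "GLU", "IND"),
    residue_index = c(1L, 1L, 2L), molecule_id = c(0L, 0L, 1L),
    donor = c(TRUE, FALSE, FALSE), polar_h = c(FALSE, TRUE, FALSE),
    acceptor = c(FALSE, FALSE, TRUE), donor_of = c(NA_integer_, 0L, NA),
    stringsAsFactors = FALSE)
  top <- asd_topology(atoms, data.frame(molecule_id = 0:1,
                                        kind = c("protein", "drug")))
  list(top = top,
       frame = list(time = 0, box = box, positions = rbind(D, H, A)))
}

test_that("criterion boundaries: distance and angle, both conventions", {
  # collinear D-H...A at 0.30 nm: detected under both conventions
  s <- two_molecule_frame(c(1, 1, 1), c(1.1, 1, 1), c(1.3, 1, 1))
  expect_equal(nrow(detect_hbonds_frame(s$frame, s$top)), 1L)
  expect_equal(nrow(detect_hbonds_frame(s$frame, s$top,
                                        vertex = "hydrogen")), 1L)
  # just past the distance cutoff
  s2 <- two_molecule_frame(c(1, 1, 1), c(1.1, 1, 1), c(1.351, 1, 1))
  expect_equal(nrow(detect_hbonds_frame(s2$frame, s2$top)), 0L)
  # 35-degree H-D-A angle: rejected at the donor vertex
  ang <- 35 * pi / 180
  s3 <- two_molecule_frame(c(1, 1, 1),
                           c(1 + 0.1 * cos(ang), 1 + 0.1 * sin(ang), 1),
                           c(1.3, 1, 1))
  expect_equal(nrow(detect_hbonds_frame(s3$frame, s3$top)), 0L)
  # 25 degrees: accepted
  ang <- 25 * pi / 180
  s4 <- two_molecule_frame(c(1, 1, 1),
                           c(1 + 0.1 * cos(ang), 1 + 0.1 * sin(ang), 1),
                           c(1.3, 1, 1))
  expect_equal(nrow(detect_hbonds_frame(s4$frame, s4$top)), 1L)
  # detection across the periodic boundary
  s5 <- two_molecule_frame(c(0.05, 1, 1), c(5.95, 1, 1), c(5.80, 1, 1))
  expect_equal(nrow(detect_hbonds_frame(s5$frame, s5$top)), 1L)
})

test_that("detection matches the brute-force oracle on random frames", {
  set.seed(7)
  for (i in 1:60) {
    sys <- random_hbond_system(50)
    for (vx in c("donor", "hydrogen")) {
      got <- detect_hbonds_frame(sys$frame, sys$topology, vertex = vx)
      expect_identical(hbond_keys(got),
                       oracle_hbonds(sys$frame, sys$topology, vertex = vx))
    }
  }
})

test_that("existence matrix: permanent bond, column-sum consistency", {
  ch <- make_chain_fixture(2, seed = 3)
  hm <- build_existence_matrix(ch$trajectory)
  expect_equal(nrow(hm$triples), 2L)
  expect_true(all(hm$occupancy))
  # per-frame column sums equal frame-wise detection counts
  for (f in seq_len(n_frames(ch$trajectory))) {
    det <- detect_hbonds_frame(get_frame(ch$trajectory, f),
                               ch$trajectory$topology)
    expect_equal(sum(hm$occupancy[, f]), nrow(det))
  }
  expect_error(build_existence_matrix(ch$trajectory, integer(0)), "empty")
})

test_that("stability thresholds are strict and class-specific", {
  nf <- 100L
  hm <- manual_hbond_matrix(
    occupancies = c(0.80, 0.80 + 1 / nf, 0.50, 0.50 + 1 / nf,
                    0.50 + 1 / nf, 0),
    pair_classes = c("protein-drug", "protein-drug", "drug-drug",
                     "drug-drug", "protein-protein", "drug-drug"),
    n_frames = nf)
  st <- classify_stable(hm)
  expect_equal(st$donor_atom_id, c(2L, 4L, 5L))
  # all-zero matrix gives the empty set
  hm0 <- manual_hbond_matrix(0, "drug-drug", nf)
  expect_equal(nrow(classify_stable(hm0)), 0L)
})

test_that("stability classification is monotone and order-invariant", {
  nf <- 50L
  occ <- seq(0, 1, length.out = 11)
  hm <- manual_hbond_matrix(occ, rep("drug-drug", 11), nf)
  st <- sort(classify_stable(hm)$occupancy)
  expect_true(all(st > 0.5))
  expect_equal(sum(occ > 0.5), length(st))
  # permuting frames leaves occupancy means, hence stability, unchanged
  perm <- sample(nf)
  hm2 <- hm
  hm2$occupancy <- hm$occupancy[, perm]
  hm2$occupancy_mean <- rowMeans(hm2$occupancy)
  expect_equal(classify_stable(hm2), classify_stable(hm))
})

test_that("generation tracing: chain, shortest-path tie, oracle equality", {
  # chain protein - d1 - d2 - d3
  top <- graph_topology(4, protein_ids = 0)
  bonds <- data.frame(donor_molecule_id = c(1L, 2L, 3L),
                      acceptor_molecule_id = c(0L, 1L, 2L),
                      pair_class = c("protein-drug", "drug-drug",
                                     "drug-drug"))
  gen <- assign_generations(bonds, top)
  expect_equal(gen$generation, c(1L, 2L, 3L))
  # bonded to protein AND to a gen-1 drug: shortest path wins
  bonds2 <- rbind(bonds, data.frame(donor_molecule_id = 2L,
                                    acceptor_molecule_id = 0L,
                                    pair_class = "protein-drug"))
  gen2 <- assign_generations(bonds2, top)
  expect_equal(gen2$generation[gen2$molecule_id == 2], 1L)
  # max_generation cap
  gen3 <- assign_generations(bonds, top, max_generation = 2)
  expect_true(is.na(gen3$generation[gen3$molecule_id == 3]))
})

test_that("generation tracing matches the igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:100, 1)
    n_prot <- sample(1:3, 1)
    top <- graph_topology(n, protein_ids = 0:(n_prot - 1))
    n_edges <- sample(0:(2 * n), 1)
    bonds <- data.frame(
      donor_molecule_id = sample(0:(n - 1), n_edges, replace = TRUE),
      acceptor_molecule_id = sample(0:(n - 1), n_edges, replace = TRUE))
    bonds <- bonds[bonds$donor_molecule_id != bonds$acceptor_molecule_id, ]
    bonds$pair_class <- "any"
    gen <- assign_generations(bonds, top)
    expect_identical(gen$generation, oracle_generations(bonds, top))
  }
})

test_that("removing a stable bond never decreases any generation", {
  set.seed(19)
  top <- graph_topology(30, protein_ids = 0)
  bonds <- data.frame(
    donor_molecule_id = sample(0:29, 60, replace = TRUE),
    acceptor_molecule_id = sample(0:29, 60, replace = TRUE))
  bonds <- bonds[bonds$donor_molecule_id != bonds$acceptor_molecule_id, ]
  bonds$pair_class <- "any"
  base <- assign_generations(bonds, top)$generation
  base[is.na(base)] <- .Machine$integer.max
  for (drop in sample(nrow(bonds), 10)) {
    red <- assign_generations(bonds[-drop, ], top)$generation
    red[is.na(red)] <- .Machine$integer.max
    expect_true(all(red >= base))
  }
})

test_that("residue ranking: fractions, major flag, alphabetical order", {
  ch <- make_chain_fixture(1, seed = 5)
  top <- ch$trajectory$topology
  # synthetic triple tables against hand arithmetic
  drug_donor <- top$atoms$atom_id[top$atoms$molecule_id == 1 &
                                    top$atoms$donor][1]
  drug_h <- top$atoms$atom_id[top$atoms$molecule_id == 1 &
                                top$atoms$polar_h][1]
  mk <- function(labels) {
    prot_atoms <- top$atoms[top$atoms$molecule_id == 0 &
                              !top$atoms$polar_h, ]
    # pick protein acceptor atoms carrying each requested label
    idx <- unlist(lapply(unique(labels), function(l) {
      cand <- prot_atoms$atom_id[prot_atoms$residue_label == l]
      rep_len(cand, sum(labels == l))
    }))
    data.frame(donor_atom_id = drug_donor, hydrogen_atom_id = drug_h,
               acceptor_atom_id = idx,
               donor_molecule_id = 1L, acceptor_molecule_id = 0L,
               pair_class = "protein-drug")
  }
  r1 <- rank_residues(mk(rep("GLU", 10)), top)
  expect_equal(r1$fraction, 1)
  expect_true(r1$major)
  r2 <- rank_residues(mk(c(rep("GLU", 6), rep("ASP", 4))), top)
  expect_equal(r2$residue_label, c("ASP", "GLU"))  # alphabetical
  expect_equal(r2$fraction, c(0.4, 0.6))
  expect_true(all(r2$major))
  expect_equal(sum(r2$fraction), 1, tolerance = 1e-12)
})

test_that("planted palette bonds are recovered through the full stack", {
  ch <- make_chain_fixture(3, n_free = 1, seed = 11)
  hm <- build_existence_matrix(ch$trajectory)
  st <- classify_stable(hm)
  gen <- assign_generations(st, ch$trajectory$topology)
  truth <- ch$truth$generation
  got <- gen$generation[match(as.integer(names(truth)), gen$molecule_id)]
  expect_equal(got, unname(as.integer(truth)))
  rr <- rank_residues(hm, ch$trajectory$topology)
  expect_equal(nrow(rr), 1L)  # single protein-drug bond, one residue
  expect_equal(rr$fraction, 1)
})
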