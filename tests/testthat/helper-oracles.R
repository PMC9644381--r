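# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's vectorized geometry helpers:
# distances come from explicit enumeration of all 27 periodic image
# translations, angles from acos on raw dot products.

# brute-force minimum-image distance over all 27 image translations
oracle_min_image <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    qq <- q + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((p - qq)^2)))
  }
  best
}

# nearest periodic image of q relative to p (27-image enumeration)
oracle_nearest_image <- function(p, q, box) {
  best <- Inf; arg <- q
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    qq <- q + c(ix, iy, iz) * box
    d <- sqrt(sum((p - qq)^2))
    if (d < best) { best <- d; arg <- qq }
  }
  arg
}

# O(N^2) brute-force hydrogen-bond detection with the same criterion
oracle_hbonds <- function(frame, topology, d_cut = 0.35, angle_cut = 30,
                          vertex = "donor") {
  a <- topology$atoms
  dh <- donor_hydrogen_pairs(topology)
  acc <- a$atom_id[a$acceptor]
  found <- list()
  for (i in seq_len(nrow(dh))) {
    d_row <- match(dh[i, 1], a$atom_id)
    h_row <- match(dh[i, 2], a$atom_id)
    D <- frame$positions[d_row, ]
    H <- oracle_nearest_image(D, frame$positions[h_row, ], frame$box)
    for (j in seq_along(acc)) {
      a_row <- match(acc[j], a$atom_id)
      if (a$molecule_id[a_row] == a$molecule_id[d_row]) next
      if (acc[j] == dh[i, 1]) next
      A <- oracle_nearest_image(D, frame$positions[a_row, ], frame$box)
      if (sqrt(sum((D - A)^2)) > d_cut) next
      if (vertex == "donor") {
        v1 <- H - D; v2 <- A - D
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang > angle_cut + 1e-9) next
      } else {
        A_h <- oracle_nearest_image(H, frame$positions[a_row, ],
                                    frame$box)
        v1 <- D - H; v2 <- A_h - H
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < 180 - angle_cut - 1e-9) next
      }
      found[[length(found) + 1L]] <-
        c(dh[i, 1], dh[i, 2], acc[j])
    }
  }
  if (!length(found)) return(character(0))
  sort(vapply(found, paste, character(1), collapse = "-"))
}

hbond_keys <- function(tab) {
  sort(paste(tab$donor_atom_id, tab$hydrogen_atom_id,
             tab$acceptor_atom_id, sep = "-"))
}

# random wrapped frame + topology with donor/H/acceptor annotations,
# ~n_atoms atoms split into small molecules
random_hbond_system <- function(n_atoms = 50, box = c(3, 3, 3)) {
  n_mol <- max(2L, n_atoms %/% 5L)
  mol_of <- sort(sample(n_mol, n_atoms, replace = TRUE)) - 1L
  n <- length(mol_of)
  role <- sample(c("donor", "acceptor", "none"), n, replace = TRUE,
                 prob = c(0.3, 0.4, 0.3))
  atoms <- data.frame(
    atom_id = seq_len(n) - 1L, name = "X", element = "O", mass = 16,
    residue_label = "RES", residue_index = mol_of + 1L,
    molecule_id = mol_of,
    donor = role == "donor", polar_h = FALSE, acceptor = role == "acceptor",
    donor_of = NA_integer_, stringsAsFactors = FALSE)
  # attach one hydrogen per donor
  don <- atoms$atom_id[atoms$donor]
  if (length(don)) {
    h <- data.frame(
      atom_id = n - 1L + seq_along(don), name = "H", element = "H",
      mass = 1, residue_label = "RES",
      residue_index = atoms$residue_index[match(don, atoms$atom_id)],
      molecule_id = atoms$molecule_id[match(don, atoms$atom_id)],
      donor = FALSE, polar_h = TRUE, acceptor = FALSE, donor_of = don,
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, h)
  }
  mols <- data.frame(molecule_id = 0:(n_mol - 1L),
                     kind = sample(c("protein", "drug"), n_mol,
                                   replace = TRUE))
  mols <- mols[mols$molecule_id %in% atoms$molecule_id, , drop = FALSE]
  top <- asd_topology(atoms, mols)
  pos <- matrix(runif(3 * nrow(atoms), 0, box[1]), ncol = 3)
  # hydrogens near their donors so angles are well defined
  hs <- which(atoms$polar_h)
  for (i in hs) {
    d_row <- match(atoms$donor_of[i], atoms$atom_id)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pos[i, ] <- (pos[d_row, ] + 0.1 * u) %% box
  }
  list(topology = top,
       frame = list(time = 0, box = box, positions = pos))
}

# igraph shortest-path oracle for generation tracing
oracle_generations <- function(stable_bonds, topology) {
  skip_if_not_installed("igraph")
  mol <- topology$molecules
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(stable_bonds$donor_molecule_id),
               to = as.character(stable_bonds$acceptor_molecule_id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(mol$molecule_id)))
  prot <- as.character(mol$molecule_id[mol$kind == "protein"])
  non_prot <- mol$molecule_id[mol$kind != "protein"]
  if (!length(prot))
    return(rep(NA_integer_, length(non_prot)))
  d <- igraph::distances(g, v = as.character(non_prot), to = prot)
  gen <- apply(d, 1, min)
  gen[!is.finite(gen)] <- NA
  as.integer(gen)
}

# single-molecule topology helper for graph-level tests
graph_topology <- function(n_mol, protein_ids) {
  atoms <- data.frame(
    atom_id = 0:(n_mol - 1L), name = "X", element = "C", mass = 12,
    residue_label = "MOL", residue_index = 1:n_mol,
    molecule_id = 0:(n_mol - 1L), donor = FALSE, polar_h = FALSE,
    acceptor = FALSE, donor_of = NA_integer_, stringsAsFactors = FALSE)
  mols <- data.frame(molecule_id = 0:(n_mol - 1L),
                     kind = ifelse(0:(n_mol - 1L) %in% protein_ids,
                                   "protein", "drug"))
  asd_topology(atoms, mols)
}

# hand-built existence matrix for threshold-semantics tests
manual_hbond_matrix <- function(occupancies, pair_classes, n_frames) {
  n <- length(occupancies)
  triples <- data.frame(
    donor_atom_id = seq_len(n), hydrogen_atom_id = 100L + seq_len(n),
    acceptor_atom_id = 200L + seq_len(n),
    donor_molecule_id = seq_len(n),
    acceptor_molecule_id = 100L + seq_len(n),
    pair_class = pair_classes, stringsAsFactors = FALSE)
  occ <- t(vapply(occupancies, function(p) {
    k <- round(p * n_frames)
    c(rep(TRUE, k), rep(FALSE, n_frames - k))
  }, logical(n_frames)))
  structure(list(triples = triples, occupancy = occ,
                 frame_times = seq_len(n_frames),
                 occupancy_mean = rowMeans(occ),
                 params = list(d_cut = 0.35, angle_cut = 30,
                               vertex = "donor")),
            class = "asd_hbond_matrix")
}

# simple linear-motion trajectory: one molecule, constant velocity v nm/ps
ballistic_trajectory <- function(v = c(0.01, 0, 0), nf = 100, dt = 1,
                                 box = c(50, 50, 50)) {
  atoms <- data.frame(
    atom_id = 0L, name = "X", element = "C", mass = 12,
    residue_label = "MOL", residue_index = 1L, molecule_id = 0L,
    donor = FALSE, polar_h = FALSE, acceptor = FALSE,
    donor_of = NA_integer_, stringsAsFactors = FALSE)
  top <- asd_topology(atoms, data.frame(molecule_id = 0L, kind = "drug"))
  tvec <- (seq_len(nf) - 1) * dt
  co <- array(NA_real_, c(1, 3, nf))
  for (f in seq_len(nf)) co[1, , f] <- box / 2 + v * tvec[f]
  asd_trajectory(top, co, tvec, box, wrapped = FALSE)
}

# vectorized brute-force oracle: enumerates all 27 image translations
# explicitly (no round()-based minimum-image), acos angles; used for the
# large acceptance batch where the triple-loop oracle would be too slow
oracle_hbonds_fast <- function(frame, topology, d_cut = 0.35,
                               angle_cut = 30, vertex = "donor") {
  a <- topology$atoms
  dh <- donor_hydrogen_pairs(topology)
  acc <- a$atom_id[a$acceptor]
  box <- frame$box
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(box)
  nd <- nrow(dh); na <- length(acc)
  if (!nd || !na) return(character(0))
  d_rows <- match(dh[, 1], a$atom_id)
  h_rows <- match(dh[, 2], a$atom_id)
  a_rows <- match(acc, a$atom_id)
  D <- frame$positions[d_rows, , drop = FALSE]
  Hw <- frame$positions[h_rows, , drop = FALSE]
  A <- frame$positions[a_rows, , drop = FALSE]
  # donor-acceptor: running minimum over the 27 enumerated translations
  best2 <- matrix(Inf, nd, na)
  best_s <- matrix(1L, nd, na)
  # hydrogen nearest image w.r.t. its donor, same enumeration
  h2 <- matrix(Inf, nd, 27)
  for (s in seq_len(27)) {
    m <- outer(D[, 1], A[, 1] + shifts[s, 1], "-")^2 +
      outer(D[, 2], A[, 2] + shifts[s, 2], "-")^2 +
      outer(D[, 3], A[, 3] + shifts[s, 3], "-")^2
    upd <- m < best2
    best2[upd] <- m[upd]
    best_s[upd] <- s
    h2[, s] <- rowSums((Hw + matrix(shifts[s, ], nd, 3, byrow = TRUE) -
                          D)^2)
  }
  h_best <- max.col(-h2, ties.method = "first")
  H <- Hw + shifts[h_best, , drop = FALSE]
  cand <- which(sqrt(best2) <= d_cut &
                  outer(a$molecule_id[d_rows], a$molecule_id[a_rows],
                        "!=") &
                  outer(dh[, 1], acc, "!="), arr.ind = TRUE)
  if (!nrow(cand)) return(character(0))
  di <- cand[, 1]; ai <- cand[, 2]
  sb <- best_s[cand]
  Ab <- A[ai, , drop = FALSE] + shifts[sb, , drop = FALSE]
  if (vertex == "donor") {
    v1 <- H[di, , drop = FALSE] - D[di, , drop = FALSE]
    v2 <- Ab - D[di, , drop = FALSE]
    ang <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                               sqrt(rowSums(v1^2) * rowSums(v2^2))))) *
      180 / pi
    keep <- ang <= angle_cut + 1e-9
  } else {
    # acceptor nearest image w.r.t. the hydrogen, enumerated per pair
    Hp <- H[di, , drop = FALSE]
    Ah <- Ab
    for (j in seq_len(nrow(cand))) {
      cands <- matrix(A[ai[j], ], 27, 3, byrow = TRUE) + shifts
      Ah[j, ] <- cands[which.min(rowSums(sweep(cands, 2, Hp[j, ])^2)), ]
    }
    v1 <- D[di, , drop = FALSE] - Hp
    v2 <- Ah - Hp
    ang <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                               sqrt(rowSums(v1^2) * rowSums(v2^2))))) *
      180 / pi
    keep <- ang >= 180 - angle_cut - 1e-9
  }
  if (!any(keep)) return(character(0))
  sort(paste(dh[di[keep], 1], dh[di[keep], 2], acc[ai[keep]], sep = "-"))
}
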