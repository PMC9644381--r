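# Brownian-dynamics synthetic-trajectory generator with planted ground
# truth: per-molecule diffusivities, harmonic tethers to protein surface
# sites, exact hydrogen-bond occupancy schedules and planted shell
# structure. Stands in for an MD engine so every analysis stage can be
# verified against known answers.
#
# Molecules are rigid bodies: untethered drugs perform translational
# Brownian motion (per-step displacement variance 2 D dt per axis),
# tethered drugs follow an overdamped harmonic (Ornstein-Uhlenbeck) walk
# around their protein site, and scheduled drugs are geometrically steered
# into/out of the hydrogen-bond criterion on an exact frame mask.

KBT_KJ_MOL <- 2.494  # kJ/mol at 300 K
D9_TO_NM2_PS <- 1e-7 # 1e-9 cm^2/s expressed in nm^2/ps

# deterministic quasi-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotation matrix mapping unit vector a onto unit vector b
rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cvec <- sum(a * b)
  if (cvec < -1 + 1e-12) {  # antiparallel: rotate pi about any orthogonal
    o <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- o - sum(o * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cvec)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Rigid drug-molecule template
#'
#' A 6-site rigid model of a small drug with exactly one hydrogen-bond
#' donor (carrying a polar hydrogen as a 7th atom), four acceptors and one
#' neutral site: a planar hexagon of heavy sites (ring radius 0.31 nm)
#' whose minor-axis radius of gyration is about 0.22 nm, matching a small
#' aromatic drug like indomethacin.
#'
#' @return list with `rel_pos` (7 x 3 matrix, nm, centered on the ring
#'   center), `roles` (per-atom donor/polar_h/acceptor flags), `masses`
#'   (Da), `names`, `elements`, `donor_of` and `h_direction` (unit vector
#'   from donor through its hydrogen)
#' @export
build_drug_template <- function() {
  r_ring <- 0.31
  ang <- (0:5) * pi / 3
  heavy <- cbind(r_ring * cos(ang), r_ring * sin(ang), 0)
  hpos <- c(r_ring + 0.10, 0, 0)  # polar H radially outward from the donor
  rel <- rbind(heavy, hpos)
  masses <- c(rep(63.4, 6), 1.008)  # totals ~381.4 Da
  list(rel_pos = rel,
       roles = data.frame(
         donor = c(TRUE, rep(FALSE, 6)),
         polar_h = c(rep(FALSE, 6), TRUE),
         acceptor = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)),
       masses = masses,
       names = c("D1", "A1", "A2", "A3", "A4", "C1", "HD1"),
       elements = c("O", "O", "O", "O", "O", "C", "H"),
       donor_of = c(rep(NA_integer_, 6), 1L),  # H attached to atom 1
       h_direction = c(1, 0, 0))
}

#' Rigid pseudo-protein with labeled surface donor/acceptor sites
#'
#' A quasi-spherical shell of heavy surface sites (deterministic Fibonacci
#' arrangement), each labeled with a residue code drawn from a palette and
#' carrying an acceptor role; a seeded subset additionally acts as donor
#' with a radially outward polar hydrogen. Emulates a protein surface for
#' contact, shell and residue-ranking analyses.
#'
#' @param n_sites number of surface sites (>= 4)
#' @param radius shell radius, nm
#' @param residue_palette character vector of 3-letter residue codes
#' @param seed integer seed (palette assignment and donor subset)
#' @param donor_fraction fraction of sites that also donate (default 0.5)
#' @return list with `rel_pos` (atoms x 3, nm, centered), `atoms` template
#'   columns (`names`, `elements`, `masses`, `roles`, `donor_of`,
#'   `residue_label`, `residue_index`) and `site_atom` (heavy-atom index
#'   per site)
#' @export
build_pseudo_protein <- function(n_sites, radius, residue_palette,
                                 seed = 1L, donor_fraction = 0.5) {
  stopifnot(n_sites >= 4, radius > 0, length(residue_palette) >= 1)
  dirs <- fibonacci_sphere(n_sites)
  with_seed(seed, function() {
    labels <- sample(residue_palette, n_sites, replace = TRUE)
    is_donor <- seq_len(n_sites) %in%
      sample(n_sites, round(donor_fraction * n_sites))
    heavy <- dirs * radius
    hpos <- dirs[is_donor, , drop = FALSE] * (radius + 0.10)
    rel <- rbind(heavy, hpos)
    nh <- sum(is_donor)
    list(rel_pos = rel,
         names = c(sprintf("S%d", seq_len(n_sites)),
                   sprintf("HS%d", which(is_donor))),
         elements = c(rep("O", n_sites), rep("H", nh)),
         masses = c(rep(110, n_sites), rep(1.008, nh)),
         roles = data.frame(
           donor = c(is_donor, rep(FALSE, nh)),
           polar_h = c(rep(FALSE, n_sites), rep(TRUE, nh)),
           acceptor = c(rep(TRUE, n_sites), rep(FALSE, nh))),
         donor_of = c(rep(NA_integer_, n_sites), which(is_donor)),
         residue_label = c(labels, labels[is_donor]),
         residue_index = c(seq_len(n_sites), which(is_donor)),
         site_atom = seq_len(n_sites),
         site_dirs = dirs)
  })
}

# stack a molecule template into global atom/molecule tables
append_molecule <- function(state, tmpl, kind, mol_label) {
  n <- length(tmpl$masses)
  id0 <- state$next_atom
  rl <- if (!is.null(tmpl$residue_label)) tmpl$residue_label else
    rep(mol_label, n)
  ri <- if (!is.null(tmpl$residue_index)) tmpl$residue_index else
    rep(state$next_mol + 1L, n)
  atoms <- data.frame(
    atom_id = id0 + seq_len(n) - 1L, name = tmpl$names,
    element = tmpl$elements, mass = tmpl$masses,
    residue_label = rl, residue_index = as.integer(ri),
    molecule_id = state$next_mol,
    donor = tmpl$roles$donor, polar_h = tmpl$roles$polar_h,
    acceptor = tmpl$roles$acceptor,
    donor_of = ifelse(is.na(tmpl$donor_of), NA_integer_,
                      id0 + as.integer(tmpl$donor_of) - 1L),
    stringsAsFactors = FALSE)
  state$atoms[[length(state$atoms) + 1L]] <- atoms
  state$mols[[length(state$mols) + 1L]] <-
    data.frame(molecule_id = state$next_mol, kind = kind)
  state$next_atom <- id0 + n
  state$next_mol <- state$next_mol + 1L
  state
}

water_template <- function() {
  list(rel_pos = rbind(c(0, 0, 0), c(0.0757, 0.0587, 0),
                       c(-0.0757, 0.0587, 0)),
       names = c("OW", "HW1", "HW2"), elements = c("O", "H", "H"),
       masses = c(15.999, 1.008, 1.008),
       roles = data.frame(donor = c(TRUE, FALSE, FALSE),
                          polar_h = c(FALSE, TRUE, TRUE),
                          acceptor = c(TRUE, FALSE, FALSE)),
       donor_of = c(NA_integer_, 1L, 1L))
}

#' Generator configuration
#'
#' Collects every knob of the synthetic-trajectory generator with the
#' package's stated-world defaults: a 6 nm cubic box, 2000 frames at 10 ps
#' (a 20 ns analysis window) and a drug diffusivity of 0.5e-9 cm^2/s.
#'
#' @param seed integer seed driving a single RNG stream per
#'   [simulate_asd()] call
#' @param box_edges box edge lengths, nm
#' @param n_frames number of frames
#' @param frame_dt frame spacing, ps (> 0)
#' @param n_protein,n_drug,n_water molecule counts (a `plan` row from
#'   [plan_system()] may be supplied instead)
#' @param plan optional `asd_system_plan` row supplying the counts
#' @param drug_D drug diffusivities, 1e-9 cm^2/s (recycled to `n_drug`)
#' @param water_D water diffusivity, 1e-9 cm^2/s
#' @param tethered_fraction fraction of drugs harmonically tethered to
#'   protein surface sites, in `[0, 1]`
#' @param tether_k harmonic tether constant, kJ/mol/nm^2 (default 1e5,
#'   a hydrogen-bond-like restraint; its relaxation time kBT/(D k) is then
#'   a few hundred ps, well inside the default 20 ns window, so tethered
#'   molecules sample their trapped plateau)
#' @param hbond_schedules list of planted bonds: each
#'   `list(drug = <1-based drug index>, protein = <1-based protein index>,
#'   site = <site index>, occupancy = <fraction in [0,1]>)`
#' @param protein_drift constant protein drift velocity, nm/ps (3-vector)
#' @param protein_sites,protein_radius pseudo-protein surface resolution
#'   and radius (nm)
#' @param residue_palette residue codes for the pseudo-protein surface
#' @return a `"asd_generator_config"` list
#' @export
generator_config <- function(seed = 1L, box_edges = c(6, 6, 6),
                             n_frames = 2000L, frame_dt = 10,
                             n_protein = 1L, n_drug = 20L, n_water = 0L,
                             plan = NULL, drug_D = 0.5, water_D = 1.0,
                             tethered_fraction = 0, tether_k = 1e5,
                             hbond_schedules = list(),
                             protein_drift = c(0, 0, 0),
                             protein_sites = 32L, protein_radius = 1.2,
                             residue_palette = c("GLU", "ASP", "LYS",
                                                 "GLN", "THR", "SER")) {
  if (!is.null(plan)) {
    n_protein <- plan$n_protein
    n_drug <- plan$n_drug
    n_water <- plan$n_water
  }
  stopifnot(frame_dt > 0, n_frames >= 1,
            tethered_fraction >= 0, tethered_fraction <= 1,
            all(vapply(hbond_schedules,
                       function(s) s$occupancy >= 0 && s$occupancy <= 1,
                       logical(1))))
  structure(list(seed = as.integer(seed), box_edges = box_edges,
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 n_protein = as.integer(n_protein),
                 n_drug = as.integer(n_drug),
                 n_water = as.integer(n_water),
                 drug_D = rep_len(drug_D, max(n_drug, 1L)),
                 water_D = water_D,
                 tethered_fraction = tethered_fraction,
                 tether_k = tether_k, hbond_schedules = hbond_schedules,
                 protein_drift = protein_drift,
                 protein_sites = as.integer(protein_sites),
                 protein_radius = protein_radius,
                 residue_palette = residue_palette),
            class = "asd_generator_config")
}

# grid of placement centers with guaranteed separation, avoiding spheres
placement_grid <- function(box, spacing, avoid_centers = NULL,
                           avoid_radius = 0) {
  nx <- pmax(1L, floor(box / spacing))
  pts <- as.matrix(expand.grid(
    x = (seq_len(nx[1]) - 0.5) * box[1] / nx[1],
    y = (seq_len(nx[2]) - 0.5) * box[2] / nx[2],
    z = (seq_len(nx[3]) - 0.5) * box[3] / nx[3]))
  colnames(pts) <- NULL
  if (!is.null(avoid_centers) && nrow(avoid_centers)) {
    d <- pairwise_min_image(pts, avoid_centers, box)
    pts <- pts[apply(d, 1, min) > avoid_radius, , drop = FALSE]
  }
  pts
}

#' Simulate a synthetic trajectory with planted ground truth
#'
#' Builds the topology (pseudo-proteins, rigid drugs, optional water),
#' places molecules without overlap, and integrates: untethered drugs and
#' waters perform translational Brownian motion with per-step variance
#' `2 D dt` per axis; tethered drugs follow an overdamped harmonic walk
#' around a protein surface site (which co-moves with the protein drift);
#' scheduled drugs are steered so that the named donor-H...acceptor triple
#' satisfies the geometric criterion in exactly the scheduled fraction of
#' frames (deterministic mask drawn from the seed). Protein bodies
#' translate with the configured drift, which is recorded. Coordinates are
#' wrapped into the box.
#'
#' @param config an [generator_config()]
#' @return list with `trajectory` (wrapped [asd_trajectory()]) and `truth`:
#'   `true_D` (named per drug molecule id; `NA` for steered molecules),
#'   `tethered`, `tether_site`, `bonds` (data.frame of planted triples with
#'   scheduled and realized occupancy), `planted_shell` (named
#'   `"contact"`/`"bulk"`), `drift` (`n_frames x 3`, nm)
#' @export
simulate_asd <- function(config) {
  stopifnot(inherits(config, "asd_generator_config"))
  cf <- config
  with_seed(cf$seed, function() {
    tmpl_drug <- build_drug_template()
    # ---- topology -----------------------------------------------------
    state <- list(atoms = list(), mols = list(), next_atom = 0L,
                  next_mol = 0L)
    prot_tmpls <- list()
    for (p in seq_len(cf$n_protein)) {
      pt <- build_pseudo_protein(cf$protein_sites, cf$protein_radius,
                                 cf$residue_palette,
                                 seed = cf$seed + p)
      prot_tmpls[[p]] <- pt
      state <- append_molecule(state, pt, "protein", "PRO")
    }
    drug_mol_ids <- integer(0)
    for (d in seq_len(cf$n_drug)) {
      drug_mol_ids <- c(drug_mol_ids, state$next_mol)
      state <- append_molecule(state, tmpl_drug, "drug", "IND")
    }
    water_mol_ids <- integer(0)
    for (w in seq_len(cf$n_water)) {
      water_mol_ids <- c(water_mol_ids, state$next_mol)
      state <- append_molecule(state, water_template(), "water", "SOL")
    }
    top <- asd_topology(do.call(rbind, state$atoms),
                        do.call(rbind, state$mols))
    box <- cf$box_edges
    nf <- cf$n_frames
    dt <- cf$frame_dt
    # ---- placement ----------------------------------------------------
    if (cf$n_protein > 0) {
      pg <- placement_grid(box, max(2.2 * cf$protein_radius + 1, 0.9))
      if (nrow(pg) < cf$n_protein) stop("box overfilled: proteins")
      prot_centers <- pg[seq_len(cf$n_protein), , drop = FALSE]
    } else prot_centers <- matrix(numeric(0), 0, 3)
    n_free <- cf$n_drug + cf$n_water
    fg <- placement_grid(box, 0.9, prot_centers,
                         cf$protein_radius + 1.0)
    if (nrow(fg) < n_free) stop("box overfilled: drugs/water")
    fg <- fg[sample(nrow(fg)), , drop = FALSE]
    drug_start <- fg[seq_len(cf$n_drug), , drop = FALSE]
    water_start <- fg[cf$n_drug + seq_len(cf$n_water), , drop = FALSE]
    # ---- roles of drugs: scheduled > tethered > free -------------------
    sched_idx <- vapply(cf$hbond_schedules, function(s) as.integer(s$drug),
                        integer(1))
    if (anyDuplicated(sched_idx))
      stop("one drug molecule cannot carry two schedules")
    n_teth <- round(cf$tethered_fraction * cf$n_drug)
    teth_pool <- setdiff(seq_len(cf$n_drug), sched_idx)
    teth_idx <- if (n_teth > 0) sort(sample(teth_pool,
                                            min(n_teth,
                                                length(teth_pool))))
      else integer(0)
    if (length(c(sched_idx, teth_idx)) && cf$n_protein == 0)
      stop("tethers and hydrogen-bond schedules require a protein")
    # tether site assignment: spread over protein 1..n, random sites
    all_anchor <- c(sched_idx, teth_idx)
    anchor_prot <- integer(cf$n_drug)
    anchor_site <- integer(cf$n_drug)
    if (length(teth_idx)) {
      anchor_prot[teth_idx] <- sample(cf$n_protein, length(teth_idx),
                                      replace = TRUE)
      anchor_site[teth_idx] <- vapply(anchor_prot[teth_idx], function(p)
        sample(cf$protein_sites, 1L), integer(1))
    }
    for (s in cf$hbond_schedules) {
      anchor_prot[s$drug] <- as.integer(s$protein)
      anchor_site[s$drug] <- as.integer(s$site)
    }
    # ---- drift and protein coordinates --------------------------------
    tvec <- (seq_len(nf) - 1L) * dt
    drift <- outer(tvec, cf$protein_drift)
    # ---- COM paths ----------------------------------------------------
    drug_rot <- replicate(cf$n_drug, random_rotation(), simplify = FALSE)
    drug_com <- array(NA_real_, c(cf$n_drug, 3, nf))
    true_D <- rep(NA_real_, cf$n_drug)
    planted_shell <- rep("bulk", cf$n_drug)
    for (d in seq_len(cf$n_drug)) {
      if (d %in% sched_idx) next  # steered below
      D_nm <- cf$drug_D[d] * D9_TO_NM2_PS
      true_D[d] <- cf$drug_D[d]
      steps <- matrix(stats::rnorm(3L * nf, sd = sqrt(2 * D_nm * dt)),
                      nf, 3)
      steps[1, ] <- 0
      if (d %in% teth_idx) {
        planted_shell[d] <- "contact"
        pt <- prot_tmpls[[anchor_prot[d]]]
        u <- pt$site_dirs[anchor_site[d], ]
        site0 <- prot_centers[anchor_prot[d], ] +
          u * (cf$protein_radius + 0.35)
        a <- min(1, D_nm * cf$tether_k * dt / KBT_KJ_MOL)
        x <- site0
        for (f in seq_len(nf)) {
          site <- site0 + drift[f, ]
          if (f > 1) x <- x + a * (site - x) + steps[f, ]
          drug_com[d, , f] <- x
        }
      } else {
        path <- apply(steps, 2, cumsum)
        drug_com[d, , ] <- t(sweep(path, 2, -drug_start[d, ]))
      }
    }
    # ---- assemble atom coordinates ------------------------------------
    nat <- n_atoms(top)
    co <- array(NA_real_, c(nat, 3, nf))
    for (p in seq_len(cf$n_protein)) {
      rows <- molecule_atoms(top, p - 1L)
      base <- prot_tmpls[[p]]$rel_pos +
        matrix(prot_centers[p, ], length(rows), 3, byrow = TRUE)
      for (f in seq_len(nf))
        co[rows, , f] <- base + matrix(drift[f, ], length(rows), 3,
                                       byrow = TRUE)
    }
    rel_drug <- tmpl_drug$rel_pos
    com_rel <- colSums(rel_drug * tmpl_drug$masses) /
      sum(tmpl_drug$masses)
    bonds <- list()
    for (d in seq_len(cf$n_drug)) {
      rows <- molecule_atoms(top, drug_mol_ids[d])
      if (d %in% sched_idx) {
        s <- cf$hbond_schedules[[match(d, sched_idx)]]
        planted_shell[d] <- "contact"
        pt <- prot_tmpls[[anchor_prot[d]]]
        u <- pt$site_dirs[anchor_site[d], ]
        R <- rotation_onto(tmpl_drug$h_direction, -u)
        rel <- t(R %*% t(rel_drug - matrix(rel_drug[1, ], 7, 3,
                                           byrow = TRUE)))
        site_atom_row <- rows_of_site(top, anchor_prot[d], anchor_site[d],
                                      prot_tmpls)
        n_on <- round(s$occupancy * nf)
        on_mask <- sort(sample(nf, n_on))
        acc0 <- prot_centers[anchor_prot[d], ] + u * cf$protein_radius
        for (f in seq_len(nf)) {
          gap <- if (f %in% on_mask) 0.30 else 0.55
          donor_pos <- acc0 + u * gap + drift[f, ]
          co[rows, , f] <- rel +
            matrix(donor_pos, length(rows), 3, byrow = TRUE)
        }
        drug_com[d, , ] <- sapply(seq_len(nf), function(f)
          colSums(co[rows, , f] * tmpl_drug$masses) /
            sum(tmpl_drug$masses))
        bonds[[length(bonds) + 1L]] <- data.frame(
          drug_molecule_id = drug_mol_ids[d],
          protein_molecule_id = anchor_prot[d] - 1L,
          donor_atom_id = top$atoms$atom_id[rows[1]],
          hydrogen_atom_id = top$atoms$atom_id[rows[7]],
          acceptor_atom_id = top$atoms$atom_id[site_atom_row],
          occupancy_scheduled = s$occupancy,
          occupancy_planted = n_on / nf)
      } else {
        R <- drug_rot[[d]]
        rel <- t(R %*% t(rel_drug - matrix(com_rel, 7, 3, byrow = TRUE)))
        for (f in seq_len(nf))
          co[rows, , f] <- rel + matrix(drug_com[d, , f], length(rows), 3,
                                        byrow = TRUE)
      }
    }
    if (cf$n_water > 0) {
      wt <- water_template()
      wrel <- wt$rel_pos - matrix(colSums(wt$rel_pos * wt$masses) /
                                    sum(wt$masses), 3, 3, byrow = TRUE)
      Dw <- cf$water_D * D9_TO_NM2_PS
      for (w in seq_len(cf$n_water)) {
        rows <- molecule_atoms(top, water_mol_ids[w])
        steps <- matrix(stats::rnorm(3L * nf, sd = sqrt(2 * Dw * dt)),
                        nf, 3)
        steps[1, ] <- 0
        path <- sweep(apply(steps, 2, cumsum), 2, -water_start[w, ])
        R <- random_rotation()
        rel <- t(R %*% t(wrel))
        for (f in seq_len(nf))
          co[rows, , f] <- rel + matrix(path[f, ], 3, 3, byrow = TRUE)
      }
    }
    traj <- wrap_trajectory(asd_trajectory(top, co, tvec, box,
                                           wrapped = FALSE))
    names(true_D) <- drug_mol_ids
    tether_flag <- seq_len(cf$n_drug) %in% teth_idx
    names(tether_flag) <- drug_mol_ids
    names(planted_shell) <- drug_mol_ids
    list(trajectory = traj,
         truth = list(
           true_D = true_D, tethered = tether_flag,
           tether_site = ifelse(anchor_site > 0, anchor_site, NA),
           bonds = if (length(bonds)) do.call(rbind, bonds) else
             data.frame(),
           planted_shell = planted_shell, drift = drift,
           drug_molecule_ids = drug_mol_ids))
  })
}

# atoms-table row of a protein surface site's heavy atom
rows_of_site <- function(top, protein_index, site, prot_tmpls) {
  rows <- molecule_atoms(top, protein_index - 1L)
  rows[prot_tmpls[[protein_index]]$site_atom[site]]
}

#' Two-layer fixture: planted first shell and second layer
#'
#' Builds a static system with one pseudo-protein and two planted drug
#' populations: `n_first_shell` molecules in direct contact (minimal atom
#' distance to the protein ~0.15-0.30 nm) and `n_second_layer` molecules at
#' 0.5-0.9 nm surface separation. Produces the bimodal minimal-distance
#' signature of an emerging second drug layer.
#'
#' @param n_first_shell,n_second_layer molecule counts (>= 0)
#' @param seed integer seed
#' @param n_frames number of (static, identical) frames (default 5)
#' @param box_edge cubic box edge, nm (default 8)
#' @return list with `trajectory` and `truth` (`planted_layer` named
#'   `"first"`/`"second"` per drug molecule id, `planted_fraction`)
#' @export
make_two_layer_fixture <- function(n_first_shell, n_second_layer,
                                   seed = 1L, n_frames = 5L,
                                   box_edge = 8) {
  stopifnot(n_first_shell >= 0, n_second_layer >= 0)
  with_seed(seed, function() {
    radius <- 1.5
    n_sites <- 200L
    pt <- build_pseudo_protein(n_sites, radius, c("GLU", "ASP", "LYS"),
                               seed = seed, donor_fraction = 0.3)
    tmpl <- build_drug_template()
    state <- list(atoms = list(), mols = list(), next_atom = 0L,
                  next_mol = 0L)
    state <- append_molecule(state, pt, "protein", "PRO")
    n_drug <- n_first_shell + n_second_layer
    drug_ids <- integer(0)
    for (d in seq_len(n_drug)) {
      drug_ids <- c(drug_ids, state$next_mol)
      state <- append_molecule(state, tmpl, "drug", "IND")
    }
    top <- asd_topology(do.call(rbind, state$atoms),
                        do.call(rbind, state$mols))
    box <- rep(box_edge, 3)
    center <- box / 2
    prot_pos <- pt$rel_pos + matrix(center, nrow(pt$rel_pos), 3,
                                    byrow = TRUE)
    targets <- c(stats::runif(n_first_shell, 0.15, 0.30),
                 stats::runif(n_second_layer, 0.50, 0.90))
    layer <- rep(c("first", "second"), c(n_first_shell, n_second_layer))
    dirs <- if (n_drug > 0) fibonacci_sphere(max(n_drug, 4)) else
      matrix(numeric(0), 0, 3)
    nat <- n_atoms(top)
    pos <- matrix(NA_real_, nat, 3)
    pos[molecule_atoms(top, 0L), ] <- prot_pos
    com_rel <- colSums(tmpl$rel_pos * tmpl$masses) / sum(tmpl$masses)
    for (d in seq_len(n_drug)) {
      u <- dirs[d, ]
      # tangent orientation (ring plane perpendicular to the radial
      # direction) keeps the COM nearly as close to the surface as the
      # nearest atom; random spin about the radial axis
      phi <- stats::runif(1, 0, 2 * pi)
      spin <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0,
                       0, 0, 1), 3, 3)
      R <- rotation_onto(c(0, 0, 1), u) %*% spin
      rel <- t(R %*% t(tmpl$rel_pos - matrix(com_rel, 7, 3, byrow = TRUE)))
      com <- center + u * (radius + 0.6)
      # radial correction: walk the COM until the minimal atom distance
      # hits the planted target (nearly 1:1 in the radial coordinate)
      for (it in 1:4) {
        at <- rel + matrix(com, 7, 3, byrow = TRUE)
        dmin <- min(pairwise_min_image(at, prot_pos, box))
        com <- com + u * (targets[d] - dmin)
      }
      pos[molecule_atoms(top, drug_ids[d]), ] <-
        rel + matrix(com, 7, 3, byrow = TRUE)
    }
    co <- array(rep(pos, n_frames), c(nat, 3, n_frames))
    traj <- wrap_trajectory(asd_trajectory(
      top, co, (seq_len(n_frames) - 1L) * 10, box, wrapped = FALSE))
    names(layer) <- drug_ids
    list(trajectory = traj,
         truth = list(planted_layer = layer,
                      planted_fraction =
                        if (n_drug > 0) n_second_layer / n_drug else 0,
                      target_min_dist = stats::setNames(targets,
                                                        drug_ids)))
  })
}

#' Chain fixture: planted hydrogen-bond generations
#'
#' Static system with one pseudo-protein and a linear chain of drug
#' molecules hydrogen-bonded protein -> d1 -> d2 -> ... -> dn with
#' permanent (occupancy 1) geometric bonds, the canonical
#' generation-tracing fixture. Additional free drug molecules can be
#' placed in the bulk.
#'
#' @param n_chain chain length (number of drug generations planted)
#' @param n_free free (unbonded) drug molecules far from the protein
#' @param seed integer seed
#' @param n_frames static frame count (default 5)
#' @return list with `trajectory` and `truth` (`generation` named per drug
#'   molecule id: 1..n_chain for the chain, `NA` for free molecules)
#' @export
make_chain_fixture <- function(n_chain, n_free = 0L, seed = 1L,
                               n_frames = 5L) {
  stopifnot(n_chain >= 1)
  with_seed(seed, function() {
    radius <- 1.0
    pt <- build_pseudo_protein(32L, radius, c("GLU", "ASP"), seed = seed)
    tmpl <- build_drug_template()
    box_edge <- max(8, 2 * (radius + 0.92 * n_chain + 1.5))
    box <- rep(box_edge, 3)
    center <- box / 2
    state <- list(atoms = list(), mols = list(), next_atom = 0L,
                  next_mol = 0L)
    state <- append_molecule(state, pt, "protein", "PRO")
    n_drug <- n_chain + n_free
    drug_ids <- integer(0)
    for (d in seq_len(n_drug)) {
      drug_ids <- c(drug_ids, state$next_mol)
      state <- append_molecule(state, tmpl, "drug", "IND")
    }
    top <- asd_topology(do.call(rbind, state$atoms),
                        do.call(rbind, state$mols))
    nat <- n_atoms(top)
    pos <- matrix(NA_real_, nat, 3)
    pos[molecule_atoms(top, 0L), ] <-
      pt$rel_pos + matrix(center, nrow(pt$rel_pos), 3, byrow = TRUE)
    site <- 1L
    u <- pt$site_dirs[site, ]
    R <- rotation_onto(tmpl$h_direction, -u)
    rel <- t(R %*% t(tmpl$rel_pos -
                       matrix(tmpl$rel_pos[1, ], 7, 3, byrow = TRUE)))
    # chain geometry: donor_g sits 0.30 nm outward of the previous
    # acceptor; within a molecule the far-side acceptor (site A3,
    # template atom 4 at 180 degrees) is 0.62 nm beyond the donor
    acc_pos <- center + u * radius  # protein surface site heavy atom
    gen_truth <- rep(NA_real_, n_drug)
    for (g in seq_len(n_chain)) {
      donor_pos <- acc_pos + u * 0.30
      pos[molecule_atoms(top, drug_ids[g]), ] <-
        rel + matrix(donor_pos, 7, 3, byrow = TRUE)
      gen_truth[g] <- g
      acc_pos <- donor_pos + u * 0.62  # this molecule's A3 acceptor
    }
    if (n_free > 0) {
      far_dirs <- fibonacci_sphere(max(n_free, 4))
      for (j in seq_len(n_free)) {
        com <- center - far_dirs[j, ] * (radius + 2.5) +
          c(0, 0, 0.3 * j)
        com <- com %% box
        Rf <- random_rotation()
        com_rel <- colSums(tmpl$rel_pos * tmpl$masses) / sum(tmpl$masses)
        relf <- t(Rf %*% t(tmpl$rel_pos -
                             matrix(com_rel, 7, 3, byrow = TRUE)))
        pos[molecule_atoms(top, drug_ids[n_chain + j]), ] <-
          relf + matrix(com, 7, 3, byrow = TRUE)
      }
    }
    co <- array(rep(pos, n_frames), c(nat, 3, n_frames))
    traj <- wrap_trajectory(asd_trajectory(
      top, co, (seq_len(n_frames) - 1L) * 10, box, wrapped = FALSE))
    names(gen_truth) <- drug_ids
    list(trajectory = traj,
         truth = list(generation = gen_truth))
  })
}

#' Serialize generator ground truth as JSON
#' @param truth the `truth` element of a generator result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
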