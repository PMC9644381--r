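# Protein-drug distance analysis: minimal distances, first-drug-shell
# membership, 0.4 nm shell indices, second-layer detection and radial
# distribution functions.
#
# Two reference points are computed for every drug molecule: the minimum
# over protein atoms of the distance to the drug center of mass
# (min_dist_com, feeds the distance histograms) and the minimum over
# protein-atom x drug-atom pairs (min_dist_atom, feeds the 0.4 nm contact
# flag and the 0.4 nm-wide shell index).

FDS_CUTOFF_NM <- 0.4
SHELL_WIDTH_NM <- 0.4

protein_atom_rows <- function(topology) {
  which(mol_kind_of_atom(topology) == "protein")
}

#' Minimal distance from a drug molecule to the protein
#'
#' @param frame a frame as returned by [get_frame()]
#' @param topology an [asd_topology()] with at least one protein molecule
#' @param molecule_id drug molecule id
#' @param mode `"com"`: minimum over protein atoms of the minimum-image
#'   distance to the drug center of mass; `"atom"`: minimum over all
#'   protein-atom x drug-atom pairs
#' @return distance, nm
#' @export
min_distance_to_protein <- function(frame, topology, molecule_id,
                                    mode = c("com", "atom")) {
  mode <- match.arg(mode)
  prot <- protein_atom_rows(topology)
  if (!length(prot)) stop("topology contains no protein molecules")
  P <- frame$positions[prot, , drop = FALSE]
  if (mode == "com") {
    pos <- unwrap_molecule(frame, topology, molecule_id)
    com <- center_of_mass(frame, topology, molecule_id, positions = pos)
    min(pairwise_min_image(P, rbind(com), frame$box))
  } else {
    idx <- molecule_atoms(topology, molecule_id)
    min(pairwise_min_image(P, frame$positions[idx, , drop = FALSE],
                           frame$box))
  }
}

#' Per-molecule, per-frame shell table
#'
#' For every drug molecule and every window frame, computes the minimal
#' protein distance in both modes, the first-drug-shell contact flag
#' (`min_dist_atom <= 0.4` nm) and the 0.4 nm shell index
#' (`floor(min_dist_atom / 0.4)`).
#'
#' @param trajectory a wrapped [asd_trajectory()]
#' @param window analysis window (see [resolve_window()])
#' @param shell_width shell width, nm (default 0.4, i.e. 4 Angstrom)
#' @param fds_cutoff first-drug-shell contact cutoff on `min_dist_atom`,
#'   nm (default 0.4)
#' @return data.frame of class `"asd_shell_table"`: `molecule_id`,
#'   `frame`, `frame_time`, `min_dist_com`, `min_dist_atom`,
#'   `shell_index`, `fds_flag`
#' @export
shell_table <- function(trajectory, window = NULL,
                        shell_width = SHELL_WIDTH_NM,
                        fds_cutoff = FDS_CUTOFF_NM) {
  top <- trajectory$topology
  idx <- resolve_window(trajectory, window)
  prot <- protein_atom_rows(top)
  if (!length(prot)) stop("topology contains no protein molecules")
  drugs <- molecules_of_kind(top, "drug")
  if (!length(drugs))
    return(structure(data.frame(molecule_id = integer(), frame = integer(),
                                frame_time = numeric(),
                                min_dist_com = numeric(),
                                min_dist_atom = numeric(),
                                shell_index = integer(),
                                fds_flag = logical()),
                     class = c("asd_shell_table", "data.frame")))
  drug_rows <- lapply(drugs, function(m) molecule_atoms(top, m))
  drug_grp <- rep(seq_along(drugs), lengths(drug_rows))
  drug_all <- unlist(drug_rows)
  masses <- top$atoms$mass
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    fr <- get_frame(trajectory, idx[j])
    P <- fr$positions[prot, , drop = FALSE]
    # whole-molecule drug coordinates and COMs
    pos <- fr$positions[drug_all, , drop = FALSE]
    anchor_rows <- vapply(drug_rows, `[`, integer(1), 1L)
    anchor <- fr$positions[anchor_rows[drug_grp], , drop = FALSE]
    pos <- anchor + min_image_disp(pos - anchor, fr$box)
    m <- masses[drug_all]
    com <- rowsum(pos * m, drug_grp, reorder = TRUE) /
      as.numeric(rowsum(m, drug_grp, reorder = TRUE))
    d_com <- apply(pairwise_min_image(com, P, fr$box), 1, min)
    d_atom_pairs <- pairwise_min_image(pos, P, fr$box)
    d_atom <- vapply(split(seq_along(drug_all), drug_grp),
                     function(r) min(d_atom_pairs[r, ]), numeric(1))
    out[[j]] <- data.frame(molecule_id = drugs, frame = idx[j],
                           frame_time = fr$time, min_dist_com = d_com,
                           min_dist_atom = d_atom)
  }
  tab <- do.call(rbind, out)
  tab$shell_index <- as.integer(floor(tab$min_dist_atom / shell_width))
  tab$fds_flag <- tab$min_dist_atom <= fds_cutoff
  rownames(tab) <- NULL
  class(tab) <- c("asd_shell_table", "data.frame")
  tab
}

#' Histogram of minimal protein-drug distances
#'
#' Pools (molecule, frame) samples of the minimal protein distance and
#' returns a normalized histogram (fractions summing to 1 when any samples
#' exist). Bins are half-open `[k w, (k+1) w)`.
#'
#' @param trajectory a wrapped [asd_trajectory()]
#' @param window analysis window
#' @param mode `"com"` (default, matching minimal-distance histograms
#'   against the drug center of mass) or `"atom"`
#' @param bin_width bin width, nm (default 0.05)
#' @param table optional precomputed [shell_table()] to reuse
#' @return data.frame `bin_lo`, `bin_hi`, `count`, `fraction`
#' @export
distance_histogram <- function(trajectory, window = NULL,
                               mode = c("com", "atom"), bin_width = 0.05,
                               table = NULL) {
  mode <- match.arg(mode)
  if (is.null(table)) table <- shell_table(trajectory, window)
  x <- if (mode == "com") table$min_dist_com else table$min_dist_atom
  if (!length(x))
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer(), fraction = numeric()))
  k <- floor(x / bin_width)
  kk <- seq.int(0L, max(k))
  cnt <- tabulate(k + 1L, nbins = max(k) + 1L)
  data.frame(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
             count = cnt, fraction = cnt / sum(cnt))
}

#' Fraction of drug molecules in the second layer
#'
#' A drug molecule belongs to the second layer (in contact only with other
#' drug molecules) iff its window-median minimal atom distance to the
#' protein exceeds the contact cutoff.
#'
#' @param table an [shell_table()] result
#' @param fds_cutoff contact cutoff, nm (default 0.4)
#' @return fraction in `[0, 1]` (0 when no drug molecules)
#' @export
second_layer_fraction <- function(table, fds_cutoff = FDS_CUTOFF_NM) {
  if (!nrow(table)) return(0)
  med <- tapply(table$min_dist_atom, table$molecule_id, stats::median)
  mean(med > fds_cutoff)
}

#' Radial distribution function between two atom selections
#'
#' Standard pair-correlation estimator: pair distances (minimum image) are
#' binned and normalized per frame by the ideal-gas expectation
#' `n_A n_B V_shell / V_box` (self pairs removed when the selections
#' overlap).
#'
#' @param trajectory an [asd_trajectory()]
#' @param selection_a,selection_b integer vectors of 0-based atom ids
#' @param r_max maximum radius, nm; must not exceed half the smallest box
#'   edge
#' @param bin_width bin width, nm (default 0.02)
#' @param window analysis window
#' @return data.frame `r` (bin centers), `g` (pair correlation)
#' @export
rdf <- function(trajectory, selection_a, selection_b, r_max,
                bin_width = 0.02, window = NULL) {
  idx <- resolve_window(trajectory, window)
  if (r_max > min(trajectory$boxes[idx, ]) / 2)
    stop("r_max exceeds half the smallest box edge")
  ra <- match(selection_a, trajectory$topology$atoms$atom_id)
  rb <- match(selection_b, trajectory$topology$atoms$atom_id)
  if (anyNA(ra) || anyNA(rb)) stop("unknown atom id in selection")
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  norm <- numeric(nb)
  edges3 <- (seq_len(nb + 1L) - 1L)^3 * bin_width^3
  vshell <- 4 / 3 * pi * diff(edges3)
  for (f in idx) {
    fr <- get_frame(trajectory, f)
    dmat <- pairwise_min_image(fr$positions[ra, , drop = FALSE],
                               fr$positions[rb, , drop = FALSE], fr$box)
    self <- outer(selection_a, selection_b, "==")
    d <- dmat[!self]
    d <- d[d < r_max]
    counts <- counts + tabulate(floor(d / bin_width) + 1L, nbins = nb)
    vbox <- prod(fr$box)
    n_pairs <- length(ra) * length(rb) - sum(self)
    norm <- norm + n_pairs * vshell / vbox
  }
  data.frame(r = (seq_len(nb) - 0.5) * bin_width, g = counts / norm)
}
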