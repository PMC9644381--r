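# Geometric hydrogen-bond detection, existence matrices, stability
# classification, generation tracing and per-residue aggregation.
#
# Criterion: a donor-H...acceptor triple is a hydrogen bond in a frame iff
# the minimum-image donor-acceptor distance is <= d_cut AND the angular
# condition holds. Two angle conventions are supported:
#   vertex = "donor":    angle H-D-A at the donor <= angle_cut
#   vertex = "hydrogen": angle D-H-A at the hydrogen >= 180 - angle_cut
#     (the supplementary reading of the same cutoff)
# The donor-vertex convention is the default, matching the common
# GROMACS-style analysis default. Intramolecular pairs are excluded.

mol_kind_of_atom <- function(topology) {
  topology$molecules$kind[match(topology$atoms$molecule_id,
                                topology$molecules$molecule_id)]
}

hbond_pair_class <- function(kind_donor, kind_acceptor) {
  ifelse(kind_donor == "water" | kind_acceptor == "water", "water-involved",
  ifelse(kind_donor == "protein" & kind_acceptor == "protein",
         "protein-protein",
  ifelse(kind_donor == "drug" & kind_acceptor == "drug", "drug-drug",
         "protein-drug")))
}

empty_hbond_table <- function() {
  data.frame(donor_atom_id = integer(), hydrogen_atom_id = integer(),
             acceptor_atom_id = integer(), donor_molecule_id = integer(),
             acceptor_molecule_id = integer(), pair_class = character(),
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion (distance cutoff on the minimum-image
#' donor-acceptor separation plus an angular cutoff) to every
#' donor-H/acceptor combination across distinct molecules.
#'
#' @param frame a frame as returned by [get_frame()]
#' @param topology an [asd_topology()] with donor/acceptor annotations
#' @param d_cut donor-acceptor distance cutoff, nm (default 0.35)
#' @param angle_cut angular cutoff, degrees (default 30)
#' @param vertex angle convention, `"donor"` (H-D-A angle `<= angle_cut`)
#'   or `"hydrogen"` (D-H-A angle `>= 180 - angle_cut`)
#' @return data.frame of detected triples: atom ids, molecule ids and
#'   `pair_class` (`protein-drug`, `drug-drug`, `protein-protein`,
#'   `water-involved`)
#' @export
detect_hbonds_frame <- function(frame, topology, d_cut = 0.35,
                                angle_cut = 30,
                                vertex = c("donor", "hydrogen")) {
  vertex <- match.arg(vertex)
  a <- topology$atoms
  dh <- donor_hydrogen_pairs(topology)
  acc <- a$atom_id[a$acceptor]
  if (!nrow(dh) || !length(acc)) return(empty_hbond_table())
  if (any(a$donor & !(a$atom_id %in% dh[, 1])))
    stop("donor atom without a paired polar hydrogen")
  box <- frame$box
  # 0-based atom ids -> row indices
  d_idx <- match(dh[, 1], a$atom_id)
  h_idx <- match(dh[, 2], a$atom_id)
  a_idx <- match(acc, a$atom_id)
  D <- frame$positions[d_idx, , drop = FALSE]
  H <- frame$positions[h_idx, , drop = FALSE]
  A <- frame$positions[a_idx, , drop = FALSE]
  dda <- pairwise_min_image(D, A, box)
  cand <- which(dda <= d_cut, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_hbond_table())
  di <- cand[, 1]; ai <- cand[, 2]
  keep <- a$molecule_id[d_idx[di]] != a$molecule_id[a_idx[ai]] &
    dh[di, 1] != acc[ai]
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(empty_hbond_table())
  v_dh <- min_image_disp(H[di, , drop = FALSE] - D[di, , drop = FALSE], box)
  v_da <- min_image_disp(A[ai, , drop = FALSE] - D[di, , drop = FALSE], box)
  if (vertex == "donor") {
    cosang <- rowSums(v_dh * v_da) /
      (sqrt(rowSums(v_dh^2)) * sqrt(rowSums(v_da^2)))
    ok <- cosang >= cos(angle_cut * pi / 180) - 1e-12
  } else {
    v_hd <- -v_dh
    v_ha <- min_image_disp(A[ai, , drop = FALSE] - H[di, , drop = FALSE],
                           box)
    cosang <- rowSums(v_hd * v_ha) /
      (sqrt(rowSums(v_hd^2)) * sqrt(rowSums(v_ha^2)))
    ok <- cosang <= cos((180 - angle_cut) * pi / 180) + 1e-12
  }
  di <- di[ok]; ai <- ai[ok]
  if (!length(di)) return(empty_hbond_table())
  out <- data.frame(
    donor_atom_id = dh[di, 1], hydrogen_atom_id = dh[di, 2],
    acceptor_atom_id = acc[ai],
    donor_molecule_id = a$molecule_id[d_idx[di]],
    acceptor_molecule_id = a$molecule_id[a_idx[ai]],
    stringsAsFactors = FALSE)
  kind <- topology$molecules$kind
  mid <- topology$molecules$molecule_id
  out$pair_class <- hbond_pair_class(kind[match(out$donor_molecule_id, mid)],
                                     kind[match(out$acceptor_molecule_id,
                                                mid)])
  out[order(out$donor_atom_id, out$acceptor_atom_id), , drop = FALSE]
}

triple_key <- function(tab) {
  paste(tab$donor_atom_id, tab$hydrogen_atom_id, tab$acceptor_atom_id,
        sep = "-")
}

#' Build a hydrogen-bond existence (occupancy) matrix
#'
#' Runs frame-wise detection over an analysis window and collects the
#' boolean occupancy of every triple ever detected in the window. Bond
#' identity across frames is the atom triple (donor, hydrogen, acceptor).
#'
#' @inheritParams detect_hbonds_frame
#' @param trajectory an [asd_trajectory()] (wrapped coordinates)
#' @param window analysis window (see [resolve_window()])
#' @return an object of class `"asd_hbond_matrix"`: list with `triples`
#'   (annotated data.frame), `occupancy` (logical triples x frames matrix),
#'   `frame_times` (ps) and `occupancy_mean` per triple
#' @export
build_existence_matrix <- function(trajectory, window = NULL, d_cut = 0.35,
                                   angle_cut = 30,
                                   vertex = c("donor", "hydrogen")) {
  vertex <- match.arg(vertex)
  idx <- resolve_window(trajectory, window)
  per_frame <- lapply(idx, function(f)
    detect_hbonds_frame(get_frame(trajectory, f), trajectory$topology,
                        d_cut, angle_cut, vertex))
  all_tab <- do.call(rbind, per_frame)
  triples <- all_tab[!duplicated(triple_key(all_tab)), , drop = FALSE]
  triples <- triples[order(triples$donor_atom_id, triples$acceptor_atom_id),
                     , drop = FALSE]
  rownames(triples) <- NULL
  keys <- triple_key(triples)
  occ <- matrix(FALSE, nrow(triples), length(idx),
                dimnames = list(keys, NULL))
  for (j in seq_along(idx)) {
    k <- triple_key(per_frame[[j]])
    occ[match(k, keys), j] <- TRUE
  }
  structure(list(triples = triples, occupancy = occ,
                 frame_times = trajectory$times[idx],
                 occupancy_mean = rowMeans(occ),
                 params = list(d_cut = d_cut, angle_cut = angle_cut,
                               vertex = vertex)),
            class = "asd_hbond_matrix")
}

#' @export
print.asd_hbond_matrix <- function(x, ...) {
  cat(sprintf("asd_hbond_matrix: %d triples x %d frames (d_cut %.3g nm, angle %.3g deg, vertex %s)\n",
              nrow(x$triples), ncol(x$occupancy), x$params$d_cut,
              x$params$angle_cut, x$params$vertex))
  invisible(x)
}

#' Classify stable hydrogen bonds from occupancy fractions
#'
#' A protein-drug bond is stable iff its occupancy over the analysed frames
#' strictly exceeds `threshold_protein_drug`; drug-drug, protein-protein
#' and water-involved bonds use `threshold_other`. Both inequalities are
#' strict ("more than").
#'
#' @param matrix an `"asd_hbond_matrix"` from [build_existence_matrix()]
#' @param threshold_protein_drug occupancy threshold for protein-drug bonds
#'   (default 0.80)
#' @param threshold_other occupancy threshold for all other pair classes
#'   (default 0.50)
#' @return the stable subset of `matrix$triples` with an `occupancy` column
#' @export
classify_stable <- function(matrix, threshold_protein_drug = 0.80,
                            threshold_other = 0.50) {
  if (!inherits(matrix, "asd_hbond_matrix")) stop("need an asd_hbond_matrix")
  if (!nrow(matrix$triples)) {
    out <- matrix$triples
    out$occupancy <- numeric(0)
    return(out)
  }
  occ <- matrix$occupancy_mean
  thr <- ifelse(matrix$triples$pair_class == "protein-drug",
                threshold_protein_drug, threshold_other)
  out <- matrix$triples[occ > thr, , drop = FALSE]
  out$occupancy <- occ[occ > thr]
  rownames(out) <- NULL
  out
}

#' Trace hydrogen-bond generations from the protein surface
#'
#' Builds the molecule-level graph whose edges are stable hydrogen bonds
#' and runs a breadth-first search rooted at all protein molecules.
#' A drug molecule is generation 1 iff it has a stable bond to a protein,
#' generation g > 1 iff its shortest stable-bond path to any protein has
#' length g; unreachable molecules (or those beyond `max_generation`) get
#' `NA` ("none"). Water-involved bonds are excluded unless
#' `include_water = TRUE`, in which case water molecules may act as bridge
#' nodes (they still receive no generation themselves).
#'
#' @param stable_bonds data.frame of stable triples (from
#'   [classify_stable()]); only molecule ids are used
#' @param topology an [asd_topology()]
#' @param max_generation cap on reported generations (default `Inf`)
#' @param include_water allow water molecules as bridge nodes
#' @return data.frame `molecule_id`, `kind`, `generation` (integer or `NA`)
#'   for all non-protein molecules
#' @export
assign_generations <- function(stable_bonds, topology,
                               max_generation = Inf,
                               include_water = FALSE) {
  mol <- topology$molecules
  allowed <- if (include_water) mol$molecule_id else
    mol$molecule_id[mol$kind != "water"]
  edges <- unique(data.frame(a = stable_bonds$donor_molecule_id,
                             b = stable_bonds$acceptor_molecule_id))
  edges <- edges[edges$a %in% allowed & edges$b %in% allowed, , drop = FALSE]
  # adjacency as index lists over the molecule table
  nid <- mol$molecule_id
  adj <- vector("list", length(nid))
  ia <- match(edges$a, nid); ib <- match(edges$b, nid)
  for (e in seq_along(ia)) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
    adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
  }
  depth <- rep(NA_integer_, length(nid))
  sources <- which(mol$kind == "protein")
  depth[sources] <- 0L
  frontier <- sources
  g <- 0L
  while (length(frontier)) {
    g <- g + 1L
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(depth[nxt])]
    if (!length(nxt)) break
    depth[nxt] <- g
    frontier <- nxt
  }
  gen <- depth
  gen[!is.na(gen) & gen > max_generation] <- NA_integer_
  out <- data.frame(molecule_id = nid, kind = mol$kind, generation = gen)
  out <- out[out$kind != "protein", , drop = FALSE]
  # water bridges carry no generation label of their own
  out$generation[out$kind == "water"] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Rank protein residues by hydrogen-bond contribution
#'
#' Aggregates protein-drug hydrogen bonds by the protein-side residue
#' label. With an existence matrix and `weighted = TRUE` (default) each
#' triple contributes its occupancy fraction; otherwise each unique triple
#' counts once. Major contributors are residues holding more than 10% of
#' the total.
#'
#' @param bonds an `"asd_hbond_matrix"` or a data.frame of triples (e.g.
#'   the output of [classify_stable()])
#' @param topology an [asd_topology()]
#' @param stable_only with a matrix input, first reduce to stable bonds via
#'   [classify_stable()] defaults
#' @param weighted weight triples by occupancy when available
#' @param major_cut fraction above which a residue is flagged major
#'   (default 0.10, strict)
#' @return data.frame `residue_label`, `weight`, `fraction`, `major`,
#'   sorted alphabetically by label
#' @export
rank_residues <- function(bonds, topology, stable_only = FALSE,
                          weighted = TRUE, major_cut = 0.10) {
  if (inherits(bonds, "asd_hbond_matrix")) {
    tab <- bonds$triples
    tab$occupancy <- bonds$occupancy_mean
    if (stable_only) tab <- classify_stable(bonds)
  } else {
    tab <- bonds
  }
  tab <- tab[tab$pair_class == "protein-drug", , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(residue_label = character(), weight = numeric(),
                      fraction = numeric(), major = logical()))
  a <- topology$atoms
  kind <- mol_kind_of_atom(topology)
  prot_side <- ifelse(
    kind[match(tab$donor_atom_id, a$atom_id)] == "protein",
    tab$donor_atom_id, tab$acceptor_atom_id)
  labels <- a$residue_label[match(prot_side, a$atom_id)]
  w <- if (weighted && !is.null(tab$occupancy)) tab$occupancy
       else rep(1, nrow(tab))
  agg <- rowsum(w, labels)
  out <- data.frame(residue_label = rownames(agg), weight = agg[, 1])
  out <- out[order(out$residue_label), , drop = FALSE]
  out$fraction <- out$weight / sum(out$weight)
  out$major <- out$fraction > major_cut
  rownames(out) <- NULL
  out
}

#' Serialize an existence matrix as TSV + JSON index
#'
#' Writes a tab-separated matrix (one row per triple, annotated with atom,
#' molecule and residue information; one column per frame time) and a JSON
#' index file describing the triples and detection parameters.
#'
#' @param matrix an `"asd_hbond_matrix"`
#' @param topology an [asd_topology()]
#' @param path_tsv,path_json output paths
#' @return invisibly, a list of the two paths
#' @export
write_existence_matrix <- function(matrix, topology, path_tsv, path_json) {
  tr <- matrix$triples
  a <- topology$atoms
  ann <- data.frame(
    donor_atom_id = tr$donor_atom_id,
    hydrogen_atom_id = tr$hydrogen_atom_id,
    acceptor_atom_id = tr$acceptor_atom_id,
    donor_molecule_id = tr$donor_molecule_id,
    acceptor_molecule_id = tr$acceptor_molecule_id,
    pair_class = tr$pair_class,
    donor_residue = a$residue_label[match(tr$donor_atom_id, a$atom_id)],
    acceptor_residue = a$residue_label[match(tr$acceptor_atom_id,
                                             a$atom_id)],
    occupancy = matrix$occupancy_mean)
  occ <- matrix$occupancy + 0L  # logical -> integer, dims preserved
  colnames(occ) <- sprintf("t%.6g", matrix$frame_times)
  utils::write.table(cbind(ann, occ), path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_triples = nrow(tr), n_frames = ncol(matrix$occupancy),
         frame_times_ps = matrix$frame_times, params = matrix$params,
         triples = ann),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = path_tsv, json = path_json))
}
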