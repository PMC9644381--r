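# Trajectory container and periodic-boundary geometry.
#
# A trajectory stores coordinates as a 3-D array [n_atoms x 3 x n_frames]
# (nm), per-frame orthorhombic box edges (nm) and times (ps). Wrapped
# coordinates lie in [0, edge) per axis.

#' Construct a trajectory
#'
#' @param topology an [asd_topology()]
#' @param coords numeric array `n_atoms x 3 x n_frames`, nm
#' @param times numeric vector of frame times, ps, strictly increasing
#' @param boxes `n_frames x 3` matrix of box edge lengths, nm (a single
#'   length-3 vector is recycled)
#' @param wrapped logical: are coordinates wrapped into the box?
#' @return an object of class `"asd_trajectory"`
#' @export
asd_trajectory <- function(topology, coords, times, boxes, wrapped = TRUE) {
  stopifnot(inherits(topology, "asd_topology"))
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  nf <- dim(coords)[3]
  if (dim(coords)[1] != n_atoms(topology))
    stop("coords atom count does not match topology")
  if (length(times) != nf) stop("times length != number of frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nf, 3, byrow = TRUE)
  if (any(boxes <= 0)) stop("box edges must be positive")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), boxes = boxes,
                 wrapped = isTRUE(wrapped)),
            class = "asd_trajectory")
}

#' @export
print.asd_trajectory <- function(x, ...) {
  cat(sprintf(
    "asd_trajectory: %d atoms, %d frames, t = %g..%g ps, box %s nm (%s)\n",
    dim(x$coords)[1], n_frames(x), x$times[1], x$times[n_frames(x)],
    paste(signif(x$boxes[1, ], 4), collapse = " x "),
    if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `asd_trajectory`
#' @return integer
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame
#' @param trajectory an `asd_trajectory`
#' @param i frame index (1-based)
#' @return list with `time` (ps), `box` (nm, length 3) and `positions`
#'   (`n_atoms x 3` matrix, nm)
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  list(time = trajectory$times[i], box = trajectory$boxes[i, ],
       positions = trajectory$coords[, , i, drop = FALSE][, , 1])
}

#' Resolve an analysis window
#'
#' Windows select the frames an analysis runs on, either as an explicit
#' index range or as `"last:N"` (the final N frames, mirroring the common
#' practice of analysing only the tail of a production run).
#'
#' @param trajectory an `asd_trajectory`
#' @param window `NULL` (all frames), an integer vector of frame indices,
#'   a length-2 range `c(first, last)`, or a string `"last:N"`
#' @return integer vector of frame indices
#' @export
resolve_window <- function(trajectory, window = NULL) {
  nf <- n_frames(trajectory)
  if (is.null(window)) return(seq_len(nf))
  if (is.character(window)) {
    if (!grepl("^last:[0-9]+$", window))
      stop("window string must have the form 'last:N'")
    n <- as.integer(sub("^last:", "", window))
    n <- min(n, nf)
    return(seq.int(nf - n + 1L, nf))
  }
  window <- as.integer(window)
  if (length(window) == 2L && window[2] >= window[1])
    window <- seq.int(window[1], window[2])
  if (any(window < 1L | window > nf)) stop("window outside trajectory")
  if (!length(window)) stop("empty analysis window")
  window
}

# ---- periodic geometry ------------------------------------------------------

# minimum-image displacement: rows of d mapped into (-box/2, box/2]
min_image_disp <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Smallest distance between `p` and any periodic image of `q`.
#'
#' @param p,q numeric 3-vectors (or `n x 3` matrices for row-wise
#'   distances), nm
#' @param box orthorhombic box edge lengths, nm, all positive
#' @return distance(s) in nm
#' @export
minimum_image_distance <- function(p, q, box) {
  if (any(box <= 0)) stop("box edges must be positive")
  d <- min_image_disp(rbind(p) - rbind(q), box)
  unname(sqrt(rowSums(d * d)))
}

# all-pairs minimum-image distance matrix between coordinate sets A, B
pairwise_min_image <- function(A, B, box) {
  s2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    s2 <- s2 + dk * dk
  }
  sqrt(s2)
}

#' Make a molecule whole across periodic boundaries
#'
#' Rebuilds a molecule split by wrapping: the first atom keeps its wrapped
#' position and each subsequent atom (in topology atom order) is placed at
#' the periodic image nearest its predecessor. Valid when the molecule
#' diameter is below half the smallest box edge; exact half-box ties resolve
#' toward the negative image (`round` half-to-even on the image count is
#' overridden explicitly).
#'
#' @param frame a frame as returned by [get_frame()]
#' @param topology an `asd_topology`
#' @param molecule_id 0-based molecule id
#' @return `n_mol_atoms x 3` matrix of whole-molecule coordinates, nm
#' @export
unwrap_molecule <- function(frame, topology, molecule_id) {
  idx <- molecule_atoms(topology, molecule_id)
  if (!length(idx)) stop("unknown molecule_id")
  pos <- frame$positions[idx, , drop = FALSE]
  box <- frame$box
  if (nrow(pos) == 1L) return(pos)
  for (i in 2:nrow(pos)) {
    d <- pos[i, ] - pos[i - 1L, ]
    n <- round(d / box)
    # tie at exactly half a box edge: prefer the negative image
    tie <- abs(abs(d / box) - (abs(n) + 0.5)) < 1e-12
    n[tie & d > 0] <- n[tie & d > 0] + 1
    pos[i, ] <- pos[i, ] - n * box
  }
  dmax <- max(stats::dist(pos))
  if (dmax >= min(box) / 2)
    stop("molecule diameter ", signif(dmax, 4),
         " nm exceeds half the smallest box edge; cannot unwrap")
  pos
}

#' Mass-weighted center of mass of a whole molecule
#'
#' The molecule must be whole (no atom split across the boundary); use
#' [unwrap_molecule()] first for wrapped frames.
#'
#' @inheritParams unwrap_molecule
#' @param positions optional pre-unwrapped `n x 3` coordinates for the
#'   molecule's atoms (bypasses the wholeness repair, still checked)
#' @return numeric 3-vector, nm
#' @export
center_of_mass <- function(frame, topology, molecule_id, positions = NULL) {
  idx <- molecule_atoms(topology, molecule_id)
  if (is.null(positions)) positions <- frame$positions[idx, , drop = FALSE]
  if (nrow(positions) > 1 && max(stats::dist(positions)) > min(frame$box) / 2)
    stop("molecule is not whole; unwrap before taking the center of mass")
  m <- topology$atoms$mass[idx]
  colSums(positions * m) / sum(m)
}

#' Wrap trajectory coordinates into the primary box
#' @param trajectory an `asd_trajectory`
#' @return a wrapped `asd_trajectory`
#' @export
wrap_trajectory <- function(trajectory) {
  co <- trajectory$coords
  for (f in seq_len(n_frames(trajectory))) {
    box <- trajectory$boxes[f, ]
    for (k in 1:3) co[, k, f] <- co[, k, f] %% box[k]
  }
  asd_trajectory(trajectory$topology, co, trajectory$times,
                 trajectory$boxes, wrapped = TRUE)
}

#' Unwrap a trajectory into continuous per-atom paths
#'
#' Two-step reconstruction: within each frame every molecule is made whole
#' (atoms moved to the image nearest the molecule's first atom — equivalent
#' to the bonded-chain traversal whenever the molecule diameter is below
#' half the box edge, where the whole-molecule reconstruction is unique);
#' across frames each molecule is translated by the lattice vector that
#' keeps its center-of-mass displacement between consecutive frames inside
#' the minimum-image cell. Valid when no molecule moves more than half a box
#' edge between frames.
#'
#' @param trajectory a wrapped `asd_trajectory`
#' @return an unwrapped `asd_trajectory` (`wrapped = FALSE`)
#' @export
unwrap_trajectory <- function(trajectory) {
  top <- trajectory$topology
  co <- trajectory$coords
  nf <- n_frames(trajectory)
  mol_ids <- top$molecules$molecule_id
  idx_list <- lapply(mol_ids, function(m) molecule_atoms(top, m))
  first_idx <- vapply(idx_list, `[`, integer(1), 1L)
  masses <- top$atoms$mass
  mol_of_atom <- match(top$atoms$molecule_id, mol_ids)
  mtot <- vapply(idx_list, function(i) sum(masses[i]), numeric(1))
  com_prev <- NULL
  for (f in seq_len(nf)) {
    box <- trajectory$boxes[f, ]
    pos <- co[, , f]
    # intra-frame: atoms to image nearest their molecule's first atom
    anchor <- pos[first_idx[mol_of_atom], , drop = FALSE]
    rel <- min_image_disp(pos - anchor, box)
    pos <- anchor + rel
    # inter-frame: molecule COM continuity
    wsum <- rowsum(pos * masses, mol_of_atom, reorder = TRUE)
    com <- wsum / mtot
    if (!is.null(com_prev)) {
      shift <- round((com - com_prev) / rep(box, each = nrow(com))) *
        rep(box, each = nrow(com))
      pos <- pos - shift[mol_of_atom, , drop = FALSE]
      com <- com - shift
    }
    com_prev <- com
    co[, , f] <- pos
  }
  asd_trajectory(top, co, trajectory$times, trajectory$boxes,
                 wrapped = FALSE)
}

#' Per-frame molecular centers of mass
#'
#' @param trajectory an `asd_trajectory`; unwrap first for continuous paths
#' @param molecule_ids molecules to include (default: all)
#' @return array `n_molecules x 3 x n_frames` of COM coordinates, nm, with
#'   `dimnames[[1]]` the molecule ids
#' @export
com_trajectory <- function(trajectory, molecule_ids = NULL) {
  top <- trajectory$topology
  if (is.null(molecule_ids)) molecule_ids <- top$molecules$molecule_id
  keep <- top$atoms$molecule_id %in% molecule_ids
  m <- top$atoms$mass[keep]
  grp <- match(top$atoms$molecule_id[keep], molecule_ids)
  nf <- n_frames(trajectory)
  out <- array(NA_real_, c(length(molecule_ids), 3, nf),
               dimnames = list(molecule_ids, NULL, NULL))
  mtot <- as.numeric(rowsum(m, grp, reorder = TRUE))
  for (f in seq_len(nf)) {
    pos <- trajectory$coords[keep, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(pos) <- c(sum(keep), 3)
    out[, , f] <- rowsum(pos * m, grp, reorder = TRUE) / mtot
  }
  out
}
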