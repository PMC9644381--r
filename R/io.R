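# Readers/writers for the supported on-disk trajectory formats.
#
# GRO series: standard GROMACS GRO frames concatenated; the title line must
# carry "t=<time in ps>"; fixed-column atom records; box line holds the
# three orthorhombic edges in nm. Velocities, if present, are ignored.
#
# Extended-XYZ dialect: line 1 atom count; line 2 key=value pairs including
# Lattice (9 floats, row-major; only the diagonal is used) and Time (ps);
# then one "element x y z" record per atom, coordinates in nm.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, X = 12.011)

guess_element_mass <- function(element) {
  m <- .element_masses[element]
  m[is.na(m)] <- .element_masses[["X"]]
  unname(m)
}

# fallback topology when no sidecar is supplied: one molecule per residue,
# water detected by residue name, no H-bond roles
infer_topology <- function(name, element, residue_label, residue_index) {
  mol_key <- paste(residue_index, residue_label)
  mol_id <- as.integer(factor(mol_key, levels = unique(mol_key))) - 1L
  kind <- ifelse(toupper(residue_label) %in% c("SOL", "WAT", "HOH"),
                 "water", "drug")
  atoms <- data.frame(
    atom_id = seq_along(name) - 1L, name = name, element = element,
    mass = guess_element_mass(element), residue_label = residue_label,
    residue_index = as.integer(residue_index), molecule_id = mol_id,
    donor = FALSE, polar_h = FALSE, acceptor = FALSE,
    donor_of = NA_integer_, stringsAsFactors = FALSE)
  mol <- data.frame(molecule_id = unique(mol_id),
                    kind = kind[!duplicated(mol_id)],
                    stringsAsFactors = FALSE)
  asd_topology(atoms, mol)
}

#' Read a trajectory from disk
#'
#' @param path path to a GRO coordinate series or extended-XYZ file
#' @param format `"gro_series"` or `"extxyz"`
#' @param topology optional [asd_topology()] (typically from
#'   [read_topology()]); when omitted a minimal topology without
#'   hydrogen-bond roles is inferred from the file
#' @return an [asd_trajectory()] with coordinates in nm and times in ps
#' @export
read_trajectory <- function(path, format = c("gro_series", "extxyz"),
                            topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  switch(format,
         gro_series = read_gro_series(lines, topology, path),
         extxyz = read_extxyz(lines, topology, path))
}

read_gro_series <- function(lines, topology, path) {
  frames <- list()
  i <- 1L
  frame_no <- 0L
  repeat {
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > length(lines)) break
    frame_no <- frame_no + 1L
    title <- lines[i]
    tm <- regmatches(title, regexpr("t=\\s*[-+0-9.eE]+", title))
    if (!length(tm))
      stop(sprintf("%s: frame %d title (line %d) lacks 't=<time>'",
                   path, frame_no, i))
    time <- as.numeric(sub("t=\\s*", "", tm))
    if (i + 1L > length(lines) ||
        is.na(nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))))
      stop(sprintf("%s: frame %d malformed atom-count line %d",
                   path, frame_no, i + 1L))
    last <- i + 1L + nat + 1L
    if (last > length(lines))
      stop(sprintf("%s: frame %d truncated (expected %d atoms + box)",
                   path, frame_no, nat))
    rec <- lines[(i + 2L):(i + 1L + nat)]
    if (any(nchar(rec) < 44))
      stop(sprintf("%s: frame %d has a short atom record (line %d)",
                   path, frame_no,
                   i + 1L + which(nchar(rec) < 44)[1]))
    resno <- as.integer(substr(rec, 1, 5))
    resnm <- trimws(substr(rec, 6, 10))
    atnm <- trimws(substr(rec, 11, 15))
    x <- as.numeric(substr(rec, 21, 28))
    y <- as.numeric(substr(rec, 29, 36))
    z <- as.numeric(substr(rec, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop(sprintf("%s: frame %d unparsable coordinates", path, frame_no))
    box <- as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]])[1:3]
    if (anyNA(box))
      stop(sprintf("%s: frame %d malformed box line %d", path, frame_no,
                   last))
    frames[[frame_no]] <- list(time = time, box = box,
                               pos = cbind(x, y, z),
                               resno = resno, resnm = resnm, atnm = atnm)
    i <- last + 1L
  }
  if (!length(frames)) stop(path, ": no frames found")
  nat <- nrow(frames[[1]]$pos)
  bad <- which(vapply(frames, function(f) nrow(f$pos), integer(1)) != nat)
  if (length(bad))
    stop(sprintf("%s: frame %d atom count differs from frame 1", path,
                 bad[1]))
  if (is.null(topology)) {
    f1 <- frames[[1]]
    el <- toupper(substr(f1$atnm, 1, 1))
    topology <- infer_topology(f1$atnm, el, f1$resnm, f1$resno)
  }
  assemble_frames(topology, frames)
}

read_extxyz <- function(lines, topology, path) {
  frames <- list()
  i <- 1L
  frame_no <- 0L
  repeat {
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > length(lines)) break
    frame_no <- frame_no + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop(sprintf("%s: frame %d malformed atom-count line %d", path,
                   frame_no, i))
    if (i + 1L + nat > length(lines))
      stop(sprintf("%s: frame %d truncated", path, frame_no))
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    tm <- regmatches(hdr, regexpr("Time=[-+0-9.eE]+", hdr))
    if (!length(lat) || !length(tm))
      stop(sprintf("%s: frame %d header (line %d) needs Lattice and Time",
                   path, frame_no, i + 1L))
    lat9 <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                                "\\s+")[[1]])
    if (length(lat9) != 9 || anyNA(lat9))
      stop(sprintf("%s: frame %d Lattice must hold 9 floats", path,
                   frame_no))
    box <- lat9[c(1, 5, 9)]
    time <- as.numeric(sub("Time=", "", tm))
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    if (any(lengths(rec) < 4))
      stop(sprintf("%s: frame %d has a short atom record", path, frame_no))
    el <- vapply(rec, `[`, character(1), 1L)
    pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(pos))
      stop(sprintf("%s: frame %d unparsable coordinates", path, frame_no))
    frames[[frame_no]] <- list(time = time, box = box, pos = pos,
                               resno = rep(1L, nat), resnm = rep("MOL", nat),
                               atnm = el, el = el)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop(path, ": no frames found")
  nat <- nrow(frames[[1]]$pos)
  bad <- which(vapply(frames, function(f) nrow(f$pos), integer(1)) != nat)
  if (length(bad))
    stop(sprintf("%s: frame %d atom count differs from frame 1", path,
                 bad[1]))
  if (is.null(topology)) {
    f1 <- frames[[1]]
    topology <- infer_topology(f1$el, f1$el, f1$resnm,
                               seq_len(nat))
  }
  assemble_frames(topology, frames)
}

assemble_frames <- function(topology, frames) {
  nat <- nrow(frames[[1]]$pos)
  if (nat != n_atoms(topology))
    stop("trajectory atom count does not match topology")
  nf <- length(frames)
  co <- array(NA_real_, c(nat, 3, nf))
  boxes <- matrix(NA_real_, nf, 3)
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    co[, , f] <- frames[[f]]$pos
    boxes[f, ] <- frames[[f]]$box
    times[f] <- frames[[f]]$time
  }
  asd_trajectory(topology, co, times, boxes, wrapped = TRUE)
}

#' Write a trajectory to disk
#'
#' @param trajectory an [asd_trajectory()]
#' @param path output file
#' @param format `"gro_series"` (positions at GRO's 3-decimal precision) or
#'   `"extxyz"` (full precision)
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("gro_series", "extxyz")) {
  format <- match.arg(format)
  top <- trajectory$topology
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    pos <- trajectory$coords[, , f]
    box <- trajectory$boxes[f, ]
    t_ps <- trajectory$times[f]
    if (format == "gro_series") {
      writeLines(sprintf("frame t= %.5f", t_ps), con)
      writeLines(sprintf("%5d", nrow(a)), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$residue_index %% 100000L,
                         substr(a$residue_label, 1, 5),
                         substr(a$name, 1, 5),
                         (seq_len(nrow(a))) %% 100000L,
                         pos[, 1], pos[, 2], pos[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]),
                 con)
    } else {
      writeLines(sprintf("%d", nrow(a)), con)
      writeLines(sprintf(
        'Lattice="%.9g 0 0 0 %.9g 0 0 0 %.9g" Time=%.9g Properties=species:S:1:pos:R:3',
        box[1], box[2], box[3], t_ps), con)
      writeLines(sprintf("%-3s %.9g %.9g %.9g", a$element,
                         pos[, 1], pos[, 2], pos[, 3]), con)
    }
  }
  invisible(path)
}
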