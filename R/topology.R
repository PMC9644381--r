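# Topology data model: atoms, molecules, donor-hydrogen pairing.
# Internal units throughout the package: nm, ps, Da.
# Diffusivities are reported in 1e-9 cm^2/s (see mobility.R for the constant).

#' Construct a system topology
#'
#' A topology is the static description of a periodic molecular system:
#' which atoms exist, which molecule each belongs to, atom masses, residue
#' labels, and hydrogen-bonding roles (donor, polar hydrogen, acceptor).
#' Polar hydrogens are covalently assigned to exactly one donor heavy atom
#' via `donor_of`.
#'
#' @param atoms data.frame with columns `atom_id` (0-based integer), `name`,
#'   `element`, `mass` (Da, > 0), `residue_label` (3-letter code or molecule
#'   name), `residue_index` (integer), `molecule_id` (0-based integer),
#'   `donor`, `polar_h`, `acceptor` (logical role flags; an atom may be both
#'   donor and acceptor), `donor_of` (for polar hydrogens, the `atom_id` of
#'   the attached donor; `NA` otherwise).
#' @param molecules data.frame with columns `molecule_id` (0-based integer)
#'   and `kind` (one of `"protein"`, `"drug"`, `"water"`).
#' @return An object of class `"asd_topology"`.
#' @export
asd_topology <- function(atoms, molecules) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  molecules <- as.data.frame(molecules, stringsAsFactors = FALSE)
  required <- c("atom_id", "name", "element", "mass", "residue_label",
                "residue_index", "molecule_id", "donor", "polar_h",
                "acceptor", "donor_of")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  if (!all(molecules$kind %in% c("protein", "drug", "water")))
    stop("molecule kind must be protein, drug or water")
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom_id")
  if (anyDuplicated(molecules$molecule_id)) stop("duplicate molecule_id")
  if (!all(atoms$molecule_id %in% molecules$molecule_id))
    stop("atom references unknown molecule_id")
  # every polar hydrogen carries exactly one donor assignment
  ph <- atoms$polar_h
  if (any(ph & is.na(atoms$donor_of)))
    stop("polar hydrogen without an assigned donor atom")
  if (any(!is.na(atoms$donor_of) & !ph))
    stop("donor_of set on a non-hydrogen atom")
  dh <- atoms[ph, , drop = FALSE]
  if (nrow(dh)) {
    if (!all(dh$donor_of %in% atoms$atom_id[atoms$donor]))
      stop("polar hydrogen assigned to a non-donor atom")
    same_mol <- atoms$molecule_id[match(dh$donor_of, atoms$atom_id)] ==
      dh$molecule_id
    if (!all(same_mol)) stop("donor-hydrogen pair spans two molecules")
  }
  n_water_atoms <- table(atoms$molecule_id[atoms$molecule_id %in%
    molecules$molecule_id[molecules$kind == "water"]])
  if (length(n_water_atoms) && any(n_water_atoms != 3L))
    stop("water molecules must have exactly 3 atoms")
  rownames(atoms) <- NULL
  rownames(molecules) <- NULL
  top <- structure(list(atoms = atoms, molecules = molecules),
                   class = "asd_topology")
  top
}

#' @export
print.asd_topology <- function(x, ...) {
  k <- table(x$molecules$kind)
  cat(sprintf("asd_topology: %d atoms, %d molecules (%s)\n",
              nrow(x$atoms), nrow(x$molecules),
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology an `asd_topology`
#' @return integer
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Atom row indices (1-based) of a molecule
#' @param topology an `asd_topology`
#' @param molecule_id 0-based molecule id
#' @return integer vector of row indices into `topology$atoms`
#' @export
molecule_atoms <- function(topology, molecule_id) {
  which(topology$atoms$molecule_id == molecule_id)
}

#' Donor-hydrogen pairs
#'
#' @param topology an `asd_topology`
#' @return two-column integer matrix (`donor_atom_id`, `hydrogen_atom_id`),
#'   0-based atom ids, one row per covalent donor-H pair.
#' @export
donor_hydrogen_pairs <- function(topology) {
  a <- topology$atoms
  h <- a[a$polar_h, , drop = FALSE]
  cbind(donor_atom_id = h$donor_of, hydrogen_atom_id = h$atom_id)
}

#' Molecule ids of a given kind
#' @param topology an `asd_topology`
#' @param kind `"protein"`, `"drug"` or `"water"`
#' @return integer vector of molecule ids
#' @export
molecules_of_kind <- function(topology, kind) {
  topology$molecules$molecule_id[topology$molecules$kind == kind]
}

#' Read a topology sidecar table
#'
#' The sidecar is a tab-separated table with one row per atom and columns
#' `molecule_id`, `kind`, `residue_label`, `residue_index`, `name`,
#' `element`, `mass`, `roles`, `donor_of`. `roles` is a comma-separated
#' subset of `donor,polar_h,acceptor` (or `none`); `donor_of` is the 1-based
#' atom number of the attached donor for polar hydrogens, `0` otherwise.
#' Atom ids are assigned 0-based in file order (files are 1-based).
#'
#' @param path file path
#' @return an `asd_topology`
#' @export
read_topology <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  roles <- strsplit(tab$roles, ",", fixed = TRUE)
  atoms <- data.frame(
    atom_id = seq_len(nrow(tab)) - 1L,
    name = as.character(tab$name),
    element = as.character(tab$element),
    mass = as.numeric(tab$mass),
    residue_label = as.character(tab$residue_label),
    residue_index = as.integer(tab$residue_index),
    molecule_id = as.integer(tab$molecule_id),
    donor = vapply(roles, function(r) "donor" %in% r, logical(1)),
    polar_h = vapply(roles, function(r) "polar_h" %in% r, logical(1)),
    acceptor = vapply(roles, function(r) "acceptor" %in% r, logical(1)),
    donor_of = ifelse(tab$donor_of > 0L, as.integer(tab$donor_of) - 1L,
                      NA_integer_),
    stringsAsFactors = FALSE)
  mol <- unique(data.frame(molecule_id = as.integer(tab$molecule_id),
                           kind = as.character(tab$kind),
                           stringsAsFactors = FALSE))
  asd_topology(atoms, mol)
}

#' Write a topology sidecar table
#' @param topology an `asd_topology`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_topology <- function(topology, path) {
  a <- topology$atoms
  kind <- topology$molecules$kind[match(a$molecule_id,
                                        topology$molecules$molecule_id)]
  roles <- mapply(function(d, h, ac) {
    r <- c("donor", "polar_h", "acceptor")[c(d, h, ac)]
    if (!length(r)) "none" else paste(r, collapse = ",")
  }, a$donor, a$polar_h, a$acceptor)
  tab <- data.frame(molecule_id = a$molecule_id, kind = kind,
                    residue_label = a$residue_label,
                    residue_index = a$residue_index,
                    name = a$name, element = a$element, mass = a$mass,
                    roles = roles,
                    donor_of = ifelse(is.na(a$donor_of), 0L,
                                      a$donor_of + 1L),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# run fn with a private RNG stream; caller's RNG state untouched
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
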