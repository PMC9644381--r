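# Full-analysis orchestration: shells -> hydrogen bonds -> generations ->
# mobility -> cross-tabulations, from one declarative config, with
# machine-readable TSV/JSON outputs and a manifest.

#' Build a run configuration
#'
#' All defaults are the named analysis presets: 0.35 nm / 30 degree
#' hydrogen-bond criterion, 0.80 / 0.50 stability thresholds, 0.4 nm
#' shells, 1/5/10 Angstrom displacement classes, MSD fit over lags
#' 1-10% of the window.
#'
#' @param trajectory an [asd_trajectory()], or `NULL` if `traj_path` given
#' @param traj_path,traj_format,top_path on-disk inputs (used when
#'   `trajectory` is `NULL`)
#' @param window analysis window spec (frame indices, range or `"last:N"`)
#' @param d_cut,angle_cut,vertex hydrogen-bond criterion
#' @param threshold_protein_drug,threshold_other stability thresholds
#' @param shell_width,fds_cutoff shell geometry, nm
#' @param displacement_thresholds Angstrom class limits
#' @param fit_window,max_lag MSD fit parameters (lag fractions of
#'   the analysis window; see [fit_diffusivity()])
#' @param out_dir output directory (created if missing)
#' @param seed seed for any subsampling (recorded in the manifest)
#' @return an `"asd_run_config"` list
#' @export
run_config <- function(trajectory = NULL, traj_path = NULL,
                       traj_format = "extxyz", top_path = NULL,
                       window = NULL, d_cut = 0.35, angle_cut = 30,
                       vertex = "donor",
                       threshold_protein_drug = 0.80,
                       threshold_other = 0.50,
                       shell_width = 0.4, fds_cutoff = 0.4,
                       displacement_thresholds = c(1, 5, 10),
                       fit_window = c(0.01, 0.1), max_lag = 0.5,
                       out_dir = tempfile("asd_run_"), seed = 1L) {
  if (is.null(trajectory) && is.null(traj_path))
    stop("config error: either trajectory or traj_path is required")
  num <- c(d_cut = d_cut, angle_cut = angle_cut,
           threshold_protein_drug = threshold_protein_drug,
           threshold_other = threshold_other, shell_width = shell_width,
           fds_cutoff = fds_cutoff, displacement_thresholds,
           fit_window_hi = fit_window[2], max_lag = max_lag)
  if (any(num <= 0)) stop("config error: numeric parameters must be > 0")
  structure(as.list(environment()), class = "asd_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Deterministic for fixed inputs and config. Emits the shell table,
#' hydrogen-bond existence matrix (TSV + JSON index), stable-bond set,
#' generation assignment, residue ranking, per-molecule diffusivity
#' records, group summaries, distance and diffusivity histograms, and a
#' JSON manifest of parameters and artifact files. Partial outputs are
#' retained next to a `FAILED` marker naming the failing stage.
#'
#' @param config an [run_config()]
#' @return invisibly, a list with all in-memory results and
#'   `manifest_path`
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "asd_run_config"))
  cf <- config
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(cf$out_dir, f)
  artifacts <- character(0)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), art("FAILED"))
    stop(e)
  }
  tryCatch({
    traj <- stage("input", {
      if (!is.null(cf$trajectory)) cf$trajectory else {
        topo <- if (!is.null(cf$top_path)) read_topology(cf$top_path)
                else NULL
        read_trajectory(cf$traj_path, cf$traj_format, topo)
      }
    })
    win <- resolve_window(traj, cf$window)

    shells <- stage("shells", shell_table(traj, win, cf$shell_width,
                                          cf$fds_cutoff))
    utils::write.table(shells, art("shell_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "shell_table.tsv")

    dist_hist <- stage("shells", distance_histogram(traj, win,
                                                    table = shells))
    utils::write.table(dist_hist, art("distance_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "distance_histogram.tsv")

    hmat <- stage("hbonds", build_existence_matrix(
      traj, win, cf$d_cut, cf$angle_cut, cf$vertex))
    write_existence_matrix(hmat, traj$topology,
                           art("existence_matrix.tsv"),
                           art("hbond_index.json"))
    artifacts <- c(artifacts, "existence_matrix.tsv", "hbond_index.json")

    stable <- stage("stability", classify_stable(
      hmat, cf$threshold_protein_drug, cf$threshold_other))
    utils::write.table(stable, art("stable_bonds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "stable_bonds.tsv")

    gens <- stage("generations", assign_generations(stable,
                                                    traj$topology))
    utils::write.table(gens, art("generations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "generations.tsv")

    resrank <- stage("residues", rank_residues(hmat, traj$topology))
    utils::write.table(resrank, art("residue_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "residue_ranking.tsv")

    mobility <- stage("mobility", {
      unwrapped <- unwrap_trajectory(traj)
      ref <- subtract_protein_motion(unwrapped, win)
      # group labels: shell at window start, bonding status
      first_frame <- shells[shells$frame == win[1], ]
      shell_start <- stats::setNames(first_frame$shell_index,
                                     first_frame$molecule_id)
      status <- bonded_status_labels(gens, stable, hmat,
                                     traj$topology)
      rec <- diffusivity_records(ref$trajectory, "drug", cf$max_lag,
                                 cf$fit_window, shell_start, status)
      list(records = rec, ref = ref)
    })
    rec <- mobility$records
    utils::write.table(as.data.frame(rec), art("diffusivity_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "diffusivity_records.tsv")

    ddist <- stage("mobility", diffusivity_distribution(rec))
    utils::write.table(ddist$histogram, art("diffusivity_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "diffusivity_histogram.tsv")

    groups <- stage("groups", list(
      by_shell = group_diffusivity(rec, "shell_index"),
      by_status = group_diffusivity(rec, "bonded_status"),
      overall = group_diffusivity(rec, "none"),
      crosstab = crosstab_mobility_bonding(rec)))
    jsonlite::write_json(groups, art("group_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    artifacts <- c(artifacts, "group_summary.json")

    disp <- stage("displacement", displacement_classes(
      mobility$ref$trajectory, NULL, cf$displacement_thresholds,
      "molecule"))
    utils::write.table(disp, art("displacement_classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "displacement_classes.tsv")

    manifest <- list(
      package = "asdtraj",
      version = as.character(utils::packageVersion("asdtraj")),
      parameters = list(
        window = paste(range(win), collapse = ":"),
        d_cut = cf$d_cut, angle_cut = cf$angle_cut, vertex = cf$vertex,
        threshold_protein_drug = cf$threshold_protein_drug,
        threshold_other = cf$threshold_other,
        shell_width = cf$shell_width, fds_cutoff = cf$fds_cutoff,
        displacement_thresholds = cf$displacement_thresholds,
        fit_window = cf$fit_window, max_lag = cf$max_lag,
        seed = cf$seed),
      artifacts = artifacts)
    jsonlite::write_json(manifest, art("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(shells = shells, distance_histogram = dist_hist,
                   hbond_matrix = hmat, stable_bonds = stable,
                   generations = gens, residue_ranking = resrank,
                   diffusivity = rec, diffusivity_distribution = ddist,
                   groups = groups, displacement = disp,
                   manifest = manifest,
                   manifest_path = art("manifest.json")))
  }, error = on_fail)
}

# per-drug-molecule bonding status: gen1 / gen2 / bonded_any / nonbonded
bonded_status_labels <- function(gens, stable, hmat, topology) {
  drugs <- molecules_of_kind(topology, "drug")
  status <- rep("nonbonded", length(drugs))
  names(status) <- drugs
  bonded_mols <- unique(c(stable$donor_molecule_id,
                          stable$acceptor_molecule_id))
  status[as.character(intersect(drugs, bonded_mols))] <- "bonded_any"
  g <- gens$generation[match(drugs, gens$molecule_id)]
  status[!is.na(g) & g == 2] <- "gen2"
  status[!is.na(g) & g == 1] <- "gen1"
  status
}

#' Cross-tabulate mean diffusivity by shell and bonding status
#'
#' @param records an `"asd_diffusivity"` data.frame with `shell_index` and
#'   `bonded_status` labels
#' @return data.frame `shell_index`, `bonded_status`, `n`, `mean_D`;
#'   empty cells have `n = 0` and `mean_D = NA`
#' @export
crosstab_mobility_bonding <- function(records) {
  r <- records
  shells <- sort(unique(r$shell_index))
  statuses <- sort(unique(r$bonded_status))
  if (!length(shells) || !length(statuses))
    return(data.frame(shell_index = integer(), bonded_status = character(),
                      n = integer(), mean_D = numeric()))
  grid <- expand.grid(shell_index = shells, bonded_status = statuses,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$mean_D <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- r$shell_index == grid$shell_index[i] &
      r$bonded_status == grid$bonded_status[i]
    sel[is.na(sel)] <- FALSE
    grid$n[i] <- sum(sel)
    if (any(sel)) grid$mean_D[i] <- mean(r$D[sel])
  }
  grid
}
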