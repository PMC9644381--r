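# Per-molecule displacement, MSD and diffusivity in the protein reference
# frame, plus group statistics, distributional summaries and displacement
# classes.
#
# Unit constant: MSD slopes are in nm^2/ps. 1 nm^2/ps = 1e-14 cm^2 / 1e-12 s
# = 1e-2 cm^2/s, so D [1e-9 cm^2/s] = slope/6 [nm^2/ps] * 1e7.

NM2_PER_PS_TO_1E9_CM2_S <- 1e7

#' Subtract protein motion from a trajectory
#'
#' Per frame, subtracts the displacement of the joint protein center of
#' mass relative to the window's first frame from all coordinates, so the
#' protein serves as the reference frame for molecular mobility. The
#' transform is a rigid global translation per frame: all intra-frame
#' distances are unchanged.
#'
#' @param trajectory an unwrapped [asd_trajectory()] (see
#'   [unwrap_trajectory()])
#' @param window analysis window; the returned trajectory covers exactly
#'   these frames
#' @return list with `trajectory` (protein-referenced, unwrapped) and
#'   `drift` (`n_frames x 3` matrix of the subtracted protein displacement,
#'   nm). With no protein present the transform is the identity and a
#'   warning is emitted.
#' @export
subtract_protein_motion <- function(trajectory, window = NULL) {
  idx <- resolve_window(trajectory, window)
  top <- trajectory$topology
  prot <- protein_atom_rows(top)
  co <- trajectory$coords[, , idx, drop = FALSE]
  if (!length(prot)) {
    warning("no protein molecules; protein-frame transform is the identity")
    drift <- matrix(0, length(idx), 3)
  } else {
    m <- top$atoms$mass[prot]
    com <- t(apply(co[prot, , , drop = FALSE], 3, function(p) {
      dim(p) <- c(length(prot), 3)
      colSums(p * m) / sum(m)
    }))
    drift <- sweep(com, 2, com[1, ])
    for (j in seq_along(idx))
      for (k in 1:3) co[, k, j] <- co[, k, j] - drift[j, k]
  }
  list(trajectory = asd_trajectory(top, co, trajectory$times[idx],
                                   trajectory$boxes[idx, , drop = FALSE],
                                   wrapped = FALSE),
       drift = drift)
}

#' Mean squared displacement of one molecule
#'
#' Time-origin-averaged MSD of the molecule's center of mass:
#' `MSD(tau) = <|r(t + tau) - r(t)|^2>_t` over all valid origins.
#'
#' @param trajectory an unwrapped, protein-referenced [asd_trajectory()]
#' @param molecule_id molecule id
#' @param max_lag maximum lag as a fraction of the window length
#'   (default 0.5)
#' @param com optional precomputed `n_frames x 3` COM path, nm (skips the
#'   per-frame COM computation)
#' @return data.frame `lag_ps`, `msd_nm2`, starting at lag 0 with MSD 0
#' @export
per_molecule_msd <- function(trajectory, molecule_id, max_lag = 0.5,
                             com = NULL) {
  if (is.null(com)) {
    ca <- com_trajectory(trajectory, molecule_id)
    com <- t(ca[1, , ])
  }
  nf <- nrow(com)
  if (nf < 10) stop("need at least 10 frames for an MSD")
  times <- trajectory$times[seq_len(nf)]
  nlag <- max(1L, floor(max_lag * (nf - 1L)))
  msd <- numeric(nlag + 1L)
  for (L in seq_len(nlag)) {
    d <- com[(1L + L):nf, , drop = FALSE] - com[1:(nf - L), , drop = FALSE]
    msd[L + 1L] <- mean(rowSums(d * d))
  }
  data.frame(lag_ps = c(0, times[1L + seq_len(nlag)] - times[1]),
             msd_nm2 = msd)
}

#' Fit a diffusion coefficient from an MSD curve
#'
#' Least-squares line over the lag window; in three dimensions
#' `MSD = 6 D tau`, so `D = slope / 6` converted from nm^2/ps to
#' 1e-9 cm^2/s. Negative slopes (finite-sampling artifacts) are clipped to
#' zero and flagged.
#'
#' @param msd_curve data.frame from [per_molecule_msd()]
#' @param fit_window lag range as fractions of the analysis-window length
#'   (default `c(0.01, 0.1)`: lags between 1% and 10% of the window).
#'   Short lags carry far less time-averaging variance — the relative
#'   variance of a time-averaged MSD grows with lag/window — so a
#'   short-lag fit is what lets planted diffusivities be recovered within
#'   a few percent; there is no ballistic regime to avoid at >= ps frame
#'   spacing in dense amorphous systems.
#' @param max_lag the `max_lag` fraction the curve was built with
#'   (default 0.5), used to convert `fit_window` to curve-relative lags
#' @return list `D` (1e-9 cm^2/s), `slope_nm2_ps`, `fit_r2`, `clipped`,
#'   `fit_window_ps`
#' @export
fit_diffusivity <- function(msd_curve, fit_window = c(0.01, 0.1),
                            max_lag = 0.5) {
  lag_max <- max(msd_curve$lag_ps)
  window_len <- lag_max / max_lag
  lo <- fit_window[1] * window_len
  hi <- fit_window[2] * window_len
  keep <- msd_curve$lag_ps >= lo & msd_curve$lag_ps <= hi &
    msd_curve$lag_ps > 0
  if (sum(keep) < 2) stop("degenerate fit window: fewer than 2 lag points")
  x <- msd_curve$lag_ps[keep]
  y <- msd_curve$msd_nm2[keep]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  clipped <- slope < 0
  D <- max(slope, 0) / 6 * NM2_PER_PS_TO_1E9_CM2_S
  list(D = D, slope_nm2_ps = slope, fit_r2 = r2, clipped = clipped,
       fit_window_ps = c(lo, hi))
}

#' Diffusivity records for all molecules of a kind
#'
#' Convenience wrapper: COM paths, MSD curves and diffusivity fits for
#' every molecule of `kind`, with group labels (shell index at the window
#' start, hydrogen-bonding status) attached when provided.
#'
#' @param trajectory an unwrapped, protein-referenced [asd_trajectory()]
#' @param kind molecule kind to analyse (default `"drug"`)
#' @param max_lag,fit_window see [per_molecule_msd()], [fit_diffusivity()]
#' @param shell_start optional named vector: shell index per molecule id at
#'   the window start
#' @param bonded_status optional named character vector per molecule id
#'   (`"gen1"`, `"gen2"`, `"bonded_any"`, `"nonbonded"`)
#' @return data.frame of class `"asd_diffusivity"`: `molecule_id`, `D`,
#'   `slope_nm2_ps`, `fit_r2`, `clipped`, `shell_index`, `bonded_status`;
#'   MSD curves in `attr(, "msd_curves")`
#' @export
diffusivity_records <- function(trajectory, kind = "drug", max_lag = 0.5,
                                fit_window = c(0.01, 0.1),
                                shell_start = NULL, bonded_status = NULL) {
  ids <- molecules_of_kind(trajectory$topology, kind)
  if (!length(ids)) stop("no molecules of kind ", kind)
  coms <- com_trajectory(trajectory, ids)
  curves <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    curve <- per_molecule_msd(trajectory, ids[i], max_lag,
                              com = t(coms[i, , ]))
    if (i == 1L) {
      # short windows: widen the fit range to the two smallest positive
      # lags so few-frame trajectories remain analysable
      wl <- max(curve$lag_ps) / max_lag
      in_win <- curve$lag_ps > 0 & curve$lag_ps >= fit_window[1] * wl &
        curve$lag_ps <= fit_window[2] * wl
      if (sum(in_win) < 2) {
        pos <- sort(curve$lag_ps[curve$lag_ps > 0])
        fit_window <- c(0, pos[2] / wl)
      }
    }
    fit <- fit_diffusivity(curve, fit_window, max_lag)
    curves[[i]] <- curve
    rows[[i]] <- data.frame(molecule_id = ids[i], D = fit$D,
                            slope_nm2_ps = fit$slope_nm2_ps,
                            fit_r2 = fit$fit_r2, clipped = fit$clipped)
  }
  out <- do.call(rbind, rows)
  out$shell_index <- if (is.null(shell_start)) NA_integer_ else
    as.integer(shell_start[as.character(out$molecule_id)])
  out$bonded_status <- if (is.null(bonded_status)) NA_character_ else
    as.character(bonded_status[as.character(out$molecule_id)])
  names(curves) <- ids
  attr(out, "msd_curves") <- curves
  class(out) <- c("asd_diffusivity", "data.frame")
  out
}

#' Group mean diffusivities
#'
#' Arithmetic mean of per-molecule D within groups. Supports the three
#' canonical series: all molecules; excluding generation-1/2 bonded
#' molecules; excluding every molecule hydrogen-bonded more than half the
#' time — optionally crossed with shell index. Empty groups are reported
#' with `n = 0` and `mean_D = NA`.
#'
#' @param records an `"asd_diffusivity"` data.frame
#' @param by grouping column (`"shell_index"`, `"bonded_status"`) or
#'   `"none"` for a single overall group
#' @param exclude optional character vector of molecule ids to drop before
#'   averaging (the "custom exclusion set")
#' @return data.frame `group`, `n`, `mean_D`
#' @export
group_diffusivity <- function(records, by = c("none", "shell_index",
                                              "bonded_status"),
                              exclude = NULL) {
  by <- match.arg(by)
  r <- records
  if (!is.null(exclude))
    r <- r[!(r$molecule_id %in% exclude), , drop = FALSE]
  if (!nrow(r))
    return(data.frame(group = "all", n = 0L, mean_D = NA_real_))
  g <- if (by == "none") rep("all", nrow(r)) else as.character(r[[by]])
  agg <- tapply(r$D, g, mean)
  cnt <- tapply(r$D, g, length)
  out <- data.frame(group = names(agg), n = as.integer(cnt),
                    mean_D = as.numeric(agg))
  rownames(out) <- NULL
  out
}

#' Diffusivity histogram and cumulative contribution curve
#'
#' Histogram of per-molecule D plus the cumulative contribution curve:
#' molecules sorted by D ascending, cumulative sum of D over total D
#' against the molecule quantile. Also reports the D level at which the
#' curve crosses 90% of the total.
#'
#' @param records an `"asd_diffusivity"` data.frame
#' @param bin_width histogram bin width in 1e-9 cm^2/s (default: 1/40 of
#'   the D range, floor 1e-4)
#' @param level crossing level of total diffusivity to report
#'   (default 0.9)
#' @return list `histogram` (data.frame `bin_lo`, `bin_hi`, `count`,
#'   `fraction`), `cumulative` (data.frame `quantile`, `D`,
#'   `cum_fraction`), `d_at_level` (D where the curve first reaches
#'   `level`; `NA` when total D is 0)
#' @export
diffusivity_distribution <- function(records, bin_width = NULL,
                                     level = 0.9) {
  if (!nrow(records)) stop("need at least one diffusivity record")
  D <- sort(records$D)
  n <- length(D)
  if (is.null(bin_width))
    bin_width <- max(diff(range(D)) / 40, 1e-4)
  k <- floor(D / bin_width)
  kk <- seq.int(0L, max(k))
  cnt <- tabulate(k + 1L, nbins = max(k) + 1L)
  hist <- data.frame(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
                     count = cnt, fraction = cnt / sum(cnt))
  tot <- sum(D)
  cum <- if (tot > 0) cumsum(D) / tot else rep(0, n)
  curve <- data.frame(quantile = seq_len(n) / n, D = D, cum_fraction = cum)
  d_at <- if (tot > 0) D[which(cum >= level)[1]] else NA_real_
  list(histogram = hist, cumulative = curve, d_at_level = d_at,
       level = level)
}

#' Displacement classes relative to the window start
#'
#' For each molecule (COM) or atom, the maximum displacement from its
#' position in the window's first frame, in Angstrom, classified against
#' increasing thresholds: the class is the smallest threshold not
#' exceeded, or `"above-max"`.
#'
#' @param trajectory an unwrapped, protein-referenced [asd_trajectory()]
#' @param window analysis window
#' @param thresholds class upper limits in Angstrom (default `c(1, 5, 10)`)
#' @param level `"molecule"` (COM displacement of drug molecules) or
#'   `"atom"` (per-atom, all kinds)
#' @return data.frame `id` (molecule or atom id), `max_disp_A`, `class`
#'   (ordered factor over threshold labels plus `"above-max"`)
#' @export
displacement_classes <- function(trajectory, window = NULL,
                                 thresholds = c(1, 5, 10),
                                 level = c("molecule", "atom")) {
  level <- match.arg(level)
  idx <- resolve_window(trajectory, window)
  thresholds <- sort(thresholds)
  if (level == "molecule") {
    ids <- molecules_of_kind(trajectory$topology, "drug")
    coms <- com_trajectory(trajectory, ids)[, , idx, drop = FALSE]
    ref <- coms[, , 1]
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
    dmax <- rep(0, length(ids))
    for (j in seq_along(idx)) {
      d <- coms[, , j, drop = FALSE]
      dim(d) <- c(length(ids), 3)
      dmax <- pmax(dmax, sqrt(rowSums((d - ref)^2)))
    }
  } else {
    ids <- trajectory$topology$atoms$atom_id
    co <- trajectory$coords[, , idx, drop = FALSE]
    ref <- co[, , 1]
    dmax <- rep(0, length(ids))
    for (j in seq_along(idx))
      dmax <- pmax(dmax, sqrt(rowSums((co[, , j] - ref)^2)))
  }
  disp_A <- dmax * 10  # nm -> Angstrom
  labels <- c(sprintf("<=%gA", thresholds), "above-max")
  cls <- labels[findInterval(disp_A, thresholds, left.open = TRUE) + 1L]
  data.frame(id = ids, max_disp_A = disp_A,
             class = factor(cls, levels = labels, ordered = TRUE))
}
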