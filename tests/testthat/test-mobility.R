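test_that("MSD closed forms: ballistic and frozen", {
  v <- c(0.01, -0.005, 0.002)
  tr <- ballistic_trajectory(v, nf = 200, dt = 2)
  msd <- per_molecule_msd(tr, 0L)
  expect_equal(msd$msd_nm2[1], 0)
  pred <- sum(v^2) * msd$lag_ps^2
  expect_equal(msd$msd_nm2, pred, tolerance = 1e-10)
  # frozen molecule
  tr0 <- ballistic_trajectory(c(0, 0, 0), nf = 50)
  msd0 <- per_molecule_msd(tr0, 0L)
  expect_true(all(msd0$msd_nm2 == 0))
  expect_error(per_molecule_msd(ballistic_trajectory(nf = 5), 0L),
               "10 frames")
})

test_that("fit_diffusivity: unit constant, clipping, degenerate window", {
  # MSD = 6 tau nm^2 (tau in ps) -> slope 6 nm^2/ps -> D = 1 nm^2/ps
  # = 1e-2 cm^2/s = 1e7 in units of 1e-9 cm^2/s
  curve <- data.frame(lag_ps = 0:100, msd_nm2 = 6 * (0:100))
  fit <- fit_diffusivity(curve, fit_window = c(0.1, 0.5))
  expect_equal(fit$D, 1e7)
  expect_equal(fit$fit_r2, 1)
  # flat curve
  flat <- data.frame(lag_ps = 0:100, msd_nm2 = rep(0, 101))
  expect_equal(fit_diffusivity(flat)$D, 0)
  # negative slope clipped and flagged
  neg <- data.frame(lag_ps = 0:100, msd_nm2 = seq(1, 0, length.out = 101))
  fneg <- fit_diffusivity(neg)
  expect_equal(fneg$D, 0)
  expect_true(fneg$clipped)
  expect_error(fit_diffusivity(curve, fit_window = c(0.4999, 0.5)),
               "degenerate")
})

test_that("planted Brownian D is recovered (ensemble and single)", {
  sim <- simulate_asd(generator_config(seed = 31, n_drug = 50,
                                       n_frames = 800, n_protein = 0,
                                       drug_D = 1.0))
  ref <- suppressWarnings(
    subtract_protein_motion(unwrap_trajectory(sim$trajectory)))
  rec <- diffusivity_records(ref$trajectory)
  expect_lt(abs(mean(rec$D) - 1.0), 0.15)
  # single molecules are noisier but unbiased in the median
  expect_lt(abs(stats::median(rec$D) - 1.0), 0.35)
})

test_that("protein-frame subtraction: drift recovery and rigidity", {
  cfg <- generator_config(seed = 12, n_drug = 5, n_frames = 50,
                          drug_D = 0.5, box_edges = c(8, 8, 8),
                          protein_drift = c(2e-4, -1e-4, 5e-5))
  sim <- simulate_asd(cfg)
  un <- unwrap_trajectory(sim$trajectory)
  ref <- subtract_protein_motion(un)
  expect_lt(max(abs(ref$drift - sim$truth$drift)), 1e-9)
  # inter-molecular distances within a frame unchanged (rigid translation)
  f <- 25
  keep <- c(1, 20, 40, 60, 80)
  d_before <- dist(un$coords[keep, , f])
  d_after <- dist(ref$trajectory$coords[keep, , f])
  expect_equal(as.numeric(d_after), as.numeric(d_before),
               tolerance = 1e-12)
  # whole-box rigid translation: all displacements become zero
  tr <- ballistic_trajectory(c(0.01, 0, 0), nf = 30)
  tr$topology$molecules$kind <- "protein"
  ref2 <- subtract_protein_motion(tr)
  expect_lt(max(abs(sweep(ref2$trajectory$coords, c(1, 2),
                          ref2$trajectory$coords[, , 1]))), 1e-12)
})

test_that("group_diffusivity: partitions, exclusions, empty groups", {
  rec <- structure(data.frame(
    molecule_id = 1:6, D = c(1, 1, 1, 5, 5, 5),
    slope_nm2_ps = 0, fit_r2 = 1, clipped = FALSE,
    shell_index = c(0L, 0L, 1L, 1L, 2L, 2L),
    bonded_status = c("gen1", "gen1", "gen2", "nonbonded", "nonbonded",
                      "nonbonded")),
    class = c("asd_diffusivity", "data.frame"))
  overall <- group_diffusivity(rec)
  expect_equal(overall$mean_D, 3)
  by_shell <- group_diffusivity(rec, "shell_index")
  expect_equal(sum(by_shell$n), 6L)
  expect_equal(by_shell$mean_D[by_shell$group == "0"], 1)
  # excluding the bonded raises the mean (stabilized molecules are slow)
  excl <- group_diffusivity(rec, exclude = 1:3)
  expect_gt(excl$mean_D, overall$mean_D)
  # all-equal D: every group mean equals that D
  rec2 <- rec; rec2$D <- 2
  expect_true(all(group_diffusivity(rec2, "shell_index")$mean_D == 2))
})

test_that("cumulative diffusivity contribution curve properties", {
  rec <- structure(data.frame(molecule_id = 1:5, D = rep(2, 5)),
                   class = c("asd_diffusivity", "data.frame"))
  dd <- diffusivity_distribution(rec)
  expect_equal(dd$cumulative$cum_fraction, seq(0.2, 1, 0.2))  # diagonal
  # one mobile + N-1 frozen: curve flat then jumps to 1
  rec2 <- structure(data.frame(molecule_id = 1:10,
                               D = c(rep(0, 9), 4)),
                    class = c("asd_diffusivity", "data.frame"))
  dd2 <- diffusivity_distribution(rec2)
  expect_equal(dd2$cumulative$cum_fraction[9], 0)
  expect_equal(dd2$cumulative$cum_fraction[10], 1)
  # monotone, ends at exactly 1
  set.seed(3)
  rec3 <- structure(data.frame(molecule_id = 1:40,
                               D = rexp(40)),
                    class = c("asd_diffusivity", "data.frame"))
  dd3 <- diffusivity_distribution(rec3)
  expect_true(all(diff(dd3$cumulative$cum_fraction) >= 0))
  expect_equal(dd3$cumulative$cum_fraction[40], 1)
  expect_true(dd3$d_at_level >= stats::quantile(rec3$D, 0.5))
})

test_that("displacement classes: frozen, planted translation, fast subset", {
  tr0 <- ballistic_trajectory(c(0, 0, 0), nf = 20)
  dc0 <- displacement_classes(tr0)
  expect_equal(as.character(dc0$class), "<=1A")
  expect_equal(dc0$max_disp_A, 0)
  # molecule translated 7 A: between the 5 and 10 A limits
  tr7 <- ballistic_trajectory(c(0.7 / 19, 0, 0), nf = 20, dt = 1)
  dc7 <- displacement_classes(tr7)
  expect_equal(as.character(dc7$class), "<=10A")
  expect_equal(dc7$max_disp_A, 7, tolerance = 1e-9)
  # planted fast subset tops the 5 A threshold exactly
  sim <- simulate_asd(generator_config(seed = 6, n_drug = 12,
                                       n_frames = 200, n_protein = 0,
                                       drug_D = c(rep(400, 4),
                                                  rep(0.001, 8))))
  ref <- suppressWarnings(
    subtract_protein_motion(unwrap_trajectory(sim$trajectory)))
  dc <- displacement_classes(ref$trajectory, thresholds = c(5))
  fast <- names(sim$truth$true_D)[sim$truth$true_D > 1]
  expect_setequal(dc$id[dc$class == "above-max"], as.integer(fast))
  # atom-level table covers every atom
  dca <- displacement_classes(ref$trajectory, level = "atom")
  expect_equal(nrow(dca), n_atoms(ref$trajectory$topology))
})
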