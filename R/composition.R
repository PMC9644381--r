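# Composition planner: integer molecule counts for target weight fractions.
#
# Weight fractions are planning targets; integer rounding means the achieved
# fractions differ from the targets by at most one molecule's worth of mass,
# and it is the achieved fractions that downstream modules report.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Plan a simulation-box composition from target weight fractions
#'
#' Given a target drug weight fraction, a protein count and a water weight
#' fraction, computes the integer molecule counts whose total masses best
#' meet the targets. Counts are rounded half-away-from-zero. The protein
#' fraction is the remainder `100 - drug - water`. When no protein is
#' present (pure-drug systems), `mass_scale` sets the total-mass scale that
#' the protein mass would otherwise provide.
#'
#' @param drug_fraction_wt target drug weight percent, in `[0, 100]`
#' @param n_protein number of protein molecules (0 allowed only when the
#'   protein fraction is 0)
#' @param water_fraction_wt target water weight percent, in `[0, 20]`
#' @param mw_drug,mw_protein,mw_water molar masses, Da; defaults are
#'   indomethacin (381.37), beta-lactoglobulin (18300) and water (18.015)
#' @param mass_scale reference total mass (Da) used only when
#'   `n_protein = 0`; default: the mass of 4 protein molecules
#' @return a one-row `data.frame` of class `"asd_system_plan"` with target
#'   and achieved weight percents and integer counts
#' @export
plan_system <- function(drug_fraction_wt, n_protein,
                        water_fraction_wt = 0,
                        mw_drug = 381.37, mw_protein = 18300,
                        mw_water = 18.015,
                        mass_scale = 4 * mw_protein) {
  stopifnot(drug_fraction_wt >= 0, drug_fraction_wt <= 100,
            water_fraction_wt >= 0, water_fraction_wt <= 20,
            drug_fraction_wt + water_fraction_wt <= 100,
            n_protein >= 0)
  f_drug <- drug_fraction_wt
  f_water <- water_fraction_wt
  f_protein <- 100 - f_drug - f_water
  if (n_protein == 0 && f_protein > 0)
    stop("nonzero protein fraction requires at least one protein molecule")
  m_protein <- if (n_protein > 0) n_protein * mw_protein else 0
  # mass scale: protein mass when present, otherwise the reference scale
  if (f_protein > 0) {
    ref_mass <- m_protein / (f_protein / 100)
  } else {
    ref_mass <- mass_scale
  }
  n_drug <- as.integer(round_half_away(f_drug / 100 * ref_mass / mw_drug))
  n_water <- as.integer(round_half_away(f_water / 100 * ref_mass / mw_water))
  m_tot <- m_protein + n_drug * mw_drug + n_water * mw_water
  plan <- data.frame(
    drug_fraction_wt = f_drug, protein_fraction_wt = f_protein,
    water_fraction_wt = f_water,
    n_protein = as.integer(n_protein), n_drug = n_drug, n_water = n_water,
    achieved_drug_wt = if (m_tot > 0) 100 * n_drug * mw_drug / m_tot else 0,
    achieved_protein_wt = if (m_tot > 0) 100 * m_protein / m_tot else 0,
    achieved_water_wt =
      if (m_tot > 0) 100 * n_water * mw_water / m_tot else 0,
    mw_drug = mw_drug, mw_protein = mw_protein, mw_water = mw_water,
    total_mass = m_tot)
  class(plan) <- c("asd_system_plan", "data.frame")
  plan
}

#' Reference composition grid: dry and 5%-water humid schemes
#'
#' The dry series targets drug weight fractions of 13, 25, 38, 50, 62, 75,
#' 87 and 100%; the humid series keeps 5% water and targets 12, 22.5, 35,
#' 47.5, 60, 72.5 and 83% drug (the remainder being protein in both).
#' Systems below 40% drug use 8 protein molecules, systems above use 4
#' (pure drug uses 0) — low-loading boxes need more protein copies so each
#' stays screened from its own periodic image.
#'
#' @inheritParams plan_system
#' @return a 15-row `data.frame` (8 dry + 7 humid) of system plans, with a
#'   `condition` column (`"dry"`/`"humid"`)
#' @export
composition_grid <- function(mw_drug = 381.37, mw_protein = 18300,
                             mw_water = 18.015) {
  dry <- c(13, 25, 38, 50, 62, 75, 87, 100)
  humid <- c(12, 22.5, 35, 47.5, 60, 72.5, 83)
  n_prot <- function(f_drug) if (f_drug >= 100) 0L else
    if (f_drug < 40) 8L else 4L
  rows <- c(
    lapply(dry, function(f)
      cbind(condition = "dry",
            plan_system(f, n_prot(f), 0, mw_drug, mw_protein, mw_water))),
    lapply(humid, function(f)
      cbind(condition = "humid",
            plan_system(f, n_prot(f), 5, mw_drug, mw_protein, mw_water))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
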