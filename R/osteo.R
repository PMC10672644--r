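# Clinical-endpoint analytics: WHO-style osteoporosis threshold on
# reference-population statistics, threshold-crossing times of simulated
# BMD trajectories under load scenarios, stage-wise porosity changes, and
# density-space (rho_mat vs rho_app) exports.

#' Reference total-femur BMD statistics
#'
#' Population reference statistics for total-femur areal BMD in women:
#' young-adult (20-29 y) mean and standard deviation and the 40-59 y
#' reference-cohort mean, per population, shipped as a packaged CSV.
#'
#' @return A data.frame with columns `population`, `bmd_s`, `bmd_sd`,
#'   `bmd_ref` (g/cm^2) and sample sizes `n_s`, `n_ref`.
#' @export
reference_bmd_table <- function() {
  read.csv(system.file("extdata", "reference_total_femur_bmd.csv",
                       package = "osteosim"))
}

#' Normalized osteoporosis threshold
#'
#' WHO-style criterion expressed on the normalized BMD scale: osteoporosis
#' when BMD falls below `z` standard deviations under the young-adult mean,
#' normalized by the reference-cohort mean,
#' `threshold = (bmd_s - z * bmd_sd) / bmd_ref`.  Reported rounded to 3
#' decimals.
#'
#' @param bmd_s young-adult mean BMD, g/cm^2 (vectorized).
#' @param bmd_sd young-adult standard deviation, g/cm^2.
#' @param bmd_ref reference-cohort mean BMD, g/cm^2.
#' @param z standard-deviation multiplier (default 2.5).
#' @return Normalized threshold(s), 3 decimals.
#' @export
#' @examples
#' osteoporosis_threshold(0.942, 0.122, 0.885)
#' threshold_table()
osteoporosis_threshold <- function(bmd_s, bmd_sd, bmd_ref, z = 2.5) {
  stopifnot(all(bmd_s > 0), all(bmd_sd > 0), all(bmd_ref > 0), z > 0)
  th <- (bmd_s - z * bmd_sd) / bmd_ref
  if (any(th <= 0)) stop("non-positive threshold: check inputs", call. = FALSE)
  round(th, 3)
}

#' @rdname osteoporosis_threshold
#' @param table a data.frame like [reference_bmd_table()].
#' @export
threshold_table <- function(table = reference_bmd_table(), z = 2.5) {
  table$threshold <- osteoporosis_threshold(table$bmd_s, table$bmd_sd,
                                            table$bmd_ref, z = z)
  table
}

.bmd_series <- function(x) {
  if (inherits(x, "bone_sim")) {
    data.frame(t_years = x$time, bmd_rel = x$femur$bmd_rel)
  } else if (is.data.frame(x) && all(c("t_years", "bmd_rel") %in% names(x))) {
    x
  } else {
    stop("expected a bone_sim or a data.frame with t_years and bmd_rel",
         call. = FALSE)
  }
}

#' First time a BMD trajectory crosses a threshold
#'
#' Linear interpolation between samples; returns the series start if it
#' begins at or below the threshold and `NA` if the threshold is never
#' reached within the span.
#'
#' @param x a `bone_sim` or a data.frame with `t_years` and `bmd_rel`.
#' @param threshold normalized BMD threshold (default 0.72).
#' @return Crossing time in years, or `NA`.
#' @export
threshold_crossing_time <- function(x, threshold = 0.72) {
  s <- .bmd_series(x)
  if (!nrow(s)) stop("empty series", call. = FALSE)
  y <- s$bmd_rel
  t <- s$t_years
  if (y[1] <= threshold) return(t[1])
  below <- which(y <= threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - threshold) / (y[i - 1] - y[i])
}

#' Years by which an underload scenario reaches the threshold earlier
#'
#' @param underload,overload `bone_sim` objects (or BMD data.frames) for
#'   the reduced- and increased-load scenarios.
#' @inheritParams threshold_crossing_time
#' @return Positive "earlier by" gap in years,
#'   `crossing(overload) - crossing(underload)`.  `NA` (with a message)
#'   if either trajectory never crosses within its span.
#' @export
crossing_gap <- function(underload, overload, threshold = 0.72) {
  t_u <- threshold_crossing_time(underload, threshold)
  t_o <- threshold_crossing_time(overload, threshold)
  if (is.na(t_u) || is.na(t_o)) {
    message("threshold ", threshold, " not reached within the simulated span",
            if (is.na(t_o)) " (overload censored)" else " (underload censored)")
    return(NA_real_)
  }
  t_o - t_u
}

#' Stage-wise annual porosity change
#'
#' Splits the simulated span into menopausal stages and reports the change
#' in femur-average porosity per year of each stage, in percentage points
#' per year (negative values indicate recovery).
#'
#' @param sim a `bone_sim` covering all stage boundaries.
#' @param stages named list of `c(start, end)` years (defaults: pre-to-peri
#'   `[-4, 0]`, peri-to-post `[0, 4]`, postmenopause `[4, 15]`).
#' @return A data.frame with `stage`, `from`, `to` and
#'   `delta_porosity_pct_per_year`.
#' @export
stage_porosity_change <- function(sim,
                                  stages = list(pre_to_peri = c(-4, 0),
                                                peri_to_post = c(0, 4),
                                                post = c(4, 15))) {
  s <- if (inherits(sim, "bone_sim")) {
    data.frame(t_years = sim$time, porosity = sim$femur$porosity)
  } else sim
  rng <- range(s$t_years)
  lims <- range(unlist(stages))
  if (lims[1] < rng[1] - 1e-6 || lims[2] > rng[2] + 1e-6) {
    stop("simulation span [", signif(rng[1], 3), ", ", signif(rng[2], 3),
         "] does not cover the stages", call. = FALSE)
  }
  at <- function(t) approx(s$t_years, s$porosity, xout = t, rule = 2)$y
  out <- data.frame(
    stage = names(stages),
    from = vapply(stages, `[`, 0, 1),
    to = vapply(stages, `[`, 0, 2)
  )
  out$delta_porosity_pct_per_year <- vapply(stages, function(b) {
    100 * (at(b[2]) - at(b[1])) / (b[2] - b[1])
  }, 0)
  rownames(out) <- NULL
  out
}

#' Material-apparent density pairs per site
#'
#' Extracts the (rho_mat, rho_app) point of every ensemble site at time
#' `t_years`, the density-space view in which mineralization shifts move
#' points horizontally and porosity shifts move them vertically.
#'
#' @param sim a `bone_sim`.
#' @param t_years time at which to extract, within the simulated span.
#' @return A data.frame with `site`, `v_b`, `alpha_mean`, `rho_mat`,
#'   `rho_app`.
#' @export
density_space_export <- function(sim, t_years = 15) {
  stopifnot(inherits(sim, "bone_sim"))
  if (t_years < sim$time[1] - 1e-9 || t_years > sim$time[length(sim$time)] + 1e-9) {
    stop("t_years outside the simulated span", call. = FALSE)
  }
  i <- which.min(abs(sim$time - t_years))
  tc <- sim$params$tissue
  rows <- lapply(names(sim$sites), function(lbl) {
    s <- sim$sites[[lbl]]
    rho_mat <- material_density(s[i, "v_m_mean"], tc)
    data.frame(site = lbl, v_b = s[i, "v_b"], alpha_mean = s[i, "alpha_mean"],
               rho_mat = rho_mat,
               rho_app = apparent_density(rho_mat, s[i, "v_b"]))
  })
  do.call(rbind, rows)
}
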