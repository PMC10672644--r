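# Model parameter container and JSON configuration I/O.

#' Bone remodeling model parameters
#'
#' Collects every tunable constant of the remodeling model in one validated
#' list.  Defaults are the standard parameter set of the model:
#'
#' * BMU periods `T_R` (resorption, 24 d), `T_I` (reversal, 18 d),
#'   `T_F` (formation, 64 d) and progression speed `v_bmu` (0.04 mm/day).
#' * `f_bio`: maximal biological activation frequency, BMU per mm^2 of free
#'   surface per day (5e-3); inhibited by the mechanical stimulus.
#' * Focal-balance curve: dead-zone half width `w`, linear-zone width `v`
#'   (both 1.5e-3 stimulus units), bounds `f_bb_min` = 0.85 and
#'   `f_bb_max` = 1.15.
#' * `m`: cycle-weighting exponent of the daily stimulus (4);
#'   `phi`: accommodation rate of the reference stimulus (1e-4 per day).
#' * `a_bmu`: effective remodeling cross-section, mm^2.  Together with
#'   `v_bmu` and the origination-rate history it sets the absolute turnover
#'   scale; the default (1.0) puts premenopausal femur-average turnover near
#'   10-15 %/yr (about 5 %/yr at a cortical site and 15-20 %/yr in the
#'   transition zone), in the range of histomorphometric estimates.
#' * Mineralization law `alpha(age) = alpha_max - (alpha_max - alpha_0)
#'   exp(-age/tau_sec)`: primary mineralization level `alpha_0` = 0.45,
#'   asymptote `alpha_max` = 0.72, secondary time constant `tau_sec` =
#'   1500 days.
#' * `lifo_fraction`: share of daily resorption taken youngest-first from
#'   the surface layers (0.7); the remainder tunnels proportionally through
#'   layers of all ages.  The default puts equilibrium mean ash near 0.67.
#' * `zeta_target`: habitual daily stimulus at which every site is
#'   initialized in equilibrium (8e-3; about 950 microstrain of walking
#'   effective strain after cycle weighting, making the dead zone a +/-19%
#'   band around habitual stimulus).
#' * `stair_stress_ratio`: habitual stair-climbing stress amplitude
#'   relative to walking (1.2).
#' * `coalesce_days`: adjacent tissue layers closer in age than this are
#'   merged, thickness-weighted (30 d); `0` disables coalescing.
#'
#' @param ... named overrides of any default listed above (also
#'   `tissue`, a [tissue_constants()] object, and `sv_coef`, the
#'   specific-surface polynomial coefficients).
#' @return A list of class `bone_params`.
#' @export
#' @examples
#' p <- bone_params(f_bio = 4e-3)
#' p$f_bio
bone_params <- function(...) {
  p <- list(
    tissue = tissue_constants(),
    sv_coef = c(32.3, -93.9, 134, -101, 28.8),
    T_R = 24, T_I = 18, T_F = 64,
    a_bmu = 1.0, v_bmu = 0.04,
    f_bio = 5e-3,
    f_bb_min = 0.85, f_bb_max = 1.15,
    w = 1.5e-3, v = 1.5e-3,
    m = 4, phi = 1e-4,
    alpha_0 = 0.45, alpha_max = 0.72, tau_sec = 1500,
    lifo_fraction = 0.7,
    zeta_target = 8e-3,
    stair_stress_ratio = 1.2,
    coalesce_days = 30
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  with(p, {
    stopifnot(T_R > 0, T_I > 0, T_F > 0, a_bmu > 0, v_bmu > 0, f_bio > 0,
              f_bb_min <= 1, f_bb_max >= 1, w > 0, v > 0, m >= 1, phi > 0,
              alpha_0 >= 0, alpha_0 < alpha_max, alpha_max < 1, tau_sec > 0,
              lifo_fraction >= 0, lifo_fraction <= 1,
              zeta_target > 0, stair_stress_ratio > 0, coalesce_days >= 0)
  })
  if (p$phi * 1 >= 1) stop("phi * dt must be below 1 for the explicit accommodation update")
  structure(p, class = "bone_params")
}

#' @export
print.bone_params <- function(x, ...) {
  cat("Bone remodeling parameters\n")
  cat(sprintf("  BMU periods (days): T_R = %g, T_I = %g, T_F = %g\n", x$T_R, x$T_I, x$T_F))
  cat(sprintf("  turnover scale: a_bmu = %g mm^2, v_bmu = %g mm/day, f_bio = %g /(mm^2 day)\n",
              x$a_bmu, x$v_bmu, x$f_bio))
  cat(sprintf("  focal balance: [%g, %g], dead zone w = %g, linear zone v = %g\n",
              x$f_bb_min, x$f_bb_max, x$w, x$v))
  cat(sprintf("  stimulus: m = %g, phi = %g /day, habitual zeta = %g\n", x$m, x$phi, x$zeta_target))
  cat(sprintf("  mineralization: alpha %g -> %g, tau = %g days; lifo fraction %g\n",
              x$alpha_0, x$alpha_max, x$tau_sec, x$lifo_fraction))
  invisible(x)
}

#' Habitual load cases
#'
#' Daily habitual loading expressed as stress-amplitude load cases at a
#' material point.  The default schedule is 5000 walking cycles and 500
#' stair-climbing cycles per day; the walking stress amplitude is solved at
#' initialization so the site sits at its habitual stimulus, with
#' stair-climbing stress a fixed ratio above walking.
#'
#' @param label character labels.
#' @param cycles_per_day cycles per day for each case.
#' @param stress_amplitude stress amplitudes, MPa.  `NA` amplitudes are
#'   solved at equilibration (see [simulate_remodeling()]).
#' @return A data.frame of class `load_cases`.
#' @export
load_cases <- function(label = c("walking", "stair_climbing"),
                       cycles_per_day = c(5000, 500),
                       stress_amplitude = c(NA_real_, NA_real_)) {
  stopifnot(length(label) == length(cycles_per_day),
            length(label) == length(stress_amplitude),
            all(cycles_per_day >= 0),
            all(is.na(stress_amplitude) | stress_amplitude >= 0))
  structure(data.frame(label = label, cycles_per_day = cycles_per_day,
                       stress_amplitude = stress_amplitude,
                       stringsAsFactors = FALSE),
            class = c("load_cases", "data.frame"))
}

#' Load-change schedule
#'
#' A multiplicative load scenario: all stress amplitudes are scaled by
#' `factor` from `tolc_years` (time of load change, years relative to the
#' last menses) onwards.  `factor = 1.3` is a 30% overload (sustained
#' physical activity), `factor = 0.7` a 30% underload (sedentary trend).
#'
#' @param factor positive load multiplier applied from `tolc_years` on.
#' @param tolc_years time of load change, years relative to last menses.
#' @return A list of class `load_schedule`.
#' @export
load_schedule <- function(factor = 1, tolc_years = 0) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0,
            is.numeric(tolc_years), length(tolc_years) == 1)
  structure(list(factor = factor, tolc_years = tolc_years), class = "load_schedule")
}

#' Scenario load factor at a given time
#'
#' @param t_years time, years relative to last menses (vectorized).
#' @param schedule a [load_schedule()].
#' @return The multiplier applied to all stress amplitudes at `t_years`.
#' @export
scenario_factor <- function(t_years, schedule = load_schedule()) {
  ifelse(t_years >= schedule$tolc_years, schedule$factor, 1)
}

#' Site ensemble standing in for femur geometry
#'
#' A small set of material points spanning cortical (low porosity),
#' transition-zone and trabecular (high porosity) bone, with mass weights
#' used for femur averaging.  The default five sites cover bone volume
#' fractions 0.2-0.95.
#'
#' @param v_b initial bone volume fractions, strictly inside (0, 1).
#' @param weight positive averaging weights (normalized internally).
#' @param label site labels.
#' @return A data.frame of class `bone_ensemble`.
#' @export
bone_ensemble <- function(v_b = c(0.95, 0.85, 0.60, 0.35, 0.20),
                          weight = c(0.35, 0.25, 0.15, 0.15, 0.10),
                          label = NULL) {
  stopifnot(length(v_b) >= 1, all(v_b > 0), all(v_b < 1),
            length(weight) == length(v_b), all(weight > 0))
  if (is.null(label)) {
    zone <- ifelse(v_b >= 0.7, "cortical", ifelse(v_b >= 0.4, "transition", "trabecular"))
    label <- make.unique(paste0(zone, "_vb", format(v_b, trim = TRUE)), sep = "_")
  }
  structure(data.frame(label = label, v_b = v_b,
                       weight = weight / sum(weight), stringsAsFactors = FALSE),
            class = c("bone_ensemble", "data.frame"))
}

#' Read or write a model configuration as JSON
#'
#' Serializes a full model configuration (parameters, menopause schedule,
#' load schedule, ensemble, time span) to a JSON file and back.
#'
#' @param params a [bone_params()] object.
#' @param schedule a [menopause_schedule()].
#' @param loads a [load_schedule()].
#' @param ensemble a [bone_ensemble()].
#' @param t_start,t_end simulation span, years relative to last menses.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a named list with the reconstructed components.
#' @export
write_config <- function(path, params = bone_params(),
                         schedule = menopause_schedule("combined"),
                         loads = load_schedule(),
                         ensemble = bone_ensemble(),
                         t_start = -4, t_end = 15) {
  cfg <- list(
    params = unclass(params[setdiff(names(params), "tissue")]),
    tissue = unclass(params$tissue),
    schedule = list(
      scenario = schedule$scenario,
      fbio = unclass(schedule$fbio),
      fbb = unclass(schedule$fbb)
    ),
    loads = unclass(loads),
    ensemble = as.data.frame(ensemble),
    t_start = t_start, t_end = t_end
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  par_args <- cfg$params
  par_args$tissue <- do.call(tissue_constants, as.list(cfg$tissue))
  params <- do.call(bone_params, par_args)
  schedule <- menopause_schedule(
    scenario = cfg$schedule$scenario,
    fbio = do.call(kappa_params, as.list(cfg$schedule$fbio)),
    fbb = do.call(kappa_params, as.list(cfg$schedule$fbb))
  )
  loads <- do.call(load_schedule, as.list(cfg$loads))
  ensemble <- bone_ensemble(v_b = cfg$ensemble$v_b, weight = cfg$ensemble$weight,
                            label = cfg$ensemble$label)
  list(params = params, schedule = schedule, loads = loads, ensemble = ensemble,
       t_start = cfg$t_start, t_end = cfg$t_end)
}
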