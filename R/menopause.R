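# kappa(t) modifiers: permanent menopausal change plus long-term ageing drift.

#' Parameters of a kappa(t) modifier
#'
#' A kappa(t) function is 1 before perimenopause onset `t1`, ramps linearly
#' to the permanent multiplier `kappa_perm` at postmenopause onset `t2`, and
#' thereafter drifts linearly at `slope` per day (the ageing effect).  The
#' modifier multiplies the BMU activation frequency (increasing,
#' `kappa >= 1`) or the focal-balance curve (decreasing, `kappa <= 1`).
#'
#' @param t1 perimenopause onset, years relative to last menses (default -4).
#' @param t2 postmenopause onset, years (default +4).
#' @param kappa_perm permanent multiplier reached at `t2`.
#' @param slope long-term drift, per day, applied after `t2`.
#' @param ramp `"linear"` (default) or `"smoothstep"` shape between `t1`
#'   and `t2`.
#' @return A list of class `kappa_params`.
#' @export
kappa_params <- function(kappa_perm = 1, slope = 0, t1 = -4, t2 = 4,
                         ramp = c("linear", "smoothstep")) {
  ramp <- match.arg(ramp)
  stopifnot(t1 < 0, t2 > 0, kappa_perm > 0)
  structure(list(t1 = t1, t2 = t2, kappa_perm = kappa_perm, slope = slope,
                 ramp = ramp),
            class = "kappa_params")
}

#' Evaluate a kappa(t) modifier
#'
#' @param t_years time, years relative to last menses (vectorized).
#' @param p a [kappa_params()] object.
#' @return kappa values, floored at zero (a vanishing kappa on the focal
#'   balance means no bone formation regardless of stimulus).
#' @export
#' @examples
#' p <- kappa_params(kappa_perm = 1.23, slope = 1.61e-4)
#' kappa(c(-10, 0, 4, 15), p)
kappa <- function(t_years, p) {
  stopifnot(inherits(p, "kappa_params"))
  s <- (t_years - p$t1) / (p$t2 - p$t1)
  s <- pmin(pmax(s, 0), 1)
  if (p$ramp == "smoothstep") s <- s * s * (3 - 2 * s)
  k <- 1 + (p$kappa_perm - 1) * s
  post <- t_years > p$t2
  k[post] <- p$kappa_perm + p$slope * (t_years[post] - p$t2) * 365
  pmax(k, 0)
}

#' Menopause and ageing schedule
#'
#' Pairs the kappa(t) modifiers applied to the biological activation
#' frequency (`fbio`, increasing) and to the focal-balance curve (`fbb`,
#' decreasing).  The named presets carry the fitted parameter values of the
#' model's three calibration scenarios:
#'
#' | scenario    | kappa_perm fbio | slope fbio | kappa_perm fbb | slope fbb  |
#' |-------------|-----------------|------------|----------------|------------|
#' | `none`      | 1               | 0          | 1              | 0          |
#' | `fbio_only` | 1.489           | 3.654e-4   | 1              | 0          |
#' | `fbb_only`  | 1               | 0          | 0.793          | -7.085e-5  |
#' | `combined`  | 1.230           | 1.610e-4   | 0.903          | -4.452e-5  |
#'
#' @param scenario preset name, or the tag stored alongside custom
#'   parameters.
#' @param fbio,fbb optional [kappa_params()] overriding the preset.
#' @return A list of class `menopause_schedule`.
#' @export
#' @examples
#' sch <- menopause_schedule("combined")
#' effective_parameters(5, sch, base_fbio = 5e-3)
menopause_schedule <- function(scenario = c("none", "fbio_only", "fbb_only", "combined"),
                               fbio = NULL, fbb = NULL) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    none      = list(kappa_params(), kappa_params()),
    fbio_only = list(kappa_params(1.489, 3.654e-4), kappa_params()),
    fbb_only  = list(kappa_params(), kappa_params(0.793, -7.085e-5)),
    combined  = list(kappa_params(1.230, 1.610e-4), kappa_params(0.903, -4.452e-5))
  )
  if (!is.null(fbio)) preset[[1]] <- fbio
  if (!is.null(fbb)) preset[[2]] <- fbb
  stopifnot(inherits(preset[[1]], "kappa_params"), inherits(preset[[2]], "kappa_params"))
  if (preset[[1]]$kappa_perm < 1) stop("fbio kappa_perm must be >= 1 (activation increases)")
  if (preset[[2]]$kappa_perm > 1) stop("fbb kappa_perm must be <= 1 (balance decreases)")
  structure(list(scenario = scenario, fbio = preset[[1]], fbb = preset[[2]]),
            class = "menopause_schedule")
}

#' @export
print.menopause_schedule <- function(x, ...) {
  cat("Menopause/ageing schedule [", x$scenario, "]\n", sep = "")
  cat(sprintf("  fbio: kappa_perm = %.4g, slope = %.4g /day (t1 = %g y, t2 = %g y)\n",
              x$fbio$kappa_perm, x$fbio$slope, x$fbio$t1, x$fbio$t2))
  cat(sprintf("  fbb:  kappa_perm = %.4g, slope = %.4g /day\n",
              x$fbb$kappa_perm, x$fbb$slope))
  invisible(x)
}

#' Effective remodeling parameters at time t
#'
#' Applies the schedule's modifiers: the activation frequency is scaled to
#' `base_fbio * kappa_fbio(t)` and the multiplier `kappa_fbb(t)` is passed
#' to [focal_balance()].  A `"none"` scenario leaves both at their
#' premenopausal values.
#'
#' @param t_years time, years relative to last menses.
#' @param schedule a [menopause_schedule()].
#' @param base_fbio premenopausal biological activation frequency.
#' @return A list with elements `f_bio_eff` and `kappa_fbb`.
#' @export
effective_parameters <- function(t_years, schedule, base_fbio) {
  stopifnot(inherits(schedule, "menopause_schedule"))
  list(f_bio_eff = base_fbio * kappa(t_years, schedule$fbio),
       kappa_fbb = kappa(t_years, schedule$fbb))
}
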