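# Multi-site daily simulation: composes tissue composition, BMU kinetics,
# stimulus/accommodation and the kappa(t) schedules into femur-averaged
# time series.

#' Initialize a site in remodeling equilibrium
#'
#' Constructs the state of one material point so that the forward model
#' starts at steady state: the layer stack carries the stationary tissue-age
#' distribution implied by the equilibrium turnover (superficial churn plus
#' proportional tunneling at rate `g = (1 - lifo_fraction) * turnover / v_b`),
#' the BMU history is pre-filled with the equilibrium origination density,
#' and the habitual stress amplitudes are solved (unless supplied) so the
#' daily stimulus equals `zeta_target` at the site's stiffness, putting the
#' stimulus error in the centre of the dead zone.
#'
#' @param v_b target bone volume fraction at which stresses are solved.
#' @param params a [bone_params()] object.
#' @param cases a [load_cases()] data.frame; `NA` stress amplitudes are
#'   solved here (walking at 1, other cases at `stair_stress_ratio` times
#'   the walking amplitude).
#' @param v_b_start optional starting bone volume fraction different from
#'   `v_b` (the stack is scaled accordingly), used to study relaxation back
#'   to equilibrium.
#' @return A list of class `bone_site` with elements `thickness`, `age`
#'   (layer stack, youngest first), `sigma`, `cycles`, `zeta_ref`,
#'   `n_bmu_eq`, `v_b`, `alpha_mean`.
#' @export
init_site <- function(v_b, params = bone_params(), cases = load_cases(),
                      v_b_start = v_b) {
  stopifnot(v_b > 0, v_b < 1, v_b_start > 0, v_b_start <= 1)
  s_v <- specific_surface(1 - v_b, params$sv_coef)
  n_bmu_eq <- params$f_bio / 2 * s_v
  turnover <- params$a_bmu * params$v_bmu * n_bmu_eq
  g <- (1 - params$lifo_fraction) * turnover / v_b

  horizon <- 6 * params$tau_sec
  binw <- 30
  mids <- seq(binw / 2, horizon - binw / 2, by = binw)
  if (g > 0) {
    dens <- (1 - params$lifo_fraction) * turnover * binw * exp(-g * mids)
    tail_mass <- v_b - sum(dens)
    tail_age <- min(horizon + 1 / g, 20 * params$tau_sec)
  } else {
    dens <- numeric(0)
    mids <- numeric(0)
    tail_mass <- v_b
    tail_age <- 12 * params$tau_sec
  }
  th <- c(dens, tail_mass)
  age <- c(mids, tail_age)
  keep <- th > 0
  th <- th[keep]; age <- age[keep]
  if (v_b_start != v_b) th <- th * (v_b_start / v_b)

  al <- layer_mineral(age, params)
  alpha_mean <- sum(th * al) / sum(th)
  E0 <- elastic_modulus(v_b, alpha_mean)

  sigma <- cases$stress_amplitude
  if (anyNA(sigma)) {
    rel <- c(1, rep(params$stair_stress_ratio, nrow(cases) - 1))
    norm <- sum(cases$cycles_per_day * rel^params$m)^(1 / params$m)
    sigma <- params$zeta_target * E0 / norm * rel
    zeta_ref <- params$zeta_target
  } else {
    zeta_ref <- daily_stimulus(cases$cycles_per_day, site_strain(sigma, E0), params$m)
  }

  structure(list(thickness = th, age = age, sigma = sigma,
                 cycles = cases$cycles_per_day, zeta_ref = zeta_ref,
                 n_bmu_eq = n_bmu_eq, v_b = v_b, alpha_mean = alpha_mean),
            class = "bone_site")
}

.par_for_cpp <- function(params) {
  c(unclass(params)[setdiff(names(params), c("tissue", "sv_coef"))],
    list(sv_coef = params$sv_coef,
         rho_m = params$tissue$rho_m, rho_o = params$tissue$rho_o,
         v_o = params$tissue$v_o))
}

# Pure-R reference engine: one site, one day per iteration, written with the
# exported module operations in the documented update order.  Slow but
# transparent; the C++ engine is tested against it.
.run_site_r <- function(site, params, kfbio, kfbb, loadf) {
  ndays <- length(kfbio)
  tc <- params$tissue
  stack <- layer_stack(site$thickness, site$age)
  hist <- bmu_history(params, n_bmu_eq = site$n_bmu_eq)
  zref <- site$zeta_ref
  out <- matrix(NA_real_, ndays, 9,
                dimnames = list(NULL, c("v_b", "alpha_mean", "v_m_mean", "bmd",
                                        "zeta", "zeta_ref", "f_or",
                                        "v_f_dot", "v_r_dot")))
  for (d in seq_len(ndays)) {
    cs <- stack_summary(stack, params)
    E <- elastic_modulus(cs$v_b, cs$alpha_mean)
    zeta <- if (E > 0) {
      daily_stimulus(site$cycles, site_strain(site$sigma * loadf[d], E), params$m)
    } else 0
    f_bb <- focal_balance(zeta - zref, kfbb[d], params)
    f_or <- activation_frequency(zeta, zref, params$f_bio * kfbio[d])
    n_dot <- origination_rate(f_or, specific_surface(1 - cs$v_b, params$sv_coef))
    v_f <- formation_rate(hist, params)
    v_r <- resorption_rate(hist, params)
    out[d, ] <- c(cs$v_b, cs$alpha_mean, cs$v_m_mean,
                  bone_mineral_density(cs$v_b, cs$v_m_mean, tc),
                  zeta, zref, f_or, v_f, v_r)
    stack <- apply_turnover(stack, v_f, min(v_r, cs$v_b), dt = 1, params = params)
    # merge the fresh deposit into the previous surface layer while the
    # latter is younger than the coalescing window (bounds stack size)
    if (params$coalesce_days > 0 && length(stack$thickness) > 1 &&
        stack$age[2] - stack$age[1] < params$coalesce_days) {
      w <- stack$thickness[1] + stack$thickness[2]
      a <- (stack$age[1] * stack$thickness[1] + stack$age[2] * stack$thickness[2]) / w
      stack$thickness <- c(w, stack$thickness[-(1:2)])
      stack$age <- c(a, stack$age[-(1:2)])
    }
    zref <- update_reference(zeta, zref, params$phi)
    hist <- push_history(hist, n_dot, f_bb)
  }
  out
}

.run_site_cpp <- function(site, params, kfbio, kfbb, loadf) {
  res <- .sim_site_cpp(.par_for_cpp(params), site$thickness, site$age,
                       site$sigma, site$cycles, site$zeta_ref, site$n_bmu_eq,
                       kfbio, kfbb, loadf)
  res$series
}

#' Verify or establish remodeling equilibrium at a site
#'
#' Initializes a site with [init_site()] and runs the forward model with
#' both kappa modifiers at 1 and unchanged loads, checking that the daily
#' drift of the bone volume fraction stays below `tol` and that the
#' stimulus error remains inside the dead zone.
#'
#' @inheritParams init_site
#' @param n_days verification span, days.
#' @param run_in_years discarded burn-in before the verification span.
#' @param tol maximum tolerated `|d v_b / d t|`, 1/day.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return The `bone_site`, with attributes `drift` (max daily `|d v_b|`)
#'   and `stimulus_error` (max `|zeta - zeta_ref|`).  Errors if the site
#'   fails to hold equilibrium.
#' @export
equilibrate_site <- function(v_b, params = bone_params(), cases = load_cases(),
                             n_days = 730, run_in_years = 5, tol = 1e-7,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  site <- init_site(v_b, params, cases)
  burn <- round(run_in_years * 365)
  ones <- rep(1, burn + n_days)
  runner <- if (engine == "cpp") .run_site_cpp else .run_site_r
  series <- runner(site, params, ones, ones, ones)
  if (burn > 0) series <- series[-seq_len(burn), , drop = FALSE]
  drift <- max(abs(diff(series[, "v_b"])))
  serr <- max(abs(series[, "zeta"] - series[, "zeta_ref"]))
  if (drift >= tol) {
    stop(sprintf(paste0("site v_b = %.3g failed to equilibrate: |dv_b/dt| = %.3g ",
                        ">= %.3g after %d days"), v_b, drift, tol, n_days),
         call. = FALSE)
  }
  if (serr >= params$w) {
    stop(sprintf("site v_b = %.3g stimulus error %.3g escaped the dead zone (w = %.3g)",
                 v_b, serr, params$w), call. = FALSE)
  }
  attr(site, "drift") <- drift
  attr(site, "stimulus_error") <- serr
  site
}

#' Simulate bone remodeling through menopause
#'
#' Runs the daily-stepped remodeling model for every site of the ensemble
#' over `[t_start, t_end]` years relative to the last menses, under a
#' menopause/ageing schedule and a load scenario, and returns per-site and
#' femur-averaged series.  The forward model is deterministic.
#'
#' Each simulated day updates, in order: tissue composition from the layer
#' stack; stiffness; strains and the daily stimulus (with the scenario load
#' factor); the focal balance under `kappa_fbb(t)`; the activation
#' frequency under `kappa_fbio(t)`; the BMU origination density on the free
#' surface; the delayed formation/resorption rates from the history
#' windows; the layer-stack turnover; the accommodation of the reference
#' stimulus; and the history push.
#'
#' @param schedule a [menopause_schedule()].
#' @param loads a [load_schedule()] (load factor and time of change).
#' @param params a [bone_params()] object.
#' @param ensemble a [bone_ensemble()] of sites with averaging weights.
#' @param cases habitual [load_cases()].
#' @param t_start,t_end simulation span, years relative to last menses.
#' @param run_in_years discarded burn-in simulated before `t_start` (with
#'   whatever kappa/load values the schedules prescribe there; at the
#'   default `t_start = -4` both are at their premenopausal values).  The
#'   analytically constructed equilibrium age distribution relaxes to the
#'   model's own fixed point during the burn-in; 5 years brings the
#'   residual drift of `v_b` below 1e-7 per day for the default ensemble.
#' @param engine `"cpp"` (default) or `"r"` (pure-R reference loop, slow;
#'   intended for validation on short spans).
#' @return An object of class `bone_sim`: list with `time` (years),
#'   `femur` (data.frame of femur-averaged series, including `bmd_rel`
#'   normalized to 1 at `t_start`), `sites` (list of per-site series
#'   matrices), and the inputs.
#' @export
#' @examples
#' sim <- simulate_remodeling(menopause_schedule("combined"),
#'                            t_start = -4, t_end = 2)
#' sim
simulate_remodeling <- function(schedule = menopause_schedule("none"),
                                loads = load_schedule(),
                                params = bone_params(),
                                ensemble = bone_ensemble(),
                                cases = load_cases(),
                                t_start = -4, t_end = 15,
                                run_in_years = 5,
                                engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(schedule, "menopause_schedule"),
            inherits(loads, "load_schedule"),
            inherits(params, "bone_params"),
            t_start < t_end, run_in_years >= 0)
  burn <- round(run_in_years * 365)
  t0_day <- round(t_start * 365) - burn
  ndays <- burn + round((t_end - t_start) * 365) + 1  # inclusive of the end day
  t_years <- (t0_day + seq_len(ndays) - 1) / 365
  kfbio <- kappa(t_years, schedule$fbio)
  kfbb <- kappa(t_years, schedule$fbb)
  loadf <- scenario_factor(t_years, loads)
  runner <- if (engine == "cpp") .run_site_cpp else .run_site_r

  sites <- vector("list", nrow(ensemble))
  names(sites) <- ensemble$label
  for (i in seq_len(nrow(ensemble))) {
    site <- init_site(ensemble$v_b[i], params, cases)
    sites[[i]] <- runner(site, params, kfbio, kfbb, loadf)
  }
  if (burn > 0) {
    keep <- -seq_len(burn)
    t_years <- t_years[keep]
    sites <- lapply(sites, function(s) s[keep, , drop = FALSE])
  }

  wts <- ensemble$weight
  avg <- function(col) {
    acc <- 0
    for (i in seq_along(sites)) acc <- acc + wts[i] * sites[[i]][, col]
    acc
  }
  tc <- params$tissue
  rho_mat_site <- lapply(sites, function(s) material_density(s[, "v_m_mean"], tc))
  rho_mat <- Reduce(`+`, Map(`*`, rho_mat_site, wts))
  rho_app <- Reduce(`+`, Map(function(s, rm, w) w * rm * s[, "v_b"],
                             sites, rho_mat_site, as.list(wts)))
  bmd <- avg("bmd")
  femur <- data.frame(
    t_years = t_years,
    bmd = bmd,
    bmd_rel = bmd / bmd[1],
    v_b = avg("v_b"),
    alpha_mean = avg("alpha_mean"),
    porosity = 1 - avg("v_b"),
    rho_mat = rho_mat,
    rho_app = rho_app,
    zeta = avg("zeta"),
    zeta_ref = avg("zeta_ref"),
    f_or = avg("f_or")
  )
  structure(list(time = t_years, femur = femur, sites = sites,
                 ensemble = ensemble, params = params, schedule = schedule,
                 loads = loads, engine = engine),
            class = "bone_sim")
}

#' Weighted femur average of aligned per-site series
#'
#' @param series list of equal-length numeric vectors (or a matrix with one
#'   column per site).
#' @param weights positive site weights.
#' @return The weighted mean series.
#' @export
femur_average <- function(series, weights) {
  if (is.list(series)) {
    if (length(unique(lengths(series))) != 1) {
      stop("site series have mismatched lengths", call. = FALSE)
    }
    series <- do.call(cbind, series)
  }
  stopifnot(is.numeric(series), length(weights) == ncol(series), all(weights > 0))
  drop(series %*% (weights / sum(weights)))
}

#' @export
print.bone_sim <- function(x, ...) {
  n <- length(x$time)
  cat("Bone remodeling simulation [", x$schedule$scenario, " scenario]\n", sep = "")
  cat(sprintf("  span: %.2f to %.2f years (%d days), %d sites, engine %s\n",
              x$time[1], x$time[n], n, length(x$sites), x$engine))
  if (x$loads$factor != 1) {
    cat(sprintf("  load factor %.2f from t = %g y\n", x$loads$factor, x$loads$tolc_years))
  }
  cat(sprintf("  femur BMD (relative to start): %.3f at end of run\n",
              x$femur$bmd_rel[n]))
  invisible(x)
}

#' @export
summary.bone_sim <- function(object, at = c(0, 4, 15), ...) {
  at <- at[at >= object$time[1] & at <= object$time[length(object$time)]]
  rows <- vapply(at, function(t) which.min(abs(object$time - t)), integer(1))
  out <- object$femur[rows, c("t_years", "bmd_rel", "v_b", "alpha_mean", "porosity")]
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.bone_sim <- function(x, ...) {
  pieces <- lapply(names(x$sites), function(lbl) {
    s <- x$sites[[lbl]]
    data.frame(t_years = rep(x$time, ncol(s)),
               site = lbl,
               variable = rep(colnames(s), each = nrow(s)),
               value = as.vector(s))
  })
  do.call(rbind, pieces)
}

#' @export
plot.bone_sim <- function(x, variable = "bmd_rel", threshold = NULL, ...) {
  y <- x$femur[[variable]]
  plot(x$time, y, type = "l", xlab = "years from last menses",
       ylab = variable, ...)
  abline(v = c(x$schedule$fbio$t1, x$schedule$fbio$t2), lty = 3, col = "grey50")
  if (!is.null(threshold)) abline(h = threshold, lty = 4, col = "red3")
  invisible(x)
}
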