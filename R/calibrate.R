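# Calibration of the kappa(t) parameters to relative-BMD observations by
# mean-squared-error minimization: coarse grid, parabolic refinement of the
# grid optimum, then a derivative-free simplex polish.

#' Relative-BMD observation series
#'
#' @param t_years observation times, years relative to last menses,
#'   strictly increasing.
#' @param bmd_rel relative femur-average BMD (1 at the series start).
#' @param sd optional per-observation noise standard deviation.
#' @return A data.frame of class `bmd_obs`.
#' @export
bmd_observations <- function(t_years, bmd_rel, sd = NULL) {
  stopifnot(length(t_years) == length(bmd_rel), !is.unsorted(t_years, strictly = TRUE),
            all(bmd_rel > 0))
  out <- data.frame(t_years = t_years, bmd_rel = bmd_rel)
  if (!is.null(sd)) out$sd <- sd
  structure(out, class = c("bmd_obs", "data.frame"))
}

#' Read or write observation series CSV
#'
#' CSV with columns `t_years`, `bmd_rel` and optionally `sd`.
#'
#' @param path file path.
#' @param obs a [bmd_observations()] data.frame.
#' @return `read_observations()` returns a `bmd_obs` data.frame.
#' @export
read_observations <- function(path) {
  d <- read.csv(path)
  bmd_observations(d$t_years, d$bmd_rel, sd = d$sd)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Mean squared error of a simulation against observations
#'
#' The femur-averaged relative BMD of the simulation is linearly
#' interpolated to the observation times.
#'
#' @param sim a `bone_sim` from [simulate_remodeling()].
#' @param obs a [bmd_observations()] data.frame.
#' @return Mean of squared residuals.
#' @export
bmd_mse <- function(sim, obs) {
  stopifnot(inherits(sim, "bone_sim"))
  rng <- range(sim$time)
  if (any(obs$t_years < rng[1] - 1e-9) || any(obs$t_years > rng[2] + 1e-9)) {
    stop("observations fall outside the simulated span [",
         signif(rng[1], 3), ", ", signif(rng[2], 3), "] years", call. = FALSE)
  }
  pred <- approx(sim$time, sim$femur$bmd_rel, xout = obs$t_years, rule = 2)$y
  mean((pred - obs$bmd_rel)^2)
}

.free_par_names <- function(scenario) {
  switch(scenario,
         fbio_only = c("kappa_perm_fbio", "slope_fbio"),
         fbb_only = c("kappa_perm_fbb", "slope_fbb"),
         combined = c("kappa_perm_fbio", "slope_fbio", "kappa_perm_fbb", "slope_fbb"),
         stop("calibration needs scenario fbio_only, fbb_only or combined"))
}

.schedule_from_par <- function(theta, scenario) {
  full <- c(kappa_perm_fbio = 1, slope_fbio = 0, kappa_perm_fbb = 1, slope_fbb = 0)
  full[names(theta)] <- theta
  menopause_schedule(scenario,
                     fbio = kappa_params(full[["kappa_perm_fbio"]], full[["slope_fbio"]]),
                     fbb = kappa_params(full[["kappa_perm_fbb"]], full[["slope_fbb"]]))
}

.default_bounds <- function() {
  list(kappa_perm_fbio = c(1, 2),
       slope_fbio = c(0, 1e-3),
       kappa_perm_fbb = c(0.5, 1),
       slope_fbb = c(-1e-3, 0))
}

# vertex of the parabola through three equispaced points, clamped to the
# outer points; falls back to the best point when degenerate
.parabolic_vertex <- function(x, y) {
  d2 <- y[1] - 2 * y[2] + y[3]
  if (!is.finite(d2) || d2 <= 0) return(x[which.min(y)])
  v <- x[2] - (x[3] - x[1]) / 4 * (y[3] - y[1]) / d2
  min(max(v, x[1]), x[3])
}

#' Fit kappa parameters to a relative-BMD series
#'
#' Estimates the permanent menopausal multipliers and long-term ageing
#' slopes of the kappa(t) modifiers by minimizing the mean squared error
#' between the femur-averaged relative BMD of the forward model and an
#' observation series.  The `fbio_only` and `fbb_only` scenarios have two
#' free parameters, `combined` has four; the respective monotonicity
#' constraints (`kappa_perm_fbio >= 1`, `kappa_perm_fbb <= 1`, slope signs)
#' are enforced through the parameter bounds.
#'
#' The optimizer is deterministic: successive grid refinements (each level
#' shrinks the search box around the parabolic vertex through the current
#' optimum), followed by a bounded derivative-free polish (L-BFGS-B on
#' scaled numerical gradients by default; `control$polish_method =
#' "nelder-mead"` selects a simplex).
#'
#' @param obs a [bmd_observations()] data.frame.
#' @param scenario which parameters vary: `"fbio_only"`, `"fbb_only"` or
#'   `"combined"`.
#' @param params,ensemble,cases,loads forward-model configuration passed to
#'   [simulate_remodeling()].
#' @param bounds named list of `c(lower, upper)` per free parameter
#'   (defaults: `kappa_perm_fbio` in `[1, 2]`, `kappa_perm_fbb` in
#'   `[0.5, 1]`, slope magnitudes at most `1e-3` per day).
#' @param control list: `grid_n` points per dimension at the first level
#'   (default 5 for 4 free parameters, 7 for 2), `refine_n` points per
#'   dimension at refinement levels (default 3 resp. 5), `refine_levels`
#'   (default 1), `shrink` box shrink factor per level (default 0.5),
#'   `polish_method` (`"lbfgsb"` or `"nelder-mead"`) and `polish_maxit`
#'   (default 300 for four free parameters, 100 for two).
#' @param normalize if `TRUE` (default) a free multiplicative scale is
#'   profiled out of the objective,
#'   `mse = min_c mean((c * model - obs)^2)`.  Relative series are pinned
#'   to 1 at their first (noisy) observation; the profiled scale absorbs
#'   that normalization so it cannot bias the kappa estimates, and makes
#'   the fit exactly invariant to re-scaling the observation series.
#' @param engine forward engine, `"cpp"` or `"r"`.
#' @return An object of class `kappa_fit` with [coef()], [predict()],
#'   [residuals()], `print()`, `summary()` and `plot()` methods.
#' @export
#' @examples
#' \donttest{
#' obs <- generate_observations(menopause_schedule("fbb_only"), seed = 1)
#' fit <- fit_kappa(obs, "fbb_only")
#' coef(fit)
#' }
fit_kappa <- function(obs, scenario = c("combined", "fbio_only", "fbb_only"),
                      params = bone_params(), ensemble = bone_ensemble(),
                      cases = load_cases(), loads = load_schedule(),
                      bounds = list(), control = list(), normalize = TRUE,
                      engine = c("cpp", "r")) {
  scenario <- match.arg(scenario)
  engine <- match.arg(engine)
  stopifnot(inherits(obs, "data.frame"), nrow(obs) >= 4)
  free <- .free_par_names(scenario)
  bnd <- .default_bounds()
  bnd[names(bounds)] <- bounds
  bnd <- bnd[free]

  t_start <- min(-4, floor(min(obs$t_years)))
  t_end <- max(obs$t_years)
  n_eval <- 0L
  lower <- vapply(bnd, `[`, 0, 1)
  upper <- vapply(bnd, `[`, 0, 2)
  objective <- function(theta) {
    clamped <- pmin(pmax(theta, lower), upper)
    # smooth penalty outside the box keeps the simplex polish oriented
    excess <- sum(((theta - clamped) / pmax(upper - lower, 1e-12))^2)
    theta <- clamped
    names(theta) <- free
    sch <- .schedule_from_par(theta, scenario)
    sim <- simulate_remodeling(sch, loads, params, ensemble, cases,
                               t_start = t_start, t_end = t_end, engine = engine)
    n_eval <<- n_eval + 1L
    pred <- approx(sim$time, sim$femur$bmd_rel, xout = obs$t_years, rule = 2)$y
    if (normalize) {
      sc <- sum(pred * obs$bmd_rel) / sum(pred * pred)
      pred <- sc * pred
    }
    mean((pred - obs$bmd_rel)^2) * (1 + excess) + 1e-3 * excess
  }

  ctrl <- list(grid_n = if (length(free) > 2) 5L else 7L,
               refine_n = if (length(free) > 2) 3L else 5L,
               refine_levels = 1L, shrink = 0.5,
               polish_method = "lbfgsb",
               polish_maxit = if (length(free) > 2) 300L else 100L)
  ctrl[names(control)] <- control

  centre <- (lower + upper) / 2
  half <- (upper - lower) / 2
  trace <- list()
  best <- NULL

  for (level in 0:ctrl$refine_levels) {
    n_axis <- if (level == 0) ctrl$grid_n else ctrl$refine_n
    axes <- Map(function(c0, h, lo, hi) {
      seq(max(c0 - h, lo), min(c0 + h, hi), length.out = n_axis)
    }, as.list(centre), as.list(half), as.list(lower), as.list(upper))
    names(axes) <- free
    grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    vals <- apply(grid, 1, objective)
    k <- which.min(vals)
    best <- list(par = grid[k, ], value = vals[k])
    # parabolic vertex along each axis through the grid optimum
    new_centre <- best$par
    for (j in seq_along(free)) {
      ax <- axes[[j]]
      i <- match(best$par[j], ax)
      if (!is.na(i) && i > 1 && i < length(ax)) {
        sel <- grid[, -j, drop = FALSE]
        at <- matrix(best$par[-j], nrow(grid), length(free) - 1, byrow = TRUE)
        on_line <- rowSums(abs(sel - at)) < 1e-15
        y <- vals[on_line][order(grid[on_line, j])]
        xs <- sort(grid[on_line, j])
        new_centre[j] <- .parabolic_vertex(xs[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
      }
    }
    trace[[level + 1]] <- data.frame(level = level, mse = best$value,
                                     t(best$par))
    centre <- pmin(pmax(new_centre, lower), upper)
    half <- half * ctrl$shrink
  }
  grid_best <- best

  if (ctrl$polish_maxit > 0) {
    scale <- pmax(upper - lower, 1e-8)
    polish_nm <- function(st) {
      optim(st, objective, method = "Nelder-Mead",
            control = list(maxit = ctrl$polish_maxit, parscale = scale,
                           reltol = 1e-12))
    }
    pol <- if (ctrl$polish_method == "lbfgsb") {
      # bounded quasi-Newton with scaled numerical gradients tracks the
      # long curved valley of the combined fit far better than a simplex
      tryCatch(
        optim(centre, objective, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = ctrl$polish_maxit, parscale = scale,
                             ndeps = scale * 1e-4, factr = 1e3)),
        error = function(e) polish_nm(centre))
    } else {
      polish_nm(centre)
    }
    if (pol$value <= best$value) {
      best <- list(par = pmin(pmax(pol$par, lower), upper), value = pol$value)
    }
  }
  if (best$value > grid_best$value) best <- grid_best

  theta <- best$par
  names(theta) <- free
  fit <- structure(list(
    scenario = scenario,
    coefficients = theta,
    schedule = .schedule_from_par(theta, scenario),
    mse = best$value,
    trace = do.call(rbind, trace),
    n_eval = n_eval,
    obs = obs,
    bounds = bnd,
    params = params, ensemble = ensemble, cases = cases, loads = loads,
    engine = engine,
    normalize = normalize,
    t_start = t_start, t_end = t_end
  ), class = "kappa_fit")
  pred <- predict(fit)
  fit$scale <- if (normalize) sum(pred * obs$bmd_rel) / sum(pred * pred) else 1
  fit$fitted <- fit$scale * pred
  fit
}

#' @export
coef.kappa_fit <- function(object, ...) object$coefficients

#' @export
print.kappa_fit <- function(x, ...) {
  cat("kappa(t) calibration [", x$scenario, " scenario]\n", sep = "")
  print(signif(x$coefficients, 4))
  cat(sprintf("  mse = %.3g over %d observations (%d forward runs)\n",
              x$mse, nrow(x$obs), x$n_eval))
  invisible(x)
}

#' @export
summary.kappa_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(res^2)),
                 max_abs_resid = max(abs(res))), class = "summary.kappa_fit")
}

#' @export
print.summary.kappa_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  rmse = %.4g, max |residual| = %.4g\n", x$rmse, x$max_abs_resid))
  bnd <- x$fit$bounds
  at_bound <- vapply(names(bnd), function(nm) {
    th <- x$fit$coefficients[[nm]]
    th <= bnd[[nm]][1] + 1e-12 || th >= bnd[[nm]][2] - 1e-12
  }, logical(1))
  if (any(at_bound)) {
    cat("  at bound:", paste(names(bnd)[at_bound], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted relative BMD from a fitted kappa model
#'
#' @param object a `kappa_fit`.
#' @param t_years times at which to predict; defaults to the observation
#'   times.
#' @param ... unused.
#' @return Predicted femur-average relative BMD.
#' @export
predict.kappa_fit <- function(object, t_years = object$obs$t_years, ...) {
  sim <- simulate_remodeling(object$schedule, object$loads, object$params,
                             object$ensemble, object$cases,
                             t_start = min(object$t_start, floor(min(t_years))),
                             t_end = max(object$t_end, max(t_years)),
                             engine = object$engine)
  approx(sim$time, sim$femur$bmd_rel, xout = t_years, rule = 2)$y
}

#' @export
residuals.kappa_fit <- function(object, ...) {
  object$obs$bmd_rel - object$fitted
}

#' @export
plot.kappa_fit <- function(x, ...) {
  plot(x$obs$t_years, x$obs$bmd_rel, pch = 16, cex = 0.7,
       xlab = "years from last menses", ylab = "relative BMD", ...)
  ord <- order(x$obs$t_years)
  lines(x$obs$t_years[ord], x$fitted[ord], col = "red3", lwd = 2)
  legend("bottomleft", c("observed", "fitted"), pch = c(16, NA),
         lty = c(NA, 1), col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Simulate new observation series from a fitted kappa model
#'
#' @param object a `kappa_fit`.
#' @param nsim number of replicate series.
#' @param seed RNG seed.
#' @param noise_sd observation noise; defaults to the fitted rmse.
#' @param ... unused.
#' @return A list of [bmd_observations()] series.
#' @export
simulate.kappa_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = sqrt(object$mse), ...) {
  lapply(seq_len(nsim), function(i) {
    generate_observations(object$schedule, times = object$obs$t_years,
                          noise_sd = noise_sd,
                          seed = if (is.null(seed)) NULL else seed + i - 1,
                          loads = object$loads, params = object$params,
                          ensemble = object$ensemble, cases = object$cases,
                          engine = object$engine)
  })
}
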