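# Synthetic observation series and ensemble fixtures.  The generator runs
# the forward model under a known ("true") schedule and adds seeded
# Gaussian noise, emulating longitudinal densitometry follow-up: a
# premenopausal plateau at 1, an accelerating perimenopausal decline, and a
# sustained postmenopausal decline.  It closes the calibration loop: truth
# in, noisy series out, parameter recovery testable without external data.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic relative-BMD observation series
#'
#' Runs the forward model under `schedule` (the true parameters), samples
#' the femur-averaged relative BMD at `times`, adds i.i.d. Gaussian noise,
#' and re-normalizes so the first observation is exactly 1.  The generating
#' schedule is attached as attribute `truth` for parameter-recovery
#' studies.
#'
#' @param schedule the generating [menopause_schedule()].
#' @param times sampling times, years relative to last menses (default
#'   half-yearly densitometry over `[-4, 15]`).
#' @param noise_sd observation noise standard deviation in relative units
#'   (default 0.005).
#' @param seed RNG seed; the global RNG state is restored afterwards.
#' @param loads,params,ensemble,cases,engine forward-model configuration.
#' @return A [bmd_observations()] data.frame with attributes `truth`,
#'   `noise_sd`, `seed`.
#' @export
#' @examples
#' obs <- generate_observations(menopause_schedule("combined"),
#'                              times = seq(-4, 2, 0.5), seed = 7)
#' head(obs)
generate_observations <- function(schedule = menopause_schedule("combined"),
                                  times = seq(-4, 15, by = 0.5),
                                  noise_sd = 0.005, seed = NULL,
                                  loads = load_schedule(),
                                  params = bone_params(),
                                  ensemble = bone_ensemble(),
                                  cases = load_cases(),
                                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(noise_sd >= 0, !is.unsorted(times, strictly = TRUE))
  sim <- simulate_remodeling(schedule, loads, params, ensemble, cases,
                             t_start = min(-4, floor(min(times))),
                             t_end = max(times), engine = engine)
  clean <- approx(sim$time, sim$femur$bmd_rel, xout = times, rule = 2)$y
  noisy <- .with_seed(seed, clean + rnorm(length(times), 0, noise_sd))
  noisy <- noisy / noisy[1]
  obs <- bmd_observations(times, noisy)
  attr(obs, "truth") <- schedule
  attr(obs, "noise_sd") <- noise_sd
  attr(obs, "seed") <- seed
  obs
}

#' Generate a deterministic site-ensemble fixture
#'
#' Builds a seeded ensemble of `n_sites` bone volume fractions spanning
#' `vb_range` (strictly increasing: even spacing plus bounded seeded
#' jitter) with seeded positive weights, normalized.
#'
#' @param n_sites number of sites (>= 1).
#' @param vb_range range of bone volume fractions, inside (0, 1).
#' @param seed RNG seed.
#' @return A [bone_ensemble()].
#' @export
generate_ensemble_fixture <- function(n_sites = 5, vb_range = c(0.2, 0.95),
                                      seed = 1) {
  stopifnot(n_sites >= 1, length(vb_range) == 2,
            vb_range[1] > 0, vb_range[2] < 1, vb_range[1] < vb_range[2])
  .with_seed(seed, {
    if (n_sites == 1) {
      v_b <- mean(vb_range)
      wts <- 1
    } else {
      base <- seq(vb_range[1], vb_range[2], length.out = n_sites)
      gap <- diff(base)[1]
      jit <- runif(n_sites, -0.35 * gap, 0.35 * gap)
      jit[c(1, n_sites)] <- 0  # keep the span endpoints inside the range
      v_b <- base + jit
      wts <- runif(n_sites, 0.5, 1.5)
    }
    bone_ensemble(v_b = v_b, weight = wts)
  })
}
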