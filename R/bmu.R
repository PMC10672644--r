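# BMU population kinetics: activation, origination, delayed formation and
# resorption windows, the focal-balance curve, and the layered tissue stack.
#
# Time is discrete with dt = 1 day.  The history ring buffer stores, for the
# last T_R + T_I + T_F days, the daily BMU origination density and the
# focal-balance value that prevailed on each day; formation at day t refills
# what BMUs originated T_R + T_I to T_R + T_I + T_F days ago resorbed, so
# both windowed rates read from this shared history.

#' BMU activation frequency under mechanical inhibition
#'
#' Activation cannot exceed the biological frequency set by genetic and
#' hormonal influences and is inhibited by the mechanical stimulus:
#' `f_or = f_bio_eff * (1 - zeta / (zeta + zeta_ref))`, i.e. half the
#' biological frequency at habitual stimulus (`zeta = zeta_ref`).
#'
#' @param zeta daily mechanical stimulus (>= 0).
#' @param zeta_ref reference (habitual) stimulus (> 0).
#' @param f_bio_eff effective biological activation frequency,
#'   1/(mm^2 day), after any kappa(t) scaling.
#' @return Origination frequency per unit free surface, 1/(mm^2 day).
#' @export
activation_frequency <- function(zeta, zeta_ref, f_bio_eff) {
  stopifnot(all(zeta >= 0), all(f_bio_eff >= 0))
  if (any(zeta_ref <= 0)) stop("zeta_ref must be positive", call. = FALSE)
  f_bio_eff * zeta_ref / (zeta + zeta_ref)
}

#' BMU origination rate per unit volume
#'
#' BMUs originate on free surface: `dN_bmu/dt = f_or * S_v`.
#'
#' @param f_or activation frequency, 1/(mm^2 day).
#' @param s_v specific surface, 1/mm.
#' @return Origination density, BMU/(mm^3 day).
#' @export
origination_rate <- function(f_or, s_v) {
  stopifnot(all(f_or >= 0), all(s_v >= 0))
  f_or * s_v
}

#' Focal bone balance curve
#'
#' Ratio of bone formed to bone resorbed by a BMU as a piecewise-linear
#' function of the stimulus error `x = zeta - zeta_ref`: a dead zone of
#' half-width `w` where remodeling is balanced, linear transition zones of
#' width `v`, and saturation at `f_bb_min` (disuse) and `f_bb_max`
#' (overload).  The whole curve scales multiplicatively with
#' `kappa_fbb(t)`; `kappa < 1` shifts it down so that even the dead zone
#' resorbs on net.
#'
#' @param x stimulus error `zeta - zeta_ref` (vectorized).
#' @param kappa_fbb multiplicative modifier (>= 0).
#' @param params a [bone_params()] object (uses `w`, `v`, `f_bb_min`,
#'   `f_bb_max`).
#' @return Focal balance values.
#' @export
#' @examples
#' focal_balance(c(-5e-3, 0, 5e-3), kappa_fbb = 0.903)
focal_balance <- function(x, kappa_fbb = 1, params = bone_params()) {
  stopifnot(all(kappa_fbb >= 0))
  w <- params$w; v <- params$v
  lo <- params$f_bb_min; hi <- params$f_bb_max
  y <- ifelse(x <= -(w + v), lo,
       ifelse(x < -w, lo + (1 - lo) * (x + w + v) / v,
       ifelse(x <= w, 1,
       ifelse(x < w + v, 1 + (hi - 1) * (x - w) / v, hi))))
  kappa_fbb * y
}

#' BMU history ring buffer
#'
#' Stores the last `T_R + T_I + T_F` days of BMU origination density and
#' focal balance, oldest first, together with incrementally maintained
#' window sums (`sum_r` over the resorption window, `sum_f` over the
#' formation window of `n_bmu * f_bb`).  Buffers are pre-filled with
#' equilibrium values so a simulation starts at steady state.
#'
#' @param params a [bone_params()] object.
#' @param n_bmu_eq equilibrium origination density used to pre-fill.
#' @param f_bb_eq equilibrium focal balance used to pre-fill (1 at steady
#'   state).
#' @return A list of class `bmu_history`.
#' @export
bmu_history <- function(params = bone_params(), n_bmu_eq = 0, f_bb_eq = 1) {
  stopifnot(n_bmu_eq >= 0, f_bb_eq >= 0)
  len <- params$T_R + params$T_I + params$T_F
  h <- list(n_bmu = rep(n_bmu_eq, len), f_bb = rep(f_bb_eq, len),
            T_R = params$T_R, T_I = params$T_I, T_F = params$T_F)
  h$sum_r <- sum(h$n_bmu[(len - params$T_R + 1):len])
  h$sum_f <- sum(h$n_bmu[1:params$T_F] * h$f_bb[1:params$T_F])
  structure(h, class = "bmu_history")
}

#' Advance the BMU history by one day
#'
#' Pushes today's origination density and focal balance and updates the
#' incremental window sums in O(1).
#'
#' @param history a [bmu_history()].
#' @param n_bmu today's origination density, BMU/(mm^3 day).
#' @param f_bb today's focal balance.
#' @return The updated history.
#' @export
push_history <- function(history, n_bmu, f_bb) {
  stopifnot(inherits(history, "bmu_history"), n_bmu >= 0, f_bb >= 0)
  len <- length(history$n_bmu)
  T_R <- history$T_R; T_F <- history$T_F
  # entries shift one day older: update sums before the shift
  history$sum_r <- history$sum_r + n_bmu - history$n_bmu[len - T_R + 1]
  history$sum_f <- history$sum_f +
    history$n_bmu[T_F + 1] * history$f_bb[T_F + 1] -
    history$n_bmu[1] * history$f_bb[1]
  history$n_bmu <- c(history$n_bmu[-1], n_bmu)
  history$f_bb <- c(history$f_bb[-1], f_bb)
  history
}

#' Windowed formation and resorption rates
#'
#' Formation at day t integrates the origination history over the window
#' `[t - T_R - T_I - T_F, t - T_R - T_I)` — the BMUs whose formation phase
#' is active today — weighted by the focal balance that prevailed when each
#' cohort originated, and scaled by `a_bmu * v_bmu / T_F`.  Resorption
#' integrates the last `T_R` days scaled by `a_bmu * v_bmu / T_R`.  Both
#' recompute their window sum directly from the stored history (the
#' incremental `sum_r`/`sum_f` fields exist for the engines and can be
#' checked against these).
#'
#' @param history a [bmu_history()].
#' @param params a [bone_params()] object.
#' @return Rate of change of bone volume fraction, 1/day.
#' @export
formation_rate <- function(history, params = bone_params()) {
  stopifnot(inherits(history, "bmu_history"))
  len <- length(history$n_bmu)
  need <- params$T_R + params$T_I + params$T_F
  if (len < need) {
    stop("history too short: formation needs ", need, " days of warm-up", call. = FALSE)
  }
  idx <- seq_len(params$T_F)
  params$a_bmu * params$v_bmu / params$T_F *
    sum(history$n_bmu[idx] * history$f_bb[idx])
}

#' @rdname formation_rate
#' @export
resorption_rate <- function(history, params = bone_params()) {
  stopifnot(inherits(history, "bmu_history"))
  len <- length(history$n_bmu)
  if (len < params$T_R) {
    stop("history too short: resorption needs ", params$T_R, " days", call. = FALSE)
  }
  idx <- (len - params$T_R + 1):len
  params$a_bmu * params$v_bmu / params$T_R * sum(history$n_bmu[idx])
}

#' Net remodeling rate
#'
#' @param v_f_dot formation rate, 1/day.
#' @param v_r_dot resorption rate, 1/day.
#' @return `v_f_dot - v_r_dot` (negative under net resorption).
#' @export
net_rate <- function(v_f_dot, v_r_dot) {
  stopifnot(all(v_f_dot >= 0), all(v_r_dot >= 0))
  v_f_dot - v_r_dot
}

#' Ash fraction of a tissue layer as a function of age
#'
#' Secondary mineralization law
#' `alpha(age) = alpha_max - (alpha_max - alpha_0) exp(-age / tau_sec)`:
#' fresh osteoid is deposited at the primary level `alpha_0` and
#' asymptotically approaches `alpha_max` over the long secondary phase.
#'
#' @param age layer age, days (vectorized).
#' @param params a [bone_params()] object.
#' @return Ash fraction.
#' @export
layer_mineral <- function(age, params = bone_params()) {
  stopifnot(all(age >= 0))
  params$alpha_max - (params$alpha_max - params$alpha_0) * exp(-age / params$tau_sec)
}

#' Layered tissue stack
#'
#' The tissue at a material point is a stack of layers, youngest at the
#' surface (element 1), each carrying the bone volume fraction it
#' contributes and its age in days.
#'
#' @param thickness layer thicknesses (bone volume fraction), youngest
#'   first.
#' @param age layer ages, days, non-decreasing from surface to depth.
#' @return A list of class `layer_stack`.
#' @export
layer_stack <- function(thickness = numeric(), age = numeric()) {
  stopifnot(length(thickness) == length(age), all(thickness > 0), all(age >= 0),
            !is.unsorted(age))
  if (sum(thickness) > 1 + 1e-9) stop("total bone volume fraction exceeds 1")
  structure(list(thickness = as.numeric(thickness), age = as.numeric(age)),
            class = "layer_stack")
}

#' Apply one day of turnover to a layer stack
#'
#' Removes `v_r_dot * dt` of bone volume and deposits a fresh surface layer
#' of `v_f_dot * dt`.  A fraction `lifo_fraction` of the resorbed volume is
#' taken youngest-first from the surface (splitting a layer if needed) —
#' superficial, less mineralized tissue goes first, and deeper, older
#' tissue is reached only when superficial volume is exhausted.  The
#' remainder tunnels proportionally through layers of all ages, standing
#' for BMUs that cut through older interstitial tissue; it is what couples
#' turnover to mean tissue age.  Surviving layers age by `dt`.
#'
#' @param stack a [layer_stack()].
#' @param v_f_dot formation rate, 1/day.
#' @param v_r_dot resorption rate, 1/day.
#' @param dt time step, days.
#' @param params a [bone_params()] object (uses `lifo_fraction`).
#' @return The updated stack.  If resorption exceeds the available volume
#'   the stack is emptied with a warning.
#' @export
apply_turnover <- function(stack, v_f_dot, v_r_dot, dt = 1,
                           params = bone_params()) {
  stopifnot(inherits(stack, "layer_stack"), v_f_dot >= 0, v_r_dot >= 0, dt > 0)
  th <- stack$thickness
  age <- stack$age
  total <- sum(th)
  resorb <- v_r_dot * dt
  if (resorb > total) {
    warning("resorption exceeds available bone volume; tissue depleted")
    th <- numeric(); age <- numeric()
  } else if (resorb > 0 && total > 0) {
    mix <- (1 - params$lifo_fraction) * resorb
    if (mix > 0) th <- th * (1 - mix / total)
    rem <- params$lifo_fraction * resorb
    while (rem > 0 && length(th)) {
      if (th[1] > rem) {
        th[1] <- th[1] - rem
        rem <- 0
      } else {
        rem <- rem - th[1]
        th <- th[-1]
        age <- age[-1]
      }
    }
  }
  age <- age + dt
  form <- v_f_dot * dt
  if (form > 0) {
    th <- c(form, th)
    age <- c(0, age)
  }
  structure(list(thickness = th, age = age), class = "layer_stack")
}

#' Coalesce adjacent layers of similar age
#'
#' Merges neighbouring layers whose ages differ by less than `window`
#' days (thickness-weighted age), bounding stack size over multi-decade
#' runs at the cost of sub-`window` age resolution.
#'
#' @param stack a [layer_stack()].
#' @param window merging window, days; `0` disables.
#' @return The coalesced stack.
#' @export
coalesce_stack <- function(stack, window = 30) {
  stopifnot(inherits(stack, "layer_stack"), window >= 0)
  n <- length(stack$thickness)
  if (window == 0 || n < 2) return(stack)
  th <- stack$thickness; age <- stack$age
  out_th <- th[1]; out_age <- age[1]
  j <- 1
  for (i in 2:n) {
    if (age[i] - out_age[j] < window) {
      w <- out_th[j] + th[i]
      out_age[j] <- (out_age[j] * out_th[j] + age[i] * th[i]) / w
      out_th[j] <- w
    } else {
      j <- j + 1
      out_th[j] <- th[i]
      out_age[j] <- age[i]
    }
  }
  structure(list(thickness = out_th, age = out_age), class = "layer_stack")
}

#' Aggregate a layer stack into a composition point
#'
#' @param stack a [layer_stack()].
#' @param params a [bone_params()] object.
#' @return A list with `v_b` (total bone volume fraction), `alpha_mean`
#'   (thickness-weighted mean ash fraction) and `v_m_mean`
#'   (thickness-weighted mean mineral volume fraction); zeros for an empty
#'   stack.
#' @export
stack_summary <- function(stack, params = bone_params()) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!length(stack$thickness)) return(list(v_b = 0, alpha_mean = 0, v_m_mean = 0))
  v_b <- sum(stack$thickness)
  al <- layer_mineral(stack$age, params)
  wts <- stack$thickness / v_b
  list(v_b = v_b,
       alpha_mean = sum(wts * al),
       v_m_mean = sum(wts * mineral_fraction_from_ash(al, params$tissue)))
}
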