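# Daily mechanical stimulus and reference-stimulus accommodation.

#' Uniaxial site strain
#'
#' Effective strain of a habitual stress amplitude at a site,
#' `epsilon = sigma / E`.  Stands in for the organ-level strain field: each
#' ensemble site carries habitual stress amplitudes whose strains rise as
#' the tissue loses stiffness.
#'
#' @param sigma stress amplitude, MPa.
#' @param E elastic modulus, MPa (> 0).
#' @return Strain (dimensionless).
#' @export
site_strain <- function(sigma, E) {
  stopifnot(all(sigma >= 0))
  if (any(E <= 0)) stop("degenerate tissue: elastic modulus must be positive", call. = FALSE)
  sigma / E
}

#' Daily mechanical stimulus
#'
#' Cycle-weighted strain norm over the day's load cases:
#' `zeta = (sum_i N_i epsilon_i^m)^(1/m)` with `m = 4` by default.  It is a
#' weighted m-norm: scale-equivariant in strain and monotone in every cycle
#' count.
#'
#' @param cycles cycles per day for each load case.
#' @param strains effective strain of each load case.
#' @param m cycle-weighting exponent.
#' @return The daily stimulus (0 for an empty case list).
#' @export
#' @examples
#' daily_stimulus(5000, 0.002)
daily_stimulus <- function(cycles, strains, m = 4) {
  stopifnot(length(cycles) == length(strains), all(cycles >= 0),
            all(strains >= 0), m >= 1)
  if (!length(cycles)) return(0)
  sum(cycles * strains^m)^(1 / m)
}

#' Accommodation of the reference stimulus
#'
#' The reference stimulus slowly adapts to the experienced stimulus,
#' `d zeta_ref / dt = phi (zeta - zeta_ref)`, integrated with an explicit
#' Euler step: after a sustained load step the gap contracts by
#' `(1 - phi dt)` per day, i.e. approximately `exp(-phi t)`.
#'
#' @param zeta daily stimulus.
#' @param zeta_ref current reference stimulus.
#' @param phi accommodation rate, 1/day.
#' @param dt time step, days; `phi * dt` must be below 1.
#' @return The updated reference stimulus.
#' @export
update_reference <- function(zeta, zeta_ref, phi, dt = 1) {
  stopifnot(all(zeta >= 0), all(zeta_ref >= 0), dt > 0)
  if (phi * dt >= 1 || phi <= 0) {
    stop("phi * dt must lie in (0, 1) for a stable accommodation update", call. = FALSE)
  }
  zeta_ref + phi * (zeta - zeta_ref) * dt
}
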