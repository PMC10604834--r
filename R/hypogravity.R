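#' Physical constants for the underwater hypogravity simulation
#'
#' @param g_earth gravitational acceleration, m/s^2.
#' @param g_target simulated gravity, m/s^2; default is lunar gravity.
#' @param rho_water water density, kg/m^3 (freshwater tank).
#' @param rho_ballast ballast density, kg/m^3 (lead).
#' @return A list of class `sim_constants`.
#' @export
sim_constants <- function(g_earth = 9.81, g_target = 1.626,
                          rho_water = 1000, rho_ballast = 11340) {
  stopifnot(g_earth > 0, g_target > 0, g_target < g_earth,
            rho_water > 0, rho_ballast > rho_water)
  structure(list(g_earth = g_earth, g_target = g_target,
                 rho_water = rho_water, rho_ballast = rho_ballast),
            class = "sim_constants")
}

#' Ballast mass compensating a submerged segment's buoyancy
#'
#' Solves the vertical force balance for a submerged body segment so that its
#' apparent weight equals its weight under the target gravity:
#' `(m + m_b) g - rho_w (V + m_b / rho_b) g = m g_t`, giving
#' `m_b = (m (g_t - g) + rho_w V g) / (g (1 - rho_w / rho_b))`.
#'
#' With `include_ballast_in_target = TRUE` the ballast itself counts as part of
#' the simulated mass (right-hand side `(m + m_b) g_t`), the alternative
#' accounting in which the ballast is payload rather than pure compensation
#' hardware.
#'
#' @param segment_mass segment mass, kg (vectorized).
#' @param segment_volume segment volume, m^3 (vectorized).
#' @param constants a [sim_constants()] object.
#' @param include_ballast_in_target logical; see Details.
#' @return A data frame with columns `ballast_mass` (kg), `ballast_volume`
#'   (m^3) and `residual_force` (N, the balance evaluated at the solution).
#' @export
#' @examples
#' ballast_mass(1.55, 1.37e-3)  # mean male forearm: ~0.084 kg of lead
ballast_mass <- function(segment_mass, segment_volume,
                         constants = sim_constants(),
                         include_ballast_in_target = FALSE) {
  stopifnot(is.numeric(segment_mass), is.numeric(segment_volume),
            all(is.finite(segment_mass)), all(is.finite(segment_volume)),
            all(segment_mass > 0), all(segment_volume > 0))
  g <- constants$g_earth; gt <- constants$g_target
  rw <- constants$rho_water; rb <- constants$rho_ballast
  if (rb <= rw) stop("ballast density must exceed water density (it would float)")
  denom <- if (include_ballast_in_target) g - gt - rw * g / rb else g * (1 - rw / rb)
  m_b <- (segment_mass * (gt - g) + rw * segment_volume * g) / denom
  if (any(m_b < 0)) {
    flot <- -m_b[m_b < 0]
    stop(sprintf(paste0(
      "segment already heavier than its target-gravity weight; ",
      "requires flotation of %s kg, not ballast"),
      paste(format(flot), collapse = ", ")))
  }
  res <- balance_residual(segment_mass, segment_volume, m_b, constants,
                          include_ballast_in_target)
  data.frame(ballast_mass = m_b, ballast_volume = m_b / rb, residual_force = res)
}

# net vertical force: (weight + ballast weight) - buoyancy - simulated weight (N)
balance_residual <- function(m, V, m_b, constants,
                             include_ballast_in_target = FALSE) {
  g <- constants$g_earth; gt <- constants$g_target
  rw <- constants$rho_water; rb <- constants$rho_ballast
  target_mass <- if (include_ballast_in_target) m + m_b else m
  (m + m_b) * g - rw * (V + m_b / rb) * g - target_mass * gt
}

#' Build a per-segment ballast plan
#'
#' @param segments data frame with columns `name`, `mass_kg`, `volume_dm3`.
#' @param constants a [sim_constants()] object.
#' @param include_ballast_in_target see [ballast_mass()].
#' @return A data frame of class `ballast_plan`: per-segment masses, volumes,
#'   ballast masses/volumes (kg, m^3) and the force-balance residual (N).
#' @export
ballast_plan <- function(segments, constants = sim_constants(),
                         include_ballast_in_target = FALSE) {
  stopifnot(is.data.frame(segments),
            all(c("name", "mass_kg", "volume_dm3") %in% names(segments)))
  V <- segments$volume_dm3 * 1e-3
  sol <- ballast_mass(segments$mass_kg, V, constants, include_ballast_in_target)
  out <- data.frame(
    name = segments$name,
    segment_mass = segments$mass_kg,
    segment_volume = V,
    ballast_mass = sol$ballast_mass,
    ballast_volume = sol$ballast_volume,
    residual_force = sol$residual_force,
    stringsAsFactors = FALSE
  )
  attr(out, "constants") <- constants
  attr(out, "include_ballast_in_target") <- include_ballast_in_target
  class(out) <- c("ballast_plan", "data.frame")
  out
}

#' Validate a ballast plan against the force balance
#'
#' Recomputes weight minus buoyancy minus simulated target weight for every
#' entry, independently of how the plan was produced, and returns the maximum
#' absolute residual (N). An empty plan validates to 0.
#'
#' @param plan a [ballast_plan()] (or any data frame with `segment_mass`,
#'   `segment_volume`, `ballast_mass` columns).
#' @param constants a [sim_constants()] object; defaults to the constants the
#'   plan was built with, if recorded.
#' @return Maximum absolute net force over entries, N.
#' @export
validate_balance <- function(plan, constants = NULL) {
  if (is.null(constants)) constants <- attr(plan, "constants")
  if (is.null(constants)) constants <- sim_constants()
  ibt <- isTRUE(attr(plan, "include_ballast_in_target"))
  if (nrow(plan) == 0L) return(0)
  res <- balance_residual(plan$segment_mass, plan$segment_volume,
                          plan$ballast_mass, constants, ibt)
  max(abs(res))
}

#' Drag-limited maximum hand speed
#'
#' Largest steady speed at which quadratic drag stays below a given fraction of
#' a reference weight: from `F_drag = 0.5 rho C_d A v^2 = f W`,
#' `v = sqrt(2 f W / (rho C_d A))`.
#'
#' @param reference_weight reference weight W, N (e.g. the forearm's simulated
#'   target-gravity weight).
#' @param drag_fraction allowed drag as a fraction of `reference_weight`.
#' @param drag_area frontal area A, m^2.
#' @param drag_coefficient dimensionless C_d (default 1, a blunt cylinder).
#' @param rho_water water density, kg/m^3.
#' @return Speed, m/s.
#' @export
#' @examples
#' max_hand_speed(10, 0.1, 0.01)  # sqrt(0.2) ~ 0.447 m/s
max_hand_speed <- function(reference_weight, drag_fraction = 0.1, drag_area,
                           drag_coefficient = 1.0, rho_water = 1000) {
  vals <- c(reference_weight, drag_fraction, drag_area, drag_coefficient, rho_water)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all drag inputs must be positive and finite")
  }
  if (drag_fraction >= 1) stop("drag_fraction must be in (0, 1)")
  sqrt(2 * drag_fraction * reference_weight /
         (rho_water * drag_coefficient * drag_area))
}

#' Flag ballasts whose rotational inertia is non-negligible
#'
#' Point-mass moment of inertia `I = m_b r^2` at each segment's CoM, flagged
#' when the ballast mass exceeds the threshold (3 kg) above which ballast
#' inertia noticeably affects movement.
#'
#' @param plan a [ballast_plan()].
#' @param lever_arms numeric vector (m), one per plan entry: distance of the
#'   ballast from the rotation axis.
#' @param threshold_mass kg; ballasts heavier than this are flagged.
#' @return Data frame with `name`, `ballast_mass`, `I` (kg m^2), `flagged`.
#' @export
inertia_flag <- function(plan, lever_arms, threshold_mass = 3.0) {
  stopifnot(length(lever_arms) == nrow(plan), all(lever_arms >= 0))
  data.frame(
    name = plan$name,
    ballast_mass = plan$ballast_mass,
    I = plan$ballast_mass * lever_arms^2,
    flagged = plan$ballast_mass > threshold_mass,
    stringsAsFactors = FALSE
  )
}
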