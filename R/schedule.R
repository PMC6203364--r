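#' Dosing schedule (drug boundary condition)
#'
#' Describes the drug concentration imposed on the Dirichlet shell of the
#' simulation domain. Three modes:
#'
#' * `constant`: time-independent level `C0` (continuous infusion).
#' * `periodic`: infusion-decay cycles; within each cycle of length
#'   `tau_cycle` the boundary level is the logistic
#'   `C(t) = C0 / (1 + exp((t mod tau_cycle - tau_decay) / (tau_decay/10)))`,
#'   i.e. a plateau near `C0` that decays around `tau_decay`. Small
#'   `tau_decay` mimics the fast drug washout of a vascularized
#'   micro-environment, large `tau_decay` the slow diffusive decay of an
#'   avascular one (per the PBPK analysis).
#' * `periodic_regional`: the periodic value applied only on shell voxels
#'   satisfying a spatial `region` predicate (localized vasculature); the
#'   rest of the shell is zero-gradient.
#'
#' @param mode one of `"constant"`, `"periodic"`, `"periodic_regional"`.
#' @param C0 boundary concentration scale (ug/ml). Concentrations elsewhere
#'   are conveniently reported normalized by `C0`.
#' @param tau_cycle dosing period (min).
#' @param tau_decay decay time (min); steepness of the decay is
#'   `tau_decay / 10`.
#' @param tau_infusion infusion time (min), informational only.
#' @param region for the regional mode: `function(x, y, z)` returning TRUE on
#'   dosed shell voxels.
#' @param R_boundary dosing shell radius (cm); voxels at radius >=
#'   `R_boundary` from the domain center carry the boundary condition.
#' @return An object of class `dose_schedule`.
#' @examples
#' sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440, tau_decay = 600)
#' boundary_value(sch, t_min = 600)  # logistic midpoint: C0/2
#' @export
dose_schedule <- function(mode = c("constant", "periodic", "periodic_regional"),
                          C0 = 1, tau_cycle = 1440, tau_decay = 600,
                          tau_infusion = NULL, region = NULL,
                          R_boundary = NULL) {
  mode <- match.arg(mode)
  stopifnot(C0 >= 0)
  if (mode != "constant") {
    stopifnot(tau_cycle > 0, tau_decay > 0)
  }
  if (mode == "periodic_regional" && !is.function(region))
    stop("periodic_regional mode needs a region predicate function(x, y, z)")
  structure(list(mode = mode, C0 = C0, tau_cycle = tau_cycle,
                 tau_decay = tau_decay, tau_infusion = tau_infusion,
                 region = region, R_boundary = R_boundary),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %s, C0 = %g ug/ml", x$mode, x$C0))
  if (x$mode != "constant")
    cat(sprintf(", tau_cycle = %g min, tau_decay = %g min",
                x$tau_cycle, x$tau_decay))
  cat("\n")
  invisible(x)
}

# schedule mode code shared with the C++ stepper
.sched_mode_code <- function(schedule) {
  switch(schedule$mode, constant = 0L, periodic = 1L, periodic_regional = 1L)
}

#' Boundary concentration at a given time
#'
#' @param schedule a [dose_schedule()].
#' @param t_min time (min), >= 0.
#' @return Concentration (ug/ml) imposed on the dosed shell at `t_min`.
#' @export
boundary_value <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "dose_schedule"), all(t_min >= 0))
  if (schedule$mode == "constant") return(rep_len(schedule$C0, length(t_min)))
  tm <- t_min %% schedule$tau_cycle
  schedule$C0 / (1 + exp((tm - schedule$tau_decay) / (schedule$tau_decay / 10)))
}
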