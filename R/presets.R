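#' Experiment presets
#'
#' Canned configurations for the study scenarios: growth of an invasive
#' tumor in homogeneous matrix under free growth, idealized constant dosing,
#' or periodic dosing in vascularized/avascular micro-environments; plus the
#' steady-state-tumor drug-transport validations. Each preset builds its
#' lattice and environment from the seed and runs the appropriate driver.
#'
#' Scenario conventions (shared across presets): 0.8 cm cubic box with a
#' spherical growth domain of radius 0.4 cm; hard-sphere radius 0.01 cm at
#' packing fraction 0.3 (~37k automaton cells); homogeneous ECM density 0.3;
#' seeded tumor of linear size 0.06 cm; invasive phenotype enabled with
#' mutation rate 0.05, mobility 3 and ECM degradation ability 0.4;
#' `Kmet = 2e-4 min^-1`. Periodic presets couple the full drug PDE on a
#' 21^3 grid (dx = 0.04 cm) with `Np = 50` sub-steps/day; the division
#' reduction floor is `Pgamma = 0.05` and `tau_cycle = 1` day.
#'
#' @param seed integer seed controlling packing and automaton randomness.
#' @param days simulated days (default 120).
#' @param scenario one of `"free"`, `"constant"` (uniform reduction
#'   `Pgamma0`), `"periodic_vascularized"` (`tau_decay = 600` min),
#'   `"periodic_avascular"` (`tau_decay = 1800` min).
#' @param Pgamma0 uniform division-reduction factor of the constant-dosing
#'   scenario (0.6 or 0.3 in the study).
#' @param lambda14 consumption coefficient (s^-1) of the periodic scenarios.
#' @param lattice optionally, a prebuilt lattice (so paired scenarios can
#'   share one tessellation); when NULL a lattice is generated from `seed`.
#' @param days,seed passed through to the drivers.
#' @return A `simulation_run`.
#' @export
run_growth_experiment <- function(scenario = c("free", "constant",
                                               "periodic_vascularized",
                                               "periodic_avascular"),
                                  seed, days = 120, Pgamma0 = 0.6,
                                  lambda14 = 2.5e-4, lattice = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(lattice)) lattice <- growth_lattice(seed)
  ecm <- homogeneous_ecm(lattice, 0.3)
  params <- ca_params(gamma = 0.05, mu = 3, chi = 0.4,
                      Pgamma = if (scenario == "constant") Pgamma0 else 0.05)
  switch(scenario,
    free = run_ca(lattice, ecm, params, days = days, seed = seed,
                  phi_norm = 0, R_domain = 0.4),
    constant = run_ca(lattice, ecm, params, days = days, seed = seed,
                      phi_norm = 1, R_domain = 0.4),
    periodic_vascularized = ,
    periodic_avascular = {
      tau_decay <- if (scenario == "periodic_avascular") 1800 else 600
      sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440,
                           tau_decay = tau_decay)
      run_coupled(lattice, ecm, params, schedule = sch,
                  drug = drug_params(lambda14 = lambda14),
                  coupling = coupling_config(Np = 50),
                  days = days, seed = seed, R_domain = 0.4)
    })
}

#' @rdname run_growth_experiment
#' @export
growth_lattice <- function(seed) {
  pk <- generate_packing(0.8, radius = 0.01, target_fraction = 0.3,
                         seed = seed)
  build_lattice(pk, grid_spacing = 0.04)
}

#' Steady-state-tumor drug-transport presets
#'
#' The ideal-tumor validations: drug transport into a static Fermi-profile
#' tumor (`r0 = 0.2` cm, `sigma = 0.01` cm) in a 0.8 cm box with the dosing
#' shell at `R = 0.4` cm, `D0 = 1.3e-6 cm^2/s`.
#'
#' * `constant`: constant dosing, `Kmet = 2.0e-4 min^-1`, grid `dx = 0.01`
#'   cm, Euler step 0.1 s unless overridden.
#' * `periodic`: infusion-decay dosing (`tau_cycle = 1440` min) with
#'   `Kmet = 2.5e-4 min^-1`; `tau_decay` 600 min (vascularized) or 1800 min
#'   (avascular).
#'
#' @param mode `"constant"` or `"periodic"`.
#' @param lambda14 consumption coefficient (s^-1).
#' @param t_end_min simulated minutes.
#' @param tau_decay_min decay time for the periodic mode (min).
#' @param dx grid spacing (cm).
#' @param dt Euler step (s); NULL uses `0.4 dx^2 / D0`.
#' @param r0,sigma Fermi-profile radius and boundary-layer thickness (cm).
#' @param record_every_min sampling interval of the center trace (min).
#' @param profile_times_min times at which radial profiles are stored.
#' @return As [solve_steady_state_tumor()].
#' @export
run_steady_tumor_experiment <- function(mode = c("constant", "periodic"),
                                        lambda14 = 2.5e-4,
                                        t_end_min = 300,
                                        tau_decay_min = 600,
                                        dx = 0.01, dt = NULL,
                                        r0 = 0.2, sigma = 0.01,
                                        record_every_min = 10,
                                        profile_times_min = t_end_min) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    sch <- dose_schedule("constant", C0 = 1)
    Kmet <- 2.0e-4
  } else {
    sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440,
                         tau_decay = tau_decay_min)
    Kmet <- 2.5e-4
  }
  solve_steady_state_tumor(fermi_profile(r0, sigma), sch,
                           t_end_min = t_end_min, L = 0.8, dx = dx,
                           record_every_min = record_every_min,
                           profile_times_min = profile_times_min,
                           D0 = 1.3e-6, Kmet = Kmet, lambda14 = lambda14,
                           dt = dt)
}
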