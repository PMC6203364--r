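#' Characteristic diffusion time
#'
#' From the free-space Green's function of the diffusion equation, the time
#' `t_m = x0^2 / (4 D)` at which the concentration a distance `x0` from an
#' impulse source reaches about `e^-1` of the source level. For typical
#' drugs (`D ~ 1.3e-6 cm^2/s`) and tumor sizes (`x0 ~ 0.3 cm`), `t_m` is a
#' fraction of a day — shorter than a cell cycle, which motivates
#' sub-stepping drug transport within each proliferation cycle.
#'
#' @param D diffusion coefficient (cm^2/s), > 0.
#' @param x0 distance (cm), >= 0.
#' @return Time in seconds.
#' @examples
#' characteristic_diffusion_time(1.3e-6, 0.3)  # ~1.73e4 s, about 0.2 day
#' @export
characteristic_diffusion_time <- function(D, x0) {
  stopifnot(D > 0, all(x0 >= 0))
  x0^2 / (4 * D)
}

#' Quasi-parallel coupling configuration
#'
#' One cell cycle and one dosing period are divided into the same number
#' `Np` of sub-steps: in each sub-step the drug field advances by
#' `cell_cycle/Np` of physical time and the cohort of proliferative cells
#' assigned to that sub-step attempts division at the current local drug
#' concentration; the cell-density and diffusivity fields seen by the PDE
#' are refreshed in between. `Np` of 50-100 approximates the fully coupled
#' dynamics; cells are assigned to sub-steps uniformly at random so cells in
#' different regions divide at different times within the cycle.
#'
#' @param Np sub-steps per cycle, >= 1.
#' @param cell_cycle cell-cycle duration (day).
#' @param exchange_phi pass the drug field to the division-reduction factor.
#' @param exchange_n pass the cell occupancy to the consumption term.
#' @param exchange_D refresh the heterogeneous diffusivity from ECM/tumor
#'   occupancy.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(Np = 50, cell_cycle = 1, exchange_phi = TRUE,
                            exchange_n = TRUE, exchange_D = TRUE) {
  stopifnot(Np >= 1, cell_cycle > 0)
  structure(list(Np = as.integer(Np), cell_cycle = cell_cycle,
                 exchange_phi = exchange_phi, exchange_n = exchange_n,
                 exchange_D = exchange_D),
            class = "coupling_config")
}

#' Drug transport/consumption parameter bundle
#'
#' @param D0 reference diffusion coefficient (cm^2/s).
#' @param Kmet first-order decay rate (min^-1).
#' @param lambda14 per-cell consumption coefficient (s^-1).
#' @param phi0 Michaelis constant (ug/ml); default `0.5 * C0` at field
#'   construction.
#' @param eta intratumoral diffusivity factor.
#' @param rho_res residual ECM density after full degradation.
#' @param rho0 reference ECM density.
#' @param heterogeneous_D use the ECM/occupancy-dependent diffusivity
#'   (otherwise uniform `D0`).
#' @return A list of class `drug_params`.
#' @export
drug_params <- function(D0 = 1.3e-6, Kmet = 2.0e-4, lambda14 = 2.5e-4,
                        phi0 = NULL, eta = 0.75, rho_res = 0.1, rho0 = 0.3,
                        heterogeneous_D = TRUE) {
  structure(list(D0 = D0, Kmet = Kmet, lambda14 = lambda14, phi0 = phi0,
                 eta = eta, rho_res = rho_res, rho0 = rho0,
                 heterogeneous_D = heterogeneous_D),
            class = "drug_params")
}

#' Run the coupled tumor-growth simulation
#'
#' The main driver: grows the cellular-automaton tumor day by day, with drug
#' transport interleaved by the quasi-parallel scheme of
#' [coupling_config()]. Each day the proliferative cells present at the day
#' start are partitioned at random into `Np` cohorts; sub-step `s` advances
#' the diffusion-reaction field by `cell_cycle/Np` of physical time (as many
#' stable Euler steps as needed) and then lets cohort `s` attempt division
#' at the current local normalized concentration. At the day boundary the
#' remaining automaton rules run: necrosis, quiescence, and invasive
#' degradation/migration. Daily summary metrics are recorded.
#'
#' With `schedule = NULL` no drug field is simulated and dividing cells see
#' the uniform normalized concentration `phi_norm_const` (0 for free
#' growth, 1 with `params$Pgamma` for an idealized constant dosing at full
#' strength); the cohort partition and all draws are unchanged, so a
#' zero-concentration schedule reproduces the drug-free run exactly at the
#' same seed.
#'
#' @param lattice a [build_lattice()] result.
#' @param ecm per-site ECM densities.
#' @param params a [ca_params()].
#' @param schedule a [dose_schedule()] or NULL.
#' @param drug a [drug_params()].
#' @param coupling a [coupling_config()].
#' @param days number of simulated days.
#' @param seed integer seed (`set.seed` is called when non-NULL).
#' @param R_domain spherical domain radius (cm); default half the box edge.
#' @param initial_radius seed-tumor radius (cm).
#' @param phi_norm_const uniform normalized drug level for `schedule = NULL`
#'   runs.
#' @return An object of class `simulation_run`: `metrics` (daily data
#'   frame), `events` (daily data frame), final `state`, final drug `phi`
#'   (or NULL), and the configuration.
#' @export
run_coupled <- function(lattice, ecm, params = ca_params(), schedule = NULL,
                        drug = drug_params(), coupling = coupling_config(),
                        days = 120, seed = NULL, R_domain = NULL,
                        initial_radius = 0.03, phi_norm_const = 0) {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (!is.null(seed)) set.seed(seed)
  ts <- tumor_state(lattice, ecm, R_domain = R_domain,
                    initial_radius = initial_radius)
  ts <- .own_state(ts)
  pos <- lattice$points
  Np <- coupling$Np
  has_drug <- !is.null(schedule)
  field <- NULL
  phi <- NULL
  nvox <- lattice$grid$N^3
  if (has_drug) {
    Lx <- lattice$domain$hi[1] - lattice$domain$lo[1]
    field <- drug_field(Lx, lattice$grid$dx, schedule,
                        R_boundary = ts$R_domain, D0 = drug$D0,
                        Kmet = drug$Kmet, lambda14 = drug$lambda14,
                        phi0 = drug$phi0, eta = drug$eta,
                        rho_res = drug$rho_res, rho0 = drug$rho0)
    phi <- field$phi + 0
    sub_s <- .day2s(coupling$cell_cycle) / Np
  }
  metrics <- vector("list", days)
  events <- vector("list", days)
  zero_n <- numeric(0)
  for (day in seq_len(days)) {
    prolif <- which(ts$state == .ST[["proliferative"]]) - 1L
    cohort_of <- if (length(prolif))
      sample.int(Np, length(prolif), replace = TRUE) else integer(0)
    ndiv <- 0L; nmut <- 0L
    for (s in seq_len(Np)) {
      if (has_drug) {
        vox <- voxel_fields_cpp(ts$state, ts$rho, lattice$site_voxel,
                                as.integer(nvox), drug$D0, drug$eta,
                                drug$rho0, drug$rho_res)
        Dv <- if (drug$heterogeneous_D && coupling$exchange_D) vox$D else NULL
        nv <- if (coupling$exchange_n) vox$n else zero_n
        Dmax <- if (is.null(Dv)) drug$D0 else max(Dv)
        dt <- 0.95 * field$dx^2 / (6 * Dmax)
        nst <- max(1L, as.integer(ceiling(sub_s / dt)))
        dt <- sub_s / nst
        pmin <- .fd_advance(field, phi, nv, Dv, dt, nst)
        if (is.finite(pmin) && pmin < -1e-9 * max(schedule$C0, 1))
          stop(sprintf("drug field went negative (min %.3g) at day %d", pmin,
                       day))
        field$t_s <- field$t_s + sub_s
      }
      cohort <- prolif[cohort_of == s]
      if (length(cohort) || Np == 1L) {
        use_field <- has_drug && coupling$exchange_phi
        div <- ca_divide_cpp(cohort, ts$state, ts$rho, pos,
                             lattice$adj_ptr, lattice$adj_idx, ts$cstat,
                             if (use_field) phi else numeric(0),
                             lattice$site_voxel, phi_norm_const,
                             if (has_drug && schedule$C0 > 0) schedule$C0 else 1,
                             params$p0, params$Pgamma, params$gamma,
                             params$Ai,
                             as.integer(params$division_rule == "additive"),
                             as.integer(params$adhesion_neighbors == "tumor"),
                             ts$domain_center, ts$R_domain)
        ndiv <- ndiv + length(div$daughters)
        nmut <- nmut + length(div$mutated)
      }
    }
    nec <- ca_necrosis_cpp(ts$state, pos, lattice$adj_ptr, lattice$adj_idx,
                           ts$cstat[1:3], params$a)
    qui <- ca_quiescence_cpp(ts$state, pos, lattice$adj_ptr, lattice$adj_idx,
                             ts$cstat[1:3], params$b)
    mig <- ca_invasion_cpp(ts$state, ts$rho, pos, lattice$adj_ptr,
                           lattice$adj_idx, ts$cstat[1:3],
                           as.integer(params$mu), params$chi,
                           as.integer(params$migration == "random"))
    ts$day <- day
    if (has_drug && anyNA(phi)) stop("NaN in drug field at day ", day)
    metrics[[day]] <- compute_metrics(ts, lattice, phi_field = phi, day = day)
    events[[day]] <- data.frame(day = day, divisions = ndiv, mutations = nmut,
                                necrosed = nec, quiesced = qui,
                                migrations = mig)
  }
  structure(list(metrics = do.call(rbind, metrics),
                 events = do.call(rbind, events),
                 state = ts, phi = phi,
                 pde_t_s = if (has_drug) field$t_s else NA_real_,
                 lattice = lattice,
                 params = params, schedule = schedule, drug = drug,
                 coupling = coupling, seed = seed, days = days),
            class = "simulation_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cellular automaton without a drug field
#'
#' Convenience wrapper around [run_coupled()] with `schedule = NULL`:
#' free growth (`phi_norm = 0`) or idealized spatially uniform constant
#' dosing (`phi_norm = 1` with the reduction floor `params$Pgamma`).
#'
#' @inheritParams run_coupled
#' @param phi_norm uniform normalized drug level in `[0, 1]`.
#' @param Np sub-steps per day (1 suffices without a drug field).
#' @return A `simulation_run`.
#' @export
run_ca <- function(lattice, ecm, params = ca_params(), days = 120,
                   seed = NULL, phi_norm = 0, Np = 1, R_domain = NULL,
                   initial_radius = 0.03) {
  run_coupled(lattice, ecm, params = params, schedule = NULL,
              coupling = coupling_config(Np = Np), days = days, seed = seed,
              R_domain = R_domain, initial_radius = initial_radius,
              phi_norm_const = phi_norm)
}

#' @export
print.simulation_run <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("Simulation run: %d days, seed %s\n", x$days,
              format(x$seed %||% "none")))
  cat(sprintf("  day %d: R_P = %.3f cm, N_inv = %d, cells = %d\n",
              last$day, last$R_P, last$N_Inv,
              last$proliferative + last$quiescent + last$necrotic +
                last$N_Inv))
  invisible(x)
}
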