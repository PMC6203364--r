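#' Explicit-scheme stability check
#'
#' The Euler forward / 7-point-Laplacian scheme is stable for the diffusion
#' equation when `D_max * dt / dx^2 < 1/2` (strict). Heterogeneous runs use
#' the maximum per-voxel diffusivity.
#'
#' @param D_max (maximum) diffusion coefficient (cm^2/s).
#' @param dt time step (s).
#' @param dx grid spacing (cm).
#' @return List with `pass` (logical), `ratio` (`D_max*dt/dx^2`) and
#'   `dt_max` (largest admissible step, s).
#' @examples
#' check_stability(1.3e-6, dt = 0.1, dx = 0.01)
#' @export
check_stability <- function(D_max, dt, dx) {
  stopifnot(D_max > 0, dt > 0, dx > 0)
  ratio <- D_max * dt / dx^2
  list(pass = ratio < 0.5, ratio = ratio, dt_max = 0.5 * dx^2 / D_max)
}

#' Drug concentration field on a regular grid
#'
#' Sets up the scalar drug field phi on an `N^3` grid over the cubic domain,
#' with a spherical Dirichlet dosing shell: all nodes at radius >=
#' `R_boundary` from the domain center carry the schedule's boundary value;
#' the interior starts drug free. Consumption follows the diffusion-reaction
#' model
#' \deqn{\partial\phi/\partial t = \nabla\cdot(D\nabla\phi) - K_{met}\phi
#'       - \lambda_{14} n \phi/(\phi+\phi_0)}
#' with first-order chemical decomposition `Kmet` and Michaelis-Menten
#' cellular uptake scaled by the local (dimensionless) tumor-cell occupancy
#' `n`.
#'
#' @param L cube edge length (cm).
#' @param dx grid spacing (cm); `L/dx` must be a whole number.
#' @param schedule a [dose_schedule()].
#' @param R_boundary dosing-shell radius (cm); defaults to
#'   `schedule$R_boundary`, else `L/2`.
#' @param D0 reference diffusion coefficient (cm^2/s).
#' @param Kmet first-order decay rate (min^-1).
#' @param lambda14 per-cell consumption coefficient (s^-1).
#' @param phi0 Michaelis constant, same units as phi (default `0.5 * C0`).
#' @param eta intratumoral diffusivity factor (used when a heterogeneous
#'   diffusivity is derived from the environment).
#' @param rho_res residual ECM density after complete degradation.
#' @param rho0 reference ECM density of the uniform-matrix calibration.
#' @return An object of class `drug_field`.
#' @export
drug_field <- function(L, dx, schedule, R_boundary = NULL,
                       D0 = 1.3e-6, Kmet = 2.0e-4, lambda14 = 0,
                       phi0 = NULL, eta = 0.75, rho_res = 0.1, rho0 = 0.3) {
  steps <- L / dx
  if (abs(steps - round(steps)) > 1e-8) stop("L/dx must be a whole number")
  N <- as.integer(round(steps)) + 1L
  if (is.null(R_boundary)) R_boundary <- schedule$R_boundary
  if (is.null(R_boundary)) R_boundary <- L / 2
  if (R_boundary > L / 2 + 1e-12)
    stop("R_boundary must not exceed L/2 (the shell must enclose the interior)")
  if (is.null(phi0)) phi0 <- 0.5 * schedule$C0
  center <- rep(L / 2, 3)
  g <- seq(0, L, by = dx)
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(sweep(coords, 2, center)^2))
  shell <- r >= R_boundary - 1e-12
  mask <- integer(N^3)
  mask[shell] <- 1L
  zg_idx <- integer(0); zg_src <- integer(0)
  if (schedule$mode == "periodic_regional") {
    dosed <- shell & schedule$region(coords[, 1], coords[, 2], coords[, 3])
    mask[shell & !dosed] <- 2L
    zg <- which(mask == 2L)
    zg <- zg[order(r[zg])]  # copy inward-out so sources are already set
    src <- vapply(zg, function(id0) {
      id <- id0 - 1L
      i <- id %% N; j <- (id %/% N) %% N; k <- id %/% (N * N)
      nb <- c(if (i > 0) id - 1L, if (i < N - 1) id + 1L,
              if (j > 0) id - N, if (j < N - 1) id + N,
              if (k > 0) id - N * N, if (k < N - 1) id + N * N)
      nb[which.min(r[nb + 1L])]
    }, integer(1))
    zg_idx <- as.integer(zg - 1L)
    zg_src <- as.integer(src)
  }
  structure(list(
    phi = numeric(N^3), N = N, dx = dx, L = L, center = center, r = r,
    int_idx = as.integer(which(mask == 0L) - 1L),
    dir_idx = as.integer(which(mask == 1L) - 1L),
    zg_idx = zg_idx, zg_src = zg_src,
    schedule = schedule, D0 = D0, Kmet_s = Kmet / 60, lambda14 = lambda14,
    phi0 = phi0, eta = eta, rho_res = rho_res, rho0 = rho0,
    R_boundary = R_boundary, t_s = 0), class = "drug_field")
}

#' @export
print.drug_field <- function(x, ...) {
  cat(sprintf(
    "Drug field: %d^3 grid, dx = %g cm, shell R = %g cm, t = %.1f min\n",
    x$N, x$dx, x$R_boundary, x$t_s / 60))
  invisible(x)
}

# internal: advance a field's phi in place (phi vector owned by caller)
.fd_advance <- function(field, phi, nocc, D, dt, nsteps) {
  sched <- field$schedule
  uniform <- is.null(D)
  fd_run_cpp(phi, field$int_idx, field$dir_idx, field$zg_idx, field$zg_src,
             if (uniform) numeric(0) else D, uniform, field$D0,
             if (is.null(nocc)) numeric(0) else nocc,
             field$Kmet_s, field$lambda14, field$phi0,
             field$dx, dt, as.integer(nsteps), field$t_s,
             .sched_mode_code(sched), sched$C0,
             .min2s(sched$tau_cycle), .min2s(sched$tau_decay), field$N)
}

# Default production step. The classical von Neumann gate of
# check_stability() (ratio < 1/2) is the textbook one-dimensional bound; the
# 3D 7-point scheme is positivity-preserving and stable only for
# D*dt/dx^2 <= 1/6, so defaults sit just under that.
.default_dt <- function(field, D_max = field$D0, safety = 0.95) {
  safety * field$dx^2 / (6 * D_max)
}

#' Advance the drug field (uniform diffusivity)
#'
#' Euler-forward update with the 7-point Laplacian; the Dirichlet shell is
#' re-imposed at every step from the schedule. Refuses to step when the
#' stability bound `D0*dt/dx^2 < 1/2` is violated.
#'
#' @param field a [drug_field()].
#' @param nocc per-voxel dimensionless tumor-cell occupancy in `[0, 1]`
#'   (length `N^3`), or NULL for no cellular uptake.
#' @param n_steps number of Euler steps.
#' @param dt step (s); default `0.4 * dx^2 / D0`.
#' @return The updated field (the input is not modified).
#' @export
step_uniform <- function(field, nocc = NULL, n_steps = 1, dt = NULL) {
  stopifnot(inherits(field, "drug_field"))
  if (is.null(dt)) dt <- .default_dt(field)
  st <- check_stability(field$D0, dt, field$dx)
  if (!st$pass)
    stop(sprintf("unstable step: D0*dt/dx^2 = %.3g >= 0.5; need dt < %.4g s",
                 st$ratio, st$dt_max))
  phi <- field$phi + 0  # force a copy; the kernel works in place
  .fd_advance(field, phi, nocc, D = NULL, dt, n_steps)
  field$phi <- phi
  field$t_s <- field$t_s + n_steps * dt
  field
}

#' Advance the drug field (heterogeneous diffusivity)
#'
#' Face-averaged conservative discretization of `div(D grad phi)`:
#' `(Dc/2) Lap(phi) + sum_faces (D_nb/2)(phi_nb - phi_c)/dx^2`,
#' which reduces exactly to the uniform stencil when `D` is constant.
#' Stability is enforced with `max(D)`.
#'
#' @inheritParams step_uniform
#' @param D per-voxel diffusion coefficient (cm^2/s), length `N^3`.
#' @return The updated field.
#' @export
step_heterogeneous <- function(field, D, nocc = NULL, n_steps = 1, dt = NULL) {
  stopifnot(inherits(field, "drug_field"), length(D) == field$N^3)
  Dmax <- max(D)
  if (is.null(dt)) dt <- .default_dt(field, Dmax)
  st <- check_stability(Dmax, dt, field$dx)
  if (!st$pass)
    stop(sprintf("unstable step: Dmax*dt/dx^2 = %.3g >= 0.5; need dt < %.4g s",
                 st$ratio, st$dt_max))
  phi <- field$phi + 0
  .fd_advance(field, phi, nocc, D = as.numeric(D), dt, n_steps)
  field$phi <- phi
  field$t_s <- field$t_s + n_steps * dt
  field
}

#' Per-voxel diffusivity from the heterogeneous environment
#'
#' Gas-diffusion-style relation between ECM density and drug diffusivity:
#' a voxel containing at least one tumor cell gets `eta * D0`; an ECM voxel
#' gets `D0 * rho0 / (mean rho_ECM + rho_res)`, so fully degraded matrix
#' (`rho = 0`) is the most permeable (`D = D0 * rho0 / rho_res`).
#'
#' @param ecm per-site ECM densities (an `ecm_field` or numeric vector).
#' @param tumor_occupancy logical (or 0/1) per-site flag marking tumor cells.
#' @param lattice the `cell_lattice` providing the site-to-voxel map.
#' @param D0 reference diffusivity (cm^2/s).
#' @param eta intratumoral diffusivity factor.
#' @param rho_res residual ECM density.
#' @param rho0 reference ECM density.
#' @return List with per-voxel `D` (cm^2/s) and occupancy fraction `n`.
#' @export
diffusivity_from_environment <- function(ecm, tumor_occupancy, lattice,
                                         D0 = 1.3e-6, eta = 0.75,
                                         rho_res = 0.1, rho0 = 0.3) {
  stopifnot(D0 > 0, eta > 0, rho_res > 0, rho0 > 0,
            length(ecm) == lattice$nsites,
            length(tumor_occupancy) == lattice$nsites)
  state <- ifelse(as.logical(tumor_occupancy), 1L, 0L)  # PROLIF vs ECM codes
  voxel_fields_cpp(state, as.numeric(ecm), lattice$site_voxel,
                   as.integer(lattice$grid$N^3), D0, eta, rho0, rho_res)[
                     c("D", "n")]
}

#' Drug dynamics in an idealized steady-state tumor
#'
#' Runs the diffusion-reaction solver against a static Fermi-profile tumor
#' (cell occupancy `n(r) = 1/(1+exp((r-r0)/sigma))`), recording the
#' concentration at the tumor center and radial concentration profiles.
#' Used to study how consumption and dosing mode shape the intratumoral
#' drug distribution before coupling to the growth model.
#'
#' @param profile a [fermi_profile()]; its center defaults to the domain
#'   center.
#' @param schedule a [dose_schedule()] (constant or periodic).
#' @param t_end_min simulated time (min).
#' @param L,dx domain edge and grid spacing (cm).
#' @param record_every_min interval between recorded center samples (min).
#' @param profile_times_min times (min) at which full radial profiles are
#'   stored.
#' @param D0,Kmet,lambda14,phi0 transport/consumption parameters (cm^2/s,
#'   min^-1, s^-1; `phi0` defaults to `0.5 * C0`).
#' @param dt Euler step (s); default `0.4 * dx^2 / D0`.
#' @return List with `center` (data frame `t_min`, `phi`), `profiles`
#'   (data frame `t_min`, `r`, `phi`), and the final `field`.
#' @export
solve_steady_state_tumor <- function(profile, schedule, t_end_min,
                                     L = 0.8, dx = 0.01,
                                     record_every_min = 10,
                                     profile_times_min = t_end_min,
                                     D0 = 1.3e-6, Kmet = 2.0e-4,
                                     lambda14 = 0, phi0 = NULL, dt = NULL) {
  stopifnot(inherits(profile, "fermi_profile"))
  field <- drug_field(L, dx, schedule, D0 = D0, Kmet = Kmet,
                      lambda14 = lambda14, phi0 = phi0)
  prof <- profile
  prof$center <- field$center
  g <- seq(0, L, by = dx)
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  nocc <- fermi_density(prof, coords)
  if (is.null(dt)) dt <- .default_dt(field)
  st <- check_stability(field$D0, dt, field$dx)
  if (!st$pass) stop("unstable step for steady-tumor run")

  phi <- field$phi + 0
  cid <- which.min(field$r)
  rec_t <- seq(0, t_end_min, by = record_every_min)
  # schedule all stops (center records + profile snapshots), in step units
  prof_t <- sort(unique(pmin(profile_times_min, t_end_min)))
  stops_min <- sort(unique(c(rec_t, prof_t)))
  center <- numeric(length(stops_min))
  profs <- vector("list", length(prof_t))
  rbin <- round(field$r / dx)
  done_steps <- 0
  for (q in seq_along(stops_min)) {
    target_steps <- round(.min2s(stops_min[q]) / dt)
    if (target_steps > done_steps) {
      .fd_advance(field, phi, nocc, D = NULL, dt, target_steps - done_steps)
      field$t_s <- field$t_s + (target_steps - done_steps) * dt
      done_steps <- target_steps
    }
    center[q] <- phi[cid]
    pi_ <- match(stops_min[q], prof_t)
    if (!is.na(pi_)) {
      keep <- field$r < field$R_boundary
      agg <- tapply(phi[keep], rbin[keep], mean)
      profs[[pi_]] <- data.frame(t_min = stops_min[q],
                                 r = as.numeric(names(agg)) * dx,
                                 phi = as.numeric(agg))
    }
  }
  field$phi <- phi
  list(center = data.frame(t_min = stops_min, phi = center),
       profiles = do.call(rbind, profs),
       field = field)
}
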