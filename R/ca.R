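# site state codes shared with src/ca.cpp
.ST <- c(ECM = 0L, proliferative = 1L, quiescent = 2L, necrotic = 3L,
         invasive = 4L, degraded_ECM = 5L, blocked = 6L)
.state_names <- names(.ST)

#' Cellular-automaton parameters
#'
#' Parameter bundle for the tumor automaton. Defaults follow the standard
#' calibration of the invasive-tumor CA lineage: rim-thickness scalings
#' `a` (necrotic) and `b` (proliferative) in mm^(1/3), base division
#' probability `p0`, mutation rate `gamma`, adhesion threshold `Ai`, ECM
#' degradation ability `chi` and invasive-cell mobility `mu`.
#'
#' `Pgamma` is the division-reduction floor reached at full normalized drug
#' concentration: the per-division reduction factor is
#' `P_{gamma,phi} = 1 - (1 - Pgamma) * phi_norm`, so `phi_norm = 0` leaves
#' division untouched and `phi_norm = 1` multiplies it by `Pgamma`.
#'
#' Two combination rules for the division probability are supported (see
#' [division_probability()]); `"multiplicative"` is the default. The
#' adhesion test of the mutation rule counts invasive neighbors by default
#' (`adhesion_neighbors = "invasive"`); `"tumor"` counts all tumor
#' neighbors. Invasive migration heads outward from the tumor centroid by
#' default (`migration = "outward"`), or uniformly at random
#' (`"random"`).
#'
#' @param a base necrotic rim thickness (mm^(1/3)).
#' @param b base proliferative rim thickness (mm^(1/3)).
#' @param p0 base probability of division per day.
#' @param gamma mutation rate to the invasive phenotype.
#' @param Ai adhesion value (neighbor-count threshold of the mutation rule).
#' @param chi ECM degradation ability (per-attempt density decrement is
#'   Uniform\[0, chi\]).
#' @param mu invasive-cell mobility (max degradation/migration attempts per
#'   day).
#' @param d spatial dimension (3).
#' @param Pgamma division-reduction floor at full drug.
#' @param cell_cycle cell-cycle duration (day).
#' @param division_rule `"multiplicative"` or `"additive"`.
#' @param adhesion_neighbors `"invasive"` or `"tumor"`.
#' @param migration `"outward"` or `"random"`.
#' @return An object of class `ca_params`.
#' @examples
#' ca_params()
#' @export
ca_params <- function(a = 0.12, b = 0.08, p0 = 0.192, gamma = 0.05,
                      Ai = 2, chi = 0.15, mu = 3, d = 3, Pgamma = 0.05,
                      cell_cycle = 1,
                      division_rule = c("multiplicative", "additive"),
                      adhesion_neighbors = c("invasive", "tumor"),
                      migration = c("outward", "random")) {
  division_rule <- match.arg(division_rule)
  adhesion_neighbors <- match.arg(adhesion_neighbors)
  migration <- match.arg(migration)
  stopifnot(a > 0, b > 0, chi >= 0, mu >= 0,
            p0 >= 0, p0 <= 1, gamma >= 0, gamma <= 1,
            Pgamma >= 0, Pgamma <= 1, d == 3, cell_cycle > 0)
  structure(list(a = a, b = b, p0 = p0, gamma = gamma, Ai = Ai, chi = chi,
                 mu = mu, d = d, Pgamma = Pgamma, cell_cycle = cell_cycle,
                 division_rule = division_rule,
                 adhesion_neighbors = adhesion_neighbors,
                 migration = migration),
            class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat("CA parameters:\n")
  cat(sprintf("  a = %g, b = %g mm^(1/3); p0 = %g; gamma = %g; Ai = %g\n",
              x$a, x$b, x$p0, x$gamma, x$Ai))
  cat(sprintf("  chi = %g; mu = %g; Pgamma = %g; rule = %s\n",
              x$chi, x$mu, x$Pgamma, x$division_rule))
  invisible(x)
}

#' Rim thicknesses
#'
#' Geometric nutrient-access rules of the automaton: a quiescent cell deeper
#' than `delta_n = a * Lt^((d-1)/d)` below the tumor surface starves to
#' necrosis, and a proliferative cell deeper than `delta_p = b * Lt^((d-1)/d)`
#' turns quiescent. `Lt` is the local tumor radius (centroid to the nearest
#' tumor edge cell). With `a`, `b` in mm^(1/3) and lengths in cm, the
#' conversion is handled internally (1 cm = 10 mm).
#'
#' @param Lt local tumor radius (cm), >= 0.
#' @param params a [ca_params()].
#' @return Thickness in cm.
#' @examples
#' necrotic_thickness(0.1, ca_params())       # Lt = 1 mm -> 0.12 mm
#' proliferative_thickness(0.8, ca_params())  # Lt = 8 mm -> 0.32 mm
#' @export
necrotic_thickness <- function(Lt, params = ca_params()) {
  stopifnot(all(Lt >= 0))
  params$a * (10 * Lt)^((params$d - 1) / params$d) / 10
}

#' @rdname necrotic_thickness
#' @export
proliferative_thickness <- function(Lt, params = ca_params()) {
  stopifnot(all(Lt >= 0))
  params$b * (10 * Lt)^((params$d - 1) / params$d) / 10
}

#' Division probability of a proliferative cell
#'
#' Combines the drug, confinement and ECM contributions. The drug enters
#' through the reduction factor `P_{gamma,phi} = 1 - (1 - Pgamma) * phi_norm`
#' with `phi_norm` the local drug concentration normalized by the boundary
#' level and clamped to `[0, 1]`. The confinement factor is `1 - r/Lmax`
#' with `r` the cell's distance from the tumor centroid and `Lmax` the
#' distance from the centroid to the closest growth-permitting boundary in
#' the growth direction. The mechanical resistance of the target matrix
#' enters as `(1 - rho_ECM)^2`.
#'
#' Under the default `"multiplicative"` rule
#' `P_div = p0 * P_{gamma,phi} * (1 - r/Lmax) * (1 - rho_ECM)^2`;
#' the `"additive"` rule uses
#' `clamp01(p0 * P_{gamma,phi} * (1 - r/Lmax) + (1 - rho_ECM)^2)`.
#'
#' @param phi_norm normalized drug concentration in `[0, 1]`.
#' @param rho_ECM density of the target ECM site.
#' @param r distance of the dividing cell from the tumor centroid (cm).
#' @param Lmax distance from the centroid to the growth-permitting boundary
#'   (cm), > 0.
#' @param params a [ca_params()].
#' @return Division probability in `[0, 1]`.
#' @examples
#' division_probability(0, 0.3, r = 0, Lmax = 0.4)    # no drug
#' division_probability(1, 0.3, r = 0, Lmax = 0.4)    # full drug: x Pgamma
#' @export
division_probability <- function(phi_norm, rho_ECM, r, Lmax,
                                 params = ca_params()) {
  if (any(Lmax <= 0)) stop("degenerate geometry: Lmax must be > 0")
  stopifnot(all(r >= 0), all(r <= Lmax), all(phi_norm >= 0), all(phi_norm <= 1))
  Pgf <- 1 - (1 - params$Pgamma) * phi_norm
  conf <- pmax(0, 1 - r / Lmax)
  ecmf <- (1 - .clamp01(rho_ECM))^2
  if (params$division_rule == "additive") {
    .clamp01(params$p0 * Pgf * conf + ecmf)
  } else {
    params$p0 * Pgf * conf * ecmf
  }
}

#' Initialize the tumor state on a lattice
#'
#' Marks sites outside the spherical simulation domain as blocked
#' (boundary-condition carriers), seeds a small proliferative tumor at the
#' domain center, and attaches the per-site ECM densities (tumor sites get
#' `rho_ECM = 0`).
#'
#' @param lattice a [build_lattice()] result.
#' @param ecm per-site ECM densities (see [ecm_fields]).
#' @param R_domain radius (cm) of the spherical growth-permitting region,
#'   centered in the box.
#' @param initial_radius radius (cm) of the seeded tumor (default 0.03 cm,
#'   a tumor of linear size 0.06 cm).
#' @return An object of class `tumor_state`: integer `state` per site
#'   (codes ECM = 0, proliferative = 1, quiescent = 2, necrotic = 3,
#'   invasive = 4, degraded_ECM = 5, blocked = 6), numeric `rho`, centroid
#'   bookkeeping `cstat = (x, y, z, N)` over noninvasive tumor cells, and
#'   the day counter.
#' @export
tumor_state <- function(lattice, ecm, R_domain = NULL,
                        initial_radius = 0.03) {
  stopifnot(inherits(lattice, "cell_lattice"),
            length(ecm) == lattice$nsites)
  dom <- lattice$domain
  center <- (dom$lo + dom$hi) / 2
  if (is.null(R_domain)) R_domain <- min(dom$hi - dom$lo) / 2
  r <- sqrt(rowSums(sweep(lattice$points, 2, center)^2))
  state <- integer(lattice$nsites)
  state[r > R_domain] <- .ST[["blocked"]]
  seed_idx <- which(r <= initial_radius & state == 0L)
  if (length(seed_idx) == 0)
    stop("initial_radius too small: no lattice site inside the seed sphere")
  state[seed_idx] <- .ST[["proliferative"]]
  rho <- as.numeric(ecm)
  rho[state != .ST[["ECM"]]] <- 0
  cstat <- c(colMeans(lattice$points[seed_idx, , drop = FALSE]),
             length(seed_idx))
  structure(list(state = state, rho = rho, cstat = cstat,
                 domain_center = center, R_domain = R_domain,
                 day = 0L), class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cnt <- state_counts(x)
  cat(sprintf("Tumor state, day %d:\n", x$day))
  print(cnt)
  invisible(x)
}

#' Count sites per automaton state
#'
#' @param state a `tumor_state`.
#' @return Named integer vector over the state codes.
#' @export
state_counts <- function(state) {
  cnt <- tabulate(state$state + 1L, nbins = 7L)
  names(cnt) <- .state_names
  cnt
}

# internal: ensure private, modifiable copies for the in-place C++ kernels
.own_state <- function(ts) {
  ts$state <- ts$state + 0L
  ts$rho <- ts$rho + 0
  ts$cstat <- ts$cstat + 0
  ts
}

#' One daily update of the cellular automaton
#'
#' Applies the automaton rules for one day, in order: (1) starvation of deep
#' quiescent cells to necrosis, (2) division of all proliferative cells (in
#' random order) with probability [division_probability()], with rule (4)
#' mutation to the invasive phenotype decided at each birth, (3) transition
#' of deep or space-less proliferative cells to quiescence, and (5) invasive
#' ECM degradation and migration. Rule 6 (invasive cells never divide) is
#' implicit: only proliferative cells enter the division step.
#'
#' All randomness is drawn from R's global RNG, so runs are reproducible
#' via `set.seed()`.
#'
#' @param ts a [tumor_state()].
#' @param params a [ca_params()].
#' @param phi_norm normalized drug concentration seen by dividing cells:
#'   a single number in `[0, 1]` or a per-site vector.
#' @param lattice the `cell_lattice` the state lives on.
#' @return List with the updated `state` (a `tumor_state`) and `events`
#'   (counts: divisions, mutations, necrosed, quiesced, migrations).
#' @export
daily_update <- function(ts, lattice, params = ca_params(), phi_norm = 0) {
  stopifnot(inherits(ts, "tumor_state"), inherits(lattice, "cell_lattice"))
  ts <- .own_state(ts)
  pos <- lattice$points
  if (length(phi_norm) == 1) {
    phi_vox <- numeric(0)
    site_voxel <- integer(0)
    phi_fixed <- phi_norm
  } else {
    stopifnot(length(phi_norm) == lattice$nsites)
    phi_vox <- .clamp01(as.numeric(phi_norm))
    site_voxel <- seq_len(lattice$nsites) - 1L
    phi_fixed <- 0
  }
  nec <- ca_necrosis_cpp(ts$state, pos, lattice$adj_ptr, lattice$adj_idx,
                         ts$cstat[1:3], params$a)
  cohort <- which(ts$state == .ST[["proliferative"]]) - 1L
  div <- ca_divide_cpp(cohort, ts$state, ts$rho, pos,
                       lattice$adj_ptr, lattice$adj_idx, ts$cstat,
                       phi_vox, site_voxel, phi_fixed, 1.0,
                       params$p0, params$Pgamma, params$gamma, params$Ai,
                       as.integer(params$division_rule == "additive"),
                       as.integer(params$adhesion_neighbors == "tumor"),
                       ts$domain_center, ts$R_domain)
  qui <- ca_quiescence_cpp(ts$state, pos, lattice$adj_ptr, lattice$adj_idx,
                           ts$cstat[1:3], params$b)
  mig <- ca_invasion_cpp(ts$state, ts$rho, pos, lattice$adj_ptr,
                         lattice$adj_idx, ts$cstat[1:3],
                         as.integer(params$mu), params$chi,
                         as.integer(params$migration == "random"))
  ts$day <- ts$day + 1L
  list(state = ts,
       events = list(divisions = length(div$daughters),
                     mutations = length(div$mutated),
                     necrosed = nec, quiesced = qui, migrations = mig))
}
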