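#' ECM density fields on the automaton lattice
#'
#' Constructors for the initial extracellular-matrix density per automaton
#' cell. `rho_ECM` is dimensionless in `[0, 1]` and doubles as a proxy for
#' local ECM rigidity: it reduces the division probability of adjacent tumor
#' cells and (through the gas-diffusion relation) the local drug diffusivity.
#'
#' * `homogeneous_ecm`: constant density.
#' * `sinusoidal_ecm`: deterministic heterogeneity
#'   `rho = rho_av - rho_fluc/2 + rho_fluc * |sin(pi x/Lx + pi y/Ly + pi z/Lz)|`.
#' * `uniform_random_ecm`: i.i.d. per-site densities on `[rho_min, rho_max]`.
#' * `two_region_ecm`: step profile, `rho_left` for `x < interface_x`, else
#'   `rho_right` (a hard basal membrane next to soft tissue).
#'
#' @param lattice a [build_lattice()] result.
#' @param rho,rho_av,rho_fluc,rho_left,rho_right densities in `[0, 1]`.
#' @param Lx,Ly,Lz sinusoidal periods (cm).
#' @param rho_min,rho_max range of the i.i.d. mode.
#' @param interface_x interface position (cm).
#' @return Numeric vector of per-site densities with class `ecm_field`; the
#'   construction parameters are kept in attributes.
#' @examples
#' pk <- generate_packing(0.1, 0.005, 0.2, seed = 1)
#' lat <- build_lattice(pk, grid_spacing = 0.05)
#' rho <- sinusoidal_ecm(lat, 0.3, 0.4, 0.02, 0.02, 0.02)
#' range(rho)
#' @name ecm_fields
NULL

.ecm_field <- function(rho, mode, params) {
  structure(as.numeric(rho), class = "ecm_field", mode = mode, params = params)
}

#' @rdname ecm_fields
#' @export
homogeneous_ecm <- function(lattice, rho = 0.3) {
  stopifnot(rho >= 0, rho <= 1)
  .ecm_field(rep(rho, lattice$nsites), "homogeneous", list(rho = rho))
}

#' @rdname ecm_fields
#' @export
sinusoidal_ecm <- function(lattice, rho_av, rho_fluc, Lx, Ly = Lx, Lz = Lx) {
  if (rho_av - rho_fluc / 2 < 0 || rho_av + rho_fluc / 2 > 1)
    stop("sinusoidal ECM out of range: need rho_av - rho_fluc/2 >= 0 and rho_av + rho_fluc/2 <= 1")
  p <- lattice$points
  arg <- pi * p[, 1] / Lx + pi * p[, 2] / Ly + pi * p[, 3] / Lz
  rho <- rho_av - rho_fluc / 2 + rho_fluc * abs(sin(arg))
  .ecm_field(rho, "sinusoidal",
             list(rho_av = rho_av, rho_fluc = rho_fluc,
                  Lx = Lx, Ly = Ly, Lz = Lz))
}

#' @rdname ecm_fields
#' @export
uniform_random_ecm <- function(lattice, rho_min = 0.1, rho_max = 0.5) {
  stopifnot(rho_min >= 0, rho_max <= 1, rho_min <= rho_max)
  rho <- runif(lattice$nsites, rho_min, rho_max)
  .ecm_field(rho, "uniform_random", list(rho_min = rho_min, rho_max = rho_max))
}

#' @rdname ecm_fields
#' @export
two_region_ecm <- function(lattice, rho_left = 0.6, rho_right = 0.2,
                           interface_x) {
  stopifnot(rho_left >= 0, rho_left <= 1, rho_right >= 0, rho_right <= 1)
  rho <- ifelse(lattice$points[, 1] < interface_x, rho_left, rho_right)
  .ecm_field(rho, "two_region",
             list(rho_left = rho_left, rho_right = rho_right,
                  interface_x = interface_x))
}

#' Idealized steady-state tumor density profile
#'
#' A radially symmetric tumor whose cell-density fraction follows the Fermi
#' (logistic) function `1 / (1 + exp((r - r0)/sigma))`: ~1 deep inside the
#' tumor, 0.5 at the nominal radius `r0`, and decaying to 0 over a boundary
#' layer of thickness `sigma`.
#'
#' @param r0 tumor radius (cm), > 0.
#' @param sigma boundary-layer thickness (cm), > 0.
#' @param center tumor center (cm).
#' @return An object of class `fermi_profile`.
#' @examples
#' pr <- fermi_profile(r0 = 0.2, sigma = 0.01, center = c(0.4, 0.4, 0.4))
#' fermi_density(pr, c(0.6, 0.4, 0.4))  # at r = r0: 0.5
#' @export
fermi_profile <- function(r0, sigma, center = c(0, 0, 0)) {
  stopifnot(r0 > 0, sigma > 0, length(center) == 3)
  structure(list(r0 = r0, sigma = sigma, center = as.numeric(center)),
            class = "fermi_profile")
}

#' @rdname fermi_profile
#' @param profile a `fermi_profile`.
#' @param points a length-3 vector or an n x 3 matrix of positions (cm).
#' @return `fermi_density`: densities in (0, 1).
#' @export
fermi_density <- function(profile, points) {
  stopifnot(inherits(profile, "fermi_profile"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt(rowSums(sweep(points, 2, profile$center)^2))
  1 / (1 + exp((r - profile$r0) / profile$sigma))
}
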