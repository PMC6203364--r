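#' Random sequential addition packing of congruent hard spheres
#'
#' Generates the point pattern underlying the automaton lattice: sphere
#' centers are proposed uniformly in the box and accepted when at least
#' `2 * radius` from every accepted center (random sequential addition, RSA).
#' The automaton cells are the Voronoi polyhedra of these centers.
#'
#' @param domain box as `list(lo = c(x,y,z), hi = c(x,y,z))` in cm, or a
#'   single number `L` for the cube `[0, L]^3`.
#' @param radius hard-sphere radius (cm).
#' @param target_fraction target sphere volume fraction; must be in
#'   (0, 0.38], below the RSA saturation bound for spheres. Default 0.3.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the same seed reproduces the same packing.
#' @param max_attempts cap on insertion attempts (the generator never loops
#'   forever; if the target is unreachable the achieved fraction is reported
#'   in a warning).
#' @return An object of class `sphere_packing`: `points` (n x 3 matrix, cm),
#'   `radius`, `domain`, `achieved_fraction`, `target_fraction`.
#' @examples
#' pk <- generate_packing(0.1, radius = 0.005, target_fraction = 0.2, seed = 1)
#' nrow(pk$points)
#' @export
generate_packing <- function(domain, radius, target_fraction = 0.3,
                             seed = NULL, max_attempts = NULL) {
  domain <- .as_domain(domain)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (target_fraction <= 0 || target_fraction > 0.38)
    stop("target_fraction must be in (0, 0.38] (RSA saturation bound)")
  if (!is.null(seed)) set.seed(seed)
  V <- prod(domain$hi - domain$lo)
  vs <- 4 / 3 * pi * radius^3
  n_target <- max(1L, as.integer(round(target_fraction * V / vs)))
  if (is.null(max_attempts)) max_attempts <- 500 * n_target + 1e4
  pts <- rsa_pack_cpp(domain$lo, domain$hi, radius, n_target, max_attempts)
  achieved <- nrow(pts) * vs / V
  if (nrow(pts) < n_target)
    warning(sprintf(
      "target fraction %.3f unreachable; achieved %.3f with %d spheres",
      target_fraction, achieved, nrow(pts)))
  structure(list(points = pts, radius = radius, domain = domain,
                 achieved_fraction = achieved,
                 target_fraction = target_fraction),
            class = "sphere_packing")
}

.as_domain <- function(domain) {
  if (is.numeric(domain) && length(domain) == 1)
    domain <- list(lo = c(0, 0, 0), hi = rep(domain, 3))
  stopifnot(is.list(domain), length(domain$lo) == 3, length(domain$hi) == 3,
            all(domain$hi > domain$lo))
  list(lo = as.numeric(domain$lo), hi = as.numeric(domain$hi))
}

#' @export
print.sphere_packing <- function(x, ...) {
  cat(sprintf("Hard-sphere packing: %d centers, radius %g cm, fraction %.3f\n",
              nrow(x$points), x$radius, x$achieved_fraction))
  invisible(x)
}

#' Write / read a packing as whitespace-delimited text
#'
#' Plain xyz text: a two-line header (`radius`, domain bounds) followed by
#' one center per line.
#'
#' @param packing a `sphere_packing`.
#' @param path file path.
#' @return `write_packing` the path invisibly; `read_packing` a
#'   `sphere_packing`.
#' @export
write_packing <- function(packing, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# radius %.17g", packing$radius), con)
  writeLines(sprintf("# domain %.17g %.17g %.17g %.17g %.17g %.17g",
                     packing$domain$lo[1], packing$domain$lo[2],
                     packing$domain$lo[3], packing$domain$hi[1],
                     packing$domain$hi[2], packing$domain$hi[3]), con)
  utils::write.table(packing$points, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_packing
#' @export
read_packing <- function(path) {
  hdr <- readLines(path, n = 2)
  radius <- as.numeric(strsplit(hdr[1], "\\s+")[[1]][3])
  dv <- as.numeric(strsplit(hdr[2], "\\s+")[[1]][3:8])
  pts <- as.matrix(utils::read.table(path, skip = 2))
  dimnames(pts) <- NULL
  vs <- 4 / 3 * pi * radius^3
  V <- prod(dv[4:6] - dv[1:3])
  structure(list(points = pts, radius = radius,
                 domain = list(lo = dv[1:3], hi = dv[4:6]),
                 achieved_fraction = nrow(pts) * vs / V,
                 target_fraction = NA_real_),
            class = "sphere_packing")
}

#' Build the automaton lattice from a packing
#'
#' Computes (i) the Voronoi face-sharing adjacency of the packing points and
#' (ii) the bidirectional mapping between automaton cells and the regular
#' finite-difference grid with spacing `grid_spacing`. Grid node `(i,j,k)`
#' (0-based) sits at `lo + (i,j,k) * grid_spacing`; each site maps to its
#' nearest node, so the voxels partition the sites.
#'
#' Face-sharing is decided exactly per candidate pair by a linear-program
#' feasibility test on the pair's bisector plane (a pair shares a face iff
#' some plane point is at least as close to the pair as to every other site).
#' For large lattices constraint sites are gathered within a cutoff of
#' several nearest-neighbor distances; `adjacency = "surrogate"` selects the
#' cruder distance-cutoff rule (neighbors = sites within
#' `surrogate_factor` x mean nearest-neighbor distance).
#'
#' @param packing a [generate_packing()] result.
#' @param grid_spacing finite-difference grid spacing (cm); must divide the
#'   box edge into a whole number of intervals.
#' @param adjacency `"voronoi"` (exact face-sharing, default) or
#'   `"surrogate"`.
#' @param cutoff_factor candidate/constraint search radius in units of the
#'   mean nearest-neighbor distance (Voronoi mode).
#' @param surrogate_factor cutoff in the same units (surrogate mode),
#'   default 2.2.
#' @return An object of class `cell_lattice` with fields `points`,
#'   `adj_ptr`/`adj_idx` (0-based CSR adjacency), `degree`, `site_volume`
#'   (mean, cm^3), `grid` (`N`, `dx`, `lo`), `site_voxel` (0-based voxel id
#'   per site) and `nsites`.
#' @export
build_lattice <- function(packing, grid_spacing,
                          adjacency = c("voronoi", "surrogate"),
                          cutoff_factor = 2.5, surrogate_factor = 2.2) {
  stopifnot(inherits(packing, "sphere_packing"))
  adjacency <- match.arg(adjacency)
  pts <- packing$points
  n <- nrow(pts)
  if (n < 1) stop("packing is empty")
  if (n > 1) {
    dup <- .find_colocated(pts, tol = 1e-12)
    if (!is.null(dup))
      stop(sprintf("degenerate co-located points at indices %d and %d",
                   dup[1], dup[2]))
  }
  dom <- packing$domain
  Ls <- dom$hi - dom$lo
  steps <- Ls / grid_spacing
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("grid_spacing must divide the domain edge lengths")
  Ns <- as.integer(round(steps)) + 1L
  if (length(unique(Ns)) != 1)
    stop("only cubic grids are supported (equal edge lengths)")
  N <- Ns[1]

  if (n == 1) {
    edges <- matrix(integer(0), 0, 2)
    dnn <- NA_real_
  } else {
    dnn <- mean_nn_dist_cpp(pts, dom$lo, dom$hi, guess = 2 * packing$radius)
    diag_len <- sqrt(sum(Ls^2))
    if (adjacency == "voronoi") {
      cutoff <- cutoff_factor * dnn
      exact_all <- n <= 400
      if (exact_all) cutoff <- diag_len * 1.01
      edges <- voronoi_adjacency_cpp(pts, dom$lo, dom$hi, cutoff,
                                     exact_all,
                                     eps_len = 1e-7 * dnn,
                                     bound = 4 * diag_len)
    } else {
      edges <- surrogate_adjacency_cpp(pts, dom$lo, dom$hi,
                                       surrogate_factor * dnn)
    }
  }
  adj <- .edges_to_csr(edges, n)

  sv <- .assign_grid(pts, dom$lo, grid_spacing, N)
  structure(list(points = pts, radius = packing$radius, domain = dom,
                 adj_ptr = adj$ptr, adj_idx = adj$idx, degree = adj$degree,
                 mean_nn_dist = dnn,
                 site_volume = prod(Ls) / n,
                 grid = list(N = N, dx = grid_spacing, lo = dom$lo),
                 site_voxel = sv, nsites = n, adjacency = adjacency),
            class = "cell_lattice")
}

.find_colocated <- function(pts, tol) {
  o <- order(pts[, 1], pts[, 2], pts[, 3])
  d <- rowSums(abs(pts[o[-1], , drop = FALSE] -
                   pts[o[-length(o)], , drop = FALSE]))
  w <- which(d < tol)
  if (length(w) == 0) return(NULL)
  c(o[w[1]], o[w[1] + 1])
}

# symmetric CSR (0-based) from a 2-column 0-based edge matrix
.edges_to_csr <- function(edges, n) {
  if (nrow(edges) == 0) {
    return(list(ptr = integer(n + 1), idx = integer(0), degree = integer(n)))
  }
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  degree <- tabulate(from + 1L, nbins = n)
  ptr <- c(0L, cumsum(degree))
  list(ptr = as.integer(ptr), idx = as.integer(to), degree = degree)
}

.assign_grid <- function(pts, lo, dx, N) {
  ijk <- round(sweep(pts, 2, lo) / dx)
  ijk <- pmin(pmax(ijk, 0), N - 1)
  as.integer(ijk[, 1] + N * (ijk[, 2] + N * ijk[, 3]))
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf("Voronoi cell lattice: %d sites, mean degree %.1f (%s)\n",
              x$nsites, mean(x$degree), x$adjacency))
  cat(sprintf("  FD grid: %d^3 nodes, dx = %g cm\n", x$grid$N, x$grid$dx))
  invisible(x)
}

#' Neighbors of a lattice site
#'
#' @param lattice a `cell_lattice`.
#' @param i site index (1-based).
#' @return Integer vector of 1-based neighbor indices.
#' @export
lattice_neighbors <- function(lattice, i) {
  stopifnot(i >= 1, i <= lattice$nsites)
  lattice$adj_idx[(lattice$adj_ptr[i] + 1):lattice$adj_ptr[i + 1]] + 1L
}

#' Map occupied automaton cells to a per-voxel cell density
#'
#' Implements the cell-density mapping from tessellation to grid,
#' n_(i,j,k) = (1/dV) * sum_m n_m with n_m = 0 or 1 over the sites mapped to
#' voxel (i,j,k); dV is the voxel volume dx^3, so the result is in
#' cells cm^-3.
#'
#' @param lattice a `cell_lattice`.
#' @param occupied integer vector of occupied site indices (1-based).
#' @return Numeric vector of length `N^3` (voxel-linearized, x fastest).
#' @export
cell_density_field <- function(lattice, occupied) {
  nvox <- lattice$grid$N^3
  if (length(occupied)) {
    stopifnot(all(occupied >= 1), all(occupied <= lattice$nsites))
  }
  counts <- tabulate(lattice$site_voxel[occupied] + 1L, nbins = nvox)
  counts / lattice$grid$dx^3
}

#' Brute-force Voronoi adjacency (reference oracle)
#'
#' Voxelizes the domain at `res^3` samples, assigns every sample to its
#' nearest site and reads adjacency off owner changes between 6-connected
#' samples. Exact up to sampling resolution; intended for validating the
#' production adjacency on small instances.
#'
#' @param points n x 3 matrix of site coordinates.
#' @param domain box (`list(lo, hi)` or edge length).
#' @param res samples per edge (default 96).
#' @return 2-column matrix of 1-based site index pairs (i < j).
#' @export
voronoi_adjacency_bruteforce <- function(points, domain, res = 96) {
  domain <- .as_domain(domain)
  voronoi_bruteforce_cpp(points, domain$lo, domain$hi, as.integer(res)) + 1L
}
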