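#' Summary growth metrics
#'
#' Computes the study's summary observables of a tumor state: the averaged
#' radius of proliferative cells `R_P` (mean distance from the tumor
#' centroid), the averaged radius of invasive cells `R_Inv` (NA while no
#' invasive cells exist), the invasive count `N_Inv`, per-state site counts,
#' and the mean normalized drug concentration over living tumor cells.
#'
#' @param ts a `tumor_state`.
#' @param lattice the `cell_lattice`.
#' @param phi_field optional per-voxel drug concentrations (length `N^3`).
#' @param day day stamp for the output row.
#' @return One-row data frame.
#' @export
compute_metrics <- function(ts, lattice, phi_field = NULL, day = ts$day) {
  st <- ts$state
  cen <- ts$cstat[1:3]
  pos <- lattice$points
  dist_to_cen <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mean(sqrt((pos[idx, 1] - cen[1])^2 + (pos[idx, 2] - cen[2])^2 +
              (pos[idx, 3] - cen[3])^2))
  }
  ip <- which(st == .ST[["proliferative"]])
  iq <- which(st == .ST[["quiescent"]])
  inc <- which(st == .ST[["necrotic"]])
  ii <- which(st == .ST[["invasive"]])
  mean_phi <- NA_real_
  if (!is.null(phi_field)) {
    living <- c(ip, iq, ii)
    if (length(living))
      mean_phi <- mean(phi_field[lattice$site_voxel[living] + 1L])
  }
  data.frame(day = day,
             R_P = dist_to_cen(ip), R_Q = dist_to_cen(c(iq, inc)),
             R_Inv = dist_to_cen(ii),
             N_Inv = length(ii),
             proliferative = length(ip), quiescent = length(iq),
             necrotic = length(inc), degraded = sum(st == .ST[["degraded_ECM"]]),
             N_noninv = ts$cstat[4],
             xc = cen[1], yc = cen[2], zc = cen[3],
             mean_phi_tumor = mean_phi)
}

#' Percent decrease of a treated metric relative to a drug-free baseline
#'
#' @param metric_treated metric under treatment.
#' @param metric_free drug-free baseline, > 0.
#' @return `100 * (metric_free - metric_treated) / metric_free` (percent).
#' @examples
#' relative_suppression(0.5, 1.0)  # 50
#' @export
relative_suppression <- function(metric_treated, metric_free) {
  if (any(!is.finite(metric_free)) || any(metric_free <= 0)) {
    warning("zero or undefined baseline; suppression undefined")
    return(rep(NA_real_, length(metric_treated)))
  }
  100 * (metric_free - metric_treated) / metric_free
}

#' Write a cell-state snapshot as CSV
#'
#' Tabular export (site id, coordinates, state label, ECM density) of all
#' non-ECM sites plus, optionally, everything.
#'
#' @param ts a `tumor_state`.
#' @param lattice the `cell_lattice`.
#' @param path output path.
#' @param all_sites include unperturbed ECM sites too.
#' @return The path, invisibly.
#' @export
write_state_csv <- function(ts, lattice, path, all_sites = FALSE) {
  keep <- if (all_sites) seq_along(ts$state)
          else which(!(ts$state %in% .ST[c("ECM", "blocked")]))
  df <- data.frame(site = keep,
                   x = lattice$points[keep, 1],
                   y = lattice$points[keep, 2],
                   z = lattice$points[keep, 3],
                   state = .state_names[ts$state[keep] + 1L],
                   rho_ECM = ts$rho[keep])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a snapshot written by [write_state_csv()]
#'
#' @param path CSV path.
#' @return Data frame with site, coordinates, state, rho_ECM.
#' @export
read_state_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Plot growth curves of one or more runs
#'
#' Base-graphics helper: primary-tumor radius (and invasive extent, when
#' present) against time.
#'
#' @param runs a `simulation_run` or list of them.
#' @param labels legend labels.
#' @param main plot title.
#' @return Invisibly, NULL.
#' @export
plot_growth_curves <- function(runs, labels = NULL, main = "Tumor growth") {
  if (inherits(runs, "simulation_run")) runs <- list(runs)
  cols <- seq_along(runs)
  ylim <- range(unlist(lapply(runs, function(r)
    c(r$metrics$R_P, r$metrics$R_Inv))), na.rm = TRUE)
  plot(NULL, xlim = c(0, max(vapply(runs, function(r) max(r$metrics$day),
                                    numeric(1)))),
       ylim = ylim, xlab = "day", ylab = "radius (cm)", main = main)
  for (i in seq_along(runs)) {
    m <- runs[[i]]$metrics
    lines(m$day, m$R_P, col = cols[i], lty = 1)
    if (any(is.finite(m$R_Inv))) lines(m$day, m$R_Inv, col = cols[i], lty = 2)
  }
  if (!is.null(labels))
    legend("topleft", legend = labels, col = cols, lty = 1, bty = "n")
  invisible(NULL)
}
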