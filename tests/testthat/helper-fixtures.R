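# Shared fixtures, built once per session and cached.
# Small lattices keep the unit tests fast; the full-size study lattice is
# only built inside the acceptance blocks that need it.

.fixtures <- new.env(parent = emptyenv())

# a ~570-site lattice in a 0.2 cm box (desk-scale CA playground)
small_lattice <- function(seed = 3) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    pk <- generate_packing(0.2, radius = 0.01, target_fraction = 0.3,
                           seed = seed)
    .fixtures[[key]] <- build_lattice(pk, grid_spacing = 0.04)
  }
  .fixtures[[key]]
}

# a ~4600-site lattice in a 0.4 cm box (mid-size growth tests)
mid_lattice <- function(seed = 5) {
  key <- paste0("mid", seed)
  if (is.null(.fixtures[[key]])) {
    pk <- generate_packing(0.4, radius = 0.01, target_fraction = 0.3,
                           seed = seed)
    .fixtures[[key]] <- build_lattice(pk, grid_spacing = 0.04)
  }
  .fixtures[[key]]
}

# full-size study lattices (0.8 cm box, ~37k sites), one per seed
study_lattice <- function(seed) {
  key <- paste0("study", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- growth_lattice(seed)
  }
  .fixtures[[key]]
}

# hand-rolled lattice from explicit points (for metric / geometry oracles)
lattice_from_points <- function(pts, L, grid_spacing = L / 2) {
  pk <- structure(list(points = pts, radius = 1e-4,
                       domain = list(lo = c(0, 0, 0), hi = rep(L, 3)),
                       achieved_fraction = NA_real_,
                       target_fraction = NA_real_),
                  class = "sphere_packing")
  build_lattice(pk, grid_spacing = grid_spacing)
}

edge_list <- function(lat) {
  e <- cbind(rep(seq_len(lat$nsites), diff(lat$adj_ptr)), lat$adj_idx + 1L)
  e[e[, 1] < e[, 2], , drop = FALSE]
}

edge_key <- function(e) paste(e[, 1], e[, 2])
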