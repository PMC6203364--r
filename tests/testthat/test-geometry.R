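test_that("RSA packing honors the hard-core condition and the domain", {
  pk <- generate_packing(0.1, radius = 0.005, target_fraction = 0.3, seed = 42)
  d <- as.matrix(dist(pk$points)); diag(d) <- Inf
  expect_gte(min(d), 2 * pk$radius)
  expect_true(all(pk$points >= 0 & pk$points <= 0.1))
  expect_lt(abs(pk$achieved_fraction - 0.3) / 0.3, 0.05)

  # determinism: same seed, same points
  pk2 <- generate_packing(0.1, radius = 0.005, target_fraction = 0.3, seed = 42)
  expect_identical(pk$points, pk2$points)

  # radius larger than the domain: degenerates to a single sphere
  pk3 <- generate_packing(0.1, radius = 0.2, target_fraction = 0.3, seed = 1)
  expect_equal(nrow(pk3$points), 1)
})

test_that("an unreachable target fraction reports the achieved fraction", {
  expect_warning(
    pk <- generate_packing(0.05, radius = 0.005, target_fraction = 0.38,
                           seed = 7, max_attempts = 2000),
    "achieved")
  expect_lt(pk$achieved_fraction, 0.38)
  expect_error(generate_packing(0.1, 0.005, target_fraction = 0.5),
               "saturation")
})

test_that("lattice adjacency is symmetric, irreflexive, and degenerate input errors", {
  lat <- small_lattice()
  # CSR symmetry: edge (i,j) implies (j,i)
  e <- cbind(rep(seq_len(lat$nsites), diff(lat$adj_ptr)), lat$adj_idx + 1L)
  expect_true(all(e[, 1] != e[, 2]))
  expect_setequal(edge_key(e), edge_key(e[, 2:1]))

  pts <- rbind(c(0.02, 0.02, 0.02), c(0.05, 0.05, 0.05), c(0.02, 0.02, 0.02))
  expect_error(lattice_from_points(pts, 0.1), "co-located")
})

test_that("two points are mutual neighbors; cubic interiors have 6 faces", {
  lat2 <- lattice_from_points(rbind(c(0.02, 0.05, 0.05), c(0.08, 0.05, 0.05)),
                              L = 0.1)
  expect_equal(lattice_neighbors(lat2, 1), 2L)
  expect_equal(lattice_neighbors(lat2, 2), 1L)

  g <- seq(0.01, 0.09, by = 0.02)  # 5^3 simple cubic arrangement
  cub <- as.matrix(expand.grid(g, g, g)); dimnames(cub) <- NULL
  latc <- lattice_from_points(cub, L = 0.1)
  interior <- which(apply(cub, 1, function(p) all(p > 0.015 & p < 0.085)))
  expect_true(all(latc$degree[interior] == 6))
})

test_that("face-sharing adjacency agrees with the brute-force Voronoi oracle", {
  set.seed(14)
  pts <- matrix(runif(3 * 150, 0.03, 0.97), ncol = 3) * 0.1
  lat <- lattice_from_points(pts, L = 0.1)
  e_lp <- edge_list(lat)
  e_bf <- voronoi_adjacency_bruteforce(pts, 0.1, res = 100)
  # every face the voxel oracle resolves must be present ...
  expect_gt(mean(edge_key(e_bf) %in% edge_key(e_lp)), 0.95)
  # ... and the production set may only add faces below sampling resolution
  jac <- length(intersect(edge_key(e_lp), edge_key(e_bf))) /
    length(union(edge_key(e_lp), edge_key(e_bf)))
  expect_gt(jac, 0.80)
})

test_that("the distance-cutoff surrogate captures the brute-force edges", {
  set.seed(15)
  pk <- generate_packing(0.1, radius = 0.006, target_fraction = 0.25, seed = 15)
  lat_s <- build_lattice(pk, grid_spacing = 0.05, adjacency = "surrogate")
  e_s <- edge_list(lat_s)
  e_bf <- voronoi_adjacency_bruteforce(pk$points, 0.1, res = 100)
  expect_gt(mean(edge_key(e_bf) %in% edge_key(e_s)), 0.95)
})

test_that("sites partition into voxels and densities count correctly", {
  lat <- small_lattice()
  nvox <- lat$grid$N^3
  # every site maps to exactly one voxel; the inverse map partitions sites
  expect_true(all(lat$site_voxel >= 0 & lat$site_voxel < nvox))
  expect_equal(sum(tabulate(lat$site_voxel + 1L, nvox)), lat$nsites)

  dV <- lat$grid$dx^3
  expect_equal(cell_density_field(lat, integer(0)), numeric(nvox))
  n_all <- cell_density_field(lat, seq_len(lat$nsites))
  expect_equal(sum(n_all) * dV, lat$nsites)
  n_one <- cell_density_field(lat, 17L)
  expect_equal(sum(n_one > 0), 1)
  expect_equal(max(n_one), 1 / dV)

  # mean site volume ~ domain volume / site count
  expect_equal(lat$site_volume, 0.2^3 / lat$nsites)
})

test_that("packings round-trip through the text reader/writer", {
  pk <- generate_packing(0.1, radius = 0.006, target_fraction = 0.2, seed = 9)
  f <- tempfile(fileext = ".xyz")
  write_packing(pk, f)
  back <- read_packing(f)
  expect_equal(back$points, pk$points, tolerance = 1e-15)
  expect_equal(back$radius, pk$radius)
  expect_equal(back$domain, pk$domain)
  unlink(f)
})
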