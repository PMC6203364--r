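test_that("the stability gate applies the classical bound strictly", {
  # Fig-2-style validation configuration
  st <- check_stability(1.3e-6, dt = 0.1, dx = 0.01)
  expect_true(st$pass)
  expect_equal(st$ratio, 1.3e-3, tolerance = 1e-12)
  # exactly at the bound: rejected (strict inequality)
  expect_false(check_stability(1e-6, dt = 0.5 * 0.01^2 / 1e-6, dx = 0.01)$pass)
  expect_true(check_stability(1e-6, dt = 0.49 * 0.01^2 / 1e-6, dx = 0.01)$pass)
  expect_equal(check_stability(2e-6, 1, 0.01)$dt_max, 0.5 * 1e-4 / 2e-6)
})

test_that("boundary values follow the infusion-decay logistic", {
  sch <- dose_schedule("periodic", C0 = 2, tau_cycle = 1440, tau_decay = 600)
  expect_equal(boundary_value(sch, 600), 1)            # midpoint: C0/2
  expect_equal(boundary_value(sch, 1440 + 600), 1)     # periodic in the cycle
  expect_equal(boundary_value(sch, 0), 2 / (1 + exp(-10)))
  expect_equal(boundary_value(dose_schedule("constant", C0 = 3), 1e5), 3)
  # the C++ stepper evaluates the same function (seconds-based)
  expect_equal(tumorca:::boundary_conc_cpp(600 * 60, 1L, 2, 1440 * 60, 600 * 60),
               boundary_value(sch, 600))
  expect_equal(tumorca:::boundary_conc_cpp(250 * 60, 1L, 2, 1440 * 60, 600 * 60),
               boundary_value(sch, 250))
})

test_that("an all-zero field with zero boundary stays zero", {
  f <- drug_field(L = 0.2, dx = 0.02, schedule = dose_schedule("constant", C0 = 0))
  f2 <- step_uniform(f, n_steps = 200)
  expect_equal(max(abs(f2$phi)), 0)
})

test_that("unstable steps are refused with the admissible bound reported", {
  f <- drug_field(L = 0.2, dx = 0.02, schedule = dose_schedule("constant"))
  expect_error(step_uniform(f, n_steps = 1, dt = 0.6 * f$dx^2 / f$D0),
               "unstable")
  expect_error(step_heterogeneous(f, D = rep(2 * f$D0, f$N^3), n_steps = 1,
                                  dt = 0.3 * f$dx^2 / f$D0), "unstable")
})

test_that("pure first-order decay matches the exponential closed form", {
  N <- 9L
  phi <- rep(2.5, N^3)
  Kmet_s <- 1e-4; dt <- 1   # Kmet*dt = 1e-4
  tumorca:::fd_run_sealed_cpp(phi, numeric(0), TRUE, 1.3e-6, numeric(0),
                              Kmet_s, 0, 0.5, 0.02, dt, 10000L, N,
                              integer(0), numeric(0))
  expect_lt(max(abs(phi - 2.5 * exp(-1)) / (2.5 * exp(-1))), 1e-3)
})

test_that("a sealed no-reaction box conserves mass to 1e-10", {
  N <- 11L
  set.seed(4)
  phi <- runif(N^3)
  s0 <- sum(phi)
  tumorca:::fd_run_sealed_cpp(phi, numeric(0), TRUE, 1.3e-6, numeric(0),
                              0, 0, 0.5, 0.02, 40, 3000L, N,
                              integer(0), numeric(0))
  expect_lt(abs(sum(phi) - s0) / s0, 1e-10)
  expect_gte(min(phi), 0)
  # heterogeneous diffusivity conserves as well (conservative face fluxes)
  set.seed(5)
  phi2 <- runif(N^3); D <- runif(N^3, 0.5e-6, 3e-6); s0 <- sum(phi2)
  tumorca:::fd_run_sealed_cpp(phi2, D, FALSE, 0, numeric(0),
                              0, 0, 0.5, 0.02, 20, 3000L, N,
                              integer(0), numeric(0))
  expect_lt(abs(sum(phi2) - s0) / s0, 1e-10)
})

test_that("the heterogeneous stencil reduces to the uniform one for constant D", {
  sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440, tau_decay = 600)
  f <- drug_field(L = 0.2, dx = 0.02, schedule = sch,
                  Kmet = 2e-4, lambda14 = 2.5e-4)
  set.seed(6)
  nocc <- runif(f$N^3)
  fu <- step_uniform(f, nocc, n_steps = 400)
  fh <- step_heterogeneous(f, D = rep(f$D0, f$N^3), nocc, n_steps = 400)
  expect_equal(fh$phi, fu$phi, tolerance = 1e-13)
})

test_that("an impulse spreads like the free-space Green's function", {
  N <- 41L; dx <- 0.01; D <- 1.3e-6
  phi <- numeric(N^3)
  cen <- (N - 1L) / 2L
  cid <- cen + N * (cen + N * cen) + 1L
  phi[cid] <- 1
  dt <- 0.95 * dx^2 / (6 * D)
  tend <- 1000
  nst <- round(tend / dt)
  tumorca:::fd_run_sealed_cpp(phi, numeric(0), TRUE, D, numeric(0),
                              0, 0, 0.5, dx, dt, nst, N,
                              integer(0), numeric(0))
  t <- nst * dt
  pred <- dx^3 * (4 * pi * D * t)^(-3 / 2)
  expect_lt(abs(phi[cid] - pred) / pred, 0.02)
})

test_that("drug concentration is pointwise non-increasing in the uptake rate", {
  prof <- fermi_profile(0.1, 0.01)
  runs <- lapply(c(0, 2.5e-5, 2.5e-4), function(lam)
    solve_steady_state_tumor(prof, dose_schedule("constant", C0 = 1),
                             t_end_min = 120, L = 0.4, dx = 0.02,
                             lambda14 = lam, record_every_min = 60))
  p0 <- runs[[1]]$field$phi; p1 <- runs[[2]]$field$phi; p2 <- runs[[3]]$field$phi
  expect_true(all(p1 <= p0 + 1e-12))
  expect_true(all(p2 <= p1 + 1e-12))
})

test_that("a mirror-symmetric configuration evolves symmetrically", {
  sch <- dose_schedule("constant", C0 = 1)
  f <- drug_field(L = 0.2, dx = 0.02, schedule = sch, lambda14 = 2.5e-4)
  N <- f$N
  idx <- as.matrix(expand.grid(i = 0:(N - 1), j = 0:(N - 1), k = 0:(N - 1)))
  r <- sqrt(rowSums((idx * f$dx - 0.1)^2))
  D <- f$D0 * (1 + exp(-(r / 0.05)^2))     # radially symmetric diffusivity
  nocc <- as.numeric(r < 0.05)
  f2 <- step_heterogeneous(f, D, nocc, n_steps = 300)
  mirror <- (N - 1L - idx[, 1]) + N * (idx[, 2] + N * idx[, 3]) + 1L
  expect_equal(f2$phi, f2$phi[mirror], tolerance = 1e-12)
})

test_that("two-conductivity slab reaches the analytic steady profile", {
  # quasi-1D: Dirichlet plates at x = 0 (phi = 1) and x = L (phi = 0),
  # sealed sides, D jumping at the midplane
  N <- 21L; dx <- 0.01
  D1 <- 2.6e-6; D2 <- 0.65e-6
  ii <- 0:(N - 1)
  Dx <- ifelse(ii < (N - 1) / 2, D1, D2)
  D <- rep(Dx, times = N * N)
  dir0 <- which(rep(ii, N * N) == 0L) - 1L
  dirL <- which(rep(ii, N * N) == N - 1L) - 1L
  phi <- numeric(N^3)
  dt <- 0.95 * dx^2 / (6 * max(D))
  tumorca:::fd_run_sealed_cpp(phi, D, FALSE, 0, numeric(0), 0, 0, 0.5,
                              dx, dt, 30000L,
                              N, c(dir0, dirL),
                              c(rep(1, length(dir0)), rep(0, length(dirL))))
  prof <- phi[1:N]  # x-column (y = z = 0); solution is uniform in y, z
  expect_equal(phi[1:N + N * 5 + N * N * 7], prof, tolerance = 1e-8)

  # independent oracle: exact steady state of the discrete resistance chain
  Dface <- (Dx[-N] + Dx[-1]) / 2
  Rface <- dx / Dface
  Jd <- 1 / sum(Rface)
  disc <- 1 - c(0, cumsum(Rface)) * Jd
  expect_equal(prof, disc, tolerance = 1e-4)

  # continuum check: piecewise linear with flux continuity (interface falls
  # mid-face, so the discrete and continuum interface positions agree)
  xm <- (N - 1) / 2 * dx - dx / 2
  L <- (N - 1) * dx
  J <- 1 / (xm / D1 + (L - xm) / D2)
  x <- ii * dx
  cont <- ifelse(x <= xm, 1 - J * x / D1, (L - x) * J / D2)
  expect_equal(prof, cont, tolerance = 0.02)
})

test_that("region-restricted dosing builds an asymmetric field", {
  sch <- dose_schedule("periodic_regional", C0 = 1, tau_cycle = 1440,
                       tau_decay = 600,
                       region = function(x, y, z) x < 0.1 & y < 0.1)
  f <- drug_field(L = 0.2, dx = 0.02, schedule = sch, lambda14 = 0)
  f2 <- step_uniform(f, n_steps = 500)
  xyz <- as.matrix(expand.grid(x = seq(0, 0.2, 0.02), y = seq(0, 0.2, 0.02),
                               z = seq(0, 0.2, 0.02)))
  inner <- f$r < f$R_boundary
  lower_left <- xyz[, 1] < 0.1 & xyz[, 2] < 0.1
  expect_gt(mean(f2$phi[inner & lower_left]), mean(f2$phi[inner & !lower_left]))
  expect_false(anyNA(f2$phi))
  expect_gte(min(f2$phi), 0)
})

test_that("per-voxel diffusivity follows the gas-diffusion relation", {
  lat <- small_lattice()
  rho <- homogeneous_ecm(lat, 0.3)
  occ <- rep(FALSE, lat$nsites)
  env <- diffusivity_from_environment(rho, occ, lat, D0 = 1.3e-6, eta = 0.75,
                                      rho_res = 0.1, rho0 = 0.3)
  has_sites <- tabulate(lat$site_voxel + 1L, lat$grid$N^3) > 0
  expect_equal(unique(env$D[has_sites]), 0.75 * 1.3e-6, tolerance = 1e-12)

  # tumor voxels get eta * D0
  occ[1:50] <- TRUE
  env2 <- diffusivity_from_environment(rho, occ, lat)
  tv <- unique(lat$site_voxel[1:50]) + 1L
  expect_equal(unique(env2$D[tv]), 0.75 * 1.3e-6)

  # fully degraded matrix: D = D0 * rho0 / rho_res = 3 * D0
  env3 <- diffusivity_from_environment(homogeneous_ecm(lat, 0), rep(FALSE, lat$nsites), lat)
  expect_equal(unique(env3$D[has_sites]), 3 * 1.3e-6, tolerance = 1e-12)
})
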