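test_that("characteristic diffusion time follows x0^2/(4D)", {
  expect_equal(characteristic_diffusion_time(1.3e-6, 0.3),
               0.09 / (4 * 1.3e-6))
  expect_equal(signif(characteristic_diffusion_time(1.3e-6, 0.3), 3), 1.73e4)
  expect_equal(characteristic_diffusion_time(1.3e-6, 0), 0)
  # doubling the distance quadruples the time
  expect_equal(characteristic_diffusion_time(2e-6, 0.6),
               4 * characteristic_diffusion_time(2e-6, 0.3))
})

test_that("a zero-concentration schedule reproduces the drug-free run exactly", {
  lat <- mid_lattice()
  ecm <- homogeneous_ecm(lat, 0.3)
  params <- ca_params(gamma = 0.05, chi = 0.4, mu = 3)
  sch0 <- dose_schedule("constant", C0 = 0)
  a <- run_coupled(lat, ecm, params, schedule = sch0,
                   coupling = coupling_config(Np = 10), days = 25, seed = 77,
                   R_domain = 0.2, initial_radius = 0.03)
  b <- run_ca(lat, ecm, params, days = 25, seed = 77, phi_norm = 0, Np = 10,
              R_domain = 0.2, initial_radius = 0.03)
  expect_identical(a$state$state, b$state$state)
  expect_identical(a$state$rho, b$state$rho)
  expect_equal(a$metrics$R_P, b$metrics$R_P)
  expect_equal(a$events, b$events)
})

test_that("pinning the field exchange reduces to the fixed-factor CA run", {
  lat <- mid_lattice()
  ecm <- homogeneous_ecm(lat, 0.3)
  params <- ca_params(gamma = 0.05, chi = 0.4, mu = 3, Pgamma = 0.6)
  sch <- dose_schedule("constant", C0 = 1)
  a <- run_coupled(lat, ecm, params, schedule = sch,
                   coupling = coupling_config(Np = 10, exchange_phi = FALSE),
                   days = 20, seed = 55, R_domain = 0.2,
                   initial_radius = 0.03, phi_norm_const = 1)
  b <- run_ca(lat, ecm, params, days = 20, seed = 55, phi_norm = 1, Np = 10,
              R_domain = 0.2, initial_radius = 0.03)
  expect_identical(a$state$state, b$state$state)
  expect_equal(a$metrics$R_P, b$metrics$R_P)
})

test_that("identical configuration and seed give identical runs", {
  lat <- mid_lattice()
  ecm <- sinusoidal_ecm(lat, 0.3, 0.4, Lx = 0.4 / 30)
  sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440, tau_decay = 1800)
  args <- list(lat, ecm, ca_params(gamma = 0.05, chi = 0.4, mu = 3),
               schedule = sch, drug = drug_params(lambda14 = 2.5e-4),
               coupling = coupling_config(Np = 10), days = 15, seed = 123,
               R_domain = 0.2, initial_radius = 0.03)
  a <- do.call(run_coupled, args)
  b <- do.call(run_coupled, args)
  expect_identical(a$state$state, b$state$state)
  expect_identical(a$phi, b$phi)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$events, b$events)
})

test_that("the PDE clock and the CA clock agree at the day boundary", {
  lat <- mid_lattice()
  sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440, tau_decay = 600)
  run <- run_coupled(lat, homogeneous_ecm(lat, 0.3),
                     ca_params(gamma = 0, chi = 0.4), schedule = sch,
                     coupling = coupling_config(Np = 7), days = 9, seed = 5,
                     R_domain = 0.2, initial_radius = 0.03)
  expect_equal(run$pde_t_s, 9 * 86400)
  expect_gte(min(run$phi), 0)
})

test_that("growth converges in the number of coupling sub-steps", {
  lat <- mid_lattice()
  ecm <- homogeneous_ecm(lat, 0.3)
  params <- ca_params(gamma = 0, chi = 0.4, Pgamma = 0.05)
  sch <- dose_schedule("periodic", C0 = 1, tau_cycle = 1440, tau_decay = 1800)
  mean_rp <- function(np) {
    mean(sapply(1:10, function(s) {
      m <- run_coupled(lat, ecm, params, schedule = sch,
                       drug = drug_params(lambda14 = 2.5e-4),
                       coupling = coupling_config(Np = np), days = 40,
                       seed = 300 + s, R_domain = 0.2,
                       initial_radius = 0.03)$metrics
      mean(m$R_P[35:40])   # time-averaged endpoint damps per-day noise
    }))
  }
  r50 <- mean_rp(50)
  r100 <- mean_rp(100)
  expect_lt(abs(r50 - r100) / r50, 0.05)
})

test_that("each proliferative cell divides in exactly one daily cohort", {
  # with p0 = 1 and zero-density matrix every day-start proliferative cell
  # with space divides exactly once, daughters only join the next day's
  # partition; so the daily division count equals the day-start rim size for
  # any Np
  lat <- mid_lattice()
  ecm <- homogeneous_ecm(lat, 0)
  params <- ca_params(p0 = 1, gamma = 0, chi = 0.4, b = 10)  # huge rim
  n_seed <- sum(tumor_state(lat, ecm, R_domain = 0.2,
                            initial_radius = 0.03)$state == 1L)
  for (np in c(1, 25)) {
    run <- run_coupled(lat, ecm, params,
                       schedule = dose_schedule("constant", C0 = 0),
                       coupling = coupling_config(Np = np), days = 6,
                       seed = 9, R_domain = 0.2, initial_radius = 0.03)
    m <- run$metrics; ev <- run$events
    # day 1: every seed cell has free matrix around it and p0 = 1
    expect_equal(ev$divisions[1], n_seed)
    # never more than one division per day-start rim cell
    start_rim <- c(n_seed, m$proliferative[-6])
    expect_true(all(ev$divisions <= start_rim))
    # bookkeeping identity: rim evolves by births minus quiescence exits
    expect_equal(m$proliferative,
                 start_rim + ev$divisions - ev$quiesced - ev$mutations)
  }
})
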