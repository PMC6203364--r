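test_that("rim thicknesses follow the 2/3-power scaling with unit handling", {
  p <- ca_params()
  expect_equal(necrotic_thickness(0.1, p), 0.012)        # Lt = 1 mm -> 0.12 mm
  expect_equal(necrotic_thickness(0, p), 0)
  expect_equal(necrotic_thickness(0.8, p), 0.048)        # Lt = 8 mm -> 0.48 mm
  expect_equal(proliferative_thickness(0.1, p), 0.008)   # 0.08 mm
  expect_equal(proliferative_thickness(0, p), 0)
  expect_equal(proliferative_thickness(0.8, p), 0.032)   # 0.32 mm
})

test_that("division probability combines drug, confinement and ECM factors", {
  p <- ca_params(Pgamma = 0.6)
  # no drug: no reduction
  expect_equal(division_probability(0, 0, r = 0, Lmax = 0.4, p), p$p0)
  # full drug: reduction floor Pgamma
  expect_equal(division_probability(1, 0, r = 0, Lmax = 0.4, p), p$p0 * 0.6)
  # at the boundary with full-density matrix both terms vanish (literal rule)
  p_add <- ca_params(Pgamma = 0.6, division_rule = "additive")
  expect_equal(division_probability(1, 1, r = 0.4, Lmax = 0.4, p_add), 0)
  expect_equal(division_probability(0, 1, r = 0.4, Lmax = 0.4, p), 0)
  # additive rule is clamped to [0, 1]
  expect_lte(division_probability(0, 0, r = 0, Lmax = 1, p_add), 1)
  expect_error(division_probability(0, 0.3, r = 0, Lmax = 0, p), "Lmax")
})

test_that("single-cell division frequency matches its Bernoulli probability", {
  lat <- small_lattice()
  ts0 <- tumor_state(lat, homogeneous_ecm(lat, 0), R_domain = 0.1,
                     initial_radius = 0.011)
  seed_sites <- which(ts0$state == 1L)
  expect_gte(length(seed_sites), 1)
  i0 <- seed_sites[1]
  ts0$state[seed_sites[-1]] <- 0L       # keep exactly one proliferative cell
  ts0$cstat <- c(lat$points[i0, ], 1)
  p <- ca_params(gamma = 0)
  # the centroid sits on the single cell, so r = 0 and the expected
  # probability is exactly p0 (rho of every target is 0)
  pdiv <- division_probability(0, 0, r = 0, Lmax = 0.1, p)
  expect_equal(pdiv, p$p0)
  n <- 10000
  set.seed(99)
  hits <- 0L
  for (k in seq_len(n)) {
    st <- ts0$state + 0L; rho <- ts0$rho + 0; cs <- ts0$cstat + 0
    div <- tumorca:::ca_divide_cpp(i0 - 1L, st, rho, lat$points,
                                   lat$adj_ptr, lat$adj_idx, cs,
                                   numeric(0), integer(0), 0, 1,
                                   p$p0, p$Pgamma, 0, p$Ai, 0L, 0L,
                                   ts0$domain_center, 0.1)
    hits <- hits + length(div$daughters)
  }
  phat <- hits / n
  se <- sqrt(pdiv * (1 - pdiv) / n)
  expect_lt(abs(phat - pdiv), 3 * se)
})

test_that("zero mutation rate never produces invasive cells", {
  lat <- small_lattice()
  run <- run_ca(lat, homogeneous_ecm(lat, 0.3),
                ca_params(gamma = 0, chi = 0.4, mu = 3), days = 50,
                seed = 21, R_domain = 0.1, initial_radius = 0.02)
  expect_equal(max(run$metrics$N_Inv), 0)
  expect_equal(sum(run$events$mutations), 0)
})

test_that("zero degradation ability means invasive cells never migrate", {
  lat <- small_lattice()
  run <- run_ca(lat, homogeneous_ecm(lat, 0.3),
                ca_params(gamma = 0.5, chi = 0, mu = 3), days = 50,
                seed = 22, R_domain = 0.1, initial_radius = 0.02)
  expect_gt(max(run$metrics$N_Inv), 0)    # mutants do appear ...
  expect_equal(sum(run$events$migrations), 0)  # ... but never move
  expect_equal(sum(run$metrics$degraded), 0)   # and leave no trail
})

test_that("phenotype flow is one-way and ECM density never increases", {
  lat <- mid_lattice()
  ecm <- sinusoidal_ecm(lat, 0.3, 0.4, Lx = 0.4 / 30)
  params <- ca_params(gamma = 0.05, chi = 0.4, mu = 3)
  set.seed(31)
  ts <- tumor_state(lat, ecm, R_domain = 0.2, initial_radius = 0.03)
  prev_state <- ts$state
  prev_rho <- ts$rho
  necro_prev <- 0; n_prev <- ts$cstat[4]
  allowed <- list(`0` = c(0L, 1L, 4L, 5L), `1` = c(1L, 2L),
                  `2` = c(2L, 3L), `3` = 3L, `4` = c(4L, 5L),
                  `5` = c(5L, 1L, 4L), `6` = 6L)
  for (day in 1:40) {
    up <- daily_update(ts, lat, params, phi_norm = 0)
    ts <- up$state
    for (s in names(allowed)) {
      from <- prev_state == as.integer(s)
      expect_true(all(ts$state[from] %in% allowed[[s]]),
                  info = paste("day", day, "state", s))
    }
    expect_true(all(ts$rho <= prev_rho + 1e-12))
    necro <- sum(ts$state == 3L)
    expect_gte(necro, necro_prev)
    expect_gte(ts$cstat[4], n_prev)
    prev_state <- ts$state; prev_rho <- ts$rho
    necro_prev <- necro; n_prev <- ts$cstat[4]
  }
  # invasive count grew and cells moved outward beyond the rim
  expect_gt(sum(ts$state == 4L), 0)
})

test_that("centroid bookkeeping matches the noninvasive tumor mean", {
  lat <- mid_lattice()
  set.seed(41)
  ts <- tumor_state(lat, homogeneous_ecm(lat, 0.3), R_domain = 0.2,
                    initial_radius = 0.03)
  params <- ca_params(gamma = 0.05, chi = 0.4, mu = 3)
  for (day in 1:20) ts <- daily_update(ts, lat, params, 0)$state
  noninv <- which(ts$state %in% c(1L, 2L, 3L))
  expect_equal(ts$cstat[4], length(noninv))
  expect_equal(ts$cstat[1:3], colMeans(lat$points[noninv, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("stronger uniform drug slows primary growth monotonically", {
  lat <- mid_lattice()
  radii <- sapply(c(0, 0.5, 1), function(phin) {
    r <- sapply(1:6, function(s)
      run_ca(lat, homogeneous_ecm(lat, 0.3),
             ca_params(gamma = 0, Pgamma = 0.3), days = 45, seed = 100 + s,
             phi_norm = phin, R_domain = 0.2, initial_radius = 0.03
      )$metrics$R_P[45])
    mean(r)
  })
  expect_true(all(diff(radii) < 0))
})
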