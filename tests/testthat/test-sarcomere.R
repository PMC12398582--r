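## Half-sarcomere cross-bridge model.

test_that("thin-filament fluxes match direct evaluation", {
  p <- xb_params(k_on = 1, k_off = 1, k_coop = 2)
  st <- xb_state_init(p)
  st[1, 1:2] <- c(0.5, 0.5) # N_off, N_on
  fl <- thin_filament_fluxes(st, ca = 1, n_overlap = 1, p)
  ## J_on = 1*1*(1-0.5)*(1+2*0.5) = 1; J_off = 1*0.5*(1+2*0.5) = 1
  expect_equal(fl$J_on, 1.0)
  expect_equal(fl$J_off, 1.0)
  ## zero calcium silences activation
  expect_equal(thin_filament_fluxes(st, 0, 1, p)$J_on, 0)
  ## saturated overlap: no free sites
  st[1, 1:2] <- c(0, 1)
  expect_equal(thin_filament_fluxes(st, 1, 1, p)$J_on, 0)
})

test_that("SRX/DRX fluxes follow the force-dependent recruitment law", {
  p <- xb_params(k_1 = 2, k_force = 0.5, k_2 = 7)
  st <- xb_state_init(p)
  st[1, 3:4] <- c(0.3, 0.7)
  fl <- srx_drx_fluxes(st, f_total = 4, p)
  expect_equal(fl$J_1, 2 * (1 + 0.5 * 4) * 0.3) # = 1.8
  expect_equal(fl$J_2, 7 * 0.7)
  ## force term collapses at zero and negative load
  expect_equal(srx_drx_fluxes(st, 0, p)$J_1, 2 * 0.3)
  expect_equal(srx_drx_fluxes(st, -100, p)$J_1, 2 * 0.3)
  ## no SRX heads, no flux
  st[1, 3:4] <- c(0, 1)
  expect_equal(srx_drx_fluxes(st, 4, p)$J_1, 0)
})

test_that("attachment and detachment fluxes are even in cross-bridge strain", {
  p <- xb_params()
  st <- xb_state_init(p)
  st[1, 2] <- 0.6                  # some active sites
  st[1, 4] <- 0.5; st[1, 3] <- 0.3 # DRX pool
  st[1, 5:25] <- 0.2 / 21          # uniform attached population
  fl <- attach_detach_fluxes(st, p)
  expect_equal(fl$J_3, rev(fl$J_3))
  expect_equal(fl$J_4, rev(fl$J_4))
  ## x = 0 bin: Gaussian factor 1, strain-dependent detachment absent
  i0 <- which(fl$x == 0)
  expect_equal(fl$J_3[i0], p$k_3 * (0.6 - 0.2) * 0.5)
  expect_equal(fl$J_4[i0], p$k_4_0 * 0.2 / 21)
})

test_that("active force is the first moment of the attached distribution", {
  p <- xb_params()
  st <- xb_state_init(p)
  expect_equal(active_force(st, p), 0) # no attached heads
  ## single populated bin at x = 0
  st[1, 5:25] <- 0
  st[1, 4 + 11] <- 0.2
  expect_equal(active_force(st, p),
               p$N_0 * p$k_cb * 0.2 * p$x_ps * 1e-9)
  ## symmetric distribution: strain terms cancel, power stroke remains
  st[1, 5:25] <- rep(0.01, 21)
  expect_equal(active_force(st, p),
               p$N_0 * p$k_cb * 0.21 * p$x_ps * 1e-9)
})

test_that("conservation sums hold to 1e-8 per step under arbitrary driving", {
  set.seed(7)
  p <- xb_params()
  st <- xb_state_init(p, n = 4)
  thin_drift <- thick_drift <- 0
  min_entry <- Inf
  for (i in 1:300) {
    ca <- 10^runif(4, -7.5, -5.5)
    ft <- runif(4, 0, 8e4)
    dh <- rnorm(4, 0, 2)
    st <- step_states(st, ca, ft, dh, p, 1e-3)
    thin_drift <- max(thin_drift, abs(rowSums(st[, 1:2]) - 1))
    thick_drift <- max(thick_drift, abs(rowSums(st[, 3:25]) - 1))
    min_entry <- min(min_entry, st)
  }
  expect_lt(thin_drift, 1e-8)
  expect_lt(thick_drift, 1e-8)
  expect_gte(min_entry, 0)
})

test_that("zero calcium for all time keeps the sarcomere passive", {
  p <- xb_params()
  st <- xb_state_init(p)
  for (i in 1:100) st <- step_states(st, 0, 0, 0, p, 1e-3)
  expect_equal(active_force(st, p), 0)
  expect_equal(st[1, 2], 0) # no activated sites
})

test_that("isolated SRX/DRX subsystem reaches its closed-form balance", {
  ## no calcium -> no attachment; fixed load F drives recruitment:
  ## M_DRX/M_SRX -> k_1 (1 + k_force F) / k_2
  p <- xb_params()
  for (Fload in c(0, 2e4, 6e4)) {
    st <- xb_state_init(p)
    for (i in 1:400) st <- step_states(st, 0, Fload, 0, p, 1e-3)
    ratio <- st[1, 4] / st[1, 3]
    expect_equal(ratio, p$k_1 * (1 + p$k_force * Fload) / p$k_2,
                 tolerance = 1e-6)
  }
})

test_that("twitch force agrees with a fine-step explicit-Euler reference", {
  p <- xb_params(dt_sub = 1e-4)
  cap <- calcium_params()
  ca_fun <- function(t) calcium_transient(t, cap)
  ## package path at the 1 ms global step
  st <- xb_state_init(p)
  f <- 0
  fmax <- 0
  n <- 100
  for (i in 1:n) {
    st <- step_states(st, ca_fun(i * 1e-3), max(f, 0), 0, p, 1e-3)
    f <- active_force(st, p)
    fmax <- max(fmax, f)
  }
  ## brute-force oracle: 1 microsecond Euler, force feedback updated
  ## continuously
  ref <- xb_euler_reference(xb_state_init(p), ca_fun, p, n * 1e-3, 1e-6)
  expect_equal(f, ref$F_active, tolerance = 5e-3)
  expect_equal(unname(as.numeric(st)), ref$state, tolerance = 5e-3)
})

test_that("twitch peak force increases monotonically with k_1", {
  p <- xb_params()
  cap <- calcium_params()
  peaks <- vapply(c(0.5, 1, 2) * p$k_1, function(k1) {
    tw <- twitch_protocol(p, cap, duration_s = 0.4, dt_s = 2e-3, k1 = k1)
    max(tw$F_active_Pa)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("strain advection conserves attached mass and detaches at the grid edge", {
  p <- xb_params(k_on = 0, k_off = 0, k_1 = 0, k_2 = 0, k_3 = 0,
                 k_4_0 = 0, k_4_1 = 0)
  st <- xb_state_init(p)
  st[1, 3] <- 0.6; st[1, 4] <- 0.2
  st[1, 4 + 11] <- 0.2 # attached at x = 0
  ## shift +3 nm: half-sarcomere shortens by -3 nm -> x shifts +3
  s1 <- step_states(st, 0, 0, -3, p, 1e-3)
  expect_equal(s1[1, 4 + 14], 0.2) # landed at x = +3
  expect_equal(sum(s1[1, 3:25]), 1)
  ## shift far beyond the grid: all mass force-detaches into DRX
  s2 <- step_states(st, 0, 0, -25, p, 1e-3)
  expect_equal(sum(s2[1, 5:25]), 0)
  expect_equal(s2[1, 4], 0.4)
})

test_that("calcium transient is periodic, conserved and decays to baseline", {
  p <- calcium_params()
  tt <- seq(0, p$period, by = 1e-3)
  ca <- calcium_transient(tt, p)
  ## periodicity of the closed-form steady state
  expect_equal(calcium_transient(0.1, p), calcium_transient(0.1 + p$period, p))
  ## late diastole sits near the leak/uptake baseline
  expect_equal(ca[length(ca)], calcium_baseline(p), tolerance = 0.05)
  ## release gate shut -> flat line at baseline
  p0 <- calcium_params(k_release = 0)
  ca0 <- calcium_transient(tt, p0)
  expect_lt(diff(range(ca0)) / mean(ca0), 1e-6)
  ## two-pool conservation: the myoplasmic trace never exceeds the total
  expect_true(all(ca > 0 & ca < p$ca_total))
})
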