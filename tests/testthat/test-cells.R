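test_that("temperature factor matches its closed form", {
  expect_equal(round(qt_factor(), 4), 2.9529)
  expect_equal(qt_factor(Q = 1), 1)
})

test_that("cell parameter tables enforce the cell-kind restrictions", {
  expect_equal(cell_params("PY")$g_Na_soma, 3000)
  expect_equal(cell_params("IN")$g_Nap_soma, 0)
  expect_equal(cell_params("RE")$g_h, 0)
  expect_equal(cell_params("TC")$S, 2.9e-4)
  expect_error(cell_params("RE", g_h = 0.01), "TC-only")
  expect_error(cell_params("IN", g_Nap_dend = 1), "PY-only")
  expect_error(cell_params("PY", g_Km = -2), ">= 0")
  expect_error(cell_params("PY", nonsense = 1), "unknown")
})

test_that("h-current activation is a shifted decreasing sigmoid", {
  expect_equal(ih_activation(-(75 - 24), ha_gh = -24), 0.5)
  expect_equal(ih_activation(-51, ha_gh = -24), 0.5)
  expect_equal(ih_activation(-74, ha_gh = -1), 0.5)
  expect_equal(ih_activation(-1e4), 1)
  expect_equal(ih_activation(1e4), 0)
  v <- seq(-120, 0, by = 1)
  expect_true(all(diff(ih_activation(v, -2)) < 0))
})

test_that("mini rate has the stated limits and midpoint value", {
  expect_equal(mini_rate(0, 0), 0)
  expect_equal(mini_rate(1e6, 0), 1 / 250)
  expect_equal(mini_rate(30 * log(3), 0), 0.002)
  expect_equal(mini_rate(-5, 0), 0)        # clamp before the spike
  tt <- seq(0, 500, by = 1)
  expect_true(all(diff(mini_rate(tt, 0)) >= 0))
})

test_that("null and leak-only dendrites satisfy the current balance", {
  p0 <- cell_params("PY", g_Na_dend = 0, g_Nap_dend = 0, g_Km = 0,
                    g_KCa = 0, g_HVA = 0, G_L = 0, G_KL = 0,
                    kappa_Mohm = 1e12)
  s <- cortical_state(-60, p0)
  d <- cortical_dendrite_rhs(s, p0, ach_gkl = 1)
  expect_equal(d$dstate[["V_D"]], 0, tolerance = 1e-9)

  pl <- cell_params("PY", g_Na_dend = 0, g_Nap_dend = 0, g_Km = 0,
                    g_KCa = 0, g_HVA = 0, G_KL = 0, kappa_Mohm = 1e12)
  sl <- cortical_state(pl$E_L, pl)
  expect_equal(cortical_dendrite_rhs(sl, pl, 1)$dstate[["V_D"]], 0,
               tolerance = 1e-9)
  # displaced 10 mV: linear relaxation at G_L / C_m
  s10 <- sl; s10["V_D"] <- pl$E_L + 10
  expect_equal(cortical_dendrite_rhs(s10, pl, 1)$dstate[["V_D"]],
               -10 * pl$G_L / pl$C_m, tolerance = 1e-6)
})

test_that("leak-only dendrite integrates to the analytic exponential", {
  pl <- cell_params("PY", g_Na_dend = 0, g_Nap_dend = 0, g_Km = 0,
                    g_KCa = 0, g_HVA = 0, G_KL = 0, kappa_Mohm = 1e12,
                    g_Na_soma = 0, g_K_soma = 0, g_Nap_soma = 0)
  # RK4 on the package RHS vs closed form V(t) = E + 10 exp(-t G/C)
  s <- cortical_state(pl$E_L, pl)
  s["V_D"] <- pl$E_L + 10
  dt <- 0.02
  for (i in 1:5000) {
    k1 <- unlist(cortical_dendrite_rhs(s, pl, 1)$dstate)
    k2 <- unlist(cortical_dendrite_rhs(s + dt / 2 * k1, pl, 1)$dstate)
    k3 <- unlist(cortical_dendrite_rhs(s + dt / 2 * k2, pl, 1)$dstate)
    k4 <- unlist(cortical_dendrite_rhs(s + dt * k3, pl, 1)$dstate)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expected <- pl$E_L + 10 * exp(-100 * pl$G_L / pl$C_m)
  expect_equal(unname(s["V_D"]), expected, tolerance = 1e-6)
})

test_that("axosomatic equilibrium solves the coupling balance", {
  p <- cell_params("PY")
  # all axosomatic channels closed: V_S = V_D exactly
  p0 <- cell_params("PY", g_Na_soma = 0, g_K_soma = 0, g_Nap_soma = 0)
  expect_equal(solve_axosomatic_equilibrium(-63.7, c(0.2, 0.5, 0.1, 0.3),
                                            p0)$V_S, -63.7)
  # one ohmic channel: algebraic oracle (g VD + g_lin E_lin)/(g + g_lin)
  p1 <- cell_params("PY", g_Na_soma = 0, g_Nap_soma = 0)  # K only
  gate <- c(0, 0, 0.5, 0)
  g_c <- 1 / p1$kappa_Mohm * 1e-3 / p1$S_soma   # mS/cm2 on the soma
  g_lin <- p1$g_K_soma * 0.5
  oracle <- (g_c * -60 + g_lin * p1$E_K) / (g_c + g_lin)
  expect_equal(solve_axosomatic_equilibrium(-60, gate, p1)$V_S, oracle,
               tolerance = 1e-8)
})

test_that("the returned root satisfies the residual tolerance broadly", {
  set.seed(33)
  p <- cell_params("PY")
  scale <- abs(1 / p$kappa_Mohm * 1e-3 / p$S_soma) + p$g_Na_soma +
    p$g_K_soma + p$g_Nap_soma
  for (i in 1:1000) {
    vd <- runif(1, -100, 20)
    gate <- runif(4)
    out <- solve_axosomatic_equilibrium(vd, gate, p, tol = 1e-8)
    expect_lt(abs(out$residual), 1e-8 * scale)
  }
})

test_that("thalamic RHS rejects an h-current on reticular cells", {
  pre <- cell_params("RE")
  s <- rep(0.1, 7); s[1] <- -70
  expect_silent(thalamic_rhs(stats::setNames(s, tcsleep:::re_state_names),
                             pre, ach_gkl = 0.9))
  pre2 <- unclass(cell_params("RE"))
  pre2$g_h <- 0.01          # bypass the constructor guard
  class(pre2) <- "cell_params"
  expect_error(thalamic_rhs(stats::setNames(s, tcsleep:::re_state_names),
                            pre2, ach_gkl = 0.9), "TC-only")
})

test_that("a leak-only thalamic cell rests at the weighted leak reversal", {
  p <- cell_params("TC", g_Na = 0, g_K = 0, g_T = 0, g_h = 0)
  gkl <- 0.96
  vrest <- (p$G_L * p$E_L + gkl * p$G_KL * p$E_K) /
    (p$G_L + gkl * p$G_KL)
  s <- stats::setNames(numeric(10), tcsleep:::tc_state_names)
  s["V"] <- vrest; s["Ca"] <- 2.4e-4
  d <- thalamic_rhs(s, p, ach_gkl = gkl, ha_gh = -2)
  expect_equal(d$dstate[["V"]], 0, tolerance = 1e-9)
})

test_that("relay cells fire a rebound burst after hyperpolarizing release", {
  p <- cell_params("TC")
  out <- single_cell(p, "n2", duration = 1500,
                     stim = matrix(c(500, 700, -1.5), 1), v0 = -65)
  # the clamp takes the cell below -80 mV; release triggers a
  # low-threshold calcium burst
  expect_lt(min(out$v[out$t > 600 & out$t < 700]), -80)
  burst <- out$spikes[out$spikes > 700 & out$spikes < 780]
  expect_gte(length(burst), 2)
})

test_that("awake pyramidal cells fire repetitively; N3 cells rest silent", {
  p <- cell_params("PY")
  drv <- single_cell(p, "awake", duration = 1200,
                     stim = matrix(c(200, 1200, 0.4), 1))
  expect_gte(sum(drv$spikes > 200), 5)
  rest <- single_cell(p, "n3", duration = 1000)
  expect_equal(length(rest$spikes), 0)
  expect_lt(tail(rest$v, 1), -55)
})

test_that("integrated gating and open fractions stay in [0,1]", {
  set.seed(44)
  # receptor kinetics under random presynaptic trains
  for (rec in c("AMPA", "NMDA", "GABAA")) {
    spk <- sort(runif(30, 0, 800))
    out <- synapse_response(rec, spk, duration = 1000, dt = 0.02)
    expect_true(all(out$value >= 0 & out$value <= 1), info = rec)
  }
  # driven single cells never report an out-of-range voltage trajectory
  # (the integrator clamps roundoff excursions of every gate)
  r <- single_cell(cell_params("PY"), "awake", duration = 400,
                   stim = matrix(c(50, 350, 0.5), 1))
  expect_true(all(is.finite(r$v)))
})
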