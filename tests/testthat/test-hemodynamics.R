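rho <- 1050
A0 <- pi * 1e-6 # 1 mm radius vessel

single_tube <- function(N = 48, c0 = 12, L = 0.05, mu = 3.5e-3) {
  beta <- 2 * rho * c0^2 / sqrt(A0)
  pr <- segment_properties(A0, beta, L, rho = rho, mu = mu, n_grid = N)
  flow_model(list(s1 = list(from = "in", to = "out", props = pr)),
             inlet = "in")
}

test_that("zero inflow from equilibrium stays at rest", {
  m <- single_tube(N = 16)
  fs <- solve_flow(m, cardiac_input(0), t_end = 0.02, save_every = 5L)
  s <- fs$segments$s1
  expect_equal(max(abs(s$u)), 0, tolerance = 1e-12)
  expect_equal(max(abs(s$A - A0)), 0, tolerance = 1e-18)
  expect_equal(max(abs(s$p)), 0, tolerance = 1e-9)
})

test_that("steady flow in the rigid limit reproduces the Poiseuille drop", {
  mu <- 3.5e-3; L <- 0.05; Q <- 1.5e-7
  m <- single_tube(N = 48, c0 = 12, L = L, mu = mu)
  fs <- suppressWarnings(
    solve_flow(m, cardiac_input(Q), t_end = 1.0, save_every = 1e6))
  s <- fs$segments$s1
  N <- nrow(s$p)
  pend <- s$p[, ncol(s$p)]
  ## face-to-face pressure drop by linear extrapolation to the ends
  dp <- (pend[1] + 0.5 * (pend[1] - pend[2])) -
    (pend[N] + 0.5 * (pend[N] - pend[N - 1]))
  dp_pois <- 8 * pi * mu * L * Q / A0^2 # == 8 mu L Q / (pi R^4)
  expect_lt(abs(dp - dp_pois) / dp_pois, 0.01)
  ## flow settles to the prescribed inflow everywhere
  expect_equal(s$Q[, ncol(s$Q)], rep(Q, N), tolerance = 1e-6)
  ## probes at the two ends: same Q, p differs by the segment drop
  t0 <- export_timeseries(fs, "s1", 0)
  t1 <- export_timeseries(fs, "s1", 1)
  expect_equal(tail(t0$Q, 1), tail(t1$Q, 1), tolerance = 1e-6)
  expect_gt(tail(t0$p, 1), tail(t1$p, 1))
  ## mass ledger closes to round-off
  expect_lt(flow_mass_balance(fs)$relative_error, 1e-10)
})

test_that("the steady profile converges under grid refinement", {
  ## viscous case with a resolvable gradient; fine-grid reference
  mu <- 0.02; Q <- 6e-7
  prof <- function(N) {
    m <- single_tube(N = N, c0 = 6, mu = mu)
    fs <- suppressWarnings(
      solve_flow(m, cardiac_input(Q), t_end = 1.0, save_every = 1e6))
    s <- fs$segments$s1
    list(x = s$x, p = s$p[, ncol(s$p)])
  }
  ref <- prof(96)
  err <- vapply(c(12, 24), function(N) {
    pN <- prof(N)
    pr_i <- approx(ref$x, ref$p, xout = pN$x)$y
    sqrt(mean((pN$p - pr_i)^2)) / diff(range(ref$p))
  }, numeric(1))
  expect_gte(err[1] / err[2], 1.5) # halving dx cuts the error >= 1.5x
})

test_that("RCR beds reproduce closed-form steady flow and relaxation", {
  bed <- lumped_bed(R_prox = 1e8, R_dist = 2e8, C = 1e-9)
  ## steady state: Q = dp / (R_prox + R_dist)
  st <- list(p_c = 0)
  for (i in 1:400) {
    r <- bed_update(bed, 1000, 100, st, 5e-3)
    st <- r$state
  }
  expect_equal(r$Q, (1000 - 100) / (1e8 + 2e8), tolerance = 1e-6)
  ## equal pressures, equilibrated compliance: no flow
  r0 <- bed_update(bed, 500, 500, list(p_c = 500), 1e-3)
  expect_equal(r0$Q, 0, tolerance = 1e-12)
  ## step response relaxes with tau = C R1 R2 / (R1 + R2), within 2%
  tau <- bed$C * bed$R_prox * bed$R_dist / (bed$R_prox + bed$R_dist)
  st <- list(p_c = 0)
  nstep <- 200L; dt <- tau / 50
  trace <- numeric(nstep)
  for (i in seq_len(nstep)) {
    r <- bed_update(bed, 1000, 0, st, dt)
    st <- r$state
    trace[i] <- st$p_c
  }
  p_inf <- 1000 * bed$R_dist / (bed$R_prox + bed$R_dist)
  analytic <- p_inf * (1 - exp(-seq_len(nstep) * dt / tau))
  expect_lt(max(abs(trace - analytic)) / p_inf, 0.02)
})

test_that("bed dynamics agree with an independent ODE solver", {
  bed <- lumped_bed(R_prox = 3e8, R_dist = 7e8, C = 5e-10)
  p_art <- function(t) 800 + 300 * sin(2 * pi * t / 0.8)
  dt <- 1e-3; times <- seq(0, 0.8, dt)
  ## package route: exact exponential steps with frozen pressures
  st <- list(p_c = 0); mine <- numeric(length(times)); mine[1] <- 0
  for (i in seq_along(times)[-1]) {
    r <- bed_update(bed, p_art(times[i - 1]), 0, st, dt)
    st <- r$state
    mine[i] <- st$p_c
  }
  ## oracle: generic stiff integrator on the same ODE
  rhs <- function(t, y, parms)
    list((p_art(t) - y) / (bed$R_prox * bed$C) -
           (y - 0) / (bed$R_dist * bed$C))
  ode <- deSolve::ode(c(p_c = 0), times, rhs, NULL, method = "lsoda")
  expect_lt(max(abs(mine - ode[, "p_c"])) / max(ode[, "p_c"]), 0.02)
})

test_that("a symmetric bifurcation splits flow evenly and conserves mass", {
  beta <- 2 * rho * 10^2 / sqrt(A0)
  prp <- segment_properties(A0, beta, 0.04, n_grid = 12L)
  prc <- segment_properties(A0 / 1.6, 2 * rho * 10^2 / sqrt(A0 / 1.6),
                            0.03, n_grid = 12L)
  bed <- lumped_bed(5e8, 1e9, 1e-10)
  m <- flow_model(
    list(p = list(from = "in", to = "j", props = prp),
         c1 = list(from = "j", to = "t1", props = prc),
         c2 = list(from = "j", to = "t2", props = prc)),
    beds = list(list(bed = bed, from = "t1", to = NA),
                list(bed = bed, from = "t2", to = NA)),
    inlet = "in")
  fs <- suppressWarnings(
    solve_flow(m, cardiac_input(2e-7), t_end = 0.8, save_every = 1e6))
  k <- ncol(fs$segments$p$Q)
  qp <- fs$segments$p$Q[12, k]
  q1 <- fs$segments$c1$Q[1, k]
  q2 <- fs$segments$c2$Q[1, k]
  expect_lt(abs(q1 - q2) / abs(qp), 1e-9)          # symmetry
  expect_lt(abs(qp - q1 - q2) / abs(qp), 1e-6)     # junction mass balance
  expect_lt(flow_mass_balance(fs)$relative_error, 1e-8)
})

test_that("pulsatile flow through a bed network becomes cycle-periodic", {
  beta <- 2 * rho * 10^2 / sqrt(A0)
  pr <- segment_properties(A0, beta, 0.04, n_grid = 10L)
  bed <- lumped_bed(5e8, 1e9, 1e-10)
  m <- flow_model(list(s = list(from = "in", to = "t", props = pr)),
                  beds = list(list(bed = bed, from = "t", to = NA)),
                  inlet = "in")
  period <- 0.2
  fs <- suppressWarnings(
    solve_flow(m, sine_inflow(2e-7, 1e-7, period), t_end = 5 * period,
               save_every = 5L))
  ts <- export_timeseries(fs, "s", 0.5)
  cyc <- sum(ts$t < period)
  n <- nrow(ts)
  a <- ts$p[(n - cyc + 1):n]
  b <- ts$p[(n - 2 * cyc + 1):(n - cyc)]
  expect_lt(max(abs(a - b)) / diff(range(a)), 0.01)
})

test_that("probes interpolate in space and reject unknown segments", {
  m <- single_tube(N = 8)
  fs <- solve_flow(m, cardiac_input(0), t_end = 0.005, save_every = 2L)
  ## request exactly at a cell centre: exact grid values
  x <- fs$segments$s1$x
  L <- m$segments$s1$props$length
  ts <- export_timeseries(fs, "s1", x[3] / L)
  expect_equal(ts$A, fs$segments$s1$A[3, ], tolerance = 1e-12)
  expect_error(export_timeseries(fs, "nope", 0.5), "unknown segment")
  expect_error(export_timeseries(fs, "s1", 1.5), "x_fraction")
})

test_that("collapse and NaN states abort with a located error", {
  ## a violent suction at the outlet collapses the vessel
  beta_soft <- 2 * rho * 1.5^2 / sqrt(A0)
  pr <- segment_properties(A0, beta_soft, 0.02, n_grid = 8L)
  m <- flow_model(list(s = list(from = "in", to = "out", props = pr)),
                  inlet = "in", p_out = -2 * rho * 1.5^2)
  expect_error(
    suppressWarnings(solve_flow(m, cardiac_input(-1e-5), t_end = 0.5,
                                dt = 5e-4)),
    "collapse|diverged")
})
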