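geom <- crypt_geometry()

test_that("pairwise Hookean force has the printed magnitudes and symmetry", {
  p <- mechanics_params(k_over_eta = 0.05, delta_eq = 0)
  ci <- list(x = 50, y = 100, radius = 5)
  cj <- list(x = 59, y = 100, radius = 5)   # overlap 1 um
  f <- contact_force_over_eta(ci, cj, p, geom)
  expect_equal(f, c(-0.05 * 1, 0), tolerance = 1e-12)  # pushed away from j
  # attraction: 0.3-um gap within 0.5-um reach at 0.5e-8 m/s
  p2 <- mechanics_params(attr_over_eta = 0.5e-8, attr_distance = 0.5,
                         delta_eq = 0)
  cj2 <- list(x = 60.3, y = 100, radius = 5)
  f2 <- contact_force_over_eta(ci, cj2, p2, geom)
  expect_equal(f2, c(0.5e-2, 0), tolerance = 1e-12)    # pulled toward j
  # Newton's third law on random pairs
  set.seed(9)
  for (i in 1:20) {
    a <- list(x = runif(1, 0, geom$width), y = runif(1, 20, 280),
              radius = runif(1, 4, 7.5))
    b <- list(x = a$x + runif(1, -12, 12), y = a$y + runif(1, -12, 12),
              radius = runif(1, 4, 7.5))
    pp <- mechanics_params(attr_over_eta = 1e-8, attr_distance = 1)
    expect_equal(contact_force_over_eta(a, b, pp, geom),
                 -contact_force_over_eta(b, a, pp, geom), tolerance = 1e-12)
  }
})

test_that("an overlapping pair relaxes to the equilibrium overlap on the analytic curve", {
  k <- 0.02; deq <- 0.5; d0 <- 8.5   # overlap 1.5
  p <- mechanics_params(k_over_eta = k, delta_eq = deq, dt = 1)
  x <- c(100, 100 + d0); y <- c(150, 150)
  seps <- numeric(400)
  for (i in 1:400) {
    st <- mechanics_step(x, y, c(5, 5), p, geom)
    x <- st$x; y <- st$y
    seps[i] <- abs(x[2] - x[1])
  }
  overlap <- 10 - seps
  # closed form of the linear relaxation: delta(t) = deq + (1.5 - deq) e^{-2kt}
  t <- (1:400) * p$dt
  expect_equal(overlap, deq + (1.5 - deq) * exp(-2 * k * t), tolerance = 0.02)
  # monotone separation, converging to delta_eq
  expect_true(all(diff(seps) >= -1e-12))
  expect_equal(overlap[400], deq, tolerance = 1e-4)
})

test_that("halving dt halves the integration error (first-order consistency)", {
  k <- 0.02; deq <- 0; T <- 100
  run_dt <- function(dt) {
    p <- mechanics_params(k_over_eta = k, delta_eq = deq, dt = dt)
    x <- c(100, 108); y <- c(150, 150)
    for (i in seq_len(T / dt)) {
      st <- mechanics_step(x, y, c(5, 5), p, geom)
      x <- st$x; y <- st$y
    }
    abs(x[2] - x[1])
  }
  exact <- 10 - 2 * exp(-2 * k * T)
  e10 <- abs(run_dt(10) - exact)
  e5 <- abs(run_dt(5) - exact)
  expect_lt(e5, e10)
  expect_equal(e5 / e10, 0.5, tolerance = 0.2)
})

test_that("a perfectly packed lattice at equilibrium overlap does not move", {
  g <- geom
  sp <- g$effective_diameter
  grid <- expand.grid(i = 0:(g$n_circumference - 1), j = 0:(g$n_length - 1))
  x <- (grid$i + 0.5) * sp
  y <- 5 + grid$j * sp
  p <- mechanics_params(k_over_eta = 0.05, delta_eq = 0.5, dt = 10)
  st <- mechanics_step(x, y, rep(5, nrow(grid)), p, g)
  expect_equal(st$max_displacement, 0, tolerance = 1e-12)
})

test_that("movement constraints are honoured", {
  # lateral force with lateral migration disabled: no displacement
  p <- mechanics_params(k_over_eta = 0.05, delta_eq = 0,
                        lateral_migration = FALSE)
  st <- mechanics_step(c(100, 108), c(150, 150), c(5, 5), p, geom)
  expect_equal(st$x, c(100, 108))
  expect_equal(st$y, c(150, 150))
  # anchored cells do not move vertically
  p2 <- mechanics_params(k_over_eta = 0.05, delta_eq = 0)
  st2 <- mechanics_step(c(100, 100), c(150, 158), c(5, 5), p2, geom,
                        anchored = c(TRUE, FALSE))
  expect_equal(st2$y[1], 150)
  expect_gt(st2$y[2], 158)
  # base is impenetrable
  st3 <- mechanics_step(c(100, 100), c(6, 2), c(5, 5), p2, geom)
  expect_gte(min(st3$y), 0)
})

test_that("internal pair displacements cancel when no constraints act", {
  set.seed(21)
  n <- 12
  x <- runif(n, 80, 130); y <- runif(n, 120, 170); r <- runif(n, 4, 6)
  p <- mechanics_params(k_over_eta = 0.02, attr_over_eta = 1e-8,
                        attr_distance = 1, delta_eq = 0.5, dt = 1)
  st <- mechanics_step(x, y, r, p, geom)
  expect_equal(sum(st$x - x), 0, tolerance = 1e-9)
  expect_equal(sum(st$y - y), 0, tolerance = 1e-9)
})

test_that("the instability detector aborts with a diagnostic", {
  p <- mechanics_params(k_over_eta = 50, delta_eq = 0, dt = 10)
  expect_error(mechanics_step(c(100, 106), c(150, 150), c(5, 5), p, geom),
               "instability")
})
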