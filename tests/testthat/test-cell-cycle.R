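test_that("stochastic phase A is exponential with the configured mean", {
  set.seed(1)
  d <- sample_phase_a(2e4, 7, dt = 10)
  expect_equal(mean(d), 7, tolerance = 0.02)
  # distribution check against the exponential law (discretisation at 10 s
  # is far below the KS resolution at this n)
  ks <- suppressWarnings(stats::ks.test(d, stats::pexp, rate = 1 / 7))
  expect_gt(ks$p.value, 0.01)
  # the per-step rule is geometric with mean dt/(1 - exp(-dt/g1)); at the
  # 10-s step this is within 0.02% of the exponential mean, and even at a
  # coarse 1-h step it matches its own closed form
  set.seed(2)
  expect_equal(mean(sample_phase_a(2e4, 7, dt = 3600)),
               1 / (1 - exp(-1 / 7)), tolerance = 0.03)
})

test_that("deterministic phase bookkeeping walks S -> G2 -> M -> division", {
  p <- cycle_params("TA")
  cell <- list(phase = "S", clock = p$s - 0.1, radius = 6)
  cell <- advance_phase(cell, p, dt = 0.1)
  expect_equal(cell$phase, "G2")
  # total deterministic phase-B duration: S + G2 + M = 8.5 h for TA cells
  expect_equal(p$s + p$g2 + p$m, 8.5)
  cell <- list(phase = "S", clock = 0, radius = 6)
  hours <- 0; dt <- 0.1
  while (!isTRUE(cell$divide)) {
    cell <- advance_phase(cell, p, dt)
    hours <- hours + dt
  }
  expect_equal(hours, 8.5, tolerance = dt / 8.5 * 2)
})

test_that("the adapted (deterministic) cycle has zero phase-A variance", {
  p <- cycle_params("TA")
  lengths <- replicate(3, {
    cell <- list(phase = "A", clock = 0, radius = 6)
    t <- 0
    while (cell$phase == "A") {
      cell <- advance_phase(cell, p, dt = 0.05, deterministic = TRUE)
      t <- t + 0.05
    }
    t
  })
  expect_equal(var(lengths), 0)
  expect_equal(lengths[1], 7, tolerance = 0.05 / 7 * 2)
})

test_that("the minimum-size gate bars small cells from leaving G1", {
  p <- cycle_params("TA")
  cell <- list(phase = "A", clock = 100, radius = 3)  # clock long past g1
  for (i in 1:50)
    cell <- advance_phase(cell, p, dt = 1, r_min = 4.5, deterministic = TRUE)
  expect_equal(cell$phase, "A")
})

test_that("growth doubles the area over an average G1 + G2 and clamps", {
  p <- cycle_params("TA")
  cell <- list(phase = "A", clock = 0, radius = 5)
  # growth is linear in area, so one big step is exact
  g <- grow_cell(cell, p, dt = p$g1 + p$g2, r_max = 20)
  expect_equal(g$radius, sqrt(2) * 5, tolerance = 1e-12)
  # clamp at the maximum radius
  g <- grow_cell(list(phase = "G2", clock = 0, radius = 7.5), p, dt = 5)
  expect_equal(g$radius, 7.5)
  # no growth in S or G0
  for (ph in c("S", "M", "G0")) {
    g <- grow_cell(list(phase = ph, clock = 0, radius = 5), p, dt = 5)
    expect_equal(g$radius, 5)
  }
})

test_that("division conserves area and respects the orientation rule", {
  m <- list(x = 50, y = 100, radius = sqrt(2) * 5)
  d <- divide_cell(m, "vertical")
  expect_equal(d[[1]]$radius, 5)
  expect_equal(d[[2]]$radius, 5)
  expect_equal(d[[1]]$x, m$x)           # vertical: zero lateral component
  expect_equal(d[[2]]$x, m$x)
  expect_equal(abs(d[[1]]$y - d[[2]]$y), 2 * 5)  # daughters just touch
  set.seed(5)
  for (r in runif(20, 4, 7.5)) {
    d <- divide_cell(list(x = 0, y = 0, radius = r), "random")
    expect_equal(d[[1]]$radius^2 + d[[2]]$radius^2, r^2, tolerance = 1e-12)
    expect_equal(sqrt((d[[1]]$x - d[[2]]$x)^2 + (d[[1]]$y - d[[2]]$y)^2),
                 2 * d[[1]]$radius, tolerance = 1e-9)
  }
})

test_that("mean total TA cycle time matches the sum of phase means", {
  set.seed(3)
  p <- cycle_params("TA")
  total <- sample_phase_a(2e4, p$g1, dt = 10) + p$s + p$g2 + p$m
  expect_equal(mean(total), p$g1 + p$s + p$g2 + p$m, tolerance = 0.02)
})
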