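test_that("initialisation places one unsynchronised row at the base", {
  cfg <- crypt_config("niche")
  cfg$run$max_hours <- 0
  init <- suppressWarnings(run_crypt(cfg, seed = 1))
  expect_equal(nrow(init$state), 22L)
  expect_true(all(init$state$y == 5))
  expect_false(any(init$state$mature))
  expect_true(all(init$state$phase %in% c("A", "S", "G2", "M")))
  # unsynchronised: not everyone starts in the same phase
  expect_gt(length(unique(init$state$phase)), 1L)
  init2 <- suppressWarnings(run_crypt(cfg, seed = 1))
  expect_identical(init$state, init2$state)
  # pedigree variant: the founding row is stem and anchored
  cfgp <- crypt_config("pedigree")
  cfgp$run$max_hours <- 0
  initp <- suppressWarnings(run_crypt(cfgp, seed = 1))
  expect_true(all(initp$state$class == "stem"))
})

test_that("runs are bit-reproducible from (config, seed)", {
  cfg <- small_config("niche")
  a <- run_crypt(cfg, seed = 7)
  b <- run_crypt(cfg, seed = 7)
  expect_identical(a$series, b$series)
  expect_identical(a$state, b$state)
  expect_identical(a$onset, b$onset)
  c <- run_crypt(cfg, seed = 8)
  expect_false(identical(a$series, c$series))
})

test_that("hourly cell counts balance births against removals", {
  run <- run_crypt(small_config("niche"), seed = 3)
  s <- run$series
  expect_equal(diff(s$total), (s$births - s$exits)[-1])
  expect_true(all(s$total == s$proliferative + s$mature))
  expect_true(all(s$total >= 0 & s$exits >= 0 & s$births >= 0))
})

test_that("cells stay inside the crypt and within the size bounds", {
  run <- run_crypt(small_config("niche"), seed = 5,
                   snapshot_hours = c(40, 80))
  for (st in c(list(run$state), run$snapshots)) {
    expect_true(all(st$y >= 0))
    expect_true(all(st$y <= run$geometry$height))   # exited cells removed
    expect_true(all(st$radius <= run$config$cycle$r_max + 1e-9))
    expect_true(all(st$radius > 3))
  }
})

test_that("the steady-state detector reads a ramp-plateau series correctly", {
  # flat transient (hours 0-9), +20/h ramp to 622 at hour 39, then plateau.
  # The 12-h windowed gradient is 1.67 at hour 50 (window still straddles
  # the ramp) and exactly 0 at hour 51, so onset = ramp end + window = 51.
  n <- c(rep(22, 10), 22 + 20 * (1:30), rep(622, 40))
  expect_equal(detect_steady_state(n, hours = seq_along(n) - 1), 51)
  # strictly increasing: no steady state
  expect_true(is.na(detect_steady_state(22 + 5 * (0:100))))
  # never-growing series: the positive-gradient precondition is unmet
  expect_true(is.na(detect_steady_state(rep(22, 100))))
  # series shorter than the window
  expect_true(is.na(detect_steady_state(rep(22, 5))))
})

test_that("the engine's onset agrees with the offline detector", {
  run <- run_crypt(small_config("niche"), seed = 2)
  expect_equal(run$onset,
               detect_steady_state(run$series$total, run$series$hour,
                                   window = 12, tol = 0.5))
})

test_that("the calibrated niche crypt reaches steady state faster than the pedigree crypt", {
  on_n <- vapply(niche296_runs(), function(r) r$onset, 0)
  on_p <- vapply(pedigree13_runs(), function(r) r$onset, 0)
  expect_true(all(is.finite(on_n)) && all(is.finite(on_p)))
  expect_lt(median(on_n), median(on_p))
})
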