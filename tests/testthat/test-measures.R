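geom <- crypt_geometry()

test_that("single-cell order is the mature fraction of the contact set", {
  # hand-built flower: one centre cell with 6 touching neighbours
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  st <- toy_state(x = c(100, 100 + 9 * cos(ang)),
                  y = c(150, 150 + 9 * sin(ang)),
                  radius = 5,
                  mature = c(TRUE, rep(c(TRUE, FALSE), 3)))
  o <- cell_order(st, geom)
  expect_equal(o[1], 3 / 6)
  st$mature <- TRUE
  expect_equal(cell_order(st, geom)[1], 1)
  # isolated cell has order 1 by convention
  lone <- toy_state(x = c(10, 100), y = c(10, 250), mature = TRUE)
  expect_equal(cell_order(lone, geom), c(1, 1))
})

test_that("mature-cell order matches a brute-force recomputation", {
  set.seed(31)
  st <- random_state(120, geom, mature_p = 0.6)
  # independent oracle: all-pairs neighbour sets, direct averaging
  pairs <- brute_contacts(st$x, st$y, st$radius, geom, 0)
  oracle <- vapply(which(st$mature), function(i) {
    nb <- c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])
    if (!length(nb)) 1 else mean(st$mature[nb])
  }, 0)
  expect_equal(mature_cell_order(st, geom), mean(oracle))
  # two mature cells with only proliferative neighbours
  st2 <- toy_state(x = c(50, 59, 120, 129), y = rep(150, 4),
                   mature = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(mature_cell_order(st2, geom), 0)
  # no mature cells: undefined
  st2$mature <- FALSE
  expect_true(is.na(mature_cell_order(st2, geom)))
  # invariance under lateral rotation of the whole crypt
  st3 <- st
  st3$x <- wrap_lateral(st3$x + 77.7, geom)
  expect_equal(mature_cell_order(st3, geom), mature_cell_order(st, geom))
})

test_that("performance summary normalises against the reference crypt", {
  run <- run_crypt(small_config("niche"), seed = 6)
  tg <- crypt_targets(n_cells = 704, proliferative = 200)
  ps <- performance_summary(run, targets = tg)
  s <- run$series
  win <- s$hour > run$onset & s$hour <= run$onset + 24
  expect_equal(ps$n_cells, mean(s$total[win]))
  expect_equal(ps$production_rate, mean(s$exits[win]))
  expect_equal(ps$norm_n_cells, ps$n_cells / 704)
  expect_equal(ps$norm_mature_proportion,
               ps$mature_proportion / (504 / 704))
  expect_true(ps$mature_proportion >= 0 && ps$mature_proportion <= 1)
  # a run that never grew is flagged, not summarised
  cfg0 <- small_config("niche")
  cfg0$run$max_hours <- 5
  ps0 <- performance_summary(suppressWarnings(run_crypt(cfg0, seed = 1)))
  expect_false(ps0$steady)
  expect_true(is.na(ps0$n_cells))
})

test_that("LI profiles equal hand-computed bin proportions on a toy state", {
  g <- crypt_geometry(n_circumference = 4, n_length = 4, mean_radius = 5)
  rowh <- g$height / 4
  st <- toy_state(
    x = rep(5, 6),
    y = c(1, 2, rowh + 1, rowh + 2, rowh + 3, 3 * rowh + 1),
    label = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  p <- li_profile(st, g)
  expect_equal(p$proportion, c(1 / 2, 2 / 3, NA, 0))
  expect_equal(p$cells, c(2L, 3L, 0L, 1L))
  # relabelling cell ids does not change the profile
  st2 <- st[sample(nrow(st)), ]; st2$id <- seq_len(nrow(st2))
  expect_equal(li_profile(st2, g), p)
})

test_that("a simulated LI chase labels S-phase lineages only", {
  li <- simulate_li(small_config("niche"), replicates = 2, seed = 9)
  expect_equal(nrow(li$profile), 10)
  ok <- !is.na(li$profile$mean)
  expect_true(all(li$profile$mean[ok] >= 0 & li$profile$mean[ok] <= 1))
  # labelled cells exist near the base (the proliferative niche) and the
  # top rows, long past the niche, stay unlabelled after a 1-h chase
  expect_gt(mean(li$profile$mean[1:3], na.rm = TRUE), 0)
  expect_equal(li$profile$mean[10], 0, tolerance = 1e-12)
})

test_that("ribbon gaps count unmarked interlopers inside a clone column", {
  g <- crypt_geometry(n_circumference = 4, n_length = 8, mean_radius = 5)
  colw <- g$width / 4
  xc <- colw / 2
  # column L-U-L: one gap
  st <- toy_state(x = rep(xc, 3), y = c(10, 20, 30), clone = c(1L, 0L, 1L))
  expect_equal(ribbon_gap_statistic(st, g)$gaps, 1L)
  # contiguous ribbon: no gaps
  st2 <- toy_state(x = rep(xc, 3), y = c(10, 20, 30), clone = 1L)
  expect_equal(ribbon_gap_statistic(st2, g)$gaps, 0L)
  # unmarked cell outside the marked span does not count
  st3 <- toy_state(x = rep(xc, 3), y = c(10, 20, 30), clone = c(1L, 1L, 0L))
  expect_equal(ribbon_gap_statistic(st3, g)$gaps, 0L)
  # two clones scored independently
  st4 <- toy_state(x = c(xc, xc, xc + colw, xc + colw, xc + colw),
                   y = c(10, 20, 10, 20, 30),
                   clone = c(1L, 1L, 2L, 0L, 2L))
  gaps <- ribbon_gap_statistic(st4, g)
  expect_equal(gaps$gaps[gaps$clone == 1], 0L)
  expect_equal(gaps$gaps[gaps$clone == 2], 1L)
})

test_that("clone marks are heritable and label counts only grow", {
  run <- simulate_clones(small_config("niche"), seed = 12, n_clones = 2)
  expect_true(all(run$state$clone %in% 0:2))
  expect_gt(sum(run$state$clone > 0), 0)
})
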