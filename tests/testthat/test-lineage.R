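test_that("pedigree fate follows the differentiation hierarchy", {
  d <- pedigree_fate("stem")
  expect_equal(d[[1]]$class, "stem")
  expect_equal(d[[2]], list(class = "TA", generation = 1L))
  d <- pedigree_fate("TA", 2)
  expect_equal(d[[1]]$generation, 3L)
  expect_equal(d[[2]]$generation, 3L)
  d <- pedigree_fate("TA", 5, n_ta_generations = 5)
  expect_equal(d[[1]]$class, "mature")
  expect_equal(d[[2]]$class, "mature")
  expect_error(pedigree_fate("mature"), "never divide")
})

test_that("niche fate matures cells by position and scheme", {
  g <- crypt_geometry()
  cfgB <- lineage_config("niche", proliferation_region = 0.3,
                         only_new_cells_mature = FALSE)
  cfgA <- lineage_config("niche", proliferation_region = 0.3,
                         only_new_cells_mature = TRUE)
  # G1 cell above the boundary matures under scheme B
  expect_equal(niche_fate("A", 0.5 * g$height, g, cfgB), "G0")
  # an S-phase migrant continues its cycle under scheme A
  expect_equal(niche_fate("S", 0.5 * g$height, g, cfgA), "S")
  # ... and under scheme B (only G1 cells are arrested)
  expect_equal(niche_fate("S", 0.5 * g$height, g, cfgB), "S")
  # inside the niche region nothing matures
  expect_equal(niche_fate("A", 0.1 * g$height, g, cfgB), "A")
  # scheme A still matures daughters born outside the region
  expect_equal(niche_fate("A", 0.5 * g$height, g, cfgA, at_birth = TRUE), "G0")
  # irreversibility
  expect_equal(niche_fate("G0", 0, g, cfgB), "G0")
})

test_that("the position-PDF ramp is monotone with the documented anchors", {
  g <- crypt_geometry()
  cfg <- lineage_config("niche", proliferation_region = 0.3,
                        position_pdf = TRUE, pdf_half_width = 0.15)
  expect_equal(position_maturation_probability(0, g, cfg), 0)
  expect_equal(position_maturation_probability(g$height, g, cfg), 1)
  # midpoint of the linear ramp sits exactly on the boundary
  expect_equal(position_maturation_probability(0.3 * g$height, g, cfg), 0.5)
  ys <- seq(0, g$height, length.out = 200)
  p <- position_maturation_probability(ys, g, cfg)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("engine lineages respect hierarchy bounds and irreversibility", {
  # pedigree: anchored stems persist, TA generations stay within 1..5,
  # mature cells are exactly the descendants of the last generation
  runp <- run_crypt(small_config("pedigree"), seed = 4)
  expect_true(all(runp$series$stem == 6))
  ta <- runp$state[runp$state$class == "TA" & !runp$state$mature, ]
  expect_true(all(ta$generation >= 1 & ta$generation <= 5))
  expect_true(all(runp$state$generation[runp$state$mature] == 5))
  expect_false(any(runp$state$mature & runp$state$class == "stem"))

  # niche: once mature, always mature (tracked by cell id across snapshots)
  runn <- run_crypt(small_config("niche"), seed = 4,
                    snapshot_hours = c(60, 80))
  s1 <- runn$snapshots[["60"]]; s2 <- runn$snapshots[["80"]]
  common <- intersect(s1$id[s1$mature], s2$id)
  expect_true(all(s2$mature[match(common, s2$id)]))
})
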