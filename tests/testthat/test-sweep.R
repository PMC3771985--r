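test_that("parameter grids are complete Cartesian products in fixed order", {
  gp <- parameter_grid("pedigree")
  expect_equal(nrow(gp), 3 * 3 * 2 * 2 * 2)   # 72
  expect_equal(gp$run, seq_len(72))
  expect_equal(anyDuplicated(gp[, 1:5]), 0L)
  gn <- parameter_grid("niche")
  expect_equal(nrow(gn), 72 * 2 * 4)          # 576
  # deterministic ordering: regeneration is identical
  expect_identical(gn, parameter_grid("niche"))
  # single-value axes give a single config
  expect_equal(nrow(unique(gp[gp$attr_over_eta == 0 &
                                gp$attr_distance == 0 &
                                gp$active_migration &
                                gp$lateral_migration &
                                gp$vertical_division_only, ])), 1)
})

test_that("grid rows become complete runnable configurations", {
  gp <- parameter_grid("pedigree")
  cfgs <- enumerate_grid(gp[13:14, ])
  expect_length(cfgs, 2)
  expect_s3_class(cfgs[[1]], "crypt_config")
  expect_equal(cfgs[[1]]$mechanics$attr_over_eta, gp$attr_over_eta[13])
  expect_equal(cfgs[[1]]$cycle$vertical_division_only,
               gp$vertical_division_only[13])
  gn <- parameter_grid("niche")
  cfgn <- grid_config(gn[100, ])
  expect_equal(cfgn$lineage$proliferation_region,
               gn$proliferation_region[100])
  expect_error(enumerate_grid(parameter_grid("niche")[0, ]), "empty")
})

test_that("sequential gating filters and ranks like a hand-executed filter", {
  tbl <- data.frame(
    run = 1:6,
    norm_n_cells = c(1.005, 1.000, 1.03, 0.995, 1.002, 0.97),
    norm_production = c(1.00, 1.30, 1.05, 1.10, 1.02, 1.01),
    norm_mature_proportion = 1,
    mature_order = c(0.95, 0.99, 0.97, 0.92, 0.95, 0.93))
  gates <- gate_spec(
    list(measure = "norm_n_cells", lower = 0.99, upper = 1.01),
    list(measure = "norm_production", lower = 0.85, upper = 1.12),
    list(measure = "mature_order", lower = 0.90, upper = Inf))
  kept <- gate_runs(tbl, gates)
  # hand-executed: run 3 fails cells (1.03), run 6 fails cells (0.97),
  # run 2 fails production (1.30); survivors 1, 4, 5 ranked by
  # |production - 1|: 1 (0.00) < 5 (0.02) < 4 (0.10)
  expect_equal(kept$run, c(1, 5, 4))
  expect_equal(kept$rank, 1:3)
  # every survivor satisfies every gate (no leakage)
  for (g in gates)
    expect_true(all(kept[[g$measure]] >= g$lower &
                      kept[[g$measure]] <= g$upper))
  # gating is order-dependent: a permuted gate order with a binding first
  # gate reports itself when nothing survives
  tight <- gate_spec(list(measure = "norm_production", lower = 2, upper = 3))
  none <- gate_runs(tbl, tight)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "binding_gate"), "norm_production")
  # ties on production break toward higher mature order
  tie <- tbl[c(1, 1), ]; tie$run <- c(1, 2); tie$mature_order <- c(0.91, 0.99)
  expect_equal(gate_runs(tie, gates)$run[1], 2)
})

test_that("a miniature sweep runs end to end and is order-independent", {
  base <- small_config("niche")
  grid <- parameter_grid("niche")
  sub <- grid[grid$attr_over_eta == 0.5e-8 & grid$attr_distance == 0.5 &
                !grid$active_migration & grid$lateral_migration &
                grid$vertical_division_only &
                grid$proliferation_region %in% c(0.3, 0.5), ]
  res <- run_sweep(sub, base = base, replicates = 1, seed = 2)
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$norm_n_cells)))
  res_rev <- run_sweep(sub[rev(seq_len(nrow(sub))), ], base = base,
                       replicates = 1, seed = 2)
  expect_equal(res$norm_n_cells, rev(res_rev$norm_n_cells))
})
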