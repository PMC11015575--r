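test_that("morphology presets satisfy the qualitative orderings", {
  ram <- morphology_preset("ramified")
  hyp <- morphology_preset("hypertrophic")
  bsh <- morphology_preset("bushy")
  # ramified: small body, long thin processes
  expect_lt(ram$soma_radius, hyp$soma_radius)
  expect_lt(ram$soma_radius, bsh$soma_radius)
  expect_lt(ram$process_radius, hyp$process_radius)
  # bushy: big body, short processes
  expect_lt(bsh$process_length_mean, ram$process_length_mean)
  expect_lt(bsh$process_length_mean, hyp$process_length_mean)
  # hypertrophic: big body, long thick processes
  expect_gt(hyp$process_length_mean, bsh$process_length_mean)
  expect_gt(hyp$process_radius, ram$process_radius)
  expect_error(morphology_params("ramified", soma_radius = -1, n_processes = 1,
                                 process_length_mean = 5, process_length_sd = 1,
                                 process_radius = 0.5, branch_prob = 0))
})

test_that("generated ground truth preserves the preset orderings per cell", {
  feats <- lapply(c("ramified", "hypertrophic", "bushy"), function(cls) {
    cells <- simulate_cells(cls, 10, seed = 5)
    data.frame(
      soma = vapply(cells, function(c) c$record$soma_radius_um, 0),
      len = vapply(cells, function(c)
        c$record$total_process_length_um / c$record$n_processes, 0)
    )
  })
  names(feats) <- c("ramified", "hypertrophic", "bushy")
  # at least 95% of pairwise orderings hold
  expect_gte(mean(outer(feats$ramified$soma, feats$hypertrophic$soma, `<`)), 0.95)
  expect_gte(mean(outer(feats$bushy$len, feats$hypertrophic$len, `<`)), 0.95)
  expect_gte(mean(outer(feats$bushy$len, feats$ramified$len, `<`)), 0.95)
})

test_that("a sphere-only cell rasterises to its analytic volume", {
  params <- morphology_params("ramified", soma_radius = 3, n_processes = 0L,
                              process_length_mean = 0, process_length_sd = 0,
                              process_radius = 0.5, branch_prob = 0)
  sp <- c(0.3, 0.3, 0.3)   # >= 8 voxels per radius is not needed at r/h = 10
  g <- grow_cell(params, c(6, 6, 6), sp, c(41L, 41L, 41L))
  vox_vol <- sum(g$mask) * prod(sp)
  expect_equal(vox_vol, 4 / 3 * pi * 27, tolerance = 0.15)
  expect_identical(g$record$total_process_length_um, 0)
})

test_that("cell growth is deterministic under a fixed seed", {
  params <- morphology_preset("ramified")
  set.seed(123)
  g1 <- grow_cell(params, c(10, 20, 20), c(0.6, 0.4, 0.4), c(35L, 101L, 101L))
  set.seed(123)
  g2 <- grow_cell(params, c(10, 20, 20), c(0.6, 0.4, 0.4), c(35L, 101L, 101L))
  expect_identical(g1, g2)
  expect_error(grow_cell(params, c(-5, 0, 0), c(1, 1, 1), c(10L, 10L, 10L)),
               "outside")
})

test_that("identical configurations give bit-identical stacks", {
  # a small field has coarse punctum granularity: declare a matching tolerance
  cfg <- simulation_config(stack_shape = c(12L, 64L, 64L), seed = 77,
                           engulfed_tol = 0.1)
  set.seed(77); cfg <- populate_cells(cfg, n_cells = 2)
  s1 <- simulate_stack(cfg)
  s2 <- simulate_stack(cfg)
  expect_identical(rlang::hash(s1), rlang::hash(s2))
})

test_that("engulfed-fraction extremes produce the exact set relations", {
  base <- simulation_config(stack_shape = c(14L, 72L, 72L), seed = 31)
  set.seed(31); base <- populate_cells(base, n_cells = 2)

  cfg0 <- base; cfg0$engulfed_fraction <- 0
  s0 <- simulate_stack(cfg0)
  expect_identical(sum(s0$truth$th_mask & s0$truth$glial_mask), 0L)
  expect_identical(s0$truth$true_engulfed_fraction, 0)

  cfg1 <- base; cfg1$engulfed_fraction <- 1
  s1 <- simulate_stack(cfg1)
  expect_true(all(s1$truth$glial_mask[s1$truth$th_mask]))
  expect_identical(s1$truth$true_engulfed_fraction, 1)
})

test_that("the realised engulfed fraction hits the request within tolerance", {
  cfg <- simulation_config(engulfed_fraction = 0.30, seed = 9)
  set.seed(9); cfg <- populate_cells(cfg, n_cells = 3)
  s <- simulate_stack(cfg)
  expect_gte(s$truth$true_engulfed_fraction, 0.28)
  expect_lte(s$truth$true_engulfed_fraction, 0.32)
  # the stored fraction is recomputable from the masks
  expect_identical(s$truth$true_engulfed_fraction,
                   sum(s$truth$th_mask & s$truth$glial_mask) / sum(s$truth$th_mask))
})

test_that("engulfment without glia is refused", {
  cfg <- simulation_config(engulfed_fraction = 0.5, seed = 2, cells = list())
  expect_error(simulate_stack(cfg), "glial mask")
})

test_that("cohorts are reproducible from the master seed and validated", {
  template <- simulation_config(stack_shape = c(10L, 48L, 48L), engulfed_tol = 0.2)
  eff <- list(a = list(engulfed_fraction = 0.1), b = list(engulfed_fraction = 0.3))
  c1 <- make_cohort(template, 2, eff, n_cells = 1, seed = 42)
  c2 <- make_cohort(template, 2, eff, n_cells = 1, seed = 42)
  expect_identical(rlang::hash(c1), rlang::hash(c2))
  expect_identical(nrow(c1), 4L)
  expect_setequal(unique(c1$group), c("a", "b"))
  expect_error(make_cohort(template, 1, eff), "at least 2")
  expect_error(make_cohort(template, 2, list()), "at least one group")
  expect_error(make_cohort(template, 2, list(list(engulfed_fraction = 0.1))),
               "named")
})

test_that("every soma centre lies inside the glial mask", {
  cfg <- simulation_config(seed = 55)
  set.seed(55); cfg <- populate_cells(cfg, n_cells = 3)
  s <- simulate_stack(cfg)
  d <- cfg$stack_shape
  for (i in seq_len(nrow(s$truth$cells))) {
    vox <- round(c(s$truth$cells$centre_z_um[i], s$truth$cells$centre_y_um[i],
                   s$truth$cells$centre_x_um[i]) / cfg$spacing)
    expect_true(s$truth$glial_mask[vox[1] + 1, vox[2] + 1, vox[3] + 1])
  }
})
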