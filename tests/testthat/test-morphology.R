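test_that("soma centre of a sphere is its geometric centre", {
  sp <- c(0.5, 0.5, 0.5)
  ctr <- c(10, 10, 10) * sp
  m <- make_sphere_mask(c(21, 21, 21), sp, ctr, 4)
  soma <- locate_soma(m, sp)
  expect_lt(sqrt(sum((soma$centre_um - ctr)^2)), sqrt(sum(sp^2)))
  expect_equal(soma$soma_radius_um, 4, tolerance = 0.15)
  # soma volume close to the analytic sphere volume, never above the mask
  expect_equal(soma$soma_volume_um3, 4 / 3 * pi * 4^3, tolerance = 0.15)
  expect_lte(soma$soma_volume_um3, sum(m) * prod(sp))
})

test_that("degenerate masks are handled without crashing", {
  m <- array(FALSE, dim = c(3, 3, 3))
  expect_error(locate_soma(m, c(1, 1, 1)), "empty")
  m[1, 1, 1] <- TRUE; m[1, 1, 2] <- TRUE
  soma <- locate_soma(m, c(1, 1, 1))
  expect_true(is.finite(soma$soma_radius_um))
  met <- skeleton_metrics(m, soma, c(1, 1, 1))
  expect_true(is.finite(met$total_process_length_um))
})

test_that("a soma without processes has zero process metrics", {
  sp <- c(0.5, 0.3, 0.3)
  ctr <- c(12, 12, 12) * sp
  m <- make_sphere_mask(c(25, 41, 41), sp, ctr, 3)
  soma <- locate_soma(m, sp)
  met <- skeleton_metrics(m, soma, sp)
  expect_identical(met$total_process_length_um, 0)
  expect_identical(met$n_primary_processes, 0L)
  expect_identical(met$mean_process_radius_um, 0)
})

test_that("a single straight process is measured at its generated length", {
  # soma + one unbranched process of known length, grown by the simulator
  sp <- c(0.6, 0.4, 0.4)
  params <- morphology_params("ramified", soma_radius = 3, n_processes = 1L,
                              process_length_mean = 15, process_length_sd = 0,
                              process_radius = 0.5, branch_prob = 0,
                              z_flatten = 0.5)
  diag_um <- sqrt(sum(sp^2))
  withr::local_seed(21)
  for (rep in 1:5) {
    dim <- c(41L, 121L, 121L)
    ctr <- (dim - 1L) * sp / 2
    g <- grow_cell(params, ctr, sp, dim)
    soma <- locate_soma(g$mask, sp)
    met <- skeleton_metrics(g$mask, soma, sp)
    expect_identical(met$n_primary_processes, 1L)
    # generated centreline length vs skeleton measurement: the walk wiggles,
    # so allow the stated one-voxel-diagonal slack plus the soma-exit offset
    expect_lt(abs(met$total_process_length_um - g$record$total_process_length_um),
              2.5 * diag_um)
  }
})

test_that("process radius is recovered for tubes at least 2 voxels wide", {
  sp <- c(0.4, 0.4, 0.4)
  d <- c(15, 15, 61)
  ctr <- c(7, 7, 0) * sp
  m <- make_tube_mask(d, sp, ctr, c(0, 0, 1), 22, radius_um = 1.2)
  soma <- list(centre_um = ctr, soma_radius_um = 0.5,
               soma_mask = array(FALSE, dim = d))
  met <- skeleton_metrics(m, soma, sp)
  expect_equal(met$mean_process_radius_um, 1.2, tolerance = 0.4 / 1.2)
})

test_that("Sholl profile of a straight 20-um process is a unit step", {
  sp <- c(0.5, 0.25, 0.25)
  d <- c(11, 121, 41)
  ctr <- c(5 * 0.5, 10 * 0.25, 20 * 0.25)
  m <- make_tube_mask(d, sp, ctr, c(0, 1, 0), 20, 0.5)
  pr <- sholl_profile(m, ctr, sp, shell_step = 2, r_max = 26)
  expect_identical(pr$intersections[pr$radius_um <= 20], rep(1L, 10))
  expect_identical(pr$intersections[pr$radius_um > 20], rep(0L, 3))
  expect_true(all(diff(pr$radius_um) > 0))
})

test_that("Sholl profile of a soma alone is zero beyond the body", {
  sp <- c(0.5, 0.5, 0.5)
  ctr <- c(10, 10, 10) * sp
  m <- make_sphere_mask(c(21, 21, 21), sp, ctr, 3)
  pr <- sholl_profile(m, ctr, sp, shell_step = 2, r_max = 10)
  expect_true(all(pr$intersections[pr$radius_um > 3.5] == 0L))
  expect_error(sholl_profile(m, c(100, 100, 100), sp), "outside")
})

test_that("a once-branching tree yields the stepwise 1 to 2 profile", {
  sp <- c(0.5, 0.25, 0.25)
  d <- c(11, 121, 161)
  ctr <- c(5 * 0.5, 10 * 0.25, 80 * 0.25)
  fork <- ctr + c(0, 10, 0)
  dirA <- c(0, cos(pi / 6), sin(pi / 6))
  dirB <- c(0, cos(pi / 6), -sin(pi / 6))
  m <- make_tube_mask(d, sp, ctr, c(0, 1, 0), 10, 0.5) |
    make_tube_mask(d, sp, fork, dirA, 10, 0.5) |
    make_tube_mask(d, sp, fork, dirB, 10, 0.5)
  pr <- sholl_profile(m, ctr, sp, shell_step = 2, r_max = 18)
  expect_identical(pr$intersections[pr$radius_um <= 10], rep(1L, 5))
  expect_identical(pr$intersections[pr$radius_um > 10], rep(2L, 4))
})

test_that("classification rules apply in order with strict cuts", {
  th <- classifier_thresholds(soma_volume_cut = 100, process_length_cut = 50,
                              process_radius_cut = 1)
  expect_identical(classify_cell(50, 80, 0.5, th), "ramified")
  expect_identical(classify_cell(200, 80, 1.5, th), "hypertrophic")
  # big soma + short processes is bushy regardless of radius
  expect_identical(classify_cell(200, 20, 1.5, th), "bushy")
  expect_identical(classify_cell(200, 20, 0.2, th), "bushy")
  # features exactly at the cuts satisfy neither side
  expect_identical(classify_cell(100, 50, 1, th), "unclassified")
  # long thick processes on a small soma fit no definition
  expect_identical(classify_cell(50, 80, 1.5, th), "unclassified")
  expect_error(classifier_thresholds(soma_volume_cut = -1), "positive")
})

test_that("morphology counts are conserved", {
  expect_identical(sum(count_morphologies(data.frame(class_label = character(0)))$n), 0L)
  cells <- data.frame(class_label = c("ramified", "ramified", "bushy",
                                      "unclassified", "hypertrophic"))
  cnt <- count_morphologies(cells)
  expect_identical(sum(cnt$n), nrow(cells))
  expect_identical(cnt$n[cnt$class_label == "ramified"], 2L)
})

test_that("a known 5/3/2 morphology mixture is recovered by classification", {
  mix <- c(ramified = 5, hypertrophic = 3, bushy = 2)
  labels <- unlist(lapply(names(mix), function(cls) {
    cells <- simulate_cells(cls, mix[[cls]], seed = 300 + mix[[cls]])
    vapply(cells, function(cell) measure_cell(cell$mask, cell$spacing)$class_label, "")
  }))
  cnt <- count_morphologies(data.frame(class_label = labels))
  expect_identical(sum(cnt$n), 10L)
  for (cls in names(mix)) {
    expect_lte(abs(cnt$n[cnt$class_label == cls] - mix[[cls]]), 1)
  }
})

test_that("Sholl intersections just outside the soma count the primary processes", {
  # three straight processes at wide angles from one soma
  sp <- c(0.5, 0.3, 0.3)
  d <- c(31, 161, 161)
  ctr <- c(15 * 0.5, 80 * 0.3, 80 * 0.3)
  dirs <- list(c(0, 1, 0), c(0, -0.5, sqrt(3) / 2), c(0, -0.5, -sqrt(3) / 2))
  m <- make_sphere_mask(d, sp, ctr, 3)
  for (u in dirs) m <- m | make_tube_mask(d, sp, ctr + unlist(u) * 3, unlist(u), 15, 0.5)
  soma <- locate_soma(m, sp)
  met <- skeleton_metrics(m, soma, sp)
  expect_identical(met$n_primary_processes, 3L)
  pr <- sholl_profile(m, soma$centre_um, sp, shell_step = 1, r_max = 16)
  first_out <- which(pr$radius_um > soma$soma_radius_um + 1)[1]
  expect_identical(pr$intersections[first_out], 3L)
})

test_that("Sholl area under the profile grows with branching probability", {
  auc_for <- function(bp, seed) {
    params <- morphology_params("ramified", soma_radius = 3, n_processes = 4L,
                                process_length_mean = 15, process_length_sd = 1,
                                process_radius = 0.5, branch_prob = bp)
    set.seed(seed)
    aucs <- vapply(1:4, function(i) {
      dim <- c(41L, 141L, 141L)
      sp <- c(0.6, 0.4, 0.4)
      g <- grow_cell(params, (dim - 1L) * sp / 2, sp, dim)
      soma <- locate_soma(g$mask, sp)
      pr <- sholl_profile(g$mask, soma$centre_um, sp, shell_step = 2, r_max = 24)
      sum(pr$intersections) * 2
    }, 0)
    mean(aucs)
  }
  a0 <- auc_for(0, 17)
  a2 <- auc_for(0.2, 18)
  expect_gt(a2, a0)
})

test_that("per-particle morphometry flags border-touching cells", {
  sp <- c(0.5, 0.5, 0.5)
  d <- c(20, 30, 30)
  interior <- make_sphere_mask(d, sp, c(5, 7, 7), 2)
  border <- make_sphere_mask(d, sp, c(5, 14, 0.5), 2)
  seg <- extract_particles(interior | border, sp, min_size = 20)
  cells <- measure_cells(seg)
  expect_identical(nrow(cells), 2L)
  expect_identical(sum(cells$border_touching), 1L)
  expect_true(all(c("soma_volume_um3", "total_process_length_um",
                    "class_label", "sholl") %in% names(cells)))
})
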