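#' Parametric glial-cell morphology
#'
#' Parameters of the generative cell model: a spherical soma of radius
#' `soma_radius` plus `n_processes` tube-swept persistent random walks of
#' circular cross-section `process_radius`, each walking a total path length
#' drawn from `Normal(process_length_mean, process_length_sd)` (truncated at
#' 1 um) and branching into a child walker with per-step probability
#' `branch_prob`. Presets encode the three microglial activation morphologies
#' as used in the field: ramified (small body, long thin processes),
#' hypertrophic (big body, long thick processes) and bushy (big body, short
#' processes). No imaging protocol states numeric dimensions for these
#' classes; the preset values are package conventions chosen to be realistic
#' for cortical/striatal microglia and mutually orderable.
#'
#' @param class_label One of `"ramified"`, `"hypertrophic"`, `"bushy"`.
#' @param soma_radius um, > 0.
#' @param n_processes Integer >= 0.
#' @param process_length_mean,process_length_sd um.
#' @param process_radius um, > 0.
#' @param branch_prob Per-step branching probability in `[0, 1]`.
#' @param z_flatten Factor in `(0, 1]` shrinking the z component of process
#'   directions; mimics cells spread within a thin tissue section.
#' @return A `morphology_params` list.
#' @export
morphology_params <- function(class_label, soma_radius, n_processes,
                              process_length_mean, process_length_sd,
                              process_radius, branch_prob, z_flatten = 0.5) {
  class_label <- match.arg(class_label, MORPHOLOGY_CLASSES)
  stopifnot(soma_radius > 0, n_processes >= 0, process_length_mean >= 0,
            process_length_sd >= 0, process_radius > 0,
            branch_prob >= 0, branch_prob <= 1,
            z_flatten > 0, z_flatten <= 1)
  structure(
    list(class_label = class_label, soma_radius = soma_radius,
         n_processes = as.integer(n_processes),
         process_length_mean = process_length_mean,
         process_length_sd = process_length_sd,
         process_radius = process_radius, branch_prob = branch_prob,
         z_flatten = z_flatten),
    class = "morphology_params"
  )
}

#' @rdname morphology_params
#' @param jitter Relative jitter applied multiplicatively to the preset's
#'   soma radius, process length mean and process radius (uniform in
#'   `1 +/- jitter`); 0 returns the fixed preset.
#' @export
morphology_preset <- function(class_label = MORPHOLOGY_CLASSES, jitter = 0) {
  class_label <- match.arg(class_label)
  p <- switch(class_label,
    ramified = morphology_params("ramified", soma_radius = 3.0, n_processes = 5L,
                                 process_length_mean = 18, process_length_sd = 2.5,
                                 process_radius = 0.5, branch_prob = 0.06),
    hypertrophic = morphology_params("hypertrophic", soma_radius = 5.0, n_processes = 5L,
                                     process_length_mean = 16, process_length_sd = 2.5,
                                     process_radius = 1.3, branch_prob = 0.04),
    bushy = morphology_params("bushy", soma_radius = 5.5, n_processes = 6L,
                              process_length_mean = 5, process_length_sd = 1,
                              process_radius = 1.0, branch_prob = 0.02)
  )
  if (jitter > 0) {
    p$soma_radius <- p$soma_radius * stats::runif(1, 1 - jitter, 1 + jitter)
    p$process_length_mean <- p$process_length_mean * stats::runif(1, 1 - jitter, 1 + jitter)
    p$process_radius <- p$process_radius * stats::runif(1, 1 - jitter, 1 + jitter)
  }
  p
}

unit_vec <- function(v) v / sqrt(sum(v^2))

random_direction <- function(z_flatten = 1) {
  v <- stats::rnorm(3)
  v[1] <- v[1] * z_flatten
  unit_vec(v)
}

#' Grow one synthetic glial cell
#'
#' Rasterises a soma sphere and tube-swept branching random-walk processes
#' into a voxel grid, and records the analytic ground truth (soma volume,
#' summed centreline length, per-branch polylines). Processes start on the
#' soma surface; each step advances 1 um with the direction perturbed by a
#' Gaussian turn, and branching spawns a child walker that inherits the
#' remaining path length. Uses the current R random number stream.
#'
#' @param params A [morphology_params()].
#' @param centre_um Soma centre `(z, y, x)` in um; must lie inside the field.
#' @param spacing `(z, y, x)` voxel spacing in um.
#' @param dim Grid dimensions `(z, y, x)` in voxels.
#' @param step_um Walk step length (default 1 um).
#' @return List: `mask` (logical array), `record` (list with `class_label`,
#'   `centre_um`, `soma_volume_um3` analytic, `total_process_length_um`,
#'   `n_processes`, `polylines`).
#' @export
grow_cell <- function(params, centre_um, spacing, dim, step_um = 1) {
  stopifnot(inherits(params, "morphology_params"))
  spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  field_um <- (dim - 1L) * spacing
  if (any(centre_um < 0) || any(centre_um > field_um))
    abort("cell centre lies outside the field")

  mask <- array(FALSE, dim = dim)
  ctr <- matrix(centre_um, 1, 3)
  mask[cpp_ball_indices(dim, spacing, ctr, params$soma_radius)] <- TRUE

  total_len <- 0
  polylines <- list()
  sample_step <- min(spacing) / 2
  all_pts <- list(); npts <- 0L

  if (params$n_processes > 0) {
    # spread primary directions: reject directions closer than ~40 degrees
    # to an already placed process (up to 40 tries), as processes of real
    # cells radiate rather than bundle
    dirs <- list()
    for (p in seq_len(params$n_processes)) {
      for (try in 1:40) {
        cand <- random_direction(params$z_flatten)
        ok <- all(vapply(dirs, function(u) sum(u * cand) < cos(40 * pi / 180), TRUE))
        if (ok) break
      }
      dirs[[p]] <- cand
    }
    for (p in seq_len(params$n_processes)) {
      len <- max(1, stats::rnorm(1, params$process_length_mean, params$process_length_sd))
      dir0 <- dirs[[p]]
      walkers <- list(list(pos = centre_um + dir0 * params$soma_radius,
                           dir = dir0, remaining = len))
      while (length(walkers) > 0) {
        w <- walkers[[1]]; walkers <- walkers[-1]
        pts <- list(w$pos); k <- 1L
        pos <- w$pos; dir <- w$dir; remaining <- w$remaining
        while (remaining > 0) {
          adv <- min(step_um, remaining)
          newpos <- pos + dir * adv
          # centreline samples along the segment keep the tube connected
          nsub <- max(1L, ceiling(adv / sample_step))
          for (s in seq_len(nsub)) {
            k <- k + 1L
            pts[[k]] <- pos + dir * (adv * s / nsub)
          }
          total_len <- total_len + adv
          pos <- newpos
          remaining <- remaining - adv
          if (remaining > step_um && stats::runif(1) < params$branch_prob &&
              length(walkers) < 16L) {
            child_dir <- unit_vec(dir + 0.9 * stats::rnorm(3) * c(params$z_flatten, 1, 1))
            walkers[[length(walkers) + 1L]] <-
              list(pos = pos, dir = child_dir, remaining = remaining)
          }
          dir <- unit_vec(dir + 0.3 * stats::rnorm(3) * c(params$z_flatten, 1, 1))
        }
        pl <- do.call(rbind, pts)
        polylines[[length(polylines) + 1L]] <- pl
        all_pts[[length(all_pts) + 1L]] <- pl
      }
    }
    pts_mat <- do.call(rbind, all_pts)
    mask[cpp_ball_indices(dim, spacing, pts_mat, params$process_radius)] <- TRUE
  }

  list(
    mask = mask,
    record = list(
      class_label = params$class_label,
      centre_um = centre_um,
      soma_volume_um3 = 4 / 3 * pi * params$soma_radius^3,
      soma_radius_um = params$soma_radius,
      total_process_length_um = total_len,
      n_processes = params$n_processes,
      polylines = polylines
    )
  )
}

#' Simulation configuration for one synthetic confocal field
#'
#' Defines everything needed to render a two-channel (glial + TH) stack:
#' grid geometry, the cells to grow, the expected TH+ volume fraction of the
#' field, the fraction of TH+ volume to place inside glial masks, optics
#' (Gaussian PSF) and a photon-noise model. Two named spacing regimes mirror
#' common confocal objectives: `"coarse"` (20x-like, 1.0 x 0.5 x 0.5 um) and
#' `"fine"` (63x-like, 0.5 x 0.2 x 0.2 um); these are package conventions,
#' not values claimed from any acquisition protocol.
#'
#' @param stack_shape `(z, y, x)` voxels.
#' @param spacing `(z, y, x)` um, or `"coarse"` / `"fine"`.
#' @param cells List of `list(params = morphology_params, centre_um = c(z,y,x))`.
#' @param th_density Expected TH+ volume fraction of the field in `[0, 1)`.
#' @param engulfed_fraction Fraction of TH+ volume placed inside glial
#'   masks, in `[0, 1]`.
#' @param th_blob_radius Radius (um) of the spherical TH+ puncta emulating
#'   terminals/debris.
#' @param psf_sigma `(z, y, x)` Gaussian PSF sigma in um (>= 0).
#' @param noise_model `"poisson"` (photon noise at `gain`, plus additive
#'   Gaussian read noise `read_sd`) or `"gaussian"` (`read_sd` only).
#' @param gain,read_sd Noise parameters.
#' @param bg,amplitude Background and foreground mean intensities (counts).
#' @param glial_role Channel role of the glial channel.
#' @param engulfed_tol Tolerance on the realised engulfed fraction.
#' @param clearance Minimum distance (um) between non-engulfed TH puncta and
#'   the glial mask.
#' @param seed Integer seed; identical configurations give bit-identical
#'   stacks.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(stack_shape = c(20L, 96L, 96L),
                              spacing = "coarse",
                              cells = list(),
                              th_density = 0.01,
                              engulfed_fraction = 0.3,
                              th_blob_radius = 1.25,
                              psf_sigma = c(0.7, 0.25, 0.25),
                              noise_model = c("poisson", "gaussian"),
                              gain = 1, read_sd = 3,
                              bg = 20, amplitude = 180,
                              glial_role = "GLIA_IBA1",
                              engulfed_tol = 0.02,
                              clearance = 1.0,
                              seed = 1L) {
  if (is.character(spacing))
    spacing <- switch(match.arg(spacing, c("coarse", "fine")),
                      coarse = c(1.0, 0.5, 0.5), fine = c(0.5, 0.2, 0.2))
  noise_model <- match.arg(noise_model)
  stopifnot(th_density >= 0, th_density < 1,
            engulfed_fraction >= 0, engulfed_fraction <= 1,
            all(psf_sigma >= 0), gain > 0, read_sd >= 0,
            glial_role %in% GLIAL_ROLES)
  structure(
    list(stack_shape = as.integer(stack_shape), spacing = as.numeric(spacing),
         cells = cells, th_density = th_density,
         engulfed_fraction = engulfed_fraction,
         th_blob_radius = th_blob_radius, psf_sigma = as.numeric(psf_sigma),
         noise_model = noise_model, gain = gain, read_sd = read_sd,
         bg = bg, amplitude = amplitude, glial_role = glial_role,
         engulfed_tol = engulfed_tol, clearance = clearance,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default mixed-morphology cell layout for a field
#'
#' Places `n_cells` somas on jittered positions inside the field margins,
#' drawing each cell's class from `mixture`.
#'
#' @param config A [simulation_config()] (its `cells` are ignored).
#' @param n_cells Number of cells.
#' @param mixture Named probability vector over the three classes.
#' @param jitter Relative preset jitter (see [morphology_preset()]).
#' @return The config with `cells` filled in. Uses the current RNG stream.
#' @export
populate_cells <- function(config, n_cells = 3L,
                           mixture = c(ramified = 0.2, hypertrophic = 0.5, bushy = 0.3),
                           jitter = 0.08) {
  mixture <- mixture / sum(mixture)
  field_um <- (config$stack_shape - 1L) * config$spacing
  margin <- 7
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cls <- sample(names(mixture), 1, prob = mixture)
    params <- morphology_preset(cls, jitter = jitter)
    centre <- c(
      field_um[1] / 2 + stats::runif(1, -1, 1),
      stats::runif(1, margin, field_um[2] - margin),
      stats::runif(1, margin, field_um[3] - margin)
    )
    cells[[i]] <- list(params = params, centre_um = centre)
  }
  config$cells <- cells
  config
}

apply_noise <- function(img, config) {
  n <- length(img)
  noisy <- if (config$noise_model == "poisson") {
    stats::rpois(n, lambda = pmax(img, 0) * config$gain) / config$gain +
      stats::rnorm(n, 0, config$read_sd)
  } else {
    img + stats::rnorm(n, 0, config$read_sd)
  }
  as.integer(pmin(pmax(round(noisy), 0), 65535))
}

#' Render a synthetic two-channel confocal stack with ground truth
#'
#' Grows all configured cells into a glial mask, places spherical TH+
#' puncta so that the realised fraction of TH+ volume inside glia matches
#' `engulfed_fraction` (engulfed puncta are clipped to the glial mask —
#' engulfed material sits inside the cell; free puncta keep a clearance from
#' it), converts both masks to intensities, applies the Gaussian PSF and the
#' noise model, and returns the calibrated stack together with the pre-blur,
#' pre-noise ground truth. Placement steers the running engulfed fraction
#' punctum by punctum, so the realised value sits within `engulfed_tol` of
#' the request whenever the geometry allows it.
#'
#' @param config A [simulation_config()] with at least one cell when
#'   `engulfed_fraction > 0`.
#' @return List with `stack` (an [image_stack()]: channel 1 TH, channel 2
#'   glial) and `truth` (list: `glial_mask`, `th_mask`, `cells` tibble,
#'   `true_engulfed_fraction`).
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  d <- config$stack_shape
  sp <- config$spacing

  glia <- array(FALSE, dim = d)
  records <- list()
  for (cell in config$cells) {
    g <- grow_cell(cell$params, cell$centre_um, sp, d)
    glia <- glia | g$mask
    records[[length(records) + 1L]] <- g$record
  }

  if (config$engulfed_fraction > 0 && config$th_density > 0 && !any(glia))
    abort("engulfed_fraction > 0 requires a non-empty glial mask")

  th <- array(FALSE, dim = d)
  n_target <- round(config$th_density * prod(d))
  if (n_target > 0) {
    r <- config$th_blob_radius
    # deep glial voxels keep engulfed puncta mostly interior; clear voxels
    # keep free puncta away from glia even after blur
    edt_glia <- if (any(glia)) cpp_edt3d(as.vector(glia), d, sp, FALSE) else NULL
    inside_pool <- if (any(glia)) which(glia & edt_glia >= 0.8 * r) else integer(0)
    if (length(inside_pool) == 0 && any(glia)) inside_pool <- which(glia)
    dist_to_glia <- cpp_edt3d(as.vector(!glia), d, sp, FALSE)
    outside_pool <- which(!glia & dist_to_glia >= r + config$clearance)
    if (config$engulfed_fraction < 1 && length(outside_pool) == 0)
      abort("field too small: no room for TH puncta outside the glial mask")

    vox_of <- function(i) c((i - 1L) %% d[1],
                            ((i - 1L) %/% d[1]) %% d[2],
                            (i - 1L) %/% (d[1] * d[2]))
    th_in <- 0; th_tot <- 0; guard <- 0L
    # steer the engulfed voxel count towards its final target; half a
    # nominal punctum of head-room avoids overshooting by a whole punctum
    b_est <- 4 / 3 * pi * r^3 / prod(sp)
    while (th_tot < n_target && guard < 10L * n_target) {
      guard <- guard + 1L
      want_in <- config$engulfed_fraction >= 1 ||
        (config$engulfed_fraction > 0 &&
           th_in + b_est / 2 < config$engulfed_fraction * n_target)
      pool <- if (want_in) inside_pool else outside_pool
      ctr <- vox_of(pool[sample.int(length(pool), 1L)]) * sp
      idx <- cpp_ball_indices(d, sp, matrix(ctr, 1, 3), r)
      if (want_in) idx <- idx[glia[idx]]
      new <- idx[!th[idx]]
      if (length(new) == 0) next
      th[new] <- TRUE
      th_in <- th_in + sum(glia[new])
      th_tot <- th_tot + length(new)
    }
    realised <- if (th_tot > 0) th_in / th_tot else 0
    if (abs(realised - config$engulfed_fraction) > config$engulfed_tol)
      warn(sprintf("realised engulfed fraction %.3f misses request %.3f by more than %.3f",
                   realised, config$engulfed_fraction, config$engulfed_tol))
  }

  true_frac <- if (sum(th) > 0) sum(th & glia) / sum(th) else 0

  render <- function(mask) {
    img <- config$bg + (config$amplitude - config$bg) * as.numeric(mask)
    img <- cpp_gauss_blur3(img, d, config$psf_sigma / sp)
    apply_noise(img, config)
  }
  vox <- array(0L, dim = c(2L, d))
  vox[1, , , ] <- render(th)
  vox[2, , , ] <- render(glia)
  stack <- image_stack(vox, spacing = sp, channel_roles = c("TH", config$glial_role))

  cells_tbl <- if (length(records)) {
    dplyr::bind_rows(lapply(records, function(rec) tibble(
      class_label = rec$class_label,
      centre_z_um = rec$centre_um[1], centre_y_um = rec$centre_um[2],
      centre_x_um = rec$centre_um[3],
      soma_volume_um3 = rec$soma_volume_um3,
      soma_radius_um = rec$soma_radius_um,
      total_process_length_um = rec$total_process_length_um,
      n_processes = rec$n_processes
    )))
  } else {
    tibble()
  }

  list(
    stack = stack,
    truth = list(glial_mask = glia, th_mask = th, cells = cells_tbl,
                 polylines = lapply(records, `[[`, "polylines"),
                 true_engulfed_fraction = true_frac)
  )
}

#' Simulate a multi-animal cohort
#'
#' Generates `n_per_group` independent fields per experimental group, each
#' with its own seed derived from the master seed, applying per-group
#' engulfed fractions and morphology mixtures. One field stands for one
#' animal — the statistical unit downstream.
#'
#' @param template A [simulation_config()] used for geometry/optics/noise.
#' @param n_per_group Animals per group (>= 2).
#' @param group_effects Named list: one entry per group, each a list with
#'   optional `engulfed_fraction` and `mixture` (passed to
#'   [populate_cells()]).
#' @param n_cells Cells per field.
#' @param seed Master seed; the full cohort is reproducible from it.
#' @return Tibble with columns `group`, `animal`, `seed`, and list columns
#'   `stack` and `truth`.
#' @export
make_cohort <- function(template, n_per_group, group_effects, n_cells = 3L,
                        seed = 1L) {
  stopifnot(inherits(template, "simulation_config"))
  if (n_per_group < 2) abort("`n_per_group` must be at least 2")
  if (length(group_effects) == 0) abort("`group_effects` must name at least one group")
  if (is.null(names(group_effects)) || any(!nzchar(names(group_effects))))
    abort("`group_effects` must be a named list")
  set.seed(seed)
  total <- length(group_effects) * n_per_group
  seeds <- sample.int(.Machine$integer.max, total)
  rows <- list()
  k <- 0L
  for (g in names(group_effects)) {
    eff <- group_effects[[g]]
    for (a in seq_len(n_per_group)) {
      k <- k + 1L
      cfg <- template
      cfg$seed <- seeds[k]
      if (!is.null(eff$engulfed_fraction)) cfg$engulfed_fraction <- eff$engulfed_fraction
      set.seed(seeds[k])
      cfg <- populate_cells(cfg, n_cells = n_cells,
                            mixture = eff$mixture %||%
                              c(ramified = 0.2, hypertrophic = 0.5, bushy = 0.3))
      sim <- simulate_stack(cfg)
      rows[[k]] <- tibble(group = g, animal = a, seed = seeds[k],
                          stack = list(sim$stack), truth = list(sim$truth))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate standalone cells of one morphology preset
#'
#' Grows `n` cells of a preset, each in its own tight grid sized from the
#' preset's dimensions — the fixture generator for morphometry and
#' classification experiments.
#'
#' @param class_label Preset name.
#' @param n Number of cells.
#' @param spacing `(z, y, x)` um (default `c(0.6, 0.4, 0.4)`).
#' @param jitter Preset jitter (see [morphology_preset()]).
#' @param seed Seed for the whole batch.
#' @return List of `list(mask, record, spacing)`.
#' @export
simulate_cells <- function(class_label, n, spacing = c(0.6, 0.4, 0.4),
                           jitter = 0.08, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    params <- morphology_preset(class_label, jitter = jitter)
    reach_xy <- params$soma_radius + params$process_length_mean +
      4 * params$process_length_sd + 4
    reach_z <- params$soma_radius + params$z_flatten *
      (params$process_length_mean + 4 * params$process_length_sd) + 4
    dim <- as.integer(ceiling(2 * c(reach_z, reach_xy, reach_xy) / spacing)) + 1L
    centre <- (dim - 1L) * spacing / 2
    g <- grow_cell(params, centre, spacing, dim)
    list(mask = g$mask, record = g$record, spacing = spacing)
  })
}
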