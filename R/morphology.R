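# coordinates (0-based voxel indices, n x 3) of TRUE voxels in a 3-D mask
mask_coords <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  cbind(
    z = (idx - 1L) %% d[1],
    y = ((idx - 1L) %/% d[1]) %% d[2],
    x = (idx - 1L) %/% (d[1] * d[2])
  )
}

half_diagonal <- function(spacing) sqrt(sum(spacing^2)) / 2

#' Locate the soma of a single cell mask
#'
#' The soma centre is the global maximum of the Euclidean distance transform
#' of the cell mask (the deepest interior point; the grid boundary counts as
#' background so border-clipped masks are not inflated). Ties are broken by
#' the lowest `(z, y, x)` coordinate. The soma is the ball of radius equal to
#' that maximal distance around the centre, intersected with the cell — for
#' a spherical cell body this recovers the whole body, while processes
#' (thinner than the body by construction of the morphology vocabulary)
#' stay outside.
#'
#' @param cell_mask Logical 3-D array containing one connected cell.
#' @param spacing `(z, y, x)` voxel spacing in um.
#' @return List: `centre_um` (z, y, x), `centre_vox` (0-based), `soma_mask`,
#'   `soma_volume_um3`, `soma_radius_um` (the maximal interior distance).
#' @export
locate_soma <- function(cell_mask, spacing) {
  if (!is.logical(cell_mask)) abort("`cell_mask` must be logical")
  if (!any(cell_mask)) abort("empty cell mask")
  spacing <- as.numeric(spacing)
  d <- dim(cell_mask)
  edt <- cpp_edt3d(as.vector(cell_mask), as.integer(d), spacing, TRUE)
  mx <- max(edt)
  cand <- which(edt == mx)
  co <- cbind(
    (cand - 1L) %% d[1],
    ((cand - 1L) %/% d[1]) %% d[2],
    (cand - 1L) %/% (d[1] * d[2])
  )
  best <- cand[order(co[, 1], co[, 2], co[, 3])[1]]
  cz <- (best - 1L) %% d[1]
  cy <- ((best - 1L) %/% d[1]) %% d[2]
  cx <- (best - 1L) %/% (d[1] * d[2])
  centre_um <- c(cz, cy, cx) * spacing

  co_all <- mask_coords(cell_mask)
  dist2 <- (co_all[, 1] * spacing[1] - centre_um[1])^2 +
    (co_all[, 2] * spacing[2] - centre_um[2])^2 +
    (co_all[, 3] * spacing[3] - centre_um[3])^2
  soma_mask <- array(FALSE, dim = d)
  inside <- which(cell_mask)[dist2 <= mx^2]
  soma_mask[inside] <- TRUE
  list(
    centre_um = centre_um,
    centre_vox = c(cz, cy, cx),
    soma_mask = soma_mask,
    soma_volume_um3 = sum(soma_mask) * prod(spacing),
    soma_radius_um = mx
  )
}

# ordered polyline chains of a skeleton voxel set; returns list of index
# vectors (rows of coords) covering every edge of the skeleton graph
skeleton_chains <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(list())
  edges <- cpp_adjacency_coords(coords)
  if (nrow(edges) == 0) return(lapply(seq_len(n), function(i) i))
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  chains <- list()
  nodes <- which(deg != 2L)
  walk <- function(start, nb) {
    path <- c(start, nb)
    prev <- start; cur <- nb
    assign(ekey(start, nb), TRUE, envir = used)
    while (deg[cur] == 2L) {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      if (exists(ekey(cur, nxt), envir = used)) break
      assign(ekey(cur, nxt), TRUE, envir = used)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  for (s in nodes) {
    for (nb in adj[[s]]) {
      if (!exists(ekey(s, nb), envir = used))
        chains[[length(chains) + 1L]] <- walk(s, nb)
    }
  }
  # pure cycles (all degree 2)
  for (s in seq_len(n)) {
    if (deg[s] == 2L) {
      for (nb in adj[[s]]) {
        if (!exists(ekey(s, nb), envir = used))
          chains[[length(chains) + 1L]] <- walk(s, nb)
      }
    }
  }
  chains
}

# physical length of an ordered chain, resampled with stride 3 voxels to
# suppress digital staircase overestimation
chain_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  take <- unique(c(seq(1L, n, by = 3L), n))
  p <- pts[take, , drop = FALSE]
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# union-find component ids for a voxel coordinate set (26-connectivity)
coord_components <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- cpp_adjacency_coords(coords)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Skeleton-based process metrics of one cell
#'
#' Thins the whole cell mask to a 3D curve skeleton (curve thinning that
#' preserves 26-connectivity and endpoints), discards skeleton voxels inside
#' the soma ball — what remains traces the processes — and measures: total
#' process length (sum of skeleton chain lengths under the physical voxel
#' metric, chains resampled with a 3-voxel stride to suppress digital
#' staircase bias), the number of primary processes (skeleton components
#' reaching the soma surface), and the mean process radius (mean
#' distance-to-background of the cell mask sampled along the skeleton).
#' Short leaf spurs (< `prune_um`) attached to a longer structure are
#' pruned as thinning artefacts of thick, uneven tubes; an isolated short
#' chain — a genuinely short process — is never pruned.
#'
#' @param cell_mask Logical 3-D array for one cell.
#' @param soma Result of [locate_soma()] on the same mask.
#' @param spacing `(z, y, x)` spacing in um.
#' @param prune_um Leaf spurs shorter than this are dropped (default 3 um).
#' @return List: `total_process_length_um`, `n_primary_processes`,
#'   `mean_process_radius_um`, `skeleton_coords` (0-based voxel matrix of
#'   the kept skeleton).
#' @export
skeleton_metrics <- function(cell_mask, soma, spacing, prune_um = 3) {
  spacing <- as.numeric(spacing)
  d <- dim(cell_mask)
  empty <- list(total_process_length_um = 0, n_primary_processes = 0L,
                mean_process_radius_um = 0,
                skeleton_coords = matrix(integer(0), 0, 3))
  if (!any(cell_mask)) return(empty)

  skel <- array(cpp_skeletonize3(as.vector(cell_mask), as.integer(d)), dim = d)
  co <- mask_coords(skel)
  if (nrow(co) == 0) return(empty)
  pts_um <- sweep(co, 2, spacing, `*`)
  dc <- sqrt(colSums((t(pts_um) - soma$centre_um)^2))
  outside <- dc > soma$soma_radius_um
  co <- co[outside, , drop = FALSE]
  pts_um <- pts_um[outside, , drop = FALSE]
  dc <- dc[outside]
  if (nrow(co) == 0) return(empty)

  edges <- cpp_adjacency_coords(co)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(co))
  band <- soma$soma_radius_um + 2 * max(spacing)
  chains <- skeleton_chains(co)
  chain_lens <- vapply(chains, function(ch) chain_length(pts_um[ch, , drop = FALSE]), 0)
  is_leaf <- vapply(chains, function(ch) {
    deg[ch[1]] <= 1L || deg[ch[length(ch)]] <= 1L
  }, TRUE)
  attached <- vapply(chains, function(ch) {
    max(deg[ch[1]], deg[ch[length(ch)]]) > 2L
  }, TRUE)
  # chains reaching the soma surface are process roots, not spurs
  is_root <- vapply(chains, function(ch) {
    min(dc[ch[1]], dc[ch[length(ch)]]) <= band
  }, TRUE)
  drop <- is_leaf & attached & !is_root & chain_lens < prune_um
  kept <- chains[!drop]
  total_len <- sum(chain_lens[!drop])
  if (length(kept) == 0) return(empty)

  kept_idx <- sort(unique(unlist(kept)))
  co_k <- co[kept_idx, , drop = FALSE]
  dc_k <- dc[kept_idx]

  comp <- coord_components(co_k)
  # clipping the soma ball can leave skeleton crumbs hugging its surface;
  # a component that never leaves the surface band is not a process
  crumb_comp <- setdiff(unique(comp), unique(comp[dc_k > band]))
  if (length(crumb_comp)) {
    crumb_rows <- comp %in% crumb_comp
    crumb_set <- kept_idx[crumb_rows]
    keep_chain <- vapply(kept, function(ch) !all(ch %in% crumb_set), TRUE)
    total_len <- sum(vapply(kept[keep_chain], function(ch)
      chain_length(pts_um[ch, , drop = FALSE]), 0))
    kept <- kept[keep_chain]
    if (length(kept) == 0) return(empty)
    co_k <- co_k[!crumb_rows, , drop = FALSE]
    dc_k <- dc_k[!crumb_rows]
    comp <- comp[!crumb_rows]
  }
  n_primary <- length(unique(comp[dc_k <= band]))

  edt_cell <- cpp_edt3d(as.vector(cell_mask), as.integer(d), spacing, TRUE)
  lin_idx <- co_k[, 1] + d[1] * (co_k[, 2] + d[2] * co_k[, 3]) + 1L
  mean_radius <- mean(edt_cell[lin_idx])

  list(
    total_process_length_um = total_len,
    n_primary_processes = n_primary,
    mean_process_radius_um = mean_radius,
    skeleton_coords = co_k
  )
}

#' 3D Sholl profile of a cell
#'
#' Counts, for concentric spherical shells of increasing radius around the
#' soma centre, the number of distinct structures crossing each shell:
#' connected components (26-connectivity) of cell voxels whose physical
#' distance to the centre lies within half a voxel diagonal of the shell
#' radius. By default the thresholded cell mask itself is probed (the
#' behaviour of Sholl analysis on segmented images); `on = "skeleton"`
#' probes the thinned skeleton instead.
#'
#' @param cell_mask Logical 3-D array.
#' @param centre_um Shell centre `(z, y, x)` in um (typically
#'   `locate_soma()$centre_um`).
#' @param spacing `(z, y, x)` spacing in um.
#' @param shell_step Shell spacing in um (default 2).
#' @param r_max Largest shell radius in um; defaults to the distance of the
#'   farthest cell voxel plus one step.
#' @param on `"mask"` (default) or `"skeleton"`.
#' @return Tibble with `radius_um` (strictly increasing) and `intersections`.
#' @export
sholl_profile <- function(cell_mask, centre_um, spacing, shell_step = 2,
                          r_max = NULL, on = c("mask", "skeleton")) {
  on <- match.arg(on)
  if (shell_step <= 0) abort("`shell_step` must be positive")
  spacing <- as.numeric(spacing)
  d <- dim(cell_mask)
  ctr_vox <- centre_um / spacing
  if (any(ctr_vox < -0.5) || any(ctr_vox > d - 0.5))
    abort("`centre_um` lies outside the grid")
  if (on == "skeleton") {
    target <- array(cpp_skeletonize3(as.vector(cell_mask), as.integer(d)), dim = d)
  } else {
    target <- cell_mask
  }
  co <- mask_coords(target)
  dist <- sqrt((co[, 1] * spacing[1] - centre_um[1])^2 +
                 (co[, 2] * spacing[2] - centre_um[2])^2 +
                 (co[, 3] * spacing[3] - centre_um[3])^2)
  if (is.null(r_max)) r_max <- if (length(dist)) max(dist) + shell_step else shell_step
  radii <- seq(shell_step, r_max, by = shell_step)
  h <- half_diagonal(spacing)
  ints <- vapply(radii, function(r) {
    sel <- abs(dist - r) <= h
    if (!any(sel)) return(0L)
    cpp_count_components_coords(co[sel, , drop = FALSE])
  }, integer(1))
  tibble(radius_um = radii, intersections = ints)
}

#' Decision thresholds for the three-way morphology classifier
#'
#' Numeric boundaries that turn the qualitative morphology vocabulary
#' (small vs big cell body, short vs long and thin vs thick processes) into
#' reproducible rules. The defaults were calibrated on the bundled simulator
#' presets and are package conventions, not values taken from any imaging
#' protocol; all comparisons against the cuts are strict, so a feature
#' sitting exactly on a cut satisfies neither side.
#'
#' @param soma_volume_cut um^3 separating small from big cell bodies.
#' @param process_length_cut um of total process length separating short
#'   from long.
#' @param process_radius_cut um of mean process radius separating thin from
#'   thick.
#' @return A `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(soma_volume_cut = 250,
                                  process_length_cut = 60,
                                  process_radius_cut = 0.8) {
  if (soma_volume_cut <= 0 || process_length_cut <= 0 || process_radius_cut <= 0)
    abort("all classifier cuts must be positive")
  structure(
    list(soma_volume_cut = soma_volume_cut,
         process_length_cut = process_length_cut,
         process_radius_cut = process_radius_cut),
    class = "classifier_thresholds"
  )
}

#' Classify a cell into ramified / hypertrophic / bushy
#'
#' Encodes the morphology vocabulary as ordered decision rules: a small
#' body with long thin processes is ramified; a big body with long thick
#' processes is hypertrophic; a big body with short processes is bushy
#' whatever their thickness; anything else (including features exactly on a
#' cut) is unclassified.
#'
#' @param soma_volume_um3,total_process_length_um,mean_process_radius_um
#'   Cell features (vectorised).
#' @param thresholds A [classifier_thresholds()].
#' @return Character vector of class labels.
#' @export
classify_cell <- function(soma_volume_um3, total_process_length_um,
                          mean_process_radius_um,
                          thresholds = classifier_thresholds()) {
  small <- soma_volume_um3 < thresholds$soma_volume_cut
  big <- soma_volume_um3 > thresholds$soma_volume_cut
  long <- total_process_length_um > thresholds$process_length_cut
  short <- total_process_length_um < thresholds$process_length_cut
  thin <- mean_process_radius_um < thresholds$process_radius_cut
  thick <- mean_process_radius_um > thresholds$process_radius_cut
  out <- rep("unclassified", length(soma_volume_um3))
  out[small & long & thin] <- "ramified"
  out[big & long & thick] <- "hypertrophic"
  out[big & short] <- "bushy"
  out
}

#' Full morphometry of a single cell mask
#'
#' @param cell_mask Logical 3-D array holding one cell.
#' @param spacing `(z, y, x)` spacing in um.
#' @param thresholds A [classifier_thresholds()].
#' @param shell_step,r_max Passed to [sholl_profile()].
#' @param cell_id Identifier stored in the output row.
#' @return One-row tibble: soma centre and size, process metrics, the Sholl
#'   profile as a nested list column, and `class_label`.
#' @export
measure_cell <- function(cell_mask, spacing, thresholds = classifier_thresholds(),
                         shell_step = 2, r_max = NULL, cell_id = 1L) {
  soma <- locate_soma(cell_mask, spacing)
  met <- skeleton_metrics(cell_mask, soma, spacing)
  sh <- sholl_profile(cell_mask, soma$centre_um, spacing,
                      shell_step = shell_step, r_max = r_max)
  tibble(
    cell_id = cell_id,
    soma_z_um = soma$centre_um[1],
    soma_y_um = soma$centre_um[2],
    soma_x_um = soma$centre_um[3],
    soma_radius_um = soma$soma_radius_um,
    soma_volume_um3 = soma$soma_volume_um3,
    n_primary_processes = met$n_primary_processes,
    total_process_length_um = met$total_process_length_um,
    mean_process_radius_um = met$mean_process_radius_um,
    sholl = list(sh),
    class_label = classify_cell(soma$soma_volume_um3,
                                met$total_process_length_um,
                                met$mean_process_radius_um, thresholds)
  )
}

#' Morphometry of every glial particle in a segmentation
#'
#' Runs [measure_cell()] on each size-filtered particle of a glial
#' segmentation result, treating each particle as one cell. Particles
#' touching the field border are measured but flagged (`border_touching`),
#' since their clipped masks under-report soma and process metrics;
#' touching cells are not split.
#'
#' @param seg A `segmentation_result` for a glial channel.
#' @param thresholds,shell_step,r_max Passed on to [measure_cell()].
#' @return Tibble with one row per particle plus a `border_touching` flag.
#' @export
measure_cells <- function(seg, thresholds = classifier_thresholds(),
                          shell_step = 2, r_max = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  d <- dim(seg$labels)
  rows <- lapply(seg$particles$particle, function(p) {
    idx <- which(seg$labels == p)
    z <- (idx - 1L) %% d[1]; y <- ((idx - 1L) %/% d[1]) %% d[2]
    x <- (idx - 1L) %/% (d[1] * d[2])
    border <- any(z == 0L | z == d[1] - 1L | y == 0L | y == d[2] - 1L |
                    x == 0L | x == d[3] - 1L)
    # one-voxel padded bounding box
    zr <- range(z); yr <- range(y); xr <- range(x)
    dz <- zr[2] - zr[1] + 3L; dy <- yr[2] - yr[1] + 3L; dx <- xr[2] - xr[1] + 3L
    sub <- array(FALSE, dim = c(dz, dy, dx))
    sub[cbind(z - zr[1] + 2L, y - yr[1] + 2L, x - xr[1] + 2L)] <- TRUE
    row <- measure_cell(sub, seg$spacing, thresholds = thresholds,
                        shell_step = shell_step, r_max = r_max, cell_id = p)
    # shift soma centre back to field coordinates
    row$soma_z_um <- row$soma_z_um + (zr[1] - 1L) * seg$spacing[1]
    row$soma_y_um <- row$soma_y_um + (yr[1] - 1L) * seg$spacing[2]
    row$soma_x_um <- row$soma_x_um + (xr[1] - 1L) * seg$spacing[3]
    row$border_touching <- border
    row
  })
  dplyr::bind_rows(rows)
}

#' Count cells per morphology class
#'
#' @param cells Tibble from [measure_cells()] (or any data frame with a
#'   `class_label` column).
#' @return Tibble with one row per class (`ramified`, `hypertrophic`,
#'   `bushy`, `unclassified`) and the count `n`; counts sum to `nrow(cells)`.
#' @export
count_morphologies <- function(cells) {
  lv <- c(MORPHOLOGY_CLASSES, "unclassified")
  tab <- table(factor(cells$class_label, levels = lv))
  tibble(class_label = lv, n = as.integer(tab))
}
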