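#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance on a binned histogram of the full 3D
#' channel — the parameter-free default used when no fixed threshold is
#' supplied. Returns the bin-upper-edge threshold; voxels strictly above it
#' are foreground.
#'
#' @param x Numeric vector (or array) of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2])
    abort("constant-intensity input: Otsu threshold is undefined (use a fixed threshold)")
  width <- diff(rng) / n_bins
  bins <- pmin(floor((x - rng[1]) / width), n_bins - 1L) + 1L
  h <- tabulate(bins, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centres <- rng[1] + (seq_len(n_bins) - 0.5) * width
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b2)
  rng[1] + k * width
}

#' Threshold one channel of a stack
#'
#' @param stack An [image_stack()].
#' @param role Channel role to threshold.
#' @param method `"otsu"` (computed on the channel's full 3D histogram) or
#'   `"fixed"` with `value`.
#' @param value Fixed threshold, required when `method = "fixed"`.
#' @return List with `mask` (logical 3-D array: intensity strictly above the
#'   threshold) and `threshold` used.
#' @export
threshold_channel <- function(stack, role, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  chan <- get_channel(stack, role)
  thr <- switch(method,
    otsu = otsu_threshold(chan),
    fixed = {
      if (is.null(value)) abort("`value` required for a fixed threshold")
      as.numeric(value)
    }
  )
  mask <- array(chan > thr, dim = dim(chan))
  list(mask = mask, threshold = thr, method = method)
}

#' Label 3D particles and apply the minimum-size filter
#'
#' Connected components of a binary mask under 6- or 26-connectivity;
#' components whose voxel count is not strictly greater than `min_size` are
#' discarded. The default `min_size = 20` encodes the particle definition
#' "size larger than 20 pixels": a 20-voxel blob is dropped, a 21-voxel blob
#' kept. Volumes are voxel counts times the voxel volume from `spacing`.
#'
#' @param mask Logical 3-D array `(z, y, x)`.
#' @param spacing `(z, y, x)` voxel spacing in um.
#' @param min_size Voxel-count cutoff; particles must exceed it strictly.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return A `segmentation_result`: list with `mask` (filtered), `labels`
#'   (integer 3-D array, 0 = background, particle ids dense from 1),
#'   `particles` (tibble: `particle`, `n_voxels`, `volume_um3`, centroid in
#'   um), `total_volume_um3`, and the parameters used.
#' @export
extract_particles <- function(mask, spacing, min_size = 20L, connectivity = 26L) {
  if (!is.logical(mask)) {
    if (is.numeric(mask) && all(mask %in% c(0, 1))) {
      mask <- array(mask == 1, dim = dim(mask))
    } else {
      abort("`mask` must be logical (binary)")
    }
  }
  if (length(dim(mask)) != 3L) abort("`mask` must be a 3-D array")
  spacing <- as.numeric(spacing)
  d <- dim(mask)
  raw_labels <- cpp_label3d(as.vector(mask), as.integer(d), as.integer(connectivity))
  n_raw <- attr(raw_labels, "n_components")
  counts <- if (n_raw > 0) tabulate(raw_labels[raw_labels > 0L], nbins = n_raw) else integer(0)
  keep <- which(counts > min_size)
  remap <- integer(n_raw)
  remap[keep] <- seq_along(keep)
  labels <- array(0L, dim = d)
  pos <- raw_labels > 0L
  labels[pos] <- remap[raw_labels[pos]]
  fmask <- labels > 0L

  vv <- prod(spacing)
  if (length(keep)) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    z <- (idx - 1L) %% d[1]
    y <- ((idx - 1L) %/% d[1]) %% d[2]
    x <- (idx - 1L) %/% (d[1] * d[2])
    nvox <- counts[keep]
    particles <- tibble(
      particle = seq_along(keep),
      n_voxels = nvox,
      volume_um3 = nvox * vv,
      centroid_z_um = as.numeric(tapply(z * spacing[1], lab, mean)),
      centroid_y_um = as.numeric(tapply(y * spacing[2], lab, mean)),
      centroid_x_um = as.numeric(tapply(x * spacing[3], lab, mean))
    )
  } else {
    particles <- tibble(
      particle = integer(0), n_voxels = integer(0), volume_um3 = numeric(0),
      centroid_z_um = numeric(0), centroid_y_um = numeric(0), centroid_x_um = numeric(0)
    )
  }
  structure(
    list(
      mask = fmask, labels = labels, particles = particles,
      total_volume_um3 = sum(particles$volume_um3),
      spacing = spacing, min_size = as.integer(min_size),
      connectivity = as.integer(connectivity), threshold = NA_real_,
      threshold_method = NA_character_, channel_role = NA_character_
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> role %s: %d particle(s) > %d voxels, total %.1f um^3 (threshold %s)\n",
    x$channel_role, nrow(x$particles), x$min_size, x$total_volume_um3,
    if (is.na(x$threshold)) "-" else format(x$threshold)
  ))
  invisible(x)
}

#' Segment every configured channel of a stack
#'
#' Thresholds each requested channel (Otsu by default), labels 3D particles
#' and applies the minimum-size filter, returning one `segmentation_result`
#' per role with full parameter provenance.
#'
#' @param stack An [image_stack()].
#' @param roles Channel roles to segment; defaults to every non-`OTHER`
#'   channel present.
#' @param min_size,connectivity Passed to [extract_particles()].
#' @param method,value Passed to [threshold_channel()].
#' @return Named list of `segmentation_result` objects, class
#'   `segmentation_set`.
#' @export
segment_stack <- function(stack, roles = NULL, min_size = 20L, connectivity = 26L,
                          method = c("otsu", "fixed"), value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  roles <- roles %||% setdiff(unique(stack$channel_roles), "OTHER")
  missing <- setdiff(roles, stack$channel_roles)
  if (length(missing))
    abort(sprintf("stack has no channel(s) with role: %s", paste(missing, collapse = ", ")))
  out <- lapply(roles, function(role) {
    thr <- tryCatch(
      threshold_channel(stack, role, method = method, value = value),
      error = function(e) {
        # constant channel: nothing above background
        list(mask = array(FALSE, dim = dim(stack$voxels)[-1]),
             threshold = NA_real_, method = method)
      }
    )
    res <- extract_particles(thr$mask, stack$spacing,
                             min_size = min_size, connectivity = connectivity)
    res$threshold <- thr$threshold
    res$threshold_method <- thr$method
    res$channel_role <- role
    res
  })
  names(out) <- roles
  structure(out, class = "segmentation_set")
}

#' Per-particle table of a segmentation
#'
#' @param x A `segmentation_result` or `segmentation_set`.
#' @param ... Unused.
#' @return A tibble of particles (with a `channel_role` column for sets).
#' @export
tidy.segmentation_result <- function(x, ...) {
  dplyr::mutate(x$particles, channel_role = x$channel_role, .before = 1)
}

#' @rdname tidy.segmentation_result
#' @export
tidy.segmentation_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy.segmentation_result))
}
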