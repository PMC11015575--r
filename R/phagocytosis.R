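#' Volume shared by two binary masks
#'
#' @param mask_a,mask_b Logical 3-D arrays of identical shape.
#' @param spacing `(z, y, x)` voxel spacing in um.
#' @return Overlap volume in um^3.
#' @export
overlap_volume <- function(mask_a, mask_b, spacing) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort("masks must have identical shapes")
  sum(mask_a & mask_b) * prod(as.numeric(spacing))
}

#' Quantify TH engulfment inside a glial mask
#'
#' The phagocytosis readout: volume of TH+ signal, volume of the glial
#' (Iba1+ or GFAP+) signal, their shared volume, and the percentage of TH+
#' volume lying inside the glial mask. All volumes come from the
#' size-filtered particle masks, so signal is what the particle definition
#' retains. The percentage is defined as 0 when no TH+ signal survives the
#' filter (flagged in the result).
#'
#' @param seg A `segmentation_set` from [segment_stack()] containing a `TH`
#'   result and at least one glial result.
#' @param glial_role `"GLIA_IBA1"` or `"GLIA_GFAP"`; defaults to whichever
#'   glial role is present (error if ambiguous).
#' @param denominator `"th"` (default; percentage of TH+ volume that is
#'   inside glia — the readout reported per field) or `"glia"` (percentage of
#'   the glial volume occupied by TH+ signal).
#' @return One-row tibble with columns `glial_role`, `th_volume_um3`,
#'   `glial_volume_um3`, `overlap_volume_um3`, `percent_th_in_glia`,
#'   `th_empty`; segmentation provenance is attached as attribute
#'   `"provenance"`.
#' @export
quantify_phagocytosis <- function(seg, glial_role = NULL,
                                  denominator = c("th", "glia")) {
  stopifnot(inherits(seg, "segmentation_set"))
  denominator <- match.arg(denominator)
  if (!"TH" %in% names(seg)) abort("segmentation set has no TH result")
  if (is.null(glial_role)) {
    present <- intersect(GLIAL_ROLES, names(seg))
    if (length(present) != 1L)
      abort("specify `glial_role`: set contains ", length(present), " glial results")
    glial_role <- present
  }
  if (!glial_role %in% names(seg))
    abort(sprintf("segmentation set has no '%s' result", glial_role))

  th <- seg[["TH"]]
  gl <- seg[[glial_role]]
  ov <- overlap_volume(th$mask, gl$mask, th$spacing)
  denom_vol <- if (denominator == "th") th$total_volume_um3 else gl$total_volume_um3
  pct <- if (denom_vol > 0) 100 * ov / denom_vol else 0

  out <- tibble(
    glial_role = glial_role,
    th_volume_um3 = th$total_volume_um3,
    glial_volume_um3 = gl$total_volume_um3,
    overlap_volume_um3 = ov,
    percent_th_in_glia = pct,
    th_empty = th$total_volume_um3 == 0
  )
  attr(out, "provenance") <- list(
    denominator = denominator,
    min_size = th$min_size, connectivity = th$connectivity,
    th_threshold = th$threshold, glial_threshold = gl$threshold,
    threshold_method = th$threshold_method
  )
  out
}

#' Astrogliosis readout: total GFAP+ volume
#'
#' Convenience accessor for the reactive-astrocyte measure: the total
#' size-filtered GFAP+ particle volume of a field, typically compared
#' against the mean GFAP+ volume of control animals.
#'
#' @param seg A `segmentation_set` containing a `GLIA_GFAP` result.
#' @param glial_role Glial role to read (default `"GLIA_GFAP"`).
#' @return Total volume in um^3.
#' @export
astrogliosis_volume <- function(seg, glial_role = "GLIA_GFAP") {
  stopifnot(inherits(seg, "segmentation_set"))
  if (!glial_role %in% names(seg))
    abort(sprintf("segmentation set has no '%s' result", glial_role))
  seg[[glial_role]]$total_volume_um3
}

#' Run the full per-stack phagocytosis pipeline
#'
#' Segments a calibrated stack and quantifies TH engulfment in one call;
#' the per-field row this returns is the unit that gets averaged per animal
#' before group statistics.
#'
#' @param stack An [image_stack()] with a TH channel and a glial channel.
#' @param glial_role Glial role to use; default auto-detects.
#' @inheritParams segment_stack
#' @return One-row tibble as [quantify_phagocytosis()].
#' @export
measure_stack <- function(stack, glial_role = NULL, min_size = 20L,
                          connectivity = 26L, method = "otsu", value = NULL) {
  roles <- intersect(c("TH", GLIAL_ROLES), stack$channel_roles)
  seg <- segment_stack(stack, roles = roles, min_size = min_size,
                       connectivity = connectivity, method = method, value = value)
  quantify_phagocytosis(seg, glial_role = glial_role)
}
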