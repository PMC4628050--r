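#' Flag the pectoral-muscle region
#'
#' In mediolateral-oblique mammograms the pectoral muscle appears as a
#' bright wedge in one top corner and is a standard confounder for mass
#' detection. The region containing the designated top-corner pixel is
#' flagged when its mean intensity exceeds the global image mean; with
#' `side = "auto"` the top corner whose containing region has the higher
#' mean intensity is used.
#'
#' @param seg a `mammo_seg` from [segment()].
#' @param img the [gray_image] that was segmented.
#' @param side `"left"`, `"right"`, or `"auto"`.
#' @return The flagged region id, or `NULL` when neither corner region
#'   is brighter than the image average.
#' @export
flag_pectoral <- function(seg, img, side = c("auto", "left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(seg, "mammo_seg"))
  px <- if (is_gray_image(img)) img$pixels else img
  w <- ncol(seg$labels)
  rt <- seg$region_table
  mean_of <- function(id) rt$mean_intensity[rt$id == id]
  left_id <- seg$labels[1L, 1L]
  right_id <- seg$labels[1L, w]
  cand <- switch(side,
    left = left_id,
    right = right_id,
    auto = if (mean_of(left_id) >= mean_of(right_id)) left_id else right_id)
  if (mean_of(cand) > mean(px)) cand else NULL
}

#' Extract the mass region of interest
#'
#' Selects and delineates the suspected mass from a segmentation, in two
#' stages.
#'
#' *Detection* uses the supplied segmentation: candidate seed regions
#' are those with `min_area <= size <= max_area_frac * n_pixels` that do
#' not touch the image border and are not the pectoral region, and the
#' candidate with the highest mean intensity seeds the ROI. Its peak
#' intensity is estimated as the upper decile of the seed's own pixels.
#' The surrounding-tissue level is found by walking the
#' region-adjacency graph downhill from the seed (always into the
#' brightest neighbor) until a large "context" region -- the first
#' neighbor covering at least `context_frac` of the image, normally the
#' breast tissue -- is reached; its mean intensity is the surround
#' level.
#'
#' *Delineation* localizes the mass boundary at half-maximum, the
#' standard convention for mass extent: the cut level is halfway between
#' the seed's peak and the surround level. Because the scale-`k` merge
#' criterion intentionally produces regions too coarse to place this
#' boundary precisely, the boundary is resolved on the finest partition
#' the merge criterion defines -- its `k_scale = 0` limit (connected
#' components of constant intensity, agglomerated to the minimum region
#' size). The ROI is the connected union (on that fine partition's
#' adjacency graph) of fine regions with mean intensity at or above the
#' cut level, grown from the fine region holding the seed's brightest
#' pixel; fine regions lying mostly inside the pectoral region are
#' never included. The mask is therefore always a union of whole
#' regions of the delineation partition.
#'
#' @param seg a `mammo_seg` from [segment()].
#' @param img the [gray_image] that was segmented.
#' @param min_area minimum candidate size in pixels.
#' @param max_area_frac maximum candidate size as a fraction of the
#'   image.
#' @param pectoral_label region id to exclude (from [flag_pectoral()]),
#'   or `NULL`.
#' @param context_frac fraction of the image a neighbor must cover to be
#'   treated as surrounding tissue.
#' @return A logical mask, the same shape as the image. When no
#'   candidate region exists the mask is empty and a warning is issued.
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   masses = list(c(70, 60, 6, 120)), noise_sigma = 0))
#' seg <- segment(ph$image)
#' roi <- extract_roi(seg, ph$image,
#'                    pectoral_label = flag_pectoral(seg, ph$image))
#' sum(roi)
#' @export
extract_roi <- function(seg, img, min_area = 16L, max_area_frac = 0.25,
                        pectoral_label = NULL, context_frac = 0.05) {
  stopifnot(inherits(seg, "mammo_seg"))
  px <- if (is_gray_image(img)) img$pixels else img
  rt <- seg$region_table
  n <- length(seg$labels)
  empty <- matrix(FALSE, nrow(seg$labels), ncol(seg$labels))

  # ---- detection on the supplied segmentation -------------------------------
  adj <- region_adjacency(seg$labels)
  neighbors <- function(ids) {
    hit <- adj[, 1] %in% ids | adj[, 2] %in% ids
    setdiff(unique(as.vector(adj[hit, , drop = FALSE])), ids)
  }
  mean_of <- function(id) rt$mean_intensity[match(id, rt$id)]
  size_of <- function(id) rt$size[match(id, rt$id)]

  cand <- rt$size >= min_area & rt$size <= max_area_frac * n &
    !rt$touches_border
  pect_zone <- integer(0)
  if (!is.null(pectoral_label)) {
    # the muscle often shatters into a chain of fragments under noise;
    # exclude the whole structure connected to the flagged corner region
    # at near-muscle intensity. The brightness band is two-sided: darker
    # neighbors are surrounding tissue, and markedly brighter neighbors
    # are not muscle (a mass core outshines the muscle), so neither can
    # be swallowed into the zone.
    pm <- mean_of(pectoral_label)
    pect_zone <- pectoral_label
    repeat {
      nb <- neighbors(pect_zone)
      add <- nb[mean_of(nb) >= 0.85 * pm & mean_of(nb) <= 1.12 * pm]
      if (length(add) == 0L) break
      pect_zone <- c(pect_zone, add)
    }
    cand <- cand & !(rt$id %in% pect_zone)
  }
  if (!any(cand)) {
    warning("no candidate ROI region", call. = FALSE)
    return(empty)
  }
  cand_rt <- rt[cand, , drop = FALSE]
  seed <- cand_rt$id[which.max(cand_rt$mean_intensity)]

  # peak estimate: upper decile of the seed region's own pixels, robust
  # to noise spikes
  seed_idx <- which(seg$labels == seed)
  seed_px <- as.numeric(px[seed_idx])
  peak <- stats::quantile(seed_px, 0.9, names = FALSE)

  walked <- seed
  surround <- NA_real_
  for (step in seq_len(nrow(rt))) {
    nb <- setdiff(neighbors(walked), pect_zone)
    if (length(nb) == 0L) break
    best <- nb[which.max(mean_of(nb))]
    if (size_of(best) >= context_frac * n) {
      surround <- mean_of(best)
      break
    }
    walked <- c(walked, best)
  }
  if (is.na(surround)) surround <- mean(px) # fallback: global mean

  # ---- delineation on the zero-scale fine partition -------------------------
  fine <- segment(img, connectivity = seg$connectivity,
                  mode = seg$weight_mode, k_scale = 0,
                  min_size = seg$min_size)
  frt <- fine$region_table
  fine_seed <- fine$labels[seed_idx[which.max(seed_px)]]
  pect_cells <- integer(0)
  pect_px <- NULL
  if (!is.null(pectoral_label)) {
    # fine cells lying mostly inside the flagged muscle region are off
    # limits (the rest of the zone is only barred from seeding: a mass
    # shoulder reaching toward the muscle may still belong to the ROI)
    pect_px <- seg$labels == pectoral_label
    pect_frac <- as.vector(rowsum(as.numeric(pect_px),
                                  as.vector(fine$labels))) / frt$size
    pect_cells <- frt$id[pect_frac > 0.5]
  }
  fadj <- region_adjacency(fine$labels)
  grow <- function(half) {
    keep <- setdiff(frt$id[frt$mean_intensity >= half], pect_cells)
    keep <- union(keep, fine_seed)
    sub <- fadj[fadj[, 1] %in% keep & fadj[, 2] %in% keep, , drop = FALSE]
    comp <- fine_seed
    repeat {
      hit <- sub[, 1] %in% comp | sub[, 2] %in% comp
      add <- setdiff(unique(as.vector(sub[hit, , drop = FALSE])), comp)
      if (length(add) == 0L) break
      comp <- c(comp, add)
    }
    matrix(fine$labels %in% comp, nrow(seg$labels), ncol(seg$labels))
  }
  # cut at half-maximum, then refine the surround estimate from an
  # annulus around the current ROI, one to two ROI radii out -- past the
  # mass's own shoulder but still local. This corrects the rare case
  # where the context walk lands on a structure darker than the tissue
  # actually surrounding the mass.
  half <- (peak + surround) / 2
  roi <- grow(half)
  for (iter in 1:3) {
    r_roi <- max(2L, as.integer(ceiling(sqrt(sum(roi) / pi))))
    inner <- dilate_mask(roi, r_roi)
    ring <- dilate_mask(inner, r_roi) & !inner
    if (!is.null(pect_px)) ring <- ring & !pect_px
    if (!any(ring)) break
    surround_new <- stats::median(as.numeric(px[ring]))
    half_new <- (peak + max(surround, surround_new)) / 2
    if (abs(half_new - half) <= 0.5) break
    half <- half_new
    roi <- grow(half)
  }
  if (sum(roi) > max_area_frac * n)
    warning("ROI exceeds max_area_frac of the image", call. = FALSE)
  roi
}

# Binary dilation by r steps of the 8-neighborhood (chessboard ball).
dilate_mask <- function(mask, r = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  for (step in seq_len(r)) {
    padded <- matrix(FALSE, h + 2L, w + 2L)
    padded[2:(h + 1L), 2:(w + 1L)] <- mask
    out <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    }
    mask <- out
  }
  mask
}

#' Run the full segmentation pipeline on one image
#'
#' Convenience wrapper: [segment()], [flag_pectoral()] and
#' [extract_roi()] in sequence, returning everything a caller usually
#' wants.
#'
#' @inheritParams segment
#' @param pectoral `"auto"`, `"left"`, `"right"` or `"off"`.
#' @param min_area,max_area_frac passed to [extract_roi()].
#' @return A list: `segmentation` (`mammo_seg`), `roi_mask` (logical
#'   matrix), `pectoral_label` (region id or `NULL`).
#' @export
segment_mammogram <- function(img, connectivity = 8L,
                              mode = c("intensity", "spatial_literal"),
                              k_scale = NULL, min_size = NULL,
                              pectoral = c("auto", "left", "right", "off"),
                              min_area = 16L, max_area_frac = 0.25) {
  mode <- match.arg(mode)
  pectoral <- match.arg(pectoral)
  img <- as_gray_image(img)
  seg <- segment(img, connectivity, mode, k_scale, min_size)
  pect <- if (pectoral == "off") NULL else flag_pectoral(seg, img, pectoral)
  roi <- extract_roi(seg, img, min_area, max_area_frac,
                     pectoral_label = pect)
  list(segmentation = seg, roi_mask = roi, pectoral_label = pect)
}
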