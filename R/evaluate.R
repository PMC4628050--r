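#' Full evaluation report for a segmentation
#'
#' Computes every evaluation quantity the package provides for a
#' (predicted mask, ground-truth mask) pair: pixel-level confusion
#' statistics (sensitivity, specificity, PPV, NPV, accuracy),
#' region-overlap measures (IoU, Dice, the overlap-acceptance test at
#' threshold `k`), the mean local refinement errors in both directions,
#' and the boundary F-measure from bipartite edgel matching. When the
#' underlying image is supplied, intensity-based measures are added:
#' ROC AUC of intensity as a mass score, target-to-background contrast,
#' NSD/ENL over the border strip, and the fuzziness measures of the
#' image's membership plane. When an enhanced version of the image is
#' supplied as well, MSE/PSNR between the two are included.
#'
#' @param pred,truth logical masks of the same shape.
#' @param image optional [gray_image] the masks refer to.
#' @param enhanced optional enhanced [gray_image] (for MSE/PSNR).
#' @param k region-overlap acceptance threshold (default 0.75).
#' @param d_max edgel admissibility radius in pixels (default 2).
#' @return A list of class `mammo_report`.
#' @export
evaluate_segmentation <- function(pred, truth, image = NULL,
                                  enhanced = NULL, k = 0.75, d_max = 2) {
  shape_check(pred, truth)
  cs <- suppressWarnings(confusion_stats(confusion_counts(pred, truth)))
  iou <- region_iou(pred, truth)
  dice <- region_dice(pred, truth)
  accepted <- if (any(pred) && any(truth))
    as.logical(overlap_accept(pred, truth, k)) else FALSE
  ref_ab <- local_refinement_error(pred + 1L, truth + 1L)$mean
  ref_ba <- local_refinement_error(truth + 1L, pred + 1L)$mean
  bm <- suppressWarnings(edgel_match_f(pred, truth, d_max = d_max))
  rep <- list(
    schema = "mammoseg-report/1",
    overlap_threshold = k,
    d_max = d_max,
    sensitivity = cs$sensitivity, specificity = cs$specificity,
    ppv = cs$ppv, npv = cs$npv, accuracy = cs$accuracy,
    region_iou = iou, region_dice = dice, overlap_accepted = accepted,
    mean_refinement_error = ref_ab,
    mean_refinement_error_reverse = ref_ba,
    boundary_precision = bm$precision, boundary_recall = bm$recall,
    f_measure = bm$f_measure)
  if (!is.null(image)) {
    image <- as_gray_image(image)
    px <- image$pixels
    if (any(truth) && !all(truth)) {
      rep$auc <- roc_auc(as.numeric(px), as.vector(truth))
      tbc <- target_background_contrast(image, truth)
      rep$tbc_std <- tbc$tbc_std
      rep$tbc_entropy <- tbc$tbc_entropy
    }
    ne <- nsd_enl(image)
    rep$nsd <- ne$nsd
    rep$enl <- ne$enl
    if (min(px) < max(px)) {
      plane <- fuzzify_image(image)
      rep$index_of_fuzziness <- index_of_fuzziness(plane)
      rep$fuzzy_entropy <- fuzzy_entropy(plane)
    }
    if (!is.null(enhanced)) {
      mp <- mse_psnr(image, enhanced)
      rep$mse <- mp$mse
      rep$psnr <- mp$psnr
    }
  }
  structure(rep, class = "mammo_report")
}

#' @export
print.mammo_report <- function(x, ...) {
  cat("<mammo_report>\n")
  for (nm in setdiff(names(x), "schema")) {
    v <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm,
                if (is.numeric(v)) formatC(v, digits = 6, format = "g")
                else as.character(v)))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Serialization is canonical (fixed field order, 15 significant
#' digits, no pretty-printer ambiguity), so identical reports produce
#' byte-identical files.
#'
#' @param report a `mammo_report` (or any named list of scalars).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_report <- function(report, path) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(15),
                          null = "null", na = "string")
  writeLines(txt, path)
  invisible(path)
}
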