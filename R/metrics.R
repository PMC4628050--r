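# Population (biased) standard deviation: deterministic and matches the
# N-denominator convention used throughout the metric definitions.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

shape_check <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between the two inputs", call. = FALSE)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `mse = mean((a - b)^2)`; `psnr = 10 * log10(max_level^2 / mse)` in
#' dB. Identical images give `mse = 0` and `psnr = Inf`.
#'
#' @param a,b two [gray_image]s (or intensity matrices) of the same
#'   shape.
#' @param max_level peak intensity; taken from `a` when it is a
#'   [gray_image].
#' @return A list with elements `mse` and `psnr`.
#' @export
mse_psnr <- function(a, b, max_level = NULL) {
  pa <- if (is_gray_image(a)) a$pixels else a
  pb <- if (is_gray_image(b)) b$pixels else b
  if (is.null(max_level))
    max_level <- if (is_gray_image(a)) a$max_level else 255L
  shape_check(pa, pb)
  mse <- mean((as.numeric(pa) - as.numeric(pb))^2)
  psnr <- if (mse == 0) Inf else 10 * log10(as.numeric(max_level)^2 / mse)
  list(mse = mse, psnr = psnr)
}

#' Noise standard deviation and equivalent number of looks
#'
#' Over a nominally homogeneous region: `nsd` is the population standard
#' deviation of the intensities and `enl = (mean/sd)^2`. A constant
#' region gives `nsd = 0`, `enl = Inf`. When no region mask is supplied
#' a border strip of width 5% of the shorter image side is used as a
#' background proxy.
#'
#' @param img a [gray_image] or intensity matrix.
#' @param region logical mask of the measurement region, or `NULL`.
#' @return A list with elements `nsd` and `enl`.
#' @export
nsd_enl <- function(img, region = NULL) {
  px <- if (is_gray_image(img)) img$pixels else img
  if (is.null(region)) {
    w <- max(1L, round(0.05 * min(dim(px))))
    region <- matrix(FALSE, nrow(px), ncol(px))
    region[c(seq_len(w), nrow(px) - seq_len(w) + 1L), ] <- TRUE
    region[, c(seq_len(w), ncol(px) - seq_len(w) + 1L)] <- TRUE
  }
  shape_check(px, region)
  if (!any(region)) stop("empty measurement region", call. = FALSE)
  vals <- as.numeric(px[region])
  s <- pop_sd(vals)
  list(nsd = s, enl = if (s == 0) Inf else (mean(vals) / s)^2)
}

#' Linear index of fuzziness
#'
#' `gamma_f = (2/N) * sum(min(P, 1 - P))`: 0 for a crisp membership
#' plane (all P in {0, 1}), 1 when every P is 0.5.
#'
#' @param plane numeric membership values in `[0, 1]` (matrix or
#'   vector).
#' @return Scalar in `[0, 1]`.
#' @export
index_of_fuzziness <- function(plane) {
  p <- as.numeric(plane)
  if (any(p < 0 | p > 1)) stop("membership values outside [0, 1]",
                               call. = FALSE)
  2 * mean(pmin(p, 1 - p))
}

#' Normalized fuzzy entropy
#'
#' `H = mean(S(P)) / ln(2)` with the Shannon function
#' `S(P) = -P ln P - (1-P) ln(1-P)` and `S(0) = S(1) = 0`: 0 for a
#' crisp plane, 1 when every P is 0.5.
#'
#' @inheritParams index_of_fuzziness
#' @return Scalar in `[0, 1]`.
#' @export
fuzzy_entropy <- function(plane) {
  p <- as.numeric(plane)
  if (any(p < 0 | p > 1)) stop("membership values outside [0, 1]",
                               call. = FALSE)
  s <- numeric(length(p))
  inner <- p > 0 & p < 1
  pi_ <- p[inner]
  s[inner] <- -pi_ * log(pi_) - (1 - pi_) * log(1 - pi_)
  mean(s) / log(2)
}

#' Target-to-background contrast measures
#'
#' Two contrast measures between a target region and its complement:
#' one based on first/second moments,
#' `|mu_T - mu_B| / (sd_T + sd_B + eps)`, and one based on the Shannon
#' entropies (base 2) of the normalized intensity histograms,
#' `|H_T - H_B| / (H_T + H_B + eps)`, with `eps = 1e-12` guarding zero
#' denominators and results capped at `1e12`.
#'
#' @param img a [gray_image] or intensity matrix.
#' @param target logical mask of the target region; both it and its
#'   complement must be non-empty.
#' @return A list with elements `tbc_std` and `tbc_entropy`.
#' @export
target_background_contrast <- function(img, target) {
  px <- if (is_gray_image(img)) img$pixels else img
  shape_check(px, target)
  if (!any(target) || all(target))
    stop("target and background must both be non-empty", call. = FALSE)
  eps <- 1e-12
  tv <- as.numeric(px[target]); bv <- as.numeric(px[!target])
  tbc_std <- min(abs(mean(tv) - mean(bv)) / (pop_sd(tv) + pop_sd(bv) + eps),
                 1e12)
  hist_entropy <- function(v) {
    p <- tabulate(v + 1L, nbins = max(v) + 1L)
    p <- p[p > 0] / length(v)
    -sum(p * log2(p))
  }
  ht <- hist_entropy(tv); hb <- hist_entropy(bv)
  tbc_entropy <- min(abs(ht - hb) / (ht + hb + eps), 1e12)
  list(tbc_std = tbc_std, tbc_entropy = tbc_entropy)
}

#' Local refinement error between two segmentations
#'
#' For a pixel `p`, `E(A, B, p) = |R(A,p) \ R(B,p)| / |R(A,p)|` where
#' `R(X, p)` is the region of labeling `X` containing `p`. The error is
#' 0 everywhere iff `A` refines `B` (every A-region sits inside a
#' B-region); it is asymmetric in its arguments.
#'
#' @param a,b label matrices of the same shape (any integer labels).
#' @return A list: `per_pixel` (matrix of `E(A,B,p)`) and `mean` (its
#'   average, the mean refinement error).
#' @export
local_refinement_error <- function(a, b) {
  shape_check(a, b)
  la <- match(as.vector(a), unique(as.vector(a)))
  lb <- match(as.vector(b), unique(as.vector(b)))
  size_a <- tabulate(la)
  nb <- max(lb)
  # joint cell sizes via a sparse combined key (double to avoid overflow)
  key <- (la - 1) * nb + lb
  idx <- match(key, unique(key))
  cell <- tabulate(idx)
  e <- (size_a[la] - cell[idx]) / size_a[la]
  list(per_pixel = matrix(e, nrow(a), ncol(a)), mean = mean(e))
}

#' Intersection-over-union and Dice coefficient of two masks
#'
#' @param a,b logical masks of the same shape.
#' @return `region_iou`: `|A & B| / |A | B|`; `region_dice`:
#'   `2|A & B| / (|A| + |B|)`. Both are 1 when the masks are identical
#'   and both empty masks give `NaN`.
#' @export
region_iou <- function(a, b) {
  shape_check(a, b)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(NaN)
  inter / uni
}

#' @rdname region_iou
#' @export
region_dice <- function(a, b) {
  shape_check(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(NaN)
  2 * sum(a & b) / denom
}

#' Region-overlap acceptance test
#'
#' A machine-segmented region is accepted against a ground-truth region
#' when their intersection-over-union reaches the overlap threshold
#' `k` (default 0.75); the boundary is inclusive.
#'
#' @param machine,truth logical masks (same shape), both non-empty.
#' @param k overlap threshold in `(0, 1]`.
#' @return Logical scalar with the attained IoU as attribute `"iou"`.
#' @export
overlap_accept <- function(machine, truth, k = 0.75) {
  if (!any(machine) || !any(truth))
    stop("both regions must be non-empty", call. = FALSE)
  iou <- region_iou(machine, truth)
  structure(iou >= k, iou = iou)
}

#' Boundary pixels of a mask
#'
#' A pixel belongs to the boundary when it is inside the mask and at
#' least one of its 8 neighbors is outside (pixels on the image edge
#' count their missing neighbors as outside), yielding the 8-connected
#' border contour of each region.
#'
#' @param mask logical matrix.
#' @return A two-column integer matrix of `(row, col)` boundary
#'   coordinates.
#' @export
boundary_pixels <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  all_in <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_in <- all_in & padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  which(mask & !all_in, arr.ind = TRUE)
}

#' Boundary agreement by bipartite edgel matching
#'
#' Boundary pixels ("edgels") of the machine and reference masks are
#' matched one-to-one by a maximum-cardinality minimum-cost assignment
#' on the bipartite graph whose admissible edges connect edgels at
#' Euclidean distance at most `d_max`, with the distance as cost. Then
#' `precision = matched / |machine|`, `recall = matched / |reference|`,
#' `f = 2PR/(P+R)` (0 when `P + R = 0`). The assignment is solved
#' exactly up to `max_exact` edgels per side; larger inputs fall back to
#' greedy nearest-unmatched pairing with a warning (this can only affect
#' the reported counts slightly, never the admissibility radius).
#'
#' @param machine,reference logical masks of the same shape, or
#'   two-column `(row, col)` coordinate matrices of edgels.
#' @param d_max admissibility radius in pixels (default 2).
#' @param max_exact largest per-side edgel count solved exactly.
#' @return A list: `precision`, `recall`, `f_measure`, `n_matched`,
#'   `mean_match_distance`.
#' @export
edgel_match_f <- function(machine, reference, d_max = 2, max_exact = 5000L) {
  as_coords <- function(x) {
    if (is.logical(x)) boundary_pixels(x)
    else {
      stopifnot(is.matrix(x), ncol(x) == 2L)
      x
    }
  }
  a <- as_coords(machine)
  b <- as_coords(reference)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    warning("empty boundary; precision/recall use the 0/0 -> 0 convention",
            call. = FALSE)
    return(list(precision = 0, recall = 0, f_measure = 0, n_matched = 0L,
                mean_match_distance = NaN))
  }
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  adm <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(adm) == 0L) {
    matched <- 0L
    mean_d <- NaN
  } else {
    pairs <- data.frame(l = adm[, 1], r = adm[, 2],
                        cost = sqrt(d2[adm]))
    if (na > max_exact || nb > max_exact) {
      warning("large edgel sets: using greedy approximate matching",
              call. = FALSE)
      m <- greedy_matching(na, nb, pairs)
    } else {
      adj_r <- split(pairs$r, factor(pairs$l, levels = seq_len(na)))
      adj_c <- split(pairs$cost, factor(pairs$l, levels = seq_len(na)))
      m <- min_cost_max_matching(na, nb, adj_r, adj_c)
    }
    matched <- sum(m$match_l > 0L)
    mean_d <- if (matched > 0L) m$total_cost / matched else NaN
  }
  precision <- matched / na
  recall <- matched / nb
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f,
       n_matched = as.integer(matched), mean_match_distance = mean_d)
}

#' Confusion counts between predicted and reference masks
#'
#' @param pred,truth logical masks of the same shape.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  shape_check(pred, truth)
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Classification statistics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values `TP/(TP+FP)`, `TN/(TN+FN)`, and accuracy
#' `(TP+TN)/total`. A statistic with a zero denominator is returned as
#' `NA` with a warning.
#'
#' @param counts a `confusion_counts` object or a list with elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @return A list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`.
#' @export
confusion_stats <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn == 0)
    stop("invalid confusion counts", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      NA_real_
    } else num / den
  }
  list(sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       ppv = ratio(tp, tp + fp, "positive predictive value"),
       npv = ratio(tn, tn + fn, "negative predictive value"),
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal AUC, computed through the Mann-Whitney identity with
#' average ranks, so tied scores count one half:
#' `AUC = (concordant + ties/2) / (n_pos * n_neg)`.
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels logical vector of true classes, both classes present.
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores) # average ranks: ties contribute 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
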