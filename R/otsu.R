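#' Intensity histogram of an image
#'
#' Counts of each integer level `0..max_level`.
#'
#' @param img a [gray_image] or integer matrix.
#' @param max_level maximum level; taken from the image when available.
#' @return Integer vector of length `max_level + 1`; element `i` holds
#'   the count of level `i - 1`.
#' @export
intensity_histogram <- function(img, max_level = NULL) {
  px <- if (is_gray_image(img)) img$pixels else img
  if (is.null(max_level))
    max_level <- if (is_gray_image(img)) img$max_level else max(px)
  tabulate(as.vector(px) + 1L, nbins = max_level + 1L)
}

#' Otsu's between-class-variance threshold
#'
#' Finds the level `t` maximizing the between-class variance
#' \deqn{\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2}
#' where class 0 is `{level <= t}` and class 1 is `{level > t}`, over all
#' `t` for which both classes are non-empty. Ties (plateaus of
#' \eqn{\sigma_b^2}) are broken by the smallest `t`, making the result
#' deterministic.
#'
#' @param counts non-negative integer vector of histogram counts;
#'   element `i` is the count of level `i - 1` (levels `0..L`).
#' @return The threshold level `t` (integer, on the `0..L` scale), with
#'   the attained between-class variance as attribute `"sigma_b2"`.
#' @examples
#' h <- integer(256); h[51] <- 10L; h[201] <- 10L # levels 50 and 200
#' otsu_threshold(h)
#' @export
otsu_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("histogram counts must be non-negative with positive total",
         call. = FALSE)
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    stop("degenerate histogram: fewer than two occupied levels",
         call. = FALSE)
  levels <- seq_along(counts) - 1
  total <- sum(counts)
  w0 <- cumsum(counts) / total
  s0 <- cumsum(counts * levels) / total
  mu_t <- s0[length(s0)]
  w1 <- 1 - w0
  # candidates: both classes non-empty
  ok <- w0 > 0 & w1 > 0
  sigma_b2 <- rep(-Inf, length(counts))
  sigma_b2[ok] <- (mu_t * w0[ok] - s0[ok])^2 / (w0[ok] * w1[ok])
  t_idx <- which.max(sigma_b2) # which.max returns the first (smallest) argmax
  structure(levels[t_idx], sigma_b2 = sigma_b2[t_idx])
}

#' Otsu threshold of an image
#'
#' Convenience wrapper: [otsu_threshold()] on the image's intensity
#' histogram.
#'
#' @param img a [gray_image].
#' @return The threshold level (see [otsu_threshold()]).
#' @export
otsu_image_threshold <- function(img) {
  otsu_threshold(intensity_histogram(img))
}

#' Otsu scale of an edge-weight distribution
#'
#' Supplies the "dynamic" scale that couples Otsu's method to the
#' graph-merge criterion: the edge weights are binned into `n_bins`
#' equal-width bins over `[min, max]`, Otsu's threshold is taken on that
#' histogram, and the center of the threshold bin is returned. This
#' value is used as the default merge scale `k_scale` in [segment()].
#'
#' @param weights numeric vector of non-negative edge weights.
#' @param n_bins number of equal-width bins (default 256, matching the
#'   8-bit convention).
#' @return The bin-center weight at the Otsu threshold. If all weights
#'   are equal, that weight is returned with a warning.
#' @export
otsu_weight_scale <- function(weights, n_bins = 256L) {
  if (length(weights) == 0L) stop("no edge weights", call. = FALSE)
  lo <- min(weights); hi <- max(weights)
  if (lo == hi) {
    warning("all edge weights equal; scale is that weight", call. = FALSE)
    return(lo)
  }
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((weights - lo) / width), n_bins - 1) # 0-based bins
  counts <- tabulate(bin + 1L, nbins = n_bins)
  t_bin <- as.integer(otsu_threshold(counts)) # 0-based bin index
  lo + (t_bin + 0.5) * width
}
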