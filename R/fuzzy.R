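#' Five-parameter fuzzy histogram characterization
#'
#' The contrast-enhancement transform is driven by five parameters read
#' off the global gray-level histogram: `alpha` (observed minimum),
#' `max` (observed maximum), `gamma = max/2`, `beta1 = (alpha+gamma)/2`
#' and `beta2 = (max+gamma)/2`, all kept as reals (no rounding). Note
#' that when the observed minimum exceeds `max/2` the ordering
#' degenerates (`gamma <= alpha`); the piecewise membership rules then
#' simply have empty lower branches.
#'
#' @param img a [gray_image] (or intensity matrix).
#' @return A list of class `fuzzy_params` with elements `alpha`, `beta1`,
#'   `gamma`, `beta2`, `max`.
#' @examples
#' img <- gray_image(matrix(c(0L, 100L, 200L, 255L), 2, 2))
#' compute_params(img)
#' @export
compute_params <- function(img) {
  px <- if (is_gray_image(img)) img$pixels else img
  a <- as.numeric(min(px))
  m <- as.numeric(max(px))
  if (a == m)
    stop("degenerate histogram: image is constant, enhancement undefined",
         call. = FALSE)
  g <- m / 2
  structure(list(alpha = a, beta1 = (a + g) / 2, gamma = g,
                 beta2 = (m + g) / 2, max = m),
            class = "fuzzy_params")
}

#' @export
print.fuzzy_params <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_params alpha=%g beta1=%g gamma=%g beta2=%g max=%g>\n",
    x$alpha, x$beta1, x$gamma, x$beta2, x$max))
  invisible(x)
}

#' Fuzzify intensities into membership values
#'
#' Maps gray levels `u` in `[alpha, max]` to membership values `P` by the
#' piecewise intensification rules
#' \deqn{R1: \alpha \le u < \beta_1:\quad P = 2((u-\alpha)/(\gamma-\alpha))^2}
#' \deqn{R2: \beta_1 \le u < \gamma:\quad P = 1 - 2((u-\gamma)/(\gamma-\alpha))^2}
#' \deqn{R3: \gamma \le u < \beta_2:\quad P = 1 - 2((u-\gamma)/(max-\gamma))^2}
#' with the fourth branch depending on `mode`. As printed in the source
#' material the fourth rule is \eqn{P = 2((u-\gamma)/(max-\gamma))^2},
#' which reaches 2 at `u = max` and contradicts both the membership range
#' `[0, 1]` and the stated aim of suppressing levels above `beta2`; mode
#' `"literal"` keeps it (clamping to `[0, 1]`). The default mode
#' `"corrected"` uses \eqn{P = 2((u-max)/(max-\gamma))^2}, which is
#' continuous at `beta2` (both give 1/2), vanishes at `max`, and makes
#' `P` unimodal with its peak 1 at `gamma`.
#'
#' @param u numeric vector of intensities in `[alpha, max]`.
#' @param p a `fuzzy_params` object from [compute_params()].
#' @param mode `"corrected"` (default) or `"literal"`.
#' @return Numeric vector of membership values in `[0, 1]`.
#' @export
fuzzify <- function(u, p, mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "fuzzy_params"))
  # degenerate orderings (gamma <= alpha when min > max/2) need no special
  # case: the affected rules simply have empty domains below
  if (any(u < p$alpha | u > p$max))
    stop("intensity outside [alpha, max]", call. = FALSE)
  P <- numeric(length(u))
  r1 <- u >= p$alpha & u < p$beta1
  r2 <- u >= p$beta1 & u < p$gamma
  r3 <- u >= p$gamma & u < p$beta2
  r4 <- u >= p$beta2 & u <= p$max # closed at max so the domain is covered
  if (any(r1)) P[r1] <- 2 * ((u[r1] - p$alpha) / (p$gamma - p$alpha))^2
  if (any(r2)) P[r2] <- 1 - 2 * ((u[r2] - p$gamma) / (p$gamma - p$alpha))^2
  if (any(r3)) P[r3] <- 1 - 2 * ((u[r3] - p$gamma) / (p$max - p$gamma))^2
  if (any(r4)) {
    P[r4] <- if (mode == "corrected") {
      2 * ((u[r4] - p$max) / (p$max - p$gamma))^2
    } else {
      2 * ((u[r4] - p$gamma) / (p$max - p$gamma))^2
    }
  }
  pmin(pmax(P, 0), 1)
}

#' Fuzzify a whole image into a membership plane
#'
#' Element-wise [fuzzify()]; returns the "fuzzy plane", the image-shaped
#' array of membership values.
#'
#' @inheritParams fuzzify
#' @param img a [gray_image].
#' @return A numeric matrix of membership values with the image's shape.
#' @export
fuzzify_image <- function(img, p = compute_params(img),
                          mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  px <- if (is_gray_image(img)) img$pixels else img
  matrix(fuzzify(as.numeric(px), p, mode), nrow(px), ncol(px))
}

#' Defuzzify a membership plane back to gray levels
#'
#' The inverse mapping is the affine transform
#' `g = round(alpha + P * (max - alpha))` with rounding half away from
#' zero, so `P = 0` maps to `alpha` and `P = 1` to `max`; the output is
#' monotone non-decreasing in `P` and stays inside the input's dynamic
#' range.
#'
#' @param plane numeric matrix of membership values in `[0, 1]`.
#' @param p a `fuzzy_params` object.
#' @param max_level maximum representable intensity of the result.
#' @return A [gray_image].
#' @export
defuzzify <- function(plane, p, max_level = 255L) {
  stopifnot(is.matrix(plane), inherits(p, "fuzzy_params"))
  plane <- pmin(pmax(plane, 0), 1)
  g <- floor(p$alpha + plane * (p$max - p$alpha) + 0.5) # half away from zero
  gray_image(matrix(as.integer(g), nrow(plane), ncol(plane)),
             max_level = max_level)
}

#' Fuzzy contrast enhancement
#'
#' Full enhancement pipeline: compute the five histogram parameters,
#' fuzzify ([fuzzify_image()]), apply the fuzzy modification step (the
#' identity by default -- the intensification already lives in the
#' membership rules; `modify` is a hook for alternative operators), and
#' defuzzify back to gray levels. Deterministic and pointwise: an output
#' pixel depends only on its own input value and the global parameters.
#' A constant image is returned unchanged with a warning.
#'
#' @inheritParams fuzzify
#' @param img a [gray_image].
#' @param modify optional function `plane -> plane` applied between
#'   fuzzification and defuzzification.
#' @return A [gray_image] of the same shape and `max_level`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0))
#' enh <- enhance(ph$image)
#' range(enh$pixels)
#' @export
enhance <- function(img, mode = c("corrected", "literal"), modify = NULL) {
  mode <- match.arg(mode)
  img <- as_gray_image(img)
  if (min(img$pixels) == max(img$pixels)) {
    warning("constant image: enhancement is the identity", call. = FALSE)
    return(img)
  }
  p <- compute_params(img)
  plane <- fuzzify_image(img, p, mode)
  if (!is.null(modify)) plane <- modify(plane)
  defuzzify(plane, p, max_level = img$max_level)
}
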