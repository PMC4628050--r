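#' Specification of a synthetic mammogram phantom
#'
#' Describes a mammogram-like test image with exact, analytic ground
#' truth: a dark background, a bright half-elliptical breast silhouette
#' anchored to one image side (the chest wall), a brighter pectoral
#' wedge in the top corner of that side, zero or more Gaussian-profile
#' masses, and additive Gaussian noise. All geometry is owned by the
#' generator, so the ground-truth masks are exact by construction.
#'
#' @param height,width image size in pixels.
#' @param background_level,breast_level,pectoral_level the three base
#'   intensities; must be strictly increasing.
#' @param pectoral_side `"left"` or `"right"`: which top corner carries
#'   the pectoral wedge (and which side the breast is anchored to).
#' @param pectoral_frac fraction of the image width spanned by the wedge
#'   along the top edge.
#' @param masses list of numeric vectors `c(row, col, sigma, amplitude)`:
#'   each mass adds `amplitude * exp(-d^2 / (2 sigma^2))` to the image
#'   (clipped at `max_level`). Centers must lie inside the breast
#'   silhouette and the half-maximum disc must avoid the pectoral wedge.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (intensity units; 0 disables noise).
#' @param seed integer seed making the phantom fully reproducible.
#' @param max_level maximum representable intensity.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         background_level = 25L, breast_level = 100L,
                         pectoral_level = 180L,
                         pectoral_side = c("left", "right"),
                         pectoral_frac = 0.35,
                         masses = list(), noise_sigma = 5, seed = 1L,
                         max_level = 255L) {
  pectoral_side <- match.arg(pectoral_side)
  spec <- structure(list(height = as.integer(height),
                         width = as.integer(width),
                         background_level = as.integer(background_level),
                         breast_level = as.integer(breast_level),
                         pectoral_level = as.integer(pectoral_level),
                         pectoral_side = pectoral_side,
                         pectoral_frac = pectoral_frac,
                         masses = masses,
                         noise_sigma = noise_sigma,
                         seed = as.integer(seed),
                         max_level = as.integer(max_level)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(0 <= background_level && background_level < breast_level &&
          breast_level < pectoral_level && pectoral_level <= max_level))
      stop("levels must satisfy 0 <= background < breast < pectoral <= max",
           call. = FALSE)
    if (height < 8L || width < 8L)
      stop("phantom too small", call. = FALSE)
    if (pectoral_frac <= 0 || pectoral_frac >= 1)
      stop("pectoral_frac must be in (0, 1)", call. = FALSE)
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  })
  geo <- phantom_geometry(spec)
  for (m in spec$masses) {
    if (length(m) != 4L || m[3] <= 0 || m[4] <= 0)
      stop("each mass is c(row, col, sigma > 0, amplitude > 0)",
           call. = FALSE)
    r <- round(m[1]); c <- round(m[2])
    if (r < 1 || r > spec$height || c < 1 || c > spec$width ||
        !geo$breast[r, c])
      stop("mass center must lie inside the breast silhouette",
           call. = FALSE)
    half_r <- m[3] * sqrt(2 * log(2))
    disc <- (geo$rows - m[1])^2 + (geo$cols - m[2])^2 <= half_r^2
    if (any(disc & geo$pectoral))
      stop("mass half-maximum disc overlaps the pectoral wedge",
           call. = FALSE)
  }
  invisible(spec)
}

# Breast silhouette (half-ellipse anchored to the chest-wall side) and
# pectoral wedge (right triangle at the top corner of that side),
# plus the coordinate grids, as H x W matrices.
phantom_geometry <- function(spec) {
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  x <- if (spec$pectoral_side == "left") cols - 1 else w - cols
  # vertical semi-axis slightly exceeds h/2 so the chest-wall column spans
  # the full image height and the pectoral wedge reaches the top corner
  breast <- ((rows - (h + 1) / 2) / (0.52 * h))^2 + (x / (0.78 * w))^2 <= 1
  wedge <- x / (spec$pectoral_frac * w) + (rows - 1) / (0.45 * h) <= 1
  list(rows = rows, cols = cols, breast = breast,
       pectoral = wedge & breast)
}

#' Generate a synthetic mammogram phantom
#'
#' Renders a [phantom_spec()] into an image plus its exact ground-truth
#' masks. The mass mask is the analytic union of the half-maximum discs
#' (radius `sigma * sqrt(2 log 2)`) of the individual masses, the
#' standard full-width-at-half-maximum support convention. Gaussian
#' noise is added last, then the image is clipped to
#' `[0, max_level]` and rounded. The same spec (including its seed)
#' always produces a bit-identical phantom; the caller's random state is
#' left untouched.
#'
#' @param spec a `phantom_spec`.
#' @return A list of class `phantom`: `image` ([gray_image]),
#'   `mass_mask`, `pectoral_mask`, `breast_mask` (logical matrices), and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   masses = list(c(64, 64, 6, 80)), noise_sigma = 0))
#' table(ph$image$pixels[ph$pectoral_mask])
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  img <- matrix(as.numeric(spec$background_level),
                spec$height, spec$width)
  img[geo$breast] <- spec$breast_level
  img[geo$pectoral] <- spec$pectoral_level
  mass_mask <- matrix(FALSE, spec$height, spec$width)
  for (m in spec$masses) {
    d2 <- (geo$rows - m[1])^2 + (geo$cols - m[2])^2
    img <- img + m[4] * exp(-d2 / (2 * m[3]^2))
    mass_mask <- mass_mask | d2 <= 2 * log(2) * m[3]^2
  }
  if (spec$noise_sigma > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sigma)
  }
  img <- pmin(pmax(floor(img + 0.5), 0), spec$max_level)
  structure(list(image = gray_image(matrix(as.integer(img),
                                           spec$height, spec$width),
                                    max_level = spec$max_level,
                                    source = sprintf("phantom(seed=%d)",
                                                     spec$seed)),
                 mass_mask = mass_mask,
                 pectoral_mask = geo$pectoral,
                 breast_mask = geo$breast,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %d x %d, %d mass(es), noise_sigma = %g, seed = %d>\n",
              x$spec$height, x$spec$width, length(x$spec$masses),
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

# Draw a random mass placement inside the breast, away from the wedge
# and the image border, for a phantom of the given geometry. Uses the
# current RNG stream.
random_mass <- function(spec, geo, sigma_range, amp_range) {
  half_factor <- sqrt(2 * log(2))
  for (try in 1:200) {
    sigma <- stats::runif(1, sigma_range[1], sigma_range[2])
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    r <- stats::runif(1, 0.15 * spec$height, 0.9 * spec$height)
    c <- stats::runif(1, 0.1 * spec$width, 0.9 * spec$width)
    ri <- round(r); ci <- round(c)
    margin <- 3 * sigma
    if (ri < margin + 1 || ri > spec$height - margin ||
        ci < margin + 1 || ci > spec$width - margin) next
    if (!geo$breast[ri, ci]) next
    half_r <- half_factor * sigma
    d2 <- (geo$rows - r)^2 + (geo$cols - c)^2
    disc <- d2 <= (half_r + 2)^2
    if (any(disc & geo$pectoral) || any(disc & !geo$breast)) next
    return(c(r, c, sigma, amp))
  }
  NULL
}

#' Generate a varied suite of phantoms
#'
#' `n` phantoms with sizes, mass counts (0-3), mass shapes, and noise
#' levels drawn deterministically from `master_seed` (phantom `i` uses
#' seed `master_seed + i`). The first phantom always has zero masses, so
#' every suite contains a negative case.
#'
#' @param n number of phantoms.
#' @param master_seed integer master seed.
#' @return A list of `phantom` objects.
#' @export
phantom_suite <- function(n = 10L, master_seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    seed_i <- as.integer(master_seed) + i
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed_i)
    size <- sample(c(96L, 128L, 160L), 1L)
    side <- sample(c("left", "right"), 1L)
    noise <- sample(c(0, 3, 5, 8), 1L)
    n_masses <- if (i == 1L) 0L else sample(0:3, 1L)
    spec0 <- phantom_spec(height = size, width = size,
                          pectoral_side = side, masses = list(),
                          noise_sigma = noise, seed = seed_i)
    geo <- phantom_geometry(spec0)
    masses <- list()
    while (length(masses) < n_masses) {
      m <- random_mass(spec0, geo, sigma_range = c(4, 8),
                       amp_range = c(60, 130))
      if (is.null(m)) break
      # keep half-maximum discs of distinct masses disjoint
      ok <- all(vapply(masses, function(prev) {
        sqrt(sum((m[1:2] - prev[1:2])^2)) >
          sqrt(2 * log(2)) * (m[3] + prev[3]) + 2
      }, logical(1)))
      if (ok) masses <- c(masses, list(m))
    }
    spec0$masses <- masses
    generate_phantom(spec0)
  })
}

#' Generate the mass-recovery benchmark suite
#'
#' Single-mass phantoms used to measure how well the pipeline recovers a
#' known mass: 128 x 128, one conspicuous well-circumscribed mass per
#' image (sigma 4-7 px, amplitude 100-160 over a breast level of 90),
#' which emulates the clearly delineated bright masses a segmentation
#' method is expected to capture. Mass position, size and amplitude vary
#' deterministically with `master_seed` (phantom `i` uses seed
#' `master_seed + i`).
#'
#' @param n number of phantoms.
#' @param master_seed integer master seed.
#' @param noise_sigma additive noise level applied to every phantom.
#' @return A list of single-mass `phantom` objects.
#' @export
phantom_recovery_suite <- function(n = 20L, master_seed = 1L,
                                   noise_sigma = 0) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    seed_i <- as.integer(master_seed) + i
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed_i)
    spec0 <- phantom_spec(height = 128L, width = 128L,
                          breast_level = 90L, pectoral_level = 170L,
                          masses = list(), noise_sigma = noise_sigma,
                          seed = seed_i)
    geo <- phantom_geometry(spec0)
    m <- NULL
    while (is.null(m)) {
      m <- random_mass(spec0, geo, sigma_range = c(4, 7),
                       amp_range = c(100, 160))
    }
    spec0$masses <- list(m)
    generate_phantom(spec0)
  })
}
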