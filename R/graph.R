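#' @useDynLib mammoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Pixel ids are row-major ranks: id = (row - 1) * width + col, 1-based.
pixel_id <- function(r, c, width) (r - 1L) * width + c

#' Dissimilarity weight of a neighboring pixel pair
#'
#' Two weight modes are provided. The default, `"intensity"`, reads the
#' graph vertices as pixel values and returns the Euclidean distance in
#' the one-dimensional intensity feature, `|I(vi) - I(vj)|` -- the only
#' reading under which the weight measures dissimilarity of pixel
#' values. Mode `"spatial_literal"` is the coordinate-only form
#' `sqrt((xi-xj)^2 + (yi-yj)^2)`, kept for fidelity to the published
#' formula; under it every 4-neighbor weight is 1 and every diagonal
#' weight is `sqrt(2)`, independent of image content.
#'
#' @param vi,vj pixel references as `c(row, col)` (1-based).
#' @param img a [gray_image].
#' @param mode `"intensity"` (default) or `"spatial_literal"`.
#' @return Non-negative scalar weight.
#' @export
edge_weight <- function(vi, vj, img, mode = c("intensity", "spatial_literal")) {
  mode <- match.arg(mode)
  dr <- abs(vi[1] - vj[1]); dc <- abs(vi[2] - vj[2])
  if (max(dr, dc) != 1L)
    stop("pixels are not neighbors under 4/8-connectivity", call. = FALSE)
  if (mode == "spatial_literal") return(sqrt(dr^2 + dc^2))
  px <- if (is_gray_image(img)) img$pixels else img
  abs(as.numeric(px[vi[1], vi[2]]) - as.numeric(px[vj[1], vj[2]]))
}

#' Build the weighted pixel graph of an image
#'
#' One vertex per pixel (row-major rank), one undirected edge per
#' neighboring pair under the chosen connectivity, weighted by
#' [edge_weight()]. For an `H x W` image, 4-connectivity yields
#' `H*(W-1) + W*(H-1)` edges and 8-connectivity adds `2*(H-1)*(W-1)`
#' diagonal edges.
#'
#' @param img a [gray_image].
#' @param connectivity 4 or 8 (default 8).
#' @param mode weight mode, see [edge_weight()].
#' @return A list of class `pixel_graph`: `n_vertices`, `edges` (a
#'   data.frame with columns `i`, `j` (`i < j`, 1-based row-major ids)
#'   and `w`), `connectivity`, `weight_mode`, `dim`.
#' @export
build_graph <- function(img, connectivity = 8L,
                        mode = c("intensity", "spatial_literal")) {
  mode <- match.arg(mode)
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(4L, 8L))
  px <- if (is_gray_image(img)) img$pixels else img
  h <- nrow(px); w <- ncol(px)
  vals <- as.numeric(t(px)) # row-major vector, vals[id]
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  add_pairs <- function(r1, c1, r2, c2, diag_pair) {
    a <- pixel_id(r1, c1, w); b <- pixel_id(r2, c2, w)
    lo <- pmin(a, b); hi <- pmax(a, b)
    wt <- if (mode == "intensity") abs(vals[a] - vals[b])
          else if (diag_pair) rep(sqrt(2), length(a)) else rep(1, length(a))
    ii <<- c(ii, lo); jj <<- c(jj, hi); ww <<- c(ww, wt)
  }
  if (w > 1L) { # horizontal
    g <- expand.grid(r = seq_len(h), c = seq_len(w - 1L))
    add_pairs(g$r, g$c, g$r, g$c + 1L, FALSE)
  }
  if (h > 1L) { # vertical
    g <- expand.grid(r = seq_len(h - 1L), c = seq_len(w))
    add_pairs(g$r, g$c, g$r + 1L, g$c, FALSE)
  }
  if (connectivity == 8L && h > 1L && w > 1L) {
    g <- expand.grid(r = seq_len(h - 1L), c = seq_len(w - 1L))
    add_pairs(g$r, g$c, g$r + 1L, g$c + 1L, TRUE) # down-right
    add_pairs(g$r, g$c + 1L, g$r + 1L, g$c, TRUE) # down-left
  }
  structure(list(n_vertices = h * w,
                 edges = data.frame(i = ii, j = jj, w = ww),
                 connectivity = connectivity, weight_mode = mode,
                 dim = c(h, w)),
            class = "pixel_graph")
}

#' Sort graph edges ascending by weight
#'
#' Stable ascending order with ties broken by `(weight, i, j)`
#' lexicographically, so the processing order is fully deterministic.
#'
#' @param g a `pixel_graph` from [build_graph()].
#' @return The graph with its `edges` reordered.
#' @export
sort_edges <- function(g) {
  stopifnot(inherits(g, "pixel_graph"))
  e <- g$edges
  g$edges <- e[order(e$w, e$i, e$j), , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' The dynamic-threshold merge criterion
#'
#' Given two distinct regions connected by the current edge of weight
#' `w_current` (the inter-region measure IRM: because edges are
#' processed in ascending order, the current weight is the minimum
#' weight connecting the two regions), the pair merges iff
#' `IRM <= DT` where the dynamic threshold is
#' `DT = min(Int(R1) + k_scale/|R1|, Int(R2) + k_scale/|R2|)` and
#' `Int(R)` is the largest edge weight accepted into `R`'s merge
#' history. The threshold adapts per pair: small or homogeneous regions
#' merge readily, large heterogeneous ones resist.
#'
#' @param int1,int2 internal measures `Int(R1)`, `Int(R2)`.
#' @param size1,size2 region sizes in pixels.
#' @param w_current weight of the connecting edge (IRM).
#' @param k_scale merge scale; larger values produce fewer, larger
#'   regions.
#' @return `TRUE` if the pair should merge.
#' @examples
#' merge_criterion(0, 0, 1, 1, w_current = 5, k_scale = 8) # singletons
#' merge_criterion(1, 0, 4, 1, w_current = 5, k_scale = 8) # DT = 3 < 5
#' @export
merge_criterion <- function(int1, int2, size1, size2, w_current, k_scale) {
  dt <- min(int1 + k_scale / size1, int2 + k_scale / size2)
  w_current <= dt
}

#' Graph-cut region-merging segmentation
#'
#' The core segmenter: builds the weighted pixel graph, sorts the edges
#' ascending, and makes a single pass applying [merge_criterion()] via a
#' union-find forest. When `k_scale` is `NULL` it is set "dynamically"
#' from the data by [otsu_weight_scale()] on the edge-weight
#' distribution. A cleanup pass then merges any region smaller than
#' `min_size` with its lowest-connecting-weight neighbor. Labels are
#' renumbered deterministically (region 1 contains the first row-major
#' pixel, and so on), so identical inputs give bit-identical results.
#'
#' @param img a [gray_image].
#' @param connectivity 4 or 8 (default 8).
#' @param mode weight mode, see [edge_weight()].
#' @param k_scale merge scale; `NULL` (default) derives it from the edge
#'   weights via Otsu's method.
#' @param min_size minimum surviving region size in pixels; `NULL`
#'   (default) uses `max(16, 1e-4 * n_pixels)`.
#' @return An object of class `mammo_seg`: `labels` (integer matrix,
#'   1-based contiguous region ids), `region_table` (data.frame with
#'   `id`, `size`, `mean_intensity`, bounding box `rmin,rmax,cmin,cmax`,
#'   `touches_border`), `k_scale`, `connectivity`, `weight_mode`,
#'   `min_size`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0))
#' seg <- segment(ph$image)
#' nrow(seg$region_table)
#' @export
segment <- function(img, connectivity = 8L,
                    mode = c("intensity", "spatial_literal"),
                    k_scale = NULL, min_size = NULL) {
  mode <- match.arg(mode)
  img <- as_gray_image(img)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  n <- h * w
  if (is.null(min_size)) min_size <- as.integer(max(16, 1e-4 * n))
  g <- sort_edges(build_graph(img, connectivity, mode))
  e <- g$edges
  if (nrow(e) == 0L) {
    roots <- seq_len(n)
  } else {
    if (is.null(k_scale)) k_scale <- suppressWarnings(otsu_weight_scale(e$w))
    roots <- .uf_segment(n, e$i - 1L, e$j - 1L, e$w,
                         as.numeric(k_scale), as.integer(min_size))
  }
  # deterministic renumbering by each region's minimum row-major pixel id
  first <- !duplicated(roots)
  new_id <- integer(n)
  new_id[roots[first]] <- seq_len(sum(first))
  lab_rowmajor <- new_id[roots]
  labels <- matrix(lab_rowmajor, h, w, byrow = TRUE)
  structure(list(labels = labels,
                 region_table = region_table(labels, img),
                 k_scale = if (is.null(k_scale)) NA_real_ else k_scale,
                 connectivity = g$connectivity, weight_mode = mode,
                 min_size = as.integer(min_size)),
            class = "mammo_seg")
}

#' @export
print.mammo_seg <- function(x, ...) {
  cat(sprintf("<mammo_seg %d x %d, %d regions, k_scale = %.4g>\n",
              nrow(x$labels), ncol(x$labels), nrow(x$region_table),
              x$k_scale))
  invisible(x)
}

# Per-region size, mean intensity, bounding box, border contact.
region_table <- function(labels, img) {
  px <- if (is_gray_image(img)) img$pixels else img
  h <- nrow(labels); w <- ncol(labels)
  lab <- as.vector(labels)
  ids <- sort(unique(lab))
  size <- tabulate(lab, nbins = max(ids))[ids]
  mean_int <- as.vector(rowsum(as.numeric(px), lab)[, 1]) / size
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  rmin <- tapply(rows, lab, min)[as.character(ids)]
  rmax <- tapply(rows, lab, max)[as.character(ids)]
  cmin <- tapply(cols, lab, min)[as.character(ids)]
  cmax <- tapply(cols, lab, max)[as.character(ids)]
  data.frame(id = ids, size = size, mean_intensity = mean_int,
             rmin = as.integer(rmin), rmax = as.integer(rmax),
             cmin = as.integer(cmin), cmax = as.integer(cmax),
             touches_border = rmin == 1L | rmax == h | cmin == 1L |
               cmax == w,
             row.names = NULL)
}

# Region adjacency pairs (a < b) under the 8-neighborhood of the label
# image; used by ROI extraction.
region_adjacency <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pairs <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    cbind(pmin(a, b), pmax(a, b))
  }
  out <- NULL
  if (w > 1L) out <- rbind(out, pairs(labels[, -w], labels[, -1]))
  if (h > 1L) out <- rbind(out, pairs(labels[-h, ], labels[-1, ]))
  if (h > 1L && w > 1L) {
    out <- rbind(out, pairs(labels[-h, -w], labels[-1, -1]))
    out <- rbind(out, pairs(labels[-h, -1], labels[-1, -w]))
  }
  out <- out[out[, 1] != out[, 2], , drop = FALSE]
  unique(out)
}
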