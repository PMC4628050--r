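#' Grayscale image container
#'
#' A `gray_image` is the currency of the whole pipeline: an integer
#' intensity matrix (rows = image rows, columns = image columns, 1-based
#' `[row, col]` indexing) together with the maximum representable
#' intensity and an optional provenance string.
#'
#' @param pixels numeric matrix of intensities; coerced to integer.
#' @param max_level maximum representable intensity (255 for 8-bit,
#'   65535 for 16-bit).
#' @param source optional provenance string (e.g. the file it came from).
#' @return An object of class `gray_image` with elements `pixels`,
#'   `max_level` and `source`.
#' @examples
#' img <- gray_image(matrix(c(0L, 255L, 10L, 20L), 2, 2), max_level = 255)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, max_level = 255L, source = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  storage.mode(pixels) <- "integer"
  max_level <- as.integer(max_level)
  if (anyNA(pixels)) stop("image contains missing intensities", call. = FALSE)
  if (min(pixels) < 0L || max(pixels) > max_level)
    stop("intensities must lie in [0, max_level]", call. = FALSE)
  structure(list(pixels = pixels, max_level = max_level, source = source),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, max_level = %d%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$max_level,
              if (is.null(x$source)) "" else paste0(", source = ", x$source)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

as_gray_image <- function(x, max_level = 255L) {
  if (is_gray_image(x)) x else gray_image(x, max_level = max_level)
}

# ---- PGM (portable graymap), P2 ASCII and P5 binary dialects ----------------
# No installed R package reads PGM, so the (tiny) format is handled here.

read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # tokenizer over the header: whitespace-separated tokens, '#' comments
  pos <- 1L
  n <- length(raw)
  next_token <- function() {
    repeat {
      while (pos <= n && raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d)))
        pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(0x23)) { # comment
        while (pos <= n && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !(raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x23))))
      pos <<- pos + 1L
    if (start > n) stop("truncated PGM header: ", path, call. = FALSE)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM (P2/P5) file: ", path, call. = FALSE)
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L ||
      maxval < 1L || maxval > 65535L)
    stop("invalid PGM header in ", path, call. = FALSE)
  if (magic == "P2") {
    txt <- rawToChar(raw[pos:n])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) != width * height || anyNA(vals))
      stop("corrupt P2 pixel data in ", path, call. = FALSE)
  } else {
    pos <- pos + 1L # exactly one whitespace byte after maxval
    bytes_per <- if (maxval > 255L) 2L else 1L
    need <- width * height * bytes_per
    if (n - pos + 1L < need)
      stop("truncated P5 pixel data in ", path, call. = FALSE)
    body <- raw[pos:(pos + need - 1L)]
    if (bytes_per == 1L) {
      vals <- as.integer(body)
    } else { # big-endian 16-bit
      vals <- as.integer(body[c(TRUE, FALSE)]) * 256L +
        as.integer(body[c(FALSE, TRUE)])
    }
  }
  px <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  gray_image(px, max_level = maxval, source = path)
}

write_pgm <- function(img, path, ascii = FALSE) {
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(img$max_level)), con)
    writeLines(apply(px, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", w, h, img$max_level), con,
              eos = NULL)
    vals <- as.vector(t(px)) # row-major
    if (img$max_level > 255L) {
      bytes <- raw(2L * length(vals))
      bytes[c(TRUE, FALSE)] <- as.raw(vals %/% 256L)
      bytes[c(FALSE, TRUE)] <- as.raw(vals %% 256L)
    } else {
      bytes <- as.raw(vals)
    }
    writeBin(bytes, con)
  }
  invisible(NULL)
}

# ---- front-end readers/writers ----------------------------------------------

#' Read a grayscale image
#'
#' Reads a PGM (P2 or P5) or PNG file into a [gray_image]. The format is
#' detected from the file's magic bytes, not its extension. 8- and
#' 16-bit grayscale PNGs are supported; RGB PNGs are collapsed to
#' luminance (Rec. 601 weights 0.299, 0.587, 0.114) with a warning, and
#' an alpha channel is dropped with a warning.
#'
#' @param path path to an existing PGM or PNG file.
#' @return A [gray_image] whose `max_level` reflects the file's bit depth.
#' @seealso [write_image()], [read_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head <- readBin(path, "raw", 8L)
  if (length(head) >= 2L && rawToChar(head[1:2]) %in% c("P2", "P5"))
    return(read_pgm(path))
  png_magic <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(head) == 8L && identical(head, png_magic)) {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    maxv <- as.integer(2^depth - 1)
    if (length(dim(arr)) == 3L) {
      nc <- dim(arr)[3]
      if (nc %in% c(2L, 4L)) {
        warning("dropping alpha channel of ", path, call. = FALSE)
        arr <- arr[, , -nc, drop = FALSE]
        nc <- dim(arr)[3]
      }
      if (nc == 3L) {
        warning("collapsing RGB to luminance for ", path, call. = FALSE)
        arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      } else {
        arr <- arr[, , 1]
      }
    }
    px <- matrix(as.integer(round(arr * maxv)), nrow(arr), ncol(arr))
    return(gray_image(px, max_level = maxv, source = path))
  }
  stop("unreadable image (not PGM or PNG): ", path, call. = FALSE)
}

#' Write a grayscale image
#'
#' Writes a [gray_image] to PGM or PNG, chosen by the file extension
#' (`.pgm` vs `.png`; anything else defaults to PGM). 8-bit images
#' round-trip losslessly through either format. PNG output is limited to
#' `max_level` 255; deeper images are written as 16-bit binary PGM.
#'
#' @param img a [gray_image].
#' @param path output path.
#' @param ascii write PGM as plain-text P2 instead of binary P5.
#' @return `invisible(NULL)`.
#' @export
write_image <- function(img, path, ascii = FALSE) {
  stopifnot(is_gray_image(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (img$max_level > 255L)
      stop("PNG output supports max_level <= 255; use .pgm for deeper images",
           call. = FALSE)
    png::writePNG(img$pixels / img$max_level, path)
  } else {
    write_pgm(img, path, ascii = ascii)
  }
  invisible(NULL)
}

#' Read a binary mask
#'
#' Reads a PGM/PNG file and thresholds it into a logical matrix: any
#' nonzero pixel is `TRUE`.
#'
#' @param path path to a PGM or PNG file.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  img$pixels > 0L
}

#' Write a binary mask
#'
#' Writes a logical matrix as a 0 / `max_level` image so that
#' `read_mask(write_mask(m, f))` reproduces `m` exactly.
#'
#' @param mask logical matrix.
#' @param path output path (`.pgm` or `.png`).
#' @param max_level intensity used for `TRUE` pixels.
#' @return `invisible(NULL)`.
#' @export
write_mask <- function(mask, path, max_level = 255L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  px <- matrix(ifelse(mask, as.integer(max_level), 0L),
               nrow(mask), ncol(mask))
  write_image(gray_image(px, max_level = max_level), path)
}
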