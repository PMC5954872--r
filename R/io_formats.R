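#' Construct a mammogram object
#'
#' The package-wide raster container: an 8-bit single-channel image stored as
#' a numeric matrix in (row, col) order, 0-based origin at the top-left.
#'
#' @param pixels numeric matrix of gray levels in `[0, 255]`.
#' @param id image identifier.
#' @param laterality one of `"left"`, `"right"`, `"unknown"` -- the side of
#'   the imaged breast (decides which image edge is the chest wall).
#' @return an object of class `mammogram` with fields `pixels`, `height`,
#'   `width`, `laterality`, `id`.
#' @export
mammogram <- function(pixels, id = "image", laterality = c("unknown", "left", "right")) {
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("mammogram pixels must be finite")
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("mammogram must be at least 64x64 pixels")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("mammogram intensities must lie in [0, 255] (8-bit)")
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 laterality = laterality, id = as.character(id)),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram '%s'> %dx%d, laterality=%s, gray range [%g, %g]\n",
              x$id, x$height, x$width, x$laterality,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  vals <- integer(0)
  header <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  buf <- character(0)
  while (length(header) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("truncated PGM header in ", path)
    if (ch == "#") { repeat { ch <- readChar(con, 1); if (ch == "\n" || length(ch) == 0) break } ; ch <- " " }
    if (grepl("[0-9]", ch)) buf <- c(buf, ch)
    else if (length(buf) > 0) { header <- c(header, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
  }
  W <- header[1]; H <- header[2]; maxval <- header[3]
  n <- H * W
  if (magic == "P2") {
    txt <- readChar(con, 10 * n + 1024, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])[seq_len(n)]
  } else {
    if (maxval < 256) vals <- as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
    else vals <- as.integer(readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big"))
  }
  if (anyNA(vals)) stop("truncated PGM data in ", path)
  list(pixels = matrix(vals, nrow = H, ncol = W, byrow = TRUE), maxval = maxval)
}

write_pgm <- function(pixels, path, ascii = FALSE) {
  v <- as.integer(round(pixels))
  H <- nrow(pixels); W <- ncol(pixels)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(W, H), "255"), con)
    write(t(pixels), con, ncolumns = W)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", W, H), con, eos = NULL)
    writeBin(as.integer(t(pixels)), con, size = 1)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".yaml")

#' Read a mammogram image
#'
#' Reads an 8-bit grayscale PNG or PGM (ASCII `P2` or binary `P5`).  Deeper
#' rasters (e.g. 16-bit) are rescaled to `[0, 255]` by a linear min-max map.
#' If a YAML sidecar `<name>.yaml` exists next to the image, `laterality`
#' and `id` are taken from it.
#'
#' @param path image file path (`.png`, `.pgm`).
#' @return a [mammogram] object.
#' @export
read_mammogram <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    p <- read_pgm(path)
    px <- p$pixels
    if (p$maxval > 255) {
      rng <- range(px)
      px <- if (diff(rng) == 0) px * 0 else round((px - rng[1]) / diff(rng) * 255)
    }
  } else if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) {
      nc <- dim(arr)[3]
      if (nc == 2) arr <- arr[, , 1]          # gray + alpha
      else stop(sprintf("expected single-channel image, got %d channels", nc))
    }
    ## readPNG normalizes by bit depth; 8-bit values are k/255 exactly.
    px <- arr * 255
    if (max(abs(px - round(px))) > 1e-6) {    # deeper than 8 bits
      rng <- range(px)
      px <- if (diff(rng) == 0) px * 0 else (px - rng[1]) / diff(rng) * 255
    }
    px <- round(px)
  } else stop("unsupported image format: .", ext)
  id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  laterality <- "unknown"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    laterality <- meta$laterality %||% "unknown"
    id <- meta$id %||% id
  }
  mammogram(px, id = id, laterality = laterality)
}

#' Write a mammogram image
#'
#' @param image a [mammogram] or numeric matrix in `[0, 255]`.
#' @param path destination path; format chosen by extension (`.png`, `.pgm`).
#' @param sidecar write a YAML sidecar with id and laterality (mammogram
#'   input only).
#' @export
write_mammogram <- function(image, path, sidecar = inherits(image, "mammogram")) {
  px <- round(as_pixels(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(px / 255, path)
  else if (ext == "pgm") write_pgm(px, path)
  else stop("unsupported image format: .", ext)
  if (sidecar && inherits(image, "mammogram"))
    yaml::write_yaml(list(id = image$id, laterality = image$laterality),
                     sidecar_path(path))
  invisible(path)
}

#' Ground-truth mass region
#'
#' Either a circle (MIAS convention: center + radius) or an explicit binary
#' mask; exactly one of the two representations is present.
#'
#' @param center numeric `(row, col)`, 0-based.
#' @param radius circle radius in pixels (> 0).
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param id region identifier.
#' @return an object of class `gt_region`.
#' @export
gt_region <- function(center = NULL, radius = NULL, mask = NULL, id = "gt") {
  circle <- !is.null(center)
  if (circle == !is.null(mask) && circle) stop("give either circle or mask, not both")
  if (!circle && is.null(mask)) stop("give either circle or mask")
  if (circle) {
    stopifnot(length(center) == 2, radius > 0)
  } else {
    stopifnot(is.matrix(mask), sum(mask) >= 1)
  }
  structure(list(center = center, radius = radius, mask = mask,
                 id = as.character(id)), class = "gt_region")
}

#' Rasterize a ground-truth region to a binary mask
#'
#' @param gt a [gt_region].
#' @param dim image dimensions `(H, W)`.
#' @return logical matrix.
#' @export
gt_mask <- function(gt, dim) {
  if (!is.null(gt$mask)) return(gt$mask)
  r <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  c <- matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2])
  (r - gt$center[1])^2 + (c - gt$center[2])^2 <= gt$radius^2
}

#' Read mass annotations (MIAS-style text)
#'
#' One region per line: `id x y radius`.  In the `"mias"` dialect the stored
#' coordinates are column-first with the origin at the *bottom*-left, and are
#' flipped to this package's top-left (row, col) convention; the `"rowcol"`
#' dialect stores `id row col radius` already in package convention.
#' Circles are validated to lie fully inside the image.
#'
#' @param path annotation file; an empty file yields an empty list.
#' @param image the [mammogram] the annotations refer to.
#' @param dialect `"mias"` (default) or `"rowcol"`.
#' @return list of [gt_region] circles.
#' @export
read_annotations <- function(path, image, dialect = c("mias", "rowcol")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read annotations, no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  out <- vector("list", length(lines))
  H <- image$height; W <- image$width
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (length(tok) != 4) stop("malformed annotation line: ", lines[i])
    id <- tok[1]; a <- as.numeric(tok[2]); b <- as.numeric(tok[3])
    radius <- as.numeric(tok[4])
    if (dialect == "mias") { col <- a; row <- (H - 1) - b } else { row <- a; col <- b }
    if (radius <= 0)
      stop("invalid annotation '", id, "': radius must be positive")
    if (row - radius < 0 || row + radius > H - 1 ||
        col - radius < 0 || col + radius > W - 1)
      stop("annotation '", id, "' circle does not lie inside the image")
    out[[i]] <- gt_region(center = c(row, col), radius = radius, id = id)
  }
  out
}

#' Write mass annotations (MIAS dialect)
#'
#' @param gts list of circle [gt_region]s.
#' @param path destination text file.
#' @param image the [mammogram] (needed for the bottom-left flip).
#' @export
write_annotations <- function(gts, path, image) {
  H <- image$height
  lines <- vapply(gts, function(g) {
    if (is.null(g$center)) stop("only circle regions can be written in MIAS dialect")
    sprintf("%s %g %g %g", g$id, g$center[2], (H - 1) - g$center[1], g$radius)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a detection result to JSON
#'
#' One JSON document per image: id, per-stage candidate counts and the final
#' ROIs with run-length-encoded masks and classifier scores, so stage-wise
#' accounting can be reconstructed from files alone.
#'
#' @param result a `detection_result` from [detect_masses()].
#' @param path destination `.json` path.
#' @export
write_detections <- function(result, path) {
  rois <- lapply(result$rois, function(r) {
    list(patch_ids = r$patch_ids, score = r$score, label = r$label,
         mask = mask_to_rle(r$mask))
  })
  doc <- list(id = result$id, provenance = result$provenance, rois = rois)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a detection result written by [write_detections()]
#' @param path `.json` path.
#' @return list with `id`, `provenance`, `rois` (masks decoded).
#' @export
read_detections <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  doc$rois <- lapply(doc$rois, function(r) {
    r$mask <- rle_to_mask(r$mask)
    r$patch_ids <- as.integer(r$patch_ids)
    r
  })
  doc
}
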