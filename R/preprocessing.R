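#' Segment the breast region (figure-ground segregation)
#'
#' An adaptive global threshold (Otsu's criterion over the image histogram)
#' separates tissue from the dark background; the largest connected
#' component above the threshold is kept and hole-filled.  Small bright
#' structures such as film labels and tape markings fall in separate
#' components and are discarded by the largest-component rule.
#'
#' @param image a [mammogram] or numeric matrix.
#' @return an object of class `breast_mask` with fields `mask` (logical
#'   matrix), `area` (pixel count) and `pectoral_removed`/`warning` flags.
#' @export
segment_breast <- function(image) {
  px <- as_pixels(image)
  if (diff(range(px)) == 0)
    stop("EmptyBreast: image is constant, adaptive threshold is degenerate")
  th <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1), levels = 256) * 255
  fg <- px > th
  if (!any(fg)) stop("EmptyBreast: no foreground pixel above adaptive threshold")
  lab <- label_components(fg, connectivity = 8)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  mask <- matrix(as.logical(EBImage::fillHull(mask)), nrow(mask))
  structure(list(mask = mask, area = sum(mask), threshold = th,
                 pectoral_removed = FALSE, warning = FALSE),
            class = "breast_mask")
}

## Side of the chest wall: from laterality when known, else the image half
## holding the mask centroid (the breast is attached to the chest wall).
chest_side <- function(image, mask) {
  lat <- if (inherits(image, "mammogram")) image$laterality else "unknown"
  if (lat == "left") return("left")
  if (lat == "right") return("right")
  m <- as_mask(mask)
  ctr <- mean(which(m, arr.ind = TRUE)[, 2])
  if (ctr <= ncol(m) / 2) "left" else "right"
}

#' Remove the pectoral muscle wedge
#'
#' Seeded region growing from the top chest-wall corner of the breast with
#' an intensity tolerance, clipped by a straight line fitted to the grown
#' boundary.  Fail-safe by contract: if the grown region exceeds 40% of the
#' breast area (e.g. the wedge is indistinguishable from tissue) removal is
#' aborted, the input mask is returned and its `warning` flag set.
#'
#' @param image a [mammogram] (laterality used when known).
#' @param mask a `breast_mask` from [segment_breast()].
#' @param tolerance intensity tolerance (gray levels) of the region growing.
#' @return a `breast_mask` with the wedge excised (or unchanged on abort).
#' @export
remove_pectoral <- function(image, mask, tolerance = 18) {
  px <- as_pixels(image)
  m <- as_mask(mask)
  H <- nrow(m); W <- ncol(m)
  side <- chest_side(image, mask)
  ## seed: topmost breast pixel on the chest-wall column band
  cols <- if (side == "left") seq_len(min(8, W)) else seq(W - min(8, W) + 1, W)
  band <- which(m[, cols, drop = FALSE], arr.ind = TRUE)
  out <- mask
  if (nrow(band) == 0) { out$warning <- TRUE; return(out) }
  r0 <- min(band[, 1])
  c0 <- if (side == "left") min(cols[band[band[, 1] == r0, 2]]) else
    max(cols[band[band[, 1] == r0, 2]])
  win <- px[max(1, r0):min(H, r0 + 4),
            max(1, c0 - 4):min(W, c0 + 4)]
  seed_val <- mean(win[win > 0])
  ## region = connected component containing the seed among breast pixels
  ## within the intensity tolerance of the seed value
  cand <- m & abs(px - seed_val) <= tolerance
  lab <- label_components(cand, connectivity = 8)
  seed_lab <- lab[r0, c0]
  if (seed_lab == 0) { out$warning <- TRUE; return(out) }
  grown <- lab == seed_lab
  if (sum(grown) > 0.4 * mask$area) { out$warning <- TRUE; return(out) }
  ## straight-line clip: fit the grown boundary (extent per row) linearly
  rows <- which(apply(grown, 1, any))
  ext <- vapply(rows, function(r) {
    cs <- which(grown[r, ])
    if (side == "left") max(cs) else min(cs)
  }, numeric(1))
  wedge <- matrix(FALSE, H, W)
  if (length(rows) >= 2) {
    fit <- stats::lm(ext ~ rows)
    bnd <- stats::predict(fit, data.frame(rows = rows))
    for (i in seq_along(rows)) {
      r <- rows[i]
      if (side == "left") wedge[r, seq_len(max(1, min(W, round(bnd[i]))))] <- TRUE
      else wedge[r, seq(max(1, min(W, round(bnd[i]))), W)] <- TRUE
    }
  }
  wedge <- (wedge | grown) & m
  if (sum(wedge) > 0.4 * mask$area) { out$warning <- TRUE; return(out) }
  out$mask <- m & !wedge
  out$area <- sum(out$mask)
  out$pectoral_removed <- TRUE
  out
}

#' Morphological enhancement of mass-like structure
#'
#' `clip(I + whiteTopHat(I, r) - blackTopHat(I, r))` restricted to the
#' breast: bright structures smaller than the disk are boosted, dark ones
#' suppressed, and the background forced to exactly 0.  To avoid spurious
#' response at the breast outline, the background is filled with the breast
#' mean before the morphology and zeroed afterwards.
#'
#' @param image a [mammogram] or matrix.
#' @param mask a `breast_mask`.
#' @param radius disk radius in pixels (default 30).
#' @return a [mammogram] (when the input was one) or matrix of enhanced
#'   intensities, integer-valued in `[0, 255]`.
#' @export
enhance_mammogram <- function(image, mask, radius = 30) {
  px <- as_pixels(image)
  m <- as_mask(mask)
  work <- px
  if (any(m)) work[!m] <- mean(px[m])
  k <- disk_kernel(radius)
  th <- work - gray_dilate(gray_erode(work, k), k)            # white top-hat
  bh <- gray_erode(gray_dilate(work, k), k) - work            # black top-hat
  out <- round(clip8(work + th - bh))
  out[!m] <- 0
  if (inherits(image, "mammogram")) {
    image$pixels <- out
    image
  } else out
}
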