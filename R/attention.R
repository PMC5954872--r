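#' Grayscale opening with a flat disk
#'
#' Erosion followed by dilation with a flat disk-shaped structuring element
#' (pixels within Euclidean distance `radius` of the center).  Opening is
#' anti-extensive: the output is pointwise less than or equal to the input.
#' Bright structures narrower than the disk are leveled while larger focal
#' areas survive as plateaus, which is what makes the subsequent regional
#' maxima a medical attention map.
#'
#' @param image enhanced [mammogram] or numeric matrix.
#' @param radius disk radius in pixels (default 6).
#' @param reconstruct if `TRUE`, opening-by-reconstruction is used instead
#'   of plain opening: the eroded-then-opened image is geodesically dilated
#'   under the original, which preserves the exact shape of surviving
#'   structures.
#' @return matrix of the opened image (same dimensions).
#' @export
open_with_disk <- function(image, radius = 6, reconstruct = FALSE) {
  px <- as_pixels(image)
  if (radius < 1) stop("structuring element radius must be >= 1")
  if (radius > min(dim(px)) / 2)
    stop("structuring element radius larger than half the image extent")
  k <- disk_kernel(radius)
  opened <- gray_dilate(gray_erode(px, k), k)
  if (reconstruct) opened <- reconstruct_by_dilation(opened, px)
  opened
}

## Geodesic reconstruction by dilation of `marker` under `mask` (marker <=
## mask pointwise); iterated 3x3 dilation clipped by the mask until stable.
reconstruct_by_dilation <- function(marker, mask) {
  box <- matrix(1, 3, 3)
  cur <- pmin(marker, mask)
  repeat {
    nxt <- pmin(gray_dilate(cur, box), mask)
    if (all(nxt == cur)) return(nxt)
    cur <- nxt
  }
}

#' Regional maxima of a gray-level image
#'
#' A regional maximum is a connected plateau of constant intensity none of
#' whose pixels has a strictly brighter neighbor (8-connectivity).  Intended
#' for quantized (integer-valued) images such as opened 8-bit mammograms.
#'
#' @param image numeric matrix with a modest number of distinct levels.
#' @return logical matrix marking all regional-maximum pixels.
#' @export
regional_maxima <- function(image) {
  px <- as_pixels(image)
  vals <- unique(as.vector(px))
  if (length(vals) > 4096)
    stop("regional_maxima expects a quantized image (<= 4096 distinct levels)")
  nbmax <- gray_dilate(px, matrix(1, 3, 3))   # max over 8-neighborhood + self
  H <- nrow(px); W <- ncol(px)
  out <- matrix(FALSE, H, W)
  ## candidate values: only levels that contain at least one local-max pixel
  cand_vals <- unique(px[px == nbmax])
  for (v in cand_vals) {
    idx <- which(px == v)
    rows <- range((idx - 1) %% H + 1)
    cols <- range((idx - 1) %/% H + 1)
    iso <- px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE] == v
    lab <- label_components(iso, connectivity = 8)
    if (max(lab) == 0) next
    ## a plateau is a maximum iff no member pixel sees a brighter neighbor
    nb <- nbmax[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    pxc <- px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    bad <- unique(lab[iso & nb > pxc])
    good <- setdiff(seq_len(max(lab)), bad)
    if (length(good) > 0) {
      hit <- iso & matrix(lab %in% good, nrow(iso))
      sub <- out[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
      sub[hit] <- TRUE
      out[rows[1]:rows[2], cols[1]:cols[2]] <- sub
    }
  }
  out
}

#' Salient focal regions (medical visual attention)
#'
#' Regional maxima of the opened image intersected with the breast mask;
#' connected components whose normalized peak intensity (`peak / 255`)
#' falls below `attention_threshold` are discarded.
#'
#' @param opened matrix from [open_with_disk()].
#' @param breast a `breast_mask` (or logical matrix).
#' @param attention_threshold fraction in `[0, 1]` (default 0.5).
#' @return an object of class `saliency_mask`: fields `mask` (logical),
#'   `n_components`, `peaks` (normalized peak per component).
#' @export
salient_regions <- function(opened, breast, attention_threshold = 0.5) {
  m <- as_mask(breast)
  stopifnot(all(dim(opened) == dim(m)))
  mx <- regional_maxima(opened) & m
  lab <- label_components(mx, connectivity = 8)
  n <- max(lab)
  keep_mask <- matrix(FALSE, nrow(opened), ncol(opened))
  peaks <- numeric(0)
  if (n > 0) {
    peak <- vapply(seq_len(n), function(i) max(opened[lab == i]) / 255, numeric(1))
    keep <- which(peak >= attention_threshold)
    peaks <- peak[keep]
    if (length(keep) > 0) keep_mask <- lab %in% keep & mx
  }
  structure(list(mask = matrix(keep_mask, nrow(opened)),
                 n_components = length(peaks), peaks = peaks),
            class = "saliency_mask")
}
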