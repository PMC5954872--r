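#' Specification of a synthetic mammographic phantom
#'
#' The phantom emulates the gross structure of a digitized screening film
#' at desk scale: a bright breast half-disk on a dark background, an
#' optional pectoral-muscle wedge in the top chest-wall corner, glandular
#' tissue as Gaussian-profile ridges radiating from the nipple ("like a
#' crown"), round-to-oval masses rendered as Gaussian-smoothed filled
#' ellipses, an optional bright film-label rectangle, and additive Gaussian
#' noise.  Breast-density analogs follow the three MIAS classes: fatty
#' (`"F"`), fatty-glandular (`"G"`) and dense-glandular (`"D"`) raise both
#' the base tissue intensity and the number/contrast of gland ridges, which
#' is what makes dense breasts harder.  All randomness flows from the
#' mandatory `seed`; generation is bit-reproducible.
#'
#' @param size image dimensions `(H, W)` (default 384 x 384).
#' @param laterality `"left"` or `"right"` chest wall.
#' @param n_masses number of masses (0 for a normal image).
#' @param mass_radius_range semi-minor axis range in pixels.
#' @param mass_contrast_range mass contrast range in gray levels (mean over
#'   the mass footprint above the local tissue).
#' @param density one of `"F"`, `"G"`, `"D"`.
#' @param n_gland_strips number of gland ridges; `NULL` picks a
#'   density-dependent default (F 6, G 10, D 18).
#' @param pectoral render a pectoral wedge.
#' @param noise_sigma additive Gaussian noise sd in gray levels.
#' @param label_artifact render a bright film label outside the breast.
#' @param seed integer seed (mandatory).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(384, 384), laterality = "left",
                         n_masses = 2, mass_radius_range = c(18, 34),
                         mass_contrast_range = c(20, 60),
                         density = c("G", "F", "D"), n_gland_strips = NULL,
                         pectoral = FALSE, noise_sigma = 0.25,
                         label_artifact = TRUE, seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  density <- match.arg(density)
  stopifnot(length(size) == 2, size[1] >= 64, size[2] >= 64,
            laterality %in% c("left", "right"),
            n_masses >= 0, diff(mass_radius_range) >= 0,
            diff(mass_contrast_range) >= 0, noise_sigma >= 0)
  if (is.null(n_gland_strips))
    n_gland_strips <- c(F = 6, G = 10, D = 18)[[density]]
  structure(list(size = as.integer(size), laterality = laterality,
                 n_masses = as.integer(n_masses),
                 mass_radius_range = mass_radius_range,
                 mass_contrast_range = mass_contrast_range,
                 density = density, n_gland_strips = as.integer(n_gland_strips),
                 pectoral = isTRUE(pectoral), noise_sigma = noise_sigma,
                 label_artifact = isTRUE(label_artifact),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

density_params <- function(density) {
  switch(density,
         F = list(base = 110, gland_amp = c(10, 18)),
         G = list(base = 120, gland_amp = c(14, 26)),
         D = list(base = 130, gland_amp = c(22, 35)))
}

#' Generate a phantom mammogram with full ground truth
#'
#' Render order: background (5) -> breast half-disk at the density base
#' intensity -> pectoral wedge (+40) -> gland ridges -> masses -> film
#' label -> Gaussian noise -> clip to `[0, 255]`.  Mass layers are
#' Gaussian-smoothed and renormalized so that the mean added intensity over
#' the mass footprint equals the sampled contrast.  Mass placement uses
#' rejection sampling (inside the breast with a margin, outside the
#' pectoral wedge, non-overlapping); 100 failures raise a `PlacementError`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [mammogram]) and `truth` (class
#'   `phantom_truth`): `breast_mask`, `pectoral_mask`, `gland_mask`,
#'   `mass_masks` (list), `mass_circles` (list of [gt_region]s),
#'   `tissue_labels` (0 bg, 1 fat, 2 pectoral, 3 gland, 4 mass).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  dp <- density_params(spec$density)
  rr <- matrix(seq_len(H) - 1, H, W)
  cc <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  ## chest wall on the left for a left breast; mirror columns for right
  mirror <- spec$laterality == "right"
  x <- if (mirror) (W - 1) - cc else cc        # distance from chest wall
  img <- matrix(5, H, W)
  Rb <- 0.45 * H
  cy <- (H - 1) / 2
  breast <- (rr - cy)^2 + x^2 <= Rb^2
  img[breast] <- dp$base
  ## pectoral wedge: triangle in the top chest-wall corner
  pect <- matrix(FALSE, H, W)
  if (spec$pectoral) {
    h_p <- 0.45 * H; w_p <- 0.38 * Rb
    pect <- breast & rr < h_p & x < w_p * (1 - rr / h_p)
    img[pect] <- img[pect] + 40
  }
  ## gland ridges radiating from the nipple
  nipple <- c(cy, Rb * 0.96)                   # (row, x)
  gland_layer <- matrix(0, H, W)
  if (spec$n_gland_strips > 0) {
    for (s in seq_len(spec$n_gland_strips)) {
      ang <- pi + runif(1, -pi / 3, pi / 3)    # from nipple toward chest wall
      len <- runif(1, 0.45, 0.85) * Rb
      wdt <- runif(1, 4, 10)
      amp <- runif(1, dp$gland_amp[1], dp$gland_amp[2])
      p0 <- nipple + runif(2, -6, 6)
      p1 <- p0 + len * c(sin(ang), cos(ang))
      d <- dist_to_segment(rr, x, p0, p1)
      gland_layer <- gland_layer + amp * exp(-d^2 / (2 * (wdt / 2)^2))
    }
    gland_layer[!breast] <- 0
    ## glandular tissue is speckled, not smooth: multiplicative short-range
    ## texture makes gland patches heterogeneous (poor densification) while
    ## masses stay smooth -- the generative basis for the densification rule
    speckle <- matrix(EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = 1), H, W)
    speckle <- speckle / stats::sd(speckle)
    gland_layer <- gland_layer * (1 + 0.35 * speckle)
    ## a few wide, smooth duct-like ridges: focal normal structures that can
    ## pass the densification and shape rules (the realistic false-positive
    ## supply that the verification classifier must learn to reject)
    n_ducts <- c(F = 1, G = 2, D = 3)[[spec$density]]
    duct_layer <- matrix(0, H, W)
    for (s in seq_len(n_ducts)) {
      ang <- pi + runif(1, -pi / 3, pi / 3)
      len <- runif(1, 0.35, 0.6) * Rb
      wdt <- runif(1, 12, 20)
      amp <- runif(1, 15, 28)
      p0 <- nipple + c(runif(1, -0.4, 0.4) * Rb, -runif(1, 0.1, 0.5) * Rb)
      p1 <- p0 + len * c(sin(ang), cos(ang))
      d <- dist_to_segment(rr, x, p0, p1)
      duct_layer <- duct_layer + amp * exp(-d^2 / (2 * (wdt / 2)^2))
    }
    duct_layer[!breast] <- 0
    smooth_tex <- matrix(EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = 10), H, W)
    smooth_tex <- smooth_tex / stats::sd(smooth_tex)
    gland_layer <- gland_layer + duct_layer * (1 + 0.3 * smooth_tex)
  }
  gland_mask <- gland_layer >= 5
  ## masses: smooth dome profiles (lightly Gaussian-smoothed) that displace
  ## the glandular texture beneath them, like a solid lump
  mass_masks <- list(); mass_circles <- list(); mass_meta <- list()
  mass_total <- matrix(0, H, W)
  atten <- matrix(1, H, W)
  if (spec$n_masses > 0) {
    occupied <- matrix(FALSE, H, W)
    for (k in seq_len(spec$n_masses)) {
      placed <- FALSE
      for (try in 1:100) {
        b <- runif(1, spec$mass_radius_range[1], spec$mass_radius_range[2])
        q <- runif(1, 1.0, 1.6)
        a <- b * q
        theta <- runif(1, 0, pi)
        contrast <- runif(1, spec$mass_contrast_range[1], spec$mass_contrast_range[2])
        mr <- runif(1, cy - 0.8 * Rb, cy + 0.8 * Rb)
        mx <- runif(1, 0.15 * Rb, 0.9 * Rb)
        ## ellipse in (row, x) frame
        dr <- rr - mr; dx <- x - mx
        u <- dx * cos(theta) + dr * sin(theta)
        v <- -dx * sin(theta) + dr * cos(theta)
        rho2 <- (u / a)^2 + (v / b)^2
        emask <- rho2 <= 1
        ## fully inside the breast (3 px margin), clear of pectoral & others;
        ## the annotation circle (radius = semi-major axis) must also stay
        ## inside the raster, including its chest-wall side
        margin_ok <- sqrt((mr - cy)^2 + mx^2) + a + 3 <= Rb &&
          mx - a >= 1 && mr - a >= 1 && mr + a <= H - 2
        if (!margin_ok || !all(breast[emask]) ||
            any(pect[emask]) || any(occupied[emask])) next
        prof <- matrix(0, H, W)
        prof[emask] <- 1 - pmin(sqrt(rho2[emask]), 1)^1.5
        prof <- matrix(EBImage::gblur(prof, sigma = 1.5), H, W)
        atten <- atten * (1 - pmin(prof / max(prof), 1))
        ## long-correlation-length texture keeps every patch smoothly varying
        tex <- matrix(EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = 12), H, W)
        tex <- tex / stats::sd(tex)
        layer <- prof * (1 + 0.45 * tex)
        layer <- layer * (contrast / mean(layer[emask]))
        mass_total <- mass_total + layer
        occupied <- occupied | rho2 <= 1.8^2
        col_center <- if (mirror) (W - 1) - mx else mx
        mass_masks[[k]] <- emask
        mass_circles[[k]] <- gt_region(center = c(mr, col_center), radius = a,
                                       id = sprintf("mass%02d", k))
        mass_meta[[k]] <- list(center = c(mr, col_center), a = a, b = b,
                               theta = theta, contrast = contrast)
        placed <- TRUE
        break
      }
      if (!placed) stop("PlacementError: could not place mass ", k,
                        " after 100 tries")
    }
  }
  img <- img + gland_layer * atten + mass_total
  ## film label artifact: bright rectangle in the corner away from the chest
  label_mask <- matrix(FALSE, H, W)
  if (spec$label_artifact) {
    rs <- 8:27
    cs_x <- (W - 48):(W - 9)                   # far from chest wall in x
    label_mask[rs, cs_x] <- TRUE
    near_breast <- matrix(EBImage::dilate(breast, matrix(1, 11, 11)) > 0, H, W)
    label_mask <- label_mask & !near_breast
    img[label_mask] <- 220
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
  img <- round(clip8(img))
  ## (right-lateral scenes are rendered directly in image coordinates via
  ## the chest-wall distance substitution above; no flip is needed)
  tissue <- matrix(0L, H, W)
  tissue[breast] <- 1L
  tissue[pect] <- 2L
  tissue[gland_mask & breast] <- 3L
  for (m in mass_masks) tissue[m] <- 4L
  id <- sprintf("phantom_%s_%d", spec$density, spec$seed)
  truth <- structure(list(breast_mask = breast, pectoral_mask = pect,
                          gland_mask = gland_mask, label_mask = label_mask,
                          mass_masks = mass_masks, mass_circles = mass_circles,
                          mass_meta = mass_meta, tissue_labels = tissue),
                     class = "phantom_truth")
  list(image = mammogram(img, id = id, laterality = spec$laterality),
       truth = truth)
}

## distance from each (row, x) pixel to the segment p0-p1 (in (row, x) frame)
dist_to_segment <- function(rr, xx, p0, p1) {
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- ((rr - p0[1]) * v[1] + (xx - p0[2]) * v[2]) / max(len2, 1e-12)
  t <- pmin(1, pmax(0, t))
  sqrt((rr - (p0[1] + t * v[1]))^2 + (xx - (p0[2] + t * v[2]))^2)
}

#' Write (or build in memory) a phantom benchmark dataset
#'
#' Generates `n_images` phantoms with a configurable proportion of normal
#' (mass-free) images and a mix of density classes, and -- when `dir` is
#' given -- writes a directory consumable end-to-end: 8-bit grayscale PNGs
#' with YAML sidecars, one MIAS-dialect annotation file per image (empty
#' for normals) and a `manifest.csv`.  Per-image seeds are derived from the
#' master seed, so the same seed reproduces the dataset byte for byte.
#'
#' @param n_images number of images (default 40).
#' @param dir output directory, or `NULL` for an in-memory dataset.
#' @param prop_normal proportion of mass-free images (default 0.25).
#' @param density_mix named proportions over `c("F","G","D")`.
#' @param seed master seed.
#' @param n_masses masses per abnormal image (upper bound; 1 or 2 are
#'   drawn).
#' @param ... further fields forwarded to [phantom_spec()].
#' @return invisibly, a list of records: `image`, `truth`, `gts`,
#'   `density`, `normal`, plus `manifest` (data frame) as attribute.
#' @export
make_benchmark <- function(n_images = 40, dir = NULL, prop_normal = 0.25,
                           density_mix = c(F = 1 / 3, G = 1 / 3, D = 1 / 3),
                           seed, n_masses = 2, ...) {
  if (missing(seed)) stop("make_benchmark requires an explicit seed")
  n_normal <- round(prop_normal * n_images)
  normal <- rep(FALSE, n_images)
  if (n_normal > 0) normal[round(seq(1, n_images, length.out = n_normal))] <- TRUE
  counts <- diff(round(cumsum(c(0, density_mix)) / sum(density_mix) * n_images))
  pool <- rep(names(density_mix), times = counts)
  ## interleave classes so densities are balanced across normal/abnormal
  dens <- pool[order(stats::ave(seq_along(pool), pool, FUN = seq_along))]
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, i)
    nm <- if (normal[i]) 0 else 1 + si %% n_masses
    sp <- phantom_spec(density = dens[i], n_masses = nm,
                       laterality = if (si %% 2 == 0) "left" else "right",
                       seed = si, ...)
    ph <- generate_phantom(sp)
    ph$image$id <- sprintf("img_%03d", i)
    records[[i]] <- list(image = ph$image, truth = ph$truth,
                         gts = ph$truth$mass_circles,
                         density = dens[i], normal = normal[i], seed = si)
  }
  manifest <- data.frame(
    id = vapply(records, function(r) r$image$id, character(1)),
    density = dens, normal = normal,
    n_masses = vapply(records, function(r) length(r$gts), integer(1)),
    seed = vapply(records, function(r) r$seed, integer(1)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in records) {
      write_mammogram(r$image, file.path(dir, paste0(r$image$id, ".png")))
      write_annotations(r$gts, file.path(dir, paste0(r$image$id, ".txt")), r$image)
    }
    write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  attr(records, "manifest") <- manifest
  invisible(records)
}
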