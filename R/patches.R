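#' Initialize superpixel cluster centers
#'
#' Centers are placed on a regular grid with spacing `g = sqrt(H*W / K)`
#' (so each initial rectangular patch holds about `H*W/K` pixels), then
#' perturbed to the lowest-gradient pixel in their 3x3 neighborhood so no
#' center starts on an edge; centers falling outside the breast are dropped.
#'
#' @param dim image dimensions `(H, W)`.
#' @param breast `breast_mask` or logical matrix.
#' @param image numeric matrix used for the gradient perturbation; `NULL`
#'   skips the perturbation.
#' @param K requested number of centers (>= 4).
#' @return matrix with columns `row`, `col` (0-based, inside the breast).
#' @export
init_centers <- function(dim, breast, image = NULL, K = 2000) {
  if (K < 4) stop("K must be >= 4")
  H <- dim[1]; W <- dim[2]
  m <- as_mask(breast)
  g <- sqrt(H * W / K)
  rows <- seq(g / 2, H - 1e-9, by = g)
  cols <- seq(g / 2, W - 1e-9, by = g)
  ctr <- cbind(row = rep(rows, times = length(cols)) - 0.5,
               col = rep(cols, each = length(rows)) - 0.5)
  ctr <- round(ctr)
  ctr[, 1] <- pmin(H - 1, pmax(0, ctr[, 1]))
  ctr[, 2] <- pmin(W - 1, pmax(0, ctr[, 2]))
  if (!is.null(image)) {
    px <- as_pixels(image)
    gr <- gradient_magnitude(px)
    for (i in seq_len(nrow(ctr))) {
      r <- ctr[i, 1] + 1; c <- ctr[i, 2] + 1
      rs <- max(1, r - 1):min(H, r + 1); cs <- max(1, c - 1):min(W, c + 1)
      nb <- gr[rs, cs, drop = FALSE]
      k <- which.min(nb)
      ctr[i, ] <- c(rs[(k - 1) %% length(rs) + 1] - 1,
                    cs[(k - 1) %/% length(rs) + 1] - 1)
    }
  }
  keep <- m[cbind(ctr[, 1] + 1, ctr[, 2] + 1)]
  out <- ctr[keep, , drop = FALSE]
  attr(out, "spacing") <- g
  out
}

gradient_magnitude <- function(px) {
  gx <- (shift_matrix(px, 0, -1, NA) - shift_matrix(px, 0, 1, NA))
  gy <- (shift_matrix(px, -1, 0, NA) - shift_matrix(px, 1, 0, NA))
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  sqrt(gx^2 + gy^2)
}

#' Patch similarity index
#'
#' `D_s = (mu / S) * d_xy + d_g` with `d_xy` the Euclidean distance in the
#' image plane and `d_g` the absolute gray-level difference between the
#' pixel and the cluster-center mean.  `S` balances spatial proximity
#' against gray distance (default 25); `mu` is the pixel-compactness
#' weight.
#'
#' @param pixel numeric `(row, col, gray)`.
#' @param center numeric `(row, col, mean_gray)`.
#' @param mu compactness weight.
#' @param S balance constant (default 25).
#' @return the scalar similarity index (0 = identical).
#' @export
patch_similarity <- function(pixel, center, mu = 10, S = 25) {
  dxy <- sqrt(sum((pixel[1:2] - center[1:2])^2))
  dg <- abs(pixel[3] - center[3])
  (mu / S) * dxy + dg
}

#' Generate visual patches (superpixels) and the candidate set U
#'
#' Pixels of the breast are grouped into compact, intensity-homogeneous
#' patches by iterative local k-means under the similarity index of
#' [patch_similarity()] (fixed 10 passes, search window twice the grid
#' spacing).  Connectivity is then enforced: for every label only the
#' largest 8-connected fragment is kept and orphan pixels are relabeled to
#' the dominant neighboring patch.  Finally, patches whose pixels intersect
#' the salient attention mask form the candidate set `U`; patches never
#' touching a salient position are left out of consideration (they belong
#' to neither `U` nor `N`).  The module is fully deterministic.
#'
#' @param enhanced enhanced [mammogram] or matrix.
#' @param saliency `saliency_mask` from [salient_regions()] (or logical
#'   matrix).
#' @param breast `breast_mask` or logical matrix.
#' @param config a [cad_config()]; uses `k_clusters`, `compactness_mu`,
#'   `balance_s`.
#' @param iters number of assignment passes (default 10).
#' @return an object of class `patch_partition`: `label_image` (0 =
#'   background), `patches` (list of `visual_patch`), `U`, `N` (integer id
#'   vectors), `objective` (assignment objective per pass).
#' @export
cluster_patches <- function(enhanced, saliency, breast, config = cad_config(),
                            iters = 10) {
  px <- as_pixels(enhanced)
  m <- as_mask(breast)
  sal <- as_mask(saliency)
  H <- nrow(px); W <- ncol(px)
  ctr <- init_centers(c(H, W), m, px, K = config$k_clusters)
  empty <- structure(list(label_image = matrix(0L, H, W), patches = list(),
                          U = integer(0), N = integer(0),
                          objective = numeric(0)),
                     class = "patch_partition")
  if (nrow(ctr) == 0) return(empty)
  g <- sqrt(H * W / config$k_clusters)
  cen <- cbind(ctr[, 1], ctr[, 2], px[cbind(ctr[, 1] + 1, ctr[, 2] + 1)])
  res <- .slic_iterate(px, m, cen, config$compactness_mu, config$balance_s,
                       g, as.integer(iters))
  lab <- enforce_connectivity(res$labels, m)
  patches <- build_patches(lab, px)
  ids <- vapply(patches, `[[`, integer(1), "label")
  in_sal <- vapply(patches, function(p) any(sal[p$index]), logical(1))
  structure(list(label_image = lab, patches = patches,
                 U = ids[in_sal], N = integer(0),
                 objective = as.numeric(res$objective)),
            class = "patch_partition")
}

## Keep only the largest 8-connected fragment per label, then iteratively
## relabel orphan pixels (and never-assigned masked pixels) to the modal
## neighboring label.
enforce_connectivity <- function(lab, mask) {
  H <- nrow(lab); W <- ncol(lab)
  lab <- matrix(as.integer(lab), H, W)
  for (k in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == k)
    rows <- range((idx - 1) %% H + 1); cols <- range((idx - 1) %/% H + 1)
    sub <- lab[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE] == k
    comp <- label_components(sub, connectivity = 8)
    nc <- max(comp)
    if (nc > 1) {
      sizes <- tabulate(comp[comp > 0], nc)
      keep <- which.max(sizes)
      drop <- which(sub & comp != keep, arr.ind = TRUE)
      lab[cbind(drop[, 1] + rows[1] - 1L, drop[, 2] + cols[1] - 1L)] <- 0L
    }
  }
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  repeat {
    orphan <- which(mask & lab == 0L)
    if (length(orphan) == 0) break
    ## neighbor labels per orphan across the 8 shifts
    nb <- matrix(0L, length(orphan), nrow(shifts))
    for (s in seq_len(nrow(shifts))) {
      sh <- shift_matrix(lab, shifts$dr[s], shifts$dc[s], 0L)
      nb[, s] <- sh[orphan]
    }
    has_nb <- rowSums(nb > 0) > 0
    if (!any(has_nb)) { lab[orphan] <- 0L; break }  # isolated from all labels
    idx <- which(has_nb)
    newlab <- vapply(idx, function(i) {
      v <- nb[i, ]; v <- v[v > 0]
      tab <- table(v)
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
    lab[orphan[idx]] <- newlab
  }
  lab
}

## Materialize per-patch records from a label image.
build_patches <- function(lab, px) {
  ids <- sort(unique(lab[lab > 0]))
  H <- nrow(lab)
  lapply(ids, function(k) {
    idx <- which(lab == k)
    rows <- (idx - 1) %% H
    cols <- (idx - 1) %/% H
    visual_patch(label = k, rows = rows, cols = cols, index = idx,
                 intensities = px[idx], lab = lab)
  })
}

visual_patch <- function(label, rows, cols, index, intensities, lab) {
  edge <- boundary_points(rows, cols, index, lab, label)
  structure(list(label = as.integer(label),
                 pixels = cbind(row = rows, col = cols),
                 index = index,
                 centroid = c(mean(rows), mean(cols)),
                 mean_intensity = mean(intensities),
                 intensities = intensities,
                 edge_points = edge,
                 area = length(index)),
            class = "visual_patch")
}

## Boundary of a patch: member pixels with a 4-neighbor outside the patch
## (or on the image border), ordered by angle around the centroid.
boundary_points <- function(rows, cols, index, lab, label) {
  H <- nrow(lab); W <- ncol(lab)
  r1 <- rows + 1; c1 <- cols + 1
  onb <- r1 == 1 | r1 == H | c1 == 1 | c1 == W
  nb_out <- onb
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    rr <- pmin(H, pmax(1, r1 + d[1])); cc <- pmin(W, pmax(1, c1 + d[2]))
    nb_out <- nb_out | lab[cbind(rr, cc)] != label
  }
  er <- rows[nb_out]; ec <- cols[nb_out]
  ang <- atan2(er - mean(rows), ec - mean(cols))
  ord <- order(ang, er, ec)
  cbind(row = er[ord], col = ec[ord])
}

#' @export
print.patch_partition <- function(x, ...) {
  cat(sprintf("<patch_partition> %d patches, |U|=%d, |N|=%d\n",
              length(x$patches), length(x$U), length(x$N)))
  invisible(x)
}

## id -> patch lookup
get_patch <- function(partition, id) {
  ids <- vapply(partition$patches, `[[`, integer(1), "label")
  partition$patches[[match(id, ids)]]
}
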