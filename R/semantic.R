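#' Gray-level co-occurrence matrix of a visual patch
#'
#' Intensities are quantized to `levels` bins over the patch's own min-max
#' range; co-occurrences are counted only for pixel pairs that both lie
#' inside the patch, accumulated symmetrically over the requested offsets
#' and normalized to sum 1.  A single-intensity patch concentrates all mass
#' on one diagonal cell.
#'
#' @param patch a `visual_patch` (or list with `pixels` and `intensities`).
#' @param image numeric matrix the patch indexes into (used when the patch
#'   carries no cached intensities).
#' @param levels number of gray bins (default 16).
#' @param offsets list of `(dr, dc)` displacement vectors; default the four
#'   standard directions `(0,1), (1,0), (1,1), (1,-1)`.
#' @return object of class `glcm_matrix`: `matrix` (levels x levels,
#'   sums to 1), `levels`, `offsets`, `symmetric = TRUE`.
#' @export
patch_glcm <- function(patch, image = NULL, levels = 16,
                       offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  rows <- patch$pixels[, 1]; cols <- patch$pixels[, 2]
  if (length(rows) < 4) stop("patch area must be >= 4 for a co-occurrence matrix")
  ints <- if (!is.null(image)) as_pixels(image)[cbind(rows + 1, cols + 1)]
          else patch$intensities
  rng <- range(ints)
  q <- if (diff(rng) == 0) rep(1L, length(ints))
       else pmin(levels, floor((ints - rng[1]) / diff(rng) * levels) + 1L)
  ## place quantized values on a local bounding-box grid, NA outside patch
  r0 <- min(rows); c0 <- min(cols)
  h <- max(rows) - r0 + 1; w <- max(cols) - c0 + 1
  grid <- matrix(NA_integer_, h, w)
  grid[cbind(rows - r0 + 1, cols - c0 + 1)] <- q
  M <- matrix(0, levels, levels)
  for (off in offsets) {
    a <- grid
    b <- shift_matrix(grid, -off[1], -off[2], NA_integer_)  # value at (r+dr, c+dc)
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels * levels)
    Mo <- matrix(counts, levels, levels, byrow = TRUE)
    M <- M + Mo + t(Mo)                                      # symmetric
  }
  if (sum(M) > 0) M <- M / sum(M)
  else M[1, 1] <- 1   # pathological patch with no interior pair
  structure(list(matrix = M, levels = levels, offsets = offsets,
                 symmetric = TRUE), class = "glcm_matrix")
}

#' Densification of a visual patch
#'
#' The co-occurrence correlation of the patch:
#' `Dens = (sum_ij i*j*M(i,j) - u_i*u_j) / (sigma_i * sigma_j)` with
#' marginal means `u` and standard deviations `sigma` of the normalized
#' co-occurrence matrix `M`.  High values mean the patch is a homogeneous,
#' smoothly varying unit (mass-like); noisy or textured tissue scores low.
#' The mathematical range is `[-1, 1]`; a patch that is constant after
#' quantization has `sigma = 0` and is defined as perfectly homogeneous
#' (`Dens = 1`, with attribute `degenerate = TRUE`).
#'
#' @param patch a `visual_patch`.
#' @param image image matrix (see [patch_glcm()]).
#' @param levels,offsets passed to [patch_glcm()].
#' @param glcm optionally a precomputed `glcm_matrix`.
#' @return scalar densification value.
#' @export
densification <- function(patch = NULL, image = NULL, levels = 16,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                          glcm = NULL) {
  if (is.null(glcm) && nrow(patch$pixels) < 4)
    return(structure(1, degenerate = TRUE))   # sub-texture speck: no pairs
  g <- glcm %||% patch_glcm(patch, image, levels = levels, offsets = offsets)
  M <- g$matrix
  L <- g$levels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  ui <- sum(i * M)
  uj <- sum(j * M)
  si <- sqrt(sum(M * (i - ui)^2))
  sj <- sqrt(sum(M * (j - uj)^2))
  if (si == 0 || sj == 0) return(structure(1, degenerate = TRUE))
  (sum(i * j * M) - ui * uj) / (si * sj)
}

#' Densification rule: prune the candidate set
#'
#' Every patch in `U` with `Dens < t_dens` is moved to the normal-tissue
#' set `N`; patches at or above the threshold stay in `U`.
#'
#' @param partition a `patch_partition`.
#' @param image image matrix the patches were cut from.
#' @param t_dens threshold (default 0.93).
#' @param levels co-occurrence quantization levels.
#' @return the updated `patch_partition`; a `dens` named vector of the
#'   computed values is attached.
#' @export
filter_densification <- function(partition, image = NULL, t_dens = 0.93,
                                 levels = 16) {
  if (length(partition$U) == 0) return(partition)
  dens <- vapply(partition$U, function(id) {
    as.numeric(densification(get_patch(partition, id), image, levels = levels))
  }, numeric(1))
  names(dens) <- partition$U
  reject <- partition$U[dens < t_dens]
  partition$N <- c(partition$N, reject)
  partition$U <- partition$U[dens >= t_dens]
  partition$dens <- dens
  partition
}

#' Direct least-squares ellipse fit to boundary points
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` to the points
#' by the numerically stable direct least-squares method with the ellipse
#' constraint `B^2 - 4AC < 0` built in; the semi-axes are recovered from
#' the fitted conic by the standard eigen-decomposition closed form.
#' Degenerate input (< 6 points, or collinear) yields an invalid fit that
#' downstream rules treat as maximally eccentric.
#'
#' @param edge_points n x 2 matrix of `(row, col)` boundary coordinates.
#' @return object of class `ellipse_fit`: `conic` (named A..F), `center`,
#'   `a` (semi-major), `b` (semi-minor), `eccentricity`, `valid`.
#' @export
fit_ellipse <- function(edge_points) {
  pts <- as.matrix(edge_points)
  degenerate <- structure(list(conic = rep(NA_real_, 6), center = c(NA, NA),
                               a = NA_real_, b = NA_real_, eccentricity = 1,
                               valid = FALSE), class = "ellipse_fit")
  if (nrow(pts) < 6) return(degenerate)
  x <- pts[, 2]; y <- pts[, 1]
  ## collinearity: rank of centered coordinates
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) return(degenerate)
  ## condition: center and scale
  mx <- mean(x); my <- mean(y)
  s <- max(sv) / sqrt(length(x)) * 2
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T2)) return(degenerate)
  Mred <- S1 + S2 %*% T2
  Mred <- rbind(Mred[3, ] / 2, -Mred[2, ], Mred[1, ] / 2)
  eg <- eigen(Mred)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) return(degenerate)
  a1 <- evec[, k[1]]
  coef <- c(a1, as.vector(T2 %*% a1))   # A,B,C,D,E,F in conditioned coords
  ## undo conditioning: x = (X - mx)/s, y = (Y - my)/s
  A <- coef[1] / s^2
  B <- coef[2] / s^2
  C <- coef[3] / s^2
  D <- coef[4] / s - 2 * A * mx - B * my
  E <- coef[5] / s - 2 * C * my - B * mx
  F <- coef[6] + A * mx^2 + B * mx * my + C * my^2 - coef[4] * mx / s - coef[5] * my / s
  conic_to_ellipse(c(A = A, B = B, C = C, D = D, E = E, F = F))
}

## Semi-axes / center / eccentricity from a general conic with B^2-4AC < 0.
conic_to_ellipse <- function(co) {
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]
  D <- co[["D"]]; E <- co[["E"]]; F <- co[["F"]]
  disc <- B^2 - 4 * A * C
  bad <- structure(list(conic = co, center = c(NA, NA), a = NA_real_,
                        b = NA_real_, eccentricity = 1, valid = FALSE),
                   class = "ellipse_fit")
  if (!is.finite(disc) || disc >= 0) return(bad)
  x0 <- (2 * C * D - B * E) / disc
  y0 <- (2 * A * E - B * D) / disc
  ## value of the quadratic form at the center
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)$values        # both same sign for ellipse
  ax2 <- -Fc / ev                                 # semi-axis^2 along each eigendirection
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(bad)
  a <- sqrt(max(ax2)); b <- sqrt(min(ax2))
  structure(list(conic = co, center = c(row = y0, col = x0), a = a, b = b,
                 eccentricity = sqrt(max(0, 1 - (b / a)^2)), valid = TRUE),
            class = "ellipse_fit")
}

#' Eccentricity of a fitted ellipse
#'
#' `E = sqrt(1 - (b/a)^2)` with `a >= b` the semi-axes: 0 for a circle,
#' approaching 1 for a degenerate (line-like) shape.  Invalid fits return 1
#' (maximally eccentric) so downstream rules reject them.
#'
#' @param fit an `ellipse_fit` from [fit_ellipse()].
#' @return eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(fit) {
  if (!isTRUE(fit$valid)) return(1)
  sqrt(max(0, 1 - (fit$b / fit$a)^2))
}

#' Shape rule: prune elongated candidates
#'
#' For every patch left in `U`, an ellipse is fitted to its boundary
#' points; patches with eccentricity `E >= t_e` are moved to `N` (masses
#' tend to be round or oval, so low eccentricity is retained).
#'
#' @param partition a `patch_partition`.
#' @param image unused (kept for a uniform stage signature).
#' @param t_e threshold (default 0.86); the boundary case `E == t_e` is
#'   rejected.
#' @return updated `patch_partition` with an `ecc` named vector attached.
#' @export
filter_shape <- function(partition, image = NULL, t_e = 0.86) {
  if (length(partition$U) == 0) return(partition)
  ecc <- vapply(partition$U, function(id) {
    p <- get_patch(partition, id)
    eccentricity(fit_ellipse(p$edge_points))
  }, numeric(1))
  names(ecc) <- partition$U
  reject <- partition$U[ecc >= t_e]
  partition$N <- c(partition$N, reject)
  partition$U <- partition$U[ecc < t_e]
  partition$ecc <- ecc
  partition
}
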