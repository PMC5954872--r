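`%||%` <- function(a, b) if (is.null(a)) b else a

## Accept either a mammogram object or a bare numeric matrix of gray levels.
as_pixels <- function(x) {
  if (inherits(x, "mammogram")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a mammogram or a numeric matrix")
}

as_mask <- function(x) {
  if (inherits(x, "breast_mask")) return(x$mask)
  if (inherits(x, "saliency_mask")) return(x$mask)
  if (is.matrix(x)) return(x != 0)
  stop("expected a mask object or matrix")
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

## Flat disk structuring element: pixels within Euclidean distance `radius`
## of the center (the convention shared with the brute-force test oracles).
disk_kernel <- function(radius) {
  stopifnot(radius >= 1)
  d <- 2L * as.integer(radius) + 1L
  ctr <- as.integer(radius) + 1L
  k <- matrix(0L, d, d)
  idx <- which(outer(seq_len(d), seq_len(d),
                     function(i, j) (i - ctr)^2 + (j - ctr)^2) <= radius^2)
  k[idx] <- 1L
  k
}

## Grayscale morphology on the 8-bit scale.  EBImage's grayscale kernels
## operate on [0, 1] images, so intensities are rescaled around the call;
## min/max morphology only ever selects input values, so integer-valued
## images are snapped back to exact integers afterwards.
gray_morph <- function(px, fun) {
  stopifnot(min(px) >= 0, max(px) <= 255)
  intish <- all(px == round(px))
  out <- matrix(fun(px / 255), nrow(px)) * 255
  if (intish) out <- round(out)
  out
}

gray_erode <- function(px, k) gray_morph(px, function(z) EBImage::erode(z, k))
gray_dilate <- function(px, k) gray_morph(px, function(z) EBImage::dilate(z, k))

## Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  if (abs(dr) >= H || abs(dc) >= W) return(out)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## 8 (or 4) connected component labelling.  EBImage::bwlabel is 4-connected;
## diagonal adjacencies are merged afterwards with a union-find pass.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  mask <- as_mask(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  n <- max(lab)
  if (connectivity == 4 || n == 0) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Run-length encoding of a logical mask (column-major), for JSON payloads.
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = as.integer(r$lengths),
       values = as.logical(r$values))
}

rle_to_mask <- function(x) {
  v <- inverse.rle(structure(list(lengths = as.integer(x$lengths),
                                  values = as.logical(x$values)),
                             class = "rle"))
  matrix(v, nrow = x$dim[1], ncol = x$dim[2])
}

## Local RNG scope: runs `expr` under `seed` and restores the caller's
## random state afterwards, so generators never leak global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a per-item seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2654435761 + i * 40503) %% 2147483647)
}
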