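## Independent brute-force oracles used across the suite.  These deliberately
## share no code with the package internals they check.

## flat-disk grayscale erosion/dilation/opening by direct neighborhood scan
oracle_disk_offsets <- function(radius) {
  d <- -radius:radius
  off <- expand.grid(dr = d, dc = d)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

## erosion = min over all disk translates (out-of-image samples ignored);
## computed by explicit shift-and-accumulate over every disk offset
oracle_shift_na <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  if (abs(dr) >= H || abs(dc) >= W) return(out)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

oracle_erode <- function(img, radius) {
  off <- oracle_disk_offsets(radius)
  out <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off))) {
    s <- oracle_shift_na(img, off$dr[k], off$dc[k])
    s[is.na(s)] <- Inf
    out <- pmin(out, s)
  }
  out
}

oracle_dilate <- function(img, radius) {
  off <- oracle_disk_offsets(radius)
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off))) {
    s <- oracle_shift_na(img, off$dr[k], off$dc[k])
    s[is.na(s)] <- -Inf
    out <- pmax(out, s)
  }
  out
}

oracle_open <- function(img, radius) oracle_dilate(oracle_erode(img, radius), radius)

## regional maxima by BFS plateau enumeration (8-connectivity)
oracle_regional_maxima <- function(img) {
  H <- nrow(img); W <- ncol(img)
  seen <- matrix(FALSE, H, W)
  out <- matrix(FALSE, H, W)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (r0 in 1:H) for (c0 in 1:W) {
    if (seen[r0, c0]) next
    v <- img[r0, c0]
    queue <- matrix(c(r0, c0), ncol = 2)
    seen[r0, c0] <- TRUE
    plateau <- queue
    is_max <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb$dr[k]; cc <- p[2] + nb$dc[k]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (img[rr, cc] > v) is_max <- FALSE
        else if (img[rr, cc] == v && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- rbind(queue, c(rr, cc))
          plateau <- rbind(plateau, c(rr, cc))
        }
      }
    }
    if (is_max) out[plateau] <- TRUE
  }
  out
}

## GLCM correlation by direct enumeration of pixel pairs
oracle_densification <- function(pixels, intensities, levels = 16,
                                 offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  rng <- range(intensities)
  q <- if (diff(rng) == 0) rep(1, length(intensities))
       else pmin(levels, floor((intensities - rng[1]) / diff(rng) * levels) + 1)
  key <- paste(pixels[, 1], pixels[, 2])
  M <- matrix(0, levels, levels)
  for (off in offsets) {
    nb <- match(paste(pixels[, 1] + off[1], pixels[, 2] + off[2]), key)
    for (i in seq_along(nb)) {
      if (is.na(nb[i])) next
      a <- q[i]; b <- q[nb[i]]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  if (sum(M) == 0) return(1)
  M <- M / sum(M)
  ui <- 0; uj <- 0
  for (i in 1:levels) for (j in 1:levels) { ui <- ui + i * M[i, j]; uj <- uj + j * M[i, j] }
  si2 <- 0; sj2 <- 0; cross <- 0
  for (i in 1:levels) for (j in 1:levels) {
    si2 <- si2 + M[i, j] * (i - ui)^2
    sj2 <- sj2 + M[i, j] * (j - uj)^2
    cross <- cross + i * j * M[i, j]
  }
  if (si2 == 0 || sj2 == 0) return(1)
  (cross - ui * uj) / sqrt(si2 * sj2)
}

## exhaustive greedy matching oracle for small Sens/FPI configurations:
## rois/gts given as overlap matrix (rows = rois)
oracle_match_counts <- function(overlaps, thr = 0.5) {
  nr <- nrow(overlaps); ng <- ncol(overlaps)
  used_r <- rep(FALSE, nr); used_g <- rep(FALSE, ng)
  repeat {
    best <- -1; bi <- 0; bj <- 0
    for (i in seq_len(nr)) for (j in seq_len(ng)) {
      if (used_r[i] || used_g[j] || overlaps[i, j] < thr) next
      if (overlaps[i, j] > best) { best <- overlaps[i, j]; bi <- i; bj <- j }
    }
    if (bi == 0) break
    used_r[bi] <- TRUE; used_g[bj] <- TRUE
  }
  c(tp = sum(used_r), fp = nr - sum(used_r))
}

## build a visual_patch-like record from a pixel matrix (row-major block)
block_patch <- function(m, r0 = 0, c0 = 0) {
  idx <- seq_along(m)
  rows <- (idx - 1) %% nrow(m) + r0
  cols <- (idx - 1) %/% nrow(m) + c0
  list(label = 1L, pixels = cbind(row = rows, col = cols),
       intensities = as.vector(m), area = length(m),
       centroid = c(mean(rows), mean(cols)))
}

## sample n points on an (a, b) ellipse rotated by theta, centered at ctr
ellipse_points <- function(n, a, b, theta = 0, ctr = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  x <- a * cos(t); y <- b * sin(t)
  xr <- x * cos(theta) - y * sin(theta)
  yr <- x * sin(theta) + y * cos(theta)
  cbind(row = yr + ctr[1], col = xr + ctr[2])
}

## desk-scale config / phantom arguments shared by pipeline-level tests
test_config <- function(...) benchmark_config(...)

test_phantom_args <- function() list()
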