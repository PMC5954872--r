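test_that("co-occurrence counts match hand-computed examples", {
  ## 2x2 patch [[0,0],[255,255]] (row-major), levels 2, horizontal offset:
  ## both row pairs co-occur within a row -> all mass split between (1,1),(2,2)
  p <- block_patch(matrix(c(0, 255, 0, 255), 2, 2))
  g <- patch_glcm(p, levels = 2, offsets = list(c(0, 1)))
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  ## constant patch: all mass on one diagonal cell
  gc <- patch_glcm(block_patch(matrix(100, 4, 4)), levels = 16)
  expect_equal(sum(diag(gc$matrix)), 1)
  expect_equal(sum(gc$matrix), 1)
  ## checkerboard, horizontal offset: all mass off-diagonal
  chk <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) * 255)
  gk <- patch_glcm(block_patch(chk), levels = 2, offsets = list(c(0, 1)))
  expect_equal(diag(gk$matrix), c(0, 0))
  expect_equal(sum(gk$matrix), 1)
  expect_error(patch_glcm(block_patch(matrix(1, 1, 2))), "area")
})

test_that("densification equals the brute-force GLCM correlation oracle", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:24, 1)
    m <- matrix(sample(0:255, n * n, TRUE), n, n)
    p <- block_patch(m)
    expect_lt(abs(as.numeric(densification(p)) -
                  oracle_densification(p$pixels, p$intensities)), 1e-9)
  }
})

test_that("densification separates smooth from noisy patches", {
  ## constant patch: 1 by the stated convention, flagged
  d <- densification(block_patch(matrix(42, 8, 8)))
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  ## smooth linear gradient: strongly correlated
  gr <- outer(seq(0, 120, length.out = 24), seq(0, 40, length.out = 24), "+")
  expect_gt(as.numeric(densification(block_patch(round(gr)))), 0.9)
  ## i.i.d. uniform noise 64x64: |Dens| < 0.2 in at least 99% of draws
  set.seed(52)
  vals <- replicate(100, {
    m <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    as.numeric(densification(block_patch(m)))
  })
  expect_gte(mean(abs(vals) < 0.2), 0.99)
})

test_that("densification rule moves sub-threshold candidates from U to N", {
  ## build a toy partition with two patches of engineered Dens
  img <- matrix(0, 48, 48)
  img[1:24, ] <- round(outer(seq(0, 200, length.out = 24), seq(0, 40, length.out = 48), "+") / 2)
  set.seed(53)
  img[25:48, ] <- matrix(sample(0:255, 24 * 48, TRUE), 24, 48)
  lab <- matrix(0L, 48, 48); lab[1:24, ] <- 1L; lab[25:48, ] <- 2L
  part <- structure(list(
    label_image = lab,
    patches = gestaltCAD:::build_patches(lab, img),
    U = c(1L, 2L), N = integer(0)), class = "patch_partition")
  out <- filter_densification(part, img, t_dens = 0.93)
  expect_equal(out$U, 1L)
  expect_equal(out$N, 2L)
  ## t_dens = 0 keeps every non-negatively-correlated patch (densification
  ## is a correlation, so pure noise can sit marginally below zero)
  out0 <- filter_densification(part, img, t_dens = 0)
  expect_true(1L %in% out0$U)
  expect_true(all(out0$dens[as.character(out0$N)] < 0))
  ## |U| is non-increasing and U/N stay disjoint
  expect_length(intersect(out$U, out$N), 0)
})

test_that("ellipse fitting recovers analytic shapes", {
  ## circle radius 20: a and b within 0.5%, eccentricity < 0.05
  pts <- ellipse_points(40, 20, 20, ctr = c(50, 60))
  fit <- fit_ellipse(pts)
  expect_true(fit$valid)
  expect_equal(fit$a, 20, tolerance = 0.005)
  expect_equal(fit$b, 20, tolerance = 0.005)
  expect_lt(fit$eccentricity, 0.05)
  expect_equal(unname(fit$center), c(50, 60), tolerance = 0.01)
  ## axis-aligned ellipse a=40 b=24 -> e = 0.8
  fit2 <- fit_ellipse(ellipse_points(60, 40, 24, ctr = c(100, 100)))
  expect_equal(fit2$eccentricity, 0.8, tolerance = 0.01)
  ## rotated ellipses, 20 random (a, b) with a/b in [1, 5]
  set.seed(54)
  for (i in 1:20) {
    b <- runif(1, 5, 30); ab <- runif(1, 1, 5); a <- b * ab
    th <- runif(1, 0, pi)
    f <- fit_ellipse(ellipse_points(30, a, b, theta = th, ctr = runif(2, 40, 80)))
    expect_true(f$valid)
    expect_equal(f$eccentricity, sqrt(1 - (b / a)^2), tolerance = 1e-2)
  }
})

test_that("degenerate boundaries yield the maximally eccentric convention", {
  f5 <- fit_ellipse(ellipse_points(5, 10, 6))
  expect_false(f5$valid)
  expect_equal(eccentricity(f5), 1)
  line <- cbind(row = 1:10, col = 2 * (1:10) + 3)
  fl <- fit_ellipse(line)
  expect_false(fl$valid)
  expect_equal(eccentricity(fl), 1)
})

test_that("eccentricity follows the closed form sqrt(1 - (b/a)^2)", {
  mk <- function(a, b) structure(list(a = a, b = b, valid = TRUE), class = "ellipse_fit")
  expect_equal(eccentricity(mk(7, 7)), 0)
  expect_equal(eccentricity(mk(5, 3)), 0.8)
  expect_equal(eccentricity(mk(1, 1e-8)), 1, tolerance = 1e-6)
})

test_that("shape rule rejects eccentric candidates with >= boundary semantics", {
  ## a round blob patch stays; an 8:1 strip is rejected
  img <- matrix(0, 80, 80)
  rr <- matrix(0:79, 80, 80); cc <- t(rr)
  blob <- (rr - 20)^2 + (cc - 20)^2 <= 12^2
  strip <- abs(rr - 60) <= 3 & cc >= 8 & cc <= 56     # 49x7 -> aspect 8:1
  lab <- matrix(0L, 80, 80); lab[blob] <- 1L; lab[strip] <- 2L
  part <- structure(list(label_image = lab,
                         patches = gestaltCAD:::build_patches(lab, img),
                         U = c(1L, 2L), N = integer(0)),
                    class = "patch_partition")
  out <- filter_shape(part, img, t_e = 0.86)
  expect_equal(out$U, 1L)
  expect_equal(out$N, 2L)
  expect_gt(out$ecc[["2"]], 0.95)    # analytic 8:1 strip: e ~ 0.992
  ## boundary case: E == t_e is rejected (rule uses >=)
  out_eq <- filter_shape(part, img, t_e = out$ecc[["1"]])
  expect_false(1L %in% out_eq$U)
})

test_that("semantic filters only move ids U -> N, monotonically", {
  ph <- generate_phantom(do.call(phantom_spec, c(test_phantom_args(), list(seed = 77))))
  breast <- segment_breast(ph$image)
  enh <- enhance_mammogram(ph$image, breast, 30)
  sal <- salient_regions(open_with_disk(enh, 6), breast, 0.5)
  part <- cluster_patches(enh, sal, breast, test_config())
  raw <- ph$image$pixels
  p2 <- filter_densification(part, raw, 0.93)
  p3 <- filter_shape(p2, raw, 0.86)
  expect_true(all(p2$U %in% part$U))
  expect_true(all(p3$U %in% p2$U))
  expect_lte(length(p2$U), length(part$U))
  expect_lte(length(p3$U), length(p2$U))
  expect_length(intersect(p3$U, p3$N), 0)
  expect_setequal(c(p3$U, p3$N), part$U)
})
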