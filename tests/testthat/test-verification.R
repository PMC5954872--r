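test_that("feature extraction matches closed forms on degenerate patches", {
  f <- extract_features(block_patch(matrix(100, 6, 6)))
  expect_equal(unname(f["gray_mean"]), 100)
  expect_equal(unname(f["gray_variance"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  ## two-valued {0, 255} with equal counts
  f2 <- extract_features(block_patch(matrix(c(0, 255), 4, 4)))
  expect_equal(unname(f2["gray_mean"]), 127.5)
  expect_equal(unname(f2["rms"]), sqrt((0^2 + 255^2) / 2))
  expect_equal(unname(f2["entropy"]), 1)   # two equiprobable levels
})

test_that("all 12 features match an independent per-formula recomputation", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    m <- matrix(sample(0:255, n * n, TRUE), n, n)
    p <- block_patch(m)
    f <- extract_features(p)
    x <- as.vector(m)
    mu <- mean(x); v <- mean((x - mu)^2)
    expect_equal(unname(f["gray_mean"]), mu)
    expect_equal(unname(f["gray_variance"]), v)
    expect_equal(unname(f["standard_deviation"]), sqrt(v))
    expect_equal(unname(f["kurtosis"]), mean((x - mu)^4) / v^2)
    expect_equal(unname(f["skewness"]), mean((x - mu)^3) / v^1.5)
    tab <- table(x) / length(x)
    expect_equal(unname(f["entropy"]), -sum(tab * log2(tab)))
    expect_equal(unname(f["rms"]), sqrt(mean(x^2)))
    ## GLCM-derived features recomputed from the oracle matrix
    g <- patch_glcm(p, levels = 16)$matrix
    ii <- matrix(1:16, 16, 16); jj <- t(ii)
    expect_equal(unname(f["contrast"]), sum((ii - jj)^2 * g))
    expect_equal(unname(f["energy"]), sum(g^2))
    expect_equal(unname(f["homogeneity"]), sum(g / (1 + abs(ii - jj))))
    expect_equal(unname(f["inverse_difference_moment"]), sum(g / (1 + (ii - jj)^2)))
    expect_lt(abs(unname(f["correlation"]) -
                  oracle_densification(p$pixels, p$intensities)), 1e-9)
  }
})

make_toy_partition <- function() {
  ## 2x3 grid of 10x10 patches with controlled intensities
  img <- matrix(0, 20, 30)
  lab <- matrix(0L, 20, 30)
  vals <- c(100, 102, 220, 100, 104, 30)
  k <- 0
  for (c0 in c(0, 10, 20)) for (r0 in c(0, 10)) {
    k <- k + 1
    set.seed(60 + k)
    img[r0 + 1:10, c0 + 1:10] <- vals[k] + sample(0:3, 100, TRUE)
    lab[r0 + 1:10, c0 + 1:10] <- k
  }
  list(img = img,
       part = structure(list(label_image = lab,
                             patches = gestaltCAD:::build_patches(lab, img),
                             U = integer(0), N = integer(0)),
                        class = "patch_partition"))
}

test_that("ROI growing merges similar adjacent patches and averages their features", {
  tp <- make_toy_partition()
  part <- tp$part
  ## patches 1,2 similar and adjacent; 3 is a bright outlier
  part$U <- c(1L, 2L)
  rois <- grow_rois(part, image = tp$img, tau = 0.5)
  expect_length(rois, 1)
  expect_true(all(c(1L, 2L) %in% rois[[1]]$patch_ids))
  expect_false(3L %in% rois[[1]]$patch_ids)
  ## ROI features are the exact arithmetic mean of member features
  fs <- t(vapply(rois[[1]]$patch_ids, function(id)
    extract_features(gestaltCAD:::get_patch(part, id), tp$img), numeric(12)))
  expect_equal(rois[[1]]$features, colMeans(fs), tolerance = 1e-12)
  ## mask is the union of member pixels and is connected
  expect_equal(sum(rois[[1]]$mask), 100 * length(rois[[1]]$patch_ids))
  expect_equal(max(gestaltCAD:::label_components(rois[[1]]$mask, 8)), 1)
})

test_that("two far-apart seeds give two ROIs; empty U gives none", {
  tp <- make_toy_partition()
  part <- tp$part
  part$U <- c(3L, 6L)                      # bright and dark corners
  rois <- grow_rois(part, image = tp$img, tau = 0.3)
  expect_length(rois, 2)
  part$U <- integer(0)
  expect_length(grow_rois(part, image = tp$img), 0)
  ## identical adjacent patches: single ROI, averaging leaves features fixed
  tp2 <- make_toy_partition()
  img2 <- tp2$img
  img2[lab_idx <- tp2$part$label_image %in% c(1, 2)] <- 100
  part2 <- tp2$part
  part2$patches <- gestaltCAD:::build_patches(part2$label_image, img2)
  part2$U <- c(1L, 2L)
  rois2 <- grow_rois(part2, image = img2, tau = 0.5)
  one <- rois2[[1]]
  expect_equal(sort(one$patch_ids[1:2]), c(1L, 2L))
  f1 <- extract_features(gestaltCAD:::get_patch(part2, 1L), img2)
  expect_equal(one$features[["gray_mean"]], f1[["gray_mean"]])
})

test_that("the area cap bounds ROI growth", {
  tp <- make_toy_partition()
  part <- tp$part
  part$U <- 1L
  rois <- grow_rois(part, image = tp$img, tau = 10, max_patches = 2)
  expect_lte(length(rois[[1]]$patch_ids), 2)
})

test_that("kernel ELM separates well-separated clouds and is deterministic", {
  set.seed(62)
  n <- 100
  X <- rbind(matrix(rnorm(n * 12), n, 12), matrix(rnorm(n * 12, mean = 6), n, 12))
  y <- rep(c(FALSE, TRUE), each = n)
  m <- elm_train(X, y, c = 10, gamma = 0.01)
  pr <- elm_predict(m, X)
  expect_equal(mean(pr$label == y), 1)                      # 100% training accuracy
  ## support point of the positive class scores positive
  expect_gt(elm_predict(m, X[n + 1, , drop = FALSE])$score, 0)
  ## permutation invariance of predictions
  set.seed(63)
  perm <- sample(2 * n)
  m2 <- elm_train(X[perm, ], y[perm], c = 10, gamma = 0.01)
  expect_equal(elm_predict(m2, X)$score, elm_predict(m, X)$score, tolerance = 1e-10)
})

test_that("conflicting duplicate labels average to a near-zero score", {
  set.seed(64)
  X <- matrix(rnorm(20 * 12), 20, 12)
  X[2, ] <- X[1, ]
  y <- rep(c(TRUE, FALSE), 10)
  y[1] <- TRUE; y[2] <- FALSE                               # identical points, opposite labels
  m <- elm_train(X, y, c = 10, gamma = 0.1)
  s <- elm_predict(m, X[1, , drop = FALSE])$score
  expect_lt(abs(s), 0.2)
})

test_that("the C -> Inf limit interpolates an exactly solvable set", {
  set.seed(65)
  X <- matrix(rnorm(8 * 12), 8, 12)
  y <- rep(c(TRUE, FALSE), 4)
  m <- elm_train(X, y, c = 1e10, gamma = 0.05)
  s <- elm_predict(m, X)$score
  expect_equal(s, ifelse(y, 1, -1), tolerance = 1e-6)
})

test_that("elm_train validates labels", {
  X <- matrix(rnorm(10 * 12), 10, 12)
  expect_error(elm_train(X, rep(TRUE, 10)), "single class")
  expect_error(elm_train(X, c(TRUE, rep(FALSE, 9))), "2 examples")
})

test_that("stratified cross-validation balances folds and finds signal", {
  set.seed(66)
  X <- matrix(rnorm(100 * 12), 100, 12)
  y <- rep(c(TRUE, FALSE), 50)
  X[y, 1] <- X[y, 1] + 50                                   # label encoded in feature 1
  cv <- crossval_10fold(X, y, seed = 9)
  expect_equal(cv$k, 10)
  tab <- table(cv$fold)
  expect_true(all(tab >= 9 & tab <= 11))
  for (f in 1:10) expect_gte(min(table(y[cv$fold == f])), 1)
  expect_equal(cv$accuracy, 1)
  expect_equal(sum(cv$confusion), 100)
  ## fold reduction warns when the rarer class is small
  y2 <- c(rep(TRUE, 5), rep(FALSE, 95))
  X2 <- X; X2[y2, ] <- X2[y2, ] + 10
  expect_warning(cv2 <- crossval_10fold(X2, y2, seed = 9), "reducing folds")
  expect_equal(cv2$k, 5)
})
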