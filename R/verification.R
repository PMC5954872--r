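#' Names and order of the 12 texture features
#' @export
feature_names <- function() {
  c("gray_mean", "gray_variance", "contrast", "correlation", "energy",
    "homogeneity", "standard_deviation", "inverse_difference_moment",
    "kurtosis", "skewness", "entropy", "rms")
}

#' Extract the 12-dimensional texture feature vector of a patch
#'
#' First-order statistics (mean, variance, standard deviation, kurtosis,
#' skewness, entropy, root mean square) are computed on the raw patch
#' intensities (entropy on the 256-level histogram, population moments);
#' second-order statistics (contrast, correlation, energy, homogeneity,
#' inverse difference moment) come from the patch co-occurrence matrix of
#' [patch_glcm()].  Degenerate (constant) patches get variance 0, entropy
#' 0, kurtosis/skewness 0 and co-occurrence energy 1; no error is raised.
#'
#' @param patch a `visual_patch`.
#' @param image image matrix (see [patch_glcm()]).
#' @param levels co-occurrence quantization levels.
#' @return named numeric vector in the fixed order of [feature_names()].
#' @export
extract_features <- function(patch, image = NULL, levels = 16) {
  ints <- if (!is.null(image))
    as_pixels(image)[cbind(patch$pixels[, 1] + 1, patch$pixels[, 2] + 1)]
  else patch$intensities
  n <- length(ints)
  mu <- mean(ints)
  v <- mean((ints - mu)^2)
  sdv <- sqrt(v)
  kur <- if (sdv == 0) 0 else mean((ints - mu)^4) / sdv^4
  ske <- if (sdv == 0) 0 else mean((ints - mu)^3) / sdv^3
  p <- tabulate(as.integer(round(ints)) + 1L, nbins = 256) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  rms <- sqrt(mean(ints^2))
  if (n >= 4) {
    g <- patch_glcm(patch, image, levels = levels)
  } else {
    ## sub-texture speck: same co-occurrence statistics as a constant patch
    g <- structure(list(matrix = diag(c(1, rep(0, levels - 1))), levels = levels,
                        offsets = list(), symmetric = TRUE), class = "glcm_matrix")
  }
  M <- g$matrix
  L <- g$levels
  i <- matrix(seq_len(L), L, L); j <- t(i)
  corr <- as.numeric(densification(glcm = g))
  out <- c(mu, v,
           sum((i - j)^2 * M),          # contrast
           corr,                        # correlation (= densification)
           sum(M^2),                    # energy
           sum(M / (1 + abs(i - j))),   # homogeneity
           sdv,
           sum(M / (1 + (i - j)^2)),    # inverse difference moment
           kur, ske, ent, rms)
  names(out) <- feature_names()
  out
}

#' Grow regions of interest from surviving candidate patches
#'
#' Patches left in `U` seed a region-growing agglomeration, visited in
#' increasing id order.  A growing ROI absorbs spatially adjacent patches
#' (sharing a boundary in the label image) -- candidates are all patches of
#' the partition, not just `U`, so a confident seed recovers the full
#' extent of a mass whose peripheral fragments were pruned -- while the
#' candidate's standardized feature distance to the ROI's running mean
#' stays within `tau`, iterating to a fixpoint.  Each patch joins at most
#' one ROI.  The ROI feature vector is the arithmetic mean of the member
#' patch vectors (raw scale); z-scores over all partition patches are used
#' only for the distance test.
#'
#' @param partition a `patch_partition` after the semantic stage.
#' @param features named matrix of per-patch feature vectors (rows named by
#'   patch id, covering at least all partition patches); computed on the
#'   fly when `NULL`.
#' @param image image matrix (used when computing features).
#' @param tau standardized-distance threshold (default 1.0).
#' @param max_patches maximal number of patches per ROI (area cap).
#' @param seed_priority optional named numeric (by patch id); seeds are
#'   visited in decreasing priority (e.g. densification value) so stronger
#'   candidates claim contested territory first.  Default: increasing id.
#' @param levels co-occurrence quantization levels.
#' @return list of `roi` objects: `patch_ids`, `seed_ids`, `mask`,
#'   `features`, `score` (NA until classified), `label` (`"unlabeled"`).
#' @export
grow_rois <- function(partition, features = NULL, image = NULL, tau = 1.0,
                      levels = 16, max_patches = 40, seed_priority = NULL) {
  U <- sort(partition$U)
  if (length(U) == 0) return(list())
  if (!is.null(seed_priority)) {
    pr <- seed_priority[as.character(U)]
    pr[is.na(pr)] <- -Inf
    U <- U[order(-pr, U)]    # strongest candidates claim territory first
  }
  all_ids <- vapply(partition$patches, `[[`, integer(1), "label")
  if (is.null(features)) {
    features <- t(vapply(partition$patches, function(p)
      extract_features(p, image, levels = levels), numeric(12)))
    rownames(features) <- all_ids
  } else {
    features <- as.matrix(features)[as.character(all_ids), , drop = FALSE]
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  adj <- patch_adjacency(partition$label_image)
  assigned <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  rois <- list()
  for (seed in U) {
    if (assigned[as.character(seed)]) next
    members <- seed
    assigned[as.character(seed)] <- TRUE
    ## compact absorption: among neighbors within the feature threshold,
    ## admit the one spatially closest to the seed, update the running
    ## mean, stop when no neighbor qualifies or at the area cap (masses
    ## have bounded extent; the cap also prevents chains of mutually
    ## similar background patches from merging breast-wide)
    seed_ctr <- get_patch(partition, seed)$centroid
    repeat {
      if (length(members) >= max_patches) break
      zmean <- colMeans(Z[as.character(members), , drop = FALSE])
      nbrs <- unique(unlist(adj[as.character(members)]))
      nbrs <- nbrs[nbrs %in% all_ids & !assigned[as.character(nbrs)]]
      if (length(nbrs) == 0) break
      d <- vapply(as.character(nbrs), function(id)
        sqrt(mean((Z[id, ] - zmean)^2)), numeric(1))   # RMS over feature dims
      ok <- nbrs[d <= tau]
      if (length(ok) == 0) break
      sp <- vapply(ok, function(id)
        sum((get_patch(partition, id)$centroid - seed_ctr)^2), numeric(1))
      take <- ok[which.min(sp)]
      members <- c(members, take)
      assigned[as.character(take)] <- TRUE
    }
    mask <- matrix(FALSE, nrow(partition$label_image), ncol(partition$label_image))
    for (id in members) mask[get_patch(partition, id)$index] <- TRUE
    rois[[length(rois) + 1]] <- structure(
      list(patch_ids = sort(as.integer(members)),
           seed_ids = seed,
           mask = mask,
           features = colMeans(features[as.character(members), , drop = FALSE]),
           score = NA_real_, label = "unlabeled"),
      class = "roi")
  }
  rois
}

## Adjacency between patch labels: pairs of distinct nonzero labels that
## touch through a 4-neighbor edge in the label image.
patch_adjacency <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(cbind(as.vector(lab[-H, ]), as.vector(lab[-1, ])),
                 cbind(as.vector(lab[, -W]), as.vector(lab[, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1]))
  split(as.integer(pairs[, 2]), as.character(pairs[, 1]))
}

#' Train a kernel extreme learning machine
#'
#' The deterministic kernel variant of the ELM: with standardized features
#' and RBF kernel `Omega(i,j) = exp(-gamma * ||x_i - x_j||^2)`, the output
#' weights solve `(I / C + Omega) beta = t` for targets `t = +-1`.  No
#' random hidden layer is involved, so training is reproducible from the
#' inputs alone.
#'
#' @param X numeric matrix (n x d) of feature vectors.
#' @param y binary labels (logical, 0/1, or two-level factor); the positive
#'   class is `TRUE` / `1` / the second factor level.
#' @param c regularization trade-off (default 10).
#' @param gamma RBF kernel parameter (default 0.01).
#' @return object of class `elm_model` with the support features (already
#'   standardized), output weights `beta` and the stored per-feature
#'   center/scale.
#' @export
elm_train <- function(X, y, c = 10, gamma = 0.01) {
  X <- as.matrix(X)
  yb <- as_binary_labels(y)
  if (length(unique(yb)) < 2) stop("training labels contain a single class")
  if (min(table(yb)) < 2) stop("need at least 2 examples per class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Omega <- rbf_kernel(Xs, Xs, gamma)
  t_targets <- ifelse(yb, 1, -1)
  beta <- solve(diag(nrow(Xs)) / c + Omega, t_targets)
  structure(list(kernel = "rbf", gamma = gamma, c = c,
                 support_features = Xs, beta = as.numeric(beta),
                 center = ctr, scale = scl),
            class = "elm_model")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("labels must be binary")
    y == levels(y)[2]
  } else if (is.logical(y)) y
  else if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    y == 1
  } else stop("unsupported label type")
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Predict with a kernel ELM
#'
#' @param model an `elm_model`.
#' @param X feature matrix (raw scale; the model's standardization is
#'   applied).
#' @return list with `score` (real decision values, `k(x, support) %*%
#'   beta`) and `label` (logical, `score > 0`).
#' @export
elm_predict <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  K <- rbf_kernel(Xs, model$support_features, model$gamma)
  score <- as.numeric(K %*% model$beta)
  list(score = score, label = score > 0)
}

#' Stratified k-fold cross-validation of the kernel ELM
#'
#' Fold assignment is stratified per class from an explicit seed.  When the
#' rarer class has fewer members than `k`, the number of folds is reduced
#' (with a warning) so every fold can hold both classes.  Returns
#' out-of-fold scores and predictions for every example plus pooled
#' confusion counts.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param c,gamma ELM hyperparameters.
#' @param seed integer seed driving the fold shuffle.
#' @param k requested number of folds (default 10).
#' @return list: `fold` (per-example fold id), `score`, `pred` (logical),
#'   `confusion` (tp/fp/tn/fn), `accuracy`, `per_fold_accuracy`, `k`.
#' @export
crossval_10fold <- function(X, y, c = 10, gamma = 0.01, seed = 1, k = 10) {
  X <- as.matrix(X)
  yb <- as_binary_labels(y)
  n <- nrow(X)
  npos <- sum(yb); nneg <- n - npos
  if (min(npos, nneg) < 2) stop("need at least 2 examples per class")
  keff <- min(k, npos, nneg)
  if (keff < k)
    warning(sprintf("reducing folds from %d to %d (rarer class has %d members)",
                    k, keff, min(npos, nneg)))
  fold <- integer(n)
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(yb == cls))
      fold[idx] <- rep_len(seq_len(keff), length(idx))
    }
  })
  score <- numeric(n); pred <- logical(n)
  for (f in seq_len(keff)) {
    tr <- fold != f; te <- !tr
    m <- elm_train(X[tr, , drop = FALSE], yb[tr], c = c, gamma = gamma)
    p <- elm_predict(m, X[te, , drop = FALSE])
    score[te] <- p$score; pred[te] <- p$label
  }
  conf <- c(tp = sum(pred & yb), fp = sum(pred & !yb),
            tn = sum(!pred & !yb), fn = sum(!pred & yb))
  per_fold <- vapply(seq_len(keff), function(f)
    mean(pred[fold == f] == yb[fold == f]), numeric(1))
  list(fold = fold, score = score, pred = pred, confusion = conf,
       accuracy = mean(pred == yb), per_fold_accuracy = per_fold, k = keff)
}
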