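#' Run the full three-stage mass detection pipeline on one image
#'
#' Stage order: breast segmentation -> (optional) pectoral removal ->
#' morphological enhancement -> attention (opening + regional maxima) ->
#' visual patch generation (candidate set `U`) -> densification rule ->
#' shape rule -> texture features -> ROI growing -> (when a model is
#' given) kernel-ELM classification.  Without a model the result holds the
#' post-shape candidate ROIs unclassified.  An empty candidate set at any
#' stage short-circuits to an empty, valid result.
#'
#' @param image a [mammogram].
#' @param config a [cad_config()].
#' @param model optional `elm_model` for the verification stage.
#' @param gts optional list of [gt_region]s; when present, per-stage
#'   positive/negative accounting is recorded in the provenance (a patch
#'   counts as positive when at least half of its pixels lie inside a
#'   ground-truth region; an ROI when it meets the 50% overlap rule).
#' @return object of class `detection_result`: `id`, `rois` (scored and
#'   labeled when a model was given), `provenance` (`patch_counts`,
#'   `roi_counts`, config snapshot), `partition`, `breast`, `saliency`.
#' @export
detect_masses <- function(image, config = cad_config(), model = NULL,
                          gts = NULL) {
  stopifnot(inherits(image, "mammogram"))
  breast <- segment_breast(image)
  if (config$pectoral_removal) breast <- remove_pectoral(image, breast)
  enhanced <- if (config$enable_enhancement)
    enhance_mammogram(image, breast, radius = config$enhance_radius)
  else { tmp <- image; tmp$pixels[!breast$mask] <- 0; tmp }
  opened <- open_with_disk(enhanced, radius = config$opening_radius)
  sal <- if (config$enable_attention)
    salient_regions(opened, breast, config$attention_threshold)
  else structure(list(mask = breast$mask, n_components = 1L, peaks = numeric(0)),
                 class = "saliency_mask")
  part <- cluster_patches(enhanced, sal, breast, config)
  ## semantic and texture statistics are measured on the raw intensities:
  ## the enhancement exists to drive attention and patch grouping, and
  ## would otherwise amplify film noise into every texture feature
  px <- as_pixels(image)
  gmasks <- if (!is.null(gts)) lapply(gts, gt_mask, dim = dim(px)) else NULL
  patch_pos <- function(ids) {
    if (is.null(gmasks) || length(ids) == 0) return(0L)
    sum(vapply(ids, function(id) {
      p <- get_patch(part, id)
      any(vapply(gmasks, function(g) sum(g[p$index]) >= p$area / 2, logical(1)))
    }, logical(1)))
  }
  counts <- matrix(0, 3, 3, dimnames = list(c("total", "positive", "negative"),
                                            c("attention", "densification", "shape")))
  snap <- function(stage) {
    pos <- patch_pos(part$U)
    counts["total", stage] <<- length(part$U)
    counts["positive", stage] <<- pos
    counts["negative", stage] <<- length(part$U) - pos
  }
  snap("attention")
  if (config$enable_densification && length(part$U) > 0)
    part <- filter_densification(part, px, t_dens = config$t_dens,
                                 levels = config$glcm_levels)
  snap("densification")
  if (config$enable_shape && length(part$U) > 0)
    part <- filter_shape(part, px, t_e = config$t_e)
  snap("shape")
  rois <- grow_rois(part, image = px, tau = config$roi_tau,
                    levels = config$glcm_levels,
                    max_patches = config$roi_max_patches,
                    seed_priority = part$dens)
  roi_pos <- function(rs) {
    if (is.null(gts) || length(rs) == 0) return(0L)
    mr <- match_regions(rs, gts, dim = dim(px),
                        overlap_min = config$overlap_min,
                        denominator = config$overlap_denominator)
    mr$tp
  }
  rc <- matrix(0, 3, 2, dimnames = list(c("total", "positive", "negative"),
                                        c("rois", "texture")))
  rc["total", "rois"] <- length(rois)
  rc["positive", "rois"] <- roi_pos(rois)
  rc["negative", "rois"] <- length(rois) - rc["positive", "rois"]
  if (!is.null(model) && config$enable_texture && length(rois) > 0) {
    X <- do.call(rbind, lapply(rois, `[[`, "features"))
    pr <- elm_predict(model, X)
    for (i in seq_along(rois)) {
      rois[[i]]$score <- pr$score[i]
      rois[[i]]$label <- if (pr$label[i]) "mass" else "normal"
    }
    kept <- rois[pr$label]
  } else kept <- rois
  rc["total", "texture"] <- length(kept)
  rc["positive", "texture"] <- roi_pos(kept)
  rc["negative", "texture"] <- length(kept) - rc["positive", "texture"]
  structure(list(id = image$id, rois = kept, all_rois = rois,
                 provenance = list(patch_counts = counts, roi_counts = rc,
                                   config = unclass(config)),
                 partition = part, breast = breast, saliency = sal),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result '%s'> %d ROI(s); patches %d -> %d -> %d\n",
              x$id, length(x$rois),
              x$provenance$patch_counts["total", "attention"],
              x$provenance$patch_counts["total", "densification"],
              x$provenance$patch_counts["total", "shape"]))
  invisible(x)
}

#' Train the verification classifier on a labeled dataset
#'
#' Runs the first two stages on every image, labels the candidate ROIs by
#' the 50% overlap rule against the annotations, trains the kernel ELM on
#' the ROI feature vectors and evaluates it by stratified 10-fold
#' cross-validation.  The pooled report scores an ROI as a detection mark
#' only when its out-of-fold prediction is positive.
#'
#' @param dataset either a directory written by [make_benchmark()] or an
#'   in-memory list of records with fields `image` and `gts`.
#' @param config a [cad_config()].
#' @param seed integer seed for the fold shuffle.
#' @return list: `model` (ELM trained on all ROIs), `cv` (from
#'   [crossval_10fold()]), `report` (pooled `sens`/`fpi` and per-stage
#'   [stage_report()]), `rois` (data frame of per-ROI image, label, score).
#' @export
train_detector <- function(dataset, config = cad_config(), seed = 1) {
  records <- load_dataset(dataset)
  feats <- list(); labels <- logical(0); img_of <- integer(0)
  provs <- list(); dets <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    det <- detect_masses(r$image, config, gts = r$gts)
    dets[[i]] <- det
    provs[[i]] <- det$provenance
    if (length(det$rois) > 0) {
      mr <- match_regions(det$rois, r$gts, dim = dim(r$image$pixels),
                          overlap_min = config$overlap_min,
                          denominator = config$overlap_denominator)
      pos <- rep(FALSE, length(det$rois))
      if (nrow(mr$pairs) > 0) pos[mr$pairs[, "roi"]] <- TRUE
      for (j in seq_along(det$rois)) {
        feats[[length(feats) + 1]] <- det$rois[[j]]$features
        labels <- c(labels, pos[j])
        img_of <- c(img_of, i)
      }
    }
  }
  if (sum(labels) == 0)
    stop("no positive ROIs in the dataset; cannot train the classifier")
  X <- do.call(rbind, feats)
  cv <- crossval_10fold(X, labels, c = config$elm_c, gamma = config$elm_gamma,
                        seed = seed)
  model <- elm_train(X, labels, c = config$elm_c, gamma = config$elm_gamma)
  ## pooled Sens/FPI from out-of-fold predictions
  results <- lapply(seq_along(records), function(i) {
    keep <- which(img_of == i & cv$pred)
    rois <- lapply(keep, function(k) {
      idx_in_img <- which(img_of == i)
      dets[[i]]$rois[[match(k, idx_in_img)]]
    })
    for (j in seq_along(rois)) rois[[j]]$score <- cv$score[keep[j]]
    match_regions(rois, records[[i]]$gts, dim = dim(records[[i]]$image$pixels),
                  overlap_min = config$overlap_min,
                  denominator = config$overlap_denominator)
  })
  pooled <- sens_fpi(results)
  list(model = model, cv = cv,
       report = list(sens = unname(pooled["sens"]), fpi = unname(pooled["fpi"]),
                     stage_table = stage_report(provs)),
       rois = data.frame(image = img_of, label = labels,
                         score = cv$score, pred = cv$pred),
       detections = dets, match_results = results)
}

## Accept a directory (written by make_benchmark) or an in-memory record list.
load_dataset <- function(dataset) {
  if (is.character(dataset)) {
    man <- read.csv(file.path(dataset, "manifest.csv"), stringsAsFactors = FALSE)
    lapply(seq_len(nrow(man)), function(i) {
      img <- read_mammogram(file.path(dataset, paste0(man$id[i], ".png")))
      ann <- file.path(dataset, paste0(man$id[i], ".txt"))
      gts <- if (file.exists(ann)) read_annotations(ann, img) else list()
      list(image = img, gts = gts, density = man$density[i],
           normal = man$normal[i])
    })
  } else dataset
}

#' Evaluate a trained detector on a dataset
#'
#' Runs the full pipeline (including ELM classification) on every image
#' and pools the 50%-rule match results.
#'
#' @param dataset directory or in-memory record list.
#' @param model an `elm_model`.
#' @param config a [cad_config()].
#' @return list: `sens`, `fpi`, `per_image` (match results), `detections`,
#'   `froc` (a [froc_curve()]).
#' @export
evaluate_detector <- function(dataset, model, config = cad_config()) {
  records <- load_dataset(dataset)
  dets <- lapply(records, function(r)
    detect_masses(r$image, config, model = model, gts = r$gts))
  results <- lapply(seq_along(records), function(i)
    match_regions(dets[[i]]$rois, records[[i]]$gts,
                  dim = dim(records[[i]]$image$pixels),
                  overlap_min = config$overlap_min,
                  denominator = config$overlap_denominator))
  pooled <- sens_fpi(results)
  fr <- froc_curve(lapply(dets, function(d) {
    rs <- d$all_rois
    rs[vapply(rs, function(r) !is.na(r$score), logical(1))]
  }),
  lapply(records, `[[`, "gts"),
  lapply(records, function(r) dim(r$image$pixels)),
  overlap_min = config$overlap_min,
  denominator = config$overlap_denominator)
  list(sens = unname(pooled["sens"]), fpi = unname(pooled["fpi"]),
       per_image = results, detections = dets, froc = fr)
}
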