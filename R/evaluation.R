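#' Match detected ROIs against ground-truth regions (50% rule)
#'
#' A detection is a true-positive mark when its overlap ratio with a
#' ground-truth region reaches `overlap_min` (default 0.5).  The ratio is
#' `|roi  intersect gt| / |gt|` by default (`"gt"` denominator; circles are
#' rasterized as needed) or intersection-over-union with
#' `denominator = "iou"`.  Each ground-truth region is matched at most
#' once, greedily by descending overlap (ties broken by lower roi id, then
#' lower gt id); every unmatched ROI counts as a false positive.
#'
#' @param rois list of `roi` objects (with `mask`).
#' @param gts list of [gt_region]s for the same image.
#' @param dim image dimensions `(H, W)`; taken from the first ROI mask if
#'   omitted.
#' @param overlap_min minimal overlap ratio (default 0.5).
#' @param denominator `"gt"` or `"iou"`.
#' @return object of class `match_result`: `tp`, `fp`, `n_regions`,
#'   `n_images = 1`, `pairs` (matrix of roi/gt indices and overlaps).
#' @export
match_regions <- function(rois, gts, dim = NULL, overlap_min = 0.5,
                          denominator = c("gt", "iou")) {
  denominator <- match.arg(denominator)
  if (is.null(dim)) {
    if (length(rois) > 0) dim <- dim(rois[[1]]$mask)
    else if (length(gts) > 0 && !is.null(gts[[1]]$mask)) dim <- dim(gts[[1]]$mask)
    else dim <- c(0, 0)
  }
  nr <- length(rois); ng <- length(gts)
  gmasks <- lapply(gts, gt_mask, dim = dim)
  ov <- matrix(0, nrow = nr, ncol = max(1, ng))
  if (nr > 0 && ng > 0) {
    for (i in seq_len(nr)) for (j in seq_len(ng)) {
      inter <- sum(rois[[i]]$mask & gmasks[[j]])
      den <- if (denominator == "gt") sum(gmasks[[j]])
             else sum(rois[[i]]$mask | gmasks[[j]])
      ov[i, j] <- if (den > 0) inter / den else 0
    }
  }
  pairs <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("roi", "gt", "overlap")))
  used_roi <- logical(nr); used_gt <- logical(ng)
  if (nr > 0 && ng > 0) {
    cand <- which(ov >= overlap_min, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      o <- ov[cand]
      ord <- order(-o, cand[, 1], cand[, 2])
      for (idx in ord) {
        i <- cand[idx, 1]; j <- cand[idx, 2]
        if (used_roi[i] || used_gt[j]) next
        used_roi[i] <- TRUE; used_gt[j] <- TRUE
        pairs <- rbind(pairs, c(i, j, ov[i, j]))
      }
    }
  }
  structure(list(tp = sum(used_roi), fp = nr - sum(used_roi),
                 n_regions = ng, n_images = 1L, pairs = pairs),
            class = "match_result")
}

#' Pooled sensitivity and false positives per image
#'
#' `Sens = true positive marks / ground-truth regions` and `FPI = false
#' positive marks / images`, pooled over a list of per-image match
#' results.  With no ground-truth regions at all, sensitivity is reported
#' as 0.
#'
#' @param results list of `match_result`s (one per image).
#' @return named numeric `c(sens, fpi)`.
#' @export
sens_fpi <- function(results) {
  if (inherits(results, "match_result")) results <- list(results)
  tp <- sum(vapply(results, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(results, `[[`, numeric(1), "fp"))
  ng <- sum(vapply(results, `[[`, numeric(1), "n_regions"))
  ni <- sum(vapply(results, `[[`, numeric(1), "n_images"))
  c(sens = if (ng > 0) tp / ng else 0,
    fpi = if (ni > 0) fp / ni else 0)
}

#' FROC curve over classifier score thresholds
#'
#' Sweeps the ROI decision threshold from the highest observed score down;
#' at each threshold the ROIs scoring at or above it are matched per image
#' by the 50% rule and pooled into one `(FPI, Sens)` operating point.
#' By construction both coordinates are non-decreasing along the curve.
#'
#' @param detections list (one entry per image) of lists of scored `roi`s.
#' @param gts list (same length) of lists of [gt_region]s.
#' @param dims list of image dimensions, or a single `(H, W)`.
#' @param overlap_min,denominator matching parameters.
#' @return object of class `froc_curve`: data frame `points` with columns
#'   `threshold`, `fpi`, `sens`.
#' @export
froc_curve <- function(detections, gts, dims, overlap_min = 0.5,
                       denominator = "gt") {
  stopifnot(length(detections) == length(gts))
  if (!is.list(dims[[1]]) && !is.list(dims)) dims <- rep(list(dims), length(gts))
  scores <- unlist(lapply(detections, function(rs)
    vapply(rs, `[[`, numeric(1), "score")))
  thr <- if (length(scores) == 0) NA_real_ else sort(unique(scores), decreasing = TRUE)
  pts <- lapply(thr, function(t) {
    res <- lapply(seq_along(detections), function(i) {
      keep <- if (is.na(t)) detections[[i]] else
        Filter(function(r) !is.na(r$score) && r$score >= t, detections[[i]])
      match_regions(keep, gts[[i]], dim = dims[[i]],
                    overlap_min = overlap_min, denominator = denominator)
    })
    sens_fpi(res)
  })
  pts <- do.call(rbind, pts)
  structure(list(points = data.frame(threshold = thr,
                                     fpi = pts[, "fpi"], sens = pts[, "sens"])),
            class = "froc_curve")
}

#' Per-stage candidate accounting
#'
#' Summarizes how many candidates (total, overlapping a true mass, and
#' normal) survive each stage of the pipeline, in the style of a stagewise
#' ablation table: patch counts through attention, densification and shape,
#' and ROI counts before and after the texture (classifier) stage.
#' Percentages are relative to the attention-stage counts.
#'
#' @param provenances list of per-image provenance records as produced by
#'   [detect_masses()] (each carrying `patch_counts` and `roi_counts`).
#' @return data frame with columns `unit`, `stage`, `total`, `positive`,
#'   `negative`, `pct_total`, `pct_positive`, `pct_negative`.
#' @export
stage_report <- function(provenances) {
  if (!is.null(provenances$patch_counts)) provenances <- list(provenances)
  sum_mat <- function(field) {
    Reduce(`+`, lapply(provenances, function(p) as.matrix(p[[field]])))
  }
  pc <- sum_mat("patch_counts")   # rows: total/positive/negative; cols: stages
  rc <- sum_mat("roi_counts")
  mk <- function(m, unit) {
    base <- m[, 1]
    do.call(rbind, lapply(colnames(m), function(st) {
      data.frame(unit = unit, stage = st,
                 total = m["total", st], positive = m["positive", st],
                 negative = m["negative", st],
                 pct_total = if (base["total"] > 0) 100 * m["total", st] / base["total"] else 0,
                 pct_positive = if (base["positive"] > 0) 100 * m["positive", st] / base["positive"] else 0,
                 pct_negative = if (base["negative"] > 0) 100 * m["negative", st] / base["negative"] else 0)
    }))
  }
  out <- rbind(mk(pc, "patch"), mk(rc, "roi"))
  rownames(out) <- NULL
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d TP / %d FP over %d ground-truth region(s)\n",
              x$tp, x$fp, x$n_regions))
  invisible(x)
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("<froc_curve> %d operating point(s); Sens %.2f-%.2f, FPI %.2f-%.2f\n",
              nrow(x$points), min(x$points$sens), max(x$points$sens),
              min(x$points$fpi), max(x$points$fpi)))
  invisible(x)
}
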