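mask_roi <- function(mask, score = NA_real_) {
  structure(list(patch_ids = 1L, mask = mask, features = numeric(12),
                 score = score, label = "unlabeled"), class = "roi")
}

disk_mask <- function(dim, ctr, rad) {
  rr <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  cc <- matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2])
  (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
}

test_that("the 50% overlap rule scores identity, partial and competing ROIs", {
  d <- c(64, 64)
  gt <- gt_region(center = c(32, 32), radius = 10)
  gmask <- gt_mask(gt, d)
  ## identical mask: overlap 1, tp
  mr <- match_regions(list(mask_roi(gmask)), list(gt), dim = d)
  expect_equal(mr$tp, 1); expect_equal(mr$fp, 0)
  expect_equal(unname(mr$pairs[1, "overlap"]), 1)
  ## 40% coverage: below the rule -> fp
  part <- gmask & (matrix(rep(seq_len(64), each = 64), 64, 64) < 30)
  expect_lt(sum(part & gmask) / sum(gmask), 0.5)
  mr2 <- match_regions(list(mask_roi(part)), list(gt), dim = d)
  expect_equal(mr2$tp, 0); expect_equal(mr2$fp, 1)
  ## two ROIs on one gt: best overlap wins, the other is a fp
  r_small <- mask_roi(gmask & disk_mask(d, c(32, 32), 8))    # ~0.6 overlap
  r_big <- mask_roi(gmask)                                   # 1.0 overlap
  mr3 <- match_regions(list(r_small, r_big), list(gt), dim = d)
  expect_equal(mr3$tp, 1); expect_equal(mr3$fp, 1)
  expect_equal(unname(mr3$pairs[1, "roi"]), 2)
  ## iou denominator is stricter
  big <- mask_roi(disk_mask(d, c(32, 32), 20))
  expect_equal(match_regions(list(big), list(gt), dim = d)$tp, 1)
  expect_equal(match_regions(list(big), list(gt), dim = d,
                             denominator = "iou")$tp, 0)
})

test_that("pooled Sens and FPI follow their defining ratios", {
  mk <- function(tp, fp, ng) structure(list(tp = tp, fp = fp, n_regions = ng,
                                            n_images = 1L, pairs = NULL),
                                       class = "match_result")
  ## worked case: 3 TP of 4 regions over 2 images with 2 FP
  out <- sens_fpi(list(mk(2, 1, 2), mk(1, 1, 2)))
  expect_equal(unname(out["sens"]), 0.75)
  expect_equal(unname(out["fpi"]), 1.0)
  ## no detections at all
  expect_equal(unname(sens_fpi(list(mk(0, 0, 3)))), c(0, 0))
  ## pooled equals per-image aggregation on random toy configurations
  set.seed(71)
  for (i in 1:100) {
    n_img <- sample(1:5, 1)
    res <- lapply(seq_len(n_img), function(j)
      mk(tp <- sample(0:3, 1), sample(0:4, 1), tp + sample(0:3, 1)))
    out <- sens_fpi(res)
    tps <- sum(vapply(res, `[[`, numeric(1), "tp"))
    fps <- sum(vapply(res, `[[`, numeric(1), "fp"))
    ngs <- sum(vapply(res, `[[`, numeric(1), "n_regions"))
    expect_equal(unname(out["sens"]), if (ngs > 0) tps / ngs else 0)
    expect_equal(unname(out["fpi"]), fps / n_img)
  }
})

test_that("matching agrees with the exhaustive greedy oracle on toy scenes", {
  set.seed(72)
  d <- c(48, 48)
  for (i in 1:25) {
    n_roi <- sample(0:4, 1); n_gt <- sample(0:3, 1)
    rois <- lapply(seq_len(n_roi), function(j)
      mask_roi(disk_mask(d, c(sample(10:38, 1), sample(10:38, 1)), sample(4:9, 1))))
    gts <- lapply(seq_len(n_gt), function(j)
      gt_region(center = c(sample(12:36, 1), sample(12:36, 1)),
                radius = sample(4:9, 1), id = paste0("g", j)))
    mr <- match_regions(rois, gts, dim = d)
    ov <- matrix(0, max(1, n_roi), max(1, n_gt))
    if (n_roi > 0 && n_gt > 0)
      for (a in 1:n_roi) for (b in 1:n_gt) {
        gm <- gt_mask(gts[[b]], d)
        ov[a, b] <- sum(rois[[a]]$mask & gm) / sum(gm)
      }
    cnt <- if (n_roi == 0) c(tp = 0, fp = 0)
           else if (n_gt == 0) c(tp = 0, fp = n_roi)
           else oracle_match_counts(ov)
    expect_equal(mr$tp, unname(cnt["tp"]))
    expect_equal(mr$fp, unname(cnt["fp"]))
  }
})

test_that("FROC curves are monotone and collapse to one point for tied scores", {
  d <- c(64, 64)
  gt1 <- gt_region(center = c(20, 20), radius = 8)
  gt2 <- gt_region(center = c(45, 45), radius = 8)
  hit1 <- mask_roi(gt_mask(gt1, d), score = 3)
  hit2 <- mask_roi(gt_mask(gt2, d), score = 1)
  miss <- mask_roi(disk_mask(d, c(50, 15), 6), score = 2)
  fr <- froc_curve(list(list(hit1, miss, hit2)), list(list(gt1, gt2)), d)
  expect_equal(nrow(fr$points), 3)
  expect_true(all(diff(fr$points$fpi) >= 0))
  expect_true(all(diff(fr$points$sens) >= 0))
  expect_equal(fr$points$sens[nrow(fr$points)], 1)
  ## tied scores -> single operating point
  tied <- froc_curve(list(list(mask_roi(gt_mask(gt1, d), score = 1),
                               mask_roi(gt_mask(gt2, d), score = 1))),
                     list(list(gt1, gt2)), d)
  expect_equal(nrow(tied$points), 1)
  ## adding a correct detection never lowers the curve
  fr2 <- froc_curve(list(list(hit1, miss)), list(list(gt1, gt2)), d)
  common <- intersect(fr$points$threshold, fr2$points$threshold)
  for (t in common) {
    expect_gte(fr$points$sens[fr$points$threshold == t],
               fr2$points$sens[fr2$points$threshold == t])
  }
})

test_that("stage report reconciles counts and percentages", {
  prov <- function(tot, pos, rt, rp) {
    pc <- rbind(total = tot, positive = pos, negative = tot - pos)
    colnames(pc) <- c("attention", "densification", "shape")
    rc <- rbind(total = rt, positive = rp, negative = rt - rp)
    colnames(rc) <- c("rois", "texture")
    list(patch_counts = pc, roi_counts = rc)
  }
  reps <- list(prov(c(40, 20, 12), c(6, 6, 5), c(5, 3), c(2, 2)),
               prov(c(30, 12, 8), c(4, 3, 3), c(4, 2), c(1, 1)))
  tab <- stage_report(reps)
  expect_true(all(tab$total == tab$positive + tab$negative))
  patch_tab <- tab[tab$unit == "patch", ]
  expect_equal(patch_tab$total, c(70, 32, 20))
  expect_true(all(diff(patch_tab$total) <= 0))
  expect_equal(patch_tab$pct_total[1], 100)
  expect_equal(patch_tab$pct_total[2], 100 * 32 / 70)
  roi_tab <- tab[tab$unit == "roi", ]
  expect_true(all(diff(roi_tab$total) <= 0))
  ## single provenance record is accepted too
  tab1 <- stage_report(reps[[1]])
  expect_equal(tab1$total[1], 40)
})
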