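# CLEAR-MOT tracking metrics (MOTA, identity switches) and the counting
# accuracy score used to summarise per-clip counting results.

#' Score a tracking hypothesis against ground truth (CLEAR-MOT)
#'
#' Per frame, ground-truth objects are put in correspondence with hypothesis
#' tracks: correspondences from the previous frame are kept while their IOU
#' stays at or above the threshold, and the remaining objects are matched by
#' minimum-cost assignment on `1 - IOU` (matches below the IOU threshold are
#' rejected). Misses (`fn`), false positives (`fp`) and identity switches
#' (`id_switches`: a ground-truth object re-matched to a different
#' hypothesis id than it last had) accumulate over frames into
#' `MOTA = 1 - (fn + fp + id_switches) / gt_total`.
#'
#' @param gt Ground-truth data frame: columns `frame`, `id`, `left`, `top`,
#'   `width`, `height`. Must be non-empty.
#' @param hyp Hypothesis data frame, same columns.
#' @param iou_threshold Minimum IOU for a valid correspondence (default 0.5,
#'   the CLEAR-MOT convention).
#' @return A list of class `mot_score`: `mota` (percent), `id_switches`,
#'   `fp`, `fn`, `gt_total`.
#' @export
score_tracking <- function(gt, hyp, iou_threshold = 0.5) {
  if (!is.data.frame(gt) || nrow(gt) == 0)
    stop("ground truth is empty")
  fp <- 0L; fn <- 0L; idsw <- 0L; total <- 0L
  mapping <- integer(0)                  # gt id -> last matched hyp id
  for (f in sort(unique(gt$frame))) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    total <- total + nrow(g)
    matched_g <- integer(0); matched_h <- integer(0)
    if (nrow(h) > 0) {
      iom <- iou_matrix(g[, c("left", "top", "width", "height")],
                        h[, c("left", "top", "width", "height")])
      # keep persistent correspondences first
      for (gi in seq_len(nrow(g))) {
        key <- as.character(g$id[gi])
        prev <- mapping[key]
        if (!is.na(prev) && length(prev)) {
          hi <- match(prev, h$id)
          if (!is.na(hi) && !(hi %in% matched_h) &&
              iom[gi, hi] >= iou_threshold) {
            matched_g <- c(matched_g, gi); matched_h <- c(matched_h, hi)
          }
        }
      }
      rem_g <- setdiff(seq_len(nrow(g)), matched_g)
      rem_h <- setdiff(seq_len(nrow(h)), matched_h)
      if (length(rem_g) && length(rem_h)) {
        cost <- 1 - iom[rem_g, rem_h, drop = FALSE]
        cost[cost > 1 - iou_threshold] <- infeasible_cost()
        res <- solve_assignment(cost, max_cost = 1 - iou_threshold)
        if (nrow(res$matches)) {
          for (r in seq_len(nrow(res$matches))) {
            gi <- rem_g[res$matches[r, 1]]; hi <- rem_h[res$matches[r, 2]]
            key <- as.character(g$id[gi])
            prev <- mapping[key]
            if (!is.na(prev) && length(prev) && prev != h$id[hi])
              idsw <- idsw + 1L
            mapping[key] <- h$id[hi]
            matched_g <- c(matched_g, gi); matched_h <- c(matched_h, hi)
          }
        }
      }
    }
    fn <- fn + nrow(g) - length(matched_g)
    fp <- fp + nrow(h) - length(matched_h)
  }
  structure(list(mota = 100 * (1 - (fn + fp + idsw) / total),
                 id_switches = idsw, fp = fp, fn = fn, gt_total = total),
            class = "mot_score")
}

#' @export
print.mot_score <- function(x, ...) {
  cat(sprintf("MOTA %.2f%% | IDsw %d | FP %d | FN %d | GT %d\n",
              x$mota, x$id_switches, x$fp, x$fn, x$gt_total))
  invisible(x)
}

#' Counting accuracy
#'
#' The percentage of animals counted correctly: `100 * n_correct / n_total`,
#' reported to two decimals.
#'
#' @param n_correct Number of animals correctly counted across all clips.
#' @param n_total Total number of animals appearing in the clips.
#' @return Percentage, rounded to two decimals.
#' @examples
#' counting_accuracy(711, 715) # 99.44
#' @export
counting_accuracy <- function(n_correct, n_total) {
  stopifnot(n_total > 0, n_correct >= 0, n_correct <= n_total)
  round(100 * n_correct / n_total, 2)
}

#' Correctly counted animals in one clip
#'
#' A clip with `n` animals, ground-truth signed count `gt` and system count
#' `cr` contributes `max(0, n - |gt - cr|)` correctly counted animals: each
#' unit of counting error costs one animal, floored at zero.
#'
#' @param n Number of animals in the clip.
#' @param gt Ground-truth signed counting result for the clip.
#' @param cr The system's counting result.
#' @return Integer number of correctly counted animals.
#' @examples
#' clip_correct_count(34, 0, -3) # 31
#' @export
clip_correct_count <- function(n, gt, cr) {
  as.integer(pmax(0, n - abs(gt - cr)))
}
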