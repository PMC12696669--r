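## Ground-truth recovery scoring, dice similarity, recovery reports.

#' Dice similarity between two thresholded spatial maps
#'
#' Binarises both maps at `threshold` and returns
#' `2 |A & B| / (|A| + |B|)` on the supra-threshold supports. Logical input
#' is used as-is.
#'
#' @param map_a,map_b numeric (or logical) vectors of equal length.
#' @param threshold hard threshold applied to numeric maps (default 0.3).
#' @return Dice coefficient in \[0, 1\]; 0 (with a warning) when both
#'   supports are empty.
#' @export
dice_similarity <- function(map_a, map_b, threshold = 0.3) {
  if (length(map_a) != length(map_b))
    stop("dice_similarity: maps must have equal length")
  a <- if (is.logical(map_a)) map_a else map_a > threshold
  b <- if (is.logical(map_b)) map_b else map_b > threshold
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("dice_similarity: both supports empty; returning 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

## mean paired |r| of subject maps for given truth/estimate lists
.subject_map_recovery <- function(est_maps, truth_maps, match) {
  vals <- mapply(function(e, t) {
    r <- abs(colcor(t[, seq_along(match), drop = FALSE],
                    e[, match, drop = FALSE]))
    diag(r)
  }, est_maps, truth_maps, SIMPLIFY = FALSE)
  rowMeans(do.call(cbind, lapply(vals, function(v) v)))
}

#' Score a decomposition against simulation ground truth
#'
#' Pairs estimated modes to the true modes by Hungarian matching on group
#' spatial maps, then reports the mean paired absolute Pearson correlation
#' for three elements -- group spatial maps (across voxels), subject spatial
#' maps (across voxels, averaged over subjects), and subject time courses
#' (across time, averaged over subjects and runs) -- split by mode class
#' (distributed / localised). "Accuracy" throughout this package means this
#' mean paired absolute correlation.
#'
#' @param fit a fitted `"pfm"` or `"icadr"` object (anything with
#'   `group_maps`, `subject_maps` and `timecourses` components).
#' @param truth the `"ground_truth"` of the generating simulation.
#' @return an object of class `"recovery_report"`: a data frame with columns
#'   `element` (group_maps / subject_maps / timecourses), `mode_class`, and
#'   `accuracy`, plus attributes `pairing` and `per_mode`.
#' @export
score_recovery <- function(fit, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  est_group <- fit$group_maps
  if (nrow(est_group) != nrow(truth$group_maps))
    stop("score_recovery: voxel dimension mismatch")
  pairing <- pair_modes(truth$group_maps, est_group)
  if (any(!is.finite(pairing$abs_r)))
    stop("score_recovery: degenerate maps; pairing failed")
  match <- pairing$match
  nm <- length(match)
  cls <- truth$mode_class

  group_acc <- pairing$abs_r

  subj_acc <- rep(NA_real_, nm)
  if (!is.null(fit$subject_maps) && !is.null(truth$subject_maps)) {
    acc <- matrix(0, nm, length(truth$subject_maps))
    for (s in seq_along(truth$subject_maps)) {
      r <- colcor(truth$subject_maps[[s]],
                  fit$subject_maps[[s]][, match, drop = FALSE])
      acc[, s] <- abs(diag(r))
    }
    subj_acc <- rowMeans(acc, na.rm = TRUE)
  }

  tc_acc <- rep(NA_real_, nm)
  if (!is.null(fit$timecourses) && !is.null(truth$bold_timecourses)) {
    accs <- matrix(0, nm, 0)
    for (s in seq_along(truth$bold_timecourses)) {
      for (r in seq_along(truth$bold_timecourses[[s]])) {
        est_tc <- fit$timecourses[[s]][[r]]
        true_tc <- truth$bold_timecourses[[s]][[r]]
        rr <- colcor(t(true_tc), t(est_tc[match, , drop = FALSE]))
        accs <- cbind(accs, abs(diag(rr)))
      }
    }
    tc_acc <- rowMeans(accs, na.rm = TRUE)
  }

  per_mode <- data.frame(mode = seq_len(nm), mode_class = cls,
                         group_maps = group_acc, subject_maps = subj_acc,
                         timecourses = tc_acc)
  agg <- do.call(rbind, lapply(c("group_maps", "subject_maps", "timecourses"),
    function(el) {
      data.frame(element = el,
                 mode_class = levels(cls),
                 accuracy = tapply(per_mode[[el]], cls, mean),
                 row.names = NULL)
    }))
  structure(agg, class = c("recovery_report", "data.frame"),
            pairing = pairing, per_mode = per_mode,
            method = if (!is.null(fit$method)) fit$method else class(fit)[1])
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Ground-truth recovery (%s): mean paired |r|\n",
              attr(x, "method")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Average recovery reports across simulated datasets
#'
#' @param reports list of [score_recovery()] results from replicate datasets.
#' @return a data frame in the same layout with accuracies averaged across
#'   datasets.
#' @export
average_recovery <- function(reports) {
  stopifnot(length(reports) >= 1)
  out <- reports[[1]]
  acc <- sapply(reports, function(r) r$accuracy)
  out$accuracy <- rowMeans(as.matrix(acc), na.rm = TRUE)
  out
}
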