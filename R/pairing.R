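## Mode pairing between decompositions: Hungarian assignment on absolute
## spatial correlations, plus primary/secondary labelling.

#' Solve the linear assignment problem (Hungarian algorithm)
#'
#' Minimises the total cost of a one-to-one assignment of rows to columns
#' using the shortest-augmenting-path (Jonker-Volgenant) formulation,
#' O(n^2 m). Every row is assigned, which requires `nrow <= ncol`.
#'
#' @param cost numeric cost matrix with `nrow(cost) <= ncol(cost)`.
#' @return integer vector of length `nrow(cost)`: the column assigned to
#'   each row.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("solve_assignment: more rows than columns")
  if (!all(is.finite(cost))) stop("solve_assignment: non-finite costs")
  ## 1-based port of the standard potentials formulation; column index 1 is
  ## a phantom column, real columns live at 2..(m+1)
  u <- rep(0, n + 1)
  v <- rep(0, m + 1)
  p <- integer(m + 1)      # p[j]: row currently assigned to column j-1
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(m + 1)) if (p[j] != 0L) assign[p[j]] <- j - 1L
  assign
}

#' Pair the modes of two decompositions by spatial correlation
#'
#' Finds the one-to-one matching between the columns of `maps_a` (e.g., a
#' low-dimensional decomposition, or ground truth) and `maps_b` that
#' maximises the total absolute spatial correlation (Hungarian algorithm).
#' Columns of `maps_b` matched to a column of `maps_a` are labelled
#' `primary`; unmatched columns are `secondary`. Paired correlations are also
#' binned (>= 0.7 / 0.5-0.7 / < 0.5) for reproducibility reporting.
#'
#' @param maps_a N_v x K_a matrix (reference decomposition).
#' @param maps_b N_v x K_b matrix with `K_b >= K_a`.
#' @return an object of class `"mode_pairing"`: list with `match` (for each
#'   column of `maps_a`, the paired column of `maps_b`), `r` (signed
#'   correlation of each pair), `abs_r`, `label` (per column of `maps_b`:
#'   `"primary"`/`"secondary"`), and `bins`.
#' @export
pair_modes <- function(maps_a, maps_b) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (nrow(maps_a) != nrow(maps_b))
    stop("pair_modes: maps must share the voxel dimension")
  if (ncol(maps_b) < ncol(maps_a))
    stop("pair_modes: `maps_b` must have at least as many modes as `maps_a`")
  r <- colcor(maps_a, maps_b)
  r[!is.finite(r)] <- 0
  match <- solve_assignment(-abs(r))
  paired_r <- r[cbind(seq_len(ncol(maps_a)), match)]
  label <- rep("secondary", ncol(maps_b))
  label[match] <- "primary"
  abs_r <- abs(paired_r)
  bins <- c(high = sum(abs_r >= 0.7),
            mid = sum(abs_r >= 0.5 & abs_r < 0.7),
            low = sum(abs_r < 0.5))
  structure(list(match = match, r = paired_r, abs_r = abs_r,
                 label = factor(label, levels = c("primary", "secondary")),
                 bins = bins, cor_matrix = r),
            class = "mode_pairing")
}

#' @export
print.mode_pairing <- function(x, ...) {
  cat(sprintf("Mode pairing: %d reference modes matched into %d candidates\n",
              length(x$match), length(x$label)))
  cat(sprintf("  mean |r| = %.3f; bins >=0.7 / 0.5-0.7 / <0.5: %d / %d / %d\n",
              mean(x$abs_r), x$bins["high"], x$bins["mid"], x$bins["low"]))
  invisible(x)
}

#' Reproducibility report from a mode pairing
#'
#' Counts paired absolute correlations in the bins >= 0.7 (very good match),
#' \[0.5, 0.7) (fair) and < 0.5 (poor), with the per-pair table.
#'
#' @param pairing a [pair_modes()] result.
#' @return list with `counts` (length 3) and `pairs` (data frame).
#' @export
reproducibility_report <- function(pairing) {
  stopifnot(inherits(pairing, "mode_pairing"))
  pairs <- data.frame(mode_a = seq_along(pairing$match),
                      mode_b = pairing$match,
                      r = pairing$r, abs_r = pairing$abs_r)
  list(counts = pairing$bins, pairs = pairs)
}
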