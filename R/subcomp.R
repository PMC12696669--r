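## Within-mode temporal subcomponent analysis: weighted data, explained
## variance profiles, temporal-ICA subcomponents, winner-takes-all
## assignment, and the temporally / spatially exclusive control variants.

#' Weight a dataset by a mode's spatial map
#'
#' Multiplies each voxel's time course by the mode's map weight at that
#' voxel; dimensions are unchanged (voxels inside the mode are up-weighted).
#'
#' @param dataset a [bold_dataset()] or N_v x N_t matrix.
#' @param mode_map numeric vector of length N_v.
#' @return N_v x N_t matrix.
#' @export
weight_data <- function(dataset, mode_map) {
  d <- if (inherits(dataset, "bold_dataset")) dataset$data else as.matrix(dataset)
  if (length(mode_map) != nrow(d))
    stop("weight_data: map length must equal the voxel dimension")
  d * as.numeric(mode_map)
}

## spatial PCA of one weighted dataset: top-k left singular maps (scaled)
.spatial_pcs <- function(wd, k) {
  wd <- wd - rowMeans(wd)
  k <- min(k, min(dim(wd)))
  sv <- svd(wd, nu = k, nv = 0)
  sv$u %*% diag(sv$d[seq_len(k)], k)
}

#' Group explained-variance profile of within-mode subcomponents
#'
#' Subject-level spatial PCA (`k_subject` components per subject) of the
#' mode-weighted data, concatenation of the PC maps across subjects, then a
#' group-level PCA; returns the fraction of group variance explained by each
#' of the leading `k_group` group components. A first fraction well below 1
#' indicates that no single temporal subcomponent explains the mode.
#'
#' @param weighted_datasets list (one per subject) of N_v x N_t weighted
#'   data matrices for one mode.
#' @param k_subject,k_group subject- and group-level component counts.
#' @return numeric vector of length `k_group` (explained-variance fractions
#'   of the concatenated subject-PC feature space).
#' @export
explained_variance_profile <- function(weighted_datasets, k_subject = 10,
                                       k_group = 10) {
  if (length(weighted_datasets) < 2)
    stop("explained_variance_profile: need at least two subjects")
  feats <- do.call(cbind, lapply(weighted_datasets, .spatial_pcs,
                                 k = k_subject))
  kg <- min(k_group, min(dim(feats)))
  if (kg < k_group)
    warning("explained_variance_profile: k_group truncated to rank ", kg)
  d <- svd(feats - rowMeans(feats), nu = 0, nv = 0)$d
  (d[seq_len(kg)]^2) / sum(d^2)
}

#' Temporally independent subcomponents of one mode
#'
#' Implements the within-mode subcomponent pipeline: subject spatial PCA
#' (`k` maps each), group spatial PCA of the concatenated maps (`k` group
#' maps), regression of the group maps onto each subject's weighted data
#' (subject temporal components), concatenation over subjects, temporal ICA
#' (`k` sources), splitting the source time courses back per subject, and a
#' final regression onto the weighted data for subject-specific
#' subcomponent maps.
#'
#' @param weighted_datasets list (one per subject) of N_v x N_t matrices.
#' @param k number of subcomponents (default 5).
#' @param seed optional integer seed (temporal-ICA initialisation).
#' @return object of class `"subcomponents"`: list with `timecourses` (per
#'   subject, k x N_t), `maps` (per subject, N_v x k), `group_maps`
#'   (N_v x k group spatial PCs), `k`.
#' @export
tica_subcomponents <- function(weighted_datasets, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(weighted_datasets)
  nts <- vapply(weighted_datasets, ncol, integer(1))
  subj_pcs <- lapply(weighted_datasets, .spatial_pcs, k = k)
  if (any(vapply(subj_pcs, ncol, integer(1)) < k))
    stop("tica_subcomponents: `k` exceeds the subject PCA rank")
  group_pcs <- .spatial_pcs(do.call(cbind, subj_pcs), k)
  qg <- qr(group_pcs)
  subj_tcs <- lapply(weighted_datasets, function(wd)
    qr.coef(qg, wd - rowMeans(wd)))                    # k x N_t per subject
  long <- do.call(cbind, subj_tcs)                     # k x sum(N_t)
  ica <- fast_ica(long, k, n_restarts = 5)
  src <- ica$s                                         # k x sum(N_t)
  ends <- cumsum(nts); starts <- c(1, utils::head(ends, -1) + 1)
  timecourses <- lapply(seq_len(ns), function(s)
    src[, starts[s]:ends[s], drop = FALSE])
  maps <- lapply(seq_len(ns), function(s) {
    tc <- timecourses[[s]]
    t(qr.coef(qr(t(tc)), t(weighted_datasets[[s]])))   # N_v x k
  })
  structure(list(timecourses = timecourses, maps = maps,
                 group_maps = group_pcs, k = k),
            class = "subcomponents")
}

#' Winner-takes-all assignment of subcomponents to candidate modes
#'
#' For each subject, each subcomponent time course is correlated with every
#' candidate mode time course; the winner is the candidate with maximal
#' absolute correlation (ties broken toward the earliest class listed, by
#' convention `lowD`). Each subcomponent's class is decided by majority
#' vote across subjects. Significance per subcomponent is an unpaired
#' t-test between the winner-class and runner-up-class best-|r|
#' distributions across subjects, Bonferroni-corrected across `n_tests`
#' subcomponents.
#'
#' @param subcomponents a [tica_subcomponents()] result (or a list of
#'   per-subject k x N_t matrices).
#' @param candidates named list of candidate classes (first class wins
#'   ties; conventionally `lowD`, `primary`, `secondary`), each a list (one
#'   per subject) of matrices with candidate time courses in rows.
#' @param n_tests Bonferroni denominator (default: the number of
#'   subcomponents assessed here; pass the pipeline-wide total, e.g.
#'   `n_lowD_modes * k`, when aggregating).
#' @return object of class `"wta_result"`: data frame with one row per
#'   subcomponent (`winner_class`, `winner_mode`, `mean_winner_r`,
#'   `t_statistic`, `p_bonferroni`) plus a `counts` attribute (per class).
#' @export
winner_takes_all <- function(subcomponents, candidates, n_tests = NULL) {
  tcs <- if (inherits(subcomponents, "subcomponents"))
    subcomponents$timecourses else subcomponents
  ns <- length(tcs)
  k <- nrow(tcs[[1]])
  classes <- names(candidates)
  if (is.null(classes) || any(classes == ""))
    stop("winner_takes_all: `candidates` must be a named list")
  if (is.null(n_tests)) n_tests <- k

  ## per subject & subcomponent: best |r| within each class
  best_r <- array(NA_real_, c(ns, k, length(classes)),
                  dimnames = list(NULL, NULL, classes))
  best_mode <- array(NA_integer_, c(ns, k, length(classes)))
  for (s in seq_len(ns)) {
    for (ci in seq_along(classes)) {
      cand <- candidates[[ci]][[s]]
      r <- abs(colcor(t(tcs[[s]]), t(cand)))           # k x n_cand
      r[!is.finite(r)] <- 0
      best_r[s, , ci] <- apply(r, 1, max)
      best_mode[s, , ci] <- apply(r, 1, which.max)
    }
  }

  rows <- lapply(seq_len(k), function(j) {
    ## per-subject winning class (ties -> earliest class, i.e. lowD)
    rj <- matrix(best_r[, j, ], ns, length(classes))
    win <- apply(rj, 1, which.max)
    tab <- tabulate(win, nbins = length(classes))
    wc <- which.max(tab)                               # majority vote
    ## runner-up class by mean best-|r|
    mr <- colMeans(matrix(best_r[, j, ], ns, length(classes)))
    ru <- order(mr, decreasing = TRUE)
    ru <- if (ru[1] == wc) ru[2] else ru[1]
    tt <- tryCatch(stats::t.test(best_r[, j, wc], best_r[, j, ru],
                                 var.equal = FALSE),
                   error = function(e) list(statistic = NA, p.value = NA))
    data.frame(subcomponent = j,
               winner_class = classes[wc],
               winner_mode = as.integer(stats::median(best_mode[, j, wc])),
               mean_winner_r = mean(best_r[, j, wc]),
               t_statistic = unname(tt$statistic),
               p_bonferroni = min(1, unname(tt$p.value) * n_tests))
  })
  out <- do.call(rbind, rows)
  counts <- table(factor(out$winner_class, levels = classes))
  structure(out, class = c("wta_result", "data.frame"), counts = counts)
}

#' @export
print.wta_result <- function(x, ...) {
  cat("Winner-takes-all subcomponent assignment:\n")
  print(attr(x, "counts"))
  invisible(x)
}

#' Temporally exclusive weighted data
#'
#' Replaces each voxel's time course by its residual after least-squares
#' regression on the time courses of every other mode, removing shared
#' co-activation periods.
#'
#' @param weighted_dataset N_v x N_t matrix.
#' @param other_mode_tcs matrix with other modes' time courses in rows.
#' @return N_v x N_t residual matrix.
#' @export
exclusive_temporal <- function(weighted_dataset, other_mode_tcs) {
  wd <- as.matrix(weighted_dataset)
  x <- t(as.matrix(other_mode_tcs))                    # N_t x n_other
  if (nrow(x) != ncol(wd))
    stop("exclusive_temporal: time dimensions do not align")
  x <- cbind(1, x)
  wd - t(x %*% qr.coef(qr(x), t(wd)))
}

#' Spatially exclusive map and weighted data
#'
#' Residualises the mode's spatial map against every other mode's map
#' (across voxels), re-weights the data by the residual map, and also
#' regresses the other maps out of each time point of the weighted data.
#'
#' @param mode_map numeric vector (N_v).
#' @param other_mode_maps N_v x n_other matrix.
#' @param dataset a [bold_dataset()] or N_v x N_t matrix (unweighted).
#' @return list with `map` (residual map) and `data` (residualised
#'   re-weighted N_v x N_t matrix).
#' @export
exclusive_spatial <- function(mode_map, other_mode_maps, dataset) {
  d <- if (inherits(dataset, "bold_dataset")) dataset$data else as.matrix(dataset)
  x <- as.matrix(other_mode_maps)
  qx <- qr(x)
  rmap <- as.numeric(mode_map) - drop(x %*% qr.coef(qx, as.numeric(mode_map)))
  wd <- d * rmap
  wd <- wd - x %*% qr.coef(qx, wd)
  list(map = rmap, data = wd)
}

#' Planted multiscale scene for the subcomponent pipeline
#'
#' Builds a small synthetic scene in which each low-dimensional distributed
#' mode contains spatial sub-nodes whose time courses are co-activation
#' mixtures: sub-node `j` of mode `i` follows `(B_i + B_k)/sqrt(2)` plus a
#' small unique part, where `B` are the core mode time courses and `k` is
#' another mode. Candidate time courses emulate three decompositions:
#' `lowD` (the merged network time course, core plus sub-node activity),
#' `primary` (the core time course as estimated by a high-dimensional
#' decomposition, i.e. with estimation noise), and `secondary` (the
#' sub-node time courses). This is the scene on which the original /
#' temporally exclusive / spatially exclusive variants of the subcomponent
#' pipeline show their qualitatively different winner-takes-all outcomes.
#'
#' @param n_lowd number of distributed (low-dimensional) modes.
#' @param k_sub sub-nodes per mode.
#' @param n_subjects,n_voxels,n_timepoints scene dimensions.
#' @param unique_sd SD of each sub-node's unique time-course part.
#' @param primary_noise_sd estimation-noise SD on the primary candidates
#'   (high-dimensional decompositions estimate each mode from less data, so
#'   their candidate time courses are noisier than the low-dimensional
#'   ones).
#' @param merge_weight weight of sub-node activity inside the lowD merged
#'   candidate.
#' @param sub_amp amplitude of sub-node map weights relative to the parent.
#' @param obs_noise_sd observation noise on the data.
#' @param seed integer seed.
#' @return list with `datasets` (per subject N_v x N_t), `mode_maps`
#'   (N_v x n_lowd), `sub_maps` (N_v x (n_lowd*k_sub)), `parent`
#'   (sub-node -> mode), and `candidates` (named list of per-subject
#'   candidate time-course matrices: `lowD`, `primary`, `secondary`).
#' @export
plant_subcomponent_scene <- function(n_lowd = 6, k_sub = 2, n_subjects = 8,
                                     n_voxels = 1200, n_timepoints = 300,
                                     unique_sd = 0.5,
                                     primary_noise_sd = 0.35,
                                     merge_weight = 0.5,
                                     sub_amp = 2,
                                     obs_noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  nv <- n_voxels
  block <- floor(nv / n_lowd)
  mode_maps <- matrix(0, nv, n_lowd)
  sub_maps <- matrix(0, nv, n_lowd * k_sub)
  parent <- integer(n_lowd * k_sub)
  for (i in seq_len(n_lowd)) {
    idx <- ((i - 1) * block + 1):(i * block)
    mode_maps[idx, i] <- stats::rgamma(length(idx), 3, scale = 0.5)
    ## sub-nodes dominate their own segments of the parent block (the
    ## parent keeps reduced weight there), so each sub-node is a spatial
    ## sub-node of the mode with its own time course
    seg <- floor(block / (k_sub + 1))
    for (j in seq_len(k_sub)) {
      sidx <- idx[((j - 1) * seg + 1):(j * seg)]
      sj <- (i - 1) * k_sub + j
      sub_maps[sidx, sj] <- sub_amp * stats::rgamma(length(sidx), 3, scale = 0.5)
      mode_maps[sidx, i] <- 0.3 * mode_maps[sidx, i]
      parent[sj] <- i
    }
  }
  datasets <- vector("list", n_subjects)
  lowD <- primary <- secondary <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    b <- matrix(stats::rnorm(n_lowd * n_timepoints), n_lowd) # core tcs
    b <- lowpass_rows(b, 1, 0.15) + 0.15 * b
    ## bursty (heavy-tailed) neural cores keep the temporal-ICA step
    ## identifiable, mimicking semi-Gaussian resting activity
    b <- sign(b) * abs(b)^1.5
    b <- (b - rowMeans(b)) / apply(b, 1, stats::sd)
    cc <- matrix(0, n_lowd * k_sub, n_timepoints)
    for (sj in seq_len(n_lowd * k_sub)) {
      i <- parent[sj]
      other <- sample(setdiff(seq_len(n_lowd), i), 1)
      ## the sub-node's distinct activity is its parent core under a slowly
      ## fluctuating zero-mean gain: uncorrelated with the core but
      ## temporally bound to it, so temporal ICA cannot split it off
      gain <- drop(lowpass_rows(matrix(stats::rnorm(n_timepoints), 1),
                                1, 0.05))
      gain <- (gain - mean(gain)) / stats::sd(gain)
      mod <- b[i, ] * gain
      mod <- (mod - mean(mod)) / stats::sd(mod)
      ## parent-dominant mixture: the sub-node mostly follows its parent,
      ## co-activates episodically with one other network, and carries the
      ## gain-modulated parent component
      cc[sj, ] <- 0.75 * b[i, ] + 0.55 * b[other, ] + unique_sd * mod
      cc[sj, ] <- cc[sj, ] / stats::sd(cc[sj, ])
    }
    d <- mode_maps %*% b + sub_maps %*% cc +
      matrix(stats::rnorm(nv * n_timepoints, sd = obs_noise_sd), nv)
    datasets[[s]] <- d
    merged <- t(vapply(seq_len(n_lowd), function(i) {
      kid <- which(parent == i)
      v <- b[i, ] + merge_weight * colSums(cc[kid, , drop = FALSE])
      v / stats::sd(v)
    }, numeric(n_timepoints)))
    lowD[[s]] <- merged
    pn <- b + primary_noise_sd * matrix(stats::rnorm(length(b)), nrow(b))
    primary[[s]] <- pn / apply(pn, 1, stats::sd)
    secondary[[s]] <- cc
  }
  list(datasets = datasets, mode_maps = mode_maps, sub_maps = sub_maps,
       parent = parent,
       candidates = list(lowD = lowD, primary = primary,
                         secondary = secondary))
}

#' Run the subcomponent pipeline over all modes of a scene
#'
#' Applies, per low-dimensional mode, the chosen variant's preprocessing
#' (none / temporally exclusive / spatially exclusive), extracts `k`
#' temporal-ICA subcomponents, and pools the winner-takes-all assignments
#' across modes with a pipeline-wide Bonferroni correction
#' (`n_modes * k` tests).
#'
#' @param scene a [plant_subcomponent_scene()] result (or a compatible
#'   list).
#' @param variant `"original"`, `"temporal"` (temporally exclusive), or
#'   `"spatial"` (spatially exclusive).
#' @param k subcomponents per mode.
#' @param seed integer seed (shared tICA initialisation across variants).
#' @return a `"wta_result"` data frame covering all modes, with class
#'   counts in `attr(, "counts")`.
#' @export
run_subcomponent_pipeline <- function(scene,
                                      variant = c("original", "temporal",
                                                  "spatial"),
                                      k = 3, seed = 1L) {
  variant <- match.arg(variant)
  n_lowd <- ncol(scene$mode_maps)
  ns <- length(scene$datasets)
  all_rows <- list()
  counts <- NULL
  for (i in seq_len(n_lowd)) {
    wlist <- vector("list", ns)
    for (s in seq_len(ns)) {
      if (variant == "spatial") {
        ex <- exclusive_spatial(scene$mode_maps[, i],
                                scene$mode_maps[, -i, drop = FALSE],
                                scene$datasets[[s]])
        wlist[[s]] <- ex$data
      } else {
        wd <- weight_data(scene$datasets[[s]], scene$mode_maps[, i])
        if (variant == "temporal")
          wd <- exclusive_temporal(wd,
                                   scene$candidates$lowD[[s]][-i, , drop = FALSE])
        wlist[[s]] <- wd
      }
    }
    sub <- tica_subcomponents(wlist, k = k, seed = seed + i)
    wta <- winner_takes_all(sub, scene$candidates, n_tests = n_lowd * k)
    wta$origin_mode <- i
    all_rows[[i]] <- wta
    counts <- if (is.null(counts)) attr(wta, "counts") else
      counts + attr(wta, "counts")
  }
  out <- do.call(rbind, all_rows)
  structure(out, class = c("wta_result", "data.frame"), counts = counts,
            variant = variant)
}
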