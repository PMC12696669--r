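## Spatial side of the generator: group maps on a 1-D voxel lattice,
## subject maps via smooth circular warps plus background noise.

#' Simulate group-level multiscale mode maps
#'
#' Builds `n_distributed + n_localised` spatial maps on a 1-D voxel lattice.
#' Each distributed mode consists of 2-4 randomly placed contiguous voxel
#' blocks; distributed modes may overlap. Each localised mode is a single
#' contiguous block nested inside one block of its parent distributed mode
#' (a spatial sub-node with its own time course downstream). Weights on the
#' support follow a Gamma distribution.
#'
#' Weights are spatially smooth rather than voxel-wise independent: a
#' low-pass Gaussian random field (correlation length
#' `weight_smoothness * n_voxels`) is mapped through the Gamma quantile
#' function, preserving the Gamma marginal while keeping the weight texture
#' coherent under subject-level warps.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return an object of class `"ground_truth"` with elements `group_maps`
#'   (N_v x N_m), `mode_class` (factor, `distributed`/`localised`),
#'   `parent_of` (localised mode -> parent distributed mode index, `NA` for
#'   distributed modes) and `config`.
#' @export
make_group_maps <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nv <- config$n_voxels
  nd <- config$n_distributed
  nl <- config$n_localised
  nm <- config$n_modes
  if (nl > 0 && nd < 1)
    stop("localised modes require at least one distributed parent")

  target_cov <- round(config$mode_coverage * nv)
  if (target_cov < 8 * 4)
    stop("configuration error: lattice too small to place mode blocks ",
         "(per-mode coverage ", target_cov, " voxels)")

  maps <- matrix(0, nv, nm)
  blocks <- vector("list", nm)  # per mode: matrix of (start, len)

  ## smooth Gamma weight field: Gaussian copula over a low-pass random field
  weight_field <- function() {
    ell <- max(2, config$weight_smoothness * nv)
    z <- stats::rnorm(nv)
    k <- exp(-0.5 * (pmin(0:(nv - 1), nv - (0:(nv - 1))) / ell)^2)
    zf <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)),
                        inverse = TRUE)) / nv
    zf <- (zf - mean(zf)) / stats::sd(zf)
    stats::qgamma(stats::pnorm(zf), shape = config$gamma_shape,
                  scale = config$gamma_scale)
  }

  place_blocks <- function(n_blocks, lens, forbidden = NULL) {
    ## sample non-overlapping (within mode) block positions; `forbidden` is a
    ## logical mask of voxels this mode must avoid (used when overlap is off)
    out <- matrix(NA_integer_, n_blocks, 2)
    taken <- if (is.null(forbidden)) rep(FALSE, nv) else forbidden
    for (b in seq_len(n_blocks)) {
      ok <- FALSE
      for (try in 1:200) {
        st <- sample.int(nv - lens[b] + 1L, 1L)
        idx <- st:(st + lens[b] - 1L)
        if (!any(taken[idx])) { ok <- TRUE; break }
      }
      if (!ok)
        stop("configuration error: cannot place mode blocks on the lattice; ",
             "reduce `mode_coverage` or the number of modes")
      out[b, ] <- c(st, lens[b])
      taken[st:(st + lens[b] - 1L)] <- TRUE
    }
    out
  }

  forbidden <- if (config$allow_overlap) NULL else rep(FALSE, nv)
  for (m in seq_len(nd)) {
    nb <- sample(2:4, 1L)
    ## split the mode's coverage over its blocks with mild size jitter
    prop <- stats::runif(nb, 0.7, 1.3); prop <- prop / sum(prop)
    lens <- pmax(8L, as.integer(round(target_cov * prop)))
    bl <- place_blocks(nb, lens, forbidden)
    if (!config$allow_overlap) {
      for (b in seq_len(nrow(bl)))
        forbidden[bl[b, 1]:(bl[b, 1] + bl[b, 2] - 1L)] <- TRUE
    }
    blocks[[m]] <- bl
    w <- weight_field()
    for (b in seq_len(nrow(bl))) {
      idx <- bl[b, 1]:(bl[b, 1] + bl[b, 2] - 1L)
      maps[idx, m] <- w[idx]
    }
  }

  parent_of <- rep(NA_integer_, nm)
  if (nl > 0) {
    parents <- rep(seq_len(nd), length.out = nl)
    for (j in seq_len(nl)) {
      m <- nd + j
      p <- parents[j]
      parent_of[m] <- p
      pb <- blocks[[p]]
      b <- sample.int(nrow(pb), 1L)
      frac <- stats::runif(1, 0.5, 0.9)
      len <- max(8L, as.integer(round(pb[b, 2] * frac)))
      st <- pb[b, 1] + sample.int(pb[b, 2] - len + 1L, 1L) - 1L
      blocks[[m]] <- matrix(c(st, len), 1, 2)
      idx <- st:(st + len - 1L)
      w <- weight_field()
      maps[idx, m] <- w[idx]
    }
  }

  structure(list(
    group_maps = maps,
    mode_class = factor(rep(c("distributed", "localised"), c(nd, nl)),
                        levels = c("distributed", "localised")),
    parent_of = parent_of,
    blocks = blocks,
    config = config
  ), class = "ground_truth")
}

#' Mean number of distributed modes covering a covered voxel
#'
#' Among voxels inside at least one distributed mode's support, the average
#' count of distributed modes whose support includes the voxel. This is the
#' generator's overlap calibration statistic.
#'
#' @param truth a `"ground_truth"` object from [make_group_maps()].
#' @return a single number >= 1.
#' @export
mode_overlap_count <- function(truth) {
  dm <- truth$group_maps[, truth$mode_class == "distributed", drop = FALSE]
  cover <- rowSums(dm > 0)
  mean(cover[cover > 0])
}

## smooth circular displacement field with RMS `mag * nv` voxels
smooth_warp_field <- function(nv, mag, n_harmonics = 4) {
  v <- seq_len(nv)
  d <- rep(0, nv)
  a <- stats::rnorm(n_harmonics)
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  for (k in seq_len(n_harmonics))
    d <- d + a[k] * cos(2 * pi * k * v / nv + phi[k])
  rms <- sqrt(mean(d^2))
  if (rms == 0) return(d)
  d * (mag * nv / rms)
}

## circular linear interpolation of columns of `maps` at positions v - d(v)
warp_map <- function(maps, disp) {
  nv <- nrow(maps)
  pos <- (seq_len(nv) - 1 - disp) %% nv        # 0-based source positions
  i0 <- floor(pos); w <- pos - i0
  i0 <- (i0 %% nv) + 1L
  i1 <- (i0 %% nv) + 1L
  maps[i0, , drop = FALSE] * (1 - w) + maps[i1, , drop = FALSE] * w
}

#' Simulate subject-level spatial maps from the group maps
#'
#' Each subject's maps are the group maps displaced by a smooth random
#' circular warp (one field per subject) with additive Gaussian background
#' noise. The default warp magnitude is calibrated so that the mean Dice
#' overlap between subject and group supports is ~0.83 (i.e., ~17% spatial
#' misalignment).
#'
#' @param truth output of [make_group_maps()].
#' @param config the [sim_config()] used for the truth (defaults to the one
#'   stored in `truth`).
#' @param seed optional integer seed.
#' @return `truth` with `subject_maps` (list of N_v x N_m matrices, including
#'   background noise) and `subject_supports` (list of logical matrices from
#'   the warped, noise-free maps) filled in.
#' @export
make_subject_maps <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$group_maps))
  if (!is.null(seed)) set.seed(seed)
  nv <- config$n_voxels
  subject_maps <- vector("list", config$n_subjects)
  subject_supports <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    disp <- smooth_warp_field(nv, config$warp_magnitude)
    warped <- warp_map(truth$group_maps, disp)
    subject_supports[[s]] <- warped > 0
    noisy <- warped
    if (config$background_noise_sd > 0)
      noisy <- noisy + matrix(stats::rnorm(length(warped),
                                           sd = config$background_noise_sd),
                              nrow(warped), ncol(warped))
    subject_maps[[s]] <- noisy
  }
  truth$subject_maps <- subject_maps
  truth$subject_supports <- subject_supports
  truth
}

#' Mean subject-group support overlap (Dice)
#'
#' Dice coefficient between each subject mode's support (warped, noise-free
#' map binarised at weight > 0) and the group mode's support, averaged over
#' subjects and modes.
#'
#' @param truth a `"ground_truth"` with subject maps.
#' @return mean Dice in \[0, 1\].
#' @export
subject_group_overlap <- function(truth) {
  stopifnot(!is.null(truth$subject_supports))
  gsup <- truth$group_maps > 0
  vals <- vapply(truth$subject_supports, function(ss) {
    mean(vapply(seq_len(ncol(gsup)), function(m)
      dice_similarity(ss[, m], gsup[, m], threshold = 0), numeric(1)))
  }, numeric(1))
  mean(vals)
}
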