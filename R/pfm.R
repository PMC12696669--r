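## Hierarchical probabilistic functional-mode decomposition.
##
## Model per subject s, run r:  D = P  diag(h)  A + E,  E ~ N(0, sigma^2).
## Spatial maps P carry a per-voxel double-Gaussian mixture prior (signal
## component centred on the group map mean, background noise component
## centred on zero); time courses A carry a matrix-normal prior with an
## N_m x N_m precision alpha that is itself tied to a group-level Wishart,
## plus a haemodynamic band-limitation penalty. Inference is penalised
## maximum a posteriori coordinate ascent at the subject level (a mean-field
## re-derivation with point posteriors for H and the noise variance) inside
## a stochastic group-level update loop with a Robbins-Monro step size
## rho_t = (t + tau)^(-beta).

#' Control parameters for the PFM fit
#'
#' @param forget_rate stochastic step-size decay exponent beta in
#'   `rho_t = (t + tau)^(-beta)`; must lie in (0.5, 1].
#' @param delay step-size delay tau (>= 0).
#' @param batch_size subjects per stochastic batch.
#' @param visits_per_subject mean number of times each subject is visited
#'   during the batched phase.
#' @param min_group_updates lower bound on the number of group updates.
#' @param batch_cycles,final_cycles subject-level coordinate-ascent cycle
#'   budgets during batches and during the final full pass.
#' @param tol relative free-energy change declaring subject convergence.
#' @param hrf_cutoff_hz cutoff of the haemodynamic band-limitation prior on
#'   time courses, in Hz.
#' @param hrf_lambda weight of that temporal prior.
#' @param wishart_prior_dof degrees of freedom of the group Wishart prior on
#'   subject time-course precisions (must exceed `n_modes + 1`; `NULL` picks
#'   `n_modes + 10`).
#' @param n_restarts random re-initialisations of the initial-map ICA.
#' @param init `"multiscale"` (default; consolidated low-dimensional
#'   parents plus within-parent temporal subcomponent seeds) or `"ica"`
#'   (plain spatial ICA of the group basis).
#' @param consolidation_rounds full-batch M-step rounds after the
#'   stochastic schedule.
#' @param reseed re-seed modes without unique explained variance from the
#'   model residuals (one round).
#' @param seed integer seed.
#' @return a list of class `"pfm_control"`.
#' @export
pfm_control <- function(forget_rate = 0.6, delay = 5, batch_size = 50,
                        visits_per_subject = 2.5, min_group_updates = 5,
                        batch_cycles = 3, final_cycles = 12, tol = 1e-4,
                        hrf_cutoff_hz = 0.15, hrf_lambda = 1,
                        wishart_prior_dof = NULL, n_restarts = 10,
                        init = c("multiscale", "ica"),
                        consolidation_rounds = 3, reseed = TRUE,
                        seed = 1L) {
  if (forget_rate <= 0.5 || forget_rate > 1)
    stop("pfm_control: `forget_rate` must lie in (0.5, 1]")
  if (delay < 0) stop("pfm_control: `delay` must be >= 0")
  structure(list(forget_rate = forget_rate, delay = delay,
                 batch_size = as.integer(batch_size),
                 visits_per_subject = visits_per_subject,
                 min_group_updates = as.integer(min_group_updates),
                 batch_cycles = as.integer(batch_cycles),
                 final_cycles = as.integer(final_cycles), tol = tol,
                 hrf_cutoff_hz = hrf_cutoff_hz, hrf_lambda = hrf_lambda,
                 wishart_prior_dof = wishart_prior_dof,
                 n_restarts = as.integer(n_restarts),
                 init = match.arg(init),
                 consolidation_rounds = as.integer(consolidation_rounds),
                 reseed = isTRUE(reseed), seed = as.integer(seed)),
            class = "pfm_control")
}

#' Initial group maps by ICA on a reduced basis
#'
#' Spatial ICA (logcosh FastICA with restarts, best objective kept) of the
#' group spatial basis; maps are variance-normalised and sign-fixed.
#'
#' @inheritParams group_ica
#' @return N_v x `n_modes` matrix of initial group maps.
#' @export
init_group <- function(basis, n_modes, n_restarts = 10, seed = NULL) {
  group_ica(basis, n_modes, n_restarts = n_restarts, seed = seed)
}

## construct the initial group model from initial maps
.new_group_model <- function(maps0, tr, control) {
  nm <- ncol(maps0)
  nu0 <- control$wishart_prior_dof
  if (is.null(nu0)) nu0 <- nm + 10
  if (nu0 <= nm + 1) stop("wishart_prior_dof must exceed n_modes + 1")
  z <- abs(maps0)
  pi0 <- pmax(pmin((z / (1 + z))^2, 0.9), 0.02)
  structure(list(
    mu = maps0,
    pi = pi0,
    q = pi0,
    v_sig = rep(1, nm),
    v_noise = rep(0.05, nm),
    wishart_scale = diag(nm),
    wishart_dof = nu0,
    tr = tr,
    hrf_cutoff_hz = control$hrf_cutoff_hz,
    hrf_lambda = control$hrf_lambda,
    n_updates = 0L
  ), class = "pfm_group")
}

## log responsibilities of the signal component of the DGMM
.responsibilities <- function(p, group) {
  nm <- ncol(p)
  pi <- pmax(pmin(group$pi, 1 - 1e-4), 1e-4)
  ls <- log(pi) +
    stats::dnorm(p, mean = group$mu,
                 sd = rep(sqrt(group$v_sig), each = nrow(p)), log = TRUE)
  ln <- log1p(-pi) +
    stats::dnorm(p, mean = 0,
                 sd = rep(sqrt(group$v_noise), each = nrow(p)), log = TRUE)
  1 / (1 + exp(pmin(ln - ls, 700)))
}

## penalised log-posterior surrogate (free energy up to constants),
## with responsibilities held fixed
.free_energy <- function(state, data_list, group, resp) {
  nm <- ncol(state$p)
  f <- 0
  v0inv <- solve(group$wishart_scale / group$wishart_dof)
  nu0 <- group$wishart_dof
  for (r in seq_along(data_list)) {
    d <- data_list[[r]]
    nt <- ncol(d)
    b <- state$h[[r]] * state$a[[r]]
    res <- d - state$p %*% b
    s2 <- state$sigma2[[r]]
    f <- f - sum(res^2) / (2 * s2) - nrow(d) * nt / 2 * log(s2)
    aa <- tcrossprod(state$a[[r]])
    ld <- determinant(state$alpha[[r]], logarithm = TRUE)$modulus
    f <- f + (nt + nu0 - nm - 1) / 2 * ld -
      sum(state$alpha[[r]] * (aa + v0inv)) / 2
    hp <- state$a[[r]] -
      lowpass_rows(state$a[[r]], group$tr, group$hrf_cutoff_hz)
    f <- f - group$hrf_lambda / 2 * sum(hp^2)
  }
  pi <- pmax(pmin(group$pi, 1 - 1e-4), 1e-4)
  vs <- rep(sqrt(group$v_sig), each = nrow(state$p))
  vn <- rep(sqrt(group$v_noise), each = nrow(state$p))
  pr <- resp * (log(pi) +
                  stats::dnorm(state$p, group$mu, vs, log = TRUE)) +
    (1 - resp) * (log1p(-pi) + stats::dnorm(state$p, 0, vn, log = TRUE))
  ent <- -resp * log(pmax(resp, 1e-12)) -
    (1 - resp) * log(pmax(1 - resp, 1e-12))
  f + sum(pr) + sum(ent)
}

## exact minimiser of the A-subproblem: ridge with precision alpha plus the
## band-limitation penalty, solved per frequency bin in the DFT domain
.update_a <- function(d, p, h, alpha, sigma2, lambda, tr, cutoff) {
  nm <- length(h); nt <- ncol(d)
  q <- (outer(h, h) * crossprod(p)) / sigma2 + alpha
  rhs <- (h * crossprod(p, d)) / sigma2            # N_m x N_t
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  low <- freqs <= cutoff
  rf <- t(stats::mvfft(t(rhs)))
  out <- matrix(0 + 0i, nm, nt)
  if (any(low)) {
    ql <- q
    out[, low] <- solve(ql, Re(rf[, low, drop = FALSE])) +
      1i * solve(ql, Im(rf[, low, drop = FALSE]))
  }
  if (any(!low)) {
    qh <- q + diag(lambda, nm)
    out[, !low] <- solve(qh, Re(rf[, !low, drop = FALSE])) +
      1i * solve(qh, Im(rf[, !low, drop = FALSE]))
  }
  Re(t(stats::mvfft(t(out), inverse = TRUE))) / nt
}

## projected coordinate descent for the non-negative amplitude diagonal
.update_h <- function(d, p, a, h) {
  m <- crossprod(p) * tcrossprod(a)
  b <- diag(crossprod(p, d) %*% t(a))
  for (sweep in 1:3) {
    for (k in seq_along(h)) {
      num <- b[k] - sum(m[k, -k] * h[-k])
      h[k] <- if (m[k, k] > 0) max(0, num / m[k, k]) else 0
    }
  }
  h
}

#' Fit one subject against the current group model
#'
#' Coordinate-ascent updates cycling time courses (ridge with Wishart-linked
#' precision and haemodynamic band-limitation prior), amplitudes
#' (non-negative), temporal precision (conjugate Wishart form), noise
#' variance, and spatial maps (per-voxel responsibility-weighted shrinkage
#' toward the double-Gaussian group prior), until the relative free-energy
#' change falls below `tol` or the cycle budget is exhausted.
#'
#' @param datasets list of the subject's runs ([bold_dataset()] or matrices).
#' @param group a `"pfm_group"` model.
#' @param max_cycles cycle budget.
#' @param tol relative free-energy tolerance.
#' @param trace if `TRUE`, record the free energy after every coordinate
#'   update (used by the monotonicity tests).
#' @return list with `p` (N_v x N_m subject maps), `a` (per-run N_m x N_t
#'   time courses), `h` (per-run amplitude vectors), `alpha` (per-run SPD
#'   precisions), `sigma2` (per-run noise variances), `resp` (final signal
#'   responsibilities), `free_energy` (per-cycle trace), and optionally
#'   `fe_steps`.
#' @export
pfm_fit_subject <- function(datasets, group, max_cycles = 20, tol = 1e-4,
                            trace = FALSE) {
  stopifnot(inherits(group, "pfm_group"))
  data_list <- lapply(datasets, function(d)
    if (inherits(d, "bold_dataset")) d$data else as.matrix(d))
  data_list <- lapply(data_list, function(d) d - rowMeans(d))
  nv <- nrow(data_list[[1]]); nm <- ncol(group$mu)
  nr <- length(data_list)
  v0inv <- solve(group$wishart_scale / group$wishart_dof)
  nu0 <- group$wishart_dof

  state <- list(
    p = group$mu,
    a = vector("list", nr), h = rep(list(rep(1, nm)), nr),
    alpha = rep(list(diag(nm)), nr),
    sigma2 = rep(list(1), nr)
  )
  for (r in seq_len(nr)) {
    state$a[[r]] <- .update_a(data_list[[r]], state$p, state$h[[r]],
                              state$alpha[[r]], state$sigma2[[r]],
                              group$hrf_lambda, group$tr, group$hrf_cutoff_hz)
    rss <- sum((data_list[[r]] - state$p %*% state$a[[r]])^2)
    state$sigma2[[r]] <- max(rss / (nv * ncol(data_list[[r]])), 1e-8)
  }

  fe_trace <- numeric(0)
  fe_steps <- list()
  fe_prev <- -Inf
  for (cyc in seq_len(max_cycles)) {
    resp <- .responsibilities(state$p, group)
    steps <- numeric(0)
    ## --- A, H, alpha, sigma2 per run
    for (r in seq_len(nr)) {
      d <- data_list[[r]]; nt <- ncol(d)
      state$a[[r]] <- .update_a(d, state$p, state$h[[r]], state$alpha[[r]],
                                state$sigma2[[r]], group$hrf_lambda,
                                group$tr, group$hrf_cutoff_hz)
      if (trace) steps <- c(steps, .free_energy(state, data_list, group, resp))
      state$h[[r]] <- .update_h(d, state$p, state$a[[r]], state$h[[r]])
      if (trace) steps <- c(steps, .free_energy(state, data_list, group, resp))
      aa <- tcrossprod(state$a[[r]])
      state$alpha[[r]] <- (nt + nu0 - nm - 1) * solve(aa + v0inv)
      state$alpha[[r]] <- (state$alpha[[r]] + t(state$alpha[[r]])) / 2
      if (trace) steps <- c(steps, .free_energy(state, data_list, group, resp))
      rss <- sum((d - state$p %*% (state$h[[r]] * state$a[[r]]))^2)
      state$sigma2[[r]] <- max(rss / (nv * nt), 1e-8)
      if (trace) steps <- c(steps, .free_energy(state, data_list, group, resp))
    }
    ## --- P: mean-field sweep over modes, all runs jointly
    prior_prec <- sweep(resp, 2, 1 / group$v_sig, "*") +
      sweep(1 - resp, 2, 1 / group$v_noise, "*")
    prior_mp <- sweep(resp * group$mu, 2, 1 / group$v_sig, "*")
    dbt <- vector("list", nr); g <- vector("list", nr)
    for (r in seq_len(nr)) {
      b <- state$h[[r]] * state$a[[r]]
      dbt[[r]] <- data_list[[r]] %*% t(b) / state$sigma2[[r]]
      g[[r]] <- tcrossprod(b) / state$sigma2[[r]]
    }
    for (m in seq_len(nm)) {
      num <- prior_mp[, m]
      den <- prior_prec[, m]
      for (r in seq_len(nr)) {
        num <- num + dbt[[r]][, m] - drop(state$p %*% g[[r]][, m]) +
          state$p[, m] * g[[r]][m, m]
        den <- den + g[[r]][m, m]
      }
      state$p[, m] <- num / den
    }
    if (trace) steps <- c(steps, .free_energy(state, data_list, group, resp))

    fe <- .free_energy(state, data_list, group, resp)
    if (!is.finite(fe)) stop("pfm_fit_subject: non-finite free energy")
    fe_trace <- c(fe_trace, fe)
    if (trace) fe_steps[[cyc]] <- steps
    if (is.finite(fe_prev) &&
        abs(fe - fe_prev) < tol * (abs(fe_prev) + 1e-12)) break
    fe_prev <- fe
  }
  state$resp <- .responsibilities(state$p, group)
  state$free_energy <- fe_trace
  if (trace) state$fe_steps <- fe_steps
  state
}

#' Blend a batch of subject posteriors into the group model
#'
#' Accumulates batch sufficient statistics (responsibility-weighted map
#' means and variances, mixture weights, background variances, mean subject
#' precision) and blends them into the group parameters with step size
#' `rho_t = (t + tau)^(-beta)`.
#'
#' @param posteriors list of [pfm_fit_subject()] results.
#' @param group current `"pfm_group"`.
#' @param t 1-based group update index.
#' @param beta,tau step-size schedule parameters; `beta` in \[0, 1\],
#'   `tau >= 0`.
#' @return the updated `"pfm_group"`.
#' @export
pfm_update_group <- function(posteriors, group, t,
                             beta = 0.6, tau = 5) {
  if (length(posteriors) < 1) stop("pfm_update_group: empty batch")
  if (beta < 0 || beta > 1) stop("pfm_update_group: `beta` must be in [0, 1]")
  if (tau < 0) stop("pfm_update_group: `tau` must be >= 0")
  rho <- (t + tau)^(-beta)
  nm <- ncol(group$mu)

  sum_rp <- 0; sum_r <- 0; sum_p2n <- 0; sum_n <- 0
  psi <- 0; n_alpha <- 0
  for (s in posteriors) {
    sum_rp <- sum_rp + s$resp * s$p
    sum_r <- sum_r + s$resp
    sum_p2n <- sum_p2n + (1 - s$resp) * s$p^2
    sum_n <- sum_n + (1 - s$resp)
    for (al in s$alpha) { psi <- psi + al; n_alpha <- n_alpha + 1 }
  }
  mu_batch <- sum_rp / pmax(sum_r, 1e-3)
  pi_batch <- sum_r / length(posteriors)
  ## group-level signal evidence: accumulate per-subject log odds of the
  ## signal component (spike-and-slab consensus; near-binary with enough
  ## subjects, which is what sharpens the group map against warp blur)
  lo <- 0
  pri <- pmax(pmin(group$pi, 1 - 1e-4), 1e-4)
  pri_lo <- log(pri / (1 - pri))
  for (s in posteriors) {
    rs <- pmax(pmin(s$resp, 1 - 1e-4), 1e-4)
    lo <- lo + log(rs / (1 - rs)) - pri_lo
  }
  q_batch <- 1 / (1 + exp(-pmin(pmax(lo + pri_lo, -30), 30)))
  v_sig_batch <- vapply(seq_len(nm), function(m) {
    num <- 0; den <- 0
    for (s in posteriors) {
      num <- num + sum(s$resp[, m] * (s$p[, m] - mu_batch[, m])^2)
      den <- den + sum(s$resp[, m])
    }
    max(num / max(den, 1e-3), 1e-4)
  }, numeric(1))
  v_noise_batch <- vapply(seq_len(nm), function(m)
    max(sum(sum_p2n[, m]) / max(sum(sum_n[, m]), 1e-3), 1e-6), numeric(1))
  psi_batch <- psi / n_alpha

  group$mu <- (1 - rho) * group$mu + rho * mu_batch
  group$pi <- (1 - rho) * group$pi + rho * pi_batch
  group$q <- (1 - rho) * group$q + rho * q_batch
  group$v_sig <- (1 - rho) * group$v_sig + rho * v_sig_batch
  group$v_noise <- (1 - rho) * group$v_noise + rho * v_noise_batch
  group$wishart_scale <- (1 - rho) * group$wishart_scale + rho * psi_batch
  group$n_updates <- group$n_updates + 1L
  group
}

## one stochastic phase: decaying-step batches, then full-batch
## consolidation M-steps (rho = 1), the desk-scale analogue of running the
## schedule to convergence
.run_phase <- function(datasets, runs_of, group, control,
                       n_batches, n_consol, cycles) {
  ns <- length(runs_of)
  batch_size <- min(control$batch_size, ns)
  for (t in seq_len(n_batches)) {
    batch <- if (batch_size >= ns) seq_len(ns) else sample.int(ns, batch_size)
    post <- lapply(batch, function(si)
      pfm_fit_subject(datasets[runs_of[[si]]], group,
                      max_cycles = cycles, tol = control$tol))
    group <- pfm_update_group(post, group, t,
                              beta = control$forget_rate, tau = control$delay)
  }
  for (it in seq_len(n_consol)) {
    post <- lapply(seq_len(ns), function(si)
      pfm_fit_subject(datasets[runs_of[[si]]], group,
                      max_cycles = 2L * cycles, tol = control$tol))
    group <- pfm_update_group(post, group, t = 1, beta = 0, tau = 0)
  }
  group
}

## subject time courses by joint spatial regression of `maps` on each run
.regress_tc <- function(maps, run_mats) {
  qm <- qr(maps)
  lapply(run_mats, function(x) qr.coef(qm, x))
}

## Multi-resolution initial maps: consolidated low-dimensional parents with
## fragment merging, then within-parent subcomponent candidates for the
## remaining modes, selected by their unexplained-variance evidence.
.init_multiscale <- function(datasets, runs_of, n_modes, tr, control) {
  run_mats <- lapply(datasets, function(d) d$data - rowMeans(d$data))
  nv <- nrow(run_mats[[1]])
  basis <- migp_reduce(datasets, n_components = min(2L * n_modes, nv))
  n1 <- max(2L, ceiling(n_modes / 2))
  k1 <- min(ncol(basis), n1 + 3L)

  ## stage 1: overcomplete ICA, short hierarchical consolidation
  m1 <- init_group(basis, k1, n_restarts = control$n_restarts)
  grp1 <- .new_group_model(m1, tr, control)
  grp1 <- .run_phase(datasets, runs_of, grp1, control,
                     n_batches = 4, n_consol = 2, cycles = control$batch_cycles)
  mu1 <- grp1$mu * grp1$q

  ## merge temporally redundant fragments (split blocks of one distributed
  ## mode share a time course; their maps simply add) down to n1 parents
  while (ncol(mu1) > n1) {
    tcs <- .regress_tc(mu1, run_mats)
    tcc <- Reduce(`+`, lapply(tcs, function(tc) abs(stats::cor(t(tc))))) /
      length(tcs)
    diag(tcc) <- 0
    ij <- which(tcc == max(tcc), arr.ind = TRUE)[1, ]
    mu1[, ij[1]] <- mu1[, ij[1]] + mu1[, ij[2]]
    mu1 <- mu1[, -ij[2], drop = FALSE]
  }
  parents <- fix_sign(scale(mu1))
  dimnames(parents) <- NULL
  if (n_modes <= n1) return(parents[, seq_len(n_modes), drop = FALSE])

  ## stage 2: temporal subcomponents inside each parent as candidates for
  ## the finer-scale modes
  resid <- lapply(run_mats, function(x)
    x - parents %*% qr.coef(qr(parents), x))
  cands <- list()
  for (i in seq_len(n1)) {
    wl <- lapply(datasets, function(d) weight_data(d, pmax(parents[, i], 0)))
    sub <- tryCatch(tica_subcomponents(wl, k = 3, seed = NULL),
                    error = function(e) NULL)
    if (is.null(sub)) next
    cands[[length(cands) + 1L]] <- Reduce(`+`, sub$maps) / length(sub$maps)
  }
  if (!length(cands)) return(init_group(basis, n_modes,
                                        n_restarts = control$n_restarts))
  cand <- scale(do.call(cbind, cands))
  cand[!is.finite(cand)] <- 0
  ## candidate evidence: variance of its regression time course on the
  ## parent-residualised data
  score <- rep(0, ncol(cand))
  for (x in resid) {
    tc <- crossprod(cand, x) / pmax(colSums(cand^2), 1e-12)
    score <- score + apply(tc, 1, stats::var)
  }
  sel <- integer(0)
  for (j in order(score, decreasing = TRUE)) {
    if (length(sel) >= n_modes - n1) break
    if (length(sel) > 0 &&
        max(abs(stats::cor(cand[, j], cand[, sel, drop = FALSE]))) > 0.8)
      next
    sel <- c(sel, j)
  }
  ## top up from the basis ICA if deduplication left a shortfall
  if (length(sel) < n_modes - n1) {
    extra <- init_group(basis, n_modes, n_restarts = control$n_restarts)
    need <- n_modes - n1 - length(sel)
    m0 <- cbind(parents, cand[, sel, drop = FALSE],
                extra[, seq_len(need), drop = FALSE])
  } else {
    m0 <- cbind(parents, cand[, sel, drop = FALSE])
  }
  m0 <- fix_sign(scale(m0))
  dimnames(m0) <- NULL
  m0
}

## per-mode unique explained variance: amplitude-scaled map energy times the
## variance of the mode's time course after regression on all other modes
.unique_variance <- function(post) {
  nm <- nrow(post[[1]]$a[[1]])
  uv <- matrix(0, nm, 0)
  for (s in seq_along(post)) {
    p2 <- colSums(post[[s]]$p^2)
    for (r in seq_along(post[[s]]$a)) {
      a <- post[[s]]$a[[r]]
      h <- post[[s]]$h[[r]]
      u <- vapply(seq_len(nm), function(m) {
        res <- stats::lsfit(t(a[-m, , drop = FALSE]), a[m, ],
                            intercept = TRUE)$residuals
        h[m]^2 * p2[m] * mean(res^2)
      }, numeric(1))
      uv <- cbind(uv, u)
    }
  }
  rowMeans(uv)
}

#' Hierarchical probabilistic functional-mode decomposition
#'
#' Fits the full two-level model. Initial group maps come from a
#' multi-resolution scheme: an incremental group PCA (MIGP) basis, a
#' consolidated low-dimensional decomposition whose temporally redundant
#' fragments are merged into parent modes, and within-parent temporal
#' subcomponents seeding the finer-scale modes (spatial ICA alone
#' under-represents localised sub-modes nested inside distributed ones).
#' The full model is then refined by a stochastic batched loop -- subjects
#' fitted against the current group model, posteriors blended back with
#' step size `(t + tau)^(-beta)` -- followed by full-batch consolidation
#' updates. Modes that end up with no unique explained variance are
#' re-seeded once from the structure of the model residuals. A final full
#' pass fits every subject against the frozen group model.
#'
#' @param datasets list of [bold_dataset()] objects (all subjects, all runs).
#' @param n_modes number of modes to estimate.
#' @param control a [pfm_control()].
#' @param basis optional precomputed N_v x K spatial basis (shared with an
#'   [icadr()] fit for head-to-head comparisons; only used by the plain ICA
#'   initialisation).
#' @return an object of class `"pfm"`: `group_maps` (N_v x N_m
#'   posterior-expected group maps), `group` (full group model),
#'   `subject_maps` (list per subject), `timecourses` (`[[subject]][[run]]`,
#'   amplitude-scaled), `amplitudes`, `precisions`, `noise_var`, `subjects`,
#'   `method = "PFM"`.
#' @export
#' @seealso [icadr()] for the baseline, [score_recovery()] for benchmarking,
#'   [qc_modes()] for mode quality control.
pfm <- function(datasets, n_modes, control = pfm_control(), basis = NULL) {
  stopifnot(inherits(control, "pfm_control"))
  set.seed(control$seed)
  subjects <- vapply(datasets, function(d) d$subject_id, numeric(1))
  tr <- datasets[[1]]$tr_seconds
  usub <- unique(subjects)
  ns <- length(usub)
  runs_of <- lapply(usub, function(u) which(subjects == u))

  if (control$init == "multiscale" && n_modes >= 4) {
    maps0 <- .init_multiscale(datasets, runs_of, n_modes, tr, control)
  } else {
    if (is.null(basis))
      basis <- migp_reduce(datasets, n_components = min(2L * n_modes,
                                                        nrow(datasets[[1]]$data)))
    maps0 <- init_group(basis, n_modes, n_restarts = control$n_restarts)
  }
  group <- .new_group_model(maps0, tr, control)

  batch_size <- min(control$batch_size, ns)
  n_batches <- max(control$min_group_updates,
                   ceiling(control$visits_per_subject * ns / batch_size))
  group <- .run_phase(datasets, runs_of, group, control, n_batches,
                      control$consolidation_rounds, control$batch_cycles)

  ## re-seed modes with no unique evidence from the model residuals
  if (isTRUE(control$reseed)) {
    post <- lapply(seq_len(ns), function(si)
      pfm_fit_subject(datasets[runs_of[[si]]], group,
                      max_cycles = control$batch_cycles, tol = control$tol))
    uv <- .unique_variance(post)
    dead <- which(uv < 0.05 * stats::median(uv))
    if (length(dead)) {
      resid <- list()
      for (si in seq_len(ns)) {
        for (r in seq_along(runs_of[[si]])) {
          d <- datasets[[runs_of[[si]][r]]]$data
          d <- d - rowMeans(d)
          resid[[length(resid) + 1L]] <-
            d - post[[si]]$p %*% (post[[si]]$h[[r]] * post[[si]]$a[[r]])
        }
      }
      cand <- tryCatch({
        b2 <- migp_reduce(resid, min(2L * length(dead) + 4L, nrow(group$mu)))
        init_group(b2, length(dead), n_restarts = control$n_restarts)
      }, error = function(e) NULL)
      if (!is.null(cand)) {
        sc <- stats::median(apply(abs(group$mu), 2, max))
        for (k in seq_along(dead)) {
          cmap <- cand[, k] * sc / max(abs(cand[, k]))
          group$mu[, dead[k]] <- cmap
          z <- abs(cmap)
          group$pi[, dead[k]] <- pmax(pmin((z / (1 + z))^2, 0.9), 0.02)
          group$q[, dead[k]] <- group$pi[, dead[k]]
        }
        group <- .run_phase(datasets, runs_of, group, control,
                            n_batches = 2, n_consol = 2,
                            cycles = control$batch_cycles)
      }
    }
  }

  ## final full pass against the frozen group model
  subject_maps <- vector("list", ns)
  timecourses <- vector("list", ns)
  amplitudes <- vector("list", ns)
  precisions <- vector("list", ns)
  noise_var <- vector("list", ns)
  for (si in seq_len(ns)) {
    st <- pfm_fit_subject(datasets[runs_of[[si]]], group,
                          max_cycles = control$final_cycles,
                          tol = control$tol)
    subject_maps[[si]] <- st$p
    timecourses[[si]] <- lapply(seq_along(st$a), function(r)
      st$h[[r]] * st$a[[r]])
    amplitudes[[si]] <- st$h
    precisions[[si]] <- st$alpha
    noise_var[[si]] <- st$sigma2
  }

  ## group map estimate: posterior-expected signal map (mixture mean gated
  ## by the accumulated group-level signal probability)
  structure(list(group_maps = fix_sign(group$mu * group$q), group = group,
                 subject_maps = subject_maps, timecourses = timecourses,
                 amplitudes = amplitudes, precisions = precisions,
                 noise_var = noise_var, subjects = usub, n_modes = n_modes,
                 basis = basis, control = control, method = "PFM"),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Probabilistic functional modes: %d modes, %d subjects, %d group update(s)\n",
              x$n_modes, length(x$subjects), x$group$n_updates))
  cat(sprintf("  mean residual variance: %.4g\n",
              mean(unlist(x$noise_var))))
  invisible(x)
}

#' @export
coef.pfm <- function(object, ...) object$group_maps

#' @export
summary.pfm <- function(object, ...) {
  qc <- qc_modes(object)
  out <- list(n_modes = object$n_modes, n_subjects = length(object$subjects),
              qc = qc,
              amplitude = sapply(object$amplitudes, function(h)
                rowMeans(do.call(cbind, h))))
  class(out) <- "summary.pfm"
  out
}

#' @export
print.summary.pfm <- function(x, ...) {
  cat(sprintf("PFM decomposition: %d modes x %d subjects\n",
              x$n_modes, x$n_subjects))
  print(x$qc)
  invisible(x)
}

#' @export
plot.pfm <- function(x, modes = seq_len(min(6, x$n_modes)), ...) {
  maps <- x$group_maps[, modes, drop = FALSE]
  graphics::matplot(maps, type = "l", lty = 1,
                    xlab = "voxel (1-D lattice)", ylab = "group map weight",
                    main = "PFM group spatial maps", ...)
  invisible(x)
}

#' @export
fitted.pfm <- function(object, subject = 1, run = 1, ...) {
  object$subject_maps[[subject]] %*% object$timecourses[[subject]][[run]]
}

#' Mode quality-control report
#'
#' Flags each mode-by-subject fit using subject-to-group spatial map
#' similarity: `noisy` below 0.1 (the subject map is essentially noise),
#' `reverted` above 0.99 (the posterior fell back to the group prior), `ok`
#' otherwise. Modes whose across-voxel map SD is an extreme outlier
#' (median +/- 5 MAD across modes) are additionally flagged `artefactual`.
#' Flagging is advisory; removal is left to the user.
#'
#' @param model a fitted `"pfm"` object.
#' @param noisy_threshold,reverted_threshold similarity thresholds.
#' @return an object of class `"qc_report"`: data frame with one row per
#'   mode x subject (`mode`, `subject`, `similarity`, `flag`) plus a
#'   per-mode summary attribute.
#' @export
qc_modes <- function(model, noisy_threshold = 0.1,
                     reverted_threshold = 0.99) {
  stopifnot(inherits(model, "pfm"))
  nm <- model$n_modes
  rows <- list()
  for (si in seq_along(model$subject_maps)) {
    r <- diag(colcor(model$subject_maps[[si]], model$group_maps))
    r[!is.finite(r)] <- 0
    flag <- ifelse(abs(r) < noisy_threshold, "noisy",
                   ifelse(abs(r) > reverted_threshold, "reverted", "ok"))
    rows[[si]] <- data.frame(mode = seq_len(nm), subject = model$subjects[si],
                             similarity = r, flag = flag)
  }
  qc <- do.call(rbind, rows)
  map_sd <- apply(model$group_maps, 2, stats::sd)
  med <- stats::median(map_sd); madv <- stats::mad(map_sd)
  artefact <- if (madv > 0) which(abs(map_sd - med) > 5 * madv) else integer(0)
  qc$flag[qc$mode %in% artefact] <- "artefactual"
  summary <- data.frame(
    mode = seq_len(nm),
    mean_similarity = tapply(qc$similarity, qc$mode, mean),
    map_sd = map_sd,
    n_noisy = tapply(qc$flag == "noisy", qc$mode, sum),
    n_reverted = tapply(qc$flag == "reverted", qc$mode, sum),
    artefactual = seq_len(nm) %in% artefact, row.names = NULL)
  structure(qc, class = c("qc_report", "data.frame"), summary = summary)
}

#' @export
print.qc_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Mode QC summary (subject-to-group map similarity):\n")
  print.data.frame(s, digits = 3, row.names = FALSE)
  invisible(x)
}
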