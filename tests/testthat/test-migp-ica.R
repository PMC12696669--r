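test_that("incremental group PCA spans single runs exactly", {
  set.seed(1)
  d <- matrix(rnorm(100 * 40), 100, 40)
  basis <- migp_reduce(list(d), n_components = 40, block_size = 60, seed = 1)
  dd <- d - rowMeans(d)
  proj <- basis %*% qr.coef(qr(basis), dd)
  expect_lt(max(abs(proj - dd)), 1e-8)
})

test_that("incremental group PCA recovers exact low-rank group structure", {
  tt <- tiny_truth(nv = 200, nm = 6, nt = 40, seed = 2)
  runs <- lapply(1:20, function(i) {
    a <- matrix(rnorm(6 * 40), 6)
    tt$maps %*% a
  })
  basis <- migp_reduce(runs, n_components = 10, block_size = 14, seed = 3)
  sv <- svd(basis)$d
  expect_lt(sv[7] / sv[1], 1e-8)                      # rank 6 signal
  ## the signal subspace is captured: projection of truth is lossless
  sig <- basis[, 1:6, drop = FALSE]
  proj <- sig %*% qr.coef(qr(sig), tt$maps)
  expect_gt(min(abs(diag(cor(proj, tt$maps)))), 1 - 1e-6)
})

test_that("incremental PCA agrees with full-concatenation SVD under noise", {
  tt <- tiny_truth(nv = 150, nm = 4, nt = 30, seed = 4)
  runs <- lapply(1:20, function(i)
    tt$maps %*% matrix(rnorm(4 * 30), 4) + matrix(rnorm(150 * 30, sd = 0.5),
                                                  150))
  basis <- migp_reduce(runs, n_components = 4, block_size = 12, seed = 5)
  concat <- do.call(cbind, lapply(runs, function(d) d - rowMeans(d)))
  full <- svd(concat, nu = 4, nv = 0)$u
  ## principal angles between the two 4-dim subspaces below 5 degrees
  qb <- qr.Q(qr(basis))
  angles <- acos(pmin(1, svd(crossprod(qb, full))$d)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("migp_reduce rejects impossible dimensions", {
  d <- matrix(rnorm(50 * 10), 50, 10)
  expect_error(migp_reduce(list(d), n_components = 60), "exceeds")
  expect_error(migp_reduce(list(d), n_components = 20, block_size = 30),
               "temporal rank")
})

test_that("FastICA recovers independent non-Gaussian sources", {
  set.seed(6)
  n <- 3000
  s <- rbind(sign(rnorm(n)) * abs(rnorm(n))^2,
             runif(n, -1, 1)^3,
             rexp(n) - 1)
  mix <- matrix(rnorm(9), 3)
  x <- mix %*% s
  res <- fast_ica(x, 3, n_restarts = 5, seed = 7)
  r <- abs(cor(t(res$s), t(s)))
  perm <- solve_assignment(-r)
  expect_gt(min(r[cbind(1:3, perm)]), 0.95)
})

test_that("FastICA flags Gaussian data instead of pretending", {
  set.seed(8)
  x <- matrix(rnorm(4 * 2000), 4)
  expect_error(fast_ica(x, 4, n_restarts = 2, max_iter = 40), "converged")
})

test_that("group ICA is deterministic under a fixed seed", {
  tt <- tiny_truth(nv = 200, nm = 4, nt = 60, seed = 9)
  basis <- tt$maps + matrix(rnorm(800, sd = 0.05), 200)
  m1 <- group_ica(basis, 4, n_restarts = 3, seed = 10)
  m2 <- group_ica(basis, 4, n_restarts = 3, seed = 10)
  expect_identical(m1, m2)
  ## on a basis that is the truth itself, sources come back
  pr <- pair_modes(tt$maps, m1)
  expect_gt(mean(pr$abs_r), 0.95)
})
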