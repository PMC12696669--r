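## tiny permutation enumerator used only as a test oracle
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

test_that("Hungarian assignment matches brute force on small instances", {
  set.seed(1)
  for (trial in 1:25) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n)
    got <- solve_assignment(cost)
    perms <- matrix(unlist(combinat_perms(n)), ncol = n, byrow = TRUE)
    totals <- apply(perms, 1, function(p) sum(cost[cbind(1:n, p)]))
    expect_equal(sum(cost[cbind(1:n, got)]), min(totals), tolerance = 1e-12)
  }
})

test_that("rectangular assignment picks the best columns", {
  cost <- rbind(c(5, 1, 9, 9), c(9, 9, 9, 2))
  expect_equal(solve_assignment(cost), c(2L, 4L))
  expect_error(solve_assignment(t(cost)), "more rows")
})

test_that("the optimal matching beats greedy on a crafted instance", {
  ## greedy grabs (1,1) = 0.9 and is then forced into a poor total
  r <- rbind(c(0.9, 0.85, 0.1),
             c(0.89, 0.1, 0.1),
             c(0.1, 0.8, 0.15))
  hung <- solve_assignment(-r)
  hung_total <- sum(r[cbind(1:3, hung)])
  greedy <- integer(3); taken <- rep(FALSE, 3)
  for (i in 1:3) {
    j <- which.max(replace(r[i, ], taken, -Inf))
    greedy[i] <- j; taken[j] <- TRUE
  }
  expect_gt(hung_total, sum(r[cbind(1:3, greedy)]))
})

test_that("pair_modes recovers permutations and labels primaries", {
  tt <- tiny_truth(nv = 200, nm = 5, nt = 50, seed = 2)
  perm <- c(4, 2, 5, 1, 3)
  pr <- pair_modes(tt$maps, tt$maps[, perm])
  expect_equal(pr$match[perm], 1:5)
  expect_equal(unname(pr$abs_r), rep(1, 5), tolerance = 1e-12)
  ## noisy copy keeps the same matching
  noisy <- tt$maps[, perm] + matrix(rnorm(1000, sd = 0.1), 200)
  pr2 <- pair_modes(tt$maps, noisy)
  expect_equal(pr2$match, pr$match)
  expect_gt(mean(pr2$abs_r), 0.9)
  ## extra candidate columns become secondary
  wide <- cbind(tt$maps, matrix(rnorm(400), 200))
  pr3 <- pair_modes(tt$maps, wide)
  expect_equal(sum(pr3$label == "primary"), 5)
  expect_equal(sum(pr3$label == "secondary"), 2)
})

test_that("reproducibility bins exhaust all pairs", {
  tt <- tiny_truth(nv = 150, nm = 4, nt = 40, seed = 3)
  pr <- pair_modes(tt$maps, tt$maps)
  rep <- reproducibility_report(pr)
  expect_equal(sum(rep$counts), 4)
  expect_equal(unname(rep$counts["high"]), 4L)
  ## crafted correlations fall into the right bins
  pr$abs_r <- c(0.8, 0.6, 0.4, 0.75)
  pr$bins <- c(high = sum(pr$abs_r >= 0.7),
               mid = sum(pr$abs_r >= 0.5 & pr$abs_r < 0.7),
               low = sum(pr$abs_r < 0.5))
  rep2 <- reproducibility_report(pr)
  expect_equal(unname(rep2$counts), c(2L, 1L, 1L))
})
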