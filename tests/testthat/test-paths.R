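test_that("optimalPathA minimizes peak then accumulated activation energy", {
  bhg <- .forkBHG()
  res <- optimalPathA(bhg, "lm001", "lm004")
  expect_identical(res$path, c("lm001", "lm002", "lm003", "lm004"))
  expect_equal(res$peak, bhgSaddle(bhg, "lm001", "lm004"))
  expect_equal(res$peak, -0.5)
  # brute force: no path has a lower peak; among minimal peaks none has a
  # lower accumulated activation energy
  all <- .allPaths(bhg, "lm001", "lm004")
  stats <- lapply(all, .pathStats, bhg = bhg)
  peaks <- vapply(stats, `[[`, numeric(1), "peak")
  expect_equal(min(peaks), res$peak)
  acts <- vapply(stats[peaks <= res$peak + 1e-9], `[[`, numeric(1),
                 "activation")
  expect_equal(min(acts), res$activation)
  # per-step bookkeeping is consistent
  expect_equal(sum(res$steps$activation), res$activation)
  expect_equal(max(res$steps$saddle), res$peak)
})

test_that("optimalPathA handles edge cases", {
  bhg <- .forkBHG()
  same <- optimalPathA(bhg, "lm003", "lm003")
  expect_identical(same$path, "lm003")
  expect_equal(same$activation, 0)
  expect_error(optimalPathA(bhg, "lm001", "zzz"), "unknown")
})

test_that("trajectoryLogLik matches a hand computation", {
  bhg <- .forkBHG()
  model <- rateMatrix(bhg)
  Q <- generator(model)
  u <- trajectory(c("lm001", "lm002", "lm003"), waits = c(2, 1), horizon = 5)
  want <- log(Q["lm001", "lm002"]) + log(Q["lm002", "lm003"]) -
    (-Q["lm001", "lm001"] * 2 + -Q["lm002", "lm002"] * 1 +
       -Q["lm003", "lm003"] * (5 - 3))
  expect_equal(unname(trajectoryLogLik(u, model)), unname(want))
  # waits beyond the horizon have zero likelihood
  u2 <- trajectory(c("lm001", "lm002"), waits = 9, horizon = 5)
  expect_identical(trajectoryLogLik(u2, model), -Inf)
  # non-adjacent consecutive states are rejected
  u3 <- trajectory(c("lm001", "lm003"), waits = 1, horizon = 5)
  expect_error(trajectoryLogLik(u3, model), "not adjacent")
})

test_that("optimalPathB at Tm = 0 maximizes the trajectory likelihood", {
  bhg <- .forkBHG()
  model <- rateMatrix(bhg)
  res <- optimalPathB(bhg, model, "lm001", "lm004", Tm = 0)
  # brute force over all simple paths
  lls <- vapply(.allPaths(bhg, "lm001", "lm004"), function(path)
    trajectoryLogLik(trajectory(path, waits = rep(0, length(path) - 1L),
                                horizon = 0), model), numeric(1))
  expect_equal(unname(res$logLik), max(lls))
})

test_that("optimalPathB with a horizon follows the closed form", {
  bhg <- .forkBHG()
  model <- rateMatrix(bhg)
  Tm <- 3.5
  res <- optimalPathB(bhg, model, "lm001", "lm004", Tm = Tm)
  path <- res$trajectory@states
  Q <- generator(model)
  at <- match(path, stateTable(model)$id)
  logr <- sum(log(Q[cbind(at[-length(at)], at[-1L])]))
  lamMin <- min(-diag(Q)[at])
  expect_equal(unname(res$logLik), unname(logr - Tm * lamMin))
  expect_equal(res$trajectory@horizon, Tm)
  expect_equal(trajectoryLogLik(res$trajectory, model), res$logLik)
})
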