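# synthetic two-state model with known closed-form relaxation
.twoStateModel <- function(e1 = -2, e2 = -1, s = 1.5) {
  lm <- data.frame(id = c("lm001", "lm002"),
                   structure = c("((((.....))))..", "..((((.....))))"),
                   energy = c(e1, e2), pkClass = "N",
                   count = NA_integer_, stringsAsFactors = FALSE)
  edges <- data.frame(from = "lm001", to = "lm002", saddle = s,
                      pkClass = NA_character_, stringsAsFactors = FALSE)
  bhg <- new("BasinHoppingGraph", sequence = strrep("A", 15L), lm = lm,
             edges = edges, witnesses = list(), variant = "psi",
             mode = "heuristic", params = energyParams())
  rateMatrix(bhg)
}

test_that("rateMatrix implements the Arrhenius rule with detailed balance", {
  bhg <- ringBHG(5L)
  model <- rateMatrix(bhg)
  Q <- generator(model)
  expect_equal(rowSums(Q), setNames(rep(0, nStates(model)),
                                    stateTable(model)$id))
  offdiag <- Q; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  # spot-check the rate formula on the first edge
  ed <- edgeTable(bhg); lm <- lmTable(bhg)
  RT <- thermalEnergy(bhg@params)
  x <- ed$from[1]; y <- ed$to[1]
  fy <- lm$energy[match(y, lm$id)]
  expect_equal(Q[y, x], exp(-(ed$saddle[1] - fy) / RT))
  # detailed balance with respect to the Boltzmann distribution
  pi <- equilibriumDistribution(model)
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12)
  expect_error(rateMatrix({
    bad <- bhg; bad@edges$saddle[1] <- -100; bad
  }), "saddle")
})

test_that("microscopicModel applies the Metropolis rule", {
  p <- energyParams()
  fx <- generateFixtures("pk_free", compute = FALSE)[[1]]
  model <- microscopicModel(fx$sequence, p, ceiling = 8)
  Q <- generator(model)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  st <- stateTable(model)
  RT <- thermalEnergy(p)
  # off-diagonal entries are min(1, exp(-dE/RT)) exactly on neighbor pairs
  nz <- which(Q > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  for (r in seq_len(min(50L, nrow(nz)))) {
    a <- nz[r, 1]; b <- nz[r, 2]
    expect_equal(Q[a, b],
                 min(1, exp(-(st$energy[b] - st$energy[a]) / RT)),
                 tolerance = 1e-12)
    # and the underlying structures differ by exactly one base pair
    pa <- pairingTable(parseStructure(st$structure[a]))
    pb <- pairingTable(parseStructure(st$structure[b]))
    expect_equal(sum(pa != pb), 2L)
  }
})

test_that("propagate matches the closed-form two-state solution", {
  model <- .twoStateModel()
  Q <- generator(model)
  times <- logTimeGrid(1e-2, 1e6, perDecade = 10)
  ser <- propagate(model, p0 = c(0, 1), times = times)
  expect_equal(ser@times, times)
  expect_equal(rowSums(ser@P), rep(1, length(times)), tolerance = 1e-9)
  analytic <- oracleTwoState(a = Q[1, 2], b = Q[2, 1], p1_0 = 0, times = times)
  expect_equal(unname(ser@P[, 1]), analytic, tolerance = 1e-9)
})

test_that("propagate conserves probability and reaches Boltzmann", {
  bhg <- ringBHG(6L)
  model <- rateMatrix(bhg)
  p0 <- as.numeric(stateTable(model)$id == "lm002")
  ser <- propagate(model, p0 = p0)
  expect_equal(rowSums(ser@P), rep(1, length(ser@times)), tolerance = 1e-9)
  expect_true(all(ser@P >= 0))
  eq <- equilibriumDistribution(model)
  expect_equal(sum(eq), 1)
  expect_equal(unname(ser@P[nrow(ser@P), ]), unname(eq), tolerance = 1e-9)
  tEq <- equilibriumTime(ser, eq)
  expect_true(is.finite(tEq))
  # populations at the first grid point are still near the start vector
  expect_equal(unname(ser@P[1, ]), p0, tolerance = 1e-3)
})

test_that("propagate validates its start vector", {
  model <- .twoStateModel()
  expect_error(propagate(model, p0 = c(0.5, 0.4)), "probability")
  expect_error(propagate(model, p0 = c(-0.5, 1.5)), "probability")
  # no open-chain state in this synthetic model, so p0 is mandatory
  expect_error(propagate(model), "open-chain")
})

test_that("qssReduce preserves row sums and the retained equilibrium", {
  bhg <- ringBHG(8L)
  full <- rateMatrix(bhg)
  red <- qssReduce(full, maxStates = 8L)
  Q <- generator(red)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(nStates(red), 8L)
  # equilibrium over retained states stays Boltzmann
  eq <- equilibriumDistribution(red)
  piQ <- as.numeric(eq %*% Q)
  expect_equal(max(abs(piQ)), 0, tolerance = 1e-12)
  # the eliminated states are the shallow intermediates (all degree 2, so
  # the documented tie-break removes the highest-energy states first)
  inter <- stateTable(full)$id[seq(2L, 16L, by = 2L)]
  expect_false(any(inter %in% stateTable(red)$id))
})

test_that("qssReduce honors protected states", {
  full <- rateMatrix(ringBHG(4L))
  keep <- stateTable(full)$id[c(2, 4, 6, 8)]  # the shallow intermediates
  red <- qssReduce(full, maxStates = 5L, protect = keep)
  expect_true(all(keep %in% stateTable(red)$id))
  expect_error(qssReduce(full, maxStates = 2L, protect = keep), "maxStates")
  expect_error(qssReduce(full, maxStates = 4L, protect = "zzz"), "unknown")
})

test_that("aggregatePopulations sums columns by group", {
  model <- rateMatrix(ringBHG(3L))
  ser <- propagate(model, p0 = as.numeric(stateTable(model)$id == "lm001"))
  groups <- rep(c("a", "b"), length.out = nStates(model))
  agg <- aggregatePopulations(ser, groups)
  expect_identical(colnames(agg@P), c("a", "b"))
  expect_equal(agg@P[, "a"],
               rowSums(ser@P[, groups == "a", drop = FALSE]))
  expect_error(aggregatePopulations(ser, c("a", "b")), "one group label")
})

test_that("logTimeGrid spans the requested decades", {
  g <- logTimeGrid(1e-2, 1e4, perDecade = 10)
  expect_equal(g[1], 1e-2)
  expect_equal(g[length(g)], 1e4)
  expect_true(all(diff(g) > 0))
  expect_length(g, 61L)
  g2 <- logTimeGrid(1e-2, 1e18, perDecade = 60, maxPoints = 600)
  expect_length(g2, 600L)
  expect_error(logTimeGrid(0, 1), "need 0 <")
})
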