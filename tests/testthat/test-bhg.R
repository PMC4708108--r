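test_that("floodExact returns a symmetric ultrametric saddle matrix", {
  fl <- sharedFlood("k_type", 10)
  S <- fl$saddles
  expect_identical(S, t(S))
  expect_gt(sum(!is.na(S[upper.tri(S)])), 0)
  L <- nrow(fl$lm)
  viol <- 0L
  for (x in seq_len(L)) for (y in seq_len(L)) {
    if (x == y || is.na(S[x, y])) next
    detour <- pmax(S[x, ], S[, y])
    viol <- viol + sum(S[x, y] > detour[-c(x, y)] + 1e-9, na.rm = TRUE)
  }
  expect_identical(viol, 0L)  # ultrametric inequality holds everywhere
  # saddles dominate the endpoint energies
  emax <- outer(fl$lm$energy, fl$lm$energy, pmax)
  off <- !is.na(S) & upper.tri(S)
  expect_true(all(S[off] >= emax[off] - 1e-9))
})

test_that("flooded basins agree with gradient walks", {
  p <- energyParams()
  s <- sharedSequence("pk_free")
  fl <- sharedFlood("pk_free", 10)
  ens <- fl$ensemble
  nE <- length(ensembleEnergies(ens))
  for (i in seq_len(nE)) {
    gw <- gradientWalk(structureAt(ens, i), s, p)
    expect_identical(writeStructure(gw$lm), fl$lm$structure[fl$basin[i]])
  }
})

test_that("estimateSaddle upper-bounds the exact saddle and tightens with width", {
  p <- energyParams()
  s <- sharedSequence("k_type")
  fl <- sharedFlood("k_type", 10)
  pairs <- which(upper.tri(fl$saddles) & !is.na(fl$saddles), arr.ind = TRUE)
  set.seed(420005)
  pick <- pairs[sample(seq_len(nrow(pairs)), min(6L, nrow(pairs))), ,
                drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    x <- parseStructure(fl$lm$structure[pick[r, 1]])
    y <- parseStructure(fl$lm$structure[pick[r, 2]])
    wide <- estimateSaddle(x, y, s, p, width = 16L, rounds = 3L)
    narrow <- estimateSaddle(x, y, s, p, width = 2L, rounds = 1L)
    exact <- fl$saddles[pick[r, 1], pick[r, 2]]
    expect_gte(wide$saddle, exact - 1e-9)
    expect_lte(wide$saddle, narrow$saddle + 1e-9)
    # the witness path runs from x to y and peaks at the estimate
    expect_identical(wide$path[1], writeStructure(x))
    expect_identical(wide$path[length(wide$path)], writeStructure(y))
    peaks <- vapply(wide$path, function(q)
      structureEnergy(s, parseStructure(q), p), numeric(1))
    expect_equal(max(peaks), wide$saddle, tolerance = 1e-9)
  }
})

test_that("exact BHG minimax saddles reproduce the flooding saddles", {
  fl <- sharedFlood("k_type", 10)
  bhg <- sharedExactBHG("k_type", 10)
  expect_identical(lmTable(bhg)$structure, fl$lm$structure)
  expect_gt(nrow(edgeTable(bhg)), 0)
  ids <- lmTable(bhg)$id
  L <- length(ids)
  mismatch <- 0L
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    exact <- fl$saddles[i, j]
    got <- bhgSaddle(bhg, ids[i], ids[j])
    ok <- if (is.na(exact)) is.na(got) else
      !is.na(got) && abs(got - exact) <= 1e-6
    if (!ok) mismatch <- mismatch + 1L
  }
  expect_identical(mismatch, 0L)
  # the graph minimax agrees with an independent union-find sweep
  set.seed(420006)
  for (k in seq_len(60L)) {
    ij <- sample(L, 2L)
    ora <- oracleMinimax(edgeTable(bhg), ids[ij[1]], ids[ij[2]], ids)
    got <- bhgSaddle(bhg, ids[ij[1]], ids[ij[2]])
    expect_equal(got, ora, tolerance = 1e-9)
  }
})

test_that("dominated edges are absent from the exact BHG", {
  bhg <- sharedExactBHG("k_type", 10)
  lm <- lmTable(bhg); ed <- edgeTable(bhg)
  Scache <- new.env(parent = emptyenv())
  S <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (is.null(Scache[[key]])) Scache[[key]] <- bhgSaddle(bhg, a, b)
    Scache[[key]]
  }
  bad <- 0L
  for (r in seq_len(nrow(ed))) {
    x <- ed$from[r]; y <- ed$to[r]; sxy <- ed$saddle[r]
    for (z in setdiff(lm$id, c(x, y))) {
      fz <- lm$energy[match(z, lm$id)]
      if (fz >= sxy - 1e-9) next
      sxz <- S(x, z); szy <- S(z, y)
      if (!is.na(sxz) && !is.na(szy) && max(sxz, szy) < sxy - 1e-9)
        bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
})

test_that("witness paths certify the recorded edge saddles", {
  p <- energyParams()
  s <- sharedSequence("k_type")
  bhg <- sharedExactBHG("k_type", 10)
  ed <- edgeTable(bhg)
  lm <- lmTable(bhg)
  nChecked <- 0L
  for (r in seq_len(nrow(ed))) {
    w <- bhg@witnesses[[paste(ed$from[r], ed$to[r], sep = "|")]]
    if (is.null(w)) next
    nChecked <- nChecked + 1L
    E <- vapply(w, function(q)
      structureEnergy(s, parseStructure(q), p), numeric(1))
    expect_equal(max(E), ed$saddle[r], tolerance = 0.005 + 1e-9)
    expect_identical(w[1], lm$structure[match(ed$from[r], lm$id)])
    expect_identical(w[length(w)], lm$structure[match(ed$to[r], lm$id)])
    # consecutive witness structures differ by exactly one base pair
    for (k in seq_len(length(w) - 1L)) {
      pa <- pairingTable(parseStructure(w[k]))
      pb <- pairingTable(parseStructure(w[k + 1L]))
      expect_equal(sum(pa != pb), 2L)
    }
  }
  expect_gt(nChecked, 0L)
})

test_that("heuristic saddle estimates equal the oracle on the shared fixture", {
  p <- energyParams()
  s <- sharedSequence("k_type")
  fl <- sharedFlood("k_type", 10)
  bhg <- buildBHG(s, p, mode = "heuristic", lms = fl$lm, ceiling = 10)
  at <- match(fl$lm$structure, lmTable(bhg)$structure)
  expect_false(anyNA(at))
  ids <- lmTable(bhg)$id
  L <- nrow(fl$lm)
  worse <- 0L; belowCount <- 0L; tot <- 0L
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    exact <- fl$saddles[i, j]
    if (is.na(exact)) next
    got <- bhgSaddle(bhg, ids[at[i]], ids[at[j]])
    tot <- tot + 1L
    if (is.na(got) || abs(got - exact) > 1e-6) worse <- worse + 1L
    if (!is.na(got) && got < exact - 1e-6) belowCount <- belowCount + 1L
  }
  expect_gt(tot, 0L)
  expect_identical(belowCount, 0L)  # estimates never undershoot the truth
  expect_identical(worse, 0L)       # and are exact on this fixture
})

test_that("bhgSaddle reports NA across disconnected components", {
  bhg <- .twoIslandBHG()
  expect_true(is.na(bhgSaddle(bhg, "lm001", "lm004")))
  expect_equal(bhgSaddle(bhg, "lm001", "lm002"), -1)
  expect_equal(bhgSaddle(bhg, "lm001", "lm001"), -5)
  expect_error(bhgSaddle(bhg, "lm001", "zzz"), "unknown")
})

test_that("pruneToBHG0 retains only pseudoknot-free minima", {
  p <- energyParams()
  s <- sharedSequence("h_type")
  bhg <- sharedExactBHG("h_type", 10)
  expect_gt(sum(lmTable(bhg)$pkClass != "N"), 0)
  b0 <- pruneToBHG0(bhg, ceiling = 10)
  expect_identical(bhgVariant(b0), "deg0")
  expect_true(all(lmTable(b0)$pkClass == "N"))
  expect_true(all(lmTable(b0)$structure %in%
                    lmTable(bhg)$structure[lmTable(bhg)$pkClass == "N"]))
  cmp <- compareSaddles(bhg, b0)
  expect_true(all(c("sPsi", "sDeg0", "deltaAbs", "pkClass") %in% names(cmp)))
  # restricting the move set can never lower a saddle (common window anchor:
  # this fixture's ground state is pseudoknot-free)
  expect_true(all(cmp$deltaAbs >= -1e-9))
})

test_that("BHG serialization round-trips", {
  bhg <- sharedExactBHG("k_type", 10)
  prefix <- file.path(tempdir(), "rt")
  writeBHG(bhg, prefix)
  back <- readBHG(prefix)
  expect_identical(back@sequence, bhg@sequence)
  expect_identical(back@variant, bhg@variant)
  expect_identical(back@mode, bhg@mode)
  expect_equal(lmTable(back), lmTable(bhg))
  expect_equal(edgeTable(back), edgeTable(bhg))
  expect_identical(back@witnesses[order(names(back@witnesses))],
                   bhg@witnesses[order(names(bhg@witnesses))])
  expect_equal(back@params@stack, bhg@params@stack)
  expect_equal(back@params@beta, bhg@params@beta)
})
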