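test_that("the open chain has energy zero", {
  p <- energyParams()
  s <- rnaStructure(NULL, 12L)
  expect_identical(structureEnergy("GGGGAAAACCCC", s, p), 0)
})

test_that("a GC hairpin energy matches the hand computation", {
  p <- energyParams()
  # three GC-on-GC stacks at -3.3 each plus one helix end penalty of +3.0
  e <- structureEnergy("GGGGAAAACCCC", parseStructure("((((....))))"), p)
  expect_equal(e, 3 * (-3.3) + 3.0)
  # a lone pair costs exactly the helix end penalty
  expect_equal(structureEnergy("GAAAAC", parseStructure("(....)"), p), 3.0)
})

test_that("structureEnergy matches the independent oracle on ensembles", {
  p <- energyParams()
  for (kind in c("pk_free", "h_type")) {
    fx <- generateFixtures(kind, compute = FALSE)[[1]]
    ens <- enumerateEnsemble(fx$sequence, p, ceiling = 8)
    n <- length(ensembleEnergies(ens))
    for (i in seq_len(min(n, 500L))) {
      s <- structureAt(ens, i)
      expect_equal(ensembleEnergies(ens)[i],
                   oracleEnergy(fx$sequence, writeStructure(s), p),
                   tolerance = 1e-9)
    }
  }
})

test_that("pseudoknot penalties are charged once per crossing component", {
  p <- energyParams()
  seqH <- "GGAAAAAACCAAAAUU"
  strH <- "((..[[..))....]]"
  nested <- "((......))......"
  lone <- "....((........))"  # same second helix, no crossing
  expect_equal(structureEnergy(seqH, parseStructure(strH), p) -
                 structureEnergy(seqH, parseStructure(nested), p) -
                 structureEnergy(seqH, parseStructure(lone), p),
               p@beta[["H"]])
})

test_that("structureEnergy rejects non-canonical pairs", {
  p <- energyParams()
  expect_error(structureEnergy("GAAAAG", parseStructure("(....)"), p),
               "non-canonical|not a 1-structure")
})

test_that("boltzmannWeight and thermalEnergy are consistent", {
  p <- energyParams()
  expect_equal(thermalEnergy(p), 310.15 * 0.0019872)
  expect_equal(boltzmannWeight(0, p), 1)
  expect_equal(boltzmannWeight(1.23, p), exp(-1.23 / thermalEnergy(p)))
})

test_that("energy parameters save/load round-trip through YAML", {
  p <- energyParams(helixEnd = 2.5, beta = c(H = 8, K = 11, L = 13, M = 13.5))
  f <- tempfile(fileext = ".yaml")
  saveEnergyParams(p, f)
  q <- loadEnergyParams(f)
  expect_equal(q@stack, p@stack)
  expect_equal(q@helixEnd, p@helixEnd)
  expect_equal(q@beta, p@beta)
  expect_equal(q@temperature, p@temperature)
  expect_equal(q@r0, p@r0)
})

test_that("the pseudoknot penalty ordering is enforced", {
  expect_error(energyParams(beta = c(H = 13, K = 12.6, L = 14.6, M = 14.6)))
  expect_error(energyParams(beta = c(H = 9.6, K = 12.6, L = 11, M = 14.6)))
})
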