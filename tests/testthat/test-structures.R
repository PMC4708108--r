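test_that("parseStructure and writeStructure round-trip", {
  strs <- c("............",
            "((((....))))",
            "((..[[..))..]]",
            "(((..[[[..)))..]]]",
            "((.[[.{{.)).]].}}")
  for (s in strs) {
    x <- parseStructure(s)
    y <- parseStructure(writeStructure(x))
    expect_identical(pairingTable(x), pairingTable(y))
  }
})

test_that("parseStructure rejects malformed input", {
  expect_error(parseStructure("(((..."), "unbalanced")
  expect_error(parseStructure("...)..."), "unbalanced")
  expect_error(parseStructure("..xx..."), "unknown structure characters")
  expect_error(parseStructure("(...)"), NA)  # hairpin of 3 is allowed: j-i=4
  expect_error(parseStructure("(..)."))      # hairpin too short
})

test_that("writeStructure assigns minimal bracket pages", {
  # pseudoknot-free structures must use only the first page
  s <- writeStructure(parseStructure("((((...(((...)))..))))"))
  expect_false(grepl("[][{}<>]", s))
  # an H-type crossing needs exactly two pages
  h <- writeStructure(parseStructure("((..[[..))..]]"))
  expect_true(grepl("\\[", h))
  expect_false(grepl("[{}<>]", h))
})

test_that("genus by boundary tracing matches the permutation-cycle oracle", {
  # deterministic cases
  expect_identical(genus(parseStructure("((((....))))")), 0L)
  expect_identical(genus(cbind(c(1L, 2L), c(3L, 4L))), 1L)
  # randomized chord diagrams, m = 2..6
  set.seed(420001)
  for (rep in seq_len(200)) {
    m <- sample(2:6, 1)
    pts <- sample(seq_len(2L * m))
    ch <- cbind(pts[seq_len(m)], pts[m + seq_len(m)])
    expect_identical(genus(ch), oracleGenus(ch))
  }
})

test_that("minimal diagrams of the four basic types all have genus 1", {
  for (t in c("H", "K", "L", "M")) {
    d <- minimalDiagram(t)
    expect_identical(genus(d), 1L)
    expect_identical(oracleGenus(d), 1L)
  }
})

test_that("decomposeHelices finds maximal stacks", {
  s <- parseStructure("((((...)))).((...))")
  hx <- decomposeHelices(s)
  expect_equal(hx$i, c(1L, 13L))
  expect_equal(hx$j, c(11L, 19L))
  expect_equal(hx$length, c(4L, 2L))
  expect_equal(hx$name, c("h1_11", "h13_19"))
})

test_that("conflictGraph records helix crossings", {
  s <- parseStructure("((..[[..))..]]")
  g <- conflictGraph(s)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  s0 <- parseStructure("((((...)))).((...))")
  expect_equal(igraph::ecount(conflictGraph(s0)), 0L)
})

test_that("classifyPK labels the basic patterns and composites", {
  expect_identical(classifyPK(parseStructure("((((....))))")), "N")
  expect_identical(classifyPK(parseStructure("((..[[..))..]]")), "H")
  # K: crossing path of three (verified against the independent classifier)
  k <- "((..[[..))..((..]]..))"
  expect_identical(oracleClasses(oraclePairTable(k)), "K")
  expect_identical(classifyPK(parseStructure(k)), "K")
  # two independent H components still report a single H letter
  hh <- "((..[[..))..]]..((..[[..))..]]"
  expect_identical(classifyPK(parseStructure(hh)), "H")
})

test_that("classifyPK agrees with the independent classifier on an ensemble", {
  fx <- generateFixtures("h_type", compute = FALSE)[[1]]
  ens <- enumerateEnsemble(fx$sequence, ceiling = 6)
  n <- length(ensembleEnergies(ens))
  idx <- seq_len(min(n, 400L))
  for (i in idx) {
    s <- structureAt(ens, i)
    want <- oracleClasses(pairingTable(s))
    want <- if (length(want) == 0L) "N" else paste(want, collapse = "")
    expect_identical(classifyPK(s), want)
  }
})

test_that("isOneStructure rejects higher-genus components", {
  # crossing path of four chords (word ABACBDCD) has genus 2
  ch <- cbind(c(1L, 2L, 4L, 6L), c(3L, 5L, 7L, 8L))
  expect_identical(oracleGenus(ch), 2L)
  expect_false(isOneStructure(ch))
  expect_true(isOneStructure(minimalDiagram("M")))
})

test_that("enumerateShadows finds the four genus-1 types at small bounds", {
  sh <- enumerateShadows(4L)
  g1 <- sh[sh$genus == 1L, ]
  expect_identical(g1$word, c("ABAB", "ABACBC", "ABCABC", "ABCADBCD"))
  expect_identical(g1$class, c("H", "K", "L", "M"))
})
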