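test_that("readFasta normalizes DNA input and validates residues", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ggaaaacc"), f)
  expect_identical(unname(readFasta(f)), "GGAAAACC")
  writeLines(c(">s1", "GGTTAACC"), f)
  expect_warning(x <- readFasta(f), "T normalized to U")
  expect_identical(unname(x), "GGUUAACC")
  writeLines(c(">s1", "GGXXAACC"), f)
  suppressWarnings(expect_error(readFasta(f), "invalid residues"))
  expect_error(readFasta(tempfile()), "no such file")
})

test_that("readStructureFile skips comments and blank lines", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# a comment", "", "((((....))))", "> header",
               "((..[[..))..]]"), f)
  structs <- readStructureFile(f)
  expect_length(structs, 2L)
  expect_identical(writeStructure(structs[[1]]), "((((....))))")
})

test_that("loadConfig applies defaults, overrides and validation", {
  cfg <- loadConfig()
  expect_equal(cfg$ceiling, 10)
  expect_equal(cfg$nSamples, 100L)
  expect_equal(cfg$tMax, 1e18)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sequence = "GGAAAACC", ceiling = 6), f)
  cfg2 <- loadConfig(f, overrides = list(ceiling = 8, seed = 3))
  expect_equal(cfg2$sequence, "GGAAAACC")
  expect_equal(cfg2$ceiling, 8)
  expect_identical(cfg2$seed, 3L)
  yaml::write_yaml(list(bogus = 1), f)
  expect_error(loadConfig(f), "unknown config keys")
  expect_error(loadConfig(NULL, overrides = list(ceiling = -1)), "ceiling")
})

test_that("generateFixtures is seed-reproducible with oracle annotations", {
  a <- generateFixtures("pk_free", count = 3L, seed = 5L, compute = FALSE)
  b <- generateFixtures("pk_free", count = 3L, seed = 5L, compute = FALSE)
  expect_identical(a, b)
  expect_error(generateFixtures("pk_free", count = 2L), "seed")
  # spec'd fixture properties, computed by the exact oracle
  pf <- generateFixtures("pk_free")[[1]]
  expect_identical(pf$expected$pkLMCount, 0L)   # only N-class minima
  ht <- generateFixtures("h_type")[[1]]
  expect_gt(ht$expected$pkLMCount, 0L)          # a reachable pseudoknot
})

test_that("the classify subcommand writes a per-structure table", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("((((....))))", "((..[[..))..]]"), f)
  out <- file.path(tempdir(), "cli-classify")
  code <- landscapeCLI(c("classify", "--structures", f, "--out", out))
  expect_identical(code, 0L)
  df <- read.delim(file.path(out, "classification.tsv"), comment.char = "#")
  expect_equal(df$pkClass, c("N", "H"))
  expect_equal(df$genus, c(0L, 1L))
})

test_that("the CLI pipeline runs end to end and is deterministic", {
  seqc <- "GGAAAACC"  # two local minima (open chain and the hairpin)
  run <- function(dir) {
    expect_identical(landscapeCLI(c("build-bhg", "--sequence", seqc,
                                    "--mode", "exact", "--out", dir)), 0L)
    expect_identical(landscapeCLI(c("kinetics", "--bhg",
                                    file.path(dir, "bhg"), "--out", dir)), 0L)
    expect_identical(landscapeCLI(c("path", "--bhg", file.path(dir, "bhg"),
                                    "--from", "lm001", "--to", "lm002",
                                    "--out", dir)), 0L)
  }
  d1 <- file.path(tempdir(), "cli-run1"); run(d1)
  d2 <- file.path(tempdir(), "cli-run2"); run(d2)
  for (f in c("bhg_lm.tsv", "bhg_edges.tsv", "trajectory.csv", "path.txt")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the trajectory conserves probability at every reported time
  tr <- read.csv(file.path(d1, "trajectory.csv"), comment.char = "#",
                 check.names = FALSE)
  # reported columns are the high-population subset; totals stay <= 1
  expect_true(all(rowSums(tr[, -1, drop = FALSE]) <= 1 + 1e-9))
  eq <- jsonlite::read_json(file.path(d1, "equilibrium.json"))
  expect_equal(sum(unlist(eq$equilibrium)), 1, tolerance = 1e-9)
  # outputs embed the provenance stamp
  hdr <- readLines(file.path(d1, "bhg_lm.tsv"), n = 2L)
  expect_match(hdr[1], "^# pkbasins ")
  expect_match(hdr[2], "^# config md5 ")
})

test_that("the CLI rejects bad invocations with a nonzero exit code", {
  expect_identical(suppressMessages(landscapeCLI(character(0))), 1L)
  expect_identical(suppressMessages(landscapeCLI("frobnicate")), 1L)
  expect_identical(suppressMessages(
    landscapeCLI(c("build-bhg", "--out", tempdir()))), 1L)
  expect_identical(suppressMessages(
    landscapeCLI(c("classify", "--structures"))), 1L)
})

test_that("writeReports handles an edge-free graph and an LM table", {
  p <- energyParams()
  lm <- data.frame(id = "lm001", structure = "((((.....))))",
                   energy = -5, pkClass = "N", count = 0L,
                   stringsAsFactors = FALSE)
  bhg <- new("BasinHoppingGraph", sequence = "GGGGAAAAACCCC", lm = lm,
             edges = data.frame(from = character(0), to = character(0),
                                saddle = numeric(0),
                                pkClass = character(0),
                                stringsAsFactors = FALSE),
             witnesses = list(), variant = "psi", mode = "heuristic",
             params = p)
  out <- file.path(tempdir(), "reports-empty")
  files <- writeReports(list(bhg = bhg, lm = lm), out)
  expect_true(all(file.exists(files)))
  ed <- read.delim(file.path(out, "bhg_edges.tsv"), comment.char = "#")
  expect_equal(nrow(ed), 0L)
  expect_identical(sort(names(ed)),
                   sort(c("from", "to", "saddle", "pkClass", "witness")))
  # and the empty graph still round-trips
  back <- readBHG(file.path(out, "bhg"))
  expect_equal(lmTable(back), lm)
  expect_equal(nrow(edgeTable(back)), 0L)
})
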