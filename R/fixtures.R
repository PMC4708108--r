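# Designed fixture sequences for testing and validation.  All designs are
# short complementary-block arrangements whose intended pairing patterns
# (nested hairpins, H-type crossings, kissing hairpins, a pseudoknot
# shortcut between two competing registers) are energetically reachable.
# Expected properties are always computed by the exact oracles, never
# hand-written.

.revComp <- function(x) {
  map <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# one random block of the given length; G/C-rich so designed helices are
# clearly favorable (study condition fixed a priori, not a tuning knob)
.randBlock <- function(len)
  paste(sample(c("G", "C", "A"), len, replace = TRUE,
               prob = c(0.4, 0.4, 0.2)), collapse = "")

# deterministic designs ------------------------------------------------------

.designPkFree <- function(stem = 5L, block = NULL) {
  if (is.null(block))
    block <- substr(strrep("GGC", stem), 1L, stem)
  paste0(block, "AAAA", .revComp(block))
}

.designHType <- function(a = 4L, x = NULL, y = NULL) {
  if (is.null(x)) x <- strrep("G", a)
  if (is.null(y)) y <- strrep("C", a)
  # X .. Y .. X' .. Y': the X helix and the Y helix cross (H pattern)
  paste0(x, "AAA", y, "AA", .revComp(x), "AAA", .revComp(y))
}

.designKType <- function(stem = 3L, kiss = 4L, p = NULL, r = NULL, k = NULL) {
  # distinct stems (identical ones let the two halves zip into one long
  # nested duplex that dominates the window) and a mixed-alphabet kiss
  # block (a homogeneous A/U block spawns too many alternative registers)
  if (is.null(p)) p <- strrep("G", stem)
  if (is.null(r)) r <- strrep("C", stem)
  if (is.null(k)) k <- substr(strrep("AG", kiss), 1L, kiss)
  # two hairpins whose loops carry complementary blocks (kissing helix)
  paste0(p, k, .revComp(p), "A", r, .revComp(k), .revComp(r))
}

.designTwoBasin <- function(a = NULL, m1 = NULL) {
  if (is.null(a)) a <- "CCCGG"
  if (is.null(m1)) m1 <- "GGCCC"
  # A .. M1 M2 .. B with A~M2 and M1~B: the two designed helices cross, so
  # the direct route between the two nested registers has a pseudoknotted
  # shortcut.  The default blocks are pattern-asymmetric on purpose: with
  # repetitive blocks the registers can slide through nested partial
  # coexistence, which bridges the basins below the pseudoknotted route and
  # destroys the strict shortcut.  Both helices must also be strong enough
  # (-10.2 here) that helix + one crossing pair + penalty stays below the
  # +3 lone-pair bottleneck of the best nested route.
  paste0(a, "AA", m1, .revComp(a), "AA", .revComp(m1))
}

#' Synthetic ring basin hopping graph
#'
#' A designed kinetics fixture: `nMajor` deep local minima arranged in a
#' ring, each consecutive pair connected through a shallow high-energy
#' intermediate, so every state has degree 2 and quasi-steady-state
#' elimination (lowest degree, then highest energy) removes exactly the
#' intermediates.  Timescales are well separated, so eliminating the
#' intermediates should reproduce the slow dynamics of the full model.
#' Energies and barriers are deterministic; the structure strings are
#' placeholder hairpins (the graph is synthetic and never energy-evaluated
#' against its sequence).
#'
#' @param nMajor number of deep minima (default 10, giving 20 states).
#' @param interEnergy base energy of the intermediates.
#' @param barrier saddle height above each intermediate.
#' @param p an [EnergyParams] object stored with the graph.
#' @return a [BasinHoppingGraph] with `2 * nMajor` local minima.
#' @export
ringBHG <- function(nMajor = 10L, interEnergy = -1.5, barrier = 2.5,
                    p = energyParams()) {
  if (nMajor < 2L) stop("need at least two major minima")
  L <- 2L * nMajor  # interleaved m1 i1 m2 i2 ... m_N i_N, ring closed
  n <- L + 13L
  mkStructure <- function(k)
    paste0(strrep(".", k - 1L), "((((.....))))", strrep(".", n - 12L - k))
  # majors: deep, slightly detuned so no two energies tie; intermediates:
  # shallow, also detuned
  majorE <- -8 + 0.37 * ((seq_len(nMajor) - 1L) %% 3) - 0.11 * seq_len(nMajor)
  interE <- interEnergy + 0.07 * seq_len(nMajor)
  energy <- numeric(L)
  energy[seq(1L, L, by = 2L)] <- majorE
  energy[seq(2L, L, by = 2L)] <- interE
  ids <- sprintf("lm%03d", seq_len(L))
  lm <- data.frame(id = ids,
                   structure = vapply(seq_len(L), mkStructure, character(1)),
                   energy = energy, pkClass = "N",
                   count = NA_integer_, stringsAsFactors = FALSE)
  from <- ids[seq_len(L)]
  to <- ids[c(seq_len(L - 1L) + 1L, 1L)]
  inter <- (seq_len(L) + 1L) %/% 2L  # edge k passes through intermediate k/2
  edges <- data.frame(from = from, to = to,
                      saddle = round(interE[inter] + barrier, 2),
                      pkClass = NA_character_, stringsAsFactors = FALSE)
  new("BasinHoppingGraph", sequence = strrep("A", n), lm = lm, edges = edges,
      witnesses = list(), variant = "psi", mode = "heuristic", params = p)
}

#' Generate designed fixture sequences
#'
#' Four deterministic sequence designs, each optionally randomized over the
#' block content with a seed: `pk_free` (a single nested hairpin), `h_type`
#' (two interleaved complementary block pairs, reachable H-type pseudoknot),
#' `k_type` (two hairpins with complementary loops, reachable kissing
#' hairpin), and `two_basin` (two competing helix registers whose direct
#' refolding route has a pseudoknotted shortcut).  Expected properties are
#' computed with the exact oracles ([floodExact]) at generation time.
#'
#' @param kind fixture family.
#' @param count number of fixtures; the first is always the deterministic
#'   design, further ones are seeded random variants.
#' @param seed RNG seed, required when `count > 1`.
#' @param p an [EnergyParams] object for the oracle annotations.
#' @param ceiling oracle energy window (kcal/mol above MFE).
#' @param compute annotate each fixture with oracle-derived expectations.
#' @return list of fixtures; each is a list with `kind`, `sequence`, `n`,
#'   and (when `compute`) `expected`: `mfeEnergy`, `mfeStructure`,
#'   `mfeClass`, `lmCount`, `pkLMCount`.
#' @export
generateFixtures <- function(kind = c("pk_free", "h_type", "k_type", "two_basin"),
                             count = 1L, seed = NULL, p = energyParams(),
                             ceiling = 10, compute = TRUE) {
  kind <- match.arg(kind)
  if (count > 1L && is.null(seed))
    stop("a seed is required for randomized fixture variants")
  base <- switch(kind,
                 pk_free = .designPkFree(),
                 h_type = .designHType(),
                 k_type = .designKType(),
                 two_basin = .designTwoBasin())
  seqs <- base
  if (count > 1L) {
    variants <- .withSeed(seed, {
      vapply(seq_len(count - 1L), function(i) {
        switch(kind,
               pk_free = .designPkFree(block = .randBlock(5L)),
               h_type = .designHType(x = .randBlock(4L), y = .randBlock(4L)),
               k_type = .designKType(p = .randBlock(3L), r = .randBlock(3L),
                                     k = .randBlock(4L)),
               two_basin = .designTwoBasin(a = .randBlock(5L),
                                           m1 = .randBlock(5L)))
      }, character(1))
    })
    seqs <- c(seqs, variants)
  }
  lapply(seq_along(seqs), function(i) {
    fx <- list(kind = kind, sequence = seqs[i], n = nchar(seqs[i]))
    if (compute) {
      oracle <- floodExact(seqs[i], p, ceiling = ceiling)
      mfeRow <- which.min(oracle$lm$energy)
      fx$expected <- list(
        mfeEnergy = oracle$lm$energy[mfeRow],
        mfeStructure = oracle$lm$structure[mfeRow],
        mfeClass = oracle$lm$pkClass[mfeRow],
        lmCount = nrow(oracle$lm),
        pkLMCount = sum(oracle$lm$pkClass != "N"))
    }
    fx
  })
}
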