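# Move set, gradient walks, exhaustive enumeration and Boltzmann sampling
# of local minima.

# run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Can a base pair be added?
#'
#' TRUE iff `(i, j)` is canonical over the sequence, both positions are
#' free, the hairpin constraint `j - i >= 4` holds, and the enlarged
#' structure is still a 1-structure (or non-crossing, when
#' `nestedOnly = TRUE`).
#'
#' @param s an [RNAStructure].
#' @param i,j candidate pair, `i < j`.
#' @param sequence RNA sequence.
#' @param nestedOnly restrict the move universe to pseudoknot-free
#'   structures.
#' @export
canAddPair <- function(s, i, j, sequence, nestedOnly = FALSE) {
  .cpp_can_add(.encodeSeq(sequence), s@pt, as.integer(i), as.integer(j),
               nestedOnly)
}

#' Single-base-pair neighbors of a structure
#'
#' All 1-structures reachable by removing one pair or adding one valid pair.
#' The relation is symmetric: `y` is a neighbor of `x` iff `x` is a neighbor
#' of `y`.
#'
#' @inheritParams canAddPair
#' @return list of [RNAStructure] objects, removals first, each block
#'   ordered by `(i, j)`.
#' @export
neighborStructures <- function(s, sequence, nestedOnly = FALSE) {
  mv <- .cpp_moves(.encodeSeq(sequence), s@pt, nestedOnly)
  out <- vector("list", nrow(mv))
  for (k in seq_len(nrow(mv))) {
    pt <- s@pt
    if (mv[k, "kind"] == 0L) {
      pt[mv[k, "i"]] <- 0L; pt[mv[k, "j"]] <- 0L
    } else {
      pt[mv[k, "i"]] <- mv[k, "j"]; pt[mv[k, "j"]] <- mv[k, "i"]
    }
    out[[k]] <- .fromPt(pt)
  }
  out
}

#' Gradient (steepest descent) walk to a local minimum
#'
#' Repeatedly moves to the lowest-energy neighbor until no neighbor is
#' strictly lower.  Ties are broken deterministically: removals before
#' additions, then lexicographically by `(i, j)`; the result is therefore a
#' function of the start structure only.
#'
#' @param s0 start [RNAStructure].
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param nestedOnly restrict moves to non-crossing additions.
#' @return list with elements `lm` ([RNAStructure]), `energy`, `path` (list
#'   of structures visited, including start and LM) and `energies`.
#' @export
gradientWalk <- function(s0, sequence, p = energyParams(), nestedOnly = FALSE) {
  res <- .cpp_gradient_walk(.encodeSeq(sequence), s0@pt, .parList(p), nestedOnly)
  k <- length(res$path)
  list(lm = .fromPt(res$path[[k]]),
       energy = res$energy[k],
       path = lapply(res$path, .fromPt),
       energies = res$energy)
}

#' Enumerate all 1-structures within an energy window
#'
#' Exhaustive depth-first enumeration of the 1-structures of a sequence,
#' keeping those with energy at most `ceiling` kcal/mol above the minimum
#' free energy.  Intended for short sequences; refuses sequences longer than
#' `maxLength`.
#'
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param ceiling energy window in kcal/mol above the MFE (default 10; may
#'   be `Inf`).
#' @param nestedOnly exclude crossing pairs.
#' @param maxLength hard guard on sequence length (default 40).
#' @param maxCount guard on the number of stored structures.
#' @return an [EnsembleIndex].
#' @export
enumerateEnsemble <- function(sequence, p = energyParams(), ceiling = 10,
                              nestedOnly = FALSE, maxLength = 40L,
                              maxCount = 2000000L) {
  seqc <- .encodeSeq(sequence)
  if (length(seqc) > maxLength)
    stop("sequence longer than the enumeration guard (", maxLength, " nt)")
  res <- .cpp_enumerate(seqc, .parList(p), ceiling, nestedOnly, maxCount)
  mfe <- which(res$energy <= res$mfe + 1e-9)[1]
  new("EnsembleIndex", sequence = toupper(sequence), pt = res$pt,
      energy = as.numeric(res$energy), mfe = as.integer(mfe),
      ceiling = as.numeric(ceiling), nestedOnly = nestedOnly)
}

# dot-bracket strings for all rows of an ensemble (internal)
.ensembleStrings <- function(ens) {
  vapply(seq_len(nrow(ens@pt)), function(i) writeStructure(ens@pt[i, ]),
         character(1))
}

#' Sample local minima by Boltzmann-weighted gradient descent
#'
#' Draws start structures from the Boltzmann distribution and gradient-walks
#' each to its local minimum.  For sequences short enough to enumerate, the
#' draw is exact categorical sampling over the [enumerateEnsemble] window;
#' otherwise a seeded Metropolis-Hastings chain over the single-pair move
#' set is used (documented burn-in 1000 sweeps, thinning 50).  The MFE
#' structure's LM is always included.
#'
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param nSamples number of Boltzmann draws.
#' @param seed mandatory RNG seed.
#' @param ceiling energy window (kcal/mol above MFE).
#' @param nestedOnly exclude crossing pairs.
#' @param ensemble optional precomputed [EnsembleIndex] to sample from.
#' @param mcmc force Markov-chain sampling even when enumeration is possible.
#' @return data.frame of local minima: `id`, `structure` (dot-bracket),
#'   `energy`, `pkClass`, `count` (discovery count), ordered by energy.
#' @export
sampleMinima <- function(sequence, p = energyParams(), nSamples = 100L,
                         seed, ceiling = 10, nestedOnly = FALSE,
                         ensemble = NULL, mcmc = FALSE) {
  if (missing(seed)) stop("a seed is required for reproducible sampling")
  seqc <- .encodeSeq(sequence)
  n <- length(seqc)
  starts <- .withSeed(seed, {
    if (!mcmc && n <= 40L) {
      if (is.null(ensemble))
        ensemble <- enumerateEnsemble(sequence, p, ceiling, nestedOnly)
      w <- exp(-(ensemble@energy - min(ensemble@energy)) / thermalEnergy(p))
      idx <- sample.int(length(w), size = nSamples, replace = TRUE, prob = w)
      c(list(ensemble@pt[ensemble@mfe, ]),
        lapply(idx, function(i) ensemble@pt[i, ]))
    } else {
      .mcmcStarts(seqc, p, nSamples, nestedOnly)
    }
  })
  lmKeys <- character(0)
  lmE <- numeric(0); lmCount <- integer(0); lmPts <- list()
  for (k in seq_along(starts)) {
    res <- .cpp_gradient_walk(seqc, starts[[k]], .parList(p), nestedOnly)
    lmpt <- res$path[[length(res$path)]]
    key <- paste(lmpt, collapse = ",")
    hit <- match(key, lmKeys)
    if (is.na(hit)) {
      lmKeys <- c(lmKeys, key)
      lmPts[[length(lmPts) + 1L]] <- lmpt
      lmE <- c(lmE, res$energy[length(res$energy)])
      # the injected MFE walk (k = 1) does not count as a sample
      lmCount <- c(lmCount, if (k == 1L) 0L else 1L)
    } else {
      lmCount[hit] <- lmCount[hit] + if (k == 1L) 0L else 1L
    }
  }
  keep <- lmE <= min(lmE) + ceiling + 1e-9
  lmPts <- lmPts[keep]; lmE <- lmE[keep]; lmCount <- lmCount[keep]
  ord <- order(lmE, vapply(lmPts, paste, character(1), collapse = ","))
  data.frame(
    id = sprintf("lm%03d", seq_along(ord)),
    structure = vapply(lmPts[ord], writeStructure, character(1)),
    energy = lmE[ord],
    pkClass = vapply(lmPts[ord], .pkClassOfPt, character(1)),
    count = lmCount[ord],
    stringsAsFactors = FALSE)
}

# Metropolis-Hastings over the single-pair move set with uniform move
# proposals; acceptance corrects for the varying neighborhood size.
.mcmcStarts <- function(seqc, p, nSamples, nestedOnly,
                        burnin = 1000L, thin = 50L) {
  pt <- integer(length(seqc))
  E <- .cpp_energy(seqc, pt, .parList(p))
  RT <- thermalEnergy(p)
  out <- list()
  total <- burnin + thin * nSamples
  mv <- .cpp_moves(seqc, pt, nestedOnly)
  for (step in seq_len(total)) {
    k <- sample.int(nrow(mv), 1L)
    pt2 <- pt
    if (mv[k, 1] == 0L) { pt2[mv[k, 2]] <- 0L; pt2[mv[k, 3]] <- 0L }
    else { pt2[mv[k, 2]] <- mv[k, 3]; pt2[mv[k, 3]] <- mv[k, 2] }
    E2 <- .cpp_energy(seqc, pt2, .parList(p))
    mv2 <- .cpp_moves(seqc, pt2, nestedOnly)
    acc <- exp(-(E2 - E) / RT) * nrow(mv) / nrow(mv2)
    if (runif(1) < acc) { pt <- pt2; E <- E2; mv <- mv2 }
    if (step > burnin && (step - burnin) %% thin == 0L)
      out[[length(out) + 1L]] <- pt
  }
  # include an MFE proxy: the lowest-energy sample (walked to its LM later)
  c(out[which.min(vapply(out, function(q) .cpp_energy(seqc, q, .parList(p)),
                         numeric(1)))], out)
}

#' Composition of a local-minimum set by pseudoknot class
#'
#' @param lms LM data.frame as returned by [sampleMinima] (or the `lm` slot
#'   of a [BasinHoppingGraph]).
#' @param weight use discovery counts as weights instead of counting LMs.
#' @return named numeric vector of fractions summing to 1.
#' @export
lmComposition <- function(lms, weight = FALSE) {
  if (nrow(lms) == 0L) stop("empty LM set")
  w <- if (weight) lms$count else rep(1, nrow(lms))
  tab <- tapply(w, lms$pkClass, sum)
  tab <- tab / sum(tab)
  tab[order(names(tab))]
}
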