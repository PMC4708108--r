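#' @useDynLib pkbasins, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head read.delim write.table packageVersion
NULL

# nucleotide codes used by the C++ engine: A=0, C=1, G=2, U=3
.NT <- c(A = 0L, C = 1L, G = 2L, U = 3L)
.PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
.PK_LETTERS <- c("H", "K", "L", "M")
.BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

.encodeSeq <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  bad <- setdiff(unique(chars), names(.NT))
  if (length(bad) > 0L)
    stop("invalid residues (expected A/C/G/U): ", paste(bad, collapse = " "))
  unname(.NT[chars])
}

#' RNA secondary structure, possibly pseudoknotted
#'
#' A set of base pairs over positions `1..n`, stored as a pairing table.
#' Crossing base pairs are allowed as long as every connected component of
#' the helix conflict graph has topological genus 1 (the "1-structure"
#' class, which covers H-, K-, L- and M-type pseudoknots).
#'
#' @slot pt integer pairing table of length `n`; `pt[i]` is the partner of
#'   position `i`, or 0 when `i` is unpaired.
#' @export
setClass("RNAStructure", representation(pt = "integer"))

setValidity("RNAStructure", function(object) {
  pt <- object@pt
  n <- length(pt)
  if (n == 0L) return("empty pairing table")
  if (anyNA(pt) || any(pt < 0L) || any(pt > n)) return("partner out of range")
  paired <- which(pt > 0L)
  if (any(pt[pt[paired]] != paired)) return("pairing table is not involutive")
  ij <- paired[pt[paired] > paired]
  if (any(pt[ij] - ij < 4L))
    return("hairpin constraint violated (need >= 3 unpaired positions)")
  if (!.cpp_is_one_structure(pt))
    return("structure is outside the 1-structure class (a crossing component has genus > 1)")
  TRUE
})

#' Construct an [RNAStructure] from a pair list or pairing table
#'
#' @param pairs two-column matrix of base pairs `(i, j)` (1-based, any order),
#'   or `NULL` for the open chain.
#' @param n sequence length.
#' @return an [RNAStructure].
#' @examples
#' rnaStructure(cbind(c(1, 2), c(12, 11)), 12)
#' @export
rnaStructure <- function(pairs = NULL, n) {
  pt <- integer(n)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    for (k in seq_len(nrow(pairs))) {
      i <- min(pairs[k, ]); j <- max(pairs[k, ])
      if (pt[i] != 0L || pt[j] != 0L)
        stop("position paired twice: (", i, ",", j, ")")
      pt[i] <- j; pt[j] <- i
    }
  }
  new("RNAStructure", pt = pt)
}

.fromPt <- function(pt) new("RNAStructure", pt = as.integer(pt))

#' Base pairs of a structure
#' @param s an [RNAStructure].
#' @return two-column integer matrix of pairs `(i, j)` with `i < j`,
#'   ordered by `i`.
#' @export
basePairs <- function(s) {
  pt <- s@pt
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}

#' Pairing table of a structure
#' @param s an [RNAStructure].
#' @export
pairingTable <- function(s) s@pt

setMethod("length", "RNAStructure", function(x) length(x@pt))

setMethod("show", "RNAStructure", function(object) {
  cat("RNAStructure of length ", length(object), ", ",
      nrow(basePairs(object)), " base pairs\n", sep = "")
  cat(" ", writeStructure(object), "\n", sep = "")
})

#' Energy model parameters
#'
#' Additive nearest-neighbor-style model: stacking terms between adjacent
#' pairs within a helix, a per-helix end penalty, and one penalty per
#' crossing (pseudoknot) component depending on its type (H, K, L, M).
#'
#' @slot stack 6x6 stacking table (kcal/mol), rows/columns indexed by the
#'   outer/inner pair type in the order AU, UA, GC, CG, GU, UG.
#' @slot helixEnd per-helix penalty (kcal/mol).
#' @slot beta pseudoknot penalties, named `H`, `K`, `L`, `M` (kcal/mol per
#'   conflict-graph component of that type).
#' @slot temperature absolute temperature (K).
#' @slot gasConstant kcal/(mol K).
#' @slot r0 rate gauge defining the time unit (dimensionless).
#' @export
setClass("EnergyParams", representation(
  stack = "matrix", helixEnd = "numeric", beta = "numeric",
  temperature = "numeric", gasConstant = "numeric", r0 = "numeric"))

setValidity("EnergyParams", function(object) {
  if (!all(dim(object@stack) == c(6L, 6L))) return("stack must be 6x6")
  if (!identical(names(object@beta), .PK_LETTERS))
    return("beta must be named H, K, L, M")
  b <- object@beta
  if (!(b["H"] <= b["K"] && b["K"] <= min(b["L"], b["M"])))
    return("pseudoknot penalties must satisfy beta_H <= beta_K <= min(beta_L, beta_M)")
  if (object@temperature <= 0 || object@gasConstant <= 0)
    return("RT must be positive")
  wc <- c("AU", "UA", "GC", "CG")
  if (any(object@stack[wc, wc] > 0))
    return("Watson-Crick stacking energies must be <= 0")
  TRUE
})

#' Thermal energy RT of an energy model
#' @param p an [EnergyParams] object.
#' @return RT in kcal/mol.
#' @export
thermalEnergy <- function(p) p@temperature * p@gasConstant

setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams: helixEnd ", object@helixEnd, " kcal/mol; beta(H,K,L,M) = ",
      paste(object@beta, collapse = ", "),
      "; T = ", object@temperature, " K (RT = ",
      signif(thermalEnergy(object), 4), ")\n", sep = "")
})

#' Enumerated landscape within an energy window
#'
#' All 1-structures of a sequence with energy at most `ceiling` kcal/mol
#' above the minimum free energy, under the single-base-pair move set.
#'
#' @slot sequence the RNA sequence (character).
#' @slot pt integer matrix, one pairing table per row.
#' @slot energy energies (kcal/mol) per structure.
#' @slot mfe row index of the MFE structure.
#' @slot ceiling the energy window (kcal/mol above MFE).
#' @slot nestedOnly whether crossing pairs were excluded.
#' @export
setClass("EnsembleIndex", representation(
  sequence = "character", pt = "matrix", energy = "numeric",
  mfe = "integer", ceiling = "numeric", nestedOnly = "logical"))

setMethod("length", "EnsembleIndex", function(x) nrow(x@pt))

setMethod("show", "EnsembleIndex", function(object) {
  cat("EnsembleIndex: ", nrow(object@pt), " 1-structures of a ",
      nchar(object@sequence), "-nt sequence within ",
      object@ceiling, " kcal/mol of the MFE (",
      sprintf("%.2f", object@energy[object@mfe]), " kcal/mol)\n", sep = "")
})

#' Extract one structure from an ensemble
#' @param ens an [EnsembleIndex].
#' @param i row index.
#' @export
structureAt <- function(ens, i) .fromPt(ens@pt[i, ])

#' Ensemble energies
#' @param ens an [EnsembleIndex].
#' @export
ensembleEnergies <- function(ens) ens@energy

#' Basin hopping graph
#'
#' Nodes are local minima (LMs) of the folding landscape; edges carry the
#' direct saddle height `S(x, y)` between the adjacent basins.  The `psi`
#' variant includes pseudoknotted LMs; the `deg0` variant is its
#' pseudoknot-free pruning with adjacency recomputed over non-crossing
#' structures only.
#'
#' @slot sequence the RNA sequence.
#' @slot lm data.frame with columns `id`, `structure` (dot-bracket),
#'   `energy`, `pkClass`, `count` (discovery count, NA for LMs admitted as
#'   path intermediates).
#' @slot edges data.frame with columns `from`, `to`, `saddle`, `pkClass`
#'   (composite pseudoknot class of the witness path).
#' @slot witnesses named list (key `"from|to"`) of witness paths, each a
#'   character vector of dot-bracket structures.
#' @slot variant `"psi"` or `"deg0"`.
#' @slot mode `"heuristic"` (findpath saddles) or `"exact"` (flooding).
#' @slot params the [EnergyParams] used.
#' @export
setClass("BasinHoppingGraph", representation(
  sequence = "character", lm = "data.frame", edges = "data.frame",
  witnesses = "list", variant = "character", mode = "character",
  params = "EnergyParams"))

setValidity("BasinHoppingGraph", function(object) {
  lm <- object@lm; ed <- object@edges
  if (nrow(ed) > 0L) {
    if (!all(c(ed$from, ed$to) %in% lm$id)) return("edge endpoint not an LM id")
    if (any(ed$from == ed$to)) return("self edge")
    fx <- lm$energy[match(ed$from, lm$id)]
    fy <- lm$energy[match(ed$to, lm$id)]
    if (any(ed$saddle < pmax(fx, fy) - 1e-9))
      return("saddle below an endpoint energy")
  }
  if (!object@variant %in% c("psi", "deg0")) return("variant must be psi or deg0")
  TRUE
})

#' @describeIn BasinHoppingGraph-class local-minimum table
#' @param bhg a [BasinHoppingGraph].
#' @export
lmTable <- function(bhg) bhg@lm

#' @describeIn BasinHoppingGraph-class edge table with saddle heights
#' @export
edgeTable <- function(bhg) bhg@edges

#' @describeIn BasinHoppingGraph-class graph variant ("psi" or "deg0")
#' @export
bhgVariant <- function(bhg) bhg@variant

setMethod("show", "BasinHoppingGraph", function(object) {
  cat("BasinHoppingGraph (", if (object@variant == "psi") "BHG-psi" else "BHG-0",
      ", ", object@mode, "): ", nrow(object@lm), " LMs, ",
      nrow(object@edges), " edges\n", sep = "")
  npk <- sum(object@lm$pkClass != "N")
  cat("  pseudoknotted LMs: ", npk, " / ", nrow(object@lm), "\n", sep = "")
})

#' Continuous-time Markov chain over landscape states
#'
#' Infinitesimal generator oriented for row-vector propagation
#' `p'(t) = p(t) Q`: the off-diagonal entry `Q[y, x]` is the rate from state
#' `y` to state `x`, and rows sum to zero.  All constructors in this package
#' satisfy detailed balance with respect to the Boltzmann weights of the
#' state energies.
#'
#' @slot states data.frame with columns `id`, `structure`, `energy`,
#'   `pkClass`.
#' @slot Q generator matrix (units of `r0`).
#' @slot r0 rate gauge.
#' @slot RT thermal energy (kcal/mol).
#' @export
setClass("RateModel", representation(
  states = "data.frame", Q = "matrix", r0 = "numeric", RT = "numeric"))

setValidity("RateModel", function(object) {
  Q <- object@Q
  if (nrow(Q) != ncol(Q) || nrow(Q) != nrow(object@states))
    return("generator dimension mismatch")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) return("negative off-diagonal rate")
  if (any(abs(rowSums(Q)) > 1e-8)) return("generator rows must sum to zero")
  TRUE
})

#' Number of states of a rate model
#' @param model a [RateModel].
#' @export
nStates <- function(model) nrow(model@Q)

#' State table of a rate model
#' @param model a [RateModel].
#' @export
stateTable <- function(model) model@states

#' Generator matrix of a rate model
#' @param model a [RateModel].
#' @export
generator <- function(model) model@Q

setMethod("show", "RateModel", function(object) {
  off <- object@Q; diag(off) <- 0
  cat("RateModel: ", nrow(object@Q), " states, ",
      sum(off > 0) / 2, " reversible transitions\n", sep = "")
})

#' Time course of state populations
#'
#' @slot times time grid (in `1/r0` units).
#' @slot P matrix of state probabilities, one row per time.
#' @export
setClass("PopulationSeries", representation(times = "numeric", P = "matrix"))

setValidity("PopulationSeries", function(object) {
  if (nrow(object@P) != length(object@times)) return("time grid mismatch")
  if (any(abs(rowSums(object@P) - 1) > 1e-9)) return("probability not conserved")
  if (any(object@P < -1e-12)) return("negative population")
  TRUE
})

setMethod("show", "PopulationSeries", function(object) {
  cat("PopulationSeries: ", ncol(object@P), " states over ",
      length(object@times), " times [",
      format(min(object@times)), ", ", format(max(object@times)), "]\n", sep = "")
})

#' Timed trajectory over basin hopping graph states
#'
#' A sequence of LM states `x0, ..., xk` with waiting times `t0, ..., t(k-1)`
#' and an upper time bound (horizon) `Tm`.
#'
#' @slot states character vector of LM ids, length `k + 1`.
#' @slot waits nonnegative waiting times, length `k`.
#' @slot horizon upper time bound `Tm`.
#' @export
setClass("Trajectory", representation(
  states = "character", waits = "numeric", horizon = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@states) < 1L) return("empty trajectory")
  if (length(object@waits) != length(object@states) - 1L)
    return("need one waiting time per transition")
  if (any(object@waits < 0)) return("negative waiting time")
  if (object@horizon < 0) return("negative horizon")
  TRUE
})

#' Construct a [Trajectory]
#' @param states LM ids visited, in order.
#' @param waits waiting time in each state except the last.
#' @param horizon upper time bound `Tm`.
#' @export
trajectory <- function(states, waits = numeric(length(states) - 1L), horizon = 0) {
  new("Trajectory", states = as.character(states), waits = as.numeric(waits),
      horizon = as.numeric(horizon))
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", paste(object@states, collapse = " -> "),
      " (horizon ", format(object@horizon), ")\n", sep = "")
})
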