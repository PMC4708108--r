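# Pluggable additive energy model with pseudoknot penalties.

# default stacking table: -kappa * (w(outer) + w(inner)), with pair weights
# GC/CG = 3, AU/UA = 2, GU/UG = 1 and kappa = 0.55 kcal/mol, giving the
# familiar range -1.1 (GU on GU) .. -3.3 (GC on GC) kcal/mol.
.defaultStack <- function(kappa = 0.55) {
  w <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)
  st <- -kappa * outer(w, w, "+")
  dimnames(st) <- list(.PAIR_TYPES, .PAIR_TYPES)
  st
}

#' Create an energy model
#'
#' @param stack 6x6 stacking table (kcal/mol) indexed by the outer and inner
#'   pair type in the order AU, UA, GC, CG, GU, UG; default is a symmetric
#'   strength-based table (see Details in the package vignette).
#' @param helixEnd per-helix penalty in kcal/mol.
#' @param beta named pseudoknot penalties (kcal/mol per crossing component);
#'   must satisfy `beta_H <= beta_K <= min(beta_L, beta_M)`.
#' @param temperature absolute temperature in Kelvin.
#' @param gasConstant kcal/(mol K).
#' @param r0 rate gauge defining the time unit.
#' @return an [EnergyParams] object.
#' @export
energyParams <- function(stack = .defaultStack(), helixEnd = 3.0,
                         beta = c(H = 9.6, K = 12.6, L = 14.6, M = 14.6),
                         temperature = 310.15, gasConstant = 0.0019872,
                         r0 = 1.0) {
  beta <- beta[.PK_LETTERS]
  names(beta) <- .PK_LETTERS
  new("EnergyParams", stack = stack, helixEnd = helixEnd, beta = beta,
      temperature = temperature, gasConstant = gasConstant, r0 = r0)
}

# plain list handed to the C++ engine
.parList <- function(p) {
  list(stack = unname(p@stack), helixEnd = p@helixEnd, beta = unname(p@beta))
}

#' Free energy of a 1-structure
#'
#' Sum of stacking terms over consecutive pairs within each helix, one helix
#' end penalty per helix, and one pseudoknot penalty per crossing component
#' according to its type.  The open chain has energy 0.
#'
#' @param sequence RNA sequence (character, alphabet ACGU).
#' @param s an [RNAStructure].
#' @param p an [EnergyParams] object.
#' @return energy in kcal/mol.
#' @examples
#' p <- energyParams()
#' structureEnergy("GGGGAAAACCCC", parseStructure("((((....))))"), p)
#' @export
structureEnergy <- function(sequence, s, p = energyParams()) {
  seqc <- .encodeSeq(sequence)
  if (length(seqc) != length(s))
    stop("sequence (", length(seqc), " nt) and structure (", length(s),
         " nt) lengths differ")
  e <- .cpp_energy(seqc, s@pt, .parList(p))
  if (is.na(e))
    stop("structure has a non-canonical pair or is not a 1-structure over this sequence")
  e
}

#' Boltzmann weight of an energy
#'
#' @param e energy in kcal/mol.
#' @param p an [EnergyParams] object.
#' @return `exp(-e / RT)`.
#' @export
boltzmannWeight <- function(e, p = energyParams()) exp(-e / thermalEnergy(p))

#' Read an energy model from a YAML config file
#'
#' Missing entries fall back to the package defaults; the pseudoknot-penalty
#' ordering `beta_H <= beta_K <= min(beta_L, beta_M)` is enforced.
#'
#' @param path YAML file; recognised keys: `kappa` (stacking scale), `stack`
#'   (full 6x6 table as a list of rows), `helixEnd`, `beta` (named list),
#'   `temperature`, `gasConstant`, `r0`.
#' @return an [EnergyParams] object.
#' @export
loadEnergyParams <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  stack <- if (!is.null(cfg$stack)) {
    m <- do.call(rbind, lapply(cfg$stack, as.numeric))
    dimnames(m) <- list(.PAIR_TYPES, .PAIR_TYPES)
    m
  } else .defaultStack(kappa = if (is.null(cfg$kappa)) 0.55 else cfg$kappa)
  beta <- c(H = 9.6, K = 12.6, L = 14.6, M = 14.6)
  if (!is.null(cfg$beta)) {
    supplied <- unlist(cfg$beta)
    beta[names(supplied)] <- supplied
  }
  energyParams(
    stack = stack, beta = beta,
    helixEnd = if (is.null(cfg$helixEnd)) 3.0 else cfg$helixEnd,
    temperature = if (is.null(cfg$temperature)) 310.15 else cfg$temperature,
    gasConstant = if (is.null(cfg$gasConstant)) 0.0019872 else cfg$gasConstant,
    r0 = if (is.null(cfg$r0)) 1.0 else cfg$r0)
}

#' Write an energy model to a YAML config file
#'
#' `loadEnergyParams()` of the written file reproduces the model.
#'
#' @param p an [EnergyParams] object.
#' @param path output file.
#' @export
saveEnergyParams <- function(p, path) {
  yaml::write_yaml(list(
    stack = lapply(seq_len(6), function(r) unname(p@stack[r, ])),
    helixEnd = p@helixEnd,
    beta = as.list(p@beta),
    temperature = p@temperature,
    gasConstant = p@gasConstant,
    r0 = p@r0), path)
  invisible(path)
}
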