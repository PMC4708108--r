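# Continuous-time Markov chain kinetics over basin hopping graphs and the
# full microscopic landscape.

#' Arrhenius rate model over a basin hopping graph
#'
#' Builds the infinitesimal generator for hopping between adjacent basins:
#' the rate out of LM `y` toward LM `x` along the edge `{x, y}` is
#' `r0 * exp(-(S(x, y) - f(y)) / RT)`; non-adjacent pairs get rate 0 and the
#' diagonal balances each row.  The generator is oriented for row-vector
#' propagation `p'(t) = p(t) Q` and satisfies detailed balance with respect
#' to the Boltzmann weights of the LM energies by construction (both
#' directed flows equal `exp(-S/RT)` up to the common normalization).
#'
#' @param bhg a [BasinHoppingGraph].
#' @param p an [EnergyParams] object (defaults to the graph's own).
#' @return a [RateModel].
#' @export
rateMatrix <- function(bhg, p = bhg@params) {
  lm <- bhg@lm; ed <- bhg@edges
  RT <- thermalEnergy(p)
  n <- nrow(lm)
  Q <- matrix(0, n, n, dimnames = list(lm$id, lm$id))
  if (nrow(ed) > 0L) {
    fx <- lm$energy[match(ed$from, lm$id)]
    fy <- lm$energy[match(ed$to, lm$id)]
    if (any(ed$saddle < pmax(fx, fy) - 1e-9))
      stop("edge saddle below an endpoint energy")
    for (r in seq_len(nrow(ed))) {
      x <- ed$from[r]; y <- ed$to[r]; S <- ed$saddle[r]
      Q[y, x] <- Q[y, x] + p@r0 * exp(-(S - fy[r]) / RT)
      Q[x, y] <- Q[x, y] + p@r0 * exp(-(S - fx[r]) / RT)
    }
  }
  diag(Q) <- -rowSums(Q)
  states <- data.frame(id = lm$id, structure = lm$structure,
                       energy = lm$energy, pkClass = lm$pkClass,
                       stringsAsFactors = FALSE)
  new("RateModel", states = states, Q = Q, r0 = p@r0, RT = RT)
}

#' Microscopic Metropolis rate model (oracle)
#'
#' Builds the generator over every enumerated 1-structure, with the
#' Metropolis rule on the single-base-pair move graph: the rate from `y` to
#' a neighbor `x` is `r0 * min(1, exp(-(f(x) - f(y)) / RT))`.  Used as the
#' full-landscape reference against which coarse-grained BHG kinetics is
#' validated.
#'
#' @param sequence RNA sequence (guarded length, see [enumerateEnsemble]).
#' @param p an [EnergyParams] object.
#' @param ceiling energy window (kcal/mol above MFE).
#' @param nestedOnly restrict to pseudoknot-free structures.
#' @param ensemble optional precomputed [EnsembleIndex].
#' @return a [RateModel] with one state per enumerated structure (ordered by
#'   energy, then structure string).
#' @export
microscopicModel <- function(sequence, p = energyParams(), ceiling = 10,
                             nestedOnly = FALSE, ensemble = NULL) {
  if (is.null(ensemble))
    ensemble <- enumerateEnsemble(sequence, p, ceiling = ceiling,
                                  nestedOnly = nestedOnly)
  N <- nrow(ensemble@pt)
  strs <- .ensembleStrings(ensemble)
  ord <- order(ensemble@energy, strs)
  pt <- ensemble@pt[ord, , drop = FALSE]
  E <- ensemble@energy[ord]
  strs <- strs[ord]
  adj <- .cpp_adjacency(pt)
  RT <- thermalEnergy(p)
  ids <- sprintf("s%04d", seq_len(N))
  Q <- matrix(0, N, N, dimnames = list(ids, ids))
  for (r in seq_len(nrow(adj))) {
    a <- adj[r, 1]; b <- adj[r, 2]
    Q[a, b] <- p@r0 * min(1, exp(-(E[b] - E[a]) / RT))
    Q[b, a] <- p@r0 * min(1, exp(-(E[a] - E[b]) / RT))
  }
  diag(Q) <- -rowSums(Q)
  states <- data.frame(
    id = ids, structure = strs, energy = E,
    pkClass = vapply(seq_len(N), function(i) .pkClassOfPt(pt[i, ]),
                     character(1)),
    stringsAsFactors = FALSE)
  new("RateModel", states = states, Q = Q, r0 = p@r0, RT = RT)
}

#' Boltzmann equilibrium distribution of a rate model
#'
#' The stationary distribution of every generator constructed in this
#' package: probabilities proportional to `exp(-f/RT)` over the model's
#' states.
#'
#' @param model a [RateModel].
#' @return named probability vector.
#' @export
equilibriumDistribution <- function(model) {
  w <- exp(-(model@states$energy - min(model@states$energy)) / model@RT)
  stats::setNames(w / sum(w), model@states$id)
}

#' Logarithmic time grid
#'
#' @param from,to grid bounds in `1/r0` time units.
#' @param perDecade grid points per decade (total capped at `maxPoints`).
#' @param maxPoints cap on the number of points.
#' @return increasing numeric vector of times.
#' @export
logTimeGrid <- function(from = 1e-2, to = 1e18, perDecade = 60L,
                        maxPoints = 600L) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  npt <- min(as.integer(ceiling(log10(to / from) * perDecade)) + 1L,
             as.integer(maxPoints))
  10^seq(log10(from), log10(to), length.out = npt)
}

#' Propagate state populations
#'
#' Computes `p(t) = p0 exp(tQ)` on a time grid.  The matrix exponential is
#' evaluated through the spectral decomposition of the symmetrized generator
#' `D^(1/2) Q D^(-1/2)` (with `D` the diagonal of Boltzmann weights), which
#' is exact for the detailed-balance generators built here and stable from
#' `t = 0` out to arbitrarily large times.
#'
#' @param model a [RateModel].
#' @param p0 initial probability row vector over the model's states; default
#'   puts all mass on the open-chain state (error if the open chain is not a
#'   state of the model).
#' @param times time grid (in `1/r0` units), default [logTimeGrid()].
#' @return a [PopulationSeries] with one row per time and the model's state
#'   ids as column names.
#' @export
propagate <- function(model, p0 = NULL, times = logTimeGrid()) {
  n <- nStates(model)
  if (is.null(p0)) {
    open <- which(!grepl("[^.]", model@states$structure))
    if (length(open) != 1L)
      stop("no open-chain state in the model; supply p0 explicitly")
    p0 <- numeric(n); p0[open] <- 1
  }
  p0 <- as.numeric(p0)
  if (length(p0) != n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability vector over the model's states")
  sq <- sqrt(equilibriumDistribution(model))
  M <- sweep(sweep(model@Q, 1, sq, "*"), 2, sq, "/")
  M <- (M + t(M)) / 2  # enforce exact symmetry before eigen
  es <- eigen(M, symmetric = TRUE)
  # left factor of p(t): (p0 D^{-1/2} V); right factor rows: (V^T D^{1/2})
  lf <- (p0 / sq) %*% es$vectors
  rf <- t(es$vectors) * rep(sq, each = n)
  P <- matrix(0, length(times), n, dimnames = list(NULL, model@states$id))
  lam <- pmin(es$values, 0)  # the generator spectrum is nonpositive
  # zero modes (one per connected component) come back as O(eps * ||M||)
  # noise; on grids reaching 1e18 time units even -1e-15 would wrongly
  # annihilate the equilibrium mode, so snap them to exactly zero
  lam[abs(lam) <= n * .Machine$double.eps * max(abs(lam))] <- 0
  for (k in seq_along(times)) {
    pk <- as.numeric((lf * exp(lam * times[k])) %*% rf)
    pk[pk < 0 & pk > -1e-12] <- 0
    P[k, ] <- pk / sum(pk)
  }
  new("PopulationSeries", times = as.numeric(times), P = P)
}

#' Time to reach equilibrium
#'
#' First time on the grid at which the L1 distance between the populations
#' and the equilibrium distribution drops below `tol`; `Inf` if the series
#' never gets that close.
#'
#' @param series a [PopulationSeries].
#' @param equilibrium equilibrium probability vector in the series' column
#'   order (e.g. [equilibriumDistribution()]).
#' @param tol L1 tolerance (default 0.01).
#' @return time in `1/r0` units, or `Inf`.
#' @export
equilibriumTime <- function(series, equilibrium, tol = 0.01) {
  if (length(equilibrium) != ncol(series@P))
    stop("equilibrium vector length mismatch")
  d <- rowSums(abs(sweep(series@P, 2, as.numeric(equilibrium))))
  hit <- which(d < tol)
  if (length(hit) == 0L) Inf else series@times[hit[1]]
}

#' Reduce a rate model by quasi-steady-state elimination
#'
#' Repeatedly removes the state with the lowest degree (number of nonzero
#' transitions; ties: highest energy first, then id) among the non-protected
#' states, redistributing its flux: `Q'[a, b] += Q[a, q] * Q[q, b] / lambda_q`
#' with `lambda_q` the total outflow of the eliminated state `q`.  The update
#' preserves row sums and detailed balance exactly, so the equilibrium of the
#' retained states stays proportional to their Boltzmann weights.
#'
#' @param model a [RateModel].
#' @param maxStates target number of states.
#' @param protect ids of states that must never be eliminated; the
#'   lowest-energy state is always protected.
#' @return the reduced [RateModel].
#' @export
qssReduce <- function(model, maxStates, protect = character(0)) {
  st <- model@states
  protect <- union(protect, st$id[which.min(st$energy)])
  if (!all(protect %in% st$id)) stop("unknown protected state id")
  if (maxStates < length(protect))
    stop("maxStates smaller than the number of protected states")
  Q <- model@Q
  keep <- st$id
  while (length(keep) > maxStates) {
    sub <- st[match(keep, st$id), ]
    off <- Q; diag(off) <- 0
    deg <- rowSums(off != 0)  # off-diagonal nonzeros per row
    elig <- which(!(keep %in% protect))
    if (length(elig) == 0L) break
    o <- elig[order(deg[elig], -sub$energy[elig], keep[elig])]
    q <- o[1L]
    lam <- -Q[q, q]
    if (lam <= 0) {  # isolated state: just drop it
      Q <- Q[-q, -q, drop = FALSE]
      keep <- keep[-q]
      next
    }
    outq <- Q[q, -q]; inq <- Q[-q, q]
    Q <- Q[-q, -q, drop = FALSE] + outer(inq, outq) / lam
    keep <- keep[-q]
  }
  new("RateModel", states = st[match(keep, st$id), ], Q = Q, r0 = model@r0,
      RT = model@RT)
}

#' Aggregate a population series by state groups
#'
#' Sums the population columns within groups (for example, microscopic
#' structures grouped by their gradient basin) and returns a series over the
#' group labels.
#'
#' @param series a [PopulationSeries].
#' @param groups character vector of group labels, one per series column.
#' @return a [PopulationSeries] with one column per distinct label (in first
#'   appearance order).
#' @export
aggregatePopulations <- function(series, groups) {
  if (length(groups) != ncol(series@P)) stop("one group label per column required")
  labs <- unique(groups)
  P <- vapply(labs, function(g)
    rowSums(series@P[, groups == g, drop = FALSE]), numeric(length(series@times)))
  P <- matrix(P, nrow = length(series@times), dimnames = list(NULL, labs))
  new("PopulationSeries", times = series@times, P = P)
}
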