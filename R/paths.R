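# Optimal refolding paths in a basin hopping graph: Criterion A (peak
# energy, then accumulated activation energy) and Criterion B
# (maximum-likelihood timed trajectories).

# adjacency list (edge row indices per node) for a BHG
.bhgAdjacency <- function(bhg) {
  ids <- bhg@lm$id
  adj <- vector("list", length(ids))
  names(adj) <- ids
  ed <- bhg@edges
  for (r in seq_len(nrow(ed))) {
    adj[[ed$from[r]]] <- rbind(adj[[ed$from[r]]], c(ed$to[r], r))
    adj[[ed$to[r]]] <- rbind(adj[[ed$to[r]]], c(ed$from[r], r))
  }
  lapply(adj, function(m) {
    if (is.null(m)) return(NULL)
    m[order(m[, 1]), , drop = FALSE]
  })
}

# exhaustive best simple path by depth-first search with branch-and-bound;
# stepCost(fromId, edgeRow) >= 0; ties broken by fewer edges then the
# lexicographic id sequence.  Returns list(path, cost) or NULL.
.bestPath <- function(bhg, adj, from, to, stepCost) {
  best <- NULL
  bestCost <- Inf; bestHops <- Inf; bestKey <- ""
  visited <- character(0)
  rec <- function(node, cost, path) {
    if (cost > bestCost + .EPS) return(invisible(NULL))
    if (node == to) {
      key <- paste(path, collapse = ">")
      better <- cost < bestCost - .EPS ||
        (cost < bestCost + .EPS &&
           (length(path) < bestHops ||
              (length(path) == bestHops && key < bestKey)))
      if (better) {
        best <<- path; bestCost <<- cost
        bestHops <<- length(path); bestKey <<- key
      }
      return(invisible(NULL))
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible(NULL))
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% path) next
      rec(nxt, cost + stepCost(node, as.integer(nb[r, 2])), c(path, nxt))
    }
  }
  rec(from, 0, from)
  if (is.null(best)) NULL else list(path = best, cost = bestCost)
}

#' Optimal refolding path, Criterion A
#'
#' Among all graph paths between two local minima, first minimizes the peak
#' energy (the maximal edge saddle along the path, equal to the exact
#' minimax saddle of the graph) and, among those, minimizes the accumulated
#' activation energy `sum(S(x_s, x_{s+1}) - f(x_s))`.  Deterministic
#' tie-break: fewer edges, then lexicographic id sequence.
#'
#' @param bhg a [BasinHoppingGraph].
#' @param from,to LM ids.
#' @return list with `path` (LM ids), `peak` (kcal/mol), `activation`
#'   (accumulated activation energy, kcal/mol) and `steps` (data.frame:
#'   `from`, `to`, `saddle`, `activation`).
#' @export
optimalPathA <- function(bhg, from, to) {
  ids <- bhg@lm$id
  if (!(from %in% ids && to %in% ids)) stop("unknown LM id")
  if (from == to)
    return(list(path = from, peak = bhg@lm$energy[match(from, ids)],
                activation = 0,
                steps = data.frame(from = character(0), to = character(0),
                                   saddle = numeric(0), activation = numeric(0))))
  bottleneck <- .graphMinimax(bhg, from, to)
  if (is.na(bottleneck)) stop("LMs ", from, " and ", to, " are disconnected")
  sub <- bhg
  sub@edges <- bhg@edges[bhg@edges$saddle <= bottleneck + .EPS, , drop = FALSE]
  adj <- .bhgAdjacency(sub)
  fE <- stats::setNames(bhg@lm$energy, ids)
  stepCost <- function(node, edgeRow) sub@edges$saddle[edgeRow] - fE[[node]]
  res <- .bestPath(sub, adj, from, to, stepCost)
  if (is.null(res)) stop("internal: bottleneck subgraph lost connectivity")
  path <- res$path
  steps <- data.frame(from = path[-length(path)], to = path[-1L],
                      saddle = NA_real_, activation = NA_real_,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(steps))) {
    hit <- which((sub@edges$from == steps$from[r] & sub@edges$to == steps$to[r]) |
                   (sub@edges$from == steps$to[r] & sub@edges$to == steps$from[r]))
    steps$saddle[r] <- sub@edges$saddle[hit[1]]
    steps$activation[r] <- steps$saddle[r] - fE[[steps$from[r]]]
  }
  list(path = path, peak = max(steps$saddle), activation = sum(steps$activation),
       steps = steps)
}

#' Log-likelihood of a timed trajectory
#'
#' For a trajectory `x0, t0, x1, t1, ..., xk` with horizon `Tm`, the
#' likelihood factorizes over jumps and waiting times; after cancellation it
#' reduces to the product of the jump rates times the exponential of the
#' accumulated waiting:
#' `log L = sum(log r(x_i -> x_{i+1})) - (sum(lambda_{x_i} t_i) +
#' lambda_{x_k} (Tm - sum(t_i)))`.
#' Returns `-Inf` when the waiting times exceed the horizon.
#'
#' @param u a [Trajectory] (LM ids, waiting times, horizon).
#' @param model a [RateModel] whose states cover the trajectory.
#' @return log-likelihood (natural log).
#' @export
trajectoryLogLik <- function(u, model) {
  ids <- model@states$id
  at <- match(u@states, ids)
  if (anyNA(at)) stop("trajectory visits a state missing from the model")
  if (sum(u@waits) > u@horizon + 1e-12) return(-Inf)
  Q <- model@Q
  lam <- -diag(Q)
  k <- length(at) - 1L
  logr <- 0
  if (k > 0L) for (i in seq_len(k)) {
    r <- Q[at[i], at[i + 1L]]
    if (r <= 0) stop("consecutive states ", u@states[i], " and ",
                     u@states[i + 1L], " are not adjacent in the model")
    logr <- logr + log(r)
  }
  waiting <- if (k > 0L) sum(lam[at[-length(at)]] * u@waits) else 0
  waiting <- waiting + lam[at[length(at)]] * (u@horizon - sum(u@waits))
  logr - waiting
}

#' Optimal refolding trajectory, Criterion B
#'
#' Finds the maximum-likelihood timed trajectory from `from` to `to` with
#' upper time bound `Tm`.  For a fixed state sequence the optimal time
#' allocation is closed-form: all slack goes to the visited state with the
#' smallest total outflow rate (the earliest such state on ties), so
#' `log L = sum(log r) - Tm * min(lambda)`.  For `Tm = 0` this reduces to
#' minimizing the accumulated activation energy.  Graphs with at most
#' `maxExhaustive` LMs are searched exhaustively over simple paths;
#' larger graphs use the minimum accumulated-activation-energy sequence.
#'
#' @param bhg a [BasinHoppingGraph].
#' @param model a [RateModel] over the graph's LMs (default
#'   `rateMatrix(bhg)`).
#' @param from,to LM ids.
#' @param Tm time horizon (in `1/r0` units), `>= 0`.
#' @param maxExhaustive node-count bound for exhaustive search.
#' @return list with `trajectory` (a [Trajectory]), `logLik`, `peak`
#'   (maximal edge saddle) and `activation` (accumulated activation
#'   energy).
#' @export
optimalPathB <- function(bhg, model = rateMatrix(bhg), from, to, Tm = 0,
                         maxExhaustive = 15L) {
  ids <- bhg@lm$id
  if (!(from %in% ids && to %in% ids)) stop("unknown LM id")
  if (Tm < 0) stop("Tm must be nonnegative")
  Q <- model@Q
  if (!identical(rownames(Q), ids))
    stop("model states must match the graph's LM ids")
  lam <- -diag(Q)
  adj <- .bhgAdjacency(bhg)

  seqScore <- function(path) {
    # log-likelihood of the best time allocation for this state sequence
    at <- match(path, ids)
    logr <- 0
    if (length(at) > 1L)
      for (i in seq_len(length(at) - 1L)) logr <- logr + log(Q[at[i], at[i + 1L]])
    logr - Tm * min(lam[at])
  }

  if (from == to) {
    path <- from
  } else if (length(ids) <= maxExhaustive) {
    best <- NULL; bestScore <- -Inf; bestKey <- ""
    rec <- function(node, path) {
      if (node == to) {
        sc <- seqScore(path)
        key <- paste(path, collapse = ">")
        if (sc > bestScore + 1e-12 ||
            (sc > bestScore - 1e-12 && (is.null(best) ||
                                        length(path) < length(best) ||
                                        (length(path) == length(best) && key < bestKey)))) {
          best <<- path; bestScore <<- sc; bestKey <<- key
        }
        return(invisible(NULL))
      }
      nb <- adj[[node]]
      if (is.null(nb)) return(invisible(NULL))
      for (r in seq_len(nrow(nb))) {
        nxt <- nb[r, 1]
        if (nxt %in% path) next
        rec(nxt, c(path, nxt))
      }
    }
    rec(from, from)
    if (is.null(best)) stop("LMs ", from, " and ", to, " are disconnected")
    path <- best
  } else {
    # large graphs: minimum accumulated-activation-energy state sequence
    fE <- stats::setNames(bhg@lm$energy, ids)
    stepCost <- function(node, edgeRow) bhg@edges$saddle[edgeRow] - fE[[node]]
    res <- .bestPath(bhg, adj, from, to, stepCost)
    if (is.null(res)) stop("LMs ", from, " and ", to, " are disconnected")
    path <- res$path
  }

  at <- match(path, ids)
  waits <- numeric(max(length(path) - 1L, 0L))
  if (Tm > 0 && length(path) > 0L) {
    slackTo <- which(lam[at] == min(lam[at]))[1L]
    if (slackTo < length(path)) waits[slackTo] <- Tm
  }
  u <- trajectory(path, waits = waits, horizon = Tm)
  peak <- NA_real_; act <- 0
  if (length(path) > 1L) {
    fE <- stats::setNames(bhg@lm$energy, ids)
    sd <- vapply(seq_len(length(path) - 1L), function(i) {
      ed <- bhg@edges
      hit <- which((ed$from == path[i] & ed$to == path[i + 1L]) |
                     (ed$from == path[i + 1L] & ed$to == path[i]))
      ed$saddle[hit[1]]
    }, numeric(1))
    peak <- max(sd)
    act <- sum(sd - fE[path[-length(path)]])
  }
  list(trajectory = u, logLik = trajectoryLogLik(u, model), peak = peak,
       activation = act)
}
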