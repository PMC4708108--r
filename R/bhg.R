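# Direct paths, saddle estimation, basin hopping graph assembly and the
# exact flooding oracle.

.EPS <- 1e-9

# --------------------------------------------------------------------------
# small utilities over pairing tables and pair tables

.keyPt <- function(pt) paste(pt, collapse = ",")

.bpDistance <- function(a, b) {
  ia <- which(a > seq_along(a)); ib <- which(b > seq_along(b))
  sum(b[ia] != a[ia]) + sum(a[ib] != b[ib])
}

.pairKey <- function(a, b) paste(min(a, b), max(a, b), sep = "|")

# union-find over 1..n
.ufNew <- function(n) seq_len(n)
.ufFind <- function(uf, x) { while (uf[x] != x) { uf[x] <- uf[uf[x]]; x <- uf[x] }; x }

#' Pseudoknot-aware direct refolding path (findpath heuristic)
#'
#' Breadth-limited best-first search over moves that strictly decrease the
#' base-pair distance to the target (removing pairs private to `x`, adding
#' pairs private to `y`), keeping every intermediate inside the 1-structure
#' class.  At each distance level the `width` partial paths with the lowest
#' peak energy are kept.
#'
#' @param x,y start and target [RNAStructure]s over `sequence`.
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param width beam width (number of partial paths kept per level).
#' @param nestedOnly restrict intermediates to pseudoknot-free structures.
#' @return list with `structures` (list of [RNAStructure], from `x` to `y`),
#'   `energies` and `peak` (kcal/mol).
#' @export
findDirectPath <- function(x, y, sequence, p = energyParams(), width = 16L,
                           nestedOnly = FALSE) {
  res <- .cpp_findpath(.encodeSeq(sequence), x@pt, y@pt, .parList(p),
                       as.integer(width), nestedOnly)
  list(structures = lapply(res$path, .fromPt),
       energies = res$energy, peak = res$peak)
}

# --------------------------------------------------------------------------
# saddle estimation with a per-build cache
#
# The cache environment carries:
#   walk[[key]] : memoized gradient walks (lmKey, path of pts, energies)
#   S[[pairKey]]: best-known saddle bound for an LM pair (any witness)
#   W[[pairKey]]: best bound carrying a *direct* (unimodal) witness:
#                 list(S, path = list of pts)
#   lmE[[key]], lmPt[[key]]: energies / pairing tables of LMs seen

.estCache <- function() {
  env <- new.env(parent = emptyenv())
  env$walk <- new.env(parent = emptyenv())
  env$S <- new.env(parent = emptyenv())
  env$W <- new.env(parent = emptyenv())
  env$lmE <- new.env(parent = emptyenv())
  env$lmPt <- new.env(parent = emptyenv())
  env
}

.walkCached <- function(env, seqc, pt, parl, nestedOnly) {
  key <- .keyPt(pt)
  got <- env$walk[[key]]
  if (!is.null(got)) return(got)
  res <- .cpp_gradient_walk(seqc, pt, parl, nestedOnly)
  k <- length(res$path)
  lmKey <- .keyPt(res$path[[k]])
  out <- list(lmKey = lmKey, path = res$path, energies = res$energy)
  env$walk[[key]] <- out
  env$lmE[[lmKey]] <- res$energy[k]
  env$lmPt[[lmKey]] <- res$path[[k]]
  out
}

.recordPair <- function(env, keyA, keyB, S, witness, direct) {
  if (keyA == keyB) return(invisible(NULL))
  pk <- paste(min(keyA, keyB), max(keyA, keyB), sep = "#")
  if (keyA > keyB && !is.null(witness)) witness <- rev(witness)
  old <- env$S[[pk]]
  if (is.null(old) || S < old - .EPS) env$S[[pk]] <- S
  if (direct && !is.null(witness)) {
    oldW <- env$W[[pk]]
    if (is.null(oldW) || S < oldW$S - .EPS) env$W[[pk]] <- list(S = S, path = witness)
  }
  invisible(NULL)
}

# crossing witness between two adjacent structures in different basins:
# reverse descent from sa, then descent from sb; unimodal by construction
.crossWitness <- function(wa, wb) c(rev(wa$path), wb$path)

# core recursive estimator over pairing tables of two (distinct) LMs;
# returns list(S, path = list of pts, direct = logical, newKeys)
.estimatePair <- function(env, seqc, parl, ptx, pty, width, rounds, nestedOnly) {
  kx <- .keyPt(ptx); ky <- .keyPt(pty)
  swapped <- kx > ky
  if (swapped) { tmp <- ptx; ptx <- pty; pty <- tmp; tmp <- kx; kx <- ky; ky <- tmp }
  fp <- .cpp_findpath(seqc, ptx, pty, parl, as.integer(width), nestedOnly)
  np <- length(fp$path)
  walks <- lapply(fp$path, function(pt) .walkCached(env, seqc, pt, parl, nestedOnly))
  bk <- vapply(walks, function(w) w$lmKey, character(1))

  # run-length encode the basin sequence and its crossing positions
  runEnd <- which(bk[-np] != bk[-1L])        # crossing between i and i+1
  segs <- list()
  prev <- 1L
  for (i in runEnd) {
    segs[[length(segs) + 1L]] <- list(a = bk[prev], b = bk[i + 1L], at = i)
    prev <- i + 1L
  }
  # best crossing per consecutive basin pair (a path may cross a boundary
  # several times; keep the lowest crossing)
  segS <- numeric(length(segs))
  segW <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    i <- segs[[s]]$at
    segS[s] <- max(fp$energy[i], fp$energy[i + 1L])
    segW[[s]] <- .crossWitness(walks[[i]], walks[[i + 1L]])
    .recordPair(env, segs[[s]]$a, segs[[s]]$b, segS[s], segW[[s]], direct = TRUE)
  }

  newKeys <- character(0)
  basinKeys <- c(bk[1L], vapply(segs, function(z) z$b, character(1)))
  if (length(basinKeys) > 2L && rounds > 1L) {
    for (s in seq_along(segs)) {
      a <- segs[[s]]$a; b <- segs[[s]]$b
      if ((a == kx && b == ky) || (a == ky && b == kx)) next
      sub <- .estimatePair(env, seqc, parl, env$lmPt[[a]], env$lmPt[[b]],
                           width, rounds - 1L, nestedOnly)
      if (sub$S < segS[s] - .EPS) {
        segS[s] <- sub$S
        segW[[s]] <- sub$path
        newKeys <- union(newKeys, sub$newKeys)
      }
    }
  }

  if (length(segs) == 0L) {
    # degenerate: whole findpath path gradient-walks into one basin; the
    # beam path itself is the witness (peak bound)
    S <- fp$peak
    path <- fp$path
    direct <- !is.unsorted(fp$energy[seq_len(which.max(fp$energy))]) &&
      !is.unsorted(rev(fp$energy[which.max(fp$energy):np]))
  } else {
    S <- max(segS)
    path <- segW[[1L]]
    if (length(segs) > 1L)
      for (s in 2L:length(segs)) path <- c(path, segW[[s]][-1L])
    direct <- length(basinKeys) == 2L
  }
  # intermediate LMs are admitted when they strictly lower the bound below
  # the raw beam peak
  inter <- setdiff(unique(basinKeys), c(kx, ky))
  if (S < fp$peak - .EPS) newKeys <- union(newKeys, inter)
  .recordPair(env, kx, ky, S, path, direct = direct)
  if (swapped) path <- rev(path)
  list(S = S, path = path, direct = direct, newKeys = newKeys)
}

#' Estimate the saddle height between two local minima
#'
#' Runs the pseudoknot-aware findpath heuristic, gradient-walks every path
#' structure, and decomposes the path at basin boundaries.  Any new local
#' minimum that strictly lowers the composite peak splits the problem into
#' two subproblems, recursively up to `rounds`.  The estimate is an upper
#' bound on the exact saddle height and is non-increasing in both `width`
#' and `rounds`.
#'
#' @param x,y local-minimum [RNAStructure]s over `sequence`.
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param width findpath beam width.
#' @param rounds recursion depth for path splitting at intermediate LMs.
#' @param nestedOnly restrict the move universe to pseudoknot-free
#'   structures.
#' @return list with `saddle` (kcal/mol), `path` (witness path as
#'   dot-bracket strings, from `x` to `y`), and `newLM` (data.frame of
#'   intermediate local minima discovered: `structure`, `energy`,
#'   `pkClass`).
#' @export
estimateSaddle <- function(x, y, sequence, p = energyParams(), width = 16L,
                           rounds = 3L, nestedOnly = FALSE) {
  seqc <- .encodeSeq(sequence)
  parl <- .parList(p)
  if (identical(x@pt, y@pt))
    return(list(saddle = structureEnergy(sequence, x, p),
                path = writeStructure(x),
                newLM = data.frame(structure = character(0), energy = numeric(0),
                                   pkClass = character(0))))
  env <- .estCache()
  res <- .estimatePair(env, seqc, parl, x@pt, y@pt, width, as.integer(rounds),
                       nestedOnly)
  newLM <- data.frame(
    structure = vapply(res$newKeys, function(k) writeStructure(env$lmPt[[k]]),
                       character(1), USE.NAMES = FALSE),
    energy = vapply(res$newKeys, function(k) env$lmE[[k]], numeric(1),
                    USE.NAMES = FALSE),
    pkClass = vapply(res$newKeys, function(k) .pkClassOfPt(env$lmPt[[k]]),
                     character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  newLM <- newLM[order(newLM$energy, newLM$structure), , drop = FALSE]
  rownames(newLM) <- NULL
  list(saddle = res$S,
       path = vapply(res$path, writeStructure, character(1)),
       newLM = newLM)
}

# --------------------------------------------------------------------------
# graph assembly: dominated-edge pruning + connectivity repair

# pairTab: data.frame(a, b, S) over LM indices (a < b), the best-known
# saddle bound for each pair. edges: logical subset of pairTab rows taken as
# initial edges.  An edge (x, y) is dropped when a third LM z with
# f(z) < S(x, y) routes around it at no extra height:
# max(S(x, z), S(z, y)) <= S(x, y).  Edges are processed in descending
# saddle order so that ties cannot erase a whole plateau triangle, and a
# final union-find pass restores any pair connectivity implied by the pair
# table (lowest pairs first), keeping graph minimax saddles equal to the
# table's.
.pruneDominated <- function(pairTab, edges, lmE) {
  L <- length(lmE)
  Smat <- matrix(NA_real_, L, L)
  for (r in seq_len(nrow(pairTab)))
    Smat[pairTab$a[r], pairTab$b[r]] <- Smat[pairTab$b[r], pairTab$a[r]] <- pairTab$S[r]
  keep <- edges
  ord <- order(-pairTab$S, pairTab$a, pairTab$b)
  for (r in ord) {
    if (!keep[r]) next
    x <- pairTab$a[r]; y <- pairTab$b[r]; S <- pairTab$S[r]
    z <- which(!is.na(Smat[x, ]) & !is.na(Smat[, y]) &
                 pmax(Smat[x, ], Smat[, y]) <= S + .EPS &
                 lmE < S - .EPS)
    z <- setdiff(z, c(x, y))
    if (length(z) > 0L) keep[r] <- FALSE
  }
  # connectivity repair: every pair-table link must survive as a graph path
  uf <- .ufNew(L)
  for (r in which(keep)) {
    ra <- .ufFind(uf, pairTab$a[r]); rb <- .ufFind(uf, pairTab$b[r])
    if (ra != rb) uf[ra] <- rb
  }
  # ties broken toward pairs with a direct witness so that every repaired
  # edge remains certifiable by its witness path
  for (r in order(pairTab$S, !edges, pairTab$a, pairTab$b)) {
    ra <- .ufFind(uf, pairTab$a[r]); rb <- .ufFind(uf, pairTab$b[r])
    if (ra != rb) { keep[r] <- TRUE; uf[ra] <- rb }
  }
  keep
}

# composite pseudoknot class over a witness path (dot-bracket strings)
.pathClass <- function(strs) {
  if (is.null(strs) || length(strs) == 0L) return(NA_character_)
  letters <- unique(unlist(lapply(strs, function(s) {
    cls <- .pkClassOfPt(parseStructure(s)@pt)
    if (cls == "N") character(0) else strsplit(cls, "")[[1]]
  })))
  if (length(letters) == 0L) "N" else
    paste(.PK_LETTERS[.PK_LETTERS %in% letters], collapse = "")
}

# assemble a BasinHoppingGraph from an LM table, a pair table and witnesses
.assembleBHG <- function(sequence, lmdf, pairTab, edges, witnessOf,
                         variant, mode, p) {
  ord <- order(lmdf$energy, lmdf$structure)
  lmdf <- lmdf[ord, , drop = FALSE]
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  lmdf$id <- sprintf("lm%03d", seq_len(nrow(lmdf)))
  rownames(lmdf) <- NULL
  edf <- data.frame(from = character(0), to = character(0),
                    saddle = numeric(0), pkClass = character(0),
                    stringsAsFactors = FALSE)
  wit <- list()
  if (any(edges)) {
    rows <- which(edges)
    a2 <- remap[pairTab$a[rows]]; b2 <- remap[pairTab$b[rows]]
    fromI <- pmin(a2, b2); toI <- pmax(a2, b2)
    o <- order(fromI, toI)
    rows <- rows[o]; fromI <- fromI[o]; toI <- toI[o]
    S <- round(pairTab$S[rows], 2)
    S <- pmax(S, pmax(lmdf$energy[fromI], lmdf$energy[toI]))
    wpaths <- lapply(seq_along(rows), function(k) {
      w <- witnessOf(pairTab$a[rows[k]], pairTab$b[rows[k]])
      if (!is.null(w) && remap[pairTab$a[rows[k]]] != fromI[k]) w <- rev(w)
      if (!is.null(w)) {
        # a witness must certify the recorded saddle; a direct-contact path
        # that peaks above the edge saddle (possible when connectivity
        # repair kept a pair at its lower minimax value) is dropped
        peak <- max(vapply(w, function(q)
          structureEnergy(sequence, parseStructure(q), p), numeric(1)))
        if (peak > S[k] + 0.005 + .EPS) w <- NULL
      }
      w
    })
    edf <- data.frame(from = lmdf$id[fromI], to = lmdf$id[toI], saddle = S,
                      pkClass = vapply(wpaths, .pathClass, character(1)),
                      stringsAsFactors = FALSE)
    for (k in seq_along(rows))
      if (!is.null(wpaths[[k]]))
        wit[[paste(lmdf$id[fromI[k]], lmdf$id[toI[k]], sep = "|")]] <- wpaths[[k]]
  }
  new("BasinHoppingGraph", sequence = toupper(sequence), lm = lmdf,
      edges = edf, witnesses = wit, variant = variant, mode = mode, params = p)
}

# --------------------------------------------------------------------------
# public builders

#' Build a basin hopping graph
#'
#' Nodes are local minima, edges carry direct saddle heights.  In
#' `"heuristic"` mode, LMs come from `lms` (or from [sampleMinima]), saddles
#' from [estimateSaddle] between candidate pairs (all pairs among the
#' `kLowest` lowest-energy LMs plus each remaining LM's nearest neighbor by
#' base-pair distance), and intermediate LMs discovered during estimation
#' are added to the graph.  In `"exact"` mode the landscape is enumerated
#' within `ceiling` kcal/mol of the MFE and flooded, giving exact basins and
#' saddles.  In both modes an edge is dropped when a third LM routes around
#' it at no extra height (dominated-edge rule), and connectivity implied by
#' the computed saddles is preserved.
#'
#' @param sequence RNA sequence.
#' @param p an [EnergyParams] object.
#' @param mode `"heuristic"` or `"exact"`.
#' @param lms optional LM data.frame (as from [sampleMinima]); must contain
#'   the MFE LM. Required columns: `structure`, `energy`; `count` optional.
#' @param nSamples,seed passed to [sampleMinima] when `lms` is `NULL`
#'   (heuristic mode); `seed` is then required.
#' @param ceiling energy window (kcal/mol above MFE) for sampling or
#'   enumeration.
#' @param width,rounds findpath beam width and splitting recursion depth.
#' @param kLowest all-pairs candidate set size (heuristic mode).
#' @param nestedOnly build over the pseudoknot-free move universe; the
#'   resulting graph has variant `"deg0"` (see [pruneToBHG0] for the pruning
#'   of an existing psi graph).
#' @return a [BasinHoppingGraph] (variant `"psi"` unless `nestedOnly`).
#' @export
buildBHG <- function(sequence, p = energyParams(),
                     mode = c("heuristic", "exact"), lms = NULL,
                     nSamples = 100L, seed = NULL, ceiling = 10,
                     width = 16L, rounds = 3L, kLowest = 50L,
                     nestedOnly = FALSE) {
  mode <- match.arg(mode)
  variant <- if (nestedOnly) "deg0" else "psi"
  if (mode == "exact")
    return(.buildBHGExact(sequence, p, ceiling, nestedOnly, variant))

  if (is.null(lms)) {
    if (is.null(seed)) stop("seed required when lms are sampled internally")
    lms <- sampleMinima(sequence, p, nSamples = nSamples, seed = seed,
                        ceiling = ceiling, nestedOnly = nestedOnly)
  }
  if (is.null(lms$count)) lms$count <- NA_integer_
  lms <- lms[, c("structure", "energy", "count")]
  seqc <- .encodeSeq(sequence)
  parl <- .parList(p)
  pts <- lapply(lms$structure, function(s) parseStructure(s)@pt)
  keys <- vapply(pts, .keyPt, character(1))
  env <- .estCache()
  for (k in seq_along(pts)) {
    env$lmPt[[keys[k]]] <- pts[[k]]
    env$lmE[[keys[k]]] <- lms$energy[k]
  }

  candidatePairs <- function(keys, energies, pts) {
    L <- length(keys)
    low <- order(energies, keys)[seq_len(min(kLowest, L))]
    cand <- list()
    if (length(low) > 1L)
      for (a in seq_along(low)[-length(low)])
        for (b in (a + 1L):length(low))
          cand[[length(cand) + 1L]] <- c(low[a], low[b])
    for (i in setdiff(seq_len(L), low)) {
      d <- vapply(seq_len(L), function(j)
        if (j == i) Inf else .bpDistance(pts[[i]], pts[[j]]), numeric(1))
      j <- which(d == min(d))[1L]
      cand[[length(cand) + 1L]] <- c(min(i, j), max(i, j))
    }
    unique(cand)
  }

  estimateAll <- function(cand) {
    found <- character(0)
    for (cp in cand) {
      res <- .estimatePair(env, seqc, parl, pts[[cp[1]]], pts[[cp[2]]],
                           width, as.integer(rounds), nestedOnly)
      found <- union(found, res$newKeys)
    }
    setdiff(found, keys)
  }

  newKeys <- estimateAll(candidatePairs(keys, lms$energy, pts))
  if (length(newKeys) > 0L) {
    # single admission pass: discovered LMs join the node set and are
    # connected against the low-energy core
    addPts <- lapply(newKeys, function(k) env$lmPt[[k]])
    addE <- vapply(newKeys, function(k) env$lmE[[k]], numeric(1))
    pts <- c(pts, addPts); keys <- c(keys, newKeys)
    lms <- rbind(lms[, c("structure", "energy", "count")],
                 data.frame(structure = vapply(addPts, writeStructure, character(1)),
                            energy = addE, count = NA_integer_,
                            stringsAsFactors = FALSE))
    low <- order(lms$energy, keys)[seq_len(min(kLowest, length(keys)))]
    for (i in (length(keys) - length(newKeys) + 1L):length(keys))
      for (j in setdiff(low, i))
        .estimatePair(env, seqc, parl, pts[[i]], pts[[j]],
                      width, as.integer(rounds), nestedOnly)
  }

  pairTab <- .pairTabFromCache(env, keys)
  edges <- rep(TRUE, nrow(pairTab))
  witnessOf <- function(a, b) {
    pk <- paste(min(keys[a], keys[b]), max(keys[a], keys[b]), sep = "#")
    w <- env$W[[pk]]
    if (is.null(w)) return(NULL)
    out <- vapply(w$path, writeStructure, character(1))
    if (keys[a] > keys[b]) out <- rev(out)
    out
  }
  keep <- .pruneDominated(pairTab, edges, lms$energy)
  lmdf <- data.frame(id = NA_character_, structure = lms$structure,
                     energy = lms$energy,
                     pkClass = vapply(pts, .pkClassOfPt, character(1)),
                     count = lms$count, stringsAsFactors = FALSE)
  .assembleBHG(sequence, lmdf, pairTab, keep, witnessOf, variant,
               "heuristic", p)
}

# pair table (a, b, S with a < b over LM indices) from the estimate cache
.pairTabFromCache <- function(env, keys) {
  idx <- stats::setNames(seq_along(keys), keys)
  a <- integer(0); b <- integer(0); S <- numeric(0)
  for (pk in ls(env$S)) {
    kk <- strsplit(pk, "#", fixed = TRUE)[[1]]
    ia <- idx[kk[1]]; ib <- idx[kk[2]]
    if (is.na(ia) || is.na(ib)) next  # pair involving an unadmitted LM
    a <- c(a, min(ia, ib)); b <- c(b, max(ia, ib)); S <- c(S, env$S[[pk]])
  }
  o <- order(a, b)
  data.frame(a = a[o], b = b[o], S = S[o])
}

# exact-mode builder on top of the flooding oracle
.buildBHGExact <- function(sequence, p, ceiling, nestedOnly, variant) {
  fx <- floodExact(sequence, p, ceiling = ceiling, nestedOnly = nestedOnly)
  L <- nrow(fx$lm)
  a <- integer(0); b <- integer(0); S <- numeric(0); edge <- logical(0)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    mm <- fx$saddles[i, j]
    if (is.na(mm)) next
    a <- c(a, i); b <- c(b, j); S <- c(S, mm)
    edge <- c(edge, !is.na(fx$direct[i, j]) && fx$direct[i, j] <= mm + .EPS)
  }
  pairTab <- data.frame(a = a, b = b, S = S)
  keep <- if (nrow(pairTab) > 0L)
    .pruneDominated(pairTab, edge, fx$lm$energy) else logical(0)
  witnessOf <- function(i, j) fx$witness(i, j)
  lmdf <- data.frame(id = NA_character_, structure = fx$lm$structure,
                     energy = fx$lm$energy, pkClass = fx$lm$pkClass,
                     count = fx$lm$basinSize, stringsAsFactors = FALSE)
  .assembleBHG(sequence, lmdf, pairTab, keep, witnessOf, variant, "exact", p)
}

#' Exhaustively flood a landscape (exact oracle)
#'
#' Enumerates every 1-structure within `ceiling` kcal/mol of the MFE and
#' processes structures by increasing energy: gradient basins are assigned
#' by memoized descent, and a union-find merge records the exact minimal
#' saddle height for every pair of local minima (a minimax, hence
#' ultrametric-compatible, matrix), together with the barrier tree of
#' merge events.
#'
#' @param sequence RNA sequence (guarded length, see [enumerateEnsemble]).
#' @param p an [EnergyParams] object.
#' @param ceiling energy window (kcal/mol above MFE); pairs whose exact
#'   saddle exceeds the window remain `NA`.
#' @param nestedOnly restrict to pseudoknot-free structures.
#' @return list with:
#'   `lm` (data.frame: `id`, `structure`, `energy`, `pkClass`, `basinSize`,
#'   ordered by energy),
#'   `saddles` (exact minimax saddle matrix, `lm$id` dimnames),
#'   `direct` (direct saddle between gradient-adjacent basins, else `NA`),
#'   `tree` (barrier-tree merge list: `height`, `lmA`, `lmB`),
#'   `basin` (basin id per enumerated structure),
#'   `ensemble` (the [EnsembleIndex]),
#'   `witness(i, j)` (function returning a direct witness path, dot-bracket,
#'   for gradient-adjacent basin pairs, else `NULL`).
#' @export
floodExact <- function(sequence, p = energyParams(), ceiling = 10,
                       nestedOnly = FALSE) {
  ens <- enumerateEnsemble(sequence, p, ceiling = ceiling,
                           nestedOnly = nestedOnly)
  seqc <- .encodeSeq(sequence)
  parl <- .parList(p)
  fl <- .cpp_flood(seqc, ens@pt, ens@energy, parl, nestedOnly)
  L <- length(fl$lm)
  # order LMs by (energy, structure) and remap all outputs
  lmE <- ens@energy[fl$lm]
  lmStr <- vapply(fl$lm, function(s) writeStructure(ens@pt[s, ]), character(1))
  ord <- order(lmE, lmStr)
  remap <- integer(L); remap[ord] <- seq_len(L)
  ids <- sprintf("lm%03d", seq_len(L))
  lm <- data.frame(id = ids, structure = lmStr[ord], energy = lmE[ord],
                   pkClass = vapply(fl$lm[ord], function(s)
                     .pkClassOfPt(ens@pt[s, ]), character(1)),
                   basinSize = as.integer(tabulate(fl$basin, L))[ord],
                   stringsAsFactors = FALSE)
  perm <- ord  # new position k holds old LM index perm[k]
  saddles <- fl$minimax[perm, perm, drop = FALSE]
  direct <- fl$direct[perm, perm, drop = FALSE]
  dA <- fl$directA[perm, perm, drop = FALSE]
  dB <- fl$directB[perm, perm, drop = FALSE]
  dimnames(saddles) <- dimnames(direct) <- list(ids, ids)
  tree <- data.frame(height = fl$merges$height,
                     lmA = ids[remap[fl$merges$lm_a]],
                     lmB = ids[remap[fl$merges$lm_b]],
                     stringsAsFactors = FALSE)
  witness <- function(i, j) {
    if (is.na(dA[i, j])) return(NULL)
    wa <- .cpp_gradient_walk(seqc, ens@pt[dA[i, j], ], parl, nestedOnly)
    wb <- .cpp_gradient_walk(seqc, ens@pt[dB[i, j], ], parl, nestedOnly)
    # orientation: dA's descent must end in LM i
    ptsPath <- c(rev(wa$path), wb$path)
    if (.keyPt(wa$path[[length(wa$path)]]) !=
        .keyPt(ens@pt[fl$lm[perm[i]], ]))
      ptsPath <- rev(ptsPath)
    vapply(ptsPath, writeStructure, character(1))
  }
  list(lm = lm, saddles = saddles, direct = direct, tree = tree,
       basin = remap[fl$basin], ensemble = ens, witness = witness)
}

#' Prune a BHG-psi to the pseudoknot-free BHG-0
#'
#' Removes all pseudoknotted local minima and recomputes every adjacency
#' with the move universe restricted to pseudoknot-free structures.  The
#' re-evaluation can remove edges (when the only low route was
#' pseudoknotted) and generally raises saddle heights.
#'
#' @param bhg a variant-`"psi"` [BasinHoppingGraph].
#' @param ceiling energy window used for exact-mode re-flooding.
#' @param width,rounds findpath parameters for heuristic-mode
#'   re-estimation.
#' @return a [BasinHoppingGraph] with variant `"deg0"` over the
#'   pseudoknot-free LMs of `bhg`.
#' @export
pruneToBHG0 <- function(bhg, ceiling = 10, width = 16L, rounds = 3L) {
  if (bhg@variant != "psi") stop("expected a variant-'psi' graph")
  keepLM <- bhg@lm$pkClass == "N"
  lms <- bhg@lm[keepLM, , drop = FALSE]
  if (nrow(lms) == 0L) stop("no pseudoknot-free LMs to retain")
  sequence <- bhg@sequence
  p <- bhg@params
  if (bhg@mode == "exact") {
    fx <- floodExact(sequence, p, ceiling = ceiling, nestedOnly = TRUE)
    at <- match(lms$structure, fx$lm$structure)
    if (anyNA(at))
      stop("a pseudoknot-free LM is missing from the nested flooding window")
    L <- length(at)
    a <- integer(0); b <- integer(0); S <- numeric(0); edge <- logical(0)
    if (L > 1L) for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
      mm <- fx$saddles[at[i], at[j]]
      if (is.na(mm)) next
      a <- c(a, i); b <- c(b, j); S <- c(S, mm)
      edge <- c(edge, !is.na(fx$direct[at[i], at[j]]) &&
                  fx$direct[at[i], at[j]] <= mm + .EPS)
    }
    pairTab <- data.frame(a = a, b = b, S = S)
    keep <- if (nrow(pairTab) > 0L)
      .pruneDominated(pairTab, edge, lms$energy) else logical(0)
    witnessOf <- function(i, j) fx$witness(at[i], at[j])
    lmdf <- data.frame(id = NA_character_, structure = lms$structure,
                       energy = lms$energy, pkClass = lms$pkClass,
                       count = lms$count, stringsAsFactors = FALSE)
    return(.assembleBHG(sequence, lmdf, pairTab, keep, witnessOf, "deg0",
                        "exact", p))
  }
  # heuristic mode: re-estimate all retained pairs over nested moves
  seqc <- .encodeSeq(sequence)
  parl <- .parList(p)
  pts <- lapply(lms$structure, function(s) parseStructure(s)@pt)
  keys <- vapply(pts, .keyPt, character(1))
  env <- .estCache()
  for (k in seq_along(pts)) {
    env$lmPt[[keys[k]]] <- pts[[k]]
    env$lmE[[keys[k]]] <- lms$energy[k]
  }
  L <- length(pts)
  if (L > 1L) for (i in seq_len(L - 1L)) for (j in (i + 1L):L)
    .estimatePair(env, seqc, parl, pts[[i]], pts[[j]], width,
                  as.integer(rounds), TRUE)
  pairTab <- .pairTabFromCache(env, keys)
  keep <- .pruneDominated(pairTab, rep(TRUE, nrow(pairTab)), lms$energy)
  witnessOf <- function(a, b) {
    pk <- paste(min(keys[a], keys[b]), max(keys[a], keys[b]), sep = "#")
    w <- env$W[[pk]]
    if (is.null(w)) return(NULL)
    out <- vapply(w$path, writeStructure, character(1))
    if (keys[a] > keys[b]) out <- rev(out)
    out
  }
  lmdf <- data.frame(id = NA_character_, structure = lms$structure,
                     energy = lms$energy, pkClass = lms$pkClass,
                     count = lms$count, stringsAsFactors = FALSE)
  .assembleBHG(sequence, lmdf, pairTab, keep, witnessOf, "deg0",
               "heuristic", p)
}

# --------------------------------------------------------------------------
# saddle queries and comparison

# minimax saddle between two LM ids over the graph's edges; NA if
# disconnected; also returns the bottleneck path (LM ids) when asked
.graphMinimax <- function(bhg, from, to, withPath = FALSE) {
  ids <- bhg@lm$id
  i <- match(from, ids); j <- match(to, ids)
  if (is.na(i) || is.na(j)) stop("unknown LM id")
  if (i == j)
    return(if (withPath) list(S = bhg@lm$energy[i], path = from)
           else bhg@lm$energy[i])
  ed <- bhg@edges
  if (nrow(ed) == 0L) return(if (withPath) list(S = NA_real_, path = NULL) else NA_real_)
  o <- order(ed$saddle, ed$from, ed$to)
  uf <- .ufNew(length(ids))
  S <- NA_real_; cut <- 0L
  for (r in o) {
    ra <- .ufFind(uf, match(ed$from[r], ids))
    rb <- .ufFind(uf, match(ed$to[r], ids))
    if (ra != rb) uf[ra] <- rb
    if (.ufFind(uf, i) == .ufFind(uf, j)) { S <- ed$saddle[r]; cut <- r; break }
  }
  if (!withPath) return(S)
  if (is.na(S)) return(list(S = NA_real_, path = NULL))
  # path over edges with saddle <= S
  sub <- ed[ed$saddle <= S + .EPS, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  vp <- igraph::shortest_paths(g, from = from, to = to, output = "vpath")
  list(S = S, path = names(vp$vpath[[1]]))
}

#' Minimax saddle height between two LMs of a BHG
#'
#' The lowest possible peak over all graph paths between two local minima,
#' taking each edge at its saddle height.
#'
#' @param bhg a [BasinHoppingGraph].
#' @param from,to LM ids (see [lmTable]).
#' @return saddle height in kcal/mol; `NA` if the LMs are disconnected.
#' @export
bhgSaddle <- function(bhg, from, to) .graphMinimax(bhg, from, to)

#' Compare saddle heights between BHG-psi and BHG-0
#'
#' For every pair of pseudoknot-free local minima present in both graphs,
#' reports the psi and pruned saddle heights (graph minimax), their
#' difference, and the composite pseudoknot class seen along the psi
#' bottleneck route.
#'
#' @param bhgPsi variant-`"psi"` [BasinHoppingGraph].
#' @param bhg0 variant-`"deg0"` graph over (a subset of) the same LMs.
#' @return data.frame with columns `lmPsiA`, `lmPsiB` (psi-graph ids),
#'   `structureA`, `structureB`, `sPsi`, `sDeg0`, `deltaAbs`
#'   (`sDeg0 - sPsi`, kcal/mol), `deltaPct`, `pkClass` (classes on the psi
#'   route, `N` if none).
#' @export
compareSaddles <- function(bhgPsi, bhg0) {
  if (bhgPsi@variant != "psi" || bhg0@variant != "deg0")
    stop("expected a psi graph and a deg0 graph")
  common <- intersect(bhgPsi@lm$structure[bhgPsi@lm$pkClass == "N"],
                      bhg0@lm$structure)
  out <- NULL
  if (length(common) >= 2L) {
    for (u in seq_along(common)[-length(common)]) {
      for (v in (u + 1L):length(common)) {
        idA <- bhgPsi@lm$id[match(common[u], bhgPsi@lm$structure)]
        idB <- bhgPsi@lm$id[match(common[v], bhgPsi@lm$structure)]
        id0A <- bhg0@lm$id[match(common[u], bhg0@lm$structure)]
        id0B <- bhg0@lm$id[match(common[v], bhg0@lm$structure)]
        mmP <- .graphMinimax(bhgPsi, idA, idB, withPath = TRUE)
        mm0 <- .graphMinimax(bhg0, id0A, id0B)
        if (is.na(mmP$S) || is.na(mm0)) next
        cls <- "N"
        if (length(mmP$path) > 1L) {
          steps <- cbind(mmP$path[-length(mmP$path)], mmP$path[-1L])
          letters <- unique(unlist(lapply(seq_len(nrow(steps)), function(r) {
            ed <- bhgPsi@edges
            hit <- which((ed$from == steps[r, 1] & ed$to == steps[r, 2]) |
                           (ed$from == steps[r, 2] & ed$to == steps[r, 1]))
            cl <- ed$pkClass[hit[1]]
            if (is.na(cl) || cl == "N") character(0) else strsplit(cl, "")[[1]]
          })))
          # route classes also include the visited LMs themselves
          lmCls <- bhgPsi@lm$pkClass[match(mmP$path, bhgPsi@lm$id)]
          letters <- unique(c(letters,
                              unlist(strsplit(lmCls[lmCls != "N"], ""))))
          if (length(letters) > 0L)
            cls <- paste(.PK_LETTERS[.PK_LETTERS %in% letters], collapse = "")
        }
        out <- rbind(out, data.frame(
          lmPsiA = idA, lmPsiB = idB,
          structureA = common[u], structureB = common[v],
          sPsi = mmP$S, sDeg0 = mm0, deltaAbs = mm0 - mmP$S,
          deltaPct = 100 * (mm0 - mmP$S) / abs(mm0),
          pkClass = cls, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(lmPsiA = character(0), lmPsiB = character(0),
                      structureA = character(0), structureB = character(0),
                      sPsi = numeric(0), sDeg0 = numeric(0),
                      deltaAbs = numeric(0), deltaPct = numeric(0),
                      pkClass = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
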