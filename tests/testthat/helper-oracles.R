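# Independent oracles used to validate package results.  Everything here is
# implemented from first principles in plain R, without calling the package
# functions under test (the permutation-cycle genus, the brute-force move
# set, the additive energy model, minimax saddles by edge sweep, and the
# closed-form two-state kinetics).

# --- genus by permutation cycles -------------------------------------------
# For a chord diagram, the number of boundary components of the fattened
# one-vertex ribbon graph equals the number of cycles of sigma o alpha,
# where sigma is the backbone cycle (1 2 ... 2m) and alpha the chord
# involution; then g = (m - b + 1) / 2.
oracleGenus <- function(chords) {
  chords <- matrix(as.integer(chords), ncol = 2L)
  m <- nrow(chords)
  if (m == 0L) return(0L)
  pts <- sort(as.vector(chords))
  stopifnot(!anyDuplicated(pts))
  rk <- function(x) match(x, pts)
  alpha <- integer(2L * m)
  for (r in seq_len(m)) {
    i <- rk(chords[r, 1]); j <- rk(chords[r, 2])
    alpha[i] <- j; alpha[j] <- i
  }
  sigma <- c(seq_len(2L * m - 1L) + 1L, 1L)
  gamma <- sigma[alpha]
  seen <- rep(FALSE, 2L * m)
  b <- 0L
  for (s in seq_len(2L * m)) {
    if (seen[s]) next
    b <- b + 1L
    x <- s
    while (!seen[x]) { seen[x] <- TRUE; x <- gamma[x] }
  }
  as.integer((m - b + 1L) / 2L)
}

# --- structure parsing (own tiny multi-page parser) ------------------------
oraclePairTable <- function(text) {
  pages <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  chars <- strsplit(text, "")[[1]]
  pt <- integer(length(chars))
  for (pg in pages) {
    stack <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == pg[1]) stack <- c(stack, i)
      else if (chars[i] == pg[2]) {
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        pt[i] <- j; pt[j] <- i
      }
    }
    stopifnot(length(stack) == 0L)
  }
  pt
}

# helices (maximal stacks) of a pair table: matrix of outer pairs + length
oracleHelices <- function(pt) {
  n <- length(pt)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- pt[i]
    if (j > i) {
      len <- 1L
      while (i + len <= n && pt[i + len] == j - len && j - len > i + len)
        len <- len + 1L
      out <- rbind(out, c(i, j, len))
      i <- i + len
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(0), ncol = 3L) else out
}

.oracleCross <- function(h) {
  m <- nrow(h)
  X <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
    X[a, b] <- (h[a, 1] < h[b, 1] && h[b, 1] < h[a, 2] && h[a, 2] < h[b, 2]) ||
      (h[b, 1] < h[a, 1] && h[a, 1] < h[b, 2] && h[b, 2] < h[a, 2])
  X
}

# pseudoknot class letters of a pair table: collapse each crossing component
# to its shadow, then identify the pattern by crossing-graph shape
oracleClasses <- function(pt) {
  h <- oracleHelices(pt)
  m <- nrow(h)
  if (m == 0L) return(character(0))
  X <- .oracleCross(h)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m)) for (b in seq_len(m))
      if (X[a, b] && comp[b] != comp[a]) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    if (!changed) break
  }
  out <- character(0)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2L) next
    ch <- h[idx, 1:2, drop = FALSE]
    # collapse nested chords with identical crossing sets
    repeat {
      k <- nrow(ch)
      Xc <- .oracleCross(cbind(ch, 0L))
      drop <- NA_integer_
      for (a in seq_len(k)) for (b in seq_len(k)) {
        if (a == b || !is.na(drop)) next
        if (ch[a, 1] < ch[b, 1] && ch[b, 2] < ch[a, 2] &&
            identical(Xc[a, -c(a, b)], Xc[b, -c(a, b)]))
          drop <- b
      }
      if (is.na(drop)) break
      ch <- ch[-drop, , drop = FALSE]
    }
    k <- nrow(ch)
    Xc <- .oracleCross(cbind(ch, 0L))
    ecount <- sum(Xc) / 2L
    if (oracleGenus(ch) != 1L) { out <- c(out, "?"); next }
    cls <- if (k == 2L && ecount == 1L) "H"
      else if (k == 3L && ecount == 2L) "K"
      else if (k == 3L && ecount == 3L) "L"
      else if (k == 4L && ecount == 5L) "M"
      else "?"
    out <- c(out, cls)
  }
  sort(unique(out))
}

# --- energy model ----------------------------------------------------------
oracleEnergy <- function(sequence, text, p) {
  pt <- oraclePairTable(text)
  res <- strsplit(toupper(sequence), "")[[1]]
  h <- oracleHelices(pt)
  pairType <- function(i, j) paste0(res[i], res[j])
  e <- 0
  for (r in seq_len(nrow(h))) {
    e <- e + p@helixEnd
    if (h[r, 3] > 1L) for (t in 0:(h[r, 3] - 2L)) {
      outer <- pairType(h[r, 1] + t, h[r, 2] - t)
      inner <- pairType(h[r, 1] + t + 1L, h[r, 2] - t - 1L)
      e <- e + p@stack[outer, inner]
    }
  }
  for (cls in oracleClasses(pt)) {
    stopifnot(cls %in% c("H", "K", "L", "M"))
    e <- e + p@beta[[cls]]
  }
  e
}

# --- move set --------------------------------------------------------------
# brute-force single-pair neighbors as pair tables (keys for set comparison)
oracleNeighborKeys <- function(pt, sequence, nestedOnly = FALSE) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  ok1 <- function(q) {
    h <- oracleHelices(q)
    X <- .oracleCross(h)
    if (nestedOnly && any(X)) return(FALSE)
    comp <- seq_len(nrow(h))
    repeat {
      changed <- FALSE
      for (a in seq_len(nrow(h))) for (b in seq_len(nrow(h)))
        if (X[a, b] && comp[b] != comp[a]) {
          comp[comp == comp[b]] <- comp[a]; changed <- TRUE
        }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (length(idx) > 1L &&
          oracleGenus(h[idx, 1:2, drop = FALSE]) != 1L) return(FALSE)
    }
    TRUE
  }
  keys <- character(0)
  for (i in seq_len(n)) if (pt[i] > i) {       # removals
    q <- pt; q[i] <- 0L; q[pt[i]] <- 0L
    keys <- c(keys, paste(q, collapse = ","))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {  # additions
    if (j - i < 4L || pt[i] != 0L || pt[j] != 0L) next
    if (!(paste0(res[i], res[j]) %in% canonical)) next
    q <- pt; q[i] <- j; q[j] <- i
    if (ok1(q)) keys <- c(keys, paste(q, collapse = ","))
  }
  sort(keys)
}

# --- graph minimax saddle by edge sweep ------------------------------------
oracleMinimax <- function(edges, from, to, ids) {
  o <- order(edges$saddle)
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in o) {
    ra <- find(edges$from[r]); rb <- find(edges$to[r])
    if (ra != rb) parent[[ra]] <- rb
    if (find(from) == find(to)) return(edges$saddle[r])
  }
  NA_real_
}

# --- closed-form two-state relaxation --------------------------------------
# generator rows: state1 -> state2 at rate a, state2 -> state1 at rate b
oracleTwoState <- function(a, b, p1_0, times) {
  pi1 <- b / (a + b)
  pi1 + (p1_0 - pi1) * exp(-(a + b) * times)
}
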