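# Structure parsing, helix decomposition, conflict graphs, genus and
# pseudoknot classification.

#' Parse extended dot-bracket notation
#'
#' Pseudoknotted structures are written with several bracket "pages":
#' `()`, `[]`, `{}` and `<>`; dots mark unpaired positions.
#'
#' @param text dot-bracket string.
#' @param n expected sequence length (defaults to `nchar(text)`).
#' @return an [RNAStructure].
#' @examples
#' parseStructure("((((....))))")
#' parseStructure("((..[[.))..]]")
#' @export
parseStructure <- function(text, n = nchar(text)) {
  if (nchar(text) != n)
    stop("structure string has length ", nchar(text), ", expected ", n)
  chars <- strsplit(text, "")[[1]]
  pt <- integer(n)
  for (page in .BRACKETS) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (chars[i] == page[1]) {
        stack <- c(stack, i)
      } else if (chars[i] == page[2]) {
        if (length(stack) == 0L)
          stop("unbalanced '", page[2], "' at position ", i)
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pt[i] <- j; pt[j] <- i
      }
    }
    if (length(stack) > 0L)
      stop("unbalanced '", page[1], "' at position ", stack[length(stack)])
  }
  known <- c(".", unlist(.BRACKETS))
  bad <- setdiff(unique(chars), known)
  if (length(bad) > 0L)
    stop("unknown structure characters: ", paste(bad, collapse = " "))
  .fromPt(pt)  # validity enforces hairpin + 1-structure constraints
}

#' Write a structure in extended dot-bracket notation
#'
#' Bracket pages are assigned per helix by a minimal coloring of the helix
#' crossing graph (pages in the fixed order `()`, `[]`, `{}`, `<>`), so
#' pseudoknot-free structures always use a single page and H/K/M-type
#' components use two.
#'
#' @param s an [RNAStructure].
#' @param n sequence length (defaults to the structure's own length).
#' @return a dot-bracket string; `parseStructure(writeStructure(s))`
#'   recovers `s`.
#' @export
writeStructure <- function(s, n = length(s)) {
  pt <- if (is(s, "RNAStructure")) s@pt else as.integer(s)
  if (length(pt) != n) stop("length mismatch")
  hx <- .cpp_helices(pt)
  out <- rep(".", n)
  if (nrow(hx) == 0L) return(paste(out, collapse = ""))
  comp <- .cpp_components(pt)$component
  page <- .colorHelices(hx, comp)
  if (max(page) > length(.BRACKETS))
    stop("structure needs more than ", length(.BRACKETS),
         " bracket pages; not a 1-structure?")
  for (h in seq_len(nrow(hx))) {
    br <- .BRACKETS[[page[h]]]
    for (t in 0:(hx[h, "length"] - 1L)) {
      out[hx[h, "i"] + t] <- br[1]
      out[hx[h, "j"] - t] <- br[2]
    }
  }
  paste(out, collapse = "")
}

# minimal, deterministic page assignment: per crossing component, try the
# smallest number of colors (1, 2, 3, ...) by exhaustive assignment in helix
# order; helices that cross must differ.
.colorHelices <- function(hx, comp) {
  m <- nrow(hx)
  cross <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a < b && comp[a] == comp[b]) {
      i1 <- hx[a, "i"]; j1 <- hx[a, "j"]; i2 <- hx[b, "i"]; j2 <- hx[b, "j"]
      if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp; tmp <- j1; j1 <- j2; j2 <- tmp }
      cross[a, b] <- cross[b, a] <- (i2 < j1 && j1 < j2)
    }
  }
  page <- integer(m)
  for (cc in sort(unique(comp))) {
    idx <- which(comp == cc)
    for (k in 1:4) {
      col <- .tryColor(cross[idx, idx, drop = FALSE], k)
      if (!is.null(col)) { page[idx] <- col; break }
      if (k == 4L) stop("helix crossing graph needs more than 4 pages")
    }
  }
  page
}

.tryColor <- function(adj, k) {
  m <- nrow(adj)
  col <- integer(m)
  rec <- function(v) {
    if (v > m) return(TRUE)
    for (cl in 1:k) {
      if (any(adj[v, seq_len(v - 1L)] & col[seq_len(v - 1L)] == cl)) next
      col[v] <<- cl
      if (rec(v + 1L)) return(TRUE)
    }
    col[v] <<- 0L
    FALSE
  }
  if (m == 0L) return(integer(0))
  if (rec(1L)) col else NULL
}

#' Decompose a structure into helices
#'
#' A helix is a maximal run of consecutively stacked pairs
#' `(i, j), (i+1, j-1), ...`.  The field notation `h_i^j` names a helix by
#' its outermost pair.
#'
#' @param s an [RNAStructure].
#' @return data.frame with columns `i`, `j` (outermost pair), `length`
#'   (number of stacked pairs) and `name` (`h<i>_<j>`), ordered by `i`.
#' @export
decomposeHelices <- function(s) {
  hx <- as.data.frame(.cpp_helices(s@pt))
  hx$name <- sprintf("h%d_%d", hx$i, hx$j)
  hx
}

#' Helix conflict graph
#'
#' Vertices are the helices of the structure; an edge connects two helices
#' whenever they cross (their outermost pairs interleave).  A structure is a
#' 1-structure exactly when every connected component of this graph, taken
#' as a chord diagram with one chord per helix, has genus 1.
#'
#' @param s an [RNAStructure].
#' @return an [igraph::igraph] with vertex attributes `i`, `j`, `length` and
#'   `component`.
#' @export
conflictGraph <- function(s) {
  hx <- decomposeHelices(s)
  comp <- .cpp_components(s@pt)
  g <- igraph::make_empty_graph(n = nrow(hx), directed = FALSE)
  if (nrow(hx) > 0L) {
    igraph::V(g)$name <- hx$name
    igraph::V(g)$i <- hx$i
    igraph::V(g)$j <- hx$j
    igraph::V(g)$length <- hx$length
    igraph::V(g)$component <- comp$component
    el <- NULL
    for (a in seq_len(nrow(hx))) for (b in seq_len(nrow(hx))) {
      if (a < b && comp$component[a] == comp$component[b]) {
        i1 <- hx$i[a]; j1 <- hx$j[a]; i2 <- hx$i[b]; j2 <- hx$j[b]
        lo <- min(i1, i2); hi <- if (lo == i1) i2 else i1
        jlo <- if (lo == i1) j1 else j2; jhi <- if (lo == i1) j2 else j1
        if (hi < jlo && jlo < jhi) el <- rbind(el, c(a, b))
      }
    }
    if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  }
  g
}

#' Topological genus of a chord diagram
#'
#' The backbone with the base pairs drawn as chords is fattened into a
#' ribbon graph; tracing its boundary components `b` gives the genus
#' `g = (c - b + 1) / 2` for `c` chords.  Nested structures have genus 0;
#' each elementary pseudoknot component (H, K, L or M type) has genus 1.
#'
#' @param x an [RNAStructure] or a two-column matrix of chords `(i, j)`.
#' @return nonnegative integer genus.
#' @examples
#' genus(parseStructure("((((....))))"))        # 0
#' genus(cbind(c(1, 2), c(3, 4)))               # H pattern: 1
#' @export
genus <- function(x) {
  pairs <- if (is(x, "RNAStructure")) basePairs(x) else {
    m <- matrix(as.integer(x), ncol = 2L)
    t(apply(m, 1L, sort))
  }
  if (NROW(pairs) == 0L) return(0L)
  if (anyDuplicated(as.vector(pairs)) > 0L) stop("chord endpoints must be distinct")
  .cpp_genus(matrix(as.integer(pairs), ncol = 2L))
}

#' Test membership in the 1-structure class
#'
#' TRUE iff every connected component of the helix conflict graph, reduced
#' to one chord per helix, has genus exactly 1 (isolated helices are always
#' allowed).
#'
#' @param x an [RNAStructure] or a two-column matrix of pairs.
#' @export
isOneStructure <- function(x) {
  pt <- if (is(x, "RNAStructure")) x@pt else {
    m <- matrix(as.integer(x), ncol = 2L)
    n <- max(m)
    pt <- integer(n)
    for (k in seq_len(nrow(m))) {
      i <- min(m[k, ]); j <- max(m[k, ])
      if (pt[i] != 0L || pt[j] != 0L) stop("position paired twice")
      pt[i] <- j; pt[j] <- i
    }
    pt
  }
  .cpp_is_one_structure(pt)
}

#' Classify the pseudoknot type of a 1-structure
#'
#' Each crossing component is matched, on its shadow (one chord per helix,
#' parallel chords collapsed), against the four genus-1 patterns: H (two
#' crossing helices), K (kissing hairpin, crossing path of three), L
#' (three mutually crossing helices) and M (the unique four-chord genus-1
#' shadow, word ABCADBCD).  The
#' composite label lists the types appearing, in the order H, K, L, M;
#' pseudoknot-free structures are labelled `N`.
#'
#' @param s an [RNAStructure].
#' @return single character label, e.g. `"N"`, `"H"`, `"K"`, `"HK"`.
#' @export
classifyPK <- function(s) {
  cls <- .cpp_components(s@pt)$class
  if (any(cls < 0L))
    stop("component matches no genus-1 pattern; not a 1-structure")
  pk <- sort(unique(cls[cls > 0L]))
  if (length(pk) == 0L) "N" else paste(.PK_LETTERS[pk], collapse = "")
}

# component classes as letters (internal)
.pkClassOfPt <- function(pt) {
  cls <- .cpp_components(pt)$class
  pk <- sort(unique(cls[cls > 0L]))
  if (length(pk) == 0L) "N" else paste(.PK_LETTERS[pk], collapse = "")
}

#' Minimal chord diagram of a basic pseudoknot type
#'
#' The smallest crossing chord diagram realizing each of the four genus-1
#' pseudoknot patterns: H (two crossing chords, word ABAB), K (kissing
#' hairpin, crossing path of three, ABACBC), L (three mutually crossing
#' chords, ABCABC) and M (the unique four-chord genus-1 shadow, ABCADBCD).
#'
#' @param type one of `"H"`, `"K"`, `"L"`, `"M"`.
#' @return a two-column integer matrix of chords `(i, j)`, suitable for
#'   [genus()].
#' @examples
#' genus(minimalDiagram("K"))  # 1
#' @export
minimalDiagram <- function(type = c("H", "K", "L", "M")) {
  type <- match.arg(type)
  switch(type,
         H = cbind(c(1L, 2L), c(3L, 4L)),
         K = cbind(c(1L, 2L, 4L), c(3L, 5L, 6L)),
         L = cbind(c(1L, 2L, 3L), c(4L, 5L, 6L)),
         M = cbind(c(1L, 2L, 3L, 5L), c(4L, 6L, 7L, 8L)))
}

# letter word of a chord diagram: letters in order of first appearance
.chordWord <- function(ch) {
  n <- 2L * nrow(ch)
  lab <- integer(n)
  for (r in seq_len(nrow(ch))) lab[ch[r, ]] <- r
  paste(LETTERS[match(lab, unique(lab))], collapse = "")
}

#' Exhaustively enumerate irreducible chord-diagram shadows
#'
#' Generates every chord diagram (perfect matching of `2m` backbone points)
#' for `m = 2, ..., maxChords` and keeps the irreducible shadows: diagrams
#' whose crossing graph is connected and which contain no nested chord pair
#' with identical crossing sets (such a pair would collapse under the
#' helix-shadow reduction).  Each surviving diagram is reported with its
#' boundary-tracing [genus()] and, for genus-1 diagrams, its pattern class
#' from the same classifier used on structures.  Runs in well under a minute
#' for the default bound; genus-1 shadows can have at most four chords, so
#' the default bound of six demonstrates completeness with margin.
#'
#' @param maxChords largest number of chords to enumerate (default 6).
#' @return data frame with columns `chords` (count), `word` (letter word,
#'   e.g. `"ABAB"`), `genus`, and `class` (`"H"`, `"K"`, `"L"`, `"M"` for
#'   genus-1 diagrams, `NA` otherwise), ordered by `chords` then `word`.
#' @export
enumerateShadows <- function(maxChords = 6L) {
  if (maxChords < 2L) stop("maxChords must be at least 2")
  matchings <- function(pts) {
    if (length(pts) == 0L) return(list(NULL))
    out <- list()
    for (k in seq_along(pts)[-1L]) {
      for (rest in matchings(pts[-c(1L, k)]))
        out[[length(out) + 1L]] <- rbind(c(pts[1L], pts[k]), rest)
    }
    out
  }
  rows <- list()
  for (m in 2:maxChords) {
    for (ch in matchings(seq_len(2L * m))) {
      X <- matrix(FALSE, m, m)
      for (a in seq_len(m)) for (b in seq_len(m)) if (a != b) {
        i1 <- ch[a, 1]; j1 <- ch[a, 2]; i2 <- ch[b, 1]; j2 <- ch[b, 2]
        X[a, b] <- (i1 < i2 && i2 < j1 && j1 < j2) ||
          (i2 < i1 && i1 < j2 && j2 < j1)
      }
      # crossing graph connected?
      seen <- 1L; front <- 1L
      while (length(front) > 0L) {
        nb <- setdiff(which(apply(X[front, , drop = FALSE], 2L, any)), seen)
        seen <- c(seen, nb); front <- nb
      }
      if (length(seen) != m) next
      # shadow: no nested pair with identical crossing sets
      shadow <- TRUE
      for (a in seq_len(m)) for (b in seq_len(m)) {
        if (a == b) next
        if (ch[a, 1] < ch[b, 1] && ch[b, 2] < ch[a, 2] &&
            identical(X[a, -c(a, b)], X[b, -c(a, b)])) {
          shadow <- FALSE; break
        }
      }
      if (!shadow) next
      g <- genus(ch)
      cls <- NA_character_
      if (g == 1L) {
        pt <- integer(2L * m)
        for (r in seq_len(m)) {
          pt[ch[r, 1]] <- ch[r, 2]; pt[ch[r, 2]] <- ch[r, 1]
        }
        cls <- .pkClassOfPt(pt)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chords = m, word = .chordWord(ch), genus = g, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chords, out$word), , drop = FALSE]
}
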