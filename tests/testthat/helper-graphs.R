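# Synthetic basin hopping graphs and brute-force path utilities shared by
# the path and acceptance tests.

# two disconnected components
.twoIslandBHG <- function() {
  n <- 20L
  mk <- function(k) paste0(strrep(".", k - 1L), "((((.....))))",
                           strrep(".", n - 12L - k))
  lm <- data.frame(id = sprintf("lm%03d", 1:4),
                   structure = vapply(1:4, mk, character(1)),
                   energy = c(-5, -4, -3, -2), pkClass = "N",
                   count = NA_integer_, stringsAsFactors = FALSE)
  edges <- data.frame(from = c("lm001", "lm003"), to = c("lm002", "lm004"),
                      saddle = c(-1, 0.5), pkClass = NA_character_,
                      stringsAsFactors = FALSE)
  new("BasinHoppingGraph", sequence = strrep("A", n + 13L), lm = lm,
      edges = edges, witnesses = list(), variant = "psi",
      mode = "heuristic", params = energyParams())
}

# two competing routes between lm001 and lm004: a low-peak long way around
# and a high-peak short cut through lm005
.forkBHG <- function() {
  n <- 24L
  mk <- function(k) paste0(strrep(".", k - 1L), "((((.....))))",
                           strrep(".", n - 12L - k))
  lm <- data.frame(id = sprintf("lm%03d", 1:5),
                   structure = vapply(1:5, mk, character(1)),
                   energy = c(-6, -5.5, -3, -5, -1.2), pkClass = "N",
                   count = NA_integer_, stringsAsFactors = FALSE)
  edges <- data.frame(
    from   = c("lm001", "lm002", "lm003", "lm001", "lm005"),
    to     = c("lm002", "lm003", "lm004", "lm005", "lm004"),
    saddle = c(-2,      -1,      -0.5,    1.8,     2.2),
    pkClass = NA_character_, stringsAsFactors = FALSE)
  new("BasinHoppingGraph", sequence = strrep("A", n + 13L), lm = lm,
      edges = edges, witnesses = list(), variant = "psi",
      mode = "heuristic", params = energyParams())
}

# brute-force enumeration of all simple paths (as id vectors)
.allPaths <- function(bhg, from, to) {
  ed <- edgeTable(bhg)
  adj <- list()
  for (r in seq_len(nrow(ed))) {
    adj[[ed$from[r]]] <- c(adj[[ed$from[r]]], ed$to[r])
    adj[[ed$to[r]]] <- c(adj[[ed$to[r]]], ed$from[r])
  }
  out <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == to) { out[[length(out) + 1L]] <<- path; return(invisible(NULL)) }
    for (nb in adj[[last]]) if (!nb %in% path) rec(c(path, nb))
  }
  rec(from)
  out
}

# peak and accumulated activation energy of an id path
.pathStats <- function(bhg, path) {
  ed <- edgeTable(bhg); lm <- lmTable(bhg)
  sad <- vapply(seq_len(length(path) - 1L), function(i) {
    hit <- which((ed$from == path[i] & ed$to == path[i + 1L]) |
                   (ed$from == path[i + 1L] & ed$to == path[i]))
    ed$saddle[hit[1]]
  }, numeric(1))
  list(peak = max(sad),
       activation = sum(sad - lm$energy[match(path[-length(path)], lm$id)]))
}
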