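# File input/output: sequences, structure lists, run configuration,
# BHG serialization and report writers.

#' Read RNA sequences from a FASTA file
#'
#' Sequences are uppercased and DNA-style `T` is normalized to `U` with a
#' warning.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    warning("DNA alphabet detected; T normalized to U")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("invalid residues in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Read structures from a dot-bracket file
#'
#' One structure per line in extended dot-bracket notation; empty lines and
#' lines starting with `#` or `>` are skipped.
#'
#' @param path text file.
#' @param n expected length (optional check).
#' @return list of [RNAStructure] objects.
#' @export
readStructureFile <- function(path, n = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#>]", lines)]
  if (length(lines) == 0L) stop("no structures in ", path)
  lapply(lines, function(x)
    parseStructure(x, n = if (is.null(n)) nchar(x) else n))
}

# --------------------------------------------------------------------------
# run configuration

#' Load and validate a run configuration
#'
#' YAML keys (all optional except one of `sequence`/`fasta`, and `seed` when
#' sampling is involved): `sequence`, `fasta`, `params` (energy YAML, see
#' [loadEnergyParams]), `ceiling` (default 10), `nSamples` (default 100),
#' `seed`, `width` (default 16), `rounds` (default 3), `maxStates` (default
#' 5000), `threshold` (reporting threshold, default 0.07), `tMin`/`tMax`
#' (time grid bounds, defaults 1e-2 and 1e18).
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides named list merged over the file's values.
#' @return validated config list (class `"runConfig"`).
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  def <- list(sequence = NULL, fasta = NULL, params = NULL, ceiling = 10,
              nSamples = 100L, seed = NULL, width = 16L, rounds = 3L,
              maxStates = 5000L, threshold = 0.07, tMin = 1e-2, tMax = 1e18)
  for (k in names(def)) if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$fasta) && is.null(cfg$sequence))
    cfg$sequence <- unname(readFasta(cfg$fasta)[1])
  if (cfg$ceiling <= 0) stop("ceiling must be positive")
  if (cfg$nSamples < 1) stop("nSamples must be at least 1")
  if (cfg$width < 1 || cfg$rounds < 1) stop("width and rounds must be >= 1")
  if (cfg$maxStates < 2) stop("maxStates must be at least 2")
  if (cfg$threshold < 0 || cfg$threshold > 1) stop("threshold must be in [0, 1]")
  if (cfg$tMin <= 0 || cfg$tMax <= cfg$tMin) stop("need 0 < tMin < tMax")
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "runConfig"
  cfg
}

# md5 of the canonical YAML serialization of a config
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- unclass(cfg)
  yaml::write_yaml(plain[order(names(plain))], tmp)
  unname(tools::md5sum(tmp))
}

# provenance header lines for every output file
.stamp <- function(cfg = NULL) {
  c(paste0("# pkbasins ", as.character(utils::packageVersion("pkbasins"))),
    if (!is.null(cfg)) paste0("# config md5 ", .configHash(cfg)))
}

.writeTable <- function(df, path, cfg = NULL, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.stamp(cfg), extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --------------------------------------------------------------------------
# BHG serialization (round-trip safe)

#' Write a basin hopping graph to TSV files
#'
#' Writes `<prefix>_lm.tsv` (LM table), `<prefix>_edges.tsv` (edge list with
#' witness paths) and `<prefix>_params.yaml` (energy model).  Graph metadata
#' (sequence, variant, mode) is embedded as comment lines.
#' [readBHG()] of the same prefix reconstructs an equal graph.
#'
#' @param bhg a [BasinHoppingGraph].
#' @param prefix output path prefix.
#' @param cfg optional config for the provenance stamp.
#' @return the prefix, invisibly.
#' @export
writeBHG <- function(bhg, prefix, cfg = NULL) {
  meta <- c(paste0("# sequence ", bhg@sequence),
            paste0("# variant ", bhg@variant),
            paste0("# mode ", bhg@mode))
  .writeTable(bhg@lm, paste0(prefix, "_lm.tsv"), cfg, meta)
  ed <- bhg@edges
  ed$witness <- vapply(seq_len(nrow(ed)), function(r) {
    w <- bhg@witnesses[[paste(ed$from[r], ed$to[r], sep = "|")]]
    if (is.null(w)) "" else paste(w, collapse = ",")
  }, character(1))
  .writeTable(ed, paste0(prefix, "_edges.tsv"), cfg, meta)
  saveEnergyParams(bhg@params, paste0(prefix, "_params.yaml"))
  invisible(prefix)
}

#' Read a basin hopping graph written by [writeBHG()]
#'
#' @param prefix path prefix used when writing.
#' @return a [BasinHoppingGraph].
#' @export
readBHG <- function(prefix) {
  lmPath <- paste0(prefix, "_lm.tsv")
  hdr <- readLines(lmPath, n = 10L)
  getMeta <- function(key) {
    hit <- grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]
    sub(paste0("^# ", key, " "), "", hit)
  }
  lm <- utils::read.delim(lmPath, comment.char = "#", stringsAsFactors = FALSE)
  ed <- utils::read.delim(paste0(prefix, "_edges.tsv"), comment.char = "#",
                          colClasses = c(from = "character", to = "character",
                                         pkClass = "character",
                                         witness = "character"),
                          stringsAsFactors = FALSE)
  wit <- list()
  for (r in seq_len(nrow(ed)))
    if (nzchar(ed$witness[r]))
      wit[[paste(ed$from[r], ed$to[r], sep = "|")]] <-
        strsplit(ed$witness[r], ",", fixed = TRUE)[[1]]
  ed$witness <- NULL
  if (nrow(ed) > 0L) ed$pkClass[is.na(ed$pkClass)] <- NA_character_
  lm$count <- as.integer(lm$count)
  new("BasinHoppingGraph", sequence = getMeta("sequence"), lm = lm,
      edges = ed, witnesses = wit, variant = getMeta("variant"),
      mode = getMeta("mode"),
      params = loadEnergyParams(paste0(prefix, "_params.yaml")))
}

# --------------------------------------------------------------------------
# report writers

#' Write analysis reports
#'
#' Writes whichever artifacts are supplied: `lm` (local-minimum table, TSV),
#' `bhg` (see [writeBHG()]), `comparison` (saddle comparison table, TSV),
#' `series` + `model` (population trajectory CSV, columns limited to states
#' whose population ever exceeds `threshold`, plus an equilibrium summary
#' JSON), `path` (path report from [optimalPathA()]/[optimalPathB()], text).
#' Every file embeds the package version and the config hash.
#'
#' @param artifacts named list with any of the elements above.
#' @param outdir output directory (created if missing).
#' @param cfg a config list from [loadConfig()] (used for the provenance
#'   stamp and the reporting threshold).
#' @return character vector of files written, invisibly.
#' @export
writeReports <- function(artifacts, outdir, cfg = loadConfig()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(artifacts$lm)) {
    f <- file.path(outdir, "lm.tsv")
    .writeTable(artifacts$lm, f, cfg)
    files <- c(files, f)
  }
  if (!is.null(artifacts$bhg)) {
    prefix <- file.path(outdir, "bhg")
    writeBHG(artifacts$bhg, prefix, cfg)
    files <- c(files, paste0(prefix, c("_lm.tsv", "_edges.tsv", "_params.yaml")))
  }
  if (!is.null(artifacts$comparison)) {
    f <- file.path(outdir, "saddle_comparison.tsv")
    .writeTable(artifacts$comparison, f, cfg)
    files <- c(files, f)
  }
  if (!is.null(artifacts$series)) {
    ser <- artifacts$series
    keep <- apply(ser@P, 2, max) > cfg$threshold
    if (!any(keep)) keep[which.max(apply(ser@P, 2, max))] <- TRUE
    df <- data.frame(time = ser@times, ser@P[, keep, drop = FALSE],
                     check.names = FALSE)
    f <- file.path(outdir, "trajectory.csv")
    con <- file(f, "w")
    writeLines(c(.stamp(cfg), "# time in arbitrary time units (1/r0)"), con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    files <- c(files, f)
    if (!is.null(artifacts$model)) {
      eq <- equilibriumDistribution(artifacts$model)
      f2 <- file.path(outdir, "equilibrium.json")
      jsonlite::write_json(
        list(equilibrium = as.list(eq),
             equilibrationTime = equilibriumTime(ser, eq),
             configMd5 = .configHash(cfg),
             package = as.character(utils::packageVersion("pkbasins"))),
        f2, auto_unbox = TRUE, digits = NA)
      files <- c(files, f2)
    }
  }
  if (!is.null(artifacts$path)) {
    f <- file.path(outdir, "path.txt")
    pr <- artifacts$path
    states <- if (!is.null(pr$path)) pr$path else pr$trajectory@states
    lines <- c(.stamp(cfg),
               paste0("path: ", paste(states, collapse = " -> ")))
    if (!is.null(pr$peak)) lines <- c(lines, paste0("peak: ", pr$peak))
    if (!is.null(pr$activation))
      lines <- c(lines, paste0("accumulated activation energy: ", pr$activation))
    if (!is.null(pr$logLik)) lines <- c(lines, paste0("logLik: ", pr$logLik))
    if (!is.null(pr$steps) && nrow(pr$steps) > 0L)
      lines <- c(lines, "", utils::capture.output(print(pr$steps)))
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}
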