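## Degron and kinase-consensus motif scanning, and PSSM scoring of
## phosphosite flanks with percentile calibration against a background.
##
## Mini-pattern syntax: uppercase residue letters are literal, "x" is a
## wildcard, "[..]" is a residue class (e.g. D-box "RxxL", KEN-box "KEN",
## SCF/beta-TrCP "DSGxxS", Cdk1 full consensus "[ST]Px[KR]").

#' Default degron motif set
#'
#' Literature-standard degrons recognized by the APC/C (D-box, KEN-box) and
#' the SCF/beta-TrCP ubiquitin ligases. Motif sets are configuration; any
#' census output should name the set used.
#' @return Named character vector of patterns.
#' @export
default_degron_motifs <- function() {
  c(Dbox = "RxxL", KEN = "KEN", bTrCP = "DSGxxS")
}

pattern_to_regex <- function(pattern) {
  if (!grepl("^(\\[[A-Z]+\\]|[A-Zx])+$", pattern))
    stop("invalid motif pattern: '", pattern, "'")
  gsub("x", ".", pattern, fixed = TRUE)
}

pattern_width <- function(pattern) {
  nchar(gsub("\\[[A-Z]+\\]", "#", pattern))
}

#' Scan a protein sequence for motif matches
#'
#' Reports all matches, including overlapping ones, in coordinate order.
#'
#' @param sequence Uppercase protein sequence.
#' @param motifs Named character vector of patterns (default degrons,
#'   [default_degron_motifs()]).
#' @param accession Optional accession carried into the output.
#' @return data.frame(accession, motif, start, end, match) with 1-based
#'   inclusive coordinates.
#' @export
scan_motifs <- function(sequence, motifs = default_degron_motifs(),
                        accession = NA_character_) {
  out <- list()
  for (id in names(motifs)) {
    rx <- pattern_to_regex(motifs[[id]])
    w <- pattern_width(motifs[[id]])
    hits <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    for (s in as.integer(hits)) {
      out[[length(out) + 1]] <- data.frame(
        accession = accession, motif = id, start = s, end = s + w - 1,
        match = substr(sequence, s, s + w - 1), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(accession = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$motif), , drop = FALSE]
}

#' Default kinase consensus set for phosphosite flanks
#'
#' Patterns are anchored on the phosphoacceptor (position 0 = flank center):
#' Cdk1 minimal `[ST]-P` at +1; Cdk1 full `[ST]-P-x-[KR]`; PKA basic
#' residues at -3/-2; Plk1 phospho-binding (PBD) docking `S` at -1.
#' @return List of functions flank -> logical (internal representation),
#'   exposed as a named list of descriptors for [tag_consensus()].
#' @export
default_consensus_set <- function() {
  list(
    cdk1_minimal = list(center = c("S", "T"), offsets = list(`1` = "P")),
    cdk1_full    = list(center = c("S", "T"),
                        offsets = list(`1` = "P", `3` = c("K", "R"))),
    pka          = list(center = c("S", "T"),
                        offsets = list(`-3` = c("R", "K"),
                                       `-2` = c("R", "K"))),
    plk1_pbd     = list(center = c("S", "T"), offsets = list(`-1` = "S")))
}

#' Tag a phosphosite flank with matching kinase consensus motifs
#'
#' @param flank Character, odd length, centered on the phosphoacceptor
#'   (default width 11 = +-5).
#' @param consensus Named list of descriptors (center residues + required
#'   residues at signed offsets); default [default_consensus_set()].
#' @return Character vector of matching consensus ids (possibly empty).
#' @export
tag_consensus <- function(flank, consensus = default_consensus_set()) {
  n <- nchar(flank)
  if (n %% 2 == 0) stop("flank must have odd length")
  c0 <- (n + 1) / 2
  aa <- strsplit(flank, "")[[1]]
  if (!aa[c0] %in% c("S", "T", "Y"))
    stop("flank center must be S, T or Y")
  hits <- character(0)
  for (id in names(consensus)) {
    d <- consensus[[id]]
    if (!aa[c0] %in% d$center) next
    ok <- TRUE
    for (off in names(d$offsets)) {
      i <- c0 + as.integer(off)
      if (i < 1 || i > n || !aa[i] %in% d$offsets[[off]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, id)
  }
  hits
}

#' Score a flank against a position-specific scoring matrix
#'
#' Raw score = sum over non-center positions of the log2-odds of the
#' observed residue. Positions beyond the protein termini (padded `"-"`)
#' contribute 0 — neutral, not missing; residues absent from the matrix
#' alphabet are an error.
#'
#' @param flank Character, odd length; `"-"` marks positions beyond termini.
#' @param pssm Numeric matrix, rows = residues (rownames = 20 amino acids),
#'   columns = flank positions (ncol must equal nchar(flank)).
#' @return Numeric raw score.
#' @export
score_pssm <- function(flank, pssm) {
  n <- nchar(flank)
  if (ncol(pssm) != n)
    stop("flank length does not match matrix width")
  c0 <- (n + 1) / 2
  aa <- strsplit(flank, "")[[1]]
  s <- 0
  for (i in seq_len(n)) {
    if (i == c0 || aa[i] == "-") next
    if (!aa[i] %in% rownames(pssm))
      stop("residue '", aa[i], "' not in matrix alphabet")
    s <- s + pssm[aa[i], i]
  }
  unname(s)
}

#' Percentile of a score against a background distribution
#'
#' Strict-rank percentile: 100 x fraction of background scores strictly
#' below the score (ties excluded from the numerator), or midrank when
#' `ties = "midrank"`.
#'
#' @param score Numeric scalar.
#' @param background Nonempty numeric vector of background scores.
#' @param ties `"strict"` (default) or `"midrank"`.
#' @return Percentile in \[0, 100\].
#' @export
percentile_score <- function(score, background, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (!length(background)) stop("background must be nonempty")
  below <- mean(background < score)
  if (ties == "midrank") below <- below + mean(background == score) / 2
  100 * below
}

#' Predict kinase substrates by PSSM percentile threshold
#'
#' @param flanks Named character vector of site flanks.
#' @param pssm PSSM matrix (see [score_pssm()]).
#' @param background Numeric vector of background raw scores.
#' @param threshold Percentile threshold (default 90).
#' @return data.frame(site, score, percentile, predicted), prediction iff
#'   percentile >= threshold.
#' @export
predict_substrates <- function(flanks, pssm, background, threshold = 90) {
  score <- vapply(flanks, score_pssm, numeric(1), pssm = pssm)
  pct <- vapply(score, percentile_score, numeric(1), background = background)
  data.frame(site = names(flanks), score = score, percentile = pct,
             predicted = pct >= threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Extract the +-w flank of a site from its protein sequence
#'
#' @param sequence Protein sequence.
#' @param position 1-based position of the phosphoacceptor.
#' @param w Half-width (default 5).
#' @return Character of length 2w+1, padded with `"-"` beyond termini.
#' @export
site_flank <- function(sequence, position, w = 5L) {
  n <- nchar(sequence)
  if (position < 1 || position > n) stop("position outside sequence")
  idx <- (position - w):(position + w)
  aa <- strsplit(sequence, "")[[1]]
  paste(ifelse(idx >= 1 & idx <= n, aa[pmax(pmin(idx, n), 1)], "-"),
        collapse = "")
}
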