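## Cross-species phosphosite matching: pairwise protein alignment (BLOSUM90,
## affine gaps, global with free end gaps), Karlin-Altschul E-values, site
## matching at aligned identical phosphoacceptor residues, and correlation
## of the matched sites' dynamics.

#' Load a named substitution matrix
#'
#' BLOSUM90 (the matrix the cross-species comparison uses) ships with the
#' package as a plain-text copy of the standard NCBI matrix; other named
#' matrices come from Biostrings.
#'
#' @param id Matrix name, e.g. `"BLOSUM90"`, `"BLOSUM62"`.
#' @return Numeric substitution matrix.
#' @export
load_substitution_matrix <- function(id = "BLOSUM90") {
  if (id == "BLOSUM90") {
    path <- system.file("extdata", "BLOSUM90.txt", package = "meiophos")
    m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    return(m)
  }
  ok <- try(suppressWarnings(utils::data(list = id, package = "Biostrings",
                                         envir = environment())),
            silent = TRUE)
  if (inherits(ok, "try-error") || !exists(id, envir = environment(),
                                           inherits = FALSE))
    stop("unknown substitution matrix: ", id)
  get(id, envir = environment())
}

#' Align two protein sequences and map their coordinates
#'
#' Global alignment with free end gaps (so terminal extensions are not
#' penalized) under an affine gap model, maximizing the substitution-matrix
#' score. The E-value uses the Karlin-Altschul formula
#' E = K m n exp(-lambda S) with configurable parameters.
#'
#' @param seqA,seqB Nonempty uppercase protein sequences.
#' @param accA,accB Optional accessions carried into the map.
#' @param matrix Substitution matrix name (default `"BLOSUM90"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters (defaults
#'   0.267, 0.041 — gapped protein-search values; configuration, not claims).
#' @return An `alignment_map`: list(accA, accB, map = data.frame(posA, posB)
#'   of aligned (ungapped) coordinate pairs, score, evalue).
#' @export
align_pair <- function(seqA, seqB, accA = "A", accB = "B",
                       matrix = "BLOSUM90", gap_open = 11, gap_extend = 1,
                       karlin_lambda = 0.267, karlin_k = 0.041) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be nonempty")
  sub <- load_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(seqA, seqB, type = "overlap",
                                      substitutionMatrix = sub,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  iA <- Biostrings::pattern(pa)@range@start
  iB <- Biostrings::subject(pa)@range@start
  posA <- integer(0); posB <- integer(0)
  a <- iA - 1; b <- iB - 1
  for (i in seq_along(ap)) {
    ga <- ap[i] == "-"; gb <- as_[i] == "-"
    if (!ga) a <- a + 1
    if (!gb) b <- b + 1
    if (!ga && !gb) { posA <- c(posA, a); posB <- c(posB, b) }
  }
  score <- Biostrings::score(pa)
  evalue <- karlin_k * nchar(seqA) * nchar(seqB) *
    exp(-karlin_lambda * score)
  structure(list(accA = accA, accB = accB,
                 map = data.frame(posA = posA, posB = posB),
                 score = score, evalue = evalue),
            class = "alignment_map")
}

#' Match phosphosites between two species' datasets
#'
#' A site pair is kept iff the covering alignment passes the E-value filter
#' (strictly below `e_threshold`; or the raw-score filter when
#' `score_threshold` is given), the positions are aligned without a gap,
#' both residues are phosphoacceptors (S/T/Y) and — by default — identical,
#' and both sites are measured. Grouped B-side accessions (";"-separated)
#' are resolved to the specific protein whose aligned residue matches.
#'
#' @param sitesA,sitesB data.frames with columns `accession`, `position`,
#'   `residue`, `log2fc` (the measured Log2FC(MII/PRO)).
#' @param alignments List of `alignment_map` objects.
#' @param e_threshold Keep alignments with E strictly below this (1e-20).
#' @param score_threshold If non-`NULL`, use score > threshold instead of
#'   the E-value filter (deterministic alternative).
#' @param require_identical_residue Require the same residue letter on both
#'   sides (default TRUE), not merely both-phosphoacceptor.
#' @return data.frame(acc_a, pos_a, residue_a, acc_b, pos_b, residue_b,
#'   log2fc_a, log2fc_b).
#' @export
match_sites <- function(sitesA, sitesB, alignments, e_threshold = 1e-20,
                        score_threshold = NULL,
                        require_identical_residue = TRUE) {
  out <- list()
  for (al in alignments) {
    pass <- if (is.null(score_threshold)) al$evalue < e_threshold
            else al$score > score_threshold
    if (!pass) next
    sa <- sitesA[sitesA$accession == al$accA, , drop = FALSE]
    grouped <- strsplit(sitesB$accession, ";", fixed = TRUE)
    bmask <- vapply(grouped, function(g) al$accB %in% g, logical(1))
    sb <- sitesB[bmask, , drop = FALSE]
    if (!nrow(sa) || !nrow(sb)) next
    for (i in seq_len(nrow(sa))) {
      j <- match(sa$position[i], al$map$posA)
      if (is.na(j)) next                      # gapped position
      pb <- al$map$posB[j]
      hit <- which(sb$position == pb)
      for (h in hit) {
        ra <- sa$residue[i]; rb <- sb$residue[h]
        if (!ra %in% c("S", "T", "Y") || !rb %in% c("S", "T", "Y")) next
        if (require_identical_residue && ra != rb) next
        out[[length(out) + 1]] <- data.frame(
          acc_a = al$accA, pos_a = sa$position[i], residue_a = ra,
          acc_b = al$accB, pos_b = pb, residue_b = rb,
          log2fc_a = sa$log2fc[i], log2fc_b = sb$log2fc[h],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(acc_a = character(0), pos_a = integer(0),
                      residue_a = character(0), acc_b = character(0),
                      pos_b = integer(0), residue_b = character(0),
                      log2fc_a = numeric(0), log2fc_b = numeric(0)))
  unique(do.call(rbind, out))
}

#' Correlate phosphorylation dynamics of matched sites
#'
#' @param matched Output of [match_sites()] (needs >= 3 rows, finite
#'   log2 fold changes, nonzero variance on both sides).
#' @return list(r = Pearson correlation, p = two-sided t-based p-value,
#'   n = number of matched sites).
#' @export
correlate_dynamics <- function(matched) {
  x <- matched$log2fc_a; y <- matched$log2fc_b
  if (length(x) < 3) stop("need at least 3 matched sites")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("log2 fold changes must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
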