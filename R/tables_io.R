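## Peptide-table I/O, post-search filters, protein inference, phosphosite
## grouping/site sets, and unmodified-partner matching.

#' Validate and class a peptide table
#'
#' The canonical column schema is: `peptide_id`, `sequence`, `proteins`
#' (";"-separated accessions), `start`, `end` (1-based inclusive protein
#' coordinates), `phospho_positions` (";"-separated 1-based protein
#' coordinates, empty allowed), `replicate`, `isolation_specificity` in
#' \[0,1\], then one `sn_<channel>` signal-to-noise column per design channel.
#'
#' @param df A data.frame following the schema.
#' @param design The [plex_design()] the channel columns must match.
#' @return The data.frame with class `peptide_table`.
#' @export
as_peptide_table <- function(df, design) {
  fixed <- c("peptide_id", "sequence", "proteins", "start", "end",
             "phospho_positions", "replicate", "isolation_specificity")
  miss <- setdiff(fixed, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  want <- paste0("sn_", channel_names(design))
  have <- grep("^sn_", names(df), value = TRUE)
  if (!identical(sort(want), sort(have)))
    stop("channel columns do not match design: expected {",
         paste(want, collapse = ","), "} got {", paste(have, collapse = ","), "}")
  df <- df[, c(fixed, want)]
  if (any(df$isolation_specificity < 0 | df$isolation_specificity > 1))
    stop("isolation_specificity must be in [0,1]")
  sn <- as.matrix(df[, want])
  if (any(sn < 0)) stop("signal-to-noise values must be nonnegative")
  df$phospho_positions <- as.character(df$phospho_positions)
  df$phospho_positions[is.na(df$phospho_positions)] <- ""
  bad <- vapply(seq_len(nrow(df)), function(i) {
    p <- parse_positions(df$phospho_positions[i])
    length(p) && (any(p < df$start[i]) || any(p > df$end[i]))
  }, logical(1))
  if (any(bad))
    stop("phospho positions outside [start,end] in rows: ",
         paste(which(bad), collapse = ","))
  class(df) <- c("peptide_table", "data.frame")
  attr(df, "channels") <- channel_names(design)
  df
}

parse_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  out <- suppressWarnings(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))
  if (anyNA(out)) stop("malformed phospho position field: '", s, "'")
  out
}

#' Read / write a peptide table (TSV)
#'
#' @param path File path.
#' @param design The [plex_design()] whose channels the table must match.
#' @return A `peptide_table`.
#' @export
read_peptide_table <- function(path, design) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(phospho_positions = "character"),
                          check.names = FALSE)
  as_peptide_table(df, design)
}

#' @rdname read_peptide_table
#' @param table A `peptide_table`.
#' @export
write_peptide_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector of sequences
#' @param path FASTA file path.
#' @return Named character vector (accession -> sequence).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Keep spectra exceeding an isolation-specificity threshold
#'
#' Rows are kept iff `isolation_specificity` is strictly greater than the
#' threshold (the post-search filter applied to the real data); row order is
#' preserved and the filter is idempotent.
#'
#' @param table A `peptide_table`.
#' @param threshold Specificity cutoff (default 0.75).
#' @return The filtered table.
#' @export
filter_isolation_specificity <- function(table, threshold = 0.75) {
  table[table$isolation_specificity > threshold, , drop = FALSE]
}

#' Assign multi-mapped peptides to the protein with most unique peptides
#'
#' Peptides matching multiple proteins are reassigned to the candidate with
#' the largest count of uniquely mapping peptide sequences in the same table;
#' ties go to the lexicographically smallest accession and are flagged.
#'
#' @param table A `peptide_table` (accessions ";"-separated in `proteins`).
#' @param sequences Optional named character vector (from [read_fasta()]);
#'   when given, every accession must be present in it.
#' @return list(table = table with a single accession per row,
#'   report = data.frame(peptide_id, candidates, assigned, tie)).
#' @export
infer_proteins <- function(table, sequences = NULL) {
  accs <- strsplit(table$proteins, ";", fixed = TRUE)
  if (any(lengths(accs) == 0))
    stop("rows without protein accession: ",
         paste(which(lengths(accs) == 0), collapse = ","))
  if (!is.null(sequences)) {
    unknown <- setdiff(unique(unlist(accs)), names(sequences))
    if (length(unknown))
      stop("accessions absent from FASTA: ", paste(unknown, collapse = ","))
  }
  ## unique-peptide counts: distinct sequences mapping to exactly one protein
  uni <- accs[lengths(accs) == 1]
  useq <- table$sequence[lengths(accs) == 1]
  counts <- table(unlist(uni[!duplicated(paste(unlist(uni), useq))]))
  score <- function(a) if (a %in% names(counts)) counts[[a]] else 0L
  rep_rows <- list()
  assigned <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    cand <- accs[[i]]
    if (length(cand) == 1) { assigned[i] <- cand; next }
    sc <- vapply(cand, score, integer(1))
    best <- cand[sc == max(sc)]
    tie <- length(best) > 1
    assigned[i] <- sort(best)[1]
    rep_rows[[length(rep_rows) + 1]] <- data.frame(
      peptide_id = table$peptide_id[i],
      candidates = paste(cand, collapse = ";"),
      assigned = assigned[i], tie = tie, stringsAsFactors = FALSE)
  }
  out <- table
  out$proteins <- assigned
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(peptide_id = character(0), candidates = character(0),
               assigned = character(0), tie = logical(0))
  list(table = out, report = report)
}

site_residue <- function(table, row, pos) {
  substr(table$sequence[row], pos - table$start[row] + 1,
         pos - table$start[row] + 1)
}

#' Group phosphopeptide rows by unique phosphosite identifier
#'
#' Rows carrying the same (protein, phospho position set) — including
#' composite multi-site peptides — form one group. Residue letters are read
#' from the peptide sequences. Requires single-accession rows
#' (run [infer_proteins()] first).
#'
#' @param table A `peptide_table`.
#' @return Named list: site key (see [site_key()]) -> integer row indices.
#' @export
group_sites <- function(table) {
  if (any(grepl(";", table$proteins, fixed = TRUE)))
    stop("run infer_proteins() before grouping sites")
  keys <- vapply(seq_len(nrow(table)), function(i) {
    pos <- parse_positions(table$phospho_positions[i])
    if (!length(pos)) return(NA_character_)
    res <- vapply(pos, function(p) site_residue(table, i, p), character(1))
    site_key(table$proteins[i], res, pos)
  }, character(1))
  idx <- which(!is.na(keys))
  split(idx, keys[idx])
}

#' Parse a site key back into its components
#' @param key A key produced by [site_key()].
#' @return list(accession, residues, positions).
#' @export
parse_site_key <- function(key) {
  m <- regmatches(key, regexpr(":[STY0-9+]+$", key))
  acc <- substr(key, 1, nchar(key) - nchar(m))
  parts <- strsplit(substring(m, 2), "+", fixed = TRUE)[[1]]
  list(accession = acc,
       residues = substr(parts, 1, 1),
       positions = as.integer(substring(parts, 2)))
}

#' Connect phosphosites ever co-measured on one peptide into site sets
#'
#' Two sites are placed in the same set iff some row measures both positions
#' simultaneously (a composite phosphopeptide), closed transitively.
#'
#' @param table A `peptide_table` (single accession per row).
#' @return list of character vectors of site keys (the partition), each
#'   sorted; sets ordered by accession then first position.
#' @export
build_site_sets <- function(table) {
  groups <- group_sites(table)
  keys <- names(groups)
  parsed <- lapply(keys, parse_site_key)
  ## union-find over (accession, position) atoms
  atoms <- unique(do.call(rbind, lapply(parsed, function(p)
    data.frame(acc = p$accession, pos = p$positions,
               stringsAsFactors = FALSE))))
  id <- stats::setNames(seq_len(nrow(atoms)), paste0(atoms$acc, "#", atoms$pos))
  parent <- seq_len(nrow(atoms))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (p in parsed) {
    ids <- id[paste0(p$accession, "#", p$positions)]
    if (length(ids) > 1) for (k in 2:length(ids)) union_(ids[1], ids[k])
  }
  roots <- vapply(lapply(parsed, function(p)
    id[paste0(p$accession, "#", p$positions[1])]), find, integer(1))
  sets <- split(keys, roots)
  sets <- lapply(sets, sort)
  first_pos <- vapply(sets, function(s) parse_site_key(s[1])$positions[1],
                      integer(1))
  first_acc <- vapply(sets, function(s) parse_site_key(s[1])$accession,
                      character(1))
  unname(sets[order(first_acc, first_pos)])
}

#' Find unmodified partner peptides for a phosphosite
#'
#' Returns rows with no phospho positions at all whose \[start, end\] span
#' covers every position of the site — the "different form" needed to make
#' occupancy computable. A peptide phosphorylated elsewhere is a different
#' molecular species and is not a partner.
#'
#' @param site A site key (string) or list(accession, positions).
#' @param table A `peptide_table`.
#' @return Integer vector of row indices (possibly empty).
#' @export
match_unmodified <- function(site, table) {
  if (is.character(site)) site <- parse_site_key(site)
  pos <- site$positions
  which(table$proteins == site$accession &
          !nzchar(table$phospho_positions) &
          table$start <= min(pos) & table$end >= max(pos))
}
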