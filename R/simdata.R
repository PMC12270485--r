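## Synthetic-data generator: proteomes, in-silico digestion, ground-truth
## trajectories, and peptide-level reporter tables with multinomial counting
## noise, emulating the 9-timepoint / 2-anchor / 3-replicate study design.

AMINO_ACIDS <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

## Average residue masses (Da); protein MW = sum(residues) + water.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.01528

#' Average molecular mass of a protein sequence (Da)
#' @param sequence Uppercase amino-acid string.
#' @return Mass in daltons.
#' @export
protein_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(bad)) stop("unknown residues: ", paste(unique(bad), collapse = ","))
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Generate a synthetic proteome
#'
#' Random protein sequences (uniform residue composition) with an optional
#' fraction of homeologous L/S allo-allele pairs, as found in the
#' allotetraploid *Xenopus laevis* genome: pairs `ACC.L`/`ACC.S` differ by
#' ~5% point substitutions.
#'
#' @param n_proteins Total number of proteins (>= 1).
#' @param length_range Length range (residues), both ends >= 30.
#' @param allo_allele_fraction Fraction of proteins emitted as L/S pairs.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param substitution_rate Point-substitution rate between alleles (0.05).
#' @return A `synthetic_truth` skeleton: list with `proteins` (data.frame of
#'   accession, sequence, mass_da), `fasta` (character, FASTA text), `seed`.
#' @export
gen_proteome <- function(n_proteins, length_range = c(200L, 600L),
                         allo_allele_fraction = 0.3, seed = 1L,
                         substitution_rate = 0.05) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (length(length_range) != 2 || any(length_range < 30))
    stop("length_range must be two values >= 30")
  if (allo_allele_fraction < 0 || allo_allele_fraction > 1)
    stop("allo_allele_fraction must be in [0,1]")
  set.seed(seed)
  n_pairs <- floor(n_proteins * allo_allele_fraction / 2)
  n_single <- n_proteins - 2 * n_pairs
  acc <- character(0); seqs <- character(0)
  idx <- 0
  rand_seq <- function() {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    paste(sample(AMINO_ACIDS, len, replace = TRUE), collapse = "")
  }
  for (p in seq_len(n_pairs)) {
    idx <- idx + 1
    base <- rand_seq()
    aa <- strsplit(base, "")[[1]]
    nsub <- rbinom(1, length(aa), substitution_rate)
    if (nsub > 0) {
      pos <- sample(length(aa), nsub)
      aa[pos] <- vapply(aa[pos], function(r)
        sample(setdiff(AMINO_ACIDS, r), 1), character(1))
    }
    acc <- c(acc, sprintf("SP%04d.L", idx), sprintf("SP%04d.S", idx))
    seqs <- c(seqs, base, paste(aa, collapse = ""))
  }
  for (s in seq_len(n_single)) {
    idx <- idx + 1
    acc <- c(acc, sprintf("SP%04d.L", idx))
    seqs <- c(seqs, rand_seq())
  }
  fasta <- paste0(">", acc, "\n", seqs, collapse = "\n")
  proteins <- data.frame(accession = acc, sequence = seqs,
                         mass_da = vapply(seqs, protein_mass, numeric(1),
                                          USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  structure(list(proteins = proteins, fasta = fasta, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' In-silico proteolytic digestion
#'
#' Cleavage rules: trypsin cuts after K/R except when the next residue is P;
#' LysC cuts after K including before P; `"trypsin+lysC"` cuts after K
#' (always) and after R unless followed by P. All peptides with 0 to
#' `max_missed` missed cleavages are emitted.
#'
#' @param sequence Uppercase protein sequence.
#' @param enzyme One of `"trypsin"`, `"lysC"`, `"trypsin+lysC"`.
#' @param max_missed Maximum missed cleavages (default 2).
#' @return data.frame with columns `peptide`, `start`, `end`, `missed`
#'   (1-based inclusive protein coordinates).
#' @export
digest <- function(sequence, enzyme = c("trypsin", "lysC", "trypsin+lysC"),
                   max_missed = 2L) {
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  enzyme <- match.arg(enzyme)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- logical(n)  # cleavage between i and i+1
  for (i in seq_len(n - 1)) {
    nxt <- aa[i + 1]
    cut_after[i] <- switch(enzyme,
      "trypsin"       = aa[i] %in% c("K", "R") && nxt != "P",
      "lysC"          = aa[i] == "K",
      "trypsin+lysC"  = aa[i] == "K" || (aa[i] == "R" && nxt != "P"))
  }
  bounds <- c(0, which(cut_after), n)         # fragment boundaries
  starts <- head(bounds, -1) + 1
  ends <- bounds[-1]
  nfrag <- length(starts)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      out[[length(out) + 1]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i], end = ends[j], missed = m,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

## ---- trajectory archetypes -------------------------------------------------

## Occupancy archetypes over the default 9 timepoints (0,2,3,4,5,6,7,8,9 h).
## Stage log2 fold changes clear the +-1 class thresholds with margin >= 0.25.
site_class_archetypes <- function() {
  list(
    I            = c(0.60, rep(0.15, 8)),
    II           = c(0.10, 0.10, rep(0.80, 7)),
    III          = c(0.10, 0.10, 0.80, 0.80, 0.50, 0.30, 0.15, 0.15, 0.15),
    IV           = c(0.10, 0.10, 0.30, 0.30, 0.45, 0.60, 0.90, 0.90, 0.90),
    V            = c(0.20, 0.20, 0.20, 0.20, 0.30, 0.50, 0.80, 0.80, 0.80),
    unclassified = rep(0.30, 9))
}

## Protein relative-level archetypes: accumulating reaches 2x by 7 h then
## plateaus (stage MII average exactly 2); decreasing mirrors to 0.5x.
protein_trend_archetypes <- function(timepoints) {
  ramp <- pmin(timepoints, 7) / 7
  list(accumulating = 1 + ramp,
       stable       = rep(1, length(timepoints)),
       decreasing   = 1 - 0.5 * ramp)
}

#' Assign ground-truth trajectories and phosphosites
#'
#' Each protein receives a relative-abundance trajectory drawn from its trend
#' archetype (accumulating / stable / decreasing; 1.5x and 0.75x thresholds
#' cleared with margin) and `sites_per_protein` phosphosites placed on
#' S/T/Y residues (residue mix defaults to 80% S, 19.9% T, 0.1% Y), each with
#' an occupancy trajectory drawn from one of the five dynamics-class
#' archetypes (or flat, unclassified).
#'
#' @param truth A `synthetic_truth` skeleton from [gen_proteome()].
#' @param class_mix Named fractions over classes I..V + unclassified, sum 1.
#' @param trend_mix Named fractions over accumulating/stable/decreasing.
#' @param design A [plex_design()]; default [default_design()].
#' @param sites_per_protein Mean phosphosites per protein (default 3).
#' @param seed Integer seed.
#' @return The completed `synthetic_truth`: adds `design`, `protein_traj`
#'   (matrix proteins x timepoints), `sites` (data.frame accession, position,
#'   residue, class, site_key), `site_traj` (matrix sites x timepoints).
#' @export
simulate_trajectories <- function(truth,
    class_mix = c(I = 0.02, II = 0.39, III = 0.05, IV = 0.09, V = 0.05,
                  unclassified = 0.40),
    trend_mix = c(accumulating = 0.05, stable = 0.88, decreasing = 0.07),
    design = default_design(), sites_per_protein = 3, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix fractions must sum to 1")
  if (abs(sum(trend_mix) - 1) > 1e-9) stop("trend_mix fractions must sum to 1")
  set.seed(seed)
  tp <- design$timepoints
  n_tp <- length(tp)
  if (n_tp != 9)
    stop("trajectory archetypes are defined for the 9-timepoint design")
  arch_site <- site_class_archetypes()
  arch_prot <- protein_trend_archetypes(tp)
  prot <- truth$proteins
  n_prot <- nrow(prot)
  trends <- sample(names(trend_mix), n_prot, replace = TRUE, prob = trend_mix)
  protein_traj <- t(vapply(trends, function(tr) arch_prot[[tr]],
                           numeric(n_tp)))
  rownames(protein_traj) <- prot$accession
  prot$trend <- trends

  site_rows <- list(); site_traj <- list()
  for (i in seq_len(n_prot)) {
    aa <- strsplit(prot$sequence[i], "")[[1]]
    cand <- which(aa %in% c("S", "T", "Y"))
    if (!length(cand)) next
    wt <- c(S = 0.80, T = 0.199, Y = 0.001)[aa[cand]]
    ns <- min(length(cand), max(1L, rpois(1, sites_per_protein)))
    pos <- sort(sample(cand, ns, prob = wt))
    cls <- sample(names(class_mix), ns, replace = TRUE, prob = class_mix)
    for (k in seq_along(pos)) {
      base <- arch_site[[cls[k]]]
      # multiplicative jitter that provably preserves class margins
      traj <- pmin(0.99, pmax(0.01, base * runif(1, 0.92, 1.08)))
      if (!identical(classify_occupancy_trajectory(traj, tp), cls[k]))
        traj <- base
      key <- site_key(prot$accession[i], aa[pos[k]], pos[k])
      site_rows[[length(site_rows) + 1]] <- data.frame(
        accession = prot$accession[i], position = pos[k],
        residue = aa[pos[k]], class = cls[k], site_key = key,
        stringsAsFactors = FALSE)
      site_traj[[length(site_traj) + 1]] <- traj
    }
  }
  sites <- do.call(rbind, site_rows)
  traj_m <- do.call(rbind, site_traj)
  rownames(traj_m) <- sites$site_key
  bad <- traj_m < 0 | traj_m > 1
  if (any(bad))
    stop("occupancy forced outside [0,1] for site ",
         sites$site_key[which(rowSums(bad) > 0)[1]])
  truth$design <- design
  truth$proteins <- prot
  truth$protein_traj <- protein_traj
  truth$sites <- sites
  truth$site_traj <- traj_m
  truth$seed <- as.integer(seed)
  truth
}

## classify a noise-free occupancy trajectory by the stage fold-change rules
classify_occupancy_trajectory <- function(traj, timepoints) {
  names(traj) <- timepoints
  s <- stage_summary(traj)
  as.character(assign_class(s)$label)
}

#' Canonical phosphosite key
#' @param accession Protein accession.
#' @param residues Residue letter(s) (S/T/Y).
#' @param positions 1-based protein position(s); composite sites give several.
#' @return Character key, e.g. `"SP0001.L:S59"` or `"SP0001.L:S10+S14"`.
#' @export
site_key <- function(accession, residues, positions) {
  o <- order(positions)
  paste0(accession, ":",
         paste0(residues[o], positions[o], collapse = "+"))
}

#' Dump a synthetic truth object to JSON
#'
#' Serializes the ground-truth trajectories, site classes and protein trends
#' (not the design object) so recovery tests can reload what was planted.
#'
#' @param truth A completed `synthetic_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(seed = truth$seed,
              proteins = truth$proteins[, c("accession", "mass_da", "trend")],
              protein_traj = truth$protein_traj,
              sites = truth$sites,
              site_traj = truth$site_traj,
              timepoints = truth$design$timepoints)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

## ---- peptide tables --------------------------------------------------------

#' Simulate peptide-level TMT reporter tables
#'
#' Draws, for each peptide species and replicate, a total reporter depth from
#' a log-normal (median `depth`, sdlog `sigma_log`) and reporter counts from
#' a multinomial over channels with the forward-model expectation
#' (loading x protein level x occupancy fraction; anchors carry the full
#' dephosphorylated signal and only `epsilon` leakage of phospho signal).
#' A fraction `1 - phospho_purity` of rows in the phospho table are
#' unmodified contaminant peptides; these are allocated to cover phosphosites
#' first (they are what makes occupancy identifiable), then at random.
#'
#' @param truth Completed `synthetic_truth` (see [simulate_trajectories()]).
#' @param peptides_per_protein Peptides sampled per protein for the proteome
#'   table and maximum covering peptides per site (default 3).
#' @param depth Median total reporter count per peptide row (>= 10).
#' @param phospho_purity Fraction of phospho-table rows carrying a
#'   phosphosite (default 0.8, the enrichment purity the protocol attains).
#' @param noise If `FALSE`, emit exact expected signal at `depth` total
#'   (no log-normal, no multinomial; isolation specificity set to 1).
#' @param sigma_log Log-normal sdlog of per-row depth (default 1).
#' @param epsilon Anchor phospho leakage (default 1e-3).
#' @param seed Integer seed.
#' @return list(phospho = PeptideTable, proteome = PeptideTable); see
#'   [read_peptide_table()] for the column schema.
#' @export
simulate_tables <- function(truth, peptides_per_protein = 3L, depth = 1000,
                            phospho_purity = 0.8, noise = TRUE,
                            sigma_log = 1.0, epsilon = 1e-3, seed = 1L) {
  if (is.null(truth$site_traj)) stop("truth has no trajectories; run simulate_trajectories() first")
  if (depth < 10) stop("depth must be >= 10")
  set.seed(seed)
  design <- truth$design
  nch <- n_channels(design)
  prot <- truth$proteins
  seq_of <- stats::setNames(prot$sequence, prot$accession)
  digests <- lapply(prot$sequence, digest, enzyme = "trypsin", max_missed = 1L)
  names(digests) <- prot$accession

  draw_row <- function(expect) {
    p <- expect / sum(expect)
    if (noise) {
      n_tot <- max(1, round(stats::rlnorm(1, log(depth), sigma_log)))
      as.numeric(stats::rmultinom(1, n_tot, p))
    } else depth * p
  }
  iso <- function() if (noise) stats::runif(1, 0.5, 1) else 1

  ## effective occupancy of the fully-unmodified form of a peptide: the
  ## unmod fraction is the product of (1 - f) over every covered site
  unmod_eff_occ <- function(acc, start, end) {
    s <- sites_of(acc, start, end)
    if (!length(s)) return(NULL)
    fm <- truth$site_traj[s, , drop = FALSE]
    1 - apply(1 - fm, 2, prod)
  }
  sites_of <- function(acc, start, end) {
    s <- truth$sites
    s$site_key[s$accession == acc & s$position >= start & s$position <= end]
  }

  rows <- list()
  pid <- 0
  add_row <- function(tab, accession, pep, phospho_pos, rep_id, expect) {
    pid <<- pid + 1
    sn <- draw_row(expect)
    row <- data.frame(peptide_id = sprintf("pep%06d", pid),
                      sequence = pep$peptide, proteins = accession,
                      start = pep$start, end = pep$end,
                      phospho_positions = paste(phospho_pos, collapse = ";"),
                      replicate = rep_id,
                      isolation_specificity = iso(),
                      stringsAsFactors = FALSE)
    row[paste0("sn_", channel_names(design))] <- as.list(sn)
    rows[[length(rows) + 1]] <<- list(tab = tab, row = row)
  }

  ## --- proteome table: prefer peptides that carry no phosphosite, so the
  ## per-protein trend tracks total protein level
  for (i in seq_len(nrow(prot))) {
    acc <- prot$accession[i]
    dg <- digests[[acc]]
    dg <- dg[nchar(dg$peptide) >= 7, , drop = FALSE]
    if (!nrow(dg)) next
    free <- vapply(seq_len(nrow(dg)), function(k)
      length(sites_of(acc, dg$start[k], dg$end[k])) == 0, logical(1))
    if (any(free)) dg <- dg[free, , drop = FALSE]
    r <- truth$protein_traj[acc, ]
    pick <- dg[sample(nrow(dg), min(nrow(dg), peptides_per_protein)), ,
               drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      exp_u <- expected_channel_intensity(
        design, r, unmod_eff_occ(acc, pick$start[k], pick$end[k]),
        "unmod", epsilon)
      for (rep_id in seq_len(design$replicates))
        add_row("proteome", acc, pick[k, ], integer(0), rep_id, exp_u)
    }
  }

  ## --- phospho table: covering peptides, phospho form
  sites <- truth$sites
  cover <- vector("list", nrow(sites))
  n_phos_rows <- 0
  for (s in seq_len(nrow(sites))) {
    acc <- sites$accession[s]
    pos <- sites$position[s]
    dg <- digests[[acc]]
    cv <- dg[dg$start <= pos & dg$end >= pos & nchar(dg$peptide) >= 7, ,
             drop = FALSE]
    if (!nrow(cv)) next
    cv <- cv[sample(nrow(cv), min(nrow(cv), peptides_per_protein)), ,
             drop = FALSE]
    cover[[s]] <- cv
    r <- truth$protein_traj[acc, ]
    f <- truth$site_traj[sites$site_key[s], ]
    exp_p <- expected_channel_intensity(design, r, f, "phospho", epsilon)
    for (k in seq_len(nrow(cv)))
      for (rep_id in seq_len(design$replicates)) {
        add_row("phospho", acc, cv[k, ], pos, rep_id, exp_p)
        n_phos_rows <- n_phos_rows + 1
      }
  }

  ## --- contaminant (unmodified) rows in the phospho table
  n_contam_species <- round(n_phos_rows / design$replicates *
                              (1 / phospho_purity - 1))
  order_sites <- sample(nrow(sites))
  emitted <- 0
  for (s in order_sites) {
    if (emitted >= n_contam_species) break
    if (is.null(cover[[s]]) || !nrow(cover[[s]])) next
    acc <- sites$accession[s]
    r <- truth$protein_traj[acc, ]
    pep <- cover[[s]][1, ]
    f_eff <- unmod_eff_occ(acc, pep$start, pep$end)
    exp_u <- expected_channel_intensity(design, r, f_eff, "unmod", epsilon)
    for (rep_id in seq_len(design$replicates))
      add_row("phospho", acc, pep, integer(0), rep_id, exp_u)
    emitted <- emitted + 1
  }
  while (emitted < n_contam_species) {    # remainder: random unmod peptides
    i <- sample(nrow(prot), 1)
    acc <- prot$accession[i]
    dg <- digests[[acc]]
    dg <- dg[nchar(dg$peptide) >= 7, , drop = FALSE]
    if (!nrow(dg)) next
    pep <- dg[sample(nrow(dg), 1), ]
    r <- truth$protein_traj[acc, ]
    exp_u <- expected_channel_intensity(design, r,
                                        unmod_eff_occ(acc, pep$start, pep$end),
                                        "unmod", epsilon)
    for (rep_id in seq_len(design$replicates))
      add_row("phospho", acc, pep, integer(0), rep_id, exp_u)
    emitted <- emitted + 1
  }

  tabs <- split(lapply(rows, `[[`, "row"), vapply(rows, `[[`, "", "tab"))
  assemble <- function(lst) {
    t <- do.call(rbind, lst)
    rownames(t) <- NULL
    as_peptide_table(t, design)
  }
  list(phospho = assemble(tabs$phospho), proteome = assemble(tabs$proteome))
}
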