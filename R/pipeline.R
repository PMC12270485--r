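## End-to-end orchestration on synthetic data: simulate -> filter ->
## aggregate -> occupancy -> normalize/classify -> cluster -> enrich ->
## absolute quantification -> degron census -> cross-species (L vs S
## allo-allele) matching. Every stage is also callable on its own; this
## driver wires them together, writes TSVs and a checksum manifest, and is
## bit-reproducible given the config seed.

#' Default pipeline configuration
#'
#' Sizes are chosen so that the full run finishes in well under a minute;
#' thresholds are the analysis's fixed constants (isolation specificity 0.75,
#' class cutoffs +-1 in log2, protein trend cutoffs 1.5x/0.75x, k-means
#' cluster counts 60/90 capped at half the number of trajectories,
#' PSSM percentile 90, E-value 1e-20).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named list of parameters, editable before [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       n_proteins = 60L, length_range = c(150L, 400L),
       allo_allele_fraction = 0.4,
       sites_per_protein = 3, peptides_per_protein = 3L,
       depth = 2000, phospho_purity = 0.8, noise = TRUE,
       iso_threshold = 0.75,
       n_boot = 100L, epsilon = 1e-3,
       k_protein = 60L, k_phospho = 90L, kmeans_restarts = 20L,
       percentile_threshold = 90, e_threshold = 1e-20)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [default_config()] fields.
#' @return Config list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(if (is.null(user$seed)) 1L else user$seed)
  utils::modifyList(cfg, user)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory; created if absent. Re-running with the
#'   same config gives byte-identical outputs.
#' @return Invisibly, a list with the in-memory results (`truth`, `tables`,
#'   `occupancy`, `site_classes`, `protein_trends`, `clusters`,
#'   `enrichment`, `concentrations`, `degrons`, `xspecies`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  design <- default_design()

  ## 1. synthetic truth + tables
  truth <- gen_proteome(config$n_proteins, config$length_range,
                        config$allo_allele_fraction, seed = seed)
  truth <- simulate_trajectories(truth, design = design,
                                 sites_per_protein = config$sites_per_protein,
                                 seed = seed + 1L)
  tabs <- simulate_tables(truth, config$peptides_per_protein, config$depth,
                          config$phospho_purity, noise = config$noise,
                          epsilon = config$epsilon, seed = seed + 2L)
  writeLines(truth$fasta, file.path(out_dir, "proteome.fasta"))
  write_peptide_table(tabs$phospho, file.path(out_dir, "phospho_peptides.tsv"))
  write_peptide_table(tabs$proteome, file.path(out_dir, "proteome_peptides.tsv"))

  ## 2. post-search filter
  phos <- filter_isolation_specificity(tabs$phospho, config$iso_threshold)
  prot <- filter_isolation_specificity(tabs$proteome, config$iso_threshold)

  ## 3. protein trends
  by_acc <- split(seq_len(nrow(prot)), prot$proteins)
  prot_trends <- aggregate_groups(prot, by_acc,
                                  round_counts = config$noise)
  prot_tp <- t(vapply(prot_trends, trend_by_timepoint, design = design,
                      numeric(length(design$timepoints))))
  colnames(prot_tp) <- design$timepoints
  trend_class <- vapply(rownames(prot_tp), function(a) {
    s <- stage_summary(prot_tp[a, ])
    classify_protein_trend(s$mii / s$pro)$label
  }, character(1))
  protein_trends_df <- data.frame(accession = rownames(prot_tp),
                                  fc_mii_pro = apply(prot_tp, 1, function(v) {
                                    s <- stage_summary(stats::setNames(v, design$timepoints))
                                    s$mii / s$pro
                                  }),
                                  trend = trend_class, row.names = NULL,
                                  stringsAsFactors = FALSE)
  write_tsv(protein_trends_df, file.path(out_dir, "protein_trends.tsv"))

  ## 4. occupancy
  occ <- occupancy_batch(phos, design, proteome_table = prot,
                         n_boot = config$n_boot, epsilon = config$epsilon,
                         seed = seed + 3L, round_counts = config$noise)
  occ_df <- do.call(rbind, lapply(occ$trajectories, function(o)
    data.frame(site = o$site, timepoint = o$timepoints,
               occupancy = o$occupancy, ci_low = o$ci_low,
               ci_high = o$ci_high,
               flags = paste(o$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
  if (is.null(occ_df)) occ_df <- data.frame()
  write_tsv(occ_df, file.path(out_dir, "occupancy.tsv"))
  write_tsv(occ$exclusions, file.path(out_dir, "occupancy_exclusions.tsv"))

  ## 5. phosphosite dynamics classes (protein-normalized phospho trends)
  groups <- group_sites(phos)
  site_trends <- aggregate_groups(phos, groups, round_counts = config$noise)
  site_classes <- lapply(names(site_trends), function(key) {
    acc <- parse_site_key(key)$accession
    ph <- trend_by_timepoint(site_trends[[key]], design)
    pr <- if (acc %in% rownames(prot_tp))
      stats::setNames(prot_tp[acc, ], design$timepoints)
      else stats::setNames(rep(1, length(design$timepoints)), design$timepoints)
    s <- stage_summary(normalize_by_protein(ph, pr))
    cl <- assign_class(s)
    data.frame(site = key, log2fc_mi_pro = cl$log2fc_mi_pro,
               log2fc_mii_mi = cl$log2fc_mii_mi, class = cl$label,
               stringsAsFactors = FALSE)
  })
  site_classes <- do.call(rbind, site_classes)
  write_tsv(site_classes, file.path(out_dir, "site_classes.tsv"))

  ## 6. clustering (phospho trends and protein trends)
  phos_m <- t(vapply(site_trends, trend_by_timepoint, design = design,
                     numeric(length(design$timepoints))))
  k_p <- min(config$k_phospho, max(2L, nrow(phos_m) %/% 2L))
  k_r <- min(config$k_protein, max(2L, nrow(prot_tp) %/% 2L))
  cl_phos <- kmeans_cosine(phos_m, k_p, config$kmeans_restarts,
                           seed = seed + 4L)
  cl_prot <- kmeans_cosine(prot_tp, k_r, config$kmeans_restarts,
                           seed = seed + 5L)
  write_tsv(data.frame(site = rownames(phos_m), cluster = cl_phos$labels),
            file.path(out_dir, "clusters_phospho.tsv"))
  write_tsv(data.frame(accession = rownames(prot_tp),
                       cluster = cl_prot$labels),
            file.path(out_dir, "clusters_protein.tsv"))

  ## 7. degron census + enrichment of decreasing proteins
  seqs <- stats::setNames(truth$proteins$sequence, truth$proteins$accession)
  degrons <- do.call(rbind, lapply(names(seqs), function(a)
    scan_motifs(seqs[[a]], accession = a)))
  write_tsv(degrons, file.path(out_dir, "degron_hits.tsv"))
  annotation <- split(degrons$accession, degrons$motif)
  decreasing <- protein_trends_df$accession[
    protein_trends_df$trend == "decreasing"]
  enr <- if (length(decreasing))
    enrich(decreasing, annotation, protein_trends_df$accession)
    else data.frame()
  write_tsv(enr, file.path(out_dir, "enrichment_decreasing.tsv"))

  ## 8. absolute quantification (ion current proxied by summed peptide S/N)
  sn_cols <- grep("^sn_", names(prot), value = TRUE)
  ion <- tapply(rowSums(prot[, sn_cols]), prot$proteins, sum)
  masses <- stats::setNames(truth$proteins$mass_da, truth$proteins$accession)
  conc <- estimate_concentrations(as.numeric(ion) |>
                                    stats::setNames(names(ion)), masses)
  write_tsv(conc$estimates, file.path(out_dir, "concentrations.tsv"))

  ## 9. cross-species stand-in: match sites between L and S allo-alleles
  xsp <- xspecies_allo_match(truth, site_classes, config$e_threshold)
  write_tsv(xsp$matched, file.path(out_dir, "xspecies_matched.tsv"))

  ## manifest
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(truth = truth, tables = tabs, design = design,
                 occupancy = occ, site_classes = site_classes,
                 protein_trends = protein_trends_df,
                 clusters = list(phospho = cl_phos, protein = cl_prot),
                 enrichment = enr, concentrations = conc$estimates,
                 degrons = degrons, xspecies = xsp, manifest = manifest,
                 out_dir = out_dir))
}

## Treat the L and S homeologs as two "species": align each pair, map the
## measured sites across, and correlate their MII/PRO dynamics.
xspecies_allo_match <- function(truth, site_classes, e_threshold = 1e-20) {
  prot <- truth$proteins
  base <- sub("\\.[LS]$", "", prot$accession)
  pairs <- names(which(table(base) == 2))
  aln <- list()
  for (p in pairs) {
    sl <- prot$sequence[prot$accession == paste0(p, ".L")]
    ss <- prot$sequence[prot$accession == paste0(p, ".S")]
    aln[[p]] <- align_pair(sl, ss, paste0(p, ".L"), paste0(p, ".S"))
  }
  parsed <- lapply(site_classes$site, parse_site_key)
  sites <- data.frame(
    accession = vapply(parsed, `[[`, "", "accession"),
    position = vapply(parsed, function(x) x$positions[1], integer(1)),
    residue = vapply(parsed, function(x) x$residues[1], character(1)),
    log2fc = site_classes$log2fc_mi_pro + site_classes$log2fc_mii_mi,
    stringsAsFactors = FALSE)
  sitesL <- sites[grepl("\\.L:", paste0(sites$accession, ":")), , drop = FALSE]
  sitesS <- sites[grepl("\\.S:", paste0(sites$accession, ":")), , drop = FALSE]
  matched <- match_sites(sitesL, sitesS, aln, e_threshold = e_threshold)
  corr <- if (nrow(matched) >= 3 && stats::sd(matched$log2fc_a) > 0 &&
                stats::sd(matched$log2fc_b) > 0)
    correlate_dynamics(matched) else list(r = NA_real_, p = NA_real_,
                                          n = nrow(matched))
  list(alignments = aln, matched = matched, correlation = corr)
}
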