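test_that("seeded proteome generation is byte-reproducible", {
  a <- gen_proteome(1, c(30, 60), 0, seed = 7)
  b <- gen_proteome(1, c(30, 60), 0, seed = 7)
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$proteins, b$proteins)
})

test_that("allo-allele fraction controls L/S pair emission", {
  none <- gen_proteome(10, c(50, 80), 0, seed = 3)
  expect_false(any(grepl("\\.S$", none$proteins$accession)))

  all_pairs <- gen_proteome(10, c(200, 300), 1, seed = 3)
  acc <- all_pairs$proteins$accession
  expect_equal(sum(grepl("\\.S$", acc)), 5)
  expect_equal(sum(grepl("\\.L$", acc)), 5)
  ## pairwise identity >= 90% under the 5% substitution rate
  for (p in unique(sub("\\.[LS]$", "", acc))) {
    sl <- strsplit(all_pairs$proteins$sequence[acc == paste0(p, ".L")], "")[[1]]
    ss <- strsplit(all_pairs$proteins$sequence[acc == paste0(p, ".S")], "")[[1]]
    expect_gte(mean(sl == ss), 0.90)
  }
})

test_that("digestion follows the stated cleavage rules with coordinates", {
  d <- digest("AAKAAARPAAA", "trypsin", 0)
  expect_equal(d$peptide, c("AAK", "AAARPAAA"))
  expect_equal(d$start, c(1, 4))
  expect_equal(d$end, c(3, 11))

  d <- digest("AAKPAA", "lysC", 0)              # lysC cuts K-P
  expect_equal(d$peptide, c("AAK", "PAA"))

  expect_equal(digest("AAAGGGWWW", "trypsin", 0)$peptide, "AAAGGGWWW")
  expect_error(digest("AAK", "pepsin"), "arg")
})

test_that("digestion emits all missed-cleavage products consistent with slicing", {
  set.seed(42)
  for (i in 1:5) {
    sq <- paste(sample(c("A", "K", "R", "P", "S", "G"), 60, TRUE), collapse = "")
    d <- digest(sq, "trypsin", 2)
    expect_true(all(substring(sq, d$start, d$end) == d$peptide))
    expect_true(all(d$missed <= 2))
    ## zero-missed peptides tile the sequence
    d0 <- d[d$missed == 0, ]
    expect_equal(sum(nchar(d0$peptide)), nchar(sq))
  }
})

test_that("trajectory archetypes satisfy their class definitions with margin", {
  truth <- gen_proteome(40, c(150, 300), 0.3, seed = 5)
  truth <- simulate_trajectories(truth, design = default_design(), seed = 6)
  tp <- truth$design$timepoints
  for (i in seq_len(nrow(truth$sites))) {
    traj <- stats::setNames(truth$site_traj[i, ], tp)
    s <- stage_summary(traj)
    expect_identical(assign_class(s)$label, truth$sites$class[i])
  }
  ## every planted site indexes an S/T/Y residue
  for (i in seq_len(nrow(truth$sites))) {
    sq <- truth$proteins$sequence[truth$proteins$accession ==
                                    truth$sites$accession[i]]
    expect_true(substr(sq, truth$sites$position[i], truth$sites$position[i])
                %in% c("S", "T", "Y"))
  }
  expect_true(all(truth$site_traj >= 0 & truth$site_traj <= 1))
  expect_true(all(truth$protein_traj > 0))
})

test_that("class II and I archetype stage fold changes match their values", {
  arch <- meiophos:::site_class_archetypes()
  tp <- c(0, 2, 3, 4, 5, 6, 7, 8, 9)
  s2 <- stage_summary(stats::setNames(arch$II, tp))
  expect_equal(s2$log2fc_mi_pro, 3)       # log2(0.8 / 0.1)
  expect_equal(s2$log2fc_mii_mi, 0)
  s1 <- stage_summary(stats::setNames(arch$I, tp))
  expect_equal(s1$log2fc_mi_pro, -2)      # log2(0.15 / 0.6)
})

test_that("accumulating protein archetype doubles by the MII stage", {
  arch <- meiophos:::protein_trend_archetypes(c(0, 2, 3, 4, 5, 6, 7, 8, 9))
  s <- stage_summary(stats::setNames(arch$accumulating, c(0,2,3,4,5,6,7,8,9)))
  expect_equal(s$mii / s$pro, 2)
  s <- stage_summary(stats::setNames(arch$decreasing, c(0,2,3,4,5,6,7,8,9)))
  expect_equal(s$mii / s$pro, 0.5)
})

test_that("simulated reporter tables respect the counting model", {
  design <- default_design()
  truth <- gen_proteome(10, c(150, 300), 0, seed = 8)
  truth <- simulate_trajectories(truth, design = design, seed = 9)
  tabs <- simulate_tables(truth, depth = 500, seed = 10)
  sn_cols <- grep("^sn_", names(tabs$phospho), value = TRUE)
  m <- as.matrix(tabs$phospho[, sn_cols])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))          # integer counts at kappa = 1
  expect_true(all(rowSums(m) >= 1))
  expect_true(all(tabs$phospho$isolation_specificity >= 0.5 &
                    tabs$phospho$isolation_specificity <= 1))
  ## determinism
  tabs2 <- simulate_tables(truth, depth = 500, seed = 10)
  expect_identical(tabs, tabs2)
  ## roughly 1 - purity of phospho-table species are unmodified contaminants
  frac_unmod <- mean(!nzchar(tabs$phospho$phospho_positions))
  expect_gt(frac_unmod, 0.10)
  expect_lt(frac_unmod, 0.30)
})

test_that("anchor channels carry near-zero phospho and full unmod signal", {
  design <- default_design()
  r <- rep(1, 9); f <- rep(0.5, 9)
  ep <- expected_channel_intensity(design, r, f, "phospho", epsilon = 0)
  expect_equal(ep[10:11], c(0, 0))
  eu <- expected_channel_intensity(design, r, f, "unmod")
  ## anchors hold everything after dephosphorylation: loading x protein level
  expect_equal(eu[10], 100)
  expect_equal(eu[11], 100)
  ## constant occupancy 0.5, flat protein, equal loadings: uniform over
  ## regular channels
  expect_true(all(abs(ep[1:9] - ep[1]) < 1e-12))
})

test_that("empirical shares converge to model shares at high depth", {
  design <- default_design()
  truth <- gen_proteome(2, c(200, 300), 0, seed = 31)
  truth <- simulate_trajectories(truth, design = design, seed = 32)
  tabs <- simulate_tables(truth, depth = 1e6, sigma_log = 0, seed = 33)
  groups <- group_sites(tabs$phospho)
  key <- names(groups)[1]
  sn_cols <- grep("^sn_", names(tabs$phospho), value = TRUE)
  m <- as.matrix(tabs$phospho[groups[[key]], sn_cols])
  emp <- colSums(m) / sum(m)
  p <- parse_site_key(key)
  f <- truth$site_traj[key, ]
  r <- truth$protein_traj[p$accession, ]
  model <- expected_channel_intensity(design, r, f, "phospho", 1e-3)
  expect_lt(max(abs(emp - model / sum(model))), 0.005)
})
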