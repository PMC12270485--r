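hours9 <- c(0, 2, 3, 4, 5, 6, 7, 8, 9)

test_that("protein normalization rescales to PRO = 1", {
  tp <- c(0, 3, 4)
  ## phospho doubles, protein doubles -> flat
  n <- normalize_by_protein(stats::setNames(c(1, 2, 2), tp),
                            stats::setNames(c(1, 2, 2), tp))
  expect_equal(unname(n), c(1, 1, 1))
  ## protein flat -> phospho rescaled
  n <- normalize_by_protein(stats::setNames(c(2, 4, 8), tp),
                            stats::setNames(c(1, 1, 1), tp))
  expect_equal(unname(n), c(1, 2, 4))
  ## worked arithmetic: phospho (1,2,4), protein (1,1,2) -> (1,2,2)
  n <- normalize_by_protein(stats::setNames(c(1, 2, 4), tp),
                            stats::setNames(c(1, 1, 2), tp))
  expect_equal(unname(n), c(1, 2, 2))
  expect_error(normalize_by_protein(stats::setNames(c(1, 2, 4), tp),
                                    stats::setNames(c(0, 0, 0), tp)),
               "degenerate")
})

test_that("stage summary averages the stage hours and floors ratios", {
  flat <- stats::setNames(rep(1, 9), hours9)
  s <- stage_summary(flat)
  expect_equal(c(s$pro, s$mi, s$mii), c(1, 1, 1))
  expect_equal(c(s$log2fc_mi_pro, s$log2fc_mii_mi, s$log2fc_mii_pro),
               c(0, 0, 0))

  v <- stats::setNames(c(1, 1, 4, 4, 1, 1, 2, 2, 2), hours9)
  s <- stage_summary(v)
  expect_equal(s$pro, 1); expect_equal(s$mi, 4); expect_equal(s$mii, 2)
  expect_equal(s$log2fc_mi_pro, 2)
  expect_equal(s$log2fc_mii_mi, -1)

  expect_error(stage_summary(stats::setNames(rep(1, 8), c(0, 2, 3, 4, 5, 6, 7, 9))),
               "hours")

  z <- stats::setNames(c(0, 1, 1, 1, 1, 1, 1, 1, 1), hours9)
  s <- stage_summary(z)
  expect_true(s$floored)
  expect_true(is.finite(s$log2fc_mi_pro))
})

test_that("class assignment matches a hand-built truth table on the grid", {
  ## rows: log2fc_mi_pro in -3..3; cols: log2fc_mii_mi in -3..3
  truth_table <- rbind(
    c("I", "I", "I", "I", "I", "I", "I"),
    c("I", "I", "I", "I", "I", "I", "I"),
    rep("unclassified", 7),
    c(rep("unclassified", 5), "V", "V"),
    rep("unclassified", 7),
    c("III", "III", "unclassified", "II", "unclassified", "IV", "IV"),
    c("III", "III", "unclassified", "II", "unclassified", "IV", "IV"))
  for (i in 1:7) for (j in 1:7) {
    s <- list(log2fc_mi_pro = i - 4, log2fc_mii_mi = j - 4)
    expect_identical(assign_class(s)$label, truth_table[i, j],
                     label = sprintf("x=%d y=%d", i - 4, j - 4))
  }
  ## spot checks from the class definitions
  expect_identical(assign_class(list(log2fc_mi_pro = -1.5, log2fc_mii_mi = 0))$label, "I")
  expect_identical(assign_class(list(log2fc_mi_pro = 2, log2fc_mii_mi = 0))$label, "II")
  expect_identical(assign_class(list(log2fc_mi_pro = 2, log2fc_mii_mi = -2))$label, "III")
  expect_identical(assign_class(list(log2fc_mi_pro = 2, log2fc_mii_mi = 2))$label, "IV")
  expect_identical(assign_class(list(log2fc_mi_pro = 0.5, log2fc_mii_mi = 2))$label, "V")
  ## exact-threshold values are unclassified
  expect_identical(assign_class(list(log2fc_mi_pro = 1, log2fc_mii_mi = 0))$label,
                   "unclassified")
  expect_identical(assign_class(list(log2fc_mi_pro = 0, log2fc_mii_mi = 0))$label,
                   "unclassified")
})

test_that("protein trends split at the 1.5x and 0.75x thresholds", {
  expect_identical(classify_protein_trend(1.6)$label, "accumulating")
  expect_identical(classify_protein_trend(1.0)$label, "stable")
  expect_identical(classify_protein_trend(0.5)$label, "decreasing")
  expect_identical(classify_protein_trend(1.5)$label, "stable")
  expect_identical(classify_protein_trend(0.75)$label, "stable")
  expect_error(classify_protein_trend(0), "> 0")
})

test_that("planted classes are recovered through the full normalization path", {
  design <- default_design()
  truth <- gen_proteome(30, c(150, 400), 0, seed = 71)
  truth <- simulate_trajectories(truth, design = design, seed = 72)
  tabs <- simulate_tables(truth, depth = 1000, noise = FALSE, seed = 73)
  groups <- group_sites(tabs$phospho)
  st <- aggregate_groups(tabs$phospho, groups, round_counts = FALSE,
                         prior_alpha = 0)
  pg <- split(seq_len(nrow(tabs$proteome)), tabs$proteome$proteins)
  pt <- aggregate_groups(tabs$proteome, pg, round_counts = FALSE,
                         prior_alpha = 0)
  n_ok <- 0; n_tot <- 0
  for (key in names(st)) {
    acc <- parse_site_key(key)$accession
    ph <- trend_by_timepoint(st[[key]], design)
    pr <- trend_by_timepoint(pt[[acc]], design)
    cl <- assign_class(stage_summary(normalize_by_protein(ph, pr)))$label
    planted <- truth$sites$class[truth$sites$site_key == key]
    if (length(planted) == 1) {
      n_tot <- n_tot + 1
      if (cl == planted) n_ok <- n_ok + 1
    }
  }
  expect_gt(n_tot, 50)
  expect_equal(n_ok, n_tot)   # 100% recovery noise-free
})

test_that("cosine k-means reaches the brute-force optimum on small instances", {
  ## 6 points on 2 rays at different radii
  m <- rbind(c(1, 0.10), c(2, 0.20), c(3, 0.30),
             c(0.2, 1.0), c(0.4, 2.0), c(0.6, 3.0))
  km <- kmeans_cosine(m, 2, n_restarts = 50, seed = 1)
  expect_equal(km$objective, brute_force_cosine_kmeans(m, 2),
               tolerance = 1e-9)
  ## perfect separation of the two rays
  expect_equal(adjusted_rand_index(km$labels, c(1, 1, 1, 2, 2, 2)), 1)
  ## duplicated rows land in the same cluster
  expect_equal(km$labels[1], km$labels[2])
  ## largest cluster is labeled 1
  expect_true(which.max(km$sizes) == 1)
})

test_that("cosine k-means is invariant to row permutation up to relabeling", {
  set.seed(9)
  m <- rbind(matrix(rnorm(30, mean = 3), 10, 3),
             matrix(rnorm(30, mean = -3), 10, 3))
  km1 <- kmeans_cosine(m, 2, n_restarts = 20, seed = 5)
  perm <- sample(nrow(m))
  km2 <- kmeans_cosine(m[perm, ], 2, n_restarts = 20, seed = 6)
  expect_equal(adjusted_rand_index(km1$labels[perm], km2$labels), 1)
  expect_error(kmeans_cosine(rbind(c(0, 0), c(1, 1)), 2), "zero-norm")
  expect_error(kmeans_cosine(m, nrow(m) + 1), "k must be")
})

test_that("hypergeometric enrichment and BH adjustment are exact", {
  universe <- sprintf("g%02d", 1:20)
  members <- universe[1:10]
  annotation <- list(termA = universe[1:5],     # all 5 annotated in query
                     termB = universe[16:20])   # none in query
  out <- enrich(members, annotation, universe)
  pa <- out$p[out$term == "termA"]
  expect_equal(pa, 3003 / 184756, tolerance = 1e-12)
  expect_equal(out$p[out$term == "termB"], 1)   # k = 0 -> P(X >= 0) = 1
  expect_error(enrich(members, annotation, character(0)), "universe")
  expect_error(enrich(c(members, "zz"), annotation, universe), "subset")
})

test_that("enrichment FDR equals the hand-applied step-up procedure", {
  universe <- sprintf("g%02d", 1:30)
  members <- universe[1:12]
  set.seed(3)
  annotation <- lapply(1:6, function(i) sample(universe, 8))
  names(annotation) <- paste0("t", 1:6)
  out <- enrich(members, annotation, universe)
  p <- out$p  # ordered ascending by enrich()
  m <- length(p)
  step_up <- rev(cummin(rev(p * m / seq_len(m))))  # BH by hand
  expect_equal(out$fdr, pmin(step_up, 1))
})
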