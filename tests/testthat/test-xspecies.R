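test_that("identical sequences align as the identity mapping", {
  sq <- "MKRSAALDENSPQR"
  al <- align_pair(sq, sq)
  expect_equal(al$map$posA, seq_len(nchar(sq)))
  expect_equal(al$map$posB, seq_len(nchar(sq)))
  expect_true(al$evalue >= 0)
})

test_that("a single insertion shifts downstream coordinates by one", {
  al <- align_pair("MKSPR", "MKASPR")
  j <- match(3, al$map$posA)             # the S at A position 3
  expect_equal(al$map$posB[j], 4)        # maps to B position 4
  ## mapping strictly increasing on both sides
  expect_true(all(diff(al$map$posA) > 0))
  expect_true(all(diff(al$map$posB) > 0))
})

test_that("Karlin-Altschul E-value arithmetic is reproduced", {
  ## K = 0.041, lambda = 0.267, m = n = 100, S = 50
  e <- 0.041 * 100 * 100 * exp(-0.267 * 50)
  expect_equal(e, 6.5e-4, tolerance = 0.01)
  ## align_pair applies the same formula to its own score
  al <- align_pair("MKSPRLLE", "MKSPRLLE", karlin_lambda = 0.267,
                   karlin_k = 0.041)
  expect_equal(al$evalue,
               0.041 * 8 * 8 * exp(-0.267 * al$score))
})

test_that("substitution matrices load from package data and Biostrings", {
  b90 <- load_substitution_matrix("BLOSUM90")
  expect_equal(b90["A", "A"], 5)
  expect_equal(b90["W", "W"], 11)
  expect_true(isSymmetric(b90[1:20, 1:20]))
  b62 <- load_substitution_matrix("BLOSUM62")
  expect_equal(b62["A", "A"], 4)
  expect_error(load_substitution_matrix("NOSUCH"), "unknown")
})

test_that("site matching applies alignment, residue and E-value rules", {
  sqA <- "MKRSAALDENSPQRWWAADEKLMNPQ"
  sqB <- sub("^MKR", "MKAR", sqA)        # insert A at position 3
  al <- align_pair(sqA, sqB, accA = "a1", accB = "b1")
  sitesA <- data.frame(accession = "a1", position = 4, residue = "S",
                       log2fc = 1.5)
  sitesB <- data.frame(accession = "b1", position = 5, residue = "S",
                       log2fc = 1.2)
  ## identical toy pair with one shared site -> 1 match
  m <- match_sites(sitesA, sitesB, list(al), e_threshold = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos_b, 5)

  ## S <-> T at the aligned position: excluded under the identity rule
  sitesB_T <- transform(sitesB, residue = "T")
  expect_equal(nrow(match_sites(sitesA, sitesB_T, list(al), e_threshold = 1)), 0)
  expect_equal(nrow(match_sites(sitesA, sitesB_T, list(al), e_threshold = 1,
                                require_identical_residue = FALSE)), 1)

  ## E-value filter is strict: E = threshold is excluded
  al_fail <- al; al_fail$evalue <- 1e-19
  expect_equal(nrow(match_sites(sitesA, sitesB, list(al_fail),
                                e_threshold = 1e-19)), 0)
  ## raw-score mode is the deterministic alternative
  expect_equal(nrow(match_sites(sitesA, sitesB, list(al_fail),
                                score_threshold = al$score - 1)), 1)

  ## grouped B-side accessions resolve to the aligned protein
  sitesB_grp <- transform(sitesB, accession = "bx;b1")
  m <- match_sites(sitesA, sitesB_grp, list(al), e_threshold = 1)
  expect_equal(m$acc_b, "b1")
})

test_that("site matching is symmetric in the two datasets", {
  truth <- gen_proteome(8, c(120, 200), 1, seed = 91)
  acc <- truth$proteins$accession
  base <- unique(sub("\\.[LS]$", "", acc))
  aln_f <- list(); aln_r <- list()
  sitesL <- list(); sitesS <- list()
  set.seed(92)
  for (p in base) {
    sl <- truth$proteins$sequence[acc == paste0(p, ".L")]
    ss <- truth$proteins$sequence[acc == paste0(p, ".S")]
    aln_f[[p]] <- align_pair(sl, ss, paste0(p, ".L"), paste0(p, ".S"))
    aln_r[[p]] <- align_pair(ss, sl, paste0(p, ".S"), paste0(p, ".L"))
    ## plant sites at shared S residues
    pos <- which(strsplit(sl, "")[[1]] == "S")
    pos <- pos[pos <= nchar(ss)]
    take <- head(pos, 3)
    sitesL[[p]] <- data.frame(accession = paste0(p, ".L"), position = take,
                              residue = "S", log2fc = rnorm(length(take)))
    sitesS[[p]] <- data.frame(accession = paste0(p, ".S"), position = take,
                              residue = substr(rep(ss, length(take)), take, take),
                              log2fc = rnorm(length(take)))
  }
  sl <- do.call(rbind, sitesL); ss_df <- do.call(rbind, sitesS)
  fwd <- match_sites(sl, ss_df, aln_f, e_threshold = 1)
  rev <- match_sites(ss_df, sl, aln_r, e_threshold = 1)
  key_f <- paste(fwd$acc_a, fwd$pos_a, fwd$acc_b, fwd$pos_b)
  key_r <- paste(rev$acc_b, rev$pos_b, rev$acc_a, rev$pos_a)
  expect_setequal(key_f, key_r)
  expect_gt(nrow(fwd), 0)
})

test_that("dynamics correlation reproduces Pearson arithmetic", {
  m <- data.frame(log2fc_a = c(1, 2, 3), log2fc_b = c(2, 4, 6))
  expect_equal(correlate_dynamics(m)$r, 1)
  m$log2fc_b <- -m$log2fc_a
  expect_equal(correlate_dynamics(m)$r, -1)
  m2 <- data.frame(log2fc_a = c(1, 2, 3), log2fc_b = c(1, 3, 2))
  out <- correlate_dynamics(m2)
  expect_equal(out$r, 0.5)               # sum(dx dy) / sqrt(sum dx^2 sum dy^2)
  expect_equal(out$n, 3)
  expect_error(correlate_dynamics(data.frame(log2fc_a = 1:2, log2fc_b = 2:3)),
               "at least 3")
  expect_error(correlate_dynamics(data.frame(log2fc_a = c(1, 1, 1),
                                             log2fc_b = 1:3)), "variance")
})
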