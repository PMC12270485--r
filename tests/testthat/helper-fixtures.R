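## shared fixtures and small independent oracles

## minimal 3-channel design: t0 regular, t9 regular, one pure-t9 anchor
design_3ch <- function() {
  ch <- data.frame(channel = c("t0", "t9", "anc"),
                   type = c("regular", "regular", "anchor"),
                   timepoint = c(1, 2, NA), loading = c(1, 1, 1))
  w <- matrix(0, 3, 2); w[3, 2] <- 1
  plex_design(c(0, 9), ch, w, replicates = 1L)
}

## wrap a bare share vector as a share_trend (tight nominal intervals)
fake_trend <- function(shares, spread = 1e-3, n_eff = 1e6) {
  shares <- shares / sum(shares)
  structure(list(shares = shares,
                 ci_low = pmax(shares - spread, 0),
                 ci_high = pmin(shares + spread, 1),
                 alpha = n_eff * shares,
                 effective_counts = n_eff, n_peptides = 1L,
                 overdispersion = 1, level = 0.95,
                 channels = NULL),
            class = "share_trend")
}

## small peptide table builder
toy_table <- function(design, rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  df$peptide_id <- sprintf("pep%03d", seq_len(nrow(df)))
  as_peptide_table(df, design)
}

toy_row <- function(design, sequence, proteins, start, phospho = integer(0),
                    sn = NULL, iso = 1, replicate = 1L) {
  if (is.null(sn)) sn <- rep(10, nrow(design$channels))
  r <- list(sequence = sequence, proteins = proteins, start = start,
            end = start + nchar(sequence) - 1L,
            phospho_positions = paste(phospho, collapse = ";"),
            replicate = replicate, isolation_specificity = iso)
  for (i in seq_along(sn)) r[[paste0("sn_", design$channels$channel[i])]] <- sn[i]
  r
}

## grid-integration oracle for a 2-channel Dirichlet-multinomial posterior:
## density prop. p^(a1-1) (1-p)^(a2-1) evaluated on a fine grid
beta_grid_oracle <- function(x1, x2, prior_alpha = 1, n_grid = 200001L) {
  ## substitution p = v^2 (3 - 2v) clusters grid points near both
  ## boundaries, where the density can be steep; integrate in v
  v <- seq(0, 1, length.out = n_grid)
  p <- v^2 * (3 - 2 * v)
  jac <- 6 * v * (1 - v)
  e1 <- x1 + prior_alpha - 1
  e2 <- x2 + prior_alpha - 1
  logd <- (if (e1 == 0) 0 else e1 * log(p)) +
    (if (e2 == 0) 0 else e2 * log1p(-p))
  d <- exp(logd - max(logd[is.finite(logd)]))
  d[!is.finite(d)] <- 0
  g <- d * jac                                   # density wrt v
  h <- v[2] - v[1]
  cdf <- cumsum((g + c(0, g[-n_grid])) / 2) * h  # trapezoid in v
  z <- cdf[n_grid]
  mean_p <- sum(((p * g) + c(0, (p * g)[-n_grid])) / 2) * h / z
  keep <- !duplicated(cdf)
  qfun <- function(q) {
    vq <- stats::approx(cdf[keep] / z, v[keep], xout = q)$y
    vq^2 * (3 - 2 * vq)
  }
  list(mean = mean_p, q025 = qfun(0.025), q975 = qfun(0.975))
}

## adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## brute-force spherical k-means optimum by labeling enumeration (k = 2)
brute_force_cosine_kmeans <- function(m, k = 2) {
  x <- m / sqrt(rowSums(m^2))
  n <- nrow(x)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < k) next
    obj <- 0
    for (j in 1:k) {
      xs <- x[lab == j, , drop = FALSE]
      mu <- colMeans(xs)
      nmu <- sqrt(sum(mu^2))
      obj <- obj + sum(1 - (xs %*% mu) / nmu)
    }
    if (obj < best) best <- obj
  }
  best
}
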