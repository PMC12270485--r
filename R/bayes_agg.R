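## Dirichlet-multinomial aggregation of peptide reporter-ion counts into a
## posterior channel-share trend with credible intervals. Between-peptide
## disagreement is absorbed by a method-of-moments overdispersion factor that
## deflates the pooled counts, so concordant peptides tighten the interval
## and discordant ones widen it — the role hierarchical reporter-ion models
## play in TMT pipelines, here in conjugate closed form.

#' Convert signal-to-noise values to ion counts
#'
#' Reporter S/N is proportional to the number of ions detected; `kappa` is
#' the ions-per-S/N conversion factor of the instrument.
#'
#' @param sn Numeric vector or matrix of nonnegative S/N values.
#' @param kappa Conversion factor (default 1).
#' @return Nonnegative integers, `round(kappa * sn)` (half-to-even).
#' @export
sn_to_counts <- function(sn, kappa = 1.0) {
  if (any(sn < 0)) stop("signal-to-noise values must be nonnegative")
  round(kappa * sn)
}

#' Method-of-moments overdispersion of peptide share vectors
#'
#' Pearson chi-square of the per-peptide count rows about the pooled share,
#' divided by its degrees of freedom (n_rows - 1)(n_channels - 1), floored
#' at 1. A single row, or perfectly concordant rows, give 1.
#'
#' @param counts Matrix of counts, rows = peptide measurements.
#' @return Overdispersion phi >= 1.
#' @export
estimate_overdispersion <- function(counts) {
  counts <- rbind(counts)
  if (nrow(counts) < 1) stop("need at least one row")
  if (nrow(counts) == 1) return(1)
  tot <- rowSums(counts)
  keep <- tot > 0
  counts <- counts[keep, , drop = FALSE]
  tot <- tot[keep]
  if (nrow(counts) < 2) return(1)
  p <- colSums(counts) / sum(counts)
  expd <- outer(tot, p)
  ok <- expd > 0
  chi2 <- sum(((counts - expd)^2 / ifelse(ok, expd, 1))[ok])
  df <- (nrow(counts) - 1) * (sum(p > 0) - 1)
  if (df <= 0) return(1)
  max(1, chi2 / df)
}

#' Aggregate count rows into a posterior share trend
#'
#' Conjugate update: posterior = Dirichlet(`prior_alpha` + colSums(counts)/phi)
#' where phi is the estimated overdispersion ([estimate_overdispersion()]),
#' unless supplied. Shares are the posterior mean; per-channel equal-tailed
#' credible intervals come from the marginal Beta distributions.
#'
#' @param counts Matrix (rows = peptide measurements) or vector of counts.
#' @param prior_alpha Symmetric Dirichlet prior (default 1, flat).
#' @param level Credible level (default 0.95).
#' @param phi Overdispersion; `NULL` (default) estimates it from the rows.
#' @param channels Optional channel names.
#' @return A `share_trend`: list(shares, ci_low, ci_high, alpha (posterior
#'   Dirichlet parameters), effective_counts, n_peptides, overdispersion,
#'   level, channels).
#' @export
aggregate_counts <- function(counts, prior_alpha = 1.0, level = 0.95,
                             phi = NULL, channels = NULL) {
  counts <- rbind(counts)
  if (!nrow(counts)) stop("need at least one row")
  if (all(counts == 0)) stop("degenerate input: all counts are zero")
  if (is.null(phi)) phi <- estimate_overdispersion(counts)
  eff <- colSums(counts) / phi
  alpha <- prior_alpha + eff
  a0 <- sum(alpha)
  q <- (1 - level) / 2
  trend <- list(
    shares = alpha / a0,
    ci_low = stats::qbeta(q, alpha, a0 - alpha),
    ci_high = stats::qbeta(1 - q, alpha, a0 - alpha),
    alpha = alpha,
    effective_counts = sum(eff),
    n_peptides = nrow(counts),
    overdispersion = phi,
    level = level,
    channels = if (is.null(channels)) colnames(counts) else channels)
  class(trend) <- "share_trend"
  trend
}

#' @export
print.share_trend <- function(x, ...) {
  cat("Share trend over", length(x$shares), "channels;",
      x$n_peptides, "peptide rows; phi =", signif(x$overdispersion, 3),
      "; effective counts =", round(x$effective_counts, 1), "\n")
  m <- rbind(share = x$shares, ci_low = x$ci_low, ci_high = x$ci_high)
  colnames(m) <- x$channels
  print(round(m, 4))
  invisible(x)
}

#' Aggregate a peptide table into per-group share trends
#'
#' @param table A `peptide_table`.
#' @param groups Named list of row-index vectors (e.g. from [group_sites()],
#'   or split by protein accession).
#' @param kappa S/N-to-counts conversion (default 1).
#' @param prior_alpha,level Passed to [aggregate_counts()].
#' @param round_counts Round `kappa * sn` to integers (default). Set `FALSE`
#'   for noise-free synthetic tables where the S/N values are exact
#'   expectations and rounding would itself inject noise.
#' @return Named list of `share_trend` objects.
#' @export
aggregate_groups <- function(table, groups, kappa = 1.0, prior_alpha = 1.0,
                             level = 0.95, round_counts = TRUE) {
  sn_cols <- grep("^sn_", names(table), value = TRUE)
  lapply(groups, function(idx) {
    m <- as.matrix(table[idx, sn_cols, drop = FALSE])
    m <- if (round_counts) sn_to_counts(m, kappa) else kappa * m
    aggregate_counts(m, prior_alpha = prior_alpha, level = level,
                     channels = sub("^sn_", "", sn_cols))
  })
}
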