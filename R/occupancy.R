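## Phosphatase-anchored phospho-occupancy estimation.
##
## Forward model for the normalized share vectors of the two molecular forms
## of a site (phospho / unmodified) across channels, with f_t the occupancy
## at timepoint t, r_t the relative protein level, L_c the channel loading:
##   regular channel c at t:  phospho share  prop. L_c r_t f_t
##                            unmod  share  prop. L_c r_t (1 - f_t)
##   anchor channel d:        phospho share  prop. eps * L_d sum_t w_dt r_t
##                            unmod  share  prop. L_d sum_t w_dt r_t
## The anchors (phosphatase-treated, occupancy ~0) pin the absolute scale of
## the unmodified form and make f identifiable from relative shares.
##
## Estimator: joint weighted least squares on the two normalized share
## vectors (box-constrained quasi-Newton with analytic gradient), started
## from a closed-form anchor back-substitution. Exact on noise-free
## forward-model data.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

## per-timepoint protein level from a protein share trend (regular channels)
protein_level_from_trend <- function(shares, design) {
  ch <- design$channels
  r <- vapply(seq_along(design$timepoints), function(t) {
    i <- which(ch$type == "regular" & ch$timepoint == t)
    mean(shares[i] / ch$loading[i])
  }, numeric(1))
  r / mean(r)
}

## geometry of the fit, precomputed once per (design, r)
occ_geometry <- function(r, design, epsilon) {
  ch <- design$channels
  reg <- which(ch$type == "regular")
  anc <- which(ch$type == "anchor")
  t_of <- ch$timepoint[reg]
  n_tp <- length(design$timepoints)
  Lr <- ch$loading[reg] * r[t_of]               # L_c r_t per regular channel
  A <- ch$loading[anc] *
    as.numeric(design$anchor_weights[anc, , drop = FALSE] %*% r)
  G <- matrix(0, length(reg), n_tp)             # regular channel -> timepoint
  G[cbind(seq_along(reg), t_of)] <- 1
  list(reg = reg, anc = anc, t_of = t_of, n_tp = n_tp, Lr = Lr, A = A,
       sumA = sum(A), S_t = as.numeric(Lr %*% G), G = G, epsilon = epsilon)
}

occ_predict <- function(f, geom) {
  D_p <- sum(geom$Lr * f[geom$t_of]) + geom$epsilon * geom$sumA
  D_u <- sum(geom$Lr * (1 - f[geom$t_of])) + geom$sumA
  nch <- length(geom$reg) + length(geom$anc)
  p_hat <- u_hat <- numeric(nch)
  p_hat[geom$reg] <- geom$Lr * f[geom$t_of] / D_p
  p_hat[geom$anc] <- geom$epsilon * geom$A / D_p
  u_hat[geom$reg] <- geom$Lr * (1 - f[geom$t_of]) / D_u
  u_hat[geom$anc] <- geom$A / D_u
  list(p = p_hat, u = u_hat, D_p = D_p, D_u = D_u)
}

occ_objective <- function(f, geom, p_obs, u_obs, w_p, w_u) {
  pr <- occ_predict(f, geom)
  sum(w_p * (p_obs - pr$p)^2) + sum(w_u * (u_obs - pr$u)^2)
}

occ_gradient <- function(f, geom, p_obs, u_obs, w_p, w_u) {
  pr <- occ_predict(f, geom)
  e_p <- p_obs - pr$p
  e_u <- u_obs - pr$u
  wep <- w_p * e_p; weu <- w_u * e_u
  term_p <- as.numeric((wep[geom$reg] * geom$Lr) %*% geom$G) -
    geom$S_t * sum(wep * pr$p)
  term_u <- -as.numeric((weu[geom$reg] * geom$Lr) %*% geom$G) +
    geom$S_t * sum(weu * pr$u)
  -2 * (term_p / pr$D_p + term_u / pr$D_u)
}

## anchor back-substitution: u_d = A_d / D_u  =>  D_u = A_d / u_d; then
## 1 - f_t = u_c D_u / (L_c r_t). Exact on noise-free data; the WLS start.
occ_backsub_init <- function(u_obs, geom, w_u) {
  ud <- u_obs[geom$anc]
  ok <- ud > 0
  if (!any(ok)) stop("anchor unmodified signal is zero; cannot anchor scale")
  D_u <- sum(w_u[geom$anc][ok] * (geom$A[ok] / ud[ok])) / sum(w_u[geom$anc][ok])
  fi <- 1 - (u_obs[geom$reg] * D_u) / geom$Lr
  f0 <- as.numeric((fi * 1) %*% geom$G) / colSums(geom$G)
  pmin(1, pmax(0, f0))
}

## joint WLS fit of the occupancy trajectory (box-constrained quasi-Newton
## with analytic gradient; the objective has a unique practical minimum and
## is exactly zero on noise-free forward-model data)
fit_occupancy <- function(p_obs, u_obs, r, design, w_p, w_u, epsilon,
                          f_init = NULL) {
  g <- occ_geometry(r, design, epsilon)
  if (is.null(f_init)) f_init <- occ_backsub_init(u_obs, g, w_u)
  opt <- stats::optim(f_init, occ_objective, occ_gradient,
                      geom = g, p_obs = p_obs, u_obs = u_obs,
                      w_p = w_p, w_u = w_u,
                      method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(factr = 10, maxit = 200))
  list(f = opt$par, residual = opt$value,
       D_u = occ_predict(opt$par, g)$D_u)
}

ci_weights <- function(trend) {
  hw <- pmax((trend$ci_high - trend$ci_low) / 2, 1e-6)
  1 / hw^2
}

#' Estimate absolute phospho-occupancy per timepoint
#'
#' Fits the anchor-identified forward model (see the package vignette) to the
#' phospho-form and unmodified-form share trends of one site by weighted
#' least squares, weights the inverse squared credible-interval half-widths.
#' Credible intervals come from refitting on `n_boot` draws from the
#' Dirichlet posteriors of the input trends (2.5/97.5 percentiles at the
#' default level).
#'
#' @param phospho `share_trend` of the phosphorylated form.
#' @param unmod `share_trend` of the unmodified partner peptides.
#' @param protein `share_trend` of total protein level, or `NULL` for a
#'   uniform protein trend (flagged).
#' @param design A [plex_design()] with at least one anchor channel.
#' @param n_boot Posterior-resampling draws for the CI (default 500).
#' @param epsilon Anchor phospho leakage fraction (default 1e-3).
#' @param seed Integer seed for the resampling.
#' @param site Optional site key carried through to the result.
#' @return An `occupancy_trajectory`: list(site, timepoints, occupancy,
#'   ci_low, ci_high, fit_residual, flags).
#' @export
estimate_occupancy <- function(phospho, unmod, protein = NULL, design,
                               n_boot = 500L, epsilon = 1e-3, seed = 1L,
                               site = NA_character_) {
  if (!any(design$channels$type == "anchor"))
    stop("absolute occupancy requires a phosphatase anchor channel")
  nch <- n_channels(design)
  if (length(phospho$shares) != nch || length(unmod$shares) != nch)
    stop("trend channel dimension does not match design")
  flags <- character(0)
  if (is.null(protein)) {
    r <- rep(1, length(design$timepoints))
    flags <- c(flags, "protein-uniform")
  } else {
    r <- protein_level_from_trend(protein$shares, design)
  }
  w_p <- ci_weights(phospho)
  w_u <- ci_weights(unmod)
  fit <- fit_occupancy(phospho$shares, unmod$shares, r, design,
                       w_p, w_u, epsilon)

  ## clipping flag: how far did the unconstrained per-t estimates overshoot
  anc <- which(design$channels$type == "anchor")
  if (length(anc) >= 2) {
    du <- design$channels$loading[anc] *
      as.numeric(design$anchor_weights[anc, , drop = FALSE] %*% r) /
      pmax(unmod$shares[anc], 1e-12)
    if (max(du) / min(du) > 1.1) flags <- c(flags, "anchor-inconsistent")
  }

  boot <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    P <- rdirichlet(n_boot, phospho$alpha)
    U <- rdirichlet(n_boot, unmod$alpha)
    Rmat <- if (is.null(protein)) {
      matrix(r, n_boot, length(design$timepoints), byrow = TRUE)
    } else {
      draws <- rdirichlet(n_boot, protein$alpha)
      t(apply(draws, 1, protein_level_from_trend, design = design))
    }
    boot <- matrix(NA_real_, n_boot, length(design$timepoints))
    for (b in seq_len(n_boot))
      boot[b, ] <- fit_occupancy(P[b, ], U[b, ], Rmat[b, ], design,
                                 w_p, w_u, epsilon)$f
  }
  ci_l <- ci_h <- rep(NA_real_, length(design$timepoints))
  if (!is.null(boot)) {
    ci_l <- pmin(fit$f, apply(boot, 2, stats::quantile, probs = 0.025))
    ci_h <- pmax(fit$f, apply(boot, 2, stats::quantile, probs = 0.975))
  }
  structure(list(site = site, timepoints = design$timepoints,
                 occupancy = fit$f, ci_low = ci_l, ci_high = ci_h,
                 fit_residual = fit$residual, flags = flags),
            class = "occupancy_trajectory")
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat("Occupancy trajectory", if (!is.na(x$site)) paste0("(", x$site, ")"),
      "\n")
  m <- rbind(occupancy = x$occupancy, ci_low = x$ci_low, ci_high = x$ci_high)
  colnames(m) <- paste0(x$timepoints, "h")
  print(round(m, 3))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Batch occupancy over all site sets of a phospho table
#'
#' Builds site sets ([build_site_sets()]), aggregates the phospho form per
#' set and the unmodified partners ([match_unmodified()]) from the same
#' table, takes protein trends from an aggregated proteome table when
#' available (uniform otherwise, flagged), and estimates occupancy per set.
#' Sites whose unmodified form was never measured are excluded and reported,
#' not errored.
#'
#' @param phospho_table `peptide_table` from the phospho-enrichment run
#'   (single accession per row; its unmodified contaminant rows supply the
#'   partner peptides).
#' @param design A [plex_design()].
#' @param proteome_table Optional `peptide_table` of the proteome run, used
#'   for protein trends.
#' @param n_boot,epsilon,seed Passed to [estimate_occupancy()].
#' @param round_counts,prior_alpha Passed to [aggregate_groups()]. A flat
#'   prior (`prior_alpha = 1`, the default) shrinks shares by O(1/total
#'   counts); use `prior_alpha = 0` with noise-free synthetic tables when
#'   exact recovery is the point.
#' @return list(trajectories = named list of `occupancy_trajectory`,
#'   exclusions = data.frame(site, reason)).
#' @export
occupancy_batch <- function(phospho_table, design, proteome_table = NULL,
                            n_boot = 500L, epsilon = 1e-3, seed = 1L,
                            round_counts = TRUE, prior_alpha = 1.0) {
  sets <- build_site_sets(phospho_table)
  groups <- group_sites(phospho_table)

  ## all measured site positions per accession: an unmodified partner that
  ## spans a phosphosite outside the current set is an ambiguous form (its
  ## abundance also tracks that other site's occupancy) and is not used
  all_pos <- list()
  for (key in names(groups)) {
    p <- parse_site_key(key)
    all_pos[[p$accession]] <- sort(unique(c(all_pos[[p$accession]],
                                            p$positions)))
  }

  protein_trends <- list()
  if (!is.null(proteome_table)) {
    by_acc <- split(seq_len(nrow(proteome_table)), proteome_table$proteins)
    protein_trends <- aggregate_groups(proteome_table, by_acc,
                                       round_counts = round_counts,
                                       prior_alpha = prior_alpha)
  }
  trajectories <- list()
  excl <- list()
  for (i in seq_along(sets)) {
    keys <- sets[[i]]
    parsed <- lapply(keys, parse_site_key)
    acc <- parsed[[1]]$accession
    pos <- sort(unique(unlist(lapply(parsed, `[[`, "positions"))))
    res <- vapply(pos, function(p) {
      for (q in parsed) {
        j <- match(p, q$positions)
        if (!is.na(j)) return(q$residues[j])
      }
      "S"
    }, character(1))
    unit_key <- site_key(acc, res, pos)
    rows_p <- sort(unique(unlist(groups[keys])))
    rows_u <- match_unmodified(list(accession = acc, positions = pos),
                               phospho_table)
    if (!length(rows_u)) {
      excl[[length(excl) + 1]] <- data.frame(
        site = unit_key, reason = "no unmodified form measured",
        stringsAsFactors = FALSE)
      next
    }
    other <- setdiff(all_pos[[acc]], pos)
    if (length(other)) {
      exclusive <- vapply(rows_u, function(rw)
        !any(other >= phospho_table$start[rw] &
               other <= phospho_table$end[rw]), logical(1))
      rows_u <- rows_u[exclusive]
    }
    if (!length(rows_u)) {
      excl[[length(excl) + 1]] <- data.frame(
        site = unit_key,
        reason = "unmodified form overlaps another phosphosite",
        stringsAsFactors = FALSE)
      next
    }
    tr <- aggregate_groups(phospho_table,
                           list(p = rows_p, u = rows_u),
                           round_counts = round_counts,
                           prior_alpha = prior_alpha)
    ptrend <- protein_trends[[acc]]
    traj <- tryCatch(
      estimate_occupancy(tr$p, tr$u, ptrend, design, n_boot = n_boot,
                         epsilon = epsilon, seed = seed + i,
                         site = unit_key),
      error = function(e) e)
    if (inherits(traj, "error")) {
      excl[[length(excl) + 1]] <- data.frame(
        site = unit_key, reason = conditionMessage(traj),
        stringsAsFactors = FALSE)
    } else {
      trajectories[[unit_key]] <- traj
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(site = character(0), reason = character(0))
  list(trajectories = trajectories, exclusions = exclusions)
}
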