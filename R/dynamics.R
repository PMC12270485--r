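## Stage summaries, dynamics classification, cosine k-means clustering and
## annotation-set enrichment for time-course trends.
##
## Stages: PRO = 0 h (prophase arrest), MI = average of 3 and 4 h (around
## nuclear envelope breakdown / first metaphase), MII = average of 7-9 h
## (second-metaphase arrest). Phosphosite classes I-V are defined by strict
## +-1 thresholds on Log2FC(MI/PRO) and Log2FC(MII/MI); protein trends by
## 1.5x / 0.75x thresholds on FC(MII/PRO).

LOG2_FLOOR <- 1e-4

#' Per-timepoint relative trend from a channel share trend
#'
#' Averages `share / loading` over the regular channels of each timepoint
#' (anchor channels carry pooled material and are ignored).
#'
#' @param trend A `share_trend` (or bare share vector).
#' @param design A [plex_design()].
#' @return Named numeric vector keyed by timepoint hours.
#' @export
trend_by_timepoint <- function(trend, design) {
  shares <- if (inherits(trend, "share_trend")) trend$shares else trend
  ch <- design$channels
  v <- vapply(seq_along(design$timepoints), function(t) {
    i <- which(ch$type == "regular" & ch$timepoint == t)
    mean(shares[i] / ch$loading[i])
  }, numeric(1))
  stats::setNames(v, design$timepoints)
}

#' Normalize a phospho trend by the protein-level trend
#'
#' Removes changes in total protein so that what remains reflects
#' phosphorylation: n_t = (phospho_t / protein_t) / (phospho_0 / protein_0),
#' i.e. rescaled to 1 at PRO. Protein values are floored at `r LOG2_FLOOR`.
#'
#' @param phospho,protein Named numeric trends over the same timepoints.
#' @return Named numeric normalized trend with PRO = 1.
#' @export
normalize_by_protein <- function(phospho, protein) {
  if (length(phospho) != length(protein))
    stop("trends must cover the same timepoints")
  if (all(protein <= 0)) stop("degenerate input: protein trend is all zero")
  pr <- pmax(protein, LOG2_FLOOR)
  ratio <- phospho / pr
  if (ratio[1] <= 0) stop("phospho signal at PRO is zero; cannot rescale")
  stats::setNames(ratio / ratio[1], names(phospho))
}

#' Summarize a trend into the three meiotic stages
#'
#' @param trend Named numeric vector keyed by hours; hours 0, 3, 4, 7, 8, 9
#'   must be present.
#' @return list(pro, mi, mii, log2fc_mi_pro, log2fc_mii_mi, log2fc_mii_pro,
#'   floored). Values are floored at `r LOG2_FLOOR` before ratios (flagged in
#'   `floored`) so the log2 fold changes are always finite.
#' @export
stage_summary <- function(trend) {
  h <- as.numeric(names(trend))
  need <- c(0, 3, 4, 7, 8, 9)
  if (anyNA(h) || !all(need %in% h))
    stop("trend must be keyed by hours including ",
         paste(need, collapse = ","))
  val <- function(hh) mean(trend[match(hh, h)])
  pro <- val(0); mi <- val(c(3, 4)); mii <- val(c(7, 8, 9))
  floored <- any(c(pro, mi, mii) < LOG2_FLOOR)
  fl <- function(x) max(x, LOG2_FLOOR)
  list(pro = pro, mi = mi, mii = mii,
       log2fc_mi_pro = log2(fl(mi) / fl(pro)),
       log2fc_mii_mi = log2(fl(mii) / fl(mi)),
       log2fc_mii_pro = log2(fl(mii) / fl(pro)),
       floored = floored)
}

#' Assign one of the five phosphosite dynamics classes
#'
#' With x = Log2FC(MI/PRO) and y = Log2FC(MII/MI), all inequalities strict:
#' Class I: x < -1 (dephosphorylated on meiosis resumption).
#' Class II: x > 1 and -1 < y < 1 (phosphorylated from MI, stays high).
#' Class III: x > 1 and y < -1 (MI-specific peak).
#' Class IV: x > 1 and y > 1 (keeps rising to MII).
#' Class V: -1 < x < 1 and y > 1 (MII-specific).
#' Anything else — including values exactly on a threshold — is unclassified.
#'
#' @param s A [stage_summary()] (or any list with the two log2 fields).
#' @return list(label, log2fc_mi_pro, log2fc_mii_mi); label is one of
#'   `"I".."V"`, `"unclassified"`.
#' @export
assign_class <- function(s) {
  x <- s$log2fc_mi_pro; y <- s$log2fc_mii_mi
  if (!is.finite(x) || !is.finite(y)) stop("log2 fold changes must be finite")
  label <-
    if (x < -1) "I"
    else if (x > 1 && y > -1 && y < 1) "II"
    else if (x > 1 && y < -1) "III"
    else if (x > 1 && y > 1) "IV"
    else if (x > -1 && x < 1 && y > 1) "V"
    else "unclassified"
  list(label = label, log2fc_mi_pro = x, log2fc_mii_mi = y)
}

#' Classify a protein's accumulation trend
#'
#' @param fc_mii_pro Fold change of protein level between MII and PRO (> 0).
#' @return list(label, fc_mii_pro); accumulating iff FC > 1.5, decreasing iff
#'   FC < 0.75, stable otherwise.
#' @export
classify_protein_trend <- function(fc_mii_pro) {
  if (fc_mii_pro <= 0) stop("fold change must be > 0")
  label <- if (fc_mii_pro > 1.5) "accumulating"
           else if (fc_mii_pro < 0.75) "decreasing"
           else "stable"
  list(label = label, fc_mii_pro = fc_mii_pro)
}

#' K-means clustering with cosine similarity distance
#'
#' Rows are unit-normalized; distance is 1 - cosine similarity; centroids
#' are normalized cluster means (spherical k-means). The best of
#' `n_restarts` seeded random initializations by total within-cluster
#' distance is returned, with clusters relabeled by size, most populated
#' first (cluster 1 is the largest).
#'
#' @param m Numeric matrix, rows = trajectories. All rows must have nonzero
#'   norm.
#' @param k Number of clusters (<= nrow(m)).
#' @param n_restarts Random restarts (default 50).
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param seed Integer seed.
#' @return list(labels, centroids (k x ncol), sizes, objective).
#' @export
kmeans_cosine <- function(m, k, n_restarts = 50L, max_iter = 100L, seed = 1L) {
  m <- as.matrix(m)
  if (k > nrow(m)) stop("k must be <= number of rows")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("zero-norm rows: ", paste(which(nrm == 0), collapse = ","))
  x <- m / nrm
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- x[sample(nrow(x), k), , drop = FALSE]
    lab <- integer(nrow(x))
    for (it in seq_len(max_iter)) {
      sim <- x %*% t(cen)
      new_lab <- max.col(sim, ties.method = "first")
      ## re-seed each empty cluster with a distinct worst-fit point
      empty <- which(tabulate(new_lab, k) == 0)
      if (length(empty)) {
        fit <- sim[cbind(seq_len(nrow(x)), new_lab)]
        worst <- order(fit)[seq_along(empty)]
        new_lab[worst] <- empty
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
      for (j in seq_len(k)) {
        pts <- which(lab == j)
        if (!length(pts)) next
        mu <- colMeans(x[pts, , drop = FALSE])
        n2 <- sqrt(sum(mu^2))
        if (n2 > 0) cen[j, ] <- mu / n2
      }
    }
    obj <- sum(1 - rowSums(x * cen[lab, , drop = FALSE]))
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(labels = lab, centroids = cen, objective = obj)
  }
  ## relabel by cardinality, largest first (ties: original label order)
  sizes <- tabulate(best$labels, k)
  ord <- order(-sizes, seq_len(k))
  relab <- match(best$labels, ord)
  list(labels = relab,
       centroids = best$centroids[ord, , drop = FALSE],
       sizes = sizes[ord],
       objective = best$objective)
}

#' Annotation-set enrichment by the hypergeometric tail with BH FDR
#'
#' For each term with K annotated members in a universe of size N, and a
#' query set of size n with k annotated members, computes the upper-tail
#' hypergeometric probability P(X >= k) and Benjamini-Hochberg FDR over
#' terms.
#'
#' @param members Character vector, the query set (must be within universe).
#' @param annotation Named list: term -> character vector of members.
#' @param universe Character vector, the background.
#' @return data.frame(term, k, K, n, N, p, fdr), ordered by p.
#' @export
enrich <- function(members, annotation, universe) {
  if (!length(universe)) stop("universe must be nonempty")
  universe <- unique(universe)
  members <- unique(members)
  if (!all(members %in% universe))
    stop("query members must be a subset of the universe")
  N <- length(universe); n <- length(members)
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(unique(annotation[[term]]), universe)
    K <- length(ann)
    k <- length(intersect(members, ann))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
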