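#' Construct a multiplex (plex) design
#'
#' Describes which TMT channel holds which biological timepoint, how much
#' material was loaded per channel, and which channels are phosphatase-treated
#' "anchor" channels. Anchors contain dephosphorylated material built as a
#' mixture of timepoints; because phosphatase treatment forces phosphosite
#' occupancy to (near) zero, anchor channels make absolute occupancy
#' identifiable from relative reporter-ion shares.
#'
#' @param timepoints Numeric vector of biological timepoints (hours),
#'   strictly increasing.
#' @param channels A data.frame with one row per channel and columns
#'   `channel` (name), `type` (`"regular"` or `"anchor"`), `timepoint`
#'   (index into `timepoints` for regular channels, `NA` for anchors) and
#'   `loading` (amount of material, e.g. oocyte-equivalents, > 0).
#' @param anchor_weights Numeric matrix, one row per channel and one column
#'   per timepoint. Rows for anchor channels hold nonnegative mixture weights
#'   summing to 1; rows for regular channels are ignored (and may be zero).
#' @param replicates Number of biological replicates (default 3).
#'
#' @return An object of class `plex_design`.
#' @seealso [default_design()] for the default 11-channel layout.
#' @export
plex_design <- function(timepoints, channels, anchor_weights, replicates = 3L) {
  stopifnot(is.numeric(timepoints), length(timepoints) >= 1,
            !is.unsorted(timepoints, strictly = TRUE))
  stopifnot(is.data.frame(channels),
            all(c("channel", "type", "timepoint", "loading") %in% names(channels)))
  if (!all(channels$type %in% c("regular", "anchor")))
    stop("channel type must be 'regular' or 'anchor'")
  if (any(channels$loading <= 0)) stop("loadings must be > 0")
  reg <- channels$type == "regular"
  if (any(is.na(channels$timepoint[reg])))
    stop("regular channels must reference a timepoint")
  if (any(channels$timepoint[reg] < 1 | channels$timepoint[reg] > length(timepoints)))
    stop("regular channel timepoint index out of range")
  if (!all(seq_along(timepoints) %in% channels$timepoint[reg]))
    stop("every timepoint must be referenced by at least one regular channel")
  anchor_weights <- as.matrix(anchor_weights)
  if (nrow(anchor_weights) != nrow(channels) ||
      ncol(anchor_weights) != length(timepoints))
    stop("anchor_weights must be n_channels x n_timepoints")
  for (i in which(!reg)) {
    w <- anchor_weights[i, ]
    if (any(w < 0)) stop("anchor mixture weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-9)
      stop("anchor mixture weights must sum to 1")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(
    timepoints = as.numeric(timepoints),
    channels = channels,
    anchor_weights = anchor_weights,
    replicates = as.integer(replicates)
  ), class = "plex_design")
}

#' The default 11-channel plex design
#'
#' Nine regular channels carry timepoints 0, 2, 3, 4, 5, 6, 7, 8, 9 h after
#' progesterone stimulation (100 oocyte-equivalents each). Channel 10 is a
#' phosphatase-treated anchor of 100 oocytes from the latest timepoint;
#' channel 11 is a phosphatase-treated 50/50 mixture of the first and last
#' timepoints.
#'
#' @param replicates Number of biological replicates (default 3).
#' @return A [plex_design()] object.
#' @export
default_design <- function(replicates = 3L) {
  tp <- c(0, 2, 3, 4, 5, 6, 7, 8, 9)
  n_tp <- length(tp)
  ch <- data.frame(
    channel = sprintf("c%02d", 1:11),
    type = c(rep("regular", n_tp), "anchor", "anchor"),
    timepoint = c(seq_len(n_tp), NA, NA),
    loading = rep(100, 11),
    stringsAsFactors = FALSE
  )
  w <- matrix(0, nrow = 11, ncol = n_tp)
  w[10, n_tp] <- 1                      # pure latest timepoint
  w[11, c(1, n_tp)] <- c(0.5, 0.5)      # 50/50 first + last
  plex_design(tp, ch, w, replicates)
}

#' @export
print.plex_design <- function(x, ...) {
  cat("Plex design:", length(x$timepoints), "timepoints (h):",
      paste(x$timepoints, collapse = ", "), "\n")
  cat(sum(x$channels$type == "regular"), "regular +",
      sum(x$channels$type == "anchor"), "anchor channels;",
      x$replicates, "replicates\n")
  invisible(x)
}

n_channels <- function(design) nrow(design$channels)

channel_names <- function(design) design$channels$channel

#' Expected unnormalized channel intensities for one peptide species
#'
#' Forward model of reporter-ion signal: a regular channel at timepoint t
#' carries loading x protein level r_t x (occupancy f_t for the phospho form,
#' 1 - f_t for the unmodified form); an anchor channel carries its loading x
#' the mixture-weighted protein level for the unmodified form and only a
#' small leakage fraction `epsilon` of that for the phospho form
#' (phosphatase treatment is near-complete).
#'
#' @param design A `plex_design`.
#' @param protein_level Numeric, relative protein level per timepoint (> 0).
#' @param occupancy Numeric in \[0,1\] per timepoint, or `NULL` for an
#'   unmodified peptide from a protein with no site on this peptide.
#' @param form `"phospho"` or `"unmod"`.
#' @param epsilon Anchor phospho leakage fraction (default 1e-3).
#' @return Numeric vector of expected intensities, one per channel.
#' @export
expected_channel_intensity <- function(design, protein_level, occupancy = NULL,
                                       form = c("unmod", "phospho"),
                                       epsilon = 1e-3) {
  form <- match.arg(form)
  stopifnot(length(protein_level) == length(design$timepoints))
  if (form == "phospho" && is.null(occupancy))
    stop("phospho form requires an occupancy trajectory")
  if (is.null(occupancy)) occupancy <- rep(0, length(design$timepoints))
  stopifnot(length(occupancy) == length(design$timepoints))
  ch <- design$channels
  out <- numeric(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    if (ch$type[i] == "regular") {
      t <- ch$timepoint[i]
      frac <- if (form == "phospho") occupancy[t] else 1 - occupancy[t]
      out[i] <- ch$loading[i] * protein_level[t] * frac
    } else {
      base <- ch$loading[i] * sum(design$anchor_weights[i, ] * protein_level)
      out[i] <- if (form == "phospho") epsilon * base else base
    }
  }
  out
}
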