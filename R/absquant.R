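## Absolute protein concentration from precursor ion current, prorated
## across TMT channels by the isobaric share trend. Total soluble protein
## mass per oocyte (default 30 ug) is split among proteins in proportion to
## their summed precursor ion current; molar concentration follows from the
## molecular mass and the oocyte volume.

#' Oocyte volume from its diameter
#' @param diameter_mm Diameter in mm (default 1.2, the full-grown oocyte).
#' @return Volume in microliters (a sphere; 1 mm^3 = 1 uL).
#' @export
oocyte_volume <- function(diameter_mm = 1.2) {
  if (diameter_mm <= 0) stop("diameter must be > 0")
  pi * diameter_mm^3 / 6
}

#' Estimate absolute protein concentrations
#'
#' mass_p = total_protein_mass * I_p / sum(I); conc_p = (mass_p / MW_p) /
#' volume, in nM.
#'
#' @param ion_current Named numeric vector: accession -> total precursor ion
#'   current (>= 0, not all zero).
#' @param masses Named numeric vector: accession -> molecular mass (Da).
#'   Proteins without a mass are excluded and reported.
#' @param total_protein_mass_ug Soluble protein per oocyte (default 30 ug).
#' @param volume_ul Oocyte volume (default from a 1.2 mm sphere).
#' @return list(estimates = data.frame(accession, ion_current, mass_fraction,
#'   mass_ug, mw_da, conc_nM), excluded = character vector of accessions
#'   without a molecular mass).
#' @export
estimate_concentrations <- function(ion_current, masses,
                                    total_protein_mass_ug = 30,
                                    volume_ul = oocyte_volume()) {
  if (any(ion_current < 0)) stop("ion currents must be >= 0")
  if (all(ion_current == 0)) stop("all ion currents are zero")
  excluded <- setdiff(names(ion_current), names(masses))
  keep <- setdiff(names(ion_current), excluded)
  ic <- ion_current[keep]
  mw <- masses[keep]
  if (any(mw <= 0)) stop("molecular masses must be > 0")
  frac <- ic / sum(ic)
  mass_ug <- total_protein_mass_ug * frac
  ## ug / (g/mol) = umol * 1e-6; / uL -> mol/L; report nM
  conc_nM <- (mass_ug * 1e-6 / mw) / (volume_ul * 1e-6) * 1e9
  list(estimates = data.frame(accession = keep, ion_current = ic,
                              mass_fraction = frac, mass_ug = mass_ug,
                              mw_da = mw, conc_nM = conc_nM,
                              row.names = NULL, stringsAsFactors = FALSE),
       excluded = excluded)
}

#' Prorate a reference concentration across channels
#'
#' conc_c = reference * (share_c / loading_c) / (share_ref / loading_ref):
#' the per-loading-unit reporter share scales the reference channel's
#' concentration to every other channel.
#'
#' @param reference_conc Concentration in the reference channel (any unit).
#' @param trend `share_trend` (or bare share vector) over design channels.
#' @param design A [plex_design()].
#' @param reference_channel Index of the reference channel (default 1).
#' @return Named numeric vector of per-channel concentrations; channels with
#'   zero share in the reference are an error, zero elsewhere give 0.
#' @export
prorate_channels <- function(reference_conc, trend, design,
                             reference_channel = 1L) {
  shares <- if (inherits(trend, "share_trend")) trend$shares else trend
  if (length(shares) != n_channels(design))
    stop("trend channels do not match design")
  L <- design$channels$loading
  ref <- shares[reference_channel] / L[reference_channel]
  if (ref <= 0) stop("zero share in the reference channel")
  stats::setNames(reference_conc * (shares / L) / ref,
                  channel_names(design))
}
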