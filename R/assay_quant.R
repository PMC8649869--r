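#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Relative quantification from qPCR threshold cycles assuming perfect
#' doubling per cycle:
#' \deqn{\mathrm{fold} = 2^{-\left[(Ct^{tgt}_{s} - Ct^{ref}_{s}) -
#'   (Ct^{tgt}_{c} - Ct^{ref}_{c})\right]}}
#' where the reference is a housekeeping gene (e.g. RPL19) and the control
#' is the calibrator sample. Vectorized over wells; adding a constant to all
#' four Ct values leaves the fold change unchanged.
#'
#' @param target_ct_sample,ref_ct_sample Target- and reference-gene Ct in
#'   the sample of interest.
#' @param target_ct_control,ref_ct_control Same in the calibrator sample.
#' @return Fold change (linear scale).
#' @export
ddct_fold <- function(target_ct_sample, ref_ct_sample,
                      target_ct_control, ref_ct_control) {
  ct <- cbind(target_ct_sample, ref_ct_sample,
              target_ct_control, ref_ct_control)
  if (any(!is.finite(ct)) || any(ct <= 0))
    abort_validation("all Ct values must be finite and positive")
  ddct <- (target_ct_sample - ref_ct_sample) -
    (target_ct_control - ref_ct_control)
  2^(-ddct)
}

#' ChIP-qPCR fold enrichment over isotype control
#'
#' Enrichment is the IP-over-input ratio of the specific antibody
#' normalized to the IP-over-input ratio of the isotype IgG negative
#' control.
#'
#' @param ip_frac_input Specific-antibody IP/input ratio (> 0).
#' @param igg_frac_input Isotype IgG IP/input ratio (> 0).
#' @return Fold enrichment.
#' @export
chip_fold_enrichment <- function(ip_frac_input, igg_frac_input) {
  if (any(!is.finite(ip_frac_input)) || any(ip_frac_input <= 0))
    abort_validation("IP/input ratios must be positive")
  if (any(!is.finite(igg_frac_input)) || any(igg_frac_input <= 0))
    abort_validation("IgG control ratios must be positive")
  ip_frac_input / igg_frac_input
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `volume = length x width^2 x 0.52` (mm^3), the standard modified
#' ellipsoid formula. Warns (does not fail) when width exceeds length,
#' since calipers are conventionally read with length as the longer axis.
#'
#' @param length,width Caliper measurements in mm (> 0), vectorized.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(width)) || any(width <= 0))
    abort_validation("length and width must be positive")
  if (any(width > length))
    warning("width > length for some measurements; axes may be swapped")
  length * width^2 * 0.52
}
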