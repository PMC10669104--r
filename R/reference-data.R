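#' Published reference tracking scores
#'
#' Per-identity tracking bookkeeping reported for a smartphone hand-held
#' CASA platform (three 90-frame clips at 29.80 fps): appear/disappear
#' frames, frames tracked (Ft), frames present (Fw) and the printed tracking
#' rate Rt. Note that Fw is an independently reported presence count — for
#' several identities it is not derivable from the appear/disappear columns
#' — so Ft and Fw are taken as given inputs when re-deriving Rt.
#'
#' @return data.frame with columns `id`, `appear_frame`, `disappear_frame`,
#'   `ft`, `fw`, `rt` (printed, %).
#' @export
referenceTrackingScores <- function() {
  utils::read.csv(system.file("extdata", "reference_tracking_scores.csv",
                              package = "spermtrack"))
}

#' Published reference motility parameters
#'
#' Per-identity kinematic parameters (VCL/VSL/VAP in um/s, LIN/STR/WOB in
#' %) with A-D motility grades from the same platform. The
#' `ratios_consistent` flag marks rows whose printed ratio columns agree
#' with the ratio definitions applied to the printed velocities at 2
#' decimals; the remaining rows carry printing inconsistencies (two have
#' STR/WOB transposed) and are kept for the grade column only.
#'
#' @return data.frame with columns `id`, `vcl`, `vsl`, `vap`, `lin`, `str`,
#'   `wob`, `grade`, `ratios_consistent`.
#' @export
referenceMotility <- function() {
  utils::read.csv(system.file("extdata", "reference_motility.csv",
                              package = "spermtrack"))
}
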