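#' Diagnostic group labels
#'
#' The five diagnostic groups handled by the pipeline, in the fixed order
#' used everywhere for tie-breaking and factor levels: non-Parkinsonian
#' syndrome (NPS), Parkinson's disease (PD), dementia with Lewy bodies (DLB),
#' progressive supranuclear palsy (PSP) and multiple system atrophy (MSA).
#'
#' @return Character vector of length 5.
#' @export
diagnostic_groups <- function() {
  c("NPS", "PD", "DLB", "PSP", "MSA")
}

#' Quantitative index names
#'
#' The six quantitative indices, in the fixed order used for split
#' tie-breaking: early and delayed heart-to-mediastinum ratios, cardiac
#' washout rate (percent), striatal binding ratio, putamen-to-caudate
#' ratio, and asymmetry index.
#'
#' @return Character vector of length 6.
#' @export
index_features <- function() {
  c("hm_early", "hm_delay", "wr", "sbr", "pcr", "ai")
}

# Display names for the six indices, keyed by column name.
index_display_names <- function() {
  c(hm_early = "H/M (Early)", hm_delay = "H/M (Delay)", wr = "WR",
    sbr = "SBR", pcr = "PCR", ai = "AI")
}

# Physical half-life of iodine-123, in hours.
I123_HALF_LIFE_H <- 13.2232

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Round half away from zero
#'
#' Decimal rounding where exact halves round away from zero (so 0.25 at one
#' digit gives 0.3), the convention used when displaying diagnostic
#' percentages to one decimal. Base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
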