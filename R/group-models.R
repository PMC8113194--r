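#' Built-in per-group marginal models for the six indices
#'
#' Marginal mean and standard deviation of each quantitative index in each
#' of the five diagnostic groups, as reported for the 216-patient clinical
#' cohort the pipeline emulates, together with physiologically motivated
#' truncation bounds used by the simulator. The default per-group sample
#' sizes are NPS 80, PD 90, DLB 21, PSP 16 and MSA 9.
#'
#' Truncation bounds (same for every group): H/M ratios in \[0.5, 6\],
#' washout rate in \[-30, 100\] percent, SBR in \[-0.5, 8\], PCR in
#' \[0.05, 2.5\], AI in \[0, 1.5\]. The reported group means sit well inside
#' these bounds, so truncation only trims implausible tails.
#'
#' @return A data frame of class `group_models` with one row per
#'   (group, index) pair and columns `group`, `index`, `mean`, `sd`,
#'   `lower`, `upper`, `n_default`.
#' @export
#' @examples
#' m <- default_group_models()
#' subset(m, group == "NPS" & index == "sbr")
default_group_models <- function() {
  groups <- diagnostic_groups()
  idx <- index_features()
  means <- rbind(
    #          hm_early hm_delay   wr   sbr  pcr   ai
    NPS = c(2.61, 2.72, 29.3, 2.13, 0.85, 0.03),
    PD  = c(1.99, 1.82, 50.1, 1.08, 0.71, 0.09),
    DLB = c(1.98, 1.73, 55.1, 1.10, 0.84, 0.08),
    PSP = c(2.61, 2.67, 31.0, 1.01, 0.77, 0.08),
    MSA = c(2.46, 2.50, 31.1, 1.24, 0.72, 0.10)
  )
  sds <- rbind(
    NPS = c(0.43, 0.54, 13.5, 0.51, 0.10, 0.02),
    PD  = c(0.44, 0.54, 16.1, 0.33, 0.07, 0.06),
    DLB = c(0.58, 0.62, 16.0, 0.43, 0.11, 0.07),
    PSP = c(0.40, 0.52, 13.3, 0.63, 0.08, 0.07),
    MSA = c(0.44, 0.58, 16.4, 0.49, 0.08, 0.09)
  )
  colnames(means) <- colnames(sds) <- idx
  bounds <- list(
    hm_early = c(0.5, 6), hm_delay = c(0.5, 6), wr = c(-30, 100),
    sbr = c(-0.5, 8), pcr = c(0.05, 2.5), ai = c(0, 1.5)
  )
  sizes <- default_group_sizes()
  out <- data.frame(
    group = rep(groups, each = length(idx)),
    index = rep(idx, times = length(groups)),
    mean = as.vector(t(means)),
    sd = as.vector(t(sds)),
    lower = rep(vapply(bounds, `[`, numeric(1), 1L), times = length(groups)),
    upper = rep(vapply(bounds, `[`, numeric(1), 2L), times = length(groups)),
    n_default = rep(unname(sizes), each = length(idx)),
    stringsAsFactors = FALSE
  )
  validate_group_models(out)
  class(out) <- c("group_models", "data.frame")
  out
}

#' Default per-group cohort sizes
#'
#' @return Named integer vector `c(NPS = 80, PD = 90, DLB = 21, PSP = 16,
#'   MSA = 9)`, summing to 216.
#' @export
default_group_sizes <- function() {
  c(NPS = 80L, PD = 90L, DLB = 21L, PSP = 16L, MSA = 9L)
}

validate_group_models <- function(models) {
  need <- c("group", "index", "mean", "sd", "lower", "upper")
  if (!is.data.frame(models) || !all(need %in% names(models)))
    stop_input("group models must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (any(models$sd < 0)) stop_input("index standard deviations must be >= 0")
  if (any(models$lower >= models$upper))
    stop_input("every truncation lower bound must be below its upper bound")
  bad <- models$mean < models$lower | models$mean > models$upper
  if (any(bad))
    stop_input("group means must lie inside their truncation bounds (%s)",
               paste(unique(models$group[bad]), collapse = ", "))
  invisible(models)
}

#' Mean of a truncated normal distribution
#'
#' Closed-form mean of a normal distribution with the given mean and
#' standard deviation truncated to \[lower, upper\]. Used to state the
#' exact target the simulated marginals converge to (truncation shifts the
#' sample mean away from the nominal mean when a bound is close).
#'
#' @param mean,sd Nominal (pre-truncation) mean and standard deviation.
#' @param lower,upper Truncation bounds.
#' @return The truncated mean (vectorized).
#' @export
truncated_normal_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop_input("sd must be >= 0")
  n <- max(length(mean), length(sd), length(lower), length(upper))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  out <- mean
  pos <- sd > 0
  a <- (lower[pos] - mean[pos]) / sd[pos]
  b <- (upper[pos] - mean[pos]) / sd[pos]
  z <- stats::pnorm(b) - stats::pnorm(a)
  out[pos] <- mean[pos] + sd[pos] * (stats::dnorm(a) - stats::dnorm(b)) / z
  out
}

# Quantile function of the truncated normal, by inverse-CDF mapping of a
# uniform variate; degenerates to the point mass at `mean` when sd = 0.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(u)))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}
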