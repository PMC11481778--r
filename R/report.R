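# Presentation layer: effects are reported in the direction that mimics the
# drug (e.g. pharmacological lowering of the target protein), so estimates
# from a "lowering" exposure are sign-flipped and their CI bounds swapped.

#' Orient an estimate to the direction of interest
#'
#' Applies a multiplier of -1 for `"lowering"` (report the effect of a lower
#' exposure, mimicking inhibition of the target) or +1 for `"raising"`.
#' Under -1 the CI bounds are negated and swapped; SE and p are unchanged.
#' Applying the same orientation twice returns the original.
#'
#' @param estimate slope (or log-OR).
#' @param ci length-2 CI `(lower, upper)`.
#' @param direction `"lowering"` or `"raising"`.
#' @return list with `estimate`, `ci`, `multiplier`.
#' @export
orient_estimate <- function(estimate, ci, direction = c("lowering", "raising")) {
  direction <- match.arg(direction)
  m <- if (direction == "lowering") -1 else 1
  list(estimate = m * estimate,
       ci = if (m < 0) c(-ci[2], -ci[1]) else ci,
       multiplier = m)
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param estimate log-odds effect.
#' @param se its standard error.
#' @return Named vector `c(or, lower, upper)` with
#'   `exp(estimate -/+ 1.96 * se)` bounds.
#' @examples
#' to_odds_ratio(log(0.92), 0.019) # ~ 0.92 (0.89; 0.96)
#' @export
to_odds_ratio <- function(estimate, se) {
  c(or = exp(estimate),
    lower = exp(estimate - 1.96 * se),
    upper = exp(estimate + 1.96 * se))
}

#' Recover a log-scale SE from a published 95% CI
#'
#' `(log(upper) - log(lower)) / (2 * 1.96)` for ratio scales (the default),
#' or the same without logs for additive scales.
#'
#' @param lower,upper CI bounds.
#' @param log_scale take logs first (CI given as OR), default TRUE.
#' @export
se_from_ci <- function(lower, upper, log_scale = TRUE) {
  if (log_scale) (log(upper) - log(lower)) / (2 * 1.96)
  else (upper - lower) / (2 * 1.96)
}

#' Signed, truncated -log10 p display score
#'
#' `sign * min(-log10(p), cap)`: the direction of effect times the evidence
#' strength, truncated so extreme p-values do not dominate a figure.
#'
#' @param direction +1 or -1 (sign of the oriented estimate).
#' @param p two-sided p-value in (0, 1].
#' @param cap truncation, default 8.
#' @export
signed_logp <- function(direction, p, cap = 8) {
  stopifnot(all(direction %in% c(-1, 1)))
  if (any(p < 0 | p > 1)) stop("p must be in (0, 1]")
  if (any(p == 0)) {
    warning("p = 0 truncated to the cap")
    p[p == 0] <- 10^(-cap - 1)
  }
  direction * pmin(-log10(p), cap)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level, default 0.05.
#' @param m number of tests, default 29 (the biomarker + disease outcome
#'   panel of the primary analysis).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold() # 0.05/29 ~ 1.7e-3
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 29) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Three-tier significance annotation
#'
#' `"significant"` below `alpha/m`, `"nominal"` in `[alpha/m, alpha)` (the
#' star of the figures), `"none"` otherwise (the dot).
#'
#' @param p p-values.
#' @inheritParams bonferroni_threshold
#' @export
significance_tier <- function(p, alpha = 0.05, m = 29) {
  cut <- bonferroni_threshold(alpha, m)
  ifelse(p < cut, "significant", ifelse(p < alpha, "nominal", "none"))
}

#' Interaction test between two stratified estimates
#'
#' Two-stratum z-difference test on a common (log) scale:
#' `z = (estimate_1 - estimate_2) / sqrt(se_1^2 + se_2^2)` with a two-sided
#' normal p. This is the test computable from two published stratum
#' estimates and their CIs alone.
#'
#' @param estimate_1,se_1 first stratum (log-OR and SE).
#' @param estimate_2,se_2 second stratum.
#' @return list of class `mr_interaction`: the inputs plus `z` and `p`.
#' @examples
#' # carrier vs non-carrier stratified odds ratios from published CIs
#' interaction_test(log(0.61), se_from_ci(0.51, 0.73),
#'                  log(0.89), se_from_ci(0.79, 1.01))
#' @export
interaction_test <- function(estimate_1, se_1, estimate_2, se_2) {
  if (se_1 <= 0 || se_2 <= 0) stop("standard errors must be positive")
  z <- (estimate_1 - estimate_2) / sqrt(se_1^2 + se_2^2)
  structure(
    list(estimate_1 = estimate_1, se_1 = se_1,
         estimate_2 = estimate_2, se_2 = se_2,
         z = z, p = 2 * stats::pnorm(-abs(z))),
    class = "mr_interaction"
  )
}

#' @export
print.mr_interaction <- function(x, ...) {
  cat(sprintf("stratified interaction: z = %.3f, p = %.3g\n", x$z, x$p))
  cat(sprintf("  stratum 1: %.4f (se %.4f); stratum 2: %.4f (se %.4f)\n",
              x$estimate_1, x$se_1, x$estimate_2, x$se_2))
  invisible(x)
}

#' Build a presentation table from MR fits
#'
#' Orients each fit to its exposure's direction of interest, optionally
#' exponentiates to the odds-ratio scale for binary outcomes, and annotates
#' with the signed truncated -log10 p score and the Bonferroni /
#' nominal-significance tier.
#'
#' @param fits an `mr_fit` or list of them.
#' @param or_scale logical (recycled): outcome is binary, report OR.
#' @param cap truncation of the display score, default 8.
#' @param alpha,m multiplicity parameters, defaults 0.05 and 29.
#' @return data.frame with one row per fit: `exposure_weighting`,
#'   `outcome`, `method`, `J_final`, `direction_multiplier`, `estimate`,
#'   `ci_low`, `ci_high`, `or`, `or_low`, `or_high`, `p`, `signed_logp`,
#'   `passes_bonferroni`, `significance_tier`.
#' @export
mr_report <- function(fits, or_scale = FALSE, cap = 8, alpha = 0.05, m = 29) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  or_scale <- rep_len(or_scale, length(fits))
  rows <- Map(function(f, use_or) {
    o <- orient_estimate(f$slope, f$slope_ci, f$direction_of_interest)
    dir_sign <- if (o$estimate == 0) 1 else sign(o$estimate)
    or <- if (use_or) to_odds_ratio(o$estimate, f$slope_se) else c(NA, NA, NA)
    data.frame(
      exposure_weighting = f$exposure %||% NA_character_,
      outcome = f$outcome %||% NA_character_,
      method = f$method, J_final = f$J,
      direction_multiplier = o$multiplier,
      estimate = o$estimate, ci_low = o$ci[1], ci_high = o$ci[2],
      or = or[1], or_low = or[2], or_high = or[3],
      p = f$slope_p,
      signed_logp = signed_logp(dir_sign, f$slope_p, cap = cap),
      passes_bonferroni = f$slope_p < bonferroni_threshold(alpha, m),
      significance_tier = significance_tier(f$slope_p, alpha, m),
      stringsAsFactors = FALSE
    )
  }, fits, or_scale)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format an odds ratio as in a results table
#'
#' Two decimals, `"OR (low; high)"`.
#'
#' @param or named vector from [to_odds_ratio()].
#' @export
format_or <- function(or) {
  sprintf("%.2f (%.2f; %.2f)", or[1], or[2], or[3])
}
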