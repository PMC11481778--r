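# GLS machinery. Omega = D R D with D = diag(sy), R the signed LD matrix.
# All solves go through the Cholesky factor; the brute-force normal-equation
# route lives only in the test oracles.

#' Outcome covariance matrix for correlated instruments
#'
#' `Omega[i, j] = sy[i] * sy[j] * r[i, j]`: the sampling covariance of the
#' outcome betas implied by the LD between instruments, the standard
#' correlated-instrument GLS weighting. Reduces to `diag(sy^2)` for
#' independent instruments.
#'
#' @param instr an `instrument_set`.
#' @return Symmetric positive-definite matrix.
#' @export
omega <- function(instr) {
  om <- outer(instr$sy, instr$sy) * instr$ld
  ch <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(ch)) {
    ld <- regularize_ld(instr$ld)
    om <- outer(instr$sy, instr$sy) * ld
    ch <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf("Omega not positive definite (condition number %.3g)", kappa(om)))
    }
  }
  om
}

# Solve Omega^{-1} %*% b via the upper Cholesky factor U (Omega = U'U).
.chol_solve <- function(U, b) backsolve(U, backsolve(U, b, transpose = TRUE))

.new_mr_fit <- function(method, slope, slope_se, J, q_stat = NA_real_, q_df = NA_real_,
                        intercept = NULL, intercept_se = NULL,
                        leverage = NULL, outlier_stat = NULL,
                        instr = NULL, pruned_ids = character(0), fitted = NULL) {
  z <- slope / slope_se
  fit <- list(
    method = method, slope = slope, slope_se = slope_se,
    slope_ci = c(slope - 1.96 * slope_se, slope + 1.96 * slope_se),
    # clamped above double underflow so log10 displays stay finite
    slope_p = max(2 * stats::pnorm(-abs(z)), 1e-300),
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = if (!is.null(intercept)) 2 * stats::pnorm(-abs(intercept / intercept_se)),
    q_stat = q_stat, q_df = q_df,
    q_p = if (is.finite(q_stat) && is.finite(q_df) && q_df > 0)
      stats::pchisq(q_stat, q_df, lower.tail = FALSE) else NA_real_,
    leverage = leverage, outlier_stat = outlier_stat,
    J = J, pruned_ids = pruned_ids,
    exposure = instr$exposure, outcome = instr$outcome,
    direction_of_interest = instr$direction_of_interest %||% "lowering",
    fitted = fitted, instruments = instr
  )
  class(fit) <- "mr_fit"
  fit
}

#' GLS inverse-variance-weighted estimator
#'
#' Fits `by = slope * bx` by generalized least squares with covariance
#' [omega()]: `slope = (bx' O^-1 by) / (bx' O^-1 bx)`,
#' `se = (bx' O^-1 bx)^-1/2`. Heterogeneity is the GLS Cochran Q,
#' `(by - slope*bx)' O^-1 (by - slope*bx)` on `J - 1` degrees of freedom.
#' With a single variant this is the Wald ratio `by/bx` with first-order
#' standard error `sy/|bx|` and no heterogeneity statistic.
#'
#' Exposure betas are treated as fixed (the usual no-measurement-error
#' assumption, tenable when every instrument passes a high F threshold).
#'
#' @param instr an `instrument_set`.
#' @return An object of class `mr_fit`; see [mr_fit()] for the fields.
#' @export
fit_ivw <- function(instr) {
  J <- length(instr$bx)
  if (all(instr$bx == 0)) stop("degenerate instruments: all exposure betas are zero")
  if (J == 1L) {
    return(.new_mr_fit("Wald", slope = instr$by / instr$bx,
                       slope_se = instr$sy / abs(instr$bx), J = 1L,
                       instr = instr, fitted = instr$by))
  }
  om <- omega(instr)
  U <- chol(om)
  oi_bx <- .chol_solve(U, instr$bx)
  denom <- sum(instr$bx * oi_bx)
  slope <- sum(oi_bx * instr$by) / denom
  slope_se <- 1 / sqrt(denom)
  resid <- instr$by - slope * instr$bx
  q <- sum(resid * .chol_solve(U, resid))
  lo <- .leverage_outliers_core(instr, U, X = matrix(instr$bx, ncol = 1), resid)
  .new_mr_fit("IVW", slope, slope_se, J = J, q_stat = q, q_df = J - 1,
              leverage = lo$leverage, outlier_stat = lo$outlier,
              instr = instr, fitted = slope * instr$bx)
}

#' GLS MR-Egger estimator
#'
#' Regresses outcome betas on exposure betas with a free intercept, by GLS
#' with covariance [omega()]. Variants are first oriented so that every
#' exposure beta is non-negative (flipping `bx`, `by` and the corresponding
#' LD row/column signs), the convention that makes the intercept a measure
#' of average directional pleiotropy. Coefficients are
#' `(X' O^-1 X)^-1 X' O^-1 by` with `X = [1, bx]` and covariance
#' `(X' O^-1 X)^-1`; Q has `J - 2` degrees of freedom.
#'
#' @param instr an `instrument_set` with at least 3 variants.
#' @return An object of class `mr_fit` with `intercept`, `intercept_se`
#'   fields.
#' @export
fit_egger <- function(instr) {
  J <- length(instr$bx)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  flip <- instr$bx < 0
  instr_o <- flip_orientation(instr, flip)
  if (stats::sd(instr_o$bx) == 0) {
    stop("exposure betas constant after orientation; Egger design collinear")
  }
  om <- omega(instr_o)
  U <- chol(om)
  X <- cbind(intercept = 1, bx = instr_o$bx)
  oi_X <- .chol_solve(U, X)
  XtOX <- crossprod(X, oi_X)
  cov_coef <- unname(solve(XtOX))
  coef <- unname(drop(cov_coef %*% crossprod(oi_X, instr_o$by)))
  fitted <- drop(X %*% coef)
  resid <- instr_o$by - fitted
  q <- sum(resid * .chol_solve(U, resid))
  lo <- .leverage_outliers_core(instr_o, U, X = X, resid)
  .new_mr_fit("Egger", slope = coef[2], slope_se = sqrt(cov_coef[2, 2]),
              J = J, q_stat = q, q_df = J - 2,
              intercept = coef[1], intercept_se = sqrt(cov_coef[1, 1]),
              leverage = lo$leverage, outlier_stat = lo$outlier,
              instr = instr, fitted = fitted)
}

#' Flip the orientation of selected variants
#'
#' Re-expresses variant effects on the opposite allele: negates `bx` and
#' `by` and the signs of the corresponding LD rows/columns. Estimators are
#' invariant to this re-labelling.
#'
#' @param instr an `instrument_set`.
#' @param flip logical vector, which variants to flip.
#' @return The flipped `instrument_set`.
#' @export
flip_orientation <- function(instr, flip) {
  stopifnot(length(flip) == length(instr$bx))
  s <- ifelse(flip, -1, 1)
  out <- instr
  out$bx <- instr$bx * s
  out$by <- instr$by * s
  out$ld <- instr$ld * outer(s, s)
  out$orientation_flips <- xor(instr$orientation_flips, flip)
  out
}

# Leverage = diag of the (oblique) GLS hat matrix H = X (X'O^-1 X)^-1 X'O^-1,
# which sums to the parameter count. Outlier statistics are the squared
# whitened residuals, whitening by the inverse lower Cholesky factor of
# Omega with variants in genomic order; they decompose Q exactly.
.leverage_outliers_core <- function(instr, U, X, resid) {
  oi_X <- .chol_solve(U, X)
  lev <- rowSums(X * t(solve(crossprod(X, oi_X), t(oi_X))))
  w <- backsolve(U, resid, transpose = TRUE) # L^-1 resid, L = t(U)
  list(leverage = stats::setNames(lev, instr$variant_ids),
       outlier = stats::setNames(w^2, instr$variant_ids))
}

#' Per-variant leverage and outlier statistics
#'
#' Leverage is the diagonal of the GLS hat matrix (design `bx` for IVW,
#' `[1, bx]` for Egger); its values sum to the number of fitted parameters.
#' The outlier statistic attributes the Cochran Q to variants: it is the
#' squared j-th whitened residual (inverse-Cholesky whitening of Omega, in
#' genomic order), so the values sum to Q and are each approximately
#' chi-square(1) under homogeneity.
#'
#' @param instr an `instrument_set`.
#' @param method `"ivw"` or `"egger"`.
#' @return data.frame with `variant_id`, `leverage`, `outlier_stat`.
#' @export
leverage_outliers <- function(instr, method = c("ivw", "egger")) {
  method <- match.arg(method)
  fit <- if (method == "ivw") fit_ivw(instr) else fit_egger(instr)
  if (is.null(fit$leverage)) stop("leverage undefined for a single-variant fit")
  data.frame(variant_id = instr$variant_ids,
             leverage = unname(fit$leverage),
             outlier_stat = unname(fit$outlier_stat),
             stringsAsFactors = FALSE)
}

.min_J <- c(ivw = 2L, egger = 3L)

#' Iterative leverage / heterogeneity pruning
#'
#' Repeatedly fits the chosen estimator and removes the single worst
#' offender among variants whose leverage exceeds `leverage_mult` times the
#' mean leverage (`parameters / J`) or whose outlier statistic exceeds
#' `outlier_max` (default the chi-square(1) 0.001 critical value, 10.83).
#' The worst offender is the violator with the largest outlier statistic
#' (ties: larger leverage, then smaller position). Stops when no variant
#' violates either rule; errors (carrying the partial log) if pruning would
#' drop the set below the method's minimum size.
#'
#' @param instr an `instrument_set`.
#' @param method `"ivw"` or `"egger"` (which fit drives the statistics).
#' @param leverage_mult multiple of the mean leverage, default 3.
#' @param outlier_max chi-square cutoff, default `qchisq(0.999, 1)` = 10.83.
#' @return list with `instruments` (the pruned set) and `log`
#'   (data.frame of removals in order: `variant_id`, `leverage`,
#'   `outlier_stat`, `reason`).
#' @export
prune_instruments <- function(instr, method = c("ivw", "egger"),
                              leverage_mult = 3, outlier_max = stats::qchisq(0.999, 1)) {
  method <- match.arg(method)
  n_par <- if (method == "ivw") 1L else 2L
  log <- data.frame(variant_id = character(0), leverage = numeric(0),
                    outlier_stat = numeric(0), reason = character(0),
                    stringsAsFactors = FALSE)
  repeat {
    J <- length(instr$variant_ids)
    stats_df <- leverage_outliers(instr, method)
    lev_cut <- leverage_mult * n_par / J
    viol <- stats_df$leverage > lev_cut | stats_df$outlier_stat > outlier_max
    if (!any(viol)) break
    if (J <= .min_J[[method]]) {
      warning(sprintf(
        "pruning stopped at the minimum of %d instruments for %s with violations remaining",
        .min_J[[method]], method))
      break
    }
    cand <- which(viol)
    ord <- order(-stats_df$outlier_stat[cand], -stats_df$leverage[cand],
                 instr$position[cand])
    worst <- cand[ord[1]]
    reason <- paste(c(
      if (stats_df$leverage[worst] > lev_cut) "leverage",
      if (stats_df$outlier_stat[worst] > outlier_max) "outlier"), collapse = "+")
    log <- rbind(log, data.frame(
      variant_id = stats_df$variant_id[worst],
      leverage = stats_df$leverage[worst],
      outlier_stat = stats_df$outlier_stat[worst],
      reason = reason, stringsAsFactors = FALSE))
    instr <- instr[-worst]
  }
  list(instruments = instr, log = log)
}

#' Q-difference model selection between IVW and Egger
#'
#' Computes `q_diff = q_ivw - q_egger` and refers it to chi-square with one
#' degree of freedom; Egger is chosen iff `q_diff` strictly exceeds the
#' `1 - alpha_select` quantile (i.e. the heterogeneity absorbed by the
#' intercept is larger than chance), otherwise the more precise IVW is kept.
#'
#' @param fit_i an IVW `mr_fit`.
#' @param fit_e an Egger `mr_fit` on the same variants.
#' @param alpha_select significance level of the rule, default 0.05.
#' @return list of class `mr_model_choice`: `chosen` ("IVW"/"Egger"),
#'   `q_ivw`, `q_egger`, `q_diff`, `q_diff_p`, `alpha_select`.
#' @export
select_model <- function(fit_i, fit_e, alpha_select = 0.05) {
  stopifnot(inherits(fit_i, "mr_fit"), inherits(fit_e, "mr_fit"),
            fit_i$method %in% c("IVW", "Wald"), fit_e$method == "Egger")
  if (!identical(fit_i$instruments$variant_ids, fit_e$instruments$variant_ids)) {
    stop("model selection requires both fits on the same variant set")
  }
  q_diff <- fit_i$q_stat - fit_e$q_stat
  if (q_diff < -1e-8) stop("q_ivw < q_egger; inconsistent fits")
  q_diff <- max(q_diff, 0)
  crit <- stats::qchisq(1 - alpha_select, df = 1)
  structure(
    list(chosen = if (q_diff > crit) "Egger" else "IVW",
         q_ivw = fit_i$q_stat, q_egger = fit_e$q_stat,
         q_diff = q_diff,
         q_diff_p = stats::pchisq(q_diff, df = 1, lower.tail = FALSE),
         alpha_select = alpha_select),
    class = "mr_model_choice"
  )
}

#' @export
print.mr_model_choice <- function(x, ...) {
  cat(sprintf("model selection: Q_ivw = %.3f, Q_egger = %.3f, Q_diff = %.3f (p = %.3g)\n",
              x$q_ivw, x$q_egger, x$q_diff, x$q_diff_p))
  cat(sprintf("  chosen: %s (alpha = %g)\n", x$chosen, x$alpha_select))
  invisible(x)
}

#' Fit a cis-MR causal-effect model
#'
#' The front-end estimator. Optionally prunes high-leverage / outlying
#' variants under the IVW fit, then fits GLS-IVW and (when at least three
#' instruments remain) GLS MR-Egger on the common pruned set, and either
#' returns the method requested or lets the Q-difference rule choose.
#'
#' @param instr an `instrument_set` from [build_instrument_set()] or
#'   [sim_instrument_set()].
#' @param method `"auto"` (Q-difference selection, the default), `"ivw"`,
#'   or `"egger"`.
#' @param prune logical, apply [prune_instruments()] first (default TRUE).
#' @param leverage_mult,outlier_max pruning thresholds, see
#'   [prune_instruments()].
#' @param alpha_select level of the model-selection rule.
#' @return An object of class `mr_fit`: a list with elements
#'   \describe{
#'     \item{method}{"IVW", "Egger" or "Wald" (single variant).}
#'     \item{slope, slope_se, slope_ci, slope_p}{causal-effect estimate per
#'       exposure unit, its SE, 95\% CI (`slope +/- 1.96 se`) and two-sided
#'       normal p.}
#'     \item{intercept, intercept_se, intercept_p}{Egger only: average
#'       directional pleiotropy.}
#'     \item{q_stat, q_df, q_p}{Cochran heterogeneity.}
#'     \item{leverage, outlier_stat}{per-variant diagnostics (named).}
#'     \item{J, pruned_ids}{final variant count and removal log.}
#'     \item{model_choice}{the `mr_model_choice` (method `"auto"` only).}
#'     \item{instruments}{the (pruned) `instrument_set` used.}
#'   }
#'   Methods: [print.mr_fit()], [summary.mr_fit()], `coef`, `confint`,
#'   `residuals`, `plot`.
#' @examples
#' study <- simulate_two_sample(sim_config(seed = 7, J = 10, n_outcome = 20000))
#' fit <- mr_fit(sim_instrument_set(study))
#' fit
#' @export
mr_fit <- function(instr, method = c("auto", "ivw", "egger"),
                   prune = TRUE, leverage_mult = 3,
                   outlier_max = stats::qchisq(0.999, 1),
                   alpha_select = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(instr, "instrument_set"))
  pruned_ids <- character(0)
  prune_log <- NULL
  if (prune && length(instr$variant_ids) > .min_J[["ivw"]]) {
    pr <- prune_instruments(instr, "ivw", leverage_mult = leverage_mult,
                            outlier_max = outlier_max)
    instr <- pr$instruments
    prune_log <- pr$log
    pruned_ids <- pr$log$variant_id
  }
  J <- length(instr$variant_ids)
  fit_i <- fit_ivw(instr)
  fit_i$pruned_ids <- pruned_ids
  fit_i$prune_log <- prune_log
  if (method == "ivw" || (method == "auto" && J < 3)) {
    return(fit_i)
  }
  fit_e <- fit_egger(instr)
  fit_e$pruned_ids <- pruned_ids
  fit_e$prune_log <- prune_log
  if (method == "egger") return(fit_e)
  choice <- select_model(fit_i, fit_e, alpha_select = alpha_select)
  out <- if (choice$chosen == "Egger") fit_e else fit_i
  out$model_choice <- choice
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("cis-MR fit (%s, J = %d)\n", x$method, x$J))
  if (!is.null(x$exposure)) {
    cat(sprintf("  %s -> %s\n", x$exposure, x$outcome %||% "outcome"))
  }
  cat(sprintf("  slope: %s (se %s), 95%% CI [%s, %s], p = %.3g\n",
              format(x$slope, digits = digits), format(x$slope_se, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits), x$slope_p))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept: %s (se %s), p = %.3g\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits), x$intercept_p))
  }
  if (is.finite(x$q_stat)) {
    cat(sprintf("  Cochran Q = %.3f on %d df (p = %.3g)\n", x$q_stat, x$q_df, x$q_p))
  }
  if (length(x$pruned_ids)) {
    cat("  pruned:", paste(x$pruned_ids, collapse = ", "), "\n")
  }
  if (!is.null(x$model_choice)) {
    cat(sprintf("  selected by Q-difference rule (q_diff = %.3f, p = %.3g)\n",
                x$model_choice$q_diff, x$model_choice$q_diff_p))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (is.null(object$intercept)) c(slope = object$slope)
  else c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.mr_fit <- function(object, parm = "slope", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- c(intercept = object$intercept_se %||% NA_real_, slope = object$slope_se)
  parm <- intersect(parm, names(est))
  cbind(lower = est[parm] - z * se[parm], upper = est[parm] + z * se[parm])
}

#' @export
residuals.mr_fit <- function(object, type = c("raw", "whitened"), ...) {
  type <- match.arg(type)
  instr <- object$instruments
  if (object$method == "Egger") {
    instr <- flip_orientation(instr, instr$bx < 0)
  }
  r <- instr$by - object$fitted
  if (type == "whitened") {
    U <- chol(omega(instr))
    r <- drop(backsolve(U, r, transpose = TRUE))
  }
  stats::setNames(r, instr$variant_ids)
}

#' @export
summary.mr_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = coef(object),
    se = c(if (!is.null(object$intercept)) object$intercept_se, object$slope_se),
    z = NA_real_, p = NA_real_
  )
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$fit$leverage)) {
    cat(sprintf("\nleverage: mean %.3f, max %.3f; outlier stat max %.3f\n",
                mean(x$fit$leverage), max(x$fit$leverage), max(x$fit$outlier_stat)))
  }
  invisible(x)
}

#' Scatter plot of an MR fit
#'
#' Outcome betas against exposure betas with per-variant 95\% error bars and
#' the fitted line (through the origin for IVW, free intercept for Egger).
#'
#' @param x an `mr_fit`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  instr <- x$instruments
  if (x$method == "Egger") instr <- flip_orientation(instr, instr$bx < 0)
  graphics::plot(instr$bx, instr$by,
                 xlab = "exposure beta", ylab = "outcome beta",
                 main = sprintf("%s fit (J = %d)", x$method, x$J), ...)
  graphics::segments(instr$bx, instr$by - 1.96 * instr$sy,
                     instr$bx, instr$by + 1.96 * instr$sy, col = "grey60")
  graphics::abline(a = x$intercept %||% 0, b = x$slope, col = "firebrick")
  invisible(x)
}
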