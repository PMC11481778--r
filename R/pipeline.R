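#' Configure an end-to-end cis-MR run
#'
#' Bundles file paths, the gene region and every analysis threshold. All
#' thresholds default to the primary-analysis values: 25 kbp flank, F >= 24,
#' MAF >= 0.01, clump r^2 <= 0.30, leverage cutoff 3x mean, outlier
#' chi-square cutoff 10.83, model-selection level 0.05, Bonferroni family
#' size 29.
#'
#' @param exposure_path,outcome_path,panel_path input files (tab-delimited;
#'   see [read_sumstats()] and [read_panel()]); `ld_path` may replace
#'   `panel_path` with a precomputed LD matrix.
#' @param region a [gene_region()].
#' @param out_dir output directory (created if absent).
#' @param flank,f_min,maf_min,r2_max instrument-selection thresholds.
#' @param leverage_mult,outlier_max,alpha_select estimator thresholds.
#' @param bonferroni_m multiplicity family size.
#' @param or_scale report odds ratios (binary outcome).
#' @param method `"auto"`, `"ivw"` or `"egger"`.
#' @param prune apply outlier/leverage pruning.
#' @param palindrome_policy see [harmonize()].
#' @param exposure_dialect,outcome_dialect column mappings.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the config is used to simulate).
#' @param ld_path optional precomputed LD matrix file.
#' @return list of class `run_config`.
#' @export
run_config <- function(exposure_path, outcome_path, panel_path = NULL,
                       region, out_dir = ".",
                       flank = 25000L, f_min = 24, maf_min = 0.01,
                       r2_max = 0.30, leverage_mult = 3,
                       outlier_max = stats::qchisq(0.999, 1),
                       alpha_select = 0.05, bonferroni_m = 29,
                       or_scale = FALSE, method = "auto", prune = TRUE,
                       palindrome_policy = "infer-by-eaf",
                       exposure_dialect = sumstats_dialect(),
                       outcome_dialect = sumstats_dialect(),
                       seed = 1L, ld_path = NULL) {
  stopifnot(inherits(region, "gene_region"),
            f_min >= 0, maf_min >= 0, maf_min <= 0.5,
            r2_max > 0, r2_max <= 1, leverage_mult > 0, outlier_max > 0,
            alpha_select > 0, alpha_select < 1, bonferroni_m >= 1)
  region$flank <- as.integer(flank)
  structure(
    list(exposure_path = exposure_path, outcome_path = outcome_path,
         panel_path = panel_path, ld_path = ld_path, region = region,
         out_dir = out_dir, f_min = f_min, maf_min = maf_min,
         r2_max = r2_max, leverage_mult = leverage_mult,
         outlier_max = outlier_max, alpha_select = alpha_select,
         bonferroni_m = bonferroni_m, or_scale = or_scale,
         method = method, prune = prune,
         palindrome_policy = palindrome_policy,
         exposure_dialect = exposure_dialect,
         outcome_dialect = outcome_dialect, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the cis-MR pipeline end to end
#'
#' Reads the inputs, builds the instrument set (cis window, F/MAF filters,
#' harmonization, clumping), prunes, fits IVW and Egger, applies
#' Q-difference model selection, and writes three files to
#' `config$out_dir`: `results.tsv` (the report row plus fit fields),
#' `fit_log.txt` (per-stage counts, pruning order, regularization, Q
#' statistics, chosen model) and `manifest.txt` (config values + seed;
#' enough to reproduce the run byte for byte given the same inputs).
#'
#' @param config a [run_config()].
#' @return The selected `mr_fit`, invisibly, with the report row attached
#'   as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  exposure <- read_sumstats(config$exposure_path, dialect = config$exposure_dialect,
                            trait_label = "exposure")
  outcome <- read_sumstats(config$outcome_path, dialect = config$outcome_dialect,
                           trait_label = "outcome")
  panel <- if (!is.null(config$panel_path)) read_panel(config$panel_path)
  ld <- if (!is.null(config$ld_path)) read_ld(config$ld_path)

  instr <- build_instrument_set(
    exposure, outcome, panel = panel, region = config$region,
    f_min = config$f_min, maf_min = config$maf_min, r2_max = config$r2_max,
    palindrome_policy = config$palindrome_policy, ld = ld)

  fit <- mr_fit(instr, method = config$method, prune = config$prune,
                leverage_mult = config$leverage_mult,
                outlier_max = config$outlier_max,
                alpha_select = config$alpha_select)

  report <- mr_report(fit, or_scale = config$or_scale,
                      m = config$bonferroni_m)
  res <- cbind(report, data.frame(
    slope = fit$slope, slope_se = fit$slope_se,
    intercept = fit$intercept %||% NA_real_,
    q_stat = fit$q_stat, q_df = fit$q_df,
    n_pruned = length(fit$pruned_ids)))
  fmt <- res
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], formatC, digits = 15, format = "g")
  utils::write.table(fmt, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_lines <- c(
    "cis-MR pipeline fit log",
    paste0("stage counts: ",
           paste(sprintf("%s=%d", names(attr(instr, "stage_log")),
                         attr(instr, "stage_log")), collapse = " -> ")),
    sprintf("LD shrinkage lambda: %g", attr(instr, "lambda") %||% 0),
    sprintf("pruned (%d): %s", length(fit$pruned_ids),
            paste(fit$pruned_ids, collapse = ", ")),
    sprintf("Q (%s): %.6g on %d df", fit$method, fit$q_stat, fit$q_df),
    if (!is.null(fit$model_choice)) sprintf(
      "model selection: Q_ivw=%.6g Q_egger=%.6g Q_diff=%.6g p=%.6g chosen=%s",
      fit$model_choice$q_ivw, fit$model_choice$q_egger,
      fit$model_choice$q_diff, fit$model_choice$q_diff_p,
      fit$model_choice$chosen),
    sprintf("method reported: %s (J = %d)", fit$method, fit$J))
  writeLines(log_lines, file.path(config$out_dir, "fit_log.txt"))

  scalar <- vapply(config, function(v)
    is.atomic(v) && length(v) == 1 && !is.null(v), logical(1))
  manifest <- c(
    sprintf("package: cismr %s", as.character(utils::packageVersion("cismr"))),
    sprintf("region: chr%s:%d-%d flank %d", config$region$chromosome,
            config$region$gene_start, config$region$gene_end, config$region$flank),
    sprintf("%s: %s", names(config)[scalar],
            vapply(config[scalar], as.character, character(1))))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  attr(fit, "report") <- report
  invisible(fit)
}
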