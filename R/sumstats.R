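#' Default column mapping for summary-statistics files
#'
#' Maps the internal field names onto the column headers found in a file.
#' Override entries to parse files with other header conventions, e.g.
#' GWAS-SSF style (`"chromosome"`, `"base_pair_location"`, ...) or legacy
#' (`"SNP"`, `"BP"`, `"A1"`, ...).
#'
#' @param ... named overrides, e.g. `variant_id = "SNP"`, `position = "BP"`.
#' @return Named character vector mapping internal names to file headers.
#' @examples
#' sumstats_dialect(variant_id = "SNP", position = "BP")
#' @export
sumstats_dialect <- function(...) {
  d <- c(
    variant_id = "variant_id", chromosome = "chromosome",
    position = "position", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta",
    se = "se", p_value = "p_value", n = "n"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

# Fields a file must provide; eaf and n may be absent (filled with NA).
.mandatory_fields <- c("variant_id", "chromosome", "position",
                       "effect_allele", "other_allele", "beta", "se", "p_value")

#' Construct a validated summary-statistics table
#'
#' Validates per-variant GWAS records, drops rows violating hard invariants
#' (non-positive SE, eaf outside \[0,1\], identical alleles, p outside (0,1],
#' duplicated variant id) with a warning, and sorts by chromosome and
#' position. Rows whose p-value disagrees with the normal approximation
#' `2*pnorm(-|beta/se|)` by more than a factor of 2 draw a warning but are
#' kept (GWAS p-values are often from slightly different tests).
#'
#' @param x data.frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p_value`, `n`
#'   (`eaf`/`n` optional).
#' @param trait_label,trait_units,direction_of_interest trait metadata;
#'   `direction_of_interest` is `"lowering"` or `"raising"` and controls how
#'   report estimates are oriented (see [orient_estimate()]).
#' @return data.frame of class `sumstats` with attributes `trait_label`,
#'   `trait_units`, `direction_of_interest`, `n_dropped`.
#' @export
sumstats <- function(x, trait_label = "trait", trait_units = "",
                     direction_of_interest = c("lowering", "raising")) {
  direction_of_interest <- match.arg(direction_of_interest)
  stopifnot(is.data.frame(x))
  miss <- setdiff(.mandatory_fields, names(x))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(x$eaf)) x$eaf <- NA_real_
  if (is.null(x$n)) x$n <- NA_real_
  x <- x[, c(.mandatory_fields[1:5], "eaf", "beta", "se", "p_value", "n")]
  x$chromosome <- as.character(x$chromosome)
  x$position <- as.integer(x$position)
  for (a in c("effect_allele", "other_allele")) x[[a]] <- toupper(as.character(x[[a]]))

  ok <- is.finite(x$beta) & is.finite(x$se) & x$se > 0 &
    is.finite(x$p_value) & x$p_value > 0 & x$p_value <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    x$effect_allele != x$other_allele &
    !is.na(x$position) & !duplicated(x$variant_id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d record(s) violating summary-statistic invariants", n_dropped))
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no usable summary-statistic records")

  z <- abs(x$beta / x$se)
  p_norm <- 2 * stats::pnorm(-z)
  inconsistent <- p_norm > 1e-300 & (x$p_value / p_norm > 2 | p_norm / x$p_value > 2)
  if (any(inconsistent)) {
    warning(sprintf("%d record(s) have p-values inconsistent with beta/se (factor > 2)",
                    sum(inconsistent)))
  }

  x <- x[order(x$chromosome, x$position), , drop = FALSE]
  rownames(x) <- NULL
  structure(x,
    class = c("sumstats", "data.frame"),
    trait_label = trait_label, trait_units = trait_units,
    direction_of_interest = direction_of_interest,
    n_dropped = n_dropped
  )
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect column mapping from [sumstats_dialect()].
#' @param ... passed on to [sumstats()] (trait metadata).
#' @return A `sumstats` table, validated and sorted by (chromosome, position).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  have <- dialect[dialect %in% names(raw)]
  miss <- setdiff(.mandatory_fields, names(have))
  if (length(miss)) {
    stop("file ", path, " lacks mapped column(s) for: ", paste(miss, collapse = ", "))
  }
  out <- raw[, have, drop = FALSE]
  names(out) <- names(have)
  sumstats(out, ...)
}

#' Write a summary-statistics table
#'
#' Tab-delimited, default headers, full double precision (round-trips through
#' [read_sumstats()] to 15 significant digits).
#'
#' @param x a `sumstats` table (or plain data.frame with the same columns).
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  y <- as.data.frame(x)
  for (v in c("eaf", "beta", "se", "p_value", "n")) {
    if (is.numeric(y[[v]])) y[[v]] <- formatC(y[[v]], digits = 15, format = "g")
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs the two tables variant by variant and puts outcome effects on the
#' exposure's effect allele. Variants are matched on `variant_id`, falling
#' back to `chromosome:position` for ids present in only one table; positions
#' carrying more than one variant in either table are dropped (multi-allelic
#' ambiguity). When the outcome's alleles are swapped relative to the
#' exposure, the outcome beta is negated and its eaf replaced by `1 - eaf`;
#' strand flips (A<->T, C<->G re-labelling) are recognised the same way.
#' Incompatible allele pairs are dropped, never silently kept.
#'
#' Palindromic variants (A/T or C/G pairs), for which swap and strand flip
#' are indistinguishable from the alleles alone, are resolved by `policy`:
#' \describe{
#'   \item{`"infer-by-eaf"`}{(default) drop if either minor-allele frequency
#'     exceeds 0.42 (too close to 0.5 to call); otherwise keep as-is if the
#'     two eafs agree within 0.08, flip if eaf agrees with `1 - eaf` within
#'     0.08, drop otherwise.}
#'   \item{`"drop-ambiguous"`}{drop every palindromic variant.}
#' }
#'
#' @param exposure,outcome `sumstats` tables.
#' @param palindrome_policy `"infer-by-eaf"` or `"drop-ambiguous"`.
#' @return data.frame of class `harmonized` with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `bx`, `sx`, `px`, `nx`, `by`, `sy`, `py`, `ny`, `flipped` (logical:
#'   outcome beta was negated). Attribute `n_dropped` counts unmatched or
#'   incompatible variants; `drop_log` names them.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer-by-eaf", "drop-ambiguous")) {
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)

  # match on id, fall back to chromosome:position for the remainder
  ou_idx <- match(ex$variant_id, ou$variant_id)
  no_id <- is.na(ou_idx)
  if (any(no_id)) {
    key_ex <- paste(ex$chromosome, ex$position, sep = ":")
    key_ou <- paste(ou$chromosome, ou$position, sep = ":")
    multi <- union(key_ex[duplicated(key_ex)], key_ou[duplicated(key_ou)])
    fallback <- match(key_ex[no_id], key_ou)
    fallback[key_ex[no_id] %in% multi] <- NA_integer_
    ou_idx[no_id] <- fallback
  }

  # paste0() recycles zero-length ids to "", so guard every log append
  add_log <- function(log, ids, reason) {
    if (length(ids)) c(log, paste0(ids, ": ", reason)) else log
  }
  drop_log <- character(0)
  keep <- !is.na(ou_idx)
  drop_log <- add_log(drop_log, ex$variant_id[!keep], "unmatched")
  ex2 <- ex[keep, , drop = FALSE]
  ou2 <- ou[ou_idx[keep], , drop = FALSE]

  ea_x <- ex2$effect_allele; oa_x <- ex2$other_allele
  ea_y <- ou2$effect_allele; oa_y <- ou2$other_allele
  pal <- .is_palindromic(ea_x, oa_x)

  same  <- ea_y == ea_x & oa_y == oa_x
  swap  <- ea_y == oa_x & oa_y == ea_x
  flip  <- ea_y == unname(.complement[ea_x]) & oa_y == unname(.complement[oa_x])
  flipswap <- ea_y == unname(.complement[oa_x]) & oa_y == unname(.complement[ea_x])

  action <- rep(NA_character_, nrow(ex2)) # "keep", "swap", "drop"
  action[same & !pal] <- "keep"
  action[swap & !pal] <- "swap"
  action[!pal & !same & !swap & flip] <- "keep"
  action[!pal & !same & !swap & flipswap] <- "swap"

  if (any(pal)) {
    if (palindrome_policy == "drop-ambiguous") {
      action[pal] <- "drop"
      drop_log <- add_log(drop_log, ex2$variant_id[pal & (same | swap)], "palindromic")
    } else {
      idx <- which(pal & (same | swap))
      for (i in idx) {
        fx <- ex2$eaf[i]; fy <- ou2$eaf[i]
        if (is.na(fx) || is.na(fy) ||
            min(fx, 1 - fx) > 0.42 || min(fy, 1 - fy) > 0.42) {
          action[i] <- "drop"
          drop_log <- c(drop_log, paste0(ex2$variant_id[i], ": palindromic, ambiguous frequency"))
        } else if (abs(fx - fy) <= 0.08) {
          action[i] <- "keep"
        } else if (abs(fx - (1 - fy)) <= 0.08) {
          action[i] <- "swap"
        } else {
          action[i] <- "drop"
          drop_log <- c(drop_log, paste0(ex2$variant_id[i], ": palindromic, frequency mismatch"))
        }
      }
    }
  }
  incompatible <- is.na(action)
  drop_log <- add_log(drop_log, ex2$variant_id[incompatible], "incompatible alleles")
  action[incompatible] <- "drop"

  keep2 <- action != "drop"
  ex3 <- ex2[keep2, , drop = FALSE]
  ou3 <- ou2[keep2, , drop = FALSE]
  flipped <- action[keep2] == "swap"

  by <- ifelse(flipped, -ou3$beta, ou3$beta)
  eay <- ifelse(flipped, 1 - ou3$eaf, ou3$eaf)

  out <- data.frame(
    variant_id = ex3$variant_id, chromosome = ex3$chromosome,
    position = ex3$position, effect_allele = ex3$effect_allele,
    other_allele = ex3$other_allele, eaf = ex3$eaf,
    bx = ex3$beta, sx = ex3$se, px = ex3$p_value, nx = ex3$n,
    by = by, sy = ou3$se, py = ou3$p_value, ny = ou3$n,
    eaf_outcome = eay, flipped = flipped,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  n_dropped <- length(drop_log)
  if (n_dropped > 0) {
    message(sprintf("harmonize: dropped %d variant(s)", n_dropped))
  }
  structure(out, class = c("harmonized", "data.frame"),
            n_dropped = n_dropped, drop_log = drop_log)
}

#' Read / write an LD matrix
#'
#' Square tab-delimited signed correlation matrix whose one-line header
#' carries the variant ids (row order identical).
#'
#' @param path file path.
#' @return For `read_ld`: numeric matrix with variant ids as dimnames.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("LD matrix is not square")
  rownames(m) <- colnames(m)
  validate_ld(m)
}

#' @rdname read_ld
#' @param r LD matrix with variant-id dimnames.
#' @export
write_ld <- function(r, path) {
  df <- as.data.frame(formatC(r, digits = 15, format = "g"), stringsAsFactors = FALSE)
  names(df) <- colnames(r)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an LD matrix
#'
#' Checks symmetry, unit diagonal, entries in \[-1, 1\] and near-positive
#' semidefiniteness (smallest eigenvalue >= -1e-8 before regularization).
#'
#' @param r square numeric matrix.
#' @return `r`, invisibly symmetrized.
#' @export
validate_ld <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix is not symmetric")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal is not 1")
  if (max(abs(r)) > 1 + 1e-8) stop("LD entries outside [-1, 1]")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD matrix has eigenvalue below -1e-8; not a correlation matrix")
  r
}

#' Write fitted MR results to a delimited table
#'
#' One row per fit; numeric fields at full precision so that
#' [read_results()] round-trips field for field.
#'
#' @param fits a single `mr_fit` or a list of them.
#' @param path output path.
#' @return The results data.frame, invisibly.
#' @export
write_results <- function(fits, path) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("no fits to write")
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "mr_fit"))
    data.frame(
      exposure = f$exposure %||% NA_character_,
      outcome = f$outcome %||% NA_character_,
      method = f$method,
      J_final = f$J,
      slope = f$slope, slope_se = f$slope_se,
      ci_low = f$slope_ci[1], ci_high = f$slope_ci[2], p = f$slope_p,
      intercept = f$intercept %||% NA_real_,
      intercept_se = f$intercept_se %||% NA_real_,
      q_stat = f$q_stat %||% NA_real_, q_df = f$q_df %||% NA_real_,
      n_pruned = length(f$pruned_ids),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  fmt <- out
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], formatC, digits = 15, format = "g")
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
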