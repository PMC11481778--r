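#' Define a gene-centred cis region
#'
#' The instrument window is `[gene_start - flank, gene_end + flank]`,
#' inclusive at both ends, anchored on the gene body (1-based coordinates).
#'
#' @param chromosome chromosome label (character).
#' @param gene_start,gene_end gene body coordinates in base pairs.
#' @param flank flank added on each side, default 25,000 bp.
#' @return list of class `gene_region`.
#' @examples
#' gene_region("16", 56995762, 57017757) # CETP, GRCh37, +/- 25 kbp
#' @export
gene_region <- function(chromosome, gene_start, gene_end, flank = 25000L) {
  stopifnot(gene_start <= gene_end, flank >= 0)
  structure(
    list(chromosome = as.character(chromosome),
         gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
         flank = as.integer(flank)),
    class = "gene_region"
  )
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("cis region chr%s:%d-%d (gene %d-%d, flank %d bp)\n",
              x$chromosome, x$gene_start - x$flank, x$gene_end + x$flank,
              x$gene_start, x$gene_end, x$flank))
  invisible(x)
}

#' Restrict summary statistics to a cis window
#'
#' @param table a `sumstats` table.
#' @param region a [gene_region()].
#' @return The records on `region$chromosome` with
#'   `gene_start - flank <= position <= gene_end + flank` (both ends
#'   inclusive); errors if none remain.
#' @export
select_cis <- function(table, region) {
  stopifnot(inherits(region, "gene_region"))
  lo <- region$gene_start - region$flank
  hi <- region$gene_end + region$flank
  keep <- table$chromosome == region$chromosome &
    table$position >= lo & table$position <= hi
  if (!any(keep)) {
    stop(sprintf("no variants in cis window chr%s:%d-%d", region$chromosome, lo, hi))
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_label", "trait_units", "direction_of_interest")] <-
    attributes(table)[c("trait_label", "trait_units", "direction_of_interest")]
  class(out) <- class(table)
  out
}

#' Per-variant instrument-strength F-statistic
#'
#' The large-sample approximation `(beta/se)^2`, the usual form when only
#' summary statistics are available.
#'
#' @param beta,se per-variant effect and standard error (`se > 0`).
#' @return F values.
#' @examples
#' f_statistic(0.5, 0.1) # 25
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Filter instruments on strength and allele frequency
#'
#' Retains variants with `f_statistic(beta, se) >= f_min` and minor-allele
#' frequency `min(eaf, 1 - eaf) >= maf_min`; both thresholds are inclusive.
#' If `eaf` is entirely missing the MAF filter is skipped with a warning.
#'
#' @param table a `sumstats` table.
#' @param f_min minimum F, default 24.
#' @param maf_min minimum minor-allele frequency, default 0.01.
#' @return Filtered `sumstats` table; errors if nothing survives.
#' @export
filter_instruments <- function(table, f_min = 24, maf_min = 0.01) {
  f <- f_statistic(table$beta, table$se)
  keep <- f >= f_min
  if (all(is.na(table$eaf))) {
    warning("eaf missing for all records; MAF filter skipped")
  } else {
    maf <- pmin(table$eaf, 1 - table$eaf)
    keep <- keep & !is.na(maf) & maf >= maf_min
  }
  if (!any(keep)) stop("no variants pass the instrument filters")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_label", "trait_units", "direction_of_interest")] <-
    attributes(table)[c("trait_label", "trait_units", "direction_of_interest")]
  class(out) <- class(table)
  out
}

#' Estimate a signed LD matrix from a reference panel
#'
#' Pearson correlation of dosage columns, regularized to positive
#' definiteness by shrinkage towards the identity when needed: the smallest
#' lambda in `c(0.001, 0.005, 0.01, 0.05)` with
#' `r <- (1 - lambda) * r + lambda * I` whose smallest eigenvalue exceeds
#' 1e-8 is applied and recorded in the `"lambda"` attribute (`0` when no
#' shrinkage was needed).
#'
#' @param panel a [reference_panel()].
#' @param ids variant ids to extract (subset of the panel's).
#' @return Correlation matrix with unit diagonal, dimnames `ids`,
#'   attribute `lambda`.
#' @export
compute_ld <- function(panel, ids = panel$variant_ids) {
  stopifnot(inherits(panel, "reference_panel"))
  miss <- setdiff(ids, panel$variant_ids)
  if (length(miss)) stop("ids absent from panel: ", paste(miss, collapse = ", "))
  if (panel$n_individuals < 2) stop("need at least 2 reference individuals")
  g <- panel$dosages[, ids, drop = FALSE]
  sds <- apply(g, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant dosage column(s): ", paste(ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(g)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  regularize_ld(r)
}

#' @rdname compute_ld
#' @param r a correlation matrix to regularize directly.
#' @export
regularize_ld <- function(r) {
  lambda_used <- 0
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    for (lambda in c(0.001, 0.005, 0.01, 0.05)) {
      r2 <- (1 - lambda) * r
      diag(r2) <- 1
      ev <- eigen(r2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) >= 1e-8) {
        r <- r2
        lambda_used <- lambda
        break
      }
    }
    if (min(ev) < 1e-8) {
      stop(sprintf("LD matrix not positive definite after shrinkage (min eigenvalue %.3g)",
                   min(ev)))
    }
  }
  attr(r, "lambda") <- lambda_used
  r
}

#' Greedy LD clumping
#'
#' Ranks variants by exposure p-value (ascending; ties broken by smaller
#' position, then variant id), repeatedly keeps the best-ranked remaining
#' variant and discards every remaining variant with squared correlation
#' `r^2 > r2_max` against it. The retained set has all pairwise
#' `r^2 <= r2_max` and does not depend on input row order.
#'
#' @param table a `sumstats` or `harmonized` table (p-values taken from
#'   `p_value` or `px`).
#' @param ld LD matrix covering all of the table's variants.
#' @param r2_max squared-correlation ceiling, default 0.30.
#' @return The retained subset of `table`, original (chromosome, position)
#'   order.
#' @export
clump <- function(table, ld, r2_max = 0.30) {
  p <- table$p_value %||% table$px
  ids <- table$variant_id
  miss <- setdiff(ids, colnames(ld))
  if (length(miss)) stop("variants absent from LD matrix: ", paste(miss, collapse = ", "))
  ord <- order(p, table$position, ids)
  remaining <- ids[ord]
  kept <- character(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    r2 <- ld[top, remaining]^2
    remaining <- remaining[r2 <= r2_max & remaining != top]
  }
  out <- table[table$variant_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_label", "trait_units", "direction_of_interest")] <-
    attributes(table)[c("trait_label", "trait_units", "direction_of_interest")]
  class(out) <- class(table)
  out
}

#' Reference panel of allele dosages
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns
#'   (values in \[0, 2\]); column names are the variant ids unless given.
#' @param variant_ids optional explicit ids.
#' @return list of class `reference_panel`.
#' @export
reference_panel <- function(dosages, variant_ids = colnames(dosages)) {
  stopifnot(is.matrix(dosages), !is.null(variant_ids),
            length(variant_ids) == ncol(dosages))
  colnames(dosages) <- variant_ids
  structure(
    list(variant_ids = variant_ids, dosages = dosages,
         n_individuals = nrow(dosages)),
    class = "reference_panel"
  )
}

#' Read / write a dosage reference panel
#'
#' Tab-delimited matrix, individuals as rows, one-line header of variant ids.
#'
#' @param path file path.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE))
  reference_panel(m)
}

#' @rdname read_panel
#' @param panel a [reference_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel$dosages), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the instrument set an estimator consumes
#'
#' Composes the selection pipeline in fixed order: cis-window restriction,
#' F/MAF filtering, exposure-outcome harmonization, LD clumping, and LD
#' submatrix extraction. Per-stage variant counts are recorded in the
#' `stage_log` attribute.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param panel a [reference_panel()] (dosages coded on the exposure effect
#'   allele); alternatively pass a precomputed LD matrix as `ld`.
#' @param region a [gene_region()].
#' @param f_min,maf_min,r2_max selection thresholds (defaults 24, 0.01, 0.30).
#' @param palindrome_policy see [harmonize()].
#' @param ld optional precomputed signed correlation matrix (dimnames are
#'   variant ids); used instead of `panel`.
#' @return An `instrument_set`: list with `variant_ids`, `position`, `bx`,
#'   `sx`, `by`, `sy`, `ld`, `orientation_flips`, `exposure`, `outcome`,
#'   `direction_of_interest`, plus a `stage_log` attribute.
#' @export
build_instrument_set <- function(exposure, outcome, panel = NULL, region,
                                 f_min = 24, maf_min = 0.01, r2_max = 0.30,
                                 palindrome_policy = "infer-by-eaf",
                                 ld = NULL) {
  log <- c(input = nrow(exposure))
  tab <- select_cis(exposure, region)
  log <- c(log, cis = nrow(tab))
  tab <- filter_instruments(tab, f_min = f_min, maf_min = maf_min)
  log <- c(log, filtered = nrow(tab))
  harm <- harmonize(tab, outcome, palindrome_policy = palindrome_policy)
  if (nrow(harm) == 0L) stop("no variants remain after harmonization")
  log <- c(log, harmonized = nrow(harm))
  if (is.null(ld)) {
    if (is.null(panel)) stop("either a reference panel or an LD matrix is required")
    ld <- compute_ld(panel, harm$variant_id)
  } else {
    miss <- setdiff(harm$variant_id, colnames(ld))
    if (length(miss)) stop("variants absent from LD matrix: ", paste(miss, collapse = ", "))
    ld <- regularize_ld(ld[harm$variant_id, harm$variant_id, drop = FALSE])
  }
  harm <- clump(harm, ld, r2_max = r2_max)
  log <- c(log, clumped = nrow(harm))
  instr <- instrument_set(
    variant_ids = harm$variant_id, position = harm$position,
    bx = harm$bx, sx = harm$sx, by = harm$by, sy = harm$sy,
    ld = ld[harm$variant_id, harm$variant_id, drop = FALSE],
    orientation_flips = harm$flipped,
    exposure = attr(exposure, "trait_label"),
    outcome = attr(outcome, "trait_label"),
    direction_of_interest = attr(exposure, "direction_of_interest")
  )
  attr(instr, "stage_log") <- log
  attr(instr, "lambda") <- attr(ld, "lambda") %||% 0
  instr
}

#' Construct an instrument set directly
#'
#' Low-level constructor used by [build_instrument_set()] and the
#' simulator; all vectors and the LD matrix must agree in length, with
#' variants in genomic order.
#'
#' @param variant_ids,position variant identifiers and base-pair positions.
#' @param bx,sx exposure betas and standard errors.
#' @param by,sy outcome betas and standard errors.
#' @param ld signed correlation matrix (unit diagonal).
#' @param orientation_flips logical, outcome beta was flipped during
#'   harmonization.
#' @param exposure,outcome,direction_of_interest trait metadata.
#' @return list of class `instrument_set`.
#' @export
instrument_set <- function(variant_ids, position = seq_along(variant_ids),
                           bx, sx, by, sy, ld,
                           orientation_flips = rep(FALSE, length(variant_ids)),
                           exposure = NULL, outcome = NULL,
                           direction_of_interest = "lowering") {
  J <- length(variant_ids)
  ld <- as.matrix(ld)
  stopifnot(J >= 1,
            length(bx) == J, length(sx) == J, length(by) == J, length(sy) == J,
            all(sx > 0), all(sy > 0),
            nrow(ld) == J, ncol(ld) == J)
  dimnames(ld) <- list(variant_ids, variant_ids)
  structure(
    list(variant_ids = as.character(variant_ids), position = position,
         bx = as.numeric(bx), sx = as.numeric(sx),
         by = as.numeric(by), sy = as.numeric(sy),
         ld = ld, orientation_flips = orientation_flips,
         exposure = exposure, outcome = outcome,
         direction_of_interest = direction_of_interest),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument set: %d variant(s)%s%s\n", length(x$variant_ids),
              if (!is.null(x$exposure)) paste0(", exposure ", x$exposure) else "",
              if (!is.null(x$outcome)) paste0(", outcome ", x$outcome) else ""))
  mf <- f_statistic(x$bx, x$sx)
  cat(sprintf("  F-statistics: min %.1f, median %.1f, max %.1f\n",
              min(mf), stats::median(mf), max(mf)))
  off <- x$ld[upper.tri(x$ld)]
  if (length(off)) cat(sprintf("  max pairwise r^2: %.3f\n", max(off^2)))
  log <- attr(x, "stage_log")
  if (!is.null(log)) {
    cat("  selection:", paste(sprintf("%s=%d", names(log), log), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Subset an instrument set
#'
#' @param x an `instrument_set`.
#' @param i index or variant-id selection.
#' @param ... unused.
#' @export
`[.instrument_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$variant_ids)
  instrument_set(
    variant_ids = x$variant_ids[i], position = x$position[i],
    bx = x$bx[i], sx = x$sx[i], by = x$by[i], sy = x$sy[i],
    ld = x$ld[i, i, drop = FALSE],
    orientation_flips = x$orientation_flips[i],
    exposure = x$exposure, outcome = x$outcome,
    direction_of_interest = x$direction_of_interest
  )
}
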