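# Two-sample GWAS simulator. Haplotypes come from a latent Gaussian with
# block-AR(1) correlation thresholded at per-variant MAF quantiles; dosages
# are sums of two independent haplotypes. Exposure and outcome samples are
# drawn separately (no overlap by construction), summary statistics per
# variant by single-variant least squares (continuous) or the logistic score
# approximation (binary).

#' Simulation configuration
#'
#' Defines a synthetic cis locus and two-sample GWAS study. Defaults emulate
#' a strong cis-pQTL drug-target setting: a small protein-concentration
#' exposure GWAS (n = 4,248), a large outcome GWAS with no overlapping
#' samples, a 5,000-individual LD reference, and 20 variants in AR(1) LD
#' blocks inside the cis window.
#'
#' @param seed integer seed; all generation is deterministic given it.
#' @param J number of variants.
#' @param block_sizes LD-block sizes summing to `J` (default blocks of 5).
#' @param within_block_rho latent-Gaussian AR(1) base within a block
#'   (`corr = rho^|i-j|`); dosage-scale LD is somewhat attenuated by
#'   thresholding, see [latent_rho_for()].
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param n_ref,n_exposure,n_outcome sample sizes of the reference panel,
#'   exposure GWAS and outcome GWAS.
#' @param causal_alpha true causal effect of the exposure on the outcome
#'   (per exposure SD; log-odds per SD for binary outcomes).
#' @param h2_exposure variance of the exposure explained by the locus
#'   (strong cis-pQTL regime by default).
#' @param gamma per-variant conditional effects on the exposure; by default
#'   built with geometric decay `gamma_decay^(0:(J-1))` and alternating
#'   signs, scaled to reach `h2_exposure` exactly.
#' @param gamma_decay decay of the automatic `gamma` (1 = uniform).
#' @param pleiotropy_delta per-variant direct effects on the outcome
#'   (recycled), expressed relative to each variant's exposure-raising
#'   allele, so a constant positive value is directional pleiotropy in the
#'   MR-Egger sense; internally re-signed to the dosage coding.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction case prevalence for binary outcomes.
#' @param region a [gene_region()] the variants are placed in.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, J = 20L, block_sizes = NULL,
                       within_block_rho = 0.6, maf_range = c(0.1, 0.5),
                       n_ref = 5000L, n_exposure = 4248L, n_outcome = 100000L,
                       causal_alpha = -0.2, h2_exposure = 0.5,
                       gamma = NULL, gamma_decay = 0.85,
                       pleiotropy_delta = 0,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.1,
                       region = gene_region("16", 56995762L, 57017757L)) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(block_sizes)) {
    block_sizes <- c(rep(5L, J %/% 5L), if (J %% 5L) J %% 5L)
  }
  stopifnot(sum(block_sizes) == J, J >= 1,
            within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] >= 0.01, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_exposure > 0, h2_exposure < 1,
            case_fraction > 0, case_fraction < 1)
  structure(
    list(seed = as.integer(seed), J = as.integer(J),
         block_sizes = as.integer(block_sizes),
         within_block_rho = within_block_rho, maf_range = maf_range,
         n_ref = as.integer(n_ref), n_exposure = as.integer(n_exposure),
         n_outcome = as.integer(n_outcome),
         causal_alpha = causal_alpha, h2_exposure = h2_exposure,
         gamma = gamma, gamma_decay = gamma_decay,
         pleiotropy_delta = pleiotropy_delta,
         outcome_type = outcome_type, case_fraction = case_fraction,
         region = region),
    class = "sim_config"
  )
}

# Deterministic locus parameters shared by panel/exposure/outcome draws:
# MAFs, thresholds, latent block Cholesky factors, variant metadata, gamma
# scaled to the target variance explained via the analytic dosage covariance.
.sim_locus <- function(config) {
  set.seed(config$seed)
  J <- config$J
  mafs <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  thresholds <- stats::qnorm(1 - mafs)
  block <- rep(seq_along(config$block_sizes), config$block_sizes)
  chol_blocks <- lapply(config$block_sizes, function(m) {
    chol(config$within_block_rho^abs(outer(seq_len(m), seq_len(m), "-")))
  })
  # latent pairwise correlation (0 across blocks)
  latent <- matrix(0, J, J)
  for (b in seq_along(config$block_sizes)) {
    i <- which(block == b)
    latent[i, i] <- config$within_block_rho^abs(outer(seq_along(i), seq_along(i), "-"))
  }
  diag(latent) <- 1
  S <- dosage_covariance(latent, mafs)
  gamma <- config$gamma
  if (is.null(gamma)) {
    raw <- config$gamma_decay^(0:(J - 1)) * rep_len(c(1, -1), J) / sqrt(diag(S))
    gamma <- raw * sqrt(config$h2_exposure / drop(crossprod(raw, S %*% raw)))
  } else {
    stopifnot(length(gamma) == J)
  }
  # pleiotropy is directional in the MR-Egger sense: delta is specified
  # relative to each variant's exposure-raising allele, so re-sign to the
  # dosage coding by the sign of the marginal exposure effect
  marg_sign <- sign(drop(S %*% gamma))
  marg_sign[marg_sign == 0] <- 1
  delta <- rep_len(config$pleiotropy_delta, J) * marg_sign
  pos0 <- config$region$gene_start - config$region$flank
  pos1 <- config$region$gene_end + config$region$flank
  positions <- as.integer(round(seq(pos0, pos1, length.out = J + 2)))[2:(J + 1)]
  allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2, byrow = TRUE)
  ap <- allele_pairs[(seq_len(J) - 1) %% 4 + 1, , drop = FALSE]
  list(mafs = mafs, thresholds = thresholds, block = block,
       chol_blocks = chol_blocks, latent = latent, S = S,
       gamma = gamma, delta = delta,
       variant_ids = sprintf("rs%d", positions),
       positions = positions,
       effect_allele = ap[, 1], other_allele = ap[, 2])
}

#' Analytic dosage covariance of the threshold model
#'
#' Covariance of dosages (sums of two thresholded latent-Gaussian
#' haplotypes): `2 * (P(Z_j > t_j, Z_k > t_k) - maf_j * maf_k)` with the
#' orthant probability computed by one-dimensional quadrature.
#'
#' @param latent latent correlation matrix.
#' @param mafs per-variant minor-allele (haplotype) frequencies.
#' @return Covariance matrix of the dosages.
#' @export
dosage_covariance <- function(latent, mafs) {
  J <- length(mafs)
  t <- stats::qnorm(1 - mafs)
  S <- diag(2 * mafs * (1 - mafs), J)
  for (j in seq_len(J - 1)) {
    for (k in (j + 1):J) {
      rho <- latent[j, k]
      if (rho != 0) {
        p11 <- .orthant2(t[j], t[k], rho)
        S[j, k] <- S[k, j] <- 2 * (p11 - mafs[j] * mafs[k])
      }
    }
  }
  S
}

# P(Z1 > t1, Z2 > t2) for standard bivariate normal with correlation rho.
.orthant2 <- function(t1, t2, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(stats::pnorm(-max(t1, t2)))
    return(max(0, stats::pnorm(-t1) - stats::pnorm(t2)))
  }
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((rho * z - t2) / sqrt(1 - rho^2))
  }, lower = t1, upper = Inf, rel.tol = 1e-10)$value
}

#' Latent correlation achieving a target dosage correlation
#'
#' Thresholding attenuates correlation, so a latent AR(1) base of e.g. 0.6
#' yields dosage-scale LD below 0.6. This inverts the attenuation for one
#' pair of variants.
#'
#' @param target_r desired dosage-scale correlation.
#' @param maf1,maf2 the two minor-allele frequencies.
#' @return Latent Gaussian correlation.
#' @export
latent_rho_for <- function(target_r, maf1, maf2) {
  f <- function(rho) {
    t1 <- stats::qnorm(1 - maf1); t2 <- stats::qnorm(1 - maf2)
    cv <- .orthant2(t1, t2, rho) - maf1 * maf2
    cv / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2)) - target_r
  }
  stats::uniroot(f, c(-0.9999, 0.9999), tol = 1e-9)$root
}

# Draw an n x J dosage matrix from the locus model (uses current RNG state).
.draw_dosages <- function(locus, n) {
  J <- length(locus$mafs)
  g <- matrix(0L, n, J)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * J), n, J)
    for (b in seq_along(locus$chol_blocks)) {
      i <- which(locus$block == b)
      if (length(i) > 1) z[, i] <- z[, i] %*% locus$chol_blocks[[b]]
    }
    g <- g + (z > rep(locus$thresholds, each = n))
  }
  colnames(g) <- locus$variant_ids
  g
}

#' Simulate a reference dosage panel
#'
#' @param config a [sim_config()].
#' @return A [reference_panel()] of `config$n_ref` individuals, deterministic
#'   under `config$seed`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  locus <- .sim_locus(config)
  g <- .draw_dosages(locus, config$n_ref)
  sds <- apply(g, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate panel: constant dosage column (raise n_ref or maf)")
  reference_panel(g)
}

# Vectorized single-variant least-squares summary statistics.
.sumstats_ols <- function(g, y) {
  n <- length(y)
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- as.vector(crossprod(gc, yc)) / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  z <- beta / se
  # clamp: p-values below the double range would be dropped by validation
  list(beta = beta, se = se, p = pmax(2 * stats::pnorm(-abs(z)), 1e-300))
}

# Single-variant logistic score-approximation summary statistics.
.sumstats_logistic_score <- function(g, y) {
  ybar <- mean(y)
  gc <- sweep(g, 2, colMeans(g))
  u <- as.vector(crossprod(gc, y - ybar))
  v <- ybar * (1 - ybar) * colSums(gc^2)
  beta <- u / v
  se <- 1 / sqrt(v)
  z <- beta / se
  list(beta = beta, se = se, p = pmax(2 * stats::pnorm(-abs(z)), 1e-300))
}

.as_sumstats_table <- function(locus, stat, eaf, n, label, units, direction) {
  sumstats(data.frame(
    variant_id = locus$variant_ids, chromosome = locus$region_chr,
    position = locus$positions,
    effect_allele = locus$effect_allele, other_allele = locus$other_allele,
    eaf = eaf, beta = stat$beta, se = stat$se, p_value = stat$p, n = n,
    stringsAsFactors = FALSE
  ), trait_label = label, trait_units = units, direction_of_interest = direction)
}

#' Simulate a two-sample GWAS study with known truth
#'
#' Generates a reference panel, an exposure GWAS and an outcome GWAS from
#' non-overlapping individual draws of the same locus, with exposure
#' `x = G gamma + noise` (unit variance) and outcome
#' `y = causal_alpha * x + G delta + noise` (continuous, unit variance) or a
#' logistic liability model with the intercept solved to hit
#' `case_fraction` (binary).
#'
#' @param config a [sim_config()].
#' @param panel optionally, a pre-simulated [reference_panel()] to reuse (a
#'   real reference panel is one fixed dataset across analyses); by default
#'   a panel is drawn from the config.
#' @return list of class `simulated_study`: `panel`, `exposure_stats`,
#'   `outcome_stats`, and `truth` (list: `causal_alpha`, `gamma`, `delta`,
#'   `true_marginal` — the analytic per-variant marginal exposure effects
#'   `(S gamma)_j / S_jj`, `dosage_cov` — the generating covariance).
#' @export
simulate_two_sample <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  locus <- .sim_locus(config) # also seeds the RNG
  locus$region_chr <- config$region$chromosome
  if (is.null(panel)) {
    g_ref <- .draw_dosages(locus, config$n_ref)
    panel <- reference_panel(g_ref)
  }

  # exposure sample
  gx <- .draw_dosages(locus, config$n_exposure)
  var_e_x <- 1 - config$h2_exposure
  x <- drop(gx %*% locus$gamma) + stats::rnorm(config$n_exposure, 0, sqrt(var_e_x))
  stat_x <- .sumstats_ols(gx, x)
  exposure_stats <- .as_sumstats_table(
    locus, stat_x, eaf = colMeans(gx) / 2, n = config$n_exposure,
    label = "exposure", units = "SD", direction = "lowering")

  # outcome sample (disjoint draw)
  gy <- .draw_dosages(locus, config$n_outcome)
  xo <- drop(gy %*% locus$gamma) + stats::rnorm(config$n_outcome, 0, sqrt(var_e_x))
  eta <- config$causal_alpha * xo + drop(gy %*% locus$delta)
  if (config$outcome_type == "continuous") {
    coef_g <- config$causal_alpha * locus$gamma + locus$delta
    var_eta <- drop(crossprod(coef_g, locus$S %*% coef_g)) +
      config$causal_alpha^2 * var_e_x
    var_e_y <- 1 - var_eta
    if (var_e_y < 1e-8) {
      stop(sprintf("infeasible variance target: genetic + causal variance %.3f leaves residual %.3f",
                   var_eta, var_e_y))
    }
    y <- eta + stats::rnorm(config$n_outcome, 0, sqrt(var_e_y))
    stat_y <- .sumstats_ols(gy, y)
    units <- "SD"
  } else {
    c0 <- stats::uniroot(function(c) mean(stats::plogis(c + eta)) - config$case_fraction,
                         c(-30, 30), tol = 1e-10)$root
    y <- stats::rbinom(config$n_outcome, 1L, stats::plogis(c0 + eta))
    stat_y <- .sumstats_logistic_score(gy, y)
    case_fraction_realized <- mean(y)
    units <- "log-odds"
  }
  outcome_stats <- .as_sumstats_table(
    locus, stat_y, eaf = colMeans(gy) / 2, n = config$n_outcome,
    label = "outcome", units = units, direction = "lowering")

  structure(
    list(panel = panel,
         exposure_stats = exposure_stats, outcome_stats = outcome_stats,
         truth = list(causal_alpha = config$causal_alpha,
                      gamma = locus$gamma, delta = locus$delta,
                      true_marginal = drop(locus$S %*% locus$gamma) / diag(locus$S),
                      dosage_cov = locus$S,
                      case_fraction_realized = if (config$outcome_type == "binary")
                        case_fraction_realized),
         config = config),
    class = "simulated_study"
  )
}

#' Instrument set straight from a simulated study
#'
#' Convenience for tests and simulations: pairs the exposure and outcome
#' tables (alleles already aligned) and attaches panel LD, without the
#' window / strength / clumping selection steps. Pass `ld` to reuse a
#' precomputed matrix across replicates.
#'
#' @param study a `simulated_study`.
#' @param ld optional precomputed LD matrix over the study's variants.
#' @return An `instrument_set`.
#' @export
sim_instrument_set <- function(study, ld = NULL) {
  ex <- study$exposure_stats
  ou <- study$outcome_stats
  if (is.null(ld)) ld <- compute_ld(study$panel, ex$variant_id)
  instrument_set(
    variant_ids = ex$variant_id, position = ex$position,
    bx = ex$beta, sx = ex$se, by = ou$beta, sy = ou$se,
    ld = ld[ex$variant_id, ex$variant_id],
    exposure = attr(ex, "trait_label"), outcome = attr(ou, "trait_label"),
    direction_of_interest = attr(ex, "direction_of_interest")
  )
}

#' Canonical small simulated fixtures
#'
#' Deterministic named fixtures used across the test suite: `clean`
#' (homogeneous, nothing to prune), `outlier_spiked` (one outcome beta
#' shifted by 10 SE; `truth$spiked_id` names it), `pleiotropic` (constant
#' directional pleiotropy 0.08), `single_variant`, and `palindrome`
#' (outcome allele representation scrambled: swapped, strand-flipped and
#' palindromic variants; `truth$palindromic_ids` and `truth$swapped_ids`
#' record the construction).
#'
#' @param seed integer seed.
#' @return Named list of `simulated_study` objects (each <= 50 variants).
#' @export
fixture_suite <- function(seed) {
  base <- function(...) {
    sim_config(..., n_ref = 2000L, n_exposure = 4248L, n_outcome = 20000L)
  }
  clean <- simulate_two_sample(base(seed = seed, J = 12L, gamma_decay = 1))

  spiked <- simulate_two_sample(base(seed = seed + 1L, J = 12L, gamma_decay = 1))
  k <- 7L
  spiked$outcome_stats$beta[k] <- spiked$outcome_stats$beta[k] +
    10 * spiked$outcome_stats$se[k]
  spiked$truth$spiked_id <- spiked$outcome_stats$variant_id[k]

  pleio <- simulate_two_sample(base(seed = seed + 2L, J = 20L,
                                    pleiotropy_delta = 0.08))

  single <- simulate_two_sample(base(seed = seed + 3L, J = 1L,
                                     block_sizes = 1L, h2_exposure = 0.1))

  pal <- simulate_two_sample(base(seed = seed + 4L, J = 8L, gamma_decay = 1,
                                  within_block_rho = 0.3))
  ot <- as.data.frame(pal$outcome_stats)
  # variant 2: swapped alleles; variant 3: strand flip; variants 5, 6: palindromic
  ot[2, c("effect_allele", "other_allele")] <- ot[2, c("other_allele", "effect_allele")]
  ot$beta[2] <- -ot$beta[2]; ot$eaf[2] <- 1 - ot$eaf[2]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ot[3, c("effect_allele", "other_allele")] <-
    comp[unlist(ot[3, c("effect_allele", "other_allele")])]
  for (tab in c("exposure_stats", "outcome_stats")) {
    df <- as.data.frame(pal[[tab]])
    df[5, c("effect_allele", "other_allele")] <- c("A", "T")
    df[6, c("effect_allele", "other_allele")] <- c("C", "G")
    at <- attributes(pal[[tab]])
    pal[[tab]] <- sumstats(df, trait_label = at$trait_label,
                           trait_units = at$trait_units,
                           direction_of_interest = at$direction_of_interest)
  }
  # variant 6 ambiguous: push both eafs near 0.5
  pal$exposure_stats$eaf[6] <- 0.49
  pal$outcome_stats$eaf[6] <- 0.50
  at <- attributes(pal$outcome_stats)
  ot[5, c("effect_allele", "other_allele")] <- c("A", "T")
  ot[6, c("effect_allele", "other_allele")] <- c("C", "G")
  ot$eaf[6] <- 0.50
  pal$outcome_stats <- sumstats(ot, trait_label = at$trait_label,
                                trait_units = at$trait_units,
                                direction_of_interest = at$direction_of_interest)
  pal$exposure_stats$eaf[5] <- 0.22
  pal$outcome_stats$eaf[5] <- 0.21
  pal$truth$palindromic_ids <- pal$exposure_stats$variant_id[c(5, 6)]
  pal$truth$ambiguous_id <- pal$exposure_stats$variant_id[6]
  pal$truth$swapped_ids <- pal$exposure_stats$variant_id[2]

  list(clean = clean, outlier_spiked = spiked, pleiotropic = pleio,
       single_variant = single, palindrome = pal)
}
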