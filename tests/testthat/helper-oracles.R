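# Independent oracles: brute-force GLS via explicit matrix inversion
# (solve(Omega)), classic fixed-effect Wald-ratio meta-analysis, and an
# exhaustive re-implementation of greedy clumping. These deliberately avoid
# the package's Cholesky code paths.

oracle_gls <- function(X, y, Omega) {
  Oi <- solve(Omega)
  A <- t(X) %*% Oi %*% X
  coef <- solve(A, t(X) %*% Oi %*% y)
  list(coef = unname(drop(coef)), cov = unname(solve(A)))
}

oracle_ivw <- function(instr) {
  Omega <- outer(instr$sy, instr$sy) * instr$ld
  g <- oracle_gls(matrix(instr$bx, ncol = 1), instr$by, Omega)
  resid <- instr$by - g$coef * instr$bx
  list(slope = g$coef, se = sqrt(g$cov[1, 1]),
       q = drop(t(resid) %*% solve(Omega) %*% resid))
}

oracle_egger <- function(instr) {
  s <- ifelse(instr$bx < 0, -1, 1)
  bx <- instr$bx * s
  by <- instr$by * s
  ld <- instr$ld * outer(s, s)
  Omega <- outer(instr$sy, instr$sy) * ld
  X <- cbind(1, bx)
  g <- oracle_gls(X, by, Omega)
  resid <- by - drop(X %*% g$coef)
  list(intercept = g$coef[1], slope = g$coef[2],
       intercept_se = sqrt(g$cov[1, 1]), slope_se = sqrt(g$cov[2, 2]),
       q = drop(t(resid) %*% solve(Omega) %*% resid))
}

# classic fixed-effect meta-analysis of per-variant Wald ratios,
# weights bx^2 / sy^2 (valid under identity LD)
oracle_wald_meta <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  ratio <- by / bx
  est <- sum(w * ratio) / sum(w)
  list(slope = est, se = 1 / sqrt(sum(w)))
}

# exhaustive greedy clump: same ranking rule, written independently
oracle_clump <- function(ids, p, pos, ld, r2_max) {
  ord <- order(p, pos, ids)
  ids <- ids[ord]
  kept <- character(0)
  while (length(ids) > 0) {
    kept <- c(kept, ids[1])
    drop <- vapply(ids, function(v) ld[ids[1], v]^2 > r2_max, logical(1))
    drop[1] <- TRUE
    ids <- ids[!drop]
  }
  sort(kept)
}

# random positive-definite correlation fixture
random_ld <- function(J, strength = 1) {
  A <- matrix(stats::rnorm(J * J), J)
  S <- crossprod(A) / strength + diag(J) * J / 4
  stats::cov2cor(S)
}

random_instrument_set <- function(J, ld = random_ld(J)) {
  instrument_set(
    variant_ids = sprintf("v%02d", seq_len(J)),
    position = seq_len(J) * 1000L,
    bx = stats::rnorm(J, 0, 0.3),
    sx = stats::runif(J, 0.01, 0.05),
    by = stats::rnorm(J, 0, 0.05),
    sy = stats::runif(J, 0.01, 0.1),
    ld = ld
  )
}

make_sumstats_df <- function(n = 3, chromosome = "16", start = 57000000L,
                             beta = NULL, se = NULL, eaf = NULL,
                             ea = NULL, oa = NULL, p = NULL) {
  pos <- start + seq_len(n) * 1000L
  se <- se %||% rep(0.02, n)
  if (!is.null(p) && is.null(beta)) beta <- -stats::qnorm(p / 2) * se
  beta <- beta %||% rep_len(seq(0.02, 0.2, length.out = min(n, 8)), n)
  data.frame(
    variant_id = sprintf("rs%d", pos), chromosome = chromosome,
    position = pos,
    effect_allele = ea %||% rep_len(c("A", "C", "G"), n),
    other_allele = oa %||% rep_len(c("G", "T", "A"), n),
    eaf = eaf %||% rep(0.3, n), beta = beta, se = se,
    p_value = p %||% (2 * stats::pnorm(-abs(beta / se))),
    n = 4248, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
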