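test_that("read_sumstats parses, validates and sorts a well-formed table", {
  df <- make_sumstats_df(3)
  df <- df[c(3, 1, 2), ] # scrambled row order
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sumstats(path)
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$position, sort(df$position))
  expect_equal(attr(tab, "n_dropped"), 0)
})

test_that("rows violating invariants are dropped with a warning", {
  df <- make_sumstats_df(3)
  df$se[2] <- 0
  expect_warning(tab <- sumstats(df), "dropped 1")
  expect_equal(nrow(tab), 2)
  expect_false(df$variant_id[2] %in% tab$variant_id)

  df2 <- make_sumstats_df(4)
  df2$eaf[1] <- 1.4
  df2$other_allele[3] <- df2$effect_allele[3]
  expect_warning(tab2 <- sumstats(df2), "dropped 2")
  expect_equal(nrow(tab2), 2)
})

test_that("p-values inconsistent with beta/se warn but are kept", {
  df <- make_sumstats_df(2)
  df$p_value[1] <- min(1, df$p_value[1] * 5)
  expect_warning(tab <- sumstats(df), "inconsistent")
  expect_equal(nrow(tab), 2)
})

test_that("alternate column names parse identically through a dialect", {
  df <- make_sumstats_df(3)
  path1 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path1, sep = "\t", quote = FALSE, row.names = FALSE)
  legacy <- df
  names(legacy) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(legacy, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- sumstats_dialect(variant_id = "SNP", chromosome = "CHR", position = "BP",
                        effect_allele = "A1", other_allele = "A2", eaf = "FRQ",
                        beta = "BETA", se = "SE", p_value = "P", n = "N")
  t1 <- read_sumstats(path1)
  t2 <- read_sumstats(path2, dialect = d)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_error(read_sumstats(path2), "lacks mapped column")
  expect_error(sumstats_dialect(nonsense = "X"), "unknown dialect")
})

test_that("summary statistics survive a write/read round trip to full precision", {
  set.seed(41)
  df <- make_sumstats_df(6, beta = rnorm(6) / 3, se = runif(6, 1e-4, 0.1),
                         eaf = runif(6, 0.05, 0.95))
  df$p_value <- 2 * pnorm(-abs(df$beta / df$se))
  tab <- sumstats(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path)
  for (v in c("beta", "se", "p_value", "eaf")) {
    expect_equal(back[[v]], tab[[v]], tolerance = 1e-12)
  }
})

test_that("harmonize aligns identical, swapped and strand-flipped alleles", {
  ex <- sumstats(make_sumstats_df(4, ea = c("A", "A", "C", "G"),
                                  oa = c("G", "C", "T", "T"),
                                  eaf = c(0.3, 0.2, 0.4, 0.25)))
  ou_df <- make_sumstats_df(4, ea = c("A", "C", "G", "A"),
                            oa = c("G", "A", "A", "C"),
                            beta = c(0.5, 0.3, -0.2, 0.1),
                            eaf = c(0.31, 0.79, 0.61, 0.74))
  ou <- sumstats(ou_df)
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 4)
  # identical -> unchanged; swapped / flip+swap -> negated, eaf complemented;
  # pure strand flip -> unchanged
  expect_equal(h$by, c(0.5, -0.3, -0.2, -0.1))
  expect_equal(h$eaf_outcome, c(0.31, 0.21, 0.61, 0.26))
  expect_equal(h$flipped, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("harmonize is idempotent and double swap is an involution", {
  set.seed(23)
  ex <- sumstats(make_sumstats_df(5, eaf = runif(5, 0.1, 0.4)))
  ou <- sumstats(make_sumstats_df(5, beta = rnorm(5) / 10, eaf = runif(5, 0.1, 0.4)))
  h1 <- harmonize(ex, ou)
  # feed the aligned outcome back in: nothing should change
  ou_aligned <- sumstats(data.frame(
    variant_id = h1$variant_id, chromosome = h1$chromosome,
    position = h1$position, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_outcome,
    beta = h1$by, se = h1$sy, p_value = h1$py, n = h1$ny))
  h2 <- harmonize(ex, ou_aligned)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$flipped, rep(FALSE, nrow(h2)))

  # double swap returns the original exactly
  ou_df <- as.data.frame(ou)
  swapped <- ou_df
  swapped[, c("effect_allele", "other_allele")] <- swapped[, c("other_allele", "effect_allele")]
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  twice <- swapped
  twice[, c("effect_allele", "other_allele")] <- twice[, c("other_allele", "effect_allele")]
  twice$beta <- -twice$beta
  twice$eaf <- 1 - twice$eaf
  expect_identical(twice$beta, ou_df$beta)
  expect_equal(twice$eaf, ou_df$eaf, tolerance = 1e-15)
  h3 <- harmonize(ex, sumstats(swapped))
  expect_equal(h3$by, h1$by, tolerance = 1e-15)
})

test_that("palindrome policies behave per the rule table", {
  # enumerated cases: (exposure eaf, outcome eaf, policy) -> expectation
  ex <- sumstats(make_sumstats_df(4, ea = c("A", "A", "C", "A"),
                                  oa = c("T", "T", "G", "T"),
                                  eaf = c(0.20, 0.20, 0.50, 0.30)))
  ou <- sumstats(make_sumstats_df(4, ea = c("A", "A", "C", "A"),
                                  oa = c("T", "T", "G", "T"),
                                  beta = c(0.4, 0.4, 0.4, 0.4),
                                  eaf = c(0.21, 0.79, 0.50, 0.55)))
  expect_message(h <- harmonize(ex, ou, palindrome_policy = "infer-by-eaf"),
                 "dropped")
  # v1: eafs agree -> kept unflipped; v2: complement agrees -> flipped;
  # v3: maf > 0.42 -> dropped; v4: neither agrees -> dropped
  expect_equal(nrow(h), 2)
  expect_equal(h$flipped, c(FALSE, TRUE))
  expect_equal(h$by, c(0.4, -0.4))

  expect_message(h2 <- harmonize(ex, ou, palindrome_policy = "drop-ambiguous"),
                 "dropped")
  expect_equal(nrow(h2), 0)
})

test_that("incompatible allele pairs are dropped and logged, never kept", {
  ex <- sumstats(make_sumstats_df(2, ea = c("A", "C"), oa = c("G", "T")))
  ou <- sumstats(make_sumstats_df(2, ea = c("A", "T"), oa = c("C", "C")))
  expect_message(h <- harmonize(ex, ou), "dropped")
  expect_equal(nrow(h), 1)
  expect_match(attr(h, "drop_log"), "incompatible", all = FALSE)
})

test_that("matching falls back to chromosome:position and drops multi-allelic collisions", {
  ex_df <- make_sumstats_df(3)
  ou_df <- ex_df
  ou_df$variant_id <- paste0("chr16_", ou_df$position) # different id scheme
  h <- harmonize(sumstats(ex_df), sumstats(ou_df))
  expect_equal(nrow(h), 3)

  # second outcome variant at the same position -> collision dropped
  ou_df2 <- rbind(ou_df, ou_df[1, ])
  ou_df2$variant_id[4] <- "chr16_dup"
  ou_df2$effect_allele[4] <- "C"; ou_df2$other_allele[4] <- "A"
  expect_message(h2 <- harmonize(sumstats(ex_df), sumstats(ou_df2)), "dropped")
  expect_equal(nrow(h2), 2)
})

test_that("LD matrices round-trip and are validated", {
  set.seed(5)
  r <- random_ld(4)
  dimnames(r) <- list(letters[1:4], letters[1:4])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld(r, path)
  back <- read_ld(path)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-12, ignore_attr = TRUE)

  bad <- r; bad[1, 2] <- 0.9 # asymmetric
  expect_error(validate_ld(bad), "symmetric")
  bad2 <- r; diag(bad2) <- 0.5
  expect_error(validate_ld(bad2), "diagonal")
  notpd <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(validate_ld(notpd), "eigenvalue")
})

test_that("write_results emits one row per fit and round-trips numerically", {
  set.seed(11)
  fits <- list(fit_ivw(random_instrument_set(5)),
               fit_egger(random_instrument_set(6)),
               fit_ivw(random_instrument_set(4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_results(fits, path)
  back <- read_results(path)
  expect_equal(nrow(back), 3)
  expect_true(all(back$method %in% c("IVW", "Egger")))
  for (v in c("slope", "slope_se", "ci_low", "ci_high", "p", "q_stat")) {
    expect_equal(back[[v]], out[[v]], tolerance = 1e-12)
  }
  expect_error(write_results(list(), path), "no fits")

  single <- write_results(fits[[1]], path)
  expect_equal(nrow(read_results(path)), 1)
})
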