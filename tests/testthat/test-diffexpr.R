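toy_counts <- function(n_genes = 50, seed = 21, lfc = NULL, sigma = 0.1,
                       n_rep = 3, base_count = 200) {
  # two groups (vehicle / drug) in one cell line, lognormal-ish counts
  withr::with_seed(seed, {
    mu <- log2(base_count) + rnorm(n_genes)
    samples <- c(paste0("veh", 1:n_rep), paste0("drg", 1:n_rep))
    eff <- if (is.null(lfc)) rep(0, n_genes) else lfc
    m <- vapply(seq_along(samples), function(i) {
      shift <- if (grepl("drg", samples[i])) eff else 0
      round(2^(mu + shift + rnorm(n_genes, 0, sigma)))
    }, numeric(n_genes))
    rownames(m) <- paste0("G", seq_len(n_genes))
    colnames(m) <- samples
    m
  })
}

toy_design <- function(n_rep = 3) {
  tibble::tibble(sample = c(paste0("veh", 1:n_rep), paste0("drg", 1:n_rep)),
                 cell_line = "CL",
                 condition = rep(c("vehicle", "drugX"), each = n_rep),
                 replicate = rep(1:n_rep, 2))
}

test_that("log-CPM normalisation matches the direct formula and filters", {
  counts <- matrix(c(1000, 0, 999000,
                     2000, 0, 1998000), ncol = 2,
                   dimnames = list(c("G1", "Gzero", "Gbig"), c("s1", "s2")))
  # no filtering: every gene must pass in >= 1 sample
  out <- normalize_log_counts(counts, min_group_size = 1, cpm_cutoff = -1)
  expect_equal(out["G1", "s1"], log2(1000.5 / 1000001 * 1e6), tolerance = 1e-12)
  # default-style filter drops the all-zero gene
  out2 <- normalize_log_counts(counts, min_group_size = 2, cpm_cutoff = 1)
  expect_false("Gzero" %in% rownames(out2))
  # CPM scale invariance: doubling all counts in a sample barely moves values
  # for expressed genes (the +0.5 offset dominates only at zero counts)
  doubled <- counts
  doubled[, 1] <- counts[, 1] * 2
  out3 <- normalize_log_counts(doubled, min_group_size = 1, cpm_cutoff = -1)
  expressed <- c("G1", "Gbig")
  expect_lt(max(abs(out3[expressed, 1] - out[expressed, 1])), 1e-3)
  expect_error(normalize_log_counts(matrix(0, 2, 1)), "zero library")
})

test_that("variance squeeze has the right d0 limits", {
  withr::local_seed(31)
  s2 <- stats::rchisq(500, df = 4) / 4
  raw <- squeeze_variances(s2, df = 4, d0 = 0)
  expect_equal(raw$s2_post, s2)
  inf <- squeeze_variances(s2, df = 4, d0 = Inf)
  expect_true(all(inf$s2_post == inf$s02))
  est <- squeeze_variances(s2, df = 4)
  expect_gt(est$d0, 0)
  # shrinkage pulls everything toward the prior
  expect_true(all(abs(est$s2_post - est$s02) <= abs(s2 - est$s02) + 1e-12))
})

test_that("identical group means give logFC 0 and planted effects are recovered", {
  counts <- toy_counts(lfc = rep(0, 50), sigma = 0)
  le <- normalize_log_counts(counts, min_group_size = 1)
  sig <- fit_contrasts(le, toy_design())
  expect_true(all(abs(sig$logFC) < 1e-8))
  expect_true(all(abs(sig$t_stat) < 1e-6 | is.nan(sig$t_stat)))

  lfc <- c(1, rep(0, 49))
  sig2 <- fit_contrasts(normalize_log_counts(toy_counts(lfc = lfc, sigma = 0.05),
                                             min_group_size = 1),
                        toy_design())
  expect_equal(sig2$logFC[sig2$gene == "G1"], 1, tolerance = 0.1)
  expect_equal(attr(sig2, "polarity"), "drug_minus_vehicle")
})

test_that("swapping condition labels negates logFC and t", {
  counts <- toy_counts(lfc = withr::with_seed(5, rnorm(50, 0, 0.5)))
  le <- normalize_log_counts(counts, min_group_size = 1)
  d <- toy_design()
  swapped <- dplyr::mutate(d, condition = ifelse(condition == "vehicle",
                                                 "drugX", "vehicle"))
  a <- fit_contrasts(le, d)
  b <- fit_contrasts(le, swapped)
  expect_equal(b$logFC, -a$logFC)
  expect_equal(b$t_stat, -a$t_stat)
})

test_that("ordinary logFC agrees with the sample-mean difference and limma", {
  skip_if_not_installed("limma")
  counts <- toy_counts(n_genes = 40, lfc = withr::with_seed(9, rnorm(40, 0, 0.7)))
  le <- normalize_log_counts(counts, min_group_size = 1)
  sig <- fit_contrasts(le, toy_design(), d0 = 0)
  mean_diff <- rowMeans(le[, 4:6]) - rowMeans(le[, 1:3])
  expect_equal(sig$logFC, unname(mean_diff), tolerance = 1e-10)

  design_mm <- cbind(vehicle = rep(c(1, 0), each = 3),
                     drug = rep(c(0, 1), each = 3))
  fit <- limma::lmFit(le, design_mm)
  fit <- limma::contrasts.fit(fit, c(-1, 1))
  expect_equal(sig$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  # moderated t ordering matches limma's eBayes on the same data
  mod <- fit_contrasts(le, toy_design())
  eb <- limma::eBayes(fit)
  expect_gt(cor(mod$t_stat, eb$t[, 1], method = "spearman"), 0.99)
})

test_that("moderated t is calibrated on null data", {
  counts <- toy_counts(n_genes = 2000, seed = 77, sigma = 0.15)
  le <- normalize_log_counts(counts, min_group_size = 1)
  sig <- fit_contrasts(le, toy_design())
  d0 <- attr(sig, "moderation")$d0
  df_tot <- if (is.infinite(d0)) Inf else d0 + attr(sig, "moderation")$df_resid
  frac <- mean(abs(sig$t_stat) > qt(0.975, df_tot))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("degenerate designs are rejected with informative errors", {
  counts <- toy_counts()
  le <- normalize_log_counts(counts, min_group_size = 1)
  # aliasing cell line with condition leaves no within-line drug/vehicle pair
  d <- toy_design()
  d$cell_line <- c(rep("A", 3), rep("B", 3))
  expect_error(fit_contrasts(le, d), "no drug-vs-vehicle contrast")
  # a single group has no contrast and no residual structure
  d2 <- toy_design()
  d2$condition <- "drugX"
  expect_error(fit_contrasts(le, d2), "fewer than 2")
  # one sample per group exhausts the residual degrees of freedom
  le1 <- le[, c(1, 4)]
  d3 <- toy_design()[c(1, 4), ]
  expect_error(fit_contrasts(le1, d3), "residual degrees")
  # requesting a contrast whose groups are absent names them
  expect_error(fit_contrasts(le, toy_design(),
                             contrasts = tibble::tibble(cell_line = "CL",
                                                        drug = "absent")),
               "contrast groups absent")
})
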