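test_that("camera at rho = 0 equals the textbook pooled two-sample t-test", {
  for (seed in 1:50) {
    withr::local_seed(seed)
    n <- sample(10:50, 1)
    m <- sample(2:(n - 2), 1)
    stats_vec <- setNames(rnorm(n), paste0("g", 1:n))
    idx <- sample(n, m)
    got <- camera_test(stats_vec, idx, rho = 0)
    ref <- t.test(stats_vec[idx], stats_vec[-idx], var.equal = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$direction,
                 if (ref$estimate[1] > ref$estimate[2]) "Up" else "Down")
  }
})

test_that("camera respects symmetry, shift invariance and rho monotonicity", {
  withr::local_seed(101)
  stats_vec <- setNames(rnorm(30), paste0("g", 1:30))
  idx <- order(stats_vec, decreasing = TRUE)[1:5]
  up <- camera_test(stats_vec, idx, rho = 0.01)
  expect_equal(up$direction, "Up")
  comp <- camera_test(stats_vec, setdiff(1:30, idx), rho = 0)
  base <- camera_test(stats_vec, idx, rho = 0)
  expect_equal(comp$direction, "Down")
  expect_equal(comp$p, base$p, tolerance = 1e-10)
  shifted <- camera_test(stats_vec + 7, idx, rho = 0.01)
  expect_equal(shifted$p, up$p, tolerance = 1e-12)

  ps <- vapply(c(0, 0.01, 0.05, 0.2, 0.5), function(r) {
    camera_test(stats_vec, idx, rho = r)$p
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))

  expect_error(camera_test(stats_vec, 1), "2 <= m < n")
  expect_error(camera_test(stats_vec, 1:30), "2 <= m < n")
})

test_that("camera agrees with the preranked camera in limma", {
  skip_if_not_installed("limma")
  withr::local_seed(55)
  stats_vec <- setNames(rnorm(200), paste0("g", 1:200))
  idx <- sample(200, 25)
  for (r in c(0, 0.01, 0.1)) {
    ours <- camera_test(stats_vec, idx, rho = r)
    ref <- limma::cameraPR(stats_vec, list(set = idx), inter.gene.cor = r,
                           sort = FALSE)
    expect_equal(ours$p, ref$PValue, tolerance = 1e-8)
    expect_equal(ours$direction, as.character(ref$Direction))
  }
})

test_that("signed log score follows the sign convention", {
  expect_equal(signed_log_score(0.001, "Up"), 3)
  expect_equal(signed_log_score(0.01, "Down"), -2)
  expect_equal(signed_log_score(1, "Up"), 0)
  expect_error(signed_log_score(0, "Up"), "\\(0, 1\\]")
  expect_error(signed_log_score(0.5, "sideways"), "Up.*Down")
})

test_that("enrich_all yields one record per set x signature x direction", {
  withr::local_seed(77)
  genes <- paste0("g", 1:100)
  sigs <- tidyr::expand_grid(contrast = c("CL1_drug", "CL2_drug"), gene = genes) %>%
    dplyr::mutate(t_stat = rnorm(dplyr::n()))
  ids <- sprintf("CGS%03d_%s_%s:1", 1:4, c("A375", "MCF7", "A375", "MCF7"),
                 c("TP53", "TP53", "GPX4", "GPX4"))
  up <- setNames(lapply(1:4, function(i) sample(genes, 10)), ids)
  down <- setNames(lapply(1:4, function(i) sample(genes, 10)), ids)
  res <- enrich_all(sigs, up, down, rho = 0)
  expect_equal(nrow(res), 16)
  expect_setequal(unique(res$pert_gene), c("TP53", "GPX4"))
  expect_setequal(unique(res$collection), c("up", "down"))

  # vectorised path equals the single-set reference implementation
  stats_vec <- setNames(sigs$t_stat[sigs$contrast == "CL1_drug"], genes)
  for (i in 1:4) {
    row <- res[res$pert == "CL1_drug" & res$sig_id == ids[i] &
                 res$collection == "up", ]
    ref <- camera_test(stats_vec, which(genes %in% up[[i]]), rho = 0)
    expect_equal(row$p, ref$p, tolerance = 1e-12)
    expect_equal(row$signed_score, ref$signed_score, tolerance = 1e-12)
  }

  # a planted mimic set (large positive t in the signature) comes out Up
  mimic_genes <- order(stats_vec, decreasing = TRUE)[1:10]
  up2 <- setNames(list(genes[mimic_genes]), ids[1])
  down2 <- setNames(list(sample(genes, 10)), ids[1])
  res2 <- enrich_all(sigs[sigs$contrast == "CL1_drug", ], up2, down2)
  expect_equal(res2$direction[res2$collection == "up"], "Up")

  # permuting the gene order of the inputs changes no score
  perm <- sample(nrow(sigs))
  res3 <- enrich_all(sigs[perm, ], up, down, rho = 0)
  key <- function(x) dplyr::arrange(x, pert, sig_id, collection)
  expect_equal(key(res3)$signed_score, key(res)$signed_score)

  # sets too small for a universe are recorded as missing, not zero
  up_small <- setNames(list(c(genes[1], "absent1", "absent2")), ids[1])
  suppressWarnings(res4 <- enrich_all(sigs, up_small, up_small))
  expect_true(all(is.na(res4$signed_score)))
})

test_that("preranked GSEA ES matches the brute-force walk", {
  for (seed in 1:50) {
    withr::local_seed(seed + 1000)
    ranks <- setNames(rnorm(12), paste0("g", 1:12))
    set <- sample(names(ranks), sample(2:6, 1))
    got <- preranked_gsea(ranks, set, n_perm = 10, seed = 1)
    expect_equal(got$es, brute_walk_es(ranks, set), tolerance = 1e-12)
  }
})

test_that("preranked GSEA handles closed-form and symmetry cases", {
  # equal |value| everywhere, set = top 3 of 10: two-rate walk peaks after the set
  ranks <- setNames(rep(1, 10), paste0("g", 1:10))
  ranks <- ranks + seq(0.001, 0.01, length.out = 10)  # strict order, ~equal weight
  set <- names(sort(ranks, decreasing = TRUE))[1:3]
  got <- preranked_gsea(ranks, set, n_perm = 10, seed = 1)
  expect_equal(got$es, brute_walk_es(ranks, set), tolerance = 1e-12)
  expect_gt(got$es, 0.9)  # all in-set increments land before any decrement

  withr::local_seed(9)
  ranks2 <- setNames(rnorm(30), paste0("g", 1:30))
  set2 <- sample(names(ranks2), 6)
  a <- preranked_gsea(ranks2, set2, n_perm = 50, seed = 3)
  b <- preranked_gsea(-ranks2, set2, n_perm = 50, seed = 3)
  expect_equal(b$es, -a$es, tolerance = 1e-12)

  expect_error(preranked_gsea(ranks2, "missing", n_perm = 10, seed = 1), "overlap")
  expect_error(preranked_gsea(ranks2, names(ranks2), n_perm = 10, seed = 1),
               "degenerate")
  expect_error(preranked_gsea(ranks2, set2, n_perm = 10), "mandatory")
  expect_true(got$p_perm >= 1 / 11 && got$p_perm <= 1)
})

test_that("preranked GSEA ES agrees with fgsea on a fixed instance", {
  skip_if_not_installed("fgsea")
  withr::local_seed(123)
  ranks <- setNames(rnorm(500), paste0("g", 1:500))
  set <- sample(names(ranks), 40)
  ours <- preranked_gsea(ranks, set, n_perm = 100, seed = 5)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = set), ranks, scoreType = "std", nproc = 1)
  )
  expect_equal(ours$es, ref$ES, tolerance = 1e-6)
})
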