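example_pm <- function() {
  readr::read_csv(example_path("example_predictor_matrix.csv"),
                  show_col_types = FALSE)
}

test_that("best-predictor family means match hand arithmetic on the worked example", {
  bp <- best_predictors_rank(example_pm())
  cyp <- bp[bp$gene == "CYP1B1", ]
  expect_equal(cyp$mean_r_expression, (-0.279 + -0.234) / 2)
  expect_equal(cyp$mean_r_depscore, (-0.049 + -0.102) / 2)
  expect_equal(cyp$mean_similarity, mean(c(-3783, 1074, -35, -1640)))
  expect_equal(cyp$biggest_r, -0.0755)
})

test_that("full best-predictors ranking matches a spreadsheet-style recomputation", {
  pm <- example_pm()
  bp <- best_predictors_rank(pm, similarity_best = "positive")
  # independent recomputation: base loops + counting ranks
  vals <- as.matrix(pm[-1])
  me <- rowMeans(vals[, 1:2])
  md <- rowMeans(vals[, 3:4])
  ms <- rowMeans(vals[, 5:8])
  rank_corr <- pmax(counting_rank(me), counting_rank(md))
  rank_sim <- counting_rank(-ms)
  mean_rank <- (rank_corr + rank_sim) / 2
  rank_total <- counting_rank(mean_rank)
  ref <- tibble::tibble(gene = pm$gene, rank_corr, rank_sim, rank_total)
  merged <- dplyr::inner_join(bp, ref, by = "gene")
  expect_equal(merged$rank_corr.x, merged$rank_corr.y)
  expect_equal(merged$rank_similarity, merged$rank_sim)
  expect_equal(merged$rank_total.x, merged$rank_total.y)
  # sorted strongest candidate first
  expect_equal(bp$rank_total, sort(bp$rank_total))
})

test_that("ranking is invariant to row order and duplicated family columns", {
  pm <- example_pm()
  shuffled <- withr::with_seed(2, pm[sample(nrow(pm)), ])
  expect_equal(best_predictors_rank(shuffled), best_predictors_rank(pm))
  dup <- dplyr::bind_cols(pm, setNames(pm[-1], paste0(names(pm)[-1], " copy")))
  expect_equal(best_predictors_rank(dup)$rank_total,
               best_predictors_rank(pm)$rank_total)
})

test_that("polarity flips the similarity ranking direction", {
  pm <- example_pm()
  pos <- best_predictors_rank(pm, similarity_best = "positive")
  neg <- best_predictors_rank(pm, similarity_best = "negative")
  merged <- dplyr::inner_join(pos, neg, by = "gene")
  n <- nrow(pm)
  # no tied similarity means in the example, so the rankings are mirror images
  expect_equal(merged$rank_similarity.x, n + 1 - merged$rank_similarity.y)
  # under "negative", the most negative similarity gene ranks first in that family
  expect_equal(neg$gene[neg$rank_similarity == 1],
               pm$gene[which.min(rowMeans(as.matrix(pm[6:9])))])
})

test_that("a single-gene matrix gets rank 1 everywhere; empty families error", {
  pm <- example_pm()[1, ]
  bp <- best_predictors_rank(pm)
  expect_equal(bp$rank_corr, 1)
  expect_equal(bp$rank_similarity, 1)
  expect_equal(bp$rank_total, 1)
  expect_error(best_predictors_rank(example_pm()[1:5]), "similarity")
})

test_that("UMAP embedding is deterministic and respects predictor geometry", {
  withr::local_seed(88)
  n <- 200
  pm <- tibble::tibble(gene = sprintf("G%03d", 1:n),
                       `d1 AUC cor to expression` = rnorm(n),
                       `d1 AUC cor to depscore` = rnorm(n),
                       `Transcriptomic similarity to p1` = rnorm(n, sd = 100))
  pm[2, -1] <- pm[1, -1]  # identical predictor rows
  emb1 <- embed_predictors(pm, seed = 11)
  emb2 <- embed_predictors(pm, seed = 11)
  expect_identical(emb1, emb2)
  d12 <- sqrt((emb1$x[1] - emb1$x[2])^2 + (emb1$y[1] - emb1$y[2])^2)
  all_d <- as.vector(dist(cbind(emb1$x, emb1$y)))
  expect_lte(d12, quantile(all_d, 0.01))
})

test_that("the embedding refuses too-few complete rows, suggesting the fallback", {
  pm <- tibble::tibble(gene = paste0("G", 1:20),
                       `d1 AUC cor to expression` = c(rnorm(10), rep(NA, 10)),
                       `d1 AUC cor to depscore` = rnorm(20))
  expect_error(embed_predictors(pm), "pca_kmeans_fallback")
})

test_that("nearest neighbours order by distance with the key gene first", {
  coords <- tibble::tibble(gene = c("key", "b", "c"),
                           x = c(0, 3, 6), y = c(0, 4, 8))
  nn <- nearest_neighbors(coords, "key", n = 3)
  expect_equal(nn$gene, c("key", "b", "c"))
  expect_equal(nn$distance, c(0, 5, 10))
  expect_equal(nn$order, 1:3)
  expect_error(nearest_neighbors(coords, "kee"), "close matches")

  withr::local_seed(14)
  big <- tibble::tibble(gene = sprintf("G%03d", 1:500),
                        x = rnorm(500), y = rnorm(500))
  expect_equal(nrow(nearest_neighbors(big, "G001")), 75)
})

test_that("PCA fallback captures dominant variance, separates blobs, is deterministic", {
  withr::local_seed(23)
  line <- tibble::tibble(gene = paste0("G", 1:30),
                         `d1 AUC cor to expression` = seq(-1, 1, length.out = 30),
                         `d1 AUC cor to depscore` = seq(-1, 1, length.out = 30) +
                           rnorm(30, 0, 1e-4))
  pc <- pca_kmeans_fallback(line, k_clusters = 2, seed = 1)
  expect_gte(attr(pc, "var_explained")[1], 0.99)

  blob <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
  pmb <- tibble::tibble(gene = paste0("G", 1:60),
                        `d1 AUC cor to expression` = blob[, 1],
                        `d1 AUC cor to depscore` = blob[, 2])
  pk <- pca_kmeans_fallback(pmb, k_clusters = 2, seed = 4)
  truth <- rep(1:2, each = 30)
  agreement <- max(mean(pk$cluster == truth), mean(pk$cluster == 3 - truth))
  expect_equal(agreement, 1)
  expect_identical(pk, pca_kmeans_fallback(pmb, k_clusters = 2, seed = 4))
})

test_that("citation counts come from the fixture verbatim, with zero for unknowns", {
  client <- citation_client_fixture(list("GPX4 AND Ferroptosis" = 1500,
                                         "GPX4 AND Iron" = 800,
                                         "NOVEL1 AND Ferroptosis" = 0))
  got <- citation_counts("GPX4", c("Ferroptosis", "Iron"), client)
  expect_equal(got$count, c(1500L, 800L))
  expect_warning(miss <- citation_counts("UNKNOWN9", "Ferroptosis", client),
                 "not in fixture")
  expect_equal(miss$count, 0L)
  grid <- suppressWarnings(citation_counts(c("GPX4", "NOVEL1"),
                                           c("Ferroptosis", "Iron", "GPX4"),
                                           client))
  expect_equal(nrow(grid), 6)
  # JSON round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list("A AND t" = 3), tmp, auto_unbox = TRUE)
  expect_equal(citation_counts("A", "t", citation_client_fixture(tmp))$count, 3L)
})

test_that("candidate selection truncates then filters cited genes", {
  ranking <- tibble::tibble(gene = sprintf("G%03d", 1:100),
                            rank_total = 1:100)
  expect_equal(nrow(select_candidates(ranking, NULL, top_n = 75)), 75)

  cites <- tibble::tibble(gene = c("G001", "G001", "G080"),
                          term = c("Ferroptosis", "Iron", "Ferroptosis"),
                          count = c(10L, 2L, 5L))
  sel <- select_candidates(ranking, cites, top_n = 75)
  expect_false("G001" %in% sel$gene)   # cited, inside top 75 -> dropped
  expect_false("G080" %in% sel$gene)   # outside top 75 anyway
  expect_equal(nrow(sel), 74)

  cites10 <- tibble::tibble(gene = sprintf("G%03d", 1:10), term = "t", count = 1L)
  expect_equal(nrow(select_candidates(ranking, cites10, top_n = 75)), 65)
  # filter-first keeps the list at top_n when enough uncited genes exist
  expect_equal(nrow(select_candidates(ranking, cites10, top_n = 75,
                                      filter_first = TRUE)), 75)
})

test_that("text-mining aggregation forwards the top genes by mean similarity", {
  withr::local_seed(3)
  totals <- tidyr::expand_grid(gene = sprintf("G%03d", 1:500),
                               pert = c("p1", "p2")) %>%
    dplyr::mutate(total = sample(-499:499, 1000, replace = TRUE))
  top <- top_similarity_genes(totals, n = 100)
  expect_equal(nrow(top), 100)
  means <- totals %>% dplyr::group_by(gene) %>%
    dplyr::summarise(m = mean(total))
  expect_gte(min(top$mean_similarity), sort(means$m, decreasing = TRUE)[101])
})
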