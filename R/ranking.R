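# Candidate ranking: best-predictors rank aggregation, UMAP
# nearest-neighbour ranking with a PCA/k-means fallback, and
# citation-count novelty filtering.

predictor_families <- function(pm) {
  list(
    expression = grep("AUC cor to expression", names(pm), value = TRUE),
    depscore = grep("AUC cor to depscore", names(pm), value = TRUE),
    similarity = grep("Transcriptomic similarity", names(pm), value = TRUE)
  )
}

#' Aggregate all predictors into one rank per gene (best-predictors method)
#'
#' Per gene: the expression-correlation and essentiality-correlation
#' columns are averaged within family and competition-ranked (most negative
#' correlation = rank 1, the suppressor convention); `rank_corr` is the
#' elementwise maximum (i.e. worse) of the two, so a gene must rank well in
#' both omics arms. The similarity columns are averaged and ranked with
#' rank 1 for the strongest candidate under `similarity_best` ("positive":
#' largest total is best, the default; "negative": smallest). `mean_rank`
#' averages `rank_corr` and `rank_similarity`, and `rank_total` is its
#' competition rank, so rank_total 1 is the strongest candidate; the output
#' is sorted strongest first. Genes with no similarity evidence are dropped
#' before ranking. `biggest_r` (the larger of the two family means) is
#' reported but not ranked on.
#'
#' @param pm Predictor matrix from [assemble_predictor_matrix()].
#' @param similarity_best Polarity of the similarity total
#'   (`"positive"`/`"negative"`).
#' @return Tibble `gene`, `mean_r_expression`, `mean_r_depscore`,
#'   `biggest_r`, `mean_similarity`, `rank_corr`, `rank_similarity`,
#'   `mean_rank`, `rank_total`.
#' @export
best_predictors_rank <- function(pm, similarity_best = c("positive", "negative")) {
  similarity_best <- match.arg(similarity_best)
  fam <- predictor_families(pm)
  empty <- names(fam)[vapply(fam, length, integer(1)) == 0]
  if (length(empty) > 0) {
    stop("predictor matrix lacks any column for family: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  row_mean <- function(cols) rowMeans(as.matrix(pm[cols]), na.rm = TRUE)
  out <- tibble::tibble(
    gene = pm$gene,
    mean_r_expression = row_mean(fam$expression),
    mean_r_depscore = row_mean(fam$depscore),
    mean_similarity = row_mean(fam$similarity)
  ) %>%
    mutate(biggest_r = pmax(.data$mean_r_expression, .data$mean_r_depscore,
                            na.rm = TRUE)) %>%
    dplyr::filter(!is.na(.data$mean_similarity),
                  !is.na(.data$mean_r_expression),
                  !is.na(.data$mean_r_depscore))
  if (nrow(out) == 0) stop("no gene has all three predictor families", call. = FALSE)
  sim_key <- if (similarity_best == "positive") -out$mean_similarity else out$mean_similarity
  out %>%
    mutate(
      rank_corr = pmax(competition_rank(.data$mean_r_expression),
                       competition_rank(.data$mean_r_depscore)),
      rank_similarity = competition_rank(sim_key),
      mean_rank = (.data$rank_corr + .data$rank_similarity) / 2,
      rank_total = competition_rank(.data$mean_rank)
    ) %>%
    arrange(.data$rank_total, .data$gene)
}

standardized_predictors <- function(pm, min_rows = 15) {
  complete <- pm[complete.cases(pm), , drop = FALSE]
  if (nrow(complete) < min_rows) {
    stop("only ", nrow(complete), " genes have complete predictors ",
         "(need >= ", min_rows, "); consider pca_kmeans_fallback()",
         call. = FALSE)
  }
  x <- scale(as.matrix(complete[setdiff(names(complete), "gene")]))
  keep <- !is.nan(colSums(x))         # drop zero-variance predictors
  x <- x[, keep, drop = FALSE]
  list(x = x, genes = complete$gene)
}

#' Embed the standardized predictor matrix in 2D with UMAP
#'
#' Rows with any missing predictor are dropped and columns standardized to
#' zero mean / unit variance before embedding. The embedding is
#' deterministic at a fixed seed and input order (single-threaded layout
#' optimisation).
#'
#' @param pm Predictor matrix (`gene` column + numeric predictors).
#' @param seed Integer seed (default 5023).
#' @param min_dist UMAP min_dist (default 0.05).
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @return Tibble `gene`, `x`, `y`.
#' @export
embed_predictors <- function(pm, seed = 5023, min_dist = 0.05, n_neighbors = 15) {
  sp <- standardized_predictors(pm)
  coords <- withr::with_seed(seed, {
    uwot::umap(sp$x, n_neighbors = min(n_neighbors, nrow(sp$x) - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  })
  tibble::tibble(gene = sp$genes, x = coords[, 1], y = coords[, 2])
}

#' Nearest neighbours of a key gene in an embedding
#'
#' Euclidean distances from the key gene, ascending, truncated to the `n`
#' smallest (ties at the boundary are all kept). The key gene itself is
#' first with distance 0.
#'
#' @param coords Tibble `gene`, `x`, `y` from [embed_predictors()] or
#'   [pca_kmeans_fallback()].
#' @param key_gene Gene symbol present in `coords`.
#' @param n Number of neighbours to keep (default 75).
#' @return Tibble `gene`, `distance`, `order`.
#' @export
nearest_neighbors <- function(coords, key_gene, n = 75) {
  hit <- coords$gene == key_gene
  if (!any(hit)) {
    near <- agrep(key_gene, coords$gene, max.distance = 0.2, value = TRUE)
    stop("key gene '", key_gene, "' not in the embedding",
         if (length(near) > 0) paste0("; close matches: ",
                                      paste(head(near, 5), collapse = ", ")),
         call. = FALSE)
  }
  kx <- coords$x[hit][1]
  ky <- coords$y[hit][1]
  coords %>%
    mutate(distance = sqrt((.data$x - kx)^2 + (.data$y - ky)^2)) %>%
    slice_min(.data$distance, n = n, with_ties = TRUE) %>%
    arrange(.data$distance, .data$gene) %>%
    mutate(order = row_number()) %>%
    select("gene", "distance", "order")
}

#' PCA + k-means fallback for the 2D embedding
#'
#' First two principal components of the standardized predictor matrix as
#' coordinates, with k-means cluster labels; deterministic at a fixed seed.
#'
#' @param pm Predictor matrix.
#' @param k_clusters Number of k-means clusters (default 4).
#' @param seed Integer seed.
#' @return Tibble `gene`, `x`, `y`, `cluster` plus a `"var_explained"`
#'   attribute (per-PC fraction).
#' @export
pca_kmeans_fallback <- function(pm, k_clusters = 4, seed = 5023) {
  sp <- standardized_predictors(pm)
  pc <- prcomp(sp$x, center = FALSE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  km <- withr::with_seed(seed, kmeans(coords, centers = k_clusters, nstart = 10))
  out <- tibble::tibble(gene = sp$genes, x = coords[, 1], y = coords[, 2],
                        cluster = km$cluster)
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}

#' Top genes by average transcriptomic similarity (text-mining aggregation)
#'
#' Averages the similarity totals per gene across drug signatures and
#' forwards the genes with the highest (under the default polarity)
#' averages, the list typically sent to the citation search.
#'
#' @param totals Similarity tibble from [similarity_totals()].
#' @param n Number of genes to forward (default 100).
#' @param similarity_best Polarity (`"positive"`/`"negative"`).
#' @return Tibble `gene`, `mean_similarity`, strongest first, `n` rows
#'   (plus boundary ties).
#' @export
top_similarity_genes <- function(totals, n = 100,
                                 similarity_best = c("positive", "negative")) {
  similarity_best <- match.arg(similarity_best)
  means <- totals %>%
    group_by(.data$gene) %>%
    summarise(mean_similarity = mean(.data$total), .groups = "drop")
  key <- if (similarity_best == "positive") -means$mean_similarity else means$mean_similarity
  means %>%
    mutate(.key = key) %>%
    arrange(.data$.key, .data$gene) %>%   # boundary ties break by gene symbol
    head(n) %>%
    select("gene", "mean_similarity")
}

#' Filter a ranked candidate list by citation counts
#'
#' Takes the strongest `top_n` genes from a ranking (by `rank_total` when
#' present, otherwise row order) and removes genes whose summed
#' pathway-term citation count exceeds `max_citations` (default 0:
#' novelty-first, any hit disqualifies). With `filter_first = TRUE` the
#' citation filter is applied before truncation instead.
#'
#' @param ranking Tibble with a `gene` column, strongest candidate first
#'   (e.g. [best_predictors_rank()] output or a [nearest_neighbors()] list).
#' @param citations Citation tibble from [citation_counts()] (`gene`,
#'   `term`, `count`), or NULL to skip filtering.
#' @param top_n Candidates to keep before filtering (default 75).
#' @param max_citations Maximum allowed summed citations (default 0).
#' @param filter_first Apply the citation filter before truncation.
#' @return Tibble of surviving candidates with a `citations` column.
#' @export
select_candidates <- function(ranking, citations = NULL, top_n = 75,
                              max_citations = 0, filter_first = FALSE) {
  if ("rank_total" %in% names(ranking)) ranking <- arrange(ranking, .data$rank_total)
  totals <- if (is.null(citations)) {
    tibble::tibble(gene = ranking$gene, citations = 0L)
  } else {
    citations %>%
      group_by(.data$gene) %>%
      summarise(citations = sum(.data$count), .groups = "drop")
  }
  with_cites <- ranking %>%
    left_join(totals, by = "gene") %>%
    mutate(citations = dplyr::coalesce(.data$citations, 0L))
  if (filter_first) {
    with_cites %>%
      dplyr::filter(.data$citations <= max_citations) %>%
      head(top_n)
  } else {
    with_cites %>%
      head(top_n) %>%
      dplyr::filter(.data$citations <= max_citations)
  }
}
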