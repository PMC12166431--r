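# End-to-end orchestration: one declarative config drives
# dose_response -> predictors -> diffexpr -> signature sets -> enrichment
# -> similarity (with optional consensus pre-filter) -> ranking, with
# per-stage logging, seeded determinism and a provenance record.

#' Default pipeline configuration
#'
#' Defaults follow the pipeline's standard operating values:
#' set size k = 20, camera rho = 0.01, similarity polarity "positive",
#' top_n = 75 (100 for text-mining aggregation), consensus threshold 9,
#' citation threshold 0, embedding seed 5023 with min_dist 0.05.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for per-stage artifacts.
#' @param simulate Manifest arguments (list) for the synthetic scenario;
#'   set to NULL and fill `inputs` to run on files instead.
#' @param inputs Named list of input file paths (`dose_response` - named
#'   character vector of wide CSVs, one per inducer; `expression`,
#'   `dependency`, `model_map` - DepMap-style CSVs; `signature_scores`,
#'   `signature_meta` - long TSVs; `counts`, `design` - counts TSV and
#'   design CSV).
#' @param key_genes Key genes for the nearest-neighbour ranking (default:
#'   first planted suppressor when simulating).
#' @param citation_fixture Path to a citation-count JSON fixture, or NULL
#'   to skip novelty filtering.
#' @param pubmed_terms Pathway terms for the citation queries.
#' @param ... Overrides for the remaining parameters (`k`, `rho`,
#'   `similarity_best`, `top_n`, `consensus_filter`, `consensus_threshold`,
#'   `max_citations`, `time_filter`, `umap_seed`, `min_dist`).
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 42, out_dir = NULL, simulate = list(),
                           inputs = NULL, key_genes = NULL,
                           citation_fixture = NULL, pubmed_terms = NULL, ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    simulate = simulate,
    inputs = inputs,
    key_genes = key_genes,
    k = 20,
    rho = 0.01,
    similarity_best = "positive",
    top_n = 75,
    consensus_filter = TRUE,
    consensus_threshold = 9,
    citation_fixture = citation_fixture,
    pubmed_terms = pubmed_terms,
    max_citations = 0,
    time_filter = "96H",
    umap_seed = 5023,
    min_dist = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read and validate a pipeline config from YAML
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config must provide either `simulate` parameters or `inputs` paths",
         call. = FALSE)
  }
  if (!is.null(cfg$inputs)) {
    needed <- c("dose_response", "expression", "dependency", "model_map",
                "signature_scores", "signature_meta", "counts", "design")
    missing_in <- setdiff(needed, names(cfg$inputs))
    if (length(missing_in) > 0) {
      stop("config inputs missing required path(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
    }
    paths <- unlist(cfg$inputs)
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(cfg$k >= 1, cfg$rho >= 0, cfg$rho < 1,
            cfg$similarity_best %in% c("positive", "negative"),
            cfg$top_n >= 1)
  invisible(cfg)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate) && is.null(cfg$inputs)) {
    manifest <- do.call(scenario_manifest,
                        c(list(seed = cfg$seed), cfg$simulate))
    sc <- make_scenario(manifest)
    list(manifest = manifest,
         dose_response = sc$dose_response$table,
         expression = sc$omics$expression,
         dependency = sc$omics$dependency,
         model_map = sc$omics$model_map,
         store = sc$signatures$store,
         counts = sc$signatures$counts,
         design = sc$signatures$design)
  } else {
    drc <- purrr::imap_dfr(cfg$inputs$dose_response,
                           function(p, ind) read_dose_response(p, inducer = ind))
    counts_raw <- readr::read_tsv(cfg$inputs$counts, show_col_types = FALSE)
    counts <- as.matrix(counts_raw[-1])
    rownames(counts) <- counts_raw[[1]]
    list(manifest = NULL,
         dose_response = drc,
         expression = read_depmap_matrix(cfg$inputs$expression),
         dependency = read_depmap_matrix(cfg$inputs$dependency),
         model_map = readr::read_csv(cfg$inputs$model_map, show_col_types = FALSE),
         store = read_signature_store_tsv(cfg$inputs$signature_scores,
                                          cfg$inputs$signature_meta),
         counts = counts,
         design = readr::read_csv(cfg$inputs$design, show_col_types = FALSE))
  }
}

stage_log <- function(log, stage, n_in, n_out) {
  message(sprintf("[%s] %d records in -> %d out", stage, n_in, n_out))
  bind_rows(log, tibble::tibble(stage = stage, n_in = n_in, n_out = n_out))
}

#' Run the full target-prediction pipeline
#'
#' Sequences all stages from one config: sensitivity AUCs from
#' dose-response curves; per-gene expression and essentiality correlations;
#' drug-response signatures from counts; knockdown gene-set extraction;
#' camera enrichment; similarity aggregation (after an optional
#' consensus-weight filter of outlier drug signatures); predictor assembly;
#' and both ranking methods with optional citation filtering. Per-stage
#' artifacts and a provenance JSON (config hash, seeds, package version)
#' are written when `out_dir` is set.
#'
#' @param config A `pipeline_config` from [default_config()] /
#'   [read_pipeline_config()].
#' @return List with the per-stage tables, both candidate lists
#'   (`candidates_best`, `candidates_nn`), the stage log and provenance.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  log <- tibble::tibble()
  inp <- load_pipeline_inputs(config)

  aucs <- auc_table(inp$dose_response)
  log <- stage_log(log, "dose_response", nrow(inp$dose_response), nrow(aucs))

  joined_expr <- harmonize_cell_lines(aucs, inp$expression, inp$model_map)
  joined_dep <- harmonize_cell_lines(aucs, inp$dependency, inp$model_map)
  corr_expr <- correlate_auc_to_omics(joined_expr, source = "expression")
  corr_dep <- correlate_auc_to_omics(joined_dep, source = "essentiality")
  log <- stage_log(log, "predictors", nrow(aucs),
                   nrow(corr_expr) + nrow(corr_dep))

  logexpr <- normalize_log_counts(inp$counts)
  drug_sigs <- fit_contrasts(logexpr, inp$design)
  log <- stage_log(log, "diffexpr", nrow(logexpr), nrow(drug_sigs))

  sh_ids <- filter_consensus_shrna(inp$store, time_filter = config$time_filter)
  sets <- extract_top_bottom_sets(inp$store, sig_ids = sh_ids, k = config$k)
  log <- stage_log(log, "signature_store", ncol(inp$store$scores), length(sh_ids))

  scores <- enrich_all(drug_sigs, sets$up, sets$down, rho = config$rho)
  log <- stage_log(log, "enrichment", length(sh_ids) * 2, nrow(scores))

  consensus <- NULL
  if (isTRUE(config$consensus_filter)) {
    fc <- fold_change_matrix(drug_sigs)
    if (ncol(fc) >= 2) {
      consensus <- consensus_weights(fc, threshold = config$consensus_threshold)
      dropped <- consensus$signature[consensus$flagged]
      if (length(dropped) > 0) {
        message("consensus filter removed drug signature(s): ",
                paste(dropped, collapse = ", "))
        scores <- scores[!scores$pert %in% dropped, ]
      }
    }
  }
  sim <- similarity_totals(max_over_cells(scores))
  log <- stage_log(log, "similarity", nrow(scores), nrow(sim))

  pm <- assemble_predictor_matrix(corr_expr, corr_dep, sim)
  best <- best_predictors_rank(pm, similarity_best = config$similarity_best)
  log <- stage_log(log, "ranking_best", nrow(pm), nrow(best))

  emb <- embed_predictors(pm, seed = config$umap_seed,
                          min_dist = config$min_dist)
  key_genes <- config$key_genes
  if (is.null(key_genes) && !is.null(inp$manifest) &&
      length(inp$manifest$planted_suppressors) > 0) {
    key_genes <- inp$manifest$planted_suppressors[1]
  }
  neighbors <- NULL
  if (!is.null(key_genes)) {
    neighbors <- purrr::map_dfr(key_genes, function(g) {
      nearest_neighbors(emb, g, n = config$top_n) %>%
        mutate(key_gene = g)
    })
  }
  log <- stage_log(log, "ranking_nn", nrow(emb),
                   if (is.null(neighbors)) 0L else nrow(neighbors))

  citations <- NULL
  client <- NULL
  if (!is.null(config$citation_fixture)) {
    client <- citation_client_fixture(config$citation_fixture)
  }
  candidates_best <- select_candidates(
    best,
    citations = if (!is.null(client)) {
      citation_counts(head(best$gene, config$top_n), config$pubmed_terms, client)
    },
    top_n = config$top_n, max_citations = config$max_citations)
  candidates_nn <- NULL
  if (!is.null(neighbors)) {
    first_key <- neighbors[neighbors$key_gene == key_genes[1], ]
    candidates_nn <- select_candidates(
      first_key,
      citations = if (!is.null(client)) {
        citation_counts(head(first_key$gene, config$top_n),
                        config$pubmed_terms, client)
      },
      top_n = config$top_n, max_citations = config$max_citations)
  }

  provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    umap_seed = config$umap_seed,
    package_version = as.character(utils::packageVersion("deathmark")),
    generated = "deathmark::run_pipeline"
  )

  result <- list(
    manifest = inp$manifest, aucs = aucs,
    corr_expr = corr_expr, corr_dep = corr_dep,
    drug_signatures = drug_sigs, consensus = consensus,
    enrichment = scores, similarity = sim,
    predictor_matrix = pm, best_rank = best,
    embedding = emb, neighbors = neighbors,
    candidates_best = candidates_best, candidates_nn = candidates_nn,
    log = log, provenance = provenance
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config)
  result
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  write_auc_table(result$aucs, out("aucs.csv"))
  readr::write_tsv(result$similarity, out("similarity.tsv"))
  readr::write_tsv(result$best_rank, out("best_predictors_rank.tsv"))
  readr::write_tsv(result$candidates_best, out("candidates_best.tsv"))
  if (!is.null(result$candidates_nn)) {
    readr::write_tsv(result$candidates_nn, out("candidates_nn.tsv"))
  }
  if (!is.null(result$consensus)) {
    readr::write_tsv(result$consensus, out("consensus_weights.tsv"))
  }
  readr::write_tsv(result$log, out("stage_log.tsv"))
  jsonlite::write_json(result$provenance, out("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' Pan-cancer validation of a candidate list
#'
#' Correlates every gene's expression with the drugs' sensitivity AUCs
#' across cell lines (reusing the predictor machinery), averages the
#' correlations per gene, and tests whether the candidate set is enriched
#' in one tail of that correlation ranking with [preranked_gsea()]. For
#' suppressors the expected enrichment is in the negative tail.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param expression Omics tibble (model_id/cell_line rows, gene columns).
#' @param aucs Long AUC tibble (`cell_line`, `inducer`, `auc`).
#' @param model_map Optional model map for [harmonize_cell_lines()].
#' @param n_perm,seed Permutation settings for [preranked_gsea()].
#' @return List: `correlations` (per-gene mean r) and `gsea` (ES and
#'   permutation p).
#' @export
validate_pancancer <- function(candidates, expression, aucs, model_map = NULL,
                               n_perm = 1000, seed = 1) {
  joined <- harmonize_cell_lines(aucs, expression, model_map)
  corr <- correlate_auc_to_omics(joined)
  mean_r <- corr %>%
    group_by(.data$gene) %>%
    summarise(r = mean(.data$r), .groups = "drop")
  ranks <- setNames(mean_r$r, mean_r$gene)
  overlap <- intersect(candidates, names(ranks))
  if (length(overlap) == 0) {
    stop("candidate set does not overlap the expression gene universe",
         call. = FALSE)
  }
  gsea <- preranked_gsea(ranks, overlap, n_perm = n_perm, seed = seed)
  list(correlations = mean_r, gsea = gsea)
}
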