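# Synthetic-data generator with planted ground truth. Emulates every input
# class the pipeline consumes - dose-response viability tables, DepMap-style
# omics matrices, a knockdown signature store, and drug-vs-vehicle RNA-seq
# counts - with a set of planted suppressor genes that carry signal in all
# three evidence channels (expression correlation, essentiality
# correlation, signature concordance), plus partial-evidence decoys that
# carry signal in only one arm. Fully deterministic given the manifest
# seed.

CMAP_CELL_POOL <- c("A375", "MCF7", "PC3", "VCAP", "HT29", "A549")

#' Scenario manifest for the synthetic-data generator
#'
#' Fixes every size, effect size and identity used by the `make_*`
#' generators, so that a manifest plus its seed fully determines every
#' emitted table. The default scenario is 2000 genes, 20 cell lines, 500
#' knockdowns, 2 inducers and 10 planted suppressors, with 10
#' correlation-only and 10 signature-only decoys to exercise the
#' aggregation.
#'
#' @param seed Master integer seed.
#' @param n_genes,n_cell_lines,n_knockdowns,n_planted,n_decoys,n_inducers
#'   Scenario sizes.
#' @param b_corr,sigma_expr Planted expression slope per SD of AUC and
#'   residual noise SD (log-TPM units).
#' @param b_dep,sigma_dep Same for the gene-effect (essentiality) channel.
#' @param rho_sig Concordance of planted knockdown signatures with the
#'   death-program direction (0-1).
#' @param sigma_viability Viability noise SD in percentage points.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param n_doses,n_reps Dose-response grid size and replicate count.
#' @return A `scenario_manifest` list; the dose grid, per-curve 4PL truth
#'   and true AUCs are precomputed in `$truth`.
#' @export
scenario_manifest <- function(seed = 42,
                              n_genes = 2000,
                              n_cell_lines = 20,
                              n_knockdowns = 500,
                              n_planted = 10,
                              n_decoys = 10,
                              n_inducers = 2,
                              b_corr = 1.0,
                              sigma_expr = 0.35,
                              b_dep = 0.3,
                              sigma_dep = 0.12,
                              rho_sig = 0.8,
                              sigma_viability = 3,
                              nb_dispersion = 0.1,
                              n_doses = 8,
                              n_reps = 3) {
  stopifnot(n_knockdowns <= n_genes,
            n_planted + 2 * n_decoys <= n_knockdowns)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  cell_lines <- sprintf("CL%02d", seq_len(n_cell_lines))
  model_map <- tibble::tibble(model_id = sprintf("ACH-%06d", seq_len(n_cell_lines)),
                              cell_line_name = cell_lines)
  inducers <- paste0("inducer", LETTERS[seq_len(n_inducers)])
  doses <- 10^seq(-7.3, -4.7, length.out = n_doses)

  withr::with_seed(seed, {
    knockdowns <- sort(sample(genes, n_knockdowns))
    planted <- sort(sample(knockdowns, n_planted))
    rest <- setdiff(knockdowns, planted)
    decoys_corr <- sort(sample(rest, n_decoys))
    decoys_sig <- sort(sample(setdiff(rest, decoys_corr), n_decoys))
    # one latent vulnerability per cell line drives its EC50 for every
    # inducer of the pathway (plus inducer-specific jitter), so AUCs
    # correlate across inducers as they do for drugs hitting one pathway
    vulnerability <- runif(n_cell_lines, 0, 1)
    truth <- tidyr::expand_grid(cell_line = cell_lines, inducer = inducers) %>%
      mutate(slope = runif(n(), 0.8, 1.6),
             ec50_log = -6.8 +
               1.6 * (1 - rep(vulnerability, each = length(inducers))) +
               runif(n(), -0.12, 0.12))
  })
  truth$auc_true <- purrr::map2_dbl(truth$slope, truth$ec50_log, function(b, e) {
    sensitivity_auc_points(log10(doses), logistic4_viability(log10(doses), b, e))
  })

  structure(list(
    seed = seed,
    genes = genes, n_genes = n_genes,
    cell_lines = cell_lines, model_map = model_map,
    inducers = inducers,
    knockdowns = knockdowns,
    planted_suppressors = planted,
    decoys_corr = decoys_corr,
    decoys_sig = decoys_sig,
    b_corr = b_corr, sigma_expr = sigma_expr,
    b_dep = b_dep, sigma_dep = sigma_dep,
    rho_sig = rho_sig,
    sigma_viability = sigma_viability,
    nb_dispersion = nb_dispersion,
    doses = doses, n_reps = n_reps,
    truth = truth
  ), class = "scenario_manifest")
}

#' @export
print.scenario_manifest <- function(x, ...) {
  cat("scenario_manifest: seed", x$seed, "-", x$n_genes, "genes,",
      length(x$cell_lines), "cell lines,", length(x$knockdowns),
      "knockdowns,", length(x$planted_suppressors), "planted\n")
  invisible(x)
}

#' Simulate dose-response viability tables
#'
#' Viability follows the fixed-asymptote 4PL curves recorded in the
#' manifest truth, plus Gaussian noise (SD `sigma_viability` percentage
#' points), clipped at 0.
#'
#' @param manifest A [scenario_manifest()].
#' @return List: `table` (long dose-response tibble over all cell lines and
#'   inducers) and `truth` (true slope, log-EC50 and noise-free AUC per
#'   curve).
#' @export
make_dose_response <- function(manifest) {
  grid <- tidyr::expand_grid(
    manifest$truth,
    replicate = paste0("Repeat_", seq_len(manifest$n_reps)),
    concentration = manifest$doses
  ) %>%
    mutate(log_conc = log10(.data$concentration),
           v_true = logistic4_viability(.data$log_conc, .data$slope, .data$ec50_log))
  tbl <- withr::with_seed(manifest$seed + 1L, {
    grid %>%
      mutate(viability = pmax(.data$v_true +
                                rnorm(n(), 0, manifest$sigma_viability), 0))
  }) %>%
    select("cell_line", "inducer", "concentration", "log_conc", "replicate",
           "viability")
  list(table = as_dose_response_table(tbl), truth = manifest$truth)
}

#' Simulate DepMap-style omics matrices with planted suppressors
#'
#' Planted suppressors (and correlation-only decoys) get expression
#' `a - b_corr * z(AUC) + eps` and gene effect `c - b_dep * z(AUC) + eps`,
#' i.e. high expression / low essentiality in resistant lines; background
#' genes are independent noise. Gene-effect values are bounded in
#' \[-1.5, 0.5\].
#'
#' @param manifest A [scenario_manifest()].
#' @param seed Noise seed (default derived from the manifest). Passing a
#'   different value regenerates an independent cell-line panel with the
#'   same planted biology - the stand-in for an external pan-cancer
#'   validation dataset.
#' @return List: `expression` and `dependency` tibbles (model_id rows, gene
#'   columns) and `model_map`.
#' @export
make_omics <- function(manifest, seed = manifest$seed + 2L) {
  n_cl <- length(manifest$cell_lines)
  auc_mean <- manifest$truth %>%
    group_by(.data$cell_line) %>%
    summarise(auc = mean(.data$auc_true), .groups = "drop")
  auc_mean <- auc_mean[match(manifest$cell_lines, auc_mean$cell_line), ]
  z <- as.vector(scale(auc_mean$auc))
  corr_genes <- union(manifest$planted_suppressors, manifest$decoys_corr)

  withr::with_seed(seed, {
    base_expr <- runif(manifest$n_genes, 1, 8)
    expr <- matrix(rnorm(n_cl * manifest$n_genes, 0, 0.8), nrow = n_cl) +
      matrix(base_expr, nrow = n_cl, ncol = manifest$n_genes, byrow = TRUE)
    dep <- matrix(rnorm(n_cl * manifest$n_genes, -0.2, 0.2), nrow = n_cl)
    for (g in match(corr_genes, manifest$genes)) {
      expr[, g] <- base_expr[g] - manifest$b_corr * z +
        rnorm(n_cl, 0, manifest$sigma_expr)
      dep[, g] <- -0.4 - manifest$b_dep * z + rnorm(n_cl, 0, manifest$sigma_dep)
    }
  })
  expr <- pmax(expr, 0)
  dep <- pmin(pmax(dep, -1.5), 0.5)
  colnames(expr) <- manifest$genes
  colnames(dep) <- manifest$genes
  wrap <- function(m) {
    dplyr::bind_cols(tibble::tibble(model_id = manifest$model_map$model_id),
                     tibble::as_tibble(m))
  }
  list(expression = wrap(expr), dependency = wrap(dep),
       model_map = manifest$model_map)
}

#' Simulate the knockdown signature store and drug-treated RNA-seq counts
#'
#' A latent death-program direction `D0` over genes drives everything:
#' each inducer's transcriptomic direction is `D0` plus an inducer-specific
#' component; the count matrix for drug-vs-vehicle samples encodes those
#' directions as log2 fold changes (negative-binomial counts); planted
#' suppressors' (and signature-only decoys') knockdown signatures are
#' `rho_sig * D0 + sqrt(1 - rho_sig^2) * noise` across 4-6 pseudo cell
#' lines, while other knockdowns are pure noise. Metadata follows the
#' consensus-shRNA convention (`trt_sh.cgs`, time `"96H"`, `CGS` id
#' grammar); a few over-expression and 144H distractor signatures are
#' included to exercise the filters.
#'
#' @param manifest A [scenario_manifest()].
#' @param rnaseq_cell_lines Cell lines profiled by RNA-seq (default
#'   `c("HCC70", "BT549")`).
#' @return List: `store` (a [signature_store()] with numeric gene ids +
#'   gene_info), `counts` (genes x samples matrix), `design` (sample
#'   sheet), `directions` (list with `D0` and per-inducer directions).
#' @export
make_signature_store <- function(manifest, rnaseq_cell_lines = c("HCC70", "BT549")) {
  n_genes <- manifest$n_genes
  stopifnot(n_genes >= 40)
  sig_genes <- union(manifest$planted_suppressors, manifest$decoys_sig)

  withr::with_seed(manifest$seed + 3L, {
    d0 <- rnorm(n_genes)
    d_ind <- lapply(manifest$inducers, function(ind) {
      sqrt(0.75) * d0 + sqrt(0.25) * rnorm(n_genes)
    })
    names(d_ind) <- manifest$inducers

    # knockdown signatures across 4-6 pseudo cell lines each
    n_cells <- sample(4:6, length(manifest$knockdowns), replace = TRUE)
    kd <- purrr::map2(manifest$knockdowns, n_cells, function(g, nc) {
      cells <- sample(CMAP_CELL_POOL, nc)
      scores <- vapply(cells, function(cl) {
        if (g %in% sig_genes) {
          manifest$rho_sig * d0 + sqrt(1 - manifest$rho_sig^2) * rnorm(n_genes)
        } else {
          rnorm(n_genes)
        }
      }, numeric(n_genes))
      list(cells = cells, scores = scores)
    })

    # drug-treated vs vehicle counts
    design <- tidyr::expand_grid(
      cell_line = rnaseq_cell_lines,
      condition = c("vehicle", manifest$inducers),
      replicate = seq_len(manifest$n_reps)
    ) %>%
      mutate(sample = paste(.data$cell_line, .data$condition, .data$replicate,
                            sep = "_"))
    mu_log2 <- runif(n_genes, 3, 9)
    counts <- vapply(seq_len(nrow(design)), function(i) {
      cond <- design$condition[i]
      lfc <- if (cond == "vehicle") 0 else d_ind[[cond]]
      mu <- 2^(mu_log2 + lfc)
      rnbinom(n_genes, mu = mu, size = 1 / manifest$nb_dispersion)
    }, numeric(n_genes))
  })

  colnames(counts) <- design$sample
  rownames(counts) <- manifest$genes

  sig_id <- character(0)
  meta <- vector("list", length(kd))
  score_cols <- vector("list", length(kd))
  for (i in seq_along(kd)) {
    g <- manifest$knockdowns[i]
    ids <- sprintf("CGS%03d_%s_%s:1", i, kd[[i]]$cells, g)
    meta[[i]] <- tibble::tibble(sig_id = ids, pert_type = "trt_sh.cgs",
                                pert_gene = g, cell = kd[[i]]$cells,
                                time = "96H")
    colnames(kd[[i]]$scores) <- ids
    score_cols[[i]] <- kd[[i]]$scores
  }
  scores <- do.call(cbind, score_cols)
  # entrez-like numeric row ids; translation back to symbols goes through
  # gene_info at extraction time
  gene_ids <- as.character(seq_len(n_genes) + 1000L)
  rownames(scores) <- gene_ids
  gene_info <- tibble::tibble(gene_id = gene_ids, symbol = manifest$genes)
  meta <- bind_rows(meta)

  # distractors: over-expression and late-time signatures must be filtered out
  distract <- withr::with_seed(manifest$seed + 4L, {
    cells <- sample(CMAP_CELL_POOL, 4, replace = TRUE)
    m <- matrix(rnorm(4 * n_genes), nrow = n_genes)
    ids <- sprintf("CGS9%02d_%s_%s:1", 1:4, cells, manifest$knockdowns[1:4])
    colnames(m) <- ids
    rownames(m) <- gene_ids
    list(scores = m,
         meta = tibble::tibble(sig_id = ids,
                               pert_type = c("trt_oe.cgs", "trt_oe.cgs",
                                             "trt_sh.cgs", "trt_sh.cgs"),
                               pert_gene = manifest$knockdowns[1:4],
                               cell = cells,
                               time = c("96H", "96H", "144H", "144H")))
  })
  store <- signature_store(cbind(scores, distract$scores),
                           bind_rows(meta, distract$meta),
                           gene_info = gene_info)
  list(store = store, counts = counts, design = design,
       directions = c(list(D0 = d0), d_ind))
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running all three generators off one manifest.
#'
#' @param manifest A [scenario_manifest()] (default scenario if omitted).
#' @return List: `manifest`, `dose_response`, `omics`, `signatures`.
#' @export
make_scenario <- function(manifest = scenario_manifest()) {
  list(manifest = manifest,
       dose_response = make_dose_response(manifest),
       omics = make_omics(manifest),
       signatures = make_signature_store(manifest))
}
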