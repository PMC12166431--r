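# Correlation predictors: join sensitivity AUCs to cell-line omics matrices
# (expression TPM-like, CRISPR gene effect) and compute per-gene Pearson
# correlations to each inducer's AUC.

#' Read a DepMap-style omics CSV
#'
#' Rows are cell-line models keyed by the first column (model id), columns
#' are genes with `"SYMBOL (entrez)"` headers; the entrez suffix is
#' stripped. Values are log-scaled TPM-like expression or CRISPR
#' gene-effect scores.
#'
#' @param path CSV path.
#' @return Tibble with a `model_id` column followed by one numeric column
#'   per gene symbol.
#' @export
read_depmap_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  names(raw)[1] <- "model_id"
  names(raw) <- sub(" \\(\\d+\\)$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    stop("duplicate gene symbols after stripping entrez ids in ", path,
         call. = FALSE)
  }
  raw
}

#' Join a sensitivity AUC table to an omics matrix by cell line
#'
#' Omics rows keyed by model id are translated to cell-line names through
#' the model map, then inner-joined to the AUC table. Unmatched names on
#' either side are reported in the `"unmatched"` attribute; an empty
#' intersection is an error listing near-miss names.
#'
#' @param aucs Long AUC tibble (`cell_line`, `inducer`, `auc`).
#' @param omics Tibble from [read_depmap_matrix()] (or with a `cell_line`
#'   key column directly).
#' @param model_map Optional tibble `model_id`, `cell_line_name`.
#' @return Tibble with one row per matched cell line: `cell_line`, one
#'   `auc:<inducer>` column per inducer, then gene columns.
#' @export
harmonize_cell_lines <- function(aucs, omics, model_map = NULL) {
  omics <- tibble::as_tibble(omics)
  if (!is.null(model_map)) {
    if (anyDuplicated(model_map$model_id) || anyDuplicated(model_map$cell_line_name)) {
      stop("model map must be one-to-one on the rows used", call. = FALSE)
    }
    if (!"model_id" %in% names(omics)) {
      stop("omics table lacks a model_id column to map", call. = FALSE)
    }
    omics <- omics %>%
      inner_join(model_map, by = "model_id") %>%
      select(-"model_id") %>%
      rename(cell_line = "cell_line_name") %>%
      select("cell_line", dplyr::everything())
  } else if ("model_id" %in% names(omics) && !"cell_line" %in% names(omics)) {
    omics <- rename(omics, cell_line = "model_id")
  }
  auc_wide <- aucs %>%
    tidyr::pivot_wider(id_cols = "cell_line", names_from = "inducer",
                       values_from = "auc", names_prefix = "auc:")
  shared <- intersect(auc_wide$cell_line, omics$cell_line)
  if (length(shared) == 0) {
    near <- unlist(lapply(auc_wide$cell_line, function(nm) {
      agrep(nm, omics$cell_line, max.distance = 0.2, value = TRUE)
    }))
    stop("no cell lines shared between AUC table and omics matrix",
         if (length(near) > 0) paste0("; near misses: ",
                                      paste(unique(near), collapse = ", ")),
         call. = FALSE)
  }
  unmatched <- list(aucs = setdiff(auc_wide$cell_line, shared),
                    omics = setdiff(omics$cell_line, shared))
  if (length(unmatched$aucs) > 0) {
    message(length(unmatched$aucs), " AUC cell line(s) had no omics match: ",
            paste(unmatched$aucs, collapse = ", "))
  }
  joined <- inner_join(auc_wide, omics, by = "cell_line")
  attr(joined, "unmatched") <- unmatched
  joined
}

#' Per-gene Pearson correlation between omics values and sensitivity AUCs
#'
#' For each gene and each inducer, the Pearson correlation is computed over
#' pairwise-complete cell lines. Genes with fewer than `min_pairs` complete
#' pairs, or zero variance over the complete pairs, are omitted (not set to
#' NA).
#'
#' @param joined Output of [harmonize_cell_lines()].
#' @param source Label recorded in the output (`"expression"` or
#'   `"essentiality"`).
#' @param min_pairs Minimum complete cell-line pairs per gene (default 3).
#' @return Tibble `gene`, `inducer`, `r`, `n_pairs`, `source`.
#' @export
correlate_auc_to_omics <- function(joined, source = "expression", min_pairs = 3) {
  auc_cols <- grep("^auc:", names(joined), value = TRUE)
  if (length(auc_cols) == 0) stop("no auc:<inducer> columns in `joined`", call. = FALSE)
  gene_cols <- setdiff(names(joined), c("cell_line", auc_cols))
  gmat <- as.matrix(joined[gene_cols])
  amat <- as.matrix(joined[auc_cols])
  r <- suppressWarnings(cor(gmat, amat, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(gmat), !is.na(amat))
  out <- tibble::tibble(
    gene = rep(rownames(r), times = ncol(r)),
    inducer = rep(sub("^auc:", "", colnames(r)), each = nrow(r)),
    r = as.vector(r),
    n_pairs = as.vector(n_pairs)
  )
  out %>%
    dplyr::filter(is.finite(.data$r), .data$n_pairs >= min_pairs) %>%
    mutate(source = source)
}

#' Assemble the per-gene predictor matrix
#'
#' Full outer join of the expression correlations, essentiality
#' correlations and transcriptomic-similarity totals into one row per gene.
#' Column naming follows the worked-example layout:
#' `"<inducer> AUC cor to expression"`, `"<inducer> AUC cor to depscore"`,
#' `"Transcriptomic similarity to <pert>"`.
#'
#' @param corr_expr,corr_dep Correlation tibbles from
#'   [correlate_auc_to_omics()].
#' @param sim Similarity tibble (`gene`, `pert`, `total`) from
#'   [similarity_totals()], or NULL to omit that family.
#' @return Wide tibble, one row per gene.
#' @export
assemble_predictor_matrix <- function(corr_expr, corr_dep, sim = NULL) {
  widen <- function(corr, label) {
    if (anyDuplicated(corr[c("gene", "inducer")])) {
      stop("duplicated gene symbols within an inducer in the ", label,
           " correlations", call. = FALSE)
    }
    corr %>%
      mutate(col = paste(.data$inducer, "AUC cor to", label)) %>%
      tidyr::pivot_wider(id_cols = "gene", names_from = "col", values_from = "r")
  }
  parts <- list(widen(corr_expr, "expression"), widen(corr_dep, "depscore"))
  if (!is.null(sim)) {
    parts <- c(parts, list(
      sim %>%
        mutate(col = paste("Transcriptomic similarity to", .data$pert)) %>%
        tidyr::pivot_wider(id_cols = "gene", names_from = "col",
                           values_from = "total")
    ))
  }
  pm <- purrr::reduce(parts, full_join, by = "gene")
  if (anyDuplicated(pm$gene)) {
    stop("duplicated gene symbols in predictor matrix: ",
         paste(unique(pm$gene[duplicated(pm$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(names(parts[[1]]), names(parts[[2]]))) > 1) {
    stop("expression and depscore predictors produced clashing column names",
         call. = FALSE)
  }
  pm
}
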