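# Transcriptomic similarity: aggregate signed enrichment scores into one
# integer rank-difference score per knockdown gene per drug signature, and
# consensus weights for flagging outlier drug signatures.

#' Aggregate enrichment scores over knockdown cell lines
#'
#' Each knockdown gene is profiled in several cell lines (4-9 in the
#' reference store); for every (gene, drug signature, collection) the
#' maximum signed score over whatever cell lines are present is kept.
#'
#' @param scores Long enrichment tibble from [enrich_all()].
#' @return Tibble `pert_gene`, `pert`, `collection`, `signed_score`
#'   (the per-group maximum), `n_cells`.
#' @export
max_over_cells <- function(scores) {
  scores %>%
    dplyr::filter(!is.na(.data$signed_score)) %>%
    group_by(.data$pert_gene, .data$pert, .data$collection) %>%
    summarise(n_cells = n(), signed_score = max(.data$signed_score),
              .groups = "drop")
}

#' Competition ("min") rank
#'
#' Ascending ranks starting at 1 for the smallest value; tied values share
#' the smallest rank of their block and the next block skips accordingly.
#'
#' @param values Finite numeric vector.
#' @return Integer ranks.
#' @export
competition_rank <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  rank(values, ties.method = "min")
}

#' Combine up and down ranks into the similarity total
#'
#' @param rank_up,rank_down Integer ranks over the same gene universe.
#' @return `rank_up - rank_down`: for N genes the total lies in
#'   \[-(N-1), N-1\]. A knockdown that mimics the drug (up set enriched Up,
#'   down set enriched Down) gets a large positive total.
#' @export
combine_up_down <- function(rank_up, rank_down) {
  if (length(rank_up) != length(rank_down)) {
    stop("rank vectors must come from the same gene universe", call. = FALSE)
  }
  rank_up - rank_down
}

#' Per-gene transcriptomic similarity totals
#'
#' Within each drug signature, the cell-line-aggregated up and down scores
#' are competition-ranked across knockdown genes (rank 1 = lowest score)
#' and the down rank is subtracted from the up rank. Genes missing one of
#' the two directions for a drug signature are excluded with a warning.
#'
#' @param max_scores Output of [max_over_cells()].
#' @return Tibble `gene`, `pert`, `total` (integer).
#' @export
similarity_totals <- function(max_scores) {
  wide <- max_scores %>%
    tidyr::pivot_wider(id_cols = c("pert_gene", "pert"),
                       names_from = "collection", values_from = "signed_score")
  if (!all(c("up", "down") %in% names(wide))) {
    stop("scores must contain both an up and a down collection", call. = FALSE)
  }
  incomplete <- !complete.cases(wide[c("up", "down")])
  if (any(incomplete)) {
    warning(sum(incomplete), " (gene, signature) pair(s) missing one ",
            "direction were excluded", call. = FALSE)
    wide <- wide[!incomplete, ]
  }
  wide %>%
    group_by(.data$pert) %>%
    mutate(total = combine_up_down(competition_rank(.data$up),
                                   competition_rank(.data$down))) %>%
    ungroup() %>%
    select(gene = "pert_gene", "pert", "total")
}

#' Wide (gene x drug signature) similarity table
#'
#' @param totals Output of [similarity_totals()].
#' @return Wide tibble, one row per gene, one column per drug signature.
#' @export
similarity_wide <- function(totals) {
  tidyr::pivot_wider(totals, id_cols = "gene", names_from = "pert",
                     values_from = "total")
}

#' Consensus weights for drug-response signatures
#'
#' Pairwise Pearson correlations among fold-change vectors; self
#' correlations and negative entries are zeroed; each signature's weight is
#' its share (in percent) of the total remaining correlation mass.
#' Signatures below `threshold` percent are flagged as outliers to be
#' removed before similarity aggregation.
#'
#' @param fold_changes Numeric matrix, genes in rows, one column per
#'   signature (>= 2 signatures, >= 3 genes).
#' @param threshold Flagging threshold in percent (default 9).
#' @return Tibble `signature`, `weight`, `flagged`, sorted ascending by
#'   weight.
#' @export
consensus_weights <- function(fold_changes, threshold = 9) {
  fold_changes <- as.matrix(fold_changes)
  fold_changes <- fold_changes[complete.cases(fold_changes), , drop = FALSE]
  if (ncol(fold_changes) < 2) stop("need >= 2 signatures", call. = FALSE)
  if (nrow(fold_changes) < 3) stop("need >= 3 genes per signature", call. = FALSE)
  sds <- apply(fold_changes, 2, sd)
  if (any(sds == 0)) {
    stop("constant fold-change vector(s): correlation undefined for ",
         paste(colnames(fold_changes)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  cm <- cor(fold_changes, method = "pearson")
  diag(cm) <- 0
  cm[cm < 0] <- 0
  sums <- rowSums(cm)
  weights <- unname(sums / sum(sums) * 100)
  tibble::tibble(signature = colnames(fold_changes), weight = weights,
                 flagged = weights < threshold) %>%
    arrange(.data$weight)
}
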