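# Differential expression of drug-treated vs vehicle RNA-seq: log-CPM
# normalisation, per-gene least squares on a group-means design, and
# empirical-Bayes variance moderation. The per-contrast log2 fold-change
# vectors are the "drug response signatures" consumed by the enrichment
# stage.

#' Normalise a count matrix to filtered log2 counts-per-million
#'
#' Per-sample counts are converted to an offset log2-CPM scale,
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, and genes failing the
#' low-count filter (CPM > `cpm_cutoff` in at least `min_group_size`
#' samples) are removed.
#'
#' @param counts Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns. Non-negative counts.
#' @param min_group_size Minimum number of samples in which a gene must
#'   pass the CPM cutoff (default: smallest group size makes sense; 3).
#' @param cpm_cutoff CPM threshold for the filter (default 1).
#' @return Matrix of log2-CPM values for the retained genes.
#' @export
normalize_log_counts <- function(counts, min_group_size = 3, cpm_cutoff = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- t(t(counts) / lib) * 1e6
  keep <- rowSums(cpm > cpm_cutoff) >= min_group_size
  logcpm <- log2(t(t(counts[keep, , drop = FALSE] + 0.5) / (lib + 1)) * 1e6)
  logcpm
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Residual variances are shrunk toward a common prior by inverse-chi-square
#' moderation. The prior degrees of freedom `d0` and prior variance `s0^2`
#' are estimated by method of moments on the observed variances (marginally
#' `s^2 ~ s0^2 F(df, d0)`); `d0 = 0` returns the raw variances (ordinary t)
#' and `d0 = Inf` returns `s0^2` for every gene.
#'
#' @param s2 Numeric vector of residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @param d0 Optional fixed prior degrees of freedom overriding estimation.
#' @return List with `d0`, `s02`, and the posterior variances `s2_post`.
#' @export
squeeze_variances <- function(s2, df, d0 = NULL) {
  if (length(df) != 1 || df <= 0) stop("`df` must be a positive scalar", call. = FALSE)
  m1 <- mean(s2)
  if (is.null(d0)) {
    v <- var(s2)
    ratio <- v / m1^2
    # Var/E^2 of F(df, d0) is 2 (df + d0 - 2) / (df (d0 - 4)); invert for d0
    if (!is.finite(ratio) || ratio * df <= 2) {
      d0 <- Inf
    } else {
      d0 <- (4 * ratio * df + 2 * df - 4) / (ratio * df - 2)
      if (d0 < 0) d0 <- Inf
    }
  }
  if (is.infinite(d0)) {
    s02 <- m1
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s02 <- m1
    s2_post <- s2
  } else {
    s02 <- if (d0 > 2) m1 * (d0 - 2) / d0 else median(s2)
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

default_drug_contrasts <- function(design) {
  drugs <- setdiff(unique(design$condition), "vehicle")
  tidyr::expand_grid(cell_line = unique(design$cell_line), drug = drugs) %>%
    dplyr::filter(purrr::map2_lgl(.data$cell_line, .data$drug, function(cl, dr) {
      any(design$cell_line == cl & design$condition == dr) &&
        any(design$cell_line == cl & design$condition == "vehicle")
    }))
}

#' Fit drug-vs-vehicle contrasts with moderated t-statistics
#'
#' Per-gene ordinary least squares on a group-means design
#' (one coefficient per cell line x condition group), followed by
#' [squeeze_variances()] moderation. Every contrast is drug minus vehicle
#' within a cell line, so positive logFC means up in drug; this polarity is
#' recorded in the `"polarity"` attribute of the result.
#'
#' @param logexpr Log-expression matrix (genes x samples) from
#'   [normalize_log_counts()].
#' @param design Tibble `sample`, `cell_line`, `condition` (`"vehicle"` or a
#'   drug name), `replicate`; `sample` must match `colnames(logexpr)`.
#' @param contrasts Optional tibble `cell_line`, `drug`; defaults to every
#'   cell line x drug pair present with a vehicle arm.
#' @param d0 Optional fixed prior df passed to [squeeze_variances()].
#' @return Tibble `gene`, `contrast`, `cell_line`, `drug`, `logFC`,
#'   `t_stat`, `p_value`, with attributes `polarity` and `moderation`.
#' @export
fit_contrasts <- function(logexpr, design, contrasts = NULL, d0 = NULL) {
  design <- tibble::as_tibble(design)
  if (!setequal(design$sample, colnames(logexpr))) {
    stop("design samples and logexpr columns disagree", call. = FALSE)
  }
  design <- design[match(colnames(logexpr), design$sample), ]
  group <- factor(paste(design$cell_line, design$condition, sep = "."))
  if (nlevels(group) < 2) {
    stop("design has fewer than 2 cell line x condition groups", call. = FALSE)
  }
  X <- stats::model.matrix(~ 0 + group)
  colnames(X) <- levels(group)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 1) {
    stop("no residual degrees of freedom: need >= 2 replicates per group",
         call. = FALSE)
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  coefs <- logexpr %*% X %*% xtx_inv            # genes x groups (group means)
  fitted <- coefs %*% t(X)
  s2 <- rowSums((logexpr - fitted)^2) / df_resid
  sq <- squeeze_variances(s2, df_resid, d0 = d0)
  df_total <- if (is.infinite(sq$d0)) Inf else sq$d0 + df_resid

  if (is.null(contrasts)) contrasts <- default_drug_contrasts(design)
  if (nrow(contrasts) == 0) {
    stop("no drug-vs-vehicle contrast can be formed from the design",
         call. = FALSE)
  }
  out <- purrr::pmap_dfr(contrasts, function(cell_line, drug) {
    cvec <- rep(0, ncol(X))
    names(cvec) <- colnames(X)
    trt <- paste(cell_line, drug, sep = ".")
    veh <- paste(cell_line, "vehicle", sep = ".")
    if (!all(c(trt, veh) %in% colnames(X))) {
      stop("contrast groups absent from design: ", trt, " vs ", veh, call. = FALSE)
    }
    cvec[trt] <- 1
    cvec[veh] <- -1
    logfc <- as.vector(coefs %*% cvec)
    se_unscaled <- sqrt(as.numeric(t(cvec) %*% xtx_inv %*% cvec))
    tval <- logfc / (se_unscaled * sqrt(sq$s2_post))
    tibble::tibble(
      gene = rownames(logexpr),
      contrast = paste(cell_line, drug, sep = "_"),
      cell_line = cell_line, drug = drug,
      logFC = logfc, t_stat = tval,
      p_value = 2 * pt(-abs(tval), df = df_total)
    )
  })
  attr(out, "polarity") <- "drug_minus_vehicle"
  attr(out, "moderation") <- list(d0 = sq$d0, s02 = sq$s02, df_resid = df_resid)
  out
}

#' Wide log2 fold-change matrix from drug signatures
#'
#' @param signatures Output of [fit_contrasts()].
#' @return Matrix genes x contrasts of logFC values (used by the consensus
#'   filter).
#' @export
fold_change_matrix <- function(signatures) {
  wide <- signatures %>%
    tidyr::pivot_wider(id_cols = "gene", names_from = "contrast",
                       values_from = "logFC")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}
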