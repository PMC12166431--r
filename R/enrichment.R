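# Competitive gene-set enrichment of knockdown gene sets in drug-response
# signatures. The directional test is a camera-style two-sample t on
# gene-level statistics with a variance-inflation factor for inter-gene
# correlation; scores are reported as signed -log10 p. A preranked GSEA
# (weighted Kolmogorov-Smirnov, permutation p) supports the pan-cancer
# validation.

#' Camera-style competitive gene-set test
#'
#' Compares the mean gene-level statistic inside a set against the rest of
#' the gene universe with a pooled-variance two-sample t-test whose set
#' term is inflated by `VIF = 1 + (m - 1) * rho` to account for inter-gene
#' correlation (`rho = 0` recovers the textbook pooled t-test exactly).
#'
#' @param gene_stats Named numeric vector of per-gene statistics (e.g.
#'   moderated t) over the universe.
#' @param set_index Gene names or integer indices of the set; 2 <= m < n
#'   required after intersection with the universe.
#' @param rho Inter-gene correlation (default 0.01, the published camera
#'   default).
#' @param set_name Optional label carried into the result.
#' @return One-row tibble `set_name`, `n_genes`, `direction` (`"Up"` iff
#'   the set mean exceeds the background mean), `p` (two-sided),
#'   `signed_score` (see [signed_log_score()]).
#' @export
camera_test <- function(gene_stats, set_index, rho = 0.01, set_name = NA_character_) {
  n <- length(gene_stats)
  if (is.character(set_index)) {
    set_index <- which(names(gene_stats) %in% set_index)
  }
  m <- length(set_index)
  if (m < 2 || m >= n) {
    stop("set must satisfy 2 <= m < n after intersection (m = ", m,
         ", n = ", n, ")", call. = FALSE)
  }
  in_set <- gene_stats[set_index]
  out_set <- gene_stats[-set_index]
  delta <- mean(in_set) - mean(out_set)
  df <- n - 2
  s2p <- ((m - 1) * var(in_set) + (n - m - 1) * var(out_set)) / df
  vif <- 1 + (m - 1) * rho
  tval <- delta / sqrt(s2p * (vif / m + 1 / (n - m)))
  p <- 2 * pt(-abs(tval), df = df)
  direction <- if (delta > 0) "Up" else "Down"
  tibble::tibble(set_name = set_name, n_genes = m, direction = direction,
                 p = p, signed_score = signed_log_score(p, direction))
}

#' Signed log10 transform of an enrichment p-value
#'
#' Up-enriched sets get `-log10(p)` (positive), down-enriched sets get
#' `+log10(p)` (negative), so a large positive score means the set's genes
#' are strongly up in the signature.
#'
#' @param p P-value(s) in (0, 1].
#' @param direction `"Up"` or `"Down"` (recycled).
#' @return Numeric signed score(s).
#' @export
signed_log_score <- function(p, direction) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (!all(direction %in% c("Up", "Down"))) {
    stop('direction must be "Up" or "Down"', call. = FALSE)
  }
  ifelse(direction == "Up", -log10(p), log10(p))
}

# Vectorised camera over a whole collection: same formula as camera_test()
# (asserted equal in the tests), computed from set sums/sums-of-squares.
enrich_collection <- function(stats_vec, collection, rho, max_silent_loss = 0.1) {
  universe <- names(stats_vec)
  idx_list <- lapply(collection, function(members) which(universe %in% members))
  lost <- 1 - lengths(idx_list) / lengths(collection)
  if (any(lost > max_silent_loss & lost < 1)) {
    warning(sum(lost > max_silent_loss & lost < 1),
            " set(s) lost more than ", round(100 * max_silent_loss),
            "% of their genes against the universe", call. = FALSE)
  }
  n <- length(stats_vec)
  tot <- sum(stats_vec)
  tot2 <- sum(stats_vec^2)
  m <- unname(lengths(idx_list))
  s_in <- unname(vapply(idx_list, function(i) sum(stats_vec[i]), numeric(1)))
  s2_in <- unname(vapply(idx_list, function(i) sum(stats_vec[i]^2), numeric(1)))
  mean_in <- s_in / m
  mean_out <- (tot - s_in) / (n - m)
  delta <- mean_in - mean_out
  ss_in <- s2_in - s_in^2 / m
  ss_out <- (tot2 - s2_in) - (tot - s_in)^2 / (n - m)
  df <- n - 2
  s2p <- (ss_in + ss_out) / df
  vif <- 1 + (m - 1) * rho
  tval <- delta / sqrt(s2p * (vif / m + 1 / (n - m)))
  p <- 2 * pt(-abs(tval), df = df)
  ok <- m >= 2 & m < n
  direction <- ifelse(delta > 0, "Up", "Down")
  tibble::tibble(
    set_name = names(collection),
    n_genes = m,
    direction = ifelse(ok, direction, NA_character_),
    p = ifelse(ok, p, NA_real_),
    signed_score = ifelse(ok, ifelse(direction == "Up", -log10(p), log10(p)),
                          NA_real_)
  )
}

#' Enrich every knockdown gene set in every drug-response signature
#'
#' Runs [camera_test()] for each (gene set, drug signature) pair, for the
#' up and down collections separately, and attaches the parsed signature
#' identity (cell line, perturbed gene). Sets with fewer than 2 genes in a
#' signature's universe are recorded with missing scores, not zeros.
#'
#' @param signatures Drug signatures from [fit_contrasts()] (long tibble
#'   with `gene`, `contrast`, `t_stat`).
#' @param up_sets,down_sets Gene-set collections (named lists) from
#'   [extract_top_bottom_sets()], keyed by sig_id.
#' @param rho Inter-gene correlation for [camera_test()].
#' @return Long tibble `sig_id`, `cell`, `pert_gene`, `pert` (the drug
#'   signature / contrast), `collection` (`"up"`/`"down"`), `n_genes`,
#'   `direction`, `p`, `signed_score`.
#' @export
enrich_all <- function(signatures, up_sets, down_sets, rho = 0.01) {
  stopifnot(identical(names(up_sets), names(down_sets)))
  parsed <- parse_signature_id(names(up_sets))
  out <- purrr::map_dfr(unique(signatures$contrast), function(ctr) {
    sub <- signatures[signatures$contrast == ctr, ]
    stats_vec <- setNames(sub$t_stat, sub$gene)
    if (length(intersect(names(stats_vec), unlist(up_sets[1]))) == 0 &&
        length(intersect(names(stats_vec), unlist(down_sets[1]))) == 0) {
      stop("gene universes of signatures and sets do not overlap", call. = FALSE)
    }
    bind_rows(
      enrich_collection(stats_vec, up_sets, rho) %>% mutate(collection = "up"),
      enrich_collection(stats_vec, down_sets, rho) %>% mutate(collection = "down")
    ) %>%
      mutate(pert = ctr)
  })
  out %>%
    rename(sig_id = "set_name") %>%
    left_join(parsed, by = "sig_id") %>%
    select("sig_id", "cell", "pert_gene", "pert", "collection", "n_genes",
           "direction", "p", "signed_score")
}

gsea_walk_es <- function(stats_sorted, in_set, weight = 1) {
  n <- length(stats_sorted)
  m <- sum(in_set)
  w <- abs(stats_sorted)^weight
  nr <- sum(w[in_set])
  if (nr == 0) {
    inc <- ifelse(in_set, 1 / m, 0)           # all-zero weights: flat credit
  } else {
    inc <- ifelse(in_set, w / nr, 0)
  }
  dec <- ifelse(in_set, 0, 1 / (n - m))
  walk <- cumsum(inc - dec)
  walk[which.max(abs(walk))]
}

#' Preranked GSEA with gene-label permutation p-values
#'
#' Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1:
#' in-set increments proportional to |value|) on genes sorted by
#' decreasing value; ES is the signed maximum deviation of the running
#' sum. The p-value permutes gene labels (random sets of the same size)
#' and uses the `(b + 1) / (n_perm + 1)` estimator, one-tailed in the
#' direction of the observed ES.
#'
#' @param ranks Named numeric vector (gene-level values, e.g. correlations);
#'   no duplicate names.
#' @param set Character vector of gene symbols; must overlap `ranks` and
#'   not cover it entirely.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations (mandatory).
#' @return One-row tibble `es`, `p_perm`, `n_genes`.
#' @export
preranked_gsea <- function(ranks, set, n_perm = 1000, seed) {
  if (missing(seed)) stop("`seed` is mandatory for preranked_gsea()", call. = FALSE)
  if (anyDuplicated(names(ranks))) stop("duplicate gene names in `ranks`", call. = FALSE)
  ord <- order(ranks, decreasing = TRUE)
  stats_sorted <- ranks[ord]
  in_set <- names(stats_sorted) %in% set
  m <- sum(in_set)
  if (m < 1) stop("set does not overlap the ranked genes", call. = FALSE)
  if (m >= length(ranks)) {
    stop("set covers the whole ranked universe; ES is degenerate", call. = FALSE)
  }
  es <- gsea_walk_es(stats_sorted, in_set)
  n <- length(stats_sorted)
  perm_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, m)
      flags <- logical(n)
      flags[idx] <- TRUE
      gsea_walk_es(stats_sorted, flags)
    }, numeric(1))
  })
  b <- if (es >= 0) sum(perm_es >= es) else sum(perm_es <= es)
  tibble::tibble(es = es, p_perm = (b + 1) / (n_perm + 1), n_genes = m)
}
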