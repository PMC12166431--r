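# Knockdown signature store: consensus-shRNA signature matrices with
# metadata, top/bottom-k gene-set extraction, signature-id parsing, and GMT
# round trip. The store mirrors the LINCS Level-5 layout (moderated z-like
# scores, genes x signatures) at fixture scale; backends are an in-memory
# matrix and a long-format TSV.

#' Construct a knockdown signature store
#'
#' @param scores Numeric matrix of differential-expression scores, genes in
#'   rows (rownames = gene ids or symbols), signatures in columns
#'   (colnames = sig_id).
#' @param meta Tibble `sig_id`, `pert_type`, `pert_gene`, `cell`, `time`;
#'   every column of `scores` must have a metadata row.
#' @param gene_info Optional tibble `gene_id`, `symbol` used to translate
#'   row ids to symbols at extraction time.
#' @return A `signature_store` list.
#' @export
signature_store <- function(scores, meta, gene_info = NULL) {
  scores <- as.matrix(scores)
  meta <- tibble::as_tibble(meta)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("`scores` needs gene rownames and sig_id colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(scores)) || anyDuplicated(colnames(scores))) {
    stop("duplicate gene or signature ids in `scores`", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(scores), meta$sig_id)
  if (length(missing_meta) > 0) {
    stop("signatures without metadata: ",
         paste(head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(scores = scores, meta = meta, gene_info = gene_info),
            class = "signature_store")
}

#' @export
print.signature_store <- function(x, ...) {
  cat("signature_store:", nrow(x$scores), "genes x", ncol(x$scores),
      "signatures\n")
  cat("pert types:", paste(unique(x$meta$pert_type), collapse = ", "), "\n")
  invisible(x)
}

#' Read a signature store from long-format TSV files
#'
#' The scores file has columns `gene_id`, `sig_id`, `score` (one row per
#' pair); the metadata file follows the sig-info convention (`sig_id`,
#' `pert_type`, `pert_gene`, `cell`, `time`).
#'
#' @param scores_path,meta_path TSV paths.
#' @param gene_info Optional gene-id to symbol tibble.
#' @return A [signature_store()].
#' @export
read_signature_store_tsv <- function(scores_path, meta_path, gene_info = NULL) {
  long <- readr::read_tsv(scores_path, show_col_types = FALSE)
  if (!all(c("gene_id", "sig_id", "score") %in% names(long))) {
    stop("scores TSV needs gene_id, sig_id, score columns", call. = FALSE)
  }
  if (anyDuplicated(long[c("gene_id", "sig_id")])) {
    stop("duplicate (gene_id, sig_id) pairs in ", scores_path, call. = FALSE)
  }
  wide <- tidyr::pivot_wider(long, names_from = "sig_id", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$gene_id)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  signature_store(m, meta, gene_info = gene_info)
}

#' Select consensus shRNA signatures by perturbation type and time
#'
#' Keeps signatures with `pert_type == "trt_sh.cgs"` (aggregated knockdown
#' signatures) whose `time` matches `time_filter`.
#'
#' @param meta Signature metadata tibble (or a [signature_store()]).
#' @param time_filter Time label to keep (default `"96H"`); NULL disables
#'   the time filter.
#' @return Character vector of sig_ids (empty, with a warning, if none
#'   match).
#' @export
filter_consensus_shrna <- function(meta, time_filter = "96H") {
  if (inherits(meta, "signature_store")) meta <- meta$meta
  keep <- meta$pert_type == "trt_sh.cgs"
  if (!is.null(time_filter)) {
    keep <- keep & stringr::str_detect(meta$time, stringr::fixed(time_filter))
  }
  ids <- meta$sig_id[keep]
  if (length(ids) == 0) {
    warning("no consensus shRNA signatures match the filter", call. = FALSE)
  }
  ids
}

extract_one_signature <- function(scores, ids, symbols, k) {
  ok <- is.finite(scores)
  scores <- scores[ok]
  ids <- ids[ok]
  symbols <- symbols[ok]
  if (length(scores) < 2 * k) {
    stop("signature has fewer than 2k = ", 2 * k, " finite scores", call. = FALSE)
  }
  up_ord <- order(-scores, ids)
  down_ord <- order(scores, ids)
  list(up = symbols[up_ord[seq_len(k)]], down = symbols[down_ord[seq_len(k)]])
}

#' Extract top/bottom-k gene sets from knockdown signatures
#'
#' For each selected signature, the `k` genes with the highest scores form
#' the up set and the `k` with the lowest scores the down set. Ties at the
#' k-th rank are broken by ascending gene id, so extraction is
#' deterministic and invariant to row order. Row ids are translated to
#' symbols through the store's `gene_info` when present.
#'
#' @param store A [signature_store()].
#' @param sig_ids Signatures to extract (default: all columns).
#' @param k Set size per direction (default 20).
#' @return List with `up` and `down`, each a named list of gene-symbol
#'   vectors keyed by sig_id (a gene-set collection).
#' @export
extract_top_bottom_sets <- function(store, sig_ids = NULL, k = 20) {
  stopifnot(inherits(store, "signature_store"))
  if (is.null(sig_ids)) sig_ids <- colnames(store$scores)
  missing_ids <- setdiff(sig_ids, colnames(store$scores))
  if (length(missing_ids) > 0) {
    stop("unknown sig_id(s): ", paste(head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  }
  ids <- rownames(store$scores)
  symbols <- ids
  if (!is.null(store$gene_info)) {
    hit <- match(ids, as.character(store$gene_info$gene_id))
    symbols <- ifelse(is.na(hit), ids, store$gene_info$symbol[hit])
  }
  up <- vector("list", length(sig_ids))
  down <- vector("list", length(sig_ids))
  for (i in seq_along(sig_ids)) {
    sets <- extract_one_signature(store$scores[, sig_ids[i]], ids, symbols, k)
    up[[i]] <- sets$up
    down[[i]] <- sets$down
  }
  names(up) <- sig_ids
  names(down) <- sig_ids
  list(up = up, down = down)
}

#' Parse a consensus-signature id into cell line and perturbed gene
#'
#' Ids follow the `CGS<digits>_<CELL>_<GENE>[:<tail>]` grammar, with an
#' optional time token before the gene (`CGS1_A375_96H:TP53:1`).
#'
#' @param sig_id Character vector of signature ids.
#' @return Tibble `sig_id`, `cell`, `pert_gene`.
#' @export
parse_signature_id <- function(sig_id) {
  m <- stringr::str_match(sig_id,
    "^CGS[0-9]+_([A-Za-z0-9]+)_(?:[0-9]+H:)?([A-Za-z0-9-]+)(?::.*)?$")
  bad <- sig_id[is.na(m[, 1])]
  if (length(bad) > 0) {
    stop("cannot parse signature id(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(sig_id = sig_id, cell = m[, 2], pert_gene = m[, 3])
}

#' Write and read gene-set collections in GMT format
#'
#' Each GMT line is `set_name<TAB>description<TAB>member...`. Writing then
#' reading is the identity on the collection (descriptions default to the
#' set name).
#'
#' @param collection Named list of character vectors (gene symbols).
#' @param path File path.
#' @return `read_gmt()` returns the named list; `write_gmt()` returns
#'   `path` invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (length(collection) > 0 && is.null(names(collection))) {
    stop("gene-set collection must be named", call. = FALSE)
  }
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, nm, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " in ", path,
           ": fewer than 3 tab-separated fields", call. = FALSE)
    }
    nms[i] <- fields[1]
    out[[i]] <- fields[-(1:2)]
  }
  names(out) <- nms
  out
}
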