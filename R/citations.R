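# Citation-count clients for novelty filtering. Queries have the form
# "GENE AND TERM". The offline fixture client serves stored counts (the
# tested path); the Entrez client talks to NCBI eutils and is intended for
# interactive use with an API key.

#' Offline citation-count client from a fixture
#'
#' The fixture maps `"GENE AND TERM"` query strings to integer counts; it
#' can be a named list/vector or a path to a JSON object of the same shape.
#' Queries absent from the fixture return 0 with a warning.
#'
#' @param fixture Named list/numeric vector or JSON file path.
#' @return A citation client usable with [citation_counts()].
#' @export
citation_client_fixture <- function(fixture) {
  if (is.character(fixture) && length(fixture) == 1 && file.exists(fixture)) {
    fixture <- jsonlite::read_json(fixture, simplifyVector = TRUE)
  }
  counts <- unlist(fixture)
  structure(list(counts = counts), class = c("citation_client_fixture",
                                             "citation_client"))
}

#' Live PubMed citation-count client (NCBI eutils)
#'
#' Issues esearch queries with `retmax=0` and parses the `Count` field.
#' Requests are rate limited and retried with exponential backoff; counts
#' are never fabricated - persistent failure is an error.
#'
#' @param api_key Optional NCBI API key.
#' @param sleep Seconds between requests (default 0.34).
#' @param max_retries Retries per query (default 3).
#' @return A citation client usable with [citation_counts()].
#' @export
citation_client_entrez <- function(api_key = NULL, sleep = 0.34, max_retries = 3) {
  structure(list(api_key = api_key, sleep = sleep, max_retries = max_retries),
            class = c("citation_client_entrez", "citation_client"))
}

query_count <- function(client, query) UseMethod("query_count")

#' @export
query_count.citation_client_fixture <- function(client, query) {
  if (query %in% names(client$counts)) {
    as.integer(client$counts[[query]])
  } else {
    warning("query not in fixture, returning 0: ", query, call. = FALSE)
    0L
  }
}

#' @export
query_count.citation_client_entrez <- function(client, query) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi"
  url <- paste0(base, "?db=pubmed&retmax=0&term=", URLencode(query, reserved = TRUE),
                if (!is.null(client$api_key)) paste0("&api_key=", client$api_key))
  for (attempt in seq_len(client$max_retries)) {
    Sys.sleep(client$sleep * 2^(attempt - 1))
    resp <- tryCatch(paste(readLines(url, warn = FALSE), collapse = ""),
                     error = function(e) NULL)
    if (!is.null(resp)) {
      count <- stringr::str_match(resp, "<Count>(\\d+)</Count>")[, 2]
      if (!is.na(count)) return(as.integer(count))
    }
  }
  stop("PubMed query failed after ", client$max_retries, " retries: ", query,
       call. = FALSE)
}

#' Citation counts for genes x pathway terms
#'
#' One query per (gene, term) pair, of the form `"GENE AND TERM"`.
#'
#' @param genes Character vector of gene symbols.
#' @param terms Character vector of pathway terms.
#' @param client A citation client ([citation_client_fixture()] or
#'   [citation_client_entrez()]).
#' @return Tibble `gene`, `term`, `count`.
#' @export
citation_counts <- function(genes, terms, client) {
  stopifnot(inherits(client, "citation_client"))
  tidyr::expand_grid(gene = genes, term = terms) %>%
    mutate(count = purrr::map2_int(.data$gene, .data$term, function(g, t) {
      query_count(client, paste0(g, " AND ", t))
    }))
}
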