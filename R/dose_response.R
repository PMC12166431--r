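# Dose-response curves: fixed-asymptote 4PL fits, IC50, and sensitivity AUC.
#
# The vulnerability measure used throughout the pipeline is the sensitivity
# AUC: 100 minus the range-normalised trapezoidal area under the viability
# vs log10(concentration) curve, so 0 = fully resistant and 100 = fully
# sensitive.

#' Log10-transform molar concentrations
#'
#' @param concentration Numeric vector of molar concentrations (> 0).
#' @return `log10(concentration)`.
#' @examples
#' log10_concentration(5e-8) # -7.30103
#' @export
log10_concentration <- function(concentration) {
  if (!is.numeric(concentration)) {
    stop("`concentration` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be finite and > 0", call. = FALSE)
  }
  log10(concentration)
}

#' Validate and normalise a dose-response table
#'
#' A dose-response table holds viability measurements (% of untreated
#' control) at increasing drug concentrations, one row per
#' (cell line, replicate, concentration).
#'
#' @param tbl Data frame with columns `cell_line`, `concentration`,
#'   `log_conc`, `replicate`, `viability` (an `inducer` column is allowed
#'   and preserved).
#' @return The validated tibble.
#' @export
as_dose_response_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  needed <- c("cell_line", "concentration", "log_conc", "replicate", "viability")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("dose-response table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tbl$viability)) || any(tbl$viability < 0)) {
    stop("viability must be finite and >= 0 (% of control)", call. = FALSE)
  }
  if (any(tbl$concentration <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (any(abs(tbl$log_conc - log10(tbl$concentration)) >= 1e-4)) {
    stop("`log_conc` disagrees with log10(concentration)", call. = FALSE)
  }
  n_conc <- tbl %>%
    group_by(.data$cell_line, .data$replicate) %>%
    summarise(n = dplyr::n_distinct(.data$log_conc), .groups = "drop")
  if (any(n_conc$n < 3)) {
    stop("each (cell_line, replicate) needs >= 3 distinct concentrations",
         call. = FALSE)
  }
  tbl
}

#' Read a dose-response CSV in the wide worked-example layout
#'
#' Expected header: `Cell_line, Concentration, logConc, Repeat_1, ...`
#' (one viability column per replicate). Returns the long table used by the
#' fitting and AUC functions.
#'
#' @param path CSV file path.
#' @param inducer Optional inducer label attached to every row.
#' @return A dose-response tibble (see [as_dose_response_table()]).
#' @export
read_dose_response <- function(path, inducer = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("Cell_line", "Concentration", "logConc") %in% names(raw))) {
    stop("expected columns Cell_line, Concentration, logConc in ", path,
         call. = FALSE)
  }
  rep_cols <- grep("^Repeat_", names(raw), value = TRUE)
  if (length(rep_cols) == 0) {
    stop("no Repeat_* viability columns found in ", path, call. = FALSE)
  }
  long <- raw %>%
    tidyr::pivot_longer(all_of(rep_cols), names_to = "replicate",
                        values_to = "viability") %>%
    dplyr::filter(!is.na(.data$viability)) %>%
    rename(cell_line = "Cell_line", concentration = "Concentration",
           log_conc = "logConc")
  if (!is.null(inducer)) long$inducer <- inducer
  as_dose_response_table(long)
}

logistic4_viability <- function(log_conc, slope, ec50_log) {
  100 / (1 + exp(slope * (log_conc - ec50_log)))
}

#' Fit a fixed-asymptote four-parameter logistic curve
#'
#' Fits viability(x) = 100 / (1 + exp(b (x - e))) with the lower and upper
#' asymptotes fixed at 0% and 100%, by least squares (Levenberg-Marquardt,
#' started at b = 1, e = median(log_conc)). `x` is log10(concentration), so
#' `e` is the log10 EC50 and, under the fixed asymptotes, the log10 IC50.
#'
#' @param tbl Dose-response tibble for one cell line (and one inducer).
#' @param per `"replicate"` (default, one fit per replicate, as with a
#'   per-curve id) or `"pooled"` (one fit over all points).
#' @return Tibble with one row per fit: `cell_line`, `replicate`, `slope`,
#'   `ec50_log`, `sse`, `n_points`.
#' @export
fit_logistic4 <- function(tbl, per = c("replicate", "pooled")) {
  per <- match.arg(per)
  tbl <- as_dose_response_table(tbl)
  if (dplyr::n_distinct(tbl$cell_line) != 1) {
    stop("fit_logistic4() expects a single cell line; split first",
         call. = FALSE)
  }
  groups <- if (per == "replicate") split(tbl, tbl$replicate) else list(pooled = tbl)
  purrr::imap_dfr(groups, function(g, nm) {
    fit <- fit_logistic4_one(g$log_conc, g$viability)
    tibble::tibble(cell_line = g$cell_line[1], replicate = nm,
                   slope = fit$slope, ec50_log = fit$ec50_log,
                   sse = fit$sse, n_points = nrow(g))
  })
}

fit_logistic4_one <- function(log_conc, viability) {
  if (dplyr::n_distinct(log_conc) < 3) {
    stop("need >= 3 distinct log-concentrations to fit", call. = FALSE)
  }
  if (dplyr::n_distinct(viability) == 1) {
    stop("degenerate data: viability is constant, no dose response to fit",
         call. = FALSE)
  }
  dat <- data.frame(x = log_conc, y = viability)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 100 / (1 + exp(b * (x - e))),
      data = dat,
      start = list(b = 1, e = median(log_conc)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(err) {
      stop("logistic fit failed to converge: ", conditionMessage(err),
           call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  list(slope = unname(est["b"]), ec50_log = unname(est["e"]),
       sse = sum(stats::resid(fit)^2))
}

#' IC50 from a logistic fit
#'
#' Under the fixed 0/100 asymptotes the fitted curve crosses 50% viability
#' exactly at the EC50, so the IC50 is `10^ec50_log` (molar).
#'
#' @param fit Tibble returned by [fit_logistic4()] (or anything with an
#'   `ec50_log` column).
#' @return `fit` with an added `ic50` column.
#' @export
ic50_from_fit <- function(fit) {
  if (!"ec50_log" %in% names(fit)) stop("`fit` lacks an ec50_log column", call. = FALSE)
  dplyr::mutate(fit, ic50 = 10^.data$ec50_log)
}

sensitivity_auc_points <- function(log_conc, viability) {
  ord <- order(log_conc)
  x <- log_conc[ord]
  y <- viability[ord]
  if (dplyr::n_distinct(x) < 2) {
    stop("sensitivity AUC needs >= 2 distinct concentrations", call. = FALSE)
  }
  area <- pracma::trapz(x, y) / (max(x) - min(x))
  auc <- 100 - area
  if (auc < 0 || auc > 100) {
    warning("sensitivity AUC ", format(auc), " outside [0, 100]; clipped",
            call. = FALSE)
    auc <- min(max(auc, 0), 100)
  }
  auc
}

#' Sensitivity AUC from observed viability points
#'
#' Computes 100 minus the range-normalised trapezoidal area of viability vs
#' log10(concentration), per (cell line, replicate) and, when present, per
#' inducer. Higher values mean greater drug sensitivity. Values outside
#' \[0, 100\] (possible when viability exceeds 100%) are clipped with a
#' warning.
#'
#' @param tbl Dose-response tibble.
#' @return Tibble `cell_line` (, `inducer`), `replicate`, `auc`.
#' @export
sensitivity_auc <- function(tbl) {
  tbl <- as_dose_response_table(tbl)
  keys <- intersect(c("cell_line", "inducer", "replicate"), names(tbl))
  tbl %>%
    group_by(across(all_of(keys))) %>%
    summarise(auc = sensitivity_auc_points(.data$log_conc, .data$viability),
              .groups = "drop")
}

#' Aggregate replicate AUCs into a cell line x inducer sensitivity table
#'
#' Replicate AUCs are averaged to one value per (cell line, inducer), the
#' layout used downstream for the correlation predictors.
#'
#' @param tbl Dose-response tibble with an `inducer` column, or the output
#'   of [sensitivity_auc()].
#' @return Tibble `cell_line`, `inducer`, `auc` (long format).
#' @export
auc_table <- function(tbl) {
  if (!"auc" %in% names(tbl)) tbl <- sensitivity_auc(tbl)
  if (!"inducer" %in% names(tbl)) tbl$inducer <- "inducer"
  tbl %>%
    group_by(.data$cell_line, .data$inducer) %>%
    summarise(auc = mean(.data$auc), .groups = "drop")
}

#' Read / write the wide AUC table layout
#'
#' The wide layout has one `Cell_line` column and one column per inducer.
#'
#' @param path CSV path.
#' @param aucs Long AUC tibble (`cell_line`, `inducer`, `auc`).
#' @return `read_auc_table()` returns the long tibble; `write_auc_table()`
#'   returns `path` invisibly.
#' @export
read_auc_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!"Cell_line" %in% names(raw)) {
    stop("expected a Cell_line column in ", path, call. = FALSE)
  }
  raw %>%
    tidyr::pivot_longer(-"Cell_line", names_to = "inducer", values_to = "auc") %>%
    rename(cell_line = "Cell_line")
}

#' @rdname read_auc_table
#' @export
write_auc_table <- function(aucs, path) {
  wide <- aucs %>%
    tidyr::pivot_wider(id_cols = "cell_line", names_from = "inducer",
                       values_from = "auc") %>%
    rename(Cell_line = "cell_line")
  readr::write_csv(wide, path)
  invisible(path)
}
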