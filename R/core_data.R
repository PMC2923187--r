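#' @keywords internal
"_PACKAGE"

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: a numeric matrix of
#' finite, non-negative intensities with unique probe ids as row names and
#' unique sample ids as column names.
#'
#' @param expr numeric matrix, probes in rows, samples in columns.
#' @return `expr`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix (probes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have probe ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(expr)))
    stop("duplicated probe id(s): ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample id(s): ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (anyNA(expr) || any(!is.finite(expr)))
    stop("expression matrix contains missing or non-finite values")
  if (any(expr < 0))
    stop("expression matrix contains negative intensities")
  invisible(expr)
}

#' Read a probes-by-samples expression matrix from tab-delimited text
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Decimal separator is ".", missing token is "NA".
#'
#' @param path path to a TSV file.
#' @param missing_policy `"error"` (default) fails on any missing value;
#'   `"drop_row"` silently removes probes with at least one missing cell.
#' @return a numeric matrix with probe rownames and sample colnames, in file
#'   order.
#' @export
read_expression <- function(path, missing_policy = c("error", "drop_row")) {
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs a probe-id column plus >= 1 sample")
  probe_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(probe_ids))
    stop("duplicated probe id(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !(vals == "NA" | is.na(vals))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at probe '%s', sample '%s' (value '%s')",
                 probe_ids[idx[1L]], sample_ids[idx[2L]], vals[idx[1L], idx[2L]]))
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  if (anyNA(num)) {
    if (missing_policy == "error") {
      idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at probe '%s', sample '%s' (use missing_policy = 'drop_row')",
                   probe_ids[idx[1L]], sample_ids[idx[2L]]))
    }
    num <- num[!apply(is.na(num), 1L, any), , drop = FALSE]
  }
  validate_expression(num)
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(x, f))`
#' reproduces `x`.
#'
#' @param expr numeric matrix, probes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical sub-stage -> coarse stage map; unknown strings pass through
.coarse_stage_map <- c(I = "I", IA = "I", IB = "I", II = "II", IIA = "II",
                       IIB = "II", III = "III", IIIA = "III", IIIB = "III")

#' Read a per-sample clinical table from tab-delimited text
#'
#' Mandatory columns are `sample_id`, `time_months` (follow-up, months) and
#' `event` (1 = death observed, 0 = censored). Optional covariates
#' (`stage`, `age_years`, `gender`, `race`, `smoking`, `differentiation`,
#' `chemo`) default to `"Unknown"` (or `NA` for age, 0 for chemo) when
#' absent. Stage strings are normalised case-insensitively and a coarse
#' stage view collapsing sub-stages (IA/IB -> I, ...) is added.
#'
#' @param path path to a TSV file with a header row.
#' @return a `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("sample_id", "time_months", "event"))
    if (!col %in% names(df))
      stop("clinical table is missing mandatory column '", col, "'")
  as_clinical_table(df)
}

#' Coerce a data frame to the clinical-table layout
#'
#' @param df data.frame with at least `sample_id`, `time_months`, `event`.
#' @return a typed clinical `data.frame` (see [read_clinical()]).
#' @export
as_clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s) in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  time <- as.numeric(df$time_months)
  event <- as.integer(df$event)
  if (anyNA(time) || any(!is.finite(time))) stop("time_months must be finite")
  if (any(time < 0)) stop("negative follow-up time for sample(s): ",
                          paste(df$sample_id[time < 0], collapse = ", "))
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (death)")
  cat_or_unknown <- function(col) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[is.na(v) | v == ""] <- "Unknown"
      v
    } else rep("Unknown", nrow(df))
  }
  stage <- toupper(cat_or_unknown("stage"))
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    time_months = time,
    event = event,
    stage = stage,
    coarse_stage = ifelse(stage %in% names(.coarse_stage_map),
                          .coarse_stage_map[stage], stage),
    age_years = if ("age_years" %in% names(df)) as.numeric(df$age_years) else NA_real_,
    gender = cat_or_unknown("gender"),
    race = cat_or_unknown("race"),
    smoking = cat_or_unknown("smoking"),
    differentiation = cat_or_unknown("differentiation"),
    chemo = if ("chemo" %in% names(df)) as.integer(df$chemo) else 0L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Dichotomize a cohort into low- and high-risk prognosis labels
#'
#' Deaths at or before the horizon are labelled `high_risk`; samples with
#' follow-up beyond the horizon (any event status) are `low_risk`; censored
#' samples whose follow-up ends before the horizon are excluded as
#' uninformative. Reaching the horizon alive (censored exactly at the
#' horizon) counts as low risk.
#'
#' @param clinical clinical table (see [read_clinical()]).
#' @param horizon_months dichotomization horizon, months (default 60, i.e.
#'   5-year survival).
#' @return an object of class `prognosis_labels`: list with `sample_id`,
#'   `label` (factor low_risk/high_risk), `excluded_ids`, `horizon_months`.
#' @export
dichotomize <- function(clinical, horizon_months = 60) {
  if (nrow(clinical) == 0L) stop("empty clinical table")
  if (horizon_months <= 0) stop("horizon must be positive")
  t <- clinical$time_months
  e <- clinical$event
  high <- e == 1L & t <= horizon_months
  low <- t > horizon_months | (e == 0L & t == horizon_months)
  excluded <- !high & !low
  structure(list(
    sample_id = clinical$sample_id[!excluded],
    label = factor(ifelse(high[!excluded], "high_risk", "low_risk"),
                   levels = c("low_risk", "high_risk")),
    excluded_ids = clinical$sample_id[excluded],
    horizon_months = horizon_months
  ), class = "prognosis_labels")
}

#' @export
print.prognosis_labels <- function(x, ...) {
  cat(sprintf("prognosis labels at %g months: %d low-risk, %d high-risk, %d excluded\n",
              x$horizon_months, sum(x$label == "low_risk"),
              sum(x$label == "high_risk"), length(x$excluded_ids)))
  invisible(x)
}

#' Restrict expression and clinical data to their common samples
#'
#' Both outputs are restricted to the intersection of sample ids, in the
#' expression matrix's order. Dropped ids are reported as a warning.
#'
#' @param expr expression matrix.
#' @param clinical clinical table.
#' @return list with elements `expr` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) == 0L) stop("no samples in common between expression and clinical data")
  dropped <- setdiff(union(colnames(expr), clinical$sample_id), common)
  if (length(dropped) > 0L)
    warning("dropping sample(s) absent from one input: ",
            paste(dropped, collapse = ", "))
  common <- colnames(expr)[colnames(expr) %in% common]
  list(expr = expr[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample_id), , drop = FALSE])
}

# Resolve a label argument against the columns of an expression matrix.
# Accepts a prognosis_labels object or a named factor/character vector; the
# expression matrix is subset to the labelled samples.
resolve_labels <- function(expr, labels) {
  if (inherits(labels, "prognosis_labels")) {
    ids <- labels$sample_id
    lab <- labels$label
    names(lab) <- ids
  } else {
    if (is.null(names(labels))) {
      if (length(labels) != ncol(expr))
        stop("unnamed labels must have one entry per expression column")
      lab <- factor(labels)
      names(lab) <- colnames(expr)
    } else lab <- factor(labels)
  }
  keep <- intersect(colnames(expr), names(lab))
  if (length(keep) < 2L) stop("fewer than two labelled samples match the expression matrix")
  lab <- droplevels(lab[keep])
  if (nlevels(lab) != 2L) stop("exactly two classes are required, got: ",
                               paste(levels(lab), collapse = ", "))
  list(expr = expr[, keep, drop = FALSE], labels = lab)
}
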