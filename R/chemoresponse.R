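#' Label cell-line drug response from log10(GI50) activity
#'
#' Activities are z-normalized over the lines with non-missing values;
#' lines at least `threshold_sd` SDs above the mean (boundary inclusive)
#' are labelled resistant, at least `threshold_sd` SDs below sensitive,
#' and the remainder intermediate. Missing activities are excluded from
#' the normalization and reported separately.
#'
#' @param gi50 named numeric vector of per-line log10(GI50) values (NA =
#'   not screened).
#' @param threshold_sd labelling threshold in SD units (default 0.5).
#' @return object of class `drug_response`: data.frame `table` (`line_id`,
#'   `gi50`, `z`, `label`), `missing_ids`, `threshold_sd`.
#' @export
label_response <- function(gi50, threshold_sd = 0.5) {
  if (is.null(names(gi50))) stop("gi50 must be a named vector of cell-line activities")
  ok <- !is.na(gi50)
  if (sum(ok) < 3L) stop("need at least 3 lines with non-missing GI50")
  x <- gi50[ok]
  s <- stats::sd(x)
  if (s == 0) stop("zero SD across GI50 values; response labels undefined")
  z <- (x - mean(x)) / s
  label <- ifelse(z >= threshold_sd, "resistant",
           ifelse(z <= -threshold_sd, "sensitive", "intermediate"))
  structure(list(
    table = data.frame(line_id = names(x), gi50 = unname(x), z = unname(z),
                       label = factor(label, levels = c("sensitive", "intermediate",
                                                        "resistant")),
                       row.names = NULL, stringsAsFactors = FALSE),
    missing_ids = names(gi50)[!ok],
    threshold_sd = threshold_sd
  ), class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("drug response: %s (+%d missing)\n",
              paste(sprintf("%d %s", table(x$table$label),
                            names(table(x$table$label))), collapse = ", "),
              length(x$missing_ids)))
  invisible(x)
}

# k-nearest-neighbour prediction, Euclidean distance, majority vote with the
# nearest neighbour breaking vote ties; distance ties broken by line order.
knn_predict <- function(train_x, train_y, test_x, k = 3L) {
  apply(test_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else as.character(train_y[nn[1L]])
  })
}

#' Chemoresponse metrics from per-class correct counts
#'
#' Computes the report-style metrics from confusion counts: sensitivity is
#' the fraction of resistant lines correctly called, specificity the
#' fraction of sensitive lines correctly called, and overall accuracy the
#' pooled fraction.
#'
#' @param resistant_correct,resistant_total,sensitive_correct,sensitive_total
#'   integer counts.
#' @return list: `sensitivity`, `specificity`, `accuracy`, `counts`.
#' @export
chemo_metrics <- function(resistant_correct, resistant_total,
                          sensitive_correct, sensitive_total) {
  stopifnot(resistant_correct <= resistant_total,
            sensitive_correct <= sensitive_total)
  list(sensitivity = resistant_correct / resistant_total,
       specificity = sensitive_correct / sensitive_total,
       accuracy = (resistant_correct + sensitive_correct) /
         (resistant_total + sensitive_total),
       counts = c(resistant_correct = resistant_correct,
                  resistant_total = resistant_total,
                  sensitive_correct = sensitive_correct,
                  sensitive_total = sensitive_total))
}

#' Signature-restricted chemoresponse classification with LOOCV
#'
#' Intermediate lines are excluded; over the retained resistant and
#' sensitive lines, leave-one-out cross-validation of the classifier on
#' z-scored signature gene profiles yields per-class correct counts and the
#' usual metrics (sensitivity = resistant recall, specificity = sensitive
#' recall).
#'
#' @param expr expression matrix (genes x lines) restricted to the
#'   signature genes.
#' @param response a [label_response()] result.
#' @param classifier `"knn"` (default) or a function
#'   `f(train_x, train_y, test_x, k)` returning predicted labels (rows of
#'   the `*_x` matrices are lines).
#' @param k neighbour count for the knn classifier (default 3).
#' @return object of class `chemo_report`: `sensitivity`, `specificity`,
#'   `accuracy`, `counts`, `predictions`.
#' @export
classify_chemo <- function(expr, response, classifier = "knn", k = 3L) {
  stopifnot(inherits(response, "drug_response"))
  tab <- response$table[response$table$label != "intermediate", ]
  ids <- intersect(tab$line_id, colnames(expr))
  tab <- tab[match(ids, tab$line_id), ]
  y <- droplevels(tab$label)
  if (nlevels(y) < 2L || any(table(y) < 2L))
    stop("need at least 2 resistant and 2 sensitive lines with expression data")
  X <- t(expr[, ids, drop = FALSE])            # lines x genes
  X <- scale(X)                                 # z-score each gene over lines
  X[is.na(X)] <- 0                              # constant gene
  clf <- if (is.function(classifier)) classifier
         else if (identical(classifier, "knn")) knn_predict
         else stop("unknown classifier: ", classifier)
  pred <- vapply(seq_len(nrow(X)), function(i) {
    as.character(clf(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE], k))
  }, character(1))
  yc <- as.character(y)
  rc <- sum(pred == "resistant" & yc == "resistant")
  sc <- sum(pred == "sensitive" & yc == "sensitive")
  m <- chemo_metrics(rc, sum(yc == "resistant"), sc, sum(yc == "sensitive"))
  structure(c(m, list(predictions = stats::setNames(pred, ids), k = k)),
            class = "chemo_report")
}

#' @export
print.chemo_report <- function(x, ...) {
  cat(sprintf("chemoresponse LOOCV: sensitivity %.0f%% (%d/%d), specificity %.0f%% (%d/%d), accuracy %.0f%%\n",
              100 * x$sensitivity, x$counts["resistant_correct"],
              x$counts["resistant_total"], 100 * x$specificity,
              x$counts["sensitive_correct"], x$counts["sensitive_total"],
              100 * x$accuracy))
  invisible(x)
}

#' Permutation significance of a signature's chemoresponse accuracy
#'
#' Draws random gene signatures of the same size from the profiled
#' universe (excluding the observed signature genes), reruns the identical
#' LOOCV classification for each, and reports the permutation p-value with
#' the +1 correction: `p = (1 + #[random accuracy >= observed]) /
#' (n_random + 1)`.
#'
#' @param observed_accuracy overall LOOCV accuracy of the real signature.
#' @param expr full expression matrix (genes x lines).
#' @param response a [label_response()] result.
#' @param signature_size number of genes per random signature.
#' @param exclude probe ids excluded from sampling (the observed
#'   signature).
#' @param n_random number of random signatures (>= 100; default 1000).
#' @param classifier,k passed to [classify_chemo()].
#' @param seed sampling seed.
#' @return list: `p`, `n_random`, `random_accuracy`.
#' @export
permutation_significance <- function(observed_accuracy, expr, response,
                                     signature_size, exclude = character(0),
                                     n_random = 1000L, classifier = "knn",
                                     k = 3L, seed = 1L) {
  if (n_random < 100L) stop("n_random must be at least 100")
  universe <- setdiff(rownames(expr), exclude)
  if (length(universe) < signature_size)
    stop("profiled universe smaller than the signature size")
  set.seed(seed)
  acc <- vapply(seq_len(n_random), function(b) {
    sig <- sample(universe, signature_size)
    classify_chemo(expr[sig, , drop = FALSE], response, classifier, k)$accuracy
  }, numeric(1))
  list(p = (1 + sum(acc >= observed_accuracy)) / (n_random + 1),
       n_random = n_random, random_accuracy = acc)
}

#' Differential expression between resistant and sensitive lines
#'
#' Per-gene fold change (resistant mean over sensitive mean) with over- /
#' under-expression flags at 1.5 and 0.67, plus two-sided Welch t-test
#' p-values; a gene is called significant at `p <= 0.05`.
#'
#' @param expr expression matrix (genes x lines).
#' @param response a [label_response()] result.
#' @param p_threshold significance threshold (default 0.05).
#' @return data.frame: `probe_id`, `fold_change`, `flag`, `t`, `p`,
#'   `significant`.
#' @export
resistant_vs_sensitive_de <- function(expr, response, p_threshold = 0.05) {
  stopifnot(inherits(response, "drug_response"))
  tab <- response$table[response$table$label != "intermediate", ]
  ids <- intersect(tab$line_id, colnames(expr))
  lab <- factor(stats::setNames(as.character(tab$label[match(ids, tab$line_id)]), ids),
                levels = c("resistant", "sensitive"))
  fc <- group_fold_change(expr[, ids, drop = FALSE], lab)
  tt <- de_ttest(expr[, ids, drop = FALSE], lab, variant = "different_variance")
  data.frame(probe_id = fc$probe_id, fold_change = fc$fold_change,
             flag = fc$flag, t = tt$t, p = tt$p,
             significant = tt$p <= p_threshold & fc$flag %in% c("over", "under"),
             row.names = NULL, stringsAsFactors = FALSE)
}
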