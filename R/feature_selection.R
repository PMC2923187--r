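#' Relief ranking of candidate genes
#'
#' ReliefF-style attribute weighting for a two-class problem on continuous
#' attributes. For each sampled instance the k nearest hits (same class) and
#' k nearest misses (other class) are found under Manhattan distance on
#' range-normalized attributes; the weight of attribute A accumulates
#' `+diff(A, x, miss)` and `-diff(A, x, hit)`, each divided by `m * k`,
#' with `diff(A, x, y) = |x_A - y_A| / range(A)`. Attributes that better
#' separate the classes than they scatter within a class therefore gain
#' weight. Constant attributes (range 0) have diff 0 and weight exactly 0.
#' Distance ties are broken by sample order; with `m = NULL` every instance
#' is used once in input order, making the result deterministic.
#'
#' @param expr expression matrix restricted to candidate probes.
#' @param labels a [dichotomize()] result or named two-level factor.
#' @param k number of nearest hits/misses (default 10; `k = 1` gives
#'   classic Relief).
#' @param m number of sampled instances; `NULL` (default) uses all.
#' @param seed seed for instance sampling when `m` is given.
#' @return object of class `relief_ranking`: data.frame `ranking`
#'   (`probe_id`, `weight`, descending weight, stable in input order), plus
#'   parameters.
#' @export
relief_rank <- function(expr, labels, k = 10L, m = NULL, seed = 1L) {
  if (k < 1L) stop("k must be at least 1")
  r <- resolve_labels(expr, labels)
  lab <- r$labels
  if (nlevels(lab) != 2L) stop("two classes required")
  if (min(table(lab)) < 2L) stop("each class needs at least 2 samples")
  X <- t(r$expr)                       # samples x attributes
  rng <- apply(X, 2L, function(v) diff(range(v)))
  Xn <- sweep(X, 2L, ifelse(rng == 0, 1, rng), "/")
  Xn[, rng == 0] <- 0                  # constant attribute: diff always 0
  n <- nrow(Xn)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))

  if (is.null(m)) {
    idx <- seq_len(n)
  } else {
    if (m < 1L) stop("m must be at least 1")
    set.seed(seed)
    idx <- sample.int(n, min(m, n))
  }
  m_used <- length(idx)
  W <- numeric(ncol(Xn))
  for (i in idx) {
    same <- which(lab == lab[i]); same <- same[same != i]
    other <- which(lab != lab[i])
    # ties in distance broken by sample order
    hits <- same[order(D[i, same], same)][seq_len(min(k, length(same)))]
    misses <- other[order(D[i, other], other)][seq_len(min(k, length(other)))]
    if (length(hits))
      W <- W - colSums(abs(Xn[hits, , drop = FALSE] -
                             matrix(Xn[i, ], length(hits), ncol(Xn), byrow = TRUE))) /
        (m_used * length(hits))
    if (length(misses))
      W <- W + colSums(abs(Xn[misses, , drop = FALSE] -
                             matrix(Xn[i, ], length(misses), ncol(Xn), byrow = TRUE))) /
        (m_used * length(misses))
  }
  ord <- order(-W)                     # stable: ties keep input probe order
  structure(list(
    ranking = data.frame(probe_id = colnames(Xn)[ord], weight = W[ord],
                         row.names = NULL, stringsAsFactors = FALSE),
    weights = stats::setNames(W, colnames(Xn)),
    k = k, m = m_used, seed = seed
  ), class = "relief_ranking")
}

#' @export
print.relief_ranking <- function(x, ...) {
  cat(sprintf("Relief ranking of %d attributes (k = %d, m = %d)\n",
              nrow(x$ranking), x$k, x$m))
  print(utils::head(x$ranking))
  invisible(x)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
make_stratified_folds <- function(labels, cv_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  fold
}

# Cross-validated Naive Bayes accuracy for a fixed gene set and fixed folds.
cv_nb_accuracy <- function(expr, labels, genes, fold) {
  correct <- 0L
  for (f in unique(fold)) {
    tr <- fold != f
    model <- train_nb(expr[genes, tr, drop = FALSE], labels[tr])
    post <- nb_posterior(model, expr[genes, !tr, drop = FALSE])
    pred <- classify_risk(post)
    # generic class names: map posterior's second level back
    correct <- correct + sum(as.character(pred) == as.character(labels[!tr]))
  }
  correct / length(labels)
}

#' Stepwise forward selection over a Relief ranking
#'
#' Starting from the top-ranked gene, each next gene in the ranking is
#' tentatively added and the stratified `cv_folds`-fold cross-validated
#' accuracy of the Gaussian Naive Bayes classifier on the enlarged set is
#' computed; the gene is accepted only if accuracy strictly increases, and
#' the first rejection stops the search. Folds are drawn once from `seed`
#' and reused at every step, so accuracy differences reflect gene sets and
#' not fold noise.
#'
#' @param expr expression matrix covering at least the ranked probes.
#' @param labels a [dichotomize()] result or named two-level factor.
#' @param ranking a [relief_rank()] result (or data.frame with `probe_id`).
#' @param cv_folds number of folds (default 10).
#' @param seed seed fixing the fold partition.
#' @param max_genes optional cap on the number of evaluated steps.
#' @return object of class `selection_trace`: data.frame `trace`
#'   (`probe_id`, `cv_accuracy`, `accepted`), `selected` probe ids,
#'   `stop_reason` in `"no_improvement"` / `"exhausted"` / `"max_genes"`.
#' @export
stepwise_select <- function(expr, labels, ranking, cv_folds = 10L, seed = 1L,
                            max_genes = Inf) {
  if (cv_folds < 2L) stop("cv_folds must be at least 2")
  genes <- if (inherits(ranking, "relief_ranking")) ranking$ranking$probe_id
           else ranking$probe_id
  if (length(genes) == 0L) stop("empty ranking")
  r <- resolve_labels(expr, labels)
  if (length(r$labels) < cv_folds) stop("fewer samples than folds")
  fold <- make_stratified_folds(r$labels, cv_folds, seed)

  selected <- character(0)
  trace <- data.frame(probe_id = character(0), cv_accuracy = numeric(0),
                      accepted = logical(0), stringsAsFactors = FALSE)
  best <- -Inf
  stop_reason <- "exhausted"
  for (gidx in seq_along(genes)) {
    if (length(selected) >= max_genes) { stop_reason <- "max_genes"; break }
    g <- genes[gidx]
    acc <- cv_nb_accuracy(r$expr, r$labels, c(selected, g), fold)
    accept <- acc > best             # first gene always accepted (best = -Inf)
    trace <- rbind(trace, data.frame(probe_id = g, cv_accuracy = acc,
                                     accepted = accept, stringsAsFactors = FALSE))
    if (!accept) { stop_reason <- "no_improvement"; break }
    selected <- c(selected, g)
    best <- acc
  }
  structure(list(trace = trace, selected = selected, stop_reason = stop_reason,
                 cv_folds = cv_folds, seed = seed),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("stepwise selection: %d gene(s) selected (%s)\n",
              length(x$selected), x$stop_reason))
  print(x$trace)
  invisible(x)
}
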