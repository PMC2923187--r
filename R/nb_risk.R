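#' Train a Gaussian Naive Bayes risk classifier
#'
#' Class priors are maximum-likelihood class fractions (no smoothing);
#' per-class per-gene means and standard deviations (denominator n - 1) are
#' the Gaussian class-conditional parameters. Each gene's SD is floored at
#' `sigma_floor_rel` times that gene's pooled range (with a small absolute
#' fallback for globally constant genes) so densities never degenerate.
#'
#' @param expr expression matrix restricted to the signature genes
#'   (genes x samples).
#' @param labels a [dichotomize()] result or named two-level factor; the
#'   second factor level is treated as the positive ("high-risk") class.
#' @param sigma_floor_rel relative SD floor (default 1e-6 of the gene range).
#' @return object of class `nb_model`: `classes`, `priors`, `mean` and `sd`
#'   (genes x 2 matrices), `genes`, `sigma_floor` per gene.
#' @export
train_nb <- function(expr, labels, sigma_floor_rel = 1e-6) {
  r <- resolve_labels(expr, labels)
  lab <- r$labels
  counts <- table(lab)
  if (any(counts < 2L))
    stop("each class needs at least 2 samples, got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  classes <- levels(lab)
  X <- r$expr
  rng <- apply(X, 1L, function(v) diff(range(v)))
  floor_i <- sigma_floor_rel * rng
  floor_i[floor_i == 0] <- sigma_floor_rel   # globally constant gene
  mu <- sapply(classes, function(cl) rowMeans(X[, lab == cl, drop = FALSE]))
  sdm <- sapply(classes, function(cl) apply(X[, lab == cl, drop = FALSE], 1L, stats::sd))
  mu <- matrix(mu, nrow = nrow(X), dimnames = list(rownames(X), classes))
  sdm <- matrix(pmax(sdm, floor_i), nrow = nrow(X),
                dimnames = list(rownames(X), classes))
  structure(list(classes = classes,
                 priors = as.numeric(counts) / length(lab),
                 mean = mu, sd = sdm, genes = rownames(X),
                 sigma_floor = floor_i),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Gaussian Naive Bayes model: %d genes, classes %s (priors %s)\n",
              length(x$genes), paste(x$classes, collapse = "/"),
              paste(sprintf("%.3f", x$priors), collapse = "/")))
  invisible(x)
}

#' Posterior probability of the positive class
#'
#' Log-domain accumulation of `log P(c) + sum_i log N(a_i; mu_ic, sd_ic)`
#' over the model genes, normalised across the two classes. The returned
#' score is the posterior of the model's second class (high risk for
#' prognosis models).
#'
#' @param model an [train_nb()] / [load_published_model()] model.
#' @param newdata expression matrix (genes x samples) or a named numeric
#'   vector for a single sample; must provide every model gene.
#' @return named numeric vector of positive-class posteriors in \[0,1\],
#'   with the class names in attribute `"classes"`.
#' @export
nb_posterior <- function(model, newdata) {
  stopifnot(inherits(model, "nb_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1L,
                                               dimnames = list(names(newdata), "sample"))
  missing <- setdiff(model$genes, rownames(newdata))
  if (length(missing))
    stop("missing value for model gene(s): ", paste(missing, collapse = ", "))
  X <- newdata[model$genes, , drop = FALSE]
  ll <- sapply(1:2, function(j) {
    colSums(stats::dnorm(X, mean = model$mean[, j], sd = model$sd[, j],
                         log = TRUE)) + log(model$priors[j])
  })
  ll <- matrix(ll, ncol = 2L)
  post <- 1 / (1 + exp(ll[, 1L] - ll[, 2L]))
  structure(stats::setNames(as.numeric(post), colnames(X)),
            classes = model$classes)
}

#' Threshold a posterior risk score into class labels
#'
#' Strict rule: posterior greater than the threshold gives the positive
#' (second) class; a posterior exactly at the threshold gives the first
#' class.
#'
#' @param score numeric posterior vector from [nb_posterior()].
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @param classes class names; defaults to the score's `"classes"`
#'   attribute, falling back to low_risk/high_risk.
#' @return factor of predicted classes.
#' @export
classify_risk <- function(score, threshold = 0.5, classes = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(classes)) classes <- attr(score, "classes")
  if (is.null(classes)) classes <- c("low_risk", "high_risk")
  factor(ifelse(score > threshold, classes[2L], classes[1L]), levels = classes)
}

#' Write a Naive Bayes model as a tab-delimited parameter table
#'
#' Layout mirrors a published parameter table: a `#priors` header line with
#' the two class priors, then one row per gene and class with the Gaussian
#' mean and SD.
#'
#' @param model an `nb_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nb_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#priors\t%s\t%.10g\t%s\t%.10g",
                     model$classes[1L], model$priors[1L],
                     model$classes[2L], model$priors[2L]), con)
  df <- data.frame(
    gene = rep(model$genes, times = 2L),
    class = rep(model$classes, each = length(model$genes)),
    mean = c(model$mean[, 1L], model$mean[, 2L]),
    sd = c(model$sd[, 1L], model$sd[, 2L]), stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Naive Bayes model from a parameter table
#'
#' @param path file written by [write_nb_model()] (or typed by hand in the
#'   same layout).
#' @return an `nb_model`.
#' @export
read_nb_model <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#priors")) stop("model file lacks the #priors header line")
  parts <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  classes <- parts[c(2L, 4L)]
  priors <- as.numeric(parts[c(3L, 5L)])
  if (anyNA(priors) || any(priors <= 0) || abs(sum(priors) - 1) > 1e-6)
    stop("invalid priors in model file")
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  mu <- sdm <- matrix(NA_real_, length(genes), 2L,
                      dimnames = list(genes, classes))
  for (i in seq_len(nrow(df))) {
    mu[df$gene[i], df$class[i]] <- df$mean[i]
    sdm[df$gene[i], df$class[i]] <- df$sd[i]
  }
  if (anyNA(mu) || anyNA(sdm)) stop("incomplete parameter grid in model file")
  if (any(sdm <= 0)) stop("non-positive SD in model file")
  structure(list(classes = classes, priors = priors, mean = mu, sd = sdm,
                 genes = genes, sigma_floor = stats::setNames(rep(0, length(genes)), genes)),
            class = "nb_model")
}

#' Load the bundled published 12-gene prognostic model
#'
#' Returns the 12-probe lung adenocarcinoma signature with its published
#' Gaussian class-conditional parameters and class priors (0.45 low-risk /
#' 0.55 high-risk), bundled as a plain-text fixture and verified against a
#' stored checksum.
#'
#' @return an `nb_model` over the 12 probe ids.
#' @export
load_published_model <- function() {
  path <- system.file("extdata", "nb_model_12gene.tsv", package = "progsig",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, "2f8d8b2ef635a47aaae01e6e9af61ddb"))
    stop("bundled 12-gene model fixture is corrupted (checksum mismatch)")
  model <- read_nb_model(path)
  ann <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  model$symbols <- stats::setNames(ann$symbol[!duplicated(ann$gene)],
                                   ann$gene[!duplicated(ann$gene)])[model$genes]
  model
}

#' Calibration of risk scores against observed survival
#'
#' Bins samples by posterior risk score and estimates, per bin, the
#' Kaplan-Meier probability of death by the horizon with a Greenwood
#' (log-log) 95% confidence interval. Bins holding fewer than `min_n`
#' samples are flagged unstable; empty bins are skipped.
#'
#' @param score named posterior vector.
#' @param clinical clinical table covering the scored samples.
#' @param horizon_months evaluation horizon (default 60).
#' @param bin_width score bin width (default 0.05).
#' @param min_n minimum per-bin size for a stable estimate (default 5).
#' @return data.frame: `bin_mid`, `n`, `death_prob`, `lower`, `upper`,
#'   `stable`.
#' @export
calibration_curve <- function(score, clinical, horizon_months = 60,
                              bin_width = 0.05, min_n = 5L) {
  ids <- intersect(names(score), clinical$sample_id)
  if (length(ids) == 0L) stop("no scored samples found in the clinical table")
  cl <- clinical[match(ids, clinical$sample_id), ]
  sc <- score[ids]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- cut(sc, breaks, include.lowest = TRUE)
  out <- lapply(levels(bin), function(b) {
    in_bin <- which(bin == b)
    if (length(in_bin) == 0L) return(NULL)
    fit <- survival::survfit(survival::Surv(cl$time_months[in_bin],
                                            cl$event[in_bin]) ~ 1,
                             conf.type = "log-log")
    s <- summary(fit, times = horizon_months, extend = TRUE)
    i <- which(levels(bin) == b)
    data.frame(bin_mid = (breaks[i] + breaks[i + 1L]) / 2,
               n = length(in_bin),
               death_prob = 1 - s$surv,
               lower = 1 - ifelse(is.na(s$upper), 1, s$upper),
               upper = 1 - ifelse(is.na(s$lower), 0, s$lower),
               stable = length(in_bin) >= min_n)
  })
  do.call(rbind, out)
}
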