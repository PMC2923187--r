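# Shared test helpers: tiny in-code fixtures and independent oracles.

# named two-level factor over generated sample ids
make_labels <- function(n_low, n_high, classes = c("low_risk", "high_risk")) {
  ids <- sprintf("s%03d", seq_len(n_low + n_high))
  stats::setNames(factor(rep(classes, c(n_low, n_high)), levels = classes), ids)
}

# expression matrix from a plain numeric matrix, adding ids
make_expr <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probe_ids %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("s%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clinical table built from raw vectors
make_clinical <- function(time, event, ids = sprintf("s%03d", seq_along(time))) {
  as_clinical_table(data.frame(sample_id = ids, time_months = time,
                               event = event, stringsAsFactors = FALSE))
}

# independent oracle: Naive Bayes posterior by direct density-product
# evaluation of the Bayes formula (no logs)
nb_posterior_bruteforce <- function(priors, mu, sdm, x) {
  lik <- vapply(1:2, function(j)
    prod(stats::dnorm(x, mu[, j], sdm[, j])) * priors[j], numeric(1))
  lik[2L] / sum(lik)
}

# independent oracle: unweighted (p = 0) enrichment running sum by explicit
# enumeration over the ranked list
es_bruteforce_p0 <- function(ranked_ids, gene_set) {
  hit <- ranked_ids %in% gene_set
  nh <- sum(hit)
  run <- cumsum(ifelse(hit, 1 / nh, -1 / (length(ranked_ids) - nh)))
  run[which.max(abs(run))]
}

# write a small TSV fixture and return the path
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
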