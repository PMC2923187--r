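# Per-gene ranking metric between two classes. signal_to_noise applies the
# usual GSEA variance fix (per-class SD floored at 0.2 * |class mean|).
ranking_metric <- function(expr, labels, metric) {
  s <- group_summaries(expr, labels)
  if (metric == "signal_to_noise") {
    s1 <- pmax(sqrt(s$v1), 0.2 * abs(s$m1))
    s2 <- pmax(sqrt(s$v2), 0.2 * abs(s$m2))
    denom <- s1 + s2
    ifelse(denom == 0, 0, (s$m1 - s$m2) / denom)
  } else {
    se <- sqrt(s$v1 / s$n1 + s$v2 / s$n2)
    ifelse(se == 0, 0, (s$m1 - s$m2) / se)
  }
}

#' Rank genes by differential expression between two phenotype classes
#'
#' Genes are ordered by decreasing metric (signal-to-noise ratio with the
#' standard variance floor, or the Welch-style t statistic); the sign
#' convention is mean(first level) - mean(second level). Ties are broken
#' deterministically by probe id.
#'
#' @param expr expression matrix.
#' @param labels a [dichotomize()] result or named two-level factor.
#' @param metric `"signal_to_noise"` (default) or `"t_statistic"`.
#' @return data.frame (`probe_id`, `score`) in descending score order.
#' @export
rank_genes <- function(expr, labels, metric = c("signal_to_noise", "t_statistic")) {
  metric <- match.arg(metric)
  r <- resolve_labels(expr, labels)
  if (min(table(r$labels)) < 3L) stop("each class needs at least 3 samples")
  score <- ranking_metric(r$expr, r$labels, metric)
  ord <- order(-score, rownames(r$expr))
  data.frame(probe_id = rownames(r$expr)[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enrichment score of a gene set along a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: walking down the ranked list,
#' the sum rises by `|score|^p / sum(|score|^p over set hits)` at each set
#' member and falls by `1 / (N - N_hit)` otherwise; the enrichment score is
#' the signed extremum of the walk. With `weight_p = 0` the walk is
#' unweighted and the ES equals the classic two-sample KS statistic between
#' the hit and miss rank distributions.
#'
#' @param ranked data.frame from [rank_genes()] (or with columns
#'   `probe_id`, `score`).
#' @param gene_set character vector of probe ids.
#' @param weight_p score weighting exponent (default 1).
#' @return list: `es`, `running` (full running-sum profile), `hit_index`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  ids <- ranked$probe_id
  hit <- ids %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the ranked universe")
  if (n_hit == length(ids)) stop("gene set equals the entire universe")
  w <- abs(ranked$score)^weight_p
  w[!hit] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else ifelse(hit, 1 / n_hit, 0)
  dec <- ifelse(hit, 0, 1 / (length(ids) - n_hit))
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hit_index = which(hit))
}

#' Gene-set enrichment analysis with phenotype permutation
#'
#' For each gene set, computes the observed enrichment score on the ranked
#' list, then permutes the phenotype labels `n_perm` times, re-ranks, and
#' recomputes the scores. The normalized enrichment score (NES) divides the
#' observed ES by the mean magnitude of same-sign permutation scores, and
#' the FDR q-value follows the standard pooled positive/negative NES
#' procedure.
#'
#' @param expr expression matrix.
#' @param labels a [dichotomize()] result or named two-level factor.
#' @param gene_sets named list of probe-id vectors.
#' @param n_perm number of phenotype permutations (>= 100; default 200).
#' @param weight_p running-sum weight exponent (default 1).
#' @param metric ranking metric, see [rank_genes()].
#' @param seed permutation seed.
#' @return object of class `enrichment_result`: data.frame `table`
#'   (`set`, `size`, `es`, `nes`, `fdr_q`), plus parameters.
#' @export
gsea <- function(expr, labels, gene_sets, n_perm = 200L, weight_p = 1,
                 metric = "signal_to_noise", seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets)))
    stop("gene_sets must be a uniquely named list")
  r <- resolve_labels(expr, labels)
  lab <- r$labels
  ranked <- rank_genes(r$expr, lab, metric)
  obs_es <- vapply(gene_sets, function(gs)
    enrichment_score(ranked, gs, weight_p)$es, numeric(1))

  set.seed(seed)
  perm_es <- matrix(NA_real_, length(gene_sets), n_perm,
                    dimnames = list(names(gene_sets), NULL))
  for (b in seq_len(n_perm)) {
    plab <- lab
    levels_keep <- levels(lab)
    plab <- factor(sample(as.character(lab)), levels = levels_keep)
    names(plab) <- names(lab)
    pranked <- rank_genes(r$expr, plab, metric)
    perm_es[, b] <- vapply(gene_sets, function(gs)
      enrichment_score(pranked, gs, weight_p)$es, numeric(1))
  }

  norm_by_sign <- function(es, perms) {
    pos_mean <- mean(perms[perms > 0])
    neg_mean <- mean(abs(perms[perms < 0]))
    if (es >= 0) { if (is.nan(pos_mean)) NA_real_ else es / pos_mean }
    else { if (is.nan(neg_mean)) NA_real_ else es / neg_mean }
  }
  nes <- vapply(seq_along(gene_sets), function(i)
    norm_by_sign(obs_es[i], perm_es[i, ]), numeric(1))
  # normalized permutation scores, pooled across sets
  perm_nes <- t(vapply(seq_along(gene_sets), function(i) {
    vapply(perm_es[i, ], function(e) norm_by_sign(e, perm_es[i, ]), numeric(1))
  }, numeric(n_perm)))
  pool <- perm_nes[!is.na(perm_nes)]
  fdr_q <- vapply(seq_along(gene_sets), function(i) {
    v <- nes[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(pool >= v)
      den <- mean(nes >= v, na.rm = TRUE)
    } else {
      num <- mean(pool <= v)
      den <- mean(nes <= v, na.rm = TRUE)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  structure(list(
    table = data.frame(
      set = names(gene_sets),
      size = vapply(gene_sets, function(gs) sum(ranked$probe_id %in% gs), integer(1)),
      es = unname(obs_es), nes = nes, fdr_q = fdr_q,
      row.names = NULL, stringsAsFactors = FALSE),
    n_perm = n_perm, weight_p = weight_p, metric = metric, seed = seed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
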