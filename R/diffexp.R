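# Per-gene two-group summary statistics, vectorized across genes.
# Returns means, variances and counts for group 1 (first factor level) and 2.
group_summaries <- function(expr, labels) {
  g1 <- labels == levels(labels)[1L]
  x1 <- expr[, g1, drop = FALSE]
  x2 <- expr[, !g1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  list(m1 = m1, m2 = m2, v1 = v1, v2 = v2, n1 = n1, n2 = n2)
}

#' Per-gene two-sample t-tests
#'
#' Computes, for every probe, a two-sided two-sample t-test between the two
#' label classes. The `different_variance` variant is the Welch statistic
#' with Welch-Satterthwaite degrees of freedom; `pooled` uses the
#' pooled-variance statistic with n1 + n2 - 2 df. The statistic's sign is
#' mean(first level) - mean(second level). Genes with zero spread in both
#' classes are reported with t = 0, p = 1 and flagged.
#'
#' @param expr expression matrix (probes x samples).
#' @param labels a [dichotomize()] result, or a named two-level factor.
#' @param variant `"different_variance"` (Welch, default) or `"pooled"`.
#' @return data.frame: `probe_id`, `t`, `df`, `p`, `zero_variance`, with the
#'   variant recorded in attribute `"variant"`.
#' @export
de_ttest <- function(expr, labels, variant = c("different_variance", "pooled")) {
  variant <- match.arg(variant)
  r <- resolve_labels(expr, labels)
  if (min(table(r$labels)) < 2L)
    stop("each class needs at least 2 samples")
  s <- group_summaries(r$expr, r$labels)
  num <- s$m1 - s$m2
  if (variant == "different_variance") {
    se2 <- s$v1 / s$n1 + s$v2 / s$n2
    df <- se2^2 / (s$v1^2 / (s$n1^2 * (s$n1 - 1L)) + s$v2^2 / (s$n2^2 * (s$n2 - 1L)))
    se <- sqrt(se2)
  } else {
    vp <- ((s$n1 - 1L) * s$v1 + (s$n2 - 1L) * s$v2) / (s$n1 + s$n2 - 2L)
    se <- sqrt(vp * (1 / s$n1 + 1 / s$n2))
    df <- rep(s$n1 + s$n2 - 2L, length(num))
  }
  zero <- se == 0
  t <- ifelse(zero, 0, num / se)
  df[zero] <- NA_real_
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(t), df))
  structure(data.frame(probe_id = rownames(r$expr), t = t, df = df, p = p,
                       zero_variance = zero, row.names = NULL,
                       stringsAsFactors = FALSE),
            variant = variant)
}

# SAM relative difference d_i = (m1 - m2) / (s_i + s0), s_i the gene-specific
# pooled standard error. Vectorized over permutations: Z is an n x B matrix of
# 0/1 membership indicators for group 1.
sam_d_stats <- function(expr, Z, n1, n2, s0) {
  S1 <- expr %*% Z
  SQ1 <- (expr^2) %*% Z
  tot <- rowSums(expr)
  totsq <- rowSums(expr^2)
  m1 <- S1 / n1
  m2 <- (tot - S1) / n2
  ss1 <- pmax(SQ1 - S1^2 / n1, 0)          # guards tiny negative round-off
  ss2 <- pmax((totsq - SQ1) - (tot - S1)^2 / n2, 0)
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2L))
  (m1 - m2) / (si + s0)
}

# Tusher-style exchangeability constant search: pick s0 among percentiles of
# the gene-specific scatter s_i minimizing the coefficient of variation of
# the d-statistic spread across s_i bins.
choose_s0 <- function(r, si) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(si, alphas, names = FALSE)
  nbin <- max(1L, min(100L, floor(length(si) / 5)))
  bins <- cut(rank(si, ties.method = "first"), breaks = nbin, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- r / (si + s0)
    v <- tapply(d, bins, stats::mad)
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

#' Significance analysis of microarrays (SAM) by label permutation
#'
#' Computes the observed per-gene relative difference
#' `d_i = (mean1 - mean2) / (s_i + s0)` (s_i the gene-specific pooled
#' standard error) and its permutation null: class labels are permuted
#' `n_perm` times and the expected relative difference is the mean of the
#' permutation order statistics. With `s0 = 0` the statistic reduces
#' exactly to the pooled-variance t-statistic. Use [sam_significant()] /
#' [select_delta()] to threshold the result.
#'
#' @param expr expression matrix (probes x samples).
#' @param labels a [dichotomize()] result or named two-level factor.
#' @param n_perm number of label permutations (>= 25; default 300).
#' @param s0 exchangeability constant; `NULL` (default) triggers the
#'   percentile search, a number fixes it.
#' @param seed integer seed for the permutations.
#' @return object of class `sam_result`: per-gene `d` (named), sorted
#'   observed statistics `d_sorted`, expected order statistics `d_bar`,
#'   permutation matrix of sorted null statistics, `s0`, `n_perm`.
#' @export
sam_test <- function(expr, labels, n_perm = 300L, s0 = NULL, seed = 1L) {
  if (n_perm < 25L) stop("n_perm must be at least 25 for a stable null")
  r <- resolve_labels(expr, labels)
  lab <- r$labels
  n <- length(lab)
  g1 <- lab == levels(lab)[1L]
  n1 <- sum(g1); n2 <- n - n1
  if (min(n1, n2) < 2L) stop("each class needs at least 2 samples")

  z_obs <- matrix(as.numeric(g1), ncol = 1L)
  # gene-specific scatter for the s0 search
  s <- group_summaries(r$expr, lab)
  si <- sqrt((1 / n1 + 1 / n2) * ((n1 - 1L) * s$v1 + (n2 - 1L) * s$v2) / (n - 2L))
  ri <- s$m1 - s$m2
  if (is.null(s0)) s0 <- choose_s0(ri, si)
  if (s0 < 0) stop("s0 must be non-negative")

  d_obs <- drop(sam_d_stats(r$expr, z_obs, n1, n2, s0))
  names(d_obs) <- rownames(r$expr)

  set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(b) as.numeric(sample(g1)),
              numeric(n))
  d_perm <- sam_d_stats(r$expr, Z, n1, n2, s0)  # genes x n_perm
  d_perm_sorted <- apply(d_perm, 2L, sort)
  d_bar <- rowMeans(d_perm_sorted)

  ord <- order(d_obs)
  structure(list(d = d_obs, order = ord, d_sorted = d_obs[ord], d_bar = d_bar,
                 d_perm = d_perm, s0 = s0, n_perm = n_perm,
                 n1 = n1, n2 = n2, pi0 = 1),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM result: %d genes, %d permutations, s0 = %.4g\n",
              length(x$d), x$n_perm, x$s0))
  invisible(x)
}

#' Significant genes and estimated FDR at a given delta
#'
#' Applies the standard upper/lower cut construction: scanning the sorted
#' observed statistics against the expected order statistics, the upper cut
#' is the smallest observed d whose deviation exceeds `delta` upward, the
#' lower cut the largest exceeding it downward. The FDR estimate is the
#' median (optionally 90th percentile) permutation count of genes beyond
#' the cuts, scaled by `pi0`, divided by the observed count.
#'
#' @param sam a [sam_test()] result.
#' @param delta non-negative threshold on |d - d_bar|.
#' @param false_count `"median"` (default) or `"p90"`.
#' @return list: `significant` (probe ids, expression order), `n_sig`,
#'   `fdr` (clamped to \[0,1\] in `fdr_display`), `cut_lower`, `cut_upper`,
#'   `delta`.
#' @export
sam_significant <- function(sam, delta, false_count = c("median", "p90")) {
  false_count <- match.arg(false_count)
  stopifnot(inherits(sam, "sam_result"), delta >= 0)
  dev <- sam$d_sorted - sam$d_bar
  up <- which(dev >= delta & sam$d_sorted >= 0)
  cut_upper <- if (length(up)) sam$d_sorted[min(up)] else Inf
  lo <- which(-dev >= delta & sam$d_sorted <= 0)
  cut_lower <- if (length(lo)) sam$d_sorted[max(lo)] else -Inf
  sig_mask <- sam$d >= cut_upper | sam$d <= cut_lower
  n_sig <- sum(sig_mask)
  false_per_perm <- colSums(sam$d_perm >= cut_upper | sam$d_perm <= cut_lower)
  n_false <- if (false_count == "median") stats::median(false_per_perm)
             else stats::quantile(false_per_perm, 0.9, names = FALSE)
  fdr <- if (n_sig == 0L) NA_real_ else sam$pi0 * n_false / n_sig
  list(significant = names(sam$d)[sig_mask], n_sig = n_sig,
       fdr = fdr, fdr_display = if (is.na(fdr)) NA_real_ else min(fdr, 1),
       cut_lower = cut_lower, cut_upper = cut_upper, delta = delta)
}

#' Smallest delta achieving a target FDR
#'
#' Scans the grid of observed |d - d_bar| deviations (plus 0) in increasing
#' order and returns the smallest delta whose estimated FDR is at or below
#' the target with a non-empty significant set.
#'
#' @param sam a [sam_test()] result.
#' @param target_fdr target false discovery rate in (0, 1).
#' @param false_count passed to [sam_significant()].
#' @return list: `delta`, `fdr`, `n_sig`, `significant`.
#' @export
select_delta <- function(sam, target_fdr = 0.25, false_count = "median") {
  stopifnot(inherits(sam, "sam_result"))
  if (target_fdr <= 0 || target_fdr >= 1) stop("target_fdr must be in (0, 1)")
  ds <- sam$d_sorted
  dev <- ds - sam$d_bar
  G <- length(ds)
  grid <- sort(unique(c(0, abs(dev))))

  # cut_upper(delta): smallest (in d order) observed d >= 0 whose upward
  # deviation reaches delta; the first index where the prefix max of the
  # deviations reaches delta is such an element, so a single findInterval
  # over the nondecreasing prefix max resolves the whole grid at once.
  ip <- which(ds >= 0)
  if (length(ip)) {
    pmax_up <- cummax(dev[ip])
    ju <- findInterval(grid, pmax_up, left.open = TRUE) + 1L
    cut_up <- ifelse(ju <= length(ip), ds[ip[pmin(ju, length(ip))]], Inf)
  } else cut_up <- rep(Inf, length(grid))
  # cut_lower(delta): largest observed d <= 0 with downward deviation >= delta
  im <- rev(which(ds <= 0))
  if (length(im)) {
    pmax_lo <- cummax(-dev[im])
    jl <- findInterval(grid, pmax_lo, left.open = TRUE) + 1L
    cut_lo <- ifelse(jl <= length(im), ds[im[pmin(jl, length(im))]], -Inf)
  } else cut_lo <- rep(-Inf, length(grid))

  n_ge <- G - findInterval(cut_up, ds, left.open = TRUE)
  n_le <- findInterval(cut_lo, ds)
  n_sig <- n_ge + n_le
  # permutation false counts per grid delta, by binary search in each
  # perm's sorted statistics
  cnt_up <- vapply(seq_len(ncol(sam$d_perm)), function(b) {
    col <- sort(sam$d_perm[, b])
    G - findInterval(cut_up, col, left.open = TRUE)
  }, numeric(length(grid)))
  cnt_lo <- vapply(seq_len(ncol(sam$d_perm)), function(b) {
    col <- sort(sam$d_perm[, b])
    findInterval(cut_lo, col)
  }, numeric(length(grid)))
  false_mat <- matrix(cnt_up + cnt_lo, nrow = length(grid))
  n_false <- if (false_count == "median") apply(false_mat, 1L, stats::median)
             else apply(false_mat, 1L, stats::quantile, probs = 0.9, names = FALSE)
  fdr <- ifelse(n_sig > 0, sam$pi0 * n_false / n_sig, NA_real_)

  ok <- which(n_sig > 0 & !is.na(fdr) & fdr <= target_fdr)
  if (length(ok) == 0L)
    stop(sprintf("no delta achieves FDR <= %g (minimum achievable FDR: %.4g)",
                 target_fdr, min(fdr[n_sig > 0], na.rm = TRUE)))
  sam_significant(sam, grid[min(ok)], false_count)
}

#' Intersect t-test and SAM candidate gene sets
#'
#' Returns probes significant in both screens (t-test p below threshold and
#' membership in the SAM significant set), preserving expression-matrix
#' order. Both results must cover the same probe universe.
#'
#' @param ttest a [de_ttest()] result.
#' @param sam a [sam_test()] result.
#' @param p_threshold t-test p-value threshold (default 0.01).
#' @param delta SAM delta; default chosen by [select_delta()] at
#'   `target_fdr`.
#' @param target_fdr used when `delta` is missing (default 0.25).
#' @return character vector of probe ids.
#' @export
intersect_candidates <- function(ttest, sam, p_threshold = 0.01, delta = NULL,
                                 target_fdr = 0.25) {
  if (!setequal(ttest$probe_id, names(sam$d)))
    stop("t-test and SAM results cover different probe universes")
  sam_set <- if (is.null(delta)) select_delta(sam, target_fdr)$significant
             else sam_significant(sam, delta)$significant
  t_set <- ttest$probe_id[ttest$p < p_threshold]
  out <- ttest$probe_id[ttest$probe_id %in% t_set & ttest$probe_id %in% sam_set]
  if (length(out) == 0L)
    warning("t-test and SAM significant sets are disjoint; no candidates")
  out
}

#' Per-gene fold change between two groups
#'
#' Ratio of group means (group1 / group2), flagged over-expressed at
#' `over_threshold` (default 1.5) and under-expressed at `under_threshold`
#' (default 0.67). A zero group-2 mean yields `NA` and a flag of
#' `"undefined"`.
#'
#' @param expr expression matrix.
#' @param groups named two-level factor over (a subset of) the columns; the
#'   first level is the numerator group.
#' @param over_threshold,under_threshold flag thresholds.
#' @return data.frame: `probe_id`, `mean1`, `mean2`, `fold_change`, `flag`
#'   in over/under/none/undefined.
#' @export
group_fold_change <- function(expr, groups, over_threshold = 1.5,
                              under_threshold = 0.67) {
  r <- resolve_labels(expr, groups)
  s <- group_summaries(r$expr, r$labels)
  fc <- ifelse(s$m2 == 0, NA_real_, s$m1 / s$m2)
  flag <- ifelse(is.na(fc), "undefined",
          ifelse(fc >= over_threshold, "over",
          ifelse(fc <= under_threshold, "under", "none")))
  data.frame(probe_id = rownames(r$expr), mean1 = s$m1, mean2 = s$m2,
             fold_change = fc, flag = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Relative RT-PCR fold change by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per group,
#' `ddCt = mean dCt(group) - mean dCt(calibrator)`; the fold change is
#' `2^-ddCt` (1 for the calibrator itself).
#'
#' @param ct_target numeric vector of target-gene Ct values.
#' @param ct_reference numeric vector of reference-gene Ct values, same
#'   samples (sample-wise normalisation).
#' @param group factor of group membership per sample.
#' @param calibrator name of the calibrator group level.
#' @return named numeric vector of fold changes, one per group.
#' @export
ddct_fold_change <- function(ct_target, ct_reference, group, calibrator) {
  if (length(ct_target) != length(ct_reference) ||
      length(ct_target) != length(group))
    stop("ct_target, ct_reference and group must have equal length")
  if (anyNA(ct_reference))
    stop("missing reference-gene Ct for sample(s): ",
         paste(which(is.na(ct_reference)), collapse = ", "))
  group <- factor(group)
  if (!calibrator %in% levels(group)) stop("calibrator group not present")
  dct <- ct_target - ct_reference
  mean_dct <- tapply(dct, group, mean)
  ddct <- mean_dct - mean_dct[[calibrator]]
  fc <- 2^(-ddct)
  stats::setNames(as.numeric(fc), names(mean_dct))
}
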