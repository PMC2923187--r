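#' Pipeline configuration with published defaults
#'
#' Collects the thresholds and variant flags used across the discovery
#' pipeline. Defaults are the settings of the published analysis: t-test
#' p < 0.01 (different-variance), SAM FDR target 25%, 10-fold
#' cross-validation in the stepwise search, risk threshold 0.5, 60-month
#' prognosis horizon, chemoresponse labelling at 0.5 SD and 1000 random
#' signatures.
#'
#' @param p_threshold t-test screening threshold.
#' @param target_fdr SAM FDR target.
#' @param ttest_variant `"different_variance"` or `"pooled"`.
#' @param n_perm SAM permutation count.
#' @param relief_k Relief neighbour count.
#' @param cv_folds stepwise cross-validation folds.
#' @param risk_threshold posterior decision threshold.
#' @param horizon_months prognosis dichotomization horizon.
#' @param chemo_threshold_sd drug-response labelling threshold.
#' @param n_random random signatures for chemoresponse significance.
#' @param gsea_metric ranking metric for enrichment.
#' @param seed root seed for all randomized stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(p_threshold = 0.01, target_fdr = 0.25,
                            ttest_variant = "different_variance",
                            n_perm = 300L, relief_k = 10L, cv_folds = 10L,
                            risk_threshold = 0.5, horizon_months = 60,
                            chemo_threshold_sd = 0.5, n_random = 1000L,
                            gsea_metric = "signal_to_noise", seed = 1L) {
  cfg <- list(p_threshold = p_threshold, target_fdr = target_fdr,
              ttest_variant = ttest_variant, n_perm = as.integer(n_perm),
              relief_k = as.integer(relief_k), cv_folds = as.integer(cv_folds),
              risk_threshold = risk_threshold, horizon_months = horizon_months,
              chemo_threshold_sd = chemo_threshold_sd,
              n_random = as.integer(n_random), gsea_metric = gsea_metric,
              seed = as.integer(seed))
  if (cfg$p_threshold <= 0 || cfg$p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (cfg$target_fdr <= 0 || cfg$target_fdr >= 1) stop("target_fdr must be in (0,1)")
  if (cfg$risk_threshold <= 0 || cfg$risk_threshold >= 1) stop("risk_threshold must be in (0,1)")
  if (cfg$horizon_months <= 0) stop("horizon_months must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the signature-discovery pipeline on a cohort
#'
#' Chains the full discovery workflow: prognosis dichotomization at the
#' horizon, candidate screening by the intersection of per-gene t-tests
#' and SAM at the target FDR, Relief ranking of the candidates, stepwise
#' forward selection under cross-validated Naive Bayes accuracy, and final
#' model training on the selected signature.
#'
#' @param expr expression matrix (probes x samples).
#' @param clinical clinical table for the same samples.
#' @param config a [pipeline_config()].
#' @return object of class `signature_pipeline`: `labels`, `ttest`, `sam`,
#'   `sam_delta` (chosen delta and FDR), `candidates`, `ranking`, `trace`,
#'   `signature`, `model`, `config`.
#' @export
run_signature_pipeline <- function(expr, clinical, config = pipeline_config()) {
  al <- align_cohort(expr, clinical)
  labels <- dichotomize(al$clinical, config$horizon_months)
  tt <- de_ttest(al$expr, labels, variant = config$ttest_variant)
  sam <- sam_test(al$expr, labels, n_perm = config$n_perm, seed = config$seed)
  dl <- select_delta(sam, config$target_fdr)
  candidates <- intersect_candidates(tt, sam, p_threshold = config$p_threshold,
                                     delta = dl$delta)
  if (length(candidates) == 0L) stop("screening produced no candidate genes")
  ranking <- relief_rank(al$expr[candidates, , drop = FALSE], labels,
                         k = config$relief_k, seed = config$seed)
  trace <- stepwise_select(al$expr, labels, ranking,
                           cv_folds = config$cv_folds, seed = config$seed)
  model <- train_nb(al$expr[trace$selected, , drop = FALSE], labels)
  structure(list(labels = labels, ttest = tt, sam = sam, sam_delta = dl,
                 candidates = candidates, ranking = ranking, trace = trace,
                 signature = trace$selected, model = model, config = config),
            class = "signature_pipeline")
}

#' @export
print.signature_pipeline <- function(x, ...) {
  cat(sprintf(paste0("signature pipeline: %d candidates (t p<%g ",
                     "∩ SAM delta=%.3g, FDR %.3g) -> %d-gene signature\n"),
              length(x$candidates), x$config$p_threshold, x$sam_delta$delta,
              x$sam_delta$fdr, length(x$signature)))
  cat("signature:", paste(x$signature, collapse = ", "), "\n")
  invisible(x)
}

#' Score a cohort with a trained model and evaluate survival separation
#'
#' Computes posterior risk scores, thresholds them into risk groups, and
#' (when clinical follow-up is supplied) evaluates the stratification with
#' a log-rank test, a univariate Cox fit of the continuous risk score with
#' its hazard ratio and concordance probability estimate, and horizon
#' sensitivity/specificity.
#'
#' @param model an `nb_model`.
#' @param expr expression matrix covering the model genes.
#' @param clinical optional clinical table.
#' @param threshold decision threshold (default 0.5).
#' @param horizon_months horizon for sensitivity/specificity (default 60).
#' @return list: `score`, `group`, and with clinical data `logrank`,
#'   `cox`, `hr`, `cpe`, `sens_spec`.
#' @export
score_cohort <- function(model, expr, clinical = NULL, threshold = 0.5,
                         horizon_months = 60) {
  score <- nb_posterior(model, expr)
  group <- classify_risk(score, threshold)
  names(group) <- names(score)
  out <- list(score = score, group = group)
  if (!is.null(clinical)) {
    ids <- intersect(names(score), clinical$sample_id)
    cl <- clinical[match(ids, clinical$sample_id), ]
    if (nlevels(droplevels(group[ids])) == 2L) {
      out$logrank <- logrank_test(cl$time_months, cl$event, group[ids])
    }
    cox <- tryCatch(
      cox_fit(data.frame(risk_score = unname(score[ids])),
              cl$time_months, cl$event),
      error = function(e) NULL)
    if (!is.null(cox)) {
      out$cox <- cox
      out$hr <- cox$coefficients$hr[1L]
      out$cpe <- cpe(cox)
    }
    out$sens_spec <- tryCatch(
      horizon_sens_spec(group, cl, horizon_months),
      error = function(e) NULL)
  }
  out
}
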