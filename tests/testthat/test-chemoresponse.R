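test_that("response labels apply the +/- 0.5 SD rule with inclusive boundaries", {
  # constructed so z-scores are exactly (-1.118, -0.5, +0.5, +1.118)
  a <- sqrt(5)
  gi50 <- setNames(c(-a, -1, 1, a), c("l1", "l2", "l3", "l4"))
  resp <- label_response(gi50)
  expect_equal(resp$table$z, c(-a / 2, -0.5, 0.5, a / 2))
  expect_identical(as.character(resp$table$label),
                   c("sensitive", "sensitive", "resistant", "resistant"))
  # z = 0 is intermediate
  resp2 <- label_response(setNames(c(-1, 0, 1), c("a", "b", "c")))
  expect_identical(as.character(resp2$table$label[2]), "intermediate")
  # z-scores are standardized and labels partition the panel
  set.seed(4)
  gi <- setNames(c(rnorm(20), NA, NA), sprintf("x%02d", 1:22))
  r3 <- label_response(gi)
  expect_equal(mean(r3$table$z), 0, tolerance = 1e-9)
  expect_equal(sd(r3$table$z), 1, tolerance = 1e-9)
  expect_identical(nrow(r3$table) + length(r3$missing_ids), 22L)
  expect_error(label_response(setNames(rep(1, 5), letters[1:5])), "zero SD")
})

test_that("report metrics reproduce the published count arithmetic", {
  # counts 11/12 and 20/21: sensitivity 92%, specificity 95%, overall 94%
  g <- chemo_metrics(11, 12, 20, 21)
  expect_equal(round(100 * g$sensitivity), 92)
  expect_equal(round(100 * g$specificity), 95)
  expect_equal(round(100 * g$accuracy), 94)
  # counts 19/25: sensitivity 76%
  expect_equal(round(100 * chemo_metrics(19, 25, 16, 20)$sensitivity), 76)
  # counts 13/15: specificity 87%
  expect_equal(round(100 * chemo_metrics(8, 11, 13, 15)$specificity), 87)
})

test_that("LOOCV classification is consistent and aces a separable panel", {
  p <- simulate_panel(panel_spec(response_effect = 3, seed = 2))
  resp <- label_response(p$gi50)
  rep <- classify_chemo(p$expr[p$truth$signature_genes, ], resp)
  expect_equal(rep$accuracy, 1)
  # metrics recompute from the report's own counts
  expect_equal(rep$sensitivity,
               unname(rep$counts["resistant_correct"] / rep$counts["resistant_total"]))
  expect_equal(rep$accuracy,
               unname((rep$counts["resistant_correct"] + rep$counts["sensitive_correct"]) /
                        (rep$counts["resistant_total"] + rep$counts["sensitive_total"])))
  # intermediate lines are excluded from the report
  expect_equal(unname(rep$counts["resistant_total"] + rep$counts["sensitive_total"]),
               sum(resp$table$label != "intermediate"))
})

test_that("a pluggable classifier function is honoured", {
  p <- simulate_panel(panel_spec(n_lines = 20, n_genes = 50, seed = 3))
  resp <- label_response(p$gi50)
  always_resistant <- function(train_x, train_y, test_x, k) "resistant"
  rep <- classify_chemo(p$expr[p$truth$signature_genes, ], resp,
                        classifier = always_resistant)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 0)
})

test_that("permutation p-value respects its attainable bounds", {
  p <- simulate_panel(panel_spec(n_lines = 24, n_genes = 120, n_signature = 6,
                                 response_effect = 3, seed = 5))
  resp <- label_response(p$gi50)
  obs <- classify_chemo(p$expr[p$truth$signature_genes, ], resp)$accuracy
  ps <- permutation_significance(obs, p$expr, resp, signature_size = 6,
                                 exclude = p$truth$signature_genes,
                                 n_random = 100, seed = 5)
  expect_gte(ps$p, 1 / 101)
  expect_lte(ps$p, 1)
  # an unbeatable observed accuracy attains the floor 1/(n_random + 1)
  ps_floor <- permutation_significance(1.01, p$expr, resp, 6,
                                       n_random = 100, seed = 6)
  expect_equal(ps_floor$p, 1 / 101)
  # an accuracy below chance is never significant
  ps_worst <- permutation_significance(0, p$expr, resp, 6,
                                       n_random = 100, seed = 7)
  expect_equal(ps_worst$p, 1)
})

test_that("resistant-vs-sensitive screening flags planted response genes", {
  p <- simulate_panel(panel_spec(n_lines = 40, n_genes = 60, n_signature = 5,
                                 response_effect = 2, seed = 11))
  resp <- label_response(p$gi50)
  de <- resistant_vs_sensitive_de(p$expr, resp)
  planted <- de[de$probe_id %in% p$truth$signature_genes, ]
  # resistant lines over-express the signature genes
  expect_true(all(planted$fold_change > 1))
  expect_gte(sum(planted$significant), 4)
  # mirrored groups: fold change 1, unflagged, not significant
  gi <- setNames(c(-2, -1.9, 1.9, 2), c("l1", "l2", "l3", "l4"))
  resp2 <- label_response(gi)
  m <- make_expr(rbind(c(3, 4, 3, 4), c(10, 20, 20, 10)),
                 sample_ids = names(gi))
  de2 <- resistant_vs_sensitive_de(m, resp2)
  expect_equal(de2$fold_change, c(1, 1))
  expect_identical(de2$flag, c("none", "none"))
  expect_false(any(de2$significant))
})
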