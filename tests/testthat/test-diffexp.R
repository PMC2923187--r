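test_that("Welch t-test matches the closed-form toy example", {
  m <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1))
  lab <- make_labels(3, 3)
  colnames(m) <- names(lab)
  tt <- de_ttest(m, lab, "different_variance")
  # oracle: |t| = 3 / sqrt(1/3 + 1/3), df = 4 by direct formula evaluation
  expect_equal(abs(tt$t), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4, tolerance = 1e-9)
  expect_equal(tt$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
})

test_that("degenerate genes and equal groups are flagged, not errors", {
  m <- make_expr(rbind(c(5, 5, 5, 5, 5, 5), c(1, 2, 3, 1, 2, 3)))
  lab <- make_labels(3, 3)
  colnames(m) <- names(lab)
  for (v in c("different_variance", "pooled")) {
    tt <- de_ttest(m, lab, v)
    expect_equal(tt$t[1], 0)
    expect_equal(tt$p[1], 1)
    expect_true(tt$zero_variance[1])
    expect_equal(tt$t[2], 0)     # identical groups: zero difference
    expect_equal(tt$p[2], 1)
  }
  expect_error(de_ttest(m, make_labels(1, 5, classes = levels(lab))), "at least 2")
})

test_that("t-test results are equivariant under gene reordering", {
  set.seed(3)
  m <- make_expr(matrix(rexp(80, 0.1), nrow = 8))
  lab <- make_labels(5, 5)
  colnames(m) <- names(lab)
  tt <- de_ttest(m, lab)
  perm <- sample(nrow(m))
  tt_perm <- de_ttest(m[perm, ], lab)
  expect_equal(tt_perm$t, tt$t[perm])
  expect_equal(tt_perm$p, tt$p[perm])
})

test_that("SAM with s0 = 0 reduces exactly to the pooled t-statistic", {
  set.seed(11)
  for (i in 1:5) {
    m <- make_expr(matrix(rgamma(50 * 12, 2, 0.02), nrow = 50))
    lab <- make_labels(6, 6)
    colnames(m) <- names(lab)
    sam <- sam_test(m, lab, n_perm = 25, s0 = 0, seed = i)
    tt <- de_ttest(m, lab, "pooled")
    expect_equal(unname(sam$d), tt$t, tolerance = 1e-10)
  }
})

test_that("SAM significant set shrinks as delta grows and empties at the max", {
  set.seed(12)
  m <- make_expr(matrix(rnorm(100 * 16, 100, 20), nrow = 100))
  m[1:10, 9:16] <- m[1:10, 9:16] + 40
  lab <- make_labels(8, 8)
  colnames(m) <- names(lab)
  sam <- sam_test(m, lab, n_perm = 50, seed = 4)
  deltas <- seq(0, 2, length.out = 10)
  sizes <- vapply(deltas, function(d) sam_significant(sam, d)$n_sig, integer(1))
  expect_true(all(diff(sizes) <= 0))
  dmax <- max(abs(sam$d_sorted - sam$d_bar))
  expect_identical(sam_significant(sam, dmax + 1e-9)$n_sig, 0L)
  expect_error(sam_test(m, lab, n_perm = 10), "at least 25")
})

test_that("delta selection agrees with a linear-scan oracle and errors when unreachable", {
  set.seed(13)
  m <- make_expr(matrix(rnorm(200 * 20, 500, 100), nrow = 200))
  m[1:15, 11:20] <- m[1:15, 11:20] + 150
  lab <- make_labels(10, 10)
  colnames(m) <- names(lab)
  sam <- sam_test(m, lab, n_perm = 60, seed = 7)
  chosen <- select_delta(sam, 0.25)
  # oracle: scan the same grid linearly with the single-delta routine
  grid <- sort(unique(c(0, abs(sam$d_sorted - sam$d_bar))))
  oracle <- NULL
  for (d in grid) {
    s <- sam_significant(sam, d)
    if (s$n_sig > 0 && !is.na(s$fdr) && s$fdr <= 0.25) { oracle <- s; break }
  }
  expect_equal(chosen$delta, oracle$delta)
  expect_identical(chosen$significant, oracle$significant)

  big <- select_delta(sam, 0.99)
  expect_gt(big$n_sig, 0)

  # unreachable target: a null where every permutation mirrors the observed
  # statistics keeps the FDR estimate at 1 for every delta
  d <- setNames(c(-2, -1, 0, 1, 2), sprintf("n%d", 1:5))
  fake <- structure(list(d = d, order = order(d), d_sorted = sort(d),
                         d_bar = rep(0, 5),
                         d_perm = matrix(rep(d, 30), nrow = 5),
                         s0 = 1, n_perm = 30L, n1 = 3L, n2 = 3L, pi0 = 1),
                    class = "sam_result")
  expect_error(select_delta(fake, 0.5), "minimum achievable")
})

test_that("null data yields an essentially empty SAM call set at FDR 25%", {
  sim <- simulate_cohort(cohort_spec(n_samples = 60, n_genes = 500,
                                     n_informative = 0, effect_size = 0,
                                     seed = 31))
  sam <- sam_test(sim$expr, sim$truth$class, n_perm = 100, seed = 31)
  n_called <- tryCatch(select_delta(sam, 0.25)$n_sig, error = function(e) 0L)
  expect_lt(n_called, 0.05 * 500)
})

test_that("candidate intersection is an ordered subset of both screens", {
  set.seed(14)
  m <- make_expr(matrix(rnorm(100 * 20, 300, 60), nrow = 100))
  m[1:12, 11:20] <- m[1:12, 11:20] + 90
  lab <- make_labels(10, 10)
  colnames(m) <- names(lab)
  tt <- de_ttest(m, lab)
  sam <- sam_test(m, lab, n_perm = 50, seed = 5)
  dl <- select_delta(sam, 0.25)
  cand <- intersect_candidates(tt, sam, 0.01, delta = dl$delta)
  expect_true(all(cand %in% tt$probe_id[tt$p < 0.01]))
  expect_true(all(cand %in% dl$significant))
  expect_identical(cand, rownames(m)[rownames(m) %in% cand])  # order preserved

  sam2 <- sam_test(m[1:50, ], make_labels(10, 10), n_perm = 25, seed = 1)
  expect_error(intersect_candidates(tt, sam2, 0.01, delta = 0.1), "universe")
})

test_that("fold change flags follow the 1.5 / 0.67 thresholds", {
  m <- make_expr(rbind(c(150, 150, 100, 100), c(100, 100, 150, 150),
                       c(120, 120, 120, 120)))
  grp <- make_labels(2, 2, classes = c("resistant", "sensitive"))
  colnames(m) <- names(grp)
  fc <- group_fold_change(m, grp)
  expect_equal(fc$fold_change, c(1.5, 100 / 150, 1))
  expect_identical(fc$flag, c("over", "under", "none"))
  # same membership with the numerator group swapped: reciprocal fold changes
  grp_swap <- factor(as.character(grp), levels = rev(levels(grp)))
  names(grp_swap) <- names(grp)
  fc_swap <- group_fold_change(m, grp_swap)
  expect_equal(fc_swap$fold_change, 1 / fc$fold_change)
})

test_that("ddCt fold change follows the 2^-ddCt closed form", {
  grp <- factor(c("ctrl", "ctrl", "tum", "tum"))
  # dCt: ctrl = {5, 5}; tum = {4, 4} -> ddCt(tum) = -1 -> FC = 2
  fc <- ddct_fold_change(ct_target = c(25, 25, 24, 24),
                         ct_reference = c(20, 20, 20, 20),
                         group = grp, calibrator = "ctrl")
  expect_equal(unname(fc["ctrl"]), 1)
  expect_equal(unname(fc["tum"]), 2)
  # ddCt = +1 halves, -2 quadruples
  fc2 <- ddct_fold_change(c(25, 26), c(20, 20), factor(c("a", "b")), "a")
  expect_equal(unname(fc2["b"]), 0.5)
  fc3 <- ddct_fold_change(c(25, 23), c(20, 20), factor(c("a", "b")), "a")
  expect_equal(unname(fc3["b"]), 4)
  expect_error(ddct_fold_change(c(25, 25), c(20, NA), factor(c("a", "b")), "a"),
               "reference")
})
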