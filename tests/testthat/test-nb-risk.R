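test_that("training recovers ML priors and per-class Gaussian parameters", {
  # class sizes 104 / 125 give priors rounding to 0.45 / 0.55
  lab <- make_labels(104, 125)
  set.seed(6)
  m <- make_expr(matrix(rnorm(229, 50, 5), nrow = 1))
  colnames(m) <- names(lab)
  model <- train_nb(m, lab)
  expect_equal(model$priors, c(104, 125) / 229)
  expect_equal(round(model$priors, 2), c(0.45, 0.55))

  # parameter recovery: known Gaussians, n = 500 per class
  set.seed(7)
  x <- cbind(matrix(rnorm(500, 100, 10), 1), matrix(rnorm(500, 130, 20), 1))
  m2 <- make_expr(x)
  lab2 <- make_labels(500, 500)
  colnames(m2) <- names(lab2)
  fit <- train_nb(m2, lab2)
  expect_lt(abs(fit$mean[1, 1] - 100), 3 * 10 / sqrt(500))
  expect_lt(abs(fit$mean[1, 2] - 130), 3 * 20 / sqrt(500))
  expect_lt(abs(fit$sd[1, 1] / 10 - 1), 0.05)
  expect_lt(abs(fit$sd[1, 2] / 20 - 1), 0.05)
})

test_that("a constant gene within a class is floored, not degenerate", {
  m <- make_expr(rbind(c(5, 5, 5, 8, 9, 10)))
  lab <- make_labels(3, 3)
  colnames(m) <- names(lab)
  model <- train_nb(m, lab)
  expect_true(all(model$sd > 0))
  expect_true(is.finite(nb_posterior(model, m)[1]))
})

test_that("posteriors normalize, are symmetric at the midpoint, and ignore gene order", {
  model <- structure(list(
    classes = c("low_risk", "high_risk"), priors = c(0.5, 0.5),
    mean = matrix(c(10, 100, 20, 120), 2,
                  dimnames = list(c("gA", "gB"), c("low_risk", "high_risk"))),
    sd = matrix(c(3, 12, 3, 12), 2,
                dimnames = list(c("gA", "gB"), c("low_risk", "high_risk"))),
    genes = c("gA", "gB"), sigma_floor = c(gA = 0, gB = 0)), class = "nb_model")
  # classes mirrored about the midpoint with equal priors -> posterior 1/2
  expect_equal(as.numeric(nb_posterior(model, c(gA = 15, gB = 110))), 0.5,
               tolerance = 1e-12)
  x <- c(gA = 12, gB = 118)
  expect_equal(nb_posterior(model, x), nb_posterior(model, x[c("gB", "gA")]),
               tolerance = 1e-12)
  expect_error(nb_posterior(model, c(gA = 12)), "gB")
})

test_that("log-domain posterior equals brute-force Bayes evaluation", {
  set.seed(15)
  for (i in 1:200) {
    g <- sample(1:3, 1)
    genes <- sprintf("g%d", seq_len(g))
    pri <- runif(1, 0.05, 0.95)
    mu <- matrix(runif(2 * g, -50, 50), g, dimnames = list(genes, NULL))
    sdm <- matrix(runif(2 * g, 0.5, 30), g, dimnames = list(genes, NULL))
    model <- structure(list(classes = c("c1", "c2"), priors = c(pri, 1 - pri),
                            mean = mu, sd = sdm, genes = genes,
                            sigma_floor = setNames(numeric(g), genes)),
                       class = "nb_model")
    x <- setNames(rnorm(g, 0, 40), genes)
    expect_equal(as.numeric(nb_posterior(model, x)),
                 nb_posterior_bruteforce(model$priors, mu, sdm, x),
                 tolerance = 1e-10)
  }
})

test_that("the decision rule sends a posterior of exactly 0.5 to low risk", {
  sc <- structure(c(0.5, 0.51, 0), classes = c("low_risk", "high_risk"))
  expect_identical(as.character(classify_risk(sc)),
                   c("low_risk", "high_risk", "low_risk"))
  expect_error(classify_risk(sc, threshold = 1.5), "threshold")
})

test_that("the bundled published 12-gene model loads with its printed parameters", {
  model <- load_published_model()
  expect_length(model$genes, 12)
  expect_true("212041_at" %in% model$genes)
  expect_identical(unname(model$symbols["212041_at"]), "ATP6V0D1")
  expect_equal(model$priors, c(0.45, 0.55))
  # PKLR probe parameters, low-risk class
  expect_equal(unname(model$mean["222078_at", "low_risk"]), 14.3474)
  expect_equal(unname(model$sd["222078_at", "low_risk"]), 6.872)
  # at the vector of low-risk class means the high-risk posterior is < 0.5,
  # and it agrees with direct density-product evaluation
  x <- setNames(model$mean[, "low_risk"], model$genes)
  post <- as.numeric(nb_posterior(model, x))
  expect_lt(post, 0.5)
  expect_equal(post, nb_posterior_bruteforce(model$priors, model$mean,
                                             model$sd, x),
               tolerance = 1e-10)
})

test_that("training and scoring agree with an independent Naive Bayes implementation", {
  set.seed(60)
  lab <- make_labels(30, 40)
  m <- make_expr(matrix(rnorm(4 * 70, 300, 60), nrow = 4))
  colnames(m) <- names(lab)
  model <- train_nb(m, lab)
  ref <- e1071::naiveBayes(x = as.data.frame(t(m)), y = lab)
  # same per-class Gaussian parameters ...
  for (g in rownames(m)) {
    expect_equal(unname(model$mean[g, ]), unname(ref$tables[[g]][, 1]))
    expect_equal(unname(model$sd[g, ]), unname(ref$tables[[g]][, 2]),
                 tolerance = 1e-9)
  }
  # ... and the same posteriors on new samples
  post_ref <- predict(ref, as.data.frame(t(m)), type = "raw")[, "high_risk"]
  expect_equal(as.numeric(nb_posterior(model, m)), unname(post_ref),
               tolerance = 1e-6)
})

test_that("model serialization round-trips through the parameter table", {
  lab <- make_labels(10, 12)
  set.seed(30)
  m <- make_expr(matrix(rnorm(3 * 22, 200, 40), nrow = 3))
  colnames(m) <- names(lab)
  model <- train_nb(m, lab)
  f <- tempfile(fileext = ".tsv")
  write_nb_model(model, f)
  back <- read_nb_model(f)
  expect_equal(back$priors, model$priors)
  expect_equal(back$mean, model$mean)
  expect_equal(back$sd, model$sd, tolerance = 1e-9)
  sc1 <- nb_posterior(model, m)
  sc2 <- nb_posterior(back, m)
  expect_equal(sc1, sc2, tolerance = 1e-8)
})

test_that("calibration curve hits the degenerate limits and tracks risk", {
  # one occupied bin, everyone dies before the horizon
  cl <- make_clinical(time = c(10, 20, 30), event = c(1, 1, 1))
  sc <- setNames(c(0.62, 0.63, 0.64), cl$sample_id)
  cc <- calibration_curve(sc, cl, horizon_months = 60)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$death_prob, 1)
  # no events anywhere
  cl2 <- make_clinical(time = c(70, 80, 90), event = c(0, 0, 0))
  sc2 <- setNames(c(0.2, 0.22, 0.24), cl2$sample_id)
  cc2 <- calibration_curve(sc2, cl2, horizon_months = 60)
  expect_true(all(cc2$death_prob == 0))
  # synthetic cohort scored by a model trained on the truth: monotone curve
  sim <- simulate_cohort(cohort_spec(n_samples = 400, n_genes = 30,
                                     n_informative = 10, seed = 44))
  lab <- dichotomize(sim$clinical)
  model <- train_nb(sim$expr[sim$truth$informative_genes, ], lab)
  sim2 <- simulate_cohort(cohort_spec(n_samples = 400, n_genes = 30,
                                      n_informative = 10, seed = 45))
  sc3 <- nb_posterior(model, sim2$expr)
  cc3 <- calibration_curve(sc3, sim2$clinical, bin_width = 0.2, min_n = 10)
  occ <- cc3[cc3$stable, ]
  expect_gt(cor(occ$bin_mid, occ$death_prob, method = "spearman"), 0.8)
})

test_that("end-to-end risk model transfers across independent cohorts", {
  ps <- vapply(1:20, function(s) {
    sim <- simulate_cohort(cohort_spec(n_genes = 50, seed = s))
    lab <- dichotomize(sim$clinical)
    model <- train_nb(sim$expr[sim$truth$informative_genes, ], lab)
    sim2 <- simulate_cohort(cohort_spec(n_genes = 50, seed = s + 5000))
    sc <- score_cohort(model, sim2$expr, sim2$clinical)
    if (is.null(sc$logrank)) 1 else sc$logrank$p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.95)
})
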