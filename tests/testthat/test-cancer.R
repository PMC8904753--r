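make_design <- function(n, beta = NULL, seed = 1) {
  # direct z-scored design with independent predictors; y from a logit model
  set.seed(seed)
  preds <- c("mdi", "mono", "gran", "lympho", "cd4_cd8", "nlr", "mlr")
  X <- as.data.frame(lapply(stats::setNames(preds, preds),
                            function(nm) as.numeric(scale(rnorm(n)))))
  eta <- rep(qlogis(0.4), n)
  if (!is.null(beta)) for (tm in names(beta)) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    eta <- eta + beta[[tm]] * Reduce(`*`, X[parts])
  }
  cbind(data.frame(sample_id = sprintf("P%04d", 1:n),
                   y = rbinom(n, 1, plogis(eta))), X)
}

test_that("z_transform centres, scales and is idempotent", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(40, 5, 3)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 5)), "zero standard deviation")
  expect_error(z_transform(1), ">= 2")
})

test_that("risk design derives ratios and z-scores every column", {
  set.seed(6)
  n <- 50
  ph <- data.frame(sample_id = sprintf("P%04d", 1:n),
                   label = rbinom(n, 1, 0.4),
                   mono = runif(n, 0.05, 0.15), gran = runif(n, 0.4, 0.7),
                   lympho = runif(n, 0.2, 0.4), cd4 = runif(n, 0.1, 0.2),
                   cd8 = runif(n, 0.05, 0.15))
  sc <- data.frame(sample_id = ph$sample_id, mdi = rnorm(n, 1))
  d <- build_risk_design(ph, sc)
  for (cl in c("mdi", "mono", "gran", "lympho", "cd4_cd8", "nlr", "mlr")) {
    expect_equal(mean(d[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(d[[cl]]), 1, tolerance = 1e-9)
  }
  expect_equal(cor(d$cd4_cd8, ph$cd4 / ph$cd8), 1, tolerance = 1e-12)
  expect_error(build_risk_design(ph, sc[-1, ]), "missing")
})

test_that("per-year cohorts are cumulative and skip thin years", {
  ph <- data.frame(sample_id = sprintf("P%03d", 1:60),
                   label = rep(c(1L, 0L), c(20, 40)),
                   diagnosis_year = c(rep(5L, 20), rep(NA, 40)))
  w <- capture_warnings(ch <- build_per_year_cohorts(ph, year_min = 3))
  expect_true(all(grepl("skipped", w)))
  expect_equal(names(ch), "5")
  expect_length(ch[["5"]]$case_ids, 20)
  expect_length(ch[["5"]]$control_ids, 40)
  ph2 <- ph
  ph2$diagnosis_year[1:20] <- rep(3:7, each = 4)
  ch2 <- build_per_year_cohorts(ph2, year_min = 3, min_cases = 4)
  counts <- vapply(ch2, function(e) length(e$case_ids), 0L)
  expect_equal(unname(counts), c(4L, 8L, 12L, 16L, 20L))
  expect_true(all(diff(counts) >= 0))
})

test_that("stepwise selects a strong single predictor and nothing spurious dominates", {
  d <- make_design(600, beta = list(mdi = 1.5), seed = 10)
  fit <- stepwise_logistic(d, cv_folds = 0)
  expect_true("mdi" %in% fit$terms)
  expect_gt(fit$coefficients$estimate[fit$coefficients$term == "mdi"], 1.0)
  expect_gt(fit$auc, 0.7)
})

test_that("stepwise is invariant to candidate order and matches a single LR test", {
  d <- make_design(300, beta = list(mdi = 0.8), seed = 21)
  f1 <- stepwise_logistic(d, cv_folds = 0)
  set.seed(5)
  f2 <- stepwise_logistic(d, cv_folds = 0,
                          candidates = sample(methdex:::default_candidates()))
  expect_identical(f1$terms, f2$terms)
  expect_equal(f1$coefficients, f2$coefficients)
  # single candidate: selection = one likelihood-ratio test at p_enter
  g0 <- glm(y ~ 1, binomial, data = d)
  g1 <- glm(y ~ mdi, binomial, data = d)
  p <- pchisq(deviance(g0) - deviance(g1), 1, lower.tail = FALSE)
  fit1 <- stepwise_logistic(d, candidates = "mdi", cv_folds = 0)
  expect_identical(length(fit1$terms) == 1, p < 0.05)
  expect_equal(fit1$coefficients$estimate[2], unname(coef(g1)[2]),
               tolerance = 1e-6)
})

test_that("interaction entry pulls in and protects its parents", {
  d <- make_design(700, beta = list("mdi:cd4_cd8" = 1.2), seed = 33)
  fit <- stepwise_logistic(d, cv_folds = 0)
  expect_true("mdi:cd4_cd8" %in% fit$terms)
  expect_true(all(c("mdi", "cd4_cd8") %in% fit$terms))
})

test_that("z-scoring is an affine reparameterization of the plain fit", {
  set.seed(55)
  n <- 400
  raw <- data.frame(a = rnorm(n, 5, 2), b = rnorm(n, -1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * scale(raw$a) + 0.6 * scale(raw$b)))
  fr <- glm(y ~ a + b, binomial, data = raw)
  fz <- glm(y ~ az + bz, binomial,
            data = data.frame(az = z_transform(raw$a), bz = z_transform(raw$b)))
  expect_equal(unname(coef(fz)[2]), unname(coef(fr)[2]) * sd(raw$a),
               tolerance = 1e-6)
  expect_equal(unname(coef(fz)[3]), unname(coef(fr)[3]) * sd(raw$b),
               tolerance = 1e-6)
})

test_that("r2_contribution quantifies a predictor block", {
  d <- make_design(600, beta = list(mdi = 1.2), seed = 8)
  rc <- r2_contribution(d, full_terms = c("mdi", "mono"),
                        reduced_terms = "mono")
  expect_gt(rc$r2_full, rc$r2_reduced)
  expect_lt(rc$p, 0.05)
  same <- r2_contribution(d, c("mdi", "mono"), c("mdi", "mono"))
  expect_equal(same$r2_full, same$r2_reduced)
  expect_equal(same$p, 1)
  expect_error(r2_contribution(d, "mdi", "gran"), "subset")
})

test_that("random forest ranks a deterministic driver first", {
  d <- make_design(240, seed = 71)
  d$y <- as.integer(d$mdi > median(d$mdi))
  rf <- rf_model(d, n_trees = 150, seed = 2, n_perm = 5)
  expect_gt(rf$cv_auc, 0.95)
  expect_equal(rf$importance$predictor[which.max(rf$importance$importance)],
               "mdi")
  # label-shuffled response: no signal
  set.seed(3)
  d$y <- sample(d$y)
  rf0 <- rf_model(d, n_trees = 150, seed = 2, n_perm = 3)
  expect_gt(rf0$cv_auc, 0.35)
  expect_lt(rf0$cv_auc, 0.65)
  expect_error(rf_model(d[1:30, ], n_trees = 50, seed = 1), ">= 20")
})

test_that("the per-year wrapper produces coherent fits on a simulated cohort", {
  set.seed(91)
  sc <- data.frame(sample_id = sprintf("P%04d", 1:659), mdi = rnorm(659, 1, 1))
  ph <- simulate_cancer_cohort(sc, seed = 14)
  cr <- fit_cancer_risk(ph, sc, seed = 7, n_trees = 100, cv_folds = 0)
  expect_s3_class(cr, "cancer_risk_model")
  years <- vapply(cr$per_year, function(e) e$year, 0)
  expect_true(all(diff(vapply(cr$per_year, function(e) e$n_cases, 0)) >= 0))
  last <- cr$per_year[[length(cr$per_year)]]
  expect_true("mdi" %in% last$fit$terms)
  expect_lt(cr$mdi_contribution$p, 0.05)
  expect_gt(cr$rf$cv_auc, 0.5)
  expect_output(print(cr), "Per-year")
})
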