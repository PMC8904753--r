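test_that("mdi_score matches the Welch worked example and oracle", {
  expect_equal(mdi_score(c(0, 2), c(-1, 3)), 1.0)   # equal means
  pos <- c(2, 3, 4); neg <- c(1, 1.5, 0.5)
  expect_equal(mdi_score(pos, neg), 4.0984, tolerance = 1e-4)
  expect_equal(mdi_score(pos, neg),
               1 + unname(t.test(pos, neg)$statistic), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:100) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    m <- mdi_score(a, b)
    expect_equal(m, 1 + unname(t.test(a, b)$statistic), tolerance = 1e-10)
    # swapping sides reflects about 1
    expect_equal(mdi_score(b, a), 2 - m, tolerance = 1e-10)
    # order within sides is irrelevant
    expect_equal(mdi_score(sample(a), sample(b)), m, tolerance = 1e-12)
  }
})

test_that("mdi_score flags undefined cases", {
  expect_true(is.na(mdi_score(1, c(0, 1))))
  expect_true(is.na(mdi_score(c(0, 1), 2)))
  expect_true(is.na(mdi_score(c(1, 1), c(0, 0))))  # zero denominator
  expect_true(is.na(mdi_score(c(1, NA), c(0, 1))))
})

test_that("score_cohort reproduces the training correlation and guards sets", {
  co <- cohort_simpo(n_cases = 60, n_controls = 60, n_genes = 150,
                     n_causal = 20, seed = 41)
  fit <- mdi_fit(co$simpo, co$labels, n_iter = 20, k_min = 10, k_max = 100,
                 seed = 2)
  sc <- predict(fit, co$simpo)
  expect_equal(cor(sc$mdi, co$labels), fit$training_correlation,
               tolerance = 1e-8)
  expect_equal(sc$n_positive_used, rep(length(fit$positive_genes), nrow(sc)))
  # unknown genes are dropped with a warning naming them
  model2 <- fit
  model2$positive_genes <- c(fit$positive_genes, "GHOST")
  expect_warning(score_cohort(co$simpo, model2), "GHOST")
  # missing all negative genes -> error naming the set
  model3 <- fit
  model3$negative_genes <- c("NOPE1", "NOPE2")
  expect_error(suppressWarnings(score_cohort(co$simpo, model3)), "negative")
})

test_that("mdi is invariant to gene order and reflects under global negation", {
  co <- cohort_simpo(n_cases = 40, n_controls = 40, n_genes = 100,
                     n_causal = 10, seed = 19)
  fit <- mdi_fit(co$simpo, co$labels, n_iter = 10, k_min = 10, k_max = 60,
                 seed = 4)
  sc <- score_cohort(co$simpo, fit)
  shuf <- list(positive_genes = sample(fit$positive_genes),
               negative_genes = sample(fit$negative_genes))
  expect_equal(score_cohort(co$simpo, shuf)$mdi, sc$mdi, tolerance = 1e-12)
  # globally negating the matrix reflects the index about 1 and flips the AUC
  sc_neg <- score_cohort(-co$simpo, fit)
  expect_equal(sc_neg$mdi - 1, -(sc$mdi - 1), tolerance = 1e-10)
  expect_equal(roc_auc(sc_neg$mdi, co$labels)$auc,
               1 - roc_auc(sc$mdi, co$labels)$auc, tolerance = 1e-12)
  # swapping the two sets is the same reflection; doing both is the identity
  swapped <- list(positive_genes = fit$negative_genes,
                  negative_genes = fit$positive_genes)
  expect_equal(score_cohort(co$simpo, swapped)$mdi - 1, -(sc$mdi - 1),
               tolerance = 1e-10)
  expect_equal(score_cohort(-co$simpo, swapped)$mdi, sc$mdi,
               tolerance = 1e-10)
})

test_that("sweep picks the k with maximal correlation, smallest on ties", {
  # construct a toy SIMPO matrix where the first 4 ranked genes carry all
  # the signal: r(k) peaks at k = 4 and declines as noise genes dilute it
  set.seed(77)
  n <- 60; labels <- rep(c(1, 0), each = n / 2)
  genes <- sprintf("g%02d", 1:20)
  sm <- matrix(rnorm(20 * n, 0, 1), 20, n, dimnames = list(genes, paste0("S", 1:n)))
  sm[1:2, labels == 1] <- sm[1:2, labels == 1] + 3
  sm[3:4, labels == 1] <- sm[3:4, labels == 1] - 3
  tt <- gene_case_control_t(sm, labels)
  sel <- make_selection(genes, mean_t = tt$t[match(genes, tt$gene)],
                        occurrence = c(rep(10, 4), rep(0, 16)))
  # ranks follow construction order: g01..g04 first
  fit <- sweep_k(sel, sm, labels, k_min = 2, k_max = 20)
  expect_equal(fit$k, which.max(fit$curve$r) + 1)
  # k < 4 leaves one side below two genes (undefined); the peak sits at or
  # just past the four signal genes
  expect_gte(fit$k, 4)
  expect_lte(fit$k, 8)
  expect_true(all(is.na(fit$curve$r[fit$curve$k < 4])))
  expect_equal(fit$curve$k, 2:20)
  expect_setequal(c(fit$positive_genes, fit$negative_genes),
                  genes[seq_len(fit$k)])
})

test_that("per-k scores agree with direct cohort scoring", {
  co <- cohort_simpo(n_cases = 30, n_controls = 30, n_genes = 80,
                     n_causal = 10, missing_rate = 0.05, seed = 55)
  sel <- resample_select(co$simpo, co$labels, n_iter = 10, seed = 6)
  fit <- sweep_k(sel, co$simpo, co$labels, k_min = 10, k_max = 60)
  for (k in c(10, 25, 60)) {
    sets <- partition_signs(sel, k)
    if (length(sets$positive) < 2 || length(sets$negative) < 2) next
    direct <- score_cohort(co$simpo, list(positive_genes = sets$positive,
                                          negative_genes = sets$negative))
    r_direct <- suppressWarnings(cor(direct$mdi, co$labels,
                                     use = "complete.obs"))
    expect_equal(fit$curve$r[fit$curve$k == k], r_direct, tolerance = 1e-8)
  }
})

test_that("the chosen k tracks the causal gene count and the curve drops after", {
  co <- cohort_simpo(n_cases = 100, n_controls = 100, n_genes = 200,
                     n_causal = 60, effect_size = 0.8, seed = 61)
  fit <- mdi_fit(co$simpo, co$labels, n_iter = 30, k_min = 10, k_max = 150,
                 seed = 9)
  expect_gte(fit$k, 48)
  expect_lte(fit$k, 72)
  tail_r <- mean(fit$curve$r[fit$curve$k >= 120])
  expect_gt(fit$training_correlation, tail_r)
})

test_that("mDI model JSON round-trips and rescoring matches", {
  co <- cohort_simpo(n_cases = 30, n_controls = 30, n_genes = 80,
                     n_causal = 10, seed = 3)
  fit <- mdi_fit(co$simpo, co$labels, n_iter = 10, k_min = 10, k_max = 50,
                 seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_mdi_model(fit, f)
  back <- read_mdi_model(f)
  expect_equal(back$positive_genes, fit$positive_genes)
  expect_equal(back$negative_genes, fit$negative_genes)
  expect_equal(back$k, fit$k)
  expect_equal(score_cohort(co$simpo, back)$mdi,
               score_cohort(co$simpo, fit)$mdi)
})
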