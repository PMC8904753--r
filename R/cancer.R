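# The seven candidate main effects of the risk design.
RISK_PREDICTORS <- c("mdi", "mono", "gran", "lympho", "cd4_cd8", "nlr", "mlr")

#' z-transform a numeric column
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator),
#' so the result has mean 0 and SD 1.
#'
#' @param values Numeric vector, length >= 2, non-zero SD.
#' @return z-scored vector.
#' @export
z_transform <- function(values) {
  if (length(values) < 2) stop("need >= 2 values to z-transform")
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("zero standard deviation: cannot z-transform")
  (values - mean(values)) / s
}

#' Assemble the z-scored risk design for a modelling subset
#'
#' Joins per-sample index scores with the phenotype's blood cell
#' proportions, derives the CD4/CD8 ratio, the granulocyte-to-lymphocyte
#' ratio (NLR) and the monocyte-to-lymphocyte ratio (MLR), and z-scores all
#' seven predictors over the given subset (each modelling subset is scaled
#' on its own mean/SD).
#'
#' @param pheno Phenotype data.frame with \code{sample_id}, \code{label} and
#'   cell-proportion columns \code{mono}, \code{gran}, \code{lympho},
#'   \code{cd4}, \code{cd8}.
#' @param scores data.frame with \code{sample_id} and \code{mdi} (as returned
#'   by [score_cohort()]), or a named numeric vector of index values.
#' @return data.frame with \code{sample_id}, response \code{y} and the seven
#'   z-scored predictor columns.
#' @export
build_risk_design <- function(pheno, scores) {
  if (is.numeric(scores)) scores <- data.frame(sample_id = names(scores), mdi = scores)
  i <- match(pheno$sample_id, scores$sample_id)
  if (anyNA(i)) stop("scores missing for sample(s): ",
                     paste(utils::head(pheno$sample_id[is.na(i)], 3), collapse = ", "))
  raw <- data.frame(
    mdi = scores$mdi[i],
    mono = pheno$mono, gran = pheno$gran, lympho = pheno$lympho,
    cd4_cd8 = pheno$cd4 / pheno$cd8,
    nlr = pheno$gran / pheno$lympho,
    mlr = pheno$mono / pheno$lympho)
  if (anyNA(raw)) stop("missing predictor values in the modelling subset")
  z <- as.data.frame(lapply(raw, z_transform))
  cbind(data.frame(sample_id = pheno$sample_id, y = pheno$label), z)
}

#' Cumulative per-year case/control cohorts
#'
#' For each follow-up year y >= \code{year_min}, the cases are the samples
#' diagnosed by year y (diagnosis_year <= y) and the controls are the
#' samples never diagnosed through the final follow-up. Years with fewer
#' than \code{min_cases} cases are skipped with a warning.
#'
#' @param pheno Phenotype data.frame with a \code{diagnosis_year} column
#'   (NA = cancer-free through follow-up).
#' @param year_min First modelling year (default 3).
#' @param min_cases Minimum cases per modelled year (default 10).
#' @return Named list of \code{list(year, case_ids, control_ids)}.
#' @export
build_per_year_cohorts <- function(pheno, year_min = 3, min_cases = 10) {
  dy <- pheno$diagnosis_year
  if (all(is.na(dy))) stop("no diagnosed sample in phenotype")
  controls <- pheno$sample_id[is.na(dy)]
  years <- year_min:max(dy, na.rm = TRUE)
  out <- list()
  for (y in years) {
    cases <- pheno$sample_id[!is.na(dy) & dy <= y]
    if (length(cases) < min_cases) {
      warning("year ", y, ": only ", length(cases), " case(s); skipped")
      next
    }
    out[[as.character(y)]] <- list(year = y, case_ids = cases,
                                   control_ids = controls)
  }
  out
}

# ---- stepwise logistic machinery -------------------------------------------

interaction_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
is_interaction <- function(term) grepl(":", term, fixed = TRUE)

default_candidates <- function(predictors = RISK_PREDICTORS) {
  pairs <- utils::combn(predictors, 2, FUN = function(p) paste(p, collapse = ":"))
  c(predictors, pairs)
}

term_matrix <- function(design, terms) {
  if (length(terms) == 0)
    return(matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)")))
  cols <- lapply(terms, function(tm) {
    parts <- interaction_parents(tm)
    Reduce(`*`, design[parts])
  })
  m <- cbind(1, do.call(cbind, lapply(cols, as.numeric)))
  colnames(m) <- c("(Intercept)", terms)
  m
}

logistic_fit <- function(X, y) {
  suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
}

# Ridge-penalized IRLS (penalty on non-intercept terms); used when the
# unpenalized fit shows signs of separation.
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 50) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  b <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / W
    XtW <- t(X * W)
    b_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(b_new - b)) < 1e-10) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  W <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(t(X * W) %*% X + pen)
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coefficients = stats::setNames(b, colnames(X)),
       se = sqrt(diag(cov)), fitted = mu, deviance = dev)
}

#' Bidirectional p-value-guided stepwise logistic regression
#'
#' Emulates classical stepwise GLM construction on a binomial model with
#' logit link: starting from the intercept-only model, the candidate term
#' with the smallest deviance (likelihood-ratio) test p-value enters while
#' that p-value is below \code{p_enter}; after each entry, included terms
#' whose drop-one deviance p-value exceeds \code{p_remove} are removed,
#' worst first. When an interaction term enters, any absent parent main
#' effect is brought in with it and parents of included interactions are
#' protected from removal — so a main effect can sit in the final table with
#' a large p-value purely in support of its interaction. Candidates are
#' examined in lexicographic term order, making the procedure deterministic
#' and invariant to the order in which candidates are supplied.
#'
#' @param design data.frame from [build_risk_design()] (response \code{y}
#'   plus z-scored predictor columns).
#' @param p_enter Entry threshold on the deviance-test p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @param candidates Character vector of candidate terms; default the seven
#'   main effects plus all 21 pairwise interactions (\code{"a:b"} denotes a
#'   product of z-scored columns).
#' @param cv_folds Stratified folds for the cross-validated AUC (default 5);
#'   0 disables.
#' @param seed Seed for the CV fold assignment.
#' @return Object of class \code{stepwise_glm}: \code{$terms},
#'   \code{$coefficients} (term, estimate, se, tstat, p), \code{$auc},
#'   \code{$cv_auc}, \code{$pseudo_r2} (McFadden), \code{$separation} flag,
#'   \code{$fitted}.
#' @export
stepwise_logistic <- function(design, p_enter = 0.05, p_remove = 0.10,
                              candidates = NULL, cv_folds = 5, seed = 1) {
  y <- design$y
  if (is.null(candidates))
    candidates <- default_candidates(intersect(RISK_PREDICTORS, colnames(design)))
  candidates <- sort(unique(candidates))
  deviance_of <- function(terms) {
    logistic_fit(term_matrix(design, terms), y)$deviance
  }
  current <- character(0)
  dev_cur <- deviance_of(current)
  protected <- function(terms) {
    unique(unlist(lapply(terms[vapply(terms, is_interaction, TRUE)],
                         interaction_parents)))
  }
  seen <- character(0)
  repeat {
    state <- paste(sort(current), collapse = "+")
    if (state %in% seen) break
    seen <- c(seen, state)
    changed <- FALSE
    # --- entry ---
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      ps <- vapply(pool, function(tm) {
        d <- deviance_of(c(current, tm))
        stats::pchisq(pmax(dev_cur - d, 0), df = 1, lower.tail = FALSE)
      }, 0.0)
      best <- which.min(ps)   # ties: first in sorted order
      if (ps[best] < p_enter) {
        tm <- pool[best]
        add <- tm
        if (is_interaction(tm))
          add <- c(setdiff(interaction_parents(tm), current), tm)
        current <- c(current, add)
        dev_cur <- deviance_of(current)
        changed <- TRUE
      }
    }
    # --- removal ---
    repeat {
      keep <- protected(current)
      removable <- setdiff(current, keep)
      if (!length(removable)) break
      ps <- vapply(removable, function(tm) {
        d <- deviance_of(setdiff(current, tm))
        stats::pchisq(pmax(d - dev_cur, 0), df = 1, lower.tail = FALSE)
      }, 0.0)
      worst <- which.max(ps)
      if (ps[worst] > p_remove) {
        current <- setdiff(current, removable[worst])
        dev_cur <- deviance_of(current)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  current <- sort(current)
  X <- term_matrix(design, current)
  fit <- logistic_fit(X, y)
  separation <- any(abs(fit$coefficients) > 15, na.rm = TRUE)
  if (separation) {
    rf <- ridge_logistic(X, y)
    est <- rf$coefficients; se <- rf$se; fitted <- rf$fitted; dev <- rf$deviance
  } else {
    est <- fit$coefficients
    cov <- tryCatch(chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                       drop = FALSE]),
                    error = function(e) NULL)
    se <- if (is.null(cov)) rep(NA_real_, length(est)) else sqrt(diag(cov))
    fitted <- fit$fitted.values; dev <- fit$deviance
  }
  tstat <- est / se
  ptab <- data.frame(term = names(est), estimate = unname(est),
                     se = unname(se), tstat = unname(tstat),
                     p = unname(2 * stats::pnorm(-abs(tstat))),
                     stringsAsFactors = FALSE)
  null_dev <- deviance_of(character(0))
  auc_in <- if (length(unique(y)) == 2 && length(current))
    roc_auc(fitted, y)$auc else NA_real_
  cv <- if (cv_folds > 0 && length(current))
    cv_auc_terms(design, current, cv_folds, seed) else NA_real_
  out <- list(terms = current, coefficients = ptab,
              deviance = dev, null_deviance = null_dev,
              pseudo_r2 = 1 - dev / null_dev,
              auc = auc_in, cv_auc = cv,
              separation = separation, fitted = fitted,
              p_enter = p_enter, p_remove = p_remove,
              design_cols = setdiff(colnames(design), c("sample_id", "y")))
  class(out) <- "stepwise_glm"
  out
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_auc_terms <- function(design, terms, k, seed) {
  y <- design$y
  fold <- stratified_folds(y, k, seed)
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    X <- term_matrix(design[tr, , drop = FALSE], terms)
    fit <- logistic_fit(X, y[tr])
    Xte <- term_matrix(design[!tr, , drop = FALSE], terms)
    pred[!tr] <- stats::plogis(drop(Xte %*% fit$coefficients))
  }
  roc_auc(pred, y)$auc
}

#' @export
print.stepwise_glm <- function(x, ...) {
  cat("Stepwise logistic model (p_enter =", x$p_enter,
      ", p_remove =", x$p_remove, ")\n")
  if (!length(x$terms)) {
    cat("  no term selected (intercept-only model)\n")
  } else {
    cat("  terms:", paste(x$terms, collapse = ", "), "\n")
    print(format(x$coefficients, digits = 4), row.names = FALSE)
  }
  cat(sprintf("  McFadden R2 = %.3f; in-sample AUC = %.3f; CV AUC = %.3f\n",
              x$pseudo_r2, x$auc, x$cv_auc))
  if (x$separation) cat("  note: separation detected; ridge fallback used\n")
  invisible(x)
}

#' @export
summary.stepwise_glm <- function(object, ...) print(object, ...)

#' @export
coef.stepwise_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predicted case probabilities from a stepwise logistic fit
#'
#' @param object A \code{stepwise_glm}.
#' @param newdata Design data.frame with the same z-scored predictor columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.stepwise_glm <- function(object, newdata, ...) {
  X <- term_matrix(newdata, object$terms)
  b <- stats::setNames(object$coefficients$estimate, object$coefficients$term)
  stats::plogis(drop(X %*% b[colnames(X)]))
}

#' Quartile odds ratio of the index within a per-year cohort
#'
#' Top-quartile vs bottom-quartile odds ratio of case status, delegating to
#' [odds_ratio()] in \code{q4_vs_q1} mode.
#'
#' @param scores data.frame (\code{sample_id}, \code{mdi}) or named vector.
#' @param case_ids,control_ids Sample ids of the cohort's two arms.
#' @return As [odds_ratio()].
#' @export
quartile_or <- function(scores, case_ids, control_ids) {
  if (is.numeric(scores)) scores <- data.frame(sample_id = names(scores), mdi = scores)
  ids <- c(case_ids, control_ids)
  s <- scores$mdi[match(ids, scores$sample_id)]
  odds_ratio(s, rep(c(1, 0), c(length(case_ids), length(control_ids))),
             mode = "q4_vs_q1")
}

#' Random-forest comparator for the risk design
#'
#' Fits a random forest on the seven main-effect columns, reports a
#' stratified 5-fold cross-validated AUC and a seeded permutation importance
#' per predictor: the mean drop in held-out AUC over \code{n_perm}
#' within-fold permutations of that predictor, with a normal-approximation
#' 95% CI. Raw (unclipped) importances are reported.
#'
#' @param design data.frame from [build_risk_design()].
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed (folds, forests and permutations).
#' @param n_perm Permutations per predictor per fold (default 20).
#' @param cv_folds Stratified folds (default 5).
#' @return list(cv_auc, importance = data.frame(predictor, importance,
#'   ci_low, ci_high)).
#' @export
rf_model <- function(design, n_trees = 500, seed = 1, n_perm = 20,
                     cv_folds = 5) {
  y <- design$y
  if (min(table(y)) < 20) stop("need >= 20 samples per class")
  preds <- intersect(RISK_PREDICTORS, colnames(design))
  X <- design[preds]
  fold <- stratified_folds(y, cv_folds, seed)
  prob <- numeric(length(y))
  drops <- matrix(NA_real_, nrow = cv_folds * n_perm, ncol = length(preds),
                  dimnames = list(NULL, preds))
  set.seed(seed)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    rf <- randomForest::randomForest(x = X[tr, , drop = FALSE],
                                     y = factor(y[tr]), ntree = n_trees)
    base_p <- stats::predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "1"]
    prob[!tr] <- base_p
    base_auc <- roc_auc(base_p, y[!tr])$auc
    for (v in seq_along(preds)) {
      for (r in seq_len(n_perm)) {
        Xp <- X[!tr, , drop = FALSE]
        Xp[[v]] <- sample(Xp[[v]])
        p <- stats::predict(rf, Xp, type = "prob")[, "1"]
        drops[(f - 1) * n_perm + r, v] <- base_auc - roc_auc(p, y[!tr])$auc
      }
    }
  }
  imp <- colMeans(drops)
  sdev <- apply(drops, 2, stats::sd) / sqrt(nrow(drops))
  list(cv_auc = roc_auc(prob, y)$auc,
       importance = data.frame(predictor = preds, importance = unname(imp),
                               ci_low = unname(imp - 1.96 * sdev),
                               ci_high = unname(imp + 1.96 * sdev),
                               stringsAsFactors = FALSE))
}

#' Pseudo-R-squared contribution of a term block
#'
#' McFadden pseudo-R2 of a full and a nested reduced logistic model, with
#' the likelihood-ratio p-value for the removed block (e.g. the index main
#' effect together with every interaction containing it).
#'
#' @param design Risk design data.frame.
#' @param full_terms Character vector of terms in the full model.
#' @param reduced_terms Subset of \code{full_terms} for the reduced model.
#' @return list(r2_full, r2_reduced, lr_stat, df, p).
#' @export
r2_contribution <- function(design, full_terms, reduced_terms) {
  if (!all(reduced_terms %in% full_terms))
    stop("reduced_terms must be a subset of full_terms")
  y <- design$y
  dev <- function(terms) logistic_fit(term_matrix(design, terms), y)$deviance
  d_full <- dev(full_terms); d_red <- dev(reduced_terms)
  d_null <- dev(character(0))
  lr <- max(d_red - d_full, 0)
  df <- length(full_terms) - length(reduced_terms)
  list(r2_full = 1 - d_full / d_null,
       r2_reduced = 1 - d_red / d_null,
       lr_stat = lr, df = df,
       p = if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Fit the full per-year breast-cancer risk model
#'
#' For each follow-up year from \code{year_min} onwards this builds the
#' cumulative case/control cohort, z-scores the design on that subset, runs
#' the bidirectional stepwise logistic selection, and records the quartile
#' odds ratio of the raw index. At the final year it adds the random-forest
#' comparator and the pseudo-R2 contribution of the index block.
#'
#' @param pheno Phenotype with \code{diagnosis_year} and cell proportions.
#' @param scores Index scores (data.frame \code{sample_id}, \code{mdi}).
#' @param year_min First modelled year (default 3).
#' @param seed Integer seed (CV folds, forests, permutations).
#' @param n_trees Random-forest size (default 500).
#' @param ... Passed to [stepwise_logistic()].
#' @return Object of class \code{cancer_risk_model}: \code{$per_year} (one
#'   entry per modelled year with the stepwise fit, AUCs and quartile OR),
#'   \code{$final_year}, \code{$rf}, \code{$mdi_contribution}.
#' @export
fit_cancer_risk <- function(pheno, scores, year_min = 3, seed = 1,
                            n_trees = 500, ...) {
  cohorts <- build_per_year_cohorts(pheno, year_min = year_min)
  if (!length(cohorts)) stop("no modellable year")
  per_year <- list()
  for (ch in cohorts) {
    ids <- c(ch$case_ids, ch$control_ids)
    ph <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
    ph$label <- rep(c(1L, 0L), c(length(ch$case_ids), length(ch$control_ids)))
    design <- build_risk_design(ph, scores)
    fit <- stepwise_logistic(design, seed = seed, ...)
    qor <- tryCatch(quartile_or(scores, ch$case_ids, ch$control_ids),
                    error = function(e) NULL)
    per_year[[as.character(ch$year)]] <-
      list(year = ch$year, n_cases = length(ch$case_ids),
           n_controls = length(ch$control_ids), fit = fit,
           auc = fit$auc, cv_auc = fit$cv_auc,
           or_q4_vs_q1 = qor, design = design)
  }
  last <- per_year[[length(per_year)]]
  rf <- rf_model(last$design, n_trees = n_trees, seed = seed)
  mdi_terms <- last$fit$terms[vapply(last$fit$terms, function(tm)
    "mdi" %in% interaction_parents(tm), TRUE)]
  contrib <- r2_contribution(last$design, last$fit$terms,
                             setdiff(last$fit$terms, mdi_terms))
  out <- list(per_year = per_year, final_year = last$year,
              rf = rf, mdi_contribution = contrib)
  class(out) <- "cancer_risk_model"
  out
}

#' @export
print.cancer_risk_model <- function(x, ...) {
  cat("Per-year breast-cancer risk model (years",
      names(x$per_year)[1], "-", x$final_year, ")\n")
  tab <- do.call(rbind, lapply(x$per_year, function(e)
    data.frame(year = e$year, cases = e$n_cases, controls = e$n_controls,
               auc = round(e$auc, 3), cv_auc = round(e$cv_auc, 3),
               or_q4_q1 = if (is.null(e$or_q4_vs_q1)) NA else
                 round(e$or_q4_vs_q1$or, 2))))
  print(tab, row.names = FALSE)
  cat("Final-year stepwise fit:\n")
  print(x$per_year[[length(x$per_year)]]$fit)
  cat(sprintf("Random forest CV AUC = %.3f\n", x$rf$cv_auc))
  cat(sprintf("Index contribution: R2 %.3f -> %.3f without it (LR p = %.3g)\n",
              x$mdi_contribution$r2_full, x$mdi_contribution$r2_reduced,
              x$mdi_contribution$p))
  invisible(x)
}
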