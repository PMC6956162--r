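#' Fit flexibility-versus-age growth curves with AIC model selection
#'
#' Fits five candidate families by least squares and selects the best by
#' the Akaike information criterion `AIC = n log(RSS / n) + 2 k` (smaller
#' is better):
#' \describe{
#'   \item{linear}{`FI = b * age + c`}
#'   \item{quadratic}{`FI = a * age^2 + b * age + c`}
#'   \item{log}{`FI = a * log(age) + b`}
#'   \item{exponential}{`FI = a * exp(b * age) + c`}
#'   \item{von_bertalanffy}{`FI = A * (1 - exp(-k (age - t0)))`}
#' }
#' Families that fail to converge are excluded with a warning. An optional
#' permutation test (age shuffles, refitting the winning family) assesses
#' the observed r-squared.
#'
#' @param cohort data frame with columns `age` and `FI` (e.g.
#'   [gen_cohort()] output), n >= 10, ages positive.
#' @param n_perm number of age permutations for the r-squared test
#'   (0 = skip; 1000 for the standard test).
#' @param seed seed for the permutation test.
#' @return Object of class `fi_age_fit` with [print()], [summary()],
#'   [coef()], [predict()], [fitted()], [residuals()], [plot()] and
#'   [simulate()] methods.
#' @export
#' @examples
#' coh <- gen_cohort(n = 60, seed = 2)
#' fit <- fit_fi_age(coh)
#' fit
#' coef(fit)
fit_fi_age <- function(cohort, n_perm = 0, seed = 1) {
  stopifnot(all(c("age", "FI") %in% names(cohort)))
  age <- cohort$age; fi <- cohort$FI
  if (length(age) < 10) stop("need at least 10 participants")
  if (any(age <= 0)) stop("ages must be positive")
  fits <- fit_families(age, fi)
  if (!length(fits)) stop("no model family converged")
  aic <- vapply(fits, function(f) f$aic, 0)
  best <- names(which.min(aic))
  obj <- structure(
    list(best_family = best, fits = fits,
         aic_table = data.frame(family = names(aic), aic = unname(aic),
                                r2 = vapply(fits, function(f) f$r2, 0),
                                stringsAsFactors = FALSE),
         data = data.frame(age = age, FI = fi),
         r2 = fits[[best]]$r2, perm_p = NA_real_, n_perm = n_perm),
    class = "fi_age_fit")
  if (n_perm > 0) {
    set.seed(seed)
    r2_obs <- obj$r2
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      f <- fit_families(sample(age), fi, families = best)
      if (length(f) && f[[1]]$r2 >= r2_obs) exceed <- exceed + 1L
    }
    obj$perm_p <- (1 + exceed) / (1 + n_perm)
  }
  obj
}

fit_families <- function(age, fi,
                         families = c("linear", "quadratic", "log",
                                      "exponential", "von_bertalanffy")) {
  n <- length(age)
  out <- list()
  add <- function(name, params, pred_fn, k) {
    rss <- sum((fi - pred_fn(age))^2)
    tss <- sum((fi - mean(fi))^2)
    out[[name]] <<- list(params = params, predict = pred_fn,
                         aic = n * log(rss / n) + 2 * k,
                         r2 = max(0, 1 - rss / tss), rss = rss,
                         sigma = sqrt(rss / n))
  }
  # prediction-function constructors take the parameter vector as an
  # argument so each family's closure captures its own copy
  preds <- list(
    linear = function(p) function(x) p[["c"]] + p[["b"]] * x,
    quadratic = function(p) function(x)
      p[["c"]] + p[["b"]] * x + p[["a"]] * x^2,
    log = function(p) function(x) p[["b"]] + p[["a"]] * log(x),
    exponential = function(p) function(x)
      p[["a"]] * exp(p[["b"]] * x) + p[["c"]],
    von_bertalanffy = function(p) function(x)
      p[["A"]] * (1 - exp(-p[["k"]] * (x - p[["t0"]])))
  )
  for (fam in families) {
    res <- tryCatch({
      params <- if (fam == "linear") {
        cf <- stats::coef(stats::lm(fi ~ age))
        c(b = unname(cf[2]), c = unname(cf[1]))
      } else if (fam == "quadratic") {
        cf <- stats::coef(stats::lm(fi ~ age + I(age^2)))
        c(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]))
      } else if (fam == "log") {
        cf <- stats::coef(stats::lm(fi ~ log(age)))
        c(a = unname(cf[2]), b = unname(cf[1]))
      } else if (fam == "exponential") {
        cf <- stats::coef(minpack.lm::nlsLM(
          fi ~ a * exp(b * age) + cc,
          start = list(a = -0.3, b = -0.02, cc = mean(fi)),
          control = minpack.lm::nls.lm.control(maxiter = 200)))
        c(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["cc"]))
      } else {
        cf <- stats::coef(minpack.lm::nlsLM(
          fi ~ A * (1 - exp(-k * (age - t0))),
          start = list(A = max(fi), k = 0.05, t0 = min(age) - 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)))
        c(A = unname(cf["A"]), k = unname(cf["k"]), t0 = unname(cf["t0"]))
      }
      add(fam, params, preds[[fam]](params), length(params))
      TRUE
    }, error = function(e) FALSE)
    if (identical(res, FALSE) && length(families) > 1)
      warning("family '", fam, "' failed to converge; excluded")
  }
  out
}

#' @export
print.fi_age_fit <- function(x, ...) {
  cat(sprintf("<fi_age_fit> best family: %s (AIC = %.2f, r2 = %.3f)\n",
              x$best_family, min(x$aic_table$aic), x$r2))
  cat("parameters:", paste(sprintf("%s = %.6g", names(coef(x)), coef(x)),
                           collapse = ", "), "\n")
  if (!is.na(x$perm_p))
    cat(sprintf("permutation p (r2, %d shuffles): %.4g\n", x$n_perm, x$perm_p))
  invisible(x)
}

#' @export
summary.fi_age_fit <- function(object, ...) {
  tab <- object$aic_table[order(object$aic_table$aic), ]
  cat("Flexibility-age model comparison (lower AIC wins):\n")
  print(tab, row.names = FALSE)
  cat(sprintf("\nBest family: %s; n = %d; residual SD = %.4g\n",
              object$best_family, nrow(object$data),
              object$fits[[object$best_family]]$sigma))
  invisible(tab)
}

#' @export
coef.fi_age_fit <- function(object, ...) object$fits[[object$best_family]]$params

#' @export
predict.fi_age_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age else newdata$age
  as.numeric(object$fits[[object$best_family]]$predict(age))
}

#' @export
fitted.fi_age_fit <- function(object, ...) predict(object)

#' @export
residuals.fi_age_fit <- function(object, ...) object$data$FI - predict(object)

#' @export
simulate.fi_age_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  s <- object$fits[[object$best_family]]$sigma
  as.data.frame(replicate(nsim, pmin(pmax(mu + stats::rnorm(length(mu), 0, s), 0), 1)))
}

#' @export
plot.fi_age_fit <- function(x, ...) {
  graphics::plot(x$data$age, x$data$FI, xlab = "age (years)",
                 ylab = "flexibility index", pch = 16,
                 col = grDevices::grey(0.4), ...)
  ag <- seq(min(x$data$age), max(x$data$age), length.out = 200)
  graphics::lines(ag, x$fits[[x$best_family]]$predict(ag), lwd = 2,
                  col = "steelblue")
  invisible(x)
}

zscore_cols <- function(x) {
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  scale(x, center = TRUE, scale = s)
}

stratified_folds <- function(groups, k) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Multi-class SVM classification of age groups
#'
#' Z-scored features, linear-kernel one-vs-one multi-class SVM, stratified
#' folds; the k-fold scheme is repeated over shuffled splits to report
#' mean and SD accuracy.
#'
#' @param x feature matrix (participants x features).
#' @param groups factor of group labels.
#' @param scheme `"kfold"` or `"loo"`.
#' @param k number of folds (>= 2).
#' @param reps shuffled repetitions of the k-fold split.
#' @param cost SVM cost parameter.
#' @param seed integer seed.
#' @return Object of class `prediction_report` with per-repetition
#'   accuracies (%), their mean and SD.
#' @export
classify_age_groups <- function(x, groups, scheme = c("kfold", "loo"),
                                k = 5, reps = 100, cost = 1, seed = 1) {
  scheme <- match.arg(scheme)
  x <- zscore_cols(as.matrix(x))
  groups <- factor(groups)
  if (scheme == "kfold") {
    if (k < 2) stop("k-fold cross-validation needs k >= 2")
    if (min(table(groups)) < k)
      stop("a group has fewer members than folds; use scheme = 'loo'")
  }
  set.seed(seed)
  one_rep <- function() {
    fold <- if (scheme == "loo") seq_along(groups)
            else stratified_folds(groups, k)
    pred <- factor(rep(NA_character_, length(groups)), levels = levels(groups))
    for (f in unique(fold)) {
      tr <- fold != f
      m <- e1071::svm(x[tr, , drop = FALSE], groups[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
      pred[!tr] <- stats::predict(m, x[!tr, , drop = FALSE])
    }
    100 * mean(pred == groups)
  }
  acc <- if (scheme == "loo") one_rep() else replicate(reps, one_rep())
  structure(list(scheme = scheme, accuracy = acc, mean = mean(acc),
                 sd = stats::sd(acc), k = if (scheme == "kfold") k else NA,
                 chance = 100 / nlevels(groups)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  what <- if (!is.null(x$r2)) "out-of-fold R2" else "accuracy (%)"
  cat(sprintf("<prediction_report> %s %s: %.2f", x$scheme, what, x$mean))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.2f", x$sd))
  cat("\n")
  invisible(x)
}

#' Support-vector regression of age on connectivity features
#'
#' Linear-kernel epsilon-SVR with fold-wise inner selection of the cost
#' parameter; reports the out-of-fold R-squared (pooled over folds) per
#' repetition. Negative pooled R-squared is reported as 0 with a flag.
#'
#' @param x feature matrix.
#' @param ages numeric response.
#' @param scheme `"kfold"` or `"loo"`.
#' @param k folds; `reps` repetitions (k-fold only).
#' @param cost_grid candidate costs for the inner 3-fold selection.
#' @param reps repetitions.
#' @param seed integer seed.
#' @return A `prediction_report` with element `r2` (per-repetition values).
#' @export
regress_age <- function(x, ages, scheme = c("kfold", "loo"), k = 5,
                        cost_grid = c(0.1, 1, 10), reps = 10, seed = 1) {
  scheme <- match.arg(scheme)
  x <- zscore_cols(as.matrix(x))
  if (scheme == "kfold" && k < 2) stop("k-fold cross-validation needs k >= 2")
  set.seed(seed)
  fit_svr <- function(xtr, ytr, cost) {
    tryCatch(e1071::svm(xtr, ytr, type = "eps-regression", kernel = "linear",
                        cost = cost, scale = FALSE),
             error = function(e) NULL)
  }
  one_rep <- function() {
    fold <- if (scheme == "loo") seq_along(ages)
            else sample(rep(seq_len(k), length.out = length(ages)))
    pred <- numeric(length(ages))
    for (f in unique(fold)) {
      tr <- which(fold != f); te <- which(fold == f)
      best_cost <- cost_grid[1]
      if (length(cost_grid) > 1 && length(tr) >= 6) {
        inner <- sample(rep(1:3, length.out = length(tr)))
        errs <- vapply(cost_grid, function(cc) {
          e <- 0
          for (g in 1:3) {
            m <- fit_svr(x[tr[inner != g], , drop = FALSE],
                         ages[tr[inner != g]], cc)
            p <- if (is.null(m)) mean(ages[tr[inner != g]])
                 else stats::predict(m, x[tr[inner == g], , drop = FALSE])
            e <- e + sum((ages[tr[inner == g]] - p)^2)
          }
          e
        }, 0)
        best_cost <- cost_grid[which.min(errs)]
      }
      m <- fit_svr(x[tr, , drop = FALSE], ages[tr], best_cost)
      pred[te] <- if (is.null(m)) mean(ages[tr])
                  else stats::predict(m, x[te, , drop = FALSE])
    }
    1 - sum((ages - pred)^2) / sum((ages - mean(ages))^2)
  }
  r2 <- if (scheme == "loo") one_rep() else replicate(reps, one_rep())
  flagged <- any(r2 <= 0)
  r2 <- pmax(r2, 0)
  structure(list(scheme = scheme, r2 = r2, mean = mean(r2),
                 sd = if (length(r2) > 1) stats::sd(r2) else NA_real_,
                 flag_nonpositive = flagged),
            class = "prediction_report")
}

#' Two-sided Wilcoxon rank-sum comparison of flexibility values
#'
#' @param fi_a,fi_b numeric vectors (each n >= 3), e.g. per-group global
#'   flexibility indices.
#' @return List with `statistic` (W), `p.value`, group sizes.
#' @export
compare_groups <- function(fi_a, fi_b) {
  if (length(fi_a) < 3 || length(fi_b) < 3)
    stop("each group needs at least 3 values")
  if (length(unique(c(fi_a, fi_b))) == 1L) {
    warning("degenerate input: all values tied; p = 1")
    return(list(statistic = NA_real_, p.value = 1,
                n_a = length(fi_a), n_b = length(fi_b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(fi_a, fi_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_a = length(fi_a), n_b = length(fi_b))
}
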