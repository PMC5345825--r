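#' Per-group descriptive statistics
#'
#' Mean, SD, minimum and maximum of every numeric feature per group.
#'
#' @param table `data.frame` of features.
#' @param grouping factor/character vector (length `nrow(table)`) or the
#'   name of a column in `table`.
#' @param features optional character vector restricting the features.
#' @return Long-format `data.frame`: `group`, `feature`, `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
describe_features <- function(table, grouping, features = NULL) {
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  g <- resolve_grouping(table, grouping)
  num <- vapply(table, is.numeric, logical(1))
  feats <- names(table)[num]
  if (!is.null(features)) feats <- intersect(features, feats)
  rows <- list()
  for (lev in unique(as.character(g))) {
    sel <- which(as.character(g) == lev)
    if (length(sel) == 0L) {
      warning(sprintf("group '%s' is empty; omitted", lev))
      next
    }
    for (f in feats) {
      v <- table[[f]][sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, feature = f, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

resolve_grouping <- function(table, grouping) {
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(table)) {
    return(table[[grouping]])
  }
  if (length(grouping) != nrow(table)) {
    stop("grouping length does not match the table", call. = FALSE)
  }
  grouping
}

#' Two-group comparison of one feature
#'
#' Welch's unequal-variance t test by default (`var_equal = TRUE` for
#' Student's). Missing values are dropped pairwise; the per-group n used
#' is reported. Two degenerate groups with equal means give p = 1.
#'
#' @param table feature `data.frame`.
#' @param feature feature (column) name.
#' @param grouping grouping vector or column name with exactly two levels
#'   (or the two levels to compare, when more are present).
#' @param groups optional length-2 character vector selecting the levels.
#' @param var_equal use the pooled-variance Student t (default `FALSE`).
#' @return List: `statistic`, `p_value`, `df`, `n` (per group), `means`.
#' @export
two_group_test <- function(table, feature, grouping, groups = NULL,
                           var_equal = FALSE) {
  g <- as.character(resolve_grouping(table, grouping))
  if (is.null(groups)) {
    groups <- unique(g)
    if (length(groups) != 2L) {
      stop("grouping must have exactly two levels (or pass `groups`)",
           call. = FALSE)
    }
  }
  a <- table[[feature]][g == groups[1]]
  b <- table[[feature]][g == groups[2]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf, p_value = if (eq) 1 else 0,
                df = NA_real_, n = c(length(a), length(b)),
                means = c(mean(a), mean(b))))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n = c(length(a), length(b)),
       means = c(mean(a), mean(b)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_A - ECDF_B| with the asymptotic p value.
#'
#' @param a,b numeric samples.
#' @return List: `D`, `p_value`, `n`.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(ht$statistic), p_value = ht$p.value,
       n = c(length(a), length(b)))
}

#' Per-feature multi-group linear-model comparison
#'
#' One-way fixed-effects F test per feature (the "general linear model"
#' group comparison): for two groups it reduces to the squared pooled t.
#'
#' @param table feature `data.frame`.
#' @param grouping grouping vector or column name with >= 2 levels, each
#'   with >= 2 members.
#' @param features optional restriction of the features tested.
#' @param alpha significance level for the flag column (default 0.05).
#' @return `data.frame`: `feature`, `F`, `df1`, `df2`, `p_value`,
#'   `significant`.
#' @export
multi_group_comparison <- function(table, grouping, features = NULL,
                                   alpha = 0.05) {
  g <- factor(as.character(resolve_grouping(table, grouping)))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  num <- vapply(table, is.numeric, logical(1))
  feats <- names(table)[num]
  if (!is.null(features)) feats <- intersect(features, feats)
  rows <- lapply(feats, function(f) {
    y <- table[[f]]
    ok <- is.finite(y)
    ht <- stats::oneway.test(y[ok] ~ g[ok], var.equal = TRUE)
    data.frame(feature = f, F = unname(ht$statistic),
               df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
               p_value = ht$p.value,
               significant = ht$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prevalence / cohort summary
#'
#' Totals and percentage shares of category counts, shares rounded to one
#' decimal (share = 100 * part / total).
#'
#' @param counts named (or unnamed) nonnegative numeric vector of
#'   category counts.
#' @return List: `counts`, `total`, `share_pct` (rounded to 1 decimal).
#' @export
cohort_summary <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("zero total", call. = FALSE)
  list(counts = counts, total = total,
       share_pct = round(100 * counts / total, 1))
}

wilks_lambda <- function(X, g) {
  # X: matrix n x p (p >= 1); g: factor
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Tm <- crossprod(Xc)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    sel <- g == lev
    Xg <- X[sel, , drop = FALSE]
    Xgc <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Xgc)
  }
  dW <- det(W); dT <- det(Tm)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  max(dW / dT, 0)
}

#' Stepwise linear discriminant analysis
#'
#' Forward-backward feature selection minimising Wilks' lambda with
#' F-to-enter / F-to-remove thresholds (SPSS-conventional defaults
#' 3.84 / 2.71), followed by a Fisher linear discriminant on the selected
#' features: observations are assigned to the nearest class mean in
#' Mahalanobis distance under the pooled within-class covariance, with
#' equal priors. The confusion matrix is resubstitution by default;
#' leave-one-out cross-validation is available.
#'
#' @param table feature `data.frame` (numeric columns are candidates).
#' @param class_labels class vector or column name.
#' @param features optional candidate restriction.
#' @param f_enter,f_remove partial-F thresholds (3.84, 2.71).
#' @param cv `"none"` (resubstitution) or `"loo"`.
#' @param ridge relative ridge added to a singular pooled covariance.
#' @return An object of class `stepwise_lda`: list with `selected`,
#'   `means` (class x feature), `cov_pooled`, `classes`, `confusion`
#'   (row percentages), `confusion_counts`, `correct_rate`, `history`.
#' @export
stepwise_lda <- function(table, class_labels, features = NULL,
                         f_enter = 3.84, f_remove = 2.71,
                         cv = c("none", "loo"), ridge = 1e-8) {
  cv <- match.arg(cv)
  g <- factor(as.character(resolve_grouping(table, class_labels)))
  if (nlevels(g) < 2L) stop("need at least two classes", call. = FALSE)
  num <- vapply(table, is.numeric, logical(1))
  feats <- names(table)[num]
  if (!is.null(features)) feats <- intersect(features, feats)
  X <- as.matrix(table[, feats, drop = FALSE])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  n <- nrow(X); k <- nlevels(g)
  if (any(table(g) < 2L)) stop("every class needs n >= 2", call. = FALSE)
  # drop constant features (zero total variance)
  v <- apply(X, 2, stats::var)
  feats <- feats[v > 0]
  X <- X[, v > 0, drop = FALSE]

  selected <- character(0)
  history <- list()
  lambda_of <- function(set) {
    if (length(set) == 0L) return(1)
    wilks_lambda(X[, set, drop = FALSE], g)
  }
  partial_F <- function(lam_small, lam_big, p_small) {
    # F for the change small -> small+1 variables
    lam <- lam_big / lam_small
    if (!is.finite(lam) || lam <= 0) return(Inf)
    if (lam >= 1) return(0)
    ((n - k - p_small) / (k - 1)) * (1 - lam) / lam
  }
  iter <- 0L
  max_iter <- 4L * length(feats) + 8L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    changed <- FALSE
    lam_cur <- lambda_of(selected)
    # forward step
    cand <- setdiff(feats, selected)
    if (length(cand)) {
      Fs <- vapply(cand, function(f) {
        lam_new <- lambda_of(c(selected, f))
        if (!is.finite(lam_new)) return(-Inf)
        partial_F(lam_cur, lam_new, length(selected))
      }, numeric(1))
      if (max(Fs) >= f_enter) {
        best <- cand[which.max(Fs)]
        selected <- c(selected, best)
        history[[length(history) + 1L]] <-
          list(action = "enter", feature = best, F = max(Fs),
               lambda = lambda_of(selected))
        changed <- TRUE
      }
    }
    # backward step
    if (length(selected) > 1L) {
      lam_cur <- lambda_of(selected)
      Fr <- vapply(selected, function(f) {
        lam_small <- lambda_of(setdiff(selected, f))
        partial_F(lam_small, lam_cur, length(selected) - 1L)
      }, numeric(1))
      if (min(Fr) < f_remove) {
        worst <- selected[which.min(Fr)]
        selected <- setdiff(selected, worst)
        history[[length(history) + 1L]] <-
          list(action = "remove", feature = worst, F = min(Fr),
               lambda = lambda_of(selected))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0L) {
    # nothing passed the entry threshold: fall back to the single best
    lam1 <- vapply(feats, function(f) lambda_of(f), numeric(1))
    selected <- feats[which.min(lam1)]
    history[[length(history) + 1L]] <-
      list(action = "fallback", feature = selected, F = NA_real_,
           lambda = min(lam1))
  }
  Xs <- X[, selected, drop = FALSE]
  fit <- lda_fit(Xs, g, ridge)
  pred <- if (cv == "none") {
    lda_classify(Xs, fit)
  } else {
    loo_classify(Xs, g, ridge)
  }
  cm <- table(truth = g, predicted = factor(pred, levels = levels(g)))
  pct <- 100 * prop.table(cm, 1)
  structure(list(selected = selected, means = fit$means,
                 cov_pooled = fit$cov, classes = levels(g),
                 confusion = pct, confusion_counts = cm,
                 correct_rate = 100 * sum(diag(cm)) / sum(cm),
                 cv = cv, history = history),
            class = "stepwise_lda")
}

lda_fit <- function(X, g, ridge = 1e-8) {
  k <- nlevels(g); n <- nrow(X); p <- ncol(X)
  means <- matrix(NA_real_, k, p,
                  dimnames = list(levels(g), colnames(X)))
  W <- matrix(0, p, p)
  for (i in seq_len(k)) {
    sel <- g == levels(g)[i]
    Xg <- X[sel, , drop = FALSE]
    means[i, ] <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, means[i, ]))
  }
  S <- W / (n - k)
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) {
    S <- S + diag(ridge * max(diag(S)), p)
    inv <- solve(S)
    message("singular pooled covariance: ridge added")
  }
  list(means = means, cov = S, cov_inv = inv)
}

lda_classify <- function(X, fit) {
  # nearest class mean in Mahalanobis distance, equal priors
  k <- nrow(fit$means)
  scores <- matrix(NA_real_, nrow(X), k)
  for (i in seq_len(k)) {
    d <- sweep(X, 2, fit$means[i, ])
    scores[, i] <- rowSums((d %*% fit$cov_inv) * d)
  }
  rownames(fit$means)[max.col(-scores, ties.method = "first")]
}

loo_classify <- function(X, g, ridge) {
  n <- nrow(X)
  out <- character(n)
  for (i in seq_len(n)) {
    fit <- lda_fit(X[-i, , drop = FALSE], droplevels(g[-i]), ridge)
    out[i] <- lda_classify(X[i, , drop = FALSE], fit)
  }
  out
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat(sprintf("<stepwise_lda> %d classes, %d features selected: %s\n",
              length(x$classes), length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("overall correct (%s): %.1f%%\n",
              if (x$cv == "none") "resubstitution" else "leave-one-out",
              x$correct_rate))
  cat("confusion (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Predict classes for new data with a fitted stepwise LDA
#'
#' @param object a `stepwise_lda` fit.
#' @param newdata `data.frame` containing the selected feature columns.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.stepwise_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$selected, drop = FALSE])
  fit <- list(means = object$means[, object$selected, drop = FALSE],
              cov_inv = solve(object$cov_pooled))
  lda_classify(X, fit)
}
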