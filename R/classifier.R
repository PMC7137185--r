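#' Stepwise-forward logistic classifier of nodal involvement
#'
#' Greedy forward selection of up to `max_features` tumour features
#' into a logistic regression of the binary involvement label. The
#' search starts from the intercept-only model and at each step adds
#' the candidate that most improves the criterion (AIC by default; a
#' likelihood-ratio entry test at `alpha` as the alternative),
#' stopping when no candidate improves it or the feature budget is
#' exhausted. Ties are broken by candidate order, so the selection is
#' deterministic and invariant to row permutations of the cohort.
#'
#' If the final model is perfectly separable (maximum-likelihood
#' coefficients diverge), it is refitted with a small ridge penalty
#' (`lambda`, on standardised features, intercept unpenalised) so the
#' coefficients are finite; the report flags this.
#'
#' @param data Data frame with the candidate feature columns and the
#'   label column.
#' @param label Name of the binary label column (logical, 0/1, or a
#'   two-level factor); both classes need at least 2 patients.
#' @param candidates Character vector of candidate feature names; the
#'   default is the four VOI-level features. Histogram percentiles can
#'   be added by naming their columns.
#' @param max_features Maximum number of selected features (default 2).
#' @param criterion `"aic"` (default) or `"lrt"`.
#' @param alpha Entry p-value threshold when `criterion = "lrt"`.
#' @param cutoff Probability cutoff for class labels (default 0.5).
#' @param lambda Ridge penalty used only under separation.
#' @return An object of class `"pln_classifier"`.
#' @export
pln_classifier <- function(data, label = "involved",
                           candidates = c("dtv", "adc", "d", "f"),
                           max_features = 2L,
                           criterion = c("aic", "lrt"), alpha = 0.05,
                           cutoff = 0.5, lambda = 1e-3) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data), label %in% names(data),
            all(candidates %in% names(data)), max_features >= 1L)
  y <- as_binary_label(data[[label]])
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 patients in each class", call. = FALSE)
  X <- data[candidates]
  if (!all(vapply(X, is.numeric, TRUE)))
    stop("candidate features must be numeric", call. = FALSE)

  selected <- character(0)
  trace <- data.frame(step = 0L, added = NA_character_,
                      aic = stats::glm(y ~ 1, family = stats::binomial())$aic)
  repeat {
    if (length(selected) >= max_features) break
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    fits <- lapply(remaining, function(cand) {
      quiet_glm(y, X[c(selected, cand)])
    })
    aics <- vapply(fits, function(f) f$aic, 0)
    devs <- vapply(fits, function(f) f$deviance, 0)
    cur <- quiet_glm(y, X[selected])
    improve <- if (criterion == "aic") {
      aics < cur$aic - 1e-8
    } else {
      p_lrt <- stats::pchisq(cur$deviance - devs, df = 1, lower.tail = FALSE)
      p_lrt < alpha
    }
    if (!any(improve)) break
    score <- if (criterion == "aic") aics else devs
    score[!improve] <- Inf
    pick <- which.min(score)  # first minimum: tie broken by candidate order
    selected <- c(selected, remaining[pick])
    trace <- rbind(trace, data.frame(step = length(selected),
                                     added = remaining[pick], aic = aics[pick]))
  }

  final <- quiet_glm(y, X[selected])
  separable <- final$separable
  if (separable) {
    rf <- ridge_logistic(as.matrix(X[selected]), y, lambda = lambda)
    coefs <- rf$coef
  } else {
    coefs <- stats::coef(final$fit)
  }
  structure(list(selected = selected, coefficients = coefs,
                 separable = separable, lambda = if (separable) lambda else NULL,
                 criterion = criterion, cutoff = cutoff, label = label,
                 candidates = candidates, trace = trace,
                 glm = if (separable) NULL else final$fit,
                 data = data, y = y),
            class = "pln_classifier")
}

as_binary_label <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("label factor must have 2 levels", call. = FALSE)
    return(as.integer(y) - 1L)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("label must be binary (0/1)", call. = FALSE)
  as.integer(y)
}

# glm with separation detection; warnings about fitted 0/1 probabilities
# mark the fit separable instead of surfacing to the user
quiet_glm <- function(y, X) {
  df <- if (ncol(as.data.frame(X))) cbind(.y = y, as.data.frame(X))
        else data.frame(.y = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, aic = fit$aic, deviance = fit$deviance,
       separable = sep || any(abs(stats::coef(fit)[-1]) > 1e3 *
                                max(1, abs(stats::coef(fit)[1]))))
}

# Newton-IRLS logistic regression with an L2 penalty on the
# standardised slopes (intercept unpenalised); coefficients are
# returned on the original feature scale
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100L, tol = 1e-10) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, mu), 2, sdv, "/"))
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    prob <- stats::plogis(eta)
    W <- prob * (1 - prob)
    H <- crossprod(Z, Z * W) + pen
    g <- crossprod(Z, y - prob) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  slopes <- beta[-1] / sdv
  intercept <- beta[1] - sum(slopes * mu)
  coefs <- c(intercept, slopes)
  names(coefs) <- c("(Intercept)", colnames(X))
  list(coef = coefs)
}

#' Refit the developed model on another reader's features
#'
#' Keeps the selected feature set fixed (no re-selection) and refits
#' the logistic coefficients on a new cohort table — typically the
#' same patients measured by a second reader — so the effect of
#' interobserver variation on the developed model can be assessed.
#'
#' @param object A fitted [pln_classifier].
#' @param newdata Data frame with the selected feature columns and the
#'   label column.
#' @return A `pln_classifier` with the same selected features,
#'   refitted coefficients, and `newdata` as its training data.
#' @export
refit_classifier <- function(object, newdata) {
  stopifnot(inherits(object, "pln_classifier"))
  miss <- setdiff(c(object$selected, object$label), names(newdata))
  if (length(miss))
    stop("newdata lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- as_binary_label(newdata[[object$label]])
  final <- quiet_glm(y, newdata[object$selected])
  out <- object
  out$separable <- final$separable
  if (final$separable) {
    lam <- if (is.null(object$lambda)) 1e-3 else object$lambda
    out$coefficients <- ridge_logistic(as.matrix(newdata[object$selected]), y,
                                       lambda = lam)$coef
    out$lambda <- lam
  } else {
    out$coefficients <- stats::coef(final$fit)
    out$lambda <- NULL
  }
  out$glm <- if (final$separable) NULL else final$fit
  out$data <- newdata
  out$y <- y
  out
}

#' @export
coef.pln_classifier <- function(object, ...) object$coefficients

#' @export
print.pln_classifier <- function(x, ...) {
  cat("Stepwise-forward logistic classifier of nodal involvement\n")
  cat(sprintf("  selected (%s): %s\n", x$criterion,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "<intercept only>"))
  print(signif(x$coefficients, 4))
  if (x$separable)
    cat(sprintf("  note: perfect separation; ridge fit (lambda = %g)\n", x$lambda))
  invisible(x)
}

#' @export
summary.pln_classifier <- function(object, ...) {
  cat("Selection trace (AIC):\n")
  print(object$trace)
  print(object)
  invisible(object)
}

#' @export
predict.pln_classifier <- function(object, newdata = NULL,
                                   type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss))
    stop("newdata lacks feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  Xm <- cbind(1, as.matrix(newdata[object$selected]))
  eta <- drop(Xm %*% object$coefficients)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) >= object$cutoff))
}

#' Area under the ROC curve
#'
#' Threshold-free discrimination of a score vector against binary
#' labels: the ROC curve is traced over all score thresholds and its
#' area computed by the trapezoidal rule. Equal to the concordant-pair
#' fraction with ties counted one half, and invariant to any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric predictions (higher = more likely positive).
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("need both classes to compute an AUC", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1L] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0L] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Score a fitted classifier on a labelled cohort
#'
#' Applies the classifier, labels patients at the configured
#' probability cutoff, and reports the confusion-matrix accuracy,
#' sensitivity and specificity with 95% Wilson confidence intervals,
#' together with the ROC AUC of the predicted probabilities. With no
#' `newdata` this is the resubstitution performance on the training
#' cohort (reported as such; it is optimistic relative to held-out
#' data).
#'
#' @param object A [pln_classifier].
#' @param newdata Optional data frame with the selected feature
#'   columns and the label column.
#' @param label Label column name (defaults to the training label).
#' @return An object of class `"pln_score"`.
#' @export
score_classifier <- function(object, newdata = NULL, label = object$label) {
  stopifnot(inherits(object, "pln_classifier"))
  data <- if (is.null(newdata)) object$data else newdata
  if (!label %in% names(data)) stop("label column not found", call. = FALSE)
  y <- as_binary_label(data[[label]])
  prob <- predict(object, data, type = "response")
  pred <- as.integer(prob >= object$cutoff)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  n <- length(y)
  metric <- function(x, m) list(estimate = if (m > 0) x / m else NA_real_,
                                ci = if (m > 0) wilson_ci(x, m) else c(NA, NA),
                                n = m)
  structure(list(accuracy = metric(tp + tn, n),
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 auc = auc_roc(prob, y),
                 confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                                    dimnames = list(predicted = c("0", "1"),
                                                    truth = c("0", "1"))),
                 prob = prob, predicted = pred, truth = y,
                 cutoff = object$cutoff,
                 resubstitution = is.null(newdata)),
            class = "pln_score")
}

#' @export
print.pln_score <- function(x, ...) {
  fmt <- function(m, name)
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f, n = %d)\n", name,
                m$estimate, m$ci[1], m$ci[2], m$n))
  cat(sprintf("Classifier performance%s (cutoff %.2f):\n",
              if (x$resubstitution) " [resubstitution]" else "", x$cutoff))
  fmt(x$accuracy, "accuracy"); fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  cat(sprintf("  %-12s %.3f\n", "AUC", x$auc))
  invisible(x)
}

#' Accuracy within a patient subgroup
#'
#' Fraction of a subgroup predicted positive. For a subgroup whose
#' members are all truly node-positive (e.g. the sub-centimetre
#' metastasis patients) this is the sensitivity restricted to that
#' subgroup.
#'
#' @param score A [pln_score] (or an integer vector of predicted
#'   labels).
#' @param subgroup Logical vector selecting the subgroup (all members
#'   assumed truly positive).
#' @return Proportion predicted positive within the subgroup.
#' @export
subgroup_accuracy <- function(score, subgroup) {
  pred <- if (inherits(score, "pln_score")) score$predicted else as.integer(score)
  subgroup <- as.logical(subgroup)
  if (length(pred) != length(subgroup)) stop("length mismatch", call. = FALSE)
  if (!any(subgroup)) stop("subgroup is empty", call. = FALSE)
  mean(pred[subgroup] == 1L)
}

#' Compare two classification accuracies
#'
#' Pooled two-proportion Z test of two accuracies observed on `n1` and
#' `n2` patients, with a two-sided normal p-value; each accuracy's 95%
#' Wilson interval is reported alongside (with a CI-overlap
#' indicator), since confidence-interval overlap is the other common
#' way such comparisons are summarised.
#'
#' @param acc1,acc2 Observed accuracies in `[0, 1]`.
#' @param n1,n2 Numbers of patients behind each accuracy.
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `"accuracy_comparison"`.
#' @examples
#' compare_accuracy(0.9, 10, 0.3, 10)  # Z = 2.74, p = 0.006
#' @export
compare_accuracy <- function(acc1, n1, acc2, n2, conf = 0.95) {
  stopifnot(n1 >= 1, n2 >= 1, acc1 >= 0, acc1 <= 1, acc2 >= 0, acc2 <= 1)
  x1 <- acc1 * n1; x2 <- acc2 * n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (acc1 - acc2) / se else 0
  p <- 2 * stats::pnorm(-abs(z))
  ci1 <- wilson_ci(x1, n1, conf); ci2 <- wilson_ci(x2, n2, conf)
  structure(list(z = z, p.value = p, acc1 = acc1, acc2 = acc2,
                 n1 = n1, n2 = n2, ci1 = ci1, ci2 = ci2,
                 ci_overlap = ci1["lower"] <= ci2["upper"] &&
                              ci2["lower"] <= ci1["upper"]),
            class = "accuracy_comparison")
}

#' @export
print.accuracy_comparison <- function(x, ...) {
  cat(sprintf("Two-proportion comparison of accuracies: Z = %.3f, p = %.4g\n",
              x$z, x$p.value))
  cat(sprintf("  acc1 = %.3f (CI %.3f-%.3f, n = %d)\n",
              x$acc1, x$ci1[1], x$ci1[2], x$n1))
  cat(sprintf("  acc2 = %.3f (CI %.3f-%.3f, n = %d)\n",
              x$acc2, x$ci2[1], x$ci2[2], x$n2))
  cat(sprintf("  95%% CIs %s\n", if (x$ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}
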