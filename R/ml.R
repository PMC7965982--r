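# ---- internal helpers -------------------------------------------------

is_indicator <- function(x) all(x %in% c(0, 1))

stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

fit_logistic <- function(X, y) {
  df <- data.frame(X, .y = y, check.names = FALSE)
  suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
}

predict_logistic <- function(fit, X) {
  as.numeric(suppressWarnings(
    predict(fit, newdata = data.frame(X, check.names = FALSE),
            type = "response")))
}

cv_auc_logistic <- function(X, y, folds) {
  n_folds <- max(folds)
  aucs <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      return(NA_real_)
    }
    fit <- fit_logistic(X[tr, , drop = FALSE], y[tr])
    p <- predict_logistic(fit, X[!tr, , drop = FALSE])
    auc_rank(p, y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# ---- forward feature selection ----------------------------------------

#' Greedy forward feature selection by cross-validated logistic AUC
#'
#' Iteratively adds the candidate feature that maximizes the mean
#' stratified `n_folds`-fold cross-validation AUC of a logistic-regression
#' classifier; stops when the best improvement falls below `tol`. Ties are
#' broken by feature declaration (column) order.
#'
#' @param features data frame / tibble of candidate features (columns in
#'   declaration order).
#' @param labels binary labels (0/1).
#' @param n_folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @param tol minimum AUC improvement to keep adding features.
#' @return character vector of selected feature names, in selection order,
#'   with the selection AUC trace as attribute `"auc_trace"`.
#' @export
forward_feature_selection <- function(features, labels, n_folds = 5,
                                      seed = 0L, tol = 1e-4) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("labels contain a single class; selection undefined.")
  }
  if (min(table(labels)) < n_folds) {
    abort("`n_folds` exceeds the size of the smallest class.")
  }
  folds <- stratified_folds(labels, n_folds, seed)

  selected <- character(0)
  best_auc <- 0.5
  trace <- numeric(0)
  remaining <- names(features)
  repeat {
    if (length(remaining) == 0L) break
    cand_auc <- vapply(remaining, function(f) {
      cv_auc_logistic(features[, c(selected, f), drop = FALSE], labels, folds)
    }, numeric(1))
    best <- which.max(cand_auc)   # first max wins: declaration-order tie-break
    if (cand_auc[best] - best_auc < tol) break
    selected <- c(selected, remaining[best])
    best_auc <- cand_auc[best]
    trace <- c(trace, best_auc)
    remaining <- setdiff(remaining, selected)
  }
  if (length(selected) == 0L) {
    # keep the single best candidate so downstream models have an input
    selected <- remaining[which.max(cand_auc)]
    trace <- max(cand_auc)
  }
  structure(selected, auc_trace = trace)
}

# ---- ensemble members -------------------------------------------------

standardize_fit <- function(X) {
  cont <- !vapply(X, is_indicator, logical(1))
  center <- ifelse(cont, vapply(X, mean, numeric(1)), 0)
  scale <- ifelse(cont & vapply(X, sd, numeric(1)) > 0,
                  vapply(X, sd, numeric(1)), 1)
  list(center = center, scale = scale, indicator = !cont)
}

standardize_apply <- function(X, std) {
  as.data.frame(Map(function(x, c, s) (x - c) / s, X,
                    std$center[names(X)], std$scale[names(X)]),
                check.names = FALSE)
}

fit_members <- function(X, y, std, knn_k) {
  Z <- standardize_apply(X, std)
  Zm <- as.matrix(Z)
  yf <- factor(y, levels = c(0, 1))

  nb_frame <- function(df) {
    df <- as.data.frame(df, check.names = FALSE)
    for (nm in names(df)[std$indicator[names(df)]]) {
      df[[nm]] <- factor(df[[nm]], levels = c(0, 1))
    }
    df
  }

  members <- list()
  members$logistic <- fit_logistic(Z, y)
  members$gda <- MASS::lda(Zm, grouping = yf)
  members$knn <- list(X = Zm, y = y, k = knn_k)
  members$nbayes <- e1071::naiveBayes(nb_frame(X), yf, laplace = 1)
  svm_fit <- e1071::svm(Zm, yf, kernel = "radial", cost = 1, scale = FALSE)
  dv_train <- as.numeric(attr(predict(svm_fit, Zm, decision.values = TRUE),
                              "decision.values"))
  platt <- suppressWarnings(glm(y ~ dv, data.frame(dv = dv_train, y = y),
                                family = binomial()))
  members$svm <- list(fit = svm_fit, platt = platt)
  list(members = members, nb_frame = nb_frame)
}

predict_members <- function(model, X) {
  std <- model$std
  Z <- standardize_apply(X, std)
  Zm <- as.matrix(Z)
  m <- model$members

  p_log <- predict_logistic(m$logistic, Z)
  p_gda <- as.numeric(predict(m$gda, Zm)$posterior[, "1"])
  # direct neighbour count: fraction of the k nearest training points
  # (standardized Euclidean metric) with label 1; deterministic
  d2 <- outer(rowSums(Zm^2), rowSums(m$knn$X^2), "+") -
    2 * Zm %*% t(m$knn$X)
  p_knn <- apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(m$knn$k)]
    mean(m$knn$y[nn])
  })
  p_nb <- as.numeric(predict(m$nbayes, model$nb_frame(X), type = "raw")[, "1"])
  dv <- as.numeric(attr(predict(m$svm$fit, Zm, decision.values = TRUE),
                        "decision.values"))
  p_svm <- as.numeric(suppressWarnings(
    predict(m$svm$platt, data.frame(dv = dv), type = "response")))

  cbind(logistic = p_log, gda = p_gda, knn = p_knn,
        nbayes = p_nb, svm = p_svm)
}

#' Train the five-member bagging ensemble
#'
#' Fits logistic regression, Gaussian (linear) discriminant analysis,
#' k-nearest-neighbour, naive Bayes and a support-vector machine on the
#' standardized selected features; the ensemble prediction is the
#' arithmetic mean of the five member probabilities. Continuous features
#' are z-scored with parameters stored in the model; 0/1 indicators pass
#' through. The SVM probability is a Platt sigmoid fitted on its training
#' decision values; the neighbour count uses `k = round(sqrt(n))`,
#' adjusted to odd.
#'
#' @param features feature tibble (see [extract_features()]).
#' @param labels binary labels (0/1).
#' @param selected non-empty character vector of feature names to use.
#' @param damage_threshold the DMN damage threshold (%) the labels encode;
#'   stored for reporting.
#' @param seed stored seed (training itself is deterministic).
#' @return object of class `dmn_ensemble`.
#' @export
train_bagging_ensemble <- function(features, labels, selected,
                                   damage_threshold = NA_real_, seed = 0L) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  selected <- as.character(selected)   # drop any selection-trace attributes
  if (length(selected) == 0L) abort("`selected` must be non-empty.")
  if (!all(selected %in% names(features))) {
    abort("`selected` names features absent from `features`.")
  }
  if (length(unique(labels)) < 2L) abort("labels contain a single class.")
  X <- features[, selected, drop = FALSE]
  if (any(vapply(X, function(col) var(col) == 0, logical(1)))) {
    abort("zero-variance selected feature.", class = "dmnimpact_degenerate_feature")
  }
  std <- standardize_fit(X)
  n <- nrow(X)
  k <- round(sqrt(n))
  if (k %% 2 == 0) k <- k + 1L
  k <- max(1L, min(k, n))
  fitted <- local_seed(seed, fit_members(X, labels, std, k))
  structure(
    list(members = fitted$members, nb_frame = fitted$nb_frame, std = std,
         selected = selected, damage_threshold = damage_threshold,
         seed = as.integer(seed), n_train = n,
         balance = mean(labels)),
    class = "dmn_ensemble"
  )
}

#' @export
print.dmn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<dmn_ensemble> 5 members, threshold %s%%, %d training records\n",
    format(x$damage_threshold), x$n_train))
  cat("  features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Predict damage probability from a trained ensemble
#'
#' @param object a `dmn_ensemble`.
#' @param newdata feature tibble containing the selected features.
#' @param type `"prob"` for the ensemble mean probability, `"members"`
#'   for the 5-column member probability matrix.
#' @param ... unused.
#' @return numeric vector of probabilities, or a matrix for
#'   `type = "members"`.
#' @export
predict.dmn_ensemble <- function(object, newdata, type = c("prob", "members"),
                                 ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$selected, drop = FALSE]
  P <- predict_members(object, X)
  if (type == "members") return(P)
  rowMeans(P)
}

# ---- leave-one-out evaluation -----------------------------------------

#' Leave-one-out evaluation of the damage classifier
#'
#' Feature selection is performed once on the full data (a deliberate,
#' documented optimistic-bias choice matching the training pre-step); each
#' record is then predicted by a model trained on the remaining records.
#' Pooled held-out probabilities give the rank AUC, Brier score, and
#' sensitivity/specificity/accuracy at a 0.5 probability cutoff.
#'
#' @param features feature tibble.
#' @param labels binary labels (0/1).
#' @param method `"bagging"` (five-member ensemble) or `"logistic"`.
#' @param selected optional pre-selected feature names; selection is run
#'   when missing.
#' @param n_folds CV folds for the selection step.
#' @param seed seed for fold assignment / member fitting.
#' @param cutoff probability cutoff for the confusion-matrix metrics.
#' @return object of class `dmn_eval`: list with `metrics` (one-row
#'   tibble: auc, brier, sensitivity, specificity, accuracy,
#'   dataset_balance), `predictions` (tibble of held-out probability and
#'   label), `selected`, `method`.
#' @export
evaluate_loo <- function(features, labels, method = c("bagging", "logistic"),
                         selected = NULL, n_folds = 5, seed = 0L,
                         cutoff = 0.5) {
  method <- match.arg(method)
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (n < 10L) abort("need at least 10 records for leave-one-out evaluation.")
  if (length(unique(labels)) < 2L) abort("labels contain a single class.")

  if (is.null(selected)) {
    selected <- forward_feature_selection(features, labels,
                                          n_folds = n_folds, seed = seed)
  }
  X <- features[, selected, drop = FALSE]

  p_out <- vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2L) return(mean(ytr))
    keep <- vapply(Xtr, function(col) var(col) > 0, logical(1))
    Xi <- Xtr[, keep, drop = FALSE]
    if (ncol(Xi) == 0L) return(mean(ytr))
    if (method == "logistic") {
      fit <- fit_logistic(Xi, ytr)
      predict_logistic(fit, X[i, keep, drop = FALSE])
    } else {
      ens <- train_bagging_ensemble(Xtr[, keep, drop = FALSE], ytr,
                                    names(Xi), seed = seed)
      unname(predict(ens, X[i, keep, drop = FALSE]))
    }
  }, numeric(1))

  pred1 <- p_out >= cutoff
  metrics <- tibble::tibble(
    auc = auc_rank(p_out, labels),
    brier = mean((p_out - labels)^2),
    sensitivity = sum(pred1 & labels == 1L) / sum(labels == 1L),
    specificity = sum(!pred1 & labels == 0L) / sum(labels == 0L),
    accuracy = mean(pred1 == (labels == 1L)),
    dataset_balance = mean(labels)
  )
  structure(
    list(metrics = metrics,
         predictions = tibble::tibble(probability = p_out, label = labels),
         selected = as.character(selected), method = method),
    class = "dmn_eval"
  )
}

#' @export
print.dmn_eval <- function(x, ...) {
  cat(sprintf("<dmn_eval> %s, %d held-out predictions\n", x$method,
              nrow(x$predictions)))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}
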