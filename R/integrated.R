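# Integrated multi-dimensional model: recursive feature elimination with
# cross-validated AUROC, then standardized logistic regression on the
# retained features. Defaults mirror the mutation-centric feature set:
# abundance (DNA AF, RNA AF, expression quartile), presentation (PHBR) and
# recognition (the immunogenicity score).

cv_folds <- function(n, k) {
  split(sample(n), rep_len(seq_len(k), n))
}

cv_auroc <- function(features, labels, folds) {
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  probs <- rep(NA_real_, length(labels))
  for (test_idx in folds) {
    train_idx <- setdiff(seq_along(labels), test_idx)
    mu <- colMeans(features[train_idx, , drop = FALSE])
    sd_ <- apply(features[train_idx, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    z_train <- scale(features[train_idx, , drop = FALSE], mu, sd_)
    z_test <- scale(features[test_idx, , drop = FALSE], mu, sd_)
    df <- data.frame(y = labels[train_idx], as.data.frame(z_train))
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    probs[test_idx] <- stats::predict(fit, newdata = as.data.frame(z_test),
                                      type = "response")
  }
  as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Fit the integrated multi-dimensional logistic model
#'
#' Recursive feature elimination: starting from all (non-constant) feature
#' columns, the feature with the smallest standardized coefficient magnitude
#' is dropped one step at a time while the cross-validated AUROC of every
#' visited subset is recorded; exactly `retain` features are kept. The final
#' logistic regression is fit on the retained features standardized by
#' training-set means and standard deviations, which are stored for
#' prediction.
#'
#' @param features Data.frame or matrix of numeric feature columns (no
#'   missing values; impute beforehand).
#' @param labels 0/1 vector.
#' @param folds Number of cross-validation folds (default 4).
#' @param retain Number of features to keep (default 5).
#' @param seed RNG seed for fold assignment.
#' @return An object of class `integrated_model`: list with
#'   `selected_features`, `means`, `sds`, `coefficients` (including
#'   `(Intercept)`) and `cv_path` (data.frame of subset size vs CV AUROC).
#' @export
fit_integrated <- function(features, labels, folds = 4L, retain = 5L,
                           seed = 1L) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c(0, 1)), length(unique(labels)) == 2L,
            !anyNA(features))
  constant <- vapply(features, function(x) stats::sd(x) == 0, logical(1))
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(names(features)[constant], collapse = ", "), call. = FALSE)
    features <- features[, !constant, drop = FALSE]
  }
  if (ncol(features) < retain) {
    stop("fewer than `retain` usable features", call. = FALSE)
  }
  current <- names(features)
  cv_path <- list()
  with_private_seed(seed, {
    fold_idx <- cv_folds(length(labels), folds)
    repeat {
      X <- as.matrix(features[, current, drop = FALSE])
      cv_path[[length(cv_path) + 1L]] <- data.frame(
        n_features = length(current),
        auroc = cv_auroc(X, labels, fold_idx),
        features = paste(current, collapse = ","))
      if (length(current) <= retain) break
      z <- scale(X)
      df <- data.frame(y = labels, z)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      beta <- stats::coef(fit)[-1]
      names(beta) <- current
      drop_feat <- names(beta)[which.min(abs(beta))]
      current <- setdiff(current, drop_feat)
    }
  })
  X <- as.matrix(features[, current, drop = FALSE])
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  z <- scale(X, mu, sd_)
  df <- data.frame(y = labels, z)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  structure(list(selected_features = current, means = mu, sds = sd_,
                 coefficients = stats::coef(fit),
                 cv_path = do.call(rbind, cv_path)),
            class = "integrated_model")
}

#' Predict probabilities from an integrated model
#'
#' Standardizes the selected feature columns with the stored training
#' constants and applies the logistic coefficients.
#'
#' @param object An `integrated_model`.
#' @param features Data.frame containing the selected feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.integrated_model <- function(object, features, ...) {
  features <- as.data.frame(features)
  missing <- setdiff(object$selected_features, names(features))
  if (length(missing) > 0L) {
    stop("missing selected feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, object$selected_features, drop = FALSE])
  z <- scale(X, object$means, object$sds)
  beta <- object$coefficients
  eta <- beta[["(Intercept)"]] +
    as.vector(z %*% beta[colnames(z)])
  1 / (1 + exp(-eta))
}

#' @export
print.integrated_model <- function(x, ...) {
  cat("integrated logistic model on", length(x$selected_features),
      "features:\n ", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
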