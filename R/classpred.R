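CLASSIFIER_METHODS <- c("CCP", "BCC", "DLDA", "NC", "SVM")

#' Select differentially expressed features for classification
#'
#' Pooled-variance two-sample t-test over the training samples only;
#' features with p < `alpha` are kept, ordered by ascending p, ties by
#' |t| descending and then feature identifier.
#'
#' @param x training expression matrix, features x samples.
#' @param labels two-level factor over the training samples.
#' @param alpha p-value threshold (default 0.001).
#' @return list with `features` (ordered identifiers) and `stats` (the
#'   selected rows of the t-test table, in order).
#' @export
select_features <- function(x, labels, alpha = 0.001) {
  tt <- two_group_ttest(x, labels)
  keep <- tt[tt$p < alpha, , drop = FALSE]
  if (!nrow(keep))
    stop("no features pass p < ", alpha,
         "; increase alpha or treat the fold as uninformative")
  ord <- order(keep$p, -abs(keep$t), keep$feature_id)
  keep <- keep[ord, , drop = FALSE]
  list(features = keep$feature_id, stats = keep)
}

#' Fit a class-prediction model
#'
#' Methods, on the selected features only:
#' \describe{
#'   \item{CCP}{compound covariate predictor: per-sample score
#'     c_j = sum_i t_i x_ij with t_i the training t statistics; classify
#'     by the midpoint of the two class-mean scores.}
#'   \item{BCC}{Bayesian compound covariate: the same score with Gaussian
#'     class-conditional densities (class means, pooled variance) and
#'     equal priors; classification by posterior probability.}
#'   \item{DLDA}{diagonal linear discriminant analysis: per-class feature
#'     means and pooled within-class variances; zero-variance features are
#'     dropped with a warning.}
#'   \item{NC}{nearest centroid in Euclidean geometry.}
#'   \item{SVM}{linear soft-margin support vector machine, cost C = 1, no
#'     internal rescaling.}
#' }
#' Class 1 is the first factor level (HSC by convention).
#'
#' @param method one of `"CCP"`, `"BCC"`, `"DLDA"`, `"NC"`, `"SVM"`
#'   (case-insensitive).
#' @param x training expression matrix, features x samples.
#' @param labels two-level factor over the training samples.
#' @param features feature identifiers to use (from [select_features()]).
#' @return object of class `classifier_model`.
#' @export
fit_classifier <- function(method, x, labels, features) {
  method <- match.arg(toupper(method), CLASSIFIER_METHODS)
  validate_expression(x)
  labels <- align_labels(labels, colnames(x))
  if (!length(features)) stop("selected feature list is empty")
  missing <- setdiff(features, rownames(x))
  if (length(missing)) stop("features absent from matrix: ", paste(missing, collapse = ", "))
  xs <- x[features, , drop = FALSE]
  cls <- levels(labels)
  g1 <- labels == cls[1L]
  n1 <- sum(g1); n2 <- sum(!g1)

  params <- switch(method,
    CCP = , BCC = {
      tt <- two_group_ttest(xs, labels)
      w <- setNames(tt$t, tt$feature_id)[features]
      cc <- as.vector(w %*% xs)
      mu <- c(mean(cc[g1]), mean(cc[!g1]))
      if (method == "CCP") {
        list(weights = w, class_means = mu, threshold = mean(mu))
      } else {
        v1 <- if (n1 > 1) stats::var(cc[g1]) else 0
        v2 <- if (n2 > 1) stats::var(cc[!g1]) else 0
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        if (sp2 == 0) stop("BCC: pooled variance of the compound covariate is zero")
        list(weights = w, class_means = mu, pooled_sd = sqrt(sp2), priors = c(0.5, 0.5))
      }
    },
    DLDA = {
      m1 <- rowMeans(xs[, g1, drop = FALSE]); m2 <- rowMeans(xs[, !g1, drop = FALSE])
      ss1 <- rowSums((xs[, g1, drop = FALSE] - m1)^2)
      ss2 <- rowSums((xs[, !g1, drop = FALSE] - m2)^2)
      v <- (ss1 + ss2) / (n1 + n2 - 2)
      drop <- v == 0
      if (all(drop)) stop("DLDA: all selected features have zero pooled variance")
      if (any(drop)) warning("DLDA: dropping ", sum(drop), " zero-variance feature(s)")
      list(means = cbind(m1, m2)[!drop, , drop = FALSE], var = v[!drop],
           used = features[!drop])
    },
    NC = list(centroids = cbind(rowMeans(xs[, g1, drop = FALSE]),
                                rowMeans(xs[, !g1, drop = FALSE]))),
    SVM = list(fit = e1071::svm(x = t(xs), y = labels, kernel = "linear",
                                cost = 1, scale = FALSE))
  )
  structure(list(method = method, features = features, params = params,
                 class_labels = cls),
            class = "classifier_model")
}

#' Predict class labels with a fitted model
#'
#' Deterministic tie rules: a compound covariate exactly at the CCP
#' threshold goes to the class with the lower mean score; a BCC posterior
#' of exactly 0.5, and exact DLDA/NC distance ties, go to class 1.
#'
#' @param object a `classifier_model`.
#' @param x expression matrix containing all model features.
#' @param ... unused.
#' @return factor of predicted labels named by sample; for BCC the
#'   posterior probability of class 1 is attached as attribute
#'   `"posterior"`.
#' @export
predict.classifier_model <- function(object, x, ...) {
  validate_expression(x)
  missing <- setdiff(object$features, rownames(x))
  if (length(missing)) stop("matrix is missing model features: ",
                            paste(missing, collapse = ", "))
  cls <- object$class_labels
  p <- object$params
  pred <- switch(object$method,
    CCP = {
      cc <- as.vector(p$weights %*% x[object$features, , drop = FALSE])
      hi <- which.max(p$class_means); lo <- 3L - hi
      ifelse(cc > p$threshold, cls[hi], cls[lo])
    },
    BCC = {
      cc <- as.vector(p$weights %*% x[object$features, , drop = FALSE])
      l1 <- dnorm(cc, p$class_means[1L], p$pooled_sd, log = TRUE) + log(p$priors[1L])
      l2 <- dnorm(cc, p$class_means[2L], p$pooled_sd, log = TRUE) + log(p$priors[2L])
      post1 <- 1 / (1 + exp(l2 - l1))
      out <- ifelse(post1 >= 0.5, cls[1L], cls[2L])
      attr(out, "posterior") <- post1
      out
    },
    DLDA = {
      xs <- x[p$used, , drop = FALSE]
      d1 <- colSums((xs - p$means[, 1L])^2 / p$var)
      d2 <- colSums((xs - p$means[, 2L])^2 / p$var)
      ifelse(d1 <= d2, cls[1L], cls[2L])
    },
    NC = {
      xs <- x[object$features, , drop = FALSE]
      d1 <- colSums((xs - p$centroids[, 1L])^2)
      d2 <- colSums((xs - p$centroids[, 2L])^2)
      ifelse(d1 <= d2, cls[1L], cls[2L])
    },
    SVM = as.character(stats::predict(p$fit, t(x[object$features, , drop = FALSE])))
  )
  post <- attr(pred, "posterior")
  out <- factor(setNames(as.character(pred), colnames(x)), levels = cls)
  if (!is.null(post)) attr(out, "posterior") <- setNames(post, colnames(x))
  out
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' For each sample: remove it, rerun [select_features()] on the remaining
#' samples, fit the classifier, and predict the held-out sample. The
#' held-out sample influences nothing in its own fold's selection or fit.
#' A fold whose training set yields no significant features is recorded as
#' failed and predicted as the training majority class.
#'
#' @param method classifier method, see [fit_classifier()].
#' @param x expression matrix, features x samples (n >= 6).
#' @param labels two-level factor (both classes >= 3 samples).
#' @param alpha in-fold selection threshold.
#' @param keep_folds also return each fold's selected features and model
#'   (used for leakage audits).
#' @return object of class `cv_result`: predictions, truth, per-fold
#'   selected-feature counts, failed folds, confusion table, and (if
#'   requested) per-fold artifacts.
#' @export
loocv <- function(method, x, labels, alpha = 0.001, keep_folds = FALSE) {
  validate_expression(x)
  labels <- align_labels(labels, colnames(x))
  n <- ncol(x)
  if (n < 6L) stop("LOOCV needs at least 6 samples")
  if (any(table(labels) < 3L)) stop("both classes need at least 3 samples for LOOCV")
  cls <- levels(labels)
  pred <- character(n)
  n_selected <- integer(n)
  failed <- logical(n)
  folds <- if (keep_folds) vector("list", n) else NULL
  for (i in seq_len(n)) {
    xtr <- x[, -i, drop = FALSE]
    ltr <- labels[-i]
    if (any(table(ltr) < 2L))
      stop("class collapse in fold ", i, ": a class has < 2 training members")
    sel <- tryCatch(select_features(xtr, ltr, alpha = alpha), error = function(e) NULL)
    if (is.null(sel)) {
      failed[i] <- TRUE
      pred[i] <- names(which.max(table(ltr)))
      next
    }
    model <- fit_classifier(method, xtr, ltr, sel$features)
    n_selected[i] <- length(sel$features)
    pred[i] <- as.character(predict(model, x[, i, drop = FALSE]))
    if (keep_folds) folds[[i]] <- list(features = sel$features, model = model)
  }
  pred <- factor(setNames(pred, colnames(x)), levels = cls)
  structure(list(method = toupper(method), predictions = pred, truth = labels,
                 n_selected = n_selected, failed_folds = which(failed),
                 confusion = table(truth = labels, predicted = pred),
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- mean(x$predictions == x$truth)
  cat("cv_result (", x$method, "): ", length(x$truth), " folds, accuracy ",
      signif(acc, 4), if (length(x$failed_folds))
        paste0(", ", length(x$failed_folds), " failed fold(s)") else "", "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Confusion metrics per class
#'
#' Sensitivity, specificity, PPV and NPV with each class in turn treated
#' as positive (the two-row-per-method layout of class-prediction
#' reports). Undefined ratios (zero denominators) are reported as `NA`,
#' never as 0.
#'
#' @param predictions factor of predicted labels.
#' @param truth factor of true labels (same levels).
#' @return data.frame: class, sensitivity, specificity, ppv, npv.
#' @export
confusion_metrics <- function(predictions, truth) {
  truth <- factor(truth)
  predictions <- factor(predictions, levels = levels(truth))
  if (length(predictions) != length(truth)) stop("length mismatch")
  if (!length(truth)) stop("empty input")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- lapply(levels(truth), function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fn <- sum(predictions != cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    tn <- sum(predictions != cl & truth != cl)
    data.frame(class = cl,
               sensitivity = ratio(tp, tp + fn),
               specificity = ratio(tn, tn + fp),
               ppv = ratio(tp, tp + fp),
               npv = ratio(tn, tn + fn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train on one cohort, evaluate on an independent cohort
#'
#' For each requested method: select features on the full training cohort,
#' fit, predict the independent cohort, and tabulate per-class confusion
#' metrics.
#'
#' @param train_x,train_labels training expression matrix and labels.
#' @param test_x,test_labels independent cohort and its reference labels.
#' @param methods character vector of classifier methods.
#' @param alpha feature-selection threshold.
#' @return data.frame with columns method, class, sensitivity,
#'   specificity, ppv, npv.
#' @export
validate_classifiers <- function(train_x, train_labels, test_x, test_labels,
                                 methods = CLASSIFIER_METHODS, alpha = 0.001) {
  train_labels <- align_labels(train_labels, colnames(train_x))
  test_labels <- align_labels(test_labels, colnames(test_x))
  sel <- select_features(train_x, train_labels, alpha = alpha)
  out <- lapply(methods, function(m) {
    model <- fit_classifier(m, train_x, train_labels, sel$features)
    pred <- predict(model, test_x)
    cbind(method = toupper(m), confusion_metrics(pred, test_labels))
  })
  do.call(rbind, out)
}
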