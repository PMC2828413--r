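test_that("feature selection keeps significant features in p order", {
  set.seed(41)
  toy <- toy_cohort_matrix(n1 = 10, n2 = 10, n_signal = 1, n_noise = 30,
                           delta = 5)
  sel <- select_features(toy$x, toy$labels, alpha = 0.001)
  expect_equal(sel$features[1], "g01")  # the planted feature leads
  expect_true(all(diff(sel$stats$p) >= 0))

  # alpha = 1 keeps every finite-variance feature
  sel_all <- select_features(toy$x, toy$labels, alpha = 1)
  expect_equal(sort(sel_all$features), sort(rownames(toy$x)))

  # nothing significant: explicit error so folds can be flagged
  set.seed(42)
  noise <- make_expr(rnorm(100), nrow = 10)
  labels <- factor(rep(c("a", "b"), each = 5))
  names(labels) <- colnames(noise)
  expect_error(select_features(noise, labels, alpha = 1e-12), "alpha")
})

test_that("CCP uses t-weighted scores with a midpoint threshold", {
  # class2 mirrors class1, so the class-mean scores are symmetric and the
  # threshold sits exactly at zero
  set.seed(43)
  x1 <- matrix(rnorm(20, mean = 2), 4, 5)
  x <- make_expr(cbind(x1, -x1))
  labels <- factor(rep(c("HSC", "LSC"), each = 5), levels = c("HSC", "LSC"))
  names(labels) <- colnames(x)
  m <- fit_classifier("ccp", x, labels, rownames(x))
  expect_equal(m$params$threshold, 0, tolerance = 1e-12)
  expect_equal(sum(m$params$class_means), 0, tolerance = 1e-12)

  # the compound covariate is the plain weighted sum: weights t = (2, -1)
  # on a sample (1, 1) give c = 1
  hand <- structure(list(method = "CCP", features = c("f1", "f2"),
                         params = list(weights = c(f1 = 2, f2 = -1),
                                       class_means = c(3, -3), threshold = 0),
                         class_labels = c("HSC", "LSC")),
                    class = "classifier_model")
  probe <- matrix(c(1, 1), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  expect_equal(as.character(predict(hand, probe)), "HSC")  # c = 1 > 0
  probe0 <- matrix(c(0.5, 1), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  expect_equal(as.character(predict(hand, probe0)), "LSC") # c = 0: lower-mean class
})

test_that("CCP and BCC share the same compound covariate", {
  toy <- toy_cohort_matrix()
  feats <- select_features(toy$x, toy$labels, alpha = 0.01)$features
  ccp <- fit_classifier("ccp", toy$x, toy$labels, feats)
  bcc <- fit_classifier("bcc", toy$x, toy$labels, feats)
  expect_identical(ccp$params$weights, bcc$params$weights)
  expect_equal(ccp$params$class_means, bcc$params$class_means, tolerance = 1e-12)
})

test_that("BCC reports posteriors and breaks exact ties toward class 1", {
  hand <- structure(list(method = "BCC", features = "f1",
                         params = list(weights = c(f1 = 1), class_means = c(2, 2),
                                       pooled_sd = 1, priors = c(0.5, 0.5)),
                         class_labels = c("HSC", "LSC")),
                    class = "classifier_model")
  probe <- matrix(c(0, 5), 1, 2, dimnames = list("f1", c("s1", "s2")))
  pred <- predict(hand, probe)
  expect_equal(unname(attr(pred, "posterior")), c(0.5, 0.5))
  expect_equal(as.character(pred), c("HSC", "HSC"))
})

test_that("DLDA classifies by variance-scaled squared distance", {
  # one feature, class means 0 and 4, sigma^2 = 1: x = 1 gives d1 = 1 < d2 = 9
  hand <- structure(list(method = "DLDA", features = "f1",
                         params = list(means = matrix(c(0, 4), 1, 2,
                                                      dimnames = list("f1", NULL)),
                                       var = c(f1 = 1), used = "f1"),
                         class_labels = c("HSC", "LSC")),
                    class = "classifier_model")
  probe <- matrix(1, 1, 1, dimnames = list("f1", "s1"))
  expect_equal(as.character(predict(hand, probe)), "HSC")
  probe2 <- matrix(3, 1, 1, dimnames = list("f1", "s1"))
  expect_equal(as.character(predict(hand, probe2)), "LSC")
})

test_that("NC classifies to the nearest Euclidean centroid", {
  hand <- structure(list(method = "NC", features = c("f1", "f2"),
                         params = list(centroids = matrix(c(0, 0, 4, 4), 2, 2,
                                                          dimnames = list(c("f1", "f2"), NULL))),
                         class_labels = c("HSC", "LSC")),
                    class = "classifier_model")
  probe <- matrix(c(1, 1), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  expect_equal(as.character(predict(hand, probe)), "HSC")  # sqrt(2) vs sqrt(18)
})

test_that("DLDA reduces to NC when all pooled variances are equal", {
  set.seed(44)
  base <- matrix(rnorm(12), 2, 6)
  # duplicate the same per-class sample layout for both features so the
  # pooled variances coincide
  x <- make_expr(rbind(base[1, ], base[1, ] + 1))
  labels <- factor(rep(c("a", "b"), each = 3)); names(labels) <- colnames(x)
  dlda <- fit_classifier("dlda", x, labels, rownames(x))
  nc <- fit_classifier("nc", x, labels, rownames(x))
  probe <- make_expr(rnorm(20), nrow = 2)
  expect_equal(as.character(predict(dlda, probe)), as.character(predict(nc, probe)))
})

test_that("a linear SVM separates a separable 1-D problem", {
  x <- matrix(c(-3, -2, -1.5, -1, 1, 1.5, 2, 3), 1, 8,
              dimnames = list("f1", sprintf("s%d", 1:8)))
  labels <- factor(rep(c("HSC", "LSC"), each = 4), levels = c("HSC", "LSC"))
  names(labels) <- colnames(x)
  m <- fit_classifier("svm", x, labels, "f1")
  expect_equal(as.character(predict(m, x)), as.character(labels))
})

test_that("class-swapped training swaps every method's predictions", {
  toy <- toy_cohort_matrix(n1 = 8, n2 = 8, delta = 4, seed = 45)
  swapped <- factor(ifelse(toy$labels == "HSC", "LSC", "HSC"),
                    levels = c("HSC", "LSC"))
  names(swapped) <- names(toy$labels)
  probe <- toy_cohort_matrix(n1 = 5, n2 = 5, delta = 4, seed = 46)$x
  feats <- select_features(toy$x, toy$labels, alpha = 0.001)$features
  for (method in c("CCP", "BCC", "DLDA", "NC", "SVM")) {
    m1 <- fit_classifier(method, toy$x, toy$labels, feats)
    m2 <- fit_classifier(method, toy$x, swapped, feats)
    p1 <- as.character(predict(m1, probe))
    p2 <- as.character(predict(m2, probe))
    expect_equal(p2, ifelse(p1 == "HSC", "LSC", "HSC"),
                 label = paste(method, "swap"))
  }
})

test_that("missing model features are reported by name", {
  toy <- toy_cohort_matrix()
  m <- fit_classifier("nc", toy$x, toy$labels, c("g01", "g02"))
  probe <- toy$x[-1, , drop = FALSE]
  expect_error(predict(m, probe), "g01")
})

test_that("LOOCV is perfect on separable cohorts and guards its preconditions", {
  toy <- toy_cohort_matrix(n1 = 7, n2 = 7, delta = 5, seed = 47)
  for (method in c("CCP", "BCC", "DLDA", "NC", "SVM")) {
    cv <- loocv(method, toy$x, toy$labels, alpha = 0.001)
    expect_equal(mean(cv$predictions == cv$truth), 1, label = method)
    expect_equal(length(cv$predictions), 14L)
  }
  idx <- c(1:3, 8:9)  # 3 HSC + 2 LSC
  expect_error(loocv("ccp", toy$x[, idx], toy$labels[idx]), "at least 6")
  lab_bad <- factor(c(rep("a", 2), rep("b", 10)))
  names(lab_bad) <- colnames(toy$x)[1:12]
  expect_error(loocv("ccp", toy$x[, 1:12], lab_bad), "at least 3")
})

test_that("LOOCV on label-independent data hovers at the majority rate", {
  set.seed(48)
  accs <- replicate(5, {
    x <- make_expr(rnorm(30 * 12), nrow = 30)
    labels <- factor(rep(c("a", "b"), c(7, 5))); names(labels) <- colnames(x)
    cv <- loocv("nc", x, labels, alpha = 0.05)
    mean(cv$predictions == cv$truth)
  })
  expect_lt(abs(mean(accs) - 7 / 12), 0.35)
})

test_that("confusion metrics follow their definitions and report NA when undefined", {
  # arithmetic of a 48/2/51/2 confusion layout
  truth <- factor(rep(c("HSC", "LSC"), c(50, 53)), levels = c("HSC", "LSC"))
  pred <- truth
  pred[which(truth == "HSC")[1:2]] <- "LSC"
  pred[which(truth == "LSC")[1:2]] <- "HSC"
  m <- confusion_metrics(pred, truth)
  hsc <- m[m$class == "HSC", ]
  expect_equal(hsc$sensitivity, 0.96)
  expect_equal(hsc$specificity, 0.9622642, tolerance = 1e-6)
  expect_equal(hsc$ppv, 0.96)
  expect_equal(hsc$npv, 0.9622642, tolerance = 1e-6)
  lsc <- m[m$class == "LSC", ]
  expect_equal(lsc$sensitivity, hsc$specificity)  # two-class symmetry
  expect_equal(lsc$specificity, hsc$sensitivity)

  # balanced errors: everything 0.5
  truth2 <- factor(rep(c("a", "b"), each = 2))
  pred2 <- factor(c("a", "b", "a", "b"))
  m2 <- confusion_metrics(pred2, truth2)
  expect_true(all(unlist(m2[, -1]) == 0.5))

  # no false positives: PPV = 1; a never-predicted class: PPV = NA
  truth3 <- factor(c("a", "a", "b"))
  pred3 <- factor(c("a", "b", "b"), levels = c("a", "b"))
  m3 <- confusion_metrics(pred3, truth3)
  expect_equal(m3$ppv[m3$class == "a"], 1)
  pred4 <- factor(c("b", "b", "b"), levels = c("a", "b"))
  m4 <- confusion_metrics(pred4, truth3)
  expect_true(is.na(m4$ppv[m4$class == "a"]))
})
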