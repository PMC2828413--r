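# Small fixture builders and independent brute-force oracles. Oracles are
# written from the defining formulas, not by calling the package, so the
# two routes stay independent.

make_expr <- function(values, nrow = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = nrow)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

# A small, strongly separated two-cluster cohort for classifier tests.
toy_cohort_matrix <- function(n1 = 6, n2 = 6, n_signal = 5, n_noise = 25,
                              delta = 3, seed = 42) {
  set.seed(seed)
  n <- n1 + n2
  signal <- matrix(rnorm(n_signal * n, sd = 0.5), n_signal, n)
  signal[, seq_len(n1)] <- signal[, seq_len(n1)] + delta
  noise <- matrix(rnorm(n_noise * n), n_noise, n)
  x <- make_expr(rbind(signal, noise))
  labels <- factor(rep(c("HSC", "LSC"), c(n1, n2)), levels = c("HSC", "LSC"))
  names(labels) <- colnames(x)
  list(x = x, labels = labels)
}

# UPGMA by literal re-averaging over the ORIGINAL distance matrix: average
# inter-cluster distance recomputed from scratch at every step (O(n^3)).
bf_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (is.null(best) || avg < best$avg) best <- list(i = i, j = j, avg = avg)
    }
    merge[step, ] <- sort(c(codes[best$i], codes[best$j]))
    height[step] <- best$avg
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[best$i] <- step
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
  }
  list(merge = merge, height = height)
}

# Product-limit estimator straight from its definition.
bf_km <- function(time, event) {
  tu <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tu))
  for (i in seq_along(tu)) {
    n_i <- sum(time >= tu[i])
    d_i <- sum(time == tu[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = tu, surv = out)
}

# Log-rank chi-square from the spreadsheet-style O/E/V sums.
bf_logrank <- function(time, event, group) {
  group <- factor(group)
  g1 <- group == levels(group)[1L]
  tu <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tu) {
    n_i <- sum(time >= t); n_1i <- sum(time >= t & g1)
    d_i <- sum(time == t & event == 1)
    d_1i <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + (d_1i - d_i * n_1i / n_i)
    if (n_i > 1)
      v <- v + d_i * (n_1i / n_i) * (1 - n_1i / n_i) * (n_i - d_i) / (n_i - 1)
  }
  o_minus_e^2 / v
}

# Exact Cox partial log-likelihood for one covariate, no ties.
bf_cox_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Numeric fingerprint of a fitted classifier, for leakage audits.
model_fingerprint <- function(model) {
  p <- model$params
  switch(model$method,
    CCP = list(w = p$weights, mu = p$class_means, thr = p$threshold),
    BCC = list(w = p$weights, mu = p$class_means, sd = p$pooled_sd),
    DLDA = list(m = p$means, v = p$var, used = p$used),
    NC = list(c = p$centroids),
    SVM = list(sv = p$fit$SV, coefs = p$fit$coefs, rho = p$fit$rho,
               index = p$fit$index)
  )
}
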