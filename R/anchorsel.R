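#' Dichotomize samples at the median of an anchor gene
#'
#' Samples with anchor expression strictly above the cohort median are
#' labelled `high`; samples at or below the median go to `low`. With an
#' odd sample count the median-tied middle sample therefore falls in the
#' low group (103 samples split 52 low / 51 high).
#'
#' @param x expression matrix, features x samples.
#' @param anchor_id feature identifier of the anchor gene.
#' @return factor of `high`/`low` labels named by sample id.
#' @export
median_dichotomize <- function(x, anchor_id) {
  validate_expression(x)
  if (!anchor_id %in% rownames(x)) stop("anchor feature not found: ", anchor_id)
  if (ncol(x) < 2L) stop("need at least 2 samples to dichotomize")
  v <- x[anchor_id, ]
  if (diff(range(v)) == 0) stop("degenerate dichotomy: all anchor values equal")
  med <- median(v)
  factor(ifelse(v > med, "high", "low"), levels = c("high", "low"))
}

#' Pearson correlation screen against an anchor gene
#'
#' Correlates every non-anchor feature with the anchor across all samples.
#' Two-sided p-values come from t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees
#' of freedom. A feature enters the signature when p < `alpha` AND
#' |r| > `r_threshold`; the anchor itself is excluded from screening but
#' always heads the signature feature list. Zero-variance features have
#' undefined r and are excluded (their count is recorded).
#'
#' @param x expression matrix, features x samples (n >= 4).
#' @param anchor_id anchor feature identifier.
#' @param alpha p-value threshold (default 0.001).
#' @param r_threshold absolute-correlation threshold (default 0.3).
#' @return object of class `correlation_screen`: a list with `table`
#'   (feature_id, r, p, selected), `selected`, `signature` (anchor first),
#'   `anchor_id`, `alpha`, `r_threshold`, `n_zero_variance`.
#' @export
pearson_screen <- function(x, anchor_id, alpha = 0.001, r_threshold = 0.3) {
  validate_expression(x)
  if (!anchor_id %in% rownames(x)) stop("anchor feature not found: ", anchor_id)
  n <- ncol(x)
  if (n < 4L) stop("pearson_screen needs at least 4 samples (n-2 >= 2 df)")
  a <- x[anchor_id, ]
  if (stats::sd(a) == 0) stop("anchor has zero variance")
  feats <- setdiff(rownames(x), anchor_id)
  xm <- x[feats, , drop = FALSE]
  xc <- xm - rowMeans(xm)
  ac <- a - mean(a)
  ss_x <- rowSums(xc^2)
  zero_var <- ss_x == 0
  r <- rep(NA_real_, length(feats))
  r[!zero_var] <- (xc[!zero_var, , drop = FALSE] %*% ac) /
    sqrt(ss_x[!zero_var] * sum(ac^2))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0  # |r| = 1 exactly
  selected <- !is.na(r) & p < alpha & abs(r) > r_threshold
  tab <- data.frame(feature_id = feats, r = r, p = p, selected = selected,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(zero_var))
    message(sum(zero_var), " zero-variance feature(s) excluded from the screen")
  structure(list(table = tab,
                 selected = feats[selected],
                 signature = c(anchor_id, feats[selected]),
                 anchor_id = anchor_id, alpha = alpha, r_threshold = r_threshold,
                 n_zero_variance = sum(zero_var)),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("correlation_screen: anchor", x$anchor_id, "|",
      nrow(x$table), "features screened,", length(x$selected),
      sprintf("selected (p < %g, |r| > %g)\n", x$alpha, x$r_threshold))
  invisible(x)
}

#' Per-feature pooled-variance two-sample t-test
#'
#' Classical class-comparison t-test per feature: pooled variance across
#' the two groups, n1 + n2 - 2 degrees of freedom, two-sided p. The t sign
#' follows `mean(group1) - mean(group2)` with group1 the first factor
#' level. Degenerate features (zero pooled variance) get t = 0, p = 1 when
#' the group means agree and p = 0 (flagged) when they differ.
#'
#' @param x expression matrix, features x samples.
#' @param labels two-level factor over the samples of `x` (aligned with
#'   columns, or named by sample id).
#' @return data.frame: feature_id, t, p, mean_diff, degenerate.
#' @export
two_group_ttest <- function(x, labels) {
  validate_expression(x)
  labels <- align_labels(labels, colnames(x))
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least 2 samples (got ", n1, " and ", n2, ")")
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  df <- n1 + n2 - 2
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df = df)
  degenerate <- sp2 == 0
  zero_eq <- degenerate & diff == 0
  zero_ne <- degenerate & diff != 0
  tstat[zero_eq] <- 0; p[zero_eq] <- 1
  p[zero_ne] <- 0
  data.frame(feature_id = rownames(x), t = tstat, p = p, mean_diff = diff,
             degenerate = zero_ne, stringsAsFactors = FALSE, row.names = NULL)
}

# Accepts a factor/character vector either named by sample id or aligned
# positionally; returns a two-level factor aligned with `sample_ids`.
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) stop("labels missing for samples: ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length (", length(labels), ") does not match sample count (",
         length(sample_ids), ")")
  }
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly 2 levels, got ", nlevels(f))
  f
}
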