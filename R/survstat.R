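#' Kaplan-Meier estimate of the progression-free curve
#'
#' Product-limit estimator over distinct event times, with the Greenwood
#' variance of the survival estimate at each step. Censored-only times
#' shrink the risk set but add no factor to the product.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators (1 = progression).
#' @return object of class `km_curve`: data.frame with time, n_risk,
#'   n_event, n_censor, surv, var_greenwood.
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("empty input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  d <- fit$n.event; n <- fit$n.risk; s <- fit$surv
  gw_term <- ifelse(n > d, d / (n * (n - d)), 0)
  var_gw <- s^2 * cumsum(gw_term)
  var_gw[s == 0] <- 0
  structure(data.frame(time = fit$time, n_risk = n, n_event = d,
                       n_censor = fit$n.censor, surv = s,
                       var_greenwood = var_gw),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' The standard (rho = 0) log-rank statistic: at each distinct event time
#' the observed group-1 events are compared with their hypergeometric
#' expectation E_1i = d_i n_1i / n_i, and
#' chi^2 = (sum (O_1i - E_1i))^2 / sum V_i with the hypergeometric
#' variance V_i; p from a chi-square with 1 df.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-level grouping (factor or character).
#' @return object of class `logrank_result`: chi_square, df, p, and a
#'   per-group table of n, observed and expected events.
#' @export
logrank_two_group <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 non-empty levels")
  if (any(table(group) == 0L)) stop("a group has zero samples")
  if (any(time <= 0)) stop("times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  structure(list(chi_square = unname(sd$chisq), df = 1L, p = p,
                 groups = data.frame(group = levels(group),
                                     n = as.vector(sd$n),
                                     observed = as.vector(sd$obs),
                                     expected = as.vector(sd$exp))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("log-rank test: chi-square =", signif(x$chi_square, 5),
      "on 1 df, p =", format.pval(x$p, digits = 4), "\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with the Efron tie correction by
#' Newton-Raphson (convergence tolerance 1e-9, at most 50 iterations).
#' Standard errors come from the inverse observed information; hazard
#' ratios are exp(beta) with Wald 95% confidence intervals
#' exp(beta +/- 1.96 SE). A monotone likelihood (perfect separation) is
#' flagged as non-converged rather than hidden; singular information
#' raises an error naming the collinear columns.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param covariates data.frame or matrix of numeric covariate columns
#'   (already dummy-encoded; no constant column).
#' @return object of class `cox_fit`: `table` (term, beta, se, hr,
#'   ci_low, ci_high, p), `converged`, `iterations`, `score_test` (score
#'   chi-square at beta = 0), `warnings`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (!nrow(covariates) || nrow(covariates) != length(time))
    stop("covariates must have one row per sample")
  if (!all(vapply(covariates, is.numeric, logical(1L))))
    stop("covariates must be numeric (dummy-encode categories first)")
  const <- vapply(covariates, function(v) length(unique(v)) == 1L, logical(1L))
  if (any(const)) stop("constant covariate column(s): ",
                       paste(names(covariates)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50L)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("singular information; collinear column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  diverged <- any(grepl("infinite|did not converge|Loglik converged", warns))
  tab <- data.frame(term = names(beta), beta = unname(beta), se = se,
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - 1.96 * se),
                    ci_high = exp(unname(beta) + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, converged = !diverged, iterations = fit$iter,
                 score_test = unname(fit$score), warnings = warns),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties), ",
      if (x$converged) "converged" else "NOT converged (monotone likelihood?)",
      " in ", x$iterations, " iterations\n", sep = "")
  tab <- x$table
  tab$`HR (95% CI)` <- sprintf("%.3f (%.3f - %.3f)", tab$hr, tab$ci_low, tab$ci_high)
  print(tab[, c("term", "HR (95% CI)", "p")], row.names = FALSE)
  invisible(x)
}

#' Multivariate Cox model for disease progression
#'
#' Encodes the clinical covariates with the conventional reference levels
#' (stage Ta, grade low, single tumor, size <= 3 cm, no intravesical
#' therapy, low-anchor cluster) and fits [cox_fit()] with the cluster
#' signature as the variable of interest.
#'
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param cluster_labels factor of HSC/LSC labels named by sample id.
#' @return a `cox_fit` whose table rows are stage_T1, grade_high,
#'   n_tumors_2to7, n_tumors_ge8, size_gt3cm, intravesical_therapy,
#'   signature_HSC.
#' @export
cox_progression <- function(clinical, cluster_labels) {
  clinical <- validate_clinical(clinical)
  if (is.null(names(cluster_labels)))
    stop("cluster_labels must be named by sample id")
  missing <- setdiff(clinical$sample_id, names(cluster_labels))
  if (length(missing)) stop("cluster labels missing for samples: ",
                            paste(missing, collapse = ", "))
  lab <- cluster_labels[clinical$sample_id]
  cov <- data.frame(
    stage_T1 = as.integer(clinical$stage == "T1"),
    grade_high = as.integer(clinical$grade == "high"),
    n_tumors_2to7 = as.integer(clinical$n_tumors == "2to7"),
    n_tumors_ge8 = as.integer(clinical$n_tumors == "ge8"),
    size_gt3cm = clinical$size_gt3cm,
    intravesical_therapy = clinical$intravesical_therapy,
    signature_HSC = as.integer(lab == "HSC")
  )
  cox_fit(clinical$time_months, clinical$event, cov)
}
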