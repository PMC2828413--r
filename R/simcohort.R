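#' Default per-cluster covariate distributions
#'
#' Each covariate maps to a list with elements `low` and `high` (the two
#' latent clusters), each a named probability vector over its categories.
#' Defaults are independent of cluster, so the covariates carry no
#' prognostic information beyond the expression clusters, and the marginal
#' frequencies echo a typical non-muscle invasive bladder cancer cohort
#' (mostly low-grade T1 disease).
#'
#' @return named list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  same <- function(p) list(low = p, high = p)
  list(
    stage = same(c(Ta = 0.223, T1 = 0.777)),
    grade = same(c(low = 0.835, high = 0.165)),
    n_tumors = same(c(single = 0.5, `2to7` = 0.4, ge8 = 0.1)),
    size_gt3cm = same(c(`0` = 0.7, `1` = 0.3)),
    intravesical_therapy = same(c(`0` = 0.5, `1` = 0.5))
  )
}

#' Configure a synthetic expression cohort
#'
#' The generator emulates the statistical structure the anchor-signature
#' analysis assumes: a latent two-cluster structure drives an anchor gene,
#' a block of features correlated (both signs) with the anchor, independent
#' background features, cluster-dependent exponential progression hazards
#' and uniform right-censoring, plus categorical clinical covariates.
#'
#' Defaults describe a cohort of 103 samples with a 1,000-feature
#' correlated module among 2,000 features, a 4-standard-deviation anchor
#' separation between clusters, and hazards calibrated so the expected
#' progression fraction is 10.7% over a 137-month accrual window.
#'
#' @param n_samples number of samples.
#' @param n_features total features excluding the anchor (module + background).
#' @param n_module_features number of anchor-correlated features (< n_features).
#' @param frac_negative_module fraction of module features with negative loading.
#' @param cluster_prob probability a sample belongs to the high cluster.
#' @param anchor_means length-2 numeric, low- and high-cluster anchor means (log2 units).
#' @param anchor_sd within-cluster anchor standard deviation.
#' @param module_loading_range length-2 positive range for absolute module loadings.
#' @param module_noise_sd standard deviation of module feature noise.
#' @param baseline_hazard low-cluster progression hazard per month.
#' @param hazard_ratio high- vs low-cluster hazard ratio.
#' @param censor_horizon censoring times are Uniform(0, censor_horizon) months.
#' @param covariate_spec per-cluster category probabilities, see
#'   [default_covariate_spec()].
#' @param anchor_id feature identifier for the anchor gene.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 103L,
                       n_features = 2000L,
                       n_module_features = 1000L,
                       frac_negative_module = 0.3,
                       cluster_prob = 0.49,
                       anchor_means = c(-1, 1),
                       anchor_sd = 0.5,
                       module_loading_range = c(0.4, 1),
                       module_noise_sd = 1,
                       baseline_hazard = 3.9994e-4,
                       hazard_ratio = 8,
                       censor_horizon = 137,
                       covariate_spec = default_covariate_spec(),
                       anchor_id = "S100A8",
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
              n_module_features = as.integer(n_module_features),
              frac_negative_module = frac_negative_module, cluster_prob = cluster_prob,
              anchor_means = as.numeric(anchor_means), anchor_sd = anchor_sd,
              module_loading_range = as.numeric(module_loading_range),
              module_noise_sd = module_noise_sd, baseline_hazard = baseline_hazard,
              hazard_ratio = hazard_ratio, censor_horizon = censor_horizon,
              covariate_spec = covariate_spec, anchor_id = as.character(anchor_id),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  need_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid sim_config field '", field, "': must be a positive number")
  }
  need_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid sim_config field '", field, "': must be a fraction in [0,1]")
  }
  if (cfg$n_samples < 1L) stop("invalid sim_config field 'n_samples': must be >= 1")
  if (cfg$n_features < 1L) stop("invalid sim_config field 'n_features': must be >= 1")
  if (cfg$n_module_features < 0L || cfg$n_module_features >= cfg$n_features)
    stop("invalid sim_config field 'n_module_features': must satisfy 0 <= n_module_features < n_features")
  need_frac("frac_negative_module"); need_frac("cluster_prob")
  if (length(cfg$anchor_means) != 2L || !all(is.finite(cfg$anchor_means)))
    stop("invalid sim_config field 'anchor_means': must be two finite numbers (low, high)")
  need_pos("anchor_sd"); need_pos("module_noise_sd")
  need_pos("baseline_hazard"); need_pos("hazard_ratio"); need_pos("censor_horizon")
  if (length(cfg$module_loading_range) != 2L || any(cfg$module_loading_range <= 0) ||
      cfg$module_loading_range[1L] > cfg$module_loading_range[2L])
    stop("invalid sim_config field 'module_loading_range': must be a positive increasing interval")
  if (!is.list(cfg$covariate_spec)) stop("invalid sim_config field 'covariate_spec': must be a list")
  for (nm in names(cfg$covariate_spec)) {
    sp <- cfg$covariate_spec[[nm]]
    if (!is.list(sp) || !all(c("low", "high") %in% names(sp)))
      stop("invalid sim_config field 'covariate_spec': '", nm, "' needs 'low' and 'high' entries")
    for (cl in c("low", "high")) {
      p <- sp[[cl]]
      if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("invalid sim_config field 'covariate_spec': '", nm, "' ", cl,
             " probabilities must be named, non-negative and sum to 1")
    }
  }
  if (!is.finite(cfg$seed)) stop("invalid sim_config field 'seed': must be an integer")
  invisible(cfg)
}

#' Simulate a synthetic cohort
#'
#' Draws, per sample j: cluster z_j ~ Bernoulli(cluster_prob); anchor
#' a_j ~ N(anchor_means\[z_j\], anchor_sd^2); each module feature g as
#' beta_g (a_j - mean(anchor_means)) + N(0, module_noise_sd^2) with
#' |beta_g| ~ Uniform(module_loading_range) and a `frac_negative_module`
#' share of negative signs; background features i.i.d. N(0,1); progression
#' time T_j ~ Exp(baseline_hazard * hazard_ratio^z_j), censoring
#' C_j ~ Uniform(0, censor_horizon), observed time min(T,C) with event
#' indicator \[T <= C\]; covariates per the cluster's category probabilities.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (matrix, anchor + module + background rows), `clinical` (data.frame),
#'   `true_cluster` (named 0/1 integer, 1 = high cluster) and `true_module`
#'   (data.frame feature_id, sign).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  z <- rbinom(n, 1L, config$cluster_prob)
  anchor <- rnorm(n, mean = config$anchor_means[z + 1L], sd = config$anchor_sd)
  centered <- anchor - mean(config$anchor_means)

  n_mod <- config$n_module_features
  n_bg <- config$n_features - n_mod
  module_ids <- if (n_mod) sprintf("MOD%04d", seq_len(n_mod)) else character(0)
  bg_ids <- if (n_bg) sprintf("BG%04d", seq_len(n_bg)) else character(0)

  if (n_mod) {
    beta <- runif(n_mod, config$module_loading_range[1L], config$module_loading_range[2L])
    n_neg <- round(config$frac_negative_module * n_mod)
    sign_g <- rep(c(-1, 1), c(n_neg, n_mod - n_neg))
    beta <- beta * sign_g
    module <- outer(beta, centered) +
      matrix(rnorm(n_mod * n, sd = config$module_noise_sd), n_mod, n)
  } else {
    beta <- numeric(0); sign_g <- numeric(0)
    module <- matrix(numeric(0), 0L, n)
  }
  background <- matrix(rnorm(n_bg * n), n_bg, n)

  expr <- rbind(matrix(anchor, 1L, n), module, background)
  dimnames(expr) <- list(c(config$anchor_id, module_ids, bg_ids), sample_ids)

  rate <- config$baseline_hazard * config$hazard_ratio^z
  t_prog <- rexp(n, rate = rate)
  t_cens <- runif(n, 0, config$censor_horizon)
  time_obs <- pmin(t_prog, t_cens)
  event <- as.integer(t_prog <= t_cens)

  clin <- data.frame(sample_id = sample_ids, time_months = time_obs, event = event,
                     stringsAsFactors = FALSE)
  for (nm in names(config$covariate_spec)) {
    sp <- config$covariate_spec[[nm]]
    vals <- character(n)
    for (cl in c(0L, 1L)) {
      idx <- which(z == cl)
      p <- sp[[if (cl == 0L) "low" else "high"]]
      if (length(idx)) vals[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    clin[[nm]] <- vals
  }
  clin$size_gt3cm <- as.integer(clin$size_gt3cm)
  clin$intravesical_therapy <- as.integer(clin$intravesical_therapy)
  clin <- validate_clinical(clin[CLINICAL_COLUMNS])

  structure(list(
    expression = expr,
    clinical = clin,
    true_cluster = setNames(z, sample_ids),
    true_module = data.frame(feature_id = module_ids,
                             sign = as.integer(sign(beta)),
                             stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_cohort")
}

#' Analytic expected event fraction under the generator
#'
#' For an Exponential(lambda) progression time censored by an independent
#' Uniform(0, tau) time, P(event) = 1 - (1 - exp(-lambda tau)) / (lambda tau).
#' The cohort value mixes the two cluster-specific hazards by
#' `cluster_prob`.
#'
#' @param config a [sim_config()].
#' @return expected fraction of samples observed to progress.
#' @export
expected_event_fraction <- function(config) {
  validate_sim_config(config)
  p_event <- function(lambda) {
    lt <- lambda * config$censor_horizon
    1 - (1 - exp(-lt)) / lt
  }
  (1 - config$cluster_prob) * p_event(config$baseline_hazard) +
    config$cluster_prob * p_event(config$baseline_hazard * config$hazard_ratio)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv` and `clinical.tsv` in the package's TSV dialects
#' plus two-column ground-truth files `true_cluster.tsv` (sample_id,
#' cluster) and `true_module.tsv` (feature_id, sign).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(outdir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(outdir, "clinical.tsv"))
  write.table(data.frame(sample_id = names(cohort$true_cluster),
                         cluster = unname(cohort$true_cluster)),
              file.path(outdir, "true_cluster.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$true_module, file.path(outdir, "true_module.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "features (",
      nrow(x$true_module), "module +",
      nrow(x$expression) - nrow(x$true_module) - 1L, "background + anchor )\n")
  cat("  events:", sum(x$clinical$event), "/", nrow(x$clinical),
      " high-cluster samples:", sum(x$true_cluster), "\n")
  invisible(x)
}
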