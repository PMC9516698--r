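# Per-feature cohort comparison: Welch t-tests / one-way ANOVA, fold changes,
# a Gibbs-sampled Bayesian probability of up-regulation, and the
# pseudo-internal-standard measurement-noise QC.

#' Per-feature frequentist tests and fold changes
#'
#' Two-tailed Welch t-test and one-way ANOVA (Welch form; identical to the
#' t-test for two groups) on each feature row, plus the raw fold change
#' `mean(test group) / mean(reference group)`. Raw `p < alpha` defines the
#' `significant` flag; Benjamini-Hochberg q-values are reported additionally.
#'
#' @param fm A `feature_matrix` with a two-level `group` column in
#'   `fm$samples`.
#' @param group_test,group_ref Group labels; default `"PD"` vs `"control"`.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return data.frame: `feature_id`, group means, `fold_change`,
#'   `log_fold_change` (natural log), `t_p`, `anova_p`, `q_value`,
#'   `significant`.
#' @export
t_test_features <- function(fm, group_test = "PD", group_ref = "control",
                            alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  g <- fm$samples$group
  a <- fm$intensity[, g == group_test, drop = FALSE]
  b <- fm$intensity[, g == group_ref, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("both groups need at least 2 samples")
  n <- nrow(fm$intensity)
  t_p <- anova_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xa <- a[i, ]; xb <- b[i, ]
    p <- tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) 1)
    t_p[i] <- p
    anova_p[i] <- tryCatch(
      stats::oneway.test(v ~ grp, data.frame(
        v = c(xa, xb), grp = rep(c("a", "b"), c(length(xa), length(xb)))))$p.value,
      error = function(e) 1)
  }
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  fc <- ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
  fc[mean_a == mean_b] <- 1
  data.frame(feature_id = fm$features$feature_id,
             mean_test = mean_a, mean_ref = mean_b,
             fold_change = fc, log_fold_change = log(fc),
             t_p = t_p, anova_p = anova_p,
             q_value = stats::p.adjust(t_p, method = "BH"),
             significant = !is.na(t_p) & t_p < alpha)
}

#' Bayesian model configuration
#'
#' @param p_reliability Prior probability that an intensity observation is
#'   correctly assigned to its feature (0 < p <= 1; default 0.95).
#' @param lambda_scale Prior scale Lambda of the group-mean distribution, in
#'   units of the feature's intensity spread (default 10, weakly informative).
#' @param n_iterations Gibbs iterations (default 100, as small direct-infusion
#'   workflows typically run; note the wide Monte-Carlo error at this length).
#' @param burn_in Discarded initial iterations (default 10).
#' @param seed Integer seed for the sampler.
#' @return A `bayes_config` list.
#' @export
bayes_config <- function(p_reliability = 0.95, lambda_scale = 10,
                         n_iterations = 100L, burn_in = 10L, seed = 1L) {
  if (p_reliability <= 0 || p_reliability > 1) {
    stop("p_reliability must be in (0, 1]")
  }
  if (lambda_scale <= 0) stop("lambda_scale must be positive")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  structure(list(p_reliability = p_reliability, lambda_scale = lambda_scale,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "bayes_config")
}

# truncated normal draw, upper-bounded at `upper`
rtruncnorm_upper <- function(n, mean, sd, upper) {
  p_up <- stats::pnorm(upper, mean, sd)
  p_up <- pmax(p_up, 1e-12)
  stats::qnorm(stats::runif(n) * p_up, mean, sd)
}

# Gibbs sampler for one feature. y: log intensities; cens: TRUE where the
# observation is a left-censored zero (y holds the per-sample floor);
# g: logical, TRUE = test group.
gibbs_one_feature <- function(y, cens, g, cfg) {
  obs <- y[!cens]
  m0 <- mean(obs)
  s0 <- max(stats::sd(obs), 0.25, na.rm = TRUE)
  if (!is.finite(s0)) s0 <- 0.25
  tau2 <- (cfg$lambda_scale * s0)^2     # prior variance of group means
  bg_sd <- 5 * s0                       # broad mis-assignment background
  a0 <- 2; b0 <- s0^2                   # inverse-gamma prior on sigma^2
  p <- cfg$p_reliability
  mu <- c(test = mean(y[g]), ref = mean(y[!g]))
  sigma2 <- s0^2
  yy <- y
  n_keep <- cfg$n_iterations - cfg$burn_in
  diffs <- numeric(n_keep)
  for (it in seq_len(cfg$n_iterations)) {
    mu_i <- ifelse(g, mu["test"], mu["ref"])
    # impute left-censored observations from the truncated model
    if (any(cens)) {
      yy[cens] <- rtruncnorm_upper(sum(cens), mu_i[cens], sqrt(sigma2),
                                   y[cens])
    }
    # latent correct-assignment indicators
    if (p < 1) {
      w1 <- p * stats::dnorm(yy, mu_i, sqrt(sigma2))
      w0 <- (1 - p) * stats::dnorm(yy, m0, bg_sd)
      r <- stats::runif(length(yy)) < w1 / (w1 + w0)
    } else {
      r <- rep(TRUE, length(yy))
    }
    # conjugate updates of the group means
    for (grp in c(TRUE, FALSE)) {
      sel <- r & (g == grp)
      ng <- sum(sel)
      prec <- ng / sigma2 + 1 / tau2
      mean_post <- (sum(yy[sel]) / sigma2 + m0 / tau2) / prec
      mu[if (grp) "test" else "ref"] <- stats::rnorm(1, mean_post,
                                                     sqrt(1 / prec))
    }
    # conjugate update of the shared variance
    mu_i <- ifelse(g, mu["test"], mu["ref"])
    ss <- sum((yy[r] - mu_i[r])^2)
    sigma2 <- 1 / stats::rgamma(1, a0 + sum(r) / 2, b0 + ss / 2)
    if (it > cfg$burn_in) diffs[it - cfg$burn_in] <- mu["test"] - mu["ref"]
  }
  diffs
}

#' Bayesian probability of up-regulation
#'
#' Per-feature hierarchical mixture model on natural-log intensities:
#' observations are Normal around their group mean with a shared variance
#' (Normal / inverse-gamma conjugate priors scaled by `lambda_scale`), each
#' observation carries a latent correct-assignment indicator with prior
#' `p_reliability` (mis-assigned points come from a broad background), and
#' zeros are treated as left-censored at the per-sample detection floor.
#' A Gibbs sampler alternates censored-value imputation, indicators, group
#' means and variance; the posterior of `mu_test - mu_ref` gives the natural
#' log fold change, a central 95% credible interval, and the probability of
#' up-regulation `P(mu_test > mu_ref)`.
#'
#' @inheritParams t_test_features
#' @param cfg A [bayes_config()].
#' @param feature_ids Optional subset of feature ids to analyse.
#' @return data.frame: `feature_id`, `log_fold_change` (natural log posterior
#'   mean), `ci_low`, `ci_high` (95% credible), `probability_up`,
#'   `probability_down`, `flag` (`"ok"` or `"degenerate"` for all-zero
#'   features). Reproducible under a fixed `cfg$seed`.
#' @export
bayes_upregulation <- function(fm, cfg = bayes_config(), group_test = "PD",
                               group_ref = "control", feature_ids = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "bayes_config"))
  set.seed(cfg$seed)
  keep <- fm$samples$group %in% c(group_test, group_ref)
  x <- fm$intensity[, keep, drop = FALSE]
  g <- fm$samples$group[keep] == group_test
  if (!is.null(feature_ids)) {
    x <- x[fm$features$feature_id %in% feature_ids, , drop = FALSE]
  }
  # per-sample detection floor: half the smallest positive intensity
  floors <- apply(x, 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) == 0) 1 else min(pos) / 2
  })
  n <- nrow(x)
  out <- data.frame(feature_id = rownames(x),
                    log_fold_change = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, probability_up = NA_real_,
                    probability_down = NA_real_, flag = "degenerate",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- x[i, ]
    if (all(v[g] == 0) || all(v[!g] == 0)) next   # flagged, not crashed
    cens <- v == 0
    y <- ifelse(cens, log(floors), log(pmax(v, .Machine$double.xmin)))
    diffs <- gibbs_one_feature(y, cens, g, cfg)
    qs <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
    out$log_fold_change[i] <- mean(diffs)
    out$ci_low[i] <- qs[1]; out$ci_high[i] <- qs[2]
    out$probability_up[i] <- mean(diffs > 0)
    out$probability_down[i] <- 1 - out$probability_up[i]
    out$flag[i] <- "ok"
  }
  rownames(out) <- NULL
  out
}

#' Pseudo-internal-standard QC
#'
#' Locates the three drift-separated low-m/z matrix ions nominated as pseudo
#' internal standards (103.05 Th/1.0 ms, 105.07 Th/1.0 ms, 109.10 Th/1.2 ms
#' by default), t-tests their intensities between cohorts, and reports PASS
#' when all standards are found and show no significant group difference
#' (p >= alpha), WARN when a standard is missing, FAIL when one differs. Also
#' reports the per-sample summed intensity (sebum biomass proxy) and its
#' group association.
#'
#' @inheritParams t_test_features
#' @param standards data.frame with `mz` and `drift_time` of the standard
#'   ions.
#' @param mz_tol Absolute m/z search tolerance in Th (default 0.02).
#' @param dt_tol Drift-time search tolerance in ms (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @return List with `status` (`"PASS"`, `"WARN"` or `"FAIL"`), `standards`
#'   (per-ion table: found, feature id, group means, p-value), and `biomass`
#'   (per-sample summed intensity with its group t-test p-value).
#' @export
qc_pseudo_standards <- function(fm,
                                standards = data.frame(
                                  mz = c(103.05, 105.07, 109.10),
                                  drift_time = c(1.0, 1.0, 1.2)),
                                mz_tol = 0.02, dt_tol = 0.3,
                                group_test = "PD", group_ref = "control",
                                alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  g <- fm$samples$group
  res <- lapply(seq_len(nrow(standards)), function(i) {
    d_mz <- abs(fm$features$mz - standards$mz[i])
    d_dt <- abs(fm$features$drift_time - standards$drift_time[i])
    hit <- which(d_mz <= mz_tol & d_dt <= dt_tol)
    if (length(hit) == 0) {
      return(data.frame(mz = standards$mz[i],
                        drift_time = standards$drift_time[i], found = FALSE,
                        feature_id = NA_character_, mean_test = NA_real_,
                        mean_ref = NA_real_, p_value = NA_real_))
    }
    hit <- hit[which.min(d_mz[hit])]
    v <- fm$intensity[hit, ]
    a <- v[g == group_test]; b <- v[g == group_ref]
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    data.frame(mz = standards$mz[i], drift_time = standards$drift_time[i],
               found = TRUE, feature_id = fm$features$feature_id[hit],
               mean_test = mean(a), mean_ref = mean(b), p_value = p)
  })
  tab <- do.call(rbind, res)
  status <- if (!all(tab$found)) "WARN"
            else if (any(tab$p_value < alpha)) "FAIL"
            else "PASS"
  tic <- colSums(fm$intensity)
  biomass_p <- tryCatch(
    stats::t.test(tic[g == group_test], tic[g == group_ref])$p.value,
    error = function(e) NA_real_)
  list(status = status, standards = tab,
       biomass = list(per_sample = data.frame(
         sample_id = fm$samples$sample_id, group = g,
         summed_intensity = unname(tic)),
         group_p_value = biomass_p))
}
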