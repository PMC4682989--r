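#' Sample-level homophily ratio
#'
#' Observed over expected cross-group referral ties:
#' \code{cross / (T * 2 p (1 - p))}, with \code{T} the number of referral
#' ties and \code{p} the (unweighted) sample proportion with attribute 1.
#' A value of 1 matches proportionate mixing; 0 means no cross-group
#' referrals at all. Undefined (NA) when only one category is present.
#'
#' @param forest a \code{recruitment_forest} with at least one referral.
#' @return The homophily ratio, or NA for a single-category sample.
#' @export
homophily_ratio <- function(forest) {
  rec <- forest$records
  pr <- rec$recruiter_row
  kids <- which(!is.na(pr))
  if (!length(kids)) stop_fmt("sample has no referral ties")
  p <- mean(rec$y)
  if (p == 0 || p == 1) return(NA_real_)
  cross <- sum(rec$y[kids] != rec$y[pr[kids]])
  cross / (length(kids) * 2 * p * (1 - p))
}

#' Replicated RDS simulation study on one network
#'
#' Draws \code{r} independent branching RDS samples, applies the requested
#' variance estimators to each, and aggregates the study metrics: the
#' population sampling variance (mean squared deviation of replicate RDS-2
#' means around the true mean), per-method bias (mean estimated variance
#' minus population sampling variance), ratio, 95\% coverage rate, and
#' empirical / estimated design effects, together with a split of the
#' aggregates by the sample-level FOM verdict (not-FOM vs may-be-FOM
#' panels). Replicates are driven by independent sub-seeds derived from
#' \code{seed}, so the full study is reproducible bit for bit.
#'
#' @param net a connected \code{rds_network}.
#' @param s sample size per replicate.
#' @param r number of replicates (>= 2).
#' @param methods subset of \code{c("vhe", "vhewbc", "vhehom2", "vhehom3",
#'   "sbe")}; may be empty, in which case only the sampling distribution is
#'   summarized.
#' @param seed master integer seed.
#' @param branch_probs,with_replacement passed to \code{\link{rds_sample}}.
#' @param b_boot bootstrap replicates for the SBE.
#' @param fom_level significance level for the per-sample FOM verdict.
#' @return An object of class \code{rds_study}: \code{replicates} (one row
#'   per replicate with the mean, per-method variance estimates and
#'   coverage hits, FOM verdict and homophily ratio) and \code{aggregates}.
#' @export
run_study <- function(net, s = 200L, r = 500L, methods = c("vhe", "sbe"),
                      seed = 1L, branch_probs = c(1/3, 1/6, 1/6, 1/3),
                      with_replacement = TRUE, b_boot = 1000L,
                      fom_level = 0.05) {
  stopifnot(r >= 2)
  methods <- unique(methods)
  known <- c("vhe", "vhewbc", "vhehom2", "vhehom3", "sbe")
  if (length(setdiff(methods, known))) {
    stop_fmt("unknown method(s): %s", paste(setdiff(methods, known), collapse = ", "))
  }
  mu <- mean(net$y)
  seeds <- derive_seeds(seed, 2L * r)
  rows <- vector("list", r)
  for (i in seq_len(r)) {
    f <- rds_sample(net, s, branch_probs = branch_probs,
                    with_replacement = with_replacement, seed = seeds[i])
    row <- data.frame(replicate = i, mean = rds2_mean(f))
    ft <- fom_test(f, level = "sample")
    row$fom_p <- ft$p_value
    row$fom_verdict <- if (is.na(ft$f_stat)) "may_be_FOM" else {
      if (ft$p_value < fom_level) "reject" else "may_be_FOM"
    }
    row$homophily <- tryCatch(homophily_ratio(f), error = function(e) NA_real_)
    for (m in methods) {
      est <- tryCatch(
        estimate_variance(f, m, b = b_boot, seed = seeds[r + i]),
        error = function(e) NULL)
      row[[paste0("var_", m)]] <- if (is.null(est)) NA_real_ else est$variance
      row[[paste0("cover_", m)]] <- if (is.null(est)) NA else coverage_hit(est, mu)
    }
    rows[[i]] <- row
  }
  reps <- do.call(rbind, rows)
  agg <- summarize_study(reps, mu, s, methods)
  structure(list(network_n = length(net$nodes), mu = mu, s = s, r = r,
                 methods = methods, replicates = reps, aggregates = agg),
            class = "rds_study")
}

summarize_study <- function(reps, mu, s, methods) {
  popvar <- empirical_sampling_variance(reps$mean, mu)
  srs <- mu * (1 - mu) / s
  agg <- list(mu = mu, population_sampling_variance = popvar,
              empirical_design_effect = if (srs > 0) popvar / srs else NA_real_)
  for (m in methods) {
    v <- reps[[paste0("var_", m)]]
    cv <- reps[[paste0("cover_", m)]]
    agg[[m]] <- list(
      mean_estimated_variance = mean(v, na.rm = TRUE),
      bias = mean(v, na.rm = TRUE) - popvar,
      ratio = mean(v, na.rm = TRUE) / popvar,
      coverage = mean(cv, na.rm = TRUE),
      mean_estimated_design_effect = if (srs > 0) mean(v, na.rm = TRUE) / srs
                                     else NA_real_)
  }
  panels <- split(seq_len(nrow(reps)), reps$fom_verdict == "reject")
  agg$panels <- lapply(list(not_fom = panels[["TRUE"]],
                            may_be_fom = panels[["FALSE"]]), function(ix) {
    if (is.null(ix) || length(ix) < 2L) return(NULL)
    sub <- reps[ix, , drop = FALSE]
    out <- list(n = length(ix),
                empirical_de = empirical_sampling_variance(sub$mean, mu) / srs)
    for (m in methods) {
      out[[paste0(m, "_estimated_de")]] <-
        mean(sub[[paste0("var_", m)]], na.rm = TRUE) / srs
      out[[paste0(m, "_coverage")]] <- mean(sub[[paste0("cover_", m)]], na.rm = TRUE)
    }
    out
  })
  agg
}

#' @export
print.rds_study <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("rds_study: %d replicates of size %d (N = %d, mu = %.3f)\n",
              x$r, x$s, x$network_n, x$mu))
  cat(sprintf("population sampling variance %.6g (empirical DE %.2f)\n",
              a$population_sampling_variance, a$empirical_design_effect))
  for (m in x$methods) {
    cat(sprintf("  %-8s mean var %.6g  bias %+.3g  ratio %.3f  coverage %.3f\n",
                m, a[[m]]$mean_estimated_variance, a[[m]]$bias,
                a[[m]]$ratio, a[[m]]$coverage))
  }
  invisible(x)
}

#' Per-replicate table of a study, suitable for CSV export
#'
#' @param x an \code{rds_study}.
#' @param ... unused.
#' @return The replicate-level data frame.
#' @export
as.data.frame.rds_study <- function(x, ...) x$replicates

#' Regression of variance-estimate bias on sample homophily
#'
#' Standardized (mean 0, sd 1) OLS of per-sample bias in the variance
#' estimate on the per-sample homophily ratio, optionally absorbing network
#' fixed effects (within-network demeaning of both standardized variables).
#' Replicates with undefined homophily or bias are dropped listwise and
#' counted. Robust (HC1) standard errors.
#'
#' @param per_sample data frame with columns \code{network}, \code{bias},
#'   \code{homophily}.
#' @param standardize logical; default TRUE (XY-standardized regression).
#' @param fixed_effects logical; absorb network indicators.
#' @return List with \code{coef} (slope), \code{se} (robust), \code{r2},
#'   \code{n_used}, \code{n_dropped}.
#' @export
bias_homophily_regression <- function(per_sample, standardize = TRUE,
                                      fixed_effects = FALSE) {
  need <- c("network", "bias", "homophily")
  stopifnot(all(need %in% names(per_sample)))
  ok <- stats::complete.cases(per_sample[, c("bias", "homophily")])
  d <- per_sample[ok, , drop = FALSE]
  dropped <- sum(!ok)
  if (nrow(d) < 3L) stop_fmt("too few usable replicates")
  if (stats::sd(d$bias) == 0 || stats::sd(d$homophily) == 0) {
    stop_fmt("zero variance in bias or homophily")
  }
  if (fixed_effects && length(unique(d$network)) < 2L) {
    stop_fmt("fixed effects require at least two networks")
  }
  if (standardize) {
    d$bias <- as.numeric(scale(d$bias))
    d$homophily <- as.numeric(scale(d$homophily))
  }
  if (fixed_effects) {
    fit <- stats::lm(bias ~ homophily + factor(network), data = d)
  } else {
    fit <- stats::lm(bias ~ homophily, data = d)
  }
  V <- sandwich::vcovHC(fit, type = "HC1")
  list(coef = unname(stats::coef(fit)["homophily"]),
       se = unname(sqrt(V["homophily", "homophily"])),
       r2 = summary(fit)$r.squared,
       n_used = nrow(d), n_dropped = dropped)
}

#' Correlation of mean estimated and population sampling variance
#'
#' Pearson correlation across networks between each network's mean
#' estimated sampling variance (for one method) and its population sampling
#' variance. A high correlation would mean the estimator could be rescued
#' by a constant inflation factor even if biased.
#'
#' @param results list of \code{rds_study} objects (>= 3 networks).
#' @param method method name present in every study.
#' @return The correlation, or NA if either vector has zero variance.
#' @export
cross_network_correlation <- function(results, method) {
  stopifnot(length(results) >= 3L)
  est <- vapply(results, function(st) {
    st$aggregates[[method]]$mean_estimated_variance
  }, 0)
  pop <- vapply(results, function(st) {
    st$aggregates$population_sampling_variance
  }, 0)
  if (stats::sd(est) == 0 || stats::sd(pop) == 0) return(NA_real_)
  stats::cor(est, pop)
}
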