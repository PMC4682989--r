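#' Neighborhood-proportion observations for the FOM diagnostic
#'
#' Builds the observation table behind the first-order-Markov test. At the
#' network level there is one observation per ordered adjacent pair
#' (ego, alter): the response is the proportion of alter's neighbors - with
#' ego counted among them - whose attribute is 1, and the predictors are
#' alter's and ego's attribute values. At the sample level the pairs are
#' recruiter -> recruit referrals, and the recruit's neighborhood is taken
#' in the sampled relation: the recruit's own recruits plus the recruiter
#' (mirroring the ego-inclusion rule, which also keeps pendant recruits in
#' the table).
#'
#' @param x an \code{rds_network} (network level) or
#'   \code{recruitment_forest} (sample level).
#' @param level \code{"network"} or \code{"sample"}; inferred from the class
#'   of \code{x} when omitted.
#' @param ego_rule how ego enters alter's neighborhood: \code{"union"}
#'   (ego counted once; at network level ego is already a neighbor of alter,
#'   so the response is the mean attribute over alter's neighbors) or
#'   \code{"multiset"} (ego appended as an extra element even when already
#'   present).
#' @param orientation \code{"both"} (two observations per undirected edge,
#'   one per ordering - the default, since the ego and alter roles are
#'   asymmetric) or \code{"random"} (one observation per edge, orientation
#'   drawn with \code{seed}; sensitivity option).
#' @param seed seed for \code{orientation = "random"}.
#' @return Data frame with columns \code{ego}, \code{alter}, \code{resp},
#'   \code{y_alter}, \code{y_ego}.
#' @export
neighborhood_observations <- function(x, level = NULL,
                                      ego_rule = c("union", "multiset"),
                                      orientation = c("both", "random"),
                                      seed = NULL) {
  ego_rule <- match.arg(ego_rule)
  orientation <- match.arg(orientation)
  level <- level %||% if (inherits(x, "recruitment_forest")) "sample" else "network"
  if (level == "network") {
    stopifnot(inherits(x, "rds_network"))
    if (!x$m) stop_fmt("network has no edges")
    e <- x$edges
    if (orientation == "both") {
      ego <- c(e[, 1L], e[, 2L]); alter <- c(e[, 2L], e[, 1L])
    } else {
      flip <- with_seed(seed, stats::runif(nrow(e)) < 0.5)
      ego <- ifelse(flip, e[, 2L], e[, 1L])
      alter <- ifelse(flip, e[, 1L], e[, 2L])
    }
    deg <- x$degree
    nbsum <- numeric(length(x$nodes))   # sum of neighbors' y per node
    for (k in 1:2) {
      from <- e[, k]; to <- e[, 3L - k]
      agg <- tapply(x$y[to], from, sum)
      ix <- as.integer(names(agg))
      nbsum[ix] <- nbsum[ix] + as.numeric(agg)
    }
    if (ego_rule == "union") {
      resp <- nbsum[alter] / deg[alter]          # ego already a neighbor
    } else {
      resp <- (nbsum[alter] + x$y[ego]) / (deg[alter] + 1)
    }
    data.frame(ego = x$nodes[ego], alter = x$nodes[alter], resp = resp,
               y_alter = x$y[alter], y_ego = x$y[ego],
               stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(x, "recruitment_forest"))
    rec <- x$records
    pr <- rec$recruiter_row
    kids <- which(!is.na(pr))
    if (!length(kids)) stop_fmt("sample has no referrals")
    # recruits of each record
    ksum <- tapply(rec$y[kids], pr[kids], sum)
    kcnt <- table(pr[kids])
    nb_sum <- numeric(x$s); nb_cnt <- numeric(x$s)
    ix <- as.integer(names(ksum))
    nb_sum[ix] <- as.numeric(ksum); nb_cnt[ix] <- as.numeric(kcnt)
    ego <- pr[kids]; alter <- kids
    # recruit's sampled neighborhood = own recruits + the recruiter
    resp <- (nb_sum[alter] + rec$y[ego]) / (nb_cnt[alter] + 1)
    data.frame(ego = rec$id[ego], alter = rec$id[alter], resp = resp,
               y_alter = rec$y[alter], y_ego = rec$y[ego],
               stringsAsFactors = FALSE)
  }
}

#' First-order-Markov regression test
#'
#' Fits the OLS regression
#' \deqn{Pr(Y_s) = \beta_0 + \beta_1 Y_{s-1} + \beta_2 Y_{s-2} +
#'   \beta_3 (Y_{s-1} \times Y_{s-2}) + \delta}
#' on a neighborhood-observation table, with heteroskedasticity-consistent
#' (HC1) standard errors, and evaluates the joint Wald F-test of
#' \eqn{\beta_2 = \beta_3 = 0} against F(2, n - 4). Rejection is a
#' sufficient condition for the process not being first-order Markov. An
#' incomputable regression (constant response or collinear design, e.g. a
#' single-category sample) yields an undefined verdict, which downstream
#' summaries count as "may be FOM".
#'
#' @param obs observation table from
#'   \code{\link{neighborhood_observations}} (needs >= 5 rows).
#' @return An object of class \code{fom_test}: \code{beta},
#'   \code{robust_cov}, \code{f_stat}, \code{p_value}, \code{n_obs}, and
#'   \code{verdict} - a character vector at levels 0.05, 0.01, 0.001 with
#'   values \code{"reject"} (not FOM), \code{"may_be_FOM"} or
#'   \code{"undefined"}.
#' @export
fom_regression <- function(obs) {
  res <- list(beta = rep(NA_real_, 4L), robust_cov = matrix(NA_real_, 4L, 4L),
              f_stat = NA_real_, p_value = NA_real_, n_obs = nrow(obs),
              verdict = c(`0.05` = "undefined", `0.01` = "undefined",
                          `0.001` = "undefined"))
  class(res) <- "fom_test"
  if (nrow(obs) < 5L) return(res)
  if (stats::var(obs$resp) == 0 || stats::var(obs$y_alter) == 0 ||
      stats::var(obs$y_ego) == 0) {
    return(res)
  }
  fit <- stats::lm(resp ~ y_alter * y_ego, data = obs)
  beta <- stats::coef(fit)
  if (anyNA(beta)) return(res)   # rank-deficient design
  # near-singular covariances (hat values ~1 in tiny samples) surface as a
  # warning here and an undefined verdict below
  V <- suppressWarnings(sandwich::vcovHC(fit, type = "HC1"))
  b23 <- beta[c("y_ego", "y_alter:y_ego")]
  V23 <- V[c("y_ego", "y_alter:y_ego"), c("y_ego", "y_alter:y_ego")]
  Fstat <- if (max(abs(b23)) < 1e-12) {
    0   # exact null fit (possibly zero residuals, where V23 is singular)
  } else {
    tryCatch(drop(crossprod(b23, solve(V23, b23))) / 2,
             error = function(e) NA_real_)
  }
  if (!is.finite(Fstat) || Fstat < 0) return(res)
  p <- stats::pf(Fstat, 2, nrow(obs) - 4L, lower.tail = FALSE)
  res$beta <- unname(beta)
  res$robust_cov <- V
  res$f_stat <- Fstat
  res$p_value <- p
  res$verdict <- vapply(c(0.05, 0.01, 0.001), function(a) {
    if (p < a) "reject" else "may_be_FOM"
  }, "")
  names(res$verdict) <- c("0.05", "0.01", "0.001")
  res
}

#' @export
print.fom_test <- function(x, ...) {
  if (is.na(x$f_stat)) {
    cat("FOM test: undefined (degenerate observations) -> may be FOM\n")
  } else {
    cat(sprintf("FOM test: F = %.3f on (2, %d) df, p = %.4g; verdict at 0.05: %s\n",
                x$f_stat, x$n_obs - 4L, x$p_value, x$verdict[["0.05"]]))
    cat(sprintf("beta: %s\n", paste(sprintf("%.4f", x$beta), collapse = ", ")))
  }
  invisible(x)
}

#' Run the FOM diagnostic on a network or a sample
#'
#' Convenience wrapper: builds the observation table and runs
#' \code{\link{fom_regression}}.
#'
#' @inheritParams neighborhood_observations
#' @return A \code{fom_test}.
#' @export
fom_test <- function(x, level = NULL, ego_rule = c("union", "multiset"),
                     orientation = c("both", "random"), seed = NULL) {
  obs <- tryCatch(
    neighborhood_observations(x, level = level, ego_rule = ego_rule,
                              orientation = orientation, seed = seed),
    error = function(e) NULL)
  if (is.null(obs)) {
    return(fom_regression(data.frame(resp = numeric(0), y_alter = numeric(0),
                                     y_ego = numeric(0))))
  }
  fom_regression(obs)
}

#' Tidy one-row summary of a FOM test
#'
#' @param x a \code{fom_test}.
#' @param ... unused.
#' @return One-row data frame with the coefficients, F statistic, p-value
#'   and verdicts, suitable for CSV export.
#' @export
as.data.frame.fom_test <- function(x, ...) {
  data.frame(n_obs = x$n_obs,
             beta0 = x$beta[1L], beta1 = x$beta[2L],
             beta2 = x$beta[3L], beta3 = x$beta[4L],
             f_stat = x$f_stat, p_value = x$p_value,
             verdict_05 = x$verdict[["0.05"]],
             verdict_01 = x$verdict[["0.01"]],
             verdict_001 = x$verdict[["0.001"]],
             stringsAsFactors = FALSE)
}
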