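#' RDS-2 (Volz-Heckathorn) mean estimator
#'
#' Inverse-degree-weighted sample mean
#' \eqn{\hat\mu = \sum_j Y_j/d_j \big/ \sum_j 1/d_j}, which undoes the
#' degree-proportional inclusion probabilities of a stationary walk.
#'
#' @param forest a \code{recruitment_forest}; all degrees must be >= 1.
#' @return The estimated population proportion.
#' @export
rds2_mean <- function(forest) {
  d <- forest$records$degree
  y <- forest$records$y
  if (any(is.na(d)) || any(d < 1)) stop_fmt("degrees must all be >= 1")
  sum(y / d) / sum(1 / d)
}

# All maximal ancestor windows: for each record with at least `len - 1`
# linked ancestors, the y-sequence of the window of length `len` ending at it
# (oldest first). Returns a character matrix, one row per window.
ancestor_windows <- function(forest, len) {
  pr <- forest$records$recruiter_row
  y <- forest$records$y
  s <- forest$s
  out <- matrix(NA_integer_, s, len)
  ok <- rep(TRUE, s)
  for (i in seq_len(s)) {
    at <- i
    for (k in len:1) {
      if (is.na(at)) { ok[i] <- FALSE; break }
      out[i, k] <- y[at]
      at <- pr[at]
    }
  }
  out[ok, , drop = FALSE]
}

hist_labels <- function(order) {
  if (order == 1L) return(c("0", "1"))
  prev <- hist_labels(order - 1L)
  as.vector(t(outer(prev, c("0", "1"), paste0)))
}

#' Estimate category transition probabilities from a sample
#'
#' Row-normalized tallies of the attribute transitions along recruiter
#' chains. Order 1 is the classic 2-by-2 matrix C over recruiter -> recruit
#' pairs. Orders 2 and 3 estimate higher-order chains over history states
#' (the most recent 2 or 3 attribute values): a 4-by-4 matrix with 8
#' structural zeros, or an 8-by-8 matrix with 48, populated from
#' grandparent-parent-child triples and 4-chains within recruitment trees.
#' Rows never observed as a history are undefined (NA).
#'
#' @param forest a \code{recruitment_forest}.
#' @param order 1, 2 or 3.
#' @param smooth logical; for order 1 only, symmetrize the pair tallies
#'   (reciprocity smoothing). Off by default.
#' @return An object of class \code{rds_transitions}: \code{order},
#'   \code{counts}, \code{matrix} (row-stochastic, NA rows where undefined),
#'   \code{states}, \code{state_y} (attribute of the most recent element),
#'   \code{hist_freq} (empirical history-state frequencies),
#'   \code{degenerate} (TRUE when only one category was observed).
#' @export
estimate_transitions <- function(forest, order = 1L, smooth = FALSE) {
  order <- as.integer(order)
  stopifnot(order %in% 1:3)
  win <- ancestor_windows(forest, order + 1L)
  if (!nrow(win)) {
    stop_fmt("insufficient linked chains of length %d for an order-%d estimate",
             order + 1L, order)
  }
  states <- hist_labels(order)
  from <- apply(win[, 1:order, drop = FALSE], 1L, paste0, collapse = "")
  to <- apply(win[, 2:(order + 1L), drop = FALSE], 1L, paste0, collapse = "")
  counts <- table(factor(from, levels = states), factor(to, levels = states))
  counts <- matrix(as.numeric(counts), length(states), length(states),
                   dimnames = list(states, states))
  if (smooth && order == 1L) {
    counts <- (counts + t(counts)) / 2
  }
  hw <- ancestor_windows(forest, order)
  hstates <- apply(hw, 1L, paste0, collapse = "")
  hf <- as.numeric(table(factor(hstates, levels = states)))
  hf <- hf / sum(hf)
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA)
  state_y <- as.integer(substring(states, order, order))
  structure(
    list(order = order, counts = counts, matrix = P, states = states,
         state_y = state_y, hist_freq = stats::setNames(hf, states),
         n_chains = nrow(win),
         degenerate = length(unique(forest$records$y)) < 2L),
    class = "rds_transitions")
}

#' @export
print.rds_transitions <- function(x, ...) {
  cat(sprintf("rds_transitions: order %d, %d chains%s\n", x$order, x$n_chains,
              if (x$degenerate) " (degenerate: single category)" else ""))
  print(round(x$matrix, 3))
  invisible(x)
}

# Turn a transition estimate into (P, pi, y) usable for covariance sums.
# Undefined rows are imputed from the order-1 estimate applied to the
# history suffix (uniform 0.5 if that is undefined too); structural zeros
# stay zero. pi is the chain's stationary law for a well-defined order-1
# estimate, and the empirical history frequencies otherwise / for higher
# orders.
transitions_covchain <- function(te) {
  P <- te$matrix
  states <- te$states
  imputed <- FALSE
  und <- which(rowSums(is.na(P)) > 0)   # zero-tally rows are entirely NA
  for (r in und) {
    imputed <- TRUE
    if (te$order > 1L) {
      # split mass evenly over the two structurally reachable successors
      tgt <- which(startsWith(states, substring(states[r], 2L)))
      P[r, ] <- 0
      P[r, tgt] <- 1 / length(tgt)
    } else {
      P[r, ] <- 0.5
    }
  }
  pi <- te$hist_freq
  if (te$order == 1L && !imputed) {
    p01 <- P["0", "1"]; p10 <- P["1", "0"]
    if (p01 + p10 > 0) {
      pi <- c(p10, p01) / (p01 + p10)
    }
  }
  list(P = P, pi = as.numeric(pi), y = te$state_y, imputed = imputed)
}

# cov(t) for t = 1..maxlag under the (possibly lifted) estimated chain:
# spectral when the chain is reversible wrt pi, matrix powers otherwise.
covchain_lags <- function(cc, maxlag) {
  if (maxlag < 1L) return(numeric(0))
  ystar <- cc$y - sum(cc$pi * cc$y)
  out <- numeric(maxlag)
  v <- ystar
  for (t in seq_len(maxlag)) {
    v <- as.vector(cc$P %*% v)
    out[t] <- sum(cc$pi * ystar * v)
  }
  out
}

new_rds_variance <- function(method, mean, variance, s, flags = character(0)) {
  variance <- max(0, variance)
  de <- if (mean > 0 && mean < 1) variance / (mean * (1 - mean) / s) else NA_real_
  structure(list(method = method, mean = mean, variance = variance,
                 sd = sqrt(variance),
                 ci95 = c(mean - 1.96 * sqrt(variance), mean + 1.96 * sqrt(variance)),
                 design_effect = de, s = s, flags = flags),
            class = "rds_variance")
}

#' @export
print.rds_variance <- function(x, ...) {
  cat(sprintf("%s: mean %.4f, variance %.6g (sd %.4f), DE %.2f, 95%% CI [%.4f, %.4f]\n",
              x$method, x$mean, x$variance, x$sd,
              x$design_effect %||% NA, x$ci95[1L], x$ci95[2L]))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rds_variance <- function(x, ...) {
  data.frame(method = x$method, mean = x$mean, variance = x$variance,
             sd = x$sd, design_effect = x$design_effect,
             ci_low = x$ci95[1L], ci_high = x$ci95[2L],
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Volz-Heckathorn algebraic variance estimator and its corrections
#'
#' Estimates the sampling variance of the RDS-2 mean from the sample alone:
#' \deqn{\hat\sigma^2 = S^{-2}\Big[S\,\hat v + \sum_{i \ne j}
#'   \widehat{cov}(i, j)\Big],}
#' where \eqn{\hat v = \sum_i \hat\pi_i (Y_i - \hat\mu)^2} is the
#' degree-weighted analog of the population variance
#' (\eqn{\hat\pi_i \propto d_i}, normalized over the sample, centering at
#' the RDS-2 mean) and the pair covariances come from the eigensystem of the
#' estimated category transition chain evaluated at the chain distance of
#' each pair. \code{distance_mode = "sequence"} uses interview-order
#' distances (the classic VHE); \code{"tree"} uses recruitment-tree path
#' lengths (the branching correction, VHEwbc), with unlinked cross-tree
#' pairs contributing zero. Orders 2 and 3 replace the 2-by-2 matrix C by
#' the lifted history-state chain (VHEhom), whose state weights are the
#' empirical history frequencies.
#'
#' @param forest a \code{recruitment_forest}.
#' @param distance_mode \code{"sequence"} or \code{"tree"}.
#' @param order Markov order of the transition estimate (1, 2 or 3).
#' @param smooth passed to \code{\link{estimate_transitions}} (order 1).
#' @return An \code{rds_variance} with method \code{"VHE"},
#'   \code{"VHEwbc"}, \code{"VHEhom2"} or \code{"VHEhom3"}.
#' @export
vhe_variance <- function(forest, distance_mode = c("sequence", "tree"),
                         order = 1L, smooth = FALSE) {
  distance_mode <- match.arg(distance_mode)
  order <- as.integer(order)
  method <- if (order == 1L) {
    if (distance_mode == "tree") "VHEwbc" else "VHE"
  } else paste0("VHEhom", order)
  s <- forest$s
  mu <- rds2_mean(forest)
  d <- forest$records$degree
  y <- forest$records$y
  w <- d / sum(d)
  vhat <- sum(w * (y - mu)^2)
  flags <- character(0)
  te <- estimate_transitions(forest, order = order, smooth = smooth)
  if (te$degenerate) {
    return(new_rds_variance(method, mu, vhat / s, s,
                            flags = "degenerate: single observed category"))
  }
  cc <- transitions_covchain(te)
  if (cc$imputed) flags <- c(flags, "undefined transition rows imputed")
  dist <- chain_distances(forest, mode = distance_mode)
  dv <- dist[upper.tri(dist)]
  dv <- dv[!is.na(dv) & dv > 0]
  if (length(dv)) {
    ntab <- tabulate(dv)            # unordered pair counts by distance
    covs <- covchain_lags(cc, length(ntab))
    covsum <- 2 * sum(ntab * covs)  # ordered pairs
  } else {
    covsum <- 0
    flags <- c(flags, "no linked pairs; covariance term zero")
  }
  v <- (s * vhat + covsum) / s^2
  if (v < 0) flags <- c(flags, "negative raw estimate clamped to zero")
  new_rds_variance(method, mu, v, s, flags = flags)
}

#' Salganik bootstrap variance estimator (SBE)
#'
#' Simulates \code{b} synthetic first-order chains of the sample's length
#' from the estimated category transition matrix C: the initial category is
#' drawn from the observed category frequencies, successive categories
#' follow C, and each synthetic respondent's degree is resampled uniformly
#' with replacement from observed respondents of that category. The
#' variance estimate is the variance across the \code{b} replicate RDS-2
#' means.
#'
#' @param forest a \code{recruitment_forest}.
#' @param b number of bootstrap replicates (at least 100; default 1000).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return An \code{rds_variance} with method \code{"SBE"}.
#' @export
sbe_variance <- function(forest, b = 1000L, seed = NULL) {
  stopifnot(b >= 100L)
  s <- forest$s
  mu <- rds2_mean(forest)
  y <- forest$records$y
  d <- forest$records$degree
  flags <- character(0)
  if (length(unique(y)) < 2L) {
    return(new_rds_variance("SBE", mu, 0, s,
                            flags = "degenerate: single observed category"))
  }
  te <- estimate_transitions(forest, order = 1L)
  P <- te$matrix
  if (anyNA(P)) {
    # a category never observed as recruiter: jump to the marginal
    marg <- mean(y)
    for (r in which(apply(P, 1L, anyNA))) P[r, ] <- c(1 - marg, marg)
    flags <- c(flags, "undefined transition rows imputed from category frequencies")
  }
  p1 <- P[, "1"]                    # P(next = 1 | current)
  deg0 <- d[y == 0L]; deg1 <- d[y == 1L]
  with_seed(seed, {
    cat <- matrix(0L, b, s)
    cat[, 1L] <- stats::rbinom(b, 1L, mean(y))
    for (t in 2:s) {
      cat[, t] <- stats::rbinom(b, 1L, p1[cat[, t - 1L] + 1L])
    }
    degm <- matrix(0, b, s)
    n0 <- sum(cat == 0L); n1 <- sum(cat == 1L)
    degm[cat == 0L] <- deg0[sample.int(length(deg0), n0, replace = TRUE)]
    degm[cat == 1L] <- deg1[sample.int(length(deg1), n1, replace = TRUE)]
    means <- rowSums(cat / degm) / rowSums(1 / degm)
    new_rds_variance("SBE", mu, stats::var(means), s, flags = flags)
  })
}

#' Estimate RDS sampling variance by a named method
#'
#' Convenience dispatcher over \code{\link{vhe_variance}} and
#' \code{\link{sbe_variance}}.
#'
#' @param forest a \code{recruitment_forest}.
#' @param method one of \code{"vhe"}, \code{"vhewbc"}, \code{"vhehom2"},
#'   \code{"vhehom3"}, \code{"sbe"}.
#' @param b bootstrap replicates for the SBE.
#' @param seed seed for the SBE.
#' @return An \code{rds_variance}.
#' @export
estimate_variance <- function(forest,
                              method = c("vhe", "vhewbc", "vhehom2", "vhehom3", "sbe"),
                              b = 1000L, seed = NULL) {
  method <- match.arg(method)
  switch(method,
         vhe = vhe_variance(forest, "sequence", order = 1L),
         vhewbc = vhe_variance(forest, "tree", order = 1L),
         vhehom2 = vhe_variance(forest, "tree", order = 2L),
         vhehom3 = vhe_variance(forest, "tree", order = 3L),
         sbe = sbe_variance(forest, b = b, seed = seed))
}

#' Does the 95\% interval cover the true mean?
#'
#' TRUE iff \code{|mean - mu| <= 1.96 * sqrt(variance)}.
#'
#' @param estimate an \code{rds_variance}.
#' @param mu true population mean.
#' @return Logical.
#' @export
coverage_hit <- function(estimate, mu) {
  stopifnot(estimate$variance >= 0)
  abs(estimate$mean - mu) <= 1.96 * sqrt(estimate$variance)
}
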