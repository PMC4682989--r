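# Fixtures are built in code; no data files.

triangle_net <- function(y = c(a = 1L, b = 1L, c = 1L)) {
  rds_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")), y)
}

path_net <- function(y = c(a = 0L, b = 1L, c = 0L)) {
  rds_network(rbind(c("a", "b"), c("b", "c")), y)
}

star_net <- function(k = 4L, y_center = 1L, y_leaf = 0L) {
  leaves <- sprintf("l%d", seq_len(k))
  y <- stats::setNames(c(y_center, rep(y_leaf, k)), c("ctr", leaves))
  rds_network(cbind("ctr", leaves), y)
}

complete_net <- function(n, y) {
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  rds_network(pairs, stats::setNames(y, ids))
}

# Erdos-Renyi G(n, m) with i.i.d. Bernoulli(p) attribute.
er_net <- function(n, m, p = 0.5, seed = 1L) {
  rdsvar:::with_seed(seed, {
    g <- igraph::sample_gnm(n, m)
    el <- igraph::as_edgelist(g, names = FALSE)
    ids <- sprintf("v%04d", seq_len(n))
    net <- rds_network(cbind(ids[el[, 1L]], ids[el[, 2L]]),
                       stats::setNames(stats::rbinom(n, 1L, p), ids))
    net
  })
}

# Forest from explicit record vectors (recruiter_row given directly).
make_forest <- function(y, recruiter_row, degree = rep(2L, length(y)),
                        with_replacement = TRUE) {
  n <- length(y)
  ids <- sprintf("r%03d", seq_len(n))
  wave <- integer(n)
  for (i in seq_len(n)) {
    wave[i] <- if (is.na(recruiter_row[i])) 0L else wave[recruiter_row[i]] + 1L
  }
  recruitment_forest(
    data.frame(id = ids,
               recruiter_id = ifelse(is.na(recruiter_row), NA_character_,
                                     ids[recruiter_row]),
               wave = wave, y = y, degree = degree,
               recruiter_row = recruiter_row,
               stringsAsFactors = FALSE),
    with_replacement = with_replacement)
}

# Non-branching chain forest whose y-sequence follows a 2-state transition
# matrix C with a stationary (uniform for symmetric C) start.
sim_chain_forest <- function(C, S, seed, degree = 2L) {
  y <- rdsvar:::with_seed(seed, {
    out <- integer(S)
    pi1 <- C[2L, 1L] / (C[1L, 2L] + C[2L, 1L])
    out[1L] <- stats::rbinom(1L, 1L, 1 - pi1)
    for (t in 2:S) out[t] <- stats::rbinom(1L, 1L, C[out[t - 1L] + 1L, 2L])
    out
  })
  make_forest(y, c(NA_integer_, seq_len(S - 1L)), degree = rep(degree, S))
}

# Monte Carlo sampling variance of the mean of y over R stationary walks of
# length S on a chain; returns the MC estimate and its standard error.
mc_walk_variance <- function(chain, S, R, seed) {
  n <- length(chain$states)
  cumP <- t(apply(chain$P, 1L, cumsum))
  mu <- sum(chain$pi * chain$y)
  rdsvar:::with_seed(seed, {
    cur <- sample.int(n, R, replace = TRUE, prob = chain$pi)
    ysum <- chain$y[cur]
    for (t in 2:S) {
      u <- stats::runif(R)
      cur <- rowSums(u > cumP[cur, , drop = FALSE]) + 1L
      ysum <- ysum + chain$y[cur]
    }
    dev2 <- (ysum / S - mu)^2
    list(variance = mean(dev2), se = stats::sd(dev2) / sqrt(R))
  })
}

# Illustration fixtures: the two computational-example parameterizations.
spec_ex1 <- function(n_per_cell = 30L) block_spec(E = 10, F = 10, H = 10,
                                                  n_per_cell = n_per_cell)
spec_ex2 <- function(n_per_cell = 30L) block_spec(E = 1, F = 10, H = 10,
                                                  n_per_cell = n_per_cell)
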