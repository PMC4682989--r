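#' Finite Markov chain with an attribute mapping
#'
#' The spectral workhorse of the package. A \code{state_chain} couples a
#' row-stochastic transition matrix over states (network nodes, Y-by-Z cells,
#' or Y categories) with the binary attribute value of each state, the
#' stationary distribution, and - for reversible chains - the eigensystem of
#' the symmetrized matrix together with the loadings \code{alpha} of the
#' mean-centered, sqrt(pi)-weighted attribute vector on the orthonormal
#' eigenvectors. Those loadings are exactly what the step-covariance and
#' exact random-walk variance formulas consume.
#'
#' @param P square row-stochastic matrix (rows sum to 1 within 1e-10).
#' @param y attribute value (0/1) of each state.
#' @param states optional state labels; defaults to rownames or indices.
#' @param pi optional stationary distribution; computed from \code{P} when
#'   omitted (left eigenvector for eigenvalue 1).
#' @return An object of class \code{state_chain} with fields \code{states},
#'   \code{P}, \code{y}, \code{pi}, \code{lambdas}, \code{alphas},
#'   \code{reversible}, \code{irreducible}.
#' @export
state_chain <- function(P, y, states = NULL, pi = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n) stop_fmt("P must be square")
  if (length(y) != n) stop_fmt("y must have one value per state")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-10)) stop_fmt("rows of P must sum to 1 (max dev %.3g)",
                                         max(abs(rs - 1)))
  if (any(P < -1e-12)) stop_fmt("P must be nonnegative")
  states <- states %||% rownames(P) %||% as.character(seq_len(n))
  y <- as.numeric(y)
  irreducible <- chain_irreducible(P)
  if (is.null(pi)) {
    if (!irreducible) {
      stop_fmt("chain is reducible; supply `pi` explicitly if it is still meaningful")
    }
    e <- eigen(t(P))
    k <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, k])
    pi <- v / sum(v)
  }
  pi <- as.numeric(pi)
  if (abs(sum(pi) - 1) > 1e-8) stop_fmt("pi must sum to 1")
  flux <- pi * P
  reversible <- max(abs(flux - t(flux))) <= 1e-9 * max(1, max(abs(flux)))
  lambdas <- NULL; alphas <- NULL; vectors <- NULL
  if (reversible && all(pi > 0)) {
    sq <- sqrt(pi)
    Ms <- sweep(sweep(P, 1L, sq, "*"), 2L, sq, "/")
    es <- eigen((Ms + t(Ms)) / 2, symmetric = TRUE)
    ord <- order(es$values, decreasing = TRUE)
    lambdas <- es$values[ord]
    vectors <- es$vectors[, ord, drop = FALSE]
    ystar <- y - sum(pi * y)
    alphas <- as.vector(crossprod(vectors, sq * ystar))
  }
  structure(
    list(states = states, P = unname(P), y = y, pi = pi,
         lambdas = lambdas, alphas = alphas, vectors = vectors,
         reversible = reversible, irreducible = irreducible),
    class = "state_chain")
}

chain_irreducible <- function(P) {
  g <- igraph::graph_from_adjacency_matrix(1 * (P > 0), mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' @export
print.state_chain <- function(x, ...) {
  l2 <- if (!is.null(x$lambdas) && length(x$lambdas) > 1L) {
    sprintf("%.4f", x$lambdas[2L])
  } else "n/a"
  cat(sprintf("state_chain: %d states, lambda2 = %s%s%s\n",
              length(x$states), l2,
              if (x$reversible) "" else " (non-reversible)",
              if (x$irreducible) "" else " [reducible]"))
  invisible(x)
}

#' Random-walk transition chain of a network
#'
#' Builds the node-level Markov chain of a simple random walk: transition
#' probabilities \code{G_ij / d_i}, degree-proportional stationary law
#' \code{pi_i = d_i / 2m}, and the eigensystem of the symmetrized matrix
#' \code{G_ij / sqrt(d_i d_j)} (which shares its eigenvalues with the walk).
#'
#' @param net a connected \code{rds_network} with at least two nodes.
#' @return A \code{state_chain} over the network's nodes.
#' @export
node_chain <- function(net) {
  n <- length(net$nodes)
  if (n < 2L) stop_fmt("need at least 2 nodes")
  if (!is_connected_net(net)) {
    stop_fmt("network is disconnected; stationary distribution undefined (use largest_component)")
  }
  G <- matrix(0, n, n)
  G[net$edges] <- 1
  G[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  P <- G / net$degree
  pi <- net$degree / (2 * net$m)
  state_chain(P, net$y, states = net$nodes, pi = pi)
}

#' Four-state cell chain of the block model
#'
#' The transition chain over the Y-by-Z cells (Y0Z0, Y0Z1, Y1Z1, Y1Z0)
#' implied by a \code{\link{block_spec}}, with mixing parameters
#' \code{a = E/(E+F+H)} and \code{b = H/(E+F+H)}:
#' rows \code{(1-a, a, 0, 0)}, \code{(a, 1-a-b, b, 0)},
#' \code{(0, b, 1-a-b, a)}, \code{(0, 0, a, 1-a)}. Equal cell degrees give a
#' uniform stationary distribution. When \code{b = 0} the chain is reducible
#' across Y and flagged as such.
#'
#' @param spec a \code{\link{block_spec}}.
#' @return A \code{state_chain} with \code{y = (0, 0, 1, 1)}.
#' @seealso \code{\link{table1_collapse}} for the dyadic two-state collapse.
#' @export
table1_chain <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  a <- spec$a; b <- spec$b
  if (a + b > 1 + 1e-12) stop_fmt("invalid spec: a + b > 1")
  P <- matrix(c(1 - a,     a,         0,         0,
                a,         1 - a - b, b,         0,
                0,         b,         1 - a - b, a,
                0,         0,         a,         1 - a),
              4L, 4L, byrow = TRUE)
  state_chain(P, c(0, 0, 1, 1),
              states = c("Y0Z0", "Y0Z1", "Y1Z1", "Y1Z0"),
              pi = rep(0.25, 4L))
}

#' Two-state dyadic collapse of the block model
#'
#' The Y-category transition matrix a first-order (VHE-style) analysis sees:
#' off-diagonal \code{i = b/2}, the share of friendship ends crossing Y.
#'
#' @param spec a \code{\link{block_spec}}.
#' @return A two-state \code{state_chain} with \code{y = (0, 1)}.
#' @export
table1_collapse <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  i <- spec$b / 2
  P <- matrix(c(1 - i, i, i, 1 - i), 2L, 2L, byrow = TRUE)
  state_chain(P, c(0, 1), states = c("Y0", "Y1"), pi = c(0.5, 0.5))
}

#' Closed-form eigenvalues of the four-state block chain
#'
#' Returns \code{(1, 1-b-a+sqrt(a^2+b^2), 1-2a, 1-b-a-sqrt(a^2+b^2))}
#' sorted in decreasing order; agrees with the numeric eigendecomposition of
#' \code{\link{table1_chain}} to 1e-10.
#'
#' @param spec a \code{\link{block_spec}}.
#' @return Numeric vector of length four.
#' @export
table1_eigenvalues <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  a <- spec$a; b <- spec$b
  r <- sqrt(a^2 + b^2)
  sort(c(1, 1 - b - a + r, 1 - 2 * a, 1 - b - a - r), decreasing = TRUE)
}

#' Propagate a start distribution through the chain
#'
#' Computes \code{p0 \%*\% P^s}; on a connected aperiodic chain this
#' approaches the stationary distribution as \code{s} grows.
#'
#' @param chain a \code{state_chain}.
#' @param p0 probability vector over states (sums to 1).
#' @param s nonnegative integer step count.
#' @return Probability vector after \code{s} steps.
#' @export
propagate <- function(chain, p0, s) {
  stopifnot(length(p0) == length(chain$states), s >= 0)
  if (abs(sum(p0) - 1) > 1e-8) stop_fmt("p0 must sum to 1")
  p <- matrix(p0, nrow = 1L)
  s <- as.integer(s)
  while (s > 0L) {
    p <- p %*% chain$P
    s <- s - 1L
  }
  as.vector(p)
}

# Covariance of the attribute between walk steps at each requested lag:
# cov(t) = sum_{k>=2} alpha_k^2 lambda_k^t for reversible chains, and the
# matrix-power equivalent sum_i pi_i Y*_i (P^t Y*)_i otherwise.
cov_at_lags <- function(chain, lags) {
  lags <- as.integer(lags)
  if (!is.null(chain$alphas)) {
    a2 <- chain$alphas[-1L]^2
    lam <- chain$lambdas[-1L]
    vapply(lags, function(t) {
      if (t == 0L) sum(a2) else sum(a2 * lam^t)
    }, 0)
  } else {
    ystar <- chain$y - sum(chain$pi * chain$y)
    maxlag <- max(lags)
    out <- numeric(maxlag + 1L)
    v <- ystar
    out[1L] <- sum(chain$pi * ystar * v)
    if (maxlag > 0L) {
      for (t in seq_len(maxlag)) {
        v <- as.vector(chain$P %*% v)
        out[t + 1L] <- sum(chain$pi * ystar * v)
      }
    }
    out[lags + 1L]
  }
}

#' Covariance between two steps of a stationary walk
#'
#' \code{sum_{k>=2} alpha_k^2 lambda_k^lag}: at lag 0 this is the population
#' variance \code{sum_i pi_i (Y*_i)^2}; it decays geometrically in the
#' spectral gap at larger lags.
#'
#' @param chain a \code{state_chain}.
#' @param lag nonnegative integer number of steps between the two draws.
#' @return The covariance (a scalar).
#' @export
step_covariance <- function(chain, lag) {
  stopifnot(lag >= 0)
  cov_at_lags(chain, lag)
}

#' Exact sampling variance of a stationary random-walk sample mean
#'
#' For a walk of \code{s} steps started from the stationary distribution,
#' the variance of the sample mean of the attribute is
#' \deqn{Var(\bar y) = S^{-2}\Big[S\,\sigma^2 +
#'   2\sum_{t=1}^{S-1}(S-t)\sum_{k\ge 2}\alpha_k^2\lambda_k^t\Big],}
#' with \eqn{\sigma^2 = \sum_i \pi_i (Y^*_i)^2}. The design effect divides
#' this by the variance \eqn{\sigma^2/S} of an equal-size sample of
#' independent draws from \eqn{\pi}.
#'
#' @param chain a \code{state_chain} (connected).
#' @param s sample size (walk length), at least 2.
#' @return List with \code{variance}, \code{sd} and \code{design_effect}.
#'   A constant attribute gives variance 0 and an undefined design effect.
#' @export
exact_rw_variance <- function(chain, s) {
  stopifnot(s >= 2)
  if (!chain$irreducible) stop_fmt("chain is reducible; exact variance undefined")
  s <- as.integer(s)
  sigma2 <- cov_at_lags(chain, 0L)
  if (sigma2 <= .Machine$double.eps) {
    return(list(variance = 0, sd = 0, design_effect = NA_real_))
  }
  covs <- cov_at_lags(chain, seq_len(s - 1L))
  v <- (s * sigma2 + 2 * sum((s - seq_len(s - 1L)) * covs)) / s^2
  list(variance = v, sd = sqrt(v), design_effect = v / (sigma2 / s))
}

#' Serialize a chain to a transition-matrix CSV plus state metadata CSV
#'
#' @param chain a \code{state_chain}.
#' @param matrix_path destination CSV for the transition matrix.
#' @param meta_path destination CSV with columns \code{state}, \code{y},
#'   \code{pi}.
#' @export
write_chain <- function(chain, matrix_path, meta_path) {
  P <- chain$P
  dimnames(P) <- list(chain$states, chain$states)
  utils::write.csv(P, matrix_path, row.names = TRUE)
  utils::write.csv(data.frame(state = chain$states, y = chain$y, pi = chain$pi),
                   meta_path, row.names = FALSE)
  invisible(chain)
}

#' Read a chain written by \code{\link{write_chain}}
#'
#' @param matrix_path transition-matrix CSV.
#' @param meta_path state-metadata CSV.
#' @return A \code{state_chain}.
#' @export
read_chain <- function(matrix_path, meta_path) {
  P <- as.matrix(utils::read.csv(matrix_path, row.names = 1L, check.names = FALSE))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  ord <- match(rownames(P), as.character(meta$state))
  state_chain(P, meta$y[ord], states = rownames(P), pi = meta$pi[ord])
}
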