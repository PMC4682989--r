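#' Recruitment forest: one RDS sample
#'
#' Wraps the ordered record table of a chain-referral sample: respondent node,
#' recruiter (NA for seeds), wave, attribute value and degree at recruitment.
#' With-replacement samples may revisit nodes, in which case each visit is a
#' distinct record and recruiter links point at a specific earlier record.
#'
#' @param records data frame with columns \code{id}, \code{recruiter_id}
#'   (NA for seeds), \code{wave}, \code{y}, \code{degree}, in interview
#'   order. An optional \code{recruiter_row} column gives the record index
#'   of each recruiter; when absent it is reconstructed as the most recent
#'   earlier record carrying \code{recruiter_id}.
#' @param with_replacement logical flag recorded on the sample.
#' @return An object of class \code{recruitment_forest}.
#' @export
recruitment_forest <- function(records, with_replacement = TRUE) {
  need <- c("id", "recruiter_id", "wave", "y", "degree")
  if (!all(need %in% names(records))) {
    stop_fmt("records must have columns %s", paste(need, collapse = ", "))
  }
  records$id <- as.character(records$id)
  records$recruiter_id <- as.character(records$recruiter_id)
  records$recruiter_id[records$recruiter_id %in% c("", "NA")] <- NA_character_
  n <- nrow(records)
  records$order <- seq_len(n)
  if (is.null(records$recruiter_row)) {
    rr <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      rid <- records$recruiter_id[i]
      if (!is.na(rid)) {
        prev <- which(records$id[seq_len(i - 1L)] == rid)
        if (!length(prev)) stop_fmt("record %d: recruiter '%s' not seen earlier", i, rid)
        # revisited nodes occur with replacement: prefer the occurrence in
        # the previous wave, else the most recent one
        inwave <- prev[records$wave[prev] == records$wave[i] - 1L]
        rr[i] <- if (length(inwave)) inwave[length(inwave)] else prev[length(prev)]
      }
    }
    records$recruiter_row <- rr
  }
  seeds <- which(is.na(records$recruiter_row))
  if (!length(seeds)) stop_fmt("forest has no seed records")
  nonseed <- which(!is.na(records$recruiter_row))
  if (length(nonseed)) {
    pr <- records$recruiter_row[nonseed]
    if (any(pr >= nonseed)) stop_fmt("recruiters must appear before their recruits")
    if (any(records$wave[nonseed] != records$wave[pr] + 1L)) {
      stop_fmt("waves must increase by 1 along recruiter -> recruit links")
    }
    nrec <- table(pr)
    if (any(nrec > 3L)) stop_fmt("a recruiter has more than 3 recruits")
  }
  if (!with_replacement && anyDuplicated(records$id)) {
    stop_fmt("repeated respondents in a without-replacement sample")
  }
  if (any(records$degree < 1L)) stop_fmt("all degrees must be >= 1")
  structure(list(records = records, s = n, seeds = seeds,
                 with_replacement = with_replacement),
            class = "recruitment_forest")
}

#' @export
print.recruitment_forest <- function(x, ...) {
  cat(sprintf("recruitment_forest: %d respondents, %d seed(s), %d wave(s), mean y %.3f\n",
              x$s, length(x$seeds), max(x$records$wave) + 1L, mean(x$records$y)))
  invisible(x)
}

sample_stationary <- function(net, pool = NULL) {
  w <- net$degree
  if (!is.null(pool)) {
    w <- w * 0
    w[pool] <- net$degree[pool]
  }
  sample.int(length(net$nodes), 1L, prob = w)
}

#' Non-branching random-walk sample
#'
#' The idealized RDS model: a with-replacement simple random walk of
#' \code{s} steps, started from the degree-proportional stationary
#' distribution, each step moving to a uniformly chosen neighbor.
#'
#' @param net a connected \code{rds_network}.
#' @param s walk length (sample size), at least 1.
#' @param seed integer seed.
#' @return A \code{recruitment_forest} forming a single chain.
#' @export
random_walk_sample <- function(net, s, seed) {
  stopifnot(s >= 1)
  if (!is_connected_net(net)) stop_fmt("network must be connected")
  adj <- adjacency_list(net)
  with_seed(seed, {
    v <- sample_stationary(net)
    idx <- integer(s); idx[1L] <- v
    if (s > 1L) {
      for (t in 2:s) {
        nb <- adj[[v]]
        v <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
        idx[t] <- v
      }
    }
    forest_from_indices(net, idx,
                        recruiter_row = c(NA_integer_, seq_len(s - 1L))[seq_len(s)],
                        with_replacement = TRUE)
  })
}

forest_from_indices <- function(net, idx, recruiter_row, with_replacement) {
  wave <- integer(length(idx))
  for (i in seq_along(idx)) {
    wave[i] <- if (is.na(recruiter_row[i])) 0L else wave[recruiter_row[i]] + 1L
  }
  rec <- data.frame(
    id = net$nodes[idx],
    recruiter_id = ifelse(is.na(recruiter_row), NA_character_,
                          net$nodes[idx[recruiter_row]]),
    wave = wave,
    y = net$y[idx],
    degree = net$degree[idx],
    recruiter_row = recruiter_row,
    stringsAsFactors = FALSE)
  recruitment_forest(rec, with_replacement = with_replacement)
}

#' Branching RDS sample
#'
#' Simulates coupon-style recruitment: the seed is drawn from the
#' degree-proportional stationary distribution, and recruitment proceeds
#' breadth-first (wave order). Each respondent draws a recruit count from
#' \code{branch_probs} (number of recruits 0-3, default 1/3, 1/6, 1/6, 1/3)
#' and each recruit is a uniformly chosen neighbor - any neighbor when
#' sampling with replacement, an uninterviewed neighbor (count truncated to
#' availability) otherwise. Sampling halts at exactly \code{s} records, with
#' overflow recruits of the final batch dropped in draw order. If the queue
#' dies out before reaching \code{s}, a fresh seed is drawn from the
#' stationary distribution (restricted to unsampled nodes when sampling
#' without replacement), so the requested size is always attained.
#'
#' @param net a connected \code{rds_network}.
#' @param s sample size, at least 1 (at most the population size when
#'   sampling without replacement).
#' @param branch_probs probability vector for 0-3 recruits; must sum to 1.
#' @param with_replacement logical; default TRUE.
#' @param seed integer seed.
#' @return A \code{recruitment_forest}.
#' @export
rds_sample <- function(net, s, branch_probs = c(1/3, 1/6, 1/6, 1/3),
                       with_replacement = TRUE, seed = NULL) {
  stopifnot(s >= 1, length(branch_probs) == 4L)
  if (abs(sum(branch_probs) - 1) > 1e-8) stop_fmt("branch_probs must sum to 1")
  n <- length(net$nodes)
  if (!with_replacement && s > n) stop_fmt("s > population size without replacement")
  if (!is_connected_net(net)) stop_fmt("network must be connected")
  adj <- adjacency_list(net)
  with_seed(seed, {
    idx <- integer(s); parent <- rep(NA_integer_, s)
    sampled <- logical(n)
    count <- 0L
    queue <- integer(0)   # record rows awaiting their recruitment draw
    add_record <- function(v, par) {
      count <<- count + 1L
      idx[count] <<- v
      parent[count] <<- par
      sampled[v] <<- TRUE
      queue <<- c(queue, count)
    }
    new_seed <- function() {
      pool <- if (with_replacement) NULL else which(!sampled)
      add_record(sample_stationary(net, pool), NA_integer_)
    }
    new_seed()
    while (count < s) {
      if (!length(queue)) { new_seed(); next }
      r <- queue[1L]; queue <- queue[-1L]
      k <- sample.int(4L, 1L, prob = branch_probs) - 1L
      if (k == 0L) next
      v <- idx[r]
      if (with_replacement) {
        nb <- adj[[v]]
        picks <- nb[sample.int(length(nb), k, replace = TRUE)]
      } else {
        nb <- adj[[v]][!sampled[adj[[v]]]]
        if (!length(nb)) next
        k <- min(k, length(nb))
        picks <- nb[sample.int(length(nb), k)]
      }
      for (w in picks) {
        if (count >= s) break
        if (!with_replacement && sampled[w]) next  # earlier pick this batch
        add_record(w, r)
      }
    }
    forest_from_indices(net, idx, parent, with_replacement = with_replacement)
  })
}

#' Pairwise chain distances within a sample
#'
#' \code{mode = "sequence"} returns the classic interview-order distances
#' \code{|j - i|}; \code{mode = "tree"} returns undirected path lengths in
#' the recruitment forest, so that if i recruits j who recruits both k and
#' l, the distance from i to each of k and l is 2 (and between k and l it
#' is also 2, through j). Pairs in different recruitment trees have no
#' defined tree distance and are returned as \code{NA} (unlinked).
#'
#' @param forest a \code{recruitment_forest}.
#' @param mode \code{"sequence"} or \code{"tree"}.
#' @return An s-by-s matrix of nonnegative integer distances
#'   (\code{NA} for unlinked pairs in tree mode).
#' @export
chain_distances <- function(forest, mode = c("sequence", "tree")) {
  mode <- match.arg(mode)
  s <- forest$s
  if (mode == "sequence") {
    return(abs(outer(seq_len(s), seq_len(s), "-")))
  }
  pr <- forest$records$recruiter_row
  kids <- which(!is.na(pr))
  g <- igraph::make_empty_graph(n = s, directed = FALSE)
  if (length(kids)) {
    g <- igraph::add_edges(g, rbind(pr[kids], kids))
  }
  d <- igraph::distances(g)
  d[is.infinite(d)] <- NA
  unname(d)
}

#' Empirical sampling variance of replicate estimates
#'
#' The mean squared deviation of replicate mean estimates around the true
#' population mean (an MSE, not a central variance - deviations are taken
#' around truth). Set \code{central = TRUE} for the conventional variance
#' around the replicate average instead.
#'
#' @param estimates numeric vector of replicate mean estimates (length >= 2).
#' @param mu true population mean.
#' @param central logical; default FALSE (deviations around \code{mu}).
#' @return The empirical sampling variance.
#' @export
empirical_sampling_variance <- function(estimates, mu, central = FALSE) {
  stopifnot(length(estimates) >= 2)
  if (central) mu <- mean(estimates)
  mean((estimates - mu)^2)
}

#' Write a recruitment forest as CSV
#'
#' Columns \code{id}, \code{recruiter_id} (empty for seeds), \code{wave},
#' \code{y}, \code{degree}, \code{order}, plus \code{recruiter_order}
#' pinning the exact recruiter record (node labels alone are ambiguous when
#' with-replacement samples revisit a node). Also the input format of the
#' estimator functions.
#'
#' @param forest a \code{recruitment_forest}.
#' @param path destination CSV.
#' @export
write_forest <- function(forest, path) {
  rec <- forest$records
  out <- data.frame(id = rec$id,
                    recruiter_id = ifelse(is.na(rec$recruiter_id), "", rec$recruiter_id),
                    wave = rec$wave, y = rec$y, degree = rec$degree,
                    order = rec$order,
                    recruiter_order = ifelse(is.na(rec$recruiter_row), "",
                                             rec$recruiter_row))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(forest)
}

#' Read a recruitment forest CSV written by \code{\link{write_forest}}
#'
#' @param path CSV file.
#' @param with_replacement flag recorded on the sample (not stored in the
#'   CSV); defaults to TRUE.
#' @return A \code{recruitment_forest}.
#' @export
read_forest <- function(path, with_replacement = TRUE) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", recruiter_id = "character"))
  rec <- rec[order(rec$order), ]
  rownames(rec) <- NULL
  if ("recruiter_order" %in% names(rec)) {
    # exact recruiter record, needed when with-replacement samples revisit
    # a node; plain recruiter_id would be ambiguous
    rec$recruiter_row <- suppressWarnings(as.integer(rec$recruiter_order))
    rec$recruiter_order <- NULL
  }
  recruitment_forest(rec, with_replacement = with_replacement)
}
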