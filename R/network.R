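#' Undirected network with a binary node attribute
#'
#' Constructs the population object used throughout the package: a simple
#' undirected graph together with a dichotomous node attribute \code{y}
#' (the survey variable of interest) and, optionally, a second attribute
#' \code{z} (used by the block generator to record the hidden mixing
#' variable). Edge direction is ignored, duplicate and reciprocal edges are
#' collapsed, and self-loops are dropped. Node identifiers are treated as
#' opaque strings and stored in sorted (lexicographic) order so that all
#' downstream computations are deterministic.
#'
#' @param edges two-column matrix or data frame of edge endpoints
#'   (character or coercible to character).
#' @param y named vector of 0/1 attribute values; names are node identifiers.
#'   Every node appearing in \code{edges} must be covered. Nodes named in
#'   \code{y} but absent from \code{edges} are kept as isolates.
#' @param z optional named vector of secondary attribute values.
#' @return An object of class \code{rds_network} with components
#'   \code{nodes}, \code{edges} (integer index pairs, one row per edge),
#'   \code{y}, \code{z}, \code{degree} and \code{m} (edge count).
#' @export
rds_network <- function(edges, y, z = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop_fmt("`edges` must have two columns")
  ea <- as.character(edges[, 1L]); eb <- as.character(edges[, 2L])
  if (is.null(names(y))) stop_fmt("`y` must be a named vector (names = node ids)")
  nodes <- sort(unique(c(ea, eb, names(y))))
  miss <- setdiff(unique(c(ea, eb)), names(y))
  if (length(miss)) {
    stop_fmt("missing `y` values for node(s): %s",
             paste(utils::head(miss, 10L), collapse = ", "))
  }
  yv <- y[nodes]
  if (anyNA(yv)) {
    stop_fmt("missing `y` values for node(s): %s",
             paste(utils::head(nodes[is.na(yv)], 10L), collapse = ", "))
  }
  yv <- as.integer(yv)
  if (!all(yv %in% c(0L, 1L))) stop_fmt("`y` values must be 0 or 1")
  ia <- match(ea, nodes); ib <- match(eb, nodes)
  keep <- ia != ib                       # drop self-loops
  ia <- ia[keep]; ib <- ib[keep]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib) # symmetrize
  key <- unique(cbind(lo, hi))           # collapse duplicates
  key <- key[order(key[, 1L], key[, 2L]), , drop = FALSE]
  deg <- tabulate(c(key[, 1L], key[, 2L]), nbins = length(nodes))
  zv <- if (!is.null(z)) unname(z[nodes]) else NULL
  structure(
    list(nodes = nodes, edges = unname(key), y = unname(yv), z = zv,
         degree = deg, m = nrow(key)),
    class = "rds_network")
}

#' @export
print.rds_network <- function(x, ...) {
  cat(sprintf("rds_network: %d nodes, %d edges, mean degree %.2f, mean y %.3f\n",
              length(x$nodes), x$m, mean(x$degree), mean(x$y)))
  invisible(x)
}

# igraph view of the network (vertex order preserved).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = net$nodes[net$edges[, 1L]],
                   to = net$nodes[net$edges[, 2L]]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

# Adjacency list as integer vectors, in node-index space.
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  if (net$m > 0L) {
    e <- net$edges
    both <- c(e[, 1L], e[, 2L])
    other <- c(e[, 2L], e[, 1L])
    adj <- split(other, factor(both, levels = seq_len(n)))
    adj <- lapply(adj, as.integer)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  adj
}

is_connected_net <- function(net) {
  if (length(net$nodes) == 0L) return(FALSE)
  igraph::is_connected(as_igraph(net))
}

#' Read a network from an edge list or GraphML file
#'
#' Edge lists are whitespace- or tab-separated, may carry an optional header
#' naming the first two columns, and lines starting with \code{#} are
#' comments. Reciprocal or duplicated rows collapse to a single undirected
#' edge and self-loops are dropped. Node attributes for the edge-list dialect
#' are supplied as a separate CSV (columns \code{node}, the attribute, and
#' optionally \code{z}); GraphML attributes are read from the file itself.
#'
#' @param path file to read.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @param attr_name name of the node attribute holding the survey variable.
#' @param attrs for \code{format = "edgelist"}: path to the node-attribute
#'   CSV. Ignored for GraphML.
#' @param dichotomize optional function mapping raw attribute values to
#'   0/1 (e.g. \code{function(v) as.integer(v == "white")}). The package
#'   never guesses a reference category: non-binary attributes without a
#'   \code{dichotomize} rule are an error.
#' @return An \code{rds_network}.
#' @export
load_network <- function(path, format = c("edgelist", "graphml"),
                         attr_name = "y", attrs = NULL, dichotomize = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop_fmt("no edges found in %s", path)
    toks <- strsplit(lines, "[[:space:]]+")
    if (any(lengths(toks) < 2L)) stop_fmt("malformed edge list: %s", path)
    em <- cbind(vapply(toks, `[[`, "", 1L), vapply(toks, `[[`, "", 2L))
    # optional header: first row repeated nowhere as node & looks like labels
    if (nrow(em) > 1L && tolower(em[1L, 1L]) %in% c("from", "source", "ego", "node1")) {
      em <- em[-1L, , drop = FALSE]
    }
    if (is.null(attrs)) stop_fmt("edge-list format requires a node-attribute CSV via `attrs`")
    at <- utils::read.csv(attrs, stringsAsFactors = FALSE,
                          colClasses = c(node = "character"))
    if (!all(c("node", attr_name) %in% names(at))) {
      stop_fmt("attribute file must have columns 'node' and '%s'", attr_name)
    }
    raw <- at[[attr_name]]; names(raw) <- at$node
    zv <- if ("z" %in% names(at)) stats::setNames(at$z, at$node) else NULL
  } else {
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e) stop_fmt("cannot parse GraphML %s: %s",
                                               path, conditionMessage(e)))
    nm <- igraph::vertex_attr(g, "name") %||%
      igraph::vertex_attr(g, "id") %||% as.character(seq_len(igraph::vcount(g)))
    if (!attr_name %in% igraph::vertex_attr_names(g)) {
      stop_fmt("attribute '%s' not present in %s", attr_name, path)
    }
    raw <- stats::setNames(igraph::vertex_attr(g, attr_name), nm)
    zv <- if ("z" %in% igraph::vertex_attr_names(g)) {
      stats::setNames(igraph::vertex_attr(g, "z"), nm)
    } else NULL
    el <- igraph::as_edgelist(g, names = TRUE)
    em <- cbind(as.character(el[, 1L]), as.character(el[, 2L]))
    if (!nrow(em)) stop_fmt("no edges found in %s", path)
  }
  if (anyNA(raw)) {
    stop_fmt("attribute '%s' missing for node(s): %s", attr_name,
             paste(utils::head(names(raw)[is.na(raw)], 10L), collapse = ", "))
  }
  yv <- if (!is.null(dichotomize)) {
    as.integer(dichotomize(raw))
  } else if (all(raw %in% c(0, 1, "0", "1", TRUE, FALSE))) {
    as.integer(as.numeric(raw))
  } else {
    stop_fmt("attribute '%s' is not binary; supply a `dichotomize` rule", attr_name)
  }
  names(yv) <- names(raw)
  rds_network(em, yv, z = zv)
}

#' Write a network as an edge list plus node-attribute CSV
#'
#' @param net an \code{rds_network}.
#' @param edge_path destination for the tab-separated edge list.
#' @param attr_path destination for the node-attribute CSV
#'   (columns \code{node}, \code{y} and, when present, \code{z}).
#' @export
write_network <- function(net, edge_path, attr_path) {
  el <- cbind(net$nodes[net$edges[, 1L]], net$nodes[net$edges[, 2L]])
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  at <- data.frame(node = net$nodes, y = net$y, stringsAsFactors = FALSE)
  if (!is.null(net$z)) at$z <- net$z
  utils::write.csv(at, attr_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Restrict a network to its largest connected component
#'
#' Ties in component size are broken deterministically in favour of the
#' component containing the smallest node identifier.
#'
#' @param net an \code{rds_network}.
#' @return The induced subnetwork on the largest component.
#' @export
largest_component <- function(net) {
  if (!length(net$nodes)) stop_fmt("empty network")
  comp <- igraph::components(as_igraph(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # nodes are sorted, so the first node's membership wins the tie only if
    # its component is among the largest; otherwise take the tied component
    # whose minimum member (in sorted order) comes first
    firsts <- vapply(best, function(k) min(which(comp$membership == k)), 0L)
    best <- best[which.min(firsts)]
  }
  keep <- which(comp$membership == best)
  induced_network(net, keep)
}

induced_network <- function(net, keep) {
  keep <- sort(unique(keep))
  sel <- net$edges[, 1L] %in% keep & net$edges[, 2L] %in% keep
  nodes <- net$nodes[keep]
  y <- stats::setNames(net$y[keep], nodes)
  em <- cbind(net$nodes[net$edges[sel, 1L]], net$nodes[net$edges[sel, 2L]])
  if (!length(em)) em <- matrix(character(0), 0L, 2L)
  z <- if (!is.null(net$z)) stats::setNames(net$z[keep], nodes) else NULL
  rds_network(em, y, z = z)
}

#' Specification of the two-block (Y by Z) homophily model
#'
#' The population is split into four equal cells by the observed binary
#' variable Y and a hidden binary variable Z that structures cross-group
#' mixing: Z = 0 individuals befriend only their own Y group, Z = 1
#' individuals carry all cross-Y ties. \code{D}, \code{E}, \code{F} and
#' \code{H} are friendship-end (ordered-pair) counts per cell pair: \code{D}
#' within each Z = 0 cell, \code{E} between the two cells of a Y group,
#' \code{F} within each Z = 1 cell, and \code{H} across Y groups (between
#' the two Z = 1 cells). Equal total degree per cell forces
#' \code{D = F + H}. The induced mixing parameters are
#' \code{a = E/(E+F+H)} (within-Y, cross-Z transitions) and
#' \code{b = H/(E+F+H)} (cross-Y transitions).
#'
#' @param E,F,H nonnegative tie counts.
#' @param D within-cell count for the Z = 0 cells; defaults to \code{F + H}.
#' @param n_per_cell population size of each of the four Y-by-Z cells
#'   (used by \code{\link{realize_block_network}}).
#' @return An object of class \code{block_spec} with fields \code{D},
#'   \code{E}, \code{F}, \code{H}, \code{a}, \code{b}, \code{n_per_cell}.
#' @export
block_spec <- function(E, F, H, D = F + H, n_per_cell = 30L) {
  vals <- c(D = D, E = E, F = F, H = H)
  if (any(vals < 0)) stop_fmt("tie counts must be nonnegative")
  if (D != F + H) stop_fmt("equal cell degrees require D = F + H (got D=%g, F+H=%g)",
                           D, F + H)
  tot <- E + F + H
  if (tot <= 0) stop_fmt("E + F + H must be positive")
  a <- E / tot; b <- H / tot
  if (a + b > 1 + 1e-12) stop_fmt("infeasible spec: a + b > 1")
  structure(list(D = D, E = E, F = F, H = H, a = a, b = b,
                 n_per_cell = as.integer(n_per_cell)),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("block_spec: D=%g E=%g F=%g H=%g  (a=%.4f, b=%.4f), %d per cell\n",
              x$D, x$E, x$F, x$H, x$a, x$b, x$n_per_cell))
  invisible(x)
}

# cells in fixed order: 1 = Y0Z0, 2 = Y0Z1, 3 = Y1Z1, 4 = Y1Z0
block_cells <- function() {
  data.frame(cell = 1:4, y = c(0L, 0L, 1L, 1L), z = c(0L, 1L, 1L, 0L))
}

#' Realize a block specification as a node-level network
#'
#' Places the exact number of edges implied by the specification uniformly at
#' random (without replacement) within each cell pair: \code{D/2} undirected
#' edges inside each Z = 0 cell, \code{F/2} inside each Z = 1 cell, \code{E}
#' between the two cells of each Y group, and \code{H} between the two Z = 1
#' cells. Counts are friendship ends, so \code{D} and \code{F} must be even.
#' Aggregated to cells, the realized network's transition chain equals
#' \code{\link{table1_chain}} in expectation.
#'
#' @param spec a \code{\link{block_spec}}.
#' @param seed integer seed; the realization is reproducible given the seed.
#' @return An \code{rds_network} with \code{y} and \code{z} assigned per cell.
#' @export
realize_block_network <- function(spec, seed) {
  stopifnot(inherits(spec, "block_spec"))
  n <- spec$n_per_cell
  if (n < 2L) stop_fmt("n_per_cell must be at least 2")
  if (spec$D %% 2 != 0) stop_fmt("D must be even (friendship-end count)")
  if (spec$F %% 2 != 0) stop_fmt("F must be even (friendship-end count)")
  within <- c(spec$D / 2, spec$F / 2, spec$F / 2, spec$D / 2)
  maxw <- n * (n - 1) / 2
  for (k in 1:4) {
    if (within[k] > maxw) {
      stop_fmt("infeasible within-cell count for cell %d: %g edges > %g possible",
               k, within[k], maxw)
    }
  }
  cross <- list(c(1L, 2L, spec$E), c(3L, 4L, spec$E), c(2L, 3L, spec$H))
  for (cp in cross) {
    if (cp[3L] > n * n) {
      stop_fmt("infeasible cross-cell count for cells %d-%d: %g edges > %g possible",
               cp[1L], cp[2L], cp[3L], n * n)
    }
  }
  cells <- block_cells()
  wid <- max(2L, nchar(as.character(n)))
  ids <- lapply(1:4, function(k) sprintf("c%d_%0*d", k, wid, seq_len(n)))
  with_seed(seed, {
    ep <- list()
    for (k in 1:4) {
      nw <- within[k]
      if (nw > 0) {
        sel <- sample.int(maxw, nw)
        # decode unordered pair index -> (i, j), i < j; guard sqrt rounding
        j <- ceiling((1 + sqrt(1 + 8 * sel)) / 2)
        i <- sel - (j - 1) * (j - 2) / 2
        bad <- i < 1
        j[bad] <- j[bad] - 1L
        i[bad] <- sel[bad] - (j[bad] - 1) * (j[bad] - 2) / 2
        bad <- i > j - 1
        j[bad] <- j[bad] + 1L
        i[bad] <- sel[bad] - (j[bad] - 1) * (j[bad] - 2) / 2
        ep[[length(ep) + 1L]] <- cbind(ids[[k]][i], ids[[k]][j])
      }
    }
    for (cp in cross) {
      ncr <- cp[3L]
      if (ncr > 0) {
        sel <- sample.int(n * n, ncr)
        i <- ((sel - 1L) %% n) + 1L
        j <- ((sel - 1L) %/% n) + 1L
        ep[[length(ep) + 1L]] <- cbind(ids[[cp[1L]]][i], ids[[cp[2L]]][j])
      }
    }
    em <- do.call(rbind, ep)
    allids <- unlist(ids)
    y <- stats::setNames(rep(cells$y, each = n), allids)
    z <- stats::setNames(rep(cells$z, each = n), allids)
    rds_network(em, y, z = z)
  })
}

#' Assign an i.i.d. Bernoulli attribute to a network
#'
#' Null-model fixture: replaces \code{y} with independent Bernoulli(p) draws,
#' one per node, reproducibly given the seed.
#'
#' @param net an \code{rds_network}.
#' @param p success probability in [0, 1].
#' @param seed integer seed.
#' @return The network with the new attribute.
#' @export
assign_iid_attribute <- function(net, p, seed) {
  stopifnot(p >= 0, p <= 1)
  y <- with_seed(seed, stats::rbinom(length(net$nodes), 1L, p))
  net$y <- as.integer(y)
  net
}
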