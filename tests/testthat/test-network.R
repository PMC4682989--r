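test_that("edge lists parse, symmetrize and collapse duplicates", {
  ed <- tempfile(fileext = ".tsv"); at <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "1 2", "2 3", "3 1", "2 1"), ed)
  write.csv(data.frame(node = c("1", "2", "3"), y = c(1, 1, 1)), at,
            row.names = FALSE)
  net <- load_network(ed, "edgelist", attrs = at)
  expect_equal(net$m, 3L)
  expect_equal(net$degree, c(2L, 2L, 2L))
  expect_equal(sum(net$degree), 2L * net$m)
  # self-loops dropped, reciprocal rows merged
  writeLines(c("1 1", "1 2", "2 1"), ed)
  net2 <- load_network(ed, "edgelist", attrs = at)
  expect_equal(net2$m, 1L)
})

test_that("missing or non-binary attributes are rejected with named nodes", {
  ed <- tempfile(); at <- tempfile()
  writeLines(c("1 2", "2 3"), ed)
  write.csv(data.frame(node = c("1", "2"), y = c(1, 0)), at, row.names = FALSE)
  expect_error(load_network(ed, "edgelist", attrs = at), "3")
  write.csv(data.frame(node = c("1", "2", "3"), y = c("x", "y", "x")), at,
            row.names = FALSE)
  expect_error(load_network(ed, "edgelist", attrs = at), "dichotomize")
  net <- load_network(ed, "edgelist", attrs = at,
                      dichotomize = function(v) v == "x")
  expect_equal(sum(net$y), 2L)
})

test_that("largest_component keeps the biggest piece, ties to smallest id", {
  tri_plus <- rds_network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                c("x", "y")),
                          c(a = 1, b = 1, c = 1, x = 0, y = 0))
  lc <- largest_component(tri_plus)
  expect_setequal(lc$nodes, c("a", "b", "c"))
  # connected graph is unchanged
  tri <- triangle_net()
  expect_equal(largest_component(tri)$nodes, tri$nodes)
  # equal components: keep the one holding the smallest identifier
  two <- rds_network(rbind(c("1", "2"), c("3", "4")),
                     c(`1` = 1, `2` = 0, `3` = 1, `4` = 0))
  expect_setequal(largest_component(two)$nodes, c("1", "2"))
})

test_that("GraphML round trip preserves structure and attributes", {
  net <- rds_network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                           c("p", "q")),
                     c(a = 1, b = 0, c = 1, p = 0, q = 1))
  g <- rdsvar:::as_igraph(net)
  igraph::V(g)$y <- net$y
  gp <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, gp, format = "graphml")
  back <- load_network(gp, "graphml", attr_name = "y")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$y, net$y)
  expect_equal(back$m, net$m)
  expect_setequal(largest_component(back)$nodes, c("a", "b", "c"))
})

test_that("edge-list writer round-trips a network", {
  net <- realize_block_network(block_spec(E = 20, F = 10, H = 10,
                                          n_per_cell = 10L), seed = 5L)
  ed <- tempfile(); at <- tempfile()
  write_network(net, ed, at)
  back <- load_network(ed, "edgelist", attrs = at)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$y, net$y)
})

test_that("block realization places the exact per-cell-pair edge counts", {
  sp <- block_spec(E = 10, F = 10, H = 10, n_per_cell = 30L)
  expect_equal(sp$D, 20)        # equal-degree identity D = F + H
  net <- realize_block_network(sp, seed = 11L)
  cell <- substr(net$nodes, 1L, 2L)
  pair <- table(cell[net$edges[, 1L]], cell[net$edges[, 2L]])
  count <- function(u, v) {
    n <- 0
    if (u %in% rownames(pair) && v %in% colnames(pair)) n <- n + pair[u, v]
    if (u != v && v %in% rownames(pair) && u %in% colnames(pair))
      n <- n + pair[v, u]
    as.numeric(n)
  }
  expect_equal(count("c1", "c1"), sp$D / 2)
  expect_equal(count("c2", "c2"), sp$F / 2)
  expect_equal(count("c3", "c3"), sp$F / 2)
  expect_equal(count("c4", "c4"), sp$D / 2)
  expect_equal(count("c1", "c2"), sp$E)
  expect_equal(count("c3", "c4"), sp$E)
  expect_equal(count("c2", "c3"), sp$H)
  expect_equal(count("c1", "c3") + count("c1", "c4") + count("c2", "c4"), 0)
  expect_equal(sum(net$degree), 2 * net$m)
  # same seed, same realization
  net2 <- realize_block_network(sp, seed = 11L)
  expect_identical(net$edges, net2$edges)
})

test_that("cell-aggregated walk chain of a realization matches the block chain", {
  sp <- block_spec(E = 40, F = 30, H = 50, n_per_cell = 25L)
  net <- realize_block_network(sp, seed = 3L)
  cell <- substr(net$nodes, 1L, 2L)
  # friendship-end counts per ordered cell pair / cell degree sums:
  # the stationary-weighted aggregation of the node walk is exact
  ends <- matrix(0, 4, 4, dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
  for (k in 1:2) {
    from <- cell[net$edges[, k]]; to <- cell[net$edges[, 3L - k]]
    tab <- table(factor(from, levels = rownames(ends)),
                 factor(to, levels = rownames(ends)))
    ends <- ends + as.matrix(tab)
  }
  agg <- ends / rowSums(ends)
  expect_equal(unname(agg), table1_chain(sp)$P, tolerance = 1e-12)
})

test_that("infeasible block specs fail naming the violated cell pair", {
  expect_error(block_spec(E = 10, F = 10, H = 10, D = 15), "D = F \\+ H")
  sp <- block_spec(E = 10, F = 10, H = 10, n_per_cell = 4L)
  expect_error(realize_block_network(sp, seed = 1L), "within-cell")
})

test_that("i.i.d. attribute assignment is Bernoulli(p) and reproducible", {
  net <- er_net(1000L, 3000L, seed = 9L)
  expect_equal(sum(assign_iid_attribute(net, 0, seed = 1L)$y), 0L)
  expect_equal(sum(assign_iid_attribute(net, 1, seed = 1L)$y), 1000L)
  p <- mean(assign_iid_attribute(net, 0.5, seed = 2L)$y)
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / 1000))
  expect_identical(assign_iid_attribute(net, 0.5, seed = 2L)$y,
                   assign_iid_attribute(net, 0.5, seed = 2L)$y)
})
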