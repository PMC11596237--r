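test_that("pairwise correlation handles duplicates, reversals, guards", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(5, 4, 3, 2, 1))
  pc <- pairwise_correlation(m)
  expect_equal(pc$r["a", "b"], 1)
  expect_equal(pc$r["a", "c"], -1)
  expect_equal(diag(pc$r), c(a = 1, b = 1, c = 1))
  expect_equal(pc$r, t(pc$r))

  expect_error(pairwise_correlation(m[1:3, ]), ">= 4 samples")
  m2 <- cbind(m, flat = rep(2, 5))
  expect_warning(pc2 <- pairwise_correlation(m2), "zero-variance")
  expect_equal(pc2$dropped, "flat")
  expect_false("flat" %in% colnames(pc2$r))
})

test_that("Spearman r and p match an exhaustive permutation oracle", {
  set.seed(19)
  x <- matrix(c(3, 1, 4, 2, 5,
                2, 3, 1, 5, 4,
                5, 1, 2, 4, 3), ncol = 3)
  colnames(x) <- c("t1", "t2", "t3")
  pc <- pairwise_correlation(x, method = "spearman")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(pc$r[i, j],
                   cor(x[, i], x[, j], method = "spearman"))
      expect_equal(pc$p[i, j], perm_spearman_p(x[, i], x[, j]))
    }
  }
})

test_that("planted perfect pairs give the expected signed edge counts", {
  # one perfect positive (a~b) and two perfect negative (a~c, b~c);
  # exact two-sided permutation p = 1/60 for each, passing 0.05
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(10, 8, 6, 4, 2))
  net <- build_cooccurrence_network(pairwise_correlation(m))
  expect_equal(net$summary$total_links, 3L)
  expect_equal(net$summary$positive_links, 1L)
  expect_equal(net$summary$negative_links, 2L)
  expect_equal(net$summary$total_links,
               net$summary$positive_links + net$summary$negative_links)
})

test_that("edge filtering is monotone in r_min and respects p_max", {
  set.seed(3)
  m <- matrix(rnorm(8 * 10), 8, dimnames = list(NULL, letters[1:10]))
  pc <- pairwise_correlation(m)
  sizes <- sapply(c(0, 0.3, 0.6, 0.9), function(rm) {
    build_cooccurrence_network(pc, r_min = rm)$summary$total_links
  })
  expect_true(all(diff(sizes) <= 0))
  # all p forced to 1 -> empty network
  empty <- build_cooccurrence_network(pc$r,
                                      matrix(1, 10, 10,
                                             dimnames = dimnames(pc$r)))
  expect_equal(empty$summary$total_links, 0L)
  expect_error(build_cooccurrence_network(pc, r_min = 1.5), "r_min")
  # every kept edge satisfies both thresholds
  net <- build_cooccurrence_network(pc, r_min = 0.3, p_max = 0.2)
  if (nrow(net$edges) > 0) {
    expect_true(all(abs(net$edges$r) >= 0.3))
    expect_true(all(net$edges$p <= 0.2))
  }
})

test_that("edge summaries are invariant under taxon column permutation", {
  set.seed(29)
  m <- matrix(rpois(6 * 8, 20), 6, dimnames = list(NULL, letters[1:8]))
  n1 <- build_cooccurrence_network(pairwise_correlation(m),
                                   r_min = 0.5, p_max = 0.3)
  perm <- sample(8)
  n2 <- build_cooccurrence_network(pairwise_correlation(m[, perm]),
                                   r_min = 0.5, p_max = 0.3)
  expect_equal(n1$summary, n2$summary)
  key <- function(e) sort(paste(pmin(e$source, e$target),
                                pmax(e$source, e$target)))
  expect_equal(key(n1$edges), key(n2$edges))
})

test_that("independent taxa yield a near-empty BH-adjusted network", {
  set.seed(41)
  hits <- replicate(5, {
    m <- matrix(rpois(12 * 15, 30), 12,
                dimnames = list(NULL, paste0("t", 1:15)))
    net <- build_cooccurrence_network(pairwise_correlation(m),
                                      adjust = "BH")
    net$summary$total_links
  })
  expect_lte(mean(hits), 1)
})

test_that("centrality scores match structural expectations and a loop", {
  # star: hub h connected to 4 leaves
  star_p <- matrix(0.5, 5, 5,
                   dimnames = list(c("h", "l1", "l2", "l3", "l4"),
                                   c("h", "l1", "l2", "l3", "l4")))
  star_r <- diag(5)
  dimnames(star_r) <- dimnames(star_p)
  star_r["h", c("l1", "l2", "l3", "l4")] <- 0.9
  star_r[c("l1", "l2", "l3", "l4"), "h"] <- 0.9
  star_p[abs(star_r) > 0.5] <- 0.001
  star <- build_cooccurrence_network(star_r, star_p)
  deg <- network_centrality(star, "degree")
  expect_equal(unname(deg["h"]), 4)
  expect_true(all(deg["h"] > deg[c("l1", "l2", "l3", "l4")]))
  # degree equals brute-force neighbour count from the edge list
  for (v in names(deg)) {
    expect_equal(unname(deg[v]),
                 sum(star$edges$source == v | star$edges$target == v))
  }
  expect_equal(keystone_taxa(star, top_k = 1)$taxon, "h")

  # path a - b - c: middle betweenness 1, ends 0
  path_r <- diag(3); dimnames(path_r) <- list(letters[1:3], letters[1:3])
  path_r["a", "b"] <- path_r["b", "a"] <- 0.9
  path_r["b", "c"] <- path_r["c", "b"] <- 0.9
  path_p <- matrix(1, 3, 3, dimnames = dimnames(path_r))
  path_p[abs(path_r) > 0.5 & row(path_r) != col(path_r)] <- 0.001
  pth <- build_cooccurrence_network(path_r, path_p)
  btw <- network_centrality(pth, "betweenness")
  expect_equal(unname(btw), c(0, 1, 0))

  # eigenvector on an edgeless graph is an undefined-flag
  none <- build_cooccurrence_network(diag(3) * 0 + diag(3),
                                     matrix(1, 3, 3,
                                            dimnames = dimnames(path_r)))
  expect_warning(ev <- network_centrality(none, "eigenvector"),
                 "undefined")
  expect_true(all(is.na(ev)))
})

test_that("keystone ranking is deterministic with lexicographic ties", {
  scores <- c(zeta = 3, alpha = 3, mid = 2)
  net <- structure(list(), class = "cooccurrence_network")
  ks <- keystone_taxa(net, scores, top_k = 3)
  expect_equal(ks$taxon, c("alpha", "zeta", "mid"))
  expect_equal(keystone_taxa(net, scores, top_k = 10)$taxon,
               c("alpha", "zeta", "mid"))
  expect_error(keystone_taxa(net, scores, top_k = 0), "top_k")
})

test_that("network files round-trip the edge list and summary", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(10, 8, 6, 4, 2))
  net <- build_cooccurrence_network(pairwise_correlation(m))
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  edges <- read.csv(paths["edges"])
  expect_equal(nrow(edges), 3L)
  summ <- jsonlite::read_json(paths["summary"])
  expect_equal(summ$total_links, 3L)
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::ecount(g), 3)
})
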