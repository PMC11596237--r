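test_that("trait fixture covers every component (trophic, c-p) class", {
  tr <- default_trait_fixture()
  nem <- tr[tr$group == "nematode", ]
  expect_gte(nrow(nem), 24)
  expect_gte(sum(tr$group == "bacteria"), 40)
  expect_gte(sum(tr$group == "fungi"), 20)
  expect_true(all(nem$mass_ug > 0))
  # every combination entering e, b or s is represented
  need <- rbind(expand.grid(trophic = "BF", cp = 1:5),
                expand.grid(trophic = "FF", cp = 2:5),
                expand.grid(trophic = "OP", cp = 3:5),
                expand.grid(trophic = "PP", cp = 2:5))
  have <- unique(nem[c("trophic", "cp")])
  for (i in seq_len(nrow(need))) {
    expect_true(any(have$trophic == need$trophic[i] &
                      have$cp == need$cp[i]),
                info = paste(need$trophic[i], need$cp[i]))
  }
  # round-trips through the trait reader unchanged
  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tr, path)
  expect_equal(read_trait_table(path), tr)
})

test_that("simulation is a deterministic function of the config", {
  cfg <- synthetic_config(seed = 123)
  s1 <- simulate_foodweb(cfg)
  s2 <- simulate_foodweb(cfg)
  expect_identical(s1$nematodes$abundance, s2$nematodes$abundance)
  expect_identical(s1$bacteria$abundance, s2$bacteria$abundance)
  expect_identical(s1$fungi$abundance, s2$fungi$abundance)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_foodweb(synthetic_config(seed = 124))
  expect_false(identical(s1$nematodes$abundance,
                         s3$nematodes$abundance))
  # simulation does not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(simulate_foodweb(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("config validation rejects degenerate designs", {
  expect_error(synthetic_config(n_replicates = 1), "n_replicates")
  expect_error(synthetic_config(dispersion = 0), "dispersion")
  mult <- rbind(BF = 1, FF = 1, PP = -1, OP = 1)
  colnames(mult) <- "CK"
  expect_error(synthetic_config(treatments = "CK", multipliers = mult),
               "> 0")
})

test_that("near-unit multipliers leave group means flat at large n", {
  mult <- matrix(1, 4, 4, dimnames = list(c("BF", "FF", "PP", "OP"),
                                          c("CK", "Y2", "Y9", "Y18")))
  sim <- simulate_foodweb(synthetic_config(seed = 5, n_replicates = 150,
                                           multipliers = mult))
  agg <- aggregate_trophic(sim$nematodes, sim$traits)
  agg$treatment <- sim$metadata$treatment
  means <- tapply(agg$PP, agg$treatment, mean)
  expect_lt(diff(range(means)) / mean(means), 0.15)
})

test_that("declining PP multipliers give monotone mean PP abundance", {
  mult <- rbind(BF = c(1, 1, 1), FF = c(1, 1, 1),
                PP = c(1.0, 0.6, 0.3), OP = c(1, 1, 1))
  colnames(mult) <- c("Y2", "Y9", "Y18")
  cfg <- synthetic_config(seed = 11, treatments = c("Y2", "Y9", "Y18"),
                          n_replicates = 200, multipliers = mult,
                          covariate_trends = data.frame(
                            treatment = c("Y2", "Y9", "Y18"),
                            SM = 0.15, SOC = 10, TN = 1, TP = 0.8,
                            AP = 10, pH = 8.4, BD = 1.25))
  sim <- simulate_foodweb(cfg)
  agg <- aggregate_trophic(sim$nematodes, sim$traits)
  means <- tapply(agg$PP, sim$metadata$treatment, mean)[
    c("Y2", "Y9", "Y18")]
  expect_true(all(diff(means) < 0))
})

test_that("counts recover the configured negative-binomial moments", {
  cfg <- synthetic_config(seed = 31, treatments = "CK",
                          n_replicates = 400,
                          multipliers = matrix(
                            1, 4, 1, dimnames = list(
                              c("BF", "FF", "PP", "OP"), "CK")),
                          dispersion = 0.5,
                          n_correlated_pairs = 0L,
                          covariate_trends = data.frame(
                            treatment = "CK", SM = 0.15, SOC = 10,
                            TN = 1, TP = 0.8, AP = 10, pH = 8.4,
                            BD = 1.25))
  sim <- simulate_foodweb(cfg)
  x <- sim$nematodes$abundance
  n <- nrow(x)
  ok_mean <- ok_var <- 0L
  for (tx in colnames(x)) {
    mu <- sim$expected_mu$nematodes[1, tx]  # constant within treatment
    m <- mean(x[, tx]); v <- var(x[, tx])
    # NB with dispersion phi: var = mu + phi mu^2
    v_expect <- mu + 0.5 * mu^2
    se_mean <- sqrt(v_expect / n)
    # SE of the sample variance via the empirical 4th central moment
    mu4 <- mean((x[, tx] - m)^4)
    se_var <- sqrt((mu4 - v^2 * (n - 3) / (n - 1)) / n)
    if (abs(m - mu) <= 3 * se_mean) ok_mean <- ok_mean + 1L
    if (abs(v - v_expect) <= 3 * se_var) ok_var <- ok_var + 1L
  }
  # ~3-sigma bands: nearly all of the 36 taxa must land inside
  expect_gte(ok_mean / ncol(x), 0.9)
  expect_gte(ok_var / ncol(x), 0.9)
})

test_that("planted pairs carry their configured correlation signs", {
  cfg <- synthetic_config(seed = 77, n_replicates = 50,
                          n_correlated_pairs = 6L)
  sim <- simulate_foodweb(cfg)
  all_mat <- cbind(sim$bacteria$abundance, sim$fungi$abundance)
  for (q in seq_len(nrow(sim$planted_pairs))) {
    r <- cor(all_mat[, sim$planted_pairs$taxon1[q]],
             all_mat[, sim$planted_pairs$taxon2[q]],
             method = "spearman")
    if (sim$planted_pairs$sign[q] == "positive") {
      expect_gt(r, 0.3)
    } else {
      expect_lt(r, -0.3)
    }
  }
})
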