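test_that("per-taxon metabolic footprint matches hand arithmetic", {
  expect_equal(metabolic_footprint(10, 1, 2), 3.23)
  expect_equal(metabolic_footprint(0, 5, 3), 0)
  expect_equal(metabolic_footprint(1, 16, 4), 0.4 + 0.273 * 8)
  expect_error(metabolic_footprint(1, 0, 2), "mass")
  expect_error(metabolic_footprint(1, 1, 0), "c-p")
})

test_that("group footprints are additive, homogeneous and match a loop", {
  tr <- toy_traits()
  nem <- tr[tr$group == "nematode", ]
  one <- toy_table(cbind(bf2 = 12), ids = "s1")
  gf1 <- group_footprints(one, tr)
  expect_equal(gf1$NMF_total, gf1$NMF_BF)
  expect_equal(gf1$NMF_FF + gf1$NMF_PP + gf1$NMF_OP, 0)

  set.seed(9)
  m <- matrix(rpois(3 * nrow(nem), 25), 3,
              dimnames = list(paste0("s", 1:3), nem$taxon))
  tab <- community_table(m, unit = "count_per_100g_dry")
  gf <- group_footprints(tab, tr)
  # doubling abundances doubles every footprint
  gf2 <- group_footprints(community_table(2 * m,
                                          unit = "count_per_100g_dry"),
                          tr)
  for (cl in c("NMF_BF", "NMF_FF", "NMF_PP", "NMF_OP", "NMF_total")) {
    expect_equal(gf2[[cl]], 2 * gf[[cl]])
  }
  # naive per-taxon accumulation oracle
  for (i in 1:3) {
    acc <- c(BF = 0, FF = 0, PP = 0, OP = 0)
    for (tx in nem$taxon) {
      row <- nem[nem$taxon == tx, ]
      acc[row$trophic] <- acc[row$trophic] +
        m[i, tx] * (0.1 * row$mass_ug / row$cp +
                    0.273 * row$mass_ug^0.75)
    }
    expect_equal(unlist(gf[i, c("NMF_BF", "NMF_FF", "NMF_PP",
                                "NMF_OP")]),
                 acc, ignore_attr = TRUE)
    expect_equal(gf$NMF_total[i], sum(acc))
  }
})

test_that("faunal components follow the literal memberships", {
  tr <- toy_traits()
  # only BF cp1
  c1 <- faunal_components(toy_table(cbind(bf1 = 10), ids = "s"), tr)
  expect_equal(unlist(c1[c("e", "b", "s")]), c(e = 10, b = 0, s = 0))
  # FF cp2 alone sits in both e and b
  c2 <- faunal_components(toy_table(cbind(ff2 = 8), ids = "s"), tr)
  expect_equal(unlist(c2[c("e", "b", "s")]), c(e = 8, b = 8, s = 0))
  # structural membership includes BF3-5, FF3, OP, and PP >= 2
  c3 <- faunal_components(
    toy_table(cbind(bf3 = 1, bf5 = 2, ff3 = 3, op4 = 4, pp2 = 5,
                    pp3 = 6), ids = "s"), tr)
  expect_equal(c3$s, 21)
  expect_equal(c3$e, 0)
})

test_that("ferris2001 weighting matches hand-weighted sums, excludes PP", {
  tr <- toy_traits()
  tab <- toy_table(cbind(bf1 = 10, ff2 = 8, bf3 = 5, pp3 = 7),
                   ids = "s")
  cw <- faunal_components(tab, tr, weights = "ferris2001")
  expect_equal(cw$e, 3.2 * 10 + 0.8 * 8)
  expect_equal(cw$b, 0.8 * 8)
  expect_equal(cw$s, 1.8 * 5)           # pp3 excluded from s
  cf <- component_footprints(tab, tr, weights = "ferris2001")
  # Fe/Fs stay unweighted sums of per-taxon footprints over memberships
  expect_equal(cf$Fe, metabolic_footprint(10, 0.5, 1) +
                 metabolic_footprint(8, 0.25, 2))
  expect_equal(cf$Fs, metabolic_footprint(5, 0.6, 3))
  expect_error(faunal_components(tab, tr, weights = c(1, -1, 1, 1, 1)),
               "> 0")
})

test_that("enrichment and structure indices are bounded shares of 100", {
  expect_equal(enrichment_index(10, 10), 50)
  expect_equal(enrichment_index(30, 10), 75)
  expect_equal(structure_index(0, 5), 0)
  expect_true(is.na(enrichment_index(0, 0)))
  expect_error(structure_index(-1, 2), ">= 0")
  # basal-only community: EI = 0 and SI = 0
  tr <- toy_traits()
  comp <- faunal_components(toy_table(cbind(bf2 = 30), ids = "s"), tr)
  expect_equal(enrichment_index(comp$e, comp$b), 0)
  expect_equal(structure_index(comp$s, comp$b), 0)
})

test_that("functional footprint traces the stated rhombus", {
  ff <- functional_footprint(50, 50, 200, 400, k = 100)
  expect_equal(ff$vertices,
               rbind(c(50, 49), c(52, 50), c(50, 51), c(48, 50)),
               ignore_attr = TRUE)
  expect_equal(ff$area, 4.0)
  expect_equal(functional_footprint(50, 50, 0, 400)$area, 0)
  expect_error(functional_footprint(50, 50, 1, 1, k = 0), "k")
})

test_that("shoelace area equals the closed form and scales as 1/k^2", {
  set.seed(31)
  for (i in 1:200) {
    fe <- runif(1, 0, 1000); fs <- runif(1, 0, 1000)
    k <- runif(1, 10, 500)
    si <- runif(1, 0, 100); ei <- runif(1, 0, 100)
    a <- functional_footprint(si, ei, fe, fs, k)$area
    expect_equal(a, 0.5 * (fe / k) * (fs / k), tolerance = 1e-9)
    # translation invariance of (SI, EI)
    expect_equal(functional_footprint(si + 7, ei - 3, fe, fs, k)$area, a)
    # 1/k^2 scaling
    expect_equal(functional_footprint(si, ei, fe, fs, 2 * k)$area, a / 4)
  }
})

test_that("quadrant classification uses the 50/50 convention with ties", {
  expect_equal(faunal_quadrant(70, 30), "A")
  expect_equal(faunal_quadrant(70, 70), "B")
  expect_equal(faunal_quadrant(30, 70), "C")
  expect_equal(faunal_quadrant(30, 30), "D")
  expect_equal(faunal_quadrant(70, 50), "A")   # SI tie goes down
  expect_equal(faunal_quadrant(50, 70), "C")   # EI tie goes down
  expect_true(is.na(faunal_quadrant(NA, 30)))
})

test_that("compute_footprints assembles a consistent faunal profile", {
  tr <- toy_traits()
  nem <- tr[tr$group == "nematode", ]
  set.seed(13)
  m <- matrix(rpois(3 * nrow(nem), 20), 3,
              dimnames = list(paste0("s", 1:3), nem$taxon))
  tab <- community_table(m, unit = "count_per_100g_dry")
  fp <- compute_footprints(tab, tr)
  comp <- faunal_components(tab, tr)
  cf <- component_footprints(tab, tr)
  expect_equal(fp$NMF_total,
               fp$NMF_BF + fp$NMF_FF + fp$NMF_PP + fp$NMF_OP)
  expect_equal(fp$EI, enrichment_index(comp$e, comp$b))
  expect_equal(fp$SI, structure_index(comp$s, comp$b))
  expect_equal(fp$F_area, 0.5 * (cf$Fe / 100) * (cf$Fs / 100))
  expect_equal(fp$quadrant, faunal_quadrant(fp$EI, fp$SI))
})
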