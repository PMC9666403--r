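# Goodness of fit, exact Fisher, and the enrichment scan.

test_that("expected counts are the unrounded composition-proportional null", {
  comp <- data.frame(category = c("helix", "sheet", "loop"),
                     fraction = c(0.39, 0.12, 0.49))
  e <- expected_counts(comp, 119)
  expect_equal(unname(e), c(46.41, 14.28, 58.31))
  expect_equal(sum(e), 119)
  expect_equal(unname(expected_counts(comp, 0)), c(0, 0, 0))
  # conservation under arbitrary compositions
  set.seed(7)
  for (i in 1:20) {
    f <- as.numeric(rmultinom(1, 500, runif(5))) / 500
    comp_i <- data.frame(category = letters[1:5], fraction = f)
    expect_equal(sum(expected_counts(comp_i, 37)), 37, tolerance = 1e-9)
  }
  expect_error(expected_counts(data.frame(category = "a", fraction = 0.5), 3),
               "sum to 1")
})

test_that("goodness of fit matches hand arithmetic and the density integral", {
  g0 <- chi2_gof(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(g0$statistic), 0)
  expect_equal(g0$p.value, 1)
  g <- chi2_gof(c(8, 2), c(5, 5))
  expect_equal(unname(g$statistic), 3.6)
  expect_identical(unname(g$parameter), 1L)
  # oracle: numerically integrate the chi-squared density over the tail
  tail_mass <- integrate(function(t) dchisq(t, 1), 3.6, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(g$p.value, tail_mass, tolerance = 1e-8)
  expect_equal(g$p.value, 0.05778, tolerance = 1e-4)
  # statistic is category-permutation invariant
  perm <- sample(3)
  ga <- chi2_gof(c(5, 9, 16), c(6, 10, 14))
  gb <- chi2_gof(c(5, 9, 16)[perm], c(6, 10, 14)[perm])
  expect_equal(ga$statistic, gb$statistic)
  expect_error(chi2_gof(c(1, 2), c(3, 0)), "merge")
  expect_error(chi2_gof(c(1, 2, 3), c(1, 2)), "same length")
})

test_that("chi-squared tail and quantile behave at the boundaries", {
  expect_equal(chi2_sf(0, 1), 1)
  expect_equal(chi2_sf(0, 17), 1)
  expect_error(chi2_sf(-1, 2), ">= 0")
  expect_error(chi2_sf(1, 0), "df")
  expect_error(chi2_quantile(0, 2), "in \\(0, 1\\)")
  expect_error(chi2_quantile(1, 2), "in \\(0, 1\\)")
  expect_lt(chi2_quantile(1e-10, 3), 1e-2)
  # quantile inverts the tail probability
  for (df in c(1, 2, 4, 6, 11)) {
    for (q in c(0.05, 0.5, 0.9, 0.95, 0.999)) {
      x <- chi2_quantile(q, df)
      expect_equal(chi2_sf(x, df), 1 - q, tolerance = 1e-6)
    }
  }
})

test_that("the two-sided Fisher p matches enumeration and known values", {
  expect_equal(fisher_two_sided(rbind(c(3, 1), c(1, 3))), 34 / 70)
  expect_equal(fisher_two_sided(rbind(c(0, 0), c(5, 7))), 1)
  expect_equal(fisher_two_sided(rbind(c(0, 5), c(0, 7))), 1)
  expect_error(fisher_two_sided(rbind(c(0, 0), c(0, 0))), "positive")
  expect_error(fisher_two_sided(rbind(c(-1, 2), c(1, 1))), "non-negative")
  # symmetry: transpose and row swap leave p unchanged
  set.seed(11)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_two_sided(tab)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(fisher_two_sided(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_two_sided(tab[2:1, ]), p, tolerance = 1e-12)
    # independent route: stats::fisher.test
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-8)
    }
  }
  # one-sided enrichment option
  expect_equal(fisher_two_sided(rbind(c(4, 0), c(0, 4)), "greater"),
               1 / choose(8, 4))
})

test_that("the enrichment scan has the right shape and degenerate behavior", {
  toy <- get_toy(1)
  labels <- toy_alpha_labels(toy)
  comp <- toy_domain_composition(toy)
  tbl <- make_variant_table(labels, alpha_sequence(toy$model),
                            n_per_phenotype = c(lissencephaly = 15,
                                                pachygyria = 15,
                                                not_available = 10),
                            seed = 2)
  w <- testthat::capture_warnings(scan <- enrichment_scan(tbl, labels, comp))
  expect_true(any(grepl("zero variants", w)))
  expect_identical(nrow(scan$results), 4L * 7L)
  expect_true(all(scan$results$p >= 0 & scan$results$p <= 1))
  # phenotypes with no variants get p = 1 across the board
  deg <- scan$results[scan$results$phenotype == "polymicrogyria", ]
  expect_true(all(deg$p == 1) && all(deg$degenerate))
  # the not_available rows were dropped from the per-phenotype tests but
  # kept in the global goodness of fit
  expect_identical(scan$n_clinical, 30L)
  expect_identical(scan$n_total, 40L)
  expect_identical(sum(scan$gof$observed), 40L)
  # summary matrix mirrors the long results
  sm <- summary(scan)$p_matrix
  expect_identical(dim(sm), c(7L, 4L))
  expect_equal(sm["lateral", "pachygyria"],
               scan$results$p[scan$results$phenotype == "pachygyria" &
                                scan$results$category == "lateral"])
  # background modes are accepted and stay in [0, 1]
  for (bg in c("expected", "other_mutations")) {
    s2 <- suppressWarnings(enrichment_scan(tbl, labels, comp,
                                           background = bg))
    expect_true(all(s2$results$p >= 0 & s2$results$p <= 1))
  }
  expect_error(enrichment_scan(tbl, labels, comp, alpha = 1.2), "alpha")
})

test_that("simulate() draws composition-null count tables", {
  toy <- get_toy(1)
  labels <- toy_alpha_labels(toy)
  comp <- toy_domain_composition(toy)
  tbl <- make_variant_table(labels, alpha_sequence(toy$model), seed = 3)
  scan <- enrichment_scan(tbl, labels, comp)
  sims <- simulate(scan, nsim = 3, seed = 1)
  expect_length(sims, 3L)
  expect_identical(dim(sims[[1]]), c(7L, 4L))
  expect_equal(unname(colSums(sims[[1]])), rep(30, 4))
})
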