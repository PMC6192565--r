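# Scaling, imputation, the five weighting schemes, pipeline properties.

test_that("dissimilarity conversion flips similarities and preserves order", {
  expect_equal(to_dissimilarity(0.9, "similarity"), -0.9)
  expect_equal(to_dissimilarity(2.5, "dissimilarity"), 2.5)
  a <- runif(10)
  expect_equal(order(to_dissimilarity(a, "similarity")), order(-a))
})

test_that("scaling parameters are the mean and population sd", {
  p <- fit_scaling_params(c(1, 1, 1))
  expect_equal(c(p$mu, p$sigma), c(1, 0))
  p2 <- fit_scaling_params(c(0, 2))
  expect_equal(c(p2$mu, p2$sigma), c(1, 1))
  p3 <- fit_scaling_params(c(1, NA, 3))
  expect_equal(p3$mu, 2)
  expect_error(fit_scaling_params(c(NA_real_, NA_real_), "m"), "no scores")
})

test_that("the sigmoid maps mu to 0.5 and decreases with dissimilarity", {
  p <- list(mu = 3, sigma = 2)
  expect_equal(logistic_scale(3, p), 0.5, tolerance = 1e-15)
  expect_equal(logistic_scale(5, p), 1 - 1 / (1 + exp(-1)), tolerance = 1e-15)
  expect_lt(logistic_scale(1e6, p), 1e-10)
  expect_gt(logistic_scale(-1e6, p), 1 - 1e-10)
  # degenerate sigma: midpoint everywhere
  expect_equal(logistic_scale(c(-1, 0, 7), list(mu = 0, sigma = 0)),
               rep(0.5, 3))
  # affine invariance: positive-slope transforms of raw dissimilarities
  x <- rnorm(20)
  s1 <- logistic_scale(x, fit_scaling_params(x))
  y <- 3.7 * x + 11
  s2 <- logistic_scale(y, fit_scaling_params(y))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("local-average fill follows the directed-set union rule", {
  # missing (a,c): first-domain set for a = {0.8}, second-domain set for
  # c = {} -> impute 0.8
  tab <- score_table(data.frame(domain1 = c("a", "c"), domain2 = c("b", "a"),
                                method = "m", scaled = c(0.8, 0.4)),
                     domains = c("a", "b", "c"))
  out <- impute_local_average(tab, "m")
  rec <- out$records
  ac <- rec[rec$domain1 == "a" & rec$domain2 == "c", ]
  expect_equal(ac$scaled, 0.8)
  expect_true(ac$imputed)
  # present values untouched
  ab <- rec[rec$domain1 == "a" & rec$domain2 == "b", ]
  expect_equal(ab$scaled, 0.8)
  expect_false(ab$imputed)
  # no missing values remain, full ordered-pair coverage
  expect_equal(nrow(rec), 6)
  expect_false(anyNA(rec$scaled))
})

test_that("imputation matches a brute-force transcription on seeded tables", {
  for (seed in 1:20) {
    fix <- random_small_table(seed, miss_rate = 0.35)
    oracle <- naive_consensus(fix)
    res <- run_consensus(fix$table, specs_from(fix), m5_weights = fix$m5w)
    v <- res$views$imputed
    for (m in fix$table$methods)
      expect_equal(v[[m]], oracle$Simp[, m], tolerance = 1e-12)
    expect_false(anyNA(v[fix$table$methods]))
  }
})

test_that("generalized mean, weighted average and median behave per formula", {
  expect_equal(m1_generalized_mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(m1_generalized_mean(c(0.5), q = 3), 0.5)
  expect_equal(m1_generalized_mean(c(0.25, 1.0), q = 2),
               sqrt((0.0625 + 1) / 2), tolerance = 1e-15)
  expect_error(m1_generalized_mean(numeric(0)), "no available")

  expect_equal(weighted_consensus(c(0.2, 0.8), c(1, 3)), 0.65)
  expect_equal(weighted_consensus(c(NA, 0.8), c(1, 3)), 0.8)   # m = 1
  expect_equal(weighted_consensus(c(0.2, 0.8), c(1, 1)),
               m1_generalized_mean(c(0.2, 0.8)))
  expect_error(weighted_consensus(c(0.2, 0.8), c(0, 0)), "zero weight")

  expect_equal(median_mcpsc(c(0.1, 0.2, 0.3, 0.4, 0.9)), 0.3)
  expect_equal(median_mcpsc(rep(0.7, 5)), 0.7)
})

test_that("coverage and expert weighting compose as documented", {
  fix <- random_small_table(31, n_dom = 4, n_meth = 2, miss_rate = 0.4)
  tab <- mirror_symmetric(fix$table)
  P <- 4^2 - 4
  w2 <- m2_coverage_weights(tab)
  counts <- table(tab$records$method[!is.na(tab$records$raw)])
  expect_equal(unname(w2[names(counts)]), as.numeric(counts) / P)

  # published-style coverage arithmetic: counts / P give the percentages
  expect_equal(round(100 * 64964 / 72630), 89)
  expect_equal(round(100 * 39604 / 72630), 55)
  expect_equal(round(100 * 56406 / 72630), 78)

  w3 <- m3_expert_weights(tab, fix$expert)
  expect_equal(w3, w2 * fix$expert[names(w2)])
  specs_unit <- lapply(names(fix$polarity), function(m)
    psc_method(m, polarity = fix$polarity[[m]]))
  expect_equal(m3_expert_weights(tab, specs_unit), w2)
  expect_error(psc_method("z", expert_weight = 0), "> 0")

  # full coverage + halved expert weight on one of two methods
  full <- random_small_table(32, n_dom = 3, n_meth = 2, miss_rate = 0)
  full$expert <- c(meth1 = 1, meth2 = 0.5)
  w3f <- m3_expert_weights(mirror_symmetric(full$table), full$expert)
  expect_equal(unname(w3f / sum(w3f)), c(2 / 3, 1 / 3))
})

test_that("divergence weights match direct evaluation and degenerate to equal", {
  S <- cbind(a = c(0.1, 0.5, 0.9), b = c(0.2, 0.4, 0.8), c = c(0.9, 0.1, 0.3))
  w <- m4_divergence_weights(S)
  rmsd <- function(i, j) sqrt(mean((S[, i] - S[, j])^2))
  r <- c(a = (rmsd(1, 2) + rmsd(1, 3)) / 3,
         b = (rmsd(1, 2) + rmsd(2, 3)) / 3,
         c = (rmsd(1, 3) + rmsd(2, 3)) / 3)
  expect_equal(as.numeric(w), unname(r / max(r)), tolerance = 1e-12)
  expect_equal(max(w), 1)

  # identical methods: all divergences zero -> equal weights
  S2 <- cbind(a = c(0.1, 0.5), b = c(0.1, 0.5))
  expect_equal(as.numeric(m4_divergence_weights(S2)), c(1, 1))

  # order invariance: permuting methods permutes weights identically
  perm <- c(3, 1, 2)
  wp <- m4_divergence_weights(S[, perm])
  expect_equal(as.numeric(wp), as.numeric(w)[perm], tolerance = 1e-12)

  # no shared pairs is an error naming the methods
  S3 <- cbind(a = c(0.1, NA), b = c(NA, 0.5))
  expect_error(m4_divergence_weights(S3), "no scored pairs")
})

test_that("user weights pass through and learned weights find the signal", {
  expect_equal(m5_user_weights(weights = c(A = 1, B = 3)), c(A = 1, B = 3))
  expect_error(m5_user_weights(weights = c(A = -1, B = 1)), "non-negative")

  # planted fixture where one method is pure noise: learning should
  # weight the informative method higher
  cfg <- planted_config(domains_per_family = 2,
                        method_noise = c(good = 0.1, noise = 1e4), seed = 21)
  rec <- generate_labels(cfg)
  res <- run_consensus(generate_planted_scores(rec, cfg),
                       planted_method_specs(cfg),
                       m5_learn = list(labels = setNames(rec$label, rec$domain_id),
                                       level = 1, train_fraction = 0.2,
                                       seed = 7))
  expect_gt(res$weights$m5[["good"]], res$weights$m5[["noise"]])
})

test_that("pipeline equals the independent transcription on random tables", {
  for (seed in 1:40) {
    fix <- random_small_table(seed)
    oracle <- naive_consensus(fix)
    res <- run_consensus(fix$table, specs_from(fix), m5_weights = fix$m5w)
    for (col in c("m1", "m2", "m3", "m4", "m5", "median")) {
      expect_equal(res$views$imputed[[col]], oracle$imputed[[col]],
                   tolerance = 1e-12, label = paste("imputed", col, "seed", seed))
      expect_equal(res$views$original[[col]], oracle$original[[col]],
                   tolerance = 1e-12, label = paste("original", col, "seed", seed))
    }
  }
})

test_that("all consensus schemes are convex combinations of scaled scores", {
  fix <- random_small_table(99, n_dom = 5, n_meth = 3, miss_rate = 0.3)
  res <- run_consensus(fix$table, specs_from(fix), m5_weights = fix$m5w)
  for (view in names(res$views)) {
    v <- res$views[[view]]
    S <- as.matrix(v[fix$table$methods])
    # rows with no available method are all-NA; their consensus is NA too
    lo <- suppressWarnings(apply(S, 1, min, na.rm = TRUE))
    hi <- suppressWarnings(apply(S, 1, max, na.rm = TRUE))
    for (col in c("m1", "m2", "m3", "m4", "m5", "median")) {
      ok <- !is.na(v[[col]])
      expect_true(all(v[[col]][ok] >= lo[ok] - 1e-12))
      expect_true(all(v[[col]][ok] <= hi[ok] + 1e-12))
      expect_true(all(v[[col]][ok] >= 0 & v[[col]][ok] <= 1))
    }
  }
})

test_that("identical methods collapse every scheme to the common score", {
  base <- random_small_table(55, n_dom = 4, n_meth = 1, miss_rate = 0)
  rec <- base$table$records
  rec2 <- rbind(rec, transform(rec, method = "methB"),
                transform(rec, method = "methC"))
  tab <- score_table(rec2, methods = c("meth1", "methB", "methC"))
  pol <- setNames(rep(base$polarity[[1]], 3), c("meth1", "methB", "methC"))
  res <- run_consensus(tab, pol)
  v <- res$views$imputed
  for (col in c("m2", "m3", "m4", "m5", "median"))
    expect_equal(v[[col]], v$m1, tolerance = 1e-12)
})

test_that("a single method propagates unchanged through every scheme", {
  fix <- random_small_table(77, n_dom = 4, n_meth = 1, miss_rate = 0.2)
  res <- run_consensus(fix$table, specs_from(fix),
                       m5_weights = fix$m5w)
  v <- res$views$imputed
  for (col in c("m1", "m2", "m3", "m4", "m5", "median"))
    expect_equal(v[[col]], v[[fix$table$methods[1]]], tolerance = 1e-12)
})

test_that("common view keeps exactly the pairs scored by all methods", {
  fix <- random_small_table(13, n_dom = 5, n_meth = 3, miss_rate = 0.4)
  oracle <- naive_consensus(fix)
  res <- run_consensus(fix$table, specs_from(fix), m5_weights = fix$m5w)
  expect_equal(nrow(res$views$common), sum(rowSums(is.na(oracle$S0)) == 0))
  expect_equal(nrow(res$views$imputed), nrow(oracle$pairs))
})
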