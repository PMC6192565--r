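# Built-in scorers, external wrapper contract, parallel dispatch.

test_that("pair enumeration covers the all-to-all and pair-list modes", {
  expect_equal(enumerate_pairs(c("b", "a", "c")),
               data.frame(domain1 = c("a", "a", "b"),
                          domain2 = c("b", "c", "c")))
  pl <- data.frame(domain1 = "a", domain2 = "b")
  expect_equal(enumerate_pairs(c("a", "b", "c"), "pair_list", pl), pl)
  expect_error(enumerate_pairs(c("a", "b"), "pair_list",
                               data.frame(domain1 = "a", domain2 = "z")),
               "unknown domains: z")
  expect_error(enumerate_pairs("a"), "at least 2")
})

test_that("contact map obeys cutoff and sequence-separation rules", {
  colinear <- cbind(3.8 * (0:4), 0, 0)     # spacing 3.8 A
  m <- contact_map(colinear, cutoff = 8)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(0L, 5))
  # |i-j| = 2 -> 7.6 <= 8 contact; |i-j| = 1 excluded; |i-j| = 3 -> 11.4 > 8
  expect_equal(m[1, 3], 1L)
  expect_equal(m[1, 2], 0L)
  expect_equal(m[1, 4], 0L)
  expect_equal(sum(contact_map(colinear, cutoff = 5)), 0)

  set.seed(1)
  rnd <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_true(isSymmetric(contact_map(rnd)))
})

test_that("compression distance separates self from independent maps", {
  set.seed(7)
  mk <- function() contact_map(matrix(rnorm(150, sd = 6), 50, 3), cutoff = 8)
  a <- mk(); b <- mk()
  expect_equal(usm_distance(a, b), usm_distance(b, a))
  expect_lt(usm_distance(a, a), 0.3)                 # near-identity
  expect_gt(usm_distance(a, b), usm_distance(a, a))  # self < independent
  expect_gte(usm_distance(a, b), 0)
})

test_that("superposition similarity is exact on rigid motions", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_similarity(A, A), 1.0)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  moved <- A %*% R + matrix(c(5, -2, 3), 10, 3, byrow = TRUE)
  expect_equal(kabsch_similarity(A, moved), 1.0, tolerance = 1e-6)
  # length mismatch truncates to common leading length
  expect_equal(kabsch_similarity(A, rbind(moved, c(0, 0, 0))), 1.0,
               tolerance = 1e-6)
})

test_that("superposition similarity matches a brute-force rotation search", {
  set.seed(11)
  for (k in 1:3) {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(12), 4, 3)
    expected <- 1 / (1 + rmsd_bruteforce(A, B) / 3)
    expect_equal(kabsch_similarity(A, B), expected, tolerance = 1e-6)
  }
})

test_that("external method wrapper extracts scores and degrades on failure", {
  mkstub <- function(lines) {
    f <- tempfile(fileext = ".sh")
    writeLines(c("#!/bin/sh", lines), f)
    Sys.chmod(f, "0755")
    f
  }
  ok <- mkstub("echo \"TM-score= 0.4321 (normalized)\"")
  spec <- psc_method("tm", "similarity",
                     runner = list(command = paste(ok, "{pdb1}", "{pdb2}"),
                                   pattern = "TM-score=\\s*([0-9.]+)"))
  expect_equal(run_external_method(spec, "a.pdb", "b.pdb"), 0.4321)

  bad <- mkstub("exit 1")
  spec_bad <- psc_method("tm", "similarity",
                         runner = list(command = paste(bad, "{pdb1}", "{pdb2}"),
                                       pattern = "TM-score=\\s*([0-9.]+)"))
  expect_true(is.na(run_external_method(spec_bad, "a.pdb", "b.pdb")))

  slow <- mkstub(c("sleep 5", "echo \"TM-score= 0.9\""))
  spec_slow <- psc_method("tm", "similarity", timeout = 1,
                          runner = list(command = paste(slow, "{pdb1}", "{pdb2}"),
                                        pattern = "TM-score=\\s*([0-9.]+)"))
  expect_true(is.na(run_external_method(spec_slow, "a.pdb", "b.pdb")))

  nomatch <- mkstub("echo nothing useful")
  spec_nm <- psc_method("tm", "similarity",
                        runner = list(command = paste(nomatch, "{pdb1}", "{pdb2}"),
                                      pattern = "TM-score=\\s*([0-9.]+)"))
  expect_true(is.na(run_external_method(spec_nm, "a.pdb", "b.pdb")))
})

test_that("method config files declare external and builtin scorers", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# external aligner",
               "name = tmalign",
               "polarity = similarity",
               "command = tmalign {pdb1} {pdb2}",
               "pattern = TM-score=\\s*([0-9.]+)",
               "expert_weight = 2",
               "",
               "builtin = usm"), f)
  specs <- read_method_config(f)
  expect_length(specs, 2)
  expect_equal(specs[[1]]$name, "tmalign")
  expect_equal(specs[[1]]$expert_weight, 2)
  expect_equal(specs[[2]]$polarity, "dissimilarity")
  expect_equal(specs[[2]]$expert_weight, 0.5)
})

test_that("job dispatch is deterministic in the thread count", {
  cfg <- planted_config(folds_per_class = 1, superfams_per_fold = 1,
                        families_per_superfam = 2, domains_per_family = 2)
  rec <- generate_labels(cfg)             # 8 domains
  dir <- withr::local_tempdir()
  rec <- generate_toy_structures(rec, dir, seed = 4)
  t1 <- distribute_jobs(rec, builtin_methods(), threads = 1)
  t2 <- distribute_jobs(rec, builtin_methods(), threads = 4)
  expect_identical(t1$records, t2$records)
  expect_equal(nrow(t1$records), choose(8, 2) * 2)

  # built-in scorers are symmetric and full-coverage here
  cov <- method_coverage(mirror_symmetric(t1))
  expect_equal(cov$coverage, c(1, 1))

  # a failing method degrades its own coverage only
  rec_bad <- rec
  rec_bad$structure_path[1] <- file.path(dir, "missing.pdb")
  t3 <- mirror_symmetric(distribute_jobs(rec_bad, builtin_methods(), threads = 1))
  cov3 <- method_coverage(t3)
  expect_true(all(cov3$coverage < 1))
  expect_true(all(cov3$pairs_scored == 7 * 6))   # pairs not touching domain 1
})
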