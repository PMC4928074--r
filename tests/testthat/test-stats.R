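test_that("group summaries report mean, SD and SEM", {
  s <- summarize_group(c(1, 2, 3), "a")
  expect_equal(s$n, 3)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_error(summarize_group(5), "n >= 2")
})

test_that("Welch t handles degenerate variance cases and is antisymmetric", {
  same <- welch_t(c(3, 3, 3), c(3, 3, 3, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_values, 1)
  expect_error(welch_t(c(3, 3, 3), c(4, 4, 4)), "zero variance")

  set.seed(5)
  a <- rnorm(10, 1); b <- rnorm(13, 1.5)
  ab <- welch_t(a, b)
  ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_values, ba$p_values)
  expect_equal(ab$df, ba$df)
})

test_that("Welch p-value agrees with a permutation test within Monte-Carlo error", {
  set.seed(17)
  a <- rnorm(12, 100, 8)
  b <- rnorm(12, 106, 8)
  obs <- abs(welch_t(a, b)$statistic)
  pooled <- c(a, b)
  B <- 4000
  perm <- replicate(B, {
    ix <- sample(24, 12)
    abs(welch_t(pooled[ix], pooled[-ix])$statistic)
  })
  p_perm <- (1 + sum(perm >= obs)) / (B + 1)
  p_welch <- welch_t(a, b)$p_values
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_perm - p_welch), 4 * mc_se + 0.01)
})

test_that("summary-statistics Welch t reproduces the raw-data test exactly", {
  set.seed(23)
  a <- rnorm(8, 300, 20); b <- rnorm(11, 330, 35)
  raw <- welch_t(a, b)
  smry <- welch_t_from_summary(length(a), mean(a), length(b), mean(b),
                               sd1 = sd(a), sd2 = sd(b))
  expect_equal(smry$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(smry$df, raw$df, tolerance = 1e-12)
  expect_equal(smry$p_values, raw$p_values, tolerance = 1e-12)

  via_sem <- welch_t_from_summary(length(a), mean(a), length(b), mean(b),
                                  sem1 = sd(a) / sqrt(length(a)),
                                  sem2 = sd(b) / sqrt(length(b)))
  expect_equal(via_sem$p_values, raw$p_values, tolerance = 1e-12)
})

test_that("ANOVA handles identical groups and matches pooled t at k = 2", {
  ident <- anova_tukey(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_omnibus, 1)

  set.seed(29)
  a <- rnorm(9, 10, 2); b <- rnorm(7, 12, 2)
  res <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p_values["a", "b"], tt$p.value, tolerance = 1e-9)
  expect_equal(res$p_omnibus, tt$p.value, tolerance = 1e-9)
  expect_error(anova_tukey(list(a = a)), "at least 2 groups")
  expect_error(anova_tukey(list(a = a, b = 1)), "n >= 2")
})

test_that("Tukey-adjusted p-values are never smaller than unadjusted t-tests", {
  set.seed(37)
  g <- list(a = rnorm(8, 0), b = rnorm(8, 0.8), c = rnorm(8, 1.6))
  res <- anova_tukey(g)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    unadj <- t.test(g[[pair[1]]], g[[pair[2]]], var.equal = TRUE)$p.value
    expect_gte(res$p_values[pair[1], pair[2]] + 1e-12, unadj)
  }
  expect_equal(res$p_values, t(res$p_values))   # symmetric
  expect_equal(unname(diag(res$p_values)), rep(1, 3))
})

test_that("summary-statistics ANOVA + Tukey matches the raw-data version", {
  set.seed(41)
  g <- list(x = rnorm(6, 200, 15), y = rnorm(9, 215, 15), z = rnorm(5, 230, 15))
  raw <- anova_tukey(g)
  smry <- anova_tukey_from_summary(
    n = vapply(g, length, 0L), means = vapply(g, mean, 0),
    sds = vapply(g, sd, 0), labels = names(g))
  expect_equal(smry$statistic, raw$statistic, tolerance = 1e-9)
  expect_equal(smry$p_omnibus, raw$p_omnibus, tolerance = 1e-9)
  expect_equal(smry$p_values, raw$p_values, tolerance = 1e-6)
})

test_that("restitution comparison controls false positives on null data", {
  set.seed(43)
  clean <- replicate(100, {
    samples <- lapply(c(A = 1, B = 2, C = 3), function(i)
      list("600" = rnorm(6, 250, 12)))
    flags <- compare_restitution(samples)
    !any(flags$significant)
  })
  expect_gte(mean(clean), 0.88)   # familywise level ~5% per cycle length
})

test_that("restitution comparison detects a 40 ms separation", {
  set.seed(47)
  hits <- replicate(50, {
    samples <- list(
      ctrl = list("600" = rnorm(6, 250, 10), "400" = rnorm(6, 200, 10)),
      drug = list("600" = rnorm(6, 290, 10), "400" = rnorm(6, 240, 10)))
    flags <- compare_restitution(samples)
    all(flags$significant)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("restitution comparison restricts to shared cycle lengths", {
  set.seed(53)
  samples <- list(
    a = list("600" = rnorm(5, 250, 5), "400" = rnorm(5, 200, 5)),
    b = list("600" = rnorm(5, 252, 5)))
  expect_warning(flags <- compare_restitution(samples), "shared")
  expect_equal(unique(flags$pcl_ms), 600)

  expect_equal(nrow(compare_restitution(samples[1])), 0)
  expect_error(compare_restitution(list(a = list("600" = 1:5),
                                        b = list("400" = 1:5))),
               "share no")
})

test_that("report writing is complete, collision-safe and deterministic", {
  set.seed(59)
  a <- rnorm(6, 250, 10); b <- rnorm(6, 290, 10)
  sums <- list(summarize_group(a, "ctrl"), summarize_group(b, "drug"))
  comps <- list(apd = welch_t(a, b),
                omnibus = anova_tukey(list(ctrl = a, drug = b)))
  flags <- compare_restitution(list(ctrl = list("600" = a),
                                    drug = list("600" = b)))
  dir1 <- withr::local_tempdir()
  paths <- write_report(sums, comps, flags, dir1,
                        config = list(alpha = 0.05, level = 0.8))
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("group_summaries.csv", "pairwise_p.csv",
                    "per_pcl_flags.csv", "run_log.txt"))

  gs <- read.csv(file.path(dir1, "group_summaries.csv"))
  expect_equal(gs$label, c("ctrl", "drug"))
  expect_equal(gs$mean, c(mean(a), mean(b)))
  pw <- read.csv(file.path(dir1, "pairwise_p.csv"))
  expect_true(all(c("apd", "omnibus") %in% pw$comparison))

  dir2 <- withr::local_tempdir()
  write_report(sums, comps, flags, dir2,
               config = list(alpha = 0.05, level = 0.8))
  for (f in c("group_summaries.csv", "pairwise_p.csv", "per_pcl_flags.csv",
              "run_log.txt"))
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))

  expect_error(write_report(list(sums[[1]], sums[[1]]), out_dir = dir1),
               "collide")
})
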