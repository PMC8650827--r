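test_that("cell summaries match hand-computed confidence intervals", {
  res <- fake_results(c(0.8, 0.9), rep("baseline", 2), rep("n1", 2), 1:2)
  s <- summarize_results(res)
  expect_equal(s$mean_accuracy, 0.85)
  half <- qnorm(0.975) * sd(c(0.8, 0.9)) / sqrt(2)
  expect_equal(s$ci_high - s$mean_accuracy, half, tolerance = 1e-12)
  expect_equal(half, 0.098, tolerance = 1e-3)
  ## degenerate cell: zero-width interval
  s0 <- summarize_results(fake_results(c(0.7, 0.7), rep("x", 2), rep("n", 2)))
  expect_equal(s0$ci_low, s0$ci_high)
  ## near-ceiling mean: upper limit clipped at 1
  s1 <- summarize_results(fake_results(c(0.9, 1.0), rep("x", 2), rep("n", 2)))
  expect_equal(s1$ci_high, 1)
  expect_error(summarize_results(fake_results(0.5, "x", "n")), "fewer than 2")
})

test_that("summaries are invariant to record order", {
  withr::with_seed(5, {
    res <- fake_results(runif(24), rep(c("a", "b"), each = 12),
                        rep(rep(c("n1", "n2"), each = 6), 2))
  })
  s1 <- summarize_results(res)
  s2 <- summarize_results(res[sample(nrow(res)), ])
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("the two-way ANOVA matches the brute-force decomposition", {
  withr::with_seed(7, {
    a <- rep(c("r1", "r2"), each = 15)
    b <- rep(rep(c("n1", "n2", "n3"), each = 5), 2)
    v <- rnorm(30, mean = 0.7 + 0.05 * (a == "r2") + 0.02 * (b == "n2"), sd = 0.05)
  })
  tab <- anova_two_way(fake_results(v, a, b), "accuracy")
  bf <- brute_force_ss(v, a, b)
  expect_equal(tab$sum_sq[tab$term == "Representation"], bf$a, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "Deficit"], bf$b, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "Interaction"], bf$int, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "Residual"], bf$res, tolerance = 1e-8)
  expect_equal(sum(tab$sum_sq), bf$total, tolerance = 1e-8)
  expect_equal(sum(tab$df), length(v) - 1)
  ## F ratios against residual mean square
  ms_res <- bf$res / tab$df[tab$term == "Residual"]
  expect_equal(tab$F[tab$term == "Representation"],
               (bf$a / 1) / ms_res, tolerance = 1e-8)
})

test_that("the single-factor reduction reproduces the squared pooled t", {
  withr::with_seed(9, {
    v <- c(rnorm(10, 0.8, 0.04), rnorm(10, 0.86, 0.04))
    a <- rep(c("r1", "r2"), each = 10)
  })
  tab <- anova_two_way(fake_results(v, a, rep("n1", 20)), "accuracy")
  tt <- t.test(v[a == "r1"], v[a == "r2"], var.equal = TRUE)
  expect_equal(tab$F[tab$term == "Representation"],
               unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(tab$p[tab$term == "Representation"],
               tt$p.value, tolerance = 1e-8)
})

test_that("a purely additive zero-noise design has no interaction or residual", {
  a <- rep(c("r1", "r2"), each = 6)
  b <- rep(rep(c("n1", "n2"), each = 3), 2)
  v <- 0.7 + 0.1 * (a == "r2") + 0.05 * (b == "n2")
  tab <- anova_two_way(fake_results(v, a, b), "accuracy")
  expect_equal(tab$sum_sq[tab$term == "Interaction"], 0, tolerance = 1e-12)
  expect_equal(tab$sum_sq[tab$term == "Residual"], 0, tolerance = 1e-12)
  ## F against a zero residual mean square is not finite
  Fr <- tab$F[tab$term == "Representation"]
  expect_true(is.na(Fr) || !is.finite(Fr) || Fr > 1e10)
})

test_that("unbalanced or incomplete designs are rejected", {
  res <- fake_results(runif(10), rep(c("a", "b"), each = 5),
                      c(rep("n1", 5), rep("n1", 3), "n2", "n2"))
  expect_error(anova_two_way(res, "accuracy"), "incomplete|unbalanced")
  res2 <- fake_results(runif(6), c("a", "a", "a", "a", "b", "b"),
                       rep("n1", 6))
  expect_error(anova_two_way(res2, "accuracy"), "unbalanced")
})

test_that("reports round-trip through CSV and honour the plot flag", {
  withr::with_seed(3, {
    res <- fake_results(runif(24, 0.6, 0.9), rep(c("a", "b"), each = 12),
                        rep(rep(c("n1", "n2"), each = 6), 2))
  })
  s <- summarize_results(res)
  an <- anova_two_way(res, "accuracy")
  out <- withr::local_tempdir()
  files <- export_report(s, an, out, manifest = list(master_seed = 99L))
  s2 <- read.csv(file.path(out, "summary.csv"), stringsAsFactors = FALSE)
  expect_equal(s2$mean_accuracy, s$mean_accuracy, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$master_seed, 99L)
  expect_false(file.exists(file.path(out, "accuracy_spider.png")))
  export_report(s, an, out, plot = TRUE)
  expect_true(file.exists(file.path(out, "accuracy_spider.png")))
})

test_that("representation p-values are roughly uniform under the null", {
  ## deficits independent of features: the Representation main effect
  ## should be null across replicate experiments
  pvals <- vapply(1:20, function(repl) {
    withr::with_seed(1000 + repl, {
      n <- 60
      feats <- list(
        baseline = structure(list(values = matrix(rnorm(n * 2), n, 2),
                                  kind = "baseline"), class = "feature_matrix"),
        `2d` = structure(list(values = matrix(rnorm(n * 4), n, 4),
                              kind = "2d"), class = "feature_matrix"))
      labs <- cbind(a = rep(c(TRUE, FALSE), n / 2),
                    b = rep(c(TRUE, TRUE, FALSE, FALSE), n / 4))
    })
    res <- run_experiment(feats, labs, n_outer = 3, seed = 1000 + repl)
    tab <- anova_two_way(res, "accuracy")
    tab$p[tab$term == "Representation"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.25)
})
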