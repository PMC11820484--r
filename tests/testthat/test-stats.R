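test_that("Shapiro-Wilk wrapper: degenerate input flagged, bounds enforced", {
  expect_true(shapiroWilk(rep(3.2, 10))$degenerate)
  expect_error(shapiroWilk(c(1, 2)), "at least 3")
  set.seed(1)
  out <- shapiroWilk(rnorm(50))
  expect_false(out$degenerate)
  expect_true(out$p >= 0 && out$p <= 1)
})

test_that("Shapiro-Wilk p-values are uniform under normality (KS check)", {
  set.seed(42)
  ps <- replicate(200, shapiroWilk(rnorm(50))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Shapiro-Wilk detects heavy tails in most seeded samples", {
  set.seed(43)
  rejected <- replicate(100, shapiroWilk(rcauchy(50))$p < 0.05)
  expect_gte(mean(rejected), 0.90)
})

test_that("one-way ANOVA with two groups reduces to the squared t statistic", {
  set.seed(11)
  g <- list(rnorm(8), rnorm(8, 1))
  an <- oneWayAnova(g)
  tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA input is flagged instead of reporting an F", {
  out <- oneWayAnova(list(rep(1, 4), rep(1, 5)))
  expect_true(out$degenerate)
  expect_true(is.na(out$F))
  expect_error(oneWayAnova(list(rnorm(5))), "at least 2 groups")
  expect_error(oneWayAnova(list(rnorm(5), 1)), "at least 2 observations")
})

test_that("Tukey HSD with two groups matches the pooled t-test p-value", {
  set.seed(12)
  g <- list(a = rnorm(7), b = rnorm(7, 0.8))
  tk <- tukeyHsd(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey HSD separates disjoint groups and stars match thresholds", {
  g <- list(a = c(0, 0.01, 0.02, 0.01), b = c(10, 10.01, 10.02, 9.99),
            c = c(0.005, 0.015, 0.012, 0.02))
  tk <- tukeyHsd(g)
  ab <- tk[tk$group_a == "b" & tk$group_b == "a", ]
  expect_lt(ab$p_adj, 1e-6)
  expect_equal(ab$stars, "***")
  ac <- tk[(tk$group_a == "c" & tk$group_b == "a") |
           (tk$group_a == "a" & tk$group_b == "c"), ]
  expect_false(ac$significant)
  expect_equal(ac$stars, "")
})

test_that("Tukey-adjusted p is never below the unadjusted p on the same contrast", {
  set.seed(13)
  for (rep in 1:20) {
    g <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1))
    tk <- tukeyHsd(g)
    # unadjusted pairwise p from the same ANOVA decomposition (pooled MSE)
    n <- lengths(g)
    mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) /
      (sum(n) - length(g))
    dfw <- sum(n) - length(g)
    for (i in seq_len(nrow(tk))) {
      se <- sqrt(mse * (1 / n[[tk$group_a[i]]] + 1 / n[[tk$group_b[i]]]))
      pUnadj <- 2 * pt(-abs(tk$diff[i]) / se, dfw)
      expect_gte(tk$p_adj[i] + 1e-10, pUnadj)
    }
  }
})

test_that("report builder produces the direction matrix against the control", {
  des <- studyDesign(data.frame(
    sample_id = c(paste0("c", 1:4), paste0("o", 1:4), paste0("t", 1:4)),
    group = rep(c("control", "oa_steatosis", "topiramate"), each = 4)))
  set.seed(21)
  val <- c(rnorm(4, 1, 0.01), rnorm(4, 5, 0.01), rnorm(4, 1, 0.01))
  outcomes <- data.frame(sample_id = samples(des)$sample_id,
                         outcome = "fns_palmitate", value = val)
  rep1 <- buildReport(outcomes, des)
  expect_equal(unname(rep1$direction["fns_palmitate", ]),
               c("reference", "increased", "no change"))
  cmp <- rep1$comparisons$fns_palmitate
  expect_equal(cmp$summary$n, rep(4L, 3))
  expect_lt(cmp$anova$p, 1e-6)
  # all-equal data: everything "no change"
  outcomes$value <- 1
  rep2 <- buildReport(outcomes, des)
  expect_true(all(rep2$direction[, -1] == "no change"))
})
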