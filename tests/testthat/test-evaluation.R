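test_that("chunk-size weighting follows the summed-size definition", {
  expect_equal(weighted_accuracy(c(TRUE, FALSE, TRUE), c(2000, 2600, 2000)),
               4000 / 6600)
  expect_equal(weighted_accuracy(rep(TRUE, 5), rep(800, 5)), 1.0)
  # equal sizes reduce to plain accuracy
  expect_equal(weighted_accuracy(c(TRUE, TRUE, TRUE, FALSE), rep(800, 4)),
               0.75)
  set.seed(41)
  for (i in 1:10) {
    correct <- runif(20) > 0.5
    expect_equal(weighted_accuracy(correct, rep(123, 20)), mean(correct))
  }
  expect_error(weighted_accuracy(logical(0), numeric(0)), "domain error")
})

test_that("functional-use share is the size-weighted functional fraction", {
  expect_equal(functional_use_percent(rep("functional", 4), rep(800, 4)), 100)
  labs <- c("functional", "nonfunctional", "excluded", "functional")
  expect_equal(functional_use_percent(labs, c(2000, 2000, 5000, 1000)),
               100 * 3000 / 5000)
  expect_error(functional_use_percent(rep("excluded", 3), rep(1, 3)),
               "all blocks excluded")
  # per-sample expansion oracle: block weighting equals the sample fraction
  set.seed(43)
  gt <- sample(c("functional", "nonfunctional"), 50, TRUE)
  sizes <- sample(800:2600, 50)
  expanded <- rep(gt, sizes)
  expect_equal(functional_use_percent(gt, sizes),
               100 * mean(expanded == "functional"))
})

test_that("functional-use error is the absolute difference in points", {
  expect_equal(fu_error(78.98, 61.23), 17.75)
  expect_equal(fu_error(64.79, 63.50), 1.29)
  expect_equal(fu_error(55, 55), 0)
  expect_error(fu_error(120, 50))
})

test_that("median and range summarize like the reporting convention", {
  expect_equal(unname(median_range(c(85.84, 83.73, 82.70, 82.17, 79.31))),
               c(82.70, 79.31, 85.84))
  expect_equal(unname(median_range(c(1, 2, 3, 4))), c(2.5, 1, 4))
  expect_error(median_range(numeric(0)), "domain error")
})

test_that("mann-whitney U handles separation, symmetry and tie fallbacks", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)           # maximal separation
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p, 1)          # identical groups (tied: normal branch)
  expect_equal(r2$method, "normal")
  expect_error(mann_whitney_u(numeric(0), 1), "empty group")
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), exact = TRUE), "ties")
})

test_that("exact mann-whitney p matches exhaustive relabelling enumeration", {
  set.seed(47)
  enumerate_p <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    idx <- utils::combn(length(pooled), na)
    u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    u_all <- apply(idx, 2, function(k) u_of(pooled[k], pooled[-k]))
    u_obs <- u_of(a, b)
    min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  }
  for (i in 1:8) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.8)
    r <- mann_whitney_u(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enumerate_p(a, b), tolerance = 1e-12)
  }
})

test_that("wilcoxon signed-rank handles extremes, symmetry and zero-dropping", {
  r <- wilcoxon_signed_rank(c(1.2, 0.5, 2.2, 0.9, 3.1))
  expect_equal(r$V, 15)          # all positive: full rank sum, none negative
  expect_equal(r$p, 2 / 2^5)     # most extreme two-sided exact p
  r2 <- wilcoxon_signed_rank(c(1.5, -1.5, 2.5, -2.5), exact = FALSE)
  expect_equal(r2$p, 1)          # antisymmetric differences
  r3 <- wilcoxon_signed_rank(c(0, 0, 1.3))
  expect_equal(r3$n, 1)          # zeros dropped before ranking
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate-input")
})

test_that("exact wilcoxon p matches sign-flip enumeration", {
  set.seed(53)
  enumerate_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  }
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- rnorm(n, 0.4)
    r <- wilcoxon_signed_rank(d)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enumerate_p(d), tolerance = 1e-12)
  }
})

test_that("cohort reports aggregate metrics with group summaries and tests", {
  per <- data.frame(subject = 1:6,
                    group = rep(c("control", "amputee"), each = 3),
                    acc = c(0.9, 0.95, 0.92, 0.7, 0.75, 0.72))
  rep1 <- build_report(per)
  expect_equal(unname(rep1$summary$control$acc["median"]), 0.92)
  expect_equal(unname(rep1$summary$amputee$acc["max"]), 0.75)
  expect_false(is.null(rep1$group_tests$acc))
  expect_lt(rep1$group_tests$acc$p, 0.2)
  # single subject: degenerate range
  rep2 <- build_report(data.frame(acc = 0.8))
  expect_equal(unname(rep2$summary$all$acc["min"]),
               unname(rep2$summary$all$acc["max"]))
  expect_error(build_report(data.frame()), "non-empty")
  md <- render_report_md(rep1)
  expect_true(any(grepl("median", md)))
})
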