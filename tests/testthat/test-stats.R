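# Randomized-blocks ANOVA and the Tukey-Kramer post-hoc machinery.

test_that("one-way blocked ANOVA matches the direct SS decomposition", {
  y <- matrix(c(0.70, 0.72, 0.68, 0.74,
                0.75, 0.78, 0.72, 0.80,
                0.71, 0.74, 0.69, 0.76), nrow = 3, byrow = TRUE)
  oracle <- rcbd_oracle(y)
  an <- rb_anova_oneway(blocked_table(y), "condition")
  expect_equal(an$effects$condition$F, 117, tolerance = 1e-10)
  expect_equal(an$effects$condition$F, oracle$F, tolerance = 1e-10)
  expect_equal(an$effects$condition$p, oracle$p, tolerance = 1e-10)
  expect_equal(an$ms_residual, oracle$ms_residual, tolerance = 1e-10)
  expect_equal(an$effects$condition$df1, oracle$df1)
  expect_equal(an$df_residual, oracle$df2)
})

test_that("degrees of freedom follow the blocked design algebra", {
  y <- matrix(stats::rnorm(18, 0.7, 0.02), nrow = 2)  # 2 levels x 9 blocks
  an <- rb_anova_oneway(blocked_table(y), "condition")
  expect_equal(an$effects$condition$df1, 1L)
  expect_equal(an$df_residual, 8L)
})

test_that("no treatment effect gives F = 0 and missing cells are reported", {
  y <- matrix(rep(c(0.6, 0.7, 0.8), each = 3), nrow = 3, byrow = TRUE)
  an <- suppressWarnings(rb_anova_oneway(blocked_table(t(y)), "condition"))
  expect_equal(an$effects$condition$F, 0, tolerance = 1e-20)
  tab <- blocked_table(matrix(stats::rnorm(6), 2))
  expect_error(rb_anova_oneway(tab[-1, ], "condition"), "cells|balanced")
  expect_error(rb_anova_oneway(tab[tab$condition == tab$condition[1], ],
                               "condition"), "2 levels")
})

test_that("SS decomposition is exact on random blocked tables", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      a <- sample(2:5, 1); b <- sample(2:9, 1)
      y <- matrix(stats::rnorm(a * b, 0.7, 0.1), a, b)
      an <- rb_anova_oneway(blocked_table(y), "condition")
      oracle <- rcbd_oracle(y)
      ssb <- a * sum((colMeans(y) - mean(y))^2)
      expect_equal(an$effects$condition$ss + ssb + an$ss_residual,
                   oracle$sst, tolerance = 1e-10)
      expect_equal(an$effects$condition$F, oracle$F, tolerance = 1e-8)
    }
  })
})

test_that("multi-way blocked ANOVA isolates the injected main effect", {
  # 4 window sizes x 3 slides x 9 blocks; window effect spans 0.05,
  # no slide effect; residual noise 0.01
  windows <- c(0.5, 1, 2, 3); slides <- c(0.125, 0.25, 0.5)
  n_rej_w <- 0; n_null_s <- 0; reps <- 10
  withr::with_seed(52, {
    for (r in seq_len(reps)) {
      d <- expand.grid(window_s = windows, slide_s = slides,
                       subject = paste0("S", 1:9))
      blk <- stats::rnorm(9, 0, 0.05)
      d$accuracy <- 0.7 + (match(d$window_s, windows) - 1) / 3 * 0.05 +
        blk[match(d$subject, paste0("S", 1:9))] +
        stats::rnorm(nrow(d), 0, 0.01)
      an <- rb_anova_multiway(d, c("window_s", "slide_s"))
      if (an$effects$window_s$p < 0.01) n_rej_w <- n_rej_w + 1
      if (an$effects$slide_s$p > 0.1) n_null_s <- n_null_s + 1
      expect_equal(an$effects$window_s$df1, length(windows) - 1L)
      expect_equal(an$effects$slide_s$df1, length(slides) - 1L)
    }
  })
  expect_equal(n_rej_w, reps)       # a 0.05 spread over 9 blocks is blatant
  expect_gte(n_null_s, reps * 0.6)  # null p-values are uniform
})

test_that("constant responses give all-zero F in the multi-way model", {
  d <- expand.grid(window_s = c(0.5, 1), slide_s = c(0.125, 0.25),
                   subject = paste0("S", 1:3))
  d$accuracy <- 0.75
  an <- suppressWarnings(rb_anova_multiway(d, c("window_s", "slide_s")))
  expect_equal(an$effects$window_s$F, 0)
  expect_equal(an$effects$slide_s$F, 0)
  d2 <- d[-1, ]
  expect_error(rb_anova_multiway(d2, c("window_s", "slide_s")),
               "balanced|cells")
})

test_that("Tukey-Kramer agrees with an independent studentized-range computation", {
  y <- matrix(c(0.70, 0.72, 0.68, 0.74, 0.73,
                0.76, 0.79, 0.73, 0.81, 0.78,
                0.71, 0.74, 0.69, 0.76, 0.74), nrow = 3, byrow = TRUE)
  an <- rb_anova_oneway(blocked_table(y), "condition")
  tk <- tukey_kramer(an)
  oracle <- rcbd_oracle(y)
  means <- rowMeans(y); b <- ncol(y); a <- nrow(y)
  for (r in seq_len(nrow(tk))) {
    lv <- strsplit(tk$comparison[r], " - ")[[1]]
    i <- match(lv[2], paste0("L", 1:a)); j <- match(lv[1], paste0("L", 1:a))
    se <- sqrt(oracle$ms_residual / b)
    q <- abs(means[j] - means[i]) / se
    p_ref <- stats::ptukey(q, a, oracle$df2, lower.tail = FALSE)
    expect_equal(tk$p_adj[r], p_ref, tolerance = 1e-6)
  }
  # identical level means (degenerate perfect fit): nothing rejected
  y0 <- matrix(rep(stats::rnorm(4, 0.7, 0.05), each = 3), nrow = 3)
  tk0 <- suppressWarnings(
    tukey_kramer(rb_anova_oneway(blocked_table(y0), "condition")))
  expect_false(any(tk0$reject))
})

test_that("with two levels Tukey-Kramer and the blocked F-test agree", {
  withr::with_seed(53, {
    for (rep in 1:10) {
      y <- matrix(stats::rnorm(18, 0.7, 0.04), nrow = 2)
      y[2, ] <- y[2, ] + stats::runif(1, 0, 0.06)
      an <- rb_anova_oneway(blocked_table(y), "condition")
      tk <- tukey_kramer(an)
      expect_equal(tk$reject[1], an$effects$condition$p < 0.05)
      # exact identity in theory; ptukey vs pf agree to ~1e-6 numerically
      expect_equal(tk$p_adj[1], an$effects$condition$p, tolerance = 1e-5)
    }
  })
})

test_that("level-vs-overall flags only levels above the grand mean", {
  withr::with_seed(54, {
    base <- stats::rnorm(9, 0.72, 0.03)
    noise <- stats::rnorm(9, 0, 0.005)
  })
  y <- rbind(with_feat = base + 0.05 + noise, without = base)
  an <- rb_anova_oneway(blocked_table(y), "condition")
  ph <- level_vs_overall(an)
  expect_true(ph$reject[ph$level == "with_feat"])
  expect_false(ph$reject[ph$level == "without"])
  expect_equal(ph$p_adj[ph$level == "without"], 1)
  expect_lt(ph$p_adj[ph$level == "with_feat"], 0.001)
  # symmetric two-level case: at most one level can exceed the grand mean
  expect_lte(sum(ph$reject), 1L)
  # identical levels (degenerate perfect fit): no rejections
  y0 <- rbind(a = base, b = base)
  ph0 <- suppressWarnings(
    level_vs_overall(rb_anova_oneway(blocked_table(y0), "condition")))
  expect_false(any(ph0$reject))
})

test_that("stats reports are written as CSV plus text", {
  y <- matrix(stats::rnorm(12, 0.7, 0.03), nrow = 2)
  y[1, ] <- y[1, ] + 0.05
  an <- rb_anova_oneway(blocked_table(y), "condition")
  dir <- withr::local_tempdir()
  write_stats_report(an, level_vs_overall(an), dir, prefix = "cmp")
  expect_true(file.exists(file.path(dir, "cmp.csv")))
  expect_true(file.exists(file.path(dir, "cmp_posthoc.csv")))
  expect_true(any(grepl("Randomized-blocks",
                        readLines(file.path(dir, "cmp.txt")))))
})
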