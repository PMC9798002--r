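# Shared-covariance Gaussian discriminant: fitting, scoring, invariances.

sim_gauss <- function(n, mu, seed) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n * 2, mu[1]), n),
               matrix(stats::rnorm(n * 2, mu[2]), n))
    list(x = x, y = rep(c("a", "b"), each = n))
  })
}

test_that("fit recovers empirical priors, means, and errors on bad input", {
  d <- sim_gauss(20, c(-1, 1), seed = 1)
  fit <- mi_lda(d$x, d$y, lambda = 1e-3)
  expect_equal(fit$priors, c(0.5, 0.5))
  expect_equal(fit$means["a", ], colMeans(d$x[d$y == "a", ]),
               ignore_attr = TRUE)
  expect_error(mi_lda(d$x, rep("a", 40)), "2 classes")
  expect_error(mi_lda(d$x[1:3, ], c("a", "a", "b")), ">= 2 trials")
  # identical vectors within class: pooled covariance 0, still invertible
  xx <- rbind(matrix(1, 3, 2), matrix(2, 3, 2))
  fit0 <- mi_lda(xx, rep(c("a", "b"), each = 3), lambda = 0.1)
  expect_error(mi_lda(xx, rep(c("a", "b"), each = 3), lambda = 0),
               "singular|shrinkage")
  expect_equal(predict(fit0, matrix(1, 1, 2)), "a")
})

test_that("class means are recovered within sampling error at n = 1e4", {
  d <- sim_gauss(10000, c(-1, 1), seed = 2)
  fit <- mi_lda(d$x, d$y, lambda = 0)
  se <- 1 / sqrt(10000)
  expect_true(all(abs(fit$means["a", ] - (-1)) < 3 * se))
  expect_true(all(abs(fit$means["b", ] - 1) < 3 * se))
})

test_that("discriminant matches the closed-form Gaussian score", {
  # hand fixture: 2-D, unequal priors
  mu <- rbind(a = c(0, 0), b = c(1, 2))
  sigma <- matrix(c(2, 0.3, 0.3, 1), 2)
  fit <- structure(list(means = mu, cov = sigma, chol = chol(sigma),
                        logdet = 2 * sum(log(diag(chol(sigma)))),
                        priors = c(0.3, 0.7), classes = c("a", "b"),
                        lambda = 0, p = 2), class = "mi_lda")
  x <- c(0.5, -1.2)
  direct <- vapply(1:2, function(k) {
    dd <- x - mu[k, ]
    -0.5 * log(det(sigma)) -
      0.5 * drop(dd %*% solve(sigma) %*% dd) + log(fit$priors[k])
  }, 0)
  expect_equal(drop(discriminant(fit, x)), direct, tolerance = 1e-10,
               ignore_attr = TRUE)
  # equidistant point under equal priors scores equally
  fit$priors <- c(0.5, 0.5)
  mid <- colMeans(mu)
  sc <- drop(discriminant(fit, mid))
  expect_equal(unname(sc[1]), unname(sc[2]), tolerance = 1e-10)
})

test_that("1-D two-class boundary sits at the midpoint and ties go first", {
  x <- matrix(c(rep(-1, 10), rep(1, 10)) + rep(c(-0.01, 0.01), 10), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  fit <- mi_lda(x, y, lambda = 0)
  expect_equal(predict(fit, matrix(-0.5)), "a")
  expect_equal(predict(fit, matrix(0.5)), "b")
  # exact boundary: first (lexicographic) label
  mid <- matrix(mean(fit$means))
  sc <- drop(discriminant(fit, mid))
  expect_equal(unname(sc[1]), unname(sc[2]), tolerance = 1e-9)
  expect_equal(predict(fit, mid), "a")
})

test_that("well-separated simulation is classified above 0.95", {
  d <- sim_gauss(250, c(-2, 2), seed = 3)
  fit <- mi_lda(d$x, d$y, lambda = 1e-3)
  test <- sim_gauss(250, c(-2, 2), seed = 4)
  expect_gt(mean(predict(fit, test$x) == test$y), 0.95)
})

test_that("score differences are affine in x under a shared covariance", {
  d <- sim_gauss(40, c(-1, 1), seed = 5)
  fit <- mi_lda(d$x, d$y, lambda = 1e-2)
  withr::with_seed(6, {
    for (i in 1:10) {
      x1 <- stats::rnorm(2); x2 <- stats::rnorm(2); a <- stats::runif(1)
      dd <- function(x) { s <- drop(discriminant(fit, x)); s[1] - s[2] }
      expect_equal(dd(a * x1 + (1 - a) * x2),
                   a * dd(x1) + (1 - a) * dd(x2), tolerance = 1e-8)
    }
  })
})

test_that("predictions are invariant to invertible affine transforms (lambda = 0)", {
  d <- sim_gauss(50, c(-1, 1), seed = 7)
  A <- matrix(c(2, 0.5, -1, 1.5), 2); b <- c(3, -2)
  xt <- d$x %*% t(A) + rep(b, each = nrow(d$x))
  test <- sim_gauss(30, c(-1, 1), seed = 8)
  tt <- test$x %*% t(A) + rep(b, each = nrow(test$x))
  p1 <- predict(mi_lda(d$x, d$y, lambda = 0), test$x)
  p2 <- predict(mi_lda(xt, d$y, lambda = 0), tt)
  expect_equal(p1, p2)
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  d <- sim_gauss(60, c(-0.8, 0.8), seed = 9)
  test <- sim_gauss(40, c(-0.8, 0.8), seed = 10)
  ours <- predict(mi_lda(d$x, d$y, lambda = 0), test$x)
  ref <- as.character(predict(MASS::lda(d$x, grouping = d$y),
                              test$x)$class)
  expect_equal(ours, ref)
})

test_that("only interaction features separate a coupling-only cohort", {
  p <- paradigm_config(n_runs = 2L, trials_per_class_per_run = 50L) # 200
  train <- generate_session(p, coupling_only_model(), seed = 41)
  test <- generate_session(p, coupling_only_model(), seed = 42,
                           session_id = 2L)
  labs_tr <- vapply(train, `[[`, "", "label")
  labs_te <- vapply(test, `[[`, "", "label")
  acc <- vapply(c("none", "correlation", "jaccard"), function(mode) {
    f <- function(trials) t(vapply(trials, function(tr)
      flatten_features(extract_features(tr, interaction_mode = mode)),
      numeric(if (mode == "none") 6 else 9)))
    fit <- mi_lda(f(train), labs_tr, lambda = 1e-3)
    mean(predict(fit, f(test)) == labs_te)
  }, 0)
  half_width <- 1.96 * sqrt(0.25 / 200)
  expect_lt(abs(acc["none"] - 0.5), half_width)
  expect_gt(acc["correlation"], 0.5 + half_width)
  expect_gt(acc["jaccard"], 0.5 + half_width)
})

test_that("fitted parameters serialize to text and back", {
  d <- sim_gauss(25, c(-1, 1), seed = 11)
  fit <- mi_lda(d$x, d$y, lambda = 1e-2)
  path <- withr::local_tempfile(fileext = ".json")
  write_mi_lda(fit, path)
  back <- read_mi_lda(path)
  expect_equal(back$means, fit$means, tolerance = 1e-12)
  expect_equal(back$cov, fit$cov, tolerance = 1e-12, ignore_attr = TRUE)
  x <- matrix(stats::rnorm(10), 5)
  expect_equal(predict(back, x), predict(fit, x))
})
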