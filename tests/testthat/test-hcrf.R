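# Hidden CRF: forward recursion vs exhaustive enumeration, gradient vs
# finite differences, training behaviour, and the static-vs-dynamic
# temporal-order property.

test_that("forward recursion equals brute-force path enumeration", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      m <- sample(1:3, 1); Tt <- sample(1:4, 1); d <- sample(1:3, 1)
      theta <- stats::rnorm(mieeg:::hcrf_n_par(2, m, d), 0, 1.5)
      stub <- hcrf_stub(theta, m, d)
      X <- matrix(stats::rnorm(Tt * d), Tt, d)
      for (k in 1:2) {
        expect_equal(label_log_score(stub, X, c("a", "b")[k]),
                     brute_label_score(stub$par[[k]], X),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("zero weights give the path-counting scores", {
  d <- 2
  stub <- hcrf_stub(rep(0, mieeg:::hcrf_n_par(2, 3, d)), 3, d)
  X <- matrix(stats::rnorm(5 * d), 5, d)
  expect_equal(label_log_score(stub, X, "a"), 5 * log(3), tolerance = 1e-12)
  # T = 1: no transitions, log of summed state scores
  X1 <- matrix(stats::rnorm(d), 1, d)
  theta <- stats::rnorm(mieeg:::hcrf_n_par(2, 2, d))
  stub2 <- hcrf_stub(theta, 2, d)
  par <- stub2$par[[1]]
  expect_equal(label_log_score(stub2, X1, "a"),
               mieeg:::logsumexp(drop(par$W %*% X1[1, ]) + par$b),
               tolerance = 1e-12)
})

test_that("posteriors normalize and count paths for unequal state sets", {
  d <- 3
  stub <- hcrf_stub(rep(0, mieeg:::hcrf_n_par(2, c(1, 2), d)), c(1, 2), d)
  pr <- predict(stub, matrix(stats::rnorm(2 * d), 2, d), type = "prob")
  # 1^2 = 1 path vs 2^2 = 4 paths
  expect_equal(drop(pr), c(a = 0.2, b = 0.8), tolerance = 1e-12)
  theta <- stats::rnorm(mieeg:::hcrf_n_par(2, 2, d))
  pr2 <- predict(hcrf_stub(theta, 2, d),
                 matrix(stats::rnorm(3 * d), 3, d), type = "prob")
  expect_equal(sum(pr2), 1, tolerance = 1e-12)
  # equal-m zero weights: uniform posterior, tie goes to the first label
  stub0 <- hcrf_stub(rep(0, mieeg:::hcrf_n_par(2, 2, d)), 2, d)
  X <- matrix(stats::rnorm(2 * d), 2, d)
  expect_equal(drop(predict(stub0, X, type = "prob")), c(a = 0.5, b = 0.5),
               tolerance = 1e-12)
  expect_equal(predict(stub0, X), "a")
})

test_that("analytic gradient matches central finite differences", {
  withr::with_seed(32, {
    for (rep in 1:20) {
      m <- sample(1:3, 1); Tt <- sample(2:4, 1); d <- 2
      seqs <- lapply(1:6, function(i) matrix(stats::rnorm(Tt * d), Tt, d))
      y <- c("a", "b", sample(c("a", "b"), 4, TRUE))
      theta <- stats::rnorm(mieeg:::hcrf_n_par(2, m, d), 0, 0.5)
      ob <- hcrf_objective(theta, seqs, y, c("a", "b"), m, reg = 0.7)
      fd <- vapply(seq_along(theta), function(j) {
        e <- replace(numeric(length(theta)), j, 1e-5)
        (hcrf_objective(theta + e, seqs, y, c("a", "b"), m, 0.7)$value -
           hcrf_objective(theta - e, seqs, y, c("a", "b"), m, 0.7)$value) /
          2e-5
      }, 0)
      expect_lt(max(abs(fd - ob$gradient)), 1e-5)
    }
  })
})

test_that("zero weights on a balanced set give n log 2, and heavy ridge shrinks theta", {
  seqs <- lapply(1:8, function(i) matrix(stats::rnorm(6), 3, 2))
  y <- rep(c("a", "b"), 4)
  theta0 <- rep(0, mieeg:::hcrf_n_par(2, 2, 2))
  expect_equal(hcrf_objective(theta0, seqs, y, c("a", "b"), 2, 0)$value,
               8 * log(2), tolerance = 1e-12)
  fit <- mi_hcrf(seqs, y, m = 2, reg = 1e6, seed = 2, restarts = 1)
  expect_lt(sqrt(sum(fit$theta^2)), 1e-3)
})

test_that("log-space scoring survives weight scales up to 1e3", {
  d <- 2
  theta <- withr::with_seed(33,
    stats::rnorm(mieeg:::hcrf_n_par(2, 2, d), 0, 1000))
  stub <- hcrf_stub(theta, 2, d)
  X <- matrix(stats::rnorm(4 * d), 4, d)
  s <- vapply(c("a", "b"), function(y) label_log_score(stub, X, y), 0)
  expect_true(all(is.finite(s)))
  pr <- predict(stub, X, type = "prob")
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("training separates a separable fixture and is seed-deterministic", {
  mkseq <- function(dir, seed)
    withr::with_seed(seed, {
      t <- 1:5
      cbind(dir * t / 2 + stats::rnorm(5, 0, 0.3), stats::rnorm(5, 0, 0.3))
    })
  seqs <- c(lapply(1:15, function(i) mkseq(1, i)),
            lapply(1:15, function(i) mkseq(-1, 100 + i)))
  y <- rep(c("up", "down"), each = 15)
  fit <- mi_hcrf(seqs, y, m = 2, reg = 0.1, seed = 5, restarts = 2)
  expect_equal(mean(predict(fit, seqs) == y), 1.0)
  fit2 <- mi_hcrf(seqs, y, m = 2, reg = 0.1, seed = 5, restarts = 2)
  expect_identical(fit$theta, fit2$theta)
  fit3 <- mi_hcrf(seqs, y, m = 2, reg = 0.1, seed = 6, restarts = 2)
  expect_false(identical(fit$theta, fit3$theta))
})

test_that("label-shuffled training yields chance-level test accuracy", {
  withr::with_seed(34, {
    seqs <- lapply(1:260, function(i) matrix(stats::rnorm(8), 4, 2))
    y <- sample(rep(c("a", "b"), 130))
  })
  fit <- mi_hcrf(seqs[1:60], y[1:60], m = 2, reg = 1, seed = 7,
                 restarts = 1)
  n_test <- 200
  acc <- mean(predict(fit, seqs[61:260]) == y[61:260])
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / n_test))
})

test_that("temporal order helps the HCRF where shuffled-window LDA is blind", {
  # class differs only in window *order*: rising vs falling ramp with a
  # label-independent marginal distribution of window values
  mkseq <- function(dir, seed) withr::with_seed(seed, {
    ramp <- seq(-1, 1, length.out = 4) * dir
    cbind(ramp + stats::rnorm(4, 0, 0.4), stats::rnorm(4, 0, 0.4))
  })
  n <- 60
  seqs <- c(lapply(seq_len(n), function(i) mkseq(1, i)),
            lapply(seq_len(n), function(i) mkseq(-1, 1000 + i)))
  y <- rep(c("up", "down"), each = n)
  tr <- c(1:40, n + (1:40)); te <- setdiff(seq_len(2 * n), tr)
  hfit <- mi_hcrf(seqs[tr], y[tr], m = 2, reg = 0.1, seed = 8, restarts = 2)
  hacc <- mean(predict(hfit, seqs[te]) == y[te])
  # LDA sees the same windows but in per-trial shuffled order
  shuffled <- withr::with_seed(35,
    lapply(seqs, function(s) s[sample(nrow(s)), , drop = FALSE]))
  flat <- t(vapply(shuffled, function(s) as.vector(t(s)), numeric(8)))
  lfit <- mi_lda(flat[tr, ], y[tr], lambda = 1e-2)
  lacc <- mean(predict(lfit, flat[te, ]) == y[te])
  se <- sqrt(hacc * (1 - hacc) / length(te) + lacc * (1 - lacc) / length(te))
  expect_gt(hacc - lacc, 1.96 * se)
})

test_that("trained weights serialize to text and back", {
  seqs <- lapply(1:12, function(i) matrix(stats::rnorm(6), 3, 2))
  y <- rep(c("a", "b"), 6)
  fit <- mi_hcrf(seqs, y, m = 2, reg = 1, seed = 9, restarts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_mi_hcrf(fit, path)
  back <- read_mi_hcrf(path)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_equal(predict(back, seqs, type = "prob"),
               predict(fit, seqs, type = "prob"), tolerance = 1e-12)
})

test_that("mismatched feature dimension is rejected", {
  seqs <- lapply(1:6, function(i) matrix(stats::rnorm(6), 3, 2))
  fit <- mi_hcrf(seqs, rep(c("a", "b"), 3), m = 2, reg = 1, seed = 1,
                 restarts = 1)
  expect_error(label_log_score(fit, matrix(0, 3, 5), "a"), "features")
  expect_error(mi_hcrf(c(seqs, list(matrix(0, 3, 4))),
                       rep(c("a", "b"), length.out = 7)), "dimension")
})
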