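# Linear-chain hidden conditional random field with disjoint hidden-state
# sets per label.  Every label y owns m private hidden states; a trial's
# unnormalized score for y sums exp(path score) over all m^T hidden paths
# within y's set, where the per-step score is a linear function of the
# window's features (state-observation weights), a state bias, and a
# within-label transition weight.  Transitions across label sets are
# structurally excluded (equivalent to weight -Inf).  All probabilities are
# handled in log space; the partition function is never formed in linear
# space.

# m may differ per label: each label k owns m_k hidden states and a
# parameter block of m_k*d + m_k + m_k^2 weights.
hcrf_m_vec <- function(m, n_classes) {
  m <- as.integer(m)
  if (length(m) == 1L) m <- rep(m, n_classes)
  stopifnot(length(m) == n_classes, all(m >= 1L))
  m
}

hcrf_n_par <- function(n_classes, m, d) {
  m <- hcrf_m_vec(m, n_classes)
  sum(m * d + m + m * m)
}

hcrf_unpack <- function(theta, n_classes, m, d) {
  m <- hcrf_m_vec(m, n_classes)
  per <- m * d + m + m * m
  off <- c(0, cumsum(per))
  lapply(seq_len(n_classes), function(k) {
    mk <- m[k]
    th <- theta[(off[k] + 1):(off[k + 1])]
    list(W = matrix(th[1:(mk * d)], mk, d),
         b = th[(mk * d + 1):(mk * d + mk)],
         A = matrix(th[(mk * d + mk + 1):length(th)], mk, mk))
  })
}

# log(exp(la) %*% exp(A)) with max-subtraction on both factors
log_mat_step <- function(la, A) {
  off <- apply(la, 1L, max)
  amax <- max(A)
  p <- exp(la - off) %*% exp(A - amax)
  log(p) + off + amax
}

# Forward recursion for one label over a batch of equal-length sequences.
# psi: list over t of n x m node-potential matrices.  Returns list of
# per-step alpha matrices plus the per-trial log score.
hcrf_forward <- function(psi, A) {
  Tt <- length(psi)
  la <- vector("list", Tt)
  la[[1]] <- psi[[1]]
  if (Tt > 1) for (t in 2:Tt) la[[t]] <- log_mat_step(la[[t - 1]], A) + psi[[t]]
  list(alpha = la, logscore = row_logsumexp(la[[Tt]]))
}

hcrf_backward <- function(psi, A) {
  Tt <- length(psi)
  lb <- vector("list", Tt)
  lb[[Tt]] <- matrix(0, nrow(psi[[1]]), ncol(psi[[1]]))
  if (Tt > 1) for (t in (Tt - 1):1)
    lb[[t]] <- log_mat_step(lb[[t + 1]] + psi[[t + 1]], t(A))
  lb
}

# Node potentials for one label: list over t of n x m matrices.
hcrf_psi <- function(Xt, par) {
  lapply(Xt, function(x) x %*% t(par$W) + rep(par$b, each = nrow(x)))
}

# Negative conditional log-likelihood and analytic gradient over a batch of
# equal-length sequences.  Xt: list over t of n x d matrices; y: integer
# labels 1..n_classes; weight c_i on trial i applied to both.
hcrf_nll_grad_batch <- function(theta, Xt, y, n_classes, m, d) {
  n <- nrow(Xt[[1]])
  Tt <- length(Xt)
  pars <- hcrf_unpack(theta, n_classes, m, d)
  psis <- lapply(pars, hcrf_psi, Xt = Xt)
  fwd <- lapply(seq_len(n_classes), function(k) hcrf_forward(psis[[k]],
                                                             pars[[k]]$A))
  L <- vapply(fwd, `[[`, numeric(n), "logscore")    # n x n_classes
  if (is.null(dim(L))) L <- matrix(L, nrow = n)
  lz <- row_logsumexp(L)
  obs <- L[cbind(seq_len(n), y)]
  nll <- -sum(obs - lz)
  if (!is.finite(nll))
    stop("non-finite HCRF objective at trial ",
         which(!is.finite(obs - lz))[1])
  post <- exp(L - lz)                               # p(y | x_i)
  grad <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    cvec <- post[, k] - as.numeric(y == k)          # model - empirical
    bwd <- hcrf_backward(psis[[k]], pars[[k]]$A)
    la <- fwd[[k]]$alpha
    Lk <- fwd[[k]]$logscore
    mk <- nrow(pars[[k]]$W)
    gW <- matrix(0, mk, d); gb <- numeric(mk); gA <- matrix(0, mk, mk)
    for (t in seq_len(Tt)) {
      q <- exp(la[[t]] + bwd[[t]] - Lk)             # node marginals, rows sum 1
      qc <- q * cvec
      gW <- gW + crossprod(qc, Xt[[t]])
      gb <- gb + colSums(qc)
      if (t > 1) {
        off <- apply(la[[t - 1]], 1L, max)
        U <- exp(la[[t - 1]] - off)
        V <- exp(psis[[k]][[t]] + bwd[[t]] - Lk + off)
        gA <- gA + exp(pars[[k]]$A) * crossprod(U * cvec, V)
      }
    }
    grad[[k]] <- c(as.vector(gW), gb, as.vector(gA))
  }
  list(nll = nll, grad = unlist(grad))
}

seqs_by_length <- function(seqs) {
  lens <- vapply(seqs, nrow, 1L)
  split(seq_along(seqs), lens)
}

# Stack sequences (equal length) into a list over t of n x d matrices.
stack_seqs <- function(seqs) {
  Tt <- nrow(seqs[[1]])
  d <- ncol(seqs[[1]])
  lapply(seq_len(Tt), function(t)
    matrix(vapply(seqs, function(s) s[t, ], numeric(d)),
           ncol = d, byrow = TRUE))
}

#' HCRF objective and gradient
#'
#' Regularized negative conditional log-likelihood
#' `-sum(log p(y_i | x_i)) + reg/2 * ||theta||^2` of a weight vector over a
#' training set, with its analytic gradient computed by the log-space
#' forward-backward recursions (expected feature counts under the model
#' minus those clamped to the observed label, plus the ridge term).
#' Sequences of different lengths are grouped and batched internally.
#'
#' @param theta numeric weight vector of length
#'   `n_classes * (m*d + m + m^2)`.
#' @param seqs list of feature matrices (windows x features), e.g.
#'   `feature_seq` objects.
#' @param labels class label per sequence.
#' @param classes ordered label set defining the packing order of `theta`.
#' @param m hidden states per label (scalar, or one count per label).
#' @param reg L2 regularization strength.
#' @return list with elements `value` and `gradient`.
#' @export
hcrf_objective <- function(theta, seqs, labels, classes, m, reg = 0) {
  d <- ncol(seqs[[1]])
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stop_config("labels outside the declared class set")
  groups <- seqs_by_length(seqs)
  nll <- 0; grad <- numeric(length(theta))
  for (ix in groups) {
    Xt <- stack_seqs(seqs[ix])
    r <- hcrf_nll_grad_batch(theta, Xt, y[ix], length(classes), m, d)
    nll <- nll + r$nll
    grad <- grad + r$grad
  }
  list(value = nll + reg / 2 * sum(theta^2), gradient = grad + reg * theta)
}

#' Fit a hidden conditional random field sequence classifier
#'
#' Trains a linear-chain HCRF with `m` disjoint hidden states per label by
#' quasi-Newton (L-BFGS-B) minimization of the L2-regularized negative
#' conditional log-likelihood, from small random initial weights
#' (standard deviation 0.1, seeded).  The hidden-variable likelihood is
#' non-convex, so `restarts` independent starts are run and the one with
#' the lowest final objective is kept.  Convergence is declared when the
#' projected gradient falls below `1e-5` or after 500 iterations.
#'
#' @param seqs list of per-trial feature matrices (windows x features); all
#'   sequences must share the feature dimension.
#' @param labels class label per sequence (>= 1 trial per label).
#' @param m hidden states per label: a scalar shared by all labels or
#'   a vector with one count per label (the state sets are disjoint either
#'   way).
#' @param reg L2 regularization strength.
#' @param seed integer seed controlling the random initializations.
#' @param restarts number of random restarts.
#' @return an object of class `"mi_hcrf"` with the packed weights `theta`,
#'   the per-label parameter blocks, and training diagnostics.
#' @export
mi_hcrf <- function(seqs, labels, m = 3L, reg = 1, seed = 1L, restarts = 3L) {
  labels <- as.character(labels)
  stopifnot(length(seqs) == length(labels), length(seqs) >= 2L)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_config("need >= 2 classes in training data")
  d <- ncol(seqs[[1]])
  if (any(vapply(seqs, ncol, 1L) != d))
    stop_config("all sequences must share the feature dimension ", d)
  seqs <- lapply(seqs, function(s) {
    s <- unclass(s); attributes(s)[setdiff(names(attributes(s)),
                                           c("dim", "dimnames"))] <- NULL; s
  })
  npar <- hcrf_n_par(length(classes), m, d)
  # objective/gradient cache so optim's fn and gr share one evaluation
  cache <- new.env(parent = emptyenv())
  evalobj <- function(th) {
    key <- cache$theta
    if (is.null(key) || !identical(key, th)) {
      cache$res <- hcrf_objective(th, seqs, labels, classes, m, reg)
      cache$theta <- th
    }
    cache$res
  }
  best <- NULL
  fails <- character(0)
  for (r in seq_len(restarts)) {
    init <- with_seed(derive_seed(seed, r), stats::rnorm(npar, 0, 0.1))
    fit <- tryCatch(
      stats::optim(init, fn = function(th) evalobj(th)$value,
                   gr = function(th) evalobj(th)$gradient,
                   method = "L-BFGS-B",
                   control = list(maxit = 500L, pgtol = 1e-5, factr = 1e4)),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit)); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_config("HCRF training failed on all restarts: ",
                paste(unique(fails), collapse = "; "))
  structure(list(theta = best$par,
                 par = hcrf_unpack(best$par, length(classes), m, d),
                 classes = classes, m = m, d = d, reg = reg,
                 value = best$value, convergence = best$convergence,
                 restarts = restarts, seed = seed),
            class = "mi_hcrf")
}

#' Unnormalized log score of a label for one sequence
#'
#' The log of the sum, over all hidden paths within the label's private
#' state set, of the exponentiated path score — computed by the forward
#' recursion in log space.  With all weights zero this equals
#' `T * log(m)` for every label (every path scores 1).
#'
#' @param object a fitted `mi_hcrf`.
#' @param seq a windows x features matrix.
#' @param label one of the model's class labels.
#' @return scalar log score.
#' @export
label_log_score <- function(object, seq, label) {
  stopifnot(inherits(object, "mi_hcrf"))
  k <- match(as.character(label), object$classes)
  if (is.na(k)) stop_config("unknown label '", label, "'")
  seq <- matrix(as.numeric(seq), nrow = nrow(seq))
  if (ncol(seq) != object$d)
    stop_config("sequence has ", ncol(seq), " features; model expects ",
                object$d)
  Xt <- lapply(seq_len(nrow(seq)), function(t) seq[t, , drop = FALSE])
  psi <- hcrf_psi(Xt, object$par[[k]])
  hcrf_forward(psi, object$par[[k]]$A)$logscore
}

#' @export
#' @describeIn mi_hcrf posterior class probabilities (`type = "prob"`,
#'   summing to 1) or argmax labels (`type = "class"`, ties broken towards
#'   the first label).
#' @param object,newdata,type,... standard predict arguments; `newdata` is
#'   one matrix or a list of matrices.
predict.mi_hcrf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata) || inherits(newdata, "feature_seq"))
    newdata <- list(newdata)
  scores <- t(vapply(newdata, function(s)
    vapply(object$classes, function(y) label_log_score(object, s, y),
           0), numeric(length(object$classes))))
  post <- exp(scores - row_logsumexp(scores))
  colnames(post) <- object$classes
  if (type == "prob") return(post)
  # which.max takes the first maximum: deterministic first-label tie-break
  object$classes[apply(post, 1L, which.max)]
}

#' @export
print.mi_hcrf <- function(x, ...) {
  cat(sprintf(
    "<mi_hcrf> %d classes (%s), %d hidden states/label, %d features\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$m, x$d))
  cat(sprintf("reg = %g, final objective = %.4f, restarts = %d\n",
              x$reg, x$value, x$restarts))
  invisible(x)
}

#' Serialize HCRF weights to plain text
#'
#' Writes (and reads back) the trained weights as JSON keyed by label,
#' with named state-observation, bias and transition blocks.
#'
#' @param object a fitted `mi_hcrf`.
#' @param path file path.
#' @export
write_mi_hcrf <- function(object, path) {
  # flat theta is authoritative for the round trip; the per-label blocks
  # are a human-readable audit view keyed by (label, state, feature)
  blocks <- lapply(seq_along(object$classes), function(k) {
    p <- object$par[[k]]
    list(label = object$classes[k], state_obs = p$W, state_bias = p$b,
         transitions = p$A)
  })
  jsonlite::write_json(list(classes = object$classes, m = object$m,
                            d = object$d, reg = object$reg,
                            theta = object$theta, blocks = blocks),
                       path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mi_hcrf
#' @export
read_mi_hcrf <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- as.numeric(j$theta)
  m <- as.integer(j$m); d <- as.integer(j$d)
  structure(list(theta = theta,
                 par = hcrf_unpack(theta, length(j$classes), m, d),
                 classes = j$classes, m = m, d = d, reg = j$reg,
                 value = NA_real_, convergence = NA, restarts = NA,
                 seed = NA),
            class = "mi_hcrf")
}
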