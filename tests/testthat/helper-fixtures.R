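# Small in-code fixtures shared across test files.

# A short session with few trials for structural checks.
tiny_session <- function(seed = 1L, n_per_class = 6L, model = signal_model()) {
  generate_session(paradigm_config(n_runs = 1L,
                                   trials_per_class_per_run = n_per_class),
                   model, seed = seed)
}

# Signal model in which band powers carry no class information (no ERD) and
# only the inter-channel coupling differs between classes.
coupling_only_model <- function(g = c(left = 0.45, right = 0.75)) {
  flat <- rbind(left  = c(C3 = 1, Cz = 1, C4 = 1),
                right = c(C3 = 1, Cz = 1, C4 = 1))
  signal_model(erd_depth = flat, coupling_strength = g,
               subject_effect_sd = 0)
}

# Signal model with neither ERD nor coupling differences: pure null.
null_model <- function() {
  flat <- rbind(left  = c(C3 = 1, Cz = 1, C4 = 1),
                right = c(C3 = 1, Cz = 1, C4 = 1))
  signal_model(erd_depth = flat, coupling_strength = c(left = 0, right = 0),
               subject_effect_sd = 0)
}

# Deterministic mi_trial wrapper around a plain signal matrix.
trial_from_signal <- function(signal, label = "left", fs = 250) {
  rownames(signal) <- c("C3", "Cz", "C4")
  structure(list(signal = signal, label = label, fs = fs,
                 subject_id = 1L, session_id = 1L, trial_index = 1L),
            class = "mi_trial")
}

# Random HCRF parameter object without training, for scoring tests.
hcrf_stub <- function(theta, m, d, classes = c("a", "b")) {
  structure(list(theta = theta,
                 par = mieeg:::hcrf_unpack(theta, length(classes), m, d),
                 classes = classes, m = m, d = d, reg = 0),
            class = "mi_hcrf")
}

# Exhaustive hidden-path enumeration: the independent oracle for the
# forward recursion.
brute_label_score <- function(par, X) {
  m <- nrow(par$W)
  Tt <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), Tt)))
  scores <- apply(paths, 1L, function(h) {
    s <- 0
    for (t in seq_len(Tt)) {
      s <- s + sum(par$W[h[t], ] * X[t, ]) + par$b[h[t]]
      if (t > 1) s <- s + par$A[h[t - 1], h[t]]
    }
    s
  })
  mieeg:::logsumexp(scores)
}

# Independent randomized-complete-block sums-of-squares decomposition
# (levels x blocks response matrix).
rcbd_oracle <- function(y) {
  a <- nrow(y); b <- ncol(y); g <- mean(y)
  ssf <- b * sum((rowMeans(y) - g)^2)
  ssb <- a * sum((colMeans(y) - g)^2)
  sst <- sum((y - g)^2)
  ssr <- sst - ssf - ssb
  df1 <- a - 1; df2 <- (a - 1) * (b - 1)
  F <- (ssf / df1) / (ssr / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       ssf = ssf, ssb = ssb, ssr = ssr, sst = sst,
       ms_residual = ssr / df2, df1 = df1, df2 = df2)
}

# Long-format blocked table from a levels x blocks matrix.
blocked_table <- function(y, levels = rownames(y), blocks = colnames(y)) {
  if (is.null(levels)) levels <- paste0("L", seq_len(nrow(y)))
  if (is.null(blocks)) blocks <- paste0("B", seq_len(ncol(y)))
  data.frame(condition = rep(levels, times = ncol(y)),
             subject = rep(blocks, each = nrow(y)),
             accuracy = as.vector(y), stringsAsFactors = FALSE)
}
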