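#' Sliding-window specification
#'
#' A window of `window_s` seconds (k = `window_s * fs` samples) displaced by
#' `slide_s` seconds between successive windows.  Both must resolve to whole
#' sample counts at the trial's sampling rate.
#'
#' @param window_s window length in seconds.
#' @param slide_s displacement between window starts in seconds.
#' @return an object of class `"window_spec"`.
#' @export
window_spec <- function(window_s, slide_s = window_s) {
  if (!is.finite(window_s) || window_s <= 0)
    stop_config("window_s must be positive, got ", window_s)
  if (!is.finite(slide_s) || slide_s <= 0)
    stop_config("slide_s must be positive, got ", slide_s)
  structure(list(window_s = window_s, slide_s = slide_s),
            class = "window_spec")
}

#' Enumerate sliding-window sample ranges
#'
#' Returns the half-open sample ranges `[start, start + k)` produced by
#' sliding a k-sample window in steps of `delta` samples over a segment of
#' `n_samples` samples, starting at 0.  Only complete windows are emitted:
#' the last window ends at or before `n_samples`, so the window count is
#' `floor((n_samples - k) / delta) + 1`.
#'
#' @param n_samples segment length in samples.
#' @param spec a [window_spec()].
#' @param fs sampling rate in Hz.
#' @return integer matrix with columns `start`, `end` (0-based, half-open),
#'   one row per window.
#' @examples
#' slide_windows(750, window_spec(2, 0.5), 250)  # 3 windows
#' @export
slide_windows <- function(n_samples, spec, fs) {
  k <- spec$window_s * fs
  delta <- spec$slide_s * fs
  if (abs(k - round(k)) > 1e-9 || abs(delta - round(delta)) > 1e-9)
    stop_config("window (", spec$window_s, " s) and slide (", spec$slide_s,
                " s) must be whole sample counts at fs = ", fs, " Hz")
  k <- as.integer(round(k)); delta <- as.integer(round(delta))
  if (k > n_samples)
    stop_config("window of ", k, " samples exceeds segment of ", n_samples,
                " samples")
  starts <- seq.int(0L, n_samples - k, by = delta)
  cbind(start = starts, end = starts + k)
}

#' Band power of a single-channel segment
#'
#' Integrates a Welch-style averaged periodogram over a frequency band.  The
#' segment is split into up to two Hann-tapered half-overlapping
#' sub-segments (one when the segment is short), their periodograms are
#' averaged, and the power spectral density is summed over the bins inside
#' `[low_hz, high_hz]`.
#'
#' @param segment numeric vector of samples from one channel.
#' @param band numeric `c(low_hz, high_hz)` with `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return non-negative scalar band power.
#' @export
band_power <- function(segment, band, fs) {
  n <- length(segment)
  if (n < 2L) stop_config("segment must have at least 2 samples")
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop_config("band (", band[1], ", ", band[2],
                ") Hz must satisfy 0 < low < high < fs/2 = ", fs / 2)
  # adaptive Welch segmentation: two half-overlapping segments when long
  # enough to keep >= 2 bins inside a 4 Hz band, otherwise one segment
  seg_len <- if (n >= 250L) as.integer(floor(n / 1.5)) else n
  starts <- if (seg_len < n) c(0L, n - seg_len) else 0L
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- sum(taper^2)
  f <- seq(0, floor(seg_len / 2)) * fs / seg_len
  sel <- f >= band[1] & f <= band[2]
  psd <- rep(0, sum(sel))
  for (s in starts) {
    x <- segment[(s + 1L):(s + seg_len)] * taper
    p <- (Mod(stats::fft(x))^2 / (fs * u))[seq_along(f)]
    psd <- psd + p[sel]
  }
  sum(psd / length(starts)) * fs / seg_len
}

#' Power-of-ten feature scaling fitted on training data
#'
#' Fits the common multiplicative factor `10^e` that brings the maximum
#' band power of a training set into `[1, 10)`; the same factor is then
#' applied to test data (which may therefore exceed 10).
#'
#' @param values non-negative training powers.
#' @return an object of class `"power_scale"` with element `factor`.
#' @export
fit_power_scale <- function(values) {
  if (any(values < 0)) stop_config("band powers must be non-negative")
  mx <- max(values)
  if (mx == 0) {
    warning("all-zero powers; using identity scaling")
    factor <- 1
  } else {
    factor <- 10^(-floor(log10(mx)))
  }
  structure(list(factor = factor), class = "power_scale")
}

#' @rdname fit_power_scale
#' @param scale a fitted `power_scale`.
#' @export
apply_power_scale <- function(scale, values) values * scale$factor

#' Pearson correlation of two equal-length windows
#'
#' The ratio of the cross-moment E\[xy\] to the product of the standard
#' deviations, computed after removing each window's mean (the definition
#' assumes zero-mean variables).  A zero-variance input yields 0 with a
#' warning rather than an error, so degenerate flat windows cannot abort a
#' cross-validation fold.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_config("x and y must have equal length >= 2")
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) {
    warning("zero-variance window in pearson_cor; returning 0")
    return(0)
  }
  max(-1, min(1, sum(x * y) / (sx * sy)))
}

#' Generalized Jaccard index and distance for real-valued signals
#'
#' The set-based Jaccard index extends to real vectors by taking the dot
#' product as the measure of the intersection:
#' `J(A, B) = (A . B) / (||A||^2 + ||B||^2 - A . B)`, which ranges from
#' -1/3 (attained at `B = -A`) to 1 (at `B = A`).  The companion distance
#' is `JD = 1 - J = ||A - B||^2 / (||A||^2 + ||B||^2 - A . B)`, ranging
#' from 0 to 4/3.  Both are undefined when `A` and `B` are both zero.
#'
#' @param a,b numeric vectors of equal length, not both zero.
#' @return `jaccard_index` in `[-1/3, 1]`; `jaccard_distance` in `[0, 4/3]`.
#' @examples
#' a <- c(1, -2, 3)
#' jaccard_index(a, a)      # 1
#' jaccard_index(a, -a)     # -1/3
#' jaccard_distance(a, a)   # 0
#' @export
jaccard_index <- function(a, b) {
  if (length(a) != length(b))
    stop_config("a and b must have equal length")
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0)
    stop_config("jaccard_index undefined: both inputs are zero")
  ab / denom
}

#' @rdname jaccard_index
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_config("a and b must have equal length")
  d2 <- sum((a - b)^2)
  denom <- sum(a^2) + sum(b^2) - sum(a * b)
  if (denom == 0)
    stop_config("jaccard_distance undefined: both inputs are zero")
  d2 / denom
}

# fixed feature layout -------------------------------------------------------
mi_channels <- c("C3", "Cz", "C4")
mi_pairs <- list(c("C3", "Cz"), c("C4", "Cz"), c("C3", "C4"))

feature_names <- function(interaction_mode) {
  bp <- as.vector(t(outer(mi_channels, c("alpha", "beta"), paste, sep = "_")))
  if (interaction_mode == "none") return(bp)
  tag <- switch(interaction_mode, correlation = "cor", jaccard = "jd")
  c(bp, vapply(mi_pairs, function(p) paste(tag, p[1], p[2], sep = "_"), ""))
}

#' Extract per-window features from a trial
#'
#' For each sliding window: the mu/alpha and beta band powers of each
#' channel in fixed order (C3 alpha, C3 beta, Cz alpha, Cz beta, C4 alpha,
#' C4 beta), followed — when `interaction_mode` is not `"none"` — by the
#' three pairwise interaction values (C3-Cz, C4-Cz, C3-C4) computed on the
#' raw windowed samples: Pearson correlation or generalized Jaccard
#' distance.  Band powers are returned unscaled; the train-fold-fitted
#' [fit_power_scale()] factor is applied later by the evaluation layer (or
#' by `scale` here for standalone use).
#'
#' @param trial an `mi_trial`.
#' @param spec a [window_spec()]; defaults to one whole-trial window.
#' @param interaction_mode `"none"`, `"correlation"` or `"jaccard"`.
#' @param bands named list with `alpha` and `beta` frequency intervals.
#' @param scale optional fitted `power_scale` applied to the band-power
#'   columns.
#' @return an object of class `"feature_seq"`: a windows x features numeric
#'   matrix with named columns, plus trial metadata attributes.
#' @export
extract_features <- function(trial, spec = NULL,
                             interaction_mode = c("none", "correlation",
                                                  "jaccard"),
                             bands = list(alpha = c(8, 12), beta = c(15, 25)),
                             scale = NULL) {
  interaction_mode <- match.arg(interaction_mode)
  stopifnot(inherits(trial, "mi_trial"))
  n <- ncol(trial$signal)
  fs <- trial$fs
  if (is.null(spec)) spec <- window_spec(n / fs)
  win <- slide_windows(n, spec, fs)
  nms <- feature_names(interaction_mode)
  out <- matrix(NA_real_, nrow(win), length(nms),
                dimnames = list(NULL, nms))
  for (w in seq_len(nrow(win))) {
    ix <- (win[w, "start"] + 1L):win[w, "end"]
    seg <- trial$signal[, ix, drop = FALSE]
    v <- numeric(0)
    for (ch in mi_channels)
      v <- c(v, band_power(seg[ch, ], bands$alpha, fs),
             band_power(seg[ch, ], bands$beta, fs))
    if (interaction_mode != "none") {
      fun <- switch(interaction_mode, correlation = pearson_cor,
                    jaccard = jaccard_distance)
      v <- c(v, vapply(mi_pairs, function(p) fun(seg[p[1], ], seg[p[2], ]),
                       0))
    }
    out[w, ] <- v
  }
  if (!all(is.finite(out)))
    stop_config("non-finite feature values in trial ", trial$trial_index)
  if (!is.null(scale)) {
    bp_cols <- seq_len(2L * length(mi_channels))
    out[, bp_cols] <- apply_power_scale(scale, out[, bp_cols, drop = FALSE])
  }
  structure(out, class = c("feature_seq", class(out)),
            interaction_mode = interaction_mode,
            label = trial$label, subject_id = trial$subject_id,
            session_id = trial$session_id, trial_index = trial$trial_index,
            window_s = spec$window_s, slide_s = spec$slide_s)
}

#' Flatten a feature sequence for a static classifier
#'
#' Concatenates the per-window feature vectors in window order into one
#' vector of length `windows * features`, the form the shared-covariance
#' linear discriminant consumes.
#'
#' @param seq a `feature_seq`.
#' @return named numeric vector.
#' @export
flatten_features <- function(seq) {
  stopifnot(inherits(seq, "feature_seq"), nrow(seq) >= 1L)
  v <- as.vector(t(unclass(seq)))
  names(v) <- paste0("w", rep(seq_len(nrow(seq)), each = ncol(seq)), "_",
                     rep(colnames(seq), nrow(seq)))
  v
}

#' Write a list of feature sequences to CSV
#'
#' One row per trial-window: metadata columns (subject, session, trial,
#' label, window) followed by the named feature columns.
#'
#' @param seqs list of `feature_seq` objects.
#' @param path output file.
#' @export
features_to_csv <- function(seqs, path) {
  rows <- do.call(rbind, lapply(seqs, function(fs) {
    cbind(data.frame(subject = attr(fs, "subject_id"),
                     session = attr(fs, "session_id"),
                     trial = attr(fs, "trial_index"),
                     label = attr(fs, "label"),
                     window = seq_len(nrow(fs))),
          as.data.frame(unclass(fs)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
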