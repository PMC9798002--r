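#' Paradigm configuration for a synthetic motor-imagery session
#'
#' Describes the trial structure of one recording session in a cue-based
#' two-class (left vs right hand) motor-imagery experiment: runs per session,
#' trials per class per run, sampling rate and the bounds of the imagery
#' segment within a trial.  The feedback paradigm default (4 runs, 20 trials
#' per class per run) yields 160 trials per session; the screening paradigm
#' (6 runs, 10 per class per run) yields 120.
#'
#' @param n_runs number of runs per session.
#' @param trials_per_class_per_run trials of each class within one run.
#' @param classes ordered character vector of class labels.
#' @param fs sampling rate in Hz.
#' @param segment_start_s,segment_end_s imagery-segment bounds in seconds
#'   relative to trial start.  Only this segment is emitted by default.
#' @param session_kind `"feedback"` or `"screening"`; metadata only, the
#'   counts are controlled by the other arguments.
#' @return an object of class `"paradigm_config"`.
#' @seealso [screening_paradigm()] for the screening-session preset.
#' @examples
#' p <- paradigm_config()
#' n_trials_per_session(p)  # 160
#' @export
paradigm_config <- function(n_runs = 4L, trials_per_class_per_run = 20L,
                            classes = c("left", "right"), fs = 250,
                            segment_start_s = 3, segment_end_s = 6,
                            session_kind = c("feedback", "screening")) {
  session_kind <- match.arg(session_kind)
  n_runs <- as.integer(n_runs)
  trials_per_class_per_run <- as.integer(trials_per_class_per_run)
  if (is.na(n_runs) || n_runs < 1L)
    stop_config("n_runs must be a positive integer, got ", n_runs)
  if (is.na(trials_per_class_per_run) || trials_per_class_per_run < 1L)
    stop_config("trials_per_class_per_run must be a positive integer, got ",
                trials_per_class_per_run)
  if (length(classes) < 2L || anyDuplicated(classes))
    stop_config("classes must be at least two distinct labels")
  if (!is.finite(fs) || fs <= 0)
    stop_config("fs must be positive, got ", fs)
  if (!(segment_end_s > segment_start_s) || segment_start_s < 0)
    stop_config("need 0 <= segment_start_s < segment_end_s, got [",
                segment_start_s, ", ", segment_end_s, "]")
  structure(list(n_runs = n_runs,
                 trials_per_class_per_run = trials_per_class_per_run,
                 classes = as.character(classes), fs = as.numeric(fs),
                 segment_start_s = as.numeric(segment_start_s),
                 segment_end_s = as.numeric(segment_end_s),
                 session_kind = session_kind),
            class = "paradigm_config")
}

#' @rdname paradigm_config
#' @export
screening_paradigm <- function(fs = 250) {
  paradigm_config(n_runs = 6L, trials_per_class_per_run = 10L, fs = fs,
                  session_kind = "screening")
}

#' @rdname paradigm_config
#' @param paradigm a `paradigm_config`.
#' @export
n_trials_per_session <- function(paradigm) {
  paradigm$n_runs * length(paradigm$classes) * paradigm$trials_per_class_per_run
}

#' Generative signal model for synthetic motor-imagery EEG
#'
#' Parameters of the three-channel (C3, Cz, C4) signal generator.  Each
#' channel is a sum of 1/f^alpha background noise and narrow-band mu and
#' beta oscillations (band-limited Gaussian noise).  Class structure enters
#' two ways: (i) event-related desynchronization (ERD) — a per-class,
#' per-channel multiplicative attenuation `erd_depth` of the oscillation
#' amplitude over the contralateral sensorimotor channel during imagery; and
#' (ii) inter-channel coupling — a fraction `coupling_strength` of the C3
#' and C4 mu-band oscillation is a shared latent source, producing a
#' class-dependent C3-C4 correlation while leaving the marginal band power
#' unchanged (the private and shared parts are mixed with weights
#' sqrt(1-g^2) and g).  Subjects differ through a per-subject additive shift
#' on `erd_depth` with standard deviation `subject_effect_sd`, giving the
#' block structure the downstream randomized-blocks ANOVA assumes.
#'
#' @param background_sd broadband background noise standard deviation.
#' @param one_over_f_exponent spectral slope alpha of the background.
#' @param mu_band,beta_band frequency intervals in Hz.
#' @param mu_amplitude,beta_amplitude oscillation standard deviations before
#'   ERD attenuation.
#' @param erd_depth classes x channels matrix of multiplicative amplitude
#'   factors in (0, 1] applied during the imagery segment; 1 means no
#'   desynchronization.  The default attenuates the channel contralateral to
#'   the imagined hand (C4 for left, C3 for right) to 0.9 and Cz to 0.95, a
#'   moderate desynchronization that keeps single-trial classification off
#'   the ceiling.
#' @param coupling_strength named per-class mixing coefficient in [0, 1) of
#'   the shared mu-band source on the C3-C4 pair.
#' @param subject_effect_sd standard deviation of the per-subject additive
#'   shift applied to `erd_depth` (clamped back into (0, 1]).
#' @return an object of class `"signal_model"`.
#' @export
signal_model <- function(background_sd = 1, one_over_f_exponent = 1,
                         mu_band = c(8, 12), beta_band = c(15, 25),
                         mu_amplitude = 1, beta_amplitude = 0.7,
                         erd_depth = NULL,
                         coupling_strength = c(left = 0.45, right = 0.75),
                         subject_effect_sd = 0.05) {
  channels <- c("C3", "Cz", "C4")
  if (is.null(erd_depth)) {
    erd_depth <- rbind(left  = c(C3 = 1.0, Cz = 0.95, C4 = 0.9),
                       right = c(C3 = 0.9, Cz = 0.95, C4 = 1.0))
  }
  erd_depth <- as.matrix(erd_depth)
  if (any(erd_depth <= 0) || any(erd_depth > 1))
    stop_config("erd_depth values must lie in (0, 1]")
  if (any(coupling_strength < 0) || any(coupling_strength >= 1))
    stop_config("coupling_strength must lie in [0, 1)")
  if (subject_effect_sd < 0)
    stop_config("subject_effect_sd must be >= 0")
  for (b in list(mu_band, beta_band))
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1])
      stop_config("bands must be increasing positive intervals, got (",
                  paste(b, collapse = ", "), ")")
  structure(list(background_sd = background_sd,
                 one_over_f_exponent = one_over_f_exponent,
                 mu_band = mu_band, beta_band = beta_band,
                 mu_amplitude = mu_amplitude, beta_amplitude = beta_amplitude,
                 erd_depth = erd_depth,
                 coupling_strength = coupling_strength,
                 subject_effect_sd = subject_effect_sd,
                 channels = channels),
            class = "signal_model")
}

# --- frequency-domain noise synthesis ---------------------------------------
# Real Gaussian noise with spectral amplitude profile `amp` (length
# floor(n/2) + 1, bins 0..n/2), scaled so that the *expected* variance is 1.
# Sampling in the frequency domain keeps trial-to-trial power fluctuation
# (chi-squared per bin), which band-power estimators then see.
spectral_noise <- function(n, amp) {
  nh <- length(amp)
  stopifnot(nh == floor(n / 2) + 1L)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * amp
  # DC and (for even n) Nyquist bins must be real
  z[1] <- complex(real = Re(z[1]) * sqrt(2), imaginary = 0)
  if (n %% 2L == 0L) z[nh] <- complex(real = Re(z[nh]) * sqrt(2), imaginary = 0)
  spec <- c(z, Conj(z[seq(if (n %% 2L == 0L) nh - 1L else nh, 2L)]))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  # expected per-sample variance: paired bins contribute 4*amp^2, the real
  # DC/Nyquist bins (scaled by sqrt(2) above) contribute 2*amp^2 each
  w <- 4 * amp^2
  w[1] <- 2 * amp[1]^2
  if (n %% 2L == 0L) w[nh] <- 2 * amp[nh]^2
  ev <- sum(w) / n^2
  if (ev <= 0) return(numeric(n))
  x / sqrt(ev)
}

one_over_f_noise <- function(n, fs, exponent) {
  f <- seq(0, floor(n / 2)) * fs / n
  amp <- c(0, f[-1]^(-exponent / 2))  # no DC power
  spectral_noise(n, amp)
}

band_noise <- function(n, fs, band) {
  f <- seq(0, floor(n / 2)) * fs / n
  amp <- as.numeric(f >= band[1] & f <= band[2])
  if (sum(amp) == 0)
    stop_config("band (", band[1], ", ", band[2],
                ") Hz contains no frequency bin at n = ", n, ", fs = ", fs)
  spectral_noise(n, amp)
}

# ERD matrix for one subject: additive shift, clamped into (0, 1].
subject_erd <- function(model, shift) {
  pmin(pmax(model$erd_depth + shift, 0.05), 1)
}

synth_trial_signal <- function(n, model, label, fs, erd) {
  ch <- model$channels
  g <- unname(model$coupling_strength[label])
  if (is.na(g))
    stop_config("coupling_strength has no entry for class '", label, "'")
  bg <- vapply(ch, function(c)
    model$background_sd * one_over_f_noise(n, fs, model$one_over_f_exponent),
    numeric(n))
  shared <- band_noise(n, fs, model$mu_band)
  mu_priv <- vapply(ch, function(c) band_noise(n, fs, model$mu_band),
                    numeric(n))
  beta <- vapply(ch, function(c) band_noise(n, fs, model$beta_band),
                 numeric(n))
  depth <- erd[label, ch]
  mu <- mu_priv
  # shared latent source on the C3-C4 pair; unit marginal variance preserved
  mu[, "C3"] <- sqrt(1 - g^2) * mu_priv[, "C3"] + g * shared
  mu[, "C4"] <- sqrt(1 - g^2) * mu_priv[, "C4"] + g * shared
  sig <- bg +
    sweep(mu, 2L, model$mu_amplitude * depth, `*`) +
    sweep(beta, 2L, model$beta_amplitude * depth, `*`)
  t(sig)  # channels x samples
}

new_trial <- function(signal, label, fs, subject_id, session_id, trial_index) {
  structure(list(signal = signal, label = label, fs = fs,
                 subject_id = subject_id, session_id = session_id,
                 trial_index = trial_index),
            class = "mi_trial")
}

#' @export
print.mi_trial <- function(x, ...) {
  cat(sprintf("<mi_trial> subject %s session %s trial %d: class '%s', %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$session_id, x$trial_index, x$label,
              nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

#' Generate one synthetic motor-imagery session
#'
#' Emits the session's trials in run order, with the class sequence within
#' each run randomized (each run contains `trials_per_class_per_run` trials
#' of every class).  Each trial carries only the imagery segment
#' (`segment_start_s` to `segment_end_s`), the portion the analysis uses.
#'
#' @param paradigm a [paradigm_config()].
#' @param model a [signal_model()].
#' @param subject_id subject identifier stored on each trial.
#' @param seed integer seed; identical seeds and parameters give
#'   bit-identical output.
#' @param session_id session identifier stored on each trial.
#' @param subject_shift additive ERD shift for this subject (drawn by
#'   [generate_cohort()]; 0 for a standalone session).
#' @param full_trial if `TRUE`, emit the whole trial timeline (cue epoch,
#'   imagery segment, pause: 0 to `segment_end_s + 2` seconds) with the
#'   class-dependent modulation applied only inside the imagery segment;
#'   the analysis pipeline uses the default imagery-segment-only form.
#' @return list of `mi_trial` objects, length [n_trials_per_session()].
#' @export
generate_session <- function(paradigm, model, subject_id = 1L, seed = 1L,
                             session_id = 1L, subject_shift = 0,
                             full_trial = FALSE) {
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(model, "signal_model"))
  if (!all(paradigm$classes %in% rownames(model$erd_depth)))
    stop_config("signal model erd_depth lacks rows for classes: ",
                paste(setdiff(paradigm$classes, rownames(model$erd_depth)),
                      collapse = ", "))
  fs <- paradigm$fs
  n <- round((paradigm$segment_end_s - paradigm$segment_start_s) * fs)
  erd <- subject_erd(model, subject_shift)
  with_seed(seed, {
    trials <- vector("list", n_trials_per_session(paradigm))
    idx <- 0L
    for (run in seq_len(paradigm$n_runs)) {
      labels <- sample(rep(paradigm$classes,
                           each = paradigm$trials_per_class_per_run))
      for (lab in labels) {
        idx <- idx + 1L
        sig <- synth_trial_signal(n, model, lab, fs, erd)
        if (full_trial) {
          # neutral (resting) epochs before the cue and during the pause:
          # no desynchronization, no class-dependent coupling
          rest <- model
          rest$coupling_strength[] <- 0
          neutral <- erd; neutral[] <- 1
          pre <- synth_trial_signal(round(paradigm$segment_start_s * fs),
                                    rest, lab, fs, neutral)
          post <- synth_trial_signal(round(2 * fs), rest, lab, fs, neutral)
          sig <- cbind(pre, sig, post)
        }
        trials[[idx]] <- new_trial(sig, lab, fs, subject_id, session_id, idx)
      }
    }
    trials
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' Subject-level ERD shifts are drawn once per subject and reused across all
#' of that subject's sessions, so subjects act as blocks for the
#' randomized-blocks ANOVA downstream.  Per-subject and per-session seeds are
#' derived from the root seed by a counter-based scheme, making the cohort
#' reproducible and independent of generation order.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param sessions_per_subject sessions per subject.
#' @param paradigm a [paradigm_config()].
#' @param model a [signal_model()].
#' @param seed root integer seed.
#' @return an object of class `"mi_cohort"`: a list with one element per
#'   subject, each a list of sessions, each a list of `mi_trial`s.
#' @export
generate_cohort <- function(n_subjects, sessions_per_subject = 1L,
                            paradigm = paradigm_config(),
                            model = signal_model(), seed = 1L) {
  if (n_subjects < 1L) stop_config("n_subjects must be >= 1")
  subjects <- vector("list", n_subjects)
  names(subjects) <- paste0("S", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    shift <- if (model$subject_effect_sd > 0)
      with_seed(derive_seed(seed, c(s, 0L)),
                stats::rnorm(1, 0, model$subject_effect_sd)) else 0
    sessions <- vector("list", sessions_per_subject)
    names(sessions) <- paste0("sess", seq_len(sessions_per_subject))
    for (k in seq_len(sessions_per_subject)) {
      sessions[[k]] <- generate_session(paradigm, model, subject_id = s,
                                        seed = derive_seed(seed, c(s, k)),
                                        session_id = k,
                                        subject_shift = shift)
    }
    subjects[[s]] <- sessions
  }
  structure(subjects, class = "mi_cohort",
            paradigm = paradigm, model = model, seed = seed)
}

#' @export
print.mi_cohort <- function(x, ...) {
  ns <- length(x)
  nk <- length(x[[1]])
  nt <- length(x[[1]][[1]])
  cat(sprintf("<mi_cohort> %d subjects x %d sessions x %d trials (%s paradigm)\n",
              ns, nk, nt, attr(x, "paradigm")$session_kind))
  invisible(x)
}

#' Flatten a cohort (or one subject) to a plain list of trials
#'
#' @param cohort an `mi_cohort`.
#' @param subject optional subject index or name; all subjects if `NULL`.
#' @return list of `mi_trial` objects.
#' @export
cohort_trials <- function(cohort, subject = NULL) {
  subs <- if (is.null(subject)) seq_along(cohort) else subject
  unlist(lapply(subs, function(s) unlist(cohort[[s]], recursive = FALSE)),
         recursive = FALSE)
}

#' Write / read a cohort as plain-text CSV
#'
#' One file per session (`subject<S>_session<K>.csv` with columns subject,
#' session, trial, label, channel, sample_index, value) plus a
#' `cohort_config.json` sidecar recording the paradigm, model and seed.
#'
#' @param cohort an `mi_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv`
#'   returns an `mi_cohort`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(cohort)) for (k in seq_along(cohort[[s]])) {
    trials <- cohort[[s]][[k]]
    rows <- do.call(rbind, lapply(trials, function(tr) {
      nsamp <- ncol(tr$signal)
      data.frame(subject = tr$subject_id, session = tr$session_id,
                 trial = tr$trial_index, label = tr$label,
                 channel = rep(rownames(tr$signal), each = nsamp),
                 sample_index = rep(seq_len(nsamp) - 1L, nrow(tr$signal)),
                 value = as.vector(t(tr$signal)))
    }))
    utils::write.csv(rows, file.path(dir, sprintf("subject%d_session%d.csv",
                                                  s, k)), row.names = FALSE)
  }
  cfg <- list(paradigm = unclass(attr(cohort, "paradigm")),
              model = unclass(attr(cohort, "model")),
              seed = attr(cohort, "seed"),
              n_subjects = length(cohort),
              sessions_per_subject = length(cohort[[1]]))
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "cohort_config.json"),
                             simplifyVector = TRUE)
  paradigm <- do.call(paradigm_config,
                      cfg$paradigm[setdiff(names(cfg$paradigm), NULL)])
  model_fields <- cfg$model[setdiff(names(cfg$model), "channels")]
  model_fields$erd_depth <- as.matrix(model_fields$erd_depth)
  model_fields$coupling_strength <- unlist(model_fields$coupling_strength)
  model <- do.call(signal_model, model_fields)
  subjects <- vector("list", cfg$n_subjects)
  names(subjects) <- paste0("S", seq_len(cfg$n_subjects))
  for (s in seq_len(cfg$n_subjects)) {
    sessions <- vector("list", cfg$sessions_per_subject)
    names(sessions) <- paste0("sess", seq_len(cfg$sessions_per_subject))
    for (k in seq_len(cfg$sessions_per_subject)) {
      rows <- utils::read.csv(file.path(dir, sprintf(
        "subject%d_session%d.csv", s, k)), stringsAsFactors = FALSE)
      sessions[[k]] <- lapply(split(rows, rows$trial), function(d) {
        d <- d[order(match(d$channel, c("C3", "Cz", "C4")), d$sample_index), ]
        sig <- matrix(d$value, nrow = length(unique(d$channel)),
                      byrow = TRUE,
                      dimnames = list(unique(d$channel), NULL))
        new_trial(sig, d$label[1], paradigm$fs, d$subject[1], d$session[1],
                  d$trial[1])
      })
      sessions[[k]] <- sessions[[k]][order(vapply(sessions[[k]],
                                                  `[[`, 1L, "trial_index"))]
    }
    subjects[[s]] <- sessions
  }
  structure(subjects, class = "mi_cohort",
            paradigm = paradigm, model = model, seed = cfg$seed)
}

#' Adapter contract for real recorded sessions
#'
#' Accepts a session file in a biosignal container format (e.g. GDF from the
#' public motor-imagery datasets) together with a caller-supplied
#' `reader` function, and returns trials satisfying the same contract as
#' [generate_session()]: a list of `mi_trial`s holding the imagery segment
#' of the three bipolar channels C3, Cz, C4.  The package ships no binary
#' format parser; `reader` must return a list with elements `signal`
#' (channels x samples), `label`, and `fs` per trial.
#'
#' @param path path to a session file.
#' @param reader function(path) returning a list of per-trial lists.
#' @param subject_id,session_id identifiers stored on the trials.
#' @return list of `mi_trial` objects.
#' @export
read_session_adapter <- function(path, reader, subject_id = 1L,
                                 session_id = 1L) {
  if (!is.function(reader))
    stop_config("a reader function is required; no binary biosignal parser ",
                "is bundled")
  raw <- reader(path)
  lapply(seq_along(raw), function(i) {
    tr <- raw[[i]]
    stopifnot(is.matrix(tr$signal), !is.null(tr$label), tr$fs > 0)
    new_trial(tr$signal, tr$label, tr$fs, subject_id, session_id, i)
  })
}
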