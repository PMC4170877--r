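#' Default EEG frequency bands (Hz)
#'
#' Theta 4-8, alpha 8-13, beta 13-30; the shared endpoints mean a spectral
#' peak sitting exactly on a boundary bin (e.g. 8 Hz) belongs to both
#' neighbouring bands, and their band features then coincide.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and reverse
#' ([signal::filtfilt()]), giving zero phase shift and doubling the
#' amplitude roll-off outside the 1-40 Hz pass band.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must exceed `2 * hi`.
#' @param lo,hi Pass-band edges in Hz.
#' @param order Filter order of the underlying design.
#' @return Filtered series, same length.
#' @export
bandpass_filter <- function(x, fs, lo = 1, hi = 40, order = 4) {
  if (fs <= 2 * hi) abort("Sampling rate must exceed twice the upper band edge.")
  if (lo <= 0 || hi <= lo) abort("Need 0 < lo < hi.")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segment a series into zero-mean epochs
#'
#' Consecutive non-overlapping windows of `epoch_seconds` (1 s of 400
#' samples at the default rate), each de-meaned. Epochs whose absolute
#' amplitude exceeds `reject_k` standard deviations of the whole series are
#' rejected by a simple amplitude-threshold rule (a deliberately plain
#' placeholder for a full artifact-rejection procedure). When more than
#' `max_epochs` survive, the first `max_epochs` in temporal order are kept;
#' when fewer than `min_epochs` survive the set is flagged (`qualifies =
#' FALSE`) so the recording can be excluded from matrix assembly.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param epoch_seconds Epoch duration (s).
#' @param max_epochs Epochs retained at most (default 150).
#' @param min_epochs Inclusion threshold (default 150).
#' @param reject_k Amplitude-threshold multiplier; `Inf` disables rejection.
#' @return Object of class `epoch_set`: list with `epochs` (E x L matrix of
#'   zero-mean rows), `fs`, `n_rejected`, `qualifies`.
#' @export
make_epochs <- function(x, fs, epoch_seconds = 1, max_epochs = 150,
                        min_epochs = 150, reject_k = Inf) {
  L <- round(fs * epoch_seconds)
  if (length(x) < L) abort("Series shorter than one epoch.")
  E <- floor(length(x) / L)
  m <- matrix(x[seq_len(E * L)], nrow = E, ncol = L, byrow = TRUE)
  keep <- rep(TRUE, E)
  if (is.finite(reject_k)) {
    s <- sd(x)
    keep <- apply(abs(m), 1, max) <= reject_k * s
  }
  m <- m[keep, , drop = FALSE]
  n_rejected <- E - nrow(m)
  if (nrow(m) > max_epochs) m <- m[seq_len(max_epochs), , drop = FALSE]
  m <- m - rowMeans(m)
  structure(list(epochs = m, fs = fs, n_rejected = n_rejected,
                 qualifies = nrow(m) >= min_epochs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epochs x %d samples at %g Hz (%d rejected)%s\n",
              nrow(x$epochs), ncol(x$epochs), x$fs, x$n_rejected,
              if (x$qualifies) "" else " [below inclusion threshold]"))
  invisible(x)
}

#' Bartlett averaged periodogram
#'
#' One-sided power spectral density: a rectangular window is applied to
#' each epoch, per-epoch periodograms are computed and averaged across
#' epochs, which shrinks the estimate's variance as 1/E at an unchanged
#' frequency resolution of `fs / L` (1 Hz for 1-s epochs at 400 Hz). The
#' normalization conserves energy: `sum(psd) * df` equals the mean squared
#' signal (Parseval).
#'
#' @param es An [make_epochs()] epoch set.
#' @return Tibble with `freq` (Hz, 0..Nyquist) and `psd` (power per Hz).
#' @export
bartlett_psd <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  m <- es$epochs
  if (nrow(m) < 1) abort("Need at least one epoch.")
  L <- ncol(m)
  fs <- es$fs
  nk <- floor(L / 2) + 1 # one-sided bins incl. DC and (for even L) Nyquist
  acc <- numeric(nk)
  for (e in seq_len(nrow(m))) {
    spec <- abs(fft(m[e, ]))^2 / (L * fs) # two-sided density
    one <- spec[seq_len(nk)]
    dup <- if (L %% 2 == 0) 2:(nk - 1) else 2:nk # bins with a mirror image
    one[dup] <- 2 * one[dup]
    acc <- acc + one
  }
  tibble::tibble(freq = (seq_len(nk) - 1) * fs / L, psd = acc / nrow(m))
}

#' Band maximum and trapezoidal band power from a PSD
#'
#' The band maximum is the largest PSD value over the bins inside the band
#' (endpoints inclusive). The band power is the trapezoidal area of the PSD
#' over a window of `half_width` Hz on either side of the peak bin, clipped
#' to the band — the smallest symmetric window the 1 Hz default resolution
#' supports. Both are returned as log10 values (power per Hz, and power).
#'
#' @param psd A [bartlett_psd()] tibble (`freq`, `psd`).
#' @param band Length-2 numeric, band edges in Hz.
#' @param half_width Half-width (Hz) of the trapezoid around the peak.
#' @return Named list `max_log10`, `power_log10`, `peak_freq`.
#' @export
band_features <- function(psd, band, half_width = 1) {
  in_band <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(in_band)) abort(sprintf("No PSD bins inside band [%g, %g] Hz.", band[1], band[2]))
  sub <- psd[in_band, ]
  peak <- sub$freq[which.max(sub$psd)]
  win <- psd$freq >= max(band[1], peak - half_width) &
    psd$freq <= min(band[2], peak + half_width)
  pw <- psd[win, ]
  power <- if (nrow(pw) >= 2) pracma::trapz(pw$freq, pw$psd) else pw$psd
  list(max_log10 = log10(max(sub$psd)), power_log10 = log10(power),
       peak_freq = peak)
}

#' Time-domain statistics per epoch, medianed across epochs
#'
#' Per epoch: root mean square, sample standard deviation (n - 1), moment
#' skewness `m3 / m2^1.5`, and Mm, the span from the maximal positive to
#' the minimal negative sample. The median over epochs of each statistic is
#' returned — for zero-mean epochs of length L, RMS and SD are tied through
#' the factor `sqrt((L - 1) / L)`, which is why the two feature columns are
#' perfectly rank-correlated.
#'
#' @param es An [make_epochs()] epoch set.
#' @param skew_type Skewness estimator type as in [e1071::skewness()]
#'   (1 = moment coefficient g1, 2 = adjusted Fisher-Pearson).
#' @return Tibble with one row: `rms`, `sd`, `skewness`, `mm`.
#' @export
time_features <- function(es, skew_type = 1) {
  stopifnot(inherits(es, "epoch_set"))
  m <- es$epochs
  per <- apply(m, 1, function(ep) {
    c(rms = sqrt(mean(ep^2)), sd = sd(ep),
      skewness = e1071::skewness(ep, type = skew_type),
      mm = max(ep) - min(ep))
  })
  tibble::as_tibble(as.list(apply(per, 1, median)))
}

#' Full 10-variable feature row for one recording
#'
#' @param es An [make_epochs()] epoch set.
#' @param bands Band definitions, see [eeg_bands()].
#' @param half_width Trapezoid half-width (Hz), see [band_features()].
#' @param skew_type Skewness estimator, see [time_features()].
#' @return One-row tibble: `alpha_power`, `beta_power`, `theta_power`,
#'   `alpha_max`, `beta_max`, `theta_max`, `rms`, `sd`, `skewness`, `mm`.
#' @export
feature_row <- function(es, bands = eeg_bands(), half_width = 1, skew_type = 1) {
  psd <- bartlett_psd(es)
  bf <- purrr::map(bands, ~ band_features(psd, .x, half_width = half_width))
  tf <- time_features(es, skew_type = skew_type)
  tibble::tibble(
    alpha_power = bf$alpha$power_log10,
    beta_power = bf$beta$power_log10,
    theta_power = bf$theta$power_log10,
    alpha_max = bf$alpha$max_log10,
    beta_max = bf$beta$max_log10,
    theta_max = bf$theta$max_log10,
    rms = tf$rms, sd = tf$sd, skewness = tf$skewness, mm = tf$mm
  )
}

#' Assemble the subjects-by-features matrix from raw recordings
#'
#' Takes a long tibble of raw single-channel signals (one row per sample)
#' and builds one feature row per subject-condition recording. Subjects
#' missing any condition, or with fewer than `min_epochs` artifact-free
#' epochs in any condition, are dropped entirely (both conditions), so the
#' result pairs every retained subject across conditions.
#'
#' @param signals Tibble with columns `subject`, `condition`, `value`
#'   (samples in temporal order within each subject-condition group).
#' @param fs Sampling rate (Hz).
#' @param filter Apply [bandpass_filter()] first (default TRUE).
#' @param bands,half_width,skew_type Passed to [feature_row()].
#' @param epoch_seconds,max_epochs,min_epochs,reject_k Passed to
#'   [make_epochs()].
#' @return A feature-matrix tibble (first column `object_id` =
#'   `subject_condition`) ready for [fit_pca()]; attribute `excluded` lists
#'   dropped subjects.
#' @export
build_feature_matrix <- function(signals, fs, filter = TRUE,
                                 bands = eeg_bands(), half_width = 1,
                                 skew_type = 1, epoch_seconds = 1,
                                 max_epochs = 150, min_epochs = 150,
                                 reject_k = Inf) {
  if (!all(c("subject", "condition", "value") %in% names(signals))) {
    abort("`signals` must have columns subject, condition, value.")
  }
  groups <- dplyr::group_split(dplyr::group_by(signals, .data$subject, .data$condition))
  rows <- purrr::map(groups, function(g) {
    x <- g$value
    if (filter) x <- bandpass_filter(x, fs)
    es <- make_epochs(x, fs, epoch_seconds = epoch_seconds,
                      max_epochs = max_epochs, min_epochs = min_epochs,
                      reject_k = reject_k)
    tibble::tibble(subject = as.character(g$subject[1]),
                   condition = as.character(g$condition[1]),
                   qualifies = es$qualifies,
                   row = list(if (es$qualifies) {
                     feature_row(es, bands, half_width, skew_type)
                   } else {
                     NULL
                   }))
  })
  meta <- dplyr::bind_rows(rows)
  all_conditions <- unique(as.character(signals$condition))
  complete <- vapply(split(meta$condition, meta$subject),
                     function(cc) setequal(cc, all_conditions), logical(1))
  excluded <- unique(c(meta$subject[!meta$qualifies],
                       names(complete)[!complete]))
  keep <- meta[!meta$subject %in% excluded, ]
  out <- dplyr::bind_cols(
    tibble::tibble(object_id = paste(keep$subject, keep$condition, sep = "_")),
    dplyr::bind_rows(keep$row)
  )
  attr(out, "excluded") <- excluded
  out
}
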