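test_that("the band-pass filter preserves the pass band and rejects outside it", {
  fs <- 400
  t <- seq_len(8 * fs) / fs
  mid <- (2 * fs):(6 * fs) # steady-state section, away from edge transients
  amp <- function(x) max(abs(x[mid]))

  in_band <- sin(2 * pi * 10 * t)
  expect_lt(abs(amp(bandpass_filter(in_band, fs)) - 1), 0.05)

  out_band <- sin(2 * pi * 60 * t)
  expect_lt(amp(bandpass_filter(out_band, fs)), 0.10)

  # >= 20 dB at half the low edge and twice the high edge
  expect_lt(amp(bandpass_filter(sin(2 * pi * 0.5 * t), fs)), 0.1)
  expect_lt(amp(bandpass_filter(sin(2 * pi * 80 * t), fs)), 0.1)

  expect_equal(bandpass_filter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass_filter(in_band, fs = 60), "Sampling rate")
})

test_that("epoching yields zero-mean non-overlapping windows with inclusion rules", {
  fs <- 400
  set.seed(61)
  x <- rnorm(fs * 150)
  es <- make_epochs(x, fs)
  expect_equal(dim(es$epochs), c(150L, 400L))
  expect_lt(max(abs(rowMeans(es$epochs))), 1e-9)
  expect_true(es$qualifies)
  # epochs are the consecutive segments, de-meaned
  seg <- x[401:800]
  expect_equal(es$epochs[2, ], seg - mean(seg))

  expect_equal(make_epochs(rep(7, 2000), fs)$epochs,
               matrix(0, 5, 400), ignore_attr = TRUE)
  short <- make_epochs(rnorm(fs * 20), fs)
  expect_false(short$qualifies)
  expect_equal(nrow(make_epochs(x, fs, max_epochs = 30)$epochs), 30)
  expect_error(make_epochs(rnorm(100), fs), "shorter")

  # amplitude-threshold rejection drops the contaminated epoch
  spiky <- rnorm(fs * 10)
  spiky[900] <- 50
  es2 <- make_epochs(spiky, fs, min_epochs = 5, reject_k = 10)
  expect_equal(es2$n_rejected, 1L)
  expect_equal(nrow(es2$epochs), 9)
})

test_that("the Bartlett periodogram peaks correctly and conserves energy", {
  es <- sine_epochs(10, E = 8)
  psd <- bartlett_psd(es)
  expect_equal(psd$freq[which.max(psd$psd)], 10)
  expect_equal(diff(psd$freq)[1], 1) # fs / L resolution

  # Parseval: integrated PSD = mean squared signal
  set.seed(62)
  es_n <- make_epochs(rnorm(400 * 20), 400, min_epochs = 5)
  psd_n <- bartlett_psd(es_n)
  msq <- mean(es_n$epochs^2)
  expect_lt(abs(sum(psd_n$psd) * 1 - msq) / msq, 1e-6)

  # averaging across epochs shrinks the estimator variance roughly as 1/E
  spread <- function(E) {
    set.seed(63)
    var(bartlett_psd(make_epochs(rnorm(400 * E), 400, min_epochs = 2))$psd[2:199])
  }
  expect_lt(spread(64), spread(4) / 4)
})

test_that("band features take maxima and trapezoidal powers on stated bins", {
  flat <- tibble::tibble(freq = 0:200, psd = rep(1, 201))
  got <- band_features(flat, c(8, 13))
  expect_equal(got$max_log10, 0)

  # triangular peak of height 100 at 10 Hz on unit bins: trapezoid = 101
  tri <- tibble::tibble(freq = 0:200, psd = rep(0.001, 201))
  tri$psd[tri$freq %in% 9:11] <- c(1, 100, 1)
  got <- band_features(tri, c(8, 13), half_width = 1)
  expect_equal(got$max_log10, 2)
  expect_equal(got$power_log10, log10(101), tolerance = 1e-12)
  expect_equal(got$peak_freq, 10)

  # a peak on the 8 Hz boundary belongs to both alpha and theta
  es <- sine_epochs(8, E = 6)
  psd <- bartlett_psd(es)
  al <- band_features(psd, eeg_bands()$alpha)
  th <- band_features(psd, eeg_bands()$theta)
  expect_equal(al$max_log10, th$max_log10)
  expect_equal(al$peak_freq, 8)
  expect_equal(th$peak_freq, 8)

  expect_error(band_features(flat, c(300, 310)), "inside band")
})

test_that("time-domain statistics match closed forms on sinusoid epochs", {
  es <- sine_epochs(10, E = 5)
  tf <- time_features(es)
  expect_equal(tf$rms, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(tf$mm, 2, tolerance = 1e-4)
  expect_lt(abs(tf$skewness), 1e-6)
  # zero-mean epochs tie RMS and SD through sqrt((L-1)/L)
  L <- ncol(es$epochs)
  expect_equal(tf$rms, tf$sd * sqrt((L - 1) / L), tolerance = 1e-10)

  set.seed(64)
  es_n <- make_epochs(rnorm(400 * 12), 400, min_epochs = 5)
  tf_n <- time_features(es_n)
  per_epoch_rms <- apply(es_n$epochs, 1, function(e) sqrt(mean(e^2)))
  expect_equal(tf_n$rms, median(per_epoch_rms), tolerance = 1e-12)
  expect_equal(tf_n$mm, median(apply(es_n$epochs, 1, max) - apply(es_n$epochs, 1, min)))
})

test_that("feature-matrix assembly pairs subjects and drops incomplete ones", {
  sig <- synth_eeg_study(n_subjects = 5, duration_s = 12, seed = 65)
  fm <- build_feature_matrix(sig, fs = 400, max_epochs = 10, min_epochs = 8)
  expect_equal(nrow(fm), 10)
  expect_named(fm, c("object_id", "alpha_power", "beta_power", "theta_power",
                     "alpha_max", "beta_max", "theta_max", "rms", "sd",
                     "skewness", "mm"))
  expect_equal(cor(fm$rms, fm$sd, method = "spearman"), 1)

  # a subject missing one condition is dropped entirely
  sig2 <- sig[!(sig$subject == "S03" & sig$condition == "B"), ]
  fm2 <- build_feature_matrix(sig2, fs = 400, max_epochs = 10, min_epochs = 8)
  expect_equal(nrow(fm2), 8)
  expect_false(any(grepl("S03", fm2$object_id)))
  # a subject with too few clean epochs is excluded the same way
  sig3 <- sig[!(sig$subject == "S02" & sig$condition == "A" &
                  seq_len(nrow(sig)) %in% which(sig$subject == "S02")[1:3000]), ]
  fm3 <- build_feature_matrix(sig3, fs = 400, max_epochs = 10, min_epochs = 8)
  expect_true("S02" %in% attr(fm3, "excluded"))
  expect_equal(nrow(fm3), 8)
})

test_that("synthetic study features separate conditions and correlate positively", {
  sig <- synth_eeg_study(n_subjects = 24, duration_s = 40, seed = 66)
  fm <- build_feature_matrix(sig, fs = 400, max_epochs = 35, min_epochs = 30)
  expect_equal(nrow(fm), 48)

  cond <- sub(".*_", "", fm$object_id)
  a <- fm$alpha_power[cond == "A"]
  b <- fm$alpha_power[cond == "B"]
  expect_lt(stats::wilcox.test(a, b, alternative = "greater", paired = TRUE)$p.value,
            0.01) # eyes-closed alpha dominates

  rho <- cor(as.matrix(fm[-1]), method = "spearman")
  expect_true(all(rho[upper.tri(rho)] > 0))
  expect_equal(rho["rms", "sd"], 1)
})
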