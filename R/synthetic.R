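#' Synthetic feature matrix with a planted factor structure
#'
#' Generates an objects-by-variables table shaped like a paired two-condition
#' EEG feature matrix (default 24 subjects x 2 conditions = 48 rows, 10
#' columns in the order `alpha_power`, `beta_power`, `theta_power`,
#' `alpha_max`, `beta_max`, `theta_max`, `rms`, `sd`, `skewness`, `mm`).
#' All variables load on one common latent factor, producing the strongly
#' positive inter-correlation typical of EEG spectral/time-domain features,
#' and two column pairs are exact duplicates (`alpha_max` copies
#' `alpha_power`, `sd` copies `rms`), mirroring the redundant
#' power/peak and RMS/SD pairs of real feature sets (Spearman rho exactly
#' 1). The common-factor loading is calibrated (on the population
#' correlation matrix, duplicates included) so the leading eigenvalue is
#' `lambda1_fraction * p`.
#'
#' A second, orthogonal factor with loading `+beta_theta_contrast` on the
#' beta columns and `-beta_theta_contrast` on the theta columns plants a
#' beta-versus-theta contrast — the canonical shape of a second principal
#' component in such data — turning the design into a two-factor one.
#'
#' Each subject draws from its own seed substream (`seed + 104729 * i`), so
#' adding subjects never changes existing rows.
#'
#' @param n_subjects Number of subjects (rows = `n_subjects * length(conditions)`).
#' @param conditions Condition labels, one row per subject per condition.
#' @param lambda1_fraction Target leading-eigenvalue fraction of the
#'   population correlation matrix, in (0, 1).
#' @param beta_theta_contrast Raw loading of the second factor (0 = one
#'   factor only).
#' @param seed Integer seed.
#' @return A feature-matrix tibble (`object_id` first), attribute
#'   `true_n_factors` (1 or 2).
#' @export
synth_feature_matrix <- function(n_subjects = 24, conditions = c("A", "B"),
                                 lambda1_fraction = 0.84,
                                 beta_theta_contrast = 0, seed = 1) {
  vars <- c("alpha_power", "beta_power", "theta_power", "alpha_max",
            "beta_max", "theta_max", "rms", "sd", "skewness", "mm")
  dup_of <- c(alpha_max = "alpha_power", sd = "rms")
  free <- setdiff(vars, names(dup_of))
  p <- length(vars)
  rho <- calibrate_equicorrelation(lambda1_fraction, vars, dup_of)
  w <- sqrt(rho / (1 - rho)) # factor loading giving corr rho at unit noise
  contrast <- setNames(numeric(length(free)), free)
  contrast[c("beta_power", "beta_max")] <- beta_theta_contrast
  contrast[c("theta_power", "theta_max")] <- -beta_theta_contrast
  rows <- purrr::map(seq_len(n_subjects), function(i) {
    with_seed((seed + 104729 * i) %% .Machine$integer.max, {
      purrr::map(conditions, function(cond) {
        f1 <- rnorm(1)
        f2 <- rnorm(1)
        e <- rnorm(length(free))
        x <- setNames(w * f1 + contrast * f2 + e, free)
        row <- c(x, setNames(x[dup_of], names(dup_of)))[vars]
        tibble::tibble(object_id = sprintf("S%02d_%s", i, cond),
                       !!!as.list(row))
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "true_n_factors") <- if (beta_theta_contrast != 0) 2L else 1L
  out
}

# solve for the common correlation rho whose population correlation matrix
# (with exact-duplicate pairs at 1) has leading eigenvalue frac * p
calibrate_equicorrelation <- function(frac, vars, dup_of) {
  p <- length(vars)
  lead_eig <- function(rho) {
    cm <- matrix(rho, p, p, dimnames = list(vars, vars))
    diag(cm) <- 1
    for (d in names(dup_of)) {
      cm[d, dup_of[d]] <- 1
      cm[dup_of[d], d] <- 1
    }
    max(eigen(cm, symmetric = TRUE, only.values = TRUE)$values)
  }
  lo_frac <- lead_eig(1e-6) / p
  if (length(frac) != 1 || frac <= lo_frac || frac >= 1) {
    abort(sprintf("`lambda1_fraction` must lie in (%.3f, 1) for this structure.", lo_frac))
  }
  uniroot(function(r) lead_eig(r) - frac * p, c(1e-6, 1 - 1e-9), tol = 1e-10)$root
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic single-channel EEG series
#'
#' A minimal surrogate for occipital resting EEG: 1/f-shaped background
#' noise plus an alpha-band oscillation whose amplitude depends on the
#' condition (larger with eyes closed — the alpha-blocking contrast), all
#' scaled by a per-subject gain. A mild gain-dependent quadratic asymmetry
#' (`x + skew_coef * gain * x^2 / sd(x)`) gives the signal a positive
#' skewness that grows with the overall amplitude, so all ten downstream
#' feature columns — including the scale-invariant skewness — share the
#' subject-gain factor and correlate positively across subjects. This is
#' statistical plumbing, not physiological modelling.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param alpha_amp Alpha oscillation amplitude (micro-V) before gain.
#' @param alpha_freq Alpha peak frequency (Hz).
#' @param gain Per-subject multiplicative gain.
#' @param bg_sd Background-noise SD (micro-V) before gain.
#' @param skew_coef Asymmetry strength (0 disables).
#' @param seed Integer seed.
#' @return Numeric series of `duration_s * fs` samples (micro-V scale).
#' @export
synth_eeg <- function(duration_s, fs = 400, alpha_amp = 15, alpha_freq = 10,
                      gain = 1, bg_sd = 10, skew_coef = 0.05, seed = 1) {
  if (duration_s <= 0 || fs <= 0) abort("`duration_s` and `fs` must be positive.")
  n <- round(duration_s * fs)
  with_seed(seed, {
    # 1/f background: shape white noise in the frequency domain
    wn <- rnorm(n)
    fr <- fft(wn)
    f <- c(seq(0, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1), -1)) * fs / n
    shape <- 1 / sqrt(pmax(abs(f), 1))
    bg <- Re(fft(fr * shape, inverse = TRUE)) / n
    bg <- bg / sd(bg) * bg_sd
    t <- seq_len(n) / fs
    osc <- alpha_amp * sin(2 * pi * alpha_freq * t + runif(1, 0, 2 * pi))
    x <- gain * (bg + osc)
    if (skew_coef > 0) x <- x + skew_coef * gain * x^2 / sd(x)
    x
  })
}

#' Synthetic multi-subject EEG study
#'
#' Draws per-subject parameters (gain, alpha peak frequency in 8-13 Hz with
#' probability `p_boundary` of sitting exactly on the 8 Hz alpha/theta
#' boundary) and simulates one recording per subject per condition, with
#' the alpha amplitude attenuated in the eyes-open condition.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Condition labels; the first is treated as eyes-closed.
#' @param duration_s Recording length per condition (s); 160 s gives a
#'   margin over the 150 one-second epochs used downstream.
#' @param fs Sampling rate (Hz).
#' @param alpha_closed,alpha_open Alpha amplitudes (micro-V) by condition.
#' @param p_boundary Probability of an exactly-8-Hz peak.
#' @param gain_sdlog Log-SD of the lognormal subject gain.
#' @param skew_coef See [synth_eeg()].
#' @param seed Integer seed.
#' @return Long tibble `subject`, `condition`, `value` (samples in order),
#'   with per-subject parameters in attribute `subjects`.
#' @export
synth_eeg_study <- function(n_subjects = 24, conditions = c("A", "B"),
                            duration_s = 160, fs = 400, alpha_closed = 15,
                            alpha_open = 5, p_boundary = 0.1,
                            gain_sdlog = 0.35, skew_coef = 0.05, seed = 1) {
  subjects <- purrr::map(seq_len(n_subjects), function(i) {
    with_seed((seed + 7919 * i) %% .Machine$integer.max, {
      tibble::tibble(
        subject = sprintf("S%02d", i),
        gain = exp(rnorm(1, 0, gain_sdlog)),
        alpha_freq = if (runif(1) < p_boundary) 8 else runif(1, 8, 13)
      )
    })
  })
  subjects <- dplyr::bind_rows(subjects)
  out <- purrr::map(seq_len(n_subjects), function(i) {
    purrr::map(seq_along(conditions), function(k) {
      amp <- if (k == 1) alpha_closed else alpha_open
      x <- synth_eeg(
        duration_s = duration_s, fs = fs, alpha_amp = amp,
        alpha_freq = subjects$alpha_freq[i], gain = subjects$gain[i],
        skew_coef = skew_coef,
        seed = (seed + 7919 * i + 31 * k) %% .Machine$integer.max
      )
      tibble::tibble(subject = subjects$subject[i],
                     condition = conditions[k], value = x)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  attr(out, "subjects") <- subjects
  out
}
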