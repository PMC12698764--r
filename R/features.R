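# Per-window feature extraction. The default registry holds exactly 56
# features per channel: 8 time-domain statistics, 8 band powers (4 absolute
# + 4 relative over the delta/theta/alpha/beta bands), 10 entropy features
# (5 families x 2 parameterizations), and 30 wavelet-subband statistics
# (6 statistics x 5 subbands of a 4-level DWT).

.eeg_bands <- list(delta = c(1, 4), theta = c(4, 8),
                   alpha = c(8, 12), beta = c(12, 20))

#' Time-domain features of one window
#'
#' Line length `sum(|x[i+1]-x[i]|)`, mean amplitude `mean(|x|)`, mean,
#' population variance, standard deviation, and the Hjorth parameters:
#' activity (= variance), mobility `sqrt(var(diff x)/var(x))`, and
#' complexity (mobility of the first difference over mobility of the
#' signal). A constant segment yields zero mobility/complexity with a
#' `degenerate` attribute set.
#'
#' @param segment Numeric vector of at least 3 samples.
#' @return Named numeric vector of the 8 features.
#' @export
time_domain <- function(segment) {
  assert_that(length(segment) >= 3, "segment must have >= 3 samples")
  n <- length(segment)
  mu <- mean(segment)
  v <- mean((segment - mu)^2)
  dx <- diff(segment)
  ddx <- diff(dx)
  vd <- mean((dx - mean(dx))^2)
  vdd <- mean((ddx - mean(ddx))^2)
  degenerate <- v <= 0
  mob <- if (degenerate) 0 else sqrt(vd / v)
  mob_d <- if (vd <= 0) 0 else sqrt(vdd / vd)
  cmp <- if (degenerate || mob == 0) 0 else mob_d / mob
  out <- c(line_length = sum(abs(dx)), mean_amplitude = mean(abs(segment)),
           mean = mu, variance = v, std = sqrt(v), hjorth_activity = v,
           hjorth_mobility = mob, hjorth_complexity = cmp)
  attr(out, "degenerate") <- degenerate
  out
}

#' Absolute and relative EEG band powers of one window
#'
#' Powers are integrated from a Welch estimate (1 s epochs, Hann taper)
#' over `[lo, hi)` Hz bins. Relative powers are normalized by the summed
#' power over the defined bands, so they sum to one; for an all-zero
#' segment they are returned as `NaN` (undefined) with a `zero_power`
#' attribute.
#'
#' @param segment Numeric vector covering at least one second.
#' @param fs Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @return Named vector `bp_<band>` (absolute, unit^2) and `rbp_<band>`
#'   (relative).
#' @export
band_powers <- function(segment, fs, bands = .eeg_bands) {
  assert_that(length(segment) >= fs, "segment must cover at least 1 s")
  hi_max <- max(vapply(bands, `[`, 0, 2))
  if (hi_max > fs / 2) {
    stop_validation("band edge ", hi_max, " Hz above Nyquist ", fs / 2, " Hz")
  }
  psd <- welch_psd(segment, fs, epoch_s = min(1, length(segment) / fs))
  absolute <- vapply(bands, function(b) band_power_from_psd(psd, b[1], b[2]), 0)
  names(absolute) <- paste0("bp_", names(bands))
  total <- sum(absolute)
  relative <- absolute / total
  names(relative) <- paste0("rbp_", names(bands))
  out <- c(absolute, relative)
  attr(out, "zero_power") <- total <= 0
  out
}

entropy_from_probs <- function(p, kind = c("shannon", "tsallis", "renyi"),
                               q = 2) {
  kind <- match.arg(kind)
  p <- p[p > 0]
  if (kind == "shannon" || abs(q - 1) < 1e-12) return(-sum(p * log(p)))
  if (kind == "tsallis") (1 - sum(p^q)) / (q - 1) else log(sum(p^q)) / (1 - q)
}

hist_probs <- function(segment, bins) {
  mu <- mean(segment); s <- stats::sd(segment)
  if (!is.finite(s) || s == 0) {
    p <- numeric(bins); p[1] <- 1
    return(p)
  }
  lo <- mu - 3 * s
  idx <- floor((segment - lo) / (6 * s / bins)) + 1
  idx <- pmin(pmax(idx, 1L), bins)
  tabulate(idx, bins) / length(segment)
}

sampen_counts <- function(segment, m, r) {
  n <- length(segment)
  D <- abs(outer(segment, segment, `-`))
  cheb <- D
  for (k in seq_len(m)) {
    nn <- nrow(cheb)
    cheb <- pmax(cheb[-nn, -nn, drop = FALSE], D[(k + 1):n, (k + 1):n])
    if (k == m - 1) b_mat <- cheb
  }
  if (m == 1) b_mat <- D
  # both counts use the same N - m template set (standard convention)
  nt <- n - m
  b_mat <- b_mat[seq_len(nt), seq_len(nt), drop = FALSE]
  pairs <- function(M) (sum(M < r) - nrow(M)) / 2
  list(B = pairs(b_mat), A = pairs(cheb))
}

#' Sample entropy of one window
#'
#' `-log(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev tolerance `r` and `A` the pairs still matching at length
#' `m + 1` (self-matches excluded). Zero matches yield `Inf` with a
#' `no_matches` attribute.
#'
#' @param segment Numeric vector.
#' @param m Template length (default 2).
#' @param r Tolerance; default `0.2 * sd(segment)`.
#' @return Sample entropy (nats).
#' @export
sample_entropy <- function(segment, m = 2, r = 0.2 * stats::sd(segment)) {
  cnt <- sampen_counts(segment, m, r)
  if (cnt$A == 0 || cnt$B == 0) {
    return(structure(Inf, no_matches = TRUE))
  }
  -log(cnt$A / cnt$B)
}

perm_codes <- function(segment, order, delay = 1) {
  n <- length(segment) - (order - 1) * delay
  assert_that(n >= 1, "segment too short for permutation order ", order)
  code <- numeric(n)
  w <- rev(cumprod(c(1, seq_len(order - 1))))    # Lehmer weights (o-1)!, ...
  for (i in seq_len(order - 1)) {
    xi <- segment[seq_len(n) + (i - 1) * delay]
    ci <- numeric(n)
    for (j in (i + 1):order) {
      xj <- segment[seq_len(n) + (j - 1) * delay]
      ci <- ci + (xj < xi)
    }
    code <- code + ci * w[i]
  }
  code
}

#' Permutation entropy of one window
#'
#' Shannon entropy of the ordinal patterns of `order` consecutive samples
#' (spacing `delay`), normalized by `log(order!)` to `[0, 1]`. A strictly
#' monotone segment has a single pattern and entropy 0.
#'
#' @param segment Numeric vector.
#' @param order Pattern length (default 3).
#' @param delay Sample spacing (default 1).
#' @return Normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(segment, order = 3, delay = 1) {
  code <- perm_codes(segment, order, delay)
  p <- tabulate(code + 1, factorial(order)) / length(code)
  entropy_from_probs(p) / log(factorial(order))
}

#' The five entropy families of one window
#'
#' Histogram entropies (Shannon, Tsallis, Renyi) use `bins` amplitude bins
#' spanning mean +/- 3 sd; `q = 1` (or `alpha = 1`) returns the Shannon
#' limit. Sample entropy uses Chebyshev tolerance `r_factor * sd`;
#' permutation entropy is normalized to `[0, 1]`.
#'
#' @param segment Numeric vector.
#' @param bins Histogram bins (default 10).
#' @param q Tsallis order (default 2).
#' @param alpha Renyi order (default 2).
#' @param m Sample-entropy template length (default 2).
#' @param r_factor Sample-entropy tolerance as a multiple of sd.
#' @param order,delay Permutation-entropy parameters.
#' @return Named vector `(shannon, tsallis, renyi, sample_entropy,
#'   permutation_entropy)`; sample entropy may be `Inf` (no matches).
#' @export
entropies <- function(segment, bins = 10, q = 2, alpha = 2, m = 2,
                      r_factor = 0.2, order = 3, delay = 1) {
  p <- hist_probs(segment, bins)
  c(shannon = entropy_from_probs(p),
    tsallis = entropy_from_probs(p, "tsallis", q),
    renyi = entropy_from_probs(p, "renyi", alpha),
    sample_entropy = as.numeric(sample_entropy(segment, m,
                                               r_factor * stats::sd(segment))),
    permutation_entropy = permutation_entropy(segment, order, delay))
}

#' The default 56-entry feature registry
#'
#' Ordered names and family tags of the per-channel feature set: 8
#' time-domain, 8 band-power, 10 entropy (two parameterizations of each of
#' the five families), and 30 DWT-subband statistics (mean, std, RMS, mean
#' amplitude, line length, peak amplitude over `d1..d4, a4`). The manifest
#' (names + parameters) travels with every feature matrix so the
#' composition is auditable.
#'
#' @return Data frame of class `feature_registry` with columns `name`,
#'   `family`; parameters are stored in the `params` attribute.
#' @export
feature_registry <- function() {
  td <- c("line_length", "mean_amplitude", "mean", "variance", "std",
          "hjorth_activity", "hjorth_mobility", "hjorth_complexity")
  bp <- c(paste0("bp_", names(.eeg_bands)), paste0("rbp_", names(.eeg_bands)))
  ent <- c("shannon_b10", "shannon_b20", "tsallis_q2", "tsallis_q3",
           "renyi_a2", "renyi_a3", "sampen_m2", "sampen_m3",
           "permen_o3", "permen_o5")
  sub <- c(paste0("d", 1:4), "a4")
  stat <- c("mean", "std", "rms", "mean_amp", "line_length", "max_abs")
  dw <- as.vector(t(outer(sub, stat, paste, sep = "_")))
  dw <- paste0("dwt_", dw)
  reg <- data.frame(
    name = c(td, bp, ent, dw),
    family = c(rep("time_domain", 8), rep("band_power", 8),
               rep("entropy", 10), rep("dwt", 30)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(reg) == 56, !anyDuplicated(reg$name))
  attr(reg, "params") <- list(bands = .eeg_bands, hist_bins = c(10, 20),
                              tsallis_q = c(2, 3), renyi_alpha = c(2, 3),
                              sampen = list(m = c(2, 3), r_factor = 0.2),
                              permen = list(order = c(3, 5), delay = 1),
                              dwt = list(wavelet = "db4", levels = 4))
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

# ---- vectorized per-channel extraction over a samples-x-windows matrix ----

col_pop_var <- function(x) colMeans(x^2) - colMeans(x)^2

features_time_domain_mat <- function(seg) {
  mu <- colMeans(seg)
  v <- pmax(col_pop_var(seg), 0)
  dx <- diff(seg)
  vd <- pmax(col_pop_var(dx), 0)
  vdd <- pmax(col_pop_var(diff(dx)), 0)
  mob <- ifelse(v > 0, sqrt(vd / v), 0)
  mob_d <- ifelse(vd > 0, sqrt(vdd / vd), 0)
  cmp <- ifelse(mob > 0, mob_d / mob, 0)
  cbind(line_length = colSums(abs(dx)), mean_amplitude = colMeans(abs(seg)),
        mean = mu, variance = v, std = sqrt(v), hjorth_activity = v,
        hjorth_mobility = mob, hjorth_complexity = cmp)
}

# Welch PSD for every window at once: epochs of epoch_s with 50 % overlap.
welch_psd_mat <- function(seg, fs, epoch_s = 1) {
  n <- nrow(seg)
  nseg <- round(epoch_s * fs)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(w^2)
  nfreq <- nseg %/% 2 + 1
  acc <- matrix(0, nfreq, ncol(seg))
  for (s in starts) {
    ep <- seg[s:(s + nseg - 1), , drop = FALSE]
    ep <- sweep(ep, 2, colMeans(ep)) * w
    X <- stats::mvfft(ep)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  interior <- 2:(nfreq - if (nseg %% 2 == 0) 1 else 0)
  psd[interior, ] <- 2 * psd[interior, , drop = FALSE]
  list(freq = seq(0, nfreq - 1) * fs / nseg, psd = psd)
}

features_band_power_mat <- function(seg, fs, bands = .eeg_bands) {
  p <- welch_psd_mat(seg, fs, epoch_s = min(1, nrow(seg) / fs))
  df <- p$freq[2] - p$freq[1]
  absolute <- vapply(bands, function(b) {
    colSums(p$psd[p$freq >= b[1] & p$freq < b[2], , drop = FALSE]) * df
  }, numeric(ncol(seg)))
  if (is.null(dim(absolute))) absolute <- matrix(absolute, nrow = 1)
  total <- rowSums(absolute)
  relative <- absolute / total
  out <- cbind(absolute, relative)
  colnames(out) <- c(paste0("bp_", names(bands)), paste0("rbp_", names(bands)))
  out
}

hist_prob_mat <- function(seg, bins) {
  mu <- colMeans(seg)
  s <- sqrt(pmax(col_pop_var(seg), 0)) * sqrt(nrow(seg) / (nrow(seg) - 1))
  s[s == 0] <- 1e-300
  idx <- floor(sweep(sweep(seg, 2, mu - 3 * s), 2, 6 * s / bins, `/`)) + 1
  idx <- pmin(pmax(idx, 1L), bins)
  vapply(seq_len(ncol(seg)), function(w) tabulate(idx[, w], bins),
         integer(bins)) / nrow(seg)
}

features_entropy_mat <- function(seg) {
  nw <- ncol(seg)
  p10 <- hist_prob_mat(seg, 10)
  p20 <- hist_prob_mat(seg, 20)
  plogp <- function(p) colSums(ifelse(p > 0, -p * log(p), 0))
  out <- matrix(0, nw, 10,
                dimnames = list(NULL, c("shannon_b10", "shannon_b20",
                                        "tsallis_q2", "tsallis_q3",
                                        "renyi_a2", "renyi_a3",
                                        "sampen_m2", "sampen_m3",
                                        "permen_o3", "permen_o5")))
  out[, "shannon_b10"] <- plogp(p10)
  out[, "shannon_b20"] <- plogp(p20)
  out[, "tsallis_q2"] <- 1 - colSums(p10^2)
  out[, "tsallis_q3"] <- (1 - colSums(p10^3)) / 2
  out[, "renyi_a2"] <- -log(colSums(p10^2))
  out[, "renyi_a3"] <- -log(colSums(p10^3)) / 2
  sds <- sqrt(pmax(col_pop_var(seg), 0)) * sqrt(nrow(seg) / (nrow(seg) - 1))
  cnt <- .sampen_counts_mat(seg, 0.2 * sds)
  safe_sampen <- function(a, b) {
    # cap at log(B+1) when no (m+1)-matches survive, keeping values finite
    ifelse(a > 0 & b > 0, -log(a / b), log(b + 1))
  }
  out[, "sampen_m2"] <- safe_sampen(cnt[2, ], cnt[1, ])
  out[, "sampen_m3"] <- safe_sampen(cnt[4, ], cnt[3, ])
  out[, "permen_o3"] <- .permen_mat(seg, 3L, 1L)
  out[, "permen_o5"] <- .permen_mat(seg, 5L, 1L)
  out
}

features_dwt_mat <- function(seg, wavelet = "db4", levels = 4) {
  # periodized DWT needs a multiple of 2^levels; drop trailing samples of
  # each window when the rate does not divide (a < 2^levels/fs s loss)
  keep <- (nrow(seg) %/% 2^levels) * 2^levels
  if (keep < nrow(seg)) seg <- seg[seq_len(keep), , drop = FALSE]
  pyr <- dwt_enhance(seg, wavelet, levels)
  bandnames <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  cols <- lapply(bandnames, function(b) {
    cf <- pyr[[b]]
    cbind(mean = colMeans(cf),
          std = sqrt(pmax(col_pop_var(cf), 0)),
          rms = sqrt(colMeans(cf^2)),
          mean_amp = colMeans(abs(cf)),
          line_length = colSums(abs(diff(cf))),
          max_abs = apply(abs(cf), 2, max))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(bandnames, function(b) {
    paste0("dwt_", b, "_", c("mean", "std", "rms", "mean_amp",
                             "line_length", "max_abs"))
  }, character(6)))
  out
}

#' Extract the feature matrix of a windowed recording
#'
#' Computes every registry feature for every channel of every unmasked
#' window. Columns are named `<channel>.<feature>` in registry order, so a
#' two-channel recording under the default registry yields 112 columns.
#' Windows with non-finite feature values are repaired to 0 and flagged.
#'
#' @param windows An [make_windows()] result.
#' @param registry A [feature_registry()] (default).
#' @param mask Optional logical vector (`TRUE` = drop the window), e.g.
#'   from [reject_artifacts()].
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `window_times` (start seconds of retained windows), `win_s`,
#'   `kept_idx` (indices into the original window sequence),
#'   `channel_labels`, `registry`, and `flagged` (windows with repaired
#'   values).
#' @export
extract_features <- function(windows, registry = feature_registry(),
                             mask = NULL) {
  assert_that(inherits(windows, "eeg_windows"), "windows must be eeg_windows")
  nw <- length(windows$starts)
  assert_that(nw >= 1, "no windows to extract features from")
  keep <- if (is.null(mask)) rep(TRUE, nw) else !mask
  params <- attr(registry, "params")
  blocks <- lapply(windows$channel_labels, function(ch) {
    seg <- windows$segments[[ch]][, keep, drop = FALSE] * 1e6  # work in uV
    out <- cbind(features_time_domain_mat(seg),
                 features_band_power_mat(seg, windows$fs, params$bands),
                 features_entropy_mat(seg),
                 features_dwt_mat(seg, params$dwt$wavelet, params$dwt$levels))
    out <- out[, registry$name, drop = FALSE]
    colnames(out) <- paste0(ch, ".", registry$name)
    out
  })
  x <- do.call(cbind, blocks)
  flagged <- which(rowSums(!is.finite(x)) > 0)
  x[!is.finite(x)] <- 0
  structure(x, window_times = windows$starts[keep], win_s = windows$win_s,
            kept_idx = which(keep), channel_labels = windows$channel_labels,
            registry = registry, flagged = flagged,
            class = c("feature_matrix", class(x)))
}

#' Feature-manifest of a feature matrix
#'
#' @param fm A [extract_features()] result.
#' @return List with the registry names, families, and parameters.
#' @export
feature_manifest <- function(fm) {
  reg <- attr(fm, "registry")
  list(features = reg$name, families = reg$family,
       params = attr(reg, "params"),
       channels = attr(fm, "channel_labels"))
}

#' Write a feature matrix as CSV with a JSON manifest sidecar
#'
#' @param fm A [extract_features()] result.
#' @param path CSV output path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(window_time = attr(fm, "window_times"),
                   unclass(fm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(feature_manifest(fm),
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
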