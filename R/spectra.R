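#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-half-bandwidth
#' product `nw`, as the leading eigenvectors of the standard symmetric
#' tridiagonal matrix whose eigenvectors approximate the Slepian sequences.
#' Tapers are unit-energy (`sum(h^2) = 1`), ordered by decreasing
#' eigenvalue. Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product `T * W` (s x Hz).
#' @param k number of tapers.
#' @return `[n x k]` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  cached <- dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (k < 1 || nw <= 0 || n < 2) stop("invalid taper request", call. = FALSE)
  w <- nw / n
  i <- seq_len(n) - 1
  m <- matrix(0, n, n)
  diag(m) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1)) * (n - seq_len(n - 1)) / 2
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eg <- eigen(m, symmetric = TRUE)
  h <- eg$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: even-order tapers positive mean, odd-order positive
  # initial slope (irrelevant for PSDs, fixed for reproducibility)
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (abs(s) < 1e-8) s <- h[2, j] - h[1, j]
    if (s < 0) h[, j] <- -h[, j]
  }
  dpss_cache[[key]] <- h
  h
}

dpss_cache <- new.env(parent = emptyenv())

#' SVD dimensionality reduction of an ROI channel matrix
#'
#' Reduces `n_channels` vertex time series to the smallest number `k` of
#' orthogonal components whose squared singular values account for at least
#' `variance_fraction` of the total variance (default 95%). Components are
#' the left-singular-vector projections, ordered by decreasing singular
#' value.
#'
#' @param channels `[n_channels x n_samples]` matrix.
#' @param variance_fraction proportion of variance to retain, in (0, 1].
#' @return `[k x n_samples]` matrix with attribute `variance_retained`.
#' @export
svd_reduce <- function(channels, variance_fraction = 0.95) {
  channels <- as.matrix(channels)
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  if (all(channels == 0)) stop("all-zero channel matrix", call. = FALSE)
  cc <- tcrossprod(channels)               # channels x channels
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_fraction - 1e-12)[1]
  comps <- t(eg$vectors[, seq_len(k), drop = FALSE]) %*% channels
  attr(comps, "variance_retained") <- frac[k]
  comps
}

#' Segment component time series into fixed-length epochs
#'
#' Cuts each component into consecutive non-overlapping epochs of
#' `epoch_length` seconds; the trailing remainder is discarded.
#'
#' @param components `[k x n_samples]` matrix (a vector is treated as one
#'   component).
#' @param epoch_length seconds per epoch.
#' @param sampling_rate Hz.
#' @return An `epoch_set`: list with `epochs` (`[n_samples_per_epoch x
#'   (n_epochs * k)]`, epochs of component 1 first), `epoch_length`,
#'   `sampling_rate`, `n_epochs`, `n_components`.
#' @export
segment_epochs <- function(components, epoch_length, sampling_rate) {
  if (is.vector(components)) components <- matrix(components, nrow = 1)
  len <- round(epoch_length * sampling_rate)
  n <- ncol(components)
  if (n < len) stop("signal shorter than one epoch", call. = FALSE)
  n_epochs <- as.integer(n %/% len)
  k <- as.integer(nrow(components))
  segs <- lapply(seq_len(k), function(ki) {
    matrix(components[ki, seq_len(n_epochs * len)], nrow = len)
  })
  structure(list(epochs = do.call(cbind, segs), epoch_length = epoch_length,
                 sampling_rate = sampling_rate, n_epochs = n_epochs,
                 n_components = k),
            class = "epoch_set")
}

#' Multitaper power spectral density of one epoch
#'
#' Averages `K = max(1, floor(2 * T * W - 1))` Slepian-tapered periodograms
#' (T = epoch length in s, W = `smoothing` half-bandwidth in Hz; the default
#' 2-s epochs with 2 Hz smoothing give 7 tapers and 0.5 Hz resolution). The
#' epoch mean is removed first. One-sided scaling: the integral of the PSD
#' over frequency approximates the signal variance.
#'
#' @param epoch numeric vector.
#' @param sampling_rate Hz.
#' @param smoothing spectral smoothing half-bandwidth W in Hz.
#' @return Tibble (`frequency`, `power`) with attributes `n_tapers`,
#'   `smoothing`.
#' @export
multitaper_psd <- function(epoch, sampling_rate, smoothing = 2) {
  p <- multitaper_psd_matrix(matrix(epoch, ncol = 1), sampling_rate,
                             smoothing)
  out <- tibble::tibble(frequency = attr(p, "frequency"), power = p[, 1])
  attr(out, "n_tapers") <- attr(p, "n_tapers")
  attr(out, "smoothing") <- smoothing
  out
}

# PSDs of many equal-length epochs at once: epochs in columns
multitaper_psd_matrix <- function(epochs, sampling_rate, smoothing = 2) {
  n <- nrow(epochs)
  t_len <- n / sampling_rate
  nw <- t_len * smoothing
  if (nw < 1) {
    stop("smoothing half-bandwidth times epoch length must be >= 1",
         call. = FALSE)
  }
  k <- max(1, floor(2 * nw - 1))
  h <- dpss_tapers(n, nw, k)
  epochs <- sweep(epochs, 2, colMeans(epochs))
  n_keep <- floor(n / 2) + 1
  acc <- matrix(0, n_keep, ncol(epochs))
  for (j in seq_len(k)) {
    x <- stats::mvfft(epochs * h[, j])
    acc <- acc + Mod(x[seq_len(n_keep), , drop = FALSE])^2
  }
  p <- acc / k * (2 / sampling_rate)
  p[1, ] <- p[1, ] / 2                      # DC not doubled
  if (n %% 2 == 0) p[n_keep, ] <- p[n_keep, ] / 2  # Nyquist not doubled
  attr(p, "frequency") <- (seq_len(n_keep) - 1) * sampling_rate / n
  attr(p, "n_tapers") <- k
  p
}

#' Robust pooled ROI spectrum
#'
#' Computes the multitaper PSD of every epoch of every retained component,
#' pools them, and takes the per-frequency-bin trimmed mean (default 10%
#' from each tail) — a robust single spectrum per ROI that resists
#' occasional artefactual epochs.
#'
#' @param epoch_set an [segment_epochs()] result.
#' @param smoothing multitaper half-bandwidth, Hz.
#' @param trim_proportion proportion trimmed from each tail, in \[0, 0.5).
#' @return Tibble (`frequency`, `power`) of class `roi_spectrum` with
#'   attributes `n_pooled`, `n_components`, `n_epochs`, `n_tapers`.
#' @export
pooled_roi_spectrum <- function(epoch_set, smoothing = 2,
                                trim_proportion = 0.1) {
  stopifnot(trim_proportion >= 0, trim_proportion < 0.5)
  if (ncol(epoch_set$epochs) < 1) stop("empty epoch pool", call. = FALSE)
  p <- multitaper_psd_matrix(epoch_set$epochs, epoch_set$sampling_rate,
                             smoothing)
  pooled <- apply(p, 1, mean, trim = trim_proportion)
  out <- tibble::tibble(frequency = attr(p, "frequency"), power = pooled)
  class(out) <- c("roi_spectrum", class(out))
  attr(out, "n_pooled") <- ncol(p)
  attr(out, "n_components") <- epoch_set$n_components
  attr(out, "n_epochs") <- epoch_set$n_epochs
  attr(out, "n_tapers") <- attr(p, "n_tapers")
  out
}

#' ROI spectra for one participant recording
#'
#' Full spectral chain for every ROI of a recording: SVD reduction to the
#' components carrying `variance_fraction` of the variance, segmentation
#' into epochs, multitaper PSD per epoch and component, and per-bin
#' trimmed-mean pooling.
#'
#' @param recording a `participant_recording` (see
#'   [simulate_roi_timeseries()]) or any list with fields `participant`,
#'   `sampling_rate`, `hemisphere_of_roi`, `rois`.
#' @param variance_fraction SVD variance retention threshold.
#' @param epoch_length seconds.
#' @param smoothing multitaper half-bandwidth, Hz.
#' @param trim_proportion trimmed-mean proportion per tail.
#' @return Tibble (`participant`, `hemisphere`, `roi_id`, `frequency`,
#'   `power`, `n_components`, `n_epochs`).
#' @export
roi_spectra <- function(recording, variance_fraction = 0.95,
                        epoch_length = 2, smoothing = 2,
                        trim_proportion = 0.1) {
  purrr::map_dfr(names(recording$rois), function(roi) {
    comps <- svd_reduce(recording$rois[[roi]], variance_fraction)
    es <- segment_epochs(comps, epoch_length, recording$sampling_rate)
    sp <- pooled_roi_spectrum(es, smoothing, trim_proportion)
    tibble::tibble(participant = recording$participant,
                   hemisphere = unname(recording$hemisphere_of_roi[roi]),
                   roi_id = roi,
                   frequency = sp$frequency, power = sp$power,
                   n_components = nrow(comps), n_epochs = es$n_epochs)
  })
}
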