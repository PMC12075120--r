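#' Population firing-rate trace
#'
#' Mean per-neuron firing rate of one cell group on a uniform time grid:
#' `rate(t)` is the spike count of the group in the sliding window
#' `[t - window/2, t + window/2)` divided by `window * group size`, in Hz.
#' At the edges of the recording the window is truncated and the
#' normalization shortened accordingly.
#'
#' @param spikes a spike record: data.frame with columns `neuron` (integer id)
#'   and `time` (ms).
#' @param spec the [column_spec()] of the simulated column.
#' @param group group label (e.g. `"E4"`).
#' @param window sliding window length (ms, default 200 as used for the
#'   published rate traces).
#' @param step grid step (ms, default 1).
#' @param t_range length-2 numeric, time span covered by the recording (ms).
#' @return A data.frame of class `rate_trace` with columns `time` (ms) and
#'   `rate` (Hz), plus attributes `group` and `n_neurons`.
#' @export
population_rate <- function(spikes, spec, group, window = 200, step = 1,
                            t_range) {
  stopifnot(window >= step)
  ids <- neurons_of_group(spec, group)
  st <- sort(spikes$time[spikes$neuron %in% ids])
  if (missing(t_range)) {
    t_range <- c(0, if (length(st)) max(st) else 0)
  }
  grid <- seq(t_range[1], t_range[2], by = step)
  lo <- pmax(grid - window / 2, t_range[1])
  hi <- pmin(grid + window / 2, t_range[2])
  counts <- findInterval(hi, st, left.open = TRUE) -
    findInterval(lo, st, left.open = TRUE)
  eff <- hi - lo   # truncated window length at the edges
  rate <- 1000 * counts / (eff * length(ids))   # ms -> s
  out <- data.frame(time = grid, rate = rate)
  attr(out, "group") <- group
  attr(out, "n_neurons") <- length(ids)
  class(out) <- c("rate_trace", "data.frame")
  out
}

#' Irregularity of single-unit spike trains
#'
#' Coefficient of variation of the inter-spike intervals, per unit. Units with
#' fewer than `min_spikes` spikes (default 3, i.e. fewer than two intervals)
#' are excluded and counted in the summary. A perfectly periodic train has
#' CV = 0; a Poisson train has CV -> 1.
#'
#' @inheritParams population_rate
#' @param min_spikes minimum spikes for a unit to be included.
#' @return A list with `cv` (named numeric per included unit), `mean_cv`, and
#'   `n_excluded`.
#' @export
isi_cv <- function(spikes, spec, group, min_spikes = 3) {
  ids <- neurons_of_group(spec, group)
  sel <- spikes$neuron %in% ids
  by_unit <- split(spikes$time[sel], spikes$neuron[sel])
  n_units_with_spikes <- length(by_unit)
  by_unit <- by_unit[lengths(by_unit) >= min_spikes]
  cv <- vapply(by_unit, function(t) {
    isi <- diff(sort(t))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  list(cv = cv,
       mean_cv = if (length(cv)) mean(cv) else NA_real_,
       n_excluded = length(ids) - length(cv))
}

#' Membrane-potential synchrony (Golomb chi measure)
#'
#' For a set of simultaneously sampled membrane-potential traces, computes
#' `chi = sqrt( Var_t(mean_i V_i(t)) / mean_i(Var_t V_i(t)) )`: 1 for
#' identical traces, approaching 0 (as `1/sqrt(N)`) for independent ones.
#' Invariant under a common affine rescaling of all traces.
#'
#' @param V numeric matrix, one column per neuron, rows = time samples on a
#'   common grid.
#' @return Scalar synchrony in `[0, 1]` (up to sampling noise).
#' @export
synchrony_chi <- function(V) {
  stopifnot(is.matrix(V), ncol(V) >= 2)
  var_each <- apply(V, 2, stats::var)
  if (all(var_each == 0)) {
    stop("all traces are constant; synchrony is undefined", call. = FALSE)
  }
  sqrt(stats::var(rowMeans(V)) / mean(var_each))
}

#' Welch power spectrum of a rate trace
#'
#' Power spectral density of the mean-subtracted population rate, estimated
#' by Welch's method: the signal is split into segments (default 2 s) with
#' 50% overlap, each Hann-windowed, and the one-sided periodograms are
#' averaged. The peak is reported over the 5-100 Hz band.
#'
#' @param trace a [population_rate()] result (1 ms grid), or any data.frame
#'   with `time` (ms) and `rate` columns on a uniform grid.
#' @param t_start,t_end analysis window (ms); at least 1 s long.
#' @param segment_ms Welch segment length (ms).
#' @param band frequency band (Hz) searched for the peak.
#' @return A list of class `spectrum_result`: `frequency` (Hz), `power`,
#'   `peak_frequency`, `peak_power`.
#' @export
power_spectrum <- function(trace, t_start = min(trace$time),
                           t_end = max(trace$time), segment_ms = 2000,
                           band = c(5, 100)) {
  sel <- trace$time >= t_start & trace$time <= t_end
  x <- trace$rate[sel]
  tms <- trace$time[sel]
  if (length(x) < 2) stop("analysis window contains no samples", call. = FALSE)
  dt <- diff(tms[1:2])
  fs <- 1000 / dt   # Hz
  if ((length(x) - 1) * dt < 1000) {
    stop("analysis window must be at least 1 s long", call. = FALSE)
  }
  seg <- min(round(segment_ms / dt), length(x))
  res <- welch_psd(x - mean(x), fs, seg)
  in_band <- res$frequency >= band[1] & res$frequency <= band[2]
  if (!any(in_band)) stop("no frequency bins inside the search band", call. = FALSE)
  ipk <- which(in_band)[which.max(res$power[in_band])]
  structure(list(frequency = res$frequency, power = res$power,
                 peak_frequency = res$frequency[ipk],
                 peak_power = res$power[ipk]),
            class = "spectrum_result")
}

# one-sided Welch PSD, Hann window, 50% overlap; density normalization such
# that sum(power) * df equals the signal variance (Parseval)
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / seg_len)  # Hann
  norm <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2 / norm
    # one-sided: double everything except DC (and Nyquist for even lengths)
    sp[-1] <- sp[-1] * 2
    if (seg_len %% 2 == 0) sp[nf] <- sp[nf] / 2
    acc <- acc + sp
  }
  list(frequency = (seq_len(nf) - 1) * fs / seg_len,
       power = acc / length(starts))
}

#' Activation latency of an evoked response
#'
#' Time (after stimulus onset) at which a population rate first reaches half
#' of its maximum evoked increase: latency = first crossing of
#' `baseline + 0.5 * (peak - baseline)`, with linear interpolation between
#' grid points. The baseline is the mean rate over `baseline_window` before
#' onset.
#'
#' @param trace a rate trace (`time` ms, `rate` Hz).
#' @param stim_onset stimulus onset time (ms).
#' @param baseline_window length of the pre-onset baseline window (ms).
#' @return Latency in ms, or an error if there is no evoked increase.
#' @export
activation_latency <- function(trace, stim_onset, baseline_window = 200) {
  pre <- trace$time >= stim_onset - baseline_window & trace$time < stim_onset
  post <- trace$time >= stim_onset
  if (!any(pre) || !any(post)) {
    stop("trace must span the stimulus onset with a baseline", call. = FALSE)
  }
  base <- mean(trace$rate[pre])
  rt <- trace$rate[post]
  tt <- trace$time[post]
  peak <- max(rt)
  if (peak <= base + 1e-12) {
    stop("no evoked rate increase; latency is undefined", call. = FALSE)
  }
  thr <- base + 0.5 * (peak - base)
  i <- which(rt >= thr)[1]
  if (i == 1) return(tt[1] - stim_onset)
  # linear interpolation between the straddling grid points
  t_cross <- tt[i - 1] + (thr - rt[i - 1]) / (rt[i] - rt[i - 1]) *
    (tt[i] - tt[i - 1])
  t_cross - stim_onset
}

#' Normalized cross-correlation of two rate traces
#'
#' Pearson correlation of the two (mean-subtracted) traces at integer-bin lags
#' up to `max_lag`. Positive lag means `b` follows `a`.
#'
#' @param trace_a,trace_b rate traces on a common uniform grid.
#' @param max_lag maximum lag (ms).
#' @return A list: `lag` (ms), `correlation`, `peak_lag`, `peak_correlation`
#'   (signed value of the correlation largest in magnitude).
#' @export
rate_cross_correlation <- function(trace_a, trace_b, max_lag = 100) {
  stopifnot(nrow(trace_a) == nrow(trace_b),
            all(trace_a$time == trace_b$time))
  a <- trace_a$rate - mean(trace_a$rate)
  b <- trace_b$rate - mean(trace_b$rate)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant trace; cross-correlation is undefined", call. = FALSE)
  }
  dt <- diff(trace_a$time[1:2])
  L <- floor(max_lag / dt)
  n <- length(a)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ai <- seq_len(n - l); bi <- ai + l
    } else {
      bi <- seq_len(n + l); ai <- bi - l
    }
    sum(a[ai] * b[bi]) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  ipk <- which.max(abs(cc))
  list(lag = lags * dt, correlation = cc,
       peak_lag = lags[ipk] * dt, peak_correlation = cc[ipk])
}
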