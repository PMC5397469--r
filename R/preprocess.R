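#' Field-potential extraction parameters
#'
#' @param band Two-element numeric, pass-band edges in Hz. Default `c(1, 100)`,
#'   the conventional field-potential band for slice MEA work.
#' @param target_rate Output sampling rate in Hz after decimation (default
#'   1000).
#' @param order Butterworth order of the band-pass prototype (default 4; the
#'   filter is applied forward and backward, so the effective order doubles
#'   and the phase response is zero).
#' @return A list of class `fp_params`.
#' @export
fp_params <- function(band = c(1, 100), target_rate = 1000, order = 4) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("`band` must be c(low, high) with 0 < low < high")
  if (band[2] >= target_rate / 2)
    stop("band high edge (", band[2], " Hz) violates the Nyquist limit of the ",
         "target rate (", target_rate / 2, " Hz)")
  structure(list(band = band, target_rate = target_rate, order = order),
            class = "fp_params")
}

# Butterworth band-pass as second-order sections. The polynomial
# (transfer-function) form of a 1-100 Hz band-pass is numerically unusable
# at acquisition rates like 20 kHz (poles cluster at the unit circle and the
# expanded 8th-order polynomials overflow catastrophically in any direct
# form); the zero-pole-gain design is exact, and cascaded biquads preserve
# it. Design primitives (analog prototype, band transform, bilinear) come
# from the signal package; only the conjugate-pair pairing is local.
butter_sos <- function(order, W) {
  n <- order
  T <- 2
  Wt <- 2 / T * tan(pi * W / T)
  pole <- exp(1i * pi * (2 * (1:n) + n - 1) / (2 * n))
  if (n %% 2 == 1) pole[(n + 1) / 2] <- -1
  zpg <- signal::Zpg(zero = complex(0), pole = pole, gain = 1)
  zpg <- signal::sftrans(zpg, W = Wt, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)
  p <- zpg$pole
  g <- Re(zpg$gain)
  # conjugate pole pairs -> one biquad denominator each
  cplx <- p[Im(p) > 1e-10]
  realp <- sort(Re(p[abs(Im(p)) <= 1e-10]))
  dens <- lapply(cplx, function(pk) c(1, -2 * Re(pk), Mod(pk)^2))
  angs <- abs(Arg(cplx))
  mods <- Mod(cplx)
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[length(realp)]
    realp <- realp[-c(1, length(realp))]
    dens[[length(dens) + 1L]] <- c(1, -(p1 + p2), p1 * p2)
    angs <- c(angs, abs(Arg(complex(real = (p1 + p2) / 2))))
    mods <- c(mods, sqrt(abs(p1 * p2)))
  }
  # the band-pass zeros are n at z = +1 and n at z = -1. Pair both +1 zeros
  # with the pole pairs closest to z = +1 (the lower band edge): the (z-1)^2
  # numerator cancels their near-DC response, which keeps every section's
  # intermediate gain bounded (the reason second-order sections stay
  # numerically healthy where the expanded polynomial overflows)
  nsec <- length(dens)
  low <- rank(angs, ties.method = "first") <= ceiling(nsec / 2)
  secs <- lapply(seq_len(nsec), function(i)
    c(if (low[i]) c(1, -2, 1) else c(1, 2, 1), dens[[i]]))
  # order sections from farthest to nearest the unit circle; gain up front
  sos <- do.call(rbind, secs[order(mods)])
  sos[1, 1:3] <- sos[1, 1:3] * g
  sos
}

# forward-backward (zero-phase) filtering through a biquad cascade with
# odd-reflection padding and steady-state initial conditions
sos_filtfilt <- function(sos, x, padlen = 3L * nrow(sos)) {
  N <- length(x)
  padlen <- as.integer(min(N - 1L, padlen))
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[N] - x[(N - 1):(N - padlen)])
  zi_for <- function(x0) {
    zi <- matrix(0, nrow(sos), 2)
    scale <- x0
    for (s in seq_len(nrow(sos))) {
      b <- sos[s, 1:3]; a <- sos[s, 4:6]
      zi[s, ] <- lfilter_zi(b, a) * scale
      scale <- scale * sum(b) / sum(a)
    }
    zi
  }
  y <- sos_df2t(sos, ext, zi_for(ext[1]))
  y <- rev(y)
  y <- sos_df2t(sos, y, zi_for(y[1]))
  y <- rev(y)
  y[(padlen + 1):(padlen + N)]
}

# steady-state initial filter state for a step input of height 1
# (solves the direct-form-II-transposed state fixed point)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)       # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  tryCatch(as.numeric(solve(IminusA, B)),
           # ill-conditioned high-order designs: fall back to zero state and
           # rely on the reflection padding to absorb the edge transient
           error = function(e) rep(0, n - 1))
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies an IIR filter forward and then backward so that the net phase
#' response is zero and onset times are not displaced. Edges are handled by
#' odd-reflection padding plus steady-state initial conditions, so a constant
#' input passes through (or is removed, for a high-pass) without large edge
#' transients. The per-pass magnitude response is squared.
#'
#' @param b,a Filter numerator / denominator coefficients (e.g. from
#'   [signal::butter()]).
#' @param x Numeric vector.
#' @param padlen Edge padding length in samples. Default `3 * (n - 1)`
#'   coefficients-based padding; for filters with a low cut-off relative to
#'   the sampling rate, pass a padding of a few time constants of that
#'   cut-off so the edge transient is absorbed in the padding.
#' @return Filtered vector, same length as `x`.
#' @export
zp_filtfilt <- function(b, a, x, padlen = NULL) {
  n <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3L * (n - 1L)
  padlen <- as.integer(padlen)
  N <- length(x)
  if (N <= padlen)
    stop("input too short for zero-phase filtering (need > ", padlen, " samples)")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[N] - x[(N - 1):(N - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_df2t(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_df2t(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + N)]
}

#' Convert a raw recording to field potentials
#'
#' Band-pass filters every channel into the field-potential band with a
#' zero-phase Butterworth filter, then decimates to the target rate. The
#' pass-band upper edge must sit below the output Nyquist frequency, so the
#' band-pass itself is the anti-alias guard. Channel ids, start time and
#' epoch annotations are preserved.
#'
#' @param rec An [new_recording()]; all channels share the sampling rate.
#' @param params An [fp_params()].
#' @return A new `mea_recording` at `params$target_rate` Hz with
#'   `floor(n_samples * target_rate / source_rate)` samples per channel.
#' @export
to_field_potential <- function(rec, params = fp_params()) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$sample_rate
  if (fs < 2 * params$band[2])
    stop("source rate (", fs, " Hz) must be at least twice the band high edge")
  if (params$target_rate > fs)
    stop("target rate (", params$target_rate, " Hz) exceeds source rate (", fs, " Hz)")
  factor <- fs / params$target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("source rate must be an integer multiple of target rate (got ratio ",
         format(factor), ")")
  factor <- as.integer(round(factor))
  sos <- butter_sos(params$order, params$band / (fs / 2))
  n_in <- ncol(rec$data)
  n_out <- floor(n_in / factor)
  idx <- seq(1L, by = factor, length.out = n_out)
  # pad several time constants of the low cut-off so high-pass edge
  # transients land in the padding, not in the output
  padlen <- min(n_in - 1L, max(24L, ceiling(3 * fs / params$band[1])))
  out <- matrix(0, nrow = nrow(rec$data), ncol = n_out)
  for (ch in seq_len(nrow(rec$data))) {
    y <- sos_filtfilt(sos, rec$data[ch, ], padlen = padlen)
    out[ch, ] <- y[idx]
  }
  new_recording(out, params$target_rate, rec$channels,
                start_time_s = rec$start_time_s, epochs = rec$epochs)
}
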