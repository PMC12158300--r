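# Digital filter design and zero-phase filtering.
#
# Implemented from first principles (analog Butterworth prototype,
# lowpass-to-bandpass transform, bilinear transform with frequency
# prewarping, second-order sections) because no signal-processing
# package is available in the supported environment. The design path
# mirrors the classical butter/filtfilt pair: cascade of biquads,
# forward-backward filtering with odd-reflection padding and
# steady-state initial conditions.

#' Design a Butterworth bandpass filter as second-order sections
#'
#' An order-`order` analog Butterworth prototype is transformed to a
#' bandpass filter (final polynomial order `2 * order`) and discretized
#' by the bilinear transform with prewarped band edges.
#'
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 8).
#' @return a `butter_sos` object: list with matrix `sos` (one row per
#'   biquad: b0 b1 b2 a0 a1 a2) and scalar `fs`.
#' @export
butter_bandpass <- function(low, high, fs, order = 8L) {
  if (!(low > 0 && high > low)) stopf("need 0 < low < high")
  if (high >= fs / 2) stopf("high (%g Hz) must be below the Nyquist frequency (%g Hz)", high, fs / 2)
  N <- as.integer(order)
  fs2 <- 2 * fs
  # prewarped analog band edges
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog prototype poles (Butterworth, left half plane)
  k <- 1:N
  p_lp <- exp(1i * pi * (2 * k + N - 1) / (2 * N))
  # lowpass -> bandpass: each prototype pole maps to a pair
  plp <- p_lp * bw / 2
  root <- sqrt(plp^2 - w0^2 + 0i)
  p_bp <- c(plp + root, plp - root)          # 2N poles
  # zeros: N at s = 0 (the other N at infinity); gain bw^N
  gain <- bw^N
  # bilinear transform
  zd_p <- (fs2 + p_bp) / (fs2 - p_bp)
  # digital gain: k * prod(fs2 - zeros)/prod(fs2 - poles); zeros at 0
  gd <- gain * Re(prod(fs2 - rep(0, N)) / prod(fs2 - p_bp))
  # digital zeros: N at +1 (from s = 0), N at -1 (from infinity)
  # pair conjugate poles into biquads, each with zeros (+1, -1)
  p_sorted <- zd_p[order(Im(zd_p))]
  up <- p_sorted[Im(p_sorted) > 0]
  dn <- Conj(up)
  if (length(up) != N) {
    # real poles possible in principle; fall back to magnitude pairing
    idx <- order(Mod(Im(zd_p)), decreasing = TRUE)
    up <- zd_p[idx[seq_len(N)]]
    dn <- zd_p[idx[N + seq_len(N)]]
  }
  gmag <- abs(gd)^(1 / N)
  sgn <- if (gd < 0) -1 else 1
  sos <- matrix(0, N, 6)
  for (i in seq_len(N)) {
    p <- up[i]; q <- dn[i]
    a1 <- -Re(p + q); a2 <- Re(p * q)
    b <- gmag * c(1, 0, -1)       # zeros at +1 and -1
    if (i == 1) b <- b * sgn
    sos[i, ] <- c(b, 1, a1, a2)
  }
  rmax <- max(Mod(c(up, dn)))
  structure(list(sos = sos, fs = fs, max_pole_radius = rmax),
            class = "butter_sos")
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_response <- function(filt, f) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    H <- H * (s[1] + s[2] * z + s[3] * z^2) / (s[4] + s[5] * z + s[6] * z^2)
  }
  H
}

#' Magnitude response of a designed filter
#'
#' @param filt a `butter_sos`.
#' @param f frequencies in Hz.
#' @return numeric vector `|H(f)|`.
#' @export
filter_gain <- function(filt, f) Mod(sos_response(filt, f))

# Steady-state initial conditions for one biquad (direct form II
# transposed), scaled by the first input sample at call time.
biquad_zi <- function(b, a) {
  K <- sum(b) / sum(a)
  zi2 <- b[3] - a[3] * K
  zi1 <- b[2] - a[2] * K + zi2
  c(zi1, zi2)
}

biquad_filter <- function(x, b, a, zi) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; a1 <- a[2]; a2 <- a[3]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b0 * xi + z1
    z1 <- b1 * xi - a1 * yi + z2
    z2 <- b2 * xi - a2 * yi
    y[i] <- yi
  }
  y
}

sos_filter <- function(x, filt) {
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    x <- biquad_filter(x, s[1:3], s[4:6], biquad_zi(s[1:3], s[4:6]) * x[1])
  }
  x
}

#' Zero-phase filtering of one signal
#'
#' Forward-backward application of an SOS cascade with odd-reflection
#' padding and steady-state initial conditions, so the net filter has
#' zero phase and the squared magnitude response of the design.
#'
#' @param x numeric vector.
#' @param filt a `butter_sos`.
#' @param padlen samples of odd reflection prepended/appended. The
#'   default scales with the decay length of the slowest pole
#'   (`9 / (1 - max pole radius)`) so that highpass transients die out
#'   inside the padding; capped at `length(x) - 1`.
#' @return filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(x, filt, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) {
    r <- filt$max_pole_radius %||% 0.95
    padlen <- ceiling(9 / max(1 - r, 1e-4))
  }
  padlen <- as.integer(min(padlen, n - 1L))
  ext <- c(2 * x[1] - x[seq(padlen + 1, 2)],
           x,
           2 * x[n] - x[seq(n - 1, n - padlen)])
  y <- sos_filter(ext, filt)
  y <- rev(sos_filter(rev(y), filt))
  y[(padlen + 1):(padlen + n)]
}

# --- polyphase resampling --------------------------------------------------

kaiser_window <- function(n, beta) {
  m <- n - 1
  x <- (0:m - m / 2) / (m / 2)
  besselI(beta * sqrt(pmax(0, 1 - x^2)), 0) / besselI(beta, 0)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Rational approximation of a rate ratio with bounded denominator.
rational_ratio <- function(target, orig, max_den = 1000L) {
  r <- target / orig
  best <- c(1L, 1L); best_err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) { best <- c(p, q); best_err <- err }
    if (best_err == 0) break
  }
  best
}

#' Polyphase resampling of a signal
#'
#' Upsample by p (zero stuffing), apply a Kaiser-windowed sinc anti-alias
#' lowpass, downsample by q, with group-delay compensation — the
#' classical resample-poly scheme.
#'
#' @param x numeric vector.
#' @param p,q integer up/down factors.
#' @return resampled vector of length `ceiling(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (p == q) return(x)
  n <- length(x)
  mx <- max(p, q)
  half <- 10L * mx
  taps <- 2L * half + 1L
  t <- (-half):half
  h <- sinc(t / mx) * kaiser_window(taps, 5)
  h <- p * h / sum(h)
  up <- numeric(n * p)
  up[seq(1, by = p, length.out = n)] <- x
  # zero-padded convolution; sample i of the filtered upsampled signal
  # with the group delay `half` removed is full[i + half]
  full <- stats::convolve(c(up, numeric(taps - 1)), rev(h), type = "open")
  y_full <- full[half + seq_len(n * p)]
  n_out <- ceiling(n * p / q)
  idx <- seq(1, by = q, length.out = n_out)
  y_full[idx]
}
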