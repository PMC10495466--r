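# Chebyshev Type II design in zero-pole-gain form, converted to second-order
# sections. Transfer-function (b, a) coefficients are numerically hopeless at
# the narrow relative bandwidths used here (2.5 Hz edges at fs = 1000 Hz), so
# the whole chain -- analog prototype, band transform, bilinear transform,
# conjugate-pair pairing -- stays in zpk until the final biquads.

# analog Chebyshev II low-pass prototype, stopband edge at 1 rad/s
.cheb2ap <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p <- 1 / (-sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta))
  keep <- abs(cos(theta)) > 1e-12          # odd n: drop the zero at infinity
  z <- 1i / cos(theta[keep])
  list(z = z, p = p, k = Re(prod(-p) / prod(-z)))
}

.lp2bp_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zl <- zpk$z * bw / 2
  pl <- zpk$p * bw / 2
  list(z = c(zl + sqrt(as.complex(zl^2 - wo^2)),
             zl - sqrt(as.complex(zl^2 - wo^2)),
             rep(0 + 0i, degree)),
       p = c(pl + sqrt(as.complex(pl^2 - wo^2)),
             pl - sqrt(as.complex(pl^2 - wo^2))),
       k = zpk$k * bw^degree)
}

.lp2bs_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zl <- (bw / 2) / zpk$z
  pl <- (bw / 2) / zpk$p
  list(z = c(zl + sqrt(as.complex(zl^2 - wo^2)),
             zl - sqrt(as.complex(zl^2 - wo^2)),
             rep(1i * wo, degree), rep(-1i * wo, degree)),
       p = c(pl + sqrt(as.complex(pl^2 - wo^2)),
             pl - sqrt(as.complex(pl^2 - wo^2))),
       k = zpk$k * Re(prod(-zpk$z) / prod(-zpk$p)))
}

.bilinear_zpk <- function(zpk, fs) {
  degree <- length(zpk$p) - length(zpk$z)
  fs2 <- 2 * fs
  list(z = c((fs2 + zpk$z) / (fs2 - zpk$z), rep(-1 + 0i, degree)),
       p = (fs2 + zpk$p) / (fs2 - zpk$p),
       k = zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p)))
}

.conj_pairs <- function(v, tol = 1e-8) {
  re <- abs(Im(v)) < tol * pmax(1, abs(v))
  up <- v[!re & Im(v) > 0]
  up <- up[order(Re(up), Im(up))]
  list(pairs = up, reals = sort(Re(v[re])))
}

# pair conjugate pole pairs (ordered by closeness to the unit circle) with
# the nearest zero pairs; overall gain goes on the last (highest-Q) section
.zpk2sos <- function(zpk) {
  stopifnot(length(zpk$z) == length(zpk$p), length(zpk$p) %% 2 == 0)
  ps <- .conj_pairs(zpk$p)
  zs <- .conj_pairs(zpk$z)
  pair_up <- function(cp) {
    out <- lapply(cp$pairs, function(x) c(x, Conj(x)))
    r <- cp$reals
    while (length(r) >= 2) {
      out <- c(out, list(c(r[1] + 0i, r[2] + 0i)))
      r <- r[-(1:2)]
    }
    out
  }
  pp <- pair_up(ps)
  zz <- pair_up(zs)
  stopifnot(length(pp) == length(zz))
  ord <- order(vapply(pp, function(x) abs(1 - abs(x[1])), 0), decreasing = TRUE)
  pp <- pp[ord]
  used <- rep(FALSE, length(zz))
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  for (i in seq_along(pp)) {
    d <- vapply(seq_along(zz), function(j) {
      if (used[j]) return(Inf)
      min(Mod(pp[[i]][1] - zz[[j]]))
    }, 0)
    j <- which.min(d)
    used[j] <- TRUE
    sos[i, 1:3] <- Re(c(1, -sum(zz[[j]]), prod(zz[[j]])))
    sos[i, 4:6] <- Re(c(1, -sum(pp[[i]]), prod(pp[[i]])))
  }
  sos[nrow(sos), 1:3] <- sos[nrow(sos), 1:3] * zpk$k
  sos
}

.prewarp <- function(f, fs) 2 * fs * tan(pi * f / fs)

# minimal Chebyshev II order meeting `rs` dB at the stopband edges and at
# most `rp` dB at the passband edges
.cheb2_order <- function(fs, stopband, passband, rp, rs, kind) {
  ws <- .prewarp(stopband, fs)
  wp <- .prewarp(passband, fs)
  wo2 <- ws[1] * ws[2]
  bw <- ws[2] - ws[1]
  om <- if (kind == "pass") abs(wp^2 - wo2) / (bw * wp)
        else (bw * wp) / abs(wp^2 - wo2)
  g <- acosh(sqrt((10^(0.1 * rs) - 1) / (10^(0.1 * rp) - 1)))
  list(n = as.integer(ceiling(g / acosh(1 / max(om)))),
       wo = sqrt(wo2), bw = bw)
}

.design_cheby2 <- function(fs, stopband, passband, rp, rs, kind) {
  ord <- .cheb2_order(fs, stopband, passband, rp, rs, kind)
  zpk <- .cheb2ap(ord$n, rs)
  zpk <- if (kind == "pass") .lp2bp_zpk(zpk, ord$wo, ord$bw)
         else .lp2bs_zpk(zpk, ord$wo, ord$bw)
  zpk <- .bilinear_zpk(zpk, fs)
  if (any(Mod(zpk$p) >= 1 - 1e-9))
    stop("unstable filter design (poles on the unit circle); ",
         "relax the transition width or attenuation")
  new("FilterSpec", kind = kind, passband = passband, stopband = stopband,
      attenuation = rs, ripple = rp, order = ord$n,
      sos = .zpk2sos(zpk), fs = fs)
}

#' Design a zero-phase Chebyshev Type II band-pass filter
#'
#' Designs the band-pass filters used for the low (2.5-12 Hz) and high
#' (12-80 Hz) frequency bands: cutoff (stopband-edge) frequencies at
#' `f1 - margin` and `f2 + margin` with `attenuation` dB of stopband
#' attenuation per pass, at the minimal order for which the passband edges
#' (one transition width inside the stopband edges) see at most `ripple` dB.
#' The transition width per edge is `max(2 * margin, 0.05 * f)`, i.e. 0.6 Hz
#' at the 2.5 and 12 Hz edges and 5% at edges where 0.6 Hz would be
#' needlessly sharp (see the methods vignette). Apply with [filterSignal()],
#' which runs the filter forward and backward so the effective attenuation
#' doubles and the phase delay is nullified.
#'
#' @param fs Sampling rate (Hz).
#' @param f1,f2 Nominal band edges (Hz), `0 < f1 < f2 < fs/2`.
#' @param margin Stopband-edge margin (Hz) around the nominal band.
#' @param attenuation Stopband attenuation per pass (dB).
#' @param ripple Maximum passband attenuation per pass (dB).
#' @return A [FilterSpec-class].
#' @examples
#' lowBand <- designBandpass(1000, 2.5, 12)
#' lowBand
#' @export
designBandpass <- function(fs, f1, f2, margin = 0.3, attenuation = 60,
                           ripple = 0.5) {
  stopifnot(f1 > margin, f1 < f2, f2 + margin < fs / 2)
  trans <- pmax(2 * margin, 0.05 * c(f1, f2))
  stopband <- c(f1 - margin, f2 + margin)
  passband <- c(stopband[1] + trans[1], stopband[2] - trans[2])
  stopifnot(passband[1] < passband[2])
  .design_cheby2(fs, stopband, passband, ripple, attenuation, "pass")
}

#' Design a zero-phase Chebyshev Type II notch (band-stop) filter
#'
#' Line-noise removal filter: `attenuation` dB within `f0 +- halfWidth` Hz,
#' with passband edges at `f0 +- 2 * halfWidth`.
#'
#' @param fs Sampling rate (Hz).
#' @param f0 Line frequency (Hz), 60 by default.
#' @param halfWidth Stopband half width (Hz), 0.6 by default.
#' @param attenuation Stopband attenuation per pass (dB).
#' @param ripple Maximum passband attenuation per pass (dB).
#' @return A [FilterSpec-class].
#' @export
designNotch <- function(fs, f0 = 60, halfWidth = 0.6, attenuation = 60,
                        ripple = 0.5) {
  stopifnot(f0 > 2 * halfWidth, f0 + 2 * halfWidth < fs / 2)
  .design_cheby2(fs, f0 + c(-1, 1) * halfWidth, f0 + c(-2, 2) * halfWidth,
                 ripple, attenuation, "stop")
}

#' Apply a filter with zero phase (forward-backward)
#'
#' Filters each signal forward, reverses it, filters again and reverses back,
#' so that the phase delay of the filter is nullified and the amplitude
#' response is applied twice. Signals are extended by odd reflection before
#' filtering and the extension is discarded afterwards, so that start-up
#' transients decay outside the data.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param spec A [FilterSpec-class].
#' @param pad Reflection padding in samples; defaults to 0.3 s worth of
#'   samples (capped at the signal length minus one).
#' @return Filtered data with the shape of `x`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 8 * t) + sin(2 * pi * 60 * t)
#' y <- filterSignal(x, designNotch(fs))
#' sd(y - sin(2 * pi * 8 * t)) / sd(x)  # 60 Hz component removed
#' @export
filterSignal <- function(x, spec, pad = NULL) {
  stopifnot(is(spec, "FilterSpec"))
  if (is.null(pad)) pad <- as.integer(round(0.3 * spec@fs))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  out <- sos_filtfilt_cpp(xm, spec@sos, as.integer(pad))
  if (vec) out[, 1] else out
}

#' Frequency response of a filter design
#'
#' Complex response of one forward pass at the requested frequencies (the
#' zero-phase application in [filterSignal()] has magnitude equal to its
#' square and zero phase).
#'
#' @param spec A [FilterSpec-class].
#' @param f Frequencies (Hz).
#' @return Complex response, one value per frequency.
#' @export
frequencyResponse <- function(spec, f) {
  w <- exp(-1i * 2 * pi * f / spec@fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(spec@sos))) {
    b <- spec@sos[i, 1:3]
    a <- spec@sos[i, 4:6]
    h <- h * (b[1] + b[2] * w + b[3] * w^2) / (a[1] + a[2] * w + a[3] * w^2)
  }
  h
}

# per-(fs, band) design cache: the narrow designs cost a few ms and are
# requested for every session analyzed
.filter_cache <- new.env(parent = emptyenv())

.cached_bandpass <- function(fs, band) {
  key <- paste0("bp_", fs, "_", band[1], "_", band[2])
  if (is.null(.filter_cache[[key]]))
    .filter_cache[[key]] <- designBandpass(fs, band[1], band[2])
  .filter_cache[[key]]
}

#' @describeIn FilterSpec-class Compact display of a design.
#' @param object A `FilterSpec`.
#' @export
setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "Chebyshev II band-%s FilterSpec: stopband %g-%g Hz (%g dB/pass), %d sections, fs %g Hz\n",
    object@kind, object@stopband[1], object@stopband[2], object@attenuation,
    nrow(object@sos), object@fs))
})
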