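## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: enumeration, closed forms and the raw FFT.

## all permutations of 1..n as an (n! x n) matrix, recursively
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## plain-formula cosine, no clamping, no package code
oracleCosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

## exact permutation p-value by full enumeration: count(null >= obs) / n!
exactPermutationP <- function(fixed, moving) {
  perms <- allPermutations(length(moving))
  obs <- oracleCosine(fixed, moving)
  null <- apply(perms, 1L, function(ix) oracleCosine(fixed, moving[ix]))
  sum(null >= obs) / nrow(perms)
}

## fraction of spectral power above f0 (Hz): Hann-tapered periodogram via
## the raw discrete Fourier transform. The taper matters: a smooth but
## non-periodic record leaks rectangular-window sidelobe power across the
## whole band (~25% apparent high-frequency power for a low-pass signal
## whose true out-of-band residual is ~3e-4), which would mask the
## quantity under test.
powerFractionAbove <- function(x, fps, f0) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1L) / (n - 1L))
  p <- Mod(fft((x - mean(x)) * w))^2
  k <- seq_len(floor(n / 2))          # positive frequencies only
  f <- k * fps / n
  sum(p[k + 1L][f > f0]) / sum(p[k + 1L])
}

## Tukey hinges by brute force: medians of the lower/upper halves of the
## sorted data, halves including the overall median when n is odd
bruteHinges <- function(v) {
  s <- sort(v)
  n <- length(s)
  h <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L
  c(q1 = median(s[1:h]), q3 = median(s[(n - h + 1L):n]))
}

## exact polygon area, shoelace formula
shoelaceArea <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

## short smooth noiseless test series on the analysis grid
smoothSeries <- function(n = 435, fps = 8.7, f = 0.02, amp = 0.5,
                         base = 36) {
  t <- (seq_len(n) - 1L) / fps
  TemperatureSeries(base + amp * sin(2 * pi * f * t) +
                      0.3 * amp * cos(2 * pi * 0.5 * f * t), fps = fps)
}
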