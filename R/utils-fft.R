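# FFT bookkeeping shared by the forward model, the engines and the metrics.
# Convention: frames and waves are (row, col) matrices with row 1 at the top;
# after fftshift2 the reciprocal-space origin sits at the geometric array
# centre (floor(n/2) + 1).

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n %/% 2 + 1):n, 1:(n %/% 2)), c((m %/% 2 + 1):m, 1:(m %/% 2))]
}

ifftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n - n %/% 2 + 1):n, 1:(n - n %/% 2)), c((m - m %/% 2 + 1):m, 1:(m - m %/% 2))]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT frequency axis in cycles per unit length, unshifted order (DC first).
fft_freqs <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -(n %/% 2):-1) / (n * d)
}

# Reciprocal-space coordinate matrices in 1/Angstrom, *shifted* so the origin
# is at the array centre (matches fftshift2-ed transforms).
kgrid <- function(n, pixel_size_pm) {
  d_A <- pixel_size_pm / 100          # pm -> Angstrom
  f <- sort(fft_freqs(n, d_A))        # monotone axis, centre at n %/% 2 + 1
  list(kx = matrix(rep(f, each = n), n, n),
       ky = matrix(rep(f, times = n), n, n))
}

# Same grid in unshifted (DC-first) FFT order, for propagators.
kgrid_fft <- function(n, pixel_size_pm) {
  d_A <- pixel_size_pm / 100
  f <- fft_freqs(n, d_A)
  list(kx = matrix(rep(f, each = n), n, n),
       ky = matrix(rep(f, times = n), n, n))
}

# Subpixel shift by (dy, dx) pixels via the Fourier shift theorem.
fourier_shift <- function(wave, dy, dx) {
  n <- nrow(wave); m <- ncol(wave)
  fy <- fft_freqs(n, 1); fx <- fft_freqs(m, 1)
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, m)) + outer(rep(1, n), fx * dx)))
  ifft2(fft2(wave) * ph)
}

# Integer centre index convention used everywhere: (n %/% 2) + 1.
centre_index <- function(n) n %/% 2 + 1
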