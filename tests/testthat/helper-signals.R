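# Shared fixtures, built in code at test time.

alpha_band <- function() frequency_band("alpha", 8, 13)

# Plain sine sampled at fs, cosine-referenced phase offset in radians.
make_cosine <- function(freq, fs, n, phase = 0) {
  cos(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Independent brute-force DFT oracle: evaluates |X(f)| and arg X(f) by the
# definition on an explicit frequency grid, without using stats::fft.
# Returns the grid maximum over (0, fs/2).
brute_force_dominant <- function(x, fs, nfft = 10000L) {
  n <- length(x)
  kmax <- ceiling(nfft / 2) - 1L
  k <- 1:kmax
  # X_k = sum_n x_n exp(-2 pi i k n / nfft), n = 0..n-1
  E <- exp(-2i * pi * outer(k, 0:(n - 1)) / nfft)   # bins x samples
  X <- as.vector(E %*% x)
  j <- which.max(Mod(X))
  list(freq = k[j] * fs / nfft, magnitude = Mod(X[j]), phase = Arg(X[j]))
}

# Noiseless sine recording of the given duration.
noiseless_rec <- function(freq = 10, duration = 5, fs = 500, seed = 1L) {
  make_pure_sine_noise(synthetic_spec("pure_sine_noise", carrier_freq = freq,
                                      noiseless = TRUE, duration = duration,
                                      fs = fs, seed = seed))
}
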