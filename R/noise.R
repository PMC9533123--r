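#' Generate 1/f^beta colored noise
#'
#' Spectral synthesis of a zero-mean, unit-variance noise sequence whose
#' expected periodogram follows power ~ f^(-beta): Fourier amplitudes are set
#' to f^(-beta/2) with independent uniform random phases and the result is
#' inverse-transformed and standardized. `beta = 0` gives white noise,
#' `beta = 1` pink (1/f) noise, `beta = 2` brown (1/f^2) noise.
#'
#' @param n_samples Number of samples (>= 2).
#' @param beta Spectral exponent (>= 0, finite).
#' @param seed Optional integer seed; when given, the sequence is a
#'   deterministic function of `(n_samples, beta, seed)` and the caller's RNG
#'   state is left untouched.
#' @return Numeric vector of length `n_samples` with mean 0 and sample SD 1.
#' @export
#' @examples
#' x <- generate_colored_noise(1024, beta = 1, seed = 42)
#' c(mean(x), sd(x))
generate_colored_noise <- function(n_samples, beta, seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples < 2)
    stop("`n_samples` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a single finite number >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  with_seed(seed, {
    nf <- n %/% 2L                      # positive-frequency bins
    amp <- seq_len(nf)^(-beta / 2)
    ph <- runif(nf) * 2 * pi
    full <- complex(real = rep(0, n))
    if (n %% 2L == 0L) {
      # Nyquist bin must be real for a real-valued inverse transform
      full[2:nf] <- complex(modulus = amp[-nf], argument = ph[-nf])
      full[nf + 1L] <- complex(real = amp[nf] * sign(cos(ph[nf])))
      full[seq(n, nf + 2L)] <- Conj(full[2:nf])
    } else {
      full[2:(nf + 1L)] <- complex(modulus = amp, argument = ph)
      full[seq(n, nf + 2L)] <- Conj(full[2:(nf + 1L)])
    }
    x <- Re(fft(full, inverse = TRUE))
    (x - mean(x)) / sd(x)
  })
}
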