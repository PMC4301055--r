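## shared fixture builders

rate_std <- 11025

make_tone <- function(freq, dur = 0.5, rate = rate_std, amp = 1) {
  waveform(amp * sin(2 * pi * freq * seq_len(round(dur * rate)) / rate), rate)
}

## linear chirp f0(t) = f_from + (f_to - f_from) * t / dur
make_chirp <- function(f_from, f_to, dur, rate = rate_std) {
  tt <- seq_len(round(dur * rate)) / rate
  f <- f_from + (f_to - f_from) * tt / dur
  waveform(sin(2 * pi * cumsum(f) / rate), rate)
}

small_population <- function(caller_class = "hind", n = 8, icc = 0.7,
                             seed = 420) {
  make_population(population_spec(caller_class, icc = icc), n, seed = seed)
}

## deterministic well-separated 3-group toy table for classifier oracles
toy_3group <- function() {
  set.seed(99)
  mu <- rbind(c(0, 0, 0), c(3, -1, 1), c(-2, 2, 3))
  g <- rep(1:3, each = 6)
  X <- mu[g, ] + matrix(rnorm(18 * 3), 18, 3)
  data.frame(individual_id = sprintf("id%d", g),
             v1 = X[, 1], v2 = X[, 2], v3 = X[, 3])
}
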