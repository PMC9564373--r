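# shared synthetic feature-table generator for selection/modeling tests
make_table <- function(n = 126, p = 50, n_signal = 0, effect = 1.5,
                       seed = 1, event_frac = 64 / 126) {
  set.seed(seed)
  y <- c(rep(1L, round(n * event_frac)), rep(0L, n - round(n * event_frac)))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  if (n_signal > 0)
    x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] + effect * y
  feature_table(x, y)
}

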