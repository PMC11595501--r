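# Independent reference implementations used as oracles, plus tiny fixture
# builders. These deliberately use naive loops / direct formulas so they
# share no code path with the package internals they check.

# direct septuple-loop 3D convolution (same padding, zero fill, linear)
naive_conv3d <- function(x, w, b) {
  d <- dim(x)
  k <- dim(w)
  off <- (k[1:3] - 1) %/% 2
  out <- array(0, dim = c(d[1:3], k[5]))
  for (co in seq_len(k[5])) {
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (xx in seq_len(d[1])) {
      s <- b[co]
      for (ci in seq_len(d[4])) {
        for (r in seq_len(k[3])) for (q in seq_len(k[2])) for (p in seq_len(k[1])) {
          sx <- xx + p - 1 - off[1]
          sy <- y + q - 1 - off[2]
          sz <- z + r - 1 - off[3]
          if (sx >= 1 && sx <= d[1] && sy >= 1 && sy <= d[2] &&
              sz >= 1 && sz <= d[3]) {
            s <- s + w[p, q, r, ci, co] * x[sx, sy, sz, ci]
          }
        }
      }
      out[xx, y, z, co] <- s
    }
  }
  out
}

# direct gate-formula LSTM sequence evaluator; weights as separate matrices
naive_lstm_seq <- function(X, W_i, W_f, W_c, W_o, b_i, b_f, b_c, b_o, u) {
  sig <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, u)
  cc <- rep(0, u)
  for (t in seq_along(X)) {
    z <- c(h, X[[t]])
    i <- sig(as.vector(z %*% W_i) + b_i)
    f <- sig(as.vector(z %*% W_f) + b_f)
    g <- tanh(as.vector(z %*% W_c) + b_c)
    o <- sig(as.vector(z %*% W_o) + b_o)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  list(h = h, c = cc)
}

# constant-valued reference-geometry trial (15 channels, 512 samples, 256 Hz)
const_trial <- function(value = 7, label = "hello", subject = "S01") {
  trial_recording(matrix(value, 15, 512), 256, label, subject,
                  frontal_subset())
}

# trial whose every channel equals the 1-based sample index (for window
# index arithmetic)
ramp_trial <- function() {
  trial_recording(matrix(rep(1:512, each = 15), 15), 256, "hello", "S01",
                  frontal_subset())
}

# small labelled trial set with the given per-class counts
toy_set <- function(counts, n_ch = 4, n_s = 32, rate = 256, subject = "S01",
                    seed = 1) {
  set.seed(seed)
  trials <- list()
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      trials[[length(trials) + 1]] <-
        trial_recording(matrix(rnorm(n_ch * n_s), n_ch), rate, cl, subject,
                        paste0("ch", seq_len(n_ch)))
    }
  }
  trial_set(trials, classes = names(counts))
}

frontal_m2d <- function() {
  project_to_disk(standard_1020_positions(frontal_subset()))
}
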