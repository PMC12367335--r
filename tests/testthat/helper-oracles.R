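# Independent reference implementations and small fixture builders used
# across the suite. These deliberately avoid the package's own code paths:
# the DWT oracle builds the analysis operator as an explicit matrix, and
# the LSTM oracle is a plain R loop over the six cell equations.

# Brute-force single-stage DWT: pad, full correlation matrix, keep every
# second row.
oracle_analysis <- function(x, spec, padding_mode = "symmetric") {
  n <- length(x)
  L <- length(spec$dec_lo)
  K <- ceiling(n / 2)
  need <- 2 * (K - 1) + L
  xe <- numeric(need)
  for (i in seq_len(need)) {
    xe[i] <- if (i <= n) x[i] else switch(padding_mode,
      zero = 0,
      periodic = x[((i - 1) %% n) + 1],
      symmetric = x[n - ((i - n - 1) %% n)])
  }
  A <- matrix(0, K, need)
  D <- matrix(0, K, need)
  for (k in seq_len(K)) {
    cols <- (2 * (k - 1) + 1):(2 * (k - 1) + L)
    A[k, cols] <- spec$dec_lo
    D[k, cols] <- spec$dec_hi
  }
  list(approx = drop(A %*% xe), detail = drop(D %*% xe))
}

# Plain-R loop over the six printed cell equations, seq-to-one.
oracle_lstm_forward <- function(X, w) {
  sig <- function(a) 1 / (1 + exp(-a))
  H <- w$hidden_dim
  h <- rep(0, H); cc <- rep(0, H)
  hid <- matrix(NA_real_, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    f <- sig(drop(xt %*% w$U_f + h %*% w$W_f) + if (w$bias_enabled) w$b_f else 0)
    g <- tanh(drop(xt %*% w$U_c + h %*% w$W_c) + if (w$bias_enabled) w$b_c else 0)
    i <- sig(drop(xt %*% w$U_i + h %*% w$W_i) + if (w$bias_enabled) w$b_i else 0)
    o <- sig(drop(xt %*% w$U_o + h %*% w$W_o) + if (w$bias_enabled) w$b_o else 0)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    hid[t, ] <- h
  }
  list(H = h, C = cc, hidden = hid)
}

# Random LSTM weights with entries in +/- range, via the current RNG.
random_weights <- function(input_dim = 3, hidden_dim = 4, range = 0.5,
                           bias_enabled = FALSE) {
  w <- lstm_weights(input_dim, hidden_dim, init = "zero", bias_enabled = bias_enabled)
  for (g in c("f", "c", "i", "o")) {
    w[[paste0("U_", g)]] <- matrix(runif(input_dim * hidden_dim, -range, range),
                                   input_dim, hidden_dim)
    w[[paste0("W_", g)]] <- matrix(runif(hidden_dim^2, -range, range),
                                   hidden_dim, hidden_dim)
    if (bias_enabled) w[[paste0("b_", g)]] <- runif(hidden_dim, -range, range)
  }
  w$w_out <- runif(hidden_dim, -range, range)
  w$b_out <- runif(1, -range, range)
  w
}

# A tiny hand-built stay on the 5-minute grid.
toy_stay <- function(id = "s1", n = 48, los = 2.5, hr = 80, rr = 18, spo2 = 97) {
  stay_record(id, rep(hr, n), rep(rr, n), rep(spo2, n), los = los)
}

# Small deterministic cohort with varying LOS for split/training tests.
toy_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  records <- lapply(seq_len(n), function(i) {
    los <- exp(rnorm(1, log(2.5), 0.7))
    len <- 36 + (i %% 5)
    stay_record(sprintf("t%03d", i),
                80 + los + rnorm(len), 18 + rnorm(len),
                pmin(100, 96 + rnorm(len)), los = los)
  })
  cohort_table(records)
}
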