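# LSTM sequence-to-one regressor. One cell step follows the gate equations
#   f_t = sigma(X_t U_f + H_{t-1} W_f)      (forget gate)
#   c~_t = tanh (X_t U_c + H_{t-1} W_c)     (candidate)
#   i_t = sigma(X_t U_i + H_{t-1} W_i)      (input gate)
#   O_t = sigma(X_t U_o + H_{t-1} W_o)      (output gate)
#   C_t = f_t . C_{t-1} + i_t . c~_t
#   H_t = O_t . tanh(C_t)
# with optional bias terms, and a linear head w_out . H_T + b_out mapping the
# final hidden state to the predicted length of stay in days.

.GATES <- c("f", "c", "i", "o")

#' LSTM parameter set
#'
#' Creates the full parameter set of a unidirectional LSTM regressor:
#' input-to-gate matrices `U_f, U_c, U_i, U_o` (`input_dim x hidden_dim`),
#' recurrent matrices `W_f, W_c, W_i, W_o` (`hidden_dim x hidden_dim`),
#' optional gate biases, and the linear head `w_out`, `b_out`.
#'
#' @param input_dim Number of input channels (3 for heart rate, respiration,
#'   SaO2).
#' @param hidden_dim Hidden-state width `h`.
#' @param init `"zero"` or `"uniform"` (uniform in `±1/sqrt(hidden_dim)`,
#'   drawn from the current RNG stream so `set.seed()` controls it).
#' @param bias_enabled If `FALSE` (the equation-conformant default) all
#'   biases are exactly zero; training uses `TRUE`.
#' @return Object of class `lstm_weights`.
#' @export
lstm_weights <- function(input_dim = 3L, hidden_dim = 32L,
                         init = c("zero", "uniform"), bias_enabled = FALSE) {
  init <- match.arg(init)
  D <- as.integer(input_dim); H <- as.integer(hidden_dim)
  stopifnot(D >= 1L, H >= 1L)
  draw <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(stats::runif(nr * nc, -1 / sqrt(H), 1 / sqrt(H)), nr, nc)
  }
  w <- list(input_dim = D, hidden_dim = H, bias_enabled = bias_enabled)
  for (g in .GATES) {
    w[[paste0("U_", g)]] <- draw(D, H)
    w[[paste0("W_", g)]] <- draw(H, H)
    w[[paste0("b_", g)]] <- if (bias_enabled && init == "uniform")
      stats::runif(H, -1 / sqrt(H), 1 / sqrt(H)) else numeric(H)
  }
  w$w_out <- if (init == "zero") numeric(H) else stats::runif(H, -1 / sqrt(H), 1 / sqrt(H))
  w$b_out <- 0
  structure(w, class = "lstm_weights")
}

#' @export
print.lstm_weights <- function(x, ...) {
  cat(sprintf("<lstm_weights>  input_dim %d, hidden_dim %d, bias %s\n",
              x$input_dim, x$hidden_dim, if (x$bias_enabled) "on" else "off"))
  invisible(x)
}

#' Bidirectional LSTM parameter set
#'
#' Two independent gate-parameter sets (one applied to the series as-is,
#' one to the reversed series) whose final hidden states are concatenated
#' and fed to one linear head. With the backward set zeroed and
#' `w_out[(h+1):(2h)] = 0`, predictions equal the unidirectional model's.
#'
#' @param forward,backward [lstm_weights()] objects of equal dimensions
#'   (their own heads are ignored).
#' @param w_out Head weights of length `2 * hidden_dim`.
#' @param b_out Head bias scalar.
#' @return Object of class `bilstm_weights`.
#' @export
bilstm_weights <- function(forward, backward,
                           w_out = numeric(2L * forward$hidden_dim), b_out = 0) {
  stopifnot(inherits(forward, "lstm_weights"), inherits(backward, "lstm_weights"),
            forward$hidden_dim == backward$hidden_dim,
            forward$input_dim == backward$input_dim,
            length(w_out) == 2L * forward$hidden_dim)
  structure(list(forward = forward, backward = backward,
                 input_dim = forward$input_dim, hidden_dim = forward$hidden_dim,
                 w_out = w_out, b_out = b_out),
            class = "bilstm_weights")
}

.validate_x <- function(x_t, D) {
  if (!is.numeric(x_t) || length(x_t) != D) {
    stop(sprintf("input vector must be numeric of length %d", D), call. = FALSE)
  }
  if (any(!is.finite(x_t))) stop("input contains non-finite values", call. = FALSE)
}

#' One LSTM cell step
#'
#' Applies the six gate equations to one input vector and the previous
#' state. With all-zero weights and state, every sigmoid gate is 0.5, the
#' candidate is 0, so the new state is exactly zero.
#'
#' @param x_t Numeric input vector of length `input_dim` (order heartrate,
#'   respiration, sao2 for vitals models).
#' @param state List with hidden vector `H` and cell memory `C` (both
#'   length `hidden_dim`); `NULL` means the zero state.
#' @param weights An [lstm_weights()].
#' @param details If `TRUE`, also return the gate activations `f`, `i`,
#'   `o` and candidate `c_tilde`.
#' @return List with `H` and `C` (and gates when requested).
#' @export
cell_step <- function(x_t, state, weights, details = FALSE) {
  stopifnot(inherits(weights, "lstm_weights"))
  D <- weights$input_dim; H <- weights$hidden_dim
  .validate_x(x_t, D)
  if (is.null(state)) state <- list(H = numeric(H), C = numeric(H))
  if (length(state$H) != H || length(state$C) != H) {
    stop(sprintf("state vectors must have length %d", H), call. = FALSE)
  }
  if (any(!is.finite(state$H)) || any(!is.finite(state$C))) {
    stop("state contains non-finite values", call. = FALSE)
  }
  x <- matrix(x_t, 1L, D)
  h <- matrix(state$H, 1L, H)
  pre <- function(g) {
    a <- x %*% weights[[paste0("U_", g)]] + h %*% weights[[paste0("W_", g)]]
    if (weights$bias_enabled) a <- a + matrix(weights[[paste0("b_", g)]], 1L, H)
    drop(a)
  }
  sig <- function(a) 1 / (1 + exp(-a))
  f <- sig(pre("f")); ctil <- tanh(pre("c")); i <- sig(pre("i")); o <- sig(pre("o"))
  C_new <- f * state$C + i * ctil
  H_new <- o * tanh(C_new)
  out <- list(H = H_new, C = C_new)
  if (details) out <- c(out, list(f = f, i = i, o = o, c_tilde = ctil))
  out
}

# Pack one direction's gate parameters into the flat layout the C++ core
# uses: U (D x 4H, gate blocks f|c|i|o), then W (H x 4H), then b (4H).
.dir_theta <- function(w) {
  U <- do.call(cbind, lapply(.GATES, function(g) w[[paste0("U_", g)]]))
  W <- do.call(cbind, lapply(.GATES, function(g) w[[paste0("W_", g)]]))
  b <- unlist(lapply(.GATES, function(g) {
    if (isTRUE(w$bias_enabled)) w[[paste0("b_", g)]] else numeric(w$hidden_dim)
  }), use.names = FALSE)
  c(as.numeric(U), as.numeric(W), b)
}

# Full flat parameter vector (gate blocks + head) for uni/bidirectional.
weights_to_theta <- function(weights) {
  if (inherits(weights, "lstm_weights")) {
    c(.dir_theta(weights), weights$w_out, weights$b_out)
  } else if (inherits(weights, "bilstm_weights")) {
    c(.dir_theta(weights$forward), .dir_theta(weights$backward),
      weights$w_out, weights$b_out)
  } else stop("unsupported weights object", call. = FALSE)
}

# Inverse of weights_to_theta for the unidirectional case.
theta_to_weights <- function(theta, input_dim, hidden_dim, bias_enabled = TRUE) {
  D <- input_dim; H <- hidden_dim
  w <- lstm_weights(D, H, init = "zero", bias_enabled = bias_enabled)
  pos <- 0L
  take <- function(k) {
    out <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  Uall <- matrix(take(4L * D * H), D, 4L * H)
  Wall <- matrix(take(4L * H * H), H, 4L * H)
  ball <- take(4L * H)
  for (gi in seq_along(.GATES)) {
    cols <- ((gi - 1L) * H + 1L):(gi * H)
    w[[paste0("U_", .GATES[gi])]] <- Uall[, cols, drop = FALSE]
    w[[paste0("W_", .GATES[gi])]] <- Wall[, cols, drop = FALSE]
    w[[paste0("b_", .GATES[gi])]] <- ball[cols]
  }
  w$w_out <- take(H)
  w$b_out <- take(1L)
  w
}

#' Run an LSTM over a whole series
#'
#' Iterates [cell_step()] left to right from the zero state (or a supplied
#' initial state) and returns the final state together with the full
#' hidden-state trajectory.
#'
#' @param series Numeric matrix, one row per time step, `input_dim` columns.
#' @param weights An [lstm_weights()].
#' @param initial_state Optional list with `H` and `C`; default zero.
#' @return List with `H` and `C` (final state) and matrix `hidden`
#'   (`nrow(series) x hidden_dim`, hidden state after every step).
#' @export
forward_sequence <- function(series, weights, initial_state = NULL) {
  stopifnot(inherits(weights, "lstm_weights"))
  series <- as.matrix(series)
  if (nrow(series) < 1L) stop("series must contain at least one time step", call. = FALSE)
  if (ncol(series) != weights$input_dim) {
    stop(sprintf("series has %d columns, expected %d", ncol(series),
                 weights$input_dim), call. = FALSE)
  }
  if (any(!is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  H <- weights$hidden_dim
  if (is.null(initial_state)) {
    st <- cpp_forward_states(series, .dir_theta(weights),
                             weights$input_dim, H)
    T_ <- nrow(series)
    return(list(H = st$hidden[T_, ], C = st$cell[T_, ], hidden = st$hidden))
  }
  state <- initial_state
  hid <- matrix(NA_real_, nrow(series), H)
  for (t in seq_len(nrow(series))) {
    state <- cell_step(series[t, ], state, weights)
    hid[t, ] <- state$H
  }
  list(H = state$H, C = state$C, hidden = hid)
}

#' Predict length of stay from a denoised, normalized series
#'
#' Runs the LSTM (or BiLSTM) over the series and applies the linear head to
#' the final hidden state: `w_out . H_T + b_out`, in days. No clamping is
#' applied here; reporting layers may floor at zero.
#'
#' @param series Numeric matrix, one row per time step (already windowed,
#'   denoised and normalized).
#' @param weights An [lstm_weights()] or [bilstm_weights()].
#' @return A single finite numeric value (days).
#' @export
predict_los <- function(series, weights) {
  series <- as.matrix(series)
  if (nrow(series) < 1L) {
    stop(paste("series has no time steps after denoising;",
               "use a smaller wavelet/level or a longer window"), call. = FALSE)
  }
  if (inherits(weights, "lstm_weights")) {
    fs <- forward_sequence(series, weights)
    return(sum(weights$w_out * fs$H) + weights$b_out)
  }
  stopifnot(inherits(weights, "bilstm_weights"))
  h_f <- forward_sequence(series, weights$forward)$H
  h_b <- forward_sequence(series[rev(seq_len(nrow(series))), , drop = FALSE],
                          weights$backward)$H
  sum(weights$w_out * c(h_f, h_b)) + weights$b_out
}
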