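test_that("zero weights give half-open gates and an exactly zero state", {
  w <- lstm_weights(3, 4, init = "zero")
  st <- cell_step(c(0.3, -1, 2), NULL, w, details = TRUE)
  expect_equal(st$f, rep(0.5, 4))
  expect_equal(st$i, rep(0.5, 4))
  expect_equal(st$o, rep(0.5, 4))
  expect_equal(st$c_tilde, rep(0, 4))
  expect_equal(st$C, rep(0, 4))
  expect_equal(st$H, rep(0, 4))
})

test_that("the scalar hand-worked cell case matches", {
  w <- lstm_weights(1, 1, init = "zero")
  for (g in c("f", "c", "i", "o")) {
    w[[paste0("U_", g)]] <- matrix(1, 1, 1)
    w[[paste0("W_", g)]] <- matrix(1, 1, 1)
  }
  st <- cell_step(0, list(H = 0, C = 1), w)
  expect_equal(st$C, 0.5)                       # 0.5 * 1 + 0.5 * 0
  expect_equal(st$H, 0.5 * tanh(0.5))           # ~ 0.231059
  expect_equal(st$H, 0.231059, tolerance = 1e-5)
  # composed with a pass-through head, single step
  w$w_out <- 1; w$b_out <- 0
  fs <- forward_sequence(matrix(0, 1, 1), w, initial_state = list(H = 0, C = 1))
  expect_equal(sum(w$w_out * fs$H) + w$b_out, 0.5 * tanh(0.5))
})

test_that("gates stay in (0,1), candidates in (-1,1), hidden states bounded by 1", {
  set.seed(41)
  for (r in 1:10) {
    w <- random_weights(3, 5, range = 2)
    st <- cell_step(rnorm(3), list(H = runif(5, -0.9, 0.9), C = rnorm(5)), w,
                    details = TRUE)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(st$c_tilde > -1 & st$c_tilde < 1))
    X <- matrix(rnorm(60, sd = 3), 20, 3)
    fs <- forward_sequence(X, w)
    expect_lt(max(abs(fs$hidden)), 1)
  }
})

test_that("forward_sequence matches the independent equation-by-equation loop", {
  set.seed(43)
  for (r in 1:20) {
    bias <- r %% 2 == 0
    w <- random_weights(3, sample(2:6, 1), range = 0.8, bias_enabled = bias)
    X <- matrix(rnorm(3 * sample(1:15, 1)), ncol = 3)
    got <- forward_sequence(X, w)
    want <- oracle_lstm_forward(X, w)
    expect_lt(max(abs(got$H - want$H)), 1e-12)
    expect_lt(max(abs(got$C - want$C)), 1e-12)
    expect_lt(max(abs(got$hidden - want$hidden)), 1e-12)
  }
})

test_that("a length-1 series equals a single cell step; zero weights give zero output", {
  set.seed(47)
  w <- random_weights(3, 4)
  x <- rnorm(3)
  fs <- forward_sequence(matrix(x, 1, 3), w)
  st <- cell_step(x, NULL, w)
  expect_equal(fs$H, st$H, tolerance = 1e-14)
  expect_equal(fs$C, st$C, tolerance = 1e-14)
  wz <- lstm_weights(3, 4, init = "zero")
  fz <- forward_sequence(matrix(rnorm(30), 10, 3), wz)
  expect_true(all(fz$hidden == 0))
})

test_that("predict_los applies the linear head to the final hidden state", {
  set.seed(53)
  X <- matrix(rnorm(24), 8, 3)
  w <- random_weights(3, 4)
  w$w_out <- rep(0, 4); w$b_out <- 3
  expect_equal(predict_los(X, w), 3)
  wz <- lstm_weights(3, 4, init = "zero")
  wz$w_out <- rnorm(4); wz$b_out <- -1.25
  expect_equal(predict_los(X, wz), -1.25)  # hidden state identically zero
  expect_error(predict_los(X[0, , drop = FALSE], w), "no time steps")
})

test_that("predictions are deterministic and validate their inputs", {
  set.seed(59)
  w <- random_weights(3, 6)
  X <- matrix(rnorm(45), 15, 3)
  expect_identical(predict_los(X, w), predict_los(X, w))
  expect_error(forward_sequence(X[, 1:2], w), "expected 3")
  expect_error(cell_step(c(1, 2), NULL, w), "length 3")
  expect_error(cell_step(c(1, 2, Inf), NULL, w), "non-finite")
  expect_error(cell_step(c(1, 2, 3), list(H = rep(NaN, 6), C = rep(0, 6)), w),
               "non-finite")
})

test_that("a BiLSTM with its backward half zeroed reproduces the unidirectional model", {
  set.seed(61)
  fw <- random_weights(3, 4)
  bw <- lstm_weights(3, 4, init = "zero")
  head_w <- c(rnorm(4), rep(0, 4))
  bi <- bilstm_weights(fw, bw, w_out = head_w, b_out = 0.7)
  uni <- fw; uni$w_out <- head_w[1:4]; uni$b_out <- 0.7
  X <- matrix(rnorm(36), 12, 3)
  expect_equal(predict_los(X, bi), predict_los(X, uni), tolerance = 1e-12)
  # and an active backward half changes the prediction
  bw2 <- random_weights(3, 4)
  bi2 <- bilstm_weights(fw, bw2, w_out = c(head_w[1:4], rnorm(4)), b_out = 0.7)
  expect_false(isTRUE(all.equal(predict_los(X, bi2), predict_los(X, uni))))
})

test_that("analytic gradients match central finite differences", {
  set.seed(67)
  for (bidir in c(FALSE, TRUE)) {
    H <- 3L
    gate <- 4L * 3L * H + 4L * H * H + 4L * H
    n_th <- if (bidir) 2L * gate + 2L * H + 1L else gate + H + 1L
    th <- runif(n_th, -0.4, 0.4)
    X <- lapply(1:4, function(i) matrix(rnorm(3 * sample(2:7, 1)), ncol = 3))
    y <- rnorm(4, 3)
    got <- wtlstm:::cpp_loss_grad(X, y, th, 3L, H, bidir)
    eps <- 1e-6
    fd <- vapply(seq_along(th), function(j) {
      tp <- th; tp[j] <- tp[j] + eps
      tm <- th; tm[j] <- tm[j] - eps
      (wtlstm:::cpp_loss_grad(X, y, tp, 3L, H, bidir)$loss -
         wtlstm:::cpp_loss_grad(X, y, tm, 3L, H, bidir)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(fd - got$grad)), 1e-6)
  }
})
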