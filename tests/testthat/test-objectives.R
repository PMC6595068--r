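test_that("loss specs validate their fields", {
  expect_error(loss_spec("Convex_HF_lastHF"), "alpha")
  expect_error(loss_spec("LastHF", alpha = 0.5), "convex")
  expect_error(loss_spec("LastHF", p_dropout = 1), "0, 1")
  expect_error(loss_spec("LastHF", lambda = -1), ">= 0")
  expect_s3_class(loss_spec("Convex_HF_NonHF", alpha = 0.3), "loss_spec")
})

test_that("per-step cross-entropy matches its closed forms", {
  expect_identical(step_loss(1L, c(0, 1), 1), 0)
  expect_equal(step_loss(1L, c(0.5, 0.5), 1), log(2))
  expect_equal(step_loss(0L, c(0.5, 0.5), 2), 2 * log(2))
  expect_error(step_loss(1L, c(0.7, 0.6)), "distribution")
  expect_error(step_loss(2L, c(0.5, 0.5)), "0 or 1")
  # clamped at p >= 1e-12
  expect_lt(step_loss(1L, c(1, 0), 1), 28)
})

rand_seq <- function() {
  T_len <- sample(1:6, 1)
  y <- rbinom(T_len, 1, 0.5)
  hf <- rbinom(T_len, 1, 0.6)
  hf[T_len] <- 1L
  p1 <- runif(T_len, 0.05, 0.95)
  list(y = y, hf = hf, probs = cbind(1 - p1, p1), T_len = T_len)
}

test_that("objectives degenerate correctly on a single-event timeline", {
  set.seed(51)
  for (i in 1:50) {
    p1 <- runif(1, 0.05, 0.95)
    probs <- matrix(c(1 - p1, p1), 1)
    y <- rbinom(1, 1, 0.5)
    a <- runif(1)
    ref <- step_loss(y, probs[1, ])
    for (spec in list(loss_spec("LastHF"), loss_spec("Uniform_HF"),
                      loss_spec("Convex_HF_lastHF", alpha = a)))
      expect_equal(sequence_loss(y, probs, 1L, spec), ref)
    # the non-HF average term is defined as 0 when no non-HF events exist
    expect_equal(sequence_loss(y, probs, 1L,
                               loss_spec("Convex_HF_NonHF", alpha = a)),
                 a * ref)
  }
})

test_that("convex endpoints reduce to the pure objectives", {
  set.seed(52)
  for (i in 1:200) {
    s <- rand_seq()
    at1 <- sequence_loss(s$y, s$probs, s$hf,
                         loss_spec("Convex_HF_lastHF", alpha = 1))
    expect_equal(at1, sequence_loss(s$y, s$probs, s$hf,
                                    loss_spec("Uniform_HF")), tolerance = 0)
    at0 <- sequence_loss(s$y, s$probs, s$hf,
                         loss_spec("Convex_HF_lastHF", alpha = 0))
    expect_equal(at0, sequence_loss(s$y, s$probs, s$hf,
                                    loss_spec("LastHF")), tolerance = 0)
  }
})

test_that("a hand-computed three-event example matches all four kinds", {
  # events: HF, non-HF, HF(last); labels 1, 0, 1
  y <- c(1L, 0L, 1L)
  hf <- c(1L, 0L, 1L)
  probs <- rbind(c(0.3, 0.7), c(0.6, 0.4), c(0.2, 0.8))
  l <- c(-log(0.7), -log(0.6), -log(0.8))  # per-step CE, by hand
  a <- 0.4
  expect_equal(sequence_loss(y, probs, hf, loss_spec("LastHF")), l[3])
  expect_equal(sequence_loss(y, probs, hf, loss_spec("Uniform_HF")),
               mean(l[c(1, 3)]))
  expect_equal(
    sequence_loss(y, probs, hf, loss_spec("Convex_HF_lastHF", alpha = a)),
    a * mean(l[c(1, 3)]) + (1 - a) * l[3])
  expect_equal(
    sequence_loss(y, probs, hf, loss_spec("Convex_HF_NonHF", alpha = a)),
    a * mean(l[c(1, 3)]) + (1 - a) * l[2])
  # with class weights multiplying per-step losses
  cw <- c("0" = 2, "1" = 0.5)
  lw <- l * c(0.5, 2, 0.5)
  expect_equal(
    sequence_loss(y, probs, hf, loss_spec("Uniform_HF"), cw),
    mean(lw[c(1, 3)]))
})

test_that("the non-HF average term is zero when no non-HF events exist", {
  y <- c(1L, 0L); hf <- c(1L, 1L)
  probs <- rbind(c(0.4, 0.6), c(0.7, 0.3))
  a <- 0.6
  expect_equal(
    sequence_loss(y, probs, hf, loss_spec("Convex_HF_NonHF", alpha = a)),
    a * mean(c(-log(0.6), -log(0.7))))
})

test_that("objectives are nonnegative and vanish only at perfection", {
  set.seed(53)
  for (i in 1:50) {
    s <- rand_seq()
    spec <- loss_spec("Uniform_HF")
    expect_gte(sequence_loss(s$y, s$probs, s$hf, spec), 0)
  }
  perfect <- rbind(c(1, 0), c(0, 1))
  expect_equal(sequence_loss(c(0L, 1L), perfect, c(1L, 1L),
                             loss_spec("Uniform_HF")), 0)
})

test_that("total objective adds the L2 term and excludes biases", {
  losses <- c(1, 3)
  expect_equal(total_objective(losses), 2)
  theta <- list(W = matrix(c(1, 1, 1, 1), 2), by = c(100, 100))
  expect_equal(total_objective(losses, theta, lambda = 0.1), 2 + 0.2)
  expect_equal(total_objective(losses, list(W = matrix(0, 2, 2)), 5), 2)
})

test_that("batched step weights agree with the per-sequence definition", {
  set.seed(54)
  for (i in 1:30) {
    s <- rand_seq()
    spec <- list(loss_spec("LastHF"), loss_spec("Uniform_HF"),
                 loss_spec("Convex_HF_lastHF", alpha = runif(1)),
                 loss_spec("Convex_HF_NonHF", alpha = runif(1)))[[sample(4, 1)]]
    ref <- readmitr:::loss_step_weights(s$y, s$hf, spec)
    t_max <- s$T_len + sample(0:2, 1)
    pad <- function(v) c(v, rep(0L, t_max - s$T_len))
    batch <- structure(list(
      X = array(0, c(1, t_max, 2)),
      mask = matrix(seq_len(t_max) <= s$T_len, 1),
      y = matrix(pad(s$y), 1), hf = matrix(pad(s$hf), 1),
      len = s$T_len, n = 1L, d = 2L, t_max = t_max), class = "seq_batch")
    W <- readmitr:::batch_step_weights(batch, spec)
    expect_equal(as.numeric(W[1, seq_len(s$T_len)]), ref)
    expect_true(all(W[1, -seq_len(s$T_len)] == 0))
  }
})
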