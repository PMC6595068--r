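test_that("potential containers validate their shapes", {
  expect_error(chain_potentials(matrix(0, 2, 3), matrix(0, 2, 2)), "2 columns")
  expect_error(chain_potentials(matrix(0, 2, 2), matrix(0, 3, 2)), "2 x 2")
  expect_error(chain_potentials(matrix(0, 3, 2), array(0, c(2, 2, 2)),
                                "Pairwise"), "T x 2 x 2")
  expect_error(chain_potentials(matrix(c(0, NA), 1), matrix(0, 2, 2)),
               "finite")
})

test_that("sequence scores match direct summation", {
  pot <- chain_potentials(matrix(c(3, 7), 1), matrix(0, 2, 2))
  expect_equal(sequence_score(pot, 0L), 3)
  expect_equal(sequence_score(pot, 1L), 7)
  zero <- chain_potentials(matrix(0, 4, 2), matrix(0, 2, 2))
  for (i in 1:5) expect_equal(sequence_score(zero, rbinom(4, 1, 0.5)), 0)
  set.seed(61)
  for (variant in c("Unary", "Pairwise")) {
    pot <- random_potentials(4, variant)
    y <- rbinom(4, 1, 0.5)
    expect_equal(sequence_score(pot, y), enum_score_one(pot, y))
  }
  expect_error(sequence_score(pot, c(0L, 1L)), "length")
})

test_that("log partition matches closed forms and enumeration", {
  for (T_len in c(1, 3, 6)) {
    zero <- chain_potentials(matrix(0, T_len, 2), matrix(0, 2, 2))
    expect_equal(log_partition(zero), T_len * log(2))
  }
  set.seed(62)
  for (i in 1:100) {
    T_len <- sample(1:8, 1)
    variant <- sample(c("Unary", "Pairwise"), 1)
    pot <- random_potentials(T_len, variant, scale = 2)
    expect_equal(log_partition(pot), enum_oracle(pot)$logZ, tolerance = 1e-8)
  }
  # shifting every unary row by c shifts log Z by T*c
  pot <- random_potentials(5, "Unary")
  shifted <- chain_potentials(pot$unary + 1.7, pot$pairwise, "Unary")
  expect_equal(log_partition(shifted), log_partition(pot) + 5 * 1.7)
})

test_that("the NLL is a proper nonnegative conditional log-likelihood", {
  # overwhelming margin toward the true labeling
  y <- c(1L, 0L, 1L)
  un <- matrix(0, 3, 2)
  un[cbind(1:3, y + 1)] <- 50
  pot <- chain_potentials(un, matrix(0, 2, 2))
  expect_lt(crf_nll(pot, y), 1e-10)
  zero <- chain_potentials(matrix(0, 4, 2), matrix(0, 2, 2))
  expect_equal(crf_nll(zero, c(0L, 0L, 0L, 0L)), 4 * log(2))
  set.seed(63)
  for (i in 1:50) {
    T_len <- sample(1:7, 1)
    pot <- random_potentials(T_len, sample(c("Unary", "Pairwise"), 1))
    y <- rbinom(T_len, 1, 0.5)
    or <- enum_oracle(pot)
    p_y <- exp(enum_score_one(pot, y) - or$logZ)
    expect_equal(crf_nll(pot, y), -log(p_y), tolerance = 1e-8)
    expect_gte(crf_nll(pot, y), 0)
  }
})

test_that("marginals match enumeration and factorize without coupling", {
  zero <- chain_potentials(matrix(0, 3, 2), matrix(0, 2, 2))
  expect_equal(crf_marginals(zero), matrix(0.5, 3, 2))
  set.seed(64)
  for (i in 1:100) {
    T_len <- sample(1:8, 1)
    pot <- random_potentials(T_len, sample(c("Unary", "Pairwise"), 1), 2)
    m <- crf_marginals(pot)
    expect_equal(unname(rowSums(m)), rep(1, T_len), tolerance = 1e-9)
    expect_equal(unname(m), unname(enum_oracle(pot)$marg), tolerance = 1e-8)
  }
  # pairwise == 0 (Unary variant): marginals are per-step softmaxes
  pot <- chain_potentials(matrix(rnorm(8), 4, 2), matrix(0, 2, 2))
  sm <- t(apply(pot$unary, 1, function(u) exp(u) / sum(exp(u))))
  expect_equal(unname(crf_marginals(pot)), sm, tolerance = 1e-10)
})

test_that("Viterbi attains the enumeration maximum with 0-biased ties", {
  un <- matrix(0, 3, 2)
  un[cbind(1:3, c(2, 1, 2))] <- 10
  pot <- chain_potentials(un, matrix(0, 2, 2))
  expect_identical(crf_viterbi(pot), c(1L, 0L, 1L))
  zero <- chain_potentials(matrix(0, 5, 2), matrix(0, 2, 2))
  expect_identical(crf_viterbi(zero), rep(0L, 5))
  set.seed(65)
  for (i in 1:100) {
    T_len <- sample(1:8, 1)
    pot <- random_potentials(T_len, sample(c("Unary", "Pairwise"), 1), 2)
    y_hat <- crf_viterbi(pot)
    expect_equal(sequence_score(pot, y_hat), enum_oracle(pot)$max_score,
                 tolerance = 1e-9)
  }
})

test_that("log-space inference stays finite under 100x score scaling", {
  set.seed(66)
  for (variant in c("Unary", "Pairwise")) {
    pot <- random_potentials(6, variant, scale = 100)
    expect_true(is.finite(log_partition(pot)))
    m <- crf_marginals(pot)
    expect_true(all(is.finite(m)))
    expect_true(is.finite(crf_nll(pot, rbinom(6, 1, 0.5))))
  }
})

test_that("batched inference agrees with the per-sequence reference", {
  set.seed(67)
  for (variant in c("Unary", "Pairwise")) {
    n <- 7; t_max <- 5
    len <- sample(1:t_max, n, replace = TRUE)
    U <- array(rnorm(n * t_max * 2), c(n, t_max, 2))
    A <- matrix(rnorm(4), 2, 2)
    P <- array(rnorm(n * t_max * 4), c(n, t_max, 4))
    inf <- readmitr:::crf_batch_infer(U, if (variant == "Pairwise") P,
                                      if (variant == "Unary") A, len, variant)
    for (b in 1:n) {
      pw <- if (variant == "Unary") A else {
        arr <- array(0, c(len[b], 2, 2))
        for (t in seq_len(len[b])) {
          arr[t, 1, 1] <- P[b, t, 1]; arr[t, 1, 2] <- P[b, t, 2]
          arr[t, 2, 1] <- P[b, t, 3]; arr[t, 2, 2] <- P[b, t, 4]
        }
        arr
      }
      pot <- chain_potentials(matrix(U[b, seq_len(len[b]), ], len[b], 2),
                              pw, variant)
      expect_equal(inf$logZ[b], log_partition(pot), tolerance = 1e-10)
      marg <- crf_marginals(pot)
      expect_equal(exp(inf$la[b, len[b], 2] - inf$logZ[b]),
                   marg[len[b], 2], tolerance = 1e-10)
    }
  }
})
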