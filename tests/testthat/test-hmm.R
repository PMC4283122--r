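test_that("supervised initialization reproduces hand-computed frequency ratios", {
  # two 3-state annotated sequences: Drug->Kw->Se and Drug->Se->Kw
  # (state indices: 1 = Drug, 2 = Se, 3 = Kw), no smoothing
  data <- list(list(symbols = c(1L, 3L, 2L), states = c(1L, 3L, 2L)),
               list(symbols = c(1L, 2L, 3L), states = c(1L, 2L, 3L)))
  m <- init_from_annotations(data, N = 3, M = 3, pseudocount = 0)
  expect_equal(m$pi, c(1, 0, 0))
  expect_equal(m$A[1, ], c(0, 0.5, 0.5))   # Drug -> Se / Kw equally often
  expect_equal(m$A[2, ], c(0, 0, 1))
  expect_equal(m$A[3, ], c(0, 1, 0))
  expect_equal(rowSums(m$A), rep(1, 3))
  expect_equal(rowSums(m$B), rep(1, 3))
})

test_that("supervised initialization agrees with an independent counting oracle", {
  withr::local_seed(21)
  N <- 2; M <- 2
  data <- replicate(8, {
    T_ <- sample(2:6, 1)
    list(symbols = sample.int(M, T_, replace = TRUE),
         states = sample.int(N, T_, replace = TRUE))
  }, simplify = FALSE)
  pc <- 0.5
  m <- init_from_annotations(data, N = N, M = M, pseudocount = pc)
  # brute-force count-and-divide
  starts <- numeric(N); trans <- matrix(0, N, N); emit <- matrix(0, N, M)
  for (d in data) {
    starts[d$states[1]] <- starts[d$states[1]] + 1
    for (t in seq_along(d$states)) {
      emit[d$states[t], d$symbols[t]] <- emit[d$states[t], d$symbols[t]] + 1
      if (t > 1) trans[d$states[t - 1], d$states[t]] <-
          trans[d$states[t - 1], d$states[t]] + 1
    }
  }
  expect_equal(m$pi, (starts + pc) / sum(starts + pc), tolerance = 1e-12)
  expect_equal(m$A, (trans + pc) / rowSums(trans + pc), tolerance = 1e-12)
  expect_equal(m$B, (emit + pc) / rowSums(emit + pc), tolerance = 1e-12)
})

test_that("a state with zero counts and no pseudocount cannot be normalised", {
  data <- list(list(symbols = c(1L, 1L), states = c(1L, 1L)))
  expect_error(init_from_annotations(data, N = 2, M = 1, pseudocount = 0),
               "zero total count")
})

test_that("Viterbi and forward likelihood agree with exhaustive enumeration", {
  withr::local_seed(31)
  for (rep in 1:25) {
    N <- sample(2:4, 1); M <- sample(2:5, 1)
    model <- random_hmm(N, M)
    T_ <- sample(1:6, 1)
    sy <- sample.int(M, T_, replace = TRUE)
    or <- enum_oracle(model, sy)
    v <- viterbi(model, sy)
    expect_equal(v$loglik, or$best_logprob, tolerance = 1e-10)
    expect_equal(log(path_joint_prob(model, v$path, sy)), v$loglik,
                 tolerance = 1e-12)
    expect_equal(sequence_loglik(model, sy), or$loglik, tolerance = 1e-10)
    # sum over paths is at least the best single path
    expect_gte(sequence_loglik(model, sy), v$loglik - 1e-12)
  }
})

test_that("single-state decoding and degenerate likelihoods are exact", {
  m1 <- hmm_model(1, matrix(1, 1, 1), matrix(c(0.3, 0.7), 1, 2))
  sy <- c(1L, 2L, 2L)
  v <- viterbi(m1, sy)
  expect_equal(v$path, rep(1L, 3))
  expect_equal(v$loglik, sum(log(m1$B[1, sy])))
  # deterministic one-symbol model emits with probability one
  det <- hmm_model(1, matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(sequence_loglik(det, rep(1L, 50)), 0)
  expect_equal(viterbi(m1, integer(0))$path, integer(0))
  expect_equal(viterbi(m1, integer(0))$loglik, 0)
  expect_equal(sequence_loglik(m1, integer(0)), 0)
  expect_error(viterbi(m1, 3L), "out of range")
  expect_error(sequence_loglik(m1, 0L), "out of range")
})

test_that("Viterbi ties break toward the lowest state index", {
  # two exchangeable states: every path has equal probability
  m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
                 matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  v <- viterbi(m, c(1L, 2L, 1L))
  expect_equal(v$path, c(1L, 1L, 1L))
})

test_that("Baum-Welch keeps a fixed point fixed", {
  # deterministic chain whose one-hot rows already explain its sequence
  pi <- c(1, 0)
  A <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)  # 1 -> 2 -> 2 ...
  B <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)  # state i emits symbol i
  m <- hmm_model(pi, A, B)
  bw <- baum_welch(m, list(c(1L, 2L, 2L, 2L)), tol = 1e-8, max_iter = 5)
  expect_equal(bw$model$pi, pi)
  expect_equal(bw$model$A, A)
  expect_equal(bw$model$B, B)
  expect_true(bw$report$converged)
})

test_that("Baum-Welch log-likelihood trace is non-decreasing and the final model improves", {
  withr::local_seed(41)
  for (rep in 1:8) {
    N <- sample(2:4, 1); M <- sample(2:4, 1)
    model <- random_hmm(N, M)
    seqs <- replicate(4, sample.int(M, sample(3:10, 1), replace = TRUE),
                      simplify = FALSE)
    bw <- baum_welch(model, seqs, tol = 1e-6, max_iter = 25)
    tr <- bw$report$loglik_trace
    expect_true(all(diff(tr) >= -1e-8))
    ll0 <- sum(vapply(seqs, sequence_loglik, numeric(1), model = model))
    ll1 <- sum(vapply(seqs, sequence_loglik, numeric(1), model = bw$model))
    expect_gte(ll1, ll0 - 1e-8)
    validate_model <- bw$model
    expect_equal(sum(validate_model$pi), 1, tolerance = 1e-9)
    expect_equal(rowSums(validate_model$A), rep(1, N), tolerance = 1e-9)
    expect_equal(rowSums(validate_model$B), rep(1, N), tolerance = 1e-9)
  }
})

test_that("one E-step matches the path-enumeration oracle on a 2-state toy", {
  withr::local_seed(51)
  for (rep in 1:10) {
    model <- random_hmm(2, 2)
    sy <- sample.int(2, sample(2:6, 1), replace = TRUE)
    est <- adrminer:::hmm_estep(model, sy)
    or <- enum_estep(model, sy)
    expect_equal(est$gamma, or$gamma, tolerance = 1e-10)
    expect_equal(est$xi_sum, or$xi_sum, tolerance = 1e-10)
  }
})

test_that("refining a supervised fit on its own annotated data keeps likelihood", {
  withr::local_seed(61)
  N <- 3; M <- 4
  data <- replicate(6, {
    T_ <- sample(3:8, 1)
    list(symbols = sample.int(M, T_, replace = TRUE),
         states = sample.int(N, T_, replace = TRUE))
  }, simplify = FALSE)
  m0 <- init_from_annotations(data, N = N, M = M, pseudocount = 0.1)
  seqs <- lapply(data, `[[`, "symbols")
  ll0 <- sum(vapply(seqs, sequence_loglik, numeric(1), model = m0))
  bw <- baum_welch(m0, seqs, tol = 1e-6, max_iter = 50)
  ll1 <- sum(vapply(seqs, sequence_loglik, numeric(1), model = bw$model))
  expect_gte(ll1, ll0 - 1e-8)
})

test_that("model JSON serialization round-trips exactly", {
  withr::local_seed(71)
  model <- random_hmm(4, 6)
  model$symbol_table <- stats::setNames(1:6, c("<drug>", "<se>", "<kw>",
                                               "<unk>", "pain", "taking"))
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm(model, f)
  back <- read_hmm(f)
  expect_equal(back$pi, model$pi, tolerance = 1e-15)
  expect_equal(back$A, model$A, tolerance = 1e-15)
  expect_equal(back$B, model$B, tolerance = 1e-15)
  expect_equal(back$state_labels, model$state_labels)
  expect_equal(names(back$symbol_table), names(model$symbol_table))
})

test_that("invalid models are rejected", {
  expect_error(hmm_model(c(0.5, 0.4), matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               "sum to 1")
  expect_error(hmm_model(c(0.5, 0.5), matrix(c(0.9, 0.2, 0.2, 0.8), 2, 2),
                         matrix(0.5, 2, 2)), "sum to 1")
  expect_error(hmm_model(c(1.5, -0.5), matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               "non-negative")
})
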