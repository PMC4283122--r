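#' Construct a discrete-emission hidden Markov model
#'
#' The message model is an ergodic four-state HMM over
#' \{Drug, SideEffect, Keyword, Other\}: every state can reach every other,
#' so drug, side-effect and keyword mentions may appear in any order in a
#' forum post. Start/End are not hidden states: the start is encoded by the
#' initial distribution and the end is unmodelled.
#'
#' @param pi Initial state probability vector (length N, sums to 1).
#' @param A N x N state transition matrix (rows sum to 1).
#' @param B N x M observation (emission) matrix (rows sum to 1).
#' @param state_labels Character vector of state names; defaults to the
#'   four message-model states when N = 4.
#' @param symbol_table Optional named integer vector mapping observation
#'   identifiers/words to symbol indices (see \code{\link{build_vocab}}).
#' @return An object of class \code{adr_hmm} with elements \code{N},
#'   \code{M}, \code{pi}, \code{A}, \code{B}, \code{state_labels},
#'   \code{symbol_table}.
#' @export
hmm_model <- function(pi, A, B, state_labels = NULL, symbol_table = NULL) {
  pi <- as.numeric(pi)
  A <- as.matrix(A); B <- as.matrix(B)
  N <- length(pi); M <- ncol(B)
  if (is.null(state_labels))
    state_labels <- if (N == 4L) .adr_states else paste0("S", seq_len(N))
  model <- structure(
    list(N = N, M = M, pi = pi, A = A, B = B,
         state_labels = state_labels, symbol_table = symbol_table),
    class = "adr_hmm"
  )
  validate_hmm(model)
  model
}

validate_hmm <- function(model, tol = 1e-9) {
  with(model, {
    if (nrow(A) != N || ncol(A) != N) stop("A must be N x N")
    if (nrow(B) != N) stop("B must have N rows")
    if (length(state_labels) != N) stop("state_labels must have length N")
    if (any(pi < 0) || any(A < 0) || any(B < 0))
      stop("probabilities must be non-negative")
    if (abs(sum(pi) - 1) > tol) stop("pi must sum to 1")
    if (any(abs(rowSums(A) - 1) > tol)) stop("rows of A must sum to 1")
    if (any(abs(rowSums(B) - 1) > tol)) stop("rows of B must sum to 1")
  })
  invisible(model)
}

#' @export
print.adr_hmm <- function(x, ...) {
  cat(sprintf("<adr_hmm> N=%d states (%s), M=%d symbols\n",
              x$N, paste(x$state_labels, collapse = ", "), x$M))
  invisible(x)
}

check_symbols <- function(model, symbols) {
  symbols <- as.integer(symbols)
  if (length(symbols) && (any(symbols < 1L) || any(symbols > model$M)))
    stop("observation symbol out of range [1, M]")
  symbols
}

#' Supervised initialization from annotated sequences
#'
#' Estimates the initial, transition and emission probabilities by counting
#' frequencies in state-annotated observation sequences: how often
#' sequences start in each state, how often each state transition occurs,
#' and how often each symbol is emitted from each state. A Laplace
#' pseudocount (default 1) smooths zero counts so that Baum-Welch
#' refinement is never locked out of a transition or emission.
#'
#' @param data List of annotated sequences, each a list with equal-length
#'   integer vectors \code{symbols} (in 1..M) and \code{states} (in 1..N).
#' @param N Number of states (default 4, the message model).
#' @param M Number of observation symbols.
#' @param pseudocount Additive smoothing constant (>= 0; with 0, a state
#'   with no counts in some row is an error because the row cannot be
#'   normalised).
#' @param state_labels,symbol_table Passed to \code{\link{hmm_model}}.
#' @return An \code{adr_hmm}.
#' @export
init_from_annotations <- function(data, N = 4L, M, pseudocount = 1,
                                  state_labels = NULL, symbol_table = NULL) {
  stopifnot(length(data) > 0, pseudocount >= 0)
  starts <- numeric(N)
  trans <- matrix(0, N, N)
  emit <- matrix(0, N, M)
  for (d in data) {
    st <- as.integer(d$states); sy <- as.integer(d$symbols)
    if (length(st) != length(sy) || length(st) < 1L)
      stop("states and symbols must be equal-length and non-empty")
    if (any(st < 1L | st > N)) stop("state index out of range")
    if (any(sy < 1L | sy > M)) stop("symbol index out of range")
    starts[st[1L]] <- starts[st[1L]] + 1
    T_ <- length(st)
    if (T_ > 1L) {
      for (t in seq_len(T_ - 1L))
        trans[st[t], st[t + 1L]] <- trans[st[t], st[t + 1L]] + 1
    }
    for (t in seq_len(T_))
      emit[st[t], sy[t]] <- emit[st[t], sy[t]] + 1
  }
  pi <- normalize_row(starts + pseudocount, "initial state")
  A <- t(apply(trans + pseudocount, 1L, normalize_row, what = "transition"))
  B <- t(apply(emit + pseudocount, 1L, normalize_row, what = "emission"))
  hmm_model(pi, A, B, state_labels = state_labels, symbol_table = symbol_table)
}

normalize_row <- function(x, what = "probability") {
  s <- sum(x)
  if (s <= 0)
    stop(sprintf("cannot normalise %s row with zero total count (use a pseudocount > 0)",
                 what))
  x / s
}

# scaled forward pass: returns normalised alpha (T x N), per-step scale
# factors s_t (sum of unnormalised alpha), and log-likelihood sum(log s_t)
hmm_forward <- function(model, symbols) {
  T_ <- length(symbols)
  N <- model$N
  alpha <- matrix(0, T_, N)
  s <- numeric(T_)
  a <- model$pi * model$B[, symbols[1L]]
  s[1L] <- sum(a)
  if (s[1L] <= 0) return(list(alpha = alpha, scale = s, loglik = -Inf))
  alpha[1L, ] <- a / s[1L]
  if (T_ > 1L) {
    for (t in 2L:T_) {
      a <- (alpha[t - 1L, ] %*% model$A)[1L, ] * model$B[, symbols[t]]
      s[t] <- sum(a)
      if (s[t] <= 0) return(list(alpha = alpha, scale = s, loglik = -Inf))
      alpha[t, ] <- a / s[t]
    }
  }
  list(alpha = alpha, scale = s, loglik = sum(log(s)))
}

# scaled backward pass using the forward scale factors
hmm_backward <- function(model, symbols, scale) {
  T_ <- length(symbols)
  N <- model$N
  beta <- matrix(0, T_, N)
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      beta[t, ] <- (model$A %*% (model$B[, symbols[t + 1L]] * beta[t + 1L, ]))[, 1L] /
        scale[t + 1L]
    }
  }
  beta
}

#' Forward-algorithm log-likelihood of a sequence
#'
#' \code{log P(observations | model)}, summed over all hidden state paths,
#' computed with per-step scaling so that long messages do not underflow.
#' An empty sequence has log-likelihood 0 (probability 1).
#'
#' @param model An \code{adr_hmm}.
#' @param symbols Integer vector of observation symbols (1..M).
#' @return Log-likelihood (scalar; \code{-Inf} for an impossible sequence).
#' @export
sequence_loglik <- function(model, symbols) {
  symbols <- check_symbols(model, symbols)
  if (!length(symbols)) return(0)
  hmm_forward(model, symbols)$loglik
}

#' Viterbi decoding
#'
#' Most probable hidden state path for an observation sequence, in log
#' space. Ties are broken toward the lowest state index at each backtrack
#' step. An empty sequence yields an empty path with log-probability 0.
#'
#' @inheritParams sequence_loglik
#' @return List with \code{path} (integer state indices) and \code{loglik}
#'   (joint log-probability of the path and observations).
#' @export
viterbi <- function(model, symbols) {
  symbols <- check_symbols(model, symbols)
  T_ <- length(symbols)
  if (T_ == 0L) return(list(path = integer(0), loglik = 0))
  N <- model$N
  logpi <- log(model$pi)
  logA <- log(model$A)
  logB <- log(model$B)
  delta <- matrix(-Inf, T_, N)
  psi <- matrix(0L, T_, N)
  delta[1L, ] <- logpi + logB[, symbols[1L]]
  if (T_ > 1L) {
    for (t in 2L:T_) {
      for (j in seq_len(N)) {
        cand <- delta[t - 1L, ] + logA[, j]
        best <- which.max(cand)  # first maximum = lowest state index
        psi[t, j] <- best
        delta[t, j] <- cand[best] + logB[j, symbols[t]]
      }
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  list(path = path, loglik = delta[T_, path[T_]])
}

# E-step sufficient statistics for one sequence: state posteriors gamma
# (T x N), summed transition posteriors xi_sum (N x N), log-likelihood
hmm_estep <- function(model, symbols) {
  symbols <- check_symbols(model, symbols)
  T_ <- length(symbols)
  fwd <- hmm_forward(model, symbols)
  if (!is.finite(fwd$loglik))
    return(list(gamma = matrix(0, T_, model$N),
                xi_sum = matrix(0, model$N, model$N), loglik = -Inf))
  beta <- hmm_backward(model, symbols, fwd$scale)
  gamma <- fwd$alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, model$N, model$N)
  if (T_ > 1L) {
    for (t in seq_len(T_ - 1L)) {
      xi <- (fwd$alpha[t, ] %o% (model$B[, symbols[t + 1L]] * beta[t + 1L, ])) *
        model$A
      xi_sum <- xi_sum + xi / sum(xi)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = fwd$loglik)
}

#' Baum-Welch parameter refinement
#'
#' Multi-sequence expectation-maximisation in scaled space. Iterates until
#' the per-observation log-likelihood improvement falls below \code{tol} or
#' \code{max_iter} is reached. The log-likelihood trace is non-decreasing
#' (up to numerical tolerance); rows that receive no posterior mass keep
#' their previous values.
#'
#' @param model Starting \code{adr_hmm} (typically from
#'   \code{\link{init_from_annotations}}).
#' @param sequences List of integer symbol vectors; empty sequences are
#'   ignored.
#' @param tol Convergence threshold on per-observation log-likelihood
#'   improvement (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100).
#' @return List with \code{model} (the refined \code{adr_hmm}) and
#'   \code{report}: \code{loglik_trace} (one entry per iteration, evaluated
#'   at the iteration's starting parameters), \code{iterations},
#'   \code{converged}.
#' @export
baum_welch <- function(model, sequences, tol = 1e-4, max_iter = 100L) {
  validate_hmm(model)
  sequences <- lapply(sequences, function(s) check_symbols(model, s))
  sequences <- sequences[lengths(sequences) > 0L]
  if (!length(sequences)) stop("no non-empty training sequences")
  n_obs <- sum(lengths(sequences))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  prev_ll <- -Inf
  N <- model$N; M <- model$M
  while (iter < max_iter) {
    iter <- iter + 1L
    pi_num <- numeric(N)
    trans_num <- matrix(0, N, N)
    trans_den <- numeric(N)
    emit_num <- matrix(0, N, M)
    emit_den <- numeric(N)
    ll <- 0
    for (sy in sequences) {
      e <- hmm_estep(model, sy)
      ll <- ll + e$loglik
      T_ <- length(sy)
      pi_num <- pi_num + e$gamma[1L, ]
      trans_num <- trans_num + e$xi_sum
      if (T_ > 1L)
        trans_den <- trans_den + colSums(e$gamma[seq_len(T_ - 1L), , drop = FALSE])
      emit_den <- emit_den + colSums(e$gamma)
      agg <- rowsum(e$gamma, group = sy)  # per-symbol posterior mass, states in columns
      syms <- as.integer(rownames(agg))
      emit_num[, syms] <- emit_num[, syms] + t(agg)
    }
    trace <- c(trace, ll)
    improvement <- (ll - prev_ll) / n_obs
    if (is.finite(prev_ll) && improvement < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    # M-step
    pi_new <- pi_num / sum(pi_num)
    A_new <- model$A
    B_new <- model$B
    for (j in seq_len(N)) {
      if (trans_den[j] > 0) A_new[j, ] <- trans_num[j, ] / trans_den[j]
      if (emit_den[j] > 0) B_new[j, ] <- emit_num[j, ] / emit_den[j]
    }
    A_new <- A_new / rowSums(A_new)
    B_new <- B_new / rowSums(B_new)
    model <- hmm_model(pi_new, A_new, B_new,
                       state_labels = model$state_labels,
                       symbol_table = model$symbol_table)
  }
  list(model = model,
       report = list(loglik_trace = trace, iterations = iter,
                     converged = converged))
}

#' Serialize a model to JSON
#'
#' Writes N, M, state labels, probabilities (row-major) and the symbol
#' table at 17 significant digits, so that a write/read round trip is exact
#' to printed precision.
#'
#' @param model An \code{adr_hmm}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_hmm <- function(model, path) {
  obj <- list(
    N = model$N, M = model$M, state_labels = model$state_labels,
    pi = model$pi,
    A = as.vector(t(model$A)),
    B = as.vector(t(model$B)),
    symbol_table = as.list(model$symbol_table)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path Path written by \code{\link{write_hmm}}.
#' @return An \code{adr_hmm}.
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  N <- obj$N; M <- obj$M
  symtab <- NULL
  if (!is.null(obj$symbol_table) && length(obj$symbol_table)) {
    symtab <- unlist(obj$symbol_table)
    storage.mode(symtab) <- "integer"
    attr(symtab, "M") <- M
  }
  hmm_model(obj$pi,
            matrix(obj$A, N, N, byrow = TRUE),
            matrix(obj$B, N, M, byrow = TRUE),
            state_labels = obj$state_labels,
            symbol_table = symtab)
}
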