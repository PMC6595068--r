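# First-order linear-chain CRF over binary label sequences: potential
# containers, exact inference (forward-backward in log-space, Viterbi) and
# the negative conditional log-likelihood.
#
# Two potential variants are supported:
#   "Unary"    per-step unary scores (T x 2) plus one static transition
#              matrix A (2 x 2) shared across steps;
#   "Pairwise" input-dependent per-step pairwise scores (T x 2 x 2) that
#              replace A and subsume the unaries for t >= 2; step 1 keeps a
#              unary term.
# The chain is open at both ends (no start/stop boundary states). All
# inference runs in log-space with log-sum-exp, stable for scores up to
# about +-1e3.

N_LABELS <- 2L

#' Construct chain potentials
#'
#' @param unary `T x 2` matrix of per-step unary scores (columns are labels
#'   0, 1). For the `"Pairwise"` variant only row 1 is used.
#' @param pairwise `"Unary"` variant: a static `2 x 2` transition matrix
#'   `A[y_prev, y_next]`. `"Pairwise"` variant: a `T x 2 x 2` array of
#'   per-step scores; slice `t` scores the transition into step `t`
#'   (`t >= 2`; slice 1 is ignored).
#' @param variant `"Unary"` or `"Pairwise"`.
#' @return a `chain_potentials` object.
#' @export
chain_potentials <- function(unary, pairwise, variant = c("Unary", "Pairwise")) {
  variant <- match.arg(variant)
  unary <- as.matrix(unary)
  if (ncol(unary) != N_LABELS) stopf("`unary` must have 2 columns")
  T_len <- nrow(unary)
  if (T_len < 1L) stopf("`unary` must have at least one row")
  if (variant == "Unary") {
    pairwise <- as.matrix(pairwise)
    if (!all(dim(pairwise) == c(N_LABELS, N_LABELS)))
      stopf("static transition matrix must be 2 x 2")
  } else {
    if (!is.array(pairwise) || length(dim(pairwise)) != 3L ||
        !all(dim(pairwise) == c(T_len, N_LABELS, N_LABELS)))
      stopf("per-step pairwise scores must be a T x 2 x 2 array")
  }
  if (any(!is.finite(unary)) || any(!is.finite(pairwise)))
    stopf("potential scores must be finite")
  structure(list(unary = unary, pairwise = pairwise, variant = variant,
                 T_len = T_len),
            class = "chain_potentials")
}

# Canonical form: psi1 (scores of y_1) and M[[t]][a, b] combined transition
# scores for t >= 2.
crf_canonical <- function(pot) {
  T_len <- pot$T_len
  psi1 <- pot$unary[1L, ]
  M <- vector("list", T_len)
  if (T_len >= 2L) {
    for (t in 2:T_len) {
      M[[t]] <- if (pot$variant == "Unary")
        pot$pairwise + rep(pot$unary[t, ], each = N_LABELS)
      else
        matrix(pot$pairwise[t, , ], N_LABELS, N_LABELS)
    }
  }
  list(psi1 = psi1, M = M)
}

#' Score of one labeling under chain potentials
#'
#' `sum_t unary[t, y_t] + sum_{t>=2} pairwise(t, y_{t-1}, y_t)` (with the
#' variant-specific reading of the two terms).
#'
#' @param pot a [chain_potentials()].
#' @param y label sequence in \{0, 1\} of length `T`.
#' @return scalar score.
#' @export
sequence_score <- function(pot, y) {
  if (length(y) != pot$T_len)
    stopf("labeling length %d does not match T = %d", length(y), pot$T_len)
  can <- crf_canonical(pot)
  s <- can$psi1[y[1L] + 1L]
  if (pot$T_len >= 2L)
    for (t in 2:pot$T_len)
      s <- s + can$M[[t]][y[t - 1L] + 1L, y[t] + 1L]
  s
}

crf_forward <- function(can, T_len) {
  la <- matrix(NA_real_, T_len, N_LABELS)
  la[1L, ] <- can$psi1
  if (T_len >= 2L)
    for (t in 2:T_len)
      la[t, ] <- apply(la[t - 1L, ] + can$M[[t]], 2L, logsumexp)
  la
}

crf_backward <- function(can, T_len) {
  lb <- matrix(0, T_len, N_LABELS)
  if (T_len >= 2L)
    for (t in (T_len - 1L):1L)
      lb[t, ] <- apply(t(can$M[[t + 1L]]) + lb[t + 1L, ], 2L, logsumexp)
  lb
}

#' Log partition function of the chain
#'
#' `log sum_y exp(score(y))` over all `2^T` labelings, computed by the
#' forward recursion in log-space.
#'
#' @param pot a [chain_potentials()].
#' @return scalar `log Z`.
#' @export
log_partition <- function(pot) {
  can <- crf_canonical(pot)
  logsumexp(crf_forward(can, pot$T_len)[pot$T_len, ])
}

#' Negative conditional log-likelihood of a labeling
#'
#' `log Z - score(y_true)`; non-negative.
#'
#' @inheritParams sequence_score
#' @return scalar `>= 0`.
#' @export
crf_nll <- function(pot, y) {
  max(log_partition(pot) - sequence_score(pot, y), 0)
}

#' Exact per-step (and pairwise) marginals via forward-backward
#'
#' @param pot a [chain_potentials()].
#' @param edges also return pairwise marginals `p(y_{t-1}, y_t | x)`?
#' @return `T x 2` matrix of `p(y_t = c | x)` (rows sum to 1); with
#'   `edges = TRUE`, a list with `node` and `edge` (a `T x 2 x 2` array,
#'   slices `t >= 2`).
#' @export
crf_marginals <- function(pot, edges = FALSE) {
  can <- crf_canonical(pot)
  T_len <- pot$T_len
  la <- crf_forward(can, T_len)
  lb <- crf_backward(can, T_len)
  logZ <- logsumexp(la[T_len, ])
  node <- exp(la + lb - logZ)
  node <- node / rowSums(node)
  if (!edges) return(node)
  edge <- array(NA_real_, c(T_len, N_LABELS, N_LABELS))
  if (T_len >= 2L)
    for (t in 2:T_len)
      edge[t, , ] <- exp(outer(la[t - 1L, ], lb[t, ], "+") + can$M[[t]] - logZ)
  list(node = node, edge = edge)
}

#' Viterbi decoding
#'
#' Returns `argmax_y score(y)`. Ties are broken toward label 0 at every
#' backtrack step and at the final step.
#'
#' @param pot a [chain_potentials()].
#' @return integer label sequence in \{0, 1\}.
#' @export
crf_viterbi <- function(pot) {
  can <- crf_canonical(pot)
  T_len <- pot$T_len
  delta <- matrix(NA_real_, T_len, N_LABELS)
  ptr <- matrix(NA_integer_, T_len, N_LABELS)
  delta[1L, ] <- can$psi1
  if (T_len >= 2L) {
    for (t in 2:T_len) {
      cand <- delta[t - 1L, ] + can$M[[t]]
      # which.max picks the first maximizer: state 1 = label 0 on ties
      ptr[t, ] <- apply(cand, 2L, which.max)
      delta[t, ] <- cand[cbind(ptr[t, ], seq_len(N_LABELS))]
    }
  }
  y <- integer(T_len)
  state <- which.max(delta[T_len, ])
  y[T_len] <- state - 1L
  if (T_len >= 2L) {
    for (t in T_len:2L) {
      state <- ptr[t, state]
      y[t - 1L] <- state - 1L
    }
  }
  y
}
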