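#' Closed-form solution of a linear first-order cascade
#'
#' Computes the amount in every compartment of a catenary chain
#' (depot -> parent -> metabolite 1 -> ...) at the requested times. Each
#' compartment `i` empties with first-order rate constant `rates[i]`; the
#' flow feeding compartment `i + 1` proceeds at `transfer[i]` (at most
#' `rates[i]`; the remainder is elimination to outside the chain). The
#' whole dose starts in compartment 1. This is the classical Bateman
#' sum-of-exponentials solution; when two rate constants (near-)coincide
#' the sum is numerically singular and the amounts are instead evaluated
#' exactly by the matrix exponential of the cascade rate matrix, which is
#' valid for repeated roots.
#'
#' @param rates Positive first-order exit rate constants (1/h), one per
#'   compartment, in chain order.
#' @param amount0 Amount placed in the first compartment at time zero
#'   (any amount unit; outputs share it).
#' @param times Nonnegative times (h) at which to evaluate.
#' @param transfer Rate constants (1/h) of the flow from compartment `i`
#'   into compartment `i + 1`, length `length(rates) - 1`. Defaults to
#'   full transfer (`rates[-length(rates)]`).
#' @param tol_rel Relative tolerance below which two exit rates are
#'   treated as coincident and the matrix-exponential branch is used.
#' @return Numeric matrix, `length(times)` rows by `length(rates)`
#'   columns: amount in each compartment at each time.
#' @examples
#' # one compartment, one half-life
#' bateman_chain(log(2), 100, 1)
#' # depot -> parent -> metabolite
#' bateman_chain(c(6, 0.204, 0.0433), 12328, c(0.5, 4, 12))
#' @export
bateman_chain <- function(rates, amount0, times,
                          transfer = rates[-length(rates)],
                          tol_rel = 1e-8) {
  n <- length(rates)
  if (n < 1L || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be positive and finite", call. = FALSE)
  if (length(transfer) != max(n - 1L, 0L))
    stop("'transfer' must have one entry per chain link", call. = FALSE)
  if (any(transfer < 0) || any(transfer > rates[-n] * (1 + 1e-12)))
    stop("each transfer rate must lie in [0, rates[i]]", call. = FALSE)
  if (!is.numeric(amount0) || length(amount0) != 1L || amount0 < 0)
    stop("'amount0' must be a single nonnegative amount", call. = FALSE)
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)

  confluent <- n > 1L &&
    min(abs(diff(sort(rates)))) < tol_rel * max(rates)
  out <- if (confluent) {
    .chain_expm(rates, transfer, amount0, times)
  } else {
    .chain_bateman(rates, transfer, amount0, times)
  }
  # clip trapped negative round-off from the alternating exponential sum
  out[out < 0 & out > -1e-9 * amount0] <- 0
  dimnames(out) <- list(NULL, paste0("compartment_", seq_len(n)))
  out
}

# distinct-rate Bateman sum: A_j(t) = a0 * prod(transfer[1:(j-1)]) *
#   sum_i exp(-k_i t) / prod_{l != i} (k_l - k_i), over k_1..k_j
.chain_bateman <- function(rates, transfer, amount0, times) {
  n <- length(rates)
  out <- matrix(0, length(times), n)
  for (j in seq_len(n)) {
    ks <- rates[seq_len(j)]
    coefs <- vapply(seq_len(j),
                    function(i) 1 / prod(ks[-i] - ks[i]), numeric(1))
    gain <- if (j > 1L) prod(transfer[seq_len(j - 1L)]) else 1
    out[, j] <- amount0 * gain *
      colSums(coefs * exp(-outer(ks, times)))
  }
  out
}

# exact for coincident rates: expm of the lower-bidiagonal rate matrix
.chain_expm <- function(rates, transfer, amount0, times) {
  n <- length(rates)
  A <- diag(-rates, n)
  if (n > 1L) A[cbind(seq_len(n)[-1], seq_len(n - 1L))] <- transfer
  out <- matrix(0, length(times), n)
  x0 <- c(amount0, rep(0, n - 1L))
  for (i in seq_along(times)) {
    out[i, ] <- as.numeric(Matrix::expm(A * times[i]) %*% x0)
  }
  out
}
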