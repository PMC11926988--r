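#' State-space model primitives
#'
#' Continuous linear state-space systems h'(t) = A h(t) + B x(t),
#' y(t) = C h(t) are discretized with a zero-order hold and evaluated
#' either as a sequential scan or, in the time-invariant case, as a
#' causal convolution with a truncated impulse-response kernel. These
#' are the building blocks of the selective-scan (Mamba) token mixer;
#' the state matrix is diagonal throughout, the standard structured-SSM
#' parameterization.
#'
#' @name ssm
NULL

#' Zero-order-hold discretization of a diagonal SSM
#'
#' Converts continuous parameters (A, B) with timescale `delta` into the
#' discrete pair (A_bar, B_bar):
#' A_bar = exp(delta * A) and B_bar = (delta A)^{-1} (exp(delta A) - I) delta B,
#' which for diagonal A reduces elementwise to (exp(delta*A) - 1)/A * B.
#' The removable singularity at delta*A -> 0 is evaluated by its series
#' limit B_bar -> delta * B (switch at |delta*A| < 1e-6).
#'
#' @param A diagonal of the state matrix (numeric vector, length n_state).
#' @param B input map (numeric vector, length n_state).
#' @param delta positive timescale, scalar.
#' @return list with elements `A_bar` and `B_bar`, both length n_state.
#' @export
zoh_discretize <- function(A, B, delta) {
  stopifnot(is.numeric(A), is.numeric(B), length(A) == length(B))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a positive finite scalar")
  z <- delta * A
  A_bar <- exp(z)
  B_bar <- ifelse(abs(z) < 1e-6, delta * B, (A_bar - 1) / A * B)
  list(A_bar = A_bar, B_bar = B_bar)
}

# phi(z) = (exp(z) - 1)/z with its removable singularity; used by the
# selective path where delta varies per timestep and channel. expm1 keeps
# the quotient accurate down to |z| ~ machine epsilon.
ssm_phi <- function(z) {
  out <- expm1(z) / z
  out[z == 0] <- 1
  out
}

# phi'(z) = (exp(z)(z - 1) + 1)/z^2 = (z e^z - expm1(z))/z^2,
# series 1/2 + z/3 near 0 (the subtraction cancels below |z| ~ 1e-4).
ssm_phi_grad <- function(z) {
  out <- (z * exp(z) - expm1(z)) / (z * z)
  small <- abs(z) < 1e-4
  if (any(small)) out[small] <- 0.5 + z[small] / 3
  out
}

#' Sequential SSM scan
#'
#' Evaluates the discrete recurrence h_t = A_bar_t * h_{t-1} + B_bar_t * x_t,
#' y_t = <C_t, h_t> with h_0 = 0. Parameters may be time-invariant
#' (vectors, recycled across timesteps) or per-timestep matrices with L
#' rows (the selective case).
#'
#' @param x input sequence, numeric vector of length L.
#' @param A_bar,B_bar discrete parameters: length-n vectors or L x n matrices.
#' @param C_out output map: length-n vector or L x n matrix.
#' @return numeric vector y of length L.
#' @export
ssm_scan <- function(x, A_bar, B_bar, C_out) {
  L <- length(x)
  as_steps <- function(m, nm) {
    if (is.matrix(m)) {
      if (nrow(m) != L) stop("per-timestep `", nm, "` must have L rows")
      m
    } else matrix(m, nrow = L, ncol = length(m), byrow = TRUE)
  }
  Am <- as_steps(A_bar, "A_bar"); Bm <- as_steps(B_bar, "B_bar")
  Cm <- as_steps(C_out, "C_out")
  if (ncol(Am) != ncol(Bm) || ncol(Am) != ncol(Cm))
    stop("state dimensions of A_bar, B_bar, C_out disagree")
  h <- numeric(ncol(Am))
  y <- numeric(L)
  for (t in seq_len(L)) {
    h <- Am[t, ] * h + Bm[t, ] * x[t]
    y[t] <- sum(Cm[t, ] * h)
  }
  y
}

#' Truncated impulse-response kernel of a time-invariant SSM
#'
#' K_bar = (C B_bar, C A_bar B_bar, ..., C A_bar^{M-1} B_bar): the first M
#' taps of the system's impulse response, so that causal convolution with
#' K_bar reproduces the scan for sequences shorter than M.
#'
#' @param A_bar,B_bar discrete diagonal parameters (vectors, length n_state).
#' @param C_out output map (vector, length n_state).
#' @param M kernel length, integer >= 1.
#' @return numeric vector of length M.
#' @export
ssm_conv_kernel <- function(A_bar, B_bar, C_out, M) {
  if (!is.numeric(M) || length(M) != 1L || M < 1) stop("`M` must be >= 1")
  M <- as.integer(M)
  k <- numeric(M)
  pow <- rep(1, length(A_bar))
  for (m in seq_len(M)) {
    k[m] <- sum(C_out * pow * B_bar)
    pow <- pow * A_bar
  }
  k
}

#' Causal convolution of a sequence with an SSM kernel
#'
#' y_t = sum_m K_m x_{t-m+1}, zero-padded on the left; equals
#' [ssm_scan()] for a time-invariant system whenever M >= L.
#'
#' @param x numeric input sequence.
#' @param kernel numeric kernel (first tap acts on the current timestep).
#' @return numeric vector, same length as `x`.
#' @export
ssm_conv_apply <- function(x, kernel) {
  L <- length(x); M <- length(kernel)
  xp <- c(rep(0, M - 1), x)
  y <- numeric(L)
  for (m in seq_len(M)) {
    y <- y + kernel[m] * xp[(M - m + 1):(M - m + L)]
  }
  y
}
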