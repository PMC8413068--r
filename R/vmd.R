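# Variational mode decomposition: frequency-domain ADMM with Wiener-filter
# mode updates and spectral-centroid frequency updates, after mirror
# extension of the input.

.fftshift <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1):n], x[1:floor(n / 2)])
}

.ifftshift <- function(x) {
  n <- length(x)
  c(x[(ceiling(n / 2) + 1):n], x[1:ceiling(n / 2)])
}

#' Variational mode decomposition of a single-channel signal
#'
#' Splits a real signal into `K` band-limited modes u_k, each compact
#' around a center frequency w_k found during the optimisation, by
#' minimising the summed H1 bandwidths of the analytic, baseband-shifted
#' modes subject to the modes (softly) reconstructing the input. Solved
#' in the frequency domain by ADMM: the signal is mirror-extended by half
#' its length on each side, then iterates alternate
#' \itemize{
#'   \item Wiener-filter mode updates
#'     \eqn{\hat u_k \leftarrow (\hat f - \sum_{i \ne k}\hat u_i +
#'       \hat\lambda/2) / (1 + 2\alpha(\omega-\omega_k)^2)},
#'   \item center-frequency updates (spectral centroid of
#'     \eqn{|\hat u_k|^2} over the positive half-spectrum), and
#'   \item the dual ascent
#'     \eqn{\hat\lambda \leftarrow \hat\lambda + \tau(\hat f - \sum_k \hat u_k)},
#' }
#' stopping when \eqn{\sum_k \|u_k^{n+1}-u_k^n\|^2 / \|u_k^n\|^2} falls
#' below `tol` or `maxIter` is reached. Modes are inverted to the time
#' domain, cropped back to the original support, and returned sorted by
#' ascending center frequency.
#'
#' With `tau = 0` (the default) the reconstruction constraint is not
#' enforced exactly; the unmodelled remainder is returned in the
#' `residual` slot, never dropped. With `tau > 0` the residual shrinks
#' towards zero on band-limited signals.
#'
#' @param signal numeric vector, finite values, length at least `2 * K`.
#' @param fs sampling rate in Hz.
#' @param K number of modes (default 10; downstream feature extraction
#'   conventionally keeps modes 1-8).
#' @param alpha bandwidth penalty (> 0); larger values give narrower
#'   modes. Default 2000.
#' @param tau dual-ascent step (>= 0); 0 disables the Lagrangian update.
#' @param tol convergence tolerance on the summed relative mode change.
#' @param maxIter iteration cap.
#' @param init center-frequency initialisation: `"uniform"` spreads K
#'   centers over `[0, fs/2)`, `"zero"` starts all at 0, `"random"`
#'   draws uniformly (seeded by `seed`).
#' @param seed integer seed used only when `init = "random"`.
#' @return A [VMDResult-class].
#' @examples
#' t <- seq(0, 2, by = 1 / 200)[-1]
#' x <- cos(2 * pi * 10 * t)
#' res <- vmd(x, fs = 200, K = 1)
#' centerFreqs(res)   # ~10 Hz
#' @export
vmd <- function(signal, fs, K = 10L, alpha = 2000, tau = 0, tol = 1e-7,
                maxIter = 500L, init = c("uniform", "zero", "random"),
                seed = NULL) {
  init <- match.arg(init)
  signal <- as.numeric(signal)
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples")
  K <- as.integer(K)
  stopifnot(K >= 1L, alpha > 0, tau >= 0, tol > 0, maxIter >= 1L, fs > 0)
  N0 <- length(signal)
  if (N0 < 2L * K)
    stop("signal too short for K = ", K, " modes: length ", N0,
         " < minimum ", 2L * K)

  # mirror extension: about half the signal reflected onto each side,
  # arranged so the extended length 2*N0 is even
  left <- ceiling(N0 / 2)
  right <- N0 - left
  f <- c(rev(signal[seq_len(left)]), signal,
         if (right > 0) rev(signal[(N0 - right + 1):N0]))
  T <- length(f)
  freqs <- (seq_len(T) - 1) / T - 0.5           # normalised, [-0.5, 0.5)
  posHalf <- (floor(T / 2) + 1):T               # non-negative frequencies

  fhat <- .fftshift(stats::fft(f))
  fhatPlus <- fhat
  fhatPlus[seq_len(floor(T / 2))] <- 0          # analytic (one-sided) spectrum

  omega <- switch(init,
    uniform = (0.5 / K) * (seq_len(K) - 1),
    zero    = rep(0, K),
    random  = .with_seed(seed, sort(stats::runif(K, 0, 0.5))))

  U <- matrix(0 + 0i, K, T)        # one-sided mode spectra
  lambdaHat <- rep(0 + 0i, T)
  sumU <- rep(0 + 0i, T)
  nIter <- 0L
  convergedFlag <- FALSE

  for (n in seq_len(maxIter)) {
    nIter <- n
    uDiff <- 0
    for (k in seq_len(K)) {
      old <- U[k, ]
      numer <- fhatPlus - (sumU - old) + lambdaHat / 2
      U[k, ] <- numer / (1 + 2 * alpha * (freqs - omega[k])^2)
      sumU <- sumU + U[k, ] - old
      p <- Mod(U[k, posHalf])^2
      e <- sum(p)
      if (e > 0)
        omega[k] <- sum(freqs[posHalf] * p) / e
      d <- U[k, ] - old
      uDiff <- uDiff + sum(Mod(d)^2) / max(sum(Mod(old)^2), .Machine$double.eps)
    }
    if (tau > 0)
      lambdaHat <- lambdaHat + tau * (fhatPlus - sumU)
    if (uDiff < tol) { convergedFlag <- TRUE; break }
  }

  # back to time domain: rebuild two-sided spectra by conjugate symmetry
  # (index i holds frequency (i-1)/T - 1/2, so -freq(i) lives at T+2-i)
  modesExt <- matrix(0, K, T)
  negHalf <- 2:(T / 2)
  for (k in seq_len(K)) {
    uh <- rep(0 + 0i, T)
    uh[posHalf] <- U[k, posHalf]
    uh[negHalf] <- Conj(uh[T + 2 - negHalf])
    uh[1] <- Conj(uh[T])
    modesExt[k, ] <- Re(stats::fft(.ifftshift(uh), inverse = TRUE)) / T
  }
  m <- modesExt[, (left + 1):(left + N0), drop = FALSE]

  ord <- order(omega)
  m <- m[ord, , drop = FALSE]
  cf <- pmin(pmax(omega[ord], 0), 0.5) * fs
  resid <- signal - colSums(m)
  new("VMDResult", modes = m, centerFreqs = cf, fs = as.numeric(fs),
      nIter = nIter, converged = convergedFlag, residual = resid)
}

# Evaluate expr under a seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Decompose every channel of a recording
#'
#' Applies [vmd()] independently to each channel of a
#' [Recording-class]; deterministic given the arguments (and `seed` when
#' `init = "random"`). Errors from individual channels are re-signalled
#' with the channel name attached.
#'
#' @param rec a [Recording-class].
#' @param ... arguments passed on to [vmd()] (`K`, `alpha`, `tau`,
#'   `tol`, `maxIter`, `init`, `seed`).
#' @return A [DecomposedRecording-class] holding one [VMDResult-class]
#'   per channel.
#' @export
decomposeRecording <- function(rec, ...) {
  stopifnot(is(rec, "Recording"))
  x <- samples(rec)
  fs <- samplingRate(rec)
  dec <- lapply(rownames(x), function(ch) {
    tryCatch(vmd(x[ch, ], fs = fs, ...),
             error = function(e)
               stop("channel '", ch, "': ", conditionMessage(e), call. = FALSE))
  })
  names(dec) <- rownames(x)
  new("DecomposedRecording", subjectId = subjectId(rec), trial = trial(rec),
      fs = fs, decompositions = dec)
}
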