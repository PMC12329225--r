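#' Graph Fourier transform of regional signals
#'
#' Projects a regions-by-timepoints signal matrix onto the connectome
#' harmonics: `Xhat = t(U) %*% X`. Because `U` is orthonormal the transform
#' is energy-preserving (Parseval) and inverted exactly by `U %*% Xhat`.
#'
#' @param basis A `"harmonic_basis"` from [eigendecompose()].
#' @param signals N x T numeric matrix (rows = regions, columns =
#'   timepoints), or a `"regional_signals"` object.
#' @return N x T matrix of spectral coefficients (rows = harmonics).
#' @export
gft <- function(basis, signals) {
  x <- as_signal_matrix(signals)
  u <- basis_matrix(basis)
  if (nrow(x) != nrow(u)) {
    stop_invalid("signal rows (", nrow(x), ") do not match basis size (",
                 nrow(u), ")")
  }
  crossprod(u, x)
}

#' Inverse graph Fourier transform
#'
#' @param basis A `"harmonic_basis"`.
#' @param coefficients N x T spectral coefficient matrix.
#' @return N x T signal matrix `U %*% coefficients`.
#' @export
inverse_gft <- function(basis, coefficients) {
  u <- basis_matrix(basis)
  if (nrow(coefficients) != ncol(u)) {
    stop_invalid("coefficient rows do not match basis size")
  }
  u %*% coefficients
}

#' Average spectral energy density
#'
#' For each harmonic, the mean over timepoints (and over subjects, when a
#' list of coefficient matrices is supplied) of the squared GFT
#' coefficient. The vector sums to the mean total signal energy per
#' timepoint.
#'
#' @param coefficients One N x T coefficient matrix, or a list of them
#'   (all sharing N) to pool across subjects.
#' @return Length-N non-negative vector.
#' @export
mean_energy_density <- function(coefficients) {
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  if (!is.list(coefficients) || length(coefficients) == 0L) {
    stop_invalid("need at least one coefficient matrix")
  }
  n <- nrow(coefficients[[1]])
  per_subject <- vapply(coefficients, function(m) {
    if (!is.matrix(m) || nrow(m) != n) {
      stop_invalid("all coefficient matrices must share the same region count")
    }
    rowMeans(m^2)
  }, numeric(n))
  rowMeans(as.matrix(per_subject))
}

#' Select the spectral cutoff splitting energy into equal halves
#'
#' The cutoff harmonic `C` is the smallest index at which the cumulative
#' average spectral energy density reaches half of the total; harmonic `C`
#' itself belongs to the low (coupled) band. The realized low-band energy
#' share is recorded (it equals 0.5 only when the cumulative sum crosses
#' one half exactly).
#'
#' @param density Non-negative length-N vector with positive total, as
#'   returned by [mean_energy_density()].
#' @return A `"spectral_cutoff"`: list with `C`, `low_band`, `high_band`,
#'   `energy_fraction_low`, `n`.
#' @export
select_cutoff <- function(density) {
  density <- as.numeric(density)
  if (length(density) < 1L || any(!is.finite(density)) || any(density < 0)) {
    stop_invalid("density must be a finite non-negative vector")
  }
  tot <- sum(density)
  if (tot <= 0) stop_invalid("density is all zero; cannot place a cutoff")
  cs <- cumsum(density)
  c_idx <- which(cs >= tot / 2)[1]
  band_cutoff(c_idx, length(density), energy_fraction_low = cs[c_idx] / tot)
}

#' Construct a spectral cutoff at a given harmonic index
#'
#' Low band = harmonics `1..C`, high band = `C+1..N` (empty when `C = N`).
#'
#' @param C Cutoff harmonic index in `[1, N]`.
#' @param n Total number of harmonics N.
#' @param energy_fraction_low Optional realized low-band energy share.
#' @return A `"spectral_cutoff"` object.
#' @export
band_cutoff <- function(C, n, energy_fraction_low = NA_real_) {
  C <- as.integer(C)
  n <- as.integer(n)
  if (C < 1L || C > n) stop_invalid("cutoff C must lie in [1, N]")
  structure(
    list(C = C,
         low_band = seq_len(C),
         high_band = if (C < n) seq.int(C + 1L, n) else integer(0),
         energy_fraction_low = energy_fraction_low,
         n = n),
    class = "spectral_cutoff"
  )
}

#' Split signals into structurally coupled and decoupled components
#'
#' Graph-filters the signal with complementary band projectors:
#' `X_coupled = U_low t(U_low) X` (smooth over the connectome) and
#' `X_decoupled = U_high t(U_high) X` (varying against it). The two
#' components are orthogonal and sum back to the input.
#'
#' @param basis A `"harmonic_basis"`.
#' @param signals N x T signal matrix.
#' @param cutoff A `"spectral_cutoff"` valid for N.
#' @return A `"filtered_signals"`: list with `X_coupled` and `X_decoupled`.
#' @export
filter_signals <- function(basis, signals, cutoff) {
  x <- as_signal_matrix(signals)
  u <- basis_matrix(basis)
  if (nrow(x) != nrow(u)) stop_invalid("signal/basis dimension mismatch")
  if (!inherits(cutoff, "spectral_cutoff") || cutoff$n != nrow(u)) {
    stop_invalid("cutoff does not match basis size")
  }
  u_low <- u[, cutoff$low_band, drop = FALSE]
  xc <- u_low %*% crossprod(u_low, x)
  if (length(cutoff$high_band)) {
    u_high <- u[, cutoff$high_band, drop = FALSE]
    xd <- u_high %*% crossprod(u_high, x)
  } else {
    xd <- matrix(0, nrow(x), ncol(x))
  }
  structure(list(X_coupled = xc, X_decoupled = xd),
            class = "filtered_signals")
}

basis_matrix <- function(basis) {
  if (inherits(basis, "harmonic_basis")) basis$U
  else if (is.matrix(basis)) basis
  else stop_invalid("basis must be a harmonic_basis or matrix")
}

as_signal_matrix <- function(signals) {
  x <- if (is.list(signals) && !is.null(signals$X)) signals$X else signals
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) stop_invalid("signals contain non-finite entries")
  x
}
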