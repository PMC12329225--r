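#' Structural decoupling index per region
#'
#' For each region, the base-2 log ratio of the L2 norms of the decoupled
#' and coupled signal components, taken over the full retained time
#' series: `SDI_i = log2(||X_decoupled[i, ]|| / ||X_coupled[i, ]||)`.
#' Negative values mean the region's activity aligns with the structural
#' connectome (coupled); positive values mean relative independence
#' (decoupled).
#'
#' A region whose coupled (or decoupled) component has essentially zero
#' norm gives an unbounded ratio: the SDI is set to `NA` and the region is
#' flagged `coupled_zero` (or `decoupled_zero`) instead of raising an
#' error. Zero is judged relative to the region's total signal norm.
#'
#' @param filtered A `"filtered_signals"` object from [filter_signals()].
#' @return A `data.frame` with columns `region_id`, `sdi`, `flag`
#'   (`"ok"`, `"coupled_zero"`, `"decoupled_zero"`).
#' @export
compute_sdi <- function(filtered) {
  if (!inherits(filtered, "filtered_signals")) {
    stop_invalid("filtered must come from filter_signals()")
  }
  nc <- sqrt(rowSums(filtered$X_coupled^2))
  nd <- sqrt(rowSums(filtered$X_decoupled^2))
  tot <- sqrt(nc^2 + nd^2)
  tol <- 1e-9 * pmax(tot, .Machine$double.xmin)

  flag <- rep("ok", length(nc))
  flag[nd <= tol] <- "decoupled_zero"
  flag[nc <= tol] <- "coupled_zero"  # total-zero rows fall here too
  sdi <- ifelse(flag == "ok", log2(nd / nc), NA_real_)
  data.frame(region_id = seq_along(sdi), sdi = sdi, flag = flag,
             stringsAsFactors = FALSE)
}

#' Coupled and decoupled functional connectivity matrices
#'
#' Pearson correlation over time between every pair of regions, computed
#' separately within the coupled component (c-FC) and within the decoupled
#' component (d-FC), plus Fisher z-transformed copies. c-FC captures
#' connectivity carried by activity consistent with the structural
#' connectome; d-FC captures connectivity independent of it.
#'
#' Diagonals are set to `NA` and excluded from all downstream statistics.
#' Rows with zero temporal variance cannot be correlated: their entries are
#' set to `NA` and a warning names the regions.
#'
#' @param filtered A `"filtered_signals"` object with T >= 3 timepoints.
#' @return An `"fc_matrices"` object: list with `cfc`, `dfc`, `cfc_z`,
#'   `dfc_z` (all N x N, symmetric, `NA` diagonal).
#' @export
fc_decompose <- function(filtered) {
  if (!inherits(filtered, "filtered_signals")) {
    stop_invalid("filtered must come from filter_signals()")
  }
  if (ncol(filtered$X_coupled) < 3) stop_invalid("need at least 3 timepoints")
  cfc <- corr_among_rows(filtered$X_coupled, "coupled")
  dfc <- corr_among_rows(filtered$X_decoupled, "decoupled")
  structure(
    list(cfc = cfc, dfc = dfc,
         cfc_z = fisher_z_matrix(cfc), dfc_z = fisher_z_matrix(dfc)),
    class = "fc_matrices"
  )
}

corr_among_rows <- function(m, label) {
  sds <- apply(m, 1, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  r <- suppressWarnings(stats::cor(t(m)))
  if (any(bad)) {
    warning("constant ", label, " component in region(s) ",
            paste(which(bad), collapse = ", "),
            "; correlations set to NA", call. = FALSE)
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  diag(r) <- NA_real_
  r
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)` with `r` clipped to +/-(1 - 1e-12) so that correlations of
#' exactly +/-1 map to large finite values instead of infinities. Odd
#' function; `NA` passes through.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop_invalid("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

fisher_z_matrix <- function(r) {
  z <- fisher_z(ifelse(is.na(r), 0, r))
  z[is.na(r)] <- NA_real_
  z
}
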