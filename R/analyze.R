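#' Run the subject-level coupling analysis
#'
#' The per-subject pipeline: GMV-normalized adjacency -> symmetric
#' normalized Laplacian -> harmonic basis -> GFT of the retained BOLD
#' volumes -> spectral-energy cutoff -> coupled/decoupled filtering ->
#' SDI and (optionally) c-FC/d-FC matrices.
#'
#' @param streamline_counts N x N streamline-count matrix.
#' @param gmv Length-N gray-matter volumes.
#' @param bold N x T_acquired BOLD matrix; the first `n_discard` columns
#'   are dropped before any computation.
#' @param n_discard Leading volumes to discard (default 5).
#' @param cutoff Optional `"spectral_cutoff"` to impose (e.g. a
#'   group-level one); when `NULL` the subject's own mean energy density
#'   decides.
#' @param sc_threshold Adjacency weights strictly below this value are
#'   zeroed before the Laplacian (default 0 = no thresholding).
#' @param compute_fc Compute the c-FC/d-FC matrices (default `TRUE`).
#' @param basis Optional precomputed `"harmonic_basis"` for this subject's
#'   connectome (skips the eigendecomposition; it must match
#'   `streamline_counts`).
#' @return List with `basis`, `cutoff`, `sdi` (data frame), `fc`
#'   (`"fc_matrices"` or `NULL`), `density`, `n_retained`.
#' @export
analyze_subject <- function(streamline_counts, gmv, bold, n_discard = 5L,
                            cutoff = NULL, sc_threshold = 0,
                            compute_fc = TRUE, basis = NULL) {
  if (is.null(basis)) {
    a <- build_adjacency(streamline_counts, gmv)
    if (sc_threshold > 0) a[a < sc_threshold] <- 0
    basis <- eigendecompose(normalized_laplacian(a))
  }
  t_acq <- ncol(bold)
  if (n_discard >= t_acq) stop_invalid("n_discard leaves no timepoints")
  x <- bold[, (n_discard + 1L):t_acq, drop = FALSE]

  xhat <- gft(basis, x)
  density <- mean_energy_density(xhat)
  if (is.null(cutoff)) cutoff <- select_cutoff(density)
  filtered <- filter_signals(basis, x, cutoff)
  list(
    basis = basis,
    cutoff = cutoff,
    density = density,
    sdi = compute_sdi(filtered),
    fc = if (compute_fc) fc_decompose(filtered) else NULL,
    n_retained = ncol(x)
  )
}

#' Analyze every subject of a cohort
#'
#' Runs [analyze_subject()] for each subject and assembles the matrices
#' the inference layer consumes. With `cutoff_scope = "subject"` (the
#' default) each subject's cutoff comes from their own average spectral
#' energy density; with `"group"` the densities are pooled across all
#' subjects first and a single common cutoff is used.
#'
#' @param cohort An `"sfc_cohort"` from [generate_cohort()] or
#'   [load_cohort()].
#' @param cutoff_scope `"subject"` or `"group"`.
#' @param compute_fc Compute connectivity matrices (default `TRUE`;
#'   disable for SDI-only runs).
#' @param sc_threshold Passed to [analyze_subject()].
#' @return An `"sfc_analysis"`: list with `sdi` (subjects x N matrix),
#'   `flags` (same shape, character), `cutoffs` (per-subject C),
#'   `cfc_z`/`dfc_z` (subjects x N x N arrays, or `NULL`), `manifest`,
#'   `atlas`, `cutoff_scope`, `n_retained`.
#' @export
analyze_cohort <- function(cohort, cutoff_scope = c("subject", "group"),
                           compute_fc = TRUE, sc_threshold = 0) {
  cutoff_scope <- match.arg(cutoff_scope)
  stopifnot(inherits(cohort, "sfc_cohort"))
  n_discard <- cohort$config$n_discard
  ids <- cohort$manifest$subject_id
  n_sub <- length(ids)
  n_reg <- nrow(cohort$atlas)

  shared_cutoff <- NULL
  if (cutoff_scope == "group") {
    densities <- lapply(ids, function(id) {
      s <- cohort$subjects[[id]]
      t_acq <- ncol(s$bold)
      x <- s$bold[, (n_discard + 1L):t_acq, drop = FALSE]
      b <- subject_basis(s)
      mean_energy_density(gft(b, x))
    })
    shared_cutoff <- select_cutoff(Reduce(`+`, densities) / length(densities))
  }

  sdi <- matrix(NA_real_, n_sub, n_reg, dimnames = list(ids, NULL))
  flags <- matrix(NA_character_, n_sub, n_reg, dimnames = list(ids, NULL))
  cutoffs <- integer(n_sub)
  cfc_z <- if (compute_fc) array(NA_real_, c(n_sub, n_reg, n_reg)) else NULL
  dfc_z <- if (compute_fc) array(NA_real_, c(n_sub, n_reg, n_reg)) else NULL
  n_retained <- NA_integer_

  for (s in seq_len(n_sub)) {
    subj <- cohort$subjects[[ids[s]]]
    out <- analyze_subject(subj$streamline_counts, subj$gmv, subj$bold,
                           n_discard = n_discard, cutoff = shared_cutoff,
                           sc_threshold = sc_threshold,
                           compute_fc = compute_fc,
                           basis = subject_basis(subj))
    sdi[s, ] <- out$sdi$sdi
    flags[s, ] <- out$sdi$flag
    cutoffs[s] <- out$cutoff$C
    n_retained <- out$n_retained
    if (compute_fc) {
      cfc_z[s, , ] <- out$fc$cfc_z
      dfc_z[s, , ] <- out$fc$dfc_z
    }
  }
  structure(
    list(sdi = sdi, flags = flags, cutoffs = cutoffs,
         cfc_z = cfc_z, dfc_z = dfc_z,
         manifest = cohort$manifest, atlas = cohort$atlas,
         cutoff_scope = cutoff_scope, n_retained = n_retained),
    class = "sfc_analysis"
  )
}

subject_basis <- function(subj) {
  if (!is.null(subj$basis)) return(subj$basis)
  eigendecompose(normalized_laplacian(
    build_adjacency(subj$streamline_counts, subj$gmv)))
}
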