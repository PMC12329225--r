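#' Generate a synthetic structural connectome and regional volumes
#'
#' Streamline counts follow a community (block) model: region pairs inside
#' the same community draw from a Poisson with mean
#' `within_community_weight`, pairs across communities from a Poisson with
#' mean `between_community_weight`. Communities are contiguous blocks of
#' near-equal size over the atlas order. Counts are drawn once for the
#' upper triangle and mirrored, so the matrix is symmetric with zero
#' diagonal. If the resulting graph is disconnected, unit-count edges are
#' added deterministically (lowest-id node of each extra component to the
#' lowest-id node of the first) until it is connected. Gray-matter volumes
#' are log-normal.
#'
#' @param atlas Atlas table from [generate_atlas()].
#' @param config An `"sfc_config"`.
#' @param subject_seed Integer seed for this subject's draws.
#' @return List with `streamline_counts` (N x N integer-valued),
#'   `gmv` (length N, positive), and `community` (block labels).
#' @export
generate_structural <- function(atlas, config, subject_seed) {
  n <- nrow(atlas)
  if (n < 2) stop_invalid("atlas must contain at least two regions")
  community <- region_communities(n, config$community_count)
  with_seed(subject_seed, {
    same <- outer(community, community, `==`)
    mu <- ifelse(same, config$within_community_weight,
                 config$between_community_weight)
    counts <- matrix(0, n, n)
    up <- upper.tri(counts)
    counts[up] <- stats::rpois(sum(up), mu[up])
    counts <- counts + t(counts)

    g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      anchor <- min(which(comp$membership == comp$membership[1]))
      for (k in setdiff(unique(comp$membership), comp$membership[anchor])) {
        j <- min(which(comp$membership == k))
        counts[anchor, j] <- counts[anchor, j] + 1
        counts[j, anchor] <- counts[anchor, j]
      }
    }
    gmv <- stats::rlnorm(n, config$gmv_log_mean, config$gmv_log_sd)
    list(streamline_counts = counts, gmv = gmv, community = community)
  })
}

region_communities <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

#' Generate band-limited BOLD-like signals with known coupling structure
#'
#' The signal is built directly in the harmonic basis of the subject's own
#' connectome: `X = P_low E_c + G (P_high E_d)`, where `E_c` and `E_d` are
#' independent white-noise matrices, `P_low`/`P_high` are band projectors
#' at the generator's nominal cutoff (the median harmonic index,
#' `floor(N/2)`), and `G` is a diagonal per-region gain on the decoupled
#' band. The gain combines the planted unimodal/transmodal gradient
#' (`2^{+/- gradient_shift}`) with the group offset `2^{decoupling_shift}`
#' applied to `target_regions` in the pilot group only.
#'
#' Row-scaling a band-limited component does not exactly preserve band
#' membership, so the nominal gains are a knob, not the truth: the
#' generator re-runs the analysis filters ([filter_signals()] +
#' [compute_sdi()]) on the retained timepoints at the nominal cutoff and
#' returns that *realized* SDI as the ground truth. Degenerate bands (e.g.
#' `high_noise_scale = 0`) surface as flagged regions in the realized map.
#'
#' @param basis The subject's `"harmonic_basis"`.
#' @param config An `"sfc_config"`.
#' @param group `"pilot"` or `"control"`.
#' @param subject_seed Integer seed.
#' @param atlas Optional atlas table; needed to apply the system-label
#'   gradient (skipped when `NULL`).
#' @param behavior_rho Latent correlation in `(-1, 1)` planted between the
#'   decoupled-band innovations of the two `behavior_edge` regions
#'   (0 disables).
#' @param coupled_rho Same, but planted in the coupled-band innovations;
#'   used to construct crossover patterns (one group coupled-connected,
#'   the other decoupled-connected at the same edge).
#' @param high_noise_scale Multiplier on the decoupled-band noise
#'   (0 produces a fully coupled signal; realized SDI is then flagged).
#' @return List with `X` (N x `n_timepoints_acquired`), `realized_sdi`
#'   (data frame from [compute_sdi()] on the retained timepoints),
#'   `cutoff_nominal`, and `gain` (the per-region diagonal of `G`).
#' @export
generate_bold <- function(basis, config, group, subject_seed, atlas = NULL,
                          behavior_rho = 0, coupled_rho = 0,
                          high_noise_scale = 1) {
  u <- basis_matrix(basis)
  n <- nrow(u)
  if (n != n_regions(config)) {
    stop_invalid("basis size (", n, ") does not match config regions (",
                 n_regions(config), ")")
  }
  if (!group %in% c("pilot", "control")) {
    stop_invalid("group must be 'pilot' or 'control'")
  }
  if (abs(behavior_rho) >= 1) stop_invalid("behavior_rho must lie in (-1, 1)")
  if (abs(coupled_rho) >= 1) stop_invalid("coupled_rho must lie in (-1, 1)")
  t_acq <- config$n_timepoints_acquired
  c_nom <- max(1L, n %/% 2L)
  cutoff <- band_cutoff(c_nom, n)

  gain <- rep(1, n)
  if (!is.null(atlas)) {
    gain[atlas$system_label == "unimodal"] <- 2^(-config$gradient_shift)
    gain[atlas$system_label == "transmodal"] <- 2^(config$gradient_shift)
  }
  if (group == "pilot" && length(config$target_regions)) {
    gain[config$target_regions] <-
      gain[config$target_regions] * 2^config$decoupling_shift
  }

  plant_shared <- function(e, rho, edge) {
    z <- stats::rnorm(ncol(e))
    a <- abs(rho)
    e[edge[1], ] <- sqrt(1 - a) * e[edge[1], ] + sqrt(a) * z
    e[edge[2], ] <- sqrt(1 - a) * e[edge[2], ] + sign(rho) * sqrt(a) * z
    e
  }
  x <- with_seed(subject_seed, {
    e_c <- matrix(stats::rnorm(n * t_acq), n, t_acq)
    e_d <- matrix(stats::rnorm(n * t_acq), n, t_acq)
    if (!is.null(config$behavior_edge)) {
      if (behavior_rho != 0) {
        e_d <- plant_shared(e_d, behavior_rho, config$behavior_edge)
      }
      if (coupled_rho != 0) {
        e_c <- plant_shared(e_c, coupled_rho, config$behavior_edge)
      }
    }
    low <- filter_signals(basis, e_c, cutoff)$X_coupled
    high <- filter_signals(basis, e_d, cutoff)$X_decoupled
    low + gain * (high_noise_scale * high)
  })

  retained <- x[, (config$n_discard + 1L):t_acq, drop = FALSE]
  realized <- compute_sdi(filter_signals(basis, retained, cutoff))

  list(X = x, realized_sdi = realized, cutoff_nominal = c_nom, gain = gain)
}

#' Generate a complete synthetic cohort
#'
#' Draws two groups of `n_subjects_per_group` subjects. Demographic
#' covariates (age, education, TIV, mean framewise displacement) come from
#' the same distribution for both groups, so the groups are matched by
#' construction. Pilots get log-uniform flight hours over
#' `flight_hours_range`; controls have none. Each subject gets their own
#' community-structured connectome, gray-matter volumes, harmonic basis,
#' and band-limited BOLD-like signals. When `behavior_effect` is nonzero,
#' the latent correlation planted at `behavior_edge` scales linearly with
#' the pilot's normalized log flight hours, peaking at `behavior_effect`,
#' so realized decoupled connectivity at that edge co-varies monotonically
#' with (any monotone transform of) flight hours.
#'
#' @param config An `"sfc_config"`; its `seed` drives everything.
#' @param out_dir Optional directory: when given, the atlas, manifest,
#'   per-subject matrices and ground truth are written there via
#'   [write_cohort()].
#' @return An `"sfc_cohort"`: list with `atlas`, `manifest` (one row per
#'   subject), `subjects` (named list carrying `streamline_counts`, `gmv`,
#'   `bold`, `basis`, `realized_sdi`, `cutoff_nominal`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  if (!inherits(config, "sfc_config")) stop_invalid("config must be an sfc_config")
  n_per <- config$n_subjects_per_group
  n_tot <- 2L * n_per
  atlas <- generate_atlas(config$n_regions_cortical,
                          config$n_regions_subcortical,
                          seed = config$seed,
                          unimodal_fraction = config$unimodal_fraction)

  subject_id <- sprintf("sub-%03d", seq_len(n_tot))
  group <- rep(c("pilot", "control"), each = n_per)
  seeds <- derive_seeds(config$seed, 2L * n_tot + 1L)
  cov_seed <- seeds[1L]
  struct_seeds <- seeds[1L + seq_len(n_tot)]
  bold_seeds <- seeds[1L + n_tot + seq_len(n_tot)]

  covars <- with_seed(cov_seed, {
    lo <- log(config$flight_hours_range[1])
    hi <- log(config$flight_hours_range[2])
    data.frame(
      subject_id = subject_id,
      group = group,
      age = round(stats::rnorm(n_tot, 34, 5), 1),
      education = round(stats::rnorm(n_tot, 16, 1), 1),
      tiv = round(stats::rlnorm(n_tot, log(1.5e6), 0.05)),
      mfd = round(stats::rlnorm(n_tot, log(0.12), 0.3), 4),
      flight_hours = ifelse(group == "pilot",
                            round(exp(stats::runif(n_tot, lo, hi))),
                            NA_real_),
      stringsAsFactors = FALSE
    )
  })

  lo <- log(config$flight_hours_range[1])
  hi <- log(config$flight_hours_range[2])
  subjects <- vector("list", n_tot)
  names(subjects) <- subject_id
  for (s in seq_len(n_tot)) {
    structural <- generate_structural(atlas, config, struct_seeds[s])
    basis <- eigendecompose(
      normalized_laplacian(
        build_adjacency(structural$streamline_counts, structural$gmv)))
    rho <- 0
    if (group[s] == "pilot" && config$behavior_effect != 0) {
      u <- (log(covars$flight_hours[s]) - lo) / (hi - lo)
      rho <- config$behavior_effect * u
    }
    bold <- generate_bold(basis, config, group[s], bold_seeds[s],
                          atlas = atlas, behavior_rho = rho)
    subjects[[s]] <- list(
      streamline_counts = structural$streamline_counts,
      gmv = structural$gmv,
      bold = bold$X,
      basis = basis,
      realized_sdi = bold$realized_sdi,
      cutoff_nominal = bold$cutoff_nominal
    )
  }

  cohort <- structure(
    list(atlas = atlas, manifest = covars, subjects = subjects,
         config = config),
    class = "sfc_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
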