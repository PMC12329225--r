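#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of the generative model. The defaults
#' are the study conditions used throughout the package: a 246-region
#' parcellation (210 cortical + 36 subcortical), 255 acquired volumes of
#' which the first 5 are discarded (250 retained), two groups of 20
#' subjects, community-structured streamline-count connectomes, and pilot
#' flight hours spanning 350 to 19,000 on a log scale.
#'
#' @param n_regions_cortical,n_regions_subcortical Parcellation sizes.
#' @param n_timepoints_acquired Number of acquired BOLD volumes per subject.
#' @param n_discard Leading volumes dropped before any analysis
#'   (signal-stabilization discard).
#' @param n_subjects_per_group Subjects per group (>= 3; the inference layer
#'   needs degrees of freedom).
#' @param community_count Number of connectome communities.
#' @param within_community_weight,between_community_weight Poisson means for
#'   streamline counts inside / between communities.
#' @param gmv_log_mean,gmv_log_sd Log-normal parameters (log mm^3) for
#'   regional gray-matter volumes.
#' @param gradient_shift Half-width (log2 units) of the planted
#'   unimodal-coupled / transmodal-decoupled gradient: the decoupled band is
#'   scaled by `2^(-gradient_shift)` in unimodal and `2^(+gradient_shift)` in
#'   transmodal regions for every subject.
#' @param decoupling_shift Planted group offset (log2 units) added to the
#'   decoupled-band gain of `target_regions` in the pilot group only.
#' @param target_regions Integer region ids receiving the planted offset.
#' @param behavior_edge Length-2 region pair whose decoupled-connectivity
#'   strength is made to co-vary with log flight hours.
#' @param behavior_effect Peak latent correlation (in (-1, 1)) planted at
#'   `behavior_edge` for the pilot with the most flight hours; 0 disables
#'   the behavioral effect.
#' @param flight_hours_range Positive `(min, max)` range of pilot flight
#'   hours; draws are log-uniform over it.
#' @param unimodal_fraction Passed to [generate_atlas()].
#' @param seed Master integer seed.
#'
#' @return A validated list of class `"sfc_config"`.
#' @export
sfc_config <- function(n_regions_cortical = 210L,
                       n_regions_subcortical = 36L,
                       n_timepoints_acquired = 255L,
                       n_discard = 5L,
                       n_subjects_per_group = 20L,
                       community_count = 6L,
                       within_community_weight = 20,
                       between_community_weight = 10,
                       gmv_log_mean = log(2500),
                       gmv_log_sd = 0.4,
                       gradient_shift = 0.5,
                       decoupling_shift = 0,
                       target_regions = integer(0),
                       behavior_edge = NULL,
                       behavior_effect = 0,
                       flight_hours_range = c(350, 19000),
                       unimodal_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_regions_cortical = as.integer(n_regions_cortical),
    n_regions_subcortical = as.integer(n_regions_subcortical),
    n_timepoints_acquired = as.integer(n_timepoints_acquired),
    n_discard = as.integer(n_discard),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    community_count = as.integer(community_count),
    within_community_weight = within_community_weight,
    between_community_weight = between_community_weight,
    gmv_log_mean = gmv_log_mean,
    gmv_log_sd = gmv_log_sd,
    gradient_shift = gradient_shift,
    decoupling_shift = decoupling_shift,
    target_regions = as.integer(target_regions),
    behavior_edge = if (is.null(behavior_edge)) NULL else as.integer(behavior_edge),
    behavior_effect = behavior_effect,
    flight_hours_range = as.numeric(flight_hours_range),
    unimodal_fraction = unimodal_fraction,
    seed = as.integer(seed)
  )
  n <- cfg$n_regions_cortical + cfg$n_regions_subcortical

  if (cfg$n_regions_cortical < 1) stop_invalid("need at least one cortical region")
  if (cfg$n_regions_subcortical < 0) stop_invalid("n_regions_subcortical must be >= 0")
  if (cfg$n_discard < 0) stop_invalid("n_discard must be >= 0")
  if (cfg$n_discard >= cfg$n_timepoints_acquired) {
    stop_invalid("n_discard must be smaller than n_timepoints_acquired")
  }
  if (cfg$n_timepoints_acquired - cfg$n_discard < 2) {
    stop_invalid("fewer than 2 retained timepoints")
  }
  if (cfg$n_subjects_per_group < 3) {
    stop_invalid("n_subjects_per_group must be >= 3 (inference layer needs df)")
  }
  if (cfg$community_count < 1 || cfg$community_count > n) {
    stop_invalid("community_count must lie in [1, n_regions]")
  }
  if (cfg$within_community_weight <= 0 || cfg$between_community_weight <= 0) {
    stop_invalid("community weights must be positive")
  }
  if (length(cfg$target_regions) &&
      (any(cfg$target_regions < 1) || any(cfg$target_regions > n))) {
    stop_invalid("target_regions outside the atlas")
  }
  if (!is.null(cfg$behavior_edge)) {
    if (length(cfg$behavior_edge) != 2L ||
        cfg$behavior_edge[1] == cfg$behavior_edge[2] ||
        any(cfg$behavior_edge < 1) || any(cfg$behavior_edge > n)) {
      stop_invalid("behavior_edge must be two distinct valid region ids")
    }
  }
  if (abs(cfg$behavior_effect) >= 1) {
    stop_invalid("behavior_effect must lie in (-1, 1)")
  }
  if (cfg$behavior_effect != 0 && is.null(cfg$behavior_edge)) {
    stop_invalid("behavior_effect != 0 requires a behavior_edge")
  }
  if (length(cfg$flight_hours_range) != 2L ||
      any(cfg$flight_hours_range <= 0) ||
      diff(cfg$flight_hours_range) <= 0) {
    stop_invalid("flight_hours_range must be positive and increasing")
  }
  class(cfg) <- "sfc_config"
  cfg
}

n_regions <- function(config) {
  config$n_regions_cortical + config$n_regions_subcortical
}
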