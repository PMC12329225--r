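#' Generate a synthetic brain parcellation table
#'
#' Builds an atlas in the style of a whole-brain parcellation with separate
#' cortical and subcortical compartments (the default full-scale
#' configuration elsewhere in the package uses 210 cortical plus 36
#' subcortical parcels). Cortical regions are split as evenly as possible
#' across hemispheres, with the odd region going to the left; subcortical
#' regions carry no hemisphere label. Each cortical region is tagged as
#' `unimodal` (primary sensory/motor-like) or `transmodal` (association-like);
#' the tag is used only to plant and evaluate the coupling gradient in the
#' synthetic signal generator.
#'
#' @param n_cortical Number of cortical regions (>= 1).
#' @param n_subcortical Number of subcortical regions (>= 0).
#' @param seed Integer seed controlling the (deterministic) assignment of
#'   system labels to cortical regions.
#' @param unimodal_fraction Fraction of cortical regions labelled unimodal
#'   (default 0.5).
#'
#' @return A `data.frame` with columns `region_id` (1..N, contiguous),
#'   `region_name`, `hemisphere` (`"L"`, `"R"`, or `NA` for subcortical),
#'   `tissue_class` (`"cortical"`/`"subcortical"`), and `system_label`
#'   (`"unimodal"`, `"transmodal"`, or `"subcortical"`).
#' @export
generate_atlas <- function(n_cortical, n_subcortical, seed = 1L,
                           unimodal_fraction = 0.5) {
  if (length(n_cortical) != 1L || !is.finite(n_cortical) || n_cortical < 1 ||
      n_cortical != round(n_cortical)) {
    stop_invalid("n_cortical must be a positive integer")
  }
  if (length(n_subcortical) != 1L || !is.finite(n_subcortical) ||
      n_subcortical < 0 || n_subcortical != round(n_subcortical)) {
    stop_invalid("n_subcortical must be a non-negative integer")
  }
  if (unimodal_fraction < 0 || unimodal_fraction > 1) {
    stop_invalid("unimodal_fraction must lie in [0, 1]")
  }
  n_cortical <- as.integer(n_cortical)
  n_subcortical <- as.integer(n_subcortical)
  n <- n_cortical + n_subcortical

  n_left <- ceiling(n_cortical / 2)
  hemi <- c(rep("L", n_left), rep("R", n_cortical - n_left),
            rep(NA_character_, n_subcortical))
  tissue <- c(rep("cortical", n_cortical), rep("subcortical", n_subcortical))

  n_uni <- round(unimodal_fraction * n_cortical)
  uni_idx <- with_seed(seed, sample.int(n_cortical, n_uni))
  system <- rep("transmodal", n_cortical)
  system[uni_idx] <- "unimodal"
  system <- c(system, rep("subcortical", n_subcortical))

  name <- character(n)
  ctx <- seq_len(n_cortical)
  name[ctx] <- sprintf("CTX_%s_%03d", hemi[ctx], ctx)
  if (n_subcortical > 0) {
    sub <- n_cortical + seq_len(n_subcortical)
    name[sub] <- sprintf("SUB_%03d", seq_len(n_subcortical))
  }

  data.frame(
    region_id = seq_len(n),
    region_name = name,
    hemisphere = hemi,
    tissue_class = tissue,
    system_label = system,
    stringsAsFactors = FALSE
  )
}
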