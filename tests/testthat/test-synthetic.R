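test_that("structural generator obeys symmetry, connectivity, determinism", {
  cfg <- small_config(61)
  atlas <- generate_atlas(cfg$n_regions_cortical, cfg$n_regions_subcortical,
                          seed = cfg$seed)
  for (s in 1:5) {
    st <- generate_structural(atlas, cfg, subject_seed = 100 + s)
    m <- st$streamline_counts
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0) && all(m == round(m)))
    g <- igraph::graph_from_adjacency_matrix(m > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
    expect_true(all(st$gmv > 0))
  }
  expect_identical(generate_structural(atlas, cfg, 7),
                   generate_structural(atlas, cfg, 7))
})

test_that("equal community weights give near-zero modularity, contrast does not", {
  atlas <- generate_atlas(16, 4, seed = 62)
  cfg_flat <- small_config(62, within_community_weight = 15,
                           between_community_weight = 15)
  cfg_block <- small_config(62, within_community_weight = 30,
                            between_community_weight = 10)
  mod_of <- function(cfg, s) {
    st <- generate_structural(atlas, cfg, s)
    g <- igraph::graph_from_adjacency_matrix(st$streamline_counts,
                                             mode = "undirected",
                                             weighted = TRUE)
    igraph::modularity(g, st$community, weights = igraph::E(g)$weight)
  }
  mods_flat <- sapply(1:50, function(s) mod_of(cfg_flat, s))
  mods_block <- sapply(1:50, function(s) mod_of(cfg_block, s))
  # equal weights: modularity of the planted partition stays near zero
  # (finite-size bias of order 1/edges, bounded by the simulated spread)
  expect_lt(abs(mean(mods_flat)), 0.05)
  expect_lt(max(abs(mods_flat)), 0.12)
  expect_gt(mean(mods_block), mean(mods_flat) + 0.05)
})

test_that("null construction: zero shift gives matching group SDI laws", {
  cfg <- small_config(63, n_subjects_per_group = 8, decoupling_shift = 0)
  coh <- generate_cohort(cfg)
  rs <- t(sapply(coh$subjects, function(s) s$realized_sdi$sdi))
  g <- coh$manifest$group
  diff <- mean(rs[g == "pilot", ]) - mean(rs[g == "control", ])
  # same generative law: group difference within sampling error
  expect_lt(abs(diff), 3 * sd(rs) / sqrt(length(rs) / 2))
})

test_that("degenerate decoupled band is flagged in the realized ground truth", {
  cfg <- small_config(64)
  atlas <- generate_atlas(cfg$n_regions_cortical, cfg$n_regions_subcortical,
                          seed = cfg$seed)
  st <- generate_structural(atlas, cfg, 1)
  basis <- eigendecompose(normalized_laplacian(
    build_adjacency(st$streamline_counts, st$gmv)))
  out <- generate_bold(basis, cfg, "control", 2, atlas = atlas,
                       high_noise_scale = 0)
  expect_true(all(out$realized_sdi$flag == "decoupled_zero"))
  expect_true(all(is.na(out$realized_sdi$sdi)))
})

test_that("realized SDI equals the analysis filters at the nominal cutoff", {
  cfg <- small_config(65, decoupling_shift = 1, target_regions = c(2L, 9L))
  atlas <- generate_atlas(cfg$n_regions_cortical, cfg$n_regions_subcortical,
                          seed = cfg$seed)
  st <- generate_structural(atlas, cfg, 3)
  basis <- eigendecompose(normalized_laplacian(
    build_adjacency(st$streamline_counts, st$gmv)))
  out <- generate_bold(basis, cfg, "pilot", 4, atlas = atlas)
  retained <- out$X[, (cfg$n_discard + 1):ncol(out$X)]
  recomputed <- compute_sdi(
    filter_signals(basis, retained,
                   band_cutoff(out$cutoff_nominal, nrow(atlas))))
  expect_equal(out$realized_sdi$sdi, recomputed$sdi, tolerance = 1e-10)
})

test_that("planted decoupling raises realized SDI in targets for pilots only", {
  targets <- c(2L, 9L, 15L)
  cfg <- small_config(66, n_subjects_per_group = 8, decoupling_shift = 1,
                      target_regions = targets)
  coh <- generate_cohort(cfg)
  rs <- t(sapply(coh$subjects, function(s) s$realized_sdi$sdi))
  g <- coh$manifest$group
  expect_gt(mean(rs[g == "pilot", targets]) - mean(rs[g == "control", targets]),
            0.1)
})

test_that("the planted coupling gradient orders system labels", {
  cfg <- small_config(67, n_subjects_per_group = 6)
  coh <- generate_cohort(cfg)
  rs <- t(sapply(coh$subjects, function(s) s$realized_sdi$sdi))
  lab <- coh$atlas$system_label
  expect_gt(mean(rs[, lab == "transmodal"]), mean(rs[, lab == "unimodal"]) + 0.3)
})

test_that("cohort covariates respect the schema and the flight-hours range", {
  cfg <- small_config(68, n_subjects_per_group = 12)
  coh <- generate_cohort(cfg)
  m <- coh$manifest
  expect_equal(nrow(m), 24)
  expect_true(all(is.finite(m$flight_hours[m$group == "pilot"])))
  expect_true(all(is.na(m$flight_hours[m$group == "control"])))
  fh <- m$flight_hours[m$group == "pilot"]
  expect_true(all(fh >= 350 & fh <= 19000))
  expect_true(all(m$age > 0) && all(m$tiv > 0) && all(m$mfd > 0))
  expect_error(sfc_config(n_subjects_per_group = 2), ">= 3")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(69, n_subjects_per_group = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[["sub-001"]]$bold,
                   c2$subjects[["sub-001"]]$bold)
  expect_identical(c1$subjects[["sub-004"]]$streamline_counts,
                   c2$subjects[["sub-004"]]$streamline_counts)
})
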