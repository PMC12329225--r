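#' Run the full coupling pipeline on a cohort
#'
#' Executes the whole analysis on a cohort directory or in-memory cohort:
#' per-subject structural graph, harmonics, GFT, band split, SDI and
#' c-FC/d-FC; then the inference layer (region-wise permutation tests on
#' SDI, 2x2 mixed ANOVA over edges with FWE control, and residualized
#' Spearman correlations of FWE-significant edges -- plus any explicitly
#' requested edge -- with flight hours). Results and a machine-readable
#' run log are written under `out_dir`.
#'
#' Reruns with the same inputs and seed produce byte-identical tables.
#'
#' @param cohort An `"sfc_cohort"` or a path to a cohort directory.
#' @param out_dir Output directory for the result tables.
#' @param cutoff_scope `"subject"` (default) or `"group"`.
#' @param sc_threshold Optional adjacency threshold (default 0, off).
#' @param n_perm Permutation count for the SDI tests (default 5000).
#' @param alpha_region Significance level for regional SDI tests (0.05).
#' @param alpha_fwe FWE threshold for the edge ANOVA (0.01).
#' @param fwe_method `"bonferroni"` or `"maxF"`.
#' @param outlier_z Outlier cutoff for the behavior correlation (3).
#' @param behavior_edge Optional region pair always included in the
#'   behavior-correlation stage.
#' @param seed Integer seed for all permutation draws.
#' @return List with `analysis`, `sdi_test`, `edge_anova`,
#'   `behavior` (data frame, possibly empty), and `log`.
#' @export
run_pipeline <- function(cohort, out_dir,
                         cutoff_scope = "subject", sc_threshold = 0,
                         n_perm = 5000, alpha_region = 0.05,
                         alpha_fwe = 0.01,
                         fwe_method = "bonferroni", outlier_z = 3,
                         behavior_edge = NULL, seed = 1L) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  stopifnot(inherits(cohort, "sfc_cohort"))
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  for (a in c(alpha_region, alpha_fwe)) {
    if (a <= 0 || a >= 1) stop_invalid("alpha levels must lie in (0, 1)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  analysis <- analyze_cohort(cohort, cutoff_scope = cutoff_scope,
                             compute_fc = TRUE, sc_threshold = sc_threshold)

  sdi_test <- sdi_group_test(analysis$sdi, analysis$manifest,
                             n_perm = n_perm, alpha = alpha_region,
                             seed = seed)
  edge_anova <- mixed_anova_edges(analysis$cfc_z, analysis$dfc_z,
                                  analysis$manifest,
                                  fwe_method = fwe_method,
                                  alpha = alpha_fwe, n_perm = n_perm,
                                  seed = seed)

  beh_edges <- unique(rbind(
    as.matrix(edge_anova[edge_anova$significant, c("region_i", "region_j")]),
    if (!is.null(behavior_edge)) matrix(sort(as.integer(behavior_edge)), 1)
  ))
  behavior <- data.frame(region_i = integer(0), region_j = integer(0),
                         rho = numeric(0), p = numeric(0),
                         rho_sq = numeric(0), n_used = integer(0),
                         n_outliers_removed = integer(0))
  if (!is.null(beh_edges) && nrow(beh_edges)) {
    rows <- lapply(seq_len(nrow(beh_edges)), function(e) {
      b <- behavior_correlation(analysis$dfc_z, analysis$manifest,
                                beh_edges[e, ], outlier_z = outlier_z)
      data.frame(region_i = b$edge[1], region_j = b$edge[2],
                 rho = b$rho, p = b$p, rho_sq = b$rho_sq,
                 n_used = b$n_used, n_outliers_removed = b$n_outliers_removed)
    })
    behavior <- do.call(rbind, rows)
  }

  # per-subject SDI in long form
  subject_sdi <- data.frame(
    subject_id = rep(rownames(analysis$sdi), ncol(analysis$sdi)),
    region_id = rep(seq_len(ncol(analysis$sdi)), each = nrow(analysis$sdi)),
    sdi = as.vector(analysis$sdi),
    flag = as.vector(analysis$flags),
    stringsAsFactors = FALSE
  )

  cfg_hash <- config_hash(list(config = unclass(cohort$config),
                               cutoff_scope = cutoff_scope,
                               sc_threshold = sc_threshold, n_perm = n_perm,
                               alpha_region = alpha_region,
                               alpha_fwe = alpha_fwe,
                               fwe_method = fwe_method,
                               outlier_z = outlier_z, seed = seed))

  write_result <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(sprintf("# config_hash=%s seed=%d", cfg_hash, as.integer(seed)),
               con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }
  write_result(subject_sdi, "subject_sdi.csv")
  write_result(sdi_test, "sdi_group_test.csv")
  write_result(edge_anova, "edge_anova.csv")
  write_result(behavior, "behavior_correlation.csv")

  log <- list(
    seed = as.integer(seed),
    config_hash = cfg_hash,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("brainsfc")),
    n_subjects = nrow(analysis$manifest),
    n_regions = nrow(analysis$atlas),
    n_retained_timepoints = analysis$n_retained,
    n_discard = cohort$config$n_discard,
    cutoff_scope = cutoff_scope,
    cutoffs = stats::setNames(as.list(analysis$cutoffs),
                              analysis$manifest$subject_id),
    options = list(sc_threshold = sc_threshold, n_perm = n_perm,
                   alpha_region = alpha_region, alpha_fwe = alpha_fwe,
                   fwe_method = fwe_method, outlier_z = outlier_z),
    excluded_regions = attr(sdi_test, "excluded_regions"),
    n_skipped_edges = nrow(attr(edge_anova, "skipped_edges"))
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  list(analysis = analysis, sdi_test = sdi_test, edge_anova = edge_anova,
       behavior = behavior, log = log)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
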