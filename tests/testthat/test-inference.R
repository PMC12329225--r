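test_that("residualization: orthogonality, perfect fit, normal-equations oracle", {
  set.seed(71)
  # covariate orthogonal to the centered values -> residuals are exactly
  # the centered values (zero-mean vc with vc . cov = 0 by construction)
  vc <- c(1, 1, -2, -2, 1, 1)
  cov_orth <- c(-1, 1, -1, 1, -1, 1)
  expect_equal(residualize(vc + 10, cbind(cov_orth)), vc, tolerance = 1e-10)

  # values an exact linear function of covariates -> ~0 residuals
  x <- cbind(a = rnorm(8), b = rnorm(8))
  y_lin <- 2 + 3 * x[, 1] - 0.5 * x[, 2]
  expect_lt(max(abs(residualize(y_lin, x))), 1e-10)

  # 6-point system against explicit normal equations
  x6 <- cbind(u = c(1, 2, 3, 5, 8, 13), w = c(0, 1, 0, 1, 1, 0))
  y6 <- c(2.2, 1.9, 3.7, 4.1, 6.0, 8.5)
  design <- cbind(1, x6)
  beta <- solve(t(design) %*% design, t(design) %*% y6)
  expect_equal(residualize(y6, x6), drop(y6 - design %*% beta),
               tolerance = 1e-10)

  # residuals orthogonal to every design column
  r <- residualize(y6, x6)
  expect_lt(max(abs(t(design) %*% r)) / sum(abs(y6)), 1e-8)

  # idempotence
  expect_equal(residualize(r, x6), r, tolerance = 1e-10)

  # collinear design names the offending column
  expect_error(residualize(y6, cbind(x6, dup = 2 * x6[, 1])),
               "collinear.*dup")
})

test_that("permutation p-values agree with exhaustive enumeration", {
  set.seed(72)
  v <- rnorm(8) + rep(c(0.8, 0), each = 4)
  g <- factor(rep(c("pilot", "control"), each = 4),
              levels = c("pilot", "control"))
  res <- permutation_ttest(v, g, n_perm = 2000, seed = 9)

  # oracle: enumerate all 70 group-1 assignments with an independent t
  pooled_t <- function(x1, x2) {
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    (mean(x1) - mean(x2)) / (sp * sqrt(1 / length(x1) + 1 / length(x2)))
  }
  t_obs <- pooled_t(v[1:4], v[5:8])
  splits <- combn(8, 4)
  t_all <- apply(splits, 2, function(idx) pooled_t(v[idx], v[-idx]))
  p_exact <- mean(abs(t_all) >= abs(t_obs) - 1e-12)

  expect_equal(res$t_value, t_obs, tolerance = 1e-12)
  expect_lt(abs(res$p_perm - p_exact), 2 / sqrt(2000) + 0.02)
})

test_that("permutation test edge cases and reproducibility", {
  set.seed(73)
  g <- factor(rep(c("pilot", "control"), each = 15),
              levels = c("pilot", "control"))
  v <- rnorm(30)

  # maximal separation attains the minimal p = 1/(n_perm + 1)
  v_shift <- v
  v_shift[1:15] <- v_shift[1:15] + 10 * sd(v)
  out <- permutation_ttest(v_shift, g, n_perm = 999, seed = 1)
  expect_equal(out$p_perm, 1 / 1000)
  expect_equal(out$direction, "pilot_higher")

  # globally identical values: degenerate exchangeable case
  flat <- permutation_ttest(rep(2, 30), g, n_perm = 200, seed = 1)
  expect_equal(flat$t_value, 0)
  expect_equal(flat$p_perm, 1)

  # one constant group against a varying one with different mean: error
  bad <- c(rep(5, 15), rnorm(15))
  expect_error(permutation_ttest(bad, g, n_perm = 200, seed = 1),
               "fewer than 2 distinct")

  # same seed -> identical; different seeds -> within Monte-Carlo error
  p1 <- permutation_ttest(v, g, n_perm = 1000, seed = 5)$p_perm
  p2 <- permutation_ttest(v, g, n_perm = 1000, seed = 5)$p_perm
  p3 <- permutation_ttest(v, g, n_perm = 1000, seed = 6)$p_perm
  expect_identical(p1, p2)
  expect_lt(abs(p1 - p3), 2 / sqrt(1000))

  expect_error(permutation_ttest(v[1:5], factor(c("a", "a", "a", "b", "b"))),
               "at least 3")
})

test_that("region-wise SDI table matches the single-region test and flags", {
  set.seed(74)
  n <- 12
  sdi <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
  sdi[3, 2] <- NA  # degenerate region must be excluded
  man <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    group = rep(c("pilot", "control"), each = 6),
                    age = rnorm(n, 34, 5), education = rnorm(n, 16, 1),
                    tiv = rnorm(n, 1.5e6, 5e4), mfd = runif(n, 0.05, 0.2))
  tab <- sdi_group_test(sdi, man, n_perm = 500, seed = 11)
  expect_equal(tab$region_id, c(1, 3, 4))
  expect_equal(attr(tab, "excluded_regions"), 2L)
  expect_true(all(tab$p_perm > 0 & tab$p_perm <= 1))
  expect_true(all(tab$p_fdr >= tab$p_perm - 1e-12))

  single <- permutation_ttest(
    sdi[, 1], factor(man$group, levels = c("pilot", "control")),
    covariates = man[c("age", "education", "tiv", "mfd")],
    n_perm = 500, seed = 11)
  expect_equal(tab$t_value[1], single$t_value)
  expect_equal(tab$p_perm[1], single$p_perm)

  # minimal viable cohort: 3 per group, one region
  mini <- sdi_group_test(
    matrix(rnorm(6), 6, 1, dimnames = list(paste0("m", 1:6), NULL)),
    data.frame(subject_id = paste0("m", 1:6),
               group = rep(c("pilot", "control"), each = 3)),
    covariates = character(0), n_perm = 200, seed = 1)
  expect_equal(nrow(mini), 1)
})

test_that("interaction F matches a split-plot aov oracle", {
  set.seed(75)
  n <- 12
  yc <- rnorm(n)
  yd <- rnorm(n) + rep(c(0.8, 0), each = 6)
  cfc <- array(rnorm(n * 9), c(n, 3, 3))
  dfc <- array(rnorm(n * 9), c(n, 3, 3))
  cfc[, 1, 2] <- cfc[, 2, 1] <- yc
  dfc[, 1, 2] <- dfc[, 2, 1] <- yd
  man <- data.frame(subject_id = paste0("s", 1:n),
                    group = rep(c("pilot", "control"), each = 6))
  res <- mixed_anova_edges(cfc, dfc, man, covariates = NULL, alpha = 0.05)
  row12 <- res[res$region_i == 1 & res$region_j == 2, ]

  long <- data.frame(
    y = c(yc, yd),
    comp = factor(rep(c("cfc", "dfc"), each = n)),
    subj = factor(rep(1:n, 2)),
    grp = factor(rep(man$group, 2))
  )
  fit <- stats::aov(y ~ grp * comp + Error(subj), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  f_oracle <- within["grp:comp", "F value"]
  p_oracle <- within["grp:comp", "Pr(>F)"]

  expect_equal(row12$F_interaction, f_oracle, tolerance = 1e-9)
  expect_equal(row12$p_uncorrected, p_oracle, tolerance = 1e-9)
})

test_that("FWE correction dominates and the df guard trips", {
  set.seed(76)
  n <- 10
  cfc <- array(rnorm(n * 16), c(n, 4, 4))
  dfc <- array(rnorm(n * 16), c(n, 4, 4))
  man <- data.frame(subject_id = paste0("s", 1:n),
                    group = rep(c("pilot", "control"), each = 5))
  res <- mixed_anova_edges(cfc, dfc, man, covariates = NULL)
  m <- nrow(res)
  expect_equal(res$p_fwe, pmin(1, m * res$p_uncorrected))
  expect_true(all(res$p_fwe >= res$p_uncorrected))
  # monotone in p_uncorrected
  ord <- order(res$p_uncorrected)
  expect_true(all(diff(res$p_fwe[ord]) >= -1e-12))

  man2 <- data.frame(subject_id = paste0("s", 1:4),
                     group = rep(c("pilot", "control"), each = 2))
  expect_error(
    mixed_anova_edges(cfc[1:4, , ], dfc[1:4, , ], man2, covariates = NULL),
    "insufficient degrees of freedom")
})

test_that("a planted crossover edge is detected with correct simple effects", {
  edge <- c(3L, 7L)
  n_sub <- 50L
  detected <- sapply(1:10, function(rep) {
    cfg <- small_config(760 + rep, n_subjects_per_group = 25,
                        n_timepoints_acquired = 255,
                        behavior_edge = edge)
    atlas <- generate_atlas(cfg$n_regions_cortical, cfg$n_regions_subcortical,
                            seed = cfg$seed)
    n_reg <- nrow(atlas)
    seeds <- matrix(seq_len(2 * n_sub) + 7000 * rep, ncol = 2)
    groups <- rep(c("pilot", "control"), each = n_sub / 2)
    cfc <- array(NA_real_, c(n_sub, n_reg, n_reg))
    dfc <- array(NA_real_, c(n_sub, n_reg, n_reg))
    for (s in seq_len(n_sub)) {
      st <- generate_structural(atlas, cfg, seeds[s, 1])
      basis <- eigendecompose(normalized_laplacian(
        build_adjacency(st$streamline_counts, st$gmv)))
      bold <- generate_bold(
        basis, cfg, groups[s], seeds[s, 2], atlas = atlas,
        behavior_rho = if (groups[s] == "pilot") 0.8 else 0,
        coupled_rho = if (groups[s] == "pilot") 0 else 0.8)
      an <- analyze_subject(st$streamline_counts, st$gmv, bold$X,
                            n_discard = cfg$n_discard, basis = basis,
                            cutoff = band_cutoff(n_reg %/% 2, n_reg))
      cfc[s, , ] <- an$fc$cfc_z
      dfc[s, , ] <- an$fc$dfc_z
    }
    man <- data.frame(subject_id = sprintf("x%02d", seq_len(n_sub)),
                      group = groups)
    res <- mixed_anova_edges(cfc, dfc, man, covariates = NULL, alpha = 0.01)
    hit <- res[res$region_i == edge[1] & res$region_j == edge[2], ]
    hit$significant && !is.na(hit$t_dfc) && hit$t_dfc > 0 && hit$t_cfc < 0
  })
  expect_gte(mean(detected), 0.8)
})

test_that("behavior correlation: perfect ranks, monotone invariance, outliers", {
  n <- 15
  set.seed(77)
  hours <- sort(exp(runif(n, log(350), log(19000))))
  man <- data.frame(subject_id = paste0("p", 1:n), group = "pilot",
                    flight_hours = hours)
  fc <- array(0, c(n, 4, 4))
  y <- 0.1 + 0.02 * rank(hours)
  fc[, 2, 3] <- fc[, 3, 2] <- y

  res <- behavior_correlation(fc, man, c(2, 3), covariates = NULL)
  expect_equal(res$rho, 1)
  expect_equal(res$rho_sq, 1)
  expect_equal(res$n_used, n)

  # strictly monotone transform of hours leaves rho unchanged
  man_log <- man
  man_log$flight_hours <- log(man$flight_hours)
  res_log <- behavior_correlation(fc, man_log, c(2, 3), covariates = NULL)
  expect_equal(res$rho, res_log$rho)

  # a gross outlier is removed once and counted
  fc_out <- fc
  yo <- y + rnorm(n, sd = 0.01)
  yo[5] <- yo[5] + 1
  fc_out[, 2, 3] <- fc_out[, 3, 2] <- yo
  res_out <- behavior_correlation(fc_out, man, c(2, 3), covariates = NULL)
  expect_equal(res_out$n_outliers_removed, 1)
  expect_equal(res_out$n_used, n - 1)
})
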