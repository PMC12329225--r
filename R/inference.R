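#' Regress nuisance covariates out of per-subject values
#'
#' Ordinary least squares of `values` on an intercept plus the covariate
#' columns; returns the residuals, which are exactly orthogonal to every
#' design column. A rank-deficient design is an input error and is reported
#' with the names of the collinear columns.
#'
#' @param values Numeric vector (or matrix: one response per column).
#' @param covariates Numeric matrix or data frame of covariate columns, or
#'   `NULL` to residualize on the intercept only (i.e. center).
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  was_vector <- is.null(dim(values))
  y <- as.matrix(values)
  x <- design_matrix(covariates, nrow(y))
  if (nrow(y) <= ncol(x) + 1L) {
    stop_invalid("need more observations than covariates + 1")
  }
  res <- qr.resid(qr_full_rank(x), y)
  if (was_vector) drop(res) else res
}

design_matrix <- function(covariates, n) {
  x <- cbind(`(intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    if (nrow(cm) != n) stop_invalid("covariate rows do not match values")
    if (!all(is.finite(cm))) stop_invalid("covariates contain non-finite values")
    if (is.null(colnames(cm))) colnames(cm) <- paste0("x", seq_len(ncol(cm)))
    x <- cbind(x, cm)
  }
  x
}

qr_full_rank <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop_invalid("rank-deficient covariate design; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  qx
}

# Pooled-variance two-sample t statistics for many responses at once.
# `r` is an n x m residual matrix, `g1` a logical vector marking group 1.
# Convention: t > 0 means group 1 mean exceeds group 2 mean. Degenerate
# columns (zero within-group variance) give t = 0 when the means also
# agree, +/-Inf otherwise.
two_sample_t <- function(r, g1) {
  n1 <- sum(g1)
  n2 <- sum(!g1)
  m1 <- colMeans(r[g1, , drop = FALSE])
  m2 <- colMeans(r[!g1, , drop = FALSE])
  ssw <- colSums(r^2) - n1 * m1^2 - n2 * m2^2
  ssw <- pmax(ssw, 0)
  se <- sqrt(ssw / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t <- ifelse(se > 0, num / se, ifelse(abs(num) < 1e-12, 0, Inf * sign(num)))
  t
}

# Shared permutation engine: observed and permuted pooled t statistics for
# each column of `r`, with group labels permuted identically across
# columns. Returns t_obs (length m) and p (length m, +1-corrected).
perm_t_matrix <- function(r, g1, n_perm, seed) {
  r <- as.matrix(r)
  n <- nrow(r)
  n1 <- sum(g1)
  t_obs <- two_sample_t(r, g1)
  perm <- with_seed(seed, {
    z <- matrix(FALSE, n, n_perm)
    for (b in seq_len(n_perm)) z[sample.int(n, n1), b] <- TRUE
    z
  })
  # group-1 sums for every permutation and column via one crossprod
  s1 <- crossprod(perm, r)                    # n_perm x m
  tot <- colSums(r)
  ss <- colSums(r^2)
  m1 <- s1 / n1
  n2 <- n - n1
  m2 <- sweep(-s1, 2, tot, `+`) / n2
  ssw <- pmax(sweep(-(n1 * m1^2 + n2 * m2^2), 2, ss, `+`), 0)
  se <- sqrt(ssw / (n - 2) * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t_perm <- ifelse(se > 0, num / se, ifelse(abs(num) < 1e-12, 0, Inf * sign(num)))
  exceed <- colSums(abs(t_perm) >= rep(abs(t_obs), each = n_perm) - 1e-12)
  p <- (1 + exceed) / (n_perm + 1)
  list(t_obs = t_obs, p = p, t_perm = t_perm)
}

#' Covariate-adjusted two-sample permutation t-test
#'
#' Residualizes the values on the pooled covariate design, computes the
#' pooled-variance two-sample t statistic on the residuals, and builds the
#' null by permuting the group labels `n_perm` times under a fixed seed.
#' The two-tailed p-value uses the +1 correction,
#' `p = (1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1)`, so its smallest
#' attainable value is `1 / (n_perm + 1)` and it is never zero.
#'
#' @param values Numeric vector, one value per subject.
#' @param groups Two-level factor (or coercible); the *first* level is the
#'   reference for the sign of `t` and for `direction`.
#' @param covariates Optional covariate matrix/data frame.
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed for the permutation draw.
#' @return List with `t_value`, `p_perm`, and `direction`
#'   (`"<level1>_higher"` / `"<level1>_lower"`).
#' @export
permutation_ttest <- function(values, groups, covariates = NULL,
                              n_perm = 5000, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_invalid("groups must have exactly two levels")
  tab <- table(groups)
  if (any(tab < 3)) stop_invalid("each group needs at least 3 subjects")
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_invalid("values contain non-finite entries")

  r <- if (is.null(covariates)) values else residualize(values, covariates)
  g1 <- groups == levels(groups)[1]

  if (max(r) - min(r) < 1e-12) {
    # globally constant residuals: exchangeable degenerate case
    return(list(t_value = 0, p_perm = 1,
                direction = paste0(levels(groups)[1], "_higher")))
  }
  for (lev in levels(groups)) {
    rg <- r[groups == lev]
    if (length(unique(rg)) < 2L) {
      stop_invalid("fewer than 2 distinct residual values in group '", lev, "'")
    }
  }

  out <- perm_t_matrix(matrix(r, ncol = 1), g1, n_perm, seed)
  list(
    t_value = out$t_obs[1],
    p_perm = out$p[1],
    direction = paste0(levels(groups)[1],
                       if (out$t_obs[1] >= 0) "_higher" else "_lower")
  )
}

#' Region-wise permutation test of SDI group differences
#'
#' Applies the covariate-adjusted permutation t-test to every region's SDI
#' across subjects. Covariates are residualized out once on the pooled
#' design; the same permutation draw is shared across regions. Regions
#' with a degenerate flag (NA SDI) in any subject are excluded and
#' reported in the `excluded_regions` attribute. A Benjamini-Hochberg FDR
#' column accompanies the uncorrected p-values.
#'
#' @param sdi Subjects x regions numeric matrix of SDI values (rownames =
#'   subject ids, matching `manifest$subject_id`).
#' @param manifest Data frame with `subject_id`, `group`, and covariate
#'   columns.
#' @param covariates Character vector of manifest columns to adjust for.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Significance level for the `significant` column.
#' @param seed Integer seed.
#' @return Data frame with one row per tested region: `region_id`,
#'   `t_value`, `p_perm`, `direction`, `p_fdr`, `significant`; excluded
#'   region ids in `attr(, "excluded_regions")`.
#' @export
sdi_group_test <- function(sdi, manifest,
                           covariates = c("age", "education", "tiv", "mfd"),
                           n_perm = 5000, alpha = 0.05, seed = 1L) {
  sdi <- as.matrix(sdi)
  manifest <- check_manifest_order(sdi, manifest)
  groups <- factor(manifest$group, levels = c("pilot", "control"))
  if (any(table(groups) < 3)) stop_invalid("each group needs at least 3 subjects")

  keep <- which(colSums(!is.finite(sdi)) == 0)
  excluded <- setdiff(seq_len(ncol(sdi)), keep)
  if (!length(keep)) stop_invalid("no region with complete SDI values")

  cov_m <- if (length(covariates)) as.matrix(manifest[covariates]) else NULL
  r <- if (is.null(cov_m)) sdi[, keep, drop = FALSE] else
    residualize(sdi[, keep, drop = FALSE], cov_m)
  out <- perm_t_matrix(r, groups == "pilot", n_perm, seed)

  res <- data.frame(
    region_id = keep,
    t_value = out$t_obs,
    p_perm = out$p,
    direction = ifelse(out$t_obs >= 0, "pilot_higher", "pilot_lower"),
    stringsAsFactors = FALSE
  )
  res$p_fdr <- stats::p.adjust(res$p_perm, method = "BH")
  res$significant <- res$p_perm < alpha
  attr(res, "excluded_regions") <- excluded
  res
}

#' 2x2 mixed-design ANOVA on coupled vs decoupled connectivity
#'
#' For each edge, tests the group-by-component interaction in a
#' mixed design with within-subject factor component (c-FC z vs d-FC z)
#' and between-subject factor group. Covariates are regressed out of each
#' component beforehand (pooled design). With a two-level within factor
#' the interaction test reduces exactly to a pooled two-sample t-test on
#' the per-subject difference scores (d-FC z minus c-FC z residuals), with
#' `F = t^2` on (1, n-2) degrees of freedom.
#'
#' Family-wise error is controlled by Bonferroni over all tested edges
#' (default), or by a max-F permutation distribution. For edges passing
#' `p_fwe < alpha`, simple effects (per-component two-sample t-tests on
#' the residuals) are reported.
#'
#' @param cfc_z,dfc_z Subjects x N x N arrays of Fisher-z connectivity.
#' @param manifest Data frame with `subject_id`, `group`, covariates.
#' @param edges `"all"` (upper triangle) or a 2-column matrix of region
#'   pairs.
#' @param covariates Manifest columns to adjust for.
#' @param fwe_method `"bonferroni"` or `"maxF"`.
#' @param alpha FWE significance threshold (default 0.01).
#' @param n_perm Permutations for `fwe_method = "maxF"`.
#' @param seed Integer seed (used by maxF only).
#' @return Data frame with one row per tested edge: `region_i`,
#'   `region_j`, `F_interaction`, `p_uncorrected`, `p_fwe`, `significant`,
#'   and simple-effect columns (`t_cfc`, `p_cfc`, `t_dfc`, `p_dfc`, filled
#'   only for significant edges). Edges skipped for missing values are in
#'   `attr(, "skipped_edges")`.
#' @export
mixed_anova_edges <- function(cfc_z, dfc_z, manifest, edges = "all",
                              covariates = c("age", "education", "tiv", "mfd"),
                              fwe_method = c("bonferroni", "maxF"),
                              alpha = 0.01, n_perm = 1000, seed = 1L) {
  fwe_method <- match.arg(fwe_method)
  stopifnot(length(dim(cfc_z)) == 3L, identical(dim(cfc_z), dim(dfc_z)))
  n_sub <- dim(cfc_z)[1]
  n_reg <- dim(cfc_z)[2]
  manifest <- check_manifest_order_n(n_sub, manifest)
  groups <- factor(manifest$group, levels = c("pilot", "control"))
  if (any(table(groups) < 3)) {
    stop_invalid("insufficient degrees of freedom: each group needs >= 3 subjects")
  }

  if (identical(edges, "all")) {
    ut <- which(upper.tri(matrix(0, n_reg, n_reg)), arr.ind = TRUE)
  } else {
    ut <- as.matrix(edges)
    if (ncol(ut) != 2L) stop_invalid("edges must be a 2-column matrix")
    ut <- t(apply(ut, 1, sort))  # upper-triangle orientation
  }
  colnames(ut) <- c("row", "col")

  pull_edges <- function(a) {
    m <- matrix(NA_real_, n_sub, nrow(ut))
    for (e in seq_len(nrow(ut))) m[, e] <- a[, ut[e, 1], ut[e, 2]]
    m
  }
  yc <- pull_edges(cfc_z)
  yd <- pull_edges(dfc_z)
  ok <- colSums(!is.finite(yc)) == 0 & colSums(!is.finite(yd)) == 0
  skipped <- ut[!ok, , drop = FALSE]
  if (!any(ok)) stop_invalid("no edge with complete connectivity values")
  ut <- ut[ok, , drop = FALSE]
  yc <- yc[, ok, drop = FALSE]
  yd <- yd[, ok, drop = FALSE]

  cov_m <- if (length(covariates)) as.matrix(manifest[covariates]) else NULL
  if (!is.null(cov_m)) {
    qx <- qr_full_rank(design_matrix(cov_m, n_sub))
    yc <- qr.resid(qx, yc)
    yd <- qr.resid(qx, yd)
  }

  g1 <- groups == "pilot"
  d <- yd - yc
  t_int <- two_sample_t(d, g1)
  f_int <- t_int^2
  df2 <- n_sub - 2
  p_unc <- stats::pf(f_int, 1, df2, lower.tail = FALSE)

  m <- length(f_int)
  if (fwe_method == "bonferroni") {
    p_fwe <- pmin(1, m * p_unc)
  } else {
    perm <- with_seed(seed, {
      z <- matrix(FALSE, n_sub, n_perm)
      for (b in seq_len(n_perm)) z[sample.int(n_sub, sum(g1)), b] <- TRUE
      z
    })
    max_f <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      max_f[b] <- max(two_sample_t(d, perm[, b])^2)
    }
    p_fwe <- vapply(f_int, function(f) {
      (1 + sum(max_f >= f - 1e-12)) / (n_perm + 1)
    }, numeric(1))
  }

  res <- data.frame(
    region_i = ut[, 1], region_j = ut[, 2],
    F_interaction = f_int, p_uncorrected = p_unc, p_fwe = p_fwe,
    significant = p_fwe < alpha,
    t_cfc = NA_real_, p_cfc = NA_real_,
    t_dfc = NA_real_, p_dfc = NA_real_
  )
  if (any(res$significant)) {
    idx <- which(res$significant)
    tc <- two_sample_t(yc[, idx, drop = FALSE], g1)
    td <- two_sample_t(yd[, idx, drop = FALSE], g1)
    res$t_cfc[idx] <- tc
    res$p_cfc[idx] <- 2 * stats::pt(abs(tc), df2, lower.tail = FALSE)
    res$t_dfc[idx] <- td
    res$p_dfc[idx] <- 2 * stats::pt(abs(td), df2, lower.tail = FALSE)
  }
  attr(res, "skipped_edges") <- skipped
  res
}

#' Residualized Spearman correlation between an edge and flight hours
#'
#' Within the pilot group only: the edge's Fisher-z connectivity is
#' residualized on the nuisance covariates, outliers with
#' `|standardized residual| > outlier_z` are removed once (no iteration),
#' and Spearman's rank correlation with total flight hours is computed on
#' the survivors. `rho^2` is reported alongside `rho` for comparability
#' with squared-correlation conventions.
#'
#' @param fc_z Subjects x N x N array of Fisher-z connectivity (the
#'   decoupled component, in the primary analysis).
#' @param manifest Data frame with `subject_id`, `group`, `flight_hours`,
#'   covariates.
#' @param edge Length-2 region pair.
#' @param covariates Manifest columns to adjust for.
#' @param outlier_z Standardized-residual cutoff (default 3).
#' @return List with `edge`, `rho`, `p`, `rho_sq`, `n_used`,
#'   `n_outliers_removed`.
#' @export
behavior_correlation <- function(fc_z, manifest, edge,
                                 covariates = c("age", "education", "tiv", "mfd"),
                                 outlier_z = 3) {
  stopifnot(length(dim(fc_z)) == 3L)
  manifest <- check_manifest_order_n(dim(fc_z)[1], manifest)
  edge <- sort(as.integer(edge))
  if (length(edge) != 2L || edge[1] == edge[2]) {
    stop_invalid("edge must be two distinct region ids")
  }
  pilots <- which(manifest$group == "pilot" & is.finite(manifest$flight_hours))
  if (length(pilots) < 6) stop_invalid("need at least 6 pilots with flight hours")

  y <- fc_z[pilots, edge[1], edge[2]]
  if (any(!is.finite(y))) stop_invalid("edge has missing connectivity values")
  hours <- manifest$flight_hours[pilots]
  cov_m <- if (length(covariates)) as.matrix(manifest[pilots, covariates]) else NULL
  res <- residualize(y, cov_m)
  zs <- res / stats::sd(res)
  keep <- abs(zs) <= outlier_z
  n_out <- sum(!keep)
  if (sum(keep) < 5) stop_invalid("fewer than 5 pilots left after outlier removal")
  if (stats::sd(res[keep]) == 0) stop_invalid("constant residuals after outlier removal")

  ct <- suppressWarnings(
    stats::cor.test(res[keep], hours[keep], method = "spearman", exact = FALSE))
  list(edge = edge,
       rho = unname(ct$estimate),
       p = ct$p.value,
       rho_sq = unname(ct$estimate)^2,
       n_used = sum(keep),
       n_outliers_removed = n_out)
}

check_manifest_order <- function(values, manifest) {
  manifest <- check_manifest_order_n(nrow(values), manifest)
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), manifest$subject_id)) {
    stop_invalid("row order of values does not match manifest subject_id")
  }
  manifest
}

check_manifest_order_n <- function(n, manifest) {
  if (!is.data.frame(manifest) || !all(c("subject_id", "group") %in% names(manifest))) {
    stop_invalid("manifest must contain subject_id and group")
  }
  if (nrow(manifest) != n) stop_invalid("manifest rows do not match subjects")
  if (anyDuplicated(manifest$subject_id)) stop_invalid("duplicated subject_id")
  manifest
}
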