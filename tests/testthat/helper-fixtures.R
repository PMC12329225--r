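# Shared fixtures: everything is generated in code at test time.

# Dense random weighted graph (always connected) and its harmonic basis.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.05, 1), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

random_basis <- function(n, seed) {
  eigendecompose(normalized_laplacian(random_adjacency(n, seed)))
}

# Independent eigenvalue oracle: characteristic polynomial via
# Faddeev-LeVerrier recursion, roots via polyroot. Deliberately avoids
# eigen().
charpoly_eigenvalues <- function(a) {
  n <- nrow(a)
  coef <- numeric(n + 1)
  coef[1] <- 1
  mk <- a
  for (k in seq_len(n)) {
    ck <- -sum(diag(mk)) / k
    coef[k + 1] <- ck
    mk <- a %*% (mk + ck * diag(n))
  }
  sort(Re(polyroot(rev(coef))))
}

# Small test cohort configuration (null unless overridden).
small_config <- function(seed, ...) {
  defaults <- list(
    n_regions_cortical = 16L, n_regions_subcortical = 4L,
    n_timepoints_acquired = 105L, n_subjects_per_group = 5L,
    community_count = 4L, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sfc_config, args)
}

# Hand-built filtered_signals object with prescribed row norms.
filtered_fixture <- function(coupled_rows, decoupled_rows) {
  structure(list(X_coupled = coupled_rows, X_decoupled = decoupled_rows),
            class = "filtered_signals")
}
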