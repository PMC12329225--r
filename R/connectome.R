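#' Build the GMV-normalized structural adjacency matrix
#'
#' Converts a streamline-count matrix into the weighted structural
#' connectivity (SC) adjacency: the count between two regions is divided by
#' the sum of their gray-matter volumes, `A[i,j] = counts[i,j] /
#' (gmv[i] + gmv[j])`. Probabilistic tractography returns asymmetric
#' seed-to-target counts, so counts are first symmetrized by the arithmetic
#' mean of the two directions; the diagonal is forced to zero.
#'
#' @param streamline_counts Square non-negative matrix of streamline counts.
#' @param gmv Vector of strictly positive regional gray-matter volumes
#'   (mm^3), one per region.
#'
#' @return Symmetric non-negative adjacency matrix with zero diagonal.
#' @export
build_adjacency <- function(streamline_counts, gmv) {
  check_square_matrix(streamline_counts, "streamline_counts")
  n <- nrow(streamline_counts)
  gmv <- as.numeric(gmv)
  if (length(gmv) != n) {
    stop_invalid("gmv length (", length(gmv), ") does not match matrix size (", n, ")")
  }
  if (any(!is.finite(gmv)) || any(gmv <= 0)) {
    stop_invalid("all gray-matter volumes must be finite and > 0")
  }
  if (any(streamline_counts < 0)) {
    stop_invalid("streamline counts must be non-negative")
  }
  counts <- (streamline_counts + t(streamline_counts)) / 2
  a <- counts / outer(gmv, gmv, `+`)
  diag(a) <- 0
  a
}

#' Symmetric normalized Laplacian of a structural connectome
#'
#' Computes `L = I - D^{-1/2} A D^{-1/2}` with `D` the diagonal degree
#' (strength) matrix. A region with zero degree makes `D^{-1/2}` undefined
#' and indicates broken input, so it raises an error naming the offending
#' region rather than being silently regularized.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @return An object of class `"structural_graph"`: a list with elements
#'   `A`, `degrees`, and `L`.
#' @export
normalized_laplacian <- function(A) {
  check_square_matrix(A, "A")
  if (any(A < 0)) stop_invalid("adjacency must be non-negative")
  if (any(diag(A) != 0)) stop_invalid("adjacency diagonal must be zero")
  if (!is_symmetric_num(A)) stop_invalid("adjacency must be symmetric")
  d <- rowSums(A)
  if (any(d <= 0)) {
    stop_invalid("isolated region(s) with zero degree: ",
                 paste(which(d <= 0), collapse = ", "))
  }
  inv_sqrt_d <- 1 / sqrt(d)
  l <- diag(nrow(A)) - (inv_sqrt_d * A) * rep(inv_sqrt_d, each = nrow(A))
  l <- (l + t(l)) / 2  # enforce exact symmetry against rounding
  structure(list(A = A, degrees = d, L = l), class = "structural_graph")
}

#' Connectome harmonics: eigendecomposition of the normalized Laplacian
#'
#' Returns the orthonormal eigenvectors ("SC harmonics") and ascending
#' eigenvalues ("frequencies") of `L`. Low-eigenvalue harmonics vary
#' smoothly over the network; high-eigenvalue harmonics vary rapidly.
#'
#' Two determinism conventions are applied on top of the raw decomposition:
#' in each column the entry of largest absolute value is made positive
#' (first such entry wins on ties), and eigenpairs with numerically equal
#' eigenvalues are ordered by the sign-fixed eigenvectors' lexicographic
#' order.
#'
#' @param graph A `"structural_graph"` from [normalized_laplacian()], or a
#'   bare symmetric matrix to decompose.
#' @return An object of class `"harmonic_basis"`: list with `U` (N x N,
#'   orthonormal columns) and `lambdas` (ascending eigenvalues).
#' @export
eigendecompose <- function(graph) {
  l <- if (inherits(graph, "structural_graph")) graph$L else graph
  check_square_matrix(l, "L")
  if (!is_symmetric_num(l)) stop_invalid("L must be symmetric")
  e <- eigen(l, symmetric = TRUE)
  idx <- order(e$values)
  lam <- e$values[idx]
  u <- e$vectors[, idx, drop = FALSE]

  u <- fix_signs(u)

  # Deterministic order inside numerically degenerate eigenvalue groups.
  grp <- cumsum(c(TRUE, diff(lam) > 1e-10))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) > 1L) {
      ord <- do.call(order, as.data.frame(t(u[, cols, drop = FALSE])))
      u[, cols] <- u[, cols[ord], drop = FALSE]
      lam[cols] <- lam[cols[ord]]
    }
  }

  recon <- u %*% (lam * t(u))
  if (max(abs(recon - l)) >= 1e-8) {
    stop_invalid("eigendecomposition failed to reconstruct L to 1e-8")
  }
  structure(list(U = u, lambdas = lam), class = "harmonic_basis")
}

# Sign convention: make the largest-magnitude entry of each column
# positive; which.max resolves exact ties to the lowest row index.
fix_signs <- function(u) {
  for (k in seq_len(ncol(u))) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) u[, k] <- -u[, k]
  }
  u
}
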