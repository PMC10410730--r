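#' Sample difference vectors between data rows
#'
#' Draws unordered sample pairs uniformly -- without replacement while
#' distinct pairs remain, with replacement beyond -- and returns the matrix
#' of row differences `X[i, ] - X[j, ]`. Difference vectors are the targets
#' of the reconstruction loss that the unsupervised weight matrices
#' minimize: a hidden layer can realize a decision boundary between two
#' samples only if their difference lies (close to) the row space of its
#' weight matrix.
#'
#' @param X Numeric matrix (samples x features), at least 2 rows.
#' @param n_pairs Number of difference vectors; default 10 per sample.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A `difference_matrix`: list with `rows` (n_pairs x features),
#'   `pair_index` (n_pairs x 2 integer matrix, first minus second), `seed`.
#' @export
sample_differences <- function(X, n_pairs = 10L * nrow(X), seed = 1L) {
  if (!is.matrix(X) || nrow(X) < 2L)
    dm_stop("dm_insufficient_data", "X needs at least 2 rows")
  stopifnot(n_pairs >= 1L)
  m <- nrow(X)
  n_avail <- m * (m - 1) / 2
  with_seed(seed, {
    decode <- function(code) {
      # code in 1..m(m-1)/2 -> unordered pair (i < j), row-major over i
      i <- ceiling(((2 * m - 1) - sqrt((2 * m - 1)^2 - 8 * code)) / 2)
      j <- code - (i - 1) * (2 * m - i) / 2 + i
      cbind(as.integer(i), as.integer(j))
    }
    k1 <- min(n_pairs, n_avail)
    codes <- if (n_avail <= .Machine$integer.max) {
      sample.int(n_avail, k1)
    } else {
      unique_codes <- numeric(0)
      while (length(unique_codes) < k1) {
        unique_codes <- unique(c(unique_codes, ceiling(runif(k1) * n_avail)))
      }
      unique_codes[seq_len(k1)]
    }
    if (n_pairs > n_avail)
      codes <- c(codes, ceiling(runif(n_pairs - n_avail) * n_avail))
    pairs <- decode(codes)
    rows <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    structure(list(rows = rows, pair_index = pairs, seed = seed),
              class = "difference_matrix")
  })
}

new_weight_matrix <- function(W, method, constraints = list(), seed = NA_integer_) {
  structure(list(W = W, method = method, constraints = constraints, seed = seed),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %s, %d x %d\n", x$method, nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Principal components of a difference matrix
#'
#' Rows of the returned weight matrix are the top-`k` right singular
#' vectors of the difference matrix: the rank-`k` minimizer of the
#' reconstruction loss `||DX - C W||^2`. Sign convention: the
#' largest-magnitude entry of each row is positive.
#'
#' @param dx A `difference_matrix` from [sample_differences()].
#' @param k Number of components, `k <= min(dim(dx$rows))`.
#' @return A `weight_matrix` with orthonormal rows, method `"dpca"`.
#' @export
delta_pca <- function(dx, k) {
  DX <- dx$rows
  if (k > min(dim(DX)))
    dm_stop("dm_rank_error", "k = %d exceeds min(dim) = %d", k, min(dim(DX)))
  sv <- svd(DX, nu = 0, nv = k)
  W <- fix_row_signs(t(sv$v))
  new_weight_matrix(W, "dpca", seed = dx$seed)
}

#' Gaussian random-projection weight matrix
#'
#' I.i.d. Gaussian entries with standard deviation `sd` (default fan-in
#' normalized, `1/sqrt(n)`), the baseline the structured decompositions are
#' compared against.
#'
#' @param n Input dimensionality (columns).
#' @param k Number of rows; `k = 0` yields an empty matrix.
#' @param seed Integer seed.
#' @param sd Entry standard deviation.
#' @return A `weight_matrix`, method `"rp"`.
#' @export
random_projection <- function(n, k, seed = 1L, sd = 1 / sqrt(n)) {
  stopifnot(n >= 1L, k >= 0L)
  W <- with_seed(seed, matrix(rnorm(k * n, sd = sd), nrow = k, ncol = n))
  new_weight_matrix(W, "rp", constraints = list(sd = sd), seed = seed)
}

#' Unconstrained reconstruction residual
#'
#' `||DX - C* W||_F^2` with `C*` the least-squares coefficients, i.e. the
#' squared Frobenius distance between the difference matrix and its
#' projection onto the row space of `W`.
#'
#' @param W A `weight_matrix` or plain matrix (k x n).
#' @param dx A `difference_matrix` (rows are length n).
#' @return Non-negative scalar.
#' @export
reconstruction_residual <- function(W, dx) {
  Wm <- if (inherits(W, "weight_matrix")) W$W else W
  DX <- dx$rows
  stopifnot(ncol(Wm) == ncol(DX))
  if (nrow(Wm) == 0L) return(sum(DX^2))
  qrW <- qr(t(Wm))
  r <- qrW$rank
  Q <- qr.Q(qrW)[, seq_len(r), drop = FALSE]
  sum(DX^2) - sum((DX %*% Q)^2)
}

# one full coordinate-descent sparse-coding pass for all rows of DX:
# minimize ||x - c W||^2 + lambda ||c||_1 per row, W rows unit L2 norm
sparse_code <- function(DX, W, lambda, C0 = NULL, sweeps = 25L, tol = 1e-9) {
  k <- nrow(W)
  G <- W %*% t(W)                # k x k Gram
  B <- DX %*% t(W)               # m x k correlations
  C <- if (is.null(C0)) matrix(0, nrow(DX), k) else C0
  diagG <- diag(G)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      # residual correlation with atom j, excluding its own contribution
      rj <- drop(B[, j] - C %*% G[, j]) + C[, j] * diagG[j]
      new <- soft_threshold(rj, lambda / 2) / diagG[j]
      delta <- max(delta, max(abs(new - C[, j])))
      C[, j] <- new
    }
    if (delta < tol) break
  }
  C
}

sd_objective <- function(DX, C, W, lambda) sum((DX - C %*% W)^2) + lambda * sum(abs(C))

#' Sparse dictionary learning on a difference matrix
#'
#' Alternating minimization of `||DX - C W||^2 + lambda ||C||_1` with unit
#' L2-norm rows of `W`: coordinate-descent sparse coding for `C`, exact
#' row-wise dictionary updates for `W`. Both steps are exact blockwise
#' minimizers, so the objective is non-increasing across outer iterations.
#'
#' @param dx A `difference_matrix`.
#' @param k Dictionary size (rows of `W`).
#' @param lambda Non-negative L1 penalty on the coefficients.
#' @param n_iter Outer iterations.
#' @param seed Seed for the dictionary initialization.
#' @return List with `W` (a `weight_matrix`, method `"dsd"`), `C`
#'   (m x k coefficients), and `objective` (value per outer iteration).
#' @export
delta_sd <- function(dx, k, lambda, n_iter = 30L, seed = 1L) {
  if (lambda < 0) dm_stop("dm_parameter_error", "lambda must be >= 0")
  DX <- dx$rows
  n <- ncol(DX)
  W <- with_seed(derive_seed(seed, "dsd_init"), {
    W0 <- matrix(rnorm(k * n), k, n)
    W0 / sqrt(rowSums(W0^2))
  })
  C <- NULL
  obj <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    C <- sparse_code(DX, W, lambda, C0 = C)
    # exact minimizer over each unit-norm row given the others fixed
    for (j in seq_len(k)) {
      cj <- C[, j]
      if (sum(cj^2) == 0) next   # unused atom: keep previous direction
      Rj <- DX - C[, -j, drop = FALSE] %*% W[-j, , drop = FALSE]
      wj <- drop(crossprod(Rj, cj))
      nrm <- sqrt(sum(wj^2))
      if (nrm > 0) W[j, ] <- wj / nrm
      # refit the coefficient scale for this atom (keeps objective monotone)
      C[, j] <- soft_threshold(drop(Rj %*% W[j, ]), lambda / 2)
    }
    obj[it] <- sd_objective(DX, C, W, lambda)
    if (it > 1 && obj[it - 1] - obj[it] < 1e-10 * max(1, obj[1])) {
      obj <- obj[seq_len(it)]
      break
    }
  }
  # sign convention; flipping a row and its coefficient column together
  # leaves the objective unchanged
  for (j in seq_len(k)) {
    jj <- which.max(abs(W[j, ]))
    if (W[j, jj] < 0) { W[j, ] <- -W[j, ]; C[, j] <- -C[, j] }
  }
  list(W = new_weight_matrix(W, "dsd", constraints = list(lambda = lambda), seed = seed),
       C = C, objective = obj)
}

# project x onto {u : ||u||_2 = 1, ||u||_1 <= c} via soft-threshold with
# the threshold found by binary search (penalized matrix decomposition step)
l1l2_project <- function(x, c1, tol = 1e-9, max_iter = 200L) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x)
  u <- x / nrm
  if (sum(abs(u)) <= c1) return(u)
  lo <- 0; hi <- max(abs(x))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    su <- soft_threshold(x, mid)
    nn <- sqrt(sum(su^2))
    l1 <- if (nn > 0) sum(abs(su)) / nn else 0
    if (l1 > c1) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, max(abs(x)))) break
  }
  su <- soft_threshold(x, hi)
  su / sqrt(sum(su^2))
}

#' Penalized matrix decomposition of a difference matrix
#'
#' Rank-1 factors extracted sequentially with deflation. Each factor pair
#' `(u, v)` maximizes `u' DX v` subject to `||u||_2 <= 1, ||u||_1 <= delta`
#' (left factor, coefficient side) and `||v||_2 <= 1, ||v||_1 <= eps`
#' (right factor, weight side), by alternating soft-thresholded power
#' iterations with the threshold level set by binary search. The L1 bounds
#' drive the weight rows toward localized receptive fields.
#'
#' @param dx A `difference_matrix` (m x n rows).
#' @param k Number of factors.
#' @param eps L1 bound on rows of `W`; feasible range `[1, sqrt(n)]`.
#' @param delta L1 bound on the unit-scaled columns of `C`; range
#'   `[1, sqrt(m)]`.
#' @param n_iter Power iterations per factor.
#' @param seed Seed for factor initialization.
#' @return List with `W` (`weight_matrix`, method `"dpmd"`, unit-L2 rows),
#'   `C` (m x k, columns `d_j * u_j` so that `DX ~ C W`), `d` (factor
#'   scales), and `U` (unit-scaled left factors).
#' @export
delta_pmd <- function(dx, k, eps, delta, n_iter = 50L, seed = 1L) {
  DX <- dx$rows
  m <- nrow(DX); n <- ncol(DX)
  if (eps < 1 || delta < 1)
    dm_stop("dm_infeasible_constraint",
            "eps and delta must be >= 1 (L1 bounds on unit-L2 vectors)")
  R <- DX
  W <- matrix(0, k, n); U <- matrix(0, m, k); d <- numeric(k)
  for (f in seq_len(k)) {
    v <- with_seed(derive_seed(seed, paste0("pmd_init_", f)), {
      v0 <- svd(R, nu = 0, nv = 1)$v[, 1]
      v0 + rnorm(n, sd = 1e-6)       # break exact ties deterministically
    })
    v <- v / sqrt(sum(v^2))
    u <- rep(0, m)
    for (it in seq_len(n_iter)) {
      u_new <- l1l2_project(drop(R %*% v), delta)
      v_new <- l1l2_project(drop(crossprod(R, u_new)), eps)
      if (max(abs(u_new - u)) < 1e-10 && max(abs(v_new - v)) < 1e-10) {
        u <- u_new; v <- v_new; break
      }
      u <- u_new; v <- v_new
    }
    dj <- drop(t(u) %*% R %*% v)
    if (dj < 0) { v <- -v; dj <- -dj }
    W[f, ] <- v; U[, f] <- u; d[f] <- dj
    R <- R - dj * tcrossprod(u, v)
  }
  # sign convention on rows of W, propagated to U so DX ~ U diag(d) W holds
  for (f in seq_len(k)) {
    j <- which.max(abs(W[f, ]))
    if (W[f, j] < 0) { W[f, ] <- -W[f, ]; U[, f] <- -U[, f] }
  }
  C <- U %*% diag(d, nrow = k)
  list(W = new_weight_matrix(W, "dpmd",
                             constraints = list(eps = eps, delta = delta),
                             seed = seed),
       C = C, d = d, U = U)
}
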