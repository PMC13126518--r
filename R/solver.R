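#' Compress a least-squares system by truncated SVD
#'
#' Projects the system `K g ~ c` onto the singular subspace of `K` whose
#' singular values satisfy `sigma_i >= rel_tol * sigma_max`. With
#' `K = U S V'`, the projected design is `S_r V_r'` and the projected
#' target `U_r' c`: least-squares solutions of the projected and full
#' systems coincide up to the discarded (numerically null) directions.
#' The default threshold removes only noise-level singular directions —
#' resolution control is the job of the regularization parameter, not of
#' truncation.
#'
#' @param K Numeric matrix (n x N), e.g. a [build_kernel()] matrix.
#' @param c Numeric vector of length n (the measured amplitudes).
#' @param rel_tol Relative singular-value cutoff in (0, 1).
#' @return A list with `design` (r x N), `target` (length r) and
#'   `rank_kept` (r).
#' @export
svd_compress <- function(K, c, rel_tol = 1e-12) {
  if (!is.matrix(K) || nrow(K) == 0 || ncol(K) == 0) {
    abort("`K` must be a non-empty numeric matrix.")
  }
  if (length(c) != nrow(K)) {
    abort(sprintf("length(c) == %d but nrow(K) == %d.", length(c), nrow(K)))
  }
  if (!is.numeric(rel_tol) || length(rel_tol) != 1 ||
      rel_tol <= 0 || rel_tol >= 1) {
    abort("`rel_tol` must be a single number in (0, 1).")
  }
  dec <- svd(unclass(K))
  r <- sum(dec$d >= rel_tol * dec$d[1])
  design <- dec$d[seq_len(r)] * t(dec$v[, seq_len(r), drop = FALSE])
  target <- drop(crossprod(dec$u[, seq_len(r), drop = FALSE], c))
  list(design = design, target = target, rank_kept = r)
}

#' Stack a Tikhonov penalty onto a least-squares system
#'
#' Appends `sqrt(alpha) * L` below the design matrix and zeros below the
#' target, so that minimizing the stacked residual norm minimizes
#' `||K g - c||^2 + alpha ||L g||^2`. `L` is the identity (classical
#' Tikhonov, the default) or the (N-2) x N second-difference operator
#' (curvature-penalizing smoothing).
#'
#' @param design Numeric matrix (possibly SVD-compressed).
#' @param target Numeric vector, `length(target) == nrow(design)`.
#' @param alpha Non-negative regularization parameter. Larger values give
#'   smoother, broader distributions; typical values are 0.01, 0.1, 1, 10.
#' @param operator_kind `"identity"` or `"second_difference"` (alias
#'   `"d2"`).
#' @return A `regularized_system`: list with stacked `design`, `target`,
#'   plus `alpha`, `operator_kind` and `n_data` (rows before stacking).
#' @export
assemble_regularized_system <- function(design, target, alpha,
                                        operator_kind = c("identity",
                                                          "second_difference",
                                                          "d2")) {
  operator_kind <- match.arg(operator_kind)
  if (operator_kind == "d2") operator_kind <- "second_difference"
  if (!is.matrix(design) || length(target) != nrow(design)) {
    abort("`design` must be a matrix with one row per element of `target`.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 0) {
    abort("`alpha` must be a single non-negative number.")
  }
  N <- ncol(design)
  n_data <- nrow(design)
  if (alpha > 0) {
    L <- regularization_operator(operator_kind, N)
    design <- rbind(unclass(design), sqrt(alpha) * L)
    target <- c(target, numeric(nrow(L)))
  }
  structure(
    list(design = design, target = target, alpha = alpha,
         operator_kind = operator_kind, n_data = n_data),
    class = "regularized_system"
  )
}

regularization_operator <- function(operator_kind, N) {
  if (operator_kind == "identity") {
    diag(N)
  } else {
    if (N < 3) abort("second-difference operator needs at least 3 unknowns.")
    L <- matrix(0, N - 2, N)
    for (i in seq_len(N - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
    L
  }
}

#' Non-negative least squares
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` by the Lawson–Hanson
#' active-set algorithm. At the solution the Karush–Kuhn–Tucker
#' conditions hold: the gradient `A'(A x - b)` is (numerically) zero on
#' the positive coordinates and non-negative on the zero coordinates.
#'
#' @param system A `regularized_system` from
#'   [assemble_regularized_system()], or any list with elements `design`
#'   and `target`.
#' @param max_iter Iteration cap; defaults to `10 * ncol(design)`.
#' @return The non-negative solution vector, with attributes `iterations`
#'   and `rss` (residual sum of squares of the stacked system).
#' @export
solve_nnls <- function(system, max_iter = NULL) {
  A <- system$design
  b <- system$target
  if (!is.matrix(A) || length(b) != nrow(A)) {
    abort("`system` must carry a design matrix and a target of matching length.")
  }
  N <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * N
  x <- numeric(N)
  passive <- logical(N)
  AtB <- drop(crossprod(A, b))
  # dual feasibility tolerance, scaled to the problem
  tol <- 1e-10 * max(1, max(abs(AtB)))
  w <- AtB  # negative gradient of 0.5*||Ax-b||^2 at x = 0
  iter <- 0L
  fail <- function() {
    abort(sprintf(
      "NNLS did not converge within %d iterations (N = %d, %d coordinates in the passive set, max dual = %.3g).",
      max_iter, N, sum(passive), max(w[!passive])
    ))
  }
  while (any(!passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter) fail()
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) fail()
      P <- which(passive)
      zz <- qr.coef(qr(A[, P, drop = FALSE]), b)
      zz[is.na(zz)] <- 0  # rank-deficient passive set: drop null directions
      z <- numeric(N)
      z[P] <- zz
      if (all(z[P] > 0)) {
        x <- z
        break
      }
      # step from x toward z until the first passive coordinate reaches zero
      neg <- P[z[P] <= 0]
      ratios <- x[neg] / (x[neg] - z[neg])
      ratios[!is.finite(ratios)] <- 0
      step <- min(ratios)
      x <- x + step * (z - x)
      drop_idx <- neg[ratios <= step + 1e-12]
      x[drop_idx] <- 0
      passive[drop_idx] <- FALSE
      x[!passive] <- 0
    }
    w <- AtB - drop(crossprod(A, A %*% x))
  }
  resid <- b - drop(A %*% x)
  structure(x, iterations = iter, rss = sum(resid^2))
}

#' Sum of squared residuals between data and model
#'
#' The misfit minimized by the inversion: `||observed - model||^2`.
#'
#' @param observed,model Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
chi_squared <- function(observed, model) {
  if (length(observed) != length(model)) {
    abort(sprintf("length mismatch: %d observed vs %d model values.",
                  length(observed), length(model)))
  }
  sum((observed - model)^2)
}
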