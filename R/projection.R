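# The projection algorithm: power iteration converging to the unit term
# vector that maximizes the sum of squared projections of a fixed document
# set — the first right singular vector of the stacked row matrix.

as_row_matrix <- function(rows) {
  if (inherits(rows, "theme_corpus")) return(rows$Xn)
  rows
}

check_phi <- function(rows, phi) {
  if (length(phi) != ncol(rows))
    stop("dimension mismatch: phi has length ", length(phi),
         " but rows have ", ncol(rows), " columns")
  if (!all(is.finite(phi))) stop("phi contains non-finite entries")
  invisible(TRUE)
}

#' Projection objective
#'
#' The sum of squared projections of the document rows onto the unit vector
#' `phi`: \eqn{\sum_i (u_i, \phi)^2}.  At the optimum over unit vectors this
#' equals the squared largest singular value of the row matrix.
#'
#' @param rows Matrix (dense or sparse) whose rows are document vectors, or
#'   a `theme_corpus` (its normalized rows are used).
#' @param phi Numeric unit vector over the same term space.
#' @return Non-negative scalar.
#' @export
projection_objective <- function(rows, phi) {
  rows <- as_row_matrix(rows)
  check_phi(rows, phi)
  sum(as.vector(rows %*% phi)^2)
}

#' Projection residual
#'
#' Total squared distance of the rows from their projections onto `phi`:
#' \eqn{\sum_i \|u_i - (u_i,\phi)\phi\|^2}.  For unit `phi` this equals
#' \eqn{\sum_i \|u_i\|^2} minus the projection objective, so minimizing the
#' residual and maximizing the objective are the same problem.
#'
#' @inheritParams projection_objective
#' @return Non-negative scalar.
#' @export
projection_residual <- function(rows, phi) {
  rows <- as_row_matrix(rows)
  check_phi(rows, phi)
  s <- as.vector(rows %*% phi)
  sum(Matrix::rowSums(rows^2)) - 2 * sum(s^2) + sum(s^2) * sum(phi^2)
}

#' One projection-algorithm step
#'
#' The update \eqn{\phi \leftarrow \mathrm{normalize}(\sum_i (u_i,\phi)\,u_i)}:
#' a single power-iteration step on the Gram operator of the rows.  The
#' objective never decreases along these steps.
#'
#' @inheritParams projection_objective
#' @return Unit-norm numeric vector.
#' @export
projection_step <- function(rows, phi) {
  rows <- as_row_matrix(rows)
  check_phi(rows, phi)
  w <- as.vector(rows %*% phi)
  v <- as.vector(Matrix::crossprod(rows, w))
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("degenerate start: phi is orthogonal to the row space")
  v / nv
}

#' Run the projection algorithm
#'
#' Iterates [projection_step()] from `phi0` until the direction stabilises:
#' the stopping criterion is \eqn{1 - (\phi_{t+1}, \phi_t) < tol}, a
#' scale-free bound on the angular change per step.  For non-negative input
#' rows and a start vector with positive overlap, the iteration converges
#' to the first right singular vector of the row matrix (power-iteration
#' theory; when the top two singular values coincide the limit depends on
#' the start vector).
#'
#' @inheritParams projection_objective
#' @param phi0 Starting unit vector.  Default: the normalized column-sum of
#'   the rows, which has positive overlap with the top singular vector for
#'   non-negative input.
#' @param tol Convergence tolerance on `1 - cos(angle between iterates)`.
#' @param max_iter Iteration cap.
#' @return A `consensus_vector`: named numeric unit vector with attributes
#'   `iterations`, `converged` and `objective`.  The sign is fixed so the
#'   coordinate of largest magnitude is non-negative.
#' @export
run_projection <- function(rows, phi0 = NULL, tol = 1e-10, max_iter = 500L) {
  rows <- as_row_matrix(rows)
  if (tol <= 0) stop("tol must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (is.null(phi0)) {
    phi0 <- as.vector(Matrix::colSums(rows))
    n0 <- sqrt(sum(phi0^2))
    if (n0 == 0) stop("degenerate start: rows are all zero")
    phi0 <- phi0 / n0
  }
  check_phi(rows, phi0)

  phi <- phi0
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    phi_new <- projection_step(rows, phi)
    iterations <- it
    if (1 - sum(phi_new * phi) < tol) {
      phi <- phi_new
      converged <- TRUE
      break
    }
    phi <- phi_new
  }

  # deterministic sign: largest-magnitude coordinate non-negative (for
  # non-negative rows this leaves phi entrywise non-negative)
  if (phi[[which.max(abs(phi))]] < 0) phi <- -phi
  cn <- colnames(rows)
  if (!is.null(cn)) names(phi) <- cn
  structure(phi, class = "consensus_vector",
            iterations = iterations, converged = converged,
            objective = projection_objective(rows, phi))
}

#' @export
print.consensus_vector <- function(x, n = 10L, ...) {
  cat("Consensus vector over", length(x), "terms",
      sprintf("(objective %.6g, %d iteration%s%s)\n",
              attr(x, "objective"), attr(x, "iterations"),
              if (attr(x, "iterations") == 1L) "" else "s",
              if (isTRUE(attr(x, "converged"))) "" else ", NOT converged"))
  top <- top_terms(x, n)
  if (length(top) > 0L) {
    cat("Top terms:\n")
    print(round(top, 4))
  }
  invisible(x)
}

#' Top-weighted terms of a consensus vector
#'
#' @param phi A `consensus_vector` (or any named numeric vector).
#' @param n How many terms.
#' @return Named numeric vector of the `n` largest-magnitude coordinates,
#'   in decreasing magnitude order (ties broken by term name).
#' @export
top_terms <- function(phi, n = 10L) {
  w <- as.numeric(phi)
  names(w) <- names(phi)
  if (is.null(names(w))) names(w) <- as.character(seq_along(w))
  ord <- order(-abs(w), names(w), method = "radix")
  w[ord[seq_len(min(n, length(w)))]]
}
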