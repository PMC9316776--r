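# Gauss-Hermite rules and the group-level integration helpers shared by the
# marginal likelihood. Nodes/weights come from the Golub-Welsch eigenvalue
# decomposition of the Hermite Jacobi matrix (weight function e^{-x^2}).

#' Gauss-Hermite nodes and weights
#'
#' Physicists' convention: `sum(w * f(x))` approximates the integral of
#' `f(x) exp(-x^2)`. Computed by eigendecomposition of the symmetric
#' tridiagonal Jacobi matrix, exact for polynomials up to degree `2n - 1`.
#'
#' @param n Number of nodes.
#' @return List with `nodes` (increasing) and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

# Vectorised-over-groups Newton ascent for a scalar random effect.
# g: function(b_vector[m]) -> per-group objective (length m), assumed
# smooth and concave near the optimum. Derivatives by central differences.
# Returns list(mode, hess = -g'' at the mode, value = g(mode)).
.newton_modes_1d <- function(g, m, start = NULL, h = 1e-4,
                             max_iter = 50, tol = 1e-9) {
  b <- if (is.null(start) || length(start) != m) numeric(m) else start
  clean <- function(v) ifelse(is.finite(v), v, -Inf)  # overflow = downhill
  g0 <- clean(g(b))
  for (it in seq_len(max_iter)) {
    gp <- clean(g(b + h)); gm <- clean(g(b - h))
    d1 <- (gp - gm) / (2 * h)
    d2 <- (gp - 2 * g0 + gm) / h^2
    d2[!is.finite(d2)] <- -1
    d1[!is.finite(d1)] <- 0
    d2 <- pmin(d2, -1e-8)
    step <- pmax(pmin(-d1 / d2, 3), -3)
    bn <- b + step
    gn <- clean(g(bn))
    # halve steps for groups whose objective worsened
    for (tries in 1:8) {
      worse <- gn < g0 - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      bn[worse] <- b[worse] + step[worse]
      gn <- clean(g(bn))
    }
    moved <- max(abs(step))
    b <- bn; g0 <- gn
    if (moved < tol) break
  }
  gp <- clean(g(b + h)); gm <- clean(g(b - h))
  d2 <- (gp - 2 * g0 + gm) / h^2
  d2[!is.finite(d2)] <- -1
  list(mode = b, hess = pmax(-d2, 1e-10), value = g0)
}

# log-sum-exp across the columns of a matrix (rows kept)
.row_logsumexp <- function(L) {
  M <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  M + log(rowSums(exp(L - M)))
}
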