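#' Solve the frequency step: best simplex mixture weights for fixed profiles
#'
#' With clone profiles `C` held fixed, the per-sample clone frequencies `U`
#' minimizing the L1 reconstruction error `sum |F - U C|` subject to
#' `U >= 0` and unit row sums are a linear program (absolute values
#' linearized with auxiliary variables); the returned `U` is a global LP
#' optimum. In leaf-only mode the frequencies of internal non-root clones
#' are fixed to zero, so bulk samples are mixtures of leaf clones and the
#' normal root only.
#'
#' @param F bulk matrix m x (l+g+2r), or a `bulk_obs`.
#' @param C integer clone profile matrix N x (l+g+2r).
#' @param leaf_only restrict mass to leaves and root.
#' @param time_limit optional LP time limit (seconds).
#' @return list with `U` (m x N), `objective` (the L1 data term) and
#'   `status`.
#' @examples
#' \donttest{
#' C <- rbind(c(2, 1, 1), c(0, 1, 1))  # one aberrant clone over the root
#' F <- 0.3 * C[1, ] + 0.7 * C[2, ]
#' fit <- solve_u_step(matrix(F, 1), C)
#' round(fit$U, 3)  # recovers (0.3, 0.7)
#' }
#' @export
solve_u_step <- function(F, C, leaf_only = FALSE, time_limit = NULL) {
  if (inherits(F, "bulk_obs")) F <- F$F
  F <- as.matrix(F)
  m <- nrow(F)
  N <- nrow(C)
  V <- ncol(C)
  if (ncol(F) != V) stop("F and C disagree on column count")

  mod <- milp_model()
  u_idx <- matrix(milp_add_vars(mod, m * N, lb = 0, ub = 1), m, N)
  t_idx <- matrix(milp_add_vars(mod, m * V, lb = 0, ub = Inf, obj = 1), m, V)
  if (leaf_only && N > 1) {
    n <- (N + 1L) %/% 2L
    internal <- setdiff(seq_len(N), c(seq_len(n), N))
    if (length(internal)) milp_fix(mod, u_idx[, internal], 0)
  }
  for (p in seq_len(m)) {
    milp_add_constr(mod, u_idx[p, ], rep(1, N), lb = 1, ub = 1)
    for (v in seq_len(V)) {
      nz <- which(C[, v] != 0)
      # t >= F - sum u c  and  t >= -(F - sum u c)
      milp_add_constr(mod, c(t_idx[p, v], u_idx[p, nz]),
                      c(1, C[nz, v]), lb = F[p, v])
      milp_add_constr(mod, c(t_idx[p, v], u_idx[p, nz]),
                      c(1, -C[nz, v]), lb = -F[p, v])
    }
  }
  sol <- milp_solve(mod, time_limit = time_limit)
  if (!identical(sol$status, "optimal")) {
    stop("frequency LP did not reach optimality (status: ", sol$status, ")")
  }
  U <- matrix(sol$x[u_idx], m, N)
  list(U = U, objective = sol$objective, status = sol$status)
}

#' Default regularization weights
#'
#' Scale-normalizing defaults for the copy-number evolution penalty
#' (`lambda1`, weighting `R`) and the VAF-consistency penalty (`lambda2`,
#' weighting `S`):
#' `lambda1 = (l+g+2r) / (2 r m N)` and `lambda2 = (l+g+2r) / (2 (l+g))`.
#' Both normalize the penalty to the expected scale of the L1 data term and
#' both can be overridden in [solver_config()]. Results are not very
#' sensitive to these weights.
#'
#' @param l,g,r breakpoint, SNV and segment counts.
#' @param m sample count.
#' @param N clone count.
#' @return named list with `lambda1` and `lambda2`.
#' @examples
#' default_lambdas(l = 2, g = 1, r = 2, m = 1, N = 3)  # 7/12 and 7/6
#' @export
default_lambdas <- function(l, g, r, m, N) {
  if (l + g == 0) stop("lambda2 undefined when there are no variants (l+g=0)")
  if (r <= 0 || m <= 0 || N <= 0) stop("counts must be positive")
  list(lambda1 = (l + g + 2 * r) / (2 * r * m * N),
       lambda2 = (l + g + 2 * r) / (2 * (l + g)))
}
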