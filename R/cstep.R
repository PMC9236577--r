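#' Solver configuration
#'
#' Tuning knobs for the coordinate-descent solver. The tree size is set
#' either by `n_leaves` (clone count `N = 2 n_leaves - 1`) or by
#' `max_nodes` (an odd clone count, default 9, whose surplus nodes are
#' meant to be removed afterwards by [collapse_tree()]).
#'
#' `phasing` selects how variant copy changes are coupled to allele-specific
#' segment copy changes along active non-introduction edges: `"strict"`
#' enforces the coupling equalities for every variant and matched allele on
#' every active edge; `"gated"` additionally deactivates them for variants
#' absent from the parent clone, the reading under which every trajectory of
#' the bundled simulator is a feasible solution.
#'
#' @param n_leaves leaf count, or `NULL` to use `max_nodes`.
#' @param max_nodes total clone count (odd), used when `n_leaves` is `NULL`.
#' @param c_max maximum copy number (default 10).
#' @param lambda1,lambda2 penalty weights; `NULL` uses [default_lambdas()].
#' @param max_iters maximum coordinate-descent iterations (default 10).
#' @param time_limit time limit per ILP solve in seconds (default 1000).
#' @param n_restarts random restarts (default 5).
#' @param tol relative objective improvement below which descent stops.
#' @param leaf_only restrict clone frequencies to leaves + root.
#' @param phasing `"strict"` or `"gated"` (see Details).
#' @param mip_gap optional relative MIP gap passed to the backend.
#' @param seed master seed for restart initializations.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(n_leaves = NULL, max_nodes = 9, c_max = 10,
                          lambda1 = NULL, lambda2 = NULL, max_iters = 10,
                          time_limit = 1000, n_restarts = 5, tol = 1e-4,
                          leaf_only = FALSE,
                          phasing = c("strict", "gated"),
                          mip_gap = NULL, seed = NULL) {
  phasing <- match.arg(phasing)
  if (is.null(n_leaves)) {
    if (max_nodes %% 2 != 1) stop("max_nodes must be odd (N = 2n - 1)")
    n_leaves <- (max_nodes + 1) / 2
  }
  if (n_leaves < 2) stop("n_leaves must be at least 2")
  if (c_max < 1) stop("c_max must be at least 1")
  stopifnot(max_iters >= 1, time_limit > 0, n_restarts >= 1, tol > 0)
  structure(
    list(n_leaves = as.integer(n_leaves), c_max = as.integer(c_max),
         lambda1 = lambda1, lambda2 = lambda2,
         max_iters = as.integer(max_iters), time_limit = time_limit,
         n_restarts = as.integer(n_restarts), tol = tol,
         leaf_only = leaf_only, phasing = phasing, mip_gap = mip_gap,
         seed = seed),
    class = "solver_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the profile step: phylogeny-constrained integer program
#'
#' With frequencies `U` held fixed, solves for integer clone profiles `C`,
#' the binary tree (edge matrix `E`, ancestry `A`), variant introduction
#' edges `W` and allele assignments `D` minimizing
#' `sum |F - U C| + lambda1 R + lambda2 S`, where `R` is the total L1
#' copy-number change along tree edges and `S` the L1 discrepancy between
#' observed VAFs and the VAFs implied by the solution. Constraints enforce a
#' rooted binary tree on `N = 2n - 1` nodes with a diploid variant-free
#' root, copy numbers in `[0, c_max]`, Dollo introduction and persistence of
#' breakpoints and SNVs (gain once, loss only by copy-number loss), shared
#' introduction edges and alleles for breakpoint mate pairs, allele-phased
#' coupling of variant and segment copy changes, and variant copies bounded
#' by their allele's segment copy.
#'
#' Clone labels are canonicalized to break tree symmetry: leaves are
#' `1..n`, internal nodes `n+1..N-1` with every internal child labeled
#' below its parent, the root is `N`. Any binary tree can be labeled this
#' way, so the restriction loses no solutions.
#'
#' @param F bulk matrix m x (l+g+2r) or `bulk_obs` (its clamped VAFs are
#'   used for the consistency term).
#' @param U fixed frequency matrix m x N, rows on the simplex.
#' @param panel a [variant_panel].
#' @param config a [solver_config()] (its `n_leaves` fixes N).
#'
#' @return list with `profiles` (`clone_profiles`), `tree` (`clone_tree`
#'   with `W` and `rho`), penalty values `R` and `S`, the backend `status`
#'   (`"optimal"` or `"limit"` for a best-incumbent solution) and
#'   `objective` (backend value, equal to data + lambda1 R + lambda2 S at
#'   the incumbent).
#' @export
solve_c_step <- function(F, U, panel, config) {
  bulk <- NULL
  if (inherits(F, "bulk_obs")) {
    bulk <- F
    F <- bulk$F
  }
  F <- as.matrix(F)
  U <- as.matrix(U)
  n <- config$n_leaves
  N <- 2L * n - 1L
  if (ncol(U) != N) stop("U has ", ncol(U), " columns but N = ", N)
  m <- nrow(F)
  V <- n_cols(panel)
  nv <- panel$l + panel$g
  r <- panel$r
  cmax <- config$c_max
  gated <- identical(config$phasing, "gated")

  lam <- if (nv > 0) default_lambdas(panel$l, panel$g, r, m, N)
         else list(lambda1 = 1 / (m * N), lambda2 = 0)
  lambda1 <- config$lambda1 %||% lam$lambda1
  lambda2 <- config$lambda2 %||% lam$lambda2

  if (is.null(bulk)) {
    psi <- mixed_segment_copy(F, panel)
    vaf <- pmin(pmax(compute_vaf(F, panel), 0), 1)
  } else {
    psi <- bulk$psi
    vaf <- bulk$vaf
  }

  seg_of <- variant_segment(panel)
  internals <- if (n >= 2 && N - 1L >= n + 1L) (n + 1L):(N - 1L) else integer()
  parents <- c(internals, N)

  # possible edges under the canonical labeling
  ep_i <- integer(); ep_j <- integer()
  for (i in parents) {
    for (j in seq_len(N - 1L)) {
      if (j == i) next
      if (j %in% internals && i < j) next
      ep_i <- c(ep_i, i); ep_j <- c(ep_j, j)
    }
  }
  nE <- length(ep_i)

  mod <- milp_model()
  C_idx <- matrix(milp_add_vars(mod, N * V, lb = 0, ub = cmax, type = "I"),
                  N, V)
  if (nv > 0) milp_fix(mod, C_idx[N, seq_len(nv)], 0)
  milp_fix(mod, C_idx[N, nv + seq_len(2 * r)], 1)

  E_idx <- milp_add_vars(mod, nE, type = "B")
  # no ancestry variables: under the canonical labeling (internal edges
  # strictly decrease in label, leaves are sinks, root has no parent) any
  # in-degree-1 edge set is automatically acyclic, so the ancestry matrix
  # is fully determined by E and is reconstructed after the solve

  W_idx <- if (nv > 0) matrix(milp_add_vars(mod, nE * nv, type = "B"),
                              nE, nv) else NULL
  Cb_idx <- NULL
  if (nv > 0) {
    Cb_idx <- matrix(0L, N, nv)
    for (k in seq_len(N - 1L)) {
      Cb_idx[k, ] <- milp_add_vars(mod, nv, type = "B")
    }
  }
  D_idx <- if (nv > 0) milp_add_vars(mod, nv, type = "B") else integer()
  X1_idx <- matrix(milp_add_vars(mod, nE * r, lb = 0, ub = cmax,
                                 obj = lambda1), nE, r)
  X2_idx <- matrix(milp_add_vars(mod, nE * r, lb = 0, ub = cmax,
                                 obj = lambda1), nE, r)
  T_idx <- matrix(milp_add_vars(mod, m * V, lb = 0, obj = 1), m, V)
  Z_idx <- if (nv > 0) matrix(milp_add_vars(mod, m * nv, lb = 0,
                                            obj = lambda2), m, nv) else NULL

  # ---- tree constraints: in-degree 1, out-degree 2 ----
  milp_add_constr(mod, E_idx, rep(1, nE), lb = N - 1, ub = N - 1)
  for (j in seq_len(N - 1L)) {
    es <- which(ep_j == j)
    milp_add_constr(mod, E_idx[es], rep(1, length(es)), lb = 1, ub = 1)
  }
  for (i in parents) {
    es <- which(ep_i == i)
    milp_add_constr(mod, E_idx[es], rep(1, length(es)), lb = 2, ub = 2)
  }
  # leaf symmetry breaking: leaves are exchangeable, so require their
  # parent labels to be non-increasing in leaf order
  if (n >= 2) {
    for (lf in seq_len(n - 1L)) {
      e1 <- which(ep_j == lf)
      e2 <- which(ep_j == lf + 1L)
      milp_add_constr(mod, c(E_idx[e1], E_idx[e2]),
                      c(ep_i[e1], -ep_i[e2]), lb = 0)
    }
  }

  # ---- per-edge absolute allele-specific segment copy changes ----
  for (e in seq_len(nE)) {
    i <- ep_i[e]; j <- ep_j[e]
    for (s in seq_len(r)) {
      for (al in 1:2) {
        xv <- if (al == 1) X1_idx[e, s] else X2_idx[e, s]
        cc <- nv + (al - 1L) * r + s
        milp_add_constr(mod, c(xv, E_idx[e]), c(1, -cmax), ub = 0)
        milp_add_constr(mod, c(C_idx[i, cc], C_idx[j, cc], xv, E_idx[e]),
                        c(1, -1, -1, cmax), ub = cmax)
        milp_add_constr(mod, c(C_idx[i, cc], C_idx[j, cc], xv, E_idx[e]),
                        c(-1, 1, -1, cmax), ub = cmax)
      }
    }
  }

  if (nv > 0) {
    # ---- binarization: cbar <= c <= cmax cbar ----
    for (k in seq_len(N - 1L)) {
      for (b in seq_len(nv)) {
        milp_add_constr(mod, c(Cb_idx[k, b], C_idx[k, b]), c(1, -1), ub = 0)
        milp_add_constr(mod, c(C_idx[k, b], Cb_idx[k, b]), c(1, -cmax),
                        ub = 0)
      }
    }
    # ---- Dollo introduction and persistence ----
    for (b in seq_len(nv)) {
      milp_add_constr(mod, W_idx[, b], rep(1, nE), ub = 1)
      # presence anywhere requires an introduction (tightens the relaxation;
      # implied by the persistence chain)
      for (k in seq_len(N - 1L)) {
        milp_add_constr(mod, c(Cb_idx[k, b], W_idx[, b]),
                        c(1, rep(-1, nE)), ub = 0)
      }
      for (e in seq_len(nE)) {
        i <- ep_i[e]; j <- ep_j[e]
        milp_add_constr(mod, c(W_idx[e, b], E_idx[e]), c(1, -1), ub = 0)
        if (i != N) {
          milp_add_constr(mod, c(W_idx[e, b], Cb_idx[i, b]), c(1, 1), ub = 1)
        }
        milp_add_constr(mod, c(W_idx[e, b], Cb_idx[j, b]), c(1, -1), ub = 0)
        ind <- c(Cb_idx[j, b], W_idx[e, b], E_idx[e])
        val <- c(1, -1, 1)
        if (i != N) { ind <- c(ind, Cb_idx[i, b]); val <- c(val, -1) }
        milp_add_constr(mod, ind, val, ub = 1)
      }
    }
    # ---- breakpoint mate pairs share allele and introduction edge ----
    if (panel$l > 0) {
      mate <- max.col(panel$G, ties.method = "first")
      for (b in seq_len(panel$l)) {
        b2 <- mate[b]
        if (b2 <= b) next
        milp_add_constr(mod, c(D_idx[b], D_idx[b2]), c(1, -1), lb = 0,
                        ub = 0)
        for (e in seq_len(nE)) {
          milp_add_constr(mod, c(W_idx[e, b], W_idx[e, b2]), c(1, -1),
                          lb = 0, ub = 0)
        }
      }
    }

    # ---- allele-phased coupling of variant and segment copy changes ----
    # active on edge (i,j) for allele 1 when e=1, d=1, w=0 (and, gated,
    # cbar_i = 1); for allele 2 when e=1, d=0, w=0 (gated likewise)
    M1 <- 2 * cmax + 1
    M2 <- 2 * cmax + 2
    for (e in seq_len(nE)) {
      i <- ep_i[e]; j <- ep_j[e]
      if (gated && i == N) next  # root has no variants: gate never open
      for (b in seq_len(nv)) {
        s <- seg_of[b]
        a1 <- nv + s
        a2 <- nv + r + s
        dgam <- function(acol) list(
          ind = c(C_idx[j, acol], C_idx[i, acol], C_idx[j, b], C_idx[i, b]),
          val = c(1, -1, -1, 1))
        cb_i <- if (gated) Cb_idx[i, b] else 0L
        slack <- if (gated) 1 else 0
        # allele 1 lower: dGam0 - dc + M1(2 - e - d + w [+ 1 - cb]) >= 0
        g1 <- dgam(a1)
        ind <- c(g1$ind, E_idx[e], D_idx[b], W_idx[e, b])
        val <- c(g1$val, -M1, -M1, M1)
        if (gated) { ind <- c(ind, cb_i); val <- c(val, -M1) }
        milp_add_constr(mod, ind, val, lb = -(2 + slack) * M1)
        # allele 1 upper: dGam0 - dc - M2(2 - e - d + w [+ 1 - cb]) <= 0
        ind <- c(g1$ind, E_idx[e], D_idx[b], W_idx[e, b])
        val <- c(g1$val, M2, M2, -M2)
        if (gated) { ind <- c(ind, cb_i); val <- c(val, M2) }
        milp_add_constr(mod, ind, val, ub = (2 + slack) * M2)
        # allele 2 lower: dGam1 - dc + M1(1 - e + d + w [+ 1 - cb]) >= 0
        g2 <- dgam(a2)
        ind <- c(g2$ind, E_idx[e], D_idx[b], W_idx[e, b])
        val <- c(g2$val, -M1, M1, M1)
        if (gated) { ind <- c(ind, cb_i); val <- c(val, -M1) }
        milp_add_constr(mod, ind, val, lb = -(1 + slack) * M1)
        # allele 2 upper
        ind <- c(g2$ind, E_idx[e], D_idx[b], W_idx[e, b])
        val <- c(g2$val, M2, -M2, -M2)
        if (gated) { ind <- c(ind, cb_i); val <- c(val, M2) }
        milp_add_constr(mod, ind, val, ub = (1 + slack) * M2)
      }
    }

    # ---- variant copy bounded by its allele's segment copy ----
    for (k in seq_len(N - 1L)) {
      for (b in seq_len(nv)) {
        s <- seg_of[b]
        milp_add_constr(mod, c(C_idx[k, b], C_idx[k, nv + s], D_idx[b]),
                        c(1, -1, cmax), ub = cmax)
        milp_add_constr(mod, c(C_idx[k, b], C_idx[k, nv + r + s], D_idx[b]),
                        c(1, -1, -cmax), ub = 0)
      }
    }

    # ---- VAF consistency term ----
    for (p in seq_len(m)) {
      for (b in seq_len(nv)) {
        if (psi[p, b] <= 0) next  # no VAF information for this entry
        s <- seg_of[b]
        a1 <- nv + s
        a2 <- nv + r + s
        uk <- U[p, ]
        keep <- which(abs(uk) > 1e-9)
        if (!length(keep)) next
        ind <- c(Z_idx[p, b],
                 C_idx[keep, a1], C_idx[keep, a2], C_idx[keep, b])
        co <- vaf[p, b] * uk[keep]
        # z >= pi * sum u (g0 + g1) - sum u c
        milp_add_constr(mod, ind, c(1, -co, -co, uk[keep]), lb = 0)
        # z >= -(...)
        milp_add_constr(mod, ind, c(1, co, co, -uk[keep]), lb = 0)
      }
    }
  }

  # ---- L1 data term ----
  for (p in seq_len(m)) {
    uk <- U[p, ]
    keep <- which(abs(uk) > 1e-12)
    for (v in seq_len(V)) {
      ind <- c(T_idx[p, v], C_idx[keep, v])
      milp_add_constr(mod, ind, c(1, uk[keep]), lb = F[p, v])
      milp_add_constr(mod, ind, c(1, -uk[keep]), lb = -F[p, v])
    }
  }

  sol <- milp_solve(mod, time_limit = config$time_limit,
                    mip_gap = config$mip_gap)
  if (identical(sol$status, "infeasible")) {
    stop("C-step ILP reported infeasible; this is a modeling bug (the ",
         "all-normal solution is always feasible)")
  }
  if (is.null(sol$x)) {
    stop("C-step ILP returned no incumbent within the time limit")
  }

  x <- sol$x
  C <- matrix(as.integer(round(x[C_idx])), N, V)
  colnames(C) <- layout_colnames(panel)
  E <- matrix(0L, N, N)
  E[cbind(ep_i, ep_j)] <- as.integer(round(x[E_idx]))
  W <- array(0L, dim = c(N, N, nv))
  if (nv > 0) {
    wv <- matrix(round(x[W_idx]), nE, nv)
    for (b in seq_len(nv)) {
      W[cbind(ep_i, ep_j, b)] <- as.integer(wv[, b])
    }
  }
  D <- if (nv > 0) as.integer(round(x[D_idx])) else integer()
  rho <- matrix(0, N, N)
  seg_cols <- nv + seq_len(2 * r)
  for (e in seq_len(nE)) {
    if (E[ep_i[e], ep_j[e]] > 0) {
      rho[ep_i[e], ep_j[e]] <-
        sum(abs(C[ep_i[e], seg_cols] - C[ep_j[e], seg_cols]))
    }
  }
  tree <- clone_tree(n, E, W = W, rho = rho)
  R <- sum(rho)
  S <- if (nv > 0) {
    sum(vapply(seq_len(m), function(p) {
      gam0 <- C[, nv + seg_of, drop = FALSE]
      gam1 <- C[, nv + r + seg_of, drop = FALSE]
      tot <- as.numeric(U[p, ] %*% (gam0 + gam1))
      est <- as.numeric(U[p, ] %*% C[, seq_len(nv), drop = FALSE])
      sum(abs(vaf[p, ] * tot - est)[psi[p, ] > 0])
    }, numeric(1)))
  } else 0

  list(profiles = clone_profiles(C, D, cmax), tree = tree,
       R = R, S = S, status = sol$status, objective = sol$objective,
       lambda1 = lambda1, lambda2 = lambda2)
}
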