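#' Recompute the objective and its components outside any solver
#'
#' Evaluates `sum |F - U C| + lambda1 R + lambda2 S` directly from the
#' matrices: the L1 data term; `R`, the total absolute allele-specific
#' segment copy change summed over tree edges; and `S`, the L1 discrepancy
#' between observed VAFs and the VAFs implied by `(U, C)` (entries without
#' VAF information, i.e. zero mixed segment copy, are skipped). Used to
#' verify backend-reported objectives and to drive convergence checks.
#'
#' @param F bulk matrix or `bulk_obs`.
#' @param U frequency matrix m x N.
#' @param C clone profile matrix N x (l+g+2r).
#' @param tree a `clone_tree` providing the edges.
#' @param panel a [variant_panel].
#' @param lambda1,lambda2 penalty weights.
#' @return list with `total`, `data`, `R`, `S`.
#' @export
compute_objective <- function(F, U, C, tree, panel, lambda1, lambda2) {
  bulk <- NULL
  if (inherits(F, "bulk_obs")) {
    bulk <- F
    F <- bulk$F
  }
  U <- as.matrix(U)
  nv <- panel$l + panel$g
  r <- panel$r
  data_term <- sum(abs(F - U %*% C))
  seg_cols <- nv + seq_len(2 * r)
  edges <- tree_edges(tree)
  R <- 0
  for (e in seq_len(nrow(edges))) {
    R <- R + sum(abs(C[edges[e, 1], seg_cols] - C[edges[e, 2], seg_cols]))
  }
  S <- 0
  if (nv > 0) {
    psi <- if (is.null(bulk)) mixed_segment_copy(F, panel) else bulk$psi
    vaf <- if (is.null(bulk)) pmin(pmax(compute_vaf(F, panel), 0), 1)
           else bulk$vaf
    seg_of <- variant_segment(panel)
    gam_tot <- C[, nv + seg_of, drop = FALSE] +
      C[, nv + r + seg_of, drop = FALSE]
    est_tot <- U %*% gam_tot
    est_var <- U %*% C[, seq_len(nv), drop = FALSE]
    disc <- abs(vaf * est_tot - est_var)
    S <- sum(disc[psi > 0])
  }
  list(total = data_term + lambda1 * R + lambda2 * S,
       data = data_term, R = R, S = S)
}

#' Deconvolve bulk samples by coordinate descent
#'
#' The full inference: starting from random simplex frequencies, alternates
#' the phylogeny-constrained integer program for clone profiles
#' ([solve_c_step()]) with the frequency linear program ([solve_u_step()])
#' until the relative objective improvement drops below `tol` or
#' `max_iters` is reached. Multiple random restarts guard against local
#' optima; the restart with the lowest final objective is returned.
#'
#' @param F bulk matrix m x (l+g+2r) or a `bulk_obs`.
#' @param panel a [variant_panel].
#' @param config a [solver_config()].
#' @param seed optional master seed for restart initializations (falls back
#'   to `config$seed`).
#' @return a `clone_fit`: list with `tree`, `profiles`, `U`, `objective`
#'   (components from [compute_objective()]), per-iteration `trace`
#'   tibble, `status` flags, `panel` and `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_leaves = 2, m_samples = 2, sv_rate_total = 2,
#'                   snv_count_param = 2, sv_length_mean = 5e5)
#' cohort <- simulate_cohort(cfg, noisy = FALSE, seed = 1)
#' fit <- coordinate_descent(cohort$bulk, cohort$panel,
#'                           solver_config(n_leaves = 2, c_max = 4,
#'                                         n_restarts = 2, max_iters = 4),
#'                           seed = 1)
#' fit$objective$total
#' }
#' @export
coordinate_descent <- function(F, panel, config, seed = NULL) {
  seed <- seed %||% config$seed
  m <- if (inherits(F, "bulk_obs")) F$m else nrow(F)
  N <- 2L * config$n_leaves - 1L
  restart_seeds <- with_sim_seed(seed, {
    sample.int(.Machine$integer.max %/% 2L, config$n_restarts)
  })

  best <- NULL
  traces <- list()
  failures <- character()
  for (rs in seq_len(config$n_restarts)) {
    res <- tryCatch(
      run_descent_once(F, panel, config, m, N, restart_seeds[rs], rs),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    traces[[length(traces) + 1L]] <- res$trace
    if (is.null(best) || res$objective$total < best$objective$total) {
      best <- res
    }
    # a zero-objective solution cannot be improved by further restarts
    if (best$objective$total <= 1e-12) break
  }
  if (is.null(best)) {
    stop("all restarts failed: ", paste(unique(failures), collapse = "; "))
  }
  best$trace <- dplyr::bind_rows(traces)
  best$n_failed_restarts <- length(failures)
  best$panel <- panel
  best$config <- config
  class(best) <- "clone_fit"
  best
}

#' @noRd
run_descent_once <- function(F, panel, config, m, N, seed, restart) {
  U <- with_sim_seed(seed, {
    U0 <- matrix(0, m, N)
    active <- if (config$leaf_only) c(seq_len(config$n_leaves), N)
              else seq_len(N)
    for (p in seq_len(m)) {
      w <- stats::rexp(length(active))
      U0[p, active] <- w / sum(w)
    }
    U0
  })
  trace <- list()
  prev_obj <- Inf
  cres <- NULL
  obj <- NULL
  n_stalled <- 0L
  for (it in seq_len(config$max_iters)) {
    cres <- solve_c_step(F, U, panel, config)
    ures <- solve_u_step(F, cres$profiles$C, leaf_only = config$leaf_only,
                         time_limit = config$time_limit)
    U <- ures$U
    obj <- compute_objective(F, U, cres$profiles$C, cres$tree, panel,
                             cres$lambda1, cres$lambda2)
    trace[[it]] <- tibble::tibble(
      restart = restart, iter = it, objective = obj$total,
      data = obj$data, R = obj$R, S = obj$S, c_status = cres$status)
    if (is.finite(prev_obj)) {
      rel <- (prev_obj - obj$total) / max(abs(prev_obj), 1e-12)
      # alternating steps can plateau for one round and then improve;
      # stop only after two consecutive stalls
      n_stalled <- if (rel < config$tol) n_stalled + 1L else 0L
      if (n_stalled >= 2L) break
    }
    if (obj$total <= 1e-12) break
    prev_obj <- obj$total
  }
  list(tree = cres$tree, profiles = cres$profiles, U = U,
       objective = obj, trace = dplyr::bind_rows(trace),
       status = cres$status, lambda1 = cres$lambda1,
       lambda2 = cres$lambda2, restart_seed = seed)
}

#' Collapse a solved tree to estimate the clone number
#'
#' Iteratively (i) removes zero-total-frequency nodes that have a single
#' remaining child, re-attaching the child to the grandparent, and (ii)
#' merges into their parent those children whose incoming branch has zero
#' copy-number length and no introduced variants (frequencies summed). The
#' number of remaining (uncollapsed) nodes estimates the clone count; the
#' procedure is idempotent.
#'
#' @param fit a `clone_fit` from [coordinate_descent()], or a list with
#'   `tree`, `profiles`, `U`.
#' @param tol frequencies below `tol` (summed over samples) count as zero.
#' @return list with `n_clones` (uncollapsed clone count), `members`
#'   (list mapping each kept node to the original nodes merged into it),
#'   `edges` (tibble of kept parent-child pairs) and `kept` (node ids).
#' @export
collapse_tree <- function(fit, tol = 1e-6) {
  tree <- fit$tree
  U <- as.matrix(fit$U)
  N <- tree$N
  freq <- colSums(U)
  intro_count <- if (!is.null(tree$W) && length(tree$W)) {
    apply(tree$W, c(1, 2), sum)
  } else matrix(0, N, N)
  rho <- if (!is.null(tree$rho)) tree$rho else matrix(0, N, N)

  parent <- rep(NA_integer_, N)
  for (j in seq_len(N)) {
    p <- which(tree$E[, j] > 0)
    if (length(p)) parent[j] <- p
  }
  alive <- rep(TRUE, N)
  members <- as.list(seq_len(N))

  children_of <- function(i) which(alive & !is.na(parent) & parent == i)
  repeat {
    changed <- FALSE
    # (ii) merge zero-length, variant-free branches into the parent
    for (j in seq_len(N)) {
      if (!alive[j] || is.na(parent[j])) next
      p <- parent[j]
      if (rho[p, j] <= tol && intro_count[p, j] == 0) {
        freq[p] <- freq[p] + freq[j]
        members[[p]] <- c(members[[p]], members[[j]])
        members[[j]] <- integer()
        kids <- children_of(j)
        parent[kids] <- p
        rho[p, kids] <- rho[j, kids]
        intro_count[p, kids] <- intro_count[j, kids]
        alive[j] <- FALSE
        changed <- TRUE
      }
    }
    # (i) splice out zero-frequency single-child nodes
    for (j in seq_len(N)) {
      if (!alive[j]) next
      kids <- children_of(j)
      if (length(kids) == 1L && freq[j] <= tol && !is.na(parent[j])) {
        p <- parent[j]
        parent[kids] <- p
        rho[p, kids] <- rho[p, j] + rho[j, kids]
        intro_count[p, kids] <- intro_count[p, j] + intro_count[j, kids]
        alive[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  kept <- which(alive)
  edges <- tibble::tibble(
    parent = parent[kept], child = kept)
  edges <- edges[!is.na(edges$parent), , drop = FALSE]
  list(n_clones = length(kept), members = members[kept],
       edges = edges, kept = kept)
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("<clone_fit> ", x$tree$n, " leaves (", x$tree$N, " clones), ",
      nrow(x$U), " sample(s)\n", sep = "")
  cat("  objective ", format(x$objective$total, digits = 6),
      " = data ", format(x$objective$data, digits = 6),
      " + lambda1*R (R = ", format(x$objective$R, digits = 6),
      ") + lambda2*S (S = ", format(x$objective$S, digits = 6), ")\n",
      sep = "")
  cat("  C-step status: ", x$status, "\n", sep = "")
  invisible(x)
}
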