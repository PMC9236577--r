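#' Match inferred clones to true clones
#'
#' Clone labels are arbitrary, so matrices are compared after a
#' minimum-cost bipartite matching between clone rows under L1 profile
#' distance (solved as an assignment linear program, whose polytope is
#' integral). In leaf-only mode the matching is restricted to leaves and
#' the root.
#'
#' @param C_true,C_est clone profile matrices over the same columns.
#' @param leaf_only restrict to leaf + root rows (assumes both matrices
#'   use the `1..n` leaves, `N` root layout).
#' @param U_true,U_est optional frequency matrices; when given, ties
#'   between profile-identical clones are broken toward the matching with
#'   the closest frequencies (weighted by `tie_break_weight`, which does
#'   not affect the reported cost).
#' @param tie_break_weight weight of the frequency tie-break term.
#' @return list with `matching` (tibble `est`, `true` row indices),
#'   `cost` (total matched L1 profile distance) and the row subsets used.
#' @export
match_clones <- function(C_true, C_est, leaf_only = FALSE,
                         U_true = NULL, U_est = NULL,
                         tie_break_weight = 1e-6) {
  if (ncol(C_true) != ncol(C_est)) {
    stop("profile matrices must share a column universe")
  }
  rows_of <- function(C) {
    N <- nrow(C)
    if (!leaf_only) return(seq_len(N))
    n <- (N + 1L) %/% 2L
    c(seq_len(n), N)
  }
  rt <- rows_of(C_true)
  re <- rows_of(C_est)
  n1 <- length(re)
  n2 <- length(rt)
  cost <- matrix(0, n1, n2)
  tie <- matrix(0, n1, n2)
  for (a in seq_len(n1)) {
    for (b in seq_len(n2)) {
      cost[a, b] <- sum(abs(C_est[re[a], ] - C_true[rt[b], ]))
      if (!is.null(U_true) && !is.null(U_est)) {
        tie[a, b] <- sum(abs(as.matrix(U_est)[, re[a]] -
                               as.matrix(U_true)[, rt[b]]))
      }
    }
  }
  mod <- milp_model()
  x <- matrix(milp_add_vars(mod, n1 * n2, lb = 0, ub = 1,
                            obj = as.numeric(cost + tie_break_weight * tie)),
              n1, n2)
  for (a in seq_len(n1)) milp_add_constr(mod, x[a, ], rep(1, n2), ub = 1)
  for (b in seq_len(n2)) milp_add_constr(mod, x[, b], rep(1, n1), ub = 1)
  milp_add_constr(mod, as.integer(x), rep(1, n1 * n2),
                  lb = min(n1, n2), ub = min(n1, n2))
  sol <- milp_solve(mod)
  if (!identical(sol$status, "optimal")) stop("assignment LP failed")
  xm <- matrix(sol$x[as.integer(x)], n1, n2)
  hit <- which(xm > 0.5, arr.ind = TRUE)
  matching <- tibble::tibble(est = re[hit[, 1]], true = rt[hit[, 2]])
  matching <- matching[order(matching$est), , drop = FALSE]
  list(matching = matching, cost = sum(cost[hit]),
       rows_est = re, rows_true = rt)
}

#' Profile and frequency RMSE after clone matching
#'
#' Element-wise root mean square error over matched clone rows of `C` and
#' matched clone columns of `U`. With `leaf_only`, only matched pairs whose
#' true clone is a leaf or the root contribute (frequencies and profiles of
#' internal clones are not compared).
#'
#' @param C_true,C_est profile matrices.
#' @param U_true,U_est frequency matrices (samples x clones).
#' @param matching result of [match_clones()].
#' @param leaf_only restrict to true leaf/root clones.
#' @return named list `rmse_C`, `rmse_U`.
#' @export
rmse_matrices <- function(C_true, C_est, U_true, U_est, matching,
                          leaf_only = FALSE) {
  mt <- matching$matching
  if (leaf_only) {
    N <- nrow(C_true)
    n <- (N + 1L) %/% 2L
    mt <- mt[mt$true %in% c(seq_len(n), N), , drop = FALSE]
  }
  if (nrow(mt) == 0) stop("empty matching")
  dC <- C_est[mt$est, , drop = FALSE] - C_true[mt$true, , drop = FALSE]
  dU <- as.matrix(U_est)[, mt$est, drop = FALSE] -
    as.matrix(U_true)[, mt$true, drop = FALSE]
  list(rmse_C = sqrt(mean(dC^2)), rmse_U = sqrt(mean(dU^2)))
}

#' Clusters (subtree label sets) of a clone tree
#' @noRd
tree_clusters <- function(tree, labels) {
  N <- tree$N
  out <- list()
  for (j in seq_len(N)) {
    if (j == tree$N) next
    members <- sort(labels[c(j, which(tree$A[j, ] > 0))])
    if (length(members) < 2) next
    out[[length(out) + 1L]] <- paste(members, collapse = "|")
  }
  unique(unlist(out)) %||% character()
}

#' Normalized Robinson-Foulds distance between rooted clone trees
#'
#' Rooted RF on the matched clone labels: the symmetric difference of the
#' two trees' nontrivial clusters (subtree label sets below each edge),
#' normalized by the total cluster count, giving a value in `[0, 1]` (0 for
#' identical labeled topologies). Unmatched clones receive fresh distinct
#' labels.
#'
#' @param tree_true,tree_est `clone_tree` objects.
#' @param matching optional [match_clones()] result used to translate
#'   estimated clone indices into true ones; identity if `NULL`.
#' @return a number in `[0, 1]`.
#' @export
normalized_rf <- function(tree_true, tree_est, matching = NULL) {
  lab_true <- paste0("t", seq_len(tree_true$N))
  lab_est <- paste0("e", seq_len(tree_est$N))
  if (!is.null(matching)) {
    mt <- matching$matching
    lab_est[mt$est] <- lab_true[mt$true]
  } else {
    if (tree_true$N != tree_est$N) stop("trees differ in size; supply a matching")
    lab_est <- lab_true
  }
  n_shared <- length(intersect(lab_true, lab_est))
  if (n_shared < 2) {
    stop("fewer than 2 matched clones; RF undefined")
  }
  cl_t <- tree_clusters(tree_true, lab_true)
  cl_e <- tree_clusters(tree_est, lab_est)
  denom <- length(cl_t) + length(cl_e)
  if (denom == 0) return(0)
  length(union(setdiff(cl_t, cl_e), setdiff(cl_e, cl_t))) / denom
}

#' Step-interpolated average precision
#' @noRd
average_precision <- function(labels, scores) {
  if (sum(labels) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  # thresholds at distinct score values
  idx <- which(!duplicated(scores, fromLast = FALSE))
  ends <- c(idx[-1] - 1L, length(scores))
  tp <- cumsum(labels)
  ap <- 0
  prev_recall <- 0
  total_pos <- sum(labels)
  for (k in seq_along(ends)) {
    e <- ends[k]
    precision <- tp[e] / e
    recall <- tp[e] / total_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Co-clustering average precision of variant assignments
#'
#' Builds, over unordered variant pairs within a block (breakpoint pairs,
#' SNV pairs, or breakpoint-SNV cross pairs), the binary indicator of
#' "same clone of origin", and scores the estimated indicators against the
#' true ones with step-interpolated average precision. Returns `NA` (with a
#' message attribute) when the truth has no co-clustered pair.
#'
#' @param assign_true,assign_est named vectors or tibbles (`id`, `node`)
#'   mapping each variant to its clone of origin.
#' @param is_bp logical vector (named like the assignments) marking
#'   breakpoints.
#' @param block `"bp"`, `"snv"`, or `"bp_snv"`.
#' @return average precision in `[0, 1]`, or `NA` when undefined.
#' @export
coclustering_average_precision <- function(assign_true, assign_est, is_bp,
                                           block = c("bp", "snv",
                                                     "bp_snv")) {
  block <- match.arg(block)
  as_named <- function(a) {
    if (is.data.frame(a)) stats::setNames(a$node, a$id) else a
  }
  at <- as_named(assign_true)
  ae <- as_named(assign_est)
  ids <- intersect(names(at), names(ae))
  at <- at[ids]; ae <- ae[ids]; bp <- is_bp[ids]

  pairs <- switch(block,
    bp = {
      v <- which(bp)
      if (length(v) < 2) return(NA_real_)
      t(utils::combn(v, 2))
    },
    snv = {
      v <- which(!bp)
      if (length(v) < 2) return(NA_real_)
      t(utils::combn(v, 2))
    },
    bp_snv = {
      v1 <- which(bp); v2 <- which(!bp)
      if (!length(v1) || !length(v2)) return(NA_real_)
      as.matrix(expand.grid(v1, v2))
    })
  truth <- as.integer(at[pairs[, 1]] == at[pairs[, 2]])
  est <- as.integer(ae[pairs[, 1]] == ae[pairs[, 2]])
  average_precision(truth, est)
}

#' Relative clone-number distance
#'
#' `(k_true - k_est) / k_true`: zero when the clone number is recovered,
#' positive when underestimated, negative when overestimated.
#'
#' @param k_true true clone count (> 0).
#' @param k_est estimated clone count.
#' @return signed relative distance.
#' @examples
#' clone_number_distance(5, 9)  # -0.8
#' @export
clone_number_distance <- function(k_true, k_est) {
  if (k_true <= 0) stop("k_true must be positive")
  (k_true - k_est) / k_true
}

#' Clone of origin of each variant from an introduction tensor
#'
#' @param tree a `clone_tree` with `W`.
#' @param panel the matching [variant_panel].
#' @return named integer vector: variant id -> child node of its
#'   introduction edge (`NA` for never-introduced variants).
#' @export
variant_origins <- function(tree, panel) {
  nv <- panel$l + panel$g
  out <- rep(NA_integer_, nv)
  for (b in seq_len(nv)) {
    hit <- which(tree$W[, , b] > 0, arr.ind = TRUE)
    if (nrow(hit)) out[b] <- hit[1, 2]
  }
  stats::setNames(out, panel$variants$id)
}

#' Evaluate a fit against simulator ground truth
#'
#' Computes the full metric set: clone matching cost, RMSE of `C` and `U`
#' after matching, normalized RF distance, relative clone-number distance
#' (after [collapse_tree()]) and co-clustering average precisions.
#'
#' @param fit a `clone_fit`.
#' @param truth a cohort from [simulate_cohort()].
#' @param leaf_only evaluate in leaf-only mode.
#' @return one-row tibble of metrics.
#' @export
evaluate_solution <- function(fit, truth, leaf_only = FALSE) {
  mc <- match_clones(truth$profiles$C, fit$profiles$C,
                     leaf_only = leaf_only,
                     U_true = truth$U, U_est = fit$U)
  rm <- rmse_matrices(truth$profiles$C, fit$profiles$C, truth$U, fit$U,
                      mc, leaf_only = leaf_only)
  rf <- tryCatch(normalized_rf(truth$tree, fit$tree, mc),
                 error = function(e) NA_real_)
  # the true clone number is the number of distinguishable clones: nodes
  # that survive collapsing event-free, frequency-less branches of the truth
  k_true <- collapse_tree(list(tree = truth$tree, U = truth$U))$n_clones
  k_est <- collapse_tree(fit)$n_clones
  at <- variant_origins(truth$tree, truth$panel)
  ae <- variant_origins(fit$tree, fit$panel)
  is_bp <- stats::setNames(truth$panel$variants$type == "breakpoint",
                           truth$panel$variants$id)
  tibble::tibble(
    matching_cost = mc$cost,
    rmse_C = rm$rmse_C, rmse_U = rm$rmse_U,
    normalized_rf = rf,
    k_true = k_true, k_est = k_est,
    clone_number_distance = clone_number_distance(k_true, k_est),
    ap_bp = coclustering_average_precision(at, ae, is_bp, "bp"),
    ap_snv = coclustering_average_precision(at, ae, is_bp, "snv"),
    ap_bp_snv = coclustering_average_precision(at, ae, is_bp, "bp_snv"))
}
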