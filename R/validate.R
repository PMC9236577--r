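#' Validate a clone-tree solution against all model invariants
#'
#' Checks a (tree, profiles, frequencies) triple against every structural
#' invariant of the model: binary-tree shape, ancestry consistency,
#' anti-cycle conditions, copy-number bounds, normal root profile, the Dollo
#' life cycle of each variant (introduced on at most one edge, present only
#' inside the subtree below that edge, never reappearing after loss),
#' variant-vs-allele copy bounds, and simplex frequencies. Violations are
#' reported, not raised.
#'
#' @param tree a `clone_tree` (with `W` filled in).
#' @param profiles a `clone_profiles`.
#' @param freqs numeric matrix m x N of per-sample clone frequencies.
#' @param panel a [variant_panel].
#' @param leaf_only if `TRUE`, additionally require zero frequency on
#'   internal non-root clones.
#' @param tol numeric tolerance for real-valued checks.
#' @param int_tol tolerance for integrality of `C`.
#'
#' @return a tibble with columns `check`, `ok`, `detail`; attribute `ok`
#'   (scalar logical) and class `solution_report`.
#' @export
validate_solution <- function(tree, profiles, freqs, panel,
                              leaf_only = FALSE, tol = 1e-6,
                              int_tol = 1e-6) {
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = name, ok = ok, detail = detail)
  }
  N <- tree$N
  n <- tree$n
  E <- tree$E
  A <- tree$A
  C <- profiles$C
  D <- profiles$D
  nv <- panel$l + panel$g

  indeg <- colSums(E)
  outdeg <- rowSums(E)
  add("root_in_degree_0", indeg[N] == 0)
  add("nonroot_in_degree_1", all(indeg[-N] == 1),
      paste0(sum(indeg[-N] != 1), " node(s) off"))
  internal <- if (N > 1) c(n + seq_len(max(N - n - 1L, 0L)), N) else integer()
  leaves <- seq_len(n)
  if (N > 1) {
    add("internal_out_degree_2", all(outdeg[internal] == 2))
    add("leaf_out_degree_0", all(outdeg[leaves] == 0))
  }
  add("ancestry_is_closure", all(A == ancestry_closure(E)))
  add("no_mutual_ancestry", all(A + t(A) <= 1))
  add("no_self_ancestry", all(diag(A) == 0))

  add("C_nonnegative", all(C >= -int_tol))
  add("C_below_cmax", all(C <= profiles$c_max + int_tol))
  add("C_integer", all(abs(C - round(C)) <= int_tol))
  if (nv > 0) {
    add("root_has_no_variants", all(abs(C[N, cols_variant(panel)]) <= tol))
  }
  add("root_segments_single_copy",
      all(abs(C[N, cols_seg(panel)] - 1) <= tol))

  if (nv > 0) {
    gam <- gamma_of(C, panel)
    allele_cap <- ifelse(rep(D, each = N) == 1, gam[, , 1], gam[, , 2])
    dim(allele_cap) <- c(N, nv)
    add("variant_copy_within_allele",
        all(C[, seq_len(nv), drop = FALSE] <= allele_cap + int_tol),
        paste0(sum(C[, seq_len(nv), drop = FALSE] > allele_cap + int_tol),
               " entr(ies) exceed allele copy"))
    if (panel$l > 0) {
      mate <- max.col(panel$G, ties.method = "first")
      add("mate_pairs_share_allele", all(D[seq_len(panel$l)] ==
                                           D[mate[seq_len(panel$l)]]))
    }

    W <- tree$W
    if (is.null(W)) {
      add("introduction_tensor_present", FALSE, "W is NULL")
    } else {
      pres <- (C[, seq_len(nv), drop = FALSE] > int_tol) * 1L
      per_var <- apply(W, 3, sum)
      add("dollo_single_introduction", all(per_var <= 1),
          paste0(sum(per_var > 1), " variant(s) multiply introduced"))
      on_edges <- TRUE
      for (b in seq_len(nv)) {
        if (any(W[, , b] > E)) on_edges <- FALSE
      }
      add("introductions_on_edges", on_edges)
      ok_scope <- TRUE
      ok_persist <- TRUE
      edges <- tree_edges(tree)
      for (b in seq_len(nv)) {
        intro <- which(W[, , b] > 0, arr.ind = TRUE)
        if (nrow(intro) == 1L) {
          i <- intro[1, 1]; j <- intro[1, 2]
          if (pres[i, b] > 0) ok_scope <- FALSE
          inside <- c(j, which(A[j, ] > 0))
          if (any(pres[setdiff(seq_len(N), inside), b] > 0)) ok_scope <- FALSE
          if (pres[j, b] == 0) ok_scope <- FALSE
        } else if (nrow(intro) == 0L && any(pres[, b] > 0)) {
          ok_scope <- FALSE
        }
        for (e in seq_len(nrow(edges))) {
          i <- edges[e, 1]; j <- edges[e, 2]
          if (pres[j, b] > pres[i, b] + W[i, j, b]) ok_persist <- FALSE
        }
      }
      add("dollo_presence_within_subtree", ok_scope)
      add("dollo_no_reappearance", ok_persist)
    }

    if (panel$l > 0 && !is.null(tree$W)) {
      mate <- max.col(panel$G, ties.method = "first")
      same_edge <- TRUE
      for (b in seq_len(panel$l)) {
        if (any(tree$W[, , b] != tree$W[, , mate[b]])) same_edge <- FALSE
      }
      add("mate_pairs_share_edge", same_edge)
    }
  }

  U <- as.matrix(freqs)
  add("U_nonnegative", all(U >= -tol))
  add("U_rows_sum_to_1", all(abs(rowSums(U) - 1) <= tol),
      paste0("max |rowsum - 1| = ", format(max(abs(rowSums(U) - 1)))))
  if (leaf_only && N > 1) {
    internal_nonroot <- setdiff(internal, N)
    if (length(internal_nonroot)) {
      add("leaf_only_internal_zero",
          all(abs(U[, internal_nonroot, drop = FALSE]) <= tol))
    }
  }

  report <- dplyr::bind_rows(checks)
  attr(report, "ok") <- all(report$ok)
  class(report) <- c("solution_report", class(report))
  report
}

#' @export
print.solution_report <- function(x, ...) {
  bad <- x[!x$ok, , drop = FALSE]
  cat("<solution_report> ", sum(x$ok), "/", nrow(x), " checks passed\n",
      sep = "")
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat("  FAIL ", bad$check[i],
          if (nzchar(bad$detail[i])) paste0(" (", bad$detail[i], ")") else "",
          "\n", sep = "")
    }
  }
  invisible(x)
}
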