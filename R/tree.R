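#' Clone tree representation
#'
#' A clone tree on `N = 2n - 1` nodes: leaves are nodes `1..n`, internal
#' nodes `n+1..N-1`, and the root (the diploid normal clone) is node `N`.
#' `E[i, j] = 1` iff `i` is the direct parent of `j`; `A` is the strict
#' transitive closure of `E` (`A[i, j] = 1` iff `i` is a proper ancestor of
#' `j`). `W[i, j, b] = 1` marks the edge on which variant `b` is introduced;
#' `rho[i, j]` is the copy-number evolutionary length of edge `(i, j)`.
#'
#' @param n leaf count (>= 1; `n = 1` is the degenerate single-root tree
#'   only used internally).
#' @param E binary N x N edge matrix.
#' @param W optional N x N x (l+g) introduction tensor.
#' @param rho optional N x N branch length matrix.
#' @return object of class `clone_tree`.
#' @keywords internal
#' @export
clone_tree <- function(n, E, W = NULL, rho = NULL) {
  N <- 2L * as.integer(n) - 1L
  stopifnot(nrow(E) == N, ncol(E) == N)
  structure(
    list(n = as.integer(n), N = N, E = E, A = ancestry_closure(E),
         W = W, rho = rho),
    class = "clone_tree"
  )
}

#' Strict transitive closure of an edge matrix
#' @noRd
ancestry_closure <- function(E) {
  N <- nrow(E)
  A <- (E > 0) * 1L
  repeat {
    A2 <- ((A + A %*% A) > 0) * 1L
    if (all(A2 == A)) break
    A <- A2
  }
  A
}

#' @noRd
tree_parent <- function(tree, j) {
  p <- which(tree$E[, j] > 0)
  if (length(p) == 0) NA_integer_ else p[[1]]
}

#' @noRd
tree_children <- function(tree, i) which(tree$E[i, ] > 0)

#' Edges as a two-column matrix (parent, child), deterministic order
#' @noRd
tree_edges <- function(tree) {
  idx <- which(tree$E > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("parent", "child")
  idx
}

#' Convert a clone tree to an ape "phylo" object
#'
#' Node labels are `clone_<k>` with the package's clone indexing. Branch
#' lengths come from `rho` when present, else 1.
#'
#' @param tree a `clone_tree`.
#' @return an `ape::phylo` object (requires the ape package).
#' @export
as_phylo_clone_tree <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for phylo conversion")
  }
  ape::read.tree(text = tree_newick(tree))
}

#' Newick serialization of a clone tree
#'
#' @param tree a `clone_tree`.
#' @param labels optional node labels (default `clone_<k>`).
#' @return single Newick string, terminated with ";".
#' @export
tree_newick <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- paste0("clone_", seq_len(tree$N))
  rec <- function(i) {
    kids <- tree_children(tree, i)
    len <- if (!is.null(tree$rho) && !is.na(tree_parent(tree, i))) {
      paste0(":", format(tree$rho[tree_parent(tree, i), i], scientific = FALSE))
    } else ""
    if (length(kids) == 0) return(paste0(labels[i], len))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           labels[i], len)
  }
  paste0(rec(tree$N), ";")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", x$n, " leaves, ", x$N, " nodes; root = clone_",
      x$N, "\n", sep = "")
  invisible(x)
}
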