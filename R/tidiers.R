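#' Tidy a clone fit
#'
#' Returns the fitted quantities in long tibble form: `matrix = "U"` gives
#' one row per (sample, clone) with the mixture fraction; `matrix = "C"`
#' one row per (clone, column) with the integer copy number and the column
#' kind (breakpoint, snv, segment allele 1/2).
#'
#' @param x a `clone_fit`.
#' @param matrix `"U"` or `"C"`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy clone_fit
#' @export
tidy.clone_fit <- function(x, matrix = c("U", "C"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "U") {
    U <- as.matrix(x$U)
    samples <- rownames(U) %||% paste0("sample_", seq_len(nrow(U)))
    tidyr::expand_grid(sample = samples,
                       clone = seq_len(ncol(U))) |>
      dplyr::mutate(frequency = as.numeric(t(U)),
                    clone = paste0("clone_", .data$clone))
  } else {
    C <- x$profiles$C
    p <- x$panel
    kind <- c(rep("breakpoint", p$l), rep("snv", p$g),
              rep("segment_a1", p$r), rep("segment_a2", p$r))
    tidyr::expand_grid(clone = seq_len(nrow(C)),
                       column = colnames(C)) |>
      dplyr::mutate(kind = rep(kind, nrow(C)),
                    copy_number = as.integer(t(C)),
                    clone = paste0("clone_", .data$clone))
  }
}

#' One-row summary of a clone fit
#'
#' @param x a `clone_fit`.
#' @param ... unused.
#' @return tibble with objective components, penalty weights, iteration
#'   and restart counts, and the backend status.
#' @method glance clone_fit
#' @export
glance.clone_fit <- function(x, ...) {
  tibble::tibble(
    n_clones = x$tree$N,
    n_leaves = x$tree$n,
    m_samples = nrow(as.matrix(x$U)),
    objective = x$objective$total,
    data_term = x$objective$data,
    R = x$objective$R,
    S = x$objective$S,
    lambda1 = x$lambda1,
    lambda2 = x$lambda2,
    iterations = max(x$trace$iter),
    restarts = length(unique(x$trace$restart)),
    status = x$status)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot clone composition of each sample
#'
#' Stacked bar chart of per-sample clone frequencies.
#'
#' @param object a `clone_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot clone_fit
#' @export
autoplot.clone_fit <- function(object, ...) {
  dat <- tidy.clone_fit(object, "U")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$frequency,
                                    fill = .data$clone)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "clone fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a clone tree
#'
#' Simple layered tree drawing: nodes placed by depth, edges annotated
#' with branch length (`rho`) and the number of introduced variants.
#'
#' @param tree a `clone_tree` (or a `clone_fit`, whose tree is used).
#' @return a ggplot object.
#' @export
plot_clone_tree <- function(tree) {
  if (inherits(tree, "clone_fit")) tree <- tree$tree
  N <- tree$N
  depth <- rep(0L, N)
  ord <- integer()
  queue <- N
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, v)
    kids <- tree_children(tree, v)
    depth[kids] <- depth[v] + 1L
    queue <- c(queue, kids)
  }
  xpos <- numeric(N)
  leaves <- which(rowSums(tree$E) == 0)
  xpos[leaves] <- seq_along(leaves)
  for (v in rev(ord)) {
    kids <- tree_children(tree, v)
    if (length(kids)) xpos[v] <- mean(xpos[kids])
  }
  edges <- tree_edges(tree)
  seg <- tibble::tibble(
    x = xpos[edges[, 1]], y = -depth[edges[, 1]],
    xend = xpos[edges[, 2]], yend = -depth[edges[, 2]],
    label = if (!is.null(tree$rho)) {
      paste0("rho=", round(tree$rho[edges], 2))
    } else "")
  nodes <- tibble::tibble(x = xpos, y = -depth,
                          name = paste0("clone_", seq_len(N)))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name)) +
    ggplot2::theme_void()
}
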