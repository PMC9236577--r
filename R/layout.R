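#' Column layout of the F and C matrices
#'
#' Bulk observations `F` (samples x variants) and clone profiles `C`
#' (clones x variants) share one fixed column layout:
#' breakpoints `1..l`, SNVs `l+1..l+g`, allele-1 segment copies
#' `l+g+1..l+g+r`, allele-2 segment copies `l+g+r+1..l+g+2r`.
#' These helpers are the single source of truth for that layout.
#'
#' @param panel a [variant_panel].
#' @name layout
#' @keywords internal
NULL

#' @rdname layout
#' @noRd
n_cols <- function(panel) panel$l + panel$g + 2L * panel$r

#' @rdname layout
#' @noRd
cols_bp <- function(panel) seq_len(panel$l)

#' @rdname layout
#' @noRd
cols_snv <- function(panel) panel$l + seq_len(panel$g)

#' @rdname layout
#' @noRd
cols_variant <- function(panel) seq_len(panel$l + panel$g)

#' @rdname layout
#' @noRd
cols_seg1 <- function(panel) panel$l + panel$g + seq_len(panel$r)

#' @rdname layout
#' @noRd
cols_seg2 <- function(panel) panel$l + panel$g + panel$r + seq_len(panel$r)

#' @rdname layout
#' @noRd
cols_seg <- function(panel) panel$l + panel$g + seq_len(2L * panel$r)

#' Segment index of each variant (length l+g)
#' @noRd
variant_segment <- function(panel) {
  if (panel$l + panel$g == 0L) return(integer())
  max.col(panel$Q, ties.method = "first")
}

#' Column names for F/C matrices: variant ids then per-allele segment ids
#' @noRd
layout_colnames <- function(panel) {
  c(panel$variants$id,
    paste0(panel$segments$id, ":a1"),
    paste0(panel$segments$id, ":a2"))
}
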