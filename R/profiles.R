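#' Clone copy-number profiles
#'
#' Integer per-clone copy numbers in the shared column layout (breakpoints,
#' SNVs, allele-1 segments, allele-2 segments), the allele assignment vector
#' `D` (`d[b] = 1` places variant `b` on allele 1) and the copy-number cap
#' `c_max`.
#'
#' @param C integer matrix N x (l+g+2r).
#' @param D binary vector of length l+g.
#' @param c_max maximum copy number per column.
#' @return object of class `clone_profiles`.
#' @keywords internal
#' @export
clone_profiles <- function(C, D, c_max) {
  structure(list(C = C, D = as.integer(D), c_max = as.integer(c_max)),
            class = "clone_profiles")
}

#' Allele-specific segment copy number at each variant's locus
#'
#' `gamma[k, b, a]` is the copy number in clone `k`, on allele `a`, of the
#' segment containing variant `b`. Derived from the segment columns of `C`.
#'
#' @param C clone profile matrix N x (l+g+2r).
#' @param panel a [variant_panel].
#' @return numeric array N x (l+g) x 2.
#' @keywords internal
#' @export
gamma_of <- function(C, panel) {
  nv <- panel$l + panel$g
  N <- nrow(C)
  seg <- variant_segment(panel)
  out <- array(0, dim = c(N, nv, 2))
  if (nv > 0) {
    out[, , 1] <- C[, cols_seg1(panel), drop = FALSE][, seg, drop = FALSE]
    out[, , 2] <- C[, cols_seg2(panel), drop = FALSE][, seg, drop = FALSE]
  }
  out
}

#' @export
print.clone_profiles <- function(x, ...) {
  cat("<clone_profiles> ", nrow(x$C), " clones x ", ncol(x$C),
      " columns, c_max = ", x$c_max, "\n", sep = "")
  invisible(x)
}
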