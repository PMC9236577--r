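#' Order segment alleles and derive VAFs for a bulk cohort
#'
#' The model assumes a fixed "first" allele per segment, shared by all
#' samples, carrying the larger copy number: copy numbers of the two allele
#' columns of each segment are compared and the columns swapped so that
#' allele 1 >= allele 2. When samples disagree, the swap is decided by
#' majority vote across samples (a sample votes "swap" when its allele-2
#' entry exceeds its allele-1 entry); ties keep the input order. The swap is
#' applied to all samples of a segment at once so the allele identity stays
#' common across the cohort.
#'
#' Also computes, per sample `p` and variant `b` in segment `s(b)`, the mixed
#' segment copy number `psi[p, b] = F[p, a1(s)] + F[p, a2(s)]` and the
#' variant allele frequency `vaf[p, b] = F[p, b] / psi[p, b]`. Entries with
#' `psi = 0` get VAF 0; VAFs are clamped to `[0, 1]` and the number of
#' clamped entries recorded.
#'
#' @param F_raw numeric matrix, samples x (l+g+2r), allele columns in
#'   arbitrary per-caller order.
#' @param panel a [variant_panel] fixing the column layout.
#' @param samples optional character vector of sample ids (row names).
#'
#' @return a `bulk_obs`: list with `m`, ordered matrix `F`, `psi` and `vaf`
#'   (m x (l+g)), `swapped` (logical per segment), `n_clamped`,
#'   `n_zero_psi`.
#' @examples
#' seg <- tibble::tibble(chrom = "chr1", start = 1, end = 1000)
#' p <- build_panel(segments = seg,
#'                  snvs = tibble::tibble(id = "s1", chrom = "chr1", pos = 5))
#' F_raw <- matrix(c(0.5, 0.8, 1.4), nrow = 1)
#' obs <- order_alleles(F_raw, p)
#' obs$F        # allele columns swapped so 1.4 precedes 0.8
#' obs$vaf      # 0.5 / 2.2
#' @export
order_alleles <- function(F_raw, panel, samples = NULL) {
  F_raw <- as.matrix(F_raw)
  if (ncol(F_raw) != n_cols(panel)) {
    stop("F has ", ncol(F_raw), " columns; panel layout requires ",
         n_cols(panel))
  }
  if (any(F_raw < 0)) stop("negative copy numbers in F")
  m <- nrow(F_raw)
  FF <- F_raw
  swapped <- logical(panel$r)
  for (s in seq_len(panel$r)) {
    c1 <- panel$l + panel$g + s
    c2 <- panel$l + panel$g + panel$r + s
    votes_swap <- sum(FF[, c2] > FF[, c1])
    votes_keep <- sum(FF[, c1] > FF[, c2])
    if (votes_swap > votes_keep) {
      tmp <- FF[, c1]
      FF[, c1] <- FF[, c2]
      FF[, c2] <- tmp
      swapped[s] <- TRUE
    }
  }
  if (!is.null(samples)) rownames(FF) <- samples
  colnames(FF) <- layout_colnames(panel)

  psi <- mixed_segment_copy(FF, panel)
  vaf_raw <- compute_vaf(FF, panel)
  n_clamped <- sum(vaf_raw > 1)
  vaf <- pmin(pmax(vaf_raw, 0), 1)

  structure(
    list(m = m, F = FF, psi = psi, vaf = vaf,
         swapped = swapped, n_clamped = n_clamped,
         n_zero_psi = sum(psi[, seq_len(panel$l + panel$g), drop = FALSE] == 0),
         samples = rownames(FF)),
    class = "bulk_obs"
  )
}

#' Mixed (both-allele) segment copy number per variant
#'
#' `psi[p, b]` is the total copy number, summed over both alleles, of the
#' segment containing variant `b` in sample `p`.
#'
#' @inheritParams compute_vaf
#' @return numeric matrix m x (l+g).
#' @keywords internal
#' @export
mixed_segment_copy <- function(F, panel) {
  nv <- panel$l + panel$g
  m <- nrow(F)
  if (nv == 0L) return(matrix(numeric(), nrow = m, ncol = 0))
  seg <- variant_segment(panel)
  tot <- F[, cols_seg1(panel), drop = FALSE] +
    F[, cols_seg2(panel), drop = FALSE]
  out <- tot[, seg, drop = FALSE]
  dimnames(out) <- list(rownames(F), panel$variants$id)
  out
}

#' Variant allele frequencies from mean copy numbers
#'
#' `vaf[p, b] = F[p, b] / psi[p, b]`, the ratio of the mean variant copy
#' number to the mixed copy number of its segment. Entries with `psi = 0`
#' are set to 0; the count of such entries is attached as attribute
#' `n_zero_psi`. No clamping is applied here (see [order_alleles()] for the
#' clamped cohort-level version), so `vaf * psi` reproduces `F` exactly
#' wherever `psi > 0`.
#'
#' @param F numeric matrix, samples x (l+g+2r), in panel column layout.
#' @param panel a [variant_panel].
#' @return numeric matrix m x (l+g) of VAFs.
#' @export
compute_vaf <- function(F, panel) {
  psi <- mixed_segment_copy(F, panel)
  nv <- panel$l + panel$g
  if (nv == 0L) return(psi)
  num <- F[, cols_variant(panel), drop = FALSE]
  out <- ifelse(psi > 0, num / pmax(psi, .Machine$double.xmin), 0)
  dimnames(out) <- dimnames(psi)
  attr(out, "n_zero_psi") <- sum(psi == 0)
  out
}

#' @export
print.bulk_obs <- function(x, ...) {
  cat("<bulk_obs> ", x$m, " samples x ", ncol(x$F), " columns (",
      ncol(x$vaf), " variants); ", sum(x$swapped),
      " segment(s) allele-swapped, ", x$n_clamped, " VAF(s) clamped\n",
      sep = "")
  invisible(x)
}
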