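# Shared fixtures: small panels and cohorts built in code.

toy_panel <- function() {
  seg <- tibble::tibble(chrom = "chr1", start = c(1, 501), end = c(500, 1000))
  bp <- tibble::tibble(id = c("b1", "b2"), chrom = "chr1",
                       pos = c(100, 700),
                       direction = c("right", "left"),
                       mate_id = c("b2", "b1"))
  snv <- tibble::tibble(id = "s1", chrom = "chr1", pos = 250)
  build_panel(bp, snv, seg)
}

# a desk-scale simulation configuration (small genome footprint events)
desk_config <- function(n_leaves = 2, m_samples = 3, sv = 3, snv = 3,
                        ...) {
  sim_config(n_leaves = n_leaves, m_samples = m_samples,
             sv_rate_total = sv, snv_count_param = snv,
             sv_length_mean = 4e5, ...)
}

# normal-diploid bulk matrix for a panel
normal_F <- function(panel, m = 1) {
  F <- matrix(0, m, clonedecomp:::n_cols(panel))
  F[, panel$l + panel$g + seq_len(2 * panel$r)] <- 1
  F
}

random_simplex <- function(m, N) {
  U <- matrix(stats::rexp(m * N), m, N)
  U / rowSums(U)
}
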