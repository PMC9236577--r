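test_that("build_panel indexes a small universe and enforces pairing", {
  p <- toy_panel()
  expect_equal(c(p$l, p$g, p$r), c(2L, 1L, 2L))
  expect_equal(dim(p$Q), c(3L, 2L))
  expect_equal(rowSums(p$Q), c(1, 1, 1))
  expect_equal(p$G, matrix(c(0L, 1L, 1L, 0L), 2))

  bad_bp <- tibble::tibble(id = "b1", chrom = "chr1", pos = 10,
                           direction = "left", mate_id = "nope")
  seg <- tibble::tibble(chrom = "chr1", start = 1, end = 100)
  expect_error(build_panel(bad_bp, NULL, seg), "unmatched mate")

  lonely <- tibble::tibble(id = "s9", chrom = "chr1", pos = 4000)
  expect_error(build_panel(NULL, lonely, seg), "s9")
})

test_that("random panels satisfy Q/G row structure (interval-scan oracle)", {
  set.seed(71)
  genome <- c(chrA = 1e6, chrB = 8e5)
  segs <- dplyr::bind_rows(lapply(names(genome), function(ch) {
    cuts <- sort(sample(2:(genome[[ch]] - 1), 5))
    tibble::tibble(chrom = ch,
                   start = c(1, cuts),
                   end = c(cuts - 1, genome[[ch]]))
  }))
  n_sv <- 10
  bp <- purrr::map_dfr(seq_len(n_sv), function(k) {
    tibble::tibble(
      id = paste0("sv", k, "_", 1:2),
      chrom = sample(names(genome), 2, replace = TRUE),
      pos = c(sample(genome[[1]], 1), sample(genome[[2]], 1)),
      direction = c("right", "left"),
      mate_id = paste0("sv", k, "_", 2:1))
  })
  snv <- tibble::tibble(id = paste0("snv", 1:20),
                        chrom = sample(names(genome), 20, replace = TRUE),
                        pos = sample(5e5, 20))
  p <- build_panel(bp, snv, segs)
  expect_equal(rowSums(p$Q), rep(1, p$l + p$g))
  expect_equal(rowSums(p$G), rep(1, p$l))
  expect_true(all(p$G == t(p$G)))
  expect_equal(diag(p$G), rep(0L, p$l))
  # independent interval-overlap scan
  for (b in seq_len(p$l + p$g)) {
    v <- p$variants[b, ]
    hits <- sum(p$segments$chrom == v$chrom & p$segments$start <= v$pos &
                  p$segments$end >= v$pos)
    expect_equal(hits, 1)
    s <- which(p$Q[b, ] == 1)
    expect_true(p$segments$chrom[s] == v$chrom &&
                  p$segments$start[s] <= v$pos &&
                  p$segments$end[s] >= v$pos)
  }
})

test_that("column layout is invariant to input record order", {
  set.seed(72)
  seg <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 2),
                        start = c(1, 501, 1, 901), end = c(500, 1000, 900, 2000))
  bp <- tibble::tibble(id = paste0("x", 1:4),
                       chrom = c("chr1", "chr2", "chr1", "chr2"),
                       pos = c(40, 950, 600, 1500),
                       direction = c("right", "left", "right", "left"),
                       mate_id = paste0("x", c(2, 1, 4, 3)))
  snv <- tibble::tibble(id = paste0("m", 1:3), chrom = "chr1",
                        pos = c(77, 800, 20))
  p1 <- build_panel(bp, snv, seg)
  perm <- sample(nrow(bp))
  p2 <- build_panel(bp[perm, ], snv[sample(3), ], seg[sample(4), ])
  expect_identical(p1$Q, p2$Q)
  expect_identical(p1$G, p2$G)
  expect_identical(p1$variants$id, p2$variants$id)
  expect_identical(p1$segments$id, p2$segments$id)
})

test_that("order_alleles swaps by majority vote and computes psi/vaf", {
  p <- toy_panel()
  # single sample: allele copies (0.8, 1.4) on both segments get swapped
  F1 <- matrix(c(0.5, 0.5, 0.7, 0.8, 0.8, 1.4, 1.4), nrow = 1)
  obs <- order_alleles(F1, p)
  expect_equal(unname(obs$F[1, 4:7]), c(1.4, 1.4, 0.8, 0.8))
  expect_true(all(obs$swapped))

  # balanced segment stays put
  F2 <- matrix(c(0.5, 0.5, 0.7, 1, 1, 1, 1), nrow = 1)
  expect_false(any(order_alleles(F2, p)$swapped))

  # majority across five samples: 3 of 5 favor the swap on segment 1
  F5 <- matrix(0, 5, 7)
  F5[, 4] <- c(0.5, 0.6, 0.7, 2.0, 2.1)  # segment 1 allele A
  F5[, 6] <- c(1.5, 1.6, 1.7, 0.5, 0.2)  # segment 1 allele B
  F5[, 5] <- 1; F5[, 7] <- 1
  obs5 <- order_alleles(F5, p)
  expect_true(obs5$swapped[1])
  expect_false(obs5$swapped[2])
  # swap applied to all samples, including the dissenters
  expect_equal(unname(obs5$F[4, 4]), 0.5)
  expect_equal(unname(obs5$F[4, 6]), 2.0)

  expect_error(order_alleles(-F1, p), "negative")
})

test_that("vaf times mixed segment copy reproduces F", {
  set.seed(73)
  p <- toy_panel()
  for (rep in 1:5) {
    Fseg <- matrix(runif(1 * 4, 0.2, 2), 1)
    psi_by_seg <- Fseg[, 1:2] + Fseg[, 3:4]
    Fv <- cbind(runif(1, 0, psi_by_seg[1]), runif(1, 0, psi_by_seg[2]),
                runif(1, 0, psi_by_seg[1]))
    F <- cbind(Fv, Fseg)
    vaf <- compute_vaf(F, p)
    psi <- mixed_segment_copy(F, p)
    expect_lt(max(abs(vaf * psi - F[, 1:3, drop = FALSE])), 1e-9)
  }
  # zero cases
  F0 <- normal_F(p)
  F0[1, 4:7] <- 0  # psi = 0 for all variants
  v <- compute_vaf(F0, p)
  expect_equal(unname(v[1, ]), c(0, 0, 0))
  expect_equal(attr(v, "n_zero_psi"), 3L)
  # arithmetic: one variant copy over mixed copy 2
  F1 <- normal_F(p)
  F1[1, 3] <- 1
  expect_equal(unname(compute_vaf(F1, p)[1, 3]), 0.5)
})

test_that("validate_solution passes normal-only solutions and flags Dollo breaks", {
  p <- toy_panel()
  E <- matrix(0L, 3, 3); E[3, 1] <- E[3, 2] <- 1L
  W <- array(0L, dim = c(3, 3, 3))
  tree <- clone_tree(2, E, W = W)
  C <- matrix(rep(c(0, 0, 0, 1, 1, 1, 1), each = 3), 3)
  prof <- clone_profiles(C, D = c(1L, 1L, 1L), c_max = 4)
  U <- matrix(c(0, 0, 1), 1)
  rep1 <- validate_solution(tree, prof, U, p)
  expect_true(attr(rep1, "ok"))

  # two introduction edges for one variant
  W2 <- W
  W2[3, 1, 1] <- 1L; W2[3, 2, 1] <- 1L
  tree2 <- clone_tree(2, E, W = W2)
  C2 <- C; C2[1, 1] <- 1; C2[2, 1] <- 1
  rep2 <- validate_solution(tree2, clone_profiles(C2, c(1L, 1L, 1L), 4),
                            U, p)
  expect_false(attr(rep2, "ok"))
  expect_false(rep2$ok[rep2$check == "dollo_single_introduction"])

  # presence outside the introduction subtree
  W3 <- W
  W3[3, 1, 2] <- 1L
  C3 <- C; C3[2, 2] <- 1  # introduced into leaf 1 but present in leaf 2
  rep3 <- validate_solution(clone_tree(2, E, W = W3),
                            clone_profiles(C3, c(1L, 1L, 1L), 4), U, p)
  expect_false(rep3$ok[rep3$check == "dollo_presence_within_subtree"])
})

test_that("simulator truths validate across random configurations", {
  set.seed(74)
  for (s in 1:8) {
    cfg <- desk_config(n_leaves = sample(2:4, 1), sv = 4, snv = 4)
    co <- simulate_cohort(cfg, seed = 100 + s)
    rep <- validate_solution(co$tree, co$profiles, co$U, co$panel)
    expect_true(attr(rep, "ok"))
  }
})
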