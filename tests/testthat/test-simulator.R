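test_that("simulate_tree produces canonical binary clone trees", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(t2$N, 3L)
  expect_equal(which(t2$E > 0, arr.ind = TRUE)[, "row"], c(3L, 3L),
               ignore_attr = TRUE)

  t5 <- simulate_tree(5, seed = 2)
  expect_equal(t5$N, 9L)
  outdeg <- rowSums(t5$E)
  expect_equal(sort(unique(outdeg[6:9])), 2)
  expect_equal(unname(outdeg[1:5]), rep(0, 5))
  expect_equal(colSums(t5$E)[9], 0, ignore_attr = TRUE)
  # internal children are labeled below their parents
  edges <- which(t5$E > 0, arr.ind = TRUE)
  internal_child <- edges[edges[, 2] > 5, , drop = FALSE]
  expect_true(all(internal_child[, 1] > internal_child[, 2]))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("tree topologies on 4 leaves are uniform over the 15 labelings", {
  # a labeled rooted binary tree on 4 leaves is determined by its set of
  # leaf clusters; hash them over many draws
  set.seed(3)
  draws <- 3000
  hash <- character(draws)
  for (k in seq_len(draws)) {
    tr <- simulate_tree(4)
    cls <- sapply(5:6, function(v) {
      paste(sort(which(tr$A[v, 1:4] > 0)), collapse = "")
    })
    hash[k] <- paste(sort(cls), collapse = "/")
  }
  tab <- table(hash)
  expect_equal(length(tab), 15L)
  # uniformity: chi-square against equal probabilities
  chi <- stats::chisq.test(tab, p = rep(1 / 15, 15))
  expect_gt(chi$p.value, 1e-4)
})

test_that("simulate_events draws the configured event mix", {
  tree <- simulate_tree(2, seed = 4)
  cfg0 <- desk_config(sv = 0, snv = 0)
  ev0 <- simulate_events(tree, cfg0, seed = 1)
  expect_equal(nrow(ev0), 0L)

  # pooled over replicates: type weights 2:2:1:1 and span mean
  set.seed(5)
  cfg <- sim_config(n_leaves = 2, m_samples = 1, sv_rate_total = 120,
                    snv_count_param = 0, sv_length_mean = 2e5,
                    genome = c(chr1 = 5e7, chr2 = 5e7))
  evs <- dplyr::bind_rows(lapply(1:15, function(k) {
    simulate_events(simulate_tree(2), cfg)
  }))
  counts <- table(factor(evs$type, levels = c("dup", "del", "trans", "inv")))
  n <- sum(counts)
  # duplication : inversion ratio ~ 2 within a generous binomial band
  p_dup <- counts[["dup"]] / (counts[["dup"]] + counts[["inv"]])
  expect_gt(p_dup, 2 / 3 - 3 * sqrt((2 / 3) * (1 / 3) /
                                      (counts[["dup"]] + counts[["inv"]])))
  expect_lt(p_dup, 2 / 3 + 3 * sqrt((2 / 3) * (1 / 3) /
                                      (counts[["dup"]] + counts[["inv"]])))
  # span mean close to the Poisson parameter
  spans <- evs$pos2 - evs$pos1 + 1
  spans <- spans[evs$type %in% c("dup", "del", "inv")]
  expect_lt(abs(mean(spans) - 2e5) / 2e5, 0.01)
  # duplication multiplicities live in 2..6
  mult <- evs$mult[evs$type == "dup"]
  expect_true(all(mult >= 2 & mult <= 6))
})

test_that("realize_profiles applies event semantics", {
  # single deletion on the edge into leaf 1 of a two-leaf tree
  tree <- simulate_tree(2, seed = 6)
  cfg <- desk_config()
  ev <- tibble::tibble(
    event = 1L, type = "del", parent = 3L, child = 1L, allele = 1L,
    chrom = "chr1", chrom2 = NA_character_, pos1 = 1e6, pos2 = 2e6,
    mult = NA_integer_, bp1_id = "sv0001_1", bp2_id = "sv0001_2",
    snv_id = NA_character_)
  out <- realize_profiles(tree, ev, cfg)
  p <- out$panel
  C <- out$profiles$C
  del_seg <- which(p$segments$start == 1e6)
  expect_equal(unname(C[1, p$l + p$g + del_seg]), 0)  # allele 1 lost in leaf 1
  expect_equal(unname(C[2, p$l + p$g + del_seg]), 1)
  expect_equal(unname(C[3, p$l + p$g + del_seg]), 1)
  expect_equal(unname(C[1, 1:2]), c(1, 1))  # both flank breakpoints copy 1
  expect_equal(unname(C[2, 1:2]), c(0, 0))

  # duplication x3 of a region containing an earlier SNV on the same allele
  ev2 <- tibble::tibble(
    event = 1:2,
    type = c("snv", "dup"), parent = c(3L, 3L), child = c(1L, 1L),
    allele = 1L, chrom = "chr1", chrom2 = NA_character_,
    pos1 = c(1.5e6, 1e6), pos2 = c(NA, 2e6), mult = c(NA, 3L),
    bp1_id = c(NA, "sv0001_1"), bp2_id = c(NA, "sv0001_2"),
    snv_id = c("snv0001", NA))
  out2 <- realize_profiles(tree, ev2, cfg)
  snv_col <- match("snv0001", out2$panel$variants$id)
  expect_equal(unname(out2$profiles$C[1, snv_col]), 3)

  # clone-wise: every variant copy is bounded by its allele's segment copy
  set.seed(7)
  for (s in 1:5) {
    co <- simulate_cohort(desk_config(n_leaves = 3, sv = 5, snv = 5),
                          seed = 200 + s)
    gam <- gamma_of(co$profiles$C, co$panel)
    nv <- co$panel$l + co$panel$g
    for (b in seq_len(nv)) {
      cap <- if (co$profiles$D[b] == 1) gam[, b, 1] else gam[, b, 2]
      expect_true(all(co$profiles$C[, b] <= cap))
    }
  }
})

test_that("mixtures live on the simplex and F = U C holds exactly", {
  co <- simulate_cohort(desk_config(m_samples = 4), seed = 8)
  expect_equal(rowSums(co$U), rep(1, 4))
  expect_equal(co$F_true, co$U %*% co$profiles$C, tolerance = 1e-12)

  # Dirichlet(1,...,1) coordinate means are 1/N
  set.seed(9)
  prof <- clone_profiles(matrix(1, 3, 2), integer(0), 4)
  mix <- simulate_mixture(prof, m_samples = 4000)
  mu <- colMeans(mix$U)
  expect_true(all(abs(mu - 1 / 3) < 4 * sqrt(2 / 27 / 4000)))

  # leaf-only mixtures put no mass on internal non-root clones
  co5 <- simulate_cohort(desk_config(n_leaves = 4), leaf_only = TRUE,
                         seed = 10)
  internal <- setdiff(seq_len(7), c(1:4, 7))
  expect_true(all(co5$U[, internal] == 0))
})

test_that("read noise follows the Poisson/binomial model", {
  co <- simulate_cohort(desk_config(), noisy = FALSE, seed = 11)
  # infinite-depth limit: noisy F converges to the noiseless mixture
  deep <- sim_config(n_leaves = 2, m_samples = 3, read_depth = 1e6,
                     sv_rate_total = 3, snv_count_param = 3,
                     sv_length_mean = 4e5)
  noisy <- add_read_noise(co$F_true, co$panel, deep, seed = 12)
  rel <- abs(noisy$F - co$F_true) / pmax(co$F_true, 1)
  expect_lt(max(rel), 0.01)

  # a variant with zero theoretical VAF stays exactly zero
  nv <- co$panel$l + co$panel$g
  zero_b <- which(colSums(co$F_true[, seq_len(nv), drop = FALSE]) == 0)
  if (length(zero_b)) {
    n100 <- add_read_noise(co$F_true, co$panel, desk_config(), seed = 13)
    expect_true(all(n100$F[, zero_b] == 0))
  }
})

test_that("identical configuration and seed reproduce the cohort bitwise", {
  cfg <- desk_config(n_leaves = 3, sv = 4, snv = 5)
  a <- simulate_cohort(cfg, seed = 14)
  b <- simulate_cohort(cfg, seed = 14)
  expect_identical(a$events, b$events)
  expect_identical(a$profiles$C, b$profiles$C)
  expect_identical(a$U, b$U)
  expect_identical(a$bulk$F, b$bulk$F)
})

test_that("per-branch rate mode draws events on every edge independently", {
  set.seed(15)
  tree <- simulate_tree(4)
  cfg <- sim_config(n_leaves = 4, m_samples = 1, sv_rate_branch = 3,
                    snv_count_param = 0, sv_length_mean = 3e5)
  ev <- simulate_events(tree, cfg)
  # Poisson(3) per each of the 6 edges: total should be near 18
  expect_gt(nrow(ev), 4)
  expect_lt(nrow(ev), 45)
})
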