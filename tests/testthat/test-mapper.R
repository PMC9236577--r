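test_that("subsampling keeps mate pairs together and is deterministic", {
  co <- simulate_cohort(desk_config(sv = 6, snv = 6), noisy = FALSE,
                        seed = 51)
  p <- co$panel
  # identity when limits exceed availability
  sub0 <- subsample_variants(p, co$bulk, seed = 1)
  expect_identical(sub0$panel$variants$id, p$variants$id)
  expect_null(sub0$held_out)

  sub <- subsample_variants(p, co$bulk, max_breakpoints = 2,
                            max_total = 4, seed = 2)
  expect_equal(sub$panel$l, 2L)
  expect_lte(sub$panel$l + sub$panel$g, 4L)
  expect_equal(rowSums(sub$panel$G), rep(1, sub$panel$l))
  # mates kept together
  kept_bp <- sub$panel$variants$id[sub$panel$variants$type == "breakpoint"]
  mates <- sub$panel$variants$mate_id[sub$panel$variants$type == "breakpoint"]
  expect_true(all(mates %in% kept_bp))
  # all segments retained
  expect_equal(sub$panel$r, p$r)
  # determinism
  sub2 <- subsample_variants(p, co$bulk, max_breakpoints = 2,
                             max_total = 4, seed = 2)
  expect_identical(sub$plan$kept, sub2$plan$kept)
  # F slices agree with the original columns
  for (id in sub$panel$variants$id) {
    expect_equal(sub$bulk$F[, id], co$bulk$F[, id])
  }
})

test_that("copy-neutral held-out SNVs map to their true edge at distance 0", {
  # construct a solved fit equal to a noiseless truth, hold out one SNV
  co <- simulate_cohort(desk_config(n_leaves = 3, sv = 0, snv = 6),
                        noisy = FALSE, seed = 52)
  p <- co$panel
  fit <- structure(list(tree = co$tree, profiles = co$profiles, U = co$U,
                        panel = p), class = "clone_fit")
  nv <- p$l + p$g
  held_ids <- p$variants$id[seq_len(min(2, nv))]
  keep <- setdiff(seq_len(nv), match(held_ids, p$variants$id))
  sub <- list(
    panel = clonedecomp:::panel_subset(p, keep),
    held = clonedecomp:::panel_subset(p, match(held_ids, p$variants$id)))
  held_bulk <- list(
    panel = sub$held,
    bulk = clonedecomp:::new_bulk_obs(
      co$bulk$F[, c(match(sub$held$variants$id, p$variants$id),
                    clonedecomp:::cols_seg(p)), drop = FALSE],
      sub$held))
  # solved fit keeps the full panel; its segments host the held-out SNVs
  asg <- assign_unsampled(fit, held_bulk)
  truth_origin <- variant_origins(co$tree, p)
  for (k in seq_len(nrow(asg))) {
    b <- match(asg$id[k], p$variants$id)
    # copy-neutral cohort: prediction is exact at the true node
    expect_equal(asg$node[k], unname(truth_origin[asg$id[k]]))
    expect_lt(asg$distance[k], 1e-9)
  }
})

test_that("assignment equals an independent brute force on random fits", {
  set.seed(53)
  n_checked <- 0
  for (s in 1:6) {
    co <- simulate_cohort(desk_config(n_leaves = 3, sv = 3, snv = 6),
                          noisy = FALSE, seed = 300 + s)
    p <- co$panel
    flt <- filter_segments_to_variant_bearing(p, co$bulk)
    sub <- subsample_variants(flt$panel, flt$bulk, max_total = 4,
                              seed = s)
    if (is.null(sub$held_out)) next
    fit <- structure(list(tree = co$tree, profiles = NULL, U = co$U,
                          panel = flt$panel), class = "clone_fit")
    # profiles on the filtered panel
    keep_cols <- c(match(flt$panel$variants$id, p$variants$id),
                   p$l + p$g + match(flt$panel$segments$id, p$segments$id),
                   p$l + p$g + p$r + match(flt$panel$segments$id,
                                           p$segments$id))
    fit$profiles <- clone_profiles(
      co$profiles$C[, keep_cols, drop = FALSE],
      co$profiles$D, co$profiles$c_max)
    fit$panel <- flt$panel
    a1 <- assign_unsampled(fit, sub$held_out)
    a2 <- assign_bruteforce(fit, sub$held_out)
    expect_equal(a1$node, a2$node)
    expect_equal(a1$d, a2$d)
    expect_equal(a1$scenario, a2$scenario)
    expect_equal(a1$distance, a2$distance, tolerance = 1e-9)
    n_checked <- n_checked + nrow(a1)
  }
  expect_gte(n_checked, 10)
})

test_that("most copy-neutral held-out variants recover their true edge", {
  set.seed(54)
  hits <- 0; total <- 0
  for (s in 1:8) {
    co <- simulate_cohort(desk_config(n_leaves = 3, sv = 0, snv = 8,
                                      m_samples = 4),
                          noisy = FALSE, seed = 400 + s)
    p <- co$panel
    nv <- p$l + p$g
    if (nv < 4) next
    held_idx <- sample(nv, 2)
    keep <- setdiff(seq_len(nv), held_idx)
    fit <- structure(list(tree = co$tree, profiles = co$profiles, U = co$U,
                          panel = p), class = "clone_fit")
    held <- list(panel = clonedecomp:::panel_subset(p, held_idx))
    held$bulk <- clonedecomp:::new_bulk_obs(
      co$bulk$F[, c(match(held$panel$variants$id, p$variants$id),
                    clonedecomp:::cols_seg(p)), drop = FALSE],
      held$panel)
    asg <- assign_unsampled(fit, held)
    origin <- variant_origins(co$tree, p)
    for (k in seq_len(nrow(asg))) {
      total <- total + 1
      if (asg$node[k] == origin[[asg$id[k]]]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("merged assignments extend the fit consistently", {
  co <- simulate_cohort(desk_config(n_leaves = 2, sv = 2, snv = 5,
                                    m_samples = 3),
                        noisy = FALSE, seed = 55)
  flt <- filter_segments_to_variant_bearing(co$panel, co$bulk)
  sub <- subsample_variants(flt$panel, flt$bulk, max_total = 4, seed = 5)
  skip_if(is.null(sub$held_out))
  cfg <- solver_config(n_leaves = 2, c_max = 8, time_limit = 120,
                       phasing = "gated", n_restarts = 2, max_iters = 4)
  fit <- coordinate_descent(sub$bulk, sub$panel, cfg, seed = 6)
  asg <- assign_unsampled(fit, sub$held_out)
  merged <- merge_assignment(fit, sub$held_out, asg)
  nv_new <- merged$panel$l + merged$panel$g
  expect_equal(nv_new, sub$panel$l + sub$panel$g +
                 sub$held_out$panel$l + sub$held_out$panel$g)
  # merged solution still satisfies the structural invariants
  repv <- validate_solution(merged$tree, merged$profiles, merged$U,
                            merged$panel)
  bad <- repv[!repv$ok, , drop = FALSE]
  # scenario-2 rounding can break only the allele-cap check; Dollo and the
  # tree structure must hold exactly
  expect_true(all(bad$check %in% "variant_copy_within_allele"))
  # empty assignment is the identity
  same <- merge_assignment(fit, NULL, asg[0, ])
  expect_identical(same$profiles$C, fit$profiles$C)
})
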