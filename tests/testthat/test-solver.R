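test_that("default lambdas follow the scale-normalizing formulas", {
  lam <- default_lambdas(l = 2, g = 1, r = 2, m = 1, N = 3)
  expect_equal(lam$lambda1, 7 / 12)
  expect_equal(lam$lambda2, 7 / 6)
  lam2 <- default_lambdas(l = 2, g = 1, r = 2, m = 2, N = 3)
  expect_equal(lam2$lambda1, lam$lambda1 / 2)
  expect_equal(lam2$lambda2, lam$lambda2)
  expect_error(default_lambdas(0, 0, 2, 1, 3), "lambda2")
})

test_that("U-step returns simplex-exact global optima", {
  # degenerate single-clone case: the simplex forces U = 1
  C1 <- matrix(c(0, 1, 1), 1)
  fit1 <- solve_u_step(matrix(c(0.2, 1.1, 0.9), 1), C1)
  expect_equal(unname(fit1$U), matrix(1, 1, 1))

  # exact recovery at a full-row-rank C
  set.seed(21)
  C <- rbind(c(2, 0, 1, 3), c(0, 2, 1, 0), c(1, 1, 1, 1))
  stopifnot(qr(C)$rank == 3)
  u_star <- c(0.25, 0.35, 0.4)
  F <- matrix(u_star %*% C, 1)
  fit <- solve_u_step(F, C)
  expect_lt(fit$objective, 1e-9)
  expect_equal(unname(fit$U[1, ]), u_star, tolerance = 1e-7)

  # simplex row sums hold to numerical exactness
  co <- simulate_cohort(desk_config(m_samples = 3), noisy = FALSE,
                        seed = 22)
  fitc <- solve_u_step(co$bulk, co$profiles$C)
  expect_lt(max(abs(rowSums(fitc$U) - 1)), 1e-9)

  # leaf-only mode zeroes internal non-root clones
  co5 <- simulate_cohort(desk_config(n_leaves = 3, m_samples = 2),
                         noisy = FALSE, seed = 23)
  fit5 <- solve_u_step(co5$bulk, co5$profiles$C, leaf_only = TRUE)
  expect_true(all(fit5$U[, 4] == 0))
})

test_that("U-step LP matches an exhaustive simplex grid on a tiny instance", {
  C <- rbind(c(0, 2, 1), c(2, 0, 1), c(1, 1, 1))
  F <- matrix(c(0.9, 1.3, 1.0), 1)
  fit <- solve_u_step(F, C)
  # grid over the 2-simplex at step 0.001
  u1 <- seq(0, 1, by = 0.001)
  best <- Inf
  for (a in u1) {
    b <- seq(0, 1 - a, by = 0.001)
    res <- abs(outer(a * C[1, 1] + b * C[2, 1] + (1 - a - b) * C[3, 1],
                     0) + 0)
    UU <- cbind(a, b, 1 - a - b)
    r <- abs(UU %*% C - matrix(F, nrow(UU), 3, byrow = TRUE))
    best <- min(best, min(rowSums(r)))
  }
  expect_lt(abs(fit$objective - best), 1e-3 * max(1, best) + 1e-6)
  expect_lte(fit$objective, best + 1e-9)
})

test_that("C-step returns the all-normal optimum on diploid data", {
  p <- toy_panel()
  F <- normal_F(p)
  U <- matrix(c(0.3, 0.3, 0.4), 1)
  res <- solve_c_step(F, U, p, solver_config(n_leaves = 2, c_max = 2,
                                             time_limit = 60))
  expect_identical(res$status, "optimal")
  expect_equal(res$objective, 0, tolerance = 1e-9)
  expect_equal(res$R, 0)
  expect_equal(res$S, 0)
  expect_true(all(res$profiles$C[, 1:3] == 0))
  expect_true(all(res$profiles$C[, 4:7] == 1))
})

test_that("C-step with true frequencies recovers a noiseless truth", {
  co <- simulate_cohort(desk_config(n_leaves = 2, m_samples = 4, sv = 4),
                        noisy = FALSE, seed = 24)
  cfg <- solver_config(n_leaves = 2, c_max = 8, time_limit = 300,
                       phasing = "gated")
  res <- solve_c_step(co$bulk, co$U, co$panel, cfg)
  expect_identical(res$status, "optimal")
  # the solution is at least as good as the (feasible) truth
  tobj <- compute_objective(co$bulk, co$U, co$profiles$C, co$tree, co$panel,
                            res$lambda1, res$lambda2)
  expect_lte(res$objective, tobj$total + 1e-6)
  # backend objective agrees with the independent recomputation
  oobj <- compute_objective(co$bulk, co$U, res$profiles$C, res$tree,
                            co$panel, res$lambda1, res$lambda2)
  expect_equal(res$objective, oobj$total, tolerance = 1e-6)
  # and the solution validates (Dollo and all)
  repv <- validate_solution(res$tree, res$profiles, co$U, co$panel)
  expect_true(attr(repv, "ok"))
})

test_that("a single perturbed entry moves the data term by its size", {
  co <- simulate_cohort(desk_config(n_leaves = 2, m_samples = 4, sv = 4),
                        noisy = FALSE, seed = 24)
  cfg <- solver_config(n_leaves = 2, c_max = 8, time_limit = 300,
                       phasing = "gated")
  base <- solve_c_step(co$bulk, co$U, co$panel, cfg)
  F2 <- co$bulk$F
  j <- co$panel$l + co$panel$g + 1  # a segment column
  F2[1, j] <- F2[1, j] + 0.4
  res2 <- solve_c_step(F2, co$U, co$panel, cfg)
  d2 <- sum(abs(F2 - co$U %*% res2$profiles$C))
  expect_equal(d2, 0.4, tolerance = 1e-6)
  expect_equal(res2$profiles$C[, j], base$profiles$C[, j])
})

test_that("compute_objective components follow the edge distances", {
  p <- toy_panel()
  E <- matrix(0L, 3, 3); E[3, 1] <- E[3, 2] <- 1L
  tree <- clone_tree(2, E)
  C <- matrix(rep(c(0, 0, 0, 1, 1, 1, 1), each = 3), 3)
  U <- random_simplex(2, 3)
  F <- U %*% C
  obj0 <- compute_objective(F, U, C, tree, p, 0.5, 0.5)
  expect_equal(obj0$R, 0)
  expect_equal(obj0$total, 0)
  # one allele-1 segment gain on the edge into leaf 1
  C1 <- C; C1[1, 4] <- 2
  obj1 <- compute_objective(U %*% C1, U, C1, tree, p, 0.5, 0.5)
  expect_equal(obj1$R, 1)
  expect_equal(obj1$data, 0)
})

test_that("coordinate descent fits diploid data immediately and toys exactly", {
  p <- toy_panel()
  F <- normal_F(p, m = 2)
  cfg <- solver_config(n_leaves = 2, c_max = 2, time_limit = 60,
                       n_restarts = 1, max_iters = 3)
  fit <- coordinate_descent(F, p, cfg, seed = 1)
  expect_equal(fit$objective$total, 0, tolerance = 1e-9)
  expect_equal(fit$trace$iter[nrow(fit$trace)] <= 2, TRUE)

  co <- simulate_cohort(desk_config(n_leaves = 2, m_samples = 4, sv = 3,
                                    snv = 12),
                        noisy = FALSE, seed = 25)
  cfg2 <- solver_config(n_leaves = 2, c_max = 8, time_limit = 120,
                        phasing = "gated", n_restarts = 3, max_iters = 6)
  fit2 <- coordinate_descent(co$bulk, co$panel, cfg2, seed = 2)
  expect_lt(fit2$objective$data, 1e-6)
  mc <- match_clones(co$profiles$C, fit2$profiles$C)
  expect_equal(mc$cost, 0)
  # trace is non-increasing whenever the C-steps solved to optimality
  tr <- fit2$trace
  for (rs in unique(tr$restart)) {
    o <- tr$objective[tr$restart == rs]
    st <- tr$c_status[tr$restart == rs]
    if (all(st == "optimal") && length(o) > 1) {
      expect_true(all(diff(o) <= 1e-6))
    }
  }
})

test_that("leaf-only mode keeps internal clone frequencies at zero", {
  co <- simulate_cohort(desk_config(n_leaves = 3, m_samples = 3, sv = 2,
                                    snv = 2),
                        leaf_only = TRUE, noisy = FALSE, seed = 26)
  cfg <- solver_config(n_leaves = 3, c_max = 8, time_limit = 120,
                       phasing = "gated", n_restarts = 2, max_iters = 4,
                       leaf_only = TRUE)
  fit <- coordinate_descent(co$bulk, co$panel, cfg, seed = 3)
  expect_true(all(abs(fit$U[, 4]) < 1e-9))
})

test_that("collapse_tree prunes and is idempotent", {
  # chain root -> x (freq 0, one child) -> leaf after a zero-length merge
  E <- matrix(0L, 3, 3); E[3, 1] <- E[3, 2] <- 1L
  W <- array(0L, dim = c(3, 3, 1)); W[3, 1, 1] <- 1L
  rho <- matrix(0, 3, 3); rho[3, 1] <- 2
  tree <- clone_tree(2, E, W = W, rho = rho)
  U <- matrix(c(0.6, 0, 0.4), 1)  # leaf 2 carries no mass, rho(3,2)=0
  fit <- list(tree = tree, profiles = NULL, U = U)
  cl <- collapse_tree(fit)
  # leaf 2: zero-length, variant-free branch -> merged into root
  expect_equal(cl$n_clones, 2)
  expect_true(all(sort(unlist(cl$members)) == c(1, 2, 3)))

  # fully supported tree is untouched
  U2 <- matrix(c(0.3, 0.3, 0.4), 1)
  rho2 <- matrix(0, 3, 3); rho2[3, 1] <- 1; rho2[3, 2] <- 2
  fit2 <- list(tree = clone_tree(2, E, W = W, rho = rho2), U = U2)
  expect_equal(collapse_tree(fit2)$n_clones, 3)

  # idempotence on solver output
  co <- simulate_cohort(desk_config(sv = 2, snv = 2), noisy = FALSE,
                        seed = 27)
  cfg <- solver_config(n_leaves = 2, c_max = 8, time_limit = 60,
                       phasing = "gated", n_restarts = 1, max_iters = 2)
  fit3 <- coordinate_descent(co$bulk, co$panel, cfg, seed = 4)
  c1 <- collapse_tree(fit3)
  expect_equal(collapse_tree(fit3)$n_clones, c1$n_clones)
})
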