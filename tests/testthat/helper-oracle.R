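# Independent brute-force oracle for the profile step on N = 3 instances
# (root + two leaves; the unique binary topology). Enumerates every segment
# copy configuration and, per variant group (a breakpoint mate pair or a
# single SNV), every allele / copy / introduction option, checking
# feasibility with straight-line replay code that shares nothing with the
# ILP model builder.

cstep_bruteforce <- function(F, U, panel, cmax, lambda1, lambda2,
                             phasing = "strict") {
  nv <- panel$l + panel$g
  r <- panel$r
  m <- nrow(F)
  seg_of <- clonedecomp:::variant_segment(panel)
  psi <- clonedecomp:::mixed_segment_copy(F, panel)
  vaf <- pmin(pmax(clonedecomp:::compute_vaf(F, panel), 0), 1)

  # variant groups: mate pairs then single SNVs
  groups <- list()
  if (panel$l > 0) {
    mate <- max.col(panel$G, ties.method = "first")
    for (b in seq_len(panel$l)) {
      if (b < mate[b]) groups[[length(groups) + 1L]] <- c(b, mate[b])
    }
  }
  for (b in panel$l + seq_len(panel$g)) {
    groups[[length(groups) + 1L]] <- b
  }

  # all segment configurations for leaf rows 1 and 2 (root row is all 1)
  vals <- 0:cmax
  nseg <- 2L * r
  grid <- as.matrix(expand.grid(rep(list(vals), 2L * nseg)))

  # per-group option list, evaluated lazily against a segment config
  # option: list(d, intro (0 = absent, 1 or 2 = leaf), copies[leaf, member])
  group_options <- lapply(groups, function(grp) {
    k <- length(grp)
    opts <- list()
    for (d in c(1L, 0L)) {
      opts[[length(opts) + 1L]] <- list(d = d, intro = 0L,
                                        copies = matrix(0L, 2, k))
    }
    for (d in c(1L, 0L)) {
      for (leaf in 1:2) {
        cc <- as.matrix(expand.grid(rep(list(1:cmax), k)))
        for (q in seq_len(nrow(cc))) {
          copies <- matrix(0L, 2, k)
          copies[leaf, ] <- as.integer(cc[q, ])
          opts[[length(opts) + 1L]] <- list(d = d, intro = leaf,
                                            copies = copies)
        }
      }
    }
    opts
  })

  best <- Inf
  for (cfg_row in seq_len(nrow(grid))) {
    segC <- matrix(grid[cfg_row, ], nrow = 2)  # 2 leaves x 2r columns
    R <- sum(abs(segC - 1))
    seg_data <- 0
    for (p in seq_len(m)) {
      mixed <- U[p, 1] * segC[1, ] + U[p, 2] * segC[2, ] + U[p, 3] * 1
      seg_data <- seg_data + sum(abs(F[p, nv + seq_len(nseg)] - mixed))
    }
    total <- seg_data + lambda1 * R
    feasible <- TRUE

    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      gbest <- Inf
      for (opt in group_options[[gi]]) {
        ok <- TRUE
        for (mi in seq_along(grp)) {
          b <- grp[mi]
          s <- seg_of[b]
          gam <- function(leaf, allele) {
            segC[leaf, (allele - 1L) * r + s]
          }
          for (leaf in 1:2) {
            cv <- opt$copies[leaf, mi]
            cap <- if (opt$d == 1) gam(leaf, 1) else gam(leaf, 2)
            if (cv > cap) { ok <- FALSE; break }
            if (phasing == "strict") {
              w <- as.integer(opt$intro == leaf)
              if (w == 0) {
                # active when the allele matches d; requires equality of
                # variant and segment change from the root (variant change
                # = cv - 0, segment change = gam - 1)
                if (opt$d == 1 && (gam(leaf, 1) - 1) != cv) ok <- FALSE
                if (opt$d == 0 && (gam(leaf, 2) - 1) != cv) ok <- FALSE
              }
            }
            if (!ok) break
          }
          if (!ok) break
        }
        if (!ok) next
        contrib <- 0
        for (mi in seq_along(grp)) {
          b <- grp[mi]
          s <- seg_of[b]
          for (p in seq_len(m)) {
            est <- U[p, 1] * opt$copies[1, mi] + U[p, 2] * opt$copies[2, mi]
            contrib <- contrib + abs(F[p, b] - est)
            if (psi[p, b] > 0) {
              gtot <- U[p, 1] * (segC[1, s] + segC[1, r + s]) +
                U[p, 2] * (segC[2, s] + segC[2, r + s]) + U[p, 3] * 2
              contrib <- contrib + lambda2 * abs(vaf[p, b] * gtot - est)
            }
          }
        }
        if (contrib < gbest) gbest <- contrib
      }
      if (!is.finite(gbest)) { feasible <- FALSE; break }
      total <- total + gbest
    }
    if (feasible && total < best) best <- total
  }
  unname(best)
}

# Independent brute force for held-out variant assignment: enumerate all
# (allele, node, scenario) for each variant (pairs jointly), mirroring the
# published pseudocode directly.
assign_bruteforce <- function(fit, held_out, admissibility = "printed") {
  hp <- held_out$panel
  Fh <- held_out$bulk$F
  C <- fit$profiles$C
  U <- as.matrix(fit$U)
  tree <- fit$tree
  N <- tree$N
  sp <- fit$panel
  nvs <- sp$l + sp$g

  seg_idx <- vapply(seq_len(hp$l + hp$g), function(b) {
    which(sp$segments$chrom == hp$variants$chrom[b] &
            sp$segments$start <= hp$variants$pos[b] &
            sp$segments$end >= hp$variants$pos[b])
  }, integer(1))
  parent <- vapply(seq_len(N), function(j) {
    p <- which(tree$E[, j] > 0)
    if (length(p)) p[[1]] else NA_integer_
  }, integer(1))

  one <- function(b, d, i, scen) {
    s <- seg_idx[b]
    chat <- C[, if (d == 1) nvs + s else nvs + sp$r + s]
    desc <- which(tree$A[i, ] > 0)
    if (scen == 1) {
      adm <- if (admissibility == "printed") {
        chat[i] == 1 || chat[i] - chat[parent[i]] > 1
      } else chat[i] >= 1
      if (!adm) return(Inf)
      pred <- U[, i] * chat[i]
      for (k in desc) pred <- pred + U[, k] * chat[k]
    } else {
      if (chat[i] < 1) return(Inf)
      pred <- U[, i]
      for (k in desc) pred <- pred + U[, k] * chat[k] / chat[i]
    }
    sum(abs(pred - Fh[, b]))
  }

  groups <- list()
  if (hp$l > 0) {
    mate <- max.col(hp$G, ties.method = "first")
    for (b in seq_len(hp$l)) {
      if (b < mate[b]) groups[[length(groups) + 1L]] <- c(b, mate[b])
    }
  }
  for (b in hp$l + seq_len(hp$g)) groups[[length(groups) + 1L]] <- b

  out <- list()
  for (grp in groups) {
    best <- NULL
    for (i in seq_len(N - 1L)) {
      for (d in c(1L, 0L)) {
        for (scen in 1:2) {
          dd <- sum(vapply(grp, one, numeric(1), d = d, i = i,
                           scen = scen))
          if (is.finite(dd) && (is.null(best) || dd < best$dist - 1e-12)) {
            best <- list(node = i, d = d, scen = scen, dist = dd)
          }
        }
      }
    }
    for (b in grp) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = hp$variants$id[b], node = best$node, d = best$d,
        scenario = best$scen, distance = best$dist)
    }
  }
  dplyr::bind_rows(out)
}
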