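#' Subset a panel to chosen variant indices
#' @noRd
panel_subset <- function(panel, keep) {
  keep <- sort(unique(as.integer(keep)))
  vr <- panel$variants[keep, , drop = FALSE]
  is_bp <- vr$type == "breakpoint"
  bp <- if (any(is_bp)) vr[is_bp, c("id", "chrom", "pos", "direction",
                                    "mate_id")] else NULL
  snv <- if (any(!is_bp)) vr[!is_bp, c("id", "chrom", "pos")] else NULL
  build_panel(bp, snv, panel$segments)
}

#' Subsample breakpoint pairs and SNVs for tractable solving
#'
#' Uniform random subsampling: breakpoint mate pairs are kept or dropped
#' together, up to `max_breakpoints` individual breakpoints; SNVs then fill
#' the remaining budget of `max_total` (breakpoints + SNVs). All segments
#' are always kept. With limits at or above the available counts the
#' subsample is the identity.
#'
#' @param panel a [variant_panel].
#' @param F bulk matrix or `bulk_obs`.
#' @param max_breakpoints maximum number of breakpoints (pairs count 2).
#' @param max_total maximum breakpoints + SNVs in the subsample.
#' @param seed optional integer seed.
#' @return list with `panel` and `bulk` (the subsample), `held_out`
#'   (a similar list for the held-out variants, or `NULL` if empty) and
#'   `plan` (kept/held-out variant ids and the seed).
#' @export
subsample_variants <- function(panel, F, max_breakpoints = Inf,
                               max_total = Inf, seed = NULL) {
  if (inherits(F, "bulk_obs")) F <- F$F
  stopifnot(max_breakpoints >= 0, max_total >= 0)
  with_sim_seed(seed, {
    l <- panel$l
    g <- panel$g
    keep_bp <- integer()
    if (l > 0) {
      mate <- max.col(panel$G, ties.method = "first")
      firsts <- which(seq_len(l) < mate)
      n_pairs_max <- min(floor(min(max_breakpoints, max_total) / 2),
                         length(firsts))
      chosen <- if (n_pairs_max >= length(firsts)) firsts
                else sort(sample(firsts, n_pairs_max))
      keep_bp <- sort(c(chosen, mate[chosen]))
    }
    keep_snv <- integer()
    if (g > 0) {
      budget <- max_total - length(keep_bp)
      n_snv <- min(max(floor(budget), 0), g)
      pool <- l + seq_len(g)
      keep_snv <- if (n_snv >= g) pool else sort(sample(pool, n_snv))
    }
    keep <- c(keep_bp, keep_snv)
    held <- setdiff(seq_len(l + g), keep)

    slice <- function(idx) {
      if (!length(idx)) return(NULL)
      sub <- panel_subset(panel, idx)
      # variant columns in sub order, then all segment columns
      F_sub <- F[, c(match(sub$variants$id, panel$variants$id),
                     cols_seg(panel)), drop = FALSE]
      list(panel = sub, bulk = new_bulk_obs(F_sub, sub,
                                            samples = rownames(F)))
    }
    out <- slice(keep)
    if (is.null(out)) stop("subsample is empty; raise the limits")
    list(panel = out$panel, bulk = out$bulk,
         held_out = slice(held),
         plan = list(kept = panel$variants$id[keep],
                     held_out = panel$variants$id[held],
                     max_breakpoints = max_breakpoints,
                     max_total = max_total, seed = seed))
  })
}

#' Assign held-out variants to edges of a solved tree
#'
#' For each variant left out of the solve, every candidate introduction
#' edge (identified by its child node `i`), allele `d` and timing scenario
#' is scored by the L1 distance, across samples, between the variant's
#' observed mean copy number and the value implied by the solved
#' frequencies `U` and segment copies `C`:
#'
#' * scenario 1 (variant acquired before any copy change on the edge): the
#'   variant count equals its allele's segment copy, so the prediction is
#'   `U[, i] chat_i + sum_k U[, k] chat_k` over descendants `k`; admissible
#'   when `chat_i = 1` or the copy gain on the edge exceeds 1 (with
#'   `admissibility = "gain1"`, simply `chat_i >= 1`).
#' * scenario 2 (acquired after the change): one copy in the assigned
#'   clone, and the expectation `chat_k / chat_i` in each descendant;
#'   admissible when `chat_i >= 1` (coincides with scenario 1 when
#'   `chat_i = 1`).
#'
#' Mate pairs of a breakpoint are assigned jointly (summed distance, shared
#' edge and allele). Ties break deterministically: smaller node index, then
#' allele 1, then scenario 1. The root is not a candidate (it carries no
#' variants).
#'
#' @param fit a `clone_fit` (solved `tree`, `U`, `profiles`).
#' @param held_out the `held_out` element of [subsample_variants()] (panel
#'   + bulk of held-out variants), or a list with `panel` and `bulk`.
#' @param admissibility `"printed"` for the `chat_i = 1 or gain > 1` rule,
#'   `"gain1"` for `chat_i >= 1`.
#' @return tibble with one row per held-out variant: `id`, `node`,
#'   `allele` (1 or 2 mapped from `d`: `d = 1` is allele 1), `scenario`,
#'   `distance`.
#' @export
assign_unsampled <- function(fit, held_out,
                             admissibility = c("printed", "gain1")) {
  admissibility <- match.arg(admissibility)
  hp <- held_out$panel
  Fh <- if (inherits(held_out$bulk, "bulk_obs")) held_out$bulk$F
        else held_out$bulk
  tree <- fit$tree
  C <- fit$profiles$C
  U <- as.matrix(fit$U)
  N <- tree$N
  solved_panel <- fit$panel
  nv_solved <- solved_panel$l + solved_panel$g

  # map each held-out variant's position into the solved segmentation
  seg_idx <- vapply(seq_len(hp$l + hp$g), function(b) {
    ch <- hp$variants$chrom[b]
    pos <- hp$variants$pos[b]
    hit <- which(solved_panel$segments$chrom == ch &
                   solved_panel$segments$start <= pos &
                   solved_panel$segments$end >= pos)
    if (length(hit) != 1L) {
      stop("held-out variant ", hp$variants$id[b],
           " does not map into the solved segmentation")
    }
    hit
  }, integer(1))

  parent <- vapply(seq_len(N), function(j) {
    p <- which(tree$E[, j] > 0)
    if (length(p)) p[[1]] else NA_integer_
  }, integer(1))

  score_one <- function(b, d, i, scen) {
    s <- seg_idx[b]
    acol <- if (d == 1) nv_solved + s else nv_solved + solved_panel$r + s
    chat <- C[, acol]
    ci <- chat[i]
    cp <- chat[parent[i]]
    desc <- which(tree$A[i, ] > 0)
    if (scen == 1) {
      ok <- if (admissibility == "printed") (ci == 1 || ci - cp > 1)
            else ci >= 1
      if (!ok) return(Inf)
      pred <- U[, i] * ci +
        if (length(desc)) as.numeric(U[, desc, drop = FALSE] %*% chat[desc])
        else 0
    } else {
      if (ci < 1) return(Inf)
      pred <- U[, i] * 1 +
        if (length(desc)) {
          as.numeric(U[, desc, drop = FALSE] %*% (chat[desc] / ci))
        } else 0
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

  rows <- list()
  for (grp in groups) {
    best <- NULL
    for (i in seq_len(N - 1L)) {
      for (d in c(1L, 0L)) {
        for (scen in 1:2) {
          dist <- sum(vapply(grp, score_one, numeric(1), d = d, i = i,
                             scen = scen))
          if (is.finite(dist) &&
              (is.null(best) || dist < best$distance - 1e-12)) {
            best <- list(node = i, d = d, scenario = scen, distance = dist)
          }
        }
      }
    }
    if (is.null(best)) {
      stop("no admissible assignment for variant(s) ",
           paste(hp$variants$id[grp], collapse = ", "))
    }
    for (b in grp) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = hp$variants$id[b], node = best$node, d = best$d,
        scenario = best$scenario, distance = best$distance)
    }
  }
  dplyr::bind_rows(rows)
}

#' Merge assigned held-out variants back into a solved fit
#'
#' Extends the clone profile matrix with one column per held-out variant:
#' under scenario 1 the variant copy equals its allele's segment copy
#' throughout the subtree; under scenario 2 it is 1 in the assigned clone
#' and the rounded expectation `chat_k / chat_i` in descendants (half-up;
#' the pre-rounding value is returned). The introduction tensor `W` and
#' allele vector `D` are extended accordingly, and the panel rebuilt to
#' include the merged variants.
#'
#' @param fit a `clone_fit`.
#' @param held_out as in [assign_unsampled()].
#' @param assignment tibble from [assign_unsampled()].
#' @return a `clone_fit` with extended `panel`, `profiles`, `tree$W`, plus
#'   `merged_prerounding` (named list of pre-rounding descendant values).
#' @export
merge_assignment <- function(fit, held_out, assignment) {
  if (is.null(held_out) || nrow(assignment) == 0) return(fit)
  hp <- held_out$panel
  tree <- fit$tree
  N <- tree$N
  sp <- fit$panel
  nv_old <- sp$l + sp$g

  # merged panel: solved + held-out variants on the solved segmentation
  vr_all <- dplyr::bind_rows(sp$variants, hp$variants)
  is_bp <- vr_all$type == "breakpoint"
  merged_panel <- build_panel(
    if (any(is_bp)) vr_all[is_bp, c("id", "chrom", "pos", "direction",
                                    "mate_id")] else NULL,
    if (any(!is_bp)) vr_all[!is_bp, c("id", "chrom", "pos")] else NULL,
    sp$segments)
  nv_new <- merged_panel$l + merged_panel$g

  seg_of_merged <- variant_segment(merged_panel)
  parent <- vapply(seq_len(N), function(j) {
    p <- which(tree$E[, j] > 0)
    if (length(p)) p[[1]] else NA_integer_
  }, integer(1))

  C_old <- fit$profiles$C
  C_new <- matrix(0L, N, n_cols(merged_panel))
  colnames(C_new) <- layout_colnames(merged_panel)
  seg_cols_new <- nv_new + seq_len(2 * merged_panel$r)
  seg_cols_old <- nv_old + seq_len(2 * sp$r)
  C_new[, seg_cols_new] <- C_old[, seg_cols_old]
  D_new <- integer(nv_new)
  W_new <- array(0L, dim = c(N, N, nv_new))
  prer <- list()

  old_pos <- match(sp$variants$id, merged_panel$variants$id)
  C_new[, old_pos] <- C_old[, seq_len(nv_old), drop = FALSE]
  D_new[old_pos] <- fit$profiles$D
  if (nv_old > 0 && !is.null(tree$W)) {
    for (b in seq_len(nv_old)) W_new[, , old_pos[b]] <- tree$W[, , b]
  }

  for (k in seq_len(nrow(assignment))) {
    id <- assignment$id[k]
    bnew <- match(id, merged_panel$variants$id)
    i <- assignment$node[k]
    d <- assignment$d[k]
    s <- seg_of_merged[bnew]
    acol <- if (d == 1) nv_new + s else nv_new + merged_panel$r + s
    chat <- C_new[, acol]
    desc <- which(tree$A[i, ] > 0)
    col <- numeric(N)
    if (assignment$scenario[k] == 1) {
      col[i] <- chat[i]
      col[desc] <- chat[desc]
    } else {
      col[i] <- 1
      if (length(desc)) {
        expv <- chat[desc] / max(chat[i], 1)
        prer[[id]] <- expv
        col[desc] <- floor(expv + 0.5)
      }
    }
    C_new[, bnew] <- as.integer(col)
    D_new[bnew] <- d
    W_new[parent[i], i, bnew] <- 1L
  }

  tree$W <- W_new
  fit$tree <- tree
  fit$profiles <- clone_profiles(C_new, D_new, fit$profiles$c_max)
  fit$panel <- merged_panel
  fit$merged_prerounding <- prer
  fit
}
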