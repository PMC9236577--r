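#' Simulation configuration
#'
#' Parameters of the clonal-evolution generator. Structural variants are
#' drawn with type weights duplication : deletion : translocation :
#' inversion of 2:2:1:1, span lengths from a Poisson with mean
#' `sv_length_mean` (default 5,745,000 bp, the empirical mean SV length in
#' breast-cancer whole genomes), allele-specific duplication multiplicities
#' uniform on `dup_mult_range` (default 2..6), and read-count noise at
#' `read_depth` expected reads per segment (default 100). Copy-number
#' alterations arise only as consequences of duplications and deletions and
#' are not simulated separately.
#'
#' Either a total SV rate (`sv_rate_total`: Poisson mean for the total SV
#' count, each event then assigned to a uniformly random tree edge) or a
#' per-branch rate (`sv_rate_branch`: Poisson mean per edge) may be given.
#' The SNV count is Poisson with mean `snv_count_param`, which defaults to
#' 100 times the total SV rate.
#'
#' The default genome is a compact two-chromosome reference (2 x 50 Mb)
#' suitable for method studies; supply `genome` to change it.
#'
#' @param n_leaves number of leaf clones (>= 2).
#' @param m_samples number of bulk samples.
#' @param sv_rate_total Poisson mean of the total SV count (ignored when
#'   `sv_rate_branch` is given).
#' @param sv_rate_branch Poisson mean of the per-edge SV count, or `NULL`.
#' @param snv_count_param Poisson mean of the total SNV count; default
#'   `100 * total SV rate`.
#' @param sv_length_mean mean SV span in bp.
#' @param event_type_weights positive weights for duplication, deletion,
#'   translocation, inversion.
#' @param dup_mult_range integer range of duplication multiplicities.
#' @param read_depth expected reads per segment for the noise model.
#' @param c_max copy-number cap applied when realizing profiles.
#' @param genome named numeric vector of chromosome lengths.
#' @param max_retries placement retries per event before failing.
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 4,
                       m_samples = 5,
                       sv_rate_total = 20,
                       sv_rate_branch = NULL,
                       snv_count_param = NULL,
                       sv_length_mean = 5745000,
                       event_type_weights = c(dup = 2, del = 2,
                                              trans = 1, inv = 1),
                       dup_mult_range = c(2L, 6L),
                       read_depth = 100,
                       c_max = 10,
                       genome = c(chr1 = 5e7, chr2 = 5e7),
                       max_retries = 100L) {
  if (n_leaves < 2) stop("n_leaves must be at least 2")
  if (any(event_type_weights <= 0)) stop("event type weights must be positive")
  if (dup_mult_range[1] < 2 || dup_mult_range[2] > c_max) {
    stop("dup_mult_range must lie within [2, c_max]")
  }
  if (read_depth <= 0) stop("read_depth must be positive")
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  n_edges <- 2L * as.integer(n_leaves) - 2L
  total_rate <- if (!is.null(sv_rate_branch)) sv_rate_branch * n_edges
                else sv_rate_total
  if (is.null(snv_count_param)) snv_count_param <- 100 * total_rate
  structure(
    list(n_leaves = as.integer(n_leaves),
         m_samples = as.integer(m_samples),
         sv_rate_total = sv_rate_total,
         sv_rate_branch = sv_rate_branch,
         snv_count_param = snv_count_param,
         sv_length_mean = sv_length_mean,
         event_type_weights = event_type_weights,
         dup_mult_range = as.integer(dup_mult_range),
         read_depth = read_depth,
         c_max = as.integer(c_max),
         genome = genome,
         max_retries = as.integer(max_retries)),
    class = "sim_config"
  )
}

#' Evaluate code under an optional fixed seed
#' @noRd
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# ---- piecewise-constant copy number over one chromosome ---------------------
# Represented as boundaries b (ascending, b[1] = 1, b[last] = len + 1) and
# values v per interval [b[i], b[i+1] - 1].

pw_new <- function(len) list(b = c(1, len + 1), v = 1)

pw_split <- function(pw, pos) {
  i <- findInterval(pos, pw$b)
  if (pw$b[i] == pos) return(pw)
  list(b = append(pw$b, pos, after = i),
       v = append(pw$v, pw$v[i], after = i))
}

pw_min <- function(pw, s, e) {
  i <- findInterval(s, pw$b)
  j <- findInterval(e, pw$b)
  min(pw$v[i:j])
}

pw_add <- function(pw, s, e, delta, lo = 0, hi = Inf) {
  pw <- pw_split(pw, s)
  pw <- pw_split(pw, e + 1)
  i <- findInterval(s, pw$b)
  j <- findInterval(e + 1, pw$b) - 1L
  pw$v[i:j] <- pmin(pmax(pw$v[i:j] + delta, lo), hi)
  pw
}

pw_value <- function(pw, pos) pw$v[findInterval(pos, pw$b)]

# ---- clone genome state -----------------------------------------------------
# state$cn[[allele]][[chrom]] is a pw; state$vars is a data frame of point
# variants (id, chrom, pos, allele, copy).

new_clone_state <- function(genome) {
  cn <- lapply(1:2, function(a) lapply(genome, pw_new))
  list(cn = cn,
       vars = data.frame(id = character(), chrom = character(),
                         pos = numeric(), allele = integer(),
                         copy = numeric()))
}

state_min_copy <- function(st, allele, chrom, s, e) {
  pw_min(st$cn[[allele]][[chrom]], s, e)
}

state_add_var <- function(st, id, chrom, pos, allele, copy) {
  st$vars[nrow(st$vars) + 1L, ] <- list(id, chrom, pos, allele, copy)
  st
}

# Apply one event to a clone state. Events must already be applicable
# (positive copy over their footprint); enforced by the generator.
# Duplications add (mult - 1) copies and multiply resident variants along;
# deletions remove one copy, taking a variant-bearing copy first.
apply_event <- function(st, ev, c_max) {
  capped <- FALSE
  in_span <- function(chrom, s, e, allele) {
    which(st$vars$chrom == chrom & st$vars$pos >= s & st$vars$pos <= e &
            st$vars$allele == allele & st$vars$copy > 0)
  }
  if (ev$type == "dup") {
    k <- ev$mult
    pw <- st$cn[[ev$allele]][[ev$chrom]]
    if (max(pw$v[findInterval(ev$pos1, pw$b):findInterval(ev$pos2, pw$b)]) +
          k - 1 > c_max) capped <- TRUE
    st$cn[[ev$allele]][[ev$chrom]] <-
      pw_add(pw, ev$pos1, ev$pos2, k - 1, hi = c_max)
    hit <- in_span(ev$chrom, ev$pos1, ev$pos2, ev$allele)
    st$vars$copy[hit] <- st$vars$copy[hit] + (k - 1)
    st <- state_add_var(st, ev$bp1_id, ev$chrom, ev$pos2, ev$allele, k - 1)
    st <- state_add_var(st, ev$bp2_id, ev$chrom, ev$pos1, ev$allele, k - 1)
  } else if (ev$type == "del") {
    st$cn[[ev$allele]][[ev$chrom]] <-
      pw_add(st$cn[[ev$allele]][[ev$chrom]], ev$pos1, ev$pos2, -1, lo = 0)
    hit <- in_span(ev$chrom, ev$pos1, ev$pos2, ev$allele)
    st$vars$copy[hit] <- pmax(st$vars$copy[hit] - 1, 0)
    st <- state_add_var(st, ev$bp1_id, ev$chrom, ev$pos1 - 1, ev$allele, 1)
    st <- state_add_var(st, ev$bp2_id, ev$chrom, ev$pos2 + 1, ev$allele, 1)
  } else if (ev$type == "inv") {
    st <- state_add_var(st, ev$bp1_id, ev$chrom, ev$pos1, ev$allele, 1)
    st <- state_add_var(st, ev$bp2_id, ev$chrom, ev$pos2, ev$allele, 1)
  } else if (ev$type == "trans") {
    st <- state_add_var(st, ev$bp1_id, ev$chrom, ev$pos1, ev$allele, 1)
    st <- state_add_var(st, ev$bp2_id, ev$chrom2, ev$pos2, ev$allele, 1)
  } else if (ev$type == "snv") {
    st <- state_add_var(st, ev$snv_id, ev$chrom, ev$pos1, ev$allele, 1)
  }
  # enforce variant <= allele segment copy after capping
  for (i in which(st$vars$copy > 0)) {
    cap <- pw_value(st$cn[[st$vars$allele[i]]][[st$vars$chrom[i]]],
                    st$vars$pos[i])
    if (st$vars$copy[i] > cap) {
      st$vars$copy[i] <- cap
      capped <- TRUE
    }
  }
  attr(st, "capped") <- capped
  st
}

# Is an event applicable to a state (its footprint has a molecule to act on)?
event_applicable <- function(st, ev) {
  ok_span <- function(chrom, s, e, allele) {
    s >= 1 && e <= unname(attr(st, "genome")[chrom]) &&
      state_min_copy(st, allele, chrom, s, e) >= 1
  }
  switch(ev$type,
    dup = ok_span(ev$chrom, ev$pos1, ev$pos2, ev$allele),
    del = ok_span(ev$chrom, ev$pos1 - 1, ev$pos2 + 1, ev$allele),
    inv = ok_span(ev$chrom, ev$pos1, ev$pos2, ev$allele),
    trans = ok_span(ev$chrom, ev$pos1, ev$pos1, ev$allele) &&
      ok_span(ev$chrom2, ev$pos2, ev$pos2, ev$allele),
    snv = ok_span(ev$chrom, ev$pos1, ev$pos1, ev$allele)
  )
}

#' Draw a uniformly random rooted binary clone tree
#'
#' Topologies are uniform over the `(2n - 3)!!` labeled rooted binary trees
#' on `n` leaves, generated by sequential uniform edge insertion on the
#' unrooted tree with an auxiliary root leaf. Leaves are nodes `1..n`,
#' internal nodes are labeled in decreasing order from the root (node `N`),
#' so every internal child has a smaller index than its parent.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed optional integer seed.
#' @return a `clone_tree`.
#' @examples
#' t <- simulate_tree(4, seed = 1)
#' t$N  # 7 nodes
#' @export
simulate_tree <- function(n_leaves, seed = NULL) {
  if (n_leaves < 2) stop("n_leaves must be at least 2")
  with_sim_seed(seed, {
    n <- as.integer(n_leaves)
    # nodes: 0 = auxiliary root leaf, 1..n = leaves, negatives = internals
    edges <- matrix(c(0L, 1L), ncol = 2)
    next_int <- -1L
    for (k in seq_len(n)[-1]) {
      e <- if (nrow(edges) == 1L) 1L else sample.int(nrow(edges), 1L)
      a <- edges[e, 1]; b <- edges[e, 2]
      t <- next_int; next_int <- next_int - 1L
      edges <- rbind(edges[-e, , drop = FALSE],
                     c(a, t), c(t, b), c(t, k))
    }
    # root the tree at the auxiliary leaf's neighbor
    adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    root_old <- adj[["0"]][1]
    N <- 2L * n - 1L
    label <- integer(0)
    label[as.character(seq_len(n))] <- seq_len(n)
    # BFS from root assigning internal labels N, N-1, ... so parents get
    # larger labels than internal children
    E <- matrix(0L, N, N)
    queue <- root_old
    parent_of <- c(`0` = NA)
    seen <- c("0")
    next_lab <- N
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      vs <- as.character(v)
      seen <- c(seen, vs)
      if (v < 0) {
        label[vs] <- next_lab
        next_lab <- next_lab - 1L
      }
      kids <- adj[[vs]][!as.character(adj[[vs]]) %in% seen]
      for (w in kids) {
        parent_of[as.character(w)] <- v
        queue <- c(queue, w)
      }
    }
    for (ws in names(parent_of)) {
      w <- as.numeric(ws)
      v <- parent_of[[ws]]
      if (is.na(v) || w == 0) next
      E[label[[as.character(v)]], label[[ws]]] <- 1L
    }
    clone_tree(n, E)
  })
}

#' Draw structural variant and SNV events along a clone tree
#'
#' The total SV count is Poisson (`sv_rate_total`), or per-branch Poisson
#' when `sv_rate_branch` is set; each event lands on a uniformly random tree
#' edge and a uniformly random allele. Types follow the 2:2:1:1
#' duplication : deletion : translocation : inversion weights; spans are
#' Poisson with mean `sv_length_mean`; duplication multiplicities are
#' uniform on `dup_mult_range`. SNV counts are Poisson
#' (`snv_count_param`) with positions uniform over the genome. Placements
#' are validated against the evolving clone genomes (an event must act on at
#' least one surviving copy of its footprint) and redrawn up to
#' `max_retries` times; exhaustion raises a placement error.
#'
#' @param tree a `clone_tree` from [simulate_tree()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return tibble event log, one row per event, in application order
#'   (ancestor edges first, draw order within an edge).
#' @export
simulate_events <- function(tree, config, seed = NULL) {
  with_sim_seed(seed, {
    edges <- tree_edges(tree)
    n_edges <- nrow(edges)
    n_sv <- if (!is.null(config$sv_rate_branch)) {
      stats::rpois(n_edges, config$sv_rate_branch)
    } else {
      tot <- stats::rpois(1, config$sv_rate_total)
      tabulate(sample.int(n_edges, tot, replace = TRUE), nbins = n_edges)
    }
    n_snv <- stats::rpois(1, config$snv_count_param)
    snv_edge <- if (n_snv > 0) sample.int(n_edges, n_snv, replace = TRUE)
                else integer()

    types <- names(config$event_type_weights)
    genome <- config$genome
    chroms <- names(genome)

    # per-edge event stubs (type and counters); placement drawn during the
    # topological replay below so applicability can be checked
    stubs <- vector("list", n_edges)
    sv_id <- 0L
    for (e in seq_len(n_edges)) {
      ts <- if (n_sv[e] > 0) {
        sample(types, n_sv[e], replace = TRUE,
               prob = config$event_type_weights)
      } else character()
      stubs[[e]] <- ts
    }
    snv_per_edge <- tabulate(snv_edge, nbins = n_edges)

    states <- vector("list", tree$N)
    st0 <- new_clone_state(genome)
    attr(st0, "genome") <- genome
    states[[tree$N]] <- st0

    log <- list()
    snv_id <- 0L
    # process edges so parents come before children (root has index N and
    # internal labels decrease away from the root)
    ord <- order(-edges[, 1], edges[, 2])
    for (e in ord) {
      i <- edges[e, 1]; j <- edges[e, 2]
      st <- states[[i]]
      kinds <- c(stubs[[e]], rep("snv", snv_per_edge[e]))
      for (kind in kinds) {
        placed <- FALSE
        for (try in seq_len(config$max_retries)) {
          ev <- list(type = kind, parent = i, child = j)
          ev$allele <- sample.int(2L, 1L)
          ev$chrom <- sample(chroms, 1L)
          if (kind == "snv") {
            snv_id_try <- snv_id + 1L
            ev$pos1 <- sample.int(genome[[ev$chrom]], 1L)
            ev$pos2 <- NA_real_
            ev$snv_id <- sprintf("snv%04d", snv_id_try)
          } else {
            sv_id_try <- sv_id + 1L
            if (kind == "trans") {
              ev$chrom2 <- sample(chroms, 1L)
              ev$pos1 <- sample.int(genome[[ev$chrom]] - 2L, 1L) + 1L
              ev$pos2 <- sample.int(genome[[ev$chrom2]] - 2L, 1L) + 1L
              if (ev$chrom2 == ev$chrom && ev$pos2 == ev$pos1) next
            } else {
              len <- stats::rpois(1, config$sv_length_mean)
              if (len < 1 || len + 2 > genome[[ev$chrom]]) next
              s <- sample.int(max(genome[[ev$chrom]] - len - 1L, 1L), 1L) + 1L
              ev$pos1 <- s
              ev$pos2 <- s + len - 1
            }
            if (kind == "dup") {
              ev$mult <- sample(seq(config$dup_mult_range[1],
                                    config$dup_mult_range[2]), 1L)
            }
            ev$bp1_id <- sprintf("sv%04d_1", sv_id_try)
            ev$bp2_id <- sprintf("sv%04d_2", sv_id_try)
          }
          if (event_applicable(st, ev)) {
            gen <- attr(st, "genome")
            st <- apply_event(st, ev, config$c_max)
            attr(st, "genome") <- gen
            if (kind == "snv") snv_id <- snv_id + 1L else sv_id <- sv_id + 1L
            log[[length(log) + 1L]] <- ev
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place a ", kind, " event after ",
               config$max_retries, " retries; genome too saturated")
        }
      }
      states[[j]] <- st
    }

    if (length(log) == 0) {
      return(tibble::tibble(
        event = integer(), type = character(), parent = integer(),
        child = integer(), allele = integer(), chrom = character(),
        chrom2 = character(), pos1 = numeric(), pos2 = numeric(),
        mult = integer(), bp1_id = character(), bp2_id = character(),
        snv_id = character()))
    }
    purrr::map_dfr(seq_along(log), function(k) {
      ev <- log[[k]]
      tibble::tibble(
        event = k, type = ev$type, parent = ev$parent, child = ev$child,
        allele = ev$allele, chrom = ev$chrom,
        chrom2 = if (is.null(ev$chrom2)) NA_character_ else ev$chrom2,
        pos1 = ev$pos1, pos2 = ev$pos2,
        mult = if (is.null(ev$mult)) NA_integer_ else ev$mult,
        bp1_id = if (is.null(ev$bp1_id)) NA_character_ else ev$bp1_id,
        bp2_id = if (is.null(ev$bp2_id)) NA_character_ else ev$bp2_id,
        snv_id = if (is.null(ev$snv_id)) NA_character_ else ev$snv_id)
    })
  })
}

#' Realize clone profiles from an event log
#'
#' Replays the event log along the tree (events inherited by all descendants
#' of their edge), derives the shared segmentation from the union of event
#' endpoints across clones, and emits integer allele-specific segment copy
#' numbers, breakpoint junction copy numbers and SNV copy numbers per clone,
#' capped at `c_max`.
#'
#' @param tree a `clone_tree`.
#' @param events event log from [simulate_events()].
#' @param config the [sim_config()] used to draw the events.
#' @return list with `panel` (a [variant_panel]), `profiles` (a
#'   `clone_profiles` with the true `C` and allele assignment `D`), `tree`
#'   (input tree with the true introduction tensor `W` and branch lengths
#'   `rho` filled in), and `n_capped` (count of copy-cap truncations).
#' @export
realize_profiles <- function(tree, events, config) {
  genome <- config$genome
  N <- tree$N

  # replay states along the tree
  states <- vector("list", N)
  st0 <- new_clone_state(genome)
  attr(st0, "genome") <- genome
  states[[N]] <- st0
  n_capped <- 0L
  edges <- tree_edges(tree)
  ord <- order(-edges[, 1], edges[, 2])
  for (e in ord) {
    i <- edges[e, 1]; j <- edges[e, 2]
    st <- states[[i]]
    evs <- events[events$parent == i & events$child == j, , drop = FALSE]
    if (nrow(evs)) {
      for (k in seq_len(nrow(evs))) {
        ev <- as.list(evs[k, ])
        gen <- attr(st, "genome")
        st <- apply_event(st, ev, config$c_max)
        if (isTRUE(attr(st, "capped"))) n_capped <- n_capped + 1L
        attr(st, "genome") <- gen
      }
    }
    states[[j]] <- st
  }

  # segmentation: union of event endpoints across clones
  cuts <- lapply(names(genome), function(ch) 1)
  names(cuts) <- names(genome)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      if (ev$type %in% c("dup", "del", "inv")) {
        cuts[[ev$chrom]] <- c(cuts[[ev$chrom]], ev$pos1, ev$pos2 + 1)
      } else if (ev$type == "trans") {
        cuts[[ev$chrom]] <- c(cuts[[ev$chrom]], ev$pos1 + 1)
        cuts[[ev$chrom2]] <- c(cuts[[ev$chrom2]], ev$pos2 + 1)
      }
    }
  }
  segments <- purrr::map_dfr(names(genome), function(ch) {
    b <- sort(unique(pmin(pmax(cuts[[ch]], 1), genome[[ch]] + 1)))
    b <- b[b <= genome[[ch]]]
    tibble::tibble(chrom = ch, start = b,
                   end = c(b[-1] - 1, genome[[ch]]))
  })

  # variant records from the root-to-leaf union (every variant appears in
  # the event log exactly once)
  bp_rows <- events[events$type != "snv", , drop = FALSE]
  breakpoints <- NULL
  if (nrow(bp_rows)) {
    breakpoints <- purrr::map_dfr(seq_len(nrow(bp_rows)), function(k) {
      ev <- bp_rows[k, ]
      pos <- switch(ev$type,
        dup = c(ev$pos2, ev$pos1),
        del = c(ev$pos1 - 1, ev$pos2 + 1),
        inv = c(ev$pos1, ev$pos2),
        trans = c(ev$pos1, ev$pos2))
      chr <- if (ev$type == "trans") c(ev$chrom, ev$chrom2)
             else c(ev$chrom, ev$chrom)
      tibble::tibble(
        id = c(ev$bp1_id, ev$bp2_id), chrom = chr, pos = pos,
        direction = c("right", "left"),
        mate_id = c(ev$bp2_id, ev$bp1_id))
    })
  }
  snv_rows <- events[events$type == "snv", , drop = FALSE]
  snvs <- if (nrow(snv_rows)) {
    tibble::tibble(id = snv_rows$snv_id, chrom = snv_rows$chrom,
                   pos = snv_rows$pos1)
  } else NULL

  panel <- build_panel(breakpoints, snvs, segments)
  nv <- panel$l + panel$g

  # allele assignment: the allele each variant event landed on
  var_allele <- integer(nv)
  if (nv > 0) {
    lookup <- c(
      stats::setNames(bp_rows$allele, bp_rows$bp1_id),
      stats::setNames(bp_rows$allele, bp_rows$bp2_id),
      stats::setNames(snv_rows$allele, snv_rows$snv_id))
    var_allele <- unname(lookup[panel$variants$id])
  }
  D <- as.integer(var_allele == 1L)

  # C matrix
  C <- matrix(0L, nrow = N, ncol = n_cols(panel))
  colnames(C) <- layout_colnames(panel)
  for (k in seq_len(N)) {
    st <- states[[k]]
    for (s in seq_len(panel$r)) {
      ch <- panel$segments$chrom[s]
      p0 <- panel$segments$start[s]
      C[k, panel$l + panel$g + s] <-
        pw_value(st$cn[[1]][[ch]], p0)
      C[k, panel$l + panel$g + panel$r + s] <-
        pw_value(st$cn[[2]][[ch]], p0)
    }
    if (nv > 0 && nrow(st$vars)) {
      hit <- match(st$vars$id, panel$variants$id)
      C[k, hit] <- st$vars$copy
    }
  }

  # introduction tensor and branch lengths
  W <- array(0L, dim = c(N, N, nv))
  if (nv > 0 && nrow(events)) {
    edge_of <- rbind(
      if (nrow(bp_rows)) data.frame(id = bp_rows$bp1_id,
                                    i = bp_rows$parent, j = bp_rows$child),
      if (nrow(bp_rows)) data.frame(id = bp_rows$bp2_id,
                                    i = bp_rows$parent, j = bp_rows$child),
      if (nrow(snv_rows)) data.frame(id = snv_rows$snv_id,
                                     i = snv_rows$parent, j = snv_rows$child))
    hit <- match(panel$variants$id, edge_of$id)
    for (b in seq_len(nv)) {
      W[edge_of$i[hit[b]], edge_of$j[hit[b]], b] <- 1L
    }
  }
  rho <- matrix(0, N, N)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    rho[i, j] <- sum(abs(C[i, cols_seg(panel)] - C[j, cols_seg(panel)]))
  }
  tree$W <- W
  tree$rho <- rho

  list(panel = panel,
       profiles = clone_profiles(C, D, config$c_max),
       tree = tree,
       n_capped = n_capped)
}

#' Draw per-sample clone frequencies and mix noiseless bulk profiles
#'
#' Each sample's clone-frequency vector is uniform on the simplex
#' (Dirichlet(1, ..., 1)); the noiseless bulk matrix is the mixture
#' `F = U C`.
#'
#' @param profiles a `clone_profiles` (the true `C`).
#' @param m_samples number of samples.
#' @param leaf_only if `TRUE`, only leaves and the root receive mass.
#' @param n_leaves leaf count (required when `leaf_only`).
#' @param seed optional integer seed.
#' @return list with `U` (m x N) and `F` (m x (l+g+2r), equal to `U %*% C`).
#' @export
simulate_mixture <- function(profiles, m_samples, leaf_only = FALSE,
                             n_leaves = NULL, seed = NULL) {
  with_sim_seed(seed, {
    N <- nrow(profiles$C)
    U <- matrix(0, m_samples, N)
    active <- if (leaf_only) {
      if (is.null(n_leaves)) stop("n_leaves required in leaf_only mode")
      c(seq_len(n_leaves), N)
    } else seq_len(N)
    for (p in seq_len(m_samples)) {
      w <- stats::rexp(length(active))
      U[p, active] <- w / sum(w)
    }
    list(U = U, F = U %*% profiles$C)
  })
}

#' Add read-count noise to a noiseless bulk observation
#'
#' Per sample and segment, a read count `rc ~ Poisson(read_depth)` is drawn.
#' Each variant in that segment receives `alt ~ Binomial(rc, VAF)` variant
#' reads, where the VAF is the theoretical one from the noiseless mixture,
#' and its noisy mean copy number is `(alt / rc) * psi` with `psi` the
#' theoretical mixed segment copy. Each segment's allele split is redrawn
#' from `Binomial(rc, BAF)` (BAF = allele-2 share of the mixed copy); the
#' noisy allele-2 copy is the drawn fraction of the theoretical total.
#' Segments with `rc = 0` keep their theoretical values (counted in
#' `n_fallback`).
#'
#' @param F_true noiseless bulk matrix `U %*% C`.
#' @param panel a [variant_panel].
#' @param config a [sim_config()] (uses `read_depth`).
#' @param seed optional integer seed.
#' @return list with the noisy `F`, the read-count matrix `rc`
#'   (m x r) and `n_fallback`.
#' @export
add_read_noise <- function(F_true, panel, config, seed = NULL) {
  with_sim_seed(seed, {
    m <- nrow(F_true)
    r <- panel$r
    nv <- panel$l + panel$g
    depth <- config$read_depth
    rc <- matrix(stats::rpois(m * r, depth), m, r)
    vaf <- compute_vaf(F_true, panel)
    psi <- mixed_segment_copy(F_true, panel)
    seg_of <- variant_segment(panel)

    FF <- F_true
    n_fallback <- sum(rc == 0)
    for (p in seq_len(m)) {
      for (b in seq_len(nv)) {
        n_reads <- rc[p, seg_of[b]]
        if (n_reads == 0) next
        prob <- min(max(vaf[p, b], 0), 1)
        alt <- stats::rbinom(1, n_reads, prob)
        FF[p, b] <- alt / n_reads * psi[p, b]
      }
      for (s in seq_len(r)) {
        n_reads <- rc[p, s]
        if (n_reads == 0) next
        a1 <- F_true[p, panel$l + panel$g + s]
        a2 <- F_true[p, panel$l + panel$g + r + s]
        tot <- a1 + a2
        if (tot <= 0) next
        baf <- a2 / tot
        bcount <- stats::rbinom(1, n_reads, baf)
        FF[p, panel$l + panel$g + r + s] <- bcount / n_reads * tot
        FF[p, panel$l + panel$g + s] <- tot - bcount / n_reads * tot
      }
    }
    list(F = FF, rc = rc, n_fallback = n_fallback)
  })
}

#' Simulate a complete cohort with ground truth
#'
#' Runs the full generative protocol: random tree, SV/SNV events, clone
#' profile realization, uniform clonal mixing, canonical allele ordering
#' (decided on the noiseless mixture, applied consistently to truth and
#' noisy data) and read-count noise.
#'
#' @param config a [sim_config()].
#' @param leaf_only draw frequencies on leaves + root only.
#' @param noisy add read-count noise (else the bulk equals the noiseless
#'   mixture).
#' @param seed optional integer seed.
#' @return list with `panel`, `tree` (with true `W`, `rho`), `profiles`
#'   (true `C`, `D`), `U` (true frequencies), `F_true` (noiseless `U C`),
#'   `bulk` (a `bulk_obs`, noisy when requested), `events`, `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_leaves = 2, m_samples = 2, sv_rate_total = 3,
#'                   snv_count_param = 4, sv_length_mean = 5e5)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' cohort$panel
#' }
#' @export
simulate_cohort <- function(config, leaf_only = FALSE, noisy = TRUE,
                            seed = NULL) {
  with_sim_seed(seed, {
    tree <- simulate_tree(config$n_leaves)
    events <- simulate_events(tree, config)
    truth <- realize_profiles(tree, events, config)
    panel <- truth$panel
    mix <- simulate_mixture(truth$profiles, config$m_samples,
                            leaf_only = leaf_only,
                            n_leaves = config$n_leaves)

    # canonical allele order, decided on the noiseless mixture
    swap <- logical(panel$r)
    for (s in seq_len(panel$r)) {
      c1 <- panel$l + panel$g + s
      c2 <- panel$l + panel$g + panel$r + s
      votes_swap <- sum(mix$F[, c2] > mix$F[, c1])
      votes_keep <- sum(mix$F[, c1] > mix$F[, c2])
      swap[s] <- votes_swap > votes_keep
    }
    profiles <- truth$profiles
    F_true <- mix$F
    seg_of <- variant_segment(panel)
    for (s in which(swap)) {
      c1 <- panel$l + panel$g + s
      c2 <- panel$l + panel$g + panel$r + s
      tmp <- profiles$C[, c1]
      profiles$C[, c1] <- profiles$C[, c2]
      profiles$C[, c2] <- tmp
      tmp <- F_true[, c1]
      F_true[, c1] <- F_true[, c2]
      F_true[, c2] <- tmp
      flip <- which(seg_of == s)
      profiles$D[flip] <- 1L - profiles$D[flip]
    }

    F_obs <- F_true
    noise <- NULL
    if (noisy) {
      noise <- add_read_noise(F_true, panel, config)
      F_obs <- noise$F
    }
    bulk <- new_bulk_obs(F_obs, panel)

    list(panel = panel, tree = truth$tree, profiles = profiles,
         U = mix$U, F_true = F_true, bulk = bulk, events = events,
         noise = noise, n_capped = truth$n_capped, config = config)
  })
}

#' Construct a bulk_obs without re-voting allele order
#' @noRd
new_bulk_obs <- function(F, panel, samples = NULL) {
  if (!is.null(samples)) rownames(F) <- samples
  colnames(F) <- layout_colnames(panel)
  psi <- mixed_segment_copy(F, panel)
  vaf_raw <- compute_vaf(F, panel)
  structure(
    list(m = nrow(F), F = F, psi = psi,
         vaf = pmin(pmax(vaf_raw, 0), 1),
         swapped = logical(panel$r),
         n_clamped = sum(vaf_raw > 1),
         n_zero_psi = sum(psi == 0),
         samples = rownames(F)),
    class = "bulk_obs"
  )
}
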