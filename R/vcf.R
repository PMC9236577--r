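#' @title VCF cohort input/output
#'
#' @description
#' One single-sample VCF 4.2 file per bulk sample, all sharing one variant
#' universe. The dialect carries mean copy numbers in FORMAT fields:
#'
#' * SV breakpoints: `SVTYPE=BND` records with bracketed ALT and `MATEID`;
#'   FORMAT field `BPCN` holds the mean adjacency (junction) copy number.
#'   A breakpoint facing right is written `N[chrom:pos[`, facing left
#'   `]chrom:pos]N`, with the mate's coordinates inside the brackets.
#' * SNVs: ordinary SNV records with FORMAT field `SCN` (mean variant copy
#'   number). `VAF` is accepted on input as an alternative and converted
#'   using the sample's CNA records.
#' * CNAs: `SVTYPE=CNV` records with `END` in INFO and FORMAT fields
#'   `CN1`/`CN2` (allele-specific mean segment copy numbers).
#'
#' @name vcf-io
NULL

#' Write a cohort of single-sample VCFs
#'
#' @param panel a [variant_panel].
#' @param F bulk matrix (rows = samples) or `bulk_obs`.
#' @param dir output directory (created if needed).
#' @param samples sample names; default `sample_1..m` or bulk row names.
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(panel, F, dir, samples = NULL) {
  if (inherits(F, "bulk_obs")) {
    samples <- samples %||% F$samples
    F <- F$F
  }
  m <- nrow(F)
  samples <- samples %||% rownames(F) %||% paste0("sample_", seq_len(m))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  chrom_len <- panel$segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop")
  vr <- panel$variants
  paths <- character(m)
  for (p in seq_len(m)) {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=clonedecomp",
      paste0("##contig=<ID=", chrom_len$chrom, ",length=",
             format(chrom_len$len, scientific = FALSE), ">"),
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakpoint\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Segment end\">",
      "##FORMAT=<ID=BPCN,Number=1,Type=Float,Description=\"Mean breakpoint copy number\">",
      "##FORMAT=<ID=SCN,Number=1,Type=Float,Description=\"Mean SNV copy number\">",
      "##FORMAT=<ID=CN1,Number=1,Type=Float,Description=\"Mean allele 1 segment copy number\">",
      "##FORMAT=<ID=CN2,Number=1,Type=Float,Description=\"Mean allele 2 segment copy number\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
             samples[p])
    )
    body <- character()
    if (panel$l > 0) {
      for (b in seq_len(panel$l)) {
        mate <- vr[vr$id == vr$mate_id[b], ]
        alt <- if (vr$direction[b] == "right") {
          paste0("N[", mate$chrom, ":", format(mate$pos, scientific = FALSE),
                 "[")
        } else {
          paste0("]", mate$chrom, ":", format(mate$pos, scientific = FALSE),
                 "]N")
        }
        body <- c(body, paste(
          vr$chrom[b], format(vr$pos[b], scientific = FALSE), vr$id[b],
          "N", alt, ".", "PASS",
          paste0("SVTYPE=BND;MATEID=", vr$mate_id[b]),
          "BPCN", format(F[p, b], digits = 10), sep = "\t"))
      }
    }
    if (panel$g > 0) {
      for (j in seq_len(panel$g)) {
        b <- panel$l + j
        body <- c(body, paste(
          vr$chrom[b], format(vr$pos[b], scientific = FALSE), vr$id[b],
          "N", "A", ".", "PASS", ".", "SCN",
          format(F[p, b], digits = 10), sep = "\t"))
      }
    }
    for (s in seq_len(panel$r)) {
      body <- c(body, paste(
        panel$segments$chrom[s],
        format(panel$segments$start[s], scientific = FALSE),
        panel$segments$id[s], "N", "<CNV>", ".", "PASS",
        paste0("SVTYPE=CNV;END=",
               format(panel$segments$end[s], scientific = FALSE)),
        "CN1:CN2",
        paste0(format(F[p, panel$l + panel$g + s], digits = 10), ":",
               format(F[p, panel$l + panel$g + panel$r + s], digits = 10)),
        sep = "\t"))
    }
    paths[p] <- file.path(dir, paste0(samples[p], ".vcf"))
    writeLines(c(lines, body), paths[p])
  }
  invisible(paths)
}

#' Parse one sample VCF of the cohort dialect
#' @noRd
read_sample_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- as.data.frame(v@gt, stringsAsFactors = FALSE)
  if (ncol(gt) != 2) stop("expected a single-sample VCF: ", path)
  sample_id <- colnames(gt)[2]
  info_get <- function(info, key) {
    hit <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"),
                                    info))
    vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_,
           character(1))
  }
  fmt_get <- function(fmt, val, key) {
    ks <- strsplit(fmt, ":", fixed = TRUE)
    vs <- strsplit(val, ":", fixed = TRUE)
    mapply(function(k, x) {
      i <- match(key, k)
      if (is.na(i) || i > length(x)) NA_character_ else x[i]
    }, ks, vs)
  }
  svtype <- info_get(fix$INFO, "SVTYPE")
  is_bnd <- !is.na(svtype) & svtype == "BND"
  is_cnv <- !is.na(svtype) & svtype == "CNV"
  is_snv <- !is_bnd & !is_cnv

  bp <- NULL
  if (any(is_bnd)) {
    alt <- fix$ALT[is_bnd]
    direction <- ifelse(grepl("^[^]\\[]*\\[", alt), "right", "left")
    bp <- tibble::tibble(
      id = fix$ID[is_bnd], chrom = fix$CHROM[is_bnd],
      pos = as.numeric(fix$POS[is_bnd]), direction = direction,
      mate_id = info_get(fix$INFO[is_bnd], "MATEID"),
      bpcn = as.numeric(fmt_get(gt[is_bnd, 1], gt[is_bnd, 2], "BPCN")))
    if (anyNA(bp$mate_id)) {
      stop("BND record without MATEID in ", path)
    }
  }
  snv <- NULL
  if (any(is_snv)) {
    scn <- as.numeric(fmt_get(gt[is_snv, 1], gt[is_snv, 2], "SCN"))
    vafv <- as.numeric(fmt_get(gt[is_snv, 1], gt[is_snv, 2], "VAF"))
    snv <- tibble::tibble(
      id = fix$ID[is_snv], chrom = fix$CHROM[is_snv],
      pos = as.numeric(fix$POS[is_snv]), scn = scn, vaf = vafv)
  }
  cna <- NULL
  if (any(is_cnv)) {
    cna <- tibble::tibble(
      id = fix$ID[is_cnv], chrom = fix$CHROM[is_cnv],
      start = as.numeric(fix$POS[is_cnv]),
      end = as.numeric(info_get(fix$INFO[is_cnv], "END")),
      cn1 = as.numeric(fmt_get(gt[is_cnv, 1], gt[is_cnv, 2], "CN1")),
      cn2 = as.numeric(fmt_get(gt[is_cnv, 1], gt[is_cnv, 2], "CN2")))
  }
  if (is.null(cna)) stop("no CNV records in ", path)
  list(sample = sample_id, bp = bp, snv = snv, cna = cna)
}

#' Read a cohort of single-sample VCFs into a panel and bulk observation
#'
#' All samples must share one variant universe (identical breakpoints and
#' SNVs); CNA segment boundaries are unioned across samples and every
#' sample's copy numbers re-segmented onto the shared boundaries, so every
#' input CNA record is a union of output segments.
#'
#' @param paths character vector of VCF paths, or a single directory (all
#'   `*.vcf` files, sorted by name).
#' @return list with `panel` (a [variant_panel]), `bulk` (a `bulk_obs`
#'   with allele ordering applied) and `F_raw` (the matrix before allele
#'   ordering), rows in input sample order.
#' @export
read_cohort <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.vcf$", full.names = TRUE))
  }
  if (!length(paths)) stop("no VCF files found")
  calls <- lapply(paths, read_sample_vcf)

  key_bp <- function(x) {
    if (is.null(x$bp)) return(character())
    sort(paste(x$bp$id, x$bp$chrom, x$bp$pos, x$bp$direction, x$bp$mate_id))
  }
  key_snv <- function(x) {
    if (is.null(x$snv)) return(character())
    sort(paste(x$snv$id, x$snv$chrom, x$snv$pos))
  }
  for (i in seq_along(calls)[-1]) {
    if (!identical(key_bp(calls[[i]]), key_bp(calls[[1]])) ||
        !identical(key_snv(calls[[i]]), key_snv(calls[[1]]))) {
      stop("inconsistent variant universe between ", calls[[1]]$sample,
           " and ", calls[[i]]$sample)
    }
  }

  # shared segmentation: union of all CNA boundaries
  all_cna <- dplyr::bind_rows(lapply(calls, function(x) x$cna))
  segments <- all_cna |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(cut = sort(unique(c(.data$start, .data$end + 1)))) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(start = utils::head(.data$cut, -1),
                   end = utils::tail(.data$cut, -1) - 1)

  bp <- calls[[1]]$bp
  snv <- calls[[1]]$snv
  panel <- build_panel(
    if (is.null(bp)) NULL else bp[, c("id", "chrom", "pos", "direction",
                                      "mate_id")],
    if (is.null(snv)) NULL else snv[, c("id", "chrom", "pos")],
    segments)

  m <- length(calls)
  F_raw <- matrix(0, m, n_cols(panel))
  for (p in seq_len(m)) {
    x <- calls[[p]]
    if (panel$l > 0) {
      F_raw[p, seq_len(panel$l)] <-
        x$bp$bpcn[match(panel$variants$id[seq_len(panel$l)], x$bp$id)]
    }
    # per-sample segment copies mapped onto the shared segmentation
    cn1 <- rep(NA_real_, panel$r)
    cn2 <- rep(NA_real_, panel$r)
    for (k in seq_len(nrow(x$cna))) {
      hit <- which(panel$segments$chrom == x$cna$chrom[k] &
                     panel$segments$start >= x$cna$start[k] &
                     panel$segments$end <= x$cna$end[k])
      cn1[hit] <- x$cna$cn1[k]
      cn2[hit] <- x$cna$cn2[k]
    }
    if (anyNA(cn1) || anyNA(cn2)) {
      stop("sample ", x$sample, " does not cover all segments")
    }
    F_raw[p, cols_seg1(panel)] <- cn1
    F_raw[p, cols_seg2(panel)] <- cn2
    if (panel$g > 0) {
      ids <- panel$variants$id[panel$l + seq_len(panel$g)]
      hit <- match(ids, x$snv$id)
      scn <- x$snv$scn[hit]
      if (anyNA(scn)) {
        # convert VAF to mean copy number with the mixed segment copy
        vafv <- x$snv$vaf[hit]
        if (anyNA(vafv[is.na(scn)])) {
          stop("SNV records need SCN or VAF in sample ", x$sample)
        }
        seg <- variant_segment(panel)[panel$l + seq_len(panel$g)]
        psi <- cn1[seg] + cn2[seg]
        scn[is.na(scn)] <- (vafv * psi)[is.na(scn)]
      }
      F_raw[p, panel$l + seq_len(panel$g)] <- scn
    }
  }
  samples <- vapply(calls, function(x) x$sample, character(1))
  bulk <- order_alleles(F_raw, panel, samples = samples)
  list(panel = panel, bulk = bulk, F_raw = F_raw)
}

#' Drop segments that carry no breakpoint or SNV
#'
#' Reduces problem size before solving: segments without any variant inside
#' are removed, with the positional matrix `Q` and the allele columns of
#' `F` sliced consistently. The mixed segment copy of every retained
#' variant is unchanged.
#'
#' @param panel a [variant_panel].
#' @param F bulk matrix or `bulk_obs`.
#' @return list with the reduced `panel` and `bulk` (a `bulk_obs`).
#' @export
filter_segments_to_variant_bearing <- function(panel, F) {
  if (inherits(F, "bulk_obs")) F <- F$F
  keep <- which(colSums(panel$Q) > 0)
  if (length(keep) == 0) stop("no variant-bearing segments")
  new_panel <- panel
  new_panel$segments <- panel$segments[keep, , drop = FALSE]
  new_panel$Q <- panel$Q[, keep, drop = FALSE]
  new_panel$r <- length(keep)
  nv <- panel$l + panel$g
  cols <- c(seq_len(nv), nv + keep, nv + panel$r + keep)
  F_new <- F[, cols, drop = FALSE]
  list(panel = new_panel, bulk = new_bulk_obs(F_new, new_panel,
                                              samples = rownames(F)))
}

#' Write a solved clone decomposition to disk
#'
#' Writes `C.tsv` (clones x variant/segment columns), `U.tsv` (samples x
#' clones), `tree.dot` (edges labeled with branch length and introduced
#' variant count), `tree.newick`, and `assignment.tsv` when an assignment
#' of held-out variants is supplied. Output is deterministic for a fixed
#' input.
#'
#' @param fit a `clone_fit` (or list with `tree`, `profiles`, `U`).
#' @param dir output directory.
#' @param assignment optional tibble from [assign_unsampled()].
#' @return invisibly, the written paths.
#' @export
write_solution <- function(fit, dir, assignment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- fit$tree
  N <- tree$N
  clones <- paste0("clone_", seq_len(N))

  C <- fit$profiles$C
  cdf <- as.data.frame(C)
  names(cdf) <- colnames(C) %||% paste0("col_", seq_len(ncol(C)))
  cdf <- cbind(clone = clones, cdf)
  utils::write.table(cdf, file.path(dir, "C.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  U <- as.matrix(fit$U)
  udf <- as.data.frame(U)
  names(udf) <- clones
  udf <- cbind(sample = rownames(U) %||% paste0("sample_", seq_len(nrow(U))),
               udf)
  utils::write.table(udf, file.path(dir, "U.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  edges <- tree_edges(tree)
  intro <- if (!is.null(tree$W) && length(tree$W)) {
    apply(tree$W, c(1, 2), sum)
  } else matrix(0, N, N)
  rho <- tree$rho %||% matrix(0, N, N)
  dot <- c("digraph clones {",
           paste0("  ", clones, ";"),
           vapply(seq_len(nrow(edges)), function(e) {
             i <- edges[e, 1]; j <- edges[e, 2]
             paste0("  ", clones[i], " -> ", clones[j],
                    " [label=\"rho=", format(rho[i, j]), ",vars=",
                    intro[i, j], "\"];")
           }, character(1)),
           "}")
  writeLines(dot, file.path(dir, "tree.dot"))
  writeLines(tree_newick(tree), file.path(dir, "tree.newick"))

  if (!is.null(assignment)) {
    utils::write.table(assignment, file.path(dir, "assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file.path(dir, c("C.tsv", "U.tsv", "tree.dot", "tree.newick")))
}

#' Read matrices written by [write_solution()]
#'
#' @param dir directory holding `C.tsv` and `U.tsv`.
#' @return list with matrices `C` and `U`.
#' @export
read_solution <- function(dir) {
  cdf <- utils::read.table(file.path(dir, "C.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  C <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(C) <- cdf[[1]]
  udf <- utils::read.table(file.path(dir, "U.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  U <- as.matrix(udf[, -1, drop = FALSE])
  rownames(U) <- udf[[1]]
  list(C = C, U = U)
}
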