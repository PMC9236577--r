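#' Build the indexed variant universe
#'
#' Assembles breakpoints, SNVs and copy-number segments into a validated
#' `variant_panel`: the indexed universe of `l` breakpoints, `g` SNVs and `r`
#' segments, together with the positional matrix `Q` (`q[b, s] = 1` iff
#' variant `b` lies in segment `s`) and the breakpoint pairing matrix `G`
#' (`g[b1, b2] = 1` iff `b1` and `b2` are mate ends of one structural
#' variant).
#'
#' Column ordering is deterministic regardless of input record order:
#' breakpoints sort by (chromosome, position, direction), SNVs by
#' (chromosome, position), segments by (chromosome, start); chromosomes sort
#' lexicographically. Coordinates are 1-based inclusive.
#'
#' @param breakpoints tibble with columns `id`, `chrom`, `pos`, `direction`
#'   (`"left"` or `"right"`), `mate_id`. May be empty or `NULL`.
#' @param snvs tibble with columns `id`, `chrom`, `pos`. May be empty/`NULL`.
#' @param segments tibble with columns `chrom`, `start`, `end` and optional
#'   `id` (defaults to `chrom:start-end`).
#'
#' @return a `variant_panel`: list with counts `l`, `g`, `r`, matrices `Q`
#'   ((l+g) x r) and `G` (l x l), and tibbles `variants` (breakpoints first,
#'   then SNVs, in panel order) and `segments`.
#'
#' @examples
#' seg <- tibble::tibble(chrom = "chr1", start = c(1, 501), end = c(500, 1000))
#' bp <- tibble::tibble(id = c("b1", "b2"), chrom = "chr1", pos = c(100, 700),
#'                      direction = c("right", "left"), mate_id = c("b2", "b1"))
#' snv <- tibble::tibble(id = "s1", chrom = "chr1", pos = 250)
#' p <- build_panel(bp, snv, seg)
#' p$l; p$g; p$r
#' @export
build_panel <- function(breakpoints = NULL, snvs = NULL, segments) {
  empty_bp <- tibble::tibble(id = character(), chrom = character(),
                             pos = numeric(), direction = character(),
                             mate_id = character())
  empty_snv <- tibble::tibble(id = character(), chrom = character(),
                              pos = numeric())
  breakpoints <- if (is.null(breakpoints) || nrow(breakpoints) == 0) {
    empty_bp
  } else {
    tibble::as_tibble(breakpoints)
  }
  snvs <- if (is.null(snvs) || nrow(snvs) == 0) {
    empty_snv
  } else {
    tibble::as_tibble(snvs)
  }
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) stop("at least one segment is required")
  if (!"id" %in% names(segments)) {
    segments$id <- paste0(segments$chrom, ":", segments$start, "-",
                          segments$end)
  }

  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  overlap <- segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bad = .data$start <= dplyr::lag(.data$end,
                                                  default = -Inf)) |>
    dplyr::ungroup()
  if (any(overlap$bad)) {
    stop("segments overlap or are unsorted within a chromosome: ",
         paste(segments$id[overlap$bad], collapse = ", "))
  }
  if (any(segments$end < segments$start)) {
    stop("segment end precedes start")
  }

  if (nrow(breakpoints) > 0) {
    if (anyDuplicated(breakpoints$id)) stop("duplicate breakpoint ids")
    if (!all(breakpoints$direction %in% c("left", "right"))) {
      stop("breakpoint direction must be 'left' or 'right'")
    }
    mate_row <- match(breakpoints$mate_id, breakpoints$id)
    if (anyNA(mate_row)) {
      stop("unmatched mate id for breakpoint(s): ",
           paste(breakpoints$id[is.na(mate_row)], collapse = ", "))
    }
    if (any(breakpoints$id[mate_row[mate_row]] != breakpoints$id) ||
        any(mate_row == seq_len(nrow(breakpoints)))) {
      stop("breakpoint mate pairing is not a symmetric perfect matching")
    }
    breakpoints <- dplyr::arrange(breakpoints, .data$chrom, .data$pos,
                                  .data$direction, .data$id)
  }
  if (nrow(snvs) > 0) {
    if (anyDuplicated(snvs$id)) stop("duplicate SNV ids")
    snvs <- dplyr::arrange(snvs, .data$chrom, .data$pos, .data$id)
  }

  l <- nrow(breakpoints)
  g <- nrow(snvs)
  r <- nrow(segments)

  locate <- function(chrom, pos, what) {
    hit <- which(segments$chrom == chrom & segments$start <= pos &
                   segments$end >= pos)
    if (length(hit) != 1L) {
      stop("variant ", what, " at ", chrom, ":", pos,
           " does not fall inside exactly one segment")
    }
    hit
  }
  seg_of <- integer(l + g)
  if (l > 0) {
    seg_of[seq_len(l)] <- vapply(
      seq_len(l),
      function(i) locate(breakpoints$chrom[i], breakpoints$pos[i],
                         breakpoints$id[i]),
      integer(1)
    )
  }
  if (g > 0) {
    seg_of[l + seq_len(g)] <- vapply(
      seq_len(g),
      function(i) locate(snvs$chrom[i], snvs$pos[i], snvs$id[i]),
      integer(1)
    )
  }

  Q <- matrix(0L, nrow = l + g, ncol = r)
  if (l + g > 0) Q[cbind(seq_len(l + g), seg_of)] <- 1L
  G <- matrix(0L, nrow = l, ncol = l)
  if (l > 0) {
    mate_row <- match(breakpoints$mate_id, breakpoints$id)
    G[cbind(seq_len(l), mate_row)] <- 1L
  }

  variants <- dplyr::bind_rows(
    dplyr::mutate(breakpoints, type = "breakpoint"),
    dplyr::mutate(snvs, type = "snv", direction = NA_character_,
                  mate_id = NA_character_)
  )
  if (nrow(variants)) variants$segment <- segments$id[seg_of]

  structure(
    list(l = l, g = g, r = r, Q = Q, G = G,
         variants = variants, segments = segments),
    class = "variant_panel"
  )
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("<variant_panel> ", x$l, " breakpoints, ", x$g, " SNVs, ",
      x$r, " segments\n", sep = "")
  invisible(x)
}

#' @export
format.variant_panel <- function(x, ...) {
  paste0("variant_panel(l=", x$l, ", g=", x$g, ", r=", x$r, ")")
}
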