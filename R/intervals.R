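#' Intersect two feature tracks
#'
#' All pairs of intervals from `a` and `b` that overlap by at least one
#' base, under 0-based half-open semantics (adjacent intervals do not
#' overlap). Backed by IRanges.
#'
#' @param a,b Tibbles with columns `seq_id`, `start`, `end` (other columns
#'   carried through with prefixes `a_`/`b_`).
#' @return Tibble of overlapping pairs: `seq_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, plus carried columns.
#' @export
intersect_tracks <- function(a, b) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(a)),
            all(c("seq_id", "start", "end") %in% names(b)))
  common <- intersect(unique(a$seq_id), unique(b$seq_id))
  purrr::map_dfr(common, function(sid) {
    aa <- a[a$seq_id == sid, , drop = FALSE]
    bb <- b[b$seq_id == sid, , drop = FALSE]
    ov <- IRanges::findOverlaps(IRanges::IRanges(aa$start + 1L, aa$end),
                                IRanges::IRanges(bb$start + 1L, bb$end))
    if (length(ov) == 0) return(NULL)
    ai <- S4Vectors::queryHits(ov); bi <- S4Vectors::subjectHits(ov)
    out <- tibble::tibble(seq_id = sid,
                          a_start = aa$start[ai], a_end = aa$end[ai],
                          b_start = bb$start[bi], b_end = bb$end[bi])
    extra_a_cols <- setdiff(names(aa), c("seq_id", "start", "end"))
    for (cc in extra_a_cols) out[[paste0("a_", cc)]] <- aa[[cc]][ai]
    extra_b_cols <- setdiff(names(bb), c("seq_id", "start", "end"))
    for (cc in extra_b_cols) out[[paste0("b_", cc)]] <- bb[[cc]][bi]
    out
  })
}

#' Flag intervals of `a` that overlap anything in `b`
#'
#' @inheritParams intersect_tracks
#' @return `a` with a logical column `overlaps`.
#' @export
overlaps_any <- function(a, b) {
  a$overlaps <- FALSE
  for (sid in unique(a$seq_id)) {
    bb <- b[b$seq_id == sid, , drop = FALSE]
    if (nrow(bb) == 0) next
    ai <- which(a$seq_id == sid)
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(bb$start + 1L, bb$end))
    a$overlaps[ai] <- ov
  }
  a
}

#' Call heterozygous tandem repeats
#'
#' A repeat is heterozygous when at least one filtered heterozygous indel
#' overlaps it (the indel occupies its REF span). Run the variants through
#' `filter_variants(..., het_only = TRUE)` first.
#'
#' @param trs Tandem repeats ([detect_trs()] layout).
#' @param indels Filtered indel variants (tibble with `seq_id`, `pos`,
#'   `ref`).
#' @return One-row tibble: `n_trs`, `n_het`, `fraction`, `pct` (rounded to
#'   integer percent).
#' @export
het_tr_call <- function(trs, indels) {
  if (nrow(trs) == 0) stop("no tandem repeats; fraction undefined")
  itrack <- tibble::tibble(seq_id = indels$seq_id, start = indels$pos,
                           end = indels$pos + nchar(indels$ref))
  flagged <- overlaps_any(trs, itrack)
  n_het <- sum(flagged$overlaps)
  tibble::tibble(n_trs = nrow(trs), n_het = n_het,
                 fraction = n_het / nrow(trs),
                 pct = round(100 * n_het / nrow(trs)))
}

#' Promoter regions upstream of genes
#'
#' The `flank` bp immediately 5' of each gene's transcription start on the
#' gene's strand, clipped at sequence boundaries. Genes without a strand
#' are skipped with a message.
#'
#' @param genes Tibble with `seq_id`, `start`, `end` (0-based half-open)
#'   and `strand` (`+`/`-`).
#' @param x Assembly tibble (for sequence lengths).
#' @param flank Promoter length in bp (default 2000).
#' @return Feature-track tibble `seq_id`, `start`, `end` with
#'   `label = "promoter"`.
#' @export
promoter_regions <- function(genes, x, flank = 2000) {
  x <- as_assembly(x)
  lens <- stats::setNames(nchar(x$bases), x$seq_id)
  bad <- is.na(genes$strand) | !(genes$strand %in% c("+", "-"))
  if (any(bad)) {
    message(sum(bad), " gene(s) without strand skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  out <- dplyr::mutate(genes,
    p_start = ifelse(.data$strand == "+",
                     pmax(0L, .data$start - flank), .data$end),
    p_end = ifelse(.data$strand == "+", .data$start,
                   pmin(unname(lens[.data$seq_id]), .data$end + flank)))
  out <- out[out$p_end > out$p_start, , drop = FALSE]
  tibble::tibble(label = "promoter", seq_id = out$seq_id,
                 start = as.integer(out$p_start),
                 end = as.integer(out$p_end))
}

#' Read gene records from GFF3
#'
#' Extracts records of the requested type as a 0-based half-open tibble.
#' Uses rtracklayer when available, otherwise a plain nine-column read.
#'
#' @param path Path to a GFF3 file.
#' @param type Feature type to keep (default `"gene"`).
#' @export
read_gff_genes <- function(path, type = "gene") {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    g <- g[as.character(g$type) == type, , drop = FALSE]
    return(tibble::tibble(
      seq_id = as.character(g$seqnames),
      start = as.integer(g$start) - 1L,
      end = as.integer(g$end),
      strand = as.character(g$strand)))
  }
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- stringr::str_split_fixed(ln, "\t", 9)
  keep <- f[, 3] == type
  tibble::tibble(seq_id = f[keep, 1],
                 start = as.integer(f[keep, 4]) - 1L,
                 end = as.integer(f[keep, 5]),
                 strand = f[keep, 7])
}

#' Contig termini from alignments
#'
#' For each contig alignment with mapping quality at least `min_mapq`, a
#' primary (unique) location, and an unclipped contig end, emits a 1-bp
#' interval at the reference position of that terminal contig base.
#' Clipped ends emit nothing.
#'
#' @param aln Tibble with columns `contig`, `seq_id`, `t_start`, `t_end`
#'   (reference span, 0-based half-open), `strand`, `mapq`, `clip_left`,
#'   `clip_right` (clipped bp at the contig's own start/end) and optionally
#'   `primary` (logical; default TRUE).
#' @param min_mapq Minimum mapping quality (default 3).
#' @return Tibble: `seq_id`, `start`, `end` (1-bp), `contig`, `end_type`
#'   (`left`/`right` on the contig).
#' @export
contig_termini <- function(aln, min_mapq = 3) {
  if (!"primary" %in% names(aln)) aln$primary <- TRUE
  keep <- aln$mapq >= min_mapq & aln$primary
  aln <- aln[keep, , drop = FALSE]
  out <- list()
  emit <- function(sid, pos, contig, end_type) {
    tibble::tibble(seq_id = sid, start = as.integer(pos),
                   end = as.integer(pos + 1L), contig = contig,
                   end_type = end_type)
  }
  for (i in seq_len(nrow(aln))) {
    a <- aln[i, ]
    left_ref <- if (a$strand == "+") a$t_start else a$t_end - 1L
    right_ref <- if (a$strand == "+") a$t_end - 1L else a$t_start
    if (a$clip_left == 0)
      out[[length(out) + 1L]] <- emit(a$seq_id, left_ref, a$contig, "left")
    if (a$clip_right == 0)
      out[[length(out) + 1L]] <- emit(a$seq_id, right_ref, a$contig, "right")
  }
  if (length(out) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), contig = character(),
                          end_type = character()))
  }
  dplyr::bind_rows(out)
}

#' Attribute contig termini to annotation classes
#'
#' For each labeled feature track, the percent of termini overlapping it by
#' at least one base. Classes are not mutually exclusive; termini hitting
#' no track are reported as `no_annotation`.
#'
#' @param termini Output of [contig_termini()].
#' @param tracks Named list of feature-track tibbles (`seq_id`, `start`,
#'   `end`).
#' @return Tibble: `class`, `n_termini`, `pct`.
#' @export
attribute_termini <- function(termini, tracks) {
  if (nrow(termini) == 0) stop("no termini to attribute")
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  any_hit <- rep(FALSE, nrow(termini))
  rows <- purrr::imap_dfr(tracks, function(tr, label) {
    hit <- overlaps_any(termini, tr)$overlaps
    any_hit <<- any_hit | hit
    tibble::tibble(class = label, n_termini = sum(hit),
                   pct = 100 * sum(hit) / nrow(termini))
  })
  dplyr::bind_rows(rows, tibble::tibble(
    class = "no_annotation", n_termini = sum(!any_hit),
    pct = 100 * sum(!any_hit) / nrow(termini)))
}

#' Zero-coverage intervals from per-base depth
#'
#' Maximal runs of zero depth; positions absent from `depth` count as zero.
#'
#' @param depth Tibble `seq_id`, `pos` (0-based), `depth`.
#' @param x Assembly tibble (defines sequence universe and lengths).
#' @return Feature-track tibble `seq_id`, `start`, `end`.
#' @export
zero_coverage <- function(depth, x) {
  x <- as_assembly(x)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    sid <- x$seq_id[i]
    len <- nchar(x$bases[i])
    d <- depth[depth$seq_id == sid & depth$depth > 0, , drop = FALSE]
    covered <- logical(len)
    if (nrow(d) > 0) covered[d$pos + 1L] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    zero <- !r$values
    if (!any(zero)) return(NULL)
    tibble::tibble(seq_id = sid, start = as.integer(starts[zero]),
                   end = as.integer(ends[zero]))
  })
}

#' Read per-base depth from TSV
#'
#' Three columns `seq pos depth` with 1-based positions (samtools-depth
#' style), converted to 0-based.
#'
#' @param path Path to the TSV (no header).
#' @export
read_depth_tsv <- function(path) {
  d <- readr::read_tsv(path, col_names = c("seq_id", "pos", "depth"),
                       show_col_types = FALSE)
  d$pos <- as.integer(d$pos) - 1L
  d
}

#' Write a feature track as BED
#'
#' @param track Tibble `seq_id`, `start`, `end` (0-based half-open; BED
#'   native convention) and optionally a `name`-like fourth column.
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  cols <- c("seq_id", "start", "end")
  extra <- setdiff(names(track), cols)
  out <- track[, c(cols, extra), drop = FALSE]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file as a feature track
#' @param path Path to a BED file.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(seq_id = as.character(d[[1]]),
                        start = as.integer(d[[2]]),
                        end = as.integer(d[[3]]))
  if (ncol(d) >= 4) out$name <- as.character(d[[4]])
  out
}
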