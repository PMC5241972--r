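#' Load a linkage map from TSV
#'
#' Expects columns `marker_id`, `linkage_group`, `map_position`,
#' `flank_length` (marker id, chromosome-scale group, centimorgan-like
#' position, and the length in bp of the flanking sequence used to place
#' the marker on an assembly).
#'
#' @param path Path to a TSV file.
#' @return Tibble with the four columns, validated.
#' @export
load_linkage_map <- function(path) {
  mp <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          marker_id = readr::col_character(),
                          linkage_group = readr::col_character(),
                          map_position = readr::col_double(),
                          flank_length = readr::col_integer()))
  if (nrow(mp) == 0) stop("no markers in ", path)
  validate_linkage_map(mp)
}

validate_linkage_map <- function(mp) {
  req <- c("marker_id", "linkage_group", "map_position", "flank_length")
  if (!all(req %in% names(mp)))
    stop("linkage map must have columns: ", paste(req, collapse = ", "))
  dup <- unique(mp$marker_id[duplicated(mp$marker_id)])
  if (length(dup) > 0)
    stop("duplicate marker_id: ", paste(dup, collapse = ", "))
  if (any(is.na(mp$map_position)))
    stop("non-numeric map_position")
  tibble::as_tibble(mp)
}

#' Write a linkage map as TSV
#' @param map Linkage-map tibble.
#' @param path Output path.
#' @export
write_linkage_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Resolve candidate marker placements to one placement per marker
#'
#' Per marker, the single best-scoring hit is retained. A marker whose top
#' score is attained at more than one distinct location (different scaffold
#' or different position) is flagged ambiguous and carries no resolved
#' placement; such markers are excluded from all downstream use, mirroring
#' the exclusion of SNPs that mapped equally well to several linkage
#' groups. Markers of the map with no hit at all are dropped with a message.
#'
#' @param hits Tibble of candidate alignments: `marker_id`, `seq_id`,
#'   `start`, `end` (0-based half-open span of the aligned flank), `strand`,
#'   `score`.
#' @param map Linkage-map tibble (defines the marker universe).
#' @return Tibble `marker_id`, `seq_id`, `start`, `end`, `strand`, `score`,
#'   `ambiguous`; ambiguous markers have NA coordinates.
#' @export
resolve_placements <- function(hits, map) {
  stopifnot(all(c("marker_id", "seq_id", "start", "end", "score")
                %in% names(hits)))
  if (!"strand" %in% names(hits)) hits$strand <- "+"
  missing <- setdiff(map$marker_id, hits$marker_id)
  if (length(missing) > 0)
    message(length(missing), " marker(s) with zero hits dropped")
  hits <- hits[hits$marker_id %in% map$marker_id, , drop = FALSE]
  out <- purrr::map_dfr(split(hits, hits$marker_id), function(h) {
    top <- h[h$score == max(h$score), , drop = FALSE]
    loc <- unique(top[, c("seq_id", "start")])
    if (nrow(loc) > 1) {
      return(tibble::tibble(marker_id = h$marker_id[1],
                            seq_id = NA_character_, start = NA_integer_,
                            end = NA_integer_, strand = NA_character_,
                            score = max(h$score), ambiguous = TRUE))
    }
    top <- top[1, ]
    tibble::tibble(marker_id = top$marker_id, seq_id = top$seq_id,
                   start = as.integer(top$start), end = as.integer(top$end),
                   strand = top$strand, score = top$score, ambiguous = FALSE)
  })
  out[order(out$marker_id), , drop = FALSE]
}

#' Read marker placements from PAF or a placement TSV
#'
#' PAF records are interpreted with the marker flank as query; columns used
#' are query name, target name/start/end, strand and the residue-match count
#' as score. A plain TSV with columns `marker_id seq_id start end strand
#' score` is accepted too (detected from the header).
#'
#' @param path Path to a PAF file or placement TSV.
#' @return Tibble of candidate hits suitable for [resolve_placements()].
#' @export
read_placements <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (startsWith(first, "marker_id")) {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  paf <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble::tibble(marker_id = as.character(paf[[1]]),
                 seq_id = as.character(paf[[6]]),
                 start = as.integer(paf[[8]]),
                 end = as.integer(paf[[9]]),
                 strand = as.character(paf[[5]]),
                 score = as.numeric(paf[[10]]))
}

#' Find linkage conflicts
#'
#' A conflict is a sequence whose placed markers belong to more than one
#' linkage group — evidence of misassembly. Sequences with no placed marker
#' are absent from the report.
#'
#' @param placements Resolved placements ([resolve_placements()]).
#' @param map Linkage-map tibble.
#' @return Tibble `seq_id`, `n_markers`, `linkage_groups` (comma-joined),
#'   `n_groups`, `conflict`; the number of conflicting sequences is the
#'   `n_conflicts` attribute.
#' @export
find_conflicts <- function(placements, map) {
  pl <- placements[!placements$ambiguous & !is.na(placements$seq_id), ,
                   drop = FALSE]
  pl <- dplyr::inner_join(pl, map, by = "marker_id")
  rep <- pl |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      linkage_groups = paste(sort(unique(.data$linkage_group)),
                             collapse = ","),
      n_groups = dplyr::n_distinct(.data$linkage_group),
      .groups = "drop") |>
    dplyr::mutate(conflict = .data$n_groups > 1)
  attr(rep, "n_conflicts") <- sum(rep$conflict)
  rep
}

#' Split scaffolds that conflict with the linkage map
#'
#' Each maximal run of same-group markers along a conflicted scaffold
#' contributes a kept piece; the segment between the flank of the last
#' marker of one run and the flank of the first marker of the next run is
#' discarded (its true linkage assignment is unknown). For the classic
#' two-group conflict this yields three pieces: two kept and one discarded.
#' Pieces are named `<scaffold>.p1`, `.p2`, ... Interleaved groups (no
#' clean runs) are split at every transition with the same rule, with a
#' warning.
#'
#' @param x Assembly tibble.
#' @param placements Resolved placements on `x` ([resolve_placements()]).
#' @param map Linkage-map tibble.
#' @return List: `$assembly` (conflicted scaffolds replaced by pieces),
#'   `$placements` (remapped onto the pieces; markers in discarded middles
#'   dropped), `$discards` (log of discarded segments), `$pieces`
#'   (piece coordinate table: `seq_id`, `source_scaffold`, `src_start`,
#'   `src_end`).
#' @export
split_at_conflicts <- function(x, placements, map) {
  x <- as_assembly(x)
  conf <- find_conflicts(placements, map)
  conflicted <- conf$seq_id[conf$conflict]
  pl <- placements[!placements$ambiguous & !is.na(placements$seq_id), ,
                   drop = FALSE]
  pl <- dplyr::inner_join(pl, map, by = "marker_id")

  pieces <- list(); discards <- list()
  out_ids <- character(); out_bases <- character()
  new_placements <- placements[!(placements$seq_id %in% conflicted) |
                                 is.na(placements$seq_id), , drop = FALSE]

  for (i in seq_len(nrow(x))) {
    sid <- x$seq_id[i]
    if (!(sid %in% conflicted)) {
      out_ids <- c(out_ids, sid)
      out_bases <- c(out_bases, x$bases[i])
      next
    }
    mk <- pl[pl$seq_id == sid, , drop = FALSE]
    mk <- mk[order(mk$start), , drop = FALSE]
    runs <- rle(mk$linkage_group)
    if (length(runs$values) > dplyr::n_distinct(mk$linkage_group))
      warning("markers of scaffold ", sid,
              " interleave linkage groups; splitting at every transition")
    idx_end <- cumsum(runs$lengths)
    idx_start <- c(1L, utils::head(idx_end, -1) + 1L)
    len <- nchar(x$bases[i])
    n_runs <- length(runs$values)
    for (r in seq_len(n_runs)) {
      p_start <- if (r == 1) 0L else mk$start[idx_start[r]]
      p_end <- if (r == n_runs) len else mk$end[idx_end[r]]
      pname <- paste0(sid, ".p", r)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        seq_id = pname, source_scaffold = sid,
        src_start = as.integer(p_start), src_end = as.integer(p_end))
      out_ids <- c(out_ids, pname)
      out_bases <- c(out_bases,
                     substr(x$bases[i], p_start + 1L, p_end))
      if (r < n_runs) {
        d_start <- mk$end[idx_end[r]]
        d_end <- mk$start[idx_start[r + 1L]]
        discards[[length(discards) + 1L]] <- tibble::tibble(
          source_scaffold = sid, start = as.integer(d_start),
          end = as.integer(d_end))
      }
      # remap markers of this run onto the piece
      run_mk <- mk[idx_start[r]:idx_end[r], , drop = FALSE]
      moved <- placements[placements$marker_id %in% run_mk$marker_id, ,
                          drop = FALSE]
      moved$seq_id <- pname
      moved$start <- moved$start - as.integer(p_start)
      moved$end <- moved$end - as.integer(p_start)
      new_placements <- dplyr::bind_rows(new_placements, moved)
    }
  }
  pieces_df <- if (length(pieces)) dplyr::bind_rows(pieces) else {
    tibble::tibble(seq_id = character(), source_scaffold = character(),
                   src_start = integer(), src_end = integer())
  }
  discard_df <- if (length(discards)) dplyr::bind_rows(discards) else {
    tibble::tibble(source_scaffold = character(), start = integer(),
                   end = integer())
  }
  list(assembly = assembly(out_ids, out_bases,
                           name = attr(x, "assembly_name")),
       placements = new_placements, discards = discard_df,
       pieces = pieces_df)
}

#' Order and orient scaffolds into linkage groups
#'
#' Scaffolds carrying markers of a single linkage group are ordered within
#' that group by the median map position of their markers (ties: longer
#' scaffold first, then lexicographic id) and joined with a constant spacer
#' of Ns. Orientation is decided by a pairwise vote: every unordered pair
#' of markers with distinct map positions and distinct scaffold positions
#' votes "reverse" when scaffold order disagrees with map order; the
#' scaffold is reverse complemented only when strictly more than half of
#' the decidable pairs vote reverse. Single-marker scaffolds keep their
#' orientation. Markerless scaffolds are reported unplaced; scaffolds still
#' touching several groups are left unplaced with a warning.
#'
#' @param x Assembly tibble (run [split_at_conflicts()] first).
#' @param placements Resolved placements ([resolve_placements()]).
#' @param map Linkage-map tibble.
#' @param spacer_n Number of Ns between adjacent scaffolds (default 100).
#' @return Object of class `anchored_assembly`: `$assembly` (one sequence
#'   per linkage group), `$placement` (scaffold order table: `group`,
#'   `order`, `seq_id`, `start_in_group`, `orientation`), `$unplaced`
#'   (assembly tibble). [tidy()] returns the placement table.
#' @export
orient_and_order <- function(x, placements, map, spacer_n = 100) {
  x <- as_assembly(x)
  pl <- placements[!placements$ambiguous & !is.na(placements$seq_id), ,
                   drop = FALSE]
  pl <- dplyr::inner_join(pl, map, by = "marker_id")

  per_seq <- split(pl, pl$seq_id)
  assign <- purrr::map_dfr(per_seq, function(mk) {
    groups <- unique(mk$linkage_group)
    if (length(groups) > 1) {
      warning("scaffold ", mk$seq_id[1],
              " still touches several linkage groups; left unplaced")
      return(NULL)
    }
    votes <- 0L; decidable <- 0L
    if (nrow(mk) > 1) {
      cmb <- utils::combn(nrow(mk), 2)
      for (ci in seq_len(ncol(cmb))) {
        a <- cmb[1, ci]; b <- cmb[2, ci]
        if (mk$map_position[a] == mk$map_position[b]) next
        if (mk$start[a] == mk$start[b]) next
        decidable <- decidable + 1L
        if (sign(mk$start[a] - mk$start[b]) !=
              sign(mk$map_position[a] - mk$map_position[b]))
          votes <- votes + 1L
      }
    }
    tibble::tibble(seq_id = mk$seq_id[1], group = mk$linkage_group[1],
                   med_pos = stats::median(mk$map_position),
                   reverse = decidable > 0 && votes > decidable / 2)
  })

  placed_ids <- assign$seq_id
  unplaced <- x[!(x$seq_id %in% placed_ids), , drop = FALSE]
  lens <- stats::setNames(nchar(x$bases), x$seq_id)

  placement <- list(); out_ids <- character(); out_bases <- character()
  for (g in sort(unique(assign$group))) {
    ag <- assign[assign$group == g, , drop = FALSE]
    ag <- ag[order(ag$med_pos, -lens[ag$seq_id], ag$seq_id), , drop = FALSE]
    seqs <- character(nrow(ag)); pos <- 0L
    for (i in seq_len(nrow(ag))) {
      s <- x$bases[x$seq_id == ag$seq_id[i]]
      if (ag$reverse[i]) s <- reverse_complement(s)
      seqs[i] <- s
      placement[[length(placement) + 1L]] <- tibble::tibble(
        group = g, order = i, seq_id = ag$seq_id[i],
        start_in_group = pos,
        orientation = if (ag$reverse[i]) "-" else "+")
      pos <- pos + nchar(s) + spacer_n
    }
    out_ids <- c(out_ids, g)
    out_bases <- c(out_bases, paste(seqs, collapse = strrep("N", spacer_n)))
  }
  structure(list(
    assembly = assembly(out_ids, out_bases, name = "anchored"),
    placement = if (length(placement)) dplyr::bind_rows(placement) else
      tibble::tibble(group = character(), order = integer(),
                     seq_id = character(), start_in_group = integer(),
                     orientation = character()),
    unplaced = unplaced, spacer_n = spacer_n),
    class = "anchored_assembly")
}

#' @export
print.anchored_assembly <- function(x, ...) {
  cat("Anchored assembly:", nrow(x$assembly), "linkage group(s),",
      nrow(x$placement), "scaffold(s) placed,",
      nrow(x$unplaced), "unplaced\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anchored_assembly <- function(x, ...) x$placement

#' @exportS3Method generics::glance
glance.anchored_assembly <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$assembly),
                 n_placed = nrow(x$placement),
                 n_unplaced = nrow(x$unplaced),
                 total_bp = sum(nchar(x$assembly$bases)))
}

#' Write the scaffold placement table of an anchored assembly
#'
#' AGP-like TSV with columns `group order seq_id start_in_group orientation`.
#'
#' @param x An `anchored_assembly`.
#' @param path Output path.
#' @export
write_placement_tsv <- function(x, path) {
  readr::write_tsv(x$placement, path)
  invisible(path)
}
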