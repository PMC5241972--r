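# Draft-assembly fragmentation with full truth bookkeeping.
#
# The skeleton draft is scaffolded: breaks leave N-gaps, and a fraction of
# breaks separate scaffolds (junction candidates for the joining pass).
# Donor drafts are emitted as contig sets (one sequence per unbroken
# segment): the short-read-like donor breaks at repeat loci and randomly,
# the long-read-like donor breaks only at TE-like duplicates. Alignment
# blocks are emitted from truth coordinates: one block per skeleton gap
# (skeleton row carries the N-run, intact donors carry the true sequence)
# and a pair of blocks per scaffold junction for every donor contig that
# spans it.

GAP_FLANK <- 50L    # aligned flank on each side of a gap block
JUNCTION_FLANK <- 200L

break_points <- function(truth, config, chrom_i, long_read) {
  sid <- truth$genome$seq_id[chrom_i]
  L <- nchar(truth$genome$bases[chrom_i])
  br <- NULL
  if (long_read) {
    tes <- truth$tes[truth$tes$seq_id == sid, , drop = FALSE]
    if (nrow(tes) > 0) {
      pick <- stats::runif(nrow(tes)) < 0.5
      br <- tibble::tibble(b_start = tes$start[pick], b_end = tes$end[pick])
    }
  } else {
    trs <- truth$trs[truth$trs$seq_id == sid, , drop = FALSE]
    if (nrow(trs) > 0) {
      pick <- stats::runif(nrow(trs)) < config$break_at_tr_prob
      if (any(pick)) {
        e1 <- sample(0:10, sum(pick), replace = TRUE)
        e2 <- sample(0:10, sum(pick), replace = TRUE)
        br <- tibble::tibble(b_start = pmax(0L, trs$start[pick] - e1),
                             b_end = pmin(L, trs$end[pick] + e2))
      }
    }
    n_rand <- stats::rbinom(1, L, config$break_random_prob)
    if (n_rand > 0) {
      at <- sort(sample.int(L - 300L, n_rand))
      w <- sample(50:200, n_rand, replace = TRUE)
      br <- dplyr::bind_rows(br, tibble::tibble(b_start = at,
                                                b_end = at + w))
    }
  }
  if (is.null(br) || nrow(br) == 0) {
    return(tibble::tibble(b_start = integer(), b_end = integer()))
  }
  br <- br[order(br$b_start), , drop = FALSE]
  # enforce >= 1500 bp segments between breaks and at chromosome edges
  keep <- logical(nrow(br)); last_end <- 0L
  for (i in seq_len(nrow(br))) {
    if (br$b_start[i] - last_end >= 1500L &&
          L - br$b_end[i] >= 1500L) {
      keep[i] <- TRUE
      last_end <- br$b_end[i]
    }
  }
  br[keep, , drop = FALSE]
}

# Segment table for one chromosome of one draft: truth intervals between
# missing intervals, plus per-break type.
segment_chrom <- function(L, br, types) {
  seg_start <- c(0L, br$b_end)
  seg_end <- c(br$b_start, L)
  tibble::tibble(g_start = seg_start, g_end = seg_end,
                 break_after = c(types, NA)) # type of break following seg
}

#' Fragment a truth genome into draft assemblies with truth bookkeeping
#'
#' See [fixture_config()] for the fragmentation model. Returns the drafts,
#' truth alignment blocks, a linkage map with marker placement hits on the
#' skeleton draft (a random subset of skeleton scaffolds is
#' reverse-complemented so anchoring has orientation signal to recover),
#' and per-gap/per-junction truth tables.
#'
#' @param truth A [simulate_genome()] result.
#' @param config The same [fixture_config()].
#' @return Object of class `fixture_set`; see Details in the package
#'   vignette. Key members: `$drafts` (named list of assemblies, skeleton
#'   first), `$skeleton`, `$donor_priority`, `$maf`, `$map`, `$hits`,
#'   `$gaps`, `$junctions`, `$scaffold_truth`.
#' @export
fragment_assemblies <- function(truth, config) {
  set.seed(config$seed + 2L)
  n_chr <- nrow(truth$genome)
  chrom_ids <- truth$genome$seq_id
  chrom_len <- nchar(truth$genome$bases)
  n_asm <- config$n_assemblies
  draft_names <- c("draft_ilm",
                   if (n_asm > 2) paste0("draft_454",
                                         if (n_asm > 3) seq_len(n_asm - 2)
                                         else ""),
                   "draft_pb")
  skeleton <- draft_names[1]

  segmaps <- list()   # per draft: segment map with scaffold assignment
  drafts <- list()
  gap_rows <- list()
  junction_rows <- list()

  for (d in seq_along(draft_names)) {
    dn <- draft_names[d]
    long_read <- d == length(draft_names)
    is_skel <- d == 1L
    seg_all <- list(); seqs <- character(); ids <- character()
    for (ci in seq_len(n_chr)) {
      L <- chrom_len[ci]
      chrom_seq <- truth$genome$bases[ci]
      br <- break_points(truth, config, ci, long_read)
      types <- if (nrow(br) == 0) character(0) else if (is_skel) {
        ifelse(stats::runif(nrow(br)) < config$scaffold_break_prob,
               "scaffold", "gap")
      } else {
        rep("scaffold", nrow(br)) # donors are emitted as contigs
      }
      segs <- segment_chrom(L, br, types)
      # group segments into scaffolds
      scaf_no <- cumsum(c(1L, utils::head(segs$break_after == "scaffold",
                                          -1)))
      segs$scaf <- scaf_no
      for (sc in unique(scaf_no)) {
        ss <- segs[segs$scaf == sc, , drop = FALSE]
        sid <- paste0(dn, "_", chrom_ids[ci], "_s", sc)
        pieces <- character(); pos <- 0L
        for (j in seq_len(nrow(ss))) {
          seg_seq <- substr(chrom_seq, ss$g_start[j] + 1L, ss$g_end[j])
          seg_all[[length(seg_all) + 1L]] <- tibble::tibble(
            draft = dn, seq_id = sid, chrom = chrom_ids[ci],
            g_start = ss$g_start[j], g_end = ss$g_end[j],
            s_start = pos)
          pieces <- c(pieces, seg_seq)
          pos <- pos + (ss$g_end[j] - ss$g_start[j])
          if (j < nrow(ss)) {
            miss <- ss$g_start[j + 1L] - ss$g_end[j]
            g_len <- if (is.null(config$gap_len_range)) miss else
              sample(config$gap_len_range[1]:config$gap_len_range[2], 1)
            pieces <- c(pieces, strrep("N", g_len))
            if (is_skel) {
              gap_rows[[length(gap_rows) + 1L]] <- tibble::tibble(
                seq_id = sid, gap_start = pos, gap_end = pos + g_len,
                chrom = chrom_ids[ci], miss_start = ss$g_end[j],
                miss_end = ss$g_start[j + 1L])
            }
            pos <- pos + g_len
          } else if (is_skel && !is.na(ss$break_after[j]) &&
                       ss$break_after[j] == "scaffold") {
            junction_rows[[length(junction_rows) + 1L]] <- tibble::tibble(
              s1 = sid, s2 = paste0(dn, "_", chrom_ids[ci], "_s", sc + 1L),
              chrom = chrom_ids[ci], miss_start = ss$g_end[j],
              miss_end = NA_integer_) # filled below
          }
        }
        ids <- c(ids, sid)
        seqs <- c(seqs, paste(pieces, collapse = ""))
      }
    }
    segmaps[[dn]] <- dplyr::bind_rows(seg_all)
    drafts[[dn]] <- assembly(ids, seqs, name = dn)
  }

  # complete junction miss_end from the next scaffold's first segment
  junctions <- if (length(junction_rows)) {
    jr <- dplyr::bind_rows(junction_rows)
    sm <- segmaps[[skeleton]]
    first_seg <- sm |> dplyr::group_by(.data$seq_id) |>
      dplyr::slice_min(.data$s_start, n = 1) |> dplyr::ungroup()
    jr$miss_end <- first_seg$g_start[match(jr$s2, first_seg$seq_id)]
    jr
  } else {
    tibble::tibble(s1 = character(), s2 = character(), chrom = character(),
                   miss_start = integer(), miss_end = integer())
  }

  # donor coverage query: scaffold + local coords if one donor segment
  # covers [lo, hi) of a chromosome
  locate <- function(dn, chrom, lo, hi) {
    sm <- segmaps[[dn]]
    sm <- sm[sm$chrom == chrom & sm$g_start <= lo & sm$g_end >= hi, ,
             drop = FALSE]
    if (nrow(sm) == 0) return(NULL)
    s <- sm[1, ]
    list(seq_id = s$seq_id, start = s$s_start + (lo - s$g_start),
         end = s$s_start + (hi - s$g_start))
  }

  donor_names <- setdiff(draft_names, skeleton)
  skel_lens <- stats::setNames(nchar(drafts[[skeleton]]$bases),
                               drafts[[skeleton]]$seq_id)

  # ---- MAF emission -------------------------------------------------------
  maf_rows <- list(); blk <- -1L
  truth_seq <- stats::setNames(truth$genome$bases, chrom_ids)
  gaps <- if (length(gap_rows)) dplyr::bind_rows(gap_rows) else {
    tibble::tibble(seq_id = character(), gap_start = integer(),
                   gap_end = integer(), chrom = character(),
                   miss_start = integer(), miss_end = integer())
  }
  gaps$donors <- ""
  gaps$intact_long_read <- FALSE
  fk <- GAP_FLANK
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    tseq <- truth_seq[[g$chrom]]
    a <- g$miss_start; b <- g$miss_end
    g_len <- g$gap_end - g$gap_start
    miss <- b - a
    flankL <- substr(tseq, a - fk + 1L, a)
    flankR <- substr(tseq, b + 1L, b + fk)
    donors_here <- character()
    rows <- NULL
    for (dn in donor_names) {
      loc <- locate(dn, g$chrom, a - fk, b + fk)
      if (is.null(loc)) next
      donors_here <- c(donors_here, dn)
      mid <- substr(tseq, a + 1L, b)
      if (g_len > miss) mid <- paste0(mid, strrep("-", g_len - miss))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        assembly = dn, seq_id = loc$seq_id, start = loc$start,
        size = 2L * fk + miss, strand = "+",
        src_size = nchar(drafts[[dn]]$bases[
          drafts[[dn]]$seq_id == loc$seq_id]),
        text = paste0(flankL, mid, flankR)))
    }
    if (is.null(rows)) next # unclosable gap: no block emitted
    blk <- blk + 1L
    sk_mid <- strrep("N", g_len)
    if (miss > g_len) sk_mid <- paste0(sk_mid, strrep("-", miss - g_len))
    sk_row <- tibble::tibble(
      assembly = skeleton, seq_id = g$seq_id, start = g$gap_start - fk,
      size = 2L * fk + g_len, strand = "+",
      src_size = unname(skel_lens[g$seq_id]),
      text = paste0(flankL, sk_mid, flankR))
    rows <- dplyr::bind_rows(sk_row, rows)
    rows$block_id <- blk
    maf_rows[[length(maf_rows) + 1L]] <- rows
    gaps$donors[i] <- paste(donors_here, collapse = ",")
    gaps$intact_long_read[i] <- draft_names[n_asm] %in% donors_here
  }
  gaps$closable <- nzchar(gaps$donors)

  jk <- JUNCTION_FLANK
  junctions$donors <- ""
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    tseq <- truth_seq[[j$chrom]]
    a <- j$miss_start; b <- j$miss_end
    donors_here <- character()
    for (dn in donor_names) {
      loc <- locate(dn, j$chrom, a - jk, b + jk)
      if (is.null(loc)) next
      donors_here <- c(donors_here, dn)
      src <- nchar(drafts[[dn]]$bases[drafts[[dn]]$seq_id == loc$seq_id])
      # block 1: end of s1
      blk <- blk + 1L
      maf_rows[[length(maf_rows) + 1L]] <- tibble::tibble(
        block_id = blk,
        assembly = c(skeleton, dn),
        seq_id = c(j$s1, loc$seq_id),
        start = c(unname(skel_lens[j$s1]) - jk, loc$start),
        size = jk, strand = "+",
        src_size = c(unname(skel_lens[j$s1]), src),
        text = substr(tseq, a - jk + 1L, a))
      # block 2: start of s2
      blk <- blk + 1L
      maf_rows[[length(maf_rows) + 1L]] <- tibble::tibble(
        block_id = blk,
        assembly = c(skeleton, dn),
        seq_id = c(j$s2, loc$seq_id),
        start = c(0L, loc$start + (b - a) + jk),
        size = jk, strand = "+",
        src_size = c(unname(skel_lens[j$s2]), src),
        text = substr(tseq, b + 1L, b + jk))
    }
    junctions$donors[i] <- paste(donors_here, collapse = ",")
  }
  junctions$planted <- nzchar(junctions$donors)

  maf <- if (length(maf_rows)) add_fwd_coords(dplyr::bind_rows(maf_rows)) else
    tibble::tibble(block_id = integer(), assembly = character(),
                   seq_id = character(), start = integer(), size = integer(),
                   strand = character(), src_size = integer(),
                   text = character(), fwd_start = integer(),
                   fwd_end = integer())

  # ---- linkage map and marker hits on the skeleton draft ------------------
  fl <- config$flank_length
  mk <- list()
  for (ci in seq_len(n_chr)) {
    pos <- seq(floor(config$marker_spacing / 2),
               chrom_len[ci] - fl - 1L, by = config$marker_spacing)
    if (length(pos) == 0) next
    mk[[ci]] <- tibble::tibble(
      marker_id = sprintf("M_%s_%05d", chrom_ids[ci], seq_along(pos)),
      linkage_group = paste0("LG", ci),
      map_position = pos / 1e4,
      flank_length = fl, chrom = chrom_ids[ci], t_pos = as.integer(pos))
  }
  mk <- dplyr::bind_rows(mk)
  map <- mk[, c("marker_id", "linkage_group", "map_position",
                "flank_length")]

  hits <- purrr::map_dfr(seq_len(nrow(mk)), function(i) {
    loc <- locate(skeleton, mk$chrom[i], mk$t_pos[i], mk$t_pos[i] + fl)
    if (is.null(loc)) return(NULL)
    tibble::tibble(marker_id = mk$marker_id[i], seq_id = loc$seq_id,
                   start = loc$start, end = loc$end, strand = "+",
                   score = as.numeric(fl))
  })

  # ---- scaffold truth and orientation flips -------------------------------
  sm <- segmaps[[skeleton]]
  scaffold_truth <- sm |>
    dplyr::group_by(.data$seq_id, .data$chrom) |>
    dplyr::summarise(truth_start = min(.data$g_start), .groups = "drop") |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(true_order = rank(.data$truth_start)) |>
    dplyr::ungroup()
  n_mk <- table(hits$seq_id)
  distinct_pos <- vapply(split(hits$start, hits$seq_id),
                         function(s) length(unique(s)) > 1, logical(1))
  junction_adjacent <- unique(c(junctions$s1, junctions$s2))
  eligible <- scaffold_truth$seq_id[
    scaffold_truth$seq_id %in% names(n_mk)[n_mk >= 2] &
      scaffold_truth$seq_id %in% names(distinct_pos)[distinct_pos] &
      !(scaffold_truth$seq_id %in% junction_adjacent)]
  flipped <- eligible[stats::runif(length(eligible)) < 0.4]
  scaffold_truth$true_orientation <-
    ifelse(scaffold_truth$seq_id %in% flipped, "-", "+")

  if (length(flipped) > 0) {
    skel <- drafts[[skeleton]]
    for (sid in flipped) {
      ix <- which(skel$seq_id == sid)
      len <- nchar(skel$bases[ix])
      skel$bases[ix] <- reverse_complement(skel$bases[ix])
      # MAF rows: same start/text on the minus strand of the flipped seq
      mi <- which(maf$assembly == skeleton & maf$seq_id == sid)
      maf$strand[mi] <- "-"
      # placements: mirror coordinates
      hi <- which(hits$seq_id == sid)
      new_start <- len - hits$end[hi]
      hits$end[hi] <- len - hits$start[hi]
      hits$start[hi] <- new_start
      hits$strand[hi] <- "-"
      # gap truth: mirror coordinates
      gi <- which(gaps$seq_id == sid)
      new_gs <- len - gaps$gap_end[gi]
      gaps$gap_end[gi] <- len - gaps$gap_start[gi]
      gaps$gap_start[gi] <- new_gs
    }
    drafts[[skeleton]] <- skel
    maf <- add_fwd_coords(maf)
  }

  structure(list(
    drafts = drafts, skeleton = skeleton,
    donor_priority = rev(donor_names), # long-read-like donor first
    maf = maf, map = map, hits = hits,
    gaps = gaps, junctions = junctions,
    scaffold_truth = scaffold_truth,
    segment_maps = segmaps,
    truth = truth, config = config), class = "fixture_set")
}

#' Simulate a constant-depth track with zero-coverage holes
#'
#' @param truth A [simulate_genome()] result.
#' @param holes Tibble `seq_id`, `start`, `end` of zero-depth intervals.
#' @param depth Constant depth elsewhere (default 30).
#' @return Tibble `seq_id`, `pos` (0-based), `depth`.
#' @export
simulate_depth <- function(truth, holes, depth = 30) {
  purrr::map_dfr(seq_len(nrow(truth$genome)), function(i) {
    sid <- truth$genome$seq_id[i]
    L <- nchar(truth$genome$bases[i])
    d <- rep(depth, L)
    h <- holes[holes$seq_id == sid, , drop = FALSE]
    for (j in seq_len(nrow(h))) d[(h$start[j] + 1L):h$end[j]] <- 0L
    tibble::tibble(seq_id = sid, pos = seq_len(L) - 1L, depth = d)
  })
}

#' Write a fixture set to a directory
#'
#' Emits FASTA per draft (plus the truth genome), the truth MAF, the
#' linkage map and marker hit TSVs, and a JSON file with the truth tables.
#'
#' @param fx A [fragment_assemblies()] result.
#' @param dir Output directory (created if needed).
#' @export
write_fixture_set <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$truth$genome, file.path(dir, "truth_genome.fasta"))
  for (dn in names(fx$drafts))
    write_fasta(fx$drafts[[dn]], file.path(dir, paste0(dn, ".fasta")))
  write_maf(fx$maf, file.path(dir, "alignments.maf"))
  write_linkage_map(fx$map, file.path(dir, "linkage_map.tsv"))
  readr::write_tsv(fx$hits, file.path(dir, "marker_hits.tsv"))
  jsonlite::write_json(
    list(gaps = fx$gaps, junctions = fx$junctions,
         scaffold_truth = fx$scaffold_truth,
         trs = fx$truth$trs, tes = fx$truth$tes),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
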