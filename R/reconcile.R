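#' Reconciliation configuration
#'
#' @param skeleton Name of the assembly whose sequence order is followed.
#' @param donor_priority Character vector of assembly names tried first when
#'   choosing gap-filling sequence (the preferred donor first). Assemblies
#'   not listed rank after listed ones, alphabetically.
#' @param containment_identity_min Identity above which a fully contained
#'   sequence is removed (strict `>`; default 0.98).
#' @param containment_coverage_min Fraction of the contained sequence that
#'   must be covered (default 0.99; set 1 for strict full containment).
#' @param min_seq_len Sequences shorter than this are removed (default 1000).
#' @param terminal_window Window (bp) from a scaffold terminus within which a
#'   spanning alignment counts for a join (default 5000).
#' @return A list of class `reconcile_config`.
#' @export
reconcile_config <- function(skeleton, donor_priority = character(),
                             containment_identity_min = 0.98,
                             containment_coverage_min = 0.99,
                             min_seq_len = 1000, terminal_window = 5000) {
  stopifnot(is.character(skeleton), length(skeleton) == 1,
            containment_identity_min > 0, containment_identity_min <= 1)
  if (skeleton %in% donor_priority)
    stop("skeleton must not appear in donor_priority")
  if (anyDuplicated(donor_priority))
    stop("duplicate assembly in donor_priority")
  structure(list(skeleton = skeleton, donor_priority = donor_priority,
                 containment_identity_min = containment_identity_min,
                 containment_coverage_min = containment_coverage_min,
                 min_seq_len = min_seq_len,
                 terminal_window = terminal_window),
            class = "reconcile_config")
}

#' Remove sequences fully contained in another sequence
#'
#' A sequence is removed when a self-alignment shows it covered over at
#' least `containment_coverage_min` of its length inside a *different*
#' sequence at identity strictly greater than `containment_identity_min`.
#' Shorter sequences are processed first, so a container is never examined
#' after being used.
#'
#' @param x Assembly tibble.
#' @param self_aln Pairwise self-alignments: tibble with columns `refid`,
#'   `qid`, `rstart`, `rend`, `qstart`, `qend`, `identity` (0-based
#'   half-open; identity as a proportion, or percent if > 1.5).
#' @param identity_min,coverage_min See [reconcile_config()].
#' @return List with `$assembly` (filtered) and `$removed` (tibble of
#'   removed seq_ids and their containers).
#' @export
remove_contained <- function(x, self_aln, identity_min = 0.98,
                             coverage_min = 0.99) {
  x <- as_assembly(x)
  if (nrow(self_aln) == 0) {
    return(list(assembly = x,
                removed = tibble::tibble(seq_id = character(),
                                         container = character())))
  }
  unknown <- setdiff(unique(c(self_aln$refid, self_aln$qid)), x$seq_id)
  if (length(unknown) > 0)
    stop("self-alignment references unknown seq_id: ",
         paste(unknown, collapse = ", "))
  ident <- self_aln$identity
  if (any(ident > 1.5)) ident <- ident / 100
  lens <- stats::setNames(nchar(x$bases), x$seq_id)
  removed <- character()
  containers <- character()
  for (b in x$seq_id[order(lens[x$seq_id])]) {
    hits <- self_aln[self_aln$qid == b & self_aln$refid != b &
                       ident > identity_min &
                       (self_aln$qend - self_aln$qstart) >=
                         coverage_min * lens[[b]], , drop = FALSE]
    hits <- hits[!(hits$refid %in% removed), , drop = FALSE]
    if (nrow(hits) > 0) {
      removed <- c(removed, b)
      containers <- c(containers, hits$refid[1])
    }
  }
  list(assembly = x[!(x$seq_id %in% removed), , drop = FALSE],
       removed = tibble::tibble(seq_id = removed, container = containers))
}

#' Remove sequences shorter than a threshold
#'
#' @param x Assembly tibble.
#' @param min_len Minimum retained length in bp (strictly shorter sequences
#'   are removed; default 1000).
#' @return List with `$assembly` and `$removed` (tibble of seq_id, length).
#' @export
drop_short <- function(x, min_len = 1000) {
  x <- as_assembly(x)
  short <- nchar(x$bases) < min_len
  list(assembly = x[!short, , drop = FALSE],
       removed = tibble::tibble(seq_id = x$seq_id[short],
                                length = nchar(x$bases[short])))
}

# Map a skeleton-forward base interval to alignment columns of a block row.
# text: gapped text of the (normalized, '+') skeleton row. Returns the
# column index (1-based) of each base fwd_start..fwd_end-1.
base_columns <- function(text, row_fwd_start, lo, hi) {
  chars <- strsplit(text, "")[[1]]
  base_cols <- which(chars != "-")
  idx <- (lo - row_fwd_start + 1L):(hi - row_fwd_start)
  base_cols[idx]
}

#' Close skeleton gaps from donor assemblies
#'
#' First reconciliation pass: for every N-run of the skeleton that lies
#' wholly inside one alignment block (with at least one aligned skeleton
#' base on each side), the aligned donor sequence opposite the gap columns
#' replaces the gap. The donor is the first assembly in `donor_priority`
#' offering an N-free filling, otherwise the candidate with the fewest Ns
#' (ties: higher priority rank, longer filling, lexicographic assembly
#' name). A filling with fewer Ns than the gap, but more than zero, shrinks
#' the gap instead of closing it.
#'
#' @param skeleton Assembly tibble of the skeleton assembly.
#' @param maf Alignment blocks ([parse_maf()] layout).
#' @param config A [reconcile_config()].
#' @return List: `$assembly` (gap-filled), `$events` (one row per gap
#'   examined), `$offsets` (per-sequence coordinate deltas introduced by
#'   fillings, for downstream remapping).
#' @export
close_gaps <- function(skeleton, maf, config) {
  skeleton <- as_assembly(skeleton)
  gaps <- find_gaps(skeleton)
  events <- list()
  repl <- list() # per seq: list of (start, end, filling)
  offsets <- list()

  sk_rows <- maf[maf$assembly == config$skeleton, , drop = FALSE]
  for (gi in seq_len(nrow(gaps))) {
    g <- gaps[gi, ]
    cand_blocks <- sk_rows[sk_rows$seq_id == g$seq_id &
                             sk_rows$fwd_start <= g$start - 1L &
                             sk_rows$fwd_end >= g$end + 1L, , drop = FALSE]
    cand_blocks <- cand_blocks[order(cand_blocks$fwd_start), , drop = FALSE]
    done <- FALSE
    for (bi in seq_len(nrow(cand_blocks))) {
      if (done) {
        events[[length(events) + 1L]] <- gap_event(g, "block_skipped")
        next
      }
      block <- normalize_block(
        maf[maf$block_id == cand_blocks$block_id[bi], , drop = FALSE],
        config$skeleton)
      ski <- which(block$assembly == config$skeleton &
                     block$seq_id == g$seq_id)[1]
      skrow <- block[ski, ]
      cols <- base_columns(skrow$text, skrow$fwd_start, g$start, g$end)
      chars <- strsplit(skrow$text, "")[[1]]
      # expand to the maximal run of N/'-' columns containing the gap
      lo <- cols[1]; hi <- cols[length(cols)]
      while (lo > 1 && chars[lo - 1] %in% c("N", "n", "-")) lo <- lo - 1
      while (hi < length(chars) && chars[hi + 1] %in% c("N", "n", "-"))
        hi <- hi + 1
      if (lo == 1 || hi == length(chars)) next # no anchored flank
      donors <- block[-ski, , drop = FALSE]
      donors <- donors[donors$assembly != config$skeleton, , drop = FALSE]
      if (nrow(donors) == 0) next
      fill <- gsub("-", "", substring(donors$text, lo, hi), fixed = TRUE)
      nN <- stringr::str_count(fill, "[Nn]")
      ok <- nchar(fill) > 0
      if (!any(ok)) next
      donors <- donors[ok, , drop = FALSE]
      fill <- fill[ok]; nN <- nN[ok]
      rank <- match(donors$assembly, config$donor_priority)
      rank[is.na(rank)] <- length(config$donor_priority) + 1L
      pick <- order(nN > 0, rank, -nchar(fill), donors$assembly)[1]
      gap_len <- g$end - g$start
      gap_n <- gap_len # a gap is all Ns by construction
      if (nN[pick] == 0) {
        type <- "gap_closed"
      } else if (nN[pick] < gap_n) {
        type <- "gap_shrunk"
      } else {
        events[[length(events) + 1L]] <- gap_event(g, "gap_unfilled")
        done <- TRUE
        next
      }
      # replace skeleton bases corresponding to columns [lo,hi]: these are
      # the gap bases plus any adjacent '-' columns (no extra bases)
      repl[[g$seq_id]] <- c(repl[[g$seq_id]],
                            list(list(start = g$start, end = g$end,
                                      filling = fill[pick])))
      events[[length(events) + 1L]] <- tibble::tibble(
        type = type, seq_id = g$seq_id, gap_start = g$start,
        gap_end = g$end, donor_assembly = donors$assembly[pick],
        donor_seq = donors$seq_id[pick],
        filling_len = nchar(fill[pick]), filling_n = nN[pick])
      offsets[[g$seq_id]] <- dplyr::bind_rows(
        offsets[[g$seq_id]],
        tibble::tibble(pos = g$end,
                       delta = nchar(fill[pick]) - gap_len))
      done <- TRUE
    }
    if (!done && nrow(cand_blocks) == 0) {
      events[[length(events) + 1L]] <- gap_event(g, "gap_unspanned")
    }
  }

  out <- skeleton
  for (sid in names(repl)) {
    i <- which(out$seq_id == sid)
    s <- out$bases[i]
    rs <- repl[[sid]]
    ord <- order(vapply(rs, function(r) r$start, numeric(1)),
                 decreasing = TRUE)
    for (r in rs[ord]) {
      s <- paste0(substr(s, 1, r$start), r$filling,
                  substr(s, r$end + 1, nchar(s)))
    }
    out$bases[i] <- s
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else empty_events()
  off <- if (length(offsets)) {
    dplyr::bind_rows(purrr::imap(offsets, ~dplyr::mutate(.x, seq_id = .y)))
  } else {
    tibble::tibble(seq_id = character(), pos = integer(), delta = integer())
  }
  list(assembly = out, events = ev, offsets = off)
}

gap_event <- function(g, type) {
  tibble::tibble(type = type, seq_id = g$seq_id, gap_start = g$start,
                 gap_end = g$end, donor_assembly = NA_character_,
                 donor_seq = NA_character_, filling_len = NA_integer_,
                 filling_n = NA_integer_)
}

empty_events <- function() {
  tibble::tibble(type = character(), seq_id = character(),
                 gap_start = integer(), gap_end = integer(),
                 donor_assembly = character(), donor_seq = character(),
                 filling_len = integer(), filling_n = integer())
}

# Shift MAF skeleton-row coordinates through the close_gaps offset ledger.
# Rows of the skeleton that straddle a modified gap are dropped.
remap_maf_offsets <- function(maf, offsets, skeleton) {
  if (nrow(offsets) == 0) return(maf)
  keep <- rep(TRUE, nrow(maf))
  for (i in seq_len(nrow(maf))) {
    if (maf$assembly[i] != skeleton) next
    off <- offsets[offsets$seq_id == maf$seq_id[i], , drop = FALSE]
    if (nrow(off) == 0) next
    straddle <- any(off$delta != 0 & off$pos > maf$fwd_start[i] &
                      off$pos <= maf$fwd_end[i])
    if (straddle) { keep[i] <- FALSE; next }
    d <- sum(off$delta[off$pos <= maf$fwd_start[i]])
    maf$fwd_start[i] <- maf$fwd_start[i] + d
    maf$fwd_end[i] <- maf$fwd_end[i] + d
    maf$src_size[i] <- maf$src_size[i] +
      sum(off$delta)
    maf$start[i] <- ifelse(maf$strand[i] == "+", maf$fwd_start[i],
                           maf$src_size[i] - maf$fwd_end[i])
  }
  maf[keep, , drop = FALSE]
}

#' Join skeleton scaffolds using spanning donor scaffolds
#'
#' Second reconciliation pass: two skeleton scaffolds are joined when one
#' donor scaffold aligns near the end of the first and near the start of
#' the second (within `terminal_window`), in consistent orientation and
#' order; the donor's intervening sequence fills the junction. If linkage
#' placements are supplied, joins uniting scaffolds carrying markers of
#' different linkage groups are refused. Each scaffold participates in at
#' most one join per end; circular proposals are refused.
#'
#' @param skeleton Assembly tibble (after [close_gaps()]).
#' @param maf Alignment blocks, coordinates valid for `skeleton`.
#' @param config A [reconcile_config()].
#' @param placements,map Optional resolved marker placements and linkage
#'   map used as a guard against uniting different linkage groups.
#' @return List: `$assembly`, `$events`.
#' @export
join_scaffolds <- function(skeleton, maf, config, placements = NULL,
                           map = NULL) {
  skeleton <- as_assembly(skeleton)
  lens <- stats::setNames(nchar(skeleton$bases), skeleton$seq_id)
  events <- list()
  tw <- config$terminal_window

  seq_groups <- NULL
  if (!is.null(placements) && !is.null(map)) {
    pl <- placements[!placements$ambiguous & !is.na(placements$start), ,
                     drop = FALSE]
    pl <- dplyr::inner_join(pl, map, by = "marker_id")
    seq_groups <- lapply(split(pl$linkage_group, pl$seq_id), unique)
  }

  # candidate junctions from donor scaffolds with blocks on two skeleton seqs
  donor_rows <- maf[maf$assembly != config$skeleton, , drop = FALSE]
  donor_keys <- unique(donor_rows[, c("assembly", "seq_id")])
  proposals <- list()
  for (d in seq_len(nrow(donor_keys))) {
    da <- donor_keys$assembly[d]; ds <- donor_keys$seq_id[d]
    bids <- unique(maf$block_id[maf$assembly == da & maf$seq_id == ds])
    binfo <- list()
    for (b in bids) {
      rows <- normalize_block(maf[maf$block_id == b, , drop = FALSE],
                              config$skeleton)
      ski <- which(rows$assembly == config$skeleton)
      dki <- which(rows$assembly == da & rows$seq_id == ds)
      if (length(ski) == 0 || length(dki) == 0) next
      skrow <- rows[ski[1], ]; drow <- rows[dki[1], ]
      if (!skrow$seq_id %in% names(lens)) next
      binfo[[length(binfo) + 1L]] <- tibble::tibble(
        sk_seq = skrow$seq_id, sk_start = skrow$fwd_start,
        sk_end = skrow$fwd_end, d_strand = drow$strand,
        d_fwd_start = drow$fwd_start, d_fwd_end = drow$fwd_end,
        d_src_size = drow$src_size)
    }
    if (length(binfo) < 2) next
    binfo <- dplyr::bind_rows(binfo)
    for (i in seq_len(nrow(binfo))) for (j in seq_len(nrow(binfo))) {
      if (i == j) next
      b1 <- binfo[i, ]; b2 <- binfo[j, ]
      if (b1$sk_seq == b2$sk_seq) next
      near_end1 <- lens[[b1$sk_seq]] - b1$sk_end <= tw
      near_start2 <- b2$sk_start <= tw
      if (!near_end1 || !near_start2) next
      if (b1$d_strand != b2$d_strand) next
      if (b1$d_strand == "+") {
        if (b1$d_fwd_end > b2$d_fwd_start) next
        filler_coords <- c(b1$d_fwd_end, b2$d_fwd_start)
        rc <- FALSE
      } else {
        if (b2$d_fwd_end > b1$d_fwd_start) next
        filler_coords <- c(b2$d_fwd_end, b1$d_fwd_start)
        rc <- TRUE
      }
      proposals[[length(proposals) + 1L]] <- tibble::tibble(
        s1 = b1$sk_seq, s2 = b2$sk_seq, donor_assembly = da,
        donor_seq = ds, f_start = filler_coords[1],
        f_end = filler_coords[2], rc = rc,
        slack = (lens[[b1$sk_seq]] - b1$sk_end) + b2$sk_start +
          (filler_coords[2] - filler_coords[1]))
    }
  }

  out <- skeleton
  if (length(proposals) > 0) {
    pr <- dplyr::bind_rows(proposals)
    # tightest junctions first: least donor filler and alignment blocks
    # closest to the scaffold termini; then deterministic name order
    pr <- pr[order(pr$slack, pr$s1, pr$s2, pr$donor_assembly,
                   pr$donor_seq), , drop = FALSE]
    used_right <- character(); used_left <- character()
    comp <- stats::setNames(seq_along(skeleton$seq_id), skeleton$seq_id)
    find_root <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    accepted <- list()
    for (i in seq_len(nrow(pr))) {
      p <- pr[i, ]
      reason <- NULL
      if (p$s1 %in% used_right || p$s2 %in% used_left) {
        reason <- "end_in_use"
      } else if (find_root(match(p$s1, skeleton$seq_id)) ==
                   find_root(match(p$s2, skeleton$seq_id))) {
        reason <- "circular"
      } else if (!is.null(seq_groups)) {
        g1 <- seq_groups[[p$s1]]; g2 <- seq_groups[[p$s2]]
        if (!is.null(g1) && !is.null(g2) &&
            length(intersect(g1, g2)) == 0) {
          reason <- "linkage_conflict"
        }
      }
      if (!is.null(reason)) {
        events[[length(events) + 1L]] <- join_event(p, "join_refused", reason)
        next
      }
      used_right <- c(used_right, p$s1)
      used_left <- c(used_left, p$s2)
      comp[find_root(match(p$s2, skeleton$seq_id))] <-
        find_root(match(p$s1, skeleton$seq_id))
      accepted[[length(accepted) + 1L]] <- p
      events[[length(events) + 1L]] <- join_event(p, "join", NA_character_)
    }
    if (length(accepted) > 0) {
      acc <- dplyr::bind_rows(accepted)
      out <- apply_joins(skeleton, acc, maf, config)
    }
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else {
    tibble::tibble(type = character(), s1 = character(), s2 = character(),
                   donor_assembly = character(), donor_seq = character(),
                   filler_len = integer(), reason = character())
  }
  list(assembly = out, events = ev)
}

join_event <- function(p, type, reason) {
  tibble::tibble(type = type, s1 = p$s1, s2 = p$s2,
                 donor_assembly = p$donor_assembly, donor_seq = p$donor_seq,
                 filler_len = p$f_end - p$f_start, reason = reason)
}

# Concatenate accepted junction chains. Donor filler sequence is taken from
# the donor assemblies recorded in the proposals via the `donor_seqs`
# attribute set by reconcile(); when absent (standalone use) the filler is
# an N-run of the recorded length.
apply_joins <- function(skeleton, acc, maf, config) {
  donor_asms <- attr(maf, "donor_assemblies")
  succ <- stats::setNames(rep(NA_character_, nrow(skeleton)),
                          skeleton$seq_id)
  filler <- list()
  for (i in seq_len(nrow(acc))) {
    p <- acc[i, ]
    s <- NULL
    if (!is.null(donor_asms) && p$donor_assembly %in% names(donor_asms)) {
      da <- donor_asms[[p$donor_assembly]]
      ri <- which(da$seq_id == p$donor_seq)
      if (length(ri) == 1) {
        s <- substr(da$bases[ri], p$f_start + 1L, p$f_end)
        if (p$rc) s <- reverse_complement(s)
      }
    }
    if (is.null(s)) s <- strrep("N", p$f_end - p$f_start)
    succ[[p$s1]] <- p$s2
    filler[[p$s1]] <- s
  }
  has_pred <- skeleton$seq_id %in% acc$s2
  out_ids <- character(); out_bases <- character()
  for (i in seq_len(nrow(skeleton))) {
    sid <- skeleton$seq_id[i]
    if (has_pred[i]) next # emitted as part of its chain
    chain_ids <- sid; chain <- skeleton$bases[i]
    cur <- sid
    while (!is.na(succ[[cur]])) {
      nxt <- succ[[cur]]
      chain <- paste0(chain, filler[[cur]],
                      skeleton$bases[skeleton$seq_id == nxt])
      chain_ids <- c(chain_ids, nxt)
      cur <- nxt
    }
    out_ids <- c(out_ids, paste(chain_ids, collapse = "+"))
    out_bases <- c(out_bases, chain)
  }
  assembly(out_ids, out_bases, name = attr(skeleton, "assembly_name"))
}

#' Reconcile draft assemblies into one improved assembly
#'
#' Runs the full pipeline: per-assembly containment removal, splitting of
#' skeleton scaffolds that conflict with the linkage map, removal of short
#' sequences, gap closing from donor assemblies, and scaffold joining via
#' spanning donor scaffolds.
#'
#' @param assemblies Named list of assembly tibbles; must include the
#'   skeleton named in `config`.
#' @param maf Alignment blocks over the assemblies ([parse_maf()] layout).
#' @param config A [reconcile_config()].
#' @param self_alignments Optional named list (per assembly) of
#'   self-alignment tables for [remove_contained()].
#' @param map,placements Optional linkage map and resolved marker placements
#'   (on skeleton scaffolds) used for conflict splitting and the join guard.
#' @return Object of class `reconciliation` with `$assembly`, `$events`,
#'   and `$removed`. [glance()] gives event counts, [tidy()] the event log.
#' @export
reconcile <- function(assemblies, maf, config, self_alignments = NULL,
                      map = NULL, placements = NULL) {
  stopifnot(is.list(assemblies), config$skeleton %in% names(assemblies))
  if (!any(maf$assembly == config$skeleton))
    stop("MAF contains no rows for skeleton assembly '",
         config$skeleton, "'")
  removed <- list()

  for (nm in names(assemblies)) {
    assemblies[[nm]] <- as_assembly(assemblies[[nm]])
    if (!is.null(self_alignments[[nm]])) {
      rc <- remove_contained(assemblies[[nm]], self_alignments[[nm]],
                             config$containment_identity_min,
                             config$containment_coverage_min)
      assemblies[[nm]] <- rc$assembly
      if (nrow(rc$removed) > 0)
        removed[[length(removed) + 1L]] <- dplyr::mutate(
          rc$removed, assembly = nm, why = "contained")
    }
  }

  discards <- NULL
  if (!is.null(map) && !is.null(placements)) {
    sp <- split_at_conflicts(assemblies[[config$skeleton]], placements, map)
    assemblies[[config$skeleton]] <- sp$assembly
    placements <- sp$placements
    discards <- sp$discards
    maf <- remap_maf_splits(maf, config$skeleton, sp$pieces)
  }

  for (nm in names(assemblies)) {
    ds <- drop_short(assemblies[[nm]], config$min_seq_len)
    assemblies[[nm]] <- ds$assembly
    if (nrow(ds$removed) > 0)
      removed[[length(removed) + 1L]] <- tibble::tibble(
        seq_id = ds$removed$seq_id, container = NA_character_,
        assembly = nm, why = "short")
  }

  # drop MAF rows that reference sequences no longer present
  present <- purrr::imap(assemblies, ~tibble::tibble(assembly = .y,
                                                     seq_id = .x$seq_id))
  present <- dplyr::bind_rows(present)
  maf <- dplyr::semi_join(maf, present, by = c("assembly", "seq_id"))

  cg <- close_gaps(assemblies[[config$skeleton]], maf, config)
  maf2 <- remap_maf_offsets(maf, cg$offsets, config$skeleton)
  attr(maf2, "donor_assemblies") <-
    assemblies[setdiff(names(assemblies), config$skeleton)]
  js <- join_scaffolds(cg$assembly, maf2, config, placements, map)

  rem <- if (length(removed)) dplyr::bind_rows(removed) else {
    tibble::tibble(seq_id = character(), container = character(),
                   assembly = character(), why = character())
  }
  structure(list(assembly = js$assembly,
                 events = dplyr::bind_rows(cg$events, js$events),
                 removed = rem, discards = discards, config = config),
            class = "reconciliation")
}

# Rename/shift skeleton MAF rows onto conflict-split pieces; rows crossing a
# piece boundary (or inside a discarded middle) are dropped.
remap_maf_splits <- function(maf, skeleton, pieces) {
  if (is.null(pieces) || nrow(pieces) == 0) return(maf)
  keep <- rep(TRUE, nrow(maf))
  for (i in seq_len(nrow(maf))) {
    if (maf$assembly[i] != skeleton) next
    pc <- pieces[pieces$source_scaffold == maf$seq_id[i], , drop = FALSE]
    if (nrow(pc) == 0) next
    hit <- which(pc$src_start <= maf$fwd_start[i] &
                   pc$src_end >= maf$fwd_end[i])
    if (length(hit) != 1) { keep[i] <- FALSE; next }
    p <- pc[hit, ]
    maf$seq_id[i] <- p$seq_id
    maf$fwd_start[i] <- maf$fwd_start[i] - p$src_start
    maf$fwd_end[i] <- maf$fwd_end[i] - p$src_start
    maf$src_size[i] <- p$src_end - p$src_start
    maf$start[i] <- if (maf$strand[i] == "+") maf$fwd_start[i] else
      maf$src_size[i] - maf$fwd_end[i]
  }
  maf[keep, , drop = FALSE]
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Reconciled assembly:", nrow(x$assembly), "sequences,",
      sum(nchar(x$assembly$bases)), "bp\n")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.reconciliation <- function(x, ...) {
  tibble::tibble(
    gaps_closed = sum(x$events$type == "gap_closed"),
    gaps_shrunk = sum(x$events$type == "gap_shrunk"),
    joins_made = sum(x$events$type == "join"),
    sequences_removed_contained = sum(x$removed$why == "contained"),
    sequences_removed_short = sum(x$removed$why == "short"),
    n_seqs = nrow(x$assembly),
    total_bp = sum(nchar(x$assembly$bases))
  )
}

#' @exportS3Method generics::tidy
tidy.reconciliation <- function(x, ...) x$events

#' Write a reconciliation report as JSON
#'
#' @param x A `reconciliation` object.
#' @param path Output path.
#' @export
write_reconcile_report <- function(x, path) {
  jsonlite::write_json(list(counts = as.list(glance(x)),
                            events = x$events),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
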