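#' Tandem-repeat detector configuration
#'
#' The scoring reconstructs a Phobos-style scheme: match +1, mismatch
#' `-mismatch_penalty`, indel `-indel_penalty`, and a final deduction of the
#' unit size, so a perfect repeat of length L with unit size k scores
#' `L - k`. At the default `min_score = 12` the shortest accepted perfect
#' repeats are therefore 13, 14 and 15 bp for unit sizes 1, 2 and 3.
#'
#' @param min_score Minimum score for a reported repeat (default 12; the
#'   comparison is `>=`).
#' @param max_unit Maximum repeat-unit size in bp (default 50).
#' @param mismatch_penalty,indel_penalty Positive penalties (default 5 each).
#' @return A list of class `tr_config`.
#' @export
tr_config <- function(min_score = 12, max_unit = 50,
                      mismatch_penalty = 5, indel_penalty = 5) {
  stopifnot(min_score >= 1, max_unit >= 1,
            mismatch_penalty > 0, indel_penalty > 0)
  structure(list(min_score = min_score, max_unit = max_unit,
                 mismatch_penalty = mismatch_penalty,
                 indel_penalty = indel_penalty),
            class = "tr_config")
}

#' Preset: repeat-library style detection (long, short-unit repeats)
#'
#' A configuration preset for the alternative definition used for
#' repeat-library work: units 2-6 bp and a minimum length of 20 bp
#' (score `>= 20 - unit` for perfect repeats, approximated by a score
#' threshold of 14 = 20 - 6).
#' @export
tr_config_library <- function() tr_config(min_score = 14, max_unit = 6)

#' Score a region against a repeat unit
#'
#' Wraparound dynamic programming: the region is globally aligned against
#' the infinite periodic extension of `unit`, anchored at phase 0 with a
#' free end phase; match +1, mismatch/indel minus the configured penalties;
#' the unit size is subtracted from the final score. Perfection is the
#' percent of aligned columns that are matches.
#'
#' @param region Sequence to score (no N allowed in `unit`).
#' @param unit The repeat unit.
#' @param config A [tr_config()].
#' @return One-row tibble: `score`, `perfection`, `matches`, `columns`.
#' @export
#' @examples
#' score_repeat(strrep("AC", 7), "AC") # score 12, perfection 100
score_repeat <- function(region, unit, config = tr_config()) {
  region <- toupper(region)
  unit <- toupper(unit)
  if (!nzchar(unit)) stop("unit must be non-empty")
  if (grepl("N", unit)) stop("unit must not contain N")
  k <- nchar(unit)
  L <- nchar(region)
  if (L < k) stop("region shorter than unit")
  mm <- config$mismatch_penalty
  ind <- config$indel_penalty
  u <- strsplit(unit, "")[[1]]
  r <- strsplit(region, "")[[1]]

  D <- rep(-Inf, k); M <- integer(k); C <- integer(k)
  D[1] <- 0
  for (pass in 1:2) for (j in seq_len(k)) {
    jn <- if (j == k) 1L else j + 1L
    if (is.finite(D[j]) && D[j] - ind > D[jn]) {
      D[jn] <- D[j] - ind; M[jn] <- M[j]; C[jn] <- C[j] + 1L
    }
  }
  for (i in seq_len(L)) {
    Dn <- rep(-Inf, k); Mn <- integer(k); Cn <- integer(k)
    for (j in seq_len(k)) {
      if (!is.finite(D[j])) next
      jn <- if (j == k) 1L else j + 1L
      eq <- r[i] == u[j]
      v <- D[j] + if (eq) 1 else -mm
      if (v > Dn[jn]) {
        Dn[jn] <- v; Mn[jn] <- M[j] + as.integer(eq); Cn[jn] <- C[j] + 1L
      }
    }
    for (j in seq_len(k)) {
      if (!is.finite(D[j])) next
      if (D[j] - ind > Dn[j]) {
        Dn[j] <- D[j] - ind; Mn[j] <- M[j]; Cn[j] <- C[j] + 1L
      }
    }
    for (pass in 1:2) for (j in seq_len(k)) {
      jn <- if (j == k) 1L else j + 1L
      if (is.finite(Dn[j]) && Dn[j] - ind > Dn[jn]) {
        Dn[jn] <- Dn[j] - ind; Mn[jn] <- Mn[j]; Cn[jn] <- Cn[j] + 1L
      }
    }
    D <- Dn; M <- Mn; C <- Cn
  }
  bj <- which.max(D)
  tibble::tibble(score = D[bj] - k,
                 perfection = 100 * M[bj] / C[bj],
                 matches = M[bj], columns = C[bj])
}

# Lexicographically least rotation of a unit string.
canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k == 1) return(u)
    rot <- vapply(seq_len(k) - 1L, function(i) {
      paste0(substring(u, i + 1, k), substring(u, 1, i))
    }, character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

# Split a scaffold at Ns; returns tibble(offset, segment) of N-free pieces.
split_at_n <- function(bases) {
  m <- stringr::str_locate_all(bases, "[^Nn]+")[[1]]
  if (nrow(m) == 0) {
    return(tibble::tibble(offset = integer(), segment = character()))
  }
  tibble::tibble(offset = unname(m[, 1]) - 1L,
                 segment = unname(stringr::str_sub(bases, m[, 1], m[, 2])))
}

# Greedy canonical overlap resolution: highest score, then smallest unit
# size, then leftmost start (then smallest end). Overlap checked per seq_id
# with an occupancy vector.
resolve_tr_overlaps <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  out <- purrr::map_dfr(split(cands, cands$seq_id), function(cc) {
    cc <- cc[order(-cc$score, cc$unit_size, cc$start, cc$end), , drop = FALSE]
    maxend <- max(cc$end)
    occ <- logical(maxend)
    keep <- logical(nrow(cc))
    for (i in seq_len(nrow(cc))) {
      span <- (cc$start[i] + 1L):cc$end[i]
      if (!any(occ[span])) {
        keep[i] <- TRUE
        occ[span] <- TRUE
      }
    }
    cc[keep, , drop = FALSE]
  })
  out[order(out$seq_id, out$start), , drop = FALSE]
}

tr_detect_engine <- function(x, config, engine) {
  x <- as_assembly(x)
  cands <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    segs <- split_at_n(x$bases[i])
    purrr::map_dfr(seq_len(nrow(segs)), function(s) {
      seg <- toupper(segs$segment[s])
      df <- engine(seg, config$max_unit, config$min_score,
                   config$mismatch_penalty, config$indel_penalty)
      df <- tibble::as_tibble(df)
      if (nrow(df) == 0) return(NULL)
      unit_raw <- substring(seg, df$start + 1L, df$start + df$unit_size)
      tibble::tibble(
        seq_id = x$seq_id[i],
        start = df$start + segs$offset[s],
        end = df$end + segs$offset[s],
        unit_size = df$unit_size,
        unit = canonical_unit(unit_raw),
        score = df$score,
        perfection = 100 * df$matches / df$cols
      )
    })
  })
  if (nrow(cands) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), unit_size = integer(),
                          unit = character(), score = numeric(),
                          perfection = numeric()))
  }
  resolve_tr_overlaps(cands)
}

#' Detect tandem repeats
#'
#' Finds all repeat regions with unit size up to `max_unit` and score at
#' least `min_score` under the wraparound-DP scoring of [score_repeat()].
#' Candidate regions are seeded from period-k self-match runs, extended by
#' dynamic programming, restricted to N-free sequence (an N terminates
#' extension), suppressed when their unit is internally periodic (the
#' primitive unit wins), and canonicalized: among overlapping candidates the
#' highest score is kept, ties broken by smaller unit size then leftmost
#' start. Units are reported as their lexicographically least rotation, on
#' the strand as written.
#'
#' @param x Assembly tibble.
#' @param config A [tr_config()].
#' @return Tibble: `seq_id`, `start`, `end` (0-based half-open),
#'   `unit_size`, `unit`, `score`, `perfection`.
#' @export
detect_trs <- function(x, config = tr_config()) {
  tr_detect_engine(x, config, .tr_candidates_seeded)
}

#' Brute-force reference tandem-repeat scanner
#'
#' Exhaustively enumerates every anchor position and unit size and extends
#' each by full-table wraparound DP — an independently coded reference
#' implementation used to validate [detect_trs()] on small sequences. Output
#' format and canonicalization are identical to [detect_trs()].
#'
#' @inheritParams detect_trs
#' @export
detect_trs_exhaustive <- function(x, config = tr_config()) {
  tr_detect_engine(x, config, .tr_candidates_exhaustive)
}

#' Summarize tandem-repeat content of an assembly
#'
#' @param x Assembly tibble the repeats were called on.
#' @param trs Output of [detect_trs()].
#' @return An object of class `tr_summary` with `$stats` (count, mean and sd
#'   of repeat length, percent of assembly bases inside repeats) and
#'   `$unit_counts` (count per unit size). [tidy()] returns the per-unit
#'   counts, [glance()] the one-row stats.
#' @export
tr_summary <- function(x, trs) {
  x <- as_assembly(x)
  total <- sum(nchar(x$bases))
  lens <- trs$end - trs$start
  covered <- if (nrow(trs) == 0) 0 else {
    sum(vapply(split(trs, trs$seq_id), function(tt) {
      sum(S4Vectors::width(IRanges::reduce(
        IRanges::IRanges(tt$start + 1L, tt$end))))
    }, numeric(1)))
  }
  stats <- tibble::tibble(
    count = nrow(trs),
    mean_length = if (nrow(trs)) mean(lens) else NA_real_,
    sd_length = if (nrow(trs) > 1) stats::sd(lens) else NA_real_,
    density_pct = 100 * covered / total
  )
  unit_counts <- if (nrow(trs) == 0) {
    tibble::tibble(unit_size = integer(), n = integer())
  } else {
    dplyr::count(trs, .data$unit_size)
  }
  structure(list(stats = stats, unit_counts = unit_counts),
            class = "tr_summary")
}

#' @exportS3Method generics::tidy
tidy.tr_summary <- function(x, ...) x$unit_counts

#' @exportS3Method generics::glance
glance.tr_summary <- function(x, ...) x$stats

#' @export
print.tr_summary <- function(x, ...) {
  cat("Tandem-repeat summary\n")
  print(x$stats)
  invisible(x)
}

#' Tandem-repeat density and frequency per region class
#'
#' For each region label: density is the percent of region bases covered by
#' repeats; frequency is the number of repeats per Mbp of region, counting a
#' repeat once per region it intersects.
#'
#' @param trs Output of [detect_trs()].
#' @param regions Tibble with columns `label`, `seq_id`, `start`, `end`.
#' @param x Assembly tibble (unused for arithmetic but validates provenance).
#' @return Tibble: `label`, `region_bp`, `n_trs`, `density_pct`,
#'   `freq_per_mbp`.
#' @export
tr_region_density <- function(trs, regions, x = NULL) {
  stopifnot(all(c("label", "seq_id", "start", "end") %in% names(regions)))
  purrr::map_dfr(split(regions, regions$label), function(rg) {
    rir <- IRanges::IRanges(rg$start + 1L, rg$end)
    region_bp <- sum(rg$end - rg$start)
    tt <- trs[trs$seq_id %in% rg$seq_id, , drop = FALSE]
    n_hits <- 0L
    cov_bp <- 0
    for (sid in unique(rg$seq_id)) {
      rs <- rg[rg$seq_id == sid, ]
      ts <- tt[tt$seq_id == sid, ]
      if (nrow(ts) == 0 || nrow(rs) == 0) next
      ri <- IRanges::IRanges(rs$start + 1L, rs$end)
      ti <- IRanges::IRanges(ts$start + 1L, ts$end)
      ov <- IRanges::findOverlaps(ti, ri)
      n_hits <- n_hits + length(ov)
      cov_bp <- cov_bp +
        sum(S4Vectors::width(IRanges::intersect(
          IRanges::reduce(ti), IRanges::reduce(ri))))
    }
    tibble::tibble(label = rg$label[1], region_bp = region_bp,
                   n_trs = n_hits,
                   density_pct = 100 * cov_bp / region_bp,
                   freq_per_mbp = n_hits / (region_bp / 1e6))
  })
}

#' Write tandem repeats as GFF3
#'
#' Records of type `tandem_repeat` with attributes `unit`, `unit_size`,
#' `score`, `perfection`.
#'
#' @param trs Output of [detect_trs()].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_tr_gff3 <- function(trs, path, source = "recweave") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(trs) > 0) {
    lines <- sprintf(
      "%s\t%s\ttandem_repeat\t%d\t%d\t%s\t.\t.\tunit=%s;unit_size=%d;score=%s;perfection=%s",
      trs$seq_id, source, trs$start + 1L, trs$end,
      format_num(trs$score), trs$unit, trs$unit_size,
      format_num(trs$score), format_num(trs$perfection))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read tandem repeats from a GFF3 file written by [write_tr_gff3()]
#' @param path Path to the GFF3 file.
#' @export
read_tr_gff3 <- function(path) {
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), unit_size = integer(),
                          unit = character(), score = numeric(),
                          perfection = numeric()))
  }
  f <- stringr::str_split_fixed(ln, "\t", 9)
  attr_get <- function(attrs, key) {
    stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  }
  tibble::tibble(
    seq_id = f[, 1],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    unit_size = as.integer(attr_get(f[, 9], "unit_size")),
    unit = attr_get(f[, 9], "unit"),
    score = as.numeric(attr_get(f[, 9], "score")),
    perfection = as.numeric(attr_get(f[, 9], "perfection"))
  )
}

format_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sprintf("%.4g", x))
}
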