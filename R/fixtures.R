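#' Fixture generator configuration
#'
#' Defaults emulate the repeat landscape and variant rates of a highly
#' repetitive teleost genome: tandem repeats covering ~10% of the assembly
#' with a dinucleotide-dominated unit mix, SNP heterozygosity 4.07e-3,
#' indel rate 0.98e-3, and about a fifth of repeat loci heterozygous.
#' Short-read-like drafts break preferentially at repeat loci; one
#' long-read-like draft breaks only at interspersed (TE-like) duplicates.
#'
#' @param seed Integer seed; all fixture randomness derives from it.
#' @param genome_len Total genome length in bp (>= 1e4).
#' @param n_chromosomes Number of chromosomes.
#' @param tr_density_target Target fraction of bases inside planted repeats.
#' @param tr_unit_mix Named weights over unit sizes for planted repeats.
#' @param te_count,te_len Number and length of planted TE-like duplicates.
#' @param het_tr_fraction Fraction of planted repeats given a heterozygous
#'   whole-unit indel.
#' @param snp_rate,indel_rate Per-base background variant rates.
#' @param n_assemblies Number of draft assemblies (>= 2; the last is the
#'   long-read-like draft).
#' @param break_at_tr_prob Probability that a planted repeat breaks a
#'   short-read-like draft.
#' @param break_random_prob Per-base probability of a random break.
#' @param scaffold_break_prob Probability that a skeleton break separates
#'   scaffolds instead of leaving an N-gap.
#' @param gap_len_range NULL (gap length equals the true missing length) or
#'   a length-2 range to sample estimated gap lengths from.
#' @param marker_spacing,flank_length Linkage-marker spacing and flank
#'   length in bp.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, genome_len = 1e5, n_chromosomes = 2,
                           tr_density_target = 0.10,
                           tr_unit_mix = c("1" = 0.09, "2" = 0.55,
                                           "3" = 0.08, "4" = 0.08,
                                           "5" = 0.06, "6" = 0.14),
                           te_count = 10, te_len = 500,
                           het_tr_fraction = 0.21,
                           snp_rate = 4.07e-3, indel_rate = 0.98e-3,
                           n_assemblies = 3,
                           break_at_tr_prob = 0.1,
                           break_random_prob = 2e-5,
                           scaffold_break_prob = 0.15,
                           gap_len_range = NULL,
                           marker_spacing = 5000, flank_length = 100) {
  stopifnot(genome_len >= 1e4, n_chromosomes >= 1,
            tr_density_target >= 0, tr_density_target <= 1,
            het_tr_fraction >= 0, het_tr_fraction <= 1,
            break_at_tr_prob >= 0, break_at_tr_prob <= 1,
            n_assemblies >= 2)
  structure(as.list(environment()), class = "fixture_config")
}

rand_unit <- function(k) {
  repeat {
    u <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    # require a primitive unit so the planted unit size is the true one
    prim <- TRUE
    for (d in seq_len(k - 1)) {
      if (k %% d != 0) next
      if (u == strrep(substr(u, 1, d), k / d)) { prim <- FALSE; break }
    }
    if (prim) return(u)
  }
}

#' Simulate a truth genome with planted repeats and TE-like duplicates
#'
#' Uniform random background with perfect tandem repeats planted to the
#' target density (unit sizes drawn from `tr_unit_mix`, lengths a few units
#' above the detection minimum) and `te_count` mutated copies of a single
#' TE-like element. Deterministic under `config$seed`.
#'
#' @param config A [fixture_config()].
#' @return Object of class `fixture_truth`: `$genome` (assembly tibble),
#'   `$trs`, `$tes` (truth coordinate tables), `$config`.
#' @export
simulate_genome <- function(config) {
  if (config$tr_density_target > 0.3)
    stop("tr_density_target infeasible (> 0.3)")
  set.seed(config$seed)
  chr_len <- rep(floor(config$genome_len / config$n_chromosomes),
                 config$n_chromosomes)
  chr_ids <- paste0("chr", seq_len(config$n_chromosomes))
  # chromosomes kept as character vectors while planting (cheap splicing)
  gv <- lapply(chr_len, function(L) sample(c("A", "C", "G", "T"), L,
                                           replace = TRUE))
  occ <- lapply(chr_len, logical)

  target_bp <- config$tr_density_target * sum(chr_len)
  mix <- config$tr_unit_mix / sum(config$tr_unit_mix)
  sizes <- as.integer(names(mix))
  trs <- list(); planted_bp <- 0
  attempts <- 0
  while (planted_bp < target_bp && attempts < 1e6) {
    attempts <- attempts + 1
    k <- sample(sizes, 1, prob = mix)
    units <- ceiling((12 + k) / k) + 1 + stats::rgeom(1, 0.25)
    len <- k * units
    ci <- sample(seq_along(chr_ids), 1)
    L <- chr_len[ci]
    if (len + 40 >= L) next
    pos <- sample.int(L - len - 40, 1) + 20L # 0-based start
    span <- (pos - 19L):(pos + len + 20L)
    if (any(occ[[ci]][span])) next
    u <- rand_unit(k)
    gv[[ci]][(pos + 1L):(pos + len)] <-
      strsplit(strrep(u, units), "")[[1]]
    occ[[ci]][span] <- TRUE
    trs[[length(trs) + 1L]] <- tibble::tibble(
      seq_id = chr_ids[ci], start = pos, end = pos + len,
      unit_size = k, unit = canonical_unit(u))
    planted_bp <- planted_bp + len
  }

  te <- sample(c("A", "C", "G", "T"), config$te_len, replace = TRUE)
  tes <- list()
  placed <- 0; attempts <- 0
  while (placed < config$te_count && attempts < 1e5) {
    attempts <- attempts + 1
    ci <- sample(seq_along(chr_ids), 1)
    L <- chr_len[ci]
    if (config$te_len + 40 >= L) break
    pos <- sample.int(L - config$te_len - 40, 1) + 20L
    span <- (pos - 19L):(pos + config$te_len + 20L)
    if (any(occ[[ci]][span])) next
    copy <- te
    nmut <- stats::rbinom(1, config$te_len, 0.02)
    if (nmut > 0) {
      at <- sample.int(config$te_len, nmut)
      copy[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    gv[[ci]][(pos + 1L):(pos + config$te_len)] <- copy
    occ[[ci]][span] <- TRUE
    tes[[length(tes) + 1L]] <- tibble::tibble(
      seq_id = chr_ids[ci], start = pos, end = pos + config$te_len)
    placed <- placed + 1
  }

  genome <- vapply(gv, paste, character(1), collapse = "")
  structure(list(
    genome = assembly(chr_ids, genome, name = "truth"),
    trs = if (length(trs)) dplyr::bind_rows(trs) else
      tibble::tibble(seq_id = character(), start = integer(),
                     end = integer(), unit_size = integer(),
                     unit = character()),
    tes = if (length(tes)) dplyr::bind_rows(tes) else
      tibble::tibble(seq_id = character(), start = integer(),
                     end = integer()),
    config = config), class = "fixture_truth")
}

#' Simulate a diploid individual over a truth genome
#'
#' A fraction of planted repeats receive a heterozygous whole-unit indel
#' (repeat-length polymorphism); background SNPs and short indels are
#' placed outside repeat loci at the configured rates. Every event is
#' recorded as a left-anchored VCF-style variant with genotype 0/1 and a
#' plausible depth. The alternate haplotype carries all ALT alleles.
#'
#' @param truth A [simulate_genome()] result.
#' @param config The same [fixture_config()].
#' @return List: `$variants` (truth variant tibble with an `origin`
#'   column), `$alt_genome` (assembly tibble).
#' @export
simulate_diploid <- function(truth, config) {
  set.seed(config$seed + 1L)
  g <- truth$genome
  vars <- list()
  tr_occ <- truth$trs

  if (nrow(truth$trs) > 0 && config$het_tr_fraction > 0) {
    pick <- which(stats::runif(nrow(truth$trs)) < config$het_tr_fraction)
    for (i in pick) {
      tr <- truth$trs[i, ]
      k <- tr$unit_size
      n_units <- sample(1:2, 1)
      ins <- stats::runif(1) < 0.5
      chrom <- g$bases[g$seq_id == tr$seq_id]
      # anchor on the first repeat base so the REF span overlaps the locus
      anchor_pos <- tr$start
      anchor <- substr(chrom, anchor_pos + 1L, anchor_pos + 1L)
      unit_here <- substr(chrom, tr$start + 2L, tr$start + 1L + k)
      if (ins) {
        ref <- anchor
        alt <- paste0(anchor, strrep(unit_here, n_units))
      } else {
        if (n_units * k >= tr$end - tr$start - 1L) n_units <- 1L
        ref <- paste0(anchor, substr(chrom, tr$start + 2L,
                                     tr$start + 1L + n_units * k))
        alt <- anchor
      }
      vars[[length(vars) + 1L]] <- tibble::tibble(
        seq_id = tr$seq_id, pos = anchor_pos, ref = ref, alt = alt,
        qual = round(stats::runif(1, 30, 60), 1),
        depth = 5L + stats::rpois(1, 25),
        genotype = "0/1", origin = "tr_indel")
    }
  }

  for (ci in seq_len(nrow(g))) {
    sid <- g$seq_id[ci]
    L <- nchar(g$bases[ci])
    occ <- tr_occ[tr_occ$seq_id == sid, , drop = FALSE]
    in_tr <- logical(L)
    for (j in seq_len(nrow(occ)))
      in_tr[(occ$start[j] + 1L):occ$end[j]] <- TRUE
    free <- which(!in_tr & seq_len(L) > 1 & seq_len(L) < L - 10)
    n_snp <- stats::rbinom(1, length(free), config$snp_rate)
    n_ind <- stats::rbinom(1, length(free), config$indel_rate)
    at <- sample(free, min(n_snp + n_ind, length(free)))
    chrom <- g$bases[ci]
    for (idx in seq_along(at)) {
      p <- at[idx] - 1L # 0-based
      is_snp <- idx <= n_snp
      base <- substr(chrom, p + 1L, p + 1L)
      if (is_snp) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
        ref <- base
        origin <- "snp"
      } else {
        w <- sample(1:3, 1)
        if (stats::runif(1) < 0.5) {
          ref <- base
          alt <- paste0(base, paste(sample(c("A", "C", "G", "T"), w,
                                           replace = TRUE), collapse = ""))
        } else {
          ref <- substr(chrom, p + 1L, p + 1L + w)
          alt <- base
          if (nchar(ref) < 2) next
        }
        origin <- "indel"
      }
      if (ref == alt) next
      vars[[length(vars) + 1L]] <- tibble::tibble(
        seq_id = sid, pos = p, ref = ref, alt = alt,
        qual = round(stats::runif(1, 15, 60), 1),
        depth = 2L + stats::rpois(1, 28),
        genotype = sample(c("0/1", "0/1", "0/1", "1/1"), 1),
        origin = origin)
    }
  }

  variants <- if (length(vars)) dplyr::bind_rows(vars) else
    tibble::tibble(seq_id = character(), pos = integer(), ref = character(),
                   alt = character(), qual = numeric(), depth = integer(),
                   genotype = character(), origin = character())
  variants <- variants[order(variants$seq_id, variants$pos), , drop = FALSE]
  # drop events whose REF spans collide (keep the first)
  keep <- rep(TRUE, nrow(variants))
  last_end <- -1L; last_seq <- ""
  for (i in seq_len(nrow(variants))) {
    if (variants$seq_id[i] != last_seq) { last_end <- -1L }
    if (variants$pos[i] < last_end) { keep[i] <- FALSE; next }
    last_seq <- variants$seq_id[i]
    last_end <- variants$pos[i] + nchar(variants$ref[i])
  }
  variants <- variants[keep, , drop = FALSE]
  variants$vclass <- classify_variant(variants$ref, variants$alt)

  alt_g <- g
  het <- variants[variants$genotype %in% c("0/1", "1/1"), , drop = FALSE]
  for (ci in seq_len(nrow(alt_g))) {
    vv <- het[het$seq_id == alt_g$seq_id[ci], , drop = FALSE]
    if (nrow(vv) == 0) next
    s <- alt_g$bases[ci]
    # splice in one pass: background pieces between REF spans + ALT alleles
    bg_start <- c(0L, vv$pos + nchar(vv$ref))
    bg_end <- c(vv$pos, nchar(s))
    parts <- character(2L * nrow(vv) + 1L)
    parts[seq(1, length(parts), by = 2)] <-
      substring(s, bg_start + 1L, bg_end)
    parts[seq(2, length(parts), by = 2)] <- vv$alt
    alt_g$bases[ci] <- paste(parts, collapse = "")
  }
  list(variants = variants, alt_genome = alt_g)
}
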