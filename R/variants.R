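#' Classify a variant by its REF/ALT alleles
#'
#' Equal-length alleles are `snp` (length 1) or `mnp` (longer). For
#' length-changing alleles the shared prefix and suffix are trimmed; if one
#' allele is then empty the variant is a pure `indel`, otherwise `complex`
#' (a composite insertion and substitution event).
#'
#' @param ref,alt Character vectors of alleles (non-empty; `ref != alt`
#'   elementwise).
#' @return Character vector: `"snp"`, `"mnp"`, `"indel"` or `"complex"`.
#' @export
#' @examples
#' classify_variant(c("A", "A", "AT"), c("T", "AT", "GCA"))
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele")
  if (any(ref == alt)) stop("identical REF and ALT alleles")
  nr <- nchar(ref); na <- nchar(alt)
  out <- character(length(ref))
  out[nr == na & nr == 1] <- "snp"
  out[nr == na & nr > 1] <- "mnp"
  idx <- which(nr != na)
  for (i in idx) {
    r <- ref[i]; a <- alt[i]
    # trim shared suffix, then shared prefix
    while (nchar(r) > 0 && nchar(a) > 0 &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
    }
    p <- 0L
    while (p < min(nchar(r), nchar(a)) &&
             substr(r, p + 1, p + 1) == substr(a, p + 1, p + 1)) p <- p + 1L
    r <- substr(r, p + 1, nchar(r)); a <- substr(a, p + 1, nchar(a))
    out[i] <- if (nchar(r) == 0 || nchar(a) == 0) "indel" else "complex"
  }
  out
}

#' Read variants from a single-sample VCF
#'
#' Reads a VCF 4.x file, splits multi-ALT records into one row per ALT
#' allele, extracts genotype (GT) and depth (DP) from the first and only
#' sample, and classifies each variant. Multi-sample files are rejected
#' (the analyses target a single sequenced individual).
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return Tibble: `seq_id`, `pos` (0-based), `ref`, `alt`, `qual`,
#'   `depth`, `genotype`, `vclass`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gtmat <- v@gt
  if (!is.null(gtmat) && ncol(gtmat) > 2)
    stop("multi-sample VCF not supported (",
         ncol(gtmat) - 1, " samples)")
  gt <- rep(NA_character_, nrow(fix)); dp <- rep(NA_integer_, nrow(fix))
  if (!is.null(gtmat) && ncol(gtmat) == 2) {
    gt_raw <- suppressWarnings(
      vcfR::extract.gt(v, element = "GT")[, 1])
    dp_raw <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, 1])
    gt <- unname(gt_raw); dp <- as.integer(unname(dp_raw))
  }
  base <- tibble::tibble(
    seq_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT,
    qual = as.numeric(fix$QUAL),
    depth = dp, genotype = gsub("\\|", "/", gt))
  base <- tidyr::separate_rows(base, "alt", sep = ",")
  base <- base[base$alt != base$ref, , drop = FALSE]
  base$vclass <- classify_variant(base$ref, base$alt)
  base
}

#' Filter variant calls
#'
#' Keeps calls with quality strictly greater than `min_qual`. With
#' `het_only = TRUE`, additionally requires genotype 0/1 and depth of at
#' least `min_depth` reads; records lacking a depth are dropped and
#' counted (attribute `n_missing_depth`).
#'
#' @param variants Tibble from [read_vcf()] (or with the same columns).
#' @param min_qual Quality threshold (strict `>`; default 20).
#' @param het_only Restrict to heterozygous 0/1 calls with depth support.
#' @param min_depth Minimum depth when `het_only` (default 5).
#' @return Filtered tibble.
#' @export
filter_variants <- function(variants, min_qual = 20, het_only = FALSE,
                            min_depth = 5) {
  out <- variants[!is.na(variants$qual) & variants$qual > min_qual, ,
                  drop = FALSE]
  n_missing <- 0L
  if (het_only) {
    miss <- is.na(out$depth)
    n_missing <- sum(miss & !is.na(out$genotype) & out$genotype == "0/1")
    out <- out[!miss & out$depth >= min_depth &
                 !is.na(out$genotype) & out$genotype == "0/1", ,
               drop = FALSE]
  }
  attr(out, "n_missing_depth") <- n_missing
  out
}

#' Write variants as a minimal single-sample VCF
#'
#' Emits VCF 4.2 with QUAL, and GT/DP for one sample — the format consumed
#' by [read_vcf()]. Used by the fixture simulator.
#'
#' @param variants Tibble with `seq_id`, `pos` (0-based), `ref`, `alt`,
#'   `qual`, `depth`, `genotype`.
#' @param path Output path.
#' @param sample Sample name.
#' @export
write_vcf <- function(variants, path, sample = "sample1") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample)), con)
  if (nrow(variants) > 0) {
    v <- variants[order(variants$seq_id, variants$pos), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s:%d",
                       v$seq_id, v$pos + 1L, v$ref, v$alt,
                       format_num(v$qual), v$genotype, v$depth), con)
  }
  invisible(path)
}

#' Per-base variant rates
#'
#' @param counts Named integer vector or tibble with columns `vclass`, `n`.
#' @param span Assembly span in bp (> 0).
#' @return Tibble: `vclass`, `n`, `rate` (per base), `mean_spacing_bp`.
#' @export
#' @examples
#' variant_rates(c(indel = 631063), 643e6) # rate 0.98e-3, ~1020 bp spacing
variant_rates <- function(counts, span) {
  if (span <= 0) stop("span must be positive")
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(vclass = names(counts),
                             n = as.numeric(counts))
  }
  dplyr::mutate(counts,
                rate = .data$n / span,
                mean_spacing_bp = ifelse(.data$n > 0, span / .data$n, Inf))
}
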