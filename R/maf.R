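#' Parse a MAF multiple-alignment file
#'
#' Reads standard MAF (`a` block lines, `s` sequence rows). Row source names
#' are expected to encode `<assembly><sep><seq_id>`; the split happens at the
#' first occurrence of `sep`. Negative-strand starts are converted to
#' forward-strand half-open intervals (`fwd_start`, `fwd_end`) alongside the
#' original MAF fields.
#'
#' @param path Path to a MAF file.
#' @param sep Separator between assembly name and sequence id in the source
#'   field (default `"."`).
#' @return Tibble with columns `block_id`, `assembly`, `seq_id`, `start`,
#'   `size`, `strand`, `src_size`, `text`, `fwd_start`, `fwd_end`.
#' @export
parse_maf <- function(path, sep = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readr::read_lines(path)
  rows <- list()
  block <- -1L
  block_first_len <- NA_integer_
  for (i in seq_along(ln)) {
    l <- ln[i]
    if (startsWith(l, "a")) {
      block <- block + 1L
      block_first_len <- NA_integer_
    } else if (startsWith(l, "s")) {
      if (block < 0L) stop("line ", i, ": 's' row before any 'a' line")
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      if (length(f) != 7) stop("line ", i, ": malformed 's' row")
      src <- f[2]
      p <- regexpr(sep, src, fixed = TRUE)
      if (p < 0) stop("line ", i, ": source '", src,
                      "' lacks assembly separator '", sep, "'")
      text <- f[7]
      start <- as.integer(f[3]); size <- as.integer(f[4])
      src_size <- as.integer(f[6]); strand <- f[5]
      if (is.na(start) || is.na(size) || is.na(src_size))
        stop("line ", i, ": non-numeric coordinates")
      if (!strand %in% c("+", "-")) stop("line ", i, ": bad strand")
      ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ungapped != size)
        stop("line ", i, ": size ", size, " does not match text (",
             ungapped, " bases)")
      if (start + size > src_size)
        stop("line ", i, ": start + size exceeds src_size")
      if (is.na(block_first_len)) {
        block_first_len <- nchar(text)
      } else if (nchar(text) != block_first_len) {
        stop("line ", i, ": row text length differs within block")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block_id = block,
        assembly = substr(src, 1, p - 1),
        seq_id = substr(src, p + nchar(sep), nchar(src)),
        start = start, size = size, strand = strand,
        src_size = src_size, text = text)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(block_id = integer(), assembly = character(),
                          seq_id = character(), start = integer(),
                          size = integer(), strand = character(),
                          src_size = integer(), text = character(),
                          fwd_start = integer(), fwd_end = integer()))
  }
  out <- dplyr::bind_rows(rows)
  add_fwd_coords(out)
}

add_fwd_coords <- function(maf) {
  dplyr::mutate(maf,
    fwd_start = ifelse(.data$strand == "+", .data$start,
                       .data$src_size - .data$start - .data$size),
    fwd_end = .data$fwd_start + .data$size)
}

#' Write alignment blocks as MAF
#'
#' @param maf Tibble in the layout returned by [parse_maf()].
#' @param path Output path.
#' @param sep Separator joining assembly and seq_id in the source field.
#' @export
write_maf <- function(maf, path, sep = ".") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in unique(maf$block_id)) {
    rows <- maf[maf$block_id == b, , drop = FALSE]
    writeLines("", con)
    writeLines("a score=0", con)
    writeLines(sprintf("s %s%s%s %d %d %s %d %s",
                       rows$assembly, sep, rows$seq_id, rows$start,
                       rows$size, rows$strand, rows$src_size, rows$text),
               con)
  }
  invisible(path)
}

# View one block from the opposite strand: reverse-complement all row texts
# and swap every row to the other strand. The alignment is unchanged.
flip_block <- function(rows) {
  rows$text <- rev_comp_aln(rows$text)
  rows$start <- rows$src_size - rows$start - rows$size
  rows$strand <- ifelse(rows$strand == "+", "-", "+")
  add_fwd_coords(rows)
}

# Reverse-complement gapped alignment text ('-' preserved, reversed).
rev_comp_aln <- function(text) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", text))
}

# Normalize a block so its skeleton row is on the + strand.
normalize_block <- function(rows, skeleton) {
  sk <- which(rows$assembly == skeleton)
  if (length(sk) == 0) return(rows)
  if (rows$strand[sk[1]] == "-") flip_block(rows) else rows
}
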