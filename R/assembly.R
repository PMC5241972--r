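#' Construct an assembly table
#'
#' An assembly is a tibble with one row per scaffold and columns `seq_id`
#' (unique identifier) and `bases` (sequence over `{A,C,G,T,N}`, lowercase
#' soft-masking allowed). Any other IUPAC ambiguity letter is folded to `N`
#' on ingest; case is preserved. All coordinates used throughout the package
#' are 0-based, half-open.
#'
#' @param seq_id Character vector of scaffold identifiers (must be unique).
#' @param bases Character vector of sequences (non-empty).
#' @param name Optional assembly name, stored as the `"assembly_name"`
#'   attribute.
#' @return A tibble with columns `seq_id`, `bases`.
#' @export
#' @examples
#' asm <- assembly(c("s1", "s2"), c("ACGTNNNACGT", "GGGG"))
#' assembly_stats(asm)
assembly <- function(seq_id, bases, name = NULL) {
  seq_id <- as.character(seq_id)
  bases <- as.character(bases)
  if (length(seq_id) != length(bases)) {
    stop("seq_id and bases must have the same length")
  }
  dup <- unique(seq_id[duplicated(seq_id)])
  if (length(dup) > 0) {
    stop("duplicate seq_id: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(bases))) {
    stop("empty sequence for: ",
         paste(seq_id[!nzchar(bases)], collapse = ", "))
  }
  bases <- fold_to_n(bases)
  out <- tibble::tibble(seq_id = seq_id, bases = bases)
  if (!is.null(name)) attr(out, "assembly_name") <- name
  out
}

#' @rdname assembly
#' @param x A data frame with columns `seq_id` and `bases`.
#' @export
as_assembly <- function(x, name = attr(x, "assembly_name")) {
  stopifnot(is.data.frame(x), all(c("seq_id", "bases") %in% names(x)))
  assembly(x$seq_id, x$bases, name = name)
}

# Fold non-ACGTN letters (IUPAC ambiguity codes and anything else) to N,
# preserving the case of retained letters.
fold_to_n <- function(bases) {
  stringr::str_replace_all(bases, "[^ACGTNacgtn]", "N")
}

#' Read a FASTA file into an assembly table
#'
#' Record order is preserved, case is preserved, and letters outside
#' `{A,C,G,T,N}` (either case) are folded to `N`.
#'
#' @param path Path to a FASTA file.
#' @param name Assembly name; defaults to the file name without extension.
#' @return An assembly tibble (see [assembly()]).
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !startsWith(first, ">"))
    stop("no sequences in ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  if (length(recs) == 0) stop("no sequences in ", path)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  assembly(ids, seqs, name = name)
}

#' Write an assembly table to FASTA
#'
#' @param x Assembly tibble.
#' @param path Output path.
#' @param width Line width for sequence lines (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80) {
  x <- as_assembly(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$seq_id[i]), con)
    s <- x$bases[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Locate assembly gaps (runs of N)
#'
#' Finds maximal runs of `N`/`n` of length at least `min_run` in each
#' scaffold, the definition used when cutting scaffolds into contigs
#' ("cut at each gap of at least one basepair").
#'
#' @param x Assembly tibble.
#' @param min_run Minimum N-run length to report (default 1).
#' @return Tibble with columns `seq_id`, `start`, `end` (0-based half-open),
#'   in coordinate order within each scaffold.
#' @export
find_gaps <- function(x, min_run = 1) {
  x <- as_assembly(x)
  stopifnot(min_run >= 1)
  loc <- stringr::str_locate_all(x$bases, "[Nn]+")
  out <- purrr::map2_dfr(x$seq_id, loc, function(id, m) {
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(seq_id = id, start = unname(m[, 1]) - 1L,
                   end = unname(m[, 2]))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer()))
  }
  dplyr::filter(out, .data$end - .data$start >= min_run)
}

#' Cut scaffolds into contigs at gaps
#'
#' Partitions each scaffold at its N-runs of length `>= min_run`. Contigs are
#' named `<scaffold>.<ordinal>` and carry their 0-based offset on the source
#' scaffold. Scaffolds consisting only of Ns yield no contigs (with a
#' warning).
#'
#' @inheritParams find_gaps
#' @return Tibble with columns `seq_id`, `source_scaffold`, `offset`, `bases`.
#' @export
cut_at_gaps <- function(x, min_run = 1) {
  x <- as_assembly(x)
  gaps <- find_gaps(x, min_run = min_run)
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    id <- x$seq_id[i]
    s <- x$bases[i]
    len <- nchar(s)
    g <- gaps[gaps$seq_id == id, , drop = FALSE]
    bounds <- c(0L, rbind(g$start, g$end), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) {
      warning("scaffold ", id, " is all Ns; no contigs emitted")
      return(NULL)
    }
    tibble::tibble(
      seq_id = paste0(id, ".", seq_along(starts)),
      source_scaffold = id,
      offset = as.integer(starts),
      bases = substring(s, starts + 1L, ends)
    )
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(seq_id = character(), source_scaffold = character(),
                          offset = integer(), bases = character()))
  }
  out
}

#' N50 of a set of piece lengths
#'
#' The largest length `L` such that pieces of length `>= L` together contain
#' at least half of the total. `L` is always the length of an actual piece.
#'
#' @param lengths Positive integer vector of piece lengths.
#' @return A single integer.
#' @export
#' @examples
#' n50(c(6, 5, 4, 3, 2)) # 5
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50 of an empty set is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(l)
  as.integer(l[which(cs >= sum(l) / 2)[1]])
}

#' Contiguity statistics for an assembly
#'
#' Computes total size, gap bases, contig and scaffold N50. The contig N50 is
#' computed over [cut_at_gaps()] pieces (gaps of at least one basepair).
#'
#' @param x Assembly tibble.
#' @return One-row tibble: `assembly`, `total_bp`, `contig_n50`,
#'   `scaffold_n50`, `gap_bp`, `gap_fraction`, `n_seqs`.
#' @export
assembly_stats <- function(x) {
  x <- as_assembly(x)
  lens <- nchar(x$bases)
  gaps <- find_gaps(x)
  gap_bp <- if (nrow(gaps) == 0) 0L else sum(gaps$end - gaps$start)
  contigs <- suppressWarnings(cut_at_gaps(x))
  tibble::tibble(
    assembly = attr(x, "assembly_name") %||% NA_character_,
    total_bp = sum(lens),
    contig_n50 = if (nrow(contigs) > 0) n50(nchar(contigs$bases)) else 0L,
    scaffold_n50 = n50(lens),
    gap_bp = as.integer(gap_bp),
    gap_fraction = gap_bp / sum(lens),
    n_seqs = nrow(x)
  )
}

#' Write assembly statistics as TSV
#'
#' Emits the columns `assembly total_bp contig_n50 scaffold_n50 gap_bp
#' gap_pct n_seqs`, with `gap_pct` in percent.
#'
#' @param stats Output of [assembly_stats()] (rows may be bound together).
#' @param path Output path.
#' @export
write_stats_tsv <- function(stats, path) {
  out <- dplyr::mutate(stats, gap_pct = 100 * .data$gap_fraction)
  out <- out[, c("assembly", "total_bp", "contig_n50", "scaffold_n50",
                 "gap_bp", "gap_pct", "n_seqs")]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Reverse complement
#'
#' Case-preserving reverse complement over `{A,C,G,T,N}` (N maps to N).
#' Vectorized; an involution.
#'
#' @param bases Character vector of sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(bases) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", bases))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
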