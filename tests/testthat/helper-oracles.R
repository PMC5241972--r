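# Independent reference implementations used to validate package routines.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Definition-driven N50: the largest length L among the pieces such that
# pieces of length >= L hold at least half the total.
oracle_n50 <- function(lengths) {
  tot <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  }
  stop("unreachable")
}

# All-pairs interval overlap under half-open semantics.
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (sid in intersect(unique(a$seq_id), unique(b$seq_id))) {
    aa <- a[a$seq_id == sid, ]; bb <- b[b$seq_id == sid, ]
    hit <- outer(aa$start, bb$end, `<`) & outer(aa$end, bb$start, `>`)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    out[[sid]] <- tibble::tibble(
      seq_id = sid,
      a_start = aa$start[idx[, 1]], a_end = aa$end[idx[, 1]],
      b_start = bb$start[idx[, 2]], b_end = bb$end[idx[, 2]])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  res[order(res$seq_id, res$a_start, res$a_end, res$b_start, res$b_end), ]
}

# Wraparound-DP repeat score computed by per-row relaxation to a fixpoint
# (independent of the package's fixed-pass implementations). Score only.
oracle_repeat_score <- function(region, unit, mm = 5, ind = 5) {
  r <- strsplit(toupper(region), "")[[1]]
  u <- strsplit(toupper(unit), "")[[1]]
  k <- length(u)
  relax <- function(D) {
    repeat {
      changed <- FALSE
      for (j in seq_len(k)) {
        jn <- if (j == k) 1L else j + 1L
        if (is.finite(D[j]) && D[j] - ind > D[jn] + 1e-9) {
          D[jn] <- D[j] - ind; changed <- TRUE
        }
      }
      if (!changed) break
    }
    D
  }
  D <- rep(-Inf, k); D[1] <- 0
  D <- relax(D)
  for (i in seq_along(r)) {
    Dn <- rep(-Inf, k)
    for (j in seq_len(k)) {
      if (!is.finite(D[j])) next
      jn <- if (j == k) 1L else j + 1L
      sc <- if (r[i] == u[j]) 1 else -mm
      Dn[jn] <- max(Dn[jn], D[j] + sc)
      Dn[j] <- max(Dn[j], D[j] - ind)
    }
    D <- relax(Dn)
  }
  max(D) - k
}

# A toy MAF tibble from parallel row vectors.
toy_maf <- function(block_id, assembly, seq_id, start, size, strand,
                    src_size, text) {
  recweave:::add_fwd_coords(tibble::tibble(
    block_id = block_id, assembly = assembly, seq_id = seq_id,
    start = start, size = size, strand = strand, src_size = src_size,
    text = text))
}
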