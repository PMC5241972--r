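test_that("repeat scoring reproduces the published threshold anchors", {
  expect_equal(score_repeat(strrep("A", 13), "A")$score, 12)
  expect_equal(score_repeat(strrep("A", 13), "A")$perfection, 100)
  expect_equal(score_repeat(strrep("AC", 7), "AC")$score, 12)
  expect_equal(score_repeat(strrep("ACG", 5), "ACG")$score, 12)
  # 14 bp dinucleotide repeat with one C->G mismatch: 12 - 1 - 5
  expect_equal(score_repeat("ACACACAGACACAC", "AC")$score, 6)
  expect_error(score_repeat("ACAC", "AN"), "N")
  expect_error(score_repeat("ACAC", ""), "non-empty")
})

test_that("perfect repeats score length minus unit size", {
  is_primitive <- function(u) {
    k <- nchar(u)
    k == 1 || !any(vapply(seq_len(k - 1), function(d)
      k %% d == 0 && u == strrep(substr(u, 1, d), k / d), logical(1)))
  }
  set.seed(21)
  for (i in 1:30) {
    k <- sample(1:6, 1)
    u <- random_dna(k)
    while (!is_primitive(u)) u <- random_dna(k)
    copies <- sample(3:12, 1)
    expect_equal(score_repeat(strrep(u, copies), u)$score, k * copies - k)
  }
})

test_that("scoring agrees with a fixpoint-relaxation reference on noisy repeats", {
  set.seed(33)
  for (i in 1:40) {
    k <- sample(1:4, 1)
    u <- random_dna(k)
    r <- strsplit(strrep(u, sample(4:8, 1)), "")[[1]]
    # random mutations: substitution, insertion, deletion
    for (m in seq_len(sample(0:2, 1))) {
      op <- sample(3, 1); p <- sample(length(r), 1)
      if (op == 1) r[p] <- sample(c("A", "C", "G", "T"), 1)
      if (op == 2) r <- append(r, sample(c("A", "C", "G", "T"), 1), after = p)
      if (op == 3 && length(r) > k + 1) r <- r[-p]
    }
    region <- paste(r, collapse = "")
    expect_equal(score_repeat(region, u)$score,
                 oracle_repeat_score(region, u),
                 info = paste(region, u))
  }
})

test_that("detection finds embedded repeats with exact spans and rejects short ones", {
  d <- detect_trs(assembly("s1", paste0("GG", strrep("AC", 7), "TT")))
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 2L)
  expect_equal(d$end, 16L)
  expect_equal(d$unit, "AC")
  expect_equal(d$score, 12)

  expect_equal(nrow(detect_trs(assembly("s", strrep("AC", 6)))), 0)
  expect_equal(nrow(detect_trs(assembly("s", strrep("A", 12)))), 0)
  expect_equal(nrow(detect_trs(assembly("s", strrep("A", 13)))), 1)
})

test_that("an N terminates repeat extension", {
  s <- paste0(strrep("AC", 5), "N", strrep("AC", 5)) # each side below minimum
  expect_equal(nrow(detect_trs(assembly("s", s))), 0)
  s2 <- paste0(strrep("AC", 7), "N", strrep("A", 13))
  d <- detect_trs(assembly("s", s2))
  expect_equal(nrow(d), 2)
  expect_false(any(d$start < 14 & d$end > 14)) # nothing spans the N
})

test_that("internally periodic units are reported as their primitive unit", {
  d <- detect_trs(assembly("s", strrep("ACAC", 8)))
  expect_equal(d$unit_size, 2L)
  expect_equal(d$unit, "AC")
})

test_that("reverse complementing maps repeats to mirrored repeats of equal score", {
  set.seed(44)
  for (i in 1:10) {
    s <- paste0(random_dna(30), strrep("AGC", 8), random_dna(20),
                strrep("TG", 9), random_dna(30))
    a <- assembly("s", s)
    b <- assembly("s", reverse_complement(s))
    da <- detect_trs(a); db <- detect_trs(b)
    expect_equal(nrow(da), nrow(db))
    key <- function(d, L) {
      d <- d[order(d$start), ]
      paste(d$end - d$start, d$unit_size, d$score, sep = ":")
    }
    expect_setequal(key(da), key(db))
    # spans mirror exactly
    L <- nchar(s)
    expect_equal(sort(da$start), sort(L - db$end))
  }
})

test_that("seeded detector equals the exhaustive scanner on random sequences", {
  set.seed(7)
  cfg <- tr_config(max_unit = 15)
  for (i in 1:30) {
    s <- random_dna(sample(50:150, 1))
    if (i %% 3 == 0) {
      u <- random_dna(sample(1:6, 1))
      p <- sample(nchar(s) - 1, 1)
      s <- paste0(substr(s, 1, p), strrep(u, ceiling(30 / nchar(u))),
                  substr(s, p + 1, nchar(s)))
    }
    a <- assembly("s", s)
    expect_equal(as.data.frame(detect_trs(a, cfg)),
                 as.data.frame(detect_trs_exhaustive(a, cfg)))
  }
})

test_that("summary statistics and unit histogram are consistent", {
  a <- assembly("s", paste0(random_dna(63), strrep("AC", 7),
                            random_dna(63)))
  trs <- tibble::tibble(seq_id = "s", start = 63L, end = 77L,
                        unit_size = 2L, unit = "AC", score = 12,
                        perfection = 100)
  sm <- tr_summary(a, trs)
  expect_equal(glance(sm)$density_pct, 10)
  expect_equal(glance(sm)$count, 1)
  expect_equal(sum(tidy(sm)$n), glance(sm)$count)

  empty <- tr_summary(a, trs[0, ])
  expect_equal(glance(empty)$density_pct, 0)
  expect_equal(glance(empty)$count, 0)
})

test_that("per-region repeat density and frequency follow the definitions", {
  trs <- tibble::tibble(seq_id = "s", start = c(10L, 500L),
                        end = c(20L, 520L), unit_size = 2L, unit = "AC",
                        score = 12, perfection = 100)
  regions <- tibble::tibble(label = "promoter", seq_id = "s",
                            start = 0L, end = 100L)
  rd <- tr_region_density(trs, regions)
  expect_equal(rd$density_pct, 10)
  expect_equal(rd$freq_per_mbp, 1 / (100 / 1e6))
  expect_equal(rd$n_trs, 1L) # the repeat outside the region contributes 0
})

test_that("repeat GFF3 output round-trips", {
  trs <- detect_trs(assembly("s1", paste0("GG", strrep("AC", 7), "TT")))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_tr_gff3(trs, p)
  back <- read_tr_gff3(p)
  expect_equal(as.data.frame(back), as.data.frame(trs))
})
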