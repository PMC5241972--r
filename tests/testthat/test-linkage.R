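toy_map <- function() {
  tibble::tibble(
    marker_id = c("m1", "m2", "m3", "m4"),
    linkage_group = c("LG1", "LG1", "LG5", "LG2"),
    map_position = c(10, 20, 5, 1),
    flank_length = 200L)
}

test_that("linkage maps load from TSV and are validated", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_map(toy_map(), p)
  mp <- load_linkage_map(p)
  expect_equal(nrow(mp), 4)
  expect_equal(mp$marker_id[1], "m1")

  bad <- toy_map(); bad$marker_id[2] <- "m1"
  write_linkage_map(bad, p)
  expect_error(load_linkage_map(p), "duplicate")

  writeLines("marker_id\tlinkage_group\tmap_position\tflank_length", p)
  expect_error(load_linkage_map(p), "no markers")
})

test_that("placement resolution keeps the best hit and excludes ties across locations", {
  map <- toy_map()
  hits <- tibble::tibble(
    marker_id = c("m1", "m1", "m2", "m2", "m3"),
    seq_id = c("sA", "sA", "sA", "sB", "sC"),
    start = c(100L, 900L, 50L, 70L, 5L),
    end = c(300L, 1100L, 250L, 270L, 205L),
    strand = "+",
    score = c(50, 40, 60, 60, 33))
  pl <- suppressMessages(resolve_placements(hits, map))
  expect_equal(pl$start[pl$marker_id == "m1"], 100L) # argmax
  expect_true(pl$ambiguous[pl$marker_id == "m2"])    # equal best, two places
  expect_true(is.na(pl$seq_id[pl$marker_id == "m2"]))
  expect_equal(pl$seq_id[pl$marker_id == "m3"], "sC") # single hit
  expect_false("m4" %in% pl$marker_id)               # zero hits: dropped
})

test_that("conflicts are sequences whose markers span several linkage groups", {
  map <- toy_map()
  pl <- tibble::tibble(
    marker_id = c("m1", "m2", "m3", "m4"),
    seq_id = c("sA", "sA", "sA", "sB"),
    start = c(100L, 400L, 900L, 10L),
    end = c(300L, 600L, 1100L, 210L),
    strand = "+", score = 50, ambiguous = FALSE)
  rep <- find_conflicts(pl, map)
  expect_true(rep$conflict[rep$seq_id == "sA"])   # LG1 + LG5
  expect_false(rep$conflict[rep$seq_id == "sB"])  # single group
  expect_false("sC" %in% rep$seq_id)              # no markers, absent
  expect_equal(attr(rep, "n_conflicts"), 1L)
})

test_that("conflict splitting follows the published three-piece rule", {
  map <- tibble::tibble(marker_id = c("a1", "a2", "b1"),
                        linkage_group = c("LG1", "LG1", "LG5"),
                        map_position = c(1, 2, 3), flank_length = 200L)
  pl <- tibble::tibble(marker_id = c("a1", "a2", "b1"),
                       seq_id = "sA",
                       start = c(100L, 2000L, 7000L),
                       end = c(300L, 2200L, 7200L),
                       strand = "+", score = 50, ambiguous = FALSE)
  x <- assembly("sA", random_dna(10000))
  sp <- split_at_conflicts(x, pl, map)
  expect_equal(sp$pieces$src_start, c(0L, 7000L))
  expect_equal(sp$pieces$src_end, c(2200L, 10000L))
  expect_equal(sp$pieces$seq_id, c("sA.p1", "sA.p2"))
  expect_equal(sp$discards$start, 2200L)
  expect_equal(sp$discards$end, 7000L)
  # three pieces in total: two kept plus one discarded middle
  expect_equal(nrow(sp$pieces) + nrow(sp$discards), 3)
  expect_equal(substr(x$bases, 1, 2200), sp$assembly$bases[1])
  # placements remapped onto the pieces
  expect_equal(sp$placements$start[sp$placements$marker_id == "b1"], 0L)
  # after splitting there are no conflicts left
  expect_equal(attr(find_conflicts(sp$placements, map), "n_conflicts"), 0L)
})

test_that("unconflicted scaffolds pass through splitting unchanged", {
  map <- toy_map()
  pl <- tibble::tibble(marker_id = c("m1", "m2"), seq_id = "sA",
                       start = c(0L, 500L), end = c(200L, 700L),
                       strand = "+", score = 10, ambiguous = FALSE)
  x <- assembly("sA", random_dna(1000))
  sp <- split_at_conflicts(x, pl, map)
  expect_identical(sp$assembly$bases, x$bases)
  expect_equal(nrow(sp$discards), 0)
})

test_that("splitting never increases kept sequence", {
  map <- tibble::tibble(marker_id = paste0("m", 1:4),
                        linkage_group = c("LG1", "LG2", "LG1", "LG2"),
                        map_position = 1:4, flank_length = 100L)
  pl <- tibble::tibble(marker_id = paste0("m", 1:4), seq_id = "sA",
                       start = c(100L, 300L, 500L, 700L),
                       end = c(200L, 400L, 600L, 800L),
                       strand = "+", score = 9, ambiguous = FALSE)
  x <- assembly("sA", random_dna(1000))
  expect_warning(sp <- split_at_conflicts(x, pl, map), "interleave")
  expect_lte(sum(nchar(sp$assembly$bases)), nchar(x$bases))
  # every kept piece is a verbatim substring at its recorded coordinates
  for (i in seq_len(nrow(sp$pieces))) {
    p <- sp$pieces[i, ]
    expect_equal(
      sp$assembly$bases[sp$assembly$seq_id == p$seq_id],
      substr(x$bases, p$src_start + 1, p$src_end))
  }
})

test_that("orientation voting reverse-complements when map order disagrees", {
  map <- tibble::tibble(marker_id = c("m1", "m2", "m3"),
                        linkage_group = "LG1",
                        map_position = c(30, 20, 10), flank_length = 50L)
  pl <- tibble::tibble(marker_id = c("m1", "m2", "m3"), seq_id = "sA",
                       start = c(100L, 200L, 300L),
                       end = c(150L, 250L, 350L),
                       strand = "+", score = 50, ambiguous = FALSE)
  x <- assembly("sA", random_dna(500))
  an <- orient_and_order(x, pl, map)
  expect_equal(an$placement$orientation, "-")
  expect_equal(an$assembly$bases, reverse_complement(x$bases))
})

test_that("single-marker scaffolds keep their orientation", {
  map <- tibble::tibble(marker_id = "m1", linkage_group = "LG1",
                        map_position = 5, flank_length = 50L)
  pl <- tibble::tibble(marker_id = "m1", seq_id = "sA", start = 10L,
                       end = 60L, strand = "-", score = 50,
                       ambiguous = FALSE)
  x <- assembly("sA", random_dna(300))
  an <- orient_and_order(x, pl, map)
  expect_equal(an$placement$orientation, "+")
  expect_equal(an$assembly$bases, x$bases)
})

test_that("anchoring joins scaffolds with the exact spacer and orders by map position", {
  map <- tibble::tibble(marker_id = c("m1", "m2"), linkage_group = "LG1",
                        map_position = c(10, 20), flank_length = 50L)
  pl <- tibble::tibble(marker_id = c("m1", "m2"),
                       seq_id = c("sA", "sB"),
                       start = 10L, end = 60L, strand = "+", score = 50,
                       ambiguous = FALSE)
  x <- assembly(c("sB", "sA"), c(random_dna(400), random_dna(300)))
  an <- orient_and_order(x, pl, map)
  expect_equal(nchar(an$assembly$bases), 300 + 100 + 400)
  expect_equal(an$placement$seq_id, c("sA", "sB")) # by map position
  expect_equal(an$placement$start_in_group, c(0L, 400L))
  g <- find_gaps(an$assembly)
  expect_equal(g$end - g$start, 100L)
  # markerless scaffolds are unplaced
  x2 <- dplyr::bind_rows(x, tibble::tibble(seq_id = "sC",
                                           bases = random_dna(100)))
  an2 <- orient_and_order(as_assembly(x2), pl, map)
  expect_equal(an2$unplaced$seq_id, "sC")
})

test_that("anchoring is idempotent on its own placement table", {
  map <- tibble::tibble(marker_id = paste0("m", 1:4),
                        linkage_group = "LG1",
                        map_position = c(5, 10, 15, 20), flank_length = 20L)
  pl <- tibble::tibble(marker_id = paste0("m", 1:4),
                       seq_id = c("sA", "sA", "sB", "sB"),
                       start = c(200L, 100L, 10L, 80L),
                       end = c(220L, 120L, 30L, 100L),
                       strand = "+", score = 20, ambiguous = FALSE)
  x <- assembly(c("sA", "sB"), c(random_dna(300), random_dna(150)))
  an <- orient_and_order(x, pl, map)
  # transform placements through the recorded order/orientation and re-run
  lens <- stats::setNames(nchar(x$bases), x$seq_id)
  pl2 <- dplyr::inner_join(pl, an$placement, by = "seq_id")
  flip <- pl2$orientation == "-"
  s <- ifelse(flip, lens[pl2$seq_id] - pl2$end, pl2$start)
  e <- ifelse(flip, lens[pl2$seq_id] - pl2$start, pl2$end)
  pl2$start <- as.integer(s); pl2$end <- as.integer(e)
  pl2 <- pl2[, names(pl)]
  x2 <- an$assembly # one sequence per group; markers remapped per scaffold
  pl3 <- dplyr::inner_join(pl2, an$placement, by = "seq_id")
  pl3$start <- pl3$start + pl3$start_in_group
  pl3$end <- pl3$end + pl3$start_in_group
  pl3$seq_id <- pl3$group
  an2 <- orient_and_order(x2, pl3[, names(pl)], map)
  expect_equal(an2$placement$orientation, "+")
  expect_equal(an2$assembly$bases, an$assembly$bases)
})
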