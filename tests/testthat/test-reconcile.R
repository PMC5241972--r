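test_that("containment removal honors identity and coverage thresholds", {
  a <- assembly(c("A", "B"), c(random_dna(5000), random_dna(1000)))
  aln <- function(qs, qe, ident) {
    tibble::tibble(refid = "A", qid = "B", rstart = 100L,
                   rend = 100L + (qe - qs), qstart = qs, qend = qe,
                   identity = ident)
  }
  r1 <- remove_contained(a, aln(0L, 1000L, 0.99))
  expect_equal(r1$removed$seq_id, "B")
  expect_equal(r1$removed$container, "A")

  r2 <- remove_contained(a, aln(0L, 1000L, 0.97)) # below "more than 98%"
  expect_equal(nrow(r2$removed), 0)

  r3 <- remove_contained(a, aln(0L, 900L, 0.99))  # only 90% covered
  expect_equal(nrow(r3$removed), 0)

  expect_error(remove_contained(a, tibble::tibble(
    refid = "Z", qid = "B", rstart = 0L, rend = 10L, qstart = 0L,
    qend = 10L, identity = 0.99)), "unknown seq_id")
})

test_that("length filtering removes strictly shorter sequences only", {
  a <- assembly(c("a", "b", "c"),
                c(random_dna(999), random_dna(1000), random_dna(1)))
  d <- drop_short(a)
  expect_equal(d$assembly$seq_id, "b")
  expect_equal(sort(d$removed$seq_id), c("a", "c"))
  empty <- drop_short(a[0, ])
  expect_equal(nrow(empty$assembly), 0)
})

make_gap_fixture <- function(donor_texts, donor_names = names(donor_texts),
                             gap_n = 5L) {
  flank1 <- "AAAA"; flank2 <- "TTTT"
  skel_seq <- paste0(flank1, strrep("N", gap_n), flank2)
  skel_text <- skel_seq
  n <- length(donor_texts)
  maf <- toy_maf(rep(0L, n + 1),
                 c("skel", donor_names),
                 c("s1", paste0("d", seq_len(n))),
                 0L, c(nchar(gsub("-", "", skel_text)),
                       nchar(gsub("-", "", donor_texts))),
                 "+",
                 c(nchar(skel_seq), rep(2000L, n)),
                 c(skel_text, unname(donor_texts)))
  list(skeleton = assembly("s1", skel_seq, name = "skel"), maf = maf)
}

test_that("gap closing replaces the N-run with the aligned donor sequence", {
  fx <- make_gap_fixture(c(pb = "AAAACCCCCTTTT"))
  cfg <- reconcile_config("skel", donor_priority = "pb", min_seq_len = 1)
  out <- close_gaps(fx$skeleton, fx$maf, cfg)
  expect_equal(out$assembly$bases, "AAAACCCCCTTTT")
  expect_equal(sum(out$events$type == "gap_closed"), 1)
  expect_equal(out$events$donor_assembly[1], "pb")
})

test_that("the least-missing-bases donor wins over a gappy priority donor", {
  fx <- make_gap_fixture(c(pb = "AAAACCNCCTTTT", alt = "AAAACCCCCTTTT"))
  cfg <- reconcile_config("skel", donor_priority = c("pb", "alt"))
  out <- close_gaps(fx$skeleton, fx$maf, cfg)
  expect_equal(out$assembly$bases, "AAAACCCCCTTTT")
  expect_equal(out$events$donor_assembly[1], "alt")

  # with no N-free candidate, fewest Ns wins; here the gap shrinks
  fx2 <- make_gap_fixture(c(pb = "AAAACCNCCTTTT", alt = "AAAACNN-CTTTT"))
  out2 <- close_gaps(fx2$skeleton, fx2$maf,
                     reconcile_config("skel",
                                      donor_priority = c("pb", "alt")))
  expect_equal(out2$assembly$bases, "AAAACCNCCTTTT")
  expect_equal(out2$events$type[1], "gap_shrunk")
})

test_that("a gap spanned by no block is left unchanged", {
  skel <- assembly("s1", "AAAANNNNNTTTT", name = "skel")
  maf <- toy_maf(0L, "skel", "s1", 0L, 3L, "+", 13L, "AAA")
  out <- close_gaps(skel, maf, reconcile_config("skel"))
  expect_equal(out$assembly$bases, "AAAANNNNNTTTT")
  expect_equal(out$events$type, "gap_unspanned")
})

test_that("donor fillings restore truth even when the gap size estimate is off", {
  # gap of 7 Ns but only 5 bp truly missing: donor pads with '-'
  skel <- assembly("s1", "AAAANNNNNNNTTTT", name = "skel")
  maf <- toy_maf(c(0L, 0L), c("skel", "pb"), c("s1", "d1"), 0L,
                 c(15L, 13L), "+", c(15L, 2000L),
                 c("AAAANNNNNNNTTTT", "AAAACCCCC--TTTT"))
  out <- close_gaps(skel, maf, reconcile_config("skel"))
  expect_equal(out$assembly$bases, "AAAACCCCCTTTT")

  # gap of 3 Ns but 5 bp missing: skeleton row padded with '-'
  skel2 <- assembly("s1", "AAAANNNTTTT", name = "skel")
  maf2 <- toy_maf(c(0L, 0L), c("skel", "pb"), c("s1", "d1"), 0L,
                  c(11L, 13L), "+", c(11L, 2000L),
                  c("AAAANNN--TTTT", "AAAACCCCCTTTT"))
  out2 <- close_gaps(skel2, maf2, reconcile_config("skel"))
  expect_equal(out2$assembly$bases, "AAAACCCCCTTTT")
})

make_join_fixture <- function(bridge_strand = c("+", "+"),
                              b2_start = 600L) {
  s1 <- random_dna(1000); s2 <- random_dna(1000)
  bridge <- paste0(substr(s1, 501, 1000), "GATTACAGATT",
                   substr(s2, 1, 500))
  skel <- assembly(c("s1", "s2"), c(s1, s2), name = "skel")
  maf <- dplyr::bind_rows(
    toy_maf(c(0L, 0L), c("skel", "pb"), c("s1", "b1"), c(500L, 0L), 500L,
            c("+", bridge_strand[1]), c(1000L, nchar(bridge)),
            substr(s1, 501, 1000)),
    toy_maf(c(1L, 1L), c("skel", "pb"), c("s2", "b1"), c(0L, 511L), 500L,
            c("+", bridge_strand[2]), c(1000L, nchar(bridge)),
            substr(s2, 1, 500)))
  attr(maf, "donor_assemblies") <-
    list(pb = assembly("b1", bridge, name = "pb"))
  list(skeleton = skel, maf = maf, s1 = s1, s2 = s2,
       filler = "GATTACAGATT")
}

test_that("a spanning donor joins two scaffolds with its intervening sequence", {
  fx <- make_join_fixture()
  cfg <- reconcile_config("skel", donor_priority = "pb", min_seq_len = 1)
  out <- join_scaffolds(fx$skeleton, fx$maf, cfg)
  expect_equal(nrow(out$assembly), 1)
  expect_equal(out$assembly$bases, paste0(fx$s1, fx$filler, fx$s2))
  expect_equal(out$assembly$seq_id, "s1+s2")
  expect_equal(sum(out$events$type == "join"), 1)
})

test_that("inconsistent bridge orientations block a join", {
  fx <- make_join_fixture(bridge_strand = c("+", "-"))
  out <- join_scaffolds(fx$skeleton, fx$maf,
                        reconcile_config("skel", donor_priority = "pb"))
  expect_equal(nrow(out$assembly), 2)
  expect_equal(sum(out$events$type == "join"), 0)
})

test_that("joins uniting different linkage groups are refused", {
  fx <- make_join_fixture()
  map <- tibble::tibble(marker_id = c("m1", "m2"),
                        linkage_group = c("LG1", "LG3"),
                        map_position = c(1, 2), flank_length = 100L)
  placements <- tibble::tibble(marker_id = c("m1", "m2"),
                               seq_id = c("s1", "s2"),
                               start = c(100L, 100L), end = c(200L, 200L),
                               strand = "+", score = 100,
                               ambiguous = FALSE)
  out <- join_scaffolds(fx$skeleton, fx$maf,
                        reconcile_config("skel", donor_priority = "pb"),
                        placements = placements, map = map)
  expect_equal(sum(out$events$type == "join"), 0)
  expect_true(any(out$events$reason == "linkage_conflict"))
})

test_that("reconciling an assembly with itself is the identity", {
  set.seed(13)
  a <- assembly(c("s1", "s2"),
                c(paste0(random_dna(1500), "NNNNN", random_dna(1500)),
                  random_dna(2000)), name = "only")
  maf <- dplyr::bind_rows(
    toy_maf(0L, "only", "s1", 0L, 3005L, "+", 3005L,
            a$bases[1]),
    toy_maf(1L, "only", "s2", 0L, 2000L, "+", 2000L, a$bases[2]))
  rec <- reconcile(list(only = a), maf, reconcile_config("only"))
  expect_identical(rec$assembly$bases, a$bases)
  expect_identical(rec$assembly$seq_id, a$seq_id)
  g <- glance(rec)
  expect_equal(g$gaps_closed + g$gaps_shrunk + g$joins_made +
                 g$sequences_removed_contained + g$sequences_removed_short,
               0L)
})

test_that("the full pipeline closes fixture gaps and makes planted joins", {
  cfg <- fixture_config(seed = 23, genome_len = 1e5, n_chromosomes = 1,
                        te_count = 4, break_at_tr_prob = 0.15,
                        scaffold_break_prob = 0.3)
  tr <- simulate_genome(cfg)
  fx <- fragment_assemblies(tr, cfg)
  pl <- suppressMessages(resolve_placements(fx$hits, fx$map))
  rcfg <- reconcile_config(fx$skeleton, donor_priority = fx$donor_priority)
  rec <- suppressMessages(reconcile(fx$drafts, fx$maf, rcfg,
                                    map = fx$map, placements = pl))
  ev <- rec$events
  expect_equal(sum(ev$type == "gap_closed"), sum(fx$gaps$closable))
  pj <- fx$junctions[fx$junctions$planted, ]
  joined <- mapply(function(a, b)
    any(ev$type == "join" & !is.na(ev$s1) & ev$s1 == a & ev$s2 == b),
    pj$s1, pj$s2)
  expect_true(all(joined))
  # contiguity never degrades
  expect_gte(assembly_stats(rec$assembly)$contig_n50,
             assembly_stats(fx$drafts[[fx$skeleton]])$contig_n50)
  expect_lte(assembly_stats(rec$assembly)$gap_bp,
             assembly_stats(fx$drafts[[fx$skeleton]])$gap_bp)
})
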