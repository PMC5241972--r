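small_cfg <- function(seed = 5, ...) {
  fixture_config(seed = seed, genome_len = 5e4, n_chromosomes = 2,
                 te_count = 4, ...)
}

test_that("genome simulation is deterministic and hits the density target", {
  cfg <- fixture_config(seed = 1, genome_len = 1e5, n_chromosomes = 1,
                        te_count = 4, tr_density_target = 0.10)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1$genome$bases, t2$genome$bases)
  expect_identical(t1$trs, t2$trs)
  planted <- sum(t1$trs$end - t1$trs$start) / 1e5
  expect_gte(planted, 0.08)
  expect_lte(planted, 0.12)

  t0 <- simulate_genome(small_cfg(tr_density_target = 0))
  expect_equal(nrow(t0$trs), 0)
  expect_error(simulate_genome(small_cfg(tr_density_target = 0.4)),
               "infeasible")
})

test_that("planted repeats are recovered by the detector at high recall", {
  cfg <- fixture_config(seed = 5, genome_len = 1e5, n_chromosomes = 1,
                        te_count = 4)
  tr <- simulate_genome(cfg)
  found <- detect_trs(tr$genome)
  hit <- vapply(seq_len(nrow(tr$trs)), function(i) {
    p <- tr$trs[i, ]
    f <- found[found$seq_id == p$seq_id & found$start < p$end &
                 found$end > p$start, ]
    any(f$unit == p$unit)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # and the measured density is close to the planted density
  sm <- tr_summary(tr$genome, found)
  expect_lt(abs(glance(sm)$density_pct / 100 - cfg$tr_density_target), 0.03)
})

test_that("diploid simulation plants unit-multiple repeat indels at the set rate", {
  cfg <- small_cfg(seed = 9, het_tr_fraction = 0.2)
  tr <- simulate_genome(cfg)
  dip <- simulate_diploid(tr, cfg)
  tri <- dip$variants[dip$variants$origin == "tr_indel", ]
  n <- nrow(tr$trs)
  expect_gt(nrow(tri), n * 0.2 - 3 * sqrt(n * 0.2 * 0.8))
  expect_lt(nrow(tri), n * 0.2 + 3 * sqrt(n * 0.2 * 0.8))
  # indel length is a whole number of repeat units
  sz <- abs(nchar(tri$ref) - nchar(tri$alt))
  us <- tr$trs$unit_size[match(
    paste(tri$seq_id, tri$pos),
    paste(tr$trs$seq_id, tr$trs$start))]
  expect_true(all(sz %% us == 0))
  expect_true(all(tri$genotype == "0/1"))

  none <- simulate_diploid(tr, small_cfg(seed = 9, het_tr_fraction = 0))
  expect_equal(sum(none$variants$origin == "tr_indel"), 0)
})

test_that("planted heterozygous-repeat fraction is recovered end to end", {
  cfg <- fixture_config(seed = 12, genome_len = 1e5, n_chromosomes = 1,
                        te_count = 2, het_tr_fraction = 0.21)
  tr <- simulate_genome(cfg)
  dip <- simulate_diploid(tr, cfg)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(dip$variants, p)
  v <- read_vcf(p)
  v <- filter_variants(v, het_only = TRUE)
  ind <- v[v$vclass == "indel", ]
  res <- het_tr_call(tr$trs, ind)
  n <- res$n_trs
  ci <- 1.96 * sqrt(0.21 * 0.79 / n)
  expect_lt(abs(res$fraction - 0.21), ci + 0.02)
})

test_that("fragmentation is deterministic and drafts cover the truth", {
  cfg <- small_cfg(seed = 4, break_at_tr_prob = 0.2,
                   scaffold_break_prob = 0.3)
  tr <- simulate_genome(cfg)
  f1 <- fragment_assemblies(tr, cfg)
  f2 <- fragment_assemblies(tr, cfg)
  expect_identical(f1$drafts$draft_ilm$bases, f2$drafts$draft_ilm$bases)
  expect_identical(f1$maf, f2$maf)
  # with no breaks (and no TE loci for the long-read draft to break at)
  # every draft equals the truth genome
  cfg0 <- fixture_config(seed = 4, genome_len = 5e4, n_chromosomes = 2,
                         te_count = 0, break_at_tr_prob = 0,
                         break_random_prob = 0, scaffold_break_prob = 0)
  tr0 <- simulate_genome(cfg0)
  f0 <- fragment_assemblies(tr0, cfg0)
  expect_equal(sort(nchar(f0$drafts$draft_ilm$bases)),
               sort(nchar(tr0$genome$bases)))
  expect_setequal(f0$drafts$draft_pb$bases, tr0$genome$bases)
})

test_that("every emitted format round-trips through the package readers", {
  cfg <- small_cfg(seed = 6, break_at_tr_prob = 0.2,
                   scaffold_break_prob = 0.3)
  tr <- simulate_genome(cfg)
  fx <- fragment_assemblies(tr, cfg)
  dir <- withr::local_tempdir()
  write_fixture_set(fx, dir)
  for (dn in names(fx$drafts)) {
    back <- read_fasta(file.path(dir, paste0(dn, ".fasta")))
    expect_equal(back$bases, fx$drafts[[dn]]$bases)
  }
  maf_back <- parse_maf(file.path(dir, "alignments.maf"))
  expect_equal(as.data.frame(maf_back[, names(fx$maf)]),
               as.data.frame(fx$maf))
  map_back <- load_linkage_map(file.path(dir, "linkage_map.tsv"))
  expect_equal(as.data.frame(map_back), as.data.frame(fx$map))
})

test_that("skeleton gaps sit exactly over their missing truth segments", {
  cfg <- small_cfg(seed = 8, break_at_tr_prob = 0.3,
                   scaffold_break_prob = 0.2)
  tr <- simulate_genome(cfg)
  fx <- fragment_assemblies(tr, cfg)
  skel <- fx$drafts[[fx$skeleton]]
  found <- find_gaps(skel)
  found_key <- paste(found$seq_id, found$start, found$end)
  truth_key <- paste(fx$gaps$seq_id, fx$gaps$gap_start, fx$gaps$gap_end)
  expect_setequal(truth_key, found_key)
})

test_that("depth simulation yields the configured zero-coverage holes", {
  cfg <- small_cfg(seed = 2)
  tr <- simulate_genome(cfg)
  holes <- tibble::tibble(seq_id = "chr1", start = c(100L, 900L),
                          end = c(200L, 950L))
  d <- simulate_depth(tr, holes)
  z <- zero_coverage(d, tr$genome)
  expect_equal(as.data.frame(z[z$seq_id == "chr1", ]),
               as.data.frame(holes))
})
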