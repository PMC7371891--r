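test_that("major-isoform selection keeps the longest CDS unless a canonical list overrides", {
  fa <- write_tmp_fasta(c(
    "geneX|t1" = strrep("ACG", 100),   # 300 nt
    "geneX|t2" = strrep("TGC", 50),    # 150 nt
    "geneY"    = "ATGAAATAG"))
  g <- read_cds_fasta(fa)
  expect_equal(g$n_genes, 2L)
  expect_equal(nchar(g$cds[["geneX"]]), 300L)
  expect_equal(g$cds[["geneY"]], "ATGAAATAG")

  g2 <- read_cds_fasta(fa, canonical_list = c(geneX = "t2"))
  expect_equal(g2$cds[["geneX"]], strrep("TGC", 50))

  # equal lengths: lexicographically smallest record id wins
  fa_tie <- write_tmp_fasta(c("geneZ|b" = "ACGACG", "geneZ|a" = "TGCTGC"))
  expect_equal(read_cds_fasta(fa_tie)$cds[["geneZ"]], "TGCTGC")
})

test_that("FASTA reader rejects empty files and duplicate ids by name", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_cds_fasta(empty), "empty")
  fa <- write_tmp_fasta(c(gA = "ACGT", gA = "TTTT"))
  expect_error(read_cds_fasta(fa), "gA")
})

test_that("HGVS coding-change strings parse into SNV and MNV records", {
  p <- parse_hgvs_c(c("c.215C>G", "c.375_376CC>TT", "c.10delA", "c.5A>A"))
  expect_equal(p$cds_pos[1], 215L)
  expect_equal(p$ref[1], "C")
  expect_equal(p$alt[1], "G")
  expect_false(p$is_mnv[1])
  expect_true(p$ok[1])
  expect_true(p$is_mnv[2] && p$ok[2])
  expect_equal(p$ref[2], "CC")
  expect_false(p$ok[3])   # deletion
  expect_false(p$ok[4])   # ref == alt
})

test_that("cosmic dialect: mixed file yields SNVs, one MNV, and logged skips", {
  tab <- data.frame(gene = "TP53", sample = paste0("s", 1:5),
                    primary_site = "lung",
                    hgvs_c = c("c.215C>G", "c.742C>T", "c.817C>T",
                               "c.375_376CC>TT", "c.100delA"),
                    stringsAsFactors = FALSE)
  rec <- read_mutation_table(write_tmp_tsv(tab), dialect = "cosmic")
  expect_equal(sum(!rec$is_mnv), 3L)
  expect_equal(sum(rec$is_mnv), 1L)
  expect_equal(attr(rec, "n_skipped_indel"), 1L)
  expect_equal(attr(rec, "n_skipped_unparsed"), 0L)
})

test_that("generic dialect requires its mandatory columns", {
  tab <- data.frame(gene = "g", sample = "s", cds_pos = 1, ref = "A",
                    alt = "C")
  expect_error(read_mutation_table(write_tmp_tsv(tab)), "cancer_type")
})

test_that("events count distinct samples, overall and per cancer type", {
  # 10 distinct samples, same change -> O = 10
  r1 <- rec_df("g", paste0("s", 1:10), "colorectal", 5, "C", "T")
  e1 <- aggregate_events(r1)
  expect_equal(e1$original_count, 10L)

  # same change twice from one sample -> O = 1
  r2 <- rec_df("g", c("s1", "s1"), "lung", 5, "C", "T")
  expect_equal(aggregate_events(r2)$original_count, 1L)

  # 10 colorectal + 5 lung records of one change
  r3 <- rbind(rec_df("g", paste0("c", 1:10), "colorectal", 5, "C", "T"),
              rec_df("g", paste0("l", 1:5), "lung", 5, "C", "T"))
  e3 <- aggregate_events(r3)
  expect_equal(e3$original_count, 15L)
  pt <- event_type_counts(e3)
  expect_equal(pt$count[pt$cancer_type == "colorectal"], 10L)
  expect_equal(pt$count[pt$cancer_type == "lung"], 5L)
})

test_that("total original counts equal distinct (sample, change) tuples", {
  set.seed(42)
  rec <- rec_df(sample(c("g1", "g2"), 200, TRUE),
                sample(paste0("s", 1:30), 200, TRUE),
                sample(c("lung", "skin"), 200, TRUE),
                sample(5:20, 200, TRUE),
                "C", sample(c("A", "G", "T"), 200, TRUE))
  ev <- aggregate_events(rec)
  tuples <- unique(rec[c("sample", "gene", "cds_pos", "ref", "alt")])
  expect_equal(sum(ev$original_count), nrow(tuples))
  pt <- event_type_counts(ev)
  expect_equal(sum(pt$count), nrow(tuples))
})

test_that("an MNV producing the same protein change sets mnv_support", {
  g <- coding_genome(c(gm = "ATGTCCGGGAAA"))  # M S G K
  rec <- rbind(rec_df("gm", paste0("s", 1:5), "lung", 5, "C", "T"),  # TCC->TTC = S2F
               rec_df("gm", "s9", "lung", 5, "CC", "TT", is_mnv = TRUE)) # TCC->TTT = S2F
  ev <- aggregate_events(rec, g)
  expect_true(ev$mnv_support[ev$cds_pos == 5 & ev$alt == "T"])
  # without the genome the flag cannot be resolved
  expect_false(any(aggregate_events(rec)$mnv_support))
})

test_that("recurrence filter drops events above the cutoff and is idempotent", {
  rec <- rbind(rec_df("g", paste0("a", 1:6), "lung", 5, "C", "T"),  # O = 6
               rec_df("g", paste0("b", 1:5), "lung", 7, "G", "A"),  # O = 5
               rec_df("g", "c1", "lung", 9, "A", "G"))              # O = 1
  ev <- aggregate_events(rec)
  kept <- filter_recurrent(rec, ev, max_samples = 5)
  expect_false(any(kept$cds_pos == 5))     # "more than five" excluded
  expect_equal(sum(kept$cds_pos == 7), 5L) # boundary kept
  expect_equal(attr(kept, "excluded_fraction"), 6 / 12)
  again <- filter_recurrent(kept, aggregate_events(kept), max_samples = 5)
  expect_equal(again[names(kept)], kept[names(kept)])
  expect_error(filter_recurrent(rec, ev, max_samples = 0), "max_samples")
})

test_that("a half-cohort driver is excluded with a hand-computable fraction", {
  driver <- rec_df("g", paste0("s", 1:50), "lung", 11, "C", "A")
  passengers <- rec_df("g", paste0("s", 1:50), "lung", 14, "G", "T")[1:2, ]
  rec <- rbind(driver, passengers)
  kept <- filter_recurrent(rec, aggregate_events(rec))
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "excluded_fraction"), 50 / 52)
})

test_that("events written to tab-separated text round-trip field-for-field", {
  rec <- rbind(rec_df("g1", paste0("c", 1:10), "colorectal", 5, "C", "T"),
               rec_df("g1", paste0("l", 1:5), "lung", 5, "C", "T"),
               rec_df("g2", "x1", "skin", 8, "A", "G"))
  ev <- aggregate_events(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back, ev, ignore_attr = "per_type")
  expect_equal(event_type_counts(back), event_type_counts(ev))
})
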