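# Toy setup shared by the revised-count tests: one gene, one assessable
# event class, difficulty tables engineered through the real constructor
# path (reference_rate / tendency ratios give exact difficulties).
revise_fixture <- function() {
  g <- coding_genome(c(tp = "ACGTACGTACGTACG"))
  # position 8 (T) in pentamer CGTAC; alt G
  pent <- "CGTAC"
  r <- 1e-6
  tt <- tendency_table(pent, "G", r)
  list(genome = g, pent = pent, rate = r, tt = tt,
       table_for = function(difficulty, scope)
         build_difficulty(tt, reference_rate = difficulty * r, scope = scope))
}

test_that("revised count is the difficulty-weighted sum over cancer types", {
  fx <- revise_fixture()
  rec <- rbind(rec_df("tp", paste0("c", 1:10), "colorectal", 8, "T", "G"),
               rec_df("tp", paste0("l", 1:5), "lung", 8, "T", "G"))
  ev <- aggregate_events(rec)
  tabs <- list(colorectal = fx$table_for(1, "colorectal"),
               lung = fx$table_for(3, "lung"))
  a <- revised_count(ev, fx$genome, fx$table_for(1, "pan-cancer"), tabs)
  expect_equal(a$revised_count, 10 * 1 + 5 * 3)
  expect_equal(a$original_count, 15L)
  expect_equal(sort(a$contributions$contribution), c(10, 15))
})

test_that("a single-type event scales its original count by one difficulty", {
  fx <- revise_fixture()
  rec <- rec_df("tp", paste0("s", 1:11), "lung", 8, "T", "G")
  ev <- aggregate_events(rec)
  a <- revised_count(ev, fx$genome, fx$table_for(233, "pan-cancer"))
  expect_equal(a$revised_count, 11 * 233)
})

test_that("types without their own table fall back to the pan-cancer one", {
  fx <- revise_fixture()
  rec <- rbind(rec_df("tp", paste0("c", 1:2), "colorectal", 8, "T", "G"),
               rec_df("tp", "x1", "skin", 8, "T", "G"))
  ev <- aggregate_events(rec)
  a <- revised_count(ev, fx$genome, fx$table_for(5, "pan-cancer"),
                     list(colorectal = fx$table_for(2, "colorectal")))
  expect_equal(a$revised_count, 2 * 2 + 1 * 5)
})

test_that("assessment errors are informative for degenerate inputs", {
  fx <- revise_fixture()
  # undefined difficulty class -> advice to use the pseudocount policy
  tt0 <- tendency_table(fx$pent, "G", 0, sites_per_genome = 10L,
                        count = 0L, n_genomes = 100L)
  undef <- build_difficulty(tt0, reference_rate = 1e-5)
  ev <- aggregate_events(rec_df("tp", "s1", "lung", 8, "T", "G"))
  expect_error(revised_count(ev, fx$genome, undef), "pseudocount")
  # context-unavailable event names the site
  ev_edge <- aggregate_events(rec_df("tp", "s1", "lung", 1, "A", "G"))
  expect_error(revised_count(ev_edge, fx$genome, fx$table_for(1, "pan")),
               "tp:1:A:G")
})

test_that("functional classification follows the strict 700/900 contract", {
  expect_equal(classify_functional(186), "wt_like")
  expect_equal(classify_functional(2887), "lof")
  expect_equal(classify_functional(c(700, 800, 900)),
               rep("indeterminate", 3))
  expect_equal(classify_functional(400, mnv_support = TRUE), "unscored")
  expect_equal(classify_functional(2887, mnv_support = TRUE), "lof")
  expect_error(classify_functional(1, wt_max = 1000, lof_min = 900), "wt_max")
})

test_that("classification is monotone in the revised count", {
  r <- sort(c(0, 150, 699.9, 700, 899, 900, 900.1, 5000))
  lab <- classify_functional(r)
  rank <- c(wt_like = 1, indeterminate = 2, lof = 3)[lab]
  expect_true(all(diff(rank) >= 0))
})

test_that("threshold calibration is an order statistic of the synonymous sample", {
  set.seed(9)
  x <- runif(40, 10, 650)
  cal <- calibrate_thresholds(x, percentile = 95)
  expect_equal(cal$wt_max, sort(x)[ceiling(0.95 * 40)])  # brute-force oracle
  expect_lte(cal$wt_max, 700)
  expect_equal(nrow(cal$outliers), sum(x > cal$wt_max))

  # degenerate all-equal distribution
  expect_equal(calibrate_thresholds(rep(5, 25))$wt_max, 5)

  # single huge outlier: listed, percentile robust to it
  y <- c(runif(24, 10, 300), 5000)
  cal2 <- calibrate_thresholds(y, percentile = 95)
  expect_lt(cal2$wt_max, 400)
  expect_true(5000 %in% cal2$outliers$revised_count)

  expect_error(calibrate_thresholds(runif(10)), "default thresholds")
})

test_that("gene annotation matches row-by-row manual computation", {
  g <- coding_genome(c(tp = "ATGCCTAGACCTTACGGA"))  # M P R P Y G
  # all classes present at uniform tendency; reference 4x -> difficulty 4
  cl <- all_context_classes()
  tt <- tendency_table(cl$pentamer, cl$alt, rep(2.5e-6, nrow(cl)))
  pan <- build_difficulty(tt, reference_rate = 1e-5)
  rec <- rbind(
    rec_df("tp", paste0("a", 1:3), "lung", 5, "C", "T"),   # P2L missense
    rec_df("tp", paste0("b", 1:2), "lung", 6, "T", "A"),   # P2P synonymous
    rec_df("tp", "c1", "lung", 8, "G", "T"),               # R3M? manual below
    rec_df("tp", paste0("d", 1:4), "lung", 10, "C", "A"),  # P4T missense
    rec_df("tp", "e1", "lung", 13, "T", "A"))              # Y5N missense
  ev <- aggregate_events(rec)
  ann <- annotate_gene(ev, "tp", g, pan)
  expect_equal(nrow(ann), 5L)
  expect_equal(ann$revised_count, ann$original_count * 4)
  expect_equal(ann$original_count[match("c.5C>T", ann$cds_change)], 3L)
  expect_equal(ann$consequence[match("c.6T>A", ann$cds_change)], "synonymous")
  expect_true(all(ann$label == "wt_like"))

  # per-residue aggregation sums events sharing an amino acid
  rees <- annotate_gene(ev, "tp", g, pan, by_residue = TRUE)
  expect_equal(rees$original_count[rees$residue == 2], 3 + 2)
  expect_equal(rees$revised_count[rees$residue == 2], (3 + 2) * 4)
  expect_equal(rees$n_events[rees$residue == 2], 2L)
})

test_that("with all difficulties 1 the revised ranking equals the original", {
  g <- coding_genome(c(tp = random_cds(60, seed = 21)))
  cl <- all_context_classes()
  pan <- build_difficulty(tendency_table(cl$pentamer, cl$alt,
                                         rep(1e-5, nrow(cl))))
  pos <- c(10, 20, 30)
  ref <- substring(g$cds[["tp"]], pos, pos)
  alt <- vapply(ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  rec <- do.call(rbind, lapply(seq_along(pos), function(i)
    rec_df("tp", paste0("s", i, "_", seq_len(i * 2)), "lung",
           pos[i], ref[i], alt[i])))
  ann <- annotate_gene(aggregate_events(rec), "tp", g, pan)
  expect_equal(ann$revised_count, as.numeric(ann$original_count))
  expect_equal(order(ann$revised_count), order(ann$original_count))
})

test_that("annotation of a gene with no events yields an empty table", {
  g <- toy_genome()
  cl <- all_context_classes()
  pan <- build_difficulty(tendency_table(cl$pentamer, cl$alt,
                                         rep(1e-5, nrow(cl))))
  ev <- aggregate_events(rec_df(character(0), character(0), character(0),
                                integer(0), character(0), character(0)))
  expect_equal(nrow(annotate_gene(ev, "gA", g, pan)), 0L)
})

test_that("resistance index follows the competition-assay formula", {
  expect_equal(resistance_index(0.3, 0.6), 3.5)
  expect_equal(resistance_index(0.5, 0.25), 1 / 3)
  for (g1 in c(0.1, 0.4, 0.8)) expect_equal(resistance_index(g1, g1), 1)
  # strictly increasing in G2
  ri <- resistance_index(0.3, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_true(all(diff(ri) > 0))
  expect_error(resistance_index(0, 0.5), "undefined")
  expect_error(resistance_index(1, 0.5), "undefined")
  expect_error(resistance_index(0.5, 1), "undefined")
})
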