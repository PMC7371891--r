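test_that("tendency is count over sites times genomes", {
  expect_equal(mutation_tendency(10, 5, 2), 1)
  expect_true(is.na(mutation_tendency(3, 0, 2)))
  expect_error(mutation_tendency(3, 5, 0), "n_genomes")
})

test_that("estimated tendencies equal hand-computed quotients on a toy catalog", {
  g <- coding_genome(c(g = "AATTCGTAA"))  # windows: AATTC ATTCG TTCGT TCGTA CGTAA
  rec <- rbind(rec_df("g", c("s1", "s2"), "lung", 5, "C", "T"),
               rec_df("g", "s3", "lung", 6, "G", "A"))
  tt <- estimate_tendencies(rec, g, n_genomes = 10)
  expect_equal(nrow(tt), 3072L)
  expect_equal(tt$tendency[tt$class == "TTCGT>T"], 2 / (1 * 10))
  expect_equal(tt$tendency[tt$class == "TCGTA>A"], 1 / (1 * 10))
  # zero-count class on an existing pentamer has tendency 0
  expect_equal(tt$tendency[tt$class == "TTCGT>A"], 0)
  # pentamers absent from the genome are undefined and reported
  expect_true(is.na(tt$tendency[tt$class == "AAAAA>C"]))
  expect_equal(attr(tt, "n_no_sites"),
               sum(tt$sites_per_genome == 0))
  expect_error(estimate_tendencies(rec, g, 0), "n_genomes")
})

test_that("difficulty is the reference rate over the tendency", {
  tt <- tendency_table(c("AACAA", "AACAA", "TTCGT"), c("G", "T", "T"),
                       tendency = c(1e-5, 1e-6, 0),
                       sites_per_genome = c(10, 10, 5),
                       count = c(10, 1, 0), n_genomes = 100)
  d <- build_difficulty(tt)
  expect_equal(attr(d, "reference_rate"), 1e-5)
  expect_equal(d$difficulty[d$class == "AACAA>G"], 1)   # reference class
  expect_equal(d$difficulty[d$class == "AACAA>T"], 10)
  # zero-count class undefined by default
  expect_true(is.na(d$difficulty[d$class == "TTCGT>T"]))
  expect_equal(d$flag[d$class == "TTCGT>T"], "undefined")

  dp <- build_difficulty(tt, zero_policy = "pseudocount", pseudocount = 0.5)
  expect_equal(dp$tendency[dp$class == "TTCGT>T"], 0.5 / (5 * 100))
  expect_equal(dp$difficulty[dp$class == "TTCGT>T"], 1e-5 / (0.5 / 500))
  expect_equal(dp$flag[dp$class == "TTCGT>T"], "pseudocount")

  expect_error(build_difficulty(tt, reference_rate = 0), "reference_rate")
})

test_that("difficulty is scale-free and monotone in the class count", {
  g <- coding_genome(c(g = random_cds(200, seed = 5)))
  pos <- c(10, 10, 25, 40, 40, 40)
  ref <- substring(g$cds[["g"]], pos, pos)
  alt <- vapply(ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  rec1 <- rec_df("g", paste0("s", seq_along(pos)), "lung", pos, ref, alt)
  # triplicate every record under new sample ids: all counts scale by 3
  rec3 <- do.call(rbind, lapply(1:3, function(k) {
    r <- rec1; r$sample <- paste0(r$sample, "_", k); r
  }))
  d1 <- build_difficulty(estimate_tendencies(rec1, g, 50))
  d3 <- build_difficulty(estimate_tendencies(rec3, g, 50))
  expect_equal(d1$difficulty, d3$difficulty)

  # monotonicity: same sites and N, larger count never raises difficulty
  tt <- tendency_table(rep("AACAA", 3), rep("G", 3),
                       tendency = mutation_tendency(c(1, 5, 25), 100, 10))
  expect_true(all(diff(build_difficulty(tt)$difficulty) <= 0))
})

test_that("cancer-type tables reuse the pan-cancer reference and fall back when sparse", {
  g <- coding_genome(c(g = random_cds(300, seed = 8)))
  pos <- sample(3:298, 40, replace = TRUE)
  ref <- substring(g$cds[["g"]], pos, pos)
  alt <- vapply(ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
  rec <- rec_df("g", paste0("s", 1:40), "lung", pos, ref, alt)

  tt <- estimate_tendencies(rec, g, n_genomes = 150)
  pan <- build_difficulty(tt)
  out <- cancer_type_difficulty(rec, g, c(lung = 150, rare = 10),
                                pan_reference_rate = attr(pan, "reference_rate"))
  # a type with the pan-cancer records and N reproduces the pan difficulties
  expect_equal(out$lung$difficulty, pan$difficulty)
  expect_equal(attr(out, "fallback_types"), "rare")
  expect_error(
    cancer_type_difficulty(rec, g, c(skin = 100), pan_reference_rate = 1e-5),
    "unknown cancer type")
})

test_that("per-type difficulties below 1 mark easier-than-reference classes", {
  # endometrial-style example: a type with a much higher class rate than the
  # pan-cancer reference gets difficulty < 1
  t_pan <- mutation_tendency(10389, 21446, 26154)
  t_endo <- mutation_tendency(1195, 21446, 296)
  tt <- tendency_table("TTCGT", "T", t_endo, 21446, 1195, 296)
  d <- build_difficulty(tt, reference_rate = t_pan, scope = "endometrial")
  expect_lt(d$difficulty[1], 1)
})

test_that("difficulty tables round-trip through their text serialization", {
  tt <- tendency_table(c("AACAA", "TTCGT"), c("G", "T"),
                       tendency = c(1.85e-5, 0.93e-7),
                       sites_per_genome = c(100, 21446),
                       count = c(50, 10), n_genomes = 26154)
  d <- build_difficulty(tt, scope = "pan-cancer")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_difficulty_table(d, path)
  back <- read_difficulty_table(path)
  expect_equal(back$difficulty, d$difficulty, tolerance = 1e-12)
  expect_equal(attr(back, "scope"), "pan-cancer")
  expect_equal(attr(back, "reference_rate"), attr(d, "reference_rate"))
  expect_equal(lookup_difficulty(back, "TTCGT", "T")$difficulty,
               d$difficulty[d$class == "TTCGT>T"], tolerance = 1e-12)
})
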