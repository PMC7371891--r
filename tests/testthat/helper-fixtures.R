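# Shared toy fixtures, all built in code.

# Three-gene toy genome: gA exercises interior windows, gB flank-padded
# edges, gC a flankless edge and an ambiguous base.
toy_genome <- function() {
  coding_genome(
    c(gA = "AATTCGTAA", gB = "TGCAAATGC", gC = "ACNTTGCA"),
    flanks = list(gB = list(up = "CA", down = "GT")))
}

write_tmp_fasta <- function(seqs, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

write_tmp_tsv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_cds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force pentamer window counter (oracle).
brute_force_sites <- function(cds_vec) {
  counts <- integer(0)
  skipped <- 0L
  for (cds in cds_vec) {
    L <- nchar(cds)
    if (L < 5L) next
    for (i in 1:(L - 4L)) {
      w <- substr(cds, i, i + 4L)
      if (grepl("[^ACGT]", w)) { skipped <- skipped + 1L; next }
      counts[w] <- (if (is.na(counts[w])) 0L else counts[w]) + 1L
    }
  }
  list(counts = counts, skipped = skipped)
}

# Generic record constructor for hand-built catalogs.
rec_df <- function(gene, sample, cancer_type, cds_pos, ref, alt,
                   is_mnv = FALSE) {
  n <- max(length(gene), length(sample), length(cds_pos))
  data.frame(gene = rep_len(gene, n), sample = rep_len(sample, n),
             cancer_type = rep_len(cancer_type, n),
             cds_pos = rep_len(as.integer(cds_pos), n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             is_mnv = rep_len(is_mnv, n), stringsAsFactors = FALSE)
}

# Uniform tendency table over all 3072 classes.
uniform_tendencies <- function(rate = 1e-5) {
  cl <- all_context_classes()
  tendency_table(cl$pentamer, cl$alt, rep(rate, nrow(cl)))
}
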