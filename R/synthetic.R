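#' Specification for a synthetic coding genome and mutation catalog
#'
#' Defines the study conditions a simulated catalog emulates: a coding
#' genome of `n_genes` CDSs, per-class true mutation rates (per site, per
#' alternate allele, per sample), cancer types with per-type burden
#' multipliers and sample counts, and selectively enriched driver events.
#'
#' @param n_genes Number of genes (default 20).
#' @param gene_lengths Integer vector of CDS lengths, recycled to `n_genes`;
#'   must be multiples of 3 (default 1500, i.e. 500 codons, giving a 30 kb
#'   coding genome at the default `n_genes`).
#' @param gc GC content of the simulated genome (default 0.52, typical of
#'   human coding sequence).
#' @param baseline_rate Per-site, per-alt, per-sample mutation probability
#'   for classes with multiplier 1 (default 3e-5).
#' @param rate_multipliers Named numeric vector keyed by central substitution
#'   (e.g. `c("C>T" = 10)`); unnamed routes keep multiplier 1. Ignored when
#'   `rate_map` is given.
#' @param rate_map Optional full named rate vector keyed by class id
#'   (`"PENTAMER>ALT"`); classes absent from it get rate 0.
#' @param cancer_types data.frame with columns `type`, `n_samples`,
#'   `multiplier` (default one type, 200 samples, multiplier 1).
#' @param drivers Optional data.frame with columns `gene`, `cds_pos`, `alt`,
#'   `prob`: per-sample probability that the driver event is present
#'   (selection-driven enrichment, on top of the background rate).
#' @param mnvs Optional data.frame with columns `gene`, `cds_pos`, `ref`,
#'   `alt`, `n_samples` injecting fixed-count multi-nucleotide records.
#' @param seed Random seed fixing genome and catalog (default 1).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20, gene_lengths = 1500, gc = 0.52,
                           baseline_rate = 3e-5, rate_multipliers = NULL,
                           rate_map = NULL,
                           cancer_types = data.frame(
                             type = "pan", n_samples = 200, multiplier = 1),
                           drivers = NULL, mnvs = NULL, seed = 1) {
  if (n_genes < 1) stop("need at least one gene")
  gene_lengths <- rep_len(as.integer(gene_lengths), n_genes)
  if (any(gene_lengths %% 3L != 0L) || any(gene_lengths < 3L))
    stop("gene lengths must be positive multiples of 3")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (baseline_rate < 0 || any(rate_map < 0))
    stop("rates must be >= 0")
  if (any(cancer_types$n_samples < 1)) stop("sample counts must be >= 1")
  structure(list(n_genes = n_genes, gene_lengths = gene_lengths, gc = gc,
                 baseline_rate = baseline_rate,
                 rate_multipliers = rate_multipliers, rate_map = rate_map,
                 cancer_types = cancer_types, drivers = drivers, mnvs = mnvs,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' True rate of a mutation class under a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @param class Character vector of class ids (`"PENTAMER>ALT"`).
#' @return Per-site, per-sample probabilities.
#' @export
true_rate <- function(spec, class) {
  if (!is.null(spec$rate_map)) {
    r <- unname(spec$rate_map[class])
    r[is.na(r)] <- 0
    return(r)
  }
  route <- paste0(substr(class, 3L, 3L), ">", substr(class, 7L, 7L))
  mult <- rep(1, length(class))
  if (!is.null(spec$rate_multipliers)) {
    m <- unname(spec$rate_multipliers[route])
    mult[!is.na(m)] <- m[!is.na(m)]
  }
  spec$baseline_rate * mult
}

#' Generate a synthetic coding genome
#'
#' Reproducible under the spec's seed (the catalog uses a shifted seed, so
#' genome and catalog are independently reproducible); CDS lengths are
#' multiples of 3 and contain no ambiguous bases.
#'
#' @param spec A [synthetic_spec()].
#' @return A [coding_genome()] with genes `g1 ... gN`.
#' @export
make_genome <- function(spec) {
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  cds <- vapply(spec$gene_lengths, function(L)
    paste(sample(NUCLEOTIDES, L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(cds) <- paste0("g", seq_len(spec$n_genes))
  coding_genome(cds)
}

#' Simulate a multi-cancer-type somatic mutation catalog
#'
#' Per-site Bernoulli model: for each sample of cancer type t and each
#' classifiable site/alternate-allele pair, an SNV occurs with probability
#' `true_rate(class) * multiplier_t`, independently across sites and
#' samples, so the expected count of class c is
#' r_c * s_p * sum_t N_t * m_t. Driver events are additionally present in
#' each sample with their enrichment probability; optional fixed-count MNV
#' records support the unscored-label rule downstream.
#'
#' @param spec A [synthetic_spec()].
#' @param genome The genome generated from `spec` by [make_genome()].
#' @return Mutation records data.frame in the same shape that
#'   [read_mutation_table()] returns.
#' @export
simulate_catalog <- function(spec, genome) {
  set.seed((spec$seed + 1000003L) %% 2147483647L)

  # classifiable sites and their 3 alternate alleles
  site <- do.call(rbind, lapply(names(genome$cds), function(g) {
    cds <- genome$cds[[g]]
    L <- nchar(cds)
    if (L < 5L) return(NULL)
    pos <- 3:(L - 2L)
    data.frame(gene = g, cds_pos = pos,
               ref = substring(cds, pos, pos),
               pentamer = substring(cds, pos - 2L, pos + 2L),
               stringsAsFactors = FALSE)
  }))
  site <- site[!grepl("[^ACGT]", site$pentamer), , drop = FALSE]
  alts <- lapply(site$ref, function(r) setdiff(NUCLEOTIDES, r))
  pair <- data.frame(gene = rep(site$gene, each = 3L)[],
                     cds_pos = rep(site$cds_pos, each = 3L),
                     ref = rep(site$ref, each = 3L),
                     pentamer = rep(site$pentamer, each = 3L),
                     alt = unlist(alts), stringsAsFactors = FALSE)
  rate <- true_rate(spec, class_id(pair$pentamer, pair$alt))

  out <- vector("list", nrow(spec$cancer_types) + 2L)
  for (k in seq_len(nrow(spec$cancer_types))) {
    ty <- spec$cancer_types$type[k]
    n_t <- spec$cancer_types$n_samples[k]
    p <- rate * spec$cancer_types$multiplier[k]
    if (any(p > 1)) stop("per-sample probability exceeds 1 for type ", ty)
    hits <- stats::rbinom(length(p), n_t, p)
    nz <- which(hits > 0L)
    if (length(nz)) {
      samples <- lapply(nz, function(i) sample.int(n_t, hits[i]))
      idx <- rep(nz, hits[nz])
      out[[k]] <- data.frame(
        gene = pair$gene[idx], sample = paste0(ty, "_s", unlist(samples)),
        cancer_type = ty, cds_pos = pair$cds_pos[idx], ref = pair$ref[idx],
        alt = pair$alt[idx], is_mnv = FALSE, stringsAsFactors = FALSE)
    }
  }

  if (!is.null(spec$drivers)) {
    drv <- lapply(seq_len(nrow(spec$drivers)), function(i) {
      d <- spec$drivers[i, ]
      ref <- substr(genome$cds[[d$gene]], d$cds_pos, d$cds_pos)
      if (ref == d$alt) stop("driver alt equals the reference base")
      do.call(rbind, lapply(seq_len(nrow(spec$cancer_types)), function(k) {
        ty <- spec$cancer_types$type[k]
        n_t <- spec$cancer_types$n_samples[k]
        n_hit <- stats::rbinom(1L, n_t, d$prob)
        if (n_hit == 0L) return(NULL)
        data.frame(gene = d$gene,
                   sample = paste0(ty, "_s", sample.int(n_t, n_hit)),
                   cancer_type = ty, cds_pos = d$cds_pos, ref = ref,
                   alt = d$alt, is_mnv = FALSE, stringsAsFactors = FALSE)
      }))
    })
    out[[nrow(spec$cancer_types) + 1L]] <- do.call(rbind, drv)
  }

  if (!is.null(spec$mnvs)) {
    out[[nrow(spec$cancer_types) + 2L]] <-
      do.call(rbind, lapply(seq_len(nrow(spec$mnvs)), function(i) {
        m <- spec$mnvs[i, ]
        ty <- spec$cancer_types$type[1L]
        data.frame(gene = m$gene,
                   sample = paste0(ty, "_mnv", i, "_", seq_len(m$n_samples)),
                   cancer_type = ty, cds_pos = m$cds_pos, ref = m$ref,
                   alt = m$alt, is_mnv = TRUE, stringsAsFactors = FALSE)
      }))
  }

  rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rec))
    rec <- data.frame(gene = character(), sample = character(),
                      cancer_type = character(), cds_pos = integer(),
                      ref = character(), alt = character(),
                      is_mnv = logical(), stringsAsFactors = FALSE)
  rec <- rec[!duplicated(rec[c("gene", "sample", "cds_pos", "ref", "alt")]), ,
             drop = FALSE]
  rec <- rec[order(rec$gene, rec$cds_pos, rec$alt, rec$sample), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write a genome / catalog in the formats the readers consume
#'
#' @param genome A [coding_genome()].
#' @param path Output FASTA path.
#' @export
write_cds_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$cds), path,
                              width = 70L)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @param records Mutation records.
#' @export
write_catalog <- function(records, path) {
  utils::write.table(
    records[c("gene", "sample", "cancer_type", "cds_pos", "ref", "alt")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
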