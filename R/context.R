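#' Enumerate all pentanucleotide mutation classes
#'
#' A mutation class is a pentamer (positions -2,-1,0,+1,+2; the center is the
#' reference base) together with an alternate allele different from the
#' center: 12 central substitution routes x 4^4 flank combinations = 3072
#' classes. No reverse-complement collapsing is performed; C>T and G>A are
#' distinct classes.
#'
#' @return data.frame with columns `pentamer`, `alt`, `class` (the id
#'   `"PENTAMER>ALT"`), 3072 rows in lexicographic order.
#' @export
all_context_classes <- function() {
  g <- expand.grid(m2 = NUCLEOTIDES, m1 = NUCLEOTIDES, c0 = NUCLEOTIDES,
                   p1 = NUCLEOTIDES, p2 = NUCLEOTIDES, alt = NUCLEOTIDES,
                   stringsAsFactors = FALSE)
  g <- g[g$c0 != g$alt, , drop = FALSE]
  out <- data.frame(pentamer = paste0(g$m2, g$m1, g$c0, g$p1, g$p2),
                    alt = g$alt, stringsAsFactors = FALSE)
  out$class <- class_id(out$pentamer, out$alt)
  out <- out[order(out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation class identifier
#'
#' @param pentamer 5-mer context (center = reference base).
#' @param alt Alternate allele at the center.
#' @return Character id `"PENTAMER>ALT"`.
#' @export
class_id <- function(pentamer, alt) paste0(pentamer, ">", alt)

#' Collapse a pentamer to its central trinucleotide
#'
#' Aggregation helper for comparing against trinucleotide (96-class style)
#' summaries; the package itself always works at pentamer resolution.
#'
#' @param pentamer Character vector of 5-mers.
#' @return The central 3-mers.
#' @export
context_trinucleotide <- function(pentamer) substr(pentamer, 2L, 4L)

#' Extract the pentanucleotide context of a coding site
#'
#' The 5-mer centered on `cds_position`. When the window overruns a CDS end
#' the gene's genomic flank is used if available; otherwise (or when the
#' window contains a non-ACGT base) the context is unavailable and NA is
#' returned.
#'
#' @param genome A [coding_genome()].
#' @param gene_id Gene identifier.
#' @param cds_position 1-based position on the coding strand.
#' @return The 5-mer, or `NA_character_` if the context is unavailable.
#' @export
extract_context <- function(genome, gene_id, cds_position) {
  cds <- unname(genome$cds[gene_id])
  if (is.na(cds)) stop("unknown gene: ", gene_id)
  i <- as.integer(cds_position)
  L <- nchar(cds)
  if (is.na(i) || i < 1L || i > L)
    stop("cds_position ", cds_position, " outside CDS of ", gene_id,
         " (length ", L, ")")
  left_need <- max(0L, 3L - i)
  right_need <- max(0L, i + 2L - L)
  core <- substr(cds, max(1L, i - 2L), min(L, i + 2L))
  if (left_need > 0L || right_need > 0L) {
    fl <- genome$flanks[[gene_id]]
    up <- fl$up %||% ""
    down <- fl$down %||% ""
    if (left_need > nchar(up) || right_need > nchar(down))
      return(NA_character_)
    pre <- if (left_need > 0L)
      substr(up, nchar(up) - left_need + 1L, nchar(up)) else ""
    post <- if (right_need > 0L) substr(down, 1L, right_need) else ""
    core <- paste0(pre, core, post)
  }
  if (nchar(core) != 5L || grepl("[^ACGT]", core)) return(NA_character_)
  core
}

# Vectorized context extraction for many sites of one genome; interior sites
# are sliced in bulk, edge sites fall back to extract_context().
contexts_for <- function(genome, gene, cds_pos) {
  out <- rep(NA_character_, length(gene))
  for (g in unique(gene)) {
    idx <- which(gene == g)
    cds <- unname(genome$cds[g])
    if (is.na(cds)) stop("unknown gene: ", g)
    L <- nchar(cds)
    pos <- cds_pos[idx]
    if (any(pos < 1L | pos > L))
      stop("cds_position outside CDS of ", g)
    interior <- pos >= 3L & pos <= L - 2L
    if (any(interior)) {
      p <- pos[interior]
      w <- substring(cds, p - 2L, p + 2L)
      w[grepl("[^ACGT]", w)] <- NA_character_
      out[idx[interior]] <- w
    }
    for (j in idx[!interior])
      out[j] <- extract_context(genome, g, cds_pos[j])
  }
  out
}

#' Count pentanucleotide sites across the coding genome
#'
#' Counts every overlapping 5-mer window fully inside each CDS (the
#' denominator of the mutational tendency). Windows containing a non-ACGT
#' base are skipped; the skip count is reported as an attribute. Flank
#' sequences never contribute to the denominator.
#'
#' @param genome A [coding_genome()].
#' @return Named integer vector of length 1024 (sites per pentamer), class
#'   `context_site_table`, with attribute `n_skipped_windows`.
#' @export
count_context_sites <- function(genome) {
  x <- Biostrings::DNAStringSet(genome$cds)
  freq <- Biostrings::oligonucleotideFrequency(x, width = 5L, step = 1L)
  sites <- if (is.matrix(freq)) colSums(freq) else freq
  sites <- sites[order(names(sites))]
  total_windows <- sum(pmax(nchar(genome$cds) - 4L, 0L))
  structure(as.integer(sites), names = names(sites),
            n_skipped_windows = as.integer(total_windows - sum(sites)),
            class = "context_site_table")
}

#' Serialize / read a context site table
#'
#' Two-column tab-separated text (pentamer, count), sorted lexicographically.
#'
#' @param sites A `context_site_table` from [count_context_sites()].
#' @param path File path.
#' @export
write_context_sites <- function(sites, path) {
  utils::write.table(data.frame(pentamer = names(sites),
                                count = as.integer(sites)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_context_sites
#' @export
read_context_sites <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(as.integer(tab$count), names = tab$pentamer,
            class = "context_site_table")
}

#' Assign mutation records to pentanucleotide classes
#'
#' Each SNV with an available context maps to exactly one of the 3072 classes.
#' Records whose context is unavailable (CDS edge without flank, ambiguous
#' base) or whose stated reference disagrees with the sequence are returned
#' with NA class and counted in the `n_unclassified` attribute.
#'
#' @param records Mutation records (SNVs; rows with `is_mnv` are rejected).
#' @param genome A [coding_genome()].
#' @return `records` with added columns `pentamer` and `class`; attribute
#'   `n_unclassified`.
#' @export
classify_mutation <- function(records, genome) {
  if (any(records$is_mnv))
    stop("classify_mutation expects single-nucleotide records only")
  pent <- contexts_for(genome, records$gene, records$cds_pos)
  mism <- !is.na(pent) & substr(pent, 3L, 3L) != records$ref
  if (any(mism)) {
    warning(sum(mism), " record(s) whose ref allele disagrees with the CDS",
            " were left unclassified")
    pent[mism] <- NA_character_
  }
  records$pentamer <- pent
  records$class <- ifelse(is.na(pent), NA_character_,
                          class_id(pent, records$alt))
  attr(records, "n_unclassified") <- sum(is.na(pent))
  records
}

# ---- translation helpers (standard genetic code) ------------------------

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

codon_at <- function(genome, gene, codon_index) {
  cds <- unname(genome$cds[gene])
  if (is.na(cds)) stop("unknown gene: ", gene)
  start <- 3L * (codon_index - 1L) + 1L
  if (start + 2L > nchar(cds))
    stop("codon index ", codon_index, " outside CDS of ", gene)
  substr(cds, start, start + 2L)
}

# "M133R"-style label for an SNV; synonymous changes give e.g. "T125T".
protein_change_label <- function(genome, gene, cds_pos, ref, alt) {
  cds <- unname(genome$cds[gene])
  if (is.na(cds) || cds_pos > nchar(cds)) return(NA_character_)
  if (substr(cds, cds_pos, cds_pos) != ref) return(NA_character_)
  ci <- (cds_pos - 1L) %/% 3L + 1L
  start <- 3L * (ci - 1L) + 1L
  if (start + 2L > nchar(cds)) return(NA_character_)
  codon <- substr(cds, start, start + 2L)
  off <- cds_pos - start + 1L
  new_codon <- codon
  substr(new_codon, off, off) <- alt
  aa0 <- translate_codon(codon)
  aa1 <- translate_codon(new_codon)
  if (is.na(aa0) || is.na(aa1)) return(NA_character_)
  paste0(aa0, ci, aa1)
}

# Protein-change label for a multi-nucleotide run substitution, defined only
# when exactly one codon's amino acid changes (the situation behind the
# "same protein change via CC->TT" flag).
mnv_protein_change <- function(genome, gene, cds_pos, ref, alt) {
  cds <- unname(genome$cds[gene])
  n <- nchar(ref)
  if (is.na(cds) || nchar(alt) != n || cds_pos + n - 1L > nchar(cds))
    return(NA_character_)
  if (substr(cds, cds_pos, cds_pos + n - 1L) != ref) return(NA_character_)
  mod <- cds
  substr(mod, cds_pos, cds_pos + n - 1L) <- alt
  ci <- unique(((cds_pos:(cds_pos + n - 1L)) - 1L) %/% 3L + 1L)
  labs <- character(0)
  for (k in ci) {
    start <- 3L * (k - 1L) + 1L
    if (start + 2L > nchar(cds)) next
    aa0 <- translate_codon(substr(cds, start, start + 2L))
    aa1 <- translate_codon(substr(mod, start, start + 2L))
    if (is.na(aa0) || is.na(aa1)) return(NA_character_)
    if (aa0 != aa1) labs <- c(labs, paste0(aa0, k, aa1))
  }
  if (length(labs) == 1L) labs else NA_character_
}
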