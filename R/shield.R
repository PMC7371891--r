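#' Synonymous alternatives of a codon
#'
#' All codons encoding the same amino acid under the standard genetic code,
#' excluding the input codon itself.
#'
#' @param codon A valid sense codon (3 uppercase bases).
#' @return Character vector of synonymous codons (possibly empty, e.g. for
#'   ATG or TGG).
#' @export
synonymous_codons <- function(codon) {
  codon <- toupper(codon)
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon has no synonymous sense alternatives: ",
                      codon)
  syn <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
  setdiff(syn, codon)
}

# Tendency lookup: classes absent from the table count as rate 0.
rate_lookup <- function(tendencies) {
  stats::setNames(tendencies$tendency, tendencies$class)
}

# Sum of class tendencies over the 9 single-nucleotide changes of one codon
# whose translated amino-acid change is in `lof_aas`, with contexts read
# from `seq` (a possibly recoded CDS).
lof_sum_seq <- function(seq, flanks, codon_index, lof_aas, rates) {
  start <- 3L * (codon_index - 1L) + 1L
  codon <- substr(seq, start, start + 2L)
  aa0 <- translate_codon(codon)
  total <- 0
  genome1 <- coding_genome(c(g = seq),
                           if (!is.null(flanks)) list(g = flanks))
  for (off in 0:2) {
    pos <- start + off
    ref <- substr(seq, pos, pos)
    for (alt in setdiff(NUCLEOTIDES, ref)) {
      new_codon <- codon
      substr(new_codon, off + 1L, off + 1L) <- alt
      aa1 <- translate_codon(new_codon)
      if (is.na(aa1) || aa1 == aa0 || !(aa1 %in% lof_aas)) next
      pent <- extract_context(genome1, "g", pos)
      if (is.na(pent)) next
      r <- unname(rates[class_id(pent, alt)])
      if (!is.na(r)) total <- total + r
    }
  }
  total
}

#' Summed tendency of LOF-generating substitutions at a codon
#'
#' Over the 9 possible single-nucleotide changes in the codon, sums the
#' mutational tendency (rate, not difficulty: "chance of generating" is a
#' rate-space quantity) of those whose amino-acid change is in the
#' deleterious target set. When a codon override is given, the codon is
#' replaced in-sequence first, so the pentanucleotide contexts of all three
#' positions — and of neighbouring positions within 2 nt — reflect the
#' recoding.
#'
#' @param genome A [coding_genome()].
#' @param gene Gene id.
#' @param codon_index 1-based amino-acid position.
#' @param lof_changes Character vector of deleterious target amino acids
#'   (single letters, `"*"` for stop) at this residue.
#' @param tendencies A `tendency_table`; classes absent from it contribute
#'   rate 0.
#' @param codon_override Optional synonymous replacement codon.
#' @param ref_aa Optional expected amino acid at the residue; mismatch is an
#'   error.
#' @return The summed tendency T.
#' @export
lof_tendency_sum <- function(genome, gene, codon_index, lof_changes,
                             tendencies, codon_override = NULL,
                             ref_aa = NULL) {
  cds <- unname(genome$cds[gene])
  if (is.na(cds)) stop("unknown gene: ", gene)
  start <- 3L * (codon_index - 1L) + 1L
  if (start + 2L > nchar(cds))
    stop("codon index ", codon_index, " outside CDS of ", gene)
  codon <- substr(cds, start, start + 2L)
  aa0 <- translate_codon(codon)
  if (!is.null(ref_aa) && !identical(aa0, ref_aa))
    stop("residue ", codon_index, " of ", gene, " is ", aa0,
         ", expected ", ref_aa)
  if (!is.null(codon_override)) {
    codon_override <- toupper(codon_override)
    aa1 <- translate_codon(codon_override)
    if (is.null(aa1) || is.na(aa1) || aa1 != aa0)
      stop("override codon ", codon_override, " is not synonymous with ",
           codon, " (", aa0, ")")
    substr(cds, start, start + 2L) <- codon_override
  }
  lof_sum_seq(cds, genome$flanks[[gene]], codon_index, lof_changes,
              rate_lookup(tendencies))
}

#' Shielding report for synonymous recoding of a hotspot codon
#'
#' For every synonymous alternative of the codon at `codon_index`, computes
#' the LOF-generating tendency sum before (T0) and after (T1) recoding, the
#' fold reduction F = T0/T1 (infinite when the recoding removes every LOF
#' route — "complete shielding"), and, for each neighbouring residue within
#' `neighbor_window` codons, the change its own nonsynonymous-change
#' tendency sum suffers because the recoding alters shared flanking contexts.
#'
#' @inheritParams lof_tendency_sum
#' @param neighbor_window Residues each side to audit (default 2).
#' @param include_self If TRUE, include the identity "recoding" (F = 1) as a
#'   reference row.
#' @return data.frame of class `shield_report`, ranked by fold reduction
#'   (columns `candidate`, `T0`, `T1`, `fold_reduction`, `flag`, then one
#'   `delta_res<i>` column per audited neighbour).
#' @export
shield_report <- function(genome, gene, codon_index, lof_changes, tendencies,
                          neighbor_window = 2, include_self = FALSE,
                          ref_aa = NULL) {
  cds <- unname(genome$cds[gene])
  if (is.na(cds)) stop("unknown gene: ", gene)
  start <- 3L * (codon_index - 1L) + 1L
  codon <- substr(cds, start, start + 2L)
  aa0 <- translate_codon(codon)
  if (!is.null(ref_aa) && !identical(aa0, ref_aa))
    stop("residue ", codon_index, " of ", gene, " is ", aa0,
         ", expected ", ref_aa)
  rates <- rate_lookup(tendencies)
  flanks <- genome$flanks[[gene]]
  n_res <- nchar(cds) %/% 3L
  neighbors <- setdiff(
    seq(max(1L, codon_index - neighbor_window),
        min(n_res, codon_index + neighbor_window)), codon_index)

  t0 <- lof_sum_seq(cds, flanks, codon_index, lof_changes, rates)
  nb_aas <- function(s, k) {        # target set for a neighbour: any
    a <- translate_codon(codon_at0(s, k)) # amino-acid-changing substitution
    setdiff(c(LETTERS_AA, "*"), a)
  }
  nb0 <- vapply(neighbors, function(k)
    lof_sum_seq(cds, flanks, k, nb_aas(cds, k), rates), numeric(1))

  candidates <- synonymous_codons(codon)
  if (include_self) candidates <- c(codon, candidates)
  if (length(candidates) == 0L) {
    out <- data.frame(candidate = character(), T0 = numeric(),
                      T1 = numeric(), fold_reduction = numeric(),
                      flag = character(), stringsAsFactors = FALSE)
    for (k in neighbors) out[[paste0("delta_res", k)]] <- numeric(0)
    return(structure(out, gene = gene, codon_index = codon_index,
                     original_codon = codon, amino_acid = aa0,
                     class = c("shield_report", "data.frame")))
  }
  rows <- lapply(candidates, function(cand) {
    mod <- cds
    substr(mod, start, start + 2L) <- cand
    t1 <- lof_sum_seq(mod, flanks, codon_index, lof_changes, rates)
    nb1 <- vapply(neighbors, function(k)
      lof_sum_seq(mod, flanks, k, nb_aas(mod, k), rates), numeric(1))
    c(list(candidate = cand, T0 = t0, T1 = t1,
           fold_reduction = if (t1 > 0) t0 / t1 else Inf,
           flag = if (t1 == 0) "complete_shielding" else ""),
      stats::setNames(as.list(nb1 - nb0), paste0("delta_res", neighbors)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(-out$fold_reduction, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, gene = gene, codon_index = codon_index,
            original_codon = codon, amino_acid = aa0,
            class = c("shield_report", "data.frame"))
}

codon_at0 <- function(seq, codon_index) {
  start <- 3L * (codon_index - 1L) + 1L
  substr(seq, start, start + 2L)
}

LETTERS_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Serialize a shield report
#'
#' @param report A `shield_report`.
#' @param path Output file (tab-separated, one row per candidate codon).
#' @export
write_shield_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
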