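#' Coding genome container
#'
#' Bundles one coding sequence (CDS) per gene, with optional genomic flanking
#' sequences used to recover pentanucleotide contexts at CDS edges (sites next
#' to intron-exon junctions in real data).
#'
#' @param cds Named character vector, one uppercase A/C/G/T/N string per gene.
#' @param flanks Optional named list; each element a list with `up` and `down`
#'   genomic strings (each at least 2 nt) immediately flanking that gene's CDS.
#' @return An object of class `coding_genome` with elements `cds`, `flanks`
#'   and `n_genes`.
#' @export
coding_genome <- function(cds, flanks = NULL) {
  if (length(cds) == 0L) stop("coding genome must contain at least one gene")
  if (is.null(names(cds)) || any(names(cds) == "") || anyNA(names(cds)))
    stop("all CDS entries must be named by gene id")
  if (anyDuplicated(names(cds)))
    stop("duplicate gene ids: ",
         paste(unique(names(cds)[duplicated(names(cds))]), collapse = ", "))
  cds <- toupper(cds)
  if (any(nchar(cds) < 1L)) stop("each CDS must have length >= 1")
  if (any(grepl("[^ACGTN]", cds))) stop("CDS sequences may only contain A/C/G/T/N")
  if (!is.null(flanks)) {
    bad <- setdiff(names(flanks), names(cds))
    if (length(bad)) stop("flanks supplied for unknown genes: ",
                          paste(bad, collapse = ", "))
    flanks <- lapply(flanks, function(f) {
      f <- list(up = toupper(f$up %||% ""), down = toupper(f$down %||% ""))
      if ((nzchar(f$up) && nchar(f$up) < 2L) ||
          (nzchar(f$down) && nchar(f$down) < 2L))
        stop("flank strings, when present, must have length >= 2")
      f
    })
  }
  structure(list(cds = cds, flanks = flanks, n_genes = length(cds)),
            class = "coding_genome")
}

#' @export
print.coding_genome <- function(x, ...) {
  cat("coding_genome:", x$n_genes, "genes,",
      sum(nchar(x$cds)), "coding nucleotides",
      if (!is.null(x$flanks)) sprintf("(%d genes with flanks)", length(x$flanks)),
      "\n")
  invisible(x)
}

#' Read coding sequences from FASTA
#'
#' One CDS is retained per gene (the "major isoform"). FASTA record ids are
#' either plain gene ids, or `gene|transcript`; when several records share a
#' gene, the canonical list wins if supplied, otherwise the longest CDS is
#' kept (ties broken by lexicographically smallest record id).
#'
#' @param path FASTA file of coding sequences.
#' @param canonical_list Optional named character vector `gene -> transcript`
#'   selecting the canonical record where several isoforms are present.
#' @param flank_path Optional FASTA whose record ids are `gene_upstream` /
#'   `gene_downstream`, holding genomic sequence immediately flanking each CDS.
#' @return A [coding_genome()].
#' @export
read_cds_fasta <- function(path, canonical_list = NULL, flank_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene <- sub("\\|.*$", "", ids)
  transcript <- ifelse(grepl("\\|", ids), sub("^[^|]*\\|", "", ids), ids)
  len <- nchar(as.character(seqs))

  keep <- logical(length(ids))
  for (g in unique(gene)) {
    idx <- which(gene == g)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else if (!is.null(canonical_list) && g %in% names(canonical_list)) {
      hit <- idx[transcript[idx] == canonical_list[[g]]]
      if (length(hit) == 0L)
        stop("canonical transcript ", canonical_list[[g]],
             " not found for gene ", g)
      keep[hit[1L]] <- TRUE
    } else {
      idx <- idx[order(-len[idx], ids[idx])]
      keep[idx[1L]] <- TRUE
    }
  }
  cds <- as.character(seqs)[keep]
  names(cds) <- gene[keep]

  flanks <- NULL
  if (!is.null(flank_path)) {
    fs <- Biostrings::readDNAStringSet(flank_path)
    fid <- sub("\\s.*$", "", names(fs))
    fseq <- as.character(fs)
    up <- grepl("_upstream$", fid)
    down <- grepl("_downstream$", fid)
    fgene <- sub("_(upstream|downstream)$", "", fid)
    flanks <- lapply(setNames(nm = intersect(unique(fgene), names(cds))),
      function(g) list(up = unname(fseq[up & fgene == g][1]) %||% "",
                       down = unname(fseq[down & fgene == g][1]) %||% ""))
    flanks <- lapply(flanks, function(f) {
      f$up <- if (is.na(f$up)) "" else f$up
      f$down <- if (is.na(f$down)) "" else f$down
      f
    })
  }
  coding_genome(cds, flanks)
}

#' Parse HGVS-style coding substitution strings
#'
#' Understands single-nucleotide substitutions (`c.215C>G`) and
#' multi-nucleotide run substitutions (`c.375_376CC>TT`). Insertions,
#' deletions, duplications and anything else return NA rows.
#'
#' @param x Character vector of `c.` strings.
#' @return data.frame with columns `cds_pos`, `ref`, `alt`, `is_mnv`, `ok`.
#' @export
parse_hgvs_c <- function(x) {
  out <- data.frame(cds_pos = NA_integer_, ref = NA_character_,
                    alt = NA_character_, is_mnv = FALSE, ok = FALSE,
                    stringsAsFactors = FALSE)[rep(1L, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  x <- trimws(x)

  snv <- regmatches(x, regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", x))
  is_snv <- lengths(snv) == 4L
  if (any(is_snv)) {
    m <- do.call(rbind, snv[is_snv])
    out$cds_pos[is_snv] <- as.integer(m[, 2L])
    out$ref[is_snv] <- m[, 3L]
    out$alt[is_snv] <- m[, 4L]
    out$ok[is_snv] <- m[, 3L] != m[, 4L]
  }

  mnv <- regmatches(x, regexec("^c\\.(\\d+)_(\\d+)([ACGT]+)>([ACGT]+)$", x))
  is_mnv <- lengths(mnv) == 5L
  if (any(is_mnv)) {
    m <- do.call(rbind, mnv[is_mnv])
    span <- as.integer(m[, 3L]) - as.integer(m[, 2L]) + 1L
    good <- span >= 2L & nchar(m[, 4L]) == span & nchar(m[, 5L]) == span &
      m[, 4L] != m[, 5L]
    out$cds_pos[is_mnv] <- as.integer(m[, 2L])
    out$ref[is_mnv] <- m[, 4L]
    out$alt[is_mnv] <- m[, 5L]
    out$is_mnv[is_mnv] <- TRUE
    out$ok[is_mnv] <- good
  }
  out
}

#' Read a somatic mutation catalog
#'
#' @param path Tab-separated file with a header.
#' @param dialect `"generic"` expects columns `gene`, `sample`, `cancer_type`,
#'   `cds_pos`, `ref`, `alt`; `"cosmic"` expects `gene`, `sample`,
#'   `primary_site` and an HGVS coding-change column (`hgvs_c` or
#'   `mutation_cds`).
#' @return data.frame of mutation records (columns `gene`, `sample`,
#'   `cancer_type`, `cds_pos`, `ref`, `alt`, `is_mnv`) with attributes
#'   `n_skipped_indel` and `n_skipped_unparsed` recording dropped rows.
#' @export
read_mutation_table <- function(path, dialect = c("generic", "cosmic")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)

  if (dialect == "generic") {
    need <- c("gene", "sample", "cancer_type", "cds_pos", "ref", "alt")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("missing mandatory column(s): ",
                           paste(miss, collapse = ", "))
    rec <- data.frame(gene = as.character(tab$gene),
                      sample = as.character(tab$sample),
                      cancer_type = as.character(tab$cancer_type),
                      cds_pos = as.integer(tab$cds_pos),
                      ref = toupper(tab$ref), alt = toupper(tab$alt),
                      stringsAsFactors = FALSE)
    rec$is_mnv <- nchar(rec$ref) > 1L
    indel <- nchar(rec$ref) != nchar(rec$alt) | rec$ref == "-" | rec$alt == "-"
    bad <- !grepl("^[ACGT]+$", rec$ref) | !grepl("^[ACGT]+$", rec$alt) |
      rec$ref == rec$alt | is.na(rec$cds_pos)
    n_indel <- sum(indel)
    n_unparsed <- sum(bad & !indel)
    rec <- rec[!(indel | bad), , drop = FALSE]
  } else {
    hcol <- intersect(c("hgvs_c", "mutation_cds"), names(tab))[1]
    need <- c("gene", "sample", "primary_site")
    miss <- setdiff(need, names(tab))
    if (length(miss) || is.na(hcol))
      stop("missing mandatory column(s): ",
           paste(c(miss, if (is.na(hcol)) "hgvs_c"), collapse = ", "))
    parsed <- parse_hgvs_c(tab[[hcol]])
    indel <- grepl("del|ins|dup", tab[[hcol]])
    n_indel <- sum(indel)
    n_unparsed <- sum(!parsed$ok & !indel)
    keep <- parsed$ok
    rec <- data.frame(gene = as.character(tab$gene)[keep],
                      sample = as.character(tab$sample)[keep],
                      cancer_type = as.character(tab$primary_site)[keep],
                      cds_pos = parsed$cds_pos[keep],
                      ref = parsed$ref[keep], alt = parsed$alt[keep],
                      is_mnv = parsed$is_mnv[keep],
                      stringsAsFactors = FALSE)
  }
  rownames(rec) <- NULL
  attr(rec, "n_skipped_indel") <- n_indel
  attr(rec, "n_skipped_unparsed") <- n_unparsed
  rec
}

event_id <- function(gene, cds_pos, ref, alt) {
  paste(gene, cds_pos, ref, alt, sep = ":")
}

#' Aggregate mutation records into unique coding-change events
#'
#' One event per unique (gene, position, ref, alt); each sample contributes at
#' most once to an event (the event's "original count" is a count of distinct
#' cancer samples). When a genome is supplied, multi-nucleotide records that
#' produce the same single-codon protein change as an SNV event set that
#' event's `mnv_support` flag.
#'
#' @param records data.frame from [read_mutation_table()] or
#'   [simulate_catalog()].
#' @param genome Optional [coding_genome()]; needed only to resolve
#'   `mnv_support` via protein-change comparison.
#' @return data.frame of events (`gene`, `cds_pos`, `ref`, `alt`,
#'   `original_count`, `mnv_support`) carrying a `per_type` attribute: a long
#'   data.frame of per-cancer-type sample counts (see [event_type_counts()]).
#' @export
aggregate_events <- function(records, genome = NULL) {
  snv <- records[!records$is_mnv, , drop = FALSE]
  snv <- snv[!duplicated(snv[c("gene", "sample", "cds_pos", "ref", "alt")]), ,
             drop = FALSE]
  id <- event_id(snv$gene, snv$cds_pos, snv$ref, snv$alt)

  if (nrow(snv) == 0L) {
    ev <- data.frame(gene = character(), cds_pos = integer(),
                     ref = character(), alt = character(),
                     original_count = integer(), mnv_support = logical(),
                     stringsAsFactors = FALSE)
    attr(ev, "per_type") <- data.frame(event_id = character(),
                                       cancer_type = character(),
                                       count = integer(),
                                       stringsAsFactors = FALSE)
    return(ev)
  }

  key <- !duplicated(id)
  ev <- data.frame(gene = snv$gene[key], cds_pos = snv$cds_pos[key],
                   ref = snv$ref[key], alt = snv$alt[key],
                   stringsAsFactors = FALSE)
  ev_id <- id[key]
  ev$original_count <- as.integer(table(id)[ev_id])
  ev$mnv_support <- FALSE

  pt <- stats::aggregate(list(count = rep(1L, nrow(snv))),
                         by = list(event_id = id, cancer_type = snv$cancer_type),
                         FUN = sum)
  pt <- pt[order(pt$event_id, pt$cancer_type), , drop = FALSE]
  rownames(pt) <- NULL

  if (!is.null(genome) && any(records$is_mnv)) {
    mnv <- records[records$is_mnv, , drop = FALSE]
    ev_prot <- mapply(protein_change_label, ev$gene, ev$cds_pos, ev$ref, ev$alt,
                      MoreArgs = list(genome = genome))
    for (i in seq_len(nrow(mnv))) {
      lab <- mnv_protein_change(genome, mnv$gene[i], mnv$cds_pos[i],
                                mnv$ref[i], mnv$alt[i])
      if (!is.na(lab)) {
        hit <- ev$gene == mnv$gene[i] & !is.na(ev_prot) & ev_prot == lab
        ev$mnv_support[hit] <- TRUE
      }
    }
  }

  ev <- ev[order(ev$gene, ev$cds_pos, ev$ref, ev$alt), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "per_type") <- pt
  ev
}

#' Per-cancer-type sample counts of aggregated events
#'
#' @param events Output of [aggregate_events()].
#' @return Long data.frame with columns `event_id`, `cancer_type`, `count`.
#' @export
event_type_counts <- function(events) attr(events, "per_type")

#' Exclude highly recurrent events before tendency estimation
#'
#' Events observed in more than `max_samples` cancer samples are assumed to be
#' selectively enriched (drivers) and would inflate the background rate of
#' their mutation class; their records are removed. Used only for difficulty
#' estimation — assessment still sees all events. Multi-nucleotide records are
#' dropped too (they never enter rate estimation).
#'
#' @param records Mutation records.
#' @param events Events aggregated from `records`.
#' @param max_samples Recurrence cutoff; events with original count strictly
#'   greater are excluded (default 5).
#' @return Filtered records; attribute `excluded_fraction` gives the fraction
#'   of deduplicated SNV records removed by the recurrence rule.
#' @export
filter_recurrent <- function(records, events, max_samples = 5) {
  if (max_samples < 1) stop("max_samples must be >= 1")
  snv <- records[!records$is_mnv, , drop = FALSE]
  snv <- snv[!duplicated(snv[c("gene", "sample", "cds_pos", "ref", "alt")]), ,
             drop = FALSE]
  id <- event_id(snv$gene, snv$cds_pos, snv$ref, snv$alt)
  ev_id <- event_id(events$gene, events$cds_pos, events$ref, events$alt)
  o <- events$original_count[match(id, ev_id)]
  keep <- !is.na(o) & o <= max_samples
  out <- snv[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_fraction") <-
    if (nrow(snv)) sum(!keep) / nrow(snv) else 0
  out
}

#' Write aggregated events to tab-separated text
#'
#' Long format, one row per (event, cancer type); integer counts. Re-reading
#' with [read_events()] reproduces the events field-for-field.
#'
#' @param events Output of [aggregate_events()].
#' @param path Output file.
#' @export
write_events <- function(events, path) {
  pt <- event_type_counts(events)
  ev_id <- event_id(events$gene, events$cds_pos, events$ref, events$alt)
  i <- match(pt$event_id, ev_id)
  out <- data.frame(gene = events$gene[i], cds_pos = events$cds_pos[i],
                    ref = events$ref[i], alt = events$alt[i],
                    cancer_type = pt$cancer_type, count = as.integer(pt$count),
                    mnv_support = events$mnv_support[i],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$cds_pos, out$ref, out$alt, out$cancer_type), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @return `read_events()` returns the events data.frame.
#' @export
read_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  id <- event_id(tab$gene, tab$cds_pos, tab$ref, tab$alt)
  key <- !duplicated(id)
  ev <- data.frame(gene = tab$gene[key], cds_pos = as.integer(tab$cds_pos[key]),
                   ref = tab$ref[key], alt = tab$alt[key],
                   stringsAsFactors = FALSE)
  ev$original_count <- as.integer(tapply(tab$count, id, sum)[id[key]])
  ev$mnv_support <- as.logical(tab$mnv_support[key])
  ev <- ev[order(ev$gene, ev$cds_pos, ev$ref, ev$alt), , drop = FALSE]
  rownames(ev) <- NULL
  pt <- data.frame(event_id = id, cancer_type = tab$cancer_type,
                   count = as.integer(tab$count), stringsAsFactors = FALSE)
  pt <- pt[order(pt$event_id, pt$cancer_type), , drop = FALSE]
  rownames(pt) <- NULL
  attr(ev, "per_type") <- pt
  ev
}
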