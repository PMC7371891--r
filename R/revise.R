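# Difficulty lookup vectors for fast per-class access.
difficulty_lookup <- function(table) {
  list(d = stats::setNames(table$difficulty, table$class),
       flag = stats::setNames(table$flag, table$class),
       scope = attr(table, "scope"))
}

# Shared assessment engine: revised count and per-type contributions for a
# set of events. Cancer types with their own table use it; all others fall
# back to the pan-cancer table.
assess_events <- function(events, genome, pan_table, type_tables = NULL) {
  if (nrow(events) == 0L)
    return(data.frame(event_id = character(), gene = character(),
                      cds_pos = integer(), ref = character(),
                      alt = character(), pentamer = character(),
                      original_count = integer(), revised_count = numeric(),
                      mnv_support = logical(), stringsAsFactors = FALSE))
  pent <- contexts_for(genome, events$gene, events$cds_pos)
  if (anyNA(pent))
    stop("context unavailable for event(s): ",
         paste(event_id(events$gene, events$cds_pos, events$ref,
                        events$alt)[is.na(pent)], collapse = ", "))
  mism <- substr(pent, 3L, 3L) != events$ref
  if (any(mism))
    stop("reference allele disagrees with the CDS for event(s): ",
         paste(event_id(events$gene, events$cds_pos, events$ref,
                        events$alt)[mism], collapse = ", "))
  cls <- class_id(pent, events$alt)
  ids <- event_id(events$gene, events$cds_pos, events$ref, events$alt)

  pan <- difficulty_lookup(pan_table)
  per_type <- lapply(type_tables %||% list(), difficulty_lookup)

  pt <- event_type_counts(events)
  pt <- pt[pt$event_id %in% ids, , drop = FALSE]
  ev_idx <- match(pt$event_id, ids)
  pt$class <- cls[ev_idx]
  pt$difficulty <- NA_real_
  pt$scope <- NA_character_
  for (i in seq_len(nrow(pt))) {
    lk <- per_type[[pt$cancer_type[i]]] %||% pan
    d <- unname(lk$d[pt$class[i]])
    fl <- unname(lk$flag[pt$class[i]])
    if (is.na(match(pt$class[i], names(lk$d))))
      stop("class ", pt$class[i], " not present in the ", lk$scope, " table")
    if (is.na(d))
      stop("difficulty undefined for class ", pt$class[i], " (flag '", fl,
           "') in the ", lk$scope,
           " table; rebuild with zero_policy = \"pseudocount\"")
    pt$difficulty[i] <- d
    pt$scope[i] <- lk$scope
  }
  pt$contribution <- pt$count * pt$difficulty

  revised <- tapply(pt$contribution, factor(pt$event_id, levels = ids), sum)
  out <- data.frame(event_id = ids, gene = events$gene,
                    cds_pos = events$cds_pos, ref = events$ref,
                    alt = events$alt, pentamer = pent,
                    original_count = events$original_count,
                    revised_count = as.numeric(revised),
                    mnv_support = events$mnv_support,
                    stringsAsFactors = FALSE)
  attr(out, "contributions") <- pt
  out
}

#' Difficulty-weighted revised count of one mutation event
#'
#' The revised count is the sum over cancer types of the event's per-type
#' sample count times the per-type relative mutational difficulty of its
#' class, R = sum_t O_t * D_t. Types without their own difficulty table use
#' the fallback (pan-cancer) table.
#'
#' @param events An [aggregate_events()] data.frame (its `per_type`
#'   attribute supplies the per-cancer-type sample counts).
#' @param genome A [coding_genome()].
#' @param fallback_table Pan-cancer `difficulty_table`.
#' @param type_tables Optional named list of per-cancer-type
#'   `difficulty_table`s, e.g. from [cancer_type_difficulty()].
#' @param which Row index of the event to assess (default 1; use
#'   [annotate_gene()] for whole-gene batches).
#' @return A `revised_assessment`: list with `event`, `original_count`,
#'   `contributions` (data.frame of cancer_type, count, difficulty,
#'   contribution) and `revised_count`.
#' @export
revised_count <- function(events, genome, fallback_table, type_tables = NULL,
                          which = 1L) {
  event <- events[which, , drop = FALSE]
  if (nrow(event) != 1L)
    stop("'which' must select exactly one event")
  pt <- event_type_counts(events)
  if (is.null(pt))
    stop("events lack their per-type counts; pass the object returned by ",
         "aggregate_events()")
  attr(event, "per_type") <- pt
  a <- assess_events(event, genome, fallback_table, type_tables)
  ctr <- attr(a, "contributions")
  structure(list(event = event,
                 original_count = a$original_count,
                 pentamer = a$pentamer,
                 contributions = ctr[, c("cancer_type", "count", "difficulty",
                                         "contribution")],
                 revised_count = a$revised_count),
            class = "revised_assessment")
}

#' @export
print.revised_assessment <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s  original count %d, revised count %.5g\n",
              x$event$gene, x$event$cds_pos, x$event$ref, x$event$alt,
              x$original_count, x$revised_count))
  print(x$contributions, row.names = FALSE)
  invisible(x)
}

#' Classify a revised count as wild-type-like or loss-of-function
#'
#' Strict thresholds: R below `wt_max` suggests retained wild-type function,
#' R above `lof_min` suggests loss of function, anything in between is
#' indeterminate. Events whose protein change is also produced by a
#' multi-nucleotide substitution (mnv_support) are left unscored unless their
#' SNV-derived revised count already exceeds the loss-of-function bound.
#'
#' @param revised Numeric revised counts.
#' @param mnv_support Logical, recycled.
#' @param wt_max Wild-type bound (default 700).
#' @param lof_min Loss-of-function bound (default 900).
#' @return Character labels: `wt_like`, `indeterminate`, `lof`, `unscored`.
#' @export
classify_functional <- function(revised, mnv_support = FALSE,
                                wt_max = 700, lof_min = 900) {
  if (wt_max > lof_min) stop("wt_max must not exceed lof_min")
  mnv_support <- rep_len(mnv_support, length(revised))
  label <- ifelse(revised < wt_max, "wt_like",
                  ifelse(revised > lof_min, "lof", "indeterminate"))
  label[mnv_support & revised < lof_min] <- "unscored"
  label
}

#' Calibrate the wild-type threshold from synonymous mutations
#'
#' Synonymous mutations are (mostly) functionally neutral, so the bulk of
#' their revised-count distribution delimits the range compatible with
#' retained function. The threshold is the stated percentile of the
#' synonymous revised counts (inverse-ECDF, i.e. a sorted-sample order
#' statistic). Synonymous events above it are reported as outliers — these
#' can be genuinely deleterious, e.g. splice-disrupting synonymous changes.
#'
#' @param synonymous Either a numeric vector of synonymous revised counts or
#'   an assessment data.frame with a `revised_count` column (rows above the
#'   threshold are then reported in full).
#' @param percentile Percentile in (0, 100] (default 95).
#' @param min_events Minimum sample size (default 20).
#' @return List of class `calibration_result`: `wt_max`, `percentile`,
#'   `n`, `sample` (the revised counts) and `outliers`.
#' @export
calibrate_thresholds <- function(synonymous, percentile = 95,
                                 min_events = 20) {
  df <- NULL
  if (is.data.frame(synonymous)) {
    df <- synonymous
    x <- synonymous$revised_count
  } else x <- as.numeric(synonymous)
  if (length(x) < min_events)
    stop("need at least ", min_events, " synonymous events to calibrate; ",
         "consider keeping the default thresholds (700/900)")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  s <- sort(x)
  wt_max <- s[ceiling(percentile / 100 * length(s))]
  above <- x > wt_max
  outliers <- if (!is.null(df)) df[above, , drop = FALSE] else
    data.frame(revised_count = x[above])
  structure(list(wt_max = wt_max, percentile = percentile, n = length(x),
                 sample = x, outliers = outliers),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: wt_max = %.5g (percentile %g of %d synonymous events)\n",
              x$wt_max, x$percentile, x$n))
  if (nrow(x$outliers))
    cat(nrow(x$outliers), "synonymous event(s) above wt_max",
        "(possible splice-disrupting changes)\n")
  invisible(x)
}

#' Assessment table for all events of a gene
#'
#' Computes original and revised counts and the functional label for every
#' event of one gene; optionally aggregates to amino-acid residues (all
#' events on a residue summed, as in per-residue mutation histograms).
#'
#' @param events Events from [aggregate_events()] (any genes; rows of `gene`
#'   are used).
#' @param gene Gene to assess.
#' @param genome A [coding_genome()].
#' @param fallback_table Pan-cancer `difficulty_table`.
#' @param type_tables Optional per-type tables.
#' @param wt_max,lof_min Classification thresholds (defaults 700/900).
#' @param by_residue If TRUE, return the per-residue aggregation instead of
#'   per-event rows.
#' @return data.frame with columns `protein_change`, `cds_change`,
#'   `pentamer`, `residue`, `consequence`, `original_count`, `revised_count`,
#'   `label`, `flags` (or residue sums when `by_residue`).
#' @export
annotate_gene <- function(events, gene, genome, fallback_table,
                          type_tables = NULL, wt_max = 700, lof_min = 900,
                          by_residue = FALSE) {
  keep <- events$gene == gene
  ev <- events[keep, , drop = FALSE]
  pt <- event_type_counts(events)
  attr(ev, "per_type") <- pt[pt$event_id %in%
    event_id(ev$gene, ev$cds_pos, ev$ref, ev$alt), , drop = FALSE]
  a <- assess_events(ev, genome, fallback_table, type_tables)
  if (nrow(a) == 0L) {
    out <- data.frame(protein_change = character(), cds_change = character(),
                      pentamer = character(), residue = integer(),
                      consequence = character(), original_count = integer(),
                      revised_count = numeric(), label = character(),
                      flags = character(), stringsAsFactors = FALSE)
    return(out)
  }
  prot <- mapply(protein_change_label, a$gene, a$cds_pos, a$ref, a$alt,
                 MoreArgs = list(genome = genome))
  residue <- (a$cds_pos - 1L) %/% 3L + 1L
  aa_ref <- substr(prot, 1L, 1L)
  aa_alt <- substring(prot, nchar(prot))
  consequence <- ifelse(is.na(prot), "unknown",
                 ifelse(aa_ref == aa_alt, "synonymous",
                 ifelse(aa_alt == "*", "nonsense", "missense")))
  out <- data.frame(protein_change = prot,
                    cds_change = sprintf("c.%d%s>%s", a$cds_pos, a$ref, a$alt),
                    pentamer = a$pentamer, residue = residue,
                    consequence = consequence,
                    original_count = a$original_count,
                    revised_count = a$revised_count,
                    label = classify_functional(a$revised_count,
                                                a$mnv_support,
                                                wt_max, lof_min),
                    flags = ifelse(a$mnv_support, "mnv_support", ""),
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue, out$cds_change), , drop = FALSE]
  rownames(out) <- NULL
  if (!by_residue) return(out)
  res <- stats::aggregate(out[c("original_count", "revised_count")],
                          by = list(residue = out$residue), FUN = sum)
  res$n_events <- as.integer(table(out$residue)[as.character(res$residue)])
  res[order(res$residue), , drop = FALSE]
}

#' Relative resistance index from a GFP competition assay
#'
#' RI = (G2 - G1*G2) / (G1 - G1*G2), where G1 and G2 are the GFP-positive
#' fractions before and after drug treatment. RI > 1 means the construct
#' enriched under treatment (dominant-negative readout); RI < 1 means it
#' sensitized cells.
#'
#' @param g1 GFP-positive fraction before treatment, strictly in (0, 1).
#' @param g2 GFP-positive fraction after treatment, in [0, 1); `g2 = 1`
#'   makes the denominator vanish.
#' @return The resistance index.
#' @export
resistance_index <- function(g1, g2) {
  if (any(g1 <= 0 | g1 >= 1))
    stop("RI is undefined for G1 of 0 or 1")
  if (any(g2 < 0 | g2 > 1)) stop("G2 must be in [0, 1]")
  if (any(g2 == 1)) stop("RI is undefined for G2 = 1 (denominator is zero)")
  (g2 - g1 * g2) / (g1 - g1 * g2)
}
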