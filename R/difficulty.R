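#' Per-class mutational tendency from counts
#'
#' The tendency of a mutation class is its mutation count divided by the
#' number of available context sites per coding genome times the number of
#' genomes surveyed: r = n / (s * N).
#'
#' @param count Class mutation count.
#' @param sites Context sites per coding genome for the class's pentamer.
#' @param n_genomes Number of cancer genomes surveyed.
#' @return Numeric tendency (per site per genome).
#' @export
mutation_tendency <- function(count, sites, n_genomes) {
  if (any(n_genomes <= 0)) stop("n_genomes must be positive")
  ifelse(sites > 0, count / (sites * n_genomes), NA_real_)
}

new_tendency_table <- function(df, n_genomes, n_unclassified = 0L) {
  rownames(df) <- NULL
  structure(df, n_genomes = n_genomes, n_unclassified = n_unclassified,
            class = c("tendency_table", "data.frame"))
}

#' Construct a tendency table from explicit rates
#'
#' Mainly useful for toy analyses and codon-shielding what-ifs where the
#' class rates are given rather than estimated from a catalog.
#'
#' @param pentamer,alt Class definition vectors (center of `pentamer` must
#'   differ from `alt`).
#' @param tendency Per-site, per-genome rates.
#' @param sites_per_genome,count Optional bookkeeping columns.
#' @param n_genomes Number of genomes the rates refer to (optional).
#' @return A `tendency_table` data.frame (columns `pentamer`, `alt`, `class`,
#'   `count`, `sites_per_genome`, `tendency`).
#' @export
tendency_table <- function(pentamer, alt, tendency,
                           sites_per_genome = NA_integer_,
                           count = NA_integer_, n_genomes = NA_integer_) {
  if (any(nchar(pentamer) != 5L)) stop("pentamers must be 5-mers")
  if (any(substr(pentamer, 3L, 3L) == alt))
    stop("alt must differ from the pentamer center")
  if (any(tendency < 0, na.rm = TRUE)) stop("tendencies must be >= 0")
  df <- data.frame(pentamer = pentamer, alt = alt,
                   class = class_id(pentamer, alt),
                   count = as.integer(count),
                   sites_per_genome = as.integer(sites_per_genome),
                   tendency = as.numeric(tendency),
                   stringsAsFactors = FALSE)
  new_tendency_table(df, n_genomes)
}

#' Estimate per-class mutational tendencies from a catalog
#'
#' Classifies the (recurrence-filtered) SNV records into the 3072 pentamer
#' classes and computes each class's tendency r = n / (s * N), where s is the
#' pentamer's site count per coding genome and N the number of genomes.
#' Classes whose pentamer never occurs in the coding genome (s = 0) have
#' undefined tendency and are reported via the `n_no_sites` attribute.
#'
#' @param records SNV records, normally the output of [filter_recurrent()].
#' @param genome A [coding_genome()].
#' @param n_genomes Number of cancer genomes the records came from.
#' @return A `tendency_table` covering all 3072 classes, with attributes
#'   `n_genomes`, `n_unclassified`, `n_no_sites` and `sites` (the full
#'   context site table).
#' @export
estimate_tendencies <- function(records, genome, n_genomes) {
  if (n_genomes <= 0) stop("n_genomes must be positive")
  classes <- all_context_classes()
  sites <- count_context_sites(genome)
  snv <- records[!records$is_mnv, , drop = FALSE]
  classified <- classify_mutation(snv, genome)
  counts <- table(factor(classified$class, levels = classes$class))
  df <- data.frame(pentamer = classes$pentamer, alt = classes$alt,
                   class = classes$class,
                   count = as.integer(counts[classes$class]),
                   sites_per_genome = as.integer(sites[classes$pentamer]),
                   stringsAsFactors = FALSE)
  df$sites_per_genome[is.na(df$sites_per_genome)] <- 0L
  df$tendency <- mutation_tendency(df$count, df$sites_per_genome, n_genomes)
  tt <- new_tendency_table(df, n_genomes,
                           attr(classified, "n_unclassified"))
  attr(tt, "n_no_sites") <- sum(df$sites_per_genome == 0L)
  attr(tt, "sites") <- sites
  tt
}

new_difficulty_table <- function(df, scope, n_genomes, reference_rate) {
  rownames(df) <- NULL
  structure(df, scope = scope, n_genomes = n_genomes,
            reference_rate = reference_rate,
            class = c("difficulty_table", "data.frame"))
}

#' Build a relative difficulty table from tendencies
#'
#' The difficulty of a class is the reference rate divided by the class's
#' tendency, D = r0 / r. By default r0 is the maximum tendency in the table
#' (the easiest class), which therefore gets difficulty 1 and every other
#' class difficulty >= 1. Cancer-type tables built against the pan-cancer
#' reference may have difficulties below 1 (easier than the pan-cancer
#' reference class).
#'
#' @param tendencies A `tendency_table`.
#' @param reference_rate Reference tendency r0; defaults to the table
#'   maximum.
#' @param zero_policy How to handle classes with zero observed mutations:
#'   `"undefined"` (default) flags them with NA difficulty; `"pseudocount"`
#'   recomputes their tendency with `count + pseudocount` (requires counts,
#'   sites and `n_genomes` in the table).
#' @param pseudocount Additive count used under the pseudocount policy
#'   (default 0.5).
#' @param scope Label stored with the table (`"pan-cancer"` or a cancer
#'   type).
#' @return A `difficulty_table` data.frame (columns `scope`, `pentamer`,
#'   `alt`, `class`, `count`, `sites_per_genome`, `tendency`, `difficulty`,
#'   `flag`).
#' @export
build_difficulty <- function(tendencies, reference_rate = NULL,
                             zero_policy = c("undefined", "pseudocount"),
                             pseudocount = 0.5, scope = "pan-cancer") {
  zero_policy <- match.arg(zero_policy)
  t <- tendencies$tendency
  if (is.null(reference_rate))
    reference_rate <- max(t, na.rm = TRUE)
  if (!is.finite(reference_rate) || reference_rate <= 0)
    stop("reference_rate must be positive")

  flag <- rep("", nrow(tendencies))
  no_sites <- !is.na(tendencies$sites_per_genome) &
    tendencies$sites_per_genome == 0L
  flag[no_sites | is.na(t)] <- "no_sites"
  zero <- !is.na(tendencies$count) & tendencies$count == 0L & !no_sites

  if (zero_policy == "pseudocount" && any(zero)) {
    n_genomes <- attr(tendencies, "n_genomes")
    if (is.null(n_genomes) || is.na(n_genomes))
      stop("pseudocount policy requires n_genomes in the tendency table")
    t[zero] <- mutation_tendency(tendencies$count[zero] + pseudocount,
                                 tendencies$sites_per_genome[zero], n_genomes)
    flag[zero] <- "pseudocount"
  } else if (any(zero)) {
    flag[zero] <- "undefined"
  }

  difficulty <- ifelse(flag %in% c("no_sites", "undefined") | is.na(t) | t == 0,
                       NA_real_, reference_rate / t)
  df <- data.frame(scope = scope, pentamer = tendencies$pentamer,
                   alt = tendencies$alt, class = tendencies$class,
                   count = tendencies$count,
                   sites_per_genome = tendencies$sites_per_genome,
                   tendency = t, difficulty = difficulty, flag = flag,
                   stringsAsFactors = FALSE)
  new_difficulty_table(df, scope, attr(tendencies, "n_genomes"),
                       reference_rate)
}

#' Cancer-type-specific difficulty tables
#'
#' Splits the (recurrence-filtered) records by cancer type, estimates each
#' type's tendencies with that type's sample count, and scores difficulty
#' against the pan-cancer reference rate, so per-type difficulties below 1
#' mean "easier than the pan-cancer reference class" and values are directly
#' comparable across types. Types with fewer than `min_samples` samples are
#' not estimated (too noisy); their names are returned in the
#' `fallback_types` attribute and downstream assessment uses the pan-cancer
#' table for them.
#'
#' @param records Filtered SNV records with a `cancer_type` column.
#' @param genome A [coding_genome()].
#' @param samples_per_type Named integer vector, samples surveyed per cancer
#'   type; every type present in `records` must be named.
#' @param pan_reference_rate The pan-cancer reference tendency r0.
#' @param min_samples Minimum samples for a per-type table (default 100).
#' @param zero_policy,pseudocount Passed to [build_difficulty()].
#' @return Named list of `difficulty_table`s (one per estimated type) with
#'   attribute `fallback_types`.
#' @export
cancer_type_difficulty <- function(records, genome, samples_per_type,
                                   pan_reference_rate, min_samples = 100,
                                   zero_policy = "undefined",
                                   pseudocount = 0.5) {
  types <- unique(records$cancer_type)
  unknown <- setdiff(types, names(samples_per_type))
  if (length(unknown))
    stop("unknown cancer type label(s): ", paste(unknown, collapse = ", "))
  est <- names(samples_per_type)[samples_per_type >= min_samples]
  out <- lapply(setNames(nm = est), function(ty) {
    tt <- estimate_tendencies(records[records$cancer_type == ty, ,
                                      drop = FALSE],
                              genome, samples_per_type[[ty]])
    build_difficulty(tt, reference_rate = pan_reference_rate,
                     zero_policy = zero_policy, pseudocount = pseudocount,
                     scope = ty)
  })
  attr(out, "fallback_types") <-
    setdiff(names(samples_per_type), est)
  out
}

#' Look up the difficulty of one mutation class
#'
#' @param table A `difficulty_table`.
#' @param pentamer,alt The class.
#' @return List with `difficulty` and `flag`.
#' @export
lookup_difficulty <- function(table, pentamer, alt) {
  i <- match(class_id(pentamer, alt), table$class)
  if (is.na(i))
    stop("class ", class_id(pentamer, alt), " not present in the ",
         attr(table, "scope") %||% "difficulty", " table")
  list(difficulty = table$difficulty[i], flag = table$flag[i])
}

#' Serialize / read a difficulty table
#'
#' Tab-separated text with a `#`-prefixed header line carrying the scope,
#' genome count and reference rate, then one row per class. Difficulties are
#' written at full precision.
#'
#' @param table A `difficulty_table`.
#' @param path File path.
#' @export
write_difficulty_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scope=%s n_genomes=%s reference_rate=%.17g",
                     attr(table, "scope"),
                     attr(table, "n_genomes") %||% NA,
                     attr(table, "reference_rate")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_difficulty_table
#' @export
read_difficulty_table <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
    regexec("^# scope=(.*) n_genomes=(\\S+) reference_rate=(\\S+)$",
            header))[[1]]
  if (length(meta) != 4L) stop("not a difficulty table file: ", path)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  df$flag[is.na(df$flag)] <- ""
  new_difficulty_table(df, meta[2L],
                       suppressWarnings(as.integer(meta[3L])),
                       as.numeric(meta[4L]))
}
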