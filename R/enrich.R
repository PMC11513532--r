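#' Build a per-sample count table
#'
#' Counts each variable region within every (tissue, cycle) sample. This is
#' the count-file step of the NGS analysis: one row per (sequence, tissue,
#' cycle) with its read count.
#'
#' @param samples A list of samples, each a list with elements `tissue`,
#'   `cycle`, and `regions` (character vector of accepted variable regions,
#'   one element per read). Alternatively a data.frame with columns
#'   `region`, `tissue`, `cycle`, one row per read.
#' @param last_cycle_map Named integer vector mapping tissue to its last
#'   sequenced cycle; defaults to [default_last_cycle_map()].
#' @return An object of class `count_table`: a list with `counts` (data.frame
#'   `sequence`, `tissue`, `cycle`, `count`, ordered by descending total
#'   count of the sequence, ties broken lexicographically), `sample_totals`
#'   (data.frame `tissue`, `cycle`, `total`), `last_cycle_map`, and
#'   `var_len`.
#' @examples
#' tab <- build_count_table(list(
#'   list(tissue = "retina", cycle = 10,
#'        regions = c("ACGT", "ACGT", "TTTT"))
#' ))
#' tab$counts
#' @export
build_count_table <- function(samples, last_cycle_map = default_last_cycle_map()) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("region", "tissue", "cycle") %in% names(samples)))
    reads <- samples[, c("region", "tissue", "cycle")]
  } else {
    parts <- lapply(samples, function(s) {
      stopifnot(all(c("tissue", "cycle", "regions") %in% names(s)))
      if (length(s$regions) == 0L) return(NULL)
      data.frame(region = as.character(s$regions),
                 tissue = s$tissue, cycle = as.integer(s$cycle),
                 stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, parts)
  }
  if (is.null(reads) || nrow(reads) == 0L) {
    counts <- data.frame(sequence = character(0), tissue = character(0),
                         cycle = integer(0), count = integer(0))
    totals <- data.frame(tissue = character(0), cycle = integer(0),
                         total = integer(0))
    return(structure(list(counts = counts, sample_totals = totals,
                          last_cycle_map = last_cycle_map,
                          var_len = NA_integer_),
                     class = "count_table"))
  }
  tissue_compartment(unique(reads$tissue))  # validates tissue names

  lens <- nchar(reads$region)
  if (length(unique(lens)) > 1L) {
    bad <- unique(reads$tissue[lens != lens[1L]])[1L]
    stop("mixed-length variable regions (sample tissue ", bad,
         "); filter to one length first")
  }

  agg <- stats::aggregate(list(count = rep(1L, nrow(reads))),
                          by = list(sequence = reads$region,
                                    tissue = reads$tissue,
                                    cycle = as.integer(reads$cycle)),
                          FUN = sum)
  seq_tot <- tapply(agg$count, agg$sequence, sum)
  agg <- agg[order(-seq_tot[agg$sequence], agg$sequence, agg$tissue,
                   agg$cycle), , drop = FALSE]
  rownames(agg) <- NULL

  totals <- stats::aggregate(list(total = agg$count),
                             by = list(tissue = agg$tissue,
                                       cycle = agg$cycle),
                             FUN = sum)
  totals <- totals[order(totals$tissue, totals$cycle), , drop = FALSE]
  rownames(totals) <- NULL

  structure(list(counts = agg, sample_totals = totals,
                 last_cycle_map = last_cycle_map,
                 var_len = lens[1L]),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("SELEX count table:",
      length(unique(x$counts$sequence)), "unique sequences,",
      nrow(x$sample_totals), "samples,",
      sum(x$counts$count), "reads\n")
  invisible(x)
}

#' Per-sequence total counts
#'
#' Total count of every unique sequence over all samples (tissues and
#' cycles) in the table.
#'
#' @param table A `count_table`.
#' @return Named integer vector of totals, named by sequence.
#' @export
sequence_totals <- function(table) {
  if (nrow(table$counts) == 0L) return(integer(0))
  tot <- tapply(table$counts$count, table$counts$sequence, sum)
  setNames(as.integer(tot), names(tot))
}

#' Copy-number threshold summary
#'
#' For each copy-number cutoff, counts the unique sequences whose total count
#' (summed over all samples in the table) is at least the cutoff — the
#' copy-number filter characterisation of the selection pool.
#'
#' @param table A [build_count_table()] result.
#' @param thresholds Increasing positive integer cutoffs; defaults to the
#'   standard ladder 1, 10, 100, 1e3, 2e3, 5e3, 1e4, 2e4, 3e4, 4e4, 1e5,
#'   2e5, 1e6.
#' @return Data.frame with columns `threshold` and `n_unique`,
#'   non-increasing in `threshold`.
#' @examples
#' tab <- build_count_table(list(list(tissue = "retina", cycle = 10,
#'   regions = c(rep("AAAA", 12), "CCCC"))))
#' threshold_summary(tab, c(1, 10))
#' @export
threshold_summary <- function(table, thresholds = DEFAULT_THRESHOLDS) {
  stopifnot(inherits(table, "count_table"))
  thresholds <- as.numeric(thresholds)
  if (any(thresholds < 1)) stop("thresholds must be >= 1")
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending")
  }
  tot <- sequence_totals(table)
  data.frame(threshold = thresholds,
             n_unique = vapply(thresholds, function(t) sum(tot >= t),
                               integer(1)))
}

#' Candidate filter by per-cycle counts
#'
#' Keeps sequences with at least `min_count` reads, summed across all tissues,
#' within any single qualifying cycle. This is the enrichment filter used to
#' nominate candidate aptamers (default: at least 10 counts in cycle 10 or
#' cycle 12).
#'
#' @param table A [build_count_table()] result.
#' @param min_count Minimum per-cycle count, default 10.
#' @param qualifying_cycles Cycles in which the count may qualify, default
#'   `c(10, 12)`.
#' @param per_tissue If `TRUE`, the count must be reached within a single
#'   (tissue, cycle) sample rather than summed across tissues per cycle.
#' @return Character vector of qualifying variable regions (sorted).
#' @examples
#' tab <- build_count_table(list(list(tissue = "retina", cycle = 10,
#'   regions = rep("AAAA", 12))))
#' candidate_filter(tab)
#' @export
candidate_filter <- function(table, min_count = 10,
                             qualifying_cycles = c(10, 12),
                             per_tissue = FALSE) {
  stopifnot(inherits(table, "count_table"))
  cc <- table$counts[table$counts$cycle %in% qualifying_cycles, , drop = FALSE]
  if (nrow(cc) == 0L) return(character(0))
  if (per_tissue) {
    keep <- unique(cc$sequence[cc$count >= min_count])
  } else {
    per_cycle <- stats::aggregate(list(count = cc$count),
                                  by = list(sequence = cc$sequence,
                                            cycle = cc$cycle),
                                  FUN = sum)
    keep <- unique(per_cycle$sequence[per_cycle$count >= min_count])
  }
  sort(keep)
}

# Resolve a scope argument to the tissues it covers.
scope_tissues <- function(scope) {
  if (scope == "pool") return(selex_tissues())
  if (scope == "ocular") return(OCULAR_TISSUES)
  if (scope == "control") return(CONTROL_TISSUES)
  tissue <- sub("^tissue:", "", scope)
  tissue_compartment(tissue)  # validates
  tissue
}

#' Normalised abundance profile
#'
#' Converts counts to pool fractions: for each requested cycle, a sequence's
#' fraction is its count within the scope (a tissue, the ocular or control
#' compartment, or the whole pool) divided by the scope's total count in
#' that cycle. The `"last"` cycle selector resolves per tissue, so
#' RPE-choroid contributes its cycle-12 sample while other tissues
#' contribute cycle 14.
#'
#' @param table A [build_count_table()] result.
#' @param scope `"pool"`, `"ocular"`, `"control"`, a tissue name, or
#'   `"tissue:<name>"`.
#' @param cycles Integer vector of cycles, or `"last"` for the per-tissue
#'   last sequenced cycle.
#' @return An object of class `enrichment_profile`: a data.frame with
#'   columns `sequence`, `scope`, `cycle` (the label `"last"` is kept as
#'   given), and `fraction`. Fractions within each (scope, cycle) sum to 1.
#' @examples
#' tab <- build_count_table(list(list(tissue = "retina", cycle = 14,
#'   regions = c(rep("AAAA", 3), rep("CCCC", 7)))))
#' normalize_abundance(tab, "retina", 14)
#' @export
normalize_abundance <- function(table, scope = "pool", cycles = "last") {
  stopifnot(inherits(table, "count_table"))
  tissues <- scope_tissues(scope)
  cc <- table$counts[table$counts$tissue %in% tissues, , drop = FALSE]

  one_cycle <- function(cycle) {
    if (identical(cycle, "last")) {
      last <- table$last_cycle_map[cc$tissue]
      sel <- cc[cc$cycle == last, , drop = FALSE]
    } else {
      sel <- cc[cc$cycle == as.integer(cycle), , drop = FALSE]
    }
    denom <- sum(sel$count)
    if (denom == 0) {
      stop("no counts for scope '", scope, "' in cycle ", cycle)
    }
    agg <- stats::aggregate(list(count = sel$count),
                            by = list(sequence = sel$sequence), FUN = sum)
    data.frame(sequence = agg$sequence, scope = scope,
               cycle = as.character(cycle),
               fraction = agg$count / denom,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(as.list(cycles), one_cycle))
  out <- out[order(out$cycle, -out$fraction, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Assemble an enrichment profile from known fractions
#'
#' Builds an `enrichment_profile` directly from already-computed pool
#' fractions (e.g. published percentages), so fold changes can be computed
#' without the underlying count table.
#'
#' @param sequence,scope,cycle,fraction Vectors of equal length (recycled as
#'   usual); `fraction` in `[0, 1]`.
#' @return An `enrichment_profile` data.frame.
#' @examples
#' enrichment_profile("Apt5", "ocular", c(10, 14), c(0.0002, 0.0121))
#' @export
enrichment_profile <- function(sequence, scope, cycle, fraction) {
  if (any(fraction < 0 | fraction > 1)) stop("fractions must be in [0, 1]")
  out <- data.frame(sequence = sequence, scope = scope,
                    cycle = as.character(cycle), fraction = fraction,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Cross-cycle fold change of a sequence's pool fraction
#'
#' Ratio of a sequence's normalised abundance between two cycles within one
#' scope. Computed on fractions, not raw counts, because sequencing depth
#' differs per cycle.
#'
#' @param profile An `enrichment_profile` (from [normalize_abundance()] or
#'   [enrichment_profile()]) containing both cycles.
#' @param sequence Variable region (or label) to look up.
#' @param scope Scope label as present in the profile.
#' @param cycle_from,cycle_to Cycle labels.
#' @param pseudocount Optional fraction added to both numerator and
#'   denominator; default 0 (a zero baseline is an error, not silently
#'   patched).
#' @return The fold change (positive real) at full precision.
#' @examples
#' p <- enrichment_profile("Apt5", "ocular", c(10, 14), c(0.0002, 0.0121))
#' fold_change(p, "Apt5", "ocular", 10, 14)
#' @export
fold_change <- function(profile, sequence, scope, cycle_from, cycle_to,
                        pseudocount = 0) {
  lookup <- function(cycle) {
    hit <- profile$fraction[profile$sequence == sequence &
                            profile$scope == scope &
                            profile$cycle == as.character(cycle)]
    if (length(hit) == 0L) {
      stop("no fraction for ", sequence, " in scope '", scope,
           "' cycle ", cycle)
    }
    hit[1L]
  }
  from <- lookup(cycle_from) + pseudocount
  to <- lookup(cycle_to) + pseudocount
  if (from <= 0) {
    stop("zero baseline fraction at cycle ", cycle_from,
         "; pass a pseudocount explicitly if one is wanted")
  }
  to / from
}

#' Read and write count tables as TSV
#'
#' Count tables are exchanged as TSV with columns `sequence`, `tissue`,
#' `cycle`, `count`.
#'
#' @param table A `count_table`.
#' @param path File path.
#' @param last_cycle_map Passed to the rebuilt table on read.
#' @return `write_count_table` invisibly returns `table`;
#'   `read_count_table` returns a `count_table`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  write.table(table$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(table)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, last_cycle_map = default_last_cycle_map()) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer",
                                  "integer"))
  count_table_from_counts(df, last_cycle_map = last_cycle_map)
}

# Build a count_table from an already-aggregated (sequence, tissue, cycle,
# count) data.frame without expanding to per-read rows.
count_table_from_counts <- function(df, last_cycle_map = default_last_cycle_map()) {
  stopifnot(all(c("sequence", "tissue", "cycle", "count") %in% names(df)))
  df <- df[df$count > 0, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(build_count_table(list(), last_cycle_map = last_cycle_map))
  }
  tissue_compartment(unique(df$tissue))
  lens <- nchar(df$sequence)
  if (length(unique(lens)) > 1L) stop("mixed-length variable regions")
  agg <- stats::aggregate(list(count = as.integer(df$count)),
                          by = list(sequence = df$sequence,
                                    tissue = df$tissue,
                                    cycle = as.integer(df$cycle)),
                          FUN = sum)
  seq_tot <- tapply(agg$count, agg$sequence, sum)
  agg <- agg[order(-seq_tot[agg$sequence], agg$sequence, agg$tissue,
                   agg$cycle), , drop = FALSE]
  rownames(agg) <- NULL
  totals <- stats::aggregate(list(total = agg$count),
                             by = list(tissue = agg$tissue, cycle = agg$cycle),
                             FUN = sum)
  totals <- totals[order(totals$tissue, totals$cycle), , drop = FALSE]
  rownames(totals) <- NULL
  structure(list(counts = agg, sample_totals = totals,
                 last_cycle_map = last_cycle_map, var_len = lens[1L]),
            class = "count_table")
}
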