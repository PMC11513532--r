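#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis run needs: the sample manifest
#' (one sequence file per tissue x cycle), the library definition, filter
#' and clustering parameters, and the output directory.
#'
#' @param manifest Data.frame with columns `path`, `tissue`, `cycle` and
#'   optionally `format` (`"auto"` default).
#' @param lib A [library_def()].
#' @param thresholds Copy-number cutoffs for the threshold summary.
#' @param min_count,qualifying_cycles Candidate filter parameters (see
#'   [candidate_filter()]).
#' @param family_threshold Identity threshold for [cluster_families()].
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed recorded in the report (the analysis itself is
#'   deterministic).
#' @param last_cycle_map Per-tissue last sequenced cycle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest, lib = library_def(),
                       thresholds = DEFAULT_THRESHOLDS,
                       min_count = 10, qualifying_cycles = c(10, 12),
                       family_threshold = 0.80,
                       out_dir = "selexscope_report", seed = 1L,
                       last_cycle_map = default_last_cycle_map()) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    stop("manifest must be a nonempty data.frame (path, tissue, cycle)")
  }
  stopifnot(all(c("path", "tissue", "cycle") %in% names(manifest)))
  if (!"format" %in% names(manifest)) manifest$format <- "auto"
  tissue_compartment(unique(manifest$tissue))
  if (any(manifest$cycle < 1)) stop("cycles must be >= 1")
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0L) {
    stop("manifest file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(manifest = manifest, lib = lib, thresholds = thresholds,
                 min_count = min_count,
                 qualifying_cycles = qualifying_cycles,
                 family_threshold = family_threshold, out_dir = out_dir,
                 seed = as.integer(seed), last_cycle_map = last_cycle_map),
            class = "run_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes extraction, counting, threshold summary, candidate filtering,
#' family clustering, and abundance/fold-change profiling over all samples
#' in the configuration, and writes a report bundle: `report.json` (all
#' parameters plus section summaries), `counts.tsv`, `thresholds.csv`,
#' `candidates.txt`, `families.tsv`, `extraction_report.tsv`, and one
#' abundance CSV per scope. Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `count_table`,
#'   `thresholds`, `candidates`, `families`, `family_summary`,
#'   `abundance` (list per scope), `extraction` (per-sample status
#'   tallies).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  man <- config$manifest

  say("extract: ", nrow(man), " samples")
  extraction <- list()
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    reads <- tryCatch(
      read_sequences(man$path[i], man$format[i]),
      error = function(e) stop("stage extract failed for sample ",
                               man$tissue[i], " cycle ", man$cycle[i], ": ",
                               conditionMessage(e), call. = FALSE)
    )
    res <- extract_variable_region(reads$sequence, config$lib)
    flt <- filter_correct_length(res, config$lib)
    extraction[[i]] <- data.frame(tissue = man$tissue[i],
                                  cycle = man$cycle[i],
                                  status = names(flt$tallies),
                                  count = as.integer(flt$tallies),
                                  stringsAsFactors = FALSE)
    samples[[i]] <- list(tissue = man$tissue[i], cycle = man$cycle[i],
                         regions = flt$regions)
  }
  extraction <- do.call(rbind, extraction)

  say("count")
  tab <- build_count_table(samples, last_cycle_map = config$last_cycle_map)
  say("thresholds")
  thr <- threshold_summary(tab, config$thresholds)
  say("candidates")
  cand <- candidate_filter(tab, min_count = config$min_count,
                           qualifying_cycles = config$qualifying_cycles)
  say("families: ", length(cand), " candidate sequences")
  tot <- sequence_totals(tab)
  fam_counts <- tot[names(tot) %in% cand]
  fams <- cluster_families(names(fam_counts), as.integer(fam_counts),
                           threshold = config$family_threshold)
  fam_sum <- family_summary(fams, tab)

  say("abundance")
  scopes <- c("pool", "ocular", "control",
              intersect(selex_tissues(), unique(man$tissue)))
  abundance <- lapply(scopes, function(sc) {
    cycles <- sort(unique(man$cycle[man$tissue %in% scope_tissues(sc)]))
    normalize_abundance(tab, sc, cycles)
  })
  names(abundance) <- scopes

  write_report_bundle(config, extraction, tab, thr, cand, fams, fam_sum,
                      abundance)
  say("report written to ", config$out_dir)
  invisible(list(count_table = tab, thresholds = thr, candidates = cand,
                 families = fams, family_summary = fam_sum,
                 abundance = abundance, extraction = extraction))
}

write_report_bundle <- function(config, extraction, tab, thr, cand, fams,
                                fam_sum, abundance) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  write.table(extraction, out("extraction_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_count_table(tab, out("counts.tsv"))
  write.table(thr, out("thresholds.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  writeLines(cand, out("candidates.txt"))
  write_family_manifest(fams, out("families.tsv"))
  write.table(fam_sum, out("family_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (sc in names(abundance)) {
    fn <- out(sprintf("abundance_%s.csv", gsub("[^a-z_]", "", sc)))
    write.table(abundance[[sc]], fn, sep = ",", quote = FALSE,
                row.names = FALSE)
  }

  report <- list(
    version = as.character(utils::packageVersion("selexscope")),
    seed = config$seed,
    parameters = list(
      const5 = config$lib$const5, const3 = config$lib$const3,
      var_len = config$lib$var_len, max_mismatch = config$lib$max_mismatch,
      thresholds = config$thresholds, min_count = config$min_count,
      qualifying_cycles = config$qualifying_cycles,
      family_threshold = config$family_threshold,
      last_cycle_map = as.list(config$last_cycle_map)
    ),
    samples = nrow(config$manifest),
    reads_total = sum(extraction$count),
    reads_accepted = sum(extraction$count[extraction$status == "ok"]),
    unique_sequences = length(unique(tab$counts$sequence)),
    candidates = length(cand),
    families = length(fams),
    threshold_summary = thr,
    family_summary = fam_sum
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
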