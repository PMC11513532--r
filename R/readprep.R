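#' Aptamer library definition
#'
#' Describes the amplicon construct: a fixed-length randomised variable
#' region flanked by 5' and 3' constant regions used as extraction anchors.
#' Sequences are stored DNA-sense; RNA input (U) is normalised to T so the
#' same library can be written in either alphabet.
#'
#' @param const5,const3 Constant (fixed) regions flanking the variable
#'   region, 5' and 3' respectively. Defaults are the selection library used
#'   throughout this package.
#' @param var_len Length of the randomised variable region in nucleotides.
#' @param max_mismatch Number of mismatches tolerated when locating each
#'   constant region in a read (ungapped). Default 0: exact anchors.
#' @return An object of class `library_def`.
#' @examples
#' lib <- library_def()
#' lib
#' @export
library_def <- function(const5 = "GGGGCCACCAACGACATT",
                        const3 = "GTTGATATAAATAGTGCCCATGGATC",
                        var_len = 36L,
                        max_mismatch = 0L) {
  const5 <- normalize_dna(const5)
  const3 <- normalize_dna(const3)
  for (nm in c("const5", "const3")) {
    s <- get(nm)
    if (length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      stop(nm, " must be a single nonempty sequence")
    }
    if (grepl("[^ACGT]", s)) {
      stop(nm, " contains characters outside {A,C,G,T} after U->T ",
           "normalisation: ", s)
    }
  }
  var_len <- as.integer(var_len)
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(var_len) || var_len <= 0L) stop("var_len must be a positive integer")
  if (is.na(max_mismatch) || max_mismatch < 0L ||
      max_mismatch >= min(nchar(const5), nchar(const3))) {
    stop("max_mismatch must be >= 0 and smaller than the shorter constant region")
  }
  structure(
    list(const5 = const5, const3 = const3, var_len = var_len,
         max_mismatch = max_mismatch),
    class = "library_def"
  )
}

#' @export
print.library_def <- function(x, ...) {
  cat("Aptamer library definition\n")
  cat("  5' constant :", x$const5, sprintf("(%d nt)\n", nchar(x$const5)))
  cat("  variable    : N", x$var_len, "\n", sep = "")
  cat("  3' constant :", x$const3, sprintf("(%d nt)\n", nchar(x$const3)))
  cat("  max mismatch per anchor:", x$max_mismatch, "\n")
  invisible(x)
}

# Uppercase and U->T so RNA- and DNA-spelled sequences compare equal.
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGGGCCACCAACGACATT")
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file and returns the
#' records with sequences uppercased and U normalised to T. Qualities are
#' ignored.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (guessed from the file
#'   extension).
#' @return A data.frame with columns `read_id` and `sequence`, one row per
#'   record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGU", ">r2", "ggtt"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
              else if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) "fasta"
              else stop("cannot guess format from extension of ", path,
                        "; pass format explicitly")
  }
  if (format == "fastq") validate_fastq(path)
  # read as raw strings so RNA letters survive until our own U->T step
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  data.frame(
    read_id = if (is.null(names(set))) as.character(seq_along(set))
              else sub("\\s.*$", "", names(set)),
    sequence = normalize_dna(as.character(set)),
    stringsAsFactors = FALSE
  )
}

# Record-level structure check so a truncated FASTQ reports which record
# failed (Biostrings' own error does not carry the index).
validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed fastq file ", path, ": truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(invisible(TRUE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
               nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop("malformed fastq file ", path, ": record ", bad[1L], call. = FALSE)
  }
  invisible(TRUE)
}

EXTRACTION_STATUSES <- c("ok", "no_5prime_anchor", "no_3prime_anchor",
                         "wrong_length", "ambiguous_base")

#' Extract the variable region from reads
#'
#' Locates the 5' and 3' constant regions in each read (ungapped, up to
#' `lib$max_mismatch` mismatches per anchor) and returns the substring
#' strictly between them. The forward strand is searched first; if the
#' extraction fails there, the reverse complement of the read is searched.
#' When a constant occurs more than once, the leftmost 5' anchor and the
#' first 3' anchor after it are used.
#'
#' Status codes: `ok` (region extracted, exactly `var_len` unambiguous
#' bases), `no_5prime_anchor`, `no_3prime_anchor` (5' anchor present, no 3'
#' anchor after it in either orientation), `wrong_length` (inter-anchor
#' distance differs from `var_len`), `ambiguous_base` (correct length but
#' contains a base outside A/C/G/T, e.g. N).
#'
#' @param sequence Character vector of read sequences (DNA or RNA spelling).
#' @param lib A [library_def()].
#' @return A data.frame with one row per input read and columns
#'   `variable_region` (NA unless status is `ok`), `status`, and
#'   `orientation` (`"forward"` or `"reverse_complement"`, NA when no 5'
#'   anchor was found).
#' @examples
#' lib <- library_def()
#' read <- paste0(lib$const5, strrep("A", 36), lib$const3)
#' extract_variable_region(read, lib)
#' @export
extract_variable_region <- function(sequence, lib) {
  stopifnot(inherits(lib, "library_def"))
  n <- length(sequence)
  out <- data.frame(
    variable_region = rep(NA_character_, n),
    status = rep("no_5prime_anchor", n),
    orientation = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  sequence <- normalize_dna(sequence)

  fwd <- locate_between_anchors(sequence, lib)
  need_rc <- fwd$status != "extracted"
  if (any(need_rc)) {
    rc <- locate_between_anchors(reverse_complement(sequence[need_rc]), lib)
  }

  # Forward result wins when it extracted a region; otherwise the reverse
  # complement is used if it extracted, else the more informative failure.
  status <- fwd$status
  region <- fwd$region
  orientation <- ifelse(fwd$status == "extracted", "forward", NA_character_)
  if (any(need_rc)) {
    idx <- which(need_rc)
    take_rc <- rc$status == "extracted" |
      (rc$status == "no_3prime_anchor" & fwd$status[idx] == "no_5prime_anchor")
    status[idx][take_rc] <- rc$status[take_rc]
    region[idx][take_rc] <- rc$region[take_rc]
    orientation[idx][take_rc] <-
      ifelse(rc$status[take_rc] == "extracted", "reverse_complement",
             NA_character_)
  }

  extracted <- status == "extracted"
  wrong_len <- extracted & nchar(region) != lib$var_len
  ambiguous <- extracted & !wrong_len & grepl("[^ACGT]", region)
  ok <- extracted & !wrong_len & !ambiguous

  out$status[!extracted] <- status[!extracted]
  out$status[wrong_len] <- "wrong_length"
  out$status[ambiguous] <- "ambiguous_base"
  out$status[ok] <- "ok"
  out$variable_region[ok] <- region[ok]
  out$orientation <- orientation
  out
}

# Single-orientation anchored search. Returns status in
# {extracted, no_5prime_anchor, no_3prime_anchor} plus the raw inter-anchor
# substring (any length) for "extracted".
locate_between_anchors <- function(sequence, lib) {
  n <- length(sequence)
  subj <- Biostrings::DNAStringSet(sequence)
  m5 <- Biostrings::vmatchPattern(lib$const5, subj,
                                  max.mismatch = lib$max_mismatch,
                                  fixed = TRUE)
  s5 <- Biostrings::startIndex(m5)
  start5 <- vapply(s5, function(s) if (is.null(s)) NA_integer_ else min(s),
                   integer(1))
  status <- ifelse(is.na(start5), "no_5prime_anchor", "no_3prime_anchor")
  region <- rep(NA_character_, n)

  has5 <- !is.na(start5)
  if (any(has5)) {
    m3 <- Biostrings::vmatchPattern(lib$const3, subj[has5],
                                    max.mismatch = lib$max_mismatch,
                                    fixed = TRUE)
    s3 <- Biostrings::startIndex(m3)
    from <- start5[has5] + nchar(lib$const5)   # first position after const5
    start3 <- mapply(function(starts, lo) {
      if (is.null(starts)) return(NA_integer_)
      cand <- starts[starts >= lo]
      if (length(cand) == 0L) NA_integer_ else min(cand)
    }, s3, from)
    got3 <- !is.na(start3)
    idx <- which(has5)[got3]
    if (length(idx) > 0L) {
      status[idx] <- "extracted"
      region[idx] <- substr(sequence[idx], from[got3], start3[got3] - 1L)
    }
  }
  list(status = status, region = region)
}

#' Keep correct-length variable regions and tally rejections
#'
#' Filters extraction results down to the regions that extracted cleanly at
#' the library's variable-region length, and reports how many reads fell
#' into each status class.
#'
#' @param results Data.frame from [extract_variable_region()].
#' @param lib A [library_def()].
#' @return A list with `regions` (character vector of accepted variable
#'   regions) and `tallies` (named integer vector over all status codes;
#'   sums to the number of input reads).
#' @examples
#' lib <- library_def()
#' reads <- paste0(lib$const5, c(strrep("A", 36), strrep("C", 35)), lib$const3)
#' filter_correct_length(extract_variable_region(reads, lib), lib)
#' @export
filter_correct_length <- function(results, lib) {
  stopifnot(is.data.frame(results),
            all(c("variable_region", "status") %in% names(results)))
  tallies <- table(factor(results$status, levels = EXTRACTION_STATUSES))
  regions <- results$variable_region[results$status == "ok"]
  if (length(regions) > 0 && any(nchar(regions) != lib$var_len)) {
    stop("internal error: accepted region with wrong length")
  }
  list(regions = as.character(regions),
       tallies = setNames(as.integer(tallies), names(tallies)))
}

#' Write accepted regions and a rejection report
#'
#' Writes one FASTA file of accepted variable regions and a TSV rejection
#' report (columns `status`, `count`) for a sample.
#'
#' @param filtered Result of [filter_correct_length()].
#' @param fasta_path,report_path Output file paths.
#' @param sample Sample name used in FASTA record ids.
#' @return Invisibly, `filtered`.
#' @export
write_region_fasta <- function(filtered, fasta_path, report_path = NULL,
                               sample = "sample") {
  regions <- filtered$regions
  set <- Biostrings::DNAStringSet(regions)
  names(set) <- sprintf("%s_%06d", sample, seq_along(regions))
  Biostrings::writeXStringSet(set, fasta_path, format = "fasta")
  if (!is.null(report_path)) {
    rep <- data.frame(status = names(filtered$tallies),
                      count = as.integer(filtered$tallies))
    write.table(rep, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(filtered)
}
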