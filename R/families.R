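#' Ungapped pairwise nucleotide identity
#'
#' Fraction of positions at which two equal-length sequences carry the same
#' base. This is the conservation measure behind the family search: two
#' variable regions belong to the same family when their identity meets the
#' family threshold (default 80%). No gaps are considered — all regions are
#' filtered to one fixed length upstream.
#'
#' @param a,b Sequences of equal length.
#' @return Identity as a fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")")
  }
  if (nchar(a) == 0L) stop("sequences must be nonempty")
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# Identity of one sequence against many (vectorised over `many`).
identity_to <- function(seed, many) {
  if (length(many) == 0L) return(numeric(0))
  sm <- strsplit(seed, "")[[1]]
  vapply(strsplit(many, ""), function(x) mean(x == sm), numeric(1))
}

#' Cluster variable regions into families
#'
#' Greedy abundance-seeded clustering at a nucleotide-identity threshold:
#' regions are visited in descending count order (ties broken
#' lexicographically); each region joins the first existing family whose
#' seed it matches at or above the threshold (`mode = "seed"`), or whose
#' every member it matches (`mode = "complete"`); otherwise it founds a new
#' family with itself as seed. Seeds are therefore always the most abundant
#' member of their family, and the procedure is deterministic.
#'
#' @param regions Character vector of variable regions (all one length), or
#'   a named integer vector of counts.
#' @param counts Integer vector of total counts per region (>= 1), ignored
#'   when `regions` is a named count vector.
#' @param threshold Identity threshold, default 0.80.
#' @param mode `"seed"` (identity to the family seed, default) or
#'   `"complete"` (identity to every current member).
#' @param inclusive If `TRUE` (default), identity exactly at the threshold
#'   joins the family (the ">= 80%" reading); `FALSE` requires strict
#'   excess.
#' @return An object of class `family_set`: a list of families, each a list
#'   with `seed`, `members` (data.frame `region`, `count`,
#'   `identity_to_seed`, sorted by descending count), and `total_count`.
#'   Families are sorted by descending total count. The attribute
#'   `threshold` records the threshold used.
#' @examples
#' fams <- cluster_families(c(A = 10L, B = 2L),
#'   threshold = 0.8)
#' @export
cluster_families <- function(regions, counts = NULL, threshold = 0.80,
                             mode = c("seed", "complete"),
                             inclusive = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(names(regions)) && is.numeric(regions)) {
    counts <- as.integer(regions)
    regions <- names(regions)
  }
  if (length(regions) == 0L) {
    return(structure(list(), class = "family_set", threshold = threshold))
  }
  if (is.null(counts)) counts <- rep(1L, length(regions))
  stopifnot(length(counts) == length(regions), all(counts >= 1))
  if (length(unique(nchar(regions))) > 1L) {
    stop("all regions must have the same length")
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")

  ord <- order(-counts, regions)
  regions <- regions[ord]
  counts <- counts[ord]

  meets <- if (inclusive) function(id) id >= threshold
           else function(id) id > threshold
  seeds <- character(0)
  assign <- integer(length(regions))
  member_idx <- list()
  for (i in seq_along(regions)) {
    placed <- FALSE
    if (length(seeds) > 0L) {
      ids <- identity_to(regions[i], seeds)
      for (f in seq_along(seeds)) {
        if (!meets(ids[f])) next
        if (mode == "complete") {
          all_ids <- identity_to(regions[i], regions[member_idx[[f]]])
          if (!all(meets(all_ids))) next
        }
        assign[i] <- f
        member_idx[[f]] <- c(member_idx[[f]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, regions[i])
      member_idx[[length(seeds)]] <- i
      assign[i] <- length(seeds)
    }
  }

  fams <- lapply(seq_along(seeds), function(f) {
    idx <- member_idx[[f]]
    members <- data.frame(region = regions[idx], count = counts[idx],
                          identity_to_seed = identity_to(seeds[f],
                                                         regions[idx]),
                          stringsAsFactors = FALSE)
    list(seed = seeds[f], members = members,
         total_count = sum(members$count))
  })
  fams <- fams[order(-vapply(fams, `[[`, numeric(1), "total_count"),
                     vapply(fams, `[[`, character(1), "seed"))]
  structure(fams, class = "family_set", threshold = threshold)
}

#' @export
print.family_set <- function(x, ...) {
  cat("Family set:", length(x), "families at identity threshold >=",
      attr(x, "threshold"), "\n")
  for (i in seq_len(min(length(x), 10L))) {
    cat(sprintf("  family %d: %d members, %d counts, seed %s\n", i,
                nrow(x[[i]]$members), x[[i]]$total_count, x[[i]]$seed))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Summarise families against a count table
#'
#' Reports, per family, the number of member sequences and the
#' count-weighted fraction of the pool its members make up. When the
#' families were built from every sequence in the table the fractions sum
#' to 1; otherwise the remainder is the unclustered mass.
#'
#' @param families A [cluster_families()] result.
#' @param table A `count_table`, or a single number giving the grand total
#'   count of the pool.
#' @return Data.frame with columns `family`, `seed`, `n_members`,
#'   `total_count`, `pool_fraction`.
#' @export
family_summary <- function(families, table) {
  stopifnot(inherits(families, "family_set"))
  grand <- if (inherits(table, "count_table")) sum(table$counts$count)
           else as.numeric(table)
  if (grand <= 0) stop("pool total must be positive")
  if (length(families) == 0L) {
    return(data.frame(family = integer(0), seed = character(0),
                      n_members = integer(0), total_count = integer(0),
                      pool_fraction = numeric(0)))
  }
  data.frame(
    family = seq_along(families),
    seed = vapply(families, `[[`, character(1), "seed"),
    n_members = vapply(families, function(f) nrow(f$members), integer(1)),
    total_count = vapply(families, `[[`, numeric(1), "total_count"),
    pool_fraction = vapply(families, `[[`, numeric(1), "total_count") / grand,
    stringsAsFactors = FALSE
  )
}

#' Per-position conservation profile of a family
#'
#' Count-weighted base frequencies at every position of the variable region,
#' with the consensus (modal base, ties broken alphabetically and flagged)
#' and the per-position conservation fraction.
#'
#' @param family One element of a [cluster_families()] result (a list with
#'   `members`).
#' @return A list with `freq` (var_len x 4 matrix, columns A, C, G, T, rows
#'   summing to 1), `consensus` (string), `conservation` (numeric vector of
#'   modal-base fractions), and `ties` (logical vector flagging positions
#'   where the modal base was tied).
#' @export
conservation_profile <- function(family) {
  members <- family$members
  if (is.null(members) || nrow(members) == 0L) stop("family is empty")
  len <- nchar(members$region[1L])
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = len, ncol = 4L, dimnames = list(NULL, bases))
  chars <- strsplit(members$region, "")
  for (i in seq_len(nrow(members))) {
    w <- members$count[i]
    for (p in seq_len(len)) {
      mat[p, chars[[i]][p]] <- mat[p, chars[[i]][p]] + w
    }
  }
  freq <- mat / rowSums(mat)
  top <- apply(freq, 1L, max)
  ties <- apply(freq, 1L, function(r) sum(r == max(r)) > 1L)
  consensus <- paste(bases[apply(freq, 1L, which.max)], collapse = "")
  list(freq = freq, consensus = consensus, conservation = unname(top),
       ties = unname(ties))
}

#' Write a family manifest
#'
#' Writes one TSV manifest row per family member: family id, seed, member
#' region, count, identity to seed.
#'
#' @param families A `family_set`.
#' @param path Output TSV path.
#' @return Invisibly, the manifest data.frame.
#' @export
write_family_manifest <- function(families, path) {
  stopifnot(inherits(families, "family_set"))
  rows <- lapply(seq_along(families), function(i) {
    m <- families[[i]]$members
    data.frame(family = i, seed = families[[i]]$seed, member = m$region,
               count = m$count,
               identity_to_seed = round(m$identity_to_seed, 6),
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows) > 0) do.call(rbind, rows)
              else data.frame(family = integer(0), seed = character(0),
                              member = character(0), count = integer(0),
                              identity_to_seed = numeric(0))
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
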