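# Independent oracles and small fixture builders, deliberately implemented
# with primitives different from the package internals.

# Reverse complement by explicit base complement + reversal (no Biostrings).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Dictionary recount of a per-read region stream.
oracle_count <- function(regions) {
  tab <- table(regions)
  setNames(as.integer(tab), names(tab))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_seqs <- function(n, len) vapply(seq_len(n), function(i) random_seq(len),
                                       character(1))

# Mutate `k` distinct positions of a sequence (to a different base).
mutate_positions <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Printed variable regions of the named aptamers (Results section values
# reused across tests).
APT1 <- "GATTGTCCCAAATTATCCTTAGAACTTTTACCTCCA"
APT2 <- "TTGACTGAATACGCACATTCGCCAAATTGCCGGCCC"
APT5 <- "TGTACGCTCGCATTTGTGCGTTGGTGACCGCACTCA"
APT6 <- "GATTGTCCCAAATTATCCTTAGAACTTTTATCTCCA"
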