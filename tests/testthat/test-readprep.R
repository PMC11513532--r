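test_that("library_def validates and normalises its inputs", {
  lib <- library_def()
  expect_equal(lib$const5, "GGGGCCACCAACGACATT")
  expect_equal(lib$const3, "GTTGATATAAATAGTGCCCATGGATC")
  expect_equal(lib$var_len, 36L)

  # RNA spelling maps onto the same DNA-sense definition
  rna <- library_def(const5 = "GGGGCCACCAACGACAUU",
                     const3 = "GUUGAUAUAAAUAGUGCCCAUGGAUC")
  expect_identical(rna[c("const5", "const3")], lib[c("const5", "const3")])

  expect_error(library_def(const5 = ""), "nonempty")
  expect_error(library_def(const5 = "ACGTN"), "A,C,G,T")
  expect_error(library_def(var_len = 0), "positive")
  expect_error(library_def(max_mismatch = 18), "max_mismatch")
})

test_that("read_sequences round-trips FASTA and normalises RNA", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1 extra header", "ACGU", ">r2", "ggtt"), fa)
  out <- read_sequences(fa)
  expect_equal(nrow(out), 2L)
  expect_equal(out$read_id, c("r1", "r2"))
  expect_equal(out$sequence, c("ACGT", "GGTT"))
})

test_that("read_sequences reads FASTQ (plain and gzipped), ignoring quality", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGTACGT", "+", "IIIIIIII",
               "@b", "TTTT", "+", "!!!!"), fq)
  out <- read_sequences(fq)
  expect_equal(out$sequence, c("ACGTACGT", "TTTT"))

  gz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "w")
  writeLines(c("@a", "ACGT", "+", "IIII"), con)
  close(con)
  expect_equal(read_sequences(gz)$sequence, "ACGT")
})

test_that("malformed FASTQ reports the failing record", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGT", "+", "IIII", "@b", "ACG"), fq)
  expect_error(read_sequences(fq), "record 2")
  expect_error(read_sequences(tempfile(fileext = ".fq")), "not found")
  expect_error(read_sequences(fq, format = "bam"), "arg")
})

test_that("the printed Apt2 template yields its variable region", {
  lib <- library_def()
  apt2_template <- paste0(
    "GGGGCCACCAACGACATTTTGACTGAATACGCACATTCGCCAAATTGCCGGCCC",
    "GTTGATATAAATAGTGCCCATGGATCCGCGGGTGTCGGG")
  res <- extract_variable_region(apt2_template, lib)
  expect_equal(res$status, "ok")
  expect_equal(res$variable_region, APT2)
  expect_equal(res$orientation, "forward")
})

test_that("reverse-complement reads extract the same region", {
  lib <- library_def()
  construct <- paste0(lib$const5, APT1, lib$const3)
  res <- extract_variable_region(oracle_revcomp(construct), lib)
  expect_equal(res$status, "ok")
  expect_equal(res$orientation, "reverse_complement")
  expect_equal(res$variable_region, APT1)
})

test_that("extraction round-trips random inserts in both orientations", {
  set.seed(11)
  lib <- library_def()
  v <- random_seqs(500, lib$var_len)
  fwd <- extract_variable_region(paste0(lib$const5, v, lib$const3), lib)
  expect_true(all(fwd$status == "ok"))
  expect_equal(fwd$variable_region, v)
  expect_true(all(fwd$orientation == "forward"))

  rc <- extract_variable_region(
    oracle_revcomp(paste0(lib$const5, v, lib$const3)), lib)
  expect_true(all(rc$status == "ok"))
  expect_equal(rc$variable_region, v)
  expect_true(all(rc$orientation == "reverse_complement"))
})

test_that("failure statuses are assigned as specified", {
  lib <- library_def()
  cases <- c(
    empty_insert = paste0(lib$const5, lib$const3),            # wrong_length
    short_insert = paste0(lib$const5, strrep("A", 35), lib$const3),
    no5 = paste0(strrep("G", 20), lib$const3),
    no3 = paste0(lib$const5, strrep("A", 36), strrep("C", 20)),
    ambiguous = paste0(lib$const5, paste0(strrep("A", 35), "N"), lib$const3),
    empty = ""
  )
  res <- extract_variable_region(unname(cases), lib)
  expect_equal(res$status,
               c("wrong_length", "wrong_length", "no_5prime_anchor",
                 "no_3prime_anchor", "ambiguous_base", "no_5prime_anchor"))
  expect_true(all(is.na(res$variable_region)))
})

test_that("leftmost 5' anchor and first following 3' anchor are used", {
  lib <- library_def(const5 = "AAACCC", const3 = "GGGTTT", var_len = 4)
  # const5 occurs twice; the leftmost occurrence anchors the extraction
  read <- paste0("AAACCC", "ACGT", "GGGTTT", "AAACCC", "TTTT", "GGGTTT")
  res <- extract_variable_region(read, lib)
  expect_equal(res$variable_region, "ACGT")
})

test_that("mismatch budget in the anchors is honoured", {
  lib0 <- library_def(max_mismatch = 0)
  lib1 <- library_def(max_mismatch = 1)
  v <- strrep("A", 36)
  const5_mut <- paste0("T", substr(lib0$const5, 2, nchar(lib0$const5)))
  read <- paste0(const5_mut, v, lib0$const3)
  expect_equal(extract_variable_region(read, lib0)$status, "no_5prime_anchor")
  res1 <- extract_variable_region(read, lib1)
  expect_equal(res1$status, "ok")
  expect_equal(res1$variable_region, v)
})

test_that("filter_correct_length tallies every read exactly once", {
  lib <- library_def()
  reads <- c(paste0(lib$const5, strrep("A", 36), lib$const3),
             paste0(lib$const5, strrep("C", 30), lib$const3),
             paste0(lib$const5, strrep("G", 36), lib$const3),
             paste0(lib$const5, strrep("T", 36)))
  flt <- filter_correct_length(extract_variable_region(reads, lib), lib)
  expect_equal(length(flt$regions), 2L)
  expect_equal(unname(flt$tallies["wrong_length"]), 1L)
  expect_equal(unname(flt$tallies["no_3prime_anchor"]), 1L)
  expect_equal(sum(flt$tallies), length(reads))

  empty <- filter_correct_length(
    extract_variable_region(character(0), lib), lib)
  expect_equal(length(empty$regions), 0L)
  expect_true(all(empty$tallies == 0L))
})

test_that("planted 1-nt deletions are rejected, intact reads pass", {
  set.seed(21)
  lib <- library_def()
  n <- 1000L
  v <- random_seqs(n, lib$var_len)
  deleted <- rep(FALSE, n)
  deleted[sample(n, 50L)] <- TRUE
  insert <- ifelse(deleted, substr(v, 1, lib$var_len - 1L), v)
  reads <- paste0(lib$const5, insert, lib$const3)
  flt <- filter_correct_length(extract_variable_region(reads, lib), lib)
  expect_equal(sort(flt$regions), sort(v[!deleted]))
  expect_equal(unname(flt$tallies["wrong_length"]), 50L)
})

test_that("synthetic FASTQ from the simulator reads back completely", {
  sim <- simulate_selex(
    selex_config(library_size = 30, cycles = 1, sampled_cycles = 1,
                 reads_per_sample = 100), seed = 3)
  dir <- tempfile()
  manifest <- write_selex_fastq(sim, dir)
  out <- read_sequences(manifest$path[1], "fastq")
  expect_equal(nrow(out), 100L)
  expect_true(all(nchar(out$sequence) >= library_def()$var_len))
})

test_that("accepted regions and the rejection report are written", {
  lib <- library_def()
  reads <- paste0(lib$const5, c(strrep("A", 36), strrep("C", 12)), lib$const3)
  flt <- filter_correct_length(extract_variable_region(reads, lib), lib)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_region_fasta(flt, fa, tsv, sample = "s1")
  expect_equal(read_sequences(fa)$sequence, strrep("A", 36))
  rep <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(sum(rep$count), 2L)
})
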