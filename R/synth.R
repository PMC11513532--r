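#' Configuration for the selection simulator
#'
#' Describes a simulated in vivo selection experiment: a random library of
#' fixed-length variable regions, planted sequences with tissue-specific
#' fitness, multiplicative per-cycle selection, re-injection pooling of the
#' six ocular recoveries, multinomial sequencing with substitution errors.
#'
#' Defaults mirror the study protocol: 14 cycles, sequencing at cycles 10,
#' 12 and 14 with RPE-choroid last sequenced at cycle 12, equal ocular
#' pooling weights (equimolar aliquots from the six ocular tissues), and a
#' substitution error rate of 0.1% per base.
#'
#' @param library_size Number of random background variable regions.
#' @param planted Optional data.frame with column `sequence` plus one column
#'   per tissue giving that sequence's fitness there (missing tissues get
#'   `background_fitness`). Alternatively a list of
#'   `list(sequence =, fitness = c(tissue = w, ...))`.
#' @param background_fitness Fitness of background sequences in every
#'   tissue, default 1.
#' @param cycles Number of selection cycles, default 14.
#' @param sampled_cycles Cycles at which samples are sequenced, default
#'   `c(10, 12, 14)`; each tissue is only sequenced up to its
#'   `last_cycle_map` entry.
#' @param reads_per_sample Sequencing depth per (tissue, cycle) sample.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`,
#'   default 0.001.
#' @param ocular_pool_weights Mixing weights of the six ocular recoveries in
#'   the next injection, default equal; must sum to 1.
#' @param lib A [library_def()] providing the constant regions and variable
#'   length.
#' @param last_cycle_map Per-tissue last sequenced cycle, default
#'   [default_last_cycle_map()].
#' @return Object of class `selex_sim_config`.
#' @export
selex_config <- function(library_size = 500L,
                         planted = NULL,
                         background_fitness = 1.0,
                         cycles = 14L,
                         sampled_cycles = c(10L, 12L, 14L),
                         reads_per_sample = 10000L,
                         error_rate = 0.001,
                         ocular_pool_weights = NULL,
                         lib = library_def(),
                         last_cycle_map = default_last_cycle_map()) {
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]")
  }
  if (background_fitness < 0) stop("fitness must be >= 0")
  if (is.null(ocular_pool_weights)) {
    ocular_pool_weights <- setNames(rep(1 / 6, 6), OCULAR_TISSUES)
  }
  if (abs(sum(ocular_pool_weights) - 1) > 1e-9) {
    stop("ocular_pool_weights must sum to 1")
  }
  planted <- normalize_planted(planted, lib)
  structure(list(library_size = as.integer(library_size), planted = planted,
                 background_fitness = background_fitness,
                 cycles = as.integer(cycles),
                 sampled_cycles = as.integer(sampled_cycles),
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 ocular_pool_weights = ocular_pool_weights,
                 lib = lib, last_cycle_map = last_cycle_map),
            class = "selex_sim_config")
}

# Planted spec -> data.frame(sequence, <one fitness column per tissue>).
normalize_planted <- function(planted, lib) {
  tissues <- selex_tissues()
  if (is.null(planted)) {
    return(data.frame(sequence = character(0),
                      matrix(numeric(0), ncol = length(tissues),
                             dimnames = list(NULL, tissues)),
                      check.names = FALSE))
  }
  if (!is.data.frame(planted)) {
    rows <- lapply(planted, function(p) {
      w <- setNames(rep(NA_real_, length(tissues)), tissues)
      if (!is.null(p$fitness)) {
        tissue_compartment(names(p$fitness))
        w[names(p$fitness)] <- p$fitness
      }
      c(list(sequence = p$sequence), as.list(w))
    })
    planted <- do.call(rbind, lapply(rows, as.data.frame))
  }
  for (t in tissues) {
    if (!t %in% names(planted)) planted[[t]] <- NA_real_
  }
  planted$sequence <- normalize_dna(planted$sequence)
  if (any(nchar(planted$sequence) != lib$var_len)) {
    stop("planted sequences must have length var_len = ", lib$var_len)
  }
  if (any(planted[, tissues] < 0, na.rm = TRUE)) stop("fitness must be >= 0")
  planted[, c("sequence", tissues)]
}

# Random unique variable regions.
random_regions <- function(n, len) {
  regions <- character(0)
  while (length(regions) < n) {
    more <- vapply(seq_len(n - length(regions)), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
    regions <- unique(c(regions, more))
  }
  regions
}

#' Simulate an in vivo selection experiment
#'
#' Runs the per-cycle selection model: within each tissue the recovery
#' frequency of sequence i is proportional to its injected frequency times
#' its tissue fitness; the injected pool of the next cycle is the
#' ocular-weight mixture of the six ocular recovery distributions (control
#' recoveries never re-enter). Frequency trajectories are propagated
#' exactly; sampling noise enters only when reads are drawn (multinomially
#' at the configured depth, then per-base substitution errors). Reads are
#' emitted as full constructs `const5 + variable + const3`.
#'
#' @param config A [selex_config()].
#' @param seed Integer seed; identical config + seed give identical output.
#' @return A list with
#'   * `samples`: list of `list(tissue, cycle, reads, true_region)` — `reads`
#'     are the error-bearing constructs, `true_region` the error-free source
#'     variable region of each read;
#'   * `truth`: list with `sequences`, `fitness` (sequence x tissue matrix),
#'     `injected` (cycle x sequence frequency matrix, row c = pool injected
#'     into cycle c), and `recovery` (per-cycle list of tissue x sequence
#'     recovery frequency matrices);
#'   * `config`.
#' @examples
#' sim <- simulate_selex(selex_config(library_size = 20,
#'   cycles = 2, sampled_cycles = 2, reads_per_sample = 50), seed = 1)
#' length(sim$samples)
#' @export
simulate_selex <- function(config, seed = 1L) {
  stopifnot(inherits(config, "selex_sim_config"))
  set.seed(as.integer(seed))
  tissues <- selex_tissues()
  lib <- config$lib

  background <- random_regions(config$library_size, lib$var_len)
  background <- setdiff(background, config$planted$sequence)
  sequences <- c(config$planted$sequence, background)
  n <- length(sequences)

  fitness <- matrix(config$background_fitness, nrow = n,
                    ncol = length(tissues),
                    dimnames = list(sequences, tissues))
  if (nrow(config$planted) > 0) {
    for (t in tissues) {
      w <- config$planted[[t]]
      fitness[seq_len(nrow(config$planted)), t] <-
        ifelse(is.na(w), config$background_fitness, w)
    }
  }
  if (any(colSums(fitness) == 0)) {
    stop("all-zero fitness in tissue(s): ",
         paste(tissues[colSums(fitness) == 0], collapse = ", "))
  }

  injected <- matrix(NA_real_, nrow = config$cycles, ncol = n,
                     dimnames = list(NULL, sequences))
  p_inj <- rep(1 / n, n)  # uniform initial library
  recovery <- vector("list", config$cycles)
  samples <- list()

  for (cyc in seq_len(config$cycles)) {
    injected[cyc, ] <- p_inj
    rec <- vapply(tissues, function(t) {
      q <- p_inj * fitness[, t]
      q / sum(q)
    }, numeric(n))                      # n x tissues
    recovery[[cyc]] <- t(rec)           # tissues x n
    rownames(recovery[[cyc]]) <- tissues

    if (cyc %in% config$sampled_cycles) {
      for (t in tissues) {
        if (cyc > config$last_cycle_map[[t]]) next
        counts <- as.integer(rmultinom(1, config$reads_per_sample,
                                       recovery[[cyc]][t, ]))
        idx <- rep(seq_len(n), counts)
        idx <- sample(idx)              # shuffle read order
        true_region <- sequences[idx]
        reads <- paste0(lib$const5, true_region, lib$const3)
        if (config$error_rate > 0) {
          reads <- add_substitution_errors(reads, config$error_rate)
        }
        samples[[length(samples) + 1L]] <-
          list(tissue = t, cycle = cyc, reads = reads,
               true_region = true_region)
      }
    }

    # Re-injection: ocular-weight mixture of the six ocular recoveries.
    p_inj <- as.numeric(config$ocular_pool_weights %*%
                          recovery[[cyc]][OCULAR_TISSUES, , drop = FALSE])
    p_inj <- p_inj / sum(p_inj)
  }

  list(samples = samples,
       truth = list(sequences = sequences, fitness = fitness,
                    injected = injected, recovery = recovery),
       config = config)
}

# Per-base substitution noise, vectorised over reads.
add_substitution_errors <- function(reads, rate) {
  chars <- strsplit(reads, "")
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    flat[hit] <- vapply(flat[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1),
         collapse = "")
}

#' Expected one-step recovery frequencies
#'
#' Closed-form per-tissue recovery distribution for a given injected pool:
#' `p_rec(i) = p_inj(i) * w(i, tissue) / sum_j p_inj(j) * w(j, tissue)` —
#' the simulator's selection update in expectation (infinite depth, no
#' error).
#'
#' @param p_inj Injected frequency vector (sums to 1).
#' @param fitness Fitness vector of the same length.
#' @return Recovery frequency vector.
#' @examples
#' selex_expected_recovery(c(0.01, 0.99), c(2, 1))
#' @export
selex_expected_recovery <- function(p_inj, fitness) {
  stopifnot(length(p_inj) == length(fitness), all(fitness >= 0))
  if (abs(sum(p_inj) - 1) > 1e-9) stop("p_inj must sum to 1")
  q <- p_inj * fitness
  if (sum(q) == 0) stop("all-zero fitness")
  q / sum(q)
}

#' Write simulated samples as FASTQ files
#'
#' One gzipped FASTQ per (tissue, cycle) sample with constant Q30 qualities
#' (qualities are ignored downstream).
#'
#' @param sim A [simulate_selex()] result.
#' @param dir Output directory (created if needed).
#' @return Data.frame manifest: `path`, `tissue`, `cycle`, `n_reads`.
#' @export
write_selex_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim$samples, function(s) {
    path <- file.path(dir, sprintf("%s_cycle%02d.fastq.gz", s$tissue,
                                   s$cycle))
    set <- Biostrings::DNAStringSet(s$reads)
    names(set) <- sprintf("%s_c%02d_%06d", s$tissue, s$cycle,
                          seq_along(s$reads))
    qual <- Biostrings::BStringSet(strrep("?", nchar(s$reads)))  # Q30
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                compress = TRUE, qualities = qual)
    data.frame(path = path, tissue = s$tissue, cycle = s$cycle,
               n_reads = length(s$reads), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a qPCR Ct table from true abundances
#'
#' Generates replicate Ct values consistent with template abundances under
#' an exponential amplification model:
#' `Ct = ct_ref - log_efficiency(abundance / ref_abundance) + noise`. With
#' efficiency 2 this encodes the doubling law: a 16-fold abundance ratio
#' shifts Ct by exactly 4 cycles. Serves as the self-consistency arbiter for
#' the delta-Ct analysis.
#'
#' @param true_abundance Data.frame with columns `aptamer`, `tissue`,
#'   `abundance` (> 0).
#' @param ct_ref Ct of a template at `ref_abundance`, default 25.
#' @param efficiency Per-cycle amplification factor (> 1), default 2.
#' @param noise_sd Gaussian Ct noise SD, default 0.
#' @param n_replicates Replicates per (aptamer, tissue), default 3.
#' @param seed Integer seed.
#' @param ref_abundance Reference abundance mapping to `ct_ref`, default 1.
#' @return A [qpcr_table()].
#' @examples
#' simulate_qpcr(data.frame(aptamer = "A", tissue = "retina",
#'   abundance = 16), ct_ref = 25, noise_sd = 0, n_replicates = 3)
#' @export
simulate_qpcr <- function(true_abundance, ct_ref = 25, efficiency = 2,
                          noise_sd = 0, n_replicates = 3L, seed = 1L,
                          ref_abundance = 1) {
  stopifnot(all(c("aptamer", "tissue", "abundance") %in%
                  names(true_abundance)))
  if (any(true_abundance$abundance <= 0)) stop("abundances must be positive")
  if (efficiency <= 1) stop("efficiency must exceed 1")
  set.seed(as.integer(seed))
  n <- nrow(true_abundance)
  rows <- true_abundance[rep(seq_len(n), each = n_replicates), , drop = FALSE]
  rows$replicate <- rep(seq_len(n_replicates), times = n)
  rows$ct <- ct_ref -
    log(rows$abundance / ref_abundance, base = efficiency) +
    rnorm(nrow(rows), sd = noise_sd)
  qpcr_table(rows[, c("aptamer", "tissue", "replicate", "ct")])
}

#' Simulate a melt curve
#'
#' Evaluates the Boltzmann sigmoid on a temperature grid (default the
#' 22-94 degrees C, 2-degree protocol grid) and adds seeded Gaussian noise.
#'
#' @param theta_min,theta_max,tm,s Boltzmann parameters (see
#'   [boltzmann_model()]).
#' @param t_min,t_max,t_step Temperature grid, default `seq(22, 94, 2)`.
#' @param noise_sd Gaussian noise SD on the ellipticity values, default 0.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A [melt_curve()].
#' @examples
#' simulate_melt(tm = 58.92)
#' @export
simulate_melt <- function(theta_min = 0, theta_max = 1, tm = 60, s = 2,
                          t_min = 22, t_max = 94, t_step = 2,
                          noise_sd = 0, seed = 1L) {
  temp <- seq(t_min, t_max, by = t_step)
  y <- boltzmann_model(temp, theta_min, theta_max, tm, s)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  melt_curve(temp, y)
}
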