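test_that("config validation enforces the simulator invariants", {
  expect_error(selex_config(error_rate = 0.5), "error_rate")
  expect_error(selex_config(background_fitness = -1), "fitness")
  expect_error(selex_config(ocular_pool_weights = rep(0.5, 6)), "sum to 1")
  expect_error(selex_config(planted = data.frame(sequence = "ACGT",
                                                 retina = 2)),
               "var_len")
  expect_error(selex_config(planted = data.frame(sequence = strrep("A", 36),
                                                 retina = -2)),
               "fitness")
})

test_that("one selection step matches the closed-form expectation", {
  # one planted sequence, fitness 2 in one tissue, initial frequency 0.01
  rec <- selex_expected_recovery(c(0.01, 0.99), c(2, 1))
  expect_equal(rec[1], 0.02 / (0.02 + 0.99))
  expect_equal(sum(rec), 1)
  expect_error(selex_expected_recovery(c(0.5, 0.6), c(1, 1)), "sum to 1")
  expect_error(selex_expected_recovery(c(0.5, 0.5), c(0, 0)), "all-zero")

  # the simulator's internal update agrees with the closed form
  planted <- data.frame(sequence = strrep("A", 36), retina = 2)
  cfg <- selex_config(library_size = 99, planted = planted, cycles = 2,
                      sampled_cycles = integer(0), reads_per_sample = 10)
  sim <- simulate_selex(cfg, seed = 5)
  n <- length(sim$truth$sequences)
  p0 <- rep(1 / n, n)
  expect_equal(unname(sim$truth$recovery[[1]]["retina", 1]),
               unname(selex_expected_recovery(
                 p0, sim$truth$fitness[, "retina"])[1]))
})

test_that("frequency vectors always sum to 1", {
  planted <- data.frame(sequence = strrep("A", 36), retina = 3, cornea = 2)
  sim <- simulate_selex(selex_config(library_size = 40, planted = planted,
                                     cycles = 5, sampled_cycles = integer(0),
                                     reads_per_sample = 10), seed = 6)
  expect_equal(unname(rowSums(sim$truth$injected)), rep(1, 5))
  for (rec in sim$truth$recovery) {
    expect_equal(unname(rowSums(rec)), rep(1, nrow(rec)))
  }
})

test_that("neutral selection leaves sampled frequencies at their initial value", {
  cfg <- selex_config(library_size = 20, cycles = 4, sampled_cycles = 4,
                      reads_per_sample = 5000, error_rate = 0)
  sim <- simulate_selex(cfg, seed = 7)
  n <- length(sim$truth$sequences)
  p0 <- 1 / n
  se <- sqrt(p0 * (1 - p0) / cfg$reads_per_sample)
  for (s in sim$samples) {
    freq <- table(factor(s$true_region, levels = sim$truth$sequences)) /
      length(s$true_region)
    expect_true(all(abs(freq - p0) <= 4 * se))
  }
})

test_that("simulation output is reproducible from the seed", {
  cfg <- selex_config(library_size = 25, cycles = 2, sampled_cycles = 2,
                      reads_per_sample = 100, error_rate = 0.01)
  a <- simulate_selex(cfg, seed = 11)
  b <- simulate_selex(cfg, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_selex(cfg, seed = 12)
  expect_false(identical(a$samples, c_$samples))

  # written FASTQ is byte-identical across reruns
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_selex_fastq(a, d1); m2 <- write_selex_fastq(b, d2)
  expect_identical(unname(tools::md5sum(m1$path)),
                   unname(tools::md5sum(m2$path)))
})

test_that("sampled tissues respect the per-tissue last sequenced cycle", {
  cfg <- selex_config(library_size = 15, cycles = 14,
                      sampled_cycles = c(10, 12, 14), reads_per_sample = 20)
  sim <- simulate_selex(cfg, seed = 8)
  keys <- vapply(sim$samples, function(s) paste(s$tissue, s$cycle),
                 character(1))
  expect_true("rpe_choroid 12" %in% keys)
  expect_false("rpe_choroid 14" %in% keys)
  expect_true("retina 14" %in% keys)
  # 10 tissues at cycles 10 and 12, 9 at cycle 14
  expect_length(keys, 29L)
})

test_that("an ocular-selective sequence ranks first by ocular enrichment", {
  target <- strrep("AC", 18)
  planted <- data.frame(sequence = target, conjunctiva = 2, cornea = 2,
                        iris_cb = 2, lens = 2, retina = 2, rpe_choroid = 2)
  hits <- vapply(1:50, function(seed) {
    cfg <- selex_config(library_size = 60, planted = planted, cycles = 10,
                        sampled_cycles = 10, reads_per_sample = 2000,
                        error_rate = 0)
    sim <- simulate_selex(cfg, seed = seed)
    freq_of <- function(compartment) {
      tis <- if (compartment == "ocular") {
        c("conjunctiva", "cornea", "iris_cb", "lens", "retina", "rpe_choroid")
      } else c("liver", "lung", "kidney", "spleen")
      samples <- Filter(function(s) s$tissue %in% tis, sim$samples)
      regions <- unlist(lapply(samples, `[[`, "true_region"))
      tab <- table(factor(regions, levels = sim$truth$sequences))
      tab / sum(tab)
    }
    # enrichment as the excess pool fraction in ocular over control tissue
    # (a raw frequency ratio is dominated by sampling noise on rare
    # background sequences)
    excess <- freq_of("ocular") - freq_of("control")
    names(which.max(excess)) == target
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulated qPCR encodes abundance ratios exactly without noise", {
  tab <- simulate_qpcr(data.frame(aptamer = c("A", "B"), tissue = "retina",
                                  abundance = c(1, 1)), noise_sd = 0)
  expect_equal(unique(tab$ct), 25)

  tab16 <- simulate_qpcr(data.frame(aptamer = c("A", "B"), tissue = "retina",
                                    abundance = c(16, 1)), noise_sd = 0)
  s <- ct_summary(tab16)
  expect_equal(s$mean_ct[s$aptamer == "B"] - s$mean_ct[s$aptamer == "A"], 4)
  expect_error(simulate_qpcr(data.frame(aptamer = "A", tissue = "retina",
                                        abundance = 0)), "positive")
  expect_error(simulate_qpcr(data.frame(aptamer = "A", tissue = "retina",
                                        abundance = 1), efficiency = 1),
               "exceed 1")
})

test_that("delta-Ct recovers -log2 abundance ratios through simulated qPCR", {
  ratio <- 8; noise_sd <- 0.2; n <- 6
  errs <- vapply(1:100, function(seed) {
    tab <- simulate_qpcr(
      data.frame(aptamer = c("Apt", "Ctrl"), tissue = "retina",
                 abundance = c(ratio, 1)),
      noise_sd = noise_sd, n_replicates = n, seed = seed)
    delta_ct(tab, "Apt", "Ctrl", "retina") - (-log2(ratio))
  }, numeric(1))
  # mean Ct difference has SD noise_sd * sqrt(2/n)
  expect_true(mean(abs(errs) <= 3 * noise_sd / sqrt(n)) >= 0.9)
  expect_equal(mean(errs), 0, tolerance = 0.05)

  exact <- simulate_qpcr(data.frame(aptamer = c("Apt", "Ctrl"),
                                    tissue = "retina", abundance = c(8, 1)),
                         noise_sd = 0)
  expect_equal(delta_ct(exact, "Apt", "Ctrl", "retina"), -3)
})

test_that("simulated melt curves follow the model and scale their noise", {
  clean <- simulate_melt(0, 1, tm = 60, s = 2)
  expect_equal(clean$temperature, seq(22, 94, 2))
  expect_equal(clean$ellipticity,
               boltzmann_model(clean$temperature, 0, 1, 60, 2))

  res_sd <- function(noise) {
    devs <- unlist(lapply(1:30, function(seed) {
      cv <- simulate_melt(0, 1, 60, 2, noise_sd = noise, seed = seed)
      cv$ellipticity - clean$ellipticity
    }))
    sd(devs)
  }
  expect_equal(res_sd(0.04) / res_sd(0.02), 2, tolerance = 0.1)
})
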