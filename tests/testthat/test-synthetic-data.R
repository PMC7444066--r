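# The synthetic small RNA-seq generator: determinism, truth coverage,
# length/class structure, planted differential expression.

test_that("a fixed seed gives byte-identical FASTQ and truth outputs", {
  refs <- toy_ref_set()
  prof <- simulation_profile(n_reads_per_sample = 150, replicates = 1,
                             days = c(0, 7), seed = 9)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_reads(refs, prof, out_dir = d1)
  s2 <- simulate_reads(refs, prof, out_dir = d2)
  for (sid in names(s1$paths$fastq)) {
    expect_identical(readBin(s1$paths$fastq[[sid]], "raw", 1e6),
                     readBin(s2$paths$fastq[[sid]], "raw", 1e6))
  }
  expect_identical(readLines(s1$paths$truth), readLines(s2$paths$truth))
  # FASTQ on disk parses back to the in-memory reads
  expect_identical(read_fastq(s1$paths$fastq[[1]]), s1$reads[[1]])
})

test_that("the truth table covers every read and all six classes", {
  run <- pipeline_fixture()
  sim <- run$sim
  all_ids <- unlist(lapply(sim$reads, `[[`, "read_id"), use.names = FALSE)
  expect_setequal(sim$truth$read_id, all_ids)
  ts_classes <- setdiff(unique(sim$truth$class), c("miRNA", "rRNA"))
  expect_setequal(ts_classes,
                  c("tRF-5", "tRF-3", "i-tRF", "tRF-1", "5p-half", "3p-half"))
})

test_that("every tRNA-derived read is re-locatable at its stated interval", {
  run <- pipeline_fixture()
  sim <- run$sim
  refs <- run$refs
  tr <- sim$truth[!(sim$truth$class %in% c("miRNA", "rRNA")), ]
  reads <- do.call(rbind, unname(sim$reads))
  seqs <- reads$seq[match(tr$read_id, reads$read_id)]
  bodies <- substr(seqs, 1, tr$end - tr$start)
  placed <- substr(vapply(refs[tr$parent_id], `[[`, character(1),
                          "extended_seq"),
                   tr$start + 1, tr$end)
  expect_identical(bodies, unname(placed))
})

test_that("read bodies are adapter-suffixed and length modes dominate", {
  refs <- toy_ref_set()
  prof <- simulation_profile(n_reads_per_sample = 10000, replicates = 1,
                             days = 0,
                             contaminant_fractions = c(miRNA = 0, rRNA = 0),
                             seed = 21)
  sim <- simulate_reads(refs, prof)
  rd <- sim$reads[[1]]
  expect_true(all(endsWith(rd$seq, prof$adapter)))
  expect_true(all(nchar(rd$seq) > sim$truth$end - sim$truth$start))
  bodies <- trim_adapter(rd$seq, prof$adapter)
  inmode <- nchar(bodies) %in% c(17:23, 30:36)
  expect_gte(mean(inmode), 0.8)
  # empirical class fractions within 3 binomial SE of the requested mixture
  mix <- prof$class_mixture
  n <- nrow(rd)
  emp <- table(sim$truth$class)[names(mix)] / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(emp - mix) <= 3 * se))
})

test_that("unrealizable classes in the mixture are rejected by name", {
  # anticodon loop pushed so far 3' that no tRF-3 fits between it and the CCA
  g <- make_trna_gene(1, "Thr", "TGT",
                      landmarks = list(anticodon_loop = c(60L, 68L),
                                       anticodon = c(62L, 65L),
                                       t_loop = c(70L, 75L)))
  ref <- build_mature_reference(g)
  prof <- simulation_profile(class_mixture = c("tRF-3" = 0.5, "tRF-5" = 0.5),
                             seed = 1)
  expect_error(simulate_reads(list(ref), prof), "tRF-3")
})

test_that("planted fragments are absent at day 0 and peak at day 7", {
  refs <- toy_ref_set()
  planted <- plant_absent_then_peak(refs, n = 2, base_fraction = 0.02, seed = 3)
  # background mixture excludes 3' halves so every 3p-half read is planted
  prof <- simulation_profile(n_reads_per_sample = 1000, replicates = 1,
                             class_mixture = c("tRF-5" = 0.5, "i-tRF" = 0.5),
                             planted_de = planted, seed = 13)
  sim <- simulate_reads(refs, prof)
  key <- function(df) paste(df$parent_id, df$start, df$end)
  pkey <- vapply(planted, function(p) paste(p$parent, p$start, p$end), character(1))
  d0 <- sum(key(sim$truth[sim$truth$sample_id == "day0_rep1", ]) %in% pkey)
  d7 <- sum(key(sim$truth[sim$truth$sample_id == "day7_rep1", ]) %in% pkey)
  expect_gte(d7, 2 * 0.02 * 1000 * 0.5)  # near n * base_fraction per fragment
  expect_equal(d0, 0L)
})

test_that("count experiments plant exactly the requested effects", {
  x <- simulate_count_experiment(300, 6, 4, 100, 3, seed = 7)
  expect_equal(dim(x$counts), c(300L, 6L))
  expect_equal(sum(x$truth$is_de), 6L)
  expect_setequal(unique(x$truth$true_fc), c(1, 4))
  # determinism
  y <- simulate_count_experiment(300, 6, 4, 100, 3, seed = 7)
  expect_identical(x$counts, y$counts)
  # effect = 1 plants nothing
  z <- simulate_count_experiment(50, 5, 1, 100, 3, seed = 1)
  expect_false(any(z$truth$is_de))
  # absent-then-peak: day-0 mean zero for planted rows
  a <- simulate_count_experiment(50, 5, 4, 100, 3, seed = 2,
                                 mode = "absent-then-peak")
  de <- a$truth$plate_id[a$truth$is_de]
  expect_true(all(a$counts[de, grepl("^day0", colnames(a$counts))] == 0))
  expect_gt(mean(a$counts[de, grepl("^day7", colnames(a$counts))]), 100)
  # argument validation
  expect_error(simulate_count_experiment(10, 2, 4, 100, 2.5, seed = 1),
               "replicates")
  expect_error(simulate_count_experiment(10, 2, 4, -5, 3, seed = 1),
               "base_mean")
  expect_error(simulate_count_experiment(10, 20, 4, 100, 3, seed = 1),
               "n_de")
})

test_that("simulation profiles round-trip through YAML configs", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_reads_per_sample: 500",
    "replicates: 2",
    "days: [0, 7]",
    "seed: 4",
    "class_mixture:",
    "  tRF-5: 0.5",
    "  i-tRF: 0.5",
    "contaminant_fractions:",
    "  miRNA: 0.1",
    "  rRNA: 0.05",
    "length_modes:",
    "  - [17, 23]",
    "  - [30, 36]"), cfg)
  prof <- read_simulation_profile(cfg)
  expect_s3_class(prof, "simulation_profile")
  expect_equal(prof$n_reads_per_sample, 500L)
  expect_equal(prof$class_mixture, c("tRF-5" = 0.5, "i-tRF" = 0.5))
  expect_equal(prof$length_modes[[2]], c(30L, 36L))
  ref <- toy_ref()
  sim <- simulate_reads(list(ref), prof)
  expect_length(sim$reads, 4L)  # 2 days x 2 replicates
  writeLines("bogus_field: 1", cfg)
  expect_error(read_simulation_profile(cfg), "bogus_field")
})
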