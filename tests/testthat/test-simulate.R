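test_that("lesion profiles validate placement and base identity", {
  ref <- reference_set(c(r = "AACGGGUUACG"))
  les <- lesion_profile(ref, "r", 4L, "abasic")
  expect_equal(les$class, "abasic")
  expect_error(lesion_profile(ref, "nope", 1L, "abasic"), "unknown reference")
  expect_error(lesion_profile(ref, "r", 99L, "abasic"), "outside")
  expect_error(lesion_profile(ref, "r", 1L, "abasic"), "expected G")
  expect_error(lesion_profile(ref, "r", 4L, "oxo8A"), "expected A")
  expect_s3_class(lesion_profile(ref, "r", 1L, "abasic", allow_any_base = TRUE),
                  "oab_lesions")
})

test_that("identical seed and parameters reproduce the library byte for byte", {
  sc <- recovery_scenario(seed = 301L, L = 300L, n_lesions = 4L)
  pp <- protocol_params("alkaline", n_reads = 2000, seed = 77L)
  s1 <- simulate_library(sc$ref, sc$lesions, pp)
  s2 <- simulate_library(sc$ref, sc$lesions, pp)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_library(sc$ref, sc$lesions,
                         protocol_params("alkaline", n_reads = 2000, seed = 78L))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("every emitted read has exactly one truth row and causes conserve depth", {
  sc <- recovery_scenario(seed = 302L, L = 300L, n_lesions = 4L)
  pp <- protocol_params("mg", n_reads = 5000, seed = 5L)
  sim <- simulate_library(sc$ref, sc$lesions, pp)
  expect_equal(nrow(sim$truth), 5000L)
  expect_equal(sim$truth$read_id, sim$reads$read_id)
  expect_equal(sum(table(sim$truth$cause)), 5000L)
  expect_setequal(unique(sim$truth$cause), c("lesion", "leak"))
})

test_that("aniline without fragmentation cleaves only the abasic site", {
  ref <- reference_set(c(r = paste(withr::with_seed(
    303, sample(c("A", "C", "G", "U"), 120, TRUE)), collapse = "")))
  g <- which(strsplit(ref$seq, "")[[1]] == "G")
  p <- g[g > 10 & g < 60][1]
  les <- lesion_profile(ref, "r", p, "abasic")
  pp <- protocol_params("none", n_reads = 1000, epsilon = 0, seed = 9L)
  sim <- simulate_library(ref, les, pp)
  # every read starts one nt 3' of the lesion
  expect_true(all(sim$reads$start == p + 1L))
  # after counting with backshift -1 all signal sits on the lesion itself
  sam <- tempfile(fileext = ".sam")
  emit_alignments(sim, ref, sam)
  cnt <- count_five_prime_ends(sam, ref, backshift = -1L)
  expect_equal(cnt$n_start[cnt$pos == p], 1000L)
  expect_equal(sum(cnt$n_start), 1000L)
})

test_that("an unmodified reference is inert without leak and uniform with it", {
  ref <- random_ref(304, 200)
  pp0 <- protocol_params("none", n_reads = 100, epsilon = 0, seed = 2L)
  expect_error(simulate_library(ref, NULL, pp0), "no ligatable")
  ppl <- protocol_params("alkaline", n_reads = 5000, epsilon = 0.05, seed = 2L)
  sim <- simulate_library(ref, NULL, ppl)
  # leak-only library: starts spread over the reference, no position dominates
  expect_true(all(sim$truth$cause == "leak"))
  expect_gt(dplyr::n_distinct(sim$reads$start), 150L)
  expect_lt(max(tabulate(sim$reads$start, 200)), 0.05 * 5000)
})

test_that("lesion read share matches the analytic expectation within 3 sigma", {
  sc <- recovery_scenario(seed = 305L, L = 400L, n_lesions = 1L)
  p_cleave <- 0.9
  lambda <- 0.01; eps <- 0.01
  pp <- protocol_params("none", n_reads = 20000, lambda = lambda,
                        epsilon = eps, seed = 11L)
  sim <- simulate_library(sc$ref, sc$lesions, pp)
  share_true <- p_cleave / (p_cleave + lambda * eps * 400)
  n_lesion <- sum(sim$truth$cause == "lesion")
  sigma <- sqrt(20000 * share_true * (1 - share_true))
  expect_lt(abs(n_lesion - 20000 * share_true), 3 * sigma)
  # the model's own expectation table agrees (lesion weight plus the leak
  # weight of the shared start position)
  exp_at <- sim$expected$expected_n[sim$expected$pos == sc$lesion_pos + 1L]
  expect_equal(exp_at,
               20000 * (p_cleave + lambda * eps) / (p_cleave + lambda * eps * 400),
               tolerance = 1e-10)
})

test_that("emitted SAM round-trips through counting to the exact truth tally", {
  sc <- recovery_scenario(seed = 306L, L = 300L, n_lesions = 3L)
  pp <- protocol_params("alkaline", n_reads = 3000, seed = 13L)
  sim <- simulate_library(sc$ref, sc$lesions, pp)
  sam <- tempfile(fileext = ".sam")
  fq <- tempfile(fileext = ".fastq")
  emit_alignments(sim, sc$ref, sam, fastq_path = fq)
  # SAM POS equals the truth coordinate, full-match CIGAR
  rec <- read.table(sam, sep = "\t", skip = 2, comment.char = "",
                    stringsAsFactors = FALSE)
  expect_equal(rec$V4, sim$truth$start)
  expect_true(all(grepl("^\\d+M$", rec$V6)))
  expect_true(all(rec$V2 == 0L), info = "forward strand, primary")
  # FASTQ and SAM record counts agree
  expect_equal(length(readLines(fq)) / 4L, nrow(rec))
  # counting with backshift 0, no length filter reproduces the raw tally
  cnt <- count_five_prime_ends(sam, sc$ref, backshift = 0L, min_read_len = 1L)
  tally <- tabulate(sim$truth$start, nbins = sc$ref$length[1])
  expect_equal(cnt$n_start, tally)
  expect_equal(unname(n_total(cnt)[sc$ref$ref[1]]), 3000L)
})

test_that("the optional substitution model corrupts bases, not coordinates", {
  sc <- recovery_scenario(seed = 309L, L = 300L, n_lesions = 2L)
  p0 <- protocol_params("alkaline", n_reads = 2000, seed = 8L)
  p1 <- protocol_params("alkaline", n_reads = 2000, error_rate = 0.1, seed = 8L)
  s0 <- simulate_library(sc$ref, sc$lesions, p0)
  s1 <- simulate_library(sc$ref, sc$lesions, p1)
  expect_identical(s0$truth, s1$truth)  # same reads drawn, same coordinates
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, s0$reads$seq, s1$reads$seq)
  rate <- sum(mism) / sum(s0$reads$length)
  expect_gt(rate, 0.07)
  expect_lt(rate, 0.13)
  expect_identical(simulate_library(sc$ref, sc$lesions, p1)$reads, s1$reads)
})

test_that("background signal scales with the leak rate", {
  sc <- recovery_scenario(seed = 307L, L = 300L, n_lesions = 2L)
  sims <- lapply(c(0.01, 0.04), function(eps) {
    pp <- protocol_params("alkaline", n_reads = 20000, epsilon = eps, seed = 3L)
    simulate_library(sc$ref, sc$lesions, pp)
  })
  leak_frac <- vapply(sims, function(s) mean(s$truth$cause == "leak"), numeric(1))
  # quadrupling epsilon about quadruples the leak odds
  odds <- leak_frac / (1 - leak_frac)
  expect_equal(odds[2] / odds[1], 4, tolerance = 0.2)
})

test_that("YAML scenarios reconstruct reference, lesions and protocol", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "reference:",
    "  rna1: ACGGAUCGGA",
    "lesions:",
    "  - {ref: rna1, pos: 4, class: abasic}",
    "protocol: {name: mg, n_reads: 500, epsilon: 0.02, seed: 3}"), yml)
  sc <- load_scenario(yml)
  expect_equal(sc$ref$seq, "ACGGAUCGGA")
  expect_equal(sc$lesions$pos, 4L)
  expect_equal(sc$params$protocol, "mg")
  expect_equal(sc$params$epsilon, 0.02)
  sim <- simulate_library(sc$ref, sc$lesions, sc$params)
  expect_equal(nrow(sim$reads), 500L)
  writeLines("lesions: []", yml)
  expect_error(load_scenario(yml), "reference")
})

test_that("protocol contrast recovers the configured efficiency ratio", {
  sc <- recovery_scenario(seed = 308L, L = 300L, n_lesions = 1L)
  # same lesion, fourfold cleavage difference between protocols
  probs <- default_cleavage_probs()
  pa <- protocol_params("alkaline", n_reads = 30000, seed = 21L)
  pb <- protocol_params("mg", n_reads = 30000, seed = 22L)
  oxo <- lesion_profile(sc$ref, sc$lesions$ref, sc$lesions$pos, "oxo8G")
  res <- protocol_contrast_experiment(sc$ref, oxo, pa, pb,
                                      n_rep = 2L, n_boot = 10)
  expect_gt(res$ratio, 2.5)
  expect_lt(res$ratio, 6)
  expect_true(res$ci_lo < res$ci_hi)
  # equal-probability abasic lesion: ratio near 1
  ab <- lesion_profile(sc$ref, sc$lesions$ref, sc$lesions$pos, "abasic")
  res_ab <- protocol_contrast_experiment(sc$ref, ab, pa, pb,
                                         n_rep = 2L, n_boot = 10)
  expect_gt(res_ab$ratio, 0.5)
  expect_lt(res_ab$ratio, 2)
})
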