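# Correction scores, complementary scores/ratios, and the
# combination-accuracy model.

pair_panel <- function() {
  # 6 samples, reference always A*01:01+A*02:01.
  # OptiType wrong on S1..S4; HLA-HD corrects 3 of those 4 and is
  # unavailable on S4; PHLAT is identical to OptiType everywhere.
  mk <- function(tool, a1) data.frame(
    sample_id = sprintf("S%d", 1:6), tool = tool, gene = "HLA-A",
    allele1 = a1, allele2 = "A*02:01", stringsAsFactors = FALSE)
  opti <- c("A*03:01", "A*03:01", "A*03:01", "A*03:01", "A*01:01", "A*01:01")
  hd <- c("A*01:01", "A*01:01", "A*01:01", NA, "A*01:01", "A*01:01")
  calls <- call_table(rbind(mk("OptiType", opti), mk("HLA-HD", hd),
                            mk("PHLAT", opti)))
  ref <- reference_table(data.frame(
    sample_id = sprintf("S%d", 1:6), gene = "HLA-A",
    allele1 = "A*01:01", allele2 = "A*02:01", stringsAsFactors = FALSE))
  list(calls = calls, ref = ref)
}

test_that("correction score is B-right-given-A-wrong", {
  p <- pair_panel()
  expect_equal(correction_score(p$calls, p$ref, "HLA-A", "HLA-HD", "OptiType"),
               3 / 4)
  # a clone of A never corrects A
  expect_equal(correction_score(p$calls, p$ref, "HLA-A", "PHLAT", "OptiType"), 0)
  # HLA-HD is never wrong: undefined
  expect_error(correction_score(p$calls, p$ref, "HLA-A", "OptiType", "HLA-HD"),
               class = "hla_undefined_metric_error")
  expect_error(correction_score(p$calls, p$ref, "HLA-A", "OptiType", "OptiType"),
               class = "hla_usage_error")
})

test_that("correction score matches the brute-force recount on random tables", {
  set.seed(1234)
  for (i in 1:8) {
    calls <- random_call_table(20, pool_size = 3, p_missing = 0.2,
                               p_ambiguous = 0.1)
    ref <- random_reference(calls, "HLA-A", pool_size = 3)
    for (pair in list(c("OptiType", "HLA-HD"), c("Kourami", "seq2HLA"))) {
      got <- tryCatch(
        correction_score(calls, ref, "HLA-A", pair[1], pair[2]),
        hla_undefined_metric_error = function(e) NA_real_)
      expect_equal(got, oracle_correction(calls, ref, "HLA-A", pair[1], pair[2]))
    }
  }
})

test_that("complementary score is the symmetric mean of both directions", {
  set.seed(55)
  calls <- random_call_table(40, pool_size = 3, p_missing = 0.1)
  ref <- random_reference(calls, "HLA-A", pool_size = 3)
  ab <- complementary_score(calls, ref, "HLA-A", "OptiType", "HLA-HD")
  ba <- complementary_score(calls, ref, "HLA-A", "HLA-HD", "OptiType")
  expect_identical(ab, ba)
  expect_equal(ab, mean(c(
    correction_score(calls, ref, "HLA-A", "HLA-HD", "OptiType"),
    correction_score(calls, ref, "HLA-A", "OptiType", "HLA-HD"))))
})

test_that("complementary ratio arithmetic in both modes", {
  expect_equal(complementary_ratio(0.8, 0.9, "product"), 0.02)
  expect_equal(complementary_ratio(0.8, 0.9, "quotient"), 2)
  expect_equal(complementary_ratio(1, 0.5, "product"), 0)
  expect_equal(complementary_ratio(1, 0.5, "quotient"), 0)
  expect_error(complementary_ratio(0.5, 1, "quotient"), class = "hla_usage_error")
})

test_that("combination accuracy reduces, chains and stays monotone", {
  acc <- data.frame(tool = c("OptiType", "HLA-HD", "PHLAT"), gene = "HLA-A",
                    accuracy = c(0.9, 0.8, 0.7))
  corr <- data.frame(tool_a = c("OptiType", "OptiType"),
                     tool_b = c("HLA-HD", "PHLAT"),
                     gene = "HLA-A", score = c(0.75, 0.5))
  m <- hla_matrices(acc, corr)
  expect_equal(combination_accuracy("OptiType", "HLA-A", m), 0.9)
  expect_equal(combination_accuracy(c("OptiType", "HLA-HD"), "HLA-A", m),
               1 - 0.1 * 0.25)
  a2 <- combination_accuracy(c("OptiType", "HLA-HD"), "HLA-A", m)
  a3 <- combination_accuracy(c("OptiType", "HLA-HD", "PHLAT"), "HLA-A", m)
  expect_gte(a2, combination_accuracy("OptiType", "HLA-A", m))
  expect_gte(a3, a2)
  # missing correction entry falls back to the corrector's accuracy
  m2 <- hla_matrices(acc, corr[1, ])
  expect_message(
    a3b <- combination_accuracy(c("OptiType", "HLA-HD", "PHLAT"), "HLA-A", m2),
    "undefined")
  expect_equal(a3b, 1 - 0.1 * 0.25 * 0.3)
  expect_error(combination_accuracy("Kourami", "HLA-A", m),
               class = "hla_config_error")
})

test_that("custom calling applies a strict accuracy threshold", {
  m <- hla_matrices(
    data.frame(tool = c("OptiType", "HLA-HD"), gene = "HLA-A",
               accuracy = c(0.9, 0.8)),
    data.frame(tool_a = "OptiType", tool_b = "HLA-HD", gene = "HLA-A",
               score = 0.75))
  tab <- call_table(data.frame(
    sample_id = "S1", tool = c("OptiType", "HLA-HD"), gene = "HLA-A",
    allele1 = "A*01:01", allele2 = "A*02:01", stringsAsFactors = FALSE))
  rec <- modal_call(tab, "S1", "HLA-A")
  # combination accuracy 0.975 < 98%: escalate
  out <- custom_call(rec, 98, m)
  expect_identical(out$decision, "Recommend PCR-SBT")
  expect_equal(out$combination_accuracy, 0.975)
  # below the estimate: accept
  expect_identical(custom_call(rec, 97, m)$decision, "CONSENSUS")
  # strict inequality at the boundary
  expect_identical(custom_call(rec, 97.5, m)$decision, "Recommend PCR-SBT")
  expect_error(custom_call(rec, 0, m), class = "hla_usage_error")
  expect_error(custom_call(rec, 101, m), class = "hla_usage_error")
})

test_that("with independent errors corrections converge to the corrector's accuracy", {
  cfg <- simulation_config(n_samples = 4000, genes = "HLA-A", availability = 1,
                           accuracy = c(arcasHLA = 0.5, "HLA-HD" = 0.8,
                                        "HLA*LA" = 0.7, HLAscan = 0.6,
                                        Kourami = 0.6, OptiType = 0.9,
                                        PHLAT = 0.7, seq2HLA = 0.5),
                           rho = 0, seed = 42)
  sim <- simulate_calls(cfg)
  corr <- correction_score(sim$calls, sim$reference, "HLA-A",
                           "OptiType", "arcasHLA")
  expect_lt(abs(corr - 0.9), 0.03)
})

test_that("every combination of six or more tools clears the 98% threshold on benchmark-shaped matrices", {
  cfg <- simulation_config(n_samples = 1500, seed = 19, genes = "HLA-A")
  sim <- simulate_calls(cfg)
  m <- compute_matrices(sim$calls, sim$reference, genes = "HLA-A")
  combos <- c(utils::combn(hla_tools(), 6, simplify = FALSE),
              utils::combn(hla_tools(), 7, simplify = FALSE),
              list(hla_tools()))
  accs <- vapply(combos, combination_accuracy, numeric(1),
                 gene = "HLA-A", matrices = m)
  expect_true(all(accs * 100 > 98))
})
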