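# Availability, accuracy, group tallies, pooled accuracy and PRF.

tiny_panel <- function() {
  # 4 samples, 2 tools: OptiType available on all 4 (3 correct),
  # HLA-HD available on 3 (missing on S4)
  calls <- call_table(data.frame(
    sample_id = rep(c("S1", "S2", "S3", "S4"), each = 2),
    tool = rep(c("OptiType", "HLA-HD"), 4),
    gene = "HLA-A",
    allele1 = c("A*01:01", "A*01:01", "A*01:01", "A*01:01",
                "A*01:01", "A*01:01", "A*05:01", NA),
    allele2 = c("A*02:01", "A*02:01", "A*02:01", "A*02:01",
                "A*02:01", "A*02:01", "A*02:01", NA),
    stringsAsFactors = FALSE))
  ref <- reference_table(data.frame(
    sample_id = c("S1", "S2", "S3", "S4"), gene = "HLA-A",
    allele1 = "A*01:01", allele2 = "A*02:01", stringsAsFactors = FALSE))
  list(calls = calls, ref = ref)
}

test_that("availability is the share of samples with both available alleles", {
  p <- tiny_panel()
  expect_equal(availability(p$calls, "OptiType", "HLA-A"), 100)
  expect_equal(availability(p$calls, "HLA-HD", "HLA-A"), 75)
  # a tool with no rows at all is 0% available
  expect_equal(availability(p$calls, "Kourami", "HLA-A"), 0)
})

test_that("tool accuracy is matches over available calls with a reference", {
  p <- tiny_panel()
  expect_equal(tool_accuracy(p$calls, p$ref, "OptiType", "HLA-A"), 75) # 3 of 4
  expect_equal(tool_accuracy(p$calls, p$ref, "HLA-HD", "HLA-A"), 100)
  expect_error(tool_accuracy(p$calls, p$ref, "Kourami", "HLA-A"),
               class = "hla_undefined_metric_error")
})

test_that("simulated per-tool accuracy recovers the generating parameter", {
  cfg <- simulation_config(n_samples = 2000, genes = "HLA-A",
                           availability = 1, accuracy = 0.9, rho = 0, seed = 7)
  sim <- simulate_calls(cfg)
  acc <- tool_accuracy(sim$calls, sim$reference, "OptiType", "HLA-A")
  expect_gte(acc, 88)   # ~99% binomial interval around 90% at n = 2000
  expect_lte(acc, 92)
})

test_that("group tallies equal a brute-force per-sample recount", {
  set.seed(404)
  calls <- random_call_table(25, pool_size = 3, p_missing = 0.15,
                             p_ambiguous = 0.1)
  ref <- random_reference(calls, "HLA-A", pool_size = 3)
  tally <- group_tallies(calls, ref, "HLA-A")
  refk <- setNames(genotype_keys(ref), ref$sample_id)
  expected_conc <- expected_true <- setNames(integer(9), 0:8)
  for (s in unique(calls$sample_id)) {
    orc <- oracle_modal(as.data.frame(calls)[calls$sample_id == s, ])
    sz <- as.character(orc$n_agree)
    expected_conc[sz] <- expected_conc[sz] + 1L
    if (!is.na(orc$modal_key) && orc$modal_key == refk[[s]])
      expected_true[sz] <- expected_true[sz] + 1L
  }
  expect_identical(tally$n_concordant, expected_conc)
  expect_identical(tally$n_true, expected_true)
  expect_equal(sum(tally$n_concordant), tally$n_samples_evaluated)
  expect_true(all(tally$n_true <= tally$n_concordant))
})

test_that("tallies and metrics are invariant to sample order", {
  set.seed(21)
  df <- as.data.frame(random_call_table(10, pool_size = 3))
  ref <- random_reference(call_table(df), "HLA-A")
  perm <- df[sample(nrow(df)), ]
  t1 <- group_tallies(call_table(df), ref, "HLA-A")
  t2 <- group_tallies(call_table(perm), ref, "HLA-A")
  expect_identical(t1$n_concordant, t2$n_concordant)
  expect_identical(t1$n_true, t2$n_true)
  expect_equal(availability(call_table(df), "OptiType", "HLA-A"),
               availability(call_table(perm), "OptiType", "HLA-A"))
})

test_that("pooled accuracy and agreement fractions follow the tallies", {
  fx <- realize_fixture(fixture_spec("HLA-B", "thousand_genomes"))
  tally <- group_tallies(fx$calls, fx$reference, "HLA-B")
  # all tools always agreeing with the reference: single size-8 bucket
  all8 <- realize_fixture(group_spec("HLA-A", 10,
                                     data.frame(size = 8, n_true = 10, n_false = 0)))
  t8 <- group_tallies(all8$calls, all8$reference, "HLA-A")
  expect_equal(unname(t8$n_concordant["8"]), 10)
  expect_equal(unname(t8$n_true["8"]), 10)

  expect_equal(round_half_up(pooled_accuracy(tally, 6)), 98.2)
  # pooled at 2 equals the overall concordant-call accuracy
  expect_equal(pooled_accuracy(tally, 2),
               100 * sum(tally$n_true) / sum(tally$n_concordant))
  # monotone in the threshold on the benchmark fixtures
  accs <- vapply(5:8, function(m) pooled_accuracy(tally, m), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_error(pooled_accuracy(t8, 7, at_least = FALSE),
               class = "hla_undefined_metric_error")
  expect_error(pooled_accuracy(tally, 1), class = "hla_usage_error")
  expect_equal(round_half_up(agreement_fraction(tally, 7)), 12.7)
})

test_that("PRF matches its definitional recomputation", {
  fx <- realize_fixture(fixture_spec("HLA-B", "thousand_genomes"))
  tally <- group_tallies(fx$calls, fx$reference, "HLA-B")
  prf <- group_prf(tally, 6, pooled_at_least = TRUE)
  expect_equal(prf$tp, 112)
  expect_equal(prf$fp, 2)
  expect_equal(prf$fn, sum(tally$n_true) - 112)
  expect_equal(prf$precision, 112 / 114)
  expect_equal(prf$recall, prf$tp / (prf$tp + prf$fn))
  expect_equal(prf$f1, 2 * prf$precision * prf$recall / (prf$precision + prf$recall))
  # fp = 0 gives precision exactly 1
  prf8 <- group_prf(tally, 8)
  expect_identical(prf8$precision, 1)
  # all true calls in one size: recall 1 there
  one <- realize_fixture(group_spec("HLA-A", 5,
                                    data.frame(size = 7, n_true = 5, n_false = 0),
                                    filler_size = 4))
  to <- group_tallies(one$calls, one$reference, "HLA-A")
  expect_equal(group_prf(to, 7)$recall, 1)
  # random tallies recompute from tp/fp/fn
  set.seed(3)
  for (i in 1:10) {
    t <- tally
    t$n_concordant[] <- rpois(9, 5) + 1L
    t$n_true[] <- pmin(t$n_concordant, rpois(9, 4))
    p <- group_prf(t, 5, pooled_at_least = sample(c(TRUE, FALSE), 1))
    expect_equal(p$precision, p$tp / (p$tp + p$fp))
    expect_equal(p$recall, p$tp / (p$tp + p$fn))
  }
})

test_that("combine_tallies pools per-size counts across genes", {
  fxs <- lapply(hla_genes(), function(g)
    realize_fixture(fixture_spec(g, "thousand_genomes")))
  tallies <- lapply(fxs, function(fx)
    group_tallies(fx$calls, fx$reference, fx$spec$gene))
  abc <- combine_tallies(tallies)
  expect_equal(abc$n_samples_evaluated, 234 + 308 + 309)
  expect_equal(unname(abc$n_concordant["5"]), 61 + 84 + 77)
  expect_equal(group_prf(abc, 6, pooled_at_least = TRUE)$precision, 351 / 357)
})

test_that("combination tallies count each supporting set once per sample", {
  fx <- realize_fixture(group_spec("HLA-A", 4,
                                   data.frame(size = 6, n_true = 4, n_false = 0),
                                   filler_size = 4))
  ct <- combination_tallies(fx$calls)
  six <- ct[ct$n_agree == 6, ]
  expect_equal(nrow(six), 1)
  expect_equal(six$count, 4)
  expect_identical(six$combination,
                   paste(sort(hla_tools()[1:6], method = "radix"), collapse = ","))
})
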