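# Synthetic data: a seeded simulator of caller panels with controlled
# availability, accuracy and correlated errors, and a constructive generator
# realizing exact per-agreement-size tallies.

#' Default synthetic allele pool
#'
#' Ten synthetic two-field alleles per class I gene (`A*01:01` .. `A*10:01`,
#' and likewise for B and C). Large enough that distinct dissenting wrong
#' genotypes always exist.
#'
#' @return Named list of character vectors, one per gene.
#' @export
default_allele_pool <- function() {
  stats::setNames(lapply(c("A", "B", "C"), function(g)
    sprintf("%s*%02d:01", g, 1:10)), hla_genes())
}

.default_availability <- c(
  arcasHLA = 0.95, "HLA-HD" = 0.97, "HLA*LA" = 0.96, HLAscan = 0.75,
  Kourami = 0.73, OptiType = 0.99, PHLAT = 0.97, seq2HLA = 0.90)

.default_accuracy <- c(
  arcasHLA = 0.12, "HLA-HD" = 0.88, "HLA*LA" = 0.87, HLAscan = 0.84,
  Kourami = 0.80, OptiType = 0.91, PHLAT = 0.86, seq2HLA = 0.70)

.per_tool <- function(x, tools, default, what) {
  if (is.null(x)) x <- default[tools]
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(x, length(tools)), tools)
  if (is.null(names(x)) && length(x) == length(tools)) names(x) <- tools
  if (!all(tools %in% names(x)))
    stop_config(sprintf("%s must name every tool in the panel", what))
  x <- x[tools]
  if (anyNA(x) || any(x < 0 | x > 1))
    stop_config(sprintf("%s values must be in [0, 1]", what))
  x
}

#' Simulation configuration
#'
#' Defines the statistical structure of a simulated caller panel. Per-tool
#' availability and accuracy default to values shaped like an eight-tool WES
#' benchmark (high for the alignment-based exome callers, low accuracy for
#' the RNA-seq-oriented arcasHLA, low availability for HLAscan/Kourami).
#'
#' @param n_samples Number of samples.
#' @param genes Loci to simulate.
#' @param tools Tool panel.
#' @param availability Per-tool probability a call is available (scalar or
#'   named vector; default: built-in panel profile).
#' @param accuracy Per-tool probability an available call matches the
#'   reference (scalar or named vector).
#' @param rho Pairwise error correlation. With probability `rho` a tool's
#'   correctness draw reuses a sample-level shared quantile (so tools fail
#'   together on "hard" samples while each tool's marginal accuracy stays
#'   exactly `accuracy[tool]`), and a wrong call copies a previously drawn
#'   wrong genotype for the same sample/gene with probability `rho` instead
#'   of drawing a fresh one (so wrong calls can agree). At `rho = 0` errors
#'   are independent and correction scores converge to the correcting tool's
#'   accuracy.
#' @param p_ambiguous Probability an unavailable call is rendered as an
#'   ambiguous multi-allele string (e.g. `"03:01/05/06"`) rather than `NA`.
#' @param p_ref_multi Probability a reference genotype is rendered ambiguous
#'   (multi-type PCR-SBT result), exercising the single-type filter.
#' @param both_allele_errors Wrong genotypes differ from the reference in
#'   both alleles rather than one.
#' @param allele_pool,allele_freqs Per-gene allele pools (>= 3 alleles) and
#'   sampling frequencies (default [default_allele_pool()], uniform).
#' @param seed RNG seed; simulation is bit-reproducible given the config.
#' @return Object of class `hla_sim_config`.
#' @export
simulation_config <- function(n_samples, genes = hla_genes(), tools = hla_tools(),
                              availability = NULL, accuracy = NULL, rho = 0.2,
                              p_ambiguous = 0.5, p_ref_multi = 0,
                              both_allele_errors = FALSE,
                              allele_pool = NULL, allele_freqs = NULL,
                              seed = 1L) {
  stopifnot(n_samples >= 1L, all(genes %in% hla_genes()))
  for (p in c(rho, p_ambiguous, p_ref_multi))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_config("rho, p_ambiguous and p_ref_multi must be probabilities in [0, 1]")
  if (is.null(allele_pool)) allele_pool <- default_allele_pool()[genes]
  if (!all(genes %in% names(allele_pool)))
    stop_config("allele_pool must name every simulated gene")
  if (any(vapply(allele_pool[genes], function(p) length(unique(p)), integer(1)) < 3L))
    stop_config("allele_pool needs at least 3 distinct alleles per gene")
  if (is.null(allele_freqs))
    allele_freqs <- lapply(allele_pool[genes], function(p) rep(1 / length(p), length(p)))
  structure(
    list(n_samples = as.integer(n_samples), genes = genes, tools = tools,
         availability = .per_tool(availability, tools, .default_availability, "availability"),
         accuracy = .per_tool(accuracy, tools, .default_accuracy, "accuracy"),
         rho = rho, p_ambiguous = p_ambiguous, p_ref_multi = p_ref_multi,
         both_allele_errors = isTRUE(both_allele_errors),
         allele_pool = allele_pool[genes], allele_freqs = allele_freqs[genes],
         seed = as.integer(seed)),
    class = "hla_sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [simulation_config()] arguments.
#' @return An `hla_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such file: %s", path))
  args <- yaml::read_yaml(path)
  for (f in c("availability", "accuracy"))
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  do.call(simulation_config, args)
}

# fresh wrong genotype: replace one (or both) reference allele(s) with a
# uniformly drawn different pool allele.
.draw_wrong <- function(ref1, ref2, pool, both) {
  n <- length(ref1)
  k <- length(pool)
  swap <- function(cur) {
    off <- sample.int(k - 1L, n, replace = TRUE)
    pool[((match(cur, pool) - 1L + off) %% k) + 1L]
  }
  if (both) {
    list(a1 = swap(ref1), a2 = swap(ref2))
  } else {
    which1 <- sample.int(2L, n, replace = TRUE) == 1L
    new1 <- swap(ref1)
    new2 <- swap(ref2)
    list(a1 = ifelse(which1, new1, ref1), a2 = ifelse(which1, ref2, new2))
  }
}

# ambiguous multi-allele rendering of an allele string: "03:01/05/06"
.ambiguate <- function(a) {
  base <- sub("^[ABC]\\*", "", a)
  f2 <- as.integer(sub("^[0-9]+:", "", base))
  paste0(base, "/", sprintf("%02d", (f2 %% 90) + 5L), "/",
         sprintf("%02d", (f2 %% 90) + 6L))
}

#' Simulate a caller panel
#'
#' For each sample and gene: the reference genotype is drawn from the allele
#' pool; each tool's call is unavailable with probability
#' `1 - availability[tool]` (rendered as an ambiguous string with probability
#' `p_ambiguous`, otherwise missing), correct with probability
#' `accuracy[tool]`, and otherwise wrong — copying a previously drawn wrong
#' genotype for that sample with probability `rho` (correlated errors) or
#' drawing a fresh wrong genotype. Fully reproducible from `config$seed`.
#'
#' @param config An `hla_sim_config`.
#' @return List with elements `calls` (an `hla_calls`) and `reference`
#'   (an `hla_reference`).
#' @export
simulate_calls <- function(config) {
  stopifnot(inherits(config, "hla_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  tools <- config$tools
  samples <- sprintf("SIM%05d", seq_len(n))
  call_rows <- list()
  ref_rows <- list()

  for (gene in config$genes) {
    pool <- config$allele_pool[[gene]]
    freq <- config$allele_freqs[[gene]]
    ref1 <- sample(pool, n, replace = TRUE, prob = freq)
    ref2 <- sample(pool, n, replace = TRUE, prob = freq)
    ref_multi <- stats::runif(n) < config$p_ref_multi
    ref_rows[[gene]] <- data.frame(
      sample_id = samples, gene = gene,
      allele1 = ifelse(ref_multi, .ambiguate(ref1), ref1),
      allele2 = ref2, stringsAsFactors = FALSE)

    # wrong-call history for the correlated-copy mechanism
    w1 <- matrix(NA_character_, n, length(tools))
    w2 <- matrix(NA_character_, n, length(tools))
    wcount <- integer(n)
    # sample-level shared quantile: correctness draws that use it are
    # comonotone across tools, correlating error events
    u_common <- stats::runif(n)

    for (t in seq_along(tools)) {
      tool <- tools[t]
      avail <- stats::runif(n) < config$availability[[tool]]
      u_own <- stats::runif(n)
      use_common <- stats::runif(n) < config$rho
      correct <- ifelse(use_common, u_common, u_own) < config$accuracy[[tool]]
      copy <- stats::runif(n) < config$rho & wcount > 0L
      pick <- pmin(pmax(ceiling(stats::runif(n) * wcount), 1L), length(tools))
      fresh <- .draw_wrong(ref1, ref2, pool, config$both_allele_errors)
      amb <- stats::runif(n) < config$p_ambiguous

      c1 <- w1[cbind(seq_len(n), pick)]
      c2 <- w2[cbind(seq_len(n), pick)]
      a1 <- ifelse(correct, ref1, ifelse(copy, c1, fresh$a1))
      a2 <- ifelse(correct, ref2, ifelse(copy, c2, fresh$a2))

      wrong <- avail & !correct
      if (any(wrong)) {
        wcount[wrong] <- wcount[wrong] + 1L
        w1[cbind(which(wrong), wcount[wrong])] <- a1[wrong]
        w2[cbind(which(wrong), wcount[wrong])] <- a2[wrong]
      }

      out1 <- ifelse(avail, a1, ifelse(amb, .ambiguate(fresh$a1), NA_character_))
      out2 <- ifelse(avail, a2, ifelse(amb, a2, NA_character_))
      call_rows[[paste(gene, tool)]] <- data.frame(
        sample_id = samples, tool = tool, gene = gene,
        allele1 = out1, allele2 = out2, stringsAsFactors = FALSE)
    }
  }

  calls <- do.call(rbind, call_rows)
  calls <- calls[order(calls$sample_id, calls$gene, calls$tool), , drop = FALSE]
  refs <- do.call(rbind, ref_rows)
  refs <- refs[order(refs$sample_id, refs$gene), , drop = FALSE]
  list(calls = call_table(calls, tools = tools),
       reference = reference_table(refs))
}

#' Specify exact per-agreement-size tallies
#'
#' A constructive recipe: for each block, `n_true` samples whose concordant
#' call of exactly `size` tools matches the reference and `n_false` samples
#' whose concordant call of `size` tools is wrong. Remaining samples are
#' filler with agreement `filler_size` (at most 4, below any consensus
#' threshold of interest).
#'
#' @param gene Locus.
#' @param n_samples Total samples (>= sum of block counts).
#' @param blocks Data frame with columns `size` (5..8), `n_true`, `n_false`.
#' @param filler_size Agreement size of filler samples, in 2..4.
#' @return Object of class `hla_group_spec`.
#' @export
group_spec <- function(gene, n_samples, blocks, filler_size = 4L) {
  gene <- match.arg(gene, hla_genes())
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "n_true", "n_false") %in% names(blocks)))
  if (any(blocks$size < 5L | blocks$size > 8L))
    stop_config("block agreement sizes must be in 5..8 (filler covers <= 4)")
  if (any(blocks$n_true < 0L | blocks$n_false < 0L))
    stop_config("block counts must be non-negative")
  if (filler_size < 2L || filler_size > 4L)
    stop_config("filler_size must be in 2..4")
  if (sum(blocks$n_true + blocks$n_false) > n_samples)
    stop_config("block counts exceed n_samples")
  structure(list(gene = gene, n_samples = as.integer(n_samples),
                 blocks = blocks, filler_size = as.integer(filler_size)),
            class = "hla_group_spec")
}

#' Realize a group specification as a call table
#'
#' Deterministically constructs a call table and single-type reference whose
#' [group_tallies()] reproduce the specification exactly: in a true block of
#' size `s`, `s` tools call the reference and the `8 - s` dissenters each get
#' a distinct wrong genotype; in a false block, `s` tools share one wrong
#' genotype; filler samples have `filler_size` tools on the reference.
#' Dissenting calls never form a group as large as the block's agreement
#' size, and all eight calls are always available.
#'
#' @param spec An `hla_group_spec` (see [group_spec()], [fixture_spec()]).
#' @return List with `calls` (an `hla_calls`), `reference`
#'   (an `hla_reference`) and the input `spec`.
#' @export
realize_fixture <- function(spec) {
  stopifnot(inherits(spec, "hla_group_spec"))
  tools <- hla_tools()
  panel <- length(tools)
  pool <- default_allele_pool()[[spec$gene]]
  ref1 <- pool[1]
  ref2 <- pool[2]
  wrong_shared <- pool[3]
  dissent <- pool[4:length(pool)]

  sizes <- integer(0)
  truths <- logical(0)
  for (i in seq_len(nrow(spec$blocks))) {
    b <- spec$blocks[i, ]
    if (panel - b$size > length(dissent))
      stop_config(sprintf("block of size %d infeasible: not enough distinct dissent alleles", b$size))
    sizes <- c(sizes, rep(b$size, b$n_true + b$n_false))
    truths <- c(truths, rep(c(TRUE, FALSE), c(b$n_true, b$n_false)))
  }
  n_filler <- spec$n_samples - length(sizes)
  sizes <- c(sizes, rep(spec$filler_size, n_filler))
  truths <- c(truths, rep(TRUE, n_filler))

  samples <- sprintf("FIX-%s-%04d", sub("^HLA-", "", spec$gene),
                     seq_len(spec$n_samples))
  rows <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    s <- sizes[i]
    modal1 <- if (truths[i]) ref1 else wrong_shared
    a1 <- c(rep(modal1, s), dissent[seq_len(panel - s)])
    a2 <- rep(ref2, panel)
    rows[[i]] <- data.frame(sample_id = samples[i], tool = tools,
                            gene = spec$gene, allele1 = a1, allele2 = a2,
                            stringsAsFactors = FALSE)
  }
  calls <- call_table(do.call(rbind, rows), tools = tools)
  reference <- reference_table(data.frame(
    sample_id = samples, gene = spec$gene, allele1 = ref1, allele2 = ref2,
    stringsAsFactors = FALSE))
  list(calls = calls, reference = reference, spec = spec)
}

#' Packaged benchmark group specifications
#'
#' The per-agreement-size true/false tallies reported for the two validation
#' cohorts: the 1000 Genomes exome benchmark (234 / 308 / 309 samples with a
#' single-type PCR-SBT reference for HLA-A/-B/-C) and the 39-sample in-house
#' cohort (38 references for HLA-B). Counts printed only as pooled
#' (`>=6` / `>=7`) blocks are placed at agreement size 8; pooled metrics are
#' invariant to that placement.
#'
#' @param gene `"HLA-A"`, `"HLA-B"` or `"HLA-C"`.
#' @param cohort `"thousand_genomes"` or `"in_house"`.
#' @return An `hla_group_spec`.
#' @export
fixture_spec <- function(gene, cohort = c("thousand_genomes", "in_house")) {
  gene <- match.arg(gene, hla_genes())
  cohort <- match.arg(cohort)
  b <- function(...) data.frame(rbind(...))
  spec <- switch(
    cohort,
    thousand_genomes = switch(
      gene,
      "HLA-A" = list(n = 234L, blocks = b(c(size = 8, n_true = 97, n_false = 0),
                                          c(size = 5, n_true = 58, n_false = 3))),
      "HLA-B" = list(n = 308L, blocks = b(c(size = 8, n_true = 39, n_false = 0),
                                          c(size = 6, n_true = 73, n_false = 2),
                                          c(size = 5, n_true = 77, n_false = 7))),
      "HLA-C" = list(n = 309L, blocks = b(c(size = 8, n_true = 8, n_false = 0),
                                          c(size = 7, n_true = 50, n_false = 1),
                                          c(size = 6, n_true = 84, n_false = 3),
                                          c(size = 5, n_true = 74, n_false = 3)))),
    in_house = switch(
      gene,
      "HLA-A" = list(n = 39L, blocks = b(c(size = 8, n_true = 34, n_false = 0))),
      "HLA-B" = list(n = 38L, blocks = b(c(size = 8, n_true = 34, n_false = 0))),
      "HLA-C" = list(n = 39L, blocks = b(c(size = 8, n_true = 35, n_false = 0))))
  )
  group_spec(gene, spec$n, spec$blocks)
}
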