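# Pairwise error complementarity: correction scores, complementary scores
# and ratios, and the combination-accuracy model behind threshold-based
# custom calling.

#' Correction score of tool B to tool A
#'
#' Among samples where tool A presented an available call that mismatches the
#' single-type reference, the fraction where tool B's call is available and
#' matches the reference — i.e. how often B corrects A's errors.
#'
#' @param calls An `hla_calls` table.
#' @param ref An `hla_reference` table.
#' @param gene Locus.
#' @param tool_b The correcting tool.
#' @param tool_a The erring tool (`tool_a != tool_b`).
#' @param n_fields Comparison resolution (default 2).
#' @return Fraction in `[0, 1]`. If A is never wrong in the evaluated set the
#'   score is undefined and an error of class `hla_undefined_metric_error`
#'   is raised (matrix builders store it as missing).
#' @export
correction_score <- function(calls, ref, gene, tool_b, tool_a, n_fields = 2L) {
  if (tool_a == tool_b) stop_usage("correction score needs two distinct tools")
  rk <- .ref_keys(ref, gene, n_fields)
  km <- .keys_matrix(calls, gene, n_fields,
                     samples = intersect(unique(calls$sample_id), names(rk)))
  a <- km[, tool_a]
  b <- km[, tool_b]
  truth <- rk[rownames(km)]
  a_wrong <- !is.na(a) & a != truth
  if (!any(a_wrong))
    stop_metric(sprintf("correction score of %s to %s undefined for %s: %s never wrong",
                        tool_b, tool_a, gene, tool_a))
  sum(a_wrong & !is.na(b) & b == truth) / sum(a_wrong)
}

#' Complementary score between two tools
#'
#' The mean of the two directional correction scores,
#' `(correction(B to A) + correction(A to B)) / 2`; symmetric in the pair.
#'
#' @inheritParams correction_score
#' @param tool_a,tool_b The tool pair.
#' @return Fraction in `[0, 1]`; errors if either direction is undefined.
#' @export
complementary_score <- function(calls, ref, gene, tool_a, tool_b, n_fields = 2L) {
  (correction_score(calls, ref, gene, tool_b, tool_a, n_fields) +
     correction_score(calls, ref, gene, tool_a, tool_b, n_fields)) / 2
}

#' Complementary ratio
#'
#' Rescales a residual error `1 - correction(B to A)` by B's own residual
#' error `1 - accuracy(B)`. The combining operator is configurable:
#' `"product"` gives `(1 - corr) * (1 - acc_b)` (the default, the literal
#' juxtaposition reading), `"quotient"` gives `(1 - corr) / (1 - acc_b)`.
#'
#' @param correction_b_to_a Directional correction score in `[0, 1]`.
#' @param accuracy_b Tool B's accuracy as a fraction.
#' @param mode `"product"` or `"quotient"`.
#' @return Non-negative real.
#' @export
complementary_ratio <- function(correction_b_to_a, accuracy_b,
                                mode = c("product", "quotient")) {
  mode <- match.arg(mode)
  stopifnot(correction_b_to_a >= 0, correction_b_to_a <= 1,
            accuracy_b >= 0, accuracy_b <= 1)
  if (mode == "product") {
    (1 - correction_b_to_a) * (1 - accuracy_b)
  } else {
    if (accuracy_b == 1)
      stop_usage("quotient-mode complementary ratio undefined at accuracy 1")
    (1 - correction_b_to_a) / (1 - accuracy_b)
  }
}

#' Bundle accuracy and correction matrices
#'
#' Container consumed by [combination_accuracy()] and [custom_call()];
#' typically built from `model_acc.csv` / `cor_score.csv`
#' ([read_accuracy_csv()], [read_correction_csv()]) or computed from a
#' benchmarked call table via [compute_matrices()].
#'
#' @param accuracy Long data frame `(tool, gene, accuracy)`.
#' @param correction Long data frame `(tool_a, tool_b, gene, score)` where
#'   `score` is the correction score of B to A; missing pairs are treated as
#'   undefined.
#' @return Object of class `hla_matrices`.
#' @export
hla_matrices <- function(accuracy, correction) {
  stopifnot(all(c("tool", "gene", "accuracy") %in% names(accuracy)),
            all(c("tool_a", "tool_b", "gene", "score") %in% names(correction)))
  structure(list(accuracy = as.data.frame(accuracy),
                 correction = as.data.frame(correction)),
            class = "hla_matrices")
}

.m_acc <- function(m, tool, gene) {
  v <- m$accuracy$accuracy[m$accuracy$tool == tool & m$accuracy$gene == gene]
  if (!length(v) || is.na(v[1]))
    stop_config(sprintf("no accuracy entry for %s / %s", tool, gene))
  v[1]
}

.m_corr <- function(m, tool_b, tool_a, gene) {
  v <- m$correction$score[m$correction$tool_a == tool_a &
                            m$correction$tool_b == tool_b &
                            m$correction$gene == gene]
  if (!length(v)) NA_real_ else v[1]
}

#' Compute complementarity matrices from a benchmarked call table
#'
#' Per-tool accuracies, all directional correction scores, symmetric
#' complementary scores, and complementary ratios, from calls evaluated
#' against a single-type reference.
#'
#' @inheritParams correction_score
#' @param genes,tools Loci and panel to evaluate (defaults: all in table).
#' @param ratio_mode Passed to [complementary_ratio()].
#' @return An `hla_matrices` with extra elements `complementary`
#'   `(tool_a, tool_b, gene, score)` and `ratio`
#'   `(tool_a, tool_b, gene, ratio)`; undefined entries are `NA`.
#' @export
compute_matrices <- function(calls, ref, genes = NULL, tools = NULL,
                             n_fields = 2L, ratio_mode = "product") {
  stopifnot(inherits(calls, "hla_calls"), inherits(ref, "hla_reference"))
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  if (is.null(tools)) tools <- attr(calls, "tools")
  acc <- expand.grid(tool = tools, gene = genes, stringsAsFactors = FALSE)
  pairs <- expand.grid(tool_a = tools, tool_b = tools, gene = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tool_a != pairs$tool_b, , drop = FALSE]
  rownames(pairs) <- NULL
  acc$accuracy <- NA_real_
  pairs$score <- NA_real_
  # one keys matrix per gene; accuracy and all directional corrections are
  # counted from it
  for (g in genes) {
    rk <- .ref_keys(ref, g, n_fields)
    km <- .keys_matrix(calls, g, n_fields,
                       samples = intersect(unique(calls$sample_id), names(rk)),
                       tools = tools)
    truth <- rk[rownames(km)]
    for (t in tools) {
      avail <- !is.na(km[, t])
      acc$accuracy[acc$tool == t & acc$gene == g] <-
        if (any(avail)) sum(km[avail, t] == truth[avail]) / sum(avail) else NA_real_
    }
    gi <- pairs$gene == g
    for (i in which(gi)) {
      a <- km[, pairs$tool_a[i]]
      b <- km[, pairs$tool_b[i]]
      a_wrong <- !is.na(a) & a != truth
      pairs$score[i] <- if (any(a_wrong))
        sum(a_wrong & !is.na(b) & b == truth) / sum(a_wrong) else NA_real_
    }
  }
  m <- hla_matrices(acc, pairs)
  rev_score <- mapply(function(a, b, g) .m_corr(m, a, b, g),
                      pairs$tool_a, pairs$tool_b, pairs$gene)
  m$complementary <- data.frame(
    tool_a = pairs$tool_a, tool_b = pairs$tool_b, gene = pairs$gene,
    score = (pairs$score + rev_score) / 2, stringsAsFactors = FALSE)
  acc_b <- mapply(function(b, g) {
    v <- acc$accuracy[acc$tool == b & acc$gene == g]
    if (length(v)) v[1] else NA_real_
  }, pairs$tool_b, pairs$gene)
  m$ratio <- data.frame(
    tool_a = pairs$tool_a, tool_b = pairs$tool_b, gene = pairs$gene,
    ratio = ifelse(is.na(pairs$score) | is.na(acc_b), NA_real_,
                   mapply(function(c, a) {
                     if (is.na(c) || is.na(a)) NA_real_
                     else complementary_ratio(c, a, ratio_mode)
                   }, pairs$score, acc_b)),
    stringsAsFactors = FALSE)
  m
}

#' @export
print.hla_matrices <- function(x, ...) {
  cat(sprintf("<hla_matrices> %d accuracy entries, %d correction entries\n",
              nrow(x$accuracy), nrow(x$correction)))
  invisible(x)
}

#' Estimated accuracy of a tool combination
#'
#' Model of the probability that the concordant call of a tool set is
#' correct: anchored on the most accurate tool `a` in the set (ties broken
#' alphabetically), the joint error is estimated as the chain
#' `(1 - accuracy(a)) * prod(1 - correction(b to a))` over the other tools
#' `b`, i.e. the anchor is wrong and no other tool corrects it; the returned
#' accuracy is one minus that, clamped to `[0, 1]`. Under independent tool
#' errors `correction(b to a)` reduces to `accuracy(b)` and the estimate is
#' exactly `P(at least one tool in the set is correct)`. A missing correction
#' score (the anchor was never wrong in the training set) falls back to
#' `accuracy(b)`, with a message.
#'
#' @param tools Character vector of tool names (the combination).
#' @param gene Locus.
#' @param matrices An `hla_matrices`.
#' @return Estimated accuracy as a fraction in `[0, 1]`.
#' @export
combination_accuracy <- function(tools, gene, matrices) {
  stopifnot(inherits(matrices, "hla_matrices"), length(tools) >= 1L)
  tools <- sort(unique(tools), method = "radix")
  accs <- vapply(tools, .m_acc, numeric(1), gene = gene, m = matrices)
  anchor <- tools[order(-accs, tools, method = "radix")][1]
  err <- 1 - accs[[anchor]]
  for (b in setdiff(tools, anchor)) {
    corr <- .m_corr(matrices, b, anchor, gene)
    if (is.na(corr)) {
      corr <- .m_acc(matrices, b, gene)
      message(sprintf("correction score of %s to %s (%s) undefined; using %s's accuracy %.3f",
                      b, anchor, gene, b, corr))
    }
    err <- err * (1 - corr)
  }
  min(max(1 - err, 0), 1)
}

#' Threshold-based custom calling
#'
#' Accepts the concordant call of a record iff the estimated accuracy of its
#' supporting tool combination strictly exceeds `threshold_pct` percent;
#' otherwise recommends PCR-SBT. With the threshold at 98 this reproduces the
#' finding that every combination of six or more concordant tools is
#' acceptable.
#'
#' @param rec An `hla_concordance` with `n_agree >= 2`.
#' @param threshold_pct Accuracy threshold in percent, in `(0, 100]`.
#' @param matrices An `hla_matrices`.
#' @return The record with `decision` set and an added
#'   `combination_accuracy` element (fraction).
#' @export
custom_call <- function(rec, threshold_pct, matrices) {
  stopifnot(inherits(rec, "hla_concordance"))
  if (!is.numeric(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100)
    stop_usage("threshold_pct must be in (0, 100]")
  if (rec$n_agree < 2L) {
    rec$combination_accuracy <- NA_real_
    rec$decision <- RECOMMEND_SBT
    return(rec)
  }
  acc <- combination_accuracy(rec$supporting_tools, rec$gene, matrices)
  rec$combination_accuracy <- acc
  rec$decision <- if (acc * 100 > threshold_pct) "CONSENSUS" else RECOMMEND_SBT
  rec
}
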