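# Evaluation statistics: per-tool availability and accuracy against the
# PCR-SBT reference, per-agreement-size true/false-call tallies, pooled
# accuracy, and precision/recall/F1.

#' Per-tool availability
#'
#' Percentage of samples for which a tool presented a single unambiguous
#' two-field prediction for both alleles of `gene`:
#' `100 * (#samples with an available call) / (#samples)`. The denominator is
#' every sample in the table; samples with no row for the tool/gene count as
#' unavailable.
#'
#' @param calls An `hla_calls` table.
#' @param tool,gene Tool and locus.
#' @param n_fields Resolution an allele must reach to count as available.
#' @return Percentage in `[0, 100]` (unrounded).
#' @export
availability <- function(calls, tool, gene, n_fields = 2L) {
  stopifnot(inherits(calls, "hla_calls"))
  samples <- unique(calls$sample_id)
  if (!length(samples)) stop_metric("availability undefined: no samples in table")
  rows <- calls[calls$tool == tool & calls$gene == gene, , drop = FALSE]
  100 * sum(!is.na(genotype_keys(rows, n_fields))) / length(samples)
}

#' Per-tool accuracy against the reference
#'
#' Among samples where the tool's call is available *and* a single-type
#' reference genotype exists, the percentage whose call matches the reference
#' in both alleles at `n_fields` (four-digit) resolution:
#' `100 * (#both-allele matches) / (#available calls with a reference)`.
#'
#' @param calls An `hla_calls` table.
#' @param ref An `hla_reference` table (filtered to single-type internally).
#' @param tool,gene Tool and locus.
#' @param n_fields Comparison resolution (default 2).
#' @return Percentage in `[0, 100]` (unrounded).
#' @export
tool_accuracy <- function(calls, ref, tool, gene, n_fields = 2L) {
  stopifnot(inherits(calls, "hla_calls"), inherits(ref, "hla_reference"))
  rk <- .ref_keys(ref, gene, n_fields)
  rows <- calls[calls$tool == tool & calls$gene == gene &
                  calls$sample_id %in% names(rk), , drop = FALSE]
  keys <- genotype_keys(rows, n_fields)
  avail <- !is.na(keys)
  if (!any(avail))
    stop_metric(sprintf("accuracy undefined for %s/%s: no available calls with a reference",
                        tool, gene))
  100 * sum(keys[avail] == rk[rows$sample_id[avail]]) / sum(avail)
}

#' Per-agreement-size true/false-call tallies
#'
#' For every sample with a single-type reference for `gene`, computes the
#' concordant (modal) call and tallies, per agreement size 0..panel, how many
#' concordant calls there are (`n_concordant`) and how many match the
#' reference (`n_true`).
#'
#' @param calls An `hla_calls` table.
#' @param ref An `hla_reference` table.
#' @param gene Locus.
#' @param n_fields Comparison resolution (default 2).
#' @return Object of class `hla_group_tally`: `gene`, integer vectors
#'   `n_concordant` and `n_true` named by size `0..panel_size`, and
#'   `n_samples_evaluated`.
#' @export
group_tallies <- function(calls, ref, gene, n_fields = 2L) {
  stopifnot(inherits(calls, "hla_calls"), inherits(ref, "hla_reference"))
  tools <- attr(calls, "tools")
  panel <- length(tools)
  rk <- .ref_keys(ref, gene, n_fields)
  samples <- intersect(unique(calls$sample_id[calls$gene == gene]), names(rk))
  sizes <- as.character(0:panel)
  n_concordant <- n_true <- stats::setNames(integer(panel + 1L), sizes)
  km <- .keys_matrix(calls, gene, n_fields, samples = samples, tools = tools)
  for (s in samples) {
    rec <- .new_concordance(s, gene, km[s, ], tools, n_fields)
    sz <- as.character(rec$n_agree)
    n_concordant[sz] <- n_concordant[sz] + 1L
    if (!is.na(rec$modal_key) && rec$modal_key == rk[[s]])
      n_true[sz] <- n_true[sz] + 1L
  }
  structure(
    list(gene = gene, n_concordant = n_concordant, n_true = n_true,
         n_samples_evaluated = length(samples)),
    class = "hla_group_tally"
  )
}

#' @export
print.hla_group_tally <- function(x, ...) {
  cat(sprintf("<hla_group_tally> %s: %d samples evaluated\n",
              x$gene, x$n_samples_evaluated))
  nz <- x$n_concordant > 0
  df <- data.frame(size = names(x$n_concordant)[nz],
                   concordant = x$n_concordant[nz], true = x$n_true[nz])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Combine tallies across genes
#'
#' Element-wise sum of per-size counts, e.g. to report HLA-ABC pooled over
#' the three class I loci.
#'
#' @param tallies List of `hla_group_tally` objects with equal panel size.
#' @return An `hla_group_tally` with `gene` set to the joined gene names.
#' @export
combine_tallies <- function(tallies) {
  stopifnot(length(tallies) >= 1L,
            all(vapply(tallies, inherits, logical(1), "hla_group_tally")))
  out <- tallies[[1]]
  for (t in tallies[-1]) {
    stopifnot(length(t$n_concordant) == length(out$n_concordant))
    out$n_concordant <- out$n_concordant + t$n_concordant
    out$n_true <- out$n_true + t$n_true
    out$n_samples_evaluated <- out$n_samples_evaluated + t$n_samples_evaluated
  }
  out$gene <- paste(vapply(tallies, `[[`, character(1), "gene"), collapse = "+")
  out
}

.pool <- function(tally, min_size, at_least = TRUE) {
  sizes <- as.integer(names(tally$n_concordant))
  sel <- if (at_least) sizes >= min_size else sizes == min_size
  list(concordant = sum(tally$n_concordant[sel]),
       true = sum(tally$n_true[sel]), sel = sel)
}

#' Pooled accuracy of concordant calls at or above an agreement size
#'
#' `100 * sum(n_true) / sum(n_concordant)` over sizes `>= min_size`. With
#' `min_size = 6` this is the accuracy of the consensus rule's accepted
#' calls.
#'
#' @param tally An `hla_group_tally`.
#' @param min_size Minimum agreement size, in `2..panel_size`.
#' @param at_least Pool all sizes `>= min_size` (default) or take the single
#'   exclusive size.
#' @return Percentage in `[0, 100]` (unrounded; see [round_half_up()] for
#'   reporting).
#' @export
pooled_accuracy <- function(tally, min_size, at_least = TRUE) {
  stopifnot(inherits(tally, "hla_group_tally"))
  panel <- length(tally$n_concordant) - 1L
  if (min_size < 2L || min_size > panel)
    stop_usage(sprintf("min_size must be in 2..%d", panel))
  p <- .pool(tally, min_size, at_least)
  if (p$concordant == 0L)
    stop_metric(sprintf("pooled accuracy undefined: no concordant calls at size %s %d",
                        if (at_least) ">=" else "==", min_size))
  100 * p$true / p$concordant
}

#' Fraction of evaluated samples reaching an agreement size
#'
#' `100 * sum(n_concordant at sizes >= min_size) / n_samples_evaluated` —
#' e.g. the share of samples the consensus rule resolves without PCR-SBT.
#'
#' @inheritParams pooled_accuracy
#' @return Percentage in `[0, 100]` (unrounded).
#' @export
agreement_fraction <- function(tally, min_size, at_least = TRUE) {
  stopifnot(inherits(tally, "hla_group_tally"))
  if (tally$n_samples_evaluated == 0L)
    stop_metric("agreement fraction undefined: no samples evaluated")
  p <- .pool(tally, min_size, at_least)
  100 * p$concordant / tally$n_samples_evaluated
}

#' Precision, recall and F1 for an agreement-size group
#'
#' With true calls as true positives and false calls as false positives
#' within the (pooled) group, and false negatives defined as the true calls
#' appearing in all *other* agreement sizes:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1 = 2pr/(p+r)`.
#'
#' @param tally An `hla_group_tally`.
#' @param size Agreement size of the group.
#' @param pooled_at_least Treat `size` as a lower bound (pool sizes
#'   `>= size`) rather than an exclusive size.
#' @return List of class `hla_prf`: `precision`, `recall`, `f1` (fractions),
#'   and integer `tp`, `fp`, `fn`.
#' @export
group_prf <- function(tally, size, pooled_at_least = FALSE) {
  stopifnot(inherits(tally, "hla_group_tally"))
  p <- .pool(tally, size, pooled_at_least)
  tp <- p$true
  fp <- p$concordant - p$true
  fn <- sum(tally$n_true[!p$sel])
  if (tp + fp == 0L)
    stop_metric(sprintf("precision undefined: no concordant calls in group %d", size))
  precision <- tp / (tp + fp)
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NaN
  f1 <- if (is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NaN
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "hla_prf")
}

#' @export
print.hla_prf <- function(x, ...) {
  cat(sprintf("<hla_prf> precision=%.4f recall=%.4f f1=%.4f (tp=%d fp=%d fn=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Tally supporting-tool combinations (UpSet-style)
#'
#' Counts, per gene, how many samples' concordant call is supported by each
#' exact tool combination (records with `n_agree < 2` carry no combination
#' and are skipped).
#'
#' @param calls An `hla_calls` table.
#' @param n_fields Comparison resolution.
#' @return Data frame `(gene, combination, n_agree, count)` with
#'   `combination` the sorted comma-joined tool set, ordered by decreasing
#'   count within gene.
#' @export
combination_tallies <- function(calls, n_fields = 2L) {
  conc <- concordance(calls, n_fields = n_fields)
  conc <- conc[conc$n_agree >= 2L, , drop = FALSE]
  if (!nrow(conc))
    return(data.frame(gene = character(0), combination = character(0),
                      n_agree = integer(0), count = integer(0)))
  agg <- stats::aggregate(list(count = seq_len(nrow(conc))),
                          by = list(gene = conc$gene,
                                    combination = conc$supporting_tools),
                          FUN = length)
  agg$n_agree <- lengths(strsplit(agg$combination, ",", fixed = TRUE))
  agg <- agg[order(agg$gene, -agg$count, agg$combination), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[c("gene", "combination", "n_agree", "count")]
}
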