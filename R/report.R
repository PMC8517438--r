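# Benchmark report: every evaluation statistic the package defines, bundled
# for JSON serialization.

.tally_json <- function(tally) {
  list(gene = tally$gene,
       n_samples_evaluated = tally$n_samples_evaluated,
       sizes = as.integer(names(tally$n_concordant)),
       n_concordant = unname(tally$n_concordant),
       n_true = unname(tally$n_true))
}

.prf_json <- function(prf) {
  prf <- unclass(prf)
  prf[!vapply(prf, is.finite, logical(1))] <- NA
  prf
}

#' Benchmark a call table against a reference
#'
#' Computes every evaluation statistic: per-tool availability and accuracy,
#' per-gene agreement-size tallies with pooled accuracy, the share of samples
#' the consensus rule resolves, pooled precision/recall/F1 at the consensus
#' threshold, UpSet-style combination tallies, and the full complementarity
#' matrices. Percentages are reported both raw and rounded half-up to one
#' decimal.
#'
#' @param calls An `hla_calls` table.
#' @param ref An `hla_reference` table.
#' @param genes Loci to evaluate (default: all present in `calls`).
#' @param n_fields Comparison resolution (default 2).
#' @param min_agree Consensus threshold (default 6).
#' @return A nested list of class `hla_report`, serializable with
#'   [write_report()].
#' @export
benchmark_report <- function(calls, ref, genes = NULL, n_fields = 2L,
                             min_agree = 6L) {
  stopifnot(inherits(calls, "hla_calls"), inherits(ref, "hla_reference"))
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  tools <- attr(calls, "tools")

  per_tool <- expand.grid(tool = tools, gene = genes, stringsAsFactors = FALSE)
  per_tool$availability <- mapply(function(t, g)
    availability(calls, t, g, n_fields), per_tool$tool, per_tool$gene)
  per_tool$accuracy <- mapply(function(t, g) {
    tryCatch(tool_accuracy(calls, ref, t, g, n_fields),
             hla_undefined_metric_error = function(e) NA_real_)
  }, per_tool$tool, per_tool$gene)

  tallies <- lapply(genes, function(g) group_tallies(calls, ref, g, n_fields))
  names(tallies) <- genes

  gene_stats <- lapply(tallies, function(t) {
    pooled <- tryCatch(pooled_accuracy(t, min_agree),
                       hla_undefined_metric_error = function(e) NA_real_)
    prf <- tryCatch(.prf_json(group_prf(t, min_agree, pooled_at_least = TRUE)),
                    hla_undefined_metric_error = function(e) NULL)
    list(tally = .tally_json(t),
         pooled_accuracy = pooled,
         pooled_accuracy_rounded = if (is.na(pooled)) NA else round_half_up(pooled),
         agreement_fraction = agreement_fraction(t, min_agree),
         agreement_fraction_rounded = round_half_up(agreement_fraction(t, min_agree)),
         prf_pooled = prf)
  })

  combined <- if (length(tallies) > 1L) {
    ct <- combine_tallies(tallies)
    pooled <- tryCatch(pooled_accuracy(ct, min_agree),
                       hla_undefined_metric_error = function(e) NA_real_)
    list(tally = .tally_json(ct),
         pooled_accuracy = pooled,
         pooled_accuracy_rounded = if (is.na(pooled)) NA else round_half_up(pooled),
         prf_pooled = tryCatch(.prf_json(group_prf(ct, min_agree, pooled_at_least = TRUE)),
                               hla_undefined_metric_error = function(e) NULL))
  } else NULL

  matrices <- compute_matrices(calls, ref, genes = genes, tools = tools,
                               n_fields = n_fields)

  structure(
    list(panel = tools, genes = genes, n_fields = n_fields,
         min_agree = min_agree,
         per_tool = per_tool,
         per_gene = gene_stats,
         combined = combined,
         combinations = combination_tallies(calls, n_fields),
         accuracy_matrix = matrices$accuracy,
         correction_matrix = matrices$correction,
         complementary_matrix = matrices$complementary,
         complementary_ratio_matrix = matrices$ratio),
    class = "hla_report"
  )
}

#' Write a benchmark report to JSON
#'
#' @param report An `hla_report` (or any list).
#' @param path Output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}
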