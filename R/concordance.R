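# Concordance: the modal genotype across available tool calls, its
# supporting tool set, and the consensus decision.

RECOMMEND_SBT <- "Recommend PCR-SBT"

.new_concordance <- function(sample_id, gene, keys, tools, n_fields) {
  avail <- !is.na(keys)
  n_available <- sum(avail)
  if (n_available == 0L) {
    rec <- list(sample_id = sample_id, gene = gene, modal_key = NA_character_,
                n_agree = 0L, supporting_tools = character(0),
                n_available = 0L, tie = FALSE, n_fields = n_fields,
                decision = NA_character_)
    class(rec) <- "hla_concordance"
    return(rec)
  }
  tab <- table(keys[avail])
  top <- max(tab)
  winners <- sort(names(tab)[tab == top], method = "radix")
  modal_key <- winners[1]
  rec <- list(
    sample_id = sample_id, gene = gene, modal_key = modal_key,
    n_agree = as.integer(top),
    supporting_tools = sort(tools[avail & keys == modal_key], method = "radix"),
    n_available = as.integer(n_available),
    tie = length(winners) > 1L,
    n_fields = n_fields,
    decision = NA_character_
  )
  class(rec) <- "hla_concordance"
  rec
}

#' Modal genotype call for one sample and gene
#'
#' Groups the available tool calls by genotype equality at `n_fields`
#' resolution and returns the largest group (the "concordant call"), the
#' tools supporting it, and the number of available calls. Ties between
#' equally large groups are broken deterministically by the lexicographically
#' smallest canonical genotype key and flagged (`tie = TRUE`); at the default
#' consensus threshold of 6-of-8 a tied group can never reach the threshold.
#'
#' @param calls An `hla_calls` table.
#' @param sample_id,gene The sample and locus to evaluate.
#' @param n_fields Comparison resolution (default 2).
#' @return An object of class `hla_concordance`: `modal_key` (canonical
#'   genotype key or `NA`), `n_agree`, `supporting_tools`, `n_available`,
#'   `tie`, and a `decision` slot filled by [consensus_decide()].
#' @export
modal_call <- function(calls, sample_id, gene, n_fields = 2L) {
  stopifnot(inherits(calls, "hla_calls"))
  rows <- calls[calls$sample_id == sample_id & calls$gene == gene, , drop = FALSE]
  if (!nrow(rows))
    stop_contract(sprintf("no calls for sample '%s', gene '%s'", sample_id, gene))
  .new_concordance(sample_id, gene, genotype_keys(rows, n_fields),
                   rows$tool, n_fields)
}

#' @export
print.hla_concordance <- function(x, ...) {
  cat(sprintf("<hla_concordance> %s %s: %s (%d/%d agree%s)%s\n",
              x$sample_id, x$gene,
              if (is.na(x$modal_key)) "no available call" else x$modal_key,
              x$n_agree, x$n_available, if (x$tie) ", tie" else "",
              if (is.na(x$decision)) "" else paste0(" -> ", x$decision)))
  invisible(x)
}

#' Apply the consensus rule to a concordance record
#'
#' The decision rule of the combined algorithm: if at least `min_agree` of
#' the eight panel tools present the same call, that call is chosen as the
#' HLA genotype (`CONSENSUS`); otherwise the genotype should be determined
#' experimentally (`"Recommend PCR-SBT"`). The threshold is against the fixed
#' panel, not against the number of available calls: 5 agreeing of 5
#' available is still below the default threshold of 6.
#'
#' @param rec An `hla_concordance` from [modal_call()].
#' @param min_agree Agreement threshold (default 6).
#' @param panel_size Size of the tool panel (default 8).
#' @return The record with `decision` set to `"CONSENSUS"` or
#'   `"Recommend PCR-SBT"`.
#' @export
consensus_decide <- function(rec, min_agree = 6L, panel_size = 8L) {
  stopifnot(inherits(rec, "hla_concordance"))
  if (min_agree < 1L || min_agree > panel_size)
    stop_usage(sprintf("min_agree must be in 1..%d, got %s", panel_size, min_agree))
  rec$decision <- if (rec$n_agree >= min_agree) "CONSENSUS" else RECOMMEND_SBT
  rec
}

#' Canonical combination key of the supporting tool set
#'
#' Sorted tuple of the tools supporting the concordant call, used to tally
#' UpSet-style combination counts. Records with fewer than two agreeing
#' tools carry no combination: `NULL` is returned.
#'
#' @param rec An `hla_concordance`.
#' @return Sorted character vector of tool names, or `NULL` when
#'   `n_agree < 2`.
#' @export
combination_key <- function(rec) {
  stopifnot(inherits(rec, "hla_concordance"))
  if (rec$n_agree < 2L) return(NULL)
  sort(rec$supporting_tools, method = "radix")
}

#' Concordance and consensus decisions for a whole call table
#'
#' Computes [modal_call()] + [consensus_decide()] for every (sample, gene)
#' pair present in the table.
#'
#' @param calls An `hla_calls` table.
#' @param n_fields Comparison resolution (default 2).
#' @param min_agree Consensus threshold (default 6).
#' @return Data frame with one row per (sample, gene): `sample_id`, `gene`,
#'   `decision`, `allele1`, `allele2` (the consensus genotype at `n_fields`
#'   resolution, `NA` unless `CONSENSUS`), `n_agree`, `n_available`, `tie`,
#'   `modal_key`, and `supporting_tools` (comma-joined, sorted).
#' @export
concordance <- function(calls, n_fields = 2L, min_agree = 6L) {
  stopifnot(inherits(calls, "hla_calls"))
  if (min_agree < 1L || min_agree > length(attr(calls, "tools")))
    stop_usage("min_agree outside the tool panel size")
  keys <- genotype_keys(calls, n_fields)
  grp <- paste(calls$sample_id, calls$gene, sep = "\r")
  idx <- split(seq_len(nrow(calls)), grp)
  recs <- lapply(idx, function(i) {
    rec <- .new_concordance(calls$sample_id[i[1]], calls$gene[i[1]],
                            keys[i], calls$tool[i], n_fields)
    consensus_decide(rec, min_agree)
  })
  consensus <- vapply(recs, function(r) r$decision == "CONSENSUS", logical(1))
  alleles <- t(vapply(recs, function(r) {
    if (r$decision == "CONSENSUS") strsplit(r$modal_key, "+", fixed = TRUE)[[1]]
    else c(NA_character_, NA_character_)
  }, character(2)))
  out <- data.frame(
    sample_id = vapply(recs, `[[`, character(1), "sample_id"),
    gene = vapply(recs, `[[`, character(1), "gene"),
    decision = vapply(recs, `[[`, character(1), "decision"),
    allele1 = alleles[, 1],
    allele2 = alleles[, 2],
    n_agree = vapply(recs, `[[`, integer(1), "n_agree"),
    n_available = vapply(recs, `[[`, integer(1), "n_available"),
    tie = vapply(recs, `[[`, logical(1), "tie"),
    modal_key = vapply(recs, `[[`, character(1), "modal_key"),
    supporting_tools = vapply(recs, function(r)
      paste(r$supporting_tools, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
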