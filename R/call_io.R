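# Interchange I/O: the normalized TSV call/reference tables, the decisions
# output, and the accuracy/correction CSV configuration matrices.

.call_cols <- c("sample_id", "tool", "gene", "allele1", "allele2")
.ref_cols <- c("sample_id", "gene", "allele1", "allele2")

.check_gene <- function(gene) {
  bad <- setdiff(unique(gene), hla_genes())
  if (length(bad))
    stop_format(sprintf("unknown gene(s): %s (expected %s)",
                        paste(bad, collapse = ", "),
                        paste(hla_genes(), collapse = ", ")))
}

#' Construct a call table from a data frame
#'
#' One row per sample x tool x gene with the two raw allele strings as the
#' tool emitted them. Missing calls are `NA` (or the literal string "NA" /
#' ""); ambiguous multi-allele strings are kept verbatim and flagged
#' unavailable downstream. At most one row per (sample, tool, gene) key.
#'
#' @param df Data frame with columns `sample_id`, `tool`, `gene`, `allele1`,
#'   `allele2`.
#' @param tools The tool panel; rows naming tools outside the panel are
#'   rejected unless `allow_extra_tools = TRUE` (they are then appended).
#' @param allow_extra_tools Accept tool names beyond `tools`.
#' @return Object of class `hla_calls` (a data frame) with attribute
#'   `tools` (the ordered panel).
#' @export
call_table <- function(df, tools = hla_tools(), allow_extra_tools = FALSE) {
  if (!all(.call_cols %in% names(df)))
    stop_format(sprintf("call table needs columns %s",
                        paste(.call_cols, collapse = ", ")))
  df <- as.data.frame(df)[.call_cols]
  for (j in .call_cols) df[[j]] <- as.character(df[[j]])
  .check_gene(df$gene)
  extra <- setdiff(unique(df$tool), tools)
  if (length(extra)) {
    if (!allow_extra_tools)
      stop_format(sprintf("unknown tool(s): %s (use allow_extra_tools to accept)",
                          paste(extra, collapse = ", ")))
    tools <- c(tools, sort(extra))
  }
  key <- paste(df$sample_id, df$tool, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_format(sprintf("duplicate call record for (sample=%s, tool=%s, gene=%s)",
                        strsplit(d, "\r")[[1]][1], strsplit(d, "\r")[[1]][2],
                        strsplit(d, "\r")[[1]][3]))
  }
  rownames(df) <- NULL
  structure(df, tools = tools, class = c("hla_calls", "data.frame"))
}

#' @export
print.hla_calls <- function(x, ...) {
  cat(sprintf("<hla_calls> %d records | %d samples | %d tools | genes: %s\n",
              nrow(x), length(unique(x$sample_id)),
              length(unique(x$tool)), paste(sort(unique(x$gene)), collapse = " ")))
  NextMethod()
}

#' Read a call table from TSV
#'
#' Expects the interchange format
#' `sample_id<TAB>tool<TAB>gene<TAB>allele1<TAB>allele2` with a header.
#' Literal `NA` / empty allele cells give unavailable calls.
#'
#' @param path TSV file.
#' @inheritParams call_table
#' @return An `hla_calls` table.
#' @export
read_call_table <- function(path, tools = hla_tools(), allow_extra_tools = FALSE) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (!identical(names(df), .call_cols))
    stop_format(sprintf("malformed header in %s: got [%s], expected [%s]",
                        path, paste(names(df), collapse = ", "),
                        paste(.call_cols, collapse = ", ")))
  call_table(df, tools = tools, allow_extra_tools = allow_extra_tools)
}

#' Write a call table to TSV
#'
#' Lossless inverse of [read_call_table()] on the raw allele strings.
#'
#' @param x An `hla_calls` table.
#' @param path Output file.
#' @export
write_call_table <- function(x, path) {
  df <- as.data.frame(x)[.call_cols]
  df$allele1[is.na(df$allele1)] <- "NA"
  df$allele2[is.na(df$allele2)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read / write a reference genotype table
#'
#' PCR-SBT truth: one genotype per (sample, gene). Rows whose alleles are
#' ambiguous or below two-field resolution are retained until
#' [filter_reference_single_type()] is applied.
#'
#' @param df Data frame with columns `sample_id`, `gene`, `allele1`, `allele2`.
#' @return Object of class `hla_reference` (a data frame) with attribute
#'   `single_type_only` (logical).
#' @export
reference_table <- function(df) {
  if (!all(.ref_cols %in% names(df)))
    stop_format(sprintf("reference table needs columns %s",
                        paste(.ref_cols, collapse = ", ")))
  df <- as.data.frame(df)[.ref_cols]
  for (j in .ref_cols) df[[j]] <- as.character(df[[j]])
  .check_gene(df$gene)
  key <- paste(df$sample_id, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop_format(sprintf("duplicate reference record for (sample=%s, gene=%s)",
                        d[1], d[2]))
  }
  rownames(df) <- NULL
  structure(df, single_type_only = FALSE,
            class = c("hla_reference", "data.frame"))
}

#' @rdname reference_table
#' @param path TSV file `sample_id<TAB>gene<TAB>allele1<TAB>allele2`.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (!identical(names(df), .ref_cols))
    stop_format(sprintf("malformed header in %s: got [%s], expected [%s]",
                        path, paste(names(df), collapse = ", "),
                        paste(.ref_cols, collapse = ", ")))
  reference_table(df)
}

#' @rdname reference_table
#' @param x An `hla_reference` table.
#' @export
write_reference_table <- function(x, path) {
  df <- as.data.frame(x)[.ref_cols]
  df$allele1[is.na(df$allele1)] <- "NA"
  df$allele2[is.na(df$allele2)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only single-type reference genotypes
#'
#' Drops (sample, gene) reference rows whose genotype is not a single
#' unambiguous two-field type on both alleles — e.g. `/`-ambiguous PCR-SBT
#' results or missing alleles. This mirrors restricting the evaluation to
#' samples whose gold-standard genotype is one type. Idempotent.
#'
#' @param ref An `hla_reference` table.
#' @param gene Optionally restrict the filtering (and the returned rows) to
#'   one gene; by default all genes are filtered.
#' @param n_fields Resolution a reference allele must reach (default 2).
#' @return Filtered `hla_reference` with `single_type_only = TRUE`.
#' @export
filter_reference_single_type <- function(ref, gene = NULL, n_fields = 2L) {
  stopifnot(inherits(ref, "hla_reference"))
  keep <- !is.na(genotype_keys(ref, n_fields))
  if (!is.null(gene)) keep <- keep & ref$gene == gene
  out <- ref[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "single_type_only") <- TRUE
  out
}

.validate_fraction <- function(v, what) {
  v <- suppressWarnings(as.numeric(v))
  if (anyNA(v) || any(v < 0 | v > 100))
    stop_config(sprintf("%s values must be numeric in [0, 1] (or percent in (1, 100])", what))
  pct <- v > 1
  if (any(pct)) {
    message(sprintf("%s: %d value(s) > 1 interpreted as percentages and divided by 100",
                    what, sum(pct)))
    v[pct] <- v[pct] / 100
  }
  v
}

#' Read / write a per-tool accuracy matrix (model_acc.csv)
#'
#' Wide CSV: first column `tool`, one column per gene, cells are accuracies
#' as fractions in `[0, 1]` (percent-style values in `(1, 100]` are divided
#' by 100 with a notice).
#'
#' @param path CSV file.
#' @return Long data frame `(tool, gene, accuracy)` of class `hla_accuracy`.
#' @export
read_accuracy_csv <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "tool")
    stop_config(sprintf("accuracy CSV %s: first column must be 'tool'", path))
  genes <- names(df)[-1]
  .check_gene(genes)
  long <- data.frame(
    tool = rep(df$tool, times = length(genes)),
    gene = rep(genes, each = nrow(df)),
    accuracy = .validate_fraction(unlist(df[genes], use.names = FALSE),
                                  sprintf("accuracy CSV %s", path)),
    stringsAsFactors = FALSE
  )
  structure(long, class = c("hla_accuracy", "data.frame"))
}

#' @rdname read_accuracy_csv
#' @param x Long data frame `(tool, gene, accuracy)`.
#' @export
write_accuracy_csv <- function(x, path) {
  wide <- stats::reshape(as.data.frame(x)[c("tool", "gene", "accuracy")],
                         idvar = "tool", timevar = "gene", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pairwise correction-score matrix (cor_score.csv)
#'
#' Long CSV with columns `tool_a`, `tool_b`, `gene`, `score`, where `score`
#' is the correction score of B to A: among samples where tool A's available
#' call is wrong, the fraction tool B calls correctly. The diagonal
#' (`tool_a == tool_b`) is not allowed.
#'
#' @param path CSV file.
#' @return Data frame `(tool_a, tool_b, gene, score)` of class
#'   `hla_correction`.
#' @export
read_correction_csv <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("tool_a", "tool_b", "gene", "score")
  if (!all(need %in% names(df)))
    stop_config(sprintf("correction CSV %s needs columns %s", path,
                        paste(need, collapse = ", ")))
  df <- df[need]
  .check_gene(df$gene)
  if (any(df$tool_a == df$tool_b))
    stop_config(sprintf("correction CSV %s: diagonal entries (tool_a == tool_b) not allowed", path))
  df$score <- .validate_fraction(df$score, sprintf("correction CSV %s", path))
  structure(df, class = c("hla_correction", "data.frame"))
}

#' @rdname read_correction_csv
#' @param x Data frame `(tool_a, tool_b, gene, score)`.
#' @export
write_correction_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("tool_a", "tool_b", "gene", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write consensus decisions to TSV
#'
#' Output format:
#' `sample_id<TAB>gene<TAB>decision<TAB>allele1<TAB>allele2<TAB>n_agree<TAB>supporting_tools`
#' with `decision` either `CONSENSUS` (alleles filled) or
#' `Recommend PCR-SBT` (allele cells empty); `supporting_tools` is the
#' comma-joined sorted tool set.
#'
#' @param decisions Data frame as produced by [concordance()].
#' @param path Output file.
#' @export
write_decisions <- function(decisions, path) {
  df <- as.data.frame(decisions)
  rec <- df$decision != "CONSENSUS"
  df$allele1[rec] <- ""
  df$allele2[rec] <- ""
  cols <- c("sample_id", "gene", "decision", "allele1", "allele2",
            "n_agree", "supporting_tools")
  cols <- c(cols, intersect("combination_accuracy", names(df)))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
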