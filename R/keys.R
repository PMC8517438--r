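# Vectorized canonical keys over raw allele strings. This is the table-scale
# engine behind concordance and the metrics; its semantics are pinned to the
# object model in nomenclature.R (property-tested for agreement).

#' Vectorized allele keys
#'
#' Computes the canonical `"A*02:01"`-style key for each raw allele string at
#' `n_fields` resolution, or `NA` where the string is missing (`""`/`"NA"`),
#' `/`-ambiguous, unparseable, or typed below the resolution. Equivalent to
#' `parse_allele()` + truncation + formatting, but vectorized.
#'
#' @param raw Character vector of raw allele strings.
#' @param gene Character vector (recycled) of loci, used as gene hint.
#' @param n_fields Resolution (default 2).
#' @return Character vector of keys with `NA` for unavailable alleles.
#' @export
allele_keys <- function(raw, gene, n_fields = 2L) {
  n <- length(raw)
  gene <- rep_len(gene, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(raw) & nzchar(raw) & toupper(raw) != "NA" &
    !grepl("/", raw, fixed = TRUE)
  if (!any(ok)) return(out)

  x <- toupper(trimws(raw[ok]))
  x <- sub("^HLA-", "", x)
  x <- sub("^[ABC]\\*", "", x)
  x <- sub("([0-9])[NLSQCA]$", "\\1", x)
  toks <- strsplit(x, ":", fixed = TRUE)
  len <- lengths(toks)
  good <- len >= n_fields
  # fields matrix, fully vectorized: row i = first n_fields codes of allele i
  fm <- matrix(NA_character_, length(x), n_fields)
  idx <- rep(seq_along(toks), len)
  pos <- sequence(len)
  sel <- pos <= n_fields
  fm[cbind(idx[sel], pos[sel])] <- unlist(toks, use.names = FALSE)[sel]
  keys <- rep(NA_character_, length(x))
  if (any(good)) {
    sub_m <- fm[good, , drop = FALSE]
    valid <- rep(TRUE, nrow(sub_m))
    for (j in seq_len(n_fields)) {
      valid <- valid & grepl("^[0-9]+$", sub_m[, j])
      short <- valid & nchar(sub_m[, j]) < 2L
      sub_m[short, j] <- sprintf("%02d", as.integer(sub_m[short, j]))
    }
    joined <- do.call(paste, c(split(sub_m, col(sub_m)), sep = ":"))
    keys[good] <- ifelse(valid, joined, NA_character_)
  }
  out[ok] <- ifelse(is.na(keys), NA_character_,
                    paste0(sub("^HLA-", "", gene[ok]), "*", keys))
  out
}

#' Vectorized genotype keys for a call table
#'
#' Canonical order-insensitive genotype key per row (see [genotype_key()]);
#' `NA` where the call is unavailable at the resolution.
#'
#' @param x A call table ([call_table()]) or reference table.
#' @param n_fields Resolution (default 2).
#' @return Character vector, one key per row.
#' @export
genotype_keys <- function(x, n_fields = 2L) {
  k1 <- allele_keys(x$allele1, x$gene, n_fields)
  k2 <- allele_keys(x$allele2, x$gene, n_fields)
  ifelse(is.na(k1) | is.na(k2), NA_character_,
         paste(pmin(k1, k2), pmax(k1, k2), sep = "+"))
}

# samples x tools matrix of genotype keys for one gene.
.keys_matrix <- function(calls, gene, n_fields = 2L,
                         samples = NULL, tools = NULL) {
  rows <- calls[calls$gene == gene, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (is.null(tools)) tools <- attr(calls, "tools")
  m <- matrix(NA_character_, length(samples), length(tools),
              dimnames = list(samples, tools))
  if (nrow(rows)) {
    keep <- rows$sample_id %in% samples & rows$tool %in% tools
    rows <- rows[keep, , drop = FALSE]
    m[cbind(match(rows$sample_id, samples), match(rows$tool, tools))] <-
      genotype_keys(rows, n_fields)
  }
  m
}

# named vector sample_id -> reference genotype key for one gene (single-type
# references only).
.ref_keys <- function(ref, gene, n_fields = 2L) {
  ref <- filter_reference_single_type(ref, gene)
  rows <- ref[ref$gene == gene, , drop = FALSE]
  stats::setNames(genotype_keys(rows, n_fields), rows$sample_id)
}
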