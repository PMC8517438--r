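# Allele nomenclature: parsing, normalization, truncation and comparison of
# class I HLA allele strings at a fixed field resolution.

#' Class I HLA genes handled by the package
#'
#' @return Character vector `c("HLA-A", "HLA-B", "HLA-C")`.
#' @export
hla_genes <- function() c("HLA-A", "HLA-B", "HLA-C")

#' The default eight-tool typing panel
#'
#' The NGS HLA genotypers whose harmonized calls the consensus algorithm
#' combines. Order is alphabetical (case-insensitive) and is the canonical
#' panel order used throughout.
#'
#' @return Character vector of the eight tool names.
#' @export
hla_tools <- function() {
  c("arcasHLA", "HLA-HD", "HLA*LA", "HLAscan", "Kourami",
    "OptiType", "PHLAT", "seq2HLA")
}

# WHO expression-variant suffixes (null, low, secreted, questionable,
# cytoplasm, aberrant); carried on parse, ignored in comparison.
.hla_suffixes <- c("N", "L", "S", "Q", "C", "A")

.pad_field <- function(f) {
  short <- !is.na(f) & nchar(f) < 2L
  f[short] <- sprintf("%02d", as.integer(f[short]))
  f
}

#' Parse one HLA allele string
#'
#' Accepts the output dialects of the common typing tools: an optional
#' `HLA-` prefix, an optional `A*`/`B*`/`C*` locus prefix, colon-separated
#' numeric fields, an optional trailing expression suffix (N/L/S/Q/C/A), and
#' `/`-separated ambiguity tails such as `"03:01/05/06/50"`. Matching is
#' case-insensitive; field codes keep leading zeros and codes shorter than
#' two characters are left-padded (`"1"` -> `"01"`).
#'
#' An ambiguity tail with fewer fields than the base allele replaces the
#' trailing fields of the base: `"03:01/05"` expands to the alternative
#' `03:05`. Any allele carrying alternatives is treated as unavailable by
#' [is_available()], so the expansion convention affects display only.
#'
#' @param raw Allele string as emitted by a typing tool.
#' @param gene_hint Locus (`"HLA-A"`, `"HLA-B"` or `"HLA-C"`) used when `raw`
#'   lacks a locus prefix.
#' @return An object of class `hla_allele`: a list with elements `gene`,
#'   `fields` (character vector of field codes), `raw`, `alternatives`
#'   (list of alternative field vectors, empty when unambiguous) and
#'   `suffix` (`NA` or one expression-suffix character).
#' @examples
#' parse_allele("A*03:01:01:02")
#' parse_allele("03:01/05/06/50", gene_hint = "HLA-A")
#' @export
parse_allele <- function(raw, gene_hint = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop_parse("allele string must be a non-empty string", raw = raw)
  x <- toupper(trimws(raw))

  gene <- NA_character_
  x <- sub("^HLA-", "", x)
  m <- regmatches(x, regexec("^([ABC])\\*", x))[[1]]
  if (length(m)) {
    gene <- paste0("HLA-", m[2])
    x <- sub("^[ABC]\\*", "", x)
  } else if (!is.null(gene_hint)) {
    gene <- match.arg(toupper(gene_hint), hla_genes())
  }
  if (is.na(gene))
    stop_parse(sprintf("cannot resolve gene for allele '%s' (no prefix, no hint)", raw),
               raw = raw)

  segments <- strsplit(x, "/", fixed = TRUE)[[1]]
  segments <- segments[nzchar(segments)]
  if (!length(segments))
    stop_parse(sprintf("no allele fields in '%s'", raw), raw = raw)

  parse_fields <- function(seg) {
    suffix <- NA_character_
    if (grepl("[0-9][NLSQCA]$", seg)) {
      suffix <- substr(seg, nchar(seg), nchar(seg))
      seg <- substr(seg, 1L, nchar(seg) - 1L)
    }
    fields <- strsplit(seg, ":", fixed = TRUE)[[1]]
    if (!length(fields) || !all(grepl("^[0-9]+$", fields)))
      stop_parse(sprintf("non-numeric field in allele '%s'", raw), raw = raw)
    list(fields = .pad_field(fields), suffix = suffix)
  }

  base <- parse_fields(segments[1])
  alternatives <- list()
  if (length(segments) > 1L) {
    alternatives <- lapply(segments[-1], function(seg) {
      alt <- parse_fields(seg)$fields
      k <- length(alt)
      n <- length(base$fields)
      if (k < n) c(base$fields[seq_len(n - k)], alt) else alt
    })
  }

  structure(
    list(gene = gene, fields = base$fields, raw = raw,
         alternatives = alternatives, suffix = base$suffix),
    class = "hla_allele"
  )
}

#' Format an allele back to nomenclature form
#'
#' Inverse of [parse_allele()] for the base allele: `parse(format(parse(x)))`
#' recovers the same gene, fields and suffix. Ambiguity tails are re-attached
#' as second-field alternatives when present.
#'
#' @param a An `hla_allele`.
#' @param n_fields Optional resolution; when given the allele is truncated
#'   first.
#' @return A string such as `"A*03:01"`.
#' @export
format_allele <- function(a, n_fields = NULL) {
  stopifnot(inherits(a, "hla_allele"))
  if (!is.null(n_fields)) a <- truncate_allele(a, n_fields)
  out <- paste0(sub("^HLA-", "", a$gene), "*", paste(a$fields, collapse = ":"))
  if (!is.na(a$suffix)) out <- paste0(out, a$suffix)
  if (length(a$alternatives)) {
    tails <- vapply(a$alternatives, function(f) f[length(f)], character(1))
    out <- paste(c(out, tails), collapse = "/")
  }
  out
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele>", format_allele(x))
  if (length(x$alternatives)) cat(" [ambiguous]")
  cat("\n")
  invisible(x)
}

#' Truncate an allele to a fixed number of fields
#'
#' Reduces the allele (and any ambiguity alternatives) to its first
#' `min(n_fields, length(fields))` fields. Idempotent; never pads.
#'
#' @param a An `hla_allele`.
#' @param n_fields Resolution, at least 1. Two fields is the four-digit
#'   (protein-level) resolution used throughout.
#' @return The truncated `hla_allele`.
#' @export
truncate_allele <- function(a, n_fields) {
  stopifnot(inherits(a, "hla_allele"), n_fields >= 1L)
  a$fields <- a$fields[seq_len(min(n_fields, length(a$fields)))]
  a$alternatives <- lapply(a$alternatives, function(f)
    f[seq_len(min(n_fields, length(f)))])
  a
}

#' Construct a genotype call
#'
#' An unordered pair of allele calls for one sample/tool/gene. Either allele
#' may be `NULL` (tool emitted nothing for that chromosome).
#'
#' @param allele1,allele2 `hla_allele` objects, raw strings (parsed with
#'   `gene` as hint), or `NULL`/`NA` for a missing call.
#' @param sample_id,tool,gene Identifying metadata; `gene` doubles as the
#'   parse hint for raw strings.
#' @return An object of class `hla_genotype`.
#' @export
hla_genotype <- function(allele1, allele2, sample_id = NA_character_,
                         tool = NA_character_, gene = NA_character_) {
  as_allele <- function(a) {
    if (is.null(a) || (length(a) == 1L && is.na(a))) return(NULL)
    if (inherits(a, "hla_allele")) return(a)
    if (is.character(a)) {
      if (!nzchar(a) || toupper(a) == "NA") return(NULL)
      return(parse_allele(a, gene_hint = if (is.na(gene)) NULL else gene))
    }
    stop_parse("allele must be an hla_allele, a string, or NULL")
  }
  a1 <- as_allele(allele1)
  a2 <- as_allele(allele2)
  g <- gene
  if (is.na(g) && !is.null(a1)) g <- a1$gene
  structure(
    list(sample_id = sample_id, tool = tool, gene = g,
         alleles = list(a1, a2)),
    class = "hla_genotype"
  )
}

#' @export
print.hla_genotype <- function(x, ...) {
  fmt <- vapply(x$alleles, function(a)
    if (is.null(a)) "NA" else format_allele(a), character(1))
  cat(sprintf("<hla_genotype> %s %s %s: %s / %s\n",
              x$sample_id, x$tool, x$gene, fmt[1], fmt[2]))
  invisible(x)
}

#' Is a genotype call available at a given resolution?
#'
#' A call is available when the tool presented exactly one unambiguous
#' prediction for both alleles, each carrying at least `n_fields` fields.
#' Missing alleles, `/`-ambiguous alleles, and alleles typed below the
#' comparison resolution (e.g. a two-digit `B*07`) all make the call
#' unavailable.
#'
#' @param g An `hla_genotype`.
#' @param n_fields Comparison resolution (default 2, i.e. four-digit).
#' @return Logical scalar.
#' @export
is_available <- function(g, n_fields = 2L) {
  stopifnot(inherits(g, "hla_genotype"))
  all(vapply(g$alleles, function(a) {
    !is.null(a) && length(a$alternatives) == 0L && length(a$fields) >= n_fields
  }, logical(1)))
}

# Canonical string key for one allele at a resolution; assumes enough fields.
.allele_key <- function(a, n_fields) {
  paste0(sub("^HLA-", "", a$gene), "*",
         paste(a$fields[seq_len(n_fields)], collapse = ":"))
}

#' Canonical genotype key
#'
#' Order-insensitive string key for an available genotype at `n_fields`
#' resolution, e.g. `"A*02:01+A*24:02"`; `NA` for unavailable calls. Two
#' genotypes are equal iff their keys are equal, with multiset semantics
#' (a homozygous pair differs from any heterozygous pair).
#'
#' @param g An `hla_genotype`.
#' @param n_fields Comparison resolution.
#' @return Character scalar or `NA`.
#' @export
genotype_key <- function(g, n_fields = 2L) {
  if (!is_available(g, n_fields)) return(NA_character_)
  ks <- vapply(g$alleles, .allele_key, character(1), n_fields = n_fields)
  paste(sort(ks, method = "radix"), collapse = "+")
}

#' Compare two genotype calls at a fixed resolution
#'
#' True iff the unordered allele pairs are equal as multisets after
#' truncation to `n_fields` fields. Symmetric and reflexive on available
#' genotypes; expression suffixes are ignored.
#'
#' @param g1,g2 Available `hla_genotype` objects.
#' @param n_fields Comparison resolution.
#' @return Logical scalar.
#' @export
genotype_equal <- function(g1, g2, n_fields = 2L) {
  if (!is_available(g1, n_fields) || !is_available(g2, n_fields))
    stop_contract("genotype_equal requires both genotypes available at the comparison resolution")
  identical(genotype_key(g1, n_fields), genotype_key(g2, n_fields))
}
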