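# Independent oracles and random-table generators for property tests. These
# deliberately use the slow object model (parse_allele / hla_genotype /
# genotype_equal) and naive per-sample loops, never the vectorized key path
# they are checking.

# random raw allele string from a small pool, with missing/ambiguous noise
random_allele <- function(gene, pool_size = 6L, p_missing = 0.1,
                          p_ambiguous = 0.1) {
  u <- runif(1)
  if (u < p_missing) return(NA_character_)
  base <- sprintf("%s*%02d:%02d", sub("HLA-", "", gene),
                  sample.int(pool_size, 1), sample.int(3L, 1))
  if (u < p_missing + p_ambiguous)
    return(paste0(base, "/", sprintf("%02d", sample(50:60, 1))))
  base
}

# one random sample x gene slice: a call row per tool
random_calls_one <- function(sample_id, gene, tools = hla_tools(), ...) {
  data.frame(
    sample_id = sample_id, tool = tools, gene = gene,
    allele1 = vapply(tools, function(t) random_allele(gene, ...), character(1)),
    allele2 = vapply(tools, function(t) random_allele(gene, ...), character(1)),
    stringsAsFactors = FALSE
  )
}

random_call_table <- function(n_samples, gene = "HLA-A", ...) {
  rows <- lapply(seq_len(n_samples), function(i)
    random_calls_one(sprintf("R%04d", i), gene, ...))
  call_table(do.call(rbind, rows))
}

random_reference <- function(calls, gene, pool_size = 6L) {
  samples <- sort(unique(calls$sample_id))
  reference_table(data.frame(
    sample_id = samples, gene = gene,
    allele1 = sprintf("%s*%02d:%02d", sub("HLA-", "", gene),
                      sample(pool_size, length(samples), TRUE),
                      sample(3L, length(samples), TRUE)),
    allele2 = sprintf("%s*%02d:%02d", sub("HLA-", "", gene),
                      sample(pool_size, length(samples), TRUE),
                      sample(3L, length(samples), TRUE)),
    stringsAsFactors = FALSE))
}

# brute-force modal call: pairwise genotype_equal over parsed objects,
# exhaustive class construction, lexicographic tie-break on canonical keys
oracle_modal <- function(rows, n_fields = 2L) {
  gts <- lapply(seq_len(nrow(rows)), function(i)
    hla_genotype(rows$allele1[i], rows$allele2[i], rows$sample_id[i],
                 rows$tool[i], rows$gene[i]))
  avail <- vapply(gts, is_available, logical(1), n_fields = n_fields)
  idx <- which(avail)
  if (!length(idx))
    return(list(n_agree = 0L, n_available = 0L, modal_key = NA_character_,
                supporting = character(0), tie = FALSE))
  classes <- list()
  for (i in idx) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      if (genotype_equal(gts[[i]], gts[[classes[[k]][1]]], n_fields)) {
        classes[[k]] <- c(classes[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- i
  }
  sizes <- lengths(classes)
  top <- which(sizes == max(sizes))
  keys <- vapply(top, function(k)
    genotype_key(gts[[classes[[k]][1]]], n_fields), character(1))
  win <- top[order(keys, method = "radix")][1]
  list(n_agree = max(sizes), n_available = length(idx),
       modal_key = genotype_key(gts[[classes[[win]][1]]], n_fields),
       supporting = sort(rows$tool[classes[[win]]], method = "radix"),
       tie = length(top) > 1L)
}

# brute-force correction score: per-sample loop over parsed objects
oracle_correction <- function(calls, ref, gene, tool_b, tool_a, n_fields = 2L) {
  reff <- filter_reference_single_type(ref, gene)
  num <- den <- 0L
  for (s in unique(reff$sample_id)) {
    rrow <- reff[reff$sample_id == s & reff$gene == gene, ]
    if (!nrow(rrow)) next
    rg <- hla_genotype(rrow$allele1, rrow$allele2, s, "REFERENCE", gene)
    grab <- function(tool) {
      row <- calls[calls$sample_id == s & calls$tool == tool & calls$gene == gene, ]
      if (!nrow(row)) return(NULL)
      g <- hla_genotype(row$allele1, row$allele2, s, tool, gene)
      if (is_available(g, n_fields)) g else NULL
    }
    ga <- grab(tool_a)
    if (is.null(ga) || genotype_equal(ga, rg, n_fields)) next
    den <- den + 1L
    gb <- grab(tool_b)
    if (!is.null(gb) && genotype_equal(gb, rg, n_fields)) num <- num + 1L
  }
  if (den == 0L) NA_real_ else num / den
}

# random feasible group spec
random_group_spec <- function(gene = "HLA-A") {
  sizes <- sample(5:8, sample(1:4, 1))
  blocks <- data.frame(size = sizes,
                       n_true = sample(0:20, length(sizes), TRUE),
                       n_false = sample(0:5, length(sizes), TRUE))
  blocks <- blocks[blocks$n_true + blocks$n_false > 0, , drop = FALSE]
  if (!nrow(blocks))
    blocks <- data.frame(size = 6L, n_true = 3L, n_false = 1L)
  group_spec(gene, sum(blocks$n_true + blocks$n_false) + sample(0:10, 1), blocks)
}
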