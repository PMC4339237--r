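# ---------------------------------------------------------------------------
# Structural comparison of gene models: symbol-set Venn decomposition,
# per-gene definition differences across models, and within-model gene
# relations (nesting / shared identical transcripts / partial overlap).
# ---------------------------------------------------------------------------

#' Symbol-set Venn decomposition of 2-3 gene models
#'
#' Decomposes the union of gene symbols by membership pattern. Regions are
#' computed on symbols only (assumed already harmonized, e.g. to HGNC), not
#' on coordinates.
#'
#' @param models List of 2 or 3 `gene_model`s; list names (or the models'
#'   own names) label the regions.
#' @return Object of class `venn_decomposition`: `models` (names), `regions`
#'   (named list of symbol sets keyed by membership pattern like `"A&B"`)
#'   and `counts`.
#' @export
symbol_overlap <- function(models) {
  if (!is.list(models) || length(models) < 2L || length(models) > 3L)
    stop("symbol_overlap requires a list of 2 or 3 gene models")
  nms <- names(models)
  if (is.null(nms) || any(nms == ""))
    nms <- vapply(models, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("model names must be unique")
  sets <- lapply(models, gene_symbols)
  all_syms <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_syms %in% s,
                       logical(length(all_syms)))
  if (length(all_syms) == 1L) membership <- matrix(membership, nrow = 1L)
  # every non-empty membership pattern, in subset order
  pats <- lapply(seq_len(2^length(models) - 1L), function(code) {
    as.logical(bitwAnd(code, 2^(seq_along(models) - 1L)))
  })
  regions <- lapply(pats, function(p) {
    if (length(all_syms) == 0L) return(character(0))
    sel <- apply(membership, 1L, function(row) all(row == p))
    sort(all_syms[sel])
  })
  # canonical (sorted) region labels so they are model-order invariant
  names(regions) <- vapply(pats, function(p)
    paste(sort(nms[p]), collapse = "&"), "")
  structure(list(models = nms, regions = regions,
                 counts = vapply(regions, length, 0L)),
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat("Venn decomposition of models:", paste(x$models, collapse = ", "), "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write a Venn decomposition to JSON
#' @param venn A `venn_decomposition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(venn, path) {
  jsonlite::write_json(list(models = venn$models, counts = as.list(venn$counts),
                            regions = venn$regions),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# canonical structural signature of a transcript (ignores the transcript id)
.tx_struct <- function(tx) {
  paste(tx$chrom, tx$strand,
        paste(tx$exons$start, tx$exons$end, sep = "-", collapse = ","),
        sep = ":")
}

.gene_struct_set <- function(g) sort(unique(vapply(g$transcripts, .tx_struct, "")))

#' Compare one gene's definition across two models
#'
#' Categories: `identical` when the two genes' transcript sets are
#' structurally equal (same exon coordinate lists, transcript ids ignored);
#' `absent_chromosome` when either definition uses a chromosome outside
#' `genome_chroms` (the assembly-patch case — such a gene can receive no
#' reads on this genome); otherwise `span_or_exon_differs`.
#'
#' @param gene_in_a,gene_in_b The same-symbol `gene` in each model.
#' @param genome_chroms Character vector of chromosome names present in the
#'   genome.
#' @return Object of class `gene_diff_record`: `symbol`, `category`,
#'   `span_a`, `span_b` (data frames from [gene_span()]), `n_tx_a`, `n_tx_b`.
#' @export
cross_model_gene_diff <- function(gene_in_a, gene_in_b, genome_chroms) {
  if (gene_in_a$symbol != gene_in_b$symbol)
    stop("cross_model_gene_diff requires the same symbol in both models")
  chroms <- unique(c(gene_span(gene_in_a)$chrom, gene_span(gene_in_b)$chrom))
  category <- if (identical(.gene_struct_set(gene_in_a),
                            .gene_struct_set(gene_in_b))) "identical"
  else if (!all(chroms %in% genome_chroms)) "absent_chromosome"
  else "span_or_exon_differs"
  structure(list(symbol = gene_in_a$symbol, category = category,
                 span_a = gene_span(gene_in_a), span_b = gene_span(gene_in_b),
                 n_tx_a = length(gene_in_a$transcripts),
                 n_tx_b = length(gene_in_b$transcripts)),
            class = "gene_diff_record")
}

#' Per-symbol definition-difference table for two models
#'
#' Applies [cross_model_gene_diff()] to every shared symbol and labels
#' symbols present in only one model `missing_in_one_model`.
#'
#' @param model_a,model_b `gene_model`s.
#' @param genome_chroms Chromosome names present in the genome.
#' @return Data frame: `symbol`, `category`, `span_a`, `span_b`
#'   (chrom:start-end strings, `NA` when missing).
#' @export
model_diff_table <- function(model_a, model_b, genome_chroms) {
  syms <- sort(union(gene_symbols(model_a), gene_symbols(model_b)))
  span_str <- function(g) {
    sp <- gene_span(g)
    paste(sprintf("%s:%d-%d", sp$chrom, sp$start, sp$end), collapse = ";")
  }
  rows <- lapply(syms, function(s) {
    in_a <- s %in% gene_symbols(model_a)
    in_b <- s %in% gene_symbols(model_b)
    if (in_a && in_b) {
      d <- cross_model_gene_diff(model_a$genes[[s]], model_b$genes[[s]],
                                 genome_chroms)
      data.frame(symbol = s, category = d$category,
                 span_a = span_str(model_a$genes[[s]]),
                 span_b = span_str(model_b$genes[[s]]))
    } else {
      data.frame(symbol = s, category = "missing_in_one_model",
                 span_a = if (in_a) span_str(model_a$genes[[s]]) else NA,
                 span_b = if (in_b) span_str(model_b$genes[[s]]) else NA)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a model diff table as TSV
#' @param diff Data frame from [model_diff_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diff_tsv <- function(diff, path) {
  write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# genes whose exonic footprints overlap (same chromosome, any exon overlap)
.exonic_overlap_pairs <- function(model) {
  ex <- do.call(rbind, lapply(model$genes, function(g)
    do.call(rbind, lapply(g$transcripts, function(tx)
      data.frame(symbol = g$symbol, chrom = tx$chrom,
                 start = tx$exons$start, end = tx$exons$end)))))
  pairs <- list()
  syms <- gene_symbols(model)
  if (length(syms) < 2L) return(pairs)
  for (i in seq_len(length(syms) - 1L)) for (j in (i + 1L):length(syms)) {
    a <- ex[ex$symbol == syms[i], , drop = FALSE]
    b <- ex[ex$symbol == syms[j], , drop = FALSE]
    hit <- FALSE
    for (k in seq_len(nrow(a))) {
      o <- b$chrom == a$chrom[k] & b$start <= a$end[k] & b$end >= a$start[k]
      if (any(o)) { hit <- TRUE; break }
    }
    if (hit) pairs[[length(pairs) + 1L]] <- c(syms[i], syms[j])
  }
  pairs
}

#' Relations between overlapping genes within one model
#'
#' For every pair of genes with overlapping exonic positions:
#' `identical_transcripts` when their transcript sets are structurally equal
#' (the shared-bicistronic-mRNA situation — reads can never distinguish the
#' two genes); `nested_no_unique_region` when one gene has no read-length
#' window compatible with it alone (every read it can produce is also a
#' window of the other gene, so it can receive no unique reads);
#' `partial_overlap` otherwise.
#'
#' @param model A `gene_model`.
#' @param read_length Window length used to decide "unique region" (>= 1).
#' @return Data frame: `symbol_a`, `symbol_b`, `relation`, `nested_symbol`
#'   (`NA` unless nested). Zero rows when no genes overlap.
#' @export
within_model_relations <- function(model, read_length) {
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  pairs <- .exonic_overlap_pairs(model)
  empty <- data.frame(symbol_a = character(0), symbol_b = character(0),
                      relation = character(0), nested_symbol = character(0))
  if (length(pairs) == 0L) return(empty)
  idx <- build_window_index(model, read_length)
  rows <- lapply(pairs, function(p) {
    ga <- model$genes[[p[1L]]]; gb <- model$genes[[p[2L]]]
    if (identical(.gene_struct_set(ga), .gene_struct_set(gb))) {
      data.frame(symbol_a = p[1L], symbol_b = p[2L],
                 relation = "identical_transcripts",
                 nested_symbol = NA_character_)
    } else if (!idx$has_unique[[p[1L]]] || !idx$has_unique[[p[2L]]]) {
      nested <- p[c(!idx$has_unique[[p[1L]]], !idx$has_unique[[p[2L]]])]
      data.frame(symbol_a = p[1L], symbol_b = p[2L],
                 relation = "nested_no_unique_region",
                 nested_symbol = paste(nested, collapse = ","))
    } else {
      data.frame(symbol_a = p[1L], symbol_b = p[2L],
                 relation = "partial_overlap", nested_symbol = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
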