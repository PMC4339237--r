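# ---------------------------------------------------------------------------
# Gene-level counting with ambiguity rules, and annotation-concordance
# statistics (count-ratio distribution, log2 fold-change concordance).
# ---------------------------------------------------------------------------

# Enumerate the genomic block signature ("chrom:s1-e1,s2-e2,...") of every
# length-L window of a transcript, in offset order. Vectorized per
# (first exon, last exon) run; equivalent to calling project_to_genome at
# every offset (property-tested against it).
.window_signatures <- function(tx, L) {
  sl <- spliced_length(tx)
  if (L > sl) return(character(0))
  lay <- .tx_layout(tx)
  n_off <- sl - L + 1L
  off <- seq_len(n_off) - 1L
  i1 <- findInterval(off, lay$tx_start)
  i2 <- findInterval(off + L - 1L, lay$tx_start)
  out <- character(n_off)
  for (g in split(seq_len(n_off), paste(i1, i2))) {
    a <- i1[g[1L]]; b <- i2[g[1L]]
    o <- off[g]
    d_first <- o - lay$tx_start[a]                  # offset into first exon
    d_last <- (o + L - 1L) - lay$tx_start[b]        # offset into last exon
    if (tx$strand == "+") {
      first_start <- lay$start[a] + d_first
      last_end <- lay$start[b] + d_last
      if (a == b) {
        seg <- paste0(first_start, "-", last_end)
      } else {
        mid <- if (b - a > 1L)
          paste0(paste0(lay$start[(a + 1L):(b - 1L)], "-",
                        lay$end[(a + 1L):(b - 1L)], ","), collapse = "")
        else ""
        seg <- paste0(first_start, "-", lay$end[a], ",", mid,
                      lay$start[b], "-", last_end)
      }
    } else {
      # layout order is descending genomic; ascending blocks are reversed
      first_end <- lay$end[a] - d_first               # highest coordinate
      last_start <- lay$end[b] - d_last               # lowest coordinate
      if (a == b) {
        seg <- paste0(last_start, "-", first_end)
      } else {
        mid <- if (b - a > 1L)
          paste0(paste0(lay$start[(b - 1L):(a + 1L)], "-",
                        lay$end[(b - 1L):(a + 1L)], ","), collapse = "")
        else ""
        seg <- paste0(last_start, "-", lay$end[b], ",", mid,
                      lay$start[a], "-", first_end)
      }
    }
    out[g] <- paste0(tx$chrom, ":", seg)
  }
  out
}

#' Index of all read-length windows of a model
#'
#' For each distinct genomic block signature reachable as a length-`L`
#' window of some transcript, records the set of gene symbols compatible
#' with it; also records, per gene, whether it owns at least one window
#' compatible with it alone (a "unique region"). Strand is ignored
#' (unstranded library). Built once and reused by [count_reads()] and
#' [within_model_relations()].
#'
#' @param model A `gene_model`.
#' @param L Window (read) length.
#' @return List with `genes_of` (environment: signature -> symbol vector)
#'   and `has_unique` (named logical per gene symbol).
#' @export
build_window_index <- function(model, L) {
  L <- as.integer(L)
  sig2genes <- new.env(parent = emptyenv())
  for (g in model$genes) {
    for (tx in g$transcripts) {
      for (s in unique(.window_signatures(tx, L))) {
        cur <- sig2genes[[s]]
        if (is.null(cur)) sig2genes[[s]] <- g$symbol
        else if (!g$symbol %in% cur) sig2genes[[s]] <- c(cur, g$symbol)
      }
    }
  }
  has_unique <- setNames(logical(length(model$genes)), gene_symbols(model))
  for (s in ls(sig2genes)) {
    gs <- sig2genes[[s]]
    if (length(gs) == 1L) has_unique[[gs]] <- TRUE
  }
  list(genes_of = sig2genes, has_unique = has_unique, L = L)
}

#' Genes compatible with an alignment
#'
#' The symbols of genes having at least one transcript for which the
#' alignment's blocks equal the projection of some transcript window.
#' An empty set means the placement is unannotated.
#'
#' @param alignment An `alignment` (from a `mapping_result`), or a list/data
#'   frame with `chrom` and `blocks` (data frame with `start`, `end`).
#' @param model A `gene_model`.
#' @return Character vector of gene symbols (possibly empty).
#' @export
compatible_genes <- function(alignment, model) {
  blocks <- alignment$blocks
  chrom <- if (!is.null(alignment$chrom)) alignment$chrom else blocks$chrom[1L]
  out <- character(0)
  for (g in model$genes) {
    for (tx in g$transcripts) {
      if (tx$chrom != chrom) next
      if (!is.na(transcript_window_of(tx, blocks))) {
        out <- c(out, g$symbol)
        break
      }
    }
  }
  sort(unique(out))
}

#' Construct a count table
#'
#' @param counts Named numeric vector (gene symbol -> fractional count).
#' @param model_name Annotation name.
#' @param sample_name Sample label.
#' @return Object of class `count_table`: data frame `symbol`, `count` with
#'   attributes `model` and `sample`.
#' @export
count_table <- function(counts, model_name = "model", sample_name = "sample") {
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(data.frame(symbol = names(counts), count = as.numeric(counts),
                       row.names = NULL),
            model = model_name, sample = sample_name,
            class = c("count_table", "data.frame"))
}

#' Count uniquely mapped reads per gene with ambiguity rules
#'
#' For each unique alignment with compatible gene set `G`: nothing is counted
#' when `G` is empty (unannotated placement); the single gene gets +1 when
#' `|G| = 1`; when `|G| >= 2`, let `U` be the genes of `G` that possess at
#' least one read-length window compatible with them alone — if `U` is
#' non-empty each gene of `U` gets `1/|U|`, otherwise each gene of `G` gets
#' `1/|G|`. Hence a gene fully nested inside another (no unique region)
#' receives zero while its container takes all shared reads, and two genes
#' sharing one identical transcript split every read 50/50. Fractional
#' counts are kept exact.
#'
#' @param unique_alignments A `mapping_batch` (its uniquely mapped reads are
#'   used; an error is raised if none), or a data frame with one row per
#'   read: `read_id`, `chrom`, `blocks` (block string `"s1-e1,s2-e2"`).
#' @param model A `gene_model`.
#' @param read_length Read length defining the uniqueness windows.
#' @param sample_name Sample label recorded on the table.
#' @return A [count_table()] covering every gene of the model (zeros kept),
#'   with attribute `n_counted` = number of alignments with `|G| >= 1`.
#' @export
count_reads <- function(unique_alignments, model, read_length,
                        sample_name = "sample") {
  if (inherits(unique_alignments, "mapping_batch")) {
    uniq <- names(unique_alignments$ml)[unique_alignments$ml == 1L]
    aln <- unique_alignments$hits[
      unique_alignments$hits$read_id %in% uniq, , drop = FALSE]
  } else {
    aln <- as.data.frame(unique_alignments)
    if (anyDuplicated(aln$read_id))
      stop("count_reads requires uniquely mapped reads ",
           "(duplicate read_id implies #ML > 1)")
  }
  idx <- build_window_index(model, read_length)
  counts <- setNames(numeric(length(model$genes)), gene_symbols(model))
  n_counted <- 0L
  if (nrow(aln)) {
    sigs <- paste0(aln$chrom, ":", aln$blocks)
    for (s in sigs) {
      G <- idx$genes_of[[s]]
      if (is.null(G)) next
      n_counted <- n_counted + 1L
      if (length(G) == 1L) {
        counts[[G]] <- counts[[G]] + 1
      } else {
        U <- G[idx$has_unique[G]]
        tgt <- if (length(U)) U else G
        counts[tgt] <- counts[tgt] + 1 / length(tgt)
      }
    }
  }
  out <- count_table(counts, model$name, sample_name)
  attr(out, "n_counted") <- n_counted
  out
}

#' Concordance ratio of two counts
#'
#' `max(c1 + 1, c2 + 1) / min(c1 + 1, c2 + 1)`; the +1 pseudocount prevents
#' division by zero, so the ratio is always >= 1 and symmetric.
#'
#' @param c1,c2 Non-negative counts (vectorized).
#' @return Numeric ratio(s) >= 1.
#' @export
ratio <- function(c1, c2) {
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  pmax(c1 + 1, c2 + 1) / pmin(c1 + 1, c2 + 1)
}

#' Default ratio thresholds of the concordance table
#' @return Numeric vector `c(1.05, 1.10, 1.20, 1.50, 2, 5, 10, 100)`.
#' @export
default_ratio_thresholds <- function() c(1.05, 1.10, 1.20, 1.50, 2, 5, 10, 100)

#' Count-ratio concordance between two annotations
#'
#' Over the symbol intersection of the two tables: `no_expr` is the
#' percentage of genes with zero counts in both; `same` the percentage with
#' equal counts not both zero (both-zero genes are counted in `no_expr`
#' only); each threshold column is the (cumulative) percentage of common
#' genes whose ratio is `>=` that threshold.
#'
#' @param table_a,table_b [count_table()]s.
#' @param thresholds Ascending ratio thresholds.
#' @return One-row data frame of class `concordance_row`: `no_expr`, `same`,
#'   then one `ge_<t>` column per threshold (percentages rounded to 0.01),
#'   with attributes `n_common` and `fractions` (unrounded proportions).
#' @export
concordance_table <- function(table_a, table_b,
                              thresholds = default_ratio_thresholds()) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  common <- intersect(table_a$symbol, table_b$symbol)
  if (length(common) == 0L)
    stop("the two count tables share no gene symbols")
  ca <- table_a$count[match(common, table_a$symbol)]
  cb <- table_b$count[match(common, table_b$symbol)]
  n <- length(common)
  no_expr <- ca == 0 & cb == 0
  same <- ca == cb & !no_expr
  r <- ratio(ca, cb)
  fr <- c(no_expr = mean(no_expr), same = mean(same),
          setNames(vapply(thresholds, function(t) mean(r >= t), 0),
                   paste0("ge_", thresholds)))
  out <- as.data.frame(as.list(round_half_up(100 * fr, 2L)))
  attr(out, "n_common") <- n
  attr(out, "fractions") <- fr
  class(out) <- c("concordance_row", "data.frame")
  out
}

#' Log2 fold change with +1 pseudocount
#'
#' `log2((c1 + 1) / (c2 + 1))`; antisymmetric in its arguments.
#' @param count_sample1,count_sample2 Non-negative counts (vectorized).
#' @return Numeric log2 ratio(s).
#' @export
log2_ratio <- function(count_sample1, count_sample2) {
  if (any(count_sample1 < 0) || any(count_sample2 < 0))
    stop("counts must be non-negative")
  log2((count_sample1 + 1) / (count_sample2 + 1))
}

#' Fold-change concordance between two annotations
#'
#' Computes each gene's log2 fold change between two samples under each
#' annotation and counts genes whose two fold changes differ (in absolute
#' value) by more than 1, 2 and 5.
#'
#' @param table_a_s1,table_a_s2 [count_table()]s for samples 1 and 2 under
#'   annotation A.
#' @param table_b_s1,table_b_s2 The same two samples under annotation B.
#' @return Object of class `de_concordance`: `per_gene` (data frame `symbol`,
#'   `log2ratio_a`, `log2ratio_b`, `abs_diff`) and `counts` (named integer
#'   vector `gt1`, `gt2`, `gt5`).
#' @export
de_concordance <- function(table_a_s1, table_a_s2, table_b_s1, table_b_s2) {
  common <- Reduce(intersect, list(table_a_s1$symbol, table_a_s2$symbol,
                                   table_b_s1$symbol, table_b_s2$symbol))
  if (length(common) == 0L) stop("no common gene symbols across the tables")
  get <- function(tb) tb$count[match(common, tb$symbol)]
  lr_a <- log2_ratio(get(table_a_s1), get(table_a_s2))
  lr_b <- log2_ratio(get(table_b_s1), get(table_b_s2))
  d <- abs(lr_a - lr_b)
  structure(list(
    per_gene = data.frame(symbol = common, log2ratio_a = lr_a,
                          log2ratio_b = lr_b, abs_diff = d),
    counts = c(gt1 = sum(d > 1), gt2 = sum(d > 2), gt5 = sum(d > 5))),
    class = "de_concordance")
}

#' @export
print.de_concordance <- function(x, ...) {
  cat(sprintf("de_concordance over %d genes: |diff|>1: %d, >2: %d, >5: %d\n",
              nrow(x$per_gene), x$counts[["gt1"]], x$counts[["gt2"]],
              x$counts[["gt5"]]))
  invisible(x)
}

#' Write a count table as TSV
#'
#' Counts are rendered at 2 decimals (fractional halves from equal splits);
#' the underlying object keeps them exact.
#' @param tb A [count_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(tb, path) {
  out <- data.frame(symbol = tb$symbol, count = sprintf("%.2f", tb$count))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a concordance row as one-row TSV
#'
#' Column order: `no_expr`, `same` (genes with equal, not both-zero counts;
#' both-zero genes are reported under `no_expr` only), then the cumulative
#' ratio-threshold columns.
#' @param row A `concordance_row`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(row, path) {
  write.table(as.data.frame(row), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
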