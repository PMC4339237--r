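#' @useDynLib annoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames rnorm rbinom
NULL

# ---------------------------------------------------------------------------
# Domain types. Coordinates are GTF-style: 1-based, inclusive on both ends.
# ---------------------------------------------------------------------------

#' Create a genomic interval
#'
#' Intervals follow the GTF convention: 1-based, both ends inclusive, so the
#' length of an interval is `end - start + 1`.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' span_length(genomic_interval("chr7", 135612022, 135612198, "-"))
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L)
    stop("interval start must be >= 1")
  if (end < start) stop("interval end must be >= start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Length of a genomic interval
#'
#' @param x A `genomic_interval`, or a data frame with `start`/`end` columns
#'   (one length per row).
#' @return Integer length(s), `end - start + 1`.
#' @export
span_length <- function(x) {
  if (inherits(x, "genomic_interval")) return(x$end - x$start + 1L)
  if (is.data.frame(x)) return(as.integer(x$end) - as.integer(x$start) + 1L)
  stop("span_length expects a genomic_interval or a data frame")
}

#' Create a transcript
#'
#' @param id Transcript identifier.
#' @param gene_symbol Gene symbol the transcript belongs to.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with integer `start`, `end` columns (1-based
#'   inclusive). Exons must be pairwise non-overlapping; they are stored in
#'   ascending genomic order.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, gene_symbol, chrom, strand, exons) {
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  if (any(exons$start < 1L) || any(exons$end < exons$start))
    stop("invalid exon coordinates in transcript '", id, "'")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript '", id, "'")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(id = as.character(id),
                 gene_symbol = as.character(gene_symbol),
                 chrom = as.character(chrom), strand = strand, exons = exons),
            class = "transcript")
}

#' Spliced (mRNA) length of a transcript
#' @param tx A `transcript`.
#' @return Sum of its exon lengths.
#' @export
spliced_length <- function(tx) sum(span_length(tx$exons))

#' Create a gene
#' @param symbol Gene symbol.
#' @param transcripts Non-empty list of `transcript`s sharing the symbol.
#' @return An object of class `gene`.
#' @export
gene <- function(symbol, transcripts) {
  if (length(transcripts) == 0L) stop("gene must have at least one transcript")
  syms <- vapply(transcripts, `[[`, "", "gene_symbol")
  if (!all(syms == symbol))
    stop("all transcripts of '", symbol, "' must carry its symbol")
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(list(symbol = as.character(symbol), transcripts = transcripts),
            class = "gene")
}

#' Genomic span of a gene on each chromosome it touches
#' @param g A `gene`.
#' @return Data frame with `chrom`, `start`, `end` (one row per chromosome).
#' @export
gene_span <- function(g) {
  ex <- do.call(rbind, lapply(g$transcripts, function(tx)
    data.frame(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end)))
  out <- do.call(rbind, lapply(split(ex, ex$chrom), function(d)
    data.frame(chrom = d$chrom[1L], start = min(d$start), end = max(d$end))))
  rownames(out) <- NULL
  out
}

#' Create a gene model (an annotation)
#' @param name Model name, e.g. `"refgene"`, `"ensembl"`, `"custom"`.
#' @param genes List of `gene`s; symbols must be unique within the model.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(name, genes = list()) {
  syms <- vapply(genes, `[[`, "", "symbol")
  if (anyDuplicated(syms)) stop("duplicate gene symbols in model '", name, "'")
  names(genes) <- syms
  structure(list(name = as.character(name), genes = genes),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d genes, %d transcripts on {%s}\n",
              x$name, length(x$genes), length(model_transcripts(x)),
              paste(sort(model_chroms(x)), collapse = ", ")))
  invisible(x)
}

#' All transcripts of a model as a flat named list
#' @param model A `gene_model`.
#' @return Named list of `transcript`s (names are transcript ids).
#' @export
model_transcripts <- function(model) {
  out <- unlist(lapply(model$genes, `[[`, "transcripts"), recursive = FALSE,
                use.names = FALSE)
  if (length(out)) names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Chromosome names referenced by a model
#'
#' May include names absent from a given genome (e.g. assembly patches).
#' @param model A `gene_model`.
#' @return Character vector of unique chromosome names.
#' @export
model_chroms <- function(model) {
  unique(vapply(model_transcripts(model), `[[`, "", "chrom"))
}

#' Gene symbols of a model
#' @param model A `gene_model`.
#' @return Character vector.
#' @export
gene_symbols <- function(model) names(model$genes)

#' Rename gene symbols via a mapping table
#'
#' Harmonizes database-specific identifiers to shared (HGNC-style) symbols
#' before models are compared. The map is a plain table; no identifier
#' service is consulted. Symbols absent from the table are kept (identity).
#'
#' @param model A `gene_model`.
#' @param map Data frame with columns `from`, `to`.
#' @return A `gene_model` with renamed symbols.
#' @export
apply_symbol_map <- function(model, map) {
  stopifnot(is.data.frame(map), all(c("from", "to") %in% names(map)))
  lut <- setNames(as.character(map$to), as.character(map$from))
  genes <- lapply(model$genes, function(g) {
    new <- if (g$symbol %in% names(lut)) lut[[g$symbol]] else g$symbol
    txs <- lapply(g$transcripts, function(tx) { tx$gene_symbol <- new; tx })
    gene(new, txs)
  })
  gene_model(model$name, genes)
}

# ---------------------------------------------------------------------------
# Genome
# ---------------------------------------------------------------------------

#' Validate and normalize a genome
#'
#' A genome is a named character vector of chromosome sequences over
#' `{A,C,G,T}`. Lower-case input is upper-cased; ambiguity codes are
#' rejected so that the exact-match mapper stays well defined.
#'
#' @param x Named character vector of sequences.
#' @return The validated genome (named upper-case character vector).
#' @export
as_genome <- function(x) {
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x)))
    stop("genome chromosomes must have unique non-empty names")
  x <- setNames(toupper(as.character(x)), names(x))
  if (any(nchar(x) == 0L)) stop("genome sequences must be non-empty")
  if (any(grepl("[^ACGT]", x)))
    stop("genome sequences may only contain A, C, G, T")
  x
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A genome (see [as_genome()]).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as_genome(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Write a genome to FASTA
#' @param genome A genome.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GTF I/O. Strict 9-column exon dialect, 1-based inclusive; non-exon
# features skipped; attributes gene_id / transcript_id required, gene_name
# optional (falls back to gene_id).
# ---------------------------------------------------------------------------

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, '\\s+"([^"]*)"'), attrs))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0(key, '\\s+"([^"]*)"'), "\\1", m)
}

#' Parse a GTF annotation into a gene model
#'
#' Only `exon` feature lines are used; CDS/start/stop features are ignored
#' (quantification is exon-level). Malformed lines raise an error naming the
#' offending line number.
#'
#' @param x Path to a GTF file, or a character vector of GTF lines.
#' @param name Model name to record; defaults to the file base name or
#'   `"custom"`.
#' @return A `gene_model`.
#' @export
parse_gtf <- function(x, name = NULL) {
  if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    if (is.null(name)) name <- sub("\\.gtf$", "", basename(x))
    lines <- readLines(x, warn = FALSE)
  } else {
    if (is.null(name)) name <- "custom"
    lines <- as.character(x)
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  tx_acc <- new.env(parent = emptyenv())
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "columns, found ", length(f))
    if (f[3L] != "exon") next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start < 1L)
      stop("GTF parse error at line ", i, ": bad coordinates")
    if (end < start)
      stop("GTF parse error at line ", i, ": end < start")
    if (!f[7L] %in% c("+", "-"))
      stop("GTF parse error at line ", i, ": unknown strand '", f[7L], "'")
    gid <- .gtf_attr(f[9L], "gene_id")
    tid <- .gtf_attr(f[9L], "transcript_id")
    if (is.na(gid) || is.na(tid))
      stop("GTF parse error at line ", i,
           ": missing gene_id or transcript_id attribute")
    gname <- .gtf_attr(f[9L], "gene_name")
    if (is.na(gname)) gname <- gid
    rec <- if (is.null(tx_acc[[tid]])) {
      list(gene = gname, chrom = f[1L], strand = f[7L],
           starts = integer(0), ends = integer(0))
    } else tx_acc[[tid]]
    if (rec$chrom != f[1L] || rec$strand != f[7L])
      stop("GTF parse error at line ", i, ": transcript '", tid,
           "' spans multiple chromosomes or strands")
    rec$starts <- c(rec$starts, start)
    rec$ends <- c(rec$ends, end)
    tx_acc[[tid]] <- rec
  }
  tids <- ls(tx_acc)
  txs <- lapply(tids, function(tid) {
    rec <- tx_acc[[tid]]
    transcript(tid, rec$gene, rec$chrom, rec$strand,
               data.frame(start = rec$starts, end = rec$ends))
  })
  syms <- vapply(txs, `[[`, "", "gene_symbol")
  genes <- lapply(split(txs, syms), function(tl) gene(tl[[1L]]$gene_symbol, tl))
  gene_model(name, genes)
}

#' Write a gene model as GTF
#'
#' Emits one `exon` line per exon in the same dialect [parse_gtf()] reads,
#' so that write/parse round trips are structurally lossless.
#'
#' @param model A `gene_model`.
#' @param path Output file, or `NULL` to return the lines.
#' @return The GTF lines invisibly (or visibly when `path` is `NULL`).
#' @export
write_gtf <- function(model, path = NULL) {
  txs <- model_transcripts(model)
  txs <- txs[order(names(txs))]
  lines <- unlist(lapply(txs, function(tx) {
    sprintf(
      "%s\tannoquant\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
      tx$chrom, tx$exons$start, tx$exons$end, tx$strand,
      tx$gene_symbol, tx$id, tx$gene_symbol)
  }), use.names = FALSE)
  if (is.null(lines)) lines <- character(0)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# Sequence extraction and coordinate projection
# ---------------------------------------------------------------------------

#' Spliced transcript sequence
#'
#' Concatenates the exon substrings of the genome in ascending genomic
#' order; on the `-` strand the concatenation is reverse-complemented as a
#' whole, so the result always reads 5' to 3' along the mRNA.
#'
#' @param genome A genome ([as_genome()]).
#' @param tx A `transcript`.
#' @return The mRNA sequence as a single string.
#' @export
spliced_sequence <- function(genome, tx) {
  if (!tx$chrom %in% names(genome))
    stop("chromosome '", tx$chrom, "' of transcript '", tx$id,
         "' is absent from the genome")
  chr <- genome[[tx$chrom]]
  if (max(tx$exons$end) > nchar(chr))
    stop("transcript '", tx$id, "' extends past the end of '", tx$chrom, "'")
  s <- paste(substring(chr, tx$exons$start, tx$exons$end), collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

# exons in transcript (5'->3') order with cumulative transcript offsets
.tx_layout <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  len <- span_length(ex)
  ex$tx_start <- cumsum(c(0L, len[-length(len)]))  # 0-based transcript start
  ex$len <- len
  ex
}

#' Project a transcript window onto the genome
#'
#' Maps the window `[offset, offset + length)` of transcript coordinates
#' (0-based, 5' to 3' along the mRNA) to the minimal list of genomic blocks.
#' Windows crossing an exon boundary yield two or more blocks separated by
#' introns; this is the block structure of a junction read.
#'
#' @param tx A `transcript`.
#' @param offset 0-based transcript position of the window start.
#' @param length Window length (>= 1).
#' @return Data frame of blocks (`chrom`, `start`, `end`, `strand`) in
#'   ascending genomic order.
#' @export
project_to_genome <- function(tx, offset, length) {
  offset <- as.integer(offset); length <- as.integer(length)
  sl <- spliced_length(tx)
  if (length < 1L) stop("window length must be >= 1")
  if (offset < 0L || offset + length > sl)
    stop("window [", offset, ", ", offset + length, ") out of transcript ",
         "range (spliced length ", sl, ")")
  lay <- .tx_layout(tx)
  lo <- offset; hi <- offset + length  # half-open in transcript coords
  blocks <- list()
  for (i in seq_len(nrow(lay))) {
    a <- max(lo, lay$tx_start[i])
    b <- min(hi, lay$tx_start[i] + lay$len[i])
    if (a >= b) next
    d1 <- a - lay$tx_start[i]; d2 <- b - 1L - lay$tx_start[i]
    if (tx$strand == "+") {
      g1 <- lay$start[i] + d1; g2 <- lay$start[i] + d2
    } else {
      g1 <- lay$end[i] - d2; g2 <- lay$end[i] - d1
    }
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = tx$chrom, start = g1, end = g2, strand = tx$strand)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcript window matching a set of genomic blocks, if any
#'
#' The inverse of [project_to_genome()]: given alignment blocks, returns the
#' 0-based transcript offset of the window whose projection equals them
#' exactly (same chromosome, block starts and ends), or `NA` if there is
#' none. Strand of the blocks is not required to match the transcript's
#' (an unstranded library may place a read on either strand).
#'
#' @param tx A `transcript`.
#' @param blocks Data frame with `chrom`, `start`, `end` (ascending).
#' @return Integer offset or `NA`.
#' @export
transcript_window_of <- function(tx, blocks) {
  if (any(blocks$chrom != tx$chrom)) return(NA_integer_)
  len <- sum(as.integer(blocks$end) - as.integer(blocks$start) + 1L)
  if (len > spliced_length(tx)) return(NA_integer_)
  lay <- .tx_layout(tx)
  # transcript coordinate of the window's 5'-most base
  if (tx$strand == "+") {
    gpos <- min(blocks$start)
    i <- which(lay$start <= gpos & lay$end >= gpos)
    if (length(i) != 1L) return(NA_integer_)
    off <- lay$tx_start[i] + (gpos - lay$start[i])
  } else {
    gpos <- max(blocks$end)
    i <- which(lay$start <= gpos & lay$end >= gpos)
    if (length(i) != 1L) return(NA_integer_)
    off <- lay$tx_start[i] + (lay$end[i] - gpos)
  }
  if (off + len > spliced_length(tx)) return(NA_integer_)
  proj <- project_to_genome(tx, off, len)
  ok <- nrow(proj) == nrow(blocks) &&
    all(proj$start == as.integer(blocks$start)) &&
    all(proj$end == as.integer(blocks$end))
  if (ok) off else NA_integer_
}
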