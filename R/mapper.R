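# ---------------------------------------------------------------------------
# Toy deterministic read mapper. Exact/k-mismatch substitution model only:
# no indels, no soft clipping. Both read orientations are searched
# (unstranded library); the reported strand is the placement strand.
# ---------------------------------------------------------------------------

#' Splice-search parameters for genome-mode mapping
#'
#' @param min_anchor Minimum length of each of the two segments of a spliced
#'   placement (bases). Reads with a shorter overhang across a junction
#'   cannot be spliced-aligned de novo, which is why short-overhang junction
#'   reads fail without a gene model.
#' @param min_intron,max_intron Allowed gap between the two segments.
#' @return A named list of class `splice_params`.
#' @export
splice_params <- function(min_anchor = 10L, min_intron = 20L,
                          max_intron = 10000L) {
  min_anchor <- as.integer(min_anchor)
  min_intron <- as.integer(min_intron)
  max_intron <- as.integer(max_intron)
  if (min_anchor < 1L || min_intron < 1L || max_intron < min_intron)
    stop("splice parameters must be positive with min_intron <= max_intron")
  structure(list(min_anchor = min_anchor, min_intron = min_intron,
                 max_intron = max_intron), class = "splice_params")
}

#' Default mismatch budget for a read length
#'
#' 2 mismatches for reads longer than 50 bp, 1 otherwise.
#' @param read_length Read length in bases.
#' @return Integer mismatch budget.
#' @export
default_max_mismatch <- function(read_length) if (read_length > 50L) 2L else 1L

#' Build the reference transcriptome of a model
#'
#' Extracts the spliced sequence of every transcript. Transcripts on
#' chromosomes absent from the genome (e.g. assembly patches) are skipped
#' with a warning — such genes can receive no reads, the patch-chromosome
#' phenomenon.
#'
#' @param model A `gene_model`.
#' @param genome A genome.
#' @return Named character vector of transcript sequences.
#' @export
build_transcriptome <- function(model, genome) {
  txs <- model_transcripts(model)
  keep <- vapply(txs, function(tx) tx$chrom %in% names(genome), TRUE)
  if (any(!keep))
    warning("skipping ", sum(!keep), " transcript(s) on chromosomes absent ",
            "from the genome: ",
            paste(unique(vapply(txs[!keep], `[[`, "", "chrom")),
                  collapse = ", "))
  txs <- txs[keep]
  vapply(txs, function(tx) spliced_sequence(genome, tx), "")
}

.blocks_str <- function(starts, ends) {
  paste(paste0(starts, "-", ends), collapse = ",")
}

.parse_blocks <- function(s) {
  p <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(p, `[`, "", 1L)),
             end = as.integer(vapply(p, `[`, "", 2L)))
}

.empty_hits <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             strand = character(0), blocks = character(0),
             nblocks = integer(0), mm = integer(0))
}

# Keep only each read's minimal-mismatch stratum and collapse genomically
# identical placements; canonical ordering by (chrom, first start, strand).
.finalize_hits <- function(hits) {
  if (nrow(hits) == 0L) return(.empty_hits())
  best <- tapply(hits$mm, hits$read_id, min)
  hits <- hits[hits$mm == best[hits$read_id], , drop = FALSE]
  key <- paste(hits$read_id, hits$chrom, hits$strand, hits$blocks, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  first_start <- as.integer(sub("-.*$", "", hits$blocks))
  hits <- hits[order(hits$read_id, hits$chrom, first_start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Raw transcriptome hits for a batch of reads: scans every transcript in
# both orientations, projects hits to genomic blocks. Returns all hits with
# mm <= max_mismatch (stratum selection happens in .finalize_hits).
.scan_transcriptome <- function(reads, model, genome, max_mismatch) {
  txseq <- build_transcriptome(model, genome)
  txs <- model_transcripts(model)
  rc <- revcomp(reads)
  rows <- list()
  proj_cache <- new.env(parent = emptyenv())
  for (tid in names(txseq)) {
    tx <- txs[[tid]]
    for (ori in c("+", "-")) {
      qry <- if (ori == "+") reads else rc
      h <- .cpp_scan_contiguous(txseq[[tid]], qry, max_mismatch)
      if (nrow(h) == 0L) next
      strand <- if (ori == "+") tx$strand else setdiff(c("+", "-"), tx$strand)
      L <- nchar(reads[h$read])
      bl <- character(nrow(h))
      nb <- integer(nrow(h))
      for (j in seq_len(nrow(h))) {
        ck <- paste0(tid, ":", h$pos[j], ":", L[j])
        pb <- proj_cache[[ck]]
        if (is.null(pb)) {
          b <- project_to_genome(tx, h$pos[j] - 1L, L[j])
          pb <- list(str = .blocks_str(b$start, b$end), n = nrow(b))
          proj_cache[[ck]] <- pb
        }
        bl[j] <- pb$str
        nb[j] <- pb$n
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads)[h$read], chrom = tx$chrom, strand = strand,
        blocks = bl, nblocks = nb, mm = h$mm)
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  do.call(rbind, rows)
}

# Raw genome hits: contiguous placements at <= max_mismatch plus two-segment
# spliced placements. Spliced candidates are only searched with a budget
# strictly below each read's best contiguous mismatch count (contiguous wins
# ties and is then the whole stratum), or the full budget when no contiguous
# placement exists.
.scan_genome <- function(reads, genome, max_mismatch, splice) {
  rc <- revcomp(reads)
  contig <- list()
  for (chrom in names(genome)) {
    for (ori in c("+", "-")) {
      qry <- if (ori == "+") reads else rc
      h <- .cpp_scan_contiguous(genome[[chrom]], qry, max_mismatch)
      if (nrow(h) == 0L) next
      L <- nchar(reads[h$read])
      contig[[length(contig) + 1L]] <- data.frame(
        read_id = names(reads)[h$read], chrom = chrom, strand = ori,
        blocks = .blocks_str_vec(h$pos, h$pos + L - 1L),
        nblocks = 1L, mm = h$mm)
    }
  }
  contig <- if (length(contig)) do.call(rbind, contig) else .empty_hits()
  best_contig <- tapply(contig$mm, contig$read_id, min)
  budget <- rep(max_mismatch, length(reads))
  names(budget) <- names(reads)
  has <- names(reads) %in% names(best_contig)
  budget[has] <- pmin(max_mismatch,
                      as.integer(best_contig[names(reads)[has]]) - 1L)
  spliced <- list()
  for (b in sort(unique(budget[budget >= 0L]))) {
    idx <- which(budget == b)
    sub <- reads[idx]; sub_rc <- rc[idx]
    for (chrom in names(genome)) {
      for (ori in c("+", "-")) {
        qry <- if (ori == "+") sub else sub_rc
        h <- .cpp_scan_spliced(genome[[chrom]], qry, b, splice$min_anchor,
                               splice$min_intron, splice$max_intron)
        if (nrow(h) == 0L) next
        spliced[[length(spliced) + 1L]] <- data.frame(
          read_id = names(sub)[h$read], chrom = chrom, strand = ori,
          blocks = paste0(h$pos1, "-", h$pos1 + h$len1 - 1L, ",",
                          h$pos2, "-", h$pos2 + h$len2 - 1L),
          nblocks = 2L, mm = h$mm)
      }
    }
  }
  spliced <- if (length(spliced)) do.call(rbind, spliced) else .empty_hits()
  rbind(contig, spliced)
}

.blocks_str_vec <- function(starts, ends) paste0(starts, "-", ends)

# ---------------------------------------------------------------------------
# Batch mapping API (used by the protocol and the pipeline)
# ---------------------------------------------------------------------------

#' Map a batch of reads
#'
#' Maps reads in one of the three modes: `"transcriptome_only"` (scan the
#' spliced transcript sequences, project hits back to genomic blocks,
#' collapse isoform-duplicate placements), `"none"` (direct genome mapping
#' with de novo two-segment splice search), or `"transcriptome_plus_genome"`
#' (transcriptome first, then genome for the reads left unmapped). Only the
#' minimal-mismatch stratum is kept per read; in genome mode a contiguous
#' placement beats spliced placements with the same mismatch count.
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids, unique).
#' @param mode One of `"transcriptome_only"`, `"none"`,
#'   `"transcriptome_plus_genome"`.
#' @param model A `gene_model` (unused in `"none"` mode).
#' @param genome A genome.
#' @param max_mismatch Mismatch budget; default from [default_max_mismatch()].
#' @param splice [splice_params()] for genome-mode splice search.
#' @return An object of class `mapping_batch`: list with `mode`, `read_ids`,
#'   `hits` (data frame `read_id`, `chrom`, `strand`, `blocks`, `nblocks`,
#'   `mm`, canonically ordered) and `ml` (named integer, 0 for unmapped).
#' @export
map_reads <- function(reads, mode = c("transcriptome_only", "none",
                                      "transcriptome_plus_genome"),
                      model = NULL, genome, max_mismatch = NULL,
                      splice = splice_params()) {
  mode <- match.arg(mode)
  reads <- .check_reads(reads)
  if (is.null(max_mismatch))
    max_mismatch <- default_max_mismatch(max(nchar(reads)))
  hits <- switch(mode,
    transcriptome_only = .finalize_hits(
      .scan_transcriptome(reads, model, genome, max_mismatch)),
    none = .finalize_hits(.scan_genome(reads, genome, max_mismatch, splice)),
    transcriptome_plus_genome = {
      h1 <- .finalize_hits(
        .scan_transcriptome(reads, model, genome, max_mismatch))
      miss <- setdiff(names(reads), unique(h1$read_id))
      if (length(miss)) {
        h2 <- .finalize_hits(
          .scan_genome(reads[miss], genome, max_mismatch, splice))
        h1 <- rbind(h1, h2)
      }
      h1
    })
  ml <- setNames(integer(length(reads)), names(reads))
  if (nrow(hits)) {
    tab <- table(hits$read_id)
    ml[names(tab)] <- as.integer(tab)
  }
  structure(list(mode = mode, read_ids = names(reads), hits = hits, ml = ml),
            class = "mapping_batch")
}

.check_reads <- function(reads) {
  if (length(reads) == 0L) stop("no reads supplied")
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must be a named character vector with unique ids")
  toupper(reads)
}

#' @export
print.mapping_batch <- function(x, ...) {
  st <- table(factor(ml_status_vec(x$ml),
                     levels = c("unmapped", "unique", "multiple")))
  cat(sprintf("mapping_batch mode=%s: %d reads (%d unmapped, %d unique, %d multiple)\n",
              x$mode, length(x$read_ids), st[["unmapped"]], st[["unique"]],
              st[["multiple"]]))
  invisible(x)
}

# single-read MappingResult built from a batch row set
.as_mapping_result <- function(read_id, mode, hits) {
  alns <- lapply(seq_len(nrow(hits)), function(i) {
    b <- .parse_blocks(hits$blocks[i])
    structure(list(read_id = read_id, chrom = hits$chrom[i],
                   strand = hits$strand[i],
                   blocks = data.frame(chrom = hits$chrom[i],
                                       start = b$start, end = b$end,
                                       strand = hits$strand[i]),
                   mismatches = hits$mm[i]),
              class = "alignment")
  })
  structure(list(read_id = read_id, mode = mode, alignments = alns,
                 ml = length(alns)),
            class = "mapping_result")
}

#' Map one read to the reference transcriptome
#'
#' Scans every transcript sequence in both orientations for windows within
#' the mismatch budget, keeps the minimal-mismatch stratum, projects each
#' transcript hit to genomic blocks, and collapses placements that are
#' genomically identical across isoforms. `ml` counts distinct genomic
#' placements.
#'
#' @param read Read sequence (single string).
#' @param model A `gene_model`.
#' @param genome A genome.
#' @param max_mismatch Mismatch budget.
#' @param read_id Read id recorded in the result.
#' @return A `mapping_result` with `mode = "transcriptome_only"`.
#' @export
map_to_transcriptome <- function(read, model, genome,
                                 max_mismatch = default_max_mismatch(nchar(read)),
                                 read_id = "read1") {
  b <- map_reads(setNames(read, read_id), "transcriptome_only", model, genome,
                 max_mismatch)
  .as_mapping_result(read_id, "transcriptome_only", b$hits)
}

#' Map one read directly to the genome
#'
#' Candidate placements are all contiguous placements within the mismatch
#' budget plus all two-segment spliced placements (each segment at least
#' `min_anchor` bases, gap within the intron bounds). The minimal-mismatch
#' stratum is kept; at equal mismatch count contiguous placements are
#' preferred and spliced candidates discarded.
#'
#' @inheritParams map_to_transcriptome
#' @param genome A genome.
#' @param splice [splice_params()].
#' @return A `mapping_result` with `mode = "none"`.
#' @export
map_to_genome <- function(read, genome,
                          max_mismatch = default_max_mismatch(nchar(read)),
                          splice = splice_params(), read_id = "read1") {
  b <- map_reads(setNames(read, read_id), "none", genome = genome,
                 max_mismatch = max_mismatch, splice = splice)
  .as_mapping_result(read_id, "none", b$hits)
}

#' Map one read transcriptome-first, genome as fallback
#'
#' Returns the transcriptome result when it maps (`ml >= 1`); otherwise the
#' direct-genome result. Mode is tagged `"transcriptome_plus_genome"`.
#'
#' @inheritParams map_to_genome
#' @param model A `gene_model`.
#' @return A `mapping_result`.
#' @export
map_sequential <- function(read, model, genome,
                           max_mismatch = default_max_mismatch(nchar(read)),
                           splice = splice_params(), read_id = "read1") {
  res <- map_to_transcriptome(read, model, genome, max_mismatch, read_id)
  if (res$ml == 0L)
    res <- map_to_genome(read, genome, max_mismatch, splice, read_id)
  res$mode <- "transcriptome_plus_genome"
  res
}

#' Mapping status from the number of mapped locations (#ML)
#'
#' @param result A `mapping_result`, or an integer vector of #ML values.
#' @return `"unmapped"` (#ML = 0), `"unique"` (#ML = 1) or `"multiple"`
#'   (#ML >= 2).
#' @export
ml_status <- function(result) {
  ml <- if (inherits(result, "mapping_result")) result$ml else result
  ml_status_vec(ml)[if (length(ml) == 1L) 1L else seq_along(ml)]
}

#' @rdname ml_status
#' @param ml Integer vector of #ML values.
#' @export
ml_status_vec <- function(ml) {
  ifelse(ml == 0L, "unmapped", ifelse(ml == 1L, "unique", "multiple"))
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result %s mode=%s ml=%d (%s)\n", x$read_id, x$mode,
              x$ml, ml_status(x)))
  for (a in x$alignments)
    cat(sprintf("  %s:%s %s mm=%d\n", a$chrom, a$strand,
                .blocks_str(a$blocks$start, a$blocks$end), a$mismatches))
  invisible(x)
}
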