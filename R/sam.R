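# ---------------------------------------------------------------------------
# SAM writer/reader for the mapper's own dialect: M/N CIGARs only (no
# indels, no clipping), NM = mismatch count, NH = #ML, XO = mapping mode.
# ---------------------------------------------------------------------------

.blocks_to_cigar <- function(blocks_str) {
  b <- .parse_blocks(blocks_str)
  len <- b$end - b$start + 1L
  if (nrow(b) == 1L) return(paste0(len, "M"))
  gaps <- b$start[-1L] - b$end[-nrow(b)] - 1L
  paste0(paste0(len[-nrow(b)], "M", gaps, "N", collapse = ""),
         len[nrow(b)], "M")
}

#' Write mapping results as SAM
#'
#' One record per alignment; spliced alignments use `M`/`N` CIGAR
#' operations; additional placements of a multiple-mapped read are flagged
#' secondary; unmapped reads get flag 4. Tags: `NM` (mismatches), `NH`
#' (#ML), `XO` (mapping mode).
#'
#' @param batch A `mapping_batch`.
#' @param reads The named read sequences that were mapped (for the SEQ
#'   column; reverse-complemented on `-` placements as SAM requires).
#' @param genome The genome mapped against (for `@SQ` header lines).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(batch, reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
           sprintf("@PG\tID:annoquant\tPN:annoquant\tDS:mode=%s", batch$mode))
  recs <- character(0)
  for (id in batch$read_ids) {
    h <- batch$hits[batch$hits$read_id == id, , drop = FALSE]
    ml <- batch$ml[[id]]
    if (nrow(h) == 0L) {
      recs <- c(recs, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*\tNH:i:0\tXO:Z:%s",
                              id, reads[[id]], batch$mode))
      next
    }
    for (i in seq_len(nrow(h))) {
      flag <- (if (h$strand[i] == "-") 16L else 0L) +
        (if (i > 1L) 256L else 0L)
      seq <- if (i > 1L) "*" else if (h$strand[i] == "-")
        revcomp(reads[[id]]) else reads[[id]]
      recs <- c(recs, sprintf(
        "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d\tXO:Z:%s",
        id, flag, h$chrom[i], as.integer(sub("-.*$", "", h$blocks[i])),
        if (ml == 1L) 255L else 0L, .blocks_to_cigar(h$blocks[i]), seq,
        h$mm[i], ml, batch$mode))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a SAM file written by [write_sam()] back into a `mapping_batch`
#'
#' Only the dialect this package writes is supported: CIGARs restricted to
#' `M` and `N` operations.
#'
#' @param path SAM file.
#' @return A `mapping_batch` (mode recovered from the `XO` tag).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "@")]
  mode <- "none"
  pg <- grep("^@PG", lines, value = TRUE)
  if (length(pg) && grepl("DS:mode=", pg[1L]))
    mode <- sub(".*DS:mode=([^\t]+).*", "\\1", pg[1L])
  ids <- character(0); rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("malformed SAM record: ", ln)
    id <- f[1L]; flag <- as.integer(f[2L])
    ids <- c(ids, id)
    if (bitwAnd(flag, 4L) > 0L) next
    ops <- regmatches(f[6L], gregexpr("\\d+[MN]", f[6L]))[[1L]]
    if (paste(ops, collapse = "") != f[6L])
      stop("unsupported CIGAR '", f[6L], "' (only M/N supported)")
    lens <- as.integer(sub("[MN]", "", ops))
    types <- sub("\\d+", "", ops)
    pos <- as.integer(f[4L])
    starts <- integer(0); ends <- integer(0); cur <- pos
    for (k in seq_along(ops)) {
      if (types[k] == "M") {
        starts <- c(starts, cur); ends <- c(ends, cur + lens[k] - 1L)
      }
      cur <- cur + lens[k]
    }
    mm <- 0L
    nm <- grep("^NM:i:", f, value = TRUE)
    if (length(nm)) mm <- as.integer(sub("NM:i:", "", nm[1L]))
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = id, chrom = f[3L],
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      blocks = .blocks_str(starts, ends), nblocks = length(starts), mm = mm)
  }
  ids <- unique(ids)
  hits <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  hits <- .finalize_hits(hits)
  ml <- setNames(integer(length(ids)), ids)
  if (nrow(hits)) {
    tab <- table(hits$read_id)
    ml[names(tab)] <- as.integer(tab)
  }
  structure(list(mode = mode, read_ids = ids, hits = hits, ml = ml),
            class = "mapping_batch")
}
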