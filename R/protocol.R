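# ---------------------------------------------------------------------------
# Two-stage mapping protocol and four-category read reclassification.
# Stage 1 filters out reads not covered by the gene model (unmapped in
# transcriptome-only mode). Stage 2 remaps the survivors with and without
# the model and compares every read's placement in detail.
# ---------------------------------------------------------------------------

#' Round half away from zero
#'
#' Plain decimal rounding (0.005 -> 0.01 at 2 digits), used for all reported
#' percentages so that printed tables are reproducible across platforms.
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # the 1e-8 guard keeps values like 1.005 (stored as 1.00499...) rounding up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Stage 1: keep only reads covered by the gene model
#'
#' Maps all reads in transcriptome-only mode and retains exactly those with
#' at least one placement (#ML >= 1). Reads from regions the annotation does
#' not cover are removed, so that stage 2 measures the model's effect only on
#' reads it could have informed.
#'
#' @param reads Named character vector of read sequences.
#' @param model A `gene_model`.
#' @param genome A genome.
#' @param max_mismatch Mismatch budget.
#' @return List with `reads` (the retained subset, names preserved),
#'   `retained_ids`, `retained_fraction`, and `batch` (the stage-1
#'   `mapping_batch`, reusable as the with-model stage-2 result).
#' @export
stage1_filter <- function(reads, model, genome, max_mismatch = NULL) {
  b <- map_reads(reads, "transcriptome_only", model, genome, max_mismatch)
  keep <- names(b$ml)[b$ml >= 1L]
  list(reads = reads[keep], retained_ids = keep,
       retained_fraction = length(keep) / length(reads), batch = b)
}

.aln_signature <- function(res) {
  vapply(res$alignments, function(a)
    paste(a$chrom, a$strand, .blocks_str(a$blocks$start, a$blocks$end),
          sep = ":"), "")
}

#' Classify one uniquely mapped read by its without-model fate
#'
#' Defined only for reads uniquely mapped in transcriptome-only mode. The
#' without-model result decides the category: `unmapped` (#ML = 0),
#' `multiple` (#ML >= 2), `identical` (#ML = 1 and the alignment matches on
#' chromosome, strand and every block start/end — including splice sites),
#' otherwise `alternative`. A junction read re-placed contiguously over the
#' same span is therefore `alternative`, not `identical`.
#'
#' @param with_model `mapping_result` from transcriptome-only mode, `ml = 1`.
#' @param without_model `mapping_result` from genome-only mode for the same
#'   read.
#' @return List of class `read_classification`: `read_id`, `category`,
#'   `is_junction` (from the with-model unique alignment).
#' @export
classify_read <- function(with_model, without_model) {
  if (with_model$ml != 1L)
    stop("classify_read requires a uniquely mapped with-model read")
  is_junction <- nrow(with_model$alignments[[1L]]$blocks) >= 2L
  category <- if (without_model$ml == 0L) "unmapped"
  else if (without_model$ml >= 2L) "multiple"
  else if (.aln_signature(with_model) == .aln_signature(without_model))
    "identical"
  else "alternative"
  structure(list(read_id = with_model$read_id, category = category,
                 is_junction = is_junction),
            class = "read_classification")
}

#' Classify all stage-2 reads from two batch mappings
#'
#' Batch form of [classify_read()]: takes the with-model (transcriptome-only)
#' and without-model (genome) `mapping_batch`es over the same reads and
#' classifies every read that is uniquely mapped with the model.
#'
#' @param with_batch `mapping_batch`, mode `"transcriptome_only"`.
#' @param without_batch `mapping_batch`, mode `"none"`, same reads.
#' @return Data frame `read_id`, `category`, `is_junction`.
#' @export
classify_reads <- function(with_batch, without_batch) {
  uniq <- names(with_batch$ml)[with_batch$ml == 1L]
  wh <- with_batch$hits[with_batch$hits$read_id %in% uniq, , drop = FALSE]
  sig_with <- setNames(paste(wh$chrom, wh$strand, wh$blocks, sep = ":"),
                       wh$read_id)
  junc <- setNames(wh$nblocks >= 2L, wh$read_id)
  ml_wo <- without_batch$ml
  oh <- without_batch$hits
  sig_wo <- setNames(paste(oh$chrom, oh$strand, oh$blocks, sep = ":"),
                     oh$read_id)
  category <- vapply(uniq, function(id) {
    m <- ml_wo[[id]]
    if (m == 0L) "unmapped"
    else if (m >= 2L) "multiple"
    else if (identical(unname(sig_wo[[id]]), unname(sig_with[[id]])))
      "identical"
    else "alternative"
  }, "")
  data.frame(read_id = uniq, category = unname(category),
             is_junction = unname(junc[uniq]), row.names = NULL)
}

.category_levels <- c("identical", "alternative", "multiple", "unmapped")

.cat_percent <- function(categories) {
  n <- length(categories)
  tab <- table(factor(categories, levels = .category_levels))
  pct <- round_half_up(100 * as.numeric(tab) / n, 2L)
  setNames(pct, .category_levels)
}

#' Junction-stratified classification summary
#'
#' Splits stage-2 classifications into junction and non-junction strata and
#' reports per-stratum category percentages plus the overall junction
#' fraction.
#'
#' @param classifications Data frame from [classify_reads()] (or a list of
#'   `read_classification` objects).
#' @return List of class `stratified_summary`: `junction`, `non_junction`
#'   (named percentage vectors over identical/alternative/multiple/unmapped),
#'   `junction_fraction`, and per-stratum counts `n_junction`,
#'   `n_non_junction`.
#' @export
stratified_summary <- function(classifications) {
  if (is.list(classifications) && !is.data.frame(classifications))
    classifications <- data.frame(
      read_id = vapply(classifications, `[[`, "", "read_id"),
      category = vapply(classifications, `[[`, "", "category"),
      is_junction = vapply(classifications, `[[`, TRUE, "is_junction"))
  if (nrow(classifications) == 0L)
    stop("stratified_summary requires at least one classified read")
  j <- classifications$is_junction
  structure(list(
    junction = if (any(j)) .cat_percent(classifications$category[j]) else
      setNames(rep(NA_real_, 4L), .category_levels),
    non_junction = if (any(!j)) .cat_percent(classifications$category[!j])
      else setNames(rep(NA_real_, 4L), .category_levels),
    junction_fraction = mean(j),
    n_junction = sum(j), n_non_junction = sum(!j)),
    class = "stratified_summary")
}

#' @export
print.stratified_summary <- function(x, ...) {
  cat(sprintf("junction fraction: %.4f (%d junction / %d non-junction)\n",
              x$junction_fraction, x$n_junction, x$n_non_junction))
  m <- rbind(junction = x$junction, non_junction = x$non_junction)
  print(m)
  invisible(x)
}

#' Per-mode unmapped/unique/multiple percentages
#'
#' @param batches Named list of `mapping_batch`es (names are modes or
#'   labels), or a named list of integer #ML vectors.
#' @return Data frame with `mode`, `n`, `unmapped`, `unique`, `multiple`
#'   (percentages, rounded to 0.01), plus `mapped` (= unique + multiple).
#' @export
mapping_summary <- function(batches) {
  if (inherits(batches, "mapping_batch")) batches <- list(batches)
  if (is.null(names(batches)) || any(names(batches) == ""))
    names(batches) <- vapply(seq_along(batches), function(i) {
      b <- batches[[i]]
      if (inherits(b, "mapping_batch")) b$mode else paste0("set", i)
    }, "")
  rows <- lapply(names(batches), function(nm) {
    b <- batches[[nm]]
    ml <- if (inherits(b, "mapping_batch")) b$ml else b
    if (length(ml) == 0L) stop("empty read group '", nm, "'")
    st <- table(factor(ml_status_vec(ml),
                       levels = c("unmapped", "unique", "multiple")))
    pct <- round_half_up(100 * as.numeric(st) / length(ml), 2L)
    data.frame(mode = nm, n = length(ml), unmapped = pct[1L],
               unique = pct[2L], multiple = pct[3L],
               mapped = round_half_up(pct[2L] + pct[3L], 2L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of uniquely mapped reads recovering their true origin
#'
#' Compares each uniquely mapped read's placement with its simulated origin
#' on (chromosome, strand, blocks). Computed over unique reads only.
#'
#' @param batch A `mapping_batch`.
#' @param truth Data frame with `read_id`, `chrom`, `strand`, `blocks`
#'   (block string as produced by the simulator) covering every read.
#' @return Fraction in `[0, 1]` (`NaN` when no read is unique).
#' @export
truth_recovery <- function(batch, truth) {
  uniq <- names(batch$ml)[batch$ml == 1L]
  if (!all(batch$read_ids %in% truth$read_id))
    stop("truth records missing for some reads")
  h <- batch$hits[batch$hits$read_id %in% uniq, , drop = FALSE]
  tr <- truth[match(h$read_id, truth$read_id), , drop = FALSE]
  if (nrow(h) == 0L) return(NaN)
  mean(h$chrom == tr$chrom & h$strand == tr$strand & h$blocks == tr$blocks)
}
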