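# ---------------------------------------------------------------------------
# Pipeline orchestration: simulate (optional) -> stage 1 -> stage 2 mapping
# with and without the model -> read classification -> per-model counting ->
# concordance and fold-change concordance -> report bundle on disk.
# ---------------------------------------------------------------------------

#' Build a pipeline configuration
#'
#' Either a simulation specification (the default) or paths to a genome
#' FASTA, two GTFs and 1-2 FASTQ files. All stochastic steps derive from the
#' single `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param simulate Logical; when `TRUE` the synthetic world below is used.
#' @param chrom_lengths Chromosome lengths for the synthetic genome.
#' @param archetypes List of [archetype_spec()]s.
#' @param n_reads Reads per simulated sample.
#' @param n_samples 1 or 2 simulated samples (2 enables fold-change
#'   concordance).
#' @param read_length Read length.
#' @param error_rate Per-base substitution rate.
#' @param max_mismatch Mapper mismatch budget (`NULL` = read-length default).
#' @param splice [splice_params()].
#' @param thresholds Ratio thresholds for the concordance table.
#' @param genome_fasta,model_a_gtf,model_b_gtf,reads_fastq Input paths when
#'   `simulate = FALSE` (`reads_fastq` may have length 2).
#' @param write_sam_files Write stage-2 SAM files for sample 1.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            chrom_lengths = c(chr1 = 150000L, chr2 = 150000L),
                            archetypes = default_archetype_panel(),
                            n_reads = 2000L, n_samples = 2L,
                            read_length = 75L, error_rate = 0.001,
                            max_mismatch = NULL, splice = splice_params(),
                            thresholds = default_ratio_thresholds(),
                            genome_fasta = NULL, model_a_gtf = NULL,
                            model_b_gtf = NULL, reads_fastq = NULL,
                            write_sam_files = TRUE) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  if (!simulate) {
    paths <- c(genome_fasta, model_a_gtf, model_b_gtf, reads_fastq)
    if (length(paths) < 4L || !all(file.exists(paths)))
      stop("simulate = FALSE requires existing genome, two GTFs and reads")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, chrom_lengths = chrom_lengths,
                 archetypes = archetypes, n_reads = as.integer(n_reads),
                 n_samples = as.integer(n_samples),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, max_mismatch = max_mismatch,
                 splice = splice, thresholds = thresholds,
                 genome_fasta = genome_fasta, model_a_gtf = model_a_gtf,
                 model_b_gtf = model_b_gtf, reads_fastq = reads_fastq,
                 write_sam_files = write_sam_files),
            class = "pipeline_config")
}

.log_line <- function(log, ...) {
  msg <- sprintf(...)
  message(msg)
  c(log, msg)
}

#' Run the full annotation-impact pipeline
#'
#' Executes: simulation (optional), stage-1 filtering per model, stage-2
#' mapping with (transcriptome-only) and without (genome) the model, read
#' classification with junction stratification, per-model gene counting,
#' count-ratio concordance between the two models, and (with two samples)
#' fold-change concordance. All artifacts are written under
#' `config$out_dir`; re-running with the same config and seed is
#' byte-identical (no timestamps are written).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every in-memory result (`world`,
#'   `batches`, `classifications`, `summaries`, `counts`, `concordance`,
#'   `de`, `diff_table`, `venn`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log <- character(0)

  # ---- inputs -------------------------------------------------------------
  if (config$simulate) {
    genome0 <- generate_genome(config$chrom_lengths, config$seed)
    world <- generate_annotation_pair(genome0, config$archetypes, config$seed)
    samples <- paste0("s", seq_len(config$n_samples))
    sims <- lapply(seq_along(samples), function(k)
      simulate_reads(world$genome, world$model_a, NULL, config$n_reads,
                     config$read_length, config$error_rate,
                     seed = config$seed + 101L * k))
    names(sims) <- samples
    write_genome_fasta(world$genome, out("genome.fa"))
    write_gtf(world$model_a, out("model_a.gtf"))
    write_gtf(world$model_b, out("model_b.gtf"))
    write_truth_tsv(world$truth, out("archetype_truth.tsv"))
    for (s in samples) {
      write_fastq(sims[[s]]$reads, out(paste0("reads_", s, ".fastq")))
      write_truth_tsv(sims[[s]]$truth, out(paste0("read_truth_", s, ".tsv")))
    }
    log <- .log_line(log, "simulated %d sample(s) x %d reads (L=%d, e=%g)",
                     length(samples), config$n_reads, config$read_length,
                     config$error_rate)
  } else {
    world <- list(
      genome = read_genome_fasta(config$genome_fasta),
      model_a = parse_gtf(config$model_a_gtf, name = "model_a"),
      model_b = parse_gtf(config$model_b_gtf, name = "model_b"),
      truth = NULL)
    sims <- lapply(config$reads_fastq, function(p) list(reads = read_fastq(p),
                                                        truth = NULL))
    names(sims) <- paste0("s", seq_along(sims))
  }
  models <- list(model_a = world$model_a, model_b = world$model_b)
  max_mm <- if (is.null(config$max_mismatch))
    default_max_mismatch(config$read_length) else config$max_mismatch

  # ---- model structure comparison ----------------------------------------
  venn <- symbol_overlap(models)
  write_venn_json(venn, out("venn.json"))
  diff_table <- model_diff_table(world$model_a, world$model_b,
                                 names(world$genome))
  write_diff_tsv(diff_table, out("model_diff.tsv"))
  log <- .log_line(log, "model diff: %s",
                   paste(sprintf("%s=%d", names(table(diff_table$category)),
                                 table(diff_table$category)), collapse = " "))

  # ---- per-model two-stage protocol (sample 1) ----------------------------
  reads1 <- sims[[1L]]$reads
  batches <- list(); classifications <- list(); summaries <- list()
  counts <- list()
  for (mn in names(models)) {
    st1 <- stage1_filter(reads1, models[[mn]], world$genome, max_mm)
    log <- .log_line(log, "[%s] stage 1: retained %d / %d reads (%.2f%%)",
                     mn, length(st1$retained_ids), length(reads1),
                     100 * st1$retained_fraction)
    if (length(st1$retained_ids) == 0L) {
      warning("no reads retained for ", mn, "; skipping stage 2")
      next
    }
    with_b <- list(mode = st1$batch$mode,
                   read_ids = st1$retained_ids,
                   hits = st1$batch$hits[
                     st1$batch$hits$read_id %in% st1$retained_ids, ,
                     drop = FALSE],
                   ml = st1$batch$ml[st1$retained_ids])
    class(with_b) <- "mapping_batch"
    without_b <- map_reads(st1$reads, "none", genome = world$genome,
                           max_mismatch = max_mm, splice = config$splice)
    batches[[mn]] <- list(with_model = with_b, without_model = without_b)
    cl <- classify_reads(with_b, without_b)
    classifications[[mn]] <- cl
    write.table(cl, out(paste0("classification_", mn, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summaries[[mn]] <- stratified_summary(cl)
    log <- .log_line(log,
      "[%s] stage 2: %d unique reads classified; junction fraction %.4f",
      mn, nrow(cl), summaries[[mn]]$junction_fraction)
    if (config$write_sam_files) {
      write_sam(with_b, reads1[with_b$read_ids], world$genome,
                out(paste0("stage2_", mn, "_with_model.sam")))
      write_sam(without_b, st1$reads, world$genome,
                out(paste0("stage2_", mn, "_without_model.sam")))
    }
    # ---- per-model, per-sample counting ----------------------------------
    for (s in names(sims)) {
      b <- if (s == names(sims)[1L]) with_b else
        map_reads(sims[[s]]$reads, "transcriptome_only", models[[mn]],
                  world$genome, max_mm)
      tb <- count_reads(b, models[[mn]], config$read_length, sample_name = s)
      counts[[paste(mn, s, sep = ".")]] <- tb
      write_count_tsv(tb, out(paste0("counts_", mn, "_", s, ".tsv")))
      log <- .log_line(log, "[%s/%s] counted %.2f reads over %d genes",
                       mn, s, sum(tb$count), nrow(tb))
    }
  }

  # ---- mode-level mapping summary (sample 1, model A) ---------------------
  seq_b <- map_reads(reads1, "transcriptome_plus_genome", world$model_a,
                     world$genome, max_mm, config$splice)
  none_b <- map_reads(reads1, "none", genome = world$genome,
                      max_mismatch = max_mm, splice = config$splice)
  tr_b <- map_reads(reads1, "transcriptome_only", world$model_a, world$genome,
                    max_mm)
  msum <- mapping_summary(list(transcriptome_only = tr_b,
                               transcriptome_plus_genome = seq_b,
                               none = none_b))
  write.table(msum, out("mapping_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # ---- concordance --------------------------------------------------------
  concord <- NULL; de <- NULL
  s1 <- names(sims)[1L]
  ka <- paste("model_a", s1, sep = "."); kb <- paste("model_b", s1, sep = ".")
  if (!is.null(counts[[ka]]) && !is.null(counts[[kb]])) {
    concord <- concordance_table(counts[[ka]], counts[[kb]],
                                 config$thresholds)
    write_concordance_tsv(concord, out("concordance.tsv"))
    log <- .log_line(log, "concordance over %d common genes: no_expr=%.2f same=%.2f",
                     attr(concord, "n_common"), concord$no_expr, concord$same)
  }
  if (length(sims) >= 2L) {
    s2 <- names(sims)[2L]
    de <- de_concordance(counts[[ka]], counts[[paste("model_a", s2, sep = ".")]],
                         counts[[kb]], counts[[paste("model_b", s2, sep = ".")]])
    write.table(de$per_gene, out("de_concordance_per_gene.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(jsonlite::toJSON(as.list(de$counts), auto_unbox = TRUE),
               out("de_concordance_counts.json"))
    log <- .log_line(log, "fold-change discordance: >1: %d, >2: %d, >5: %d",
                     de$counts[["gt1"]], de$counts[["gt2"]], de$counts[["gt5"]])
  }

  # ---- summaries + effective config ---------------------------------------
  summary_json <- list(
    mapping_summary = msum,
    stratified = lapply(summaries, function(s) list(
      junction = as.list(s$junction), non_junction = as.list(s$non_junction),
      junction_fraction = s$junction_fraction,
      n_junction = s$n_junction, n_non_junction = s$n_non_junction)),
    concordance = if (!is.null(concord))
      c(as.list(as.data.frame(concord)),
        list(n_common = attr(concord, "n_common"))),
    de_counts = if (!is.null(de)) as.list(de$counts))
  jsonlite::write_json(summary_json, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg_echo <- config
  cfg_echo$splice <- unclass(cfg_echo$splice)
  cfg_echo$archetypes <- lapply(cfg_echo$archetypes, unclass)
  jsonlite::write_json(unclass(cfg_echo), out("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  writeLines(log, out("run.log"))
  invisible(list(world = world, sims = sims, batches = batches,
                 classifications = classifications, summaries = summaries,
                 mapping_summary = msum, counts = counts,
                 concordance = concord, de = de, diff_table = diff_table,
                 venn = venn))
}
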