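# ---------------------------------------------------------------------------
# Synthetic genomes, paired annotations embedding the classic
# annotation-difference archetypes, and reads with full ground truth.
# Everything is reproducible from a single integer seed.
# ---------------------------------------------------------------------------

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation, kept below 2^31
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 2011L + k

#' Generate a random genome
#'
#' Uniform i.i.d. A/C/G/T sequences; identical output for identical seeds.
#'
#' @param chrom_lengths Named (or unnamed, then `chr1..chrN`) integer vector
#'   of chromosome lengths, all >= 1.
#' @param seed Integer seed.
#' @return A genome ([as_genome()]).
#' @export
generate_genome <- function(chrom_lengths, seed = 1L) {
  if (any(chrom_lengths < 1L)) stop("chromosome lengths must be >= 1")
  nms <- names(chrom_lengths)
  if (is.null(nms)) nms <- paste0("chr", seq_along(chrom_lengths))
  .with_seed(.sub_seed(seed, 1L), {
    seqs <- vapply(chrom_lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      "")
  })
  as_genome(setNames(seqs, nms))
}

#' Describe one annotation-difference archetype
#'
#' The six archetypes reproduce the canonical ways two gene models disagree:
#' `identical` (same definition in both), `three_prime_extension` (model A's
#' final exon is longer by `extension_length`), `nested_gene_vs_shared_transcript`
#' (model A nests a short gene inside a container gene; model B gives both
#' symbols one identical bicistronic transcript), `absent_chromosome`
#' (model B places the gene on a patch chromosome missing from the genome),
#' `model_unique_gene` (present in model A only), `processed_retrocopy`
#' (the gene's spliced mRNA is reinserted into the genome as an intronless
#' copy, annotated as an extra gene in model A only).
#'
#' @param archetype One of the six archetype names.
#' @param n_exons Number of exons (>= 2 where a junction matters).
#' @param exon_length,intron_length Length ranges `c(min, max)`.
#' @param extension_length 3' extension length for `three_prime_extension`;
#'   must be at least the read length for detectability.
#' @param nested_length Length of the nested gene's single exon.
#' @return A list of class `archetype_spec`.
#' @export
archetype_spec <- function(archetype = c("identical", "three_prime_extension",
                                         "nested_gene_vs_shared_transcript",
                                         "absent_chromosome",
                                         "model_unique_gene",
                                         "processed_retrocopy"),
                           n_exons = NULL, exon_length = c(120L, 300L),
                           intron_length = c(200L, 1500L),
                           extension_length = 5384L, nested_length = 177L) {
  archetype <- match.arg(archetype)
  if (any(c(exon_length, intron_length, extension_length, nested_length) < 1L))
    stop("all archetype lengths must be positive")
  structure(list(archetype = archetype, n_exons = n_exons,
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 extension_length = as.integer(extension_length),
                 nested_length = as.integer(nested_length)),
            class = "archetype_spec")
}

#' Default archetype panel
#'
#' One of each non-trivial archetype plus `n_identical` plain genes; with the
#' default genome this gives a ~20-gene toy annotation pair.
#'
#' @param n_identical Number of `identical` background genes.
#' @return List of [archetype_spec()]s.
#' @export
default_archetype_panel <- function(n_identical = 14L) {
  c(replicate(n_identical, archetype_spec("identical"), simplify = FALSE),
    list(archetype_spec("three_prime_extension"),
         archetype_spec("nested_gene_vs_shared_transcript"),
         archetype_spec("absent_chromosome"),
         archetype_spec("model_unique_gene"),
         archetype_spec("processed_retrocopy")))
}

# sequential locus allocator over chromosomes (round robin), fixed margins
.make_allocator <- function(genome, margin = 800L) {
  env <- new.env(parent = emptyenv())
  env$cursor <- setNames(rep(margin + 1L, length(genome)), names(genome))
  env$turn <- 1L
  env$alloc <- function(len) {
    nms <- names(genome)
    for (k in seq_along(nms)) {
      chrom <- nms[1L + (env$turn - 1L + k - 1L) %% length(nms)]
      start <- env$cursor[[chrom]]
      if (start + len - 1L + margin <= nchar(genome[[chrom]])) {
        env$cursor[[chrom]] <- start + len + margin
        env$turn <- env$turn + 1L
        return(list(chrom = chrom, start = start))
      }
    }
    stop("insufficient genome space to place a locus of length ", len)
  }
  env
}

# random multi-exon structure within a locus; returns exon data frame + span
.draw_exons <- function(n_exons, exon_length, intron_length) {
  ex_len <- sample(seq(exon_length[1L], exon_length[2L]), n_exons,
                   replace = TRUE)
  in_len <- if (n_exons > 1L)
    sample(seq(intron_length[1L], intron_length[2L]), n_exons - 1L,
           replace = TRUE) else integer(0)
  starts <- cumsum(c(1L, head(ex_len, -1L) + in_len))
  data.frame(start = starts, end = starts + ex_len - 1L)
}

#' Generate a pair of gene models embedding archetype differences
#'
#' Builds two annotations over the same genome that differ exactly per the
#' supplied archetypes. Model A plays the "richer" annotation (extended 3'
#' exon, nested short gene, retro-copy annotated, extra unique gene); model B
#' the "leaner" one (shorter exon, shared bicistronic transcript,
#' patch-chromosome placement). For `processed_retrocopy` the source gene's
#' spliced mRNA is written into an unannotated genomic region, so the
#' returned genome differs from the input.
#'
#' @param genome A genome.
#' @param specs List of [archetype_spec()]s.
#' @param seed Integer seed.
#' @return List: `genome` (possibly modified), `model_a`, `model_b`, `truth`
#'   (data frame `symbol`, `archetype`, `in_a`, `in_b`).
#' @export
generate_annotation_pair <- function(genome, specs = default_archetype_panel(),
                                     seed = 1L) {
  stopifnot(all(vapply(specs, inherits, TRUE, "archetype_spec")))
  .with_seed(.sub_seed(seed, 2L), {
    alloc <- .make_allocator(genome)
    genes_a <- list(); genes_b <- list(); truth <- list()
    add_truth <- function(symbol, archetype, in_a, in_b)
      truth[[length(truth) + 1L]] <<- data.frame(
        symbol = symbol, archetype = archetype, in_a = in_a, in_b = in_b)
    retro_jobs <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      sym <- sprintf("G%02d", i)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- if (!is.null(sp$n_exons)) sp$n_exons else sample(2:8, 1L)
      ex <- .draw_exons(n_ex, sp$exon_length, sp$intron_length)
      place <- function(exons, extra = 0L) {
        loc <- alloc$alloc(max(exons$end) + extra)
        data.frame(start = exons$start + loc$start - 1L,
                   end = exons$end + loc$start - 1L, chrom = loc$chrom)
      }
      switch(sp$archetype,
        identical = {
          exg <- place(ex)
          tx <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand, exg)
          genes_a[[sym]] <- gene(sym, list(tx))
          genes_b[[sym]] <- gene(sym, list(tx))
          add_truth(sym, "identical", TRUE, TRUE)
        },
        three_prime_extension = {
          # placed on '+' so the 3' extension is a plain end shift
          strand <- "+"
          exg <- place(ex, extra = sp$extension_length)
          ex_a <- exg
          ex_a$end[n_ex] <- ex_a$end[n_ex] + sp$extension_length
          tx_a <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand,
                             ex_a[, c("start", "end")])
          tx_b <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand,
                             exg[, c("start", "end")])
          genes_a[[sym]] <- gene(sym, list(tx_a))
          genes_b[[sym]] <- gene(sym, list(tx_b))
          add_truth(sym, "three_prime_extension", TRUE, TRUE)
        },
        nested_gene_vs_shared_transcript = {
          # container needs one exon long enough to hold the nested gene
          ex$end[1L] <- ex$start[1L] +
            max(span_length(ex)[1L], sp$nested_length + 40L) - 1L
          ex <- transcript("tmp", "tmp", "chr", "+", ex)$exons  # renormalize
          exg <- place(ex)
          host <- which.max(span_length(exg))
          ctr_sym <- sym; nst_sym <- paste0(sym, "N")
          tx_c <- transcript(paste0(ctr_sym, ".t1"), ctr_sym, exg$chrom[1L],
                             strand, exg[, c("start", "end")])
          pad <- (span_length(exg)[host] - sp$nested_length) %/% 2L
          nest <- data.frame(start = exg$start[host] + pad,
                             end = exg$start[host] + pad + sp$nested_length - 1L)
          tx_n <- transcript(paste0(nst_sym, ".t1"), nst_sym, exg$chrom[1L],
                             strand, nest)
          genes_a[[ctr_sym]] <- gene(ctr_sym, list(tx_c))
          genes_a[[nst_sym]] <- gene(nst_sym, list(tx_n))
          # model B: both symbols share one identical bicistronic transcript
          tx_c_b <- transcript(paste0(ctr_sym, ".t1"), ctr_sym, exg$chrom[1L],
                               strand, exg[, c("start", "end")])
          tx_n_b <- transcript(paste0(nst_sym, ".t1"), nst_sym, exg$chrom[1L],
                               strand, exg[, c("start", "end")])
          genes_b[[ctr_sym]] <- gene(ctr_sym, list(tx_c_b))
          genes_b[[nst_sym]] <- gene(nst_sym, list(tx_n_b))
          add_truth(ctr_sym, "nested_gene_vs_shared_transcript", TRUE, TRUE)
          add_truth(nst_sym, "nested_gene_vs_shared_transcript", TRUE, TRUE)
        },
        absent_chromosome = {
          exg <- place(ex)
          tx_a <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand,
                             exg[, c("start", "end")])
          patch <- paste0(exg$chrom[1L], "_PATCH")
          tx_b <- transcript(paste0(sym, ".t1"), sym, patch, strand,
                             exg[, c("start", "end")])
          genes_a[[sym]] <- gene(sym, list(tx_a))
          genes_b[[sym]] <- gene(sym, list(tx_b))
          add_truth(sym, "absent_chromosome", TRUE, TRUE)
        },
        model_unique_gene = {
          exg <- place(ex)
          tx <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand, exg)
          genes_a[[sym]] <- gene(sym, list(tx))
          add_truth(sym, "model_unique_gene", TRUE, FALSE)
        },
        processed_retrocopy = {
          exg <- place(ex)
          tx <- transcript(paste0(sym, ".t1"), sym, exg$chrom[1L], strand, exg)
          genes_a[[sym]] <- gene(sym, list(tx))
          genes_b[[sym]] <- gene(sym, list(tx))
          add_truth(sym, "processed_retrocopy", TRUE, TRUE)
          retro_jobs[[length(retro_jobs) + 1L]] <- list(sym = sym, tx = tx)
        })
    }
    # insert retro-copies after all loci are known, then annotate in model A
    for (job in retro_jobs) {
      mrna <- spliced_sequence(genome, job$tx)
      loc <- alloc$alloc(nchar(mrna))
      chr <- genome[[loc$chrom]]
      substr(chr, loc$start, loc$start + nchar(mrna) - 1L) <- mrna
      genome[[loc$chrom]] <- chr
      rc_sym <- paste0(job$sym, "RC")
      rc_tx <- transcript(paste0(rc_sym, ".t1"), rc_sym, loc$chrom, "+",
                          data.frame(start = loc$start,
                                     end = loc$start + nchar(mrna) - 1L))
      genes_a[[rc_sym]] <- gene(rc_sym, list(rc_tx))
      add_truth(rc_sym, "processed_retrocopy", TRUE, FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(genome = as_genome(genome),
         model_a = gene_model("model_a", genes_a),
         model_b = gene_model("model_b", genes_b),
         truth = truth)
  })
}

#' Simulate reads from a gene model with ground truth
#'
#' Transcripts are sampled with probability proportional to
#' `weight * spliced_length` (uniform fragment coverage: a transcript twice
#' as long yields twice the reads at equal weight); start offsets are uniform
#' over the valid range; each base is substituted independently at
#' `error_rate`. The library is unstranded: each read is emitted in sense or
#' antisense orientation with probability 1/2. Transcripts on chromosomes
#' absent from the genome, and transcripts shorter than the read, produce no
#' reads.
#'
#' @param genome A genome.
#' @param model A `gene_model`.
#' @param expression_weights Named non-negative weights per transcript id;
#'   `NULL` draws log-normal(0, 1) weights (tissue-like spread) from the
#'   seed. Missing ids get weight 1.
#' @param n_reads Number of reads.
#' @param read_length Read length (default 75).
#' @param error_rate Per-base substitution probability in `[0, 1)`;
#'   default 0.001.
#' @param seed Integer seed.
#' @return List: `reads` (named character vector) and `truth` (data frame
#'   `read_id`, `tx_id`, `gene_symbol`, `offset` (0-based), `chrom`,
#'   `strand` (placement strand of the read), `blocks` (block string),
#'   `junction`, `error_pos` (comma-separated 1-based read positions, `""`
#'   if none)).
#' @export
simulate_reads <- function(genome, model, expression_weights = NULL,
                           n_reads = 1000L, read_length = 75L,
                           error_rate = 0.001, seed = 1L) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  read_length <- as.integer(read_length)
  txs <- model_transcripts(model)
  txs <- txs[vapply(txs, function(tx) tx$chrom %in% names(genome), TRUE)]
  txs <- txs[vapply(txs, spliced_length, 0L) >= read_length]
  if (length(txs) == 0L)
    stop("no transcript is mappable and at least read_length long")
  .with_seed(.sub_seed(seed, 3L), {
    w <- if (is.null(expression_weights)) {
      setNames(exp(rnorm(length(txs))), names(txs))
    } else {
      ww <- setNames(rep(1, length(txs)), names(txs))
      hit <- intersect(names(expression_weights), names(txs))
      ww[hit] <- expression_weights[hit]
      ww
    }
    if (any(w < 0)) stop("expression weights must be non-negative")
    sl <- vapply(txs, spliced_length, 0L)
    p <- w * sl
    if (sum(p) <= 0) stop("all sampling weights are zero")
    pick <- sample(seq_along(txs), n_reads, replace = TRUE, prob = p)
    seqs <- vapply(txs, function(tx) spliced_sequence(genome, tx), "")
    offs <- vapply(pick, function(i)
      sample.int(sl[i] - read_length + 1L, 1L) - 1L, 0L)
    sense <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    reads <- substring(seqs[pick], offs + 1L, offs + read_length)
    reads[!sense] <- revcomp(reads[!sense])
    # substitution errors
    err_pos <- vector("list", n_reads)
    n_err <- rbinom(n_reads, read_length, error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0L)) {
      pos <- sample.int(read_length, n_err[i])
      r <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      for (pp in pos) r[pp] <- sample(setdiff(bases, r[pp]), 1L)
      reads[i] <- paste(r, collapse = "")
      err_pos[[i]] <- sort(pos)
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    # origin blocks; cache projections per (tx, offset)
    bl_cache <- new.env(parent = emptyenv())
    blocks <- character(n_reads); nb <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      key <- paste0(pick[i], ":", offs[i])
      v <- bl_cache[[key]]
      if (is.null(v)) {
        b <- project_to_genome(txs[[pick[i]]], offs[i], read_length)
        v <- list(s = .blocks_str(b$start, b$end), n = nrow(b))
        bl_cache[[key]] <- v
      }
      blocks[i] <- v$s; nb[i] <- v$n
    }
    tx_strand <- vapply(txs, `[[`, "", "strand")[pick]
    strand <- ifelse(sense, tx_strand,
                     ifelse(tx_strand == "+", "-", "+"))
    truth <- data.frame(
      read_id = ids, tx_id = names(txs)[pick],
      gene_symbol = vapply(txs, `[[`, "", "gene_symbol")[pick],
      offset = offs, chrom = vapply(txs, `[[`, "", "chrom")[pick],
      strand = strand, blocks = blocks, junction = nb >= 2L,
      error_pos = vapply(err_pos, function(p)
        if (is.null(p)) "" else paste(p, collapse = ","), ""),
      row.names = NULL)
    list(reads = reads, truth = truth)
  })
}

#' Write reads as FASTQ
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(as.vector(rbind(paste0("@", names(reads)), unname(reads),
                             "+", qual)), path)
  invisible(path)
}

#' Read FASTQ into a named character vector
#' @param path FASTQ file (4-line records, the dialect [write_fastq()] emits).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- readLines(path, warn = FALSE)
  if (length(x) %% 4L != 0L) stop("FASTQ file is not 4-line records")
  ids <- sub("^@", "", sub("\\s.*$", "", x[seq(1L, length(x), 4L)]))
  setNames(toupper(x[seq(2L, length(x), 4L)]), ids)
}

#' Write a truth table as TSV
#' @param truth Data frame from [simulate_reads()] or
#'   [generate_annotation_pair()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
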