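# Fixtures and independent brute-force oracles. The oracles deliberately use
# a different algorithmic style (vectorized cumulative mismatch arrays and
# exhaustive enumeration in R) from the package's early-exit C++ scanner.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

tx_quick <- function(id, sym, chrom, strand, starts, ends) {
  transcript(id, sym, chrom, strand, data.frame(start = starts, end = ends))
}

# one forward-strand orientation; returns data.frame(pos, mm)
oracle_scan_contiguous <- function(subject, read, max_mm) {
  s <- strsplit(subject, "")[[1L]]
  r <- strsplit(read, "")[[1L]]
  n <- length(s); L <- length(r)
  if (L > n) return(data.frame(pos = integer(0), mm = integer(0)))
  np <- n - L + 1L
  mmv <- integer(np)
  for (k in seq_len(L)) mmv <- mmv + (s[k:(k + np - 1L)] != r[k])
  keep <- which(mmv <= max_mm)
  data.frame(pos = keep, mm = mmv[keep])
}

# all two-segment spliced placements (full budget); data.frame(pos1, len1,
# pos2, len2, mm), built from cumulative prefix/suffix mismatch matrices
oracle_scan_spliced <- function(subject, read, max_mm, min_anchor,
                                min_intron, max_intron) {
  s <- strsplit(subject, "")[[1L]]
  r <- strsplit(read, "")[[1L]]
  n <- length(s); L <- length(r)
  empty <- data.frame(pos1 = integer(0), len1 = integer(0),
                      pos2 = integer(0), len2 = integer(0), mm = integer(0))
  if (L < 2L * min_anchor || n < L + min_intron) return(empty)
  smax <- L - min_anchor
  # P[k, i]: mismatches of read[1..k] starting at i (NA when off the end)
  P <- matrix(NA_integer_, smax, n)
  acc <- integer(n)
  for (k in seq_len(smax)) {
    idx <- seq_len(n - k + 1L)
    acc[idx] <- acc[idx] + (s[idx + k - 1L] != r[k])
    acc[setdiff(seq_len(n), idx)] <- NA_integer_
    P[k, ] <- acc
  }
  # S[t, j]: mismatches of read[(L-t+1)..L] starting at j
  S <- matrix(NA_integer_, smax, n)
  acc <- rep(0L, n)
  for (t in seq_len(smax)) {
    nxt <- rep(NA_integer_, n)
    idx <- seq_len(n - t + 1L)
    prev <- if (t == 1L) rep(0L, length(idx)) else S[t - 1L, idx + 1L]
    nxt[idx] <- (s[idx] != r[L - t + 1L]) + prev
    S[t, ] <- nxt
  }
  out <- list()
  for (sp in min_anchor:smax) {
    t <- L - sp
    pi <- which(!is.na(P[sp, ]) & P[sp, ] <= max_mm)
    sj <- which(!is.na(S[t, ]) & S[t, ] <= max_mm)
    if (!length(pi) || !length(sj)) next
    for (i in pi) {
      gap <- sj - i - sp
      ok <- sj[gap >= min_intron & gap <= max_intron]
      for (j in ok) {
        tot <- P[sp, i] + S[t, j]
        if (tot <= max_mm)
          out[[length(out) + 1L]] <- data.frame(pos1 = i, len1 = sp,
                                                pos2 = j, len2 = t, mm = tot)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# canonical signature set of genome-mode mapping by pure enumeration
oracle_map_genome <- function(read, genome, max_mm, splice = splice_params()) {
  cand <- list()
  rc <- revcomp(read)
  for (chrom in names(genome)) {
    for (ori in c("+", "-")) {
      q <- if (ori == "+") read else rc
      h <- oracle_scan_contiguous(genome[[chrom]], q, max_mm)
      if (nrow(h))
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = chrom, strand = ori, contiguous = TRUE,
          blocks = paste0(h$pos, "-", h$pos + nchar(read) - 1L), mm = h$mm)
      hs <- oracle_scan_spliced(genome[[chrom]], q, max_mm, splice$min_anchor,
                                splice$min_intron, splice$max_intron)
      if (nrow(hs))
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = chrom, strand = ori, contiguous = FALSE,
          blocks = paste0(hs$pos1, "-", hs$pos1 + hs$len1 - 1L, ",",
                          hs$pos2, "-", hs$pos2 + hs$len2 - 1L), mm = hs$mm)
    }
  }
  if (!length(cand)) return(character(0))
  cand <- do.call(rbind, cand)
  cand <- cand[cand$mm == min(cand$mm), , drop = FALSE]
  if (any(cand$contiguous)) cand <- cand[cand$contiguous, , drop = FALSE]
  sort(unique(paste(cand$chrom, cand$strand, cand$blocks, sep = ":")))
}

# canonical signature set of transcriptome-mode mapping by enumeration
oracle_map_transcriptome <- function(read, model, genome, max_mm) {
  cand <- list()
  rc <- revcomp(read)
  for (tx in model_transcripts(model)) {
    if (!tx$chrom %in% names(genome)) next
    seq <- spliced_sequence(genome, tx)
    for (ori in c("+", "-")) {
      q <- if (ori == "+") read else rc
      h <- oracle_scan_contiguous(seq, q, max_mm)
      if (!nrow(h)) next
      strand <- if (ori == "+") tx$strand else setdiff(c("+", "-"), tx$strand)
      for (k in seq_len(nrow(h))) {
        b <- project_to_genome(tx, h$pos[k] - 1L, nchar(read))
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = tx$chrom, strand = strand,
          blocks = paste(paste0(b$start, "-", b$end), collapse = ","),
          mm = h$mm[k])
      }
    }
  }
  if (!length(cand)) return(character(0))
  cand <- do.call(rbind, cand)
  cand <- cand[cand$mm == min(cand$mm), , drop = FALSE]
  sort(unique(paste(cand$chrom, cand$strand, cand$blocks, sep = ":")))
}

batch_signatures <- function(batch, id) {
  h <- batch$hits[batch$hits$read_id == id, , drop = FALSE]
  sort(paste(h$chrom, h$strand, h$blocks, sep = ":"))
}

result_signatures <- function(res) {
  sort(vapply(res$alignments, function(a)
    paste(a$chrom, a$strand,
          paste(paste0(a$blocks$start, "-", a$blocks$end), collapse = ","),
          sep = ":"), ""))
}

# small random gene model over a genome, for round-trip/property tests
random_model <- function(genome, n_genes = 5L, name = "rand") {
  genes <- list()
  for (i in seq_len(n_genes)) {
    chrom <- sample(names(genome), 1L)
    n <- nchar(genome[[chrom]])
    n_ex <- sample(1:4, 1L)
    pos <- 1L
    starts <- integer(0); ends <- integer(0)
    for (k in seq_len(n_ex)) {
      gap <- sample(20:100, 1L); len <- sample(30:120, 1L)
      starts <- c(starts, pos + gap)
      ends <- c(ends, pos + gap + len - 1L)
      pos <- pos + gap + len
    }
    if (max(ends) > n) { starts <- starts[1L]; ends <- min(ends[1L], n) }
    sym <- sprintf("R%02d", i)
    n_tx <- sample(1:2, 1L)
    txs <- lapply(seq_len(n_tx), function(tno) {
      keep <- sort(sample(seq_along(starts),
                          sample(seq_along(starts), 1L)))
      tx_quick(sprintf("%s.t%d", sym, tno), sym, chrom,
               sample(c("+", "-"), 1L), starts[keep], ends[keep])
    })
    genes[[sym]] <- gene(sym, txs)
  }
  gene_model(name, genes)
}

# two-gene-model toy world used across tests (deterministic)
toy_world <- function(seed = 424L) {
  g <- generate_genome(c(chrA = 30000L, chrB = 20000L), seed)
  specs <- list(archetype_spec("identical", n_exons = 3L),
                archetype_spec("identical", n_exons = 1L),
                archetype_spec("nested_gene_vs_shared_transcript",
                               n_exons = 4L),
                archetype_spec("three_prime_extension", n_exons = 2L,
                               extension_length = 400L),
                archetype_spec("absent_chromosome", n_exons = 2L),
                archetype_spec("model_unique_gene", n_exons = 2L),
                archetype_spec("processed_retrocopy", n_exons = 3L))
  generate_annotation_pair(g, specs, seed)
}
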