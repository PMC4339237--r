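test_that("ml_status applies the exact #ML thresholds", {
  expect_identical(ml_status(0L), "unmapped")
  expect_identical(ml_status(1L), "unique")
  expect_identical(ml_status(7L), "multiple")
  expect_identical(unname(ml_status_vec(c(0L, 1L, 2L, 9L))),
                   c("unmapped", "unique", "multiple", "multiple"))
})

test_that("transcriptome mapping places exonic and junction reads", {
  set.seed(21)
  genome <- as_genome(c(c1 = rand_seq(5000)))
  tx <- tx_quick("t1", "G1", "c1", "+", c(1001, 2001), c(1100, 2100))
  model <- gene_model("m", list(gene("G1", list(tx))))
  # error-free read inside exon 1 -> unique, one block
  r1 <- substr(genome[["c1"]], 1011, 1060)
  res <- map_to_transcriptome(r1, model, genome, max_mismatch = 1L)
  expect_identical(res$ml, 1L)
  expect_identical(nrow(res$alignments[[1L]]$blocks), 1L)
  expect_identical(res$alignments[[1L]]$blocks$start, 1011L)
  expect_identical(ml_status(res), "unique")
  # read spanning the exon boundary -> two blocks abutting the exon ends
  mrna <- spliced_sequence(genome, tx)
  rj <- substr(mrna, 81, 130)  # covers last 20 of exon1 + first 30 of exon2
  resj <- map_to_transcriptome(rj, model, genome, max_mismatch = 1L)
  expect_identical(resj$ml, 1L)
  b <- resj$alignments[[1L]]$blocks
  expect_identical(nrow(b), 2L)
  expect_identical(b$end[1L], 1100L)
  expect_identical(b$start[2L], 2001L)
  # reverse-complemented read maps to the '-' placement strand
  rcres <- map_to_transcriptome(revcomp(r1), model, genome, 1L)
  expect_identical(rcres$ml, 1L)
  expect_identical(rcres$alignments[[1L]]$strand, "-")
})

test_that("a locus duplicated in a richer model turns unique reads multiple", {
  set.seed(22)
  genome <- as_genome(c(c1 = rand_seq(3000)))
  # duplicate the 201..400 region into 2201..2400
  seq1 <- substr(genome[["c1"]], 201, 400)
  chr <- genome[["c1"]]
  substr(chr, 2201, 2400) <- seq1
  genome <- as_genome(c(c1 = chr))
  tx_b1 <- tx_quick("b.t1", "Gb", "c1", "+", 201, 400)
  tx_e1 <- tx_quick("e.t1", "Ge", "c1", "+", 2201, 2400)
  model_a <- gene_model("A", list(gene("Gb", list(tx_b1))))
  model_b <- gene_model("B", list(gene("Gb", list(tx_b1)),
                                  gene("Ge", list(tx_e1))))
  read <- substr(genome[["c1"]], 231, 305)
  ra <- map_to_transcriptome(read, model_a, genome, 2L)
  rb <- map_to_transcriptome(read, model_b, genome, 2L)
  expect_identical(ra$ml, 1L)
  expect_identical(rb$ml, 2L)
})

test_that("isoform collapse: an added isoform sharing exons never raises ml", {
  set.seed(23)
  genome <- as_genome(c(c1 = rand_seq(4000)))
  tx1 <- tx_quick("t1", "G", "c1", "+", c(501, 1001, 1501),
                  c(600, 1100, 1600))
  tx2 <- tx_quick("t2", "G", "c1", "+", c(501, 1501), c(600, 1600))
  m1 <- gene_model("one", list(gene("G", list(tx1))))
  m2 <- gene_model("two", list(gene("G", list(tx1, tx2))))
  # reads from exon 1 (shared by both isoforms)
  for (off in c(0, 20, 45)) {
    read <- substr(genome[["c1"]], 501 + off, 550 + off)
    expect_identical(map_to_transcriptome(read, m2, genome, 1L)$ml,
                     map_to_transcriptome(read, m1, genome, 1L)$ml)
  }
})

test_that("genome mapping handles junction reads per the splice rules", {
  set.seed(24)
  genome <- as_genome(c(c1 = rand_seq(6000)))
  tx <- tx_quick("t", "G", "c1", "+", c(2001, 3001), c(2100, 3100))
  mrna <- spliced_sequence(genome, tx)
  # junction read with both segments >= min_anchor -> true blocks recovered
  rj <- substr(mrna, 81, 130)  # 20 bases exon1 + 30 bases exon2
  res <- map_to_genome(rj, genome, max_mismatch = 1L)
  sig <- result_signatures(res)
  expect_true("c1:+:2081-2100,3001-3030" %in% sig)
  # 4-base overhang < min_anchor = 10 and no contiguous placement -> unmapped
  r4 <- substr(mrna, 97, 146)  # 4 bases exon1 + 46 bases exon2
  res4 <- map_to_genome(r4, genome, max_mismatch = 0L)
  expect_identical(res4$ml, 0L)
  # non-junction read agrees with the transcriptome mode placement
  model <- gene_model("m", list(gene("G", list(tx))))
  rnj <- substr(genome[["c1"]], 2011, 2060)
  expect_identical(result_signatures(map_to_genome(rnj, genome, 1L)),
                   result_signatures(map_to_transcriptome(rnj, model,
                                                          genome, 1L)))
})

test_that("contiguous placements beat spliced ties; retro-copy multiplies junction reads", {
  set.seed(25)
  genome <- as_genome(c(c1 = rand_seq(8000)))
  tx <- tx_quick("t", "G", "c1", "+", c(1001, 2501), c(1150, 2650))
  mrna <- spliced_sequence(genome, tx)
  chr <- genome[["c1"]]
  substr(chr, 5001, 5000 + nchar(mrna)) <- mrna   # processed retro-copy
  genome2 <- as_genome(c(c1 = chr))
  rj <- substr(mrna, 131, 180)  # junction read, 20 + 30
  before <- map_to_genome(rj, genome, max_mismatch = 0L)
  after <- map_to_genome(rj, genome2, max_mismatch = 0L)
  # without the retro-copy: unique spliced placement
  expect_identical(before$ml, 1L)
  expect_identical(nrow(before$alignments[[1L]]$blocks), 2L)
  # with it: the contiguous copy placement wins the tie and is unique
  expect_identical(after$ml, 1L)
  expect_identical(nrow(after$alignments[[1L]]$blocks), 1L)
  expect_identical(after$alignments[[1L]]$blocks$start, 5131L)
  # a transcriptome containing both source and retro-copy gives ml = 2
  rc_tx <- tx_quick("rc", "GRC", "c1", "+", 5001, 5000 + nchar(mrna))
  m2 <- gene_model("rich", list(gene("G", list(tx_quick("t", "G", "c1", "+",
                                                        c(1001, 2501),
                                                        c(1150, 2650)))),
                                gene("GRC", list(rc_tx))))
  expect_identical(map_to_transcriptome(rj, m2, genome2, 0L)$ml, 2L)
})

test_that("map_sequential falls back to the genome only when needed", {
  set.seed(26)
  genome <- as_genome(c(c1 = rand_seq(4000)))
  tx <- tx_quick("t", "G", "c1", "+", 1001, 1200)
  model <- gene_model("m", list(gene("G", list(tx))))
  annotated <- substr(genome[["c1"]], 1051, 1125)
  intergenic <- substr(genome[["c1"]], 3001, 3075)
  r1 <- map_sequential(annotated, model, genome, 1L)
  expect_identical(r1$mode, "transcriptome_plus_genome")
  expect_identical(result_signatures(r1),
                   result_signatures(map_to_transcriptome(annotated, model,
                                                          genome, 1L)))
  r2 <- map_sequential(intergenic, model, genome, 1L)
  expect_identical(r2$ml, 1L)
  expect_identical(map_to_transcriptome(intergenic, model, genome, 1L)$ml, 0L)
  # batch property: sequential mapped fraction >= transcriptome-only
  sim <- simulate_reads(genome, model, NULL, 40L, 50L, 0.01, seed = 5)
  extra <- setNames(vapply(1:10, function(i) rand_seq(50), ""),
                    paste0("x", 1:10))
  reads <- c(sim$reads, extra)
  b_t <- map_reads(reads, "transcriptome_only", model, genome, 1L)
  b_s <- map_reads(reads, "transcriptome_plus_genome", model, genome, 1L)
  expect_gte(mean(b_s$ml >= 1L), mean(b_t$ml >= 1L))
})

test_that("mapping results are deterministic and canonically ordered", {
  set.seed(27)
  genome <- as_genome(c(c1 = rand_seq(3000), c2 = rand_seq(3000)))
  model <- random_model(genome, 4L)
  sim <- simulate_reads(genome, model, NULL, 30L, 40L, 0.02, seed = 9)
  b1 <- map_reads(sim$reads, "none", genome = genome, max_mismatch = 1L)
  b2 <- map_reads(sim$reads, "none", genome = genome, max_mismatch = 1L)
  expect_identical(b1, b2)
  h <- b1$hits
  for (id in unique(h$read_id)) {
    hh <- h[h$read_id == id, , drop = FALSE]
    first_start <- as.integer(sub("-.*$", "", hh$blocks))
    expect_false(is.unsorted(order(hh$chrom, first_start, hh$strand)))
  }
})

test_that("genome and transcriptome mapping match the brute-force oracles", {
  set.seed(28)
  genome <- as_genome(c(c1 = rand_seq(4000), c2 = rand_seq(2500)))
  model <- random_model(genome, 4L)
  sim <- simulate_reads(genome, model, NULL, 25L, 40L, 0.03, seed = 13)
  junk <- setNames(vapply(1:5, function(i) rand_seq(40), ""),
                   paste0("j", 1:5))
  reads <- c(sim$reads, junk)
  bg <- map_reads(reads, "none", genome = genome, max_mismatch = 2L)
  bt <- map_reads(reads, "transcriptome_only", model, genome,
                  max_mismatch = 2L)
  for (id in names(reads)) {
    expect_identical(batch_signatures(bg, id),
                     oracle_map_genome(reads[[id]], genome, 2L),
                     info = paste("genome", id))
    expect_identical(batch_signatures(bt, id),
                     oracle_map_transcriptome(reads[[id]], model, genome, 2L),
                     info = paste("transcriptome", id))
  }
})

test_that("an empty model leaves every read unmapped without error", {
  genome <- as_genome(c(c1 = "ACGTACGTACGTACGTACGT"))
  b <- map_reads(c(r1 = "ACGTACGT"), "transcriptome_only",
                 gene_model("empty"), genome, 0L)
  expect_identical(unname(b$ml), 0L)
})
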