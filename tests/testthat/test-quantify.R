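# two-gene worlds reused below: a nested pair (short gene fully inside the
# container's exon) and a shared-identical-transcript pair
nested_world <- function(seed = 51L) {
  set.seed(seed)
  genome <- as_genome(c(c7 = rand_seq(8000)))
  container <- tx_quick("mt.t1", "MT", "c7", "-", c(1001, 3001, 4001),
                        c(1800, 3400, 4600))
  nested <- tx_quick("lz.t1", "LZ", "c7", "-", 1201, 1377)  # 177 bp
  list(genome = genome,
       model = gene_model("ens", list(gene("MT", list(container)),
                                      gene("LZ", list(nested)))),
       container = container, nested = nested)
}

shared_world <- function(seed = 52L) {
  set.seed(seed)
  genome <- as_genome(c(c4 = rand_seq(8000)))
  t1 <- tx_quick("py.t1", "PY", "c4", "-", c(1001, 2001), c(1500, 2856))
  t2 <- tx_quick("pu.t1", "PU", "c4", "-", c(1001, 2001), c(1500, 2856))
  list(genome = genome,
       model = gene_model("ref", list(gene("PY", list(t1)),
                                      gene("PU", list(t2)))))
}

test_that("compatible_genes finds every gene whose transcript explains the alignment", {
  w <- nested_world()
  # read inside the nested gene region: compatible with both genes
  aln_both <- list(chrom = "c7", blocks = data.frame(start = 1210L,
                                                     end = 1284L))
  expect_identical(compatible_genes(aln_both, w$model), c("LZ", "MT"))
  # read in the container's private exon: container only
  aln_mt <- list(chrom = "c7", blocks = data.frame(start = 3050L,
                                                   end = 3124L))
  expect_identical(compatible_genes(aln_mt, w$model), "MT")
  # junction alignment matching the container's intron structure
  aln_j <- list(chrom = "c7", blocks = data.frame(start = c(1750L, 3001L),
                                                  end = c(1800L, 3024L)))
  expect_identical(compatible_genes(aln_j, w$model), "MT")
  # intergenic placement: empty set
  aln_ig <- list(chrom = "c7", blocks = data.frame(start = 6000L,
                                                   end = 6074L))
  expect_identical(compatible_genes(aln_ig, w$model), character(0))
})

test_that("count_reads sends all shared reads to the container of a nested gene", {
  w <- nested_world()
  # saturating error-free reads from both transcripts
  reads <- c(simulate_reads(w$genome, w$model,
                            c(mt.t1 = 1, lz.t1 = 3), 400L, 75L, 0,
                            seed = 5)$reads)
  b <- map_reads(reads, "transcriptome_only", w$model, w$genome, 0L)
  expect_true(all(b$ml == 1L))   # every placement unique at the locus
  tb <- count_reads(b, w$model, 75L)
  expect_identical(tb$count[tb$symbol == "LZ"], 0)
  expect_identical(tb$count[tb$symbol == "MT"], as.numeric(length(reads)))
  expect_identical(attr(tb, "n_counted"), length(reads))
})

test_that("count_reads splits 50/50 on a shared identical transcript", {
  w <- shared_world()
  reads <- simulate_reads(w$genome, w$model, NULL, 200L, 75L, 0,
                          seed = 6)$reads
  b <- map_reads(reads, "transcriptome_only", w$model, w$genome, 0L)
  expect_true(all(b$ml == 1L))   # identical isoforms collapse genomically
  tb <- count_reads(b, w$model, 75L)
  expect_identical(tb$count[tb$symbol == "PY"], 100)
  expect_identical(tb$count[tb$symbol == "PU"], 100)
  # conservation: summed counts = number of counted alignments, exactly
  expect_identical(sum(tb$count), as.numeric(attr(tb, "n_counted")))
})

test_that("count conservation holds on a mixed synthetic run", {
  w <- toy_world()
  sim <- simulate_reads(w$genome, w$model_a, NULL, 300L, 60L, 0.005,
                        seed = 12)
  for (model in list(w$model_a, w$model_b)) {
    # model B warns about its patch-chromosome transcript; that is the point
    b <- suppressWarnings(
      map_reads(sim$reads, "transcriptome_only", model, w$genome, 1L))
    tb <- count_reads(b, model, 60L)
    expect_equal(sum(tb$count), attr(tb, "n_counted"), tolerance = 1e-9)
    expect_lte(attr(tb, "n_counted"), sum(b$ml == 1L))
    expect_true(all(tb$count >= 0))
  }
})

test_that("count_reads rejects non-unique input", {
  w <- shared_world()
  dup <- data.frame(read_id = c("r1", "r1"), chrom = "c4",
                    blocks = c("1001-1075", "2001-2075"))
  expect_error(count_reads(dup, w$model, 75L), "unique")
})

test_that("a 3'-extension gains the extended model's reads", {
  set.seed(53)
  genome <- as_genome(c(c3 = rand_seq(12000)))
  ext <- tx_quick("e.t1", "PK", "c3", "+", c(1001, 3001), c(1300, 8000))
  short <- tx_quick("r.t1", "PK", "c3", "+", c(1001, 3001), c(1300, 3616))
  m_ext <- gene_model("ens", list(gene("PK", list(ext))))
  m_short <- gene_model("ref", list(gene("PK", list(short))))
  sim <- simulate_reads(genome, m_ext, NULL, 300L, 75L, 0, seed = 7)
  count_for <- function(model) {
    b <- map_reads(sim$reads, "transcriptome_only", model, genome, 0L)
    tb <- count_reads(b, model, 75L)
    tb$count[tb$symbol == "PK"]
  }
  expect_gt(count_for(m_ext), count_for(m_short))
})

test_that("ratio matches the printed pseudocount formula", {
  expect_identical(ratio(0, 0), 1)
  expect_identical(ratio(99, 49), 2)
  expect_identical(ratio(1094, 492), 1095 / 493)
  set.seed(54)
  a <- rpois(50, 20); b <- rpois(50, 20)
  expect_identical(ratio(a, b), ratio(b, a))
  expect_true(all(ratio(a, b) >= 1))
  expect_error(ratio(-1, 3), "non-negative")
})

test_that("concordance_table reproduces hand enumeration", {
  # 10 common genes: ratios {1,1,1,1,1.06,1.12,1.25,1.6,3,120}, 2 both-zero
  counts_a <- c(g1 = 0, g2 = 0, g3 = 7, g4 = 19, g5 = 49, g6 = 24, g7 = 4,
                g8 = 7, g9 = 29, g10 = 119)
  counts_b <- c(g1 = 0, g2 = 0, g3 = 7, g4 = 19, g5 = 52, g6 = 27,
                g7 = 5.25, g8 = 11.8, g9 = 89, g10 = 0)
  # check the intended ratio spectrum before asserting on the table
  expect_equal(unname(ratio(counts_a, counts_b)),
               c(1, 1, 1, 1, 1.06, 1.12, 1.25, 1.6, 3, 120),
               tolerance = 1e-9)
  ta <- count_table(counts_a, "A"); tb <- count_table(counts_b, "B")
  row <- concordance_table(ta, tb)
  expect_identical(row$no_expr, 20)
  expect_identical(row$same, 20)
  expect_identical(unname(unlist(row[paste0("ge_",
    c(1.05, 1.1, 1.2, 1.5, 2, 5, 10, 100))])),
    c(60, 50, 40, 30, 20, 10, 10, 10))
  expect_identical(attr(row, "n_common"), 10L)
})

test_that("concordance of a table with itself is NoExpr + Same = 100", {
  set.seed(55)
  counts <- c(setNames(rpois(20, 5), paste0("g", 1:20)), z1 = 0, z2 = 0)
  ta <- count_table(counts, "A")
  row <- concordance_table(ta, ta)
  expect_identical(row$no_expr + row$same, 100)
  expect_true(all(unlist(row[grep("^ge_", names(row))]) == 0))
  # threshold columns are non-increasing for random tables
  for (rep in 1:5) {
    tb <- count_table(setNames(rpois(22, 5), names(counts)), "B")
    r <- concordance_table(ta, tb)
    cols <- unlist(r[grep("^ge_", names(r))])
    expect_true(all(diff(cols) <= 0))
  }
  expect_error(concordance_table(ta, count_table(c(other = 1), "B")),
               "no gene symbols")
})

test_that("log2_ratio and de_concordance follow the pseudocount formulas", {
  expect_identical(log2_ratio(10, 10), 0)
  expect_identical(log2_ratio(15, 3), 2)
  set.seed(56)
  a <- rpois(30, 10); b <- rpois(30, 10)
  expect_equal(log2_ratio(a, b), -log2_ratio(b, a), tolerance = 1e-12)
  syms <- paste0("g", 1:3)
  a1 <- count_table(setNames(c(0, 10, 5), syms), "A", "s1")
  a2 <- count_table(setNames(c(100, 10, 5), syms), "A", "s2")
  b1 <- count_table(setNames(c(100, 10, 5), syms), "B", "s1")
  b2 <- count_table(setNames(c(100, 10, 5), syms), "B", "s2")
  de <- de_concordance(a1, a2, b1, b2)
  # gene g1: |log2(1/101) - log2(101/101)| = log2(101) ~ 6.66 -> all bins
  expect_identical(unname(de$counts), c(1L, 1L, 1L))
  expect_equal(de$per_gene$abs_diff[1L], log2(101), tolerance = 1e-12)
  # identity: model A tables duplicated as model B
  de0 <- de_concordance(a1, a2, a1, a2)
  expect_identical(unname(de0$counts), c(0L, 0L, 0L))
  # nested bins on random tables
  for (rep in 1:5) {
    t1 <- count_table(setNames(rpois(40, 3), paste0("g", 1:40)), "A", "s1")
    t2 <- count_table(setNames(rpois(40, 3), paste0("g", 1:40)), "A", "s2")
    t3 <- count_table(setNames(rpois(40, 3), paste0("g", 1:40)), "B", "s1")
    t4 <- count_table(setNames(rpois(40, 3), paste0("g", 1:40)), "B", "s2")
    d <- de_concordance(t1, t2, t3, t4)
    expect_true(d$counts[["gt1"]] >= d$counts[["gt2"]])
    expect_true(d$counts[["gt2"]] >= d$counts[["gt5"]])
  }
})

test_that("nested gene counts zero iff it lacks a unique region (cross-module)", {
  w <- nested_world()
  rel <- within_model_relations(w$model, 75L)
  expect_identical(rel$relation, "nested_no_unique_region")
  reads <- simulate_reads(w$genome, w$model, c(lz.t1 = 5, mt.t1 = 1),
                          300L, 75L, 0, seed = 20)$reads
  b <- map_reads(reads, "transcriptome_only", w$model, w$genome, 0L)
  tb <- count_reads(b, w$model, 75L)
  expect_identical(tb$count[tb$symbol == rel$nested_symbol], 0)
})

test_that("count tables survive a TSV round trip at 2-decimal rendering", {
  tb <- count_table(c(a = 0, b = 12.5, c = 3), "m", "s")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_tsv(tb, f)
  back <- read_count_tsv(f, "m", "s")
  expect_equal(back$count, tb$count, tolerance = 1e-9)
  expect_identical(back$symbol, tb$symbol)
})
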