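calls_df <- function(chrom, start, end, type = "loss", sample = "S1") {
  data.frame(chrom = chrom, start = start, end = end, cnv_type = type,
             sample_id = sample, stringsAsFactors = FALSE)
}

test_that("merge coalesces overlaps and book-ended intervals per type", {
  calls <- calls_df("chr1", c(100, 150), c(200, 300), sample = c("a", "b"))
  m <- merge_same_type(calls, "loss")
  expect_equal(as.data.frame(m),
               data.frame(chrom = "chr1", start = 100, end = 300),
               ignore_attr = TRUE)
  expect_equal(attr(m, "label"), "merged_loss")

  # different chromosomes never merge
  two <- merge_same_type(calls_df(c("chr1", "chr2"), c(100, 100),
                                  c(200, 200)), "loss")
  expect_equal(nrow(two), 2)

  # book-ended intervals coalesce (MergeBED default)
  be <- merge_same_type(calls_df("chr1", c(0, 100), c(100, 200)), "loss")
  expect_equal(as.data.frame(be),
               data.frame(chrom = "chr1", start = 0, end = 200),
               ignore_attr = TRUE)

  # only the requested type participates
  mixed <- rbind(calls_df("chr1", 0, 100, "loss"),
                 calls_df("chr1", 50, 150, "gain"))
  expect_equal(as.data.frame(merge_same_type(mixed, "loss")),
               data.frame(chrom = "chr1", start = 0, end = 100),
               ignore_attr = TRUE)
  expect_error(merge_same_type(mixed, "dup"), "loss.*gain")
})

test_that("merge matches the per-base oracle on random seeded intervals", {
  lens <- c(chrA = 2000, chrB = 1500)
  set.seed(42)
  for (rep in 1:10) {
    bed <- random_bed(50, lens)
    calls <- cbind(bed, cnv_type = "loss", sample_id = "S1")
    expect_true(bed_equal(merge_same_type(calls, "loss"),
                          oracle_merge(bed, lens)))
  }
})

test_that("shared and unique regions follow textbook set algebra", {
  loss <- region_set(data.frame(chrom = "chr1", start = 0, end = 100))
  gain <- region_set(data.frame(chrom = "chr1", start = 50, end = 150))
  expect_equal(as.data.frame(shared_regions(loss, gain)),
               data.frame(chrom = "chr1", start = 50, end = 100),
               ignore_attr = TRUE)
  u <- unique_regions(loss, gain)
  expect_equal(as.data.frame(u$unique_loss),
               data.frame(chrom = "chr1", start = 0, end = 50),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(u$unique_gain),
               data.frame(chrom = "chr1", start = 100, end = 150),
               ignore_attr = TRUE)

  # disjoint inputs: empty intersection, differences return inputs
  far <- region_set(data.frame(chrom = "chr1", start = 500, end = 600))
  expect_equal(nrow(shared_regions(loss, far)), 0)
  ud <- unique_regions(loss, far)
  expect_true(bed_equal(ud$unique_loss, loss))
  expect_true(bed_equal(ud$unique_gain, far))

  # identical inputs: both uniques empty
  ui <- unique_regions(loss, loss)
  expect_equal(nrow(ui$unique_loss), 0)
  expect_equal(nrow(ui$unique_gain), 0)
})

test_that("set operations match the per-base oracle and partition the union", {
  lens <- c(chrA = 3000, chrB = 2000)
  set.seed(99)
  bp <- function(df) if (nrow(df)) sum(df$end - df$start) else 0
  for (rep in 1:10) {
    loss <- region_set(oracle_merge(random_bed(20, lens), lens))
    gain <- region_set(oracle_merge(random_bed(20, lens), lens))
    sh <- shared_regions(loss, gain)
    u <- unique_regions(loss, gain)
    expect_true(bed_equal(sh, oracle_combine(loss, gain, `&`, lens)))
    expect_true(bed_equal(u$unique_loss,
                          oracle_combine(loss, gain,
                                         function(l, g) l & !g, lens)))
    expect_true(bed_equal(u$unique_gain,
                          oracle_combine(loss, gain,
                                         function(l, g) g & !l, lens)))
    # total bp identity: |uL| + |uG| + 2|shared| = |loss| + |gain|
    expect_equal(bp(u$unique_loss) + bp(u$unique_gain) + 2 * bp(sh),
                 bp(loss) + bp(gain))
  }
})

test_that("merging is idempotent", {
  set.seed(5)
  bed <- random_bed(30, c(chr1 = 1000))
  calls <- cbind(bed, cnv_type = "gain", sample_id = "S1")
  once <- merge_same_type(calls, "gain")
  twice <- merge_same_type(cbind(as.data.frame(once), cnv_type = "gain",
                                 sample_id = "S1"), "gain")
  expect_true(bed_equal(once, twice))
})

test_that("gene annotation uses >= 1 bp overlap, half-open adjacency excluded", {
  gm <- data.frame(chrom = "chr1", start = c(150, 200), end = c(160, 300),
                   symbol = c("IN", "ADJ"),
                   gene_type = "protein_coding", stringsAsFactors = FALSE)
  rs <- region_set(data.frame(chrom = "chr1", start = 100, end = 200))
  ann <- annotate_genes(rs, gm)
  expect_equal(ann$genes, "IN")
  expect_equal(ann$per_region[[1]], "IN")
})

test_that("gene annotation matches an all-pairs overlap scan", {
  lens <- c(chrA = 5000, chrB = 5000)
  set.seed(21)
  regions <- region_set(oracle_merge(random_bed(30, lens, max_width = 400),
                                     lens))
  genes <- random_bed(100, lens, max_width = 200)
  genes$symbol <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$gene_type <- sample(c("protein_coding", "lncRNA"), 100,
                            replace = TRUE)
  ann <- annotate_genes(regions, genes)
  brute <- sort(unique(genes$symbol[vapply(seq_len(nrow(genes)), function(j) {
    any(genes$chrom[j] == regions$chrom &
          genes$start[j] < regions$end & regions$start < genes$end[j])
  }, logical(1))]))
  expect_equal(ann$genes, brute)

  # invariant to region order
  shuf <- regions[sample(nrow(regions)), ]
  expect_equal(annotate_genes(shuf, genes)$genes, ann$genes)

  # type filter restricts the union
  lnc <- annotate_genes(regions, genes, gene_type_filter = "lncRNA")
  expect_true(all(lnc$genes %in% genes$symbol[genes$gene_type == "lncRNA"]))
})

test_that("malformed gene models and regions raise located errors", {
  gm_bad <- data.frame(chrom = c("chr1", "chr1"), start = c(0, 500),
                       end = c(100, 400), symbol = c("A", "B"),
                       gene_type = "protein_coding")
  expect_error(annotate_genes(region_set(data.frame(chrom = "chr1",
                                                    start = 0, end = 10)),
                              gm_bad),
               "line 2")
  expect_error(region_set(data.frame(chrom = "chr1", start = 10, end = 10)),
               "row 1")
})

test_that("BED readers round-trip calls and honor the one-based flag", {
  dir <- withr::local_tempdir()
  calls <- calls_df("chr1", c(100, 300), c(200, 400),
                    type = c("loss", "gain"), sample = c("S1", "S2"))
  p <- file.path(dir, "calls.bed")
  write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read_cnv_bed(p)
  expect_equal(back, calls)
  one <- read_cnv_bed(p, one_based = TRUE)
  expect_equal(one$start, calls$start - 1)
  expect_equal(one$end, calls$end)

  rs <- merge_same_type(calls, "loss")
  pb <- file.path(dir, "rs.bed")
  write_region_bed(rs, pb)
  expect_equal(readLines(pb), "chr1\t100\t200")
})
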