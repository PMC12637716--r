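test_that("read_bed sorts, validates, and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "chr1\t100\t200", "chr1\t50\t80"), f)
  rs <- read_bed(f)
  expect_s3_class(rs, "region_set")
  expect_equal(rs$start, c(50L, 100L))
  expect_equal(rs$end, c(80L, 200L))

  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0L)

  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f), ">= 3")
})

test_that("BED round-trip is the identity on fuzzed region sets", {
  set.seed(11)
  rs <- random_region_set(1000L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, f)
  back <- read_bed(f)
  expect_equal(as.data.frame(back)[, c("chrom", "start", "end")],
               as.data.frame(rs)[, c("chrom", "start", "end")])
  # unsorted input is written in sorted order
  shuf <- as.data.frame(rs)[sample(nrow(rs)), ]
  write_bed(as_region_set(shuf), f)
  expect_equal(read_bed(f)$start, back$start)
})

test_that("fragment ingestion groups by barcode, filters, and is codec/order independent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lines <- c("chr1\t100\t150\tB1\t2", "chr1\t300\t400\tB2\t1",
             "chr2\t10\t60\tB1\t1")
  writeLines(lines, f)
  st <- read_fragments(f)
  expect_setequal(names(st$fragments), c("B1", "B2"))
  expect_equal(st$summary$n_fragments[st$summary$barcode == "B1"], 2L)

  st1 <- read_fragments(f, allowed_barcodes = "B1")
  expect_equal(names(st1$fragments), "B1")

  # permuting input lines yields an identical store
  writeLines(rev(lines), f)
  expect_equal(read_fragments(f)$fragments, st$fragments)

  # gzip transparency
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  expect_equal(read_fragments(gz)$fragments, st$fragments)

  # 4-column dialect gets count = 1
  writeLines("chr1\t5\t25\tB9", f)
  expect_equal(read_fragments(f)$fragments$B9$count, 1L)
  # wrong column count is a parse error
  writeLines("chr1\t5\t25", f)
  expect_error(read_fragments(f), "column")
  # empty after filtering warns
  writeLines(lines, f)
  expect_warning(read_fragments(f, allowed_barcodes = "nope"), "empty")
})

test_that("count-matrix loading resolves orientation against sidecars", {
  dir <- withr::local_tempdir()
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 3, 2, 3),
                            x = c(1, 7, 2, 1), dims = c(2, 3))
  mtx <- file.path(dir, "m.mtx"); Matrix::writeMM(m, mtx)
  peaks <- file.path(dir, "peaks.bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t300", "chr1\t400\t500"), peaks)
  bcs <- file.path(dir, "barcodes.txt"); writeLines(c("c1", "c2"), bcs)
  got <- read_count_matrix(mtx, peaks, bcs)
  expect_equal(dim(got$matrix), c(2L, 3L))
  expect_equal(length(got$matrix@x), 4L)

  # peaks x cells storage is transposed on load to the same result
  mtx_t <- file.path(dir, "mt.mtx"); Matrix::writeMM(Matrix::t(m), mtx_t)
  got_t <- read_count_matrix(mtx_t, peaks, bcs)
  expect_equal(as.matrix(got_t$matrix), as.matrix(got$matrix))

  writeLines(c("c1", "c2", "c3"), bcs)
  expect_error(read_count_matrix(mtx, peaks, bcs), "3 barcode")
})

test_that("TSS extraction is strand-correct, deduplicated, and idempotent", {
  f <- withr::local_tempfile(fileext = ".gtf")
  gtf <- c(
    'chr1\tx\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\ttranscript\t1001\t2000\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tx\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "g1"; transcript_id "t3";',
    'chr1\tx\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  writeLines(gtf, f)
  tss <- extract_tss(f)
  # + strand: GTF 1-based start 1001 -> 0-based 1000; - strand: end 2000 -> 1999
  expect_equal(nrow(tss), 2L)  # t1 and t3 share chrom/pos/strand -> collapsed
  expect_equal(tss$position[tss$strand == "+"], 1000L)
  expect_equal(tss$position[tss$strand == "-"], 1999L)
  expect_equal(extract_tss(f), tss)
})

test_that("signal tracks parse, validate values, and round-trip", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t2.5", "chr1\t50\t150\t1.0"), f)
  st <- read_signal_track(f)
  expect_s3_class(st, "signal_track")
  expect_equal(st$value, c(2.5, 1.0))

  writeLines(character(0), f)
  expect_equal(nrow(read_signal_track(f)), 0L)

  writeLines("chr1\t0\t100\tnotanumber", f)
  expect_error(read_signal_track(f), "non-numeric")

  g <- withr::local_tempfile(fileext = ".bedgraph")
  write_signal_track(st[0, ], g)
  expect_equal(nrow(read_signal_track(g)), 0L)
})
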