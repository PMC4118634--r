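test_that("SAM reading skips unmapped records and round-trips simulator output", {
  si <- tiny_seqinfo()
  set.seed(42)
  reads <- make_reads("chrA", sample(1:9900, 100, replace = TRUE), 49L, si,
                      is_unique = c(rep(TRUE, 80), rep(FALSE, 20)),
                      strand = sample(c("+", "-"), 100, replace = TRUE))
  f <- tempfile(fileext = ".sam")
  write_sam(reads, f, unmapped = 7L)
  ## independent line count of the fixture: 93 mapped would be 100 here,
  ## 7 extra unmapped records must be skipped
  body <- readLines(f)
  body <- body[!startsWith(body, "@")]
  expect_equal(length(body), 107L)
  got <- read_alignments(f, "sam", line_id = "P1")
  expect_equal(length(got), 100L)
  expect_equal(S4Vectors::metadata(got)$n_skipped, 7L)
  expect_equal(start(got), start(reads))
  expect_equal(as.character(strand(got)), as.character(strand(reads)))
  expect_equal(mcols(got)$is_unique, mcols(reads)$is_unique)
  expect_true(all(mcols(got)$line_id == "P1"))
})

test_that("empty and malformed alignment input honour the I/O contract", {
  si <- tiny_seqinfo()
  ## header-only SAM: empty stream, zero skipped
  f <- tempfile(fileext = ".sam")
  write_sam(make_reads("chrA", integer(0), 49L, si), f)
  got <- read_alignments(f, "sam")
  expect_length(got, 0L)
  expect_equal(S4Vectors::metadata(got)$n_skipped, 0L)
  ## BED record on an undeclared chromosome names the offender
  fb <- tempfile(fileext = ".bed")
  writeLines(c("chrA\t0\t49\tr1\t1\t+",
               "chrZZ\t10\t59\tr2\t1\t+",
               "chrB\t5\t54\tr3\t0\t-"), fb)
  expect_error(read_alignments(fb, "bed", seqinfo = si), "chrZZ")
  ## malformed SAM line reported by number
  fs <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrA\tLN:10000", "read1\tnotanumber\tchrA"), fs)
  expect_error(read_alignments(fs, "sam"), "line 2")
})

test_that("peak readers handle MACS and BED dialects and reject bad intervals", {
  ## header-only MACS file -> empty
  fm <- tempfile(fileext = ".xls")
  writeLines(c("# MACS output", paste("chr", "start", "end", "length",
                                      "summit", sep = "\t")), fm)
  expect_length(read_peaks(fm, "macs_xls"), 0L)
  ## five well-formed rows, input order preserved
  rows <- data.frame(chr = "chrA", start = c(500, 100, 900, 300, 700),
                     end = c(650, 260, 1080, 460, 890))
  writeLines(c(paste("chr", "start", "end", sep = "\t"),
               sprintf("%s\t%d\t%d", rows$chr, rows$start, rows$end)), fm)
  pk <- read_peaks(fm, "macs_xls")
  expect_length(pk, 5L)
  expect_equal(start(pk), rows$start)  # MACS coordinates are 1-based
  ## the same intervals as 0-based BED land on identical internal coords
  fb <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d", rows$chr, rows$start - 1L, rows$end), fb)
  expect_equal(ranges(read_peaks(fb, "bed")), ranges(pk))
  ## end <= start is rejected with the line number
  writeLines(c("chrA\t100\t200", "chrA\t500\t500"), fb)
  expect_error(read_peaks(fb, "bed"), "line 2")
})

test_that("BED write/read round trip is byte-identical", {
  si <- tiny_seqinfo()
  gr <- GRanges(c("chrA", "chrA", "chrB"),
                IRanges(c(101, 501, 42), width = c(50, 120, 300)),
                strand = c("+", "-", "+"), seqinfo = si)
  mcols(gr)$name <- c("a", "b", "c")
  mcols(gr)$score <- c(1, 0, 1)
  f1 <- tempfile(fileext = ".bed")
  f2 <- tempfile(fileext = ".bed")
  write_bed(gr, f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_bed(f1)
  expect_equal(ranges(rt), ranges(gr))
  expect_equal(mcols(rt)$score, mcols(gr)$score)
})

test_that("GFF3 intron derivation and coordinate conversion are exact", {
  ## two-exon mRNA with exons 1-100 and 201-300 (1-based inclusive)
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\tsrc\tgene\t1\t300\t.\t+\t.\tID=gX",
    "chrA\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gX.1;Parent=gX",
    "chrA\tsrc\texon\t1\t100\t.\t+\t.\tParent=gX.1",
    "chrA\tsrc\texon\t201\t300\t.\t+\t.\tParent=gX.1",
    "chrA\tsrc\tCDS\t1\t100\t.\t+\t.\tParent=gX.1",
    "chrA\tsrc\tCDS\t201\t300\t.\t+\t.\tParent=gX.1"), f)
  ann <- suppressMessages(read_gff3(f, seqinfo = tiny_seqinfo()))
  introns <- ann$parts[mcols(ann$parts)$part == "intron"]
  expect_length(introns, 1L)
  expect_equal(start(introns), 101L)
  expect_equal(end(introns), 200L)
  ## single-exon gene without UTR rows: one CDS, no introns
  f2 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\tsrc\tgene\t1000\t1500\t.\t-\t.\tID=gY",
    "chrA\tsrc\tmRNA\t1000\t1500\t.\t-\t.\tID=gY.1;Parent=gY",
    "chrA\tsrc\texon\t1000\t1500\t.\t-\t.\tParent=gY.1",
    "chrA\tsrc\tCDS\t1000\t1500\t.\t-\t.\tParent=gY.1"), f2)
  ann2 <- suppressMessages(read_gff3(f2, seqinfo = tiny_seqinfo()))
  expect_equal(sum(mcols(ann2$parts)$part == "CDS"), 1L)
  expect_equal(sum(mcols(ann2$parts)$part == "intron"), 0L)
})

test_that("GFF3 structural errors are rejected", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\tsrc\tgene\t1\t300\t.\t+\t.\tID=gX",
    "chrA\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gX.1;Parent=gOrphan",
    "chrA\tsrc\texon\t1\t300\t.\t+\t.\tParent=gX.1"), f)
  expect_error(suppressMessages(read_gff3(f)), "Parent")
  writeLines(c(
    "##gff-version 3",
    "chrA\tsrc\tgene\t1\t300\t.\t+\t.\tID=gX",
    "chrA\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gX.1;Parent=gX",
    "chrA\tsrc\texon\t1\t300\t.\t+\t.\tParent=gX.1",
    "chrA\tsrc\tCDS\t1\t200\t.\t+\t.\tParent=gX.1",
    "chrA\tsrc\tCDS\t150\t300\t.\t+\t.\tParent=gX.1"), f)
  expect_error(suppressMessages(read_gff3(f)), "overlapping CDS")
})

test_that("simulator GFF3 round-trips through the reader", {
  cfg <- small_config(seed = 3L)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  f <- tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                              seqlengths = width(genome))
  back <- suppressMessages(read_gff3(f, seqinfo = si))
  expect_equal(length(back$genes), length(ann$genes))
  expect_equal(ranges(sort(back$genes)), ranges(sort(ann$genes)))
  ## per-part counts and coordinates survive the 1-based round trip
  for (p in c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")) {
    a <- sort(ann$parts[mcols(ann$parts)$part == p])
    b <- sort(back$parts[mcols(back$parts)$part == p])
    expect_equal(ranges(b), ranges(a), info = p)
  }
  ## writing the reader's result again reproduces the file byte for byte
  f2 <- tempfile(fileext = ".gff3")
  write_gff3(back, f2)
  expect_identical(readLines(f2), readLines(f))
})
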