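test_that("read_snvs parses TSV, sorts, and filters non-SNVs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tepoch", f)
  out <- read_snvs(f)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 0L)

  # rows deliberately unsorted; one indel and one multi-base alt to skip
  writeLines(c(
    "sample_id\tchrom\tpos\tref\talt\tepoch\tphase_group",
    "S1\tchr2\t500\tC\tT\tsubclonal\t",
    "S1\tchr1\t900\tG\tA\tclonal_unspecified\tPS1",
    "S1\tchr1\t100\tC\tG\tearly_clonal\tPS1",
    "S1\tchr1\t200\tCT\tC\tearly_clonal\t",
    "S1\tchr1\t300\tA\tATT\tearly_clonal\t"), f)
  out <- suppressMessages(read_snvs(f))
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_skipped"), 2L)
  expect_equal(out$pos, c(100, 900, 500))        # sorted by (chrom, pos)
  expect_equal(out$epoch, c("early_clonal", "clonal_unspecified", "subclonal"))
  expect_equal(out$phase_group, c("PS1", "PS1", NA_character_))

  # parser output identical regardless of input row order
  writeLines(c(
    "sample_id\tchrom\tpos\tref\talt\tepoch\tphase_group",
    "S1\tchr1\t100\tC\tG\tearly_clonal\tPS1",
    "S1\tchr1\t900\tG\tA\tclonal_unspecified\tPS1",
    "S1\tchr2\t500\tC\tT\tsubclonal\t"), f)
  out2 <- read_snvs(f)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)

  # closed epoch vocabulary
  writeLines(c("chrom\tpos\tref\talt\tepoch", "chr1\t10\tC\tT\tlate"), f)
  expect_error(read_snvs(f), "allowed")
})

test_that("read_snvs parses VCF with configured INFO keys", {
  skip_if_not_installed("VariantAnnotation")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##INFO=<ID=EPOCH,Number=1,Type=String,Description="timing">',
    '##INFO=<ID=PGID,Number=1,Type=String,Description="phase">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\t.\tC\tT\t.\t.\tEPOCH=subclonal;PGID=PS9",
    "chr1\t2000\t.\tCA\tC\t.\t.\tEPOCH=subclonal"), f)
  out <- suppressWarnings(suppressMessages(
    read_snvs(f, dialect = "vcf", epoch_key = "EPOCH", phase_key = "PGID")))
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_equal(out$pos, 1000)
  expect_equal(out$epoch, "subclonal")
  expect_equal(out$phase_group, "PS9")
})

test_that("read_svs applies the BEDPE conventions and invariants", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t999\t1000\tchr1\t4999\t5000\tDEL\tS1", f)
  sv <- read_svs(f)
  expect_equal(sv$pos1, 1000)     # 0-based half-open start -> 1-based point
  expect_equal(sv$pos2, 5000)
  expect_equal(sv$sv_type, "DEL")
  expect_equal(sv$size_bp, 4000)

  writeLines("chr1\t999\t1000\tchr2\t4999\t5000\tDEL\tS1", f)
  expect_error(read_svs(f), "inter-chromosomal")
  writeLines("chr1\t999\t1000\tchr1\t4999\t5000\tTRA\tS1", f)
  expect_error(read_svs(f), "intra-chromosomal")

  # 5-row round trip through the writer
  svs <- make_svs(pos1 = c(1e4, 2e4, 3e4, 4e4, 5e4),
                  sv_type = c("DEL", "DUP", "INV", "DEL", "DUP"))
  svs2 <- rbind(svs, make_svs(1e6, chrom2 = "chr2", pos2 = 99, sv_type = "TRA"))
  write_svs(svs2, f)
  back <- read_svs(f)
  expect_equal(as.data.frame(back), as.data.frame(svs2))
})

test_that("event writer round-trips coordinates and member positions", {
  members <- make_snvs(c(100, 200, 350, 400))
  ev <- make_candidate(members)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$start, ev$start)
  expect_equal(back$end, ev$end)
  expect_equal(back$snvs[[1]]$pos, members$pos)
})

test_that("annotate_intervals matches the half-open BED reading and a quadratic oracle", {
  iv <- data.frame(chrom = "chr1", start = c(150, 200), end = c(300, 300),
                   name = c("geneA", "geneB"))
  ev <- data.frame(chrom = "chr1", start = 100, end = 200)
  # overlap with geneA; geneB [200,300] 1-based inclusive abuts? pos 200 shared
  lab <- annotate_intervals(ev, iv)
  expect_true("geneA" %in% lab[[1]])

  # BED half-open: interval written as [200, 300) has 1-based start 201,
  # so an event ending at 200 does not overlap it
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t149\t300\tgeneA", "chr1\t200\t300\tgeneB"), f)
  gr <- read_bed_intervals(f)
  lab <- annotate_intervals(ev, gr)
  expect_equal(lab[[1]], "geneA")

  # 10 random events vs 10 random intervals == brute-force all-pairs overlap
  set.seed(11)
  evr <- data.frame(chrom = "chr1", start = sample(1:1000, 10))
  evr$end <- evr$start + sample(1:200, 10)
  ivr <- data.frame(chrom = "chr1", start = sample(1:1000, 10))
  ivr$end <- ivr$start + sample(1:200, 10)
  ivr$name <- paste0("iv", 1:10)
  got <- annotate_intervals(evr, ivr)
  for (i in 1:10) {
    want <- ivr$name[ivr$start <= evr$end[i] & evr$start[i] <= ivr$end]
    expect_setequal(got[[i]], want)
  }
})

test_that("mask membership agrees with a linear scan", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t400", "chr2\t0\t50"), f)
  mask <- read_mask(f)
  expect_equal(mask_width(mask), 350)  # [100,400) + [0,50) after merge
  set.seed(3)
  chrom <- sample(c("chr1", "chr2"), 1000, replace = TRUE)
  pos <- sample(1:500, 1000, replace = TRUE)
  got <- mask_member(mask, chrom, pos)
  want <- (chrom == "chr1" & pos >= 101 & pos <= 400) |
          (chrom == "chr2" & pos >= 1 & pos <= 50)
  expect_equal(got, want)
})
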