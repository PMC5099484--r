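test_that("read_fasta normalizes case and maps non-ACGTN to N", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(record_length(recs[[1]]), 4)

  writeLines(c(">a", "ACGT", ">b", "ARGTRY"), fa)
  expect_warning(recs <- read_fasta(fa), "3 non-ACGTN")
  expect_equal(vapply(recs, `[[`, "", "id"), c("a", "b"))
  # substituted count equals count of non-ACGTN input symbols
  expect_equal(lengths(regmatches(recs[[2]]$sequence,
                                  gregexpr("N", recs[[2]]$sequence))), 3)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("GenBank parsing: coordinates, joins, topology, origin wrap", {
  gb <- withr::local_tempfile(fileext = ".gb")
  L <- 60
  seq60 <- rand_seq(L, seed = 42)
  origin <- paste("        1", paste(substring(seq60,
    seq(1, L, 10), pmin(seq(1, L, 10) + 9, L)), collapse = " "))
  writeLines(c(
    "LOCUS       testrec       60 bp    DNA     circular PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..12",
    "                     /gene=\"aaa\"",
    "     tRNA            complement(join(5..6,8..9))",
    "                     /gene=\"trnX\"",
    "     CDS             join(58..60,1..3)",
    "                     /gene=\"wrap\"",
    "ORIGIN",
    origin,
    "//"), gb)
  rec <- read_genbank(gb)
  expect_equal(rec$topology, "circular")
  expect_equal(record_length(rec), 60)
  f <- Filter(function(x) x$gene == "aaa", rec$features)[[1]]
  expect_equal(unname(f$spans[1, ]), c(9, 12))
  f2 <- Filter(function(x) x$gene == "trnX", rec$features)[[1]]
  expect_equal(f2$strand, "-")
  expect_equal(nrow(f2$spans), 2)
  expect_equal(unname(f2$spans[, 1]), c(4, 7))
  # wrapped feature: extracted sequence equals the manual slice
  fw <- Filter(function(x) x$gene == "wrap", rec$features)[[1]]
  expect_equal(extract_sequence(rec, fw),
               paste0(substr(seq60, 58, 60), substr(seq60, 1, 3)))
})

test_that("read_genbank rejects missing ORIGIN and out-of-range features", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  x  10 bp DNA linear", "FEATURES",
               "     CDS   2..8", "                /gene=\"g\""), gb)
  expect_error(read_genbank(gb), "ORIGIN")
  writeLines(c("LOCUS  x  10 bp DNA linear", "FEATURES",
               "     CDS   2..80", "                /gene=\"g\"",
               "ORIGIN", "        1 acgtacgtac", "//"), gb)
  expect_error(read_genbank(gb), "beyond")
})

test_that("extract_sequence honors strand and multi-span order", {
  rec <- genome_record("r", "AAATGCCC")
  f <- feature("g", "CDS", "-", c(2, 6))
  expect_equal(extract_sequence(rec, f), "GCAT")
  # spliced CDS length is preserved over spans
  f2 <- feature("g2", "CDS", "+", rbind(c(0, 3), c(5, 8)))
  expect_equal(extract_sequence(rec, f2), "AAACCC")
})

test_that("GFF3/BED conventions and round trip", {
  rec <- genome_record("chr", rand_seq(500, seed = 1),
                       features = list(
                         feature("g1", "CDS", "+", rbind(c(9, 12), c(40, 100))),
                         feature("g2", "tRNA", "-", c(200, 272))))
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gff3(rec, gff)
  write_bed(rec, bed)
  glines <- grep("^[^#]", readLines(gff), value = TRUE)
  expect_equal(strsplit(glines[1], "\t")[[1]][4:5], c("10", "12"))
  blines <- readLines(bed)
  expect_equal(strsplit(blines[1], "\t")[[1]][2:3], c("9", "12"))
  # round trip preserves spans, strands, names
  back <- read_gff3(gff)
  expect_equal(length(back$features), 2)
  ord <- order(vapply(back$features, function(f) min(f$spans[, 1]), 1L))
  expect_equal(back$features[[ord[1]]]$spans, rec$features[[1]]$spans)
  expect_equal(back$features[[ord[2]]]$strand, "-")
  expect_equal(back$features[[ord[2]]]$gene, "g2")
})

test_that("round trip of a 10-feature synthetic record is lossless", {
  set.seed(7)
  feats <- lapply(1:10, function(i) {
    st <- 50 * i
    feature(paste0("g", i), sample(c("CDS", "tRNA", "rRNA"), 1),
            sample(c("+", "-"), 1), c(st, st + sample(10:40, 1)))
  })
  rec <- genome_record("r10", rand_seq(600), features = feats)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(rec, gff)
  back <- read_gff3(gff)
  for (i in seq_along(rec$features)) {
    expect_equal(back$features[[i]]$spans, rec$features[[i]]$spans)
    expect_equal(back$features[[i]]$strand, rec$features[[i]]$strand)
    expect_equal(back$features[[i]]$gene, rec$features[[i]]$gene)
  }
})

test_that("rotation shifts coordinates and preserves gene sequences", {
  sim <- simulate_mitogenome(small_sim(21, L = 12000,
                                       dispersed = list()))
  rec <- sim$record
  for (k in c(1, 137, 6000)) {
    rot <- rotate_record(rec, k)
    expect_equal(record_length(rot), record_length(rec))
    for (i in seq_along(rec$features)) {
      g <- rec$features[[i]]$gene
      fr <- Filter(function(f) f$gene == g, rot$features)[[1]]
      expect_equal(extract_sequence(rot, fr),
                   extract_sequence(rec, rec$features[[i]]),
                   label = sprintf("gene %s at rotation %d", g, k))
    }
  }
})
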