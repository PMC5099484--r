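test_that("SSR scanner reproduces the printed pentamer and thresholds", {
  set.seed(11)
  # G/C caps stop the periodic run from extending into the flanks
  flank1 <- paste0(rand_seq(395), "GGGCC")
  flank2 <- paste0("CCGGG", rand_seq(395))
  s <- paste0(flank1, strrep("TTTTA", 5), flank2)
  out <- find_ssrs(s)
  penta <- out[out$unit_len == 5, ]
  expect_equal(nrow(penta), 1)
  expect_equal(penta$length, 25)
  expect_equal(penta$copies, 5)
  expect_equal(penta$start, 400)

  # mononucleotide threshold of eight
  expect_equal(nrow(find_ssrs(paste0("GC", strrep("A", 7), "GC"))), 0)
  one <- find_ssrs(paste0("GC", strrep("A", 8), "GC"))
  expect_equal(nrow(one), 1)
  expect_equal(one$unit_len, 1)
  expect_equal(one$length, 8)
})

test_that("a homopolymer is a monomer SSR, never a dimer re-report", {
  out <- find_ssrs(paste0("CG", strrep("A", 12), "CG"))
  expect_equal(out$unit_len, 1)
  expect_equal(nrow(out), 1)
})

test_that("SSR scanner equals the regex enumerator on random sequences", {
  for (seed in 1:25) {
    s <- rand_seq(3000, seed = 1000 + seed)
    got <- find_ssrs(s)
    want <- oracle_ssrs(s)
    expect_equal(got[, c("unit_len", "copies", "start", "end")],
                 want[, c("unit_len", "copies", "start", "end")],
                 ignore_attr = TRUE, label = sprintf("seed %d", seed))
  }
  # and on SSR-dense composite sequences
  set.seed(77)
  for (rep in 1:10) {
    parts <- replicate(6, {
      u <- rand_seq(sample(1:6, 1))
      strrep(u, sample(2:10, 1))
    })
    s <- paste0(rand_seq(100), paste(sample(c(parts, rand_seq(80))),
                                     collapse = rand_seq(30)),
                rand_seq(100))
    got <- find_ssrs(s)
    want <- oracle_ssrs(s)
    expect_equal(got[, c("unit_len", "copies", "start", "end")],
                 want[, c("unit_len", "copies", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("reported SSRs never overlap", {
  for (seed in 1:5) {
    s <- paste0(strrep("AT", 10), strrep("A", 10), rand_seq(500, seed = seed),
                strrep("TTG", 6))
    out <- find_ssrs(s)
    if (nrow(out) > 1) {
      out <- out[order(out$start), ]
      expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
    }
  }
})

test_that("tandem scanner reports the printed units at period and x2", {
  units <- utils::read.delim(system.file("extdata",
                                         "table_tandem_repeats.tsv",
                                         package = "mitokit"))
  set.seed(5)
  # guards differ from the unit at every position so the maximal lag-run
  # is exactly the planted tandem
  guard <- function(u) chartr("ACGT", "GTAC", u)
  for (i in seq_len(nrow(units))) {
    u <- units$unit[i]
    s <- paste0(rand_seq(300), guard(u), strrep(u, 2), guard(u),
                rand_seq(300))
    out <- find_tandem_repeats(s)
    st <- 300 + nchar(u)
    hit <- out[out$start == st, ]
    expect_equal(nrow(hit), 1, label = paste("unit", i))
    expect_equal(hit$period, nchar(u))
    expect_equal(hit$copies, 2)
    expect_equal(hit$identity, 100)
    expect_equal(hit$consensus, u)
  }
})

test_that("one-mismatch tandem variant gives identity (period-1)/period", {
  set.seed(9)
  u <- rand_seq(20)
  u2 <- u
  substr(u2, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(u, 11, 11))[1]
  s <- paste0(rand_seq(200), chartr("ACGT", "GTAC", u), u, u2,
              chartr("ACGT", "GTAC", u2), rand_seq(200))
  out <- find_tandem_repeats(s)
  hit <- out[out$period == 20, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$copies, 2)
  expect_equal(hit$identity, 100 * 19 / 20)
})

test_that("planted dispersed repeats are recovered with correct types", {
  sim <- simulate_mitogenome(small_sim(31))
  fams <- find_dispersed_repeats(sim$record)
  truth <- sim$truth$dispersed
  expect_equal(length(unique(fams$family)), 2)
  # families sorted by unit length descending
  heads <- fams[fams$copy == 1, ]
  expect_true(all(diff(heads$unit_len) <= 0))
  dr <- fams[fams$family == "R1", ]
  expect_equal(dr$type[1], "DR")
  expect_gte(dr$identity[1], 99)
  ir <- fams[fams$family == "R2", ]
  expect_equal(ir$type[1], "IR")
  # recall: every planted copy matched by a reported copy
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(fams$end, truth$end[i]) - pmax(fams$start, truth$start[i])
    expect_true(any(ov >= 0.9 * truth$length[i]),
                label = sprintf("planted copy %d recovered", i))
  }
})

test_that("repeat statistics are invariant under genome rotation", {
  sim <- simulate_mitogenome(small_sim(33, L = 20000))
  rec <- sim$record
  base <- find_dispersed_repeats(rec)
  base_ssr <- find_ssrs(rec)
  base_td <- find_tandem_repeats(rec)
  rot <- rotate_record(rec, 4321)
  r_fam <- find_dispersed_repeats(rot)
  sig <- function(f) {
    h <- f[f$copy == 1, ]
    h <- h[order(-h$unit_len), ]
    data.frame(len = h$unit_len, type = h$type,
               n = as.integer(table(f$family)[h$family]))
  }
  expect_equal(sig(base), sig(r_fam), tolerance = 0.01, ignore_attr = TRUE)
  r_ssr <- find_ssrs(rot)
  expect_equal(sort(paste(base_ssr$motif, base_ssr$copies)),
               sort(paste(r_ssr$motif, r_ssr$copies)))
  r_td <- find_tandem_repeats(rot)
  expect_equal(sort(paste(base_td$period, base_td$copies)),
               sort(paste(r_td$period, r_td$copies)))
})

test_that("classify_location labels genes, introns and IGS", {
  sim <- simulate_mitogenome(small_sim(35, L = 15000,
                                       dispersed = list()))
  rec <- sim$record
  tg <- sim$truth$genes
  g1 <- tg[tg$gene == "cox1", ]
  expect_equal(classify_location(c(g1$start + 5, g1$start + 25), rec), "cox1")
  # intron of the multi-exon gene
  nf <- Filter(function(f) f$gene == "nad4", rec$features)[[1]]
  sp <- nf$spans[order(nf$spans[, 1]), ]
  mid <- c(sp[1, 2] + 5, sp[1, 2] + 20)
  expect_match(classify_location(mid, rec), "^nad4-intron")
  # intergenic interval names both flanks
  ord <- tg[order(tg$start), ]
  gap_i <- which(ord$start[-1] - ord$end[-nrow(ord)] > 200)[1]
  iv <- c(ord$end[gap_i] + 50, ord$end[gap_i] + 80)
  expect_equal(classify_location(iv, rec),
               sprintf("IGS (%s, %s)", ord$gene[gap_i], ord$gene[gap_i + 1]))
  # label invariance under rotation (flanks resolved across the origin)
  rot <- rotate_record(rec, ord$end[gap_i] + 60)
  lab <- classify_location(c(record_length(rec) - 10,
                             record_length(rec) - 10 + 20), rot)
  expect_equal(lab, sprintf("IGS (%s, %s)", ord$gene[gap_i],
                            ord$gene[gap_i + 1]))
  expect_equal(classify_location(c(0, 10), genome_record("x", "ACGTACGT")),
               "unannotated")
})

test_that("repeat length histogram conserves family counts", {
  sim <- simulate_mitogenome(small_sim(37))
  fams <- find_dispersed_repeats(sim$record)
  h <- repeat_length_histogram(fams)
  expect_equal(sum(h$count), length(unique(fams$family)))
  expect_equal(nrow(repeat_length_histogram(fams[0, ])), 0)
  # planted lengths land in the right bins
  lens <- fams$unit_len[fams$copy == 1]
  for (l in lens) {
    bin <- h[h$bin_start <= l & l < h$bin_end, ]
    expect_gte(bin$count, 1)
  }
})
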