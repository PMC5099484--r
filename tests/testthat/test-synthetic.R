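test_that("identical config gives byte-identical outputs", {
  cfg <- small_sim(51, L = 20000)
  a <- simulate_mitogenome(cfg)
  b <- simulate_mitogenome(cfg)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth, b$truth)
  fa1 <- withr::local_tempfile(); fa2 <- withr::local_tempfile()
  write_fasta(a$record, fa1); write_fasta(b$record, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  g1 <- simulate_contig_graph(a, seed = 9)
  g2 <- simulate_contig_graph(b, seed = 9)
  expect_identical(g1$graph$nodes, g2$graph$nodes)
})

test_that("realized GC of a background-only genome is close to target", {
  cfg <- sim_config(seed = 53, genome_length = 100000L,
                    gene_catalog = list(), planted_ssrs = list(),
                    planted_tandems = list(), planted_dispersed = list())
  sim <- simulate_mitogenome(cfg)
  gc <- composition_report(sim$record)
  expect_lt(abs(gc$GC[gc$category == "genome"] - 44.95), 0.5)
  expect_null(sim$truth$dispersed)
  expect_null(sim$truth$ssrs)
  # scanners report nothing above thresholds except chance background hits
  fams <- find_dispersed_repeats(
    genome_record("sub", substr(sim$record$sequence, 1, 20000)))
  expect_lte(length(unique(fams$family)), 2)
})

test_that("planted elements are discoverable at their truth coordinates", {
  sim <- simulate_mitogenome(small_sim(55, L = 20000))
  tr <- sim$truth
  # SSR truth
  ssrs <- find_ssrs(sim$record)
  for (i in seq_len(nrow(tr$ssrs))) {
    hit <- ssrs[ssrs$start <= tr$ssrs$start[i] & ssrs$end >= tr$ssrs$end[i], ]
    expect_gte(nrow(hit), 1, label = sprintf("ssr %d", i))
  }
  # tandem truth
  td <- find_tandem_repeats(sim$record)
  for (i in seq_len(nrow(tr$tandems))) {
    hit <- td[td$start <= tr$tandems$start[i] + 2 &
                td$end >= tr$tandems$end[i] - 2, ]
    expect_gte(nrow(hit), 1, label = sprintf("tandem %d", i))
  }
  # genes extract back to their planted CDS
  for (i in seq_len(nrow(tr$genes))) {
    f <- Filter(function(x) x$gene == tr$genes$gene[i],
                sim$record$features)[[1]]
    expect_equal(extract_sequence(sim$record, f), tr$genes$cds[i])
    expect_equal(nchar(tr$genes$cds[i]) %% 3, 0)
  }
})

test_that("DR pair planted from the printed template is recorded correctly", {
  cfg <- sim_config(seed = 57, genome_length = 20000L,
                    planted_dispersed = list(
                      list(length = 2532L, identity = 99.64,
                           orientation = "DR", n_copies = 2L)))
  sim <- simulate_mitogenome(cfg)
  d <- sim$truth$dispersed
  expect_equal(nrow(d), 2)
  expect_true(all(d$orientation == "+"))
  expect_true(all(d$type == "DR"))
  expect_equal(unique(d$length), 2532)
})

test_that("nuclear blocks realize the configured substitution rate", {
  sim <- simulate_mitogenome(small_sim(59, L = 30000, dispersed = list()))
  # rate 0 -> identity exactly 100
  nuc0 <- simulate_nuclear_chromosome(sim, blocks = list(
    list(start = 0, end = 10000, rate = 0)), seed = 60)
  expect_equal(nuc0$truth$blocks$identity, 100)
  # rate 1e-3 on a 10 kb block: within 3 binomial sigma of 99.9%
  nuc <- simulate_nuclear_chromosome(sim, blocks = list(
    list(start = 0, end = 10000, rate = 1e-3)), seed = 61)
  p <- 1 - nuc$truth$blocks$identity / 100
  sigma <- sqrt(1e-3 * (1 - 1e-3) / 10000)
  expect_lt(abs(p - 1e-3), 3 * sigma)
  expect_error(simulate_nuclear_chromosome(sim, blocks = list(
    list(start = 0, end = 100, rate = 1))), "rate")
})

test_that("carried genes keep source order in the nuclear block", {
  sim <- simulate_mitogenome(small_sim(63, L = 30000, dispersed = list()))
  nuc <- simulate_nuclear_chromosome(sim, blocks = list(
    list(start = 0, end = 25000, rate = 1e-3)), seed = 64)
  carried <- nuc$truth$genes
  expect_gt(nrow(carried), 2)
  mt_order <- sim$truth$genes[order(sim$truth$genes$start), "gene"]
  nuc_order <- carried[order(carried$nuc_start), "gene"]
  expect_equal(nuc_order, intersect(mt_order, nuc_order))
})

test_that("contig graph: repeat depth ratio and decoy depths", {
  sim <- simulate_mitogenome(small_sim(65, L = 25000,
    dispersed = list(list(length = 2500L, identity = 100,
                          orientation = "DR", n_copies = 2L))))
  cg <- simulate_contig_graph(sim, base_depth = 30, seed = 66)
  nodes <- cg$graph$nodes
  rep_id <- names(which(table(cg$truth$walk$contig) == 2))
  rep_ctg <- nodes[nodes$id == rep_id, ]
  expect_equal(nrow(rep_ctg), 1)
  ratio <- rep_ctg$depth / 30
  expect_gte(ratio, 1.8); expect_lte(ratio, 2.2)
  # decoys are outside the [15, 50] window
  dec <- nodes[grepl("^decoy", nodes$id), ]
  expect_true(all(dec$depth < 15 | dec$depth > 50))
  cand <- filter_by_depth(cg$graph, c(15, 50))
  expect_false(any(grepl("^decoy", cand$id)))
  # walking the truth walk reconstructs a rotation of the genome
  walk <- cg$truth$walk
  seqs <- stats::setNames(nodes$sequence, nodes$id)
  rebuilt <- paste(vapply(seq_len(nrow(walk)), function(i) {
    s <- seqs[[walk$contig[i]]]
    if (walk$orientation[i] == "-") revcomp(s) else s
  }, character(1)), collapse = "")
  doubled <- paste0(sim$record$sequence, sim$record$sequence)
  expect_true(grepl(rebuilt, doubled, fixed = TRUE))
})

test_that("plant_edits constructs a perfectly recoverable truth at noise 0", {
  sim <- simulate_mitogenome(small_sim(67, L = 15000, dispersed = list()))
  genes <- stats::setNames(sim$truth$genes$cds[1:3],
                           sim$truth$genes$gene[1:3])
  pe <- plant_edits(genes, n_sites = 5, panel_size = 8, noise = 0,
                    seed = 68)
  expect_equal(nrow(pe$truth), 15)
  expect_true(all(pe$truth$codon_pos %in% 1:2))
  for (g in names(genes)) {
    sites <- predict_edits(pe$cds[[g]], g, pe$panel[[g]])
    want <- pe$truth[pe$truth$gene == g, ]
    expect_equal(sort(sites$codon), sort(want$codon))
    expect_true(all(sites$score == 1))
  }
})

test_that("Pro->Leu edits dominate under the default type weights", {
  sim <- simulate_mitogenome(small_sim(69, L = 25000, dispersed = list()))
  genes <- stats::setNames(sim$truth$genes$cds, sim$truth$genes$gene)
  pe <- plant_edits(genes, n_sites = 6, panel_size = 6, noise = 0,
                    seed = 70)
  tab <- sort(table(pe$truth$aa_change), decreasing = TRUE)
  expect_true(names(tab)[1] %in% c("P>L", "S>L"))
})
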