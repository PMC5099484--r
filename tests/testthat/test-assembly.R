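test_that("GFA round trip preserves nodes, depths and link ends", {
  sim <- simulate_mitogenome(small_sim(201, L = 20000))
  cg <- simulate_contig_graph(sim, seed = 202)
  gfa <- withr::local_tempfile(fileext = ".gfa")
  dtsv <- withr::local_tempfile(fileext = ".tsv")
  write_gfa(cg$graph, gfa, dtsv)
  back <- read_gfa(gfa, dtsv)
  expect_equal(back$nodes$id, cg$graph$nodes$id)
  expect_equal(back$nodes$sequence, cg$graph$nodes$sequence)
  expect_equal(back$nodes$depth, cg$graph$nodes$depth, tolerance = 1e-3)
  expect_equal(back$edges[, c("from", "from_end", "to", "to_end")],
               cg$graph$edges[, c("from", "from_end", "to", "to_end")])
})

test_that("depth filter keeps the window and rescues essential bridges", {
  sim <- simulate_mitogenome(small_sim(203, L = 20000,
    dispersed = list(list(length = 2500L, identity = 100,
                          orientation = "DR", n_copies = 2L))))
  cg <- simulate_contig_graph(sim, base_depth = 30, seed = 204)
  nodes <- cg$graph$nodes
  rep_id <- names(which(table(cg$truth$walk$contig) == 2))
  # without confirmation the out-of-window repeat contig is dropped
  cand0 <- filter_by_depth(cg$graph, c(15, 50))
  expect_false(rep_id %in% cand0$id)
  # confirmed + graph-essential: rescued with the cp-like tag
  cand1 <- filter_by_depth(cg$graph, c(15, 50), confirmed = rep_id)
  expect_true(rep_id %in% cand1$id)
  expect_equal(cand1$reason[cand1$id == rep_id], "cp-like, graph-essential")
  # plain in-window contig kept, decoys dropped
  expect_true(all(cand1$depth[cand1$reason == "in-window"] >= 15))
  expect_false(any(grepl("decoy", cand1$id)))
  # widening the window never removes candidates
  cand2 <- filter_by_depth(cg$graph, c(10, 80), confirmed = rep_id)
  expect_true(all(cand1$id %in% cand2$id))
})

test_that("reference selection keeps organellar contigs, drops random ones", {
  sim <- simulate_mitogenome(small_sim(205, L = 15000, dispersed = list()))
  cg <- simulate_contig_graph(sim, seed = 206)
  ref <- mutate_seq(sim$record$sequence, 0.02)
  confirmed <- select_by_reference(cg$graph, list(ref = ref))
  mt_ids <- cg$graph$nodes$id[!grepl("decoy", cg$graph$nodes$id)]
  expect_setequal(intersect(confirmed, mt_ids), mt_ids)
  expect_false("decoy_nuc1" %in% confirmed)
  expect_error(select_by_reference(cg$graph, list()), "empty")
})

test_that("pruning removes weak links and decoy branches, keeps forks", {
  sim <- simulate_mitogenome(small_sim(207, L = 20000,
    dispersed = list(list(length = 2500L, identity = 100,
                          orientation = "DR", n_copies = 2L))))
  cg <- simulate_contig_graph(sim, seed = 208)
  cand <- cg$graph$nodes$id[!grepl("decoy", cg$graph$nodes$id)]
  pruned <- prune_graph(cg$graph, 2L, cand)
  expect_false(any(grepl("decoy", c(pruned$edges$from, pruned$edges$to))))
  expect_true(all(pruned$edges$support >= 2))
  # the repeat fork (degree 4 contig) survives
  rep_id <- names(which(table(cg$truth$walk$contig) == 2))
  deg <- sum(pruned$edges$from == rep_id) + sum(pruned$edges$to == rep_id)
  expect_equal(deg, 4)
})

test_that("walker: unique cycle, repeat reuse, loud failure", {
  # plain 5-contig cycle
  nodes <- data.frame(id = paste0("c", 1:5), length = 100, depth = 30,
                      sequence = vapply(1:5, function(i) rand_seq(100, i),
                                        ""), stringsAsFactors = FALSE)
  edges <- data.frame(from = paste0("c", 1:5), from_end = "3p",
                      to = paste0("c", c(2:5, 1)), to_end = "5p",
                      support = 10L, stringsAsFactors = FALSE)
  g <- structure(list(nodes = nodes, edges = edges), class = "ContigGraph")
  w <- walk_circular_path(g)
  expect_equal(nrow(w$path), 5)
  expect_setequal(w$path$contig, nodes$id)
  # 2-copy repeat: walk uses the repeat contig exactly twice
  sim <- simulate_mitogenome(small_sim(209, L = 20000,
    dispersed = list(list(length = 2500L, identity = 100,
                          orientation = "DR", n_copies = 2L))))
  cg <- simulate_contig_graph(sim, seed = 210, decoys = FALSE)
  w2 <- walk_circular_path(cg$graph)
  rep_id <- names(which(table(cg$truth$walk$contig) == 2))
  expect_equal(sum(w2$path$contig == rep_id), 2)
  expect_equal(unname(w2$multiplicity[rep_id]), 2)
  # walk multiplicities conserve depth: sum(usage x length) ~ genome length
  lens <- stats::setNames(cg$graph$nodes$length, cg$graph$nodes$id)
  expect_lt(abs(sum(lens[w2$path$contig]) - 20000) / 20000, 0.02)
  # impossible multiplicities fail loudly
  bad <- g
  bad$nodes$depth[2] <- 90  # demands 3 copies with no reentrant edges
  expect_error(walk_circular_path(bad), "no closed walk")
})

test_that("gap filling: supported junctions close, unsupported leave Ns", {
  sim <- simulate_mitogenome(small_sim(211, L = 15000, dispersed = list()))
  cg <- simulate_contig_graph(sim, seed = 212, decoys = FALSE)
  reads <- simulate_reads(sim$record, n = 2500, seed = 213)
  w <- walk_circular_path(cg$graph)
  fg <- fill_gaps(w, cg$graph, reads)
  expect_true(all(fg$junctions$supported))
  expect_equal(nchar(fg$sequence), 15000)
  # no reads: every junction unresolved, N-gaps inserted
  fg0 <- fill_gaps(w, cg$graph, character(0))
  expect_false(any(fg0$junctions$supported))
  expect_equal(nchar(fg0$sequence), 15000 + 10 * nrow(fg0$junctions))
  expect_true(grepl("N", fg0$sequence))
})

test_that("validation reports planted assembly errors and low coverage", {
  sim <- simulate_mitogenome(small_sim(215, L = 12000, dispersed = list()))
  reads <- simulate_reads(sim$record, n = 2500, read_len = 120, seed = 216)
  ok <- validate_assembly(sim$record$sequence, reads)
  expect_equal(nrow(ok$discrepancies), 0)
  # plant a single error
  broken <- sim$record$sequence
  substr(broken, 6000, 6000) <- setdiff(c("A", "C", "G", "T"),
                                        substr(broken, 6000, 6000))[1]
  bad <- validate_assembly(broken, reads)
  expect_true(5999 %in% bad$discrepancies$pos)
  expect_equal(bad$discrepancies$consensus[bad$discrepancies$pos == 5999],
               substr(sim$record$sequence, 6000, 6000))
  # uncovered positions flagged with a sparse read set
  sparse <- validate_assembly(sim$record$sequence,
                              simulate_reads(sim$record, n = 10,
                                             seed = 217))
  expect_gt(length(sparse$uncovered), 0)
})

test_that("end-to-end: synthetic genomes reassemble rotation-equivalent", {
  ok <- 0; n_seeds <- 8
  for (sd in seq_len(n_seeds)) {
    sim <- simulate_mitogenome(sim_config(seed = 500 + sd,
      genome_length = 25000,
      planted_dispersed = list(
        list(length = 2500L, identity = 100, orientation = "DR",
             n_copies = 2L),
        list(length = 2000L, identity = 100, orientation = "IR",
             n_copies = 2L))))
    cg <- simulate_contig_graph(sim, seed = 600 + sd)
    reads <- simulate_reads(sim$record, n = 2500, seed = 700 + sd)
    ref <- mutate_seq(sim$record$sequence, 0.02)
    asm <- suppressWarnings(assemble_organelle(
      cg$graph, reads, reference_panel = list(ref = ref)))
    doubled <- paste0(sim$record$sequence, sim$record$sequence)
    eq <- grepl(asm$sequence, doubled, fixed = TRUE) ||
      grepl(revcomp(asm$sequence), doubled, fixed = TRUE)
    ok <- ok + eq
  }
  expect_gte(ok / n_seeds, 0.95)
})
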