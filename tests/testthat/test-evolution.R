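test_that("ng86 basics: identical pair, single synonymous change", {
  a <- "ATGTTTGGACCCAAATGA"
  r0 <- ng86(a, a)
  expect_equal(r0$Ka, 0); expect_equal(r0$Ks, 0)

  b <- "ATGTTCGGACCCAAATGA"  # TTT->TTC, synonymous
  r <- ng86(a, b)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
})

test_that("ng86 agrees with the independent enumeration oracle", {
  set.seed(21)
  for (rep in 1:6) {
    # toy genes, stop-free interiors
    n_cod <- 12
    mk <- function() {
      stops <- c("TAA", "TAG", "TGA")
      cods <- character(n_cod)
      for (i in seq_len(n_cod)) {
        repeat {
          c1 <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
          if (!c1 %in% stops) break
        }
        cods[i] <- c1
      }
      paste(cods, collapse = "")
    }
    a <- mk()
    b <- mutate_seq(a, 0.06)
    # re-draw if mutation created internal stops
    ok <- !any(substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3)) %in%
                 c("TAA", "TAG", "TGA"))
    if (!ok) next
    got <- ng86(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-10)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-10)
  }
})

test_that("ng86 symmetry and codon-duplication invariance", {
  a <- "ATGTTTGGACCCAAACGGTGA"
  b <- "ATGTTCGGTCCGAAACGTTGA"
  r1 <- ng86(a, b); r2 <- ng86(b, a)
  expect_equal(r1$Ka, r2$Ka); expect_equal(r1$Ks, r2$Ks)
  # doubling every codon leaves the rates unchanged
  dup <- function(s) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    paste0(paste(rep(cods, each = 2), collapse = ""), substr(s, nchar(s) - 2,
                                                             nchar(s)))
  }
  r3 <- ng86(dup(a), dup(b))
  expect_equal(r3$Ka, r1$Ka, tolerance = 1e-10)
  expect_equal(r3$Ks, r1$Ks, tolerance = 1e-10)
})

test_that("ng86 errors and saturation handling", {
  expect_error(ng86("ATGTAAAAATGA", "ATGTAAAAATGA"), "stop")
  expect_error(ng86("ATGAAA", "ATGAAAT"), "aligned")
  expect_true(is.na(jc_correct(0.8)))
})

test_that("forced synonymous excess keeps the ratio below 1", {
  set.seed(23)
  wins <- 0; n_rep <- 40
  base_cods <- c("TTT", "GGA", "CCC", "AAA", "CGG", "ACT", "GTC", "TCA")
  for (rep in seq_len(n_rep)) {
    a <- paste(c("ATG", sample(base_cods, 30, TRUE), "TAA"), collapse = "")
    b <- a
    cods <- seq(2, 31)
    # 3 synonymous third-position changes per 1 nonsynonymous change
    syn_done <- 0; non_done <- 0
    for (ci in sample(cods, 12)) {
      pos <- (ci - 1) * 3
      cod <- substr(b, pos + 1, pos + 3)
      if (syn_done < 9 && cod %in% c("TTT", "CCC", "AAA", "GTC")) {
        alt <- cod
        substr(alt, 3, 3) <- c(TTT = "C", CCC = "T", AAA = "G",
                               GTC = "A")[[cod]]
        substr(b, pos + 1, pos + 3) <- alt; syn_done <- syn_done + 1
      } else if (non_done < 3) {
        # stop-safe nonsynonymous change: C at pos 1 (or T at pos 2 when
        # the codon already starts with C)
        if (substr(cod, 1, 1) == "C") substr(b, pos + 2, pos + 2) <- "T"
        else substr(b, pos + 1, pos + 1) <- "C"
        non_done <- non_done + 1
      }
    }
    r <- ng86(a, b)
    if (!is.na(r$ratio) && r$ratio < 1) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("concatenation, complete deletion and JC distances", {
  sets <- list(
    g1 = c(A = "ATGAAA", B = "ATGAAA", C = "ATGAAA", D = "ATGAAA"),
    g2 = c(A = "CCC", B = "CCC", C = "CCC", D = "CC-"))
  m <- concatenate_genes(sets)
  expect_equal(m$length, 6 + 2)  # one gap column removed
  expect_equal(unname(m$dist["A", "B"]), 0)
  # taxon missing from one gene is dropped with a warning
  sets2 <- list(g1 = c(A = "AAA", B = "AAA", C = "AAA", D = "AAA",
                       E = "AAA"),
                g2 = c(A = "CCC", B = "CCC", C = "CCC", D = "CCC"))
  expect_warning(m2 <- concatenate_genes(sets2), "E")
  expect_equal(sort(m2$taxa), c("A", "B", "C", "D"))
  expect_error(suppressWarnings(concatenate_genes(list(
    g1 = c(A = "AAA", B = "AAA", C = "AAA")))), "4 taxa")
})

test_that("NJ is exact on additive matrices", {
  h <- oracle_additive_matrix(4, 31)
  tr <- nj_tree(h$D)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 2)  # unrooted binary: n - 2 internal nodes
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), h$tree)), 0)
  # branch lengths: path distances reproduce the input matrix
  got <- ape::cophenetic.phylo(tr)
  got <- got[rownames(h$D), colnames(h$D)]
  expect_equal(got, h$D, tolerance = 1e-8)

  for (seed in 32:43) {
    n <- sample(5:10, 1)
    h <- oracle_additive_matrix(n, seed)
    tr <- nj_tree(h$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), h$tree)), 0,
                 label = sprintf("seed %d", seed))
    got <- ape::cophenetic.phylo(tr)[rownames(h$D), colnames(h$D)]
    expect_equal(got, h$D, tolerance = 1e-8)
  }
})

test_that("NJ errors on malformed input and handles 3 taxa", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(nj_tree(D), "symmetric")
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D3)
  expect_equal(ape::Ntip(tr), 3)
})

test_that("NJ recovers the generating topology from simulated sequences", {
  correct <- 0; n_try <- 8
  for (seed in seq_len(n_try)) {
    h <- oracle_additive_matrix(8, 300 + seed)
    set.seed(400 + seed)
    # evolve sequences down the tree under JC
    tr <- h$tree
    nsites <- 3000
    evolve <- function(s, bl) {
      rate <- 0.2 * bl
      mutate_seq(s, min(0.7, rate))
    }
    root_seq <- rand_seq(nsites)
    seqs <- vector("list", ape::Ntip(tr) + tr$Nnode)
    ord <- rev(ape::postorder(tr))
    root_node <- ape::Ntip(tr) + 1
    seqs[[root_node]] <- root_seq
    for (e in ord) {
      par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
      seqs[[chd]] <- evolve(seqs[[par]], tr$edge.length[e])
    }
    aln <- stats::setNames(unlist(seqs[seq_len(ape::Ntip(tr))]),
                           tr$tip.label)
    got <- nj_tree(jc_dist_matrix(aln))
    if (ape::dist.topo(ape::unroot(got), tr) == 0) correct <- correct + 1
  }
  expect_gte(correct / n_try, 0.85)
})

test_that("bootstrap: determinism, n = 1 extremes, strong-signal support", {
  set.seed(51)
  base <- rand_seq(400)
  aln <- c(A = base, B = mutate_seq(base, 0.01),
           C = mutate_seq(base, 0.35), D = mutate_seq(base, 0.37),
           E = mutate_seq(base, 0.36))
  b1 <- nj_bootstrap(aln, n = 100, seed = 7)
  b2 <- nj_bootstrap(aln, n = 100, seed = 7)
  expect_identical(b1$node.label, b2$node.label)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  # two near-identical tips at huge divergence from the rest: 100% support
  supports <- as.numeric(b1$node.label[b1$node.label != ""])
  expect_true(any(supports == 100))
  bb <- nj_bootstrap(aln, n = 1, seed = 3)
  sup1 <- as.numeric(bb$node.label[bb$node.label != ""])
  expect_true(all(sup1 %in% c(0, 100)))
})

test_that("outgroup rooting", {
  h <- oracle_additive_matrix(6, 61)
  tr <- nj_tree(h$D)
  rt <- root_with_outgroup(tr, "t3")
  expect_true(ape::is.rooted(rt))
  # outgroup is sister to everything else
  og_edge <- which(rt$tip.label == "t3")
  root_node <- ape::Ntip(rt) + 1
  expect_true(og_edge %in% rt$edge[rt$edge[, 1] == root_node, 2])
  # unrooting restores the topology
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt), ape::unroot(tr))), 0)
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")
  # invariant to taxon order of the distance matrix
  perm <- sample(rownames(h$D))
  tr2 <- nj_tree(h$D[perm, perm])
  rt2 <- root_with_outgroup(tr2, "t3")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt),
                                         ape::unroot(rt2))), 0)
  og2 <- which(rt2$tip.label == "t3")
  expect_true(og2 %in% rt2$edge[rt2$edge[, 1] == ape::Ntip(rt2) + 1, 2])
})
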