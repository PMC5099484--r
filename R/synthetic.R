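# ---- simulation configuration ---------------------------------------------

#' Random DNA of a given GC content
#' @param n length in bp.
#' @param gc target GC fraction.
#' @return DNA string with i.i.d. bases.
#' @export
random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a random CDS: ATG + internal-stop-free codons + stop
.random_cds <- function(n_codons, stop = "TAA", start = "ATG") {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cod %in% stops) break
    }
    body[i] <- cod
  }
  paste0(start, paste(body, collapse = ""), stop)
}

#' Simulation configuration for the synthetic mitochondrial genome
#'
#' Defaults emulate the statistical structure of a diploid-cotton-scale
#' plant mt genome at a desk-testable size: circular 100 kb background at
#' 44.95 percent GC, a gene complement planted in clusters, SSRs and
#' tandem repeats above the reporting thresholds, and dispersed repeat
#' families patterned on the large printed repeats (a 2,532 bp direct pair
#' at 99.6 percent identity and a 1 kb inverted pair). Read depth defaults
#' to 30x, inside the [15, 50] organelle depth window.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param genome_length genome size in bp.
#' @param gc_target background GC fraction.
#' @param gene_catalog list of `list(gene, n_codons, exon_lengths,
#'   intron_lengths, strand)` entries (exons optional).
#' @param planted_ssrs list of `list(motif, copies)` entries.
#' @param planted_tandems list of `list(unit, copies)` entries.
#' @param planted_dispersed list of `list(length, identity, orientation
#'   ("DR"/"IR"), n_copies)` entries.
#' @param transfer_blocks list of `list(start, end, rate)` mt intervals
#'   copied to the synthetic nuclear chromosome.
#' @param edit_sites integer: C-to-U edit sites planted per gene.
#' @param read_depth fold coverage of the simulated contig graph.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_target = 0.4495,
                       gene_catalog = NULL,
                       planted_ssrs = NULL,
                       planted_tandems = NULL,
                       planted_dispersed = NULL,
                       transfer_blocks = NULL,
                       edit_sites = 4L,
                       read_depth = 30) {
  if (is.null(gene_catalog)) {
    genes <- c("nad1", "nad2", "nad4", "cox1", "cox2", "cox3", "atp4",
               "atp9", "cob", "rps10", "rps14", "ccmB", "matR", "sdh3")
    strands <- rep(c("+", "-", "+", "-"), length.out = length(genes))
    gene_catalog <- lapply(seq_along(genes), function(i)
      list(gene = genes[i], n_codons = 160L, strand = strands[i]))
    gene_catalog[[3]]$exon_lengths <- c(120L, 180L, 180L)  # nad4, 2 introns
    gene_catalog[[3]]$intron_lengths <- c(400L, 350L)
  }
  if (is.null(planted_ssrs))
    planted_ssrs <- list(list(motif = "TTTTA", copies = 5L),
                         list(motif = "A", copies = 9L))
  if (is.null(planted_tandems))
    planted_tandems <- list(
      list(unit = "TAAGTGAAATAAAAT", copies = 2L),
      list(unit = "CTTGGCTTTCCTTTTTGTCTTGACTCTATGCCTTCCAGCTGT", copies = 2L))
  if (is.null(planted_dispersed))
    planted_dispersed <- list(
      list(length = 2532L, identity = 99.64, orientation = "DR",
           n_copies = 2L),
      list(length = 1000L, identity = 99.9, orientation = "IR",
           n_copies = 2L))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_target = gc_target, gene_catalog = gene_catalog,
                 planted_ssrs = planted_ssrs,
                 planted_tandems = planted_tandems,
                 planted_dispersed = planted_dispersed,
                 transfer_blocks = transfer_blocks,
                 edit_sites = as.integer(edit_sites),
                 read_depth = read_depth),
            class = "SimConfig")
}

# mutate a DNA string with i.i.d. substitutions at the given per-site rate
.mutate <- function(s, rate) {
  if (rate <= 0) return(s)
  if (rate >= 1) stop("mutation rate must be in [0, 1)")
  x <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

# ---- mitogenome simulator --------------------------------------------------

#' Simulate a circular mitochondrial genome with planted truth
#'
#' Background bases are i.i.d. at the requested GC; genes (optionally
#' multi-exon), SSRs, tandem repeats and dispersed direct/inverted repeat
#' families are placed at non-overlapping random positions. IR copies are
#' inserted as reverse complements; dispersed copies are substituted down
#' to the requested identity. Every planted element is recorded in a
#' machine-readable truth table in 0-based half-open coordinates.
#'
#' @param config a [sim_config()].
#' @return list with `record` (a circular [genome_record()]) and `truth`
#'   (list of data.frames: `genes`, `ssrs`, `tandems`, `dispersed`).
#' @export
simulate_mitogenome <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  s <- random_dna(L, config$gc_target)
  occupied <- matrix(numeric(0), ncol = 2)
  margin <- 80L  # clear flank around every plant
  place <- function(len) {
    # free-gap placement: sample a gap that fits, then an offset inside it
    occ <- occupied[order(occupied[, 1]), , drop = FALSE]
    gaps <- if (nrow(occ) == 0L) matrix(c(0, L), ncol = 2) else {
      g <- cbind(c(0, occ[, 2]), c(occ[, 1], L))
      g[g[, 2] > g[, 1], , drop = FALSE]
    }
    need <- len + 2 * margin
    fit <- gaps[gaps[, 2] - gaps[, 1] >= need, , drop = FALSE]
    if (nrow(fit) == 0L)
      stop("could not place a ", len, " bp element: genome too crowded")
    cap <- fit[, 2] - fit[, 1] - need + 1
    gi <- if (nrow(fit) == 1L) 1L else
      sample.int(nrow(fit), 1, prob = cap)
    p <- as.integer(fit[gi, 1] + margin + sample.int(cap[gi], 1) - 1L)
    occupied <<- rbind(occupied, c(p, p + len))
    p
  }
  insert <- function(str, pos) {
    substr(s, pos + 1L, pos + nchar(str)) <<- str
  }

  # largest elements first so fragmentation never blocks placement
  disp_truth <- list()
  fam_i <- 0L
  for (p in config$planted_dispersed) {
    fam_i <- fam_i + 1L
    proto <- random_dna(p$length, config$gc_target)
    rate <- (100 - p$identity) / 100
    for (ci in seq_len(p$n_copies)) {
      copy <- if (ci == 1L) proto else .mutate(proto, rate)
      ori <- if (ci > 1L && p$orientation == "IR") "-" else "+"
      if (ori == "-") copy <- revcomp(copy)
      pos <- place(nchar(copy))
      insert(copy, pos)
      disp_truth[[length(disp_truth) + 1L]] <- data.frame(
        family = paste0("P", fam_i), length = p$length,
        identity = p$identity, orientation = ori, copy = ci,
        start = pos, end = pos + nchar(copy),
        type = p$orientation, stringsAsFactors = FALSE)
    }
  }

  feats <- list()
  genes_truth <- list()
  for (g in config$gene_catalog) {
    cds <- .random_cds(g$n_codons)
    strand <- if (is.null(g$strand)) "+" else g$strand
    if (!is.null(g$exon_lengths)) {
      stopifnot(sum(g$exon_lengths) == nchar(cds))
      total <- sum(g$exon_lengths) + sum(g$intron_lengths)
      pos <- place(total)
      # lay out exons/introns left-to-right in transcription order for "+";
      # for "-" the genomic layout is reversed
      exs <- g$exon_lengths; ins <- g$intron_lengths
      if (strand == "-") { exs <- rev(exs); ins <- rev(ins) }
      cur <- pos; spans <- NULL
      pieces <- character(0)
      for (i in seq_along(exs)) {
        spans <- rbind(spans, c(cur, cur + exs[i]))
        cur <- cur + exs[i] + if (i <= length(ins)) ins[i] else 0L
      }
      # write exon sequence into the genome
      cds_g <- if (strand == "+") cds else revcomp(cds)
      off <- 0L
      for (i in seq_len(nrow(spans))) {
        w <- spans[i, 2] - spans[i, 1]
        insert(substr(cds_g, off + 1L, off + w), spans[i, 1])
        off <- off + w
      }
      # intron filler is background; spans ordered in transcription order
      sp_t <- if (strand == "+") spans else spans[rev(seq_len(nrow(spans))), , drop = FALSE]
      sp_t <- sp_t[order(sp_t[, 1]), , drop = FALSE]
      feats[[length(feats) + 1L]] <- feature(g$gene, "CDS", strand, sp_t)
      genes_truth[[length(genes_truth) + 1L]] <- data.frame(
        gene = g$gene, start = pos, end = pos + total, strand = strand,
        cds = cds, stringsAsFactors = FALSE)
    } else {
      pos <- place(nchar(cds))
      insert(if (strand == "+") cds else revcomp(cds), pos)
      feats[[length(feats) + 1L]] <- feature(g$gene, "CDS", strand,
                                             c(pos, pos + nchar(cds)))
      genes_truth[[length(genes_truth) + 1L]] <- data.frame(
        gene = g$gene, start = pos, end = pos + nchar(cds), strand = strand,
        cds = cds, stringsAsFactors = FALSE)
    }
  }

  ssr_truth <- list()
  for (p in config$planted_ssrs) {
    run <- strrep(p$motif, p$copies)
    pos <- place(nchar(run))
    insert(run, pos)
    ssr_truth[[length(ssr_truth) + 1L]] <- data.frame(
      motif = p$motif, unit_len = nchar(p$motif), copies = p$copies,
      start = pos, end = pos + nchar(run), stringsAsFactors = FALSE)
  }

  tandem_truth <- list()
  for (p in config$planted_tandems) {
    run <- strrep(p$unit, p$copies)
    pos <- place(nchar(run))
    insert(run, pos)
    tandem_truth[[length(tandem_truth) + 1L]] <- data.frame(
      unit = p$unit, period = nchar(p$unit), copies = p$copies,
      start = pos, end = pos + nchar(run), stringsAsFactors = FALSE)
  }

  rec <- genome_record("sim_mt", s, topology = "circular", features = feats)
  truth <- list(
    genes = if (length(genes_truth)) do.call(rbind, genes_truth) else NULL,
    ssrs = if (length(ssr_truth)) do.call(rbind, ssr_truth) else NULL,
    tandems = if (length(tandem_truth)) do.call(rbind, tandem_truth) else NULL,
    dispersed = if (length(disp_truth)) do.call(rbind, disp_truth) else NULL)
  list(record = rec, truth = truth)
}

# ---- nuclear chromosome with transferred blocks ----------------------------

#' Simulate a nuclear chromosome carrying transferred mt blocks
#'
#' Copies the configured mt intervals into a random nuclear background
#' with i.i.d. substitutions at the per-block rate, emulating recent
#' mitochondrion-to-nucleus DNA transfer at very high identity. Genes
#' fully contained in a block are carried over (with their source order)
#' and recorded in the truth table together with each block's realized
#' identity.
#'
#' @param mt_sim result of [simulate_mitogenome()].
#' @param blocks list of `list(start, end, rate)`; default: three blocks
#'   at substitution rate 1e-3 (identity about 99.9 percent).
#' @param background_length nuclear background length in bp.
#' @param seed RNG seed.
#' @return list with `record` (linear nuclear [genome_record()]) and
#'   `truth` (data.frames `blocks` and `genes`).
#' @export
simulate_nuclear_chromosome <- function(mt_sim, blocks = NULL,
                                        background_length = 60000L,
                                        seed = 2L) {
  set.seed(seed)
  mt <- mt_sim$record
  L <- record_length(mt)
  if (is.null(blocks)) {
    w <- L %/% 4L
    blocks <- list(list(start = 0L, end = w, rate = 1e-3),
                   list(start = w + 200L, end = 2L * w, rate = 1e-3),
                   list(start = 2L * w + 400L, end = 3L * w, rate = 1e-3))
  }
  for (b in blocks) if (b$rate >= 1) stop("mutation rate must be < 1")
  total_block <- sum(vapply(blocks, function(b) b$end - b$start, numeric(1)))
  bg <- random_dna(background_length, 0.35)
  # insertion offsets in the background, in order, non-overlapping
  gaps <- as.integer(background_length %/% (length(blocks) + 1L))
  pieces <- character(0)
  cur_bg <- 1L
  out_pos <- 0L
  block_truth <- list()
  gene_truth <- list()
  feats <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lead <- substr(bg, cur_bg, cur_bg + gaps - 1L)
    cur_bg <- cur_bg + gaps
    src <- substr(mt$sequence, b$start + 1L, b$end)
    mut <- .mutate(src, b$rate)
    nmatch <- sum(strsplit(src, "")[[1]] == strsplit(mut, "")[[1]])
    ident <- 100 * nmatch / nchar(src)
    pieces <- c(pieces, lead, mut)
    out_pos <- out_pos + nchar(lead)
    block_truth[[i]] <- data.frame(
      block = i, mt_start = b$start, mt_end = b$end,
      nuc_start = out_pos, nuc_end = out_pos + nchar(mut),
      identity = ident, stringsAsFactors = FALSE)
    # carry genes fully inside the block
    for (f in mt$features) {
      if (min(f$spans[, 1]) >= b$start && max(f$spans[, 2]) <= b$end) {
        sp <- f$spans - b$start + out_pos
        feats[[length(feats) + 1L]] <- feature(f$gene, f$ftype, f$strand, sp,
                                               copy_index = f$copy_index)
        gene_truth[[length(gene_truth) + 1L]] <- data.frame(
          gene = f$gene, block = i, nuc_start = min(sp),
          nuc_end = max(sp[, 2]), stringsAsFactors = FALSE)
      }
    }
    out_pos <- out_pos + nchar(mut)
  }
  pieces <- c(pieces, substr(bg, cur_bg, background_length))
  rec <- genome_record("sim_nuc_chr1", paste(pieces, collapse = ""),
                       topology = "linear", features = feats)
  list(record = rec,
       truth = list(blocks = do.call(rbind, block_truth),
                    genes = if (length(gene_truth))
                      do.call(rbind, gene_truth) else NULL))
}

# ---- contig graph simulator ------------------------------------------------

#' Shear a simulated genome into a contig graph
#'
#' Cuts the circular genome at the boundaries of planted dispersed-repeat
#' copies (plus optional extra cuts in unique sequence), collapses repeat
#' copies into a single contig carrying multiplied read depth, and emits
#' edges for every true adjacency. Optional decoy contigs emulate nuclear
#' (out-of-depth-window) and plastid-like (high-depth) sequence.
#'
#' @param mt_sim result of [simulate_mitogenome()] (needs at least one
#'   dispersed repeat).
#' @param base_depth mean organelle read depth.
#' @param n_extra_cuts additional cuts in unique regions.
#' @param decoys add decoy contigs at out-of-window depths.
#' @param seed RNG seed.
#' @return list with `graph` (a `ContigGraph`: `nodes` data.frame with
#'   `id, length, depth, sequence`; `edges` data.frame with
#'   `from, from_end, to, to_end, support`), and `truth` (walk of
#'   `contig, orientation` reconstructing the genome).
#' @export
simulate_contig_graph <- function(mt_sim, base_depth = 30,
                                  n_extra_cuts = 3L, decoys = TRUE,
                                  seed = 3L) {
  set.seed(seed)
  rec <- mt_sim$record
  L <- record_length(rec)
  disp <- mt_sim$truth$dispersed
  if (is.null(disp) || nrow(disp) == 0L)
    cuts <- integer(0)
  else
    cuts <- sort(unique(c(disp$start, disp$end)))
  # extra cuts in unique regions
  if (n_extra_cuts > 0L) {
    for (i in seq_len(n_extra_cuts)) {
      repeat {
        p <- sample.int(L, 1) - 1L
        ok <- is.null(disp) || all(p <= disp$start | p >= disp$end)
        if (ok && !(p %in% cuts)) break
      }
      cuts <- sort(c(cuts, p))
    }
  }
  if (length(cuts) < 2L) stop("need at least two cut points")
  # segments around the circle
  segs <- data.frame(start = cuts,
                     end = c(cuts[-1L], cuts[1L] + L))
  seg_seq <- vapply(seq_len(nrow(segs)), function(i) {
    if (segs$end[i] <= L) substr(rec$sequence, segs$start[i] + 1L, segs$end[i])
    else paste0(substr(rec$sequence, segs$start[i] + 1L, L),
                substr(rec$sequence, 1L, segs$end[i] - L))
  }, character(1))
  # map each segment to a repeat family copy (or unique)
  seg_fam <- rep(NA_character_, nrow(segs))
  seg_ori <- rep("+", nrow(segs))
  if (!is.null(disp)) {
    for (i in seq_len(nrow(segs))) {
      hit <- which(disp$start == segs$start[i] & disp$end == segs$end[i])
      if (length(hit)) {
        seg_fam[i] <- disp$family[hit[1]]
        seg_ori[i] <- disp$orientation[hit[1]]
      }
    }
  }
  # contig per unique segment / per family
  contig_of <- integer(nrow(segs))
  nodes <- list()
  fam_node <- list()
  for (i in seq_len(nrow(segs))) {
    if (is.na(seg_fam[i])) {
      id <- sprintf("contig%05d", length(nodes) + 1L)
      nodes[[id]] <- list(id = id, sequence = seg_seq[i],
                          copies = 1L)
      contig_of[i] <- length(nodes)
    } else if (is.null(fam_node[[seg_fam[i]]])) {
      id <- sprintf("contig%05d", length(nodes) + 1L)
      sq <- if (seg_ori[i] == "-") revcomp(seg_seq[i]) else seg_seq[i]
      nodes[[id]] <- list(id = id, sequence = sq, copies = 1L)
      fam_node[[seg_fam[i]]] <- length(nodes)
      contig_of[i] <- length(nodes)
    } else {
      contig_of[i] <- fam_node[[seg_fam[i]]]
      nodes[[contig_of[i]]]$copies <- nodes[[contig_of[i]]]$copies + 1L
    }
  }
  ids <- names(nodes)
  node_df <- data.frame(
    id = ids,
    length = vapply(nodes, function(n) nchar(n$sequence), integer(1)),
    depth = vapply(nodes, function(n)
      base_depth * n$copies * stats::runif(1, 0.93, 1.07), numeric(1)),
    sequence = vapply(nodes, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  # walk and edges: orientation of segment i on its contig
  walk <- data.frame(contig = ids[contig_of], orientation = seg_ori,
                     stringsAsFactors = FALSE)
  edges <- list()
  n_seg <- nrow(segs)
  for (i in seq_len(n_seg)) {
    j <- if (i == n_seg) 1L else i + 1L
    # leaving end of segment i, entering start of segment j
    from_end <- if (walk$orientation[i] == "+") "3p" else "5p"
    to_end <- if (walk$orientation[j] == "+") "5p" else "3p"
    edges[[i]] <- data.frame(from = walk$contig[i], from_end = from_end,
                             to = walk$contig[j], to_end = to_end,
                             support = stats::rpois(1, base_depth / 3) + 2L,
                             stringsAsFactors = FALSE)
  }
  edge_df <- do.call(rbind, edges)
  if (decoys) {
    dn <- data.frame(
      id = c("decoy_nuc1", "decoy_nuc2", "decoy_cp1"),
      length = c(4000L, 3000L, 2500L),
      depth = c(6, 4, 120),
      sequence = c(random_dna(4000, 0.35), random_dna(3000, 0.35),
                   random_dna(2500, 0.38)),
      stringsAsFactors = FALSE)
    node_df <- rbind(node_df, dn)
    # a spurious low-support link into a decoy
    edge_df <- rbind(edge_df, data.frame(
      from = ids[1], from_end = "3p", to = "decoy_nuc1", to_end = "5p",
      support = 1L, stringsAsFactors = FALSE))
  }
  graph <- structure(list(nodes = node_df, edges = edge_df),
                     class = "ContigGraph")
  list(graph = graph, truth = list(walk = walk))
}

# ---- RNA-editing plants ----------------------------------------------------

# editable candidate codons: C at position 1 or 2 whose C->T edit changes
# the amino acid and creates no stop (internal codons)
.edit_candidates <- function(cds) {
  cods <- .split_codons(cds)
  out <- list()
  for (ci in seq_along(cods)[-c(1L, length(cods))]) {
    cod <- cods[ci]
    for (p in 1:2) {
      if (substr(cod, p, p) != "C") next
      ed <- cod
      substr(ed, p, p) <- "T"
      aa0 <- .codon_table[[cod]]; aa1 <- .codon_table[[ed]]
      if (aa1 != aa0 && aa1 != "*")
        out[[length(out) + 1L]] <- data.frame(
          codon = ci, codon_pos = p, from = cod, to = ed,
          aa_change = paste0(aa0, ">", aa1), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(codon = integer(), codon_pos = integer(),
                  from = character(), to = character(),
                  aa_change = character(), stringsAsFactors = FALSE)
}

#' Plant C-to-U editing sites and build a reference protein panel
#'
#' For each CDS, selects codons whose genomic C at position 1 or 2 must be
#' edited to U to give the conserved residue. The panel is the translation
#' of the edited CDS with independent amino-acid noise applied to each
#' member/column. Site types are sampled with weights favouring
#' Pro-to-Leu and Ser-to-Leu conversions, the dominant types in plant
#' mitochondria.
#'
#' @param cds_set named character vector of CDS (lengths multiples of 3).
#' @param n_sites edit sites planted per gene.
#' @param panel_size reference proteins per gene.
#' @param noise per-member per-column probability of a random residue.
#' @param seed RNG seed.
#' @param type_weights named weights for aa-change types; unlisted types
#'   share the remaining mass uniformly.
#' @return list with `cds` (genomic, carrying C), `panel` (list of aa
#'   string vectors per gene), `truth` (data.frame `gene, codon,
#'   codon_pos, aa_change`).
#' @export
plant_edits <- function(cds_set, n_sites = 4L, panel_size = 12L,
                        noise = 0, seed = 4L,
                        type_weights = c("P>L" = 0.2338, "S>L" = 0.2213)) {
  set.seed(seed)
  truth <- list()
  panel <- list()
  for (g in names(cds_set)) {
    cds <- cds_set[[g]]
    if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3: ", g)
    cand <- .edit_candidates(cds)
    if (nrow(cand) < n_sites)
      stop("gene ", g, " has too few editable C sites")
    w <- rep(NA_real_, nrow(cand))
    for (ty in names(type_weights))
      w[cand$aa_change == ty] <- type_weights[[ty]]
    rest <- is.na(w)
    w[rest] <- (1 - sum(type_weights)) / max(1L, sum(rest))
    # one site per codon at most
    pick <- integer(0)
    seen <- integer(0)
    ord <- sample.int(nrow(cand), prob = w)
    for (i in ord) {
      if (cand$codon[i] %in% seen) next
      pick <- c(pick, i); seen <- c(seen, cand$codon[i])
      if (length(pick) == n_sites) break
    }
    sel <- cand[pick, , drop = FALSE]
    # edited CDS -> panel proteins
    edited <- cds
    for (i in seq_len(nrow(sel))) {
      pos <- (sel$codon[i] - 1L) * 3L + sel$codon_pos[i]
      substr(edited, pos, pos) <- "T"
    }
    prot <- translate_dna(edited)
    prot <- substr(prot, 1L, nchar(prot) - 1L)  # drop the stop
    aas <- setdiff(unique(unname(.codon_table)), "*")
    members <- vapply(seq_len(panel_size), function(m) {
      x <- strsplit(prot, "")[[1]]
      hit <- which(stats::runif(length(x)) < noise)
      for (i in hit) x[i] <- sample(setdiff(aas, x[i]), 1)
      paste(x, collapse = "")
    }, character(1))
    panel[[g]] <- members
    sel$gene <- g
    truth[[g]] <- sel[, c("gene", "codon", "codon_pos", "aa_change")]
  }
  list(cds = cds_set, panel = panel,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
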