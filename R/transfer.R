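# ---- intracellular DNA transfer --------------------------------------------

#' Class-specific transfer-detection thresholds
#'
#' Gene transfers use identity >= 80 percent, E-value <= 1e-10 and query
#' coverage >= 50 percent; mitochondrion-to-nucleus tRNA copies use
#' identity > 90 percent.
#'
#' @param class one of `"cp2mt_gene"`, `"cp2mt_trna"`, `"mt2nuc_gene"`,
#'   `"mt2nuc_trna"`.
#' @return list of `min_identity`, `min_coverage`, `evalue_cutoff`.
#' @export
transfer_thresholds <- function(class = c("cp2mt_gene", "cp2mt_trna",
                                          "mt2nuc_gene", "mt2nuc_trna")) {
  class <- match.arg(class)
  if (class == "mt2nuc_trna")
    list(min_identity = 90, min_coverage = 50, evalue_cutoff = 1e-10)
  else
    list(min_identity = 80, min_coverage = 50, evalue_cutoff = 1e-10)
}

#' Detect transferred gene copies in a target genome
#'
#' Cross-aligns each spliced source gene against the target record and
#' retains hits passing the class thresholds; per gene the best hit plus
#' all non-overlapping secondary hits are reported (multi-copy
#' transfers).
#'
#' @param source_genes named character vector of spliced gene sequences.
#' @param target_record target [genome_record()] (or DNA string).
#' @param class threshold class, see [transfer_thresholds()].
#' @param params an [align_params()] for the underlying search.
#' @return data.frame with `gene`, `target_start`, `target_end`,
#'   `orientation`, `identity`, `coverage`, `evalue`, `class`.
#' @export
detect_gene_transfers <- function(source_genes, target_record,
                                  class = "mt2nuc_gene",
                                  params = align_params(evalue_cutoff = 1e-3)) {
  if (length(source_genes) == 0L) stop("empty source gene set")
  th <- transfer_thresholds(class)
  target <- if (inherits(target_record, "GenomeRecord"))
    target_record$sequence else target_record
  out <- list()
  for (g in names(source_genes)) {
    hits <- seed_and_extend(source_genes[[g]], target, params)
    hits <- filter_hits(hits, th$min_identity, th$min_coverage,
                        th$evalue_cutoff, nchar(source_genes[[g]]))
    if (nrow(hits) == 0L) next
    hits <- hits[order(-hits$score), ]
    keep <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- min(hits$se[i], hits$se[j]) - max(hits$ss[i], hits$ss[j])
        if (ov > 0) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    hits <- hits[keep, , drop = FALSE]
    out[[g]] <- data.frame(
      gene = g, target_start = hits$ss, target_end = hits$se,
      orientation = hits$orientation, identity = hits$identity,
      coverage = hits$coverage, evalue = hits$evalue, class = class,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), target_start = integer(),
                      target_end = integer(), orientation = character(),
                      identity = numeric(), coverage = numeric(),
                      evalue = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Classify mitochondrial tRNA genes as native or plastid-derived
#'
#' A mt tRNA is `cp-derived` iff it hits any chloroplast tRNA at the
#' transfer thresholds; otherwise `native`. The result is a partition of
#' the input set.
#'
#' @param mt_trnas named character vector of mt tRNA sequences.
#' @param cp_trnas named character vector of cp tRNA sequences.
#' @param params an [align_params()].
#' @return data.frame with `trna`, `origin` (`native`/`cp-derived`),
#'   `best_cp_hit`, `identity`.
#' @export
classify_trna_origin <- function(mt_trnas, cp_trnas,
                                 params = align_params(evalue_cutoff = 1e-3)) {
  th <- transfer_thresholds("cp2mt_trna")
  rows <- lapply(names(mt_trnas), function(tn) {
    best <- NULL
    for (cn in names(cp_trnas)) {
      hits <- seed_and_extend(mt_trnas[[tn]], cp_trnas[[cn]], params)
      hits <- filter_hits(hits, th$min_identity, th$min_coverage,
                          th$evalue_cutoff, nchar(mt_trnas[[tn]]))
      if (nrow(hits) && (is.null(best) || max(hits$identity) > best$identity))
        best <- list(cp = cn, identity = max(hits$identity))
    }
    data.frame(trna = tn,
               origin = if (is.null(best)) "native" else "cp-derived",
               best_cp_hit = if (is.null(best)) NA_character_ else best$cp,
               identity = if (is.null(best)) NA_real_ else best$identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---- syntenic blocks -------------------------------------------------------

#' Find long high-identity syntenic blocks between two genomes
#'
#' Chains co-linear [seed_and_extend()] hits (same orientation, diagonal
#' drift below `max_gap`) into maximal blocks and keeps blocks of at
#' least `min_len` bp and `min_identity` percent identity. When both
#' records carry gene annotations, the order-conservation flag is set if
#' the carried genes appear in source order (or exactly reversed) in the
#' block.
#'
#' @param record_a,record_b [genome_record()]s (a = source/mt).
#' @param min_len minimum block length in bp (default 10 kb).
#' @param min_identity minimum percent identity (default 99.5).
#' @param max_gap largest chained gap in bp.
#' @param params an [align_params()].
#' @return data.frame with `a_start`, `a_end`, `b_start`, `b_end`,
#'   `length`, `identity`, `orientation`, `genes`, `order_conserved`.
#' @export
find_synteny_blocks <- function(record_a, record_b, min_len = 10000L,
                                min_identity = 99.5, max_gap = 500L,
                                params = align_params(evalue_cutoff = 1e-6)) {
  a <- if (inherits(record_a, "GenomeRecord")) record_a$sequence else record_a
  b <- if (inherits(record_b, "GenomeRecord")) record_b$sequence else record_b
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  hits <- seed_and_extend(a, b, params)
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character(), genes = character(),
                      order_conserved = logical(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$orientation, hits$qs), ]
  # chain co-linear hits
  chains <- list()
  cur <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (!is.null(cur) && h$orientation == cur$orientation &&
        h$qs - cur$a_end <= max_gap && h$qs >= cur$a_start &&
        ((h$orientation == "+" && abs((h$ss - h$qs) -
                                        (cur$b_start - cur$a_start)) <= max_gap) ||
         (h$orientation == "-" && abs((h$ss + h$qe) -
                                        (cur$b_start + cur$a_end)) <= max_gap))) {
      cur$a_end <- max(cur$a_end, h$qe)
      cur$b_start <- min(cur$b_start, h$ss); cur$b_end <- max(cur$b_end, h$se)
      cur$matches <- cur$matches + h$matches
      cur$alen <- cur$alen + h$alen
    } else {
      if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
      cur <- list(a_start = h$qs, a_end = h$qe, b_start = h$ss,
                  b_end = h$se, orientation = h$orientation,
                  matches = h$matches, alen = h$alen)
    }
  }
  if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
  rows <- lapply(chains, function(ch) {
    data.frame(a_start = ch$a_start, a_end = ch$a_end,
               b_start = ch$b_start, b_end = ch$b_end,
               length = ch$a_end - ch$a_start,
               identity = 100 * ch$matches / ch$alen,
               orientation = ch$orientation, genes = "",
               order_conserved = NA, stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, rows)
  blocks <- blocks[blocks$length >= min_len &
                     blocks$identity >= min_identity, , drop = FALSE]
  if (nrow(blocks) == 0L) return(empty)
  # gene carry-over and order conservation
  if (inherits(record_a, "GenomeRecord") && inherits(record_b, "GenomeRecord") &&
      length(record_a$features) && length(record_b$features)) {
    ga <- .gene_order(record_a); gb <- .gene_order(record_b)
    for (i in seq_len(nrow(blocks))) {
      ina <- ga[ga$start >= blocks$a_start[i] & ga$end <= blocks$a_end[i], ]
      inb <- gb[gb$start >= blocks$b_start[i] & gb$end <= blocks$b_end[i], ]
      common <- intersect(ina$gene, inb$gene)
      blocks$genes[i] <- paste(ina$gene[ina$gene %in% common], collapse = ",")
      if (length(common) >= 2L) {
        oa <- ina$gene[ina$gene %in% common]
        ob <- inb$gene[inb$gene %in% common]
        blocks$order_conserved[i] <- identical(oa, ob) ||
          identical(oa, rev(ob))
      } else blocks$order_conserved[i] <- length(common) > 0L
    }
  }
  rownames(blocks) <- NULL
  blocks
}

# ---- coding SNPs -----------------------------------------------------------

#' Count coding SNPs between paired gene copies
#'
#' Globally aligns each pair and counts substitution columns over match
#' columns only; indel columns are excluded from both the aligned-bp and
#' the substitution tally. Pairs aligning below 50 percent identity are
#' excluded with a warning.
#'
#' @param pairs named list of `c(seq_a, seq_b)` character pairs.
#' @return list with `aligned_bp`, `snps`, and `per_gene` data.frame.
#' @export
count_coding_snps <- function(pairs) {
  rows <- list()
  for (g in names(pairs)) {
    p <- pairs[[g]]
    al <- global_align(p[1], p[2], match = 1L, mismatch = -1L,
                       gap_open = 3L, gap_extend = 1L)
    a <- strsplit(al$a, "")[[1]]; b <- strsplit(al$b, "")[[1]]
    keep <- a != "-" & b != "-"
    aligned <- sum(keep)
    subs <- sum(a[keep] != b[keep])
    if (aligned == 0L || 100 * (aligned - subs) / aligned < 50) {
      warning("pair ", g, " unalignable (identity < 50%); excluded")
      next
    }
    rows[[g]] <- data.frame(gene = g, aligned_bp = aligned, snps = subs,
                            stringsAsFactors = FALSE)
  }
  per_gene <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
              else data.frame(gene = character(), aligned_bp = integer(),
                              snps = integer(), stringsAsFactors = FALSE)
  list(aligned_bp = sum(per_gene$aligned_bp), snps = sum(per_gene$snps),
       per_gene = per_gene)
}
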