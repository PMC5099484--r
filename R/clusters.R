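# ---- gene clusters ---------------------------------------------------------

# normalize a feature to a cluster element label: lower-case gene name plus
# exon qualifier when the name carries one ("nad1d", "nad5ab" style suffixes
# are kept as printed; matching is case-insensitive)
.element_label <- function(f) tolower(f$gene)

# ordered element list of a record (by genomic start)
.gene_order <- function(record, types = c("CDS", "tRNA", "rRNA")) {
  feats <- Filter(function(f) f$ftype %in% types, record$features)
  if (length(feats) == 0L)
    return(data.frame(gene = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  d <- data.frame(
    gene = vapply(feats, .element_label, character(1)),
    start = vapply(feats, function(f) min(f$spans[, 1]), integer(1)),
    end = vapply(feats, function(f) max(f$spans[, 2]), integer(1)),
    strand = vapply(feats, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  d[order(d$start), ]
}

#' Signed junction interval between two clustered genes
#'
#' Gap in bp between the end of the upstream gene and the start of the
#' downstream gene, computed in internal 0-based half-open coordinates as
#' `start2 - end1` (equivalently, 1-based `start2 - end1 - 1`). Negative
#' values indicate overlap. Circular-aware: when the downstream start lies
#' before the upstream end by more than half the genome, the gap wraps.
#'
#' @param end1 0-based half-open end of the upstream gene.
#' @param start2 0-based start of the downstream gene.
#' @param genome_length genome length for circular wrap (`NULL` = linear).
#' @return signed gap in bp.
#' @export
junction_interval <- function(end1, start2, genome_length = NULL) {
  gap <- start2 - end1
  if (!is.null(genome_length) && gap < -genome_length / 2)
    gap <- gap + genome_length
  gap
}

#' Find conserved gene clusters across genomes
#'
#' Maximal runs of two or more genes that are adjacent (no intervening
#' annotated gene, junction gap at most `max_gap`) and in the same
#' relative order (forward or reversed) in every supporting genome.
#' Strand is ignored for adjacency and recorded per member. Clusters whose
#' footprint lies inside a detected dispersed-repeat family inherit the
#' family's copy count.
#'
#' @param records list of >= 2 annotated [genome_record()]s with
#'   harmonized gene names.
#' @param max_gap largest within-cluster junction gap in bp.
#' @param repeats optional [find_dispersed_repeats()] result for the first
#'   record, used to assign copy counts.
#' @return data.frame with one row per cluster: `members` (hyphen-joined),
#'   `n_genes`, `intervals` (comma-joined signed gaps in the first
#'   genome), `start`, `end` (footprint in the first genome), `copies`.
#' @export
find_clusters <- function(records, max_gap = 2000L, repeats = NULL) {
  if (length(records) < 2L) stop("need at least two annotated genomes")
  orders <- lapply(records, .gene_order)
  ref <- orders[[1]]
  if (nrow(ref) < 2L) return(.empty_clusters())
  # adjacency sets (unordered pairs with gap <= max_gap) in each genome
  adj <- lapply(seq_along(orders), function(i) {
    d <- orders[[i]]
    L <- record_length(records[[i]])
    circ <- records[[i]]$topology == "circular"
    if (nrow(d) < 2L) return(character(0))
    pairs <- cbind(d$gene[-nrow(d)], d$gene[-1L])
    gaps <- d$start[-1L] - d$end[-nrow(d)]
    ok <- gaps <= max_gap
    p <- pairs[ok, , drop = FALSE]
    if (circ && nrow(d) >= 2L) {
      wrap_gap <- (d$start[1L] - d$end[nrow(d)]) %% L
      if (wrap_gap <= max_gap)
        p <- rbind(p, c(d$gene[nrow(d)], d$gene[1L]))
    }
    apply(p, 1, function(x) paste(sort(x), collapse = "|"))
  })
  shared <- Reduce(intersect, adj)
  if (length(shared) == 0L) return(.empty_clusters())
  # walk the reference order, chaining shared adjacencies into runs
  L1 <- record_length(records[[1]])
  circ1 <- records[[1]]$topology == "circular"
  n <- nrow(ref)
  linked <- vapply(seq_len(n - 1L), function(i) {
    key <- paste(sort(c(ref$gene[i], ref$gene[i + 1L])), collapse = "|")
    gap <- ref$start[i + 1L] - ref$end[i]
    key %in% shared && gap <= max_gap
  }, logical(1))
  runs <- rle(linked)
  out <- list()
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k]) {
      idx <- pos:(pos + runs$lengths[k])   # member indices in ref
      gaps <- vapply(idx[-length(idx)], function(i)
        junction_interval(ref$end[i], ref$start[i + 1L],
                          if (circ1) L1 else NULL), numeric(1))
      fs <- min(ref$start[idx]); fe <- max(ref$end[idx])
      copies <- 1L
      if (!is.null(repeats) && nrow(repeats)) {
        for (fam in unique(repeats$family)) {
          rf <- repeats[repeats$family == fam, ]
          inside <- any(rf$start <= fs & rf$end >= fe)
          if (inside) copies <- max(copies, max(rf$copy))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        members = paste(ref$gene[idx], collapse = "-"),
        n_genes = length(idx),
        intervals = paste(gaps, collapse = ","),
        start = fs, end = fe, copies = copies, stringsAsFactors = FALSE)
    }
    pos <- pos + runs$lengths[k]
  }
  if (length(out) == 0L) return(.empty_clusters())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_clusters <- function() {
  data.frame(members = character(), n_genes = integer(),
             intervals = character(), start = integer(), end = integer(),
             copies = integer(), stringsAsFactors = FALSE)
}
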