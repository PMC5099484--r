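# ---- composition -----------------------------------------------------------

# logical footprint mask over the genome for a set of spans
.span_mask <- function(L, spans_list) {
  m <- logical(L)
  for (sp in spans_list)
    for (r in seq_len(nrow(sp)))
      if (sp[r, 2] > sp[r, 1]) m[(sp[r, 1] + 1L):sp[r, 2]] <- TRUE
  m
}

.base_pct <- function(chars) {
  nn <- chars[chars != "N"]
  if (length(nn) == 0L) return(c(A = NA, C = NA, G = NA, T = NA))
  100 * c(A = sum(nn == "A"), C = sum(nn == "C"),
          G = sum(nn == "G"), T = sum(nn == "T")) / length(nn)
}

# introns of a feature: gaps between consecutive spans in genome order.
# On circular records a feature may wrap the origin (span pair ...L / 0...);
# the spans are unrolled at the largest circular gap (the arc outside the
# gene) so the wrap junction is never mistaken for an intron. Unrolled
# coordinates can exceed L; mask users re-wrap them.
.feature_introns <- function(f, L = NULL) {
  if (nrow(f$spans) < 2L) return(NULL)
  sp <- f$spans[order(f$spans[, 1]), , drop = FALSE]
  n <- nrow(sp)
  if (!is.null(L)) {
    gaps <- c(sp[-1L, 1] - sp[-n, 2], sp[1L, 1] + L - sp[n, 2])
    k <- which.max(gaps)
    if (k < n)
      sp <- rbind(sp[(k + 1L):n, , drop = FALSE],
                  sp[1:k, , drop = FALSE] + L)
  }
  g <- cbind(start = sp[-nrow(sp), 2], end = sp[-1L, 1])
  g <- g[g[, 2] > g[, 1], , drop = FALSE]  # gap 0 (wrap junction) = no intron
  if (nrow(g) == 0L) NULL else g
}

#' Genome composition report
#'
#' Nucleotide counts, genome proportions and A/C/G/T percentages for the
#' whole genome and for the protein-coding, cis-spliced-intron, tRNA and
#' rRNA fractions, plus their union ("coding"). Overlapping features
#' contribute once to the union; GC content is computed over non-N bases;
#' duplicated gene copies each contribute their genomic footprint.
#'
#' @param record an annotated [genome_record()].
#' @param trans_threshold bp gap above which an exon junction is counted
#'   as trans-spliced (its gap is then not a cis intron).
#' @return data.frame with one row per category: `category`, `bp`,
#'   `pct_genome`, `A`, `C`, `G`, `T`, `GC`.
#' @export
composition_report <- function(record, trans_threshold = 50000L) {
  L <- record_length(record)
  chars <- strsplit(record$sequence, "")[[1]]
  cds_spans <- lapply(Filter(function(f) f$ftype == "CDS", record$features),
                      `[[`, "spans")
  trna_spans <- lapply(Filter(function(f) f$ftype == "tRNA", record$features),
                       `[[`, "spans")
  rrna_spans <- lapply(Filter(function(f) f$ftype == "rRNA", record$features),
                       `[[`, "spans")
  Lc <- if (record$topology == "circular") L else NULL
  intr_spans <- list()
  for (f in Filter(function(f) f$ftype == "CDS", record$features)) {
    g <- .feature_introns(f, Lc)
    if (!is.null(g)) {
      cis <- g[g[, 2] - g[, 1] <= trans_threshold, , drop = FALSE]
      if (nrow(cis))
        intr_spans[[length(intr_spans) + 1L]] <- .wrap_spans(cis, L)
    }
  }
  masks <- list(
    genome = rep(TRUE, L),
    coding = .span_mask(L, c(cds_spans, intr_spans, trna_spans, rrna_spans)),
    CDS = .span_mask(L, cds_spans),
    cis_introns = .span_mask(L, intr_spans),
    tRNA = .span_mask(L, trna_spans),
    rRNA = .span_mask(L, rrna_spans))
  rows <- lapply(names(masks), function(nm) {
    cc <- chars[masks[[nm]]]
    pct <- .base_pct(cc)
    data.frame(category = nm, bp = length(cc),
               pct_genome = 100 * length(cc) / L,
               A = pct["A"], C = pct["C"], G = pct["G"], T = pct["T"],
               GC = pct["C"] + pct["G"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- codon survey ----------------------------------------------------------

#' Start/stop codon survey
#'
#' Extracts the first and last codon of each spliced CDS (in reading
#' orientation) and flags anomalies: `ACG-start` (editing-restored start),
#' `unknown-start` (neither ATG nor ACG), and `CGA-stop` (editing-created
#' stop). Multiple flags are joined with `";"`; unflagged genes are
#' `normal`.
#'
#' @param record an annotated [genome_record()].
#' @return data.frame with `gene`, `copy`, `start_codon`, `stop_codon`,
#'   `anomaly`.
#' @export
codon_survey <- function(record) {
  cds <- Filter(function(f) f$ftype == "CDS", record$features)
  rows <- lapply(cds, function(f) {
    s <- extract_sequence(record, f)
    if (nchar(s) < 6L) stop("CDS ", f$gene, " shorter than 6 nt")
    start <- substr(s, 1L, 3L)
    stop_ <- substr(s, nchar(s) - 2L, nchar(s))
    flags <- character(0)
    if (start == "ACG") flags <- c(flags, "ACG-start")
    else if (start != "ATG") flags <- c(flags, "unknown-start")
    if (stop_ == "CGA") flags <- c(flags, "CGA-stop")
    else if (!stop_ %in% c("TAA", "TAG", "TGA"))
      flags <- c(flags, "unknown-stop")
    data.frame(gene = f$gene, copy = f$copy_index, start_codon = start,
               stop_codon = stop_,
               anomaly = if (length(flags)) paste(flags, collapse = ";")
                         else "normal",
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(gene = character(), copy = integer(),
                      start_codon = character(), stop_codon = character(),
                      anomaly = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- intron census ---------------------------------------------------------

#' Cis/trans-spliced intron census
#'
#' Counts per gene copy: an exon junction is cis-spliced when consecutive
#' exon spans of a feature are co-located (gap below `trans_threshold`)
#' and trans-spliced when they are further apart or when a gene copy's
#' exons are split across several annotated features (distant loci /
#' opposite strands). Duplicated gene copies are counted per copy.
#'
#' @param record an annotated [genome_record()].
#' @param trans_threshold bp gap defining a trans-spliced junction.
#' @return data.frame with `gene`, `copy`, `cis`, `trans`, plus a
#'   `"total"` row.
#' @export
intron_census <- function(record, trans_threshold = 50000L) {
  cds <- Filter(function(f) f$ftype == "CDS", record$features)
  if (length(cds) == 0L)
    return(data.frame(gene = character(), copy = integer(),
                      cis = integer(), trans = integer()))
  key <- vapply(cds, function(f) paste0(tolower(f$gene), "#", f$copy_index),
                character(1))
  Lc <- if (record$topology == "circular") record_length(record) else NULL
  rows <- lapply(unique(key), function(k) {
    fs <- cds[key == k]
    cis <- 0L; trans <- 0L
    for (f in fs) {
      g <- .feature_introns(f, Lc)
      if (!is.null(g)) {
        gaps <- g[, 2] - g[, 1]
        cis <- cis + sum(gaps <= trans_threshold)
        trans <- trans + sum(gaps > trans_threshold)
      }
    }
    trans <- trans + (length(fs) - 1L)  # junctions between split segments
    data.frame(gene = fs[[1]]$gene, copy = fs[[1]]$copy_index,
               cis = cis, trans = trans, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(gene = "total", copy = NA_integer_,
                               cis = sum(out$cis), trans = sum(out$trans)))
  rownames(out) <- NULL
  out
}

# ---- gene content ----------------------------------------------------------

.gene_class_map <- function() {
  path <- system.file("extdata", "gene_classes.tsv", package = "mitokit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Grouped gene inventory
#'
#' Genes grouped by functional class (respiratory complexes I-V,
#' cytochrome c biogenesis, ribosomal proteins, maturase, transport,
#' rRNA, tRNA) from the bundled gene-to-class map; multi-copy genes are
#' annotated with their copy count.
#'
#' @param record an annotated [genome_record()].
#' @return data.frame with `class`, `genes` (comma-joined, with "(xN)"
#'   copy counts), and summary attribute columns `n_protein`, `n_rrna`,
#'   `n_trna` attached as attributes.
#' @export
gene_content_table <- function(record) {
  feats <- Filter(function(f) f$ftype %in% c("CDS", "tRNA", "rRNA"),
                  record$features)
  if (length(feats) == 0L)
    return(data.frame(class = character(), genes = character(),
                      stringsAsFactors = FALSE))
  map <- .gene_class_map()
  info <- data.frame(
    gene = vapply(feats, `[[`, character(1), "gene"),
    ftype = vapply(feats, `[[`, character(1), "ftype"),
    stringsAsFactors = FALSE)
  counts <- table(info$gene)
  uniq <- info[!duplicated(info$gene), ]
  uniq$class <- NA_character_
  for (i in seq_len(nrow(uniq))) {
    g <- tolower(uniq$gene[i])
    hit <- map$class[vapply(map$prefix, function(p) startsWith(g, p),
                            logical(1))]
    if (length(hit) == 0L) {
      warning("unknown gene name: ", uniq$gene[i], " -> class 'other'")
      uniq$class[i] <- "other"
    } else uniq$class[i] <- hit[1]
  }
  rows <- lapply(split(uniq, uniq$class), function(d) {
    lab <- vapply(seq_len(nrow(d)), function(i) {
      n <- counts[[d$gene[i]]]
      if (n > 1L) sprintf("%s (x%d)", d$gene[i], n) else d$gene[i]
    }, character(1))
    data.frame(class = d$class[1], genes = paste(sort(lab), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_protein") <- sum(info$ftype == "CDS")
  attr(out, "n_rrna") <- sum(info$ftype == "rRNA")
  attr(out, "n_trna") <- sum(info$ftype == "tRNA")
  out
}
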