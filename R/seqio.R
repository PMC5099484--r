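#' @useDynLib mitokit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- DNA string helpers ----------------------------------------------------

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# standard genetic code, DNA codons
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aa, codons)
})

#' Translate a DNA coding sequence
#'
#' Uses the standard genetic code; incomplete trailing codons are dropped,
#' codons containing N translate to `X`.
#'
#' @param dna a single DNA string.
#' @return a single amino-acid string (stop codons as `*`).
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  cods <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- .codon_table[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.split_codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# ---- data model ------------------------------------------------------------

#' Construct a genome feature
#'
#' Coordinates are 0-based half-open throughout the package; conversion to
#' 1-based happens only when reading/writing GenBank or GFF3.
#'
#' @param gene gene name, e.g. `"nad4"`.
#' @param ftype one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"exon"`,
#'   `"misc"`.
#' @param strand `"+"` or `"-"`.
#' @param spans integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon/span, in transcription order.
#' @param copy_index integer >= 1 distinguishing duplicated gene copies.
#' @param notes named list of free-form annotations.
#' @return an object of class `Feature`.
#' @export
feature <- function(gene, ftype = "CDS", strand = "+", spans,
                    copy_index = 1L, notes = list()) {
  if (!ftype %in% c("CDS", "tRNA", "rRNA", "intron", "exon", "misc"))
    stop("unknown feature type: ", ftype)
  if (is.null(dim(spans))) spans <- matrix(spans, ncol = 2, byrow = TRUE)
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) == 0L) stop("feature needs at least one span")
  if (any(spans[, 1] >= spans[, 2])) stop("span start must be < end")
  structure(list(gene = gene, ftype = ftype, strand = strand,
                 spans = spans, copy_index = as.integer(copy_index),
                 notes = notes),
            class = "Feature")
}

#' Construct a genome record
#'
#' @param id sequence identifier.
#' @param sequence DNA string; lower case is accepted, characters outside
#'   `{A,C,G,T,N}` are replaced with `N` with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @param features list of [feature()] objects; stored sorted by start.
#' @return an object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, topology = "linear",
                          features = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for record ", id)
  bad <- gregexpr("[^ACGTN]", sequence)[[1]]
  if (bad[1] != -1L) {
    warning(length(bad), " non-ACGTN base(s) in ", id, " replaced with N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  if (!topology %in% c("circular", "linear"))
    stop("topology must be 'circular' or 'linear'")
  rec <- structure(list(id = id, sequence = sequence, topology = topology,
                        features = list()),
                   class = "GenomeRecord")
  rec$features <- .sort_features(features)
  L <- nchar(sequence)
  for (f in rec$features) {
    if (any(f$spans < 0L) || any(f$spans > L))
      stop("feature ", f$gene, " outside [0, ", L, ")")
  }
  rec
}

.sort_features <- function(features) {
  if (length(features) == 0L) return(features)
  starts <- vapply(features, function(f) min(f$spans[, 1]), integer(1))
  features[order(starts)]
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord %s: %d bp, %s, %d features>\n",
              x$id, nchar(x$sequence), x$topology, length(x$features)))
  invisible(x)
}

#' @export
print.Feature <- function(x, ...) {
  cat(sprintf("<Feature %s [%s] %s, %d span(s) %d..%d>\n", x$gene, x$ftype,
              x$strand, nrow(x$spans), min(x$spans[, 1]), max(x$spans[, 2])))
  invisible(x)
}

#' Genome length of a record
#' @param record a [genome_record()].
#' @return integer length in bp.
#' @export
record_length <- function(record) nchar(record$sequence)

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N}` become `N`
#' with a warning. Duplicate identifiers and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @param topology topology assigned to every record.
#' @return list of [genome_record()] objects in file order.
#' @export
read_fasta <- function(path, topology = "linear") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA (no leading '>'): ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  lapply(seq_along(ids), function(i)
    genome_record(ids[i], seqs[[i]], topology = topology))
}

#' Write genome records to FASTA
#'
#' @param records a record or list of records (or named character vector).
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i)
      list(id = names(records)[i], sequence = records[[i]]))
  }
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- GenBank flat file -----------------------------------------------------

# parse a GenBank location string into (spans matrix, strand), 0-based
# half-open; handles complement(), join(), order().
.parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(?:join|order)\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  spans <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else {
      se <- c(as.integer(p), as.integer(p))
    }
    c(se[1] - 1L, se[2])  # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(spans) <- list(NULL, c("start", "end"))
  list(spans = spans, strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS topology, the feature table (gene/CDS/tRNA/rRNA with
#' `join()`/`complement()` locations) and the ORIGIN sequence block.
#' GenBank 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. A feature extending past the end of a
#' circular record is stored as a wrapped span pair.
#'
#' @param path path to a GenBank flat file.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  topo <- if (length(locus) && grepl("circular", locus[1])) "circular" else "linear"
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else basename(path)
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("GenBank file has no ORIGIN block: ", path)
  seq_lines <- lines[(oi[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    tbl <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # group continuation lines: a new feature starts at column 6
    is_key <- grepl("^ {5}\\S", tbl)
    grp <- cumsum(is_key)
    L <- nchar(sequence)
    for (g in unique(grp[grp > 0])) {
      chunk <- tbl[grp == g]
      key <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
      ftype <- key[1]
      if (!ftype %in% c("CDS", "tRNA", "rRNA", "exon", "intron", "misc_feature"))
        next
      # location may continue over lines until a /qualifier starts
      qual_start <- grep("^\\s+/", chunk)
      loc_lines <- if (length(qual_start)) chunk[seq_len(qual_start[1] - 1L)] else chunk
      loc <- paste0(key[2], paste(trimws(loc_lines[-1]), collapse = ""))
      pl <- .parse_gb_location(loc)
      quals <- paste(trimws(chunk), collapse = " ")
      gene <- sub('.*?/gene="([^"]+)".*', "\\1", quals)
      if (gene == quals)
        gene <- sub(".*?/gene=([^ \"]+).*", "\\1", quals)
      if (gene == quals) gene <- paste0(tolower(ftype), "_", g)
      ftype2 <- if (ftype == "misc_feature") "misc" else ftype
      spans <- pl$spans
      if (any(spans[, 2] > L)) {
        if (topo != "circular")
          stop("feature ", gene, " beyond sequence length in linear record")
        spans <- .wrap_spans(spans, L)
      }
      feats[[length(feats) + 1L]] <-
        feature(gene, ftype2, pl$strand, spans)
    }
  }
  # assign copy indices to duplicated (gene, ftype) pairs
  feats <- .assign_copy_index(feats)
  genome_record(id, sequence, topology = topo, features = feats)
}

# split spans that run past L into wrapped pairs, modulo L
.wrap_spans <- function(spans, L) {
  out <- NULL
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, 1]; e <- spans[i, 2]
    if (e <= L) out <- rbind(out, c(s, e))
    else if (s < L) out <- rbind(out, c(s, L), c(0L, e - L))
    else out <- rbind(out, c(s - L, e - L))
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

.assign_copy_index <- function(feats) {
  keys <- vapply(feats, function(f) paste(tolower(f$gene), f$ftype), character(1))
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    for (j in seq_along(idx)) feats[[idx[j]]]$copy_index <- j
  }
  feats
}

# ---- sequence extraction ---------------------------------------------------

#' Extract the spliced sequence of a feature
#'
#' Spans are concatenated in annotation order and reverse-complemented for
#' minus-strand features. Wrapped spans of circular records are honored.
#'
#' @param record a [genome_record()].
#' @param feat a [feature()] (or index into `record$features`).
#' @return DNA string.
#' @export
extract_sequence <- function(record, feat) {
  if (is.numeric(feat)) feat <- record$features[[feat]]
  L <- record_length(record)
  if (record$topology == "linear" && any(feat$spans > L))
    stop("span outside linear record")
  pieces <- apply(feat$spans, 1, function(se)
    substr(record$sequence, se[1] + 1L, se[2]))
  s <- paste(pieces, collapse = "")
  if (feat$strand == "-") s <- revcomp(s) else s
}

#' Rotate a circular genome record
#'
#' Shifts the origin by `k` bases; features are renormalized modulo the
#' genome length and wrapped spans are used where a feature crosses the
#' new origin. Extracted gene sequences are unchanged by rotation.
#'
#' @param record a circular [genome_record()].
#' @param k rotation offset in bp (new origin at old position `k`).
#' @return rotated [genome_record()].
#' @export
rotate_record <- function(record, k) {
  if (record$topology != "circular") stop("can only rotate circular records")
  L <- record_length(record)
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(record)
  s <- paste0(substr(record$sequence, k + 1L, L), substr(record$sequence, 1L, k))
  feats <- lapply(record$features, function(f) {
    # unwrap first (spans may already wrap), then shift, then rewrap
    spans <- f$spans
    # detect an existing wrap: a span pair (x, L) + (0, y) in order
    merged <- NULL
    i <- 1L
    while (i <= nrow(spans)) {
      if (i < nrow(spans) && spans[i, 2] == L && spans[i + 1L, 1] == 0L) {
        merged <- rbind(merged, c(spans[i, 1], L + spans[i + 1L, 2]))
        i <- i + 2L
      } else {
        merged <- rbind(merged, spans[i, , drop = FALSE])
        i <- i + 1L
      }
    }
    shifted <- merged
    shifted[, 1] <- (merged[, 1] - k) %% L
    shifted[, 2] <- shifted[, 1] + (merged[, 2] - merged[, 1])
    sp <- .wrap_spans(shifted, L)
    storage.mode(sp) <- "integer"
    f$spans <- sp
    f
  })
  genome_record(record$id, s, topology = "circular",
                features = .sort_features(feats))
}

# ---- GFF3 / BED / TSV ------------------------------------------------------

.gff_types <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                intron = "intron", exon = "exon", misc = "biological_region")

#' Write features to GFF3 (1-based inclusive)
#'
#' Multi-span features are written as one line per span sharing an `ID`.
#'
#' @param record a [genome_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", record$id,
                     record_length(record)), con)
  for (i in seq_along(record$features)) {
    f <- record$features[[i]]
    if (!f$ftype %in% names(.gff_types))
      stop("unknown feature type: ", f$ftype)
    id <- sprintf("%s.%d", f$gene, f$copy_index)
    for (r in seq_len(nrow(f$spans))) {
      writeLines(paste(record$id, "mitokit", .gff_types[[f$ftype]],
                       f$spans[r, 1] + 1L, f$spans[r, 2], ".", f$strand, ".",
                       sprintf("ID=%s;Name=%s;copy=%d;exon_index=%d",
                               id, f$gene, f$copy_index, r),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read features from a mitokit GFF3 file
#'
#' Inverse of [write_gff3()] for the fields both carry (gene, type, strand,
#' spans, copy index).
#'
#' @param path GFF3 path.
#' @param sequence optional DNA string for the returned record; if `NULL` a
#'   run of `N` of the annotated length is used.
#' @param topology record topology.
#' @return a [genome_record()].
#' @export
read_gff3 <- function(path, sequence = NULL, topology = "linear") {
  lines <- readLines(path, warn = FALSE)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  L <- if (length(sr)) as.integer(strsplit(sr[1], "\\s+")[[1]][4]) else NA_integer_
  id <- if (length(sr)) strsplit(sr[1], "\\s+")[[1]][2] else "gff"
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (is.null(sequence))
    sequence <- strrep("N", if (is.na(L)) 1L else L)
  if (length(body) == 0L)
    return(genome_record(id, sequence, topology = topology))
  fields <- strsplit(body, "\t")
  rev_types <- stats::setNames(names(.gff_types), unname(.gff_types))
  attr_of <- function(a, key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", a)
  ids <- vapply(fields, function(x) attr_of(x[9], "ID"), character(1))
  feats <- lapply(unique(ids), function(fid) {
    rows <- fields[ids == fid]
    spans <- t(vapply(rows, function(x)
      c(as.integer(x[4]) - 1L, as.integer(x[5])), integer(2)))
    feature(gene = attr_of(rows[[1]][9], "Name"),
            ftype = rev_types[[rows[[1]][3]]],
            strand = rows[[1]][7], spans = spans,
            copy_index = as.integer(attr_of(rows[[1]][9], "copy")))
  })
  genome_record(id, sequence, topology = topology, features = feats)
}

#' Write features to BED (0-based half-open)
#'
#' Multi-span features become one BED12-lite line per span (BED6 columns).
#'
#' @param record a [genome_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in record$features) {
    if (!f$ftype %in% names(.gff_types))
      stop("unknown feature type: ", f$ftype)
    for (r in seq_len(nrow(f$spans))) {
      writeLines(paste(record$id, f$spans[r, 1], f$spans[r, 2],
                       sprintf("%s.%d", f$gene, f$copy_index), 0, f$strand,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a data frame as TSV
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
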