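# ---- C-to-U RNA-editing prediction -----------------------------------------

#' Editing predictor configuration
#'
#' @param cutoff minimum conservation support C in (0, 1] for a reported
#'   site (default 0.6).
#' @param max_edits_per_codon joint C-to-U edits enumerated per codon
#'   (default 3 = all Cs of a codon).
#' @return an `EditingConfig` list.
#' @export
editing_config <- function(cutoff = 0.6, max_edits_per_codon = 3L) {
  stopifnot(cutoff > 0, cutoff <= 1, max_edits_per_codon >= 1L)
  structure(list(cutoff = cutoff,
                 max_edits_per_codon = as.integer(max_edits_per_codon)),
            class = "EditingConfig")
}

# map panel members onto the codon positions of the unedited protein;
# members already aligned (same length as the protein) pass through,
# otherwise a global residue alignment provides the column map
.panel_matrix <- function(prot, members) {
  n <- nchar(prot)
  rows <- lapply(members, function(m) {
    if (nchar(m) == n) return(strsplit(m, "")[[1]])
    al <- global_align(prot, m, match = 2L, mismatch = -1L,
                       gap_open = 11L, gap_extend = 1L)
    a <- strsplit(al$a, "")[[1]]
    b <- strsplit(al$b, "")[[1]]
    out <- rep("-", n)
    out[cumsum(a != "-")[a != "-"]] <- b[a != "-"]
    out
  })
  do.call(rbind, rows)
}

#' Predict C-to-U RNA-editing sites by protein conservation
#'
#' For each codon, all joint subsets of its C positions (up to the
#' configured cap) are edited to U in silico and translated; a variant's
#' support is the fraction of reference-panel members whose aligned
#' residue equals the variant's residue (gap members excluded). The
#' maximal-support variant wins; its edited positions are reported iff
#' support reaches the cutoff AND strictly exceeds the unedited variant's
#' support. Synonymous edits can therefore never be called, reproducing
#' the absence of third-codon-position edits.
#'
#' @param cds genomic CDS string (length a multiple of 3, coding strand).
#' @param gene_name gene label for reporting and error messages.
#' @param panel character vector of >= 3 homologous protein sequences
#'   (aligned members are detected by uniform length).
#' @param config an [editing_config()].
#' @return data.frame with `gene`, `codon` (1-based), `codon_pos` (1-3),
#'   `cds_pos` (0-based position in the CDS), `codon_from`, `codon_to`,
#'   `aa_change`, `score`.
#' @export
predict_edits <- function(cds, gene_name, panel, config = editing_config()) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (length(panel) < 3L)
    stop("reference panel for gene ", gene_name,
         " has fewer than 3 members")
  prot_full <- translate_dna(cds)
  has_stop <- endsWith(prot_full, "*")
  prot <- if (has_stop) substr(prot_full, 1L, nchar(prot_full) - 1L)
          else prot_full
  pm <- .panel_matrix(prot, panel)
  cods <- .split_codons(cds)
  n_cod <- if (has_stop) length(cods) - 1L else length(cods)
  out <- list()
  for (ci in seq_len(n_cod)) {
    cod <- cods[ci]
    cpos <- which(strsplit(cod, "")[[1]] == "C")
    if (length(cpos) == 0L) next
    if (length(cpos) > config$max_edits_per_codon)
      cpos <- cpos[seq_len(config$max_edits_per_codon)]
    col <- pm[, ci]
    informative <- col != "-"
    if (!any(informative)) next
    support_of <- function(aa) sum(col[informative] == aa) / sum(informative)
    base_aa <- .codon_table[[cod]]
    base_support <- support_of(base_aa)
    best <- list(support = -1)
    # all non-empty subsets of C positions
    for (mask in seq_len(2^length(cpos) - 1L)) {
      sel <- cpos[bitwAnd(mask, 2^(seq_along(cpos) - 1L)) > 0L]
      var <- cod
      for (p in sel) substr(var, p, p) <- "T"
      aa <- .codon_table[[var]]
      sup <- support_of(aa)
      if (sup > best$support ||
          (sup == best$support && length(sel) < length(best$sel))) {
        best <- list(support = sup, sel = sel, var = var, aa = aa)
      }
    }
    if (best$support >= config$cutoff && best$support > base_support &&
        best$aa != base_aa) {
      for (p in best$sel) {
        out[[length(out) + 1L]] <- data.frame(
          gene = gene_name, codon = ci, codon_pos = p,
          cds_pos = (ci - 1L) * 3L + p - 1L,
          codon_from = cod, codon_to = best$var,
          aa_change = paste0(base_aa, ">", best$aa),
          score = best$support, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), codon = integer(),
                      codon_pos = integer(), cds_pos = integer(),
                      codon_from = character(), codon_to = character(),
                      aa_change = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize predicted editing sites
#'
#' Tallies codon-position usage, amino-acid-change types and per-gene
#' counts; flags sites that restore a canonical start codon (ACG to AUG
#' at codon 1) or create a stop codon (e.g. CGA to UGA).
#'
#' @param sites data.frame from [predict_edits()] (possibly several genes
#'   row-bound).
#' @return list with `by_position`, `by_change`, `by_gene` data.frames and
#'   `flags` (per-site special-event labels).
#' @export
summarize_edits <- function(sites) {
  if (nrow(sites) == 0L)
    return(list(by_position = data.frame(codon_pos = integer(),
                                         n = integer(), pct = numeric()),
                by_change = data.frame(aa_change = character(),
                                       n = integer(), pct = numeric()),
                by_gene = data.frame(gene = character(), n = integer()),
                flags = character(0)))
  tp <- table(sites$codon_pos)
  by_position <- data.frame(codon_pos = as.integer(names(tp)),
                            n = as.integer(tp),
                            pct = 100 * as.integer(tp) / nrow(sites))
  tc <- sort(table(sites$aa_change), decreasing = TRUE)
  by_change <- data.frame(aa_change = names(tc), n = as.integer(tc),
                          pct = 100 * as.integer(tc) / nrow(sites),
                          stringsAsFactors = FALSE)
  tg <- table(sites$gene)
  by_gene <- data.frame(gene = names(tg), n = as.integer(tg),
                        stringsAsFactors = FALSE)
  flags <- vapply(seq_len(nrow(sites)), function(i) {
    if (sites$codon[i] == 1L && sites$codon_from[i] == "ACG" &&
        sites$codon_to[i] == "ATG") return("start-codon restoration")
    if (endsWith(sites$aa_change[i], ">*")) return("stop-codon creation")
    ""
  }, character(1))
  list(by_position = by_position, by_change = by_change,
       by_gene = by_gene, flags = flags)
}
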