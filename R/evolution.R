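# ---- NG86 Ka/Ks ------------------------------------------------------------

.stop_codons <- c("TAA", "TAG", "TGA")

# synonymous site count of one codon: per position, the fraction of the
# three possible changes that are synonymous; changes to stop codons count
# as nonsynonymous
.codon_syn_sites <- function(codon) {
  aa <- .codon_table[[codon]]
  s <- 0
  bases <- c("A", "C", "G", "T")
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (!alt %in% .stop_codons && .codon_table[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn differences between two codons over all minimal
# mutation paths with equal weights; paths through stop codons excluded
# unless every path passes one
.codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  perms <- .permutations(pos)
  res <- list()
  for (pm in perms) {
    cur <- c1
    sd <- 0; nd <- 0; valid <- TRUE
    for (p in pm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% .stop_codons && nxt != c2) { valid <- FALSE; break }
      if (.codon_table[[cur]] == .codon_table[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (valid) res[[length(res) + 1L]] <- c(sd, nd)
  }
  if (length(res) == 0L) { # all paths blocked by stops: use them anyway
    for (pm in perms) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in pm) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (.codon_table[[cur]] == .codon_table[[nxt]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      res[[length(res) + 1L]] <- c(sd, nd)
    }
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[1], nd = m[2])
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Jukes-Cantor distance correction
#'
#' \eqn{d = -3/4 \ln(1 - 4p/3)}; `NA` at saturation (p >= 3/4).
#'
#' @param p proportion of differing sites.
#' @return corrected distance (vectorized).
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned CDS pair
#'
#' Classic NG86 with equal pathway weights: per-codon synonymous and
#' nonsynonymous site fractions are averaged over both sequences,
#' observed differences are averaged over all minimal mutation paths,
#' and pS/pN are Jukes-Cantor corrected. Codons containing gaps or N in
#' either sequence are masked out first. The ratio is classified as
#' purifying (< 1), near-neutral (in `[0.85, 1.15]`, operationalizing
#' "close to 1") or positive (> 1).
#'
#' @param cds_a,cds_b aligned equal-length CDS strings (length a multiple
#'   of 3 after masking).
#' @param gene optional gene label.
#' @return list `KaKsResult`: `gene`, `Ka`, `Ks`, `ratio`,
#'   `classification`, plus raw `S`, `N`, `Sd`, `Nd`.
#' @export
ng86 <- function(cds_a, cds_b, gene = NA_character_) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be aligned")
  ca <- .split_codons(cds_a); cb <- .split_codons(cds_b)
  ok <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop("no complete codons after masking")
  if (any(ca[-length(ca)] %in% .stop_codons) ||
      any(cb[-length(cb)] %in% .stop_codons))
    stop("internal stop codon")
  # drop terminal stops
  if (ca[length(ca)] %in% .stop_codons || cb[length(cb)] %in% .stop_codons) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  Sa <- sum(vapply(ca, .codon_syn_sites, numeric(1)))
  Sb <- sum(vapply(cb, .codon_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) .codon_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  cls <- if (is.na(ratio)) NA_character_
         else if (ratio >= 0.85 && ratio <= 1.15) "near-neutral"
         else if (ratio < 1) "purifying" else "positive"
  list(gene = gene, Ka = Ka, Ks = Ks, ratio = ratio, classification = cls,
       S = S, N = N, Sd = Sd, Nd = Nd)
}

# ---- concatenation and distances -------------------------------------------

#' Concatenate per-gene alignments into a phylogenetic matrix
#'
#' Taxa missing from any gene are dropped with a warning; per-gene
#' alignments are concatenated; columns containing any gap or missing
#' character in any taxon are removed (complete deletion). A Jukes-Cantor
#' distance matrix is computed on the result.
#'
#' @param ortholog_sets named list (per gene) of named character vectors
#'   of aligned sequences (names = taxa).
#' @param gene_list genes to use (default: all).
#' @return list `PhyloMatrix`: `taxa`, `alignment` (named vector),
#'   `length`, `dist` (symmetric matrix).
#' @export
concatenate_genes <- function(ortholog_sets, gene_list = names(ortholog_sets)) {
  sets <- ortholog_sets[gene_list]
  taxa <- Reduce(intersect, lapply(sets, names))
  all_taxa <- unique(unlist(lapply(sets, names)))
  dropped <- setdiff(all_taxa, taxa)
  if (length(dropped))
    warning("taxa missing from some genes dropped: ",
            paste(dropped, collapse = ", "))
  if (length(taxa) < 4L) stop("fewer than 4 taxa shared across genes")
  cat_seq <- vapply(taxa, function(tx)
    paste(vapply(sets, function(s) s[[tx]], character(1)), collapse = ""),
    character(1))
  mat <- do.call(rbind, strsplit(cat_seq, ""))
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  aln <- apply(mat, 1, paste, collapse = "")
  names(aln) <- taxa
  list(taxa = taxa, alignment = aln, length = ncol(mat),
       dist = jc_dist_matrix(aln))
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param alignment named character vector of equal-length gapless
#'   sequences.
#' @return symmetric matrix of JC distances with zero diagonal.
#' @export
jc_dist_matrix <- function(alignment) {
  taxa <- names(alignment)
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(mat[i, ] != mat[j, ])
    d <- jc_correct(p)
    D[i, j] <- D[j, i] <- d
  }
  D
}

# ---- neighbor joining ------------------------------------------------------

#' Saitou-Nei neighbor-joining tree
#'
#' Classic NJ on a symmetric distance matrix. Q-matrix ties are broken by
#' the smallest taxon-index pair; negative branch lengths are clamped to
#' zero with the excess transferred to the sister branch. Returns an
#' unrooted `ape::phylo` tree.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an unrooted binary `phylo` object.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  # active nodes as newick substrings
  nodes <- labels
  Dm <- D
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- sprintf("(%s:%.10f,%s:%.10f)", nodes[i], bi, nodes[j], bj)
    dk <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    dimnames(Dm2) <- list(NULL, NULL)
    Dm <- Dm2
  }
  # terminal 3-star
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  nwk <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 nodes[1], b1, nodes[2], b2, nodes[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the JC distance
#' matrix and NJ tree for each replicate, and reports for each internal
#' edge of the original tree the percentage of replicates containing the
#' same bipartition. Deterministic for a fixed seed.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param n number of replicates (default 1000).
#' @param seed RNG seed.
#' @return the original NJ tree with `node.label` set to bootstrap
#'   percentages (root label empty).
#' @export
nj_bootstrap <- function(alignment, n = 1000L, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  orig <- nj_tree(jc_dist_matrix(alignment))
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(mat) <- names(alignment)
  ncol_a <- ncol(mat)
  boots <- vector("list", n)
  for (b in seq_len(n)) {
    idx <- sample.int(ncol_a, ncol_a, replace = TRUE)
    aln <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
    boots[[b]] <- nj_tree(jc_dist_matrix(aln))
  }
  counts <- ape::prop.clades(orig, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  orig$node.label <- as.character(round(100 * counts / n))
  orig
}

#' Root a tree on an outgroup taxon
#'
#' Places the root on the outgroup's pendant edge so the outgroup is
#' sister to everything else.
#'
#' @param tree a `phylo` object.
#' @param taxon outgroup tip label.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label)
    stop("outgroup taxon not in tree: ", taxon)
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}
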