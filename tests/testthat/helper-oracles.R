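# Independent oracles used by the property tests. These deliberately use
# different mechanisms than the package implementations (regex engine,
# plain dynamic-programming loops, Biostrings' genetic code).

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- SSR oracle: backreference regex enumeration ---------------------------
# maximal perfect repetitions found by the PCRE engine, then reduced with
# the same reporting policy (smallest true period, no overlap)
oracle_ssrs <- function(s, thresholds = c(8L, 4L, 4L, 3L, 3L, 3L)) {
  cand <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thresholds[u] - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      unit <- substr(s, m[k], m[k] + u - 1L)
      # regex may match at a non-primitive period
      sp <- u
      for (d in seq_len(u - 1L))
        if (u %% d == 0L && unit == strrep(substr(unit, 1, d), u / d)) {
          sp <- d; break
        }
      if (sp < u) next
      copies <- len[k] %/% u
      if (copies < thresholds[u]) next
      cand[[length(cand) + 1L]] <- data.frame(
        unit_len = u, copies = copies, start = m[k] - 1L,
        end = m[k] - 1L + copies * u, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(unit_len = integer(), copies = integer(),
                      start = integer(), end = integer()))
  out <- do.call(rbind, cand)
  # maximality: regex is greedy but can report a shifted sub-run already
  # covered; apply the same resolution policy as the scanner
  out <- out[order(out$unit_len, -(out$end - out$start), out$start), ]
  keep <- logical(nrow(out))
  occ <- integer(0)
  for (i in seq_len(nrow(out))) {
    span <- (out$start[i] + 1L):out$end[i]
    if (!any(span %in% occ)) { keep[i] <- TRUE; occ <- c(occ, span) }
  }
  out <- out[keep, ]
  out[order(out$start), ]
}

# --- full Smith-Waterman oracle (plain R loops, affine gaps) ----------------
oracle_sw_score <- function(a, b, match = 1L, mismatch = -3L,
                            gap_open = 3L, gap_ext = 3L) {
  n <- nchar(a); m <- nchar(b)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_ext, E[i, j - 1L] - gap_ext)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_ext, F[i - 1L, j] - gap_ext)
      sub <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# --- NG86 oracle: independent enumeration using Biostrings' code table ------
oracle_ng86 <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  aa_of <- function(cod) unname(gc[gsub("T", "T", cod)])
  stops <- names(gc)[gc == "*"]
  codons_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  codons_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  # drop terminal stop
  k <- length(codons_a)
  if (aa_of(codons_a[k]) == "*" || aa_of(codons_b[k]) == "*") {
    codons_a <- codons_a[-k]; codons_b <- codons_b[-k]
  }
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                      substr(cod, p, p))) {
      alt <- cod; substr(alt, p, p) <- nt
      if (!alt %in% stops && aa_of(alt) == aa_of(cod)) s <- s + 1 / 3
    }
    s
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (p in perms_of(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
    res
  }
  diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    acc <- list()
    for (pm in perms_of(pos)) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in pm) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops && nxt != c2) { ok <- FALSE; break }
        if (aa_of(nxt) == aa_of(cur)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc[[length(acc) + 1]] <- c(sd, nd)
    }
    colMeans(do.call(rbind, acc))
  }
  S <- (sum(vapply(codons_a, syn_sites, 0)) +
          sum(vapply(codons_b, syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  d <- vapply(seq_along(codons_a),
              function(i) diffs(codons_a[i], codons_b[i]), numeric(2))
  pS <- sum(d[1, ]) / S
  pN <- sum(d[2, ]) / N
  list(Ka = -0.75 * log(1 - 4 * pN / 3), Ks = -0.75 * log(1 - 4 * pS / 3),
       S = S, N = N, Sd = sum(d[1, ]), Nd = sum(d[2, ]))
}

# --- random additive (tree-metric) distance matrix --------------------------
# build a random binary tree, assign positive branch lengths, return the
# path-length matrix plus the ape tree it came from
oracle_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = ape::unroot(tr), D = D)
}

# mutate with i.i.d. substitutions (test-local copy)
mutate_seq <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

# small sim config used across tests (desk-scale)
small_sim <- function(seed, L = 20000L,
                      dispersed = list(list(length = 1200L, identity = 99.6,
                                            orientation = "DR", n_copies = 2L),
                                       list(length = 800L, identity = 100,
                                            orientation = "IR", n_copies = 2L))) {
  sim_config(seed = seed, genome_length = L, planted_dispersed = dispersed)
}
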