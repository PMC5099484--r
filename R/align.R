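# ---- alignment parameters --------------------------------------------------

#' Alignment scoring and filtering parameters
#'
#' Defaults follow the classic nucleotide self-search settings for plant
#' organelle repeat analysis: match +1, mismatch -3, gap open 3, gap extend
#' 3 (a gap of length k costs 3 + 3k), word size 7, repeat E-value cutoff 1.
#' `lambda` is solved from the ungapped Karlin-Altschul equation for the
#' given scores at uniform base composition; `K` defaults to the standard
#' +1/-3 value and can be re-estimated with [calibrate_evalue_k()].
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend per-base gap extension penalty (positive).
#' @param word_size exact-match seed length W (>= 4).
#' @param evalue_cutoff maximum E-value for a reported hit.
#' @param min_identity minimum percent identity (0 disables).
#' @param min_coverage minimum percent query coverage (0 disables).
#' @param band half-width of the banded extension.
#' @param K Karlin-Altschul K constant.
#' @param max_hits reporting cap (Inf = unlimited).
#' @return an object of class `AlignParams`.
#' @export
align_params <- function(match = 1L, mismatch = -3L, gap_open = 3L,
                         gap_extend = 3L, word_size = 7L,
                         evalue_cutoff = 1, min_identity = 0,
                         min_coverage = 0, band = 25L, K = 0.711,
                         max_hits = Inf) {
  stopifnot(word_size >= 4L, gap_open >= 0, gap_extend >= 0,
            evalue_cutoff >= 0, match > 0, mismatch < 0)
  lambda <- .solve_lambda(match, mismatch)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 evalue_cutoff = evalue_cutoff,
                 min_identity = min_identity, min_coverage = min_coverage,
                 band = as.integer(band), lambda = lambda, K = K,
                 max_hits = max_hits),
            class = "AlignParams")
}

# ungapped lambda for uniform composition: sum_ij p_i p_j exp(lambda s_ij) = 1
.solve_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}} for raw score `S` on a search space of
#' `query_len` by `subject_len`.
#'
#' @param score raw alignment score (>= 0).
#' @param query_len,subject_len sequence lengths (> 0).
#' @param params an [align_params()] object supplying `K` and `lambda`.
#' @return the expected number of chance hits at or above `score`.
#' @export
evalue <- function(score, query_len, subject_len, params = align_params()) {
  if (query_len <= 0 || subject_len <= 0) stop("non-positive sequence length")
  stopifnot(all(score >= 0))
  params$K * as.numeric(query_len) * as.numeric(subject_len) *
    exp(-params$lambda * score)
}

#' Empirically calibrate the E-value K constant
#'
#' Runs self-searches of shuffled random sequence pairs and fits `K` so the
#' observed top-score distribution matches the extreme-value expectation
#' \eqn{P(S \ge x) = 1 - \exp(-K m n e^{-\lambda x})}. Used once to sanity
#' check the analytic default; exposed because the source scoring scheme
#' only fixes thresholds, never constants.
#'
#' @param params an [align_params()].
#' @param n_trials number of random pairs.
#' @param len length of each random sequence.
#' @param seed RNG seed.
#' @return list with the fitted `K` and the observed mean top score.
#' @export
calibrate_evalue_k <- function(params = align_params(), n_trials = 30L,
                               len = 1000L, seed = 1L) {
  set.seed(seed)
  tops <- vapply(seq_len(n_trials), function(i) {
    a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    h <- seed_and_extend(a, b, params, filter_evalue = FALSE)
    if (nrow(h) == 0L) 0 else max(h$score)
  }, numeric(1))
  # E[S_max] ~ log(K m n)/lambda + gamma/lambda for Gumbel tail
  mn <- as.numeric(len)^2
  K_hat <- exp(mean(tops) * params$lambda - 0.5772) / mn
  list(K = K_hat, mean_top_score = mean(tops))
}

# ---- seeding and extension -------------------------------------------------

# positions (0-based) of all word_size-mer matches between q and s,
# returned as data.frame(qpos, spos, diag)
.find_seeds <- function(q, s, W) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < W || ns < W) return(data.frame(qpos = integer(), spos = integer()))
  qpos <- seq_len(nq - W + 1L)
  spos <- seq_len(ns - W + 1L)
  qk <- substring(q, qpos, qpos + W - 1L)
  sk <- substring(s, spos, spos + W - 1L)
  sidx <- split(spos, sk)
  # soft-mask over-represented words (low-complexity/AT-rich noise):
  # keep words occurring at most ~6x the random expectation
  maxocc <- max(6, ceiling(6 * ns / 4^W))
  sidx <- sidx[lengths(sidx) <= maxocc]
  hit <- qk %in% names(sidx)
  if (!any(hit)) return(data.frame(qpos = integer(), spos = integer()))
  qh <- qpos[hit]
  sl <- sidx[qk[hit]]
  reps <- lengths(sl)
  data.frame(qpos = rep(qh, reps) - 1L, spos = unlist(sl, use.names = FALSE) - 1L)
}

# two-stage seed clustering: (1) runs of seeds on the same exact diagonal
# with small query gaps -- runs with a single isolated seed are discarded
# (two-hit heuristic, removes random word collisions); (2) nearby runs
# (diagonal within band, query gap small) merged into one candidate
# region for gapped extension
.cluster_seeds <- function(seeds, band, W, min_span = W, run_gap = 40L,
                           merge_gap = 120L) {
  seeds$diag <- seeds$spos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$qpos), ]
  n <- nrow(seeds)
  new_run <- c(TRUE, (diff(seeds$diag) != 0L) |
                 (diff(seeds$qpos) > run_gap))
  run <- cumsum(new_run)
  q0 <- tapply(seeds$qpos, run, min)
  q1 <- tapply(seeds$qpos, run, max)
  runs <- data.frame(diag = seeds$diag[new_run],
                     q0 = as.integer(q0), q1 = as.integer(q1) + W)
  runs <- runs[(runs$q1 - runs$q0) >= min_span, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  runs <- runs[order(runs$diag, runs$q0), ]
  n_r <- nrow(runs)
  cl <- integer(n_r)
  cl[1] <- 1L
  if (n_r > 1L) {
    lo <- 1L
    for (i in 2:n_r) {
      while (runs$diag[i] - runs$diag[lo] > band) lo <- lo + 1L
      prev <- 0L
      if (lo <= i - 1L) {
        for (j in seq(i - 1L, lo)) {
          if (min(runs$q1[j], runs$q1[i]) + merge_gap >=
                max(runs$q0[j], runs$q0[i])) { prev <- j; break }
        }
      }
      cl[i] <- if (prev > 0L) cl[prev] else max(cl[1:(i - 1L)]) + 1L
    }
  }
  runs$cluster <- cl
  runs
}

#' Seeded, gapped local alignment
#'
#' BLAST-style search: exact `word_size`-mer seeds are clustered by
#' diagonal, each cluster is extended by banded Smith-Waterman dynamic
#' programming, and overlapping/contained hits are merged to the
#' highest-scoring representative. Both strands of the subject are
#' searched. Hits are reported with 0-based half-open query and subject
#' intervals; minus-orientation hits report the subject interval on the
#' forward strand of the subject.
#'
#' @param query,subject DNA strings (or [genome_record()]s).
#' @param params an [align_params()].
#' @param both_strands search the reverse complement of the subject too.
#' @param filter_evalue drop hits with E-value above the cutoff.
#' @return data.frame with columns `qs, qe, ss, se, orientation, alen,
#'   matches, identity, score, evalue, ops`.
#' @export
seed_and_extend <- function(query, subject, params = align_params(),
                            both_strands = TRUE, filter_evalue = TRUE) {
  if (inherits(query, "GenomeRecord")) query <- query$sequence
  if (inherits(subject, "GenomeRecord")) subject <- subject$sequence
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("empty sequence")
  hits <- .strand_hits(query, subject, params, "+")
  if (both_strands) {
    rc <- revcomp(subject)
    mh <- .strand_hits(query, rc, params, "-")
    if (nrow(mh)) {
      L <- nchar(subject)
      ss <- L - mh$se; se <- L - mh$ss
      mh$ss <- ss; mh$se <- se
      hits <- rbind(hits, mh)
    }
  }
  if (nrow(hits) == 0L) return(hits)
  hits$evalue <- evalue(hits$score, nchar(query), nchar(subject), params)
  if (filter_evalue) hits <- hits[hits$evalue <= params$evalue_cutoff, ]
  hits <- .merge_hits(hits)
  if (is.finite(params$max_hits) && nrow(hits) > params$max_hits)
    hits <- hits[seq_len(params$max_hits), ]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(qs = integer(), qe = integer(), ss = integer(), se = integer(),
             orientation = character(), alen = integer(), matches = integer(),
             identity = numeric(), score = integer(), evalue = numeric(),
             ops = character(), stringsAsFactors = FALSE)
}

.strand_hits <- function(q, s, params, orientation) {
  seeds <- .find_seeds(q, s, params$word_size)
  if (nrow(seeds) == 0L) return(.empty_hits())
  # exact-core length needed so that <= ~200 chance candidate runs survive
  # on this search space; never below the word size
  min_span <- max(params$word_size,
                  ceiling(log(as.numeric(nchar(q)) * nchar(s) / 200) / log(4)))
  runs <- .cluster_seeds(seeds, params$band, params$word_size, min_span)
  if (is.null(runs)) return(.empty_hits())
  out <- list()
  pad <- 60L
  for (cl in split(runs, runs$cluster)) {
    q0 <- max(0L, min(cl$q0) - pad)
    q1 <- min(nchar(q), max(cl$q1) + pad)
    s0 <- max(0L, min(cl$q0 + cl$diag) - pad)
    s1 <- min(nchar(s), max(cl$q1 + cl$diag) + pad)
    d0 <- as.integer(round(stats::median(cl$diag))) - (s0 - q0)
    res <- .c_banded_sw(substr(q, q0 + 1L, q1), substr(s, s0 + 1L, s1),
                        d0, params$band, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
    if (res$score <= 0L) next
    out[[length(out) + 1L]] <- data.frame(
      qs = q0 + res$qs, qe = q0 + res$qe, ss = s0 + res$ss, se = s0 + res$se,
      orientation = orientation, alen = res$alen, matches = res$matches,
      identity = 100 * res$matches / res$alen, score = res$score,
      evalue = NA_real_, ops = res$ops, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(.empty_hits())
  do.call(rbind, out)
}

# remove duplicates and hits wholly contained in a longer hit with >=
# identity; keep the highest-scoring representative
.merge_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[!duplicated(hits[, c("qs", "qe", "ss", "se", "orientation")]), ]
  hits <- hits[order(-hits$score), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[j]) next
      same_diag <- if (hits$orientation[i] == "+")
        abs((hits$qs[j] - hits$ss[j]) - (hits$qs[i] - hits$ss[i])) <= 50
      else
        abs((hits$qs[j] + hits$se[j]) - (hits$qs[i] + hits$se[i])) <= 50
      if (hits$orientation[i] == hits$orientation[j] && same_diag &&
          hits$qs[j] >= hits$qs[i] && hits$qe[j] <= hits$qe[i] &&
          hits$ss[j] >= hits$ss[i] && hits$se[j] <= hits$se[i] &&
          hits$identity[i] >= hits$identity[j] - 1e-9)
        keep[j] <- FALSE
    }
  }
  hits[keep, ]
}

#' Filter alignment hits by identity, coverage and E-value
#'
#' Coverage is aligned query bases / `query_len` * 100.
#'
#' @param hits data.frame from [seed_and_extend()].
#' @param min_identity minimum percent identity (inclusive).
#' @param min_coverage minimum percent query coverage (inclusive).
#' @param evalue_cutoff maximum E-value (inclusive).
#' @param query_len query length used for coverage.
#' @return filtered hit data.frame (with a `coverage` column added).
#' @export
filter_hits <- function(hits, min_identity = 80, min_coverage = 50,
                        evalue_cutoff = 1e-10, query_len) {
  if (nrow(hits) == 0L) { hits$coverage <- numeric(); return(hits) }
  hits$coverage <- 100 * (hits$qe - hits$qs) / query_len
  hits[hits$identity >= min_identity & hits$coverage >= min_coverage &
         hits$evalue <= evalue_cutoff, , drop = FALSE]
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps; convenience wrapper used by the
#' SNP-counting and editing-panel stages.
#'
#' @param a,b DNA or protein strings.
#' @param match,mismatch,gap_open,gap_extend scoring.
#' @return list with `score`, gapped strings `a`/`b`, `matches`, `columns`.
#' @export
global_align <- function(a, b, match = 1L, mismatch = -1L, gap_open = 3L,
                         gap_extend = 1L) {
  .c_global_align(a, b, as.integer(match), as.integer(mismatch),
                  as.integer(gap_open), as.integer(gap_extend))
}
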