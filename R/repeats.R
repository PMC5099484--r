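# ---- SSR scanner -----------------------------------------------------------

# smallest period of a string (length if primitive)
.smallest_period <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), u %/% d)) return(d)
  }
  u
}

.min_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(i)
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L)), character(1))
  min(rots)
}

#' Find simple sequence repeats (microsatellites)
#'
#' Reports maximal perfect repetitions of 1-6 bp motifs meeting the
#' per-motif-length copy-number thresholds (MISA-style, default
#' 8,4,4,3,3,3 for mono- through hexanucleotides). A run reportable at
#' several unit lengths is reported once at its smallest true period, and
#' reported SSRs never overlap. No compound-SSR merging is applied.
#'
#' @param record a [genome_record()] or DNA string.
#' @param thresholds integer vector of length 6: minimum copies for unit
#'   lengths 1..6.
#' @return data.frame with columns `motif` (canonical minimal rotation),
#'   `unit` (as in sequence), `unit_len`, `copies`, `start`, `end`
#'   (0-based half-open), `length`.
#' @export
find_ssrs <- function(record, thresholds = c(8L, 4L, 4L, 3L, 3L, 3L)) {
  s <- if (inherits(record, "GenomeRecord")) record$sequence else record
  stopifnot(length(thresholds) == 6L)
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  cand <- list()
  for (u in 1:6) {
    if (n < u * thresholds[u]) next
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & (r$lengths + u) >= u * thresholds[u])
    for (k in runs) {
      i <- starts[k]                       # 1-based start of periodic region
      total <- r$lengths[k] + u
      copies <- total %/% u
      if (copies < thresholds[u]) next
      unit <- substr(s, i, i + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      if (.smallest_period(unit) < u) next # reported at the true period
      cand[[length(cand) + 1L]] <- data.frame(
        motif = .min_rotation(unit), unit = unit, unit_len = u,
        copies = copies, start = i - 1L, end = i - 1L + copies * u,
        length = copies * u, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(motif = character(), unit = character(),
                      unit_len = integer(), copies = integer(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, cand)
  # overlap resolution: smaller period wins, then longer run, then leftmost
  out <- out[order(out$unit_len, -out$length, out$start), ]
  keep <- logical(nrow(out))
  occ <- integer(0)
  for (i in seq_len(nrow(out))) {
    span <- (out$start[i] + 1L):out$end[i]
    if (!any(span %in% occ)) { keep[i] <- TRUE; occ <- c(occ, span) }
  }
  out <- out[keep, ]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# ---- tandem repeat scanner -------------------------------------------------

#' Find tandem repeats
#'
#' Period detection by lag autocorrelation followed by verification against
#' the candidate unit (Benson-style, not a TRF port). Detects adjacent
#' repetitions of a unit of at least `min_period` bp with at least
#' `min_copies` copies at `min_identity` percent identity or better.
#' Periods reportable as SSRs (unit <= 6 bp) are excluded by the
#' `min_period` default.
#'
#' @param record a [genome_record()] or DNA string.
#' @param min_period minimum unit length in bp (default 7).
#' @param min_copies minimum copy number (default 2).
#' @param min_identity minimum percent identity (default 90).
#' @param max_period largest period searched (default 100).
#' @param max_mismatch_run mismatch interruptions merged within a run.
#' @return data.frame with `period`, `copies`, `identity`, `consensus`,
#'   `start`, `end` (0-based half-open), `length`.
#' @export
find_tandem_repeats <- function(record, min_period = 7L, min_copies = 2,
                                min_identity = 90, max_period = 100L,
                                max_mismatch_run = 2L) {
  s <- if (inherits(record, "GenomeRecord")) record$sequence else record
  stopifnot(min_period > 0L, min_copies >= 2, min_identity > 0)
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  cand <- list()
  for (p in min_period:min(max_period, n %/% 2L)) {
    eq <- x[seq_len(n - p)] == x[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    anchor <- max(4L, p %/% 3L)
    cores <- which(r$values & r$lengths >= anchor)
    if (length(cores) == 0L) next
    seen <- character(0)
    for (k in cores) {
      # greedy extension through short mismatch interruptions while the
      # lag-identity stays above the threshold
      lo <- k; hi <- k
      matches <- r$lengths[k]; span <- r$lengths[k]
      repeat {
        moved <- FALSE
        # TRF-like weighting (match +2, mismatch -7): an extension must
        # pay for its mismatches and keep the overall identity
        if (hi + 2L <= length(r$lengths) && !r$values[hi + 1L] &&
            r$lengths[hi + 1L] <= max_mismatch_run) {
          f <- r$lengths[hi + 1L]; t <- r$lengths[hi + 2L]
          if (2L * t - 7L * f >= 0L &&
              100 * (matches + t) / (span + f + t) >= min_identity) {
            matches <- matches + t; span <- span + f + t
            hi <- hi + 2L; moved <- TRUE
          }
        }
        if (lo - 2L >= 1L && !r$values[lo - 1L] &&
            r$lengths[lo - 1L] <= max_mismatch_run) {
          f <- r$lengths[lo - 1L]; t <- r$lengths[lo - 2L]
          if (2L * t - 7L * f >= 0L &&
              100 * (matches + t) / (span + f + t) >= min_identity) {
            matches <- matches + t; span <- span + f + t
            lo <- lo - 2L; moved <- TRUE
          }
        }
        if (!moved) break
      }
      idx0 <- starts[lo]; idx1 <- ends[hi]
      total <- (idx1 - idx0 + 1L) + p
      if (total < p * min_copies) next
      identity <- 100 * matches / (total - p)
      if (identity < min_identity) next
      key <- paste(p, idx0, idx1)
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- data.frame(
        period = p, start = idx0 - 1L, end = idx0 - 1L + total,
        length = total, copies = round(total / p, 1),
        identity = identity, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(period = integer(), copies = numeric(),
                      identity = numeric(), consensus = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  out <- do.call(rbind, cand)
  # drop candidates whose unit is itself periodic at a smaller period
  prim <- vapply(seq_len(nrow(out)), function(i) {
    unit <- substr(s, out$start[i] + 1L, out$start[i] + out$period[i])
    sp <- .smallest_period(unit)
    sp == out$period[i] || sp < min_period
  }, logical(1))
  smallp <- vapply(seq_len(nrow(out)), function(i) {
    unit <- substr(s, out$start[i] + 1L, out$start[i] + out$period[i])
    .smallest_period(unit) < min_period   # SSR territory
  }, logical(1))
  out <- out[prim & !smallp, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  # overlap resolution: smallest period wins, then longest
  out <- out[order(out$period, -out$length, out$start), ]
  keep <- logical(nrow(out))
  occ <- integer(0)
  for (i in seq_len(nrow(out))) {
    span <- (out$start[i] + 1L):out$end[i]
    if (!any(span %in% occ)) { keep[i] <- TRUE; occ <- c(occ, span) }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$consensus <- vapply(seq_len(nrow(out)), function(i)
    .tandem_consensus(s, out$start[i], out$end[i], out$period[i]),
    character(1))
  rownames(out) <- NULL
  out[, c("period", "copies", "identity", "consensus", "start", "end",
          "length")]
}

# per-column majority over full copies
.tandem_consensus <- function(s, start, end, p) {
  region <- substr(s, start + 1L, end)
  ncop <- nchar(region) %/% p
  rows <- substring(region, p * (seq_len(ncop) - 1L) + 1L, p * seq_len(ncop))
  cols <- do.call(rbind, strsplit(rows, ""))
  paste(apply(cols, 2, function(cc)
    names(sort(table(cc), decreasing = TRUE))[1]), collapse = "")
}

# ---- dispersed repeat families ---------------------------------------------

#' Find dispersed repeat families (direct / inverted)
#'
#' Self-alignment with [seed_and_extend()] (trivial full-length identity
#' hit removed), hits clustered into families by reciprocal interval
#' overlap, each family typed `DR` (all extra copies in the same
#' orientation as copy 1), `IR` (all inverted), or `DR/IR` (both).
#' Families are sorted by unit length descending and labelled `R1, R2,
#' ...`; ties are broken by leftmost first copy. Circular records are
#' additionally scanned at a half-genome rotation so origin-spanning
#' copies are seen; coordinates are reported on the input rotation.
#'
#' @param record a [genome_record()] or DNA string.
#' @param params an [align_params()]; the defaults are the classic
#'   +1/-3/3/3 W=7 E<=1 repeat-search settings.
#' @param min_report_len shortest reported repeat copy (default 20 bp).
#' @return data.frame with one row per family copy: `family`, `unit_len`,
#'   `identity`, `copy` (1..k), `start`, `end`, `orientation` (`+`/`-`
#'   relative to copy 1), `type` (`DR`, `IR` or `DR/IR`).
#' @export
find_dispersed_repeats <- function(record, params = align_params(),
                                   min_report_len = 20L) {
  circular <- inherits(record, "GenomeRecord") && record$topology == "circular"
  s <- if (inherits(record, "GenomeRecord")) record$sequence else record
  L <- nchar(s)
  fams <- .dispersed_scan(s, params, min_report_len)
  if (circular && L > 4L * min_report_len) {
    k <- L %/% 2L
    s2 <- paste0(substr(s, k + 1L, L), substr(s, 1L, k))
    f2 <- .dispersed_scan(s2, params, min_report_len)
    if (nrow(f2)) {
      # shift back; keep only families with a copy spanning the original
      # origin (those are invisible to the unrotated scan)
      f2$start <- (f2$start + k) %% L
      f2$end <- f2$start + f2$len0
      wraps <- tapply(f2$end > L, f2$family, any)
      f2 <- f2[f2$family %in% names(wraps)[wraps], , drop = FALSE]
      if (nrow(f2) && nrow(fams)) {
        # drop rotated families overlapping an already-found family
        ov <- vapply(unique(f2$family), function(fam) {
          rows <- f2[f2$family == fam, ]
          any(vapply(seq_len(nrow(fams)), function(i)
            any(pmin(rows$end, fams$end[i]) - pmax(rows$start, fams$start[i]) >
                  0.5 * pmin(rows$len0, fams$len0[i])), logical(1)))
        }, logical(1))
        f2 <- f2[!f2$family %in% unique(f2$family)[ov], , drop = FALSE]
      }
      fams <- rbind(fams, f2)
    }
  }
  if (nrow(fams) == 0L) return(.relabel_families(fams))
  .relabel_families(fams)
}

.dispersed_scan <- function(s, params, min_report_len) {
  hits <- seed_and_extend(s, s, params)
  empty <- data.frame(family = character(), unit_len = integer(),
                      identity = numeric(), copy = integer(),
                      start = integer(), end = integer(), len0 = integer(),
                      orientation = character(), type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  # drop the trivial self-identity hit and mirror-trivial variants
  trivial <- hits$orientation == "+" & hits$qs == hits$ss & hits$qe == hits$se
  hits <- hits[!trivial & (hits$qe - hits$qs) >= min_report_len, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  # collect copy intervals; union-find over reciprocal-80% overlap
  iv <- rbind(data.frame(start = hits$qs, end = hits$qe, hit = seq_len(nrow(hits)),
                         side = "q", stringsAsFactors = FALSE),
              data.frame(start = hits$ss, end = hits$se, hit = seq_len(nrow(hits)),
                         side = "s", stringsAsFactors = FALSE))
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  len <- iv$end - iv$start
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
    if (ov >= 0.8 * len[i] && ov >= 0.8 * len[j]) union(i, j)
  }
  # also link the two sides of each hit (same family by definition)
  for (h in seq_len(nrow(hits))) union(h, h + nrow(hits))
  comp <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (cp in unique(comp)) {
    rows <- which(comp == cp)
    # merge near-identical intervals into distinct copies
    ivc <- iv[rows, , drop = FALSE]
    ivc <- ivc[order(ivc$start), , drop = FALSE]
    copies <- list()
    for (r in seq_len(nrow(ivc))) {
      placed <- FALSE
      for (ci in seq_along(copies)) {
        co <- copies[[ci]]
        ov <- min(co$end, ivc$end[r]) - max(co$start, ivc$start[r])
        if (ov >= 0.8 * (co$end - co$start) &&
            ov >= 0.8 * (ivc$end[r] - ivc$start[r])) {
          copies[[ci]]$members <- c(co$members, rows[r])
          placed <- TRUE; break
        }
      }
      if (!placed)
        copies[[length(copies) + 1L]] <-
          list(start = ivc$start[r], end = ivc$end[r], members = rows[r])
    }
    if (length(copies) < 2L) next
    # orientation of each copy relative to copy 1, propagated through hits
    ori <- rep(NA_character_, length(copies))
    ori[1] <- "+"
    copy_of <- function(ividx) {
      for (ci in seq_along(copies)) if (ividx %in% copies[[ci]]$members) return(ci)
      NA_integer_
    }
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (h in seq_len(nrow(hits))) {
        a <- copy_of(h); b <- copy_of(h + nrow(hits))
        if (is.na(a) || is.na(b) || a == b) next
        flip <- hits$orientation[h] == "-"
        if (!is.na(ori[a]) && is.na(ori[b])) {
          ori[b] <- if (flip) setdiff(c("+", "-"), ori[a]) else ori[a]
          changed <- TRUE
        } else if (is.na(ori[a]) && !is.na(ori[b])) {
          ori[a] <- if (flip) setdiff(c("+", "-"), ori[b]) else ori[b]
          changed <- TRUE
        }
      }
    }
    ori[is.na(ori)] <- "+"
    others <- ori[-1]
    type <- if (all(others == "+")) "DR"
            else if (all(others == "-")) "IR" else "DR/IR"
    hids <- unique(iv$hit[rows])
    identity <- max(hits$identity[hids])
    starts <- vapply(copies, `[[`, numeric(1), "start")
    ends <- vapply(copies, `[[`, numeric(1), "end")
    out[[length(out) + 1L]] <- data.frame(
      family = NA_character_, unit_len = as.integer(ends[1] - starts[1]),
      identity = identity, copy = seq_along(copies),
      start = as.integer(starts), end = as.integer(ends),
      len0 = as.integer(ends - starts), orientation = ori, type = type,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

.relabel_families <- function(fams) {
  if (nrow(fams) == 0L) {
    fams$family <- character(0)
    return(fams[, c("family", "unit_len", "identity", "copy", "start",
                    "end", "orientation", "type")])
  }
  heads <- fams[fams$copy == 1L, ]
  ord <- order(-heads$unit_len, heads$start)
  lab <- stats::setNames(paste0("R", seq_along(ord)),
                         paste(heads$unit_len, heads$start)[ord])
  grp <- cumsum(fams$copy == 1L)
  hk <- paste(heads$unit_len, heads$start)
  fams$family <- lab[hk[grp]]
  fams <- fams[order(as.integer(sub("^R", "", fams$family)), fams$copy), ]
  rownames(fams) <- NULL
  fams[, c("family", "unit_len", "identity", "copy", "start", "end",
           "orientation", "type")]
}

# ---- genomic context -------------------------------------------------------

#' Label the genomic context of an interval
#'
#' Returns the gene name if the interval lies inside an annotated
#' CDS/rRNA/tRNA span, `"<gene>-intron<k>"` if inside an intron between
#' consecutive exon spans of a gene, and otherwise
#' `"IGS (<upstream>, <downstream>)"` using the nearest flanking genes in
#' genome order (circular-aware). Unannotated records yield
#' `"unannotated"`.
#'
#' @param interval numeric length-2 vector `[start, end)` (0-based).
#' @param record an annotated [genome_record()].
#' @return a single context label string.
#' @export
classify_location <- function(interval, record) {
  feats <- record$features
  feats <- Filter(function(f) f$ftype %in% c("CDS", "tRNA", "rRNA"), feats)
  if (length(feats) == 0L) return("unannotated")
  s <- interval[1]; e <- interval[2]
  L <- record_length(record)
  for (f in feats) {
    for (r in seq_len(nrow(f$spans))) {
      if (s >= f$spans[r, 1] && e <= f$spans[r, 2]) return(f$gene)
    }
    if (nrow(f$spans) > 1L) {
      sp <- f$spans[order(f$spans[, 1]), , drop = FALSE]
      for (r in seq_len(nrow(sp) - 1L)) {
        if (s >= sp[r, 2] && e <= sp[r + 1L, 1])
          return(sprintf("%s-intron%d", f$gene,
                         if (f$strand == "+") r else nrow(sp) - r))
      }
    }
  }
  # intergenic: nearest flanking genes in genome order, circular-aware
  starts <- vapply(feats, function(f) min(f$spans[, 1]), integer(1))
  ends <- vapply(feats, function(f) max(f$spans[, 2]), integer(1))
  names <- vapply(feats, function(f) f$gene, character(1))
  circ <- record$topology == "circular"
  if (circ) {
    dist_up <- (s - ends) %% L
    dist_dn <- (starts - e) %% L
  } else {
    dist_up <- s - ends; dist_up[dist_up < 0] <- NA
    dist_dn <- starts - e; dist_dn[dist_dn < 0] <- NA
    if (all(is.na(dist_up)) || all(is.na(dist_dn)))
      return("IGS (none, none)")
  }
  up <- names[which.min(dist_up)]
  dn <- names[which.min(dist_dn)]
  sprintf("IGS (%s, %s)", up, dn)
}

#' Histogram of dispersed-repeat lengths
#'
#' 10-bp bins starting at `from` (default 20 bp); one count per family at
#' its unit length. Counts conserve the family total.
#'
#' @param families data.frame from [find_dispersed_repeats()].
#' @param from left edge of the first bin.
#' @param width bin width in bp.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
repeat_length_histogram <- function(families, from = 20L, width = 10L) {
  if (nrow(families) == 0L)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  lens <- families$unit_len[families$copy == 1L]
  bin <- pmax(from, from + width * ((lens - from) %/% width))
  tb <- table(bin)
  data.frame(bin_start = as.integer(names(tb)),
             bin_end = as.integer(names(tb)) + width,
             count = as.integer(tb))
}
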