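# ---- contig graph I/O ------------------------------------------------------

#' Read a GFA 1.0 contig graph
#'
#' `S` lines provide sequences (depth from a `DP:f:` tag or the companion
#' depth TSV); `L` lines provide links. Link orientations map to contig
#' ends: `+` leaves the 3' end / enters the 5' end.
#'
#' @param path GFA file path.
#' @param depth_tsv optional TSV `contig_id<TAB>depth<TAB>length`.
#' @return a `ContigGraph` (list of `nodes`, `edges` data.frames).
#' @export
read_gfa <- function(path, depth_tsv = NULL) {
  lines <- readLines(path, warn = FALSE)
  sl <- strsplit(grep("^S\t", lines, value = TRUE), "\t")
  nodes <- do.call(rbind, lapply(sl, function(x) {
    dp <- grep("^DP:f:", x, value = TRUE)
    data.frame(id = x[2], length = nchar(x[3]),
               depth = if (length(dp)) as.numeric(sub("DP:f:", "", dp[1]))
                       else NA_real_,
               sequence = x[3], stringsAsFactors = FALSE)
  }))
  if (!is.null(depth_tsv)) {
    d <- utils::read.delim(depth_tsv, header = FALSE,
                           col.names = c("id", "depth", "length"),
                           stringsAsFactors = FALSE)
    nodes$depth <- d$depth[match(nodes$id, d$id)]
  }
  ll <- strsplit(grep("^L\t", lines, value = TRUE), "\t")
  edges <- if (length(ll)) do.call(rbind, lapply(ll, function(x) {
    rc <- grep("^RC:i:", x, value = TRUE)
    data.frame(from = x[2], from_end = if (x[3] == "+") "3p" else "5p",
               to = x[4], to_end = if (x[5] == "+") "5p" else "3p",
               support = if (length(rc)) as.integer(sub("RC:i:", "", rc[1]))
                         else 1L,
               stringsAsFactors = FALSE)
  })) else data.frame(from = character(), from_end = character(),
                      to = character(), to_end = character(),
                      support = integer(), stringsAsFactors = FALSE)
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stop("GFA links reference unknown contigs: ",
                        paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "ContigGraph")
}

#' Write a ContigGraph as GFA 1.0 (+ depth TSV)
#'
#' @param graph a `ContigGraph`.
#' @param path output GFA path.
#' @param depth_tsv optional path for the depth table.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path, depth_tsv = NULL) {
  con <- file(path, "w")
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(graph$nodes)))
    writeLines(sprintf("S\t%s\t%s\tDP:f:%.3f", graph$nodes$id[i],
                       graph$nodes$sequence[i], graph$nodes$depth[i]), con)
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M\tRC:i:%d", e$from,
                       if (e$from_end == "3p") "+" else "-",
                       e$to, if (e$to_end == "5p") "+" else "-",
                       e$support), con)
  }
  close(con)
  if (!is.null(depth_tsv))
    utils::write.table(graph$nodes[, c("id", "depth", "length")], depth_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @export
print.ContigGraph <- function(x, ...) {
  cat(sprintf("<ContigGraph: %d contigs, %d links, %d bp>\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$length)))
  invisible(x)
}

# ---- depth filtering and reference selection -------------------------------

# undirected adjacency list by contig id
.adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    adj[[e$from]] <- unique(c(adj[[e$from]], e$to))
    adj[[e$to]] <- unique(c(adj[[e$to]], e$from))
  }
  adj
}

.components <- function(ids, adj) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cid <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cid
      queue <- c(queue, intersect(adj[[v]], ids[is.na(comp[ids])]))
    }
  }
  comp
}

#' Filter contigs by the organelle depth window
#'
#' Keeps contigs with read depth inside `[low, high]`, plus out-of-window
#' contigs that are both reference-confirmed organellar (per
#' `confirmed`) and graph-essential: they bridge in-window contigs that
#' are otherwise disconnected (the plastid-like high-depth contigs that
#' are nonetheless required to close the organelle circle). Widening the
#' window never removes candidates.
#'
#' @param graph a `ContigGraph`.
#' @param window numeric `c(low, high)` depth window (default `c(15,
#'   50)`).
#' @param confirmed character vector of contig ids confirmed organellar
#'   by reference search (see [select_by_reference()]).
#' @return data.frame of candidate contigs with a `reason` column
#'   (`in-window` or `cp-like, graph-essential`).
#' @export
filter_by_depth <- function(graph, window = c(15, 50), confirmed = character(0)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  nodes <- graph$nodes
  inw <- nodes$id[nodes$depth >= window[1] & nodes$depth <= window[2]]
  adj <- .adjacency(graph)
  keep_extra <- character(0)
  out <- setdiff(nodes$id, inw)
  base_comp <- .components(inw, adj)
  for (c0 in intersect(out, confirmed)) {
    nb <- intersect(adj[[c0]], inw)
    if (length(nb) >= 2L && length(unique(base_comp[nb])) >= 2L)
      keep_extra <- c(keep_extra, c0)
  }
  res <- nodes[nodes$id %in% c(inw, keep_extra),
               c("id", "length", "depth"), drop = FALSE]
  res$reason <- ifelse(res$id %in% inw, "in-window",
                       "cp-like, graph-essential")
  rownames(res) <- NULL
  res
}

#' Confirm contigs against an organelle reference panel
#'
#' A contig is organellar if it has at least one alignment hit to any
#' panel genome passing the E-value cutoff.
#'
#' @param graph a `ContigGraph` (or its `nodes` data.frame).
#' @param reference_panel named character vector / list of reference
#'   genome sequences.
#' @param params an [align_params()].
#' @return character vector of confirmed contig ids.
#' @export
select_by_reference <- function(graph, reference_panel,
                                params = align_params(evalue_cutoff = 1e-5)) {
  if (length(reference_panel) == 0L) stop("empty reference panel")
  nodes <- if (inherits(graph, "ContigGraph")) graph$nodes else graph
  ok <- vapply(seq_len(nrow(nodes)), function(i) {
    for (ref in reference_panel) {
      h <- seed_and_extend(nodes$sequence[i], ref, params)
      if (nrow(h)) return(TRUE)
    }
    FALSE
  }, logical(1))
  nodes$id[ok]
}

#' Prune false links and decoy branches from a contig graph
#'
#' Removes edges with read support below `min_edge_support` and branches
#' leading to non-candidate contigs; forks among candidates survive (they
#' are legitimate repeat entries/exits left to the path walker).
#'
#' @param graph a `ContigGraph`.
#' @param min_edge_support minimum link read support (default 2).
#' @param candidates contig ids to keep (default: all).
#' @return pruned `ContigGraph`.
#' @export
prune_graph <- function(graph, min_edge_support = 2L,
                        candidates = graph$nodes$id) {
  nodes <- graph$nodes[graph$nodes$id %in% candidates, , drop = FALSE]
  edges <- graph$edges
  edges <- edges[edges$support >= min_edge_support &
                   edges$from %in% candidates &
                   edges$to %in% candidates, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ContigGraph")
}

# ---- circular path walking -------------------------------------------------

#' Walk the circular assembly path with repeat-contig reuse
#'
#' Each contig's multiplicity is `round(depth / base_depth)` where
#' `base_depth` is the modal (median) depth of simple degree-2 contigs;
#' exact-half ratios round down toward 1 with a warning. The walker
#' searches exhaustively (depth-first with backtracking) for a closed
#' walk using every contig exactly its multiplicity times and fails
#' loudly, listing violating contigs, if none exists.
#'
#' With collapsed repeats several closed walks can exist (the isomeric /
#' subgenomic circle ambiguity of large inverted repeats); set
#' `all_walks = TRUE` to enumerate them so junction read support can
#' disambiguate (see [assemble_organelle()]).
#'
#' @param graph a pruned `ContigGraph`.
#' @param all_walks return every closed walk (up to `max_walks`) instead
#'   of the first.
#' @param max_walks enumeration cap.
#' @return list `AssemblyPath`: `path` data.frame (`contig`,
#'   `orientation`), `multiplicity` named vector, `base_depth`; with
#'   `all_walks = TRUE` additionally `walks`, a list of path data.frames.
#' @export
walk_circular_path <- function(graph, all_walks = FALSE, max_walks = 64L) {
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(nodes) == 0L) stop("empty graph")
  deg <- table(c(edges$from, edges$to))
  simple <- nodes$id[nodes$id %in% names(deg)[deg == 2]]
  base <- if (length(simple)) stats::median(nodes$depth[nodes$id %in% simple])
          else stats::median(nodes$depth)
  ratio <- nodes$depth / base
  mult <- ifelse(abs(ratio %% 1 - 0.5) < 1e-9, floor(ratio), round(ratio))
  if (any(abs(ratio %% 1 - 0.5) < 1e-9))
    warning("depth ratio exactly .5 rounded down; resolve manually")
  mult <- pmax(1L, as.integer(mult))
  names(mult) <- nodes$id
  total <- sum(mult)
  # directed traversal: entering a contig at 5p means "+", at 3p means "-";
  # leaving from the opposite end
  exit_end <- function(entry) if (entry == "5p") "3p" else "5p"
  # edge lookup: list of (to, to_end) reachable from (from, from_end),
  # edges are bidirectional
  moves <- list()
  add_move <- function(a, ae, b, be) {
    key <- paste0(a, ":", ae)
    moves[[key]] <<- rbind(moves[[key]],
                           data.frame(to = b, to_end = be,
                                      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    add_move(e$from, e$from_end, e$to, e$to_end)
    add_move(e$to, e$to_end, e$from, e$from_end)
  }
  start <- nodes$id[1]
  used <- stats::setNames(integer(length(mult)), names(mult))
  path <- list()
  solutions <- list()
  want <- if (all_walks) as.integer(max_walks) else 1L
  dfs <- function(contig, entry) {
    if (length(solutions) >= want) return()
    used[contig] <<- used[contig] + 1L
    path[[length(path) + 1L]] <<- c(contig, if (entry == "5p") "+" else "-")
    if (length(path) == total) {
      # closed? need a move from current exit back to the start entry
      mv <- moves[[paste0(contig, ":", exit_end(entry))]]
      if (!is.null(mv) && any(mv$to == start & mv$to_end == "5p"))
        solutions[[length(solutions) + 1L]] <<- do.call(rbind, path)
    } else {
      mv <- moves[[paste0(contig, ":", exit_end(entry))]]
      if (!is.null(mv)) {
        for (r in seq_len(nrow(mv))) {
          nxt <- mv$to[r]
          if (used[nxt] < mult[nxt]) dfs(nxt, mv$to_end[r])
          if (length(solutions) >= want) break
        }
      }
    }
    used[contig] <<- used[contig] - 1L
    path[[length(path)]] <<- NULL
  }
  dfs(start, "5p")
  if (length(solutions) == 0L) {
    used[] <- 0L; path <- list()
    dfs(start, "3p")  # start contig may only occur flipped
  }
  if (length(solutions) == 0L) {
    stop("no closed walk consistent with contig multiplicities; ",
         "violating contigs: ",
         paste(names(mult)[used < mult], collapse = ", "))
  }
  as_df <- function(m) data.frame(contig = m[, 1], orientation = m[, 2],
                                  stringsAsFactors = FALSE)
  res <- list(path = as_df(solutions[[1]]), multiplicity = mult,
              base_depth = base)
  if (all_walks) res$walks <- lapply(solutions, as_df)
  res
}

# ---- gap filling and validation --------------------------------------------

#' Assemble the final sequence along a walked path, filling junctions
#'
#' For every junction between consecutive path contigs, reads overlapping
#' both flanking contig ends (within the end window) vote on the
#' junction; the junction is confirmed when a read spans it with at most
#' `max_mismatches` mismatches. Unresolved junctions are reported and
#' closed with an N-gap.
#'
#' @param path result of [walk_circular_path()].
#' @param graph the `ContigGraph` providing contig sequences.
#' @param reads character vector of (synthetic) reads.
#' @param end_window bp window at each contig end checked for read
#'   overlap (default `c(3, 60)`).
#' @param max_mismatches tolerated mismatches in a spanning read.
#' @param n_gap N-gap length for unresolved junctions.
#' @return list with `sequence` (closed circular assembly) and
#'   `junctions` data.frame (`from`, `to`, `supported`, `reads`).
#' @export
fill_gaps <- function(path, graph, reads, end_window = c(3L, 60L),
                      max_mismatches = 1L, n_gap = 10L) {
  seqs <- stats::setNames(graph$nodes$sequence, graph$nodes$id)
  pd <- path$path
  oriented <- vapply(seq_len(nrow(pd)), function(i) {
    s <- seqs[[pd$contig[i]]]
    if (pd$orientation[i] == "-") revcomp(s) else s
  }, character(1))
  w <- min(end_window[2], 30L)
  read_blob <- c(reads, revcomp(reads))
  pieces <- character(nrow(pd))
  junctions <- list()
  for (i in seq_len(nrow(pd))) {
    j <- if (i == nrow(pd)) 1L else i + 1L
    left <- substr(oriented[i], max(1L, nchar(oriented[i]) - w + 1L),
                   nchar(oriented[i]))
    nxt <- if (j == 1L && i == nrow(pd)) oriented[1] else oriented[j]
    right <- substr(nxt, 1L, min(w, nchar(nxt)))
    probe <- paste0(left, right)
    supported <- .reads_support(probe, read_blob, max_mismatches)
    junctions[[i]] <- data.frame(
      from = pd$contig[i], to = pd$contig[j],
      supported = supported$n > 0L, reads = supported$n,
      stringsAsFactors = FALSE)
    pieces[i] <- if (supported$n > 0L) oriented[i]
                 else paste0(oriented[i], strrep("N", n_gap))
  }
  list(sequence = paste(pieces, collapse = ""),
       junctions = do.call(rbind, junctions))
}

# count reads containing `probe` with at most max_mismatches mismatches,
# anchored by an exact match on the probe's central core
.reads_support <- function(probe, reads, max_mismatches) {
  n_exact <- sum(grepl(probe, reads, fixed = TRUE))
  if (n_exact > 0L || max_mismatches == 0L)
    return(list(n = n_exact))
  # mismatch-tolerant: anchor on exact left half, compare the rest
  half <- nchar(probe) %/% 2L
  lh <- substr(probe, 1L, half)
  cnt <- 0L
  for (rd in reads[grepl(lh, reads, fixed = TRUE)]) {
    p <- regexpr(lh, rd, fixed = TRUE)[1]
    rest <- substr(rd, p + half, p + nchar(probe) - 1L)
    want <- substr(probe, half + 1L, nchar(probe))
    if (nchar(rest) == nchar(want)) {
      mm <- sum(strsplit(rest, "")[[1]] != strsplit(want, "")[[1]])
      if (mm <= max_mismatches) cnt <- cnt + 1L
    }
  }
  list(n = cnt)
}

#' Validate an assembly against an independent read set
#'
#' Maps each read by exact anchor onto the (doubled, both-strand)
#' assembly and reports positions where the read consensus contradicts
#' the assembled base, plus positions with no read support.
#'
#' @param final_sequence assembled circular sequence.
#' @param validation_reads character vector of reads.
#' @param anchor_len exact seed length used for read placement.
#' @return list with `depth` (integer vector per position),
#'   `discrepancies` data.frame (`pos` 0-based, `assembly`, `consensus`,
#'   `support`), `uncovered` (0-based positions with zero depth).
#' @export
validate_assembly <- function(final_sequence, validation_reads,
                              anchor_len = 24L) {
  L <- nchar(final_sequence)
  doubled <- paste0(final_sequence, final_sequence)
  depth <- integer(L)
  votes <- list()  # per mismatch position: table of bases
  add_vote <- function(pos, base) {
    key <- as.character(pos)
    votes[[key]] <<- c(votes[[key]], base)
  }
  for (rd in validation_reads) {
    for (orient in 1:2) {
      r <- if (orient == 1L) rd else revcomp(rd)
      anchor <- substr(r, 1L, min(anchor_len, nchar(r)))
      p <- regexpr(anchor, doubled, fixed = TRUE)[1]
      if (p < 0) next
      ref <- substr(doubled, p, p + nchar(r) - 1L)
      if (nchar(ref) < nchar(r)) next
      rx <- strsplit(r, "")[[1]]; fx <- strsplit(ref, "")[[1]]
      pos <- ((p - 1L):(p + nchar(r) - 2L)) %% L
      depth[pos + 1L] <- depth[pos + 1L] + 1L
      mm <- which(rx != fx)
      for (k in mm) add_vote(pos[k], rx[k])
      break
    }
  }
  disc <- list()
  for (key in names(votes)) {
    pos <- as.integer(key)
    tb <- sort(table(votes[[key]]), decreasing = TRUE)
    support <- as.integer(tb[1])
    if (support > depth[pos + 1L] / 2) {
      disc[[length(disc) + 1L]] <- data.frame(
        pos = pos, assembly = substr(final_sequence, pos + 1L, pos + 1L),
        consensus = names(tb)[1], support = support,
        stringsAsFactors = FALSE)
    }
  }
  list(depth = depth,
       discrepancies = if (length(disc)) do.call(rbind, disc)
                       else data.frame(pos = integer(), assembly = character(),
                                       consensus = character(),
                                       support = integer(),
                                       stringsAsFactors = FALSE),
       uncovered = which(depth == 0L) - 1L)
}

#' Run the full organelle assembly pipeline on a contig graph
#'
#' Depth-window filtering, reference confirmation, pruning, circular path
#' walking and junction filling in one call.
#'
#' @param graph a `ContigGraph`.
#' @param reads read set for junction filling.
#' @param reference_panel reference genomes for out-of-window rescue and
#'   candidate confirmation (optional).
#' @param window organelle depth window.
#' @param min_edge_support link pruning threshold.
#' @return list with `sequence`, `path`, `junctions`, `candidates`.
#' @export
assemble_organelle <- function(graph, reads, reference_panel = NULL,
                               window = c(15, 50), min_edge_support = 2L) {
  confirmed <- if (!is.null(reference_panel))
    select_by_reference(graph, reference_panel) else character(0)
  cand <- filter_by_depth(graph, window, confirmed)
  pruned <- prune_graph(graph, min_edge_support, cand$id)
  walked <- walk_circular_path(pruned, all_walks = TRUE)
  # several closed walks can exist when repeats collapse; junction read
  # support picks the genuine one
  best <- NULL
  for (w in walked$walks) {
    cand_path <- list(path = w)
    fg <- fill_gaps(cand_path, pruned, reads)
    n_ok <- sum(fg$junctions$supported)
    if (is.null(best) || n_ok > best$n_ok)
      best <- list(fg = fg, path = w, n_ok = n_ok)
    if (n_ok == nrow(fg$junctions)) break
  }
  if (best$n_ok < nrow(best$fg$junctions))
    warning(nrow(best$fg$junctions) - best$n_ok,
            " junction(s) without read support left as N-gaps")
  walked$path <- best$path
  walked$walks <- NULL
  list(sequence = best$fg$sequence, path = walked,
       junctions = best$fg$junctions, candidates = cand)
}

#' Simulate error-free reads from a (circular) genome
#'
#' @param record a [genome_record()] or DNA string.
#' @param n number of reads.
#' @param read_len read length in bp.
#' @param seed RNG seed.
#' @return character vector of reads (both strands).
#' @export
simulate_reads <- function(record, n = 800L, read_len = 150L, seed = 5L) {
  set.seed(seed)
  s <- if (inherits(record, "GenomeRecord")) record$sequence else record
  circ <- !inherits(record, "GenomeRecord") ||
    record$topology == "circular"
  src <- if (circ) paste0(s, substr(s, 1L, read_len)) else s
  starts <- sample.int(nchar(s), n, replace = TRUE)
  reads <- substring(src, starts, pmin(starts + read_len - 1L, nchar(src)))
  flip <- stats::runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  reads
}
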