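#' Alignment scoring scheme
#'
#' Scoring used for the local alignment search: +1 match, -2 mismatch, gap
#' open -2, gap extend -1 (a gap of width w costs 2 + w). Stringent enough
#' that near-identity local alignments down to the 30-bp floor are recovered
#' as single locally optimal alignments, mirroring blastn HSP behaviour.
#'
#' @param match,mismatch,gap_open,gap_extend Scores/penalties (penalties
#'   given as positive costs).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 2,
                          gap_extend = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

# substitution matrix over A/C/G/T/N; N never aligns (used for masking)
scoring_matrix <- function(scoring) {
  b <- c(DNA_BASES, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- m[, "N"] <- -1e6
  m
}

# Minimum guaranteed exact-match run length inside any alignment with
# >= min_span columns at >= min_identity: m errors split the matched columns
# into at most m+1 runs. Scanning alignment lengths gives the safe seed word.
safe_seed_word <- function(min_span, min_identity, cap = 16L) {
  if (min_identity >= 1) return(min(cap, as.integer(min_span)))
  cs <- seq.int(max(min_span, 2L), max(4L * min_span, 400L))
  errs <- floor((1 - min_identity) * cs)
  runs <- ceiling((cs - errs) / (errs + 1))
  w <- min(runs)
  if (w < 8L) return(0L)  # prefilter would be too permissive to help
  min(cap, as.integer(w))
}

# which reads share an exact w-mer with the query (either orientation)?
seed_prefilter <- function(query, reads, w) {
  qrc <- revcomp(query)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < w) character() else substring(s, 1:(n - w + 1L), w:n)
  }
  qk <- unique(c(kmers(query), kmers(qrc)))
  vapply(reads, function(r) any(kmers(r) %in% qk), NA, USE.NAMES = FALSE)
}

#' Locally align reads against a query gene
#'
#' Finds locally optimal alignments of each read (both strands) against the
#' query, keeping those with an aligned query span of at least `min_span` and
#' identity (matches / alignment columns, gaps counting as non-matches) of at
#' least `min_identity`. After the best local alignment of a read is found,
#' the aligned read segment is masked and the remainder re-searched, so a
#' read contributing two disjoint query segments yields two records.
#'
#' Only locally optimal alignments are considered: a sub-window of a longer
#' alignment that would pass the identity floor on its own is not reported
#' when extending it increases the alignment score. This matches the
#' HSP-style evidence the match criteria were designed around.
#'
#' A read is only passed to dynamic programming if it shares an exact seed
#' word with the query; the word length is derived from `min_span` and
#' `min_identity` such that every reportable alignment is guaranteed to
#' contain such a word, so the prefilter is lossless.
#'
#' @param query Query gene sequence (character or `DNAString`).
#' @param reads Reads: character vector (optionally named), `DNAStringSet`,
#'   or a data.frame with `read_id` and `sequence` columns (as produced by
#'   [simulate_reads()]).
#' @param min_span Minimum aligned query span in bp.
#' @param min_identity Minimum identity fraction.
#' @param gene_id Identifier recorded in the output.
#' @param scoring An [align_scoring()] object.
#' @param max_hits_per_read Maximum number of masked re-search rounds.
#' @param prefilter Use the lossless seed-word prefilter (default `TRUE`).
#' @return data.frame with one row per kept alignment: `gene_id`, `read_id`,
#'   `strand`, `q_start`, `q_end`, `r_start`, `r_end` (0-based half-open),
#'   `matches`, `columns`, `gaps`, `identity`, `span`, `score`. Ordered by
#'   `q_start`, then strand (`+` first), then `read_id`.
#' @examples
#' g <- make_gene(400, 0.5, 1)
#' local_align(g, substr(g, 101, 250), min_span = 30, min_identity = 0.97)
#' @export
local_align <- function(query, reads, min_span = 30, min_identity = 0.97,
                        gene_id = "query", scoring = align_scoring(),
                        max_hits_per_read = 4L, prefilter = TRUE) {
  query <- toupper(as.character(query))
  if (!nzchar(query)) stop("empty query sequence", call. = FALSE)
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- toupper(reads$sequence)
  } else {
    ids <- names(reads)
    seqs <- toupper(as.character(reads))
    if (is.null(ids)) ids <- sprintf("read%05d", seq_along(seqs))
  }
  if (length(seqs) == 0L) return(empty_alignments(gene_id))
  if (any(!nzchar(seqs))) stop("empty read sequence", call. = FALSE)
  stopifnot(min_identity > 0, min_identity <= 1, min_span >= 1)

  keep <- rep(TRUE, length(seqs))
  if (isTRUE(prefilter)) {
    w <- safe_seed_word(min_span, min_identity)
    if (w > 0L) keep <- seed_prefilter(query, seqs, w)
  }
  if (!any(keep)) return(empty_alignments(gene_id))
  seqs <- seqs[keep]; ids <- ids[keep]

  mat <- scoring_matrix(scoring)
  out <- list()
  for (str in c("+", "-")) {
    cur <- if (str == "+") seqs else vapply(seqs, revcomp, "", USE.NAMES = FALSE)
    out[[str]] <- align_strand(query, cur, ids, str, min_span, min_identity,
                               mat, scoring, max_hits_per_read,
                               read_len = nchar(seqs))
  }
  res <- do.call(rbind, out)
  res <- res[res$span >= min_span & res$identity >= min_identity, ,
             drop = FALSE]
  res$gene_id <- rep(gene_id, nrow(res))
  res <- res[order(res$q_start, res$strand, res$read_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("gene_id", "read_id", "strand", "q_start", "q_end", "r_start",
          "r_end", "matches", "columns", "gaps", "identity", "span",
          "score")]
}

empty_alignments <- function(gene_id) {
  data.frame(gene_id = character(), read_id = character(),
             strand = character(), q_start = integer(), q_end = integer(),
             r_start = integer(), r_end = integer(), matches = integer(),
             columns = integer(), gaps = integer(), identity = numeric(),
             span = integer(), score = numeric(), stringsAsFactors = FALSE)
}

# one strand: vectorised best local alignment, then masked re-search of reads
# with enough unaligned sequence left to host another min_span alignment
align_strand <- function(query, seqs, ids, strand, min_span, min_identity,
                         mat, scoring, max_rounds, read_len) {
  subj <- Biostrings::DNAString(query)
  active <- seq_along(seqs)
  work <- seqs
  rows <- list()
  for (round in seq_len(max_rounds)) {
    if (length(active) == 0L) break
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(work[active]), subj, type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend)
    qs <- Biostrings::start(Biostrings::subject(pa))
    qe <- Biostrings::end(Biostrings::subject(pa))
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    nm <- Biostrings::nmatch(pa)
    sc <- Biostrings::score(pa)
    cols <- Biostrings::nchar(pa)
    span <- qe - qs + 1L
    ok <- Biostrings::score(pa) > 0 & span >= min_span
    nxt <- integer()
    for (k in which(ok)) {
      i <- active[k]
      L <- read_len[i]
      # read coordinates on the original read (0-based half-open)
      if (strand == "+") {
        r0 <- ps[k] - 1L; r1 <- pe[k]
      } else {
        r0 <- L - pe[k]; r1 <- L - ps[k] + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = ids[i], strand = strand,
        q_start = qs[k] - 1L, q_end = qe[k],
        r_start = r0, r_end = r1,
        matches = nm[k], columns = cols[k], gaps = NA_integer_,
        identity = nm[k] / cols[k], span = span[k], score = sc[k],
        stringsAsFactors = FALSE)
      # mask the aligned read segment; re-search if a flank could still
      # host a min_span alignment
      s <- work[i]
      substr(s, ps[k], pe[k]) <- strrep("N", pe[k] - ps[k] + 1L)
      work[i] <- s
      left <- ps[k] - 1L
      right <- nchar(s) - pe[k]
      if (max(left, right) >= floor(0.9 * min_span)) nxt <- c(nxt, i)
    }
    active <- nxt
  }
  if (length(rows) == 0L) {
    df <- empty_alignments("x"); df$gene_id <- NULL; return(df)
  }
  res <- do.call(rbind, rows)
  # gaps = alignment columns not occupied by both sequences
  res$gaps <- with(res, 2L * columns - (r_end - r_start) - (q_end - q_start))
  res
}

#' Percent identity of alignments
#'
#' Identity is matches divided by alignment columns; gap columns count as
#' non-matches (the common blastn convention).
#'
#' @param aln data.frame of alignments (from [local_align()]) or a single
#'   alignment row; needs `matches` and `columns` columns.
#' @return Numeric vector of identity fractions.
#' @examples
#' percent_identity(data.frame(matches = 146, columns = 150))
#' @export
percent_identity <- function(aln) {
  stopifnot(all(c("matches", "columns") %in% names(aln)))
  if (any(aln$columns <= 0)) stop("zero alignment columns", call. = FALSE)
  aln$matches / aln$columns
}

#' Union of aligned query intervals
#'
#' Merges the `[q_start, q_end)` intervals of a set of alignments on one
#' gene; overlapping stretches are counted once. This is the query-coverage
#' quantity behind the combined-reads match rule.
#'
#' @param alns data.frame with `q_start`, `q_end` and (optionally) `gene_id`
#'   columns; all rows must be on the same gene.
#' @return An object of class `coverage_set`: list with `gene_id`,
#'   `intervals` (data.frame of disjoint sorted 0-based half-open intervals)
#'   and `total_bp`.
#' @examples
#' coverage_union(data.frame(q_start = c(0, 60), q_end = c(100, 160)))
#' @export
coverage_union <- function(alns) {
  gene_id <- if ("gene_id" %in% names(alns) && nrow(alns) > 0) {
    g <- unique(alns$gene_id)
    if (length(g) > 1L) stop("alignments on mixed gene_ids", call. = FALSE)
    g
  } else NA_character_
  if (nrow(alns) == 0L) {
    return(structure(list(gene_id = gene_id,
                          intervals = data.frame(start = integer(),
                                                 end = integer()),
                          total_bp = 0L), class = "coverage_set"))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = alns$q_start + 1L,
                                         end = alns$q_end))
  structure(list(gene_id = gene_id,
                 intervals = data.frame(start = IRanges::start(ir) - 1L,
                                        end = IRanges::end(ir)),
                 total_bp = sum(IRanges::width(ir))),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> %s: %d interval(s), %d bp\n",
              ifelse(is.na(x$gene_id), "(gene)", x$gene_id),
              nrow(x$intervals), x$total_bp))
  invisible(x)
}
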