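#' Detection criteria for gene-signature matches
#'
#' The thresholds of the significant-match definition used when screening
#' raw reads: a single read aligning over >= 150 bp of the query, or shorter
#' reads (each contributing >= 30 bp) whose combined query coverage reaches
#' >= 140 bp, always at >= 97% identity. Reads that align only at a gene
#' terminus (>= 30 bp at the identity floor) are candidates for rescue
#' against the genomic flanking sequence.
#'
#' @param min_single_span Minimum aligned query span (bp) for a single read
#'   to be a significant match on its own.
#' @param min_combined_coverage Minimum combined query coverage (bp) for the
#'   shorter-read combination rule.
#' @param min_identity Identity floor applied to every alignment.
#' @param min_partial_span Minimum span (bp) of a terminal alignment for
#'   flank rescue to be attempted, and minimum in-gene overlap of a rescued
#'   alignment.
#' @param min_contributing_span Minimum span (bp) for an alignment to
#'   contribute to combined coverage.
#' @return A list of class `detection_criteria`.
#' @examples
#' detection_criteria()
#' @export
detection_criteria <- function(min_single_span = 150,
                               min_combined_coverage = 140,
                               min_identity = 0.97,
                               min_partial_span = 30,
                               min_contributing_span = 30) {
  if (min_combined_coverage > min_single_span)
    stop("min_combined_coverage must be <= min_single_span", call. = FALSE)
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]", call. = FALSE)
  stopifnot(min_partial_span >= 1, min_contributing_span >= 1)
  structure(list(min_single_span = min_single_span,
                 min_combined_coverage = min_combined_coverage,
                 min_identity = min_identity,
                 min_partial_span = min_partial_span,
                 min_contributing_span = min_contributing_span),
            class = "detection_criteria")
}

#' @export
print.detection_criteria <- function(x, ...) {
  cat(sprintf(paste0("<detection_criteria> single >=%g bp | combined >=%g bp",
                     " | identity >=%g%% | partial/contributing >=%g/%g bp\n"),
              x$min_single_span, x$min_combined_coverage,
              100 * x$min_identity, x$min_partial_span,
              x$min_contributing_span))
  invisible(x)
}

#' Classify one read's gene alignments
#'
#' Applies the match categories to the qualifying alignments of a single
#' read against a gene: `single_full` if any alignment spans at least
#' `min_single_span` of the query; otherwise `contributing` if any spans at
#' least `min_contributing_span`; `insignificant` if there is no qualifying
#' alignment. Additionally, a read whose best alignment abuts a gene
#' terminus (query position 0 or the gene end) with span at least
#' `min_partial_span` is flagged `partial_terminal`, marking it for flank
#' rescue.
#'
#' Alignments are expected to come from [local_align()] run with
#' `min_span = criteria$min_contributing_span` and
#' `min_identity = criteria$min_identity`, i.e. already identity-filtered.
#'
#' @param alns data.frame of alignments of one read against the gene.
#' @param gene_length Length of the query gene in bp.
#' @param criteria A [detection_criteria()] object.
#' @return A one-row data.frame: `read_id`, `category`, `partial_terminal`,
#'   plus the best alignment's `q_start`, `q_end`, `identity`, `span`.
#' @export
classify_read <- function(alns, gene_length, criteria = detection_criteria()) {
  if (nrow(alns) == 0L) {
    return(data.frame(read_id = NA_character_, category = "insignificant",
                      partial_terminal = FALSE, q_start = NA_integer_,
                      q_end = NA_integer_, identity = NA_real_,
                      span = NA_integer_, stringsAsFactors = FALSE))
  }
  if (length(unique(alns$read_id)) > 1L)
    stop("classify_read expects alignments of a single read", call. = FALSE)
  best <- alns[order(-alns$span, alns$q_start)[1L], ]
  category <- if (any(alns$span >= criteria$min_single_span)) "single_full"
              else "contributing"
  partial <- category != "single_full" &&
    best$span >= criteria$min_partial_span &&
    (best$q_start == 0L || best$q_end == gene_length)
  data.frame(read_id = best$read_id, category = category,
             partial_terminal = partial, q_start = best$q_start,
             q_end = best$q_end, identity = best$identity, span = best$span,
             stringsAsFactors = FALSE)
}

#' Rescue a terminal partial match against the flanking sequence
#'
#' A read flagged as matching only a gene start or end region is realigned
#' against the full genomic context `flank_left + gene + flank_right`. The
#' read is rescued when a single contiguous alignment spans at least
#' `min_single_span` at the identity floor **and** overlaps the gene itself
#' by at least `min_partial_span`. Without flanking sequence, rescue is
#' impossible and `NULL` is returned with a message.
#'
#' @param read Read sequence (character, optionally named with the read id).
#' @param context A [genome_context()] with flanks.
#' @param criteria A [detection_criteria()] object.
#' @param scoring An [align_scoring()] object.
#' @return The rescuing alignment row (coordinates on the context, plus
#'   `gene_q_start`/`gene_q_end`: the in-gene overlap in gene coordinates,
#'   0-based half-open), or `NULL`.
#' @export
rescue_partial <- function(read, context, criteria = detection_criteria(),
                           scoring = align_scoring()) {
  stopifnot(inherits(context, "genome_context"))
  if (!nzchar(context$flank_left) && !nzchar(context$flank_right)) {
    message("rescue impossible: context has no flanking sequence")
    return(NULL)
  }
  id <- names(read)
  if (is.null(id)) id <- "read"
  ctx <- context_sequence(context)
  alns <- local_align(ctx, setNames(as.character(read), id),
                      min_span = criteria$min_single_span,
                      min_identity = criteria$min_identity,
                      gene_id = context$gene_id, scoring = scoring)
  if (nrow(alns) == 0L) return(NULL)
  gr <- gene_region(context)
  ov_start <- pmax(alns$q_start, gr["start"])
  ov_end <- pmin(alns$q_end, gr["end"])
  ok <- (ov_end - ov_start) >= criteria$min_partial_span
  if (!any(ok)) return(NULL)
  alns <- alns[ok, , drop = FALSE]
  best <- alns[order(-alns$span)[1L], ]
  best$gene_q_start <- max(best$q_start, gr["start"]) - gr["start"]
  best$gene_q_end <- min(best$q_end, gr["end"]) - gr["start"]
  rownames(best) <- NULL
  best
}

#' Decide dataset-level significance from classified evidence
#'
#' The significant-match rule, applied to a table of per-alignment evidence:
#' a dataset is significant for a gene iff it has at least one `single_full`
#' read, or at least one rescued read, or the union of in-gene query
#' intervals of contributing and rescued alignments reaches
#' `min_combined_coverage`.
#'
#' @param evidence data.frame with columns `category`, `rescued` (logical),
#'   `q_start`, `q_end` (in-gene, 0-based half-open), `span`.
#' @param criteria A [detection_criteria()] object.
#' @return Logical scalar.
#' @export
is_significant_match <- function(evidence, criteria = detection_criteria()) {
  if (nrow(evidence) == 0L) return(FALSE)
  if (any(evidence$category == "single_full")) return(TRUE)
  if (any(evidence$rescued)) return(TRUE)
  comb <- evidence[(evidence$category == "contributing" | evidence$rescued) &
                     evidence$span >= criteria$min_contributing_span, ,
                   drop = FALSE]
  if (nrow(comb) == 0L) return(FALSE)
  coverage_union(comb[, c("q_start", "q_end")])$total_bp >=
    criteria$min_combined_coverage
}

#' Screen a read collection for a query gene signature
#'
#' Runs the full per-dataset detection: local alignment of all reads against
#' the gene, per-read classification, flank rescue of terminal partial
#' matches, and the dataset-level significance rule. Reports the union query
#' coverage achieved by qualifying evidence.
#'
#' @param reads Read collection: data.frame with `read_id`/`sequence`
#'   (e.g. from [simulate_reads()]), named character vector, or
#'   `DNAStringSet`. An empty collection gives `significant = FALSE`.
#' @param context A [genome_context()] for the query gene.
#' @param criteria A [detection_criteria()] object.
#' @param scoring An [align_scoring()] object.
#' @param dataset_id Identifier recorded in the result.
#' @return An object of class `dataset_detection`: list with `dataset_id`,
#'   `gene_id`, `significant`, `evidence` (per-alignment data.frame),
#'   `covered_bp`, `covered_fraction`, `n_single`, `n_contributing`,
#'   `n_rescued`.
#' @examples
#' ctx <- genome_context("g", make_gene(400, 0.5, 1))
#' rr <- simulate_reads(ctx, 20, 150, 0, 7)
#' detect_gene_in_dataset(rr, ctx)
#' @export
detect_gene_in_dataset <- function(reads, context,
                                   criteria = detection_criteria(),
                                   scoring = align_scoring(),
                                   dataset_id = "dataset") {
  stopifnot(inherits(context, "genome_context"))
  if (is.data.frame(reads)) {
    seqs <- setNames(toupper(reads$sequence), reads$read_id)
  } else {
    seqs <- toupper(as.character(reads))
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%05d",
                                                     seq_along(seqs))
  }
  glen <- nchar(context$gene)
  evidence <- data.frame(read_id = character(), category = character(),
                         partial_terminal = logical(), rescued = logical(),
                         q_start = integer(), q_end = integer(),
                         identity = numeric(), span = integer(),
                         stringsAsFactors = FALSE)
  if (length(seqs) > 0L) {
    alns <- local_align(context$gene, seqs,
                        min_span = criteria$min_contributing_span,
                        min_identity = criteria$min_identity,
                        gene_id = context$gene_id, scoring = scoring)
    if (nrow(alns) > 0L) {
      pieces <- lapply(split(alns, alns$read_id), function(a) {
        cls <- classify_read(a, glen, criteria)
        rescued <- FALSE
        if (cls$partial_terminal) {
          resc <- rescue_partial(setNames(seqs[cls$read_id], cls$read_id),
                                 context, criteria, scoring)
          if (!is.null(resc)) {
            rescued <- TRUE
            # replace in-gene interval by the rescued alignment's overlap
            a <- a[0, , drop = FALSE]
            a[1, c("q_start", "q_end")] <- c(resc$gene_q_start,
                                             resc$gene_q_end)
            a$read_id <- cls$read_id
            a$identity <- resc$identity
            a$span <- resc$gene_q_end - resc$gene_q_start
          }
        }
        data.frame(read_id = a$read_id, category = cls$category,
                   partial_terminal = cls$partial_terminal, rescued = rescued,
                   q_start = a$q_start, q_end = a$q_end,
                   identity = a$identity, span = a$span,
                   stringsAsFactors = FALSE)
      })
      evidence <- do.call(rbind, pieces)
      rownames(evidence) <- NULL
    }
  }
  qualifying <- evidence[evidence$category %in%
                           c("single_full", "contributing") |
                           evidence$rescued, , drop = FALSE]
  cov <- coverage_union(qualifying[, c("q_start", "q_end")])
  per_read <- evidence[!duplicated(evidence$read_id), , drop = FALSE]
  structure(list(
    dataset_id = dataset_id,
    gene_id = context$gene_id,
    significant = is_significant_match(evidence, criteria),
    evidence = evidence,
    covered_bp = cov$total_bp,
    covered_fraction = cov$total_bp / glen,
    n_single = sum(per_read$category == "single_full"),
    n_contributing = sum(per_read$category == "contributing" &
                           !per_read$rescued),
    n_rescued = sum(per_read$rescued)
  ), class = "dataset_detection")
}

#' @export
print.dataset_detection <- function(x, ...) {
  cat(sprintf(paste0("<dataset_detection> %s / %s: %s ",
                     "(%d single, %d contributing, %d rescued; %d bp, ",
                     "%.1f%% of query covered)\n"),
              x$dataset_id, x$gene_id,
              if (x$significant) "SIGNIFICANT" else "not significant",
              x$n_single, x$n_contributing, x$n_rescued, x$covered_bp,
              100 * x$covered_fraction))
  invisible(x)
}

#' Screen every dataset of a survey against every query gene
#'
#' Convenience wrapper running [detect_gene_in_dataset()] over a list of
#' read collections and a set of query-gene contexts, returning a flat
#' detections table ready for [aggregate_site_years()].
#'
#' @param read_sets Named list of read collections (names = dataset ids).
#' @param contexts List of [genome_context()] query genes.
#' @param criteria A [detection_criteria()] object.
#' @param scoring An [align_scoring()] object.
#' @return data.frame with one row per (dataset, gene): `dataset_id`,
#'   `gene_id`, `significant`, `n_single`, `n_contributing`, `n_rescued`,
#'   `covered_bp`, `covered_fraction`.
#' @export
scan_survey <- function(read_sets, contexts,
                        criteria = detection_criteria(),
                        scoring = align_scoring()) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  rows <- list()
  for (ds in names(read_sets)) {
    for (ctx in contexts) {
      d <- detect_gene_in_dataset(read_sets[[ds]], ctx, criteria, scoring,
                                  dataset_id = ds)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = ds, gene_id = d$gene_id, significant = d$significant,
        n_single = d$n_single, n_contributing = d$n_contributing,
        n_rescued = d$n_rescued, covered_bp = d$covered_bp,
        covered_fraction = d$covered_fraction, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
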