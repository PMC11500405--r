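#' Aggregate per-dataset detections into site-per-year counts
#'
#' A sampling site with at least one dataset containing significant matches
#' to a query gene in a given year is counted as one positive site of that
#' gene for that year, regardless of how many datasets or reads support it.
#' Sites sampled in several years count once per year.
#'
#' @param detections data.frame from [scan_survey()] (columns `dataset_id`,
#'   `gene_id`, `significant`).
#' @param meta data.frame with columns `dataset_id`, `site_id`, `year`,
#'   `region`, `size_bp`; every dataset in `detections` must appear.
#' @return data.frame with one row per (region, year, gene): `region`,
#'   `year`, `gene_id`, `n_positive_sites`, `n_sites`, `searched_bp`.
#'   `n_sites` and `searched_bp` describe all datasets of that region-year
#'   (identical across genes).
#' @examples
#' det <- data.frame(dataset_id = c("d1", "d2"), gene_id = "SUL_Sh",
#'                   significant = c(TRUE, TRUE))
#' meta <- data.frame(dataset_id = c("d1", "d2"), site_id = "s1",
#'                    year = 2020, region = "Europe", size_bp = 1e9)
#' aggregate_site_years(det, meta)  # one positive site, not two
#' @export
aggregate_site_years <- function(detections, meta) {
  need <- c("dataset_id", "site_id", "year", "region", "size_bp")
  stopifnot(is.data.frame(detections), is.data.frame(meta),
            all(c("dataset_id", "gene_id", "significant") %in%
                  names(detections)),
            all(need %in% names(meta)))
  if (any(meta$size_bp <= 0)) stop("size_bp must be > 0", call. = FALSE)
  unknown <- setdiff(detections$dataset_id, meta$dataset_id)
  if (length(unknown))
    stop("unknown dataset_id in detections: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  site_region <- unique(meta[, c("site_id", "region")])
  if (anyDuplicated(site_region$site_id))
    stop("a site_id maps to more than one region", call. = FALSE)

  d <- merge(detections, meta, by = "dataset_id")
  genes <- sort(unique(detections$gene_id))
  ry <- unique(meta[, c("region", "year")])
  rows <- list()
  for (i in seq_len(nrow(ry))) {
    r <- ry$region[i]; y <- ry$year[i]
    m <- meta[meta$region == r & meta$year == y, , drop = FALSE]
    n_sites <- length(unique(m$site_id))
    bp <- sum(m$size_bp)
    for (g in genes) {
      dg <- d[d$region == r & d$year == y & d$gene_id == g & d$significant, ,
              drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, year = y, gene_id = g,
        n_positive_sites = length(unique(dg$site_id)),
        n_sites = n_sites, searched_bp = bp, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$region, res$year, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Base pairs searched per detection
#'
#' The detection-frequency statistic: total base pairs searched divided by
#' the number of positive (site, year, gene) detections — e.g. "one
#' detection every 220 Gbp searched". With `by_gene = TRUE` the rate is
#' computed per query gene (each gene searched the full data volume);
#' pooled, all genes' detections share the total volume.
#'
#' @param summary data.frame from [aggregate_site_years()].
#' @param by_gene Compute one rate per gene instead of a pooled rate.
#' @return With `by_gene = FALSE`, a single number (bp per detection; `Inf`
#'   with a warning when there are no detections). With `by_gene = TRUE`, a
#'   data.frame `gene_id`, `searched_bp`, `detections`, `bp_per_detection`.
#' @examples
#' s <- data.frame(region = "E", year = 2020, gene_id = "g",
#'                 n_positive_sites = 2, n_sites = 10, searched_bp = 440e9)
#' detection_rate(s)  # 220 Gbp per detection
#' @export
detection_rate <- function(summary, by_gene = FALSE) {
  stopifnot(all(c("region", "year", "gene_id", "n_positive_sites",
                  "searched_bp") %in% names(summary)))
  vol <- unique(summary[, c("region", "year", "searched_bp")])
  total_bp <- sum(vol$searched_bp)
  if (by_gene) {
    out <- do.call(rbind, lapply(split(summary, summary$gene_id), function(s) {
      det <- sum(s$n_positive_sites)
      data.frame(gene_id = s$gene_id[1L], searched_bp = total_bp,
                 detections = det,
                 bp_per_detection = if (det > 0) total_bp / det else Inf,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    if (any(!is.finite(out$bp_per_detection)))
      warning("zero detections for some gene(s); rate reported as Inf")
    return(out)
  }
  det <- sum(summary$n_positive_sites)
  if (det == 0) {
    warning("zero detections; rate reported as Inf")
    return(Inf)
  }
  total_bp / det
}

#' Correlation between data volume and positive-site counts
#'
#' Tests whether the number of positive sites scales with the amount of
#' sequence searched: groups the summary by region or year, and returns the
#' least-squares slope of positives on searched bp constrained through the
#' origin, together with the Pearson correlation of the unconstrained pairs.
#'
#' @param summary data.frame from [aggregate_site_years()].
#' @param grouping `"region"` or `"year"`.
#' @param gene_id Restrict to one gene (default: pool all genes).
#' @return List with `slope` (positives per bp, through the origin), `r`
#'   (Pearson; 0 with `r_defined = FALSE` when positives have zero
#'   variance), `r_defined`, and `groups` (the aggregated pairs).
#' @export
size_detection_correlation <- function(summary,
                                       grouping = c("region", "year"),
                                       gene_id = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(gene_id))
    summary <- summary[summary$gene_id %in% gene_id, , drop = FALSE]
  vol <- unique(summary[, c("region", "year", "searched_bp")])
  x <- tapply(vol$searched_bp, vol[[grouping]], sum)
  pos <- tapply(summary$n_positive_sites, summary[[grouping]], sum)
  groups <- data.frame(group = names(x), searched_bp = as.numeric(x),
                       n_positive_sites = as.numeric(pos[names(x)]),
                       stringsAsFactors = FALSE)
  if (nrow(groups) < 3L)
    stop("need at least 3 groups for the size-detection correlation",
         call. = FALSE)
  slope <- if (all(groups$n_positive_sites == 0)) 0 else
    sum(groups$searched_bp * groups$n_positive_sites) /
      sum(groups$searched_bp^2)
  r_defined <- stats::sd(groups$n_positive_sites) > 0 &&
    stats::sd(groups$searched_bp) > 0
  r <- if (r_defined) cor(groups$searched_bp, groups$n_positive_sites) else 0
  list(slope = slope, r = r, r_defined = r_defined, groups = groups)
}

#' Median query coverage across run files
#'
#' Median of the per-dataset query-coverage fraction (union of aligned query
#' positions over gene length), expressed in percent. By default restricted
#' to run files in which any qualifying alignment was found, i.e. the runs
#' with a detected signature.
#'
#' @param detections data.frame from [scan_survey()] (or one read from a
#'   coverage TSV) with a `covered_fraction` column.
#' @param positives_only Use only rows with `covered_bp > 0` (default).
#' @return Median query coverage in percent.
#' @export
median_query_coverage <- function(detections, positives_only = TRUE) {
  stopifnot("covered_fraction" %in% names(detections))
  d <- detections
  if (positives_only && "covered_bp" %in% names(d))
    d <- d[d$covered_bp > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no run files with coverage", call. = FALSE)
  100 * median(d$covered_fraction)
}
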