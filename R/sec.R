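#' Activity-assay parameters
#'
#' End-point assay conditions for fraction activity: initial substrate
#' concentration and incubation time. Defaults mirror a 2.25 mM acesulfame
#' assay incubated for 40 min.
#'
#' @param c0 Initial substrate concentration in mM (> 0).
#' @param t_incubation Incubation time in minutes (> 0).
#' @return A list of class `assay_params`.
#' @export
assay_params <- function(c0 = 2.25, t_incubation = 40) {
  if (c0 <= 0) stop("`c0` must be > 0", call. = FALSE)
  if (t_incubation <= 0) stop("`t_incubation` must be > 0", call. = FALSE)
  structure(list(c0 = c0, t_incubation = t_incubation),
            class = "assay_params")
}

#' Fraction activity from end-point substrate concentrations
#'
#' Hydrolase activity per fraction, computed from the substrate remaining
#' after incubation: `activity = c0 - remaining`, elementwise. Values above
#' `c0` are clipped (activity 0) with a warning; negative concentrations are
#' an error. With `as_rate = TRUE` the removed amount is divided by the
#' incubation time.
#'
#' @param remaining Numeric vector of remaining substrate (mM) per fraction.
#' @param params An [assay_params()] object.
#' @param as_rate Return mM removed per minute instead of mM removed.
#' @return Numeric vector of activities, one per fraction.
#' @examples
#' endpoint_activity(c(2.25, 1.25, 0), assay_params(2.25, 40))
#' @export
endpoint_activity <- function(remaining, params = assay_params(),
                              as_rate = FALSE) {
  stopifnot(inherits(params, "assay_params"), is.numeric(remaining))
  if (any(remaining < 0))
    stop("negative substrate concentrations", call. = FALSE)
  if (any(remaining > params$c0)) {
    warning("remaining substrate above c0 in ",
            sum(remaining > params$c0), " fraction(s); clipped to c0")
    remaining <- pmin(remaining, params$c0)
  }
  removed <- params$c0 - remaining
  if (as_rate) removed / params$t_incubation else removed
}

#' Calibrate the mass-to-elution-volume relation of an SEC column
#'
#' Fits the standard log-linear SEC calibration: least squares of
#' `log10(mass in kDa)` on elution volume (mL), from a protein standard mix.
#' Larger complexes elute earlier, so the slope should be negative.
#'
#' @param standards data.frame with columns `mass_kda` and `volume_ml`
#'   (>= 3 rows, distinct volumes).
#' @return A list of class `sec_calibration`: `slope`, `intercept`,
#'   `r_squared`, `volume_range`.
#' @examples
#' std <- data.frame(mass_kda = c(600, 200, 66, 15),
#'                   volume_ml = c(9, 11.5, 14, 17.5))
#' sec_calibrate(std)
#' @export
sec_calibrate <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "volume_ml") %in% names(standards)))
  if (nrow(standards) < 3L)
    stop("need at least 3 calibration standards", call. = FALSE)
  if (anyDuplicated(standards$volume_ml))
    stop("calibration standards must have distinct elution volumes",
         call. = FALSE)
  if (any(standards$mass_kda <= 0))
    stop("standard masses must be > 0", call. = FALSE)
  fit <- lm(log10(mass_kda) ~ volume_ml, data = standards)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0)
    warning("calibration slope is non-negative; ",
            "expected larger masses to elute earlier")
  y <- log10(standards$mass_kda)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 volume_range = range(standards$volume_ml)),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(paste0("<sec_calibration> log10(kDa) = %.4f * mL + %.4f ",
                     "(R^2 = %.4f; %.2f-%.2f mL)\n"),
              x$slope, x$intercept, x$r_squared,
              x$volume_range[1L], x$volume_range[2L]))
  invisible(x)
}

#' Apparent molecular mass at an elution volume
#'
#' Inverts the calibration: `mass = 10^(slope * volume + intercept)`.
#' Volumes outside the calibrated range (plus 10% margin) are extrapolated
#' with a warning.
#'
#' @param curve A [sec_calibrate()] result.
#' @param volume Elution volume(s) in mL.
#' @return Apparent mass(es) in kDa.
#' @examples
#' curve <- structure(list(slope = -0.2, intercept = 4, r_squared = 1,
#'                         volume_range = c(8, 18)),
#'                    class = "sec_calibration")
#' apparent_mass(curve, 10)  # 100 kDa
#' @export
apparent_mass <- function(curve, volume) {
  stopifnot(inherits(curve, "sec_calibration"), is.numeric(volume))
  rng <- curve$volume_range
  margin <- 0.1 * diff(rng)
  if (any(volume < rng[1L] - margin | volume > rng[2L] + margin))
    warning("elution volume outside the calibrated range; extrapolating")
  10^(curve$slope * volume + curve$intercept)
}

#' Oligomeric-state candidates for an apparent mass
#'
#' Given a monomer mass and the apparent mass of the native complex,
#' enumerates subunit counts `n = 1..n_max` whose predicted mass
#' `n * monomer` lies within a relative tolerance of the apparent mass,
#' ranked by absolute deviation. With a 57-kDa monomer and an apparent mass
#' of about 200 kDa, the trimer (171 kDa) and tetramer (228 kDa) are the
#' two candidates.
#'
#' @param monomer_mass Monomer mass in kDa (> 0).
#' @param apparent_mass Apparent native mass in kDa (> 0).
#' @param n_max Largest subunit count considered (>= 1).
#' @param tolerance Maximum relative deviation
#'   `|n * monomer - apparent| / apparent`.
#' @return A list of class `oligomer_call`: `monomer_mass`, `apparent_mass`,
#'   and `candidates` (data.frame `n_subunits`, `predicted_mass`,
#'   `abs_deviation`, sorted by deviation; possibly zero rows).
#' @examples
#' oligomer_candidates(57, 200, n_max = 6, tolerance = 0.2)
#' @export
oligomer_candidates <- function(monomer_mass, apparent_mass, n_max = 8,
                                tolerance = 0.2) {
  stopifnot(monomer_mass > 0, apparent_mass > 0, n_max >= 1, tolerance >= 0)
  n <- seq_len(as.integer(n_max))
  predicted <- n * monomer_mass
  dev <- abs(predicted - apparent_mass)
  keep <- dev / apparent_mass <= tolerance
  candidates <- data.frame(n_subunits = n[keep],
                           predicted_mass = predicted[keep],
                           abs_deviation = dev[keep])
  candidates <- candidates[order(candidates$abs_deviation), , drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(monomer_mass = monomer_mass, apparent_mass = apparent_mass,
                 candidates = candidates), class = "oligomer_call")
}

#' @export
print.oligomer_call <- function(x, ...) {
  cat(sprintf("<oligomer_call> monomer %.1f kDa, apparent %.1f kDa\n",
              x$monomer_mass, x$apparent_mass))
  if (nrow(x$candidates) == 0L) cat("  no candidates within tolerance\n")
  else print(x$candidates)
  invisible(x)
}

#' Clustering parameters for correlation profiling
#'
#' @param top_n Number of most abundant proteins analysed together with the
#'   activity profile (ranked by summed abundance across fractions).
#' @param similarity_threshold Percent similarity above which a protein
#'   counts as co-clustering with activity (0-100, exclusive).
#' @param metric Profile-similarity definition; `"pearson"` (percent
#'   similarity = 100 * Pearson correlation, distance = 100 - similarity).
#' @param linkage Agglomeration rule for [stats::hclust()].
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(top_n = 200, similarity_threshold = 75,
                              metric = "pearson", linkage = "average") {
  if (similarity_threshold <= 0 || similarity_threshold >= 100)
    stop("similarity_threshold must be in (0, 100)", call. = FALSE)
  metric <- match.arg(metric, "pearson")
  stopifnot(top_n >= 1)
  structure(list(top_n = top_n, similarity_threshold = similarity_threshold,
                 metric = metric, linkage = linkage),
            class = "clustering_params")
}

#' Cluster protein elution profiles with an activity profile
#'
#' Correlation profiling: the activity profile (substrate removed per
#' fraction) is clustered hierarchically together with the abundance
#' profiles of the `top_n` most abundant proteins. Similarity between
#' profiles is 100 x Pearson correlation; the dendrogram is cut at
#' `100 - similarity_threshold` so that the proteins returned are exactly
#' those joined with the activity leaf at a similarity above the threshold.
#'
#' @param activity Numeric activity profile (one value per fraction), e.g.
#'   from [endpoint_activity()].
#' @param abundance Protein x fraction numeric matrix with row and column
#'   names; column count must equal `length(activity)`.
#' @param params A [clustering_params()] object.
#' @return A list of class `activity_cluster`: `members` (protein ids
#'   co-clustering with activity above the threshold), `similarity`
#'   (data.frame `protein_id`, `similarity_to_activity`,
#'   `in_threshold_set`), `hclust` (the full tree, leaf `"activity"`
#'   included), `params`.
#' @examples
#' ex <- simulate_sec(30, 50, 3, 0, 2.25, 1)
#' act <- endpoint_activity(ex$remaining_substrate, assay_params(ex$c0))
#' cl <- correlation_cluster(act, ex$abundance, clustering_params(top_n = 50))
#' sort(cl$members) == sort(ex$planted_ids)
#' @export
correlation_cluster <- function(activity, abundance,
                                params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"), is.matrix(abundance),
            is.numeric(activity))
  if (length(activity) < 5L)
    stop("need at least 5 fractions", call. = FALSE)
  if (ncol(abundance) != length(activity))
    stop("abundance columns must match the number of fractions",
         call. = FALSE)
  if (is.null(rownames(abundance)))
    stop("abundance matrix needs protein ids as rownames", call. = FALSE)
  if ("activity" %in% rownames(abundance))
    stop("protein id 'activity' collides with the activity leaf",
         call. = FALSE)
  if (stats::sd(activity) == 0)
    stop("activity profile has zero variance", call. = FALSE)

  constant <- apply(abundance, 1L, stats::sd) == 0
  if (any(constant)) {
    warning("excluding ", sum(constant),
            " constant (zero-variance) protein profile(s)")
    abundance <- abundance[!constant, , drop = FALSE]
  }
  top_n <- min(params$top_n, nrow(abundance))
  ord <- order(rowSums(abundance), decreasing = TRUE)
  abundance <- abundance[ord[seq_len(top_n)], , drop = FALSE]

  profiles <- rbind(activity = activity, abundance)
  sim <- 100 * cor(t(profiles))
  hc <- hclust(as.dist(100 - sim), method = params$linkage)
  grp <- cutree(hc, h = 100 - params$similarity_threshold)
  members <- setdiff(names(grp)[grp == grp[["activity"]]], "activity")

  sim_act <- sim["activity", rownames(abundance)]
  similarity <- data.frame(protein_id = rownames(abundance),
                           similarity_to_activity = unname(sim_act),
                           in_threshold_set = rownames(abundance) %in%
                             members,
                           stringsAsFactors = FALSE)
  similarity <- similarity[order(-similarity$similarity_to_activity), ,
                           drop = FALSE]
  rownames(similarity) <- NULL
  structure(list(members = members, similarity = similarity, hclust = hc,
                 params = params), class = "activity_cluster")
}

#' @export
print.activity_cluster <- function(x, ...) {
  cat(sprintf(paste0("<activity_cluster> %d protein(s) co-cluster with ",
                     "activity at > %g%% similarity (%s linkage, %s)\n"),
              length(x$members), x$params$similarity_threshold,
              x$params$linkage, x$params$metric))
  if (length(x$members))
    cat("  ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Write a clustering dendrogram as Newick
#'
#' @param cluster An [correlation_cluster()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(cluster, path) {
  stopifnot(inherits(cluster, "activity_cluster"))
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Check substrate/product stoichiometry
#'
#' True when the substrate removed and the product formed agree within a
#' relative tolerance (of the larger of the two), the signature of a clean
#' 1:1 enzymatic conversion. Two zeroes (no-enzyme control) pass.
#'
#' @param substrate_removed,product_formed Concentrations in mM (>= 0).
#' @param rel_tol Relative tolerance.
#' @return Logical scalar.
#' @examples
#' stoichiometry_check(1.0, 1.0)    # TRUE
#' stoichiometry_check(1.0, 0.85)   # FALSE
#' stoichiometry_check(0, 0)        # TRUE (control)
#' @export
stoichiometry_check <- function(substrate_removed, product_formed,
                                rel_tol = 0.1) {
  if (substrate_removed < 0 || product_formed < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  stopifnot(rel_tol >= 0)
  abs(substrate_removed - product_formed) <=
    rel_tol * max(substrate_removed, product_formed)
}
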