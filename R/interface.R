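#' Read sequences from FASTA or FASTQ
#'
#' Sequences are uppercased and U is normalised to T (metatranscriptome
#' reads), ids (first whitespace-delimited token of the header) must be
#' unique within the file, and FASTQ quality strings must match their
#' sequence lengths.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"` (default guessed from the
#'   extension).
#' @return A named character vector of sequences.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "fastq") {
    # the parser pads short quality strings, so check record shape directly
    ll <- readLines(path)
    ll <- ll[nzchar(ll)]
    if (length(ll) %% 4L != 0L)
      stop("malformed FASTQ (line count not a multiple of 4): ", path,
           call. = FALSE)
    sq <- nchar(ll[seq(2L, length(ll), by = 4L)])
    qq <- nchar(ll[seq(4L, length(ll), by = 4L)])
    bad <- which(sq != qq)
    if (length(bad))
      stop("FASTQ record ", bad[1L], " (line ", 4L * bad[1L] - 3L,
           "): quality length does not match sequence length",
           call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write reads to FASTQ (or FASTA)
#'
#' FASTQ output carries a constant Q30 quality (`?`) per base.
#'
#' @param reads data.frame with `read_id` and `sequence` columns, or a
#'   named character vector.
#' @param path Output file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (is.data.frame(reads)) {
    seqs <- setNames(reads$sequence, reads$read_id)
  } else seqs <- reads
  x <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq") {
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("?", Biostrings::width(x))))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' One record holding every tunable of the pipeline: detection criteria,
#' alignment scoring, assay and clustering parameters, simulation sizes and
#' the master seed. Round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param criteria A [detection_criteria()] object.
#' @param scoring An [align_scoring()] object.
#' @param assay An [assay_params()] object.
#' @param clustering A [clustering_params()] object.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param simulate List of simulation sizes: `gene_length`, `flank_length`,
#'   `n_datasets`, `n_reads`, `n_planted_reads`, `decoy_identity`,
#'   `sec` (list `n_fractions`, `n_proteins`, `n_planted`, `noise_sd`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(criteria = detection_criteria(),
                            scoring = align_scoring(),
                            assay = assay_params(),
                            clustering = clustering_params(),
                            seed = 1L,
                            simulate = list(gene_length = 1509L,
                                            flank_length = 400L,
                                            n_datasets = 6L,
                                            n_reads = 400L,
                                            n_planted_reads = 20L,
                                            decoy_identity = 0.85,
                                            sec = list(n_fractions = 30L,
                                                       n_proteins = 200L,
                                                       n_planted = 5L,
                                                       noise_sd = 0.05))) {
  stopifnot(inherits(criteria, "detection_criteria"),
            inherits(scoring, "align_scoring"),
            inherits(assay, "assay_params"),
            inherits(clustering, "clustering_params"))
  structure(list(criteria = criteria, scoring = scoring, assay = assay,
                 clustering = clustering, seed = as.integer(seed),
                 simulate = simulate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` object.
#' @param path Config file (YAML).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  pipeline_config(
    criteria = do.call(detection_criteria, raw$criteria),
    scoring = do.call(align_scoring, raw$scoring),
    assay = do.call(assay_params, raw$assay),
    clustering = do.call(clustering_params, raw$clustering),
    seed = raw$seed,
    simulate = raw$simulate)
}

# tabular artifact with a header comment naming the criteria in force
write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  cr <- config$criteria
  writeLines(sprintf(
    paste0("# acetrace v%s | criteria: single>=%gbp combined>=%gbp ",
           "identity>=%g partial>=%gbp contributing>=%gbp | ",
           "scoring: match %g mismatch %g gap %g/%g | seed %d"),
    as.character(utils::packageVersion("acetrace")),
    cr$min_single_span, cr$min_combined_coverage, cr$min_identity,
    cr$min_partial_span, cr$min_contributing_span,
    config$scoring$match, config$scoring$mismatch, config$scoring$gap_open,
    config$scoring$gap_extend, config$seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage TSV written by [run_pipeline()]
#'
#' @param path TSV path (leading `#` comment lines are skipped).
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order on fully synthetic inputs derived
#' from the single config seed: `simulate` fabricates a query gene with
#' flanks, an 85%-identity homolog decoy and a multi-site survey (reads as
#' FASTQ plus metadata/truth TSVs); `scan` screens every dataset against the
#' query gene; `aggregate` produces the site-per-year summary and
#' detection-rate statistics; `sec` simulates an SEC experiment, clusters
#' protein profiles with the activity profile and writes the subcluster
#' membership, dendrogram (Newick) and an oligomer-candidate table. Missing
#' prerequisites are reported before any stage runs; reruns with the same
#' config are bit-identical.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector, subset of
#'   `c("simulate", "scan", "aggregate", "sec")` in pipeline order.
#' @return Named list of the paths written, invisibly; the key in-memory
#'   results are returned in the `objects` element.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "scan", "aggregate", "sec")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  objects <- list()

  # pre-flight: later stages need the artifacts of earlier ones
  need <- c(scan = "simulate", aggregate = "scan")
  for (st in intersect(stages, names(need))) {
    pre <- unname(need[st])
    if (!(pre %in% stages)) {
      probe <- file.path(out_dir, if (pre == "simulate") "meta.tsv"
                         else "detections.tsv")
      if (!file.exists(probe))
        stop("stage '", st, "' needs '", pre, "' outputs; missing ", probe,
             call. = FALSE)
    }
  }

  sim <- config$simulate
  if ("simulate" %in% stages || "scan" %in% stages) {
    contexts <- with_seed(config$seed, {
      gene <- make_gene(sim$gene_length, 0.6, sample.int(2^30, 1L))
      ctx <- genome_context("SUL_Sh", gene,
                            flank_left = make_gene(sim$flank_length, 0.5,
                                                   sample.int(2^30, 1L)),
                            flank_right = make_gene(sim$flank_length, 0.5,
                                                    sample.int(2^30, 1L)))
      decoy <- genome_context("SUL_decoy",
                              mutate_to_identity(gene, sim$decoy_identity,
                                                 0.1,
                                                 sample.int(2^30, 1L)))
      list(SUL_Sh = ctx, SUL_decoy = decoy)
    })
    objects$contexts <- contexts
  }

  if ("simulate" %in% stages) {
    n <- sim$n_datasets
    site <- ((seq_len(n) - 1L) %% max(2L, n %/% 2L)) + 1L
    regions <- c("Europe", "East Asia", "North America")
    datasets <- data.frame(
      dataset_id = sprintf("DS%03d", seq_len(n)),
      site_id = sprintf("site%02d", site),
      year = 2019L + ((seq_len(n) - 1L) %% 3L),
      region = regions[(site - 1L) %% 3L + 1L],  # region fixed per site
      n_reads = sim$n_reads)
    # plant the query gene in a third of the datasets, the decoy in another
    planted <- seq(1L, n, by = 3L)
    decoyed <- seq(2L, n, by = 3L)
    planting <- rbind(
      data.frame(dataset_id = datasets$dataset_id[planted],
                 gene_id = "SUL_Sh", n_reads = sim$n_planted_reads,
                 read_length = 150L, error_rate = 0),
      data.frame(dataset_id = datasets$dataset_id[decoyed],
                 gene_id = "SUL_decoy", n_reads = sim$n_planted_reads,
                 read_length = 150L, error_rate = 0))
    survey <- simulate_survey(survey_scenario(datasets, planting),
                              objects$contexts, query_genes = "SUL_Sh",
                              seed = config$seed)
    objects$survey <- survey
    for (ds in names(survey$reads)) {
      p <- file.path(out_dir, paste0(ds, ".fastq"))
      write_reads(survey$reads[[ds]], p)
      paths[[paste0("reads_", ds)]] <- p
    }
    paths$meta <- write_stage_tsv(survey$meta,
                                  file.path(out_dir, "meta.tsv"), config)
    paths$truth <- write_stage_tsv(survey$truth,
                                   file.path(out_dir, "truth.tsv"), config)
    p <- file.path(out_dir, "genes.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      setNames(vapply(objects$contexts, context_sequence, ""),
               names(objects$contexts))), p)
    paths$genes <- p
  }

  if ("scan" %in% stages) {
    read_sets <- if (!is.null(objects$survey)) objects$survey$reads else {
      meta <- read_stage_tsv(file.path(out_dir, "meta.tsv"))
      setNames(lapply(meta$dataset_id, function(ds)
        read_sequences(file.path(out_dir, paste0(ds, ".fastq")))),
        meta$dataset_id)
    }
    detections <- scan_survey(read_sets,
                              objects$contexts["SUL_Sh"],
                              criteria = config$criteria,
                              scoring = config$scoring)
    objects$detections <- detections
    paths$detections <- write_stage_tsv(
      detections, file.path(out_dir, "detections.tsv"), config)
  }

  if ("aggregate" %in% stages) {
    detections <- if (!is.null(objects$detections)) objects$detections
                  else read_stage_tsv(file.path(out_dir, "detections.tsv"))
    meta <- if (!is.null(objects$survey)) objects$survey$meta
            else read_stage_tsv(file.path(out_dir, "meta.tsv"))
    summary <- aggregate_site_years(detections, meta)
    objects$summary <- summary
    paths$summary <- write_stage_tsv(summary,
                                     file.path(out_dir, "summary.tsv"),
                                     config)
    rate <- detection_rate(summary, by_gene = TRUE)
    paths$stats <- write_stage_tsv(rate, file.path(out_dir, "stats.tsv"),
                                   config)
    objects$rate <- rate
  }

  if ("sec" %in% stages) {
    ss <- sim$sec
    ex <- simulate_sec(ss$n_fractions, ss$n_proteins, ss$n_planted,
                       ss$noise_sd, config$assay$c0,
                       seed = config$seed)
    act <- endpoint_activity(ex$remaining_substrate, config$assay)
    cl <- correlation_cluster(act, ex$abundance, config$clustering)
    objects$sec <- ex
    objects$cluster <- cl
    paths$sec_membership <- write_stage_tsv(
      cl$similarity, file.path(out_dir, "sec_membership.tsv"), config)
    paths$sec_dendrogram <- write_dendrogram(
      cl, file.path(out_dir, "sec_dendrogram.nwk"))
    # synthetic standards on an exact log-linear curve (15-600 kDa range)
    std <- data.frame(mass_kda = c(600, 440, 200, 66, 29, 15),
                      volume_ml = c(8.943, 9.735, 11.75, 14.582, 16.683,
                                    18.367))
    curve <- sec_calibrate(std)
    peak_vol <- ex$elution_volumes[which.max(act)]
    call <- oligomer_candidates(57, apparent_mass(curve, peak_vol),
                                n_max = 8, tolerance = 0.2)
    objects$oligomer <- call
    paths$oligomer <- write_stage_tsv(
      cbind(monomer_kda = call$monomer_mass,
            apparent_kda = call$apparent_mass, call$candidates),
      file.path(out_dir, "oligomer.tsv"), config)
  }

  out <- paths
  out$objects <- objects
  invisible(out)
}
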