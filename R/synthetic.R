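#' Gene with genomic flanking context
#'
#' Bundles a query gene sequence with the genomic sequence flanking it in its
#' source replicon. The flanks are what allows rescue of reads that align only
#' partially because they straddle a gene terminus (see [rescue_partial()]).
#'
#' @param gene_id Identifier, e.g. `"SUL_Sh"` for the *Shinella*-type
#'   acesulfame sulfatase gene.
#' @param gene Nucleotide sequence of the gene (character, A/C/G/T).
#' @param flank_left,flank_right Flanking nucleotide sequences; may be empty.
#' @return An object of class `genome_context`.
#' @examples
#' ctx <- genome_context("SUL_Sh", make_gene(300, 0.6, 1),
#'                       flank_left = make_gene(100, 0.5, 2),
#'                       flank_right = make_gene(100, 0.5, 3))
#' ctx
#' @export
genome_context <- function(gene_id, gene, flank_left = "", flank_right = "") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  gene <- toupper(gene); flank_left <- toupper(flank_left)
  flank_right <- toupper(flank_right)
  if (nchar(gene) == 0L) stop("gene sequence must have length > 0", call. = FALSE)
  assert_dna(gene, "gene")
  if (nzchar(flank_left))  assert_dna(flank_left, "flank_left")
  if (nzchar(flank_right)) assert_dna(flank_right, "flank_right")
  structure(list(gene_id = gene_id, gene = gene,
                 flank_left = flank_left, flank_right = flank_right),
            class = "genome_context")
}

#' @export
print.genome_context <- function(x, ...) {
  cat(sprintf("<genome_context> %s: gene %d bp, flanks %d/%d bp\n",
              x$gene_id, nchar(x$gene), nchar(x$flank_left),
              nchar(x$flank_right)))
  invisible(x)
}

# concatenated flank_left + gene + flank_right
context_sequence <- function(context) {
  paste0(context$flank_left, context$gene, context$flank_right)
}

# 0-based half-open gene interval on the concatenated context
gene_region <- function(context) {
  off <- nchar(context$flank_left)
  c(start = off, end = off + nchar(context$gene))
}

#' Generate a random gene sequence
#'
#' Draws bases i.i.d. with the requested GC content. Used to fabricate query
#' genes and genomic flanks for simulations; a 1509-bp default-style draw
#' mimics a 502-aa coding sequence plus stop codon.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A single character string of `length` bases.
#' @examples
#' make_gene(30, 0.5, 1)
#' @export
make_gene <- function(length, gc = 0.5, seed = 1) {
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stop("`length` must be a positive integer", call. = FALSE)
  stopifnot(gc >= 0, gc <= 1)
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, as.integer(length), replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Mutate a sequence to a target overall identity
#'
#' Introduces substitutions (and optionally single-base indels) uniformly
#' along the sequence so that a global alignment of the output against the
#' input has approximately `target_identity` (within about one percentage
#' point for sequences of a few hundred bp). Used to fabricate homolog
#' decoys, e.g. an 85%-nucleotide-identity relative of a query gene.
#'
#' @param seq Input nucleotide sequence (character).
#' @param target_identity Desired identity fraction, in `(0, 1]`.
#' @param indel_fraction Fraction of edits that are single-base indels
#'   (half insertions, half deletions); the rest are substitutions.
#' @param seed Integer seed.
#' @return The mutated sequence (character).
#' @examples
#' g <- make_gene(300, 0.5, 1)
#' d <- mutate_to_identity(g, 0.85, 0.1, 11)
#' @export
mutate_to_identity <- function(seq, target_identity, indel_fraction = 0,
                               seed = 1) {
  seq <- toupper(seq); assert_dna(seq, "seq")
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("`target_identity` must be in (0, 1]", call. = FALSE)
  stopifnot(indel_fraction >= 0, indel_fraction <= 1)
  L <- nchar(seq)
  n_edit <- round(L * (1 - target_identity))
  if (n_edit == 0L) return(seq)
  with_seed(seed, {
    n_indel <- round(n_edit * indel_fraction)
    n_sub <- n_edit - n_indel
    bases <- strsplit(seq, "")[[1]]
    pos <- sample.int(L, n_sub + n_indel)
    sub_pos <- pos[seq_len(n_sub)]
    indel_pos <- pos[-seq_len(n_sub)]
    for (p in sub_pos)
      bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
    # apply indels right-to-left so positions stay valid; alternate del/ins
    if (n_indel > 0L) {
      indel_pos <- sort(indel_pos, decreasing = TRUE)
      del <- rep(c(TRUE, FALSE), length.out = n_indel)
      for (i in seq_len(n_indel)) {
        p <- indel_pos[i]
        if (del[i]) {
          bases <- bases[-p]
        } else {
          bases <- append(bases, sample(DNA_BASES, 1L), after = p)
        }
      }
    }
    paste(bases, collapse = "")
  })
}

#' Simulate shotgun reads from a genomic context, with truth labels
#'
#' Draws reads uniformly from the concatenated `flank_left + gene +
#' flank_right` sequence, from either strand with probability 0.5, and applies
#' independent per-base substitution errors. Every read carries its true
#' origin coordinates so downstream classifications can be checked against
#' ground truth. Reads are substitution-only (short-read error model).
#'
#' @param context A [genome_context()].
#' @param n_reads Number of reads (> 0).
#' @param read_length Either a single length in bp, or a function `f(n)`
#'   returning `n` integer lengths (all >= 30).
#' @param error_rate Per-base substitution probability, in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return A data.frame with columns `read_id`, `sequence`, `origin_gene`
#'   (gene_id if the read overlaps the gene, else `NA`), `origin_start`,
#'   `origin_end` (0-based half-open on the context), `strand`, `n_errors`.
#' @examples
#' ctx <- genome_context("g", make_gene(400, 0.5, 1))
#' head(simulate_reads(ctx, 5, 100, 0.01, 2))
#' @export
simulate_reads <- function(context, n_reads, read_length = 150,
                           error_rate = 0, seed = 1) {
  stopifnot(inherits(context, "genome_context"))
  if (!is.numeric(n_reads) || n_reads <= 0)
    stop("`n_reads` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.1)
    stop("`error_rate` must be in [0, 0.1]", call. = FALSE)
  n_reads <- as.integer(n_reads)
  ctx <- context_sequence(context)
  L <- nchar(ctx)
  with_seed(seed, {
    lens <- if (is.function(read_length)) as.integer(read_length(n_reads))
            else rep(as.integer(read_length), n_reads)
    if (any(lens < 30L))
      stop("read lengths must be >= 30 bp", call. = FALSE)
    if (any(lens > L))
      stop("read length exceeds context length", call. = FALSE)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L, 0L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    gr <- gene_region(context)
    seqs <- substring(ctx, starts + 1L, starts + lens)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      s <- seqs[i]
      if (strand[i] == "-") s <- revcomp(s)
      if (error_rate > 0) {
        b <- strsplit(s, "")[[1]]
        hit <- which(runif(lens[i]) < error_rate)
        for (p in hit) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1L)
        n_err[i] <- length(hit)
        s <- paste(b, collapse = "")
      }
      seqs[i] <- s
    }
    overlaps <- pmin(starts + lens, gr["end"]) - pmax(starts, gr["start"]) > 0
    data.frame(
      read_id = sprintf("read%05d", seq_len(n_reads)),
      sequence = seqs,
      origin_gene = ifelse(overlaps, context$gene_id, NA_character_),
      origin_start = starts,
      origin_end = starts + lens,
      strand = strand,
      n_errors = n_err,
      stringsAsFactors = FALSE
    )
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define a multi-site sequencing survey scenario
#'
#' A scenario describes a set of sequencing datasets (with site, year, region
#' metadata) and what is planted into each: reads from real query genes,
#' from homolog decoys, with the remainder drawn from random background
#' sequence. Emulates the structure of a public-archive survey of
#' wastewater-associated runs.
#'
#' @param datasets data.frame with columns `dataset_id`, `site_id`, `year`,
#'   `region`, `n_reads`.
#' @param planting data.frame with columns `dataset_id`, `gene_id`,
#'   `n_reads`, `read_length`, `error_rate`; zero rows means background only.
#' @return An object of class `survey_scenario`.
#' @export
survey_scenario <- function(datasets, planting = NULL) {
  need <- c("dataset_id", "site_id", "year", "region", "n_reads")
  stopifnot(is.data.frame(datasets), all(need %in% names(datasets)))
  if (anyDuplicated(datasets$dataset_id))
    stop("duplicate dataset_id in scenario", call. = FALSE)
  if (!is.numeric(datasets$year) || any(datasets$year != round(datasets$year)))
    stop("years must be integers", call. = FALSE)
  if (any(datasets$n_reads <= 0))
    stop("n_reads must be > 0 for every dataset", call. = FALSE)
  if (is.null(planting))
    planting <- data.frame(dataset_id = character(), gene_id = character(),
                           n_reads = integer(), read_length = integer(),
                           error_rate = numeric())
  stopifnot(all(c("dataset_id", "gene_id", "n_reads", "read_length",
                  "error_rate") %in% names(planting)))
  if (!all(planting$dataset_id %in% datasets$dataset_id))
    stop("planting references unknown dataset_id", call. = FALSE)
  structure(list(datasets = datasets, planting = planting),
            class = "survey_scenario")
}

#' Simulate a multi-site survey of sequencing datasets
#'
#' Generates one read collection per dataset of the scenario: planted reads
#' are drawn from the gene body of the named context (so an error-free
#' >= 150 bp planted read is a guaranteed single-read match), decoy plantings
#' reference decoy contexts by their own gene_id, and the remaining reads come
#' from a random background sequence. A truth table records, for each
#' (dataset, query gene), whether the planting guarantees a significant
#' detection by construction (at least one error-free planted read of
#' >= 150 bp from that gene).
#'
#' @param scenario A [survey_scenario()].
#' @param contexts Named list of [genome_context()] objects; names must cover
#'   every `gene_id` used in the planting.
#' @param query_genes Character vector of the gene_ids that count as query
#'   genes in the truth table (defaults to all planted gene_ids).
#' @param background_length Length of the random background sequence reads
#'   are drawn from.
#' @param read_length Background read length in bp.
#' @param seed Integer seed.
#' @return A list with `reads` (named list of per-dataset read data.frames),
#'   `truth` (data.frame `dataset_id`, `gene_id`, `planted_positive`), and
#'   `meta` (the scenario's datasets with a `size_bp` column of total bases).
#' @export
simulate_survey <- function(scenario, contexts, query_genes = NULL,
                            background_length = 20000L, read_length = 150L,
                            seed = 1) {
  stopifnot(inherits(scenario, "survey_scenario"), is.list(contexts))
  pl <- scenario$planting
  if (nrow(pl) && !all(pl$gene_id %in% names(contexts)))
    stop("planting references a gene_id without a context", call. = FALSE)
  if (is.null(query_genes)) query_genes <- sort(unique(pl$gene_id))
  ds <- scenario$datasets
  with_seed(seed, {
    bg <- genome_context("background",
                         make_gene(background_length, 0.5,
                                   sample.int(2^30, 1L)))
    reads <- vector("list", nrow(ds))
    names(reads) <- ds$dataset_id
    for (i in seq_len(nrow(ds))) {
      id <- ds$dataset_id[i]
      mine <- pl[pl$dataset_id == id, , drop = FALSE]
      parts <- list()
      for (j in seq_len(nrow(mine))) {
        ctxg <- contexts[[mine$gene_id[j]]]
        # plant from the gene body only: gene-only context
        gene_only <- genome_context(ctxg$gene_id, ctxg$gene)
        rj <- simulate_reads(gene_only, mine$n_reads[j],
                             mine$read_length[j], mine$error_rate[j],
                             seed = sample.int(2^30, 1L))
        rj$read_id <- sprintf("%s_%s_%s", id, mine$gene_id[j], rj$read_id)
        parts[[j]] <- rj
      }
      n_bg <- ds$n_reads[i] - sum(mine$n_reads)
      if (n_bg < 0) stop("planted reads exceed dataset n_reads", call. = FALSE)
      if (n_bg > 0) {
        rb <- simulate_reads(bg, n_bg, read_length, 0,
                             seed = sample.int(2^30, 1L))
        rb$origin_gene <- NA_character_
        rb$read_id <- sprintf("%s_bg_%s", id, rb$read_id)
        parts[[length(parts) + 1L]] <- rb
      }
      reads[[i]] <- do.call(rbind, parts)
      rownames(reads[[i]]) <- NULL
    }
    truth <- expand.grid(dataset_id = ds$dataset_id, gene_id = query_genes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$planted_positive <- mapply(function(d, g) {
      m <- pl[pl$dataset_id == d & pl$gene_id == g, , drop = FALSE]
      any(m$n_reads >= 1 & m$read_length >= 150 & m$error_rate == 0)
    }, truth$dataset_id, truth$gene_id)
    meta <- ds
    meta$size_bp <- unname(vapply(reads, function(r) sum(nchar(r$sequence)),
                                  0))
    list(reads = reads, truth = truth, meta = meta)
  })
}

#' Simulate an SEC activity/abundance experiment
#'
#' Emulates a size-exclusion chromatography run assayed for substrate
#' hydrolysis: an activity (substrate removed) profile with a single Gaussian
#' peak across fractions, a set of planted proteins whose abundance profiles
#' are scaled copies of the activity profile plus noise, and background
#' proteins with independent unimodal profiles peaking away from the activity
#' peak. Defaults mirror a 30-fraction run (0.5-mL fractions between 7 and
#' 22 mL elution volume), 2.25 mM initial substrate, 200 proteins of which 5
#' are planted.
#'
#' @param n_fractions Number of fractions (>= 5).
#' @param n_proteins Number of proteins in the abundance matrix.
#' @param n_planted Number of planted activity-correlated proteins
#'   (< `n_proteins`).
#' @param noise_sd Noise standard deviation as a fraction of each profile's
#'   peak height.
#' @param c0 Initial substrate concentration in mM (> 0).
#' @param seed Integer seed.
#' @param peak_fraction Index of the activity peak fraction.
#' @param peak_sd Activity peak width (sd, in fractions).
#' @return An object of class `sec_experiment`: list with `fraction_ids`,
#'   `elution_volumes` (mL), `remaining_substrate` (mM per fraction),
#'   `abundance` (protein x fraction matrix), `planted_ids`, `c0`.
#' @examples
#' ex <- simulate_sec(30, 200, 5, 0.05, 2.25, 1)
#' ex$planted_ids
#' @export
simulate_sec <- function(n_fractions = 30, n_proteins = 200, n_planted = 5,
                         noise_sd = 0.05, c0 = 2.25, seed = 1,
                         peak_fraction = 10, peak_sd = 1.5) {
  if (c0 <= 0) stop("`c0` must be > 0", call. = FALSE)
  if (n_fractions < 5) stop("need at least 5 fractions", call. = FALSE)
  if (n_planted >= n_proteins)
    stop("`n_planted` must be < `n_proteins`", call. = FALSE)
  with_seed(seed, {
    idx <- seq_len(n_fractions)
    volumes <- 7 + 0.25 + 0.5 * (idx - 1)          # 0.5-mL fractions from 7 mL
    removed <- 0.8 * c0 * exp(-(idx - peak_fraction)^2 / (2 * peak_sd^2))
    remaining <- pmin(pmax(c0 - removed, 0), c0)
    shape <- removed / max(removed)
    ids <- sprintf("prot%04d", seq_len(n_proteins))
    planted_ids <- sprintf("prot%04d_planted", seq_len(n_planted))
    ids[seq_len(n_planted)] <- planted_ids
    ab <- matrix(0, n_proteins, n_fractions,
                 dimnames = list(ids, sprintf("F%d", idx)))
    for (i in seq_len(n_planted)) {
      amp <- exp(rnorm(1, log(1e6), 0.5))
      ab[i, ] <- pmax(amp * shape + rnorm(n_fractions, 0, noise_sd * amp), 0)
    }
    # background peaks keep >= 4 fractions away from the activity peak so
    # their correlation with activity stays well below clustering thresholds
    for (i in seq.int(n_planted + 1L, n_proteins)) {
      repeat {
        ctr <- runif(1, 1, n_fractions)
        if (abs(ctr - peak_fraction) >= 4) break
      }
      w <- runif(1, 1, 3)
      amp <- exp(rnorm(1, log(3e5), 1))
      prof <- amp * exp(-(idx - ctr)^2 / (2 * w^2))
      ab[i, ] <- pmax(prof + rnorm(n_fractions, 0, noise_sd * amp), 0)
    }
    structure(list(fraction_ids = sprintf("F%d", idx),
                   elution_volumes = volumes,
                   remaining_substrate = remaining,
                   abundance = ab,
                   planted_ids = planted_ids,
                   c0 = c0),
              class = "sec_experiment")
  })
}

#' @export
print.sec_experiment <- function(x, ...) {
  cat(sprintf(paste0("<sec_experiment> %d fractions (%.2f-%.2f mL), ",
                     "%d proteins (%d planted), c0 = %g mM\n"),
              length(x$fraction_ids), min(x$elution_volumes),
              max(x$elution_volumes), nrow(x$abundance),
              length(x$planted_ids), x$c0))
  invisible(x)
}
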