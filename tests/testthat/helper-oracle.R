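# Independent oracles, deliberately written without the package's machinery.

# Brute-force local (Smith-Waterman/Gotoh) alignment with affine gaps.
# Scoring mirrors align_scoring(): gap of width w costs open + w * ext.
# M = alignments ending in a substitution column, E/F = ending in a gap.
# An optimal local alignment always ends (and starts) in a substitution
# column, so the best score is max(M). Returns the score plus
# matches/columns of one optimal traceback.
sw_oracle <- function(a, b, match = 1, mismatch = -2, open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1)  # predecessor state of M: 0 start,1 M,2 E,3 F
  pE <- matrix(0L, n + 1, m + 1)  # 1 = came from M, 2 = extends E
  pF <- matrix(0L, n + 1, m + 1)  # 1 = came from M, 3 = extends F
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      cand <- c(0, M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s
      pM[i, j] <- k - 1L
      eo <- M[i, j - 1] - (open + ext); ee <- E[i, j - 1] - ext
      E[i, j] <- max(eo, ee); pE[i, j] <- if (eo >= ee) 1L else 2L
      fo <- M[i - 1, j] - (open + ext); fe <- F_[i - 1, j] - ext
      F_[i, j] <- max(fo, fe); pF[i, j] <- if (fo >= fe) 1L else 3L
    }
  }
  best <- max(M, 0)
  if (best <= 0) return(list(score = 0, matches = 0L, columns = 0L))
  idx <- which(M == best, arr.ind = TRUE)[1, ]
  i <- idx[1]; j <- idx[2]; state <- 1L
  matches <- 0L; columns <- 0L
  repeat {
    if (state == 1L) {
      columns <- columns + 1L
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
      prev <- pM[i, j]
      i <- i - 1L; j <- j - 1L
      if (prev == 0L) break
      state <- prev
    } else if (state == 2L) {
      columns <- columns + 1L
      prev <- pE[i, j]
      j <- j - 1L
      state <- prev
    } else {
      columns <- columns + 1L
      prev <- pF[i, j]
      i <- i - 1L
      state <- prev
    }
  }
  list(score = best, matches = matches, columns = columns)
}

# Literal brute-force evaluator of the significant-match definition.
# Input: raw alignment table (read_id, q_start, q_end, span, identity,
# rescued) in gene coordinates. Enumerates alignment subsets for the
# combination rule when feasible; union via position marking.
oracle_significant <- function(alns, gene_length,
                               min_single = 150, min_combined = 140,
                               min_identity = 0.97, min_contrib = 30) {
  alns <- alns[alns$identity >= min_identity, , drop = FALSE]
  if (nrow(alns) == 0L) return(FALSE)
  if (any(alns$span >= min_single)) return(TRUE)
  if (any(alns$rescued)) return(TRUE)
  comb <- alns[alns$span >= min_contrib, , drop = FALSE]
  n <- nrow(comb)
  if (n == 0L) return(FALSE)
  union_bp <- function(rows) {
    pos <- rep(FALSE, gene_length)
    for (k in seq_len(nrow(rows))) {
      s <- rows$q_start[k] + 1L
      e <- rows$q_end[k]
      if (e >= s) pos[s:min(e, gene_length)] <- TRUE
    }
    sum(pos)
  }
  if (n <= 12L) {
    for (mask in 1:(2^n - 1L)) {
      sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1L))))
      if (union_bp(comb[sel, , drop = FALSE]) >= min_combined) return(TRUE)
    }
    FALSE
  } else {
    union_bp(comb) >= min_combined
  }
}

# random raw alignment tables for oracle-equivalence fuzzing
random_alignment_table <- function(n_reads, gene_length) {
  n <- sample(0:n_reads, 1L)
  if (n == 0L) {
    return(data.frame(read_id = character(), q_start = integer(),
                      q_end = integer(), span = integer(),
                      identity = numeric(), rescued = logical()))
  }
  span <- sample(10:160, n, replace = TRUE)
  q_start <- vapply(span, function(s)
    sample.int(gene_length - s + 1L, 1L) - 1L, 0L)
  data.frame(read_id = sprintf("r%02d", seq_len(n)),
             q_start = q_start, q_end = q_start + span, span = span,
             identity = sample(c(0.94, 0.96, 0.965, 0.97, 0.98, 1), n,
                               replace = TRUE),
             rescued = runif(n) < 0.05)
}

# mirror of the real classification flow feeding is_significant_match():
# identity filter, per-read single_full/contributing categories
evidence_from_table <- function(alns, criteria) {
  alns <- alns[alns$identity >= criteria$min_identity, , drop = FALSE]
  if (nrow(alns) == 0L) {
    return(data.frame(read_id = character(), category = character(),
                      rescued = logical(), q_start = integer(),
                      q_end = integer(), identity = numeric(),
                      span = integer()))
  }
  single <- tapply(alns$span >= criteria$min_single_span, alns$read_id, any)
  alns$category <- ifelse(single[alns$read_id], "single_full",
                          "contributing")
  alns
}

# measured identity of two sequences by independent global alignment
global_identity_oracle <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}
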