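# Shared small fixtures, built in code.

fixture_gene <- function(len = 400, seed = 101) make_gene(len, 0.55, seed)

fixture_context <- function(len = 400, flank = 200, seed = 101) {
  genome_context("SUL_Sh", fixture_gene(len, seed),
                 flank_left = make_gene(flank, 0.5, seed + 1),
                 flank_right = make_gene(flank, 0.5, seed + 2))
}

# substitute specific 1-based positions of a sequence with a different base
substitute_at <- function(seq, positions) {
  b <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) b[p] <- rot[[b[p]]]
  paste(b, collapse = "")
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))
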