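crit <- detection_criteria()

test_that("detection criteria validate their invariants", {
  expect_error(detection_criteria(min_single_span = 100,
                                  min_combined_coverage = 140),
               "min_combined_coverage")
  expect_error(detection_criteria(min_identity = 0), "min_identity")
  expect_error(detection_criteria(min_identity = 1.2), "min_identity")
  expect_s3_class(detection_criteria(), "detection_criteria")
})

test_that("reads are classified into single/contributing/partial classes", {
  ctx <- fixture_context()
  g <- ctx$gene
  glen <- nchar(g)
  cls_of <- function(read) {
    a <- local_align(g, c(r = read), crit$min_contributing_span,
                     crit$min_identity)
    classify_read(a, glen, crit)
  }
  # error-free 150-bp in-gene read -> single_full
  full <- cls_of(substr(g, 101, 250))
  expect_equal(full$category, "single_full")
  expect_false(full$partial_terminal)
  # 100-bp interior read -> contributing
  contrib <- cls_of(substr(g, 101, 200))
  expect_equal(contrib$category, "contributing")
  expect_false(contrib$partial_terminal)
  # 40-bp exact match ending exactly at the gene end -> terminal partial
  term <- cls_of(substr(g, glen - 39, glen))
  expect_equal(term$category, "contributing")
  expect_true(term$partial_terminal)
  expect_equal(term$q_end, glen)
  # terminal at gene start
  term0 <- cls_of(substr(g, 1, 40))
  expect_true(term0$partial_terminal)
  expect_equal(term0$q_start, 0)
  # no alignment -> insignificant
  none <- classify_read(local_align(g, c(r = make_gene(80, 0.5, 99)),
                                    30, 0.97), glen, crit)
  expect_equal(none$category, "insignificant")
})

test_that("flank rescue requires a contiguous full-length context match", {
  ctx <- fixture_context()
  full <- paste0(ctx$flank_left, ctx$gene, ctx$flank_right)
  gstart <- nchar(ctx$flank_left)  # 0-based gene start on the context
  # 150-bp read straddling the gene start with 40 bp inside -> rescued
  r40 <- substr(full, gstart - 110 + 1, gstart + 40)
  resc <- rescue_partial(c(rd = r40), ctx, crit)
  expect_false(is.null(resc))
  expect_equal(resc$gene_q_start, 0)
  expect_equal(resc$gene_q_end, 40)
  # only 20 bp inside the gene -> below the in-gene floor
  r20 <- substr(full, gstart - 130 + 1, gstart + 20)
  expect_null(rescue_partial(c(rd = r20), ctx, crit))
  # 100-bp straddling read -> contiguous span below 150
  r100 <- substr(full, gstart - 60 + 1, gstart + 40)
  expect_null(rescue_partial(c(rd = r100), ctx, crit))
  # flankless context: rescue impossible
  bare <- genome_context("SUL_Sh", ctx$gene)
  expect_message(out <- rescue_partial(c(rd = r40), bare, crit),
                 "impossible")
  expect_null(out)
})

test_that("dataset significance follows the match definition", {
  ctx <- fixture_context()
  g <- ctx$gene
  # one single_full read
  d1 <- detect_gene_in_dataset(c(a = substr(g, 51, 200)), ctx, crit)
  expect_true(d1$significant)
  expect_equal(d1$n_single, 1)
  # two 100-bp contributing reads, union 160 >= 140
  d2 <- detect_gene_in_dataset(c(a = substr(g, 1, 100),
                                 b = substr(g, 61, 160)), ctx, crit)
  expect_true(d2$significant)
  expect_equal(d2$covered_bp, 160)
  expect_equal(d2$n_contributing, 2)
  # two reads covering the same 100 bp: union 100 < 140
  d3 <- detect_gene_in_dataset(c(a = substr(g, 2, 101),
                                 b = substr(g, 2, 101)), ctx, crit)
  expect_false(d3$significant)
  expect_equal(d3$covered_bp, 100)
  # exactly 140 bp of union coverage from two 70-bp reads
  d4 <- detect_gene_in_dataset(c(a = substr(g, 31, 100),
                                 b = substr(g, 101, 170)), ctx, crit)
  expect_true(d4$significant)
  expect_equal(d4$covered_bp, 140)
  # a rescued read alone suffices
  full <- paste0(ctx$flank_left, ctx$gene, ctx$flank_right)
  gstart <- nchar(ctx$flank_left)
  straddle <- substr(full, gstart - 110 + 1, gstart + 40)
  d5 <- detect_gene_in_dataset(c(a = straddle), ctx, crit)
  expect_true(d5$significant)
  expect_equal(d5$n_rescued, 1)
  expect_equal(d5$covered_bp, 40)
  # empty collection
  d0 <- detect_gene_in_dataset(character(), ctx, crit)
  expect_false(d0$significant)
})

test_that("identity floor separates 4 from 5 substitutions in 150 bp", {
  g <- fixture_gene(1509, 55)
  read <- substr(g, 301, 450)
  # substitutions interior and spread: the full-span alignment stays the
  # single locally optimal one
  r5 <- substitute_at(read, c(20, 50, 80, 110, 140))  # 145/150 = 96.7%
  r4 <- substitute_at(read, c(20, 50, 80, 110))       # 146/150 = 97.3%
  ctx <- genome_context("SUL_Sh", g)
  expect_false(detect_gene_in_dataset(c(r = r5), ctx, crit)$significant)
  d4 <- detect_gene_in_dataset(c(r = r4), ctx, crit)
  expect_true(d4$significant)
  expect_equal(d4$n_single, 1)
  expect_equal(d4$evidence$identity, 146 / 150)
})

test_that("significance agrees with the brute-force subset evaluator", {
  glen <- 300L
  set.seed(314)
  n_agree <- 0L
  for (i in 1:400) {
    tab <- random_alignment_table(8L, glen)
    got <- is_significant_match(evidence_from_table(tab, crit), crit)
    want <- oracle_significant(tab, glen)
    expect_identical(got, want)
    n_agree <- n_agree + (got == want)
  }
  expect_equal(n_agree, 400L)
})

test_that("end-to-end detection agrees with the oracle on read mixtures", {
  ctx <- fixture_context(400, 200, 17)
  g <- ctx$gene
  decoy <- mutate_to_identity(g, 0.85, 0.1, 5)
  set.seed(99)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    reads <- vapply(seq_len(n), function(j) {
      kind <- sample(c("exact", "short", "mut", "decoy", "bg"), 1)
      len <- sample(c(40, 80, 100, 150, 160), 1)
      s <- sample.int(nchar(g) - len + 1L, 1)
      switch(kind,
             exact = substr(g, s, s + len - 1),
             short = substr(g, s, s + 39),
             mut = substitute_at(substr(g, s, s + len - 1),
                                 sample(5:(len - 5),
                                        sample(0:5, 1))),
             decoy = substr(decoy, s, s + len - 1),
             bg = make_gene(len, 0.5, 10000 + 100 * i + j))
    }, "")
    names(reads) <- sprintf("r%02d", seq_len(n))
    det <- detect_gene_in_dataset(reads, ctx, crit)
    ev <- det$evidence
    tab <- data.frame(read_id = ev$read_id, q_start = ev$q_start,
                      q_end = ev$q_end, span = ev$span,
                      identity = ev$identity, rescued = ev$rescued)
    expect_identical(det$significant, oracle_significant(tab, nchar(g)))
  }
})

test_that("detections are monotone in reads and identity threshold", {
  ctx <- fixture_context()
  g <- ctx$gene
  base <- c(a = substr(g, 1, 100), b = substr(g, 61, 160))
  extra <- c(base, c(z = make_gene(120, 0.5, 55)))
  expect_true(detect_gene_in_dataset(base, ctx, crit)$significant)
  expect_true(detect_gene_in_dataset(extra, ctx, crit)$significant)
  # raising the identity floor can only remove detections
  loose <- detection_criteria(min_identity = 0.9)
  strict <- detection_criteria(min_identity = 0.99)
  r <- substitute_at(substr(g, 101, 250), c(30, 70, 110))  # 98% identity
  expect_true(detect_gene_in_dataset(c(r = r), ctx, loose)$significant)
  expect_true(detect_gene_in_dataset(c(r = r), ctx, crit)$significant)
  expect_false(detect_gene_in_dataset(c(r = r), ctx, strict)$significant)
})

test_that("any error-free >=150 bp in-gene read is detected", {
  ctx <- fixture_context(600, 150, 23)
  g <- ctx$gene
  set.seed(12)
  for (i in 1:10) {
    len <- sample(150:220, 1)
    s <- sample.int(nchar(g) - len + 1L, 1)
    d <- detect_gene_in_dataset(c(r = substr(g, s, s + len - 1)), ctx, crit)
    expect_true(d$significant)
  }
})
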