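mk_meta <- function(dataset_id, site_id, year, region, size_bp = 1e9) {
  data.frame(dataset_id = dataset_id, site_id = site_id, year = year,
             region = region, size_bp = size_bp)
}
mk_det <- function(dataset_id, gene_id = "SUL_Sh", significant = TRUE) {
  data.frame(dataset_id = dataset_id, gene_id = gene_id,
             significant = significant)
}

test_that("positive sites are counted once per (site, year, gene)", {
  # 5 significant datasets, same site/year/gene -> 1 positive site
  meta <- mk_meta(sprintf("d%d", 1:5), "s1", 2020L, "Europe")
  s <- aggregate_site_years(mk_det(sprintf("d%d", 1:5)), meta)
  expect_equal(s$n_positive_sites, 1L)
  expect_equal(s$n_sites, 1L)
  expect_equal(s$searched_bp, 5e9)
  # same site significant in two years -> 2 positive site-years
  meta2 <- mk_meta(c("d1", "d2"), "s1", c(2020L, 2021L), "Europe")
  s2 <- aggregate_site_years(mk_det(c("d1", "d2")), meta2)
  expect_equal(sum(s2$n_positive_sites), 2L)
  expect_equal(nrow(s2), 2L)
  # no significant datasets -> all-zero summary
  s3 <- aggregate_site_years(mk_det(c("d1", "d2"), significant = FALSE),
                             meta2)
  expect_true(all(s3$n_positive_sites == 0L))
  expect_error(aggregate_site_years(mk_det("nope"), meta), "unknown")
})

test_that("summaries are invariant to dataset order and additive", {
  set.seed(21)
  n <- 30
  site <- sample(1:8, n, TRUE)
  meta <- mk_meta(sprintf("d%02d", 1:n),
                  sprintf("s%d", site),
                  sample(2019:2021, n, TRUE),
                  c("Europe", "East Asia")[site %% 2 + 1],  # fixed per site
                  size_bp = sample(1:5, n, TRUE) * 1e9)
  det <- mk_det(meta$dataset_id, significant = runif(n) < 0.5)
  s <- aggregate_site_years(det, meta)
  perm <- sample(n)
  s_perm <- aggregate_site_years(det[perm, ], meta[perm, ])
  expect_equal(s, s_perm)
  # region-year totals recompute from raw rows
  for (i in seq_len(nrow(s))) {
    m <- meta[meta$region == s$region[i] & meta$year == s$year[i], ]
    expect_equal(s$searched_bp[i], sum(m$size_bp))
    pos <- merge(det[det$significant, ], m, by = "dataset_id")
    expect_equal(s$n_positive_sites[i], length(unique(pos$site_id)))
  }
  # pooled rate equals total bp / total detections recomputed from rows
  rate <- detection_rate(s)
  vol <- unique(s[, c("region", "year", "searched_bp")])
  expect_equal(rate, sum(vol$searched_bp) / sum(s$n_positive_sites))
})

test_that("detection rate is total bp per positive site-year", {
  meta <- mk_meta(c("d1", "d2"), c("s1", "s2"), 2020L, "Europe", 220e9)
  s <- aggregate_site_years(mk_det(c("d1", "d2")), meta)
  expect_equal(detection_rate(s), 220e9)   # 440 Gbp, 2 detections
  bygene <- detection_rate(s, by_gene = TRUE)
  expect_equal(bygene$bp_per_detection, 220e9)
  s0 <- aggregate_site_years(mk_det(c("d1", "d2"), significant = FALSE),
                             meta)
  expect_warning(r0 <- detection_rate(s0), "zero detections")
  expect_identical(r0, Inf)
})

test_that("a planted detection rate is recovered within binomial error", {
  # 400 site-years of 2 Gbp each, true rate one detection per 10 Gbp
  set.seed(77)
  n <- 400
  hit <- rbinom(n, 1, 2 / 10)
  meta <- mk_meta(sprintf("d%03d", 1:n), sprintf("s%03d", 1:n),
                  2020L, sprintf("R%02d", rep(1:20, each = 20)), 2e9)
  s <- aggregate_site_years(mk_det(meta$dataset_id,
                                   significant = hit == 1), meta)
  est <- detection_rate(s)
  # detections ~ Binomial(400, 0.2): 3-sigma band 56..104 detections
  expect_gt(est, 800e9 / 104)
  expect_lt(est, 800e9 / 56)
})

test_that("size-detection correlation finds planted proportionality", {
  # groups exactly proportional: slope recovered, r = 1
  meta <- mk_meta(sprintf("d%d", 1:3), sprintf("s%d", 1:3), 2020L,
                  c("A", "B", "C"), c(1e9, 2e9, 3e9))
  det <- mk_det(sprintf("d%d", 1:3))
  s <- aggregate_site_years(det, meta)
  s$n_positive_sites <- 2 * s$searched_bp / 1e9  # y = 2x (per Gbp)
  res <- size_detection_correlation(s, "region")
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2 / 1e9)
  # all-zero positives: slope 0, r flagged undefined
  s$n_positive_sites <- 0
  res0 <- size_detection_correlation(s, "region")
  expect_equal(res0$slope, 0)
  expect_equal(res0$r, 0)
  expect_false(res0$r_defined)
  expect_error(size_detection_correlation(s[1:2, ], "region"), "3 groups")
  # planted proportionality with noise across many groups
  set.seed(5)
  k <- 12
  meta2 <- mk_meta(sprintf("d%02d", 1:k), sprintf("s%02d", 1:k), 2020L,
                   sprintf("R%02d", 1:k), (1:k) * 1e9)
  s2 <- aggregate_site_years(mk_det(meta2$dataset_id), meta2)
  s2$n_positive_sites <- round(3 * (1:k) + rnorm(k, 0, 1.5))
  res2 <- size_detection_correlation(s2, "region")
  expect_gt(res2$r, 0.9)
})

test_that("median query coverage summarises positive run files", {
  det <- data.frame(covered_bp = c(0, 100, 200, 300),
                    covered_fraction = c(0, 0.1, 0.22, 0.5))
  expect_equal(median_query_coverage(det), 22)
  expect_equal(median_query_coverage(det, positives_only = FALSE), 16)
  expect_error(median_query_coverage(det[det$covered_bp < 0, ]), "no run")
})
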