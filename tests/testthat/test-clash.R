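make_sites <- function() {
  data.frame(mirna_id = c("mirA", "mirA", "mirB"),
             mrna_id = c("g1", "g2", "g1"),
             site_id = c("s1", "s2", "s3"),
             chimeric_count = c(10, 5, 2),
             mfe = c(-20, -15, -8),
             stringsAsFactors = FALSE)
}

test_that("tally_reads sums chimeric and single reads per id", {
  sites <- make_sites()
  tal <- tally_reads(sites,
                     mirna_singles = c(mirA = 100, mirB = 50),
                     mrna_singles = c(g1 = 30, g2 = 40))
  expect_equal(tal$sum_i[["mirA"]], 100 + 15)
  expect_equal(tal$sum_i[["mirB"]], 50 + 2)
  expect_equal(tal$sum_j[["g1"]], 30 + 12)
  expect_equal(tal$c_all, 17)
})

test_that("tally_reads rejects sites referencing unknown ids", {
  sites <- make_sites()
  expect_error(tally_reads(sites, c(mirA = 1), c(g1 = 1, g2 = 1)),
               "mirB")
  expect_error(tally_reads(sites, c(mirA = 1, mirB = 1), c(g1 = 1)),
               "g2")
})

test_that("validate_sites enforces columns, signs and uniqueness", {
  sites <- make_sites()
  expect_silent(validate_sites(sites))
  expect_error(validate_sites(sites[, -5]), "mfe")
  bad <- sites; bad$mfe[1] <- 2
  expect_error(validate_sites(bad), "mfe")
  bad <- sites; bad$chimeric_count[1] <- -1
  expect_error(validate_sites(bad), "non-negative")
  expect_error(validate_sites(rbind(sites, sites[1, ])), "duplicated")
})

test_that("site_null_probability matches the two-share product", {
  expect_equal(site_null_probability(10, 115, 42), (10 / 115) * (10 / 42))
  expect_equal(site_null_probability(0, 5, 5), 0)
  expect_error(site_null_probability(3, 0, 5), "positive")
  expect_error(site_null_probability(6, 5, 10), "exceeds")
})

test_that("site_pvalue is the exact upper binomial tail", {
  # brute-force tail summation oracle on a small family
  p_exact <- sum(dbinom(4:20, 20, 0.1))
  expect_equal(site_pvalue(4, 20, 0.1), p_exact, tolerance = 1e-12)
  expect_equal(site_pvalue(0, 50, 0.2), 1)      # full tail
  expect_equal(site_pvalue(5, 5, 1), 1)         # certain success
  expect_equal(site_pvalue(1, 10, 0), 0)        # impossible under null
})

test_that("score_sites Bonferroni filter keeps the hand-computed set", {
  # family of five p-values {1e-6, 0.005, 0.02, 0.2, 0.9}; n = 5, alpha 0.05
  # -> p * 5 < 0.05 keeps only p < 0.01: the first two
  p <- c(1e-6, 0.005, 0.02, 0.2, 0.9)
  tests <- data.frame(mirna_id = paste0("m", 1:5), mrna_id = "g",
                      site_id = paste0("s", 1:5), p_value = p)
  fs <- filter_sites(tests, alpha = 0.05)
  expect_equal(fs$n_kept, 2L)
  expect_setequal(fs$kept$mirna_id, c("m1", "m2"))
  expect_equal(fs$fraction_kept, 0.4)
})

test_that("filter_sites is invariant to input order", {
  tests <- data.frame(mirna_id = paste0("m", 1:5), mrna_id = "g",
                      site_id = paste0("s", 1:5),
                      p_value = c(1e-6, 0.005, 0.02, 0.2, 0.9))
  a <- filter_sites(tests)
  b <- filter_sites(tests[sample.int(5), ])
  expect_equal(a$kept, b$kept)
})

test_that("score_sites output is canonical and self-consistent", {
  sites <- make_sites()
  sc <- score_sites(sites, c(mirA = 1000, mirB = 1000),
                    c(g1 = 1000, g2 = 1000))
  expect_true(all(diff(order(sc$mirna_id, sc$mrna_id, sc$site_id)) == 1))
  expect_equal(sc$adjusted_p, pmin(1, sc$p_value * nrow(sc)))
  expect_equal(sc$passed, sc$p_value * nrow(sc) < 0.05)
  manual_p <- site_pvalue(sc$chimeric_count, sum(sc$chimeric_count),
                          sc$p_null)
  expect_equal(sc$p_value, manual_p)
})

test_that("collapse_interactions counts sites per pair", {
  sites <- make_sites()
  sites$adjusted_p <- c(0.01, 0.2, 0.05)
  ci <- collapse_interactions(sites)
  expect_equal(nrow(ci), 3L)
  sites2 <- rbind(sites, transform(sites[1, ], site_id = "s9",
                                   adjusted_p = 0.001))
  ci2 <- collapse_interactions(sites2)
  row <- ci2[ci2$mirna_id == "mirA" & ci2$mrna_id == "g1", ]
  expect_equal(row$n_sites, 2L)
  expect_equal(row$min_adjusted_p, 0.001)
})
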