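test_that("link_mirnas_to_pathways maps targets to pathway membership", {
  tg <- list(mirA = c("g1", "g2"), mirB = "g3", mirC = "g9")
  pw <- list(p1 = c("g1", "g5"), p2 = c("g2", "g3"))
  mp <- link_mirnas_to_pathways(tg, pw)
  expect_setequal(mp$mirA, c("p1", "p2"))
  expect_equal(mp$mirB, "p2")
  expect_length(mp$mirC, 0L)
})

test_that("enumerate_candidates equals brute force on a small instance", {
  mp <- list(m1 = c("pA", "pB"), m2 = "pA", m3 = c("pA", "pB"), m4 = "pB")
  got <- enumerate_candidates(mp, k = 2)
  # brute force: all 2-subsets of {m1..m4} sharing at least one pathway
  all_pairs <- combn(names(mp), 2, simplify = FALSE)
  want <- Filter(function(s)
    length(Reduce(intersect, mp[s])) > 0, all_pairs)
  want_keys <- sort(vapply(want, paste, "", collapse = "+"))
  got_keys <- vapply(got, paste, "", collapse = "+")
  expect_identical(got_keys, want_keys)
  # k exceeding every pathway's linked count -> empty
  expect_length(enumerate_candidates(mp, k = 4), 0L)
})

test_that("enumerate_candidates caps oversized pathways with a warning", {
  mp <- setNames(rep(list("pBig"), 6), paste0("m", 1:6))
  expect_warning(got <- enumerate_candidates(mp, k = 2, cap = 3L), "capped")
  expect_length(got, choose(3, 2))
})

test_that("pathway_enrichment is the exact hypergeometric upper tail", {
  # population 50, 10 successes, draw 12, observe 5: brute-force oracle
  p_exact <- sum(dhyper(5:10, 10, 40, 12))
  expect_equal(pathway_enrichment(5, 50, 10 / 50, 12), p_exact,
               tolerance = 1e-12)
  expect_equal(pathway_enrichment(0, 50, 0.2, 12), 1)
  expect_error(pathway_enrichment(5, 50, 0.02, 12), "inconsistent")
})

test_that("involvement and recurrence tests are exact binomial tails", {
  # |W| = 10, P_WD = 0.1, w_MD = 3
  expect_equal(involvement_test(3, 10, 0.1),
               sum(dbinom(3:10, 10, 0.1)), tolerance = 1e-12)
  expect_equal(involvement_test(0, 10, 0.1), 1)
  expect_error(involvement_test(1, 10, 1.2), "P_WD")
  # |D| = 4, P_k = 0.25, d_M = 4 -> single tail term 0.25^4
  expect_equal(recurrence_test(4, 4, 0.25), 0.25^4, tolerance = 1e-12)
  expect_equal(recurrence_test(0, 6, 0.3), 1)
  r_exact <- sum(dbinom(2:6, 6, 0.07))
  expect_equal(recurrence_test(2, 6, 0.07), r_exact, tolerance = 1e-12)
  expect_error(recurrence_test(2, 6, -0.1), "non-negative")
})

test_that("fdr_control is exact Benjamini-Hochberg", {
  expect_equal(fdr_control(0.03), 0.03)
  expect_equal(fdr_control(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_control(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.09)
  m <- length(p)
  q_manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(fdr_control(p), q_manual)
  expect_error(fdr_control(c(0.5, 1.2)), "p")
})

test_that("find_modules reports a strong recurrent module and its conditions", {
  # two miRNAs co-target a pathway's genes in 3 of 4 conditions; further
  # decoy miRNAs have targets outside every pathway.  The decoys matter:
  # the empirical null rate for k-sets is averaged over choose(K, k)
  # candidates, so a realistic miRNA universe is needed for the
  # involvement test to have power.
  conds <- paste0("c", 1:4)
  sel <- do.call(rbind, lapply(conds[1:3], function(D)
    data.frame(condition = D, kind = "miRNA",
               regulator_id = rep(c("mirA", "mirB"), each = 4),
               gene_id = rep(paste0("g", 1:4), 2))))
  decoys <- sprintf("mir%s", c("C", "D", "E", "F", "G", "H", "I"))
  extra <- do.call(rbind, lapply(conds, function(D)
    do.call(rbind, lapply(decoys, function(m)
      data.frame(condition = D, kind = "miRNA", regulator_id = m,
                 gene_id = paste0("h_", m, "_", 1:6))))))
  sel <- rbind(sel, extra)
  pw <- c(list(mod = paste0("g", 1:4)),
          setNames(lapply(1:20, function(i) paste0("x", i, "_", 1:5)),
                   paste0("rand", 1:20)))
  mr <- find_modules(sel, pw, conditions = conds, k_min = 1, k_max = 2)
  expect_s3_class(mr, "module_report")
  row <- mr$modules[mr$modules$mirna_set == "mirA+mirB", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$d_M, 3L)
  expect_lt(row$q, 0.05)
  expect_equal(row$conditions, "c1,c2,c3")
  # detail lists the enriched pathway with its target genes
  det <- mr$detail[["mirA+mirB"]]
  expect_setequal(names(det), c("c1", "c2", "c3"))
  expect_equal(det$c1$pathway, "mod")
  # mirC never shares an enriched pathway set across conditions
  expect_false("mirC" %in% unlist(strsplit(mr$modules$mirna_set, "+",
                                           fixed = TRUE)))
})

test_that("find_modules q is NA outside the involvement-passing family", {
  conds <- paste0("c", 1:4)
  sel <- do.call(rbind, lapply(conds[1:3], function(D)
    data.frame(condition = D, kind = "miRNA",
               regulator_id = rep(c("mirA", "mirB"), each = 4),
               gene_id = rep(paste0("g", 1:4), 2))))
  pw <- c(list(mod = paste0("g", 1:4)),
          setNames(lapply(1:20, function(i) paste0("x", i, "_", 1:5)),
                   paste0("rand", 1:20)))
  mr <- find_modules(sel, pw, conditions = conds, k_min = 1, k_max = 2)
  cand <- mr$candidates
  expect_true(all(is.na(cand$q[cand$d_M == 0])))
  expect_true(all(!is.na(cand$q[cand$d_M >= 1])))
})

test_that("find_modules handles empty selections", {
  sel <- data.frame(condition = character(), kind = character(),
                    regulator_id = character(), gene_id = character())
  mr <- find_modules(sel, list(p1 = "g1"))
  expect_equal(nrow(mr$candidates), 0L)
  expect_equal(nrow(mr$modules), 0L)
})

test_that("report_modules applies the q threshold and recurrence floor", {
  cand <- data.frame(mirna_set = c("a", "b", "c"), k = 1, d_M = c(3, 1, 2),
                     p_involvement_min = 0.01, p_recurrence = 0.001,
                     q = c(0.2, 0.01, 0.01), conditions = "")
  out <- report_modules(cand, q_threshold = 0.05, min_conditions = 2)
  expect_equal(out$mirna_set, "c")  # a fails q, b fails recurrence floor
})
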