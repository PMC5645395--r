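small_truth <- function(seed = 1) {
  generate_truth(n_genes = 60L, n_mirnas = 20L, n_tfs = 5L,
                 n_conditions = 4L, regulated_fraction = 0.5,
                 module_spec = list(k = 3L, n_conditions = 2L,
                                    n_genes = 6L, n_pathways = 1L),
                 seed = seed)
}

test_that("generate_truth lays out conditions, edges and the module", {
  tr <- small_truth()
  expect_s3_class(tr, "ground_truth")
  expect_equal(nrow(tr$conditions), 4L)
  expect_length(tr$module$mirnas, 3L)
  expect_length(tr$module$conditions, 2L)
  expect_true(all(tr$module$mirnas %in% tr$mirnas))
  # module edges present in every module condition
  for (D in tr$module$conditions) {
    e <- tr$edges[tr$edges$condition == D, ]
    grid <- expand.grid(g = tr$module$genes, m = tr$module$mirnas)
    expect_true(all(paste(grid$g, grid$m) %in%
                      paste(e$gene_id, e$regulator_id)))
  }
  # no duplicated (condition, gene, regulator)
  key <- paste(tr$edges$condition, tr$edges$gene_id, tr$edges$regulator_id)
  expect_false(anyDuplicated(key) > 0)
  # miRNA effects are repressive
  expect_true(all(tr$edges$effect[tr$edges$kind == "miRNA"] < 0))
  # deterministic
  expect_identical(tr$edges, small_truth()$edges)
  expect_error(generate_truth(n_mirnas = 2,
                              module_spec = list(k = 3, n_conditions = 1,
                                                 n_genes = 2,
                                                 n_pathways = 1)),
               "infeasible")
})

test_that("binding evidence separates true pairs from decoys", {
  tr <- small_truth()
  ev <- generate_binding_evidence(tr, depth = 20, seed = 2)
  sc <- score_sites(ev$sites[, setdiff(colnames(ev$sites), "is_true")],
                    ev$mirna_singles, ev$mrna_singles)
  sc$is_true <- ev$sites$is_true[match(sc$site_id, ev$sites$site_id)]
  true_pass <- mean(sc$passed[sc$is_true])
  decoy_pass <- mean(sc$passed[!sc$is_true])
  expect_gt(true_pass, 0.9)
  expect_lt(decoy_pass, 0.2)
  expect_true(all(sc$mfe <= 0))
})

test_that("expression tables follow the generative model directions", {
  tr <- small_truth()
  ex <- generate_expression(tr, samples_per_condition = 15, n_normals = 10,
                            seed = 3)
  expect_setequal(rownames(ex$gene_expr), c(tr$genes, tr$tfs))
  expect_true(all(ex$gene_expr >= 0))
  expect_true(all(ex$meth >= 0 & ex$meth <= 1))
  ss <- ex$sample_sheet
  expect_s3_class(ss, "sample_sheet")
  conds <- list_conditions(ss)
  expect_equal(nrow(conds), 4L)
  expect_true(all(conds$n_tumor == 15L))
  # a strongly repressed gene: pick a miRNA edge and check the sign of the
  # association between regulator change and gene change
  e <- tr$edges[tr$edges$kind == "miRNA", ][1, ]
  tum <- ss$sample_id[ss$status == "tumor" &
                        paste(ss$cancer_type, ss$stage,
                              sep = ":") == e$condition]
  nor <- ss$sample_id[ss$status == "normal" &
                        ss$cancer_type == sub(":.*", "", e$condition)]
  dg <- expression_changes(ex$gene_expr, tum, nor)[e$gene_id, ]
  dm <- expression_changes(ex$mirna_expr, tum, nor)[e$regulator_id, ]
  expect_lt(cor(dg, dm) * sign(e$effect) * -1, 0)  # cor sign matches effect
})

test_that("generate_pathways plants the module pathways", {
  tr <- small_truth()
  pw <- generate_pathways(tr, n_pathways = 12, seed = 4)
  expect_length(pw, 12L)
  for (nm in tr$module$pathways) {
    expect_true(all(tr$module$genes %in% pw[[nm]]))
  }
  expect_true(all(lengths(pw) >= 5))
})

test_that("simulate_bundle round-trips through disk", {
  b <- simulate_bundle(n_genes = 40L, n_mirnas = 12L, n_tfs = 4L,
                       n_conditions = 3L, regulated_fraction = 0.5,
                       module_spec = list(k = 2L, n_conditions = 2L,
                                          n_genes = 4L, n_pathways = 1L),
                       samples_per_condition = 10L, n_normals = 5L,
                       n_pathways = 8L, seed = 9L)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  b2 <- read_bundle(d)
  expect_equal(b2$gene_expr, b$gene_expr, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(b2$sample_sheet$sample_id, b$sample_sheet$sample_id)
  expect_equal(sort(names(b2$pathways)), sort(names(b$pathways)))
  expect_equal(b2$mirna_singles, b$mirna_singles)
})

test_that("selection_f1 computes triple-level precision/recall", {
  truth <- data.frame(condition = c("c1", "c1", "c2"),
                      gene_id = c("g1", "g2", "g1"),
                      regulator_id = c("mA", "mB", "mA"))
  sel <- data.frame(condition = c("c1", "c1", "c2"),
                    gene_id = c("g1", "g3", "g1"),
                    regulator_id = c("mA", "mC", "mA"))
  f <- selection_f1(sel, truth)
  expect_equal(f$tp, 2L)
  expect_equal(f$fp, 1L)
  expect_equal(f$fn, 1L)
  expect_equal(f$precision, 2 / 3)
  expect_equal(f$recall, 2 / 3)
  expect_equal(f$f1, 2 / 3)
  f2 <- selection_f1(sel, truth, conditions = "c2")
  expect_equal(f2$f1, 1)
})
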