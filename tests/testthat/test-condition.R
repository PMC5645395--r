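test_that("log2_change applies the pseudocount to both terms", {
  expect_equal(log2_change(3.5, 1.5, 0.5), 1)     # (4)/(2) = 2
  expect_equal(log2_change(0, 0, 0.5), 0)
  expect_equal(log2_change(7, 7, 0.5), 0)
  expect_error(log2_change(-1, 2), "non-negative")
  expect_error(log2_change(1, 2, 0), "positive")
})

test_that("expression_changes compares each tumor to the control mean", {
  expr <- matrix(c(8, 2, 4, 2, 3.5, 1.5), 1, 6,
                 dimnames = list("g1", paste0("s", 1:6)))
  ch <- expression_changes(expr, tumor_ids = c("s1", "s2"),
                           normal_ids = c("s5", "s6"), pseudocount = 0.5)
  ctrl <- mean(c(3.5, 1.5))
  expect_equal(ch["g1", "s1"], log2(8.5 / (ctrl + 0.5)))
  expect_equal(dim(ch), c(1L, 2L))
  expect_error(expression_changes(expr, "sX", "s5"), "absent")
})

test_that("detect_de requires both fold change and adjusted significance", {
  set.seed(1)
  n <- 12
  tum <- paste0("t", 1:n); nor <- paste0("n", 1:n)
  expr <- rbind(
    up = c(rlnorm(n, log(400), 0.1), rlnorm(n, log(100), 0.1)),
    flat = c(rlnorm(n, log(100), 0.1), rlnorm(n, log(100), 0.1)),
    small = c(rlnorm(n, log(130), 0.05), rlnorm(n, log(100), 0.05)))
  colnames(expr) <- c(tum, nor)
  de <- detect_de(expr, tum, nor, fc_threshold = 2, alpha = 0.05)
  expect_true(de$de[de$feature_id == "up"])
  expect_false(de$de[de$feature_id == "flat"])
  # 'small' is significant but below the fold-change threshold
  expect_lt(de$adjusted_p[de$feature_id == "small"], 0.05)
  expect_false(de$de[de$feature_id == "small"])
  expect_equal(de$adjusted_p, p.adjust(de$p_value, "BH"))
})

test_that("detect_de warns and returns empty on underpowered groups", {
  expr <- matrix(1:4, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  expect_warning(out <- detect_de(expr, "s1", c("s2", "s3")), "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("applicability_filter drops mutated sites and silent features", {
  sites <- data.frame(mirna_id = c("mirA", "mirA", "mirB"),
                      mrna_id = c("g1", "g2", "g1"),
                      site_id = c("s1", "s2", "s3"),
                      mfe = -10, p_null = 0.01, passed = TRUE,
                      stringsAsFactors = FALSE)
  ge <- matrix(c(5, 0, 5, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("t1", "t2")))
  me <- matrix(c(5, 5, 5, 5), 2, 2,
               dimnames = list(c("mirA", "mirB"), c("t1", "t2")))
  out <- applicability_filter(sites, ge, me, c("t1", "t2"),
                              expression_floor = 0,
                              mutated_site_ids = "s3")
  # s3 mutated away; s2 dropped because g2 is unexpressed
  expect_equal(out$site_id, "s1")
  out2 <- applicability_filter(sites, ge, me, c("t1", "t2"),
                               mutated_site_ids = sites$site_id)
  expect_equal(nrow(out2), 0L)
})

test_that("build_design assembles Y, X1, P, R and X2 = P * R", {
  tum <- c("t1", "t2", "t3"); nor <- c("n1", "n2")
  samp <- c(tum, nor)
  ge <- rbind(g1 = c(4, 8, 2, 3.5, 1.5), tfA = c(2, 4, 8, 1.5, 3.5))
  colnames(ge) <- samp
  me <- matrix(c(1, 2, 4, 2, 2), 1, 5,
               dimnames = list("mirZ", samp))
  cnv <- matrix(c(0.2, 0.1, 0, 0, 0), 2, 5, byrow = TRUE,
                dimnames = list(c("g1", "tfA"), samp))
  meth <- matrix(0.5, 2, 5, dimnames = list(c("g1", "tfA"), samp))
  rs <- c(mirZ = 0.6, tfA = 0.4)
  kinds <- c(mirZ = "miRNA", tfA = "TF")
  des <- build_design("g1", "ca:I", rs, kinds, ge, me, cnv, meth, tum, nor)
  expect_s3_class(des, "gene_condition_design")
  # canonical ordering: TF first
  expect_equal(des$regulator_ids, c("tfA", "mirZ"))
  expect_equal(unname(des$R), c(0.4, 0.6))
  ctrl_g <- mean(c(3.5, 1.5))
  expect_equal(des$Y["t1", 1], log2(4.5 / (ctrl_g + 0.5)))
  expect_equal(des$X1["t1", "cnv_change"], 0.2 - 0)
  expect_equal(des$X2, sweep(des$P, 2, des$R, "*"))
  ctrl_m <- mean(c(2, 2))
  expect_equal(des$P["t2", "mirZ"], log2(2.5 / (ctrl_m + 0.5)))
  expect_error(build_design("g1", "ca:I", rs["mirZ"][0], kinds,
                            ge, me, cnv, meth, tum, nor), "no candidates")
})
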