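test_that("median-of-ratios matches the hand-computed example", {
  m <- matrix(c(2, 3, 8, 12), 2,
              dimnames = list(c("pA", "pB"), c("s1", "s2")))
  res <- normalize_median_of_ratios(proteome_matrix(m))
  expect_equal(unname(res$size_factors), c(0.5, 2))
  expect_equal(unname(res$matrix$intensities),
               matrix(c(4, 6, 4, 6), 2))
  # idempotence: factors of an already-normalized matrix are all 1
  res2 <- normalize_median_of_ratios(res$matrix)
  expect_equal(unname(res2$size_factors), c(1, 1))
  # scaling one column multiplies the factor ratio by 10 and leaves the
  # normalized output unchanged up to a global constant (size factors are
  # defined up to scale)
  m10 <- m; m10[, 2] <- m10[, 2] * 10
  res10 <- normalize_median_of_ratios(proteome_matrix(m10))
  expect_equal(res10$size_factors[["s2"]] / res10$size_factors[["s1"]],
               10 * res$size_factors[["s2"]] / res$size_factors[["s1"]])
  ratio <- res10$matrix$intensities / res$matrix$intensities
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("median-of-ratios agrees with DESeq2 on a complete matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  m <- matrix(2^rnorm(196, 10, 2), 49,
              dimnames = list(sprintf("p%02d", 1:49), sprintf("s%d", 1:4)))
  own <- normalize_median_of_ratios(proteome_matrix(m))$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(own), unname(ref), tolerance = 1e-8)
})

test_that("normalization preserves within-sample rank order", {
  set.seed(5)
  m <- matrix(2^rnorm(120, 15, 1), 30,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("s%d", 1:4)))
  norm <- normalize_median_of_ratios(proteome_matrix(m))$matrix
  for (j in 1:4)
    expect_equal(order(m[, j]), order(norm$intensities[, j]))
  # no complete rows -> error advising to filter
  m[1, 1] <- NA; m[-1, 2] <- NA
  expect_error(normalize_median_of_ratios(proteome_matrix(m)), "filter")
})

test_that("replicate-support filter keeps >= 2 values in some group", {
  des <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 3L)
  m <- matrix(2, 3, 6, dimnames = list(c("twice_one_group",
                                         "once_per_group", "full"),
                                       des$sample_id))
  m["twice_one_group", ] <- c(5, 5, NA, NA, NA, NA)
  m["once_per_group", ] <- c(5, NA, NA, 5, NA, NA)
  kept <- filter_replicate_support(proteome_matrix(m), des)
  expect_setequal(rownames(kept$intensities), c("twice_one_group", "full"))
})

test_that("imputation rules: group mean, kNN donor, left missing", {
  des <- make_design(c("pre_heat", "heat", "heat", "recovery"),
                     c(0, 1, 2, 0), n_rep = 3L)
  m <- matrix(NA_real_, 3, 12,
              dimnames = list(c("partial", "donor", "orphan"),
                              des$sample_id))
  grp <- paste(des$phase, des$time_h)
  # partial: 2 of 3 observed in heat 1 -> rule (i), sd 0 => group mean
  m["partial", ] <- 2^10
  m["partial", grp == "heat 1"] <- c(2^12, 2^14, NA)
  # donor/orphan: identical profiles; orphan's heat-1 group wholly missing
  m["donor", ] <- 2^c(8, 8, 8, 9, 9, 9, 10, 10, 10, 11, 11, 11)
  m["orphan", ] <- m["donor", ]
  m["orphan", grp == "heat 1"] <- NA
  # orphan2: missing everywhere except pre-heat => recovery group has
  # empty adjacent groups -> rule (iii)
  m <- rbind(m, orphan2 = c(2^7, 2^7, 2^7, rep(NA, 9)))
  pm <- proteome_matrix(m)
  res <- suppressWarnings(impute_proteome(pm, des, k = 1L, seed = 3L))
  # observed cells never altered
  obs <- !is.na(m)
  expect_equal(res$matrix$intensities[obs], m[obs])
  # report accounts for every missing cell
  expect_equal(nrow(res$report), sum(!obs))
  # sd 0 within the helper data? global sd is pooled; force check via status
  rep_partial <- res$report[res$report$protein_id == "partial", ]
  expect_equal(rep_partial$status, "imputed_group")
  # orphan imputed from its duplicate-profile donor (1-NN)
  rep_orphan <- res$report[res$report$protein_id == "orphan", ]
  expect_true(all(rep_orphan$status == "imputed_knn"))
  expect_true(all(rep_orphan$neighbors == "donor"))
  # with global sd ~0 the imputed mean equals the donor group mean
  expect_equal(mean(log2(res$matrix$intensities["orphan", grp == "heat 1"])),
               9, tolerance = 0.1)
  # rule (iii): heat 2 and recovery 0 of orphan2 have no adjacent values
  rep_o2 <- res$report[res$report$protein_id == "orphan2", ]
  expect_true(all(rep_o2$status[rep_o2$phase == "recovery"] ==
                    "left_missing"))
  expect_true(anyNA(res$matrix$intensities["orphan2", ]))
})

test_that("group-mean imputation equals the mean in the zero-sd limit", {
  des <- make_design(c("pre_heat", "heat"), c(0, 2), n_rep = 3L)
  m <- matrix(2^8, 2, 6, dimnames = list(c("a", "b"), des$sample_id))
  m["a", 4:6] <- c(2^10, 2^10, NA)
  res <- suppressWarnings(impute_proteome(proteome_matrix(m), des,
                                          seed = 1L))
  expect_equal(res$global_sd, 0)
  expect_equal(log2(res$matrix$intensities["a", 6]), 10)
})

test_that("masked-group imputation is unbiased on synthetic proteomes", {
  biases <- vapply(1:3, function(s) {
    rec <- sim_recipe(seed = 400 + s, n_genes = 600, n_proteins = 300,
                      mcar_rate = 0, mnar_max = 0, ambiguous_rate = 0)
    sim <- simulate_omics(rec, default_design("heat35", 3))
    m <- sim$proteome$intensities
    des <- sim$design
    gk <- paste(des$phase, des$time_h)[match(colnames(m), des$sample_id)]
    cells <- expand.grid(p = rownames(m), g = unique(gk),
                         stringsAsFactors = FALSE)
    set.seed(500 + s)
    masked <- cells[sample(nrow(cells), round(0.1 * nrow(cells))), ]
    m2 <- m
    for (i in seq_len(nrow(masked)))
      m2[masked$p[i], gk == masked$g[i]] <- NA
    imp <- impute_proteome(proteome_matrix(m2), des, seed = 600 + s)
    mi <- log2(imp$matrix$intensities)
    errs <- vapply(seq_len(nrow(masked)), function(i) {
      cols <- gk == masked$g[i]
      iv <- mi[masked$p[i], cols]
      if (all(is.na(iv))) return(NA_real_)
      mean(iv) - mean(log2(m[masked$p[i], cols]))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(abs(biases)), 0.2)
})

test_that("Dunnett reduces to the pooled t-test with one comparison", {
  des <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 3L)
  pm <- make_proteome(des, n_prot = 25L, seed = 11)
  dt <- dunnett_test(pm, des)
  m <- log2(pm$intensities)
  tt <- vapply(seq_len(25), function(i)
    t.test(m[i, 4:6], m[i, 1:3], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(dt$p_adj, tt, tolerance = 1e-10)
})

test_that("Dunnett quadrature agrees with the multcomp reference", {
  skip_if_not_installed("multcomp")
  set.seed(1)
  g <- 8L; n <- 3L
  y <- rnorm((g + 1L) * n)
  grp <- factor(rep(0:g, each = n))
  fit <- aov(y ~ grp)
  mc <- summary(
    multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")),
    test = multcomp::adjusted("single-step"))
  means <- tapply(y, grp, mean)
  s2 <- sum(resid(fit)^2) / fit$df.residual
  tv <- (means[-1L] - means[1L]) / sqrt(s2 * 2 / n)
  own <- heatomics:::dunnett_padj_vec(as.vector(tv), g, fit$df.residual)
  # multcomp itself is Monte-Carlo based with ~1e-4 tolerance
  expect_equal(as.vector(own), as.vector(mc$test$pvalues),
               tolerance = 1e-3)
})

test_that("Dunnett adjusted p dominates the raw t-test p", {
  des <- make_design(c("pre_heat", "heat", "heat", "recovery"),
                     c(0, 1, 8, 2), n_rep = 3L)
  pm <- make_proteome(des, n_prot = 40L, seed = 12)
  dt <- dunnett_test(pm, des)
  # unadjusted p for the same model t statistic (pooled ANOVA variance)
  df_resid <- nrow(des) - 4L
  raw <- 2 * pt(-abs(dt$t), df_resid)
  expect_true(all(dt$p_adj >= raw - 1e-9))
})

test_that("Dunnett excludes ambiguous and incompletely observed proteins", {
  des <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 3L)
  pm <- make_proteome(des, n_prot = 10L, seed = 13)
  pm$proteotypic[1] <- FALSE
  pm$intensities[2, 1] <- NA
  dt <- dunnett_test(pm, des)
  expect_false(any(dt$protein_id %in% rownames(pm$intensities)[1:2]))
  # < 2 control replicates is an error
  des1 <- tc_design(des[des$phase == "heat" | des$replicate == 1L, ])
  pm1 <- proteome_matrix(pm$intensities[, des1$sample_id])
  expect_error(dunnett_test(pm1, des1), "control")
})

test_that("unbalanced layouts use the seeded Monte-Carlo fallback", {
  des <- make_design(c("pre_heat", "heat", "heat"), c(0, 1, 8), n_rep = 3L)
  des_u <- tc_design(des[-4L, ])  # drop one replicate of heat 1
  pm <- make_proteome(des, n_prot = 15L, seed = 14)
  pm_u <- proteome_matrix(pm$intensities[, des_u$sample_id])
  dt1 <- dunnett_test(pm_u, des_u, seed = 7L)
  dt2 <- dunnett_test(pm_u, des_u, seed = 7L)
  expect_equal(dt1$p_adj, dt2$p_adj)  # seeded reproducibility
  expect_true(all(dt1$p_adj >= 0 & dt1$p_adj <= 1))
  # adjusted p still dominates the single-comparison p of the model t
  df_resid <- nrow(des_u) - 3L
  raw <- 2 * pt(-abs(dt1$t), df_resid)
  expect_true(all(dt1$p_adj >= raw - 0.02))
})
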