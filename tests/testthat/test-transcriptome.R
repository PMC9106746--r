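test_that("read-support filter applies the 10-reads-in-10% rule", {
  # 5-gene toy over 10 samples: 9 everywhere / 10 once / 10 in 10% /
  # zeros / high -> 3 survive
  counts <- rbind(
    g_nine  = rep(9L, 10),
    g_once  = c(10L, rep(0L, 9)),
    g_tenth = c(10L, rep(9L, 9)),
    g_zero  = rep(0L, 10),
    g_high  = rep(1000L, 10))
  colnames(counts) <- sprintf("s%02d", 1:10)
  em <- expr_matrix(counts, setNames(rep(1000, 5), rownames(counts)))
  kept <- filter_genes(em)
  expect_setequal(rownames(kept$counts), c("g_once", "g_tenth", "g_high"))
  # boundary: ceil(0.1 * 10) = 1 sample suffices
  expect_true("g_once" %in% rownames(kept$counts))
  expect_warning(filter_genes(em, min_reads = 1e9), "no genes")
})

test_that("TPM normalizes length-scaled rates to one million", {
  em1 <- expr_matrix(matrix(50L, 1, 1, dimnames = list("g", "s")),
                     c(g = 500))
  expect_equal(unname(compute_tpm(em1)[1, 1]), 1e6)
  em2 <- expr_matrix(matrix(c(10L, 30L), 2,
                            dimnames = list(c("a", "b"), "s")),
                     c(a = 1000, b = 2000))
  expect_equal(unname(compute_tpm(em2)[, 1]), c(4e5, 6e5))
  set.seed(1)
  cm <- matrix(rpois(60, 40), 6,
               dimnames = list(letters[1:6], sprintf("s%d", 1:10)))
  storage.mode(cm) <- "integer"
  em3 <- expr_matrix(cm, setNames(runif(6, 400, 4000), letters[1:6]))
  expect_equal(unname(colSums(compute_tpm(em3))), rep(1e6, 10),
               tolerance = 1e-9)
  zero <- expr_matrix(matrix(c(1L, 0L), 1, 2,
                             dimnames = list("g", c("ok", "bad"))),
                      c(g = 100))
  expect_error(compute_tpm(zero), "bad")
})

test_that("planted fold-change genes are called significant", {
  # 4-fold gene at low abundance (TPM ~50 scale), phi = 0.05, n = 3
  set.seed(21)
  n_bg <- 200L
  des <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 3L)
  mu <- matrix(1000, n_bg + 1L, 6)
  mu[n_bg + 1L, ] <- c(10, 10, 10, 40, 40, 40)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05),
                   nrow(mu),
                   dimnames = list(c(sprintf("bg%03d", 1:n_bg), "planted"),
                                   des$sample_id))
  storage.mode(counts) <- "integer"
  em <- expr_matrix(counts, setNames(rep(1000, nrow(counts)),
                                     rownames(counts)))
  degs <- differential_expression(em, des)
  rec <- degs[degs$gene_id == "planted", ]
  expect_true(rec$significant)
  expect_gt(abs(rec$log2fc), 1)
  expect_lt(rec$fdr, 0.05)
})

test_that("DEG flag follows all three criteria and ignores gene order", {
  rec <- sim_recipe(seed = 31, n_genes = 600, n_proteins = 1)
  sim <- simulate_omics(rec, default_design("heat35", 3))
  em <- filter_genes(sim$expression)
  degs <- differential_expression(em, sim$design)
  expect_equal(degs$significant,
               abs(degs$log2fc) > 1 & degs$fdr < 0.05 &
                 abs(degs$tpm_ctrl - degs$tpm_trt) >= 1)
  # permuting genes and samples leaves per-gene flags unchanged
  perm <- expr_matrix(em$counts[rev(seq_len(nrow(em$counts))),
                                sample(ncol(em$counts))],
                      em$gene_length)
  degs2 <- differential_expression(perm, sim$design)
  key <- function(d) d[order(d$gene_id, d$phase, d$time_h), ]
  expect_equal(key(degs2)$significant, key(degs)$significant)
  expect_equal(key(degs2)$log2fc, key(degs)$log2fc, tolerance = 1e-10)
})

test_that("contrasts with too few replicates are skipped with a warning", {
  des <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 3L)
  des1 <- tc_design(des[des$phase == "pre_heat" | des$replicate == 1L, ])
  counts <- matrix(50L, 5, nrow(des1),
                   dimnames = list(letters[1:5], des1$sample_id))
  em <- expr_matrix(counts, setNames(rep(1000, 5), letters[1:5]))
  expect_warning(degs <- differential_expression(em, des1), "skipped")
  expect_equal(nrow(degs), 0L)
})

test_that("DEG set algebra splits by sign and treatment", {
  mk <- function(ids_up, ids_down, trt) data.frame(
    gene_id = c(ids_up, ids_down), treatment = trt, phase = "heat",
    time_h = 1, log2fc = c(rep(2, length(ids_up)),
                           rep(-2, length(ids_down))),
    p = 0.001, fdr = 0.001, tpm_ctrl = 10, tpm_trt = 40,
    significant = TRUE)
  d35 <- mk(c("a", "b", "c"), "x", "heat35")
  d40 <- mk(c("b", "c", "d", "e"), "x", "heat40")
  s <- deg_sets(d35, d40)
  up <- s[s$direction == "up", ]
  expect_equal(up$overlap, 2L)
  expect_equal(up$unique_35, 1L)
  expect_equal(up$unique_40, 2L)
  down <- s[s$direction == "down", ]
  expect_equal(c(down$overlap, down$unique_35, down$unique_40),
               c(1L, 0L, 0L))
  # identical lists -> no unique genes; disjoint lists -> no overlap
  s_same <- deg_sets(d35, d35)
  expect_true(all(s_same[s_same$direction == "up", c("unique_35",
                                                     "unique_40")] == 0))
  d_disj <- mk(c("q", "r"), character(0), "heat40")
  s_disj <- deg_sets(mk(c("a"), character(0), "heat35"), d_disj)
  expect_equal(s_disj[s_disj$direction == "up", "overlap"], 0L)
})

test_that("surprisal decomposition recovers planted temporal patterns", {
  des <- make_design(c("pre_heat", rep("heat", 7), rep("recovery", 4)),
                     c(0, 0.5, 1, 2, 4, 8, 16, 24, 0, 2, 4, 8),
                     n_rep = 1L)
  n_t <- 12L
  set.seed(8)
  pats <- qr.Q(qr(matrix(rnorm(n_t * 3), n_t, 3)))
  weights <- matrix(rnorm(300 * 3), 300, 3)
  lnx <- 5 + weights %*% t(pats) + matrix(rnorm(300 * n_t, 0, 0.01),
                                          300, n_t)
  tpm <- exp(lnx) - 1
  dimnames(tpm) <- list(sprintf("g%03d", 1:300), des$sample_id)
  sa <- surprisal_analysis(tpm, des, "heat35")
  expect_equal(rownames(sa$lambda)[1], "alpha0")
  expect_true(all(diff(sa$var_fraction) <= 1e-12))
  # 3 retained constraints capture >= 95% of post-baseline variance
  d2 <- sa$svd$d^2
  expect_gte(sum(d2[2:4]) / sum(d2[-1]), 0.95)
  # reconstruction error non-increasing in retained components
  errs <- vapply(1:5, surprisal_reconstruction_error, numeric(1),
                 sd_obj = sa)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("rank-1 input puts all variance in the baseline component", {
  des <- make_design(c("pre_heat", rep("heat", 4)), c(0, 1, 2, 4, 8),
                     n_rep = 1L)
  prof <- exp(outer(runif(50, 1, 3), rep(1, 5))) - 1
  dimnames(prof) <- list(sprintf("g%02d", 1:50), des$sample_id)
  sa <- surprisal_analysis(prof, des, "heat35")
  expect_gt(sa$var_fraction[1], 0.999)
  expect_lt(max(abs(sa$lambda["alpha1", ])) / max(abs(sa$lambda["alpha0", ])),
            1e-3)
  des3 <- make_design(c("pre_heat", "heat"), c(0, 1), n_rep = 1L)
  expect_error(surprisal_analysis(prof[, 1:2], des3, "heat35"),
               "4 time points")
})

test_that("BH adjustment matches the brute-force step-up on random input", {
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p),
                 tolerance = 1e-12)
  }
})
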