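test_that("omics simulation is deterministic given the recipe seed", {
  rec <- sim_recipe(seed = 5L, n_genes = 150, n_proteins = 60,
                    n_terms = 8, genes_per_term = 15)
  des <- default_design("heat35", 2)
  a <- simulate_omics(rec, des)
  b <- simulate_omics(rec, des)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$proteome$intensities, b$proteome$intensities)
  expect_identical(a$truth$missing_mechanism, b$truth$missing_mechanism)
  c2 <- simulate_omics(sim_recipe(seed = 6L, n_genes = 150,
                                  n_proteins = 60, n_terms = 8,
                                  genes_per_term = 15), des)
  expect_false(identical(a$expression$counts, c2$expression$counts))
})

test_that("simulated structure matches the recipe contract", {
  rec <- sim_recipe(seed = 9L, n_genes = 200, n_proteins = 100)
  sim <- simulate_omics(rec, default_design(c("heat35", "heat40"), 3))
  expect_equal(dim(sim$expression$counts), c(200L, 90L))
  # archetype truth: every gene at most one archetype
  expect_equal(nrow(sim$truth$gene_archetype), 200L)
  # observed intensities strictly positive; missingness applied
  mm <- missing_mask(sim$proteome)
  expect_true(all(sim$proteome$intensities[mm] > 0))
  expect_gt(mean(!mm), 0)
  # ambiguous groups flagged non-proteotypic
  amb <- grepl(";", rownames(sim$proteome$intensities))
  expect_true(all(!sim$proteome$proteotypic[amb]))
  # invalid recipes rejected
  expect_error(sim_recipe(rho_heat = 1.5), "rho")
  expect_error(sim_recipe(n_proteins = 300, n_genes = 200))
})

test_that("archetypes missing a design time point are rejected", {
  arch <- list(bad = list(fraction = 0.1,
                          profile = c(pre_heat_0h = 0, heat_1h = 2)))
  rec <- sim_recipe(seed = 1L, n_genes = 50, n_proteins = 10,
                    archetypes = arch)
  expect_error(simulate_omics(rec, default_design("heat35", 2)),
               "lacks time point")
})

test_that("planted 4-fold genes are recoverable with >= 80% power", {
  rec <- sim_recipe(seed = 13, n_genes = 800, n_proteins = 1,
                    nb_dispersion = 0.1)
  sim <- simulate_omics(rec, default_design("heat35", 3))
  em <- filter_genes(sim$expression)
  degs <- differential_expression(em, sim$design)
  truth <- sim$truth$gene_archetype
  # heat_early genes carry |log2FC| = 2 at heat 0.5 and 1 h
  early <- truth$gene_id[truth$archetype == "heat_early"]
  hit <- degs[degs$phase == "heat" & degs$time_h == 0.5 &
                degs$gene_id %in% early, "significant"]
  expect_gte(mean(hit), 0.8)
})

test_that("OD sawtooth has the closed-form dilution cycle", {
  tr <- simulate_od_trace(4, target_od = 0.4, band = 0.08,
                          duration_h = 12, dt_h = 0.005)
  segs <- detect_cycles(tr)
  # noise-free: slope recovers 1/doubling exactly
  expect_equal(segs$slope, rep(0.25, nrow(segs)), tolerance = 1e-9)
  expect_equal(segs$doubling_h, rep(4, nrow(segs)), tolerance = 1e-9)
  # inter-dilution interval ~ Td * log2(1.08/0.92) = 0.925 h
  full <- segs[-nrow(segs), ]
  expect_equal(mean(full$end_h - full$start_h), 4 * log2(1.08 / 0.92),
               tolerance = 0.02)
  # trace bounded by the turbidostat band
  expect_lte(max(tr$y), 0.4 * 1.08 * 1.0001)
  expect_gte(min(tr$y), 0.4 * 0.92 * 0.9999)
  # duration shorter than a cycle: one monotone segment, no dilutions
  short <- simulate_od_trace(4, duration_h = 0.5)
  expect_equal(nrow(detect_cycles(short)), 1L)
  expect_error(simulate_od_trace(4, band = 1.2), "band")
  expect_error(simulate_od_trace(-1), "doubling")
})

test_that("kinetic trace generators realize their stated models", {
  # p700 noise-free: fit recovers tau exactly
  p7 <- simulate_kinetics("p700", list(amplitude = 1, tau = 0.5,
                                       offset = 0.2))
  fit <- p700_tau(p7)
  expect_equal(fit$tau, 0.5, tolerance = 1e-7)
  expect_equal(fit$amplitude, 1, tolerance = 1e-7)
  # spectrum with equal peak heights -> PSII% ~ 50
  sp <- simulate_kinetics("spectrum77k",
                          list(h686 = 1, h714 = 1, w686 = 4, w714 = 4))
  expect_equal(psii_fraction_77k(sp)$psii_percent, 50, tolerance = 0.5)
  # fluorescence levels echoed in meta and realized in the trace
  fl <- simulate_kinetics("fluorescence",
                          list(fo = 0.2, fm = 1, fs = 0.4,
                               fm_prime = 0.8, fo_prime = 0.18))
  expect_setequal(unique(fl$y), c(0.2, 1, 0.4, 0.8, 0.18))
  expect_error(simulate_kinetics("p700", list(amplitude = 1, tau = -1,
                                              offset = 0)), "tau")
  # determinism
  e1 <- simulate_kinetics("ecs", list(ecst = 1, tau = 0.02),
                          noise_sd = 0.05, seed = 3)
  e2 <- simulate_kinetics("ecs", list(ecst = 1, tau = 0.02),
                          noise_sd = 0.05, seed = 3)
  expect_identical(e1$y, e2$y)
})

test_that("ECS tau is recovered within 5% under 5% noise (median)", {
  taus <- vapply(1:100, function(s) {
    tr <- simulate_kinetics("ecs", list(ecst = 1, tau = 0.02),
                            noise_sd = 0.05, seed = s)
    dirk_ecs(tr)$tau
  }, numeric(1))
  expect_lt(median(abs(taus - 0.02) / 0.02), 0.05)
})

test_that("FACS histograms place peaks at background + ploidy * unit", {
  # cv -> 0: single sharp peak at background + unit
  h1 <- simulate_facs(c("1C" = 1), unit_signal = 2.5e5,
                      background = 0.5e5, cv = 1e-4, seed = 2)
  pk <- find_peaks(h1)
  expect_equal(pk$position[which.max(pk$height)], 3e5, tolerance = 0.01)
  # three populations near 3e5 / 5.5e5 / 10.5e5
  h3 <- simulate_facs(c("1C" = 0.5, "2C" = 0.3, "4C" = 0.2),
                      unit_signal = 2.5e5, background = 0.5e5,
                      cv = 0.05, seed = 3)
  pk3 <- find_peaks(h3, min_prominence = 0.02)
  top3 <- sort(pk3$position[order(-pk3$prominence)][1:3])
  expect_equal(top3, c(3e5, 5.5e5, 10.5e5), tolerance = 0.06)
  # reproducibility and validation
  expect_identical(simulate_facs(c("1C" = 1), 1e5, 0, seed = 9)$y,
                   simulate_facs(c("1C" = 1), 1e5, 0, seed = 9)$y)
  expect_error(simulate_facs(c("1C" = 1), 1e5, -1), "background")
  expect_error(simulate_facs(c("3C" = 1), 1e5, 0), "ploidies")
  expect_error(simulate_facs(c("1C" = 0.7), 1e5, 0), "sum to 1")
})

test_that("absorbance inversion round-trips the pigment equations", {
  ab <- simulate_absorbance(12.02, 1.75)
  expect_equal(ab$a652, 0.5, tolerance = 1e-9)
  expect_equal(ab$a665, 1.0, tolerance = 1e-9)
  expect_equal(unlist(simulate_absorbance(0, 0, 0)),
               c(a470 = 0, a652 = 0, a665 = 0))
  set.seed(66)
  for (i in 1:100) {
    chl_a <- runif(1, 0, 30); chl_b <- runif(1, 0, 15)
    car <- runif(1, 0, 10)
    ab <- simulate_absorbance(chl_a, chl_b, car)
    res <- pigments(ab$a470, ab$a652, ab$a665)
    expect_equal(res$chl_a, chl_a, tolerance = 1e-9)
    expect_equal(res$chl_b, chl_b, tolerance = 1e-9)
    expect_equal(res$carotenoids, car, tolerance = 1e-9)
  }
})
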