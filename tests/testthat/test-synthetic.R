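test_that("the generator is deterministic under the seed and varies across seeds", {
  cfg <- generator_config(seed = 7, module_sizes = c(30L, 30L, 20L))
  d1 <- generate_dossier(cfg)
  d2 <- generate_dossier(cfg)
  expect_identical(d1$fingerprints, d2$fingerprints)
  expect_identical(as.data.frame(d1$acute_studies),
                   as.data.frame(d2$acute_studies))
  expect_identical(as.data.frame(d1$repeated_studies),
                   as.data.frame(d2$repeated_studies))
  expect_identical(d1$hazards, d2$hazards)
  expect_identical(d1$descriptors, d2$descriptors)

  d3 <- generate_dossier(generator_config(seed = 8,
                                          module_sizes = c(30L, 30L, 20L)))
  expect_false(identical(d1$fingerprints, d3$fingerprints))
})

test_that("generated tables satisfy every dossier schema invariant", {
  d <- generate_dossier(generator_config(seed = 2,
                                         module_sizes = c(40L, 30L, 30L)))
  expect_s3_class(as_study_table(as.data.frame(d$acute_studies)),
                  "study_table")
  expect_s3_class(as_study_table(as.data.frame(d$repeated_studies)),
                  "study_table")
  expect_true(all(d$acute_studies$value > 0))
  ## every substance has a Klimisch-1 key acute study
  key1 <- tapply(d$acute_studies$klimisch == 1L & d$acute_studies$key_study,
                 d$acute_studies$substance_id, any)
  expect_true(all(key1))
  ## fingerprint round trip through the interchange file
  dir <- withr::local_tempdir()
  write_dossier(d, dir)
  expect_identical(read_fingerprints(file.path(dir, "fingerprints.fp")),
                   d$fingerprints)
  expect_equal(nrow(read_study_table(file.path(dir, "studies.csv"))),
               nrow(d$acute_studies) + nrow(d$repeated_studies))
})

test_that("within-module similarity hits its target and 1.0 means clones", {
  cfg <- generator_config(seed = 4, module_sizes = c(25L, 25L),
                          within_module_similarity = 1)
  g <- generate_fingerprints(cfg)
  s <- tanimoto_matrix(g$fingerprints)
  within0 <- s[g$substances$module == 0, g$substances$module == 0]
  expect_true(all(within0 == 1))

  cfg2 <- generator_config(seed = 4, module_sizes = c(60L, 60L),
                           within_module_similarity = 0.8)
  g2 <- generate_fingerprints(cfg2)
  s2 <- tanimoto_matrix(g2$fingerprints)
  m0 <- g2$substances$module == 0
  within_mean <- mean(s2[m0, m0][upper.tri(s2[m0, m0])])
  expect_equal(within_mean, 0.8, tolerance = 0.05)
  expect_lt(mean(s2[m0, !m0]), 0.7)

  expect_error(generate_fingerprints(
    generator_config(within_module_similarity = 0.2)), "not achievable")
})

test_that("toxicity follows modules exactly at full clustering strength", {
  cfg <- generator_config(seed = 6, module_sizes = rep(40L, 5),
                          clustering_strength = 1)
  g <- generate_fingerprints(cfg)
  per_module <- tapply(g$substances$toxic, g$substances$module, mean)
  expect_true(all(per_module %in% c(0, 1)))
})

test_that("zero clustering strength decouples toxicity from modules", {
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- generator_config(seed = 400 + seed, module_sizes = rep(110L, 9),
                            clustering_strength = 0)
    g <- generate_fingerprints(cfg)
    p <- suppressWarnings(
      stats::chisq.test(table(g$substances$module,
                              g$substances$toxic))$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  ## under independence, about 0.2 rejections expected at alpha = 0.01
  expect_lte(rejections, 2L)
})

test_that("realized prevalence tracks the 268/1059 target", {
  fracs <- vapply(1:5, function(seed) {
    d <- generate_fingerprints(generator_config(seed = seed))
    mean(d$toxicated <- d$substances$toxic)
  }, numeric(1))
  expect_true(all(abs(fracs - 268 / 1059) < 0.02))
  ## and the aggregated study labels agree with the latent classes
  cfg <- generator_config(seed = 9)
  fps <- generate_fingerprints(cfg)
  st <- generate_acute_studies(fps$substances, cfg)
  agg <- aggregate_endpoints(st, endpoint = "acute_oral")
  lab <- label_toxicant(agg)[match(fps$substances$substance_id,
                                   agg$substance_id)]
  expect_identical(lab, fps$substances$toxic)
})

test_that("acute values pile up on the guideline dose grids", {
  cfg <- generator_config(seed = 12, module_sizes = rep(120L, 9),
                          p_snap = 0.5)
  fps <- generate_fingerprints(cfg)
  st <- generate_acute_studies(fps$substances, cfg)
  at2000 <- mean(st$value == 2000)
  at5000 <- mean(st$value == 5000)
  expect_gt(at2000, 0.15)                 # visible pile-up at the limit dose
  expect_gt(at5000, 0.02)
  ## censored pile-ups carry their qualifier
  expect_true(all(st$qualifier[st$value == 5000] == "greater_equal"))
  ## grids are config, not code: without snapping the pile-up collapses to
  ## the residual threshold clip
  cfg0 <- generator_config(seed = 12, module_sizes = rep(120L, 9), p_snap = 0)
  st0 <- generate_acute_studies(generate_fingerprints(cfg0)$substances, cfg0)
  expect_gt(at2000, mean(st0$value == 2000) + 0.1)
  expect_lt(mean(st0$value == 5000), 0.001)
})

test_that("perfect NOAEL correlation with no shift duplicates the pairs", {
  cfg <- generator_config(seed = 3, module_sizes = c(50L, 50L),
                          noael_correlation = 1, noael_shift_log10 = 0,
                          discordant_fraction = 0, noael_limit_fraction = 0,
                          p_28d = 1, p_90d_given_28d = 1)
  st <- generate_repeated_dose_studies(generate_fingerprints(cfg)$substances,
                                       cfg)
  pairs <- matched_noael_pairs(st)
  expect_equal(pairs$noael_90d, pairs$noael_28d, tolerance = 1e-12)
})

test_that("discordant pairs appear at the configured rate and factor", {
  cfg <- generator_config(seed = 14, module_sizes = rep(110L, 9),
                          discordant_fraction = 0.05, discordant_factor = 5,
                          noael_limit_fraction = 0, p_28d = 1,
                          p_90d_given_28d = 1)
  st <- generate_repeated_dose_studies(generate_fingerprints(cfg)$substances,
                                       cfg)
  pairs <- matched_noael_pairs(st)
  hits <- abs(log10(pairs$noael_90d / pairs$noael_28d) - log10(5)) < 1e-9
  n <- nrow(pairs)
  expect_lt(abs(sum(hits) - 0.05 * n), 4 * sqrt(n * 0.05 * 0.95))
})

test_that("the NOAEL/LD50 coupling realises the configured NPV", {
  cfg <- generator_config(seed = 11, module_sizes = rep(560L, 9),
                          p_28d = 1, p_90d_given_28d = 1)
  fps <- generate_fingerprints(cfg)
  all_st <- rbind(as.data.frame(generate_acute_studies(fps$substances, cfg)),
                  as.data.frame(generate_repeated_dose_studies(fps$substances,
                                                               cfg)))
  b <- bulgheroni_table(all_st, study_scope = "all")
  expect_gt(b$n, 4500)
  expect_equal(b$npv / 100, cfg$bulgheroni_npv, tolerance = 0.021)
})

test_that("hazard flags follow the LD50 bands with configured noise rates", {
  cfg <- generator_config(seed = 5, module_sizes = rep(100L, 5),
                          data_lacking_rate = 0, inconclusive_rate = 0)
  fps <- generate_fingerprints(cfg)
  st <- generate_acute_studies(fps$substances, cfg)
  agg <- aggregate_endpoints(st, endpoint = "acute_oral")
  v <- setNames(agg$mean_value, agg$substance_id)
  hz <- generate_hazard_flags(fps$substances, v, cfg)
  vv <- v[hz$substance_id]
  expect_identical(hz$H302 == "positive", unname(vv >= 300 & vv < 2000))
  expect_identical(hz$H301 == "positive", unname(vv >= 50 & vv < 300))
  ## with nonzero rates, some records become non-conclusive
  cfg2 <- generator_config(seed = 5, module_sizes = rep(100L, 5),
                           data_lacking_rate = 0.2)
  hz2 <- generate_hazard_flags(fps$substances, v, cfg2)
  expect_equal(mean(hz2$H302 == "data_lacking"), 0.2, tolerance = 0.06)
})
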