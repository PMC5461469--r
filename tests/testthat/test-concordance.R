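test_that("hazard prevalence reproduces the published count arithmetic", {
  hz <- make_hazards(list(H301 = c(225, 5518, 272, 12),
                          H302 = c(1072, 4677, 266, 12)))
  prev <- hazard_prevalence(hz)
  ## 1072 / (1072 + 4677) = 18.6467%; the published summary says 18.7%,
  ## a one-ulp rounding inconsistency in the source counts
  expect_equal(prev$pct_positive[prev$hazard == "H302"], 18.6)
  expect_equal(prev$pct_positive[prev$hazard == "H301"], 3.9)

  ## zero positives and zero conclusive records
  hz2 <- make_hazards(list(H300 = c(0, 50, 0, 0), H303 = c(0, 0, 40, 10)))
  prev2 <- hazard_prevalence(hz2)
  expect_equal(prev2$pct_positive[prev2$hazard == "H300"], 0)
  expect_true(is.na(prev2$pct_positive[prev2$hazard == "H303"]))
})

test_that("the non-toxic complement subtracts the rounded oral percentages", {
  hz <- make_hazards(list(H300 = c(33, 5709, 237, 12),
                          H301 = c(225, 5518, 272, 12),
                          H302 = c(1072, 4677, 266, 12),
                          H303 = c(23, 5720, 272, 12)))
  prev <- hazard_prevalence(hz)
  ## 100 - (0.6 + 3.9 + 18.6 + 0.4); differs from the published 76.4 only
  ## through the H302 rounding inconsistency noted above
  expect_equal(nontoxic_complement(prev), 76.5)
})

test_that("guideline agreement follows the shared-threshold rule", {
  st <- rbind(
    make_studies(1500, substance_id = "A", guideline = "TG401"),
    make_studies(1800, substance_id = "A", guideline = "TG423"),
    make_studies(1500, substance_id = "B", guideline = "TG401"),
    make_studies(2500, substance_id = "B", guideline = "TG420"),
    make_studies(c(2200, 2800), substance_id = "C", guideline = "TG425"))
  am <- guideline_agreement(st)
  expect_equal(am$percent["TG401", "TG423"], 100)   # both toxic
  expect_equal(am$n["TG401", "TG423"], 1L)
  expect_equal(am$percent["TG401", "TG420"], 0)     # classes differ
  expect_equal(am$percent["TG425", "TG425"], 100)   # self-consistent repeats
  expect_equal(am$n["TG425", "TG425"], 1L)
  ## symmetry and range
  expect_identical(am$percent, t(am$percent))
  expect_identical(am$n, t(am$n))
  ok <- am$percent[!is.na(am$percent)]
  expect_true(all(ok >= 0 & ok <= 100))
})

test_that("the 28-day NOAEL contingency rule reports NPV, PPV and savings", {
  ## any-study counts: NPV 94.5%, PPV 33.7%
  grey <- bulgheroni_from_pairs(
    noael_28d = c(rep(100, 660 + 1301), rep(500, 183 + 3126)),
    ld50 = c(rep(100, 660), rep(3000, 1301), rep(100, 183), rep(3000, 3126)))
  expect_equal(unname(grey$table[1, ]), c(660, 1301))
  expect_equal(unname(grey$table[2, ]), c(183, 3126))
  expect_equal(grey$npv, 94.5)
  expect_equal(grey$ppv, 33.7)

  ## key-study counts: 928 avoidable acute studies
  white <- bulgheroni_from_pairs(
    noael_28d = c(rep(100, 237 + 411), rep(500, 49 + 928)),
    ld50 = c(rep(100, 237), rep(3000, 411), rep(100, 49), rep(3000, 928)))
  expect_equal(white$avoidable_count, 928)
  expect_equal(white$n, 1625)

  ## degenerate: all predictions positive and correct
  all_pos <- bulgheroni_from_pairs(rep(100, 5), rep(100, 5))
  expect_equal(all_pos$ppv, 100)
  expect_true(is.na(all_pos$npv))
  expect_error(bulgheroni_from_pairs(numeric(), numeric()), "no matched")
})

test_that("study-scope tabulation matches a brute-force recount", {
  cfg <- generator_config(seed = 23, module_sizes = rep(60L, 5))
  d <- generate_dossier(cfg)
  all_st <- rbind(as.data.frame(d$acute_studies),
                  as.data.frame(d$repeated_studies))
  for (scope in c("all", "key_only")) {
    b <- bulgheroni_table(all_st, study_scope = scope)
    ## oracle recount straight from the raw study rows
    acute <- all_st[all_st$endpoint == "acute_oral", ]
    if (scope == "key_only")
      acute <- acute[acute$key_study & !acute$read_across, ]
    ld50 <- tapply(acute$value, acute$substance_id, mean)
    n28 <- all_st[all_st$endpoint == "repeated_28d", ]
    noael <- tapply(n28$value, n28$substance_id, mean)
    common <- intersect(names(ld50), names(noael))
    lo <- noael[common] <= 200; tox <- ld50[common] < 2000
    expect_equal(unname(b$table[2, 2]), sum(!lo & !tox))
    expect_equal(b$n, length(common))             # conservation
    expect_equal(b$npv, round(100 * sum(!lo & !tox) / sum(!lo), 1))
    expect_equal(b$ppv, round(100 * sum(lo & tox) / sum(lo), 1))
  }
})

test_that("the Taylor filter applies reliability and hazard constraints", {
  st <- rbind(
    make_studies(1500, substance_id = "K3", endpoint = "repeated_28d",
                 guideline = "TG407", klimisch = 3L),
    make_studies(1500, substance_id = "OK", endpoint = "repeated_28d",
                 guideline = "TG407", klimisch = 1L),
    make_studies(500, substance_id = "HAZ", endpoint = "repeated_28d",
                 guideline = "TG407", klimisch = 1L))
  hz <- data.frame(substance_id = c("K3", "OK", "HAZ"),
                   H301 = c("negative", "negative", "positive"),
                   H302 = c("negative", "negative", "negative"),
                   stringsAsFactors = FALSE)
  out <- taylor_filter(st, hz)
  expect_identical(out$substance_id, "OK")        # Klimisch 3 and H301+ excluded
  expect_true(out$high_28d)                       # 1,500 >= 1,000 flag
})

test_that("28-to-90-day predictivity conditions strictly on the threshold", {
  pairs <- data.frame(substance_id = c("A", "B", "C", "D"),
                      noael_28d = c(1000, 1200, 999, 2000),
                      noael_90d = c(1000, 800, 1500, 2000))
  tp <- taylor_predictivity(pairs)
  ## C is excluded (28d below threshold); of A, B, D two have high 90d
  expect_equal(tp$n_high28[tp$set == "full"], 3)
  expect_equal(tp$pct_high90_given_high28[tp$set == "full"], 66.7)

  same <- data.frame(substance_id = c("A", "B"), noael_28d = c(1500, 1200),
                     noael_90d = c(1500, 1200))
  expect_equal(taylor_predictivity(same)$pct_high90_given_high28, 100)

  cons <- taylor_predictivity(pairs, constrained = c("A", "B"))
  expect_equal(cons$n_high28[cons$set == "constrained"], 2)
})

test_that("generator concordance sits near the tuned 70% at scale", {
  pct <- vapply(1:3, function(seed) {
    cfg <- generator_config(seed = 40 + seed, module_sizes = rep(250L, 9),
                            p_28d = 1, p_90d_given_28d = 1)
    st <- generate_repeated_dose_studies(
      generate_fingerprints(cfg)$substances, cfg)
    taylor_predictivity(matched_noael_pairs(st))$pct_high90_given_high28
  }, numeric(1))
  expect_lt(abs(mean(pct) - 70), 3)
})

test_that("the factor-3 DNEL check counts strict violations only", {
  pairs <- data.frame(substance_id = sprintf("P%03d", 1:133),
                      noael_28d = rep(300, 133),
                      noael_90d = c(rep(50, 11), rep(150, 122)))
  out <- factor3_check(pairs)
  expect_equal(out$n_pairs, 133)
  expect_equal(out$n_below_one_third, 11)
  expect_equal(out$pct_within, 91.7)
  ## exactly one third is within, not below
  edge <- factor3_check(data.frame(substance_id = "X", noael_28d = 300,
                                   noael_90d = 100))
  expect_equal(edge$n_below_one_third, 0)
  expect_error(factor3_check(data.frame(substance_id = character(),
                                        noael_28d = numeric(),
                                        noael_90d = numeric())),
               "no matched")
})
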