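test_that("ranking sorts by orientation-adjusted score with stable ties", {
  tb <- score_table(c("a", "d1", "d2"), c("active", "decoy", "decoy"),
                    list(s = c(3, 2, 1)))
  expect_equal(rank_compounds(tb, "s", "higher")$compound_id,
               c("a", "d1", "d2"))
  expect_equal(rank_compounds(tb, "s", "lower")$compound_id,
               c("d2", "d1", "a"))
  # ties keep input order
  tb2 <- score_table(c("a", "d1", "d2"), c("active", "decoy", "decoy"),
                     list(s = c(2, 2, 2)))
  expect_equal(rank_compounds(tb2, "s")$compound_id, c("a", "d1", "d2"))
  # 303 random scores match a comparison-sort oracle
  tb3 <- random_score_table(300, 3, seed = 21)
  rk <- rank_compounds(tb3, "s", "higher")
  expect_equal(rk$compound_id, tb3$compound_id[order(-tb3$s)])
  expect_setequal(rk$compound_id, tb3$compound_id)
  # degenerate inputs refuse
  tb4 <- score_table(c("a", "d"), c("active", "decoy"), list(s = c(NA, 1)))
  expect_error(rank_compounds(tb4, "s"), "no scored active")
})

test_that("enrichment factor reproduces the printed worked examples", {
  # perfect screen, 303 compounds / 3 actives, top 10% (floor -> 30)
  tb <- gen_seeded_database(300, 3, delta = 10, seed = 4)
  ef <- enrichment_factor(rank_compounds(tb, "score"), 0.10)
  expect_equal(ef$NC_sel, 30L)
  expect_equal(ef$Hits_sel, 3L)
  expect_equal(ef$ef_reported, 10.1)
  # 271 compounds (top 27)
  tb2 <- gen_seeded_database(268, 3, delta = 10, seed = 4)
  ef2 <- enrichment_factor(rank_compounds(tb2, "score"), 0.10)
  expect_equal(ef2$NC_sel, 27L)
  expect_equal(ef2$ef_reported, 10.0)
  # 2 of 3 actives in the top 30 of 303
  set.seed(1)
  sc <- c(rnorm(300), 50, 50, -50)
  tb3 <- score_table(c(sprintf("d%03d", 1:300), "a1", "a2", "a3"),
                     c(rep("decoy", 300), rep("active", 3)), list(s = sc))
  ef3 <- enrichment_factor(rank_compounds(tb3, "s"), 0.10)
  expect_equal(ef3$Hits_sel, 2L)
  expect_equal(ef3$ef_reported, 6.7)
})

test_that("EF normalises to 1 at fraction 1 and never exceeds the ceiling", {
  for (seed in 1:5) {
    tb <- random_score_table(40, 4, seed)
    rk <- rank_compounds(tb, "s")
    expect_equal(enrichment_factor(rk, 1.0)$ef, 1.0)
    for (f in c(0.1, 0.25, 0.5)) {
      e <- enrichment_factor(rk, f)
      expect_lte(e$ef, e$ef_max + 1e-12)
      expect_gte(e$ef, 0)
    }
  }
  expect_error(enrichment_factor(rank_compounds(
    random_score_table(5, 1, 1), "s"), 0.01), "selection size is zero")
})

test_that("maximum EF matches the printed database ceilings", {
  expect_equal(max_enrichment_factor(303, 3)$reported, 101)
  expect_equal(max_enrichment_factor(271, 3)$reported, 90.3)
  expect_equal(max_enrichment_factor(17, 17)$reported, 1.0)
  expect_error(max_enrichment_factor(10, 0), "at least one active")
  expect_error(max_enrichment_factor(3, 5), "more actives")
})

test_that("concordance AUC matches brute-force pairwise counting", {
  tb <- score_table(c("a1", "a2", "d1", "d2"),
                    c("active", "active", "decoy", "decoy"),
                    list(s = c(3, 1, 2, 0)))
  roc <- roc_auc(rank_compounds(tb, "s"))
  expect_equal(roc$auc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(roc$auc, brute_auc(c(3, 1), c(2, 0)))
  # with ties
  tb2 <- score_table(letters[1:6],
                     c("active", "active", "active", "decoy", "decoy", "decoy"),
                     list(s = c(2, 1, 1, 1, 0, 2)))
  roc2 <- roc_auc(rank_compounds(tb2, "s"))
  expect_equal(roc2$auc, brute_auc(c(2, 1, 1), c(1, 0, 2)))
})

test_that("perfect separation gives AUC 1, zero SE, excellent band", {
  tb <- gen_seeded_database(50, 3, delta = 30, seed = 8)
  roc <- roc_auc(rank_compounds(tb, "score"))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$se, 0)
  expect_equal(roc$band, "excellent")
  expect_lt(roc$p_vs_half, 0.01)
  expect_equal(roc$stars, "**")
  expect_equal(roc$curve[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(roc$curve[nrow(roc$curve), ]), c(fpr = 1, tpr = 1))
  expect_error(rank_compounds(score_table("a", "active", list(s = 1)), "s"),
               "no scored decoy")
})

test_that("trapezoidal area equals concordance AUC on random instances", {
  set.seed(123)
  for (k in 1:1000) {
    n_a <- sample(1:5, 1)
    n_d <- sample(1:8, 1)
    # coarse grid forces plenty of ties
    sc <- sample(0:4, n_a + n_d, replace = TRUE)
    tb <- score_table(sprintf("c%02d", seq_len(n_a + n_d)),
                      c(rep("active", n_a), rep("decoy", n_d)),
                      list(s = sc))
    roc <- roc_auc(rank_compounds(tb, "s"))
    expect_equal(trapezoid_auc(roc$curve), roc$auc, tolerance = 1e-12)
    expect_true(all(diff(roc$curve$fpr) >= 0))
    expect_true(all(diff(roc$curve$tpr) >= 0))
  }
})

test_that("reversing orientation maps AUC to 1 - AUC when tie-free", {
  tb <- random_score_table(25, 5, seed = 31)
  hi <- roc_auc(rank_compounds(tb, "s", "higher"))
  lo <- roc_auc(rank_compounds(tb, "s", "lower"))
  expect_equal(hi$auc + lo$auc, 1)
})

test_that("null screens centre on AUC 0.5 and shifted screens on Phi(delta/sqrt(2))", {
  aucs0 <- vapply(1:200, function(s)
    roc_auc(rank_compounds(gen_seeded_database(60, 3, delta = 0, seed = s),
                           "score"))$auc, 0)
  se0 <- sd(aucs0) / sqrt(length(aucs0))
  expect_lt(abs(mean(aucs0) - 0.5), 3 * se0 + 1e-8)
  for (delta in c(1, 3)) {
    aucs <- vapply(1:200, function(s)
      roc_auc(rank_compounds(
        gen_seeded_database(300, 3, delta = delta, seed = 1000 + s),
        "score"))$auc, 0)
    target <- pnorm(delta / sqrt(2))
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - target), 3 * se)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (k in 1:25) {
    n_a <- sample(2:6, 1)
    n_d <- sample(5:40, 1)
    sc <- round(rnorm(n_a + n_d, c(rep(1, n_a), rep(0, n_d))), 1)
    lab <- c(rep("active", n_a), rep("decoy", n_d))
    tb <- score_table(sprintf("c%02d", seq_along(sc)), lab, list(s = sc))
    ours <- roc_auc(rank_compounds(tb, "s"))$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      lab == "active", sc, quiet = TRUE, direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("AUC quality bands follow the conventional cut-offs", {
  expect_equal(auc_band(0.95), "excellent")
  expect_equal(auc_band(0.9), "excellent")  # closed lower bound
  expect_equal(auc_band(0.85), "good")
  expect_equal(auc_band(0.75), "fair")
  expect_equal(auc_band(0.55), "poor")
  expect_equal(auc_band(0.34), "failure")
})

test_that("enrichment_report assembles EF, AUC, stars and band per combination", {
  tb <- gen_seeded_database(300, 3, delta = 10, seed = 2, combination = "PLP1")
  tb$LigScore1 <- rev(tb$PLP1)  # scrambled copy: near-null combination
  rep_ <- enrichment_report(tb, fraction = 0.10)
  expect_equal(rep_$combination, c("PLP1", "LigScore1"))
  plp <- rep_[rep_$combination == "PLP1", ]
  expect_equal(plp$ef, 10.1)
  expect_equal(plp$ef_max, 101)
  expect_equal(plp$auc, 1)
  expect_equal(plp$band, "excellent")
  expect_equal(plp$stars, "**")
})
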