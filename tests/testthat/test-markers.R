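test_that("monoisotopic masses agree with atomic-mass summation", {
  expect_equal(monoisotopic_mz("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mz("SO3"), 79.95682, tolerance = 1e-4)
  # the two printed anion compositions, within 2 ppm of the observed values
  m13 <- monoisotopic_mz("C50H81O26S", "anion_composition")
  expect_lt(abs(ppm_error(m13, 1129.4729)), 2)
  m9 <- monoisotopic_mz("C51H83O25S", "anion_composition")
  expect_lt(abs(ppm_error(m9, 1127.4939)), 2)
  # deprotonation vs anion composition differ by one H atom exactly
  expect_equal(monoisotopic_mz("C50H82O26S", "anion_deprotonated"), m13,
               tolerance = 1e-9)
})

test_that("mass additivity holds to machine precision", {
  set.seed(31)
  for (i in 1:10) {
    a <- elemental_formula(c(C = sample(1:50, 1), H = sample(1:80, 1),
                             O = sample(1:20, 1)))
    b <- elemental_formula(c(S = sample(1:3, 1), O = sample(1:6, 1)))
    expect_equal(monoisotopic_mz(formula_add(a, b)),
                 monoisotopic_mz(a) + monoisotopic_mz(b),
                 tolerance = 1e-12)
  }
})

test_that("ppm error is signed, zero on equality, antisymmetric near 1", {
  expect_equal(ppm_error(100.0001, 100.0), 1, tolerance = 1e-6)
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(ppm_error(1000.001, 1000), -ppm_error(1000, 1000.001),
               tolerance = 1e-4)
})

test_that("sulfur candidates add the exact adduct masses", {
  lib <- data.frame(name = "ophiopogonin D", formula = "C44H70O16")
  cand <- sulfur_candidates(lib)
  expect_equal(nrow(cand), 2)
  d <- cand$target_mz - cand$parent_mz
  expect_equal(d[cand$adduct == "SO3"], 79.956815, tolerance = 1e-5)
  expect_equal(d[cand$adduct == "SO2"], 63.961901, tolerance = 1e-5)
  # the sulfate derivative is "79.95 Da more" than the parent
  expect_equal(d[cand$adduct == "SO3"], 79.95, tolerance = 0.01)
  expect_error(sulfur_candidates(lib[0, ]), "nrow")
})

test_that("extracted-ion matching respects the ppm window", {
  mz <- c(1129.4742, 1129.4742 * (1 + 10e-6), 800)
  names(mz) <- c("exact", "plus10ppm", "far")
  hit <- extract_hreic(mz, 1129.4742, tol_ppm = 5)
  expect_equal(hit$feature, "exact")
  expect_equal(hit$ppm, 0, tolerance = 1e-9)
})

test_that("fine-structure lines separate 34S from 13C2 at ~1e5 resolving power", {
  fs <- m2_fine_structure("C50H81O26S")
  ln <- fs$lines
  d <- ln$shift[ln$label == "C13x2"] - ln$shift[ln$label == "S34"]
  expect_lt(abs(d - 0.01091), 1e-5)
  expect_equal(fs$resolving_power, 1129.47 / 0.01091, tolerance = 0.01)
  # 34S abundance for one sulfur: n_S * (a34/a32)
  one_s <- m2_fine_structure("CH4S")
  expect_equal(one_s$lines$abundance[one_s$lines$label == "S34"],
               0.0425 / 0.9499, tolerance = 1e-6)
  # no sulfur, single C, no O: empty line list
  none <- m2_fine_structure("CH4")
  expect_equal(nrow(none$lines), 0)
})

test_that("the two reported fragment ladders are annotated exactly", {
  a <- annotate_ladder(1129, c(983, 903, 723, 591, 429))
  expect_equal(a$sequence, c("rhamnosyl", "SO3", "glucose", "xylosyl",
                             "glucosyl"))
  expect_equal(a$fragments, c(983, 903, 723, 591, 429))
  expect_equal(a$n_matched, 5)
  expect_equal(a$sulfur_call, "sulfate")

  b <- annotate_ladder(1127, c(965, 901, 755, 593, 575, 413))
  expect_equal(b$sequence, c("glucosyl", "SO2", "rhamnosyl", "glucosyl",
                             "water", "glucosyl"))
  expect_equal(b$fragments, c(965, 901, 755, 593, 575, 413))
  expect_equal(b$sulfur_call, "sulfite")
  expect_error(annotate_ladder(1129, numeric(0)), "empty")
})

test_that("ladder annotation survives decoy peaks", {
  pl <- generate_ms2(1129, c(146, 80, 180, 132, 162), noise_peaks = 20,
                     seed = 17)
  a <- annotate_ladder(1129, pl)
  expect_equal(a$sequence[1:5], c("rhamnosyl", "SO3", "glucose", "xylosyl",
                                  "glucosyl"))
  expect_true(all(c(983, 903, 723, 591, 429) %in% a$fragments))
})

test_that("noise-free generated ladders are reconstructed exactly", {
  tbl <- neutral_loss_table()
  set.seed(32)
  for (i in 1:12) {
    len <- sample(3:6, 1)
    seqn <- sample(tbl$name, len, replace = TRUE)
    losses <- tbl$nominal[match(seqn, tbl$name)]
    pre <- 1400
    if (pre - sum(losses) <= 50) next
    pl <- generate_ms2(pre, losses, noise_peaks = 0)
    a <- annotate_ladder(pre, pl)
    expect_equal(a$n_matched, length(unique(cumsum(losses))))
    # total neutral loss reconstructed exactly
    expect_equal(pre - a$fragments[length(a$fragments)],
                 sum(tbl$nominal[match(a$sequence, tbl$name)]))
  }
})

test_that("relative-area filtering is boundary-inclusive and preserves areas", {
  A <- rbind(c(98.5, 1, 0.5), c(98.5, 1, 0.5)) * 100
  ft <- feature_table(A, feature_mz = c(500, 600, 700),
                      feature_rt = c(1, 2, 3))
  kept <- relative_area_filter(ft, min_fraction = 0.01)
  expect_equal(ncol(kept$areas), 2)     # 0.5% feature dropped
  two <- feature_table(rbind(c(99, 1), c(99, 1)), c(500, 600), c(1, 2))
  kept2 <- relative_area_filter(two, min_fraction = 0.01)
  expect_equal(ncol(kept2$areas), 2)    # 1% boundary kept
  expect_equal(kept2$areas, two$areas)  # no renormalization
  expect_error(relative_area_filter(two, min_fraction = 0.999), "every")
})

test_that("a perfect class indicator passes the three-criteria screen", {
  set.seed(33)
  n <- 20
  cls <- rep(c("NSF", "SF"), each = n / 2)
  A <- matrix(exp(rnorm(n * 10, log(100), 0.2)), n, 10)
  A[, 1] <- ifelse(cls == "SF", 500, 50) * exp(rnorm(n, 0, 0.05))
  ft <- feature_table(A, feature_mz = seq(400, 850, 50),
                      feature_rt = 1:10, class_labels = cls)
  sc <- screen_markers(ft, annotate_sulfur = FALSE)
  expect_true("F001" %in% sc$hits$feature)
  expect_equal(sc$hits$direction[sc$hits$feature == "F001"], "up_in_SF")
})

test_that("screening the default generator recovers all planted derivatives", {
  ft <- generate_feature_table(synthetic_config())
  sc <- screen_markers(ft)
  der <- ft$feature_meta$feature_id[ft$feature_meta$type == "sulfur_derivative"]
  fla <- ft$feature_meta$feature_id[ft$feature_meta$type == "flavone"]
  expect_true(all(der %in% sc$hits$feature))
  expect_false(any(fla %in% sc$hits$feature))
  hits_der <- sc$hits[sc$hits$feature %in% der, ]
  expect_true(all(abs(hits_der$annotation_ppm) <= 5))
  expect_equal(hits_der$parent_feature,
               ft$feature_meta$parent_id[match(hits_der$feature,
                                               ft$feature_meta$feature_id)])
  expect_equal(hits_der$adduct,
               ft$feature_meta$adduct[match(hits_der$feature,
                                            ft$feature_meta$feature_id)])
})

test_that("on null tables hits stay at the false-positive floor", {
  # ~200 class-independent features: the raw t-test criterion admits about
  # 5% of features, and the three-way intersection can never exceed any
  # single criterion's hit set (at n = 26 the t test is the binding
  # criterion, so the intersection usually coincides with it)
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = seed, conversion_fraction = 0,
                            baseline_sulfur = 0, n_saponin_features = 5,
                            n_flavone_features = 20, n_noise_features = 170,
                            noise_sd = 0.05)
    ft <- generate_feature_table(cfg)
    keep <- apply(ft$areas, 2, sd) > 0    # all-zero derivative columns out
    ft2 <- feature_table(ft$areas[, keep], ft$feature_mz[keep],
                         ft$feature_rt[keep], ft$sample_ids,
                         ft$class_labels)
    sc <- suppressMessages(screen_markers(ft2, annotate_sulfur = FALSE))
    n <- sc$criteria_n
    p_total <- ncol(ft2$areas)
    expect_lte(n[["t_test"]], 0.05 * p_total + 2 * sqrt(0.05 * p_total))
    expect_lte(n[["intersection"]],
               min(n[["splot"]], n[["vip"]], n[["t_test"]]))
  }
})

test_that("relaxing one screening threshold never removes a hit", {
  ft <- generate_feature_table(synthetic_config(seed = 5))
  base <- screen_markers(ft, annotate_sulfur = FALSE)
  relaxed <- list(
    screen_markers(ft, annotate_sulfur = FALSE, vip_thr = 1.0),
    screen_markers(ft, annotate_sulfur = FALSE, t_thr = 0.2),
    screen_markers(ft, annotate_sulfur = FALSE, pcorr_thr = 0.1)
  )
  for (r in relaxed) {
    expect_true(all(base$hits$feature %in% r$hits$feature))
  }
})
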