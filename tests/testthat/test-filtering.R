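test_that("score differentials follow the relative-excess formula with guards", {
  expect_equal(scoreDifferential(10, 8), 0.25)
  expect_equal(scoreDifferential(4, 8), -0.5)
  expect_equal(scoreDifferential(8, 8), 0)
  # single-PSM spectra get the configured cap
  expect_equal(scoreDifferential(3, NA_real_), 1.0)
  expect_equal(scoreDifferential(3, NA_real_, single_cap = 2), 2)
  # tiny denominators are guarded by eps and the symmetric clamp
  expect_equal(scoreDifferential(1, 1e-9), 5)
  expect_equal(scoreDifferential(-1, 1e-9), -5)
  expect_equal(scoreDifferential(1, 1e-9, diff_cap = Inf), (1 - 1e-9) / 1e-6)
})

test_that("agreement classification covers unanimous, majority/minority, discordant", {
  u <- classifyAgreement(c(mvh = "A", xcorr = "A", wdp = "A"))
  expect_equal(u$class, "unanimous")
  mm <- classifyAgreement(c(mvh = "B", xcorr = "A", wdp = "A"))
  expect_setequal(mm$class, c("majority", "minority"))
  expect_equal(mm$peptide[mm$class == "majority"], "A")
  expect_equal(mm$dissenting_scorer[mm$class == "minority"], "mvh")
  d <- classifyAgreement(c(mvh = "A", xcorr = "B", wdp = "C"))
  expect_equal(d$class, rep("discordant", 3))
  expect_error(classifyAgreement(c(mvh = "A", xcorr = "B")), "three")
})

test_that("feature extraction produces the 10 features with correct counts", {
  psms <- data.frame(
    scan = c("s1", "s1", "s2", "s3", "s4"),
    charge = 2L,
    sequence = c("PEPA", "PEPB", "PEPA", "PEPA", "PEPC"),
    proteins = c("p1", "p2;p3", "p1", "p1", "p2"),
    is_decoy = FALSE,
    missed_cleavages = c(0L, 1L, 0L, 0L, 2L),
    calc_mass = c(500, 500.02, 500, 500, 700),
    meas_mass = c(500, 500, 500, 500, 700.01),
    mvh = c(10, 8, 9, 7, 5), xcorr = c(2, 1, 2, 1, 1),
    wdp = c(1.5, 1, 1, 1, 1),
    rank_mvh = c(1L, 2L, 1L, 1L, 1L), rank_xcorr = c(1L, 2L, 1L, 1L, 1L),
    rank_wdp = c(1L, 2L, 1L, 1L, 1L))
  feat <- extractFeatures(psms)
  expect_equal(nrow(feat), 4L)  # the four rank-1 PSMs
  expect_true(all(c("mvh", "xcorr", "wdp", "d_mvh", "d_xcorr", "d_wdp",
                    "delta_mass", "n_missed_cleavages",
                    "pep_spectrum_count", "pro_spectrum_count") %in%
                  names(feat)))
  f1 <- feat[feat$scan == "s1", ]
  expect_equal(f1$d_mvh, (10 - 8) / 8)
  expect_equal(f1$delta_mass, 0)
  # PEPA seen in three spectra (all charge states/mod forms pooled)
  expect_equal(f1$pep_spectrum_count, 3L)
  # protein p1 carries three PSMs; multi-parent PSMs take the best parent
  expect_equal(f1$pro_spectrum_count, 3L)
  f4 <- feat[feat$scan == "s4", ]
  expect_equal(f4$delta_mass, 0.01, tolerance = 1e-9)
  # s4 has a single PSM: differential capped at +1
  expect_equal(f4$d_mvh, 1.0)
  # multi-parent PSM uses the parent with the highest spectrum count
  psms2 <- psms
  psms2$proteins[5] <- "p1;p9"
  f42 <- extractFeatures(psms2)
  expect_equal(f42$pro_spectrum_count[f42$scan == "s4"], 4L)
  expect_equal(f42$best_parent[f42$scan == "s4"], "p1")
})

test_that("decoy protein split is seeded, recorded, and refuses degenerate alpha", {
  db <- generateDecoys(tinyProteinDb())
  expect_error(splitDecoyProteins(db, alpha = 0), "alpha")
  expect_error(splitDecoyProteins(db, alpha = 1), "alpha")
  set.seed(99)
  many <- generateDecoys(newProteinDb(sprintf("m%03d", 1:500),
    vapply(1:500, function(i)
      paste(sample(names(psmEnsemble:::.RESIDUE_MASS), 50, replace = TRUE),
            collapse = ""), "")))
  s1 <- splitDecoyProteins(many, alpha = 0.5, seed = 1L)
  s2 <- splitDecoyProteins(many, alpha = 0.5, seed = 1L)
  expect_identical(decoySplit(s1), decoySplit(s2))
  a <- realizedAlpha(s1)
  expect_gt(a, 0.4); expect_lt(a, 0.6)
  expect_true(all(decoySplit(s1)[!isDecoy(s1)] == "not_applicable"))
  # a different seed gives a different assignment
  s3 <- splitDecoyProteins(many, alpha = 0.5, seed = 2L)
  expect_false(identical(decoySplit(s1), decoySplit(s3)))
})

test_that("training data are unanimous targets vs train-split decoys only", {
  run <- cachedPipelineRun()
  feat <- run$res$features
  db <- run$res$db
  train <- buildTrainingData(feat, db)
  expect_true(all(train$positives$class == "unanimous"))
  expect_true(all(!train$positives$is_decoy))
  expect_true(all(train$negatives$is_decoy))
  split_map <- decoySplit(db)
  expect_true(all(split_map[train$negatives$best_parent] == "train"))
  # held-out integrity: no test-split decoy PSM in either set
  expect_false(any(train$positives$decoy_split %in% "test"))
  expect_false(any(split_map[train$negatives$best_parent] == "test"))
})

test_that("classifiers separate synthetic clouds and stay near chance on noise", {
  set.seed(17)
  mkfeat <- function(n, shift) {
    m <- matrix(rnorm(n * 10, mean = shift), ncol = 10)
    colnames(m) <- psmEnsemble:::.FEATURE_NAMES
    as.data.frame(m)
  }
  pos <- mkfeat(300, 1.5); neg <- mkfeat(300, -1.5)
  for (kind in c("logistic_regression", "random_forest", "adaboost")) {
    fl <- trainPsmFilter(pos, neg, model_kind = kind, alpha = 0.5)
    acc <- mean(c(predictPsmFilter(fl, pos) > 0.5,
                  predictPsmFilter(fl, neg) < 0.5))
    expect_gte(acc, 0.99)
  }
  # label-permuted data: held-out scores near 0.5
  all_feat <- rbind(mkfeat(400, 0), mkfeat(400, 0))
  fl0 <- trainPsmFilter(all_feat[1:400, ], all_feat[401:800, ],
                        model_kind = "logistic_regression", alpha = 0.5)
  held <- mkfeat(200, 0)
  expect_lt(abs(mean(predictPsmFilter(fl0, held)) - 0.5), 0.1)
  # constant features are dropped with a warning
  posc <- pos; posc$delta_mass <- 1; negc <- neg; negc$delta_mass <- 1
  expect_warning(flc <- trainPsmFilter(posc, negc, alpha = 0.5), "constant")
  expect_false("delta_mass" %in% flc@featureNames)
})

test_that("random forest and adaboost use the published ensemble sizes", {
  set.seed(18)
  m <- matrix(rnorm(4000), ncol = 10)
  colnames(m) <- psmEnsemble:::.FEATURE_NAMES
  pos <- as.data.frame(m[1:200, ] + 1)
  neg <- as.data.frame(m[201:400, ] - 1)
  rf <- trainPsmFilter(pos, neg, model_kind = "random_forest", alpha = 0.5)
  expect_equal(rf@fit$ntree, 200L)
  ab <- trainPsmFilter(pos, neg, model_kind = "adaboost", alpha = 0.5)
  expect_lte(length(ab@fit$stumps), 200L)
  expect_true(all(vapply(ab@fit$stumps, function(s)
    max(s$frame$var != "<leaf>") <= 1, TRUE)))
})

test_that("one and only one PSM per spectrum survives selection", {
  run <- cachedPipelineRun()
  sel <- run$res$selected
  expect_equal(anyDuplicated(sel$scan), 0L)
  expect_setequal(sel$scan, unique(run$res$features$scan))
  # the kept PSM attains the spectrum's maximum classification score
  feat <- run$res$features
  feat$classification_score <- predictPsmFilter(run$res$filter, feat)
  best <- tapply(feat$classification_score, feat$scan, max)
  expect_equal(sel$classification_score, as.numeric(best[sel$scan]),
               tolerance = 1e-12)
})

test_that("the decoy-split FDR estimator follows its closed form", {
  expect_equal(estimateFdr(1000, 5, 0.5)$fdr, 0.01)
  expect_equal(estimateFdr(100, 2, 0.25)$fdr, 0.08)
  expect_equal(estimateFdr(500, 0, 0.3)$fdr, 0)
  expect_equal(estimateFdr(0, 0, 0.5)$fdr, 0)
  expect_true(is.infinite(estimateFdr(0, 3, 0.5)$fdr))
  expect_error(estimateFdr(-1, 0, 0.5), "non-negative")
  expect_error(estimateFdr(10, 0, 1.2), "alpha")
})

test_that("FDR thresholding walks the score sweep correctly", {
  sel <- data.frame(
    scan = paste0("s", 1:5),
    sequence = paste0("PEP", LETTERS[1:5]),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    decoy_split = c(NA, NA, NA, NA, "test"),
    classification_score = c(0.9, 0.8, 0.7, 0.6, 0.65))
  # hand-walked sweep: at cutoff 0.7 FDR = 0/(0.5*3) = 0;
  # at 0.6 FDR = 1/(0.5*4) = 0.5
  res <- filterAtFdr(sel, alpha = 0.5, target_fdr = 0.01)
  expect_equal(res$threshold, 0.7)
  expect_equal(nrow(res$accepted), 3L)
  expect_equal(res$fdr$fdr, 0)
  res2 <- filterAtFdr(sel, alpha = 0.5, target_fdr = 0.5)
  expect_equal(nrow(res2$accepted), 5L)
  expect_equal(res2$fdr$fdr, 0.5)
  # vacuous bound accepts everything
  res3 <- filterAtFdr(sel, alpha = 0.5, target_fdr = 1.0)
  expect_equal(nrow(res3$accepted), nrow(sel))
  # adversarial order: all decoys above all targets -> empty set
  adv <- sel
  adv$is_decoy <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  adv$decoy_split <- c("test", "test", NA, NA, NA)
  res4 <- filterAtFdr(adv, alpha = 0.5, target_fdr = 0.01)
  expect_equal(nrow(res4$accepted), 0L)
  expect_true(is.na(res4$threshold))
  # training-split decoys are excluded from numerator and acceptance
  tr <- sel
  tr$is_decoy[5] <- TRUE; tr$decoy_split[5] <- "train"
  res5 <- filterAtFdr(tr, alpha = 0.5, target_fdr = 0.01)
  expect_equal(nrow(res5$accepted), 4L)
  expect_false(any(res5$accepted$decoy_split %in% "train"))
  expect_equal(res5$fdr$n_test_decoy, 0L)
})

test_that("raising the target FDR never shrinks the accepted set", {
  run <- cachedPipelineRun()
  sel <- run$res$selected
  alpha <- realizedAlpha(run$res$db)
  prev <- -1L
  for (fdr in c(0.001, 0.01, 0.05, 0.1, 0.3, 1.0)) {
    n <- nrow(filterAtFdr(sel, alpha, target_fdr = fdr)$accepted)
    expect_gte(n, prev)
    prev <- n
  }
})
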