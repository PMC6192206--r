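## Supervised ensemble filtering of search results: per-PSM features,
## agreement classes of the three scorers' rank-1 peptides, classifier
## training on unanimous target PSMs vs training-split decoy PSMs,
## per-spectrum PSM selection, and FDR-controlled thresholding using the
## held-out decoy split.

.FEATURE_NAMES <- c("mvh", "xcorr", "wdp", "d_mvh", "d_xcorr", "d_wdp",
                    "delta_mass", "n_missed_cleavages",
                    "pep_spectrum_count", "pro_spectrum_count")

#' Score differential
#'
#' `(sc - sb) / sb`, where `sc` is the PSM's score and `sb` the highest
#' score of the *other* PSMs reported for the same spectrum under the same
#' scorer. Positive for top-ranking PSMs, negative for lower-ranking ones.
#' When `|sb|` is below `eps` the denominator is replaced by `eps` carrying
#' the sign of `sb` (zero treated as positive); when a spectrum has a
#' single PSM, `sb` is undefined and the differential is set to
#' `single_cap`.
#'
#' @param sc,sb numeric vectors (recycled); `sb` may be `NA` for
#'   single-PSM spectra.
#' @param eps denominator guard (default 1e-6).
#' @param single_cap differential assigned when `sb` is `NA` (default 1).
#' @param diff_cap symmetric clamp on the result (default 5): near-zero
#'   denominators otherwise yield differentials of order `1/eps` that
#'   destabilize downstream model fitting while carrying no more
#'   information than "very large".
#' @return Numeric vector of differentials.
#' @export
scoreDifferential <- function(sc, sb, eps = 1e-6, single_cap = 1.0,
                              diff_cap = 5.0) {
  denom <- ifelse(abs(sb) >= eps, sb, eps * ifelse(sb < 0, -1, 1))
  out <- (sc - sb) / denom
  out[is.na(sb)] <- single_cap
  pmin(pmax(out, -diff_cap), diff_cap)
}

#' Classify scorer agreement for one spectrum
#'
#' Each scorer nominates a rank-1 peptide. If all three coincide the single
#' PSM is `unanimous`; if exactly two coincide, their PSM is `majority` and
#' the third scorer's PSM is `minority` (with the dissenting scorer
#' recorded); if all differ, each PSM is `discordant`.
#'
#' @param rank1 named character vector of length 3: the rank-1 peptide of
#'   scorers `mvh`, `xcorr`, `wdp`.
#' @return `data.frame` with one row per distinct peptide: `peptide`,
#'   `class`, `scorers` (";"-joined supporters), `dissenting_scorer` (NA
#'   unless `minority`).
#' @export
classifyAgreement <- function(rank1) {
  need <- c("mvh", "xcorr", "wdp")
  if (!all(need %in% names(rank1)) || anyNA(rank1[need]))
    stop("rank-1 peptide required for all three scorers")
  rank1 <- rank1[need]
  peps <- unique(unname(rank1))
  support <- lapply(peps, function(p) names(rank1)[rank1 == p])
  n_sup <- lengths(support)
  cls <- if (length(peps) == 1L) "unanimous"
         else if (length(peps) == 2L) ifelse(n_sup == 2L, "majority", "minority")
         else rep("discordant", 3L)
  dissent <- rep(NA_character_, length(peps))
  if (length(peps) == 2L)
    dissent[cls == "minority"] <- support[[which(n_sup == 1L)]]
  data.frame(peptide = peps, class = cls,
             scorers = vapply(support, paste, "", collapse = ";"),
             dissenting_scorer = dissent)
}

## Rank-1 PSM rows per scorer for every scan, with agreement class attached.
## Returns a data.table: one row per distinct rank-1 (scan, peptide).
.rank1Psms <- function(psms) {
  dt <- data.table::as.data.table(psms)
  r1 <- dt[dt$rank_mvh == 1L | dt$rank_xcorr == 1L | dt$rank_wdp == 1L, ]
  scorers <- paste0(ifelse(r1$rank_mvh == 1L, "mvh;", ""),
                    ifelse(r1$rank_xcorr == 1L, "xcorr;", ""),
                    ifelse(r1$rank_wdp == 1L, "wdp;", ""))
  r1$scorers <- sub(";$", "", scorers)
  r1$n_agree <- (r1$rank_mvh == 1L) + (r1$rank_xcorr == 1L) + (r1$rank_wdp == 1L)
  ## classes follow directly from the per-scan supporter counts
  n_agree <- NULL
  r1[, `:=`(class = {
    if (.N == 1L) "unanimous"
    else if (.N == 2L) ifelse(n_agree == 2L, "majority", "minority")
    else rep("discordant", .N)
  }), by = "scan"]
  r1$dissenting_scorer <- ifelse(r1$class == "minority", r1$scorers, NA_character_)
  r1
}

#' Extract the 10 filtering features
#'
#' For the rank-1 PSMs of a search result, computes the three scores, the
#' three score differentials (against the best *other* reported PSM of the
#' same spectrum under the same scorer), the absolute precursor mass error,
#' the number of missed cleavage sites, and the pre-filtering spectrum
#' counts of the PSM's peptide (`#PEP`, over all charge states) and of its
#' best parent protein (`#PRO`, the parent with the highest count).
#' Spectrum counts count every reported PSM before filtering by default;
#' `count_all_reported = FALSE` restricts them to rank-1-by-any-scorer
#' PSMs. Counting the full reported depth keeps the protein-level count an
#' evidence feature rather than a target/decoy proxy when the search space
#' is small and densely covered.
#'
#' @param psms search result `data.frame` from [ensembleSearch()].
#' @param eps,single_cap see [scoreDifferential()].
#' @param count_all_reported logical; see above.
#' @return `data.frame`: the rank-1 PSM rows with agreement `class`,
#'   feature columns, and `best_parent` (the protein used for `#PRO`).
#' @export
extractFeatures <- function(psms, eps = 1e-6, single_cap = 1.0,
                            count_all_reported = TRUE) {
  dt <- data.table::as.data.table(psms)
  r1 <- .rank1Psms(dt)
  ## best-other score per (scan, scorer): top-2 over all reported PSMs
  top2 <- dt[, list(
    m1 = max(mvh), m2 = if (.N > 1L) sort(mvh, decreasing = TRUE)[2L] else NA_real_,
    x1 = max(xcorr), x2 = if (.N > 1L) sort(xcorr, decreasing = TRUE)[2L] else NA_real_,
    w1 = max(wdp), w2 = if (.N > 1L) sort(wdp, decreasing = TRUE)[2L] else NA_real_
  ), by = "scan"]
  r1 <- merge(r1, top2, by = "scan", sort = FALSE)
  sb <- function(sc, s1, s2) ifelse(abs(sc - s1) < 1e-12, s2, s1)
  r1$d_mvh <- scoreDifferential(r1$mvh, sb(r1$mvh, r1$m1, r1$m2), eps, single_cap)
  r1$d_xcorr <- scoreDifferential(r1$xcorr, sb(r1$xcorr, r1$x1, r1$x2), eps, single_cap)
  r1$d_wdp <- scoreDifferential(r1$wdp, sb(r1$wdp, r1$w1, r1$w2), eps, single_cap)
  r1$delta_mass <- abs(r1$calc_mass - r1$meas_mass)
  r1$n_missed_cleavages <- r1$missed_cleavages
  ## pre-filtering spectrum counts over the configured PSM population
  pop <- if (count_all_reported) dt else r1
  pep_counts <- table(pop$sequence)
  r1$pep_spectrum_count <- as.integer(pep_counts[r1$sequence])
  prot_long <- data.table::data.table(
    protein = unlist(strsplit(pop$proteins, ";", fixed = TRUE)),
    scan = rep(pop$scan, lengths(strsplit(pop$proteins, ";", fixed = TRUE))))
  pro_counts <- table(prot_long$protein)
  pro_of <- strsplit(r1$proteins, ";", fixed = TRUE)
  best <- vapply(pro_of, function(pr) {
    cnt <- as.integer(pro_counts[pr])
    cnt[is.na(cnt)] <- 0L
    j <- which.max(cnt)
    c(pr[j], cnt[j])
  }, c("", ""))
  r1$best_parent <- best[1L, ]
  r1$pro_spectrum_count <- pmax(as.integer(best[2L, ]), 1L)
  drop <- c("m1", "m2", "x1", "x2", "w1", "w2", "n_agree")
  as.data.frame(r1[, setdiff(names(r1), drop), with = FALSE])
}

#' Split decoy proteins into training and test sets
#'
#' Each decoy protein is independently assigned to the test set with
#' probability `alpha` (the training set otherwise); targets are left
#' untouched. The realized test fraction is what enters FDR estimation.
#' Deterministic under a fixed seed.
#'
#' @param db a [ProteinDb-class] containing decoys.
#' @param alpha intended test-set fraction in (0, 1) (default 0.5).
#' @param seed integer seed (default 20170922).
#' @return The [ProteinDb-class] with `decoySplit` filled in.
#' @export
splitDecoyProteins <- function(db, alpha = 0.5, seed = 20170922L) {
  stopifnot(is(db, "ProteinDb"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  idx <- which(db@isDecoy)
  if (!length(idx)) stop("database contains no decoy proteins")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- runif(length(idx)) < alpha
  if (all(test) || !any(test))
    stop("all decoys fell in one split; cannot both train and estimate FDR")
  db@decoySplit[idx] <- ifelse(test, "test", "train")
  validObject(db)
  db
}

#' Realized test-split fraction
#'
#' @param db a split [ProteinDb-class].
#' @return Fraction of decoy proteins assigned to the test set.
#' @export
realizedAlpha <- function(db) {
  sp <- db@decoySplit[db@isDecoy]
  if (!length(sp) || any(sp == "not_applicable"))
    stop("decoy proteins have not been split; run splitDecoyProteins()")
  mean(sp == "test")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## split assignment of a decoy PSM = split of its best (highest-count)
## parent decoy protein
.psmDecoySplit <- function(feat, db) {
  split_map <- setNames(db@decoySplit, names(db@sequences))
  out <- rep(NA_character_, nrow(feat))
  out[feat$is_decoy] <- split_map[feat$best_parent[feat$is_decoy]]
  out
}

#' Attach decoy split labels to a feature table
#'
#' Adds a `decoy_split` column: the train/test assignment of each decoy
#' PSM's best parent decoy protein (NA for target PSMs). Required by
#' [filterAtFdr()].
#'
#' @param feat feature table from [extractFeatures()].
#' @param db split [ProteinDb-class].
#' @return `feat` with a `decoy_split` column.
#' @export
annotateDecoySplit <- function(feat, db) {
  feat$decoy_split <- .psmDecoySplit(feat, db)
  feat
}

#' Build classifier training data
#'
#' Positives are unanimous PSMs from target proteins; negatives are decoy
#' PSMs whose best parent decoy protein lies in the training split.
#' Test-split decoy PSMs enter neither set, preserving the held-out FDR
#' estimate.
#'
#' @param feat feature table from [extractFeatures()].
#' @param db split [ProteinDb-class].
#' @return List with `positives` and `negatives` (feature rows) and
#'   `decoy_split` (per-row split label, NA for targets).
#' @export
buildTrainingData <- function(feat, db) {
  split <- .psmDecoySplit(feat, db)
  pos <- feat[feat$class == "unanimous" & !feat$is_decoy, ]
  neg <- feat[feat$is_decoy & !is.na(split) & split == "train", ]
  if (nrow(pos) == 0L)
    stop("no unanimous target PSMs: too little input to train a filter")
  if (nrow(neg) == 0L)
    stop("no training-split decoy PSMs: too little input to train a filter")
  list(positives = pos, negatives = neg, decoy_split = split)
}

## feature matrix for model fitting/prediction
.featureMatrix <- function(feat, feature_names = .FEATURE_NAMES) {
  m <- as.matrix(feat[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train the supervised PSM filter
#'
#' Standardizes the 10 features with training-set means and standard
#' deviations (constant features are dropped with a warning) and fits the
#' requested classifier: logistic regression with L2 (ridge) penalty
#' (production default), a random forest (200 trees, Gini impurity,
#' minimum 50 samples per leaf), or AdaBoost (SAMME, 200 depth-1 stumps).
#' The classification score of a PSM is the predicted probability of the
#' positive class.
#'
#' @param positives,negatives feature tables from [buildTrainingData()].
#' @param model_kind `"logistic_regression"`, `"random_forest"` or
#'   `"adaboost"`.
#' @param alpha realized test-split fraction (stored for FDR estimation).
#' @param l2_strength ridge penalty weight (default 1.0; the glmnet lambda
#'   is `0.01 * l2_strength`, independent of training-set size so that
#'   small or separable training sets stay stably regularized and
#'   classification scores remain graded rather than saturating).
#' @return A [TrainedPsmFilter-class].
#' @export
trainPsmFilter <- function(positives, negatives,
                           model_kind = c("logistic_regression",
                                          "random_forest", "adaboost"),
                           alpha = 0.5, l2_strength = 1.0) {
  model_kind <- match.arg(model_kind)
  x <- rbind(.featureMatrix(positives), .featureMatrix(negatives))
  y <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  constant <- !is.finite(scl) | scl < 1e-12
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
  }
  xs <- scale(x, center = ctr, scale = scl)
  fit <- switch(model_kind,
    logistic_regression = glmnet::glmnet(
      xs, y, family = "binomial", alpha = 0,
      lambda = 0.01 * l2_strength, standardize = FALSE, thresh = 1e-10),
    random_forest = randomForest::randomForest(
      xs, factor(y, levels = c(0L, 1L)), ntree = 200L, nodesize = 50L),
    adaboost = .fitAdaboost(xs, y, n_estimators = 200L)
  )
  new("TrainedPsmFilter", modelKind = model_kind, fit = fit,
      featureNames = colnames(x), center = ctr, scale = scl, alpha = alpha)
}

## AdaBoost (discrete SAMME) over depth-1 rpart stumps.
.fitAdaboost <- function(x, y, n_estimators = 200L) {
  n <- length(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y, levels = c(0L, 1L)), x)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                       minsplit = 2L,
                                                       minbucket = 1L,
                                                       xval = 0L))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err <= 0 || err >= 0.5) {
      if (err <= 0) { used <- used + 1L; stumps[[used]] <- fit; alphas[used] <- 10 }
      break
    }
    a <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- a
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (used == 0L) stop("AdaBoost could not fit any stump")
  structure(list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)]),
            class = "psmAdaboost")
}

.predictAdaboost <- function(model, x) {
  df <- as.data.frame(x)
  margin <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df, type = "class")))
    margin <- margin + model$alphas[m] * ifelse(pred == 1L, 1, -1)
  }
  f <- margin / sum(abs(model$alphas))
  (f + 1) / 2
}

#' Classification scores for PSMs
#'
#' @param filter a [TrainedPsmFilter-class].
#' @param feat feature table (rows to score).
#' @return Numeric vector of classification scores in `[0, 1]`.
#' @export
predictPsmFilter <- function(filter, feat) {
  x <- .featureMatrix(feat, filter@featureNames)
  xs <- scale(x, center = filter@center, scale = filter@scale)
  switch(filter@modelKind,
    logistic_regression = as.numeric(predict(filter@fit, xs, type = "response")),
    random_forest = as.numeric(predict(filter@fit, xs, type = "prob")[, "1"]),
    adaboost = .predictAdaboost(filter@fit, xs)
  )
}

#' Select one PSM per spectrum
#'
#' Among the distinct rank-1 PSMs of the three scorers for a spectrum (1-3
#' of them), keeps the one with the highest classification score; ties go
#' to target over decoy, then to the lexicographically smaller peptide.
#' Every searched spectrum with at least one PSM yields exactly one row.
#'
#' @param feat feature table from [extractFeatures()].
#' @param filter a [TrainedPsmFilter-class].
#' @return Feature table subset with one row per scan plus a
#'   `classification_score` column.
#' @export
selectPsmPerSpectrum <- function(feat, filter) {
  feat$classification_score <- predictPsmFilter(filter, feat)
  o <- order(feat$scan, -feat$classification_score, feat$is_decoy, feat$sequence)
  feat <- feat[o, ]
  feat[!duplicated(feat$scan), ]
}

#' Decoy-split FDR estimate
#'
#' `FDR = n_test_decoy / (alpha * n_target)`: the test-split decoy count
#' scaled up by the inverse test fraction estimates the total number of
#' decoy-level false hits among the targets. With zero targets the FDR is 0
#' when the decoy count is also 0, and `Inf` otherwise.
#'
#' @param n_target number of accepted target PSMs (or peptides/proteins).
#' @param n_test_decoy number of accepted decoys from test-split proteins.
#' @param alpha realized test-split fraction in (0, 1).
#' @return List with `n_target`, `n_test_decoy`, `alpha`, `fdr`.
#' @export
estimateFdr <- function(n_target, n_test_decoy, alpha) {
  if (n_target < 0 || n_test_decoy < 0) stop("counts must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  fdr <- if (n_target > 0) n_test_decoy / (alpha * n_target)
         else if (n_test_decoy == 0) 0 else Inf
  list(n_target = as.integer(n_target), n_test_decoy = as.integer(n_test_decoy),
       alpha = alpha, fdr = fdr)
}

#' Baseline: threshold a single scoring function at a target FDR
#'
#' The comparison baseline for the trained ensemble filter: per spectrum
#' the rank-1 PSM of one scorer is taken, and that scorer's raw score is
#' swept with the same decoy-split FDR estimator and acceptance rules as
#' [filterAtFdr()].
#'
#' @param psms search result from [ensembleSearch()].
#' @param db split [ProteinDb-class].
#' @param scorer `"mvh"`, `"xcorr"` or `"wdp"`.
#' @param target_fdr FDR level (default 0.01).
#' @return List with `threshold`, `accepted`, `fdr` as in [filterAtFdr()].
#' @export
filterBySingleScore <- function(psms, db, scorer = c("mvh", "xcorr", "wdp"),
                                target_fdr = 0.01) {
  scorer <- match.arg(scorer)
  rank_col <- paste0("rank_", scorer)
  sel <- psms[psms[[rank_col]] == 1L, ]
  sel <- sel[!duplicated(sel$scan), ]
  sel$classification_score <- sel[[scorer]]
  ## attribute decoy PSMs to their best parent's split (counts over all
  ## reported PSMs, as for the ensemble features)
  feat_like <- sel
  pro_counts <- table(unlist(strsplit(psms$proteins, ";", fixed = TRUE)))
  feat_like$best_parent <- vapply(strsplit(sel$proteins, ";", fixed = TRUE),
                                  function(pr) {
                                    cnt <- as.integer(pro_counts[pr])
                                    cnt[is.na(cnt)] <- 0L
                                    pr[which.max(cnt)]
                                  }, "")
  feat_like <- annotateDecoySplit(feat_like, db)
  filterAtFdr(feat_like, realizedAlpha(db), target_fdr = target_fdr)
}

## FDR at every candidate cutoff of a score vector (descending sweep);
## train-split decoys are excluded from both numerator and acceptance.
## Ties are resolved conservatively: at equal classification score decoys
## precede targets, so tied targets can never be accepted "above" the
## decoys that price them.
.psmLevelSweep <- function(selected, alpha) {
  o <- order(-selected$classification_score, !selected$is_decoy, selected$sequence)
  s <- selected[o, ]
  is_train_decoy <- s$is_decoy & !is.na(s$decoy_split) & s$decoy_split == "train"
  n_target <- cumsum(!s$is_decoy)
  n_test_decoy <- cumsum(s$is_decoy & !is_train_decoy)
  fdr <- ifelse(n_target > 0, n_test_decoy / (alpha * n_target),
                ifelse(n_test_decoy == 0, 0, Inf))
  list(ordered = s, n_target = n_target, n_test_decoy = n_test_decoy, fdr = fdr)
}

#' Threshold the selected PSMs at a target FDR
#'
#' Sweeps the sorted classification scores and accepts down to the lowest
#' cutoff whose decoy-split FDR estimate at the requested level is at or
#' below `target_fdr`, maximizing accepted targets. Training-split decoy
#' PSMs are excluded from the FDR numerator and from the accepted set. For
#' the `peptide` and `protein` levels the identifications are re-assembled
#' at each candidate cutoff (a coarse quantile grid of at most
#' `max_thresholds` cutoffs is used when there are more distinct scores).
#'
#' @param selected output of [selectPsmPerSpectrum()] with a `decoy_split`
#'   column (see [buildTrainingData()]).
#' @param alpha realized test-split fraction.
#' @param target_fdr FDR level (default 0.01).
#' @param level `"psm"`, `"peptide"` or `"protein"`.
#' @param index [MassIndex-class]; required for `level = "protein"`.
#' @param db split [ProteinDb-class]; required for peptide/protein levels.
#' @param max_thresholds cutoff grid cap for assembly levels (default 1000).
#' @param decoy_prefix identifier prefix marking decoy proteins (protein
#'   level only).
#' @return List with `threshold`, `accepted` (data frame), and `fdr`
#'   (an [estimateFdr()] record at the chosen threshold).
#' @export
filterAtFdr <- function(selected, alpha, target_fdr = 0.01,
                        level = c("psm", "peptide", "protein"),
                        index = NULL, db = NULL, max_thresholds = 1000L,
                        decoy_prefix = "Rev_") {
  level <- match.arg(level)
  sweep <- .psmLevelSweep(selected, alpha)
  s <- sweep$ordered
  if (level == "psm") {
    ok <- which(sweep$fdr <= target_fdr)
    k <- if (length(ok)) max(ok) else 0L
  } else {
    if (is.null(db)) stop("peptide/protein level filtering needs the split ProteinDb")
    scores <- s$classification_score
    cand_k <- seq_len(nrow(s))
    if (length(cand_k) > max_thresholds)
      cand_k <- unique(round(quantile(cand_k, probs = seq(0, 1, length.out = max_thresholds))))
    cand_k <- sort(cand_k)
    lvl_fdr <- vapply(cand_k, function(kk) {
      acc <- s[seq_len(kk), ]
      acc <- acc[!(acc$is_decoy & !is.na(acc$decoy_split) & acc$decoy_split == "train"), ]
      if (level == "peptide") {
        peps <- assemblePeptides(acc)
        levelFdrCounts(peps, db, alpha)$fdr
      } else {
        peps <- assemblePeptides(acc)
        grp <- inferProteins(peps, index, decoy_prefix = decoy_prefix)
        levelFdrCounts(grp, db, alpha)$fdr
      }
    }, 0.0)
    ok <- cand_k[lvl_fdr <= target_fdr]
    k <- if (length(ok)) max(ok) else 0L
  }
  if (k == 0L) {
    best <- if (length(sweep$fdr)) min(sweep$fdr) else NA_real_
    return(list(threshold = NA_real_,
                accepted = s[0L, ],
                fdr = estimateFdr(0L, 0L, alpha),
                best_achievable_fdr = best))
  }
  acc <- s[seq_len(k), ]
  train_decoy <- acc$is_decoy & !is.na(acc$decoy_split) & acc$decoy_split == "train"
  fdr <- estimateFdr(sweep$n_target[k], sweep$n_test_decoy[k], alpha)
  list(threshold = s$classification_score[k],
       accepted = acc[!train_decoy, ],
       fdr = fdr)
}
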