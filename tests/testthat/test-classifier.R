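# A small labeled corpus with class-shifted numeric features and a binary
# feature, for encoding/imputation tests; uses real registry column names.
toy_corpus <- function(n_per_class = 30, miss = 0, seed = 1) {
  set.seed(seed)
  labels <- rep(c("benign", "recessive", "dominant"), each = n_per_class)
  n <- length(labels)
  shift <- c(benign = -2, recessive = 0, dominant = 2)[labels]
  df <- data.frame(
    label = labels,
    gene_id = paste0("g", seq_len(n)),
    transcript_id = paste0("t", seq_len(n)),
    site_gerp = rnorm(n, shift),
    gene_syn_density = rnorm(n, 8 + shift),
    cds_length = sample(seq(300, 1200, by = 3), n, replace = TRUE),
    nmd_candidate = ifelse(runif(n) < 0.5 + 0.15 * shift / 2, 1, -1),
    af_kg = pmax(0, rnorm(n, 0.05 - 0.01 * shift, 0.01)),
    stringsAsFactors = FALSE)
  if (miss > 0) {
    for (col in c("site_gerp", "gene_syn_density", "nmd_candidate"))
      df[[col]][runif(n) < miss] <- NA
  }
  df
}

test_that("imputation replaces missing values with the equal-weight mean of class means", {
  # spec example: class means (1, 2, 3) -> imputed 2
  feats <- data.frame(site_gerp = c(1, 1, 2, 2, 3, 3, NA))
  labels <- c("benign", "benign", "recessive", "recessive",
              "dominant", "dominant", "benign")
  imp <- fit_imputation(feats[1:6, , drop = FALSE], labels[1:6])
  expect_equal(unname(imp$impute["site_gerp"]), 2)
  enc <- encode_features(feats, imp)
  expect_equal(unname(enc[7, "site_gerp"]), 2)
  expect_false(anyNA(enc))

  # prior-weighted alternative uses class frequencies
  labs2 <- c("benign", "recessive", "recessive", "dominant", "dominant",
             "dominant")
  feats2 <- data.frame(site_gerp = c(1, 2, 2, 3, 3, 3))
  imp2 <- fit_imputation(feats2, labs2, weights = "prior")
  expect_equal(unname(imp2$impute["site_gerp"]),
               (1 / 6) * 1 + (2 / 6) * 2 + (3 / 6) * 3)

  # binary column imputes to a strict {-1, +1} value
  featsb <- data.frame(nmd_candidate = c(1, 1, 1, -1, 1, 1))
  impb <- fit_imputation(featsb, labs2)
  expect_true(impb$impute["nmd_candidate"] %in% c(-1, 1))

  # entirely-missing column is dropped with a warning
  feats3 <- data.frame(site_gerp = c(1, 2, 3), af_kg = c(NA, NA, NA))
  expect_warning(imp3 <- fit_imputation(
    feats3, c("benign", "recessive", "dominant")), "af_kg")
  expect_identical(imp3$dropped, "af_kg")
  expect_false("af_kg" %in% imp3$columns)
})

test_that("a 10%-missing matrix encodes complete and equals the per-column class-mean oracle", {
  corpus <- toy_corpus(n_per_class = 40, miss = 0.1, seed = 2)
  feat_cols <- c("site_gerp", "gene_syn_density", "nmd_candidate", "af_kg")
  feats <- corpus[, feat_cols]
  imp <- fit_imputation(feats, corpus$label)
  enc <- encode_features(feats, imp)
  expect_false(anyNA(enc))
  for (col in c("site_gerp", "gene_syn_density")) {
    cms <- vapply(c("benign", "recessive", "dominant"), function(k)
      mean(feats[[col]][corpus$label == k], na.rm = TRUE), numeric(1))
    expect_equal(unname(imp$impute[col]), mean(cms), tolerance = 1e-12)
    miss <- is.na(feats[[col]])
    expect_equal(unname(enc[miss, col]),
                 rep(mean(cms), sum(miss)), tolerance = 1e-12)
    expect_equal(enc[!miss, col], feats[[col]][!miss],
                 ignore_attr = TRUE)
  }
  expect_true(all(enc[, "nmd_candidate"] %in% c(-1, 1)))
})

test_that("prediction-time imputation reuses training statistics only", {
  corpus <- toy_corpus(n_per_class = 40, miss = 0.1, seed = 3)
  feat_cols <- c("site_gerp", "gene_syn_density", "nmd_candidate", "af_kg")
  imp <- fit_imputation(corpus[, feat_cols], corpus$label)
  test1 <- toy_corpus(n_per_class = 10, miss = 0.3, seed = 4)[, feat_cols]
  test2 <- test1
  test2$site_gerp[!is.na(test2$site_gerp)][1:5] <- NA  # perturb missingness
  e1 <- encode_features(test1, imp)
  e2 <- encode_features(test2, imp)
  miss1 <- is.na(test1$site_gerp)
  expect_true(all(e1[miss1, "site_gerp"] == imp$impute["site_gerp"]))
  expect_true(all(e2[is.na(test2$site_gerp), "site_gerp"] ==
                    imp$impute["site_gerp"]))
  # unperturbed entries unchanged
  same <- !is.na(test1$site_gerp) & !is.na(test2$site_gerp)
  expect_equal(e1[same, "site_gerp"], e2[same, "site_gerp"])
})

test_that("per-gene subsampling caps benign/recessive at 1 and dominant at 3, preferring the longest transcript", {
  set.seed(5)
  mk <- function(label, gene, n, cds_len = 600) data.frame(
    label = label, gene_id = gene,
    transcript_id = paste0(gene, "_t", seq_len(n)),
    cds_length = cds_len, site_gerp = rnorm(n), stringsAsFactors = FALSE)
  corpus <- rbind(
    mk("recessive", "gr", 7),
    mk("dominant", "gd", 2),
    mk("dominant", "gd2", 5),
    mk("benign", "gb", 3),
    do.call(rbind, lapply(1:3, function(i)
      mk(c("benign", "recessive", "dominant")[i], paste0("gx", i), 1))))
  sub <- build_training_replicate(corpus, seed = 9)
  tab <- table(sub$label, sub$gene_id)
  expect_equal(unname(tab["recessive", "gr"]), 1)
  expect_equal(unname(tab["dominant", "gd"]), 2)   # cap not binding
  expect_equal(unname(tab["dominant", "gd2"]), 3)
  expect_equal(unname(tab["benign", "gb"]), 1)
  # determinism under a fixed seed
  expect_identical(sub, build_training_replicate(corpus, seed = 9))
  expect_false(identical(sub, build_training_replicate(corpus, seed = 10)))

  # longest-transcript preference
  corpus2 <- rbind(
    data.frame(label = "benign", gene_id = "g", transcript_id = "short",
               cds_length = 300, site_gerp = 0),
    data.frame(label = "benign", gene_id = "g", transcript_id = "long",
               cds_length = 900, site_gerp = 0),
    mk("recessive", "gr", 1), mk("dominant", "gd", 1))
  for (s in 1:5)
    expect_equal(build_training_replicate(
      corpus2, s)$transcript_id[1], "long")
  # an empty class errors
  expect_error(build_training_replicate(corpus2[-(1:2), ], 1),
               "no examples of class benign")
})

test_that("Hand-and-Till AUC matches the O(n^2) pairwise oracle and its closed-form anchors", {
  lab3 <- rep(c("benign", "recessive", "dominant"), each = 4)
  perfect <- matrix(0, 12, 3,
                    dimnames = list(NULL, c("benign", "recessive",
                                            "dominant")))
  perfect[cbind(1:12, rep(1:3, each = 4))] <- 1
  expect_equal(hand_till_auc(lab3, perfect), 1)
  constant <- matrix(1 / 3, 12, 3,
                     dimnames = list(NULL, colnames(perfect)))
  expect_equal(hand_till_auc(lab3, constant), 0.5)

  set.seed(6)
  # 12-example toy + 50 random score sets against the brute-force oracle
  for (i in 1:50) {
    n <- sample(9:24, 1)
    labs <- c("benign", "recessive", "dominant",
              sample(c("benign", "recessive", "dominant"), n - 3,
                     replace = TRUE))
    probs <- matrix(runif(3 * n), n, 3,
                    dimnames = list(NULL, colnames(perfect)))
    probs <- probs / rowSums(probs)
    if (i %% 7 == 0) probs <- round(probs, 1)   # force ties
    expect_equal(hand_till_auc(labs, probs), oracle_hand_till(labs, probs),
                 tolerance = 1e-12)
  }
})

test_that("with one class absent, the multiclass AUC reduces to the classical two-class AUC", {
  set.seed(7)
  labs <- rep(c("benign", "dominant"), each = 10)
  probs <- matrix(runif(60), 20, 3,
                  dimnames = list(NULL, c("benign", "recessive",
                                          "dominant")))
  expect_warning(m <- hand_till_auc(labs, probs), "recessive")
  # classical two-class ranking AUC by explicit pair counting on the
  # benign-score column
  sb <- probs[labs == "benign", "benign"]
  sd_ <- probs[labs == "dominant", "benign"]
  tot <- 0
  for (a in sb) for (b in sd_) tot <- tot + (a > b) + 0.5 * (a == b)
  auc_b <- tot / (length(sb) * length(sd_))
  # symmetrized with the dominant-score direction
  sb2 <- probs[labs == "dominant", "dominant"]
  sd2 <- probs[labs == "benign", "dominant"]
  tot2 <- 0
  for (a in sb2) for (b in sd2) tot2 <- tot2 + (a > b) + 0.5 * (a == b)
  expect_equal(m, (auc_b + tot2 / (length(sb2) * length(sd2))) / 2,
               tolerance = 1e-12)
  expect_error(suppressWarnings(
    hand_till_auc(rep("benign", 5), probs[1:5, ])), "at least 2")
})

test_that("precision and recall follow the TP/(TP+FP) and TP/(TP+FN) definitions", {
  labs <- rep(c("benign", "recessive", "dominant"), each = 4)
  pr <- precision_recall(labs, labs)
  expect_true(all(pr$precision == 1) && all(pr$recall == 1))

  # TP = 8, FP = 2, FN = 2 for class a
  labels <- c(rep("a", 10), rep("b", 10))
  predicted <- c(rep("a", 8), "b", "b", rep("b", 8), "a", "a")
  pr2 <- precision_recall(labels, predicted)
  expect_equal(pr2$precision[pr2$class == "a"], 0.8)
  expect_equal(pr2$recall[pr2$class == "a"], 0.8)
  expect_error(precision_recall(labels, predicted[-1]), "length")

  set.seed(8)
  for (i in 1:20) {
    n <- 30
    labels <- sample(c("benign", "recessive", "dominant"), n, replace = TRUE)
    predicted <- sample(c("benign", "recessive", "dominant"), n,
                        replace = TRUE)
    pr3 <- precision_recall(labels, predicted)
    for (k in unique(labels)) {
      o <- oracle_precision_recall(labels, predicted, k)
      expect_equal(pr3$precision[pr3$class == k], unname(o["precision"]),
                   tolerance = 1e-12)
      expect_equal(pr3$recall[pr3$class == k], unname(o["recall"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("ensemble aggregation averages replicates, breaks ties to benign, and reports dispersion", {
  cls <- c("benign", "recessive", "dominant")
  # constant replicates: mean is the constant, class is the argmax
  probs <- array(rep(c(0.1, 0.2, 0.7), each = 2), c(2, 3, 5),
                 dimnames = list(NULL, cls, NULL))
  out <- summarize_ensemble_probs(probs)
  expect_equal(out$p_dominant, c(0.7, 0.7))
  expect_equal(out$predicted_class, c("dominant", "dominant"))
  expect_equal(out$sd_benign, c(0, 0))
  expect_equal(out$confidence, c("High", "High"))

  # exact tie resolves to the least pathogenic class
  tie <- array(rep(c(0.4, 0.4, 0.2), each = 1), c(1, 3, 3),
               dimnames = list(NULL, cls, NULL))
  expect_equal(summarize_ensemble_probs(tie)$predicted_class, "benign")
  tie2 <- array(rep(c(0.1, 0.45, 0.45), each = 1), c(1, 3, 3),
                dimnames = list(NULL, cls, NULL))
  expect_equal(summarize_ensemble_probs(tie2)$predicted_class, "recessive")

  # random 5-replicate fixture: means/SDs equal direct arithmetic
  set.seed(9)
  raw <- array(runif(4 * 3 * 5), c(4, 3, 5), dimnames = list(NULL, cls, NULL))
  for (r in 1:5) raw[, , r] <- raw[, , r] / rowSums(raw[, , r])
  out2 <- summarize_ensemble_probs(raw)
  for (i in 1:4) {
    m <- c(mean(raw[i, 1, ]), mean(raw[i, 2, ]), mean(raw[i, 3, ]))
    s <- c(sd(raw[i, 1, ]), sd(raw[i, 2, ]), sd(raw[i, 3, ]))
    m <- m / sum(m)
    expect_equal(unlist(out2[i, 1:3], use.names = FALSE), m,
                 tolerance = 1e-12)
    expect_equal(unlist(out2[i, 4:6], use.names = FALSE), s,
                 tolerance = 1e-12)
    expect_equal(sum(out2[i, 1:3]), 1, tolerance = 1e-9)
  }
})

test_that("confidence labels equal the interval-arithmetic oracle", {
  expect_equal(confidence_label(c(0.8, 0.1, 0.1), c(0, 0, 0), 40), "High")
  expect_equal(confidence_label(c(0.45, 0.44, 0.11), c(0.3, 0.3, 0.05), 40),
               "Low")
  expect_warning(lab <- confidence_label(c(0.8, 0.1, 0.1), c(0, 0, 0), 1),
                 "fewer than 2")
  expect_equal(lab, "Low")
  set.seed(10)
  for (i in 1:100) {
    m <- runif(3); m <- m / sum(m)
    s <- runif(3, 0, 0.3)
    expect_equal(confidence_label(m, s, 40), oracle_confidence(m, s, 40))
  }
})

test_that("a smoke-config ensemble trains, predicts valid probabilities, and exposes importance", {
  corpus <- toy_corpus(n_per_class = 30, miss = 0.05, seed = 11)
  suppressWarnings(model <- train_ensemble(
    corpus, n_replicates = 2L, n_folds = 3L, ntree = 60L, base_seed = 3L))
  expect_s3_class(model, "EnsembleModel")
  expect_length(model$replicates, 2)
  expect_length(model$cv_auc, 2)
  expect_true(all(model$cv_auc > 0.5))   # strong planted signal

  pred <- predict(model, corpus)
  expect_equal(nrow(pred), nrow(corpus))
  expect_equal(rowSums(pred[, 1:3]), rep(1, nrow(corpus)),
               tolerance = 1e-9)
  expect_true(all(pred$predicted_class ==
    c("benign", "recessive", "dominant")[max.col(pred[, 1:3],
                                                 ties.method = "first")]))
  imp <- feature_importance(model)
  expect_true(all(c("site_gerp", "af_kg") %in% imp$feature))
  expect_error(predict(model, corpus[, 1:3]), "absent")
})

test_that("training, saving, and reloading preserve predictions byte for byte", {
  corpus <- toy_corpus(n_per_class = 25, seed = 12)
  m1 <- train_ensemble(corpus, n_replicates = 2L, ntree = 50L,
                       base_seed = 7L, cv = FALSE)
  m2 <- train_ensemble(corpus, n_replicates = 2L, ntree = 50L,
                       base_seed = 7L, cv = FALSE)
  p1 <- predict(m1, corpus)
  expect_identical(serialize(p1, NULL), serialize(predict(m2, corpus), NULL))

  f <- tempfile(fileext = ".rds")
  save_ensemble(m1, f)
  m3 <- load_ensemble(f)
  expect_identical(serialize(predict(m3, corpus), NULL),
                   serialize(p1, NULL))
})

test_that("planted class-dependent features outrank pure-noise features in importance", {
  set.seed(13)
  corpus <- toy_corpus(n_per_class = 40, seed = 13)
  corpus$expr_mean <- rnorm(nrow(corpus))          # pure noise
  corpus$gene_mirna_sites <- rnorm(nrow(corpus))   # pure noise
  model <- train_ensemble(corpus, n_replicates = 3L, ntree = 150L,
                          base_seed = 5L, cv = FALSE)
  imp <- feature_importance(model)
  rank_of <- function(f) which(imp$feature == f)
  expect_lt(rank_of("site_gerp"), rank_of("expr_mean"))
  expect_lt(rank_of("site_gerp"), rank_of("gene_mirna_sites"))
  expect_lt(rank_of("gene_syn_density"), rank_of("expr_mean"))
})
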