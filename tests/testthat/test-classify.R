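make_feature_tibble <- function(n_per_class, classes = c("A", "B"),
                                informative = TRUE, seed = 1, p_noise = 5) {
  withr::with_seed(seed, {
    n <- sum(n_per_class)
    lab <- rep(classes, n_per_class)
    ids <- sprintf("c%04d", seq_len(n))
    tab <- tibble::tibble(cell_id = ids)
    if (informative) {
      tab$f_signal <- match(lab, classes) + rnorm(n, 0, 0.05)
    }
    for (j in seq_len(p_noise)) tab[[paste0("f_noise", j)]] <- rnorm(n)
    list(table = tab, labels = stats::setNames(lab, ids))
  })
}

test_that("undersampling caps abundant classes and keeps minorities whole", {
  labels <- stats::setNames(
    rep(c("Int", "Ana", "Telo"), c(30000, 15, 25)),
    sprintf("c%05d", 1:30040))
  expect_warning(
    ts <- build_training_set(labels, cap = 100, seed = 9),
    "empty support")
  expect_equal(ts$counts_after, c(100, 0, 0, 15, 25))
  expect_equal(ts$counts_before, c(30000, 0, 0, 15, 25))
  expect_true(all(ts$counts_after <= pmax(ts$counts_before, 100)))

  labels2 <- stats::setNames(rep(c("Int", "Pro"), c(1000, 10)),
                             sprintf("d%04d", 1:1010))
  ts2 <- build_training_set(labels2, cap = 100, seed = 1,
                            class_order = c("Int", "Pro"))
  expect_equal(ts2$counts_after, c(100, 10))
  ts2b <- build_training_set(labels2, cap = 100, seed = 1,
                             class_order = c("Int", "Pro"))
  expect_identical(ts2$cell_ids, ts2b$cell_ids)
  expect_error(build_training_set(stats::setNames("Int", "x"), cap = 10),
               "2 classes")
})

test_that("both algorithms separate linearly separable classes and are deterministic", {
  fx <- make_feature_tibble(c(40, 40), informative = TRUE, seed = 2)
  ts <- build_training_set(fx$labels, cap = 100, seed = 1,
                           class_order = c("A", "B"))
  for (alg in c("gradient_boosting", "random_forest")) {
    mdl <- train_classifier(ts, fx$table, alg, seed = 5)
    expect_identical(predict(mdl, fx$table), unname(fx$labels))
    mdl2 <- train_classifier(ts, fx$table, alg, seed = 5)
    expect_identical(predict(mdl2, fx$table), predict(mdl, fx$table))
  }
  # single-class training is refused
  ts1 <- build_training_set(fx$labels, cap = 100, seed = 1,
                            class_order = c("A", "B"))
  ts1$labels[] <- "A"
  expect_error(train_classifier(ts1, fx$table, "gradient_boosting"),
               "single class")
})

test_that("training on the default synthetic population covers all phases", {
  tab <- filter_features(default_features())
  pop <- default_population()
  labels <- stats::setNames(pop$truth$phase, pop$truth$cell_id)[tab$cell_id]
  ts <- build_training_set(labels, cap = 100, seed = 42)
  mdl <- train_classifier(ts, tab, "gradient_boosting", seed = 42)
  preds <- predict(mdl, tab[tab$cell_id %in% ts$cell_ids, ])
  expect_setequal(unique(preds), phase_levels())
})

test_that("cross-validation is stratified, exhaustive and sane under permutation", {
  # perfectly separable: diagonal 100 everywhere
  fx <- make_feature_tibble(c(30, 30, 30), classes = c("A", "B", "C"),
                            seed = 3)
  fx$table$f_signal <- match(unname(fx$labels), c("A", "B", "C")) * 2
  ts <- build_training_set(fx$labels, cap = 100, seed = 1,
                           class_order = c("A", "B", "C"))
  ev <- cross_validate(ts, fx$table, "gradient_boosting", k = 5, seed = 2)
  expect_equal(unname(diag(ev$confusion)), rep(100, 3))

  # shuffled labels, 2 balanced classes: diagonal near 50%
  fx2 <- make_feature_tibble(c(200, 200), informative = FALSE, seed = 4)
  ev2 <- cross_validate(
    build_training_set(fx2$labels, cap = 500, seed = 1,
                       class_order = c("A", "B")),
    fx2$table, "gradient_boosting", k = 10, seed = 5)
  expect_true(all(abs(diag(ev2$confusion) - 50) <= 7 * 2))  # ~2x binomial SE*1.96
  expect_equal(unname(rowSums(ev2$confusion)), c(100, 100), tolerance = 1e-4)

  expect_error(cross_validate(ts, fx$table, k = 1000), "exceeds")
})

test_that("scoring excludes training cells by id only", {
  tab <- filter_features(default_features())
  pop <- default_population()
  labels <- stats::setNames(pop$truth$phase, pop$truth$cell_id)[tab$cell_id]
  ts <- build_training_set(labels, cap = 100, seed = 42)
  mdl <- train_classifier(ts, tab, "gradient_boosting", seed = 42)
  sc <- score_all(mdl, tab)
  expect_equal(nrow(sc), nrow(tab) - length(ts$cell_ids))
  expect_length(intersect(sc$cell_id, ts$cell_ids), 0)

  # a clone of a training cell under a new id is still scored
  clone <- tab[tab$cell_id == ts$cell_ids[1], ]
  clone$cell_id <- "clone_001"
  sc2 <- score_all(mdl, dplyr::bind_rows(tab, clone))
  expect_true("clone_001" %in% sc2$cell_id)

  # missing feature column is named
  expect_error(predict(mdl, tab[, 1:10]), "lacks column")
})

test_that("confusion matrices are row-normalised with TPR on the diagonal", {
  ev <- confusion_matrix_pct(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                             class_order = c("A", "B"))
  expect_equal(unname(ev$confusion), rbind(c(50, 50), c(0, 100)))
  expect_equal(unname(ev$tpr), c(50, 100))

  perfect <- confusion_matrix_pct(rep(phase_levels(), 3),
                                  rep(phase_levels(), 3))
  expect_equal(unname(diag(perfect$confusion)), rep(100, 5))
  expect_equal(unname(perfect$confusion[perfect$confusion != 100]),
               rep(0, 20))

  # the prophase montage arithmetic: 166 correct of 224
  truth <- rep("Pro", 224)
  pred <- c(rep("Pro", 166), rep("Meta", 20), rep("Telo", 1), rep("Int", 37))
  evp <- confusion_matrix_pct(truth, pred)
  expect_equal(round(evp$confusion["Pro", "Pro"], 2), 74.11)
  expect_true(all(is.na(evp$confusion["Ana", ])))  # zero support -> blank
  expect_equal(glance(evp)$n_classes, 1)

  expect_error(confusion_matrix_pct("G2", "Int"), "outside")

  td <- tidy(evp)
  expect_equal(nrow(td), 25)
  expect_equal(sum(td$pct[td$true == "Pro"]), 100, tolerance = 1e-6)
})

test_that("feature ranking is importance-sorted, deterministic and finds planted signal", {
  # only DF granularity differs between classes
  withr::with_seed(20, {
    n <- 60
    lab <- rep(c("Int", "Pro"), each = n)
    ids <- sprintf("g%04d", seq_len(2 * n))
    tab <- tibble::tibble(cell_id = ids,
                          SSC_Granularity_1_DF_image =
                            c(rnorm(n, 10, 1), rnorm(n, 40, 1)))
    for (j in 1:10) tab[[paste0("BF_AreaShape_Zernike_", j, "_0")]] <-
        rnorm(2 * n)
    labels <- stats::setNames(lab, ids)
  })
  ts <- suppressWarnings(build_training_set(labels, cap = 100, seed = 1))
  mdl <- train_classifier(ts, tab, "gradient_boosting", seed = 2)
  rk <- rank_features(mdl, 3)
  expect_true("SSC_Granularity_1_DF_image" %in% rk$feature)
  expect_true(all(diff(rk$score) <= 0))

  rk_full <- rank_features(mdl, 1000)
  expect_equal(nrow(rk_full), 11)
  mdl2 <- train_classifier(ts, tab, "gradient_boosting", seed = 2)
  expect_identical(rank_features(mdl2, 5), rank_features(mdl, 5))
})
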