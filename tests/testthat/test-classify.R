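test_that("fitting trains a forest for every non-degenerate node", {
  fx <- small_fixture()
  model <- fx$model
  nodes <- hftc_nodes(model$hierarchy)
  for (nd in nodes) {
    rf <- model$forests[[nd$name]]
    if (nd$degenerate) {
      expect_null(rf)
    } else {
      expect_s3_class(rf, "ranger")
      expect_setequal(rf$forest$levels, nd$class_labels)
    }
  }
  # leaf nodes use k_species, routing nodes k_upper
  for (nd in nodes)
    expect_equal(model$node_ks[[nd$name]],
                 if (nd$is_leaf) 6L else 8L)
})

test_that("training-set replay recovers the training species", {
  fx <- small_fixture()
  preds <- predict(fx$model, fx$cur)
  expect_gt(mean(preds$species == fx$cur$species), 0.95)
})

test_that("predicted lineages are consistent taxonomy paths by construction", {
  fx <- small_fixture()
  preds <- predict(fx$model, fx$held)
  map <- fx$model$species_map
  for (i in seq_len(nrow(preds))) {
    m <- map[map$species == preds$species[i], ]
    expect_equal(nrow(m), 1L)
    expect_equal(unlist(preds[i, c("phylum", "class", "order", "family",
                                   "genus")], use.names = FALSE),
                 unlist(m[, c("phylum", "class", "order", "family",
                              "genus")], use.names = FALSE))
  }
  # confidences populated and in [0, 1]
  confs <- as.matrix(preds[, grep("^conf_", names(preds))])
  expect_true(all(confs >= 0 & confs <= 1))
})

test_that("an unreachable confidence threshold stops at the kingdom", {
  fx <- small_fixture()
  preds <- predict(fx$model, fx$held[1:3, ], min_confidence = 1.01)
  expect_equal(preds$kingdom, rep("Fungi", 3))
  expect_true(all(is.na(preds$phylum)))
  expect_true(all(is.na(preds$species)))
})

test_that("batch prediction preserves order and tolerates bad queries", {
  fx <- small_fixture()
  seqs <- c(good1 = fx$held$sequence[1], bad = "ACGTNACGT",
            short = "ACG", good2 = fx$held$sequence[2])
  preds <- predict(fx$model, seqs)
  expect_equal(preds$id, c("good1", "bad", "short", "good2"))
  expect_setequal(attr(preds, "failed"), c("bad", "short"))
  expect_true(all(is.na(preds$species[2:3])))
  expect_false(anyNA(preds$species[c(1, 4)]))
  # batch output equals record-wise prediction
  one <- predict(fx$model, seqs[1])
  expect_equal(preds$species[1], one$species[1])
  expect_equal(preds$conf_species[1], one$conf_species[1])
  # empty input -> empty output
  expect_equal(nrow(predict(fx$model, character())), 0L)
})

test_that("flat (T = Inf) and deep (T = 1) models agree on the training set", {
  fx <- small_fixture()
  feats <- feature_config(k_upper = 8, k_species = 6, N = 16,
                          epochs = 2, seed = 7)
  flat <- hftc(fx$cur, hierarchy_config(group_threshold = Inf),
               feats, forest_config(n_trees = 60, seed = 7))
  expect_length(hftc_nodes(flat$hierarchy), 1L)
  deep <- hftc(fx$cur, hierarchy_config(group_threshold = 1),
               feats, forest_config(n_trees = 60, seed = 7))
  p_flat <- predict(flat, fx$cur)
  p_deep <- predict(deep, fx$cur)
  expect_equal(mean(p_flat$species == fx$cur$species), 1.0)
  expect_equal(mean(p_deep$species == fx$cur$species), 1.0)
  # the infinite threshold survives the JSON manifest round trip
  dir <- withr::local_tempdir()
  save_hftc(flat, dir)
  back <- load_hftc(dir)
  expect_identical(back$configs$hierarchy$group_threshold, Inf)
  expect_equal(predict(back, fx$cur[1:5, ])$species, p_flat$species[1:5])
})

test_that("per-node hybrid k overrides concatenate feature blocks", {
  fx <- small_fixture()
  sub <- hftc_dataset(fx$cur[fx$cur$phylum == "P1", ])
  m <- hftc(sub, hierarchy_config(group_threshold = Inf),
            feature_config(k_species = 6, N = 10, epochs = 1, seed = 3,
                           k_overrides = list(Fungi2s = c(5, 7))),
            forest_config(n_trees = 40, seed = 3))
  expect_equal(m$node_ks[["Fungi2s"]], c(5L, 7L))
  expect_setequal(names(m$embeddings), c("5", "7"))
  # forest saw 2 x 2N = 40 features
  expect_equal(m$forests[["Fungi2s"]]$num.independent.variables, 40L)
  preds <- predict(m, sub[1:8, ])
  expect_equal(preds$species, sub$species[1:8])
})

test_that("retraining with identical seeds reproduces the model exactly", {
  fx <- small_fixture()
  sub <- hftc_dataset(fx$cur[fx$cur$phylum == "P1", ])
  args <- list(hierarchy = hierarchy_config(group_threshold = 3),
               features = feature_config(k_upper = 7, k_species = 5,
                                         N = 12, epochs = 2, seed = 13),
               forest = forest_config(n_trees = 40, seed = 13))
  m1 <- do.call(hftc, c(list(sub), args))
  m2 <- do.call(hftc, c(list(sub), args))
  expect_identical(m1$embeddings[["5"]]$vectors,
                   m2$embeddings[["5"]]$vectors)
  p1 <- predict(m1, fx$held)
  p2 <- predict(m2, fx$held)
  expect_identical(p1, p2)
})

test_that("models survive a save/load round trip", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  save_hftc(fx$model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "species_lineage.tsv")))
  back <- load_hftc(dir)
  p1 <- predict(fx$model, fx$held)
  p2 <- predict(back, fx$held)
  expect_equal(p1$species, p2$species)
  expect_equal(p1$conf_species, p2$conf_species, tolerance = 1e-5)
  # tampering with the version triggers the retrain error
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  man$format_version <- "0.0"
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_hftc(dir), "retrain required")
})

test_that("select_k scans candidates and breaks ties toward smaller k", {
  fx <- small_fixture()
  root <- fx$model$hierarchy
  # single candidate is returned as-is
  res1 <- select_k(fx$cur, root, k_candidates = 6, folds = 3,
                   features = feature_config(N = 12, epochs = 1))
  expect_equal(res1$k, 6L)
  # on well-separated phyla both k give perfect CV accuracy -> tie ->
  # the smaller k wins
  res2 <- select_k(fx$cur, root, k_candidates = c(6, 8), folds = 3,
                   features = feature_config(N = 12, epochs = 1))
  expect_equal(nrow(res2$accuracy), 2L)
  if (res2$accuracy$mean_accuracy[1] == res2$accuracy$mean_accuracy[2])
    expect_equal(res2$k, 6L)
  expect_true(res2$k %in% c(6L, 8L))
  expect_error(select_k(fx$cur, root, integer()), "empty candidate")
})

test_that("classes with fewer records than folds are excluded with a warning", {
  fx <- small_fixture()
  # craft a node-level shortage: species leaf with a 1-record class
  tiny <- hftc_dataset(fx$cur[c(1:20, which(fx$cur$species ==
                                              fx$cur$species[30])[1]), ])
  expect_warning(
    select_k(tiny, build_hierarchy(tiny,
                                   hierarchy_config(group_threshold = Inf)),
             k_candidates = 5, folds = 5,
             features = feature_config(N = 8, epochs = 1)),
    "fewer records than folds")
})
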