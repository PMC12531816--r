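# Model fitting and prediction: one random forest per hierarchy node on
# pooled k-mer embeddings, level-appropriate k (k = 10 for routing
# ranks, k = 7 for species leaves), and root-to-leaf traversal that
# yields consistent lineages by construction.

#' Feature configuration
#'
#' @param k_upper k-mer length for routing nodes (phylum..family
#'   decisions); default 10.
#' @param k_species k-mer length for species-level leaves; default 7.
#' @param stride Sliding-window stride L (default 1).
#' @param N Embedding dimension per direction (default 100; sequence
#'   vectors have 2N = 200 entries).
#' @param window,epochs,negative,min_count Skip-gram training
#'   parameters, see [train_embedding()].
#' @param seed Seed for embedding training.
#' @param k_overrides Optional named list: node name -> k value(s). A
#'   vector of several k gives that node a hybrid (concatenated)
#'   representation.
#' @return A `feature_config` list.
#' @export
feature_config <- function(k_upper = 10L, k_species = 7L, stride = 1L,
                           N = 100L, window = 5L, epochs = 5L,
                           negative = 5L, min_count = 1L, seed = 1L,
                           k_overrides = list()) {
  ks <- c(k_upper, k_species, unlist(k_overrides))
  stopifnot(all(ks >= 1 & ks <= 15), stride >= 1, N >= 1)
  structure(list(k_upper = as.integer(k_upper),
                 k_species = as.integer(k_species),
                 stride = as.integer(stride), N = as.integer(N),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative),
                 min_count = as.integer(min_count), seed = as.integer(seed),
                 k_overrides = k_overrides),
            class = "feature_config")
}

#' Random-forest configuration
#'
#' @param n_trees Trees per forest (default 100).
#' @param max_features Features tried at each split: an integer, or
#'   `"sqrt"`/`"log2"` of the feature count (default `"sqrt"`).
#' @param seed Seed for forest training.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 100L, max_features = "sqrt",
                          seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_features = max_features, seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(max_features, p) {
  if (is.numeric(max_features)) return(min(as.integer(max_features), p))
  switch(max_features,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown max_features: ", max_features))
}

# k value(s) a node uses, ascending
node_k <- function(node, features) {
  ov <- features$k_overrides[[node$name]]
  ks <- if (!is.null(ov)) as.integer(ov)
        else if (node$is_leaf) features$k_species
        else features$k_upper
  sort(unique(ks))
}

#' Fit a hierarchical fungal taxonomy classifier
#'
#' Builds the classifier tree from the training lineages, trains one
#' skip-gram k-mer embedding per distinct k in use on the full corpus
#' (both orientations), then fits a probability random forest at every
#' non-degenerate node on the pooled sequence vectors of the records
#' under that node. Fully deterministic for fixed seeds (embedding and
#' forest training are single-threaded).
#'
#' @param dataset A curated `hftc_dataset` (strict ACGT sequences, full
#'   lineages, unique species names).
#' @param hierarchy A [hierarchy_config()].
#' @param features A [feature_config()].
#' @param forest A [forest_config()].
#' @param verbose Print progress.
#' @return An object of class `hftc`: the hierarchy, per-node forests,
#'   per-k embeddings, the species-to-lineage map and the configs.
#' @seealso [predict.hftc()], [save_hftc()], [evaluate()]
#' @export
hftc <- function(dataset, hierarchy = hierarchy_config(),
                 features = feature_config(), forest = forest_config(),
                 verbose = FALSE) {
  if (!inherits(dataset, "hftc_dataset")) dataset <- hftc_dataset(dataset)
  if (anyNA(dataset[RANKS]))
    stop("training requires full 7-rank lineages")
  if (!all(grepl("^[ACGT]+$", dataset$sequence)))
    stop("training sequences must be curated to the strict ACGT alphabet")
  sp_map <- unique(dataset[RANKS])
  if (anyDuplicated(sp_map$species))
    stop("species names must be unique across the taxonomy (found ",
         "homonymous species labels)")
  rownames(sp_map) <- NULL

  tree <- build_hierarchy(dataset, hierarchy)
  nodes <- hftc_nodes(tree)
  ks <- sort(unique(unlist(lapply(nodes, node_k, features = features))))
  if (min(nchar(dataset$sequence)) < max(ks))
    stop("some sequences are shorter than the largest k in use (",
         max(ks), ")")

  embeddings <- list()
  feats <- list()
  for (k in ks) {
    if (verbose) message("training k = ", k, " embedding")
    corpus <- build_corpus(dataset, k, features$stride)
    embeddings[[as.character(k)]] <-
      train_embedding(corpus, N = features$N, window = features$window,
                      epochs = features$epochs,
                      negative = features$negative,
                      min_count = features$min_count,
                      seed = features$seed)
    feats[[as.character(k)]] <-
      embed_dataset(dataset, embeddings[[as.character(k)]],
                    features$stride)
  }

  forests <- list()
  node_ks <- list()
  for (nd in nodes) {
    ksn <- node_k(nd, features)
    node_ks[[nd$name]] <- ksn
    idx <- node_record_index(dataset, nd)
    labels <- node_labels_vec(dataset, nd, idx)
    if (length(unique(labels)) < 2L) next  # degenerate: no router needed
    X <- do.call(cbind, lapply(as.character(ksn),
                               function(kk) feats[[kk]][idx, , drop = FALSE]))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    if (verbose)
      message("fitting ", nd$name, ": ", length(unique(labels)),
              " classes, ", sum(idx), " records")
    forests[[nd$name]] <-
      ranger::ranger(x = as.data.frame(X), y = factor(labels),
                     num.trees = forest$n_trees,
                     mtry = resolve_mtry(forest$max_features, ncol(X)),
                     probability = TRUE, seed = forest$seed,
                     num.threads = 1L)
  }

  structure(list(hierarchy = tree, forests = forests,
                 embeddings = embeddings, species_map = sp_map,
                 node_ks = node_ks,
                 configs = list(hierarchy = hierarchy, features = features,
                                forest = forest),
                 n_train = nrow(dataset), format_version = "1.0"),
            class = "hftc")
}

# logical index of the dataset records a node is trained on
node_record_index <- function(dataset, node) {
  idx <- records_under(dataset, node$taxon_path)
  if (!is.null(node$other_members)) {
    r <- other_rank(node)
    idx <- idx & !is.na(dataset[[r]]) & dataset[[r]] %in% node$other_members
  }
  idx
}

node_labels_vec <- function(dataset, node, idx) {
  sub <- dataset[idx, , drop = FALSE]
  if (node$is_leaf) return(sub$species)
  labels <- sub[[node$child_rank]]
  for (lab in names(node$children)) {
    ch <- node$children[[lab]]
    if (!is.null(ch$other_members))
      labels[labels %in% ch$other_members] <- lab
  }
  labels
}

#' @export
print.hftc <- function(x, ...) {
  nodes <- hftc_nodes(x$hierarchy)
  n_leaf <- sum(vapply(nodes, `[[`, TRUE, "is_leaf"))
  cat(sprintf(paste0("<hftc> hierarchical taxonomy classifier\n",
                     "  %d sub-classifier nodes (%d routing, %d species",
                     " leaves), %d trained forests\n",
                     "  %d training records, %d species\n",
                     "  k: %s (routing %d, species %d); embedding dim 2N",
                     " = %d\n"),
              length(nodes), length(nodes) - n_leaf, n_leaf,
              length(x$forests), x$n_train, nrow(x$species_map),
              paste(names(x$embeddings), collapse = ", "),
              x$configs$features$k_upper, x$configs$features$k_species,
              2L * x$configs$features$N))
  invisible(x)
}

#' @export
summary.hftc <- function(object, ...) {
  nodes <- hftc_nodes(object$hierarchy)
  tab <- do.call(rbind, lapply(nodes, function(nd) {
    rf <- object$forests[[nd$name]]
    data.frame(node = nd$name,
               role = if (nd$is_leaf) "species leaf" else
                 paste0(nd$rank_from, " -> ", nd$child_rank),
               classes = length(nd$class_labels),
               species = length(nd$species),
               k = paste(object$node_ks[[nd$name]], collapse = "+"),
               oob_accuracy = if (is.null(rf)) NA_real_
                              else 1 - rf$prediction.error,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(nodes = tab, n_train = object$n_train,
                 n_species = nrow(object$species_map)),
            class = "summary.hftc")
}

#' @export
print.summary.hftc <- function(x, ...) {
  cat(sprintf("hftc model: %d records, %d species\n", x$n_train,
              x$n_species))
  print(x$nodes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.hftc <- function(x, ...) {
  s <- summary(x)$nodes
  s <- s[!is.na(s$oob_accuracy), , drop = FALSE]
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(s$oob_accuracy, names.arg = s$node, las = 2,
                    ylim = c(0, 1), ylab = "OOB accuracy",
                    main = "Per-node out-of-bag accuracy", ...)
  invisible(x)
}

#' Predict full lineages for query sequences
#'
#' Each query is routed from the root: at every node it is embedded
#' with that node's k, the forest's highest-probability class is taken
#' (ties break to the lexicographically smallest label), and traversal
#' descends until a species decision. The returned lineage is resolved
#' from the species-to-lineage map, so every prediction is a consistent
#' root-to-species path of the reference taxonomy. Ranks decided by a
#' routing forest carry that decision's probability; ranks inherited
#' from the species map carry the species decision's probability.
#'
#' @param object A fitted `hftc` model.
#' @param newdata An `hftc_dataset`, or a character vector of sequences
#'   (optionally named with query ids).
#' @param min_confidence Optional threshold: when a node's top
#'   probability falls below it, traversal stops and ranks below the
#'   last confident decision are `NA`.
#' @param ... Unused.
#' @return Data frame: `id`, the seven rank columns, `conf_phylum` ...
#'   `conf_species`, and `node_path` (visited nodes, `>`-separated).
#'   Queries that are too short or contain non-ACGT characters get
#'   all-`NA` rows and are listed in `attr(result, "failed")`.
#' @export
predict.hftc <- function(object, newdata, min_confidence = NULL, ...) {
  if (inherits(newdata, "hftc_dataset") || is.data.frame(newdata)) {
    ids <- newdata$id
    seqs <- newdata$sequence
  } else {
    seqs <- as.character(newdata)
    ids <- if (!is.null(names(newdata))) names(newdata)
           else sprintf("q%d", seq_along(seqs))
  }
  n <- length(seqs)
  max_k <- max(as.integer(names(object$embeddings)))
  valid <- grepl("^[ACGT]+$", seqs) & nchar(seqs) >= max_k

  res <- cbind(data.frame(id = ids, kingdom = rep(NA_character_, n),
                          stringsAsFactors = FALSE),
               empty_pred_block(n))
  if (any(valid)) {
    stride <- object$configs$features$stride
    sub <- data.frame(id = ids[valid], sequence = seqs[valid],
                      stringsAsFactors = FALSE)
    X <- lapply(object$embeddings, function(m)
      embed_dataset(sub, m, stride))
    filled <- route_node(object, object$hierarchy, seq_len(nrow(sub)), X,
                         min_confidence, empty_pred_block(nrow(sub)))
    res[valid, names(filled)] <- filled
    res$kingdom[valid] <- object$hierarchy$taxon_path[["kingdom"]]
  }
  attr(res, "failed") <- ids[!valid]
  res
}

# Route a group of query rows through one node. `decided` is a data
# frame (one row per query in `rows`) of the rank names / confidences
# fixed so far; returns the completed prediction block for those rows.
route_node <- function(object, node, rows, X, min_confidence, decided) {
  out <- empty_pred_block(length(rows))
  decided$node_path <- ifelse(is.na(decided$node_path), node$name,
                              paste(decided$node_path, node$name,
                                    sep = ">"))

  if (node$degenerate && !node$is_leaf) {
    # single-class router: deterministic descent, no forest
    lab <- node$class_labels[1L]
    child <- node$children[[lab]]
    if (is.null(child$other_members)) {
      decided[[node$child_rank]] <- lab
      decided[[conf_col(node$child_rank)]] <- 1
    }
    return(route_node(object, child, rows, X, min_confidence, decided))
  }

  if (node$is_leaf && node$degenerate) {
    return(resolve_species(object, rep(node$species, length(rows)),
                           rep(1, length(rows)), decided))
  }

  pr <- node_probs(object, node, rows, X)
  pick <- apply_argmax(pr)
  labels <- pick$labels[pick$ix]
  conf <- pick$p
  stopped <- if (is.null(min_confidence)) rep(FALSE, length(rows))
             else conf < min_confidence
  if (any(stopped)) out[stopped, ] <- decided[stopped, , drop = FALSE]
  if (all(stopped)) return(out)

  if (node$is_leaf) {
    ok <- !stopped
    out[ok, ] <- resolve_species(object, labels[ok], conf[ok],
                                 decided[ok, , drop = FALSE])
    return(out)
  }

  for (lab in unique(labels[!stopped])) {
    sel <- which(labels == lab & !stopped)
    child <- node$children[[lab]]
    dec <- decided[sel, , drop = FALSE]
    if (is.null(child$other_members)) {
      dec[[node$child_rank]] <- lab
      dec[[conf_col(node$child_rank)]] <- conf[sel]
    }
    out[sel, ] <- route_node(object, child, rows[sel], X, min_confidence,
                             dec)
  }
  out
}

conf_col <- function(rank) paste0("conf_", rank)

# fill the remaining ranks from the species->lineage map; ranks without
# a router decision inherit the species decision's confidence
resolve_species <- function(object, species, conf, decided) {
  m <- match(species, object$species_map$species)
  for (r in RANKS[-1]) decided[[r]] <- object$species_map[[r]][m]
  for (r in c("phylum", "class", "order", "family")) {
    cc <- conf_col(r)
    decided[[cc]] <- ifelse(is.na(decided[[cc]]), conf, decided[[cc]])
  }
  decided$conf_species <- conf
  decided
}

node_probs <- function(object, node, rows, X) {
  ks <- object$node_ks[[node$name]]
  M <- do.call(cbind, lapply(as.character(ks),
                             function(kk) X[[kk]][rows, , drop = FALSE]))
  colnames(M) <- paste0("f", seq_len(ncol(M)))
  predict(object$forests[[node$name]],
          data = as.data.frame(M), num.threads = 1L)$predictions
}

# argmax with lexicographic tie-break (columns scanned in sorted order)
apply_argmax <- function(pr) {
  ord <- order(colnames(pr))
  pr <- pr[, ord, drop = FALSE]
  ix <- max.col(pr, ties.method = "first")
  list(ix = ix, p = pr[cbind(seq_len(nrow(pr)), ix)],
       labels = colnames(pr))
}

empty_pred_block <- function(n) {
  cols <- c(lapply(RANKS[-1], function(r) rep(NA_character_, n)),
            lapply(1:5, function(i) rep(NA_real_, n)),
            list(rep(NA_character_, n)))
  names(cols) <- c(RANKS[-1],
                   paste0("conf_", c("phylum", "class", "order",
                                     "family", "species")),
                   "node_path")
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

#' Select the k-mer length for a node by cross-validation
#'
#' For each candidate k an embedding is trained on the full dataset
#' corpus, the node's records are embedded and a stratified k-fold
#' cross-validation of the node's forest is run; the accuracy-maximizing
#' k is returned, ties breaking to the smaller k. Classes with fewer
#' records than folds are excluded with a warning.
#'
#' @param dataset A curated `hftc_dataset`.
#' @param node A `hierarchy_node` (from [build_hierarchy()]).
#' @param k_candidates Candidate k values (default 7:11).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @param features,forest Configurations for embedding and forest
#'   training.
#' @return List of class `hftc_kselect`: `k` (chosen) and `accuracy`
#'   (data frame of per-k mean CV accuracies).
#' @export
select_k <- function(dataset, node, k_candidates = 7:11, folds = 5L,
                     seed = 1L, features = feature_config(),
                     forest = forest_config()) {
  if (length(k_candidates) == 0L) stop("empty candidate set")
  idx <- node_record_index(dataset, node)
  labels <- node_labels_vec(dataset, node, idx)
  sub <- dataset[idx, , drop = FALSE]
  sizes <- table(labels)
  small <- names(sizes)[sizes < folds]
  if (length(small)) {
    warning("excluding ", length(small),
            " class(es) with fewer records than folds")
    keep <- !labels %in% small
    sub <- sub[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L)
    stop("node has fewer than 2 usable classes")
  fold_of <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      f[ix[sample.int(length(ix))]] <-
        rep_len(seq_len(folds), length(ix))
    }
    f
  })
  accs <- vapply(k_candidates, function(k) {
    emb <- train_embedding(build_corpus(dataset, k, features$stride),
                           N = features$N, window = features$window,
                           epochs = features$epochs,
                           negative = features$negative,
                           min_count = features$min_count,
                           seed = features$seed)
    Xn <- embed_dataset(sub, emb, features$stride)
    colnames(Xn) <- paste0("f", seq_len(ncol(Xn)))
    fold_acc <- vapply(seq_len(folds), function(fo) {
      tr <- fold_of != fo
      rf <- ranger::ranger(x = as.data.frame(Xn[tr, , drop = FALSE]),
                           y = factor(labels[tr]),
                           num.trees = forest$n_trees,
                           mtry = resolve_mtry(forest$max_features,
                                               ncol(Xn)),
                           seed = forest$seed, num.threads = 1L)
      pred <- predict(rf, data = as.data.frame(Xn[!tr, , drop = FALSE]),
                      num.threads = 1L)$predictions
      mean(as.character(pred) == labels[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  tab <- data.frame(k = as.integer(k_candidates), mean_accuracy = accs)
  best <- tab$k[order(-tab$mean_accuracy, tab$k)][1L]
  structure(list(k = best, accuracy = tab), class = "hftc_kselect")
}

#' @export
print.hftc_kselect <- function(x, ...) {
  cat("k selected by cross-validation:", x$k, "\n")
  print(x$accuracy, row.names = FALSE, digits = 4)
  invisible(x)
}
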