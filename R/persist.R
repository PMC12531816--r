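# Model directory layout:
#   manifest.json        format_version, configs, hierarchy, file index
#   species_lineage.tsv  species -> full lineage map
#   embeddings/k<k>.w2v.txt   word2vec text format, one file per k
#   forests/<node>.rds   serialized per-node classifiers

HFTC_FORMAT_VERSION <- "1.0"

node_to_list <- function(node) {
  list(name = node$name, taxon = node$taxon,
       taxon_path = as.list(node$taxon_path),
       rank_from = node$rank_from, child_rank = node$child_rank,
       class_labels = as.list(node$class_labels),
       children = lapply(node$children, node_to_list),
       is_leaf = node$is_leaf, degenerate = node$degenerate,
       species = as.list(node$species),
       other_members = if (is.null(node$other_members)) NULL
                       else as.list(node$other_members))
}

list_to_node <- function(x) {
  structure(list(name = x$name, taxon = x$taxon,
                 taxon_path = unlist(x$taxon_path),
                 rank_from = x$rank_from, child_rank = x$child_rank,
                 class_labels = as.character(unlist(x$class_labels)),
                 children = lapply(x$children, list_to_node),
                 is_leaf = isTRUE(x$is_leaf),
                 degenerate = isTRUE(x$degenerate),
                 species = as.character(unlist(x$species)),
                 other_members = if (length(x$other_members))
                   as.character(unlist(x$other_members)) else NULL),
            class = "hierarchy_node")
}

#' Save a fitted model to a directory
#'
#' @param model A fitted `hftc` object.
#' @param dir Target directory (created if needed).
#' @export
save_hftc <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "embeddings"), showWarnings = FALSE)
  dir.create(file.path(dir, "forests"), showWarnings = FALSE)
  for (k in names(model$embeddings))
    write_embedding(model$embeddings[[k]],
                    file.path(dir, "embeddings",
                              paste0("k", k, ".w2v.txt")))
  for (nm in names(model$forests))
    saveRDS(model$forests[[nm]],
            file.path(dir, "forests", paste0(nm, ".rds")))
  write.table(model$species_map,
              file.path(dir, "species_lineage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- model$configs
  manifest <- list(
    format_version = HFTC_FORMAT_VERSION,
    n_train = model$n_train,
    hierarchy = node_to_list(model$hierarchy),
    node_ks = model$node_ks,
    configs = list(
      hierarchy = unclass(cfg$hierarchy),
      features = unclass(cfg$features),
      forest = unclass(cfg$forest)),
    embeddings = as.integer(names(model$embeddings)),
    forests = names(model$forests))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Load a fitted model from a directory
#'
#' @param dir Directory written by [save_hftc()].
#' @return An `hftc` object.
#' @export
load_hftc <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath)
  if (!identical(man$format_version, HFTC_FORMAT_VERSION))
    stop("model format version ", man$format_version,
         " not supported by this package version: retrain required")
  cfg <- man$configs
  features <- do.call(feature_config,
                      c(cfg$features[setdiff(names(cfg$features),
                                             "k_overrides")],
                        list(k_overrides = lapply(cfg$features$k_overrides,
                                                  unlist))))
  hcfg <- lapply(cfg$hierarchy, function(v)
    if (is.null(v)) NULL else unlist(v))
  # Inf survives JSON only as the string "Inf"
  for (nm in c("group_threshold", "max_leaf_classes"))
    if (!is.null(hcfg[[nm]])) hcfg[[nm]] <- as.numeric(hcfg[[nm]])
  hierarchy <- do.call(hierarchy_config, hcfg)
  forest <- do.call(forest_config, cfg$forest)
  embeddings <- list()
  for (k in unlist(man$embeddings))
    embeddings[[as.character(k)]] <-
      read_embedding(file.path(dir, "embeddings",
                               paste0("k", k, ".w2v.txt")))
  forests <- list()
  for (nm in unlist(man$forests))
    forests[[nm]] <- readRDS(file.path(dir, "forests",
                                       paste0(nm, ".rds")))
  sp_map <- read.delim(file.path(dir, "species_lineage.tsv"), sep = "\t",
                       quote = "", stringsAsFactors = FALSE,
                       colClasses = "character")
  structure(list(hierarchy = list_to_node(man$hierarchy),
                 forests = forests, embeddings = embeddings,
                 species_map = sp_map,
                 node_ks = lapply(man$node_ks, function(v)
                   as.integer(unlist(v))),
                 configs = list(hierarchy = hierarchy, features = features,
                                forest = forest),
                 n_train = man$n_train,
                 format_version = man$format_version),
            class = "hftc")
}
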