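# Recursive construction of the classifier tree: taxa with at least T
# species are expanded one rank deeper (phylum -> class -> order ->
# family); smaller taxa are merged into an "Other" species-level leaf;
# family-rank taxa always classify species directly, so genus is never a
# routing rank.

#' Hierarchy configuration
#'
#' @param group_threshold Grouping threshold T: a child taxon with fewer
#'   than T species (or sequences, see `unit`) is merged into the node's
#'   "Other" species-level leaf. Default 1000. `Inf` collapses the tree
#'   to a single flat species classifier.
#' @param unit Whether T counts distinct `"species"` (default) or
#'   `"sequences"`.
#' @param deepest_routing_rank Deepest rank whose members may themselves
#'   be split (default `"family"`; family-rank taxa become species
#'   leaves).
#' @param max_leaf_classes Optional cap on the number of species in one
#'   "Other" leaf; when exceeded the merged taxa are split alphabetically
#'   into chunks `Other1`, `Other2`, ...
#' @return A `hierarchy_config` list.
#' @export
hierarchy_config <- function(group_threshold = 1000, unit = c("species",
                                                              "sequences"),
                             deepest_routing_rank = "family",
                             max_leaf_classes = NULL) {
  unit <- match.arg(unit)
  stopifnot(group_threshold >= 1,
            deepest_routing_rank %in% RANKS[1:5])
  structure(list(group_threshold = group_threshold, unit = unit,
                 deepest_routing_rank = deepest_routing_rank,
                 max_leaf_classes = max_leaf_classes),
            class = "hierarchy_config")
}

# logical index of records whose lineage passes through taxon_path
records_under <- function(dataset, taxon_path) {
  keep <- rep(TRUE, nrow(dataset))
  for (r in names(taxon_path))
    keep <- keep & !is.na(dataset[[r]]) & dataset[[r]] == taxon_path[[r]]
  keep
}

#' Count species per child taxon under a lineage prefix
#'
#' @param dataset A curated `hftc_dataset` with full lineages.
#' @param taxon_path Named character vector of ranks already fixed
#'   (e.g. `c(kingdom = "Fungi", phylum = "Ascomycota")`).
#' @param rank Child rank at which to count.
#' @return Named integer vector: child taxon -> number of distinct
#'   species under it (within this path, so rank-name homonyms in other
#'   branches are counted separately).
#' @export
count_species <- function(dataset, taxon_path, rank) {
  if (!rank %in% RANKS) stop("unknown rank: ", rank)
  sub <- dataset[records_under(dataset, taxon_path), , drop = FALSE]
  if (nrow(sub) == 0L) return(setNames(integer(), character()))
  counts <- tapply(sub$species, sub[[rank]],
                   function(s) length(unique(s)))
  setNames(as.integer(counts), names(counts))
}

count_children <- function(dataset, taxon_path, rank, unit) {
  if (unit == "species") return(count_species(dataset, taxon_path, rank))
  sub <- dataset[records_under(dataset, taxon_path), , drop = FALSE]
  tab <- table(sub[[rank]])
  setNames(as.integer(tab), names(tab))
}

new_leaf <- function(name, taxon, taxon_path, rank, species,
                     other_members = NULL) {
  structure(list(name = name, taxon = taxon, taxon_path = taxon_path,
                 rank_from = rank, child_rank = "species",
                 class_labels = sort(species), children = list(),
                 is_leaf = TRUE, degenerate = length(species) < 2L,
                 species = sort(species), other_members = other_members),
            class = "hierarchy_node")
}

#' Build the hierarchical classifier tree
#'
#' Starting from the kingdom, each node inspects its children one rank
#' down: children with at least `group_threshold` species become
#' expanded classes (and are recursed into), the rest are merged into a
#' single "Other" species-level leaf. A node whose every child falls
#' below the threshold collapses into a direct species-level leaf.
#' Family-rank taxa always become species leaves, bypassing genus.
#' Node names follow the `<taxon>_<from>2<to>` convention
#' (`Fungi2p`, `Ascomycota_p2c`, `Cortinariaceae_f2s`, `other_p2s`,
#' `Ascomycota_p_other_c2s`).
#'
#' @param dataset A curated `hftc_dataset`; every record needs a full
#'   7-rank lineage.
#' @param config A [hierarchy_config()].
#' @return The root `hierarchy_node`.
#' @export
build_hierarchy <- function(dataset, config = hierarchy_config()) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (anyNA(dataset[RANKS]))
    stop("build_hierarchy requires full 7-rank lineages")
  kingdoms <- unique(dataset$kingdom)
  if (length(kingdoms) != 1L)
    stop("expected a single kingdom, found: ",
         paste(kingdoms, collapse = ", "))
  build_node(dataset, config, taxon = kingdoms, rank = "kingdom",
             taxon_path = c(kingdom = kingdoms))
}

build_node <- function(dataset, config, taxon, rank, taxon_path) {
  rl <- RANK_LETTER
  child_rank <- RANKS[match(rank, RANKS) + 1L]
  counts <- count_children(dataset, taxon_path, child_rank, config$unit)
  big <- sort(names(counts)[counts >= config$group_threshold])
  small <- sort(setdiff(names(counts), big))
  sub <- dataset[records_under(dataset, taxon_path), , drop = FALSE]
  node_name <- if (rank == "kingdom") paste0(taxon, "2", rl[child_rank])
               else paste0(taxon, "_", rl[rank], "2", rl[child_rank])

  if (length(big) == 0L) {
    # every child is below T: collapse to a direct species classifier
    leaf_name <- if (rank == "kingdom") paste0(taxon, "2s")
                 else paste0(taxon, "_", rl[rank], "2s")
    return(new_leaf(leaf_name, taxon, taxon_path, rank,
                    unique(sub$species)))
  }

  children <- list()
  class_labels <- character()
  for (tx in big) {
    path <- c(taxon_path, setNames(tx, child_rank))
    sp <- unique(sub$species[!is.na(sub[[child_rank]]) &
                               sub[[child_rank]] == tx])
    if (child_rank == config$deepest_routing_rank ||
        child_rank == "family") {
      children[[tx]] <- new_leaf(paste0(tx, "_", rl[child_rank], "2s"),
                                 tx, path, child_rank, sp)
    } else {
      children[[tx]] <- build_node(dataset, config, tx, child_rank, path)
    }
    class_labels <- c(class_labels, tx)
  }

  if (length(small)) {
    chunks <- chunk_other(small, counts[small], config$max_leaf_classes)
    for (ci in seq_along(chunks)) {
      members <- chunks[[ci]]
      label <- if (length(chunks) == 1L) "Other" else paste0("Other", ci)
      suffix <- if (length(chunks) == 1L) "other" else paste0("other", ci)
      leaf_name <- if (rank == "kingdom")
        paste0(suffix, "_", rl[child_rank], "2s")
      else paste0(taxon, "_", rl[rank], "_", suffix, "_",
                  rl[child_rank], "2s")
      sp <- unique(sub$species[!is.na(sub[[child_rank]]) &
                                 sub[[child_rank]] %in% members])
      children[[label]] <- new_leaf(leaf_name, label, taxon_path, rank, sp,
                                    other_members = members)
      class_labels <- c(class_labels, label)
    }
  }

  structure(list(name = node_name, taxon = taxon, taxon_path = taxon_path,
                 rank_from = rank, child_rank = child_rank,
                 class_labels = class_labels, children = children,
                 is_leaf = FALSE, degenerate = length(class_labels) < 2L,
                 species = sort(unique(sub$species)), other_members = NULL),
            class = "hierarchy_node")
}

# split the merged small taxa into alphabetical chunks whose species
# totals stay at or below `cap` (one chunk when cap is NULL)
chunk_other <- function(members, sizes, cap) {
  if (is.null(cap) || sum(sizes) <= cap) return(list(members))
  chunks <- list()
  cur <- character(); cur_n <- 0
  for (m in members) {
    if (length(cur) && cur_n + sizes[[m]] > cap) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- character(); cur_n <- 0
    }
    cur <- c(cur, m); cur_n <- cur_n + sizes[[m]]
  }
  chunks[[length(chunks) + 1L]] <- cur
  chunks
}

#' Training label of a record at a node
#'
#' @param record One-row data frame (or list) with the rank columns.
#' @param node A `hierarchy_node`.
#' @return The child taxon name if expanded, the "Other" chunk label if
#'   merged, or the species name at a leaf.
#' @export
node_label <- function(record, node) {
  for (r in names(node$taxon_path))
    if (is.na(record[[r]]) || record[[r]] != node$taxon_path[[r]])
      stop("record is not under node ", node$name)
  if (node$is_leaf) {
    if (!is.null(node$other_members)) {
      r <- other_rank(node)
      if (is.na(record[[r]]) || !record[[r]] %in% node$other_members)
        stop("record is not under node ", node$name)
    }
    return(record$species)
  }
  child <- record[[node$child_rank]]
  if (child %in% names(node$children) &&
      is.null(node$children[[child]]$other_members))
    return(child)
  for (lab in names(node$children)) {
    ch <- node$children[[lab]]
    if (!is.null(ch$other_members) && child %in% ch$other_members)
      return(lab)
  }
  stop("record's ", node$child_rank, " '", child,
       "' is unknown at node ", node$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the rank at which an Other leaf's member taxa live
other_rank <- function(node) {
  RANKS[match(node$rank_from, RANKS) + 1L]
}

#' Flatten a hierarchy into a named list of nodes
#'
#' @param root A `hierarchy_node`.
#' @return Named list of every node (routing nodes and leaves), in
#'   depth-first order.
#' @export
hftc_nodes <- function(root) {
  out <- list()
  walk <- function(node) {
    out[[node$name]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(root)
  out
}

#' @export
print.hierarchy_node <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  if (x$is_leaf) {
    cat(sprintf("%s%s [leaf, %d species]\n", pad, x$name,
                length(x$species)))
  } else {
    cat(sprintf("%s%s [%s -> %s, %d classes%s]\n", pad, x$name,
                x$rank_from, x$child_rank, length(x$class_labels),
                if (x$degenerate) ", degenerate" else ""))
    for (ch in x$children) print(ch, indent = indent + 1L)
  }
  invisible(x)
}
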