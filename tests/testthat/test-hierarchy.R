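# compact dataset builder: one record per species, lineages systematic,
# species spread over phyla according to `per_phylum`
species_table <- function(per_phylum, classes = 1L) {
  rows <- lapply(names(per_phylum), function(p) {
    n <- per_phylum[[p]]
    cl <- sprintf("%s_C%d", p, rep_len(seq_len(classes), n))
    data.frame(id = sprintf("%s_sp%04d", p, seq_len(n)),
               sequence = "ACGTACGTACGTACG", kingdom = "Fungi",
               phylum = p, class = cl, order = paste0(cl, "_O1"),
               family = paste0(cl, "_O1_F1"),
               genus = paste0(cl, "_O1_F1_G1"),
               species = sprintf("%s_sp%04d", p, seq_len(n)),
               stringsAsFactors = FALSE)
  })
  hftc_dataset(do.call(rbind, rows))
}

test_that("count_species counts distinct species per child taxon", {
  ds <- species_table(c(P1 = 3, P2 = 2))
  counts <- count_species(ds, c(kingdom = "Fungi"), "phylum")
  expect_equal(counts, c(P1 = 3L, P2 = 2L))
  expect_length(count_species(ds, c(kingdom = "Nope"), "phylum"), 0L)
  # a species name appearing under two phyla is counted once per path
  ds2 <- ds
  ds2$species[4] <- ds2$species[1]
  ds2 <- hftc_dataset(ds2[, setdiff(names(ds2), "sh_id")])
  c2 <- count_species(ds2, c(kingdom = "Fungi"), "phylum")
  expect_equal(c2, c(P1 = 3L, P2 = 2L))
  expect_error(count_species(ds, c(kingdom = "Fungi"), "strain"),
               "unknown rank")
})

test_that("taxa below the threshold merge into an Other species leaf", {
  ds <- species_table(c(P1 = 1200, P2 = 300, P3 = 500))
  root <- build_hierarchy(ds, hierarchy_config(group_threshold = 1000))
  expect_equal(root$class_labels, c("P1", "Other"))
  other <- root$children[["Other"]]
  expect_true(other$is_leaf)
  expect_length(other$species, 800L)
  expect_equal(other$name, "other_p2s")
  expect_setequal(other$other_members, c("P2", "P3"))
  # P1 is expanded one rank deeper
  expect_false(root$children[["P1"]]$is_leaf)
  expect_equal(root$children[["P1"]]$child_rank, "class")
})

test_that("degenerate and extreme thresholds collapse as documented", {
  ds <- species_table(c(P1 = 4, P2 = 4), classes = 2L)
  # T = Inf: single flat species classifier
  flat <- build_hierarchy(ds, hierarchy_config(group_threshold = Inf))
  expect_true(flat$is_leaf)
  expect_length(flat$species, 8L)
  expect_length(hftc_nodes(flat), 1L)
  # T = 1: every taxon with >= 1 species expanded down to family leaves
  deep <- build_hierarchy(ds, hierarchy_config(group_threshold = 1))
  nodes <- hftc_nodes(deep)
  leaves <- Filter(function(n) n$is_leaf, nodes)
  expect_true(all(vapply(leaves, function(n) n$rank_from, "") == "family"))
  expect_true(all(grepl("_f2s$", names(leaves))))
})

test_that("genus is never a routing rank and leaves partition the species", {
  fx <- small_fixture()
  nodes <- hftc_nodes(fx$model$hierarchy)
  routing <- Filter(function(n) !n$is_leaf, nodes)
  expect_true(all(vapply(routing, function(n) n$child_rank, "") != "genus"))
  expect_true(all(vapply(routing, function(n) n$rank_from, "")
                  %in% c("kingdom", "phylum", "class", "order")))
  leaves <- Filter(function(n) n$is_leaf, nodes)
  all_species <- unlist(lapply(leaves, function(n) n$species))
  expect_false(anyDuplicated(all_species) > 0)
  expect_setequal(all_species, unique(fx$cur$species))
})

test_that("the tree is invariant to record order", {
  ds <- species_table(c(P1 = 30, P2 = 3), classes = 2L)
  cfg <- hierarchy_config(group_threshold = 10)
  t1 <- build_hierarchy(ds, cfg)
  t2 <- build_hierarchy(hftc_dataset(ds[rev(seq_len(nrow(ds))), ]), cfg)
  expect_identical(t1, t2)
})

test_that("node_label maps records to child taxa, Other, or species", {
  ds <- species_table(c(P1 = 1200, P2 = 300, P3 = 500))
  root <- build_hierarchy(ds, hierarchy_config(group_threshold = 1000))
  rec_p1 <- ds[ds$phylum == "P1", ][1, ]
  rec_p2 <- ds[ds$phylum == "P2", ][1, ]
  expect_equal(node_label(rec_p1, root), "P1")
  expect_equal(node_label(rec_p2, root), "Other")
  expect_equal(node_label(rec_p2, root$children[["Other"]]),
               rec_p2$species)
  rec_bad <- rec_p1; rec_bad$kingdom <- "Plantae"
  expect_error(node_label(rec_bad, root), "not under node")
})

test_that("max_leaf_classes splits Other into alphabetical chunks", {
  ds <- species_table(c(P1 = 50, P2 = 8, P3 = 8, P4 = 8))
  root <- build_hierarchy(ds, hierarchy_config(group_threshold = 20,
                                               max_leaf_classes = 16))
  labs <- grep("^Other", root$class_labels, value = TRUE)
  expect_equal(labs, c("Other1", "Other2"))
  expect_equal(root$children[["Other1"]]$other_members, c("P2", "P3"))
  expect_equal(root$children[["Other2"]]$other_members, "P4")
  expect_match(root$children[["Other1"]]$name, "other1_p2s")
})
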