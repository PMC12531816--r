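# Shared fixtures, all built in code.

# A hand-written 12-record dataset: 2 phyla x 2 species each, plus
# records exercising the curation rules.
toy_dataset <- function() {
  lin <- function(p, cl, o, f, g, s)
    c(kingdom = "Fungi", phylum = p, class = cl, order = o, family = f,
      genus = g, species = s)
  rows <- list(
    c(id = "a1", sequence = "ACGTACGTACGTACGT",
      lin("P1", "C1", "O1", "F1", "G1", "S1"), sh_id = "SH1"),
    c(id = "a2", sequence = "ACGTACGTACGTACGA",
      lin("P1", "C1", "O1", "F1", "G1", "S1"), sh_id = "SH1"),
    c(id = "b1", sequence = "TTTTACGTACGTACGT",
      lin("P1", "C1", "O1", "F1", "G2", "S2"), sh_id = "SH2"),
    c(id = "c1", sequence = "GGGGACGTACGTACGT",
      lin("P2", "C2", "O2", "F2", "G3", "S3"), sh_id = "SH3"),
    c(id = "c2", sequence = "GGGGACGTACGTACGA",
      lin("P2", "C2", "O2", "F2", "G3", "S3"), sh_id = "SH3"),
    c(id = "d1", sequence = "CCCCACGTACGTACGT",
      lin("P2", "C2", "O2", "F2", "G4", "S4"), sh_id = "SH4"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  hftc_dataset(df)
}

# n_sh species hypotheses with per_sh identical-length clean records each
sh_manifest <- function(n_sh, per_sh, seq = "ACGTACGTACGTACG") {
  sh <- rep(sprintf("SH%06d", seq_len(n_sh)), each = per_sh)
  df <- data.frame(
    id = sprintf("%s_r%02d", sh, rep(seq_len(per_sh), times = n_sh)),
    sequence = seq,
    kingdom = "Fungi", phylum = "P1", class = "C1", order = "O1",
    family = "F1", genus = "G1", species = sh, sh_id = sh,
    stringsAsFactors = FALSE)
  hftc_dataset(df)
}

# random valid top-down lineages with controllable per-rank error rates
# between "truth" and "prediction" (for metric property tests)
random_lineage_pairs <- function(n, error_rate = 0.2, pools = 3L,
                                 seed = 1L) {
  set.seed(seed)
  truths <- data.frame(id = paste0("q", seq_len(n)),
                       stringsAsFactors = FALSE)
  preds <- truths
  for (r in c("phylum", "class", "order", "family", "genus", "species")) {
    truths[[r]] <- sprintf("%s%d", r, sample.int(pools, n, replace = TRUE))
    flip <- stats::runif(n) < error_rate
    preds[[r]] <- ifelse(flip,
                         sprintf("%s%d", r,
                                 sample.int(pools, n, replace = TRUE)),
                         truths[[r]])
  }
  truths$kingdom <- "Fungi"; preds$kingdom <- "Fungi"
  list(preds = preds, truths = truths)
}

# a small fitted model shared across classify/cli tests (reduced
# embedding size for speed; the acceptance suite trains at defaults)
.fixture_env <- new.env(parent = emptyenv())
small_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    ds <- simulate_dataset(sim_config(seq_length = 300, seed = 7))
    cur <- curate(ds, curation_config(seed = 7))
    model <- hftc(cur,
                  hierarchy = hierarchy_config(group_threshold = 3),
                  features = feature_config(k_upper = 8, k_species = 6,
                                            N = 16, epochs = 2, seed = 7),
                  forest = forest_config(n_trees = 60, seed = 7))
    held <- ds[!ds$id %in% cur$id, , drop = FALSE]
    .fixture_env$fx <- list(ds = ds, cur = cur, model = model,
                            held = held)
  }
  .fixture_env$fx
}
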