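# Taxonomy-aware ITS sequence simulator. Sequences diverge progressively
# down the tree: a kingdom ancestor is mutated at the phylum rate to
# create phylum ancestors, those at the class rate to create classes,
# and so on; species differ from congeners by point mutations and short
# indels only. This encodes the premise the level-dependent k choice
# exploits: broad motif divergence between high ranks, subtle local
# variation between species.

#' Simulation configuration
#'
#' Default counts give 2 x 2 x 1 x 2 x 2 x 2 = 32 species; substitution
#' rates decrease strictly with depth (phylum 0.30 ... species 0.02,
#' within-species 0.005), emulating ITS-scale divergence structure.
#' `seqs_per_species = 12` exceeds the default per-SH subsample of 10 so
#' curation's subsampling is exercised (and the surplus records serve as
#' natural held-out queries).
#'
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus
#'   Taxon counts per rank.
#' @param seq_length Ancestor sequence length (default 600, ITS scale).
#' @param rates Named per-rank substitution rates applied when
#'   descending one rank.
#' @param within_species_rate Substitution rate from species ancestor to
#'   each record.
#' @param indel_rate Per-position single-base insertion/deletion rate.
#' @param seqs_per_species Records emitted per species (default 12).
#' @param frac_ambiguous,frac_nonacgt Fractions (of the clean record
#'   count) of extra noise records with an ambiguous label or an
#'   injected non-ACGT character; default 0 (clean data).
#' @param homonym Inject a deliberate rank-name homonym: the first class
#'   of the second phylum reuses the display name of the first class of
#'   the first phylum (requires `n_phyla >= 2`).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_phyla = 2L, classes_per_phylum = 2L,
                       orders_per_class = 1L, families_per_order = 2L,
                       genera_per_family = 2L, species_per_genus = 2L,
                       seq_length = 600L,
                       rates = c(phylum = 0.30, class = 0.15,
                                 order = 0.10, family = 0.06,
                                 genus = 0.04, species = 0.02),
                       within_species_rate = 0.005, indel_rate = 0.001,
                       seqs_per_species = 12L, frac_ambiguous = 0,
                       frac_nonacgt = 0, homonym = FALSE, seed = 1L) {
  counts <- c(n_phyla, classes_per_phylum, orders_per_class,
              families_per_order, genera_per_family, species_per_genus)
  stopifnot(all(counts >= 1), seq_length >= 1, seqs_per_species >= 1,
            all(rates >= 0 & rates < 1), within_species_rate >= 0,
            within_species_rate < 1, indel_rate >= 0, indel_rate < 1,
            frac_ambiguous >= 0, frac_nonacgt >= 0)
  if (homonym && n_phyla < 2L)
    stop("homonym injection needs at least 2 phyla")
  structure(list(n_phyla = as.integer(n_phyla),
                 classes_per_phylum = as.integer(classes_per_phylum),
                 orders_per_class = as.integer(orders_per_class),
                 families_per_order = as.integer(families_per_order),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 seq_length = as.integer(seq_length), rates = rates,
                 within_species_rate = within_species_rate,
                 indel_rate = indel_rate,
                 seqs_per_species = as.integer(seqs_per_species),
                 frac_ambiguous = frac_ambiguous,
                 frac_nonacgt = frac_nonacgt, homonym = isTRUE(homonym),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutate a sequence with substitutions and single-base indels
#'
#' Each position is substituted to a uniformly chosen *different* base
#' with probability `sub_rate`; independently, each position triggers a
#' single-base indel (insertion after it or deletion of it, equally
#' likely) with probability `indel_rate`. Uses the current RNG state, so
#' results are deterministic under `set.seed()`.
#'
#' @param sequence A single ACGT string.
#' @param sub_rate Substitution probability per position.
#' @param indel_rate Indel probability per position.
#' @return The mutated sequence.
#' @export
mutate_seq <- function(sequence, sub_rate, indel_rate = 0) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hit <- runif(n) < sub_rate
  if (any(hit)) {
    cur <- match(ch[hit], BASES) - 1L
    ch[hit] <- BASES[((cur + sample.int(3L, sum(hit),
                                        replace = TRUE)) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    if (length(ev)) {
      ins <- runif(length(ev)) < 0.5
      pieces <- as.list(ch)
      for (j in seq_along(ev)) {
        pos <- ev[j]
        if (ins[j]) pieces[[pos]] <- c(pieces[[pos]],
                                       sample(BASES, 1L))
        else pieces[[pos]] <- character()
      }
      ch <- unlist(pieces)
    }
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic, fully labelled ITS-like dataset
#'
#' Descends the configured taxonomy, deriving each taxon's ancestor
#' from its parent's at the rank's substitution rate, then emits
#' `seqs_per_species` records per species at the within-species rate.
#' Names are systematic and collision-free (`P1`, `P1_C1`, ...,
#' species `P1_C1_O1_F1_G1_S1`); the SH id is the species name. Optional
#' noise records exercise curation. Byte-identical output for a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @param fasta_path,tax_path Optional output paths; when given the
#'   dataset is also written via [write_dataset()].
#' @return An `hftc_dataset`.
#' @export
simulate_dataset <- function(config = sim_config(), fasta_path = NULL,
                             tax_path = NULL) {
  ds <- with_seed(config$seed, simulate_dataset_impl(config))
  if (!is.null(fasta_path)) write_dataset(ds, fasta_path, tax_path)
  ds
}

simulate_dataset_impl <- function(config) {
  rates <- config$rates
  idr <- config$indel_rate
  kingdom_anc <- paste(sample(BASES, config$seq_length, replace = TRUE),
                       collapse = "")
  rows <- list()
  for (p in seq_len(config$n_phyla)) {
    p_name <- paste0("P", p)
    p_anc <- mutate_seq(kingdom_anc, rates[["phylum"]], idr)
    for (cc in seq_len(config$classes_per_phylum)) {
      c_name <- paste0(p_name, "_C", cc)
      if (config$homonym && p == 2L && cc == 1L) c_name <- "P1_C1"
      c_anc <- mutate_seq(p_anc, rates[["class"]], idr)
      for (o in seq_len(config$orders_per_class)) {
        o_name <- paste0(p_name, "_C", cc, "_O", o)
        o_anc <- mutate_seq(c_anc, rates[["order"]], idr)
        for (f in seq_len(config$families_per_order)) {
          f_name <- paste0(o_name, "_F", f)
          f_anc <- mutate_seq(o_anc, rates[["family"]], idr)
          for (g in seq_len(config$genera_per_family)) {
            g_name <- paste0(f_name, "_G", g)
            g_anc <- mutate_seq(f_anc, rates[["genus"]], idr)
            for (s in seq_len(config$species_per_genus)) {
              s_name <- paste0(g_name, "_S", s)
              s_anc <- mutate_seq(g_anc, rates[["species"]], idr)
              for (i in seq_len(config$seqs_per_species)) {
                rows[[length(rows) + 1L]] <- list(
                  id = sprintf("%s_r%02d", s_name, i),
                  sequence = mutate_seq(s_anc,
                                        config$within_species_rate, idr),
                  kingdom = "Fungi", phylum = p_name, class = c_name,
                  order = o_name, family = f_name, genus = g_name,
                  species = s_name, sh_id = s_name)
              }
            }
          }
        }
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  n_clean <- nrow(df)
  n_amb <- ceiling(config$frac_ambiguous * n_clean)
  n_bad <- ceiling(config$frac_nonacgt * n_clean)
  if (n_amb > 0) {
    src <- df[sample.int(n_clean, n_amb, replace = TRUE), , drop = FALSE]
    src$id <- sprintf("noise_amb_%03d", seq_len(n_amb))
    src$genus <- "Incertae_sedis"
    src$species <- NA_character_
    src$sh_id <- NA_character_
    df <- rbind(df, src)
  }
  if (n_bad > 0) {
    src <- df[sample.int(n_clean, n_bad, replace = TRUE), , drop = FALSE]
    src$id <- sprintf("noise_base_%03d", seq_len(n_bad))
    src$sequence <- vapply(src$sequence, function(s) {
      pos <- sample.int(nchar(s), 1L)
      paste0(substr(s, 1L, pos - 1L), "N",
             substr(s, pos + 1L, nchar(s)))
    }, "")
    df <- rbind(df, src)
  }
  rownames(df) <- NULL
  hftc_dataset(df)
}
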