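# UNITE-style dataset curation: ambiguous-label removal, non-standard
# base removal, minimum-SH-size filter and per-SH subsampling, with a
# telescoping provenance report.

#' Curation configuration
#'
#' @param ambiguous_tokens Case-insensitive substrings that mark a rank
#'   name as ambiguous.
#' @param min_sh_size Minimum number of records a species hypothesis (SH)
#'   must have to be retained (default 10).
#' @param per_sh_sample Number of records drawn per SH (default 10).
#' @param seed Seed governing the subsampling draw.
#' @param min_length Minimum sequence length; defaults to 10 so the
#'   largest default k-mer length (k = 10) always fits.
#' @return A `curation_config` list.
#' @export
curation_config <- function(ambiguous_tokens = c("unidentified",
                                                 "incertae sedis",
                                                 "incertae_sedis"),
                            min_sh_size = 10L, per_sh_sample = 10L,
                            seed = 1L, min_length = 10L) {
  stopifnot(min_sh_size >= 1L, per_sh_sample >= 1L, min_length >= 1L)
  structure(list(ambiguous_tokens = ambiguous_tokens,
                 min_sh_size = as.integer(min_sh_size),
                 per_sh_sample = as.integer(per_sh_sample),
                 seed = as.integer(seed),
                 min_length = as.integer(min_length)),
            class = "curation_config")
}

#' Remove records with ambiguous or incomplete labels
#'
#' Drops records whose lineage lacks the species rank or whose any rank
#' name contains one of the configured ambiguous tokens
#' (case-insensitive substring match, e.g. "Incertae_sedis").
#'
#' @param dataset An `hftc_dataset`.
#' @param config A [curation_config()].
#' @return The filtered dataset with updated provenance.
#' @export
drop_ambiguous <- function(dataset, config = curation_config()) {
  bad <- is.na(dataset$species)
  toks <- tolower(config$ambiguous_tokens)
  for (r in RANKS) {
    val <- tolower(dataset[[r]])
    for (tk in toks)
      bad <- bad | (!is.na(val) & grepl(tk, val, fixed = TRUE))
  }
  add_provenance(subset_dataset(dataset, !bad), "drop_ambiguous",
                 sum(bad), sum(!bad))
}

#' Remove records with non-standard bases or too-short sequences
#'
#' @inheritParams drop_ambiguous
#' @return The filtered dataset with updated provenance.
#' @export
drop_nonstandard <- function(dataset, config = curation_config()) {
  ok <- grepl("^[ACGT]+$", dataset$sequence) &
    nchar(dataset$sequence) >= config$min_length
  add_provenance(subset_dataset(dataset, ok), "drop_nonstandard",
                 sum(!ok), sum(ok))
}

#' Remove all records of under-represented species hypotheses
#'
#' SHs with fewer than `min_sh_size` records are excluded entirely
#' (boundary inclusive: an SH with exactly `min_sh_size` records stays).
#'
#' @inheritParams drop_ambiguous
#' @return The filtered dataset with updated provenance.
#' @export
drop_small_sh <- function(dataset, config = curation_config()) {
  n_by_sh <- table(dataset$sh_id)
  keep_sh <- names(n_by_sh)[n_by_sh >= config$min_sh_size]
  keep <- dataset$sh_id %in% keep_sh
  add_provenance(subset_dataset(dataset, keep), "drop_small_sh",
                 sum(!keep), sum(keep))
}

#' Subsample each species hypothesis to a fixed size
#'
#' Retains exactly `per_sh_sample` records per SH, drawn uniformly
#' without replacement. Records are sorted by id within each SH and SHs
#' are visited in sorted order before drawing, so the retained id set is
#' identical for a fixed seed regardless of input record order.
#'
#' @inheritParams drop_ambiguous
#' @return The subsampled dataset with updated provenance.
#' @export
subsample_per_sh <- function(dataset, config = curation_config()) {
  n <- config$per_sh_sample
  ord <- order(dataset$sh_id, dataset$id)
  sh_sorted <- dataset$sh_id[ord]
  id_sorted <- dataset$id[ord]
  sizes <- table(sh_sorted)
  if (any(sizes < n))
    stop("SH(s) with fewer than per_sh_sample records: ",
         paste(names(sizes)[sizes < n], collapse = ", "))
  keep_ids <- with_seed(config$seed, {
    # per-row uniform draw ranked within SH: the n smallest are kept
    u <- runif(length(id_sorted))
    rnk <- stats::ave(u, sh_sorted, FUN = rank)
    id_sorted[rnk <= n]
  })
  keep <- dataset$id %in% keep_ids
  add_provenance(subset_dataset(dataset, keep), "subsample_per_sh",
                 sum(!keep), sum(keep))
}

#' Run the full curation pipeline
#'
#' Applies, in order: [drop_ambiguous()], [drop_nonstandard()],
#' [drop_small_sh()], [subsample_per_sh()]. The final record count is
#' (number of surviving SHs) x `per_sh_sample`, and the provenance table
#' telescopes: raw count - sum(removed) = final count.
#'
#' @inheritParams drop_ambiguous
#' @return The curated dataset.
#' @export
curate <- function(dataset, config = curation_config()) {
  out <- drop_ambiguous(dataset, config)
  out <- drop_nonstandard(out, config)
  out <- drop_small_sh(out, config)
  subsample_per_sh(out, config)
}
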