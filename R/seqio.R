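# Sequence, taxonomy and prediction I/O.
#
# Dialects (fixed and documented so files round-trip exactly):
#  * taxonomy strings: semicolon-separated, UNITE/SINTAX-style rank
#    prefixes k__ p__ c__ o__ f__ g__ s__, underscores inside names;
#  * FASTA headers: ">id|SH|k__...;s__..." or ">id|k__...;s__..." with a
#    TSV fallback (id <tab> taxonomy [<tab> SH id], no header row);
#  * predictions and metrics: literal-tab TSV, UTF-8, no quoting.

LINEAGE_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                      order = "o__", family = "f__", genus = "g__",
                      species = "s__")

#' Parse a rank-prefixed taxonomy string into a lineage
#'
#' Accepts UNITE/SINTAX-style strings such as
#' `"k__Fungi;p__Ascomycota;...;s__Fusarium_oxysporum"`. Tokens may carry
#' rank prefixes (`k__` ... `s__`), which must appear in rank order;
#' unprefixed tokens are assigned to ranks by position. An empty token
#' after a prefix yields an absent rank.
#'
#' @param tax_string A single taxonomy string.
#' @return A named character vector of length 7 (`kingdom` ... `species`),
#'   `NA` for absent ranks.
#' @examples
#' parse_lineage("k__Fungi;p__Basidiomycota")
#' @export
parse_lineage <- function(tax_string) {
  stopifnot(is.character(tax_string), length(tax_string) == 1L)
  lin <- setNames(rep(NA_character_, 7L), RANKS)
  tokens <- trimws(strsplit(tax_string, ";", fixed = TRUE)[[1]])
  if (length(tokens) > 7L)
    stop("taxonomy string has more than 7 tokens: ", tax_string)
  last_rank <- 0L
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    pref <- regmatches(tok, regexpr("^[kpcofgs]__", tok))
    if (length(pref) == 1L) {
      rank_i <- match(pref, LINEAGE_PREFIXES)
      if (rank_i <= last_rank)
        stop("out-of-order or duplicate rank prefix at token '", tok, "'")
      last_rank <- rank_i
      name <- substring(tok, 4L)
    } else {
      if (i <= last_rank)
        stop("unprefixed token '", tok, "' conflicts with earlier prefixed ranks")
      rank_i <- i
      last_rank <- rank_i
      name <- tok
    }
    if (nzchar(name)) {
      if (grepl(";", name, fixed = TRUE) || grepl("^[kpcofgs]__", name))
        stop("malformed name token '", tok, "'")
      lin[rank_i] <- name
    }
  }
  lin
}

#' Format a lineage back into a rank-prefixed taxonomy string
#'
#' Inverse of [parse_lineage()] on valid lineages: present ranks are
#' emitted with their prefixes, trailing absent ranks are dropped.
#'
#' @param lineage Named character vector as returned by [parse_lineage()].
#' @return A single taxonomy string.
#' @export
format_lineage <- function(lineage) {
  lin <- lineage[RANKS]
  present <- which(!is.na(lin))
  if (length(present) == 0L) return("")
  deepest <- max(present)
  toks <- paste0(LINEAGE_PREFIXES[seq_len(deepest)],
                 ifelse(is.na(lin[seq_len(deepest)]), "",
                        lin[seq_len(deepest)]))
  paste(toks, collapse = ";")
}

#' Construct a labelled sequence dataset
#'
#' A dataset is a `data.frame` (class `hftc_dataset`) with columns `id`,
#' `sequence`, the seven rank columns and `sh_id`, plus a curation
#' provenance table kept in `attr(x, "provenance")`.
#'
#' @param df Data frame with at least `id`, `sequence` and the rank columns.
#' @return An `hftc_dataset`.
#' @export
hftc_dataset <- function(df) {
  needed <- c("id", "sequence", RANKS)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("dataset is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate record ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!"sh_id" %in% names(df)) df$sh_id <- NA_character_
  df$sh_id <- ifelse(is.na(df$sh_id) | !nzchar(df$sh_id), df$species, df$sh_id)
  df <- df[, c("id", "sequence", RANKS, "sh_id")]
  rownames(df) <- NULL
  structure(df,
            provenance = data.frame(step = character(), removed = integer(),
                                    retained = integer(),
                                    stringsAsFactors = FALSE),
            class = c("hftc_dataset", "data.frame"))
}

#' @export
print.hftc_dataset <- function(x, ...) {
  cat(sprintf("<hftc_dataset> %d records, %d species, %d SHs\n",
              nrow(x), length(unique(x$species[!is.na(x$species)])),
              length(unique(x$sh_id[!is.na(x$sh_id)]))))
  prov <- attr(x, "provenance")
  if (nrow(prov)) {
    cat("curation provenance:\n")
    print(prov, row.names = FALSE)
  }
  invisible(x)
}

#' Curation provenance of a dataset
#'
#' @param dataset An `hftc_dataset`.
#' @return Data frame with columns `step`, `removed`, `retained`.
#' @export
provenance <- function(dataset) {
  attr(dataset, "provenance")
}

# Record a curation step, preserving dataset class and earlier steps.
add_provenance <- function(dataset, step, removed, retained) {
  prov <- attr(dataset, "provenance")
  prov <- rbind(prov, data.frame(step = step, removed = as.integer(removed),
                                 retained = as.integer(retained),
                                 stringsAsFactors = FALSE))
  attr(dataset, "provenance") <- prov
  dataset
}

# Subset records keeping class and provenance attributes.
subset_dataset <- function(dataset, keep) {
  prov <- attr(dataset, "provenance")
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  class(out) <- c("hftc_dataset", "data.frame")
  out
}

#' Read a FASTA file plus taxonomy labels into a dataset
#'
#' Taxonomy may be embedded in the FASTA headers
#' (`>id|SH_id|taxonomy` or `>id|taxonomy`) or supplied as a TSV mapping
#' `id -> taxonomy` with an optional third SH-id column. Sequences are
#' uppercased on read; `U` is converted to `T` only when `rna_to_dna` is
#' set (curation later removes any remaining non-ACGT records).
#'
#' @param fasta_path Path to a FASTA file.
#' @param tax_source Either `"header"` or the path to a taxonomy TSV.
#' @param rna_to_dna Convert `U` to `T` on read (default `FALSE`).
#' @return An `hftc_dataset`; record order follows the FASTA.
#' @export
read_dataset <- function(fasta_path, tax_source = "header",
                         rna_to_dna = FALSE) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  set <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e) NULL)
  if (is.null(set)) {
    # empty or header-less file: treat as zero records
    empty <- data.frame(id = character(), sequence = character(),
                        stringsAsFactors = FALSE)
    for (r in RANKS) empty[[r]] <- character()
    return(hftc_dataset(empty))
  }
  seqs <- toupper(as.character(set))
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(fields, function(f) strsplit(f[1], "[ \t]")[[1]][1], "")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  if (identical(tax_source, "header")) {
    tax <- character(length(ids)); sh <- rep(NA_character_, length(ids))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) >= 3L) { sh[i] <- f[2]; tax[i] <- f[3] }
      else if (length(f) == 2L) tax[i] <- f[2]
      else stop("FASTA header for '", ids[i],
                "' carries no taxonomy field and no TSV was given")
    }
  } else {
    tab <- read.delim(tax_source, header = FALSE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stop("taxonomy TSV needs at least 2 columns")
    m <- match(ids, tab[[1]])
    if (anyNA(m))
      stop("ids missing from taxonomy TSV: ",
           paste(ids[is.na(m)], collapse = ", "))
    tax <- tab[[2]][m]
    sh <- if (ncol(tab) >= 3L) tab[[3]][m] else rep(NA_character_, length(ids))
    sh[!is.na(sh) & !nzchar(sh)] <- NA_character_
  }

  lin <- t(vapply(tax, parse_lineage, setNames(character(7), RANKS)))
  df <- data.frame(id = ids, sequence = unname(seqs),
                   stringsAsFactors = FALSE)
  for (r in RANKS) df[[r]] <- unname(lin[, r])
  df$sh_id <- sh
  hftc_dataset(df)
}

#' Write a dataset as FASTA (+ optional taxonomy TSV)
#'
#' FASTA headers use the `>id|SH|taxonomy` dialect that [read_dataset()]
#' parses back.
#'
#' @param dataset An `hftc_dataset`.
#' @param fasta_path Output FASTA path.
#' @param tax_path Optional taxonomy TSV path (id, taxonomy, SH id).
#' @export
write_dataset <- function(dataset, fasta_path, tax_path = NULL) {
  tax <- vapply(seq_len(nrow(dataset)), function(i)
    format_lineage(unlist(dataset[i, RANKS])), "")
  lines <- character(2L * nrow(dataset))
  if (nrow(dataset)) {
    lines[seq(1, length(lines), by = 2)] <-
      paste0(">", dataset$id, "|", dataset$sh_id, "|", tax)
    lines[seq(2, length(lines), by = 2)] <- dataset$sequence
  }
  writeLines(lines, fasta_path)
  if (!is.null(tax_path)) {
    tab <- data.frame(dataset$id, tax, dataset$sh_id)
    write.table(tab, tax_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

PRED_COLUMNS <- c("id", RANKS, "conf_phylum", "conf_class", "conf_order",
                  "conf_family", "conf_species")

#' Write predictions to TSV
#'
#' Columns: `id`, the seven ranks, and the per-rank confidences
#' `conf_phylum conf_class conf_order conf_family conf_species`,
#' formatted with 4 decimals. Input row order is preserved.
#'
#' @param predictions Data frame as returned by [predict.hftc()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions[, PRED_COLUMNS, drop = FALSE]
  for (cc in grep("^conf_", PRED_COLUMNS, value = TRUE))
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.4f", out[[cc]]))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(PRED_COLUMNS, collapse = "\t"), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = c(rep("character", 8), rep("numeric", 5)))
  names(df) <- PRED_COLUMNS
  df
}
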