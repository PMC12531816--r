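# Rank-wise evaluation: accuracy, hierarchical accuracy (all ranks along
# the path must be correct), one-vs-rest precision/recall/F1 under
# macro/weighted/micro averaging, and the multi-class Matthews
# correlation coefficient.
#
# Records the model refused (absent predicted ranks) count as incorrect:
# denominators always equal the number of evaluated records.

EVAL_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

as_rank_frame <- function(x) {
  if (inherits(x, "hftc_dataset") || is.data.frame(x)) return(x)
  stop("expected a data frame with rank columns")
}

check_pairs <- function(preds, truths, rank) {
  if (!rank %in% RANKS) stop("unknown rank: ", rank)
  if (nrow(preds) == 0L) stop("empty input")
  if (nrow(preds) != nrow(truths))
    stop("preds and truths differ in length")
}

# align preds to truths by id when both carry ids
align_pairs <- function(preds, truths) {
  if (!is.null(preds$id) && !is.null(truths$id)) {
    missing <- setdiff(truths$id, preds$id)
    extra <- setdiff(preds$id, truths$id)
    if (length(missing) || length(extra))
      stop("prediction/truth id sets differ; missing: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(head(extra, 10),
                                           collapse = ", ")))
    preds <- preds[match(truths$id, preds$id), , drop = FALSE]
  }
  list(preds = preds, truths = truths)
}

#' Per-rank classification accuracy
#'
#' Fraction of records whose predicted name at `rank` equals the true
#' name; absent predictions count as incorrect.
#'
#' @param preds,truths Data frames with rank columns (and optionally
#'   `id`, used for alignment).
#' @param rank One of the seven ranks.
#' @return Accuracy in `[0, 1]`.
#' @export
rank_accuracy <- function(preds, truths, rank) {
  al <- align_pairs(as_rank_frame(preds), as_rank_frame(truths))
  check_pairs(al$preds, al$truths, rank)
  p <- al$preds[[rank]]
  t <- al$truths[[rank]]
  mean(!is.na(p) & p == t)
}

#' Hierarchical accuracy
#'
#' Fraction of records whose prediction is correct at EVERY rank from
#' phylum down to `rank` (inclusive); a single upstream error makes the
#' whole path count as wrong. Always `<=` the plain accuracy at the same
#' rank, with equality at phylum.
#'
#' @inheritParams rank_accuracy
#' @return Hierarchical accuracy in `[0, 1]`.
#' @export
hierarchical_accuracy <- function(preds, truths, rank) {
  al <- align_pairs(as_rank_frame(preds), as_rank_frame(truths))
  check_pairs(al$preds, al$truths, rank)
  path <- EVAL_RANKS[seq_len(match(rank, EVAL_RANKS))]
  if (is.na(match(rank, EVAL_RANKS)))
    stop("hierarchical accuracy is defined for phylum..species")
  ok <- rep(TRUE, nrow(al$preds))
  for (r in path) {
    p <- al$preds[[r]]
    ok <- ok & !is.na(p) & p == al$truths[[r]]
  }
  mean(ok)
}

#' Precision, recall and F1 at a rank
#'
#' One-vs-rest per-label precision/recall/F1 combined under the chosen
#' averaging. Labels never predicted get precision 0.
#'
#' @inheritParams rank_accuracy
#' @param averaging `"weighted"` (by true support, default), `"macro"`,
#'   or `"micro"`.
#' @return List: `precision`, `recall`, `f1`, and `per_label` (data
#'   frame of per-label values and supports).
#' @export
prf <- function(preds, truths, rank,
                averaging = c("weighted", "macro", "micro")) {
  averaging <- match.arg(averaging)
  al <- align_pairs(as_rank_frame(preds), as_rank_frame(truths))
  check_pairs(al$preds, al$truths, rank)
  t <- al$truths[[rank]]
  p <- al$preds[[rank]]
  p[is.na(p)] <- "<none>"
  labels <- sort(unique(t))
  tp <- vapply(labels, function(l) sum(p == l & t == l), numeric(1))
  fp <- vapply(labels, function(l) sum(p == l & t != l), numeric(1))
  fn <- vapply(labels, function(l) sum(p != l & t == l), numeric(1))
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  support <- vapply(labels, function(l) sum(t == l), numeric(1))
  per_label <- data.frame(label = labels, precision = prec, recall = rec,
                          f1 = f1, support = support,
                          stringsAsFactors = FALSE)
  rownames(per_label) <- NULL
  out <- switch(averaging,
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted = {
      w <- support / sum(support)
      c(precision = sum(w * prec), recall = sum(w * rec),
        f1 = sum(w * f1))
    },
    micro = {
      P <- sum(tp) / max(1, sum(tp) + sum(fp))
      R <- sum(tp) / max(1, sum(tp) + sum(fn))
      c(precision = P, recall = R,
        f1 = if (P + R > 0) 2 * P * R / (P + R) else 0)
    })
  list(precision = unname(out["precision"]), recall = unname(out["recall"]),
       f1 = unname(out["f1"]), per_label = per_label)
}

#' Multi-class Matthews correlation coefficient at a rank
#'
#' The confusion-matrix generalization of the binary MCC (it reduces to
#' the familiar formula for two classes). Returns 0 when any marginal is
#' degenerate.
#'
#' @inheritParams rank_accuracy
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(preds, truths, rank) {
  al <- align_pairs(as_rank_frame(preds), as_rank_frame(truths))
  check_pairs(al$preds, al$truths, rank)
  t <- al$truths[[rank]]
  p <- al$preds[[rank]]
  p[is.na(p)] <- "<none>"
  if (length(unique(t)) < 2L) {
    warning("single truth label at rank ", rank, "; MCC defined as 0")
    return(0)
  }
  labels <- sort(unique(c(t, p)))
  s <- length(t)
  c_ok <- sum(p == t)
  pk <- vapply(labels, function(l) sum(p == l), numeric(1))
  tk <- vapply(labels, function(l) sum(t == l), numeric(1))
  num <- c_ok * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluate predictions at every rank
#'
#' Computes ACC, HA, recall, precision, F1 and MCC at phylum, class,
#' order, family, genus and species. Because the classifier assigns
#' species directly from the family level (genus is bypassed and only
#' ever derived from the species map), the genus row by default mirrors
#' the species decision's metrics; `genus = "derived"` instead scores
#' the derived genus *names*, under which sibling-species confusions
#' still count as correct genera.
#'
#' @inheritParams prf
#' @param genus `"mirror"` (default) or `"derived"`.
#' @return A `data.frame` of class `hftc_metrics`: one row per rank,
#'   columns `level`, `acc`, `ha`, `recall`, `precision`, `f1`, `mcc`.
#' @export
evaluate <- function(preds, truths,
                     averaging = c("weighted", "macro", "micro"),
                     genus = c("mirror", "derived")) {
  averaging <- match.arg(averaging)
  genus <- match.arg(genus)
  al <- align_pairs(as_rank_frame(preds), as_rank_frame(truths))
  one_rank <- function(r) {
    pr <- prf(al$preds, al$truths, r, averaging)
    data.frame(level = r,
               acc = rank_accuracy(al$preds, al$truths, r),
               ha = hierarchical_accuracy(al$preds, al$truths, r),
               recall = pr$recall, precision = pr$precision, f1 = pr$f1,
               mcc = mcc(al$preds, al$truths, r),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(setdiff(EVAL_RANKS, "genus"), one_rank)
  rep_tab <- do.call(rbind, rows)
  g <- if (genus == "derived") one_rank("genus")
       else {
         gg <- rep_tab[rep_tab$level == "species", , drop = FALSE]
         gg$level <- "genus"
         gg
       }
  rep_tab <- rbind(rep_tab[rep_tab$level != "species", ], g,
                   rep_tab[rep_tab$level == "species", ])
  rownames(rep_tab) <- NULL
  structure(rep_tab, averaging = averaging, genus = genus,
            n = nrow(al$preds),
            class = c("hftc_metrics", "data.frame"))
}

#' @export
print.hftc_metrics <- function(x, ...) {
  cat(sprintf("hftc metrics (%d records, %s averaging)\n",
              attr(x, "n"), attr(x, "averaging")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' @param report An `hftc_metrics` data frame from [evaluate()].
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
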