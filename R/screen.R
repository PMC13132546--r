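# Overlap screen: a gene that recurs in the top-k co-dependency lists of
# many known pathway members is itself a candidate member. The score of a
# gene is the number of distinct seed lists containing it.

#' Overlap scores across seed top-k lists
#'
#' For every gene appearing in at least one seed's top-k co-dependency
#' list, counts the number of distinct seeds whose list contains it. Seeds
#' themselves are scoreable when they occur in other seeds' lists. Genes
#' with the same symbol but distinct Entrez ids are scored separately.
#'
#' @param tab A `codependency_table` (see [build_codependency_table()]).
#' @return data.frame of class `score_table`, columns `symbol`, `entrez`,
#'   `score`, `n_pos`, `n_neg` (counts of positive/negative supporting
#'   correlations) and `seeds` (supporting seeds, `;`-joined as
#'   `SEED(r@rank)`), sorted by score descending then symbol, Entrez
#'   ascending.
#' @export
overlap_scores <- function(tab) {
  stopifnot(inherits(tab, "codependency_table"))
  nonempty <- Filter(nrow, unclass(tab))
  if (!length(nonempty)) stop("co-dependency table has no entries", call. = FALSE)
  rows <- lapply(names(nonempty), function(seed) {
    df <- nonempty[[seed]]
    key <- paste(df$symbol, df$entrez, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate gene inside the top-k list of seed '", seed, "'",
           call. = FALSE)
    }
    cbind(seed = seed, df, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, c(rows, make.row.names = FALSE))
  key <- paste(long$symbol, long$entrez, sep = "\r")
  split_idx <- split(seq_len(nrow(long)), key)
  recs <- lapply(split_idx, function(ii) {
    sub <- long[ii, , drop = FALSE]
    data.frame(
      symbol = sub$symbol[1L],
      entrez = sub$entrez[1L],
      score = length(unique(sub$seed)),
      n_pos = sum(sub$r > 0),
      n_neg = sum(sub$r < 0),
      seeds = paste(sprintf("%s(%.3f@%d)", sub$seed, sub$r, sub$rank),
                    collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(recs, make.row.names = FALSE))
  out <- out[order(-out$score, out$symbol, out$entrez, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Percentile-based score cutoff
#'
#' The smallest attained score `c` such that the fraction of scored genes
#' with score >= `c` is at most `top_fraction`. The cutoff is always a
#' score some gene actually attains (as in reporting "score >= 3 is
#' roughly the top 5%"). When even the maximum score is more common than
#' the requested fraction (e.g. all scores equal), returns
#' `max(score) + 1` with a warning.
#'
#' @param scores Integer vector of overlap scores, or a `score_table`.
#' @param top_fraction Target top fraction, in (0, 1) (default 0.05).
#' @return An integer cutoff.
#' @export
score_cutoff <- function(scores, top_fraction = 0.05) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) >= 1L, top_fraction > 0, top_fraction < 1)
  scores <- as.integer(scores)
  for (c_try in sort(unique(scores))) {
    if (mean(scores >= c_try) <= top_fraction) return(c_try)
  }
  warning("even the maximum score exceeds top_fraction; returning max + 1",
          call. = FALSE)
  max(scores) + 1L
}

#' Run the co-dependency overlap screen
#'
#' End-to-end screen: per-seed top-k co-dependency lists, overlap scores,
#' and a score cutoff. An explicit `cutoff` (default 3) takes precedence
#' over `top_fraction`; set `cutoff = NULL` to derive the cutoff from
#' `top_fraction` instead. The achieved top fraction (share of scored
#' genes at or above the cutoff) is always reported.
#'
#' @param x An [effect_matrix()], or a precomputed `codependency_table`.
#' @param seeds A [seed_list()] (ignored when `x` is already a table).
#' @param k Top-k list length (default 100).
#' @param ranking Correlation ranking convention (see
#'   [top_k_codependencies()]).
#' @param min_pairs Minimum shared observations per correlation.
#' @param cutoff Explicit integer score cutoff (default 3), or `NULL`.
#' @param top_fraction Target top fraction used when `cutoff` is `NULL`.
#' @return An object of class `screen_result`: list with `records` (a
#'   `score_table`), `cutoff`, `top_fraction_achieved`, `seeds`,
#'   `parameters`.
#' @export
run_screen <- function(x, seeds = NULL, k = 100L,
                       ranking = c("absolute", "signed_positive"),
                       min_pairs = 25L, cutoff = 3L, top_fraction = 0.05) {
  ranking <- match.arg(ranking)
  if (inherits(x, "codependency_table")) {
    tab <- x
    seed_symbols <- names(tab)
  } else {
    tab <- build_codependency_table(x, seeds, k = k, ranking = ranking,
                                    min_pairs = min_pairs)
    seed_symbols <- names(tab)
  }
  records <- overlap_scores(tab)
  cutoff <- if (is.null(cutoff)) score_cutoff(records, top_fraction) else
    as.integer(cutoff)
  structure(list(
    records = records,
    cutoff = cutoff,
    top_fraction_achieved = mean(records$score >= cutoff),
    seeds = seed_symbols,
    parameters = list(k = attr(tab, "k"), ranking = attr(tab, "ranking"),
                      min_pairs = attr(tab, "min_pairs"),
                      cutoff = cutoff, top_fraction = top_fraction)
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("overlap screen: %d seeds, %d scored genes\n",
              length(x$seeds), nrow(x$records)))
  cat(sprintf("  max score %d; cutoff %d captures %.1f%% of scored genes\n",
              max(x$records$score), x$cutoff, 100 * x$top_fraction_achieved))
  invisible(x)
}

#' Candidate hits at or above the score cutoff
#'
#' Records with score >= cutoff, optionally with seed genes removed (the
#' default: seeds are established pathway members, not novel candidates)
#' and with a free-text annotation column for manual literature triage.
#' The prior-knowledge triage itself is a human step and is represented as
#' a pass-through column, never computed.
#'
#' @param result A `screen_result`.
#' @param exclude_seeds Drop rows whose symbol is a seed (default `TRUE`).
#' @param annotations Optional named character vector, symbol -> note.
#' @return data.frame with the `score_table` columns plus `annotation`;
#'   zero rows when nothing clears the cutoff.
#' @export
candidate_hits <- function(result, exclude_seeds = TRUE, annotations = NULL) {
  stopifnot(inherits(result, "screen_result"))
  out <- result$records[result$records$score >= result$cutoff, , drop = FALSE]
  if (exclude_seeds) {
    out <- out[!(out$symbol %in% result$seeds), , drop = FALSE]
  }
  out$annotation <- if (is.null(annotations)) {
    rep(NA_character_, nrow(out))
  } else {
    unname(annotations[out$symbol])
  }
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Write screen outputs to a directory
#'
#' `scores.tsv` (all scored genes), `candidates.tsv` (score >= cutoff),
#' and `screen_params.cfg` (run parameters), all plain text.
#'
#' @param result A `screen_result`.
#' @param dir Output directory.
#' @param exclude_seeds Passed to [candidate_hits()].
#' @return Invisibly, `dir`.
#' @export
write_screen_result <- function(result, dir, exclude_seeds = TRUE) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(result$records, file.path(dir, "scores.tsv"))
  write_table(candidate_hits(result, exclude_seeds = exclude_seeds),
              file.path(dir, "candidates.tsv"))
  pars <- result$parameters
  pars$top_fraction_achieved <- result$top_fraction_achieved
  pars$n_seeds <- length(result$seeds)
  pars <- lapply(pars, function(v) if (is.null(v)) NA else v)
  write_config(pars, file.path(dir, "screen_params.cfg"))
  invisible(dir)
}
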