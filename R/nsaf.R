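# NSAF: normalized spectral abundance factor. SAF = SpC / L corrects
# spectral counts for protein length; dividing by the run total makes the
# values comparable across runs of different depth.

#' NSAF normalization of one AP-MS run
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)` within the run;
#' `pNSAF = 100 * NSAF`. Zero-count proteins get NSAF 0.
#'
#' @param table A [spectral_count_table()].
#' @param run_label Which run to normalize.
#' @return data.frame with columns `protein_id`, `spectral_count`,
#'   `length_aa`, `saf`, `nsaf`, `pnsaf`, in the input row order.
#' @export
nsaf_normalize <- function(table, run_label) {
  stopifnot(inherits(table, "spectral_count_table"))
  sub <- table[table$run_label == run_label, , drop = FALSE]
  if (!nrow(sub)) stop("run not found: '", run_label, "'", call. = FALSE)
  if (all(sub$spectral_count == 0L)) {
    stop("all spectral counts are zero in run '", run_label, "'", call. = FALSE)
  }
  saf <- sub$spectral_count / sub$length_aa
  # normalize the counts by run depth before forming the ratio: the
  # result is algebraically identical, and because IEEE division is
  # correctly rounded, (m*c)/(m*total) == c/total exactly, so scaling
  # every count by the same integer leaves every nsaf bit-identical
  rel <- (sub$spectral_count / sum(sub$spectral_count)) / sub$length_aa
  nsaf <- rel / sum(rel)
  data.frame(protein_id = sub$protein_id,
             spectral_count = sub$spectral_count,
             length_aa = sub$length_aa,
             saf = saf, nsaf = nsaf, pnsaf = 100 * nsaf,
             stringsAsFactors = FALSE)
}

#' NSAF normalization of every run in a table
#'
#' @param table A [spectral_count_table()].
#' @return Named list of per-run data.frames (see [nsaf_normalize()]).
#' @export
nsaf_normalize_all <- function(table) {
  stopifnot(inherits(table, "spectral_count_table"))
  runs <- unique(table$run_label)
  out <- lapply(runs, function(r) nsaf_normalize(table, r))
  names(out) <- runs
  out
}

#' Bait-versus-control enrichment summary
#'
#' Per protein, `log2((bait_nsaf + pseudocount) /
#' (mean_control_nsaf + pseudocount))`, where a protein absent from a run
#' contributes NSAF 0 there. This is a descriptive fold-change ranking
#' with a pseudocount, not a significance test; it makes no claim about
#' enrichment p-values.
#'
#' @param bait_run NSAF data.frame of the bait run (see
#'   [nsaf_normalize()]).
#' @param control_runs Non-empty list of NSAF data.frames of control runs.
#' @param pseudocount Positive stabilizer; default: half the smallest
#'   nonzero NSAF across all supplied runs.
#' @param fold_threshold Linear fold change at or above which a
#'   bait-present protein is flagged (default 2).
#' @return data.frame with columns `protein_id`, `bait_nsaf`,
#'   `mean_control_nsaf`, `log2_fold_enrichment`, `enrichment_flag`,
#'   sorted by fold descending then protein id.
#' @export
enrichment_vs_controls <- function(bait_run, control_runs,
                                   pseudocount = NULL, fold_threshold = 2) {
  if (!length(control_runs)) stop("need at least one control run", call. = FALSE)
  if (is.data.frame(control_runs)) control_runs <- list(control_runs)
  all_runs <- c(list(bait_run), control_runs)
  proteins <- sort(unique(unlist(lapply(all_runs, `[[`, "protein_id"))))
  nsaf_of <- function(run, ids) {
    v <- run$nsaf[match(ids, run$protein_id)]
    v[is.na(v)] <- 0
    v
  }
  bait <- nsaf_of(bait_run, proteins)
  ctrl <- rowMeans(vapply(control_runs, nsaf_of, numeric(length(proteins)),
                          ids = proteins))
  if (is.null(pseudocount)) {
    nz <- unlist(lapply(all_runs, function(r) r$nsaf[r$nsaf > 0]))
    pseudocount <- min(nz) / 2
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  fold <- log2((bait + pseudocount) / (ctrl + pseudocount))
  out <- data.frame(protein_id = proteins,
                    bait_nsaf = bait,
                    mean_control_nsaf = ctrl,
                    log2_fold_enrichment = fold,
                    enrichment_flag = (2^fold >= fold_threshold) & (bait > 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_fold_enrichment, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
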