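# Co-dependency: correlation of two genes' dependency profiles across cell
# lines. Genes whose knockout fitness effects co-vary tend to act in the
# same pathway, which is what the overlap screen exploits.

# internal: resolve a gene to a column index; entrez breaks symbol ties
gene_index <- function(em, symbol, entrez = NA_integer_) {
  idx <- which(em$genes$symbol == symbol)
  if (!length(idx)) {
    stop("gene not found in matrix: '", symbol, "'", call. = FALSE)
  }
  if (length(idx) > 1L) {
    if (!is.na(entrez)) {
      hit <- idx[which(em$genes$entrez[idx] == entrez)]
      if (length(hit) == 1L) return(hit)
    }
    idx <- idx[order(em$genes$entrez[idx], na.last = TRUE)]
  }
  idx[1L]
}

#' Pairwise co-dependency correlation between two genes
#'
#' Pearson correlation of two genes' effect profiles over the cell lines in
#' which both are observed (pairwise-complete). Returns `NA` when fewer
#' than `min_pairs` shared observations remain or either profile is
#' constant on the shared lines.
#'
#' @param em An [effect_matrix()].
#' @param gene_a,gene_b Gene symbols (character), or a list with elements
#'   `symbol` and `entrez` to disambiguate duplicated symbols.
#' @param min_pairs Minimum shared observations required (default 25).
#' @return A single correlation in `[-1, 1]`, or `NA_real_`.
#' @export
pairwise_correlation <- function(em, gene_a, gene_b, min_pairs = 25L) {
  stopifnot(inherits(em, "effect_matrix"), min_pairs >= 3L)
  ia <- resolve_gene(em, gene_a)
  ib <- resolve_gene(em, gene_b)
  profile_cor(em$values[, ia], em$values[, ib], min_pairs)
}

resolve_gene <- function(em, gene) {
  if (is.list(gene)) {
    gene_index(em, gene$symbol, if (is.null(gene$entrez)) NA_integer_ else gene$entrez)
  } else {
    gene_index(em, as.character(gene))
  }
}

profile_cor <- function(x, y, min_pairs) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Top-k co-dependency list for one seed gene
#'
#' Correlates the seed's effect profile against every other gene in the
#' matrix and returns the k strongest partners. Ranking is by absolute
#' correlation by default (so strong negative co-dependencies, e.g. with a
#' pathway repressor, are rankable) or by signed correlation descending.
#' Ties are broken deterministically by symbol then Entrez id, ascending.
#' The seed never appears in its own list.
#'
#' @param em An [effect_matrix()].
#' @param seed Seed gene (symbol or `list(symbol=, entrez=)`).
#' @param k List length (default 100, the portal-era convention).
#' @param ranking `"absolute"` (default) or `"signed_positive"`.
#' @param min_pairs Minimum shared observations per pair (default 25).
#' @return data.frame with columns `symbol`, `entrez`, `r`, `rank`,
#'   `n_pairs`, at most `k` rows, ordered by the ranking key.
#' @export
top_k_codependencies <- function(em, seed, k = 100L,
                                 ranking = c("absolute", "signed_positive"),
                                 min_pairs = 25L) {
  ranking <- match.arg(ranking)
  stopifnot(inherits(em, "effect_matrix"), k >= 1L)
  iseed <- resolve_gene(em, seed)
  x <- em$values[, iseed]
  n <- ncol(em$values)
  r <- rep(NA_real_, n)
  np <- integer(n)
  for (j in seq_len(n)) {
    if (j == iseed) next
    y <- em$values[, j]
    np[j] <- sum(!is.na(x) & !is.na(y))
    r[j] <- profile_cor(x, y, min_pairs)
  }
  usable <- which(!is.na(r))
  if (!length(usable)) {
    warning("no partner of '", em$genes$symbol[iseed], "' meets min_pairs = ",
            min_pairs, call. = FALSE)
    return(data.frame(symbol = character(), entrez = integer(),
                      r = numeric(), rank = integer(), n_pairs = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- if (ranking == "absolute") abs(r[usable]) else r[usable]
  ord <- usable[order(-key, em$genes$symbol[usable], em$genes$entrez[usable],
                      na.last = TRUE)]
  take <- utils::head(ord, k)
  data.frame(symbol = em$genes$symbol[take],
             entrez = em$genes$entrez[take],
             r = r[take],
             rank = seq_along(take),
             n_pairs = np[take],
             stringsAsFactors = FALSE)
}

#' Build the per-seed co-dependency table
#'
#' One top-k list per seed present in the matrix. Seeds absent from the
#' matrix are skipped with a warning and recorded in the
#' `skipped_seeds` attribute.
#'
#' @inheritParams top_k_codependencies
#' @param seeds A [seed_list()].
#' @return An object of class `codependency_table`: a named list (one
#'   data.frame per seed symbol) with attributes `k`, `ranking`,
#'   `min_pairs`, `skipped_seeds`.
#' @export
build_codependency_table <- function(em, seeds, k = 100L,
                                     ranking = c("absolute", "signed_positive"),
                                     min_pairs = 25L) {
  ranking <- match.arg(ranking)
  stopifnot(inherits(em, "effect_matrix"))
  if (!inherits(seeds, "seed_list")) {
    seeds <- seed_list(seeds)
  }
  present <- seeds$symbol %in% em$genes$symbol
  if (!any(present)) stop("none of the seed genes is present in the matrix",
                          call. = FALSE)
  if (any(!present)) {
    warning("seed(s) absent from matrix, skipped: ",
            paste(seeds$symbol[!present], collapse = ", "), call. = FALSE)
  }
  lists <- lapply(which(present), function(i) {
    top_k_codependencies(em, list(symbol = seeds$symbol[i],
                                  entrez = seeds$entrez[i]),
                         k = k, ranking = ranking, min_pairs = min_pairs)
  })
  names(lists) <- seeds$symbol[present]
  structure(lists, k = k, ranking = ranking, min_pairs = min_pairs,
            skipped_seeds = seeds$symbol[!present],
            class = "codependency_table")
}

#' Assemble a co-dependency table from precomputed per-seed lists
#'
#' Supports the alternate input path where portal-exported top-k lists are
#' supplied directly (one data.frame per seed, columns `symbol`, `r`,
#' optionally `entrez`, `rank`, `n_pairs`), bypassing correlation.
#'
#' @param lists Named list of data.frames, one per seed symbol.
#' @param k Nominal list length (default: longest list supplied).
#' @return A `codependency_table`.
#' @export
as_codependency_table <- function(lists, k = NULL) {
  stopifnot(is.list(lists), !is.null(names(lists)), all(nzchar(names(lists))))
  if (!length(lists)) stop("empty co-dependency table", call. = FALSE)
  nm <- names(lists)
  lists <- lapply(nm, function(seed) {
    df <- as.data.frame(lists[[seed]], stringsAsFactors = FALSE)
    if (!all(c("symbol", "r") %in% names(df))) {
      stop("precomputed list for '", seed, "' needs columns symbol, r",
           call. = FALSE)
    }
    if (is.null(df$entrez)) df$entrez <- NA_integer_
    if (is.null(df$rank)) df$rank <- seq_len(nrow(df))
    if (is.null(df$n_pairs)) df$n_pairs <- NA_integer_
    if (any(df$symbol == seed)) {
      stop("seed '", seed, "' appears in its own list", call. = FALSE)
    }
    df[, c("symbol", "entrez", "r", "rank", "n_pairs")]
  })
  names(lists) <- nm
  if (is.null(k)) k <- max(vapply(lists, nrow, integer(1L)))
  structure(lists, k = k, ranking = "precomputed", min_pairs = NA_integer_,
            skipped_seeds = character(), class = "codependency_table")
}

#' Read precomputed top-k lists from per-seed files
#'
#' @param paths Named character vector of file paths (names = seed
#'   symbols); files are tab-delimited with at least `symbol` and `r`.
#' @param k Nominal list length (see [as_codependency_table()]).
#' @return A `codependency_table`.
#' @export
read_precomputed_codependency <- function(paths, k = NULL) {
  stopifnot(!is.null(names(paths)))
  as_codependency_table(lapply(paths, read_result_table), k = k)
}

#' Write a co-dependency table to a directory
#'
#' One tab-delimited file per seed (`codep_<SEED>.tsv`, columns `symbol`,
#' `entrez`, `r`, `rank`, `n_pairs`) plus a combined long-format table
#' `codependencies.tsv` with a leading `seed` column.
#'
#' @param tab A `codependency_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_codependency_table <- function(tab, dir) {
  stopifnot(inherits(tab, "codependency_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list()
  for (seed in names(tab)) {
    write_table(tab[[seed]], file.path(dir, paste0("codep_", seed, ".tsv")))
    if (nrow(tab[[seed]])) {
      long[[seed]] <- cbind(seed = seed, tab[[seed]], stringsAsFactors = FALSE)
    }
  }
  combined <- if (length(long)) do.call(rbind, c(long, make.row.names = FALSE)) else
    data.frame(seed = character(), symbol = character(), entrez = integer(),
               r = numeric(), rank = integer(), n_pairs = integer())
  write_table(combined, file.path(dir, "codependencies.tsv"))
  invisible(dir)
}
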