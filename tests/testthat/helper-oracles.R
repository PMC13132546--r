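# Independent brute-force oracles. These deliberately share no code with
# the package internals: textbook formulas and exhaustive scans only.

# textbook Pearson: cov / (sd_x * sd_y), pairwise-complete
oracle_pearson <- function(x, y, min_pairs = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / (sx * sy)
}

# exhaustive full-sort top-k for one seed symbol
oracle_top_k <- function(em, seed_symbol, k, ranking = "absolute",
                         min_pairs = 3L) {
  vals <- em$values
  genes <- em$genes
  iseed <- which(genes$symbol == seed_symbol)[1L]
  rows <- list()
  for (j in seq_len(ncol(vals))) {
    if (j == iseed) next
    r <- oracle_pearson(vals[, iseed], vals[, j], min_pairs)
    if (is.na(r)) next
    rows[[length(rows) + 1L]] <- data.frame(
      symbol = genes$symbol[j], entrez = genes$entrez[j], r = r)
  }
  if (!length(rows)) {
    return(data.frame(symbol = character(), entrez = integer(), r = numeric()))
  }
  df <- do.call(rbind, rows)
  key <- if (ranking == "absolute") abs(df$r) else df$r
  df <- df[order(-key, df$symbol, df$entrez), , drop = FALSE]
  head(df, k)
}

# brute-force set-intersection overlap counts over raw per-seed lists
oracle_overlap_counts <- function(lists) {
  keys <- unique(unlist(lapply(lists, function(df) {
    paste(df$symbol, df$entrez, sep = "|")
  })))
  counts <- vapply(keys, function(k) {
    sum(vapply(lists, function(df) {
      k %in% paste(df$symbol, df$entrez, sep = "|")
    }, logical(1L)))
  }, integer(1L))
  names(counts) <- keys
  counts
}

# scan every attained threshold; smallest one meeting the fraction
oracle_score_cutoff <- function(scores, top_fraction) {
  for (c_try in sort(unique(scores))) {
    if (sum(scores >= c_try) / length(scores) <= top_fraction) return(c_try)
  }
  max(scores) + 1L
}

# dense 2-D grid search minimizing SSE of Req * (1 - exp(-k t))
oracle_grid_exp_assoc <- function(t, y, req_range, k_range, n_grid = 200L) {
  reqs <- seq(req_range[1L], req_range[2L], length.out = n_grid)
  ks <- seq(k_range[1L], k_range[2L], length.out = n_grid)
  best <- c(req = NA_real_, k = NA_real_, sse = Inf)
  for (req in reqs) {
    for (k in ks) {
      sse <- sum((y - req * (1 - exp(-k * t)))^2)
      if (sse < best[["sse"]]) best <- c(req = req, k = k, sse = sse)
    }
  }
  best
}

# dense 2-D grid search minimizing SSE of Rmax * C / (KD + C)
oracle_grid_hyperbola <- function(conc, req, kd_range, rmax_range,
                                  n_grid = 300L) {
  kds <- seq(kd_range[1L], kd_range[2L], length.out = n_grid)
  rmaxs <- seq(rmax_range[1L], rmax_range[2L], length.out = n_grid)
  best <- c(kd = NA_real_, rmax = NA_real_, sse = Inf)
  for (kd in kds) {
    for (rmax in rmaxs) {
      sse <- sum((req - rmax * conc / (kd + conc))^2)
      if (sse < best[["sse"]]) best <- c(kd = kd, rmax = rmax, sse = sse)
    }
  }
  best
}

# small effect matrix built directly from a values matrix
make_em <- function(values, symbols = sprintf("G%02d", seq_len(ncol(values))),
                    entrez = seq_len(ncol(values))) {
  effect_matrix(values,
                data.frame(symbol = symbols, entrez = as.integer(entrez),
                           stringsAsFactors = FALSE),
                cell_lines = sprintf("CL%03d", seq_len(nrow(values))))
}
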