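#' Parse DepMap-style gene column headers
#'
#' Gene-effect exports from the DepMap portal label columns as
#' `"SYMBOL (ENTREZ)"`, e.g. `"CDK2 (1017)"`. This splits such labels into
#' the HGNC-style symbol and the numeric Entrez identifier. A bare symbol
#' (no parenthesised id) is accepted and yields a missing Entrez id.
#'
#' @param x Character vector of column labels.
#' @return A data.frame with columns `symbol` (character) and `entrez`
#'   (integer, `NA` when absent), one row per element of `x`.
#' @examples
#' parse_gene_header(c("CDK2 (1017)", "TP53"))
#' @export
parse_gene_header <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^(\\S+)\\s*\\(([0-9]+)\\)$", x))
  symbol <- character(length(x))
  entrez <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    if (length(m[[i]]) == 3L) {
      symbol[i] <- m[[i]][2L]
      entrez[i] <- as.integer(m[[i]][3L])
    } else {
      if (!nzchar(x[i]) || grepl("\\s", x[i])) {
        stop("malformed gene header token: '", x[i], "'", call. = FALSE)
      }
      symbol[i] <- x[i]
    }
  }
  data.frame(symbol = symbol, entrez = entrez, stringsAsFactors = FALSE)
}

#' Format gene identifiers as DepMap-style headers
#'
#' Inverse of [parse_gene_header()]: `"SYMBOL (ENTREZ)"` when an Entrez id
#' is present, the bare symbol otherwise.
#'
#' @param symbol Character vector of gene symbols.
#' @param entrez Integer vector of Entrez ids (`NA` allowed).
#' @return Character vector of header labels.
#' @export
format_gene_header <- function(symbol, entrez = NA_integer_) {
  entrez <- rep_len(as.integer(entrez), length(symbol))
  ifelse(is.na(entrez), symbol, sprintf("%s (%d)", symbol, entrez))
}

#' Construct a validated gene-effect matrix
#'
#' The substrate of the co-dependency screen: a cell-line-by-gene matrix of
#' real-valued dependency scores (more negative = stronger fitness
#' dependence). Columns with fewer than two non-missing entries carry no
#' correlation information and are dropped with a warning.
#'
#' @param values Numeric matrix, rows = cell lines, columns = genes.
#' @param genes data.frame with columns `symbol`, `entrez` (one row per
#'   matrix column), as returned by [parse_gene_header()].
#' @param cell_lines Character vector of cell-line identifiers; defaults to
#'   `rownames(values)`.
#' @return An object of class `effect_matrix`: a list with elements
#'   `values` (the matrix, dimnames cell lines x symbols) and `genes`.
#' @export
effect_matrix <- function(values, genes, cell_lines = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_lines)) {
    stop("cell-line identifiers are required", call. = FALSE)
  }
  cell_lines <- as.character(cell_lines)
  if (length(cell_lines) != nrow(values)) {
    stop("cell-line labels do not match matrix rows", call. = FALSE)
  }
  if (anyDuplicated(cell_lines)) {
    stop("duplicate cell-line identifiers", call. = FALSE)
  }
  if (!is.data.frame(genes) || !all(c("symbol", "entrez") %in% names(genes))) {
    stop("'genes' must be a data.frame with columns symbol, entrez", call. = FALSE)
  }
  if (nrow(genes) != ncol(values)) {
    stop("gene table does not match matrix columns", call. = FALSE)
  }
  key <- paste(genes$symbol, genes$entrez, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- genes$symbol[duplicated(key)]
    stop("duplicate gene column: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  usable <- colSums(!is.na(values)) >= 2L
  if (!any(usable)) {
    stop("no usable columns: every gene has fewer than 2 observed values",
         call. = FALSE)
  }
  if (!all(usable)) {
    warning(sum(!usable), " gene column(s) dropped (fewer than 2 observed values): ",
            paste(utils::head(genes$symbol[!usable], 5L), collapse = ", "),
            call. = FALSE)
    values <- values[, usable, drop = FALSE]
    genes <- genes[usable, , drop = FALSE]
  }
  rownames(values) <- cell_lines
  colnames(values) <- genes$symbol
  rownames(genes) <- NULL
  structure(list(values = values, genes = genes), class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("effect_matrix: %d cell lines x %d genes (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.effect_matrix <- function(x) dim(x$values)

#' Read a gene-effect matrix from delimited text
#'
#' Reads a comma-delimited gene-effect file in the DepMap portal layout:
#' cell lines on rows, `"SYMBOL (ENTREZ)"` headers on columns
#' (`orientation = "lines_by_genes"`, the default). A transposed file is
#' handled with `orientation = "genes_by_lines"`; the returned object is
#' always in canonical lines-by-genes orientation. Empty cells and `NA`
#' are treated as missing.
#'
#' @param path Path to a CSV file whose first column holds row labels.
#' @param orientation Layout of the file on disk.
#' @return An [effect_matrix()].
#' @export
read_effect_matrix <- function(path,
                               orientation = c("lines_by_genes", "genes_by_lines")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) {
    stop("effect matrix file needs a label column plus at least one data column",
         call. = FALSE)
  }
  row_labels <- trimws(df[[1L]])
  headers <- colnames(df)[-1L]  # before subsetting: `[.data.frame` mangles duplicates
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body))
  for (j in seq_len(ncol(body))) {
    col <- trimws(body[[j]])
    col[col == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad)) {
      stop("non-numeric value '", col[bad[1L]], "' in column '",
           headers[j], "'", call. = FALSE)
    }
    vals[, j] <- num
  }
  if (orientation == "lines_by_genes") {
    genes <- parse_gene_header(headers)
    em <- effect_matrix(vals, genes, cell_lines = row_labels)
  } else {
    genes <- parse_gene_header(row_labels)
    em <- effect_matrix(t(vals), genes, cell_lines = headers)
  }
  message(sprintf("read_effect_matrix: %d x %d, %d missing cells",
                  nrow(em$values), ncol(em$values), sum(is.na(em$values))))
  em
}

#' Write a gene-effect matrix as CSV
#'
#' Lines-by-genes layout with DepMap-style headers; full double precision
#' so that write/read round-trips are bit-exact. Missing values are written
#' as empty cells.
#'
#' @param em An [effect_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_effect_matrix <- function(em, path) {
  stopifnot(inherits(em, "effect_matrix"))
  headers <- format_gene_header(em$genes$symbol, em$genes$entrez)
  body <- apply(em$values, 2L, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  })
  body <- matrix(body, nrow = nrow(em$values))
  lines <- c(
    paste(c("cell_line", headers), collapse = ","),
    vapply(seq_len(nrow(body)), function(i) {
      paste(c(rownames(em$values)[i], body[i, ]), collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a seed gene list
#'
#' One symbol per line; lines starting with `#` are comments. Symbols may
#' optionally carry a DepMap-style `"(ENTREZ)"` suffix. Duplicates are
#' removed (first occurrence kept) with a warning.
#'
#' @param path Path to a plain-text file.
#' @param label Label for the list; defaults to the file name.
#' @return An object of class `seed_list`: a data.frame with columns
#'   `symbol`, `entrez` and attribute `label`.
#' @export
read_seed_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("seed list is empty after filtering", call. = FALSE)
  genes <- parse_gene_header(lines)
  seed_list(genes$symbol, genes$entrez, label = label)
}

#' Construct a seed list in code
#'
#' @param symbols Character vector of gene symbols.
#' @param entrez Optional integer vector of Entrez ids.
#' @param label List label.
#' @return A `seed_list` (see [read_seed_list()]).
#' @export
seed_list <- function(symbols, entrez = NA_integer_, label = "seeds") {
  symbols <- as.character(symbols)
  if (!length(symbols)) stop("seed list must be non-empty", call. = FALSE)
  entrez <- rep_len(as.integer(entrez), length(symbols))
  dup <- duplicated(symbols)
  if (any(dup)) {
    warning("duplicate seed symbol(s) removed: ",
            paste(unique(symbols[dup]), collapse = ", "), call. = FALSE)
    entrez <- entrez[!dup]
    symbols <- symbols[!dup]
  }
  structure(data.frame(symbol = symbols, entrez = entrez,
                       stringsAsFactors = FALSE),
            label = label, class = c("seed_list", "data.frame"))
}

#' Write a result table as tab-delimited text
#'
#' Column order is taken from the data.frame as supplied (each producer in
#' this package documents and fixes its column order). Floating-point
#' columns are serialized with 6 significant digits; a zero-row table
#' yields a header-only file.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      col <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(signif(v, 6L), scientific = NA)
      }, character(1L))
      out[[j]] <- col
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tab-delimited result table
#'
#' @param path Path written by [write_table()].
#' @return A data.frame.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# Flat key = value config files (run manifests, truth sidecars).
#' Write a flat key-value config file
#' @param x Named list of scalar values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    if (is.double(v)) v <- sprintf("%.17g", v)
    paste0(k, " = ", paste(as.character(v), collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value config file
#' @param path Path written by [write_config()] (or hand-edited).
#' @return Named list of character values (comma-split when plural).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    out[[key]] <- strsplit(val, ",", fixed = TRUE)[[1L]]
  }
  out
}

#' Write a sensorgram set to a directory
#'
#' One tab-delimited file per curve (columns `time_s`, `response_nm`) plus
#' a `metadata.tsv` sidecar recording, per curve, the analyte concentration
#' (molar), phase boundaries, and its role (sample, matched reference,
#' zero-analyte sample, zero-analyte reference).
#'
#' @param set A `sensorgram_set` (see [simulate_sensorgrams()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sensorgram_set <- function(set, dir) {
  stopifnot(inherits(set, "sensorgram_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- flatten_sensorgram_set(set)
  meta <- data.frame(
    file = sprintf("curve_%03d.tsv", seq_along(curves)),
    role = vapply(curves, function(cv) attr(cv, "role"), character(1L)),
    analyte_concentration_M = vapply(curves, function(cv) cv$conc, numeric(1L)),
    assoc_start_s = vapply(curves, function(cv) cv$assoc_start_s, numeric(1L)),
    dissoc_start_s = vapply(curves, function(cv) cv$dissoc_start_s, numeric(1L)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(curves)) {
    df <- data.frame(time_s = sprintf("%.17g", curves[[i]]$time_s),
                     response_nm = sprintf("%.17g", curves[[i]]$response))
    utils::write.table(df, file.path(dir, meta$file[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  meta_out <- meta
  meta_out$analyte_concentration_M <- sprintf("%.17g", meta$analyte_concentration_M)
  utils::write.table(meta_out, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_config(list(ligand_label = set$ligand_label),
               file.path(dir, "set.cfg"))
  invisible(dir)
}

#' Read a sensorgram set from a directory
#'
#' @param dir Directory written by [write_sensorgram_set()] (or assembled by
#'   hand in the same layout).
#' @return A `sensorgram_set`.
#' @export
read_sensorgram_set <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("missing metadata.tsv in ", dir, call. = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "set.cfg")
  label <- if (file.exists(cfg_path)) read_config(cfg_path)$ligand_label else "ligand"
  curves <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    df <- utils::read.delim(file.path(dir, meta$file[i]))
    conc <- as.numeric(meta$analyte_concentration_M[i])
    role <- meta$role[i]
    sg <- sensorgram(df$time_s, df$response_nm, conc = conc,
                     assoc_start_s = meta$assoc_start_s[i],
                     dissoc_start_s = meta$dissoc_start_s[i],
                     is_reference = role %in% c("reference", "zero_reference"))
    attr(sg, "role") <- role
    curves[[i]] <- sg
  }
  assemble_sensorgram_set(curves, ligand_label = label)
}

# internal: sensorgram_set <-> flat role-tagged curve list
flatten_sensorgram_set <- function(set) {
  tag <- function(cv, role) { attr(cv, "role") <- role; cv }
  out <- list()
  for (i in seq_along(set$samples)) {
    out <- c(out, list(tag(set$samples[[i]], "sample")))
  }
  for (i in seq_along(set$references)) {
    out <- c(out, list(tag(set$references[[i]], "reference")))
  }
  if (!is.null(set$zero_sample)) {
    out <- c(out, list(tag(set$zero_sample, "zero_sample")))
  }
  if (!is.null(set$zero_reference)) {
    out <- c(out, list(tag(set$zero_reference, "zero_reference")))
  }
  out
}

assemble_sensorgram_set <- function(curves, ligand_label = "ligand") {
  role <- vapply(curves, function(cv) attr(cv, "role"), character(1L))
  zs <- curves[role == "zero_sample"]
  zr <- curves[role == "zero_reference"]
  sensorgram_set(
    samples = curves[role == "sample"],
    references = curves[role == "reference"],
    zero_sample = if (length(zs)) zs[[1L]] else NULL,
    zero_reference = if (length(zr)) zr[[1L]] else NULL,
    ligand_label = ligand_label
  )
}

#' Read an AP-MS spectral-count table
#'
#' Tab-delimited with columns `protein_id`, `spectral_count`, `length_aa`,
#' `run_label`, `is_control` (logical or 0/1).
#'
#' @param path Input path.
#' @return A validated `spectral_count_table` (see [spectral_count_table()]).
#' @export
read_spectral_counts <- function(path) {
  df <- read_result_table(path)
  need <- c("protein_id", "spectral_count", "length_aa", "run_label", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("spectral-count table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  spectral_count_table(df$protein_id, df$spectral_count, df$length_aa,
                       df$run_label, as.logical(df$is_control))
}

#' Construct a validated spectral-count table
#'
#' @param protein_id Character protein identifiers.
#' @param spectral_count Non-negative integer spectral counts (SpC).
#' @param length_aa Positive integer protein lengths in amino acids.
#' @param run_label Run identifier (bait or control run).
#' @param is_control Logical, control-run flag.
#' @return A data.frame of class `spectral_count_table`.
#' @export
spectral_count_table <- function(protein_id, spectral_count, length_aa,
                                 run_label, is_control) {
  df <- data.frame(protein_id = as.character(protein_id),
                   spectral_count = as.integer(spectral_count),
                   length_aa = as.integer(length_aa),
                   run_label = as.character(run_label),
                   is_control = as.logical(is_control),
                   stringsAsFactors = FALSE)
  if (any(df$spectral_count < 0L)) stop("negative spectral count", call. = FALSE)
  if (any(df$length_aa <= 0L)) stop("protein lengths must be > 0", call. = FALSE)
  key <- paste(df$protein_id, df$run_label, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (protein_id, run_label) pair", call. = FALSE)
  }
  class(df) <- c("spectral_count_table", "data.frame")
  df
}
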