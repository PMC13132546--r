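# Ground-truth-known generators for each analysis stage. Every generator
# takes an explicit rng_seed and is bit-reproducible given it.

#' Describe a planted correlated gene module
#'
#' @param members Gene indices (into the simulated gene universe) or
#'   symbols; >= 2 members.
#' @param loading Factor loading per member (recycled); sign allowed, must
#'   be nonzero. Larger |loading| relative to the noise sd means tighter
#'   within-module correlation.
#' @param label Module label.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(members, loading = 1, label = "module") {
  if (length(members) < 2L) stop("a module needs >= 2 members", call. = FALSE)
  loading <- rep_len(as.numeric(loading), length(members))
  if (any(loading == 0)) stop("module loadings must be nonzero", call. = FALSE)
  structure(list(members = members, loading = loading, label = label),
            class = "module_spec")
}

#' Simulate a gene-effect matrix with planted modules
#'
#' Latent-factor (spiked covariance) model: each module m has a
#' standard-normal latent factor f_m over cell lines, and
#' `value(line, g) = sum_m loading(g, m) * f_m(line) + noise`, with
#' i.i.d. Gaussian noise of sd `noise_sd`. Within a module with uniform
#' loading a and noise sd s, the expected pairwise correlation is
#' `a^2 / (a^2 + s^2)`. Entries are then masked missing uniformly at rate
#' `missing_rate`.
#'
#' @param n_genes,n_lines Universe size; `n_lines >= 4`.
#' @param modules List of [module_spec()] objects (may be empty).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param missing_rate Fraction of entries masked missing, in [0, 1).
#' @param rng_seed Integer seed; the generator is bit-reproducible.
#' @return List with `matrix` (an [effect_matrix()]) and `truth` (module
#'   assignments and generator parameters).
#' @export
simulate_effect_matrix <- function(n_genes, n_lines, modules = list(),
                                   noise_sd = 0.5, missing_rate = 0,
                                   rng_seed = 1L) {
  if (n_lines < 4L) stop("need at least 4 cell lines", call. = FALSE)
  stopifnot(noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  if (inherits(modules, "module_spec")) modules <- list(modules)
  symbols <- sprintf("G%03d", seq_len(n_genes))
  set.seed(rng_seed)
  values <- matrix(stats::rnorm(n_lines * n_genes, sd = noise_sd),
                   nrow = n_lines, ncol = n_genes)
  assignment <- vector("list", length(modules))
  seen <- integer(0)
  for (m in seq_along(modules)) {
    mod <- modules[[m]]
    idx <- if (is.character(mod$members)) match(mod$members, symbols) else
      as.integer(mod$members)
    if (anyNA(idx) || any(idx < 1L | idx > n_genes)) {
      stop("module members outside the gene universe", call. = FALSE)
    }
    if (length(intersect(idx, seen))) {
      message("simulate_effect_matrix: overlapping module memberships")
    }
    seen <- union(seen, idx)
    f <- stats::rnorm(n_lines)
    for (j in seq_along(idx)) {
      values[, idx[j]] <- values[, idx[j]] + mod$loading[j] * f
    }
    assignment[[m]] <- list(label = mod$label, members = symbols[idx],
                            loading = mod$loading)
  }
  if (missing_rate > 0) {
    mask <- stats::runif(length(values)) < missing_rate
    values[mask] <- NA_real_
  }
  genes <- data.frame(symbol = symbols, entrez = 1000L + seq_len(n_genes),
                      stringsAsFactors = FALSE)
  em <- effect_matrix(values, genes,
                      cell_lines = sprintf("ACH-%06d", seq_len(n_lines)))
  list(matrix = em,
       truth = list(modules = assignment, noise_sd = noise_sd,
                    missing_rate = missing_rate, rng_seed = rng_seed))
}

#' Simulate 1:1-model BLI sensorgrams
#'
#' Forward model of a 1:1 Langmuir interaction: per concentration C,
#' association `R(t) = Req * (1 - exp(-kobs t))` with
#' `Req = Rmax C / (KD + C)` and `kobs = kon C + koff`, then dissociation
#' `R(t) = R_end * exp(-koff t)`. The response is 0 at the start of
#' association before noise. Gaussian noise (sd `noise_sd`) and linear
#' drift (`drift_per_s`, shared by all sensors) are added; matched
#' unloaded-reference curves and zero-analyte blanks carry drift and their
#' own noise only, so double reference subtraction can be tested against
#' the known clean signal.
#'
#' @param kon Association rate constant, 1/(M*s).
#' @param koff Dissociation rate constant, 1/s (>= 0).
#' @param rmax Saturating response, response units.
#' @param concentrations Positive analyte concentrations, molar.
#' @param t_baseline_s,t_assoc_s,t_dissoc_s Phase durations, seconds.
#' @param dt_s Sampling interval, seconds (Octet-style instruments sample
#'   at 5-10 Hz; default 0.2 s).
#' @param noise_sd Per-point Gaussian noise sd, response units.
#' @param drift_per_s Linear drift slope, response units per second.
#' @param rng_seed Integer seed.
#' @return A `sensorgram_set` whose `truth` element records the rate
#'   constants, KD and the per-concentration kobs and Req.
#' @export
simulate_sensorgrams <- function(kon, koff, rmax, concentrations,
                                 t_baseline_s = 10, t_assoc_s = 300,
                                 t_dissoc_s = 300, dt_s = 0.2,
                                 noise_sd = 0, drift_per_s = 0,
                                 rng_seed = 1L) {
  stopifnot(kon > 0, koff >= 0, rmax > 0, length(concentrations) >= 1L,
            all(concentrations > 0))
  if (dt_s >= min(t_assoc_s, t_dissoc_s)) {
    stop("sampling interval must be shorter than each phase", call. = FALSE)
  }
  kd <- koff / kon
  tt <- seq(0, t_baseline_s + t_assoc_s + t_dissoc_s, by = dt_s)
  a0 <- t_baseline_s
  d0 <- t_baseline_s + t_assoc_s
  clean_curve <- function(conc) {
    kobs <- kon * conc + koff
    req <- rmax * conc / (kd + conc)
    r <- numeric(length(tt))
    ia <- tt >= a0 & tt < d0
    id <- tt >= d0
    r[ia] <- req * (1 - exp(-kobs * (tt[ia] - a0)))
    r_end <- req * (1 - exp(-kobs * t_assoc_s))
    r[id] <- r_end * exp(-koff * (tt[id] - d0))
    r
  }
  set.seed(rng_seed)
  noisy <- function(resp) {
    resp + drift_per_s * tt +
      if (noise_sd > 0) stats::rnorm(length(tt), sd = noise_sd) else 0
  }
  mk <- function(resp, conc, is_ref) {
    sensorgram(tt, resp, conc = conc, assoc_start_s = a0, dissoc_start_s = d0,
               is_reference = is_ref)
  }
  samples <- lapply(concentrations, function(conc) {
    mk(noisy(clean_curve(conc)), conc, FALSE)
  })
  references <- lapply(concentrations, function(conc) {
    mk(noisy(numeric(length(tt))), conc, TRUE)
  })
  zero_sample <- mk(noisy(numeric(length(tt))), 0, FALSE)
  zero_reference <- mk(noisy(numeric(length(tt))), 0, TRUE)
  truth <- list(kon = kon, koff = koff, rmax = rmax, kd = kd,
                concentrations = concentrations,
                kobs = kon * concentrations + koff,
                req = rmax * concentrations / (kd + concentrations),
                noise_sd = noise_sd, drift_per_s = drift_per_s,
                rng_seed = rng_seed)
  sensorgram_set(samples, references, zero_sample, zero_reference,
                 ligand_label = "simulated", truth = truth)
}

#' Simulate multinomial AP-MS spectral counts
#'
#' One bait run plus `n_control_runs` control runs. Within a run of
#' `total_spectra` spectra, the count vector is multinomial with
#' per-protein probability proportional to abundance x length (longer
#' proteins yield more spectra at equal abundance, which is exactly what
#' NSAF corrects). Controls draw from `control_abundance` (default: the
#' bait abundances, i.e. a null experiment).
#'
#' @param true_abundance Positive (or zero) abundances, bait run.
#' @param lengths Positive integer protein lengths, amino acids.
#' @param total_spectra Spectra per run (> 0).
#' @param n_control_runs Number of control runs (>= 0).
#' @param control_abundance Abundance vector for control runs.
#' @param protein_ids Optional identifiers (default `P001`, ...).
#' @param rng_seed Integer seed.
#' @return List with `table` (a [spectral_count_table()], runs labeled
#'   `bait`, `control_1`, ...) and `truth`.
#' @export
simulate_spectral_counts <- function(true_abundance, lengths, total_spectra,
                                     n_control_runs = 3L,
                                     control_abundance = true_abundance,
                                     protein_ids = NULL, rng_seed = 1L) {
  stopifnot(length(true_abundance) == length(lengths),
            all(true_abundance >= 0), any(true_abundance > 0),
            all(lengths > 0), total_spectra > 0, n_control_runs >= 0)
  n <- length(true_abundance)
  if (is.null(protein_ids)) protein_ids <- sprintf("P%03d", seq_len(n))
  set.seed(rng_seed)
  draw <- function(abund) {
    as.integer(stats::rmultinom(1L, size = total_spectra,
                                prob = abund * lengths))
  }
  runs <- list(bait = draw(true_abundance))
  for (i in seq_len(n_control_runs)) {
    runs[[paste0("control_", i)]] <- draw(control_abundance)
  }
  rows <- lapply(names(runs), function(lab) {
    data.frame(protein_id = protein_ids, spectral_count = runs[[lab]],
               length_aa = as.integer(lengths), run_label = lab,
               is_control = lab != "bait", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab <- spectral_count_table(df$protein_id, df$spectral_count, df$length_aa,
                              df$run_label, df$is_control)
  list(table = tab,
       truth = list(true_abundance = true_abundance,
                    control_abundance = control_abundance,
                    lengths = lengths, total_spectra = total_spectra,
                    rng_seed = rng_seed))
}
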