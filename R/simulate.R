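#' Simulation configuration for paired tumour/normal expression studies
#'
#' Describes a paired two-tissue microarray-style design: each subject
#' contributes one normal and one tumour sample, a chosen number of features
#' carry a true tumour-vs-normal log2 shift, and optional correlated modules
#' are planted on top of independent background noise. Defaults mirror a
#' small pancreatic-cancer profiling design: 9 subject pairs, 1105 miRNA
#' features, 101 differentially expressed features with absolute log2
#' fold-changes between 0.3 and 3.95.
#'
#' @param n_pairs Number of subjects; each yields one normal and one tumour
#'   sample.
#' @param n_features Number of miRNA features.
#' @param n_de Number of planted differentially expressed features.
#' @param de_log2fc_range Length-2 numeric, range of absolute log2
#'   fold-changes assigned to planted DE features (signs drawn at random).
#' @param modules List of module descriptors, each a list with `size`
#'   (integer >= 2), `rho_target` (target pairwise correlation, strictly in
#'   (0,1)) and `sign_pattern` (one of `"direct"`, `"inverse"`, `"mixed"`).
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param subject_sd Standard deviation of the per-subject (per-feature)
#'   random effect shared by both tissues of a pair; defaults to `noise_sd`.
#' @param baseline_mean_range Range of per-feature baseline log2 intensities.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 9L,
                       n_features = 1105L,
                       n_de = 101L,
                       de_log2fc_range = c(0.3, 3.95),
                       modules = list(),
                       noise_sd = 0.5,
                       subject_sd = noise_sd,
                       baseline_mean_range = c(4, 12),
                       seed = 1L) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1 ||
      n_pairs != round(n_pairs)) {
    stop_cfg("n_pairs must be a positive integer")
  }
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 1 ||
      n_features != round(n_features)) {
    stop_cfg("n_features must be a positive integer")
  }
  if (!is.numeric(n_de) || n_de < 0 || n_de != round(n_de)) {
    stop_cfg("n_de must be a non-negative integer")
  }
  if (n_de > n_features) stop_cfg("n_de exceeds n_features")
  if (length(de_log2fc_range) != 2L || any(de_log2fc_range < 0) ||
      de_log2fc_range[1] > de_log2fc_range[2]) {
    stop_cfg("de_log2fc_range must be an increasing non-negative interval")
  }
  if (!is.list(modules)) stop_cfg("modules must be a list")
  for (m in modules) {
    if (is.null(m$size) || m$size < 2 || m$size != round(m$size)) {
      stop_cfg("module size must be an integer >= 2")
    }
    if (is.null(m$rho_target) || m$rho_target <= 0 || m$rho_target >= 1) {
      stop_cfg("module rho_target must lie strictly inside (0,1)")
    }
    if (is.null(m$sign_pattern)) m$sign_pattern <- "direct"
    if (!m$sign_pattern %in% c("direct", "inverse", "mixed")) {
      stop_cfg("module sign_pattern must be direct, inverse or mixed")
    }
  }
  if (sum(vapply(modules, function(m) as.integer(m$size), 1L)) > n_features) {
    stop_cfg("sum of module sizes exceeds n_features")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop_cfg("noise_sd must be positive")
  if (!is.numeric(subject_sd) || subject_sd < 0) stop_cfg("subject_sd must be non-negative")
  if (length(baseline_mean_range) != 2L ||
      baseline_mean_range[1] > baseline_mean_range[2]) {
    stop_cfg("baseline_mean_range must be an increasing interval")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_cfg("seed must be a single integer")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 n_features = as.integer(n_features),
                 n_de = as.integer(n_de),
                 de_log2fc_range = as.numeric(de_log2fc_range),
                 modules = modules,
                 noise_sd = noise_sd,
                 subject_sd = subject_sd,
                 baseline_mean_range = as.numeric(baseline_mean_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired tumour/normal expression study with known ground truth
#'
#' Generates log2 intensities under an additive model: per-feature baseline +
#' per-feature-per-subject random effect (shared by the two tissues of a
#' pair, inducing the within-pair correlation a paired design exploits) +
#' planted tumour shift for DE features + module latent factor + independent
#' Gaussian noise. Module members load on a single Gaussian latent factor per
#' sample with loading chosen so that pairwise Pearson correlation equals
#' `rho_target`; under Gaussianity Spearman correlation is close to Pearson
#' (6/pi * asin(rho/2)), so observed Spearman approaches `rho_target` from
#' slightly below as `n_pairs` grows. `"inverse"` members take negated
#' loadings; `"mixed"` alternates signs.
#'
#' @param config A [sim_config()] object.
#' @param cohort Cohort label recorded in the sample sheet.
#'
#' @return A list with components `study` (an `expression_study`, see
#'   [read_study()]) and `truth`, a data.frame with one row per feature:
#'   `feature_id`, `true_log2fc` (0 for non-DE features) and `module_id`
#'   (`"background"` or `"M1"`, `"M2"`, ...).
#' @export
simulate_study <- function(config, cohort = "SIM") {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  p <- config$n_features
  n <- config$n_pairs
  ns <- 2L * n
  feat <- sprintf("mir-%04d", seq_len(p))
  subj <- sprintf("S%03d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0(subj, "_N"), paste0(subj, "_T")),
    subject_id = c(subj, subj),
    tissue = rep(c("normal", "tumour"), each = n),
    cohort = cohort,
    stringsAsFactors = FALSE
  )

  baseline <- runif(p, config$baseline_mean_range[1], config$baseline_mean_range[2])

  # planted DE assignment
  true_lfc <- numeric(p)
  de_idx <- integer(0)
  if (config$n_de > 0L) {
    de_idx <- sort(sample.int(p, config$n_de))
    mag <- runif(config$n_de, config$de_log2fc_range[1], config$de_log2fc_range[2])
    sgn <- sample(c(-1, 1), config$n_de, replace = TRUE)
    true_lfc[de_idx] <- mag * sgn
  }

  # module assignment: consecutive blocks over the feature indices not yet used
  module_id <- rep("background", p)
  loadings <- numeric(p)
  sizes <- vapply(config$modules, function(m) as.integer(m$size), 1L)
  pool <- seq_len(p)
  sigma_tot2 <- config$noise_sd^2 + config$subject_sd^2
  mod_members <- list()
  if (length(sizes) > 0L) {
    picked <- sample(pool, sum(sizes))
    offset <- 0L
    for (k in seq_along(config$modules)) {
      m <- config$modules[[k]]
      idx <- picked[(offset + 1L):(offset + sizes[k])]
      offset <- offset + sizes[k]
      module_id[idx] <- paste0("M", k)
      mod_members[[k]] <- idx
      lambda <- sqrt(m$rho_target / (1 - m$rho_target) * sigma_tot2)
      sp <- if (is.null(m$sign_pattern)) "direct" else m$sign_pattern
      s <- switch(sp,
                  direct = rep(1, sizes[k]),
                  inverse = rep(-1, sizes[k]),
                  mixed = rep_len(c(1, -1), sizes[k]))
      loadings[idx] <- lambda * s
    }
  }

  # assemble: features x samples
  subj_eff <- matrix(rnorm(p * n, sd = config$subject_sd), p, n)
  vals <- baseline + cbind(subj_eff, subj_eff)
  vals[, (n + 1L):ns] <- vals[, (n + 1L):ns] + true_lfc
  if (length(mod_members) > 0L) {
    z <- matrix(rnorm(length(mod_members) * ns), length(mod_members), ns)
    for (k in seq_along(mod_members)) {
      idx <- mod_members[[k]]
      vals[idx, ] <- vals[idx, ] + outer(loadings[idx], z[k, ])
    }
  }
  vals <- vals + matrix(rnorm(p * ns, sd = config$noise_sd), p, ns)
  dimnames(vals) <- list(feat, samples$sample_id)

  study <- new_expression_study(features = feat, samples = samples, values = vals)
  truth <- data.frame(feature_id = feat,
                      true_log2fc = true_lfc,
                      module_id = module_id,
                      stringsAsFactors = FALSE)
  list(study = study, truth = truth)
}

#' Write a simulated study and its ground truth as TSV fixtures
#'
#' Emits `matrix.tsv` (features x samples, first column `feature_id`),
#' `samples.tsv` (sample sheet) and `truth.tsv` (per-feature true log2
#' fold-change and module id) into `directory`; the first two round-trip
#' through [read_study()].
#'
#' @param study An `expression_study`.
#' @param truth Ground-truth data.frame as returned by [simulate_study()].
#' @param directory Output directory, created if absent.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_fixture <- function(study, truth, directory) {
  stopifnot(inherits(study, "expression_study"))
  if (length(study$features) == 0L) {
    stop("refusing to write a fixture with an empty feature set", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory, call. = FALSE)
    }
  }
  paths <- c(matrix = file.path(directory, "matrix.tsv"),
             samples = file.path(directory, "samples.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_study(study, paths[["matrix"]], paths[["samples"]])
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
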