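## Readers/validators for expression matrices, sample sheets, alias tables,
## miRNA->target maps and GMT gene sets. Expression values are assumed
## already log2-transformed and normalized; nothing here rescales data.

new_expression_study <- function(features, samples, values) {
  structure(list(features = features, samples = samples, values = values),
            class = "expression_study")
}

validate_study <- function(features, samples, values, drop_na = TRUE) {
  dup <- features[duplicated(features)]
  if (length(dup) > 0L) {
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(samples$tissue), c("normal", "tumour"))
  if (length(bad) > 0L) {
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (drop_na && anyNA(values)) {
    bad_rows <- rowSums(is.na(values)) > 0
    warning(sum(bad_rows), " feature(s) with missing values dropped: ",
            paste(utils::head(features[bad_rows], 5), collapse = ", "),
            if (sum(bad_rows) > 5) ", ..." else "", call. = FALSE)
    values <- values[!bad_rows, , drop = FALSE]
    features <- features[!bad_rows]
  }
  new_expression_study(features, samples, values)
}

#' Read a paired expression study from a TSV matrix and sample sheet
#'
#' The matrix file holds one row per miRNA (first column = feature id, header
#' = sample ids, cells = log2 intensities). The sample sheet has columns
#' `sample_id`, `subject_id`, `tissue` (`normal`/`tumour`) and `cohort`.
#' Only samples present in both files are kept; duplicate ids, non-numeric
#' cells and unknown tissue labels are errors, features containing missing
#' values are dropped with a warning.
#'
#' @param matrix_path,samples_path Paths to the two TSV files.
#' @param require_pairs If `TRUE` (default), every subject must contribute
#'   exactly one normal and one tumour sample.
#' @return An object of class `expression_study`: list with `features`
#'   (character), `samples` (data.frame) and `values` (numeric matrix,
#'   features x samples).
#' @export
read_study <- function(matrix_path, samples_path, require_pairs = TRUE) {
  for (pth in c(matrix_path, samples_path)) {
    if (!file.exists(pth)) stop("file not found: ", pth, call. = FALSE)
  }
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file has no sample columns: ", matrix_path,
                           call. = FALSE)
  features <- as.character(raw[[1L]])
  numcols <- raw[-1L]
  for (j in seq_along(numcols)) {
    v <- numcols[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(w <- as.numeric(v))
      bad <- which(is.na(w) & !is.na(v) & v != "" & toupper(v) != "NA")
      if (length(bad) > 0L) {
        stop("non-numeric cell in column '", names(numcols)[j], "', row ",
             bad[1L], " (feature ", features[bad[1L]], ")", call. = FALSE)
      }
      numcols[[j]] <- w
    }
  }
  values <- as.matrix(numcols)
  rownames(values) <- features

  samples <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "tissue", "cohort")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L) {
    stop("sample sheet misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[need]

  common <- intersect(colnames(values), samples$sample_id)
  if (length(common) == 0L) {
    stop("no sample ids shared between matrix and sample sheet", call. = FALSE)
  }
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  values <- values[, common, drop = FALSE]

  if (require_pairs) {
    tab <- table(samples$subject_id, samples$tissue)
    ok <- nrow(tab) > 0 && all(tab == 1L) && all(c("normal", "tumour") %in% colnames(tab))
    if (!ok) {
      bad <- rownames(tab)[rowSums(tab != 1L) > 0]
      stop("unpaired subject(s) in sample sheet: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  validate_study(features, samples, values)
}

#' Write an expression study as TSV files readable by [read_study()]
#'
#' @param study An `expression_study`.
#' @param matrix_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_study <- function(study, matrix_path, samples_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(feature_id = study$features, study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$features), "features x",
      nrow(x$samples), "samples\n")
  cat("  cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  cat("  tissues:", paste(sprintf("%s (%d)", names(table(x$samples$tissue)),
                                  table(x$samples$tissue)), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a study to a subset of samples and/or features
#'
#' @param study An `expression_study`.
#' @param tissue Optional tissue filter (`"normal"` or `"tumour"`).
#' @param cohort Optional cohort filter.
#' @param features Optional feature-id subset (order preserved).
#' @return The restricted `expression_study`.
#' @export
subset_study <- function(study, tissue = NULL, cohort = NULL, features = NULL) {
  stopifnot(inherits(study, "expression_study"))
  keep <- rep(TRUE, nrow(study$samples))
  if (!is.null(tissue)) keep <- keep & study$samples$tissue %in% tissue
  if (!is.null(cohort)) keep <- keep & study$samples$cohort %in% cohort
  samples <- study$samples[keep, , drop = FALSE]
  rownames(samples) <- NULL
  values <- study$values[, keep, drop = FALSE]
  feats <- study$features
  if (!is.null(features)) {
    miss <- setdiff(features, feats)
    if (length(miss) > 0L) {
      stop("unknown feature id(s): ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    feats <- features
    values <- values[features, , drop = FALSE]
  }
  new_expression_study(feats, samples, values)
}

#' Read a miRNA alias table (legacy symbol -> current symbol, accession)
#'
#' TSV with columns `legacy`, `current` and optionally `accession`. The
#' mapping must be functional: one current symbol per legacy symbol.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `alias_table`.
#' @export
read_alias_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("legacy", "current") %in% names(tab))) {
    stop("alias table needs columns 'legacy' and 'current'", call. = FALSE)
  }
  dup <- unique(tab$legacy[duplicated(tab$legacy)])
  if (length(dup) > 0L) {
    stop("alias table maps legacy symbol(s) more than once: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$accession)) tab$accession <- NA_character_
  class(tab) <- c("alias_table", "data.frame")
  tab
}

#' Rename study features using an alias table
#'
#' Feature ids present in the table's `legacy` column are replaced by the
#' `current` symbol; unmapped ids pass through. When two legacy ids collapse
#' onto the same current symbol, the feature with the higher mean intensity
#' survives and the collision is reported as a warning.
#'
#' @param study An `expression_study`.
#' @param aliases An `alias_table` (or data.frame with `legacy`/`current`).
#' @return The renamed `expression_study`.
#' @export
apply_aliases <- function(study, aliases) {
  stopifnot(inherits(study, "expression_study"))
  if (nrow(aliases) == 0L) return(study)
  idx <- match(study$features, aliases$legacy)
  newnames <- ifelse(is.na(idx), study$features, aliases$current[idx])
  if (anyDuplicated(newnames)) {
    means <- rowMeans(study$values)
    keep <- rep(TRUE, length(newnames))
    for (nm in unique(newnames[duplicated(newnames)])) {
      at <- which(newnames == nm)
      winner <- at[which.max(means[at])]
      keep[setdiff(at, winner)] <- FALSE
      warning("alias collision on '", nm, "': kept feature with highest mean intensity (",
              study$features[winner], ")", call. = FALSE)
    }
    study$values <- study$values[keep, , drop = FALSE]
    newnames <- newnames[keep]
  }
  study$features <- newnames
  rownames(study$values) <- newnames
  study
}

#' Read a miRNA -> validated target gene map
#'
#' Two-column TSV (`mirna_id`, `gene_symbol`), one pair per line; gene
#' symbols are upper-cased on load so joins against GMT sets are
#' case-insensitive.
#'
#' @param path Path to the TSV file.
#' @return Named list of class `target_map`: miRNA id -> character vector of
#'   target gene symbols.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed target-map line ", which(nf < 2L)[1L], ": expected 'mirna<TAB>gene'",
         call. = FALSE)
  }
  mir <- vapply(parts, `[[`, "", 1L)
  gene <- toupper(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(gene))) {
    stop("empty gene symbol on target-map line ", which(!nzchar(gene))[1L],
         call. = FALSE)
  }
  out <- lapply(split(gene, mir), function(g) sort(unique(g)))
  class(out) <- "target_map"
  out
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set name, description, then member gene
#' symbols. Members are upper-cased; empty sets are errors. The gene
#' universe defaults to the union of all members unless `universe` is given.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector overriding the gene universe.
#' @return A list of class `gene_set_collection` with elements `sets` (named
#'   list of member vectors), `descriptions` and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L || !any(nzchar(p[-(1:2)]))) {
      stop("malformed GMT line ", lineno[i],
           ": expected name, description and at least one gene", call. = FALSE)
    }
    genes <- toupper(p[-(1:2)])
    genes <- sort(unique(genes[nzchar(genes)]))
    if (p[1] %in% names(sets)) {
      stop("duplicate gene-set name '", p[1], "' at GMT line ", lineno[i],
           call. = FALSE)
    }
    sets[[p[1]]] <- genes
    desc[p[1]] <- p[2]
  }
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- sort(unique(toupper(universe)))
    stray <- setdiff(all_genes, universe)
    if (length(stray) > 0L) {
      stop("gene set member(s) outside the declared universe: ",
           paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sets = sets, descriptions = desc, universe = universe),
            class = "gene_set_collection")
}
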