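## Target-gene mapping and hypergeometric over-representation with
## Bonferroni control -- a local, file-driven counterpart of web enrichment
## services, so results are reproducible from packaged GMT files.

#' Validated target genes of a miRNA set
#'
#' @param mirnas Character vector of miRNA ids.
#' @param target_map A `target_map` from [read_target_map()].
#' @param mode `"union"` pools target genes across the miRNAs; `"per_mirna"`
#'   keeps the miRNA -> genes attribution.
#' @return `"union"`: sorted character vector of gene symbols. `"per_mirna"`:
#'   named list (one element per mapped miRNA). miRNAs absent from the map
#'   are skipped with a message.
#' @export
targets_of <- function(mirnas, target_map, mode = c("union", "per_mirna")) {
  mode <- match.arg(mode)
  mirnas <- unique(as.character(mirnas))
  found <- mirnas[mirnas %in% names(target_map)]
  missing <- setdiff(mirnas, found)
  if (length(missing) > 0L) {
    message(length(missing), " miRNA(s) absent from target map, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  per <- unclass(target_map)[found]
  if (mode == "per_mirna") return(per)
  out <- unlist(per, use.names = FALSE)
  if (is.null(out)) character(0) else sort(unique(out))
}

#' Hypergeometric gene-set over-representation with Bonferroni control
#'
#' For each gene set, the overlap with the query is tested against the
#' hypergeometric upper tail (probability of at least the observed overlap
#' when `query_size` genes are drawn without replacement from the
#' universe). The Bonferroni-corrected p is `min(1, p * n_sets)`; results
#' are sorted by raw p and flagged significant at Bonferroni p <= 0.05.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query_genes Character vector of gene symbols (case-insensitive).
#' @param sets A `gene_set_collection` from [read_gmt()].
#' @param alpha Bonferroni significance level for the `significant` flag.
#' @return Data.frame of class `enrichment_result`: `set_name`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `p_bonferroni`,
#'   `significant`, `overlapping_genes` (comma-joined).
#' @export
enrich <- function(query_genes, sets, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(toupper(as.character(query_genes)))
  if (length(query) == 0L) stop("empty query gene set", call. = FALSE)
  universe <- sets$universe
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("no query genes left inside the universe",
                                call. = FALSE)
  U <- length(universe)
  q <- length(query)
  nsets <- length(sets$sets)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- sets$sets[[nm]]
    ov <- intersect(query, s)
    k <- length(ov)
    p <- stats::phyper(k - 1L, length(s), U - length(s), q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = q, universe_size = U, p_value = p,
               p_bonferroni = min(1, p * nsets),
               overlapping_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni <= alpha
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param result Data.frame from [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
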