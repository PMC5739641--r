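## End-to-end orchestration: per cohort, paired DE -> per-tissue networks
## over the deregulated miRNA set -> topology -> a DE-restricted network on
## the configured stratum -> MCODE -> normal/tumour comparison and motif
## census -> optional target-gene enrichment; all outputs as TSV/GraphML
## with a JSON run manifest.

# FNV-1a over UTF-8 bytes, kept inside exact double arithmetic: the 32-bit
# product is split so no intermediate exceeds 2^53, and the xor touches only
# the low byte (the multiplier is odd, so this stays a faithful FNV-1a)
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * prime) %% 4294967296) * 65536 + lo * prime) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Pipeline run configuration
#'
#' Exactly one of `matrix_path`+`samples_path` (real data) or `synthetic`
#' (a [sim_config()]) must be supplied.
#'
#' @param matrix_path,samples_path Expression matrix and sample sheet TSVs.
#' @param aliases_path Optional alias table applied after reading.
#' @param target_map_path,gmt_path Optional target map and GMT collection;
#'   when both are given, cluster-1 members are enriched.
#' @param synthetic Optional [sim_config()] replacing the real inputs.
#' @param alpha_de DE selection threshold.
#' @param alpha_corr Correlation edge threshold.
#' @param mcode [mcode_params()].
#' @param correlation_stratum Tissue whose samples feed the DE-restricted
#'   correlation network (`"tumour"` by default; the choice is exposed
#'   because either stratum is defensible).
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(matrix_path = NULL, samples_path = NULL,
                       aliases_path = NULL, target_map_path = NULL,
                       gmt_path = NULL, synthetic = NULL,
                       alpha_de = 0.05, alpha_corr = 0.05,
                       mcode = mcode_params(),
                       correlation_stratum = c("tumour", "normal"),
                       out_dir = tempfile("mirnet_run_")) {
  real <- !is.null(matrix_path) || !is.null(samples_path)
  if (real && is.null(synthetic)) {
    if (is.null(matrix_path) || is.null(samples_path)) {
      stop("real input needs both matrix_path and samples_path", call. = FALSE)
    }
  } else if (!real && !is.null(synthetic)) {
    if (!inherits(synthetic, "sim_config")) synthetic <- do.call(sim_config, synthetic)
  } else {
    stop("supply exactly one of {matrix_path+samples_path, synthetic}",
         call. = FALSE)
  }
  stopifnot(alpha_de > 0, alpha_de < 1, alpha_corr > 0, alpha_corr < 1)
  structure(list(matrix_path = matrix_path, samples_path = samples_path,
                 aliases_path = aliases_path,
                 target_map_path = target_map_path, gmt_path = gmt_path,
                 synthetic = synthetic, alpha_de = alpha_de,
                 alpha_corr = alpha_corr, mcode = mcode,
                 correlation_stratum = match.arg(correlation_stratum),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full co-expression network pipeline
#'
#' Stage outputs (stable filenames under `config$out_dir`): per cohort
#' `de_<cohort>.tsv`, per tissue `network_<cohort>_<tissue>.tsv` and
#' `.graphml` with `topology_global_...`/`topology_nodes_...` reports, the
#' DE-restricted `network_<cohort>_de.tsv` with `clusters_<cohort>.tsv`,
#' `comparison_<cohort>.tsv` and `census_<cohort>.tsv`, optional
#' `enrichment_<cohort>.tsv`, and `manifest.json` recording the
#' configuration, its hash and package/R versions. Rerunning the same
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[mirnet] ", ...)
  stage <- "input"
  res <- list()
  outputs <- character(0)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(path) outputs <<- c(outputs, basename(path))

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      sim <- simulate_study(config$synthetic)
      res$truth <- sim$truth
      utils::write.table(sim$truth, file.path(config$out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("truth.tsv")
      sim$study
    } else {
      s <- read_study(config$matrix_path, config$samples_path)
      if (!is.null(config$aliases_path)) {
        s <- apply_aliases(s, read_alias_table(config$aliases_path))
      }
      s
    }
  })
  res$study <- study
  say("study: ", length(study$features), " features, ", nrow(study$samples),
      " samples")

  tmap <- gmt <- NULL
  if (!is.null(config$target_map_path) && !is.null(config$gmt_path)) {
    run_stage("annotation", {
      tmap <- read_target_map(config$target_map_path)
      gmt <- read_gmt(config$gmt_path)
    })
  }

  cohorts <- unique(study$samples$cohort)
  res$cohorts <- list()
  for (co in cohorts) {
    say("cohort ", co)
    cres <- list()
    de <- run_stage("differential_expression", paired_ttest(study, cohort = co))
    write_diffexpr(de, file.path(config$out_dir, paste0("de_", co, ".tsv")))
    emit(paste0("de_", co, ".tsv"))
    desel <- select_deregulated(de, alpha = config$alpha_de)
    cres$de <- de; cres$selected <- desel
    say("  ", length(desel), " deregulated miRNAs at alpha ", config$alpha_de)

    if (length(desel) >= 2L) {
      for (tis in c("normal", "tumour")) {
        net <- run_stage("correlation_network", {
          corr <- spearman_matrix(study, features = desel, tissue = tis,
                                  cohort = co)
          build_network(corr, alpha = config$alpha_corr)
        })
        base <- paste0("network_", co, "_", tis)
        write_edge_list(net, file.path(config$out_dir, paste0(base, ".tsv")))
        write_graphml(net, file.path(config$out_dir, paste0(base, ".graphml")))
        emit(paste0(base, ".tsv")); emit(paste0(base, ".graphml"))
        run_stage("network_topology", {
          gt <- global_topology(net)
          nt <- node_topology(net)
          write_topology(gt, nt,
                         file.path(config$out_dir, paste0("topology_global_", co, "_", tis, ".tsv")),
                         file.path(config$out_dir, paste0("topology_nodes_", co, "_", tis, ".tsv")))
          emit(paste0("topology_global_", co, "_", tis, ".tsv"))
          emit(paste0("topology_nodes_", co, "_", tis, ".tsv"))
          cres[[tis]] <- list(network = net, global = gt, nodes = nt,
                               ranking = rank_nodes(nt))
        })
      }

      run_stage("mcode", {
        corr <- spearman_matrix(study, features = desel,
                                tissue = config$correlation_stratum,
                                cohort = co)
        denet <- build_network(corr, alpha = config$alpha_corr)
        cl <- mcode_clusters(denet, config$mcode)
        cl <- mcode_significance(cl, denet)
        write_clusters(cl, file.path(config$out_dir, paste0("clusters_", co, ".tsv")))
        emit(paste0("clusters_", co, ".tsv"))
        cres$de_network <- denet
        cres$clusters <- cl
        say("  MCODE: ", length(cl), " cluster(s)")
      })

      run_stage("network_comparison", {
        cmp <- compare_networks(cres$normal$network, cres$tumour$network)
        cen <- motif_census(cres$de_network)
        df <- data.frame(metric = c("shared_nodes", "nodes_only_normal",
                                    "nodes_only_tumour", "shared_edges",
                                    "nodes_no_shared_links",
                                    "nodes_all_links_shared"),
                         value = c(length(cmp$shared_nodes),
                                   length(cmp$nodes_only_a),
                                   length(cmp$nodes_only_b),
                                   cmp$n_shared_edges,
                                   length(cmp$nodes_with_no_shared_links),
                                   length(cmp$nodes_with_all_links_shared)))
        utils::write.table(df, file.path(config$out_dir, paste0("comparison_", co, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_census(cen, file.path(config$out_dir, paste0("census_", co, ".tsv")))
        emit(paste0("comparison_", co, ".tsv")); emit(paste0("census_", co, ".tsv"))
        cres$comparison <- cmp; cres$census <- cen
      })

      if (!is.null(tmap) && length(cres$clusters) > 0L) {
        run_stage("target_enrichment", {
          genes <- targets_of(cres$clusters[[1L]]$members, tmap)
          if (length(genes) > 0L) {
            er <- suppressWarnings(enrich(genes, gmt))
            write_enrichment(er, file.path(config$out_dir, paste0("enrichment_", co, ".tsv")))
            emit(paste0("enrichment_", co, ".tsv"))
            cres$enrichment <- er
          }
        })
      }
    } else {
      say("  fewer than 2 deregulated miRNAs; network stages skipped")
    }
    res$cohorts[[co]] <- cres
  }

  if (length(cohorts) == 2L) {
    run_stage("cross_cohort_contrast", {
      sa <- subset_study(study, cohort = cohorts[1L])
      sb <- subset_study(study, cohort = cohorts[2L])
      cc <- cross_cohort_contrast(sa, sb)
      write_diffexpr(cc, file.path(config$out_dir, "de_cross_cohort.tsv"))
      emit("de_cross_cohort.tsv")
      res$cross_cohort <- cc
    })
  }

  cfg_txt <- paste(deparse(unclass(config)), collapse = "\n")
  manifest <- list(config_hash = fnv1a(cfg_txt),
                   alpha_de = config$alpha_de,
                   alpha_corr = config$alpha_corr,
                   correlation_stratum = config$correlation_stratum,
                   seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
                   package_version = as.character(utils::packageVersion("mirnet")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   outputs = sort(unique(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  say("done: ", length(manifest$outputs), " output file(s) in ", config$out_dir)
  invisible(res)
}
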