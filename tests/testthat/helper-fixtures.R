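# Small in-code fixtures shared across test files.

# network from a compact edge spec: "a-b", optionally with rho
make_net <- function(nodes, edge_spec, rho = NULL) {
  if (length(edge_spec) == 0L) return(coexp_network(nodes))
  parts <- do.call(rbind, strsplit(edge_spec, "-", fixed = TRUE))
  if (is.null(rho)) rho <- rep(1, nrow(parts))
  coexp_network(nodes, data.frame(a = parts[, 1L], b = parts[, 2L],
                                  rho = rho, p = 0.01))
}

clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "-")
}

path_edges <- function(ids) {
  paste(ids[-length(ids)], ids[-1L], sep = "-")
}

# tiny paired study from a features x samples matrix of log2 values
make_study <- function(values, cohort = "A") {
  n <- ncol(values) / 2L
  subj <- sprintf("P%02d", seq_len(n))
  samples <- data.frame(
    sample_id = c(paste0(subj, "_N"), paste0(subj, "_T")),
    subject_id = c(subj, subj),
    tissue = rep(c("normal", "tumour"), each = n),
    cohort = cohort, stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("mir-%03d", seq_len(nrow(values)))
  }
  mirnet:::new_expression_study(rownames(values), samples, values)
}

# the 17-node fixture mirroring the small normal-tissue network: an
# induced path of 7, two triangles and two disconnected pairs
pvac_style_fixture <- function() {
  chain <- sprintf("c%d", 1:7)
  t1 <- sprintf("t%d", 1:3); t2 <- sprintf("u%d", 1:3)
  p1 <- c("p1", "p2"); p2 <- c("q1", "q2")
  # alternate signs along the chain so sign-sequence logic is exercised
  make_net(c(chain, t1, t2, p1, p2),
           c(path_edges(chain), clique_edges(t1), clique_edges(t2),
             "p1-p2", "q1-q2"),
           rho = c(rep(c(-0.9, 0.8), length.out = 6),
                   rep(0.7, 6), 0.6, -0.5))
}
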