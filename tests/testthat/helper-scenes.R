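# Shared fixture builders: tiny cell tables and hand-made cluster objects.

toy_cells <- function(x, y, class = "excitatory", subclass = NULL,
                      section_id = "S1", layer = 1L, region = "R1",
                      cell_id = NULL) {
  n <- length(x)
  if (is.null(subclass)) {
    subclass <- ifelse(rep(class, length.out = n) == "excitatory", "L2", "PV_CHC")
  }
  if (is.null(cell_id)) cell_id <- sprintf("c%03d", seq_len(n))
  cell_table(data.frame(
    cell_id = cell_id, x = x, y = y,
    section_id = rep(section_id, length.out = n),
    layer = rep(layer, length.out = n),
    region = rep(region, length.out = n),
    class = rep(class, length.out = n),
    subclass = rep(subclass, length.out = n),
    stringsAsFactors = FALSE))
}

# Build a neuron_clusters object directly from membership sets, bypassing
# detection, for metric-level tests.
mk_clusters <- function(cells, spec) {
  membership <- do.call(rbind, lapply(names(spec), function(id) {
    data.frame(cluster_id = id, cell_id = spec[[id]]$ids,
               stringsAsFactors = FALSE)
  }))
  types <- vapply(spec, `[[`, "", "type")
  neuron_clusters(membership, types, cells)
}

# Window-stats object with prescribed member sets and significance, for
# merge-rule tests without running the scanner.
mk_window_stats <- function(cells, member_sets, sig_type = "inhibitory",
                            sig = rep(TRUE, length(member_sets))) {
  df <- as.data.frame(cells)
  n <- nrow(df)
  ii <- rep(seq_along(member_sets), lengths(member_sets))
  jj <- match(unlist(member_sets), df$cell_id)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(member_sets), n))
  p_sig <- ifelse(sig, 0.001, 1)
  stats <- data.frame(window_id = seq_along(member_sets),
                      x0 = 0, y0 = 0,
                      n_total = lengths(member_sets),
                      n_exc = 0L, n_inh = 0L,
                      p_exc = if (sig_type == "excitatory") p_sig else 1,
                      p_inh = if (sig_type == "inhibitory") p_sig else 1,
                      sig_exc = sig_type == "excitatory" & sig,
                      sig_inh = sig_type == "inhibitory" & sig)
  structure(stats, incidence = M, stratum_cells = df, alpha = 0.05,
            n_perm = 1L, min_window_n = 1L, window_size = 100,
            class = c("window_stats", "data.frame"))
}
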