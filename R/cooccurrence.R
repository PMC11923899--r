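# Subclass-level enrichment within clusters and multi-subclass co-occurrence.
#
# The null shuffles subclass labels among all neurons of a stratum
# (excitatory and inhibitory alike) while cluster memberships stay fixed, so
# for one cluster and one subclass the null count is hypergeometric. Joint
# draws across clusters and subclasses are sampled either by explicit label
# permutation or - when the clusters are pairwise disjoint - by the exactly
# equivalent nested multivariate hypergeometric decomposition, which is much
# faster and is what the label permutation induces on disjoint blocks.

# Joint null counts for all (subclass, cluster) pairs: array (q, ncl, B).
draw_cluster_counts <- function(code, q, member_blocks, n, B) {
  ncl <- length(member_blocks)
  counts <- array(0L, dim = c(q, ncl, B))
  union_idx <- sort(unique(unlist(member_blocks)))
  disjoint <- length(union_idx) == sum(lengths(member_blocks))
  if (disjoint) {
    pool <- tabulate(code, q)
    rem <- matrix(pool, q, B)
    for (j in seq_len(ncl)) {
      r <- rep.int(length(member_blocks[[j]]), B)
      for (s in seq_len(q - 1L)) {
        tot <- colSums(rem[s:q, , drop = FALSE])
        k <- as.integer(rhyper(B, rem[s, ], tot - rem[s, ], r))
        counts[s, j, ] <- k
        r <- r - k
        rem[s, ] <- rem[s, ] - k
      }
      counts[q, j, ] <- r
      rem[q, ] <- rem[q, ] - r
    }
  } else {
    m_u <- length(union_idx)
    rows_of <- lapply(member_blocks, function(b) match(b, union_idx))
    S <- vapply(seq_len(B), function(b) sample.int(n, m_u), integer(m_u))
    labs <- matrix(code[S], m_u, B)
    for (j in seq_len(ncl)) {
      sub <- labs[rows_of[[j]], , drop = FALSE]
      idx <- sub + q * rep(0:(B - 1L), each = nrow(sub))
      counts[, j, ] <- matrix(tabulate(idx, q * B), q, B)
    }
  }
  counts
}

stratum_groups <- function(clusters, cells, stratum) {
  df <- as.data.frame(cells)
  cl <- clusters$clusters
  if (stratum == "section_layer") {
    ckey <- paste(cl$section_id, cl$layer, sep = "\r")
    dkey <- paste(df$section_id, df$layer, sep = "\r")
  } else {
    ckey <- as.character(cl$layer)
    dkey <- as.character(df$layer)
  }
  keys <- sort(unique(ckey))
  lapply(keys, function(k) {
    list(key = k,
         clusters = cl$cluster_id[ckey == k],
         cells = df[dkey == k, , drop = FALSE])
  })
}

subclass_codes <- function(cells_df, vocab) {
  labels <- c(vocab$excitatory, vocab$inhibitory)
  labels <- unique(labels)
  code <- match(cells_df$subclass, labels)
  if (anyNA(code)) {
    labels <- c(labels, sort(unique(cells_df$subclass[is.na(code)])))
    code <- match(cells_df$subclass, labels)
  }
  list(code = code, labels = labels)
}

#' Subclass enrichment within each cluster
#'
#' For every cluster and every subclass in the vocabulary, the one-sided
#' permutation p-value that the cluster holds at least the observed number
#' of cells of that subclass, under shuffling of subclass labels among all
#' neurons of the cluster's stratum (memberships fixed). Uses the add-one
#' estimator, so p-values lie in (0, 1]. Subclasses absent from a stratum
#' get p = 1.
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the matching [cell_table()].
#' @param n_perm number of label shuffles (>= 1).
#' @param seed integer seed.
#' @param alpha significance level for the `enriched` flag.
#' @param stratum `"section_layer"` (default) or `"layer"` shuffling pool.
#' @return data.frame `cluster_id`, `subclass`, `subclass_class`, `observed`,
#'   `p`, `enriched`.
#' @export
subclass_enrichment <- function(clusters, cells, n_perm = 10000, seed = 1L,
                                alpha = 0.05,
                                stratum = c("section_layer", "layer")) {
  stratum <- match.arg(stratum)
  if (n_perm < 1) stop("n_perm must be >= 1")
  vocab <- subclass_vocab(cells)
  member_of <- split(clusters$membership$cell_id, clusters$membership$cluster_id)
  groups <- stratum_groups(clusters, cells, stratum)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (length(g$clusters) == 0L) next
    sc <- subclass_codes(g$cells, vocab)
    q <- length(sc$labels)
    n <- nrow(g$cells)
    blocks <- lapply(g$clusters, function(id) {
      idx <- match(member_of[[id]], g$cells$cell_id)
      if (anyNA(idx)) stop("cluster ", id, " has members outside its stratum")
      idx
    })
    obs <- vapply(blocks, function(b) tabulate(sc$code[b], q), integer(q))
    obs <- matrix(obs, nrow = q) # q x ncl
    draws <- with_seed(derive_seed(seed, gi),
                       draw_cluster_counts(sc$code, q, blocks, n, n_perm))
    exceed <- rowSums(draws >= as.vector(obs), dims = 2L)
    p <- (1 + exceed) / (1 + n_perm)
    cls_of <- ifelse(sc$labels %in% vocab$excitatory, "excitatory",
                     ifelse(sc$labels %in% vocab$inhibitory, "inhibitory",
                            "unknown"))
    out[[length(out) + 1L]] <- data.frame(
      cluster_id = rep(g$clusters, each = q),
      subclass = rep(sc$labels, times = length(g$clusters)),
      subclass_class = rep(cls_of, times = length(g$clusters)),
      observed = as.vector(obs), p = as.vector(p),
      enriched = as.vector(p) < alpha, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(cluster_id = character(0), subclass = character(0),
                      subclass_class = character(0), observed = integer(0),
                      p = numeric(0), enriched = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cluster_id, res$subclass), ]
  rownames(res) <- NULL
  res
}

#' Classify subclass combinations within clusters
#'
#' Labels each cluster by the class make-up of its significantly enriched
#' subclasses: `EE` (all excitatory), `II` (all inhibitory), `EI` (mixed)
#' for clusters with two or more enriched subclasses; `single` for exactly
#' one; `none` otherwise. Reports, per cluster type, the fraction of
#' clusters with at least two enriched subclasses and the combination
#' percentages among those.
#'
#' @param enrichment data.frame from [subclass_enrichment()].
#' @param clusters the `neuron_clusters` the enrichment was computed for.
#' @return List with `per_cluster` (data.frame `cluster_id`, `type`,
#'   `n_enriched`, `combination`, `enriched_subclasses`) and `summary`
#'   (data.frame per cluster type: `n_clusters`, `n_multi`, `frac_multi`,
#'   `pct_EE`, `pct_EI`, `pct_II` among multi-enriched clusters).
#' @export
classify_combinations <- function(enrichment, clusters) {
  cl <- clusters$clusters
  per <- do.call(rbind, lapply(cl$cluster_id, function(id) {
    e <- enrichment[enrichment$cluster_id == id & enrichment$enriched, ]
    ne <- nrow(e)
    combo <- if (ne == 0L) "none" else if (ne == 1L) "single" else {
      cls <- unique(e$subclass_class)
      if (identical(cls, "excitatory")) "EE"
      else if (identical(cls, "inhibitory")) "II"
      else "EI"
    }
    data.frame(cluster_id = id, type = cl$type[cl$cluster_id == id],
               n_enriched = ne, combination = combo,
               enriched_subclasses = paste(sort(e$subclass), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(unique(cl$type), function(tp) {
    sub <- per[per$type == tp, ]
    multi <- sub[sub$n_enriched >= 2L, ]
    pct <- function(cmb) if (nrow(multi) == 0L) NA_real_ else
      100 * mean(multi$combination == cmb)
    data.frame(type = tp, n_clusters = nrow(sub), n_multi = nrow(multi),
               frac_multi = if (nrow(sub) > 0) nrow(multi) / nrow(sub) else NA_real_,
               pct_EE = pct("EE"), pct_EI = pct("EI"), pct_II = pct("II"),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_cluster = per, summary = summary)
}

#' Meta-permutation test for excess subclass co-occurrence
#'
#' Asks whether the fraction of clusters enriched for two or more subclasses
#' exceeds what label shuffling alone produces. Each replicate shuffles the
#' subclass labels globally within each stratum, reruns the per-cluster
#' enrichment test (with `n_perm` fresh inner shuffles), and records the
#' multi-enriched fraction per cluster type; the empirical p-value is
#' `(1 + #\{replicate fraction >= observed\}) / (1 + n_rep)`.
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the matching [cell_table()].
#' @param n_perm inner shuffles per enrichment test (the replicate loop
#'   typically uses fewer than a headline analysis; 1000 by default).
#' @param n_rep number of meta-replicates (>= 1).
#' @param seed integer seed.
#' @param alpha significance level for the enriched flags.
#' @param stratum shuffling pool, as in [subclass_enrichment()].
#' @return List with `observed` (per-type multi-enriched fraction),
#'   `replicates` (n_rep x type matrix of null fractions) and `p` (per-type
#'   empirical p-value).
#' @export
meta_permutation <- function(clusters, cells, n_perm = 1000, n_rep = 500,
                             seed = 1L, alpha = 0.05,
                             stratum = c("section_layer", "layer")) {
  stratum <- match.arg(stratum)
  if (n_rep < 1) stop("n_rep must be >= 1")
  cl <- clusters$clusters
  types <- c("excitatory", "inhibitory")
  obs_enr <- subclass_enrichment(clusters, cells, n_perm = n_perm,
                                 seed = derive_seed(seed, 0L), alpha = alpha,
                                 stratum = stratum)
  n_enr_obs <- tapply(obs_enr$enriched, obs_enr$cluster_id, sum)
  multi_obs <- names(n_enr_obs)[n_enr_obs >= 2L]
  type_of <- setNames(cl$type, cl$cluster_id)
  obs_frac <- vapply(types, function(tp) {
    ids <- cl$cluster_id[cl$type == tp]
    if (length(ids) == 0L) NA_real_ else mean(ids %in% multi_obs)
  }, numeric(1))

  vocab <- subclass_vocab(cells)
  member_of <- split(clusters$membership$cell_id, clusters$membership$cluster_id)
  groups <- stratum_groups(clusters, cells, stratum)
  # multi[r, id]: does cluster id have >= 2 enriched subclasses in replicate r
  n_multi_rep <- matrix(0L, n_rep, length(types),
                        dimnames = list(NULL, types))
  denom <- vapply(types, function(tp) sum(cl$type == tp), numeric(1))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (length(g$clusters) == 0L) next
    sc <- subclass_codes(g$cells, vocab)
    q <- length(sc$labels)
    n <- nrow(g$cells)
    blocks <- lapply(g$clusters, function(id) match(member_of[[id]], g$cells$cell_id))
    ncl <- length(blocks)
    per_rep <- 1L + n_perm # one shuffled "observation" plus its inner bank
    block_reps <- max(1L, as.integer(1e7 / (q * ncl * per_rep)))
    with_seed(derive_seed(seed, gi), {
      r <- 0L
      while (r < n_rep) {
        nb <- min(block_reps, n_rep - r)
        d <- draw_cluster_counts(sc$code, q, blocks, n, nb * per_rep)
        for (b in seq_len(nb)) {
          off <- (b - 1L) * per_rep
          obs_r <- matrix(d[, , off + 1L], q, ncl)
          null_r <- d[, , off + seq(2L, per_rep), drop = FALSE]
          exceed <- rowSums(null_r >= as.vector(obs_r), dims = 2L)
          p_r <- (1 + exceed) / (1 + n_perm)
          n_enr <- colSums(p_r < alpha)
          for (tp in types) {
            sel <- type_of[g$clusters] == tp
            n_multi_rep[r + b, tp] <- n_multi_rep[r + b, tp] +
              sum(n_enr[sel] >= 2L)
          }
        }
        r <- r + nb
      }
    })
  }
  rep_frac <- sweep(n_multi_rep, 2L, pmax(denom, 1), "/")
  p <- vapply(types, function(tp) {
    if (denom[tp] == 0L) return(NA_real_)
    (1 + sum(rep_frac[, tp] >= obs_frac[tp])) / (1 + n_rep)
  }, numeric(1))
  list(observed = obs_frac, replicates = rep_frac, p = p)
}
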