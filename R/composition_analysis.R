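# Cluster composition vectors, similarity of adjacent clusters, hierarchical
# grouping on binary presence patterns, functional-system enrichment of
# groups, and cortical-hierarchy correlations.

#' Subclass composition vectors for every cluster
#'
#' For each cluster, the proportion of members in every subclass of the
#' declared vocabulary (absent subclasses contribute 0; proportions sum to
#' 1) and the binary presence vector (`1` iff the proportion is positive).
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the matching [cell_table()].
#' @return List with matrices `proportions` and `presence` (clusters x
#'   subclasses, rownames = cluster ids).
#' @export
composition_vectors <- function(clusters, cells) {
  vocab <- subclass_vocab(cells)
  labels <- unique(c(vocab$excitatory, vocab$inhibitory))
  mc <- membership_cells(clusters, cells)
  ids <- clusters$clusters$cluster_id
  prop <- matrix(0, length(ids), length(labels),
                 dimnames = list(ids, labels))
  for (i in seq_along(ids)) {
    sub <- mc$subclass[mc$cluster_id == ids[i]]
    tab <- table(factor(sub, levels = labels))
    prop[i, ] <- as.numeric(tab) / length(sub)
  }
  list(proportions = prop, presence = (prop > 0) * 1L)
}

nearest_same_type <- function(clusters, cells, type) {
  cl <- clusters$clusters[clusters$clusters$type == type, , drop = FALSE]
  mc <- membership_cells(clusters, cells)
  coords <- split(mc, mc$cluster_id)
  out <- list()
  strata <- unique(cl[, c("section_id", "layer")])
  for (si in seq_len(nrow(strata))) {
    sub <- cl[cl$section_id == strata$section_id[si] &
                cl$layer == strata$layer[si], , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub))) {
      a <- coords[[sub$cluster_id[i]]]
      d <- vapply(seq_len(nrow(sub)), function(j) {
        if (j == i) return(Inf)
        b <- coords[[sub$cluster_id[j]]]
        min_cross_distance(a$x, a$y, b$x, b$y)
      }, numeric(1))
      ord <- order(d, sub$cluster_id)
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = sub$cluster_id[i], nearest_id = sub$cluster_id[ord[1]],
        distance = d[ord[1]], section_id = strata$section_id[si],
        layer = strata$layer[si], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

pair_similarity <- function(prop, a, b, method) {
  vapply(seq_along(a), function(i) {
    suppressWarnings(cor(prop[a[i], ], prop[b[i], ], method = method))
  }, numeric(1))
}

#' Do adjacent clusters use similar subclass mixtures?
#'
#' Pairs each cluster of the given type with its nearest same-type cluster
#' in the same stratum (minimum inter-cell distance), computes the Pearson
#' and Spearman correlation of the paired composition vectors, and compares
#' those similarities against an equal number of random non-nearest
#' same-stratum pairs (seeded) with the Wilcoxon rank-sum test.
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the matching [cell_table()].
#' @param type cluster type to analyse.
#' @param seed integer seed for the control pairs.
#' @return List with `adjacent` and `control` similarity data.frames, and
#'   `test` (per method: Wilcoxon rank-sum statistic and p, one-sided:
#'   adjacent greater). `NULL` when no stratum holds two clusters of the
#'   type.
#' @export
adjacent_similarity_test <- function(clusters, cells,
                                     type = c("excitatory", "inhibitory"),
                                     seed = 1L) {
  type <- match.arg(type)
  nst <- nearest_same_type(clusters, cells, type)
  if (is.null(nst)) return(NULL)
  comp <- composition_vectors(clusters, cells)
  prop <- comp$proportions
  # unique unordered adjacent pairs
  key <- t(apply(cbind(nst$cluster_id, nst$nearest_id), 1L, sort))
  adj <- unique(data.frame(a = key[, 1], b = key[, 2],
                           stratum = paste(nst$section_id, nst$layer),
                           stringsAsFactors = FALSE))
  ctrl <- with_seed(seed, {
    rows <- list()
    for (st in unique(adj$stratum)) {
      sub <- nst[paste(nst$section_id, nst$layer) == st, ]
      ids <- unique(c(sub$cluster_id, sub$nearest_id))
      n_needed <- sum(adj$stratum == st)
      all_pairs <- t(combn(sort(ids), 2L))
      is_adj <- paste(all_pairs[, 1], all_pairs[, 2]) %in%
        paste(adj$a[adj$stratum == st], adj$b[adj$stratum == st])
      cand <- all_pairs[!is_adj, , drop = FALSE]
      if (nrow(cand) == 0L) next
      take <- sample.int(nrow(cand), min(n_needed, nrow(cand)))
      rows[[st]] <- data.frame(a = cand[take, 1], b = cand[take, 2],
                               stratum = st, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) NULL else do.call(rbind, rows)
  })
  sim <- function(df) if (is.null(df)) NULL else data.frame(
    a = df$a, b = df$b,
    pearson = pair_similarity(prop, df$a, df$b, "pearson"),
    spearman = pair_similarity(prop, df$a, df$b, "spearman"),
    stringsAsFactors = FALSE)
  adj_sim <- sim(adj)
  ctrl_sim <- sim(ctrl)
  test <- NULL
  if (!is.null(ctrl_sim)) {
    test <- lapply(c(pearson = "pearson", spearman = "spearman"), function(mm) {
      a <- adj_sim[[mm]]; b <- ctrl_sim[[mm]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) == 0L || length(b) == 0L) return(NULL)
      wt <- suppressWarnings(wilcox.test(a, b, alternative = "greater"))
      list(median_adjacent = median(a), median_control = median(b),
           statistic = unname(wt$statistic), p = wt$p.value)
    })
  }
  list(adjacent = adj_sim, control = ctrl_sim, test = test)
}

#' Group clusters by binary subclass presence
#'
#' Agglomerative hierarchical clustering of the binary presence vectors
#' (Jaccard distance, average linkage by default), cut at `k` groups.
#' Group labels `h1, h2, ...` are assigned deterministically in decreasing
#' group size (ties by the smallest member row index).
#'
#' @param presence binary matrix (clusters x subclasses), e.g. from
#'   [composition_vectors()].
#' @param k number of groups; must not exceed the number of clusters.
#' @param method distance passed to [vegan::vegdist()] (default
#'   `"jaccard"`, binary).
#' @param linkage linkage passed to [hclust()] (default `"average"`).
#' @return data.frame `cluster_id`, `group`.
#' @export
hierarchical_groups <- function(presence, k, method = "jaccard",
                                linkage = "average") {
  n <- nrow(presence)
  if (k > n) stop("k exceeds the number of clusters (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(rownames(presence))) rownames(presence) <- seq_len(n)
  d <- vegan::vegdist(presence, method = method, binary = TRUE)
  d[!is.finite(d)] <- 1 # pairs with no presence overlap at all
  cut <- cutree(hclust(d, method = linkage), k = k)
  size <- table(cut)
  first <- tapply(seq_len(n), cut, min)
  ord <- order(-as.numeric(size), as.numeric(first))
  relabel <- setNames(paste0("h", seq_len(k)), names(size)[ord])
  data.frame(cluster_id = rownames(presence),
             group = unname(relabel[as.character(cut)]),
             stringsAsFactors = FALSE)
}

#' Functional-system enrichment of cluster groups
#'
#' For every (group, system) pair, a one-sided Fisher enrichment test on the
#' 2x2 table of group membership against whether a cluster's assigned region
#' belongs to the system, with Benjamini-Hochberg adjustment across all
#' pairs tested in the call. The reported odds ratio is the sample odds
#' ratio with the Haldane-Anscombe 0.5 correction when a cell is zero.
#'
#' @param groups data.frame `cluster_id`, `group` from
#'   [hierarchical_groups()].
#' @param summaries data.frame from [cluster_summaries()] (supplies
#'   `assigned_region`).
#' @param annotation a `region_annotation`.
#' @param systems systems to test (default all three).
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame `group`, `system`, `a`..`d`, `odds_ratio`, `p`,
#'   `p_adj`, `enriched`.
#' @export
functional_enrichment <- function(groups, summaries, annotation,
                                  systems = c("dmn", "visual", "somatosensory"),
                                  alpha = 0.05) {
  reg <- setNames(summaries$assigned_region, summaries$cluster_id)
  df <- groups
  df$region <- unname(reg[df$cluster_id])
  rows <- list()
  for (sys in systems) {
    insys <- region_in_system(annotation, df$region, sys)
    for (g in sort(unique(df$group))) {
      ing <- df$group == g
      a <- sum(ing & insys); b <- sum(ing & !insys)
      c_ <- sum(!ing & insys); d <- sum(!ing & !insys)
      ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                        alternative = "greater")
      corr <- any(c(a, b, c_, d) == 0)
      or <- if (corr) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
            else (a * d) / (b * c_)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, system = sys, a = a, b = b, c = c_, d = d,
        odds_ratio = or, p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$enriched <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Correlate cluster properties with cortical hierarchy level
#'
#' Pearson correlation between the hierarchy level of each cluster's
#' assigned region and (a) `log10` cluster size, (b) the cluster E-I ratio,
#' per cluster type. Clusters in unleveled regions, and undefined ratios,
#' are excluded; Spearman values are reported alongside.
#'
#' @param summaries data.frame from [cluster_summaries()].
#' @param annotation a `region_annotation` with hierarchy levels.
#' @return data.frame `type`, `measure`, `n`, `r`, `p`, `rho`.
#' @export
hierarchy_correlation <- function(summaries, annotation) {
  lvl <- region_level(annotation, summaries$assigned_region)
  rows <- list()
  for (tp in unique(summaries$type)) {
    sel <- summaries$type == tp
    for (ms in c("log10_size", "ei_ratio")) {
      v <- if (ms == "log10_size") log10(summaries$size[sel])
           else summaries$ei_ratio[sel]
      pe <- safe_cor(lvl[sel], v)
      sp <- safe_cor(lvl[sel], v, method = "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        type = tp, measure = ms, n = pe$n, r = pe$r, p = pe$p, rho = sp$r,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-group composition and property summary
#'
#' For each group: member count, mean and median `log10` size, mean E-I
#' ratio over members with a defined ratio, and the per-subclass presence
#' frequency (the fraction of member clusters containing the subclass - the
#' heat-map source for group characterisation).
#'
#' @param groups data.frame from [hierarchical_groups()].
#' @param summaries data.frame from [cluster_summaries()].
#' @param composition list from [composition_vectors()].
#' @param enrichment optional data.frame from [functional_enrichment()] to
#'   carry alongside.
#' @return List with `groups` (one row per group) and `presence_freq`
#'   (groups x subclasses matrix), plus `enrichment` if supplied.
#' @export
group_system_summary <- function(groups, summaries, composition,
                                 enrichment = NULL) {
  pres <- composition$presence[groups$cluster_id, , drop = FALSE]
  sm <- summaries[match(groups$cluster_id, summaries$cluster_id), ]
  glab <- sort(unique(groups$group))
  tab <- do.call(rbind, lapply(glab, function(g) {
    sel <- groups$group == g
    ratios <- sm$ei_ratio[sel]
    data.frame(group = g, n = sum(sel),
               mean_log10_size = mean(log10(sm$size[sel])),
               median_log10_size = median(log10(sm$size[sel])),
               mean_ei_ratio = if (any(is.finite(ratios)))
                 mean(ratios[is.finite(ratios)]) else NA_real_,
               n_ei_defined = sum(is.finite(ratios)),
               stringsAsFactors = FALSE)
  }))
  freq <- do.call(rbind, lapply(glab, function(g) {
    colMeans(pres[groups$group == g, , drop = FALSE])
  }))
  rownames(freq) <- glab
  out <- list(groups = tab, presence_freq = freq)
  if (!is.null(enrichment)) out$enrichment <- enrichment
  out
}
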