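# Per-cluster metrics (E-I ratio, nearest-neighbour distances, interregional
# span) and cluster-pair relations (partnerships, overlap, coupling).

#' Nearest-neighbour distance for each point
#'
#' Euclidean distance from every point to its nearest other point, computed
#' by blocked brute force (all pairwise distances, never materialising the
#' full matrix).
#'
#' @param x,y numeric coordinate vectors.
#' @return Numeric vector of nearest-neighbour distances; `NA` when fewer
#'   than two points.
#' @export
nn_distances <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  out <- numeric(n)
  chunk <- max(1L, as.integer(4e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf # self
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Excitation-inhibition ratio
#'
#' Ratio of excitatory to inhibitory counts. Pure-excitatory sets
#' (`n_inh = 0`) have an undefined ratio and return `NA` (they are excluded
#' from every correlation downstream); pure-inhibitory sets return 0.
#'
#' @param n_exc,n_inh non-negative counts (vectorised).
#' @return Numeric vector of ratios.
#' @export
ei_ratio <- function(n_exc, n_inh) {
  ifelse(n_inh == 0, NA_real_, n_exc / n_inh)
}

#' Jaccard overlap coefficient from set sizes
#'
#' @param size_a,size_b sizes of the two sets.
#' @param shared size of their intersection.
#' @return `shared / (size_a + size_b - shared)` (vectorised).
#' @export
jaccard <- function(size_a, size_b, shared) {
  denom <- size_a + size_b - shared
  ifelse(denom == 0, NA_real_, shared / denom)
}

#' Does a cluster span several brain regions?
#'
#' @param regions character vector of member-cell region labels (a multiset).
#' @return `TRUE` iff at least two distinct regions occur.
#' @export
interregional_flag <- function(regions) {
  length(unique(regions)) >= 2L
}

#' Mean nearest-neighbour distance among a cluster's members
#'
#' Each member's distance to its nearest other member, averaged; computed
#' within sections (members alone in their section have no neighbour and are
#' excluded).
#'
#' @param members data.frame with `x`, `y` and `section_id`.
#' @return Mean distance in micrometres; `NA` when no member has a
#'   same-section neighbour.
#' @export
mean_nn_distance <- function(members) {
  if (nrow(members) < 2L) return(NA_real_)
  d <- unlist(lapply(split(seq_len(nrow(members)), members$section_id),
                     function(idx) nn_distances(members$x[idx], members$y[idx])))
  if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
}

membership_cells <- function(clusters, cells) {
  df <- as.data.frame(cells)
  m <- clusters$membership
  idx <- match(m$cell_id, df$cell_id)
  if (anyNA(idx)) stop("cluster membership refers to cells absent from the table")
  cbind(m, df[idx, c("x", "y", "section_id", "layer", "region", "class",
                     "subclass")])
}

#' Summarise every cluster
#'
#' One row per cluster: counts, E-I ratio with purity flags, mean
#' nearest-neighbour distance, the set of member regions, the interregional
#' flag and the assigned region (plurality vote of member cells, ties broken
#' lexicographically).
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the [cell_table()] the clusters were detected in.
#' @return A data.frame of per-cluster summaries.
#' @export
cluster_summaries <- function(clusters, cells) {
  cl <- clusters$clusters
  if (nrow(cl) == 0L) {
    return(cbind(cl, data.frame(ei_ratio = numeric(0), pure = logical(0),
                                mean_nn_dist = numeric(0),
                                n_regions = integer(0),
                                interregional = logical(0),
                                assigned_region = character(0),
                                regions = character(0))))
  }
  mc <- membership_cells(clusters, cells)
  by_cl <- split(mc, mc$cluster_id)
  extra <- do.call(rbind, lapply(cl$cluster_id, function(id) {
    g <- by_cl[[id]]
    tab <- sort(table(g$region), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    data.frame(
      ei_ratio = ei_ratio(sum(g$class == "excitatory"),
                          sum(g$class == "inhibitory")),
      pure = length(unique(g$class)) == 1L,
      mean_nn_dist = mean_nn_distance(g),
      n_regions = length(tab),
      interregional = interregional_flag(g$region),
      assigned_region = sort(top)[1],
      regions = paste(sort(names(tab)), collapse = ","),
      stringsAsFactors = FALSE)
  }))
  out <- cbind(cl, extra)
  rownames(out) <- NULL
  out
}

#' In-cluster coverage of the neuron population
#'
#' Fraction of all neurons lying in at least one cluster (either type),
#' overall and per layer, with the standard error of the mean of the
#' per-section fractions.
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the [cell_table()] of the same run.
#' @return List with `overall` (fraction), `overall_sem`, and `per_layer`
#'   (data.frame `layer`, `n_cells`, `n_in_cluster`, `fraction`, `sem`).
#' @export
coverage_stats <- function(clusters, cells) {
  df <- as.data.frame(cells)
  incl <- df$cell_id %in% unique(clusters$membership$cell_id)
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  per_section <- tapply(incl, df$section_id, mean)
  layers <- sort(unique(df$layer))
  per_layer <- do.call(rbind, lapply(layers, function(l) {
    sel <- df$layer == l
    sec_frac <- tapply(incl[sel], df$section_id[sel], mean)
    data.frame(layer = l, n_cells = sum(sel), n_in_cluster = sum(incl[sel]),
               fraction = mean(incl[sel]), sem = sem(as.numeric(sec_frac)))
  }))
  list(overall = mean(incl), overall_sem = sem(as.numeric(per_section)),
       per_layer = per_layer)
}

#' Excitatory/inhibitory proportions per region and layer
#'
#' Class proportions for every (region, layer) stratum with at least one
#' neuron, plus the per-layer Pearson correlation between per-region
#' excitatory and inhibitory counts (the cross-region E-I balance check).
#'
#' @param cells a [cell_table()].
#' @return List with `proportions` (data.frame `region`, `layer`, `n_exc`,
#'   `n_inh`, `prop_exc`, `prop_inh`) and `correlation` (data.frame `layer`,
#'   `n_regions`, `r`, `p`).
#' @export
layer_class_proportions <- function(cells) {
  df <- as.data.frame(cells)
  agg <- aggregate(cbind(n_exc = class == "excitatory",
                         n_inh = class == "inhibitory") ~ region + layer,
                   data = df, FUN = sum)
  tot <- agg$n_exc + agg$n_inh
  agg$prop_exc <- agg$n_exc / tot
  agg$prop_inh <- agg$n_inh / tot
  corr <- do.call(rbind, lapply(sort(unique(agg$layer)), function(l) {
    sub <- agg[agg$layer == l, ]
    if (nrow(sub) >= 3L && sd(sub$n_exc) > 0 && sd(sub$n_inh) > 0) {
      ct <- cor.test(sub$n_exc, sub$n_inh)
      data.frame(layer = l, n_regions = nrow(sub),
                 r = unname(ct$estimate), p = ct$p.value)
    } else {
      data.frame(layer = l, n_regions = nrow(sub), r = NA_real_, p = NA_real_)
    }
  }))
  agg <- agg[order(agg$region, agg$layer), ]
  rownames(agg) <- NULL
  list(proportions = agg, correlation = corr)
}

#' Are inhibitory clusters over-populated relative to the class balance?
#'
#' One-degree-of-freedom goodness-of-fit test comparing the observed split
#' of cluster-member cells between excitatory and inhibitory clusters with
#' the split expected from the overall class fractions (an inhibitory share
#' of cells should, under proportionality, put that share of clustered cells
#' into inhibitory clusters).
#'
#' @param clusters a `neuron_clusters` object, or `NULL` when `observed` is
#'   given directly.
#' @param cells the matching [cell_table()]; ignored when `observed` given.
#' @param observed optional numeric length-2: cells in excitatory clusters,
#'   cells in inhibitory clusters.
#' @param expected optional numeric length-2 of expected counts (same order);
#'   with `clusters`/`cells` it defaults to the overall class-fraction split.
#' @return List with `observed`, `expected`, `statistic` (chi-square, 1 df)
#'   and `p`.
#' @export
class_balance_test <- function(clusters = NULL, cells = NULL,
                               observed = NULL, expected = NULL) {
  if (is.null(observed)) {
    stopifnot(inherits(clusters, "neuron_clusters"))
    m <- clusters$membership
    type_of <- setNames(clusters$clusters$type, clusters$clusters$cluster_id)
    in_e <- unique(m$cell_id[type_of[m$cluster_id] == "excitatory"])
    in_i <- unique(m$cell_id[type_of[m$cluster_id] == "inhibitory"])
    observed <- c(exc_cluster = length(in_e), inh_cluster = length(in_i))
    if (is.null(expected)) {
      p_inh <- mean(as.data.frame(cells)$class == "inhibitory")
      expected <- sum(observed) * c(1 - p_inh, p_inh)
    }
  }
  if (is.null(expected)) stop("expected counts required")
  if (any(expected <= 0)) stop("expected count of zero in a category")
  stat <- sum((observed - expected)^2 / expected)
  list(observed = observed, expected = expected, statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Find excitatory-inhibitory cluster partnerships
#'
#' A partnership is an excitatory cluster and an inhibitory cluster sharing
#' at least one member cell. Each pair carries the shared count, the Jaccard
#' coefficient and the per-cluster overlap fractions; per-cluster partner
#' counts are returned alongside.
#'
#' @param clusters a `neuron_clusters` object.
#' @return List with `pairs` (data.frame `exc_cluster_id`, `inh_cluster_id`,
#'   `shared`, `size_exc`, `size_inh`, `jaccard`, `frac_exc`, `frac_inh`)
#'   and `partner_counts` (data.frame `cluster_id`, `type`, `n_partners`).
#' @export
find_partners <- function(clusters) {
  cl <- clusters$clusters
  m <- clusters$membership
  type_of <- setNames(cl$type, cl$cluster_id)
  size_of <- setNames(cl$size, cl$cluster_id)
  me <- m[type_of[m$cluster_id] == "excitatory", ]
  mi <- m[type_of[m$cluster_id] == "inhibitory", ]
  if (nrow(me) > 0L && nrow(mi) > 0L) {
    j <- merge(me, mi, by = "cell_id", suffixes = c("_e", "_i"))
  } else {
    j <- data.frame(cell_id = character(0), cluster_id_e = character(0),
                    cluster_id_i = character(0))
  }
  if (nrow(j) > 0L) {
    shared <- aggregate(cell_id ~ cluster_id_e + cluster_id_i, data = j,
                        FUN = length)
    names(shared) <- c("exc_cluster_id", "inh_cluster_id", "shared")
    shared$size_exc <- unname(size_of[shared$exc_cluster_id])
    shared$size_inh <- unname(size_of[shared$inh_cluster_id])
    shared$jaccard <- jaccard(shared$size_exc, shared$size_inh, shared$shared)
    shared$frac_exc <- shared$shared / shared$size_exc
    shared$frac_inh <- shared$shared / shared$size_inh
    shared <- shared[order(shared$exc_cluster_id, shared$inh_cluster_id), ]
    rownames(shared) <- NULL
  } else {
    shared <- data.frame(exc_cluster_id = character(0),
                         inh_cluster_id = character(0), shared = integer(0),
                         size_exc = integer(0), size_inh = integer(0),
                         jaccard = numeric(0), frac_exc = numeric(0),
                         frac_inh = numeric(0), stringsAsFactors = FALSE)
  }
  np <- table(c(shared$exc_cluster_id, shared$inh_cluster_id))
  partner_counts <- data.frame(
    cluster_id = cl$cluster_id, type = cl$type,
    n_partners = as.integer(ifelse(cl$cluster_id %in% names(np),
                                   np[cl$cluster_id], 0L)),
    stringsAsFactors = FALSE)
  list(pairs = shared, partner_counts = partner_counts)
}

min_cross_distance <- function(ax, ay, bx, by) {
  best <- Inf
  chunk <- max(1L, as.integer(4e6 / max(length(bx), 1L)))
  for (start in seq(1L, length(ax), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(ax))
    d2 <- outer(ax[idx], bx, "-")^2 + outer(ay[idx], by, "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Nearest opposite-type cluster for every cluster
#'
#' For each cluster, the closest cluster of the opposite type in the same
#' stratum, measured as the minimum Euclidean distance over cross-cluster
#' cell pairs (0 when the clusters share cells). Ties break to the smaller
#' cluster id.
#'
#' @param clusters a `neuron_clusters` object.
#' @param cells the matching [cell_table()].
#' @return data.frame `cluster_id`, `type`, `nearest_id`, `distance`; rows
#'   with no opposite-type cluster in the stratum carry `NA`.
#' @export
nearest_opposite_cluster <- function(clusters, cells) {
  cl <- clusters$clusters
  if (nrow(cl) == 0L) {
    return(data.frame(cluster_id = character(0), type = character(0),
                      nearest_id = character(0), distance = numeric(0)))
  }
  mc <- membership_cells(clusters, cells)
  coords <- split(mc, mc$cluster_id)
  members <- split(mc$cell_id, mc$cluster_id)
  out <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    self <- cl[i, ]
    opp <- cl[cl$type != self$type & cl$section_id == self$section_id &
                cl$layer == self$layer, , drop = FALSE]
    if (nrow(opp) == 0L) {
      return(data.frame(cluster_id = self$cluster_id, type = self$type,
                        nearest_id = NA_character_, distance = NA_real_,
                        stringsAsFactors = FALSE))
    }
    a <- coords[[self$cluster_id]]
    dists <- vapply(opp$cluster_id, function(oid) {
      if (length(intersect(members[[self$cluster_id]], members[[oid]])) > 0L)
        return(0)
      b <- coords[[oid]]
      min_cross_distance(a$x, a$y, b$x, b$y)
    }, numeric(1))
    ord <- order(dists, opp$cluster_id)
    data.frame(cluster_id = self$cluster_id, type = self$type,
               nearest_id = opp$cluster_id[ord[1]],
               distance = dists[ord[1]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

safe_cor <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(list(n = sum(ok), r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(x[ok], y[ok], method = method)
  list(n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
}

#' Coupling statistics between partnered and adjacent clusters
#'
#' Pearson correlations relating excitatory and inhibitory clusters:
#' E-I-ratio coupling across partner pairs, E-I-ratio coupling across
#' nearest-adjacent opposite pairs, `log10(size)` versus partner count per
#' cluster type, and `log10(size)` versus having any partner (partnership
#' propensity). Clusters with undefined E-I ratios are excluded; a
#' correlation needs at least three valid observations, else it is reported
#' as `NA`.
#'
#' @param summaries data.frame from [cluster_summaries()].
#' @param partners list from [find_partners()].
#' @param nearest optional data.frame from [nearest_opposite_cluster()]; the
#'   adjacent-pair coupling is skipped when absent.
#' @return Nested list of `{n, r, p}` reports.
#' @export
coupling_stats <- function(summaries, partners, nearest = NULL) {
  ratio_of <- setNames(summaries$ei_ratio, summaries$cluster_id)
  size_of <- setNames(summaries$size, summaries$cluster_id)
  pairs <- partners$pairs
  partner_ratio <- safe_cor(ratio_of[pairs$exc_cluster_id],
                            ratio_of[pairs$inh_cluster_id])
  adjacent_ratio <- NULL
  if (!is.null(nearest)) {
    ne <- nearest[!is.na(nearest$nearest_id) & nearest$type == "excitatory", ]
    adjacent_ratio <- safe_cor(ratio_of[ne$cluster_id], ratio_of[ne$nearest_id])
  }
  pc <- merge(partners$partner_counts,
              summaries[, c("cluster_id", "size", "ei_ratio")], by = "cluster_id")
  per_type <- lapply(c(excitatory = "excitatory", inhibitory = "inhibitory"),
                     function(tp) {
    sub <- pc[pc$type == tp, ]
    list(size_vs_partners = safe_cor(log10(sub$size), sub$n_partners),
         size_vs_propensity = safe_cor(log10(sub$size),
                                       as.numeric(sub$n_partners > 0)),
         ratio_vs_propensity = safe_cor(sub$ei_ratio,
                                        as.numeric(sub$n_partners > 0)))
  })
  list(partner_ratio = partner_ratio, adjacent_ratio = adjacent_ratio,
       by_type = per_type)
}

#' Layer-wise enrichment of interregional clusters
#'
#' For each layer and cluster type, the odds ratio of being interregional in
#' that layer versus all other layers (2x2 table), with the Woolf normal
#' confidence interval on the log odds ratio. Tables with a zero cell get
#' the Haldane-Anscombe 0.5 continuity correction and are flagged.
#'
#' @param summaries data.frame from [cluster_summaries()].
#' @param conf confidence level for the interval (default 0.95).
#' @return data.frame `type`, `layer`, `a`..`d` (table cells), `odds_ratio`,
#'   `ci_lo`, `ci_hi`, `corrected`.
#' @export
interregional_enrichment <- function(summaries, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  out <- list()
  for (tp in unique(summaries$type)) {
    sub <- summaries[summaries$type == tp, ]
    for (l in sort(unique(sub$layer))) {
      inl <- sub$layer == l
      a <- sum(inl & sub$interregional)
      b <- sum(inl & !sub$interregional)
      c_ <- sum(!inl & sub$interregional)
      d <- sum(!inl & !sub$interregional)
      corrected <- any(c(a, b, c_, d) == 0)
      if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
      or <- (a * d) / (b * c_)
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      out[[length(out) + 1L]] <- data.frame(
        type = tp, layer = l, a = a, b = b, c = c_, d = d,
        odds_ratio = or, ci_lo = exp(log(or) - z * se),
        ci_hi = exp(log(or) + z * se), corrected = corrected,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
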