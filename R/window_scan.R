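# Sliding-window scan: count neurons per window, score per-class enrichment
# against a label-permutation null, and merge overlapping significant windows
# into neuron clusters.
#
# The null fixes all cell positions and permutes the class labels among them
# (equivalent to shuffling the coordinates of each class within the stratum).
# For a fixed window this makes the in-window class count exactly
# hypergeometric, which exact_pvalue() exposes as an analytic cross-check of
# the Monte-Carlo estimate.

floor_to <- function(v, step) floor(round(v / step, 9)) * step

#' Enumerate occupied sliding windows over one stratum
#'
#' Lays a square grid of side `window_size` stepped by `step` over the
#' bounding box of the cells, extended one window beyond the hull on every
#' side, and records which cells fall in each window under the half-open
#' membership rule `[x0, x0 + W) x [y0, y0 + W)`. With the extended grid and
#' `window_size` a multiple of `step`, every cell lies in exactly
#' `(window_size/step)^2` windows. Empty windows are dropped.
#'
#' @param cells data.frame (or `cell_table`) of one stratum with numeric
#'   `x`, `y` and a `cell_id` column.
#' @param window_size window side in micrometres.
#' @param step grid step in micrometres; `step > window_size` is an error
#'   (the grid would skip cells).
#' @return A `window_set`: list with `windows` (data.frame `window_id`,
#'   `x0`, `y0`, `n_total`), sparse `incidence` (windows x cells) and
#'   `cell_id`.
#' @export
enumerate_windows <- function(cells, window_size, step) {
  if (step > window_size) stop("step must not exceed window_size")
  if (step <= 0) stop("step must be positive")
  n <- nrow(cells)
  if (n == 0L) stop("stratum contains no cells")
  x <- cells$x; y <- cells$y
  ox1 <- floor_to(min(x), step) - window_size + step
  oy1 <- floor_to(min(y), step) - window_size + step
  nkx <- as.integer(round((floor_to(max(x), step) - ox1) / step)) + 1L
  nky <- as.integer(round((floor_to(max(y), step) - oy1) / step)) + 1L

  k_range <- function(v, o1) {
    hi <- floor(round((v - o1) / step, 9)) + 1
    lo <- floor(round((v - window_size - o1) / step, 9)) + 2
    cbind(lo, hi)
  }
  kx <- k_range(x, ox1)
  ky <- k_range(y, oy1)
  nx <- kx[, 2] - kx[, 1] + 1
  ny <- ky[, 2] - ky[, 1] + 1

  ii <- rep.int(seq_len(n), nx * ny)
  off <- sequence(nx * ny) - 1L
  ny_i <- ny[ii]
  kxv <- kx[ii, 1] + off %/% ny_i
  kyv <- ky[ii, 1] + off %% ny_i
  w_lin <- (kxv - 1) * nky + kyv

  uw <- sort(unique(w_lin))
  wi <- match(w_lin, uw)
  M <- Matrix::sparseMatrix(i = wi, j = ii, x = 1,
                            dims = c(length(uw), n))
  x0 <- ox1 + ((uw - 1) %/% nky) * step
  y0 <- oy1 + ((uw - 1) %% nky) * step
  windows <- data.frame(window_id = seq_along(uw), x0 = x0, y0 = y0,
                        n_total = as.integer(Matrix::rowSums(M)))
  structure(list(windows = windows, incidence = M,
                 cell_id = as.character(cells$cell_id),
                 window_size = window_size, step = step),
            class = "window_set")
}

#' Member cells of one window
#'
#' @param ws a `window_set` from [enumerate_windows()].
#' @param window_id window index.
#' @return Character vector of `cell_id`s.
#' @export
window_members <- function(ws, window_id) {
  stopifnot(inherits(ws, "window_set"))
  ws$cell_id[which(ws$incidence[window_id, ] > 0)]
}

#' Exact upper-tail enrichment p-value under the label-permutation null
#'
#' For a fixed window holding `n_w` of the stratum's `N` cells, of which `K`
#' carry the class of interest, the in-window class count under a uniform
#' label permutation is hypergeometric; the one-sided enrichment p-value is
#' `P[X >= k]`. This closed form is the analytic oracle the Monte-Carlo
#' permutation estimate converges to.
#'
#' @param N stratum size.
#' @param K stratum-wide count of the class of interest.
#' @param n_w number of cells in the window.
#' @param k observed in-window count of the class.
#' @return The p-value `sum_{j >= k} C(K,j) C(N-K, n_w-j) / C(N, n_w)`.
#' @export
exact_pvalue <- function(N, K, n_w, k) {
  if (any(c(N, K, n_w, k) < 0) || K > N || n_w > N ||
      k > min(K, n_w) || k < max(0, n_w - (N - K))) {
    stop("inconsistent hypergeometric arguments")
  }
  stats::phyper(k - 1, K, N - K, n_w, lower.tail = FALSE)
}

#' Permutation enrichment p-values for every window
#'
#' Holds cell positions fixed, permutes the excitatory/inhibitory labels
#' uniformly among them `n_perm` times, and for each window and class
#' reports the one-sided enrichment p-value with the add-one estimator
#' `p = (1 + #\{count >= observed\}) / (1 + n_perm)`, so `p` is never zero.
#' One shuffle serves every window of the stratum jointly. A stratum with a
#' single class is degenerate: every p-value is 1.
#'
#' @param cells stratum cells: data.frame with `cell_id` and `class`
#'   matching the window set(s).
#' @param windows a `window_set`, or a list of `window_set`s (one per
#'   section) whose cells jointly partition `cells` - used when the
#'   permutation pool spans several sections of a layer.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param alpha significance level for the per-window flags.
#' @param min_window_n windows with fewer cells are never flagged.
#' @return A `window_stats` object: data.frame with per-window counts,
#'   `p_exc`, `p_inh` and significance flags, carrying the incidence and the
#'   stratum cells as attributes for merging.
#' @export
permutation_pvalues <- function(cells, windows, n_perm = 10000, seed = 1L,
                                alpha = 0.05, min_window_n = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ws_list <- if (inherits(windows, "window_set")) list(windows) else windows
  stopifnot(all(vapply(ws_list, inherits, logical(1), "window_set")))
  n <- nrow(cells)
  cell_id <- as.character(cells$cell_id)

  blocks <- lapply(ws_list, function(ws) {
    jj <- match(ws$cell_id, cell_id)
    if (anyNA(jj)) stop("window set refers to cells outside the stratum")
    summ <- Matrix::summary(ws$incidence)
    Matrix::sparseMatrix(i = summ$i, j = jj[summ$j], x = 1,
                         dims = c(nrow(ws$windows), n))
  })
  M <- do.call(rbind, blocks)
  wmeta <- do.call(rbind, lapply(seq_along(ws_list), function(b) {
    w <- ws_list[[b]]$windows
    data.frame(block = b, block_window = w$window_id, x0 = w$x0, y0 = w$y0)
  }))

  inh <- as.numeric(cells$class == "inhibitory")
  K <- as.integer(sum(inh))
  n_inh <- as.vector(M %*% inh)
  n_tot <- as.vector(Matrix::rowSums(M))
  n_exc <- n_tot - n_inh
  degenerate <- (K == 0L || K == n)

  exceed_inh <- numeric(length(n_tot))
  exceed_exc <- numeric(length(n_tot))
  if (degenerate) {
    exceed_inh[] <- n_perm
    exceed_exc[] <- n_perm
  } else {
    chunk <- max(1L, min(n_perm,
                         as.integer(4e6 / max(K, 1L)),
                         as.integer(8e6 / max(length(n_tot), 1L))))
    with_seed(seed, {
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        samp <- replicate(b, sample.int(n, K))
        Z <- Matrix::sparseMatrix(i = as.vector(samp),
                                  j = rep.int(seq_len(b), rep.int(K, b)),
                                  x = 1, dims = c(n, b))
        C <- as.matrix(M %*% Z)
        exceed_inh <- exceed_inh + rowSums(C >= n_inh)
        exceed_exc <- exceed_exc + rowSums(C <= n_inh)
        done <- done + b
      }
    })
  }
  p_inh <- (1 + exceed_inh) / (1 + n_perm)
  p_exc <- (1 + exceed_exc) / (1 + n_perm)
  testable <- n_tot >= min_window_n
  stats <- data.frame(window_id = seq_along(n_tot),
                      x0 = wmeta$x0, y0 = wmeta$y0,
                      n_total = as.integer(n_tot),
                      n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                      p_exc = p_exc, p_inh = p_inh,
                      sig_exc = testable & p_exc < alpha,
                      sig_inh = testable & p_inh < alpha)
  structure(stats, incidence = M, stratum_cells = as.data.frame(cells),
            alpha = alpha, n_perm = as.integer(n_perm),
            min_window_n = as.integer(min_window_n),
            window_size = ws_list[[1]]$window_size,
            degenerate = degenerate, class = c("window_stats", "data.frame"))
}

#' Merge overlapping significant windows into neuron clusters
#'
#' For each class separately, connects significant windows that share at
#' least one cell and takes connected components as clusters; a cluster's
#' members are the union of its windows' cells (all classes). Cluster ids
#' are deterministic: class prefix, stratum, and the lexicographically
#' smallest member `cell_id`.
#'
#' @param stats a `window_stats` from [permutation_pvalues()].
#' @param alpha significance level; defaults to the one the flags were
#'   computed at.
#' @param connectivity `"cells"` (default: windows sharing a cell are
#'   connected, as in the merging rule the scan is built around) or
#'   `"geometry"` (windows whose squares overlap are connected), kept for
#'   sensitivity analysis.
#' @return A `neuron_clusters` object: list with `clusters` (one row per
#'   cluster: id, stratum, type, window count, size, `n_exc`, `n_inh`) and
#'   `membership` (`cluster_id`, `cell_id`).
#' @export
merge_significant_windows <- function(stats, alpha = attr(stats, "alpha"),
                                      connectivity = c("cells", "geometry")) {
  stopifnot(inherits(stats, "window_stats"))
  connectivity <- match.arg(connectivity)
  M <- attr(stats, "incidence")
  cells <- attr(stats, "stratum_cells")
  section <- if (length(unique(cells$section_id)) == 1L)
    cells$section_id[1] else "pooled"
  layer <- if (length(unique(cells$layer)) == 1L) cells$layer[1] else NA_integer_

  min_n <- attr(stats, "min_window_n")
  if (is.null(min_n)) min_n <- 1L

  one_class <- function(type) {
    p <- if (type == "excitatory") stats$p_exc else stats$p_inh
    sig <- which(p < alpha & stats$n_total >= min_n)
    if (length(sig) == 0L) return(NULL)
    Ms <- M[sig, , drop = FALSE]
    if (connectivity == "cells") {
      S <- Matrix::tcrossprod(Ms)
    } else {
      W <- attr(stats, "window_size")
      xs <- stats$x0[sig]; ys <- stats$y0[sig]
      # squares overlap iff both axis offsets are < W
      Wd <- if (is.null(W)) max(diff(sort(unique(stats$x0))), 1) else W
      S <- Matrix::Matrix(outer(xs, xs, function(a, b) abs(a - b)) < Wd &
                          outer(ys, ys, function(a, b) abs(a - b)) < Wd,
                          sparse = TRUE)
    }
    g <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    lapply(seq_len(max(comp)), function(cc) {
      wrows <- sig[comp == cc]
      mem_idx <- which(Matrix::colSums(M[wrows, , drop = FALSE]) > 0)
      ids <- sort(cells$cell_id[mem_idx])
      cls <- cells$class[mem_idx]
      list(type = type, windows = wrows, member_ids = ids,
           n_exc = sum(cls == "excitatory"), n_inh = sum(cls == "inhibitory"))
    })
  }

  comps <- c(one_class("excitatory"), one_class("inhibitory"))
  if (length(comps) == 0L) return(empty_clusters())
  rows <- lapply(comps, function(cm) {
    data.frame(
      cluster_id = sprintf("%s_%s_L%s_%s",
                           if (cm$type == "excitatory") "E" else "I",
                           section, layer, cm$member_ids[1]),
      section_id = section, layer = as.integer(layer), type = cm$type,
      n_windows = length(cm$windows),
      size = length(cm$member_ids), n_exc = cm$n_exc, n_inh = cm$n_inh,
      stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  membership <- do.call(rbind, lapply(seq_along(comps), function(i) {
    data.frame(cluster_id = clusters$cluster_id[i],
               cell_id = comps[[i]]$member_ids, stringsAsFactors = FALSE)
  }))
  ord <- order(clusters$cluster_id)
  clusters <- clusters[ord, , drop = FALSE]
  rownames(clusters) <- NULL
  membership <- membership[order(membership$cluster_id, membership$cell_id), ,
                           drop = FALSE]
  rownames(membership) <- NULL
  structure(list(clusters = clusters, membership = membership),
            class = "neuron_clusters")
}

#' Construct a cluster set from explicit memberships
#'
#' Builds a `neuron_clusters` object from a membership table and a cluster
#' type map, deriving sizes, class counts and stratum from the cell table.
#' Useful for analysing externally defined or ground-truth cluster sets with
#' the same downstream machinery as detected clusters.
#'
#' @param membership data.frame with columns `cluster_id`, `cell_id`.
#' @param types named character vector mapping each `cluster_id` to
#'   `"excitatory"` or `"inhibitory"`.
#' @param cells the [cell_table()] the memberships refer to.
#' @return A `neuron_clusters` object.
#' @export
neuron_clusters <- function(membership, types, cells) {
  df <- as.data.frame(cells)
  ids <- unique(membership$cluster_id)
  if (!all(ids %in% names(types))) stop("every cluster_id needs a type")
  if (!all(types[ids] %in% CLASS_LEVELS)) {
    stop("cluster types must be 'excitatory' or 'inhibitory'")
  }
  idx <- match(membership$cell_id, df$cell_id)
  if (anyNA(idx)) stop("membership refers to cells absent from the table")
  rows <- do.call(rbind, lapply(ids, function(id) {
    m <- idx[membership$cluster_id == id]
    data.frame(cluster_id = id, section_id = df$section_id[m[1]],
               layer = df$layer[m[1]], type = unname(types[id]),
               n_windows = NA_integer_, size = length(m),
               n_exc = sum(df$class[m] == "excitatory"),
               n_inh = sum(df$class[m] == "inhibitory"),
               stringsAsFactors = FALSE)
  }))
  mem <- membership[order(membership$cluster_id, membership$cell_id), ,
                    drop = FALSE]
  rownames(mem) <- NULL
  structure(list(clusters = rows, membership = mem),
            class = "neuron_clusters")
}

empty_clusters <- function() {
  structure(list(
    clusters = data.frame(cluster_id = character(0), section_id = character(0),
                          layer = integer(0), type = character(0),
                          n_windows = integer(0), size = integer(0),
                          n_exc = integer(0), n_inh = integer(0),
                          stringsAsFactors = FALSE),
    membership = data.frame(cluster_id = character(0), cell_id = character(0),
                            stringsAsFactors = FALSE)),
    class = "neuron_clusters")
}

#' @export
print.neuron_clusters <- function(x, ...) {
  cat(sprintf("<neuron_clusters> %d clusters (%d excitatory, %d inhibitory), %d member cells\n",
              nrow(x$clusters), sum(x$clusters$type == "excitatory"),
              sum(x$clusters$type == "inhibitory"),
              length(unique(x$membership$cell_id))))
  invisible(x)
}

combine_clusters <- function(list_of) {
  list_of <- Filter(function(cl) nrow(cl$clusters) > 0, list_of)
  if (length(list_of) == 0L) return(empty_clusters())
  structure(list(
    clusters = do.call(rbind, lapply(list_of, `[[`, "clusters")),
    membership = do.call(rbind, lapply(list_of, `[[`, "membership"))),
    class = "neuron_clusters")
}

#' Member cells of one cluster
#'
#' @param clusters a `neuron_clusters` object.
#' @param cluster_id cluster identifier.
#' @return Character vector of member `cell_id`s.
#' @export
cluster_members <- function(clusters, cluster_id) {
  clusters$membership$cell_id[clusters$membership$cluster_id == cluster_id]
}

#' Detect excitatory and inhibitory neuron clusters in a cell table
#'
#' End-to-end scan: for every stratum, enumerate sliding windows, compute
#' permutation enrichment p-values per class, and merge overlapping
#' significant windows into clusters. Strata are `(section_id, layer)` by
#' default; with `config$stratum = "layer"` the permutation pool spans all
#' sections of a layer while windows remain per-section. Child seeds are
#' derived deterministically from `config$seed` by sorted stratum key, so
#' results do not depend on input row order beyond cell identity.
#'
#' @param cells a [cell_table()].
#' @param config an [analysis_config()] or [preset()].
#' @param verbose print per-stratum window/cluster tallies.
#' @return A `neuron_clusters` object over all strata, with a `scan_log`
#'   attribute (per-stratum window and cluster counts).
#' @export
detect_clusters <- function(cells, config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (nrow(cells) == 0L) return(empty_clusters())
  cells_df <- as.data.frame(cells)
  if (config$stratum == "section_layer") {
    keys <- sort(unique(paste(cells_df$section_id, cells_df$layer, sep = "\r")))
    groups <- lapply(keys, function(k) {
      p <- strsplit(k, "\r", fixed = TRUE)[[1]]
      cells_df[cells_df$section_id == p[1] & cells_df$layer == as.integer(p[2]), ,
               drop = FALSE]
    })
  } else {
    keys <- as.character(sort(unique(cells_df$layer)))
    groups <- lapply(keys, function(k) {
      cells_df[cells_df$layer == as.integer(k), , drop = FALSE]
    })
  }
  log <- list()
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    child <- derive_seed(config$seed, gi)
    ws_list <- lapply(split(g, g$section_id), function(sec) {
      enumerate_windows(sec, config$window_size, config$step)
    })
    stats <- permutation_pvalues(g, unname(ws_list), n_perm = config$n_perm,
                                 seed = child, alpha = config$alpha,
                                 min_window_n = config$min_window_n)
    cl <- merge_significant_windows(stats, alpha = config$alpha)
    out[[gi]] <- cl
    log[[keys[gi]]] <- c(n_cells = nrow(g), n_windows = nrow(stats),
                         n_sig_exc = sum(stats$sig_exc),
                         n_sig_inh = sum(stats$sig_inh),
                         n_clusters = nrow(cl$clusters))
    if (verbose) {
      message(sprintf("stratum %s: %d cells, %d windows, %d sig E, %d sig I, %d clusters",
                      gsub("\r", "/", keys[gi]), nrow(g), nrow(stats),
                      sum(stats$sig_exc), sum(stats$sig_inh), nrow(cl$clusters)))
    }
  }
  res <- combine_clusters(out)
  attr(res, "scan_log") <- log
  res
}
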