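test_that("window enumeration honours the half-open membership rule", {
  cells <- toy_cells(x = c(50, 150), y = c(50, 150))
  ws <- enumerate_windows(cells, 100, 100)
  nonzero <- ws$windows
  expect_equal(nrow(nonzero[nonzero$n_total > 0, ]), 2L)
  expect_true(all(nonzero$n_total == 1L))
  # a wider window catches both cells at the shared origin
  ws2 <- enumerate_windows(cells, 200, 100)
  both <- ws2$windows[ws2$windows$n_total == 2, ]
  expect_true(nrow(both) >= 1L)
  expect_true(any(both$x0 == 0 & both$y0 == 0))
  expect_error(enumerate_windows(cells, 100, 150), "step")
})

test_that("every cell lies in exactly (W/step)^2 windows of the extended grid", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    cells <- toy_cells(x = runif(n, 0, 900), y = runif(n, 0, 600))
    W <- sample(c(100, 200, 300), 1)
    step <- sample(c(50, 100), 1)
    ws <- enumerate_windows(cells, W, step)
    per_cell <- Matrix::colSums(ws$incidence)
    expect_true(all(per_cell == (W / step)^2),
                info = sprintf("W=%d step=%d", W, step))
    # membership agrees with the brute-force half-open rule on a sample
    for (k in sample(nrow(ws$windows), min(5, nrow(ws$windows)))) {
      w <- ws$windows[k, ]
      inside <- cells$x >= w$x0 & cells$x < w$x0 + W &
        cells$y >= w$y0 & cells$y < w$y0 + W
      expect_setequal(window_members(ws, k), cells$cell_id[inside])
    }
  }
})

test_that("exact hypergeometric p-values match direct enumeration", {
  expect_equal(exact_pvalue(10, 5, 4, 4), 5 / 210)
  expect_equal(exact_pvalue(4, 2, 2, 2), 1 / 6)
  expect_equal(exact_pvalue(10, 5, 4, 0), 1.0)
  expect_error(exact_pvalue(10, 12, 4, 2), "inconsistent")
  expect_error(exact_pvalue(10, 5, 4, 5), "inconsistent")
})

test_that("permutation p-values converge to the hypergeometric oracle", {
  # stratum of 10 cells, 5 inhibitory; one window holds 4 inhibitory cells
  cells <- toy_cells(x = c(1, 2, 3, 4, 101, 102, 103, 104, 105, 106),
                     y = rep(1, 10),
                     class = c(rep("inhibitory", 4),
                               "inhibitory", rep("excitatory", 5)))
  ws <- enumerate_windows(cells, 50, 50)
  pv <- permutation_pvalues(cells, ws, n_perm = 20000, seed = 2)
  target <- pv[pv$n_total == 4, ]
  p_exact <- exact_pvalue(10, 5, 4, 4)
  expect_lt(abs(target$p_inh - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-4)
  # the absent class is never "enriched": observed 0 -> p = 1
  expect_equal(target$p_exc, 1.0)
})

test_that("a window containing the whole stratum is never significant", {
  cells <- toy_cells(x = runif(30, 0, 40), y = runif(30, 0, 40),
                     class = sample(c("excitatory", "inhibitory"), 30, TRUE))
  ws <- enumerate_windows(cells, 100, 100)
  full <- which(ws$windows$n_total == 30)
  expect_true(length(full) >= 1)
  pv <- permutation_pvalues(cells, ws, n_perm = 500, seed = 1)
  expect_true(all(pv$p_inh[full] == 1))
  expect_true(all(pv$p_exc[full] == 1))
})

test_that("single-class strata are degenerate with all p = 1", {
  cells <- toy_cells(x = runif(20, 0, 200), y = runif(20, 0, 200),
                     class = "excitatory")
  ws <- enumerate_windows(cells, 100, 100)
  pv <- permutation_pvalues(cells, ws, n_perm = 100, seed = 1)
  expect_true(attr(pv, "degenerate"))
  expect_true(all(pv$p_exc == 1) && all(pv$p_inh == 1))
})

test_that("no window is significant for both classes at alpha < 0.5", {
  cfg <- scene_config(2500, 2500, lambda = 600, seed = 9)
  bg <- generate_background(cfg)
  res <- plant_clusters(bg, list(planted_cluster(c(800, 800), 400,
                                                 "inhibitory", 0.7)), cfg)
  g <- as.data.frame(res$cells)
  ws <- enumerate_windows(g, 400, 200)
  pv <- permutation_pvalues(g, ws, n_perm = 300, seed = 5)
  expect_false(any(pv$sig_exc & pv$sig_inh))
})

test_that("merging unions overlapping significant windows", {
  cells <- toy_cells(x = c(10, 20, 30, 40, 50), y = rep(1, 5),
                     cell_id = as.character(1:5),
                     class = c("inhibitory", "inhibitory", "inhibitory",
                               "excitatory", "inhibitory"))
  st <- mk_window_stats(cells, list(c("1", "2"), c("2", "3"), c("5")))
  cl <- merge_significant_windows(st)
  expect_equal(nrow(cl$clusters), 2L)
  mem <- split(cl$membership$cell_id, cl$membership$cluster_id)
  expect_setequal(vapply(mem, paste, "", collapse = ","), c("1,2,3", "5"))
  # no significant windows -> no clusters
  st0 <- mk_window_stats(cells, list(c("1", "2")), sig = FALSE)
  expect_equal(nrow(merge_significant_windows(st0)$clusters), 0L)
})

test_that("merge components equal a brute-force transitive closure", {
  closure <- function(sets) {
    labels <- seq_along(sets)
    repeat {
      changed <- FALSE
      for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (labels[i] != labels[j] &&
            length(intersect(sets[[i]], sets[[j]])) > 0) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comps <- lapply(split(seq_along(sets), labels), function(ix)
      sort(unique(unlist(sets[ix]))))
    sort(vapply(comps, paste, "", collapse = ","))
  }
  set.seed(7)
  for (rep in 1:20) {
    ids <- as.character(1:12)
    cells <- toy_cells(x = seq_along(ids), y = rep(1, 12), cell_id = ids,
                       class = "inhibitory")
    n_win <- sample(2:8, 1)
    sets <- lapply(seq_len(n_win), function(i) sample(ids, sample(1:4, 1)))
    st <- mk_window_stats(cells, sets)
    cl <- merge_significant_windows(st)
    got <- sort(vapply(split(cl$membership$cell_id, cl$membership$cluster_id),
                       function(g) paste(sort(g), collapse = ","), ""))
    expect_equal(unname(got), unname(closure(sets)))
  }
})

test_that("merging is invariant to window enumeration order", {
  ids <- as.character(1:9)
  cells <- toy_cells(x = 1:9, y = rep(1, 9), cell_id = ids, class = "inhibitory")
  sets <- list(c("1", "2"), c("2", "3"), c("4", "5"), c("5", "6"), c("8"))
  base <- merge_significant_windows(mk_window_stats(cells, sets))
  perm <- merge_significant_windows(mk_window_stats(cells, sets[c(3, 5, 1, 4, 2)]))
  expect_identical(base$membership, perm$membership)
  expect_identical(base$clusters$size, perm$clusters$size)
})

test_that("detection recovers a planted pure-inhibitory disc", {
  cfg <- scene_config(3000, 3000, lambda = 600, p_inh = 0.15, seed = 31)
  bg <- generate_background(cfg)
  res <- plant_clusters(bg, list(planted_cluster(c(1500, 1500), 500,
                                                 "inhibitory", 1.0)), cfg)
  cl <- detect_clusters(res$cells, analysis_config(400, 100, n_perm = 500,
                                                   seed = 12))
  inh <- cl$clusters[cl$clusters$type == "inhibitory", ]
  expect_gte(nrow(inh), 1L)
  truth_ids <- truth_members(res$truth, 1L)
  best <- max(vapply(inh$cluster_id, function(id) {
    length(intersect(cluster_members(cl, id), truth_ids))
  }, numeric(1)))
  expect_gte(best / length(truth_ids), 0.9)
})

test_that("detection is deterministic and clusters partition per type", {
  cfg <- scene_config(2000, 2000, lambda = 500, seed = 13)
  bg <- generate_background(cfg)
  res <- plant_clusters(bg, list(planted_cluster(c(600, 600), 350,
                                                 "inhibitory", 0.8)), cfg)
  ac <- analysis_config(400, 100, n_perm = 300, seed = 99)
  a <- detect_clusters(res$cells, ac)
  b <- detect_clusters(res$cells, ac)
  expect_identical(a$membership, b$membership)
  expect_identical(a$clusters, b$clusters)
  # same-type clusters are pairwise cell-disjoint
  for (tp in unique(a$clusters$type)) {
    ids <- a$clusters$cluster_id[a$clusters$type == tp]
    mem <- a$membership[a$membership$cluster_id %in% ids, ]
    expect_false(anyDuplicated(mem$cell_id) > 0)
  }
})

test_that("an empty cell table yields an empty cluster list", {
  empty <- toy_cells(x = numeric(0), y = numeric(0))
  cl <- detect_clusters(empty, analysis_config(400, 100, n_perm = 10))
  expect_equal(nrow(cl$clusters), 0L)
  expect_equal(nrow(cl$membership), 0L)
})
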