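test_that("E-I ratio handles pure clusters as the definition requires", {
  expect_equal(ei_ratio(10, 5), 2.0)
  expect_true(is.na(ei_ratio(7, 0)))  # pure excitatory: undefined
  expect_equal(ei_ratio(0, 4), 0.0)   # pure inhibitory
  expect_equal(ei_ratio(c(10, 7, 0), c(5, 0, 4)), c(2, NA, 0))
})

test_that("jaccard and interregional flags follow their definitions", {
  expect_equal(jaccard(4, 6, 2), 0.25)
  expect_equal(jaccard(5, 5, 5), 1.0)
  expect_equal(jaccard(3, 4, 0), 0.0)
  expect_false(interregional_flag(c("V1")))
  expect_true(interregional_flag(c("V1", "V2")))
  expect_true(interregional_flag(c("V1", "V1", "V2", "V4")))
})

test_that("mean nearest-neighbour distance matches hand values and the brute-force oracle", {
  collinear <- data.frame(x = c(0, 10, 30), y = 0, section_id = "S1")
  expect_equal(mean_nn_distance(collinear), (10 + 10 + 20) / 3)
  two <- data.frame(x = c(0, 5), y = 0, section_id = "S1")
  expect_equal(mean_nn_distance(two), 5.0)
  expect_true(is.na(mean_nn_distance(two[1, ])))
  set.seed(11)
  pts <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100),
                    section_id = "S1")
  d <- as.matrix(dist(pts[, c("x", "y")]))
  diag(d) <- Inf
  expect_equal(mean_nn_distance(pts), mean(apply(d, 1, min)))
  expect_equal(nn_distances(pts$x, pts$y), unname(apply(d, 1, min)))
})

test_that("nearest-neighbour distances are computed within sections only", {
  pts <- data.frame(x = c(0, 1, 0, 1), y = 0,
                    section_id = c("S1", "S1", "S2", "S2"))
  expect_equal(mean_nn_distance(pts), 1.0) # never the 0-distance cross-section pair
})

test_that("coverage fractions and cross-section SEM match hand computation", {
  cells <- toy_cells(x = 1:8, y = rep(1, 8),
                     section_id = c(rep("S1", 4), rep("S2", 4)))
  cl <- mk_clusters(cells, list(
    A = list(type = "excitatory", ids = c("c001", "c002", "c003")),
    B = list(type = "excitatory", ids = c("c005"))))
  cov <- coverage_stats(cl, cells)
  expect_equal(cov$overall, 4 / 8)
  # per-section fractions 0.75 and 0.25 -> SEM = sd/sqrt(2) = 0.25
  expect_equal(cov$overall_sem, 0.25)
  all_in <- mk_clusters(cells, list(A = list(type = "excitatory",
                                             ids = cells$cell_id)))
  expect_equal(coverage_stats(all_in, cells)$overall, 1.0)
  none <- detect_clusters(toy_cells(numeric(0), numeric(0)),
                          analysis_config(100, 100, n_perm = 10))
  expect_equal(coverage_stats(none, cells)$overall, 0.0)
})

test_that("layer class proportions and cross-region correlations are exact", {
  # region-layer with 80 E / 20 I
  cells <- toy_cells(x = 1:100, y = rep(1, 100), region = "A",
                     class = c(rep("excitatory", 80), rep("inhibitory", 20)))
  lcp <- layer_class_proportions(cells)
  expect_equal(lcp$proportions$prop_exc, 0.8)
  expect_equal(lcp$proportions$prop_inh, 0.2)
  # perfectly proportional counts across regions -> r = 1
  nE <- c(10, 20, 30); nI <- c(1, 2, 3)
  cls <- unlist(mapply(function(e, i) c(rep("excitatory", e), rep("inhibitory", i)),
                       nE, nI))
  regs <- rep(c("A", "B", "C"), times = nE + nI)
  cells2 <- toy_cells(x = seq_along(cls), y = 1, region = regs, class = cls)
  lcp2 <- layer_class_proportions(cells2)
  expect_equal(lcp2$correlation$r, 1.0)
})

test_that("the cluster class-balance statistic is the 1-df goodness of fit", {
  res <- class_balance_test(observed = c(60, 40), expected = c(50, 50))
  expect_equal(res$statistic, 4.0)
  eq <- class_balance_test(observed = c(50, 50), expected = c(50, 50))
  expect_equal(eq$statistic, 0.0)
  expect_equal(eq$p, 1.0)
  expect_error(class_balance_test(observed = c(10, 0), expected = c(10, 0)),
               "zero")
})

test_that("partner detection matches a brute-force intersection oracle", {
  cells <- toy_cells(x = 1:6, y = 1, cell_id = as.character(1:6),
                     class = c("excitatory", "excitatory", "inhibitory",
                               "inhibitory", "excitatory", "inhibitory"))
  cl <- mk_clusters(cells, list(
    E1 = list(type = "excitatory", ids = c("1", "2", "3")),
    I1 = list(type = "inhibitory", ids = c("3", "4"))))
  pr <- find_partners(cl)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$shared, 1L)
  expect_equal(pr$pairs$jaccard, 1 / 4)
  # disjoint memberships -> no pair
  cl2 <- mk_clusters(cells, list(
    E1 = list(type = "excitatory", ids = c("1", "2")),
    I1 = list(type = "inhibitory", ids = c("4", "6"))))
  expect_equal(nrow(find_partners(cl2)$pairs), 0L)

  # randomised oracle over small cluster sets
  set.seed(5)
  for (rep in 1:10) {
    ids <- sprintf("c%03d", 1:40)
    cells_r <- toy_cells(x = 1:40, y = 1, class = "excitatory")
    ne <- sample(2:6, 1); ni <- sample(2:6, 1)
    spec <- c(
      setNames(lapply(seq_len(ne), function(i)
        list(type = "excitatory", ids = sample(ids, sample(2:8, 1)))),
        paste0("E", seq_len(ne))),
      setNames(lapply(seq_len(ni), function(i)
        list(type = "inhibitory", ids = sample(ids, sample(2:8, 1)))),
        paste0("I", seq_len(ni))))
    cl_r <- mk_clusters(cells_r, spec)
    pr_r <- find_partners(cl_r)
    brute <- list()
    for (e in paste0("E", seq_len(ne))) for (i in paste0("I", seq_len(ni))) {
      sh <- length(intersect(spec[[e]]$ids, spec[[i]]$ids))
      if (sh > 0) brute[[paste(e, i)]] <- sh
    }
    expect_equal(nrow(pr_r$pairs), length(brute))
    if (length(brute) > 0) {
      got <- setNames(as.integer(pr_r$pairs$shared),
                      paste(pr_r$pairs$exc_cluster_id, pr_r$pairs$inh_cluster_id))
      expect_equal(got[sort(names(got))],
                   unlist(brute)[sort(names(brute))])
    }
  }
})

test_that("pair overlap metrics obey their bounds", {
  set.seed(9)
  cells <- toy_cells(x = 1:30, y = 1, class = "excitatory")
  spec <- list(
    E1 = list(type = "excitatory", ids = sprintf("c%03d", 1:12)),
    E2 = list(type = "excitatory", ids = sprintf("c%03d", 13:20)),
    I1 = list(type = "inhibitory", ids = sprintf("c%03d", 10:16)),
    I2 = list(type = "inhibitory", ids = sprintf("c%03d", 20:24)))
  pr <- find_partners(mk_clusters(cells, spec))
  expect_true(all(pr$pairs$shared <= pmin(pr$pairs$size_exc, pr$pairs$size_inh)))
  expect_true(all(pr$pairs$jaccard <= pmin(pr$pairs$frac_exc, pr$pairs$frac_inh) + 1e-12))
  expect_true(all(pr$pairs$jaccard > 0 & pr$pairs$jaccard <= 1))
})

test_that("nearest opposite cluster matches the brute-force pair minimum", {
  cells <- toy_cells(x = c(0, 0, 100, 200), y = 0,
                     cell_id = c("a", "b", "c", "d"),
                     class = c("excitatory", "inhibitory", "inhibitory",
                               "inhibitory"))
  cl <- mk_clusters(cells, list(
    E1 = list(type = "excitatory", ids = c("a", "b")),
    I1 = list(type = "inhibitory", ids = c("b")),      # shares b -> distance 0
    I2 = list(type = "inhibitory", ids = c("c", "d"))))
  no <- nearest_opposite_cluster(cl, cells)
  expect_equal(no$distance[no$cluster_id == "E1"], 0)
  expect_equal(no$nearest_id[no$cluster_id == "E1"], "I1")
  # two singletons 100 um apart
  cells2 <- toy_cells(x = c(0, 100), y = 0, cell_id = c("a", "b"),
                      class = c("excitatory", "inhibitory"))
  cl2 <- mk_clusters(cells2, list(E1 = list(type = "excitatory", ids = "a"),
                                  I1 = list(type = "inhibitory", ids = "b")))
  no2 <- nearest_opposite_cluster(cl2, cells2)
  expect_equal(no2$distance, c(100, 100))
  # randomised oracle
  set.seed(3)
  cells3 <- toy_cells(x = runif(30, 0, 500), y = runif(30, 0, 500),
                      class = "excitatory")
  spec <- list(E1 = list(type = "excitatory", ids = cells3$cell_id[1:10]),
               I1 = list(type = "inhibitory", ids = cells3$cell_id[11:20]),
               I2 = list(type = "inhibitory", ids = cells3$cell_id[21:30]))
  cl3 <- mk_clusters(cells3, spec)
  no3 <- nearest_opposite_cluster(cl3, cells3)
  d_brute <- function(a, b) {
    min(sqrt(outer(cells3$x[match(a, cells3$cell_id)],
                   cells3$x[match(b, cells3$cell_id)], "-")^2 +
             outer(cells3$y[match(a, cells3$cell_id)],
                   cells3$y[match(b, cells3$cell_id)], "-")^2))
  }
  d1 <- d_brute(spec$E1$ids, spec$I1$ids)
  d2 <- d_brute(spec$E1$ids, spec$I2$ids)
  row <- no3[no3$cluster_id == "E1", ]
  expect_equal(row$distance, min(d1, d2))
  expect_equal(row$nearest_id, if (d1 <= d2) "I1" else "I2")
})

test_that("coupling correlations behave at the extremes and under sampling", {
  # identical ratios on both sides of each pair -> r = 1
  cells <- toy_cells(x = 1:40, y = 1, class = rep(c("excitatory", "inhibitory"), 20))
  ids <- cells$cell_id
  spec <- list()
  for (k in 1:5) {
    spec[[paste0("E", k)]] <- list(type = "excitatory",
                                   ids = ids[(8 * k - 7):(8 * k - 4)])
    spec[[paste0("I", k)]] <- list(type = "inhibitory",
                                   ids = ids[(8 * k - 4):(8 * k)])
  }
  cl <- mk_clusters(cells, spec)
  sm <- cluster_summaries(cl, cells)
  # overwrite ratios so both sides of each partner pair agree exactly
  sm$ei_ratio[match(paste0("E", 1:5), sm$cluster_id)] <- 1:5
  sm$ei_ratio[match(paste0("I", 1:5), sm$cluster_id)] <- 1:5
  pr <- find_partners(cl)
  cs <- coupling_stats(sm, pr)
  expect_equal(cs$partner_ratio$r, 1.0)
  # fewer than 3 valid pairs -> undefined
  sm2 <- sm
  sm2$ei_ratio[match(c("E1", "E2", "E3"), sm2$cluster_id)] <- NA
  cs2 <- coupling_stats(sm2, pr)
  expect_true(is.na(cs2$partner_ratio$r))
})

test_that("interregional odds ratios match the hand-computed 2x2 values", {
  sm <- data.frame(
    cluster_id = sprintf("c%03d", 1:200),
    type = "excitatory",
    layer = rep(c(1L, 2L), each = 100),
    interregional = c(rep(TRUE, 10), rep(FALSE, 90),
                      rep(TRUE, 5), rep(FALSE, 95)))
  or <- interregional_enrichment(sm)
  l1 <- or[or$layer == 1, ]
  expect_equal(l1$odds_ratio, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_false(l1$corrected)
  expect_true(l1$ci_lo < l1$odds_ratio && l1$odds_ratio < l1$ci_hi)
  # identical fractions across layers -> OR = 1
  sm$interregional <- rep(c(rep(TRUE, 10), rep(FALSE, 90)), 2)
  or2 <- interregional_enrichment(sm)
  expect_equal(or2$odds_ratio, c(1, 1))
  # a zero cell triggers the Haldane-Anscombe correction
  sm$interregional <- c(rep(FALSE, 100), rep(TRUE, 5), rep(FALSE, 95))
  or3 <- interregional_enrichment(sm)
  expect_true(or3$corrected[or3$layer == 1])
})

test_that("cluster summaries assign regions by plurality with lexical ties", {
  cells <- toy_cells(x = 1:5, y = 1, region = c("V2", "V1", "V1", "V2", "V4"),
                     class = c("excitatory", "excitatory", "inhibitory",
                               "excitatory", "excitatory"))
  cl <- mk_clusters(cells, list(
    A = list(type = "excitatory", ids = cells$cell_id[1:4]),   # V1 x2, V2 x2 tie
    B = list(type = "excitatory", ids = cells$cell_id[5])))
  sm <- cluster_summaries(cl, cells)
  expect_equal(sm$assigned_region[sm$cluster_id == "A"], "V1") # lexicographic tie-break
  expect_true(sm$interregional[sm$cluster_id == "A"])
  expect_false(sm$interregional[sm$cluster_id == "B"])
  expect_equal(sm$ei_ratio[sm$cluster_id == "A"], 3.0)
  expect_true(is.na(sm$ei_ratio[sm$cluster_id == "B"]))
  expect_true(sm$pure[sm$cluster_id == "B"])
})
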