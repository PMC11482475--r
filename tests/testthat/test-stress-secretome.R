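test_that("GSH/GSSG fold change follows its definition", {
  expect_equal(gsh_gssg_fc(100, 25, 100, 25), 1)
  expect_equal(gsh_gssg_fc(50, 50, 100, 25), 0.25)  # GSH halved, GSSG doubled
  expect_equal(gsh_gssg_fc(80, 40, 100, 25), 0.5)
  expect_error(gsh_gssg_fc(-1, 1, 1, 1), "> 0")
  expect_error(gsh_gssg_fc(1, 0, 1, 1), "> 0")
})

test_that("stress_analysis recovers suppression factors and flags control", {
  stress <- simulate_stress(c(NP1 = 0.5, NP2 = 0.25), noise_sigma = 0,
                            seed = 2)
  # noise-free groups give a perfect ANOVA fit; the R warning is expected
  res <- suppressWarnings(stress_analysis(stress))
  s <- res$summary
  expect_equal(s$ratio_fc[s$treatment == "control"], 1)
  expect_equal(s$ratio_fc[s$treatment == "NP1"], 0.5)
  expect_equal(s$ratio_fc[s$treatment == "NP2"], 0.25)
  expect_error(stress_analysis(stress, control = "missing"), "control")
})

test_that("protein fold change matches by name and validates", {
  expect_equal(protein_fold_change(c(IL6 = 25), c(IL6 = 10)),
               c(IL6 = 2.5))
  out <- protein_fold_change(c(a = 5, b = 60), c(a = 10, b = 20))
  expect_equal(unname(out), c(0.5, 3.0))
  t0 <- c(a = 1); c0 <- c(a = 1)
  expect_equal(unname(protein_fold_change(t0, c0)), 1)
  expect_error(protein_fold_change(c(a = 1), c(b = 1)), "match")
  expect_error(protein_fold_change(c(a = 1), c(a = 0)), "> 0")
})

test_that("responder filtering is two-sided, boundary-inclusive and monotone", {
  m <- rbind(up = c(t1 = 1.5, t2 = 1.0),
             weak = c(t1 = 1.49, t2 = 1.0),
             down = c(t1 = 0.60, t2 = 1.0),
             flat = c(t1 = 1.0, t2 = 1.0))
  kept <- rownames(filter_responders(m, 1.5))
  expect_equal(kept, c("up", "down"))

  # monotone in the cutoff: a stricter cutoff keeps a subset
  set.seed(4)
  big <- matrix(2^rnorm(60, 0, 0.7), 20, 3,
                dimnames = list(paste0("p", 1:20), paste0("t", 1:3)))
  for (cuts in list(c(1.2, 1.5), c(1.5, 2), c(1.1, 3))) {
    loose <- rownames(filter_responders(big, cuts[1]))
    strict <- rownames(filter_responders(big, cuts[2]))
    expect_true(all(strict %in% loose))
  }
  expect_error(filter_responders(m, 1), "> 1")
  expect_error(filter_responders(m * -1, 1.5), "positive")
})

test_that("identical and perfectly correlated rows merge first at height 0", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
  colnames(m) <- paste0("t", 1:3)
  cl <- hierarchical_cluster(m)
  expect_equal(cl$row_hclust$height[1], 0)
  expect_equal(sort(cl$row_hclust$merge[1, ]), c(-2, -1))

  # pearson distance: log-scale proportional rows are distance 0
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 4, 9), c = c(3, 2, 1))
  colnames(m2) <- paste0("t", 1:3)
  cl2 <- hierarchical_cluster(m2)
  expect_equal(cl2$row_hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(cl2$row_hclust$merge[1, ]), c(-2, -1))
})

test_that("pearson clustering is invariant to per-row scaling of the log2 matrix", {
  set.seed(23)
  m <- matrix(2^rnorm(40), 8, 5,
              dimnames = list(paste0("p", 1:8), paste0("t", 1:5)))
  cl1 <- hierarchical_cluster(m)
  # positive per-row power on the ratio scale = per-row scaling in log2
  m2 <- m^rep(runif(8, 0.5, 2), 5)
  cl2 <- hierarchical_cluster(m2)
  expect_equal(cl1$row_order, cl2$row_order)
  expect_equal(cl1$row_hclust$merge, cl2$row_hclust$merge)
})

test_that("merge heights are nondecreasing and leaf orders are permutations", {
  set.seed(19)
  for (linkage in c("average", "complete")) {
    m <- matrix(2^rnorm(60), 10, 6,
                dimnames = list(paste0("p", 1:10), paste0("t", 1:6)))
    cl <- hierarchical_cluster(m, linkage = linkage)
    expect_true(all(diff(cl$row_hclust$height) >= -1e-12))
    expect_true(all(diff(cl$col_hclust$height) >= -1e-12))
    expect_setequal(cl$row_order, rownames(m))
    expect_setequal(cl$col_order, colnames(m))
  }
})

test_that("constant rows under pearson distance error with the row name", {
  m <- rbind(flat = c(2, 2, 2), var = c(1, 2, 3))
  colnames(m) <- paste0("t", 1:3)
  expect_error(hierarchical_cluster(m), "flat")
  expect_silent(hierarchical_cluster(m, distance = "euclidean"))
})

test_that("merge_table flattens the agglomeration sequence", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3.01), c = c(9, 1, 4))
  colnames(m) <- paste0("t", 1:3)
  cl <- hierarchical_cluster(m, distance = "euclidean")
  mt <- merge_table(cl$row_hclust)
  expect_equal(mt$step, 1:2)
  expect_equal(mt$members[2], "a+b+c")
  expect_equal(mt$height, cl$row_hclust$height)
})
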