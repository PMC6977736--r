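test_that("linkage_distance matches the closed-form examples", {
  # two singletons: every linkage reduces to the point distance
  for (lk in c("single", "complete", "ward")) {
    expect_equal(linkage_distance(matrix(0), matrix(3), lk), 3.0)
  }
  A <- rbind(c(0, 0), c(0, 2))
  B <- rbind(c(5, 0), c(5, 2))
  # enumerate all 4 pairs, max L1 = |5-0| + |2-0|
  expect_equal(linkage_distance(A, B, "complete", "manhattan"), 7.0)
  expect_equal(linkage_distance(A, B, "single", "manhattan"), 5.0)
  # ward: centroid distance 5, prefactor sqrt(2*2*2/4)
  expect_equal(linkage_distance(A, B, "ward"), sqrt(2) * 5)
  # the no-square-root reading of the prefactor
  expect_equal(linkage_distance(A, B, "ward", ward_sqrt = FALSE), 2 * 5)
})

test_that("linkage_distance rejects invalid input", {
  expect_error(linkage_distance(matrix(0), matrix(c(1, 2), 1), "single"),
               "dimensionality")
  expect_error(linkage_distance(matrix(numeric(0), 0, 1), matrix(1), "single"),
               "non-empty")
  expect_error(linkage_distance(matrix(0), matrix(3), "ward", "manhattan"),
               "Euclidean")
  expect_error(build_hierarchy(matrix(rnorm(10), 5), "ward", "manhattan"),
               "Euclidean")
})

test_that("forced merge sequences come out in construction order", {
  # distances 1 < 9 < 10 force (1,2) then ({1,2},3)
  h <- build_hierarchy(matrix(c(0, 1, 10), ncol = 1), "single")
  expect_equal(h$merges$a, c(1L, 3L))
  expect_equal(h$merges$b, c(2L, 4L))
  expect_equal(h$merges$node, c(4L, 5L))
  expect_equal(h$merges$height, c(1, 9))
})

test_that("duplicate points merge at height zero", {
  h <- build_hierarchy(rbind(c(1, 2), c(1, 2)), "complete")
  expect_equal(nrow(h$merges), 1L)
  expect_equal(h$merges$a, 1L)
  expect_equal(h$merges$b, 2L)
  expect_equal(h$merges$height, 0)
})

test_that("degenerate input is rejected", {
  expect_error(build_hierarchy(matrix(1, 1, 1)), "at least 2")
  expect_error(build_hierarchy(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("merge sequences equal the brute-force agglomeration oracle", {
  set.seed(42)
  for (rep in 1:30) {
    M <- sample(2:12, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(M * d), M, d)
    for (g in seq_len(nrow(linkage_metric_grid))) {
      lk <- linkage_metric_grid$linkage[g]
      mt <- linkage_metric_grid$metric[g]
      got <- build_hierarchy(X, lk, mt)$merges
      want <- oracle_hierarchy(X, lk, mt)
      expect_equal(got$a, want$a, info = sprintf("rep %d %s/%s", rep, lk, mt))
      expect_equal(got$b, want$b, info = sprintf("rep %d %s/%s", rep, lk, mt))
      expect_equal(got$node, want$node)
      expect_equal(got$height, want$height, tolerance = 1e-10)
    }
  }
})

test_that("hierarchies are invariant under translation and positive scaling", {
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    g <- sample(nrow(linkage_metric_grid), 1)
    lk <- linkage_metric_grid$linkage[g]
    mt <- linkage_metric_grid$metric[g]
    base <- build_hierarchy(X, lk, mt)$merges
    shifted <- build_hierarchy(X + 17.3, lk, mt)$merges
    scaled <- build_hierarchy(X * 4.2, lk, mt)$merges
    expect_equal(base[c("a", "b", "node")], shifted[c("a", "b", "node")])
    expect_equal(base[c("a", "b", "node")], scaled[c("a", "b", "node")])
    # heights scale linearly with the data for all three linkages
    expect_equal(scaled$height, base$height * 4.2, tolerance = 1e-12)
  }
})

test_that("child indices satisfy the structural bounds", {
  set.seed(11)
  for (rep in 1:10) {
    M <- sample(3:40, 1)
    h <- build_hierarchy(matrix(rnorm(M * 2), M, 2),
                         sample(c("single", "complete", "ward"), 1))
    m <- h$merges
    expect_true(all(m$a >= 1 & m$a < m$b & m$b < 2 * M - 1))
    expect_equal(m$node, M + seq_len(M - 1))
    expect_equal(m$node[nrow(m)], 2L * M - 1L)
    # every node except the root appears exactly once as a child
    children <- c(m$a, m$b)
    expect_equal(sort(children), seq_len(2L * M - 2L))
    # agglomeration heights are non-decreasing for these linkages
    expect_true(all(diff(m$height) >= -1e-12))
  }
})

test_that("hierarchies serialize to TSV and Newick", {
  h <- build_hierarchy(matrix(rnorm(12), 6, 2), "ward")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hierarchy(h, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$a, h$merges$a)
  expect_equal(back$height, h$merges$height, tolerance = 1e-12)
  nwk <- as_newick(h)
  tree <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tree), 6L)
})

test_that("read_points handles delimiters, headers and label columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,grp", "1,2,1", "3,4,2"), p)
  m <- read_points(p, label_col = "grp")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(attr(m, "labels"), c(1L, 2L))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "3\t4"), p2)
  expect_equal(unname(read_points(p2)), matrix(c(1, 3, 2, 4), 2))
  expect_error(read_points(file.path(tempdir(), "nope.csv")), "not found")
})
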