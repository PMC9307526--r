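test_that("degree centrality counts in- plus out-connections", {
  empty <- as_network(matrix(0L, 4, 4))
  expect_true(all(degree_centrality(empty) == 0))
  complete <- as_network(1L - diag(4L))
  expect_true(all(degree_centrality(complete) == 6))
  A <- matrix(0L, 4, 4); A[2, 1] <- 1L      # edge n01 -> n02
  nw <- as_network(A)
  dc <- degree_centrality(nw)
  expect_equal(unname(dc), c(1, 1, 0, 0))
  expect_equal(unname(degree_centrality(nw, "out")), c(1, 0, 0, 0))
  expect_equal(unname(degree_centrality(nw, "in")), c(0, 1, 0, 0))
})

test_that("betweenness matches elementary path configurations", {
  A <- matrix(0L, 3, 3)
  A[2, 1] <- 1L; A[3, 2] <- 1L              # a -> b -> c
  bc <- betweenness_centrality(as_network(A))
  expect_equal(unname(bc), c(0, 1, 0))
  complete <- as_network(1L - diag(4L))
  expect_true(all(betweenness_centrality(complete) == 0))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    A <- random_digraph(n, p = runif(1, 0.15, 0.5))
    bc <- betweenness_centrality(as_network(A))
    expect_equal(unname(bc), brute_betweenness(A), tolerance = 1e-10)
  }
})

test_that("degree sums equal the edge count in both directions", {
  set.seed(42)
  for (i in 1:10) {
    A <- random_digraph(6, 0.4)
    nw <- as_network(A)
    expect_equal(sum(degree_centrality(nw, "in")), sum(A))
    expect_equal(sum(degree_centrality(nw, "out")), sum(A))
    expect_equal(sum(degree_centrality(nw)), 2 * sum(A))
  }
})

test_that("group summaries compute mean and sample SD per group", {
  vals <- c(a = 4, b = 6, c = 2, d = 2, e = 2)
  groups <- c(a = "SOZ", b = "SOZ", c = "PSZ", d = "NSZ", e = "NSZ")
  gs <- group_summary(vals, groups)
  expect_equal(gs$mean[gs$group == "SOZ"], 5)
  expect_equal(gs$sd[gs$group == "SOZ"], sqrt(2))
  expect_equal(gs$sd[gs$group == "PSZ"], 0)
  perm <- sample(names(vals))
  gs2 <- group_summary(vals[perm], groups[perm])
  expect_equal(gs, gs2)
  expect_error(group_summary(vals[1:2], groups[1:2]), "empty group")
})

test_that("intragroup fractions match direct edge labeling", {
  groups <- c(n01 = "SOZ", n02 = "SOZ", n03 = "PSZ", n04 = "NSZ",
              n05 = "NSZ")
  # all edges inside SOZ
  A <- matrix(0L, 5, 5); A[1, 2] <- A[2, 1] <- 1L
  expect_equal(intragroup_fraction(as_network(A), groups)$mean[1], 100)
  # bipartite SOZ -> NSZ only
  B <- matrix(0L, 5, 5); B[4, 1] <- B[5, 2] <- 1L
  ifr <- intragroup_fraction(as_network(B), groups)
  expect_equal(ifr$mean[ifr$group == "SOZ"], 0)
  # random graphs vs brute-force per-node labeling
  set.seed(43)
  for (i in 1:10) {
    A <- random_digraph(5, 0.4)
    nw <- as_network(A)
    got <- intragroup_fraction(nw, groups)
    for (g in c("SOZ", "PSZ", "NSZ")) {
      props <- c()
      for (v in which(groups == g)) {
        inc <- c(which(A[v, ] == 1), which(A[, v] == 1))  # sources in, targets out
        if (!length(inc)) next
        props <- c(props, 100 * mean(groups[inc] == g))
      }
      expected <- if (length(props)) mean(props) else NA_real_
      expect_equal(got$mean[got$group == g], expected)
    }
  }
})

test_that("incoming/outgoing fractions are complementary and correct", {
  groups <- c(n01 = "SOZ", n02 = "PSZ", n03 = "NSZ", n04 = "NSZ")
  # star: all edges out of n01
  A <- matrix(0L, 4, 4); A[2:4, 1] <- 1L
  io <- inout_fractions(as_network(A), groups)
  expect_equal(io$outgoing_mean[io$group == "SOZ"], 100)
  expect_equal(io$incoming_mean[io$group == "SOZ"], 0)
  # 2-cycle
  B <- matrix(0L, 4, 4); B[1, 2] <- B[2, 1] <- 1L
  io2 <- inout_fractions(as_network(B), groups)
  expect_equal(io2$outgoing_mean[io2$group == "SOZ"], 50)
  expect_equal(io2$incoming_mean[io2$group == "PSZ"], 50)
  set.seed(44)
  for (i in 1:5) {
    C <- random_digraph(4, 0.5)
    ioc <- inout_fractions(as_network(C), groups)
    ok <- !is.na(ioc$outgoing_mean)
    expect_equal(ioc$outgoing_mean[ok] + ioc$incoming_mean[ok],
                 rep(100, sum(ok)))
  }
})

test_that("relabeling SOZ and NSZ swaps their summaries", {
  set.seed(45)
  A <- random_digraph(6, 0.4)
  g1 <- c(n01 = "SOZ", n02 = "SOZ", n03 = "PSZ", n04 = "PSZ",
          n05 = "NSZ", n06 = "NSZ")
  g2 <- c(n01 = "NSZ", n02 = "NSZ", n03 = "PSZ", n04 = "PSZ",
          n05 = "SOZ", n06 = "SOZ")
  nw <- as_network(A)
  dc <- degree_centrality(nw)
  s1 <- group_summary(dc, g1); s2 <- group_summary(dc, g2)
  expect_equal(s1[s1$group == "SOZ", -1], s2[s2$group == "NSZ", -1],
               ignore_attr = TRUE)
  expect_equal(s1[s1$group == "NSZ", -1], s2[s2$group == "SOZ", -1],
               ignore_attr = TRUE)
})

test_that("centrality time series carries one row per epoch and group", {
  set.seed(46)
  groups <- c(n01 = "SOZ", n02 = "SOZ", n03 = "PSZ", n04 = "NSZ")
  nets <- lapply(1:3, function(i) {
    nw <- as_network(random_digraph(4, 0.5), groups)
    nw$epoch_index <- i
    nw
  })
  ct <- centrality_timeseries(nets, groups)
  expect_equal(nrow(ct), 9)
  expect_setequal(unique(ct$group), c("SOZ", "PSZ", "NSZ"))
  expect_true(all(c("dc_mean", "bc_mean", "intragroup_pct",
                    "outgoing_pct") %in% names(ct)))
})
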