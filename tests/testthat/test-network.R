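fake_model <- function(target, inputs, B, accepted = TRUE) {
  structure(list(target_channel = target, input_channels = inputs,
                 B = B, m = nrow(B),
                 diagnostics = list(accepted = accepted)),
            class = "miso_model")
}

test_that("connectivity assembly places gains at (target, source)", {
  m1 <- fake_model("a", c("b"), cbind(b = c(3, 4)))
  m2 <- fake_model("b", c("a"), cbind(a = c(0, 2)))
  cm <- assemble_connectivity(list(m1, m2), epoch_index = 7)
  expect_equal(unname(cm$values), rbind(c(0, 5), c(2, 0)))
  expect_equal(cm$epoch_index, 7)
  # asymmetry preserved
  expect_false(cm$values["a", "b"] == cm$values["b", "a"])
  expect_error(assemble_connectivity(list(m1, m1)), "duplicate")
})

test_that("rejected models give zero rows and mask bits", {
  m1 <- fake_model("a", "b", cbind(b = 1), accepted = FALSE)
  m2 <- fake_model("b", "a", cbind(a = 1), accepted = FALSE)
  cm <- assemble_connectivity(list(m1, m2))
  expect_true(all(cm$values == 0))
  expect_true(all(cm$rejection_mask))
})

test_that("pooled threshold is the linear-interpolation percentile", {
  # pool of exactly {1..100}: rows 1..10 of an 11-channel matrix carry the
  # values, row 11 is masked (its entries must not enter the pool)
  V <- matrix(0, 11, 11)
  off <- which(row(V) != col(V) & row(V) <= 10, arr.ind = FALSE)
  V[off] <- sample(1:100)
  V[11, 1:10] <- 1e6                       # masked row, would distort
  cm <- as_connectivity(V, mask = c(rep(FALSE, 10), TRUE))
  expect_equal(pooled_threshold(cm), 95.05)
  # degenerate constant pool: threshold c, strict pruning retains nothing
  Vc <- matrix(5, 3, 3); diag(Vc) <- 0
  cc <- as_connectivity(Vc)
  expect_equal(pooled_threshold(cc), 5)
  expect_equal(sum(prune(cc, pooled_threshold(cc))$adjacency), 0)
})

test_that("uniform pools give thresholds near 0.95", {
  hits <- vapply(1:50, function(s) {
    set.seed(400 + s)
    V <- matrix(runif(32 * 32), 32); diag(V) <- 0
    th <- pooled_threshold(as_connectivity(V))
    th > 0.90 && th < 1.00
  }, NA)
  expect_gte(mean(hits), 0.99)
})

test_that("masked rows are excluded from the threshold pool", {
  V <- rbind(c(0, 100, 100), c(1, 0, 1), c(1, 1, 0))
  cm <- as_connectivity(V, mask = c(TRUE, FALSE, FALSE))
  expect_lt(pooled_threshold(cm), 2)
  expect_error(pooled_threshold(as_connectivity(matrix(0, 2, 2),
                                                mask = c(TRUE, TRUE))),
               "empty pool")
})

test_that("pruning keeps strictly-above entries only", {
  V <- matrix(runif(16), 4); diag(V) <- 0
  cm <- as_connectivity(V)
  expect_equal(sum(prune(cm, max(V))$adjacency), 0)
  all_in <- prune(cm, -1)
  expect_equal(sum(all_in$adjacency), 12)
  th <- median(V[row(V) != col(V)])
  pr <- prune(cm, th)
  expect_equal(unname(pr$adjacency),
               unname((V > th & row(V) != col(V)) * 1L))
})

test_that("monotonicity and scale equivariance hold", {
  set.seed(31)
  for (i in 1:10) {
    V <- matrix(rexp(100), 10); diag(V) <- 0
    cm <- as_connectivity(V)
    t1 <- pooled_threshold(cm, 90); t2 <- pooled_threshold(cm, 97)
    a1 <- prune(cm, t1)$adjacency; a2 <- prune(cm, t2)$adjacency
    expect_true(all(a2 <= a1))                 # raising threshold removes only
    c_ <- runif(1, 0.5, 4)
    cms <- as_connectivity(c_ * V)
    expect_equal(pooled_threshold(cms, 90), c_ * t1)
    expect_identical(prune(cms, c_ * t1)$adjacency, a1)
  }
})

test_that("top-fraction network equals a full-sort oracle", {
  set.seed(32)
  V <- matrix(runif(100), 10); diag(V) <- 0
  cm <- as_connectivity(V)
  k <- ceiling(0.1 * 90)
  top <- top_fraction_network(cm, 0.1)
  off <- V[row(V) != col(V)]
  cutoff <- sort(off, decreasing = TRUE)[k]
  expect_equal(sum(top$adjacency), k)
  expect_true(all(V[top$adjacency == 1] >= cutoff))
  expect_equal(sum(top_fraction_network(cm, 0.01)$adjacency), 1)  # ceil(0.9)
  expect_equal(unname(top_fraction_network(cm, 1)$adjacency),
               unname(prune(cm, -Inf)$adjacency))
})

test_that("empty graphs yield empty edge lists without error", {
  V <- matrix(0, 3, 3)
  nw <- prune(as_connectivity(V), 0.5)
  el <- edge_list(nw)
  expect_equal(nrow(el), 0)
  p <- file.path(tempdir(), "empty_edges.tsv")
  write_edge_lists(list(nw, nw), p)
  expect_true(file.exists(p))
})

test_that("edge lists preserve direction through a write/read round trip", {
  V <- rbind(c(0, 0.9, 0), c(0, 0, 0), c(0.8, 0, 0))
  cm <- as_connectivity(V)
  nw <- prune(cm, 0.5)
  el <- edge_list(nw)
  # entry (1,2): source n02 -> target n01; entry (3,1): n01 -> n03
  expect_setequal(paste(el$source, el$target),
                  c("n02 n01", "n01 n03"))
  p <- file.path(tempdir(), "edges.tsv")
  write_edge_lists(list(nw), p)
  back <- read.delim(p)
  expect_setequal(paste(back$source, back$target), paste(el$source, el$target))
})
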