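test_that("phase networks follow the planted sparsity pattern", {
  cfg <- scenario_config(seed = 2)
  gt <- build_phase_networks(cfg)
  soz <- cfg$group_assignment == "SOZ"
  W1 <- gt$phase_adjacency$interictal
  W2 <- gt$phase_adjacency$soz_delta
  W3 <- gt$phase_adjacency$recruit
  expect_true(all(diag(W1) == 0 & diag(W2) == 0 & diag(W3) == 0))
  # SOZ-delta phase differs from baseline only on SOZ->SOZ entries
  diff12 <- which(W2 != W1, arr.ind = TRUE)
  expect_true(all(soz[diff12[, 1]] & soz[diff12[, 2]]))
  # recruitment phase additionally differs only on SOZ -> non-SOZ entries
  diff23 <- which(W3 != W2, arr.ind = TRUE)
  expect_true(all(!soz[diff23[, 1]] & soz[diff23[, 2]]))
})

test_that("unit gains leave all three phases identical", {
  cfg <- scenario_config(soz_gain = 1, recruit_gain = 1, seed = 3)
  gt <- build_phase_networks(cfg)
  expect_identical(gt$phase_adjacency$interictal, gt$phase_adjacency$soz_delta)
  expect_identical(gt$phase_adjacency$soz_delta, gt$phase_adjacency$recruit)
})

test_that("zero baseline coupling gives an all-zero background", {
  cfg <- scenario_config(baseline_coupling = 0, n_backbone = 0, seed = 1)
  gt <- build_phase_networks(cfg)
  expect_true(all(gt$phase_adjacency$interictal == 0))
})

test_that("the SOZ step alters exactly |SOZ|*(|SOZ|-1) entries", {
  grp <- stats::setNames(c(rep("SOZ", 3), rep("PSZ", 3), rep("NSZ", 4)),
                         sprintf("c%02d", 1:10))
  cfg <- scenario_config(n_channels = 10, group_assignment = grp,
                         soz_gain = 3, recruit_gain = 1, n_backbone = 0,
                         seed = 1)
  gt <- build_phase_networks(cfg)
  altered <- sum(gt$phase_adjacency$soz_delta != gt$phase_adjacency$interictal)
  expect_identical(altered, 3L * 2L)
})

test_that("planted edges exactly match nonzero off-diagonal entries", {
  gt <- build_phase_networks(scenario_config(seed = 6))
  for (ph in names(gt$phase_adjacency)) {
    W <- gt$phase_adjacency[[ph]]
    idx <- which(W != 0 & row(W) != col(W))
    e <- gt$planted_edges[[ph]]
    expect_identical(nrow(e), length(idx))
    rebuilt <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
    rebuilt[cbind(e$target, e$source)] <- e$weight
    expect_identical(rebuilt, {D <- W; D[row(W) == col(W)] <- 0; D})
  }
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- scenario_config(duration = 20, t_soz_delta = 10, t_recruit = 4,
                         seed = 11)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
})

test_that("uncoupled white channels are mutually independent", {
  cfg <- scenario_config(duration = 60, t_soz_delta = 30, t_recruit = 10,
                         baseline_coupling = 0, n_backbone = 0,
                         soz_gain = 1, recruit_gain = 1,
                         pink_noise_fraction = 0, seed = 8)
  sim <- simulate_recording(cfg)
  C <- cor(t(sim$recording$samples))
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
})

test_that("a strongly coupled pair shows dominant lagged cross-correlation", {
  sim <- simulate_static_var(n_channels = 6, n_edges = 1, coupling = 0.6,
                             duration = 20, seed = 9)
  e <- sim$edges
  Y <- sim$recording$samples
  lag1 <- function(src, tgt) {
    x <- Y[src, ]; y <- Y[tgt, ]
    abs(cor(x[-length(x)], y[-1]))       # influence src(t-1) -> tgt(t)
  }
  planted <- lag1(match(e$source, rownames(Y)), match(e$target, rownames(Y)))
  others <- c()
  for (s in 1:6) for (t in 1:6) {
    if (s == t) next
    if (rownames(Y)[s] == e$source && rownames(Y)[t] == e$target) next
    others <- c(others, lag1(s, t))
  }
  expect_gt(planted, max(others))
})

test_that("each phase is variance-stationary (halves within 3x)", {
  cfg <- scenario_config(duration = 140, seed = 12)
  sim <- simulate_recording(cfg)
  x <- sim$recording$samples
  fs <- cfg$fs
  # interictal phase spans the first 100 s
  seg <- x[, 1:(100 * fs)]
  half <- ncol(seg) %/% 2
  v1 <- apply(seg[, 1:half], 1, var)
  v2 <- apply(seg[, (half + 1):(2 * half)], 1, var)
  expect_true(all(pmax(v1 / v2, v2 / v1) < 3))
})

test_that("phase boundaries use the window-centre convention", {
  gt <- build_phase_networks(scenario_config(seed = 1))
  expect_equal(unname(gt$phase_boundaries), c(85, 115))
  expect_equal(unname(gt$first_affected), c(81, 111))
})

test_that("ground-truth writer emits edge lists and transitions", {
  gt <- build_phase_networks(scenario_config(seed = 2))
  d <- file.path(tempdir(), "gt_out")
  write_ground_truth(gt, d)
  expect_true(file.exists(file.path(d, "edges_interictal.tsv")))
  tr <- read.delim(file.path(d, "transitions.tsv"))
  expect_equal(tr$epoch_index, c(85, 115))
  e <- read.delim(file.path(d, "edges_soz_delta.tsv"))
  expect_identical(nrow(e), nrow(gt$planted_edges$soz_delta))
})
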