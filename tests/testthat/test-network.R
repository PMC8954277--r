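# Brute-force oracles for the geometric layers.
oracle_fps <- function(coords, m) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  chosen <- 1L
  while (length(chosen) < m) {
    mind <- apply(d[, chosen, drop = FALSE], 1, min)
    mind[chosen] <- -Inf
    chosen <- c(chosen, as.integer(which.max(mind)))    # which.max: lowest index on ties
  }
  chosen
}

oracle_knn <- function(coords, cidx, k) {
  d <- as.matrix(dist(coords))
  t(vapply(cidx, function(i) order(d[i, ], seq_len(nrow(coords)))[seq_len(k)],
           integer(k)))
}

test_that("farthest point sampling matches greedy enumeration", {
  # collinear points 0,1,2,3: second pick is the far end
  coords <- cbind(0:3, 0, 0)
  expect_equal(farthest_point_sample(coords, 2), c(1L, 4L))
  # m = N returns all points
  expect_setequal(farthest_point_sample(coords, 4), 1:4)
  # unit square corners + centre: the four corners are chosen first
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_setequal(farthest_point_sample(sq, 4), 1:4)
  expect_error(farthest_point_sample(sq, 6), "more centroids")
})

test_that("FPS and kNN grouping agree with brute force on random instances", {
  for (trial in 1:100) {
    n <- with_seed_local(trial, sample(5:50, 1))
    coords <- with_seed_local(trial + 1000, matrix(rnorm(n * 3), ncol = 3))
    m <- max(1, n %/% 3)
    expect_identical(farthest_point_sample(coords, m), oracle_fps(coords, m))
    cidx <- farthest_point_sample(coords, m)
    k <- min(n, 5)
    expect_identical(group_neighbors(coords, cidx, k),
                     oracle_knn(coords, cidx, k))
  }
})

test_that("each centroid groups itself at k = 1", {
  coords <- with_seed_local(8, matrix(rnorm(60), ncol = 3))
  cidx <- farthest_point_sample(coords, 5)
  g <- group_neighbors(coords, cidx, 1)
  expect_equal(as.vector(g), cidx)
  expect_error(group_neighbors(coords, cidx, 21), "more neighbours")
})

test_that("set abstraction output shape is S x F and indices are valid", {
  coords <- with_seed_local(9, matrix(rnorm(120), ncol = 3))
  feats <- with_seed_local(10, matrix(rnorm(40 * 6), ncol = 6))
  sa <- set_abstraction(coords, feats, S = 8, K = 5, mlp = c(16, 32), seed = 2)
  expect_equal(dim(sa$features), c(8, 32))
  expect_equal(dim(sa$centroid_coords), c(8, 3))
  expect_true(all(sa$source_index %in% seq_len(40)))
})

test_that("set abstraction is bitwise invariant to within-region point order", {
  coords <- with_seed_local(11, matrix(rnorm(90), ncol = 3))
  feats <- with_seed_local(12, matrix(rnorm(30 * 4), ncol = 4))
  cidx <- farthest_point_sample(coords, 6)
  groups <- group_neighbors(coords, cidx, 7)
  ref <- set_abstraction(coords, feats, S = 6, K = 7, mlp = c(8, 16),
                         seed = 3, groups = groups)
  for (s in 1:5) {
    shuffled <- groups
    r <- with_seed_local(s, sample(6, 1))
    shuffled[r, ] <- with_seed_local(s + 50, sample(shuffled[r, ]))
    alt <- set_abstraction(coords, feats, S = 6, K = 7, mlp = c(8, 16),
                           seed = 3, groups = shuffled)
    expect_identical(alt$features, ref$features)
  }
})

test_that("a region of identical points pools to the single-point output", {
  coords <- matrix(rep(c(0.3, -0.2, 0.5), each = 4), ncol = 3)
  feats <- matrix(rep(c(1, 2), each = 4), ncol = 2)
  sa <- set_abstraction(coords, feats, S = 1, K = 4, mlp = c(8, 8), seed = 4)
  single <- set_abstraction(coords[1, , drop = FALSE],
                            feats[1, , drop = FALSE],
                            S = 1, K = 1, mlp = c(8, 8), seed = 4)
  expect_equal(sa$features, single$features)
})

test_that("default-config structural path emits a 1024-vector over 512 centroids", {
  cfg <- model_config(n_classes = 4)
  model <- init_bios2net(cfg, seed = 1)
  cloud <- random_cloud(1024, seed = 13)
  fw <- bios2net_forward(model, cloud)
  expect_equal(nrow(fw$sa1$features), 512)
  expect_length(fw$global_feature, 1024 + 4 * cfg$temporal_filters)
  expect_equal(sum(fw$probabilities), 1, tolerance = 1e-6)
})

test_that("sequence extractor output depends on atom order", {
  cfg <- compact_model_config(3)
  model <- init_bios2net(cfg, seed = 5)
  cloud <- random_cloud(128, seed = 14)
  fw1 <- bios2net_forward(model, cloud)
  rev_cloud <- new_point_cloud(cloud$points[128:1, ])
  fw2 <- bios2net_forward(model, rev_cloud)
  expect_gt(max(abs(fw1$main_logits - fw2$main_logits)), 1e-8)
})

test_that("rigid rotation of the input changes the output (no built-in invariance)", {
  cfg <- compact_model_config(3)
  model <- init_bios2net(cfg, seed = 6)
  cloud <- random_cloud(128, seed = 15)
  rot <- cloud
  R <- bios2net:::rotation_matrix(0.3, 1.1, -0.7)
  rot$points[, 1:3] <- rot$points[, 1:3] %*% t(R)
  fw1 <- bios2net_forward(model, cloud)
  fw2 <- bios2net_forward(model, rot)
  expect_gt(max(abs(fw1$main_logits - fw2$main_logits)), 1e-8)
})

test_that("forward pass is finite for random inputs at all point counts", {
  for (np in c(256, 512, 1024)) {
    cfg <- model_config(
      n_classes = 3, n_points = np,
      seq_filters = 4,
      sa_layers = list(list(S = 64, K = 8, mlp = c(8, 8, 16)),
                       list(S = 16, K = 8, mlp = c(16, 16, 32)),
                       list(S = 1, K = 16, mlp = c(32, 32, 64))),
      temporal_filters = 4, head = c(32, 16))
    model <- init_bios2net(cfg, seed = np)
    for (trial in 1:5) {
      fw <- bios2net_forward(model, random_cloud(np, seed = np + trial))
      expect_true(all(is.finite(fw$main_logits)))
      expect_true(all(is.finite(fw$global_feature)))
      expect_true(all(is.finite(fw$struct_logits)))
      expect_true(all(is.finite(fw$temporal_logits)))
    }
  }
})

test_that("combined loss reproduces its closed forms", {
  # all heads certain and correct -> zero loss
  sure <- matrix(c(100, 0, 0), nrow = 1)
  expect_equal(combined_loss(sure, sure, sure, labels = 1)$loss, 0,
               tolerance = 1e-9)
  # all heads uniform over C classes -> ln C
  for (C in c(2, 3, 7)) {
    unif <- matrix(0, nrow = 1, ncol = C)
    expect_equal(combined_loss(unif, unif, unif, labels = 2)$loss, log(C),
                 tolerance = 1e-9)
  }
  # weighted sum of head cross-entropies: CE values 1, 2, 4 -> 1.8
  logit_with_ce <- function(ce, C = 3) {
    # two-point distribution: p on the true class solves -log(p) = ce
    p <- exp(-ce)
    matrix(log(c(p, rep((1 - p) / (C - 1), C - 1))), nrow = 1)
  }
  lo <- combined_loss(logit_with_ce(1), logit_with_ce(2), logit_with_ce(4),
                      labels = 1)
  expect_equal(lo$loss, 0.5 * 1 + 0.35 * 2 + 0.15 * 4, tolerance = 1e-9)
  expect_equal(lo$loss, 1.8, tolerance = 1e-9)
  expect_error(combined_loss(sure, labels = 5), "out of range")
})

test_that("disabled heads redistribute loss weight proportionally", {
  l1 <- matrix(c(3, 0, 1), nrow = 1)
  l2 <- matrix(c(0, 2, 0), nrow = 1)
  lo <- combined_loss(l1, l2, NULL, labels = 1)
  ce <- function(l) -log(exp(l[1]) / sum(exp(l)))
  w <- c(0.5, 0.35) / 0.85
  expect_equal(lo$loss, w[1] * ce(l1) + w[2] * ce(l2), tolerance = 1e-12)
})

test_that("analytic loss gradients match numerical differentiation", {
  set.seed(77)
  logits <- list(main = matrix(rnorm(4), 1), structure = matrix(rnorm(4), 1),
                 temporal = matrix(rnorm(4), 1))
  lo <- combined_loss(logits$main, logits$structure, logits$temporal,
                      labels = 3)
  eps <- 1e-6
  for (h in names(logits)) {
    for (j in 1:4) {
      up <- logits; up[[h]][1, j] <- up[[h]][1, j] + eps
      dn <- logits; dn[[h]][1, j] <- dn[[h]][1, j] - eps
      num <- (combined_loss(up$main, up$structure, up$temporal, 3)$loss -
                combined_loss(dn$main, dn$structure, dn$temporal, 3)$loss) /
        (2 * eps)
      expect_equal(lo$dlogits[[h]][1, j], num, tolerance = 1e-4)
    }
  }
})

test_that("ablation switches shape the fused feature vector", {
  cloud <- random_cloud(128, seed = 16)
  cfg_s <- compact_model_config(3, temporal_on = FALSE)
  fw_s <- bios2net_forward(init_bios2net(cfg_s, 1), cloud)
  expect_length(fw_s$global_feature, 128)      # structural vector alone
  expect_null(fw_s$temporal_logits)
  cfg_t <- compact_model_config(3, structure_on = FALSE)
  fw_t <- bios2net_forward(init_bios2net(cfg_t, 1), cloud)
  expect_length(fw_t$global_feature, 32)       # temporal vector alone
  expect_null(fw_t$struct_logits)
  expect_error(compact_model_config(3, structure_on = FALSE,
                                    temporal_on = FALSE), "config error")
})
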