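# published layer table for the canonical 8-channel configuration
.table3 <- data.frame(
  layer = c("conv", "res_conv*2", "3D_CBAM", "conv", "res_conv*4", "3D_CBAM",
            "conv", "res_conv*4", "3D_CBAM", "conv", "res_conv*4", "3D_CBAM",
            "conv", "res_conv*4", "3D_CBAM", "Flatten", "Full connection",
            "Full connection", "Softmax"),
  output = c("8*64*64*64", "8*64*64*64", "8*64*64*64", "16*32*32*32",
             "16*32*32*32", "16*32*32*32", "32*16*16*16", "32*16*16*16",
             "32*16*16*16", "64*8*8*8", "64*8*8*8", "64*8*8*8", "128*4*4*4",
             "128*4*4*4", "128*4*4*4", "8192", "2048", "512", "2"),
  stringsAsFactors = FALSE)

test_that("canonical configuration reproduces every tabulated output shape", {
  cfg <- network_config(in_channels = 8L)
  expect_equal(network_shapes(cfg), .table3)
  # single-modal variant: same spatial plan, adapted stem input
  cfg1 <- network_config(in_channels = 1L)
  expect_equal(network_shapes(cfg1), .table3)
  expect_equal(cfg$fc_widths[1], 8192L)
})

test_that("an actual forward pass matches the analytic shape trace", {
  cfg <- tiny_net_config(3L)
  net <- build_network(cfg, seed = 2)
  x5 <- array(runif(16^3 * 3), c(16, 16, 16, 3, 1))
  fw <- fusemass:::net_forward(net, x5, trace = TRUE)
  expect_equal(fw$trace, network_shapes(cfg))
  expect_equal(rowSums(fw$probs), 1, tolerance = 1e-12)
})

test_that("inconsistent configurations are rejected", {
  expect_error(network_config(stage_plan = list(c(1L, 8L, 16L),
                                                c(1L, 24L, 8L)),
                              fc_widths = c(24L * 512L, 64L, 16L)),
               "double")
  expect_error(network_config(stage_plan = list(c(1L, 8L, 16L),
                                                c(1L, 16L, 6L)),
                              fc_widths = c(3456L, 64L, 16L)),
               "halve")
  expect_error(network_config(fc_widths = c(100L, 2048L, 512L)), "flatten")
  expect_error(network_config(in_channels = 0L), ">= 1")
})

test_that("CBAM gates: identity bypass, (0,1) range, channel monotonicity", {
  set.seed(15)
  x <- array(rnorm(6^3 * 4), c(6, 6, 6, 4))
  byp <- cbam_3d(x, bypass = TRUE)
  expect_identical(byp$out, x)

  for (trial in 1:100) {
    xt <- array(rnorm(4^3 * 4, sd = runif(1, 0.1, 5)), c(4, 4, 4, 4))
    r <- cbam_3d(xt, seed = trial, spatial_kernel = 3L)
    expect_true(all(r$channel_weights > 0 & r$channel_weights < 1))
    expect_true(all(r$spatial_map > 0 & r$spatial_map < 1))
    expect_equal(dim(r$out), dim(xt))
  }

  # scaling one channel up increases its attention weight monotonically
  base <- array(abs(rnorm(6^3 * 4)), c(6, 6, 6, 4))
  p <- cbam_3d(base, seed = 7, spatial_kernel = 3L)$params
  w <- vapply(c(1, 2, 4, 8, 16), function(f) {
    xs <- base; xs[, , , 2] <- xs[, , , 2] * f
    cbam_3d(xs, params = p, spatial_kernel = 3L)$channel_weights[2]
  }, 0)
  expect_true(all(diff(w) > 0))

  # softmax gating normalizes weights over channels
  sm <- cbam_3d(base, params = p, gate = "softmax", spatial_kernel = 3L)
  expect_equal(sum(sm$channel_weights), 1, tolerance = 1e-12)
})

test_that("residual blocks with zeroed branch weights are the identity", {
  width <- 4L
  p <- list(conv1 = list(w = array(0, c(3, 3, 3, width, width)),
                         b = numeric(width)),
            bn1 = list(gamma = rep(1, width), beta = numeric(width)),
            conv2 = list(w = array(0, c(3, 3, 3, width, width)),
                         b = numeric(width)),
            bn2 = list(gamma = rep(1, width), beta = numeric(width)))
  st <- list(bn1 = list(rm = numeric(width), rv = rep(1, width)),
             bn2 = list(rm = numeric(width), rv = rep(1, width)))
  set.seed(16)
  x5 <- array(rnorm(5^3 * width * 2), c(5, 5, 5, width, 2))
  out <- fusemass:::resblock_fw(x5, p, st, training = FALSE)$out
  expect_equal(out, x5, tolerance = 1e-12)
})

test_that("prediction applies the P1/P2 decision rule with ties malignant", {
  cfg <- tiny_net_config(1L)
  net <- build_network(cfg, seed = 3)
  tensor <- structure(list(channels = array(runif(16^3), c(16, 16, 16, 1)),
                           channel_labels = "d2", case_id = "c",
                           label = NA_character_),
                      class = "ModelInputTensor")
  rig <- function(b) {
    n <- net
    i <- length(n$params)
    n$params[[i]]$w[] <- 0
    n$params[[i]]$b <- b
    n
  }
  ben <- predict_lesion(rig(c(2, 0)), tensor)
  expect_equal(ben$predicted_label, "benign")
  expect_gt(ben$p_benign, ben$p_malignant)
  tie <- predict_lesion(rig(c(0, 0)), tensor)   # P1 = P2 = 0.5
  expect_equal(tie$p_benign, 0.5)
  expect_equal(tie$predicted_label, "malignant")
  expect_equal(tie$p_benign + tie$p_malignant, 1)

  bad <- tensor; bad$channels <- array(0.1, c(16, 16, 16, 2))
  expect_error(predict_lesion(net, bad), "channel mismatch")
})

test_that("initialization and inference are deterministic in the seed", {
  cfg <- tiny_net_config(2L)
  n1 <- build_network(cfg, seed = 9)
  n2 <- build_network(cfg, seed = 9)
  expect_identical(n1$params, n2$params)
  x5 <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  f1 <- fusemass:::net_forward(n1, x5)
  f2 <- fusemass:::net_forward(n2, x5)
  expect_identical(f1$probs, f2$probs)
  expect_false(identical(n1$params,
                         build_network(cfg, seed = 10)$params))
})

test_that("backpropagation matches central finite differences", {
  cfg <- network_config(in_channels = 2L,
                        stage_plan = list(c(1L, 4L, 8L), c(1L, 8L, 4L)),
                        fc_widths = c(8L * 4L^3, 32L, 8L),
                        spatial_kernel = 3L)
  net <- build_network(cfg, seed = 3)
  set.seed(17)
  x5 <- array(rnorm(8^3 * 2 * 2), c(8, 8, 8, 2, 2))
  y <- c(1L, 2L)
  loss_of <- function(net) {
    fw <- fusemass:::net_forward(net, x5, training = TRUE)
    fusemass:::softmax_ce(fw$logits, y)$loss
  }
  fw <- fusemass:::net_forward(net, x5, training = TRUE)
  sm <- fusemass:::softmax_ce(fw$logits, y)
  grads <- fusemass:::net_backward(net, fw$caches, sm$dlogits)

  get_leaf <- function(lst, path) { for (k in path) lst <- lst[[k]]; lst }
  set_elem <- function(lst, path, j, v) {
    if (!length(path)) { lst[j] <- v; return(lst) }
    lst[[path[[1]]]] <- set_elem(lst[[path[[1]]]], path[-1], j, v)
    lst
  }
  eps <- 1e-6
  probes <- list(list(1, list("conv", "w")), list(1, list("bn", "gamma")),
                 list(2, list(1, "conv1", "w")), list(2, list(1, "bn2", "beta")),
                 list(3, list("sw")), list(3, list("b2")),
                 list(4, list("conv", "w")), list(5, list(1, "conv2", "w")),
                 list(6, list("w1")), list(8, list("w")), list(10, list("w")))
  for (pr in probes) {
    i <- pr[[1]]; path <- pr[[2]]
    g <- get_leaf(grads[[i]], path)
    p <- get_leaf(net$params[[i]], path)
    j <- which.max(abs(g))   # probe the most influential element
    n2 <- net
    n2$params[[i]] <- set_elem(n2$params[[i]], path, j, p[j] + eps)
    lp <- loss_of(n2)
    n2$params[[i]] <- set_elem(n2$params[[i]], path, j, p[j] - eps)
    lm <- loss_of(n2)
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[j], num, tolerance = 1e-4,
                 label = paste("grad", i, paste(unlist(path), collapse = "$")))
  }
})
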