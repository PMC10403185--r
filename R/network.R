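#' Configuration of the 3D residual attention classifier
#'
#' The canonical plan mirrors the published layer table: five stages of
#' residual 3x3x3 conv blocks, each stage closed by a 3D CBAM attention
#' module, with a kernel-2 stride-2 downsampling convolution between stages
#' that doubles the channel width and halves the spatial side; the final
#' 128-channel 4^3 feature map is flattened (length 8192) and passed through
#' two fully connected layers (8192 -> 2048 -> 512) and a 2-way softmax
#' head. Every element is parameterized so reduced configurations can be
#' trained quickly on one CPU.
#'
#' @param in_channels Number of input channels (8 for the four-modality +
#'   Sobel fused model, 1 for a plain single-modal model).
#' @param stage_plan List of `c(res_block_count, channel_width,
#'   spatial_side)` triples; widths must double and sides halve between
#'   consecutive stages.
#' @param fc_widths Widths of `(flatten, fc1, fc2)`; `fc_widths[1]` must
#'   equal `last_width * last_side^3`.
#' @param n_classes Number of output classes (2: benign, malignant).
#' @param attention Toggles, `list(channel = TRUE, spatial = TRUE)`.
#' @param gate Attention gating nonlinearity: `"sigmoid"` (canonical CBAM,
#'   default) or `"softmax"` over channels.
#' @param spatial_kernel Spatial-attention convolution kernel (odd; 7).
#' @param bn_momentum Running-statistics momentum for batch norm.
#' @return A `NetworkConfig` object.
#' @export
network_config <- function(in_channels = 8L,
                           stage_plan = list(c(2L, 8L, 64L), c(4L, 16L, 32L),
                                             c(4L, 32L, 16L), c(4L, 64L, 8L),
                                             c(4L, 128L, 4L)),
                           fc_widths = c(8192L, 2048L, 512L),
                           n_classes = 2L,
                           attention = list(channel = TRUE, spatial = TRUE),
                           gate = c("sigmoid", "softmax"),
                           spatial_kernel = 7L,
                           bn_momentum = 0.1) {
  gate <- match.arg(gate)
  if (in_channels < 1) stop("in_channels must be >= 1")
  if (spatial_kernel %% 2 != 1) stop("spatial_kernel must be odd")
  ns <- length(stage_plan)
  if (ns < 1) stop("need at least one stage")
  for (i in seq_len(ns)) {
    if (length(stage_plan[[i]]) != 3)
      stop("each stage is c(blocks, width, side)")
    if (i > 1) {
      if (stage_plan[[i]][2] != 2L * stage_plan[[i - 1]][2])
        stop("channel widths must double at each downsampling stage")
      if (2L * stage_plan[[i]][3] != stage_plan[[i - 1]][3])
        stop("spatial sides must halve at each downsampling stage")
    }
  }
  flat <- stage_plan[[ns]][2] * stage_plan[[ns]][3]^3
  if (fc_widths[1] != flat)
    stop("fc_widths[1] (", fc_widths[1], ") must equal the flatten length ",
         flat)
  structure(list(in_channels = as.integer(in_channels),
                 stage_plan = lapply(stage_plan, as.integer),
                 fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(n_classes),
                 attention = attention, gate = gate,
                 spatial_kernel = as.integer(spatial_kernel),
                 bn_momentum = bn_momentum),
            class = "NetworkConfig")
}

.cbam_reduction <- function(C) if (C <= 8L) 2L else 8L

# module sequence mirroring the layer table rows
.compile_modules <- function(cfg) {
  mods <- list()
  add <- function(m) mods[[length(mods) + 1L]] <<- m
  sp <- cfg$stage_plan
  ns <- length(sp)
  add(list(type = "stem", name = "conv", in_c = cfg$in_channels,
           out_c = sp[[1]][2]))
  for (i in seq_len(ns)) {
    add(list(type = "resgroup", name = sprintf("res_conv*%d", sp[[i]][1]),
             width = sp[[i]][2], blocks = sp[[i]][1]))
    add(list(type = "cbam", name = "3D_CBAM", c = sp[[i]][2]))
    if (i < ns)
      add(list(type = "down", name = "conv", in_c = sp[[i]][2],
               out_c = sp[[i + 1]][2]))
  }
  add(list(type = "flatten", name = "Flatten"))
  add(list(type = "fc", name = "Full connection", in_w = cfg$fc_widths[1],
           out_w = cfg$fc_widths[2]))
  add(list(type = "fc", name = "Full connection", in_w = cfg$fc_widths[2],
           out_w = cfg$fc_widths[3]))
  add(list(type = "head", name = "Softmax", in_w = cfg$fc_widths[3],
           out_w = cfg$n_classes))
  mods
}

#' Expected per-module output shapes
#'
#' Analytic shape propagation for a configuration; useful for checking the
#' architecture against the published layer table without running a forward
#' pass.
#'
#' @param config A `NetworkConfig`.
#' @return `data.frame` with `layer` and `output` (`"C*D*H*W"` for feature
#'   maps, a single integer for flat layers).
#' @export
network_shapes <- function(config) {
  mods <- .compile_modules(config)
  side <- config$stage_plan[[1]][3]
  C <- config$in_channels
  rows <- data.frame(layer = character(0), output = character(0))
  fmt <- function(C, s) sprintf("%d*%d*%d*%d", C, s, s, s)
  for (m in mods) {
    out <- switch(m$type,
      stem = { C <- m$out_c; fmt(C, side) },
      resgroup = fmt(C, side),
      cbam = fmt(C, side),
      down = { C <- m$out_c; side <- side %/% 2L; fmt(C, side) },
      flatten = as.character(C * side^3),
      fc = as.character(m$out_w),
      head = as.character(m$out_w))
    rows <- rbind(rows, data.frame(layer = m$name, output = out))
  }
  rows
}

.init_conv <- function(k, in_c, out_c, fan = NULL) {
  fan <- fan %||% (k^3 * out_c)  # Kaiming fan-out
  array(rnorm(k^3 * in_c * out_c, sd = sqrt(2 / fan)),
        dim = c(k, k, k, in_c, out_c))
}

.init_bn <- function(C, gamma0 = 1) {
  list(gamma = rep(gamma0, C), beta = numeric(C))
}

.init_bn_state <- function(C) list(rm = numeric(C), rv = rep(1, C))

.init_cbam <- function(C, ks) {
  Cr <- max(1L, C %/% .cbam_reduction(C))
  # non-negative bottleneck weights: the initial channel gate is then a
  # strictly increasing function of each channel's pooled energy, and the
  # modest output scale keeps sigmoid gates strictly inside (0,1) instead
  # of saturating in floating point
  list(w1 = matrix(abs(rnorm(Cr * C, sd = sqrt(2 / C))), Cr, C),
       b1 = numeric(Cr),
       w2 = matrix(abs(rnorm(C * Cr, sd = 0.2 / sqrt(Cr))), C, Cr),
       b2 = numeric(C),
       sw = .init_conv(ks, 2L, 1L),
       sb = numeric(1))
}

#' Build (initialize) the classification network
#'
#' Convolution weights use Kaiming fan-out initialization; batch norm
#' scales start at 1 (a zero-scale residual-branch init would pin the
#' branch at the ReLU kink, since the shortcut add follows the branch ReLU,
#' and permanently block its gradients). Zeroing all branch weights still
#' reduces each residual block to the identity map.
#'
#' @param config A `NetworkConfig`.
#' @param seed Integer seed fixing the initialization.
#' @return A `fusemass_network`: list with `config`, `params`, `state`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "NetworkConfig"))
  mods <- .compile_modules(config)
  net <- .with_seed(seed, function() {
    params <- vector("list", length(mods))
    state <- vector("list", length(mods))
    for (i in seq_along(mods)) {
      m <- mods[[i]]
      if (m$type %in% c("stem", "down")) {
        k <- if (m$type == "stem") 3L else 2L
        params[[i]] <- list(conv = list(w = .init_conv(k, m$in_c, m$out_c),
                                        b = numeric(m$out_c)),
                            bn = .init_bn(m$out_c))
        state[[i]] <- list(bn = .init_bn_state(m$out_c))
      } else if (m$type == "resgroup") {
        params[[i]] <- lapply(seq_len(m$blocks), function(j)
          list(conv1 = list(w = .init_conv(3L, m$width, m$width),
                            b = numeric(m$width)),
               bn1 = .init_bn(m$width),
               conv2 = list(w = .init_conv(3L, m$width, m$width),
                            b = numeric(m$width)),
               # NB: the branch ends in ReLU(BN2(.)) *before* the shortcut
               # add, so a zero BN2 scale would pin the branch at the ReLU
               # kink and freeze it permanently; init at 1 instead.
               bn2 = .init_bn(m$width, gamma0 = 1)))
        state[[i]] <- lapply(seq_len(m$blocks), function(j)
          list(bn1 = .init_bn_state(m$width), bn2 = .init_bn_state(m$width)))
      } else if (m$type == "cbam") {
        params[[i]] <- .init_cbam(m$c, config$spatial_kernel)
      } else if (m$type %in% c("fc", "head")) {
        sdw <- sqrt(2 / m$in_w)
        params[[i]] <- list(w = matrix(rnorm(m$in_w * m$out_w, sd = sdw),
                                       m$in_w, m$out_w),
                            b = numeric(m$out_w))
      }
    }
    list(params = params, state = state)
  })
  structure(list(config = config, modules = mods, params = net$params,
                 state = net$state),
            class = "fusemass_network")
}

.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# full forward pass; returns logits, probs, per-module caches (training),
# updated BN state and an optional shape trace
net_forward <- function(net, x5, training = FALSE, trace = FALSE) {
  cfg <- net$config
  mods <- net$modules
  caches <- vector("list", length(mods))
  state <- net$state
  tr <- if (trace) data.frame(layer = character(0), output = character(0))
  x <- x5
  shape_of <- function(x) {
    if (is.matrix(x)) as.character(ncol(x))
    else sprintf("%d*%d*%d*%d", dim(x)[4], dim(x)[1], dim(x)[2], dim(x)[3])
  }
  for (i in seq_along(mods)) {
    m <- mods[[i]]; p <- net$params[[i]]
    if (m$type %in% c("stem", "down")) {
      k <- if (m$type == "stem") 3L else 2L
      pad <- if (m$type == "stem") 1L else 0L
      stride <- if (m$type == "stem") 1L else 2L
      cv <- conv_fw(x, p$conv$w, p$conv$b, stride, pad,
                    keep_cols = training)
      bn <- bn_fw(cv$out, p$bn$gamma, p$bn$beta, state[[i]]$bn$rm,
                  state[[i]]$bn$rv, training, cfg$bn_momentum)
      rl <- relu_fw(bn$out)
      caches[[i]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
      state[[i]]$bn <- list(rm = bn$rm, rv = bn$rv)
      x <- rl$out
    } else if (m$type == "resgroup") {
      bc <- vector("list", m$blocks)
      for (j in seq_len(m$blocks)) {
        rb <- resblock_fw(x, p[[j]], state[[i]][[j]], training)
        bc[[j]] <- rb$cache
        state[[i]][[j]] <- rb$state
        x <- rb$out
      }
      caches[[i]] <- bc
    } else if (m$type == "cbam") {
      cb <- cbam_fw(x, p, gate = cfg$gate,
                    channel = isTRUE(cfg$attention$channel),
                    spatial = isTRUE(cfg$attention$spatial),
                    training = training)
      caches[[i]] <- cb$cache
      x <- cb$out
    } else if (m$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- d
      x <- t(matrix(x, prod(d[1:4]), d[5]))
    } else if (m$type == "fc") {
      ln <- linear_fw(x, p$w, p$b)
      rl <- relu_fw(ln$out)
      caches[[i]] <- list(lin = ln$cache, relu = rl$cache)
      x <- rl$out
    } else if (m$type == "head") {
      ln <- linear_fw(x, p$w, p$b)
      caches[[i]] <- list(lin = ln$cache)
      x <- ln$out
    }
    if (trace) tr <- rbind(tr, data.frame(layer = m$name,
                                          output = shape_of(x)))
  }
  sm <- softmax_ce(x)
  list(logits = x, probs = sm$probs, caches = caches, state = state,
       trace = tr)
}

# backward pass through all modules; returns grads congruent to net$params
net_backward <- function(net, caches, dlogits) {
  mods <- net$modules
  grads <- vector("list", length(mods))
  dx <- dlogits
  for (i in rev(seq_along(mods))) {
    m <- mods[[i]]; cc <- caches[[i]]
    if (m$type == "head") {
      lb <- linear_bw(cc$lin, dx)
      grads[[i]] <- lb$grads; dx <- lb$dx
    } else if (m$type == "fc") {
      dr <- relu_bw(cc$relu, dx)
      lb <- linear_bw(cc$lin, dr)
      grads[[i]] <- lb$grads; dx <- lb$dx
    } else if (m$type == "flatten") {
      grads[i] <- list(NULL)
      dx <- array(t(dx), cc)
    } else if (m$type == "cbam") {
      cb <- cbam_bw(net$params[[i]], cc, dx)
      grads[[i]] <- cb$grads; dx <- cb$dx
    } else if (m$type == "resgroup") {
      g <- vector("list", m$blocks)
      for (j in rev(seq_len(m$blocks))) {
        rb <- resblock_bw(cc[[j]], dx)
        g[[j]] <- rb$grads; dx <- rb$dx
      }
      grads[[i]] <- g
    } else {   # stem / down
      dr <- relu_bw(cc$relu, dx)
      bb <- bn_bw(cc$bn, dr)
      cv <- conv_bw(cc$conv, bb$dx)
      grads[[i]] <- list(conv = cv$grads, bn = bb$grads)
      dx <- cv$dx
    }
  }
  grads
}

#' Run 3D CBAM attention on a feature map
#'
#' Channel attention (global average and max pooling over space, a shared
#' two-layer bottleneck MLP, summed and gated) followed by spatial attention
#' (average and max over channels, a single-channel convolution, gated);
#' both gates multiply the features and preserve the shape. With
#' `bypass = TRUE` all gates are forced to 1 and the output equals the
#' input.
#'
#' @param features 4D array `(D, H, W, C)`.
#' @param params CBAM parameter list (as built inside [build_network()]);
#'   randomly initialized from `seed` when `NULL`.
#' @param gate `"sigmoid"` (default) or `"softmax"` over channels.
#' @param channel,spatial Enable the two attention stages.
#' @param bypass Force all gates to 1 (identity).
#' @param spatial_kernel Kernel of the spatial-attention convolution.
#' @param seed Seed for parameter initialization when `params` is `NULL`.
#' @return List: `out` (same shape as input), `channel_weights` (length C,
#'   in (0,1)), `spatial_map` (`(D,H,W)` array in (0,1)); the latter two are
#'   `NULL` when the corresponding stage is disabled or bypassed.
#' @export
cbam_3d <- function(features, params = NULL, gate = c("sigmoid", "softmax"),
                    channel = TRUE, spatial = TRUE, bypass = FALSE,
                    spatial_kernel = 7L, seed = 1L) {
  gate <- match.arg(gate)
  stopifnot(is.array(features), length(dim(features)) == 4)
  C <- dim(features)[4]
  if (is.null(params))
    params <- .with_seed(seed, function() .init_cbam(C, spatial_kernel))
  x5 <- array(features, c(dim(features), 1L))
  r <- cbam_fw(x5, params, gate = gate, channel = channel,
               spatial = spatial, bypass = bypass)
  out <- array(r$out, dim(features))
  list(out = out,
       channel_weights = if (!bypass && channel) as.vector(r$cache$a),
       spatial_map = if (!bypass && spatial)
         array(r$cache$sg, dim(features)[1:3]),
       params = params)
}

#' Classify one preprocessed lesion tensor
#'
#' Runs the network in inference mode and applies the decision rule: the
#' softmax head emits `(P1, P2)`, the probabilities of benign and malignant;
#' `P1 > P2` calls the lesion benign, `P1 <= P2` (ties included) malignant.
#'
#' @param net A `fusemass_network`.
#' @param tensor A `ModelInputTensor`.
#' @return A `Prediction`: list with `p_benign`, `p_malignant`,
#'   `predicted_label`, `case_id`.
#' @export
predict_lesion <- function(net, tensor) {
  stopifnot(inherits(net, "fusemass_network"),
            inherits(tensor, "ModelInputTensor"))
  C <- dim(tensor$channels)[4]
  if (C != net$config$in_channels)
    stop("channel mismatch: tensor has ", C, " channels, network expects ",
         net$config$in_channels)
  x5 <- array(tensor$channels, c(dim(tensor$channels), 1L))
  fw <- net_forward(net, x5, training = FALSE)
  p1 <- fw$probs[1, 1]; p2 <- fw$probs[1, 2]
  structure(list(p_benign = p1, p_malignant = p2,
                 predicted_label = if (p1 > p2) "benign" else "malignant",
                 case_id = tensor$case_id),
            class = "Prediction")
}

#' @export
print.Prediction <- function(x, ...) {
  cat(sprintf("<Prediction %s: P1(benign)=%.3f P2(malignant)=%.3f -> %s>\n",
              x$case_id, x$p_benign, x$p_malignant, x$predicted_label))
  invisible(x)
}

#' Serialize / restore a network configuration (YAML)
#' @param config A `NetworkConfig`.
#' @param path YAML file path.
#' @name config_io
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "NetworkConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_network_config <- function(path) {
  x <- yaml::read_yaml(path)
  network_config(in_channels = x$in_channels, stage_plan = x$stage_plan,
                 fc_widths = unlist(x$fc_widths), n_classes = x$n_classes,
                 attention = x$attention, gate = x$gate,
                 spatial_kernel = x$spatial_kernel,
                 bn_momentum = x$bn_momentum)
}
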