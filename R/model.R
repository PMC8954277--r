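#' Model configuration
#'
#' Architecture and ablation hyperparameters. The defaults reproduce the
#' published BioS2Net layout: 1024 input points; a sequence extractor of five
#' 1D inception modules with kernel sizes 1/3/5/7; three set-abstraction
#' levels (512 and 128 centroids, then a single centroid whose PointNet
#' output is the 1024-dimensional structural feature vector); a temporal
#' network of six dilated (rate 3) inception modules over the 512
#' sequence-ordered level-1 centroids, each followed by length-2 max pooling,
#' closed by global average pooling; a dense classification head; and
#' auxiliary-loss weights 0.5 / 0.35 / 0.15 (main, structural, temporal).
#' Hidden widths follow PointNet++/inception conventions and are
#' overridable.
#'
#' @param n_classes Number of fold classes.
#' @param n_points Points sampled per cloud (256, 512 or 1024 in the original
#'   experiments; any value compatible with the centroid counts is accepted).
#' @param seq_modules,seq_filters Sequence extractor depth and per-branch
#'   filter count (output width is \code{4 * seq_filters}).
#' @param kernel_sizes Inception branch kernel sizes.
#' @param sa_layers List of 3 set-abstraction levels, each with \code{S}
#'   (centroids), \code{K} (neighbours) and \code{mlp} (PointNet widths).
#'   The last level must have \code{S = 1}.
#' @param temporal_modules,temporal_filters,temporal_dilation Temporal
#'   network depth, per-branch filters and dilation rate.
#' @param head Hidden widths of the dense classification head.
#' @param loss_weights Main / structural / temporal loss weights (sum to 1).
#' @param normalize Apply per-sample channel normalization after inception
#'   concatenations and pooled set-abstraction features. Off by default:
#'   per-sample statistics remove per-protein mean feature content (helix
#'   and sheet fractions, conservation level), which carries most of the
#'   fold signal.
#' @param sequence_on,structure_on,temporal_on Ablation switches. Disabling
#'   a component removes its features from downstream concatenations and its
#'   auxiliary head; loss weights are renormalized over the remaining heads.
#' @return A list of class \code{bios2net_config}.
#' @export
model_config <- function(n_classes,
                         n_points = 1024,
                         seq_modules = 5, seq_filters = 16,
                         kernel_sizes = c(1, 3, 5, 7),
                         sa_layers = list(
                           list(S = 512, K = 32, mlp = c(64, 64, 128)),
                           list(S = 128, K = 32, mlp = c(128, 128, 256)),
                           list(S = 1, K = 128, mlp = c(256, 512, 1024))),
                         temporal_modules = 6, temporal_filters = 16,
                         temporal_dilation = 3,
                         head = c(512, 256),
                         loss_weights = c(main = 0.5, structure = 0.35,
                                          temporal = 0.15),
                         sequence_on = TRUE, structure_on = TRUE,
                         temporal_on = TRUE, normalize = FALSE) {
  cfg <- list(n_classes = n_classes, n_points = n_points,
              seq_modules = seq_modules, seq_filters = seq_filters,
              kernel_sizes = kernel_sizes, sa_layers = sa_layers,
              temporal_modules = temporal_modules,
              temporal_filters = temporal_filters,
              temporal_dilation = temporal_dilation,
              head = head, loss_weights = loss_weights,
              sequence_on = sequence_on, structure_on = structure_on,
              temporal_on = temporal_on, normalize = normalize)
  class(cfg) <- "bios2net_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$sa_layers) != 3) {
    stop("config error: exactly 3 set-abstraction layers are required", call. = FALSE)
  }
  if (cfg$sa_layers[[3]]$S != 1) {
    stop("config error: the last set-abstraction layer must have a single centroid",
         call. = FALSE)
  }
  if (abs(sum(cfg$loss_weights) - 1) > 1e-9) {
    stop("config error: loss_weights must sum to 1", call. = FALSE)
  }
  if (!cfg$structure_on && !cfg$temporal_on) {
    stop("config error: structural and temporal components cannot both be disabled",
         call. = FALSE)
  }
  if (cfg$temporal_on) {
    s1 <- cfg$sa_layers[[1]]$S
    if (s1 %% 2^cfg$temporal_modules != 0) {
      stop(sprintf(paste("config error: first-level centroid count (%d) must be",
                         "divisible by 2^%d for the temporal pooling stages"),
                   s1, cfg$temporal_modules), call. = FALSE)
    }
  }
  if (cfg$sa_layers[[1]]$S > cfg$n_points) {
    stop("config error: first-level centroid count exceeds n_points", call. = FALSE)
  }
  if (cfg$n_classes < 2) stop("config error: n_classes must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' Compact configuration for desk-scale experiments
#'
#' A narrow, shallow-width variant of the default architecture (same layout:
#' five + six inception modules, three set-abstraction levels, identical loss
#' weighting) sized so that the synthetic benchmark trains in minutes on one
#' CPU: 128 input points, 64/16/1 centroids, reduced filter and MLP widths.
#'
#' @param n_classes Number of fold classes.
#' @param ... Overrides passed to \code{\link{model_config}}.
#' @return A \code{bios2net_config}.
#' @export
compact_model_config <- function(n_classes, ...) {
  model_config(
    n_classes = n_classes, n_points = 128,
    seq_filters = 8,
    sa_layers = list(
      list(S = 64, K = 16, mlp = c(16, 16, 32)),
      list(S = 16, K = 8, mlp = c(32, 32, 64)),
      list(S = 1, K = 16, mlp = c(64, 64, 128))),
    temporal_filters = 8,
    head = c(64, 32),
    ...
  )
}

#' @export
print.bios2net_config <- function(x, ...) {
  comp <- c(if (x$sequence_on) "sequence", if (x$structure_on) "structure",
            if (x$temporal_on) "temporal")
  cat(sprintf(paste0("<bios2net_config> %d classes, %d points; SA centroids %s;",
                     " components: %s\n"),
              x$n_classes, x$n_points,
              paste(vapply(x$sa_layers, `[[`, 0, "S"), collapse = "/"),
              paste(comp, collapse = "+")))
  invisible(x)
}

# Derived channel widths used across forward/backward.
config_dims <- function(cfg) {
  c_seq <- if (cfg$sequence_on) length(cfg$kernel_sizes) * cfg$seq_filters else 0
  d_struct <- 50 + c_seq                       # non-coordinate features
  f1 <- utils::tail(cfg$sa_layers[[1]]$mlp, 1)
  f2 <- utils::tail(cfg$sa_layers[[2]]$mlp, 1)
  f3 <- utils::tail(cfg$sa_layers[[3]]$mlp, 1)
  e_temp <- 53 + c_seq + f1
  c_temp <- length(cfg$kernel_sizes) * cfg$temporal_filters
  g_dim <- (if (cfg$structure_on) f3 else 0) + (if (cfg$temporal_on) c_temp else 0)
  list(c_seq = c_seq, d_struct = d_struct, f1 = f1, f2 = f2, f3 = f3,
       e_temp = e_temp, c_temp = c_temp, g_dim = g_dim)
}

#' Initialize a BioS2Net model
#'
#' He-initialized weights for every enabled component, reproducible from the
#' seed.
#'
#' @param config A \code{\link{model_config}}.
#' @param seed Integer seed for weight initialization.
#' @return A list of class \code{bios2net_model} with \code{config} and
#'   \code{params}.
#' @export
init_bios2net <- function(config, seed = 1) {
  validate_config(config)
  dims <- config_dims(config)
  with_local_seed(seed, {
    params <- list()
    if (config$sequence_on) {
      cin <- 53
      params$seq <- vector("list", config$seq_modules)
      for (m in seq_len(config$seq_modules)) {
        params$seq[[m]] <- init_inception(cin, config$kernel_sizes,
                                          config$seq_filters)
        cin <- dims$c_seq
      }
    }
    cin_sa <- 3 + dims$d_struct
    params$sa <- vector("list", 3)
    n_sa <- if (config$structure_on) 3 else 1
    for (l in seq_len(n_sa)) {
      widths <- config$sa_layers[[l]]$mlp
      mlp <- list()
      ci <- cin_sa
      for (w in widths) {
        mlp[[length(mlp) + 1]] <- list(W = he_weight(ci, w), b = numeric(w))
        ci <- w
      }
      fl <- utils::tail(widths, 1)
      params$sa[[l]] <- list(mlp = mlp, gamma = rep(1, fl), beta = numeric(fl))
      cin_sa <- 3 + fl
    }
    if (config$structure_on) {
      params$struct_aux <- list(W = he_weight(dims$f3, config$n_classes),
                                b = numeric(config$n_classes))
    }
    if (config$temporal_on) {
      cin <- dims$e_temp
      params$temporal <- vector("list", config$temporal_modules)
      for (m in seq_len(config$temporal_modules)) {
        params$temporal[[m]] <- init_inception(cin, config$kernel_sizes,
                                               config$temporal_filters)
        cin <- dims$c_temp
      }
      params$temp_aux <- list(W = he_weight(dims$c_temp, config$n_classes),
                              b = numeric(config$n_classes))
    }
    ci <- dims$g_dim
    params$head <- list()
    for (w in config$head) {
      params$head[[length(params$head) + 1]] <-
        list(W = he_weight(ci, w), b = numeric(w))
      ci <- w
    }
    params$head_out <- list(W = he_weight(ci, config$n_classes),
                            b = numeric(config$n_classes))
    structure(list(config = config, params = params), class = "bios2net_model")
  })
}

#' Farthest point sampling
#'
#' Greedy selection of \code{m} centroids: start from the first point, then
#' repeatedly add the point whose minimum distance to the chosen set is
#' largest, ties broken by lowest index. Deterministic.
#'
#' @param coords N x 3 coordinate matrix.
#' @param m Number of centroids (\code{m <= N}).
#' @return Integer vector of \code{m} indices into the rows of \code{coords}.
#' @export
farthest_point_sample <- function(coords, m) {
  n <- nrow(coords)
  if (m > n) stop("cannot sample more centroids than points", call. = FALSE)
  chosen <- integer(m)
  chosen[1] <- 1L
  if (m == 1) return(chosen)
  d2 <- rowSums(sweep(coords, 2, coords[1, ])^2)
  for (i in 2:m) {
    nxt <- which.max(d2)                 # which.max takes the first maximum
    chosen[i] <- nxt
    nd <- rowSums(sweep(coords, 2, coords[nxt, ])^2)
    d2 <- pmin(d2, nd)
  }
  chosen
}

#' k-nearest-neighbour grouping around centroids
#'
#' For each centroid, the \code{k} nearest points by Euclidean distance
#' (the centroid itself included), distance ties broken by lowest index.
#'
#' @param coords N x 3 coordinate matrix.
#' @param centroid_indices Integer vector of centroid row indices.
#' @param k Neighbours per region (\code{k <= N}).
#' @return An m x k integer matrix of point indices.
#' @export
group_neighbors <- function(coords, centroid_indices, k) {
  n <- nrow(coords)
  if (k > n) stop("cannot group more neighbours than points", call. = FALSE)
  C <- coords[centroid_indices, , drop = FALSE]
  d2 <- outer(rowSums(C^2), rowSums(coords^2), "+") - 2 * C %*% t(coords)
  out <- matrix(0L, nrow = length(centroid_indices), ncol = k)
  for (i in seq_along(centroid_indices)) {
    # radix sort is stable, so exact distance ties resolve to lowest index
    out[i, ] <- sort.list(d2[i, ], method = "radix")[seq_len(k)]
  }
  out
}

# Forward pass of one set-abstraction level. Local coordinates are expressed
# relative to the centroid before the shared PointNet MLP; the per-region max
# pool makes the level invariant to the order of points within a region (the
# MLP is row-wise, so permutation invariance is exact/bitwise). Channel
# normalization is applied to the pooled centroid features (skipped for the
# single-centroid level, where per-channel statistics would degenerate).
sa_forward <- function(coords, feats, level, p, groups = NULL,
                       normalize = TRUE) {
  S <- level$S; K <- level$K
  cidx <- farthest_point_sample(coords, S)
  if (is.null(groups)) groups <- group_neighbors(coords, cidx, K)
  # canonicalize region member order (ascending index): the pooled output is
  # conceptually order-free, and canonical order makes the invariance exact
  # at the floating-point level as well
  groups <- matrix(groups[order(row(groups), groups)], nrow = S, byrow = TRUE)
  flat <- as.vector(t(groups))
  local <- coords[flat, , drop = FALSE] -
    coords[rep(cidx, each = K), , drop = FALSE]
  Xr <- cbind(local, feats[flat, , drop = FALSE])
  mlp_caches <- vector("list", length(p$mlp))
  Z <- Xr
  for (l in seq_along(p$mlp)) {
    df <- dense_fw(Z, p$mlp[[l]]$W, p$mlp[[l]]$b, "relu")
    mlp_caches[[l]] <- df$cache
    Z <- df$out
  }
  rp <- region_maxpool_fw(Z, S, K)
  if (S > 1 && normalize) {
    nf <- chan_norm_fw(rp$out, p$gamma, p$beta)
    rf <- relu_fw(nf$out)
    features <- rf$out
    post <- list(norm = nf$cache, relu = rf$cache)
  } else {
    features <- rp$out
    post <- NULL
  }
  list(centroid_coords = coords[cidx, , drop = FALSE],
       features = features,
       source_index = cidx,
       cache = list(groups = groups, flat = flat, cidx = cidx,
                    mlp = mlp_caches, pool = rp$cache, post = post,
                    n = nrow(coords), d_feats = ncol(feats), S = S, K = K))
}

# Backward: returns gradient w.r.t. the input features (coordinates carry no
# parameters upstream, so their gradient is not propagated) plus parameter
# gradients for this level.
sa_backward <- function(dfeatures, p, cache) {
  if (!is.null(cache$post)) {
    d <- relu_bw(dfeatures, cache$post$relu)
    nb <- chan_norm_bw(d, cache$post$norm)
    dpooled <- nb$dX
    dgamma <- nb$dgamma; dbeta <- nb$dbeta
  } else {
    dpooled <- dfeatures
    dgamma <- 0 * p$gamma; dbeta <- 0 * p$beta
  }
  dZ <- region_maxpool_bw(dpooled, cache$pool)
  gmlp <- vector("list", length(p$mlp))
  for (l in rev(seq_along(p$mlp))) {
    db <- dense_bw(dZ, p$mlp[[l]]$W, cache$mlp[[l]])
    gmlp[[l]] <- list(W = db$dW, b = db$db)
    dZ <- db$dX
  }
  dflat <- dZ[, -(1:3), drop = FALSE]          # feature part of region input
  agg <- rowsum(dflat, group = cache$flat)
  dfeats <- matrix(0, nrow = cache$n, ncol = cache$d_feats)
  dfeats[as.integer(rownames(agg)), ] <- agg
  list(dfeats = dfeats,
       grads = list(mlp = gmlp, gamma = dgamma, beta = dbeta))
}

#' One set-abstraction level as a standalone operation
#'
#' Sampling (FPS), grouping (kNN) and a shared PointNet MLP with per-region
#' max pooling, exposed directly for inspection and testing. With
#' \code{params = NULL} a fresh level is initialized from \code{seed}.
#'
#' @param coords N x 3 coordinates.
#' @param feats N x D feature matrix.
#' @param S,K,mlp Level geometry: centroids, neighbours, MLP widths.
#' @param params Optional parameter list (as built by
#'   \code{\link{init_bios2net}} for one level).
#' @param seed Seed for fresh initialization when \code{params} is NULL.
#' @param groups Optional precomputed S x K index matrix overriding kNN
#'   grouping (rows within a region may be listed in any order).
#' @return List with \code{centroid_coords} (S x 3), \code{features}
#'   (S x F), and \code{source_index}.
#' @export
set_abstraction <- function(coords, feats, S, K, mlp = c(16, 16, 32),
                            params = NULL, seed = 1, groups = NULL) {
  if (is.null(params)) {
    params <- with_local_seed(seed, {
      ci <- 3 + ncol(feats)
      ml <- list()
      for (w in mlp) {
        ml[[length(ml) + 1]] <- list(W = he_weight(ci, w), b = numeric(w))
        ci <- w
      }
      list(mlp = ml, gamma = rep(1, utils::tail(mlp, 1)),
           beta = numeric(utils::tail(mlp, 1)))
    })
  }
  out <- sa_forward(coords, feats, list(S = S, K = K), params, groups = groups)
  out$cache <- NULL
  out
}
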