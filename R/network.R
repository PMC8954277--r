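# Full-model forward and backward passes.
#
# Information flow: the sequence extractor annotates each atom with its
# sequential context; its output (concatenated with the raw 53 features)
# feeds the structure extractor; the first set-abstraction level also feeds
# the temporal network, whose centroids are re-sorted into sequence order;
# the structural 1024-vector and the temporal vector are concatenated into
# the global feature vector and classified by the dense head. Auxiliary
# heads hang off the structural and temporal vectors.

#' Forward pass of a BioS2Net model
#'
#' @param model A \code{bios2net_model}.
#' @param cloud A \code{point_cloud} (already sampled to
#'   \code{config$n_points} rows) or a bare N x 53 matrix.
#' @param keep_cache Retain layer caches for a subsequent backward pass.
#' @return A list with \code{main_logits}, \code{probabilities},
#'   \code{global_feature} (the fused vector fed to the head),
#'   \code{struct_logits}, \code{temporal_logits} (NULL when the component
#'   is disabled), \code{sa1} (first-level set-abstraction output) and,
#'   when requested, the caches.
#' @export
bios2net_forward <- function(model, cloud, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  X <- if (inherits(cloud, "point_cloud")) cloud$points else cloud
  if (ncol(X) != 53) stop("input width must be 53 features", call. = FALSE)
  if (nrow(X) != cfg$n_points) {
    stop(sprintf("input has %d points but the model expects %d",
                 nrow(X), cfg$n_points), call. = FALSE)
  }
  dims <- config_dims(cfg)
  nrm <- isTRUE(cfg$normalize)
  cache <- list()

  # Sequence convolutional extractor.
  seq_out <- NULL
  if (cfg$sequence_on) {
    Z <- X
    cache$seq <- vector("list", cfg$seq_modules)
    for (m in seq_len(cfg$seq_modules)) {
      inc <- inception_fw(Z, p$seq[[m]], cfg$kernel_sizes, dilation = 1,
                          normalize = nrm)
      cache$seq[[m]] <- inc$cache
      Z <- inc$out
    }
    seq_out <- Z
  }

  coords <- X[, 1:3, drop = FALSE]
  feats_full <- if (is.null(seq_out)) X[, -(1:3), drop = FALSE] else
    cbind(X[, -(1:3), drop = FALSE], seq_out)

  # Structure extractor (level 1 is always needed as the temporal frontend).
  sa1 <- sa_forward(coords, feats_full, cfg$sa_layers[[1]], p$sa[[1]],
                    normalize = nrm)
  gvec <- NULL; struct_logits <- NULL
  if (cfg$structure_on) {
    sa2 <- sa_forward(sa1$centroid_coords, sa1$features,
                      cfg$sa_layers[[2]], p$sa[[2]], normalize = nrm)
    sa3 <- sa_forward(sa2$centroid_coords, sa2$features,
                      cfg$sa_layers[[3]], p$sa[[3]], normalize = nrm)
    gvec <- sa3$features                       # 1 x F3
    struct_logits <- sweep(gvec %*% p$struct_aux$W, 2, p$struct_aux$b, "+")
    cache$sa2 <- sa2$cache; cache$sa3 <- sa3$cache
    cache$gvec <- gvec
  }
  cache$sa1 <- sa1$cache

  # Temporal network on sequence-ordered level-1 centroids.
  tvec <- NULL; temporal_logits <- NULL
  if (cfg$temporal_on) {
    ord <- order(sa1$source_index)
    rows <- sa1$source_index[ord]
    tin <- cbind(X[rows, , drop = FALSE],
                 if (!is.null(seq_out)) seq_out[rows, , drop = FALSE],
                 sa1$features[ord, , drop = FALSE])
    Z <- tin
    cache$temporal <- vector("list", cfg$temporal_modules)
    cache$tpool <- vector("list", cfg$temporal_modules)
    for (m in seq_len(cfg$temporal_modules)) {
      inc <- inception_fw(Z, p$temporal[[m]], cfg$kernel_sizes,
                          dilation = cfg$temporal_dilation, normalize = nrm)
      cache$temporal[[m]] <- inc$cache
      mp <- maxpool2_fw(inc$out)
      cache$tpool[[m]] <- mp$cache
      Z <- mp$out
    }
    cache$t_rows_final <- nrow(Z)
    tvec <- matrix(colMeans(Z), nrow = 1)      # global average pooling
    cache$tvec <- tvec
    temporal_logits <- sweep(tvec %*% p$temp_aux$W, 2, p$temp_aux$b, "+")
    cache$t_ord <- ord; cache$t_rows <- rows
  }

  hvec <- cbind(gvec, tvec)
  cache$hvec <- hvec
  Z <- hvec
  cache$head <- vector("list", length(p$head))
  for (l in seq_along(p$head)) {
    df <- dense_fw(Z, p$head[[l]]$W, p$head[[l]]$b, "relu")
    cache$head[[l]] <- df$cache
    Z <- df$out
  }
  cache$head_in_final <- Z
  main_logits <- sweep(Z %*% p$head_out$W, 2, p$head_out$b, "+")

  out <- list(
    main_logits = main_logits,
    probabilities = softmax_vec(as.numeric(main_logits)),
    global_feature = as.numeric(hvec),
    struct_logits = struct_logits,
    temporal_logits = temporal_logits,
    sa1 = list(centroid_coords = sa1$centroid_coords,
               features = sa1$features,
               source_index = sa1$source_index)
  )
  if (keep_cache) out$cache <- cache
  out
}

# Backward pass given the three logit gradients; returns parameter gradients
# in the same nested shape as model$params.
bios2net_backward <- function(model, fw, d_main, d_struct = NULL, d_temp = NULL) {
  cfg <- model$config
  p <- model$params
  cache <- fw$cache
  dims <- config_dims(cfg)
  g <- list()

  # Head.
  g$head_out <- list(W = crossprod(cache$head_in_final, d_main),
                     b = colSums(d_main))
  dZ <- d_main %*% t(p$head_out$W)
  g$head <- vector("list", length(p$head))
  for (l in rev(seq_along(p$head))) {
    db <- dense_bw(dZ, p$head[[l]]$W, cache$head[[l]])
    g$head[[l]] <- list(W = db$dW, b = db$db)
    dZ <- db$dX
  }
  dhvec <- dZ
  off <- 0
  dgvec <- NULL; dtvec <- NULL
  if (cfg$structure_on) {
    dgvec <- dhvec[, seq_len(dims$f3), drop = FALSE]
    off <- dims$f3
  }
  if (cfg$temporal_on) {
    dtvec <- dhvec[, off + seq_len(dims$c_temp), drop = FALSE]
  }

  # Auxiliary heads.
  if (cfg$structure_on && !is.null(d_struct)) {
    g$struct_aux <- list(W = crossprod(cache$gvec, d_struct),
                         b = colSums(d_struct))
    dgvec <- dgvec + d_struct %*% t(p$struct_aux$W)
  } else if (cfg$structure_on) {
    g$struct_aux <- list(W = 0 * p$struct_aux$W, b = 0 * p$struct_aux$b)
  }

  n <- cfg$n_points
  dseq <- if (cfg$sequence_on) matrix(0, n, dims$c_seq) else NULL
  dsa1_feat <- matrix(0, cfg$sa_layers[[1]]$S, dims$f1)

  # Temporal network.
  if (cfg$temporal_on) {
    if (!is.null(d_temp)) {
      g$temp_aux <- list(W = crossprod(cache$tvec, d_temp), b = colSums(d_temp))
      dtvec <- dtvec + d_temp %*% t(p$temp_aux$W)
    } else {
      g$temp_aux <- list(W = 0 * p$temp_aux$W, b = 0 * p$temp_aux$b)
    }
    nfinal <- cache$t_rows_final
    dZ <- matrix(rep(as.numeric(dtvec) / nfinal, each = nfinal), nrow = nfinal)
    g$temporal <- vector("list", cfg$temporal_modules)
    for (m in rev(seq_len(cfg$temporal_modules))) {
      dZ <- maxpool2_bw(dZ, cache$tpool[[m]])
      ib <- inception_bw(dZ, p$temporal[[m]], cache$temporal[[m]])
      g$temporal[[m]] <- ib$grads
      dZ <- ib$dX
    }
    # Split the temporal input gradient: raw X block (dropped), sequence
    # block (scattered back to atom rows), sa1 feature block (unsorted).
    ord <- cache$t_ord; rows <- cache$t_rows
    colp <- 53
    if (cfg$sequence_on) {
      dseq_rows <- dZ[, colp + seq_len(dims$c_seq), drop = FALSE]
      dseq[rows, ] <- dseq[rows, , drop = FALSE] + dseq_rows
      colp <- colp + dims$c_seq
    }
    dsa1_sorted <- dZ[, colp + seq_len(dims$f1), drop = FALSE]
    dsa1_feat[ord, ] <- dsa1_feat[ord, , drop = FALSE] + dsa1_sorted
  }

  # Structure extractor levels 3 -> 2 -> 1.
  g$sa <- vector("list", 3)
  if (cfg$structure_on) {
    sb3 <- sa_backward(dgvec, p$sa[[3]], cache$sa3)
    g$sa[[3]] <- sb3$grads
    sb2 <- sa_backward(sb3$dfeats, p$sa[[2]], cache$sa2)
    g$sa[[2]] <- sb2$grads
    dsa1_feat <- dsa1_feat + sb2$dfeats
  }
  sb1 <- sa_backward(dsa1_feat, p$sa[[1]], cache$sa1)
  g$sa[[1]] <- sb1$grads

  # Gradient on the full per-atom feature block -> sequence extractor.
  if (cfg$sequence_on) {
    dseq <- dseq + sb1$dfeats[, 50 + seq_len(dims$c_seq), drop = FALSE]
    g$seq <- vector("list", cfg$seq_modules)
    dZ <- dseq
    for (m in rev(seq_len(cfg$seq_modules))) {
      ib <- inception_bw(dZ, p$seq[[m]], cache$seq[[m]])
      g$seq[[m]] <- ib$grads
      dZ <- ib$dX
    }
  }
  g
}

#' Weighted multi-head categorical cross-entropy
#'
#' \eqn{0.5\,CE_{main} + 0.35\,CE_{struct} + 0.15\,CE_{temporal}} with
#' cross-entropies averaged over the batch. Heads whose logits are
#' \code{NULL} (ablated components) redistribute their weight proportionally
#' among the remaining heads.
#'
#' @param main_logits,struct_logits,temporal_logits Numeric matrices
#'   (n x C) of unnormalized scores, or \code{NULL} for disabled heads
#'   (main is mandatory).
#' @param labels Integer class indices (1-based), length n.
#' @param weights Named weights for (main, structure, temporal).
#' @return List with \code{loss} (scalar) and \code{dlogits} (list of
#'   per-head gradient matrices, \code{NULL} for absent heads).
#' @export
combined_loss <- function(main_logits, struct_logits = NULL,
                          temporal_logits = NULL, labels,
                          weights = c(main = 0.5, structure = 0.35,
                                      temporal = 0.15)) {
  heads <- list(main = main_logits, structure = struct_logits,
                temporal = temporal_logits)
  if (is.null(names(weights))) names(weights) <- names(heads)
  present <- !vapply(heads, is.null, logical(1))
  if (!present["main"]) stop("main head logits are required", call. = FALSE)
  w <- weights[names(heads)]
  w[!present] <- 0
  w <- w / sum(w)
  n <- length(labels)
  loss <- 0
  dlogits <- list(main = NULL, structure = NULL, temporal = NULL)
  for (h in names(heads)) {
    if (!present[h]) next
    lg <- heads[[h]]
    if (is.null(dim(lg))) lg <- matrix(lg, nrow = 1)
    if (any(labels < 1 | labels > ncol(lg))) {
      stop("label out of range for the class set", call. = FALSE)
    }
    dm <- matrix(0, nrow = n, ncol = ncol(lg))
    lsum <- 0
    for (i in seq_len(n)) {
      ce <- ce_loss(lg[i, ], labels[i])
      lsum <- lsum + ce$loss
      dm[i, ] <- ce$dlogits
    }
    loss <- loss + w[h] * lsum / n
    dlogits[[h]] <- w[h] * dm / n
  }
  list(loss = unname(loss), dlogits = dlogits, weights = w)
}

# -- nested-list parameter algebra (Adam) -------------------------------------

# Recurse two parallel nested lists; when names are present the second list
# is indexed by name, so field order never has to match.
rec_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    nms <- names(a)
    names(out) <- nms
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      out[[i]] <- rec_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

rec_map1 <- function(f, a) rec_map2(function(x, y) f(x), a, a)

adam_init <- function(params) {
  list(m = rec_map1(function(x) 0 * x, params),
       v = rec_map1(function(x) 0 * x, params),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- rec_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- rec_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- rec_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  params <- rec_map2(`-`, params, upd)
  list(params = params, state = state)
}
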