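#' Read a dataset manifest
#'
#' Tab-separated file with columns \code{id}, \code{structure_path},
#' \code{pssm_path} (empty or \code{NA} for the zero-fill sentinel) and
#' \code{label}. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest TSV path.
#' @return A data.frame of class \code{dataset_manifest}.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("id", "structure_path", "pssm_path", "label")
  if (!all(req %in% names(m))) {
    stop("manifest must have columns id, structure_path, pssm_path, label",
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  m$structure_path <- fix(m$structure_path)
  m$pssm_path <- fix(m$pssm_path)
  missing <- !file.exists(m$structure_path)
  if (any(missing)) {
    stop(sprintf("%d structure path(s) in the manifest do not resolve",
                 sum(missing)), call. = FALSE)
  }
  class(m) <- c("dataset_manifest", class(m))
  m
}

# Test-set size for a fold group of size n: fixed 20 above 100 members, at
# least 30% below 30, and the linear interpolation between the anchor points
# (30, 9) and (100, 20) in between (rounded half-up, so the rule is
# continuous with both regimes).
group_test_size <- function(n) {
  if (n <= 1) return(0L)
  if (n > 100) return(20L)
  if (n < 30) return(as.integer(ceiling(0.3 * n)))
  as.integer(floor(9 + (n - 30) * 11 / 70 + 0.5))
}

#' Split a dataset into train and test sets by fold group
#'
#' Members are chosen by a seeded shuffle within each label group; the two
#' sets partition every group. Singleton groups go entirely to train (with a
#' warning), since a test set would otherwise swallow the only example.
#'
#' @param manifest A \code{dataset_manifest} (or data.frame with a
#'   \code{label} column).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} row-index vectors and
#'   \code{test_sizes} (named per-group test counts).
#' @export
split_dataset <- function(manifest, seed = 1) {
  labels <- manifest$label
  groups <- split(seq_along(labels), labels)
  train <- integer(0); test <- integer(0)
  sizes <- integer(0)
  with_local_seed(seed, {
    for (g in names(groups)) {
      idx <- groups[[g]]
      nt <- group_test_size(length(idx))
      if (nt == 0 && length(idx) == 1) {
        warning(sprintf("fold group '%s' has a single member; kept in train", g),
                call. = FALSE)
      }
      sh <- sample(idx)
      test <- c(test, sh[seq_len(nt)])
      train <- c(train, sh[setdiff(seq_along(sh), seq_len(nt))])
      sizes[g] <- nt
    }
  })
  list(train = sort(train), test = sort(test), test_sizes = sizes)
}

#' Classification accuracy metrics
#'
#' Simple accuracy is the number of correct classifications divided by all
#' classifications; mean class accuracy is the unweighted average of the
#' per-class simple accuracies (classes absent from the truth are excluded),
#' which removes the impact of class imbalance.
#'
#' @param truth,predicted Vectors of class labels (any comparable type).
#' @return List with \code{simple_accuracy} and \code{mean_class_accuracy}.
#' @export
evaluate_predictions <- function(truth, predicted) {
  if (length(truth) == 0) stop("no predictions to evaluate", call. = FALSE)
  stopifnot(length(truth) == length(predicted))
  correct <- truth == predicted
  per_class <- tapply(correct, as.character(truth), mean)
  list(simple_accuracy = mean(correct),
       mean_class_accuracy = mean(per_class))
}

#' Summarize the tail of a training history
#'
#' Mean and population standard deviation of the test accuracies over the
#' final \code{last_k} epochs (the plateau-summary convention: a fixed
#' epoch budget with last-20 averaging).
#'
#' @param history Data.frame with per-epoch \code{test_simple_accuracy} and
#'   \code{test_mean_class_accuracy} columns (as produced by
#'   \code{\link{bios2net_fit}}).
#' @param last_k Number of trailing epochs to summarize.
#' @return Named list of means and standard deviations.
#' @export
summarize_history <- function(history, last_k = 20) {
  if (nrow(history) < last_k) {
    stop(sprintf("history has %d epochs but last_k = %d", nrow(history), last_k),
         call. = FALSE)
  }
  tail_rows <- history[seq(nrow(history) - last_k + 1, nrow(history)), ]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(simple_accuracy_mean = mean(tail_rows$test_simple_accuracy),
       simple_accuracy_sd = pop_sd(tail_rows$test_simple_accuracy),
       mean_class_accuracy_mean = mean(tail_rows$test_mean_class_accuracy),
       mean_class_accuracy_sd = pop_sd(tail_rows$test_mean_class_accuracy))
}

# Featurize every manifest entry once (the expensive part: secondary
# structure, accessible areas, PSSM squashing). Returns a list of clouds.
featurize_manifest <- function(manifest, progress = FALSE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    s <- parse_structure(manifest$structure_path[i])
    pssm <- read_pssm(if (is.na(manifest$pssm_path[i])) NULL else
      manifest$pssm_path[i], nchar(s$sequence))
    cl <- featurize(s, pssm, label = as.character(manifest$label[i]))
    cl$source_id <- as.character(manifest$id[i])
    cl
  })
}

#' Fit a BioS2Net fold classifier
#'
#' The full training protocol: featurize all manifest entries, split into
#' train and test by the per-group rule, fit coordinate/B-factor
#' normalization on the training set only, then run minibatch Adam on the
#' weighted multi-head cross-entropy. Each epoch resamples and re-augments
#' the training clouds; the test clouds are sampled once with a fixed seed
#' and never augmented. Fully reproducible from \code{seed}.
#'
#' @param manifest A \code{dataset_manifest} (see \code{\link{read_manifest}})
#'   or a path to one.
#' @param config A \code{\link{model_config}}; defaults to the compact
#'   configuration sized for desk-scale data.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size (gradients are averaged per batch).
#' @param augmentation An \code{\link{augmentation_config}}, or \code{NULL}
#'   to disable augmentation.
#' @param seed Integer seed governing split, initialization, sampling,
#'   augmentation and batching.
#' @param clouds Optional precomputed list of featurized clouds (one per
#'   manifest row) to skip featurization.
#' @param verbose Print per-epoch progress.
#' @return An object of class \code{bios2net}: the fitted model, the
#'   normalization statistics, the split, the per-epoch \code{history}
#'   data.frame and the class levels.
#' @export
bios2net_fit <- function(manifest, config = NULL, epochs = 60, lr = 1e-3,
                         batch_size = 32, augmentation = augmentation_config(),
                         seed = 1, clouds = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  classes <- sort(unique(as.character(manifest$label)))
  if (is.null(config)) config <- compact_model_config(length(classes))
  if (config$n_classes != length(classes)) {
    stop(sprintf("config expects %d classes but manifest has %d",
                 config$n_classes, length(classes)), call. = FALSE)
  }
  if (is.null(clouds)) clouds <- featurize_manifest(manifest)
  y <- match(as.character(manifest$label), classes)

  sp <- split_dataset(manifest, seed = seed)
  norm <- fit_normalization(clouds[sp$train])
  clouds_n <- lapply(clouds, apply_normalization, stats = norm)

  # Fixed test-time sampling (one subsample per test cloud, no augmentation).
  test_clouds <- lapply(seq_along(sp$test), function(i)
    sample_points(clouds_n[[sp$test[i]]], config$n_points,
                  seed = (seed * 1000L + i) %% .Machine$integer.max))

  model <- init_bios2net(config, seed = seed)
  opt <- adam_init(model$params)
  history <- data.frame()

  with_local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(sp$train)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1, length(ord))]
        gacc <- NULL
        bloss <- 0
        for (j in batch) {
          cl <- sample_points(clouds_n[[j]], config$n_points)
          if (!is.null(augmentation)) cl <- augment(cl, augmentation)
          fw <- bios2net_forward(model, cl, keep_cache = TRUE)
          lo <- combined_loss(fw$main_logits, fw$struct_logits,
                              fw$temporal_logits, y[j],
                              weights = config$loss_weights)
          if (!is.finite(lo$loss)) {
            stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                 call. = FALSE)
          }
          bloss <- bloss + lo$loss
          g <- bios2net_backward(model, fw, lo$dlogits$main,
                                 lo$dlogits$structure, lo$dlogits$temporal)
          gacc <- if (is.null(gacc)) g else rec_map2(`+`, gacc, g)
        }
        gacc <- rec_map1(function(x) x / length(batch), gacc)
        st <- adam_step(model$params, gacc, opt, lr = lr)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + bloss
        nb <- nb + length(batch)
      }
      pred <- vapply(test_clouds, function(cl)
        which.max(bios2net_forward(model, cl)$probabilities), 0L)
      ev <- evaluate_predictions(y[sp$test], pred)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / nb,
        test_simple_accuracy = ev$simple_accuracy,
        test_mean_class_accuracy = ev$mean_class_accuracy))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  mca %.3f", ep,
                        ep_loss / nb, ev$simple_accuracy, ev$mean_class_accuracy))
      }
    }
  })

  structure(list(model = model, config = config, norm = norm,
                 classes = classes, split = sp, history = history,
                 manifest = manifest, seed = seed,
                 augmentation = augmentation),
            class = "bios2net")
}

#' @export
print.bios2net <- function(x, ...) {
  cat(sprintf("<bios2net> %d classes (%s), %d epochs\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              nrow(x$history)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final test accuracy: simple %.3f, mean-class %.3f\n",
              last$test_simple_accuracy, last$test_mean_class_accuracy))
  invisible(x)
}

#' @export
summary.bios2net <- function(object, last_k = min(20, nrow(object$history)), ...) {
  s <- summarize_history(object$history, last_k = last_k)
  cat(sprintf("BioS2Net fold classifier: %d train / %d test structures, %d classes\n",
              length(object$split$train), length(object$split$test),
              length(object$classes)))
  cat(sprintf("Test accuracy over the last %d epochs:\n", last_k))
  cat(sprintf("  simple      %.3f +/- %.3f\n",
              s$simple_accuracy_mean, s$simple_accuracy_sd))
  cat(sprintf("  mean-class  %.3f +/- %.3f\n",
              s$mean_class_accuracy_mean, s$mean_class_accuracy_sd))
  invisible(s)
}

#' Plot training history
#'
#' Train loss and test accuracies per epoch.
#'
#' @param x A fitted \code{bios2net}.
#' @param ... Unused.
#' @export
plot.bios2net <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "train loss",
       main = "loss")
  plot(h$epoch, h$test_mean_class_accuracy, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "test accuracy")
  graphics::lines(h$epoch, h$test_simple_accuracy, lty = 2)
  graphics::legend("bottomright", c("mean-class", "simple"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

# Prepare a cloud for prediction with a fitted object: normalize with the
# training statistics and subsample deterministically.
prepare_cloud <- function(object, cloud, seed = 99L) {
  cl <- apply_normalization(cloud, object$norm)
  sample_points(cl, object$config$n_points, seed = seed)
}

#' Predict fold classes with a fitted BioS2Net
#'
#' @param object A fitted \code{bios2net}.
#' @param newdata A \code{point_cloud}, a list of clouds, a
#'   \code{protein_structure}, or a path to a PDB file. Clouds must be
#'   un-normalized featurized output (normalization is applied here with the
#'   training statistics).
#' @param type \code{"class"} or \code{"prob"}.
#' @param seed Seed for the deterministic test-time subsample.
#' @param ... Unused.
#' @return Predicted labels, or a matrix of class probabilities.
#' @export
predict.bios2net <- function(object, newdata, type = c("class", "prob"),
                             seed = 99L, ...) {
  type <- match.arg(type)
  clouds <- as_cloud_list(newdata)
  probs <- t(vapply(seq_along(clouds), function(i) {
    cl <- prepare_cloud(object, clouds[[i]], seed = seed + i)
    bios2net_forward(object$model, cl)$probabilities
  }, numeric(length(object$classes))))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

as_cloud_list <- function(newdata) {
  if (inherits(newdata, "point_cloud")) return(list(newdata))
  if (inherits(newdata, "protein_structure")) return(list(featurize(newdata)))
  if (is.character(newdata)) {
    return(lapply(newdata, function(p) featurize(parse_structure(p))))
  }
  if (is.list(newdata)) return(newdata)
  stop("unsupported newdata type", call. = FALSE)
}

#' Extract global feature vectors for a set of proteins
#'
#' Runs the fitted network with augmentation disabled and deterministic
#' fixed-seed sampling and returns, per protein, the concatenated global
#' feature vector (the input to the classification head) used for embedding
#' and similarity analysis.
#'
#' @param object A fitted \code{bios2net}.
#' @param clouds List of un-normalized \code{point_cloud}s (defaults to the
#'   fitted test set).
#' @param seed Sampling seed.
#' @param file Optional TSV output path (identifier, label, then the vector).
#' @return Numeric matrix, one row per protein, with \code{id} and
#'   \code{label} attributes.
#' @export
extract_global_features <- function(object, clouds = NULL, seed = 99L,
                                    file = NULL) {
  stopifnot(inherits(object, "bios2net"))
  if (is.null(clouds)) {
    clouds <- featurize_manifest(object$manifest[object$split$test, ])
  }
  vecs <- t(vapply(seq_along(clouds), function(i) {
    cl <- prepare_cloud(object, clouds[[i]], seed = seed + i)
    bios2net_forward(object$model, cl)$global_feature
  }, numeric(config_dims(object$config)$g_dim)))
  ids <- vapply(clouds, function(cl) cl$source_id, "")
  labels <- vapply(clouds, function(cl) as.character(cl$label), "")
  rownames(vecs) <- ids
  attr(vecs, "label") <- labels
  if (!is.null(file)) {
    df <- data.frame(id = ids, label = labels, vecs, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  vecs
}
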