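#' Specification of an encoder-decoder segmentation network
#'
#' Captures the layer arithmetic of both architectures under study: cubic
#' convolution kernels of side \code{kernel_size}, 2x2x2 max pooling,
#' \code{base_filters} filters at the first level doubling at every
#' contraction, and \code{depth} encoder/decoder levels. With
#' \code{skip_connections = TRUE} the decoder concatenates the matching
#' encoder feature maps (a U-Net); with \code{FALSE} it does not (a
#' SegNet-style network). For an input of side \eqn{s} the latent code has
#' spatial side \eqn{s / 2^{depth}} and \code{base_filters * 2^(depth - 1)}
#' channels. The defaults mirror a typical full-scale setup (3^3 kernels,
#' 16 filters, 4 levels); desk-scale studies shrink \code{base_filters} and
#' \code{depth}.
#'
#' @param kernel_size Odd cubic convolution kernel side.
#' @param pool_size Pooling factor per level; only 2 is supported.
#' @param base_filters Filters at the first encoder level.
#' @param depth Number of encoder (and decoder) levels.
#' @param skip_connections U-Net (\code{TRUE}) or SegNet-style (\code{FALSE}).
#' @param num_classes Output classes of the per-voxel softmax (background
#'   plus tissue classes).
#' @return A \code{network_spec} object.
#' @export
network_spec <- function(kernel_size = 3L, pool_size = 2L, base_filters = 16L,
                         depth = 4L, skip_connections = TRUE, num_classes = 4L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be odd and positive")
  if (as.integer(pool_size) != 2L) stop("only pool_size 2 is supported")
  if (base_filters < 1L || depth < 1L) stop("base_filters and depth must be positive")
  if (num_classes < 2L) stop("num_classes must be at least 2")
  structure(list(kernel_size = kernel_size, pool_size = 2L,
                 base_filters = as.integer(base_filters), depth = as.integer(depth),
                 skip_connections = isTRUE(skip_connections),
                 num_classes = as.integer(num_classes)),
            class = "network_spec")
}

#' Expected latent-code shape for a spec and input size
#'
#' @param spec A \code{network_spec}.
#' @param input_dim Integer vector of input spatial dimensions.
#' @return List with \code{spatial} (input over \code{2^depth}) and
#'   \code{channels} (\code{base_filters * 2^(depth-1)}).
#' @export
latent_shape <- function(spec, input_dim) {
  f <- 2L^spec$depth
  if (any(input_dim %% f != 0))
    stop("input dims must be divisible by pool_size^depth = ", f)
  list(spatial = as.integer(input_dim %/% f),
       channels = as.integer(spec$base_filters * 2^(spec$depth - 1L)))
}

#' Build a segmentation model
#'
#' The encoder is \code{depth} blocks of (conv + ReLU + 2x max pool) with the
#' filter count doubling per block; the task decoder is \code{depth} blocks of
#' (nearest-neighbour 2x upsampling + conv + ReLU), concatenating the matching
#' encoder feature map first when skip connections are enabled, followed by a
#' final convolution to \code{num_classes} channels and a per-voxel softmax.
#'
#' @param spec A \code{network_spec}.
#' @param seed Integer seed for the (He) weight initialization.
#' @return A \code{seg_model} holding the spec, seed and parameter lists.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel_size; z <- spec$base_filters; n <- spec$depth
  with_seed(seed, function() {
    enc <- vector("list", n)
    cin <- 1L
    for (j in seq_len(n)) {
      cout <- z * 2L^(j - 1L)
      enc[[j]] <- he_init(k, cin, cout)
      cin <- cout
    }
    dec <- vector("list", n)
    for (j in rev(seq_len(n))) {
      c_below <- if (j == n) z * 2L^(n - 1L) else z * 2L^j
      c_in <- c_below + if (spec$skip_connections) z * 2L^(j - 1L) else 0L
      dec[[j]] <- he_init(k, c_in, z * 2L^(j - 1L))
    }
    final <- he_init(k, z, spec$num_classes, scale = 1)
    structure(list(spec = spec, seed = as.integer(seed),
                   params = list(enc = enc, dec = dec, final = final)),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("%s: depth %d, base filters %d, kernel %d^3, %d classes, %s parameters\n",
              if (x$spec$skip_connections) "U-Net" else "SegNet-style",
              x$spec$depth, x$spec$base_filters, x$spec$kernel_size,
              x$spec$num_classes,
              format(count_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A \code{seg_model} or \code{inversion_decoder}.
#' @return Integer count.
#' @export
n_params <- function(model) count_params(model$params)

as_input4 <- function(X) {
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  X
}

check_divisible <- function(spec, X) {
  d <- dim(X)[1:3]
  f <- 2L^spec$depth
  if (any(d %% f != 0))
    stop("input dims (", paste(d, collapse = "x"),
         ") not divisible by pool_size^depth = ", f)
}

# Encoder forward pass; keep = TRUE retains the caches needed for backprop.
encoder_forward <- function(model, X, keep = FALSE) {
  spec <- model$spec; k <- spec$kernel_size
  check_divisible(spec, X)
  h <- as_input4(X)
  n <- spec$depth
  acts <- caches <- idx <- indims <- vector("list", n)
  for (j in seq_len(n)) {
    cv <- conv_fwd(h, model$params$enc[[j]]$W, model$params$enc[[j]]$b, k)
    a <- relu(cv$y)
    pl <- maxpool3(a)
    if (keep) {
      acts[[j]] <- a; caches[[j]] <- cv; idx[[j]] <- pl$idx
      indims[[j]] <- dim(a)
    } else {
      acts[[j]] <- a                     # needed for skip connections
    }
    h <- pl$out
  }
  list(latent = h, acts = acts, caches = caches, idx = idx, indims = indims)
}

#' Latent code of a volume
#'
#' Runs only the (frozen) encoder: \code{Z = Enc(X)}, the most compressed
#' representation of the image inside the network, the quantity a model
#' inversion attack starts from.
#'
#' @param model A trained or untrained model (or any object with an
#'   \code{encode} method, such as \code{\link{linear_encoder}}).
#' @param X Preprocessed 3D volume with dimensions divisible by
#'   \code{2^depth}.
#' @return 4D array (spatial dims / \code{2^depth}, latent channels).
#' @export
encode <- function(model, X) UseMethod("encode")

#' @export
encode.seg_model <- function(model, X) {
  encoder_forward(model, X, keep = FALSE)$latent
}

decoder_forward <- function(model, ef, keep = FALSE) {
  spec <- model$spec; k <- spec$kernel_size; n <- spec$depth
  h <- ef$latent
  caches <- masks <- cin1 <- vector("list", n)
  for (j in rev(seq_len(n))) {
    hu <- upsample3(h)
    if (spec$skip_connections) {
      cin1[[j]] <- dim(hu)[4]
      hu <- concat_channels(hu, ef$acts[[j]])
    }
    cv <- conv_fwd(hu, model$params$dec[[j]]$W, model$params$dec[[j]]$b, k)
    h <- relu(cv$y)
    if (keep) { caches[[j]] <- cv; masks[[j]] <- h > 0 }
  }
  fin <- conv_fwd(h, model$params$final$W, model$params$final$b, k)
  list(logits = fin$y, final_cache = fin, dec_caches = caches,
       dec_masks = masks, cin1 = cin1)
}

#' Segment a volume
#'
#' Full forward pass: per-voxel class probabilities (softmax over channels).
#'
#' @param model A \code{seg_model}.
#' @param X Preprocessed 3D volume.
#' @return 4D array of probabilities summing to 1 at every voxel; take
#'   \code{\link{label_map}} for the argmax labels.
#' @export
segment <- function(model, X) {
  ef <- encoder_forward(model, X, keep = FALSE)
  df <- decoder_forward(model, ef, keep = FALSE)
  softmax4(df$logits)
}

#' Argmax label map of a probability volume
#' @param probs 4D probability array from \code{\link{segment}}.
#' @return 3D integer array of class labels (0-based: background = 0).
#' @export
label_map <- function(probs) {
  d <- dim(probs)
  m <- probs[, , , 1]
  lab <- array(0L, d[1:3])
  for (cc in seq_len(d[4] - 1L)) {
    p <- probs[, , , cc + 1L]
    sel <- p > m
    lab[sel] <- cc
    m[sel] <- p[sel]
  }
  lab
}

# Full forward + backward for one (X, labels) pair under voxel-wise
# cross-entropy. labels are 0-based classes (0 = background).
seg_forward_backward <- function(model, X, labels) {
  spec <- model$spec; k <- spec$kernel_size; n <- spec$depth
  ef <- encoder_forward(model, X, keep = TRUE)
  df <- decoder_forward(model, ef, keep = TRUE)
  probs <- softmax4(df$logits)
  d <- dim(probs); nv <- prod(d[1:3])
  lab1 <- as.integer(labels) + 1L
  pm <- matrix(probs, nrow = nv)
  pick <- pm[cbind(seq_len(nv), lab1)]
  loss <- -mean(log(pmax(pick, 1e-12)))
  dl <- pm
  dl[cbind(seq_len(nv), lab1)] <- dl[cbind(seq_len(nv), lab1)] - 1
  dl <- dl / nv
  dim(dl) <- d

  grads <- list(enc = vector("list", n), dec = vector("list", n), final = NULL)
  bw <- conv_bwd(df$final_cache, model$params$final$W, k, dl)
  grads$final <- list(W = bw$gW, b = bw$gb)
  g <- bw$gx
  skip_g <- vector("list", n)
  for (j in seq_len(n)) {              # decoder blocks from full-res inward
    g <- g * df$dec_masks[[j]]
    bw <- conv_bwd(df$dec_caches[[j]], model$params$dec[[j]]$W, k, g)
    grads$dec[[j]] <- list(W = bw$gW, b = bw$gb)
    gi <- bw$gx
    if (spec$skip_connections) {
      sp <- split_channels(gi, df$cin1[[j]])
      skip_g[[j]] <- sp[[2]]
      gi <- sp[[1]]
    }
    g <- upsample3_bwd(gi)
  }
  for (j in rev(seq_len(n))) {         # encoder blocks from latent outward
    ga <- maxpool3_bwd(g, ef$idx[[j]], ef$indims[[j]])
    if (spec$skip_connections && !is.null(skip_g[[j]])) ga <- ga + skip_g[[j]]
    ga <- ga * (ef$acts[[j]] > 0)
    bw <- conv_bwd(ef$caches[[j]], model$params$enc[[j]]$W, k, ga)
    grads$enc[[j]] <- list(W = bw$gW, b = bw$gb)
    g <- bw$gx
  }
  list(loss = loss, grads = grads, probs = probs)
}

#' Training configuration
#'
#' @param epochs Passes over the training volumes.
#' @param batch_size Volumes per parameter update (1, volume-at-a-time).
#' @param learning_rate Adam learning rate.
#' @param seed Seed fixing initialization and shuffling.
#' @param loss_name \code{"cross_entropy"} (segmentation) or \code{"mse"}
#'   (inversion).
#' @param val_fraction Held-out fraction for early stopping of inversion
#'   training (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @return A \code{train_config}.
#' @export
train_config <- function(epochs = 20L, batch_size = 1L, learning_rate = 1e-3,
                         seed = 1L, loss_name = "cross_entropy",
                         val_fraction = 0.2, patience = 8L) {
  if (epochs < 1L) stop("epochs must be at least 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss_name = loss_name, val_fraction = val_fraction,
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Train a segmentation model
#'
#' Volume-at-a-time Adam on voxel-wise cross-entropy over background plus the
#' tissue classes. Fully seeded: the same config and seed reproduce the loss
#' trace bit-exactly.
#'
#' @param model A \code{seg_model}.
#' @param cohort List of preprocessed training pairs: each element a list (or
#'   \code{subject}) with \code{image} and 0-based \code{labels} of a common
#'   padded shape.
#' @param cfg A \code{\link{train_config}}.
#' @return The trained model, with the per-epoch mean loss in
#'   \code{model$trace}.
#' @export
train_segmentation <- function(model, cohort, cfg) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  dims <- lapply(cohort, function(s) dim(s$image))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("training volumes must share one padded shape")
  nmax <- max(unlist(lapply(cohort, function(s) max(s$labels))))
  if (nmax + 1L > model$spec$num_classes)
    stop("labels contain class ", nmax, " but the model has only ",
         model$spec$num_classes, " classes")
  params <- model$params
  state <- adam_state_init(params)
  t <- 0L
  trace <- numeric(cfg$epochs)
  with_seed(cfg$seed, function() {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(cohort))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        s <- cohort[[ord[i]]]
        model$params <- params
        fb <- seg_forward_backward(model, s$image, s$labels)
        losses[i] <- fb$loss
        t <<- t + 1L
        res <- adam_step(params, fb$grads, state, t, cfg$learning_rate)
        params <<- res$p
        state <<- res$s
      }
      trace[ep] <<- mean(losses)
    }
  })
  model$params <- params
  model$trace <- trace
  model$trained <- TRUE
  model
}

#' Mean Dice of a model over a set of subjects
#'
#' Convenience wrapper: segments each subject and averages the per-class Dice
#' of the argmax labels against the ground truth over the tissue classes.
#'
#' @param model A \code{seg_model}.
#' @param subjects List of preprocessed subjects.
#' @param classes Classes to average over (default 1:3).
#' @return Numeric vector of per-subject mean Dice values.
#' @export
model_dice <- function(model, subjects, classes = 1:3) {
  vapply(subjects, function(s) {
    pred <- label_map(segment(model, s$image))
    mean_dice(pred, s$labels, classes)
  }, 0)
}

#' Save / load a model checkpoint
#'
#' Self-describing container: the spec, seed and parameters (and training
#' trace when present) serialized with R's native serialization.
#'
#' @param model Model to save.
#' @param path File path.
#' @return \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
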