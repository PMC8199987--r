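#' Build the attacker's inversion decoder
#'
#' Architecture mirrors the attacked encoder: \code{depth} blocks of
#' (nearest-neighbour 2x upsampling + conv + ReLU) with the filter count
#' halving towards full resolution, followed by a final linear convolution to
#' a single channel. There are no skip connections: the attacker sees only
#' the latent code \code{Z}, never the encoder's intermediate feature maps.
#' A \code{depth = 0} spec yields a purely linear single-convolution decoder,
#' useful for analyzing invertible linear encoders in closed form.
#'
#' @param spec The attacked network's \code{\link{network_spec}} (its depth,
#'   kernel and filter counts determine the mirror architecture).
#' @param latent_channels Channels of the latent code; defaults to the
#'   spec's \code{base_filters * 2^(depth-1)}.
#' @param out_channels Output channels (1 for a grayscale volume).
#' @param seed Initialization seed.
#' @param depth Number of upsampling blocks; defaults to the spec's depth.
#'   \code{0} builds the purely linear decoder.
#' @return An \code{inversion_decoder}.
#' @export
build_inversion_decoder <- function(spec, latent_channels = NULL,
                                    out_channels = 1L, seed = 1L,
                                    depth = spec$depth) {
  k <- spec$kernel_size; z <- spec$base_filters; n <- as.integer(depth)
  if (is.null(latent_channels))
    latent_channels <- if (n >= 1L) z * 2L^(n - 1L) else
      stop("latent_channels must be given for a depth-0 decoder")
  with_seed(seed, function() {
    blocks <- list()
    cin <- latent_channels
    if (n >= 1L) {
      blocks <- vector("list", n)
      for (j in rev(seq_len(n))) {       # block j acts at resolution level j
        cout <- z * 2L^(j - 1L)
        blocks[[j]] <- he_init(k, cin, cout)
        cin <- cout
      }
    }
    final <- he_init(k, cin, out_channels, scale = 1)
    structure(list(spec = spec, depth = n, seed = as.integer(seed),
                   latent_channels = as.integer(latent_channels),
                   out_channels = as.integer(out_channels),
                   params = list(blocks = blocks, final = final)),
              class = "inversion_decoder")
  })
}

inv_forward <- function(decoder, Z, keep = FALSE) {
  k <- decoder$spec$kernel_size; n <- decoder$depth
  if (length(dim(Z)) == 3L) dim(Z) <- c(dim(Z), 1L)
  if (dim(Z)[4] != decoder$latent_channels)
    stop("latent code has ", dim(Z)[4], " channels; decoder expects ",
         decoder$latent_channels)
  h <- Z
  caches <- masks <- vector("list", max(n, 0L))
  for (j in rev(seq_len(n))) {
    h <- upsample3(h)
    cv <- conv_fwd(h, decoder$params$blocks[[j]]$W, decoder$params$blocks[[j]]$b, k)
    # leaky ReLU: a rectifier that cannot die wholesale, which matters for a
    # decoder whose gradients all pass through few channels
    h <- ifelse(cv$y > 0, cv$y, 0.01 * cv$y)
    if (keep) { caches[[j]] <- cv; masks[[j]] <- cv$y > 0 }
  }
  fin <- conv_fwd(h, decoder$params$final$W, decoder$params$final$b, k)
  list(xhat = fin$y, final_cache = fin, caches = caches, masks = masks)
}

inv_forward_backward <- function(decoder, Z, X) {
  k <- decoder$spec$kernel_size; n <- decoder$depth
  fw <- inv_forward(decoder, Z, keep = TRUE)
  X4 <- as_input4(X)
  diff <- fw$xhat - X4
  nv <- length(diff)
  loss <- mean(diff^2)
  dl <- 2 * diff / nv
  grads <- list(blocks = vector("list", max(n, 0L)), final = NULL)
  bw <- conv_bwd(fw$final_cache, decoder$params$final$W, k, dl)
  grads$final <- list(W = bw$gW, b = bw$gb)
  g <- bw$gx
  for (j in seq_len(n)) {
    g <- g * ifelse(fw$masks[[j]], 1, 0.01)
    bw <- conv_bwd(fw$caches[[j]], decoder$params$blocks[[j]]$W, k, g)
    grads$blocks[[j]] <- list(W = bw$gW, b = bw$gb)
    g <- upsample3_bwd(bw$gx)
  }
  list(loss = loss, grads = grads)
}

#' Reconstruct a volume from a latent code
#'
#' Deterministic decoder forward pass: \eqn{\hat X = \hat D(Z)}.
#'
#' @param decoder A trained \code{inversion_decoder}.
#' @param Z Latent code from \code{\link{encode}}.
#' @return 3D array (the single output channel dropped), with spatial size
#'   \code{2^depth} times the latent grid.
#' @export
reconstruct <- function(decoder, Z) {
  out <- inv_forward(decoder, Z, keep = FALSE)$xhat
  if (dim(out)[4] == 1L) dim(out) <- dim(out)[1:3]
  out
}

#' A fixed linear "encoder" (analysis tool)
#'
#' Applies an arbitrary matrix voxel-wise across channels: \code{Z_c = sum_j
#' Q[c, j] X_j}, with no pooling or nonlinearity. With orthonormal \code{Q}
#' this is an exactly invertible encoder (inverse \code{t(Q)}), giving a
#' closed-form oracle for what a perfect inversion attack can achieve.
#'
#' @param Q Mixing matrix (channels out x channels in).
#' @return A \code{linear_encoder} usable wherever an encoder is expected.
#' @export
linear_encoder <- function(Q) {
  Q <- as.matrix(Q)
  structure(list(Q = Q,
                 spec = network_spec(kernel_size = 1L, base_filters = nrow(Q),
                                     depth = 1L, num_classes = 2L)),
            class = "linear_encoder")
}

#' @export
encode.linear_encoder <- function(model, X) {
  X <- as_input4(X)
  d <- dim(X)
  if (d[4] != ncol(model$Q)) stop("channel mismatch with mixing matrix")
  zm <- matrix(X, ncol = d[4]) %*% t(model$Q)
  dim(zm) <- c(d[1:3], nrow(model$Q))
  zm
}

encoder_params <- function(encoder) {
  if (inherits(encoder, "seg_model")) encoder$params$enc
  else if (inherits(encoder, "linear_encoder")) encoder$Q
  else stop("unknown encoder type")
}

#' Train the inversion decoder on the attacker's cohort
#'
#' The attacker holds an independent image database and, for each of its
#' images, the latent code produced by the frozen target encoder. The decoder
#' is trained with Adam to minimize the mean squared reconstruction error
#' \eqn{\|\hat X - X\|^2} over the attacker cohort, with an optional held-out
#' split for early stopping (best-validation weights are restored). The
#' encoder is used only through \code{\link{encode}} and is returned
#' bit-identical to how it was received.
#'
#' @param encoder The frozen target encoder (\code{seg_model} or
#'   \code{linear_encoder}).
#' @param attack_images List of preprocessed attacker volumes (arrays).
#' @param cfg A \code{\link{train_config}} (its \code{val_fraction} and
#'   \code{patience} control early stopping).
#' @param decoder Optional pre-built \code{inversion_decoder}; by default one
#'   mirroring the encoder's spec is built under \code{cfg$seed}.
#' @return The trained decoder with \code{trace} (data.frame of train and
#'   validation loss per epoch) attached.
#' @export
train_inversion_decoder <- function(encoder, attack_images, cfg, decoder = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  latents <- lapply(attack_images, function(X) encode(encoder, X))
  p_before <- encoder_params(encoder)
  if (is.null(decoder)) {
    lc <- dim(latents[[1]])
    lc <- if (length(lc) >= 4L) lc[4] else 1L
    decoder <- build_inversion_decoder(encoder$spec, latent_channels = lc,
                                       seed = cfg$seed)
  }
  nA <- length(attack_images)
  params <- decoder$params
  state <- adam_state_init(params)
  t <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  tr_loss <- val_loss <- rep(NA_real_, cfg$epochs)
  with_seed(derive_seed(cfg$seed, 97L), function() {
    n_val <- if (cfg$val_fraction > 0 && nA >= 5L)
      max(1L, floor(cfg$val_fraction * nA)) else 0L
    val_idx <- if (n_val > 0) sample(nA, n_val) else integer(0)
    train_idx <- setdiff(seq_len(nA), val_idx)
    since_best <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- train_idx[sample(length(train_idx))]
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        decoder$params <- params
        fb <- inv_forward_backward(decoder, latents[[ord[i]]],
                                   attack_images[[ord[i]]])
        losses[i] <- fb$loss
        t <<- t + 1L
        res <- adam_step(params, fb$grads, state, t, cfg$learning_rate)
        params <<- res$p
        state <<- res$s
      }
      tr_loss[ep] <<- mean(losses)
      decoder$params <- params
      monitor <- if (n_val > 0) {
        mean(vapply(val_idx, function(i) {
          fw <- inv_forward(decoder, latents[[i]])
          mean((fw$xhat - as_input4(attack_images[[i]]))^2)
        }, 0))
      } else tr_loss[ep]
      val_loss[ep] <<- monitor
      if (monitor < best$loss) {
        best <<- list(loss = monitor, params = params, epoch = ep)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= cfg$patience) break
      }
    }
  })
  if (!identical(p_before, encoder_params(encoder)))
    stop("contract violation: encoder parameters changed during the attack")
  decoder$params <- best$params
  keep <- !is.na(tr_loss)
  decoder$trace <- data.frame(epoch = which(keep), train = tr_loss[keep],
                              monitor = val_loss[keep])
  decoder$best_epoch <- best$epoch
  decoder
}

#' Run the full model-inversion attack on a private cohort
#'
#' Trains the inversion decoder on the attacker cohort only (leakage is
#' guarded by a subject-id audit), then reconstructs every private subject
#' from its latent code. Following the study's threat model, the private
#' latent codes are assumed to be available to the attacker.
#'
#' @param model The trained target segmentation model.
#' @param private List of preprocessed private \code{subject}s (the model's
#'   training cohort).
#' @param attackers List of preprocessed attacker \code{subject}s, disjoint
#'   from the private cohort.
#' @param cfg A \code{\link{train_config}} for the decoder training.
#' @return An \code{attack_result}: named list of reconstructions (one per
#'   private subject), the decoder and its trace, and the two id sets.
#' @export
run_attack <- function(model, private, attackers, cfg) {
  pids <- vapply(private, `[[`, "", "subject_id")
  aids <- vapply(attackers, `[[`, "", "subject_id")
  overlap <- intersect(pids, aids)
  if (length(overlap) > 0)
    stop("leakage: subjects in both private and attacker cohorts: ",
         paste(overlap, collapse = ", "))
  decoder <- train_inversion_decoder(model, lapply(attackers, `[[`, "image"), cfg)
  recon <- lapply(private, function(s) reconstruct(decoder, encode(model, s$image)))
  names(recon) <- pids
  structure(list(reconstructions = recon, decoder = decoder,
                 trace = decoder$trace, private_ids = pids, attacker_ids = aids,
                 seed = cfg$seed),
            class = "attack_result")
}

#' Write an attack result to disk
#'
#' Reconstructions as NIfTI volumes plus a JSON metadata file (ids, seed,
#' decoder spec, loss trace).
#'
#' @param result An \code{attack_result}.
#' @param directory Output directory.
#' @return Invisibly the metadata list.
#' @export
write_attack_result <- function(result, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (id in names(result$reconstructions)) {
    RNifti::writeNifti(RNifti::asNifti(result$reconstructions[[id]]),
                       file.path(directory, paste0(id, "_recon.nii.gz")))
  }
  meta <- list(private_ids = result$private_ids,
               attacker_ids = result$attacker_ids,
               seed = result$seed,
               decoder_spec = unclass(result$decoder$spec),
               best_epoch = result$decoder$best_epoch,
               trace = result$trace)
  jsonlite::write_json(meta, file.path(directory, "attack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}
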