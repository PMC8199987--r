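#' Seeded k-fold private/attacker split
#'
#' Partitions the cohort ids into k folds; in each fold one part is the
#' private database (used to train the target segmentation network) and the
#' complement is the attacker database (used to train the inversion decoder).
#' Every subject is private in exactly one fold, so across folds each subject
#' is reconstructed exactly once.
#'
#' @param cohort_ids Character vector of subject ids.
#' @param k Number of folds; must divide the cohort size.
#' @param seed Seed of the random partition.
#' @return List of \code{fold_split}s, each with \code{fold_id},
#'   \code{private_ids} and \code{attacker_ids}.
#' @export
make_folds <- function(cohort_ids, k, seed = 1L) {
  n <- length(cohort_ids)
  if (n %% k != 0) stop("fold count ", k, " does not divide cohort size ", n)
  per <- n %/% k
  with_seed(seed, function() {
    perm <- sample(cohort_ids)
    lapply(seq_len(k), function(f) {
      priv <- perm[((f - 1L) * per + 1L):(f * per)]
      structure(list(fold_id = f, private_ids = priv,
                     attacker_ids = setdiff(cohort_ids, priv)),
                class = "fold_split")
    })
  })
}

#' Configuration of a full inversion-attack experiment
#'
#' Bundles everything a run needs: the phantom-generator parameters, cohort
#' size and fold count, the architecture grid (U-Net and SegNet-style by
#' default), the two training configurations, the metric list and the master
#' seed from which all per-stage seeds are derived.
#'
#' The default is the desk-scale study: 16 subjects at 32^3 voxels, depth-2
#' networks with 4 base filters, 4 folds of 4 private / 12 attacker subjects.
#'
#' @param n_subjects Cohort size.
#' @param k_folds Folds (must divide \code{n_subjects}).
#' @param phantom \code{\link{phantom_params}}.
#' @param archs Named list of \code{\link{network_spec}}s to attack.
#' @param seg_epochs,inv_epochs Training epochs for segmentation / inversion.
#' @param seg_lr,inv_lr Adam learning rates for the two trainings (the tiny
#'   segmentation nets tolerate a larger step than the inversion decoder).
#' @param metrics Character subset of \code{c("ssim", "mcc", "dice",
#'   "deform")}; \code{"deform"} (registration-based) is costly and off by
#'   default.
#' @param seed Master seed.
#' @return An \code{experiment_config}.
#' @export
experiment_config <- function(n_subjects = 16L, k_folds = 4L,
                              phantom = phantom_params(),
                              archs = list(
                                unet = network_spec(base_filters = 4L, depth = 2L,
                                                    skip_connections = TRUE),
                                segnet = network_spec(base_filters = 4L, depth = 2L,
                                                      skip_connections = FALSE)),
                              seg_epochs = 25L, inv_epochs = 30L,
                              seg_lr = 5e-3, inv_lr = 1e-3,
                              metrics = c("ssim", "mcc", "dice"),
                              seed = 1L) {
  if (n_subjects %% k_folds != 0) stop("k_folds must divide n_subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 k_folds = as.integer(k_folds), phantom = phantom,
                 archs = archs, seg_epochs = as.integer(seg_epochs),
                 inv_epochs = as.integer(inv_epochs),
                 seg_lr = seg_lr, inv_lr = inv_lr,
                 metrics = metrics, seed = as.integer(seed)),
            class = "experiment_config")
}

masked_ssim <- function(a, b, ma, mb) {
  ssim(a, b, data_range = 1, mask = ma | mb)
}

masked_corr <- function(a, b, ma, mb) {
  intensity_correlation(a, b, mask = ma | mb)
}

#' Run the full inversion-attack study
#'
#' For every architecture and fold: generate/preprocess the cohort, train the
#' target segmentation network on the private subjects, run the attack (train
#' the inversion decoder on the attacker subjects, reconstruct the private
#' ones), and score all reconstructions against all originals. Results are
#' aggregated over folds into per-architecture metric matrices (one row per
#' subject, since each subject is private exactly once), identification rank
#' summaries, and segmentation-degradation tables. Everything derives from
#' \code{cfg$seed}: stage seeds for cohort, folds, initialization and
#' shuffling come from a fixed derivation tree, so a run is bit-reproducible.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param cohort Optional pre-built \code{cohort} (defaults to generating one
#'   from \code{cfg}); any NIfTI cohort read with \code{\link{read_cohort}}
#'   can be substituted for the synthetic one.
#' @param verbose Print per-stage progress.
#' @return An \code{attack_report}; see \code{\link{build_report}} for the
#'   formatted tables.
#' @export
run_experiment <- function(cfg, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("generating cohort of %d phantoms", cfg$n_subjects)
    cohort <- generate_cohort(cfg$phantom, cfg$n_subjects,
                              seed = derive_seed(cfg$seed, 1L))
  }
  depth_max <- max(vapply(cfg$archs, `[[`, 0L, "depth"))
  divisor <- 2L^depth_max
  lut <- NULL
  if (cfg$phantom$with_skull)           # skull is background for the task
    lut <- c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 0L)
  say("preprocessing (bias correction, normalization, padding to /%d)", divisor)
  prep <- lapply(cohort$subjects, preprocess_subject, divisor = divisor,
                 correct_bias = cfg$phantom$bias_amplitude > 0, lut = lut)
  names(prep) <- vapply(prep, `[[`, "", "subject_id")
  ids <- names(prep)
  folds <- make_folds(ids, cfg$k_folds, seed = derive_seed(cfg$seed, 2L))

  originals <- lapply(prep, `[[`, "image")
  masks <- lapply(prep, brain_mask)

  arch_results <- list()
  dice_rows <- list()
  for (ai in seq_along(cfg$archs)) {
    arch <- names(cfg$archs)[ai]
    spec <- cfg$archs[[ai]]
    recons <- list()
    fold_models <- list()
    for (fold in folds) {
      f <- fold$fold_id
      say("[%s] fold %d: training segmentation on %d private subjects",
          arch, f, length(fold$private_ids))
      private <- prep[fold$private_ids]
      attackers <- prep[fold$attacker_ids]
      # leakage audit at the pipeline level, independent of run_attack's own
      stopifnot(length(intersect(fold$private_ids, fold$attacker_ids)) == 0)
      model <- build_model(spec, seed = derive_seed(cfg$seed, 100L * ai + 10L * f + 1L))
      seg_cfg <- train_config(epochs = cfg$seg_epochs,
                              learning_rate = cfg$seg_lr,
                              seed = derive_seed(cfg$seed, 100L * ai + 10L * f + 2L),
                              loss_name = "cross_entropy")
      model <- train_segmentation(model, private, seg_cfg)
      say("[%s] fold %d: attack (inversion decoder on %d attackers)",
          arch, f, length(attackers))
      inv_cfg <- train_config(epochs = cfg$inv_epochs,
                              learning_rate = cfg$inv_lr,
                              seed = derive_seed(cfg$seed, 100L * ai + 10L * f + 3L),
                              loss_name = "mse")
      att <- run_attack(model, private, attackers, inv_cfg)
      recons <- c(recons, att$reconstructions)
      fold_models[[f]] <- model
      if ("dice" %in% cfg$metrics) {
        for (id in fold$private_ids) {
          dice_rows[[length(dice_rows) + 1L]] <- data.frame(
            arch = arch, fold = f, subject_id = id,
            dice_original = resegmentation_dice(model, prep[[id]]$image,
                                                prep[[id]]$labels),
            dice_reconstruction = resegmentation_dice(model,
                                                      att$reconstructions[[id]],
                                                      prep[[id]]$labels))
        }
      }
    }
    recons <- recons[ids]               # cohort order; square id universe
    arch_results[[arch]] <- list(arch = arch, spec = spec,
                                 reconstructions = recons, models = fold_models)
  }
  for (arch in names(arch_results)) {
    say("[%s] scoring metric matrices", arch)
    res <- arch_results[[arch]]
    n <- length(ids)
    if ("ssim" %in% cfg$metrics) {
      m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- masked_ssim(res$reconstructions[[i]], originals[[j]],
                               masks[[i]], masks[[j]])
      res$ssim <- structure(m, higher_is_better = TRUE,
                            class = c("metric_matrix", "matrix"))
      res$ssim_ranks <- rank_true_matches(res$ssim)
    }
    if ("mcc" %in% cfg$metrics) {
      m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- masked_corr(res$reconstructions[[i]], originals[[j]],
                               masks[[i]], masks[[j]])
      res$mcc <- structure(m, higher_is_better = TRUE,
                           class = c("metric_matrix", "matrix"))
      res$mcc_ranks <- rank_true_matches(res$mcc)
    }
    if ("deform" %in% cfg$metrics) {
      m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- deformation_score(res$reconstructions[[i]], originals[[j]],
                                     mask = masks[[j]])
      res$deform <- structure(m, higher_is_better = FALSE,
                              class = c("metric_matrix", "matrix"))
      res$deform_ranks <- rank_true_matches(res$deform)
    }
    arch_results[[arch]] <- res
  }
  dice_tab <- if (length(dice_rows) > 0) do.call(rbind, dice_rows) else NULL
  structure(list(config = cfg, folds = folds, originals = originals,
                 masks = masks,
                 skull_condition = if (cfg$phantom$with_skull) "with_skull"
                                   else "skull_stripped",
                 arch = arch_results,
                 dice_table = dice_tab,
                 subject_ids = ids),
            class = "attack_report")
}

#' Single-fold attack: reconstruction quality under one condition
#'
#' Runs one private/attacker fold of the study (by default the first fold of
#' the seeded 4-way split of 16 subjects) for one architecture and returns
#' the mean SSIM between each private subject's reconstruction and its true
#' original. This is the unit used to contrast acquisition conditions (e.g.
#' skull-stripped vs with-skull phantoms) at a fraction of the cost of the
#' full cross-validated study.
#'
#' @param phantom \code{\link{phantom_params}} describing the condition.
#' @param spec Architecture to attack (default desk-scale U-Net).
#' @param seed Master seed (cohort, fold, init, shuffling).
#' @param n_subjects,k_folds Cohort size and split (defaults 16 and 4, i.e.
#'   4 private / 12 attackers).
#' @param seg_epochs,inv_epochs,seg_lr,inv_lr Training settings as in
#'   \code{\link{experiment_config}}.
#' @return List with \code{mean_ssim}, per-subject \code{ssim}, and the
#'   \code{fold} used.
#' @export
single_fold_attack <- function(phantom, spec = network_spec(base_filters = 4L,
                                                            depth = 2L),
                               seed = 1L, n_subjects = 16L, k_folds = 4L,
                               seg_epochs = 25L, inv_epochs = 30L,
                               seg_lr = 5e-3, inv_lr = 1e-3) {
  cohort <- generate_cohort(phantom, n_subjects, seed = derive_seed(seed, 1L))
  divisor <- 2L^spec$depth
  lut <- if (phantom$with_skull)
    c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 0L) else NULL
  prep <- lapply(cohort$subjects, preprocess_subject, divisor = divisor,
                 correct_bias = phantom$bias_amplitude > 0, lut = lut)
  names(prep) <- vapply(prep, `[[`, "", "subject_id")
  fold <- make_folds(names(prep), k_folds, seed = derive_seed(seed, 2L))[[1]]
  model <- build_model(spec, seed = derive_seed(seed, 111L))
  model <- train_segmentation(model, prep[fold$private_ids],
                              train_config(epochs = seg_epochs,
                                           learning_rate = seg_lr,
                                           seed = derive_seed(seed, 112L)))
  att <- run_attack(model, prep[fold$private_ids], prep[fold$attacker_ids],
                    train_config(epochs = inv_epochs, learning_rate = inv_lr,
                                 seed = derive_seed(seed, 113L),
                                 loss_name = "mse"))
  sv <- vapply(fold$private_ids, function(id)
    ssim(att$reconstructions[[id]], prep[[id]]$image,
         mask = brain_mask(prep[[id]])), 0)
  list(mean_ssim = mean(sv), ssim = sv, fold = fold)
}

#' Summary tables of an attack report
#'
#' Produces the study's three table analogues: (1) mean +/- SD of each
#' similarity metric between reconstructions and their true originals, per
#' architecture; (2) the same against all other subjects' originals (the
#' baseline that shows reconstructions are subject-specific); (3) match
#' counts and mean identification ranks per metric. SDs are reported both
#' across subjects pooled over folds and across fold means.
#'
#' @param report An \code{attack_report} from \code{\link{run_experiment}}.
#' @return List of data.frames: \code{similarity}, \code{identification},
#'   \code{dice}.
#' @export
build_report <- function(report) {
  stopifnot(inherits(report, "attack_report"))
  sim_rows <- list()
  id_rows <- list()
  for (arch in names(report$arch)) {
    res <- report$arch[[arch]]
    fold_of <- integer(length(report$subject_ids))
    names(fold_of) <- report$subject_ids
    for (f in report$folds) fold_of[f$private_ids] <- f$fold_id
    for (metric in intersect(c("ssim", "mcc", "deform"), names(res))) {
      m <- res[[metric]]
      di <- diag(m)
      oth <- (rowSums(m) - di) / (ncol(m) - 1)
      fold_means <- tapply(di, fold_of[rownames(m)], mean)
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        arch = arch, metric = metric, condition = report$skull_condition,
        with_originals_mean = mean(di), with_originals_sd = sd(di),
        with_others_mean = mean(oth), with_others_sd = sd(oth),
        sd_across_fold_means = sd(fold_means))
      rs <- res[[paste0(metric, "_ranks")]]
      id_rows[[length(id_rows) + 1L]] <- data.frame(
        arch = arch, metric = metric, condition = report$skull_condition,
        match_count = rs$match_count, n = length(rs$ranks),
        mean_rank = rs$mean_rank)
    }
  }
  dice_df <- report$dice_table
  dice_sum <- NULL
  if (!is.null(dice_df) && nrow(dice_df) > 0) {
    dice_sum <- do.call(rbind, lapply(split(dice_df, dice_df$arch), function(d)
      data.frame(arch = d$arch[1],
                 dice_original_mean = mean(d$dice_original),
                 dice_original_sd = sd(d$dice_original),
                 dice_reconstruction_mean = mean(d$dice_reconstruction),
                 dice_reconstruction_sd = sd(d$dice_reconstruction))))
    rownames(dice_sum) <- NULL
  }
  list(similarity = do.call(rbind, sim_rows),
       identification = do.call(rbind, id_rows),
       dice = dice_sum, per_subject_dice = dice_df)
}

#' Write report tables to CSV/JSON
#'
#' @param report An \code{attack_report}.
#' @param directory Output directory.
#' @return Invisibly the list of tables.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tabs <- build_report(report)
  for (nm in c("similarity", "identification")) {
    utils::write.csv(tabs[[nm]], file.path(directory, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(tabs$dice))
    utils::write.csv(tabs$dice, file.path(directory, "dice.csv"), row.names = FALSE)
  if (!is.null(tabs$per_subject_dice))
    utils::write.csv(tabs$per_subject_dice,
                     file.path(directory, "dice_per_subject.csv"), row.names = FALSE)
  for (arch in names(report$arch)) {
    for (metric in intersect(c("ssim", "mcc", "deform"), names(report$arch[[arch]])))
      utils::write.csv(as.data.frame(unclass(report$arch[[arch]][[metric]])),
                       file.path(directory, paste0(metric, "_", arch, ".csv")))
  }
  jsonlite::write_json(
    list(seed = report$config$seed,
         n_subjects = report$config$n_subjects,
         k_folds = report$config$k_folds,
         condition = report$skull_condition),
    file.path(directory, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(tabs)
}
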