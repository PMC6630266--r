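#' Leave-one-subject-out cross-validation folds
#'
#' One fold per subject: that subject's recordings form the test set and all
#' other subjects form the training set, so no individual's data can leak
#' across the split. Folds are ordered by subject id.
#'
#' @param subject_ids integer vector of the subject id of every recording
#'   (e.g. `manifest$subject_id`), or a dataset manifest data frame.
#' @return object of class `cv_split`: list of folds, each with
#'   `train_subjects`, `test_subject`, `train_idx`, `test_idx`.
#' @export
loso_split <- function(subject_ids) {
  if (is.data.frame(subject_ids)) subject_ids <- subject_ids$subject_id
  if (anyNA(subject_ids)) stop("manifest contains missing subject ids")
  subjects <- sort(unique(subject_ids))
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  folds <- lapply(subjects, function(s) {
    list(train_subjects = setdiff(subjects, s), test_subject = s,
         train_idx = which(subject_ids != s),
         test_idx = which(subject_ids == s))
  })
  structure(folds, class = "cv_split")
}

#' Confusion counts with falls as the positive class
#'
#' Builds the full 4x4 gesture confusion table and its binary collapse:
#' TP = falls identified as falls, FP = daily activities identified as
#' falls, TN = daily activities identified as daily activities, FN = falls
#' identified as daily activities.
#'
#' @param predictions predicted gesture labels.
#' @param labels true gesture labels (same length).
#' @param positive the positive class (default `"falling"`).
#' @return object of class `confusion_summary`: `table` (4x4), `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(predictions, labels, positive = "falling") {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length")
  }
  lv <- gesture_classes()
  predictions <- factor(as.character(predictions), levels = lv)
  labels <- factor(as.character(labels), levels = lv)
  if (anyNA(labels)) stop("labels outside the four gesture classes")
  tab <- table(truth = labels, predicted = predictions)
  pos_t <- labels == positive
  pos_p <- predictions == positive
  structure(list(table = tab,
                 TP = sum(pos_t & pos_p), FP = sum(!pos_t & pos_p),
                 TN = sum(!pos_t & !pos_p), FN = sum(pos_t & !pos_p),
                 positive = positive),
            class = "confusion_summary")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Ac = (TP + TN) / (TP + FP + TN + FN) * 100`,
#' `Se = TP / (TP + FN) * 100` (detection rate of falls),
#' `Sp = TN / (FP + TN) * 100` (detection rate of daily activities).
#' An undefined ratio (empty denominator) is reported as `NA` with a
#' diagnostic attribute rather than as 0.
#'
#' @param cs a `confusion_summary`, or a list with `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector `Ac`, `Se`, `Sp` in percent.
#' @export
metrics <- function(cs) {
  tp <- cs$TP; fp <- cs$FP; tn <- cs$TN; fn <- cs$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion summary")
  ac <- 100 * (tp + tn) / total
  se <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  sp <- if (fp + tn == 0) NA_real_ else 100 * tn / (fp + tn)
  out <- c(Ac = ac, Se = se, Sp = sp)
  if (anyNA(out)) {
    attr(out, "diagnostic") <- "Se or Sp undefined: one class absent from the evaluated set"
  }
  out
}

# Per-fold feature preparation: calibrate thresholds on training recordings,
# segment everything, compute spm (PCA fit on training frames only) and rms
# feature tensors. Returns train/test tensor lists with labels.
prepare_fold <- function(recs_filtered, manifest, fold, seg_params,
                         window = 300L, step = 150L, pca_k = 8L,
                         calibration_frac = 0.2, modes = c("spm", "rms")) {
  calib <- calibrate_from_recordings(recs_filtered[fold$train_idx],
                                     seg_params,
                                     calibration_frac = calibration_frac)

  seg_one <- function(i) {
    segs <- segment_recording(recs_filtered[[i]], calib, seg_params)
    if (nrow(segs) == 0L) return(NULL)
    segs$rec_idx <- i
    segs$gesture <- manifest$gesture[i]
    segs$subject_id <- manifest$subject_id[i]
    segs
  }
  seg_train <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(fold$train_idx, seg_one)))
  seg_test <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(fold$test_idx, seg_one)))
  if (is.null(seg_train) || is.null(seg_test)) {
    stop("segmentation produced no usable segments in fold for subject ",
         fold$test_subject)
  }

  spectro <- function(segdf) {
    lapply(seq_len(nrow(segdf)), function(j) {
      r <- recs_filtered[[segdf$rec_idx[j]]]
      seg <- r$samples[(segdf$start_sample[j] + 1):segdf$end_sample[j], ,
                       drop = FALSE]
      if (nrow(seg) < window) return(NULL)
      lapply(seq_len(ncol(seg)), function(ch)
        compute_spectrogram(seg[, ch], fs_hz = r$fs_hz, window = window,
                            step = step))
    })
  }
  sp_train <- spectro(seg_train)
  sp_test <- spectro(seg_test)
  ok_train <- !vapply(sp_train, is.null, logical(1))
  ok_test <- !vapply(sp_test, is.null, logical(1))
  sp_train <- sp_train[ok_train]; seg_train <- seg_train[ok_train, ]
  sp_test <- sp_test[ok_test]; seg_test <- seg_test[ok_test, ]

  out <- list(seg_train = seg_train, seg_test = seg_test, calib = calib)

  if ("spm" %in% modes) {
    train_frames <- do.call(rbind, unlist(lapply(sp_train, function(chs)
      lapply(chs, `[[`, "mag")), recursive = FALSE))
    pca <- fit_pca(train_frames, k = pca_k)
    to_tensor <- function(chs) {
      red <- lapply(chs, apply_pca, model = pca)
      array(unlist(red), dim = c(nrow(red[[1]]), pca_k, length(red)))
    }
    out$pca <- pca
    out$spm_train <- lapply(sp_train, to_tensor)
    out$spm_test <- lapply(sp_test, to_tensor)
  }
  if ("rms" %in% modes) {
    rms_tensor <- function(segdf, j) {
      r <- recs_filtered[[segdf$rec_idx[j]]]
      seg <- r$samples[(segdf$start_sample[j] + 1):segdf$end_sample[j], ,
                       drop = FALSE]
      m <- vapply(seq_len(ncol(seg)), function(ch) {
        fr <- frame_windows(seg[, ch], window = window, step = step)
        apply(fr, 1, function(w) sqrt(mean(w^2)))
      }, numeric((nrow(seg) - window) %/% step + 1))
      if (!is.matrix(m)) m <- matrix(m, nrow = 1)  # single-window segment
      # per-channel min-max, mirroring the spectrogram normalization
      m <- apply(m, 2, function(v) {
        rg <- range(v); if (rg[2] > rg[1]) (v - rg[1]) / (rg[2] - rg[1]) else v * 0
      })
      if (!is.matrix(m)) m <- matrix(m, nrow = 1)
      array(m, dim = c(nrow(m), ncol(seg), 1L))
    }
    out$rms_train <- lapply(seq_len(nrow(seg_train)),
                            function(j) rms_tensor(seg_train, j))
    out$rms_test <- lapply(seq_len(nrow(seg_test)),
                           function(j) rms_tensor(seg_test, j))
  }
  out
}

flatten_for_baseline <- function(tensors) {
  # summarise the variable-length frame axis by per-feature mean and SD
  # (max would be constant 1 under per-channel min-max normalization)
  t(vapply(tensors, function(a) {
    mean_part <- apply(a, c(2, 3), mean)
    sd_part <- apply(a, c(2, 3), stats::sd)
    c(as.numeric(mean_part), as.numeric(sd_part))
  }, numeric(2 * prod(dim(tensors[[1]])[2:3]))))
}

#' Run the full leave-one-subject-out comparison experiment
#'
#' For every fold: band-pass filtered recordings are segmented with
#' thresholds calibrated on training subjects only, features are built (PCA
#' fit on training frames only), each requested method is trained on the
#' training subjects and evaluated on the held-out subject, and
#' accuracy/sensitivity/specificity are computed per fold with falls as the
#' positive class. Timing per method is logged as informational only (it is
#' hardware-dependent).
#'
#' @param dataset a dataset list from [generate_dataset()] (or the same
#'   structure read from disk): `recordings`, `manifest`.
#' @param methods subset of `"idpc"`, `"dpc1"`, `"dpc2"`, `"single"`,
#'   `"svm_rbf"`, `"lda"`, `"knn"`.
#' @param feature_modes subset of `"spm"` (reduced spectrogram) and `"rms"`.
#' @param seed master seed; per-fold/method training seeds derive from it.
#' @param epochs,batch_size,lr CNN training configuration.
#' @param pca_k retained principal components (default 8).
#' @param block_height,block_step network input block geometry in frames.
#' @param seg_n energy window size in samples.
#' @param window,step feature window and hop in samples.
#' @param zero_phase apply the band-pass forward-backward.
#' @param progress print one line per fold/method.
#' @return object of class `semg_experiment`: `report` (per method x mode x
#'   fold data frame), `summary` (per method x mode means), `pooled`
#'   (metrics on the pooled confusion), `confusions`, `config`.
#' @export
run_experiment <- function(dataset,
                           methods = c("idpc", "dpc1", "dpc2", "single",
                                       "svm_rbf"),
                           feature_modes = c("spm", "rms"),
                           seed = 1L, epochs = 50L, batch_size = 32L,
                           lr = 1e-3, pca_k = 8L, block_height = 8L,
                           block_step = 4L, seg_n = 100L,
                           window = 300L, step = 150L, zero_phase = FALSE,
                           progress = FALSE) {
  known <- c("idpc", "dpc1", "dpc2", "single", "svm_rbf", "lda", "knn")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  feature_modes <- match.arg(feature_modes, c("spm", "rms"),
                             several.ok = TRUE)
  fs <- dataset$manifest$fs_hz[1]
  spec <- design_bandpass(fs)
  recs_f <- lapply(dataset$recordings, apply_filter, spec = spec,
                   zero_phase = zero_phase)
  seg_params <- segmentation_params(fs, n = seg_n)
  folds <- loso_split(dataset$manifest)

  cnn_methods <- intersect(methods, c("idpc", "dpc1", "dpc2", "single"))
  base_methods <- intersect(methods, c("svm_rbf", "lda", "knn"))

  report <- list(); confusions <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    fd <- prepare_fold(recs_f, dataset$manifest, fold, seg_params,
                       window = window, step = step, pca_k = pca_k,
                       modes = feature_modes)
    for (mode in feature_modes) {
      tr_tensors <- fd[[paste0(mode, "_train")]]
      te_tensors <- fd[[paste0(mode, "_test")]]
      tr_labels <- fd$seg_train$gesture
      te_labels <- fd$seg_test$gesture
      for (mi in seq_along(methods)) {
        method <- methods[mi]
        t0 <- proc.time()[["elapsed"]]
        if (method %in% cnn_methods) {
          in_shape <- c(block_height, dim(tr_tensors[[1]])[2],
                        dim(tr_tensors[[1]])[3])
          net_seed <- (as.integer(seed) + 97L * fi + 131L * mi) %% 2147483647L
          net <- build_network(method, input_shape = in_shape,
                               seed = net_seed)
          tb <- stack_blocks(tr_tensors, tr_labels, height = block_height,
                             block_step = block_step)
          net <- cnn_train(net, tb$x, tb$y, epochs = epochs,
                           batch_size = batch_size, lr = lr, seed = net_seed)
          pred <- predict_segments(net, te_tensors, height = block_height,
                                   block_step = block_step)$class
        } else {
          xtr <- flatten_for_baseline(tr_tensors)
          xte <- flatten_for_baseline(te_tensors)
          clf <- baseline_classifier(method, xtr, tr_labels)
          pred <- predict(clf, xte)
        }
        elapsed <- proc.time()[["elapsed"]] - t0
        cs <- confusion(pred, te_labels)
        mt <- metrics(cs)
        key <- paste(method, mode, fold$test_subject, sep = "_")
        confusions[[key]] <- cs
        report[[key]] <- data.frame(
          method = method, mode = mode, fold = fi,
          test_subject = fold$test_subject,
          n_segments = length(te_labels),
          Ac = mt[["Ac"]], Se = mt[["Se"]], Sp = mt[["Sp"]],
          seconds = elapsed)
        if (progress) {
          message(sprintf("fold %d subject %d %s/%s: Ac %.1f%%",
                          fi, fold$test_subject, method, mode, mt[["Ac"]]))
        }
      }
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  summary <- do.call(rbind, lapply(split(report,
                                         list(report$method, report$mode),
                                         drop = TRUE), function(d) {
    data.frame(method = d$method[1], mode = d$mode[1], folds = nrow(d),
               mean_Ac = mean(d$Ac, na.rm = TRUE),
               mean_Se = mean(d$Se, na.rm = TRUE),
               mean_Sp = mean(d$Sp, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  pooled <- lapply(split(report, list(report$method, report$mode),
                         drop = TRUE), function(d) {
    keys <- paste(d$method, d$mode, d$test_subject, sep = "_")
    cs <- confusions[keys]
    metrics(list(TP = sum(vapply(cs, `[[`, 0, "TP")),
                 FP = sum(vapply(cs, `[[`, 0, "FP")),
                 TN = sum(vapply(cs, `[[`, 0, "TN")),
                 FN = sum(vapply(cs, `[[`, 0, "FN"))))
  })
  structure(list(report = report, summary = summary, pooled = pooled,
                 confusions = confusions,
                 config = list(methods = methods,
                               feature_modes = feature_modes, seed = seed,
                               epochs = epochs, batch_size = batch_size,
                               lr = lr, pca_k = pca_k,
                               block_height = block_height,
                               block_step = block_step, seg_n = seg_n,
                               window = window, step = step,
                               zero_phase = zero_phase)),
            class = "semg_experiment")
}

#' @export
print.semg_experiment <- function(x, ...) {
  cat("<semg_experiment>", nrow(x$report), "fold-results\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
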