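# End-to-end experiment orchestration: profile computation over a
# temperature sweep, kernel construction, grid-search cross-validation,
# undersampling replicates, and imbalance-aware evaluation on a held-out
# split.

#' Experiment configuration
#'
#' @param temperatures Temperatures in kelvin (default 310..360 step 5).
#' @param bubble_m Bubble size for the profile features (default 8; 1 =
#'   single-base opening).
#' @param kernels Kernel kinds to run, subset of `"sequence-WD"`,
#'   `"profile-RBF"`, `"hybrid"`.
#' @param d_values WD k-mer orders for the CV grid (default 6, 12, 24).
#' @param C_values SVM regularization values (default the 7-point decade
#'   grid 0.001..1000; together with the three orders this is the
#'   21-combination grid).
#' @param folds Cross-validation folds (default 10).
#' @param ir_target Post-undersampling imbalance ratio (default 1:1).
#' @param replicates Independent undersampling repetitions behind the
#'   reported confidence intervals (default 5).
#' @param test_fraction Fraction of instances held out for testing.
#' @param hybrid_weights Component weights of the hybrid kernel (sequence,
#'   profile); default the equal-weight average.
#' @param grid Quadrature grid for the PBD engine.
#' @param params PBD parameters.
#' @param rbf_gamma RBF width (`NULL` = per-temperature heuristic).
#' @param seed Master seed for splits, folds, and undersampling.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(temperatures = seq(310, 360, by = 5),
                              bubble_m = 8,
                              kernels = c("sequence-WD", "profile-RBF", "hybrid"),
                              d_values = c(6, 12, 24),
                              C_values = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                              folds = 10,
                              ir_target = 1.0,
                              replicates = 5,
                              test_fraction = 0.5,
                              hybrid_weights = c(0.5, 0.5),
                              grid = quad_grid(),
                              params = pbd_params(),
                              rbf_gamma = NULL,
                              seed = 1) {
  kernels <- match.arg(kernels, c("sequence-WD", "profile-RBF", "hybrid"),
                       several.ok = TRUE)
  if (any(temperatures < 200 | temperatures > 400)) {
    warning("temperatures outside the physically sane 200-400 K range")
  }
  cfg <- list(temperatures = temperatures, bubble_m = bubble_m,
              kernels = kernels, d_values = d_values, C_values = C_values,
              folds = folds, ir_target = ir_target, replicates = replicates,
              test_fraction = test_fraction, hybrid_weights = hybrid_weights,
              grid = grid, params = params, rbf_gamma = rbf_gamma, seed = seed)
  cfg$n_grid_combinations <- length(d_values) * length(C_values)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment: T = %s K, m = %d, kernels = %s\n",
              paste(range(x$temperatures), collapse = "-"), x$bubble_m,
              paste(x$kernels, collapse = ", ")))
  cat(sprintf("  grid: %d x %d = %d combinations, %d-fold CV, IR %g:1, %d replicates\n",
              length(x$d_values), length(x$C_values), x$n_grid_combinations,
              x$folds, x$ir_target, x$replicates))
  invisible(x)
}

#' Trimmed PBD profiles for every window of a dataset
#'
#' Runs the transfer-integral engine on each 300-base window at one
#' temperature and attaches the 200-value trimmed participation profiles
#' as the dataset's feature matrix.
#'
#' @param ds A `tss_dataset`.
#' @param temperature Kelvin.
#' @param grid,params Engine settings.
#' @param m Bubble size.
#' @return The dataset with `$profiles` set (rows follow `ds$windows`).
#' @export
compute_profiles <- function(ds, temperature, grid = quad_grid(),
                             params = pbd_params(), m = 8) {
  stopifnot(inherits(ds, "tss_dataset"))
  prof <- t(vapply(seq_len(nrow(ds$windows)), function(i) {
    profile_for_window(ds$windows$seq300[i], temperature, grid, params,
                       m = m, sequence_id = ds$windows$id[i])$values
  }, numeric(200)))
  rownames(prof) <- ds$windows$id
  ds$profiles <- prof
  ds
}

# stratified fold assignment, seeded
.make_folds <- function(labels, folds, seed) {
  .with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

# Gram lists per kernel kind over one instance set. seq_grams: named list
# of normalized WD grams per d; prof_gram: RBF gram; returns named list
# "d" -> kernel_gram (RBF: single entry "-").
.kernel_gram_set <- function(kind, seq_grams, prof_gram, hybrid_weights) {
  switch(kind,
         "sequence-WD" = seq_grams,
         "profile-RBF" = list("-" = prof_gram),
         "hybrid" = lapply(seq_grams, hybrid_gram, prof_gram = prof_gram,
                           weights = hybrid_weights),
         stop(sprintf("unknown kernel kind '%s'", kind)))
}

# CV over (gram in gram_list) x C_values; returns best (d, C) + table.
# Ties: highest mean auROC, then smallest C, then smallest d (list order).
.grid_cv <- function(gram_list, labels, C_values, folds, seed) {
  if (folds > min(table(labels))) stop("more folds than minority instances")
  fold_id <- .make_folds(labels, folds, seed)
  tab <- expand.grid(d = names(gram_list), C = C_values,
                     stringsAsFactors = FALSE)
  tab$auroc <- NA_real_
  for (r in seq_len(nrow(tab))) {
    K <- gram_list[[tab$d[r]]]$values
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      if (length(unique(labels[te])) < 2) return(NA_real_)
      g <- new_kernel_gram(K[tr, tr, drop = FALSE], as.character(tr),
                           gram_list[[tab$d[r]]]$config)
      m <- svm_train(g, labels[tr], C = tab$C[r])
      sc <- svm_score(m, K[tr, te, drop = FALSE])
      roc_auroc(sc, labels[te])$auroc
    }, numeric(1))
    tab$auroc[r] <- mean(aucs, na.rm = TRUE)
  }
  best <- tab[order(-tab$auroc, tab$C, match(tab$d, names(gram_list))), ][1, ]
  list(best_d = best$d, best_C = best$C, best_auroc = best$auroc, cv_table = tab)
}

#' Grid-search cross-validation for one kernel kind
#'
#' Stratified k-fold CV over the full `d x C` grid (21 combinations at
#' defaults), selecting the combination with the highest mean validation
#' auROC; ties go to the smallest `C`, then the smallest `d`. For the
#' profile-RBF kernel the order `d` plays no role and the grid reduces to
#' the `C` values.
#'
#' @param ds A `tss_dataset` (with `$profiles` when a profile kernel is
#'   requested).
#' @param config An [experiment_config()].
#' @param kernel One of `"sequence-WD"`, `"profile-RBF"`, `"hybrid"`.
#' @return List with `best_d`, `best_C`, `best_auroc`, and the full
#'   `cv_table`.
#' @export
run_grid_cv <- function(ds, config = experiment_config(), kernel = "sequence-WD") {
  stopifnot(inherits(ds, "tss_dataset"))
  labels <- ds$windows$label
  seq_grams <- NULL; prof_gram <- NULL
  if (kernel %in% c("sequence-WD", "hybrid")) {
    seq_grams <- wd_gram(ds$windows$seq201, d = config$d_values,
                         ids = ds$windows$id, normalize = TRUE)
    if (inherits(seq_grams, "kernel_gram")) {
      seq_grams <- stats::setNames(list(seq_grams), as.character(config$d_values))
    }
  }
  if (kernel %in% c("profile-RBF", "hybrid")) {
    if (is.null(ds$profiles)) stop("dataset has no profiles; run compute_profiles() first")
    prof_gram <- rbf_gram(ds$profiles, gamma = config$rbf_gamma,
                          ids = ds$windows$id)
  }
  gl <- .kernel_gram_set(kernel, seq_grams, prof_gram, config$hybrid_weights)
  .grid_cv(gl, labels, config$C_values, config$folds, config$seed)
}

# stratified train/test split, seeded; returns list(train_idx, test_idx)
.split_holdout <- function(labels, test_fraction, seed) {
  .with_seed(seed, {
    te <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(length(idx) * test_fraction))
    }))
    list(train = sort(setdiff(seq_along(labels), te)), test = sort(te))
  })
}

#' Run the full TSS-prediction experiment
#'
#' For each temperature: compute trimmed bubble-participation profiles for
#' every window, build the sequence-WD, profile-RBF, and hybrid Gram
#' matrices, and for each requested kernel kind repeat `replicates` times:
#' undersample the training split to the target imbalance ratio, pick
#' `(d, C)` by stratified grid-search CV, train on the undersampled set,
#' and score the untouched held-out test split. Reports per temperature x
#' kernel: mean and 95% CI of auROC and G-mean over replicates, plus mean
#' sensitivity/specificity at the zero-score threshold.
#'
#' The whole run is deterministic given `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param ds A `tss_dataset`, e.g. from [make_synthetic()] or
#'   [extract_windows()].
#' @return A data frame with one row per temperature x kernel kind.
#' @export
run_experiment <- function(config, ds) {
  stopifnot(inherits(config, "experiment_config"), inherits(ds, "tss_dataset"))
  labels <- ds$windows$label
  sp <- .split_holdout(labels, config$test_fraction, config$seed)
  tr <- sp$train; te <- sp$test
  y_te <- labels[te]

  # sequence kernels are temperature-independent: build once over all instances
  need_seq <- any(config$kernels %in% c("sequence-WD", "hybrid"))
  seq_all <- NULL
  if (need_seq) {
    seq_all <- wd_gram(ds$windows$seq201, d = config$d_values,
                       ids = ds$windows$id, normalize = TRUE)
    if (inherits(seq_all, "kernel_gram")) {
      seq_all <- stats::setNames(list(seq_all), as.character(config$d_values))
    }
  }
  need_prof <- any(config$kernels %in% c("profile-RBF", "hybrid"))

  rows <- list()
  for (Tk in config$temperatures) {
    prof_all <- NULL
    if (need_prof) {
      dsp <- compute_profiles(ds, Tk, config$grid, config$params,
                              m = config$bubble_m)
      gamma <- config$rbf_gamma %||% rbf_gamma_heuristic(dsp$profiles[tr, , drop = FALSE])
      prof_all <- rbf_gram(dsp$profiles, gamma = gamma, ids = ds$windows$id)
    }
    for (kind in config$kernels) {
      gl_all <- .kernel_gram_set(kind, seq_all, prof_all, config$hybrid_weights)
      reps <- lapply(seq_len(config$replicates), function(r) {
        rep_seed <- config$seed + 1000 * r
        us <- .with_seed(rep_seed, {
          y_tr <- labels[tr]
          minority <- if (sum(y_tr == 1) <= sum(y_tr == -1)) 1 else -1
          n_keep <- round(config$ir_target * sum(y_tr == minority))
          maj <- which(y_tr != minority)
          if (n_keep > length(maj)) stop("target_ir exceeds available majority instances")
          sort(c(which(y_tr == minority), sample(maj, n_keep)))
        })
        idx <- tr[us]
        y_us <- labels[idx]
        gl_us <- lapply(gl_all, function(g) {
          new_kernel_gram(g$values[idx, idx, drop = FALSE],
                          ds$windows$id[idx], g$config)
        })
        cv <- .grid_cv(gl_us, y_us, config$C_values, config$folds, rep_seed)
        g_best <- gl_us[[cv$best_d]]
        model <- svm_train(g_best, y_us, C = cv$best_C)
        K_cross <- gl_all[[cv$best_d]]$values[idx, te, drop = FALSE]
        sc <- svm_score(model, K_cross)
        cc <- confusion_counts(sc, y_te)
        list(auroc = roc_auroc(sc, y_te)$auroc, gmean = gmean(cc),
             sn = cc$TP / (cc$TP + cc$FN), sp = cc$TN / (cc$TN + cc$FP),
             d = cv$best_d, C = cv$best_C)
      })
      get <- function(f) vapply(reps, `[[`, numeric(1), f)
      agg <- function(v) {
        if (length(v) >= 2) ci95(v) else list(mean = mean(v), halfwidth = NA_real_)
      }
      au <- agg(get("auroc")); gm <- agg(get("gmean"))
      rows[[length(rows) + 1]] <- data.frame(
        temperature = Tk, kernel = kind, m = config$bubble_m,
        n_train = length(tr), n_test = length(te),
        auroc = au$mean, auroc_ci = au$halfwidth,
        gmean = gm$mean, gmean_ci = gm$halfwidth,
        sn = mean(get("sn")), sp = mean(get("sp")),
        best_d = paste(unique(vapply(reps, `[[`, character(1), "d")),
                       collapse = "/"),
        best_C = stats::median(get("C")))
    }
  }
  do.call(rbind, rows)
}
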