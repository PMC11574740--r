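# Multi-feature PTE / non-PTE classification: nested leave-one-pair-out
# stratified cross-validation, permutation AUC nulls, linear-SVM feature
# importance, and learning-curve extrapolation.

#' Assemble the subject-by-feature table
#'
#' Concatenates the three feature blocks in fixed order: 15 ROI lesion
#' volumes (`lesvol_*`), 105 Fisher-z connectivity features (`conn_*`), and
#' 15 ROI mean ALFF values (`alff_*`) -- 135 columns. Rows are aligned
#' across blocks by subject id; a subject missing from any block is an
#' error naming it.
#'
#' @param lesion_volumes subjects x 15 matrix, rownames = subject ids.
#' @param connectivity_z subjects x 105 matrix, rownames = subject ids.
#' @param alff_means subjects x 15 matrix, rownames = subject ids.
#' @param labels data.frame with `subject_id` and `group`
#'   (`"PTE"`/`"nonPTE"`).
#' @return a `pte_features` object: list with `x` (matrix), `labels`
#'   (character vector aligned to rows) and `feature_group` (block tag per
#'   column).
#' @export
assemble_features <- function(lesion_volumes, connectivity_z, alff_means,
                              labels) {
  ids <- labels$subject_id
  blocks <- list(lesion = lesion_volumes, connectivity = connectivity_z,
                 alff = alff_means)
  for (nm in names(blocks)) {
    missing <- setdiff(ids, rownames(blocks[[nm]]))
    if (length(missing))
      stop("subject(s) missing from the ", nm, " block: ",
           paste(missing, collapse = ", "))
  }
  les <- lesion_volumes[ids, , drop = FALSE]
  con <- connectivity_z[ids, , drop = FALSE]
  alf <- alff_means[ids, , drop = FALSE]
  colnames(les) <- paste0("lesvol_", gsub(" ", ".", colnames(les)))
  colnames(alf) <- paste0("alff_", gsub(" ", ".", colnames(alf)))
  x <- cbind(les, con, alf)
  rownames(x) <- ids
  structure(list(
    x = x,
    labels = labels$group,
    feature_group = rep(c("lesion", "connectivity", "alff"),
                        c(ncol(les), ncol(con), ncol(alf)))
  ), class = "pte_features")
}

#' Subset a feature table to one block
#' @param features a `pte_features`.
#' @param block `"lesion"`, `"connectivity"`, `"alff"`, or `"all"`.
#' @return a `pte_features` restricted to that block.
#' @export
feature_block <- function(features, block = c("all", "lesion",
                                              "connectivity", "alff")) {
  block <- match.arg(block)
  if (block == "all") return(features)
  keep <- features$feature_group == block
  structure(list(x = features$x[, keep, drop = FALSE],
                 labels = features$labels,
                 feature_group = features$feature_group[keep]),
            class = "pte_features")
}

#' Cross-validation configuration
#'
#' @param method classifier: `"ksvm"` (RBF SVM), `"svm"` (linear SVM),
#'   `"rf"` (random forest), or `"nn"` (32/16/16 multilayer perceptron).
#' @param n_repeats complete leave-one-pair-out passes, each with a fresh
#'   random PTE-to-nonPTE pairing.
#' @param inner_folds stratified folds for inner hyperparameter selection.
#' @param pca_grid candidate PCA component counts (capped at the training
#'   dimension).
#' @param cost_grid SVM cost values.
#' @param gamma_scale_grid multipliers of the `1/p` RBF bandwidth heuristic
#'   (KSVM only).
#' @param rf_trees random-forest size.
#' @param nn_epochs MLP training epochs.
#' @param seed master seed; repeats and fits derive their seeds from it.
#' @return a `pte_cv_config` list.
#' @export
cv_config <- function(method = c("ksvm", "svm", "rf", "nn"),
                      n_repeats = 25, inner_folds = 5,
                      pca_grid = c(5, 10, 20, 40),
                      cost_grid = c(0.1, 1, 10),
                      gamma_scale_grid = c(0.1, 1, 10),
                      rf_trees = 500, nn_epochs = 150, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_repeats >= 1, inner_folds >= 2,
            length(pca_grid) >= 1, length(cost_grid) >= 1)
  structure(list(method = method, n_repeats = as.integer(n_repeats),
                 inner_folds = as.integer(inner_folds),
                 pca_grid = as.integer(pca_grid), cost_grid = cost_grid,
                 gamma_scale_grid = gamma_scale_grid,
                 rf_trees = as.integer(rf_trees),
                 nn_epochs = as.integer(nn_epochs),
                 seed = as.integer(seed)),
            class = "pte_cv_config")
}

# Fit one classifier on standardized PCA scores and return a scoring
# closure (larger score = more PTE-like).
fit_scorer <- function(method, x, y, hyper, config, seed) {
  is_pte <- y == "PTE"
  if (method %in% c("ksvm", "svm")) {
    kern <- if (method == "ksvm") "radial" else "linear"
    gamma <- if (method == "ksvm") hyper$gamma_scale / ncol(x) else 1 / ncol(x)
    fit <- e1071::svm(x = x, y = factor(y, levels = c("nonPTE", "PTE")),
                      kernel = kern, cost = hyper$cost, gamma = gamma,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- if (mean(dv[is_pte]) >= mean(dv[!is_pte])) 1 else -1
    function(newx) {
      flip * attr(stats::predict(fit, newx, decision.values = TRUE),
                  "decision.values")[, 1]
    }
  } else if (method == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x = x, y = factor(y, levels = c("nonPTE", "PTE")),
      ntree = config$rf_trees)
    function(newx) stats::predict(fit, newx, type = "prob")[, "PTE"]
  } else {
    fit <- mlp_fit(x, as.numeric(is_pte), hidden = c(32, 16, 16),
                   epochs = config$nn_epochs, seed = seed)
    function(newx) mlp_predict(fit, newx)
  }
}

hyper_grid <- function(config, p) {
  pca <- unique(pmin(config$pca_grid, p))
  if (config$method == "ksvm") {
    g <- expand.grid(ncomp = pca, cost = config$cost_grid,
                     gamma_scale = config$gamma_scale_grid)
  } else if (config$method == "svm") {
    g <- expand.grid(ncomp = pca, cost = config$cost_grid, gamma_scale = 1)
  } else {
    g <- expand.grid(ncomp = pca, cost = 1, gamma_scale = 1)
  }
  g
}

# Stratified inner-fold assignment: per class, cycle 1..k over a shuffled
# order.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Standardize train/test with training statistics only.
standardize_pair <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  list(tr = sweep(sweep(xtr, 2, mu), 2, sd, `/`),
       te = sweep(sweep(xte, 2, mu), 2, sd, `/`))
}

# Inner selection + final fit on one outer training set. Returns the
# scoring closure for held-out data (in original feature space) and the
# chosen hyperparameters.
tune_and_fit <- function(xtr, ytr, config, seed) {
  std <- standardize_pair(xtr, xtr)
  pc <- stats::prcomp(std$tr, center = FALSE, scale. = FALSE)
  maxcomp <- min(ncol(pc$rotation), nrow(xtr) - 1)
  grid <- hyper_grid(config, maxcomp)
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    folds <- stratified_folds(ytr, config$inner_folds, derive_seed(seed, 11L))
    scores_all <- pc$x
    inner_auc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      h <- grid[gi, ]
      sc <- rep(NA_real_, length(ytr))
      for (f in seq_len(config$inner_folds)) {
        tr <- folds != f; te <- !tr
        if (!any(te) || length(unique(ytr[tr])) < 2) next
        xin <- scores_all[tr, seq_len(h$ncomp), drop = FALSE]
        scorer <- fit_scorer(config$method, xin, ytr[tr], h, config,
                             derive_seed(seed, 100L + gi * 7L + f))
        sc[te] <- scorer(scores_all[te, seq_len(h$ncomp), drop = FALSE])
      }
      ok <- !is.na(sc)
      inner_auc[gi] <- if (length(unique(ytr[ok])) == 2)
        auc_score(sc[ok], ytr[ok] == "PTE") else 0.5
    }
    best <- grid[which.max(inner_auc), ]
  }
  ncomp <- best$ncomp
  scorer <- fit_scorer(config$method,
                       pc$x[, seq_len(ncomp), drop = FALSE], ytr, best,
                       config, derive_seed(seed, 17L))
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2, stats::sd); sd[sd == 0] <- 1
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  list(
    score = function(newx) {
      z <- sweep(sweep(newx, 2, mu), 2, sd, `/`)
      scorer(z %*% rot)
    },
    chosen = best
  )
}

#' Nested leave-one-pair-out cross-validated AUC
#'
#' Each repeat draws a random one-to-one pairing of PTE with non-PTE
#' subjects; each pair in turn is held out as the test fold while
#' standardization, PCA and hyperparameter selection (inner stratified
#' k-fold) are performed on the remaining subjects only. Out-of-fold
#' decision scores are pooled over all pairs into one AUC per repeat.
#'
#' @param features a `pte_features` with balanced groups.
#' @param config a [cv_config()].
#' @return a `pte_cv`: `auc_samples` (one per repeat), `mean`, `sd`,
#'   `scores` (subjects x repeats out-of-fold scores), `chosen`
#'   (hyperparameters per outer fold of the first repeat).
#' @export
nested_cv_auc <- function(features, config = cv_config()) {
  x <- features$x
  y <- features$labels
  pte_i <- which(y == "PTE")
  non_i <- which(y == "nonPTE")
  if (length(pte_i) != length(non_i))
    stop("nested_cv_auc requires balanced groups (",
         length(pte_i), " PTE vs ", length(non_i), " nonPTE)")
  if (length(pte_i) < 3) stop("need at least 3 subjects per group")
  n <- length(pte_i)
  aucs <- numeric(config$n_repeats)
  scores <- matrix(NA_real_, nrow(x), config$n_repeats,
                   dimnames = list(rownames(x), NULL))
  chosen <- NULL
  for (r in seq_len(config$n_repeats)) {
    rseed <- derive_seed(config$seed, r)
    set.seed(rseed)
    pairing <- cbind(pte_i, sample(non_i))
    for (f in seq_len(n)) {
      test_idx <- pairing[f, ]
      train_idx <- setdiff(seq_len(nrow(x)), test_idx)
      fit <- tune_and_fit(x[train_idx, , drop = FALSE], y[train_idx],
                          config, derive_seed(rseed, f))
      scores[test_idx, r] <- fit$score(x[test_idx, , drop = FALSE])
      if (r == 1) chosen <- rbind(chosen, fit$chosen)
    }
    aucs[r] <- auc_score(scores[, r], y == "PTE")
  }
  structure(list(auc_samples = aucs, mean = mean(aucs),
                 sd = stats::sd(aucs), scores = scores, chosen = chosen,
                 method = config$method, config = config),
            class = "pte_cv")
}

#' @export
print.pte_cv <- function(x, ...) {
  cat("Nested leave-one-pair-out CV (", toupper(x$method), "): AUC ",
      format(x$mean, digits = 3),
      if (length(x$auc_samples) > 1)
        paste0(" (sd ", format(x$sd, digits = 2), ", ",
               length(x$auc_samples), " repeats)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Permutation AUC null distribution
#'
#' Repeats one full leave-one-pair-out CV pass per draw with the subject
#' labels randomly permuted within the balanced design, giving the AUC
#' distribution attainable by chance. The observed AUC repeats are compared
#' against the null with a rank-sum test.
#'
#' @param features a `pte_features`.
#' @param config a [cv_config()]; `n_repeats` is forced to 1 per null draw.
#' @param n_null number of label permutations.
#' @param observed optionally a precomputed `pte_cv` for the unpermuted
#'   labels (otherwise computed here).
#' @return a `pte_auc_null`: `null_auc_samples`, `observed`, `p_value`
#'   (rank-sum, observed greater), and a kernel density estimate of the
#'   null.
#' @export
permutation_auc_null <- function(features, config = cv_config(),
                                 n_null = 200, observed = NULL) {
  if (n_null < 10) warning("n_null < 10 gives an unstable p-value")
  if (is.null(observed)) observed <- nested_cv_auc(features, config)
  nulls <- numeric(n_null)
  for (b in seq_len(n_null)) {
    set.seed(derive_seed(config$seed, 5000L + b))
    perm <- sample(features$labels)
    fperm <- structure(list(x = features$x, labels = perm,
                            feature_group = features$feature_group),
                       class = "pte_features")
    cfg1 <- config
    cfg1$n_repeats <- 1L
    cfg1$seed <- derive_seed(config$seed, 6000L + b)
    nulls[b] <- nested_cv_auc(fperm, cfg1)$auc_samples[1]
  }
  p <- suppressWarnings(
    stats::wilcox.test(observed$auc_samples, nulls,
                       alternative = "greater")$p.value)
  structure(list(null_auc_samples = nulls, observed = observed,
                 p_value = p, density = stats::density(nulls)),
            class = "pte_auc_null")
}

#' @export
print.pte_auc_null <- function(x, ...) {
  cat("Permutation AUC null:", length(x$null_auc_samples), "draws, mean",
      format(mean(x$null_auc_samples), digits = 3),
      "; observed", format(x$observed$mean, digits = 3),
      "; rank-sum p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pte_auc_null <- function(x, ...) {
  graphics::plot(x$density, main = "Permutation AUC null",
                 xlab = "AUC", ...)
  graphics::abline(v = x$observed$mean, col = 2, lwd = 2)
  invisible(x)
}

#' Linear-SVM feature importance
#'
#' Fits a linear SVM on the standardized, PCA-reduced full data set,
#' back-projects the hyperplane normal through the PCA rotation to the 135
#' features, and keeps the positive part (features pushing towards the PTE
#' side). ROI-level importance sums each feature's importance into its ROI;
#' connectivity features are split equally between their two ROIs.
#'
#' @param features a `pte_features` (full 135-column table).
#' @param config a [cv_config()]; must be an SVM method. The first
#'   `pca_grid` entry and first `cost_grid` entry are used.
#' @return list with `feature_importance` (named, length = n features) and
#'   `roi_importance` (named, length 15).
#' @export
svm_feature_importance <- function(features, config = cv_config(method = "svm")) {
  if (!config$method %in% c("svm", "ksvm"))
    stop("feature importance requires linear SVM coefficients; method '",
         config$method, "' has none")
  x <- features$x
  y <- features$labels
  std <- standardize_pair(x, x)
  pc <- stats::prcomp(std$tr, center = FALSE, scale. = FALSE)
  ncomp <- min(config$pca_grid[1], ncol(pc$rotation), nrow(x) - 1)
  xs <- pc$x[, seq_len(ncomp), drop = FALSE]
  fit <- e1071::svm(x = xs, y = factor(y, levels = c("nonPTE", "PTE")),
                    kernel = "linear", cost = config$cost_grid[1],
                    scale = FALSE)
  w_pca <- as.vector(crossprod(fit$coefs, fit$SV))
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (mean(dv[y == "PTE"]) < mean(dv[y == "nonPTE"])) w_pca <- -w_pca
  w <- as.vector(pc$rotation[, seq_len(ncomp), drop = FALSE] %*% w_pca)
  names(w) <- colnames(x)
  imp <- pmax(w, 0)
  nm_all <- names(imp)
  if (is.null(nm_all) ||
      !all(grepl("^(lesvol_|alff_|conn_)", nm_all)))
    return(list(feature_importance = imp, roi_importance = NULL))
  roi <- numeric(15)
  names(roi) <- gsub(" ", ".", usc_lobe_names)
  for (k in seq_along(imp)) {
    nm <- names(imp)[k]
    if (startsWith(nm, "lesvol_") || startsWith(nm, "alff_")) {
      r <- sub("^(lesvol|alff)_", "", nm)
      roi[r] <- roi[r] + imp[k]
    } else {
      ab <- strsplit(sub("^conn_", "", nm), "_")[[1]]
      roi[ab[1]] <- roi[ab[1]] + imp[k] / 2
      roi[ab[2]] <- roi[ab[2]] + imp[k] / 2
    }
  }
  list(feature_importance = imp, roi_importance = roi)
}

#' Learning curve of AUC versus sample size
#'
#' For each sample size `n` (total subjects, kept balanced), repeatedly
#' draws a random balanced subset and runs the nested CV, recording the
#' mean and sd of the AUC.
#'
#' @param features a `pte_features`.
#' @param config a [cv_config()].
#' @param n_grid even total sample sizes to evaluate; values below 6 are
#'   skipped with a warning.
#' @param subsets random subsets drawn per sample size.
#' @return a `pte_learning_curve`: data.frame `curve` with `n`, `mean_auc`,
#'   `sd_auc`.
#' @export
learning_curve <- function(features, config = cv_config(), n_grid,
                           subsets = 3) {
  stopifnot(all(n_grid %% 2 == 0), max(n_grid) <= length(features$labels))
  keep <- n_grid >= 6
  if (any(!keep)) {
    warning("skipping n < 6: ", paste(n_grid[!keep], collapse = ", "))
    n_grid <- n_grid[keep]
  }
  pte_i <- which(features$labels == "PTE")
  non_i <- which(features$labels == "nonPTE")
  rows <- lapply(n_grid, function(n) {
    aucs <- c()
    for (s in seq_len(subsets)) {
      set.seed(derive_seed(config$seed, 9000L + n * 31L + s))
      idx <- c(sample(pte_i, n / 2), sample(non_i, n / 2))
      sub <- structure(list(x = features$x[idx, , drop = FALSE],
                            labels = features$labels[idx],
                            feature_group = features$feature_group),
                       class = "pte_features")
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 9500L + n * 31L + s)
      aucs <- c(aucs, nested_cv_auc(sub, cfg)$auc_samples)
    }
    data.frame(n = n, mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
  })
  structure(list(curve = do.call(rbind, rows), config = config),
            class = "pte_learning_curve")
}

#' @export
print.pte_learning_curve <- function(x, ...) {
  cat("Learning curve (", toupper(x$config$method), "):\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pte_learning_curve <- function(x, extrapolation = NULL, ...) {
  cv <- x$curve
  graphics::plot(cv$n, cv$mean_auc, type = "b", pch = 16,
                 ylim = range(c(cv$mean_auc - cv$sd_auc,
                                cv$mean_auc + cv$sd_auc, 0.5, 1)),
                 xlab = "total subjects", ylab = "mean AUC",
                 main = "AUC vs sample size", ...)
  graphics::arrows(cv$n, cv$mean_auc - cv$sd_auc, cv$n,
                   cv$mean_auc + cv$sd_auc,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  if (!is.null(extrapolation)) {
    nn <- seq(min(cv$n), extrapolation$target_n, length.out = 100)
    co <- extrapolation$coefficients
    graphics::lines(nn, pmin(1, pmax(0, co[1] + co[2] * nn + co[3] * nn^2)),
                    lty = 3, col = 2)
  }
  invisible(x)
}

#' Quadratic extrapolation of a learning curve
#'
#' Least-squares quadratic in `n` fitted to the last `fit_last_k` (n, mean
#' AUC) points, evaluated at `target_n` and clipped to \[0, 1\].
#'
#' @param curve a `pte_learning_curve` or a data.frame with `n` and
#'   `mean_auc`.
#' @param fit_last_k number of trailing points to fit (>= 3).
#' @param target_n sample size at which to predict the AUC.
#' @return list with `coefficients` (intercept, linear, quadratic),
#'   `predicted` AUC at `target_n`, `fitted` values and `residuals`.
#' @export
extrapolate_auc <- function(curve, fit_last_k, target_n) {
  cv <- if (inherits(curve, "pte_learning_curve")) curve$curve else curve
  stopifnot(fit_last_k >= 3)
  if (fit_last_k > nrow(cv))
    stop("fit_last_k = ", fit_last_k, " exceeds the ", nrow(cv),
         " available points")
  tail_cv <- utils::tail(cv[order(cv$n), ], fit_last_k)
  fit <- stats::lm(mean_auc ~ n + I(n^2), data = tail_cv)
  co <- unname(stats::coef(fit))
  pred <- co[1] + co[2] * target_n + co[3] * target_n^2
  if (pred > 1 || pred < 0) {
    warning("extrapolated AUC ", format(pred, digits = 3),
            " clipped to [0, 1]")
    pred <- min(1, max(0, pred))
  }
  list(coefficients = co, predicted = pred,
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)),
       fit_last_k = fit_last_k, target_n = target_n)
}

# ---- minimal MLP (32/16/16) ------------------------------------------------

mlp_fit <- function(x, y, hidden = c(32, 16, 16), epochs = 150,
                    lr = 5e-3, seed = 1L, patience = 25) {
  set.seed(seed)
  sizes <- c(ncol(x), hidden, 1)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- he_init(sizes[l], sizes[l + 1], sizes[l])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  opt <- adam_new(params)
  nl <- length(sizes) - 1
  best <- Inf; stall <- 0
  for (ep in seq_len(epochs)) {
    a <- list(x)
    pre <- list()
    for (l in seq_len(nl)) {
      z <- sweep(a[[l]] %*% params[[paste0("W", l)]], 2,
                 params[[paste0("b", l)]], `+`)
      pre[[l]] <- z
      a[[l + 1]] <- if (l < nl) relu(z) else sigmoid(z)
    }
    p <- pmin(pmax(a[[nl + 1]], 1e-7), 1 - 1e-7)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    grads <- list()
    dz <- (p - y) / length(y)
    for (l in nl:1) {
      grads[[paste0("W", l)]] <- crossprod(a[[l]], dz)
      grads[[paste0("b", l)]] <- colSums(dz)
      if (l > 1) {
        dz <- tcrossprod(dz, params[[paste0("W", l)]])
        dz[pre[[l - 1]] <= 0] <- 0
      }
    }
    st <- adam_step(opt, params, grads, lr)
    opt <- st$state; params <- st$params
    if (loss < best - 1e-5) { best <- loss; stall <- 0 } else stall <- stall + 1
    if (stall >= patience) break  # early stopping on the training objective
  }
  list(params = params, nl = nl)
}

mlp_predict <- function(fit, x) {
  a <- x
  for (l in seq_len(fit$nl)) {
    z <- sweep(a %*% fit$params[[paste0("W", l)]], 2,
               fit$params[[paste0("b", l)]], `+`)
    a <- if (l < fit$nl) relu(z) else sigmoid(z)
  }
  as.vector(a)
}
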