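# End-to-end orchestration: generate -> lesion scoring -> features ->
# group statistics -> classification, with per-stage artifact caching so a
# rerun with an identical configuration is a no-op.

#' Extract the three feature blocks from a cohort
#'
#' Runs the lesion-scoring arm (histogram matching to the first subject,
#' VAE training, residual score maps, one-class binarization, ROI lesion
#' volumes) and the functional arm (ROI-mean series, Fisher-z
#' connectivity, ROI mean ALFF), returning the assembled 135-column
#' feature table plus the intermediate maps.
#'
#' @param cohort a `pte_cohort`.
#' @param vae_model optionally a pre-trained `pte_vae`; if `NULL`, one is
#'   trained on the cohort's own slices (lesions are sparse enough that
#'   the VAE treats them as outliers).
#' @param architecture [vae_architecture()] used when training here.
#' @param train_config [vae_train_config()] used when training here.
#' @param nu one-class SVM contamination parameter.
#' @param median_size median filter window for the score maps.
#' @return list with `features` (a `pte_features`), `score_maps`,
#'   `lesion_masks`, `lesion_volumes`, `connectivity_z`, `alff_means`,
#'   `model`.
#' @export
extract_features <- function(cohort, vae_model = NULL,
                             architecture = NULL,
                             train_config = vae_train_config(),
                             nu = 0.1, median_size = 7) {
  parc <- cohort$parcellation
  cfg <- cohort$config
  subjects <- cohort$subjects
  ids <- vapply(subjects, `[[`, "", "subject_id")

  ref <- subjects[[1]]$anat
  anats <- lapply(subjects, function(s)
    histogram_match(s$anat, ref, mask = parc$mask))

  if (is.null(vae_model)) {
    if (is.null(architecture)) {
      side <- max(8, 8 * round(max(cfg$grid_shape[1:2]) / 8))
      architecture <- vae_architecture(input_size = c(side, side),
                                       channels = c(8, 16, 32),
                                       latent_dim = 16)
    }
    slices <- training_slices(anats, architecture$input_size)
    vae_model <- train_vae(slices, architecture, train_config)
  }

  score_maps <- lapply(anats, function(a)
    lesion_score_map(vae_model, a, median_size = median_size)$scores)
  lesion_masks <- binarize_lesions(score_maps, parc$mask, nu = nu)
  lesion_volumes <- t(vapply(lesion_masks, roi_lesion_volumes,
                             numeric(15), parcellation = parc))
  rownames(lesion_volumes) <- ids

  conn_z <- t(vapply(subjects, function(s) {
    connectivity(roi_mean_timeseries(s$ts, parc))$z_vector
  }, numeric(15 * 14 / 2)))
  rownames(conn_z) <- ids
  alff_means <- t(vapply(subjects, function(s) {
    lobe_alff(s$ts, parc, cfg$repetition_interval, cfg$alff_band)
  }, numeric(15)))
  rownames(alff_means) <- ids

  features <- assemble_features(lesion_volumes, conn_z, alff_means,
                                cohort_labels(cohort))
  list(features = features, score_maps = score_maps,
       lesion_masks = lesion_masks, lesion_volumes = lesion_volumes,
       connectivity_z = conn_z, alff_means = alff_means, model = vae_model)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()].
#' @param vae_train a [vae_train_config()].
#' @param vae_arch a [vae_architecture()] or `NULL` for a grid-matched
#'   default.
#' @param cv a [cv_config()].
#' @param nu one-class SVM contamination parameter.
#' @param nperm permutations for the group statistics.
#' @param stages subset of
#'   `c("cohort", "lesions", "features", "stats", "classify")` to enable.
#' @param seed global seed; stage seeds derive from it.
#' @return a `pte_run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       vae_train = vae_train_config(epochs = 5),
                       vae_arch = NULL,
                       cv = cv_config(n_repeats = 5, pca_grid = c(5, 10),
                                      cost_grid = 1, gamma_scale_grid = 1),
                       nu = 0.1, nperm = 200,
                       stages = c("cohort", "lesions", "features",
                                  "stats", "classify"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, vae_train = vae_train,
                 vae_arch = vae_arch, cv = cv, nu = nu,
                 nperm = as.integer(nperm), stages = stages,
                 seed = as.integer(seed)),
            class = "pte_run_config")
}

# Stable hash of an R object via its JSON serialization.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::serializeJSON(x), tf)
  unname(tools::md5sum(tf))
}

stage_done_path <- function(dir, stage) file.path(dir, paste0(stage, ".done.json"))

read_done <- function(dir, stage) {
  p <- stage_done_path(dir, stage)
  if (!file.exists(p)) return(NULL)
  tryCatch(jsonlite::read_json(p), error = function(e) NULL)
}

write_done <- function(dir, stage, hash, info = list()) {
  done <- c(list(stage = stage, hash = hash,
                 build_id = paste0(stage, "-", format(Sys.time(), "%Y%m%d%H%M%S"),
                                   "-", sample.int(1e9, 1)),
                 time = format(Sys.time())), info)
  jsonlite::write_json(done, stage_done_path(dir, stage), auto_unbox = TRUE)
  done
}

#' Run the full marker pipeline
#'
#' Executes the enabled stages in order, writing every artifact under
#' `out_dir` together with a per-stage status file that records the
#' configuration hash and the build ids of its upstream stages. A rerun
#' with an identical configuration skips every completed stage; corrupting
#' one stage's status re-runs exactly that stage and its descendants.
#'
#' @param rc a [run_config()].
#' @return a `pte_run_report`: per-stage status plus the summary tables
#'   (region test table, CV results).
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "pte_run_config"))
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("cohort", "lesions", "features", "stats", "classify")
  stages <- intersect(all_stages, rc$stages)
  status <- list()
  state <- new.env(parent = emptyenv())
  upstream_ids <- character()

  for (stage in stages) {
    expected <- config_hash(list(stage = stage, rc = rc[setdiff(names(rc),
                                                                "out_dir")],
                                 upstream = upstream_ids))
    done <- read_done(rc$out_dir, stage)
    if (!is.null(done) && identical(done$hash, expected)) {
      status[[stage]] <- list(status = "cached", hash = expected,
                              build_id = done$build_id)
      upstream_ids <- c(upstream_ids, done$build_id)
      next
    }
    t0 <- Sys.time()
    info <- run_stage(stage, rc, state)
    done <- write_done(rc$out_dir, stage, expected, info)
    status[[stage]] <- list(status = "ran", hash = expected,
                            build_id = done$build_id,
                            seconds = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")))
    upstream_ids <- c(upstream_ids, done$build_id)
  }

  report <- list(stages = status, out_dir = rc$out_dir,
                 region_tests = read_if(file.path(rc$out_dir,
                                                  "region_tests.tsv"), "\t"),
                 cv_results = if (file.exists(file.path(rc$out_dir,
                                                        "cv_results.json")))
                   jsonlite::read_json(file.path(rc$out_dir, "cv_results.json"),
                                       simplifyVector = TRUE) else NULL)
  class(report) <- "pte_run_report"
  jsonlite::write_json(lapply(status, function(s) s[c("status", "hash")]),
                       file.path(rc$out_dir, "run_report.json"),
                       auto_unbox = TRUE)
  report
}

read_if <- function(path, sep) {
  if (!file.exists(path)) return(NULL)
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Materialize the cohort in memory, from cache if the stage was skipped.
get_cohort <- function(rc, state) {
  if (is.null(state$cohort))
    state$cohort <- generate_cohort(rc$cohort)
  state$cohort
}

# Materialize the lesion/feature products, reloading the lesion artifacts
# written by a cached "lesions" stage when necessary.
get_fx <- function(rc, state, stage) {
  if (!is.null(state$fx)) return(state$fx)
  lv_path <- file.path(rc$out_dir, "lesion_volumes.csv")
  if (!file.exists(lv_path))
    stop("missing upstream artifact for stage '", stage, "': ", lv_path,
         " (enable stage 'lesions')")
  cohort <- get_cohort(rc, state)
  lv <- utils::read.csv(lv_path, check.names = FALSE)
  lesion_volumes <- as.matrix(lv[, -1, drop = FALSE])
  rownames(lesion_volumes) <- lv$subject_id
  ids <- lv$subject_id
  sdir <- file.path(rc$out_dir, "lesion_scores")
  score_maps <- lapply(ids, function(id) {
    p <- file.path(sdir, paste0(id, "_score.nii.gz"))
    if (!file.exists(p))
      stop("missing upstream artifact for stage '", stage, "': ", p)
    read_volume(p)
  })
  parc <- cohort$parcellation
  cfg <- cohort$config
  conn_z <- t(vapply(cohort$subjects, function(s)
    connectivity(roi_mean_timeseries(s$ts, parc))$z_vector,
    numeric(15 * 14 / 2)))
  rownames(conn_z) <- ids
  alff_means <- t(vapply(cohort$subjects, function(s)
    lobe_alff(s$ts, parc, cfg$repetition_interval, cfg$alff_band),
    numeric(15)))
  rownames(alff_means) <- ids
  state$fx <- list(
    features = assemble_features(lesion_volumes, conn_z, alff_means,
                                 cohort_labels(cohort)),
    score_maps = score_maps, lesion_volumes = lesion_volumes,
    connectivity_z = conn_z, alff_means = alff_means
  )
  state$fx
}

run_stage <- function(stage, rc, state) {
  dir <- rc$out_dir
  switch(stage,
    cohort = {
      cohort <- get_cohort(rc, state)
      write_cohort(cohort, file.path(dir, "cohort"))
      list(n_subjects = length(cohort$subjects))
    },
    lesions = {
      cohort <- get_cohort(rc, state)
      tc <- rc$vae_train
      tc$seed <- derive_seed(rc$seed, 21L)
      fx <- extract_features(cohort, architecture = rc$vae_arch,
                             train_config = tc, nu = rc$nu)
      state$fx <- fx
      sdir <- file.path(dir, "lesion_scores")
      dir.create(sdir, showWarnings = FALSE)
      ids <- rownames(fx$lesion_volumes)
      for (i in seq_along(fx$score_maps)) {
        write_volume(fx$score_maps[[i]],
                     file.path(sdir, paste0(ids[i], "_score.nii.gz")))
        write_volume(fx$lesion_masks[[i]] * 1L,
                     file.path(sdir, paste0(ids[i], "_mask.nii.gz")))
      }
      utils::write.csv(data.frame(subject_id = ids, fx$lesion_volumes,
                                  check.names = FALSE),
                       file.path(dir, "lesion_volumes.csv"),
                       row.names = FALSE)
      list(final_loss = fx$model$final_loss)
    },
    features = {
      fx <- get_fx(rc, state, "features")
      feats <- fx$features
      utils::write.csv(data.frame(subject_id = rownames(feats$x), feats$x,
                                  check.names = FALSE),
                       file.path(dir, "features.csv"), row.names = FALSE)
      list(n_features = ncol(feats$x))
    },
    stats = {
      cohort <- get_cohort(rc, state)
      fx <- get_fx(rc, state, "stats")
      groups <- cohort_labels(cohort)$group
      tab <- region_tests(fx$lesion_volumes, fx$alff_means, groups,
                          nperm = rc$nperm, seed = derive_seed(rc$seed, 31L))
      utils::write.table(tab, file.path(dir, "region_tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      vx <- voxelwise_group_analysis(fx$score_maps, groups,
                                     cohort$parcellation$mask,
                                     nperm = rc$nperm,
                                     seed = derive_seed(rc$seed, 32L))
      write_volume(ifelse(is.na(vx$F), 0, vx$F),
                   file.path(dir, "lesion_F.nii.gz"))
      write_volume(vx$sig * 1L, file.path(dir, "lesion_sig.nii.gz"))
      list(n_sig_rois = sum(tab$sig_lesion, na.rm = TRUE))
    },
    classify = {
      fx <- get_fx(rc, state, "classify")
      cfg <- rc$cv
      cfg$seed <- derive_seed(rc$seed, 41L)
      res <- list()
      for (blk in c("lesion", "connectivity", "alff", "all")) {
        cv <- nested_cv_auc(feature_block(fx$features, blk), cfg)
        res[[blk]] <- list(mean_auc = cv$mean, sd_auc = cv$sd)
      }
      jsonlite::write_json(res, file.path(dir, "cv_results.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    stop("unknown stage: ", stage)
  )
}

#' @export
print.pte_run_report <- function(x, ...) {
  cat("Pipeline run in", x$out_dir, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$cv_results)) {
    cat("CV mean AUC:",
        paste(names(x$cv_results),
              vapply(x$cv_results, function(r)
                format(r$mean_auc, digits = 3), ""),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
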