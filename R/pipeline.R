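# End-to-end pipeline: simulate -> split -> train-seg -> segment ->
# train-clf (model 1 and model 2) -> evaluate -> delong-compare, with
# per-stage caching keyed by a configuration hash so interrupted runs
# resume without recomputing upstream stages.

# polynomial rolling hash over the serialized object; cheap, deterministic,
# dependency-free (pure double arithmetic, exact below 2^53)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) {
    h <- (h * 31 + b) %% 281474976710656  # 2^48
  }
  sprintf("%06x%06x", h %/% 16777216, h %% 16777216)
}

# stage seeds fan out from the global seed by hashing the stage name
stage_seed <- function(global_seed, stage) {
  h <- strtoi(substr(config_hash(stage), 1, 7), 16L)
  as.integer((global_seed * 2654435 + h) %% 2147483647)
}

#' Pipeline run configuration
#'
#' Bundles all sub-configurations plus a single global seed from which the
#' per-stage seeds are derived deterministically (so any stage can be rerun
#' in isolation).
#'
#' @param profile `"desk"` (96-pixel phantoms, reduced networks; the
#'   default, sized for a single CPU) or `"paper"` (512-pixel, full-depth
#'   networks and 500-epoch segmentation training).
#' @param n_subjects cohort size.
#' @param seed global integer seed.
#' @param phantom,cohort,roi,seg_model,seg_train,clf_model_1,clf_model_2,clf_train
#'   optional component configurations overriding the profile defaults.
#'   `cohort` may be a [cohort_spec()] whose seed is replaced by the derived
#'   stage seed.
#' @param seg_ratios,clf_ratios split ratios for slices (segmentation) and
#'   subjects (classification).
#' @return an object of class `oppscreen_run_config`.
#' @export
run_config <- function(profile = c("desk", "paper"), n_subjects = 500L,
                       seed = 1L, phantom = NULL, cohort = NULL, roi = NULL,
                       seg_model = NULL, seg_train = NULL,
                       clf_model_1 = NULL, clf_model_2 = NULL,
                       clf_train = NULL, seg_ratios = c(5, 1, 4),
                       clf_ratios = c(5, 1, 4)) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    sp <- seg_desk_profile()
    if (is.null(phantom)) phantom <- desk_phantom_spec()
    if (is.null(seg_model)) seg_model <- sp$model
    if (is.null(seg_train)) seg_train <- sp$train
    if (is.null(clf_model_1)) {
      clf_model_1 <- clf_desk_profile(in_channels = 2L)$model
    }
    if (is.null(clf_model_2)) {
      clf_model_2 <- clf_desk_profile(in_channels = 1L)$model
    }
    if (is.null(clf_train)) clf_train <- clf_desk_profile()$train
  } else {
    pp <- seg_paper_profile()
    if (is.null(phantom)) phantom <- phantom_spec()
    if (is.null(seg_model)) seg_model <- pp$model
    if (is.null(seg_train)) seg_train <- pp$train
    if (is.null(clf_model_1)) clf_model_1 <- clf_model_config(in_channels = 2L)
    if (is.null(clf_model_2)) clf_model_2 <- clf_model_config(in_channels = 1L)
    if (is.null(clf_train)) clf_train <- clf_train_config()
  }
  if (is.null(cohort)) cohort <- cohort_spec(n_subjects = n_subjects)
  if (is.null(roi)) roi <- roi_spec()
  structure(list(profile = profile, seed = as.integer(seed),
                 phantom = phantom, cohort = cohort, roi = roi,
                 seg_model = seg_model, seg_train = seg_train,
                 clf_model_1 = clf_model_1, clf_model_2 = clf_model_2,
                 clf_train = clf_train, seg_ratios = seg_ratios,
                 clf_ratios = clf_ratios),
            class = "oppscreen_run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param config an [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
    }
    x
  }
  yaml::write_yaml(list(profile = config$profile, seed = config$seed,
                        phantom = unclass(config$phantom),
                        cohort = unclass(strip(config$cohort)),
                        roi = unclass(config$roi),
                        seg_model = unclass(config$seg_model),
                        seg_train = unclass(config$seg_train),
                        clf_model_1 = unclass(config$clf_model_1),
                        clf_model_2 = unclass(config$clf_model_2),
                        clf_train = unclass(config$clf_train),
                        seg_ratios = config$seg_ratios,
                        clf_ratios = config$clf_ratios), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rebuild <- function(fields, ctor, keep) {
    do.call(ctor, fields[intersect(names(fields), keep)])
  }
  run_config(
    profile = y$profile, seed = y$seed,
    phantom = rebuild(y$phantom, phantom_spec, names(formals(phantom_spec))),
    cohort = {
      cs <- y$cohort
      cs$bmd_params <- as.data.frame(cs$bmd_params)
      rebuild(cs, cohort_spec, names(formals(cohort_spec)))
    },
    roi = rebuild(y$roi, roi_spec, names(formals(roi_spec))),
    seg_model = rebuild(y$seg_model, seg_model_config,
                        names(formals(seg_model_config))),
    seg_train = rebuild(y$seg_train, seg_train_config,
                        names(formals(seg_train_config))),
    clf_model_1 = rebuild(y$clf_model_1, clf_model_config,
                          names(formals(clf_model_config))),
    clf_model_2 = rebuild(y$clf_model_2, clf_model_config,
                          names(formals(clf_model_config))),
    clf_train = rebuild(y$clf_train, clf_train_config,
                        names(formals(clf_train_config))),
    seg_ratios = y$seg_ratios, clf_ratios = y$clf_ratios)
}

#' Pull all vertebral slices out of a cohort
#'
#' Flattens a [generate_cohort()] result into per-slice lists (two slices
#' per subject), for segmentation training.
#'
#' @param cohort a `phantom_cohort`.
#' @return list with `images`, `masks`, `subject` (subject index per
#'   slice) and `vertebra` (`"l1"`/`"l2"`).
#' @export
cohort_slices <- function(cohort) {
  n <- length(cohort$subjects)
  images <- vector("list", 2L * n)
  masks <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    images[[2L * i - 1L]] <- s$l1_slice
    images[[2L * i]] <- s$l2_slice
    masks[[2L * i - 1L]] <- s$l1_mask
    masks[[2L * i]] <- s$l2_mask
  }
  list(images = images, masks = masks,
       subject = rep(seq_len(n), each = 2L),
       vertebra = rep(c("l1", "l2"), times = n))
}

run_stage <- function(dir, name, hash, quiet, fn) {
  path <- file.path(dir, paste0(name, ".rds"))
  mpath <- file.path(dir, paste0(name, ".manifest.json"))
  if (file.exists(path) && file.exists(mpath)) {
    man <- jsonlite::read_json(mpath)
    if (identical(man$hash, hash)) {
      if (!quiet) message("[", name, "] cached (hash ", hash, ")")
      return(readRDS(path))
    }
  }
  if (!quiet) message("[", name, "] running (hash ", hash, ")")
  t0 <- proc.time()[3]
  out <- fn()
  saveRDS(out, path)
  jsonlite::write_json(list(stage = name, hash = hash,
                            elapsed_s = round(proc.time()[3] - t0, 2),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       mpath, auto_unbox = TRUE)
  out
}

#' Run the full screening pipeline
#'
#' Executes simulate, split, segmentation training, segmentation,
#' classifier training (both variants), evaluation and the per-class
#' DeLong comparison, writing artifacts, reports and stage manifests into
#' `out_dir`. Each stage output is cached under its configuration hash:
#' rerunning with the same configuration reuses finished stages, and
#' deleting a stage file forces only that stage (and its dependents'
#' in-memory recomputation) to rerun.
#'
#' @param config an [run_config()].
#' @param out_dir writable output directory.
#' @param quiet suppress progress messages.
#' @return list with `reports` (per model/dataset classification reports),
#'   `delong` (per-class paired test on the test set), `seg_dsc` (test-set
#'   DSC summary) and the output paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "oppscreen_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ghash <- config_hash(config)

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- stage_seed(config$seed, "simulate")
  h_sim <- config_hash(list(cohort_cfg, config$phantom))
  cohort <- run_stage(out_dir, "simulate", h_sim, quiet, function() {
    generate_cohort(cohort_cfg, config$phantom)
  })

  h_split <- config_hash(list(h_sim, config$seg_ratios, config$clf_ratios,
                              config$seed))
  splits <- run_stage(out_dir, "split", h_split, quiet, function() {
    sl <- cohort_slices(cohort)
    list(
      seg = split_dataset(length(sl$images), config$seg_ratios,
                          seed = stage_seed(config$seed, "split-seg")),
      clf = split_dataset(cohort$metadata$label, config$clf_ratios,
                          stratify = TRUE,
                          seed = stage_seed(config$seed, "split-clf")))
  })

  seg_train_cfg <- config$seg_train
  seg_train_cfg$seed <- stage_seed(config$seed, "train-seg")
  h_seg <- config_hash(list(h_split, config$seg_model, seg_train_cfg))
  segnet <- run_stage(out_dir, "train-seg", h_seg, quiet, function() {
    sl <- cohort_slices(cohort)
    tr <- splits$seg$training
    tu <- splits$seg$validation
    train_segmentation(
      list(images = sl$images[tr], masks = sl$masks[tr]),
      list(images = sl$images[tu], masks = sl$masks[tu]),
      config$seg_model, seg_train_cfg)
  })

  h_segment <- config_hash(list(h_seg, "segment"))
  segmented <- run_stage(out_dir, "segment", h_segment, quiet, function() {
    sl <- cohort_slices(cohort)
    pred <- predict(segnet, sl$images)
    te <- splits$seg$test
    dscs <- vapply(te, function(i) dsc(pred[, , i], sl$masks[[i]]), 1.0)
    list(masks = pred, test_dsc_mean = mean(dscs),
         test_dsc_sd = stats::sd(dscs))
  })

  # classifier inputs: intensities masked by the predicted vertebral mask
  clf_inputs <- function(variant) {
    n <- length(cohort$subjects)
    lapply(seq_len(n), function(i) {
      s <- cohort$subjects[[i]]
      m1 <- s$l1_slice * segmented$masks[, , 2L * i - 1L]
      if (variant == "model2") return(m1)
      m2 <- s$l2_slice * segmented$masks[, , 2L * i]
      fuse_features(m1, m2)
    })
  }

  labels <- cohort$metadata$label
  fit_variant <- function(variant, model_cfg) {
    ct <- config$clf_train
    ct$seed <- stage_seed(config$seed, paste0("train-clf-", variant))
    h <- config_hash(list(h_segment, model_cfg, ct, variant))
    run_stage(out_dir, paste0("train-clf-", variant), h, quiet, function() {
      xs <- clf_inputs(variant)
      tr <- splits$clf$training
      va <- splits$clf$validation
      train_classifier(
        list(images = xs[tr], labels = labels[tr]),
        list(images = xs[va], labels = labels[va]),
        model_cfg, ct)
    })
  }
  clf1 <- fit_variant("model1", config$clf_model_1)
  clf2 <- fit_variant("model2", config$clf_model_2)

  h_eval <- config_hash(list(h_segment, "evaluate", ghash))
  evalout <- run_stage(out_dir, "evaluate", h_eval, quiet, function() {
    reports <- list()
    probs <- list()
    for (variant in c("model1", "model2")) {
      xs <- clf_inputs(variant)
      net <- if (variant == "model1") clf1 else clf2
      for (part in names(splits$clf)) {
        ii <- splits$clf[[part]]
        p <- predict(net, xs[ii], type = "prob")
        reports[[paste(variant, part, sep = ".")]] <-
          classification_report(p, labels[ii], dataset = part)
        probs[[paste(variant, part, sep = ".")]] <- p
      }
    }
    list(reports = reports, probs = probs)
  })

  h_cmp <- config_hash(list(h_eval, "compare"))
  delong <- run_stage(out_dir, "compare", h_cmp, quiet, function() {
    te <- splits$clf$test
    out <- list()
    for (cl in bmd_classes) {
      if (!cl %in% labels[te] || all(labels[te] == cl)) next
      out[[cl]] <- suppressWarnings(
        delong_test(evalout$probs[["model1.test"]][, cl],
                    evalout$probs[["model2.test"]][, cl],
                    labels[te], positive = cl))
    }
    out
  })

  # flat CSV/JSON artifacts
  allrep <- do.call(rbind, Map(function(nm, rp) {
    cbind(model = sub("\\..*$", "", nm), rp)
  }, names(evalout$reports), evalout$reports))
  utils::write.csv(allrep, file.path(out_dir, "classification_reports.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = ghash, seed = config$seed,
         seg_test_dsc = list(mean = segmented$test_dsc_mean,
                             sd = segmented$test_dsc_sd),
         delong = lapply(delong, function(d) {
           list(auc1 = d$auc1, auc2 = d$auc2, z = d$z, p = d$p.value)
         })),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  list(reports = evalout$reports, delong = delong,
       seg_dsc = c(mean = segmented$test_dsc_mean,
                   sd = segmented$test_dsc_sd),
       out_dir = out_dir, config_hash = ghash)
}
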