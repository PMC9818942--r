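# End-to-end pipeline: images -> decomposition -> parametric maps ->
# weighting -> stacks -> grouped split -> augmentation-aware training ->
# evaluation, with on-disk artifacts.

#' Pipeline configuration
#'
#' Bundles every stage choice of the classification pipeline. The
#' defaults are desk-scale (stride-4 maps, 128-px synthetic images, small
#' training budget) so a full run finishes in minutes on one CPU;
#' reference settings are `stride = 1`, `training =
#' training_config()` (batch 60, 4000 iterations).
#'
#' @param transform `"contourlet"` or `"curvelet"`.
#' @param model envelope model for the parametric maps (`"riig"`,
#'   `"nakagami"`, `"nig"`).
#' @param weighting `"correlated"` or `"multiplicative"`.
#' @param subband_keys optional list of six keys (default: the
#'   transform's six-band selection).
#' @param window sliding-window side (pixels).
#' @param stride parameter-map stride (pixels).
#' @param n_per_class synthetic images per class (when no `input_dir`).
#' @param image_size synthetic image side (pixels).
#' @param augment_variants translated copies added per base image.
#' @param max_shift largest augmentation shift (pixels).
#' @param training a [training_config()].
#' @param classifier `"cnn"`, `"svm"`, `"knn"` or `"random_forest"`.
#' @param input_dir optional directory of input images (PNG/BMP) with a
#'   `manifest.csv` (`file`, `label`, `source_id`) or `benign/` and
#'   `malignant/` subdirectories.
#' @param out_dir optional artifact directory.
#' @param seed master seed.
#' @param max_evals per-window likelihood budget for RiIG maps.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(transform = c("contourlet", "curvelet"),
                            model = c("riig", "nakagami", "nig"),
                            weighting = c("correlated", "multiplicative"),
                            subband_keys = NULL, window = 13, stride = 4,
                            n_per_class = 32, image_size = 128,
                            augment_variants = 1, max_shift = 11,
                            training = training_config(batch_size = 12,
                                                       learning_rate = 0.001,
                                                       iterations = 200),
                            classifier = c("cnn", "svm", "knn",
                                           "random_forest"),
                            input_dir = NULL, out_dir = NULL, seed = 1,
                            max_evals = 120) {
  transform <- .match_field(transform, c("contourlet", "curvelet"), "transform")
  model <- .match_field(model, c("riig", "nakagami", "nig"), "model")
  weighting <- .match_field(weighting, c("correlated", "multiplicative"),
                            "weighting")
  classifier <- .match_field(classifier, c("cnn", "svm", "knn",
                                           "random_forest"), "classifier")
  if (!inherits(training, "training_config")) {
    training <- do.call(training_config, training)
  }
  structure(list(transform = transform, model = model, weighting = weighting,
                 subband_keys = subband_keys, window = window,
                 stride = stride, n_per_class = n_per_class,
                 image_size = image_size,
                 augment_variants = augment_variants, max_shift = max_shift,
                 training = training, classifier = classifier,
                 input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), max_evals = max_evals),
            class = "pipeline_config")
}

.match_field <- function(value, choices, field) {
  value <- value[1]
  if (!value %in% choices) {
    stop("invalid value for field '", field, "': '", value,
         "' (expected one of ", paste(choices, collapse = ", "), ")",
         call. = FALSE)
  }
  value
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$training)) raw$training <- do.call(training_config, raw$training)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$training <- unclass(out$training)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

# Load labeled input images from a directory (manifest or class subdirs).
.load_input_images <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (file.exists(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(i) {
      list(image = read_gray_image(file.path(dir, tab$file[i])),
           label = tab$label[i], source_id = tab$source_id[i])
    })
  } else {
    out <- list()
    for (lab in c("benign", "malignant")) {
      files <- list.files(file.path(dir, lab), pattern = "\\.(png|bmp)$",
                          ignore.case = TRUE, full.names = TRUE)
      out <- c(out, lapply(files, function(f) {
        list(image = read_gray_image(f), label = lab,
             source_id = paste0(lab, "_", tools::file_path_sans_ext(basename(f))))
      }))
    }
    if (length(out) == 0) {
      stop("no input images found under ", dir, call. = FALSE)
    }
    out
  }
}

#' Run the classification pipeline end to end
#'
#' Executes: input images (or the synthetic two-class generator) ->
#' translational augmentation -> multiresolution decomposition -> six
#' sub-band parametric maps -> correlated (or multiplicative) weighting ->
#' 224x224x6 stacks -> source-grouped train/test split -> network
#' training -> evaluation (network head or a classical classifier on the
#' pooled features). When `config$out_dir` is set, writes `metrics.csv`,
#' `confusion.csv`, `loss_trace.csv`, the exact `config.yaml` used and a
#' `run.log`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress?
#' @return List with `metrics` (test-set [classification_metrics()]),
#'   `network`, `classifier` (or `NULL`), `split`, `loss_trace`,
#'   `config`, `test_truth`, `test_pred`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 4)

  say("stage: input images")
  base <- stage("input", {
    if (!is.null(config$input_dir)) {
      .load_input_images(config$input_dir)
    } else {
      bcfg <- benign_config(); mcfg <- malignant_config()
      bcfg$size <- mcfg$size <- as.integer(config$image_size)
      make_dataset(config$n_per_class, bcfg, mcfg, seed = seeds[1])
    }
  })

  say("stage: augmentation (%d variants)", config$augment_variants)
  samples <- stage("augment", {
    out <- list()
    for (i in seq_along(base)) {
      b <- base[[i]]
      out <- c(out, list(b))
      if (config$augment_variants > 0) {
        vars <- augment_translate(b$image, config$augment_variants,
                                  config$max_shift,
                                  seed = (seeds[2] + i) %% .Machine$integer.max)
        out <- c(out, lapply(vars, function(v) {
          list(image = v, label = b$label, source_id = b$source_id)
        }))
      }
    }
    out
  })

  say("stage: stacks (%d samples)", length(samples))
  stacks <- stage("stack", lapply(samples, function(s) {
    build_stack(s$image, transform = config$transform, model = config$model,
                keys = config$subband_keys, window = config$window,
                stride = config$stride, weighting = config$weighting,
                label = s$label, source_id = s$source_id)
  }))
  data <- stage("stack", cnn_stack_data(stacks))

  say("stage: grouped split")
  split <- stage("split", grouped_split(data,
                                        config$training$test_fraction,
                                        seed = seeds[3]))

  say("stage: training (%d iterations)", config$training$iterations)
  net <- stage("train", {
    spec <- network_spec()
    n0 <- build_network(spec, seed = config$training$seed)
    train_cnn(n0, data, config$training, indices = split$train)
  })

  say("stage: evaluation")
  truth <- as.character(data$labels[split$test])
  clf <- NULL
  pred <- stage("evaluate", {
    if (config$classifier == "cnn") {
      as.character(predict(net, data, indices = split$test))
    } else {
      ftr <- extract_features(net, data, indices = split$train)
      fte <- extract_features(net, data, indices = split$test)
      clf <<- fit_classical(ftr, data$labels[split$train],
                            kind = config$classifier, seed = seeds[4])
      as.character(predict(clf, fte))
    }
  })
  metrics <- classification_metrics(truth, pred)

  if (!is.null(config$out_dir)) {
    .write_artifacts(config, metrics, net, truth, pred)
  }
  list(metrics = metrics, network = net, classifier = clf, split = split,
       source_ids = data$source_ids, loss_trace = net$loss_trace,
       config = config, test_truth = truth, test_pred = pred)
}

.write_artifacts <- function(config, metrics, net, truth, pred) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  mx <- unclass(metrics)
  utils::write.csv(
    data.frame(metric = names(mx), value = unlist(lapply(mx, as.character))),
    file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(table(truth = truth, predicted = pred)),
                   file.path(config$out_dir, "confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(net$loss_trace),
                              loss = net$loss_trace),
                   file.path(config$out_dir, "loss_trace.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  hash <- sum(utf8ToInt(paste(readLines(cfg_path), collapse = "\n"))) %% 1e9
  writeLines(c(sprintf("time: %s", format(Sys.time())),
               sprintf("seed: %d", config$seed),
               sprintf("config_hash: %d", hash),
               sprintf("accuracy: %s", format(metrics$accuracy))),
             file.path(config$out_dir, "run.log"))
  invisible(NULL)
}
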