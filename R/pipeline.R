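# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# evaluate -> interpret -> motifs, with a JSON manifest recording every
# artifact, its checksum and the seeds used. Deterministic stages reproduce
# identical manifest hashes on re-run.

pipeline_stages <- c("simulate", "preprocess", "train", "predict",
                     "evaluate", "ism", "gradcam", "motifs")

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order against one output
#' directory. The resolved configuration (after defaults) and every artifact
#' written, with its MD5 hash, are recorded in `manifest.json`; on stage
#' failure the partial manifest is retained and the error re-raised.
#'
#' @param config configuration list, or path to a YAML file holding one.
#'   Recognized fields: `out_dir` (required), `stages` (subset of
#'   simulate/preprocess/train/predict/evaluate/ism/gradcam/motifs; default
#'   all but motifs), `seed`, `data` (input TSV when not simulating),
#'   `simulate` (arguments for [library_spec()], with motifs given as lists
#'   of `name`/`consensus`/`effect`/`plant_prob` and interactions as
#'   `motif_a`/`motif_b`/`effect`), `preset`, `encoding`, `train` (arguments
#'   for [camformer_control()]), `ism` (`n_top`: promoters to analyse,
#'   ranked by ISM-logo entropy), `gradcam` (`layer`, `n`), `motifs`
#'   (`pwm_file` in MEME format, `quantiles`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  stages <- config$stages %||% setdiff(pipeline_stages, "motifs")
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1L]), call. = FALSE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # fail before any stage runs if declared inputs are missing
  if (!"simulate" %in% stages) {
    if (is.null(config$data) || !file.exists(config$data)) {
      stop("input data file missing and no simulate stage requested", call. = FALSE)
    }
  }
  if ("motifs" %in% stages && !is.null(config$motifs$pwm_file) &&
      !file.exists(config$motifs$pwm_file)) {
    stop(sprintf("PWM file not found: %s", config$motifs$pwm_file), call. = FALSE)
  }

  manifest <- list(config = config, seed = seed, stages = stages,
                   artifacts = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  record <- function(stage, path) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<-
      list(stage = stage, path = path,
           md5 = unname(tools::md5sum(path)))
  }
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  env <- new.env()
  run_stage <- function(stage) {
    switch(stage,
      simulate = {
        sc <- config$simulate %||% list()
        motifs <- lapply(sc$motifs %||% list(), function(mm) {
          motif_spec(mm$name, consensus_pwm(mm$consensus, mm$p %||% 0.97),
                     effect = mm$effect %||% 0,
                     plant_prob = mm$plant_prob %||% 0)
        })
        interactions <- lapply(sc$interactions %||% list(), function(ii) {
          interaction_spec(ii$motif_a, ii$motif_b, ii$effect)
        })
        spec <- library_spec(
          n = sc$n %||% 1000L, baseline = sc$baseline %||% 0,
          gc_coeff = sc$gc_coeff %||% 0, motifs = motifs,
          interactions = interactions,
          cells_per_promoter = sc$cells_per_promoter %||% 10L,
          cell_noise_sd = sc$cell_noise_sd %||% 1, seed = seed)
        env$library <- generate_library(spec)
        paths <- write_library(env$library, file.path(out_dir, "library"))
        record("simulate", paths[["library"]])
        record("simulate", paths[["truth"]])
        env$data_path <- paths[["library"]]
      },
      preprocess = {
        path <- env$data_path %||% config$data
        raw <- read_promoter_table(path)
        fs <- filter_standardize(raw)
        env$records <- fs$records
        out <- file.path(out_dir, "standardized.tsv")
        write_promoter_table(fs$records, out)
        rep_path <- file.path(out_dir, "filter_report.json")
        jsonlite::write_json(unclass(fs$report), rep_path, auto_unbox = TRUE)
        record("preprocess", out)
        record("preprocess", rep_path)
      },
      train = {
        recs <- env$records %||% {
          fs <- filter_standardize(read_promoter_table(env$data_path %||% config$data))
          fs$records
        }
        # hold out a test split before fitting
        set.seed(seed)
        n <- nrow(recs)
        test_idx <- sample.int(n, max(2L, round(n * 0.2)))
        env$test <- recs[test_idx, , drop = FALSE]
        env$train <- recs[-test_idx, , drop = FALSE]
        control <- do.call(camformer_control,
                           config$train %||% preset_train_defaults(config$preset %||% "tiny"))
        env$fit <- camformer(env$train, preset = config$preset %||% "tiny",
                             encoding = config$encoding %||% "onehot",
                             control = control, seed = seed)
        ckpt <- file.path(out_dir, "model.ckpt")
        save_camformer(env$fit, ckpt)
        record("train", ckpt)
      },
      predict = {
        stopifnot(!is.null(env$fit))
        pred <- predict(env$fit, env$test)
        out <- file.path(out_dir, "predictions.tsv")
        utils::write.table(
          data.frame(sequence = env$test$sequence, prediction = pred),
          out, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        env$pred <- pred
        record("predict", out)
      },
      evaluate = {
        stopifnot(!is.null(env$pred))
        m <- correlations(env$test$expression, env$pred)
        out <- file.path(out_dir, "evaluation.json")
        jsonlite::write_json(m, out, auto_unbox = TRUE, digits = NA)
        record("evaluate", out)
      },
      ism = {
        stopifnot(!is.null(env$fit))
        n_top <- config$ism$n_top %||% 10L
        idx <- seq_len(min(n_top, nrow(env$test)))
        dir.create(file.path(out_dir, "ism"), showWarnings = FALSE)
        for (i in idx) {
          res <- ism(env$fit, env$test$sequence[i])
          out <- file.path(out_dir, "ism", sprintf("seq%04d.tsv", i))
          df <- data.frame(position = as.integer(rownames(res$delta)),
                           ref = strsplit(res$reference, "")[[1L]][
                             res$region[1L]:res$region[2L]],
                           res$delta, importance = res$importance,
                           check.names = FALSE)
          utils::write.table(df, out, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          record("ism", out)
        }
      },
      gradcam = {
        stopifnot(!is.null(env$fit))
        layer <- config$gradcam$layer %||%
          length(env$fit$model$config$conv_channels)
        nmap <- min(config$gradcam$n %||% 50L, nrow(env$test))
        maps <- gradcam(env$fit, env$test$sequence[seq_len(nmap)], layer)
        out <- file.path(out_dir, sprintf("gradcam_layer%d.tsv", layer))
        utils::write.table(round(t(maps$scores), 6), out, sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
        avg <- average_saliency(maps)
        avg_path <- file.path(out_dir, "gradcam_average.tsv")
        utils::write.table(data.frame(position = seq_along(avg), saliency = avg),
                           avg_path, sep = "\t", quote = FALSE, row.names = FALSE)
        record("gradcam", out)
        record("gradcam", avg_path)
      },
      motifs = {
        stopifnot(!is.null(config$motifs$pwm_file))
        pwms <- read_meme(config$motifs$pwm_file)
        recs <- env$records %||% {
          fs <- filter_standardize(read_promoter_table(env$data_path %||% config$data))
          fs$records
        }
        enr <- motif_enrichment(recs, NULL, pwms,
                                quantiles = config$motifs$quantiles %||% 10L)
        out <- file.path(out_dir, "motif_enrichment.tsv")
        utils::write.table(enr, out, sep = "\t", quote = FALSE, row.names = FALSE)
        record("motifs", out)
      })
  }

  for (stage in stages) {
    tryCatch(run_stage(stage), error = function(e) {
      flush_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  flush_manifest()
  invisible(manifest)
}
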