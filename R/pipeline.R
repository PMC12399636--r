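# End-to-end pipeline: phantom series -> segmentation (trained network or
# ground-truth colorization) -> per-slice thickness measurement -> merged
# table -> plots -> triangulated 3-D surface. Driven by a single config
# (YAML-compatible list), fully seeded, and summarized in a run manifest.

#' Pipeline configuration
#'
#' @param stages character vector of enabled stages, in order, from
#'   `c("phantom", "train", "segment", "measure", "merge", "plot",
#'   "reconstruct")`. The default runs the measurement path using the
#'   phantom's colorized ground truth as segmentation input.
#' @param out_dir output directory.
#' @param seed global seed propagated to every stochastic stage.
#' @param n_slices,width,height phantom series geometry.
#' @param noise_sd phantom intensity noise.
#' @param direction,sigma,pixel_mm thickness measurement settings.
#' @param slice_mm slice spacing for the reconstruction (default 0.3).
#' @param smooth_iters Laplacian smoothing iterations for the surface.
#' @param train_epochs,freeze_epochs,width_multiplier,input_size
#'   training-stage settings (desk scale defaults).
#' @param checkpoint optional path to a trained network (.rds) used by the
#'   segment stage when training is disabled.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("phantom", "measure", "merge",
                                       "plot", "reconstruct"),
                            out_dir = tempfile("gingimap_run_"),
                            seed = 1, n_slices = 5, width = 128,
                            height = 128, noise_sd = 5,
                            direction = "down", sigma = 0, pixel_mm = 0.1,
                            slice_mm = 0.3, smooth_iters = 0,
                            train_epochs = 30, freeze_epochs = 10,
                            width_multiplier = 0.25, input_size = 128,
                            checkpoint = NULL) {
  known <- c("phantom", "train", "segment", "measure", "merge", "plot",
             "reconstruct")
  check_that(all(stages %in% known),
             paste("unknown stage; valid stages:",
                   paste(known, collapse = ", ")))
  structure(list(stages = stages, out_dir = out_dir, seed = seed,
                 n_slices = n_slices, width = width, height = height,
                 noise_sd = noise_sd, direction = direction, sigma = sigma,
                 pixel_mm = pixel_mm, slice_mm = slice_mm,
                 smooth_iters = smooth_iters, train_epochs = train_epochs,
                 freeze_epochs = freeze_epochs,
                 width_multiplier = width_multiplier,
                 input_size = input_size, checkpoint = checkpoint),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  plain <- cfg[sort(names(cfg))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(plain), tf)
  unname(tools::md5sum(tf))
}

default_series_spec <- function(cfg) {
  w <- cfg$width; h <- cfg$height
  base <- slice_phantom_spec(
    width = w, height = h,
    bone_profile = function(x) {
      h * 0.35 + h * 0.12 * sin(2 * pi * x / w)
    },
    thickness_fn = function(x) 10,
    noise_sd = cfg$noise_sd, seed = cfg$seed)
  # smooth mesiodistal variation: 0.8-2.5 mm at 0.1 mm/px
  field <- local({
    ns <- cfg$n_slices; w0 <- w
    function(k, x) {
      8 + 9 * sin(pi * (k + 1) / (ns + 1)) *
        (0.6 + 0.4 * cos(2 * pi * x / w0))
    }
  })
  series_phantom_spec(cfg$n_slices, base, field, seed = cfg$seed)
}

#' Run the gingival-thickness pipeline
#'
#' Executes the enabled stages in order, halting with the failing stage
#' named; writes per-stage outputs plus a JSON manifest (inputs, outputs,
#' config hash, per-stage status and timing) into `cfg$out_dir`. Reruns
#' with an identical config and seed reproduce identical CSV and mesh
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  check_that(inherits(cfg, "pipeline_config"),
             "cfg must be a pipeline_config")
  if ("segment" %in% cfg$stages && !"train" %in% cfg$stages &&
      is.null(cfg$checkpoint)) {
    abort_gm(paste("configuration error: stage 'segment' needs either the",
                   "'train' stage or a checkpoint"))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "stages")],
                   stages_enabled = cfg$stages,
                   config_hash = config_hash(cfg),
                   stages = list(), outputs = character(0))
  state <- new.env(parent = emptyenv())
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
  }
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      fn()
      TRUE
    }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, cfg$out_dir)
      abort_gm(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] -
                                                       t0, 3))
    invisible(ok)
  }

  run_stage("phantom", function() {
    sdir <- file.path(cfg$out_dir, "slices")
    state$series <- make_series_phantom(default_series_spec(cfg),
                                        out_dir = sdir)
    add_output(file.path(sdir, names(state$series)))
    add_output(file.path(sdir, "truth.csv"))
  })

  run_stage("train", function() {
    check_that(!is.null(state$series),
               "missing artifact: phantom series (enable stage 'phantom')")
    imgs <- lapply(state$series, function(s) {
      preprocess_slice(s$gray, input_size = cfg$input_size)
    })
    msks <- lapply(state$series, function(s) s$mask)
    n <- length(imgs)
    ntr <- max(1, round(0.8 * n))
    datasets <- list(train = list(images = imgs[1:ntr],
                                  masks = msks[1:ntr]),
                     val = list(images = imgs[(ntr + 1):n],
                                masks = msks[(ntr + 1):n]))
    net <- build_segmentation_network(
      model_config(input_size = cfg$input_size,
                   width_multiplier = cfg$width_multiplier),
      seed = cfg$seed)
    tcfg <- training_config(freeze_epochs = cfg$freeze_epochs,
                            total_epochs = cfg$train_epochs,
                            seed = cfg$seed)
    res <- train_staged(net, datasets, tcfg, loss_config())
    state$net <- res$net
    ck <- file.path(cfg$out_dir, "network.rds")
    save_network(res$net, ck)
    add_output(ck)
  })

  run_stage("segment", function() {
    check_that(!is.null(state$series),
               "missing artifact: phantom series (enable stage 'phantom')")
    if (is.null(state$net)) {
      check_that(!is.null(cfg$checkpoint) && file.exists(cfg$checkpoint),
                 "missing artifact: trained network checkpoint")
      state$net <- load_network(cfg$checkpoint)
    }
    state$color <- lapply(state$series, function(s) {
      img <- preprocess_slice(s$gray, input_size = cfg$input_size)
      colorize_labels(predict_segmentation(state$net, img))
    })
  })

  run_stage("measure", function() {
    check_that(!is.null(state$series),
               "missing artifact: phantom series (enable stage 'phantom')")
    if (is.null(state$color)) {
      # no segmentation stage: measure on the ground-truth colorization
      state$color <- lapply(state$series,
                            function(s) colorize_labels(s$mask))
    }
    mcfg <- measure_config(direction = cfg$direction, sigma = cfg$sigma,
                           pixel_spacing = cfg$pixel_mm)
    state$measurements <- lapply(names(state$color), function(nm) {
      measure_slice(state$color[[nm]], mcfg, image_name = nm)
    })
    names(state$measurements) <- names(state$color)
    odir <- file.path(cfg$out_dir, "overlays")
    dir.create(odir, showWarnings = FALSE)
    for (nm in names(state$measurements)) {
      p <- file.path(odir, sub("\\.png$", "_overlay.png", nm))
      write_color_png(state$measurements[[nm]]$overlay, p)
      add_output(p)
    }
  })

  run_stage("merge", function() {
    check_that(!is.null(state$measurements),
               "missing artifact: slice measurements (enable 'measure')")
    rows <- lapply(state$measurements, function(m) m$rows)
    state$table <- merge_tables(rows)
    p <- file.path(cfg$out_dir, "table.csv")
    write_thickness_table(state$table, p)
    add_output(p)
  })

  run_stage("plot", function() {
    check_that(!is.null(state$table),
               "missing artifact: thickness table (enable 'merge')")
    pdir <- file.path(cfg$out_dir, "figures")
    plot_distribution(state$table, out_dir = pdir)
    add_output(file.path(pdir, c("scatter.png", "curves.png")))
  })

  run_stage("reconstruct", function() {
    check_that(!is.null(state$table),
               "missing artifact: thickness table (enable 'merge')")
    surf <- grid_mesh(state$table, slice_mm = cfg$slice_mm,
                      pixel_mm = cfg$pixel_mm)
    if (cfg$smooth_iters > 0) {
      surf <- laplacian_smooth(surf, cfg$smooth_iters)
    }
    p <- file.path(cfg$out_dir, "surface.ply")
    export_surface(surf, p)
    add_output(p)
    state$surface <- surf
  })

  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(NULL)
}
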