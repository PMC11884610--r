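# Pipeline orchestration and command-line entry point.

#' Derive a stage seed from the global seed
#'
#' One global seed fans out to stable per-stage child seeds so stages can be
#' rerun independently with identical results.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed < 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

default_config <- function() {
  list(
    seed = 1,
    out_dir = "sprm_run",
    log_level = "info",
    optical = list(background_level = 500, psf_extent = 32),
    noise = list(sigma_t = 0, sigma_s = 0),
    scene = list(n_particles = 3, diameter = c(20, 50), T = 8,
                 shape = c(64, 64)),
    denoiser = list(base_channels = 8, lstm_hidden_channels = 8),
    training = list(enabled = FALSE, n_pairs = 24, epochs = 10, batch = 4,
                    lr0 = 1e-4),
    stages = c("simulate", "snr")
  )
}

build_from_config <- function(config) {
  oc <- utils::modifyList(formals_defaults(optical_model),
                          config$optical %||% list())
  nc <- utils::modifyList(formals_defaults(noise_model),
                          config$noise %||% list())
  list(optical = do.call(optical_model, oc), noise = do.call(noise_model,
                                                             nc))
}

formals_defaults <- function(f) {
  fr <- formals(f)
  fr <- fr[!vapply(fr, is.symbol, logical(1))]
  lapply(fr, eval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_scene <- function(sc, optical, seed) {
  set.seed(seed)
  n <- sc$n_particles %||% 3
  H <- sc$shape[1]; W <- sc$shape[2]
  m <- optical$psf_extent %/% 2
  entries <- lapply(seq_len(n), function(i) {
    d <- stats::runif(1, min(sc$diameter), max(sc$diameter))
    list(particle = particle_state(x = stats::runif(1, m, W - 1 - m),
                                   y = stats::runif(1, m, H - 1 - m),
                                   diameter = d,
                                   phase_phi = sample(c(0.13, 0.58),
                                                      1) * pi))
  })
  do.call(particle_scene, entries)
}

#' Run a multi-stage pipeline from a configuration
#'
#' Executes the requested stages in order — `simulate`, `train`, `denoise`,
#' `snr`, `track` — writing every artifact (TIFF stacks, CSV tables, the
#' trained model, the resolved configuration with provenance) into
#' `config$out_dir`. Identical configuration and seed give identical
#' artifacts. A stage failure aborts with the stage name and cause.
#'
#' @param config A named list (see [read_config()]) or a path to a YAML
#'   config.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  ob <- build_from_config(config)
  stages <- config$stages
  ctx <- list()
  for (stage in stages) {
    res <- tryCatch(
      run_stage(stage, config, ob, ctx, art),
      error = function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                       conditionMessage(e)), call. = FALSE))
    ctx <- res$ctx; art <- res$art
  }
  config$provenance <- list(
    package_version = as.character(utils::packageVersion("sprmdeep")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_config(config, file.path(config$out_dir, "resolved_config.yaml"))
  art$config <- file.path(config$out_dir, "resolved_config.yaml")
  invisible(art)
}

run_stage <- function(stage, config, ob, ctx, art) {
  out <- config$out_dir
  if (stage == "simulate") {
    sc <- config$scene
    scene <- if ((sc$n_particles %||% 0) > 0)
      random_scene(sc, ob$optical, stage_seed(config$seed, "scene"))
    else particle_scene()
    sim <- simulate_sequence(scene, ob$optical, ob$noise, T = sc$T,
                             shape = unlist(sc$shape),
                             seed = stage_seed(config$seed, "simulate"))
    ctx$sim <- sim
    art$stack <- file.path(out, "stack.tif")
    write_stack(sim$noisy, art$stack)
    art$truth <- file.path(out, "truth.csv")
    write_table_csv(sim$truth, art$truth)
  } else if (stage == "train") {
    tc <- config$training
    dn <- config$denoiser
    spec <- denoiser_spec(base_channels = dn$base_channels %||% 8,
                          lstm_hidden_channels =
                            dn$lstm_hidden_channels %||% 8)
    pairs <- make_training_pairs(
      n_pairs = tc$n_pairs %||% 24, optical = ob$optical,
      noise = ob$noise, T = config$scene$T %||% 8,
      shape = unlist(config$scene$shape %||% c(64, 64)),
      seed = stage_seed(config$seed, "pairs"))
    cfg <- train_config(lr0 = tc$lr0 %||% 1e-4,
                        epochs = tc$epochs %||% 10,
                        batch = tc$batch %||% 4,
                        seed = stage_seed(config$seed, "train"))
    ctx$model <- train_denoiser(pairs, spec, cfg)
    art$model <- file.path(out, "model.rds")
    save_model(ctx$model, art$model)
    art$history <- file.path(out, "history.csv")
    write_table_csv(ctx$model$history, art$history)
  } else if (stage == "denoise") {
    if (is.null(ctx$sim)) stop("no simulated stack in context")
    if (is.null(ctx$model)) stop("no model: run the train stage first")
    diff <- subtract_background(ctx$sim$noisy,
                                ob$optical$background_level)
    ctx$denoised <- denoise(diff, ctx$model)
    art$denoised <- file.path(out, "denoised.tif")
    write_stack(ctx$denoised, art$denoised)
  } else if (stage == "snr") {
    if (is.null(ctx$sim)) stop("no simulated stack in context")
    diff <- subtract_background(ctx$sim$noisy,
                                ob$optical$background_level)
    img <- get_frame(frame_average(diff, min(4, n_frames(diff))), 1)
    det <- detect_particles(img, ob$optical)
    art$snr <- file.path(out, "snr.csv")
    write_table_csv(det, art$snr)
  } else if (stage == "track") {
    if (is.null(ctx$sim)) stop("no simulated stack in context")
    diff <- subtract_background(ctx$sim$noisy,
                                ob$optical$background_level)
    tk <- track_particles(diff, ob$optical, model = ctx$model)
    tab <- if (length(tk$trajectories))
      do.call(rbind, lapply(seq_along(tk$trajectories), function(i)
        cbind(particle_id = i, tk$trajectories[[i]])))
    else data.frame()
    art$trajectories <- file.path(out, "trajectories.csv")
    write_table_csv(tab, art$trajectories)
  } else stop("unknown stage '", stage, "'")
  list(ctx = ctx, art = art)
}

#' Generate synthetic training pairs
#'
#' Simulates ground-truthed sequences and returns (noisy differential,
#' clean differential) array pairs for [train_denoiser()]. Half the scenes
#' hold a stationary particle, half a particle moving a random step each
#' frame, mirroring the mixed-motion composition of the training corpus;
#' diameters are drawn log-uniformly over `diameter_range`.
#'
#' @param n_pairs Number of pairs.
#' @param optical,noise Forward models.
#' @param T,shape Sequence length and frame size.
#' @param diameter_range Diameter span in nm (default c(5, 50)).
#' @param seed Integer seed.
#' @return A list of `list(input, target, truth)` entries.
#' @export
make_training_pairs <- function(n_pairs, optical = optical_model(),
                                noise = noise_model(), T = 8,
                                shape = c(64, 64),
                                diameter_range = c(5, 50), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- optical$psf_extent %/% 2
  lapply(seq_len(n_pairs), function(i) {
    d <- exp(stats::runif(1, log(diameter_range[1]),
                          log(diameter_range[2])))
    x <- stats::runif(1, m, shape[2] - 1 - m)
    y <- stats::runif(1, m, shape[1] - 1 - m)
    phi <- stats::runif(1, 0, 2 * pi)
    moving <- i %% 2 == 0
    p <- particle_state(x = x, y = y, diameter = d, phase_phi = phi)
    entry <- if (moving) {
      list(particle = p, event = walk_event(step_px = 1))
    } else list(particle = p)
    sim <- simulate_sequence(particle_scene(entry), optical, noise, T = T,
                             shape = shape)
    bg <- optical$background_level
    list(input = sim$noisy$frames - bg, target = sim$clean$frames - bg,
         truth = sim$truth)
  })
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `train`, `denoise`, `snr`, `track`, `pipeline`.
#' Each accepts `--config` (YAML), `--seed`, `--out`. Invoke from a shell
#' via the launcher script in `inst/cli/sprmdeep`, or directly:
#' `Rscript -e 'sprmdeep::sprm_cli()' pipeline --config run.yaml`.
#'
#' @param args Character vector of arguments (default: command line).
#' @return Artifact list, invisibly.
#' @export
sprm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: sprmdeep <simulate|train|denoise|snr|track|pipeline>",
        "[--config file.yaml] [--seed N] [--out dir]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "sprm_run")
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opt$config)) read_config(opt$config) else list()
  config$seed <- opt$seed
  config$out_dir <- opt$out
  config$stages <- switch(cmd,
    simulate = "simulate",
    train = "train",
    denoise = c("simulate", "train", "denoise"),
    snr = c("simulate", "snr"),
    track = c("simulate", "track"),
    pipeline = config$stages %||% c("simulate", "snr"),
    stop("unknown subcommand '", cmd, "'"))
  run_pipeline(config)
}
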