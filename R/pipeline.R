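#' Merge trajectory data with the experiment description
#'
#' Left-joins detection- or trajectory-level rows onto a video description
#' table (one row per video with arbitrary metadata columns: treatment,
#' sampling day, magnification, ...), using the video file name as the key.
#' Rows from videos absent in the description are kept with missing metadata
#' and a warning, so no measurements are silently lost.
#'
#' @param data a table carrying a `video` column (output of
#'   [link_particles()], [compute_step_metrics()] or
#'   [summarize_trajectories()]).
#' @param description data.frame with a unique `file` column naming each
#'   video stem plus any metadata columns.
#' @return `data` with the description columns appended.
#' @export
merge_data <- function(data, description) {
  require_columns(data, "video", "data table")
  require_columns(description, "file", "video description")
  dup <- unique(description$file[duplicated(description$file)])
  if (length(dup)) {
    stop("duplicate file entries in video description: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(unique(data$video), description$file)
  if (length(missing)) {
    warning("video(s) absent from the description file: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(description$file, unique(data$video))
  if (length(uncovered)) {
    warning("description rows with no processed video: ",
            paste(uncovered, collapse = ", "), call. = FALSE)
  }
  idx <- match(data$video, description$file)
  meta <- description[idx, setdiff(names(description), "file"), drop = FALSE]
  rownames(meta) <- NULL
  out <- cbind(data, meta)
  rownames(out) <- NULL
  out
}

#' By-frame counts and mean abundance
#'
#' Counts retained detections on every frame of the analyzable range and
#' averages the counts across the video. Counting by frame (rather than
#' counting trajectories) prevents occlusions — which split one individual
#' into several partial trajectories — from inflating abundance: an
#' individual present once per frame contributes exactly 1 regardless of how
#' many trajectory fragments it was recorded as.
#'
#' The averaging range is the set of frames for which a difference image
#' exists (`n_frames` = raw frames minus the segmentation offset); frames
#' with no detections count as zero.
#'
#' @param detections filtered detection-level rows (columns video, frame).
#' @param n_frames number of valid difference frames, as a single value or a
#'   named vector/list keyed by video.
#' @return a list with `per_frame` (video, frame, count) and `abundance`
#'   (video, abundance = mean per-frame count).
#' @export
count_per_frame <- function(detections, n_frames) {
  require_columns(detections, c("video", "frame"), "detection table")
  videos <- sort(unique(detections$video))
  if (!length(videos) && length(n_frames) && !is.null(names(n_frames))) {
    videos <- names(n_frames)
  }
  per_frame <- list()
  abundance <- numeric(length(videos))
  for (k in seq_along(videos)) {
    vid <- videos[k]
    nf <- if (!is.null(names(n_frames))) n_frames[[vid]] else n_frames[[1]]
    if (is.null(nf)) stop("no n_frames entry for video ", vid, call. = FALSE)
    fr <- detections$frame[detections$video == vid]
    counts <- tabulate(factor(fr, levels = 0:(nf - 1)), nbins = nf)
    per_frame[[k]] <- data.frame(video = vid, frame = 0:(nf - 1),
                                 count = counts)
    abundance[k] <- mean(counts)
  }
  list(
    per_frame = if (length(per_frame)) do.call(rbind, per_frame) else
      data.frame(video = character(0), frame = integer(0), count = integer(0)),
    abundance = data.frame(video = videos, abundance = abundance)
  )
}

overlay_palette <- c("#FFD700", "#FF4500", "#00CED1", "#ADFF2F", "#FF69B4",
                     "#1E90FF", "#FFA500", "#9370DB")

#' Render trajectory overlays
#'
#' Draws the reconstructed trajectories over the original frames for visual
#' validation of segmentation and linking (labels that disappear or flicker
#' between ids indicate that the threshold or the tracking parameters need
#' fine-tuning). Two modes: `"label"` prints each trajectory's id at its
#' current position; `"traj"` draws the path travelled so far as a polyline.
#' With `color_by = "predicted_species"` (a column in `master`) trajectories
#' are coloured by predicted species from a fixed palette.
#'
#' One PNG is written per difference frame (the frames for which detections
#' can exist), named like the input sequence.
#'
#' @param stack the original [frame_stack()].
#' @param master detection-level table for the same video (columns video,
#'   frame, x, y, traj_id).
#' @param out_dir output directory (created if absent).
#' @param mode `"label"` or `"traj"`.
#' @param color_by NULL or `"predicted_species"`.
#' @param offset segmentation offset used (determines how many frames have
#'   detections; `n_frames(stack) - offset` PNGs are written).
#' @return invisibly, the files written.
#' @export
create_overlays <- function(stack, master, out_dir, mode = c("label", "traj"),
                            color_by = NULL, offset = 25) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"))
  require_columns(master, c("video", "frame", "x", "y", "traj_id"),
                  "master table")
  vids <- unique(master$video)
  if (length(vids) && !all(vids == stack$source_name)) {
    stop(sprintf("master table is for video '%s' but stack is '%s'",
                 paste(vids, collapse = ","), stack$source_name), call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nf_out <- n_frames(stack) - offset
  if (nf_out < 1) stop("offset leaves no frames to overlay", call. = FALSE)
  d <- dim(stack$frames)
  col_for <- function(rows) {
    if (!is.null(color_by)) {
      sp <- as.character(master[[color_by]][rows])
      overlay_palette[(as.integer(factor(sp,
        levels = sort(unique(as.character(master[[color_by]]))))) - 1L) %%
          length(overlay_palette) + 1L]
    } else rep(overlay_palette[1], length(rows))
  }
  width <- max(5L, nchar(as.character(nf_out - 1L)))
  files <- character(nf_out)
  for (t in seq_len(nf_out) - 1L) {
    f <- file.path(out_dir, sprintf("%s_overlay_%0*d.png", stack$source_name,
                                    width, t))
    grDevices::png(f, width = d[2], height = d[1])
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(-0.5, d[2] - 0.5), ylim = c(d[1] - 0.5, -0.5))
    graphics::rasterImage(grDevices::as.raster(stack$frames[, , t + 1] / 255),
                          -0.5, d[1] - 0.5, d[2] - 0.5, -0.5)
    if (mode == "label") {
      rows <- which(master$frame == t)
      if (length(rows)) {
        graphics::text(master$x[rows], master$y[rows],
                       labels = master$traj_id[rows], col = col_for(rows),
                       cex = 0.9, font = 2)
      }
    } else {
      rows <- which(master$frame <= t)
      if (length(rows)) {
        for (tid in unique(master$traj_id[rows])) {
          tr <- rows[master$traj_id[rows] == tid]
          tr <- tr[order(master$frame[tr])]
          graphics::lines(master$x[tr], master$y[tr], col = col_for(tr[1]),
                          lwd = 1.5)
        }
      }
    }
    grDevices::dev.off()
    files[t + 1L] <- f
  }
  invisible(files)
}

#' Default pipeline configuration
#'
#' Flat section/key list with the validated defaults for 25 fps dark-field
#' ciliate videos: segmentation offset 25 frames (1 s), link range 5 frames,
#' maximum displacement 20 px, and trajectory filters of 50 um net
#' displacement, 0.2 s duration, 80% detection rate and >2 um median step.
#' The segmentation threshold and the spatial scale must be set per system.
#'
#' @return a nested list; see the package vignette for every key.
#' @export
default_config <- function() {
  list(
    video = list(fps = 25, scale = 1),
    segmentation = list(offset = 25, threshold = 40, min_area = 5,
                        max_area = 1e5, method = "subtract", blur_sigma = 0,
                        grey_source = "difference"),
    linking = list(link_range = 5, max_disp = 20, gap_mode = "linear"),
    filtering = list(min_net = 50, min_duration = 0.2,
                     min_detection_rate = 0.8, min_median_step = 2),
    io = list(input_dir = ".", output_dir = "trackmorph_out",
              description_file = NULL)
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the same section/key structure as [default_config()]; keys not
#' given keep their defaults. All values are range-checked.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stop_if_not_scalar_number(cfg$video$fps, "video.fps")
  stop_if_not_scalar_number(cfg$video$scale, "video.scale")
  segmentation_params(cfg$segmentation$offset, cfg$segmentation$threshold,
                      cfg$segmentation$min_area, cfg$segmentation$max_area)
  link_params(cfg$linking$link_range, cfg$linking$max_disp,
              cfg$linking$gap_mode)
  if (!cfg$segmentation$method %in% c("subtract", "abs")) {
    stop("segmentation.method must be 'subtract' or 'abs'", call. = FALSE)
  }
  if (!cfg$segmentation$grey_source %in% c("difference", "raw")) {
    stop("segmentation.grey_source must be 'difference' or 'raw'", call. = FALSE)
  }
  for (k in names(cfg$filtering)) {
    if (!is.numeric(cfg$filtering[[k]])) {
      stop("filtering.", k, " must be numeric", call. = FALSE)
    }
  }
  cfg
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Processes every image-sequence subdirectory of `io$input_dir`: loads the
#' frames, segments and measures particles, links trajectories, computes
#' step metrics, summarizes and filters trajectories, merges the experiment
#' description (if given), and derives by-frame counts and mean abundance.
#' Writes `particles.csv`, `trajectories.csv`, `summaries.csv`,
#' `filtered.csv`, `counts_per_frame.csv`, `abundance.csv` and a
#' `manifest.yaml` recording every parameter and the package version. Given
#' identical inputs and config the outputs are byte-identical across runs.
#'
#' @param config a config list (see [default_config()]) or the path to a
#'   YAML config file.
#' @param verbose print per-video progress and stage counts.
#' @return invisibly, the output directory; the result tables are also
#'   returned in the `"results"` attribute.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else
    validate_config(utils::modifyList(default_config(), config))
  say <- function(...) if (verbose) message(sprintf(...))
  in_dir <- cfg$io$input_dir
  if (!dir.exists(in_dir)) stop("input_dir does not exist: ", in_dir, call. = FALSE)
  vids <- list.dirs(in_dir, recursive = FALSE)
  if (!length(vids)) {
    stop("no image-sequence subdirectories found in ", in_dir, call. = FALSE)
  }
  out_dir <- cfg$io$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sp <- segmentation_params(cfg$segmentation$offset, cfg$segmentation$threshold,
                            cfg$segmentation$min_area, cfg$segmentation$max_area)
  lp <- link_params(cfg$linking$link_range, cfg$linking$max_disp,
                    cfg$linking$gap_mode)
  particle_tabs <- traj_tabs <- list()
  nf_diff <- list()
  for (v in sort(vids)) {
    vname <- basename(v)
    stage <- "load_frames"
    res <- tryCatch({
      stack <- load_frames(v, fps = cfg$video$fps, scale = cfg$video$scale)
      say("[%s] loaded %d frames (%d x %d px)", vname, n_frames(stack),
          dim(stack)[1], dim(stack)[2])
      stage <- "locate_and_measure_particles"
      parts <- locate_and_measure_particles(
        stack, sp, grey_source = cfg$segmentation$grey_source,
        method = cfg$segmentation$method,
        blur_sigma = cfg$segmentation$blur_sigma)
      say("[%s] %d particles on %d difference frames", vname, nrow(parts),
          n_frames(stack) - sp$offset)
      stage <- "link_particles"
      traj <- link_particles(parts, lp)
      traj <- compute_step_metrics(traj, fps = cfg$video$fps,
                                   scale = cfg$video$scale)
      say("[%s] %d trajectories", vname,
          length(unique(traj$traj_id)))
      nf_diff[[vname]] <- n_frames(stack) - sp$offset
      list(parts = parts, traj = traj)
    }, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s' for video '%s': %s",
                   stage, vname, conditionMessage(e)), call. = FALSE)
    })
    particle_tabs[[vname]] <- res$parts
    traj_tabs[[vname]] <- res$traj
  }
  particles <- do.call(rbind, particle_tabs)
  trajectories <- do.call(rbind, traj_tabs)
  rownames(particles) <- rownames(trajectories) <- NULL
  summaries <- summarize_trajectories(trajectories, fps = cfg$video$fps,
                                      scale = cfg$video$scale)
  filtered <- filter_data(summaries,
                          min_net = cfg$filtering$min_net,
                          min_duration = cfg$filtering$min_duration,
                          min_detection_rate = cfg$filtering$min_detection_rate,
                          min_median_step = cfg$filtering$min_median_step)
  say("filter kept %d of %d trajectories", nrow(filtered), nrow(summaries))
  description <- NULL
  if (!is.null(cfg$io$description_file)) {
    description <- utils::read.csv(cfg$io$description_file,
                                   stringsAsFactors = FALSE)
    summaries <- merge_data(summaries, description)
    filtered <- merge_data(filtered, description)
  }
  kept_detections <- trajectories[trajectories$id %in% filtered$id, ,
                                  drop = FALSE]
  counts <- count_per_frame(kept_detections, nf_diff)
  # degrees alongside the radian angle columns for human readability
  trajectories$abs_angle_deg <- trajectories$abs_angle * 180 / pi
  trajectories$turning_angle_deg <- trajectories$turning_angle * 180 / pi
  trajectories$frame_1 <- trajectories$frame + 1L
  write_csv_out(particles, file.path(out_dir, "particles.csv"))
  write_csv_out(trajectories, file.path(out_dir, "trajectories.csv"))
  write_csv_out(summaries, file.path(out_dir, "summaries.csv"))
  write_csv_out(filtered, file.path(out_dir, "filtered.csv"))
  write_csv_out(counts$per_frame, file.path(out_dir, "counts_per_frame.csv"))
  write_csv_out(counts$abundance, file.path(out_dir, "abundance.csv"))
  manifest <- list(package = "trackmorph",
                   version = as.character(utils::packageVersion("trackmorph")),
                   config = cfg, videos = basename(sort(vids)),
                   n_particles = nrow(particles),
                   n_trajectories = nrow(summaries),
                   n_retained = nrow(filtered))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results <- list(particles = particles, trajectories = trajectories,
                  summaries = summaries, filtered = filtered,
                  counts = counts, n_frames_diff = nf_diff)
  out <- out_dir
  attr(out, "results") <- results
  invisible(out)
}
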