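#' Run the full scoring pipeline
#'
#' Read (if needed), preprocess, classify view and direction, detect gait
#' events, segment strides, compute angle series, and score the EVGS
#' parameters. Deterministic given input and configuration.
#'
#' @param input A `pose_sequence`, a directory of BODY25 per-frame JSON
#'   files, or a keypoint CSV path.
#' @param config A [evgs_config()] list.
#' @param fs,resolution Passed to the readers when `input` is a path.
#' @return An `evgs_report`; `$diagnostics` carries the per-stage
#'   intermediates (`scene`, `events`, `strides`, `config`).
#' @export
run_pipeline <- function(input, config = evgs_config(), fs = 60,
                         resolution = c(1080, 1920)) {
  seq <- if (inherits(input, "pose_sequence")) input
         else if (dir.exists(input)) read_body25_json(input, fs, resolution)
         else if (grepl("\\.csv$", input)) read_keypoints_csv(input, fs, resolution)
         else read_body25_json(input, fs, resolution)
  if (n_frames(seq) == 0) stop("empty input: no frames")
  pre <- preprocess(seq, config)
  scene <- detect_scene(pre, config)
  events <- detect_events(pre, scene$view, scene$direction, config)
  strides <- segment_strides(events, scene$view)
  report <- compile_report(pre, scene, events, strides, config)
  report$diagnostics <- list(scene = scene, events = events,
                             strides = strides, config = config)
  report
}
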