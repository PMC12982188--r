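# Run manifests for external scoring stages. The package never executes
# docking or MD; it writes the job lists and bookkeeping those stages need.

#' Protocol manifest for an external MD (or docking) stage
#'
#' Captures the stage settings as provenance and derives the expected frame
#' count of a trajectory: `floor(production length / frame interval)`,
#' excluding frame 0 — a 25 ns production sampled every 100 ps yields 250
#' frames.
#'
#' @param stage Stage name (free text, e.g. `"md_production"`).
#' @param production_ns Production length in ns.
#' @param frame_interval_ps Frame saving interval in ps.
#' @param pairs Optional benchmark pair tibble; when given, one job line
#'   per pair is emitted.
#' @return A `protocol_manifest`: list with `stage`, `production_ns`,
#'   `frame_interval_ps`, `expected_frames`, `jobs` (character vector).
#' @examples
#' protocol_manifest("md_production", 25, 100)$expected_frames
#' @export
protocol_manifest <- function(stage = "md_production", production_ns = 25,
                              frame_interval_ps = 100, pairs = NULL) {
  stopifnot(production_ns > 0, frame_interval_ps > 0)
  production_ps <- production_ns * 1000
  if (frame_interval_ps > production_ps) {
    rlang::abort("frame interval exceeds production length",
                 class = "decoybench_bad_input")
  }
  frames <- as.integer(floor(production_ps / frame_interval_ps))
  jobs <- character(0)
  if (!is.null(pairs)) {
    jobs <- sprintf("%s pair=%s production_ns=%g frame_interval_ps=%g",
                    stage, pairs$pair_id, production_ns, frame_interval_ps)
  }
  structure(list(stage = stage, production_ns = production_ns,
                 frame_interval_ps = frame_interval_ps,
                 expected_frames = frames, jobs = jobs),
            class = "protocol_manifest")
}

#' @export
print.protocol_manifest <- function(x, ...) {
  cat(sprintf("<protocol_manifest> %s: %g ns production, frames every %g ps -> %d frames, %d job(s)\n",
              x$stage, x$production_ns, x$frame_interval_ps,
              x$expected_frames, length(x$jobs)))
  invisible(x)
}

#' Write a protocol manifest to a plain-text job file
#'
#' @param manifest A [protocol_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  hdr <- sprintf("# stage=%s production_ns=%g frame_interval_ps=%g expected_frames=%d",
                 manifest$stage, manifest$production_ns,
                 manifest$frame_interval_ps, manifest$expected_frames)
  writeLines(c(hdr, manifest$jobs), path)
  invisible(path)
}
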