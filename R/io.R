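#' Read and write the delimited-text data formats
#'
#' Plain CSV/JSON serialisation of the package's data objects, so that
#' velocity snapshots, tracked waveforms, interrogation signals and phase
#' series can be exchanged with external tracking/PIV tools. Columns
#' follow fixed schemas: velocity frames `x_um, y_um, u_um_per_s,
#' v_um_per_s, frame, t_s`; waveforms `frame, t_s, node_index, x_um,
#' y_um`; signals `t_s, value`; ground truth is JSON.
#'
#' @param frames list of [velocity_field] objects.
#' @param file path to a CSV (or JSON, for ground truth) file.
#' @return The read functions return the corresponding package objects;
#'   the write functions return `file` invisibly.
#' @name flagsync-io
NULL

#' @rdname flagsync-io
#' @export
write_velocity_frames <- function(frames, file) {
  tab <- do.call(rbind, lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    data.frame(x_um = f$points[, 1], y_um = f$points[, 2],
               u_um_per_s = f$u[, 1], v_um_per_s = f$u[, 2],
               frame = i, t_s = f$t)
  }))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname flagsync-io
#' @export
read_velocity_frames <- function(file) {
  tab <- utils::read.csv(file)
  lapply(split(tab, tab$frame), function(d)
    velocity_field(d$x_um, d$y_um, d$u_um_per_s, d$v_um_per_s,
                   t = d$t_s[1]))
}

#' @rdname flagsync-io
#' @param waveforms list of [waveform_frame] objects.
#' @export
write_waveforms <- function(waveforms, file) {
  tab <- do.call(rbind, lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    data.frame(frame = i, t_s = w$t, node_index = seq_len(nrow(w$nodes)),
               x_um = w$nodes[, 1], y_um = w$nodes[, 2])
  }))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname flagsync-io
#' @export
read_waveforms <- function(file) {
  tab <- utils::read.csv(file)
  lapply(split(tab, tab$frame), function(d) {
    d <- d[order(d$node_index), ]
    waveform_frame(cbind(d$x_um, d$y_um), t = d$t_s[1])
  })
}

#' @rdname flagsync-io
#' @param t,value time stamps (s) and signal values.
#' @export
write_signal <- function(t, value, file) {
  utils::write.csv(data.frame(t_s = t, value = value), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname flagsync-io
#' @export
read_signal <- function(file) {
  tab <- utils::read.csv(file)
  list(t = tab$t_s, value = tab$value)
}

#' @rdname flagsync-io
#' @param pair a `phase_pair` object.
#' @export
write_phase_pair <- function(pair, file) {
  utils::write.csv(data.frame(t_s = pair$t, delta_beats = pair$delta,
                              phi1_rad = pair$phi1, phi2_rad = pair$phi2),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname flagsync-io
#' @param d,l,orientation metadata restored onto the read pair.
#' @export
read_phase_pair <- function(file, d = NA_real_, l = NA_real_,
                            orientation = NA_character_) {
  tab <- utils::read.csv(file)
  structure(list(t = tab$t_s, delta = tab$delta_beats,
                 phi1 = tab$phi1_rad, phi2 = tab$phi2_rad,
                 dt = stats::median(diff(tab$t_s)),
                 d = d, l = l, L = d / l, orientation = orientation,
                 ground_truth = NULL),
            class = "phase_pair")
}

#' @rdname flagsync-io
#' @param truth a ground-truth list as attached by the generators.
#' @export
write_ground_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(file)
}

#' @rdname flagsync-io
#' @export
read_ground_truth <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
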