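#' Calibrated multi-channel image stack
#'
#' The universal input container: a `T x C x Y x X` (or, before Z-flattening,
#' `T x C x Z x Y x X`) array of non-negative intensities together with the
#' physical in-plane pixel size (micrometres, isotropic) and the frame
#' interval (seconds). All quantification functions in the package consume
#' this object or single `Y x X` frames extracted from it with
#' [stack_frame()].
#'
#' @param data Numeric array. Accepted shapes: `Y x X` (promoted to
#'   `1 x 1 x Y x X`), `T x C x Y x X`, or `T x C x Z x Y x X`.
#' @param pixel_size_um In-plane pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s Frame interval in seconds; required (> 0) when the
#'   stack has more than one frame.
#' @param channel_names Optional character vector of channel labels, recycled
#'   to `C`.
#'
#' @return An object of class `image_stack`: a list with elements `data`,
#'   `pixel_size_um`, `frame_interval_s`, `channel_names`.
#' @examples
#' st <- image_stack(array(runif(2 * 2 * 8 * 8), c(2, 2, 8, 8)),
#'                   pixel_size_um = 0.1, frame_interval_s = 36)
#' st
#' @export
image_stack <- function(data, pixel_size_um = 1, frame_interval_s = NA_real_,
                        channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  }
  nd <- length(dim(data))
  if (!nd %in% c(4L, 5L)) {
    abort("`data` must be a Y x X matrix, a T x C x Y x X array, or a T x C x Z x Y x X array.")
  }
  if (!all(is.finite(data))) abort("stack intensities must be finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number")
  }
  n_t <- dim(data)[1L]
  if (n_t > 1L && (!is.finite(frame_interval_s) || frame_interval_s <= 0)) {
    abort("`frame_interval_s` must be > 0 for a multi-frame stack")
  }
  n_c <- dim(data)[2L]
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(n_c))
  } else {
    channel_names <- rep_len(as.character(channel_names), n_c)
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = as.numeric(frame_interval_s),
         channel_names = channel_names),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  axes <- if (length(d) == 5L) "T x C x Z x Y x X" else "T x C x Y x X"
  cat("<image_stack> ", paste(d, collapse = " x "), " (", axes, ")\n", sep = "")
  cat("  pixel size: ", x$pixel_size_um, " um/px; frame interval: ",
      x$frame_interval_s, " s\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
n_frames <- function(x) dim(x$data)[1L]

#' @rdname image_stack
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname image_stack
#' @export
has_z <- function(x) length(dim(x$data)) == 5L

#' @rdname image_stack
#' @export
frame_times <- function(x) {
  (seq_len(n_frames(x)) - 1) * x$frame_interval_s
}

#' Extract one frame of one channel as a Y x X matrix
#'
#' @param x An `image_stack` without a Z axis (see [project_z()]).
#' @param frame,channel 1-based frame and channel indices; `channel` may also
#'   be a channel name.
#' @return A numeric `Y x X` matrix.
#' @export
stack_frame <- function(x, frame = 1L, channel = 1L) {
  if (has_z(x)) abort("stack has a Z axis; flatten with project_z() first")
  if (is.character(channel)) {
    channel <- match(channel, x$channel_names)
    if (is.na(channel)) abort("unknown channel name")
  }
  d <- dim(x$data)
  if (frame < 1L || frame > d[1L] || channel < 1L || channel > d[2L]) {
    abort("frame or channel index out of range")
  }
  matrix(x$data[frame, channel, , ], d[3L], d[4L])
}

#' Flatten the Z axis by maximum or sum intensity projection
#'
#' Z-stacks are flattened before quantification by per-pixel maximum or sum
#' projection over slices; all other axes are untouched. Which projection is
#' appropriate depends on the analysis and is therefore always an explicit
#' argument (and a required config field in [run_pipeline()]), never a hidden
#' default.
#'
#' @param stack An `image_stack` with a Z axis (a stack without one is
#'   returned unchanged).
#' @param method `"max"` or `"sum"`.
#' @return An `image_stack` with shape `T x C x Y x X`.
#' @examples
#' a <- array(0, c(1, 1, 3, 4, 4)); a[1, 1, , 1, 1] <- c(2, 5, 3)
#' st <- image_stack(a, pixel_size_um = 0.1)
#' project_z(st, "max")$data[1, 1, 1, 1]  # 5
#' project_z(st, "sum")$data[1, 1, 1, 1]  # 10
#' @export
project_z <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  if (!has_z(stack)) return(stack)
  d <- dim(stack$data)
  out <- array(0, c(d[1L], d[2L], d[4L], d[5L]))
  fun <- if (method == "max") function(m) apply(m, c(2L, 3L), max) else colSums
  for (t in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      planes <- array(stack$data[t, ch, , , ], d[3L:5L])
      out[t, ch, , ] <- if (method == "max") {
        apply(planes, c(2L, 3L), max)
      } else {
        colSums(planes, dims = 1L)
      }
    }
  }
  image_stack(out, stack$pixel_size_um, stack$frame_interval_s,
              stack$channel_names)
}
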