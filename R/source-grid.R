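#' Mechanical geometry of the collimated calibration source array
#'
#' An n x n array of collimated point sources (default 11 x 11 at 4.6 mm
#' pitch, 1.2 mm collimated beam diameter) centred on the crystal face.
#'
#' @param n Sources per side.
#' @param pitch_mm Source spacing (mm).
#' @param beam_diameter_mm Diameter of the collimated beam spot (mm).
#' @return A `source_grid` list with the node table in `$nodes`.
#' @export
#' @examples
#' g <- source_grid()
#' nrow(g$nodes)   # 121
source_grid <- function(n = 11, pitch_mm = 4.6, beam_diameter_mm = 1.2) {
  stopifnot(n >= 2, pitch_mm > 0, beam_diameter_mm > 0)
  pos <- (seq_len(n) - (n + 1) / 2) * pitch_mm
  nodes <- tidyr::expand_grid(node_i = seq_len(n) - 1L, node_j = seq_len(n) - 1L)
  nodes$mech_x_mm <- pos[nodes$node_i + 1L]
  nodes$mech_y_mm <- pos[nodes$node_j + 1L]
  structure(list(n = as.integer(n), pitch_mm = pitch_mm,
                 beam_diameter_mm = beam_diameter_mm,
                 nodes = nodes),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid %d x %d, pitch %g mm, beam %g mm>\n",
              x$n, x$n, x$pitch_mm, x$beam_diameter_mm))
  invisible(x)
}

# Mechanical node positions in normalized flood-map units (mm / half-size).
grid_nodes_norm <- function(grid, half_size_mm = 25) {
  dplyr::mutate(grid$nodes,
                mech_x = .data$mech_x_mm / half_size_mm,
                mech_y = .data$mech_y_mm / half_size_mm)
}

#' Software collimation: reject oblique lines of response
#'
#' Keeps lines of response (LORs) whose angle to the detector normal does
#' not exceed `max_angle_deg` (default 1.2 degrees).  The angle is
#' `atan(transverse displacement / detector separation)`.
#'
#' @param lors Data frame with endpoint columns `ax, ay, bx, by` (mm, on the
#'   two opposing detector faces) and `separation_mm`.
#' @param max_angle_deg Maximum accepted angle from the detector normal.
#' @return The accepted subset of `lors`, with an added `angle_deg` column.
#' @export
#' @examples
#' lors <- tibble::tibble(ax = c(0, 10), ay = 0, bx = 0, by = 0,
#'                        separation_mm = 200)
#' filter_lors(lors)   # the 10 mm offset LOR (2.86 deg) is rejected
filter_lors <- function(lors, max_angle_deg = 1.2) {
  stopifnot(max_angle_deg > 0)
  req <- c("ax", "ay", "bx", "by", "separation_mm")
  if (!all(req %in% names(lors))) {
    abort(paste("`lors` must contain columns:", paste(req, collapse = ", ")))
  }
  if (any(lors$separation_mm <= 0)) abort("LOR separation must be positive.")
  lors <- dplyr::mutate(
    lors,
    angle_deg = atan(sqrt((.data$ax - .data$bx)^2 + (.data$ay - .data$by)^2) /
                       .data$separation_mm) * 180 / pi)
  dplyr::filter(lors, .data$angle_deg <= max_angle_deg)
}
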