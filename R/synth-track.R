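#' Pool-table geometry
#'
#' Physical layout used by both the track generator and the tracking
#' analysis: 48 mm balls, a 40 x 40 mm onset bounding box (half-width
#' 20 mm) around the cue ball's initial position, and cue/target/pocket
#' positions in mm table coordinates.
#'
#' @param ball_diameter ball diameter in mm (default 48)
#' @param box_half_width onset bounding-box half-width in mm (default 20)
#' @param cue_start,target_start,pocket (x, y) positions in mm
#' @return object of class `table_geometry`
#' @export
table_geometry <- function(ball_diameter = 48, box_half_width = 20,
                           cue_start = c(600, 200),
                           target_start = c(850, 325),
                           pocket = c(1150, 1050)) {
  g <- list(ball_diameter = ball_diameter, box_half_width = box_half_width,
            cue_start = as.numeric(cue_start),
            target_start = as.numeric(target_start),
            pocket = as.numeric(pocket))
  if (all(g$pocket == g$target_start))
    stop_pmbr("pocket must be distinct from the target start")
  class(g) <- "table_geometry"
  g
}

rotate2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

#' Simulate ball-tracking coordinates for one shot
#'
#' The cue ball rests at its start position (plus measurement noise) until
#' `onset_time`, then travels toward the target ball at constant speed; on
#' contact the target ball departs along a straight line whose angle
#' deviates from the pocket direction by `error_deg` (counterclockwise
#' positive), with a smooth accelerate-then-decelerate speed profile
#' peaking ~0.15 s after contact.
#'
#' @param error_deg signed directional error of the shot, degrees
#' @param onset_time cue-ball movement onset, s
#' @param geometry a [table_geometry()]
#' @param sfreq sampling rate in Hz (default 200)
#' @param t_start,t_end track time span, s (defaults: 0.4 s before onset to
#'   1.3 s after)
#' @param cue_speed cue-ball speed in mm/s (default 900)
#' @param noise_sd coordinate measurement noise SD in mm (default 0.3)
#' @return data frame with `time_s`, `cue_x_mm`, `cue_y_mm`, `target_x_mm`,
#'   `target_y_mm`
#' @export
generate_ball_track <- function(error_deg, onset_time, geometry = table_geometry(),
                                sfreq = 200, t_start = onset_time - 0.4,
                                t_end = onset_time + 1.3, cue_speed = 900,
                                noise_sd = 0.3) {
  assert_finite_scalar(error_deg, "error_deg")
  time <- seq(t_start, t_end, by = 1 / sfreq)
  sep <- geometry$target_start - geometry$cue_start
  d_contact <- sqrt(sum(sep^2)) - geometry$ball_diameter
  u_cue <- sep / sqrt(sum(sep^2))
  t_contact <- onset_time + d_contact / cue_speed

  cue_dist <- pmin(pmax(time - onset_time, 0) * cue_speed, d_contact)
  cue <- cbind(geometry$cue_start[1] + cue_dist * u_cue[1],
               geometry$cue_start[2] + cue_dist * u_cue[2])

  u_pocket <- geometry$pocket - geometry$target_start
  u_pocket <- u_pocket / sqrt(sum(u_pocket^2))
  u_target <- rotate2(u_pocket, error_deg)
  s <- pmax(time - t_contact, 0)
  tp <- 0.15; vmax <- 1200
  # v(s) = vmax * (s/tp) * exp(1 - s/tp); closed-form distance integral
  dist <- vmax * exp(1) * tp * (1 - exp(-s / tp) * (1 + s / tp))
  target <- cbind(geometry$target_start[1] + dist * u_target[1],
                  geometry$target_start[2] + dist * u_target[2])

  noise <- function(n) stats::rnorm(n, sd = noise_sd)
  data.frame(time_s = time,
             cue_x_mm = cue[, 1] + noise(length(time)),
             cue_y_mm = cue[, 2] + noise(length(time)),
             target_x_mm = target[, 1] + noise(length(time)),
             target_y_mm = target[, 2] + noise(length(time)))
}
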