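#' Per-cell migration velocity from three consecutive frames
#'
#' Central-difference velocity at a centre frame: the displacement between
#' the flanking frames (centre - 1, centre + 1) divided by twice the frame
#' interval, converted to um/h. Cells missing either flanking frame are
#' excluded (returned as `NA`), not an error.
#'
#' @param tracks track table (`data.frame` with columns `cell_id`, `group`,
#'   `frame`, `t_min`, `x_um`, `y_um`), as produced by [simulate_tracks()]
#'   or [read_tracks()].
#' @param center_frame the frame at which to evaluate velocities.
#' @return Data frame with one row per cell: `cell_id`, `group`, `x_um`,
#'   `y_um` (position at the centre frame), `vx`, `vy` (um/h; `NA` when a
#'   flanking frame is missing).
#' @export
cell_velocity <- function(tracks, center_frame) {
  check_tracks(tracks)
  dt_min <- frame_interval_min(tracks)
  cells <- unique(tracks$cell_id)
  at_frame <- function(f) {
    sub <- tracks[tracks$frame == f, , drop = FALSE]
    idx <- match(cells, sub$cell_id)
    list(x = sub$x_um[idx], y = sub$y_um[idx])
  }
  prev <- at_frame(center_frame - 1L)
  ctr <- at_frame(center_frame)
  nxt <- at_frame(center_frame + 1L)
  h <- 2 * dt_min / 60
  out <- data.frame(cell_id = cells,
                    group = tracks$group[match(cells, tracks$cell_id)],
                    x_um = ctr$x, y_um = ctr$y,
                    vx = (nxt$x - prev$x) / h,
                    vy = (nxt$y - prev$y) / h,
                    stringsAsFactors = FALSE)
  excluded <- sum(is.na(out$vx))
  if (excluded > 0)
    message(sprintf("cell_velocity: %d cell(s) lacking a complete frame triple excluded",
                    excluded))
  out
}

check_tracks <- function(tracks) {
  need <- c("cell_id", "group", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(tracks$x_um)) || !all(is.finite(tracks$y_um)))
    stop("coordinates must be finite")
  invisible(tracks)
}

frame_interval_min <- function(tracks) {
  d <- unique(diff(sort(unique(tracks$t_min))))
  if (length(d) == 0L) stop("need at least two frames")
  if (max(d) - min(d) > 1e-8)
    stop("frames must be uniformly spaced in time")
  d[1]
}

#' Grid-averaged migration vector field
#'
#' Averages per-cell velocities over a regular grid of circles: at each
#' grid point, the velocities of all labelled cells whose centre-frame
#' position lies within `radius` (inclusive) are arithmetically averaged.
#' Grid points are spaced `spacing` um apart, anchored at the track
#' bounding box minimum rounded down to a multiple of the spacing; circles
#' containing no cell are kept with `n = 0` and undefined vectors.
#'
#' Defaults follow the standard epiblast time-lapse analysis: 150 um grid
#' interval, 150 um averaging radius, velocities from the three frames
#' centred on `center_frame` (-1, 0, +1, i.e. -10/0/+10 min at 10-min
#' sampling). Each cell contributes its single triple-based velocity once.
#'
#' @param tracks track table (see [cell_velocity()]).
#' @param spacing grid interval, um.
#' @param radius averaging-circle radius, um.
#' @param center_frame centre frame of the velocity triples.
#' @return Object of class `velocity_field`: data frame with `gx`, `gy`
#'   (grid point, um), `vx`, `vy` (mean vector, um/h; `NA` when empty),
#'   `speed`, `n`; attributes `spacing`, `radius`, `center_frame`.
#' @export
grid_field <- function(tracks, spacing = 150, radius = 150, center_frame) {
  if (spacing <= 0 || radius <= 0)
    stop("spacing and radius must be positive")
  vel <- cell_velocity(tracks, center_frame)
  vel <- vel[!is.na(vel$vx) & !is.na(vel$x_um), , drop = FALSE]
  if (nrow(vel) == 0L) stop("no cell has a complete frame triple at this frame")
  gx0 <- floor(min(vel$x_um) / spacing) * spacing
  gy0 <- floor(min(vel$y_um) / spacing) * spacing
  gx <- seq(gx0, max(vel$x_um) + spacing, by = spacing)
  gy <- seq(gy0, max(vel$y_um) + spacing, by = spacing)
  grid <- expand.grid(gx = gx, gy = gy)
  n <- integer(nrow(grid))
  vx <- vy <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d2 <- (vel$x_um - grid$gx[i])^2 + (vel$y_um - grid$gy[i])^2
    inside <- d2 <= radius^2
    n[i] <- sum(inside)
    if (n[i] > 0) {
      vx[i] <- mean(vel$vx[inside])
      vy[i] <- mean(vel$vy[inside])
    }
  }
  out <- data.frame(gx = grid$gx, gy = grid$gy, vx = vx, vy = vy,
                    speed = sqrt(vx^2 + vy^2), n = n)
  structure(out, class = c("velocity_field", "data.frame"),
            spacing = spacing, radius = radius, center_frame = center_frame)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d grid points (spacing %g um, radius %g um), %d populated\n",
              nrow(x), attr(x, "spacing"), attr(x, "radius"), sum(x$n > 0)))
  pop <- x[x$n > 0, , drop = FALSE]
  if (nrow(pop))
    cat(sprintf("  mean speed over populated points: %.1f um/h\n",
                mean(pop$speed)))
  NextMethod()
}

#' Quiver plot of a velocity field
#'
#' Draws the grid vectors as arrows. Arrow length follows the conventional
#' scale in which an arrow as long as a 500 um scale bar corresponds to a
#' migration rate of 300 um/h (i.e. `um_per_umh = 500/300` when `scale` is
#' left as default).
#'
#' @param x a `velocity_field`.
#' @param scale plotted um per (um/h) of speed; default `500/300`.
#' @param ... passed to `plot.default`.
#' @export
plot.velocity_field <- function(x, scale = 500 / 300, ...) {
  pop <- x[x$n > 0, , drop = FALSE]
  plot.default(x$gx, x$gy, type = "n", asp = 1,
               xlab = "x (um)", ylab = "y (um, +posterior)", ...)
  points(x$gx[x$n == 0], x$gy[x$n == 0], pch = 3, col = "grey80", cex = 0.5)
  if (nrow(pop))
    arrows(pop$gx, pop$gy,
           pop$gx + pop$vx * scale, pop$gy + pop$vy * scale,
           length = 0.05)
  invisible(x)
}

#' Group speed summary
#'
#' For each cell of a group, velocities are computed over every complete
#' three-frame triple whose centre lies in `frames` and averaged into one
#' mean velocity vector per cell; the cell's speed is the norm of that
#' vector. Reported are the group mean speed, the sample SD across cells,
#' and the fraction of cells migrating posterior-dominantly
#' (`|vy| > |vx|` and `vy > 0`, with +y posterior).
#'
#' @param tracks track table.
#' @param group group label to summarise.
#' @param frames centre frames over which to average (default: all frames
#'   with both neighbours present).
#' @return List of class `speed_summary`: `group`, `n_cells`,
#'   `mean_speed`, `sd_speed` (um/h), `posterior_fraction`, `per_cell`
#'   data frame.
#' @export
speed_summary <- function(tracks, group, frames = NULL) {
  check_tracks(tracks)
  sub <- tracks[tracks$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no cells in group ", group)
  all_frames <- sort(unique(sub$frame))
  if (is.null(frames))
    frames <- all_frames[all_frames > min(all_frames) &
                         all_frames < max(all_frames)]
  vsum <- NULL
  for (f in frames) {
    v <- suppressMessages(cell_velocity(sub, f))
    v <- v[!is.na(v$vx), c("cell_id", "vx", "vy")]
    vsum <- rbind(vsum, v)
  }
  if (is.null(vsum) || nrow(vsum) == 0L)
    stop("no complete frame triples in the requested range")
  per_cell <- aggregate(cbind(vx, vy) ~ cell_id, data = vsum, FUN = mean)
  per_cell$speed <- sqrt(per_cell$vx^2 + per_cell$vy^2)
  if (nrow(per_cell) < 2L)
    stop("need at least two cells for a speed summary")
  structure(list(group = group, n_cells = nrow(per_cell),
                 mean_speed = mean(per_cell$speed),
                 sd_speed = sd(per_cell$speed),
                 posterior_fraction = mean(abs(per_cell$vy) > abs(per_cell$vx) &
                                             per_cell$vy > 0),
                 per_cell = per_cell),
            class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("Group %s: %.0f +/- %.0f (SD) um/h over %d cells; %.0f%% posterior-dominant\n",
              x$group, x$mean_speed, x$sd_speed, x$n_cells,
              100 * x$posterior_fraction))
  invisible(x)
}
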