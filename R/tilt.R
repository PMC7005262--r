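#' Grouped dose-symmetric tilt scheme
#'
#' Builds the acquisition order of a grouped dose-symmetric single-axis tilt
#' series: an initial positive group containing zero, then alternating
#' negative/positive side groups of `group_size` angles of increasing
#' magnitude, until `max_angle` is reached on both sides. For
#' `make_tilt_scheme(60, 2, 5)` the order begins
#' 0, +2, ..., +10, -2, ..., -10, +12, ..., +20, -12, ...
#'
#' @param max_angle maximum tilt magnitude in degrees (> 0).
#' @param step tilt increment in degrees; must divide `max_angle`.
#' @param group_size number of angles per side group (>= 1).
#' @return an object of class `tilt_scheme` with fields `max_angle`, `step`,
#'   `group_size` and `order` (signed degrees, acquisition order).
#' @examples
#' sch <- make_tilt_scheme(60, 2, 5)
#' head(sch$order, 17)
#' @export
make_tilt_scheme <- function(max_angle, step, group_size) {
  stopifnot(is.numeric(max_angle), is.numeric(step), is.numeric(group_size))
  if (max_angle <= 0 || step <= 0)
    stop("max_angle and step must be positive")
  if (abs(max_angle / step - round(max_angle / step)) > 1e-9)
    stop("step must divide max_angle")
  group_size <- as.integer(group_size)
  if (group_size < 1) stop("group_size must be >= 1")
  n_side <- as.integer(round(max_angle / step))
  if (group_size > n_side)
    stop("group_size exceeds the number of angles per side")

  pos_used <- 0L   # positive angles emitted so far (multiples of step)
  neg_used <- 0L
  order <- 0
  # first group: zero plus group_size positive angles
  k <- seq_len(min(group_size, n_side))
  order <- c(order, k * step)
  pos_used <- length(k)
  side <- -1L
  while (pos_used < n_side || neg_used < n_side) {
    if (side < 0 && neg_used < n_side) {
      k <- neg_used + seq_len(min(group_size, n_side - neg_used))
      order <- c(order, -k * step)
      neg_used <- max(k)
    } else if (side > 0 && pos_used < n_side) {
      k <- pos_used + seq_len(min(group_size, n_side - pos_used))
      order <- c(order, k * step)
      pos_used <- max(k)
    }
    side <- -side
  }
  structure(list(max_angle = max_angle, step = step, group_size = group_size,
                 order = order),
            class = "tilt_scheme")
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf("tilt_scheme: +/-%g deg in %g deg steps, groups of %d (%d tilts)\n",
              x$max_angle, x$step, x$group_size, length(x$order)))
  cat("order:", paste(utils::head(sprintf("%+g", x$order), 21), collapse = " "),
      if (length(x$order) > 21) "..." else "", "\n")
  invisible(x)
}
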