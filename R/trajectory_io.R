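TRAJECTORY_COLUMNS <- c("time", "x", "y", "pe", "pwpe_sq", "surprise",
                        "action", "mu_prior", "pi_prior", "self_efficacy",
                        "stage")

#' Write / read a trajectory
#'
#' Trajectories are stored as plain UTF-8 CSV with one header row and one
#' row per integration step, columns in the documented order
#' (`time, x, y, pe, pwpe_sq, surprise, action, mu_prior, pi_prior,
#' self_efficacy, stage`), '.' as decimal separator and no thousands
#' separators. Numeric values round-trip to at least 12 significant
#' digits, and identical configurations and seeds produce byte-identical
#' files. The generating configuration (including its seed) is serialized
#' alongside as JSON unless `config_path = NA`.
#'
#' @param trajectory A `reflex_trajectory` from [run_simulation()].
#' @param path Output CSV path.
#' @param config_path Path for the JSON scenario sidecar; defaults to
#'   `path` with a `.json` extension, `NA` suppresses it.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`:
#'   the trajectory data frame (with the configuration attached when the
#'   sidecar is found).
#' @export
write_trajectory <- function(trajectory, path,
                             config_path = default_config_path(path)) {
  stopifnot(is.data.frame(trajectory))
  if (!identical(names(trajectory), TRAJECTORY_COLUMNS))
    stop("trajectory columns must be exactly: ",
         paste(TRAJECTORY_COLUMNS, collapse = ", "))
  df <- as.data.frame(trajectory)
  for (nm in setdiff(TRAJECTORY_COLUMNS, "stage"))
    df[[nm]] <- sprintf("%.15g", df[[nm]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  cfg <- attr(trajectory, "config")
  if (!is.null(cfg) && !is.na(config_path))
    write_scenario(cfg, config_path)
  invisible(path)
}

default_config_path <- function(path) {
  sub("(\\.csv)?$", ".json", path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, config_path = default_config_path(path)) {
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            colClasses = "character")
  if (!identical(unname(unlist(header)), TRAJECTORY_COLUMNS))
    stop("parse error in ", path, " at line 1: header must be '",
         paste(TRAJECTORY_COLUMNS, collapse = ","), "'")
  df <- utils::read.csv(path, header = TRUE,
                        colClasses = c(rep("character", 10), "character"))
  names(df) <- TRAJECTORY_COLUMNS
  for (nm in setdiff(TRAJECTORY_COLUMNS, "stage")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.finite(v) & nzchar(df[[nm]]))
    if (length(bad))
      stop("parse error in ", path, " at line ", bad[1] + 1L,
           ": non-numeric value '", df[[nm]][bad[1]], "' in column ", nm)
    df[[nm]] <- v
  }
  class(df) <- c("reflex_trajectory", "data.frame")
  if (!is.na(config_path) && file.exists(config_path))
    attr(df, "config") <- read_scenario(config_path)
  df
}

#' @export
print.reflex_trajectory <- function(x, ...) {
  cat(sprintf("<reflex trajectory: %d steps over %g s>\n", nrow(x),
              if (nrow(x)) max(x$time) else 0))
  if (nrow(x)) {
    print(utils::head(as.data.frame(x), 4L))
    if (nrow(x) > 4L) cat("... (", nrow(x) - 4L, " more rows)\n", sep = "")
  }
  invisible(x)
}

#' Plot a trajectory
#'
#' Three stacked panels: the controlled state with the current setpoint,
#' the squared precision-weighted prediction error (the surprise
#' approximation), and the action signal. A convenience view, not part of
#' the numerical contract.
#'
#' @param x A `reflex_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.reflex_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$x, type = "l", xlab = "", ylab = "state x", ...)
  graphics::lines(x$time, x$mu_prior, lty = 2, col = "grey40")
  graphics::plot(x$time, x$pwpe_sq, type = "l", xlab = "",
                 ylab = expression(pwPE^2), ...)
  graphics::plot(x$time, x$action, type = "l", xlab = "time",
                 ylab = "action a", ...)
  invisible(x)
}
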