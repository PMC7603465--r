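# Plotting, tidiers and plain-text exports for simulation results.

#' Tidy a simulation series
#'
#' Returns the per-increment central-region summary as a plain tibble
#' (drops the attached simulation state).
#'
#' @param x an `artery_series` from [run_s_test()] and friends.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.artery_series <- function(x, ...) {
  out <- x
  attr(out, "final_state") <- NULL
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "artery_series")
  tibble::as_tibble(out)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a simulation series
#'
#' @param x an `artery_series`.
#' @param ... unused.
#' @return one-row tibble: final load state, final mean radius, final
#'   first-family angle and axial stress, number of increments.
#' @export
glance.artery_series <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble::tibble(
    increments = nrow(x) - 1L,
    P_mmHg = last$P_mmHg, lambda = last$lambda,
    mean_radius = last$mean_radius, rel_diameter = last$rel_diameter,
    theta1_deg = last$theta1_deg,
    axial_stress_kPa = last$axial_stress_kPa)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a simulation series
#'
#' Line plot of a chosen response against the active loading variable
#' (stretch during tension phases, pressure during inflation phases).
#'
#' @param object an `artery_series`.
#' @param y response column name (default `"theta1_deg"`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.artery_series <- function(object, y = "theta1_deg", ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2")
  }
  df <- tidy.artery_series(object)
  df$.y <- df[[y]]
  ggplot2::ggplot(df, ggplot2::aes(x = increment, y = .y, colour = phase)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "increment", y = y) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("increment", ".y", "phase"))

#' Write a simulation series to CSV
#'
#' @param series an `artery_series`.
#' @param path output file path.
#' @return the path, invisibly.
#' @importFrom utils write.csv
#' @export
write_series_csv <- function(series, path) {
  write.csv(tidy.artery_series(series), path, row.names = FALSE)
  invisible(path)
}

#' Export a simulation state as a legacy-ASCII VTK unstructured grid
#'
#' Writes the current nodal coordinates (mm), hex8 connectivity, nodal
#' displacement vectors and per-element layer tag, first-family fiber angle
#' and axial Cauchy stress (element averages over Gauss points).
#'
#' @param sim a `simulation` (e.g. `attr(series, "final_state")`).
#' @param path output file path (`.vtk`).
#' @return the path, invisibly.
#' @export
write_vtk <- function(sim, path) {
  mesh <- sim$mesh
  ne <- nrow(mesh$elems); nn <- nrow(sim$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("arterymech simulation state")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nn)
  writeLines(apply(sim$nodes, 1, function(p) sprintf("%.9g %.9g %.9g",
                                                     p[1], p[2], p[3])), con)
  w("CELLS %d %d", ne, ne * 9L)
  writeLines(apply(mesh$elems - 1L, 1, function(e) paste(c(8L, e), collapse = " ")), con)
  w("CELL_TYPES %d", ne)
  writeLines(rep("12", ne), con)
  w("POINT_DATA %d", nn)
  w("VECTORS displacement double")
  writeLines(apply(sim$U, 1, function(p) sprintf("%.9g %.9g %.9g",
                                                 p[1], p[2], p[3])), con)
  w("CELL_DATA %d", ne)
  w("SCALARS layer int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(ifelse(mesh$layer == "media", 1L, 2L)), con)
  theta <- sTT <- numeric(ne)
  for (e in seq_len(ne)) {
    th <- s <- numeric(8)
    for (k in 1:8) {
      st <- sim$states[[(e - 1L) * 8L + k]]
      s[k] <- as.numeric(st$lrs$T %*% st$stress %*% st$lrs$T)
      th[k] <- if (st$layer == "adventitia") {
        angle_from_axial(st$families[[1]]$frame$c, st$lrs)
      } else NA_real_
    }
    theta[e] <- mean(th); sTT[e] <- mean(s)
  }
  w("SCALARS theta1_deg double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.6g", ifelse(is.na(theta), -1, theta)), con)
  w("SCALARS axial_stress_MPa double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.6g", sTT), con)
  invisible(path)
}
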