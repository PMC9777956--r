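#' Write binned observations to CSV
#'
#' One row per registration period; the header encodes the half-open slot
#' intervals as \code{"lo:hi"}.
#'
#' @param obs a \code{\link{binned_observations}} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_binned_observations <- function(obs, path) {
  stopifnot(inherits(obs, "binned_observations"))
  e <- obs$slot_edges
  hdr <- sprintf("%g:%g", e[-length(e)], e[-1])
  df <- as.data.frame(obs$counts)
  names(df) <- hdr
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binned observations from CSV
#'
#' Inverse of \code{\link{write_binned_observations}}: the header row holds
#' slot intervals \code{"lo:hi"} and each subsequent row is one period's
#' counts.  Malformed headers, non-monotone edges, and negative or
#' non-integer counts are rejected with the offending cell named.
#'
#' @param path CSV file path.
#' @param period_length_days period length metadata (not stored in the CSV).
#' @return A \code{\link{binned_observations}} object.
#' @export
read_binned_observations <- function(path, period_length_days = 31L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("empty observation table in ", path, call. = FALSE)
  parts <- strsplit(names(df), ":", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed slot header %s (column %d); expected \"lo:hi\"",
                 dQuote(names(df)[bad[1]]), bad[1]), call. = FALSE)
  los <- as.numeric(vapply(parts, `[`, character(1), 1L))
  his <- as.numeric(vapply(parts, `[`, character(1), 2L))
  if (any(is.na(los)) || any(is.na(his)))
    stop("non-numeric slot boundary in header", call. = FALSE)
  if (any(abs(los[-1] - his[-length(his)]) > 1e-9))
    stop("slot intervals are not contiguous", call. = FALSE)
  edges <- c(los, his[length(his)])
  if (any(diff(edges) <= 0))
    stop("slot edges are not strictly increasing", call. = FALSE)
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col) || any(is.na(col)))
      stop(sprintf("non-numeric count in column %d (%s)", j, names(df)[j]),
           call. = FALSE)
    if (any(col < 0)) {
      i <- which(col < 0)[1]
      stop(sprintf("negative count at row %d, column %d (%s)", i, j,
                   names(df)[j]), call. = FALSE)
    }
    if (any(col != round(col))) {
      i <- which(col != round(col))[1]
      stop(sprintf("non-integer count at row %d, column %d (%s)", i, j,
                   names(df)[j]), call. = FALSE)
    }
  }
  structure(list(slot_edges = edges,
                 period_length_days = as.integer(period_length_days),
                 counts = matrix(as.integer(as.matrix(df)), nrow = nrow(df)),
                 n_overflow = 0L),
            class = "binned_observations")
}

#' Write a binned distribution to CSV
#'
#' Columns \code{slot_lo}, \code{slot_hi}, \code{mass}.
#'
#' @param d a \code{\link{binned_distribution}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_distribution <- function(d, path) {
  stopifnot(inherits(d, "binned_distribution"))
  e <- d$slot_edges
  utils::write.csv(
    data.frame(slot_lo = e[-length(e)], slot_hi = e[-1], mass = d$masses),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binned distribution from CSV
#'
#' @param path CSV with columns \code{slot_lo}, \code{slot_hi}, \code{mass}.
#' @return A \code{\link{binned_distribution}}.
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("slot_lo", "slot_hi", "mass")
  if (!all(need %in% names(df)))
    stop("distribution CSV needs columns slot_lo, slot_hi, mass",
         call. = FALSE)
  if (any(abs(df$slot_lo[-1] - df$slot_hi[-nrow(df)]) > 1e-9))
    stop("slots are not contiguous", call. = FALSE)
  binned_distribution(c(df$slot_lo, df$slot_hi[nrow(df)]), df$mass)
}

#' Write a fit result to JSON
#'
#' @param fit a \code{\link{fit_params}} result.
#' @param path output JSON path.
#' @param trace_path optional CSV path for the search trace.
#' @return \code{path}, invisibly.
#' @export
write_fit_result <- function(fit, path, trace_path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  x <- list(alpha = fit$alpha, k_alpha = fit$k_alpha, hurst = fit$hurst,
            rmse = fit$rmse, admissible = fit$admissible,
            n_evaluations = fit$n_evaluations, skipped = fit$skipped,
            target = fit$target, initial = fit$initial)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(trace_path) && !is.null(fit$search_trace))
    utils::write.csv(fit$search_trace, trace_path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation config from JSON
#'
#' Fields absent from the file keep the \code{\link{simulation_config}}
#' defaults.  The baseline distribution may be given as a \code{masses}
#' array (on the config's slot edges).
#'
#' @param path JSON file path.
#' @return A \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[names(x) %in% c("n_patients", "follow_up_days", "visit_rate",
                            "ctrw_alpha", "jump_scale", "waiting_scale",
                            "slot_edges", "period_length_days", "n_periods",
                            "seed")]
  cfg <- do.call(simulation_config, args)
  if (!is.null(x$baseline_masses))
    cfg$baseline_dist <- binned_distribution(cfg$slot_edges,
                                             x$baseline_masses,
                                             normalize = TRUE)
  cfg
}

#' Write an observation table to CSV
#'
#' @param table an \code{observation_table} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_observation_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation table from CSV
#'
#' @param path CSV with columns \code{patient_id}, \code{visit_time_days},
#'   \code{value}.
#' @return An \code{observation_table} data frame.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("patient_id", "visit_time_days", "value")
  if (!all(need %in% names(df)))
    stop("observation CSV needs columns patient_id, visit_time_days, value",
         call. = FALSE)
  if (any(!is.finite(df$value)))
    stop("non-finite values in observation table", call. = FALSE)
  class(df) <- c("observation_table", "data.frame")
  df
}
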