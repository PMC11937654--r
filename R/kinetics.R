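# Plate-reader exports put wells in columns and timepoints in rows (first
# column = time in minutes). Internally everything is one tidy table:
# (well, group, time, value), one row per measurement.

#' Parse a plate-reader kinetic fluorescence table
#'
#' Reads a delimited matrix whose first column is time (minutes) and whose
#' remaining columns are wells (header = well ids), and returns a tidy
#' long-format table. Wells absent from `layout` are assigned the group
#' `"ungrouped"`.
#'
#' @param table Path to a CSV/TSV file, or a data.frame already in
#'   wells-as-columns layout.
#' @param layout Named character vector mapping well id to replicate-group
#'   label, e.g. `c(A1 = "mut_crRNA", A2 = "mut_crRNA", B1 = "neg")`.
#' @param sep Field separator when `table` is a path; guessed from the file
#'   extension by default (`","` for .csv, `"\t"` otherwise).
#' @return `data.frame` of class `kinetic_traces` with columns `well`,
#'   `group`, `time`, `value`, ordered by well then time.
#' @export
parse_kinetic_table <- function(table, layout = NULL, sep = NULL) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) stop("kinetic table not found: ", table)
    if (is.null(sep)) sep <- if (grepl("\\.csv$", table, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(table, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table, check.names = FALSE)
  }
  if (ncol(df) < 2L) stop("kinetic table needs a time column plus >= 1 well column")
  wells <- names(df)[-1L]
  if (anyDuplicated(wells)) {
    stop("duplicate well column header(s): ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  }
  times <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(times)) stop("non-numeric cells in the time column")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  long <- do.call(rbind, lapply(wells, function(w) {
    vals <- suppressWarnings(as.numeric(df[[w]]))
    if (anyNA(vals)) stop("non-numeric cells in well column '", w, "'")
    grp <- if (!is.null(layout) && w %in% names(layout)) unname(layout[[w]])
           else "ungrouped"
    data.frame(well = w, group = grp, time = times, value = vals,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  class(long) <- c("kinetic_traces", class(long))
  long
}

#' Serialize kinetic traces back to wells-as-columns layout
#' @param traces A `kinetic_traces` data.frame.
#' @return A wide data.frame, first column `time`, one column per well.
#' @export
kinetic_wide <- function(traces) {
  wells <- unique(traces$well)
  times <- sort(unique(traces$time))
  out <- data.frame(time = times)
  for (w in wells) {
    tw <- traces[traces$well == w, ]
    out[[w]] <- tw$value[match(times, tw$time)]
  }
  out
}

#' Remove the baseline from kinetic traces
#'
#' `first_timepoint` subtracts each well's t0 value from that well's whole
#' trace (every trace then starts at exactly 0). `control_group_mean`
#' subtracts, timepoint by timepoint, the mean trace of a negative-control
#' group from every well. Times are unchanged.
#'
#' @param traces A `kinetic_traces` data.frame.
#' @param mode `"first_timepoint"` (default) or `"control_group_mean"`.
#' @param control Group label of the negative control (required for
#'   `control_group_mean`).
#' @return The baseline-subtracted `kinetic_traces`.
#' @export
baseline_subtract <- function(traces,
                              mode = c("first_timepoint", "control_group_mean"),
                              control = NULL) {
  mode <- match.arg(mode)
  out <- traces
  if (mode == "first_timepoint") {
    for (w in unique(out$well)) {
      sel <- out$well == w
      tw <- out[sel, ]
      t0 <- tw$value[which.min(tw$time)]
      out$value[sel] <- tw$value - t0
    }
  } else {
    if (is.null(control)) stop("control group label required for control_group_mean")
    ctrl <- traces[traces$group == control, , drop = FALSE]
    if (nrow(ctrl) == 0L) stop("control group '", control, "' has no traces")
    ctrl_mean <- tapply(ctrl$value, ctrl$time, mean)
    miss <- setdiff(unique(out$time), as.numeric(names(ctrl_mean)))
    if (length(miss)) stop("control group lacks timepoint(s): ",
                           paste(miss, collapse = ", "))
    out$value <- out$value - as.numeric(ctrl_mean[as.character(out$time)])
  }
  class(out) <- unique(c("kinetic_traces", class(out)))
  out
}

group_endpoints <- function(traces, group, timepoint) {
  g <- traces[traces$group == group, , drop = FALSE]
  if (nrow(g) == 0L) stop("no traces in group '", group, "'")
  wells <- unique(g$well)
  if (identical(timepoint, "last")) {
    common <- Reduce(intersect, lapply(wells, function(w) g$time[g$well == w]))
    if (length(common) == 0L) stop("group '", group, "' wells share no timepoint")
    tp <- max(common)
  } else {
    tp <- as.numeric(timepoint)
  }
  vals <- vapply(wells, function(w) {
    tw <- g[g$well == w, ]
    i <- which(tw$time == tp)
    if (length(i) != 1L) stop("timepoint ", tp, " min not measured in well ", w)
    tw$value[i]
  }, numeric(1))
  list(values = unname(vals), timepoint = tp, n = length(vals))
}

#' Replicate-aggregated endpoint fluorescence ratio between two groups
#'
#' `ratio = mean(numerator endpoints) / mean(denominator endpoints)`, taken
#' at the last common timepoint by default or at an explicit time in
#' minutes. The standard deviation is propagated to first order from the
#' two group standard deviations:
#' `sd = |ratio| * sqrt((sd_num/mean_num)^2 + (sd_den/mean_den)^2)`
#' (single-replicate groups contribute 0).
#'
#' @param traces A `kinetic_traces` data.frame (typically baseline
#'   subtracted).
#' @param numerator,denominator Group labels.
#' @param timepoint `"last"` (default) or a time in minutes present in every
#'   involved well.
#' @return One-row `data.frame` of class `ratio_result`: `numerator_group`,
#'   `denominator_group`, `timepoint`, `ratio`, `sd`, `n_num`, `n_den`.
#' @export
endpoint_ratio <- function(traces, numerator, denominator, timepoint = "last") {
  if (identical(timepoint, "last")) {
    both <- traces[traces$group %in% c(numerator, denominator), ]
    wells <- unique(both$well)
    common <- Reduce(intersect, lapply(wells, function(w) both$time[both$well == w]))
    if (length(common) == 0L) stop("groups share no common timepoint")
    timepoint <- max(common)
  }
  num <- group_endpoints(traces, numerator, timepoint)
  den <- group_endpoints(traces, denominator, timepoint)
  m_n <- mean(num$values); m_d <- mean(den$values)
  if (m_d == 0) stop("denominator group mean is 0 at t = ", timepoint, " min")
  sd_n <- if (num$n > 1L) stats::sd(num$values) else 0
  sd_d <- if (den$n > 1L) stats::sd(den$values) else 0
  ratio <- m_n / m_d
  sd <- abs(ratio) * sqrt((sd_n / m_n)^2 + (sd_d / m_d)^2)
  out <- data.frame(numerator_group = numerator,
                    denominator_group = denominator,
                    timepoint = num$timepoint, ratio = ratio, sd = sd,
                    n_num = num$n, n_den = den$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_result", class(out))
  out
}

#' Write kinetic traces as tidy TSV
#' @param traces A `kinetic_traces` data.frame.
#' @param path Output path or `""` for standard output.
#' @return Invisibly, `traces`.
#' @export
write_traces_tsv <- function(traces, path = "") {
  utils::write.table(as.data.frame(traces), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(traces)
}
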