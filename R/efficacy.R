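# Phenotype metrics on tabulated records: whole-body escape force, 2-limb
# grip strength, and per-fiber histology percentages. Image segmentation is
# out of scope; inputs are already-tabulated sessions and fiber tables.

#' Force session record
#'
#' @param peaks force peaks in newtons. Escape sessions record the pull
#'   peaks in response to tail pinches (at least 15); grip sessions record
#'   exactly 3 independent measurements.
#' @param body_weight body weight in grams.
#' @param kind `"escape"` or `"grip"`.
#' @return object of class `force_session`.
#' @export
force_session <- function(peaks, body_weight, kind = c("escape", "grip")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(peaks), body_weight > 0)
  structure(list(peaks = peaks, body_weight = body_weight, kind = kind),
            class = "force_session")
}

#' Escape-test force
#'
#' The top 5 pulling tensions are averaged and divided by the body weight.
#' Sessions record at least 15 pinches; longer sessions use all peaks for
#' the top-5 selection.
#'
#' @param s a `force_session` of kind `"escape"`.
#' @param top number of peaks averaged (default 5).
#' @param min_peaks minimum session length (default 15).
#' @return list with `max_peak` (N) and `normalized_mean` (N/g).
#' @export
escape_force <- function(s, top = 5L, min_peaks = 15L) {
  stopifnot(inherits(s, "force_session"))
  if (s$kind != "escape") stop_dq("not an escape session", "wrong_session")
  if (length(s$peaks) < min_peaks)
    stop_dq(sprintf("insufficient session: %d peaks, need >= %d",
                    length(s$peaks), min_peaks), "insufficient_session")
  list(max_peak = max(s$peaks),
       normalized_mean = top_k_mean(s$peaks, top) / s$body_weight)
}

top_k_mean <- function(x, k) mean(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])

#' Grip-strength force
#'
#' Mean of the 3 independent grip measurements normalized to body weight.
#'
#' @param s a `force_session` of kind `"grip"`.
#' @return normalized mean grip force (N/g).
#' @export
grip_force <- function(s) {
  stopifnot(inherits(s, "force_session"))
  if (s$kind != "grip") stop_dq("not a grip session", "wrong_session")
  if (length(s$peaks) != 3L)
    stop_dq(sprintf("grip sessions have exactly 3 measurements, got %d",
                    length(s$peaks)), "insufficient_session")
  top_k_mean(s$peaks, 3L) / s$body_weight
}

#' Fiber-table percentages
#'
#' Percentage of dystrophin-positive fibers and of centrally-nucleated
#' fibers, each relative to the total number of fibers in the table.
#'
#' @param t data.frame with logical columns `dys_positive` and
#'   `centrally_nucleated` (one row per fiber).
#' @return named vector `dys_positive_pct`, `centronucleation_pct`.
#' @export
fiber_percentages <- function(t) {
  t <- as.data.frame(t)
  if (nrow(t) == 0) stop_dq("empty fiber table", "empty_table")
  stopifnot(all(c("dys_positive", "centrally_nucleated") %in% names(t)))
  if (anyNA(t$dys_positive) || anyNA(t$centrally_nucleated))
    stop_dq("fiber flags must be defined for all rows", "empty_table")
  c(dys_positive_pct = 100 * mean(as.logical(t$dys_positive)),
    centronucleation_pct = 100 * mean(as.logical(t$centrally_nucleated)))
}

#' Read force sessions from CSV
#'
#' Long format with columns `animal`, `group`, `kind`, `body_weight`,
#' `peak`; one row per recorded peak.
#'
#' @param path CSV file.
#' @return named list of `force_session`s (one per animal/kind), with the
#'   group labels as a `groups` attribute.
#' @export
read_force_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "kind", "body_weight", "peak")
  if (!all(need %in% names(df)))
    stop_dq(paste("force CSV needs columns", paste(need, collapse = ", ")),
            "parse_error")
  keys <- paste(df$animal, df$kind, sep = ".")
  out <- lapply(split(df, keys), function(d)
    force_session(d$peak, d$body_weight[1], d$kind[1]))
  if ("group" %in% names(df))
    attr(out, "groups") <- vapply(split(df, keys),
                                  function(d) as.character(d$group[1]),
                                  character(1))
  out
}

#' Read a fiber table from CSV
#'
#' Columns: `fiber_id`, `dys_positive`, `centrally_nucleated` (0/1 or
#' TRUE/FALSE).
#'
#' @param path CSV file.
#' @return data.frame usable by [fiber_percentages()].
#' @export
read_fiber_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dys_positive", "centrally_nucleated")
  if (!all(need %in% names(df)))
    stop_dq(paste("fiber CSV needs columns", paste(need, collapse = ", ")),
            "parse_error")
  df$dys_positive <- as.logical(df$dys_positive)
  df$centrally_nucleated <- as.logical(df$centrally_nucleated)
  df
}

#' Cohort summary (mean +/- SEM per group)
#'
#' @param values numeric vector of per-animal metrics.
#' @param groups group label per value.
#' @return data.frame with `group`, `n`, `mean`, `sem`.
#' @export
cohort_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  sp <- split(values, groups)
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sem = vapply(sp, function(v)
               if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               numeric(1)),
             row.names = NULL)
}
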