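#' Long-format N-of-1 trial data
#'
#' `nof1_data()` validates a long-format measurement table (one row per
#' individual x time point) and returns a tibble of class `nof1_data` carrying
#' trial-level metadata as attributes.  Rows with a missing outcome `value` are
#' kept: they are design slots that imputation can fill later.
#'
#' Required columns: `id` (individual label), `time` (study weeks from the
#' first baseline measurement, 0-based), `period` (integer, 0 = baseline,
#' 1..P = experimental periods), `treatment` (integer code 1..K, 1 =
#' reference), `value` (outcome, `NA` = missing).  Optional: `reporter`
#' (selects outcome bounds, e.g. "child"/"parent"), `sequence` (e.g. "ABAB").
#'
#' @param x A data frame with the columns above.
#' @param k Number of treatments; default `max(treatment)`.
#' @param bounds Outcome bounds: a length-2 numeric `c(lower, upper)` applied
#'   to everyone, or a named list of such vectors keyed by reporter label, or
#'   `NULL` for unbounded.  Default [promis_bounds()], the pain-interference
#'   T-score ranges (34-78 child report, 38-78 parent report).
#' @param covariates Optional tibble of per-individual covariates with an `id`
#'   column (used for subgroup models).
#' @return A tibble of class `nof1_data`, sorted by individual and time.
#' @export
#' @examples
#' d <- nof1_data(data.frame(
#'   id = "p1", time = 0:3, period = c(0, 1, 1, 2),
#'   treatment = c(1, 2, 2, 1), value = c(50, 47, 46, 51)
#' ), bounds = NULL)
#' n_treatments(d)
nof1_data <- function(x, k = NULL, bounds = promis_bounds(), covariates = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("id", "time", "period", "treatment", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$time <- as.numeric(x$time)
  x$period <- as.integer(x$period)
  x$treatment <- as.integer(x$treatment)
  x$value <- as.numeric(x$value)
  x <- dplyr::arrange(x, .data$id, .data$time)

  if (any(bad <- is.na(x$treatment) | x$treatment < 1L)) {
    stop("invalid treatment code (must be an integer >= 1) in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  k <- if (is.null(k)) max(x$treatment) else as.integer(k)
  if (k < 2) stop("need at least two treatments (k >= 2)", call. = FALSE)
  if (any(bad <- x$treatment > k)) {
    stop("treatment code exceeds k = ", k, " in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  dup <- x |>
    dplyr::summarise(dup = anyDuplicated(.data$time) > 0, .by = "id")
  if (any(dup$dup)) {
    stop("times not strictly increasing within individual(s): ",
         paste(dup$id[dup$dup], collapse = ", "), call. = FALSE)
  }
  mixed <- x |>
    dplyr::summarise(n_trt = dplyr::n_distinct(.data$treatment),
                     .by = c("id", "period"))
  if (any(mixed$n_trt > 1)) {
    bad <- mixed[mixed$n_trt > 1, ]
    stop("treatment not constant within (individual, period): ",
         paste(bad$id, bad$period, sep = "/", collapse = ", "), call. = FALSE)
  }

  check_bounds(x, bounds)
  structure(
    x,
    class = c("nof1_data", class(tibble::tibble())),
    k = k,
    bounds = bounds,
    covariates = if (!is.null(covariates)) tibble::as_tibble(covariates),
    washout_log = tibble::tibble(id = character(), period = integer(),
                                 time = numeric(), value = numeric()),
    period_starts = x |>
      dplyr::summarise(start = min(.data$time), .by = c("id", "period"))
  )
}

check_bounds <- function(x, bounds) {
  if (is.null(bounds)) return(invisible(TRUE))
  bl <- bounds_for(x, bounds)
  obs <- !is.na(x$value)
  bad <- obs & (x$value < bl$lower | x$value > bl$upper)
  if (any(bad)) {
    stop("outcome outside declared bounds in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# per-row lower/upper resolved from a shared vector or reporter-keyed list
bounds_for <- function(x, bounds) {
  if (is.null(bounds)) {
    return(list(lower = rep(-Inf, nrow(x)), upper = rep(Inf, nrow(x))))
  }
  if (is.numeric(bounds)) {
    return(list(lower = rep(bounds[1], nrow(x)), upper = rep(bounds[2], nrow(x))))
  }
  rep_col <- if ("reporter" %in% names(x)) as.character(x$reporter) else
    rep(names(bounds)[1], nrow(x))
  rep_col[is.na(rep_col)] <- names(bounds)[1]
  unknown <- setdiff(unique(rep_col), names(bounds))
  if (length(unknown) > 0) {
    stop("no bounds declared for reporter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lower <- vapply(rep_col, function(r) bounds[[r]][1], numeric(1))
  upper <- vapply(rep_col, function(r) bounds[[r]][2], numeric(1))
  list(lower = unname(lower), upper = unname(upper))
}

#' @export
#' @rdname nof1_data
n_treatments <- function(x) attr(x, "k")

#' PROMIS pain-interference T-score bounds
#'
#' Default outcome bounds by reporter: 34-78 for child report, 38-78 for
#' parent report.
#' @return Named list of `c(lower, upper)` vectors.
#' @export
promis_bounds <- function() {
  list(child = c(34, 78), parent = c(38, 78))
}

# keep attributes through dplyr-style subsetting used internally
reclass_nof1 <- function(new, template) {
  attrs <- c("k", "bounds", "covariates", "washout_log", "period_starts")
  for (a in attrs) attr(new, a) <- attr(template, a)
  class(new) <- class(template)
  new
}

#' Read and write N-of-1 trial data as CSV
#'
#' `read_trials()` reads a UTF-8 CSV with a header row into an [nof1_data]
#' tibble; `write_trials()` writes one back.  Missing outcomes may be encoded
#' as empty cells or `NA` and are preserved as missing rows, not dropped.
#'
#' @param path File path.
#' @param schema Named character vector mapping the canonical column names
#'   (`id`, `time`, `period`, `treatment`, `value`, and optionally `reporter`,
#'   `sequence`) to the column names used in the file.
#' @inheritParams nof1_data
#' @return `read_trials()`: an [nof1_data] tibble.
#' @export
read_trials <- function(path, schema = NULL, k = NULL, bounds = promis_bounds(),
                        covariates = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop("schema column '", src, "' not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  nof1_data(raw, k = k, bounds = bounds, covariates = covariates)
}

#' @param data An [nof1_data] tibble.
#' @rdname read_trials
#' @export
write_trials <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, na = "NA")
  invisible(path)
}

#' Analytic washout: drop leading measurements of experimental periods
#'
#' Removes the first `n_drop` measurements of every experimental period
#' (`period >= 1`); the baseline period is untouched.  Dropped rows are
#' appended to the `washout_log` attribute.  Because the number of rows
#' already removed per period is tracked, re-applying with the same `n_drop`
#' is a no-op.
#'
#' @param data An [nof1_data] tibble.
#' @param n_drop Non-negative integer count of leading measurements to drop
#'   per experimental period.
#' @return The trimmed [nof1_data] tibble.
#' @export
apply_washout <- function(data, n_drop = 1L) {
  stopifnot(inherits(data, "nof1_data"), n_drop >= 0)
  if (n_drop == 0) return(data)
  log <- attr(data, "washout_log")
  already <- log |>
    dplyr::summarise(n_dropped = dplyr::n(), .by = c("id", "period"))

  df <- tibble::as_tibble(data)
  df$._row <- seq_len(nrow(df))
  drop_rows <- integer(0)
  for (key in split(df[df$period >= 1L, ],
                    interaction(df$id[df$period >= 1L],
                                df$period[df$period >= 1L], drop = TRUE))) {
    if (nrow(key) == 0) next
    prev <- already$n_dropped[already$id == key$id[1] &
                                already$period == key$period[1]]
    prev <- if (length(prev)) prev else 0L
    take <- max(0L, n_drop - prev)
    if (take >= nrow(key)) {
      warning("washout empties period ", key$period[1], " of individual ",
              key$id[1], call. = FALSE)
      take <- nrow(key)
    }
    if (take > 0) drop_rows <- c(drop_rows, key$._row[seq_len(take)])
  }
  if (length(drop_rows) > 0) {
    dropped <- df[df$._row %in% drop_rows, c("id", "period", "time", "value")]
    log <- dplyr::bind_rows(log, dropped)
    df <- df[-drop_rows, ]
  }
  df$._row <- NULL
  out <- reclass_nof1(df, data)
  attr(out, "washout_log") <- log
  out
}

#' @rdname apply_washout
#' @export
washout_log <- function(data) attr(data, "washout_log")

#' Classify completion strata
#'
#' Assigns each individual to a completion stratum: `"full"` if every planned
#' experimental period has at least one non-missing outcome, `"early"` if
#' exactly the first two do (a single completed crossover), `"withdrawal"`
#' otherwise.  Individuals with no non-missing experimental-period outcome at
#' all are additionally flagged `baseline_only`.
#'
#' @param data An [nof1_data] tibble (one or more individuals).
#' @param planned_periods Number of planned experimental periods (>= 2).
#' @return A tibble with columns `id`, `stratum`, `baseline_only`.
#' @export
classify_completion <- function(data, planned_periods = 4L) {
  stopifnot(planned_periods >= 2)
  df <- tibble::as_tibble(data)
  per_id <- split(df, df$id)
  out <- purrr::map(per_id, function(d) {
    obs_periods <- sort(unique(d$period[d$period >= 1L & !is.na(d$value)]))
    full <- all(seq_len(planned_periods) %in% obs_periods)
    early <- identical(obs_periods, 1:2)
    tibble::tibble(
      stratum = if (full) "full" else if (early) "early" else "withdrawal",
      baseline_only = length(obs_periods) == 0
    )
  })
  dplyr::bind_rows(out, .id = "id") |> dplyr::arrange(.data$id)
}
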