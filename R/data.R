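#' Construct and validate an intertemporal-choice trial dataset
#'
#' Builds the package's canonical trial container: one row per decision
#' between a smaller-sooner (SS) and a larger-later (LL) monetary option,
#' with the chosen option and the response time. Used by every downstream
#' fitting and simulation function.
#'
#' Required columns: `participant_id`, `session_id`, `drug`, `ss_magnitude`,
#' `ss_delay`, `ll_magnitude`, `ll_delay`, `choice` (1 = LL, 0 = SS), `rt`
#' (seconds). `trial_index` is added (per participant-session, in row order)
#' when absent. Delays are in days; no unit conversion is applied.
#'
#' Row-level invariants enforced: `rt > 0`, `choice` in {0, 1},
#' `ll_delay >= ss_delay`, `ll_magnitude >= ss_magnitude` (equalities are
#' allowed so that factorial designs whose LL option can be immediate
#' validate). Violations raise an error naming the offending rows.
#'
#' @param trials data.frame of trials.
#' @param study_design `"within"` (every participant serves in at least two
#'   drug conditions) or `"between"` (each participant in exactly one).
#' @return an object of class `itc_data` (a data.frame with design metadata).
#' @export
itc_data <- function(trials, study_design = c("within", "between")) {
  study_design <- match.arg(study_design)
  trials <- as.data.frame(trials)
  required <- c("participant_id", "session_id", "drug", "ss_magnitude",
                "ss_delay", "ll_magnitude", "ll_delay", "choice", "rt")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("ss_magnitude", "ss_delay", "ll_magnitude", "ll_delay",
                "choice", "rt")) {
    trials[[col]] <- as.numeric(trials[[col]])
    if (anyNA(trials[[col]])) {
      stop("column '", col, "' contains missing or non-numeric values (rows ",
           paste(utils::head(which(is.na(trials[[col]])), 5), collapse = ", "),
           ")")
    }
  }
  .fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop("invalid trial(s): ", what, " on row(s) ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    }
  }
  .fail_rows(trials$rt <= 0, "non-positive rt")
  .fail_rows(!trials$choice %in% c(0, 1), "choice not in {0, 1}")
  .fail_rows(trials$ll_delay < trials$ss_delay, "ll_delay < ss_delay")
  .fail_rows(trials$ll_magnitude < trials$ss_magnitude,
             "ll_magnitude < ss_magnitude")
  .fail_rows(trials$ss_delay < 0 | trials$ll_delay < 0, "negative delay")

  if (!"trial_index" %in% names(trials)) {
    key <- interaction(trials$participant_id, trials$session_id, drop = TRUE)
    trials$trial_index <- stats::ave(seq_len(nrow(trials)), key,
                                     FUN = seq_along)
  }

  n_cond <- tapply(trials$drug, trials$participant_id,
                   function(d) length(unique(d)))
  if (study_design == "within" && any(n_cond < 2)) {
    stop("within-subject design requires >= 2 drug conditions per ",
         "participant; violated by: ",
         paste(utils::head(names(n_cond)[n_cond < 2], 5), collapse = ", "))
  }
  if (study_design == "between" && any(n_cond != 1)) {
    stop("between-subject design requires exactly 1 drug condition per ",
         "participant; violated by: ",
         paste(utils::head(names(n_cond)[n_cond != 1], 5), collapse = ", "))
  }
  structure(trials, class = c("itc_data", "data.frame"),
            study_design = study_design)
}

#' @export
print.itc_data <- function(x, ...) {
  cat("Intertemporal choice dataset (", attr(x, "study_design"),
      "-subject design)\n", sep = "")
  cat(" ", nrow(x), " trials, ", length(unique(x$participant_id)),
      " participants, drug conditions: ",
      paste(sort(unique(as.character(x$drug))), collapse = ", "), "\n",
      sep = "")
  if (!is.null(attr(x, "standardization"))) {
    cat("  attribute differences standardized (z-scored)\n")
  }
  ti <- attr(x, "trim_info")
  if (!is.null(ti)) {
    cat("  RT-trimmed: ", ti$removed_low, " fast + ", ti$removed_high,
        " slow trials removed\n", sep = "")
  }
  NextMethod()
}

.itc_keep_attrs <- function(new, old) {
  for (at in c("study_design", "standardization", "trim_info")) {
    attr(new, at) <- attr(old, at)
  }
  class(new) <- c("itc_data", "data.frame")
  new
}

#' Read trial-level choice data from a delimited text file
#'
#' Reads a CSV (or other delimited) file with a header row, optionally
#' renaming columns through `schema`, and validates it with [itc_data()].
#'
#' @param path path to the file.
#' @param schema optional named character vector mapping internal column
#'   names to file column names, e.g. `c(rt = "RT_seconds")`.
#' @param study_design passed to [itc_data()].
#' @param sep field separator.
#' @return an `itc_data` object.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, schema = NULL,
                        study_design = c("within", "between"), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent)) {
      stop("schema refers to column(s) absent from the file: ",
           paste(absent, collapse = ", "))
    }
    for (internal in names(schema)) {
      names(raw)[names(raw) == schema[[internal]]] <- internal
    }
  }
  itc_data(raw, study_design = match.arg(study_design))
}

#' Write a trial dataset to a delimited text file
#'
#' Inverse of [read_trials()]: writes the trial columns as CSV so that
#' reading the file back yields an identical dataset.
#'
#' @param data an `itc_data` object.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_trials <- function(data, path, sep = ",") {
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Trim extreme response times
#'
#' Removes outlier trials whose RT falls strictly below the `lower_frac`
#' sample quantile or strictly above the `1 - upper_frac` sample quantile of
#' the RT distribution (defaults: the 2.5% fastest and 2.5% slowest trials).
#' Quantiles use the linear-interpolation sample definition
#' (`stats::quantile`, type 7); ties at the threshold are retained, which is
#' conservative at small n.
#'
#' @param data an `itc_data` object.
#' @param lower_frac,upper_frac tail fractions in `[0, 1)`,
#'   `lower_frac + upper_frac < 1`.
#' @param scope `"pooled"` computes the quantiles once over the whole study
#'   (the default, matching a single global trimming rule);
#'   `"participant"`/`"session"` compute them per participant or per
#'   participant-session.
#' @return the trimmed `itc_data`; removal counts are reported via `message`
#'   and stored in `attr(, "trim_info")`.
#' @export
trim_rts <- function(data, lower_frac = 0.025, upper_frac = 0.025,
                     scope = c("pooled", "participant", "session")) {
  scope <- match.arg(scope)
  stopifnot(inherits(data, "itc_data"))
  if (nrow(data) == 0) stop("cannot trim an empty dataset")
  if (lower_frac < 0 || upper_frac < 0 || lower_frac + upper_frac >= 1) {
    stop("require 0 <= lower_frac + upper_frac < 1")
  }
  grp <- switch(scope,
    pooled = rep(1L, nrow(data)),
    participant = as.integer(factor(data$participant_id)),
    session = as.integer(interaction(data$participant_id, data$session_id,
                                     drop = TRUE)))
  keep <- rep(TRUE, nrow(data))
  low <- high <- 0L
  for (g in unique(grp)) {
    sel <- grp == g
    qs <- stats::quantile(data$rt[sel], c(lower_frac, 1 - upper_frac),
                          type = 7, names = FALSE)
    fast <- sel & data$rt < qs[1]
    slow <- sel & data$rt > qs[2]
    keep[fast | slow] <- FALSE
    low <- low + sum(fast)
    high <- high + sum(slow)
  }
  message("trim_rts: removed ", low, " fast and ", high, " slow of ",
          nrow(data), " trials (scope = ", scope, ")")
  out <- .itc_keep_attrs(data[keep, , drop = FALSE], data)
  attr(out, "trim_info") <- list(removed_low = low, removed_high = high,
                                 lower_frac = lower_frac,
                                 upper_frac = upper_frac, scope = scope)
  out
}

#' Compute and standardize attribute-difference regressors
#'
#' Adds the attribute regressors the DDM and regression models use:
#' `magnitude_diff` (LL minus SS reward magnitude), `delay_diff` (LL minus SS
#' delay), `magnitude_sum` and `delay_sum`, each z-scored over all retained
#' trials of the study (pooled across participants and sessions) so that
#' coefficient sizes are comparable across attributes. Raw (unstandardized)
#' values are kept in `*_raw` columns; the affine transform is stored in
#' `attr(, "standardization")` so it can be inverted. A numeric drug code is
#' added: for within-subject data, 0 for the reference condition and 1
#' otherwise; for between-subject data, the drug factor is kept as the group
#' label (group structure, not a regressor, carries the drug effect).
#'
#' @param data an `itc_data` object.
#' @param drug_reference value of `drug` coded 0 (default: the first sorted
#'   unique value, e.g. `"placebo"` sorts after none in the D2 design — pass
#'   explicitly when in doubt).
#' @return the augmented `itc_data`.
#' @export
standardize_attributes <- function(data, drug_reference = NULL) {
  stopifnot(inherits(data, "itc_data"))
  raw <- list(
    magnitude_diff = data$ll_magnitude - data$ss_magnitude,
    delay_diff = data$ll_delay - data$ss_delay,
    magnitude_sum = data$ll_magnitude + data$ss_magnitude,
    delay_sum = data$ll_delay + data$ss_delay)
  std <- list()
  for (nm in names(raw)) {
    m <- mean(raw[[nm]])
    s <- stats::sd(raw[[nm]])
    if (!is.finite(s) || s == 0) {
      stop("cannot z-score '", nm, "': zero variance")
    }
    data[[paste0(nm, "_raw")]] <- raw[[nm]]
    data[[nm]] <- (raw[[nm]] - m) / s
    std[[nm]] <- c(mean = m, sd = s)
  }
  if (attr(data, "study_design") == "within") {
    if (is.null(drug_reference)) {
      drug_reference <- sort(unique(as.character(data$drug)))[1]
    }
    data$drug_code <- as.numeric(as.character(data$drug) != drug_reference)
    std$drug_reference <- drug_reference
  } else {
    data$drug_code <- 0
    std$drug_reference <- NA
  }
  attr(data, "standardization") <- std
  data
}
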