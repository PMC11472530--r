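#' Read long-format audit records
#'
#' The canonical record layout is long: one row per (unit, rater, pass,
#' item) response, with header columns `school_id, route_id, unit_type,
#' unit_id, rater_id, pass, item_id, response` — the shape of a mobile
#' survey-platform export.  All rows are validated against the schema;
#' every offending row is reported (unknown item ids, responses outside
#' the item's scale, crossing items attached to segment units, and vice
#' versa).
#'
#' A missing applicable response does not fail here: it invalidates the
#' record for scoring (see [score_records()]) but merely drops the unit
#' from that item's pairs for reliability.
#'
#' @param path path to a comma-delimited file with the header above.
#' @param schema an `instrument_schema`.
#' @return a validated `audit_records` data frame.
#' @export
read_records <- function(path, schema) {
  if (!file.exists(path))
    stop(sprintf("records file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  as_audit_records(df, schema)
}

#' Validate a data frame of audit responses
#'
#' @param df data frame with columns `school_id, route_id, unit_type,
#'   unit_id, rater_id, pass, item_id, response`.
#' @param schema an `instrument_schema`.
#' @return the validated data frame with class `audit_records`; `pass` is
#'   coerced to integer.  Stops listing all offending rows.
#' @export
as_audit_records <- function(df, schema) {
  req <- c("school_id", "route_id", "unit_type", "unit_id", "rater_id",
           "pass", "item_id", "response")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("records are missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[req]
  df$pass <- suppressWarnings(as.integer(df$pass))
  info <- schema_items(schema)
  labels <- lapply(schema$items, function(it) it$scale$labels)
  names(labels) <- info$item_id
  comp_of <- stats::setNames(info$component, info$item_id)

  probs <- character(0)
  row <- seq_len(nrow(df))
  bad <- is.na(df$pass) | df$pass < 1
  if (any(bad))
    probs <- c(probs, sprintf("row %d: pass '%s' is not a positive integer",
                              row[bad], df$pass[bad]))
  unknown <- !(df$item_id %in% info$item_id)
  if (any(unknown))
    probs <- c(probs, sprintf("row %d: unknown item_id '%s'",
                              row[unknown], df$item_id[unknown]))
  ok <- !unknown
  bad_type <- ok & !(df$unit_type %in% c("segment", "crossing"))
  if (any(bad_type))
    probs <- c(probs, sprintf("row %d: unit_type '%s' is not segment/crossing",
                              row[bad_type], df$unit_type[bad_type]))
  mismatch <- ok & !bad_type & comp_of[df$item_id] != df$unit_type
  if (any(mismatch))
    probs <- c(probs,
               sprintf("row %d: item %s belongs to the %s component, not to a %s unit",
                       row[mismatch], df$item_id[mismatch],
                       comp_of[df$item_id[mismatch]],
                       df$unit_type[mismatch]))
  off_scale <- ok & mapply(function(it, r) !(r %in% labels[[it]]),
                           df$item_id, df$response)
  off_scale[!ok] <- FALSE
  if (any(off_scale))
    probs <- c(probs,
               sprintf("row %d: response '%s' is not on the scale of item %s",
                       row[off_scale], df$response[off_scale],
                       df$item_id[off_scale]))
  key <- paste(df$school_id, df$route_id, df$unit_type, df$unit_id,
               df$rater_id, df$pass, df$item_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    probs <- c(probs, sprintf("row %d: duplicate response for item %s",
                              row[dup], df$item_id[dup]))
  ukey <- paste(df$school_id, df$route_id, df$unit_id, sep = "\r")
  n_types <- tapply(df$unit_type, ukey, function(x) length(unique(x)))
  if (any(n_types > 1)) {
    offending <- names(n_types)[n_types > 1]
    probs <- c(probs, sprintf("unit '%s' appears with more than one unit_type",
                              gsub("\r", "/", offending)))
  }
  if (length(probs))
    stop(paste(c("invalid audit records:", probs), collapse = "\n  "),
         call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("audit_records", "data.frame")
  df
}

#' Read wide-format audit records
#'
#' Convenience reader for one-row-per-audit exports: columns `school_id,
#' route_id, unit_type, unit_id, rater_id, pass` followed by one column
#' per item.  Empty cells mean "not reported" (e.g. gated-off items) and
#' are dropped during reshaping.
#'
#' @inheritParams read_records
#' @return a validated `audit_records` data frame in long format.
#' @export
read_records_wide <- function(path, schema) {
  if (!file.exists(path))
    stop(sprintf("records file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  idc <- c("school_id", "route_id", "unit_type", "unit_id", "rater_id",
           "pass")
  missing_cols <- setdiff(idc, names(df))
  if (length(missing_cols))
    stop(sprintf("wide records are missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  item_cols <- setdiff(names(df), idc)
  long <- do.call(rbind, lapply(item_cols, function(it) {
    out <- df[idc]
    out$item_id <- it
    out$response <- df[[it]]
    out
  }))
  long <- long[!is.na(long$response) & long$response != "", ]
  as_audit_records(long, schema)
}

#' Write audit records as delimited text
#' @param records an `audit_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

unit_key <- function(df)
  paste(df$school_id, df$route_id, df$unit_type, df$unit_id, sep = "\r")

# named response vector for one (unit, side) slice of the long table
responses_of <- function(df) stats::setNames(df$response, df$item_id)

#' Build per-item paired responses for a reliability design
#'
#' For `design = "inter"`, pairs the two raters' pass-1 audits of the same
#' unit; for `design = "intra"`, pairs each rater's pass 1 against their
#' own pass 2 (units pooled over raters).  For every item, a pair is
#' retained only when the item was applicable and answered on both sides.
#' Units on which the two sides disagree about a gate (e.g. one auditor
#' classifying a crossing as street-level and the other as an underpass)
#' keep their pair for the gate item itself, while items downstream of the
#' divergent gate are excluded for that unit; such exclusions are counted
#' in `n_gate_divergent`.
#'
#' @param records an `audit_records` data frame.
#' @param schema an `instrument_schema`.
#' @param design `"inter"` or `"intra"`.
#' @param raters for `"inter"`: the two rater ids to pair (default: the
#'   first two in sort order).
#' @return named list (one element per schema item, in instrument order)
#'   of `paired_responses` objects: `item_id`, `design`, `pairs` (a data
#'   frame with unit provenance and `response_a`/`response_b`),
#'   `n_gate_divergent`, `n_missing`.
#' @export
build_pairs <- function(records, schema, design = c("inter", "intra"),
                        raters = NULL) {
  design <- match.arg(design)
  sides <- split_sides(records, design, raters)
  a <- sides$a; b <- sides$b
  shared <- intersect(unique(unit_key(a)), unique(unit_key(b)))
  if (length(shared) == 0)
    stop("no overlapping units between the two sides", call. = FALSE)
  a_units <- split(a, unit_key(a))
  b_units <- split(b, unit_key(b))

  out <- list()
  for (it in schema$items) {
    id <- it$item_id
    rows <- list()
    n_div <- 0L
    n_mis <- 0L
    for (k in shared) {
      ua <- a_units[[k]]; ub <- b_units[[k]]
      if (ua$unit_type[1] != it$component) next
      ra <- responses_of(ua); rb <- responses_of(ub)
      app_a <- is_applicable(it, ra)
      app_b <- is_applicable(it, rb)
      if (is.na(app_a) || is.na(app_b)) { n_mis <- n_mis + 1L; next }
      if (app_a != app_b) { n_div <- n_div + 1L; next }
      if (!app_a) next
      if (!(id %in% names(ra)) || !(id %in% names(rb))) {
        n_mis <- n_mis + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(school_id = ua$school_id[1], route_id = ua$route_id[1],
                   unit_type = ua$unit_type[1], unit_id = ua$unit_id[1],
                   response_a = unname(ra[[id]]),
                   response_b = unname(rb[[id]]),
                   stringsAsFactors = FALSE)
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(school_id = character(0), route_id = character(0),
                 unit_type = character(0), unit_id = character(0),
                 response_a = character(0), response_b = character(0),
                 stringsAsFactors = FALSE)
    out[[id]] <- structure(
      list(item_id = id, design = design, pairs = pairs,
           n_gate_divergent = n_div, n_missing = n_mis),
      class = "paired_responses")
  }
  out
}

# Split a record table into the two sides of a reliability design:
# inter = two raters' pass-1 audits; intra = each rater's pass 1 vs their
# own pass 2 (units pooled over raters).
split_sides <- function(records, design = c("inter", "intra"),
                        raters = NULL) {
  design <- match.arg(design)
  df <- as.data.frame(records)
  if (design == "inter") {
    all_raters <- sort(unique(df$rater_id))
    if (is.null(raters)) {
      if (length(all_raters) < 2)
        stop("inter-rater pairing needs at least 2 raters", call. = FALSE)
      raters <- all_raters[1:2]
    }
    a <- df[df$rater_id == raters[1] & df$pass == 1L, ]
    b <- df[df$rater_id == raters[2] & df$pass == 1L, ]
  } else {
    a <- df[df$pass == 1L, ]
    b <- df[df$pass == 2L, ]
    if (nrow(b) == 0)
      stop("intra-rater pairing needs repeat (pass 2) audits",
           call. = FALSE)
    # a unit's two passes must come from the same rater
    ka <- paste(unit_key(a), a$rater_id)
    kb <- paste(unit_key(b), b$rater_id)
    a <- a[ka %in% kb, ]
    b <- b[kb %in% ka, ]
  }
  list(a = a, b = b)
}

# TRUE/FALSE whether `item` applies given one side's responses; NA when the
# gate response itself is missing
is_applicable <- function(item, responses) {
  if (is.null(item$gate)) return(TRUE)
  g <- item$gate$item
  if (!g %in% names(responses)) return(NA)
  responses[[g]] %in% item$gate$values
}

#' @export
print.paired_responses <- function(x, ...) {
  cat(sprintf("<paired_responses> %s (%s): %d pairs, %d gate-divergent, %d missing\n",
              x$item_id, x$design, nrow(x$pairs), x$n_gate_divergent,
              x$n_missing))
  invisible(x)
}

#' Cross-tabulate paired responses
#'
#' Builds the k x k contingency table of side-A (rows) against side-B
#' (columns) responses over the scale's categories, in schema label order
#' (weighted kappa depends on that order).
#'
#' @param pairs a `paired_responses` object, or a data frame with columns
#'   `response_a` and `response_b`.
#' @param scale the item's [response_scale()].
#' @return an integer matrix of class `contingency_table` with the labels
#'   as dimnames and attribute `n` (total pairs).
#' @export
tabulate_pairs <- function(pairs, scale) {
  if (inherits(pairs, "paired_responses")) pairs <- pairs$pairs
  if (nrow(pairs) == 0)
    stop("cannot tabulate zero pairs", call. = FALSE)
  labs <- scale$labels
  bad <- !(pairs$response_a %in% labs) | !(pairs$response_b %in% labs)
  if (any(bad))
    stop("paired responses contain labels outside the scale",
         call. = FALSE)
  tab <- table(factor(pairs$response_a, levels = labs),
               factor(pairs$response_b, levels = labs))
  m <- matrix(as.integer(tab), nrow = length(labs),
              dimnames = list(a = labs, b = labs))
  structure(m, class = c("contingency_table", class(m)), n = sum(m))
}

#' Write per-item pair dumps for audit
#' @param pairs result of [build_pairs()].
#' @param path output path (one combined delimited file).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  rows <- lapply(pairs, function(p) {
    if (nrow(p$pairs) == 0) return(NULL)
    cbind(item_id = p$item_id, design = p$design, p$pairs)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
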