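#' Score one item response
#'
#' Every scored item maps its response labels onto `[0, 1]`, larger values
#' meaning a more active-travel-supportive streetscape: nominal yes/no
#' items score 0/1, ordinal items use equally spaced maps (e.g. a little /
#' some / a lot scoring 0.33 / 0.66 / 1.00 at display precision).
#'
#' @param item an [audit_item()].
#' @param response a response label on the item's scale.
#' @return the mapped score in `[0, 1]`.
#' @export
score_item <- function(item, response) {
  if (!is_scored(item))
    stop(sprintf("item %s is not included in the scoring protocol",
                 item$item_id), call. = FALSE)
  if (!response %in% names(item$score_map))
    stop(sprintf("response '%s' is not on the scale of item %s",
                 response, item$item_id), call. = FALSE)
  unname(item$score_map[[response]])
}

#' Classify a 0-1 score into poor / moderate / good
#'
#' Band boundaries are the printed two-decimal constants: values up to and
#' including 0.33 are poor, above 0.33 up to and including 0.66 moderate,
#' above 0.66 good.  (Note the exact ordinal map fractions 1/3 and 2/3 lie
#' just above these cutoffs, so a bare "a little" response, 0.333...,
#' classifies as moderate.)
#'
#' @param value numeric in `[0, 1]` (vectorised).
#' @return character vector: `"poor"`, `"moderate"` or `"good"`.
#' @export
classify_band <- function(value) {
  if (any(is.na(value)) || any(value < 0) || any(value > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  ifelse(value <= 0.33, "poor", ifelse(value <= 0.66, "moderate", "good"))
}

#' Display form of an item/domain score
#'
#' The instrument's printed score maps truncate to two decimals (a
#' three-category ordinal map 1/3, 2/3, 1 is displayed 0.33, 0.66, 1.00,
#' matching the poor/moderate band boundaries at 0.33 and 0.66).  Full
#' precision is always retained internally; this is purely a display
#' convention.
#'
#' @param x numeric scores (vectorised).
#' @return character vector, two-decimal truncated.
#' @export
format_score <- function(x) sprintf("%.2f", trunc(x * 100) / 100)

score_node <- function(tier, focus, value, n) {
  data.frame(tier = tier, focus = focus, value = value,
             n = as.integer(n), band = classify_band(value),
             stringsAsFactors = FALSE)
}

#' Score one domain of a single audit
#'
#' The domain score is the unweighted mean of the unit's item scores over
#' the *applicable* scored items of that domain.  Gated-off items are
#' excluded from the denominator (the absence of an underpass is not
#' disorder); if no item of the domain applies, the node is absent and
#' `NULL` is returned.
#'
#' @param responses named character vector `item_id -> response` for one
#'   unit/rater/pass.
#' @param domain one of the four scored domains.
#' @param schema an `instrument_schema`.
#' @param component `"segment"` or `"crossing"` (default: inferred).
#' @return a one-row score-node data frame (`tier`, `focus`, `value`, `n`,
#'   `band`), or `NULL` when no item of the domain is applicable.
#' @export
score_domain <- function(responses, domain, schema, component = NULL) {
  domain <- match.arg(domain, setdiff(.domains, "unscored"))
  app <- applicable_items(schema, responses, component)
  vals <- numeric(0)
  for (id in app) {
    it <- schema_item(schema, id)
    if (it$domain != domain) next
    if (!id %in% names(responses))
      stop(sprintf("missing response for applicable scored item %s", id),
           call. = FALSE)
    vals <- c(vals, score_item(it, responses[[id]]))
  }
  if (length(vals) == 0) return(NULL)
  score_node("domain", domain, mean(vals), length(vals))
}

#' Score one audit unit
#'
#' The unit's overall score is the mean of its available domain scores;
#' with `mode = "domain"` the single named domain's score is returned
#' instead (the roll-up then propagates that domain up the hierarchy).
#'
#' @inheritParams score_domain
#' @param mode `"overall"` or a domain name.
#' @return a one-row score-node data frame, or `NULL` if no domain is
#'   scorable under `mode`.
#' @export
score_unit <- function(responses, schema, component = NULL,
                       mode = "overall") {
  doms <- setdiff(.domains, "unscored")
  if (mode != "overall") {
    node <- score_domain(responses, match.arg(mode, doms), schema,
                         component)
    if (is.null(node)) return(NULL)
    node$tier <- "unit"
    return(node)
  }
  nodes <- lapply(doms, function(d)
    score_domain(responses, d, schema, component))
  vals <- unlist(lapply(nodes, function(n) if (is.null(n)) NULL else n$value))
  if (length(vals) == 0) return(NULL)
  score_node("unit", "overall", mean(vals), length(vals))
}

#' Roll child scores up one tier
#'
#' Route scores are the mean of the route's unit scores (segments and
#' crossings pooled by default); school scores are the mean of the
#' school's route scores, so the school overall equals the mean of route
#' overalls to full precision.
#'
#' @param values numeric vector of child-node values.
#' @param tier `"route"` or `"school"`.
#' @param focus `"overall"` or a domain name (carried through).
#' @return a one-row score-node data frame.
#' @export
score_rollup <- function(values, tier = c("route", "school"),
                         focus = "overall") {
  tier <- match.arg(tier)
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop(sprintf("cannot compute a %s score from zero children", tier),
         call. = FALSE)
  score_node(tier, focus, mean(values), length(values))
}

#' Score a full study: the five-tier score table
#'
#' For each (rater, pass) side separately, computes domain and overall
#' scores for every unit, then route and school roll-ups, for the overall
#' focus and for each of the four domains.  A unit with a missing
#' applicable scored response is an error (complete-case scoring); use
#' reliability pairing if you only need agreement.
#'
#' @param records an `audit_records` data frame.
#' @param schema an `instrument_schema`.
#' @param aggregation `"pooled"` (default: route overall is the mean over
#'   all of the route's unit overalls, segments and crossings together) or
#'   `"stratified"` (route overall is the mean of the segment-mean and the
#'   crossing-mean).
#' @param school_rollup `"route_mean"` (default: school value is the mean
#'   of its route values) or `"pooled"` (mean over all the school's
#'   units).
#' @return a `score_table` data frame with columns `rater_id, pass,
#'   school_id, route_id, unit_type, unit_id, tier, focus, value, n,
#'   band`.  Route and school rows carry `NA` unit fields.
#' @export
score_records <- function(records, schema,
                          aggregation = c("pooled", "stratified"),
                          school_rollup = c("route_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  school_rollup <- match.arg(school_rollup)
  df <- as.data.frame(records)
  foci <- c("overall", setdiff(.domains, "unscored"))
  side_key <- paste(df$rater_id, df$pass, sep = "\r")
  out <- list()
  for (sk in unique(side_key)) {
    side <- df[side_key == sk, ]
    rater <- side$rater_id[1]; pass <- side$pass[1]
    units <- split(side, unit_key(side))
    unit_rows <- list()
    for (u in units) {
      resp <- responses_of(u)
      base <- data.frame(rater_id = rater, pass = pass,
                         school_id = u$school_id[1],
                         route_id = u$route_id[1],
                         unit_type = u$unit_type[1],
                         unit_id = u$unit_id[1],
                         stringsAsFactors = FALSE)
      nodes <- list()
      for (d in setdiff(.domains, "unscored")) {
        nd <- score_domain(resp, d, schema, u$unit_type[1])
        if (!is.null(nd)) nodes[[length(nodes) + 1L]] <- cbind(base, nd)
      }
      ov <- score_unit(resp, schema, u$unit_type[1])
      if (!is.null(ov)) nodes[[length(nodes) + 1L]] <- cbind(base, ov)
      unit_rows[[length(unit_rows) + 1L]] <- do.call(rbind, nodes)
    }
    unit_tab <- do.call(rbind, unit_rows)
    out[[length(out) + 1L]] <- unit_tab

    # route tier
    route_tab <- list()
    for (rk in unique(paste(unit_tab$school_id, unit_tab$route_id,
                            sep = "\r"))) {
      parts <- strsplit(rk, "\r", fixed = TRUE)[[1]]
      rt <- unit_tab[unit_tab$school_id == parts[1] &
                     unit_tab$route_id == parts[2], ]
      for (f in foci) {
        tier_of <- if (f == "overall") "unit" else "domain"
        ch <- rt[rt$tier == tier_of & rt$focus == f, ]
        if (nrow(ch) == 0) next
        vals <- if (aggregation == "stratified" && f == "overall") {
          strata <- tapply(ch$value, ch$unit_type, mean)
          as.numeric(strata)
        } else ch$value
        node <- score_rollup(vals, "route", f)
        route_tab[[length(route_tab) + 1L]] <-
          cbind(data.frame(rater_id = rater, pass = pass,
                           school_id = parts[1], route_id = parts[2],
                           unit_type = NA_character_,
                           unit_id = NA_character_,
                           stringsAsFactors = FALSE), node)
      }
    }
    route_tab <- do.call(rbind, route_tab)
    out[[length(out) + 1L]] <- route_tab

    # school tier
    school_tab <- list()
    for (s in unique(route_tab$school_id)) {
      for (f in foci) {
        if (school_rollup == "route_mean") {
          ch <- route_tab[route_tab$school_id == s & route_tab$focus == f, ]
        } else {
          tier_of <- if (f == "overall") "unit" else "domain"
          ch <- unit_tab[unit_tab$school_id == s & unit_tab$focus == f &
                         unit_tab$tier == tier_of, ]
        }
        if (nrow(ch) == 0) next
        node <- score_rollup(ch$value, "school", f)
        school_tab[[length(school_tab) + 1L]] <-
          cbind(data.frame(rater_id = rater, pass = pass, school_id = s,
                           route_id = NA_character_,
                           unit_type = NA_character_,
                           unit_id = NA_character_,
                           stringsAsFactors = FALSE), node)
      }
    }
    out[[length(out) + 1L]] <- do.call(rbind, school_tab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("score_table", "data.frame")
  res
}
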