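#' Response scale for an audit item
#'
#' A response scale holds the ordered response labels for one item.
#' `ordinal` scales store labels in supportiveness order, least supportive
#' of active school travel first, so that score maps increase along the
#' label order.  `nominal_binary` scales have exactly two unordered labels;
#' `categorical` scales have two or more unordered labels.
#'
#' @param kind one of `"nominal_binary"`, `"ordinal"`, `"categorical"`.
#' @param labels character vector of response labels (length >= 2).
#' @return an object of class `response_scale` with fields `kind`,
#'   `labels` and `n_categories`.
#' @examples
#' response_scale("ordinal", c("none", "a little", "some", "a lot"))
#' @export
response_scale <- function(kind, labels) {
  kind <- match.arg(kind, c("nominal_binary", "ordinal", "categorical"))
  labels <- as.character(labels)
  if (anyNA(labels) || any(labels == ""))
    stop("response labels must be non-empty strings", call. = FALSE)
  if (length(labels) < 2)
    stop("a response scale needs at least 2 labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("response labels must be unique", call. = FALSE)
  if (kind == "nominal_binary" && length(labels) != 2)
    stop("a nominal_binary scale must have exactly 2 labels", call. = FALSE)
  structure(list(kind = kind, labels = labels,
                 n_categories = length(labels)),
            class = "response_scale")
}

#' @export
print.response_scale <- function(x, ...) {
  cat(sprintf("<response_scale> %s: %s\n", x$kind,
              paste(x$labels, collapse = " | ")))
  invisible(x)
}

.domains <- c("subjective_safety", "quality", "traffic_safety",
              "physical_disorder", "unscored")

#' Define one audit item
#'
#' @param item_id item identifier, e.g. `"S1"` or `"C14a"`.
#' @param component `"segment"` or `"crossing"`.
#' @param text the item wording shown to auditors.
#' @param scale a [response_scale()].
#' @param domain one of `"subjective_safety"`, `"quality"`,
#'   `"traffic_safety"`, `"physical_disorder"`, or `"unscored"` for
#'   informational items excluded from the scoring protocol.
#' @param score_map named numeric vector mapping every response label to a
#'   score in `[0, 1]`, with maximum 1 (supportive direction is baked in at
#'   authoring time).  `NULL` for unscored items.
#' @param gate optional applicability gate: a list with elements `item`
#'   (the gating item id) and `values` (the gate responses under which this
#'   item applies).  Items whose gate is not satisfied are excluded from
#'   scoring denominators and from reliability pairing.
#' @return an object of class `audit_item`.
#' @export
audit_item <- function(item_id, component, text, scale, domain,
                       score_map = NULL, gate = NULL) {
  component <- match.arg(component, c("segment", "crossing"))
  domain <- match.arg(domain, .domains)
  stopifnot(inherits(scale, "response_scale"))
  if (!is.null(score_map)) {
    score_map <- unlist(score_map)
    if (!is.numeric(score_map) || is.null(names(score_map)))
      stop(sprintf("item %s: score_map must be a named numeric vector",
                   item_id), call. = FALSE)
  }
  if (!is.null(gate)) {
    if (!is.list(gate) || !all(c("item", "values") %in% names(gate)))
      stop(sprintf("item %s: gate must list `item` and `values`", item_id),
           call. = FALSE)
    gate$values <- as.character(gate$values)
  }
  structure(list(item_id = as.character(item_id), component = component,
                 text = as.character(text), scale = scale, domain = domain,
                 score_map = score_map, gate = gate),
            class = "audit_item")
}

#' Is an item part of the scoring protocol?
#' @param item an [audit_item()].
#' @return `TRUE` if the item carries a score map and a scored domain.
#' @export
is_scored <- function(item) {
  item$domain != "unscored" && !is.null(item$score_map)
}

# kappa family used in item-level reliability: ordinal items get linearly
# weighted kappa, everything else unweighted kappa
item_statistic <- function(item) {
  if (item$scale$kind == "ordinal") "weighted_kappa" else "kappa"
}

#' Assemble an instrument schema
#'
#' @param items list of [audit_item()]s in instrument order.
#' @param version schema version string.
#' @param strict if `TRUE` (default) enforce the full FACTS catalogue
#'   invariants (45 items, component and domain counts); if `FALSE`, only
#'   per-item structural checks are applied, which permits reduced schemas
#'   for experimentation.
#' @return an object of class `instrument_schema`.
#' @seealso [load_schema()], [facts_schema()]
#' @export
instrument_schema <- function(items, version = "1.0", strict = TRUE) {
  schema <- structure(list(items = items, version = as.character(version)),
                      class = "instrument_schema")
  validate_schema(schema, strict = strict)
  schema
}

#' Validate an instrument schema
#'
#' Checks every per-item invariant (label coverage and range of score maps,
#' monotone ordinal maps, gate references) and, when `strict = TRUE`, the
#' FACTS catalogue invariants: 45 items in total, 23 segment and 22
#' crossing items, 8 + 15 segment and 12 + 10 crossing items by kappa
#' family, exactly one unscored segment item, and the published domain
#' compositions (segment 1/8/6/7, crossing 2/8/8/4).
#'
#' @param schema an `instrument_schema`.
#' @param strict enforce catalogue-level invariants.
#' @return the schema, invisibly; stops with a message naming the first
#'   violated invariant and the offending item id.
#' @export
validate_schema <- function(schema, strict = TRUE) {
  if (!inherits(schema, "instrument_schema"))
    stop("not an instrument_schema", call. = FALSE)
  items <- schema$items
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids))
    stop(sprintf("schema invalid: duplicated item_id '%s'",
                 ids[duplicated(ids)][1]), call. = FALSE)
  for (it in items) {
    if (!inherits(it, "audit_item"))
      stop("schema invalid: items must be audit_item objects", call. = FALSE)
    sc <- it$scale
    if (sc$n_categories != length(sc$labels) || sc$n_categories < 2)
      stop(sprintf("schema invalid: item %s scale is malformed", it$item_id),
           call. = FALSE)
    if (!is.null(it$score_map)) {
      if (!setequal(names(it$score_map), sc$labels))
        stop(sprintf("schema invalid: item %s score_map does not cover its labels",
                     it$item_id), call. = FALSE)
      s <- it$score_map[sc$labels]
      if (any(s < 0) || any(s > 1))
        stop(sprintf("schema invalid: item %s maps scores outside [0, 1]",
                     it$item_id), call. = FALSE)
      if (abs(max(s) - 1) > 1e-12)
        stop(sprintf("schema invalid: item %s maximum mapped score is not 1",
                     it$item_id), call. = FALSE)
      if (sc$kind == "ordinal" && any(diff(s) <= 0))
        stop(sprintf("schema invalid: item %s ordinal scores are not strictly increasing in supportiveness order",
                     it$item_id), call. = FALSE)
    }
    if (it$domain != "unscored" && is.null(it$score_map))
      stop(sprintf("schema invalid: item %s is assigned to domain '%s' but has no score_map",
                   it$item_id, it$domain), call. = FALSE)
    if (!is.null(it$gate)) {
      g <- which(ids == it$gate$item)
      if (length(g) != 1)
        stop(sprintf("schema invalid: item %s gate refers to unknown item '%s'",
                     it$item_id, it$gate$item), call. = FALSE)
      gl <- items[[g]]$scale$labels
      if (!all(it$gate$values %in% gl))
        stop(sprintf("schema invalid: item %s gate values are not responses of %s",
                     it$item_id, it$gate$item), call. = FALSE)
      if (items[[g]]$component != it$component)
        stop(sprintf("schema invalid: item %s gated by an item of another component",
                     it$item_id), call. = FALSE)
    }
  }
  if (strict) {
    comp <- vapply(items, `[[`, "", "component")
    dom <- vapply(items, `[[`, "", "domain")
    kind <- vapply(items, function(it) it$scale$kind, "")
    .check <- function(cond, msg)
      if (!cond) stop(paste("schema invalid:", msg), call. = FALSE)
    .check(length(items) == 45,
           sprintf("expected 45 items, found %d", length(items)))
    .check(sum(comp == "segment") == 23,
           sprintf("expected 23 segment items, found %d",
                   sum(comp == "segment")))
    .check(sum(comp == "crossing") == 22,
           sprintf("expected 22 crossing items, found %d",
                   sum(comp == "crossing")))
    .check(sum(comp == "segment" & dom == "unscored") == 1,
           "expected exactly one unscored segment item")
    .check(sum(comp == "segment" & dom != "unscored") == 22,
           "expected 22 scored segment items")
    .check(sum(comp == "crossing" & dom != "unscored") == 22,
           "expected 22 scored crossing items")
    .check(sum(comp == "segment" & kind == "ordinal") == 15,
           "expected 15 ordinal segment items")
    .check(sum(comp == "segment" & kind != "ordinal") == 8,
           "expected 8 nominal segment items")
    .check(sum(comp == "crossing" & kind == "ordinal") == 10,
           "expected 10 ordinal crossing items")
    .check(sum(comp == "crossing" & kind != "ordinal") == 12,
           "expected 12 nominal crossing items")
    seg_sizes <- c(subjective_safety = 1, quality = 8,
                   traffic_safety = 6, physical_disorder = 7)
    cro_sizes <- c(subjective_safety = 2, quality = 8,
                   traffic_safety = 8, physical_disorder = 4)
    for (d in names(seg_sizes)) {
      .check(sum(comp == "segment" & dom == d) == seg_sizes[[d]],
             sprintf("segment domain '%s' must contain %d items", d,
                     seg_sizes[[d]]))
      .check(sum(comp == "crossing" & dom == d) == cro_sizes[[d]],
             sprintf("crossing domain '%s' must contain %d items", d,
                     cro_sizes[[d]]))
    }
  }
  invisible(schema)
}

#' @export
print.instrument_schema <- function(x, ...) {
  comp <- vapply(x$items, `[[`, "", "component")
  cat(sprintf("<instrument_schema> version %s: %d items (%d segment, %d crossing)\n",
              x$version, length(x$items), sum(comp == "segment"),
              sum(comp == "crossing")))
  invisible(x)
}

#' Look up one item of a schema
#' @param schema an `instrument_schema`.
#' @param item_id item identifier.
#' @return the [audit_item()]; stops if absent.
#' @export
schema_item <- function(schema, item_id) {
  ids <- vapply(schema$items, `[[`, "", "item_id")
  i <- which(ids == item_id)
  if (length(i) != 1)
    stop(sprintf("unknown item_id '%s'", item_id), call. = FALSE)
  schema$items[[i]]
}

#' Summarise a schema as a data frame
#'
#' One row per item: id, component, scale kind, number of categories,
#' domain, whether the item is scored, and the kappa family used for its
#' item-level reliability.
#'
#' @param schema an `instrument_schema`.
#' @return a data frame with one row per item, in instrument order.
#' @export
schema_items <- function(schema) {
  data.frame(
    item_id = vapply(schema$items, `[[`, "", "item_id"),
    component = vapply(schema$items, `[[`, "", "component"),
    kind = vapply(schema$items, function(it) it$scale$kind, ""),
    n_categories = vapply(schema$items,
                          function(it) it$scale$n_categories, 0L),
    domain = vapply(schema$items, `[[`, "", "domain"),
    scored = vapply(schema$items, is_scored, TRUE),
    statistic = vapply(schema$items, item_statistic, ""),
    gated_by = vapply(schema$items, function(it)
      if (is.null(it$gate)) NA_character_ else it$gate$item, ""),
    stringsAsFactors = FALSE)
}

#' Read an instrument schema from a YAML file
#'
#' The file stores `version` and a list of `items`, each with `item_id`,
#' `component`, `text`, `scale` (`kind` + `labels`), `domain`, and
#' optionally `score_map` and `gate`.  The shipped canonical FACTS schema
#' (see [facts_schema()]) is in this format.
#'
#' @param path path to the schema file.
#' @param strict passed to [validate_schema()].
#' @return a validated `instrument_schema`.
#' @export
load_schema <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop(sprintf("schema file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$items))
    stop("schema file has no `items` entry", call. = FALSE)
  items <- lapply(raw$items, function(r) {
    sm <- if (is.null(r$score_map)) NULL else unlist(r$score_map)
    audit_item(r$item_id, r$component, r$text,
               response_scale(r$scale$kind, unlist(r$scale$labels)),
               r$domain, score_map = sm, gate = r$gate)
  })
  instrument_schema(items, version = raw$version %||% "unversioned",
                    strict = strict)
}

#' Write an instrument schema to a YAML file
#' @param schema an `instrument_schema`.
#' @param path output path.
#' @return `path`, invisibly.  `load_schema(write_schema(s))` reproduces
#'   `s` (scores to full double precision).
#' @export
write_schema <- function(schema, path) {
  items <- lapply(schema$items, function(it) {
    r <- list(item_id = it$item_id, component = it$component,
              text = it$text,
              scale = list(kind = it$scale$kind,
                           labels = as.list(it$scale$labels)),
              domain = it$domain)
    if (!is.null(it$score_map))
      r$score_map <- as.list(it$score_map[it$scale$labels])
    if (!is.null(it$gate))
      r$gate <- list(item = it$gate$item,
                     values = as.list(it$gate$values))
    r
  })
  yaml::write_yaml(list(version = schema$version, items = items), path,
                   precision = 15)
  invisible(path)
}

#' The canonical FACTS schema
#'
#' Loads the schema shipped with the package: 45 items (23 segment S1-S23,
#' 22 crossing C1-C13, C14a, C14b, C15-C21), their response scales, score
#' maps coded in the active-travel-supportive direction, domain
#' assignments, and applicability gates (C1 gates C2-C12; C14b applies
#' only when C14a is "no").
#'
#' @return a validated `instrument_schema`.
#' @export
facts_schema <- function() {
  load_schema(system.file("extdata", "facts_schema.yaml",
                          package = "factsaudit", mustWork = TRUE))
}

#' Default equally spaced ordinal score map
#'
#' Two conventions are supported for mapping `m` ordered categories onto
#' `[0, 1]`.  `"without_zero"` (the default) assigns `j / m` for
#' `j = 1, ..., m`, so three categories score 1/3, 2/3, 1 (displayed 0.33,
#' 0.66, 1.00).  `"with_zero"` assigns `j / (m - 1)` for `j = 0, ...,
#' m - 1`, so the least supportive category scores exactly 0.  Full
#' precision is retained; rounding is a display concern.
#'
#' @param n_categories number of ordered categories, at least 2.
#' @param convention `"without_zero"` or `"with_zero"`.
#' @return numeric vector of length `n_categories`, increasing, ending at 1.
#' @examples
#' ordinal_score_map(3)               # 1/3, 2/3, 1
#' ordinal_score_map(4, "with_zero")  # 0, 1/3, 2/3, 1
#' @export
ordinal_score_map <- function(n_categories,
                              convention = c("without_zero", "with_zero")) {
  convention <- match.arg(convention)
  m <- as.integer(n_categories)
  if (is.na(m) || m < 2)
    stop("n_categories must be an integer >= 2", call. = FALSE)
  if (convention == "without_zero") seq_len(m) / m
  else (seq_len(m) - 1) / (m - 1)
}

#' Items applicable to one audit record
#'
#' Evaluates every applicability gate of `component`'s items against the
#' supplied responses.  Gated items (crossing items C2-C12, which apply
#' only when C1 reports an underpass, overpass or bridge, and C14b, which
#' applies only when C14a reports no signals) are excluded when their gate
#' is not satisfied; they are then dropped from scoring denominators and
#' from reliability pairing.
#'
#' @param schema an `instrument_schema`.
#' @param responses named character vector, `item_id -> response label`,
#'   for a single unit/rater/pass.  Must contain responses for all gating
#'   items of the component.
#' @param component `"segment"` or `"crossing"`; defaults to the component
#'   of the items present in `responses`.
#' @return character vector of applicable item ids, in instrument order.
#' @export
applicable_items <- function(schema, responses, component = NULL) {
  info <- schema_items(schema)
  if (is.null(component)) {
    comps <- unique(info$component[info$item_id %in% names(responses)])
    if (length(comps) != 1)
      stop("responses do not identify a single component; pass `component`",
           call. = FALSE)
    component <- comps
  }
  component <- match.arg(component, c("segment", "crossing"))
  keep <- character(0)
  for (it in schema$items) {
    if (it$component != component) next
    if (is.null(it$gate)) {
      keep <- c(keep, it$item_id)
    } else {
      g <- it$gate$item
      if (!g %in% names(responses))
        stop(sprintf("cannot resolve applicability of %s: gating response %s is missing",
                     it$item_id, g), call. = FALSE)
      if (responses[[g]] %in% it$gate$values)
        keep <- c(keep, it$item_id)
    }
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
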