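#' Item-by-item reliability report
#'
#' One row per schema item, in instrument order: pair count, percentage
#' agreement (with the > 70% "high" flag), the item's kappa-family
#' statistic (unweighted for nominal/categorical scales, linearly
#' weighted for ordinal scales) with 95% CI, one-sided p, Landis-Koch
#' interpretation, and a typed status for items whose kappa is undefined
#' because one or both sides' ratings were constant.
#'
#' @param records an `audit_records` data frame.
#' @param schema an `instrument_schema`.
#' @param design `"inter"` or `"intra"`.
#' @param raters passed to [build_pairs()].
#' @return a data frame with one row per item (45 for the canonical
#'   schema).
#' @export
item_report <- function(records, schema, design = c("inter", "intra"),
                        raters = NULL) {
  design <- match.arg(design)
  pairs <- build_pairs(records, schema, design, raters)
  rows <- lapply(schema$items, function(it) {
    p <- pairs[[it$item_id]]
    base <- data.frame(item_id = it$item_id, component = it$component,
                       domain = it$domain,
                       statistic = item_statistic(it),
                       n_pairs = nrow(p$pairs),
                       n_gate_divergent = p$n_gate_divergent,
                       n_missing = p$n_missing,
                       stringsAsFactors = FALSE)
    if (nrow(p$pairs) == 0)
      return(cbind(base,
                   data.frame(percent_agreement = NA_real_,
                              high_agreement = NA, estimate = NA_real_,
                              se = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p_value = NA_real_,
                              interpretation = NA_character_,
                              status = "no_pairs",
                              stringsAsFactors = FALSE)))
    tab <- tabulate_pairs(p, it$scale)
    pa <- percent_agreement(tab)
    res <- if (item_statistic(it) == "weighted_kappa")
      weighted_kappa(tab) else cohens_kappa(tab)
    cbind(base,
          data.frame(percent_agreement = as.numeric(pa),
                     high_agreement = attr(pa, "high"),
                     estimate = res$estimate, se = res$se,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     p_value = res$p_value,
                     interpretation = res$interpretation,
                     status = res$status, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# align one tier/focus of two score tables into a units x 2 matrix
align_scores <- function(st_a, st_b, tier, focus,
                         unit_type = NA_character_) {
  pick <- function(st) {
    sel <- st$tier == tier & st$focus == focus
    if (!is.na(unit_type)) sel <- sel & st$unit_type == unit_type
    st[sel, , drop = FALSE]
  }
  a <- pick(st_a); b <- pick(st_b)
  key <- function(x) paste(x$school_id, x$route_id, x$unit_id, sep = "\r")
  shared <- intersect(key(a), key(b))
  cbind(a$value[match(shared, key(a))], b$value[match(shared, key(b))])
}

#' Score-level reliability report
#'
#' Reproduces the shape of a published domain/segment/crossing/route/
#' school reliability table: both sides' score tables are computed,
#' aligned by unit, and summarised per row with the pooled mean (SD) of
#' the scores and the single-rater two-way random-effects ICC with 95% CI
#' and p-value.  Rows: the four domains for segments and for crossings,
#' then overall segment, crossing, route, and school scores.  The ICC at
#' each tier uses the entities of that tier as ANOVA rows, so the route
#' and school rows rest on few units and carry wide intervals.
#'
#' @inheritParams item_report
#' @param definition ICC definition, `"consistency"` (default) or
#'   `"agreement"`.
#' @param aggregation,school_rollup passed to [score_records()].
#' @return a data frame with columns `row`, `unit_type`, `focus`,
#'   `n_items`, `n`, `mean`, `sd`, `icc`, `ci_low`, `ci_high`, `p_value`,
#'   `interpretation`, `status`.
#' @export
score_report <- function(records, schema, design = c("inter", "intra"),
                         definition = c("consistency", "agreement"),
                         aggregation = c("pooled", "stratified"),
                         school_rollup = c("route_mean", "pooled"),
                         raters = NULL) {
  design <- match.arg(design)
  definition <- match.arg(definition)
  sides <- split_sides(records, design, raters)
  st_a <- score_records(as_audit_records(sides$a, schema), schema,
                        aggregation, school_rollup)
  st_b <- score_records(as_audit_records(sides$b, schema), schema,
                        aggregation, school_rollup)
  info <- schema_items(schema)
  doms <- setdiff(.domains, "unscored")

  spec <- rbind(
    expand.grid(tier = "domain", focus = doms,
                unit_type = c("segment", "crossing"),
                stringsAsFactors = FALSE)[, c("tier", "focus", "unit_type")],
    data.frame(tier = c("unit", "unit", "route", "school"),
               focus = "overall",
               unit_type = c("segment", "crossing", NA, NA)))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    tier <- spec$tier[i]; focus <- spec$focus[i]
    utype <- spec$unit_type[i]
    m <- align_scores(st_a, st_b, tier, focus, utype)
    n_items <- if (tier == "domain")
      sum(info$component == utype & info$domain == focus) else NA_integer_
    label <- if (tier == "domain") paste(utype, focus)
      else if (tier == "unit") paste0(utype, "_scores")
      else paste0(tier, "_scores")
    base <- data.frame(row = label, unit_type = utype, focus = focus,
                       n_items = n_items, n = nrow(m),
                       stringsAsFactors = FALSE)
    if (nrow(m) < 2)
      return(cbind(base, data.frame(mean = NA_real_, sd = NA_real_,
                                    icc = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_,
                                    p_value = NA_real_,
                                    interpretation = NA_character_,
                                    status = "insufficient_units",
                                    stringsAsFactors = FALSE)))
    res <- icc(m, definition)
    cbind(base,
          data.frame(mean = mean(m), sd = stats::sd(as.vector(m)),
                     icc = res$estimate, ci_low = res$ci_low,
                     ci_high = res$ci_high, p_value = res$p_value,
                     interpretation = res$interpretation,
                     status = res$status, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a report as a markdown table
#'
#' Display formatting follows publication style: statistics to 3
#' decimals, percentages to 1 decimal, small p-values as "< 0.001";
#' machine-readable columns keep full precision in the underlying data
#' frame.
#'
#' @param report output of [item_report()] or [score_report()].
#' @return character vector of markdown lines.
#' @export
format_report <- function(report) {
  df <- report
  num3 <- intersect(c("estimate", "se", "ci_low", "ci_high", "icc",
                      "mean", "sd"), names(df))
  for (cn in num3) df[[cn]] <- ifelse(is.na(df[[cn]]), "-",
                                      sprintf("%.3f", df[[cn]]))
  if ("percent_agreement" %in% names(df))
    df$percent_agreement <- ifelse(is.na(df$percent_agreement), "-",
                                   sprintf("%.1f", df$percent_agreement))
  if ("p_value" %in% names(df))
    df$p_value <- ifelse(is.na(df$p_value), "-", format_p(df$p_value))
  for (cn in names(df)) df[[cn]] <- as.character(df[[cn]])
  df[is.na(df)] <- "-"
  widths <- pmax(nchar(names(df)),
                 apply(df, 2, function(x) max(nchar(x), 0)))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste0("| ", paste(mapply(pad, names(df), widths),
                               collapse = " | "), " |")
  rule <- paste0("|", paste(vapply(widths + 2, function(w)
    paste(rep("-", w), collapse = ""), ""), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(mapply(pad, r, widths), collapse = " | "), " |"))
  c(header, rule, unname(body))
}
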