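# Fixture builders: records are always generated in code at test time.

# the most supportive response for every item of a component, choosing
# gate responses that open the gated items (C1 -> underpass, score 1)
supportive_responses <- function(schema, component) {
  out <- character(0)
  for (it in schema$items) {
    if (it$component != component) next
    if (factsaudit::is_scored(it)) {
      sm <- it$score_map
      lab <- names(sm)[which.max(sm)]
      if (it$item_id == "C1") lab <- "underpass"
    } else {
      lab <- it$scale$labels[length(it$scale$labels)]
    }
    out[it$item_id] <- lab
  }
  # drop items whose gate is closed by the chosen gate responses (C14b
  # does not apply when C14a reports signals)
  app <- factsaudit::applicable_items(schema, out, component)
  out[intersect(names(out), app)]
}

# long-format record rows for one audited unit
unit_rows <- function(school, route, utype, uid, rater, pass, responses) {
  data.frame(school_id = school, route_id = route, unit_type = utype,
             unit_id = uid, rater_id = rater, pass = pass,
             item_id = names(responses), response = unname(responses),
             stringsAsFactors = FALSE)
}

# a small deterministic study: `plan` rows (school, route, utype, uid)
# audited by each rater/pass in `sides`, with per-unit responses supplied
# by `resp_fn(utype, uid, rater, pass)`
make_records <- function(schema, plan, sides, resp_fn) {
  rows <- list()
  for (i in seq_len(nrow(plan))) for (s in seq_len(nrow(sides))) {
    rows[[length(rows) + 1L]] <- unit_rows(
      plan$school[i], plan$route[i], plan$utype[i], plan$uid[i],
      sides$rater[s], sides$pass[s],
      resp_fn(plan$utype[i], plan$uid[i], sides$rater[s], sides$pass[s]))
  }
  factsaudit::as_audit_records(do.call(rbind, rows), schema)
}

two_rater_sides <- data.frame(rater = c("A", "B"), pass = c(1L, 1L))

# an all-supportive 3-school study, two raters, one route each with two
# segments and one crossing
supportive_study <- function(schema, n_schools = 3) {
  plan <- do.call(rbind, lapply(seq_len(n_schools), function(s) {
    school <- paste0("SCH", s)
    rbind(data.frame(school = school, route = "RT1", utype = "segment",
                     uid = c("seg1", "seg2")),
          data.frame(school = school, route = "RT1", utype = "crossing",
                     uid = "crs1"))
  }))
  seg <- supportive_responses(schema, "segment")
  crs <- supportive_responses(schema, "crossing")
  make_records(schema, plan, two_rater_sides,
               function(utype, uid, rater, pass)
                 if (utype == "segment") seg else crs)
}
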