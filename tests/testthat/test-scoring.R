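schema <- facts_schema()

test_that("item scores follow the supportive-direction maps", {
  s16 <- schema_item(schema, "S16")     # yes/no, yes is supportive
  expect_equal(score_item(s16, "yes"), 1)
  expect_equal(score_item(s16, "no"), 0)
  s2 <- schema_item(schema, "S2")       # 3-category ordinal
  expect_equal(score_item(s2, "1-2 m"), 2/3, tolerance = 1e-12)
  expect_equal(format_score(score_item(s2, "1-2 m")), "0.66")
  expect_error(score_item(schema_item(schema, "S17"), "yes"),
               "not included in the scoring protocol")
  expect_error(score_item(s16, "maybe"), "not on the scale")
})

test_that("band classification uses the printed 0.33/0.66 boundaries", {
  expect_equal(classify_band(0.33), "poor")
  expect_equal(classify_band(0.3301), "moderate")
  expect_equal(classify_band(0.66), "moderate")
  expect_equal(classify_band(0.661), "good")
  expect_equal(classify_band(c(0, 1/3, 2/3, 1)),
               c("poor", "moderate", "good", "good"))
  expect_error(classify_band(1.2), "\\[0, 1\\]")
  expect_error(classify_band(-0.1), "\\[0, 1\\]")
})

test_that("domain scores are means over applicable items only", {
  # all seven physical-disorder segment items at their best -> 1.0
  seg <- supportive_responses(schema, "segment")
  nd <- score_domain(seg, "physical_disorder", schema, "segment")
  expect_equal(nd$value, 1.0)
  expect_equal(nd$n, 7L)

  # street-level crossing: the quality domain keeps only C19/C20
  crs <- supportive_responses(schema, "crossing")
  crs["C1"] <- "street-level"
  crs <- crs[applicable_items(schema, crs, "crossing")]
  crs["C19"] <- "ramps both sides"      # 1.0
  crs["C20"] <- "yes"                   # 0.0
  nd2 <- score_domain(crs, "quality", schema, "crossing")
  expect_equal(nd2$n, 2L)
  expect_equal(nd2$value, 0.5)
  # ... and physical disorder has no applicable item: node absent
  expect_null(score_domain(crs, "physical_disorder", schema, "crossing"))

  # mean of {1/3, 2/3, 1} = 2/3 on the condition items
  seg2 <- seg
  seg2["S9"] <- "poor"; seg2["S10"] <- "fair"; seg2["S11"] <- "good"
  seg2["S12"] <- "none"; seg2["S13"] <- "none"
  vals <- c(1/3, 2/3, 1)
  expect_equal(score_domain(seg2, "physical_disorder", schema,
                            "segment")$value,
               mean(c(vals, 1, 1, 1, 1)), tolerance = 1e-12)

  # a missing applicable scored response invalidates scoring
  expect_error(score_domain(seg[setdiff(names(seg), "S9")],
                            "physical_disorder", schema, "segment"),
               "missing response for applicable scored item S9")
})

test_that("roll-ups are plain means with exact aggregation consistency", {
  expect_equal(score_rollup(c(0.8, 0.6), "route")$value, 0.7)
  n <- score_rollup(c(0.82, 0.82), "school")
  expect_equal(n$value, 0.82)
  expect_equal(n$band, "good")
  expect_error(score_rollup(numeric(0), "route"), "zero children")

  rec <- supportive_study(schema)
  st <- score_records(rec, schema)
  school <- st[st$tier == "school" & st$focus == "overall", ]
  routes <- st[st$tier == "route" & st$focus == "overall", ]
  for (i in seq_len(nrow(school))) {
    r <- routes[routes$school_id == school$school_id[i] &
                  routes$rater_id == school$rater_id[i], ]
    expect_equal(school$value[i], mean(r$value))
  }
})

test_that("an all-supportive study scores exactly 1 at every tier", {
  st <- score_records(supportive_study(schema), schema)
  expect_true(all(st$value == 1))
  expect_true(all(st$band == "good"))
  # every unit yields its domain nodes plus one overall node
  units <- st[st$tier %in% c("domain", "unit"), ]
  per_unit <- table(paste(units$rater_id, units$school_id, units$unit_id))
  expect_true(all(per_unit == 5))
})

test_that("unit order never changes scores; improving an item never hurts", {
  cfg <- sim_config(n_schools = 2, seed = 303)
  rec <- generate_study(cfg, schema)
  st <- score_records(rec, schema)
  shuffled <- as_audit_records(
    as.data.frame(rec)[sample(nrow(rec)), ], schema)
  st2 <- score_records(shuffled, schema)
  key <- function(x) paste(x$rater_id, x$pass, x$school_id, x$route_id,
                           x$unit_id, x$tier, x$focus)
  expect_equal(st$value[order(key(st))], st2$value[order(key(st2))])

  # monotonicity: raise one litter response to its best category
  df <- as.data.frame(rec)
  i <- which(df$item_id == "S13" & df$response != "none")[1]
  worse_val <- df$response[i]
  df2 <- df; df2$response[i] <- "none"
  stA <- score_records(as_audit_records(df, schema), schema)
  stB <- score_records(as_audit_records(df2, schema), schema)
  expect_true(all(stB$value[order(key(stB))] -
                    stA$value[order(key(stA))] >= -1e-12))
  expect_gt(sum(stB$value) - sum(stA$value), 0)
})

test_that("score table matches a brute-force flat recomputation", {
  cfg <- sim_config(n_schools = 3, routes_per_school = 2,
                    segments_per_route = 3, crossings_per_route = 2,
                    seed = 99)
  rec <- generate_study(cfg, schema)
  st <- score_records(rec, schema)
  df <- as.data.frame(rec)
  side <- df[df$rater_id == "R1" & df$pass == 1, ]
  # explicit loops over the score definitions
  units <- split(side, paste(side$school_id, side$route_id, side$unit_id))
  flat_unit <- list()
  for (u in units) {
    resp <- stats::setNames(u$response, u$item_id)
    app <- applicable_items(schema, resp, u$unit_type[1])
    dvals <- c()
    for (d in c("subjective_safety", "quality", "traffic_safety",
                "physical_disorder")) {
      sc <- c()
      for (id in app) {
        it <- schema_item(schema, id)
        if (it$domain == d) sc <- c(sc, it$score_map[[resp[[id]]]])
      }
      if (length(sc)) dvals[d] <- sum(sc) / length(sc)
    }
    flat_unit[[paste(u$school_id[1], u$route_id[1], u$unit_id[1])]] <-
      sum(dvals) / length(dvals)
  }
  got <- st[st$tier == "unit" & st$rater_id == "R1", ]
  gk <- paste(got$school_id, got$route_id, got$unit_id)
  expect_equal(got$value, as.numeric(unlist(flat_unit)[gk]),
               tolerance = 1e-12)
})

test_that("stratified aggregation averages the segment and crossing means", {
  cfg <- sim_config(n_schools = 1, routes_per_school = 1,
                    segments_per_route = 3, crossings_per_route = 2,
                    seed = 5)
  rec <- generate_study(cfg, schema)
  st_p <- score_records(rec, schema, aggregation = "pooled")
  st_s <- score_records(rec, schema, aggregation = "stratified")
  u <- st_p[st_p$tier == "unit" & st_p$rater_id == "R1", ]
  route_p <- st_p[st_p$tier == "route" & st_p$focus == "overall" &
                    st_p$rater_id == "R1", "value"]
  route_s <- st_s[st_s$tier == "route" & st_s$focus == "overall" &
                    st_s$rater_id == "R1", "value"]
  expect_equal(route_p, mean(u$value))
  expect_equal(route_s, mean(tapply(u$value, u$unit_type, mean)))
})
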