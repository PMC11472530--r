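#' Latent-category rater model
#'
#' Each audited unit/item has a latent true category; a rater reports it
#' with probability `fidelity`, otherwise errs according to the kernel.
#' `"uniform_other"` spreads all error mass uniformly over the other
#' categories; `"adjacent"` places it on the one or two neighbouring
#' categories (split equally), emulating near-miss misgradings on ordinal
#' scales — which is also what makes weighted kappa's distance
#' sensitivity visible.  `"auto"` (default) picks `adjacent` for ordinal
#' items and `uniform_other` otherwise.
#'
#' @param fidelity probability in `(0, 1]` of reporting the true
#'   category; 1 makes both sides identical.
#' @param error_kernel `"auto"`, `"uniform_other"` or `"adjacent"`.
#' @param overrides named list (by item id) of per-item
#'   `list(fidelity =, error_kernel =)` overrides.
#' @return object of class `rater_model`.
#' @export
rater_model <- function(fidelity = 0.85,
                        error_kernel = c("auto", "uniform_other",
                                         "adjacent"),
                        overrides = list()) {
  error_kernel <- match.arg(error_kernel)
  if (!is.numeric(fidelity) || fidelity <= 0 || fidelity > 1)
    stop("fidelity must lie in (0, 1]", call. = FALSE)
  structure(list(fidelity = fidelity, error_kernel = error_kernel,
                 overrides = overrides),
            class = "rater_model")
}

resolve_model <- function(model, item = NULL) {
  fid <- model$fidelity
  ker <- model$error_kernel
  if (!is.null(item) && item$item_id %in% names(model$overrides)) {
    ov <- model$overrides[[item$item_id]]
    if (!is.null(ov$fidelity)) fid <- ov$fidelity
    if (!is.null(ov$error_kernel)) ker <- ov$error_kernel
  }
  if (ker == "auto")
    ker <- if (!is.null(item) && item$scale$kind == "ordinal")
      "adjacent" else "uniform_other"
  list(fidelity = fid, error_kernel = ker)
}

#' Emission matrix of the rater model
#'
#' Row `t` is the response distribution given true category `t`.
#'
#' @param k number of categories.
#' @param fidelity probability of reporting the truth.
#' @param error_kernel `"uniform_other"` or `"adjacent"`.
#' @return a `k x k` stochastic matrix; the identity when `fidelity = 1`.
#' @export
emission_matrix <- function(k, fidelity,
                            error_kernel = c("uniform_other",
                                             "adjacent")) {
  error_kernel <- match.arg(error_kernel)
  if (k < 2) stop("need at least 2 categories", call. = FALSE)
  e <- matrix(0, k, k)
  diag(e) <- fidelity
  err <- 1 - fidelity
  for (t in seq_len(k)) {
    if (error_kernel == "uniform_other") {
      e[t, -t] <- err / (k - 1)
    } else {
      nb <- intersect(c(t - 1, t + 1), seq_len(k))
      e[t, nb] <- err / length(nb)
    }
  }
  e
}

#' Expected kappa under the latent-category model
#'
#' Builds the exact joint distribution of the two sides' responses,
#' `J = sum_t pi_t e_t %o% e_t` (both sides emit independently given the
#' truth), and evaluates kappa from its observed and chance agreement.
#' [expected_weighted_kappa()] applies the linear agreement weights
#' instead.
#'
#' @param marginals probability vector of the latent true categories (in
#'   label order).
#' @param model a [rater_model()] (its `"auto"` kernel resolves to
#'   `uniform_other` here; pass an explicit kernel for ordinal scales).
#' @return the expected statistic; `NA` with attribute
#'   `status = "undefined"` for degenerate (single-category) marginals.
#' @examples
#' expected_kappa(c(0.5, 0.5), rater_model(0.9))  # 0.64
#' @export
expected_kappa <- function(marginals, model = rater_model()) {
  expected_kappa_engine(marginals, model, weighted = FALSE)
}

#' @rdname expected_kappa
#' @export
expected_weighted_kappa <- function(marginals, model = rater_model()) {
  expected_kappa_engine(marginals, model, weighted = TRUE)
}

expected_kappa_engine <- function(marginals, model, weighted) {
  pi <- as.numeric(marginals)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("marginals must be a probability vector", call. = FALSE)
  k <- length(pi)
  if (sum(pi > 0) < 2)
    return(structure(NA_real_, status = "undefined"))
  rm <- resolve_model(model)
  e <- emission_matrix(k, rm$fidelity, rm$error_kernel)
  joint <- matrix(0, k, k)
  for (t in seq_len(k)) joint <- joint + pi[t] * outer(e[t, ], e[t, ])
  w <- if (weighted) linear_weights(k) else identity_weights(k)
  po <- sum(w * joint)
  pe <- sum(w * outer(rowSums(joint), colSums(joint)))
  if (abs(1 - pe) < 1e-15)
    return(structure(NA_real_, status = "undefined"))
  (po - pe) / (1 - pe)
}

#' Simulate paired responses for a single item
#'
#' Draws `n` latent truths from `marginals` and two conditionally
#' independent reports per truth under the rater model.
#'
#' @param n number of unit pairs.
#' @param marginals latent category probabilities.
#' @param model a [rater_model()].
#' @param labels optional response labels; defaults to category indices.
#' @return data frame with columns `truth`, `response_a`, `response_b`.
#' @export
simulate_item_pairs <- function(n, marginals, model = rater_model(),
                                labels = NULL) {
  pi <- as.numeric(marginals)
  k <- length(pi)
  rm <- resolve_model(model)
  truth <- sample.int(k, n, replace = TRUE, prob = pi)
  emit <- function(truth) {
    out <- truth
    err <- stats::runif(length(truth)) > rm$fidelity
    ne <- sum(err)
    if (ne > 0) {
      t_err <- truth[err]
      if (rm$error_kernel == "uniform_other") {
        off <- sample.int(k - 1, ne, replace = TRUE)
        out[err] <- ((t_err - 1 + off) %% k) + 1
      } else {
        up <- stats::runif(ne) < 0.5
        cand <- ifelse(up, t_err + 1, t_err - 1)
        cand[cand < 1] <- 2
        cand[cand > k] <- k - 1
        out[err] <- cand
      }
    }
    out
  }
  a <- emit(truth); b <- emit(truth)
  if (!is.null(labels)) {
    truth <- labels[truth]; a <- labels[a]; b <- labels[b]
  }
  data.frame(truth = truth, response_a = a, response_b = b,
             stringsAsFactors = FALSE)
}

#' Default latent category marginals for a schema
#'
#' Supportive-tilted marginals emulating audits of promoted safe routes,
#' where most streetscape features are in reasonable condition: category
#' `j` of a `k`-category item gets mass proportional to `2^(j-1)` in
#' supportiveness order (a binary item is 1/3 vs 2/3).  The two unit-type
#' filters use study-like mixes: crossings are mostly street-level with a
#' substantial underpass share, segments are mostly greenway.
#'
#' @param schema an `instrument_schema`.
#' @return named list, `item_id -> probability vector` in label order.
#' @export
default_marginals <- function(schema) {
  out <- lapply(schema$items, function(it) {
    k <- it$scale$n_categories
    if (it$item_id == "C1") return(c(0.5, 0.35, 0.1, 0.05))
    if (it$item_id == "S18") return(c(0.35, 0.65))
    w <- 2^(seq_len(k) - 1)
    w / sum(w)
  })
  names(out) <- vapply(schema$items, `[[`, "", "item_id")
  out
}

#' Simulation configuration
#'
#' Defines the synthetic study design: schools, routes per school, and
#' segments/crossings per route, audited under a reliability design.
#' The defaults mirror the scale of a six-school inter-rater field study
#' (120 segment and 72 crossing pairs); an intra design conventionally
#' uses `n_schools = 8`.
#'
#' @param n_schools,routes_per_school,segments_per_route,crossings_per_route
#'   design counts, all >= 1.
#' @param design `"inter"` (two raters, single pass), `"intra"` (one
#'   rater per unit, two passes) or `"both"`.
#' @param model a [rater_model()].
#' @param marginals named list of per-item latent category probabilities;
#'   default [default_marginals()] of the schema at generation time.
#' @param seed integer seed; generation is fully reproducible from it.
#' @param drift probability that a temporally variable item's latent truth
#'   changes between passes (intra designs; emulates litter, obstructions
#'   and similar features drifting over a multi-day revisit gap).
#' @param drift_items item ids subject to drift.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_schools = 6, routes_per_school = 2,
                       segments_per_route = 10, crossings_per_route = 6,
                       design = c("inter", "intra", "both"),
                       model = rater_model(), marginals = NULL,
                       seed = 1L, drift = 0,
                       drift_items = c("S4", "S12", "S13", "C3", "C4")) {
  design <- match.arg(design)
  counts <- c(n_schools, routes_per_school, segments_per_route,
              crossings_per_route)
  if (any(counts < 1)) stop("all design counts must be >= 1", call. = FALSE)
  if (drift < 0 || drift > 1) stop("drift must lie in [0, 1]", call. = FALSE)
  if (!is.null(marginals)) {
    ok <- vapply(marginals, function(p)
      all(p >= 0) && abs(sum(p) - 1) < 1e-8, TRUE)
    if (!all(ok))
      stop(sprintf("marginals for %s do not sum to 1",
                   paste(names(marginals)[!ok], collapse = ", ")),
           call. = FALSE)
  }
  structure(list(n_schools = n_schools,
                 routes_per_school = routes_per_school,
                 segments_per_route = segments_per_route,
                 crossings_per_route = crossings_per_route,
                 design = design, model = model, marginals = marginals,
                 seed = as.integer(seed), drift = drift,
                 drift_items = drift_items),
            class = "sim_config")
}

#' Generate a synthetic paired-audit study
#'
#' Draws a latent true category per (unit, item) and independent reports
#' per side under the rater model.  Gating items are emitted first, so
#' each side's set of reported items is coherent with its own gate
#' responses (a side that misclassifies an underpass as street-level does
#' not report the underpass items).  In intra designs the same latent
#' truths are reused across passes, optionally perturbed for drift items.
#'
#' @param config a [sim_config()].
#' @param schema an `instrument_schema`.
#' @return a validated `audit_records` data frame with attributes `truth`
#'   (the latent categories, one row per unit and item) and `config`.
#' @export
generate_study <- function(config, schema) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  marg <- config$marginals %||% default_marginals(schema)
  info <- schema_items(schema)
  seg_items <- lapply(which(info$component == "segment"),
                      function(i) schema$items[[i]])
  cro_items <- lapply(which(info$component == "crossing"),
                      function(i) schema$items[[i]])
  sides <- switch(config$design,
    inter = data.frame(rater = c("R1", "R2"), pass = c(1L, 1L)),
    intra = data.frame(rater = NA_character_, pass = c(1L, 2L)),
    both  = data.frame(rater = c("R1", "R2", "R1"), pass = c(1L, 1L, 2L)))

  recs <- list()
  truths <- list()
  for (s in seq_len(config$n_schools)) {
    school <- sprintf("SCH%02d", s)
    # intra: alternate which rater owns the school's repeat audits
    own <- if (s %% 2 == 1) "R1" else "R2"
    for (r in seq_len(config$routes_per_school)) {
      route <- sprintf("RT%02d", r)
      units <- rbind(
        data.frame(unit_type = "segment",
                   unit_id = sprintf("seg%02d",
                                     seq_len(config$segments_per_route))),
        data.frame(unit_type = "crossing",
                   unit_id = sprintf("crs%02d",
                                     seq_len(config$crossings_per_route))))
      for (u in seq_len(nrow(units))) {
        items <- if (units$unit_type[u] == "segment") seg_items else
          cro_items
        truth <- vapply(items, function(it)
          sample.int(it$scale$n_categories, 1,
                     prob = marg[[it$item_id]]), 0L)
        names(truth) <- vapply(items, `[[`, "", "item_id")
        truths[[length(truths) + 1L]] <- data.frame(
          school_id = school, route_id = route,
          unit_type = units$unit_type[u], unit_id = units$unit_id[u],
          item_id = names(truth), truth = unname(truth),
          stringsAsFactors = FALSE)
        for (sd in seq_len(nrow(sides))) {
          truth_side <- truth
          if (sides$pass[sd] == 2L && config$drift > 0) {
            for (id in intersect(config$drift_items, names(truth))) {
              if (stats::runif(1) < config$drift) {
                it <- items[[which(names(truth) == id)]]
                truth_side[[id]] <- sample.int(it$scale$n_categories, 1,
                                               prob = marg[[id]])
              }
            }
          }
          resp <- character(0)
          for (it in items) {
            app <- is_applicable(it, resp)
            if (!isTRUE(app)) next
            rm <- resolve_model(config$model, it)
            k <- it$scale$n_categories
            t <- truth_side[[it$item_id]]
            rep_cat <- if (stats::runif(1) <= rm$fidelity) t else {
              if (rm$error_kernel == "uniform_other") {
                ((t - 1 + sample.int(k - 1, 1)) %% k) + 1
              } else {
                nb <- intersect(c(t - 1, t + 1), seq_len(k))
                nb[sample.int(length(nb), 1)]
              }
            }
            resp[it$item_id] <- it$scale$labels[rep_cat]
          }
          rater <- if (is.na(sides$rater[sd])) own else sides$rater[sd]
          recs[[length(recs) + 1L]] <- data.frame(
            school_id = school, route_id = route,
            unit_type = units$unit_type[u], unit_id = units$unit_id[u],
            rater_id = rater, pass = sides$pass[sd],
            item_id = names(resp), response = unname(resp),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- as_audit_records(do.call(rbind, recs), schema)
  attr(out, "truth") <- do.call(rbind, truths)
  attr(out, "config") <- config
  out
}
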