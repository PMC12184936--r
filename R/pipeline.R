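# End-to-end orchestration: generate -> grid -> route -> exposure -> train
# -> interpret, each stage independently invocable from its persisted
# upstream artifacts, with machine-readable JSON-lines logging and one
# global seed from which every stage seed is derived.

STAGES <- c("generate", "grid", "route", "exposure", "train", "interpret")

#' Configuration of a full pipeline run
#'
#' A single global \code{seed} deterministically derives the per-stage seeds
#' (city generation, flow sampling, split/rebalance/training), so one number
#' reproduces a run.
#'
#' @param city a \code{\link{city_config}}
#' @param params a \code{\link{utility_params}}
#' @param model a \code{\link{model_config}}
#' @param n_flows OD flows to generate
#' @param count_mean mean commuter count per flow
#' @param suppression_threshold flows with fewer commuters are dropped
#'   (census privacy rule; default 10)
#' @param cell_area hexagon cell area in square metres (default 25 ha)
#' @param pdp_variant partial-dependence variant written by the interpret
#'   stage
#' @param seed global integer seed
#' @return a \code{run_config}
#' @export
run_config <- function(city = city_config(), params = utility_params(),
                       model = model_config(), n_flows = 2000, count_mean = 15,
                       suppression_threshold = 10, cell_area = 250000,
                       pdp_variant = "centered", seed = 1) {
  seed <- check_count(seed, "seed")
  city$seed <- derive_seed(seed, 20L)
  model$seed <- derive_seed(seed, 30L)
  structure(list(city = city, params = params, model = model,
                 n_flows = check_count(n_flows, "n_flows", min = 1L),
                 count_mean = count_mean,
                 suppression_threshold = suppression_threshold,
                 cell_area = cell_area, pdp_variant = pdp_variant, seed = seed),
            class = "run_config")
}

#' The default recovery configuration
#'
#' The study conditions under which the analysis is validated by parameter
#' recovery: the default synthetic city and utility model, 2000 flows with
#' commuter counts of mean 15 suppressed below 10, 25 ha cells, and a
#' 500-tree forest with 3 candidate features per split (the tuned values of
#' the denser-city model in the source analyses), keep-closest near-miss
#' rebalancing and a 70/30 stratified split.
#'
#' @param seed global seed
#' @param n_flows number of OD flows (default 2000)
#' @return a \code{run_config}
#' @export
recovery_config <- function(seed = 1, n_flows = 2000) {
  run_config(model = model_config(n_trees_final = 500, max_features_final = 3),
             n_flows = n_flows, seed = seed)
}

#' Write or read a run configuration as JSON
#' @param config a \code{run_config}
#' @param path JSON path
#' @return \code{read_run_config} returns a \code{run_config}
#' @export
write_run_config <- function(config, path) {
  x <- list(city = unclass(config$city),
            params = list(coefs = config$params$coefs,
                          temperature = config$params$temperature),
            model = unclass(config$model),
            n_flows = config$n_flows, count_mean = config$count_mean,
            suppression_threshold = config$suppression_threshold,
            cell_area = config$cell_area, pdp_variant = config$pdp_variant,
            seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  city <- do.call(city_config, x$city[setdiff(names(x$city), "noise_radii")])
  city$noise_radii <- as.numeric(x$city$noise_radii)
  cf <- as.matrix(x$params$coefs)
  params <- utility_params(car = cf[1, ], bicycle = cf[2, ], walk = cf[3, ],
                           temperature = x$params$temperature)
  marg <- x$model
  marg$max_features_grid <- if (is.null(marg$max_features_grid)) NULL else as.integer(marg$max_features_grid)
  model <- do.call(model_config, marg)
  cfg <- run_config(city = city, params = params, model = model,
                    n_flows = x$n_flows, count_mean = x$count_mean,
                    suppression_threshold = x$suppression_threshold,
                    cell_area = x$cell_area, pdp_variant = x$pdp_variant,
                    seed = x$seed)
  cfg
}

log_jsonl <- function(out_dir, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(out_dir, "log.jsonl"), append = TRUE)
}

need_artifact <- function(out_dir, file, producer) {
  p <- file.path(out_dir, file)
  if (!file.exists(p))
    rx_stop("dependency", sprintf("missing artifact '%s'; run stage '%s' first", file, producer),
            required_stage = producer)
  p
}

#' Run one pipeline stage from persisted artifacts
#'
#' Stages: \code{generate} (city layers + flows), \code{grid}
#' (tessellate + aggregate), \code{route} (itineraries), \code{exposure}
#' (individual trip table), \code{train} (mode forest), \code{interpret}
#' (importance + partial dependence). Each stage reads only its upstream
#' artifacts in \code{out_dir} and is idempotent.
#'
#' @param stage one of the six stage names
#' @param config a \code{run_config}
#' @param out_dir artifact directory
#' @return stage-specific summary list, invisibly
#' @export
run_stage <- function(stage, config, out_dir) {
  stage <- match.arg(stage, STAGES)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    generate = stage_generate(config, out_dir),
    grid = stage_grid(config, out_dir),
    route = stage_route(config, out_dir),
    exposure = stage_exposure(config, out_dir),
    train = stage_train(config, out_dir),
    interpret = stage_interpret(config, out_dir))
}

stage_generate <- function(config, out_dir) {
  city <- generate_city(config$city)
  write_city_geojson(city, out_dir)
  flows <- generate_flows(city, config$params, config$n_flows,
                          seed = derive_seed(config$seed, 21L),
                          count_mean = config$count_mean)
  write_flows_csv(flows, file.path(out_dir, "flows_raw.csv"))
  kept <- suppress_small_flows(flows, config$suppression_threshold)
  write_flows_csv(kept, file.path(out_dir, "flows.csv"))
  log_jsonl(out_dir, "generate", seed = config$city$seed,
            flows_generated = nrow(flows), flows_suppressed = nrow(flows) - nrow(kept),
            flows_retained = nrow(kept))
  invisible(list(flows_generated = nrow(flows), flows_retained = nrow(kept)))
}

stage_grid <- function(config, out_dir) {
  for (f in c("streets.geojson", "buildings.geojson", "pois.geojson", "noise.geojson"))
    need_artifact(out_dir, f, "generate")
  layers <- read_city_geojson(out_dir)
  scheme <- noise_scheme(config$city$noise_scheme_name)
  grid <- make_grid(config$city$bbox, cell_area = config$cell_area)
  grid <- aggregate_buildings(grid, layers$buildings)
  grid <- aggregate_streets(grid, layers$streets)
  grid <- count_pois(grid, layers$pois, categories = config$city$poi_categories)
  grid <- assign_noise(grid, layers$noise, scheme)
  write_grid(grid, file.path(out_dir, "grid.json"))
  log_jsonl(out_dir, "grid", cells = nrow(grid$cells))
  invisible(list(cells = nrow(grid$cells)))
}

stage_route <- function(config, out_dir) {
  need_artifact(out_dir, "streets.geojson", "generate")
  flows <- read_flows_csv(need_artifact(out_dir, "flows.csv", "generate"))
  layers <- read_city_geojson(out_dir)
  net <- build_network(layers$streets)
  routed <- route_flows(net, flows)
  write_itineraries_geojson(routed$itineraries, file.path(out_dir, "routes.geojson"),
                            extra = data.frame(flow_idx = routed$flow_idx,
                                               count = flows$count[routed$flow_idx]))
  log_jsonl(out_dir, "route", flows = nrow(flows),
            routed = length(routed$itineraries), dropped = nrow(routed$dropped))
  invisible(list(routed = length(routed$itineraries), dropped = nrow(routed$dropped)))
}

stage_exposure <- function(config, out_dir) {
  grid <- read_grid(need_artifact(out_dir, "grid.json", "grid"))
  rts <- read_itineraries_geojson(need_artifact(out_dir, "routes.geojson", "route"))
  scheme <- noise_scheme(config$city$noise_scheme_name)
  recs <- vector("list", length(rts$itineraries))
  for (i in seq_along(rts$itineraries)) {
    r <- trip_features(rts$itineraries[[i]], grid, scheme)
    r$count <- as.integer(rts$extra$count[i])
    recs[[i]] <- r
  }
  trips <- expand_flows(do.call(rbind, recs))
  write_trip_table(trips, file.path(out_dir, "trips.csv"))
  log_jsonl(out_dir, "exposure", trips_expanded = nrow(trips),
            flows_summarised = length(rts$itineraries))
  invisible(list(individuals = nrow(trips)))
}

stage_train <- function(config, out_dir) {
  trips <- read_trip_table(need_artifact(out_dir, "trips.csv", "exposure"))
  fit <- mode_forest(trips, config$model)
  saveRDS(fit, file.path(out_dir, "model.rds"))
  jsonlite::write_json(list(accuracy = fit$eval$accuracy,
                            accuracy_balanced = fit$eval_balanced$accuracy,
                            oob_accuracy = fit$model$oob_accuracy,
                            n_trees = fit$model$n_trees,
                            max_features = fit$model$max_features,
                            features = fit$features,
                            classes = fit$model$classes,
                            seed = config$model$seed),
                       file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(fit$eval$confusion), file.path(out_dir, "confusion.csv"),
                   row.names = FALSE)
  if (!is.null(fit$tuning))
    utils::write.csv(fit$tuning$grid, file.path(out_dir, "tuning.csv"), row.names = FALSE)
  log_jsonl(out_dir, "train", n_train_balanced = fit$n_train_balanced,
            n_test = fit$n_test, accuracy = fit$eval$accuracy,
            n_trees = fit$model$n_trees, max_features = fit$model$max_features)
  invisible(list(accuracy = fit$eval$accuracy))
}

stage_interpret <- function(config, out_dir) {
  fit <- readRDS(need_artifact(out_dir, "model.rds", "train"))
  imp <- gini_importance(fit)
  write_importance_csv(imp, file.path(out_dir, "importance.csv"))
  pdps <- lapply(fit$features, function(f) {
    tryCatch(as.data.frame(partial_dependence(fit, feature = f, variant = config$pdp_variant)),
             routexpose_invalid_config = function(e) NULL)  # degenerate feature
  })
  pdp <- do.call(rbind, pdps[!vapply(pdps, is.null, TRUE)])
  write_pdp_csv(pdp, file.path(out_dir, "pdp.csv"))
  log_jsonl(out_dir, "interpret", top_feature = imp$feature[1],
            pdp_features = length(unique(pdp$feature)))
  invisible(list(top_feature = imp$feature[1]))
}

#' Assemble the individual-level trip table in memory
#'
#' Convenience equivalent of the generate/grid/route/exposure stages without
#' touching disk: generate the city and flows, suppress small flows,
#' tessellate and aggregate, route, summarise and expand.
#'
#' @param config a \code{run_config}
#' @return list with \code{city}, \code{grid}, \code{net}, \code{flows}
#'   (post-suppression) and the expanded \code{trips} table
#' @export
assemble_trips <- function(config) {
  city <- generate_city(config$city)
  flows <- generate_flows(city, config$params, config$n_flows,
                          seed = derive_seed(config$seed, 21L),
                          count_mean = config$count_mean)
  flows <- suppress_small_flows(flows, config$suppression_threshold)
  grid <- make_grid(config$city$bbox, cell_area = config$cell_area)
  grid <- aggregate_buildings(grid, city$buildings)
  grid <- aggregate_streets(grid, city$streets)
  grid <- count_pois(grid, city$pois, categories = config$city$poi_categories)
  grid <- assign_noise(grid, city$noise, city$scheme)
  net <- build_network(city$streets)
  trips <- build_trip_table(city, grid, net, flows)
  list(city = city, grid = grid, net = net, flows = flows, trips = trips)
}

#' Run the whole pipeline
#'
#' Executes all six stages in order, each from the previous stage's
#' persisted artifacts, then writes \code{report.json} summarising row
#' counts, selected hyperparameters, held-out accuracy and the top-5
#' importances.
#'
#' @param config a \code{\link{run_config}}
#' @param out_dir artifact directory
#' @return the run report, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in STAGES) run_stage(stage, config, out_dir)
  flows_raw <- read_flows_csv(file.path(out_dir, "flows_raw.csv"))
  flows <- read_flows_csv(file.path(out_dir, "flows.csv"))
  trips <- read_trip_table(file.path(out_dir, "trips.csv"))
  ev <- jsonlite::fromJSON(file.path(out_dir, "eval.json"))
  imp <- utils::read.csv(file.path(out_dir, "importance.csv"))
  rts <- read_itineraries_geojson(file.path(out_dir, "routes.geojson"))
  report <- list(
    seed = config$seed,
    flows_generated = nrow(flows_raw),
    flows_suppressed = nrow(flows_raw) - nrow(flows),
    flows_retained = nrow(flows),
    routes_failed = nrow(flows) - length(rts$itineraries),
    individuals = nrow(trips),
    n_trees = ev$n_trees, max_features = ev$max_features,
    accuracy = ev$accuracy, accuracy_balanced = ev$accuracy_balanced,
    oob_accuracy = ev$oob_accuracy,
    top_importances = stats::setNames(as.list(imp$importance[1:min(5, nrow(imp))]),
                                      imp$feature[1:min(5, nrow(imp))])
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
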