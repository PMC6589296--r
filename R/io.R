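# --- serialization helpers -------------------------------------------------
# Parameter and config objects are stored as versioned YAML (or JSON, by
# file extension) with matrices/arrays flattened to named structures, so
# files are diff-able and editable by hand.

matrix_to_list <- function(m) {
  lapply(setNames(rownames(m), rownames(m)),
         function(r) as.list(setNames(as.numeric(m[r, ]), colnames(m))))
}

list_to_matrix <- function(lst, colnames_) {
  m <- do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r)[colnames_])))
  dimnames(m) <- list(names(lst), colnames_)
  m
}

params_to_list <- function(params) {
  disp <- lapply(setNames(CATEGORIES, CATEGORIES), function(cat_) {
    lapply(setNames(as.character(1:5), paste0("ctas", 1:5)), function(lev) {
      as.list(setNames(as.numeric(params$disposition_prob[cat_, lev, ]),
                       DISPOSITIONS))
    })
  })
  list(schema = "pesuflow/params/v1",
       ed_beds = params$ed_beds, pesu_capacity = params$pesu_capacity,
       annual_rates = as.list(params$annual_rates),
       ctas_prob = matrix_to_list(params$ctas_prob),
       disposition_prob = disp,
       service = {
         svc <- params$service
         svc$ctas <- ifelse(is.na(svc$ctas), "any", as.character(svc$ctas))
         as.list(svc)
       },
       pesu_stay = as.list(params$pesu_stay),
       pesu_eligibility = params$pesu_eligibility,
       service_scale = params$service_scale,
       horizon_hours = params$horizon_hours,
       warmup_hours = params$warmup_hours,
       n_replications = params$n_replications,
       base_seed = params$base_seed)
}

params_from_list <- function(lst) {
  if (!identical(lst$schema, "pesuflow/params/v1")) {
    stop("unsupported or missing parameter schema (expected pesuflow/params/v1)")
  }
  disp <- array(0, c(length(CATEGORIES), 5, length(DISPOSITIONS)),
                dimnames = list(CATEGORIES, 1:5, DISPOSITIONS))
  for (cat_ in CATEGORIES) {
    for (lev in 1:5) {
      disp[cat_, lev, ] <-
        as.numeric(unlist(lst$disposition_prob[[cat_]][[paste0("ctas", lev)]])[DISPOSITIONS])
    }
  }
  svc <- as.data.frame(lapply(lst$service, unlist), stringsAsFactors = FALSE)
  svc$ctas <- suppressWarnings(as.integer(ifelse(svc$ctas == "any", NA, svc$ctas)))
  for (col in c("meanlog", "sdlog", "mean_hours")) svc[[col]] <- as.numeric(svc[[col]])
  new_sim_params(
    ed_beds = lst$ed_beds, pesu_capacity = lst$pesu_capacity,
    annual_rates = unlist(lst$annual_rates)[STREAMS],
    ctas_prob = list_to_matrix(lst$ctas_prob, as.character(1:5)),
    disposition_prob = disp, service = svc,
    pesu_stay = unlist(lst$pesu_stay)[c("min", "mode", "max")],
    pesu_eligibility = lst$pesu_eligibility,
    service_scale = lst$service_scale, horizon_hours = lst$horizon_hours,
    warmup_hours = lst$warmup_hours, n_replications = lst$n_replications,
    base_seed = lst$base_seed)
}

write_structured <- function(lst, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    # full double precision so parameter files round-trip bit-exactly
    yaml::write_yaml(lst, path, precision = 17)
  }
  invisible(path)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read and write simulation parameters
#'
#' Serializes a `sim_params` object to YAML (default) or JSON (by `.json`
#' extension) under the versioned schema key `pesuflow/params/v1`.
#'
#' @param params a `sim_params` object.
#' @param path destination/source file path.
#' @return `read_parameters` returns a validated `sim_params`;
#'   `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  write_structured(params_to_list(params), path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  params_from_list(read_structured(path))
}

config_to_list <- function(config) {
  list(schema = "pesuflow/synthetic-config/v1",
       years = config$years,
       volumes = matrix_to_list(config$volumes),
       los_mean = matrix_to_list(config$los_mean),
       los_cv = as.list(config$los_cv),
       ctas_prob = matrix_to_list(config$ctas_prob),
       disposition_prob = matrix_to_list(config$disposition_prob))
}

config_from_list <- function(lst) {
  if (!identical(lst$schema, "pesuflow/synthetic-config/v1")) {
    stop("unsupported or missing config schema (expected pesuflow/synthetic-config/v1)")
  }
  cfg <- structure(list(
    years = as.character(unlist(lst$years)),
    volumes = list_to_matrix(lst$volumes, as.character(unlist(lst$years))),
    los_mean = list_to_matrix(lst$los_mean, DISPOSITIONS),
    los_cv = unlist(lst$los_cv)[CATEGORIES],
    ctas_prob = list_to_matrix(lst$ctas_prob, as.character(1:5)),
    disposition_prob = list_to_matrix(lst$disposition_prob, DISPOSITIONS)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Read and write synthetic-history configurations
#'
#' YAML/JSON serialization of a `synthetic_config` under the schema key
#' `pesuflow/synthetic-config/v1`.
#'
#' @param config a `synthetic_config`.
#' @param path destination/source file path.
#' @return `read_synthetic_config` returns a validated `synthetic_config`;
#'   `write_synthetic_config` returns `path` invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  validate_synthetic_config(config)
  write_structured(config_to_list(config), path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  config_from_list(read_structured(path))
}

# Run manifest: every CLI output directory records the command, seed and
# schema version that produced it.
write_manifest <- function(dir, command, args, seed = NA) {
  manifest <- list(tool = "pesuflow", schema = "pesuflow/manifest/v1",
                   command = command, arguments = as.list(args),
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
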