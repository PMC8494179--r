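# Configuration reading and writing (schema-versioned YAML), and the run
# manifest that makes any output file regenerable from config hash, seed and
# version.

SPEC_SCHEMA_VERSION <- 1L

spec_known_keys <- function() list(
  top = c("schema_version", "settings", "utilities", "costs", "transitions",
          "distributions", "life_table"),
  settings = names(formals(analysis_settings)),
  life_table = c("kind", "target_life_expectancy", "max_age", "makeham_a",
                 "gompertz_theta", "path", "age", "q"),
  dist = c("family", "shape_a", "shape_b", "base_value", "range_low",
           "range_high")
)

io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "thyrocea_io_error", "error",
                                     "condition")))
}

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    io_error(sprintf("unknown key%s in %s: %s",
                     if (length(unknown) > 1L) "s" else "", where,
                     paste(unknown, collapse = ", ")),
             "thyrocea_schema_error")
  }
}

#' Write a model specification to a YAML config file
#'
#' The file is schema-versioned and carries the complete parameterization;
#' [load_spec()] restores an equivalent spec. A life table produced by
#' [synthetic_life_table()] is stored as its generator parameters, any other
#' life table inline.
#'
#' @param spec A [model_spec()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_spec <- function(spec, path) {
  lt <- spec$life_table
  lt_node <- if (!is.null(attr(lt, "life_expectancy"))) {
    list(kind = "gompertz_makeham",
         target_life_expectancy = attr(lt, "life_expectancy"),
         max_age = max(lt$age),
         makeham_a = attr(lt, "makeham_a"),
         gompertz_theta = attr(lt, "gompertz_theta"))
  } else {
    list(kind = "inline", age = lt$age, q = lt$q)
  }
  node <- list(
    schema_version = SPEC_SCHEMA_VERSION,
    settings = spec$settings,
    utilities = as.list(spec$utilities),
    costs = as.list(spec$costs),
    transitions = lapply(spec$transitions, as.list),
    distributions = lapply(spec$distributions, unclass),
    life_table = lt_node
  )
  writeLines(yaml::as.yaml(node, precision = 15L), path)
  invisible(path)
}

#' Load a model specification from a YAML config file
#'
#' Parse failures, schema mismatches (wrong version or unknown keys) and
#' validation failures raise distinct condition classes
#' (`thyrocea_parse_error`, `thyrocea_schema_error`,
#' `thyrocea_validation_error`).
#'
#' @param path Path to a config written by [write_spec()] (or by hand in the
#'   same layout).
#' @return A validated `model_spec`.
#' @export
load_spec <- function(path) {
  if (!file.exists(path)) {
    io_error(sprintf("config file not found: %s", path), "thyrocea_parse_error")
  }
  node <- tryCatch(yaml::read_yaml(path), error = function(e) {
    io_error(sprintf("cannot parse config %s: %s", path, conditionMessage(e)),
             "thyrocea_parse_error")
  })
  if (!is.list(node)) {
    io_error("config must be a YAML mapping", "thyrocea_parse_error")
  }
  check_keys(node, spec_known_keys()$top, "config")
  if (is.null(node$schema_version) ||
      node$schema_version != SPEC_SCHEMA_VERSION) {
    io_error(sprintf("unsupported schema_version %s (expected %d)",
                     node$schema_version %||% "<missing>", SPEC_SCHEMA_VERSION),
             "thyrocea_schema_error")
  }
  check_keys(node$settings, spec_known_keys()$settings, "settings")
  settings <- do.call(analysis_settings, node$settings)
  utilities <- unlist(node$utilities)
  costs <- unlist(node$costs)
  transitions <- lapply(node$transitions, unlist)
  distributions <- lapply(node$distributions, function(d) {
    check_keys(d, spec_known_keys()$dist, "distribution entry")
    param_dist(d$family, d$base_value,
               d$shape_a %||% NA_real_, d$shape_b %||% NA_real_,
               d$range_low, d$range_high)
  })
  ltn <- node$life_table
  check_keys(ltn, spec_known_keys()$life_table, "life_table")
  life_table <- switch(ltn$kind %||% "inline",
    gompertz_makeham = do.call(synthetic_life_table, ltn[
      intersect(names(ltn), names(formals(synthetic_life_table)))]),
    csv = read_life_table(ltn$path),
    inline = data.frame(age = unlist(ltn$age), q = unlist(ltn$q)),
    io_error(sprintf("unknown life_table kind '%s'", ltn$kind),
             "thyrocea_schema_error")
  )
  spec <- model_spec(utilities, costs, transitions, distributions, settings,
                     life_table)
  bad <- validate_model(spec)
  if (length(bad)) {
    io_error(paste0("config failed validation:\n",
                    paste("-", bad, collapse = "\n")),
             "thyrocea_validation_error")
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run manifest
#'
#' Records everything needed to regenerate a set of outputs bit-identically:
#' the config path and its MD5 hash, the seed, the package version, the
#' structural switches in force, a timestamp, and the produced files.
#'
#' @param config_path Path of the config the run used (NA for an in-memory
#'   spec).
#' @param seed Integer seed of the run.
#' @param spec The `model_spec` that was run.
#' @param outputs Character vector of produced file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config_path, seed, spec, outputs) {
  hash <- if (!is.na(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    NA_character_
  }
  se <- spec$settings
  structure(
    list(config = config_path, config_md5 = hash, seed = seed,
         package_version = as.character(utils::packageVersion("thyrocea")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         switches = se[c("mtn_instant", "exam_states", "nf_states", "tf_arms",
                         "ct_timing", "exam_interval", "discount_cycle_offset",
                         "half_cycle_correction")],
         outputs = outputs),
    class = "run_manifest"
  )
}

#' Write or read a run manifest as JSON
#'
#' @param manifest A `run_manifest`.
#' @param path JSON file path.
#' @return `write_manifest` returns the path invisibly; `read_manifest` the
#'   manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Path to the bundled thyroid-screening config
#'
#' @return Path of the YAML config shipped with the package, equivalent to
#'   [thyroid_screening_spec()].
#' @export
thyroid_screening_config <- function() {
  system.file("extdata", "thyroid_screening.yaml", package = "thyrocea",
              mustWork = TRUE)
}
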